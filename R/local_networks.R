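#' Local networks: projecting the metaweb onto single samples
#'
#' The central operation of the package: the induced subgraph of a
#' metaweb's positive (or negative) edge set on the species present in one
#' sample, and the community-level network properties of that subgraph.
#'
#' @name local_networks_module
NULL

#' Induced local edge set
#'
#' @param metaweb a `metaweb`.
#' @param species character vector of OTU ids (must be metaweb nodes).
#' @param sign `"pos"` or `"neg"`.
#' @return edge data.frame (otu_a, otu_b) restricted to `species`.
#' @export
extract_local <- function(metaweb, species, sign = c("pos", "neg")) {
  sign <- match.arg(sign)
  missing <- setdiff(species, metaweb$nodes)
  if (length(missing))
    stop_localweb("species not in metaweb node set: ",
                  paste(utils::head(missing, 5L), collapse = ", "),
                  if (length(missing) > 5L) ", ...")
  ed <- if (sign == "pos") metaweb$positive_edges else metaweb$negative_edges
  keep <- ed$otu_a %in% species & ed$otu_b %in% species
  ed[keep, c("otu_a", "otu_b"), drop = FALSE]
}

local_properties_one <- function(metaweb, species, steps, modularity = TRUE) {
  lapply(c(pos = "pos", neg = "neg"), function(sgn) {
    graph_properties(extract_local(metaweb, species, sgn),
                     total_otus = length(species), steps = steps,
                     modularity = modularity)
  })
}

#' Network profile of one sample
#'
#' Computes, on both the positive and the negative induced subgraphs, the
#' community-level properties of [graph_properties()], and the
#' co-occurrence / co-exclusion proportions: the induced edge counts
#' divided by C(S, 2), where S is the number of the sample's species
#' within the (filtered) metaweb universe. Properties of empty subgraphs
#' are missing (NA), never 0.
#'
#' @param metaweb a `metaweb`.
#' @param species OTU ids present in the sample (subset of the metaweb
#'   nodes).
#' @param sample_id identifier recorded in the output row.
#' @return one-row data.frame (columns suffixed `_pos` / `_neg`).
#' @export
local_profile <- function(metaweb, species, sample_id = NA_character_) {
  S <- length(species)
  if (S < 2L)
    stop_localweb("sample '", sample_id, "' has fewer than 2 metaweb species; ",
                  "edge proportions are undefined")
  pr <- local_properties_one(metaweb, species, steps = metaweb$steps)
  den <- choose(S, 2)
  fields <- c("n_nodes", "n_edges", "n_components", "modularity",
              "clustering", "avg_path_length")
  row <- c(list(sample_id = sample_id, richness_S = S),
           stats::setNames(lapply(fields, function(f) pr$pos[[f]]),
                           paste0(fields, "_pos")),
           stats::setNames(lapply(fields, function(f) pr$neg[[f]]),
                           paste0(fields, "_neg")),
           list(cooccurrence_proportion = pr$pos$n_edges / den,
                coexclusion_proportion = pr$neg$n_edges / den))
  as.data.frame(row, stringsAsFactors = FALSE)
}

#' Network profiles of every sample in a presence matrix
#'
#' One [local_profile()] row per sample; per-sample failures (e.g. fewer
#' than two metaweb species present) are logged and returned as missing
#' rows. OTUs of the presence matrix outside the metaweb universe are
#' ignored.
#'
#' @param metaweb a `metaweb`.
#' @param presence samples x OTUs 0/1 matrix from the metaweb's stratum.
#' @return data.frame of class `local_profiles`.
#' @export
profile_all <- function(metaweb, presence) {
  universe <- intersect(colnames(presence), metaweb$nodes)
  rows <- vector("list", nrow(presence))
  failed <- character(0)
  for (i in seq_len(nrow(presence))) {
    sid <- rownames(presence)[i]
    species <- universe[presence[i, universe] > 0]
    rows[[i]] <- tryCatch(local_profile(metaweb, species, sample_id = sid),
                          error = function(e) {
                            failed <<- c(failed, sid)
                            out <- local_profile_na_row(sid, length(species))
                            out
                          })
  }
  if (length(failed))
    log_msg("profiles missing for ", length(failed), " sample(s): ",
            paste(utils::head(failed, 5L), collapse = ", "))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "stratum") <- metaweb$stratum
  class(out) <- c("local_profiles", "data.frame")
  out
}

local_profile_na_row <- function(sample_id, S) {
  fields <- c("n_nodes", "n_edges", "n_components", "modularity",
              "clustering", "avg_path_length")
  row <- c(list(sample_id = sample_id, richness_S = S),
           stats::setNames(rep(list(NA_real_), 12L),
                           c(paste0(fields, "_pos"), paste0(fields, "_neg"))),
           list(cooccurrence_proportion = NA_real_,
                coexclusion_proportion = NA_real_))
  as.data.frame(row, stringsAsFactors = FALSE)
}

#' Range summary of local network properties
#'
#' Per-property minimum, mean and maximum across samples (missing values
#' excluded), mirroring the usual range table reported alongside local
#' profiles.
#'
#' @param object a `local_profiles` table.
#' @param ... unused.
#' @return data.frame with columns property, min, mean, max, n.
#' @export
summary.local_profiles <- function(object, ...) {
  num <- setdiff(names(object), "sample_id")
  out <- do.call(rbind, lapply(num, function(p) {
    v <- object[[p]]
    v <- v[!is.na(v)]
    data.frame(property = p,
               min = if (length(v)) min(v) else NA_real_,
               mean = if (length(v)) mean(v) else NA_real_,
               max = if (length(v)) max(v) else NA_real_,
               n = length(v), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.local_profiles <- function(x, ...) {
  cat("Local network profiles: ", nrow(x), " sample(s)",
      if (!is.null(attr(x, "stratum"))) paste0(" [", attr(x, "stratum"), "]"),
      "\n", sep = "")
  print.data.frame(utils::head(x, 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}
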