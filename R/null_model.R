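#' Randomization null models for local network properties
#'
#' Each randomization draws an equal-richness species set uniformly (or
#' occurrence-frequency weighted) without replacement from the metaweb
#' node pool, recomputes the requested local properties on the induced
#' subgraphs, and expresses the observed values as z-scores against the
#' null distribution. |z| > 2 is the conventional deviation band.
#'
#' @name null_model_module
NULL

# property name -> (sign subgraph, field); proportions need no graph build
null_property_plan <- function(properties) {
  known_fields <- c("n_nodes", "n_edges", "n_components", "modularity",
                    "clustering", "avg_path_length")
  plan <- lapply(properties, function(p) {
    if (p %in% c("cooccurrence_proportion", "coexclusion_proportion")) {
      list(name = p, sign = if (p == "cooccurrence_proportion") "pos" else "neg",
           field = "proportion")
    } else if (grepl("_(pos|neg)$", p)) {
      field <- sub("_(pos|neg)$", "", p)
      if (!field %in% known_fields)
        stop_localweb("unknown property '", p, "'")
      list(name = p, sign = sub("^.*_", "", p), field = field)
    } else stop_localweb("unknown property '", p, "'")
  })
  plan
}

#' Null-model z-scores for one sample
#'
#' @param metaweb a `metaweb`.
#' @param sample_species the sample's species (subset of metaweb nodes).
#' @param properties property names as in the profile columns, e.g.
#'   `"modularity_pos"`, `"clustering_pos"`, `"avg_path_length_neg"`,
#'   `"coexclusion_proportion"`.
#' @param n_rand number of randomizations (default 1000).
#' @param seed integer RNG seed.
#' @param weights optional per-node sampling weights (e.g. occurrence
#'   frequencies) for the weighted null; uniform when `NULL`.
#' @param sample_id identifier carried into the output.
#' @return data.frame of class `null_scores`: sample_id, property,
#'   observed, null_mean, null_sd, z, n_randomizations, n_used, class
#'   (deviation band at |z| = 2). `z` is NA (flagged `undefined`) when the
#'   null distribution is degenerate.
#' @export
null_zscores <- function(metaweb, sample_species,
                         properties = c("modularity_pos", "clustering_pos",
                                        "coexclusion_proportion"),
                         n_rand = 1000L, seed = 1L, weights = NULL,
                         sample_id = NA_character_) {
  if (n_rand < 2L) stop_localweb("n_rand must be at least 2")
  missing <- setdiff(sample_species, metaweb$nodes)
  if (length(missing))
    stop_localweb("species not in metaweb node set: ",
                  paste(utils::head(missing, 5L), collapse = ", "))
  S <- length(sample_species)
  if (S < 2L) stop_localweb("need at least 2 species")
  plan <- null_property_plan(properties)
  signs_needed <- unique(vapply(plan, `[[`, character(1), "sign"))
  need_graph <- vapply(plan, function(p) p$field != "proportion", logical(1))
  need_modularity <- any(vapply(plan, function(p) p$field == "modularity", logical(1)))

  nodes <- metaweb$nodes
  n_nodes <- length(nodes)
  edge_idx <- list(
    pos = cbind(match(metaweb$positive_edges$otu_a, nodes),
                match(metaweb$positive_edges$otu_b, nodes)),
    neg = cbind(match(metaweb$negative_edges$otu_a, nodes),
                match(metaweb$negative_edges$otu_b, nodes)))
  if (!is.null(weights)) {
    if (length(weights) != n_nodes)
      stop_localweb("weights must have one entry per metaweb node")
    weights <- weights / sum(weights)
  }
  den <- choose(S, 2)

  eval_set <- function(member_idx) {
    inset <- logical(n_nodes); inset[member_idx] <- TRUE
    vals <- numeric(length(plan))
    for (sgn in signs_needed) {
      ei <- edge_idx[[sgn]]
      keep <- if (nrow(ei)) inset[ei[, 1L]] & inset[ei[, 2L]] else logical(0)
      sub <- ei[keep, , drop = FALSE]
      gp <- NULL
      for (k in seq_along(plan)) {
        p <- plan[[k]]
        if (p$sign != sgn) next
        if (p$field == "proportion") {
          vals[k] <- nrow(sub) / den
        } else {
          if (is.null(gp)) {
            edges <- cbind(as.character(sub[, 1L]), as.character(sub[, 2L]))
            gp <- graph_properties(edges, total_otus = S,
                                   steps = metaweb$steps,
                                   modularity = need_modularity)
          }
          vals[k] <- as.numeric(gp[[p$field]])
        }
      }
    }
    vals
  }

  observed <- eval_set(match(sample_species, nodes))
  nulls <- with_seed(seed, {
    vapply(seq_len(n_rand), function(i) {
      draw <- sample.int(n_nodes, S, prob = weights)
      eval_set(draw)
    }, numeric(length(plan)))
  })
  if (is.null(dim(nulls))) nulls <- matrix(nulls, nrow = 1L)

  out <- do.call(rbind, lapply(seq_along(plan), function(k) {
    v <- nulls[k, ]
    used <- v[!is.na(v)]
    mu <- if (length(used)) mean(used) else NA_real_
    sdv <- if (length(used) > 1L) stats::sd(used) else NA_real_
    z <- if (!is.na(sdv) && sdv > 0 && !is.na(observed[k]))
      (observed[k] - mu) / sdv else NA_real_
    data.frame(sample_id = sample_id, property = plan[[k]]$name,
               observed = observed[k], null_mean = mu, null_sd = sdv,
               z = z, n_randomizations = n_rand, n_used = length(used),
               stringsAsFactors = FALSE)
  }))
  out$class <- deviation_class(out$z)
  class(out) <- c("null_scores", "data.frame")
  out
}

#' Null-model z-scores for every sample
#'
#' Convenience wrapper over [null_zscores()]; each sample gets a distinct
#' deterministic sub-seed derived from `seed`.
#'
#' @inheritParams null_zscores
#' @param presence samples x OTUs 0/1 matrix.
#' @export
null_zscores_all <- function(metaweb, presence,
                             properties = c("modularity_pos", "clustering_pos",
                                            "coexclusion_proportion"),
                             n_rand = 1000L, seed = 1L, weights = NULL) {
  universe <- intersect(colnames(presence), metaweb$nodes)
  rows <- lapply(seq_len(nrow(presence)), function(i) {
    sid <- rownames(presence)[i]
    species <- universe[presence[i, universe] > 0]
    if (length(species) < 2L) {
      log_msg("null model skipped for sample ", sid, " (fewer than 2 species)")
      return(NULL)
    }
    null_zscores(metaweb, species, properties = properties, n_rand = n_rand,
                 seed = (seed + i) %% .Machine$integer.max, weights = weights,
                 sample_id = sid)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("null_scores", "data.frame")
  out
}

#' Deviation band of a z-score
#'
#' `higher` if z > band, `lower` if z < -band, `within` otherwise (the
#' band edges themselves count as within); missing z propagates as
#' `undefined`.
#'
#' @param z numeric vector of z-scores.
#' @param band positive threshold (default 2).
#' @return character vector in {"higher", "lower", "within", "undefined"}.
#' @export
deviation_class <- function(z, band = 2) {
  if (!is.numeric(band) || band <= 0) stop_localweb("band must be positive")
  out <- rep("within", length(z))
  out[z > band] <- "higher"
  out[z < -band] <- "lower"
  out[is.na(z)] <- "undefined"
  out
}
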