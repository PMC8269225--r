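#' Metawebs: stratum-level signed association networks
#'
#' A metaweb holds, for one stratum of the survey (typically a country),
#' the full filtered species pool as nodes and the significant positive
#' (co-occurrence) and negative (co-exclusion) pairs as signed edge sets,
#' plus a module partition of the positive-edge subgraph.
#'
#' @name metaweb_module
NULL

#' Assemble a metaweb from an association table
#'
#' Positive edges are the pairs classified `positive`, negative edges the
#' pairs classified `negative`. The node set is the full filtered OTU pool
#' (including edge-less species, retained as denominators for edge
#' proportions). Modules are detected on the positive-edge subgraph by
#' [walktrap_communities()]; negative edges are kept as an overlay and do
#' not enter the partition.
#'
#' @param assoc an `assoc_table` (see [all_pair_associations()]).
#' @param nodes character vector of all filtered OTU ids.
#' @param stratum label for the stratum (e.g. country).
#' @param steps walktrap random-walk length.
#' @return object of class `metaweb`.
#' @export
build_metaweb <- function(assoc, nodes, stratum = "all", steps = 4L) {
  if (!all(c(assoc$otu_a, assoc$otu_b) %in% nodes))
    stop_localweb("association table mentions OTUs outside the node set")
  pos <- assoc[assoc$sign == "positive", c("otu_a", "otu_b", "p_gt"), drop = FALSE]
  neg <- assoc[assoc$sign == "negative", c("otu_a", "otu_b", "p_lt"), drop = FALSE]
  names(pos)[3L] <- "p_value"; names(neg)[3L] <- "p_value"
  rownames(pos) <- NULL; rownames(neg) <- NULL
  modules <- NULL; Q <- NA_real_; merges <- NULL
  if (nrow(pos) > 0L) {
    part <- walktrap_communities(pos[, 1:2], steps = steps)
    modules <- part$assignment
    Q <- part$Q
    merges <- part$merges
  }
  out <- list(stratum = stratum, nodes = nodes,
              positive_edges = pos, negative_edges = neg,
              modules = modules, Q = Q, merges = merges, steps = steps)
  class(out) <- "metaweb"
  out
}

#' @export
print.metaweb <- function(x, ...) {
  cat("Metaweb [", x$stratum, "]: ", length(x$nodes), " nodes, ",
      nrow(x$positive_edges), " co-occurrence edge(s), ",
      nrow(x$negative_edges), " co-exclusion edge(s)\n", sep = "")
  if (!is.null(x$modules)) {
    sizes <- sort(table(x$modules), decreasing = TRUE)
    cat("Modules (positive subgraph): ", length(sizes), ", sizes ",
        paste(as.integer(sizes), collapse = ", "),
        "; Q = ", format(x$Q, digits = 4), "\n", sep = "")
  }
  invisible(x)
}

#' Global properties of a metaweb
#'
#' Runs [graph_properties()] on the positive and negative edge sets, with
#' the full node pool as the proportion denominator.
#'
#' @param object a `metaweb`.
#' @param ... unused.
#' @return list with components `positive` and `negative`.
#' @export
summary.metaweb <- function(object, ...) {
  S <- length(object$nodes)
  out <- list(stratum = object$stratum,
              n_nodes = S,
              positive = graph_properties(object$positive_edges, S, steps = object$steps),
              negative = graph_properties(object$negative_edges, S, steps = object$steps))
  class(out) <- "summary.metaweb"
  out
}

#' @export
print.summary.metaweb <- function(x, ...) {
  cat("Metaweb [", x$stratum, "], ", x$n_nodes, " nodes\n", sep = "")
  cat("-- co-occurrence subgraph --\n"); print(x$positive)
  cat("-- co-exclusion subgraph --\n"); print(x$negative)
  invisible(x)
}

#' Per-sample completeness of each metaweb module
#'
#' completeness(s, m) = |module m intersected with the OTUs present in s| /
#' |module m|.
#'
#' @param metaweb a `metaweb` with a module partition.
#' @param presence samples x OTUs 0/1 matrix.
#' @return samples x modules matrix of fractions in \[0, 1\].
#' @export
module_completeness <- function(metaweb, presence) {
  if (is.null(metaweb$modules))
    stop_localweb("metaweb has no module partition (no positive edges)")
  mods <- sort(unique(metaweb$modules))
  out <- matrix(0, nrow(presence), length(mods),
                dimnames = list(rownames(presence), paste0("module_", mods)))
  for (k in seq_along(mods)) {
    members <- names(metaweb$modules)[metaweb$modules == mods[k]]
    members_here <- intersect(members, colnames(presence))
    hit <- if (length(members_here))
      rowSums(presence[, members_here, drop = FALSE] > 0) else 0
    out[, k] <- hit / length(members)
  }
  out
}

#' Environmental summary of metaweb modules
#'
#' For every OTU in a module, its environmental position is the mean of a
#' metadata variable over the samples where the OTU occurs; modules are
#' then summarised by the distribution of those per-OTU means (median,
#' quartiles, range). The classic use is maximum temperature, giving the
#' thermal range each module occupies.
#'
#' @param metaweb a `metaweb` with modules.
#' @param presence samples x OTUs 0/1 matrix.
#' @param metadata data.frame with `sample_id` and the variable.
#' @param variable metadata column name (default `"max_temperature"`).
#' @return list with `per_otu` (otu, module, mean value) and `per_module`
#'   (module, n_otus, median, q1, q3, min, max).
#' @export
module_env_summary <- function(metaweb, presence, metadata,
                               variable = "max_temperature") {
  if (is.null(metaweb$modules)) stop_localweb("metaweb has no module partition")
  if (!variable %in% names(metadata))
    stop_localweb("variable '", variable, "' not in metadata")
  env <- stats::setNames(metadata[[variable]], metadata$sample_id)
  env <- env[rownames(presence)]
  otus <- intersect(names(metaweb$modules), colnames(presence))
  absent <- setdiff(names(metaweb$modules), otus)
  vals <- vapply(otus, function(o) {
    here <- presence[, o] > 0 & !is.na(env)
    if (!any(here)) NA_real_ else mean(env[here])
  }, numeric(1))
  nowhere <- otus[is.na(vals)]
  if (length(nowhere) || length(absent))
    warning(length(nowhere) + length(absent),
            " module OTU(s) present in no sample were excluded", call. = FALSE)
  per_otu <- data.frame(otu = otus, module = as.integer(metaweb$modules[otus]),
                        mean_value = vals, stringsAsFactors = FALSE)
  per_otu <- per_otu[!is.na(per_otu$mean_value), , drop = FALSE]
  agg <- split(per_otu$mean_value, per_otu$module)
  per_module <- data.frame(
    module = as.integer(names(agg)),
    n_otus = vapply(agg, length, integer(1)),
    median = vapply(agg, stats::median, numeric(1)),
    q1 = vapply(agg, function(v) unname(stats::quantile(v, 0.25)), numeric(1)),
    q3 = vapply(agg, function(v) unname(stats::quantile(v, 0.75)), numeric(1)),
    min = vapply(agg, min, numeric(1)),
    max = vapply(agg, max, numeric(1)),
    row.names = NULL)
  list(per_otu = per_otu, per_module = per_module)
}

#' Write / read a metaweb as plain-text tables
#'
#' Edges as TSV (otu_a, otu_b, sign, p_value), modules as a node/module
#' TSV; the full node pool travels in the module file (module NA for nodes
#' outside the positive subgraph).
#'
#' @param metaweb a `metaweb`.
#' @param edges_path,modules_path output paths.
#' @export
write_metaweb <- function(metaweb, edges_path, modules_path) {
  ed <- rbind(
    if (nrow(metaweb$positive_edges))
      cbind(metaweb$positive_edges[, 1:2], sign = "positive",
            p_value = metaweb$positive_edges$p_value),
    if (nrow(metaweb$negative_edges))
      cbind(metaweb$negative_edges[, 1:2], sign = "negative",
            p_value = metaweb$negative_edges$p_value))
  if (is.null(ed))
    ed <- data.frame(otu_a = character(0), otu_b = character(0),
                     sign = character(0), p_value = numeric(0))
  utils::write.table(ed, edges_path, sep = "\t", quote = FALSE, row.names = FALSE)
  mods <- data.frame(otu = metaweb$nodes,
                     module = ifelse(metaweb$nodes %in% names(metaweb$modules),
                                     metaweb$modules[metaweb$nodes], NA_integer_))
  utils::write.table(mods, modules_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(edges_path, modules_path))
}

#' @rdname write_metaweb
#' @param stratum stratum label for the reread metaweb.
#' @param steps walktrap random-walk length used to re-derive the partition.
#' @export
read_metaweb <- function(edges_path, modules_path, stratum = "all", steps = 4L) {
  ed <- utils::read.delim(edges_path, stringsAsFactors = FALSE)
  mods <- utils::read.delim(modules_path, stringsAsFactors = FALSE)
  assoc <- data.frame(otu_a = ed$otu_a, otu_b = ed$otu_b,
                      p_gt = ifelse(ed$sign == "positive", ed$p_value, 1),
                      p_lt = ifelse(ed$sign == "negative", ed$p_value, 1),
                      sign = ed$sign, stringsAsFactors = FALSE)
  build_metaweb(assoc, nodes = mods$otu, stratum = stratum, steps = steps)
}
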