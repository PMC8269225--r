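#' Diversity and ordination primitives
#'
#' Shannon diversity, Bray-Curtis dissimilarity, non-metric multidimensional
#' scaling, ANOSIM, Mantel tests and multivariate dispersion: the standard
#' community-ecology toolkit used before and after the network stages.
#'
#' @name diversity
NULL

#' Shannon diversity per sample
#'
#' H' = -sum p log p in natural logarithms (nats), with p the relative
#' abundance of each OTU in the sample.
#'
#' @param m samples x OTUs count matrix with positive row sums.
#' @return named numeric vector of H' per sample.
#' @export
shannon_diversity <- function(m) {
  validate_community_matrix(m, require_positive_rows = TRUE)
  vegan::diversity(m, index = "shannon", base = exp(1))
}

#' Bray-Curtis dissimilarity matrix
#'
#' BC(a, b) = sum|a_i - b_i| / sum(a_i + b_i), returned as a full symmetric
#' matrix with a zero diagonal. Pairs of all-zero samples are undefined and
#' flagged with a warning (NaN).
#'
#' @param m samples x OTUs count matrix, at least 2 samples.
#' @export
bray_curtis <- function(m) {
  validate_community_matrix(m)
  if (nrow(m) < 2L) stop_localweb("need at least 2 samples")
  d <- as.matrix(vegan::vegdist(m, method = "bray"))
  if (anyNA(d) || any(is.nan(d)))
    warning("Bray-Curtis undefined for pair(s) of all-zero samples", call. = FALSE)
  d
}

as_square_dissimilarity <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop_localweb("expected a square dissimilarity matrix or 'dist' object")
  if (max(abs(d - t(d))) > 1e-8) stop_localweb("dissimilarity matrix must be symmetric")
  d
}

#' Mantel test between two dissimilarity matrices
#'
#' Pearson correlation of the off-diagonal upper triangles, with a
#' permutation p-value obtained by permuting the rows/columns of `d2`
#' jointly. When the number of samples is at most 7 the full permutation
#' space is enumerated and the p-value is exact; otherwise `n_perm`
#' random permutations are drawn (deterministic given `seed`) and the
#' p-value uses the standard (count + 1)/(n_perm + 1) estimator. The test
#' is one-sided towards positive correlation.
#'
#' @param d1,d2 square dissimilarity matrices (or `dist`) on the same
#'   samples.
#' @param n_perm number of random permutations when enumeration is not
#'   feasible.
#' @param seed integer RNG seed.
#' @return list with `r`, `p`, `n_perm` and `exact`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999L, seed = 1L) {
  d1 <- as_square_dissimilarity(d1)
  d2 <- as_square_dissimilarity(d2)
  n <- nrow(d1)
  if (nrow(d2) != n) stop_localweb("dissimilarity matrices must match in size")
  if (!is.null(rownames(d1)) && !is.null(rownames(d2)) &&
      !identical(rownames(d1), rownames(d2))) {
    if (!setequal(rownames(d1), rownames(d2)))
      stop_localweb("dissimilarity matrices are on different sample sets")
    d2 <- d2[rownames(d1), rownames(d1)]
  }
  ut <- upper.tri(d1)
  x <- d1[ut]
  if (stats::sd(x) == 0 || stats::sd(d2[ut]) == 0)
    stop_localweb("Mantel r undefined: constant dissimilarities")
  r_obs <- stats::cor(x, d2[ut])
  stat <- function(perm) stats::cor(x, d2[perm, perm][ut])
  if (n <= 7L) {
    perms <- all_permutations(n)
    rs <- apply(perms, 1L, stat)
    list(r = r_obs, p = mean(rs >= r_obs), n_perm = nrow(perms), exact = TRUE)
  } else {
    rs <- with_seed(seed, replicate(n_perm, stat(sample.int(n))))
    list(r = r_obs, p = (1 + sum(rs >= r_obs)) / (n_perm + 1),
         n_perm = n_perm, exact = FALSE)
  }
}

#' Non-metric multidimensional scaling
#'
#' Kruskal stress-1 minimisation of a dissimilarity matrix via vegan's
#' monotone-regression engine, taking the best of `restarts` random starts.
#' Deterministic given `seed`.
#'
#' @param d square dissimilarity matrix or `dist`.
#' @param k number of ordination dimensions (default 2).
#' @param seed integer RNG seed.
#' @param restarts number of random restarts (default 20).
#' @return list with `scores` (samples x k) and `stress` (fraction).
#' @export
nmds_ordination <- function(d, k = 2L, seed = 1L, restarts = 20L) {
  d <- stats::as.dist(as_square_dissimilarity(d))
  fit <- with_seed(seed, suppressWarnings(
    vegan::metaMDS(d, k = k, try = restarts, trymax = restarts, trace = 0)
  ))
  if (!isTRUE(fit$converged) && fit$stress > 1e-3)
    warning("nMDS did not converge within the restart budget; best solution returned",
            call. = FALSE)
  sc <- vegan::scores(fit, display = "sites")
  list(scores = sc, stress = fit$stress)
}

anosim_statistic <- function(d, groups) {
  n <- nrow(d)
  ut <- upper.tri(d)
  rk <- rank(d[ut])  # average ranks on ties
  same <- outer(groups, groups, "==")[ut]
  (mean(rk[!same]) - mean(rk[same])) / (n * (n - 1) / 4)
}

#' Analysis of similarities (ANOSIM)
#'
#' Clarke's R: the difference between mean between-group and mean
#' within-group dissimilarity ranks, scaled by n(n-1)/4 so that R lies in
#' \[-1, 1\] and equals 1 under perfect group separation. The p-value is by
#' permutation of group labels: exhaustive over all label permutations when
#' there are at most 7 samples, sampled otherwise.
#'
#' @param d square dissimilarity matrix or `dist`.
#' @param groups group label vector (at least 2 groups of at least 2).
#' @param n_perm number of random permutations.
#' @param seed integer RNG seed.
#' @return list with `R`, `p`, `n_perm`, `exact`.
#' @export
anosim_test <- function(d, groups, n_perm = 999L, seed = 1L) {
  d <- as_square_dissimilarity(d)
  groups <- as.character(groups)
  if (length(groups) != nrow(d)) stop_localweb("one group label per sample required")
  tab <- table(groups)
  if (length(tab) < 2L) stop_localweb("ANOSIM needs at least two groups")
  if (any(tab < 2L)) stop_localweb("every group needs at least two members")
  r_obs <- anosim_statistic(d, groups)
  n <- nrow(d)
  if (n <= 7L) {
    perms <- all_permutations(n)
    rs <- apply(perms, 1L, function(p) anosim_statistic(d, groups[p]))
    list(R = r_obs, p = mean(rs >= r_obs), n_perm = nrow(perms), exact = TRUE)
  } else {
    rs <- with_seed(seed, replicate(n_perm, anosim_statistic(d, groups[sample.int(n)])))
    list(R = r_obs, p = (1 + sum(rs >= r_obs)) / (n_perm + 1),
         n_perm = n_perm, exact = FALSE)
  }
}

#' Multivariate dispersion (distance to group centroid)
#'
#' Principal-coordinates embedding of the dissimilarity matrix (negative
#' eigenvalues handled by vegan's real/imaginary split), then the distance
#' of every sample to its group centroid in that space.
#'
#' @param d square dissimilarity matrix or `dist`.
#' @param groups group label vector.
#' @return list with `distances` (per sample) and `group_means`.
#' @export
betadispersion <- function(d, groups) {
  d <- as_square_dissimilarity(d)
  groups <- as.character(groups)
  if (length(groups) != nrow(d)) stop_localweb("one group label per sample required")
  if (any(table(groups) < 2L))
    warning("group(s) of size 1: their dispersion is 0 by construction", call. = FALSE)
  bd <- vegan::betadisper(stats::as.dist(d), groups, type = "centroid")
  dist_vec <- bd$distances
  names(dist_vec) <- rownames(d)
  list(distances = dist_vec,
       group_means = tapply(dist_vec, groups, mean))
}
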