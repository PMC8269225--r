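#' Exact probabilistic pairwise association model
#'
#' For two taxa occupying n1 and n2 of N sites, the number of shared sites J
#' under independent placement follows the exact combinatorial law
#' P(J = j) = C(n1, j) C(N - n1, n2 - j) / C(N, n2), a hypergeometric
#' distribution. Tail sums of this law give the probability of co-occurring
#' at a frequency less (p_lt) or greater (p_gt) than observed; thresholding
#' the raw tails classifies a pair as a significant co-occurrence
#' (positive), co-exclusion (negative) or neither.
#'
#' @name pair_association_model
NULL

check_pair_counts <- function(N, n1, n2) {
  if (any(!is.finite(N)) || any(N < 1) || any(N != floor(N)))
    stop_localweb("N must be a positive integer")
  if (any(n1 < 0) || any(n1 > N) || any(n1 != floor(n1)))
    stop_localweb("n1 must be an integer in [0, N]")
  if (any(n2 < 0) || any(n2 > N) || any(n2 != floor(n2)))
    stop_localweb("n2 must be an integer in [0, N]")
}

#' Probability mass of the shared-site count
#'
#' Computed in log-space (log-gamma binomial coefficients), so it is stable
#' for metacommunities of thousands of sites. Values of `j` outside the
#' support \[max(0, n1 + n2 - N), min(n1, n2)\] return 0. Vectorised over
#' all arguments.
#'
#' @param N number of sites.
#' @param n1,n2 occupancy counts of the two taxa.
#' @param j number of shared sites.
#' @return P(J = j).
#' @export
cooccurrence_pmf <- function(N, n1, n2, j) {
  check_pair_counts(N, n1, n2)
  len <- max(length(N), length(n1), length(n2), length(j))
  N <- rep_len(N, len); n1 <- rep_len(n1, len)
  n2 <- rep_len(n2, len); j <- rep_len(j, len)
  out <- numeric(len)
  ok <- j >= pmax(0, n1 + n2 - N) & j <= pmin(n1, n2) & j == floor(j)
  out[ok] <- exp(lchoose(n1[ok], j[ok]) + lchoose(N[ok] - n1[ok], n2[ok] - j[ok]) -
                   lchoose(N[ok], n2[ok]))
  out
}

#' Lower and upper tail probabilities for an observed shared-site count
#'
#' Both tails include the observed count, so p_lt + p_gt = 1 + P(J = j_obs).
#'
#' @param N number of sites.
#' @param n1,n2 occupancy counts.
#' @param j_obs observed number of shared sites (within the support).
#' @return named numeric vector `c(p_lt, p_gt)`.
#' @export
pair_pvalues <- function(N, n1, n2, j_obs) {
  check_pair_counts(N, n1, n2)
  lo <- max(0, n1 + n2 - N); hi <- min(n1, n2)
  if (j_obs < lo || j_obs > hi || j_obs != floor(j_obs))
    stop_localweb("j_obs = ", j_obs, " outside the support [", lo, ", ", hi, "]")
  pmf <- cooccurrence_pmf(N, n1, n2, lo:hi)
  k <- lo:hi
  c(p_lt = min(1, sum(pmf[k <= j_obs])),
    p_gt = min(1, sum(pmf[k >= j_obs])))
}

#' Classify a pair from its tail probabilities
#'
#' Positive iff p_gt < alpha; negative iff p_lt < alpha; otherwise none.
#' Comparisons are strict, so a tail exactly at alpha is not significant.
#' Since p_lt + p_gt >= 1, a pair can never be both.
#'
#' @param p_lt,p_gt tail probabilities (vectorised).
#' @param alpha significance level in (0, 0.5).
#' @return character vector in {"positive", "negative", "none"}.
#' @export
classify_pair <- function(p_lt, p_gt, alpha = 0.05) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 0.5)
    stop_localweb("alpha must lie in (0, 0.5)")
  out <- rep("none", length(p_lt))
  out[p_gt < alpha] <- "positive"
  out[p_lt < alpha] <- "negative"
  out
}

#' All pairwise associations of a presence/absence matrix
#'
#' Computes, for every unordered OTU pair, the observed number of shared
#' samples (from column dot products), the exact lower/upper tail
#' probabilities of the independent-placement law, and the sign
#' classification at level `alpha`. Pairs involving an OTU present in
#' every sample or in none carry no information about association and are
#' classified `none`. No multiple-testing correction is applied by default
#' (raw pairwise tails are thresholded); `fdr = TRUE` applies
#' Benjamini-Hochberg to each tail across pairs before classification.
#'
#' @param presence samples x OTUs 0/1 matrix (at least 2 of each).
#' @param alpha significance level (default 0.05).
#' @param fdr apply Benjamini-Hochberg across pairs (default FALSE).
#' @param flag_low_expectation mark pairs with expected shared-site count
#'   below 1 in a `low_expectation` column (no exclusion is performed).
#' @return data.frame of class `assoc_table` with columns otu_a, otu_b, N,
#'   n1, n2, j_obs, expected_j, p_lt, p_gt, sign.
#' @export
all_pair_associations <- function(presence, alpha = 0.05, fdr = FALSE,
                                  flag_low_expectation = FALSE) {
  if (!is.matrix(presence) || is.null(colnames(presence)))
    stop_localweb("presence must be a matrix with OTU column names")
  if (!all(presence %in% c(0L, 1L)))
    stop_localweb("presence matrix must be 0/1")
  if (ncol(presence) < 2L || nrow(presence) < 2L)
    stop_localweb("need at least 2 OTUs and 2 samples")
  if (any(colSums(presence) == 0))
    stop_localweb("OTU(s) present in no sample: ",
                  paste(utils::head(colnames(presence)[colSums(presence) == 0], 5L),
                        collapse = ", "))
  N <- nrow(presence)
  occ <- colSums(presence)
  J <- crossprod(presence)
  pairs <- upper_pairs(ncol(presence))
  a <- pairs[, 1L]; b <- pairs[, 2L]
  n1 <- occ[a]; n2 <- occ[b]; j <- J[pairs]
  lo <- pmax(0L, n1 + n2 - N); hi <- pmin(n1, n2)

  p_lt <- numeric(length(a)); p_gt <- numeric(length(a))
  chunk <- 50000L
  for (start in seq(1L, length(a), by = chunk)) {
    idx <- start:min(start + chunk - 1L, length(a))
    # lower tail: k = lo..j ; upper tail: k = j..hi (both inclusive of j)
    len_lt <- j[idx] - lo[idx] + 1L
    gl <- rep(seq_along(idx), len_lt)
    kl <- sequence(len_lt) - 1L + rep(lo[idx], len_lt)
    pm <- cooccurrence_pmf(N, n1[idx][gl], n2[idx][gl], kl)
    p_lt[idx] <- pmin(1, as.vector(rowsum(pm, gl)))
    len_gt <- hi[idx] - j[idx] + 1L
    gg <- rep(seq_along(idx), len_gt)
    kg <- sequence(len_gt) - 1L + rep(j[idx], len_gt)
    pm <- cooccurrence_pmf(N, n1[idx][gg], n2[idx][gg], kg)
    p_gt[idx] <- pmin(1, as.vector(rowsum(pm, gg)))
  }

  if (fdr) {
    sign <- classify_pair(stats::p.adjust(p_lt, "BH"), stats::p.adjust(p_gt, "BH"), alpha)
  } else {
    sign <- classify_pair(p_lt, p_gt, alpha)
  }
  # no-variation pairs carry no evidence either way
  degenerate <- n1 %in% c(0L, N) | n2 %in% c(0L, N)
  sign[degenerate] <- "none"

  out <- data.frame(
    otu_a = colnames(presence)[a], otu_b = colnames(presence)[b],
    N = N, n1 = as.integer(n1), n2 = as.integer(n2), j_obs = as.integer(j),
    expected_j = n1 * n2 / N, p_lt = p_lt, p_gt = p_gt, sign = sign,
    stringsAsFactors = FALSE)
  if (flag_low_expectation) out$low_expectation <- out$expected_j < 1
  attr(out, "alpha") <- alpha
  attr(out, "n_samples") <- N
  class(out) <- c("assoc_table", "data.frame")
  out
}

#' Write / read an association table as TSV
#'
#' @param assoc an `assoc_table`.
#' @param path file path.
#' @export
write_association_table <- function(assoc, path) {
  utils::write.table(as.data.frame(assoc), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_association_table
#' @param alpha significance level recorded on the reread table.
#' @export
read_association_table <- function(path, alpha = 0.05) {
  out <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("otu_a", "otu_b", "sign")
  if (!all(need %in% names(out)))
    stop_localweb("association table must contain columns: ",
                  paste(need, collapse = ", "))
  attr(out, "alpha") <- alpha
  if ("N" %in% names(out)) attr(out, "n_samples") <- out$N[1L]
  class(out) <- c("assoc_table", "data.frame")
  out
}
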