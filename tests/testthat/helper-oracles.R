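# Independent brute-force oracles, deliberately coded differently from the
# package implementations they check.

# P(J = j) by enumerating every placement of n1 and n2 occupied sites.
enum_pmf <- function(N, n1, n2, j) {
  sets1 <- if (n1 == 0) list(integer(0)) else
    asplit(utils::combn(N, n1), 2)
  sets2 <- if (n2 == 0) list(integer(0)) else
    asplit(utils::combn(N, n2), 2)
  hits <- 0L; total <- 0L
  for (a in sets1) for (b in sets2) {
    total <- total + 1L
    if (length(intersect(a, b)) == j) hits <- hits + 1L
  }
  hits / total
}

adjacency_from_edges <- function(edges, nodes = NULL) {
  e <- as.matrix(edges)[, 1:2, drop = FALSE]
  if (is.null(nodes)) nodes <- sort(unique(c(e)))
  A <- matrix(0L, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (k in seq_len(nrow(e))) {
    A[e[k, 1], e[k, 2]] <- 1L
    A[e[k, 2], e[k, 1]] <- 1L
  }
  A
}

bf_components <- function(A) {
  n <- nrow(A); seen <- rep(FALSE, n); comps <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comps <- comps + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (seen[v]) next
      seen[v] <- TRUE
      queue <- c(queue, which(A[v, ] == 1L & !seen))
    }
  }
  comps
}

bf_clustering <- function(A) {
  deg <- rowSums(A)
  vals <- c()
  for (v in which(deg >= 2)) {
    nb <- which(A[v, ] == 1L)
    links <- sum(A[nb, nb]) / 2
    vals <- c(vals, links / choose(length(nb), 2))
  }
  if (length(vals) == 0) NA_real_ else mean(vals)
}

bf_avg_path_length <- function(A) {
  n <- nrow(A)
  D <- ifelse(A == 1L, 1, Inf); diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  vals <- D[upper.tri(D)]
  mean(vals[is.finite(vals)])
}

bf_modularity <- function(edges, assignment) {
  A <- adjacency_from_edges(edges, nodes = names(assignment))
  deg <- rowSums(A); m <- sum(A) / 2
  q <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(A)))
    if (assignment[i] == assignment[j])
      q <- q + A[i, j] - deg[i] * deg[j] / (2 * m)
  unname(q / (2 * m))
}

random_edge_list <- function(n, p, prefix = "v") {
  nodes <- paste0(prefix, seq_len(n))
  pairs <- t(utils::combn(nodes, 2))
  pairs[stats::runif(nrow(pairs)) < p, , drop = FALSE]
}

# recursive permutation generator (independent of the package's)
perms_rec <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in perms_rec(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  out
}
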