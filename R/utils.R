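# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stable, dependency-free matrix/vector formatting for log messages.
log_msg <- function(...) message("[localweb] ", ...)

stop_localweb <- function(...) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)

# Upper-triangle (i < j) index pairs of an n x n matrix, as a 2-column matrix.
upper_pairs <- function(n) {
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}

# All permutations of 1..n (n small); used for exhaustive permutation tests.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- nrow(sub)
    block <- cbind(rep(k, rows), sub + (sub >= k))
    out[r + seq_len(rows), ] <- block
    r <- r + rows
  }
  out
}
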