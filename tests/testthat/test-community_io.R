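test_that("OTU table TSV and BIOM round-trips preserve counts", {
  m <- t(matrix(c(5L, 0L, 1L, 2L, 0L, 7L), nrow = 3, byrow = TRUE,
                dimnames = list(c("o1", "o2", "o3"), c("sA", "sB"))))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_otu_table(m, tsv, "tsv")
  back <- read_otu_table(tsv, "tsv")
  expect_identical(back, m)
  expect_equal(nrow(back), 2L)
  expect_equal(ncol(back), 3L)

  biom <- withr::local_tempfile(fileext = ".biom")
  write_otu_table(m, biom, "biom")
  expect_equal(read_otu_table(biom, "biom")[rownames(m), colnames(m)], m)

  # cross-format equality on a generated fixture
  sim <- small_sim()
  t2 <- withr::local_tempfile(); b2 <- withr::local_tempfile()
  write_otu_table(sim$counts, t2, "tsv")
  write_otu_table(sim$counts, b2, "biom")
  from_tsv <- read_otu_table(t2, "tsv")
  from_biom <- read_otu_table(b2, "biom")
  expect_equal(from_biom[rownames(from_tsv), colnames(from_tsv)], from_tsv)
})

test_that("malformed tables are rejected with informative errors", {
  f <- withr::local_tempfile()
  writeLines(c("otu_id\ts1\ts2", "o1\t1\t2", "o1\t3\t4"), f)
  expect_error(read_otu_table(f), "duplicate OTU identifier.*o1")
  writeLines(c("otu_id\ts1\ts2", "o1\t1\t2", "o2\t3"), f)
  expect_error(read_otu_table(f), "line 3")
  writeLines(c("otu_id\ts1\ts2", "o1\t1.5\t2", "o2\t3\t4"), f)
  expect_error(read_otu_table(f), "integer")
  writeLines(c("otu_id\ts1\ts2", "o1\t-1\t2", "o2\t3\t4"), f)
  expect_error(read_otu_table(f), "non-negative")
})

test_that("rarefaction subsamples to exact depth, deterministically", {
  set.seed(42)
  m <- matrix(rpois(60, 40), 6, 10,
              dimnames = list(paste0("s", 1:6), paste0("o", 1:10)))
  depth <- 150L
  r1 <- suppressMessages(rarefy_counts(m, depth, seed = 7))
  expect_true(all(rowSums(r1) == depth))
  expect_true(all(r1 <= m[rownames(r1), ]))
  r2 <- suppressMessages(rarefy_counts(m, depth, seed = 7))
  expect_identical(r1, r2)

  # a sample holding exactly `depth` reads passes through unchanged
  exact <- matrix(c(60L, 40L, 50L), 1, 3,
                  dimnames = list("s", c("a", "b", "c")))
  expect_identical(rarefy_counts(exact, 150L, seed = 1), exact)

  # under-depth samples are dropped, all-under is an error
  mixed <- rbind(m, low = rep(1L, 10))
  expect_message(rarefy_counts(mixed, depth, seed = 1), "dropped 1 sample")
  expect_error(rarefy_counts(m, 10^6, seed = 1), "no sample reaches depth")
})

test_that("rarefaction draws are uniform without replacement in expectation", {
  m <- matrix(c(300L, 100L, 600L), 1, 3,
              dimnames = list("s", c("a", "b", "c")))
  depth <- 200L
  draws <- sapply(1:200, function(s) rarefy_counts(m, depth, seed = s)[1, ])
  expected <- depth * m[1, ] / sum(m)
  # hypergeometric (without replacement) standard errors
  se <- sqrt(depth * (m[1, ] / sum(m)) * (1 - m[1, ] / sum(m)) *
               (sum(m) - depth) / (sum(m) - 1)) / sqrt(200)
  expect_true(all(abs(rowMeans(draws) - expected) < 3 * se + 1e-9))
})

test_that("prevalence filter keeps the inclusive boundary and is idempotent", {
  n <- 100
  m <- matrix(0L, n, 3, dimnames = list(paste0("s", 1:n), c("rare1", "rare2", "common")))
  m[1:2, "rare1"] <- 1L          # prevalence exactly 2%
  m[1, "rare2"] <- 1L            # prevalence 1%
  m[, "common"] <- 5L
  f <- prevalence_filter(m, 0.02)
  expect_setequal(colnames(f), c("rare1", "common"))
  expect_identical(prevalence_filter(f, 0.02), f)
  expect_error(prevalence_filter(m[, "rare2", drop = FALSE], 0.5), "every OTU")

  # recount oracle on a random fixture
  set.seed(1)
  big <- matrix(rbinom(50 * 40, 1, 0.1) * rpois(2000, 5), 50, 40,
                dimnames = list(paste0("s", 1:50), paste0("o", 1:40)))
  f2 <- prevalence_filter(big, 0.1)
  expect_equal(ncol(f2), sum(colSums(big > 0) / 50 >= 0.1))
})

test_that("binarization maps positive counts to 1 and keeps axes", {
  m <- matrix(c(5L, 0L, 1L, 2L), 2, 2,
              dimnames = list(c("s1", "s2"), c("o1", "o2")))
  p <- to_presence(m)
  expect_identical(unname(p), matrix(c(1L, 0L, 1L, 1L), 2, 2))
  expect_identical(dimnames(p), dimnames(m))
  # all-zero column is retained, and row sums are the per-sample richness
  m2 <- cbind(m, empty = c(0L, 0L))
  expect_true(all(to_presence(m2)[, "empty"] == 0L))
  expect_equal(rowSums(to_presence(m2)), rowSums(m2 > 0))
})

test_that("Shannon diversity matches closed forms and a direct-sum oracle", {
  uni <- matrix(rep(7L, 10), 1, 10,
                dimnames = list("s", paste0("o", 1:10)))
  expect_equal(unname(shannon_diversity(uni)), log(10), tolerance = 1e-12)
  single <- matrix(c(42L), 1, 1, dimnames = list("s", "o"))
  expect_equal(unname(shannon_diversity(single)), 0)
  set.seed(3)
  m <- matrix(rpois(50, 8) + 1L, 5, 10,
              dimnames = list(paste0("s", 1:5), paste0("o", 1:10)))
  oracle <- apply(m, 1, function(r) {
    p <- r[r > 0] / sum(r); -sum(p * log(p))
  })
  expect_equal(shannon_diversity(m), oracle, tolerance = 1e-12)
  zero <- matrix(0L, 1, 2, dimnames = list("s", c("a", "b")))
  expect_error(shannon_diversity(zero), "zero total reads")
})

test_that("Bray-Curtis matches hand-computed values", {
  m <- matrix(c(1L, 1L, 0L,
                1L, 1L, 0L,
                0L, 0L, 4L), 3, 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("x", "y", "z")))
  d <- bray_curtis(m)
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 1)   # disjoint supports
  m2 <- matrix(c(6L, 2L, 1L, 4L), 2, 2,
               dimnames = list(c("a", "b"), c("x", "y")))
  # |6-1| + |2-4| over 6+1+2+4
  expect_equal(bray_curtis(m2)["a", "b"], 7 / 13, tolerance = 1e-12)
})

test_that("Mantel test is exact on small instances and calibrated under the null", {
  set.seed(1)
  pts <- matrix(rnorm(8), 4, 2)
  d1 <- as.matrix(dist(pts))
  res <- mantel_test(d1, d1)
  expect_equal(res$r, 1)
  expect_true(res$exact)

  d2 <- as.matrix(dist(matrix(rnorm(8), 4, 2)))
  res2 <- mantel_test(d1, d2)
  # exhaustive oracle over all 4! relabelings
  ut <- upper.tri(d1)
  rs <- vapply(perms_rec(1:4), function(p) cor(d1[ut], d2[p, p][ut]), numeric(1))
  expect_equal(res2$p, mean(rs >= res2$r), tolerance = 1e-12)
  expect_equal(res2$n_perm, 24L)

  # independent random distances: p roughly uniform
  set.seed(99)
  ps <- replicate(50, {
    a <- as.matrix(dist(matrix(rnorm(24), 12, 2)))
    b <- as.matrix(dist(matrix(rnorm(24), 12, 2)))
    mantel_test(a, b, n_perm = 199, seed = sample.int(1e6, 1))$p
  })
  expect_gte(mean(ps > 0.05), 0.9)
})

test_that("nMDS recovers exact and planar geometries", {
  # three equidistant samples embed exactly
  d3 <- matrix(1, 3, 3) - diag(3)
  dimnames(d3) <- list(letters[1:3], letters[1:3])
  fit <- nmds_ordination(d3, k = 2, seed = 1, restarts = 5)
  expect_lt(fit$stress, 1e-6)

  # points on a plane with euclidean distances are recoverable at k = 2
  set.seed(2)
  pts <- matrix(runif(40), 20, 2)
  d <- as.matrix(dist(pts))
  fit2 <- nmds_ordination(d, k = 2, seed = 3, restarts = 10)
  expect_lt(fit2$stress, 0.05)

  # rank invariance: a monotone transform yields a congruent configuration
  fit3 <- nmds_ordination(d^1.7, k = 2, seed = 3, restarts = 10)
  pro <- vegan::procrustes(fit2$scores, fit3$scores, symmetric = TRUE)
  expect_lt(pro$ss, 1e-2)
})

test_that("ANOSIM equals its exhaustive oracle and the reference implementation", {
  # perfect separation: all between > all within
  pts <- rbind(matrix(rnorm(6, 0, 0.01), 3, 2),
               matrix(rnorm(6, 10, 0.01), 3, 2))
  d <- as.matrix(dist(pts)); dimnames(d) <- list(paste0("s", 1:6), paste0("s", 1:6))
  g <- rep(c("a", "b"), each = 3)
  res <- anosim_test(d, g)
  expect_equal(res$R, 1)
  expect_true(res$exact)

  # statistic agrees with vegan on a larger random instance
  set.seed(4)
  pts2 <- matrix(rnorm(40), 20, 2)
  d2 <- as.matrix(dist(pts2))
  g2 <- rep(c("a", "b"), each = 10)
  ours <- anosim_test(d2, g2, n_perm = 99, seed = 1)
  ref <- vegan::anosim(as.dist(d2), g2, permutations = 9)
  expect_equal(ours$R, unname(ref$statistic), tolerance = 1e-12)

  # exhaustive p equals a brute-force label-permutation oracle
  set.seed(5)
  d3 <- as.matrix(dist(matrix(rnorm(12), 6, 2)))
  g3 <- rep(c("a", "b"), each = 3)
  res3 <- anosim_test(d3, g3)
  rs <- vapply(perms_rec(1:6), function(p) {
    localweb:::anosim_statistic(d3, g3[p])
  }, numeric(1))
  expect_equal(res3$p, mean(rs >= res3$R), tolerance = 1e-12)

  # random labels: mean R near 0
  set.seed(6)
  meanR <- mean(replicate(100, {
    dd <- as.matrix(dist(matrix(rnorm(24), 12, 2)))
    anosim_test(dd, sample(rep(c("a", "b"), each = 6)), n_perm = 2, seed = 1)$R
  }))
  expect_lt(abs(meanR), 0.05)
  expect_error(anosim_test(d2, rep("a", 20)), "two groups")
})

test_that("betadispersion reduces to euclidean centroid distances", {
  # two groups of duplicated points: zero within-group dispersion
  m <- matrix(c(3, 3, 8, 8, 1, 1, 5, 5), 4, 2,
              dimnames = list(paste0("s", 1:4), c("x", "y")))
  d <- as.matrix(dist(m))
  bd <- betadispersion(d, c("g1", "g1", "g2", "g2"))
  expect_true(all(abs(bd$distances) < 1e-10))

  # euclidean input: distances equal direct distances to the group centroid
  set.seed(7)
  pts <- matrix(rnorm(30), 15, 2)
  g <- rep(c("a", "b", "c"), each = 5)
  bd2 <- betadispersion(as.matrix(dist(pts)), g)
  direct <- vapply(seq_len(15), function(i) {
    cen <- colMeans(pts[g == g[i], , drop = FALSE])
    sqrt(sum((pts[i, ] - cen)^2))
  }, numeric(1))
  expect_equal(unname(bd2$distances), direct, tolerance = 1e-8)
  expect_warning(betadispersion(as.matrix(dist(pts)), c("solo", g[-1])), "size 1")
})

test_that("filtered communities represent full communities (Mantel screen)", {
  ch <- small_chain()
  d_full <- bray_curtis(ch$rarefied)
  d_filt <- bray_curtis(prevalence_filter(ch$rarefied, 0.02))
  res <- mantel_test(d_full, d_filt, n_perm = 199, seed = 1)
  expect_gt(res$r, 0.9)
})
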