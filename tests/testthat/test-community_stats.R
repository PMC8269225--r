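fake_profiles <- function(n = 40, seed = 1) {
  set.seed(seed)
  x <- runif(n)
  data.frame(sample_id = paste0("s", seq_len(n)),
             modularity_pos = x,
             clustering_pos = 1 - x + rnorm(n, 0, 0.05),
             avg_path_length_pos = 1 + x^2,
             coexclusion_proportion = runif(n, 0, 0.1))
}

test_that("property correlations are rank-invariant and flag the joint rule", {
  prof <- fake_profiles()
  out <- property_correlations(prof,
                               properties = c("modularity_pos",
                                              "avg_path_length_pos"))
  r <- out$r[out$stratum == "pooled"]
  expect_equal(r, 1, tolerance = 1e-12)  # monotone transform of the same ranks
  # strong inverse relation flagged under |r| > 0.5 & p < 0.01
  out2 <- property_correlations(prof,
                                strata = rep(c("A", "B"), 20),
                                properties = c("modularity_pos",
                                               "clustering_pos"))
  expect_true(all(out2$relationship[out2$p < 0.01 & abs(out2$r) > 0.5]))
  # constant property is skipped with a warning
  prof$flat <- 1
  expect_warning(
    property_correlations(prof, properties = c("modularity_pos", "flat")),
    "constant")
})

test_that("envfit recovers a variable equal to an ordination axis", {
  set.seed(2)
  scores <- cbind(NMDS1 = rnorm(30), NMDS2 = rnorm(30))
  vars <- data.frame(axis_copy = scores[, 1], noise = rnorm(30))
  out <- envfit_vectors(scores, vars, n_perm = 199, seed = 1)
  row <- out[out$variable == "axis_copy", ]
  expect_gt(row$r2, 0.999)
  expect_gt(abs(row$NMDS1), 0.99)
  expect_lt(row$p, 0.01)
  expect_warning(envfit_vectors(scores, data.frame(flat = rep(1, 30), ok = rnorm(30))),
                 "constant")
})

test_that("pure-noise variables rarely reach the envfit display threshold", {
  set.seed(3)
  hits <- replicate(40, {
    scores <- cbind(rnorm(25), rnorm(25))
    out <- envfit_vectors(scores, data.frame(noise = rnorm(25)),
                          n_perm = 199, seed = sample.int(1e6, 1))
    out$p <= 0.01
  })
  expect_gte(mean(!hits), 0.9)
})

test_that("variation partitioning recovers planted unique fractions", {
  set.seed(4)
  n <- 120
  A <- data.frame(a1 = rnorm(n), a2 = rnorm(n))
  B <- data.frame(b1 = rnorm(n))
  C <- data.frame(c1 = rnorm(n))
  scores <- cbind(A$a1 + 0.5 * A$a2 + rnorm(n, 0, 0.3),
                  A$a1 - A$a2 + rnorm(n, 0, 0.3))
  vp <- variation_partitioning(scores, list(geo = A, weather = B, network = C))
  expect_equal(sum(vp$fractions), 1, tolerance = 1e-9)
  full <- vp$total_r2
  expect_equal(unname(vp$fractions["unique_geo"]), full, tolerance = 0.02)
  expect_lt(abs(vp$fractions[["unique_weather"]]), 0.02)
  expect_lt(abs(vp$fractions[["unique_network"]]), 0.02)
  # orthogonal blocks share (near) nothing
  shared <- vp$fractions[grep("^shared", names(vp$fractions))]
  expect_true(all(abs(shared) < 0.02))
})

test_that("variation partitioning is invariant to block order", {
  set.seed(5)
  n <- 60
  A <- data.frame(a = rnorm(n)); B <- data.frame(b = rnorm(n))
  C <- data.frame(c = rnorm(n))
  scores <- cbind(A$a + B$b + rnorm(n, 0, 0.5), rnorm(n))
  v1 <- variation_partitioning(scores, list(A = A, B = B, C = C))
  v2 <- variation_partitioning(scores, list(C = C, B = B, A = A))
  expect_equal(v1$fractions[["unique_A"]], v2$fractions[["unique_A"]],
               tolerance = 1e-9)
  expect_equal(v1$fractions[["residual"]], v2$fractions[["residual"]],
               tolerance = 1e-9)
})

test_that("forward selection removes collinear copies and finds true signals", {
  set.seed(6)
  n <- 80
  x <- rnorm(n)
  cand <- data.frame(signal = x, dup = x, noise1 = rnorm(n), noise2 = rnorm(n))
  scores <- cbind(x + rnorm(n, 0, 0.3), rnorm(n))
  sel <- forward_select(scores, cand, alpha = 0.05, n_perm = 199, seed = 1)
  expect_true(length(intersect(c("signal", "dup"), sel)) >= 1)
  expect_true("dup" %in% attr(sel, "dropped_collinear") ||
                "signal" %in% attr(sel, "dropped_collinear"))
  # selection consistency over replicates
  hits <- replicate(20, {
    x <- rnorm(n)
    cand <- data.frame(signal = x, n1 = rnorm(n), n2 = rnorm(n))
    scores <- cbind(x + rnorm(n, 0, 0.4), rnorm(n))
    "signal" %in% forward_select(scores, cand, n_perm = 99,
                                 seed = sample.int(1e6, 1))
  })
  expect_gte(mean(hits), 0.9)
  # all-noise candidates mostly select nothing
  empties <- replicate(20, {
    cand <- data.frame(n1 = rnorm(n), n2 = rnorm(n))
    scores <- cbind(rnorm(n), rnorm(n))
    length(suppressWarnings(forward_select(scores, cand, n_perm = 99,
                                           seed = sample.int(1e6, 1)))) == 0
  })
  expect_gte(mean(empties), 0.8)
})

test_that("the property mixed model recovers planted coefficients", {
  d <- sim_lmm_data(seed = 7)
  fit <- fit_property_lmm(d, "y", fixed_continuous = "humidity")
  truth <- attr(d, "truth")
  est <- fit$coefficients$estimate
  names(est) <- rownames(fit$coefficients)
  for (lev in c("conventional", "organic", "biodynamic")) {
    expect_equal(unname(est[paste0("management:", lev)]),
                 unname(truth[lev]), tolerance = 0.35)
  }
  expect_equal(unname(est["humidity"]), unname(truth["humidity"]),
               tolerance = 0.1)
  expect_true(fit$marginal_r2 > 0 && fit$marginal_r2 <= 1)
  expect_error(fit_property_lmm(transform(d, y = y - max(y)), "y",
                                fixed_continuous = "humidity"),
               "positive")
})

test_that("mixed-model CIs achieve near-nominal coverage", {
  covered <- 0; total <- 0
  for (s in 1:60) {
    d <- sim_lmm_data(n_per_region = 15, seed = 100 + s)
    fit <- tryCatch(fit_property_lmm(d, "y", fixed_continuous = "humidity"),
                    error = function(e) NULL)
    if (is.null(fit)) next
    truth <- attr(d, "truth")
    cf <- fit$coefficients
    for (lev in c("conventional", "biodynamic")) {
      row <- cf[paste0("management:", lev), ]
      total <- total + 1
      crit <- if (is.finite(row$df)) qt(0.975, row$df) else 1.96
      if (abs(row$estimate - truth[lev]) <= crit * row$std_error)
        covered <- covered + 1
    }
  }
  expect_gte(covered / total, 0.88)
  expect_lte(covered / total, 1.0)
})

test_that("a noiseless fixed-effect response gives marginal R2 of one", {
  set.seed(8)
  d <- data.frame(region = rep(c("r1", "r2"), each = 20),
                  management = rep(c("conventional", "organic"), 20),
                  humidity = runif(40))
  d$y <- exp(ifelse(d$management == "conventional", -1, -2))
  fit <- suppressWarnings(suppressMessages(
    fit_property_lmm(d, "y", fixed_continuous = character(0), scale = FALSE)))
  expect_equal(fit$marginal_r2, 1, tolerance = 1e-6)
})

test_that("two-way ANOVA matches a hand sums-of-squares oracle on balanced data", {
  set.seed(9)
  d <- expand.grid(management = c("conventional", "organic"),
                   country = c("US", "ES"), rep = 1:10)
  cell_means <- c(1, 2, 3, 4)
  d$y <- cell_means[as.integer(interaction(d$management, d$country))] +
    rnorm(nrow(d), 0, 0.5)
  out <- two_way_anova(d, "y")
  # balanced design: type II equals classical sequential sums of squares
  ref <- anova(lm(y ~ management * country, data = d))
  expect_equal(out$F[out$term == "management"],
               ref["management", "F value"], tolerance = 1e-10)
  expect_equal(out$F[out$term == "country"],
               ref["country", "F value"], tolerance = 1e-10)
  expect_equal(out$F[out$term == "management:country"],
               ref["management:country", "F value"], tolerance = 1e-10)
  # direct oracle for the management main effect
  g <- tapply(d$y, d$management, mean)
  ss_m <- sum(table(d$management) * (g - mean(d$y))^2)
  ms_e <- ref["Residuals", "Mean Sq"]
  expect_equal(out$F[out$term == "management"], (ss_m / 1) / ms_e,
               tolerance = 1e-10)
})

test_that("ANOVA p-values are calibrated and detect planted effects", {
  set.seed(10)
  null_ps <- replicate(60, {
    d <- data.frame(management = sample(c("a", "b", "c"), 60, replace = TRUE),
                    country = sample(c("US", "ES"), 60, replace = TRUE),
                    y = rnorm(60))
    out <- two_way_anova(d, "y")
    min(out$p[out$term %in% c("management", "country")], na.rm = TRUE)
  })
  expect_gte(mean(null_ps > 0.01), 0.9)
  # planted management effect: management significant, interaction not
  d <- data.frame(management = rep(c("a", "b"), 40),
                  country = rep(c("US", "ES"), each = 40))
  d$y <- ifelse(d$management == "a", 0, 2) + rnorm(80, 0, 0.5)
  out <- two_way_anova(d, "y")
  expect_lt(out$p[out$term == "management"], 0.01)
  expect_gt(out$p[out$term == "management:country"], 0.01)
})

test_that("pathogen analysis counts richness exactly and recovers a logistic signal", {
  set.seed(11)
  n <- 150
  prof <- data.frame(sample_id = paste0("s", 1:n),
                     clustering_pos = runif(n),
                     modularity_pos = runif(n),
                     avg_path_length_neg = 1 + runif(n),
                     coexclusion_proportion = runif(n, 0, 0.2))
  # plant presence driven negatively by coexclusion proportion
  eta <- 2 - 25 * prof$coexclusion_proportion
  present <- rbinom(n, 1, plogis(eta))
  pres <- matrix(0L, n, 6, dimnames = list(prof$sample_id, paste0("o", 1:6)))
  pres[, "o1"] <- present
  pres[present == 1, "o2"] <- rbinom(sum(present), 1, 0.5)
  pres[, "o3"] <- 1L  # non-pathogen background
  fit <- pathogen_analysis(prof, pres, pathogen_otus = c("o1", "o2", "absent"))
  manual <- rowSums(pres[, c("o1", "o2")] > 0)
  expect_equal(unname(fit$richness), unname(manual))
  expect_lt(fit$richness_vs_coexclusion$r, 0)
  expect_lt(fit$coefficients["coexclusion_proportion", "estimate"], 0)
  expect_true(all(fit$curve$probability >= 0 & fit$curve$probability <= 1))
  # probability falls along the coexclusion axis for this planted direction
  expect_lt(fit$curve$probability[nrow(fit$curve)], fit$curve$probability[1])
  # no pathogen anywhere: refuse clearly
  expect_error(pathogen_analysis(prof, pres, "absent"), "universe")
  pres0 <- pres; pres0[, "o1"] <- 0L; pres0[, "o2"] <- 0L
  expect_error(pathogen_analysis(prof, pres0, c("o1", "o2")), "no pathogen OTU")
})

test_that("logistic coefficient CIs achieve near-nominal coverage", {
  set.seed(12)
  covered <- 0; total <- 0
  for (s in 1:60) {
    n <- 200
    x <- runif(n, 0, 0.2)
    prof <- data.frame(sample_id = paste0("s", 1:n),
                       clustering_pos = runif(n), modularity_pos = runif(n),
                       avg_path_length_neg = runif(n),
                       coexclusion_proportion = x)
    beta <- -15
    present <- rbinom(n, 1, plogis(1.5 + beta * x))
    pres <- matrix(0L, n, 2, dimnames = list(prof$sample_id, c("p1", "bg")))
    pres[, "p1"] <- present; pres[, "bg"] <- 1L
    fit <- tryCatch(suppressWarnings(pathogen_analysis(prof, pres, "p1")),
                    error = function(e) NULL)
    if (is.null(fit) || fit$penalized) next
    row <- fit$coefficients["coexclusion_proportion", ]
    total <- total + 1
    if (abs(row$estimate - beta) <= 1.96 * row$std_error) covered <- covered + 1
  }
  expect_gte(covered / total, 0.88)
})

test_that("diversity correlations handle perfect rank relations and ties", {
  prof <- fake_profiles(30, seed = 13)
  h <- -rank(prof$modularity_pos)
  out <- diversity_property_correlation(prof, h,
                                        properties = "modularity_pos")
  expect_equal(out$r, -1, tolerance = 1e-12)
  # average-rank tie handling agrees with the reference implementation
  set.seed(13)
  v <- sample(1:5, 30, replace = TRUE)
  prof$tied <- v
  h2 <- rnorm(30)
  out2 <- diversity_property_correlation(prof, h2, properties = "tied")
  expect_equal(out2$r, cor(rank(h2), rank(v)) *
                 sd(rank(h2)) * sd(rank(v)) / (sd(rank(h2)) * sd(rank(v))),
               tolerance = 1e-12)
  expect_equal(out2$r, unname(cor(h2, v, method = "spearman")),
               tolerance = 1e-12)
})

test_that("environmental PCA reduces duplicated gradients to one axis", {
  set.seed(14)
  x <- runif(40, 1, 10)
  md <- data.frame(a = x, b = x * 3, c = rep(2, 40))
  out <- suppressWarnings(env_pca(md))
  expect_equal(out$explained_variance[1], 1, tolerance = 1e-9)
  # loadings orthonormal
  L <- out$loadings
  expect_equal(t(L) %*% L, diag(ncol(L)), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(env_pca(data.frame(a = c(-1, 2, 3), b = 1:3)), "shift")
  # near-identity covariance spreads variance evenly
  md2 <- as.data.frame(matrix(exp(rnorm(300)), 100, 3))
  ev <- env_pca(md2)$explained_variance
  expect_true(all(ev > 0.15 & ev < 0.55))
})
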