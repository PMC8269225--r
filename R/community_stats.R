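#' Downstream statistics of local network properties
#'
#' Property-property correlations, ordination vector fitting and variation
#' partitioning, forward selection, mixed models of properties on
#' management and weather, unbalanced two-way ANOVA, pathogen-presence
#' modelling and environmental PCA.
#'
#' @name community_stats_module
NULL

network_property_columns <- function() {
  c("modularity_pos", "clustering_pos", "avg_path_length_pos",
    "n_components_pos", "modularity_neg", "clustering_neg",
    "avg_path_length_neg", "n_components_neg",
    "cooccurrence_proportion", "coexclusion_proportion")
}

spearman_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  suppressWarnings(stats::cor.test(x[ok], y[ok], method = "spearman"))
}

#' Spearman correlations between network properties
#'
#' All property pairs, per stratum and pooled. A pair is flagged as a
#' relationship when |r| > 0.5 in at least one stratum and p < 0.01 (the
#' joint rule; no multiple-testing correction is layered on top of it).
#'
#' @param profiles a `local_profiles` table.
#' @param strata stratum label per profile row (e.g. country); `NULL` for
#'   pooled-only.
#' @param properties property columns to correlate.
#' @return data.frame: stratum, prop_x, prop_y, r, p, relationship.
#' @export
property_correlations <- function(profiles, strata = NULL,
                                  properties = intersect(network_property_columns(),
                                                         names(profiles))) {
  groups <- list(pooled = seq_len(nrow(profiles)))
  if (!is.null(strata)) {
    if (length(strata) != nrow(profiles))
      stop_localweb("one stratum label per profile row required")
    groups <- c(split(seq_len(nrow(profiles)), strata), groups)
  }
  pair_idx <- utils::combn(properties, 2L)
  rows <- list()
  for (g in names(groups)) {
    sub <- profiles[groups[[g]], , drop = FALSE]
    if (nrow(sub) < 10L)
      warning("stratum '", g, "' has fewer than 10 samples", call. = FALSE)
    for (k in seq_len(ncol(pair_idx))) {
      px <- pair_idx[1L, k]; py <- pair_idx[2L, k]
      x <- sub[[px]]; y <- sub[[py]]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        warning("correlation undefined for ", px, " vs ", py,
                " in stratum '", g, "' (constant or empty); skipped", call. = FALSE)
        next
      }
      ct <- spearman_cor(x, y)
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = g, prop_x = px, prop_y = py,
        r = unname(ct$estimate), p = ct$p.value, n = sum(ok),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(stratum = character(0), prop_x = character(0),
                      prop_y = character(0), r = numeric(0), p = numeric(0),
                      n = integer(0), relationship = logical(0)))
  out <- do.call(rbind, rows)
  # joint rule: |r| > 0.5 in >= 1 (non-pooled) stratum and p < 0.01
  key <- paste(out$prop_x, out$prop_y)
  per_stratum <- out[out$stratum != "pooled", , drop = FALSE]
  if (nrow(per_stratum) == 0L) per_stratum <- out
  strong <- unique(paste(per_stratum$prop_x, per_stratum$prop_y)[
    abs(per_stratum$r) > 0.5 & per_stratum$p < 0.01])
  out$relationship <- key %in% strong & out$p < 0.01
  rownames(out) <- NULL
  out
}

#' Fit metadata vectors onto an ordination
#'
#' Least-squares fit of each numeric variable onto the ordination space
#' (vegan's `envfit`), returning the direction cosines, squared
#' correlation and permutation p-value. Constant variables are skipped.
#'
#' @param scores samples x k ordination scores.
#' @param variables data.frame of numeric metadata aligned on samples.
#' @param n_perm permutations (default 999).
#' @param seed integer RNG seed.
#' @param p_max report only variables with p below this (default 1 =
#'   everything; the conventional display cut is 0.01).
#' @return data.frame: variable, per-axis direction, r2, p.
#' @export
envfit_vectors <- function(scores, variables, n_perm = 999L, seed = 1L,
                           p_max = 1) {
  variables <- as.data.frame(variables)
  keep <- vapply(variables, function(v)
    is.numeric(v) && stats::sd(v, na.rm = TRUE) > 0, logical(1))
  if (any(!keep))
    warning("skipped constant/non-numeric variable(s): ",
            paste(names(variables)[!keep], collapse = ", "), call. = FALSE)
  variables <- variables[, keep, drop = FALSE]
  if (ncol(variables) == 0L) stop_localweb("no usable variables")
  ef <- with_seed(seed, vegan::envfit(scores, variables,
                                      permutations = n_perm, na.rm = TRUE))
  arrows <- ef$vectors$arrows
  out <- data.frame(variable = rownames(arrows), arrows,
                    r2 = ef$vectors$r, p = ef$vectors$pvals,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[out$p <= p_max, , drop = FALSE]
}

adjusted_r2 <- function(scores, X) {
  # Ezekiel-adjusted redundancy R2 of a multivariate least-squares fit
  fit <- vegan::rda(scores ~ ., data = as.data.frame(X))
  vegan::RsquareAdj(fit)$adj.r.squared
}

#' Variation partitioning of ordination scores
#'
#' Decomposes the variance of (typically two-dimensional nMDS) scores into
#' the unique, pairwise-shared and three-way-shared adjusted-R2 fractions
#' of three explanatory blocks, plus the residual (inclusion-exclusion on
#' redundancy fits; negative shared fractions are reported, not
#' truncated). Fractions and residual sum to 1.
#'
#' @param scores samples x k response score matrix.
#' @param blocks named list of exactly three data.frames of explanatory
#'   variables.
#' @return object of class `variance_partition`: `fractions` (named
#'   vector: unique per block, pairwise, three-way, residual) and
#'   `total_r2`.
#' @export
variation_partitioning <- function(scores, blocks) {
  if (!is.list(blocks) || length(blocks) != 3L)
    stop_localweb("blocks must be a named list of three variable sets")
  if (is.null(names(blocks)) || any(names(blocks) == ""))
    stop_localweb("blocks must be named")
  blocks <- lapply(blocks, as.data.frame)
  vp <- vegan::varpart(scores, blocks[[1L]], blocks[[2L]], blocks[[3L]])
  fr <- vp$part$indfract$Adj.R.square
  bn <- names(blocks)
  fractions <- c(fr[1:3], fr[4:6], fr[7L], fr[8L])
  names(fractions) <- c(paste0("unique_", bn),
                        paste0("shared_", c(paste(bn[1L], bn[2L], sep = "_"),
                                            paste(bn[2L], bn[3L], sep = "_"),
                                            paste(bn[1L], bn[3L], sep = "_"))),
                        "shared_all", "residual")
  out <- list(fractions = fractions,
              total_r2 = sum(fractions[seq_len(7L)]))
  class(out) <- "variance_partition"
  out
}

#' @export
print.variance_partition <- function(x, ...) {
  cat("Variation partitioning (adjusted R2 fractions):\n")
  for (nm in names(x$fractions))
    cat(sprintf("  %-28s %8.4f\n", nm, x$fractions[nm]))
  cat(sprintf("  %-28s %8.4f\n", "total explained", x$total_r2))
  invisible(x)
}

block_vif <- function(X) {
  vapply(seq_len(ncol(X)), function(j) {
    others <- X[, -j, drop = FALSE]
    if (ncol(others) == 0L) return(1)
    r2 <- summary(stats::lm(X[, j] ~ ., data = as.data.frame(others)))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Forward selection of explanatory variables for ordination scores
#'
#' Collinear candidates (variance inflation above `vif_threshold`,
#' including exact duplicates) are removed first. The survivors enter a
#' forward selection on redundancy fits of the score matrix: at each step
#' the candidate with the largest adjusted-R2 gain is tested by a nested
#' permutation comparison and added only if its p-value is below `alpha`
#' (first stopping rule); selection also stops once the running model's
#' adjusted R2 reaches the full-model adjusted R2, so the selected set
#' never claims more structure than all candidates jointly explain
#' (second stopping rule).
#'
#' @param scores samples x k response scores.
#' @param candidates data.frame of candidate numeric variables.
#' @param alpha permutation significance level for entry (default 0.05).
#' @param n_perm permutations per entry test.
#' @param vif_threshold collinearity cut (default 10).
#' @param seed integer RNG seed.
#' @return character vector of selected variable names; attribute
#'   `dropped_collinear` lists the pre-removed candidates.
#' @export
forward_select <- function(scores, candidates, alpha = 0.05, n_perm = 199L,
                           vif_threshold = 10, seed = 1L) {
  X <- as.data.frame(candidates)
  if (ncol(X) < 1L) stop_localweb("need at least one candidate")
  keep <- vapply(X, function(v) is.numeric(v) && stats::sd(v, na.rm = TRUE) > 0,
                 logical(1))
  dropped <- names(X)[!keep]
  X <- X[, keep, drop = FALSE]
  repeat {
    if (ncol(X) < 2L) break
    vif <- block_vif(as.matrix(X))
    if (max(vif) <= vif_threshold) break
    worst <- which.max(vif)
    dropped <- c(dropped, names(X)[worst])
    X <- X[, -worst, drop = FALSE]
  }
  if (ncol(X) == 0L) {
    warning("no candidate survived collinearity screening", call. = FALSE)
    out <- character(0); attr(out, "dropped_collinear") <- dropped
    return(out)
  }
  sc <- as.matrix(scores)
  rda <- vegan::rda  # anova.cca refits via update(), resolving `rda` here
  fit_rda <- function(vars) {
    if (length(vars) == 0L) rda(sc ~ 1, data = X)
    else rda(stats::as.formula(paste("sc ~", paste(vars, collapse = " + "))),
             data = X)
  }
  adj_r2 <- function(m) {
    r <- vegan::RsquareAdj(m)$adj.r.squared
    if (is.null(r) || is.na(r)) 0 else r
  }
  r2_stop <- adj_r2(fit_rda(names(X)))
  selected <- character(0)
  remaining <- names(X)
  with_seed(seed, {
    repeat {
      if (length(remaining) == 0L) break
      current <- fit_rda(selected)
      if (length(selected) > 0L && adj_r2(current) >= r2_stop) break
      gains <- vapply(remaining, function(v)
        adj_r2(fit_rda(c(selected, v))), numeric(1))
      best <- remaining[which.max(gains)]
      cand_fit <- fit_rda(c(selected, best))
      pv <- stats::anova(current, cand_fit, permutations = n_perm)
      p <- pv$`Pr(>F)`[2L]
      if (is.na(p) || p >= alpha) break
      selected <- c(selected, best)
      remaining <- setdiff(remaining, best)
    }
  })
  if (length(selected) == 0L)
    warning("forward selection retained no variable", call. = FALSE)
  attr(selected, "dropped_collinear") <- dropped
  selected
}

#' Linear mixed model of a network property
#'
#' The property is modelled on the natural-log scale with management coded
#' as cell means (no global intercept: one estimate per management level),
#' continuous covariates centred (optionally scaled) within country, and a
#' random intercept for region; fitting is by REML with Satterthwaite
#' p-values. The marginal R2 is var(fixed predictor) / (var(fixed) +
#' var(random) + var(residual)). A singular random-effect fit falls back
#' to the fixed-effects model, flagged.
#'
#' @param data merged profiles + metadata data.frame.
#' @param response property column name (values must be positive).
#' @param fixed_continuous continuous covariate columns.
#' @param management_col,country_col,region_col grouping columns.
#' @param center,scale centre/scale continuous covariates per country.
#' @return object of class `property_lmm`.
#' @export
fit_property_lmm <- function(data, response,
                             fixed_continuous = c("humidity", "max_temperature",
                                                  "wind_speed"),
                             management_col = "management",
                             country_col = "country",
                             region_col = "region",
                             center = TRUE, scale = TRUE) {
  need <- c(response, fixed_continuous, management_col, region_col)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop_localweb("column(s) not in data: ", paste(missing_cols, collapse = ", "))
  d <- data[, unique(c(need, intersect(country_col, names(data)))), drop = FALSE]
  complete <- stats::complete.cases(d)
  if (any(!complete))
    log_msg("excluded ", sum(!complete), " row(s) with missing values (listwise)")
  d <- d[complete, , drop = FALSE]
  y <- d[[response]]
  if (any(y <= 0))
    stop_localweb("response must be positive for the log transform (",
                  sum(y <= 0), " non-positive value(s))")
  if (length(unique(d[[region_col]])) < 2L)
    stop_localweb("need at least 2 regions for the random effect")
  d$.logy <- log(y)
  d$.management <- factor(d[[management_col]])
  grp <- if (country_col %in% names(d)) d[[country_col]] else rep("all", nrow(d))
  for (v in fixed_continuous) {
    if (center) d[[v]] <- d[[v]] - stats::ave(d[[v]], grp, FUN = mean)
    if (scale) {
      s <- stats::ave(d[[v]], grp, FUN = stats::sd)
      d[[v]] <- ifelse(s > 0, d[[v]] / s, d[[v]])
    }
  }
  fixed_rhs <- paste(c("0", ".management", fixed_continuous), collapse = " + ")
  form <- stats::as.formula(paste(".logy ~", fixed_rhs,
                                  "+ (1 |", region_col, ")"))
  fit <- tryCatch(lmerTest::lmer(form, data = d, REML = TRUE),
                  error = function(e)
                    tryCatch(suppressWarnings(lme4::lmer(form, data = d, REML = TRUE)),
                             error = function(e2) NULL))
  singular <- is.null(fit) || lme4::isSingular(fit, tol = 1e-5)
  if (singular) {
    fit_lm <- stats::lm(stats::as.formula(paste(".logy ~", fixed_rhs)), data = d)
    coefs <- cbind(summary(fit_lm)$coefficients[, c(1L, 2L), drop = FALSE],
                   df = fit_lm$df.residual,
                   summary(fit_lm)$coefficients[, 4L])
    var_random <- 0
    var_resid <- summary(fit_lm)$sigma^2
    pred_fixed <- stats::fitted(fit_lm)
  } else {
    sm <- summary(fit)$coefficients
    coefs <- cbind(sm[, "Estimate"], sm[, "Std. Error"],
                   if ("df" %in% colnames(sm)) sm[, "df"] else NA_real_,
                   if ("Pr(>|t|)" %in% colnames(sm)) sm[, "Pr(>|t|)"]
                   else NA_real_)
    rownames(coefs) <- rownames(sm)
    vc <- as.data.frame(lme4::VarCorr(fit))
    var_random <- sum(vc$vcov[vc$grp != "Residual"])
    var_resid <- vc$vcov[vc$grp == "Residual"]
    pred_fixed <- as.vector(lme4::getME(fit, "X") %*% lme4::fixef(fit))
  }
  var_fixed <- stats::var(pred_fixed)
  marginal_r2 <- var_fixed / (var_fixed + var_random + var_resid)
  conditional_r2 <- (var_fixed + var_random) /
    (var_fixed + var_random + var_resid)
  coefs <- as.data.frame(coefs)
  names(coefs) <- c("estimate", "std_error", "df", "p")[seq_len(ncol(coefs))]
  rownames(coefs) <- sub("^\\.management", "management:", rownames(coefs))
  out <- list(response = response, coefficients = coefs,
              random_effect_variance = var_random,
              residual_variance = var_resid,
              marginal_r2 = marginal_r2, conditional_r2 = conditional_r2,
              n = nrow(d), singular_fallback = singular,
              fit = if (singular) NULL else fit)
  class(out) <- "property_lmm"
  out
}

#' @export
print.property_lmm <- function(x, ...) {
  cat("Mixed model of ln(", x$response, "), n = ", x$n, "\n", sep = "")
  printCoefmat(as.matrix(x$coefficients), P.values = TRUE, has.Pvalue = TRUE)
  cat("Region variance:", format(x$random_effect_variance, digits = 4),
      if (x$singular_fallback) "(singular fit; fixed-effects fallback)", "\n")
  cat("Marginal R2:", format(x$marginal_r2, digits = 4),
      " Conditional R2:", format(x$conditional_r2, digits = 4), "\n")
  invisible(x)
}

#' Two-way ANOVA of a property on management and country
#'
#' Type-II sums of squares (the design is unbalanced), with the
#' interaction included when every cell is occupied and a logged fallback
#' to the additive model otherwise. Significance is annotated at p < 0.01.
#'
#' @param data merged profiles + metadata.
#' @param response property column.
#' @param factors two factor columns (default management and country).
#' @return data.frame: term, sum_sq, df, F, p, significant.
#' @export
two_way_anova <- function(data, response, factors = c("management", "country")) {
  if (length(factors) != 2L) stop_localweb("exactly two factors required")
  d <- data[, c(response, factors)]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  f1 <- factor(d[[factors[1L]]]); f2 <- factor(d[[factors[2L]]])
  if (nlevels(f1) < 2L || nlevels(f2) < 2L)
    stop_localweb("each factor needs at least 2 levels")
  d$.f1 <- f1; d$.f2 <- f2
  full_cells <- all(table(f1, f2) > 0L)
  form <- if (full_cells) stats::as.formula(paste(response, "~ .f1 * .f2"))
          else stats::as.formula(paste(response, "~ .f1 + .f2"))
  if (!full_cells)
    log_msg("empty factor cell(s): interaction dropped, additive model fitted")
  fit <- stats::lm(form, data = d)
  aov2 <- car::Anova(fit, type = 2)
  out <- data.frame(term = rownames(aov2), sum_sq = aov2$`Sum Sq`,
                    df = aov2$Df, F = aov2$`F value`, p = aov2$`Pr(>F)`,
                    stringsAsFactors = FALSE)
  out$term <- gsub("\\.f1", factors[1L], gsub("\\.f2", factors[2L], out$term))
  out$significant <- !is.na(out$p) & out$p < 0.01
  rownames(out) <- NULL
  out
}

#' Pathogen richness and presence versus network structure
#'
#' Pathogen richness is the number of listed pathogen OTUs present in each
#' sample. The analysis reports the Spearman correlation of richness with
#' the co-exclusion proportion, a binomial GLM of pathogen presence
#' (richness >= 1) on four network properties, and the predicted
#' presence-probability curve along the co-exclusion proportion with the
#' other properties held at their medians. Complete separation triggers a
#' flagged ridge-penalized fallback fit.
#'
#' @param profiles a `local_profiles` table.
#' @param presence samples x OTUs 0/1 matrix (same samples).
#' @param pathogen_otus character vector of pathogen OTU ids.
#' @param properties the model's four properties.
#' @param curve_n number of grid points for the probability curve.
#' @return object of class `pathogen_fit`.
#' @export
pathogen_analysis <- function(profiles, presence, pathogen_otus,
                              properties = c("clustering_pos", "modularity_pos",
                                             "avg_path_length_neg",
                                             "coexclusion_proportion"),
                              curve_n = 50L) {
  hits <- intersect(pathogen_otus, colnames(presence))
  if (length(hits) == 0L)
    stop_localweb("none of the pathogen OTUs occur in the OTU universe")
  richness <- rowSums(presence[, hits, drop = FALSE] > 0)
  if (all(richness == 0))
    stop_localweb("no pathogen OTU is present in any sample; nothing to model")
  ord <- match(profiles$sample_id, rownames(presence))
  if (anyNA(ord)) stop_localweb("profiles and presence matrix sample sets differ")
  richness <- richness[ord]
  d <- profiles[, properties, drop = FALSE]
  d$present <- as.integer(richness >= 1L)
  ok <- stats::complete.cases(d)
  d <- d[ok, , drop = FALSE]
  rich_cor <- spearman_cor(richness[ok], profiles$coexclusion_proportion[ok])

  if (length(unique(d$present)) < 2L)
    stop_localweb("pathogen presence is constant (",
                  if (all(d$present == 1L)) "every" else "no",
                  " sample has a pathogen); the presence model is undefined")
  form <- stats::as.formula(paste("present ~", paste(properties, collapse = " + ")))
  penalized <- FALSE
  fit <- suppressWarnings(stats::glm(form, data = d, family = stats::binomial()))
  separated <- !fit$converged || any(abs(stats::coef(fit)[-1L]) > 20) ||
    all(fit$fitted.values > 1 - 1e-8 | fit$fitted.values < 1e-8)
  coefs <- NULL
  if (separated) {
    penalized <- TRUE
    X <- as.matrix(d[, properties, drop = FALSE])
    rf <- glmnet::glmnet(X, d$present, family = "binomial", alpha = 0,
                         lambda = 1e-2)
    beta <- c(as.numeric(rf$a0), as.numeric(rf$beta))
    names(beta) <- c("(Intercept)", properties)
    coefs <- data.frame(estimate = beta, std_error = NA_real_, p = NA_real_)
    warning("complete separation: ridge-penalized fallback fit (no p-values)",
            call. = FALSE)
  } else {
    sm <- summary(fit)$coefficients
    coefs <- data.frame(estimate = sm[, 1L], std_error = sm[, 2L], p = sm[, 4L])
  }

  grid <- data.frame(coexclusion_proportion = seq(
    min(d$coexclusion_proportion), max(d$coexclusion_proportion),
    length.out = curve_n))
  for (p in setdiff(properties, "coexclusion_proportion"))
    grid[[p]] <- stats::median(d[[p]])
  eta <- coefs$estimate[1L] +
    as.matrix(grid[, properties, drop = FALSE]) %*% coefs$estimate[-1L]
  grid$probability <- stats::plogis(as.vector(eta))

  out <- list(richness = stats::setNames(richness, profiles$sample_id),
              richness_vs_coexclusion = list(r = unname(rich_cor$estimate),
                                             p = rich_cor$p.value),
              coefficients = coefs, penalized = penalized,
              curve = grid[, c("coexclusion_proportion", "probability")],
              n = nrow(d))
  class(out) <- "pathogen_fit"
  out
}

#' @export
print.pathogen_fit <- function(x, ...) {
  cat("Pathogen-presence model, n =", x$n,
      if (x$penalized) "(ridge fallback)", "\n")
  cat("Spearman r (richness vs coexclusion proportion):",
      format(x$richness_vs_coexclusion$r, digits = 3),
      " p =", format(x$richness_vs_coexclusion$p, digits = 3), "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Spearman correlation of alpha diversity with each network property
#'
#' @param profiles a `local_profiles` table.
#' @param shannon named H' vector (names = sample ids) or unnamed vector
#'   aligned with the profile rows.
#' @param properties property columns.
#' @return data.frame: property, r, p.
#' @export
diversity_property_correlation <- function(profiles, shannon,
                                           properties = intersect(
                                             network_property_columns(),
                                             names(profiles))) {
  h <- if (!is.null(names(shannon))) shannon[profiles$sample_id] else shannon
  if (length(h) != nrow(profiles))
    stop_localweb("H' vector and profiles are not aligned")
  out <- do.call(rbind, lapply(properties, function(p) {
    v <- profiles[[p]]
    ok <- !is.na(v) & !is.na(h)
    if (sum(ok) < 3L || stats::sd(v[ok]) == 0)
      return(NULL)
    ct <- spearman_cor(h, v)
    data.frame(property = p, r = unname(ct$estimate), p = ct$p.value,
               n = sum(ok), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' PCA of log-transformed, scaled environmental variables
#'
#' Natural-log transform (with an optional additive shift for non-positive
#' values), per-variable z-scaling, then eigendecomposition of the
#' correlation matrix. Constant variables are dropped with a warning.
#'
#' @param metadata data.frame; numeric columns are used.
#' @param variables columns to use (default: all numeric).
#' @param shift added to every value before the log (default 0; required
#'   positive when non-positive values are present).
#' @return list: `scores`, `loadings`, `explained_variance` (fractions).
#' @export
env_pca <- function(metadata, variables = NULL, shift = 0) {
  md <- as.data.frame(metadata)
  if (is.null(variables))
    variables <- names(md)[vapply(md, is.numeric, logical(1))]
  X <- md[, variables, drop = FALSE]
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (any(as.matrix(X) + shift <= 0))
    stop_localweb("non-positive value(s); supply a positive `shift` for the log transform")
  X <- log(X + shift)
  keep <- vapply(X, function(v) stats::sd(v) > 0, logical(1))
  if (any(!keep))
    warning("dropped constant variable(s): ",
            paste(names(X)[!keep], collapse = ", "), call. = FALSE)
  X <- X[, keep, drop = FALSE]
  if (ncol(X) < 2L) stop_localweb("need at least 2 usable variables")
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  list(scores = pc$x, loadings = pc$rotation,
       explained_variance = pc$sdev^2 / sum(pc$sdev^2))
}
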