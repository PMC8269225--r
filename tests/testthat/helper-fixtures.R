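# Shared fixtures, generated once per session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# management-structured mixed-model simulator with known coefficients
sim_lmm_data <- function(n_per_region = 25, seed = 1,
                         beta = c(conventional = -1.6, organic = -1.7,
                                  biodynamic = -2.4),
                         b_hum = -0.12, sd_region = 0.3, sd_resid = 0.2) {
  set.seed(seed)
  regions <- paste0("R", 1:6)
  d <- data.frame(
    region = rep(regions, each = n_per_region),
    country = rep(c("US", "ES"), each = 3 * n_per_region),
    management = sample(names(beta), 6 * n_per_region, replace = TRUE),
    humidity = runif(6 * n_per_region, 0.2, 0.9),
    max_temperature = runif(6 * n_per_region, 10, 35),
    wind_speed = rgamma(6 * n_per_region, 2, 1))
  re <- rnorm(6, 0, sd_region)
  hum_c <- d$humidity - ave(d$humidity, d$country)
  hum_c <- hum_c / ave(d$humidity, d$country, FUN = sd)
  eta <- beta[d$management] + b_hum * hum_c +
    re[match(d$region, regions)] + rnorm(nrow(d), 0, sd_resid)
  d$y <- exp(eta)
  attr(d, "truth") <- c(beta, humidity = b_hum)
  d
}

# a small deterministic count matrix for IO / diversity tests
toy_counts <- function() {
  m <- matrix(c(5L, 0L, 1L, 2L, 0L, 7L), nrow = 2,
              dimnames = list(c("s1", "s2"), c("otuA", "otuB", "otuC")))
  m
}

small_sim <- function(seed = 5) {
  cached(paste0("small_sim_", seed),
         generate_metacommunity(localweb:::small_fixture_config(seed)))
}

# full chain on the standard two-regime fixture (used by several suites)
standard_chain <- function(seed) {
  cached(paste0("std_chain_", seed), {
    sim <- generate_metacommunity(localweb:::standard_fixture_config(seed))
    rar <- rarefy_counts(sim$counts, depth = 20000L, seed = seed)
    pres <- to_presence(prevalence_filter(rar, 0.02))
    assoc <- all_pair_associations(pres, alpha = 0.05)
    mw <- build_metaweb(assoc, colnames(pres), stratum = "ES")
    prof <- suppressMessages(profile_all(mw, pres))
    list(sim = sim, rarefied = rar, presence = pres, assoc = assoc,
         metaweb = mw, profiles = prof,
         regime = sim$truth$site_regime[prof$sample_id])
  })
}

# small metaweb + presence chain for cheaper structural tests
small_chain <- function(seed = 5) {
  cached(paste0("small_chain_", seed), {
    sim <- small_sim(seed)
    rar <- rarefy_counts(sim$counts, depth = 20000L, seed = seed)
    pres <- to_presence(prevalence_filter(rar, 0.02))
    assoc <- all_pair_associations(pres, alpha = 0.05)
    mw <- build_metaweb(assoc, colnames(pres), stratum = "ES")
    prof <- suppressMessages(profile_all(mw, pres))
    list(sim = sim, rarefied = rar, presence = pres, assoc = assoc,
         metaweb = mw, profiles = prof)
  })
}
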