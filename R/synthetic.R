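#' Synthetic metacommunities with planted network structure
#'
#' Generates sample-by-OTU read-count tables with the statistical
#' structure the downstream analyses assume: sites along an environmental
#' (temperature) gradient, OTUs organised into guilds (thermal bands) with
#' Gaussian niche kernels, and two community regimes mapped onto
#' management labels. A "cooperative" site hosts one well-mixed community
#' (narrow kernel around the site temperature: a dense, mutually
#' co-occurring species clump). A "partitioned" site is divided into
#' niches: a wide kernel spans several guilds but species outside the
#' site's dominant guild are suppressed by the exclusion strength, so the
#' sample combines a dominant clump with sparse satellites of globally
#' co-excluding guilds (modular local structure, local co-exclusions).
#' Reads are lognormal-abundance multinomial draws; full ground truth
#' (guilds, niche optima, pathogen flags, per-site regime) is returned.
#'
#' @name synthetic_data_module
NULL

#' Generator configuration
#'
#' Defaults mirror a two-country vineyard survey: 175 sites per country,
#' management counts 65/39/20 (+51 undeclared) in one country and
#' 78/79/15 (+3 undeclared) in the other, sequencing depths of at least
#' 20000 reads, and an environmental (maximum temperature) gradient that
#' induces niche-structured occupancy.
#'
#' @param n_otus number of OTUs in the regional pool.
#' @param countries named integer vector of sites per country.
#' @param management_mix named list (per country) of counts over
#'   conventional/organic/biodynamic/unknown; must sum to the site count.
#' @param regime_map management -> regime ("partitioned", "cooperative" or
#'   "mixed"); "mixed" draws per-site regimes with `organic_weight`.
#' @param organic_weight probability that a mixed-management site follows
#'   the partitioned regime.
#' @param n_guilds number of guilds K.
#' @param niche_breadth named niche sd (deg C) per regime.
#' @param guild_spread sd (deg C) of OTU optima around their guild centre.
#' @param exclusion_strength epsilon in \[0, 1\]: occupancy of cross-guild
#'   OTUs at partitioned sites is multiplied by (1 - epsilon).
#' @param satellite_level baseline (temperature-flat) occupancy of
#'   cross-guild OTUs at partitioned sites, relative to the kernel peak,
#'   before the (1 - epsilon) suppression.
#' @param temp_range maximum-temperature gradient (deg C).
#' @param depth_range sequencing-depth range (uniform integers; min >=
#'   20000 by default).
#' @param abundance_lognormal meanlog/sdlog of the abundance layer.
#' @param pathogen_fraction fraction of OTUs flagged as pathogens.
#' @param pathogen_affinity occupancy multiplier for pathogen OTUs at
#'   cooperative sites (its reciprocal applies at partitioned sites);
#'   values > 1 plant the negative pathogen-richness vs co-exclusion
#'   correlation, values < 1 reverse it.
#' @param target_richness desired mean number of OTUs per site; baseline
#'   occupancy is calibrated per regime to reach it.
#' @param n_regions contiguous temperature bands (regions) per country.
#' @param seed integer RNG seed.
#' @return validated list of class `generator_config`.
#' @export
generator_config <- function(
    n_otus = 1500L,
    countries = c(US = 175L, ES = 175L),
    management_mix = list(
      US = c(conventional = 65L, organic = 39L, biodynamic = 20L, unknown = 51L),
      ES = c(conventional = 78L, organic = 79L, biodynamic = 15L, unknown = 3L)),
    regime_map = c(conventional = "partitioned", organic = "mixed",
                   biodynamic = "cooperative", unknown = "mixed"),
    organic_weight = 0.5,
    n_guilds = 4L,
    niche_breadth = c(cooperative = 2, partitioned = 6),
    guild_spread = 2.5,
    exclusion_strength = 0.85,
    satellite_level = 1.5,
    temp_range = c(12, 38),
    depth_range = c(20000L, 60000L),
    abundance_lognormal = c(meanlog = 0, sdlog = 1.5),
    pathogen_fraction = 0.01,
    pathogen_affinity = 1.5,
    target_richness = 150,
    n_regions = 3L,
    seed = 1L) {
  cfg <- as.list(environment())
  if (!setequal(names(cfg$countries), names(cfg$management_mix)))
    stop_localweb("countries and management_mix must name the same countries")
  for (co in names(cfg$countries)) {
    if (sum(cfg$management_mix[[co]]) != cfg$countries[[co]])
      stop_localweb("management_mix for ", co, " must sum to its site count")
  }
  if (cfg$exclusion_strength < 0 || cfg$exclusion_strength > 1)
    stop_localweb("exclusion_strength must be in [0, 1]")
  if (any(cfg$niche_breadth <= 0)) stop_localweb("niche breadths must be positive")
  if (cfg$depth_range[1L] <= 0) stop_localweb("depths must be positive")
  if (cfg$n_guilds < 1L) stop_localweb("need at least one guild")
  class(cfg) <- "generator_config"
  cfg
}

site_regimes <- function(mgmt, regime_map, organic_weight) {
  base <- regime_map[mgmt]
  mixed <- base == "mixed"
  base[mixed] <- ifelse(stats::runif(sum(mixed)) < organic_weight,
                        "partitioned", "cooperative")
  unname(base)
}

#' Generate a synthetic metacommunity
#'
#' Sites receive uniform maximum temperatures on the gradient (regions are
#' contiguous temperature bands), humidity/wind/coordinates from simple
#' survey-like distributions, and a regime via their management. Each OTU
#' i has occupancy probability at site s
#' `p = b * exp(-(T_s - mu_i)^2 / (2 sigma_regime^2))`, with cross-guild
#' OTUs at partitioned sites additionally multiplied by
#' `(1 - exclusion_strength)`; `b` is calibrated per regime so mean
#' richness matches `target_richness`. Occupied OTUs draw lognormal
#' abundances and reads are multinomial at the site's depth. Deterministic
#' given the config seed.
#'
#' @param config a [generator_config()].
#' @return list of class `metacommunity_sim`: `counts` (samples x OTUs
#'   integer matrix), `metadata` (data.frame), `truth` (guilds, optima,
#'   guild centres, pathogen flags, per-site regime and dominant guild).
#' @export
generate_metacommunity <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    co_names <- names(config$countries)
    n_sites <- sum(config$countries)
    country <- rep(co_names, times = as.integer(config$countries))
    mgmt <- unlist(lapply(co_names, function(co) {
      mm <- config$management_mix[[co]]
      sample(rep(names(mm), times = as.integer(mm)))
    }), use.names = FALSE)
    sample_ids <- sprintf("%s_s%03d", country, unlist(lapply(
      as.integer(config$countries), seq_len)))

    tmax <- stats::runif(n_sites, config$temp_range[1L], config$temp_range[2L])
    breaks <- seq(config$temp_range[1L], config$temp_range[2L],
                  length.out = config$n_regions + 1L)
    band <- findInterval(tmax, breaks, rightmost.closed = TRUE)
    region <- paste0(country, "_band", band)
    humidity <- stats::runif(n_sites, 0.2, 0.9)
    wind <- stats::rgamma(n_sites, shape = 2, scale = 1.5)
    lat <- ifelse(country == co_names[1L], stats::runif(n_sites, 34, 46),
                  stats::runif(n_sites, 36, 43))
    lon <- ifelse(country == co_names[1L], stats::runif(n_sites, -122, -75),
                  stats::runif(n_sites, -8, 3))
    alt <- stats::runif(n_sites, 0, 900)
    date <- as.Date("2015-01-01") +
      sample.int(4L * 365L, n_sites, replace = TRUE)
    regime <- site_regimes(mgmt, config$regime_map, config$organic_weight)
    depth <- sample(seq.int(config$depth_range[1L], config$depth_range[2L]),
                    n_sites, replace = TRUE)

    K <- config$n_guilds
    guild <- rep_len(seq_len(K), config$n_otus)
    centre_span <- diff(config$temp_range)
    guild_centre <- config$temp_range[1L] +
      centre_span * (seq_len(K) - 0.5) / K
    optimum <- stats::rnorm(config$n_otus, guild_centre[guild],
                            config$guild_spread)
    pathogen <- rep(FALSE, config$n_otus)
    n_path <- round(config$pathogen_fraction * config$n_otus)
    if (n_path > 0) pathogen[sample.int(config$n_otus, n_path)] <- TRUE
    otu_ids <- sprintf("OTU%04d", seq_len(config$n_otus))

    # dominant guild per partitioned site: proximity-weighted draw
    dom_sd <- centre_span / (2 * K)
    dominant <- vapply(seq_len(n_sites), function(s) {
      w <- exp(-(tmax[s] - guild_centre)^2 / (2 * dom_sd^2))
      sample.int(K, 1L, prob = w + 1e-9)
    }, integer(1))

    # raw occupancy (sites x OTUs) before baseline calibration:
    # cooperative sites follow one narrow kernel around the site temperature;
    # partitioned sites follow a wide kernel for the dominant guild and a
    # flat, exclusion-suppressed satellite level for all other guilds.
    kernel_for <- function(sigma) {
      exp(-outer(tmax, optimum, "-")^2 / (2 * sigma^2))
    }
    part <- regime == "partitioned"
    raw <- kernel_for(config$niche_breadth[["cooperative"]])
    if (any(part)) {
      kp <- kernel_for(config$niche_breadth[["partitioned"]])
      same <- outer(dominant, guild, "==")
      sat <- (1 - config$exclusion_strength) * config$satellite_level
      raw[part, ] <- ifelse(same[part, , drop = FALSE],
                            kp[part, , drop = FALSE], sat)
    }
    if (any(pathogen)) {
      raw[!part, pathogen] <- raw[!part, pathogen] * config$pathogen_affinity
      raw[part, pathogen] <- raw[part, pathogen] / config$pathogen_affinity
    }
    # calibrate baseline occupancy per regime to the target mean richness
    p_occ <- raw
    for (rg in c("cooperative", "partitioned")) {
      rows <- regime == rg
      if (!any(rows)) next
      b <- config$target_richness / mean(rowSums(raw[rows, , drop = FALSE]))
      p_occ[rows, ] <- pmin(0.95, raw[rows, , drop = FALSE] * b)
    }

    counts <- matrix(0L, n_sites, config$n_otus,
                     dimnames = list(sample_ids, otu_ids))
    for (s in seq_len(n_sites)) {
      occ <- stats::runif(config$n_otus) < p_occ[s, ]
      tries <- 0L
      while (sum(occ) < 2L && tries < 10L) {
        occ <- stats::runif(config$n_otus) < p_occ[s, ]
        tries <- tries + 1L
      }
      if (sum(occ) < 2L) {
        warning("site ", sample_ids[s], " kept with ", sum(occ),
                " occupant(s) after 10 retries", call. = FALSE)
        if (sum(occ) == 0L) occ[which.max(p_occ[s, ])] <- TRUE
      }
      if (tries > 0L)
        log_msg("site ", sample_ids[s], " regenerated ", tries, " time(s)")
      ab <- stats::rlnorm(sum(occ), config$abundance_lognormal[["meanlog"]],
                          config$abundance_lognormal[["sdlog"]])
      counts[s, occ] <- stats::rmultinom(1L, depth[s], prob = ab)[, 1L]
    }

    metadata <- data.frame(
      sample_id = sample_ids, country = country, region = region,
      management = mgmt, latitude = lat, longitude = lon, altitude = alt,
      max_temperature = tmax, min_temperature = tmax - stats::runif(n_sites, 5, 15),
      humidity = humidity, wind_speed = wind,
      date = format(date, "%Y-%m-%d"), stringsAsFactors = FALSE)
    truth <- list(
      guild_of = stats::setNames(guild, otu_ids),
      niche_optimum = stats::setNames(optimum, otu_ids),
      guild_centre = guild_centre,
      pathogen_flags = stats::setNames(pathogen, otu_ids),
      site_regime = stats::setNames(regime, sample_ids),
      site_dominant_guild = stats::setNames(dominant, sample_ids),
      depths = stats::setNames(depth, sample_ids))
    out <- list(counts = validate_community_matrix(counts),
                metadata = metadata, truth = truth, config = config)
    class(out) <- "metacommunity_sim"
    out
  })
}

#' @export
print.metacommunity_sim <- function(x, ...) {
  cat("Synthetic metacommunity:", nrow(x$counts), "sites x",
      ncol(x$counts), "OTUs\n")
  cat("Regimes:", paste(names(table(x$truth$site_regime)),
                        table(x$truth$site_regime), collapse = ", "), "\n")
  invisible(x)
}

small_fixture_config <- function(seed) {
  generator_config(
    n_otus = 150L, countries = c(ES = 30L),
    management_mix = list(ES = c(conventional = 15L, organic = 0L,
                                 biodynamic = 15L, unknown = 0L)),
    n_regions = 2L, target_richness = 35, seed = seed)
}

standard_fixture_config <- function(seed) {
  generator_config(
    n_otus = 600L, countries = c(ES = 120L),
    management_mix = list(ES = c(conventional = 60L, organic = 0L,
                                 biodynamic = 60L, unknown = 0L)),
    n_regions = 3L, target_richness = 100, seed = seed)
}

#' Write canonical benchmark fixtures
#'
#' For each seed, writes a small (30 sites x 150 OTUs) and a standard
#' (120 sites x 600 OTUs) two-regime metacommunity as TSV and BIOM count
#' tables plus metadata and ground-truth TSVs.
#'
#' @param seeds integer vector of at least 3 seeds.
#' @param dir output directory (created if needed).
#' @param sizes subset of `c("small", "standard")`.
#' @return named list of per-fixture file paths, invisibly.
#' @export
benchmark_suite <- function(seeds, dir, sizes = c("small", "standard")) {
  if (length(seeds) < 3L) stop_localweb("need at least 3 seeds")
  sizes <- match.arg(sizes, several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  for (seed in seeds) {
    for (size in sizes) {
      cfg <- if (size == "small") small_fixture_config(seed)
             else standard_fixture_config(seed)
      sim <- generate_metacommunity(cfg)
      stem <- file.path(dir, sprintf("%s_seed%d", size, seed))
      paths <- c(counts_tsv = paste0(stem, "_counts.tsv"),
                 counts_biom = paste0(stem, "_counts.biom"),
                 metadata = paste0(stem, "_metadata.tsv"),
                 otu_truth = paste0(stem, "_otu_truth.tsv"),
                 site_truth = paste0(stem, "_site_truth.tsv"))
      write_otu_table(sim$counts, paths[["counts_tsv"]], "tsv")
      write_otu_table(sim$counts, paths[["counts_biom"]], "biom")
      utils::write.table(sim$metadata, paths[["metadata"]], sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(
        data.frame(otu_id = colnames(sim$counts),
                   guild = sim$truth$guild_of,
                   niche_optimum = sim$truth$niche_optimum,
                   pathogen = sim$truth$pathogen_flags),
        paths[["otu_truth"]], sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(
        data.frame(sample_id = rownames(sim$counts),
                   regime = sim$truth$site_regime,
                   dominant_guild = sim$truth$site_dominant_guild,
                   depth = sim$truth$depths),
        paths[["site_truth"]], sep = "\t", quote = FALSE, row.names = FALSE)
      out[[sprintf("%s_seed%d", size, seed)]] <- paths
    }
  }
  invisible(out)
}
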