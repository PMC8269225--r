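#' End-to-end pipeline: counts + metadata -> metawebs, profiles, statistics
#'
#' Executes the full chain per stratum — rarefaction, prevalence filter,
#' binarization, exact pairwise associations, metaweb assembly, local
#' network profiles, null-model z-scores — followed by the pooled
#' statistics layer, writing every stage artifact as plain-text TSV/JSON
#' plus a run manifest that makes re-runs bit-identical.
#'
#' @name pipeline_module
NULL

#' Pipeline configuration
#'
#' Defaults are the conventional settings of the analysis: rarefaction to
#' 20000 reads, a 2% prevalence filter applied per stratum, significance
#' level 0.05 on the raw pairwise tails, walktrap steps 4, and 1000 null
#' randomizations.
#'
#' @param counts path to an OTU table (or a samples x OTUs matrix).
#' @param metadata path to a metadata TSV/CSV (or a data.frame).
#' @param out_dir output directory.
#' @param stratify_by metadata column defining strata (default country).
#' @param depth rarefaction depth.
#' @param min_prevalence prevalence threshold.
#' @param alpha significance level for pair classification.
#' @param steps walktrap random-walk length.
#' @param n_rand null-model randomizations.
#' @param null_properties properties to z-score against the null.
#' @param weighted_null use occurrence-frequency-weighted null draws.
#' @param seed master seed; each randomized stage derives its own.
#' @param run_stats run the statistics layer (correlations, ANOVA, mixed
#'   models) when the metadata supports it.
#' @return list of class `run_config`.
#' @export
run_config <- function(counts, metadata, out_dir,
                       stratify_by = "country", depth = 20000L,
                       min_prevalence = 0.02, alpha = 0.05, steps = 4L,
                       n_rand = 1000L,
                       null_properties = c("modularity_pos", "clustering_pos",
                                           "coexclusion_proportion"),
                       weighted_null = FALSE, seed = 1L, run_stats = TRUE) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Read a flat key = value configuration file
#'
#' A minimal TOML-style dialect: one `key = value` per line, `#` comments,
#' bare numbers/booleans and quoted strings. Used for generator and run
#' configurations.
#'
#' @param path file path.
#' @return named list of parsed scalars.
#' @export
read_config_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop_localweb("config line without '=': ", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    out[[key]] <- if (grepl('^".*"$', val)) {
      gsub('^"|"$', "", val)
    } else if (val %in% c("true", "false")) {
      val == "true"
    } else if (grepl("^-?[0-9.eE+]+$", val)) {
      as.numeric(val)
    } else val
  }
  out
}

config_hash <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  flat <- cfg[!vapply(cfg, function(x) is.matrix(x) || is.data.frame(x),
                      logical(1))]
  flat$out_dir <- NULL  # analysis parameters only, not the output location
  writeLines(paste(names(flat),
                   vapply(flat, function(x) paste(format(x), collapse = ","),
                          character(1)), sep = "="), tf)
  unname(tools::md5sum(tf))
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' @param config a [run_config()].
#' @return the manifest list, invisibly; all artifacts are written under
#'   `config$out_dir` (per-stratum subdirectories plus pooled tables and
#'   `manifest.json`; timings go to `pipeline.log`, which is the only
#'   non-deterministic output file).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  log_lines <- character(0)
  stage <- function(name, expr) {
    ts <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop_localweb("stage '", name, "' failed (seed ", config$seed, "): ",
                    conditionMessage(e)))
    log_lines <<- c(log_lines, sprintf("%-24s %8.2fs", name,
                                       proc.time()[["elapsed"]] - ts))
    res
  }

  counts <- stage("read_counts", {
    if (is.character(config$counts))
      read_otu_table(config$counts,
                     if (grepl("\\.biom$", config$counts)) "biom" else "tsv")
    else validate_community_matrix(config$counts)
  })
  metadata <- stage("read_metadata", {
    if (is.character(config$metadata)) read_sample_metadata(config$metadata)
    else config$metadata
  })
  if (!config$stratify_by %in% names(metadata))
    stop_localweb("stratify_by column '", config$stratify_by,
                  "' not in metadata")

  rarefied <- stage("rarefy", rarefy_counts(counts, config$depth, config$seed))
  shannon <- stage("alpha_diversity", shannon_diversity(rarefied))
  write_tsv(data.frame(sample_id = names(shannon), shannon = shannon),
            file.path(config$out_dir, "diversity.tsv"))

  meta_idx <- match(rownames(rarefied), metadata$sample_id)
  if (anyNA(meta_idx))
    stop_localweb("metadata missing for sample(s): ",
                  paste(utils::head(rownames(rarefied)[is.na(meta_idx)], 5L),
                        collapse = ", "))
  strata <- metadata[[config$stratify_by]][meta_idx]
  counts_rows <- list()
  profiles_list <- list()
  nulls_list <- list()
  for (st in unique(strata)) {
    sdir <- file.path(config$out_dir, paste0("stratum_", st))
    dir.create(sdir, showWarnings = FALSE)
    sub <- rarefied[strata == st, , drop = FALSE]
    filt <- stage(paste0(st, ":prevalence_filter"),
                  prevalence_filter(sub, config$min_prevalence))
    pres <- to_presence(filt)
    assoc <- stage(paste0(st, ":associations"),
                   all_pair_associations(pres, alpha = config$alpha))
    write_association_table(assoc, file.path(sdir, "associations.tsv"))
    mw <- stage(paste0(st, ":metaweb"),
                build_metaweb(assoc, colnames(pres), stratum = st,
                              steps = config$steps))
    write_metaweb(mw, file.path(sdir, "metaweb_edges.tsv"),
                  file.path(sdir, "metaweb_modules.tsv"))
    mw_sum <- summary(mw)
    jsonlite::write_json(
      list(stratum = st, n_nodes = mw_sum$n_nodes,
           positive = unclass(mw_sum$positive),
           negative = unclass(mw_sum$negative)),
      file.path(sdir, "metaweb_properties.json"),
      auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
    prof <- stage(paste0(st, ":local_profiles"), profile_all(mw, pres))
    write_tsv(as.data.frame(prof), file.path(sdir, "profiles.tsv"))
    write_tsv(summary(prof), file.path(sdir, "profile_ranges.tsv"))
    weights <- if (config$weighted_null) colSums(pres)[mw$nodes] else NULL
    nz <- stage(paste0(st, ":null_model"),
                null_zscores_all(mw, pres, properties = config$null_properties,
                                 n_rand = config$n_rand, seed = config$seed,
                                 weights = weights))
    write_tsv(as.data.frame(nz), file.path(sdir, "null_zscores.tsv"))
    counts_rows[[st]] <- c(samples = nrow(sub), otus_filtered = ncol(filt),
                           positive_edges = nrow(mw$positive_edges),
                           negative_edges = nrow(mw$negative_edges))
    profiles_list[[st]] <- prof
    nulls_list[[st]] <- nz
  }

  profiles <- do.call(rbind, lapply(profiles_list, as.data.frame))
  rownames(profiles) <- NULL
  class(profiles) <- c("local_profiles", "data.frame")
  merged <- merge(as.data.frame(profiles), metadata, by = "sample_id",
                  sort = TRUE)
  if (config$run_stats) {
    stage("stats:correlations", {
      strat_vec <- merged[[config$stratify_by]]
      pc <- property_correlations(merged, strata = strat_vec)
      write_tsv(pc, file.path(config$out_dir, "property_correlations.tsv"))
    })
    stage("stats:diversity", {
      dc <- diversity_property_correlation(merged, shannon)
      write_tsv(dc, file.path(config$out_dir, "diversity_correlations.tsv"))
    })
    if ("management" %in% names(merged) &&
        length(unique(merged$management)) >= 2L) {
      stage("stats:anova", {
        fac2 <- if (length(unique(merged[[config$stratify_by]])) >= 2L)
          config$stratify_by else "management"
        resp <- intersect(c("modularity_pos", "clustering_pos",
                            "coexclusion_proportion"), names(merged))
        if (fac2 == "management") {
          # one stratum: one-way comparison via kruskal-wallis instead
          aout <- do.call(rbind, lapply(resp, function(r) {
            ok <- !is.na(merged[[r]])
            kw <- stats::kruskal.test(merged[[r]][ok],
                                      factor(merged$management[ok]))
            data.frame(term = "management", response = r,
                       statistic = unname(kw$statistic), p = kw$p.value)
          }))
        } else {
          aout <- do.call(rbind, lapply(resp, function(r) {
            a <- two_way_anova(merged, r, c("management", fac2))
            a$response <- r
            a
          }))
        }
        write_tsv(aout, file.path(config$out_dir, "management_tests.tsv"))
      })
    }
    if (all(c("management", "region", "humidity", "max_temperature",
              "wind_speed") %in% names(merged)) &&
        length(unique(merged$region)) >= 2L) {
      stage("stats:mixed_models", {
        resp <- intersect(c("modularity_pos", "clustering_pos",
                            "coexclusion_proportion"), names(merged))
        rows <- list()
        for (r in resp) {
          fit <- tryCatch(fit_property_lmm(merged, r), error = function(e) NULL)
          if (is.null(fit)) next
          cf <- fit$coefficients
          rows[[r]] <- data.frame(response = r, term = rownames(cf), cf,
                                  marginal_r2 = fit$marginal_r2,
                                  singular = fit$singular_fallback,
                                  row.names = NULL)
        }
        if (length(rows))
          write_tsv(do.call(rbind, rows),
                    file.path(config$out_dir, "mixed_models.tsv"))
      })
    }
  }

  manifest <- list(
    package = "localweb",
    version = as.character(utils::packageVersion("localweb")),
    config = list(stratify_by = config$stratify_by, depth = config$depth,
                  min_prevalence = config$min_prevalence,
                  alpha = config$alpha, steps = config$steps,
                  n_rand = config$n_rand,
                  null_properties = config$null_properties,
                  weighted_null = config$weighted_null, seed = config$seed),
    config_hash = config_hash(config),
    strata = counts_rows,
    n_samples_input = nrow(counts),
    n_samples_rarefied = nrow(rarefied))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_lines <- c(log_lines, sprintf("%-24s %8.2fs", "total",
                                    proc.time()[["elapsed"]] - t0))
  writeLines(log_lines, log_path)
  invisible(manifest)
}
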