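#' Community matrices: reading, writing, rarefaction and filtering
#'
#' A community matrix in this package is a plain integer matrix of read
#' counts with samples as rows and OTUs as columns, both axes named with
#' unique identifiers. This is the orientation vegan expects; the on-disk
#' TSV convention (OTUs as rows, samples as columns) is transposed on
#' read/write.
#'
#' @name community_matrix
NULL

#' Validate a community matrix
#'
#' Checks the invariants every downstream stage relies on: unique sample and
#' OTU identifiers, non-negative integer counts, and (optionally) positive
#' row sums.
#'
#' @param m numeric matrix, samples x OTUs, with dimnames.
#' @param require_positive_rows if `TRUE`, every sample must have at least
#'   one read.
#' @return `m`, invisibly, with integer storage.
#' @export
validate_community_matrix <- function(m, require_positive_rows = FALSE) {
  if (!is.matrix(m) || !is.numeric(m))
    stop_localweb("community matrix must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop_localweb("community matrix must have sample (row) and OTU (column) names")
  dup_s <- rownames(m)[duplicated(rownames(m))]
  if (length(dup_s))
    stop_localweb("duplicate sample identifier(s): ", paste(unique(dup_s), collapse = ", "))
  dup_o <- colnames(m)[duplicated(colnames(m))]
  if (length(dup_o))
    stop_localweb("duplicate OTU identifier(s): ", paste(unique(dup_o), collapse = ", "))
  if (anyNA(m) || any(m < 0))
    stop_localweb("counts must be non-negative and non-missing")
  if (any(m != floor(m)))
    stop_localweb("counts must be integers")
  if (require_positive_rows && any(rowSums(m) == 0))
    stop_localweb("sample(s) with zero total reads: ",
                  paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
  storage.mode(m) <- "integer"
  invisible(m)
}

#' Read an OTU table
#'
#' TSV dialect: OTUs as rows, samples as columns, first column the OTU
#' identifier, header row of sample identifiers. BIOM dialect: the JSON
#' BIOM 1.0 standard (read via the biomformat package).
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom"`.
#' @return an integer samples x OTUs matrix.
#' @export
read_otu_table <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (format == "biom") {
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")  # OTUs x samples
    m <- t(m)
    return(validate_community_matrix(m))
  }
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop_localweb("ragged TSV: line ", bad, " has ", nf[bad],
                  " fields, expected ", nf[1L])
  }
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, stringsAsFactors = FALSE)
  otu_ids <- as.character(tab[[1L]])
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(vals))
    stop_localweb("non-numeric count cell(s) in ", path)
  rownames(vals) <- otu_ids
  validate_community_matrix(t(vals))
}

#' Write an OTU table
#'
#' @param m samples x OTUs count matrix.
#' @param path output file path.
#' @param format `"tsv"` or `"biom"`.
#' @export
write_otu_table <- function(m, path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  validate_community_matrix(m)
  if (format == "biom") {
    b <- biomformat::make_biom(t(m))
    b$date <- "1970-01-01T00:00:00"  # fixed so identical tables give identical files
    biomformat::write_biom(b, path)
  } else {
    out <- data.frame(otu_id = colnames(m), t(m), check.names = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read per-sample metadata
#'
#' Expects a TSV/CSV with at least a `sample_id` column; the conventional
#' survey columns are `country`, `region`, `management` (one of
#' conventional, organic, biodynamic, unknown), coordinates, and weather
#' variables such as `max_temperature`, `humidity` (fraction in \[0, 1\])
#' and `wind_speed`.
#'
#' @param path file path.
#' @param sep field separator; guessed from the extension by default.
#' @return a data.frame with one row per sample.
#' @export
read_sample_metadata <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  md <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = TRUE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(md))
    stop_localweb("metadata must contain a sample_id column")
  dup <- md$sample_id[duplicated(md$sample_id)]
  if (length(dup))
    stop_localweb("duplicate metadata record(s) for sample(s): ",
                  paste(unique(dup), collapse = ", "))
  if ("management" %in% names(md)) {
    ok <- c("conventional", "organic", "biodynamic", "unknown")
    bad <- setdiff(unique(md$management), c(ok, NA))
    if (length(bad))
      stop_localweb("management level(s) outside {",
                    paste(ok, collapse = ", "), "}: ", paste(bad, collapse = ", "))
  }
  if ("humidity" %in% names(md)) {
    h <- md$humidity[!is.na(md$humidity)]
    if (any(h < 0 | h > 1))
      stop_localweb("humidity must be a fraction in [0, 1]")
  }
  md
}

#' Rarefy a community matrix to even sequencing depth
#'
#' Each retained sample's counts are replaced by a uniform subsample of its
#' reads, drawn without replacement, summing exactly to `depth` (a single
#' draw, not an average over draws). Samples whose total read count is
#' below `depth` are dropped, with a logged count. Deterministic given
#' `seed`.
#'
#' @param m samples x OTUs count matrix.
#' @param depth target reads per sample (default 20000).
#' @param seed integer RNG seed.
#' @return rarefied matrix with every row summing to `depth`.
#' @export
rarefy_counts <- function(m, depth = 20000L, seed = 1L) {
  validate_community_matrix(m)
  if (!is_count(depth) || depth <= 0) stop_localweb("depth must be a positive integer")
  totals <- rowSums(m)
  keep <- totals >= depth
  if (!any(keep))
    stop_localweb("no sample reaches depth ", depth, "; rarefaction would be empty")
  if (any(!keep))
    log_msg("rarefaction dropped ", sum(!keep), " sample(s) below depth ", depth)
  m <- m[keep, , drop = FALSE]
  with_seed(seed, {
    out <- m
    for (i in seq_len(nrow(m))) {
      row <- m[i, ]
      if (sum(row) == depth) next  # subsample of all reads is the reads themselves
      reads <- rep.int(seq_along(row), row)
      kept <- reads[sample.int(length(reads), depth)]
      out[i, ] <- tabulate(kept, nbins = length(row))
    }
    validate_community_matrix(out)
    out
  })
}

#' Filter OTUs by prevalence
#'
#' Keeps OTU j iff its occupancy (number of samples with a positive count
#' divided by the number of samples) is at least `min_prevalence`
#' (inclusive boundary). Samples are unchanged. Idempotent.
#'
#' @param m samples x OTUs count matrix.
#' @param min_prevalence fraction of samples, in (0, 1].
#' @export
prevalence_filter <- function(m, min_prevalence = 0.02) {
  validate_community_matrix(m)
  if (!is.numeric(min_prevalence) || min_prevalence <= 0 || min_prevalence > 1)
    stop_localweb("min_prevalence must be in (0, 1]")
  prev <- colMeans(m > 0)
  keep <- prev >= min_prevalence
  if (!any(keep))
    stop_localweb("prevalence filter removed every OTU")
  m[, keep, drop = FALSE]
}

#' Binarize a community matrix to presence/absence
#'
#' @param m samples x OTUs count matrix.
#' @return integer 0/1 matrix with identical axes.
#' @export
to_presence <- function(m) {
  validate_community_matrix(m)
  p <- (m > 0) * 1L
  dimnames(p) <- dimnames(m)
  storage.mode(p) <- "integer"
  p
}
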