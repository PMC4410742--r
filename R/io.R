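# Tabular on-disk artifacts. The interchange dialect throughout is TSV with a
# header row, decimal point, no thousands separators. Genomic coordinates are
# 1-based point positions; there is no strand handling.

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) fail("%s: file not found: %s", what, path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    fail("%s: missing required column(s): %s", what,
         paste(missing, collapse = ", "))
  }
  df
}

#' Read a per-nucleotide allele count table
#'
#' Reads the long-format table of targeted-assay read counts: one row per
#' (patient, SNV, sample) with the number of reads supporting each of the four
#' nucleotides. Malformed rows are rejected, never repaired; error messages
#' carry 1-based file line numbers (header is line 1).
#'
#' @param path Path to a TSV with columns `patient_id`, `snv_id`, `sample_id`,
#'   `A`, `C`, `G`, `T`.
#' @return A `data.frame` of class `allele_count_table`.
#' @export
read_count_table <- function(path) {
  req <- c("patient_id", "snv_id", "sample_id", "A", "C", "G", "T")
  df <- read_tsv_checked(path, req, "count table")
  df <- df[, req, drop = FALSE]
  if (nrow(df) > 0L) {
    for (nt in NUCLEOTIDES) {
      v <- suppressWarnings(as.numeric(df[[nt]]))
      bad <- which(is.na(v) | v < 0 | v != floor(v))
      if (length(bad) > 0L) {
        fail("count table: column %s has negative or non-integer counts at line(s) %s",
             nt, paste(bad + 1L, collapse = ", "))
      }
      df[[nt]] <- as.integer(v)
    }
    for (col in c("patient_id", "snv_id", "sample_id")) {
      df[[col]] <- check_ids(df[[col]], sprintf("count table column %s", col))
    }
    key <- paste(df$patient_id, df$snv_id, df$sample_id, sep = "\x1f")
    dup <- which(duplicated(key))
    if (length(dup) > 0L) {
      fail("count table: duplicated (patient, snv, sample) entries at line(s) %s",
           paste(dup + 1L, collapse = ", "))
    }
  }
  class(df) <- c("allele_count_table", "data.frame")
  df
}

#' Write an allele count table
#'
#' @param x An `allele_count_table` (or compatible data frame).
#' @param path Output TSV path.
#' @export
write_count_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

#' Read SNV site definitions
#'
#' @param path TSV with columns `snv_id`, `chrom`, `pos`, `ref`, `alt` and an
#'   optional logical `is_hotspot` column flagging recurrent-candidate sites
#'   (such as the PIK3CA codon-1047 position).
#' @return A `data.frame` of class `snv_sites`.
#' @export
read_snv_sites <- function(path) {
  df <- read_tsv_checked(path, c("snv_id", "chrom", "pos", "ref", "alt"),
                         "SNV sites")
  if (!"is_hotspot" %in% names(df)) df$is_hotspot <- FALSE
  df$is_hotspot <- as.logical(df$is_hotspot)
  validate_snv_sites(df)
}

validate_snv_sites <- function(df) {
  df$snv_id <- check_ids(df$snv_id, "snv_id")
  if (anyDuplicated(df$snv_id)) fail("SNV sites: duplicated snv_id")
  df$pos <- as.numeric(df$pos)
  if (any(is.na(df$pos) | df$pos < 1 | df$pos != floor(df$pos))) {
    fail("SNV sites: pos must be a 1-based integer coordinate")
  }
  bad <- !(df$ref %in% NUCLEOTIDES) | !(df$alt %in% NUCLEOTIDES)
  if (any(bad)) {
    fail("SNV sites: ref/alt must be A, C, G or T (offending: %s)",
         paste(df$snv_id[bad], collapse = ", "))
  }
  same <- df$ref == df$alt
  if (any(same)) {
    fail("SNV sites: ref and alt must differ (offending: %s)",
         paste(df$snv_id[same], collapse = ", "))
  }
  if (any(is.na(df$is_hotspot))) fail("SNV sites: is_hotspot must be TRUE/FALSE")
  class(df) <- c("snv_sites", "data.frame")
  df
}

#' Read sample metadata
#'
#' @param path TSV with columns `sample_id`, `patient_id`, `histology`
#'   (one of `r paste(HISTOLOGIES, collapse=", ")`) and `side`
#'   (`ipsilateral`, `contralateral` or `unknown`).
#' @return A `data.frame` of class `sample_meta`.
#' @export
read_sample_meta <- function(path) {
  df <- read_tsv_checked(path, c("sample_id", "patient_id", "histology", "side"),
                         "sample metadata")
  validate_sample_meta(df)
}

validate_sample_meta <- function(df) {
  df$sample_id <- check_ids(df$sample_id, "sample_id")
  if (anyDuplicated(df$sample_id)) fail("sample metadata: duplicated sample_id")
  bad <- !(df$histology %in% HISTOLOGIES)
  if (any(bad)) {
    fail("sample metadata: unknown histology value(s): %s",
         paste(unique(df$histology[bad]), collapse = ", "))
  }
  bad <- !(df$side %in% SIDES)
  if (any(bad)) {
    fail("sample metadata: unknown side value(s): %s",
         paste(unique(df$side[bad]), collapse = ", "))
  }
  class(df) <- c("sample_meta", "data.frame")
  df
}

#' Write sample metadata
#' @param x A `sample_meta` data frame.
#' @param path Output TSV path.
#' @export
write_sample_meta <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

#' Read a presence-call override list
#'
#' Overrides encode curated calls that contradict the default VAF-cutoff call
#' (values just below the cutoff that match a class well, or just above it
#' that do not). A record that agrees with the threshold call is redundant and
#' rejected when the overrides are applied in [call_presence()].
#'
#' @param path TSV with columns `snv_id`, `sample_id`, `forced_call`
#'   (`present` or `absent`) and a free-text `note`.
#' @return A `data.frame` of class `override_list`.
#' @export
read_overrides <- function(path) {
  df <- read_tsv_checked(path, c("snv_id", "sample_id", "forced_call", "note"),
                         "overrides")
  bad <- !(df$forced_call %in% c("present", "absent"))
  if (any(bad)) fail("overrides: forced_call must be 'present' or 'absent'")
  key <- paste(df$snv_id, df$sample_id, sep = "\x1f")
  if (anyDuplicated(key)) fail("overrides: duplicated (snv, sample) records")
  class(df) <- c("override_list", "data.frame")
  df
}

#' Read a VAF matrix
#'
#' Ingests a rectangular SNV-by-sample matrix of variant allele frequencies,
#' the per-patient layout in which multi-sample targeted resequencing results
#' are typically distributed: first column `snv_id`, one further column per
#' sample. Missing cells (e.g. a failed assay in one sample) are kept as
#' missing, never imputed and never conflated with 0. Read depths are not part
#' of this layout; the returned object carries an all-`NA` depth matrix.
#'
#' @param path TSV path.
#' @return A [vaf_matrix] object.
#' @export
read_vaf_matrix <- function(path) {
  df <- read_tsv_checked(path, "snv_id", "VAF matrix")
  if (ncol(df) < 2L) fail("VAF matrix: no sample columns")
  snvs <- check_ids(df$snv_id, "snv_id")
  if (anyDuplicated(snvs)) fail("VAF matrix: duplicated snv_id rows")
  samples <- check_ids(setdiff(names(df), "snv_id"), "sample column names")
  vals <- as.matrix(df[, samples, drop = FALSE])
  mode(vals) <- "numeric"
  rownames(vals) <- snvs
  out_of_range <- which(!is.na(vals) & (vals < 0 | vals > 1), arr.ind = TRUE)
  if (nrow(out_of_range) > 0L) {
    i <- out_of_range[1L, ]
    fail("VAF matrix: value %g outside [0, 1] for SNV %s in sample %s",
         vals[i[1L], i[2L]], snvs[i[1L]], samples[i[2L]])
  }
  m <- new_vaf_matrix(vals, depths = NULL)
  no_data <- rownames(vals)[rowSums(!is.na(vals)) == 0L]
  attr(m, "no_data_snvs") <- no_data
  m
}

#' Write a VAF matrix
#' @param x A [vaf_matrix].
#' @param path Output TSV path.
#' @export
write_vaf_matrix <- function(x, path) {
  df <- data.frame(snv_id = rownames(x$values), check.names = FALSE)
  df <- cbind(df, as.data.frame(x$values, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Write a JSON run report
#' @param report A run report list (see [run_patient()]).
#' @param path Output JSON path.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(NULL)
}
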