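# VAF computation and assay-level quality control.
#
# The VAF denominator is ref + alt reads: only the two tabulated alleles enter
# at ordinary sites. At declared hotspot sites all four nucleotides are
# tabulated so that co-occurring changes at one position (e.g. an A-to-G and an
# A-to-T change at the same codon) are quantified independently.

#' Construct a VAF matrix object
#'
#' @param values Numeric SNV-by-sample matrix of fractions in `[0, 1]`;
#'   `NA` marks missing (unmeasured) cells, which are distinct from 0.
#' @param depths Parallel integer matrix of informative read depths
#'   (ref + alt); `NULL` for an all-`NA` matrix when depths are unknown.
#' @param sites Optional [snv_sites] data frame for the rows.
#' @param samples Optional [sample_meta] data frame for the columns.
#' @param counts Optional `allele_count_table` the matrix was derived from
#'   (retained for hotspot multi-allele reporting).
#' @return An object of class `vaf_matrix`: a list with elements `values`,
#'   `depths`, `sites`, `samples`, `counts`.
#' @export
new_vaf_matrix <- function(values, depths = NULL, sites = NULL,
                           samples = NULL, counts = NULL) {
  stopifnot(is.matrix(values))
  if (is.null(depths)) {
    depths <- matrix(NA_integer_, nrow(values), ncol(values),
                     dimnames = dimnames(values))
  }
  stopifnot(identical(dim(values), dim(depths)))
  if (any(!is.na(values) & (values < 0 | values > 1))) {
    fail("vaf_matrix: values must lie in [0, 1]")
  }
  # a cell with zero informative depth is missing, not zero
  zero_depth <- !is.na(depths) & depths == 0L
  values[zero_depth] <- NA_real_
  structure(list(values = values, depths = depths, sites = sites,
                 samples = samples, counts = counts),
            class = "vaf_matrix")
}

#' @export
print.vaf_matrix <- function(x, ...) {
  cat(sprintf("<vaf_matrix> %d SNVs x %d samples (%d missing cells)\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.vaf_matrix <- function(x) dim(x$values)

#' Compute a VAF from per-nucleotide read counts
#'
#' The VAF is alt / (ref + alt); reads supporting the two remaining
#' nucleotides do not enter the denominator at ordinary sites. When
#' ref + alt = 0 the value is missing (`NA`), not zero. For hotspot sites the
#' fraction of every non-reference nucleotide over the total of all four is
#' additionally returned, so that two co-occurring changes at one position are
#' reported separately.
#'
#' @param counts Named numeric vector with elements `A`, `C`, `G`, `T`.
#' @param site One-row [snv_sites] data frame (or list) with `ref`, `alt` and
#'   `is_hotspot`.
#' @return List with `vaf`, `depth`, and for hotspot sites `per_nucleotide`
#'   (named fractions over the four-nucleotide total for each non-ref base).
#' @export
compute_vaf <- function(counts, site) {
  counts <- counts[NUCLEOTIDES]
  if (any(is.na(counts) | counts < 0)) fail("compute_vaf: counts must be non-negative")
  ref <- counts[[site$ref]]
  alt <- counts[[site$alt]]
  depth <- ref + alt
  vaf <- if (depth == 0) NA_real_ else alt / depth
  out <- list(vaf = vaf, depth = as.integer(depth))
  if (isTRUE(site$is_hotspot)) {
    total <- sum(counts)
    others <- setdiff(NUCLEOTIDES, site$ref)
    out$per_nucleotide <- if (total == 0) {
      stats::setNames(rep(NA_real_, 3L), others)
    } else {
      stats::setNames(as.numeric(counts[others]) / total, others)
    }
  }
  out
}

#' Flag PCR failures
#'
#' An assay (one targeted SNV in one patient) whose read total, summed over
#' all of the patient's samples and all four nucleotides, falls strictly below
#' `min_total_reads` is a PCR failure and is excluded from all downstream
#' stages. The default threshold is 1,000 reads.
#'
#' @param table An `allele_count_table`.
#' @param min_total_reads Non-negative integer threshold (strict less-than).
#' @return Data frame of class `assay_qc` with columns `patient_id`, `snv_id`,
#'   `total_reads`, `status` (`ok` or `pcr_failure`).
#' @export
flag_pcr_failures <- function(table, min_total_reads = 1000L) {
  stopifnot(min_total_reads >= 0)
  if (nrow(table) == 0L) {
    out <- data.frame(patient_id = character(0), snv_id = character(0),
                      total_reads = integer(0), status = character(0))
    class(out) <- c("assay_qc", "data.frame")
    return(out)
  }
  per_row <- table$A + table$C + table$G + table$T
  tot <- stats::aggregate(per_row,
                          by = list(patient_id = table$patient_id,
                                    snv_id = table$snv_id),
                          FUN = sum)
  names(tot)[3L] <- "total_reads"
  tot$status <- ifelse(tot$total_reads < min_total_reads, "pcr_failure", "ok")
  tot <- tot[order(tot$patient_id, tot$snv_id), , drop = FALSE]
  rownames(tot) <- NULL
  class(tot) <- c("assay_qc", "data.frame")
  tot
}

#' Build a VAF matrix from an allele count table
#'
#' @param table `allele_count_table` for a single patient.
#' @param sites [snv_sites] covering every SNV in the table.
#' @param samples Optional [sample_meta]; defines the column order and lets
#'   samples with no rows appear as all-missing columns.
#' @param qc Optional `assay_qc` from [flag_pcr_failures()]; assays flagged
#'   `pcr_failure` are dropped from the matrix.
#' @return A [vaf_matrix].
#' @export
vaf_from_counts <- function(table, sites, samples = NULL, qc = NULL) {
  pts <- unique(table$patient_id)
  if (length(pts) > 1L) {
    fail("vaf_from_counts: table spans %d patients; supply one at a time",
         length(pts))
  }
  if (!is.null(qc)) {
    failed <- qc$snv_id[qc$status == "pcr_failure"]
    table <- table[!(table$snv_id %in% failed), , drop = FALSE]
  }
  missing_sites <- setdiff(unique(table$snv_id), sites$snv_id)
  if (length(missing_sites) > 0L) {
    fail("vaf_from_counts: no site definition for SNV(s): %s",
         paste(missing_sites, collapse = ", "))
  }
  snvs <- sites$snv_id[sites$snv_id %in% table$snv_id]
  smp <- if (is.null(samples)) sort(unique(table$sample_id)) else samples$sample_id
  vals <- matrix(NA_real_, length(snvs), length(smp),
                 dimnames = list(snvs, smp))
  deps <- matrix(NA_integer_, length(snvs), length(smp),
                 dimnames = list(snvs, smp))
  ri <- match(table$snv_id, snvs)
  ci <- match(table$sample_id, smp)
  if (anyNA(ci)) fail("vaf_from_counts: count table has samples absent from metadata")
  cnt <- as.matrix(table[, NUCLEOTIDES])
  site_ref <- sites$ref[match(snvs, sites$snv_id)]
  site_alt <- sites$alt[match(snvs, sites$snv_id)]
  ref_reads <- cnt[cbind(seq_len(nrow(cnt)), match(site_ref[ri], NUCLEOTIDES))]
  alt_reads <- cnt[cbind(seq_len(nrow(cnt)), match(site_alt[ri], NUCLEOTIDES))]
  depth <- ref_reads + alt_reads
  idx <- cbind(ri, ci)
  deps[idx] <- as.integer(depth)
  vals[idx] <- ifelse(depth == 0, NA_real_, alt_reads / depth)
  new_vaf_matrix(vals, deps,
                 sites = sites[match(snvs, sites$snv_id), , drop = FALSE],
                 samples = samples, counts = table)
}

#' Estimate the background false-positive rate
#'
#' Summarizes the observed VAF over all cells called absent: with many SNVs
#' absent from subsets of samples, this distribution estimates the effective
#' per-site sequencing error. A mean at or above 1 in 1,000 — the regime the
#' presence cutoff assumes to be cleanly separated — raises a QC warning flag.
#'
#' @param matrix A [vaf_matrix].
#' @param presence A presence matrix from [call_presence()].
#' @param warn_level Background mean that triggers the QC flag (default 1e-3).
#' @return List with `n_cells`, `mean`, `q95`, `q99`, `max`, `qc_warning`;
#'   all summaries `NA` (and `defined = FALSE`) when no absent cells exist.
#' @export
estimate_background_error <- function(matrix, presence, warn_level = 1e-3) {
  stopifnot(inherits(presence, "presence_matrix"))
  absent <- !is.na(presence$calls) & presence$calls == "absent"
  v <- matrix$values[absent]
  v <- v[!is.na(v)]
  if (length(v) == 0L) {
    return(list(defined = FALSE, n_cells = 0L, mean = NA_real_,
                q95 = NA_real_, q99 = NA_real_, max = NA_real_,
                qc_warning = FALSE))
  }
  m <- mean(v)
  list(defined = TRUE, n_cells = length(v), mean = m,
       q95 = unname(stats::quantile(v, 0.95)),
       q99 = unname(stats::quantile(v, 0.99)),
       max = max(v), qc_warning = m >= warn_level)
}
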