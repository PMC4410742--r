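# Presence/absence calling, assay categorization, and grouping of somatic
# SNVs into phylogenetic classes.
#
# The presence-absence vector of an SNV across a patient's samples is its
# "phylogenetic pattern"; SNVs with identical patterns arose on the same
# ancestral branch and form one phylogenetic class.

#' Call presence/absence at a VAF cutoff
#'
#' A cell is called present when its VAF is greater than or equal to the
#' cutoff (0.02 by default, inclusive at the boundary), then curated overrides
#' are applied. Missing cells (no informative reads) stay missing. Every
#' override must contradict the threshold call — a record that agrees with it
#' is redundant and rejected — and every applied override is recorded in the
#' provenance matrix.
#'
#' @param matrix A [vaf_matrix].
#' @param cutoff Presence cutoff in (0, 1); default 0.02.
#' @param overrides Optional `override_list` from [read_overrides()].
#' @return Object of class `presence_matrix`: list with `calls` (character
#'   matrix `present`/`absent`/`NA`), `provenance` (`threshold`/`override`),
#'   and `cutoff`.
#' @export
call_presence <- function(matrix, cutoff = 0.02, overrides = NULL) {
  stopifnot(cutoff > 0, cutoff < 1)
  v <- matrix$values
  calls <- ifelse(is.na(v), NA_character_,
                  ifelse(v >= cutoff, "present", "absent"))
  prov <- ifelse(is.na(v), NA_character_, "threshold")
  if (!is.null(overrides) && nrow(overrides) > 0L) {
    for (i in seq_len(nrow(overrides))) {
      snv <- overrides$snv_id[i]
      smp <- overrides$sample_id[i]
      if (!(snv %in% rownames(calls)) || !(smp %in% colnames(calls))) {
        fail("override references unknown SNV/sample: (%s, %s)", snv, smp)
      }
      if (is.na(calls[snv, smp])) {
        fail("override targets a missing cell: (%s, %s)", snv, smp)
      }
      if (calls[snv, smp] == overrides$forced_call[i]) {
        fail("redundant override: (%s, %s) already called %s by threshold",
             snv, smp, overrides$forced_call[i])
      }
      calls[snv, smp] <- overrides$forced_call[i]
      prov[snv, smp] <- "override"
    }
  }
  structure(list(calls = calls, provenance = prov, cutoff = cutoff),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("<presence_matrix> %d SNVs x %d samples; cutoff %g; %d override cell(s)\n",
              nrow(x$calls), ncol(x$calls), x$cutoff,
              sum(x$provenance == "override", na.rm = TRUE)))
  invisible(x)
}

#' Categorize assays from their presence patterns
#'
#' Categories are exclusive and exhaustive over tested assays: `pcr_failure`
#' (from QC, not in the presence matrix), `germline` (alternative allele
#' present in every sample with a call), `false_positive` (present in none),
#' `somatic` (everything else). Only somatic assays continue downstream.
#'
#' @param presence A `presence_matrix`.
#' @param qc Optional `assay_qc`; rows with status `pcr_failure` are appended
#'   with category `pcr_failure`.
#' @return Data frame with columns `snv_id`, `category`.
#' @export
categorize_assays <- function(presence, qc = NULL) {
  calls <- presence$calls
  n_pres <- rowSums(calls == "present", na.rm = TRUE)
  n_call <- rowSums(!is.na(calls))
  category <- ifelse(n_call == 0L, "false_positive",
                     ifelse(n_pres == n_call, "germline",
                            ifelse(n_pres == 0L, "false_positive", "somatic")))
  out <- data.frame(snv_id = rownames(calls), category = category,
                    row.names = NULL)
  if (!is.null(qc)) {
    failed <- qc$snv_id[qc$status == "pcr_failure"]
    failed <- setdiff(failed, out$snv_id)
    if (length(failed) > 0L) {
      out <- rbind(out, data.frame(snv_id = failed, category = "pcr_failure"))
    }
  }
  rownames(out) <- NULL
  out
}

#' Group somatic SNVs into phylogenetic classes
#'
#' SNVs are partitioned by exact pattern identity (the set of samples called
#' present). Near-identical patterns are never merged: disagreements must be
#' resolved by overrides or remain separate classes. Each class carries the
#' per-sample mean and population standard deviation of its members' VAFs.
#'
#' @param presence A `presence_matrix`.
#' @param somatic_ids Character vector of somatic SNV ids to group (typically
#'   from [categorize_assays()], excluding hotspot/recurrent candidates).
#' @param matrix The [vaf_matrix] (for the VAF summaries).
#' @return Object of class `phylo_classes`: list of class records, each with
#'   `class_id`, `pattern` (sample ids), `members` (SNV ids), `status`
#'   (initially `unassessed`), `vaf_mean`, `vaf_sd` (named per-sample
#'   vectors). The sample universe is attached as an attribute.
#' @export
group_classes <- function(presence, somatic_ids, matrix) {
  if (length(somatic_ids) == 0L) fail("group_classes: no somatic SNVs")
  calls <- presence$calls[somatic_ids, , drop = FALSE]
  samples <- colnames(calls)
  keys <- apply(calls, 1L, function(r) pat_key(samples[!is.na(r) & r == "present"]))
  split_members <- split(somatic_ids, keys)
  # deterministic order: larger patterns first, ties by key
  ord <- order(-lengths(lapply(names(split_members), pat_from_key)),
               names(split_members))
  split_members <- split_members[ord]
  classes <- vector("list", length(split_members))
  for (i in seq_along(split_members)) {
    members <- sort(split_members[[i]])
    vv <- matrix$values[members, , drop = FALSE]
    classes[[i]] <- list(
      class_id = sprintf("c%03d", i),
      pattern = pat_from_key(names(split_members)[i]),
      members = members,
      status = "unassessed",
      vaf_mean = apply(vv, 2L, function(x) mean(x, na.rm = TRUE)),
      vaf_sd = apply(vv, 2L, pop_sd)
    )
  }
  structure(classes, class = "phylo_classes", samples = samples)
}

#' @export
print.phylo_classes <- function(x, ...) {
  st <- table(vapply(x, `[[`, "", "status"))
  cat(sprintf("<phylo_classes> %d classes over %d SNVs [%s]\n",
              length(x), sum(lengths(lapply(x, `[[`, "members"))),
              paste(names(st), st, sep = ": ", collapse = ", ")))
  invisible(x)
}

class_status <- function(classes) vapply(classes, `[[`, "", "status")

#' Assess robustness of phylogenetic classes
#'
#' A class is robust when it is supported by more than one SNV whose VAFs are
#' consistent with each other across samples — operationalized as a maximum
#' pairwise absolute VAF difference among members of at most
#' `consistency_tolerance` in every sample where the class is present. A
#' single-SNV class is allowed to be robust only if all its positive VAFs are
#' clearly positive (at least `clearly_positive_threshold`, 2.5 times the
#' default presence cutoff and far above background) and its inclusion would
#' not induce an additional mixed-lineage sample relative to the multi-SNV
#' robust core. Classes at hotspot sites are routed to the recurrence stage as
#' `recurrent_candidate` and never enter treebuilding. All remaining classes
#' are `ambiguous` and excluded from treebuilding.
#'
#' @param classes A `phylo_classes` object.
#' @param matrix The [vaf_matrix].
#' @param consistency_tolerance Maximum within-class per-sample VAF spread for
#'   a multi-SNV class to be robust (default 0.15).
#' @param clearly_positive_threshold Minimum positive VAF for the single-SNV
#'   exception (default 0.05).
#' @param hotspot_ids SNV ids at hotspot sites.
#' @param max_splits Split-search cap forwarded to the mixed-lineage check.
#' @return The `phylo_classes` object with `status` set to `robust`,
#'   `ambiguous` or `recurrent_candidate` for every class, and a
#'   `rationale` string recording why.
#' @export
assess_robustness <- function(classes, matrix, consistency_tolerance = 0.15,
                              clearly_positive_threshold = 0.05,
                              hotspot_ids = character(0), max_splits = 6L) {
  samples <- attr(classes, "samples")
  for (i in seq_along(classes)) {
    cl <- classes[[i]]
    if (any(cl$members %in% hotspot_ids)) {
      classes[[i]]$status <- "recurrent_candidate"
      classes[[i]]$rationale <- "assay at a declared hotspot site"
      next
    }
    if (length(cl$members) >= 2L) {
      spread <- 0
      if (length(cl$pattern) > 0L) {
        vv <- matrix$values[cl$members, cl$pattern, drop = FALSE]
        rng <- apply(vv, 2L, function(x) {
          x <- x[!is.na(x)]
          if (length(x) < 2L) 0 else diff(range(x))
        })
        spread <- max(rng)
      }
      if (spread <= consistency_tolerance) {
        classes[[i]]$status <- "robust"
        classes[[i]]$rationale <- sprintf(
          ">=2 members; max per-sample VAF spread %.3f <= %.3f",
          spread, consistency_tolerance)
      } else {
        classes[[i]]$status <- "ambiguous"
        classes[[i]]$rationale <- sprintf(
          "per-sample VAF spread %.3f exceeds tolerance %.3f",
          spread, consistency_tolerance)
      }
    }
  }
  # Single-SNV exception, evaluated against the growing robust core in
  # deterministic class order.
  core_ids <- which(class_status(classes) == "robust")
  baseline <- count_required_splits(classes[core_ids], samples, max_splits)
  for (i in seq_along(classes)) {
    cl <- classes[[i]]
    if (cl$status != "unassessed") next
    if (length(cl$pattern) == 0L) {
      classes[[i]]$status <- "ambiguous"
      classes[[i]]$rationale <- "single SNV with empty pattern"
      next
    }
    vv <- matrix$values[cl$members, cl$pattern]
    if (all(!is.na(vv) & vv >= clearly_positive_threshold)) {
      with_cl <- count_required_splits(c(classes[core_ids], list(cl)),
                                       samples, max_splits)
      if (!is.na(with_cl) && with_cl <= baseline) {
        classes[[i]]$status <- "robust"
        classes[[i]]$rationale <- sprintf(
          "single SNV, all positive VAFs >= %.3f, induces no additional mixed-lineage sample",
          clearly_positive_threshold)
        core_ids <- c(core_ids, i)
        baseline <- with_cl
      } else {
        classes[[i]]$status <- "ambiguous"
        classes[[i]]$rationale <- "single SNV whose inclusion would induce an additional mixed-lineage sample"
      }
    } else {
      classes[[i]]$status <- "ambiguous"
      classes[[i]]$rationale <- sprintf(
        "single SNV with positive VAF below %.3f", clearly_positive_threshold)
    }
  }
  classes
}

# Number of sample splits a class set requires; NA when unresolvable within
# the cap.
count_required_splits <- function(classes, samples, max_splits) {
  res <- tryCatch(
    resolve_mixed_lineages(classes, samples = samples, max_splits = max_splits,
                           statuses = NULL),
    error = function(e) NULL)
  if (is.null(res)) NA_integer_ else res$n_splits
}

#' Summarize classes as a data frame
#'
#' @param classes A `phylo_classes` object.
#' @return Data frame with one row per class: id, status, number of member
#'   SNVs, pattern size and the pattern itself (comma-separated).
#' @export
classes_summary <- function(classes) {
  data.frame(
    class_id = vapply(classes, `[[`, "", "class_id"),
    status = class_status(classes),
    n_snvs = lengths(lapply(classes, `[[`, "members")),
    pattern_size = lengths(lapply(classes, `[[`, "pattern")),
    pattern = vapply(classes, function(cl) paste(cl$pattern, collapse = ","), ""),
    row.names = NULL)
}
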