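# End-to-end orchestration: VAF QC -> presence calling -> phylogenetic
# classes -> treebuilding with mixed-lineage resolution -> VAF-sum check ->
# recurrence inference, with an accounting report whose identities are
# asserted on every run.

#' SNV accounting identities
#'
#' Applies the bookkeeping identities of the assay accounting: somatic =
#' tested - PCR failures - false positives - germline; the validation rate is
#' somatic / tested; treebuilding SNVs = somatic - ambiguous - recurrent
#' candidates.
#'
#' @param tested Number of assays tested.
#' @param pcr_failure,false_positive,germline,ambiguous Counts per category.
#' @param recurrent_candidate Assays routed to recurrence instead of
#'   treebuilding (0 when recurrent assays are counted inside the
#'   treebuilding total, as in a published accounting that retains them).
#' @return List with `somatic`, `validation_rate_pct` (percent, one decimal
#'   of print precision retained as a plain number), `treebuilding`.
#' @export
snv_accounting <- function(tested, pcr_failure, false_positive, germline,
                           ambiguous, recurrent_candidate = 0L) {
  somatic <- tested - pcr_failure - false_positive - germline
  list(somatic = somatic,
       validation_rate_pct = 100 * somatic / tested,
       treebuilding = somatic - ambiguous - recurrent_candidate)
}

#' Per-class VAF summary table
#'
#' The machine-readable class-by-sample summary: mean VAF, population
#' standard deviation (reported as 0 for single-member classes, by
#' convention) and the presence call of each class in each sample, for
#' positive and absent cells alike (absent cells sit near the background).
#'
#' @param classes A `phylo_classes` object.
#' @param matrix The [vaf_matrix].
#' @return Data frame with columns `class_id`, `sample_id`, `n_members`,
#'   `mean_vaf`, `sd_vaf`, `call`.
#' @export
class_vaf_summary <- function(classes, matrix) {
  samples <- attr(classes, "samples")
  rows <- lapply(classes, function(cl) {
    vv <- matrix$values[cl$members, samples, drop = FALSE]
    data.frame(class_id = cl$class_id,
               sample_id = samples,
               n_members = length(cl$members),
               mean_vaf = apply(vv, 2L, function(x) mean(x, na.rm = TRUE)),
               sd_vaf = if (length(cl$members) == 1L) 0 else
                 apply(vv, 2L, pop_sd),
               call = ifelse(samples %in% cl$pattern, "present", "absent"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full per-patient pipeline
#'
#' Executes the stage sequence on one patient's data: PCR-failure QC, VAF
#' computation, presence calling with overrides, assay categorization,
#' phylogenetic-class grouping and robustness assessment, mixed-lineage
#' resolution, treebuilding, VAF-sum validation of splits, background-error
#' estimation, and recurrence inference at hotspot sites. The pipeline is a
#' pure function of its inputs and thresholds: identical reruns give
#' identical results.
#'
#' @param counts An `allele_count_table` for one patient (or `NULL` when a
#'   precomputed `vafm` is supplied).
#' @param sites [snv_sites] covering the assays (required with `counts`;
#'   optional with `vafm`).
#' @param samples [sample_meta] for the patient's samples.
#' @param vafm Optional precomputed [vaf_matrix] (bypasses count-level QC).
#' @param overrides Optional `override_list`.
#' @param vaf_cutoff Presence cutoff (default 0.02).
#' @param min_total_reads PCR-failure threshold (default 1000).
#' @param consistency_tolerance,clearly_positive_threshold Robustness
#'   parameters (defaults 0.15 and 0.05); see [assess_robustness()].
#' @param vaf_sum_tolerance Mixed-lineage VAF-sum tolerance (default 0.10).
#' @param max_splits Split-search cap (default 6).
#' @param out_dir Optional directory; when given, the annotated tree, the
#'   branch table, the class summary and the JSON report are written there.
#' @return List of class `patient_result` with elements `tree`, `report`,
#'   `classes`, `resolution`, `vaf`, `presence`, `categories`, `vaf_sums`,
#'   `recurrences`, `background`, `qc`.
#' @export
run_patient <- function(counts = NULL, sites = NULL, samples = NULL,
                        vafm = NULL, overrides = NULL, vaf_cutoff = 0.02,
                        min_total_reads = 1000L,
                        consistency_tolerance = 0.15,
                        clearly_positive_threshold = 0.05,
                        vaf_sum_tolerance = 0.10, max_splits = 6L,
                        out_dir = NULL) {
  stage <- "input validation"
  result <- tryCatch({
    qc <- NULL
    if (is.null(vafm)) {
      if (is.null(counts) || is.null(sites)) {
        fail("run_patient: supply either counts + sites or a vaf matrix")
      }
      stage <- "vaf_qc"
      qc <- flag_pcr_failures(counts, min_total_reads)
      vafm <- vaf_from_counts(counts, sites, samples = samples, qc = qc)
    } else if (is.null(vafm$samples) && !is.null(samples)) {
      vafm$samples <- samples
    }
    sites <- sites %||% vafm$sites
    hotspot_ids <- if (is.null(sites)) character(0) else
      sites$snv_id[sites$is_hotspot]

    stage <- "presence calling"
    presence <- call_presence(vafm, cutoff = vaf_cutoff, overrides = overrides)
    categories <- categorize_assays(presence, qc = qc)

    stage <- "class grouping"
    somatic_ids <- setdiff(categories$snv_id[categories$category == "somatic"],
                           hotspot_ids)
    sample_ids <- colnames(vafm$values)
    if (length(somatic_ids) > 0L) {
      classes <- group_classes(presence, somatic_ids, vafm)
      classes <- assess_robustness(
        classes, vafm, consistency_tolerance = consistency_tolerance,
        clearly_positive_threshold = clearly_positive_threshold,
        hotspot_ids = hotspot_ids, max_splits = max_splits)
    } else {
      classes <- structure(list(), class = "phylo_classes",
                           samples = sample_ids)
    }

    stage <- "mixed-lineage resolution"
    resolution <- resolve_mixed_lineages(classes, samples = sample_ids,
                                         max_splits = max_splits)
    stage <- "treebuilding"
    tree <- build_tree(resolution, samples = samples)
    stage <- "vaf-sum check"
    vaf_sums <- vaf_sum_check(tree, vafm, tolerance = vaf_sum_tolerance)
    tree <- apply_mixing_proportions(tree, vaf_sums)

    stage <- "background estimation"
    background <- estimate_background_error(vafm, presence)

    stage <- "recurrence inference"
    recurrences <- list()
    for (hs in intersect(hotspot_ids, rownames(presence$calls))) {
      pos_samples <- sample_ids[!is.na(presence$calls[hs, ]) &
                                  presence$calls[hs, ] == "present"]
      attribution <- attribute_hotspot_components(
        tree, pos_samples, vafm$values[hs, ], vaf_sums,
        tolerance = vaf_sum_tolerance)
      rec <- min_origins(tree, attribution$components,
                         site = if (!is.null(sites))
                           sites[sites$snv_id == hs, , drop = FALSE])
      rec$lower_bound_flag <- rec$lower_bound_flag || attribution$ambiguous
      rec$forced_single_origin_conflicts <-
        test_single_origin_rearrangement(classes, pos_samples)
      recurrences[[hs]] <- rec
    }

    stage <- "report"
    st <- class_status(classes)
    n_per_class <- lengths(lapply(classes, `[[`, "members"))
    n_ambiguous <- sum(n_per_class[st == "ambiguous"])
    n_recur <- sum(categories$category == "somatic" &
                     categories$snv_id %in% hotspot_ids)
    counts_tab <- c(
      tested = nrow(categories),
      pcr_failure = sum(categories$category == "pcr_failure"),
      false_positive = sum(categories$category == "false_positive"),
      germline = sum(categories$category == "germline"),
      somatic = sum(categories$category == "somatic"),
      ambiguous = n_ambiguous,
      recurrent_candidate = n_recur)
    acc <- snv_accounting(counts_tab[["tested"]], counts_tab[["pcr_failure"]],
                          counts_tab[["false_positive"]],
                          counts_tab[["germline"]], counts_tab[["ambiguous"]],
                          counts_tab[["recurrent_candidate"]])
    report <- list(
      counts = as.list(counts_tab),
      somatic_validation_rate_pct = acc$validation_rate_pct,
      treebuilding_snvs = acc$treebuilding,
      data_points_treebuilding = acc$treebuilding * length(sample_ids),
      data_points_nonfailed = (counts_tab[["tested"]] -
                                 counts_tab[["pcr_failure"]]) *
        length(sample_ids),
      n_samples = length(sample_ids),
      mixed_samples = lapply(seq_len(nrow(vaf_sums)), function(i) list(
        sample_id = vaf_sums$sample_id[i],
        vaf_sum_pass = vaf_sums$pass[i],
        vaf_sum_skipped = vaf_sums$skipped[i],
        proportions = c(vaf_sums$prop_1[i], vaf_sums$prop_2[i]))),
      recurrences = lapply(recurrences, function(r) list(
        snv_id = if (!is.null(r$site)) r$site$snv_id else NA_character_,
        min_origins = r$min_origins,
        lower_bound = r$lower_bound_flag,
        forced_single_origin_conflicts = r$forced_single_origin_conflicts)),
      background = background,
      thresholds = list(vaf_cutoff = vaf_cutoff,
                        min_total_reads = min_total_reads,
                        consistency_tolerance = consistency_tolerance,
                        clearly_positive_threshold = clearly_positive_threshold,
                        vaf_sum_tolerance = vaf_sum_tolerance,
                        max_splits = max_splits),
      overrides_used = if (is.null(overrides)) 0L else nrow(overrides))
    # accounting identities hold on every run
    stopifnot(
      counts_tab[["tested"]] == counts_tab[["pcr_failure"]] +
        counts_tab[["false_positive"]] + counts_tab[["germline"]] +
        counts_tab[["somatic"]],
      acc$somatic == counts_tab[["somatic"]],
      report$treebuilding_snvs == counts_tab[["somatic"]] -
        counts_tab[["ambiguous"]] - counts_tab[["recurrent_candidate"]])

    structure(list(tree = tree, report = report, classes = classes,
                   resolution = resolution, vaf = vafm, presence = presence,
                   categories = categories, vaf_sums = vaf_sums,
                   recurrences = recurrences, background = background,
                   qc = qc),
              class = "patient_result")
  }, error = function(e) {
    fail("pipeline aborted in stage [%s]: %s", stage, conditionMessage(e))
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tree(result$tree, file.path(out_dir, "tree.nwk"))
    utils::write.table(branch_table(result$tree),
                       file.path(out_dir, "branches.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(class_vaf_summary(result$classes, result$vaf),
                       file.path(out_dir, "class_vaf_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_run_report(result$report, file.path(out_dir, "report.json"))
  }
  result
}

#' @export
print.patient_result <- function(x, ...) {
  ct <- x$report$counts
  cat(sprintf("<patient_result> tested %d | pcr_failure %d | false_positive %d | germline %d | somatic %d\n",
              ct$tested, ct$pcr_failure, ct$false_positive, ct$germline,
              ct$somatic))
  cat(sprintf("  treebuilding SNVs %d; %d split sample(s); %d recurrence site(s)\n",
              x$report$treebuilding_snvs, length(x$resolution$splits),
              length(x$recurrences)))
  invisible(x)
}
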