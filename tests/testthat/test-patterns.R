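presence_fixture <- function() {
  vals <- matrix(c(0.020, 0.300, 0.000,
                   0.019, 0.350, 0.400,
                   0.030, 0.001, 0.000),
                 nrow = 3, byrow = TRUE,
                 dimnames = list(c("a", "b", "c"), c("S1", "S2", "S3")))
  make_vafm(vals)
}

test_that("presence calling is cutoff-inclusive and applies overrides", {
  m <- presence_fixture()
  p <- call_presence(m, 0.02)
  expect_equal(p$calls["a", "S1"], "present")   # exactly 0.02
  expect_equal(p$calls["b", "S1"], "absent")    # 0.019

  ov <- data.frame(snv_id = c("b", "c"), sample_id = c("S1", "S1"),
                   forced_call = c("present", "absent"), note = "curated")
  p2 <- call_presence(m, 0.02, overrides = ov)
  expect_equal(p2$calls["b", "S1"], "present")
  expect_equal(p2$provenance["b", "S1"], "override")
  expect_equal(p2$calls["c", "S1"], "absent")

  redundant <- data.frame(snv_id = "a", sample_id = "S1",
                          forced_call = "present", note = "noop")
  expect_error(call_presence(m, 0.02, overrides = redundant), "redundant")
  unknown <- data.frame(snv_id = "zz", sample_id = "S1",
                        forced_call = "present", note = "x")
  expect_error(call_presence(m, 0.02, overrides = unknown), "unknown")
})

test_that("assay categories are exclusive and exhaustive", {
  vals <- matrix(c(0.5, 0.4, 0.5,    # germline: present everywhere
                   0.001, 0.0, 0.001, # false positive: present nowhere
                   0.4, 0.0, 0.3),   # somatic
                 nrow = 3, byrow = TRUE,
                 dimnames = list(c("g", "f", "s"), c("S1", "S2", "S3")))
  m <- make_vafm(vals)
  qc <- data.frame(patient_id = "P1", snv_id = "pf", total_reads = 200L,
                   status = "pcr_failure")
  cats <- categorize_assays(call_presence(m, 0.02), qc = qc)
  got <- stats::setNames(cats$category, cats$snv_id)
  expect_equal(got[["g"]], "germline")
  expect_equal(got[["f"]], "false_positive")
  expect_equal(got[["s"]], "somatic")
  expect_equal(got[["pf"]], "pcr_failure")
  expect_equal(sort(names(got)), c("f", "g", "pf", "s"))
})

test_that("classes partition somatic SNVs by exact pattern", {
  vals <- rbind(
    matrix(rep(c(0.4, 0.45, 0), 3), 3, byrow = TRUE),
    matrix(rep(c(0, 0, 0.3), 2), 2, byrow = TRUE))
  dimnames(vals) <- list(sprintf("v%d", 1:5), c("S1", "S2", "S3"))
  m <- make_vafm(vals)
  pres <- call_presence(m, 0.02)
  cls <- group_classes(pres, rownames(vals), m)
  expect_length(cls, 2L)
  expect_equal(sort(lengths(lapply(cls, `[[`, "members"))), c(2L, 3L))
  expect_equal(sum(lengths(lapply(cls, `[[`, "members"))), 5L)

  one <- group_classes(pres, "v1", m)
  expect_length(one, 1L)
})

test_that("class grouping is deterministic and partitions on simulated data", {
  sim <- simulate_patient(sim_config(seed = 11))
  res1 <- run_patient(sim$counts, sim$sites, sim$samples)
  res2 <- run_patient(sim$counts, sim$sites, sim$samples)
  expect_identical(classes_summary(res1$classes), classes_summary(res2$classes))
  n_members <- sum(lengths(lapply(res1$classes, `[[`, "members")))
  expect_equal(n_members, res1$report$counts$somatic -
                 res1$report$counts$recurrent_candidate)
})

test_that("robustness: consistent multi-SNV classes pass, inconsistent fail", {
  samples <- c("S1", "S2", "S3")
  vals <- rbind(c(0.41, 0.40, 0.00), c(0.43, 0.41, 0.00), c(0.40, 0.42, 0.00),
                c(0.10, 0.40, 0.40), c(0.35, 0.39, 0.40))  # spread 0.25 at S1
  dimnames(vals) <- list(sprintf("v%d", 1:5), samples)
  m <- make_vafm(vals)
  pres <- call_presence(m, 0.02)
  cls <- group_classes(pres, rownames(vals), m)
  cls <- assess_robustness(cls, m)
  st <- stats::setNames(class_status(cls),
                        vapply(cls, function(cl) cl$members[1], ""))
  expect_equal(unname(st[["v1"]]), "robust")
  expect_equal(unname(st[["v4"]]), "ambiguous")
})

test_that("single-SNV exception requires clear VAFs and no induced split", {
  samples <- c("S1", "S2", "S3", "S4")
  # robust core: {S1,S2} and {S3,S4}; candidate singletons:
  #   nested {S1}   (laminar -> robust)
  #   bridging {S2,S3} (would force a split -> ambiguous)
  #   weak {S4} with VAF below 0.05 (-> ambiguous)
  vals <- rbind(c(0.40, 0.41, 0.00, 0.00), c(0.42, 0.40, 0.00, 0.00),
                c(0.00, 0.00, 0.38, 0.40), c(0.00, 0.00, 0.40, 0.41),
                c(0.21, 0.00, 0.00, 0.00),
                c(0.00, 0.30, 0.28, 0.00),
                c(0.00, 0.00, 0.00, 0.03))
  dimnames(vals) <- list(sprintf("v%d", 1:7), samples)
  m <- make_vafm(vals)
  pres <- call_presence(m, 0.02)
  cls <- group_classes(pres, rownames(vals), m)
  cls <- assess_robustness(cls, m)
  st <- stats::setNames(class_status(cls),
                        vapply(cls, function(cl) cl$members[1], ""))
  expect_equal(unname(st[["v5"]]), "robust")
  expect_equal(unname(st[["v6"]]), "ambiguous")
  expect_equal(unname(st[["v7"]]), "ambiguous")
})

test_that("hotspot assays are routed to recurrence, never treebuilding", {
  sim <- simulate_patient(sim_config(seed = 5, hotspot_origins = 2))
  res <- run_patient(sim$counts, sim$sites, sim$samples)
  hs <- sim$truth$hotspot$snv_id
  in_class <- vapply(res$classes, function(cl) hs %in% cl$members, TRUE)
  if (any(in_class)) {
    expect_equal(class_status(res$classes)[in_class], "recurrent_candidate")
  }
  expect_true(hs %in% names(res$recurrences))
})

test_that("zero-noise robust classes match true branch patterns exactly", {
  sim <- simulate_patient(sim_config(seed = 21, error_rate = 0,
                                     contamination_mean = 0,
                                     read_sampling = "expected"))
  res <- run_patient(sim$counts, sim$sites, sim$samples)
  sc <- score_recovery(res, sim$truth)
  expect_true(sc$topology_ok)
})
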