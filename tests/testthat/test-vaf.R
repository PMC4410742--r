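test_that("compute_vaf uses the ref+alt denominator and flags missing cells", {
  site <- list(ref = "A", alt = "G", is_hotspot = FALSE)
  v <- compute_vaf(c(A = 98, C = 0, G = 2, T = 0), site)
  expect_equal(v$vaf, 0.02)
  expect_equal(v$depth, 100L)

  # other-nucleotide reads never rescue a zero ref+alt denominator
  v0 <- compute_vaf(c(A = 0, C = 50, G = 0, T = 0), site)
  expect_true(is.na(v0$vaf))
  expect_equal(v0$depth, 0L)

  expect_error(compute_vaf(c(A = -1, C = 0, G = 0, T = 0), site),
               "non-negative")
})

test_that("hotspot sites report each alternative nucleotide independently", {
  # two co-occurring changes at one position, quantified over all four
  # nucleotides by direct division
  site <- list(ref = "A", alt = "G", is_hotspot = TRUE)
  v <- compute_vaf(c(A = 90000, C = 0, G = 8000, T = 2000), site)
  expect_equal(unname(v$per_nucleotide["G"]), 8000 / 100000)
  expect_equal(unname(v$per_nucleotide["T"]), 2000 / 100000)
  expect_equal(unname(v$per_nucleotide["C"]), 0)
})

test_that("PCR failure threshold is a strict less-than on the assay total", {
  tab <- as_count_table(
    count_row("P1", "low", "S1", A = 500L), count_row("P1", "low", "S2", A = 499L),
    count_row("P1", "edge", "S1", A = 500L), count_row("P1", "edge", "S2", A = 500L),
    count_row("P1", "deep", "S1", A = 9000L, G = 1000L))
  qc <- flag_pcr_failures(tab, min_total_reads = 1000L)
  expect_equal(qc$status[qc$snv_id == "low"], "pcr_failure")   # 999 reads
  expect_equal(qc$status[qc$snv_id == "edge"], "ok")           # exactly 1,000
  expect_equal(qc$status[qc$snv_id == "deep"], "ok")

  # excluding a failed assay leaves every other assay's VAF untouched
  sites <- make_sites(c("low", "edge", "deep"))
  with_qc <- vaf_from_counts(tab, sites, qc = qc)
  no_qc <- vaf_from_counts(tab, sites)
  common <- intersect(rownames(with_qc$values), rownames(no_qc$values))
  expect_equal(with_qc$values[common, , drop = FALSE],
               no_qc$values[common, , drop = FALSE])
  expect_false("low" %in% rownames(with_qc$values))
})

test_that("depth-zero cells are missing, never zero", {
  vals <- matrix(c(0, 0.4), 1, 2, dimnames = list("a", c("S1", "S2")))
  deps <- matrix(c(0L, 1000L), 1, 2, dimnames = dimnames(vals))
  m <- new_vaf_matrix(vals, deps)
  expect_true(is.na(m$values["a", "S1"]))
  expect_equal(m$values["a", "S2"], 0.4)
})

test_that("background error estimate recovers the simulated error rate", {
  # mean VAF over truth-absent cells estimates the per-read error rate
  ms <- replicate(6, {
    sim <- simulate_patient(sim_config(seed = sample.int(1e6, 1),
                                       n_samples = 8, n_informative_snvs = 60))
    res <- run_patient(sim$counts, sim$sites, sim$samples)
    res$background$mean
  })
  expect_gt(mean(ms), 5e-4 / 2)
  expect_lt(mean(ms), 5e-4 * 2)
})

test_that("background summary handles degenerate inputs and warns when high", {
  vals <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("S1", "S2")))
  m <- make_vafm(vals)
  pres <- call_presence(m, 0.02)
  bg <- estimate_background_error(m, pres)
  expect_equal(bg$mean, 0)
  expect_false(bg$qc_warning)

  vals2 <- vals + 0.005
  m2 <- make_vafm(vals2)
  bg2 <- estimate_background_error(m2, call_presence(m2, 0.02))
  expect_true(bg2$qc_warning)

  # no absent cells: undefined, reported as such
  vals3 <- vals + 0.5
  m3 <- make_vafm(vals3)
  bg3 <- estimate_background_error(m3, call_presence(m3, 0.02))
  expect_false(bg3$defined)
})
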