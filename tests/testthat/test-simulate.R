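test_that("the same seed reproduces the identical count table", {
  a <- simulate_patient(sim_config(seed = 7))
  b <- simulate_patient(sim_config(seed = 7))
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth$components, b$truth$components)
  c <- simulate_patient(sim_config(seed = 8))
  expect_false(identical(a$counts, c$counts))
})

test_that("config validation rejects impossible requests", {
  expect_error(sim_config(n_samples = 4))
  expect_error(sim_config(error_rate = 0.5))
  expect_error(simulate_patient(sim_config(seed = 1, hotspot_origins = 12)),
               "disjoint clades")
  expect_error(simulate_patient(sim_config(seed = 1, n_informative_snvs = 10)),
               "two supporting SNVs")
})

test_that("the noise-free limit reproduces the true tree exactly", {
  sim <- simulate_patient(sim_config(seed = 3, mixed_rate = 0, error_rate = 0,
                                     contamination_mean = 0,
                                     read_sampling = "expected"))
  res <- run_patient(sim$counts, sim$sites, sim$samples)
  expect_equal(length(res$resolution$splits), 0L)
  sc <- score_recovery(res, sim$truth)
  expect_true(sc$topology_ok)
  expect_true(sc$mixed_ok)
  expect_true(isTRUE(sc$origins_ok))
})

test_that("thresholding noiseless expected VAFs reproduces the true patterns", {
  sim <- simulate_patient(sim_config(seed = 13, error_rate = 0,
                                     read_sampling = "expected"))
  res_vaf <- vaf_from_counts(sim$counts, sim$sites)
  pres <- call_presence(res_vaf, 0.02)
  for (b in sim$truth$branches) {
    for (snv in b$snv_ids) {
      called <- colnames(pres$calls)[pres$calls[snv, ] == "present"]
      expect_equal(sort(called), b$samples)
    }
  }
})

test_that("clonal heterozygous VAF concentrates at 0.5 x (1 - contamination)", {
  sim <- simulate_patient(sim_config(seed = 17))
  tr <- sim$truth
  vafm <- vaf_from_counts(sim$counts, sim$sites)
  # ancestral branch of the whole ipsilateral clade: lineage fraction 1 in
  # every member sample
  for (b in tr$branches) {
    if (length(b$snv_ids) < 5) next
    for (s in b$samples) {
      comps_s <- tr$components$component_id[tr$components$sample_id == s]
      if (!all(comps_s %in% b$components)) next
      expected <- 0.5 * (1 - tr$contamination[[s]])
      got <- mean(vafm$values[b$snv_ids, s])
      expect_lt(abs(got - expected), 0.02)
    }
  }
})

test_that("truth-negative cells stay below the presence cutoff", {
  sim <- simulate_patient(sim_config(seed = 23))
  vafm <- vaf_from_counts(sim$counts, sim$sites)
  above <- 0L; total <- 0L
  for (b in sim$truth$branches) {
    negs <- setdiff(colnames(vafm$values), b$samples)
    v <- vafm$values[b$snv_ids, negs, drop = FALSE]
    above <- above + sum(v >= 0.02, na.rm = TRUE)
    total <- total + sum(!is.na(v))
  }
  expect_gt(total, 500)
  expect_lt(above / total, 1e-3)
})

test_that("cohorts aggregate accounting and mix lineages at the global rate", {
  cfgs <- lapply(1:6, function(s) sim_config(seed = 100 + s))
  cohort <- simulate_cohort(cfgs)
  acc <- cohort$accounting
  tot <- acc[acc$patient_id == "total", ]
  expect_equal(tot$tested, 6L * (181L + 1L + 3L + 9L + 1L))
  expect_equal(tot$somatic, 6L * 182L)
  expect_equal(tot$n_samples, 66L)
  # mixed count within the central 99% binomial band around rate 0.1
  band <- stats::qbinom(c(0.005, 0.995), 66, 0.1)
  expect_gte(tot$n_mixed, band[1])
  expect_lte(tot$n_mixed, band[2])

  expect_error(simulate_cohort(list()), "empty")
  expect_error(simulate_cohort(cfgs[1:2], patient_ids = c("P1", "P1")),
               "duplicate")
})

test_that("simulation artifacts write to disk and read back", {
  sim <- simulate_patient(sim_config(seed = 2, n_samples = 8,
                                     n_informative_snvs = 80))
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  counts <- read_count_table(file.path(dir, "counts.tsv"))
  expect_equal(nrow(counts), nrow(sim$counts))
  sites <- read_snv_sites(file.path(dir, "sites.tsv"))
  expect_equal(sites$snv_id, sim$sites$snv_id)
  meta <- read_sample_meta(file.path(dir, "samples.tsv"))
  expect_equal(meta$sample_id, sim$samples$sample_id)
})
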