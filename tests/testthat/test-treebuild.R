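test_that("pattern compatibility covers the four relations", {
  expect_equal(check_compatibility(c("S1", "S2"), c("S1", "S2", "S3")), "nested")
  expect_equal(check_compatibility("S1", c("S2", "S3")), "disjoint")
  expect_equal(check_compatibility(c("S1", "S2"), c("S2", "S3")), "conflict")
  expect_equal(check_compatibility(c("S2", "S1"), c("S1", "S2")), "equal")
})

test_that("a conflicting pair splits its shared sample into two components", {
  samples <- c("S1", "S2", "S3")
  cls <- make_classes(list(c("S1", "S2"), c("S2", "S3"), c("S1", "S2", "S3")),
                      samples)
  res <- resolve_mixed_lineages(cls, samples = samples)
  expect_equal(res$n_splits, 1L)
  expect_equal(res$splits[[1]]$sample_id, "S2")
  pats <- lapply(res$classes, `[[`, "components")
  expect_true(any(vapply(pats, function(p)
    setequal(p, c("S1", "S2.1")) || setequal(p, c("S1", "S2.2")), TRUE)))
  # the ancestral class covers both components
  anc <- pats[[3]]
  expect_true(all(c("S2.1", "S2.2") %in% anc))
  # brute force over all split sets and assignments confirms minimality
  verdict <- check_resolution_instance(c(3L, 6L, 7L))  # {S1,S2},{S2,S3},{S1,S2,S3}
  expect_true(isTRUE(verdict))
})

test_that("a laminar family needs no splits and resolves to itself", {
  samples <- c("S1", "S2", "S3", "S4")
  pats <- list(c("S1", "S2"), c("S1", "S2", "S3"), "S4")
  cls <- make_classes(pats, samples)
  res <- resolve_mixed_lineages(cls, samples = samples)
  expect_equal(res$n_splits, 0L)
  expect_equal(lapply(res$classes, `[[`, "components"),
               lapply(cls, function(cl) sort(cl$pattern)))
})

test_that("three mutually conflicting classes at one sample are an error", {
  samples <- c("S1", "S2", "S3", "S4")
  cls <- make_classes(list(c("S1", "S2"), c("S2", "S3"), c("S2", "S4"),
                           c("S1", "S2", "S3", "S4")), samples)
  # {S1,S2} vs {S2,S3} vs {S2,S4}: odd cycle in the conflict graph at S2
  expect_error(resolve_mixed_lineages(cls, samples = samples),
               "more than two lineages")
})

test_that("build_tree turns a laminar family into the caterpillar tree", {
  samples <- c("S1", "S2", "S3")
  pats <- list(c("S1", "S2", "S3"), c("S1", "S2"), "S1", "S2", "S3")
  counts <- c(4L, 6L, 3L, 5L, 2L)
  cls <- make_classes(pats, samples, members_per = 1L)
  for (i in seq_along(cls)) {
    cls[[i]]$members <- sprintf("m%02d_%d", i, seq_len(counts[i]))
  }
  tree <- build_tree(resolve_mixed_lineages(cls, samples = samples))
  n <- tree$nodes
  expect_equal(n[["n01"]]$pattern, c("S1", "S2", "S3"))
  expect_equal(n[["n01"]]$n_snvs, 4L)
  expect_equal(n[["n01"]]$parent, "root")
  expect_equal(n[["n02"]]$pattern, c("S1", "S2"))
  expect_equal(n[["n02"]]$n_snvs, 6L)
  expect_equal(n[["n02"]]$parent, "n01")
  expect_equal(n[["S1"]]$parent, "n02")
  expect_equal(n[["S2"]]$parent, "n02")
  expect_equal(n[["S3"]]$parent, "n01")
  expect_equal(n[["S1"]]$n_snvs, 3L)
  expect_equal(n[["S2"]]$n_snvs, 5L)
  expect_equal(n[["S3"]]$n_snvs, 2L)
  # conservation of SNVs over branches
  expect_equal(sum(vapply(n, `[[`, 0L, "n_snvs")), sum(counts))
})

test_that("with no patterns every sample attaches at the root (star tree)", {
  samples <- c("S1", "S2", "S3")
  cls <- structure(list(), class = "phylo_classes", samples = samples)
  tree <- build_tree(resolve_mixed_lineages(cls, samples = samples))
  for (s in samples) expect_equal(tree$nodes[[s]]$parent, "root")
  expect_length(tree$nodes[["root"]]$children, 3L)
})

test_that("random laminar families are reproduced exactly by build_tree", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    samples <- sprintf("S%d", seq_len(n))
    # random laminar family from random binary joins, random subset kept
    pats <- list()
    clades <- as.list(samples)
    while (length(clades) > 1L) {
      pick <- sample.int(length(clades), 2L)
      merged <- sort(c(clades[[pick[1]]], clades[[pick[2]]]))
      clades <- c(clades[-pick], list(merged))
      pats <- c(pats, list(merged))
    }
    pats <- c(pats[lengths(pats) < n], as.list(samples))
    keep <- sample(length(pats), max(2, rbinom(1, length(pats), 0.7)))
    pats <- unique(pats[keep])
    cls <- make_classes(pats, samples)
    tree <- build_tree(resolve_mixed_lineages(cls, samples = samples))
    got <- tree_patterns(tree)
    expect_equal(length(got), length(pats))
    expect_setequal(vapply(got, paste, "", collapse = ","),
                    vapply(pats, function(p) paste(sort(p), collapse = ","), ""))
    # no pair of branch patterns conflicts on any built tree
    for (i in seq_along(got)) for (j in seq_len(i - 1L)) {
      expect_false(check_compatibility(got[[i]], got[[j]]) == "conflict")
    }
  }
})

test_that("adding a class on an existing branch changes counts, not topology", {
  samples <- c("S1", "S2", "S3", "S4")
  pats <- list(c("S1", "S2"), c("S1", "S2", "S3"))
  cls <- make_classes(pats, samples)
  t1 <- build_tree(resolve_mixed_lineages(cls, samples = samples))
  cls2 <- make_classes(c(pats, list(c("S1", "S2"))), samples)
  t2 <- build_tree(resolve_mixed_lineages(cls2, samples = samples))
  key <- function(t) sort(vapply(tree_patterns(t), paste, "", collapse = ","))
  expect_equal(key(t1), key(t2))
  n_at <- function(t) t$nodes[["n02"]]$n_snvs
  expect_equal(n_at(t2), n_at(t1) + 2L)
})

test_that("vaf_sum_check validates mixtures and estimates proportions", {
  samples <- c("S1", "S2", "S3")
  cls <- make_classes(list(c("S1", "S2"), c("S2", "S3"), c("S1", "S2", "S3")),
                      samples)
  res <- resolve_mixed_lineages(cls, samples = samples)
  tree <- build_tree(res)
  # ancestral mean 0.40 in S2; components 0.22 and 0.18 -> pass, 0.55/0.45
  vals <- rbind(c(0.40, 0.22, 0.00), c(0.40, 0.22, 0.00),
                c(0.00, 0.18, 0.40), c(0.00, 0.18, 0.40),
                c(0.40, 0.40, 0.40), c(0.40, 0.40, 0.40))
  dimnames(vals) <- list(sprintf("snv%03d", 1:6), samples)
  check <- vaf_sum_check(tree, make_vafm(vals), tolerance = 0.10)
  expect_equal(nrow(check), 1L)
  expect_true(check$pass)
  expect_equal(sort(c(check$prop_1, check$prop_2)), c(0.45, 0.55))

  # components far below the ancestral level flag a spurious split
  vals2 <- vals
  vals2[1:4, "S2"] <- 0.05
  check2 <- vaf_sum_check(tree, make_vafm(vals2), tolerance = 0.10)
  expect_false(check2$pass)
})

test_that("implementation matches the brute-force oracle on random instances", {
  set.seed(99)
  masks <- function(k) sort(sample(1:31, k))
  for (rep in 1:60) {
    inst <- masks(sample(2:6, 1))
    expect_true(isTRUE(check_resolution_instance(inst)))
  }
})
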