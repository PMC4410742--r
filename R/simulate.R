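# Ground-truthed simulator of targeted deep-resequencing count data.
#
# Generative model: a patient's samples descend from a rooted binary lineage
# tree with an early bilateral (left/right) split; somatic SNVs arise on
# branches (every branch carries at least two, with more SNVs on
# leaf-proximal branches, where tumor evolution concentrates cell divisions);
# each sample is the clonal expansion of one ancestral cell, or — for
# mixed-lineage lesions — of two, with near-equal mixing proportions. All
# SNVs are heterozygous and fully clonal within their lineage, so the cell
# fraction of an SNV in a sample is
#   0.5 * (1 - contamination) * (lineage fraction carrying it),
# and read counts are multinomial at the configured depth with symmetric
# per-read sequencing error. Germline (all-sample), false-positive
# (no-sample) and PCR-failure assays are appended, and a hotspot site with a
# requested number of independent origins on disjoint clades emulates
# recurrent driver mutations.

#' Simulator configuration
#'
#' Defaults emulate the targeted-resequencing matrices the pipeline is built
#' for: 11 samples and 181 informative SNVs per patient, per-site depths
#' around 10^4 (log-normal), per-read error rate 5e-4, ~50% normal-cell
#' contamination, a 1-in-10 mixed-lineage rate among lesional samples, and
#' two independent hotspot origins.
#'
#' @param seed Integer RNG seed; the single global generator is seeded once
#'   per simulated patient.
#' @param n_samples Total samples including one normal control (>= 6).
#' @param n_informative_snvs Somatic SNVs distributed over tree branches.
#' @param depth_meanlog,depth_sdlog Log-normal read-depth parameters
#'   (median `exp(depth_meanlog)`).
#' @param error_rate Per-read probability of reporting each specific wrong
#'   nucleotide (so an all-reference site shows an expected VAF of
#'   `error_rate` for any one alternative).
#' @param contamination_mean,contamination_conc Beta parameters (mean and
#'   concentration) of per-sample normal-cell contamination.
#' @param mixed_rate Per-lesional-sample probability of a two-lineage origin.
#' @param hotspot_origins Number of independent origins of the hotspot
#'   mutation placed on disjoint clades (0 disables the hotspot assay).
#' @param n_germline,n_false_positive,n_pcr_failure Extra assay counts.
#' @param mixing_prop_range Range of the first component's mixing proportion;
#'   drawn on a 1% grid (lesions mix near-equal numbers of cells).
#' @param read_sampling `"binomial"` for multinomial read sampling,
#'   `"expected"` for deterministic expected counts at fixed depth
#'   `round(exp(depth_meanlog))` (the noise-free limit).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_samples = 11L, n_informative_snvs = 181L,
                       depth_meanlog = log(1e4), depth_sdlog = 0.5,
                       error_rate = 5e-4, contamination_mean = 0.5,
                       contamination_conc = 40, mixed_rate = 0.1,
                       hotspot_origins = 2L, n_germline = 3L,
                       n_false_positive = 9L, n_pcr_failure = 1L,
                       mixing_prop_range = c(0.4, 0.6),
                       read_sampling = c("binomial", "expected")) {
  read_sampling <- match.arg(read_sampling)
  cfg <- list(seed = as.integer(seed), n_samples = as.integer(n_samples),
              n_informative_snvs = as.integer(n_informative_snvs),
              depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
              error_rate = error_rate,
              contamination_mean = contamination_mean,
              contamination_conc = contamination_conc,
              mixed_rate = mixed_rate,
              hotspot_origins = as.integer(hotspot_origins),
              n_germline = as.integer(n_germline),
              n_false_positive = as.integer(n_false_positive),
              n_pcr_failure = as.integer(n_pcr_failure),
              mixing_prop_range = mixing_prop_range,
              read_sampling = read_sampling)
  with(cfg, {
    stopifnot(n_samples >= 6L, n_informative_snvs > 0L,
              error_rate >= 0, error_rate < 1 / 3,
              contamination_mean >= 0, contamination_mean < 1,
              mixed_rate >= 0, mixed_rate <= 1,
              hotspot_origins >= 0L, n_germline >= 0L,
              n_false_positive >= 0L, n_pcr_failure >= 0L,
              mixing_prop_range[1] > 0, mixing_prop_range[2] < 1,
              mixing_prop_range[1] <= mixing_prop_range[2])
  })
  class(cfg) <- "sim_config"
  cfg
}

# random binary join over a set of leaf units; returns every clade pattern
# (including singleton leaf branches and the full side clade)
random_join_patterns <- function(leaves) {
  pats <- as.list(leaves)
  clades <- as.list(leaves)
  while (length(clades) > 1L) {
    pick <- sample.int(length(clades), 2L)
    merged <- sort(c(clades[[pick[1L]]], clades[[pick[2L]]]))
    clades <- c(clades[-pick], list(merged))
    pats <- c(pats, list(merged))
  }
  pats
}

unit_sample <- function(u) sub("\\.[12]$", "", u)

# minimum number of disjoint clades (patterns or leaves) covering exactly U,
# computed from the laminar truth family: count maximal pure nodes
truth_min_origins <- function(patterns, units, positives) {
  nodes <- c(patterns, as.list(units))
  keys <- vapply(nodes, pat_key, "")
  nodes <- nodes[!duplicated(keys)]
  pure <- nodes[vapply(nodes, function(p) all(p %in% positives), TRUE)]
  if (length(pure) == 0L) return(0L)
  maximal <- vapply(seq_along(pure), function(i) {
    !any(vapply(seq_along(pure), function(j) {
      j != i && length(pure[[j]]) > length(pure[[i]]) &&
        all(pure[[i]] %in% pure[[j]])
    }, TRUE))
  }, TRUE)
  sum(maximal)
}

#' Simulate one patient
#'
#' @param config A [sim_config()].
#' @param patient_id Patient identifier used in the emitted tables.
#' @return List with `counts` (an `allele_count_table`), `sites`
#'   ([snv_sites]), `samples` ([sample_meta]) and `truth` (class
#'   `sim_truth`): the true component tree (`branches` with their SNV ids),
#'   `components` with mixing proportions, `mixed_samples`, per-sample
#'   `contamination`, the `hotspot` origin placement, and the `expected`
#'   recoverable structure (branches grouped by sample-level pattern, with
#'   private classes of mixed samples pooled as joint-private).
#' @export
simulate_patient <- function(config = sim_config(), patient_id = "P1") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  ids <- sprintf("S%02d", seq_len(n))
  normal <- ids[1L]
  contra <- ids[2:3]
  ipsi <- ids[4:n]
  histo <- c("normal", sample(c("CCL", "AH"), 2L, replace = TRUE),
             "IDC", "DCIS",
             sample(c("CCL", "AH", "FEA", "UDH"), n - 5L, replace = TRUE))
  samples <- data.frame(sample_id = ids, patient_id = patient_id,
                        histology = histo,
                        side = c("unknown", rep("contralateral", 2L),
                                 rep("ipsilateral", n - 3L)))
  class(samples) <- c("sample_meta", "data.frame")
  lesional <- c(contra, ipsi)

  base_patterns <- c(random_join_patterns(contra), random_join_patterns(ipsi))

  # mixed-lineage lesions: a second ancestral component grafted into a clade
  # that shares a common (non-root) ancestor with the first, so that the
  # mixture leaves ancestral SNVs at full VAF and conflicting lineage
  # classes. The grafted configuration is accepted only when the conflicts
  # it induces force exactly the mixed samples to be split (sequential
  # grafts can otherwise mask an earlier mixture); rejected configurations
  # are redrawn, shrinking the mixed set if necessary.
  mixed_flags <- lesional[stats::runif(length(lesional)) < config$mixed_rate]
  graft_attempt <- function(targets) {
    patterns <- base_patterns
    units <- ids
    mixed_done <- character(0)
    graft_one <- function(m) {
      containing <- which(vapply(patterns, function(p) m %in% p, TRUE) &
                            lengths(patterns) >= 2L)
      if (length(containing) == 0L) return(FALSE)
      p1 <- patterns[[containing[which.min(lengths(patterns[containing]))]]]
      p1_samples <- unique(unit_sample(p1))
      valid_b <- which(vapply(seq_along(patterns), function(i) {
        b <- patterns[[i]]
        if (length(intersect(unique(unit_sample(b)), p1_samples)) > 0L) return(FALSE)
        any(vapply(patterns, function(cc)
          length(cc) > length(b) && all(b %in% cc) && m %in% cc, TRUE))
      }, TRUE))
      if (length(valid_b) == 0L) return(FALSE)
      b_idx <- if (length(valid_b) == 1L) valid_b else sample(valid_b, 1L)
      b <- patterns[[b_idx]]
      c2 <- paste0(m, ".2")
      for (i in seq_along(patterns)) {
        p <- patterns[[i]]
        if (length(p) > length(b) && all(b %in% p)) {
          patterns[[i]] <<- sort(c(p, c2))
        }
      }
      patterns[[length(patterns) + 1L]] <<- sort(c(b, c2))
      patterns[[length(patterns) + 1L]] <<- c2
      c1 <- paste0(m, ".1")
      patterns <<- lapply(patterns, function(p) sort(ifelse(p == m, c1, p)))
      units <<- c(setdiff(units, m), c1, c2)
      TRUE
    }
    for (m in sort(targets)) {
      if (graft_one(m)) {
        mixed_done <- c(mixed_done, m)
      } else {
        # no clade shares ancestry with this lesion: move the flag elsewhere
        alt <- setdiff(lesional, c(targets, mixed_done))
        for (a in sample(alt)) {
          if (graft_one(a)) {
            mixed_done <- c(mixed_done, a)
            break
          }
        }
      }
    }
    # forced split set = union of conflicting-pair overlaps at sample level;
    # accept only if it is exactly the mixed set
    spats <- unique(lapply(patterns, function(p) sort(unique(unit_sample(p)))))
    forced <- character(0)
    np <- length(spats)
    for (i in seq_len(np - 1L)) {
      for (j in (i + 1L):np) {
        if (pat_relation(spats[[i]], spats[[j]]) == "conflict") {
          forced <- union(forced, intersect(spats[[i]], spats[[j]]))
        }
      }
    }
    if (!setequal(forced, mixed_done)) return(NULL)
    # distinct branches projecting onto one sample-level pattern are not
    # identifiable from presence calls; only the private pools of a mixed
    # sample are allowed to coincide (they rejoin on display anyway)
    skeys <- vapply(patterns, function(p) pat_key(unique(unit_sample(p))), "")
    for (g in split(seq_along(patterns), skeys)) {
      if (length(g) < 2L) next
      samp <- unique(unit_sample(patterns[[g[1L]]]))
      if (!(length(samp) == 1L && samp %in% mixed_done)) return(NULL)
    }
    list(patterns = patterns, units = units, mixed = sort(mixed_done))
  }
  targets <- sort(mixed_flags)
  built <- NULL
  repeat {
    for (a in seq_len(20L)) {
      built <- graft_attempt(targets)
      if (!is.null(built)) break
    }
    if (!is.null(built) || length(targets) == 0L) break
    targets <- targets[-length(targets)]
  }
  patterns <- built$patterns
  units <- built$units
  mixed_samples <- built$mixed

  grid <- seq(config$mixing_prop_range[1L], config$mixing_prop_range[2L],
              by = 0.01)
  comp_rows <- lapply(ids, function(s) {
    if (s %in% mixed_samples) {
      p1 <- if (length(grid) == 1L) grid else sample(grid, 1L)
      data.frame(component_id = component_ids(s), sample_id = s,
                 proportion = c(p1, 1 - p1))
    } else {
      data.frame(component_id = s, sample_id = s, proportion = 1)
    }
  })
  components <- do.call(rbind, comp_rows)
  rownames(components) <- NULL

  # SNVs per branch: two guaranteed, the rest weighted toward the leaves
  n_br <- length(patterns)
  if (config$n_informative_snvs < 2L * n_br) {
    fail("simulate_patient: %d informative SNVs cannot give every one of %d branches two supporting SNVs",
         config$n_informative_snvs, n_br)
  }
  depth_of <- vapply(patterns, function(p) {
    1L + sum(vapply(patterns, function(q)
      length(q) > length(p) && all(p %in% q), TRUE))
  }, 0L)
  extra <- as.integer(stats::rmultinom(1L, config$n_informative_snvs - 2L * n_br,
                                       depth_of^2 / sum(depth_of^2)))
  per_branch <- 2L + extra
  snv_ids <- sprintf("snv%04d", seq_len(config$n_informative_snvs))
  branch_snvs <- split(snv_ids, rep(seq_len(n_br), per_branch))
  branches <- lapply(seq_len(n_br), function(i) {
    list(components = patterns[[i]],
         samples = sort(unique(unit_sample(patterns[[i]]))),
         snv_ids = branch_snvs[[i]])
  })

  # hotspot origins on disjoint clades whose union no smaller clade set covers
  hotspot <- NULL
  if (config$hotspot_origins > 0L) {
    k <- config$hotspot_origins
    found <- FALSE
    for (try in seq_len(200L)) {
      ord <- sample.int(n_br)
      chosen <- integer(0)
      for (i in ord) {
        if (all(vapply(chosen, function(j)
          length(intersect(patterns[[i]], patterns[[j]])) == 0L, TRUE))) {
          chosen <- c(chosen, i)
          if (length(chosen) == k) break
        }
      }
      if (length(chosen) < k) next
      pos <- sort(unique(unlist(patterns[chosen])))
      if (truth_min_origins(patterns, units, pos) == k) {
        found <- TRUE
        break
      }
    }
    if (!found) {
      fail("simulate_patient: requested %d hotspot origins exceed the available disjoint clades",
           k)
    }
    hotspot <- list(snv_id = "hotspot1",
                    origin_components = patterns[chosen],
                    positive_components = pos,
                    positive_samples = sort(unique(unit_sample(pos))),
                    n_origins = k)
  }

  germ_ids <- if (config$n_germline > 0L)
    sprintf("germ%02d", seq_len(config$n_germline)) else character(0)
  fp_ids <- if (config$n_false_positive > 0L)
    sprintf("fpos%02d", seq_len(config$n_false_positive)) else character(0)
  pcr_ids <- if (config$n_pcr_failure > 0L)
    sprintf("pfail%02d", seq_len(config$n_pcr_failure)) else character(0)
  assay_ids <- c(snv_ids, if (!is.null(hotspot)) hotspot$snv_id,
                 germ_ids, fp_ids, pcr_ids)

  contamination <- stats::setNames(
    stats::rbeta(n, config$contamination_mean * config$contamination_conc,
                 (1 - config$contamination_mean) * config$contamination_conc),
    ids)

  # cell-level alternative allele fraction per (assay, sample)
  lineage_fraction <- function(pattern) {
    vapply(ids, function(s) {
      cs <- components$component_id[components$sample_id == s]
      sum(components$proportion[components$sample_id == s][cs %in% pattern])
    }, 0)
  }
  f <- matrix(0, length(assay_ids), n, dimnames = list(assay_ids, ids))
  for (i in seq_len(n_br)) {
    lam <- lineage_fraction(patterns[[i]])
    f[branches[[i]]$snv_ids, ] <-
      matrix(0.5 * (1 - contamination) * lam, length(branches[[i]]$snv_ids),
             n, byrow = TRUE)
  }
  if (!is.null(hotspot)) {
    lam <- lineage_fraction(hotspot$positive_components)
    f[hotspot$snv_id, ] <- 0.5 * (1 - contamination) * lam
  }
  if (length(germ_ids) > 0L) f[germ_ids, ] <- 0.5

  sites <- data.frame(
    snv_id = assay_ids,
    chrom = as.character(sample.int(22L, length(assay_ids), replace = TRUE)),
    pos = sample.int(2e8L, length(assay_ids)),
    ref = "A", alt = "G", is_hotspot = FALSE)
  refs <- sample(NUCLEOTIDES, length(assay_ids), replace = TRUE)
  alts <- vapply(refs, function(r) sample(setdiff(NUCLEOTIDES, r), 1L), "")
  sites$ref <- refs
  sites$alt <- unname(alts)
  if (!is.null(hotspot)) {
    hi <- match(hotspot$snv_id, sites$snv_id)
    sites$chrom[hi] <- "3"
    sites$pos[hi] <- 178952085
    sites$ref[hi] <- "A"
    sites$alt[hi] <- "G"
    sites$is_hotspot[hi] <- TRUE
  }
  class(sites) <- c("snv_sites", "data.frame")

  # read depths and counts
  n_assay <- length(assay_ids)
  if (config$read_sampling == "expected") {
    depth <- matrix(round(exp(config$depth_meanlog)), n_assay, n,
                    dimnames = list(assay_ids, ids))
  } else {
    depth <- matrix(pmax(1L, round(stats::rlnorm(n_assay * n,
                                                 config$depth_meanlog,
                                                 config$depth_sdlog))),
                    n_assay, n, dimnames = list(assay_ids, ids))
  }
  if (length(pcr_ids) > 0L) {
    depth[pcr_ids, ] <- stats::rpois(length(pcr_ids) * n, 500 / n)
  }
  e <- config$error_rate
  p_alt <- f * (1 - 3 * e) + (1 - f) * e
  d <- as.vector(depth)
  pa <- as.vector(p_alt)
  if (config$read_sampling == "expected") {
    n_alt <- round(d * pa)
    n_o1 <- round(d * e)
    n_o2 <- round(d * e)
    n_ref <- d - n_alt - n_o1 - n_o2
  } else {
    n_alt <- stats::rbinom(length(d), d, pa)
    rem <- d - n_alt
    n_o1 <- stats::rbinom(length(d), rem, e / (1 - pa))
    rem2 <- rem - n_o1
    n_o2 <- stats::rbinom(length(d), rem2, e / (1 - pa - e))
    n_ref <- rem2 - n_o2
  }
  # distribute counts onto the four nucleotide columns per assay
  others <- t(vapply(seq_len(n_assay), function(i)
    setdiff(NUCLEOTIDES, c(sites$ref[i], sites$alt[i])), c("", "")))
  counts <- data.frame(
    patient_id = patient_id,
    snv_id = rep(assay_ids, n),
    sample_id = rep(ids, each = n_assay),
    A = 0L, C = 0L, G = 0L, T = 0L)
  put <- function(nuc_vec, val) {
    for (nt in NUCLEOTIDES) {
      sel <- rep(nuc_vec == nt, n)
      counts[[nt]][sel] <<- counts[[nt]][sel] + as.integer(val[sel])
    }
  }
  put(sites$ref, n_ref)
  put(sites$alt, n_alt)
  put(others[, 1L], n_o1)
  put(others[, 2L], n_o2)
  class(counts) <- c("allele_count_table", "data.frame")

  truth <- structure(list(
    patient_id = patient_id, config = config,
    components = components, branches = branches,
    mixed_samples = mixed_samples, contamination = contamination,
    hotspot = hotspot,
    expected = expected_structure(branches, mixed_samples)),
    class = "sim_truth")
  list(counts = counts, sites = sites, samples = samples, truth = truth)
}

# the structure the pipeline can recover: branches grouped by sample-level
# pattern; singleton-sample patterns of mixed samples pool as joint-private
expected_structure <- function(branches, mixed_samples) {
  skey <- vapply(branches, function(b) pat_key(b$samples), "")
  groups <- split(seq_along(branches), skey)
  fam <- list()
  jp <- list()
  for (g in groups) {
    samp <- branches[[g[1L]]]$samples
    n_snv <- sum(lengths(lapply(branches[g], `[[`, "snv_ids")))
    if (length(samp) == 1L && samp %in% mixed_samples) {
      jp[[samp]] <- n_snv
    } else {
      fam[[length(fam) + 1L]] <- sort(unique(unlist(
        lapply(branches[g], `[[`, "components"))))
    }
  }
  list(family = fam[order(vapply(fam, pat_key, ""))], joint_private = jp)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> patient %s: %d branches, %d mixed sample(s)%s\n",
              x$patient_id, length(x$branches), length(x$mixed_samples),
              if (is.null(x$hotspot)) "" else
                sprintf(", hotspot with %d origins", x$hotspot$n_origins)))
  invisible(x)
}

#' Simulate a cohort of independent patients
#'
#' @param configs List of [sim_config()] objects, one per patient (seeds
#'   should differ).
#' @param patient_ids Patient identifiers; must be unique.
#' @return List with `patients` (one [simulate_patient()] result each) and
#'   `accounting` (per-patient assay accounting in the tested / failures /
#'   germline / false-positive / somatic layout, plus a cohort total row).
#' @export
simulate_cohort <- function(configs, patient_ids = NULL) {
  if (length(configs) == 0L) fail("simulate_cohort: empty config list")
  patient_ids <- patient_ids %||% sprintf("P%d", seq_along(configs))
  if (anyDuplicated(patient_ids)) fail("simulate_cohort: duplicate patient ids")
  stopifnot(length(patient_ids) == length(configs))
  patients <- Map(simulate_patient, configs, patient_ids)
  acc <- do.call(rbind, lapply(patients, function(p) {
    cfg <- p$truth$config
    data.frame(patient_id = p$truth$patient_id,
               tested = length(unique(p$counts$snv_id)),
               pcr_failure = cfg$n_pcr_failure,
               germline = cfg$n_germline,
               false_positive = cfg$n_false_positive,
               somatic = cfg$n_informative_snvs +
                 as.integer(cfg$hotspot_origins > 0L),
               n_samples = cfg$n_samples,
               n_mixed = length(p$truth$mixed_samples))
  }))
  total <- data.frame(patient_id = "total", t(colSums(acc[, -1L])))
  names(total) <- names(acc)
  acc <- rbind(acc, total)
  rownames(acc) <- NULL
  list(patients = patients, accounting = acc)
}

#' Write simulated data to disk
#'
#' Emits the allele count table, site and sample metadata TSVs, and the
#' ground truth as JSON.
#'
#' @param sim Output of [simulate_patient()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("counts.tsv", "sites.tsv", "samples.tsv",
                            "truth.json"))
  write_count_table(sim$counts, paths[1L])
  utils::write.table(as.data.frame(sim$sites), paths[2L], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_sample_meta(sim$samples, paths[3L])
  jsonlite::write_json(sim$truth, paths[4L], auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(paths)
}
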