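# Independent brute-force oracles and exhaustive enumeration used by the
# property and equivalence tests. These never call the package's search
# internals: resolution is checked by enumerating every assignment of every
# pattern's split samples, and origin counts by enumerating disjoint clade
# covers.

# ---- exhaustive enumeration of pattern sets up to sample relabeling -------

# All sets of <= max_patterns distinct nonempty presence patterns over
# n_samples samples, reduced to lexicographically-minimal representatives of
# the sample-permutation orbits (a pattern is an integer bitmask).
enumerate_canonical <- function(n_samples = 5L, max_patterns = 6L) {
  nmask <- 2L^n_samples - 1L
  perms <- as.matrix(expand.grid(rep(list(seq_len(n_samples)), n_samples)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == n_samples), ,
                 drop = FALSE]
  remap <- matrix(0L, nrow(perms), nmask)
  for (p in seq_len(nrow(perms))) {
    pr <- perms[p, ]
    for (m in seq_len(nmask)) {
      bits <- which(bitwAnd(m, 2^(seq_len(n_samples) - 1)) > 0)
      remap[p, m] <- sum(2^(pr[bits] - 1))
    }
  }
  # optimal-size sorting networks (compare-exchange pairs) for k = 1..6
  nets <- list(list(), list(c(1, 2)),
    list(c(1, 2), c(1, 3), c(2, 3)),
    list(c(1, 2), c(3, 4), c(1, 3), c(2, 4), c(2, 3)),
    list(c(1, 2), c(3, 4), c(1, 3), c(2, 5), c(4, 5), c(1, 2), c(2, 3),
         c(4, 5), c(3, 4), c(2, 3)),
    list(c(1, 2), c(3, 4), c(5, 6), c(1, 3), c(2, 5), c(4, 6), c(1, 2),
         c(3, 4), c(5, 6), c(2, 3), c(4, 5), c(3, 4)))
  out <- list()
  for (k in seq_len(max_patterns)) {
    cmb <- utils::combn(nmask, k)
    keyself <- rep(0, ncol(cmb))
    for (r in seq_len(k)) keyself <- keyself * (nmask + 1) + cmb[r, ]
    alive <- seq_len(ncol(cmb))
    for (p in seq_len(nrow(perms))[-1]) {
      if (length(alive) == 0L) break
      R <- matrix(remap[p, cmb[, alive, drop = FALSE]], nrow = k)
      if (k >= 2) for (ce in nets[[k]]) {
        a <- R[ce[1], ]; b <- R[ce[2], ]
        R[ce[1], ] <- pmin(a, b); R[ce[2], ] <- pmax(a, b)
      }
      key <- rep(0, length(alive))
      for (r in seq_len(k)) key <- key * (nmask + 1) + R[r, ]
      alive <- alive[key >= keyself[alive]]
    }
    out[[k]] <- cmb[, alive, drop = FALSE]
  }
  out
}

# ---- brute-force mixed-lineage resolution oracle --------------------------

comp_bit_of <- function(s, side) as.integer(2^(5 + 2 * (s - 1) + side - 1))

# canonical key of a component-mask family under per-sample component swaps
flip_canon_masks <- function(fam, S) {
  fam <- sort(as.integer(fam))
  S <- S[vapply(S, function(s) any(bitwAnd(fam, bitwOr(comp_bit_of(s, 1),
                                                       comp_bit_of(s, 2))) > 0), TRUE)]
  nf <- length(S)
  best <- fam
  if (nf > 0L) {
    for (fm in seq_len(2^nf - 1L)) {
      flip <- S[bitwAnd(fm, 2^(seq_len(nf) - 1L)) > 0]
      ff <- fam
      for (s in flip) {
        b1 <- comp_bit_of(s, 1); b2 <- comp_bit_of(s, 2)
        a1 <- bitwAnd(ff, b1) %/% b1
        a2 <- bitwAnd(ff, b2) %/% b2
        ff <- ff - a1 * b1 - a2 * b2 + a1 * b2 + a2 * b1
      }
      ff <- sort(ff)
      d <- ff - best
      nz <- which(d != 0)
      if (length(nz) > 0L && d[nz[1L]] < 0) best <- ff
    }
  }
  paste(best, collapse = ",")
}

# Component bit layout over 15 bits: sample s (1..5) unsplit -> bit s-1;
# split sample s -> bits 5+2(s-1) (side 1) and 6+2(s-1) (side 2).
# Every pattern assigns each split sample it contains to side 1, side 2 or
# both; feasibility of a split set is decided by exhaustive forward-checking
# DFS over those assignments with pairwise laminarity as the only constraint.
# Feasibility is monotone in the split set (splitting an extra sample and
# assigning both components everywhere reproduces any smaller-set solution),
# so one search with every sample split screens out infeasible instances.
oracle_resolve_masks <- function(masks, collect = TRUE) {
  masks <- as.integer(masks)
  n <- length(masks)
  univ_bits <- which(bitwAnd(Reduce(bitwOr, masks, 0L), 2^(0:4)) > 0)
  has <- function(m, s) bitwAnd(m, as.integer(2^(s - 1))) > 0L
  comp_bit <- function(s, side) as.integer(2^(5 + 2 * (s - 1) + side - 1))
  sl_conflict <- outer(masks, masks, function(a, b) {
    ab <- bitwAnd(a, b)
    ab != 0L & ab != a & ab != b
  })
  any_conflict <- apply(sl_conflict, 1, any)

  values_for <- function(i, S) {
    slots <- S[vapply(S, function(s) has(masks[i], s), TRUE)]
    fixed <- masks[i]
    for (s in S) fixed <- bitwAnd(fixed, bitwNot(as.integer(2^(s - 1))))
    vals <- as.integer(fixed)
    for (s in slots) {
      b1 <- comp_bit(s, 1); b2 <- comp_bit(s, 2)
      vals <- c(bitwOr(vals, b1), bitwOr(vals, b2), bitwOr(vals, bitwOr(b1, b2)))
    }
    unique(vals)
  }

  search_S <- function(S, collect_env = NULL) {
    vals <- lapply(seq_len(n), function(i) values_for(i, S))
    ord <- order(-any_conflict, lengths(vals))
    vals <- vals[ord]
    pat_src <- masks[ord]
    # patterns that were singletons of a split sample project identically on
    # both components; they are excluded from the compared family (the
    # implementation pools them as joint-private)
    keep <- !vapply(seq_len(n), function(j) {
      m <- pat_src[j]
      sum(bitwAnd(m, as.integer(2^(0:4))) > 0) == 1L &&
        any(vapply(S, function(s) has(m, s), TRUE))
    }, TRUE)
    found <- FALSE
    acc <- integer(n)
    dfs <- function(i, vs) {
      if (i > n) {
        found <<- TRUE
        if (!is.null(collect_env)) {
          raw <- paste(sort(unique(acc[keep])), collapse = ",")
          if (is.null(collect_env$raw[[raw]])) collect_env$raw[[raw]] <- S
        }
        return(invisible(NULL))
      }
      for (v in vs[[i]]) {
        acc[i] <<- v
        if (i < n) {
          nvs <- vs
          dead <- FALSE
          for (j in (i + 1L):n) {
            w <- nvs[[j]]
            ab <- bitwAnd(w, v)
            w <- w[!(ab != 0L & ab != v & ab != w)]
            if (length(w) == 0L) { dead <- TRUE; break }
            nvs[[j]] <- w
          }
          if (dead) next
          dfs(i + 1L, nvs)
        } else {
          dfs(i + 1L, vs)
        }
        if (found && is.null(collect_env)) return(invisible(NULL))
      }
    }
    dfs(1L, vals)
    found
  }

  if (!search_S(univ_bits)) {
    return(list(feasible = FALSE, k = NA_integer_, families = character(0)))
  }
  for (k in 0:length(univ_bits)) {
    subs <- if (k == 0) list(integer(0)) else
      utils::combn(univ_bits, k, simplify = FALSE)
    coll <- new.env(); coll$raw <- list()
    found_any <- FALSE
    for (S in subs) {
      if (search_S(S, collect_env = if (collect) coll else NULL)) {
        found_any <- TRUE
        if (!collect) break
      }
    }
    if (found_any) {
      fams <- NULL
      if (collect) {
        fams <- unique(vapply(names(coll$raw), function(raw) {
          flip_canon_masks(as.integer(strsplit(raw, ",", fixed = TRUE)[[1]]),
                           coll$raw[[raw]])
        }, ""))
        fams <- sort(unname(fams))
      }
      return(list(feasible = TRUE, k = k, families = fams))
    }
  }
  list(feasible = FALSE, k = NA_integer_, families = character(0))
}

# run the package's resolver on a mask instance and express its revised
# family in the oracle's flip-canonical key form
impl_resolve_masks <- function(masks) {
  pats <- lapply(masks, function(m) paste0("S", which(bitwAnd(m, 2^(0:4)) > 0)))
  cls <- lapply(seq_along(pats), function(i)
    list(class_id = sprintf("c%02d", i), pattern = pats[[i]],
         members = sprintf("m%02d", i), status = "robust"))
  res <- tryCatch(resolve_mixed_lineages(cls, samples = paste0("S", 1:5),
                                         max_splits = 5L, statuses = NULL),
                  error = function(e) NULL)
  if (is.null(res)) return(list(feasible = FALSE))
  comp_to_bit <- function(cid) {
    if (grepl("\\.[12]$", cid)) {
      s <- as.integer(sub("^S(\\d+)\\..*$", "\\1", cid))
      comp_bit_of(s, as.integer(sub("^.*\\.", "", cid)))
    } else {
      as.integer(2^(as.integer(sub("^S", "", cid)) - 1))
    }
  }
  keep <- res$classes[!vapply(res$classes, `[[`, TRUE, "joint_private")]
  fam <- vapply(keep, function(cl)
    Reduce(bitwOr, vapply(cl$components, comp_to_bit, 0L), 0L), 0L)
  S <- as.integer(sub("^S", "", vapply(res$splits, `[[`, "", "sample_id")))
  list(feasible = TRUE, k = res$n_splits, key = flip_canon_masks(fam, S))
}

# agreement check for one instance; returns TRUE or a description
check_resolution_instance <- function(masks) {
  o <- oracle_resolve_masks(masks)
  im <- impl_resolve_masks(masks)
  if (o$feasible != im$feasible) {
    return(sprintf("feasibility differs for {%s}", paste(masks, collapse = ",")))
  }
  if (!o$feasible) return(TRUE)
  if (o$k != im$k) {
    return(sprintf("min splits differ for {%s}: oracle %d impl %d",
                   paste(masks, collapse = ","), o$k, im$k))
  }
  if (!(im$key %in% o$families)) {
    return(sprintf("impl family not among oracle optima for {%s}",
                   paste(masks, collapse = ",")))
  }
  if (length(o$families) == 1L && im$key != o$families[1L]) {
    return(sprintf("unique topology differs for {%s}",
                   paste(masks, collapse = ",")))
  }
  TRUE
}

# ---- brute-force minimum disjoint-clade cover -----------------------------

oracle_min_origins <- function(tree, positives) {
  positives <- sort(unique(positives))
  if (length(positives) == 0L) return(0L)
  all_comps <- sort(tree$components$component_id)
  clades <- c(tree_clades(tree), list(root = all_comps))
  pure <- clades[vapply(clades, function(cl) all(cl %in% positives), TRUE)]
  np <- length(pure)
  for (k in seq_len(np)) {
    for (pick_idx in utils::combn(np, k, simplify = FALSE)) {
      u <- unlist(pure[pick_idx])
      if (length(u) == length(unique(u)) && setequal(u, positives)) {
        return(k)
      }
    }
  }
  stop("no disjoint clade cover found")  # unreachable: leaves are clades
}

# random lineage tree over n_leaves samples via random binary joins; each
# clade carries one class
random_lineage_tree <- function(n_leaves) {
  leaves <- sprintf("L%02d", seq_len(n_leaves))
  pats <- as.list(leaves)
  clades <- as.list(leaves)
  while (length(clades) > 1L) {
    pick <- sample.int(length(clades), 2L)
    merged <- sort(c(clades[[pick[1L]]], clades[[pick[2L]]]))
    clades <- c(clades[-pick], list(merged))
    pats <- c(pats, list(merged))
  }
  pats <- pats[lengths(pats) < n_leaves]  # the full set is the root, not a branch
  cls <- make_classes(pats, samples = leaves, members_per = 1L)
  build_tree(resolve_mixed_lineages(cls, samples = leaves))
}
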