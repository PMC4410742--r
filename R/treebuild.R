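# Parsimony treebuilding from robust phylogenetic classes.
#
# A set of patterns is representable as clades of one rooted tree exactly when
# it is a laminar family: any two patterns are nested, disjoint or equal.
# Patterns that conflict (overlap without nesting) cannot place some sample
# unambiguously; such a sample is resolved by "duplicating" it into exactly
# two leaf components that are placed independently and rejoined for display.

#' Pairwise pattern compatibility
#'
#' @param a,b Character vectors of sample (or component) ids over the same
#'   universe.
#' @return One of `"equal"`, `"nested"`, `"disjoint"`, `"conflict"`. Two
#'   patterns conflict iff they overlap and neither contains the other.
#' @export
check_compatibility <- function(a, b) pat_relation(a, b)

pat_relation <- function(a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  ninter <- length(intersect(a, b))
  if (ninter == 0L) return("disjoint")
  if (ninter == length(a) && ninter == length(b)) return("equal")
  if (ninter == length(a) || ninter == length(b)) return("nested")
  "conflict"
}

relation_matrix <- function(patterns) {
  n <- length(patterns)
  rel <- matrix("equal", n, n)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        rel[i, j] <- rel[j, i] <- pat_relation(patterns[[i]], patterns[[j]])
      }
    }
  }
  rel
}

family_is_laminar <- function(patterns) {
  n <- length(patterns)
  if (n < 2L) return(TRUE)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (pat_relation(patterns[[i]], patterns[[j]]) == "conflict") return(FALSE)
    }
  }
  TRUE
}

component_ids <- function(sample_id) paste0(sample_id, c(".1", ".2"))

#' Resolve mixed-lineage samples
#'
#' Finds a minimum-cardinality set of samples to duplicate into exactly two
#' leaf components such that, after reassigning each conflicting class to one
#' component (ancestral, non-conflicting classes keep both components), all
#' pairwise pattern relations are nested, disjoint or equal. Because a
#' conflicting pair keeps private members on both sides, it can only be
#' resolved by becoming disjoint, which requires splitting every sample in
#' its overlap — so the minimum split set is exactly the union of all
#' conflicting-pair overlaps. Conflicting classes sharing a split sample take
#' opposite components (a 2-coloring of their conflict graph); remaining
#' classes default to covering both components but may be forced onto a
#' single side by nesting, found by backtracking with laminarity pruning in a
#' canonical deterministic order. At most two lineages per sample are
#' modeled; a sample whose conflicting classes admit no bipartition (odd
#' cycle in their conflict graph) raises an error naming the classes.
#'
#' Private classes of a split sample (singleton patterns) project identically
#' onto both components and cannot be attributed by pattern; they are kept as
#' a joint private pool of the rejoined sample, excluded from the laminarity
#' universe.
#'
#' @param classes A `phylo_classes` object (or plain list of class records).
#' @param samples Character vector of all sample ids of the patient (samples
#'   carrying no class still become leaves); defaults to the classes'
#'   attribute or the union of patterns.
#' @param max_splits Cap on the number of split samples searched (default 6).
#' @param statuses Class statuses admitted into resolution (default
#'   `"robust"`); `NULL` admits every class given.
#' @return Object of class `lineage_resolution`: list with `components`
#'   (data frame `component_id`, `sample_id`, `proportion`), `splits` (one
#'   record per split sample with the class partition), `classes` (input
#'   classes with revised `components` patterns and a `joint_private` flag),
#'   `n_splits`, `reassigned_classes`, `samples`.
#' @export
resolve_mixed_lineages <- function(classes, samples = NULL, max_splits = 6L,
                                   statuses = "robust") {
  cls <- unclass(classes)
  if (!is.null(statuses)) {
    keep <- vapply(cls, function(cl) (cl$status %||% "robust") %in% statuses, TRUE)
    cls <- cls[keep]
  }
  cls <- cls[lengths(lapply(cls, `[[`, "pattern")) > 0L]
  samples <- samples %||% attr(classes, "samples") %||%
    sort(unique(unlist(lapply(cls, `[[`, "pattern"))))

  pkeys <- vapply(cls, function(cl) pat_key(cl$pattern), "")
  ukeys <- unique(pkeys)
  upats <- lapply(ukeys, pat_from_key)
  pat_of_class <- match(pkeys, ukeys)
  n <- length(upats)
  rel <- relation_matrix(upats)
  conflict_pairs <- which(rel == "conflict" & upper.tri(rel), arr.ind = TRUE)

  finish <- function(S, side_of) {
    # side_of: named list sample -> integer vector over upats (1, 2, or 0=both);
    # only consulted for samples in S.
    comp_df <- do.call(rbind, lapply(samples, function(s) {
      if (s %in% S) {
        data.frame(component_id = component_ids(s), sample_id = s,
                   proportion = 0.5)
      } else {
        data.frame(component_id = s, sample_id = s, proportion = 1)
      }
    }))
    rownames(comp_df) <- NULL
    revise <- function(p) {
      out <- character(0)
      pi <- match(pat_key(p), ukeys)
      for (x in p) {
        if (!(x %in% S)) {
          out <- c(out, x)
        } else {
          side <- side_of[[x]][pi]
          out <- c(out, if (side == 0L) component_ids(x) else
            paste0(x, ".", side))
        }
      }
      sort(out)
    }
    out_classes <- lapply(cls, function(cl) {
      cl$joint_private <- length(cl$pattern) == 1L && cl$pattern %in% S
      cl$components <- revise(cl$pattern)
      cl
    })
    splits <- lapply(sort(S), function(s) {
      in_s <- vapply(cls, function(cl) s %in% cl$pattern, TRUE)
      ids <- vapply(cls, function(cl) cl$class_id %||% NA_character_, "")
      pi <- pat_of_class
      side <- vapply(seq_along(cls), function(i) {
        if (!in_s[i]) return(NA_integer_)
        side_of[[s]][pi[i]]
      }, 0L)
      list(sample_id = s,
           components = component_ids(s),
           classes_1 = ids[!is.na(side) & side == 1L],
           classes_2 = ids[!is.na(side) & side == 2L],
           classes_both = ids[!is.na(side) & side == 0L])
    })
    reassigned <- sum(vapply(seq_along(cls), function(i) {
      any(vapply(S, function(s) {
        s %in% cls[[i]]$pattern && side_of[[s]][pat_of_class[i]] != 0L
      }, TRUE))
    }, TRUE))
    structure(list(components = comp_df, splits = splits,
                   classes = structure(out_classes, samples = samples),
                   n_splits = length(S),
                   reassigned_classes = as.integer(reassigned),
                   samples = samples),
              class = "lineage_resolution")
  }

  if (nrow(conflict_pairs) == 0L) {
    return(finish(character(0), list()))
  }

  contains <- vapply(samples, function(s)
    vapply(upats, function(p) s %in% p, TRUE), logical(n))
  if (n == 1L) contains <- matrix(contains, nrow = 1L, dimnames = list(NULL, samples))

  # A conflicting pair shares members and can never become nested by
  # splitting (each side keeps private members), so it must end up disjoint:
  # every sample in its overlap has to be split, with the two patterns on
  # opposite components throughout. The minimum split set is therefore
  # exactly the union of all conflicting-pair overlaps.
  cand <- sort(unique(unlist(apply(conflict_pairs, 1L, function(pr)
    intersect(upats[[pr[1L]]], upats[[pr[2L]]]), simplify = FALSE))))
  if (length(cand) > max_splits) {
    fail("no mixed-lineage resolution found with at most %d split sample(s) (%d required)",
         max_splits, length(cand))
  }

  # Conflicting patterns at s: contain s and conflict with another pattern
  # containing s.
  k_at <- lapply(cand, function(s) {
    idx <- which(contains[, s])
    idx[vapply(idx, function(i)
      any(rel[i, idx] == "conflict"), TRUE)]
  })
  names(k_at) <- cand
  stopifnot(all(lengths(k_at) > 0L))

  odd_cycle_classes <- NULL
  # 2-colorings of the conflict graph on k_at[[s]]; NULL when non-bipartite.
  colorings_at <- lapply(cand, function(s) {
    idx <- k_at[[s]]
    m <- length(idx)
    col <- rep(NA_integer_, m)
    comp <- rep(NA_integer_, m)
    ncc <- 0L
    for (st in seq_len(m)) {
      if (!is.na(col[st])) next
      ncc <- ncc + 1L
      col[st] <- 1L; comp[st] <- ncc
      queue <- st
      while (length(queue) > 0L) {
        u <- queue[1L]; queue <- queue[-1L]
        nb <- which(rel[idx[u], idx] == "conflict")
        for (v in nb) {
          if (is.na(col[v])) {
            col[v] <- 3L - col[u]; comp[v] <- ncc
            queue <- c(queue, v)
          } else if (col[v] == col[u]) {
            bad <- unlist(lapply(cls[pat_of_class %in% idx],
                                 function(cl) cl$class_id %||% cl$members))
            odd_cycle_classes <<- unique(c(odd_cycle_classes, bad))
            return(NULL)
          }
        }
      }
    }
    # canonical labelling: the connected component holding the smallest
    # pattern key is pinned; remaining components flip freely
    keys_idx <- ukeys[idx]
    cc_min <- vapply(seq_len(ncc), function(cc) min(keys_idx[comp == cc]), "")
    cc_order <- order(cc_min)
    pinned <- cc_order[1L]
    in_pinned <- which(comp == pinned)
    seed <- in_pinned[order(keys_idx[in_pinned])[1L]]
    flips <- if (ncc > 1L) {
      as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), ncc - 1L)))
    } else {
      matrix(FALSE, 1L, 0L)
    }
    out <- vector("list", nrow(flips))
    for (f in seq_len(nrow(flips))) {
      cc_flip <- rep(FALSE, ncc)
      if (ncc > 1L) cc_flip[cc_order[-1L]] <- as.logical(flips[f, ])
      v <- ifelse(cc_flip[comp], 3L - col, col)
      if (v[seed] != 1L) v <- 3L - v   # pin seed pattern to component .1
      out[[f]] <- v
    }
    list(idx = idx, colorings = out)
  })
  names(colorings_at) <- cand

  if (any(vapply(cand, function(s) is.null(colorings_at[[s]]), TRUE))) {
    fail("more than two lineages required: conflicting classes %s admit no two-component resolution",
         paste(odd_cycle_classes, collapse = ", "))
  }

  S <- cand
  # side assignment per (pattern, split sample): 1/2 single side, 0 both,
  # NA sample not in pattern. Conflicted patterns are fixed by a coloring;
  # other patterns containing a split sample default to both components but
  # may be forced onto a single side by nesting (a pattern inside a
  # single-side pattern must follow it), searched by backtracking with
  # laminarity pruning.
  joint_priv <- vapply(seq_len(n), function(i)
    length(upats[[i]]) == 1L && upats[[i]] %in% S, TRUE)
  revise_pat <- function(i, side_row) {
    p <- upats[[i]]
    out <- character(0)
    for (x in p) {
      if (!(x %in% S)) out <- c(out, x)
      else {
        side <- side_row[[x]]
        out <- c(out, if (side == 0L) component_ids(x) else
          paste0(x, ".", side))
      }
    }
    sort(out)
  }
  free_slots <- lapply(seq_len(n), function(i) {
    if (joint_priv[i]) return(character(0))
    Filter(function(s) s %in% upats[[i]] && !(i %in% k_at[[s]]), S)
  })

  combos <- expand.grid(lapply(S, function(s)
    seq_along(colorings_at[[s]]$colorings)), KEEP.OUT.ATTRS = FALSE)
  solution <- NULL
  for (ci in seq_len(nrow(combos))) {
    side_mat <- matrix(NA_integer_, n, length(S), dimnames = list(NULL, S))
    for (m in seq_along(S)) {
      s <- S[m]
      info <- colorings_at[[s]]
      side_mat[info$idx, s] <- info$colorings[[combos[ci, m]]]
      others <- setdiff(which(contains[, s]), info$idx)
      side_mat[others, s] <- 0L  # default: both components
    }
    dfs_pats <- which(!joint_priv)
    fixed <- dfs_pats[lengths(free_slots[dfs_pats]) == 0L]
    free <- dfs_pats[lengths(free_slots[dfs_pats]) > 0L]
    revised <- stats::setNames(vector("list", n), NULL)
    ok <- TRUE
    for (i in fixed) {
      rp <- revise_pat(i, side_mat[i, , drop = TRUE])
      for (j in fixed[fixed < i]) {
        if (pat_relation(rp, revised[[j]]) == "conflict") { ok <- FALSE; break }
      }
      if (!ok) break
      revised[[i]] <- rp
    }
    if (!ok) next
    dfs <- function(pos, side_mat) {
      if (pos > length(free)) return(side_mat)
      i <- free[pos]
      slots <- free_slots[[i]]
      opts <- expand.grid(rep(list(c(0L, 1L, 2L)), length(slots)),
                          KEEP.OUT.ATTRS = FALSE)
      for (r in seq_len(nrow(opts))) {
        side_mat[i, slots] <- as.integer(opts[r, ])
        rp <- revise_pat(i, side_mat[i, , drop = TRUE])
        clash <- FALSE
        for (j in c(fixed, free[seq_len(pos - 1L)])) {
          if (pat_relation(rp, revised[[j]]) == "conflict") { clash <- TRUE; break }
        }
        if (clash) next
        revised[[i]] <<- rp
        res <- dfs(pos + 1L, side_mat)
        if (!is.null(res)) return(res)
      }
      NULL
    }
    res <- dfs(1L, side_mat)
    if (!is.null(res)) {
      solution <- res
      break
    }
  }
  if (is.null(solution)) {
    fail("no mixed-lineage resolution found: the conflicting classes admit no two-component assignment")
  }
  side_of <- stats::setNames(lapply(S, function(s) {
    v <- rep(0L, n)
    has <- which(contains[, s])
    v[has] <- solution[has, s]
    v
  }), S)
  finish(S, side_of)
}

#' @export
print.lineage_resolution <- function(x, ...) {
  cat(sprintf("<lineage_resolution> %d sample(s) split, %d class(es) reassigned\n",
              x$n_splits, x$reassigned_classes))
  invisible(x)
}

#' Build the lineage tree from a laminar pattern family
#'
#' The containment hierarchy of the revised class patterns becomes the
#' internal-node structure: equal patterns merge onto one branch (SNV counts
#' add), each leaf component attaches below the smallest pattern containing
#' it, and components carried by no pattern attach at the root, which
#' represents the zygote. Multifurcations are retained, never arbitrarily
#' resolved.
#'
#' @param resolution A `lineage_resolution` from [resolve_mixed_lineages()].
#' @param samples Optional [sample_meta] annotation for the leaves.
#' @return Object of class `lineage_tree`: list with `nodes` (named list of
#'   node records: `id`, `type`, `parent`, `children`, `pattern`, `classes`,
#'   `n_snvs`, and for leaves `sample` and `proportion`), `root`,
#'   `components`, `joint_private`, `samples`, `resolution`.
#' @export
build_tree <- function(resolution, samples = NULL) {
  stopifnot(inherits(resolution, "lineage_resolution"))
  comps <- resolution$components
  cls <- resolution$classes
  placed <- cls[!vapply(cls, `[[`, TRUE, "joint_private")]
  pats <- lapply(placed, `[[`, "components")
  if (!family_is_laminar(pats)) {
    fail("build_tree: pattern family is not laminar; resolve conflicts first")
  }
  keys <- vapply(pats, pat_key, "")
  ukeys <- unique(keys)
  merged <- lapply(ukeys, function(k) {
    idx <- which(keys == k)
    list(pattern = pat_from_key(k),
         classes = vapply(placed[idx], function(cl) cl$class_id %||% "", ""),
         n_snvs = sum(lengths(lapply(placed[idx], `[[`, "members"))))
  })

  nodes <- list()
  for (i in seq_len(nrow(comps))) {
    cid <- comps$component_id[i]
    nodes[[cid]] <- list(id = cid, type = "leaf", parent = NA_character_,
                         children = character(0), pattern = cid,
                         classes = character(0), n_snvs = 0L,
                         sample = comps$sample_id[i],
                         proportion = comps$proportion[i])
  }
  internal <- list()
  for (m in merged) {
    if (length(m$pattern) == 1L) {
      cid <- m$pattern
      nodes[[cid]]$classes <- m$classes
      nodes[[cid]]$n_snvs <- m$n_snvs
    } else {
      internal[[length(internal) + 1L]] <- m
    }
  }
  if (length(internal) > 0L) {
    ord <- order(-lengths(lapply(internal, `[[`, "pattern")),
                 vapply(internal, function(m) pat_key(m$pattern), ""))
    internal <- internal[ord]
    for (i in seq_along(internal)) {
      m <- internal[[i]]
      id <- sprintf("n%02d", i)
      nodes[[id]] <- list(id = id, type = "internal", parent = NA_character_,
                          children = character(0), pattern = m$pattern,
                          classes = m$classes, n_snvs = m$n_snvs)
    }
  }
  nodes[["root"]] <- list(id = "root", type = "root", parent = NA_character_,
                          children = character(0),
                          pattern = comps$component_id,
                          classes = character(0), n_snvs = 0L)
  # parent = smallest strict superset (unique under laminarity)
  ids <- setdiff(names(nodes), "root")
  for (id in ids) {
    p <- nodes[[id]]$pattern
    best <- "root"
    best_size <- length(comps$component_id) + 1L
    for (other in ids) {
      if (other == id) next
      q <- nodes[[other]]$pattern
      if (length(q) > length(p) && all(p %in% q) && length(q) < best_size) {
        best <- other
        best_size <- length(q)
      }
    }
    nodes[[id]]$parent <- best
    nodes[[best]]$children <- c(nodes[[best]]$children, id)
  }
  for (id in names(nodes)) {
    kids <- nodes[[id]]$children
    if (length(kids) > 1L) {
      nodes[[id]]$children <- kids[order(-lengths(lapply(kids, function(k)
        nodes[[k]]$pattern)), kids)]
    }
  }
  jp <- cls[vapply(cls, `[[`, TRUE, "joint_private")]
  joint_private <- list()
  for (cl in jp) {
    s <- cl$pattern
    if (is.null(joint_private[[s]])) {
      joint_private[[s]] <- list(sample_id = s, classes = character(0),
                                 n_snvs = 0L)
    }
    joint_private[[s]]$classes <- c(joint_private[[s]]$classes,
                                    cl$class_id %||% "")
    joint_private[[s]]$n_snvs <- joint_private[[s]]$n_snvs + length(cl$members)
  }
  tree <- structure(list(nodes = nodes, root = "root", components = comps,
                         joint_private = joint_private, samples = samples,
                         resolution = resolution),
                    class = "lineage_tree")
  # conservation: every member SNV of every admitted class is counted once
  total <- sum(vapply(nodes, `[[`, 0L, "n_snvs")) +
    sum(vapply(joint_private, `[[`, 0L, "n_snvs"))
  stopifnot(total == sum(lengths(lapply(cls, `[[`, "members"))))
  tree
}

#' Clades of a lineage tree
#'
#' @param tree A `lineage_tree`.
#' @return Named list mapping each non-root node id to its set of descendant
#'   leaf components.
#' @export
tree_clades <- function(tree) {
  ids <- setdiff(names(tree$nodes), "root")
  stats::setNames(lapply(ids, function(id) tree$nodes[[id]]$pattern), ids)
}

#' Branch patterns of a lineage tree
#'
#' @param tree A `lineage_tree`.
#' @return List of component-id patterns for every branch carrying at least
#'   one SNV class, in canonical (sorted-key) order.
#' @export
tree_patterns <- function(tree) {
  pats <- lapply(tree$nodes, function(nd)
    if (nd$n_snvs > 0L) sort(nd$pattern) else NULL)
  pats <- pats[!vapply(pats, is.null, TRUE)]
  pats[order(vapply(pats, pat_key, ""))]
}

#' Branch-by-class SNV count table
#'
#' @param tree A `lineage_tree`.
#' @return Data frame with one row per (branch, class): `node_id`, `pattern`,
#'   `class_id`, `n_snvs`; joint private pools of split samples appear with
#'   `node_id = "joint:<sample>"`.
#' @export
branch_table <- function(tree) {
  rows <- list()
  cls <- tree$resolution$classes
  nmem <- stats::setNames(lengths(lapply(cls, `[[`, "members")),
                          vapply(cls, function(cl) cl$class_id %||% "", ""))
  for (nd in tree$nodes) {
    for (cid in nd$classes) {
      rows[[length(rows) + 1L]] <- data.frame(
        node_id = nd$id, pattern = paste(sort(nd$pattern), collapse = ","),
        class_id = cid, n_snvs = unname(nmem[cid]))
    }
  }
  for (jp in tree$joint_private) {
    for (cid in jp$classes) {
      rows[[length(rows) + 1L]] <- data.frame(
        node_id = paste0("joint:", jp$sample_id), pattern = jp$sample_id,
        class_id = cid, n_snvs = unname(nmem[cid]))
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(node_id = character(0), pattern = character(0),
                      class_id = character(0), n_snvs = integer(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.lineage_tree <- function(x, ...) {
  n_int <- sum(vapply(x$nodes, function(nd) nd$type == "internal", TRUE))
  n_split <- length(x$resolution$splits)
  cat(sprintf("<lineage_tree> %d leaf component(s), %d internal node(s), %d split sample(s)\n",
              nrow(x$components), n_int, n_split))
  cat(format_newick(x), "\n")
  invisible(x)
}

#' VAF-sum check for split samples
#'
#' For a genuinely mixed-lineage sample, the mean VAF of each component's
#' lineage-specific classes should sum to the mean VAF of the ancestral
#' classes carried by all cells of the sample. Mixing proportions are
#' estimated as each component's mean VAF divided by the ancestral mean
#' (reported normalized to sum to one). Private classes of the split sample
#' are excluded: they cannot be attributed to a component by pattern.
#'
#' @param tree A `lineage_tree`.
#' @param matrix The [vaf_matrix].
#' @param tolerance Pass threshold for `|ancestral - (a + b)|` (default 0.10).
#' @return Data frame with one row per split sample: component means, the
#'   discrepancy `delta`, `pass`, `skipped` (no ancestral class), and the
#'   normalized proportions `prop_1`, `prop_2`.
#' @export
vaf_sum_check <- function(tree, matrix, tolerance = 0.10) {
  res <- tree$resolution
  out <- list()
  for (sp in res$splits) {
    s <- sp$sample_id
    a <- sp$components[1L]
    b <- sp$components[2L]
    cls <- res$classes
    mean_of <- function(pick) {
      members <- unlist(lapply(cls[pick], `[[`, "members"))
      if (length(members) == 0L) return(NA_real_)
      mean(matrix$values[members, s], na.rm = TRUE)
    }
    has <- function(cl, x) x %in% cl$components
    anc <- vapply(cls, function(cl) !cl$joint_private && has(cl, a) && has(cl, b), TRUE)
    ca <- vapply(cls, function(cl) !cl$joint_private && has(cl, a) && !has(cl, b), TRUE)
    cb <- vapply(cls, function(cl) !cl$joint_private && !has(cl, a) && has(cl, b), TRUE)
    m_anc <- mean_of(anc)
    m_a <- mean_of(ca)
    m_b <- mean_of(cb)
    skipped <- is.na(m_anc)
    delta <- if (skipped) NA_real_ else abs(m_anc - sum(c(m_a, m_b), na.rm = TRUE))
    prop <- if (skipped || is.na(m_a) || is.na(m_b) || (m_a + m_b) == 0) {
      c(NA_real_, NA_real_)
    } else {
      c(m_a, m_b) / (m_a + m_b)
    }
    out[[length(out) + 1L]] <- data.frame(
      sample_id = s, component_1 = a, component_2 = b,
      mean_ancestral = m_anc, mean_1 = m_a, mean_2 = m_b,
      delta = delta, pass = !skipped && delta <= tolerance,
      skipped = skipped, prop_1 = prop[1L], prop_2 = prop[2L])
  }
  if (length(out) == 0L) {
    return(data.frame(sample_id = character(0), component_1 = character(0),
                      component_2 = character(0), mean_ancestral = numeric(0),
                      mean_1 = numeric(0), mean_2 = numeric(0),
                      delta = numeric(0), pass = logical(0),
                      skipped = logical(0), prop_1 = numeric(0),
                      prop_2 = numeric(0)))
  }
  res_df <- do.call(rbind, out)
  rownames(res_df) <- NULL
  res_df
}

#' Annotate a tree with estimated mixing proportions
#'
#' @param tree A `lineage_tree`.
#' @param check Output of [vaf_sum_check()].
#' @return The tree with component (and leaf) proportions replaced by the
#'   normalized VAF-ratio estimates where available.
#' @export
apply_mixing_proportions <- function(tree, check) {
  for (i in seq_len(nrow(check))) {
    if (is.na(check$prop_1[i])) next
    pr <- c(check$prop_1[i], check$prop_2[i])
    cids <- c(check$component_1[i], check$component_2[i])
    for (k in 1:2) {
      tree$components$proportion[tree$components$component_id == cids[k]] <- pr[k]
      tree$nodes[[cids[k]]]$proportion <- pr[k]
    }
  }
  tree
}
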