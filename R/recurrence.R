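# Independent-origin inference for recurrent hotspot mutations on a fixed
# lineage tree. The tree is never rearranged to accommodate a hotspot
# pattern; hotspot assays are excluded from treebuilding and interpreted
# "given the tree topologies".

#' Minimum number of independent origins of a mutation
#'
#' Computes the minimum number of branches whose subtree leaf sets are
#' pairwise disjoint and whose union is exactly the positive component set,
#' by selecting maximal "pure" nodes (nodes all of whose descendant
#' components are positive). The result is a parsimony minimum: the reported
#' integer means "at least this many origins". The lower-bound flag is raised
#' when a selected node is a child of a multifurcation whose other children
#' also contain positives — branching order the data cannot resolve may hide
#' additional events.
#'
#' @param tree A `lineage_tree`.
#' @param positives Character vector of positive leaf component ids.
#' @param site Optional one-row site annotation carried through to the result.
#' @return Object of class `recurrent_mutation`: list with `site`,
#'   `positives`, `origin_nodes` (node ids), `origin_patterns` (their
#'   clades), `min_origins`, `lower_bound_flag`.
#' @export
min_origins <- function(tree, positives, site = NULL) {
  positives <- unique(as.character(positives))
  all_comps <- tree$components$component_id
  unknown <- setdiff(positives, all_comps)
  if (length(unknown) > 0L) {
    fail("min_origins: positive component(s) not in tree: %s",
         paste(unknown, collapse = ", "))
  }
  if (length(positives) == 0L) {
    return(structure(list(site = site, positives = character(0),
                          origin_nodes = character(0),
                          origin_patterns = list(), min_origins = 0L,
                          lower_bound_flag = FALSE),
                     class = "recurrent_mutation"))
  }
  pure <- vapply(tree$nodes, function(nd)
    all(nd$pattern %in% positives), TRUE)
  maximal <- vapply(names(tree$nodes), function(id) {
    if (!pure[[id]]) return(FALSE)
    par <- tree$nodes[[id]]$parent
    is.na(par) || !pure[[par]]
  }, TRUE)
  sel <- names(tree$nodes)[maximal]
  sel_pats <- lapply(sel, function(id) tree$nodes[[id]]$pattern)
  covered <- sort(unique(unlist(sel_pats)))
  stopifnot(identical(covered, sort(positives)))  # disjoint exact cover
  lb <- any(vapply(sel, function(id) {
    par <- tree$nodes[[id]]$parent
    if (is.na(par)) return(FALSE)
    sibs <- setdiff(tree$nodes[[par]]$children, id)
    length(tree$nodes[[par]]$children) >= 3L &&
      any(vapply(sibs, function(sb)
        any(tree$nodes[[sb]]$pattern %in% positives), TRUE))
  }, TRUE))
  structure(list(site = site, positives = sort(positives),
                 origin_nodes = sel, origin_patterns = sel_pats,
                 min_origins = length(sel), lower_bound_flag = lb),
            class = "recurrent_mutation")
}

#' @export
print.recurrent_mutation <- function(x, ...) {
  cat(sprintf("<recurrent_mutation> %d positive component(s), min origins %d%s\n",
              length(x$positives), x$min_origins,
              if (x$lower_bound_flag) " (+, lower bound)" else ""))
  invisible(x)
}

#' Attribute sample-level hotspot positives to leaf components
#'
#' Unsplit positive samples map to their single component. For a split
#' (mixed-lineage) sample positive for the hotspot, the hotspot VAF is
#' compared with the ancestral mean and with each component's share of it:
#' a VAF at the ancestral level means both components carry the mutation; a
#' VAF at one component's level restricts it to a single component. Only
#' candidate levels whose distance to the observed VAF is within `margin` of
#' the best match are retained — so a decisively matching level wins outright
#' — and when several remain indistinguishable (as between the components of
#' a near 50:50 mixture), the attribution among them is chosen by parsimony:
#' the candidate assignment minimizing the number of independent origins on
#' the fixed tree. The ambiguity flag is raised when the VAF matches no
#' candidate or several candidates tie at the parsimony minimum with
#' different component sets.
#'
#' @param tree A `lineage_tree`.
#' @param positive_samples Character vector of sample ids called positive.
#' @param hotspot_vafs Named per-sample VAFs of the hotspot change.
#' @param vaf_sums Output of [vaf_sum_check()] (component/ancestral means).
#' @param tolerance Consistency tolerance (default 0.10, the VAF-sum value).
#' @param margin Distance difference below which two candidate levels are
#'   indistinguishable (default 0.01, on the order of the binomial standard
#'   error of a deep-coverage VAF estimate).
#' @return List with `components` (positive component ids) and `ambiguous`.
#' @export
attribute_hotspot_components <- function(tree, positive_samples, hotspot_vafs,
                                         vaf_sums, tolerance = 0.10,
                                         margin = 0.01) {
  comps <- tree$components
  fixed <- character(0)
  choices <- list()   # per ambiguous split sample: list of candidate comp sets
  nearest <- list()   # index of the VAF-nearest candidate, for tie-breaking
  ambiguous <- FALSE
  for (s in positive_samples) {
    ids <- comps$component_id[comps$sample_id == s]
    if (length(ids) == 1L) {
      fixed <- c(fixed, ids)
      next
    }
    row <- vaf_sums[vaf_sums$sample_id == s, , drop = FALSE]
    v <- hotspot_vafs[[s]]
    if (nrow(row) == 0L || is.na(v) || row$skipped[1L]) {
      fixed <- c(fixed, ids)
      ambiguous <- TRUE
      next
    }
    cand <- list(list(row$component_1[1L]), list(row$component_2[1L]),
                 list(ids))
    targets <- c(row$mean_1[1L], row$mean_2[1L], row$mean_ancestral[1L])
    d <- abs(v - targets)
    ok <- which(!is.na(d) & d <= tolerance & d <= min(d, na.rm = TRUE) + margin)
    if (length(ok) == 0L) {
      fixed <- c(fixed, ids)
      ambiguous <- TRUE
    } else if (length(ok) == 1L) {
      fixed <- c(fixed, unlist(cand[[ok]]))
    } else {
      choices[[s]] <- lapply(ok, function(i) unlist(cand[[i]]))
      nearest[[s]] <- which.min(d[ok])
    }
  }
  if (length(choices) == 0L) {
    return(list(components = sort(unique(fixed)), ambiguous = ambiguous))
  }
  combos <- expand.grid(lapply(choices, function(ch) seq_along(ch)),
                        KEEP.OUT.ATTRS = FALSE)
  n_orig <- vapply(seq_len(nrow(combos)), function(r) {
    pick <- unlist(lapply(names(choices), function(s)
      choices[[s]][[combos[r, s]]]))
    min_origins(tree, unique(c(fixed, pick)))$min_origins
  }, 0L)
  best <- which(n_orig == min(n_orig))
  if (length(best) > 1L) {
    # prefer the VAF-nearest candidate in each sample; flag the unresolved tie
    pref <- vapply(best, function(r) sum(vapply(names(choices), function(s)
      combos[r, s] == nearest[[s]], TRUE)), 0L)
    sets <- lapply(best, function(r) sort(unique(c(fixed,
      unlist(lapply(names(choices), function(s) choices[[s]][[combos[r, s]]]))))))
    if (length(unique(vapply(sets, paste, "", collapse = ","))) > 1L) {
      ambiguous <- TRUE
    }
    best <- best[order(-pref, best)][1L]
  }
  pick <- unlist(lapply(names(choices), function(s)
    choices[[s]][[combos[best, s]]]))
  list(components = sort(unique(c(fixed, pick))), ambiguous = ambiguous)
}

#' Conflict cost of forcing a single origin
#'
#' Counts the robust phylogenetic classes whose sample-level patterns would
#' conflict with the hotspot pattern if the hotspot positives were forced to
#' form a single clade — the size of the evidence against a single origin.
#'
#' @param classes A `phylo_classes` object (robust classes are counted).
#' @param hotspot_pattern Character vector of positive sample ids.
#' @return Integer conflict count.
#' @export
test_single_origin_rearrangement <- function(classes, hotspot_pattern) {
  robust <- classes[class_status(classes) == "robust"]
  sum(vapply(robust, function(cl)
    pat_relation(cl$pattern, hotspot_pattern) == "conflict", TRUE))
}

#' Per-sample hotspot mutation report
#'
#' Emits, for each hotspot site and each non-reference nucleotide observed
#' there, the per-sample VAF over the four-nucleotide total, read depth and
#' presence call, so that two co-occurring changes at one position are
#' reported as independent rows. Normal and lymph-control samples with a
#' nonzero sub-threshold VAF are flagged as observations, not calls.
#'
#' @param matrix A [vaf_matrix] built from counts (so that all four
#'   nucleotides are available), via [vaf_from_counts()].
#' @param cutoff Presence cutoff (default 0.02).
#' @return Data frame with columns `snv_id`, `sample_id`, `alt`, `vaf`,
#'   `depth`, `call`, `subthreshold_in_control`; empty when no hotspot sites
#'   are configured.
#' @export
hotspot_report <- function(matrix, cutoff = 0.02) {
  sites <- matrix$sites
  counts <- matrix$counts
  empty <- data.frame(snv_id = character(0), sample_id = character(0),
                      alt = character(0), vaf = numeric(0),
                      depth = integer(0), call = logical(0),
                      subthreshold_in_control = logical(0))
  if (is.null(sites) || is.null(counts) || !any(sites$is_hotspot)) return(empty)
  ctrl <- character(0)
  if (!is.null(matrix$samples)) {
    ctrl <- matrix$samples$sample_id[
      matrix$samples$histology %in% c("normal", "lymph_control")]
  }
  rows <- list()
  for (hs in sites$snv_id[sites$is_hotspot]) {
    site <- sites[sites$snv_id == hs, , drop = FALSE]
    sub <- counts[counts$snv_id == hs, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      total <- sum(as.numeric(sub[i, NUCLEOTIDES]))
      for (alt in setdiff(NUCLEOTIDES, site$ref)) {
        v <- if (total == 0) NA_real_ else sub[[alt]][i] / total
        rows[[length(rows) + 1L]] <- data.frame(
          snv_id = hs, sample_id = sub$sample_id[i], alt = alt,
          vaf = v, depth = as.integer(total),
          call = !is.na(v) && v >= cutoff,
          subthreshold_in_control = sub$sample_id[i] %in% ctrl &&
            !is.na(v) && v > 0 && v < cutoff)
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
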