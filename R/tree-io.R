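# Annotated-Newick serialization of lineage trees.
#
# Standard Newick has no field for per-branch SNV-class counts or for the
# mixing proportions of duplicated samples, so these travel in structured
# comment blocks of key=value pairs, e.g.
#   (S01[&sample=S01,prop=1,n=3,classes=c002], ...)[&n=6,classes=c001];
# Comments follow the node label; the topology remains plain Newick, so any
# standard reader can recover the tree shape by ignoring comments.

fmt_num <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)

node_annotation <- function(nd) {
  kv <- character(0)
  if (nd$type == "leaf") {
    kv <- c(kv, sprintf("sample=%s", nd$sample),
            sprintf("prop=%s", fmt_num(nd$proportion)))
  }
  kv <- c(kv, sprintf("n=%d", nd$n_snvs))
  if (length(nd$classes) > 0L) {
    kv <- c(kv, sprintf("classes=%s", paste(sort(nd$classes), collapse = "|")))
  }
  sprintf("[&%s]", paste(kv, collapse = ","))
}

#' Format a lineage tree as annotated Newick
#'
#' @param tree A `lineage_tree`.
#' @return A single Newick string.
#' @export
format_newick <- function(tree) {
  rec <- function(id) {
    nd <- tree$nodes[[id]]
    inner <- if (length(nd$children) > 0L) {
      paste0("(", paste(vapply(nd$children, rec, ""), collapse = ","), ")")
    } else ""
    label <- if (nd$type == "leaf") nd$id else ""
    paste0(inner, label, node_annotation(nd))
  }
  root <- tree$nodes[[tree$root]]
  inner <- paste0("(", paste(vapply(root$children, rec, ""), collapse = ","), ")")
  kv <- "n=0"
  for (jp in tree$joint_private) {
    kv <- c(kv, sprintf("jp=%s:%s:%d", jp$sample_id,
                        paste(sort(jp$classes), collapse = "+"), jp$n_snvs))
  }
  paste0(inner, sprintf("[&%s]", paste(kv, collapse = ",")), ";")
}

#' Write a lineage tree to an annotated Newick file
#'
#' @param tree A `lineage_tree`.
#' @param path Output path.
#' @export
write_tree <- function(tree, path) {
  con <- tryCatch(file(path, "w"), error = function(e)
    fail("write_tree: cannot open %s for writing", path))
  on.exit(close(con))
  writeLines(format_newick(tree), con)
  invisible(NULL)
}

parse_annotation <- function(s) {
  if (is.null(s) || s == "") return(list())
  body <- sub("^\\[&", "", sub("\\]$", "", s))
  parts <- strsplit(body, ",", fixed = TRUE)[[1]]
  out <- list()
  for (p in parts) {
    eq <- regexpr("=", p, fixed = TRUE)
    if (eq < 0L) fail("malformed annotation entry: %s", p)
    k <- substr(p, 1L, eq - 1L)
    v <- substr(p, eq + 1L, nchar(p))
    if (k == "jp") out$jp <- c(out$jp, v) else out[[k]] <- v
  }
  out
}

#' Read a lineage tree from an annotated Newick file
#'
#' Inverse of [write_tree()]: recovers topology, per-branch class lists and
#' SNV counts, leaf components with sample ids and mixing proportions, and
#' joint private pools. The round trip is lossless up to the `resolution`
#' element (SNV-level class membership is not serialized in the tree file).
#'
#' @param path Path to an annotated Newick file.
#' @return A `lineage_tree` (with `resolution = NULL`).
#' @export
read_tree <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  txt <- gsub("[[:space:]]", "", txt)
  pos <- 1L
  n_chr <- nchar(txt)
  peek <- function() if (pos > n_chr) "" else substr(txt, pos, pos)
  take_annotation <- function() {
    if (peek() != "[") return("")
    end <- regexpr("]", substr(txt, pos, n_chr), fixed = TRUE)
    if (end < 0L) fail("read_tree: unterminated annotation")
    out <- substr(txt, pos, pos + end - 1L)
    pos <<- pos + end
    out
  }
  take_label <- function() {
    m <- regexpr("^[^(),;\\[\\]]+", substr(txt, pos, n_chr), perl = TRUE)
    if (m < 0L) return("")
    len <- attr(m, "match.length")
    out <- substr(txt, pos, pos + len - 1L)
    pos <<- pos + len
    out
  }
  parse_node <- function() {
    children <- list()
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        children[[length(children) + 1L]] <- parse_node()
        ch <- peek()
        if (ch == ",") { pos <<- pos + 1L; next }
        if (ch == ")") { pos <<- pos + 1L; break }
        fail("read_tree: malformed Newick near position %d", pos)
      }
    }
    label <- take_label()
    ann <- parse_annotation(take_annotation())
    list(label = label, ann = ann, children = children)
  }
  parsed <- parse_node()
  if (peek() != ";") fail("read_tree: expected terminating ';'")

  nodes <- list()
  comps <- list()
  n_internal <- 0L
  build <- function(pn, parent_id) {
    ann <- pn$ann
    if (length(pn$children) == 0L) {
      id <- pn$label
      prop <- as.numeric(ann$prop %||% "1")
      nodes[[id]] <<- list(id = id, type = "leaf", parent = parent_id,
                           children = character(0), pattern = id,
                           classes = if (is.null(ann$classes)) character(0)
                                     else strsplit(ann$classes, "|", fixed = TRUE)[[1]],
                           n_snvs = as.integer(ann$n %||% "0"),
                           sample = ann$sample %||% id, proportion = prop)
      comps[[length(comps) + 1L]] <<- data.frame(
        component_id = id, sample_id = ann$sample %||% id, proportion = prop)
      return(id)
    }
    n_internal <<- n_internal + 1L
    id <- sprintf("tmp%04d", n_internal)
    kid_ids <- vapply(pn$children, build, "", parent_id = id)
    pat <- sort(unique(unlist(lapply(kid_ids, function(k) nodes[[k]]$pattern))))
    nodes[[id]] <<- list(id = id, type = "internal", parent = parent_id,
                         children = kid_ids, pattern = pat,
                         classes = if (is.null(ann$classes)) character(0)
                                   else strsplit(ann$classes, "|", fixed = TRUE)[[1]],
                         n_snvs = as.integer(ann$n %||% "0"))
    id
  }
  root_tmp <- build(parsed, NA_character_)
  nodes[[root_tmp]]$type <- "root"
  # rename: root plus internal nodes in canonical (size, key) order
  internal_ids <- names(nodes)[vapply(nodes, function(nd) nd$type == "internal", TRUE)]
  ord <- order(-lengths(lapply(internal_ids, function(i) nodes[[i]]$pattern)),
               vapply(internal_ids, function(i) pat_key(nodes[[i]]$pattern), ""))
  rename <- stats::setNames(sprintf("n%02d", seq_along(internal_ids)),
                            internal_ids[ord])
  rename[root_tmp] <- "root"
  out_nodes <- list()
  for (id in names(nodes)) {
    nd <- nodes[[id]]
    new_id <- if (id %in% names(rename)) unname(rename[id]) else id
    nd$id <- new_id
    if (!is.na(nd$parent) && nd$parent %in% names(rename)) {
      nd$parent <- unname(rename[nd$parent])
    }
    nd$children <- vapply(nd$children, function(k)
      if (k %in% names(rename)) unname(rename[k]) else k, "")
    out_nodes[[new_id]] <- nd
  }
  joint_private <- list()
  for (v in parsed$ann$jp %||% character(0)) {
    bits <- strsplit(v, ":", fixed = TRUE)[[1]]
    joint_private[[bits[1L]]] <- list(
      sample_id = bits[1L],
      classes = strsplit(bits[2L], "+", fixed = TRUE)[[1]],
      n_snvs = as.integer(bits[3L]))
  }
  comp_df <- do.call(rbind, comps)
  comp_df <- comp_df[order(comp_df$component_id), , drop = FALSE]
  rownames(comp_df) <- NULL
  structure(list(nodes = out_nodes, root = "root", components = comp_df,
                 joint_private = joint_private, samples = NULL,
                 resolution = NULL),
            class = "lineage_tree")
}

#' Structural equality of two lineage trees
#'
#' Compares the canonical branch summaries (pattern, SNV count, class list of
#' every node), the leaf components with their sample assignment and mixing
#' proportions, and the joint private pools.
#'
#' @param a,b `lineage_tree` objects.
#' @param tol Numeric tolerance on proportions.
#' @return `TRUE` or `FALSE`.
#' @export
tree_equal <- function(a, b, tol = 1e-9) {
  summ <- function(t) {
    rows <- vapply(t$nodes, function(nd) {
      paste(pat_key(nd$pattern), nd$n_snvs,
            paste(sort(nd$classes), collapse = "|"), sep = "#")
    }, "")
    sort(unname(rows))
  }
  if (!identical(summ(a), summ(b))) return(FALSE)
  ca <- a$components[order(a$components$component_id), ]
  cb <- b$components[order(b$components$component_id), ]
  if (!identical(ca$component_id, cb$component_id)) return(FALSE)
  if (!identical(ca$sample_id, cb$sample_id)) return(FALSE)
  if (any(abs(ca$proportion - cb$proportion) > tol)) return(FALSE)
  jp <- function(t) {
    vapply(t$joint_private, function(j)
      paste(j$sample_id, paste(sort(j$classes), collapse = "+"), j$n_snvs,
            sep = "#"), "")
  }
  identical(sort(unname(jp(a))), sort(unname(jp(b))))
}
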