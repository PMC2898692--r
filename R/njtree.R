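#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou–Nei agglomeration with the Q-criterion. Deterministic:
#' ties in Q are broken by the lowest index pair (input order; merged
#' clusters are appended after the original taxa). Negative estimated branch
#' lengths are clamped to zero with the deficit transferred to the sister
#' branch, preserving the joined pair's distance. The final three clusters
#' are joined at one degree-3 node by the closed form
#' \eqn{b_A = (d_{AB} + d_{AC} - d_{BC})/2}, so the result is an unrooted
#' tree (basal trifurcation for n > 3).
#'
#' @param dm Labeled symmetric numeric matrix with zero diagonal,
#'   \eqn{n \ge 3}, non-negative entries.
#' @return An unrooted `ape::phylo` tree with branch lengths.
#' @examples
#' dm <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
#'              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' ape::write.tree(nj_tree(dm))
#' @export
nj_tree <- function(dm) {
  validate_distance_matrix(dm)
  labels <- rownames(dm)
  d <- unname(dm)
  frag <- labels  # Newick fragment per active cluster
  while (nrow(d) > 3) {
    m <- nrow(d)
    r <- rowSums(d)
    # lowest-index pair with strictly minimal Q
    best <- c(NA_integer_, NA_integer_); best_q <- Inf
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        qij <- (m - 2) * d[i, j] - r[i] - r[j]
        if (qij < best_q - 1e-12) {
          best_q <- qij
          best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    cl <- clamp_pair(li, lj)
    new_frag <- paste0("(", frag[i], ":", fmt_bl(cl[1]), ",",
                       frag[j], ":", fmt_bl(cl[2]), ")")
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]), c(du[keep], 0))
    frag <- c(frag[keep], new_frag)
  }
  # closed-form trifurcation for the last three clusters
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  newick <- paste0("(", frag[1], ":", fmt_bl(max(0, la)), ",",
                   frag[2], ":", fmt_bl(max(0, lb)), ",",
                   frag[3], ":", fmt_bl(max(0, lc)), ");")
  ape::read.tree(text = newick)
}

# clamp negative branch to zero, moving the deficit to the sister branch so
# the pairwise distance through the new node is preserved
clamp_pair <- function(li, lj) {
  if (li < 0) { lj <- lj + li; li <- 0 }
  if (lj < 0) { li <- li + lj; lj <- 0 }
  c(max(0, li), max(0, lj))
}

fmt_bl <- function(x) sprintf("%.15g", x)

validate_distance_matrix <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm) || nrow(dm) < 3) {
    abort_dl("Distance matrix must be square with at least 3 taxa.",
             "invalid_parameter")
  }
  if (is.null(rownames(dm))) {
    abort_dl("Distance matrix must carry taxon labels.", "invalid_parameter")
  }
  if (any(dm < 0)) {
    abort_dl("Distance matrix has negative entries.", "invalid_parameter")
  }
  if (max(abs(dm - t(dm))) > 1e-8 || any(abs(diag(dm)) > 1e-12)) {
    abort_dl("Distance matrix must be symmetric with a zero diagonal.",
             "invalid_parameter")
  }
  invisible(dm)
}

#' Newick serialisation
#'
#' Thin wrappers over ape's Newick reader/writer with structural validation.
#' Per-edge supports travel as internal node labels.
#'
#' @param tree An `ape::phylo` tree.
#' @param path Optional output file; when `NULL` the Newick string is
#'   returned.
#' @return `to_newick()`: the Newick string (invisibly when writing).
#'   `parse_newick()`: an `ape::phylo`.
#' @export
to_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  text <- ape::write.tree(tree)
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(text))
  }
  text
}

#' @rdname to_newick
#' @param input A Newick string or a file path.
#' @export
parse_newick <- function(input) {
  text <- if (length(input) == 1 && !grepl("[(;]", input) && file.exists(input)) {
    paste(readLines(input), collapse = "")
  } else {
    paste(input, collapse = "")
  }
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) {
    abort_dl("Malformed Newick: unbalanced parentheses.", "malformed_file")
  }
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo")) {
    abort_dl("Malformed Newick string.", "malformed_file")
  }
  if (anyDuplicated(tree$tip.label)) {
    abort_dl("Malformed Newick: duplicate leaf names.", "malformed_file")
  }
  tree
}

# Non-trivial bipartitions (splits) of an unrooted tree, as canonical keys.
# Each internal edge separates the leaves into two blocks; the key is the
# sorted block NOT containing the alphabetically first leaf, joined by "|".
tree_splits <- function(tree) {
  tips <- tree$tip.label
  n <- length(tips)
  anchor <- sort(tips)[1]
  parts <- ape::prop.part(tree)
  nodes <- (n + 1L):(n + tree$Nnode)
  keys <- character(0); key_nodes <- integer(0)
  for (idx in seq_along(parts)) {
    members <- tips[parts[[idx]]]
    size <- length(members)
    if (size < 2 || size > n - 2) next
    if (anchor %in% members) members <- setdiff(tips, members)
    keys <- c(keys, paste(sort(members), collapse = "|"))
    key_nodes <- c(key_nodes, nodes[idx])
  }
  dup <- duplicated(keys)  # root child can duplicate a split in rooted trees
  list(keys = keys[!dup], nodes = key_nodes[!dup])
}

#' Bipartitions of a tree
#'
#' Non-trivial splits induced by the internal edges, as canonical
#' `"|"`-joined label strings (the block not containing the alphabetically
#' first leaf).
#'
#' @param tree An `ape::phylo`.
#' @return Character vector of split keys.
#' @export
bipartitions <- function(tree) tree_splits(tree)$keys

#' Robinson-Foulds distance
#'
#' Number of non-trivial bipartitions present in exactly one of the two
#' trees (the symmetric difference), an even non-negative integer for binary
#' trees.
#'
#' @param t1,t2 `ape::phylo` trees over the same leaf set.
#' @return Non-negative integer.
#' @export
robinson_foulds <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label) ||
      length(t1$tip.label) != length(t2$tip.label)) {
    abort_dl("Trees have different leaf sets.", "leafset_mismatch")
  }
  b1 <- bipartitions(t1)
  b2 <- bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}
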