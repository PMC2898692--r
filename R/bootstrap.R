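#' Genome-by-K-mer vector table
#'
#' The bootstrap unit: a table with one row per genome's composition vector
#' and one column per K-mer. Only the union of the stored supports is held
#' explicitly; the remaining columns of the full \eqn{N = |\Sigma|^K} space
#' are identically zero in every row and are tracked by a single aggregate
#' weight. Column resample weights start at 1 (and \eqn{N - u} for the
#' implicit all-zero block).
#'
#' @param vectors List of `composition_vector`s sharing `k` and alphabet.
#' @return A `vector_table`: list with `values` (taxa x union-K-mer matrix),
#'   `weights` (per-column multiplicities), `zero_weight` (aggregate
#'   multiplicity of the all-zero columns), `n_total`, `k`, `alphabet`.
#' @export
vector_table <- function(vectors) {
  stopifnot(is.list(vectors), length(vectors) >= 1,
            all(vapply(vectors, inherits, logical(1), "composition_vector")))
  k <- vectors[[1]]$k
  alph <- vectors[[1]]$alphabet$name
  ok <- vapply(vectors, function(v) v$k == k && v$alphabet$name == alph, logical(1))
  if (!all(ok)) {
    abort_dl("All vectors must share the same k and alphabet.", "invalid_parameter")
  }
  taxa <- vapply(vectors, `[[`, character(1), "taxon_id")
  if (anyDuplicated(taxa)) {
    abort_dl("Duplicate taxon ids in vector table.", "duplicate_taxa")
  }
  cols <- sort(unique(unlist(lapply(vectors, function(v) names(v$x)),
                             use.names = FALSE)))
  mat <- matrix(0, nrow = length(vectors), ncol = length(cols),
                dimnames = list(taxa, cols))
  for (i in seq_along(vectors)) {
    mat[i, names(vectors[[i]]$x)] <- vectors[[i]]$x
  }
  n_total <- vectors[[1]]$n_total
  structure(
    list(values = mat, weights = rep(1, length(cols)),
         zero_weight = n_total - length(cols),
         n_total = n_total, k = k, alphabet = vectors[[1]]$alphabet),
    class = "vector_table"
  )
}

#' Resample K-mer columns of a vector table
#'
#' The modified bootstrap draw: N columns are drawn with replacement from the
#' full N-column space, recorded as integer multiplicities. This is done
#' exactly in two parts: the number of draws landing in the all-zero
#' complement (columns stored in no genome) is Binomial over its mass
#' \eqn{(N-u)/N}, and the remaining draws are multinomial over the \eqn{u}
#' observed columns. Distances computed from the resampled table weight each
#' column by its multiplicity; all-zero draws still count in the means and
#' variances.
#'
#' @param table A [vector_table()].
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (so successive replicate draws inside [bootstrap_supports()] stay
#'   reproducible from one top-level seed).
#' @param variant `"same_width"` draws N columns with replacement (the
#'   primary scheme); `"distinct"` keeps each drawn column at most once,
#'   giving a narrower table with every kept K-mer at its original value.
#' @return A `vector_table` with updated `weights` and `zero_weight`.
#' @export
resample_columns <- function(table, seed = NULL,
                             variant = c("same_width", "distinct")) {
  stopifnot(inherits(table, "vector_table"))
  variant <- match.arg(variant)
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
      abort_dl("`seed` must be a single integer.", "invalid_parameter")
    }
    set.seed(as.integer(seed))
  }
  u <- ncol(table$values)
  if (u == 0) abort_dl("Empty vector table.", "invalid_parameter")
  N <- table$n_total
  # draws landing among the u observed columns; the rest hit all-zero columns
  n_obs <- stats::rbinom(1, N, u / N)
  w <- as.numeric(stats::rmultinom(1, n_obs, rep(1, u)))
  zero_w <- N - n_obs
  if (variant == "distinct") {
    w <- as.numeric(w > 0)
    # the all-zero columns are interchangeable, so only how many distinct ones
    # were hit matters; expected occupancy of zero_w draws over N - u cells
    n_zero_cells <- N - u
    zero_w <- if (n_zero_cells > 0) {
      round(n_zero_cells * (1 - (1 - 1 / n_zero_cells)^zero_w))
    } else {
      0
    }
  }
  table$weights <- w
  table$zero_weight <- zero_w
  table
}

#' @export
print.vector_table <- function(x, ...) {
  cat("<vector_table> ", nrow(x$values), " taxa x ", ncol(x$values),
      " stored K-mer columns (of ", format(x$n_total, scientific = FALSE),
      "), k = ", x$k, "\n", sep = "")
  invisible(x)
}

# Pairwise distance matrix from a (possibly resampled) vector table.
# Column weights enter every moment sum; the all-zero block contributes only
# to the total weight. With unit weights this reproduces the sparse
# pair algebra of distance_matrix() exactly.
table_distance_matrix <- function(table, method = c("correlation", "chord"),
                                  type = c("pearson", "cosine")) {
  method <- match.arg(method)
  type <- match.arg(type)
  v <- table$values
  w <- table$weights
  N <- sum(w) + table$zero_weight
  taxa <- rownames(v)
  n <- nrow(v)
  wv <- sweep(v, 2, w, `*`)
  sx <- rowSums(wv)
  gram <- wv %*% t(v)  # gram[i, j] = sum_c w_c v_ic v_jc
  dm <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (method == "correlation" && type == "pearson") {
        vx <- gram[i, i] - sx[i]^2 / N
        vy <- gram[j, j] - sx[j]^2 / N
        if (vx <= 0 || vy <= 0) {
          abort_dl(sprintf("Correlation undefined for pair (%s, %s): zero variance.",
                           taxa[i], taxa[j]),
                   "undefined_correlation")
        }
        r <- (gram[i, j] - sx[i] * sx[j] / N) / sqrt(vx * vy)
        d <- (1 - min(1, max(-1, r))) / 2
      } else {
        if (gram[i, i] <= 0 || gram[j, j] <= 0) {
          abort_dl(sprintf("Distance undefined for pair (%s, %s): zero norm.",
                           taxa[i], taxa[j]),
                   "undefined_distance")
        }
        cos_theta <- gram[i, j] / sqrt(gram[i, i] * gram[j, j])
        d <- if (method == "chord") {
          sqrt(max(0, 2 - 2 * cos_theta))
        } else {
          (1 - min(1, max(-1, cos_theta))) / 2
        }
      }
      dm[i, j] <- dm[j, i] <- d
    }
  }
  dm
}

#' Modified-bootstrap branch supports
#'
#' Builds the reference NJ tree from the unresampled genome-by-K-mer table,
#' then for each of `B` replicates resamples the K-mer columns
#' ([resample_columns()]), recomputes the weighted distance matrix and NJ
#' tree, and scores each internal edge of the reference tree by the
#' percentage of replicate trees containing its bipartition. A replicate
#' whose distance matrix is undefined is discarded with a warning; more than
#' 10\% discarded is an error.
#'
#' @param records List of [genome_record()]s, or precomputed
#'   `composition_vector`s.
#' @param k Word length (ignored for precomputed vectors).
#' @param method `"correlation"` or `"chord"`.
#' @param B Number of bootstrap replicates (default 100).
#' @param seed Integer seed; the whole run is reproducible from it.
#' @param type Correlation flavour.
#' @param variant Resampling variant, see [resample_columns()].
#' @param keep_trees Keep the replicate trees (for consensus building).
#' @return A `dl_support` object: list with `tree` (reference NJ tree with
#'   integer support node labels), `supports` (tibble: bipartition, count,
#'   support), `B`, `B_used`, `seed`, and optionally `trees`.
#' @export
bootstrap_supports <- function(records, k = NULL,
                               method = c("correlation", "chord"),
                               B = 100, seed = NULL,
                               type = c("pearson", "cosine"),
                               variant = c("same_width", "distinct"),
                               keep_trees = FALSE) {
  method <- match.arg(method)
  type <- match.arg(type)
  variant <- match.arg(variant)
  if (!is.numeric(B) || length(B) != 1 || B < 1 || B != floor(B)) {
    abort_dl("`B` must be a single integer >= 1.", "invalid_parameter")
  }
  vectors <- if (inherits(records[[1]], "composition_vector")) {
    records
  } else {
    lapply(records, dl_composition, k = k)
  }
  tab <- vector_table(vectors)
  ref_dm <- table_distance_matrix(tab, method, type)
  ref_tree <- nj_tree(ref_dm)
  ref <- tree_splits(ref_tree)
  counts <- integer(length(ref$keys))
  discarded <- 0L
  trees <- if (keep_trees) vector("list", B) else NULL
  if (!is.null(seed)) set.seed(as.integer(seed))
  for (b in seq_len(B)) {
    rep_tab <- resample_columns(tab, variant = variant)
    rep_tree <- tryCatch({
      nj_tree(table_distance_matrix(rep_tab, method, type))
    },
    dl_undefined_correlation = function(e) NULL,
    dl_undefined_distance = function(e) NULL)
    if (is.null(rep_tree)) {
      discarded <- discarded + 1L
      warning(sprintf("bootstrap replicate %d discarded: undefined distance", b),
              call. = FALSE)
      next
    }
    if (keep_trees) trees[[b]] <- rep_tree
    counts <- counts + (ref$keys %in% bipartitions(rep_tree))
  }
  if (discarded > 0.1 * B) {
    abort_dl(sprintf("%d of %d bootstrap replicates discarded (> 10%%).",
                     discarded, B),
             "bootstrap_failure")
  }
  B_used <- B - discarded
  support <- 100 * counts / B_used
  annotated <- ref_tree
  node_labels <- rep("", ref_tree$Nnode)
  node_labels[ref$nodes - length(ref_tree$tip.label)] <- as.character(round(support))
  annotated$node.label <- node_labels
  if (keep_trees) trees <- trees[!vapply(trees, is.null, logical(1))]
  structure(
    list(tree = annotated,
         supports = tibble::tibble(bipartition = ref$keys,
                                   count = as.integer(counts),
                                   support = support),
         B = as.integer(B), B_used = as.integer(B_used),
         discarded = discarded,
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
         method = method, k = tab$k, trees = trees),
    class = "dl_support"
  )
}

#' @export
print.dl_support <- function(x, ...) {
  cat("<dl_support> ", length(x$tree$tip.label), " taxa, k = ", x$k,
      ", method = ", x$method, ", B = ", x$B_used, "/", x$B, " replicates\n",
      sep = "")
  if (nrow(x$supports) > 0) {
    cat("  internal-edge supports: ",
        paste(format(round(x$supports$support, 1)), collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' Majority-rule consensus tree
#'
#' Topology containing the bipartitions present in more than half of the
#' input trees (compatible by construction), with each consensus edge
#' labeled by its percentage (one decimal).
#'
#' @param trees List of `ape::phylo` trees on a common leaf set.
#' @return An `ape::phylo` with percentage node labels.
#' @export
majority_rule_consensus <- function(trees) {
  stopifnot(is.list(trees), length(trees) >= 1)
  tips <- trees[[1]]$tip.label
  same <- vapply(trees, function(t) {
    setequal(t$tip.label, tips) && length(t$tip.label) == length(tips)
  }, logical(1))
  if (!all(same)) {
    abort_dl("Input trees have inconsistent leaf sets.", "leafset_mismatch")
  }
  cons <- if (length(trees) == 1) {
    trees[[1]]
  } else {
    ape::consensus(trees, p = 0.5)
  }
  split_counts <- table(unlist(lapply(trees, bipartitions), use.names = FALSE))
  cs <- tree_splits(cons)
  pct <- round(100 * as.numeric(split_counts[cs$keys]) / length(trees), 1)
  labels <- rep("", cons$Nnode)
  labels[cs$nodes - length(cons$tip.label)] <- as.character(pct)
  cons$node.label <- labels
  cons
}
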