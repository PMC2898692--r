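# Sparse moment sums for a pair of composition vectors over the full
# N = |alphabet|^K component space. Unstored components are exactly zero, so
# sums over stored entries plus analytic corrections give exact full-space
# moments.
cv_pair_sums <- function(x, y) {
  if (!identical(x$k, y$k) || !identical(x$alphabet$name, y$alphabet$name)) {
    abort_dl("Composition vectors must share word length and alphabet.",
             "invalid_parameter")
  }
  common <- intersect(names(x$x), names(y$x))
  list(
    N = x$n_total,
    sx = sum(x$x), sy = sum(y$x),
    sxx = sum(x$x^2), syy = sum(y$x^2),
    sxy = sum(x$x[common] * y$x[common])
  )
}

#' Sample correlation between two composition vectors
#'
#' Centered Pearson sample correlation treating the \eqn{N = |\Sigma|^K}
#' components of each vector as paired samples, computed sparsely and
#' exactly: means are (sum of stored entries)/N, and cross/self products run
#' over the union of stored keys with the analytic \eqn{-N \bar x \bar y}
#' correction for the implicit zeros.
#'
#' @param x,y `composition_vector` objects at the same `k` and alphabet.
#' @param type `"pearson"` (centered; the default) or `"cosine"`
#'   (uncentered), retained as an alternative reading of the sample
#'   correlation.
#' @return Correlation in \eqn{[-1, 1]}.
#' @export
cv_correlation <- function(x, y, type = c("pearson", "cosine")) {
  type <- match.arg(type)
  s <- cv_pair_sums(x, y)
  if (type == "pearson") {
    vx <- s$sxx - s$sx^2 / s$N
    vy <- s$syy - s$sy^2 / s$N
    if (vx <= 0 || vy <= 0 || vx < 1e-12 * s$sxx || vy < 1e-12 * s$syy) {
      abort_dl(sprintf("Correlation undefined: zero variance for '%s' or '%s'.",
                       x$taxon_id, y$taxon_id),
               "undefined_correlation")
    }
    r <- (s$sxy - s$sx * s$sy / s$N) / sqrt(vx * vy)
  } else {
    if (s$sxx <= 0 || s$syy <= 0) {
      abort_dl(sprintf("Cosine correlation undefined: zero norm for '%s' or '%s'.",
                       x$taxon_id, y$taxon_id),
               "undefined_correlation")
    }
    r <- s$sxy / sqrt(s$sxx * s$syy)
  }
  min(1, max(-1, r))
}

#' Correlation distance D = (1 - C)/2
#'
#' The dissimilarity used by the dynamical-language method. It is a
#' pseudo-distance: the triangle inequality is not guaranteed.
#'
#' @inheritParams cv_correlation
#' @return Distance in \eqn{[0, 1]}.
#' @export
correlation_distance <- function(x, y, type = c("pearson", "cosine")) {
  (1 - cv_correlation(x, y, type)) / 2
}

#' Chord distance between composition vectors
#'
#' Euclidean distance between the unit-normalised full vectors,
#' \eqn{\sqrt{2 - 2\cos\theta}} with \eqn{\cos\theta} the uncentered cosine
#' over all N components; a proper metric, used by the modified
#' dynamical-language variant.
#'
#' @inheritParams cv_correlation
#' @return Distance in \eqn{[0, 2]}.
#' @export
chord_distance <- function(x, y) {
  s <- cv_pair_sums(x, y)
  if (s$sxx <= 0 || s$syy <= 0) {
    abort_dl(sprintf("Chord distance undefined: zero norm for '%s' or '%s'.",
                     x$taxon_id, y$taxon_id),
             "undefined_distance")
  }
  cos_theta <- s$sxy / sqrt(s$sxx * s$syy)
  sqrt(max(0, 2 - 2 * cos_theta))
}

#' Pairwise dissimilarity matrix for a genome collection
#'
#' Builds composition vectors for every record and computes all pairwise
#' distances. Labels follow input order; the result is symmetric with a zero
#' diagonal.
#'
#' @param records List of [genome_record()]s (at least 3, unique taxon ids),
#'   or a list of precomputed `composition_vector`s.
#' @param k Word length (\eqn{\ge 2}); ignored when vectors are supplied.
#' @param method `"correlation"` or `"chord"`.
#' @param type Correlation flavour passed to [cv_correlation()].
#' @return A labeled symmetric numeric matrix with zero diagonal.
#' @examples
#' seqs <- c(A = "ACGTACGTACGTAAGT", B = "ACGTTTGTACGTAAGA", C = "GGGTACGCACTTAAGT")
#' recs <- Map(genome_record, names(seqs), seqs, MoreArgs = list(alphabet = "dna"))
#' distance_matrix(recs, k = 3, method = "chord")
#' @export
distance_matrix <- function(records, k = NULL,
                            method = c("correlation", "chord"),
                            type = c("pearson", "cosine")) {
  method <- match.arg(method)
  type <- match.arg(type)
  stopifnot(is.list(records), length(records) >= 3)
  if (inherits(records[[1]], "genome_record")) {
    vectors <- lapply(records, dl_composition, k = k)
  } else if (inherits(records[[1]], "composition_vector")) {
    vectors <- records
  } else {
    abort_dl("`records` must be genome_record or composition_vector objects.",
             "invalid_parameter")
  }
  labels <- vapply(vectors, `[[`, character(1), "taxon_id")
  if (anyDuplicated(labels)) {
    abort_dl(sprintf("Duplicate taxon ids: %s",
                     paste(unique(labels[duplicated(labels)]), collapse = ", ")),
             "duplicate_taxa")
  }
  # the union-table gram algebra computes all pairs in one pass; identical
  # moment sums to the pairwise sparse path
  tryCatch(
    table_distance_matrix(vector_table(vectors), method, type),
    dl_undefined_correlation = rethrow_pair,
    dl_undefined_distance = rethrow_pair
  )
}

rethrow_pair <- function(e) {
  abort_dl(conditionMessage(e), "undefined_pair")
}

#' Write / read a square PHYLIP distance matrix
#'
#' Square (full) PHYLIP format: a header line with the number of taxa, then
#' one row per taxon starting with its name. `strict_names = TRUE` pads or
#' truncates names to the classic 10-character field; the default keeps full
#' names separated by whitespace (the relaxed dialect most tools accept).
#'
#' @param dm Labeled symmetric matrix, e.g. from [distance_matrix()].
#' @param path Optional file path; when `NULL` the text is returned.
#' @param digits Decimal places printed (default 6, the dialect standard).
#' @param strict_names Pad/truncate names to 10 characters.
#' @return `write_phylip()`: the formatted text, invisibly when writing to a
#'   file. `read_phylip()`: the labeled matrix.
#' @export
write_phylip <- function(dm, path = NULL, digits = 6, strict_names = FALSE) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  labels <- rownames(dm)
  if (strict_names) {
    labels <- formatC(substr(labels, 1, 10), width = -10)
  }
  rows <- vapply(seq_len(nrow(dm)), function(i) {
    paste0(labels[i], "  ",
           paste(formatC(dm[i, ], format = "f", digits = digits), collapse = " "))
  }, character(1))
  text <- paste0(paste(c(sprintf("%5d", nrow(dm)), rows), collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(sub("\n$", "", text), path)
    return(invisible(text))
  }
  text
}

#' @rdname write_phylip
#' @param input A file path or the matrix text itself.
#' @export
read_phylip <- function(input) {
  lines <- if (length(input) == 1 && !grepl("\n", input) && file.exists(input)) {
    readLines(input)
  } else {
    strsplit(paste(input, collapse = "\n"), "\n")[[1]]
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1) abort_dl("Empty PHYLIP input.", "malformed_file")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1) {
    abort_dl("Malformed PHYLIP header: expected a taxon count.", "malformed_file")
  }
  body <- lines[-1]
  if (length(body) != n) {
    abort_dl(sprintf("Malformed PHYLIP body: header says %d taxa but found %d rows.",
                     n, length(body)),
             "malformed_file")
  }
  labels <- character(n)
  dm <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    tokens <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(tokens) != n + 1) {
      abort_dl(sprintf("Malformed PHYLIP row %d: expected a name and %d values.", i, n),
               "malformed_file")
    }
    labels[i] <- tokens[1]
    vals <- suppressWarnings(as.numeric(tokens[-1]))
    if (anyNA(vals)) {
      abort_dl(sprintf("Malformed PHYLIP row %d: non-numeric distance.", i),
               "malformed_file")
    }
    dm[i, ] <- vals
  }
  dimnames(dm) <- list(labels, labels)
  dm
}
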