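#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a frequency profile
#'
#' @param x A `freq_profile`.
#' @param ... Unused.
#' @return Tibble with columns `kmer`, `frequency`.
#' @export
tidy.freq_profile <- function(x, ...) {
  tibble::tibble(kmer = names(x$freqs), frequency = unname(x$freqs))
}

#' Tidy a composition vector
#'
#' @param x A `composition_vector`.
#' @param ... Unused.
#' @return Tibble with columns `kmer`, `x` (background-subtracted value).
#' @export
tidy.composition_vector <- function(x, ...) {
  tibble::tibble(kmer = names(x$x), x = unname(x$x))
}

#' Tidy a bootstrap support result
#'
#' @param x A `dl_support` from [bootstrap_supports()].
#' @param ... Unused.
#' @return Tibble with columns `bipartition`, `count`, `support`.
#' @export
tidy.dl_support <- function(x, ...) x$supports

#' One-row summary of a bootstrap run
#'
#' @param x A `dl_support`.
#' @param ... Unused.
#' @return Tibble with replicate accounting and support summaries.
#' @export
glance.dl_support <- function(x, ...) {
  tibble::tibble(
    n_taxa = length(x$tree$tip.label),
    k = x$k, method = x$method,
    B = x$B, B_used = x$B_used, discarded = x$discarded,
    min_support = if (nrow(x$supports)) min(x$supports$support) else NA_real_,
    mean_support = if (nrow(x$supports)) mean(x$supports$support) else NA_real_
  )
}

#' Long-format pairwise distances
#'
#' @param dm Labeled distance matrix from [distance_matrix()].
#' @return Tibble with one row per unordered taxon pair.
#' @export
tidy_distances <- function(dm) {
  stopifnot(is.matrix(dm))
  idx <- which(upper.tri(dm), arr.ind = TRUE)
  tibble::tibble(
    taxon_1 = rownames(dm)[idx[, 1]],
    taxon_2 = colnames(dm)[idx[, 2]],
    distance = dm[idx]
  )
}

#' Plot bootstrap supports per bipartition
#'
#' @param object A `dl_support`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dl_support <- function(object, ...) {
  df <- object$supports
  df$bipartition <- factor(df$bipartition, levels = df$bipartition)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bipartition, y = .data$support)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 95, linetype = "dashed") +
    ggplot2::coord_flip(ylim = c(0, 100)) +
    ggplot2::labs(x = NULL, y = "bootstrap support (%)",
                  title = sprintf("Modified K-mer bootstrap (B = %d, k = %d, %s)",
                                  object$B_used, object$k, object$method)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
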