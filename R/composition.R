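#' Count K-mers in a genome record
#'
#' Slides a window of length `k` one position at a time through every sequence
#' of the record and pools the counts. Windows containing any non-canonical
#' character (ambiguity codes, gaps) are excluded from both the counts and the
#' window denominator, so observed frequencies still sum to one. Sequences
#' shorter than `k` contribute zero windows.
#'
#' @param record A [genome_record()].
#' @param k Word length, integer \eqn{\ge 1}.
#' @return An object of class `kmer_counts`: list with `k`, `counts` (named
#'   integer vector, sparse, alphabetically sorted), `valid_windows`,
#'   `alphabet`, `taxon_id`.
#' @examples
#' r <- genome_record("toy", "MAMA", "protein")
#' count_kmers(r, 2)$counts
#' @export
count_kmers <- function(record, k) {
  stopifnot(inherits(record, "genome_record"))
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 1 || k != floor(k)) {
    abort_dl("`k` must be a single integer >= 1.", "invalid_parameter")
  }
  k <- as.integer(k)
  if (!any(nchar(record$sequences) >= k)) {
    abort_dl(sprintf("Record '%s' is too short for k = %d: no sequence has length >= k.",
                     record$taxon_id, k),
             "record_too_short")
  }
  syms <- record$alphabet$symbols
  kmers <- unlist(lapply(record$sequences, canonical_windows, k = k, syms = syms),
                  use.names = FALSE)
  if (length(kmers) == 0) {
    counts <- integer(0)
  } else {
    tab <- table(kmers)
    counts <- as.integer(tab)
    names(counts) <- names(tab)
  }
  structure(
    list(k = k, counts = counts, valid_windows = sum(counts),
         alphabet = record$alphabet, taxon_id = record$taxon_id),
    class = "kmer_counts"
  )
}

# All length-k windows of one sequence whose characters are all canonical.
canonical_windows <- function(seq, k, syms) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  n_win <- L - k + 1L
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- !(ch %in% syms)
  if (any(bad)) {
    cs <- c(0L, cumsum(bad))
    # number of bad characters inside window starting at i
    bad_in_win <- cs[(k + 1L):(L + 1L)] - cs[seq_len(n_win)]
    starts <- which(bad_in_win == 0L)
  } else {
    starts <- seq_len(n_win)
  }
  if (length(starts) == 0) return(character(0))
  substring(seq, starts, starts + k - 1L)
}

#' Observed K-mer frequency profile
#'
#' Normalises pooled K-mer counts by the pooled number of valid windows:
#' \eqn{p_i = n_i / \sum_j (L_j - K + 1)}. Because counts and windows were
#' pooled across the record's sequences in [count_kmers()], this is the
#' multi-gene aggregate frequency.
#'
#' @param counts A `kmer_counts` object with `valid_windows >= 1`.
#' @return A `freq_profile`: list with `k`, `freqs` (named numeric, entries in
#'   (0, 1], summing to one), `denominator`, `alphabet`, `taxon_id`.
#' @export
frequency_profile <- function(counts) {
  stopifnot(inherits(counts, "kmer_counts"))
  if (counts$valid_windows < 1) {
    abort_dl(sprintf("Record '%s' has no valid windows at k = %d (degenerate profile).",
                     counts$taxon_id, counts$k),
             "degenerate_profile")
  }
  structure(
    list(k = counts$k, freqs = counts$counts / counts$valid_windows,
         denominator = counts$valid_windows,
         alphabet = counts$alphabet, taxon_id = counts$taxon_id),
    class = "freq_profile"
  )
}

#' Dynamical-language expected K-mer frequencies
#'
#' Background model: a K-mer \eqn{s_1 \dots s_K} can be formed by appending
#' the letter \eqn{s_K} to the observed (K-1)-mer \eqn{s_1 \dots s_{K-1}}, or
#' by prepending \eqn{s_1} to \eqn{s_2 \dots s_K}. The expected frequency is
#' the average of the two constructions:
#' \deqn{q(s_1 \dots s_K) = \frac{p(s_1 \dots s_{K-1})\,p(s_K) + p(s_1)\,p(s_2 \dots s_K)}{2}.}
#' Only K-mers with \eqn{q > 0} are stored; all others are implicit zeros.
#'
#' @param p_km1 `freq_profile` at word length K-1.
#' @param p_1 `freq_profile` at word length 1 (single-letter frequencies),
#'   from the same record.
#' @return A `freq_profile` at word length K holding `q` over its support.
#' @export
expected_profile <- function(p_km1, p_1) {
  stopifnot(inherits(p_km1, "freq_profile"), inherits(p_1, "freq_profile"))
  if (p_1$k != 1L) {
    abort_dl("`p_1` must be a single-letter (k = 1) profile.", "invalid_parameter")
  }
  if (p_km1$k < 1L) {
    abort_dl("`p_km1` must have k >= 1.", "invalid_parameter")
  }
  if (!identical(p_km1$alphabet$name, p_1$alphabet$name)) {
    abort_dl("Profiles come from different alphabets.", "invalid_parameter")
  }
  a <- names(p_km1$freqs); pa <- unname(p_km1$freqs)
  l <- names(p_1$freqs);   pl <- unname(p_1$freqs)
  # prefix extension: (K-1)-mer then letter; suffix extension: letter then
  # (K-1)-mer. Keys are unique within each construction, so the two terms of
  # the average are merged with a single hash lookup.
  pref <- as.vector(outer(pa, pl))
  names(pref) <- as.vector(outer(a, l, paste0))
  suf <- as.vector(outer(pl, pa))
  names(suf) <- as.vector(outer(l, a, paste0))
  hit <- match(names(suf), names(pref))
  found <- !is.na(hit)
  pref[hit[found]] <- pref[hit[found]] + suf[found]
  qv <- c(pref, suf[!found]) / 2
  qv <- qv[qv > 0]
  qv <- qv[order(names(qv), method = "radix")]
  structure(
    list(k = p_km1$k + 1L, freqs = qv, denominator = NA_real_,
         alphabet = p_km1$alphabet, taxon_id = p_km1$taxon_id),
    class = "freq_profile"
  )
}

#' Composition vector X = p/q - 1
#'
#' Subtracts the dynamical-language background from the observed frequencies:
#' \eqn{X_i = p_i/q_i - 1} wherever \eqn{q_i > 0}, and \eqn{X_i = 0}
#' (implicit) wherever \eqn{q_i = 0} — a component the background assigns no
#' mass carries no signal. Every observed K-mer (p > 0) necessarily has
#' \eqn{q > 0}, since its prefix, suffix and terminal letters were observed.
#'
#' @param p_k Observed `freq_profile` at word length K.
#' @param q Expected profile from [expected_profile()] at the same K.
#' @return A `composition_vector`: list with `taxon_id`, `k`, `alphabet`,
#'   `n_total` (\eqn{|\Sigma|^K}, as a double), and `x`, the named numeric
#'   vector of X values over the support of q. Components not stored are
#'   exactly zero.
#' @export
composition_vector <- function(p_k, q) {
  stopifnot(inherits(p_k, "freq_profile"), inherits(q, "freq_profile"))
  if (p_k$k != q$k) {
    abort_dl("`p_k` and `q` must share the same word length.", "invalid_parameter")
  }
  missing_p <- setdiff(names(p_k$freqs), names(q$freqs))
  # impossible by construction when q came from the same record
  stopifnot("observed K-mer with zero expected frequency" = length(missing_p) == 0)
  p_on_q <- p_k$freqs[names(q$freqs)]
  p_on_q[is.na(p_on_q)] <- 0
  x <- unname(p_on_q) / unname(q$freqs) - 1
  names(x) <- names(q$freqs)
  structure(
    list(taxon_id = p_k$taxon_id, k = p_k$k, alphabet = p_k$alphabet,
         n_total = length(p_k$alphabet$symbols)^p_k$k, x = x),
    class = "composition_vector"
  )
}

#' Composition vector straight from a record
#'
#' Convenience wrapper: counts K-mers at lengths K, K-1 and 1 (each with its
#' own window denominator), builds the background, and returns X. Requires
#' `k >= 2`: at K = 1 the background equals the observed frequencies and X is
#' identically zero.
#'
#' @param record A [genome_record()].
#' @param k Word length, integer \eqn{\ge 2}.
#' @return A `composition_vector`.
#' @examples
#' r <- genome_record("toy", "MAMA", "protein")
#' dl_composition(r, 2)$x
#' @export
dl_composition <- function(record, k) {
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 2 || k != floor(k)) {
    abort_dl("`k` must be a single integer >= 2 for composition vectors.",
             "invalid_parameter")
  }
  p_k <- frequency_profile(count_kmers(record, k))
  p_km1 <- frequency_profile(count_kmers(record, k - 1))
  p_1 <- frequency_profile(count_kmers(record, 1))
  composition_vector(p_k, expected_profile(p_km1, p_1))
}

#' @export
print.kmer_counts <- function(x, ...) {
  cat("<kmer_counts> ", x$taxon_id, ": k = ", x$k, ", ", length(x$counts),
      " distinct K-mers, ", x$valid_windows, " valid windows\n", sep = "")
  invisible(x)
}

#' @export
print.freq_profile <- function(x, ...) {
  cat("<freq_profile> ", x$taxon_id, ": k = ", x$k, ", ", length(x$freqs),
      " entries, sum = ", format(sum(x$freqs)), "\n", sep = "")
  invisible(x)
}

#' @export
print.composition_vector <- function(x, ...) {
  cat("<composition_vector> ", x$taxon_id, ": k = ", x$k, ", ",
      length(x$x), " of ", format(x$n_total, scientific = FALSE),
      " components stored\n", sep = "")
  invisible(x)
}

#' Export a profile or composition vector as TSV
#'
#' Two columns, `kmer` and `value`, one row per stored (non-zero) component.
#'
#' @param x A `freq_profile` or `composition_vector`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(x, path) {
  v <- if (inherits(x, "composition_vector")) x$x else x$freqs
  df <- data.frame(kmer = names(v), value = unname(v), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
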