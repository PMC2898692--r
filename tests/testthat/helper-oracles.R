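# Independent oracles, deliberately naive: character-by-character window
# scans and dense full-component-space algebra. They never share code with
# the sparse implementation they check.

oracle_symbols <- function(alphabet) {
  switch(alphabet,
         dna = c("A", "C", "G", "T"),
         protein = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
}

# quadratic-time sliding-window count with ambiguity masking
naive_kmer_counts <- function(seqs, k, alphabet) {
  syms <- oracle_symbols(alphabet)
  counts <- list()
  windows <- 0L
  for (s in toupper(seqs)) {
    ch <- strsplit(s, "")[[1]]
    if (length(ch) < k) next
    for (i in seq_len(length(ch) - k + 1)) {
      w <- ch[i:(i + k - 1)]
      if (all(w %in% syms)) {
        key <- paste(w, collapse = "")
        counts[[key]] <- (counts[[key]] %||% 0L) + 1L
        windows <- windows + 1L
      }
    }
  }
  list(counts = unlist(counts[order(names(counts))]), valid_windows = windows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

all_kmers <- function(k, alphabet) {
  syms <- oracle_symbols(alphabet)
  out <- syms
  for (i in seq_len(k - 1)) {
    out <- as.vector(t(outer(out, syms, paste0)))
  }
  sort(out)
}

# dense observed frequencies over the full |alphabet|^k space
dense_freqs <- function(seqs, k, alphabet) {
  space <- all_kmers(k, alphabet)
  nk <- naive_kmer_counts(seqs, k, alphabet)
  p <- stats::setNames(rep(0, length(space)), space)
  p[names(nk$counts)] <- nk$counts / nk$valid_windows
  p
}

# dense DL background and composition vector, straight from the definitions
dense_dl_vector <- function(seqs, k, alphabet) {
  p_k <- dense_freqs(seqs, k, alphabet)
  p_km1 <- dense_freqs(seqs, k - 1, alphabet)
  p_1 <- dense_freqs(seqs, 1, alphabet)
  space <- names(p_k)
  q <- vapply(space, function(w) {
    pre <- substr(w, 1, k - 1); suf <- substr(w, 2, k)
    (p_km1[[pre]] * p_1[[substr(w, k, k)]] +
       p_1[[substr(w, 1, 1)]] * p_km1[[suf]]) / 2
  }, numeric(1))
  x <- ifelse(q > 0, p_k / q - 1, 0)
  list(p = p_k, q = q, x = stats::setNames(x, space))
}

dense_correlation_distance <- function(x_dense, y_dense) {
  (1 - stats::cor(x_dense, y_dense)) / 2
}

dense_chord_distance <- function(x_dense, y_dense) {
  sqrt(sum((x_dense / sqrt(sum(x_dense^2)) - y_dense / sqrt(sum(y_dense^2)))^2))
}

random_seq <- function(len, alphabet) {
  paste(sample(oracle_symbols(alphabet), len, replace = TRUE), collapse = "")
}

random_dna_record <- function(id, len = 300, n_seqs = 1) {
  genome_record(id, replicate(n_seqs, random_seq(len, "dna")), "dna")
}
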