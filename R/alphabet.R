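#' Sequence alphabets
#'
#' Canonical residue alphabets for the composition-vector machinery: the four
#' DNA nucleotides or the twenty standard amino acids, in fixed alphabetical
#' order. The ordering defines the implicit arrangement of the
#' \eqn{N = |\Sigma|^K} K-mer component space.
#'
#' @param name `"dna"` or `"protein"`.
#' @return An object of class `dl_alphabet`: a list with `name` and the
#'   ordered character vector `symbols`.
#' @examples
#' dl_alphabet("dna")$symbols
#' length(dl_alphabet("protein")$symbols)
#' @export
dl_alphabet <- function(name = c("dna", "protein")) {
  name <- match.arg(name)
  symbols <- switch(name,
    dna = c("A", "C", "G", "T"),
    protein = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  )
  structure(list(name = name, symbols = symbols), class = "dl_alphabet")
}

as_alphabet <- function(x) {
  if (inherits(x, "dl_alphabet")) return(x)
  if (is.character(x) && length(x) == 1) return(dl_alphabet(x))
  abort_dl("`alphabet` must be \"dna\", \"protein\" or a dl_alphabet object.",
           "invalid_parameter")
}

# IUPAC-style ambiguity/edge characters tolerated in input sequences; windows
# containing them are dropped from both numerator and denominator.
ambiguity_set <- function(alphabet) {
  switch(alphabet$name,
    dna = c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "U", "-", "*", "."),
    protein = c("B", "Z", "X", "U", "O", "J", "-", "*", ".")
  )
}

#' @export
print.dl_alphabet <- function(x, ...) {
  cat("<dl_alphabet> ", x$name, ": ", paste(x$symbols, collapse = ""), "\n", sep = "")
  invisible(x)
}

abort_dl <- function(message, class, ...) {
  rlang::abort(message, class = paste0("dl_", class), ...)
}
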