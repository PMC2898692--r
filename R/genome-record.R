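#' Genome records
#'
#' A genome record is a named taxon together with one or more sequences over a
#' declared alphabet. All K-mer counts for the taxon are pooled across its
#' sequences (a multi-gene proteome or gene set behaves as the summed-window
#' aggregate), so "whole genome" and "gene set" differ only in how many
#' sequences the record carries.
#'
#' @param taxon_id Non-empty label, unique within a collection.
#' @param sequences Character vector of one or more sequences. Input is
#'   case-insensitive; it is normalised to uppercase on construction.
#' @param alphabet `"dna"`, `"protein"`, or a [dl_alphabet()].
#' @return An object of class `genome_record`.
#' @examples
#' genome_record("toy", c("MAMA", "MMA"), "protein")
#' @export
genome_record <- function(taxon_id, sequences, alphabet = "dna") {
  if (!is.character(taxon_id) || length(taxon_id) != 1 || !nzchar(taxon_id)) {
    abort_dl("`taxon_id` must be a single non-empty string.", "invalid_parameter")
  }
  if (!is.character(sequences) || length(sequences) < 1) {
    abort_dl("`sequences` must be a character vector with at least one sequence.",
             "invalid_parameter")
  }
  alphabet <- as_alphabet(alphabet)
  structure(
    list(taxon_id = taxon_id, sequences = toupper(sequences), alphabet = alphabet),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat("<genome_record> ", x$taxon_id, ": ", length(x$sequences), " sequence(s), ",
      sum(nchar(x$sequences)), " residues (", x$alphabet$name, ")\n", sep = "")
  invisible(x)
}

# Characters outside canonical symbols and the tolerated ambiguity set are a
# hard input error (likely a wrong --alphabet); ambiguity characters are fine
# and handled by window masking in count_kmers().
validate_record_characters <- function(record) {
  allowed <- c(record$alphabet$symbols, ambiguity_set(record$alphabet))
  chars <- unique(strsplit(paste(record$sequences, collapse = ""), "")[[1]])
  bad <- setdiff(chars, allowed)
  if (length(bad) > 0) {
    abort_dl(
      sprintf("Record '%s' contains characters outside the %s alphabet and its ambiguity set: %s",
              record$taxon_id, record$alphabet$name, paste(bad, collapse = " ")),
      "alphabet_violation"
    )
  }
  invisible(record)
}
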