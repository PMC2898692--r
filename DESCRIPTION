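Package: dlphylo
Title: Alignment-Free Phylogeny from Dynamical-Language K-mer Composition Vectors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Alignment-free phylogenetic reconstruction of whole genomes and
    proteomes from K-mer statistics. Observed K-mer frequencies are corrected
    by a dynamical-language background model that predicts each K-mer's
    expected frequency from its (K-1)-mer and single-letter frequencies; the
    resulting composition vectors X = p/q - 1 are compared by sample
    correlation or chord distance over the full |alphabet|^K component space
    using sparse algebra, and trees are built by neighbor joining. Branch
    robustness is assessed by a modified bootstrap that resamples K-mer
    columns of the genome-by-K-mer vector table. Includes a sequence-evolution
    simulator with known true trees, PHYLIP distance-matrix and Newick I/O,
    and an end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
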