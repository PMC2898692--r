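#' Random unrooted binary tree
#'
#' Uniform random unrooted binary topology grown by sequential random leaf
#' attachment: starting from the 3-leaf star, each further leaf is attached
#' to an edge chosen uniformly at random (every unrooted binary topology is
#' reached with equal probability). Branch lengths are i.i.d. exponential.
#'
#' @param n_taxa Number of leaves, \eqn{\ge 3}.
#' @param branch_mean Mean branch length (expected substitutions per site).
#' @param seed Optional integer seed.
#' @param labels Optional leaf labels (default `t1 ... tn`).
#' @return An unrooted `ape::phylo` with branch lengths.
#' @examples
#' random_tree(5, branch_mean = 0.1, seed = 1)
#' @export
random_tree <- function(n_taxa, branch_mean = 0.1, seed = NULL, labels = NULL) {
  if (!is.numeric(n_taxa) || length(n_taxa) != 1 || n_taxa < 3 ||
      n_taxa != floor(n_taxa)) {
    abort_dl("`n_taxa` must be a single integer >= 3.", "invalid_parameter")
  }
  if (!is.numeric(branch_mean) || branch_mean <= 0) {
    abort_dl("`branch_mean` must be positive.", "invalid_parameter")
  }
  n_taxa <- as.integer(n_taxa)
  if (is.null(labels)) labels <- sprintf("t%d", seq_len(n_taxa))
  stopifnot(length(labels) == n_taxa, !anyDuplicated(labels))
  if (!is.null(seed)) set.seed(as.integer(seed))
  # leaves 1..n, internal nodes n+1, n+2, ...; edges as an undirected pair list
  root <- n_taxa + 1L
  edges <- matrix(c(root, 1L, root, 2L, root, 3L), ncol = 2, byrow = TRUE)
  next_internal <- n_taxa + 2L
  for (leaf in seq_len(n_taxa)[-(1:3)]) {
    e <- sample.int(nrow(edges), 1)
    a <- edges[e, 1]; b <- edges[e, 2]
    c_node <- next_internal
    next_internal <- next_internal + 1L
    edges <- rbind(edges[-e, , drop = FALSE],
                   c(a, c_node), c(c_node, b), c(c_node, leaf))
  }
  lens <- stats::rexp(nrow(edges), rate = 1 / branch_mean)
  edges_to_phylo(edges, lens, n_taxa, labels, root)
}

# undirected edge list -> ape phylo, rooted for representation at `root`
# (degree-3 basal node, i.e. an unrooted binary tree)
edges_to_phylo <- function(edges, lens, n_leaves, labels, root) {
  adj <- vector("list", max(edges))
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- rbind(adj[[a]], c(b, i))
    adj[[b]] <- rbind(adj[[b]], c(a, i))
  }
  newick_of <- function(node, parent) {
    nb <- adj[[node]]
    kids <- nb[nb[, 1] != parent, , drop = FALSE]
    if (nrow(kids) == 0) return(labels[node])
    parts <- vapply(seq_len(nrow(kids)), function(j) {
      paste0(newick_of(kids[j, 1], node), ":", fmt_bl(lens[kids[j, 2]]))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  ape::read.tree(text = paste0(newick_of(root, 0L), ";"))
}

# per-site substitution probability along a branch of length t (expected
# substitutions/site) under the symmetric s-state model
p_substitution <- function(t, s) {
  (s - 1) / s * (1 - exp(-s / (s - 1) * t))
}

#' Evolve multi-gene sequences along a tree
#'
#' Root genes are drawn i.i.d. uniform over the alphabet; along each branch
#' of length `t` (expected substitutions per site) every site independently
#' substitutes with probability
#' \eqn{p_{sub} = \frac{s-1}{s}\left(1 - e^{-\frac{s}{s-1} t}\right)} for
#' alphabet size `s` (the Jukes–Cantor-type symmetric model), the new symbol
#' uniform over the other \eqn{s - 1}. Each gene evolves independently on the
#' same tree.
#'
#' @param tree An `ape::phylo` with branch lengths; its tip labels become the
#'   taxon ids.
#' @param n_genes Number of genes per genome.
#' @param gene_length Sites per gene.
#' @param alphabet `"dna"`, `"protein"`, or a [dl_alphabet()].
#' @param seed Optional integer seed.
#' @return A `dl_simulation`: list with `true_tree`, `records` (list of
#'   [genome_record()]s, one per leaf), and `config`.
#' @export
evolve_sequences <- function(tree, n_genes = 1, gene_length = 1000,
                             alphabet = "dna", seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) {
    abort_dl("Tree has no branch lengths.", "invalid_parameter")
  }
  if (n_genes < 1 || gene_length < 1) {
    abort_dl("`n_genes` and `gene_length` must be positive.", "invalid_parameter")
  }
  alphabet <- as_alphabet(alphabet)
  s <- length(alphabet$symbols)
  if (!is.null(seed)) set.seed(as.integer(seed))
  tree <- ape::reorder.phylo(tree, "cladewise")  # parents precede children
  n_tip <- length(tree$tip.label)
  n_nodes <- n_tip + tree$Nnode
  L <- as.integer(n_genes) * as.integer(gene_length)
  node_seq <- vector("list", n_nodes)
  root <- n_tip + 1L
  node_seq[[root]] <- sample.int(s, L, replace = TRUE)
  for (i in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[i, 1]; child <- tree$edge[i, 2]
    t_len <- tree$edge.length[i]
    p_sub <- p_substitution(t_len, s)
    seq_c <- node_seq[[parent]]
    hit <- which(stats::runif(L) < p_sub)
    if (length(hit) > 0) {
      r <- sample.int(s - 1L, length(hit), replace = TRUE)
      seq_c[hit] <- r + (r >= seq_c[hit])  # uniform over the other s-1 states
    }
    node_seq[[child]] <- seq_c
  }
  gene_idx <- rep(seq_len(n_genes), each = gene_length)
  records <- lapply(seq_len(n_tip), function(i) {
    genes <- vapply(split(node_seq[[i]], gene_idx), function(g) {
      paste(alphabet$symbols[g], collapse = "")
    }, character(1))
    genome_record(tree$tip.label[i], unname(genes), alphabet)
  })
  structure(
    list(true_tree = tree, records = records,
         config = list(n_taxa = n_tip, n_genes = as.integer(n_genes),
                       gene_length = as.integer(gene_length),
                       alphabet = alphabet$name,
                       seed = if (is.null(seed)) NA_integer_ else as.integer(seed))),
    class = "dl_simulation"
  )
}

#' Simulate a labeled dataset with known true tree
#'
#' Draws a [random_tree()] and evolves multi-gene genomes along it with
#' [evolve_sequences()]; one seed drives both stages.
#'
#' @inheritParams random_tree
#' @inheritParams evolve_sequences
#' @return A `dl_simulation` (see [evolve_sequences()]).
#' @export
simulate_genomes <- function(n_taxa, n_genes = 1, gene_length = 1000,
                             alphabet = "dna", branch_mean = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  tree <- random_tree(n_taxa, branch_mean = branch_mean)
  sim <- evolve_sequences(tree, n_genes = n_genes, gene_length = gene_length,
                          alphabet = alphabet)
  sim$config$branch_mean <- branch_mean
  sim$config$seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  sim
}

#' @export
print.dl_simulation <- function(x, ...) {
  cat("<dl_simulation> ", x$config$n_taxa, " taxa, ", x$config$n_genes,
      " gene(s) x ", x$config$gene_length, " sites (", x$config$alphabet,
      ")\n", sep = "")
  invisible(x)
}

#' Additive (patristic) distance matrix of a tree
#'
#' Path-length distances between all leaf pairs; feeding this matrix to
#' [nj_tree()] recovers the tree exactly (NJ consistency).
#'
#' @param tree An `ape::phylo` with branch lengths.
#' @return Labeled symmetric matrix in `tree$tip.label` order.
#' @export
additive_matrix_from_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) {
    abort_dl("Tree has no branch lengths.", "invalid_parameter")
  }
  dm <- ape::cophenetic.phylo(tree)
  dm[tree$tip.label, tree$tip.label]
}

#' Write a simulated dataset to disk
#'
#' One FASTA per taxon (genes as records), the true tree as Newick, and a
#' JSON manifest echoing the configuration.
#'
#' @param sim A `dl_simulation`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "dl_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in sim$records) {
    seqs <- Biostrings::BStringSet(rec$sequences)
    names(seqs) <- sprintf("%s_gene%d", rec$taxon_id, seq_along(rec$sequences))
    Biostrings::writeXStringSet(seqs, file.path(dir, paste0(rec$taxon_id, ".fasta")))
  }
  to_newick(sim$true_tree, file.path(dir, "true_tree.nwk"))
  jsonlite::write_json(sim$config, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
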