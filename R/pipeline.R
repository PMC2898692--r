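#' Pipeline run configuration
#'
#' Collects and validates everything one end-to-end run needs. Word-length
#' guards reflect the explored parameter space of the method: `k <= 13` for
#' DNA, `k <= 8` for protein (the component space \eqn{20^K} grows too fast
#' beyond that); `k >= 2` because the background model needs (K-1)-mers.
#'
#' @param input Directory of FASTA files, or a character vector of FASTA
#'   paths.
#' @param alphabet `"dna"` or `"protein"`.
#' @param mode `"whole"` (one sequence per file) or `"genes"` (all records
#'   of a file are pooled as one genome's gene set).
#' @param k Word length.
#' @param distance `"correlation"` or `"chord"`.
#' @param bootstrap Number of bootstrap replicates; 0 disables the
#'   bootstrap stage.
#' @param seed Integer seed for the bootstrap stage.
#' @param out_dir Output directory.
#' @param type Correlation flavour, see [cv_correlation()].
#' @param manifest Optional two-column TSV (file, taxon_id) overriding the
#'   file-stem taxon ids.
#' @param truth Optional Newick file or string with the true tree; when
#'   given, the run manifest reports the Robinson-Foulds distance to it.
#' @return A validated `run_config` list.
#' @export
run_config <- function(input, alphabet = c("dna", "protein"),
                       mode = c("whole", "genes"), k,
                       distance = c("correlation", "chord"),
                       bootstrap = 0, seed = 1L, out_dir = ".",
                       type = c("pearson", "cosine"),
                       manifest = NULL, truth = NULL) {
  alphabet <- match.arg(alphabet)
  mode <- match.arg(mode)
  distance <- match.arg(distance)
  type <- match.arg(type)
  if (!is.numeric(k) || length(k) != 1 || k < 2 || k != floor(k)) {
    abort_dl("`k` must be a single integer >= 2.", "invalid_parameter")
  }
  k_max <- if (alphabet == "dna") 13L else 8L
  if (k > k_max) {
    abort_dl(sprintf("k = %d exceeds the supported range for %s (k <= %d).",
                     k, alphabet, k_max),
             "invalid_parameter")
  }
  if (bootstrap < 0 || bootstrap != floor(bootstrap)) {
    abort_dl("`bootstrap` must be a non-negative integer.", "invalid_parameter")
  }
  structure(
    list(input = input, alphabet = alphabet, mode = mode, k = as.integer(k),
         distance = distance, type = type, bootstrap = as.integer(bootstrap),
         seed = as.integer(seed), out_dir = out_dir, manifest = manifest,
         truth = truth),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' The YAML keys mirror the [run_config()] arguments.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' Load a genome collection from FASTA files
#'
#' Each file becomes one [genome_record()] whose taxon id is the file stem
#' (overridable through a manifest TSV with columns `file`, `taxon_id`). In
#' `"whole"` mode a file must hold exactly one sequence; in `"genes"` mode
#' all of its records are pooled as the genome's gene set.
#'
#' @param config A [run_config()], or a directory/file vector when the other
#'   arguments are given directly.
#' @param alphabet,mode,k,manifest Used when `config` is a path input.
#' @return List of validated `genome_record`s.
#' @export
load_collection <- function(config, alphabet = "dna", mode = "whole",
                            k = 3, manifest = NULL) {
  if (!inherits(config, "run_config")) {
    config <- run_config(config, alphabet = alphabet, mode = mode, k = k,
                         manifest = manifest)
  }
  files <- config$input
  if (length(files) == 1 && dir.exists(files)) {
    files <- list.files(files, pattern = "\\.(fa|fasta|fna|faa|fas)$",
                        full.names = TRUE, ignore.case = TRUE)
  }
  if (length(files) == 0) {
    abort_dl("No FASTA files found in input.", "invalid_parameter")
  }
  ids <- sub("\\.[^.]*$", "", basename(files))
  if (!is.null(config$manifest)) {
    man <- utils::read.delim(config$manifest, header = TRUE,
                             stringsAsFactors = FALSE)
    if (!all(c("file", "taxon_id") %in% names(man))) {
      abort_dl("Manifest must have columns `file` and `taxon_id`.",
               "malformed_file")
    }
    hit <- match(basename(files), man$file)
    ids[!is.na(hit)] <- man$taxon_id[hit[!is.na(hit)]]
  }
  if (anyDuplicated(ids)) {
    abort_dl(sprintf("Duplicate taxon ids in collection: %s",
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")),
             "duplicate_taxa")
  }
  records <- Map(function(f, id) {
    seqs <- tryCatch(Biostrings::readBStringSet(f),
                     error = function(e) {
                       abort_dl(sprintf("Cannot parse FASTA file '%s': %s",
                                        f, conditionMessage(e)),
                                "malformed_file")
                     })
    if (length(seqs) == 0) {
      abort_dl(sprintf("FASTA file '%s' holds no records.", f), "malformed_file")
    }
    if (config$mode == "whole" && length(seqs) != 1) {
      abort_dl(sprintf("Mode 'whole' expects one record per file; '%s' has %d (use mode = 'genes').",
                       f, length(seqs)),
               "invalid_parameter")
    }
    rec <- genome_record(id, as.character(seqs), config$alphabet)
    validate_record_characters(rec)
    if (!any(nchar(rec$sequences) >= config$k)) {
      abort_dl(sprintf("Record '%s' is too short for k = %d.", id, config$k),
               "record_too_short")
    }
    rec
  }, files, ids)
  names(records) <- ids
  message(sprintf("Loaded %d taxa, %d sequences, %d residues (%s, mode = %s).",
                  length(records),
                  sum(vapply(records, function(r) length(r$sequences), integer(1))),
                  sum(vapply(records, function(r) sum(nchar(r$sequences)), integer(1))),
                  config$alphabet, config$mode))
  unname(records)
}

#' Run the full composition-vector pipeline
#'
#' FASTA collection -> composition vectors -> distance matrix (PHYLIP file)
#' -> NJ tree (Newick file) -> optional bootstrap supports (TSV + annotated
#' Newick), plus a JSON run manifest with the configuration, its hash,
#' per-stage timings, and the Robinson-Foulds distance to a supplied truth
#' tree. Deterministic given the configuration and seed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the distance matrix, tree, optional
#'   support result, and the output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  tick <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    value <- force(expr)
    list(value = value, secs = proc.time()[["elapsed"]] - t0)
  }

  st <- tick(load_collection(config))
  records <- st$value; timings$load <- st$secs

  st <- tick(lapply(records, dl_composition, k = config$k))
  vectors <- st$value; timings$composition <- st$secs

  st <- tick(distance_matrix(vectors, method = config$distance, type = config$type))
  dm <- st$value; timings$distance <- st$secs
  matrix_path <- file.path(config$out_dir, "distances.phy")
  write_phylip(dm, matrix_path)

  st <- tick(nj_tree(dm))
  tree <- st$value; timings$tree <- st$secs
  tree_path <- file.path(config$out_dir, "tree.nwk")
  to_newick(tree, tree_path)

  supports <- NULL
  support_paths <- NULL
  if (config$bootstrap > 0) {
    st <- tick(bootstrap_supports(vectors, method = config$distance,
                                  B = config$bootstrap, seed = config$seed,
                                  type = config$type))
    supports <- st$value; timings$bootstrap <- st$secs
    support_paths <- list(
      tsv = file.path(config$out_dir, "supports.tsv"),
      newick = file.path(config$out_dir, "tree_annotated.nwk")
    )
    utils::write.table(supports$supports, support_paths$tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    to_newick(supports$tree, support_paths$newick)
  }

  rf_truth <- NULL
  if (!is.null(config$truth)) {
    rf_truth <- robinson_foulds(tree, parse_newick(config$truth))
  }

  cfg_public <- unclass(config)
  manifest <- list(
    tool = "dlphylo",
    version = as.character(utils::packageVersion("dlphylo")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = cfg_public,
    config_hash = rlang::hash(cfg_public),
    timings_secs = timings,
    outputs = c(list(matrix = matrix_path, tree = tree_path), support_paths),
    rf_to_truth = rf_truth
  )
  manifest_path <- file.path(config$out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)

  invisible(list(dm = dm, tree = tree, supports = supports,
                 paths = list(matrix = matrix_path, tree = tree_path,
                              manifest = manifest_path,
                              supports = support_paths),
                 rf_to_truth = rf_truth))
}
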