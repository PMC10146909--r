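# End-to-end orchestration: one call runs architecture filtering, block
# selection, the JTT/NJ tree with bootstrap, conservation statistics,
# penalty scores, bimodal positions and the cysteine report, and writes
# every stage table plus a machine-readable manifest.

#' Pipeline configuration with the analysis defaults
#'
#' All thresholds of the stage functions in one flat list: architecture
#' e-values (0.1 per domain, one Kelch required), conservation class
#' bounds (0.33/0.50/0.66), cysteine-call thresholds (Yes 0.9 / Partially
#' 0.5, alignability 0.5), the basic-flank window (1), block selection
#' parameters, the bimodal dominance threshold, bootstrap replicates (100)
#' and the seed.
#'
#' @param ... Named overrides of any default.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    btb_evalue = 0.1, back_evalue = 0.1, kelch_evalue = 0.1, min_kelch = 1L,
    block_min_rank = 0.5, block_max_gap = 0.2, block_min_len = 3L,
    bootstrap_reps = 100L, theta = 0.8,
    yes = 0.9, partial = 0.5, alignable = 0.5, window = 1L,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  defaults[names(over)] <- over
  structure(defaults, class = "pipeline_config")
}

#' Run the full comparative analysis
#'
#' Stages: (1) optional architecture filter of the alignment rows by their
#' domain hits; (2) conserved-block selection; (3) JTT distances, NJ tree
#' and bootstrap supports on the blocks (skipped when `clades` are supplied
#' and `tree = FALSE`); (4) per-column profiles and consensus; (5) penalty
#' scores against the consensus and against the reference; (6) bimodal
#' clade-informative positions; (7) the cysteine report. With an `out_dir`,
#' every stage table is written as TSV (trees as Newick) together with a
#' JSON manifest of thresholds, seed and output checksums; re-running the
#' same inputs and config reproduces byte-identical files.
#'
#' @param aln Alignment matrix (see [as_alignment()]).
#' @param reference Reference row id for penalties and the cysteine report.
#' @param clades Clade table (`id`, `clade`). Required.
#' @param hits Optional domain-hit tibble; rows failing the architecture
#'   rule are dropped from the analysis (the rejection table is kept).
#' @param domains Optional reference domain-coordinate table.
#' @param annotations Optional per-position annotation tibble.
#' @param config A [pipeline_config()].
#' @param tree Build the bootstrap tree (set `FALSE` to reuse supplied
#'   clades without tree building).
#' @param out_dir Optional output directory.
#' @return A list of stage results: `selection`, `blocks`, `tree`
#'   (`klhl_boot_tree` or `NULL`), `profiles`, `consensus`, `penalties`,
#'   `bimodal`, `cysteine_report`, `manifest`.
#' @export
run_pipeline <- function(aln, reference, clades, hits = NULL, domains = NULL,
                         annotations = NULL, config = pipeline_config(),
                         tree = TRUE, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage %s: %s", name, conditionMessage(e)))
    })
  }
  selection <- NULL
  if (!is.null(hits)) {
    rule <- architecture_rule(config$btb_evalue, config$back_evalue,
                              config$kelch_evalue, config$min_kelch)
    selection <- stage("filter",
      filter_by_architecture(hits, rule, protein_ids = rownames(aln)))
    keep <- intersect(rownames(aln), selection$protein_id[selection$accepted])
    if (!reference %in% keep) {
      abort(sprintf("stage filter: reference %s rejected by architecture rule",
                    reference))
    }
    aln <- aln[keep, , drop = FALSE]
    clades <- clades[clades$id %in% keep, , drop = FALSE]
  }
  blocks <- stage("blocks",
    select_conserved_blocks(aln, config$block_min_rank, config$block_max_gap,
                            config$block_min_len))
  boot <- NULL
  if (isTRUE(tree)) {
    cols <- if (length(blocks)) blocks else seq_len(ncol(aln))
    boot <- stage("tree",
      bootstrap_support(aln, cols, n_reps = config$bootstrap_reps,
                        seed = config$seed))
  }
  profiles <- stage("conservation", column_profile(aln))
  consensus <- stage("conservation", column_consensus(aln))
  penalties <- stage("penalties", bind_rows(
    penalty_score(aln, columns = blocks, mode = "consensus"),
    penalty_score(aln, columns = blocks, mode = "reference",
                  reference = reference)))
  bimodal <- stage("bimodal", bimodal_positions(aln, clades, config$theta))
  report <- stage("cyscode",
    build_cysteine_report(aln, reference, clades, domains = domains,
                          window = config$window, yes = config$yes,
                          partial = config$partial,
                          alignable = config$alignable,
                          annotations = annotations))
  manifest <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, name) {
      p <- file.path(out_dir, name)
      readr::write_tsv(x, p)
      p
    }
    paths <- c(
      if (!is.null(selection)) wr(selection, "selection.tsv"),
      wr(tibble(column = blocks), "blocks.tsv"),
      if (!is.null(boot)) {
        p <- file.path(out_dir, "tree.nwk"); write_newick(boot, p); p
      },
      wr(select(profiles, -"counts"), "profiles.tsv"),
      wr(consensus, "consensus.tsv"),
      wr(penalties, "penalties.tsv"),
      wr(bimodal, "bimodal.tsv"),
      wr(report$cysteines, "cysteines.tsv"),
      wr(report$extra_columns, "extra_cysteine_columns.tsv"))
    manifest <- list(
      package = "klhlscan",
      version = as.character(utils::packageVersion("klhlscan")),
      seed = config$seed,
      thresholds = unclass(config),
      files = as.list(setNames(unname(tools::md5sum(paths)), basename(paths))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(selection = selection, blocks = blocks, tree = boot,
       profiles = profiles, consensus = consensus, penalties = penalties,
       bimodal = bimodal, cysteine_report = report, manifest = manifest)
}
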