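# Clade-structured synthetic protein families with planted conservation
# levels, cysteine codes, basic flanks and motifs; every pipeline stage can
# be checked against the generator's exact ground truth.

#' Configuration for a synthetic KLHL-like family
#'
#' The defaults emulate the study conditions of a vertebrate KLHL-style
#' analysis: five clades of eight orthologs each, a 300-column conserved
#' core, long inter-clade branches (0.8 expected substitutions/site) over
#' short intra-clade branches (0.05), and a per-column conservation mix of
#' 15% ultraconserved, 15% conservative and 15% weakly conserved columns
#' with the rest evolving freely under JTT.
#'
#' @param n_clades,taxa_per_clade Family layout.
#' @param length Alignment length (columns).
#' @param inter_clade,intra_clade Branch lengths (expected
#'   substitutions/site) from the root to each clade ancestor and from a
#'   clade ancestor to each taxon.
#' @param p_ultra,p_conservative,p_weak Fractions of columns planted at
#'   each conservation class (must sum to <= 1); remaining columns evolve
#'   freely.
#' @param cys_plan Optional tibble planting cysteine columns: `column`,
#'   `scope` (`"family"`, or `"clade:<k>"`), `fraction` (target presence in
#'   scope), `reference` (logical: force the reference row to carry /
#'   not carry the cysteine; `NA` leaves it to the scope draw),
#'   `basic_flank` (logical: plant a lysine immediately after the cysteine
#'   in carrier rows).
#' @param motif_plan Optional tibble planting motifs: `name`, `pattern`
#'   (see [motif_pattern()]), `scope`, `start` (column).
#' @param seed Integer seed; generation is fully deterministic given the
#'   config.
#' @return An object of class `family_config`.
#' @export
family_config <- function(n_clades = 5L, taxa_per_clade = 8L, length = 300L,
                          inter_clade = 0.8, intra_clade = 0.05,
                          p_ultra = 0.15, p_conservative = 0.15,
                          p_weak = 0.15, cys_plan = NULL, motif_plan = NULL,
                          seed = 1L) {
  stopifnot(n_clades >= 1L, taxa_per_clade >= 1L, length >= 1L,
            inter_clade >= 0, intra_clade >= 0,
            p_ultra + p_conservative + p_weak <= 1)
  structure(list(n_clades = as.integer(n_clades),
                 taxa_per_clade = as.integer(taxa_per_clade),
                 length = as.integer(length),
                 inter_clade = inter_clade, intra_clade = intra_clade,
                 p_ultra = p_ultra, p_conservative = p_conservative,
                 p_weak = p_weak, cys_plan = cys_plan,
                 motif_plan = motif_plan, seed = as.integer(seed)),
            class = "family_config")
}

# rows covered by a plan scope
scope_rows <- function(scope, clades) {
  if (scope == "family") return(clades$id)
  if (startsWith(scope, "clade:")) {
    cl <- sub("^clade:", "", scope)
    rows <- clades$id[as.character(clades$clade) == cl]
    if (!length(rows)) abort(sprintf("scope %s matches no rows", scope))
    return(rows)
  }
  abort(sprintf("unknown scope: %s", scope))
}

call_from_presence <- function(p, yes = 0.9, partial = 0.5) {
  ifelse(p >= yes, "Yes", ifelse(p >= partial, "Partially", "No"))
}

#' Generate a synthetic protein family with planted ground truth
#'
#' The root sequence is drawn from the JTT equilibrium; each branch of the
#' planted clade tree applies the JTT transition kernel scaled by its
#' length (no indels, so the emitted matrix is its own true alignment).
#' After evolution, cysteines arising by chance are replaced by serine so
#' that cysteine columns exist only where the plan puts them; planted
#' conservation columns are overwritten to their target top-residue
#' frequency; planted cysteine, flank and motif cells are then written
#' last. The returned truth records the generating tree, the clade map and
#' the exact planted state of every engineered column.
#'
#' @param config A [family_config()].
#' @return An object of class `synthetic_family`: list with `records`
#'   (tibble `id`, `gene`, `species`, `seq`), `alignment` (character
#'   matrix), `truth` (list: `newick`, `tree`, `clades`, `reference`,
#'   `columns`, `cysteines`, `motifs`), `config`.
#' @export
generate_family <- function(config = family_config()) {
  stopifnot(inherits(config, "family_config"))
  set.seed(config$seed)
  nc <- config$n_clades; nt <- config$taxa_per_clade; L <- config$length
  ids <- as.vector(t(outer(seq_len(nc), seq_len(nt),
                           function(c, t) sprintf("c%d_t%d", c, t))))
  clades <- tibble(id = ids,
                   clade = rep(as.character(seq_len(nc)), each = nt))
  reference <- ids[1L]

  # --- plan feasibility ------------------------------------------------
  cys_plan <- config$cys_plan
  if (!is.null(cys_plan)) {
    cys_plan <- as_tibble(cys_plan)
    if (!"reference" %in% names(cys_plan)) cys_plan$reference <- NA
    if (!"basic_flank" %in% names(cys_plan)) cys_plan$basic_flank <- FALSE
    if (anyDuplicated(cys_plan$column)) {
      abort("infeasible plan: multiple cysteine plantings at one column")
    }
    if (any(cys_plan$column < 1L | cys_plan$column > L)) {
      abort("infeasible plan: cysteine column out of range")
    }
    flank_cols <- cys_plan$column[cys_plan$basic_flank] + 1L
    if (any(flank_cols > L) || length(intersect(flank_cols, cys_plan$column))) {
      abort("infeasible plan: flank column collides with a cysteine column")
    }
  } else {
    cys_plan <- tibble(column = integer(), scope = character(),
                       fraction = double(), reference = logical(),
                       basic_flank = logical())
  }
  motif_plan <- config$motif_plan
  if (!is.null(motif_plan)) {
    motif_plan <- as_tibble(motif_plan)
    for (k in seq_len(nrow(motif_plan))) {
      pat <- motif_pattern(motif_plan$name[k], motif_plan$pattern[k])
      span <- seq.int(motif_plan$start[k], motif_plan$start[k] + pat$length - 1L)
      if (max(span) > L) abort("infeasible plan: motif exceeds alignment length")
      if (length(intersect(span, c(cys_plan$column,
                                   cys_plan$column[cys_plan$basic_flank] + 1L)))) {
        abort("infeasible plan: motif overlaps a planted cysteine/flank column")
      }
    }
  } else {
    motif_plan <- tibble(name = character(), pattern = character(),
                         scope = character(), start = integer())
  }

  # --- tree and evolution ---------------------------------------------
  clade_newick <- vapply(seq_len(nc), function(c) {
    tips <- sprintf("c%d_t%d:%.6g", c, seq_len(nt), config$intra_clade)
    if (nt == 1L) tips else sprintf("(%s)", paste(tips, collapse = ","))
  }, "")
  newick <- sprintf("(%s);", paste(
    sprintf("%s:%.6g", clade_newick, config$inter_clade), collapse = ","))
  tree <- ape::read.tree(text = newick)

  root <- jtt_sample_equilibrium(L)
  mat <- matrix(NA_integer_, nrow = nc * nt, ncol = L, dimnames = list(ids, NULL))
  for (c in seq_len(nc)) {
    anc <- jtt_evolve(root, config$inter_clade)
    for (t in seq_len(nt)) {
      mat[sprintf("c%d_t%d", c, t), ] <- jtt_evolve(anc, config$intra_clade)
    }
  }
  aln <- matrix(JTT_ALPHABET[mat], nrow = nrow(mat), dimnames = dimnames(mat))
  # chance cysteines -> serine, so cysteine truth is exactly the plan
  aln[aln == "C"] <- "S"

  # --- planted conservation columns -----------------------------------
  n_rows <- nrow(aln)
  reserved <- c(cys_plan$column, cys_plan$column[cys_plan$basic_flank] + 1L)
  for (k in seq_len(nrow(motif_plan))) {
    pat <- motif_pattern(motif_plan$name[k], motif_plan$pattern[k])
    reserved <- c(reserved, seq.int(motif_plan$start[k],
                                    motif_plan$start[k] + pat$length - 1L))
  }
  free_cols <- setdiff(seq_len(L), reserved)
  n_plant <- round(c(config$p_ultra, config$p_conservative, config$p_weak) *
                     length(free_cols))
  planted_cols <- sample(free_cols, sum(n_plant))
  plant_class <- rep(c("ultra", "conservative", "weak"), n_plant)
  target_rank <- vapply(plant_class, function(cl) {
    switch(cl,
           ultra = stats::runif(1, 0.72, 0.96),
           conservative = stats::runif(1, 0.54, 0.62),
           weak = stats::runif(1, 0.37, 0.46))
  }, 0, USE.NAMES = FALSE)
  non_c <- setdiff(AA_STANDARD, "C")
  col_truth <- list()
  for (k in seq_along(planted_cols)) {
    j <- planted_cols[k]
    top <- sample(non_c, 1L)
    others <- setdiff(non_c, top)
    k_top <- round(target_rank[k] * n_rows)
    carriers <- sample(n_rows, k_top)
    aln[, j] <- sample(others, n_rows, replace = TRUE)
    aln[carriers, j] <- top
    col_truth[[k]] <- tibble(column = j, class = plant_class[k],
                             top_residue = top, rank = k_top / n_rows)
  }
  columns_truth <- bind_rows(
    if (length(col_truth)) bind_rows(col_truth) else
      tibble(column = integer(), class = character(),
             top_residue = character(), rank = double()),
    tibble(column = setdiff(seq_len(L), c(planted_cols, reserved)),
           class = "free", top_residue = NA_character_, rank = NA_real_)
  ) %>% arrange(.data$column)

  # --- planted cysteines, flanks --------------------------------------
  cys_truth <- list()
  filler <- setdiff(non_c, BASIC_RESIDUES)   # keep flanks free of chance basics
  for (k in seq_len(nrow(cys_plan))) {
    j <- cys_plan$column[k]
    rows <- scope_rows(cys_plan$scope[k], clades)
    n_carry <- round(cys_plan$fraction[k] * length(rows))
    carriers <- sample(rows, n_carry)
    forced <- cys_plan$reference[k]
    if (isTRUE(forced) && !reference %in% carriers) {
      carriers <- c(carriers, reference)
    } else if (isFALSE(forced)) {
      carriers <- setdiff(carriers, reference)
    }
    aln[, j] <- sample(filler, n_rows, replace = TRUE)   # non-carriers: never C
    aln[carriers, j] <- "C"
    if (cys_plan$basic_flank[k]) {
      aln[, j + 1L] <- sample(filler, n_rows, replace = TRUE)
      aln[carriers, j + 1L] <- "K"
    } else {
      # guard the report's flank window: no chance basics beside the cysteine
      for (jj in c(j - 1L, j + 1L)) {
        if (jj >= 1L && jj <= L && !(jj %in% cys_plan$column)) {
          basic_here <- aln[, jj] %in% BASIC_RESIDUES
          aln[basic_here, jj] <- "T"
        }
      }
    }
    presence_of <- function(group_rows) mean(group_rows %in% carriers)
    p_ref_group <- presence_of(clades$id[clades$clade == clades$clade[1L]])
    p_family <- presence_of(clades$id)
    cys_truth[[k]] <- tibble(
      column = j, scope = cys_plan$scope[k], fraction = cys_plan$fraction[k],
      basic_flank = cys_plan$basic_flank[k],
      reference_has_c = reference %in% carriers,
      n_carriers = length(carriers),
      presence_reference_group = p_ref_group,
      presence_family = p_family,
      expected_reference_group = call_from_presence(p_ref_group),
      expected_family = call_from_presence(p_family),
      carriers = list(sort(carriers)))
  }
  cys_truth <- if (length(cys_truth)) bind_rows(cys_truth) else
    tibble(column = integer(), scope = character(), fraction = double(),
           basic_flank = logical(), reference_has_c = logical(),
           n_carriers = integer(), presence_reference_group = double(),
           presence_family = double(), expected_reference_group = character(),
           expected_family = character(), carriers = list())

  # --- planted motifs --------------------------------------------------
  motif_truth <- list()
  for (k in seq_len(nrow(motif_plan))) {
    pat <- motif_pattern(motif_plan$name[k], motif_plan$pattern[k])
    inst <- vapply(pat$tokens, function(tk) {
      if (tk == "x") "A"
      else if (tk == "b") "K"
      else if (tk == "h") "M"
      else if (startsWith(tk, "[")) substr(tk, 2L, 2L)
      else tk
    }, "")
    rows <- scope_rows(motif_plan$scope[k], clades)
    span <- seq.int(motif_plan$start[k], motif_plan$start[k] + pat$length - 1L)
    aln[rows, span] <- matrix(rep(inst, each = length(rows)),
                              nrow = length(rows))
    motif_truth[[k]] <- tibble(name = pat$name, pattern = pat$pattern,
                               id = rows, start = motif_plan$start[k])
  }
  motif_truth <- if (length(motif_truth)) bind_rows(motif_truth) else
    tibble(name = character(), pattern = character(), id = character(),
           start = integer())

  seqs <- apply(aln, 1L, paste, collapse = "")
  records <- tibble(id = ids, gene = ids,
                    species = sub("^c\\d+_", "", ids),
                    seq = unname(seqs))
  structure(list(
    records = records, alignment = aln,
    truth = list(newick = newick, tree = tree, clades = clades,
                 reference = reference, columns = columns_truth,
                 cysteines = cys_truth, motifs = motif_truth),
    config = config
  ), class = "synthetic_family")
}

#' @export
print.synthetic_family <- function(x, ...) {
  cat(sprintf(
    "<synthetic_family> %d clades x %d taxa, %d columns (seed %d)\n",
    x$config$n_clades, x$config$taxa_per_clade, x$config$length,
    x$config$seed))
  cat(sprintf("  planted: %d conservation columns, %d cysteine columns, %d motif plantings\n",
              sum(x$truth$columns$class != "free"), nrow(x$truth$cysteines),
              nrow(x$truth$motifs)))
  invisible(x)
}

#' Inject random gap runs into an alignment
#'
#' Robustness fixture for block selection and `NotAlignable` handling:
#' within the selected rows and column range, gap runs (geometric lengths,
#' mean about 4) are placed until at least `gap_fraction` of the targeted
#' cells are gapped. Deterministic given `seed`.
#'
#' @param aln Alignment matrix.
#' @param gap_fraction Fraction of targeted cells to gap, in `[0, 1)`.
#' @param seed Optional integer seed.
#' @param rows,columns Target rows (ids or indices) and column indices
#'   (defaults: all).
#' @return A list with `alignment` (the gapped matrix) and `mask` (tibble
#'   `id`, `column` of gapped cells).
#' @export
corrupt_alignment <- function(aln, gap_fraction, seed = NULL, rows = NULL,
                              columns = NULL) {
  stopifnot(gap_fraction >= 0, gap_fraction < 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(rows)) rows <- rownames(aln)
  if (is.numeric(rows)) rows <- rownames(aln)[rows]
  if (is.null(columns)) columns <- seq_len(ncol(aln))
  out <- aln
  if (gap_fraction > 0) {
    for (id in rows) {
      target <- ceiling(gap_fraction * length(columns))
      gapped <- logical(length(columns))
      while (sum(gapped) < target) {
        start <- sample(length(columns), 1L)
        len <- 1L + stats::rgeom(1L, 0.3)
        run <- seq.int(start, min(length(columns), start + len - 1L))
        gapped[run] <- TRUE
      }
      out[id, columns[gapped]] <- "-"
    }
  }
  mask_idx <- which(out == "-" & aln != "-", arr.ind = TRUE)
  mask <- tibble(id = rownames(aln)[mask_idx[, 1L]],
                 column = as.integer(mask_idx[, 2L]))
  list(alignment = out, mask = mask)
}
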