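# Per-column conservation statistics: residue profiles, rank classes,
# consensus, frequency-weighted penalty scores, clade-informative bimodal
# positions.

#' Conservation class from a column rank
#'
#' The rank of a column is the frequency of its most common residue among
#' non-gap rows. Classes use half-open intervals closed at the lower bound:
#' `ultra` for rank >= 0.66, `conservative` for 0.50 <= rank < 0.66,
#' `weak` for 0.33 <= rank < 0.50, and `excluded` below 0.33 (too noisy to
#' consider).
#'
#' @param rank Numeric vector of ranks in `[0, 1]`.
#' @return Character vector of classes.
#' @export
conservation_class <- function(rank) {
  stopifnot(all(rank >= 0 & rank <= 1))
  dplyr::case_when(
    rank >= 0.66 ~ "ultra",
    rank >= 0.50 ~ "conservative",
    rank >= 0.33 ~ "weak",
    TRUE ~ "excluded"
  )
}

#' Per-column residue profiles of an alignment
#'
#' Residue frequencies are computed over non-gap rows (an all-rows
#' denominator is available via `denominator = "all"`). An all-gap column
#' gets rank 0 and class `excluded`. Ties for the top residue are broken
#' alphabetically.
#'
#' @param aln Alignment matrix (see [as_alignment()]).
#' @param columns Optional column indices (default: all columns).
#' @param denominator `"non-gap"` (default) or `"all"`: rows counted in the
#'   frequency denominator.
#' @return A tibble of class `column_profiles` with one row per column:
#'   `column`, `n_rows`, `gaps`, `top_residue`, `rank`, `class`, and a
#'   `counts` list-column of named residue counts.
#' @export
column_profile <- function(aln, columns = NULL,
                           denominator = c("non-gap", "all")) {
  denominator <- match.arg(denominator)
  if (is.null(columns)) columns <- seq_len(ncol(aln))
  stopifnot(all(columns >= 1L), all(columns <= ncol(aln)))
  n <- nrow(aln)
  levs <- c(AA_STANDARD, "X")
  rows <- lapply(columns, function(j) {
    col <- aln[, j]
    res <- col[col != "-"]
    gaps <- n - length(res)
    cnt <- table(factor(res, levels = levs))
    cnt <- cnt[cnt > 0]
    denom <- if (denominator == "all") n else length(res)
    if (!length(res) || denom == 0L) {
      return(tibble(column = j, n_rows = n, gaps = gaps,
                    top_residue = NA_character_, rank = 0,
                    class = "excluded", counts = list(integer(0))))
    }
    top <- sort(names(cnt)[cnt == max(cnt)])[1L]   # alphabetical tie-break
    tibble(column = j, n_rows = n, gaps = gaps, top_residue = top,
           rank = max(cnt) / denom,
           class = conservation_class(max(cnt) / denom),
           counts = list(setNames(as.integer(cnt), names(cnt))))
  })
  out <- bind_rows(rows)
  class(out) <- c("column_profiles", class(out))
  out
}

#' Consensus residues for selected columns
#'
#' The most frequent non-gap residue per column; ties are broken by
#' alphabetical residue order, and a message reports every column where the
#' tie-break was invoked. The consensus of a single-sequence alignment is
#' that sequence.
#'
#' @inheritParams column_profile
#' @return A tibble with `column`, `residue`, `tie` (logical).
#' @export
column_consensus <- function(aln, columns = NULL) {
  if (is.null(columns)) columns <- seq_len(ncol(aln))
  levs <- c(AA_STANDARD, "X")
  rows <- lapply(columns, function(j) {
    res <- aln[, j][aln[, j] != "-"]
    if (!length(res)) {
      return(tibble(column = j, residue = NA_character_, tie = FALSE))
    }
    cnt <- table(factor(res, levels = levs))
    top <- names(cnt)[cnt == max(cnt)]
    tibble(column = j, residue = sort(top)[1L], tie = length(top) > 1L)
  })
  out <- bind_rows(rows)
  if (any(out$tie)) {
    inform(sprintf("consensus tie broken alphabetically at column(s) %s",
                   paste(out$column[out$tie], collapse = ", ")))
  }
  out
}

#' Frequency-weighted penalty scores against consensus or a reference
#'
#' For each scored sequence, the penalty is the sum, over the selected
#' columns where its residue differs from the target residue, of the
#' target residue's frequency in that column (computed over non-gap rows).
#' Losing a highly conserved residue therefore costs more than losing a
#' variable one. A gap in the scored row counts as a mismatch. In
#' `reference` mode the target residue is the reference row's residue;
#' columns where the reference itself is gapped are skipped.
#'
#' @param aln Alignment matrix.
#' @param ids Sequence ids to score (default: all rows).
#' @param columns Selected columns (default: all).
#' @param mode `"consensus"` or `"reference"`.
#' @param reference Reference row id (required for `mode = "reference"`).
#' @return A tibble with `id`, `penalty`, `n_mismatch`, `n_columns`,
#'   `mode`.
#' @export
penalty_score <- function(aln, ids = NULL, columns = NULL,
                          mode = c("consensus", "reference"),
                          reference = NULL) {
  mode <- match.arg(mode)
  if (is.null(ids)) ids <- rownames(aln)
  if (is.null(columns)) columns <- seq_len(ncol(aln))
  missing_ids <- setdiff(ids, rownames(aln))
  if (length(missing_ids)) {
    abort(sprintf("unknown sequence id(s): %s", paste(missing_ids, collapse = ", ")))
  }
  sub <- aln[, columns, drop = FALSE]
  # per-column target residue and its non-gap frequency
  freq_of <- function(j, residue) {
    res <- sub[, j][sub[, j] != "-"]
    if (!length(res)) return(0)
    sum(res == residue) / length(res)
  }
  if (mode == "consensus") {
    cons <- column_consensus(sub)
    target <- cons$residue
  } else {
    if (is.null(reference) || !reference %in% rownames(aln)) {
      abort("reference mode needs a valid reference id")
    }
    target <- sub[reference, ]
    target[target == "-"] <- NA_character_
  }
  weight <- vapply(seq_along(target), function(j) {
    if (is.na(target[j])) 0 else freq_of(j, target[j])
  }, 0)
  rows <- lapply(ids, function(id) {
    row <- sub[id, ]
    use <- !is.na(target)
    mism <- use & (row != target | row == "-")
    tibble(id = id, penalty = sum(weight[mism]),
           n_mismatch = sum(mism), n_columns = sum(use), mode = mode)
  })
  bind_rows(rows)
}

#' Clade-informative bimodal positions
#'
#' Reports columns where one residue dominates one clade and a different
#' residue dominates another clade, the signature of lineage-specific
#' substitutions (e.g. a tyrosine/phenylalanine split between neighboring
#' clades). Within-clade frequencies are computed over that clade's
#' non-gap rows. All qualifying residue/clade pairs are reported.
#'
#' @param aln Alignment matrix.
#' @param clades A tibble with columns `id` and `clade` covering all rows.
#' @param theta Within-clade dominance threshold, in `(0.5, 1]`.
#' @param columns Optional column indices (default: all).
#' @return A tibble with `column`, `residue_1`, `clade_1`, `freq_1`,
#'   `residue_2`, `clade_2`, `freq_2`; clades ordered so
#'   `clade_1 < clade_2`.
#' @export
bimodal_positions <- function(aln, clades, theta = 0.8, columns = NULL) {
  stopifnot(theta > 0.5, theta <= 1)
  stopifnot(all(c("id", "clade") %in% names(clades)))
  if (!all(rownames(aln) %in% clades$id)) {
    abort("clade partition does not cover all alignment rows")
  }
  if (is.null(columns)) columns <- seq_len(ncol(aln))
  clades <- clades[match(rownames(aln), clades$id), ]
  clade_ids <- sort(unique(clades$clade))
  if (length(clade_ids) < 2L) {
    return(tibble(column = integer(), residue_1 = character(),
                  clade_1 = character(), freq_1 = double(),
                  residue_2 = character(), clade_2 = character(),
                  freq_2 = double()))
  }
  rows_by_clade <- lapply(clade_ids, function(cl) which(clades$clade == cl))
  names(rows_by_clade) <- clade_ids
  out <- list()
  for (j in columns) {
    # per clade: dominant residue(s) at frequency >= theta (at most one can
    # exceed theta > 0.5)
    dom <- lapply(clade_ids, function(cl) {
      col <- aln[rows_by_clade[[cl]], j]
      res <- col[col != "-"]
      if (!length(res)) return(NULL)
      tab <- table(res) / length(res)
      top <- which(tab >= theta)
      if (!length(top)) return(NULL)
      c(residue = names(tab)[top[1L]], freq = unname(tab[top[1L]]))
    })
    names(dom) <- clade_ids
    have <- clade_ids[!vapply(dom, is.null, TRUE)]
    if (length(have) < 2L) next
    for (a in seq_along(have)) {
      for (b in seq_along(have)) {
        if (a >= b) next
        da <- dom[[have[a]]]; db <- dom[[have[b]]]
        if (da[["residue"]] != db[["residue"]]) {
          out[[length(out) + 1L]] <- tibble(
            column = j,
            residue_1 = da[["residue"]], clade_1 = as.character(have[a]),
            freq_1 = as.numeric(da[["freq"]]),
            residue_2 = db[["residue"]], clade_2 = as.character(have[b]),
            freq_2 = as.numeric(db[["freq"]]))
        }
      }
    }
  }
  if (!length(out)) {
    return(tibble(column = integer(), residue_1 = character(),
                  clade_1 = character(), freq_1 = double(),
                  residue_2 = character(), clade_2 = character(),
                  freq_2 = double()))
  }
  bind_rows(out)
}
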