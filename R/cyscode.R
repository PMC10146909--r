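# The "cysteine code": reference-coordinate mapping, per-group cysteine
# conservation calls, flanking-basic-residue scan, degenerate motif scans,
# and the combined per-cysteine report.

BASIC_RESIDUES <- c("H", "K", "R")
LARGE_HYDROPHOBIC <- c("L", "I", "V", "M", "F")

#' Map reference residue numbers to alignment columns
#'
#' The nth non-gap residue of the reference row maps to its alignment
#' column; the mapping is strictly increasing and bijective over the
#' reference's non-gap columns. All downstream reports use reference
#' numbering (1-based).
#'
#' @param aln Alignment matrix.
#' @param reference Reference row id.
#' @return A tibble of class `position_map` with `position` (reference
#'   residue number), `column`, and `residue`.
#' @export
map_reference_positions <- function(aln, reference) {
  if (!reference %in% rownames(aln)) {
    abort(sprintf("unknown reference id: %s", reference))
  }
  row <- aln[reference, ]
  cols <- which(row != "-")
  out <- tibble(position = seq_along(cols), column = cols,
                residue = unname(row[cols]))
  class(out) <- c("position_map", class(out))
  out
}

#' @rdname map_reference_positions
#' @param map A `position_map`.
#' @param position,column Positions/columns to convert; unmapped values
#'   give `NA`.
#' @export
pos_to_col <- function(map, position) {
  map$column[match(position, map$position)]
}

#' @rdname map_reference_positions
#' @export
col_to_pos <- function(map, column) {
  map$position[match(column, map$column)]
}

#' Classify conservation of a residue within a group at one column
#'
#' If the non-gap fraction of the group at the column is below `alignable`
#' the region is not alignable for that group and the call is
#' `NotAlignable`. Otherwise the presence `p` is the fraction of group rows
#' carrying `residue` (gaps count as absence): `Yes` for p >= `yes`,
#' `Partially` for `partial` <= p < `yes`, else `No`.
#'
#' @param aln Alignment matrix.
#' @param column Alignment column index.
#' @param group Character vector of row ids (non-empty).
#' @param residue Residue to assess (default `"C"`).
#' @param yes,partial,alignable Thresholds in `[0, 1]`.
#' @return A one-row tibble with `call`, `presence`, `non_gap_fraction`,
#'   `n_group`.
#' @export
classify_group_conservation <- function(aln, column, group, residue = "C",
                                        yes = 0.9, partial = 0.5,
                                        alignable = 0.5) {
  stopifnot(length(group) >= 1L, yes >= partial)
  missing <- setdiff(group, rownames(aln))
  if (length(missing)) {
    abort(sprintf("unknown group id(s): %s", paste(missing, collapse = ", ")))
  }
  col <- aln[group, column]
  non_gap <- mean(col != "-")
  if (non_gap < alignable) {
    return(tibble(call = "NotAlignable", presence = NA_real_,
                  non_gap_fraction = non_gap, n_group = length(group)))
  }
  p <- mean(col == residue)
  call <- if (p >= yes) "Yes" else if (p >= partial) "Partially" else "No"
  tibble(call = call, presence = p, non_gap_fraction = non_gap,
         n_group = length(group))
}

#' Scan a sequence for cysteines with basic residues nearby
#'
#' Examines every cysteine in the sequence and reports whether at least one
#' basic residue (H, K or R) occurs within `window` positions on either
#' side. Basic flanks stabilize the thiolate anion, lowering the thiol pKa
#' and marking the cysteine as a candidate redox sensor. Windows are
#' truncated at the sequence boundaries.
#'
#' @param seq An amino-acid sequence (string) or a protein-record tibble
#'   row's `seq`.
#' @param window Half-width of the flank window (>= 1).
#' @return A tibble sorted by position with one row per cysteine:
#'   `position`, `neighbors` (the flanking residues as a string, the
#'   cysteine marked `[C]`), `basic_neighbors`, `has_basic`.
#' @export
basic_flank_scan <- function(seq, window = 1L) {
  stopifnot(window >= 1L)
  chars <- as_residue_chars(seq)
  pos <- which(chars == "C")
  rows <- lapply(pos, function(p) {
    lo <- max(1L, p - window)
    hi <- min(length(chars), p + window)
    flank_idx <- setdiff(seq.int(lo, hi), p)
    flanks <- chars[flank_idx]
    basics <- flanks[flanks %in% BASIC_RESIDUES]
    left <- if (p > lo) paste(chars[lo:(p - 1L)], collapse = "") else ""
    right <- if (p < hi) paste(chars[(p + 1L):hi], collapse = "") else ""
    nb <- paste0(left, "[C]", right)
    tibble(position = p, neighbors = nb,
           basic_neighbors = paste(basics, collapse = ""),
           has_basic = length(basics) > 0L)
  })
  if (!length(rows)) {
    return(tibble(position = integer(), neighbors = character(),
                  basic_neighbors = character(), has_basic = logical()))
  }
  bind_rows(rows)
}

#' Define a degenerate sequence motif
#'
#' Patterns are written over residue classes: uppercase letters match
#' exactly; `x` matches any residue; `b` matches a basic residue (H/K/R);
#' `h` matches a large hydrophobic residue (L/I/V/M/F); a bracketed set
#' like `[HKR]` matches any listed residue. Examples: `"KRR"` (arginine-
#' triad mimic), `"YxxGG"` (Kelch blade motif), `"hxE"` (the
#' hydrophobic-any-glutamate Cullin 3 interaction motif).
#'
#' @param name Motif name.
#' @param pattern Pattern string (at least 2 positions).
#' @return An object of class `motif_pattern`.
#' @export
motif_pattern <- function(name, pattern) {
  tokens <- character(0)
  rest <- pattern
  while (nzchar(rest)) {
    ch <- substr(rest, 1L, 1L)
    if (ch == "[") {
      close <- regexpr("]", rest, fixed = TRUE)
      if (close < 0) abort(sprintf("unclosed residue set in pattern %s", pattern))
      tokens <- c(tokens, substr(rest, 1L, close))
      rest <- substr(rest, close + 1L, nchar(rest))
    } else {
      tokens <- c(tokens, ch)
      rest <- substr(rest, 2L, nchar(rest))
    }
  }
  if (length(tokens) < 2L) abort("motif pattern must have at least 2 positions")
  regex_parts <- vapply(tokens, function(tk) {
    if (tk == "x") "[A-Z]"
    else if (tk == "b") paste0("[", paste(BASIC_RESIDUES, collapse = ""), "]")
    else if (tk == "h") paste0("[", paste(LARGE_HYDROPHOBIC, collapse = ""), "]")
    else if (startsWith(tk, "[")) tk
    else if (tk %in% c(AA_STANDARD)) tk
    else abort(sprintf("invalid pattern token: %s", tk))
  }, "")
  structure(list(name = name, pattern = pattern, tokens = tokens,
                 length = length(tokens),
                 regex = paste(regex_parts, collapse = "")),
            class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("<motif_pattern> %s: %s (%d positions)\n",
              x$name, x$pattern, x$length))
  invisible(x)
}

#' Scan a sequence for a motif
#'
#' Reports all matches, including overlapping ones, with 1-based start and
#' end coordinates in the residue numbering of `seq`. To report in a
#' reference protein's numbering, scan that reference's ungapped sequence.
#'
#' @param seq Amino-acid sequence (string or character vector).
#' @param pattern A [motif_pattern()] (a plain string is promoted to an
#'   exact-residue pattern).
#' @return A tibble with `name`, `start`, `end`, `match`.
#' @export
motif_scan <- function(seq, pattern) {
  if (is.character(pattern) && !inherits(pattern, "motif_pattern")) {
    pattern <- motif_pattern(pattern, pattern)
  }
  s <- paste(as_residue_chars(seq), collapse = "")
  # lookahead captures overlapping matches
  m <- gregexpr(paste0("(?=(", pattern$regex, "))"), s, perl = TRUE)[[1]]
  if (m[1] < 0) {
    return(tibble(name = character(), start = integer(), end = integer(),
                  match = character()))
  }
  starts <- as.integer(m)
  tibble(name = pattern$name, start = starts,
         end = starts + pattern$length - 1L,
         match = substring(s, starts, starts + pattern$length - 1L))
}

#' Build the cysteine-code report for a reference protein
#'
#' For every cysteine of the reference row, reports its alignment column,
#' domain label, conservation call (via [classify_group_conservation()]) in
#' the reference ortholog group, in the reference's clade, and across the
#' whole family, and whether basic residues flank it in the reference
#' sequence. A second section lists family cysteine columns absent from the
#' reference: columns called Yes/Partially at family level or within any
#' clade where the reference residue is not a cysteine.
#'
#' @param aln Alignment matrix.
#' @param reference Reference row id.
#' @param clades Tibble with `id`, `clade` covering all rows.
#' @param reference_group Ids of the reference's ortholog group (default:
#'   all rows of the reference's clade).
#' @param domains Optional domain coordinate table in reference numbering
#'   (`domain`, `start`, `end`); cysteines outside any interval get `NA`.
#' @param window Basic-flank window (residues, each side).
#' @param yes,partial,alignable Conservation-call thresholds.
#' @param annotations Optional tibble (`position`, plus free columns, e.g.
#'   a literature `studied` flag) joined onto the report; never computed.
#' @return An object of class `cysteine_report`: list with `cysteines`
#'   (main tibble), `extra_columns` (family cysteine columns absent from
#'   the reference), `params`.
#' @export
build_cysteine_report <- function(aln, reference, clades,
                                  reference_group = NULL, domains = NULL,
                                  window = 1L, yes = 0.9, partial = 0.5,
                                  alignable = 0.5, annotations = NULL) {
  if (!reference %in% rownames(aln)) {
    abort(sprintf("unknown reference id: %s", reference))
  }
  stopifnot(all(c("id", "clade") %in% names(clades)))
  if (!all(rownames(aln) %in% clades$id)) {
    abort("clade partition does not cover all alignment rows")
  }
  clades <- clades[match(rownames(aln), clades$id), ]
  ref_clade <- clades$clade[clades$id == reference]
  clade_ids <- sort(unique(clades$clade))
  rows_of <- function(cl) clades$id[clades$clade == cl]
  if (is.null(reference_group)) reference_group <- rows_of(ref_clade)
  map <- map_reference_positions(aln, reference)
  ref_seq <- paste(map$residue, collapse = "")
  flanks <- basic_flank_scan(ref_seq, window = window)
  domain_of <- function(pos) {
    if (is.null(domains)) return(NA_character_)
    hit <- domains$domain[domains$start <= pos & domains$end >= pos]
    if (length(hit)) hit[1L] else NA_character_
  }
  classify <- function(column, group) {
    classify_group_conservation(aln, column, group, residue = "C",
                                yes = yes, partial = partial,
                                alignable = alignable)
  }
  cys_pos <- map$position[map$residue == "C"]
  main <- lapply(cys_pos, function(p) {
    col <- pos_to_col(map, p)
    ref_c <- classify(col, reference_group)
    cl_c <- classify(col, rows_of(ref_clade))
    fam_c <- classify(col, rownames(aln))
    fl <- flanks[flanks$position == p, ]
    tibble(position = p, column = col, domain = domain_of(p),
           in_reference_group = ref_c$call, presence_reference = ref_c$presence,
           in_clade = cl_c$call, presence_clade = cl_c$presence,
           in_family = fam_c$call, presence_family = fam_c$presence,
           basic_flank = isTRUE(fl$has_basic[1]),
           basic_neighbors = if (nrow(fl)) fl$basic_neighbors[1] else "")
  })
  main <- if (length(main)) bind_rows(main) else
    tibble(position = integer(), column = integer(), domain = character(),
           in_reference_group = character(), presence_reference = double(),
           in_clade = character(), presence_clade = double(),
           in_family = character(), presence_family = double(),
           basic_flank = logical(), basic_neighbors = character())
  if (!is.null(annotations)) {
    main <- left_join(main, annotations, by = "position")
  }
  # family cysteine columns the reference does not share
  non_ref_cols <- setdiff(seq_len(ncol(aln)), map$column[map$residue == "C"])
  extra <- list()
  for (col in non_ref_cols) {
    if (!any(aln[, col] == "C")) next
    fam_c <- classify(col, rownames(aln))
    per_clade <- lapply(clade_ids, function(cl) classify(col, rows_of(cl)))
    calls <- vapply(per_clade, function(x) x$call, "")
    hit_clades <- clade_ids[calls %in% c("Yes", "Partially")]
    if (fam_c$call %in% c("Yes", "Partially") || length(hit_clades)) {
      p_before <- suppressWarnings(max(map$position[map$column < col], 0L))
      extra[[length(extra) + 1L]] <- tibble(
        column = col,
        after_reference_position = p_before,
        reference_residue = if (col %in% map$column)
          map$residue[map$column == col] else "-",
        family_call = fam_c$call, presence_family = fam_c$presence,
        clades_with_cysteine = paste(hit_clades, collapse = ","))
    }
  }
  extra <- if (length(extra)) bind_rows(extra) else
    tibble(column = integer(), after_reference_position = integer(),
           reference_residue = character(), family_call = character(),
           presence_family = double(), clades_with_cysteine = character())
  structure(list(
    cysteines = main, extra_columns = extra,
    params = list(reference = reference, reference_clade = ref_clade,
                  reference_group = reference_group, window = window,
                  yes = yes, partial = partial, alignable = alignable)
  ), class = "cysteine_report")
}

#' @export
print.cysteine_report <- function(x, ...) {
  cat(sprintf("<cysteine_report> reference %s: %d cysteines (%d basic-flanked), %d family cysteine columns absent from reference\n",
              x$params$reference, nrow(x$cysteines),
              sum(x$cysteines$basic_flank), nrow(x$extra_columns)))
  print(as_tibble(x$cysteines))
  invisible(x)
}

#' @describeIn build_cysteine_report Tidy the main per-cysteine table.
#' @param x A `cysteine_report`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.cysteine_report <- function(x, ...) {
  as_tibble(x$cysteines)
}

#' @describeIn build_cysteine_report One-row summary: cysteine counts and
#'   call tallies.
#' @exportS3Method generics::glance
glance.cysteine_report <- function(x, ...) {
  tibble(reference = x$params$reference,
         n_cysteines = nrow(x$cysteines),
         n_basic_flanked = sum(x$cysteines$basic_flank),
         n_yes_family = sum(x$cysteines$in_family == "Yes"),
         n_extra_columns = nrow(x$extra_columns))
}

#' Spacing between consecutive basic-flanked cysteines
#'
#' Emits the successive spacings (in residues) of a set of cysteine
#' positions, e.g. to inspect the spacing distribution of reactive
#' cysteines along a sequence. Purely descriptive.
#'
#' @param positions Sorted integer vector of cysteine positions.
#' @return A tibble with `from`, `to`, `spacing`.
#' @export
cysteine_spacing <- function(positions) {
  positions <- sort(unique(as.integer(positions)))
  if (length(positions) < 2L) {
    return(tibble(from = integer(), to = integer(), spacing = integer()))
  }
  tibble(from = head(positions, -1L), to = tail(positions, -1L),
         spacing = diff(positions))
}
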