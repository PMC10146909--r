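# Sequence, alignment and domain-table I/O plus the shared containers.
#
# Containers:
#   * protein records: a tibble with columns id, gene, species, seq, description
#   * alignment: a character matrix (one row per sequence, one column per
#     alignment position, single-character entries, '-' for gaps) with row
#     names carrying the sequence ids

AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# non-standard one-letter codes folded to X (B/Z ambiguous, U/O rare, J = I/L)
AA_NONSTANDARD <- c("B", "Z", "U", "O", "J")

normalize_residues <- function(x, context = "sequence") {
  x <- toupper(x)
  bad <- unique(unlist(strsplit(x, ""), use.names = FALSE))
  bad <- setdiff(bad, c(AA_STANDARD, "X", "-"))
  if (length(bad)) {
    warn(sprintf("%s: non-standard residue(s) %s mapped to X",
                 context, paste(bad, collapse = ", ")))
    x <- chartr(paste(bad, collapse = ""),
                strrep("X", length(bad)), x)
  }
  x
}

#' Read protein sequences from a FASTA file
#'
#' Each FASTA entry becomes one row: the header token before the first
#' whitespace is the `id`, the remainder the `description`. Sequences are
#' uppercased, `*` stop characters are stripped, and non-standard residue
#' codes (B, Z, U, O, J) are folded to `X` with a warning.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `gene`, `species`, `seq`,
#'   `description`. `gene` and `species` are empty strings; fill them from
#'   your own metadata (e.g. with [dplyr::mutate()]).
#' @export
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 demo protein", "ACDE"), f)
#' read_fasta(f)
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) abort(sprintf("empty FASTA file: %s", path))
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    abort(sprintf("duplicate sequence id(s): %s",
                  paste(unique(dup), collapse = ", ")))
  }
  seqs <- gsub("*", "", as.character(set), fixed = TRUE)
  if (any(!nzchar(seqs))) {
    abort(sprintf("zero-length sequence for id(s): %s",
                  paste(ids[!nzchar(seqs)], collapse = ", ")))
  }
  seqs <- normalize_residues(seqs, context = basename(path))
  tibble(id = ids, gene = "", species = "",
         seq = unname(seqs), description = unname(desc))
}

#' Write protein records to a FASTA file
#'
#' @param records A tibble with at least `id` and `seq`; a `description`
#'   column, when present and non-empty, is appended to the header.
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  desc <- if ("description" %in% names(records)) records$description
          else rep("", nrow(records))
  header <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  set <- Biostrings::AAStringSet(setNames(records$seq, header))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Build an alignment matrix
#'
#' Coerces gapped sequences into the package's alignment container: a
#' character matrix with one row per sequence (row names = ids) and one
#' column per alignment position. Accepted inputs: a named character vector
#' of gapped strings, a tibble with `id` and `seq` columns, or an existing
#' character matrix. `.` gaps are normalized to `-`.
#'
#' @param x Input sequences (see Details).
#' @return A character matrix with row names.
#' @export
as_alignment <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) abort("alignment matrix needs row names (ids)")
    m <- x
  } else {
    if (is.data.frame(x)) x <- setNames(x$seq, x$id)
    if (is.null(names(x)) || any(!nzchar(names(x)))) {
      abort("gapped sequences must be named by id")
    }
    if (anyDuplicated(names(x))) abort("duplicate ids in alignment input")
    x <- gsub(".", "-", x, fixed = TRUE)
    x <- normalize_residues(x, context = "alignment")
    lens <- nchar(x)
    if (length(unique(lens)) != 1L) {
      abort(sprintf("alignment rows differ in length (%s)",
                    paste(unique(lens), collapse = ", ")))
    }
    m <- do.call(rbind, strsplit(unname(x), ""))
    rownames(m) <- names(x)
  }
  m[m == "."] <- "-"
  if (ncol(m) < 1L) abort("alignment has zero columns")
  m
}

#' Collapse an alignment back to gapped strings
#' @param aln Alignment matrix (see [as_alignment()]).
#' @return Named character vector of gapped sequences.
#' @export
alignment_strings <- function(aln) {
  setNames(apply(aln, 1L, paste, collapse = ""), rownames(aln))
}

#' Read an aligned FASTA file into an alignment matrix
#' @inheritParams read_fasta
#' @return A character matrix (rows = sequences, columns = positions).
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) abort(sprintf("empty FASTA file: %s", path))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) abort("duplicate sequence id(s) in alignment")
  as_alignment(setNames(as.character(set), ids))
}

#' Write an alignment matrix as aligned FASTA
#' @param aln Alignment matrix.
#' @inheritParams write_fasta
#' @export
write_alignment <- function(aln, path, width = 70L) {
  s <- alignment_strings(aln)
  write_fasta(tibble(id = names(s), seq = unname(s)), path, width = width)
}

#' Remove gaps from alignment rows
#' @param aln Alignment matrix.
#' @return A tibble with `id` and `seq` (ungapped).
#' @export
degap_alignment <- function(aln) {
  s <- gsub("-", "", alignment_strings(aln), fixed = TRUE)
  tibble(id = names(s), seq = unname(s))
}

DOMAIN_CANONICAL <- c("BTB", "BACK", "Kelch")

# Pfam-style names -> canonical domain classes used by the architecture rule
normalize_domain <- function(x) {
  out <- rep("other", length(x))
  out[grepl("BTB", x, ignore.case = TRUE)] <- "BTB"
  out[grepl("BACK", x, ignore.case = TRUE)] <- "BACK"
  out[grepl("Kelch", x, ignore.case = TRUE)] <- "Kelch"
  out
}

#' Read a per-protein domain hit table
#'
#' Supports two dialects: a 5-column TSV (`protein_id`, `domain`,
#' `e_value`, `start`, `end`; with or without a header line) and the
#' HMMER3 `--domtblout` format from `hmmscan` (protein = query, domain =
#' target model, e-value = per-domain independent e-value, coordinates =
#' alignment coordinates on the protein). Domain names are additionally
#' mapped to the canonical classes BTB/BACK/Kelch/other in `domain_class`.
#' Coordinates are 1-based inclusive throughout.
#'
#' @param path Path to the table.
#' @param dialect `"tsv"` or `"hmmer-domtbl"`.
#' @return A tibble with columns `protein_id`, `domain`, `domain_class`,
#'   `e_value`, `start`, `end`.
#' @export
read_domain_table <- function(path, dialect = c("tsv", "hmmer-domtbl")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(keep)) {
    return(tibble(protein_id = character(), domain = character(),
                  domain_class = character(), e_value = double(),
                  start = integer(), end = integer()))
  }
  parse_row <- function(i, fields, pid, dom, ev, st, en) {
    if (length(fields) < max(pid, dom, ev, st, en)) {
      abort(sprintf("%s: line %d: expected at least %d fields, got %d",
                    basename(path), i, max(pid, dom, ev, st, en),
                    length(fields)))
    }
    e <- suppressWarnings(as.numeric(fields[ev]))
    s <- suppressWarnings(as.integer(fields[st]))
    n <- suppressWarnings(as.integer(fields[en]))
    if (is.na(e) || e <= 0) {
      abort(sprintf("%s: line %d: unparsable or non-positive e-value %s",
                    basename(path), i, dQuote(fields[ev])))
    }
    if (is.na(s) || is.na(n)) {
      abort(sprintf("%s: line %d: unparsable coordinates", basename(path), i))
    }
    if (s < 1L || n < s) {
      abort(sprintf("%s: line %d: invalid interval %d-%d (need 1 <= start <= end)",
                    basename(path), i, s, n))
    }
    tibble(protein_id = fields[pid], domain = fields[dom],
           e_value = e, start = s, end = n)
  }
  if (dialect == "tsv") {
    # header sniff: a non-numeric third field marks a header line
    first <- strsplit(trimws(lines[keep[1]]), "\\s+")[[1]]
    if (length(first) >= 3 && is.na(suppressWarnings(as.numeric(first[3])))) {
      keep <- keep[-1]
    }
    rows <- lapply(keep, function(i) {
      parse_row(i, strsplit(trimws(lines[i]), "\\s+")[[1]], 1, 2, 3, 4, 5)
    })
  } else {
    rows <- lapply(keep, function(i) {
      parse_row(i, strsplit(trimws(lines[i]), "\\s+")[[1]], 4, 1, 13, 18, 19)
    })
  }
  out <- bind_rows(rows)
  out$domain_class <- normalize_domain(out$domain)
  out[, c("protein_id", "domain", "domain_class", "e_value", "start", "end")]
}
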