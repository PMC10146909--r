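# Domain-architecture family selection and isoform deduplication.

#' Architecture rule for KLHL-family membership
#'
#' A protein qualifies when it carries at least one BTB hit, at least one
#' BACK hit, and at least `min_kelch` Kelch hits, each at or below its
#' e-value threshold. The defaults are the loose architecture-check
#' threshold of 0.1 per domain with a single Kelch repeat required, since
#' Pfam often detects only a subset of the six Kelch blades.
#'
#' @param btb_evalue,back_evalue,kelch_evalue Maximum per-domain e-values.
#' @param min_kelch Minimum number of qualifying Kelch hits.
#' @return An object of class `architecture_rule`.
#' @export
architecture_rule <- function(btb_evalue = 0.1, back_evalue = 0.1,
                              kelch_evalue = 0.1, min_kelch = 1L) {
  stopifnot(btb_evalue > 0, back_evalue > 0, kelch_evalue > 0,
            min_kelch >= 0)
  structure(list(btb_evalue = btb_evalue, back_evalue = back_evalue,
                 kelch_evalue = kelch_evalue, min_kelch = as.integer(min_kelch)),
            class = "architecture_rule")
}

#' @export
print.architecture_rule <- function(x, ...) {
  cat(sprintf(
    "<architecture_rule> BTB <= %g, BACK <= %g, >= %d Kelch <= %g\n",
    x$btb_evalue, x$back_evalue, x$min_kelch, x$kelch_evalue))
  invisible(x)
}

#' Filter proteins by BTB/BACK/Kelch domain architecture
#'
#' @param hits A domain-hit tibble as returned by [read_domain_table()]
#'   (columns `protein_id`, `domain_class`, `e_value` are used; a missing
#'   `domain_class` is derived from `domain`). Overlapping hits are counted
#'   separately.
#' @param rule An [architecture_rule()].
#' @param protein_ids Optional character vector of all proteins under
#'   consideration; proteins with no hits at all are then reported as
#'   rejected rather than silently absent.
#' @return A tibble with one row per protein: `protein_id`, `accepted`
#'   (logical), `reason` (`NA` when accepted, else the first missing
#'   requirement in BTB, BACK, Kelch order), and the per-class qualifying
#'   hit counts `n_btb`, `n_back`, `n_kelch`. Rows are sorted by
#'   `protein_id`, so the result is independent of input ordering.
#' @export
filter_by_architecture <- function(hits, rule = architecture_rule(),
                                   protein_ids = NULL) {
  stopifnot(inherits(rule, "architecture_rule"), is.data.frame(hits))
  if (!"domain_class" %in% names(hits) && "domain" %in% names(hits)) {
    hits$domain_class <- normalize_domain(hits$domain)
  }
  ids <- sort(unique(c(as.character(hits$protein_id), protein_ids)))
  if (!length(ids)) {
    return(tibble(protein_id = character(), accepted = logical(),
                  reason = character(), n_btb = integer(),
                  n_back = integer(), n_kelch = integer()))
  }
  count_class <- function(class, thr) {
    qual <- hits[hits$domain_class == class & hits$e_value <= thr, ]
    tab <- table(factor(qual$protein_id, levels = ids))
    as.integer(tab)
  }
  n_btb <- count_class("BTB", rule$btb_evalue)
  n_back <- count_class("BACK", rule$back_evalue)
  n_kelch <- count_class("Kelch", rule$kelch_evalue)
  reason <- rep(NA_character_, length(ids))
  reason[n_kelch < rule$min_kelch] <- "insufficient Kelch"
  reason[n_back < 1L] <- "missing BACK"
  reason[n_btb < 1L] <- "missing BTB"
  tibble(protein_id = ids, accepted = is.na(reason), reason = reason,
         n_btb = n_btb, n_back = n_back, n_kelch = n_kelch)
}

#' Deduplicate isoforms, keeping the longest sequence per gene
#'
#' Short-isoform filtration: within each gene group only the longest
#' sequence is kept; length ties are broken by the lexicographically
#' smallest id. Records without a gene key form singleton groups.
#'
#' @param records Protein-record tibble (columns `id`, `seq`; `gene` used
#'   when `gene_key` is `NULL`).
#' @param gene_key Optional: a character vector of group keys (recycled
#'   against `records`), or a regular expression with one capture group
#'   applied to `id` to derive the key.
#' @return The kept records (original row order), with the dropped-to-kept
#'   id mapping in `attr(, "isoform_map")` (a tibble with columns
#'   `dropped`, `kept`, `gene`).
#' @export
deduplicate_isoforms <- function(records, gene_key = NULL) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  key <- if (is.null(gene_key)) {
    if (!"gene" %in% names(records)) abort("records lack a gene column")
    records$gene
  } else if (length(gene_key) == 1L && grepl("(", gene_key, fixed = TRUE)) {
    sub(gene_key, "\\1", records$id)
  } else {
    rep_len(as.character(gene_key), nrow(records))
  }
  key <- ifelse(is.na(key) | !nzchar(key), paste0(".singleton.", records$id), key)
  len <- nchar(records$seq)
  keep <- logical(nrow(records))
  for (g in unique(key)) {
    i <- which(key == g)
    best <- i[order(-len[i], records$id[i])][1L]
    keep[best] <- TRUE
  }
  map <- tibble(
    dropped = records$id[!keep],
    gene = key[!keep]
  )
  kept_by_gene <- setNames(records$id[keep], key[keep])
  map$kept <- unname(kept_by_gene[map$gene])
  map$gene <- ifelse(startsWith(map$gene, ".singleton."), "", map$gene)
  out <- records[keep, , drop = FALSE]
  attr(out, "isoform_map") <- map[, c("dropped", "kept", "gene")]
  out
}
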