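# Shared fixture builders: everything is generated in code at test time.

# alignment matrix from gapped strings
aln_from <- function(...) {
  s <- c(...)
  if (is.null(names(s))) names(s) <- paste0("s", seq_along(s))
  as_alignment(s)
}

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# small random ungapped alignment over the 20-letter alphabet
random_aln <- function(n_rows, n_cols, seed = 1) {
  set.seed(seed)
  m <- matrix(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                       "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
                     n_rows * n_cols, replace = TRUE),
              nrow = n_rows,
              dimnames = list(paste0("t", seq_len(n_rows)), NULL))
  m
}

# standard planted cysteine plan used across cyscode/pipeline tests:
# fractions {1.0, 0.7, 0.0-by-scope} against thresholds {0.9, 0.5}
standard_cys_plan <- function() {
  tibble::tibble(
    column = c(50L, 80L, 110L, 140L, 170L),
    scope = c("clade:1", "clade:1", "family", "clade:2", "family"),
    fraction = c(1.0, 0.7, 1.0, 1.0, 0.7),
    reference = c(TRUE, TRUE, NA, FALSE, TRUE),
    basic_flank = c(TRUE, FALSE, FALSE, FALSE, FALSE))
}

standard_motif_plan <- function() {
  tibble::tibble(
    name = c("KRR", "phi-xE", "YxxGG"),
    pattern = c("KRR", "hxE", "YxxGG"),
    scope = c("clade:2", "family", "clade:1"),
    start = c(200L, 220L, 240L))
}
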