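# Synthetic surrogate sequences and a synthetic structure fragment.
#
# These are NOT real UniProt/PDB entries. They are engineered stand-ins
# that plant, at the literature-documented coordinates, the sequence and
# structural features of human Keap1 and KLHL7 that the package's scanners
# are meant to detect (cysteine positions, basic flanks, the hydrophobic-
# x-glutamate Cullin-binding motif, the KRR arginine-triad mimic, and the
# C151 thiol / R135 guanidinium contact geometry). Everything outside the
# planted features is inert filler, so every reported hit is a planted
# feature by construction. Reproducing the published numbers on the real
# molecules requires downloading the UniProt sequences and PDB entry 4CXI
# and running the same functions on them.

# 27 cysteine positions annotated for human Keap1
KEAP1_CYS_POSITIONS <- c(13L, 14L, 23L, 38L, 77L, 151L, 171L, 196L, 226L,
                         241L, 249L, 257L, 273L, 288L, 297L, 319L, 368L,
                         395L, 406L, 434L, 489L, 513L, 518L, 583L, 613L,
                         622L, 624L)

# the 10 of them reported with basic residues in the +/-1 sequence window
KEAP1_BASIC_FLANKED <- c(14L, 38L, 151L, 226L, 241L, 273L, 288L, 297L,
                         319L, 613L)

#' Synthetic surrogate of the human Keap1 sequence
#'
#' A 624-residue synthetic sequence carrying cysteines at the 27 positions
#' annotated for human Keap1, a lysine immediately after each of the 10
#' cysteines reported as basic-flanked (and no basic residue within one
#' position of any other cysteine), and the M-S-E instance of the
#' hydrophobic-x-glutamate Cullin-binding motif at positions 115-117. The
#' filler alphabet excludes C, H, K, R, E, Y, G and the large hydrophobics,
#' so no feature can arise by accident. See the module comment: this is a
#' labelled synthetic stand-in, not the UniProt entry.
#'
#' @return A one-row protein-record tibble (`id`, `gene`, `species`,
#'   `seq`, `description`).
#' @export
keap1_surrogate <- function() {
  n <- 624L
  filler <- c("A", "S", "D", "T", "P", "N", "Q")
  seq <- filler[(seq_len(n) - 1L) %% length(filler) + 1L]
  seq[KEAP1_CYS_POSITIONS] <- "C"
  seq[KEAP1_BASIC_FLANKED + 1L] <- "K"
  seq[c(115L, 116L, 117L)] <- c("M", "S", "E")
  tibble(id = "KEAP1_SURROGATE", gene = "KEAP1", species = "synthetic",
         seq = paste(seq, collapse = ""),
         description = "synthetic Keap1 stand-in with planted features")
}

#' Synthetic surrogate of the human KLHL7 sequence
#'
#' A 586-residue synthetic sequence whose only basic residues form the
#' K-R-R arginine-triad mimic at positions 338-340 (the position reported
#' for human KLHL7). Labelled synthetic; not the UniProt entry.
#'
#' @return A one-row protein-record tibble.
#' @export
klhl7_surrogate <- function() {
  n <- 586L
  filler <- c("A", "S", "D", "T", "P", "N", "Q")
  seq <- filler[(seq_len(n) - 1L) %% length(filler) + 1L]
  seq[c(338L, 339L, 340L)] <- c("K", "R", "R")
  tibble(id = "KLHL7_SURROGATE", gene = "KLHL7", species = "synthetic",
         seq = paste(seq, collapse = ""),
         description = "synthetic KLHL7 stand-in with planted KRR motif")
}

#' Synthetic BTB-site structure fragment
#'
#' A small synthetic atom model (not PDB 4CXI) reproducing the reported
#' contact geometry around the reactive cysteine of the Keap1 BTB domain:
#' the C151 thiol sulfur with the R135 guanidinium nitrogen at 3.6 A (the
#' closest basic contact) and the other four reported basic residues
#' (H129, K131, K150, H154) within 12 A, plus one distant lysine outside
#' that radius as a negative control.
#'
#' @return An atom tibble in the [read_structure()] layout (single chain
#'   `A`).
#' @export
btb_site_model <- function() {
  atom <- function(resid, resno, name, x, y, z) {
    tibble(chain = "A", resno = resno, resid = resid, atom = name,
           element = substr(name, 1L, 1L), x = x, y = y, z = z,
           occupancy = 1)
  }
  bind_rows(
    atom("CYS", 151L, "CB", 0, 0, -1.8),
    atom("CYS", 151L, "SG", 0, 0, 0),
    atom("ARG", 135L, "NE", 1.2, 0, 4.6),
    atom("ARG", 135L, "NH1", 0, 0, 3.6),     # closest basic contact: 3.6 A
    atom("ARG", 135L, "NH2", -1.1, 0.8, 4.4),
    atom("ARG", 135L, "CZ", 0, 0.4, 4.3),
    atom("HIS", 129L, "ND1", 6.5, 2.0, 0),
    atom("HIS", 129L, "NE2", 7.0, 2.5, 0.8),
    atom("LYS", 131L, "NZ", 0, 9.0, 1.5),
    atom("LYS", 150L, "NZ", -5.5, -1.5, 0.5),
    atom("HIS", 154L, "ND1", 3.0, -9.5, 2.0),
    atom("HIS", 154L, "NE2", 3.5, -10.3, 2.6),
    atom("LYS", 999L, "NZ", 20, 0, 0)        # outside the 12 A radius
  )
}
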