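# 3D-structure support: PDB ATOM parsing and cysteine-to-basic-residue
# side-chain distances (thiol reactivity geometry).

# basic side-chain nitrogen atoms carrying/stabilizing the positive charge
BASIC_SIDECHAIN_ATOMS <- list(
  ARG = c("NE", "NH1", "NH2"),
  LYS = "NZ",
  HIS = c("ND1", "NE2")
)

#' Read a PDB structure (first model, ATOM records)
#'
#' Parses fixed-width `ATOM` records of the first `MODEL` only; `HETATM`
#' records are ignored by default. Alternate locations are resolved to the
#' highest-occupancy conformer per (chain, residue, atom). Malformed
#' coordinate fields raise an error naming the offending line.
#'
#' @param path Path to a PDB-format file.
#' @param include_hetatm Also parse `HETATM` records.
#' @return A tibble with `chain`, `resno`, `resid`, `atom`, `element`,
#'   `x`, `y`, `z`, `occupancy`.
#' @export
read_structure <- function(path, include_hetatm = FALSE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  types <- c("ATOM  ", if (include_hetatm) "HETATM")
  # keep only the first model
  model_starts <- which(trimws(rec) == "MODEL")
  model_ends <- which(trimws(rec) == "ENDMDL")
  keep_range <- if (length(model_starts)) {
    end1 <- if (length(model_ends)) model_ends[1L] else length(lines)
    seq.int(model_starts[1L], end1)
  } else seq_along(lines)
  idx <- intersect(which(rec %in% types), keep_range)
  if (!length(idx)) abort(sprintf("no ATOM records in %s", path))
  num_field <- function(str, from, to, i, what) {
    v <- suppressWarnings(as.numeric(substr(str, from, to)))
    bad <- which(is.na(v))
    if (length(bad)) {
      abort(sprintf("%s: line %d: malformed %s field",
                    basename(path), i[bad[1L]], what))
    }
    v
  }
  str <- lines[idx]
  occ <- suppressWarnings(as.numeric(substr(str, 55L, 60L)))
  occ[is.na(occ)] <- 1
  out <- tibble(
    chain = trimws(substr(str, 22L, 22L)),
    resno = as.integer(num_field(str, 23L, 26L, idx, "residue number")),
    resid = trimws(substr(str, 18L, 20L)),
    atom = trimws(substr(str, 13L, 16L)),
    altloc = trimws(substr(str, 17L, 17L)),
    element = trimws(substr(str, 77L, 78L)),
    x = num_field(str, 31L, 38L, idx, "x coordinate"),
    y = num_field(str, 39L, 46L, idx, "y coordinate"),
    z = num_field(str, 47L, 54L, idx, "z coordinate"),
    occupancy = occ
  )
  # altloc resolution: highest occupancy per (chain, resno, atom)
  out <- out %>%
    group_by(.data$chain, .data$resno, .data$atom) %>%
    arrange(dplyr::desc(.data$occupancy), .data$altloc, .by_group = TRUE) %>%
    slice(1L) %>%
    ungroup() %>%
    arrange(.data$chain, .data$resno, .data$atom) %>%
    select(-"altloc")
  out
}

#' Write an atom table as a minimal PDB file
#'
#' Fixed-width `ATOM` records, one model; used to emit fixtures and small
#' synthetic models.
#'
#' @param atoms Tibble as returned by [read_structure()].
#' @param path Output path.
#' @export
write_pdb <- function(atoms, path) {
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    name <- if (nchar(a$atom) < 4L) sprintf(" %-3s", a$atom) else a$atom
    sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, name, a$resid, a$chain, a$resno, a$x, a$y, a$z,
            if ("occupancy" %in% names(a)) a$occupancy else 1, 0,
            if ("element" %in% names(a)) a$element else substr(a$atom, 1L, 1L))
  }, "")
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Cysteine-to-basic-residue spatial proximity
#'
#' For each cysteine thiol (SG atom) in the selected chain(s), computes the
#' distance to every histidine, lysine and arginine of the same chain and
#' returns those within `cutoff`, sorted by distance per cysteine. The
#' default metric measures from the SG to the basic side-chain nitrogens
#' (Arg NE/NH1/NH2; Lys NZ; His ND1/NE2), matching how thiol-guanidinium
#' contacts are reported; `"all-atom"` takes the minimum over all atom
#' pairs of the two residues. Cysteines lacking an SG atom are skipped with
#' a warning.
#'
#' @param model Atom tibble from [read_structure()].
#' @param chain Chain id(s) to analyze (default: all chains).
#' @param cutoff Distance cutoff in Angstrom (> 0).
#' @param metric `"basic-N"` or `"all-atom"`.
#' @return A tibble with `chain`, `cys_resno`, `basic_resid`,
#'   `basic_resno`, `distance`, sorted by cysteine then distance.
#' @export
cys_basic_proximity <- function(model, chain = NULL, cutoff = 8,
                                metric = c("basic-N", "all-atom")) {
  metric <- match.arg(metric)
  stopifnot(cutoff > 0)
  chains <- if (is.null(chain)) unique(model$chain) else chain
  missing <- setdiff(chains, model$chain)
  if (length(missing)) {
    abort(sprintf("chain(s) not in structure: %s", paste(missing, collapse = ", ")))
  }
  out <- list()
  for (ch in chains) {
    atoms <- model[model$chain == ch, ]
    cys <- unique(atoms$resno[atoms$resid == "CYS"])
    basics <- distinct(atoms[atoms$resid %in% names(BASIC_SIDECHAIN_ATOMS),
                             c("resno", "resid")])
    for (cr in sort(cys)) {
      cys_atoms <- atoms[atoms$resno == cr & atoms$resid == "CYS", ]
      ref <- if (metric == "basic-N") {
        cys_atoms[cys_atoms$atom == "SG", ]
      } else cys_atoms
      if (metric == "basic-N" && nrow(ref) == 0L) {
        warn(sprintf("chain %s CYS %d lacks an SG atom; skipped", ch, cr))
        next
      }
      for (k in seq_len(nrow(basics))) {
        br <- basics$resno[k]; bres <- basics$resid[k]
        b_atoms <- atoms[atoms$resno == br & atoms$resid == bres, ]
        if (metric == "basic-N") {
          b_atoms <- b_atoms[b_atoms$atom %in% BASIC_SIDECHAIN_ATOMS[[bres]], ]
        }
        if (!nrow(b_atoms)) next
        dmin <- min(sqrt(outer(ref$x, b_atoms$x, "-")^2 +
                         outer(ref$y, b_atoms$y, "-")^2 +
                         outer(ref$z, b_atoms$z, "-")^2))
        if (dmin <= cutoff) {
          out[[length(out) + 1L]] <- tibble(
            chain = ch, cys_resno = cr, basic_resid = bres,
            basic_resno = br, distance = dmin)
        }
      }
    }
  }
  if (!length(out)) {
    return(tibble(chain = character(), cys_resno = integer(),
                  basic_resid = character(), basic_resno = integer(),
                  distance = double()))
  }
  bind_rows(out) %>% arrange(.data$chain, .data$cys_resno, .data$distance)
}
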