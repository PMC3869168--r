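#' @title Protein structures as atom tibbles
#'
#' @description A structure is represented as a tibble of heavy atoms with
#' columns `model` (1-based model index), `residue` (1-based sequential
#' chain index), `resname` (3-letter code), `atom` (atom name), and `x`,
#' `y`, `z` (Angstrom). Attributes carry the structure `id`, the chain
#' length `L`, the number of models, and a lookup from internal to author
#' residue numbering. All downstream functions accept this tibble.
#'
#' @name ln_structure
NULL

new_structure <- function(atoms, id = "structure", author = NULL) {
  atoms <- tibble::as_tibble(atoms)
  stop_unless(all(c("model", "residue", "resname", "atom", "x", "y", "z")
                  %in% names(atoms)), "malformed atom table")
  out <- dplyr::arrange(atoms, .data$model, .data$residue)
  attr(out, "id") <- id
  attr(out, "L") <- max(out$residue)
  attr(out, "n_models") <- length(unique(out$model))
  attr(out, "author_numbering") <- author
  class(out) <- c("ln_structure", class(tibble::tibble()))
  out
}

#' Structure accessors
#'
#' @param structure A structure tibble from [read_structure()] or a
#'   synthetic generator.
#' @return `structure_id()` the id string; `structure_length()` the residue
#'   count L; `n_models()` the model count; `structure_resnames()` the
#'   residue names of model 1 in chain order.
#' @export
structure_id <- function(structure) attr(structure, "id") %||% "structure"

#' @rdname structure_id
#' @export
structure_length <- function(structure) {
  attr(structure, "L") %||% max(structure$residue)
}

#' @rdname structure_id
#' @export
n_models <- function(structure) {
  attr(structure, "n_models") %||% length(unique(structure$model))
}

#' @rdname structure_id
#' @export
structure_resnames <- function(structure) {
  m1 <- structure[structure$model == min(structure$model), ]
  m1 <- m1[!duplicated(m1$residue), ]
  m1$resname[order(m1$residue)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Extract one model as a per-residue list of coordinate matrices.
model_atoms <- function(structure, model = 1) {
  structure[structure$model == model, , drop = FALSE]
}

#' Build a structure from bare coordinates
#'
#' Constructor used by the synthetic generators and useful in tests: one
#' bead (named `CA`) per residue, or several models of beads.
#'
#' @param coords Numeric matrix (L x 3) or list of such matrices (one per
#'   model, identical row counts).
#' @param id Structure id.
#' @param resnames 3-letter residue names, recycled to length L
#'   (default `"GLY"`).
#' @return A structure tibble (see [ln_structure]).
#' @export
as_structure <- function(coords, id = "synthetic", resnames = "GLY") {
  if (is.matrix(coords)) coords <- list(coords)
  L <- nrow(coords[[1]])
  stop_unless(all(vapply(coords, nrow, 1L) == L),
              "all models must have the same residue count")
  resnames <- toupper(rep_len(resnames, L))
  atoms <- purrr::imap_dfr(coords, function(m, k) {
    tibble::tibble(model = as.integer(k), residue = seq_len(L),
                   resname = resnames, atom = "CA",
                   x = m[, 1], y = m[, 2], z = m[, 3])
  })
  new_structure(atoms, id = id)
}

#' Read a protein structure (PDB or mmCIF)
#'
#' Parses a structure file through bio3d, keeps heavy atoms of a single
#' protein chain, resolves alternate locations by highest occupancy, and
#' renumbers residues 1..L in order of appearance (the author numbering is
#' preserved in the `author_numbering` attribute). Multi-model files (NMR
#' ensembles) return all models; models must agree in residue count and
#' names.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @param chain Chain id to keep; default the first chain with protein
#'   (`ATOM`) records.
#' @return A structure tibble (see [ln_structure]).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"),
                           chain = NULL) {
  format <- match.arg(format)
  stop_unless(file.exists(path), "file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "cif") bio3d::read.cif(path, multi = TRUE)
    else bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) abort(sprintf(
      "could not parse '%s' (models may be inconsistent): %s",
      path, conditionMessage(e)))
  )
  at <- pdb$atom
  keep <- at$type == "ATOM"
  stop_unless(any(keep), "no protein (ATOM) records in %s", path)
  if (is.null(chain)) chain <- at$chain[keep][1]
  keep <- keep & (at$chain %in% chain | is.na(at$chain))
  # heavy atoms only
  elem <- at$elesy
  bad <- is.na(elem) | elem == ""
  if (any(bad)) elem[bad] <- substr(gsub("^[0-9]*", "", at$elety[bad]), 1, 1)
  keep <- keep & !(toupper(elem) %in% c("H", "D"))
  stop_unless(any(keep), "no heavy atoms left after filtering in %s", path)
  at <- at[keep, , drop = FALSE]

  # altloc: keep highest-occupancy conformer per (residue, atom name)
  occ <- at$o
  occ[is.na(occ)] <- 1
  grp <- paste(at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(grp, -occ)
  first <- !duplicated(grp[ord])
  sel <- sort(ord[first])
  at <- at[sel, , drop = FALSE]

  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  cols <- as.vector(rbind(which(keep) * 3 - 2, which(keep) * 3 - 1,
                          which(keep) * 3))
  xyz <- xyz[, cols, drop = FALSE]
  cols2 <- as.vector(rbind(sel * 3 - 2, sel * 3 - 1, sel * 3))
  xyz <- xyz[, cols2, drop = FALSE]

  res_key <- paste(at$resno, at$insert, sep = "\r")
  residue <- match(res_key, unique(res_key))
  author <- tibble::tibble(residue = seq_along(unique(res_key)),
                           author_resno = at$resno[!duplicated(res_key)])
  nm <- length(unique(residue))
  stop_unless(nm >= 3, "structure has fewer than 3 residues")

  atoms <- purrr::map_dfr(seq_len(nrow(xyz)), function(m) {
    tibble::tibble(model = m, residue = residue,
                   resname = toupper(at$resid), atom = at$elety,
                   x = xyz[m, seq(1, ncol(xyz), 3)],
                   y = xyz[m, seq(2, ncol(xyz), 3)],
                   z = xyz[m, seq(3, ncol(xyz), 3)])
  })
  id <- sub("\\.(pdb|cif|ent)$", "", basename(path), ignore.case = TRUE)
  new_structure(atoms, id = id, author = author)
}

#' Write a structure as a (multi-model) PDB file
#'
#' Emits fixed-width ATOM records, wrapping each model in MODEL/ENDMDL when
#' the structure has more than one. Coordinates are written at PDB
#' precision (0.001 Angstrom). Used to round-trip synthetic structures
#' through the same reader as real data.
#'
#' @param structure Structure tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(structure, path) {
  con <- file(path, "w")
  on.exit(close(con))
  multi <- n_models(structure) > 1
  for (m in sort(unique(structure$model))) {
    a <- model_atoms(structure, m)
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    name4 <- ifelse(nchar(a$atom) < 4, sprintf(" %-3s", a$atom),
                    substr(a$atom, 1, 4))
    elem <- substr(gsub("^[0-9]*", "", a$atom), 1, 1)
    writeLines(sprintf(
      "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(a)), name4, substr(a$resname, 1, 3), "A", a$residue,
      a$x, a$y, a$z, 1, 0, elem), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
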