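## Octanol-water partition coefficients (pi values, kcal/mol) for the 20
## standard residues, the scale used for all default hydrophobicity ranking.
## Positive = hydrophobic; TRP is the most hydrophobic entry.
.octanol_scale <- c(
  ALA =  0.31, ARG = -1.01, ASN = -0.60, ASP = -0.77, CYS =  1.54,
  GLN = -0.22, GLU = -0.64, GLY =  0.00, HIS =  0.13, ILE =  1.80,
  LEU =  1.70, LYS = -0.99, MET =  1.23, PHE =  1.79, PRO =  0.72,
  SER = -0.04, THR =  0.26, TRP =  2.25, TYR =  0.96, VAL =  1.22
)

#' Hydrophobicity scales
#'
#' Returns a named numeric vector mapping 3-letter residue codes to
#' hydrophobicity values. The embedded `"octanol"` scale holds
#' octanol-water partition coefficients (kcal/mol). Alternative scales can
#' be supplied as a two-column whitespace- or tab-separated text file
#' (residue name, value) via [residue_hydrophobicity()].
#'
#' @param name Scale name; currently `"octanol"`.
#' @return Named numeric vector (names are 3-letter residue codes).
#' @export
#' @examples
#' hydrophobicity_scale()[["TRP"]]
hydrophobicity_scale <- function(name = "octanol") {
  stop_unless(identical(name, "octanol"),
              "unknown hydrophobicity scale '%s'", name)
  .octanol_scale
}

# Resolve a scale argument: name, named numeric vector, or path to a
# two-column text file.
resolve_scale <- function(scale) {
  if (is.character(scale) && length(scale) == 1) {
    if (file.exists(scale)) {
      tab <- utils::read.table(scale, header = FALSE,
                               col.names = c("resname", "value"),
                               stringsAsFactors = FALSE)
      return(setNames(tab$value, toupper(tab$resname)))
    }
    return(hydrophobicity_scale(scale))
  }
  stop_unless(is.numeric(scale) && !is.null(names(scale)),
              "scale must be a scale name, a file path or a named numeric vector")
  scale
}

# Centered moving average with truncated windows at the edges.
window_average <- function(x, window) {
  stop_unless(window >= 1 && window %% 2 == 1, "window must be odd")
  if (window == 1) return(x)
  half <- (window - 1) / 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Per-residue hydrophobicity
#'
#' Looks up a hydrophobicity value for each residue of a sequence and
#' optionally smooths it over a centered window (edge residues use
#' truncated windows). Values are also rescaled to \[0, 1\] over the range
#' of the scale table, so the most hydrophobic residue type in the table
#' maps to 1 regardless of the protein's composition.
#'
#' @param resnames Character vector of 3-letter residue codes, or a
#'   structure tibble from [read_structure()] (model 1 residue names used).
#' @param scale Scale name, named numeric vector, or path to a two-column
#'   text file (residue name, value).
#' @param window Odd window width for moving-average smoothing (default 1,
#'   no smoothing).
#' @return Tibble with columns `residue`, `resname`, `hydrophobicity`,
#'   `hydrophobicity_scaled`.
#' @export
#' @examples
#' residue_hydrophobicity(c("TRP", "GLY", "ARG"))
residue_hydrophobicity <- function(resnames, scale = "octanol", window = 1) {
  if (is.data.frame(resnames)) resnames <- structure_resnames(resnames)
  tab <- resolve_scale(scale)
  resnames <- toupper(resnames)
  unknown <- setdiff(unique(resnames), names(tab))
  stop_unless(length(unknown) == 0,
              "residue name(s) not in hydrophobicity scale: %s",
              paste(unknown, collapse = ", "))
  raw <- window_average(unname(tab[resnames]), window)
  rng <- range(tab)
  tibble::tibble(
    residue = seq_along(resnames),
    resname = resnames,
    hydrophobicity = raw,
    hydrophobicity_scaled = (raw - rng[1]) / diff(rng)
  )
}
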