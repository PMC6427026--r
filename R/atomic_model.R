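#' Atomic model container
#'
#' A light tabular container for labelled heavy-atom coordinates: one row
#' per atom with element, atom name, residue number/name, chain label,
#' Cartesian coordinates in Angstrom and an integer layer index per chain
#' (consecutive fibril layers get consecutive indices). By convention the
#' helix axis is the z coordinate; models read from deposits can be
#' re-aligned via [estimate_symmetry()].
#'
#' @param atoms data frame with columns `elety` (atom name, e.g. "CA"),
#'   `resid` (three-letter residue name), `resno` (integer residue number,
#'   1-based mature light-chain numbering), `chain` (chain label),
#'   `x`, `y`, `z` (Angstrom) and optionally `elesy` (element symbol,
#'   derived from the atom name when absent) and `layer` (integer,
#'   defaults to 0 for all chains in order of appearance).
#'
#' @return object of class `atomic_model` (a data frame).
#' @examples
#' mdl <- atomic_model(data.frame(
#'   elety = "CA", resid = "ALA", resno = 1, chain = "A",
#'   x = 0, y = 0, z = 0))
#' nrow(mdl)
#' @export
atomic_model <- function(atoms) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  need <- c("elety", "resid", "resno", "chain", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0) {
    stop("atomic_model: missing columns: ", paste(miss, collapse = ", "))
  }
  if (nrow(atoms) == 0) stop("atomic_model: no atoms")
  if (!is.numeric(atoms$x) || !is.numeric(atoms$y) || !is.numeric(atoms$z)) {
    stop("atomic_model: coordinates must be numeric")
  }
  if (anyNA(atoms[, c("x", "y", "z")])) {
    stop("atomic_model: NA coordinates")
  }
  if (is.null(atoms$elesy)) {
    atoms$elesy <- guess_element(atoms$elety)
  }
  if (is.null(atoms$layer)) {
    atoms$layer <- match(atoms$chain, unique(atoms$chain)) - 1L
  }
  atoms$resno <- as.integer(atoms$resno)
  atoms$layer <- as.integer(atoms$layer)
  class(atoms) <- c("atomic_model", "data.frame")
  atoms
}

# Element symbol from a PDB atom name: leading digits stripped, first letter
# (two letters only for common heavy-atom doubles not seen in proteins).
guess_element <- function(elety) {
  nm <- toupper(gsub("^[0-9' ]+", "", elety))
  el <- substr(nm, 1L, 1L)
  el[nm %in% c("SE")] <- "SE"
  el
}

#' @export
print.atomic_model <- function(x, ...) {
  cat(sprintf("atomic_model: %d atoms, %d residues, %d chains, %d layers\n",
              nrow(x),
              length(unique(paste(x$chain, x$resno))),
              length(unique(x$chain)),
              length(unique(x$layer))))
  print(head(as.data.frame(x)), ...)
  invisible(x)
}

# coordinates as an n x 3 matrix
coords <- function(model) {
  as.matrix(model[, c("x", "y", "z"), drop = FALSE])
}

# subset of an atomic_model keeping the class
model_subset <- function(model, idx) {
  out <- as.data.frame(model)[idx, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("atomic_model", "data.frame")
  out
}

# van der Waals radii (Angstrom), Bondi values for protein heavy atoms
vdw_radius <- function(element) {
  tab <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20,
           P = 1.80, SE = 1.90)
  r <- tab[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}
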