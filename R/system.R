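#' Construct a molecular system
#'
#' A `molecular_system` is the static atom table underlying all analyses:
#' one row per atom with identity (serial, name, residue, chain, element)
#' and reference coordinates in Angstrom. Atom order is significant and is
#' preserved from the source file; trajectories refer to atoms by this order.
#'
#' @param atoms data.frame with columns `serial` (integer), `type`
#'   ("ATOM"/"HETATM"), `atom_name`, `residue_name`, `residue_number`
#'   (integer), `chain_id`, `element`, and coordinates `x`, `y`, `z` (Angstrom).
#' @return An object of class `molecular_system`.
#' @export
molecular_system <- function(atoms) {
  req <- c("serial", "type", "atom_name", "residue_name", "residue_number",
           "chain_id", "element", "x", "y", "z")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols))
    stop("atom table is missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) == 0L) stop("molecular system must contain at least one atom")
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(coords)))
    stop("non-finite coordinates in atom table (rows ",
         paste(utils::head(which(!apply(is.finite(coords), 1, all)), 5), collapse = ", "), ")")
  key <- paste(atoms$chain_id, atoms$residue_number, atoms$atom_name)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, atom name) after alt-loc resolution: ",
         key[which(duplicated(key))[1]])
  atoms$serial <- as.integer(atoms$serial)
  atoms$residue_number <- as.integer(atoms$residue_number)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "molecular_system")
}

#' Number of atoms in a system
#' @param system a `molecular_system`
#' @return integer atom count
#' @export
n_atoms <- function(system) nrow(system$atoms)

#' Coordinates of a system as an n x 3 matrix
#' @param system a `molecular_system`
#' @return numeric matrix with columns x, y, z (Angstrom)
#' @export
coords <- function(system) {
  m <- as.matrix(system$atoms[, c("x", "y", "z")])
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
}

#' @export
print.molecular_system <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("molecular_system: %d atoms, %d residues, chains: %s\n",
              nrow(a), length(unique(paste(a$chain_id, a$residue_number))),
              paste(unique(a$chain_id), collapse = ", ")))
  invisible(x)
}

# Standard amino-acid residue names; backbone selection is restricted to these.
STANDARD_RESIDUES <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                       "HIS", "HSD", "HSE", "HSP", "ILE", "LEU", "LYS", "MET",
                       "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")

# Derive the chemical element from a PDB atom name when the element column
# is absent: strip digits/primes, handle leading digits (e.g. "1HB"), then
# the first remaining letter, keeping two-letter ions untouched only when a
# proper element field exists upstream.
guess_element <- function(atom_name) {
  nm <- gsub("[0-9']", "", trimws(atom_name))
  el <- toupper(substr(nm, 1, 1))
  el[el == ""] <- "X"
  el
}
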