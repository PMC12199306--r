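#' Construct a molecule from atoms and coordinates
#'
#' An `hsr_molecule` is a format-neutral record of an atomic point cloud:
#' element symbols, atomic numbers, optional mass numbers (isotopes),
#' formal charges, Cartesian coordinates in Angstrom, and an optional
#' table of extra per-atom numerical features. Atom order is preserved
#' exactly as supplied; nothing is added or removed (in particular, no
#' implicit hydrogens).
#'
#' @param elements Character vector of element symbols (`"*"` allowed for
#'   property-annotated dummy atoms).
#' @param coords Numeric matrix with one row per atom and columns x, y, z
#'   (Angstrom).
#' @param charges Integer vector of formal charges (recycled; default 0).
#' @param masses Integer vector of mass numbers, `NA` meaning "most common
#'   isotope" (recycled; default `NA`).
#' @param features Optional data frame of extra per-atom numerical
#'   features, one row per atom, named columns.
#' @param name Molecule name.
#' @param source_format One of `"SDF"`, `"XYZ"`, `"PDB"`, `"RAW"`.
#' @return An object of class `hsr_molecule`: a list with elements
#'   `atoms` (data frame with columns `element`, `atomic_number`,
#'   `mass_number`, `formal_charge`, `x`, `y`, `z`), `features`,
#'   `name` and `source_format`.
#' @examples
#' m <- hsr_molecule("C", matrix(0, 1, 3))
#' n_atoms(m)
#' @export
hsr_molecule <- function(elements, coords, charges = 0L, masses = NA_integer_,
                         features = NULL, name = "", source_format = "RAW") {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L)
    stop("coords must have 3 columns (x, y, z)")
  a <- length(elements)
  if (a < 1L) stop("a molecule must contain at least one atom")
  if (nrow(coords) != a)
    stop("coords has ", nrow(coords), " rows for ", a, " atoms")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  info <- element_info(elements)
  charges <- as.integer(rep_len(charges, a))
  masses <- as.integer(rep_len(masses, a))
  bad <- !is.na(masses) & masses < info$atomic_number
  if (any(bad))
    stop("mass number below atomic number for atom(s): ",
         paste(which(bad), collapse = ", "))
  if (!is.null(features)) {
    features <- as.data.frame(features)
    if (nrow(features) != a)
      stop("feature table has ", nrow(features), " rows for ", a, " atoms")
    if (!all(vapply(features, is.numeric, logical(1))))
      stop("feature table columns must be numeric")
  }
  atoms <- data.frame(element = as.character(elements),
                      atomic_number = info$atomic_number,
                      mass_number = masses,
                      formal_charge = charges,
                      x = coords[, 1], y = coords[, 2], z = coords[, 3],
                      stringsAsFactors = FALSE)
  structure(list(atoms = atoms, features = features, name = name,
                 source_format = source_format),
            class = "hsr_molecule")
}

#' Number of atoms in a molecule
#' @param mol An `hsr_molecule`.
#' @return Integer atom count.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

#' Atomic coordinates of a molecule
#' @param mol An `hsr_molecule`.
#' @return Numeric A x 3 matrix of coordinates (Angstrom).
#' @export
coords <- function(mol) {
  as.matrix(mol$atoms[, c("x", "y", "z")])
}

#' Attach a per-atom feature table to a molecule
#'
#' Column names become dimension names available to feature schemes that
#' reference table columns (e.g. the partial-charge dimension of the
#' ElectroShape emulation scheme).
#'
#' @param mol An `hsr_molecule`.
#' @param features Data frame of numeric columns, one row per atom in
#'   atom order.
#' @return The molecule with features attached (existing columns of the
#'   same name are replaced).
#' @export
add_features <- function(mol, features) {
  features <- as.data.frame(features)
  if (nrow(features) != n_atoms(mol))
    stop("feature table has ", nrow(features), " rows but molecule has ",
         n_atoms(mol), " atoms")
  if (!all(vapply(features, is.numeric, logical(1))))
    stop("feature table columns must be numeric")
  if (is.null(mol$features)) {
    mol$features <- features
  } else {
    keep <- setdiff(names(mol$features), names(features))
    mol$features <- cbind(mol$features[, keep, drop = FALSE], features)
  }
  mol
}

#' @export
print.hsr_molecule <- function(x, ...) {
  cat("hsr_molecule", if (nzchar(x$name)) paste0("'", x$name, "'") else "",
      "\n  atoms:", n_atoms(x),
      " source:", x$source_format, "\n")
  counts <- table(x$atoms$element)
  cat("  formula:", paste0(names(counts), ifelse(counts > 1, counts, ""),
                           collapse = ""), "\n")
  if (!is.null(x$features))
    cat("  extra features:", paste(names(x$features), collapse = ", "), "\n")
  invisible(x)
}

# Number of neutrons per atom; atoms without an explicit mass number get
# the most common isotope of their element.
neutron_count <- function(mol) {
  info <- element_info(mol$atoms$element)
  mass <- mol$atoms$mass_number
  mass[is.na(mass)] <- info$most_common_mass_number[is.na(mass)]
  mass - mol$atoms$atomic_number
}
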