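# Structure file I/O. SDF/MOL is restricted to the V2000 dialect so that
# charge (M  CHG) and isotope (M  ISO) semantics are bit-exact; V3000 is
# rejected. PDB parsing goes through bio3d; XYZ is the plain
# "count / comment / element x y z" dialect. Coordinates are Angstrom
# throughout and no unit conversion is ever applied.

#' Read a molecular structure file
#'
#' Reads SDF/MOL (V2000), XYZ or PDB into an [hsr_molecule()]. Hydrogens
#' are used exactly as present in the file; atoms are never added,
#' removed or reordered. Isotopes absent from the file default to the
#' most common natural isotope and absent formal charges to 0.
#'
#' @param path Path to the structure file.
#' @param format `"auto"` (by extension), `"sdf"`, `"xyz"` or `"pdb"`.
#' @return An [hsr_molecule()]. For multi-record SDF files only the first
#'   record is returned (with a warning); use [read_sdf()] for all records.
#' @seealso [write_molecule()], [read_feature_table()]
#' @examples
#' f <- tempfile(fileext = ".xyz")
#' writeLines(c("1", "methane fragment", "C 0.0 0.0 0.0"), f)
#' read_molecule(f)
#' @export
read_molecule <- function(path, format = c("auto", "sdf", "xyz", "pdb")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     sdf = , mol = , mdl = "sdf",
                     xyz = "xyz",
                     pdb = , ent = "pdb",
                     stop("cannot infer format from extension '", ext,
                          "'; pass format= explicitly"))
  }
  switch(format,
         sdf = {
           mols <- read_sdf(path)
           if (length(mols) > 1L)
             warning("file contains ", length(mols),
                     " records; returning the first")
           mols[[1L]]
         },
         xyz = read_xyz(path),
         pdb = read_pdb(path))
}

#' Read all records of an SDF file
#'
#' @param path Path to an SDF or MOL file (V2000 connection tables).
#' @return A list of [hsr_molecule()] objects, one per record.
#' @export
read_sdf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty file: ", path)
  # split into records on $$$$
  breaks <- grep("^\\$\\$\\$\\$", lines)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks - 1L, length(lines))
  keep <- starts <= ends
  recs <- Map(function(s, e) lines[s:e], starts[keep], ends[keep])
  recs <- Filter(function(r) any(nzchar(trimws(r))), recs)
  if (length(recs) == 0L) stop("no records found in ", path)
  lapply(seq_along(recs), function(i)
    parse_molfile(recs[[i]], path, offset = starts[keep][i] - 1L))
}

parse_molfile <- function(lines, path, offset = 0L) {
  if (length(lines) < 4L)
    stop("truncated MOL block in ", path)
  name <- trimws(lines[1L])
  counts <- lines[4L]
  if (grepl("V3000", counts, fixed = TRUE))
    stop("V3000 connection tables are not supported (", path,
         ", line ", offset + 4L, "); please convert to V2000")
  natoms <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(natoms))
    stop("unparseable counts line in ", path, " (line ", offset + 4L, ")")
  if (natoms == 0L) stop("molecule with zero atoms in ", path)
  if (length(lines) < 4L + natoms)
    stop("atom block truncated in ", path)
  atom_lines <- lines[5L:(4L + natoms)]
  xyz <- matrix(NA_real_, natoms, 3L)
  elements <- character(natoms)
  charges <- integer(natoms)
  masses <- rep(NA_integer_, natoms)
  old_charge_code <- c(`1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                       `5` = -1L, `6` = -2L, `7` = -3L)
  for (i in seq_len(natoms)) {
    ln <- atom_lines[i]
    v <- suppressWarnings(c(as.numeric(substr(ln, 1L, 10L)),
                            as.numeric(substr(ln, 11L, 20L)),
                            as.numeric(substr(ln, 21L, 30L))))
    if (any(is.na(v)))
      stop("unparseable atom coordinates in ", path,
           " (line ", offset + 4L + i, ")")
    xyz[i, ] <- v
    elements[i] <- trimws(substr(ln, 32L, 34L))
    code <- suppressWarnings(as.integer(substr(ln, 37L, 39L)))
    if (!is.na(code) && code > 0L)
      charges[i] <- old_charge_code[as.character(code)]
  }
  # properties block: M  CHG / M  ISO supersede atom-block fields
  prop <- lines[-seq_len(4L + natoms + max(nbonds, 0L, na.rm = TRUE))]
  chg_lines <- grep("^M  CHG", prop, value = TRUE)
  iso_lines <- grep("^M  ISO", prop, value = TRUE)
  if (length(chg_lines) > 0L) {
    charges[] <- 0L
    for (ln in chg_lines) {
      f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1L]])
      n <- f[1L]
      for (k in seq_len(n)) {
        idx <- f[2L * k]
        if (is.na(idx) || idx < 1L || idx > natoms)
          stop("M  CHG refers to atom ", idx, " outside molecule in ", path)
        charges[idx] <- f[2L * k + 1L]
      }
    }
  }
  for (ln in iso_lines) {
    f <- as.integer(strsplit(trimws(sub("^M  ISO", "", ln)), "\\s+")[[1L]])
    n <- f[1L]
    for (k in seq_len(n)) {
      idx <- f[2L * k]
      if (is.na(idx) || idx < 1L || idx > natoms)
        stop("M  ISO refers to atom ", idx, " outside molecule in ", path)
      masses[idx] <- f[2L * k + 1L]
    }
  }
  hsr_molecule(elements, xyz, charges = charges, masses = masses,
               name = name, source_format = "SDF")
}

read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1L) stop("empty XYZ file: ", path)
  natoms <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(natoms))
    stop("unparseable atom count in ", path, " (line 1)")
  if (natoms == 0L) stop("molecule with zero atoms in ", path)
  if (length(lines) < 2L + natoms) stop("atom lines truncated in ", path)
  elements <- character(natoms)
  xyz <- matrix(NA_real_, natoms, 3L)
  for (i in seq_len(natoms)) {
    f <- strsplit(trimws(lines[2L + i]), "\\s+")[[1L]]
    if (length(f) < 4L)
      stop("unparseable XYZ atom line in ", path, " (line ", 2L + i, ")")
    elements[i] <- f[1L]
    v <- suppressWarnings(as.numeric(f[2:4]))
    if (any(is.na(v)))
      stop("unparseable coordinates in ", path, " (line ", 2L + i, ")")
    xyz[i, ] <- v
  }
  hsr_molecule(elements, xyz, name = trimws(lines[2L]), source_format = "XYZ")
}

read_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  if (nrow(at) == 0L) stop("no ATOM/HETATM records in ", path)
  elements <- normalize_element(at$elesy)
  charges <- parse_pdb_charge(at$charge)
  hsr_molecule(elements, cbind(at$x, at$y, at$z), charges = charges,
               name = basename(path), source_format = "PDB")
}

# "CL" -> "Cl"; element columns in PDB are upper case
normalize_element <- function(sym) {
  sym <- trimws(sym)
  paste0(toupper(substr(sym, 1L, 1L)), tolower(substring(sym, 2L)))
}

# PDB formal charge strings: "1+", "2-" (columns 79-80)
parse_pdb_charge <- function(ch) {
  out <- integer(length(ch))
  has <- !is.na(ch) & nzchar(trimws(ch))
  val <- suppressWarnings(as.integer(gsub("[+-]", "", trimws(ch[has]))))
  sgn <- ifelse(grepl("-", ch[has]), -1L, 1L)
  out[has] <- ifelse(is.na(val), 0L, val * sgn)
  out
}

#' Write a molecule to SDF (V2000) or XYZ
#'
#' SDF output carries formal charges as `M  CHG` and explicit isotopes as
#' `M  ISO` property lines; coordinates are written with 4 decimals (the
#' V2000 field precision). No bond block is emitted (HSR operates on
#' point clouds, not connectivity).
#'
#' @param mol An [hsr_molecule()].
#' @param path Output path.
#' @param format `"sdf"` or `"xyz"` (default from extension).
#' @return Invisibly, `path`.
#' @export
write_molecule <- function(mol, path, format = c("auto", "sdf", "xyz")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, sdf = , mol = "sdf", xyz = "xyz",
                     stop("cannot infer output format from extension '",
                          ext, "'"))
  }
  a <- mol$atoms
  if (format == "xyz") {
    lines <- c(nrow(a), mol$name,
               sprintf("%-3s %12.6f %12.6f %12.6f", a$element, a$x, a$y, a$z))
    writeLines(lines, path)
    return(invisible(path))
  }
  header <- c(mol$name, "  hsr", "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(a), 0L)
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   a$x, a$y, a$z, a$element)
  props <- character(0)
  chg <- which(a$formal_charge != 0L)
  if (length(chg) > 0L)
    props <- c(props, prop_lines("CHG", chg, a$formal_charge[chg]))
  iso <- which(!is.na(a$mass_number))
  if (length(iso) > 0L)
    props <- c(props, prop_lines("ISO", iso, a$mass_number[iso]))
  writeLines(c(header, counts, atoms, props, "M  END", "$$$$"), path)
  invisible(path)
}

# V2000 property lines hold at most 8 (index, value) pairs each
prop_lines <- function(tag, idx, val) {
  chunks <- split(seq_along(idx), ceiling(seq_along(idx) / 8))
  vapply(chunks, function(ch) {
    pairs <- paste(sprintf("%4d%4d", idx[ch], val[ch]), collapse = "")
    sprintf("M  %s%3d%s", tag, length(ch), pairs)
  }, character(1), USE.NAMES = FALSE)
}

#' Read a per-atom feature table (CSV)
#'
#' Reads a CSV with a header row and one row per atom (in atom order) and
#' validates it against a molecule. Column names become dimension names
#' in schemes that reference them.
#'
#' @param path CSV path.
#' @param mol Optional [hsr_molecule()] to validate row count against.
#' @return A data frame of numeric features; attach with [add_features()].
#' @export
read_feature_table <- function(path, mol = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (j in seq_along(tab)) {
    if (!is.numeric(tab[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(tab[[j]]))))[1L]
      stop("non-numeric value in feature table ", path,
           " at row ", bad, ", column '", names(tab)[j], "'")
    }
  }
  if (!is.null(mol) && nrow(tab) != n_atoms(mol))
    stop("feature table ", path, " has ", nrow(tab),
         " rows but molecule has ", n_atoms(mol), " atoms")
  tab
}
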