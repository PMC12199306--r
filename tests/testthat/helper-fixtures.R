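# Shared helpers: rigid motions, atom permutations, and tiny hand-written
# structure files built in code at test time.

random_rotation <- function(n = 3L) {
  q <- qr.Q(qr(matrix(rnorm(n * n), n, n)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

apply_rigid <- function(mol, rot = diag(3), shift = c(0, 0, 0)) {
  mol$atoms[, c("x", "y", "z")] <- coords(mol) %*% t(rot) +
    matrix(shift, n_atoms(mol), 3L, byrow = TRUE)
  mol
}

reflect_x <- function(mol) {
  mol$atoms$x <- -mol$atoms$x
  mol
}

permute_atoms <- function(mol, perm) {
  mol$atoms <- mol$atoms[perm, , drop = FALSE]
  rownames(mol$atoms) <- NULL
  if (!is.null(mol$features))
    mol$features <- mol$features[perm, , drop = FALSE]
  mol
}

write_lines_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Minimal V2000 record: methane-like fragment with optional property lines
sdf_fixture <- function(props = character(0), natoms = 2L) {
  stopifnot(natoms %in% c(1L, 2L))
  atom_lines <- c(
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.5000    0.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0")
  write_lines_tmp(c("fixture", "  test", "",
                    sprintf("%3d  0  0  0  0  0  0  0  0  0999 V2000", natoms),
                    atom_lines[seq_len(natoms)], props, "M  END", "$$$$"),
                  ".sdf")
}
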