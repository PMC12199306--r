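# Seedable synthetic fixtures. Every generator is a pure function of
# (kind, parameters, seed): the RNG state is saved and restored, so the
# same call is bit-reproducible and never disturbs the caller's stream.
# The fixtures are built to trigger specific code paths by
# construction: a chiral four-point cloud, exact mirror pairs, an
# acetylene-like rod whose first PC has no sign discriminant, a planar
# achiral control, 13C-labelled amine chains of growing length, their
# protonated counterparts, and a one-dihedral conformer sweep whose
# geometry forces the USR closest-to-centroid atom to switch identity
# mid-sweep while the cloud itself deforms smoothly.

with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic test molecule or series
#'
#' Deterministic, seedable fixtures for exercising the pipeline:
#' \describe{
#'   \item{`random_cloud`}{`n_atoms` random atoms (Gaussian coordinates,
#'     random light elements).}
#'   \item{`chiral_tetrahedron`}{four atoms of distinct elements at
#'     jittered asymmetric positions with a nonzero triple product: a
#'     chiral point cloud.}
#'   \item{`mirror_pair`}{a random cloud and its exact x -> -x
#'     reflection (list of two molecules).}
#'   \item{`linear_symmetric`}{an acetylene-like H-C-C-H rod: the cloud
#'     has a mirror plane orthogonal to its first PC, so that axis has
#'     no sign discriminant.}
#'   \item{`planar`}{an achiral control: random atoms in the z = 0
#'     plane.}
#'   \item{`torsion_sweep`}{`n_steps` conformers of a 7-atom cloud in
#'     which one atom rotates about the z axis through a window where
#'     the USR closest-to-centroid atom switches between two
#'     well-separated candidates (list of molecules).}
#'   \item{`isotopologue_series`}{for each chain length in
#'     `chain_lengths`, an amine chain and its 13C-labelled (terminal
#'     carbon) isotopologue: list of `list(parent, labeled)` pairs.
#'     Default lengths grow in steps of two chain atoms so the terminal
#'     carbon keeps the same orientation within the zig-zag: one-atom
#'     increments alternate the end-group parity, which superimposes an
#'     oscillation on the label's size-dependent dilution.}
#'   \item{`protonation_series`}{for each chain length, an amine and
#'     its N-protonated form (one extra H, formal charge +1 on N):
#'     list of `list(base, protonated)` pairs.}
#' }
#'
#' @param kind Fixture kind, see Details.
#' @param n_atoms Atom count (kinds `random_cloud`, `planar`; default 8).
#' @param seed Integer seed; same spec and seed give bit-identical
#'   output.
#' @param n_steps Conformers in a `torsion_sweep` (default 21).
#' @param chain_lengths Carbon counts for the amine series
#'   (default `seq(3, 13, 2)`, a parity-consistent homologous series).
#' @param jitter Coordinate noise (Angstrom) applied to the scaffold of
#'   jittered kinds.
#' @return An [hsr_molecule()] or a list, by kind.
#' @examples
#' pair <- generate_fixture("mirror_pair", n_atoms = 6, seed = 7)
#' all(coords(pair$mirror)[, 1] == -coords(pair$original)[, 1])
#' @export
generate_fixture <- function(kind = c("random_cloud", "chiral_tetrahedron",
                                      "mirror_pair", "torsion_sweep",
                                      "isotopologue_series",
                                      "protonation_series",
                                      "linear_symmetric", "planar"),
                             n_atoms = 8L, seed = 1L, n_steps = 21L,
                             chain_lengths = seq(3L, 13L, 2L),
                             jitter = NULL) {
  kind <- match.arg(kind)
  with_seed(seed, switch(kind,
    random_cloud = fixture_random_cloud(n_atoms, seed),
    chiral_tetrahedron = fixture_chiral_tetrahedron(jitter %||% 0.05, seed),
    mirror_pair = fixture_mirror_pair(n_atoms, seed),
    torsion_sweep = fixture_torsion_sweep(n_steps, jitter %||% 0.005, seed),
    isotopologue_series = fixture_amine_series(chain_lengths, label = TRUE),
    protonation_series = fixture_amine_series(chain_lengths, label = FALSE),
    linear_symmetric = fixture_linear_symmetric(),
    planar = fixture_planar(n_atoms, seed)))
}

fixture_random_cloud <- function(n_atoms, seed) {
  if (n_atoms < 1L) stop("n_atoms must be >= 1")
  elements <- sample(c("C", "N", "O", "S", "P", "F", "Cl"), n_atoms,
                     replace = TRUE)
  xyz <- matrix(stats::rnorm(3L * n_atoms, sd = 1.5), n_atoms, 3L)
  hsr_molecule(elements, xyz, name = sprintf("cloud_s%d", seed))
}

fixture_chiral_tetrahedron <- function(jitter, seed) {
  base <- rbind(c(0, 0, 0), c(1.5, 0.1, 0), c(0.2, 1.4, 0.1),
                c(0.3, 0.4, 1.6))
  xyz <- base + matrix(stats::rnorm(12, sd = jitter), 4L, 3L)
  v <- sweep(xyz[2:4, ], 2L, xyz[1L, ])
  if (abs(det(v)) < 1e-3)
    stop("degenerate chiral tetrahedron (near-coplanar); change the seed")
  hsr_molecule(c("H", "C", "N", "O"), xyz,
               name = sprintf("chiral_tet_s%d", seed))
}

fixture_mirror_pair <- function(n_atoms, seed) {
  a <- fixture_random_cloud(n_atoms, seed)
  a$name <- sprintf("mirror_orig_s%d", seed)
  b <- a
  b$atoms$x <- -b$atoms$x
  b$name <- sprintf("mirror_refl_s%d", seed)
  list(original = a, mirror = b)
}

fixture_linear_symmetric <- function() {
  x <- c(-1.6615, -0.6015, 0.6015, 1.6615)
  hsr_molecule(c("H", "C", "C", "H"), cbind(x, 0, 0),
               name = "linear_symmetric")
}

fixture_planar <- function(n_atoms, seed) {
  if (n_atoms < 3L) stop("planar fixture needs >= 3 atoms")
  elements <- sample(c("C", "N", "O"), n_atoms, replace = TRUE)
  xy <- matrix(stats::rnorm(2L * n_atoms, sd = 1.5), n_atoms, 2L)
  hsr_molecule(elements, cbind(xy, 0), name = sprintf("planar_s%d", seed))
}

# Torsion-sweep scaffold. Two candidate closest-to-centroid atoms (P1,
# P2, ~1.4 A apart) sit near the centre; the rotor atom M circles at
# radius 5, dragging the centroid across the perpendicular bisector
# plane of P1-P2 at theta* ~ 2.385 rad. The sweep window theta* +/-
# 0.08 rad brackets the crossing for small scaffold jitter, so the USR
# ctc selection switches between two well-separated atoms (a jump in
# its distance distribution) while the cloud itself moves smoothly. M
# stays the farthest-from-centroid atom throughout.
fixture_torsion_sweep <- function(n_steps, jitter, seed) {
  if (n_steps < 3L) stop("torsion sweep needs >= 3 steps")
  base <- rbind(S1 = c(3.0, 2.0, 1.0),
                S2 = c(-2.5, 2.8, -0.8),
                S3 = c(1.2, -3.1, 1.8),
                S4 = c(-1.0, -1.5, -2.2),
                P1 = c(0.55, 0.35, 0.15),
                P2 = c(-0.5, -0.4, -0.2))
  base <- base + matrix(stats::rnorm(18, sd = jitter), 6L, 3L)
  r <- 5 + stats::rnorm(1, sd = jitter)
  z_m <- 0.5 + stats::rnorm(1, sd = jitter)
  elements <- c("C", "N", "O", "C", "C", "N", "S")
  theta <- seq(2.385 - 0.08, 2.385 + 0.08, length.out = n_steps)
  lapply(seq_len(n_steps), function(i) {
    m <- c(r * cos(theta[i]), r * sin(theta[i]), z_m)
    hsr_molecule(elements, rbind(base, M = m),
                 name = sprintf("sweep_s%d_step%02d", seed, i))
  })
}

# Amine chains: N head plus k chain carbons on a gently twisted
# zig-zag (non-planar, no accidental symmetry). label = TRUE pairs each
# chain with its 13C-labelled terminal carbon; label = FALSE pairs it
# with the N-protonated (extra H, charge +1) form.
fixture_amine_series <- function(chain_lengths, label) {
  stopifnot(all(chain_lengths >= 1L))
  lapply(stats::setNames(chain_lengths, paste0("k", chain_lengths)),
         function(k) {
    i <- 0:k
    xyz <- cbind(1.3 * i, 0.6 * (i %% 2), 0.1 * sin(1.7 * i))
    elements <- c("N", rep("C", k))
    parent <- hsr_molecule(elements, xyz, name = sprintf("amine_k%d", k))
    if (label) {
      labeled <- parent
      labeled$atoms$mass_number[k + 1L] <- 13L
      labeled$name <- sprintf("amine_k%d_13C", k)
      list(parent = parent, labeled = labeled)
    } else {
      prot <- hsr_molecule(c(elements, "H"),
                           rbind(xyz, c(-0.95, 0.35, 0.2)),
                           charges = c(1L, rep(0L, k + 1L)),
                           name = sprintf("amine_k%d_H", k))
      list(base = parent, protonated = prot)
    }
  })
}

#' Write a fixture (or fixture list) as structure files
#'
#' Flattens nested fixture lists and writes each molecule through the
#' regular I/O layer, so tests that read them back exercise the real
#' file entry path.
#'
#' @param x An [hsr_molecule()] or (nested) list of them.
#' @param dir Output directory (created if needed).
#' @param format `"sdf"` or `"xyz"`.
#' @return Character vector of paths written.
#' @export
write_fixture_set <- function(x, dir, format = c("sdf", "xyz")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mols <- flatten_molecules(x)
  vapply(mols, function(m) {
    path <- file.path(dir, paste0(gsub("[^A-Za-z0-9_.-]", "_", m$name),
                                  ".", format))
    write_molecule(m, path, format = format)
    path
  }, character(1))
}

flatten_molecules <- function(x) {
  if (inherits(x, "hsr_molecule")) return(list(x))
  unlist(lapply(x, flatten_molecules), recursive = FALSE)
}
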