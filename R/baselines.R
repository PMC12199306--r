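# Heuristic-reference baselines. USR measures distances from four
# reference points anchored on the molecule itself: the centroid (ctd),
# the atom closest to it (ctc), the atom farthest from it (ftc) and the
# atom farthest from ftc (ftf). CSR swaps the ctc distribution for one
# measured from a cross-product point, which is not reflection
# invariant, and USR:OptIso instead appends a scalar triple product as a
# 13th descriptor. Because reference points sit on atoms, all heuristic
# selections can be ambiguous under symmetry: ties are broken by lowest
# atom index and recorded, so output is deterministic for a given input
# order even when the geometry alone would not decide.

#' USR reference points of a molecule
#'
#' @param mol An [hsr_molecule()].
#' @param tol Absolute tolerance (Angstrom) for detecting tied
#'   atom-selection distances.
#' @return List with the four 3-vectors `ctd`, `ctc`, `ftc`, `ftf`, the
#'   selected atom indices `ctc_idx`, `ftc_idx`, `ftf_idx`, and `tie`
#'   (TRUE when any selection was tied and fell back to lowest index).
#' @export
usr_reference_points <- function(mol, tol = 1e-6) {
  xyz <- coords(mol)
  ctd <- colMeans(xyz)
  d_ctd <- sqrt(rowSums(sweep(xyz, 2L, ctd)^2))
  ctc_idx <- which.min(d_ctd)
  ftc_idx <- which.max(d_ctd)
  d_ftc <- sqrt(rowSums(sweep(xyz, 2L, xyz[ftc_idx, ])^2))
  ftf_idx <- which.max(d_ftc)
  tie <- sum(abs(d_ctd - d_ctd[ctc_idx]) <= tol) > 1L ||
    sum(abs(d_ctd - d_ctd[ftc_idx]) <= tol) > 1L ||
    sum(abs(d_ftc - d_ftc[ftf_idx]) <= tol) > 1L
  list(ctd = ctd, ctc = xyz[ctc_idx, ], ftc = xyz[ftc_idx, ],
       ftf = xyz[ftf_idx, ], ctc_idx = ctc_idx, ftc_idx = ftc_idx,
       ftf_idx = ftf_idx, tie = tie)
}

usr_moments <- function(xyz, refs, skewness) {
  as.vector(vapply(refs, function(r) {
    d <- sqrt(rowSums(sweep(xyz, 2L, r)^2))
    moment_triplet(d, convention = skewness)
  }, numeric(3)))
}

#' USR fingerprint (12 moments)
#'
#' Mean, standard deviation and skewness of the distance distributions
#' from `ctd`, `ctc`, `ftc` and `ftf` to all atoms, in that order.
#' Invariant to rotation, translation, reflection and (given the
#' tie-break) atom permutation; enantiomers are indistinguishable.
#'
#' @param mol An [hsr_molecule()].
#' @param skewness Skewness convention, see [moment_triplet()].
#' @return An `hsr_fingerprint` of length 12, method `"USR"`; the
#'   `extra` attribute records whether a tie occurred.
#' @export
usr_fingerprint <- function(mol, skewness = c("standardized", "cube_root")) {
  skewness <- match.arg(skewness)
  rp <- usr_reference_points(mol)
  if (rp$tie)
    warning("tied USR reference-atom selection in '", mol$name,
            "'; lowest atom index used")
  vals <- usr_moments(coords(mol), rp[c("ctd", "ctc", "ftc", "ftf")], skewness)
  new_fingerprint(vals, method = "USR", n_dims = 3L, scheme_name = "3d",
                  chirality = FALSE, skewness = skewness, name = mol$name,
                  extra = list(tie = rp$tie))
}

#' CSR cross-product reference point
#'
#' The chirality-sensitive reference point of CSR:
#' `ctd + (ctd->ftc) x (ctd->ftf)`. Under reflection the cross product
#' flips to the other side of the ftc/ftf plane, so enantiomers get one
#' differing distance distribution.
#'
#' @param mol An [hsr_molecule()].
#' @param tol Degeneracy tolerance on the cross-product norm.
#' @return List with `point` (3-vector) and `degenerate` (TRUE when the
#'   cross product vanished and the USR `ctc` point was used instead,
#'   with a warning).
#' @export
csr_reference <- function(mol, tol = 1e-8) {
  rp <- usr_reference_points(mol)
  v1 <- rp$ftc - rp$ctd
  v2 <- rp$ftf - rp$ctd
  cp <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  if (sqrt(sum(cp^2)) < tol) {
    warning("degenerate CSR geometry (collinear ctd/ftc/ftf) in '",
            mol$name, "'; falling back to the USR ctc point")
    return(list(point = rp$ctc, degenerate = TRUE))
  }
  list(point = rp$ctd + cp, degenerate = FALSE)
}

#' CSR fingerprint (12 moments, chirality-sensitive)
#'
#' As USR, but the `ctc` distribution is replaced by distances from the
#' cross-product reference point; order: `ctd`, `ftc`, `ftf`, cross.
#'
#' @inheritParams usr_fingerprint
#' @return An `hsr_fingerprint` of length 12, method `"CSR"`.
#' @export
csr_fingerprint <- function(mol, skewness = c("standardized", "cube_root")) {
  skewness <- match.arg(skewness)
  rp <- usr_reference_points(mol)
  cr <- csr_reference(mol)
  vals <- usr_moments(coords(mol),
                      list(rp$ctd, rp$ftc, rp$ftf, cr$point), skewness)
  new_fingerprint(vals, method = "CSR", n_dims = 3L, scheme_name = "3d",
                  chirality = TRUE, skewness = skewness, name = mol$name,
                  extra = list(tie = rp$tie, degenerate = cr$degenerate))
}

#' USR:OptIso chirality descriptor
#'
#' The scalar triple product `(ctd->ctc) . ((ctd->ftc) x (ctd->ftf))`:
#' zero for planar molecules, negated by reflection.
#'
#' @param mol An [hsr_molecule()].
#' @return A single real number.
#' @export
optiso_descriptor <- function(mol) {
  rp <- usr_reference_points(mol)
  a <- rp$ctc - rp$ctd
  b <- rp$ftc - rp$ctd
  d <- rp$ftf - rp$ctd
  cp <- c(b[2] * d[3] - b[3] * d[2],
          b[3] * d[1] - b[1] * d[3],
          b[1] * d[2] - b[2] * d[1])
  sum(a * cp)
}

#' USR:OptIso fingerprint (12 USR moments + triple product, K = 13)
#'
#' @inheritParams usr_fingerprint
#' @return An `hsr_fingerprint` of length 13, method `"OPTISO"`.
#' @export
optiso_fingerprint <- function(mol, skewness = c("standardized", "cube_root")) {
  skewness <- match.arg(skewness)
  usr <- usr_fingerprint(mol, skewness = skewness)
  new_fingerprint(c(as.numeric(usr), optiso_descriptor(mol)),
                  method = "OPTISO", n_dims = 3L, scheme_name = "3d",
                  chirality = TRUE, skewness = skewness, name = mol$name,
                  extra = attr(usr, "extra"))
}

#' Simple atom-type predicates for subset fingerprints
#'
#' A deliberately simple, element-based predicate set (explicitly not
#' the Credo SMARTS types of the USRCAT paper, which require bond
#' perception that breaks down for inorganics): `hydrophobic` (carbon
#' and the heavier halogens), `aromatic` (pass-through of a user
#' supplied 0/1 `aromatic` feature column, empty when absent), `donor`
#' (N, O, S) and `acceptor` (N, O, F). Each predicate maps a molecule
#' to a logical vector over atoms.
#'
#' @return Named list of predicate functions.
#' @export
default_predicates <- function() {
  list(
    hydrophobic = function(mol) mol$atoms$element %in% c("C", "Cl", "Br", "I"),
    aromatic = function(mol) {
      if (!is.null(mol$features) && "aromatic" %in% names(mol$features))
        mol$features$aromatic > 0
      else rep(FALSE, n_atoms(mol))
    },
    donor = function(mol) mol$atoms$element %in% c("N", "O", "S"),
    acceptor = function(mol) mol$atoms$element %in% c("N", "O", "F")
  )
}

#' Subset (USRCAT-style) fingerprint
#'
#' A 12-moment block for the full atom set followed by one block per
#' atom-type predicate subset: 60 moments with the four default
#' predicates. The `"usr"` engine computes each block with the USR
#' heuristic on the subset; the `"hsr"` engine uses the PCA-based 3D
#' pipeline instead (the deterministic emulation mode). A predicate
#' matching no atoms contributes a block of 12 zeros so fingerprint
#' length, and hence the normalization K, is fixed across a set.
#'
#' @param mol An [hsr_molecule()].
#' @param predicates Named list of predicate functions
#'   (default [default_predicates()]).
#' @param engine `"usr"` or `"hsr"`.
#' @param skewness Skewness convention.
#' @return An `hsr_fingerprint` of length `12 * (1 + length(predicates))`,
#'   method `"USRCAT_EMU"`.
#' @export
subset_fingerprint <- function(mol, predicates = default_predicates(),
                               engine = c("usr", "hsr"),
                               skewness = c("standardized", "cube_root")) {
  engine <- match.arg(engine)
  skewness <- match.arg(skewness)
  block <- function(m) {
    if (engine == "usr") as.numeric(usr_fingerprint(m, skewness = skewness))
    else as.numeric(hsr_fingerprint(m, scheme = "3d", skewness = skewness))
  }
  vals <- block(mol)
  for (p in predicates) {
    sel <- p(mol)
    vals <- c(vals, if (!any(sel)) rep(0, 12) else {
      sub <- mol
      sub$atoms <- mol$atoms[sel, , drop = FALSE]
      if (!is.null(mol$features))
        sub$features <- mol$features[sel, , drop = FALSE]
      block(sub)
    })
  }
  new_fingerprint(vals, method = "USRCAT_EMU", n_dims = 3L,
                  scheme_name = paste0("subset-", engine),
                  chirality = FALSE, skewness = skewness, name = mol$name,
                  extra = list(engine = engine,
                               predicates = names(predicates)))
}

#' ElectroShape-style fingerprint via the hypershape engine
#'
#' The PCA-based pipeline on the `"electroshape4d"` scheme: Cartesian
#' coordinates plus an unscaled, user-supplied `partial_charge` feature
#' column (15 moments). Partial charges are never computed here; attach
#' them with [add_features()] or [read_feature_table()].
#'
#' @param mol An [hsr_molecule()] with a `partial_charge` feature
#'   column.
#' @param ... Passed to [hsr_fingerprint()].
#' @return An `hsr_fingerprint` of length 15, method
#'   `"ELECTROSHAPE_EMU"`.
#' @export
electroshape_fingerprint <- function(mol, ...) {
  hsr_fingerprint(mol, scheme = "electroshape4d",
                  method_tag = "ELECTROSHAPE_EMU", ...)
}
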