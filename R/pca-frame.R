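# The deterministic principal-component reference frame. Eigenvectors of
# the population covariance of the centred hypershape are ordered by
# descending |eigenvalue| and each axis is given a deterministic sign by
# the orientation cascade: walk the projections by descending magnitude,
# skip symmetric +/- pairs, and flip the axis if the first unpaired
# projection is negative. Axes whose projections are fully symmetric
# (a mirror plane orthogonal to the axis, as in acetylene's molecular
# axis) are left unflipped and flagged: their sign cannot matter.
#
# Bookkeeping for enantiomer discrimination: det_i is the determinant
# sign of the eigenvector matrix before orientation, n_c the number of
# flips, and det_f = det_i * (-1)^n_c afterwards. Chirality enforcement
# flips one more axis (the one with the most skewed projections) when
# det_f = -1, so mirror images end up with non-mirror frames.

#' Centre a hypershape
#'
#' @param h A `hypershape` matrix (or any numeric matrix).
#' @return List with `centered` (column means removed) and `centroid`.
#' @export
center_hypershape <- function(h) {
  m <- unclass(as.matrix(h))
  centroid <- colMeans(m)
  list(centered = sweep(m, 2L, centroid), centroid = centroid)
}

#' Principal axes of a centred hypershape
#'
#' Eigendecomposition of the population covariance (divisor A, not
#' A - 1; eigenvectors are unaffected, only the eigenvalue scale).
#' Axes are ordered by descending absolute eigenvalue; ties are broken
#' by descending largest absolute projection, then by original column
#' order, so symmetric molecules still get a deterministic frame.
#' A single atom or an all-identical cloud yields all-zero eigenvalues
#' and an identity basis flagged as degenerate.
#'
#' @param centered Centred A x N matrix (column means ~ 0).
#' @return List with `axes` (N x N orthonormal, columns = PCs),
#'   `eigenvalues` (nonincreasing in absolute value) and `degenerate`.
#' @export
principal_axes <- function(centered) {
  centered <- as.matrix(centered)
  a <- nrow(centered)
  n <- ncol(centered)
  if (max(abs(colMeans(centered))) > 1e-8 * max(1, max(abs(centered))))
    stop("input is not centred; call center_hypershape() first")
  cv <- crossprod(centered) / a
  scale <- max(abs(cv))
  if (scale < 1e-14) {
    return(list(axes = diag(n), eigenvalues = rep(0, n), degenerate = TRUE))
  }
  eig <- eigen(cv, symmetric = TRUE)
  vals <- eig$values
  vecs <- eig$vectors
  # order by |eigenvalue| desc with deterministic tie-breaks
  scores <- centered %*% vecs
  maxabs <- apply(abs(scores), 2L, max)
  grp <- tie_groups(-abs(vals), tol = 1e-9 * max(1, max(abs(vals))))
  ord <- order(grp, -maxabs, seq_len(n))
  list(axes = vecs[, ord, drop = FALSE], eigenvalues = vals[ord],
       degenerate = FALSE)
}

# integer group labels for values equal within tol, in given order
tie_groups <- function(v, tol) {
  o <- order(v)
  g <- integer(length(v))
  lab <- 1L
  g[o[1L]] <- lab
  for (i in seq_along(o)[-1L]) {
    if (v[o[i]] - v[o[i - 1L]] > tol) lab <- lab + 1L
    g[o[i]] <- lab
  }
  g
}

#' Orient principal axes by the projection-sign cascade
#'
#' For each axis the projections (PCA scores) are sorted by descending
#' magnitude. Walking down, a projection whose magnitude is matched by a
#' projection of opposite sign (a symmetric pair, within
#' `tolerance * max(1, |score|)` on the pair sum) is skipped together
#' with its partner; the first unpaired projection decides: negative
#' means the axis is flipped (counted in `n_c`). If the walk exhausts
#' all projections the axis is undetermined -- the cloud has a mirror
#' plane orthogonal to it -- and is left unflipped and flagged.
#'
#' @param axes N x N orthonormal matrix (columns = PCs, significance
#'   order).
#' @param eigenvalues Eigenvalues matching `axes`.
#' @param centered Centred hypershape matrix.
#' @param tolerance Relative tolerance for symmetric-pair detection
#'   (default 1e-4, roughly the coordinate noise of crystal structures).
#' @param degenerate Degenerate-frame flag from [principal_axes()].
#' @return An object of class `pc_frame`: list with `axes`,
#'   `eigenvalues`, `scores` (A x N oriented projections), `n_c`,
#'   `det_i`, `det_f`, `undetermined_axes` (integer vector),
#'   `chirality_enforced`, `degenerate`.
#' @export
orient_axes <- function(axes, eigenvalues, centered, tolerance = 1e-4,
                        degenerate = FALSE) {
  axes <- as.matrix(axes)
  n <- ncol(axes)
  if (max(abs(crossprod(axes) - diag(n))) > 1e-10)
    stop("axes are not orthonormal")
  det_i <- sign_det(axes)
  scores <- as.matrix(centered) %*% axes
  n_c <- 0L
  undetermined <- integer(0)
  for (k in seq_len(n)) {
    dec <- cascade_decision(scores[, k], tolerance)
    if (is.na(dec)) {
      undetermined <- c(undetermined, k)
    } else if (dec) {
      axes[, k] <- -axes[, k]
      scores[, k] <- -scores[, k]
      n_c <- n_c + 1L
    }
  }
  det_f <- sign_det(axes)
  stopifnot(det_f == det_i * (-1L)^n_c)
  structure(list(axes = axes, eigenvalues = eigenvalues, scores = scores,
                 centroid = NULL, n_c = n_c, det_i = det_i, det_f = det_f,
                 undetermined_axes = undetermined,
                 chirality_enforced = FALSE, degenerate = degenerate),
            class = "pc_frame")
}

sign_det <- function(m) if (det(m) >= 0) 1L else -1L

# One axis of the orientation cascade. Returns TRUE (flip), FALSE (keep)
# or NA (undetermined: all projections are paired or negligible).
cascade_decision <- function(s, tolerance) {
  o <- order(-abs(s), seq_along(s))
  consumed <- logical(length(s))
  ztol <- tolerance * max(1, max(abs(s)))
  for (ii in seq_along(o)) {
    i <- o[ii]
    if (consumed[i]) next
    if (abs(s[i]) <= ztol) return(NA)  # remaining scores are all ~0
    paired <- FALSE
    for (jj in seq_along(o)[-seq_len(ii)]) {
      j <- o[jj]
      if (consumed[j]) next
      if (abs(s[j]) < abs(s[i]) - tolerance * max(1, abs(s[i]))) break
      if (abs(s[i] + s[j]) <= tolerance * max(1, abs(s[i]))) {
        consumed[i] <- consumed[j] <- TRUE
        paired <- TRUE
        break
      }
    }
    if (!paired) return(s[i] < 0)
  }
  NA
}

#' Enforce a +1 determinant on an oriented frame
#'
#' If `det_f` is already +1 the frame is returned unchanged. Otherwise
#' the axis whose projection scores are most skewed (largest absolute
#' skewness, standardized by default) is flipped once more, making the
#' determinant +1 and the frames of two enantiomers no longer mirror
#' images. Undetermined axes are never chosen (their scores are
#' symmetric, so their skewness is ~0 and their sign is meaningless);
#' ties go to the lowest axis index. If every axis is undetermined, or
#' any retained axis is undetermined (the cloud has a mirror symmetry or
#' a constant dimension, so enantiomer comparison is ill-posed), a
#' warning is emitted and the frame is returned unchanged.
#'
#' @param frame A `pc_frame`.
#' @param measure `"standardized"` (third central moment over sd^3) or
#'   `"third_moment"` (raw third central moment) as the skewness used to
#'   pick the axis.
#' @return The frame, with `chirality_enforced = TRUE` when applied.
#' @export
enforce_chirality <- function(frame, measure = c("standardized", "third_moment")) {
  measure <- match.arg(measure)
  if (length(frame$undetermined_axes) > 0L || frame$degenerate) {
    warning("chirality not applicable: frame has undetermined or ",
            "degenerate axes (mirror-symmetric or constant dimensions)")
    return(frame)
  }
  if (frame$det_f == 1L) {
    frame$chirality_enforced <- TRUE
    return(frame)
  }
  skew <- apply(frame$scores, 2L, score_skewness, measure = measure)
  k <- which.max(abs(skew))  # ties: which.max takes the lowest index
  frame$axes[, k] <- -frame$axes[, k]
  frame$scores[, k] <- -frame$scores[, k]
  frame$n_c <- frame$n_c + 1L
  frame$det_f <- sign_det(frame$axes)
  stopifnot(frame$det_f == 1L)
  frame$chirality_enforced <- TRUE
  frame
}

score_skewness <- function(s, measure) {
  m <- mean(s)
  m2 <- mean((s - m)^2)
  m3 <- mean((s - m)^3)
  if (measure == "third_moment") return(m3)
  if (m2 <= 0) 0 else m3 / m2^1.5
}

#' Full deterministic reference frame of a hypershape
#'
#' Convenience pipeline: centre, eigendecompose, orient, and optionally
#' enforce chirality. This is the frame from which reference points and
#' fingerprints are derived.
#'
#' @param h A `hypershape` (or molecule, in which case `scheme` is
#'   applied first).
#' @param scheme Scheme used when `h` is a molecule.
#' @param chirality Enforce a +1 determinant (default `FALSE`: mirror
#'   images then receive identical fingerprints).
#' @param symmetry_tolerance Relative tolerance of the symmetric-pair
#'   cascade.
#' @param skewness_measure Axis-choice measure for chirality
#'   enforcement, see [enforce_chirality()].
#' @return A `pc_frame` with the hypershape centroid attached.
#' @examples
#' m <- hsr_molecule(c("C", "N", "O", "H"),
#'                   rbind(c(0, 0, 0), c(1.5, 0.1, 0),
#'                         c(0.2, 1.4, 0.1), c(0.3, 0.4, 1.6)))
#' f <- pc_frame(build_hypershape(m, "3d"))
#' f$eigenvalues
#' @export
pc_frame <- function(h, scheme = "default6d", chirality = FALSE,
                     symmetry_tolerance = 1e-4,
                     skewness_measure = c("standardized", "third_moment")) {
  if (inherits(h, "hsr_molecule")) h <- build_hypershape(h, scheme)
  cen <- center_hypershape(h)
  pa <- principal_axes(cen$centered)
  frame <- orient_axes(pa$axes, pa$eigenvalues, cen$centered,
                       tolerance = symmetry_tolerance,
                       degenerate = pa$degenerate)
  frame$centroid <- cen$centroid
  if (chirality)
    frame <- enforce_chirality(frame, measure = match.arg(skewness_measure))
  frame
}

#' @export
print.pc_frame <- function(x, ...) {
  n <- ncol(x$axes)
  cat("pc_frame: ", n, " axes, ", nrow(x$scores), " atoms\n",
      "  eigenvalues: ", paste(signif(x$eigenvalues, 4), collapse = ", "),
      "\n  n_c = ", x$n_c, ", det_i = ", x$det_i, ", det_f = ", x$det_f,
      if (x$chirality_enforced) " (chirality enforced)", "\n", sep = "")
  if (length(x$undetermined_axes) > 0L)
    cat("  undetermined axes:", paste(x$undetermined_axes, collapse = ", "),
        "\n")
  if (x$degenerate) cat("  degenerate frame (no variance)\n")
  invisible(x)
}
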