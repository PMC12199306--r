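# Fingerprint assembly. In the PC coordinate system the N+1 reference
# points are the geometric centre (the origin) plus, on each axis, a
# point at the largest positive projection of the atoms on that axis
# (optionally rescaled). The Euclidean distances in N-space from each
# reference point to every atom form N+1 distributions; their first
# three moments (mean, population standard deviation, skewness),
# concatenated centre-first then per axis in significance order, give
# the 3(N+1)-number fingerprint: 12 values for a pure-3D scheme, 21 for
# the default 6D scheme. Zero-variance axes keep their (duplicate of
# centre) triplet so fingerprint length is fixed across a comparison
# set.

#' Reference points of an oriented frame
#'
#' @param frame A `pc_frame`.
#' @param scale Multiplier on the non-centre reference distances
#'   (default 1: the point sits exactly at the largest projection).
#' @return An (N+1) x N matrix of points in PC coordinates; row 1 is the
#'   centre. An axis with no positive extent (zero variance) yields a
#'   point at the origin, duplicating the centre.
#' @export
reference_points <- function(frame, scale = 1) {
  n <- ncol(frame$scores)
  refs <- matrix(0, n + 1L, n)
  for (k in seq_len(n)) {
    m <- max(frame$scores[, k])
    if (m > 1e-12 * max(1, max(abs(frame$scores))))
      refs[k + 1L, k] <- m * scale
  }
  refs
}

#' Distance distributions from reference points to atoms
#'
#' @param scores A x N matrix of atom projections (PC coordinates).
#' @param refs (N+1) x N reference-point matrix from
#'   [reference_points()].
#' @return An A x (N+1) matrix; column j holds the Euclidean N-space
#'   distances from reference point j to every atom.
#' @export
distance_distributions <- function(scores, refs) {
  scores <- as.matrix(scores)
  refs <- as.matrix(refs)
  out <- matrix(0, nrow(scores), nrow(refs))
  for (j in seq_len(nrow(refs)))
    out[, j] <- sqrt(rowSums(sweep(scores, 2L, refs[j, ])^2))
  out
}

#' First three moments of a distance distribution
#'
#' Mean, population standard deviation and skewness. The default
#' skewness is the standardized third central moment
#' \eqn{m_3 / m_2^{3/2}} (0 whenever the variance is 0); the
#' `"cube_root"` convention, \eqn{\mathrm{sign}(m_3)|m_3|^{1/3}}, is the
#' one used in parts of the USR literature and is provided for strict
#' emulation.
#'
#' @param d Numeric vector of distances (length >= 1).
#' @param convention `"standardized"` or `"cube_root"`.
#' @return Numeric triplet `(mean, std, skewness)`.
#' @examples
#' moment_triplet(c(0, 0, 3))  # (1, sqrt(2), 2 / 2^1.5)
#' @export
moment_triplet <- function(d, convention = c("standardized", "cube_root")) {
  convention <- match.arg(convention)
  if (length(d) < 1L) stop("empty distance distribution")
  m1 <- mean(d)
  m2 <- mean((d - m1)^2)
  m3 <- mean((d - m1)^3)
  skew <- if (convention == "cube_root") {
    sign(m3) * abs(m3)^(1 / 3)
  } else if (m2 <= 0) 0 else m3 / m2^1.5
  c(mean = m1, std = sqrt(m2), skewness = skew)
}

new_fingerprint <- function(values, method, n_dims, scheme_name, chirality,
                            skewness, name = "", extra = list()) {
  structure(as.numeric(values), class = "hsr_fingerprint",
            method = method, n_dims = n_dims, scheme_name = scheme_name,
            chirality = chirality, skewness = skewness, mol_name = name,
            extra = extra)
}

#' Hypershape fingerprint of a molecule
#'
#' End-to-end pipeline: build the hypershape under a scheme, centre it,
#' compute and orient the principal axes (optionally enforcing a +1
#' determinant for enantiomer discrimination), place the N+1 reference
#' points, and collect the 3(N+1) moments.
#'
#' @param x An [hsr_molecule()] or a `hypershape` matrix.
#' @param scheme Feature scheme (name or `hsr_scheme`); ignored when `x`
#'   is already a hypershape.
#' @param chirality Enforce determinant +1 (default `FALSE`).
#' @param symmetry_tolerance Symmetric-pair tolerance of the orientation
#'   cascade.
#' @param skewness Skewness convention, see [moment_triplet()].
#' @param ref_scale Reference-distance multiplier, see
#'   [reference_points()].
#' @param method_tag Method label recorded in the fingerprint (used by
#'   emulation wrappers).
#' @return An `hsr_fingerprint`: numeric vector of length 3(N+1) with
#'   metadata attributes (`method`, `n_dims`, `scheme_name`,
#'   `chirality`, `skewness`) and diagnostic `extra` attributes
#'   (`undetermined_axes`, `degenerate`).
#' @examples
#' m <- hsr_molecule(c("C", "N", "O", "H"),
#'                   rbind(c(0, 0, 0), c(1.5, 0.1, 0),
#'                         c(0.2, 1.4, 0.1), c(0.3, 0.4, 1.6)))
#' length(hsr_fingerprint(m))            # 21 (default 6D scheme)
#' length(hsr_fingerprint(m, "3d"))      # 12
#' @export
hsr_fingerprint <- function(x, scheme = "default6d", chirality = FALSE,
                            symmetry_tolerance = 1e-4,
                            skewness = c("standardized", "cube_root"),
                            ref_scale = 1, method_tag = "HSR") {
  skewness <- match.arg(skewness)
  if (inherits(x, "hsr_molecule")) {
    name <- x$name
    h <- build_hypershape(x, scheme)
  } else {
    h <- x
    name <- attr(h, "mol_name") %||% ""
  }
  frame <- pc_frame(h, chirality = chirality,
                    symmetry_tolerance = symmetry_tolerance)
  refs <- reference_points(frame, scale = ref_scale)
  dists <- distance_distributions(frame$scores, refs)
  values <- as.vector(apply(dists, 2L, moment_triplet,
                            convention = skewness))
  new_fingerprint(values, method = method_tag, n_dims = ncol(frame$scores),
                  scheme_name = attr(h, "scheme_name") %||% "custom",
                  chirality = frame$chirality_enforced, skewness = skewness,
                  name = name,
                  extra = list(undetermined_axes = frame$undetermined_axes,
                               degenerate = frame$degenerate,
                               n_c = frame$n_c, det_f = frame$det_f))
}

#' @export
print.hsr_fingerprint <- function(x, ...) {
  nm <- attr(x, "mol_name")
  cat(attr(x, "method"), " fingerprint",
      if (nzchar(nm)) paste0(" '", nm, "'"),
      "\n  length ", length(x), ", scheme '", attr(x, "scheme_name"),
      "', chirality ", if (isTRUE(attr(x, "chirality"))) "on" else "off",
      "\n", sep = "")
  print(round(as.numeric(x), 4))
  invisible(x)
}

#' Write fingerprints to CSV or JSON
#'
#' CSV has one row per fingerprint (`name`, `method`, `n_dims`,
#' `chirality`, `skewness`, `scheme`, then `v1..vK`); JSON keeps full
#' metadata per record.
#'
#' @param fps A single `hsr_fingerprint` or a list of them.
#' @param path Output path.
#' @param format `"csv"` or `"json"` (default from extension).
#' @return Invisibly, `path`.
#' @export
write_fingerprints <- function(fps, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "json") "json" else "csv"
  if (inherits(fps, "hsr_fingerprint")) fps <- list(fps)
  if (format == "json") {
    recs <- lapply(fps, function(fp) list(
      name = attr(fp, "mol_name"), method = attr(fp, "method"),
      n_dims = attr(fp, "n_dims"), scheme = attr(fp, "scheme_name"),
      chirality = isTRUE(attr(fp, "chirality")),
      skewness = attr(fp, "skewness"), values = as.numeric(fp)))
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  } else {
    df <- fingerprint_table(fps)
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

fingerprint_table <- function(fps) {
  k <- unique(vapply(fps, length, 1L))
  if (length(k) != 1L) stop("fingerprints have differing lengths")
  vals <- do.call(rbind, lapply(fps, as.numeric))
  colnames(vals) <- paste0("v", seq_len(k))
  data.frame(name = vapply(fps, attr, "", "mol_name"),
             method = vapply(fps, attr, "", "method"),
             n_dims = vapply(fps, function(f) as.integer(attr(f, "n_dims")), 1L),
             chirality = vapply(fps, function(f) isTRUE(attr(f, "chirality")), TRUE),
             skewness = vapply(fps, attr, "", "skewness"),
             scheme = vapply(fps, attr, "", "scheme_name"),
             vals, stringsAsFactors = FALSE)
}

#' Read fingerprints written by [write_fingerprints()]
#' @param path CSV or JSON path.
#' @return A list of `hsr_fingerprint` objects.
#' @export
read_fingerprints <- function(path) {
  if (tolower(tools::file_ext(path)) == "json") {
    recs <- jsonlite::read_json(path, simplifyVector = TRUE,
                                simplifyDataFrame = FALSE)
    return(lapply(recs, function(r)
      new_fingerprint(unlist(r$values), r$method, r$n_dims, r$scheme,
                      r$chirality, r$skewness, name = r$name %||% "")))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  vcols <- grep("^v[0-9]+$", names(df))
  lapply(seq_len(nrow(df)), function(i)
    new_fingerprint(as.numeric(df[i, vcols]), df$method[i], df$n_dims[i],
                    df$scheme[i], df$chirality[i], df$skewness[i],
                    name = df$name[i]))
}
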