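# Feature schemes map a molecule onto its A x N hypershape matrix:
# three Cartesian columns followed by one column per atomic feature
# (N = 3 + F). Feature values enter in their raw units by default; any
# rescaling is an explicit, per-dimension choice that must be applied
# uniformly across the whole set of molecules being compared.

#' Default atomic features: protons, neutron excess, formal charge
#'
#' The three features of the default 6D scheme, computed per atom:
#' \itemize{
#'   \item protons: \eqn{F_1 = \sqrt{p}} with \eqn{p} the atomic number;
#'   \item neutron excess: \eqn{F_2 = \mathrm{sign}(n - n_{ci})\sqrt{|n - n_{ci}|}},
#'     where \eqn{n} is the neutron count and \eqn{n_{ci}} that of the
#'     element's most common isotope (so unlabelled atoms score 0);
#'   \item formal charge: \eqn{F_3 = q}.
#' }
#' The square roots compress proton/neutron counts into a range
#' comparable to centred coordinates of small and mid-size molecules.
#'
#' @param mol An [hsr_molecule()].
#' @return A numeric A x 3 matrix with columns `protons`,
#'   `neutron_excess`, `formal_charge`.
#' @examples
#' m <- hsr_molecule(c("C", "C"), rbind(c(0, 0, 0), c(1.5, 0, 0)),
#'                   masses = c(NA, 13))
#' default_features(m)  # 13C row has neutron_excess 1
#' @export
default_features <- function(mol) {
  p <- mol$atoms$atomic_number
  if (any(p < 1L))
    stop("default features are undefined for dummy atoms ('*'); ",
         "supply their features explicitly")
  d <- neutron_count(mol) - (element_info(mol$atoms$element)$most_common_mass_number -
                             mol$atoms$atomic_number)
  cbind(protons = sqrt(p),
        neutron_excess = sign(d) * sqrt(abs(d)),
        formal_charge = as.numeric(mol$atoms$formal_charge))
}

# Built-in extractor registry: each maps a molecule to a numeric vector
# over atoms. Column references are handled separately.
builtin_extractors <- list(
  protons = function(mol) default_features(mol)[, "protons"],
  neutron_excess = function(mol) default_features(mol)[, "neutron_excess"],
  formal_charge = function(mol) as.numeric(mol$atoms$formal_charge)
)

#' Define a feature scheme
#'
#' A scheme names the F extra dimensions appended to the Cartesian
#' block. Each extractor is either the name of a built-in
#' (`"protons"`, `"neutron_excess"`, `"formal_charge"`), a reference
#' `"column:<name>"` to a per-atom feature-table column, or a function
#' `molecule -> numeric vector` over atoms. Optional scalers (single
#' numbers or functions) rescale one dimension each and default to the
#' identity.
#'
#' @param name Scheme name (recorded in fingerprints; fingerprints from
#'   different schemes are never comparable).
#' @param extractors Named list of extractors; may be empty for a pure
#'   3D scheme.
#' @param scalers Optional named list (by dimension name) of multipliers
#'   or functions applied after extraction.
#' @return An object of class `hsr_scheme`.
#' @seealso [hsr_scheme()] for the built-in schemes,
#'   [build_hypershape()]
#' @export
feature_scheme <- function(name, extractors = list(), scalers = NULL) {
  if (length(extractors) > 0L && is.null(names(extractors)))
    stop("extractors must be a named list")
  structure(list(name = name, extractors = extractors, scalers = scalers),
            class = "hsr_scheme")
}

#' Built-in feature schemes
#'
#' \describe{
#'   \item{`"3d"`}{Cartesian coordinates only (N = 3, 12-number fingerprint).}
#'   \item{`"4d"`}{adds the proton feature (N = 4).}
#'   \item{`"5d"`}{adds proton and neutron-excess features (N = 5).}
#'   \item{`"default6d"`}{protons, neutron excess and formal charge
#'     (N = 6, the default 21-number fingerprint).}
#'   \item{`"electroshape4d"`}{Cartesian coordinates plus an unscaled
#'     `partial_charge` feature-table column (N = 4); partial charges
#'     must be supplied by the user, they are never computed here.}
#' }
#'
#' @param name Scheme name, or an `hsr_scheme` object (returned as-is).
#' @return An `hsr_scheme`.
#' @export
hsr_scheme <- function(name = "default6d") {
  if (inherits(name, "hsr_scheme")) return(name)
  switch(name,
         "3d" = feature_scheme("3d"),
         "4d" = feature_scheme("4d", list(protons = "protons")),
         "5d" = feature_scheme("5d", list(protons = "protons",
                                          neutron_excess = "neutron_excess")),
         "default6d" = feature_scheme("default6d",
                                      list(protons = "protons",
                                           neutron_excess = "neutron_excess",
                                           formal_charge = "formal_charge")),
         "electroshape4d" = feature_scheme("electroshape4d",
                                           list(partial_charge = "column:partial_charge")),
         stop("unknown scheme '", name, "'"))
}

#' Build the hypershape matrix of a molecule
#'
#' Applies a feature scheme to a molecule, producing the A x N matrix
#' (N = 3 + F) whose rows are atoms and whose first three columns are
#' the Cartesian coordinates. Identical atoms (same element, isotope,
#' charge) always receive identical feature values under the default
#' extractors.
#'
#' @param mol An [hsr_molecule()].
#' @param scheme An `hsr_scheme` or built-in scheme name.
#' @return A numeric matrix of class `hypershape` with named columns and
#'   attributes `scheme_name` and `mol_name`.
#' @examples
#' m <- hsr_molecule(c("C", "O"), rbind(c(0, 0, 0), c(1.2, 0, 0)))
#' build_hypershape(m, "default6d")
#' @export
build_hypershape <- function(mol, scheme = "default6d") {
  scheme <- hsr_scheme(scheme)
  mat <- coords(mol)
  colnames(mat) <- c("x", "y", "z")
  for (dim_name in names(scheme$extractors)) {
    ex <- scheme$extractors[[dim_name]]
    v <- tryCatch(extract_feature(mol, ex),
                  error = function(e)
                    stop("feature extraction failed for dimension '",
                         dim_name, "': ", conditionMessage(e), call. = FALSE))
    if (length(v) != n_atoms(mol) || !is.numeric(v))
      stop("extractor for dimension '", dim_name,
           "' must return one number per atom")
    bad <- which(!is.finite(v))
    if (length(bad) > 0L)
      stop("non-finite feature value for dimension '", dim_name,
           "' at atom ", bad[1L])
    sc <- scheme$scalers[[dim_name]]
    if (!is.null(sc)) v <- if (is.function(sc)) sc(v) else v * sc
    mat <- cbind(mat, v)
    colnames(mat)[ncol(mat)] <- dim_name
  }
  as_hypershape(mat, scheme_name = scheme$name, mol_name = mol$name)
}

extract_feature <- function(mol, ex) {
  if (is.function(ex)) return(ex(mol))
  if (is.character(ex)) {
    if (startsWith(ex, "column:")) {
      col <- sub("^column:", "", ex)
      if (is.null(mol$features) || !col %in% names(mol$features))
        stop("molecule has no feature-table column '", col, "'")
      return(mol$features[[col]])
    }
    fn <- builtin_extractors[[ex]]
    if (is.null(fn)) stop("unknown built-in extractor '", ex, "'")
    return(fn(mol))
  }
  stop("extractor must be a function or a character id")
}

#' Wrap a raw matrix as a hypershape
#'
#' Entry point for programmatically supplied N-dimensional
#' representations; the first three columns must be spatial.
#'
#' @param mat Numeric A x N matrix, N >= 3, finite entries.
#' @param scheme_name Label recorded in downstream fingerprints.
#' @param mol_name Optional molecule name.
#' @return A `hypershape` matrix.
#' @export
as_hypershape <- function(mat, scheme_name = "custom", mol_name = "") {
  mat <- as.matrix(mat)
  if (ncol(mat) < 3L) stop("a hypershape needs at least 3 (spatial) columns")
  if (nrow(mat) < 1L) stop("a hypershape needs at least one atom")
  if (!all(is.finite(mat))) stop("hypershape entries must be finite")
  if (is.null(colnames(mat)))
    colnames(mat) <- c("x", "y", "z",
                       if (ncol(mat) > 3L) paste0("f", seq_len(ncol(mat) - 3L)))
  structure(mat, class = c("hypershape", "matrix", "array"),
            scheme_name = scheme_name, mol_name = mol_name)
}

#' @export
print.hypershape <- function(x, ...) {
  cat("hypershape: ", nrow(x), " atoms x ", ncol(x), " dimensions (scheme '",
      attr(x, "scheme_name"), "')\n", sep = "")
  print(unclass(x)[, , drop = FALSE], ...)
  invisible(x)
}

#' Autoscale a set of hypershapes jointly
#'
#' Mean-centres and scales selected dimensions to unit variance using
#' statistics pooled over the whole set, never per molecule: autoscaling
#' each hypershape on its own would erase set-level information (e.g.
#' the absolute proton count that separates PH3 from NH3). An opt-in
#' utility for fixed comparison sets.
#'
#' @param shapes List of `hypershape` matrices under the same scheme.
#' @param dims Dimensions (column indices) to scale; default all feature
#'   columns (4..N).
#' @return The list of rescaled hypershapes, scheme renamed
#'   `"<scheme>+autoscaled"`.
#' @export
autoscale_hypershapes <- function(shapes, dims = NULL) {
  if (length(shapes) < 1L) stop("empty set")
  schemes <- vapply(shapes, attr, "", "scheme_name")
  if (length(unique(schemes)) != 1L)
    stop("all hypershapes must share one scheme; got: ",
         paste(unique(schemes), collapse = ", "))
  n <- ncol(shapes[[1L]])
  if (is.null(dims)) dims <- if (n > 3L) 4L:n else integer(0)
  pooled <- do.call(rbind, lapply(shapes, unclass))
  mu <- colMeans(pooled[, dims, drop = FALSE])
  sdv <- apply(pooled[, dims, drop = FALSE], 2L, stats::sd)
  sdv[sdv == 0] <- 1  # constant dimension: centre only
  lapply(shapes, function(h) {
    h[, dims] <- sweep(sweep(h[, dims, drop = FALSE], 2L, mu), 2L, sdv, "/")
    attr(h, "scheme_name") <- paste0(schemes[1L], "+autoscaled")
    h
  })
}

#' Load a feature scheme from a YAML config file
#'
#' The file holds `name:`, an ordered `dimensions:` map of dimension
#' name to extractor id (a built-in id or `column:<name>`), and an
#' optional `scalers:` map of dimension name to a numeric multiplier.
#'
#' @param path YAML file path.
#' @return An `hsr_scheme`.
#' @export
read_scheme <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$name)) stop("scheme config needs a 'name' field")
  extractors <- as.list(cfg$dimensions %||% list())
  scalers <- cfg$scalers
  if (!is.null(scalers)) scalers <- lapply(scalers, as.numeric)
  feature_scheme(cfg$name, extractors, scalers)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
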