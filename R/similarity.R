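# Fingerprint comparison: the similarity of two K-number fingerprints q
# and t is the inverse scaled Manhattan distance
#   S = 1 / (1 + d_M / K),   d_M = sum_i |q_i - t_i|,
# so S lies in (0, 1] and equals 1 exactly for identical fingerprints.
# K is the fingerprint length (3(N+1) for HSR schemes, 12 for USR, 13
# for USR:OptIso), which makes scores of different dimensionality
# incomparable: metadata is checked before any distance is computed,
# and a raw-distance mode is provided for cross-dimensionality studies
# where Manhattan distances are the preferable currency.

check_comparable <- function(q, t) {
  for (fp in list(q, t))
    if (!inherits(fp, "hsr_fingerprint"))
      stop("similarity requires hsr_fingerprint objects")
  if (length(q) != length(t))
    stop("incomparable fingerprints: lengths ", length(q), " vs ", length(t))
  for (a in c("method", "scheme_name", "n_dims", "chirality", "skewness")) {
    if (!identical(attr(q, a), attr(t, a)))
      stop("incomparable fingerprints: ", a, " '", attr(q, a),
           "' vs '", attr(t, a), "'")
  }
  invisible(TRUE)
}

#' Manhattan distance between two fingerprints
#'
#' @param q,t Comparable `hsr_fingerprint` objects (same length, method,
#'   scheme, chirality and skewness settings; enforced).
#' @return Nonnegative sum of absolute component differences.
#' @export
manhattan_distance <- function(q, t) {
  check_comparable(q, t)
  sum(abs(as.numeric(q) - as.numeric(t)))
}

#' Similarity score of two fingerprints
#'
#' @param q,t Comparable `hsr_fingerprint` objects.
#' @return An `hsr_similarity` object: list with `score` in (0, 1],
#'   `manhattan` and the normalization `K` (fingerprint length).
#' @examples
#' m <- generate_fixture("random_cloud", n_atoms = 8, seed = 1)
#' similarity_score(hsr_fingerprint(m), hsr_fingerprint(m))$score  # 1
#' @export
similarity_score <- function(q, t) {
  dm <- manhattan_distance(q, t)
  k <- length(q)
  structure(list(score = 1 / (1 + dm / k), manhattan = dm, K = k),
            class = "hsr_similarity")
}

#' @export
print.hsr_similarity <- function(x, ...) {
  cat(sprintf("similarity S = %.6f  (Manhattan d = %.6f, K = %d)\n",
              x$score, x$manhattan, x$K))
  invisible(x)
}

#' Pairwise similarity (or distance) matrix
#'
#' @param fps List of mutually comparable `hsr_fingerprint` objects.
#' @param value `"score"` (default) or `"distance"` (raw Manhattan).
#' @return Symmetric matrix; unit diagonal for scores, zero diagonal
#'   for distances. Row/column names come from molecule names when set.
#' @export
pairwise_matrix <- function(fps, value = c("score", "distance")) {
  value <- match.arg(value)
  n <- length(fps)
  for (i in seq_len(n)) for (j in seq_len(i)[-i])
    tryCatch(check_comparable(fps[[i]], fps[[j]]),
             error = function(e)
               stop("fingerprints ", j, " and ", i, " are incomparable: ",
                    conditionMessage(e), call. = FALSE))
  out <- matrix(if (value == "score") 1 else 0, n, n)
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    r <- similarity_score(fps[[i]], fps[[j]])
    out[i, j] <- out[j, i] <- if (value == "score") r$score else r$manhattan
  }
  nm <- vapply(fps, function(f) attr(f, "mol_name") %||% "", "")
  if (any(nzchar(nm))) dimnames(out) <- list(nm, nm)
  out
}

#' Enrichment factor for ranked screening results
#'
#' Utility for virtual-screening benchmarks: the ratio of the fraction
#' of actives recovered in the top-ranked `fraction` of the list to the
#' fraction expected at random.
#'
#' @param active Logical vector marking actives.
#' @param score Numeric similarity scores (larger = better).
#' @param fraction Top fraction of the ranked list considered
#'   (default 0.005, i.e. 0.5%).
#' @return The enrichment factor (>= 0).
#' @export
enrichment_factor <- function(active, score, fraction = 0.005) {
  stopifnot(length(active) == length(score), fraction > 0, fraction <= 1)
  n <- length(score)
  n_top <- max(1L, floor(n * fraction))
  top <- order(-score)[seq_len(n_top)]
  hits <- sum(active[top])
  total <- sum(active)
  if (total == 0L) return(0)
  (hits / n_top) / (total / n)
}
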