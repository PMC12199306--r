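# Element data: symbols, atomic numbers and the mass number of the most
# abundant natural isotope, frozen from standard isotopic-abundance data
# (inst/extdata/isotopes.tsv). The neutron count of the most common isotope,
# n_ci = mass - Z, anchors the isotope feature of the default scheme.

.hsr_env <- new.env(parent = emptyenv())

element_table <- function() {
  if (is.null(.hsr_env$elements)) {
    path <- system.file("extdata", "isotopes.tsv", package = "hsr",
                        mustWork = TRUE)
    .hsr_env$elements <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  .hsr_env$elements
}

#' Look up an element by symbol
#'
#' Returns the atomic number and the mass number of the most abundant
#' natural isotope for an element symbol. The dummy symbol `"*"` is
#' accepted and maps to atomic number 0 (usable only in schemes whose
#' features are fully user-supplied).
#'
#' @param symbol Character vector of element symbols (case-sensitive,
#'   e.g. `"C"`, `"Cl"`, `"*"`).
#' @return A data frame with columns `symbol`, `atomic_number` and
#'   `most_common_mass_number` (`NA` for dummy atoms).
#' @examples
#' element_info(c("C", "Ir"))
#' @export
element_info <- function(symbol) {
  tab <- element_table()
  idx <- match(symbol, tab$symbol)
  out <- data.frame(symbol = symbol,
                    atomic_number = tab$atomic_number[idx],
                    most_common_mass_number = tab$most_common_mass_number[idx],
                    stringsAsFactors = FALSE)
  dummy <- symbol == "*"
  out$atomic_number[dummy] <- 0L
  bad <- is.na(out$atomic_number) & !dummy
  if (any(bad))
    stop("unknown element symbol(s): ", paste(unique(symbol[bad]), collapse = ", "))
  out
}

element_symbol <- function(atomic_number) {
  tab <- element_table()
  tab$symbol[match(atomic_number, tab$atomic_number)]
}
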