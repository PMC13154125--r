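# Element data used across the package: standard atomic weights, atomic
# numbers, and default valences (for automatic hydrogen placement in the
# fragment grammar). Covers the organic subset the generator emits.

.element_data <- function() {
  data.frame(
    symbol = c("H", "B", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I"),
    number = c(1L, 5L, 6L, 7L, 8L, 9L, 15L, 16L, 17L, 35L, 53L),
    weight = c(1.008, 10.811, 12.011, 14.007, 15.999, 18.998,
               30.974, 32.06, 35.45, 79.904, 126.904),
    valence = c(1L, 3L, 4L, 3L, 2L, 1L, 3L, 2L, 1L, 1L, 1L),
    stringsAsFactors = FALSE
  )
}

#' Standard atomic weights
#'
#' @param elements character vector of element symbols.
#' @return Numeric vector of standard atomic weights (g/mol).
#' @export
atomic_weights <- function(elements) {
  tab <- .element_data()
  i <- match(elements, tab$symbol)
  if (anyNA(i)) stop("unknown element symbol(s): ",
                     paste(unique(elements[is.na(i)]), collapse = ", "))
  tab$weight[i]
}

#' @rdname atomic_weights
#' @export
atomic_numbers <- function(elements) {
  tab <- .element_data()
  i <- match(elements, tab$symbol)
  if (anyNA(i)) stop("unknown element symbol(s): ",
                     paste(unique(elements[is.na(i)]), collapse = ", "))
  tab$number[i]
}

.default_valences <- function(elements) {
  tab <- .element_data()
  i <- match(elements, tab$symbol)
  if (anyNA(i)) stop("unknown element symbol(s): ",
                     paste(unique(elements[is.na(i)]), collapse = ", "))
  tab$valence[i]
}
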