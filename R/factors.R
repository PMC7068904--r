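#' Define an experimental factor
#'
#' A factor is one implantation parameter of the tibial component: its name,
#' the single-letter symbol used in combination labels (e.g. `"A"`), the
#' ordered list of candidate angle values (degrees), and a note on the sign
#' convention. Level *indices* are 1-based positions in `levels`; the level
#' ordering is taken verbatim from the screening design and need not be
#' monotone in the angle values.
#'
#' @param name Factor name, e.g. `"varus angle"`.
#' @param symbol Single upper-case letter used in combination labels.
#' @param levels Numeric vector of at least two pairwise-distinct angle
#'   values, in degrees, in level order.
#' @param sign_convention Free-text note on what positive values mean.
#' @param column Column name used for this factor's angle values in design
#'   tables; defaults to a slug of `name` suffixed with `_deg`.
#'
#' @return An object of class `factor_spec`.
#' @seealso [tka_factors()] for the standard three-factor set.
#' @export
factor_spec <- function(name, symbol, levels, sign_convention = "",
                        column = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!(is.character(symbol) && length(symbol) == 1L &&
        grepl("^[A-Z]$", symbol))) {
    stop("`symbol` must be a single upper-case letter, got ",
         deparse(symbol), call. = FALSE)
  }
  levels <- as.numeric(levels)
  if (length(levels) < 2L) {
    stop("factor '", name, "' needs at least 2 levels", call. = FALSE)
  }
  if (anyDuplicated(levels)) {
    stop("factor '", name, "' has duplicated level values", call. = FALSE)
  }
  if (any(!is.finite(levels))) {
    stop("factor '", name, "' has non-finite level values", call. = FALSE)
  }
  if (is.null(column)) {
    slug <- gsub("[^a-z0-9]+", "_", tolower(name))
    column <- paste0(sub("_angle$|_$", "", slug), "_deg")
  }
  structure(
    list(name = name, symbol = symbol, levels = levels,
         sign_convention = sign_convention, column = column),
    class = "factor_spec"
  )
}

#' @export
print.factor_spec <- function(x, ...) {
  cat(sprintf("<factor_spec> %s (%s): levels [%s] deg", x$name, x$symbol,
              paste(format(x$levels, trim = TRUE), collapse = ", ")))
  if (nzchar(x$sign_convention)) cat(" --", x$sign_convention)
  cat("\n")
  invisible(x)
}

#' Standard tibial-component implantation factors
#'
#' The three-factor, three-level set used throughout: varus angle A
#' (0, 3, -3 degrees; varus positive, valgus negative), posterior slope
#' angle B of the tibial cut (1, 2, 3 degrees), and external rotation angle
#' C (3, 4, 5 degrees). The varus level order is deliberately non-monotone;
#' labels always refer to level indices, not sorted angles.
#'
#' @return A list of three [factor_spec()] objects named `A`, `B`, `C`.
#' @export
#' @examples
#' tka_factors()
tka_factors <- function() {
  list(
    A = factor_spec("varus angle", "A", c(0, 3, -3),
                    "varus positive, valgus negative", column = "varus_deg"),
    B = factor_spec("posterior slope angle", "B", c(1, 2, 3),
                    "posterior slope of the tibial cut, positive backwards",
                    column = "slope_deg"),
    C = factor_spec("external rotation angle", "C", c(3, 4, 5),
                    "external rotation positive", column = "rotation_deg")
  )
}

#' Encode level indices as a combination label
#'
#' @param factors List of [factor_spec()] objects.
#' @param idx Integer vector of 1-based level indices, one per factor.
#' @return A label such as `"A1B2C2"`.
#' @export
encode_combination <- function(factors, idx) {
  stopifnot(length(factors) == length(idx))
  paste0(vapply(factors, function(f) f$symbol, ""), as.integer(idx),
         collapse = "")
}

#' Decode a combination label to level indices
#'
#' Inverse of [encode_combination()]; errors if the label's symbols do not
#' match the factor symbols in order, or an index is out of range.
#'
#' @inheritParams encode_combination
#' @param label Combination label, e.g. `"A1B2C2"`.
#' @return Named integer vector of level indices.
#' @export
decode_combination <- function(factors, label) {
  stopifnot(is.character(label), length(label) == 1L)
  m <- gregexpr("([A-Z])([0-9]+)", label)[[1]]
  parts <- regmatches(label, gregexpr("([A-Z])([0-9]+)", label))[[1]]
  if (m[1] == -1L || paste(parts, collapse = "") != label ||
      length(parts) != length(factors)) {
    stop("malformed combination label '", label, "'", call. = FALSE)
  }
  syms <- substr(parts, 1L, 1L)
  idx <- as.integer(substring(parts, 2L))
  expected <- vapply(factors, function(f) f$symbol, "")
  if (!identical(syms, unname(expected))) {
    stop("label '", label, "' does not match factor symbols ",
         paste(expected, collapse = ""), call. = FALSE)
  }
  nlev <- vapply(factors, function(f) length(f$levels), 0L)
  if (any(idx < 1L | idx > nlev)) {
    stop("label '", label, "' has a level index out of range", call. = FALSE)
  }
  stats::setNames(idx, expected)
}
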