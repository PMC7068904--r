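.design_table <- function(df, factors) {
  rownames(df) <- NULL
  structure(df, factors = factors, class = c("design_table", "data.frame"))
}

#' Instantiate a design table from an array and factor specs
#'
#' Maps the first `length(factors)` columns of the array to concrete angle
#' values and combination labels; unassigned (error) columns are dropped.
#' All factors must have exactly the array's level count.
#'
#' @param array An `orthogonal_array` from [build_orthogonal_array()].
#' @param factors List of [factor_spec()] objects, at most `array$columns`.
#' @return A `design_table`: a data.frame with `run_id`, `combination`, and
#'   one angle column per factor (named by each factor's `column`), carrying
#'   the factor list as attribute `"factors"`.
#' @export
#' @examples
#' instantiate_design(build_orthogonal_array(3, 3), tka_factors())
instantiate_design <- function(array, factors) {
  stopifnot(inherits(array, "orthogonal_array"))
  if (length(factors) > array$columns) {
    stop("more factors (", length(factors), ") than array columns (",
         array$columns, ")", call. = FALSE)
  }
  for (f in factors) {
    if (length(f$levels) != array$levels) {
      stop("factor '", f$name, "' has ", length(f$levels),
           " levels but the array requires ", array$levels, call. = FALSE)
    }
  }
  idx <- array$cells[, seq_along(factors), drop = FALSE]
  df <- data.frame(run_id = seq_len(array$runs))
  df$combination <- apply(idx, 1L, function(i) encode_combination(factors, i))
  for (j in seq_along(factors)) {
    df[[factors[[j]]$column]] <- factors[[j]]$levels[idx[, j]]
  }
  .design_table(df, factors)
}

#' Full-factorial design over a factor list
#'
#' One run per element of the Cartesian product of the factor levels, ordered
#' lexicographically: the first factor's level index varies slowest.
#'
#' @param factors Non-empty list of [factor_spec()] objects.
#' @return A `design_table` (see [instantiate_design()]).
#' @export
full_factorial <- function(factors) {
  if (length(factors) < 1L) stop("need at least one factor", call. = FALSE)
  nlev <- vapply(factors, function(f) length(f$levels), 0L)
  # expand.grid varies the first column fastest; reverse for lexicographic
  grid <- expand.grid(rev(lapply(nlev, seq_len)), KEEP.OUT.ATTRS = FALSE)
  idx <- as.matrix(grid[, rev(seq_along(factors)), drop = FALSE])
  colnames(idx) <- NULL
  df <- data.frame(run_id = seq_len(nrow(idx)))
  df$combination <- apply(idx, 1L, function(i) encode_combination(factors, i))
  for (j in seq_along(factors)) {
    df[[factors[[j]]$column]] <- factors[[j]]$levels[idx[, j]]
  }
  .design_table(df, factors)
}

#' Recover the level-index matrix of a design table
#'
#' @param design A `design_table`.
#' @return Integer matrix (runs x factors) of 1-based level indices, decoded
#'   from the combination labels and cross-checked against the angle columns.
#' @export
design_level_indices <- function(design) {
  factors <- attr(design, "factors")
  idx <- t(vapply(design$combination,
                  function(lab) decode_combination(factors, lab),
                  integer(length(factors))))
  dimnames(idx) <- NULL
  for (j in seq_along(factors)) {
    f <- factors[[j]]
    expect <- f$levels[idx[, j]]
    got <- design[[f$column]]
    if (any(abs(expect - got) > 1e-9)) {
      stop("design table inconsistent: column '", f$column,
           "' disagrees with combination labels", call. = FALSE)
    }
  }
  idx
}

#' @export
print.design_table <- function(x, ...) {
  cat(sprintf("<design_table> %d runs x %d factors\n", nrow(x),
              length(attr(x, "factors"))))
  print(as.data.frame(x))
  invisible(x)
}

#' Write / read a design table as delimited text
#'
#' Comma-separated, UTF-8, `.` decimal, header
#' `run_id,combination,<angle columns>`.
#'
#' @param design A `design_table`.
#' @param path File path.
#' @return `write_design` returns `path` invisibly; `read_design` returns a
#'   `design_table` (factor specs reconstructed from the labels and columns
#'   when `factors` is supplied, otherwise attached as `NULL`).
#' @export
write_design <- function(design, path) {
  utils::write.csv(as.data.frame(design), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_design
#' @param factors Optional factor list to attach and validate against.
#' @export
read_design <- function(path, factors = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("run_id", "combination")
  if (!all(need %in% names(df))) {
    stop("design file '", path, "' lacks columns ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  out <- .design_table(df, factors)
  if (!is.null(factors)) design_level_indices(out)  # cross-check
  out
}
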