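# Canonical L9(3^4) orthogonal array. Row order fixed; columns 1..3 carry
# factors A, B, C, column 4 is the unassigned error column.
.l9_cells <- function() {
  matrix(c(
    1L, 1L, 1L, 1L,
    1L, 2L, 2L, 2L,
    1L, 3L, 3L, 3L,
    2L, 1L, 2L, 3L,
    2L, 2L, 3L, 1L,
    2L, 3L, 1L, 2L,
    3L, 1L, 3L, 2L,
    3L, 2L, 1L, 3L,
    3L, 3L, 2L, 1L
  ), nrow = 9L, ncol = 4L, byrow = TRUE)
}

#' Build a standard orthogonal array
#'
#' Returns the tabulated L9(3^4) array: nine runs accommodating up to four
#' three-level factors such that every column is balanced (each level three
#' times) and every ordered level pair appears exactly once per column pair.
#' Only this array is supported; screening three 3-level implantation
#' factors is exactly its use case, and requesting other sizes is an error
#' rather than a silent approximation.
#'
#' @param levels_per_factor Number of levels per factor; must be 3.
#' @param n_factors Number of factors to accommodate; must be between 1 and 4.
#'   Columns beyond `n_factors` remain in the array (they are dropped at
#'   instantiation, see [instantiate_design()]).
#'
#' @return An object of class `orthogonal_array` with fields `designation`,
#'   `runs`, `columns`, and the `runs x columns` integer matrix `cells` of
#'   1-based level indices.
#' @export
#' @examples
#' oa <- build_orthogonal_array(3, 3)
#' oa$cells[1, ]
build_orthogonal_array <- function(levels_per_factor, n_factors) {
  levels_per_factor <- as.integer(levels_per_factor)
  n_factors <- as.integer(n_factors)
  if (!identical(levels_per_factor, 3L) || n_factors < 1L || n_factors > 4L) {
    stop("unsupported array request (", levels_per_factor, " levels, ",
         n_factors, " factors); supported arrays: L9(3^4) for 3-level ",
         "designs with at most 4 factors", call. = FALSE)
  }
  structure(
    list(designation = "L9(3^4)", runs = 9L, columns = 4L,
         levels = 3L, cells = .l9_cells()),
    class = "orthogonal_array"
  )
}

#' @export
print.orthogonal_array <- function(x, ...) {
  cat(sprintf("<orthogonal_array> %s: %d runs x %d columns\n",
              x$designation, x$runs, x$columns))
  print(x$cells)
  invisible(x)
}

#' Validate balance and pairwise orthogonality of an array
#'
#' Checks, per column, that every level index appears `runs/m` times, and per
#' ordered column pair, that every ordered level pair appears `runs/m^2`
#' times. Failures are reported, not raised.
#'
#' @param array An `orthogonal_array`, or a plain integer matrix of level
#'   indices (e.g. a full-factorial design).
#' @return A list of class `orthogonality_report` with `pass` (logical),
#'   `column_counts` (level-count table per column with per-column pass
#'   flags), and `pair_counts` (per ordered column pair, the m x m table of
#'   observed ordered-pair counts and a pass flag).
#' @export
validate_orthogonality <- function(array) {
  cells <- if (inherits(array, "orthogonal_array")) array$cells else
    as.matrix(array)
  storage.mode(cells) <- "integer"
  if (length(cells) == 0L) stop("empty array", call. = FALSE)
  runs <- nrow(cells)
  m <- max(cells)
  lev <- seq_len(m)

  col_tab <- lapply(seq_len(ncol(cells)), function(j) {
    counts <- tabulate(cells[, j], nbins = m)
    list(column = j, counts = stats::setNames(counts, lev),
         expected = runs / m, pass = all(counts == runs / m))
  })

  pairs <- utils::combn(ncol(cells), 2L, simplify = FALSE)
  pair_tab <- lapply(pairs, function(jk) {
    j <- jk[1]; k <- jk[2]
    counts <- matrix(0L, m, m, dimnames = list(lev, lev))
    for (r in seq_len(runs)) {
      counts[cells[r, j], cells[r, k]] <- counts[cells[r, j], cells[r, k]] + 1L
    }
    list(columns = c(j, k), counts = counts, expected = runs / m^2,
         pass = all(counts == runs / m^2))
  })

  pass_cols <- vapply(col_tab, `[[`, TRUE, "pass")
  pass_pairs <- vapply(pair_tab, `[[`, TRUE, "pass")
  structure(
    list(pass = all(pass_cols) && all(pass_pairs),
         column_counts = col_tab, pair_counts = pair_tab,
         failing_columns = which(!pass_cols),
         failing_pairs = lapply(pair_tab[!pass_pairs], `[[`, "columns")),
    class = "orthogonality_report"
  )
}

#' @export
print.orthogonality_report <- function(x, ...) {
  cat("<orthogonality_report>", if (x$pass) "PASS" else "FAIL", "\n")
  if (length(x$failing_columns)) {
    cat("  unbalanced columns:", paste(x$failing_columns, collapse = ", "),
        "\n")
  }
  for (p in x$failing_pairs) {
    cat("  non-orthogonal column pair: (", p[1], ",", p[2], ")\n")
  }
  invisible(x)
}
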