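#' Attach responses to a design table
#'
#' @param design A `design_table`.
#' @param responses Numeric vector of peak contact pressures (MPa), one per
#'   run, in run order. All values must be finite and positive.
#' @return A `response_table`: the design with an extra
#'   `peak_pressure_mpa` column.
#' @export
response_table <- function(design, responses) {
  stopifnot(inherits(design, "design_table"))
  responses <- as.numeric(responses)
  if (length(responses) != nrow(design)) {
    stop("need one response per run: got ", length(responses), " for ",
         nrow(design), " runs", call. = FALSE)
  }
  if (any(!is.finite(responses)) || any(responses <= 0)) {
    stop("responses must be finite and > 0", call. = FALSE)
  }
  df <- as.data.frame(design)
  df$peak_pressure_mpa <- responses
  structure(df, factors = attr(design, "factors"),
            class = c("response_table", "design_table", "data.frame"))
}

#' Read a response table from delimited text
#'
#' Expects the schema
#' `run_id,combination,varus_deg,slope_deg,rotation_deg,peak_pressure_mpa`
#' (angle columns per the factor specs).
#'
#' @param path File path.
#' @param factors Factor list; defaults to [tka_factors()].
#' @return A `response_table`.
#' @export
read_response_table <- function(path, factors = tka_factors()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (!"peak_pressure_mpa" %in% names(df)) {
    stop("response file '", path, "' lacks column peak_pressure_mpa",
         call. = FALSE)
  }
  design <- .design_table(df[setdiff(names(df), "peak_pressure_mpa")],
                          factors)
  design_level_indices(design)  # label/angle cross-check
  response_table(design, df$peak_pressure_mpa)
}

#' Packaged reference finite-element responses
#'
#' The nine-run L9 response table of peak contact pressures (MPa) on the
#' polyethylene liner, taken from a validated finite-element study of
#' tibial-component alignment under a 1150 N axial load at 0 degrees
#' flexion. These values are consumed as data; the contact surrogate in this
#' package does not attempt to reproduce them numerically.
#'
#' @return A `response_table` with 9 runs.
#' @export
#' @examples
#' fe_reference_responses()
fe_reference_responses <- function() {
  path <- system.file("extdata", "fe_reference_responses.csv",
                      package = "kneealign", mustWork = TRUE)
  read_response_table(path)
}

.check_balanced <- function(idx) {
  runs <- nrow(idx)
  for (j in seq_len(ncol(idx))) {
    counts <- tabulate(idx[, j])
    if (length(unique(counts)) != 1L || sum(counts) != runs) {
      stop("design is unbalanced in factor ", j,
           "; level means require a balanced design", call. = FALSE)
    }
  }
}

#' Per-factor level means of the response
#'
#' For each factor j and level i, `K[j, i]` is the arithmetic mean of the
#' response over the runs where factor j sits at level i. Requires a
#' balanced design (each level equally often); computed at full floating
#' precision (rounding is a display concern only).
#'
#' @param responses A `response_table`.
#' @return An object of class `level_mean_matrix`: list with `K` (factors x
#'   levels matrix, MPa), `counts`, `factors`, and `grand_mean`.
#' @export
level_means <- function(responses) {
  stopifnot(inherits(responses, "response_table"))
  factors <- attr(responses, "factors")
  idx <- design_level_indices(responses)
  .check_balanced(idx)
  y <- responses$peak_pressure_mpa
  if (anyNA(y)) stop("missing responses", call. = FALSE)
  m <- max(idx)
  K <- matrix(NA_real_, length(factors), m,
              dimnames = list(vapply(factors, `[[`, "", "symbol"),
                              paste0("level", seq_len(m))))
  counts <- K
  for (j in seq_along(factors)) {
    for (i in seq_len(m)) {
      sel <- idx[, j] == i
      K[j, i] <- mean(y[sel])
      counts[j, i] <- sum(sel)
    }
  }
  structure(list(K = K, counts = counts, factors = factors,
                 grand_mean = mean(y)),
            class = "level_mean_matrix")
}

#' @export
print.level_mean_matrix <- function(x, digits = 2, ...) {
  cat("<level_mean_matrix> (MPa)\n")
  print(round(x$K, digits))
  invisible(x)
}

#' Per-factor ranges of the level means
#'
#' `R[j] = max_i K[j, i] - min_i K[j, i]`; the larger the range, the more
#' influential the factor.
#'
#' @param K A `level_mean_matrix` from [level_means()].
#' @return Named numeric vector of ranges (MPa), one per factor.
#' @export
compute_ranges <- function(K) {
  stopifnot(inherits(K, "level_mean_matrix"))
  if (anyNA(K$K)) stop("incomplete level-mean matrix", call. = FALSE)
  apply(K$K, 1L, function(r) max(r) - min(r))
}

#' Rank factors by descending range
#'
#' Ties break by factor declaration order (stable sort), so equal ranges
#' rank in the order the factors were defined.
#'
#' @param R Named numeric vector of per-factor ranges.
#' @return Character vector of factor symbols, most influential first.
#' @export
rank_factors <- function(R) {
  names(R)[order(-R)]  # order() is stable: ties keep declaration order
}

#' Optimal level combination from the level means
#'
#' Per factor, the level index extremizing the level mean under the stated
#' objective direction; ties resolve to the lowest level index.
#'
#' @param K A `level_mean_matrix`.
#' @param direction `"minimize"` (default; minimum peak contact pressure) or
#'   `"maximize"`.
#' @return A list of class `range_ranking` with `optimal_level` (integer per
#'   factor), `optimal_combination` (label), `optimal_angles` (named numeric,
#'   degrees), `R` (ranges), `ranking`, `direction`, and the `K` matrix.
#' @export
optimal_combination <- function(K, direction = c("minimize", "maximize")) {
  stopifnot(inherits(K, "level_mean_matrix"))
  direction <- match.arg(direction)
  pick <- if (direction == "minimize") which.min else which.max
  opt <- apply(K$K, 1L, pick)  # which.min/max take the first tie
  R <- compute_ranges(K)
  angles <- vapply(seq_along(K$factors),
                   function(j) K$factors[[j]]$levels[opt[j]], 0)
  names(angles) <- vapply(K$factors, `[[`, "", "column")
  structure(
    list(optimal_level = opt,
         optimal_combination = encode_combination(K$factors, opt),
         optimal_angles = angles,
         R = R, ranking = rank_factors(R),
         direction = direction, K = K),
    class = "range_ranking"
  )
}

#' @export
print.range_ranking <- function(x, digits = 2, ...) {
  cat("<range_ranking> objective:", x$direction, "\n")
  print(round(x$K$K, digits))
  cat("Range R:", paste(sprintf("%s=%.*f", names(x$R), digits, x$R),
                        collapse = ", "), "\n")
  cat("Ranking:", paste(x$ranking, collapse = " > "), "\n")
  cat("Optimal:", x$optimal_combination, "(",
      paste(sprintf("%s=%g", names(x$optimal_angles), x$optimal_angles),
            collapse = ", "), ")\n")
  invisible(x)
}

#' Spread of the responses
#'
#' Maximum, minimum, their difference, and the percent spread
#' `100 * (max - min) / min` over the supplied responses, optionally
#' augmented with extra values (e.g. a verification-run response).
#'
#' @param responses A `response_table` (or numeric vector) of at least two
#'   responses.
#' @param extra Optional additional response values to include.
#' @return List with `max`, `min`, `spread` (MPa) and `spread_pct`.
#' @export
response_spread <- function(responses, extra = NULL) {
  y <- if (inherits(responses, "response_table"))
    responses$peak_pressure_mpa else as.numeric(responses)
  y <- c(y, as.numeric(extra))
  if (length(y) < 2L) stop("need at least two responses", call. = FALSE)
  list(max = max(y), min = min(y), spread = max(y) - min(y),
       spread_pct = 100 * (max(y) - min(y)) / min(y))
}

#' Long-form level-mean trend table
#'
#' One row per (factor, level): the data behind a level-mean trend chart.
#'
#' @param K A `level_mean_matrix`.
#' @param factors Factor list; defaults to the factors stored in `K`.
#' @return data.frame with columns `factor`, `symbol`, `level_index`,
#'   `level_value_deg`, `mean_peak_pressure_mpa`.
#' @export
trend_table <- function(K, factors = K$factors) {
  stopifnot(inherits(K, "level_mean_matrix"))
  rows <- do.call(rbind, lapply(seq_along(factors), function(j) {
    f <- factors[[j]]
    data.frame(factor = f$name, symbol = f$symbol,
               level_index = seq_along(f$levels),
               level_value_deg = f$levels,
               mean_peak_pressure_mpa = K$K[j, seq_along(f$levels)])
  }))
  rownames(rows) <- NULL
  rows
}

#' Range analysis of a response table
#'
#' Convenience wrapper: level means, ranges, ranking, optimal combination,
#' spread and trend table in one object.
#'
#' @inheritParams level_means
#' @inheritParams optimal_combination
#' @return A list of class `range_analysis` with components `K`, `ranking`
#'   (a `range_ranking`), `spread`, and `trend`.
#' @export
#' @examples
#' range_analysis(fe_reference_responses())
range_analysis <- function(responses, direction = "minimize") {
  K <- level_means(responses)
  rr <- optimal_combination(K, direction)
  structure(list(K = K, ranking = rr,
                 spread = response_spread(responses),
                 trend = trend_table(K)),
            class = "range_analysis")
}

#' @export
print.range_analysis <- function(x, digits = 2, ...) {
  print(x$ranking, digits = digits)
  cat(sprintf("Response spread: max %.2f, min %.2f, max-min %.2f MPa (%.1f%%)\n",
              x$spread$max, x$spread$min, x$spread$spread,
              x$spread$spread_pct))
  invisible(x)
}
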