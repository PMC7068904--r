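# Allowed config keys, used for strict validation with field-path messages.
.config_schema <- list(
  evaluator = NULL, direction = NULL, precision = NULL, seed = NULL,
  factors = NULL,
  responses = list(path = NULL, optimum_response_mpa = NULL),
  surrogate = list(
    inherent_slope_deg = NULL,
    geometry = list(condyle_radius_mm = NULL, dish_radius_mm = NULL,
                    compartment_offset_mm = NULL, liner_thickness_mm = NULL,
                    plateau_height_mm = NULL, conformity_falloff_mm3 = NULL,
                    grid_halfwidth_x_mm = NULL, grid_halfwidth_y_mm = NULL,
                    grid_spacing_mm = NULL, single_compartment = NULL),
    load = list(force_n = NULL, flexion_deg = NULL, ml_lever_mm = NULL,
                ap_lever_mm = NULL),
    materials = list(cortical_bone = NULL, cancellous_bone = NULL,
                     femoral_component = NULL, tibial_component = NULL,
                     polyethylene_liner = NULL, bone_cement = NULL,
                     friction_coefficient = NULL),
    ligaments = list(
      medial = list(c1_mpa = NULL, ref_length_mm = NULL, ref_area_mm2 = NULL,
                    lever_arm_mm = NULL, prestretch = NULL),
      lateral = list(c1_mpa = NULL, ref_length_mm = NULL, ref_area_mm2 = NULL,
                     lever_arm_mm = NULL, prestretch = NULL))),
  planted = list(base_mpa = NULL, optimum = list(varus_deg = NULL,
                                                 slope_deg = NULL,
                                                 rotation_deg = NULL),
                 weights = list(varus = NULL, slope = NULL, rotation = NULL),
                 noise_sd_mpa = NULL)
)

.check_keys <- function(x, schema, path = "") {
  if (!is.list(x)) return(invisible())
  unknown <- setdiff(names(x), names(schema))
  if (length(unknown)) {
    stop("unknown config key", if (length(unknown) > 1) "s", ": ",
         paste0(path, unknown, collapse = ", "), call. = FALSE)
  }
  for (nm in names(x)) {
    if (is.list(schema[[nm]])) {
      .check_keys(x[[nm]], schema[[nm]], paste0(path, nm, "."))
    }
  }
  invisible()
}

.merge_defaults <- function(given, defaults) {
  if (is.null(given)) return(defaults)
  for (nm in names(defaults)) {
    given[[nm]] <- if (is.list(defaults[[nm]]) && !is.null(given[[nm]])) {
      .merge_defaults(given[[nm]], defaults[[nm]])
    } else if (is.null(given[[nm]])) defaults[[nm]] else given[[nm]]
  }
  given
}

.factors_from_config <- function(lst) {
  if (is.null(lst)) return(tka_factors())
  specs <- lapply(lst, function(f) {
    factor_spec(f$name, f$symbol, unlist(f$levels),
                sign_convention = if (is.null(f$sign_convention)) "" else
                  f$sign_convention,
                column = f$column)
  })
  stats::setNames(specs, vapply(specs, `[[`, "", "symbol"))
}

#' Build a validated pipeline configuration
#'
#' Accepts a (possibly partial) nested list in the documented schema,
#' rejects unknown keys with their field path, checks cross-field
#' invariants, and fills every unset value with the package defaults
#' (standard factors, 1150 N axial load, reference material/ligament
#' constants, illustrative geometry).
#'
#' Invariants: at most one of the `surrogate` / `planted` / `responses`
#' blocks may be given and, if given, must match `evaluator`; `responses`
#' mode requires `responses.path`; a `seed` is required if and only if
#' planted noise is enabled.
#'
#' @param config Nested list (e.g. from [yaml::read_yaml()]); `list()` gives
#'   the all-defaults surrogate configuration.
#' @return An object of class `pipeline_config`.
#' @seealso [load_config()], [run_pipeline()]
#' @export
pipeline_config <- function(config = list()) {
  .check_keys(config, .config_schema)
  blocks <- intersect(c("surrogate", "planted", "responses"), names(config))
  if (length(blocks) > 1L) {
    stop("exactly one evaluator source allowed; config has blocks: ",
         paste(blocks, collapse = ", "), call. = FALSE)
  }
  evaluator <- config$evaluator
  if (is.null(evaluator)) evaluator <- if (length(blocks)) blocks else
    "surrogate"
  if (!evaluator %in% c("surrogate", "planted", "responses")) {
    stop("evaluator: must be one of surrogate, planted, responses",
         call. = FALSE)
  }
  if (length(blocks) && blocks != evaluator) {
    stop("evaluator is '", evaluator, "' but config block '", blocks,
         "' was given", call. = FALSE)
  }

  direction <- if (is.null(config$direction)) "minimize" else config$direction
  if (!direction %in% c("minimize", "maximize")) {
    stop("direction: must be minimize or maximize", call. = FALSE)
  }
  precision <- if (is.null(config$precision)) 2L else
    as.integer(config$precision)
  if (is.na(precision) || precision < 0L) {
    stop("precision: must be a non-negative integer", call. = FALSE)
  }

  factors <- .factors_from_config(config$factors)

  out <- list(evaluator = evaluator, direction = direction,
              precision = precision, seed = config$seed, factors = factors)

  if (evaluator == "responses") {
    if (is.null(config$responses$path)) {
      stop("responses.path: required for the responses evaluator",
           call. = FALSE)
    }
    out$responses <- list(
      path = config$responses$path,
      optimum_response_mpa = config$responses$optimum_response_mpa)
  } else if (evaluator == "planted") {
    pl <- .merge_defaults(config$planted,
                          list(base_mpa = 16.5,
                               optimum = list(varus_deg = 0, slope_deg = 1,
                                              rotation_deg = 4),
                               weights = list(varus = 1.0, slope = 0.8,
                                              rotation = 0.6),
                               noise_sd_mpa = 0))
    out$planted <- list(
      bowl = planted_bowl(pl$base_mpa, unlist(pl$optimum),
                          unlist(pl$weights)),
      noise_sd_mpa = pl$noise_sd_mpa)
    if (pl$noise_sd_mpa > 0 && is.null(config$seed)) {
      stop("seed: required when planted.noise_sd_mpa > 0", call. = FALSE)
    }
    if (pl$noise_sd_mpa == 0 && !is.null(config$seed)) {
      stop("seed: only meaningful when planted noise is enabled",
           call. = FALSE)
    }
  } else {
    sg <- config$surrogate
    geom <- do.call(articular_geometry,
                    .merge_defaults(sg$geometry, list()))
    ld <- do.call(load_case, .merge_defaults(sg$load, list()))
    mats <- .merge_defaults(sg$materials, default_materials())
    ligs <- list(
      medial = do.call(ligament_spec, c(list(side = "medial"),
        .merge_defaults(sg$ligaments$medial, list(c1_mpa = 6.43)))),
      lateral = do.call(ligament_spec, c(list(side = "lateral"),
        .merge_defaults(sg$ligaments$lateral, list(c1_mpa = 6.06)))))
    out$surrogate <- list(
      inherent_slope_deg = if (is.null(sg$inherent_slope_deg)) 3 else
        sg$inherent_slope_deg,
      geometry = geom, load = ld, materials = mats, ligaments = ligs)
    if (!is.null(config$seed)) {
      stop("seed: only meaningful when planted noise is enabled",
           call. = FALSE)
    }
  }
  structure(out, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path Path to a YAML file in the [pipeline_config()] schema.
#' @return A validated `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  pipeline_config(yaml::read_yaml(path))
}

#' Serialize a pipeline configuration back to a nested list / YAML
#'
#' The dumped form reloads to a semantically identical configuration.
#'
#' @param config A `pipeline_config`.
#' @param path Optional YAML output path.
#' @return The nested list (invisibly if `path` is given).
#' @export
dump_config <- function(config, path = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  lst <- list(evaluator = config$evaluator, direction = config$direction,
              precision = config$precision)
  if (!is.null(config$seed)) lst$seed <- config$seed
  lst$factors <- lapply(config$factors, function(f) {
    list(name = f$name, symbol = f$symbol, levels = as.list(f$levels),
         sign_convention = f$sign_convention, column = f$column)
  })
  names(lst$factors) <- NULL
  if (config$evaluator == "responses") {
    lst$responses <- Filter(Negate(is.null), config$responses)
  } else if (config$evaluator == "planted") {
    b <- config$planted$bowl
    lst$planted <- list(base_mpa = b$base_mpa,
                        optimum = as.list(b$optimum),
                        weights = as.list(b$weights),
                        noise_sd_mpa = config$planted$noise_sd_mpa)
  } else {
    sg <- config$surrogate
    geom <- unclass(sg$geometry)
    geom$centers <- NULL
    lst$surrogate <- list(
      inherent_slope_deg = sg$inherent_slope_deg,
      geometry = geom,
      load = unclass(sg$load),
      materials = sg$materials,
      ligaments = lapply(sg$ligaments, function(l) {
        l <- unclass(l); l$side <- NULL; l
      }))
  }
  if (!is.null(path)) {
    yaml::write_yaml(lst, path)
    return(invisible(lst))
  }
  lst
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config> evaluator:", x$evaluator, "| direction:",
      x$direction, "| precision:", x$precision, "\n")
  cat("  factors:", paste(vapply(x$factors, `[[`, "", "symbol"),
                          collapse = ", "), "\n")
  invisible(x)
}

.alignment_from_row <- function(row, inherent_slope_deg = 3) {
  implant_alignment(varus_deg = row$varus_deg,
                    cut_slope_deg = row$slope_deg,
                    rotation_deg = row$rotation_deg,
                    inherent_slope_deg = inherent_slope_deg)
}

.config_evaluator <- function(config) {
  if (config$evaluator == "planted") {
    bowl <- config$planted$bowl
    function(alignment) planted_response(alignment, bowl)
  } else if (config$evaluator == "surrogate") {
    sg <- config$surrogate
    function(alignment) {
      surrogate_response(sg$geometry, alignment, sg$materials, sg$ligaments,
                         sg$load)
    }
  } else NULL
}

#' Evaluate every design run with an evaluator function
#'
#' Applies `eval_fn` (an `implant_alignment -> peak pressure MPa` function,
#' or one returning a list with a `peak_mpa` field) to every run of a design
#' over the standard angle columns, optionally adding seeded Gaussian noise.
#'
#' @param design A `design_table` with `varus_deg`, `slope_deg`,
#'   `rotation_deg` columns.
#' @param eval_fn Evaluator function.
#' @param inherent_slope_deg Component's built-in slope passed to the
#'   alignment (default 3).
#' @param noise_sd_mpa Additive Gaussian noise standard deviation (default
#'   0 = deterministic).
#' @param seed Integer seed; required when `noise_sd_mpa > 0`.
#' @return A `response_table`.
#' @export
evaluate_design <- function(design, eval_fn, inherent_slope_deg = 3,
                            noise_sd_mpa = 0, seed = NULL) {
  stopifnot(inherits(design, "design_table"), is.function(eval_fn))
  if (noise_sd_mpa > 0 && is.null(seed)) {
    stop("noise requires an explicit seed", call. = FALSE)
  }
  y <- vapply(seq_len(nrow(design)), function(i) {
    row <- as.data.frame(design)[i, ]
    res <- tryCatch(
      eval_fn(.alignment_from_row(row, inherent_slope_deg)),
      error = function(e) {
        stop("evaluation failed on run ", row$run_id, ": ",
             conditionMessage(e), call. = FALSE)
      })
    if (is.list(res)) res$peak_mpa else as.numeric(res)
  }, 0)
  if (noise_sd_mpa > 0) {
    set.seed(seed)
    y <- y + stats::rnorm(length(y), 0, noise_sd_mpa)
    y <- pmax(y, 1e-6)  # responses stay positive
  }
  response_table(design, y)
}

#' Join an external response file onto a design
#'
#' Matches responses to design runs by `run_id` and cross-checks the
#' combination labels and angle values; any missing run, duplicated run,
#' unknown run, or label/angle mismatch is an error naming the run.
#'
#' @param design A `design_table`.
#' @param path Delimited-text response file with header
#'   `run_id,combination,<angle columns>,peak_pressure_mpa`.
#' @return A `response_table` in design run order.
#' @export
join_external_responses <- function(design, path) {
  stopifnot(inherits(design, "design_table"))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("run_id", "combination", "peak_pressure_mpa")
  if (!all(need %in% names(df))) {
    stop("response file lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$run_id)) {
    stop("duplicate run_id in response file: ",
         paste(unique(df$run_id[duplicated(df$run_id)]), collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(design$run_id, df$run_id)
  if (length(missing)) {
    stop("response file is missing run", if (length(missing) > 1) "s",
         " ", paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(df$run_id, design$run_id)
  if (length(extra)) {
    stop("response file has unknown run", if (length(extra) > 1) "s", " ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  df <- df[match(design$run_id, df$run_id), ]
  bad <- which(df$combination != design$combination)
  if (length(bad)) {
    stop("combination label mismatch for run ", design$run_id[bad[1]],
         ": design '", design$combination[bad[1]], "' vs file '",
         df$combination[bad[1]], "'", call. = FALSE)
  }
  for (f in attr(design, "factors")) {
    if (f$column %in% names(df)) {
      bad <- which(abs(df[[f$column]] - design[[f$column]]) > 1e-9)
      if (length(bad)) {
        stop("angle mismatch in column '", f$column, "' for run ",
             design$run_id[bad[1]], call. = FALSE)
      }
    }
  }
  response_table(design, df$peak_pressure_mpa)
}

#' Verify the predicted optimal combination
#'
#' Evaluates (or accepts a supplied value for) the predicted optimum's peak
#' contact pressure and compares it against every design-run response:
#' reduction from the worst run (absolute, and as a percent of the worst
#' run and of the optimum's own value) and whether the optimum beats all
#' design runs.
#'
#' @param optimal A `range_ranking` from [optimal_combination()] (or a
#'   `range_analysis`, whose ranking is used).
#' @param responses The design `response_table` the prediction came from.
#' @param eval_fn Optional evaluator (as in [evaluate_design()]) used to
#'   compute the optimum's response.
#' @param supplied_value Optional externally obtained response for the
#'   optimum (MPa); used when no evaluator is available.
#' @param inherent_slope_deg Passed to the alignment for `eval_fn`.
#' @return An object of class `verification_record`.
#' @export
verify_optimum <- function(optimal, responses, eval_fn = NULL,
                           supplied_value = NULL, inherent_slope_deg = 3) {
  if (inherits(optimal, "range_analysis")) optimal <- optimal$ranking
  stopifnot(inherits(optimal, "range_ranking"),
            inherits(responses, "response_table"))
  angles <- optimal$optimal_angles
  comp_diff <- NA_real_
  peak_comp <- NA_character_
  if (!is.null(eval_fn)) {
    al <- implant_alignment(varus_deg = angles[["varus_deg"]],
                            cut_slope_deg = angles[["slope_deg"]],
                            rotation_deg = angles[["rotation_deg"]],
                            inherent_slope_deg = inherent_slope_deg)
    res <- eval_fn(al)
    if (is.list(res)) {
      value <- res$peak_mpa
      peak_comp <- res$peak_compartment
      if (!is.null(res$compartment_peaks_mpa)) {
        comp_diff <- abs(diff(res$compartment_peaks_mpa))
      }
    } else value <- as.numeric(res)
  } else if (!is.null(supplied_value)) {
    value <- as.numeric(supplied_value)
  } else {
    stop("no evaluator and no supplied optimum response value",
         call. = FALSE)
  }
  y <- responses$peak_pressure_mpa
  worst <- max(y)
  structure(
    list(optimal_combination = optimal$optimal_combination,
         optimal_angles = angles,
         peak_mpa = value,
         peak_compartment = peak_comp,
         compartment_peak_diff_mpa = comp_diff,
         design_responses = stats::setNames(y, responses$combination),
         worst_mpa = worst,
         reduction_mpa = worst - value,
         reduction_pct_of_worst = 100 * (worst - value) / worst,
         spread_pct_vs_optimum = 100 * (worst - value) / value,
         best_of_all = value <= min(y)),
    class = "verification_record")
}

#' @export
print.verification_record <- function(x, digits = 2, ...) {
  cat("<verification_record>", x$optimal_combination, "->",
      sprintf("%.*f MPa", digits, x$peak_mpa),
      if (isTRUE(x$best_of_all)) "(best of all runs)" else
        "(NOT best of all runs)", "\n")
  cat(sprintf(
    "  reduction vs worst run: %.*f MPa (%.1f%% of worst, %.1f%% of optimum)\n",
    digits, x$reduction_mpa, x$reduction_pct_of_worst,
    x$spread_pct_vs_optimum))
  invisible(x)
}

#' Render the analysis report
#'
#' @param analysis A `range_analysis`.
#' @param verification Optional `verification_record`.
#' @param precision Display precision in decimals (default 2); the
#'   machine-readable form keeps full precision.
#' @return List of class `pipeline_report` with `text` (character lines) and
#'   `data` (nested list for JSON serialization).
#' @export
render_report <- function(analysis, verification = NULL, precision = 2) {
  stopifnot(inherits(analysis, "range_analysis"))
  K <- analysis$K$K
  rr <- analysis$ranking
  fmt <- function(v) sprintf("%.*f", precision, v)
  lines <- c(
    "Range analysis of peak contact pressure (MPa)",
    "",
    "Level means K[factor, level]:")
  for (j in seq_len(nrow(K))) {
    lines <- c(lines, sprintf("  %s: %s", rownames(K)[j],
                              paste(fmt(K[j, ]), collapse = "  ")))
  }
  lines <- c(lines,
    sprintf("Range R: %s",
            paste(sprintf("%s=%s", names(rr$R), fmt(rr$R)), collapse = "  ")),
    sprintf("Ranking: %s", paste(rr$ranking, collapse = " > ")),
    sprintf("Optimal: %s (%s)", rr$optimal_combination,
            paste(sprintf("%s=%g", names(rr$optimal_angles),
                          rr$optimal_angles), collapse = ", ")),
    sprintf("Objective: %s", rr$direction),
    sprintf("Response spread: max %s, min %s, max-min %s MPa (%.1f%%)",
            fmt(analysis$spread$max), fmt(analysis$spread$min),
            fmt(analysis$spread$spread), analysis$spread$spread_pct),
    "",
    "Trend table (factor, level value deg, mean peak pressure MPa):")
  tt <- analysis$trend
  lines <- c(lines, sprintf("  %s %6g  %s", tt$symbol, tt$level_value_deg,
                            fmt(tt$mean_peak_pressure_mpa)))
  data <- list(
    level_means_mpa = as.list(as.data.frame(t(K))),
    ranges_mpa = as.list(rr$R),
    ranking = rr$ranking,
    optimal_combination = rr$optimal_combination,
    optimal_angles_deg = as.list(rr$optimal_angles),
    direction = rr$direction,
    spread = analysis$spread,
    trend = analysis$trend)
  if (!is.null(verification)) {
    v <- verification
    lines <- c(lines, "",
      sprintf("Verification of %s: peak %s MPa%s", v$optimal_combination,
              fmt(v$peak_mpa),
              if (isTRUE(v$best_of_all)) " (best of all runs)" else
                " (NOT best of all runs)"),
      sprintf("  reduction vs worst run %s MPa: %s MPa (%.1f%% of worst, %.1f%% of optimum)",
              fmt(v$worst_mpa), fmt(v$reduction_mpa),
              v$reduction_pct_of_worst, v$spread_pct_vs_optimum))
    if (!is.na(v$compartment_peak_diff_mpa)) {
      lines <- c(lines,
        sprintf("  medial-lateral peak difference: %s MPa",
                fmt(v$compartment_peak_diff_mpa)))
    }
    data$verification <- v[c("optimal_combination", "peak_mpa",
                             "worst_mpa", "reduction_mpa",
                             "reduction_pct_of_worst",
                             "spread_pct_vs_optimum", "best_of_all")]
    data$verification$optimal_angles_deg <- as.list(v$optimal_angles)
    if (!is.na(v$compartment_peak_diff_mpa)) {
      data$verification$compartment_peak_diff_mpa <-
        v$compartment_peak_diff_mpa
    }
  }
  structure(list(text = lines, data = data), class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(x$text, sep = "\n")
  invisible(x)
}

#' Run the full design / evaluation / analysis / verification pipeline
#'
#' Builds the L9 design over the configured factors, validates its
#' orthogonality, obtains one peak-contact-pressure response per run from
#' the configured evaluator (contact surrogate, planted bowl, or an external
#' response file), performs the range analysis, evaluates the predicted
#' optimum where an evaluator is available (or uses a supplied value), and
#' writes `design.csv`, `responses.csv`, `report.txt`, `report.json` and
#' `log.txt` into `out_dir`. Identical configuration and seed give
#' byte-identical output files.
#'
#' @param config A `pipeline_config` (or nested list / YAML path accepted by
#'   [pipeline_config()] / [load_config()]).
#' @param out_dir Output directory (created if needed); `NULL` skips file
#'   output.
#' @param seed Overrides `config$seed`.
#' @return List of class `pipeline_result`: `design`, `responses`,
#'   `analysis`, `verification` (or `NULL`), `report`, `paths`.
#' @export
#' @examples
#' cfg <- pipeline_config(list(evaluator = "planted"))
#' res <- run_pipeline(cfg, out_dir = NULL)
#' res$analysis$ranking$optimal_combination
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config)) config <- load_config(config)
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  if (is.null(seed)) seed <- config$seed
  log <- character()
  say <- function(...) log <<- c(log, sprintf(...))

  say("stage=design factors=%s array=L9(3^4)",
      paste(vapply(config$factors, `[[`, "", "symbol"), collapse = ""))
  oa <- build_orthogonal_array(3, length(config$factors))
  rep_ok <- validate_orthogonality(oa)
  if (!rep_ok$pass) stop("orthogonal array failed validation", call. = FALSE)
  design <- instantiate_design(oa, config$factors)

  inherent <- if (config$evaluator == "surrogate")
    config$surrogate$inherent_slope_deg else 3
  noise <- if (config$evaluator == "planted")
    config$planted$noise_sd_mpa else 0
  say("stage=evaluate evaluator=%s noise_sd_mpa=%g seed=%s",
      config$evaluator, noise,
      if (is.null(seed)) "none" else as.character(seed))
  if (config$evaluator == "responses") {
    responses <- join_external_responses(design, config$responses$path)
  } else {
    responses <- evaluate_design(design, .config_evaluator(config),
                                 inherent_slope_deg = inherent,
                                 noise_sd_mpa = noise, seed = seed)
  }

  say("stage=analyze direction=%s", config$direction)
  analysis <- range_analysis(responses, direction = config$direction)

  eval_fn <- .config_evaluator(config)
  supplied <- if (config$evaluator == "responses")
    config$responses$optimum_response_mpa else NULL
  verification <- NULL
  if (!is.null(eval_fn) || !is.null(supplied)) {
    say("stage=verify optimum=%s", analysis$ranking$optimal_combination)
    verification <- verify_optimum(analysis, responses, eval_fn = eval_fn,
                                   supplied_value = supplied,
                                   inherent_slope_deg = inherent)
  } else {
    say("stage=verify skipped (no evaluator and no supplied optimum value)")
  }

  report <- render_report(analysis, verification,
                          precision = config$precision)
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(design = file.path(out_dir, "design.csv"),
                  responses = file.path(out_dir, "responses.csv"),
                  report_txt = file.path(out_dir, "report.txt"),
                  report_json = file.path(out_dir, "report.json"),
                  log = file.path(out_dir, "log.txt"))
    write_design(design, paths$design)
    utils::write.csv(as.data.frame(responses), paths$responses,
                     row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    writeLines(report$text, paths$report_txt)
    jsonlite::write_json(report$data, paths$report_json, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    writeLines(log, paths$log)
  }
  structure(list(design = design, responses = responses, analysis = analysis,
                 verification = verification, report = report, log = log,
                 paths = paths),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  print(x$report)
  invisible(x)
}
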