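#' The packaged shrimp-waste deacetylation experiment
#'
#' The 17-run rotatable central composite experiment (2^3 factorial, six
#' axial runs at coded +/- 1.68, three center replicates) on chitin from
#' shrimp waste, with the measured deacetylation degree (%), viscometric
#' molar mass (kDa) and extraction yield (%) per run. Deacetylation
#' temperature was held at 95 degC throughout; the varied factors are
#' those of [chitosan_factors()]. The table ships as read-only package
#' data and is the input every published model in this package is fitted
#' to.
#'
#' @return A 17-row tibble: `run_id`, coded `x1`, `x2`, `x3`,
#'   `yield_pct`, `dd_pct`, `mm_kda`.
#' @examples
#' shrimp_ccd()
#' @export
shrimp_ccd <- function() {
  path <- system.file("extdata", "shrimp_ccd.csv", package = "chitopt",
                      mustWork = TRUE)
  read_experiment_csv(path)
}

#' Read and write experiment tables
#'
#' `read_experiment_csv()` loads a coded experiment table, requiring a
#' `run_id` column, coded factor columns `x1`, `x2`, ... (real-valued
#' columns are accepted instead and coded on ingest via [code_levels()]),
#' and at least one response column. Unknown columns are preserved, and a
#' canonical file round-trips losslessly through
#' `readr::write_csv()`/`read_experiment_csv()`.
#'
#' @param path File path.
#' @param factors Factor tibble used to code real-valued columns when no
#'   coded columns are present.
#' @return A tibble.
#' @export
read_experiment_csv <- function(path, factors = chitosan_factors()) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  tbl <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_guess()))
  if (nrow(tbl) == 0 || ncol(tbl) <= 1) {
    abort(paste0("`", basename(path), "` has no data rows; expected at least ",
                 "`run_id`, coded factors and one response column."))
  }
  if (!"run_id" %in% names(tbl)) abort("Missing mandatory column `run_id`.")
  coded <- grep("^x[0-9]+$", names(tbl), value = TRUE)
  if (length(coded) == 0) {
    if (all(factors$column %in% names(tbl))) {
      tbl <- code_levels(tbl, factors)
      coded <- factors$factor
    } else {
      abort(paste0("No coded columns (x1, x2, ...) and incomplete real-valued ",
                   "columns; need ", paste(factors$column, collapse = ", "), "."))
    }
  }
  responses <- intersect(c("dd_pct", "mm_kda", "yield_pct"), names(tbl))
  if (length(responses) == 0) {
    abort("No response column found (expected dd_pct, mm_kda or yield_pct).")
  }
  for (cn in c(coded, responses)) {
    if (!is.numeric(tbl[[cn]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(tbl[[cn]]))))[1]
      abort(paste0("Non-numeric value in column `", cn, "`, row ", bad, "."))
    }
  }
  tbl
}

#' @rdname read_experiment_csv
#' @param front A `pareto_front`.
#' @param factors Factor tibble used to decode operating conditions.
#' @export
write_front_csv <- function(front, path, factors = chitosan_factors()) {
  readr::write_csv(front_report(front, factors), path)
  invisible(path)
}

#' Serialize quadratic models as JSON
#'
#' Writes/reads a [quadratic_model()] as a small JSON object (term
#' labels, coefficients, number of factors, response, units); the pair
#' round-trips exactly at full double precision.
#'
#' @param model A `quadratic_model`.
#' @param path File path.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "quadratic_model"))
  jsonlite::write_json(
    list(terms = names(model), coefficients = as.numeric(model),
         k = attr(model, "k"), response = attr(model, "response"),
         units = attr(model, "units")),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  quadratic_model(setNames(obj$coefficients, obj$terms), k = obj$k,
                  response = obj$response, units = obj$units)
}

# Published reference values the reproduction run is compared against
# (coefficients and model statistics of the shrimp-waste study).
reference_values <- function() {
  tibble::tribble(
    ~quantity, ~reference, ~tolerance, ~relative,
    "dd_full_intercept", 90.3432, 0.005, TRUE,
    "dd_full_b1", 16.0728, 0.005, TRUE,
    "dd_full_b11", -10.6993, 0.005, TRUE,
    "dd_full_r2", 0.91, 0.005, FALSE,
    "dd_full_p", 0.0052, 0.0005, FALSE,
    "mm_full_b1", 229.7859, 0.005, TRUE,
    "mm_full_b33", -202.8130, 0.005, TRUE,
    "mm_full_r2", 0.94, 0.005, FALSE,
    "mm_full_p", 0.0012, 0.0005, FALSE,
    "dd_reduced_intercept", 90.897, 0.005, TRUE,
    "dd_reduced_r2", 0.907, 0.005, FALSE,
    "mm_max_kda", 865, 1, FALSE,
    "mm_argmax_x1", 0.8583, 0.001, FALSE,
    "mm_argmax_x3", 0.268, 0.001, FALSE,
    "dd_at_front_point", 97.60, 0.05, FALSE,
    "mm_at_front_point", 863.66, 0.5, FALSE
  )
}

#' Reproduce the full deacetylation-optimization analysis
#'
#' Runs the whole pipeline on the packaged experiment (or a user table):
#' full and reduced OLS fits for deacetylation degree and molar mass, the
#' analytic molar-mass maximum over the coded box, both bi-objective
#' Pareto fronts (NSGA-II and the deterministic grid oracle), and a
#' comparison of the recomputed quantities against the published
#' reference values. When `out_dir` is given, models (JSON), ANOVA tables
#' and fronts (CSV) are written there; outputs are deterministic given
#' `seed`.
#'
#' @param data Experiment table; defaults to [shrimp_ccd()].
#' @param out_dir Optional output directory (created if missing).
#' @param grid_resolution Lattice points per axis for the grid oracle.
#' @param control NSGA-II settings from [nsga2_control()].
#' @param seed Integer seed for the genetic-algorithm runs.
#' @return A list: `fits` (full), `reduced`, `mm_optimum`, `fronts`
#'   (`max_max`/`max_min`, each with `nsga2` and `grid`), `comparison`
#'   (tibble with pass/fail per quantity) and `all_pass`.
#' @examples
#' \donttest{
#' rep <- run_reproduction(grid_resolution = 51,
#'                         control = nsga2_control(generations = 50))
#' rep$comparison
#' }
#' @export
run_reproduction <- function(data = shrimp_ccd(), out_dir = NULL,
                             grid_resolution = 201,
                             control = nsga2_control(), seed = 1) {
  fits <- list(
    dd = fit_response_surface(data, "dd_pct"),
    mm = fit_response_surface(data, "mm_kda")
  )
  reduced <- list(
    dd = reduce_fit(fits$dd, dd_reduced_terms()),
    mm = reduce_fit(fits$mm, mm_reduced_terms())
  )
  dd_model <- as_quadratic_model(reduced$dd)
  mm_model <- as_quadratic_model(reduced$mm)
  mm_opt <- maximize_quadratic(mm_model)

  models <- list(dd_model, mm_model)
  fronts <- list(
    max_max = list(
      nsga2 = nsga2(models, c("max", "max"), control = control, seed = seed),
      grid = grid_front(models, c("max", "max"), resolution = grid_resolution)
    ),
    max_min = list(
      nsga2 = nsga2(models, c("max", "min"), control = control, seed = seed),
      grid = grid_front(models, c("max", "min"), resolution = grid_resolution)
    )
  )

  probe <- c(0.80, -0.10, 0.31)
  computed <- c(
    dd_full_intercept = unname(fits$dd$coefficients["1"]),
    dd_full_b1 = unname(fits$dd$coefficients["x1"]),
    dd_full_b11 = unname(fits$dd$coefficients["x1^2"]),
    dd_full_r2 = fits$dd$r.squared,
    dd_full_p = fits$dd$f.p.value,
    mm_full_b1 = unname(fits$mm$coefficients["x1"]),
    mm_full_b33 = unname(fits$mm$coefficients["x3^2"]),
    mm_full_r2 = fits$mm$r.squared,
    mm_full_p = fits$mm$f.p.value,
    dd_reduced_intercept = unname(reduced$dd$coefficients["1"]),
    dd_reduced_r2 = reduced$dd$r.squared,
    mm_max_kda = mm_opt$value,
    mm_argmax_x1 = unname(mm_opt$par["x1"]),
    mm_argmax_x3 = unname(mm_opt$par["x3"]),
    dd_at_front_point = unname(predict(dd_model, probe)),
    mm_at_front_point = unname(predict(mm_model, probe))
  )
  comparison <- reference_values() |>
    dplyr::mutate(
      computed = unname(computed[.data$quantity]),
      delta = .data$computed - .data$reference,
      pass = ifelse(.data$relative,
                    abs(.data$delta) <= .data$tolerance * abs(.data$reference),
                    abs(.data$delta) <= .data$tolerance)
    ) |>
    dplyr::select("quantity", "computed", "reference", "delta",
                  "tolerance", "relative", "pass")

  result <- list(fits = fits, reduced = reduced, mm_optimum = mm_opt,
                 fronts = fronts, comparison = comparison,
                 all_pass = all(comparison$pass))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_model_json(dd_model, file.path(out_dir, "dd_reduced_model.json"))
    write_model_json(mm_model, file.path(out_dir, "mm_reduced_model.json"))
    write_model_json(as_quadratic_model(fits$dd), file.path(out_dir, "dd_full_model.json"))
    write_model_json(as_quadratic_model(fits$mm), file.path(out_dir, "mm_full_model.json"))
    readr::write_csv(tidy(fits$dd), file.path(out_dir, "dd_anova.csv"))
    readr::write_csv(tidy(fits$mm), file.path(out_dir, "mm_anova.csv"))
    write_front_csv(fronts$max_max$nsga2, file.path(out_dir, "front_max_max_nsga2.csv"))
    write_front_csv(fronts$max_max$grid, file.path(out_dir, "front_max_max_grid.csv"))
    write_front_csv(fronts$max_min$nsga2, file.path(out_dir, "front_max_min_nsga2.csv"))
    write_front_csv(fronts$max_min$grid, file.path(out_dir, "front_max_min_grid.csv"))
    readr::write_csv(comparison, file.path(out_dir, "comparison.csv"))
  }
  result
}
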