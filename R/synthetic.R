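#' Simulate CCD response tables from known quadratic surfaces
#'
#' Generates an experiment table whose responses are draws from
#' `predict(true model, run) + N(0, sd)`, per design run — the
#' data-generating process a central-composite experiment with
#' homoscedastic measurement error is assumed to follow. With the
#' defaults it emulates the shrimp-waste deacetylation study: the fitted
#' reduced surfaces as truth, Gaussian noise with standard deviations
#' calibrated to those fits' residual scatter (8.6 DD-percentage points
#' and 107 kDa), and the 17-run rotatable CCD.
#'
#' Simulated deacetylation degrees outside the physical `[0, 100]` range
#' are flagged in a `dd_pct_in_range` column, never silently truncated, so
#' downstream fits see exactly the generated surface plus noise.
#'
#' @param models Named list of [quadratic_model()]s; names become response
#'   columns.
#' @param sd Named numeric vector of noise standard deviations, one per
#'   response (response units).
#' @param design Coded design tibble from [ccd_design()].
#' @param seed Integer seed; the same seed reproduces the table exactly
#'   and the caller's random-number state is left untouched.
#' @return The design tibble with simulated response columns appended.
#' @examples
#' simulate_responses(seed = 42)
#' @export
simulate_responses <- function(models = list(dd_pct = dd_reduced_model(),
                                             mm_kda = mm_reduced_model()),
                               sd = c(dd_pct = 8.6, mm_kda = 107),
                               design = ccd_design(chitosan_factors()),
                               seed = NULL) {
  if (is.null(names(models)) || any(names(models) == "")) {
    abort("`models` must be a named list of quadratic models.")
  }
  sd <- sd[names(models)]
  if (anyNA(sd) || any(sd < 0)) {
    abort("`sd` must supply a nonnegative value for every response in `models`.")
  }
  draw <- function() {
    out <- tibble::as_tibble(design)
    for (resp in names(models)) {
      mu <- predict(models[[resp]], out)
      out[[resp]] <- mu + rnorm(nrow(out), 0, sd[[resp]])
    }
    out
  }
  out <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  for (resp in grep("^dd", names(models), value = TRUE)) {
    vals <- out[[resp]]
    if (any(vals < 0 | vals > 100)) {
      out[[paste0(resp, "_in_range")]] <- vals >= 0 & vals <= 100
      warn(paste0("Simulated `", resp, "` outside [0, 100] flagged in `",
                  resp, "_in_range` (values are not truncated)."))
    }
  }
  out
}

#' Monte-Carlo coefficient-recovery experiment
#'
#' Repeatedly simulates a response from a known quadratic surface,
#' refits it by OLS, and summarizes per-coefficient bias, empirical
#' spread, and the empirical coverage of the nominal t-based confidence
#' interval — the standard calibration check that the fitting machinery
#' recovers what the generator put in.
#'
#' @param model The true [quadratic_model()].
#' @param sd Noise standard deviation (response units).
#' @param design Coded design tibble from [ccd_design()].
#' @param terms Terms to fit; defaults to the generating terms.
#' @param n_replicates Number of simulated experiments (>= 2).
#' @param level Nominal confidence level for the coverage check.
#' @param seed Integer seed.
#' @return A tibble with one row per term: `true`, `mean_estimate`,
#'   `bias`, `empirical_sd`, `mean_se` and `coverage` (share of
#'   replicates whose interval covered the truth).
#' @examples
#' recovery_experiment(mm_reduced_model(), sd = 60, n_replicates = 50, seed = 7)
#' @export
recovery_experiment <- function(model, sd,
                                design = ccd_design(chitosan_factors()),
                                terms = names(model),
                                n_replicates = 500, level = 0.95,
                                seed = NULL) {
  if (n_replicates < 2) abort("`n_replicates` must be >= 2.")
  run <- function() {
    purrr::map(seq_len(n_replicates), function(r) {
      tbl <- tibble::as_tibble(design)
      tbl$y <- predict(model, tbl) + rnorm(nrow(tbl), 0, sd)
      fit <- fit_response_surface(tbl, "y", terms = terms)
      dplyr::mutate(fit$coef_table, df = fit$df.residual, replicate = r)
    }) |>
      dplyr::bind_rows()
  }
  draws <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  truth <- tibble::tibble(term = names(model), true = as.numeric(model))
  draws |>
    dplyr::left_join(truth, by = "term") |>
    dplyr::mutate(
      true = dplyr::coalesce(.data$true, 0),
      half = qt(1 - (1 - level) / 2, .data$df) * .data$std.error,
      covered = abs(.data$estimate - .data$true) <= .data$half
    ) |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      true = .data$true[1],
      mean_estimate = mean(.data$estimate),
      bias = mean(.data$estimate) - .data$true[1],
      empirical_sd = stats::sd(.data$estimate),
      mean_se = mean(.data$std.error),
      coverage = mean(.data$covered),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$term, terms))
}
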