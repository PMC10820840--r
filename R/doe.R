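#' Define the factors of a central composite design
#'
#' A factor definition ties a coded variable (`x1`, `x2`, ...) to a real
#' operating parameter through the linear map
#' `real = center + step * coded`, so that the factorial levels sit at
#' coded -1/+1 and the design center at coded 0.
#'
#' @param name Character vector of human-readable factor names.
#' @param unit Character vector of measurement units.
#' @param column Character vector of column names used for the real-valued
#'   view of the factor in data frames.
#' @param center Numeric vector, real value at coded 0.
#' @param step Numeric vector, real change per +1 coded unit; must be > 0.
#'
#' @return A tibble with one row per factor and columns `factor` (`x1`,
#'   `x2`, ...), `name`, `unit`, `column`, `center`, `step`.
#' @examples
#' ccd_factors(
#'   name = c("temperature", "pH"), unit = c("degC", ""),
#'   column = c("temp_c", "ph"), center = c(60, 7), step = c(5, 0.5)
#' )
#' @seealso [chitosan_factors()] for the chitin-deacetylation factors.
#' @export
ccd_factors <- function(name, unit, column, center, step) {
  if (any(step <= 0)) {
    abort("`step` must be strictly positive for every factor.")
  }
  k <- length(name)
  if (k < 1) abort("At least one factor is required.")
  lens <- lengths(list(unit, column, center, step))
  if (any(lens != k)) {
    abort("`name`, `unit`, `column`, `center` and `step` must have equal length.")
  }
  tibble::tibble(
    factor = paste0("x", seq_len(k)),
    name = as.character(name),
    unit = as.character(unit),
    column = as.character(column),
    center = as.numeric(center),
    step = as.numeric(step)
  )
}

#' Factors of the chitin deacetylation experiment
#'
#' The three operating parameters varied during alkaline deacetylation of
#' shrimp-waste chitin: NaOH concentration (center 45%, step 10%),
#' liquid:solid ratio (center 18, step 5) and process duration (center
#' 120 min, step 30 min). The axial runs sit at coded +/- 1.68.
#'
#' @return A factor tibble as returned by [ccd_factors()].
#' @examples
#' chitosan_factors()
#' @export
chitosan_factors <- function() {
  ccd_factors(
    name = c("NaOH concentration", "liquid:solid ratio", "duration"),
    unit = c("%", "", "min"),
    column = c("naoh_pct", "ratio", "duration_min"),
    center = c(45, 18, 120),
    step = c(10, 5, 30)
  )
}

#' Build a rotatable central composite design
#'
#' Constructs the `2^k + 2k + n_center` runs of a central composite design
#' in coded units: the full two-level factorial block (standard Yates
#' order, `x1` varying fastest), one axial pair at coded `+/- alpha` per
#' factor, and `n_center` replicated center runs.
#'
#' @param factors Factor tibble from [ccd_factors()].
#' @param n_center Number of replicated center runs (>= 0).
#' @param alpha Coded magnitude of the axial runs; must be >= 1. The
#'   default 1.68 is the rounded rotatable value for `k = 3` used
#'   throughout the packaged shrimp-waste experiment.
#'
#' @return A tibble with columns `run_id`, `type`
#'   (`"factorial"`/`"axial"`/`"center"`) and one coded column per factor.
#'   The factor definitions are carried in the `"factors"` attribute.
#' @examples
#' des <- ccd_design(chitosan_factors(), n_center = 3)
#' nrow(des) # 17
#' colSums(des[, c("x1", "x2", "x3")]) # all zero
#' @export
ccd_design <- function(factors, n_center = 3, alpha = 1.68) {
  stopifnot(is.data.frame(factors), nrow(factors) >= 1)
  if (any(factors$step <= 0)) abort("`step` must be strictly positive.")
  if (alpha < 1) abort("`alpha` must be >= 1.")
  if (n_center < 0) abort("`n_center` must be >= 0.")
  k <- nrow(factors)

  fact <- purrr::map(seq_len(k), function(i) rep(c(-1, 1), each = 2^(i - 1), times = 2^(k - i)))
  factorial <- do.call(cbind, fact)
  axial <- matrix(0, nrow = 2 * k, ncol = k)
  for (i in seq_len(k)) {
    axial[2 * i - 1, i] <- -alpha
    axial[2 * i, i] <- alpha
  }
  center <- matrix(0, nrow = n_center, ncol = k)

  coded <- rbind(factorial, axial, center)
  colnames(coded) <- factors$factor
  out <- tibble::as_tibble(coded)
  out <- dplyr::bind_cols(
    tibble::tibble(
      run_id = seq_len(nrow(coded)),
      type = rep(c("factorial", "axial", "center"), c(2^k, 2 * k, n_center))
    ),
    out
  )
  attr(out, "factors") <- factors
  attr(out, "alpha") <- alpha
  out
}

#' Convert between real and coded factor levels
#'
#' `code_levels()` appends coded columns (`x1`, ...) computed as
#' `(real - center) / step` from the real-valued columns named in the
#' factor table; `decode_levels()` appends real-valued columns computed as
#' `center + step * coded`. The two maps are exact inverses.
#'
#' @param data A data frame holding the columns to convert.
#' @param factors Factor tibble from [ccd_factors()]; defaults to the
#'   chitin-deacetylation factors.
#'
#' @return The input as a tibble with the converted columns appended
#'   (existing columns of the same name are overwritten).
#' @examples
#' library(tibble)
#' code_levels(tibble(naoh_pct = 55, ratio = 18, duration_min = 128.04))
#' decode_levels(tibble(x1 = 0.8583, x2 = 0, x3 = 0.268))
#' @export
code_levels <- function(data, factors = chitosan_factors()) {
  missing <- setdiff(factors$column, names(data))
  if (length(missing) > 0) {
    abort(paste0("Missing real-valued column(s): ", paste(missing, collapse = ", ")))
  }
  out <- tibble::as_tibble(data)
  for (i in seq_len(nrow(factors))) {
    out[[factors$factor[i]]] <-
      (out[[factors$column[i]]] - factors$center[i]) / factors$step[i]
  }
  out
}

#' @rdname code_levels
#' @export
decode_levels <- function(data, factors = chitosan_factors()) {
  missing <- setdiff(factors$factor, names(data))
  if (length(missing) > 0) {
    abort(paste0("Missing coded column(s): ", paste(missing, collapse = ", ")))
  }
  out <- tibble::as_tibble(data)
  for (i in seq_len(nrow(factors))) {
    out[[factors$column[i]]] <-
      factors$center[i] + factors$step[i] * out[[factors$factor[i]]]
  }
  out
}
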