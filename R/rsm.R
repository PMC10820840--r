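#' Second-order model terms in coded factors
#'
#' Terms of the full quadratic response-surface polynomial
#' `y = b0 + sum bi xi + sum bij xi xj + sum bii xi^2` are written as
#' labels: `"1"` (intercept), `"x1"` (linear), `"x1:x3"` (two-factor
#' interaction) and `"x1^2"` (pure quadratic). `quadratic_terms(k)` lists
#' the full set in canonical order; `term_exponents()` parses labels into
#' the exponent matrix used to build design matrices.
#'
#' @param k Number of coded factors.
#' @return `quadratic_terms()`: character vector of term labels.
#' @examples
#' quadratic_terms(3)
#' @export
quadratic_terms <- function(k) {
  stopifnot(k >= 1)
  xs <- paste0("x", seq_len(k))
  inter <- character(0)
  if (k >= 2) {
    cmb <- utils::combn(seq_len(k), 2)
    inter <- paste0("x", cmb[1, ], ":x", cmb[2, ])
  }
  c("1", xs, inter, paste0(xs, "^2"))
}

#' @rdname quadratic_terms
#' @param terms Character vector of term labels.
#' @return `term_exponents()`: integer matrix, one row per term and one
#'   column per factor, holding the exponent of each coded variable.
#' @export
term_exponents <- function(terms, k) {
  if (anyDuplicated(terms)) abort("Duplicate model terms are not allowed.")
  expo <- matrix(0L, nrow = length(terms), ncol = k,
                 dimnames = list(terms, paste0("x", seq_len(k))))
  for (i in seq_along(terms)) {
    t <- terms[i]
    if (t == "1") next
    for (part in strsplit(t, ":", fixed = TRUE)[[1]]) {
      m <- regmatches(part, regexec("^x([0-9]+)(\\^([0-9]+))?$", part))[[1]]
      if (length(m) == 0) abort(paste0("Cannot parse term `", t, "`."))
      j <- as.integer(m[2])
      p <- if (m[4] == "") 1L else as.integer(m[4])
      if (j < 1 || j > k) abort(paste0("Term `", t, "` references factor x", j,
                                       " but k = ", k, "."))
      expo[i, j] <- expo[i, j] + p
    }
  }
  if (any(rowSums(expo) > 2)) abort("Terms of total degree > 2 are not supported.")
  expo
}

#' Design matrix of a quadratic model on coded runs
#'
#' Evaluates each term on each run of a coded experiment table: entry
#' (i, j) is the product of run i's coded values raised to term j's
#' exponents, with the intercept column identically one.
#'
#' @param data Data frame with coded columns `x1`, ..., `xk`.
#' @param terms Character vector of term labels (see [quadratic_terms()]).
#' @return Numeric matrix, one column per term.
#' @examples
#' design_matrix(ccd_design(chitosan_factors()), quadratic_terms(3))
#' @export
design_matrix <- function(data, terms) {
  xs <- grep("^x[0-9]+$", names(data), value = TRUE)
  k <- length(xs)
  if (k == 0) abort("No coded columns (x1, x2, ...) found in `data`.")
  expo <- term_exponents(terms, k)
  X <- matrix(1, nrow = nrow(data), ncol = length(terms),
              dimnames = list(NULL, terms))
  for (j in seq_along(terms)) {
    for (f in seq_len(k)) {
      if (expo[j, f] > 0) X[, j] <- X[, j] * data[[paste0("x", f)]]^expo[j, f]
    }
  }
  X
}

#' Fit a second-order response-surface model by ordinary least squares
#'
#' Regresses a measured response on quadratic terms in the coded factors.
#' Coefficient standard errors, two-sided t-test p-values (residual
#' degrees of freedom), the coefficient of determination and the overall
#' regression F-test (regression vs. residual mean squares on
#' `n_terms - 1` and `n - n_terms` degrees of freedom) are all reported,
#' matching a standard ANOVA table for the model.
#'
#' @param data Experiment table with coded columns `x1..xk` and the
#'   response column.
#' @param response Name of the response column (string).
#' @param terms Term labels to fit; defaults to the full quadratic set.
#' @return An object of class `rsm_fit`. Use [tidy()] for the coefficient
#'   table, [glance()] for model-level statistics, [predict()] to evaluate
#'   the fitted polynomial, and [reduce_fit()] to refit a term subset.
#' @examples
#' tbl <- shrimp_ccd()
#' fit <- fit_response_surface(tbl, "dd_pct")
#' tidy(fit)
#' glance(fit)
#' @export
fit_response_surface <- function(data, response,
                                 terms = NULL) {
  if (!response %in% names(data)) {
    abort(paste0("Response column `", response, "` not found."))
  }
  xs <- grep("^x[0-9]+$", names(data), value = TRUE)
  k <- length(xs)
  terms <- terms %||% quadratic_terms(k)
  if (!length(terms)) abort("At least one model term is required.")
  y <- data[[response]]
  if (anyNA(y) || anyNA(as.matrix(data[xs]))) {
    abort("Missing values in the response or coded columns.")
  }
  X <- design_matrix(data, terms)
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) abort("More model terms than runs; the fit is underdetermined.")
  qrX <- qr(X)
  if (qrX$rank < p) {
    dropped <- terms[qrX$pivot[(qrX$rank + 1):p]]
    abort(paste0("Design matrix is rank deficient; collinear term(s): ",
                 paste(dropped, collapse = ", ")))
  }

  lmfit <- lm(y ~ X - 1)
  beta <- setNames(coef(lmfit), terms)
  res <- stats::residuals(lmfit)
  df_res <- n - p
  sse <- sum(res^2)
  sigma2 <- sse / df_res
  XtX_inv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * diag(XtX_inv))
  tval <- beta / se
  pval <- 2 * pt(abs(tval), df_res, lower.tail = FALSE)

  sst <- sum((y - mean(y))^2)
  ssm <- sst - sse
  r2 <- 1 - sse / sst
  f <- if (p > 1) (ssm / (p - 1)) / sigma2 else NA_real_
  f_p <- if (p > 1) pf(f, p - 1, df_res, lower.tail = FALSE) else NA_real_

  structure(
    list(
      terms = terms,
      coefficients = beta,
      coef_table = tibble::tibble(
        term = terms, estimate = unname(beta), std.error = unname(se),
        statistic = unname(tval), p.value = unname(pval)
      ),
      response = response,
      k = k,
      data = tibble::as_tibble(data),
      fitted = unname(stats::fitted(lmfit)),
      residuals = unname(res),
      sigma = sqrt(sigma2),
      df.residual = df_res,
      r.squared = r2,
      adj.r.squared = 1 - (1 - r2) * (n - 1) / df_res,
      fstatistic = c(value = unname(f), df1 = p - 1, df2 = df_res),
      f.p.value = f_p,
      nobs = n
    ),
    class = "rsm_fit"
  )
}

#' Refit a response-surface model on a subset of its terms
#'
#' Drops the terms not listed in `keep` and refits by OLS on the same
#' data. On an orthogonal central composite design, dropping only linear
#' or interaction terms leaves the retained coefficient estimates
#' unchanged; dropping pure quadratics shifts the intercept and the other
#' quadratic coefficients.
#'
#' @param fit An `rsm_fit`.
#' @param keep Character vector of term labels to retain; must be a subset
#'   of the fitted terms and include the intercept `"1"`.
#' @return A fresh `rsm_fit` on the reduced term set.
#' @examples
#' fit <- fit_response_surface(shrimp_ccd(), "dd_pct")
#' reduce_fit(fit, dd_reduced_terms())
#' @export
reduce_fit <- function(fit, keep) {
  stopifnot(inherits(fit, "rsm_fit"))
  if (!length(keep)) abort("`keep` must not be empty.")
  extra <- setdiff(keep, fit$terms)
  if (length(extra)) {
    abort(paste0("`keep` contains term(s) not in the fit: ",
                 paste(extra, collapse = ", ")))
  }
  if (!"1" %in% keep) abort("`keep` must include the intercept term \"1\".")
  fit_response_surface(fit$data, fit$response,
                       terms = fit$terms[fit$terms %in% keep])
}

#' Advisory term selection by p-value
#'
#' Returns the terms whose coefficient p-value is at or below `threshold`,
#' always keeping the intercept and any explicitly protected terms. This
#' mirrors how a practitioner screens an ANOVA table, but term reduction
#' for a final model should be a deliberate choice — use the returned list
#' with [reduce_fit()] after inspection. In the shrimp-waste DD model the
#' liquid:solid-ratio linear term is protected despite its weak
#' significance, so that the factor keeps some influence on predictions.
#'
#' @param fit An `rsm_fit`.
#' @param threshold p-value cutoff in `[0, 1]`.
#' @param protect Term labels kept regardless of p-value.
#' @return Character vector of term labels (in the fit's order).
#' @export
prune_terms <- function(fit, threshold, protect = character()) {
  stopifnot(inherits(fit, "rsm_fit"))
  keep <- fit$coef_table$term[fit$coef_table$p.value <= threshold]
  unique_terms <- union(union("1", keep), protect)
  fit$terms[fit$terms %in% unique_terms]
}

#' Term keep-lists of the reduced shrimp-waste models
#'
#' The published reduced models for the packaged shrimp-waste experiment:
#' the deacetylation-degree model retains the three linear terms (the
#' liquid:solid ratio deliberately protected), the NaOH-by-duration
#' interaction and the NaOH and duration quadratics; the molar-mass model
#' retains the NaOH and duration linear terms, their interaction, and all
#' three quadratics.
#'
#' @return Character vector of term labels for use with [reduce_fit()].
#' @export
dd_reduced_terms <- function() c("1", "x1", "x2", "x3", "x1:x3", "x1^2", "x3^2")

#' @rdname dd_reduced_terms
#' @export
mm_reduced_terms <- function() c("1", "x1", "x3", "x1:x3", "x1^2", "x2^2", "x3^2")

#' Lack-of-fit decomposition against replicate pure error
#'
#' Splits the residual sum of squares of a fitted response-surface model
#' into pure error (from replicated design points) and lack of fit, with
#' the usual F-test. Provided as a diagnostic; it needs at least one
#' replicated coded point.
#'
#' @param fit An `rsm_fit`.
#' @return A one-row tibble with sums of squares, degrees of freedom, the
#'   lack-of-fit F statistic and its p-value.
#' @export
lack_of_fit <- function(fit) {
  stopifnot(inherits(fit, "rsm_fit"))
  xs <- paste0("x", seq_len(fit$k))
  key <- do.call(paste, c(fit$data[xs], sep = "\r"))
  y <- fit$data[[fit$response]]
  grp <- split(y, key)
  reps <- grp[lengths(grp) > 1]
  if (!length(reps)) abort("No replicated design points; pure error is not estimable.")
  ss_pe <- sum(vapply(reps, function(v) sum((v - mean(v))^2), numeric(1)))
  df_pe <- sum(vapply(reps, length, integer(1))) - length(reps)
  sse <- sum(fit$residuals^2)
  ss_lof <- sse - ss_pe
  df_lof <- fit$df.residual - df_pe
  fstat <- (ss_lof / df_lof) / (ss_pe / df_pe)
  tibble::tibble(
    ss_lack_of_fit = ss_lof, df_lack_of_fit = df_lof,
    ss_pure_error = ss_pe, df_pure_error = df_pe,
    statistic = fstat,
    p.value = pf(fstat, df_lof, df_pe, lower.tail = FALSE)
  )
}

#' @export
print.rsm_fit <- function(x, ...) {
  cat("Second-order response-surface fit\n")
  cat("  response:", x$response, " runs:", x$nobs, " terms:", length(x$terms), "\n")
  cat(sprintf("  R-squared %.4f (adj %.4f), F(%d, %d) = %.3f, p = %.4g\n",
              x$r.squared, x$adj.r.squared, x$fstatistic["df1"],
              x$fstatistic["df2"], x$fstatistic["value"], x$f.p.value))
  print(x$coef_table)
  invisible(x)
}

#' @rdname fit_response_surface
#' @param x,object An `rsm_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.rsm_fit <- function(x, ...) x$coef_table

#' @rdname fit_response_surface
#' @exportS3Method generics::glance
glance.rsm_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r.squared, adj.r.squared = x$adj.r.squared,
    sigma = x$sigma, statistic = unname(x$fstatistic["value"]),
    p.value = x$f.p.value, df = unname(x$fstatistic["df1"]),
    df.residual = x$df.residual, nobs = x$nobs
  )
}

#' @rdname fit_response_surface
#' @param newdata Data frame with coded columns `x1..xk` at which to
#'   evaluate the fitted polynomial.
#' @export
predict.rsm_fit <- function(object, newdata = NULL, ...) {
  predict(as_quadratic_model(object), newdata = newdata %||% object$data)
}

#' Contour slice of a fitted response surface
#'
#' Draws the predicted response over two coded factors with the remaining
#' factors held at the design center (coded 0), the usual flat view of a
#' quadratic response surface.
#'
#' @param object An `rsm_fit`.
#' @param vary Two coded factor names to vary, e.g. `c("x1", "x3")`.
#' @param lower,upper Coded range of the slice.
#' @param resolution Grid points per axis.
#' @param ... Unused.
#' @return A ggplot contour plot.
#' @exportS3Method ggplot2::autoplot
autoplot.rsm_fit <- function(object, vary = c("x1", "x2"),
                             lower = -1.68, upper = 1.68,
                             resolution = 101, ...) {
  stopifnot(length(vary) == 2)
  xs <- paste0("x", seq_len(object$k))
  if (!all(vary %in% xs)) abort("`vary` must name coded factors of the fit.")
  grid <- tidyr::expand_grid(
    !!vary[1] := seq(lower, upper, length.out = resolution),
    !!vary[2] := seq(lower, upper, length.out = resolution)
  )
  for (f in setdiff(xs, vary)) grid[[f]] <- 0
  grid$.pred <- predict(object, grid)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data[[vary[1]]], y = .data[[vary[2]]],
                                     z = .data$.pred)) +
    ggplot2::geom_contour_filled() +
    ggplot2::labs(title = paste("Predicted", object$response),
                  fill = object$response) +
    ggplot2::theme_minimal()
}
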