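#' Standalone quadratic polynomial in coded factors
#'
#' A `quadratic_model` is a named coefficient vector over second-order
#' term labels (see [quadratic_terms()]) that can be evaluated, optimized
#' and serialized independently of the data it was fitted to.
#' `as_quadratic_model()` extracts one from an [fit_response_surface()]
#' fit; `dd_reduced_model()` and `mm_reduced_model()` return the published
#' reduced models for the shrimp-waste experiment (deacetylation degree in
#' %, molar mass in kDa).
#'
#' @param coefficients Named numeric vector; names are term labels.
#' @param k Number of coded factors; inferred from the labels if omitted.
#' @param response Optional response label (e.g. `"dd_pct"`).
#' @param units Optional units string.
#' @return An object of class `quadratic_model`.
#' @examples
#' m <- quadratic_model(c("1" = 2, "x1" = 3))
#' predict(m, data.frame(x1 = c(0, 1)))
#' @export
quadratic_model <- function(coefficients, k = NULL, response = NULL, units = NULL) {
  if (is.null(names(coefficients)) || any(names(coefficients) == "")) {
    abort("`coefficients` must be named by term labels.")
  }
  terms <- names(coefficients)
  if (is.null(k)) {
    idx <- unlist(regmatches(terms, gregexpr("(?<=x)[0-9]+", terms, perl = TRUE)))
    k <- if (length(idx)) max(as.integer(idx)) else 1L
  }
  term_exponents(terms, k) # validates labels, duplicates, degree
  structure(as.numeric(coefficients),
            names = terms, k = k, response = response, units = units,
            class = "quadratic_model")
}

#' @rdname quadratic_model
#' @param fit An `rsm_fit`.
#' @export
as_quadratic_model <- function(fit) {
  stopifnot(inherits(fit, "rsm_fit"))
  quadratic_model(fit$coefficients, k = fit$k, response = fit$response)
}

#' @rdname quadratic_model
#' @export
dd_reduced_model <- function() {
  reduce_fit(fit_response_surface(shrimp_ccd(), "dd_pct"), dd_reduced_terms()) |>
    as_quadratic_model()
}

#' @rdname quadratic_model
#' @export
mm_reduced_model <- function() {
  reduce_fit(fit_response_surface(shrimp_ccd(), "mm_kda"), mm_reduced_terms()) |>
    as_quadratic_model()
}

#' @export
print.quadratic_model <- function(x, ...) {
  cat("Quadratic model in", attr(x, "k"), "coded factor(s)")
  if (!is.null(attr(x, "response"))) cat(" for", attr(x, "response"))
  cat("\n")
  print(setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' @rdname quadratic_model
#' @param object A `quadratic_model`.
#' @param newdata Data frame with coded columns `x1..xk`, or a numeric
#'   vector (one point) or matrix (points in rows).
#' @param ... Unused.
#' @export
predict.quadratic_model <- function(object, newdata, ...) {
  k <- attr(object, "k")
  if (is.numeric(newdata) && is.null(dim(newdata))) {
    if (length(newdata) != k) abort(paste0("Point must have length ", k, "."))
    newdata <- matrix(newdata, nrow = 1)
  }
  if (is.matrix(newdata)) {
    if (ncol(newdata) != k) abort(paste0("Points must have ", k, " columns."))
    colnames(newdata) <- paste0("x", seq_len(k))
    newdata <- tibble::as_tibble(newdata)
  }
  missing <- setdiff(paste0("x", seq_len(k)), names(newdata))
  if (length(missing)) {
    abort(paste0("Missing coded column(s): ", paste(missing, collapse = ", ")))
  }
  X <- design_matrix(newdata, names(object))
  drop(X %*% as.numeric(object))
}

# Split f(x) = c0 + b'x + x' A x into (c0, b, A); A symmetric, with pure
# quadratic coefficients on the diagonal and half the interaction
# coefficients off-diagonal. Gradient is b + 2 A x.
quadratic_parts <- function(model) {
  k <- attr(model, "k")
  expo <- term_exponents(names(model), k)
  c0 <- 0
  b <- numeric(k)
  A <- matrix(0, k, k)
  for (i in seq_along(model)) {
    e <- expo[i, ]
    deg <- sum(e)
    coefi <- as.numeric(model[i])
    if (deg == 0) c0 <- c0 + coefi
    else if (deg == 1) b[which(e == 1)] <- b[which(e == 1)] + coefi
    else if (any(e == 2)) {
      j <- which(e == 2)
      A[j, j] <- A[j, j] + coefi
    } else {
      ij <- which(e == 1)
      A[ij[1], ij[2]] <- A[ij[1], ij[2]] + coefi / 2
      A[ij[2], ij[1]] <- A[ij[2], ij[1]] + coefi / 2
    }
  }
  list(c0 = c0, b = b, A = A)
}

#' Maximize a quadratic model over a coded box
#'
#' Solves the stationarity system of the quadratic analytically
#' (`grad f = b + 2 A x = 0`). If the Hessian `2A` is negative definite
#' and the stationary point lies inside the box, that interior maximum is
#' returned exactly. Otherwise (saddle, convex directions, or exterior
#' stationary point) the box is searched on a lattice and the best point
#' polished with box-constrained quasi-Newton iterations; a singular
#' Hessian triggers the same fallback with a warning.
#'
#' @param model A `quadratic_model`.
#' @param lower,upper Box bounds per coded coordinate (scalars are
#'   recycled). Defaults to the axial cube `[-1.68, 1.68]^k`.
#' @param resolution Lattice points per axis for the fallback search.
#' @return A list with `par` (named coded coordinates), `value`,
#'   `interior` (logical: analytic interior maximum) and `method`.
#' @examples
#' maximize_quadratic(mm_reduced_model())
#' @export
maximize_quadratic <- function(model, lower = -1.68, upper = 1.68,
                               resolution = 51) {
  stopifnot(inherits(model, "quadratic_model"))
  k <- attr(model, "k")
  lower <- rep_len(lower, k)
  upper <- rep_len(upper, k)
  if (any(lower >= upper)) abort("`lower` must be < `upper` per coordinate.")
  parts <- quadratic_parts(model)
  H <- 2 * parts$A
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values

  if (max(abs(ev)) > 0 && min(abs(ev)) / max(abs(ev)) > 1e-12) {
    xstar <- drop(solve(H, -parts$b))
    if (all(ev < 0) && all(xstar >= lower & xstar <= upper)) {
      return(list(
        par = setNames(xstar, paste0("x", seq_len(k))),
        value = unname(predict(model, xstar)),
        interior = TRUE, method = "stationary"
      ))
    }
  } else {
    warn("Singular Hessian; falling back to lattice search.")
  }

  grids <- purrr::map2(lower, upper, ~ seq(.x, .y, length.out = resolution))
  lattice <- as.matrix(do.call(expand.grid, grids))
  vals <- predict(model, lattice)
  x0 <- lattice[which.max(vals), ]
  opt <- stats::optim(x0, function(x) -predict(model, x),
                      method = "L-BFGS-B", lower = lower, upper = upper)
  list(
    par = setNames(unname(opt$par), paste0("x", seq_len(k))),
    value = -opt$value, interior = FALSE, method = "lattice+polish"
  )
}
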