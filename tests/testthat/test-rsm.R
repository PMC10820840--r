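full_terms <- c("1", "x1", "x2", "x3", "x1:x2", "x1:x3", "x2:x3",
                "x1^2", "x2^2", "x3^2")

test_that("design_matrix evaluates term products on coded runs", {
  tbl <- tibble::tibble(x1 = c(0, 1, 1.68), x2 = c(0, -1, 0), x3 = c(0, 1, 0))
  X <- design_matrix(tbl, full_terms)
  expect_equal(unname(X[1, ]), c(1, rep(0, 9))) # center run
  expect_equal(unname(X[2, "x1:x3"]), 1)
  expect_equal(unname(X[2, "x1:x2"]), -1)
  expect_equal(unname(X[3, "x1^2"]), 2.8224)
  expect_error(design_matrix(tbl, c("1", "x1", "x1")), "Duplicate")
  expect_error(design_matrix(tbl, c("1", "x1^3")), "degree")
  expect_error(design_matrix(tbl, c("1", "x9")), "x9")
})

test_that("a noiseless linear response is recovered exactly", {
  des <- ccd_design(chitosan_factors())
  des$y <- 2 + 3 * des$x1
  fit <- fit_response_surface(des, "y", terms = c("1", "x1"))
  expect_equal(unname(fit$coefficients), c(2, 3), tolerance = 1e-12)
  expect_equal(fit$r.squared, 1)
  expect_lt(max(fit$coef_table$std.error), 1e-10)
})

test_that("full quadratic fits reproduce the published ANOVA tables", {
  tbl <- shrimp_ccd()
  dd <- fit_response_surface(tbl, "dd_pct")
  mm <- fit_response_surface(tbl, "mm_kda")

  dd_ref <- c(90.3432, 16.0728, -2.0665, 5.6821, 1.1188, -3.3688, 2.1313,
              -10.6993, 0.4207, -3.4749)
  dd_se_ref <- c(4.9765, rep(2.3384, 3), rep(3.0539, 3), rep(2.5761, 3))
  dd_p_ref <- c(3.81e-7, 0.0002, 0.4062, 0.0454, 0.7249, 0.3065, 0.5078,
                0.0043, 0.8749, 0.2194)
  mm_ref <- c(761.5591, 229.7859, 19.9224, 41.4797, 37.7305, 78.3116, 3.4153,
              -146.0860, -103.1420, -202.8130)
  mm_se_ref <- c(61.7843, rep(29.0314, 3), rep(37.9146, 3), rep(31.9832, 3))

  expect_equal(dd$terms, full_terms)
  expect_equal(unname(dd$coefficients), dd_ref, tolerance = 0.005)
  expect_equal(dd$coef_table$std.error, dd_se_ref, tolerance = 0.005)
  expect_equal(dd$coef_table$p.value, dd_p_ref, tolerance = 0.02)
  expect_equal(unname(mm$coefficients), mm_ref, tolerance = 0.005)
  expect_equal(mm$coef_table$std.error, mm_se_ref, tolerance = 0.005)

  expect_equal(dd$r.squared, 0.91, tolerance = 0.01)
  expect_equal(mm$r.squared, 0.94, tolerance = 0.01)
  expect_equal(dd$f.p.value, 0.0052, tolerance = 0.02)
  expect_equal(mm$f.p.value, 0.0012, tolerance = 0.02)
  expect_equal(dd$df.residual, 7)
  expect_equal(unname(dd$fstatistic["df1"]), 9)
})

test_that("OLS matches the normal-equations oracle", {
  tbl <- shrimp_ccd()
  for (resp in c("dd_pct", "mm_kda")) {
    fit <- fit_response_surface(tbl, resp)
    X <- design_matrix(tbl, fit$terms)
    beta_ne <- drop(solve(crossprod(X), crossprod(X, tbl[[resp]])))
    expect_equal(unname(fit$coefficients), unname(beta_ne), tolerance = 1e-8)
    # residuals orthogonal to every design-matrix column
    expect_lt(max(abs(crossprod(X, fit$residuals))), 1e-8)
  }
})

test_that("reduction refits reproduce the published reduced models", {
  tbl <- shrimp_ccd()
  dd_red <- reduce_fit(fit_response_surface(tbl, "dd_pct"), dd_reduced_terms())
  eq_dd <- c("1" = 90.897, x1 = 16.072, x2 = -2.066, x3 = 5.682,
             "x1:x3" = -3.369, "x1^2" = -10.823, "x3^2" = -3.599)
  expect_equal(dd_red$coefficients[names(eq_dd)], eq_dd, tolerance = 0.005)
  expect_equal(dd_red$r.squared, 0.907, tolerance = 0.005)

  mm_full <- fit_response_surface(tbl, "mm_kda")
  mm_red <- reduce_fit(mm_full, mm_reduced_terms())
  eq_mm <- c("1" = 761.559, x1 = 229.786, x3 = 41.480, "x1:x3" = 78.312,
             "x1^2" = -146.086, "x2^2" = -103.142, "x3^2" = -202.813)
  expect_equal(mm_red$coefficients[names(eq_mm)], eq_mm, tolerance = 0.005)
  # dropped MM terms are all orthogonal to the retained ones, so the
  # retained estimates equal the full-fit values
  expect_equal(mm_red$coefficients, mm_full$coefficients[mm_reduced_terms()],
               tolerance = 1e-6)
})

test_that("no-op reduction returns an identical fit and R2 is monotone in terms", {
  tbl <- shrimp_ccd()
  fit <- fit_response_surface(tbl, "dd_pct")
  same <- reduce_fit(fit, fit$terms)
  expect_equal(same$coefficients, fit$coefficients)
  expect_equal(same$r.squared, fit$r.squared)

  withr::with_seed(5, {
    for (r in 1:10) {
      keep <- union("1", sample(setdiff(full_terms, "1"),
                                sample(3:8, 1)))
      red <- reduce_fit(fit, keep)
      expect_lte(red$r.squared, fit$r.squared + 1e-12)
    }
  })
  expect_error(reduce_fit(fit, character(0)), "empty")
  expect_error(reduce_fit(fit, c("x1", "x2")), "intercept")
  expect_error(reduce_fit(fit, c("1", "x4")), "x4")
})

test_that("dropping orthogonal terms leaves retained coefficients unchanged on synthetic fits", {
  withr::with_seed(21, {
    for (r in 1:5) {
      tbl <- simulate_responses(
        models = list(y = mm_reduced_model()),
        sd = c(y = 50)
      )
      full <- fit_response_surface(tbl, "y")
      # drop only linear/interaction terms: orthogonal to everything kept
      red <- reduce_fit(full, setdiff(full_terms, c("x2", "x1:x2", "x2:x3")))
      expect_equal(red$coefficients, full$coefficients[red$terms],
                   tolerance = 1e-10)
    }
  })
})

test_that("p-value screening keeps intercept and protected terms", {
  fit <- fit_response_surface(shrimp_ccd(), "dd_pct")
  expect_equal(sort(prune_terms(fit, 0.05, protect = "x2")),
               sort(c("1", "x1", "x2", "x3", "x1^2")))
  expect_equal(prune_terms(fit, 1.0), full_terms)
  expect_equal(prune_terms(fit, 0, protect = "x2"), c("1", "x2"))
})

test_that("model evaluation matches direct polynomial arithmetic", {
  m <- dd_reduced_model()
  expect_equal(unname(predict(m, c(0, 0, 0))), unname(m["1"]))
  x <- c(0.5, -0.5, 1)
  by_hand <- m["1"] + m["x1"] * x[1] + m["x2"] * x[2] + m["x3"] * x[3] +
    m["x1:x3"] * x[1] * x[3] + m["x1^2"] * x[1]^2 + m["x3^2"] * x[3]^2
  expect_equal(unname(predict(m, x)), unname(by_hand))
  expect_error(predict(m, c(1, 2)), "length 3")
})

test_that("rank-deficient designs are rejected with the collinear term named", {
  tbl <- tibble::tibble(x1 = c(-1, 1, -1, 1, 0), x2 = c(-1, 1, -1, 1, 0),
                        y = rnorm(5))
  expect_error(fit_response_surface(tbl, "y", terms = c("1", "x1", "x2")),
               "collinear")
})

test_that("tidy/glance expose the coefficient and model summaries", {
  fit <- fit_response_surface(shrimp_ccd(), "mm_kda")
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(nrow(td), 10)
  gl <- glance(fit)
  expect_equal(gl$nobs, 17)
  expect_equal(gl$df.residual, 7)
  expect_true(all(td$p.value >= 0 & td$p.value <= 1))
})

test_that("lack-of-fit decomposition uses the replicated center runs", {
  fit <- fit_response_surface(shrimp_ccd(), "dd_pct")
  lof <- lack_of_fit(fit)
  expect_equal(lof$df_pure_error, 2) # three center replicates
  expect_equal(lof$df_lack_of_fit + lof$df_pure_error, fit$df.residual)
  expect_equal(lof$ss_lack_of_fit + lof$ss_pure_error, sum(fit$residuals^2))
})
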