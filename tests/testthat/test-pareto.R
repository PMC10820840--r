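test_that("pairwise dominance respects senses and strictness", {
  expect_true(dominates(c(2, 3), c(1, 3), c("max", "max")))
  expect_false(dominates(c(2, 3), c(2, 3), c("max", "max")))
  expect_false(dominates(c(1, 3), c(2, 3), c("max", "max")))
  expect_true(dominates(c(97, 120), c(96, 200), c("max", "min")))
  expect_false(dominates(c(97, 250), c(96, 200), c("max", "min")))
  expect_error(dominates(c(1, 2), c(1, 2, 3), c("max", "max")), "equal length")
})

test_that("the nondominated filter matches hand-worked sets and keeps ties", {
  pts <- tibble::tibble(f1 = c(1, 2, 0), f2 = c(1, 2, 3))
  front <- pareto_filter(pts, c("max", "max"))
  expect_equal(dplyr::arrange(as.data.frame(front), f1),
               data.frame(f1 = c(0, 2), f2 = c(3, 2)), ignore_attr = TRUE)

  same <- tibble::tibble(f1 = rep(1, 4), f2 = rep(2, 4))
  expect_equal(nrow(pareto_filter(same, c("max", "max"))), 4)
})

test_that("the sweep filter agrees with the O(n^2) dominance oracle", {
  withr::with_seed(13, {
    configs <- list(
      list(n = 400, m = 2, senses = c("max", "max"), round = FALSE),
      list(n = 400, m = 2, senses = c("max", "min"), round = FALSE),
      list(n = 300, m = 2, senses = c("min", "min"), round = TRUE), # many ties
      list(n = 150, m = 3, senses = c("max", "min", "max"), round = FALSE)
    )
    for (cf in configs) {
      M <- matrix(runif(cf$n * cf$m), ncol = cf$m)
      if (cf$round) M <- round(M, 1)
      pts <- tibble::as_tibble(as.data.frame(M))
      mask_oracle <- oracle_nondominated(M, cf$senses)
      front <- pareto_filter(pts, cf$senses)
      srt <- function(d) dplyr::arrange(as.data.frame(d), !!!rlang::syms(names(pts)))
      expect_equal(srt(front), srt(pts[mask_oracle, ]), ignore_attr = TRUE)
      # order independence
      perm <- sample(cf$n)
      front_perm <- pareto_filter(pts[perm, ], cf$senses)
      expect_equal(srt(front_perm), srt(front), ignore_attr = TRUE)
    }
  })
})

test_that("grid oracle handles degenerate objective combinations", {
  m <- quadratic_model(c("x1^2" = -1, "x2^2" = -1), response = "f")
  # single objective: the lattice argmax alone
  g1 <- grid_front(list(m), senses = "max", resolution = 21)
  expect_equal(nrow(g1), 1)
  expect_equal(c(g1$x1, g1$x2), c(0, 0))
  # two identical objectives, same sense: still the single common argmax
  m2 <- quadratic_model(c("x1^2" = -1, "x2^2" = -1), response = "g")
  g2 <- grid_front(list(m, m2), senses = c("max", "max"), resolution = 21)
  expect_equal(nrow(g2), 1)
  expect_error(grid_front(list(m), "max", resolution = 1e5), "max_points")
})

test_that("doubling grid resolution does not lose dominance coverage", {
  models <- list(dd_reduced_model(), mm_reduced_model())
  coarse <- grid_front(models, c("max", "max"), resolution = 26)
  fine <- grid_front(models, c("max", "max"), resolution = 51)
  # every coarse front point lies within tolerance of the fine front:
  # nothing on the fine front beats it by more than one coarse cell's
  # worth of objective change
  for (i in seq_len(nrow(coarse))) {
    expect_false(dominated_beyond_tol(
      fine[c("dd_pct", "mm_kda")], c("max", "max"),
      c(coarse$dd_pct[i], coarse$mm_kda[i]), tol = c(0.5, 10)
    ))
  }
})

test_that("analytic maximization solves the stationarity system", {
  opt <- maximize_quadratic(mm_reduced_model())
  expect_true(opt$interior)
  expect_equal(unname(opt$par), c(0.8583, 0, 0.268), tolerance = 1e-3)
  expect_equal(opt$value, 865, tolerance = 1e-3)

  bowl <- quadratic_model(c("x1^2" = -1, "x2^2" = -1, "x3^2" = -1))
  opt2 <- maximize_quadratic(bowl)
  expect_equal(unname(opt2$par), c(0, 0, 0))
  expect_equal(opt2$value, 0)

  convex <- quadratic_model(c("x1^2" = 1))
  opt3 <- maximize_quadratic(convex)
  expect_false(opt3$interior)
  expect_equal(abs(unname(opt3$par)), 1.68, tolerance = 1e-6)

  linear <- quadratic_model(c("1" = 1, "x1" = 2))
  expect_warning(opt4 <- maximize_quadratic(linear), "Singular")
  expect_equal(unname(opt4$par), 1.68, tolerance = 1e-6)
})

test_that("NSGA-II collapses a degenerate problem to its known optimum", {
  sphere <- quadratic_model(c("x1^2" = -1, "x2^2" = -1, "x3^2" = -1))
  front <- nsga2(list(sphere, sphere), c("max", "max"), seed = 1)
  best <- max(front$f1)
  expect_lt(sqrt(-best), 1e-2) # within 1e-2 of the origin
})

test_that("NSGA-II is reproducible under a seed and leaves the RNG state alone", {
  models <- list(dd_reduced_model(), mm_reduced_model())
  ctrl <- nsga2_control(pop_size = 40, generations = 30)
  before <- withr::with_seed(99, runif(1))
  set.seed(99)
  f1 <- nsga2(models, c("max", "max"), control = ctrl, seed = 5)
  expect_equal(runif(1), before) # seed 99 stream undisturbed
  f2 <- nsga2(models, c("max", "max"), control = ctrl, seed = 5)
  f3 <- nsga2(models, c("max", "max"), control = ctrl, seed = 6)
  expect_equal(tibble::as_tibble(f1), tibble::as_tibble(f2))
  expect_false(isTRUE(all.equal(tibble::as_tibble(f1), tibble::as_tibble(f3))))
})

test_that("every front type is mutually nondominated", {
  models <- list(dd_reduced_model(), mm_reduced_model())
  fronts <- list(
    nsga2(models, c("max", "min"), seed = 2,
          control = nsga2_control(pop_size = 40, generations = 40)),
    grid_front(models, c("max", "min"), resolution = 31),
    pareto_filter(tibble::tibble(f1 = runif(50), f2 = runif(50)),
                  c("max", "min"))
  )
  for (front in fronts) {
    M <- as.matrix(tibble::as_tibble(front)[attr(front, "objectives")])
    expect_true(all(oracle_nondominated(M, attr(front, "senses"))))
  }
})

test_that("GA fronts for the max/max problem track the grid oracle across seeds", {
  models <- list(dd_reduced_model(), mm_reduced_model())
  grid <- grid_front(models, c("max", "max"), resolution = 201)
  rd <- diff(range(grid$dd_pct))
  rm <- diff(range(grid$mm_kda))
  for (seed in 1:5) {
    ga <- nsga2(models, c("max", "max"), seed = seed)
    d <- vapply(seq_len(nrow(ga)), function(i) {
      min(sqrt(((ga$dd_pct[i] - grid$dd_pct) / rd)^2 +
                 ((ga$mm_kda[i] - grid$mm_kda) / rm)^2))
    }, numeric(1))
    expect_lt(max(d), 0.01) # within 1% of each objective's range
  }
})

test_that("front reports decode operating conditions and sort by the first objective", {
  models <- list(dd_reduced_model(), mm_reduced_model())
  front <- nsga2(models, c("max", "max"), seed = 3,
                 control = nsga2_control(pop_size = 20, generations = 20))
  rep <- front_report(front)
  expect_named(rep, c("x1", "x2", "x3", "naoh_pct", "ratio", "duration_min",
                      "dd_pct", "mm_kda"))
  expect_true(all(diff(rep$dd_pct) <= 0))
  expect_equal(rep$duration_min, 120 + 30 * rep$x3)
  expect_equal(rep$naoh_pct, 45 + 10 * rep$x1)
  empty <- pareto_filter(tibble::tibble(f1 = 1, f2 = 1), c("max", "max"))[0, ]
  expect_error(front_report(empty), "empty")
})
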