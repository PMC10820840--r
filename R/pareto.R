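#' Pareto dominance between objective vectors
#'
#' Under senses `"max"`/`"min"` per objective, `a` dominates `b` when `a`
#' is at least as good in every objective and strictly better in at least
#' one — any move from `a` to `b` worsens something for nothing.
#'
#' @param a,b Numeric objective vectors of equal length.
#' @param senses Character vector, `"max"` or `"min"` per objective.
#' @return Logical scalar.
#' @examples
#' dominates(c(2, 3), c(1, 3), c("max", "max")) # TRUE
#' dominates(c(97, 120), c(96, 200), c("max", "min")) # TRUE
#' @export
dominates <- function(a, b, senses) {
  if (length(a) != length(b) || length(a) != length(senses)) {
    abort("`a`, `b` and `senses` must have equal length.")
  }
  sgn <- ifelse(senses == "min", -1, 1)
  av <- sgn * a
  bv <- sgn * b
  all(av >= bv) && any(av > bv)
}

# Logical nondominance mask over a numeric objective matrix (rows =
# points). Two objectives use an O(n log n) sweep; higher dimensions fall
# back to pairwise checks.
nondominated_mask <- function(M, senses) {
  if (!is.matrix(M)) M <- as.matrix(M)
  if (nrow(M) == 0) abort("Point set must be nonempty.")
  if (ncol(M) != length(senses)) abort("One sense per objective is required.")
  sgn <- ifelse(senses == "min", -1, 1)
  M <- sweep(M, 2, sgn, `*`) # now maximize everything

  if (ncol(M) == 2) {
    n <- nrow(M)
    ord <- order(-M[, 1], -M[, 2])
    s1 <- M[ord, 1]
    s2 <- M[ord, 2]
    grp <- cumsum(c(TRUE, s1[-1] != s1[-n]))
    group_max <- s2[!duplicated(grp)] # s2 is descending within groups
    best_before <- c(-Inf, cummax(group_max))[grp]
    dominated_sorted <- best_before >= s2 | s2 < group_max[grp]
    mask <- logical(n)
    mask[ord] <- !dominated_sorted
    return(mask)
  }

  n <- nrow(M)
  mask <- rep(TRUE, n)
  for (i in seq_len(n)) {
    ge <- sweep(M, 2, M[i, ], `>=`)
    gt <- sweep(M, 2, M[i, ], `>`)
    if (any(rowSums(ge) == ncol(M) & rowSums(gt) > 0)) mask[i] <- FALSE
  }
  mask
}

#' Filter a point set to its nondominated (Pareto) subset
#'
#' @param points Data frame (or matrix) of candidate solutions.
#' @param senses `"max"`/`"min"` per objective.
#' @param objectives Names of the objective columns; defaults to the last
#'   `length(senses)` columns.
#' @return The nondominated rows, as a `pareto_front` tibble carrying
#'   `senses` and `objectives` attributes. The result is independent of
#'   row order.
#' @examples
#' pts <- tibble::tibble(f1 = c(1, 2, 0), f2 = c(1, 2, 3))
#' pareto_filter(pts, c("max", "max"))
#' @export
pareto_filter <- function(points, senses, objectives = NULL) {
  points <- tibble::as_tibble(points)
  objectives <- objectives %||% utils::tail(names(points), length(senses))
  M <- as.matrix(points[objectives])
  new_pareto_front(points[nondominated_mask(M, senses), ],
                   senses, objectives, method = "filter")
}

new_pareto_front <- function(solutions, senses, objectives, method) {
  structure(tibble::as_tibble(solutions),
            senses = senses, objectives = objectives, method = method,
            class = c("pareto_front", class(tibble::tibble())))
}

#' Deterministic grid Pareto oracle over the coded box
#'
#' Evaluates every objective model on a full lattice over the box and
#' keeps the nondominated lattice points. Brute force but exact to lattice
#' resolution, which makes it the reference against which the genetic
#' algorithm front is verified.
#'
#' @param models List of [quadratic_model()]s (one per objective).
#' @param senses `"max"`/`"min"` per objective.
#' @param lower,upper Box bounds per coded coordinate (recycled).
#' @param resolution Lattice points per axis (>= 2).
#' @param max_points Guard on the lattice size (`resolution^k`).
#' @return A `pareto_front` tibble with coded coordinates and one column
#'   per objective (named after the model responses, or `f1`, `f2`, ...).
#' @examples
#' grid_front(list(dd_reduced_model(), mm_reduced_model()),
#'            senses = c("max", "max"), resolution = 21)
#' @export
grid_front <- function(models, senses, lower = -1.68, upper = 1.68,
                       resolution = 201, max_points = 2e7) {
  stopifnot(length(models) == length(senses), resolution >= 2)
  k <- attr(models[[1]], "k")
  lower <- rep_len(lower, k)
  upper <- rep_len(upper, k)
  if (resolution^k > max_points) {
    abort(paste0("Lattice of ", resolution, "^", k,
                 " points exceeds `max_points`; lower the resolution."))
  }
  grids <- purrr::map2(lower, upper, ~ seq(.x, .y, length.out = resolution))
  lattice <- do.call(expand.grid, setNames(grids, paste0("x", seq_len(k))))
  lattice <- tibble::as_tibble(lattice)
  obj_names <- objective_labels(models)
  for (j in seq_along(models)) {
    lattice[[obj_names[j]]] <- predict(models[[j]], lattice)
  }
  mask <- nondominated_mask(as.matrix(lattice[obj_names]), senses)
  new_pareto_front(lattice[mask, ], senses, obj_names, method = "grid")
}

objective_labels <- function(models) {
  labs <- purrr::map_chr(seq_along(models), function(j) {
    attr(models[[j]], "response") %||% paste0("f", j)
  })
  make.unique(labs)
}

# --- NSGA-II internals ----------------------------------------------------

# Ranks by fast nondominated sorting on a minimization objective matrix.
fast_nondominated_sort <- function(Fm) {
  n <- nrow(Fm)
  m <- ncol(Fm)
  le <- matrix(TRUE, n, n)
  lt <- matrix(FALSE, n, n)
  for (j in seq_len(m)) {
    cj <- Fm[, j]
    le <- le & outer(cj, cj, `<=`)
    lt <- lt | outer(cj, cj, `<`)
  }
  dom <- le & lt # dom[i, j]: i dominates j
  n_dominators <- colSums(dom)
  rank <- integer(n)
  current <- which(n_dominators == 0)
  r <- 1L
  while (length(current) > 0) {
    rank[current] <- r
    newly_freed <- integer(0)
    for (i in current) {
      freed <- which(dom[i, ])
      n_dominators[freed] <- n_dominators[freed] - 1L
      newly_freed <- c(newly_freed, freed[n_dominators[freed] == 0L])
    }
    current <- unique(newly_freed[rank[newly_freed] == 0L])
    r <- r + 1L
  }
  rank
}

# Crowding distance within one front (minimization matrix). Boundary
# solutions get +Inf so they are always retained.
crowding_distance <- function(Fm) {
  n <- nrow(Fm)
  if (n <= 2) return(rep(Inf, n))
  d <- numeric(n)
  for (j in seq_len(ncol(Fm))) {
    ord <- order(Fm[, j])
    rng <- Fm[ord[n], j] - Fm[ord[1], j]
    d[ord[c(1, n)]] <- Inf
    if (rng > 0) {
      d[ord[2:(n - 1)]] <- d[ord[2:(n - 1)]] +
        (Fm[ord[3:n], j] - Fm[ord[1:(n - 2)], j]) / rng
    }
  }
  d
}

# Bound-aware simulated-binary crossover (Deb & Agrawal); the spread
# factor is renormalized so children cannot leave [lower, upper], with a
# final clip guarding rounding.
sbx_crossover <- function(p1, p2, lower, upper, p_cross, eta) {
  if (stats::runif(1) > p_cross) return(rbind(p1, p2))
  c1 <- p1
  c2 <- p2
  swap <- stats::runif(length(p1)) <= 0.5
  for (j in which(swap)) {
    if (abs(p1[j] - p2[j]) < 1e-14) next
    y1 <- min(p1[j], p2[j])
    y2 <- max(p1[j], p2[j])
    u <- stats::runif(1)
    betaq <- function(beta) {
      alpha <- 2 - beta^-(eta + 1)
      if (u <= 1 / alpha) (u * alpha)^(1 / (eta + 1))
      else (1 / (2 - u * alpha))^(1 / (eta + 1))
    }
    b1 <- betaq(1 + 2 * (y1 - lower[j]) / (y2 - y1))
    b2 <- betaq(1 + 2 * (upper[j] - y2) / (y2 - y1))
    c1[j] <- 0.5 * ((y1 + y2) - b1 * (y2 - y1))
    c2[j] <- 0.5 * ((y1 + y2) + b2 * (y2 - y1))
  }
  rbind(pmin(pmax(c1, lower), upper), pmin(pmax(c2, lower), upper))
}

# Bound-aware polynomial mutation (Deb); the perturbation shrinks as a
# gene approaches its bound.
polynomial_mutation <- function(x, lower, upper, p_mut, eta) {
  mutate <- stats::runif(length(x)) <= p_mut
  for (j in which(mutate)) {
    rng <- upper[j] - lower[j]
    u <- stats::runif(1)
    if (u <= 0.5) {
      xy <- 1 - (x[j] - lower[j]) / rng
      deltaq <- (2 * u + (1 - 2 * u) * xy^(eta + 1))^(1 / (eta + 1)) - 1
    } else {
      xy <- 1 - (upper[j] - x[j]) / rng
      deltaq <- 1 - (2 * (1 - u) + 2 * (u - 0.5) * xy^(eta + 1))^(1 / (eta + 1))
    }
    x[j] <- x[j] + deltaq * rng
  }
  pmin(pmax(x, lower), upper)
}

#' NSGA-II settings
#'
#' @param pop_size Population size; even and >= 4. The shrimp-waste
#'   optimization runs use the study's population of 100.
#' @param generations Number of generations.
#' @param p_crossover Per-pair simulated-binary crossover probability.
#' @param eta_crossover SBX distribution index.
#' @param p_mutation Per-gene polynomial-mutation probability; default
#'   `1/k` filled in by [nsga2()] when `NULL`.
#' @param eta_mutation Polynomial-mutation distribution index.
#' @param archive Keep an external archive of every nondominated solution
#'   evaluated during the run and return its nondominated set (default);
#'   with `FALSE` the rank-0 set of the final population is returned,
#'   which on fronts with locally-optimal dominated branches can retain a
#'   few stragglers a finite population never cleans up.
#' @return A list of settings for [nsga2()].
#' @export
nsga2_control <- function(pop_size = 100, generations = 200,
                          p_crossover = 0.9, eta_crossover = 15,
                          p_mutation = NULL, eta_mutation = 20,
                          archive = TRUE) {
  if (pop_size < 4 || pop_size %% 2 != 0) {
    abort("`pop_size` must be even and >= 4.")
  }
  probs <- c(p_crossover, p_mutation)
  if (any(probs < 0 | probs > 1)) abort("Probabilities must lie in [0, 1].")
  list(pop_size = pop_size, generations = generations,
       p_crossover = p_crossover, eta_crossover = eta_crossover,
       p_mutation = p_mutation, eta_mutation = eta_mutation,
       archive = isTRUE(archive))
}

#' Multiobjective optimization with NSGA-II
#'
#' Elitist nondominated-sorting genetic algorithm over real-coded
#' decision vectors in a box: fast nondominated sorting, crowding-distance
#' diversity, binary tournament selection (rank, then crowding),
#' simulated-binary crossover and polynomial mutation with bound
#' clipping. Minimization objectives are handled by an internal sign flip;
#' results are always reported in natural units.
#'
#' @param models List of [quadratic_model()]s, one per objective.
#' @param senses `"max"`/`"min"` per objective.
#' @param lower,upper Box bounds per coded coordinate (recycled).
#' @param control Settings from [nsga2_control()].
#' @param seed Integer seed; runs are reproducible given the seed and do
#'   not disturb the caller's random-number state.
#' @return The rank-0 set of the final population as a `pareto_front`
#'   tibble (coded coordinates + objective columns).
#' @examples
#' \donttest{
#' nsga2(list(dd_reduced_model(), mm_reduced_model()),
#'       senses = c("max", "max"), seed = 1,
#'       control = nsga2_control(generations = 50))
#' }
#' @export
nsga2 <- function(models, senses, lower = -1.68, upper = 1.68,
                  control = nsga2_control(), seed = NULL) {
  stopifnot(length(models) == length(senses))
  k <- attr(models[[1]], "k")
  lower <- rep_len(lower, k)
  upper <- rep_len(upper, k)
  if (any(lower >= upper)) abort("`lower` must be < `upper` per coordinate.")
  control$p_mutation <- control$p_mutation %||% (1 / k)
  sgn <- ifelse(senses == "min", 1, -1) # natural -> minimization

  run <- function() {
    N <- control$pop_size
    pop <- sapply(seq_len(k), function(j) stats::runif(N, lower[j], upper[j]))
    pop <- matrix(pop, nrow = N)
    evaluate <- function(P) {
      Fm <- sapply(seq_along(models), function(j) predict(models[[j]], P))
      sweep(matrix(Fm, nrow = nrow(P)), 2, sgn, `*`)
    }
    Fm <- evaluate(pop)
    arch_x <- pop
    arch_f <- Fm
    rank <- fast_nondominated_sort(Fm)
    crowd <- unsplit(lapply(split(seq_len(N), rank),
                            function(ix) crowding_distance(Fm[ix, , drop = FALSE])),
                     rank)
    for (gen in seq_len(control$generations)) {
      # binary tournament on (rank, crowding)
      pick <- function() {
        ij <- sample.int(N, 2)
        better <- rank[ij[1]] < rank[ij[2]] ||
          (rank[ij[1]] == rank[ij[2]] && crowd[ij[1]] > crowd[ij[2]])
        if (better) ij[1] else ij[2]
      }
      offspring <- matrix(0, N, k)
      for (p in seq_len(N / 2)) {
        kids <- sbx_crossover(pop[pick(), ], pop[pick(), ], lower, upper,
                              control$p_crossover, control$eta_crossover)
        kids[1, ] <- polynomial_mutation(kids[1, ], lower, upper,
                                         control$p_mutation, control$eta_mutation)
        kids[2, ] <- polynomial_mutation(kids[2, ], lower, upper,
                                         control$p_mutation, control$eta_mutation)
        offspring[(2 * p - 1):(2 * p), ] <- kids
      }
      comb <- rbind(pop, offspring)
      Foff <- evaluate(offspring)
      Fc <- rbind(Fm, Foff)
      if (control$archive) {
        arch_x <- rbind(arch_x, offspring)
        arch_f <- rbind(arch_f, Foff)
        keep_a <- nondominated_mask(arch_f, rep("min", ncol(arch_f)))
        arch_x <- arch_x[keep_a, , drop = FALSE]
        arch_f <- arch_f[keep_a, , drop = FALSE]
      }
      r <- fast_nondominated_sort(Fc)
      keep <- integer(0)
      for (fr in sort(unique(r))) {
        ix <- which(r == fr)
        if (length(keep) + length(ix) <= N) {
          keep <- c(keep, ix)
        } else {
          cd <- crowding_distance(Fc[ix, , drop = FALSE])
          keep <- c(keep, ix[order(-cd)][seq_len(N - length(keep))])
          break
        }
      }
      pop <- comb[keep, , drop = FALSE]
      Fm <- Fc[keep, , drop = FALSE]
      rank <- fast_nondominated_sort(Fm)
      crowd <- unsplit(lapply(split(seq_len(N), rank),
                              function(ix) crowding_distance(Fm[ix, , drop = FALSE])),
                       rank)
    }
    if (control$archive) list(final = arch_x)
    else list(final = pop[rank == 1L, , drop = FALSE])
  }

  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  final <- res$final
  colnames(final) <- paste0("x", seq_len(k))
  out <- tibble::as_tibble(final)
  obj_names <- objective_labels(models)
  for (j in seq_along(models)) out[[obj_names[j]]] <- predict(models[[j]], out)
  # rank-0 of the population can still contain duplicates; drop them
  out <- dplyr::distinct(out)
  new_pareto_front(out, senses, obj_names, method = "nsga2")
}

#' Tabulate a Pareto front with decoded operating conditions
#'
#' Adds the real-valued operating conditions to a front's coded
#' coordinates and sorts by the first objective, giving the trade-off
#' table an experimenter reads to pick a compromise.
#'
#' @param front A `pareto_front`.
#' @param factors Factor tibble from [ccd_factors()].
#' @return A tibble: coded coordinates, decoded real values, objectives.
#' @export
front_report <- function(front, factors = chitosan_factors()) {
  if (nrow(front) == 0) abort("The Pareto front is empty.")
  obj <- attr(front, "objectives")
  out <- decode_levels(tibble::as_tibble(front), factors)
  out <- out[, c(factors$factor, factors$column, obj)]
  dplyr::arrange(out, dplyr::desc(.data[[obj[1]]]))
}

#' @export
print.pareto_front <- function(x, ...) {
  cat("Pareto front (", attr(x, "method"), "): ", nrow(x), " solutions, senses ",
      paste(attr(x, "senses"), collapse = "/"), "\n", sep = "")
  NextMethod()
}

#' Plot a two-objective Pareto front
#'
#' @param object A `pareto_front` with two objectives.
#' @param ... Unused.
#' @return A ggplot: objective 1 vs objective 2.
#' @exportS3Method ggplot2::autoplot
autoplot.pareto_front <- function(object, ...) {
  obj <- attr(object, "objectives")
  if (length(obj) != 2) abort("autoplot() supports two-objective fronts.")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data[[obj[1]]], y = .data[[obj[2]]])) +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::labs(
      title = paste0("Pareto front (", attr(object, "method"), ")"),
      subtitle = paste0("senses: ", paste(attr(object, "senses"), collapse = " / "))
    ) +
    ggplot2::theme_minimal()
}
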