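#' Default time grid for cumulative RT distributions
#'
#' Fixed grid on which cumulative RT distributions are represented and
#' compared: 0 to \code{t_max} seconds at \code{dt} spacing, matching the
#' simulation step.
#'
#' @param t_max end of the grid in seconds.
#' @param dt grid spacing in seconds.
#' @return numeric vector of time points.
#' @export
rt_cdf_grid <- function(t_max = 20, dt = 0.001) seq(0, t_max, by = dt)

#' Fit a gamma CDF to a reaction-time sample
#'
#' Computes the empirical cumulative distribution of the RTs on a fixed time
#' grid and fits a 2-parameter gamma distribution by minimizing the summed
#' squared deviation between the gamma CDF and the empirical CDF on that
#' grid (Nelder--Mead on log-parameters, started from moment estimates).
#'
#' @param rts numeric vector of at least 10 finite, positive reaction times
#'   in seconds.
#' @param grid time grid (see \code{\link{rt_cdf_grid}}).
#' @param fit_subsample during optimization the squared-deviation objective
#'   is evaluated on every \code{fit_subsample}-th grid point (default 10).
#'   The objective is a Riemann sum, so subsampling rescales it without
#'   moving its minimizer; the returned CDF is on the full grid.
#' @return object of class \code{rt_cdf}: list with \code{grid},
#'   \code{values} (fitted CDF on the grid), and \code{gamma_params}
#'   (named vector \code{shape}, \code{scale}).
#' @export
fit_gamma_cdf <- function(rts, grid = rt_cdf_grid(), fit_subsample = 10L) {
  rts <- rts[is.finite(rts)]
  if (length(rts) < 10L)
    stop("need at least 10 finite reaction times")
  if (any(rts <= 0)) stop("reaction times must be positive")
  if (sd(rts) == 0) stop("degenerate (constant) reaction-time sample")
  sub <- grid[seq(1L, length(grid), by = max(1L, as.integer(fit_subsample)))]
  emp <- ecdf(rts)(sub)
  m <- mean(rts); v <- var(rts)
  start <- log(c(shape = m^2 / v, scale = v / m))
  obj <- function(lp) {
    p <- exp(lp)
    sum((pgamma(sub, shape = p[1], scale = p[2]) - emp)^2)
  }
  opt <- optim(start, obj, method = "Nelder-Mead",
               control = list(maxit = 500, reltol = 1e-10))
  p <- exp(opt$par)
  structure(list(grid = grid,
                 values = pgamma(grid, shape = p[1], scale = p[2]),
                 gamma_params = c(shape = unname(p[1]),
                                  scale = unname(p[2]))),
            class = "rt_cdf")
}

#' Construct an rt_cdf from known gamma parameters
#'
#' @param shape,scale gamma parameters.
#' @param grid time grid.
#' @return object of class \code{rt_cdf}.
#' @export
gamma_rt_cdf <- function(shape, scale, grid = rt_cdf_grid()) {
  structure(list(grid = grid,
                 values = pgamma(grid, shape = shape, scale = scale),
                 gamma_params = c(shape = shape, scale = scale)),
            class = "rt_cdf")
}

#' Average several fitted RT CDFs pointwise
#'
#' Across-subject averaging of gamma-fitted cumulative distributions is
#' pointwise on the shared grid; for a single input this is the identity.
#'
#' @param cdfs list of \code{rt_cdf} objects on identical grids.
#' @return object of class \code{rt_cdf} (with \code{gamma_params = NULL},
#'   as an average of gamma CDFs is generally not a gamma CDF).
#' @export
average_rt_cdfs <- function(cdfs) {
  stopifnot(length(cdfs) >= 1L)
  g <- cdfs[[1L]]$grid
  for (cdf in cdfs)
    if (!isTRUE(all.equal(cdf$grid, g))) stop("mismatched CDF grids")
  vals <- rowMeans(vapply(cdfs, `[[`, numeric(length(g)), "values"))
  structure(list(grid = g, values = vals, gamma_params = NULL),
            class = "rt_cdf")
}

#' Overlap-based distance between two cumulative RT distributions
#'
#' The distributions are compared through the ratio of the intersection to
#' the union of the two CDF curves on their shared grid:
#' \deqn{err = 1 - \sum_t \min(A_t, B_t) / \sum_t \max(A_t, B_t).}
#' The result is symmetric, lies in [0, 1], is 0 for identical curves, and
#' tends to 1 as the supports separate.
#'
#' @param a,b \code{rt_cdf} objects on the same grid.
#' @return scalar error in [0, 1].
#' @export
rt_distribution_error <- function(a, b) {
  stopifnot(inherits(a, "rt_cdf"), inherits(b, "rt_cdf"))
  if (!isTRUE(all.equal(a$grid, b$grid))) stop("mismatched CDF grids")
  u <- sum(pmax(a$values, b$values))
  if (u == 0) return(0)
  1 - sum(pmin(a$values, b$values)) / u
}

build_condition <- function(I_cong, I_incong, k, c, theta = 0.3,
                            dt = 0.001, t_max = 20,
                            decision_type = "arbitrary",
                            difficulty = "easy") {
  condition_params(
    decision_type, difficulty,
    congruent = accumulator_params(I_cong, k, c, theta, dt, t_max),
    incongruent = accumulator_params(I_incong, k, c, theta, dt, t_max))
}

#' Error of a parameter set against behavioral targets
#'
#' Simulates the condition, fits a gamma CDF to the simulated reaction
#' times, and scores the parameter set against a target RT distribution and
#' a target consistency: the RT error is the CDF intersection-over-union
#' distance, the consistency error is the absolute difference between model
#' and target consistency, and the overall error is their mean (equal
#' weights).
#'
#' @param cond a \code{\link{condition_params}} object.
#' @param target_cdf target \code{rt_cdf}.
#' @param target_consistency target congruent-choice probability.
#' @param n_runs simulated trials per evaluation (>= 100).
#' @param seed optional integer seed.
#' @return list with \code{rt_error}, \code{consistency_error},
#'   \code{overall_error}, \code{model_cdf} and \code{model_consistency}.
#' @export
condition_error <- function(cond, target_cdf, target_consistency,
                            n_runs = 1000, seed = NULL) {
  stopifnot(n_runs >= 100, target_consistency >= 0, target_consistency <= 1)
  sim <- simulate_condition(cond, n_runs, seed = seed)
  model_cdf <- fit_gamma_cdf(sim$rt[!is.na(sim$rt)], grid = target_cdf$grid)
  rt_error <- rt_distribution_error(model_cdf, target_cdf)
  consistency_error <- abs(sim$consistency - target_consistency)
  list(rt_error = rt_error, consistency_error = consistency_error,
       overall_error = (rt_error + consistency_error) / 2,
       model_cdf = model_cdf, model_consistency = sim$consistency)
}

#' Iterative zooming grid search for condition parameters
#'
#' Fits the four free parameters of one condition --- the congruent drift
#' rate, the incongruent drift rate (searched as a fraction of the congruent
#' one), the leak and the noise scale, with the threshold fixed --- by an
#' exhaustive grid search: each parameter range is divided into five equal
#' parts, all 5^4 combinations are simulated and scored with
#' \code{\link{condition_error}}, and the search zooms in on the interval
#' between the two grid neighbors of the best entry, repeating until every
#' parameter range is narrower than \code{stop_range} or the best error
#' falls below \code{stop_error} (or \code{max_levels} is reached).
#'
#' All entries are evaluated with common random numbers (the same seed),
#' which removes simulation noise from between-entry comparisons.
#'
#' @param target_cdf target \code{rt_cdf}.
#' @param target_consistency target congruent-choice probability.
#' @param n_runs simulated trials per grid entry (default 1000).
#' @param seed integer seed used for every entry.
#' @param I_congruent_range,ratio_range,k_range,c_range initial search
#'   intervals; \code{ratio_range} is the interval for
#'   \code{I_incongruent / I_congruent} (default [0.2, 1], i.e. the
#'   incongruent drift lies between a fifth of and equal to the congruent
#'   one, at every zoom level).
#' @param theta fixed decision threshold.
#' @param dt,t_max integration settings.
#' @param n_grid grid points per parameter per level (default 5).
#' @param stop_range,stop_error stopping rule constants (default 0.025 for
#'   both).
#' @param max_levels optional cap on the number of zoom levels.
#' @return object of class \code{condition_fit}: list with \code{params}
#'   (best \code{condition_params}), \code{best} (named numeric vector of
#'   the best entry), \code{rt_error}, \code{consistency_error},
#'   \code{overall_error}, \code{n_runs_per_eval} and \code{search_trace}
#'   (one record per level: ranges, best entry, best error).
#' @export
grid_search_fit <- function(target_cdf, target_consistency,
                            n_runs = 1000, seed = 1,
                            I_congruent_range = c(0.05, 0.4),
                            ratio_range = c(0.2, 1),
                            k_range = c(0.2, 0.55),
                            c_range = c(0.01, 0.3),
                            theta = 0.3, dt = 0.001, t_max = 20,
                            n_grid = 5, stop_range = 0.025,
                            stop_error = 0.025, max_levels = Inf) {
  ranges <- list(I_congruent = I_congruent_range, ratio = ratio_range,
                 k = k_range, c = c_range)
  trace <- list()
  level <- 0L
  best <- NULL
  repeat {
    level <- level + 1L
    grids <- lapply(ranges, function(r) seq(r[1], r[2], length.out = n_grid))
    combos <- expand.grid(i1 = seq_len(n_grid), i2 = seq_len(n_grid),
                          i3 = seq_len(n_grid), i4 = seq_len(n_grid))
    errs <- numeric(nrow(combos))
    fits <- vector("list", nrow(combos))
    for (r in seq_len(nrow(combos))) {
      I1 <- grids$I_congruent[combos$i1[r]]
      ra <- grids$ratio[combos$i2[r]]
      kk <- grids$k[combos$i3[r]]
      cc <- grids$c[combos$i4[r]]
      cond <- build_condition(I1, ra * I1, kk, cc, theta, dt, t_max)
      res <- tryCatch(
        condition_error(cond, target_cdf, target_consistency,
                        n_runs = n_runs, seed = seed),
        error = function(e) list(rt_error = 1, consistency_error = 1,
                                 overall_error = 1))
      errs[r] <- res$overall_error
      fits[[r]] <- res[c("rt_error", "consistency_error", "overall_error")]
    }
    ib <- which.min(errs)
    idx <- as.integer(combos[ib, ])
    best_entry <- c(I_congruent = grids$I_congruent[idx[1]],
                    ratio = grids$ratio[idx[2]],
                    k = grids$k[idx[3]], c = grids$c[idx[4]])
    best <- c(fits[[ib]],
              list(entry = best_entry,
                   I_incongruent = unname(best_entry["ratio"] *
                                            best_entry["I_congruent"])))
    if (level == 1L && any(idx == 1L | idx == n_grid))
      warning("grid-search minimum on the boundary of the initial range")
    trace[[level]] <- list(level = level, ranges = ranges,
                           best = best_entry,
                           overall_error = errs[ib])
    widths <- c(diff(range(grids$I_congruent)),
                diff(range(grids$ratio)) * best_entry["I_congruent"],
                diff(range(grids$k)), diff(range(grids$c)))
    if (errs[ib] < stop_error || all(widths < stop_range) ||
        level >= max_levels)
      break
    ranges <- mapply(function(g, j) c(g[max(j - 1L, 1L)],
                                      g[min(j + 1L, n_grid)]),
                     grids, idx, SIMPLIFY = FALSE)
  }
  params <- build_condition(best$entry["I_congruent"], best$I_incongruent,
                            best$entry["k"], best$entry["c"],
                            theta, dt, t_max)
  structure(list(params = params,
                 best = c(I_congruent = unname(best$entry["I_congruent"]),
                          I_incongruent = best$I_incongruent,
                          k = unname(best$entry["k"]),
                          c = unname(best$entry["c"])),
                 rt_error = best$rt_error,
                 consistency_error = best$consistency_error,
                 overall_error = best$overall_error,
                 n_runs_per_eval = n_runs,
                 search_trace = trace),
            class = "condition_fit")
}
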