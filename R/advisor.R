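#' Constraints for the water-intake inversion
#'
#' The advisor searches for the plain-water intake whose predicted urine
#' osmolality hits the 500 mOsm/kg optimal-hydration target, subject to the
#' acceptable band `[uosm_min, uosm_max]` and to plain-water bounds equal to
#' the observed dataset extremes.
#'
#' @param target_uosm target urine osmolality (default 500 mOsm/kg).
#' @param uosm_min,uosm_max acceptable band (defaults 375 and 625 mOsm/kg).
#' @param water_lower,water_upper plain-water bounds (defaults 0 and 4050 mL).
#' @return An `advisor_constraints` object.
#' @export
advisor_constraints <- function(target_uosm = 500, uosm_min = 375,
                                uosm_max = 625, water_lower = 0,
                                water_upper = 4050) {
  if (!(uosm_min < target_uosm && target_uosm < uosm_max))
    stop("need uosm_min < target_uosm < uosm_max")
  if (!(water_lower < water_upper)) stop("need water_lower < water_upper")
  structure(list(target_uosm = target_uosm, uosm_min = uosm_min,
                 uosm_max = uosm_max, water_lower = water_lower,
                 water_upper = water_upper),
            class = "advisor_constraints")
}

#' Solver options for the augmented-Lagrangian inversion
#'
#' Tree-ensemble responses are piecewise constant, so the inner solver works
#' on a smoothed 1-D slice (moving average over a 100 mL kernel, i.e.
#' half-width 50 mL) with finite-difference steps of 50 mL; the final
#' reported prediction always uses the raw model at the returned water
#' value. The band constraints enter as augmented-Lagrangian penalty terms
#' with initial penalty 1, multiplier 10 per outer iteration, at most 8
#' outer iterations, converging when the band violation is below
#' 1 mOsm/kg and the water step below 1 mL.
#'
#' @param smooth_halfwidth_mL half-width of the smoothing kernel (50 mL).
#' @param fd_step_mL finite-difference step (50 mL).
#' @param cache_step_mL lattice spacing for the cached response slice (5 mL).
#' @param mu0,mu_factor,max_outer augmented-Lagrangian schedule.
#' @param tol_violation_uosm,tol_step_mL convergence tolerances.
#' @param max_inner inner-iteration cap per outer step.
#' @param penalty_weight weight of the band-violation term in the raw
#'   objective used to compare candidate solutions.
#' @param starts multi-start water values, or `NULL` for the default set
#'   (original water, 1500 mL, both bounds).
#' @return list of options.
#' @export
advisor_options <- function(smooth_halfwidth_mL = 50, fd_step_mL = 50,
                            cache_step_mL = 5, mu0 = 1, mu_factor = 10,
                            max_outer = 8, tol_violation_uosm = 1,
                            tol_step_mL = 1, max_inner = 30,
                            penalty_weight = 1e6, starts = NULL) {
  list(smooth_halfwidth_mL = smooth_halfwidth_mL, fd_step_mL = fd_step_mL,
       cache_step_mL = cache_step_mL, mu0 = mu0, mu_factor = mu_factor,
       max_outer = max_outer, tol_violation_uosm = tol_violation_uosm,
       tol_step_mL = tol_step_mL, max_inner = max_inner,
       penalty_weight = penalty_weight, starts = starts)
}

#' Predicted urine osmolality as a function of plain-water intake
#'
#' The 1-D slice the optimizer searches: a copy of the record has its
#' plain-water intake set to `water`, and total fluid intake and total
#' water intake are shifted by the same amount (drinking more plain water
#' raises both), all other fields untouched. The original record is never
#' modified. If a shift would drive total fluid intake below plain water,
#' it is clamped to preserve `plain_water <= total_fluid_intake` and the
#' result carries a `clamped` attribute.
#'
#' @param model fitted surrogate (predict method + `$features`).
#' @param record a single visit record (one-row data.frame) with observed
#'   `plain_water` and `total_fluid_intake`.
#' @param water numeric vector of plain-water values (mL).
#' @return predicted urine osmolality, one value per element of `water`.
#' @export
water_response <- function(model, record, water) {
  record <- as.data.frame(record)
  if (nrow(record) != 1L) stop("`record` must be a single row")
  w0 <- record$plain_water
  if (is.na(w0) || is.na(record$total_fluid_intake))
    stop("record must have observed plain_water and total_fluid_intake")
  n <- length(water)
  out <- record[rep(1L, n), , drop = FALSE]
  delta <- water - w0
  out$plain_water <- water
  out$total_fluid_intake <- record$total_fluid_intake + delta
  if (!is.null(record$total_water_intake) && !is.na(record$total_water_intake))
    out$total_water_intake <- record$total_water_intake + delta
  clamped <- out$total_fluid_intake < out$plain_water
  if (any(clamped)) out$total_fluid_intake[clamped] <- out$plain_water[clamped]
  p <- predict(model, out)
  attr(p, "clamped") <- any(clamped)
  p
}

# raw penalized objective used to compare candidate solutions
raw_objective <- function(pred, constraints, penalty_weight) {
  viol <- pmax(0, constraints$uosm_min - pred, pred - constraints$uosm_max)
  (pred - constraints$target_uosm)^2 + penalty_weight * viol^2
}

band_violation <- function(pred, constraints) {
  pmax(0, constraints$uosm_min - pred, pred - constraints$uosm_max)
}

new_recommendation <- function(record, w_opt, pred_opt, constraints,
                               status, iterations) {
  w0 <- record$plain_water
  tfi0 <- record$total_fluid_intake
  structure(list(
    original_water = w0,
    optimized_water = w_opt,
    original_tfi = tfi0,
    optimized_tfi = tfi0 + (w_opt - w0),
    predicted_uosm_at_optimum = pred_opt,
    feasible = pred_opt >= constraints$uosm_min & pred_opt <= constraints$uosm_max,
    solver_status = status,
    iterations = iterations
  ), class = "recommendation")
}

#' @export
print.recommendation <- function(x, ...) {
  cat(sprintf(
    "Water advice: %.0f -> %.0f mL (TFI %.0f -> %.0f mL), predicted U_Osm %.0f mOsm/kg [%s]\n",
    x$original_water, x$optimized_water, x$original_tfi, x$optimized_tfi,
    x$predicted_uosm_at_optimum, x$solver_status))
  invisible(x)
}

# inner minimization of the penalized smooth objective: safeguarded 1-D
# Newton steps with wide finite differences (quadratic local model, the
# sequential-quadratic-programming step specialized to one dimension)
inner_minimize <- function(phi, w, lo, hi, h, max_inner, tol_step) {
  trust <- 500
  iters <- 0L
  for (it in seq_len(max_inner)) {
    iters <- iters + 1L
    f0 <- phi(w)
    fp <- phi(min(w + h, hi + h)); fm <- phi(max(w - h, lo - h))
    g <- (fp - fm) / (2 * h)
    H <- (fp - 2 * f0 + fm) / h^2
    if (abs(g) < 1e-10) break
    step <- if (H > 1e-9) -g / H else -sign(g) * trust
    step <- max(min(step, trust), -trust)
    w_new <- max(min(w + step, hi), lo)
    if (phi(w_new) > f0) {  # backtrack on non-descent (flat plateaus)
      step <- step / 4
      w_new <- max(min(w + step, hi), lo)
      if (phi(w_new) > f0) w_new <- w
    }
    moved <- abs(w_new - w)
    w <- w_new
    if (moved < tol_step) break
  }
  list(w = w, iterations = iters)
}

#' Recommend plain-water intake by inverting the surrogate
#'
#' Minimizes the squared deviation of predicted urine osmolality from the
#' 500 mOsm/kg target over plain-water intake in `[water_lower,
#' water_upper]`, with the acceptable band `[uosm_min, uosm_max]` enforced
#' through augmented-Lagrangian penalty terms; the inner subproblem is
#' solved by safeguarded quadratic (Newton) steps on a smoothed response
#' slice. Multi-start (original water, 1500 mL, both bounds) guards against
#' flat plateaus of the tree response; among candidates, ties in the
#' penalized objective break toward the smallest behavior change
#' (least |optimized - original|). If no water value within bounds
#' satisfies the band, the bound-respecting value minimizing the deviation
#' from target is returned with status `"infeasible"`.
#'
#' Only plain water, total fluid intake and total water intake change
#' during the inversion; all other variables stay constant.
#'
#' @param model fitted surrogate; must include `plain_water` among its
#'   features (otherwise the model is not actionable).
#' @param record single visit record with observed plain water and TFI.
#' @param constraints an [advisor_constraints()].
#' @param options an [advisor_options()] list.
#' @return A `recommendation` (see [advisor_constraints()] for the band
#'   semantics of `feasible`).
#' @export
recommend_water <- function(model, record, constraints = advisor_constraints(),
                            options = advisor_options()) {
  if (!"plain_water" %in% model_features(model))
    stop("non-actionable model: `plain_water` is not among its features")
  record <- as.data.frame(record)
  lo <- constraints$water_lower; hi <- constraints$water_upper
  # cache the raw 1-D slice on a fine lattice (one batched predict), then
  # interpolate; the smoothed slice is a moving average over the kernel
  wgrid <- seq(lo, hi, by = options$cache_step_mL)
  if (wgrid[length(wgrid)] < hi) wgrid <- c(wgrid, hi)
  raw_vals <- as.numeric(water_response(model, record, wgrid))
  raw_fun <- approxfun(wgrid, raw_vals, rule = 2)
  k <- max(1L, round(options$smooth_halfwidth_mL / options$cache_step_mL))
  kern <- rep(1 / (2 * k + 1), 2 * k + 1)
  padded <- c(rep(raw_vals[1], k), raw_vals, rep(raw_vals[length(raw_vals)], k))
  smooth_vals <- as.numeric(stats::filter(padded, kern, sides = 2))[k + seq_along(raw_vals)]
  smooth_fun <- approxfun(wgrid, smooth_vals, rule = 2)

  tgt <- constraints$target_uosm
  # multi-start set: original water, 1500 mL, both bounds, plus a global
  # initialization at the lattice minimizer of the smoothed penalized
  # objective (the 1-D slice is already cached, so this is free and guards
  # against the plateau-riddled basins of tree responses)
  smooth_obj0 <- raw_objective(smooth_vals, constraints, options$mu0)
  global_start <- wgrid[which.min(smooth_obj0)]
  starts <- options$starts %||% unique(pmin(pmax(
    c(record$plain_water, 1500, lo, hi, global_start), lo), hi))
  total_iters <- 0L
  candidates <- numeric(0)
  for (w0 in starts) {
    lambda <- c(0, 0); mu <- options$mu0; w <- w0
    for (outer in seq_len(options$max_outer)) {
      phi <- function(ww) {
        s <- smooth_fun(ww)
        g <- c(constraints$uosm_min - s, s - constraints$uosm_max)
        (s - tgt)^2 + sum((pmax(0, lambda + mu * g)^2 - lambda^2) / (2 * mu))
      }
      res <- inner_minimize(phi, w, lo, hi, options$fd_step_mL,
                            options$max_inner, options$tol_step_mL)
      total_iters <- total_iters + res$iterations
      w_prev <- w; w <- res$w
      s <- smooth_fun(w)
      g <- c(constraints$uosm_min - s, s - constraints$uosm_max)
      lambda <- pmax(0, lambda + mu * g)
      if (max(0, g) < options$tol_violation_uosm &&
          abs(w - w_prev) < options$tol_step_mL) break
      mu <- mu * options$mu_factor
    }
    candidates <- c(candidates, w)
  }
  candidates <- unique(pmin(pmax(candidates, lo), hi))
  # polish each candidate against the raw (unsmoothed) objective on the
  # cached lattice within the smoothing window: the smoothed optimum can sit
  # half a kernel away from the raw optimum of a piecewise-constant response
  obj_lattice <- raw_objective(raw_vals, constraints, options$penalty_weight)
  refined <- vapply(candidates, function(w) {
    win <- which(abs(wgrid - w) <= 5 * options$smooth_halfwidth_mL)
    wgrid[win][which.min(obj_lattice[win])]
  }, numeric(1))
  candidates <- unique(c(candidates, refined))
  # exact raw predictions at the candidates decide the winner
  preds <- as.numeric(water_response(model, record, candidates))
  objs <- raw_objective(preds, constraints, options$penalty_weight)
  best_obj <- min(objs)
  near <- which(objs <= best_obj + 1e-6 * max(1, best_obj))
  pick <- near[which.min(abs(candidates[near] - record$plain_water))]
  w_opt <- candidates[pick]; pred_opt <- preds[pick]

  feas <- band_violation(pred_opt, constraints) == 0
  status <- if (!feas) "infeasible"
            else if (w_opt <= lo + options$tol_step_mL ||
                     w_opt >= hi - options$tol_step_mL) "boundary"
            else "converged"
  new_recommendation(record, w_opt, pred_opt, constraints, status, total_iters)
}

#' Grid-search inversion oracle
#'
#' Exhaustively evaluates the water response on a regular grid over the
#' water bounds and returns the grid point minimizing the same penalized
#' objective as [recommend_water()] (squared deviation from target plus
#' weighted squared band violation); ties break toward the smallest
#' behavior change. Used as an independent testing oracle for the
#' augmented-Lagrangian solver.
#'
#' @inheritParams recommend_water
#' @param step_mL grid spacing (> 0).
#' @param penalty_weight band-violation weight (matches [advisor_options()]).
#' @return A `recommendation`.
#' @export
brute_force_invert <- function(model, record, constraints = advisor_constraints(),
                               step_mL = 50, penalty_weight = 1e6) {
  if (step_mL <= 0) stop("`step_mL` must be positive")
  record <- as.data.frame(record)
  lo <- constraints$water_lower; hi <- constraints$water_upper
  grid <- seq(lo, hi, by = step_mL)
  if (grid[length(grid)] < hi) grid <- c(grid, hi)
  preds <- as.numeric(water_response(model, record, grid))
  objs <- raw_objective(preds, constraints, penalty_weight)
  best <- min(objs)
  near <- which(objs <= best + 1e-9 * max(1, best))
  pick <- near[which.min(abs(grid[near] - record$plain_water))]
  w_opt <- grid[pick]; pred_opt <- preds[pick]
  feas <- band_violation(pred_opt, constraints) == 0
  status <- if (!feas) "infeasible"
            else if (w_opt == lo || w_opt == hi) "boundary" else "converged"
  new_recommendation(record, w_opt, pred_opt, constraints, status,
                     length(grid))
}

#' Advise every record of a test set
#'
#' Runs [recommend_water()] on each eligible row. Rows missing plain water
#' or total fluid intake cannot be advised (the TFI coupling would be
#' undefined) and are skipped; their indices are recorded in the `skipped`
#' attribute of the result.
#'
#' @param model fitted surrogate.
#' @param test_rows visit records.
#' @param constraints an [advisor_constraints()].
#' @param options an [advisor_options()].
#' @return data.frame with one row per advised record: identifiers,
#'   original/optimized water and TFI, predicted urine osmolality at the
#'   optimum, `feasible`, `solver_status`; attribute `skipped` holds the
#'   skipped row indices.
#' @export
advise_testset <- function(model, test_rows, constraints = advisor_constraints(),
                           options = advisor_options()) {
  test_rows <- as.data.frame(test_rows)
  if (nrow(test_rows) == 0L) {
    out <- data.frame()
    attr(out, "skipped") <- integer(0)
    return(out)
  }
  eligible <- !is.na(test_rows$plain_water) & !is.na(test_rows$total_fluid_intake)
  skipped <- which(!eligible)
  recs <- lapply(which(eligible), function(i) {
    r <- recommend_water(model, test_rows[i, , drop = FALSE], constraints, options)
    data.frame(row = i,
               participant_id = test_rows$participant_id[i] %||% NA_character_,
               original_water = r$original_water,
               optimized_water = r$optimized_water,
               original_tfi = r$original_tfi,
               optimized_tfi = r$optimized_tfi,
               predicted_uosm_at_optimum = r$predicted_uosm_at_optimum,
               feasible = r$feasible,
               solver_status = r$solver_status,
               stringsAsFactors = FALSE)
  })
  out <- if (length(recs)) do.call(rbind, recs) else data.frame()
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
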