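model_features <- function(model) {
  f <- model$features
  if (is.null(f)) stop("model must expose a `features` element")
  f
}

#' Default interpretation grid for plain-water intake
#'
#' 28 equally spaced points over 0-4050 mL (150 mL step), sharing the
#' optimizer's water bounds so interpretation and inversion use one axis.
#' @return numeric grid (mL).
#' @export
water_grid <- function() seq(0, 4050, by = 150)

#' Partial dependence with ICE curves
#'
#' For each grid value g, every record's `feature` is overwritten by g and
#' the model predicts; the per-record curves are the ICE curves and their
#' pointwise mean is the PDP. Input records are not modified. Grid points
#' outside the observed feature range are allowed but flagged as
#' extrapolation.
#'
#' @param model a fitted model with a `predict` method and `$features`.
#' @param rows records to average over (>= 1).
#' @param feature feature name (must be in the model's list).
#' @param grid numeric grid; default [water_grid()] for `plain_water`, else
#'   20 equally spaced points over the observed range.
#' @return A `pdp_result`: `feature`, `grid`, `pdp` (mean prediction per
#'   grid point), `ice` (rows x grid matrix), `extrapolated` (logical per
#'   grid point).
#' @export
pdp_ice <- function(model, rows, feature, grid = NULL) {
  rows <- as.data.frame(rows)
  if (!feature %in% model_features(model))
    stop(sprintf("feature `%s` not in the model's feature list", feature))
  if (nrow(rows) < 1L) stop("need at least one row")
  if (is.null(grid)) {
    grid <- if (feature == "plain_water") water_grid() else {
      rg <- range(rows[[feature]], na.rm = TRUE)
      seq(rg[1], rg[2], length.out = 20)
    }
  }
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
  n <- nrow(rows); g <- length(grid)
  big <- rows[rep(seq_len(n), times = g), , drop = FALSE]
  big[[feature]] <- rep(grid, each = n)
  ice <- matrix(predict(model, big), nrow = n, ncol = g)
  obs <- range(rows[[feature]], na.rm = TRUE)
  structure(list(feature = feature, grid = grid,
                 pdp = colMeans(ice), ice = ice,
                 extrapolated = grid < obs[1] | grid > obs[2]),
            class = "pdp_result")
}

#' Accumulated local effects (ALE)
#'
#' Bins the observed feature values into (approximately) equi-count
#' quantile bins; within each bin the local effect is the mean, over the
#' bin's records, of the prediction difference between the bin's upper and
#' lower edge (other fields untouched). Effects are accumulated across bins
#' and centered so the count-weighted mean of the per-bin mid-curve values
#' is zero. Empty bins produced by ties are merged with their neighbor.
#'
#' @param model fitted model with `predict` and `$features`.
#' @param rows records with observed `feature` values.
#' @param feature feature name.
#' @param n_bins target number of quantile bins (default 20).
#' @return An `ale_result`: `feature`, `edges` (length K+1), `effects`
#'   (centered accumulated effect at each edge, length K+1), `counts`
#'   (records per bin).
#' @export
ale <- function(model, rows, feature, n_bins = 20) {
  rows <- as.data.frame(rows)
  if (!feature %in% model_features(model))
    stop(sprintf("feature `%s` not in the model's feature list", feature))
  x <- rows[[feature]]
  keep <- !is.na(x)
  rows <- rows[keep, , drop = FALSE]; x <- x[keep]
  if (length(unique(x)) < n_bins)
    n_bins <- max(1L, length(unique(x)) - 1L)
  edges <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                           type = 1, names = FALSE))
  if (length(edges) < 2L) stop("feature has too few distinct values for ALE")
  K <- length(edges) - 1L
  bin <- pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L), K)
  counts <- tabulate(bin, nbins = K)
  # local effect per bin: mean of f(upper, others) - f(lower, others)
  lo_rows <- rows; lo_rows[[feature]] <- edges[bin]
  hi_rows <- rows; hi_rows[[feature]] <- edges[bin + 1L]
  diffs <- predict(model, hi_rows) - predict(model, lo_rows)
  local <- vapply(seq_len(K), function(k) {
    if (counts[k] == 0L) 0 else mean(diffs[bin == k])
  }, numeric(1))
  # merge empty bins (ties) into the previous bin: zero local effect there
  acc <- c(0, cumsum(local))
  mids <- (acc[-1] + acc[-length(acc)]) / 2
  center <- sum(counts * mids) / sum(counts)
  structure(list(feature = feature, edges = edges,
                 effects = acc - center, counts = counts),
            class = "ale_result")
}

#' Interval of steepest PDP decrease
#'
#' Scans all grid intervals of width `window_mL` and returns the one with
#' the largest decrease of the PDP curve (mean prediction). If the curve
#' never decreases over any window, `no_decrease` is `TRUE`.
#'
#' @param pdp a `pdp_result`.
#' @param window_mL window width in the feature's units (must be a span the
#'   grid covers).
#' @return list with `interval` (c(lo, hi)), `drop` (mOsm/kg over the
#'   window), `no_decrease` flag.
#' @export
largest_drop_interval <- function(pdp, window_mL) {
  g <- pdp$grid; v <- pdp$pdp
  if (window_mL <= 0 || window_mL > diff(range(g)))
    stop("window not covered by the grid")
  best <- list(drop = -Inf, interval = c(NA_real_, NA_real_))
  for (i in seq_along(g)) {
    j <- which(g >= g[i] + window_mL - 1e-9)
    if (!length(j)) break
    j <- j[1]
    d <- v[i] - v[j]
    if (d > best$drop) best <- list(drop = d, interval = c(g[i], g[j]))
  }
  list(interval = best$interval, drop = best$drop,
       no_decrease = !(best$drop > 0))
}

#' Export PDP or ALE curves as CSV
#' @param curve a `pdp_result` or `ale_result`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  df <- if (inherits(curve, "pdp_result"))
    data.frame(grid = curve$grid, pdp = curve$pdp)
  else data.frame(edge = curve$edges, effect = curve$effects)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
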