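# Growth-parameter extraction from colony-size time courses.
#
# Three screening variables are derived per colony: fitness (endpoint colony
# size), lag (time to detectable growth) and t_max (time at maximal growth
# rate). The signal is first smoothed with a centered rolling median; the
# maximal growth rate is the maximum of sliding-window least-squares slopes.

#' Control parameters for growth-curve fitting
#'
#' @param smooth_window Rolling-median window, points (odd; default 5).
#' @param slope_window_h Width of the sliding least-squares window used for
#'   the growth rate, in hours (default 2 h).
#' @param lag_fraction `f` in the lag definition: lag is the first time the
#'   smoothed signal exceeds `s0 + f * (s_max - s0)` (default 0.05).
#' @param theta_rel Growth-call threshold: fitness must reach
#'   `theta_rel * s0` (default 1.5).
#' @param theta_abs Absolute fitness threshold for the growth call
#'   (default 0, i.e. inactive).
#' @return A list of class `growth_control`.
#' @export
growthControl <- function(smooth_window = 5L, slope_window_h = 2,
                          lag_fraction = 0.05, theta_rel = 1.5,
                          theta_abs = 0) {
  stopifnot(smooth_window >= 1, slope_window_h > 0,
            lag_fraction > 0, lag_fraction < 1,
            theta_rel > 0, theta_abs >= 0)
  structure(list(smooth_window = as.integer(smooth_window),
                 slope_window_h = slope_window_h,
                 lag_fraction = lag_fraction,
                 theta_rel = theta_rel, theta_abs = theta_abs),
            class = "growth_control")
}

#' Fit growth parameters to one colony time course
#'
#' Smooths the size signal with a centered rolling median, then reports:
#' `fitness` = smoothed size at the final time point; `max_slope` = maximum of
#' least-squares slopes over sliding windows spanning `slope_window_h` hours
#' (earliest maximizing window on ties); `t_max` = center time of that window;
#' `lag` = first time the smoothed signal exceeds
#' `s0 + lag_fraction * (s_max - s0)`, with `s0` the median of the first three
#' smoothed points; `growth_call` per [callGrowth()]. For non-growers `lag`
#' and `t_max` are `NA`, never fabricated.
#'
#' @param times Hours, strictly increasing, length >= 3 and >= the slope
#'   window.
#' @param sizes Colony sizes, same length, >= 0.
#' @param control A [growthControl()].
#' @return One-row data frame: `fitness`, `lag`, `t_max`, `max_slope`, `s0`,
#'   `growth_call`.
#' @examples
#' t <- seq(0, 96, by = 0.25)
#' s <- logisticSize(t, K = 2000, s0 = 100, r = 0.2, t_mid = 40)
#' fitGrowthCurve(t, s)
#' @export
fitGrowthCurve <- function(times, sizes, control = growthControl()) {
  if (length(times) != length(sizes)) stop("times and sizes differ in length")
  if (length(times) < 3) stop("need at least 3 time points")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  dt <- stats::median(diff(times))
  w <- max(2L, as.integer(round(control$slope_window_h / dt)) + 1L)
  if (length(times) < w)
    stop("fewer points (", length(times), ") than the slope window (", w, ")")

  sm <- rollMedian(sizes, control$smooth_window)
  s0 <- stats::median(sm[seq_len(min(3L, length(sm)))])
  s_max <- max(sm)
  fitness <- sm[length(sm)]

  sl <- slidingSlopes(times, sm, w)
  imax <- which.max(sl$slope)          # which.max takes the earliest tie
  max_slope <- sl$slope[imax]
  t_max <- sl$center[imax]

  thr <- s0 + control$lag_fraction * (s_max - s0)
  above <- which(sm > thr)
  lag <- if (length(above)) times[above[1]] else NA_real_

  call <- callGrowth(fitness, s0, control)
  if (!call) {
    lag <- NA_real_
    t_max <- NA_real_
  }
  data.frame(fitness = fitness, lag = lag, t_max = t_max,
             max_slope = max_slope, s0 = s0, growth_call = call)
}

#' Growth call from fitted parameters
#'
#' A colony is called a grower iff `fitness >= theta_rel * s0` and
#' `fitness >= theta_abs`. Vectorized and deterministic.
#'
#' @param fitness Endpoint size(s), a.u.
#' @param s0 Initial-size estimate(s), a.u.
#' @param control A [growthControl()] supplying the thresholds.
#' @return Logical vector.
#' @export
callGrowth <- function(fitness, s0, control = growthControl()) {
  fitness >= control$theta_rel * s0 & fitness >= control$theta_abs
}

#' Phenotype every colony of a screen
#'
#' Applies [fitGrowthCurve()] to each well of a [ColonyScreen-class] and binds
#' the layout columns to the fitted parameters.
#'
#' @param screen A `ColonyScreen`.
#' @param control A [growthControl()].
#' @return Data frame: layout columns plus `fitness`, `lag`, `t_max`,
#'   `max_slope`, `s0`, `growth_call`.
#' @export
setGeneric("phenotypeScreen", function(screen, control = growthControl())
  standardGeneric("phenotypeScreen"))

#' @rdname phenotypeScreen
#' @export
setMethod("phenotypeScreen", "ColonyScreen", function(screen, control = growthControl()) {
  t <- screenTimes(screen)
  sz <- screenSizes(screen)
  fits <- do.call(rbind, lapply(seq_len(ncol(sz)), function(i)
    fitGrowthCurve(t, sz[, i], control)))
  cbind(screenLayout(screen), fits)
})

#' Median growth parameters across replicates
#'
#' Aggregates per-colony parameters to one row per strain and medium. Medians
#' use the standard even-count rule (mean of the two central values). For
#' `lag` and `t_max` only replicates called as growers enter the median; the
#' number of replicates and of growing replicates is recorded.
#'
#' @param params Data frame from [phenotypeScreen()] (needs `strain_id`,
#'   `medium_id`, `fitness`, `lag`, `t_max`, `growth_call`).
#' @return Data frame: `strain_id`, `medium_id`, `fitness`, `lag`, `t_max`
#'   (medians), `n`, `n_grew`.
#' @export
summarizeReplicates <- function(params) {
  needed <- c("strain_id", "medium_id", "fitness", "lag", "t_max", "growth_call")
  miss <- setdiff(needed, names(params))
  if (length(miss)) stop("params lacks columns: ", paste(miss, collapse = ", "))
  if (!nrow(params)) stop("no replicates to summarize")
  groups <- split(params, paste(params$strain_id, params$medium_id, sep = "\r"))
  out <- lapply(groups, function(g) {
    grew <- g[g$growth_call, , drop = FALSE]
    data.frame(
      strain_id = g$strain_id[1], medium_id = g$medium_id[1],
      fitness = stats::median(g$fitness),
      lag = if (nrow(grew)) stats::median(grew$lag) else NA_real_,
      t_max = if (nrow(grew)) stats::median(grew$t_max) else NA_real_,
      n = nrow(g), n_grew = nrow(grew),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$strain_id, res$medium_id), ]
}

#' Percentage of a screening panel, at printed precision
#'
#' The reporting path used for all screen percentages: `100 * count / panel`,
#' rounded half-up to `digits` decimals.
#'
#' @param count Number of strains.
#' @param panel Panel size.
#' @param digits Decimal digits (default 2).
#' @return Numeric percentage.
#' @examples
#' screenPercentage(91, 1434)   # 6.35
#' screenPercentage(43, 54, 1)  # 79.6
#' @export
screenPercentage <- function(count, panel, digits = 2) {
  if (any(panel <= 0)) stop("panel must be > 0")
  roundHalfUp(100 * count / panel, digits)
}

#' Growth-call intersections across media
#'
#' Counts strains growing on at least one medium, on all media, and on each
#' exclusive medium combination (UpSet-style), with percentages of the full
#' panel.
#'
#' @param calls Logical matrix or data frame, strains x media, with strain ids
#'   as row names and medium ids as column names. No `NA` cells allowed.
#' @param panel Panel size percentages refer to (default `nrow(calls)`; the
#'   full screened collection may be larger than the table of candidates).
#' @param digits Decimal digits for percentages.
#' @return List with `n_any`, `n_all`, `pct_any`, `pct_all`, and a data frame
#'   `exclusive` of counts/percentages per exact medium combination.
#' @export
growthIntersections <- function(calls, panel = nrow(calls), digits = 2) {
  calls <- as.matrix(calls)
  if (anyNA(calls)) {
    bad <- which(is.na(calls), arr.ind = TRUE)
    labs <- paste(rownames(calls)[bad[, 1]] %||% bad[, 1],
                  colnames(calls)[bad[, 2]] %||% bad[, 2], sep = " x ")
    stop("missing growth calls for: ", paste(unique(labs), collapse = ", "))
  }
  storage.mode(calls) <- "logical"
  n_any <- sum(rowSums(calls) >= 1)
  n_all <- sum(rowSums(calls) == ncol(calls))
  media <- colnames(calls) %||% paste0("medium", seq_len(ncol(calls)))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), ncol(calls)))[-1, , drop = FALSE]
  excl <- data.frame(
    combination = apply(combos, 1, function(b) paste(media[as.logical(b)], collapse = "+")),
    count = apply(combos, 1, function(b)
      sum(apply(calls, 1, function(r) all(r == as.logical(b))))),
    stringsAsFactors = FALSE
  )
  excl$percent <- screenPercentage(excl$count, panel, digits)
  rownames(excl) <- NULL
  list(n_any = n_any, n_all = n_all,
       pct_any = screenPercentage(n_any, panel, digits),
       pct_all = screenPercentage(n_all, panel, digits),
       panel = panel, exclusive = excl)
}
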