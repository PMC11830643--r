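#' Disparity rarefaction
#'
#' Disparity (morphological variety) of a group is quantified as the sample
#' variance or cumulative range of a trait. To compare groups of unequal
#' diversity, each group is rarefied: subsamples of increasing size n are
#' drawn without replacement, the statistic is computed on each, and the
#' per-n median with a 95 percent percentile envelope summarises the curve.
#'
#' @name disparity
#' @keywords internal
NULL

disparity_stat <- function(metric) {
  switch(metric,
         variance = function(x) stats::var(x),
         range = function(x) max(x) - min(x),
         stop("unknown metric: ", metric))
}

#' Rarefaction curve of a disparity statistic
#'
#' For each subsample size n from `n_min` up to the group size, draws
#' `reps` subsamples without replacement and computes the statistic
#' (sample variance with denominator n-1, or range = max - min). At
#' n = group size there is only one distinct subsample, so the median and
#' both envelope bounds equal the full-sample statistic.
#'
#' @param values finite numeric vector for one group.
#' @param metric `"variance"` or `"range"`.
#' @param variable label of the trait measured (recorded in the output).
#' @param group group label (recorded in the output).
#' @param n_min smallest subsample size (default 5).
#' @param reps subsamples per n (default 1000).
#' @param seed integer seed; the curve is fully reproducible from it.
#' @return a data.frame of class `rarefaction_curve` with columns `group`,
#'   `variable`, `metric`, `n`, `median`, `ci_low`, `ci_high`, and
#'   attributes `reps` and `seed`; `NULL` (with a warning) if the group is
#'   smaller than `n_min`.
#' @export
rarefy <- function(values, metric = c("variance", "range"),
                   variable = NA_character_, group = NA_character_,
                   n_min = 5L, reps = 1000L, seed = NULL) {
  metric <- match.arg(metric)
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("values must be finite")
  N <- length(values)
  if (N < n_min) {
    warning(sprintf("group '%s' has %d values < n_min = %d; skipped",
                    group, N, n_min))
    return(NULL)
  }
  if (!is.null(seed)) set.seed(seed)
  stat <- disparity_stat(metric)
  grid <- seq.int(n_min, N)
  med <- lo <- hi <- numeric(length(grid))
  for (k in seq_along(grid)) {
    n <- grid[k]
    if (n == N) {
      s <- stat(values)
      med[k] <- lo[k] <- hi[k] <- s
    } else {
      draws <- vapply(seq_len(reps),
                      function(i) stat(values[sample.int(N, n)]),
                      numeric(1L))
      q <- stats::quantile(draws, c(0.025, 0.5, 0.975), names = FALSE,
                           type = 7)
      lo[k] <- q[1L]; med[k] <- q[2L]; hi[k] <- q[3L]
    }
  }
  out <- data.frame(group = group, variable = variable, metric = metric,
                    n = grid, median = med, ci_low = lo, ci_high = hi,
                    stringsAsFactors = FALSE)
  attr(out, "reps") <- reps
  attr(out, "seed") <- seed
  class(out) <- c("rarefaction_curve", "data.frame")
  out
}

#' Exhaustive rarefaction (enumeration oracle)
#'
#' Computes the exact median and 95 percent percentile envelope of the
#' disparity statistic over *all* C(N, n) subsamples at each n. Feasible
#' only for small groups; used as an independent check on the Monte-Carlo
#' curves.
#'
#' @inheritParams rarefy
#' @param max_combn guard on the largest number of subsamples enumerated.
#' @return a `rarefaction_curve` data.frame (attribute `reps` = NA).
#' @export
rarefy_exhaustive <- function(values, metric = c("variance", "range"),
                              variable = NA_character_,
                              group = NA_character_,
                              n_min = 5L, max_combn = 2e5) {
  metric <- match.arg(metric)
  values <- as.numeric(values)
  N <- length(values)
  if (N < n_min) stop("group smaller than n_min")
  stat <- disparity_stat(metric)
  grid <- seq.int(n_min, N)
  med <- lo <- hi <- numeric(length(grid))
  for (k in seq_along(grid)) {
    n <- grid[k]
    if (choose(N, n) > max_combn) {
      stop("choose(", N, ", ", n, ") exceeds max_combn")
    }
    draws <- utils::combn(values, n, stat)
    q <- stats::quantile(draws, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
    lo[k] <- q[1L]; med[k] <- q[2L]; hi[k] <- q[3L]
  }
  out <- data.frame(group = group, variable = variable, metric = metric,
                    n = grid, median = med, ci_low = lo, ci_high = hi,
                    stringsAsFactors = FALSE)
  attr(out, "reps") <- NA_integer_
  class(out) <- c("rarefaction_curve", "data.frame")
  out
}

#' Sample size at which two rarefaction envelopes diverge
#'
#' The smallest n in the shared grid at which the two 95 percent envelopes
#' are disjoint *and remain disjoint at every larger shared n* (persistence
#' guards against sporadic Monte-Carlo crossings). This is the sample size
#' at which the disparity of the two groups becomes differentiable.
#'
#' @param curve_a,curve_b `rarefaction_curve` objects with the same metric
#'   and variable.
#' @param persistent require the envelopes to stay disjoint from the
#'   threshold onward (default `TRUE`); `FALSE` returns the first
#'   separation regardless of later overlap.
#' @return integer n, or `NA` if the envelopes never diverge.
#' @export
divergence_threshold <- function(curve_a, curve_b, persistent = TRUE) {
  if (!identical(curve_a$metric[1L], curve_b$metric[1L]) ||
      !identical(curve_a$variable[1L], curve_b$variable[1L])) {
    stop("curves measure different metrics or variables")
  }
  shared <- intersect(curve_a$n, curve_b$n)
  if (length(shared) == 0L) stop("incomparable curves: n grids are disjoint")
  shared <- sort(shared)
  ia <- match(shared, curve_a$n)
  ib <- match(shared, curve_b$n)
  disjoint <- curve_a$ci_low[ia] > curve_b$ci_high[ib] |
    curve_b$ci_low[ib] > curve_a$ci_high[ia]
  if (!any(disjoint)) return(NA_integer_)
  if (!persistent) return(shared[which(disjoint)[1L]])
  # smallest n from which all larger shared n are disjoint
  ok_from <- rev(cumprod(rev(disjoint))) == 1
  if (!any(ok_from)) return(NA_integer_)
  shared[which(ok_from)[1L]]
}

#' Sample size at which the cumulative range stabilises
#'
#' The smallest n at which the median rarefied range reaches
#' `(1 - tol)` of the full-sample range and stays there for all larger n
#' ("where the curve flattens").
#'
#' @param curve a `rarefaction_curve` with metric `"range"`.
#' @param tol flattening tolerance as a fraction of the full range
#'   (default 0.01).
#' @return integer n (always at most the group size).
#' @export
range_stabilization <- function(curve, tol = 0.01) {
  if (curve$metric[1L] != "range") stop("curve metric must be 'range'")
  full <- curve$median[which.max(curve$n)]
  ok <- curve$median >= (1 - tol) * full
  ok_from <- rev(cumprod(rev(ok))) == 1
  curve$n[which(ok_from)[1L]]
}

#' Rarefy every group of a classified trait table
#'
#' Convenience wrapper producing long-format curves for each combination of
#' grouping level, variable and metric.
#'
#' @param records classified trait table.
#' @param variables trait columns to rarefy (default `pSV`, `logSL`, `XS`).
#' @param metrics disparity metrics (default both).
#' @param group_by grouping column (default `"family"`).
#' @param n_min,reps,seed see [rarefy()]; each group/variable/metric cell
#'   gets a distinct seed derived from `seed`.
#' @return a single long data.frame of all curves.
#' @export
rarefy_table <- function(records, variables = c("pSV", "logSL", "XS"),
                         metrics = c("variance", "range"),
                         group_by = "family",
                         n_min = 5L, reps = 1000L, seed = 1L) {
  groups <- sort(unique(records[[group_by]]))
  out <- list()
  offset <- 0L
  for (v in variables) {
    for (m in metrics) {
      for (g in groups) {
        offset <- offset + 1L
        vals <- records[[v]][records[[group_by]] == g]
        cur <- rarefy(vals, metric = m, variable = v, group = g,
                      n_min = n_min, reps = reps,
                      seed = seed + offset)
        if (!is.null(cur)) out[[length(out) + 1L]] <- cur
      }
    }
  }
  do.call(rbind, out)
}
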