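#' Imaging-failure rule
#'
#' A failure rule declares when an acquired image counts as an imaging
#' failure: quality strictly below \code{quality_min}, photobleaching
#' strictly above \code{bleach_max} (optional), or any extra named
#' predicate returning TRUE. Typical settings follow the published
#' analyses: quality below 0.70; quality below 0.60 or photobleaching
#' above 0.75; quality below 0.60 or photobleaching above 0.60.
#'
#' @param quality_min Quality threshold in [0, 1], or NULL to skip.
#' @param bleach_max Photobleaching threshold in [0, 1], or NULL to skip.
#' @param quality,bleach Column names of the objectives in a history
#'   data.frame.
#' @param extra Named list of functions(row) returning TRUE on failure.
#' @return An object of class \code{failure_rule}.
#' @export
failure_rule <- function(quality_min = NULL, bleach_max = NULL,
                         quality = "quality", bleach = "photobleaching",
                         extra = list()) {
  for (th in c(quality_min, bleach_max))
    if (!is.null(th) && (th < 0 || th > 1))
      stop("thresholds must lie in [0, 1]")
  structure(list(quality_min = quality_min, bleach_max = bleach_max,
                 quality = quality, bleach = bleach, extra = extra),
            class = "failure_rule")
}

#' Cumulative regret (failure count) of an optimization history
#'
#' Iteration t contributes 1 to the regret when any condition of the rule
#' fails at t ("below"/"over" thresholds are strict on the failing side);
#' the cumulative sum is returned. Missing (NA) objective values that the
#' rule references count as failures (the acquisition produced no usable
#' image).
#'
#' @param history Data.frame with one row per iteration and the objective
#'   columns the rule references (e.g. the \code{history} element of an
#'   \code{mo_run}), or a numeric vector of quality values.
#' @param rule A \code{failure_rule}.
#' @return An object of class \code{regret_curve}: integer vector of
#'   cumulative failure counts, with attribute \code{increments}.
#' @export
cumulative_regret <- function(history, rule) {
  stopifnot(inherits(rule, "failure_rule"))
  if (is.numeric(history) && is.null(dim(history)))
    history <- stats::setNames(data.frame(history), rule$quality)
  fail <- rep(FALSE, nrow(history))
  if (!is.null(rule$quality_min)) {
    if (!rule$quality %in% names(history))
      stop("history lacks objective column '", rule$quality, "'")
    q <- history[[rule$quality]]
    fail <- fail | is.na(q) | q < rule$quality_min
  }
  if (!is.null(rule$bleach_max)) {
    if (!rule$bleach %in% names(history))
      stop("history lacks objective column '", rule$bleach, "'")
    b <- history[[rule$bleach]]
    fail <- fail | is.na(b) | b > rule$bleach_max
  }
  for (pred in rule$extra)
    fail <- fail | vapply(seq_len(nrow(history)),
                          function(i) isTRUE(pred(history[i, ])), logical(1))
  structure(cumsum(as.integer(fail)), increments = as.integer(fail),
            class = "regret_curve")
}

#' Average regret curves across trials
#'
#' @param curves List of equal-length regret curves (numeric vectors).
#' @return List: \code{mean} and \code{sd}, element-wise across trials.
#' @export
average_regret <- function(curves) {
  if (length(curves) == 0) stop("no curves")
  len <- unique(vapply(curves, length, integer(1)))
  if (length(len) != 1) stop("curves must have equal length")
  M <- do.call(rbind, lapply(curves, as.numeric))
  list(mean = colMeans(M),
       sd = if (nrow(M) == 1) rep(0, ncol(M)) else apply(M, 2, stats::sd))
}

#' Percentile bootstrap confidence interval
#'
#' Draws M resamples of size n with replacement, evaluates the statistic
#' on each, and returns the percentile interval at the requested level.
#'
#' @param values Numeric sample (non-empty).
#' @param statistic Function mapping a sample to a scalar (default mean).
#' @param M Number of resamples (default 1000).
#' @param level Confidence level (default 0.95).
#' @return List: \code{estimate} (statistic on the original sample),
#'   \code{lower}, \code{upper}, \code{replicates}.
#' @export
bootstrap_ci <- function(values, statistic = mean, M = 1000, level = 0.95) {
  values <- as.numeric(values)
  if (length(values) == 0) stop("empty sample")
  stopifnot(M >= 1)
  n <- length(values)
  reps <- if (identical(statistic, mean)) {
    ## vectorized fast path for the mean
    colMeans(matrix(values[sample.int(n, n * M, replace = TRUE)], n, M))
  } else {
    vapply(seq_len(M), function(i)
      statistic(values[sample.int(n, n, replace = TRUE)]), numeric(1))
  }
  a <- (1 - level) / 2
  qs <- stats::quantile(reps, c(a, 1 - a), names = FALSE, type = 7)
  list(estimate = statistic(values), lower = qs[1], upper = qs[2],
       replicates = reps)
}

#' Relative frequency of local responses across thresholds
#'
#' For each threshold, the fraction of defined response-size ratios r with
#' 0 < r <= threshold (a local response), with percentile bootstrap bands.
#'
#' @param ratios Response-size ratios in [0, 1]; NA = undefined.
#' @param thresholds Threshold grid.
#' @param M Bootstrap resamples for the bands (default 1000).
#' @param level Confidence level (default 0.95).
#' @return Data.frame: threshold, frequency, lower, upper.
#' @export
response_frequency_curve <- function(ratios, thresholds, M = 1000,
                                     level = 0.95) {
  r <- ratios[!is.na(ratios)]
  out <- lapply(thresholds, function(th) {
    freq_stat <- function(x) mean(x > 0 & x <= th)
    if (length(r) == 0)
      return(data.frame(threshold = th, frequency = NA_real_,
                        lower = NA_real_, upper = NA_real_))
    ci <- bootstrap_ci(r, freq_stat, M = M, level = level)
    data.frame(threshold = th, frequency = ci$estimate,
               lower = ci$lower, upper = ci$upper)
  })
  do.call(rbind, out)
}
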