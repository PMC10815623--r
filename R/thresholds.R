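#' Parameters of the analytical-threshold estimators
#'
#' @param k Confidence multiplier for the mean + k*SD rules (default 3,
#'   roughly a 99.7 percent one-sided exclusion under normality).
#' @param alpha One-sided confidence level for the t-based rules
#'   (default 0.99).
#' @param q Quantile for the percentile rule (default 0.99: the value
#'   separating 99 percent of the negative signals from the rest).
#' @param rounding `"ceil_int"` (round reported thresholds up to whole RFU;
#'   conservative for noise exclusion) or `"none"`.
#' @return List of class `threshold_params`.
#' @export
threshold_params <- function(k = 3, alpha = 0.99, q = 0.99,
                             rounding = c("ceil_int", "none")) {
  rounding <- match.arg(rounding)
  stopifnot(k > 0, alpha > 0, alpha < 1, q > 0, q < 1)
  structure(list(k = k, alpha = alpha, q = q, rounding = rounding),
            class = "threshold_params")
}

round_at <- function(x, params) {
  if (params$rounding == "ceil_int") pmax(1, ceiling(x)) else x
}

#' A named set of per-dye analytical thresholds
#'
#' @param method Method label (e.g. `"AT_ori"`, `"AT1"`..`"AT5"`).
#' @param values Named numeric vector, one RFU value per analysis dye
#'   (`NA` marks a dye whose value could not be computed).
#' @return Object of class `threshold_set`.
#' @export
threshold_set <- function(method, values) {
  stopifnot(is.numeric(values), !is.null(names(values)))
  if (any(!is.na(values) & values < 1)) {
    stop("threshold values must be >= 1 RFU", call. = FALSE)
  }
  structure(list(method = method, values = values), class = "threshold_set")
}

#' @rdname threshold_set
#' @param x A `threshold_set`.
#' @export
threshold_values <- function(x) {
  if (inherits(x, "threshold_set")) x$values else x
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(x$method, ": ", paste(names(x$values), round(x$values, 2),
                            sep = "=", collapse = "  "), " RFU\n", sep = "")
  invisible(x)
}

check_stats <- function(stats, need_signals = 2, need_samples = 1) {
  if (stats$n_signals < need_signals) {
    stop("insufficient data: dye ", stats$dye, " has ", stats$n_signals,
         " signal(s), need >= ", need_signals, call. = FALSE)
  }
  if (stats$n_samples < need_samples) {
    stop("insufficient data: need >= ", need_samples,
         " negative-control injections", call. = FALSE)
  }
}

#' Threshold estimators from negative-signal baselines
#'
#' Five published estimators of the analytical threshold from the signals
#' of amplification negative controls, per dye:
#' \describe{
#'   \item{`at1`}{mean + k * SD of the negative signal heights.}
#'   \item{`at2`}{mean + t(alpha, n-1) * SD / sqrt(n), the one-sided upper
#'     confidence bound on the mean; `n` is the number of negative-control
#'     injections.}
#'   \item{`at3`}{mean + t(alpha, n-1) * sqrt(1 + 1/n) * SD, a one-sided
#'     prediction bound correcting for the uncertainty of the estimated
#'     mean.}
#'   \item{`at4`}{the q-quantile (default 99th percentile, linear
#'     interpolation between order statistics) of the pooled heights.}
#'   \item{`at5`}{exp(log-mean + k * log-SD), the lognormal-model bound;
#'     the spread parameter is the standard deviation of the log heights.}
#' }
#' All return the rounded value per `params$rounding` (default: ceiling to
#' whole RFU), with the raw value in attribute `"raw"`.
#'
#' @param stats A [compute_baseline_stats()] result.
#' @param params A [threshold_params()].
#' @return Threshold in RFU.
#' @export
at1 <- function(stats, params = threshold_params()) {
  check_stats(stats, need_signals = 2)
  raw <- stats$mean_height + params$k * stats$sd_height
  structure(round_at(raw, params), raw = raw)
}

#' @rdname at1
#' @export
at2 <- function(stats, params = threshold_params()) {
  check_stats(stats, need_signals = 2, need_samples = 2)
  nn <- stats$n_samples
  raw <- stats$mean_height +
    stats::qt(params$alpha, df = nn - 1) * stats$sd_height / sqrt(nn)
  structure(round_at(raw, params), raw = raw)
}

#' @rdname at1
#' @export
at3 <- function(stats, params = threshold_params()) {
  check_stats(stats, need_signals = 2, need_samples = 2)
  nn <- stats$n_samples
  raw <- stats$mean_height +
    stats::qt(params$alpha, df = nn - 1) * sqrt(1 + 1 / nn) * stats$sd_height
  structure(round_at(raw, params), raw = raw)
}

#' @rdname at1
#' @param heights Pooled negative signal heights (non-empty numeric).
#' @export
at4 <- function(heights, params = threshold_params()) {
  if (inherits(heights, "baseline_stats")) heights <- heights$heights
  if (!length(heights)) stop("insufficient data: no heights for at4", call. = FALSE)
  raw <- unname(stats::quantile(heights, params$q, type = 7))
  structure(round_at(raw, params), raw = raw)
}

#' @rdname at1
#' @export
at5 <- function(stats, params = threshold_params()) {
  check_stats(stats, need_signals = 2)
  if (!isTRUE(stats$all_positive)) {
    stop("at5 requires strictly positive heights (lognormal model)", call. = FALSE)
  }
  raw <- exp(stats$log_mean + params$k * stats$log_sd)
  structure(round_at(raw, params), raw = raw)
}

#' Compute all six analytical-threshold sets from negative controls
#'
#' Runs the five negative-signal estimators per analysis dye on pooled,
#' pre-filtered negative-control tables, and prepends the static empirical
#' threshold `AT_ori` (one constant value for every dye). A dye with fewer
#' than 2 signals gets `NA` for the calculated methods and is listed in the
#' `"flagged"` attribute; the other dyes are still computed.
#'
#' @param negatives List of filtered negative-role [sizing_table]s.
#' @param kit A [kit_config].
#' @param params A [threshold_params()].
#' @param static_at Static empirical threshold in RFU (default 175).
#' @return Named list of six [threshold_set]s
#'   (`AT_ori`, `AT1`..`AT5`), with attribute `"stats"` holding the per-dye
#'   [compute_baseline_stats()] objects.
#' @export
compute_all_thresholds <- function(negatives, kit, params = threshold_params(),
                                   static_at = 175) {
  if (inherits(negatives, "sizing_table")) negatives <- list(negatives)
  dyes <- kit$analysis_dyes
  stats_by_dye <- lapply(stats::setNames(dyes, dyes),
                         function(d) compute_baseline_stats(negatives, d))
  methods <- c("AT1", "AT2", "AT3", "AT4", "AT5")
  fns <- list(AT1 = at1, AT2 = at2, AT3 = at3,
              AT4 = function(s, p) at4(s$heights, p), AT5 = at5)
  flagged <- character(0)
  vals <- matrix(NA_real_, nrow = length(methods), ncol = length(dyes),
                 dimnames = list(methods, dyes))
  for (d in dyes) {
    s <- stats_by_dye[[d]]
    if (s$n_signals < 2) {
      flagged <- c(flagged, d)
      next
    }
    for (m in methods) {
      vals[m, d] <- tryCatch(as.numeric(fns[[m]](s, params)),
                             error = function(e) NA_real_)
    }
  }
  sets <- c(
    list(AT_ori = threshold_set("AT_ori", stats::setNames(rep(static_at, length(dyes)), dyes))),
    lapply(stats::setNames(methods, methods),
           function(m) threshold_set(m, vals[m, ]))
  )
  attr(sets, "stats") <- stats_by_dye
  attr(sets, "flagged") <- unique(flagged)
  sets
}

#' Threshold sets as a methods-by-dyes table
#'
#' @param sets Result of [compute_all_thresholds()] (or a list of
#'   [threshold_set]s).
#' @return data.frame, rows = methods, columns = dyes.
#' @export
thresholds_table <- function(sets) {
  rows <- lapply(sets, function(s) as.data.frame(as.list(s$values)))
  out <- do.call(rbind, rows)
  rownames(out) <- vapply(sets, function(s) s$method, character(1))
  out
}
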