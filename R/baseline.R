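#' Per-dye baseline statistics of negative-control signals
#'
#' Pools all signal heights of one dye across a collection of filtered
#' negative-control sizing tables and summarises them: count, mean and
#' sample SD (n-1 denominator) on the RFU scale, mean and SD of the natural
#' log of the heights (the lognormal model parameters), percentiles and
#' maximum. `n_samples` is the number of negative-control injections
#' pooled -- this, not the signal count, is the `n` that enters the
#' t-based threshold formulas.
#'
#' @param tables List of negative-role [sizing_table]s (post-filtering).
#' @param dye Dye label to summarise.
#' @param probs Percentiles to record (must include 0.99).
#' @return An object of class `baseline_stats`: list with `dye`,
#'   `n_signals`, `n_samples`, `mean_height`, `sd_height`, `log_mean`,
#'   `log_sd`, `percentiles`, `max_height`, `heights`, and
#'   `undefined_mean` flag when no signal was observed.
#' @export
compute_baseline_stats <- function(tables, dye, probs = c(0.5, 0.9, 0.95, 0.99)) {
  if (inherits(tables, "sizing_table")) tables <- list(tables)
  stopifnot(length(tables) >= 1, 0.99 %in% probs)
  h <- unlist(lapply(tables, function(t) t$height_rfu[t$dye == dye]),
              use.names = FALSE)
  n <- length(h)
  pos <- h[h > 0]
  stats <- list(
    dye = dye,
    n_signals = n,
    n_samples = length(tables),
    mean_height = if (n) mean(h) else NA_real_,
    sd_height = if (n > 1) stats::sd(h) else if (n == 1) 0 else NA_real_,
    log_mean = if (length(pos)) mean(log(pos)) else NA_real_,
    log_sd = if (length(pos) > 1) stats::sd(log(pos)) else if (length(pos) == 1) 0 else NA_real_,
    percentiles = if (n) stats::quantile(h, probs, type = 7) else
      stats::setNames(rep(NA_real_, length(probs)), paste0(probs * 100, "%")),
    max_height = if (n) max(h) else NA_real_,
    heights = h,
    undefined_mean = n == 0,
    all_positive = n > 0 && all(h > 0)
  )
  structure(stats, class = "baseline_stats")
}

#' @export
print.baseline_stats <- function(x, ...) {
  cat("Baseline stats, dye ", x$dye, ": ", x$n_signals, " signal(s) over ",
      x$n_samples, " injection(s)\n", sep = "")
  if (!x$undefined_mean) {
    cat(sprintf("  mean %.3f  sd %.3f  p99 %.2f  max %.1f RFU\n",
                x$mean_height, x$sd_height, x$percentiles[["99%"]], x$max_height))
    cat(sprintf("  log-mean %.4f  log-sd %.4f\n", x$log_mean, x$log_sd))
  } else cat("  no signals (mean undefined)\n")
  invisible(x)
}

#' Calendar quarter of a date
#'
#' Quarters are the calendar three-month blocks S1 = Jan-Mar, S2 = Apr-Jun,
#' S3 = Jul-Sep, S4 = Oct-Dec; keys look like `"2021_S3"`.
#'
#' @param date A Date (or something [as.Date()] accepts).
#' @return Character quarter key.
#' @export
quarter_key <- function(date) {
  date <- as.Date(date)
  y <- as.integer(format(date, "%Y"))
  m <- as.integer(format(date, "%m"))
  paste0(y, "_S", (m - 1) %/% 3 + 1)
}

#' Group sizing tables by calendar quarter
#'
#' @param tables List of [sizing_table]s, each with a `run_date`.
#' @return Named list of table lists; the partition is total and disjoint.
#' @export
group_by_quarter <- function(tables) {
  dates <- lapply(tables, function(t) attr(t, "run_date"))
  missing <- vapply(dates, function(d) is.null(d) || is.na(d), logical(1))
  if (any(missing)) {
    ids <- vapply(which(missing), function(i) {
      sid <- unique(tables[[i]]$sample_id)
      if (length(sid) && !all(is.na(sid))) sid[1] else paste0("table#", i)
    }, character(1))
    stop("run_date missing for: ", paste(ids, collapse = ", "), call. = FALSE)
  }
  keys <- vapply(dates, quarter_key, character(1))
  split(tables, keys)
}

#' Rank-based comparison of two signal groups
#'
#' Two-sided Mann-Whitney U test (normal approximation with tie
#' correction), plus the significance star band used on the figures:
#' `"*"` for 0.01 < p <= 0.05, `"**"` for 0.001 < p <= 0.01, `"***"` for
#' 0.0001 < p <= 0.001, `"****"` for p <= 0.0001, `"ns"` otherwise.
#'
#' @param a,b Numeric vectors (each of length >= 2).
#' @return List with `statistic` (U), `p_value`, `band`.
#' @export
compare_groups <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    stop("insufficient data: both groups need at least 2 values", call. = FALSE)
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided",
                                            exact = FALSE, correct = TRUE))
  p <- wt$p.value
  list(statistic = unname(wt$statistic), p_value = p, band = star_band(p))
}

#' @rdname compare_groups
#' @param p A p value.
#' @export
star_band <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p <= 1e-4) "****"
  else if (p <= 1e-3) "***"
  else if (p <= 0.01) "**"
  else if (p <= 0.05) "*"
  else "ns"
}

#' Fit the lognormal baseline-height model
#'
#' Moment fit on the log scale: the log-mean and log-SD (n-1 denominator)
#' of the natural log of the heights. Goodness of fit is a
#' Kolmogorov-Smirnov test of the log-heights against the fitted normal
#' (heights are often integer-quantised RFU, so ties are expected and the
#' KS p value is approximate; the statistic D is the primary readout).
#'
#' @param heights Numeric vector, all > 0.
#' @return List of class `lognormal_fit`: `log_mean`, `log_sd`,
#'   `gof_stat` (KS D), `gof_p`.
#' @export
fit_lognormal <- function(heights) {
  if (!length(heights)) stop("no heights supplied", call. = FALSE)
  if (any(heights <= 0)) stop("all heights must be > 0 for the lognormal model", call. = FALSE)
  lh <- log(heights)
  v <- mean(lh)
  tau <- if (length(lh) > 1) stats::sd(lh) else 0
  if (tau > 0) {
    ks <- suppressWarnings(stats::ks.test(lh, "pnorm", mean = v, sd = tau))
    gof_stat <- unname(ks$statistic); gof_p <- ks$p.value
  } else {
    gof_stat <- NA_real_; gof_p <- NA_real_
  }
  structure(list(log_mean = v, log_sd = tau, gof_stat = gof_stat, gof_p = gof_p),
            class = "lognormal_fit")
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat(sprintf("Lognormal fit: log-mean %.4f, log-sd %.4f (KS D = %.4f)\n",
              x$log_mean, x$log_sd, x$gof_stat))
  invisible(x)
}

#' Per-sample, per-dye signal summary table
#'
#' The "signal quantity and height distribution" spreadsheet: one row per
#' (sizing table, dye) with count, mean, SD, min, max and 99th percentile.
#'
#' @param tables List of [sizing_table]s.
#' @param kit A [kit_config]; analysis dyes define the rows.
#' @return data.frame.
#' @export
signal_summary <- function(tables, kit) {
  if (inherits(tables, "sizing_table")) tables <- list(tables)
  rows <- list()
  for (i in seq_along(tables)) {
    t <- tables[[i]]
    sid <- unique(t$sample_id)
    sid <- if (length(sid) && !all(is.na(sid))) sid[1] else paste0("sample_", i)
    for (d in kit$analysis_dyes) {
      h <- t$height_rfu[t$dye == d]
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = sid, dye = d, n_signals = length(h),
        mean_height = if (length(h)) mean(h) else NA_real_,
        sd_height = if (length(h) > 1) stats::sd(h) else if (length(h) == 1) 0 else NA_real_,
        min_height = if (length(h)) min(h) else NA_real_,
        max_height = if (length(h)) max(h) else NA_real_,
        p99_height = if (length(h)) unname(stats::quantile(h, 0.99, type = 7)) else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
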