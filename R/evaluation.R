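#' Label peaks as allelic or non-allelic against a reference genotype
#'
#' Each record (which must already carry a marker label, i.e. have passed
#' locus screening, and ideally pull-up removal) is labelled `allelic` when
#' its size falls in the bin (center +/- 0.5 bp) of an expected allele at
#' its marker, otherwise `non_allelic`. Expected alleles not matched by any
#' record are dropouts. Homozygous markers contribute one expected allele
#' (presence/absence scoring only).
#'
#' @param table A [sizing_table] with marker annotations.
#' @param genotype A `reference_genotype`.
#' @param kit A [kit_config].
#' @param bin_tol_bp Half-width of an allele bin (default 0.5 bp).
#' @return List of class `peak_classification`: `records` (the table with a
#'   `label` and `allele_call` column), `dropouts` (data.frame of unmatched
#'   expected alleles), `expected` (the expected-allele table).
#' @export
classify_peaks <- function(table, genotype, kit, bin_tol_bp = 0.5) {
  unknown <- setdiff(unique(stats::na.omit(table$marker)), names(genotype))
  if (length(unknown)) {
    stop("record(s) at marker(s) absent from the reference genotype: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  exp_tab <- expected_allele_table(genotype, kit)
  df <- as.data.frame(table)
  label <- rep("non_allelic", nrow(df))
  call <- rep(NA_character_, nrow(df))
  matched <- rep(FALSE, nrow(exp_tab))
  for (j in seq_len(nrow(exp_tab))) {
    hit <- !is.na(df$marker) & df$marker == exp_tab$marker[j] &
      abs(df$size_bp - exp_tab$center_bp[j]) <= bin_tol_bp
    if (any(hit)) {
      matched[j] <- TRUE
      label[hit] <- "allelic"
      call[hit] <- exp_tab$allele[j]
    }
  }
  df$label <- label
  df$allele_call <- call
  structure(
    list(records = st_replace_records(table, df),
         dropouts = exp_tab[!matched, , drop = FALSE],
         expected = exp_tab),
    class = "peak_classification"
  )
}

#' @export
print.peak_classification <- function(x, ...) {
  cat("Peak classification: ", sum(x$records$label == "allelic"), " allelic, ",
      sum(x$records$label == "non_allelic"), " non-allelic, ",
      nrow(x$dropouts), " dropout(s) of ", nrow(x$expected),
      " expected allele(s)\n", sep = "")
  invisible(x)
}

#' Tally dropouts, detections and non-allelic peaks
#'
#' Aggregates a [classify_peaks()] result into an evaluation count for one
#' dye (or all dyes pooled): expected alleles, dropouts, detections,
#' non-allelic peaks, the true-positive rate `tpr = detected / expected`,
#' the false-positive rate `fpr = min(1, non_allelic / expected)` (the
#' non-allelic tally normalised by the same denominator as the dropouts,
#' capped at 1 -- an explicit package convention), and
#' `total_error = (1 - tpr) + fpr`.
#'
#' @param classification A `peak_classification`.
#' @param dye Dye label, or `NULL` for all analysis dyes pooled.
#' @param condition Optional named list describing the condition
#'   (template_pg, cycles, ...) copied into the result.
#' @return List of class `evaluation_count`.
#' @export
count_events <- function(classification, dye = NULL, condition = list()) {
  exp_tab <- classification$expected
  drop_tab <- classification$dropouts
  rec <- as.data.frame(classification$records)
  if (!is.null(dye)) {
    exp_tab <- exp_tab[exp_tab$dye == dye, , drop = FALSE]
    drop_tab <- drop_tab[drop_tab$dye == dye, , drop = FALSE]
    rec <- rec[rec$dye == dye, , drop = FALSE]
  }
  n_expected <- nrow(exp_tab)
  n_drop <- nrow(drop_tab)
  n_detected <- n_expected - n_drop
  n_non <- sum(rec$label == "non_allelic")
  tpr <- if (n_expected) n_detected / n_expected else NA_real_
  fpr <- if (n_expected) min(1, n_non / n_expected) else NA_real_
  structure(
    c(condition,
      list(dye = if (is.null(dye)) "all" else dye,
           n_expected_alleles = n_expected,
           n_dropouts = n_drop,
           n_true_alleles_detected = n_detected,
           n_non_allelic = n_non,
           tpr = tpr, fpr = fpr,
           total_error = (1 - tpr) + fpr)),
    class = "evaluation_count"
  )
}

#' @export
print.evaluation_count <- function(x, ...) {
  cat(sprintf("Evaluation [%s]: %d/%d alleles detected, %d dropout(s), %d non-allelic; tpr %.3f fpr %.3f total error %.3f\n",
              x$dye, x$n_true_alleles_detected, x$n_expected_alleles,
              x$n_dropouts, x$n_non_allelic, x$tpr, x$fpr, x$total_error))
  invisible(x)
}

#' Total error rate of an evaluation count
#'
#' The sum of the false-negative rate and the false-positive rate:
#' `(1 - tpr) + fpr`. Ranges over \[0, 2\].
#'
#' @param count An `evaluation_count` (or anything with `tpr`/`fpr`).
#' @return Numeric total error.
#' @export
total_error <- function(count) {
  (1 - count$tpr) + count$fpr
}

# per-table pre-computation that makes sweeps and method comparisons O(1)
# per threshold: for every expected allele the tallest matching peak height
# (0 when absent from the raw data), and every non-allelic peak's height.
# Thresholding at AT then reduces to comparisons against these heights,
# which is exactly equivalent to apply_threshold() followed by
# classify_peaks() because bin matching is independent of the other peaks.
profile_summary <- function(table, genotype, kit, bin_tol_bp = 0.5) {
  cls <- classify_peaks(table, genotype, kit, bin_tol_bp)
  rec <- as.data.frame(cls$records)
  exp_tab <- cls$expected
  exp_tab$max_height <- vapply(seq_len(nrow(exp_tab)), function(j) {
    hit <- rec$label == "allelic" & !is.na(rec$allele_call) &
      rec$marker == exp_tab$marker[j] & rec$allele_call == exp_tab$allele[j]
    if (any(hit)) max(rec$height_rfu[hit]) else 0
  }, numeric(1))
  artifacts <- rec[rec$label == "non_allelic", c("dye", "height_rfu"), drop = FALSE]
  list(expected = exp_tab, artifacts = artifacts)
}

#' Sweep the analytical threshold over a range of RFU values
#'
#' For each integer AT in `at_range` and each analysis dye, applies the
#' threshold, classifies peaks against the genotype, counts dropouts and
#' non-allelic peaks, and averages over the replicate tables. Dropout
#' counts are non-decreasing and non-allelic counts non-increasing in the
#' AT by construction.
#'
#' @param tables List of replicate [sizing_table]s (post locus screening
#'   and pull-up removal).
#' @param genotype A `reference_genotype`.
#' @param kit A [kit_config].
#' @param at_range Integer thresholds to sweep (default 1:200).
#' @param dyes Dyes to report (default: all analysis dyes).
#' @return data.frame of class `sweep_curve` with columns `dye`, `at_rfu`,
#'   `mean_dropouts`, `mean_non_allelic`.
#' @export
sweep_thresholds <- function(tables, genotype, kit, at_range = 1:200,
                             dyes = kit$analysis_dyes) {
  if (inherits(tables, "sizing_table")) tables <- list(tables)
  stopifnot(length(tables) >= 1)
  summaries <- lapply(tables, profile_summary, genotype = genotype, kit = kit)
  rows <- list()
  for (d in dyes) {
    drop_mat <- vapply(summaries, function(s) {
      h <- s$expected$max_height[s$expected$dye == d]
      vapply(at_range, function(at) sum(h < at), numeric(1))
    }, numeric(length(at_range)))
    non_mat <- vapply(summaries, function(s) {
      h <- s$artifacts$height_rfu[s$artifacts$dye == d]
      vapply(at_range, function(at) sum(h >= at), numeric(1))
    }, numeric(length(at_range)))
    drop_mat <- matrix(drop_mat, nrow = length(at_range))
    non_mat <- matrix(non_mat, nrow = length(at_range))
    rows[[d]] <- data.frame(
      dye = d, at_rfu = at_range,
      mean_dropouts = rowMeans(drop_mat),
      mean_non_allelic = rowMeans(non_mat),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sweep_curve", "data.frame")
  out
}

#' Evaluate competing threshold sets on replicate profiles
#'
#' Applies each threshold set per dye to every table, classifies against
#' the genotype with identical logic across methods, and averages the
#' counts over replicates within each (method, template, cycles) condition.
#'
#' @param threshold_sets Named list of [threshold_set]s (e.g. from
#'   [compute_all_thresholds()]).
#' @param tables List of positive-role [sizing_table]s carrying
#'   `template_pg` and `pcr_cycles` metadata.
#' @param genotype A `reference_genotype`.
#' @param kit A [kit_config].
#' @return data.frame: one row per (method, template_pg, cycles) with mean
#'   counts, `tpr`, `fpr` and `total_error`.
#' @export
compare_methods <- function(threshold_sets, tables, genotype, kit) {
  if (inherits(tables, "sizing_table")) tables <- list(tables)
  summaries <- lapply(tables, profile_summary, genotype = genotype, kit = kit)
  conds <- data.frame(
    template_pg = vapply(tables, function(t) as.numeric(attr(t, "template_pg") %||% NA), numeric(1)),
    cycles = vapply(tables, function(t) as.numeric(attr(t, "pcr_cycles") %||% NA), numeric(1))
  )
  rows <- list()
  for (m in names(threshold_sets)) {
    at <- threshold_values(threshold_sets[[m]])
    per_table <- lapply(summaries, function(s) {
      thr_exp <- at[s$expected$dye]
      thr_art <- at[s$artifacts$dye]
      n_exp <- nrow(s$expected)
      n_drop <- sum(is.na(thr_exp) | s$expected$max_height < thr_exp)
      n_non <- sum(!is.na(thr_art) & s$artifacts$height_rfu >= thr_art)
      c(n_exp = n_exp, n_drop = n_drop, n_non = n_non)
    })
    pt <- do.call(rbind, per_table)
    for (key in unique(paste(conds$template_pg, conds$cycles))) {
      idx <- paste(conds$template_pg, conds$cycles) == key
      n_exp <- mean(pt[idx, "n_exp"])
      n_drop <- mean(pt[idx, "n_drop"])
      n_non <- mean(pt[idx, "n_non"])
      tpr <- if (n_exp > 0) (n_exp - n_drop) / n_exp else NA_real_
      fpr <- if (n_exp > 0) min(1, n_non / n_exp) else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        method = m,
        template_pg = conds$template_pg[idx][1],
        cycles = conds$cycles[idx][1],
        n_replicates = sum(idx),
        n_expected_alleles = n_exp,
        mean_dropouts = n_drop,
        mean_non_allelic = n_non,
        tpr = tpr, fpr = fpr,
        total_error = (1 - tpr) + fpr,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Clean a positive profile for evaluation
#'
#' The low-template cleaning order: locus screening first, then pull-up
#' removal, where the allelic reference peaks for the pull-up criterion are
#' the records of the same injection that match the reference genotype.
#'
#' @param table A raw positive [sizing_table].
#' @param genotype A `reference_genotype`.
#' @param kit A [kit_config].
#' @param ... Passed to [remove_pullup()] (`size_tol_bp`, `height_frac`).
#' @return List: `table` (cleaned), `reports` (locus screen and pull-up
#'   [filter_report]s).
#' @export
prepare_profile <- function(table, genotype, kit, ...) {
  scr <- screen_locus_positions(table, kit)
  cls <- classify_peaks(scr$table, genotype, kit)
  rec <- as.data.frame(cls$records)
  allelic <- rec[rec$label == "allelic", , drop = FALSE]
  pu <- remove_pullup(scr$table, allelic, ...)
  list(table = pu$table, reports = list(locus_screen = scr$report,
                                        pull_up = pu$report))
}

#' ROC points and optimal method per condition
#'
#' Places each method at its (fpr, tpr) point per condition; the optimal
#' method minimises the Euclidean distance to the ideal corner (0, 1), with
#' ties broken toward the lower false-positive rate.
#'
#' @param counts data.frame from [compare_methods()] (columns `method`,
#'   `template_pg`, `cycles`, `tpr`, `fpr`).
#' @return List: `points` (the counts with a `distance` column) and `best`
#'   (one row per condition naming the selected method).
#' @export
roc_points <- function(counts) {
  counts <- as.data.frame(counts)
  counts$distance <- sqrt(counts$fpr^2 + (1 - counts$tpr)^2)
  key <- paste(counts$template_pg, counts$cycles)
  best <- lapply(unique(key), function(k) {
    sub <- counts[key == k, , drop = FALSE]
    sub <- sub[order(sub$distance, sub$fpr), , drop = FALSE]
    sub[1, , drop = FALSE]
  })
  best <- do.call(rbind, best)
  rownames(best) <- NULL
  list(points = counts, best = best)
}
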