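#' @name filtering
#' @title Signal-cleaning cascade for STR sizing tables
#' @description
#' Negative-control cleaning runs read-region filtering then ILS-proximity
#' removal; the low-template evaluation path runs locus screening then
#' pull-up removal; thresholding (`apply_threshold`) implements the AT rule
#' itself ("at and above" is inclusive). Every filter returns both the
#' retained table and a `filter_report` whose counts always reconcile
#' (input = removed + retained) and whose removed rows carry a reason tag
#' from the closed set `out_of_read_region`, `near_ILS`, `pull_up`,
#' `off_locus`, `below_AT`.
NULL

new_filter_report <- function(stage, table, keep, reason) {
  removed <- as.data.frame(table)[!keep, , drop = FALSE]
  if (nrow(removed)) removed$reason <- reason else removed$reason <- character(0)
  rownames(removed) <- NULL
  structure(
    list(stage = stage,
         n_input = nrow(table),
         n_removed = sum(!keep),
         n_retained = sum(keep),
         removed = removed),
    class = "filter_report"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Filter stage '", x$stage, "': input ", x$n_input,
      ", removed ", x$n_removed, ", retained ", x$n_retained, "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.filter_report <- function(x, ...) {
  data.frame(stage = x$stage, n_input = x$n_input,
             n_removed = x$n_removed, n_retained = x$n_retained)
}

filter_result <- function(table, keep, stage, reason) {
  list(table = st_replace_records(table, as.data.frame(table)[keep, , drop = FALSE]),
       report = new_filter_report(stage, table, keep, reason))
}

#' Remove signals outside the kit's read region
#'
#' Retains records with `min_bp <= size_bp <= max_bp` (closed interval on
#' both ends).
#'
#' @param table A [sizing_table].
#' @param kit A [kit_config].
#' @return `list(table, report)`.
#' @export
filter_read_region <- function(table, kit) {
  rr <- kit$read_region
  keep <- table$size_bp >= rr[1] & table$size_bp <= rr[2]
  filter_result(table, keep, "read_region", "out_of_read_region")
}

#' Remove signals adjacent to internal-lane-standard fragments
#'
#' Drops any record within `window_bp` bases (distance <= window, in bp) of
#' an ILS fragment, to avoid ILS pull-up contaminating the baseline; records
#' in the ILS dye itself are always removed from analysis.
#'
#' @param table A [sizing_table].
#' @param kit A [kit_config] with non-empty `ils_fragments`.
#' @param window_bp Proximity window in bp (default 2.0).
#' @return `list(table, report)`.
#' @export
filter_ils_adjacent <- function(table, kit, window_bp = 2.0) {
  stopifnot(length(kit$ils_fragments) > 0)
  mindist <- vapply(table$size_bp,
                    function(s) min(abs(s - kit$ils_fragments)), numeric(1))
  keep <- (mindist > window_bp) & (table$dye != kit$ils_dye)
  if (!nrow(table)) keep <- logical(0)
  filter_result(table, keep, "ils_adjacent", "near_ILS")
}

#' Screen signals for locus (marker) positions
#'
#' Retains records falling inside some marker interval on their own dye and
#' annotates each retained record with that marker (overwriting any prior
#' label). Off-ladder ("OL") labels do not force removal; position alone
#' decides.
#'
#' @param table A [sizing_table].
#' @param kit A [kit_config] with marker intervals.
#' @return `list(table, report)`; retained records carry the marker name.
#' @export
screen_locus_positions <- function(table, kit) {
  mk <- kit$markers
  assigned <- rep(NA_character_, nrow(table))
  for (i in seq_len(nrow(mk))) {
    hit <- table$dye == mk$dye[i] &
      table$size_bp >= mk$min_bp[i] & table$size_bp <= mk$max_bp[i]
    assigned[hit] <- mk$marker[i]
  }
  keep <- !is.na(assigned)
  res <- filter_result(table, keep, "locus_screen", "off_locus")
  res$table$marker <- assigned[keep]
  res
}

#' Remove cross-dye pull-up artifacts
#'
#' A record is removed iff some allelic peak in a *different* dye sits at
#' the same position within `size_tol_bp` and the record's height is at most
#' `height_frac` of that peak's height (both criteria inclusive). When
#' several allelic peaks qualify positionally, the tallest is used, which is
#' the most conservative removal rule.
#'
#' @param table Candidate [sizing_table].
#' @param allelic_peaks [sizing_table] (or data.frame) of allelic peaks with
#'   `dye`, `size_bp`, `height_rfu`.
#' @param size_tol_bp Positional tolerance in bp (default 0.3).
#' @param height_frac Height ratio bound (default 0.05, i.e. 5 percent).
#' @return `list(table, report)`.
#' @export
remove_pullup <- function(table, allelic_peaks, size_tol_bp = 0.3, height_frac = 0.05) {
  ap <- as.data.frame(allelic_peaks)
  is_pullup <- vapply(seq_len(nrow(table)), function(i) {
    near <- ap$dye != table$dye[i] &
      abs(ap$size_bp - table$size_bp[i]) <= size_tol_bp
    if (!any(near)) return(FALSE)
    table$height_rfu[i] <= height_frac * max(ap$height_rfu[near])
  }, logical(1))
  filter_result(table, !is_pullup, "pull_up", "pull_up")
}

#' Apply an analytical threshold to a sizing table
#'
#' Retains records with `height_rfu >= AT(dye)` -- the AT is the minimum
#' height *at and above* which peaks are kept, so the boundary is inclusive.
#'
#' @param table A [sizing_table].
#' @param thresholds A [threshold_set] covering every dye present in the
#'   table (a dye without a threshold is a configuration error).
#' @return `list(table, report)`.
#' @export
apply_threshold <- function(table, thresholds) {
  at <- threshold_values(thresholds)
  present <- unique(table$dye)
  missing <- setdiff(present, names(at))
  if (length(missing)) {
    stop("no threshold configured for dye(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  keep <- if (nrow(table)) table$height_rfu >= at[table$dye] else logical(0)
  filter_result(table, keep, "threshold", "below_AT")
}
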