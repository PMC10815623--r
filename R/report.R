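#' Height-distribution figure of negative signals per dye
#'
#' One density trace per analysis dye over the pooled negative signal
#' heights, x axis capped at `plot_x_max` RFU. With no signals at all an
#' annotated placeholder plot is returned rather than an error.
#'
#' @param heights data.frame with columns `dye`, `height_rfu` (e.g. the
#'   records of filtered negative tables).
#' @param plot_x_max Upper x limit in RFU.
#' @return A ggplot object.
#' @export
render_distribution_plot <- function(heights, plot_x_max = 100) {
  stopifnot(plot_x_max > 0)
  heights <- as.data.frame(heights)
  heights <- heights[!is.na(heights$height_rfu) &
                       heights$height_rfu <= plot_x_max, , drop = FALSE]
  if (!nrow(heights)) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = plot_x_max / 2, y = 0.5,
                               label = "no negative signals") +
             ggplot2::xlim(0, plot_x_max) +
             ggplot2::labs(x = "signal height (RFU)", y = "density") +
             ggplot2::theme_minimal())
  }
  single <- !vapply(split(heights$height_rfu, heights$dye),
                    function(h) length(unique(h)) > 1, logical(1))
  p <- ggplot2::ggplot(heights, ggplot2::aes(x = height_rfu,
                                             colour = dye, fill = dye))
  if (any(single)) {
    # degenerate (constant) groups cannot carry a density; draw a histogram
    p <- p + ggplot2::geom_histogram(position = "identity", alpha = 0.3,
                                     bins = 50)
  } else {
    p <- p + ggplot2::geom_density(alpha = 0.15)
  }
  p + ggplot2::coord_cartesian(xlim = c(0, plot_x_max)) +
    ggplot2::labs(x = "signal height (RFU)", y = "density",
                  colour = "dye", fill = "dye") +
    ggplot2::theme_minimal()
}

#' Baseline report over negative-control sizing tables
#'
#' The NegaProcess-style command-line contract as a function: read a
#' sizing-table export of any number of negative controls, filter to the
#' read region (and away from the ILS when a kit configuration is given),
#' and write an output bundle: a per-sample per-dye signal summary
#' spreadsheet, a threshold spreadsheet with the five calculated methods
#' per dye, and a height-distribution figure.
#'
#' The five user parameters of the tool are the sizing-table path, the
#' number of fluorescence channels (including the ILS channel), the two
#' ends of the recommended read region, and the x-axis maximum of the
#' figure. Without a full kit configuration the dyes are taken from the
#' file (the ILS channel, if present in the file, is the last dye label in
#' channel order) and only the read-region filter runs; with `kit` the full
#' negative-control cascade (read region, then ILS proximity) runs.
#'
#' @param sizing_table_path Path to the tab-delimited sizing table.
#' @param n_channels Number of fluorescence channels incl. ILS (>= 2).
#' @param read_region_min,read_region_max Read region in bp.
#' @param plot_x_max X-axis maximum of the distribution figure (RFU).
#' @param out_dir Output directory (created if needed).
#' @param kit Optional [kit_config]; overrides the ad hoc kit.
#' @param dialect Sizing-table dialect, see [parse_sizing_table()].
#' @param static_at Static threshold reported alongside (default 175).
#' @return Invisibly, a list: `paths` (summary_csv, thresholds_csv,
#'   plot_png), `summary`, `thresholds`, `plot`.
#' @export
run_negaprocess <- function(sizing_table_path, n_channels,
                            read_region_min, read_region_max,
                            plot_x_max = 200, out_dir = ".",
                            kit = NULL, dialect = "long", static_at = 175) {
  stopifnot(n_channels >= 2, read_region_min < read_region_max, plot_x_max > 0)
  if (!file.exists(sizing_table_path)) {
    stop("input file not found: ", sizing_table_path, call. = FALSE)
  }
  if (is.null(kit)) {
    kit <- adhoc_kit(sizing_table_path, n_channels,
                     read_region_min, read_region_max, dialect)
  }
  table <- parse_sizing_table(sizing_table_path, kit, dialect = dialect,
                              sample_role = "negative")
  if (!nrow(table)) warning("empty sizing table: reports will have zero counts",
                            call. = FALSE)
  # split into per-sample tables so the summary is per negative control
  ids <- table$sample_id
  ids[is.na(ids)] <- "sample_1"
  per_sample <- lapply(split(seq_len(nrow(table)), ids), function(idx)
    st_replace_records(table, as.data.frame(table)[idx, , drop = FALSE]))
  if (!length(per_sample)) per_sample <- list(table)

  cleaned <- lapply(per_sample, function(t) {
    t <- filter_read_region(t, kit)$table
    filter_ils_adjacent(t, kit)$table
  })

  summary_tab <- signal_summary(cleaned, kit)
  params <- threshold_params()
  sets <- compute_all_thresholds(cleaned, kit, params, static_at = static_at)
  thr_tab <- thresholds_table(sets)

  pooled <- do.call(rbind, lapply(cleaned, function(t)
    as.data.frame(t)[, c("dye", "height_rfu")]))
  plot <- render_distribution_plot(pooled, plot_x_max)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p_sum <- file.path(out_dir, "negative_signal_summary.csv")
  p_thr <- file.path(out_dir, "analytical_thresholds.csv")
  p_fig <- file.path(out_dir, "height_distribution.png")
  utils::write.csv(summary_tab, p_sum, row.names = FALSE)
  utils::write.csv(cbind(method = rownames(thr_tab), thr_tab), p_thr,
                   row.names = FALSE)
  ggplot2::ggsave(p_fig, plot, width = 7, height = 4, dpi = 150)

  invisible(list(
    paths = list(summary_csv = p_sum, thresholds_csv = p_thr, plot_png = p_fig),
    summary = summary_tab, thresholds = thr_tab, plot = plot
  ))
}

# minimal kit built from the observed dye labels when no configuration is
# supplied: the read region comes from the CLI arguments; the last observed
# dye (channel order) is treated as the ILS channel when the file carries
# n_channels distinct dyes. ILS fragment positions are unknown here, so a
# far-away pseudo fragment keeps the proximity window inert -- only the ILS
# channel itself is excluded; supply a full kit for fragment-level removal.
adhoc_kit <- function(path, n_channels, rr_min, rr_max, dialect) {
  dyes <- character(0)
  if (dialect == "long") {
    first <- utils::read.delim(path, check.names = FALSE,
                               colClasses = "character", na.strings = NULL)
    mapped <- normalize_header(names(first))
    if ("dye" %in% mapped) dyes <- unique(first[[which(mapped == "dye")[1]]])
  } else {
    dyes <- unique(sub("^#\\s*Dye=\\s*", "",
                       grep("^#\\s*Dye=", readLines(path), value = TRUE)))
  }
  if (!length(dyes)) dyes <- paste0("D", seq_len(max(2, n_channels)))
  has_ils <- length(dyes) >= n_channels
  if (!has_ils) dyes <- c(dyes, "__ILS__")
  dummy_marker <- data.frame(marker = "NONE", dye = dyes[1],
                             min_bp = rr_min, max_bp = rr_min + 1,
                             repeat_bp = 4, stringsAsFactors = FALSE)
  dummy_bins <- data.frame(marker = "NONE", allele = "1",
                           size_bp = rr_min + 0.5, stringsAsFactors = FALSE)
  kit_config("adhoc", dyes, c(rr_min, rr_max), ils_fragments = 1e6,
             markers = dummy_marker, bins = dummy_bins)
}
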