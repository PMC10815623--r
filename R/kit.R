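#' Construct an STR kit configuration
#'
#' A kit configuration declares everything the pipeline needs to know about
#' one STR multiplex: the ordered dye set (the last dye is the internal lane
#' standard, ILS), the manufacturer-recommended read region, the ILS fragment
#' sizes, and the marker geometry (per-marker size interval, repeat unit and
#' allele bin centers; bins are +/- 0.5 bp around each center).
#'
#' @param kit_name Kit identifier.
#' @param dyes Character vector of dye labels in channel order; the last
#'   entry is the ILS dye. At least two entries (one analysis dye + ILS).
#' @param read_region Numeric length-2 vector `c(min_bp, max_bp)`, closed
#'   interval in base pairs.
#' @param ils_fragments Numeric vector of ILS fragment sizes (bp); must be
#'   non-empty.
#' @param markers data.frame with columns `marker`, `dye`, `min_bp`,
#'   `max_bp`, `repeat_bp` (repeat unit length in bp).
#' @param bins data.frame with columns `marker`, `allele`, `size_bp` giving
#'   the bin center of each allele label.
#' @return An object of class `kit_config`.
#' @export
kit_config <- function(kit_name, dyes, read_region, ils_fragments, markers, bins) {
  stopifnot(is.character(dyes), length(dyes) >= 2)
  if (length(ils_fragments) == 0 || !is.numeric(ils_fragments)) {
    stop("kit configuration must declare at least one ILS fragment", call. = FALSE)
  }
  read_region <- as.numeric(read_region)
  if (length(read_region) != 2 || !(read_region[1] < read_region[2])) {
    stop("read_region must be c(min_bp, max_bp) with min < max", call. = FALSE)
  }
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  bins <- as.data.frame(bins, stringsAsFactors = FALSE)
  need_m <- c("marker", "dye", "min_bp", "max_bp", "repeat_bp")
  if (!all(need_m %in% names(markers))) {
    stop("markers table must have columns: ", paste(need_m, collapse = ", "), call. = FALSE)
  }
  need_b <- c("marker", "allele", "size_bp")
  if (!all(need_b %in% names(bins))) {
    stop("bins table must have columns: ", paste(need_b, collapse = ", "), call. = FALSE)
  }
  kit <- structure(
    list(
      kit_name = as.character(kit_name),
      dyes = dyes,
      ils_dye = dyes[length(dyes)],
      analysis_dyes = dyes[-length(dyes)],
      n_channels = length(dyes),
      read_region = read_region,
      ils_fragments = sort(as.numeric(ils_fragments)),
      markers = markers,
      bins = bins
    ),
    class = "kit_config"
  )
  validate_kit_config(kit)
  kit
}

validate_kit_config <- function(kit) {
  bad_dye <- setdiff(kit$markers$dye, kit$analysis_dyes)
  if (length(bad_dye)) {
    stop("markers declared on unknown analysis dye(s): ",
         paste(unique(bad_dye), collapse = ", "), call. = FALSE)
  }
  # marker intervals must not overlap within a dye (closed intervals)
  for (d in unique(kit$markers$dye)) {
    m <- kit$markers[kit$markers$dye == d, , drop = FALSE]
    m <- m[order(m$min_bp), , drop = FALSE]
    if (nrow(m) > 1 && any(m$min_bp[-1] <= m$max_bp[-nrow(m)])) {
      stop("overlapping marker intervals on dye ", d, call. = FALSE)
    }
  }
  orphan <- setdiff(kit$bins$marker, kit$markers$marker)
  if (length(orphan)) {
    stop("allele bins reference undeclared marker(s): ",
         paste(unique(orphan), collapse = ", "), call. = FALSE)
  }
  invisible(kit)
}

#' @export
print.kit_config <- function(x, ...) {
  cat("STR kit configuration: ", x$kit_name, "\n", sep = "")
  cat("  channels: ", x$n_channels, " (", paste(x$analysis_dyes, collapse = ", "),
      " + ILS ", x$ils_dye, ")\n", sep = "")
  cat("  read region: [", x$read_region[1], ", ", x$read_region[2], "] bp\n", sep = "")
  cat("  ILS fragments: ", length(x$ils_fragments), "\n", sep = "")
  cat("  markers: ", nrow(x$markers), " over ", length(unique(x$markers$dye)),
      " dyes; ", nrow(x$bins), " allele bins\n", sep = "")
  invisible(x)
}

#' Load a kit configuration from a YAML file
#'
#' The file declares `kit_name`, `dyes` (channel order, ILS last),
#' `read_region` (`[min, max]`), `ils_fragments`, and a `markers` list where
#' each entry has `name`, `dye`, `range` (`[min, max]`), `repeat_bp` and an
#' `alleles` map of allele label to bin center (bp).
#'
#' @param path Path to the YAML configuration.
#' @return A [kit_config] object; kit invariants are verified at load time.
#' @export
load_kit_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("kit_name", "dyes", "read_region", "ils_fragments", "markers")
  missing <- setdiff(need, names(cfg))
  if (length(missing)) {
    stop("kit configuration is missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  mk <- lapply(cfg$markers, function(m) {
    data.frame(marker = m$name, dye = m$dye,
               min_bp = m$range[[1]], max_bp = m$range[[2]],
               repeat_bp = m$repeat_bp, stringsAsFactors = FALSE)
  })
  bn <- lapply(cfg$markers, function(m) {
    data.frame(marker = m$name,
               allele = names(m$alleles),
               size_bp = as.numeric(unlist(m$alleles, use.names = FALSE)),
               stringsAsFactors = FALSE)
  })
  kit_config(
    kit_name = cfg$kit_name,
    dyes = unlist(cfg$dyes),
    read_region = unlist(cfg$read_region),
    ils_fragments = unlist(cfg$ils_fragments),
    markers = do.call(rbind, mk),
    bins = do.call(rbind, bn)
  )
}

#' Synthetic six-channel STR kit
#'
#' Builds a synthetic 6-channel kit (five analysis dyes B, G, Y, R, P plus an
#' orange ILS channel) modelled on the geometry of modern megaplex kits:
#' read region 80-480 bp, an ILS ladder every 20 bp, and `markers_per_dye`
#' tetranucleotide markers per analysis dye with alleles 5-17 on a 4 bp
#' ladder. The kit is synthetic: marker names and bin positions do not
#' correspond to any commercial product.
#'
#' @param markers_per_dye Number of markers per analysis dye (1-4).
#' @return A [kit_config].
#' @export
synth_kit <- function(markers_per_dye = 4) {
  stopifnot(markers_per_dye >= 1, markers_per_dye <= 4)
  dyes <- c("B", "G", "Y", "R", "P", "O")
  lo <- c(90, 155, 230, 300)[seq_len(markers_per_dye)]
  mk <- list()
  bn <- list()
  for (d in dyes[-length(dyes)]) {
    for (i in seq_along(lo)) {
      name <- paste0("M_", d, i)
      mk[[name]] <- data.frame(marker = name, dye = d,
                               min_bp = lo[i], max_bp = lo[i] + 54,
                               repeat_bp = 4, stringsAsFactors = FALSE)
      alleles <- 5:17
      bn[[name]] <- data.frame(marker = name,
                               allele = as.character(alleles),
                               size_bp = lo[i] + 3 + 4 * (alleles - 5),
                               stringsAsFactors = FALSE)
    }
  }
  kit_config(
    kit_name = "SynthPlex-24",
    dyes = dyes,
    read_region = c(80, 480),
    ils_fragments = seq(80, 480, by = 20),
    markers = do.call(rbind, mk),
    bins = do.call(rbind, bn)
  )
}

#' Synthetic single-source reference genotype for the synthetic kit
#'
#' A fixed single-contributor genotype over the markers of [synth_kit()],
#' mixing heterozygous and homozygous loci. Synthetic stand-in for a typed
#' control DNA; it matches no real reference material.
#'
#' @param kit A [kit_config] built by [synth_kit()] (or with the same
#'   marker/allele naming).
#' @return A `reference_genotype`: named list of 1- or 2-element character
#'   vectors of expected allele labels.
#' @export
synth_genotype <- function(kit = synth_kit()) {
  markers <- kit$markers$marker
  gt <- vector("list", length(markers))
  names(gt) <- markers
  for (i in seq_along(markers)) {
    if (i %% 3 == 0) {
      gt[[i]] <- as.character(7 + (i %% 5))            # homozygote
    } else {
      a <- 6 + (i %% 4)
      gt[[i]] <- as.character(c(a, a + 3 + (i %% 3)))  # heterozygote
    }
  }
  new_reference_genotype(gt, kit)
}

new_reference_genotype <- function(gt, kit) {
  bad_n <- vapply(gt, function(a) length(a) < 1 || length(a) > 2, logical(1))
  if (any(bad_n)) {
    stop("each marker must carry 1 or 2 expected alleles; offending: ",
         paste(names(gt)[bad_n], collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(gt), kit$markers$marker)
  if (length(unknown)) {
    stop("genotype references marker(s) absent from kit: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (m in names(gt)) {
    kb <- kit$bins$allele[kit$bins$marker == m]
    miss <- setdiff(gt[[m]], kb)
    if (length(miss)) {
      stop("allele label(s) without a bin at ", m, ": ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  structure(gt, class = "reference_genotype")
}

#' @export
print.reference_genotype <- function(x, ...) {
  cat("Reference genotype over", length(x), "markers\n")
  for (m in names(x)) cat("  ", m, ": ", paste(x[[m]], collapse = "/"), "\n", sep = "")
  invisible(x)
}

# expected alleles as a long table: one row per expected allele copy is NOT
# used -- homozygous markers contribute a single expected allele (presence/
# absence scoring only)
expected_allele_table <- function(genotype, kit, dyes = NULL) {
  rows <- lapply(names(genotype), function(m) {
    d <- kit$markers$dye[match(m, kit$markers$marker)]
    al <- unique(genotype[[m]])
    centers <- kit$bins$size_bp[match(paste(m, al), paste(kit$bins$marker, kit$bins$allele))]
    data.frame(marker = m, dye = d, allele = al, center_bp = centers,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(dyes)) out <- out[out$dye %in% dyes, , drop = FALSE]
  rownames(out) <- NULL
  out
}
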