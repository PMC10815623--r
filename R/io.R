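#' Sizing-table container
#'
#' A sizing table is the per-peak export of a genotyping run: one row per
#' detected signal with its dye, size (bp), height (RFU), area and scan data
#' point, plus optional marker/allele labels. Run-level metadata (lab, kit,
#' run date, PCR cycle number, sample role) travels as attributes.
#'
#' @param records data.frame with columns `sample_id`, `dye`, `marker`,
#'   `allele`, `size_bp`, `height_rfu`, `area`, `data_point`.
#' @param lab_id,kit_id,run_date,pcr_cycles,sample_role Run metadata.
#'   `run_date` is coerced with [as.Date()]; `sample_role` is one of
#'   `"negative"`, `"positive"`, `"ladder"`.
#' @param ... Further metadata attributes (e.g. `template_pg`).
#' @return An object of class `sizing_table` (a data.frame).
#' @export
sizing_table <- function(records,
                         lab_id = NA_character_, kit_id = NA_character_,
                         run_date = NA, pcr_cycles = NA_integer_,
                         sample_role = c("negative", "positive", "ladder"),
                         ...) {
  sample_role <- match.arg(sample_role)
  cols <- c("sample_id", "dye", "marker", "allele",
            "size_bp", "height_rfu", "area", "data_point")
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (nm in setdiff(cols, names(records))) {
    records[[nm]] <- rep(if (nm %in% c("size_bp", "height_rfu", "area")) NA_real_
                         else if (nm == "data_point") NA_integer_
                         else NA_character_, nrow(records))
  }
  records <- records[, cols, drop = FALSE]
  rownames(records) <- NULL
  st <- structure(records,
                  class = c("sizing_table", "data.frame"),
                  lab_id = lab_id, kit_id = kit_id,
                  run_date = if (all(is.na(run_date))) as.Date(NA) else as.Date(run_date),
                  pcr_cycles = pcr_cycles, sample_role = sample_role)
  extra <- list(...)
  for (nm in names(extra)) attr(st, nm) <- extra[[nm]]
  st
}

#' Run metadata of a sizing table
#' @param table A `sizing_table`.
#' @return Named list of metadata attributes.
#' @export
table_meta <- function(table) {
  keep <- setdiff(names(attributes(table)), c("names", "row.names", "class"))
  attributes(table)[keep]
}

# replace the record rows of a sizing_table, preserving metadata attributes
st_replace_records <- function(table, records) {
  meta <- attributes(table)
  keep <- setdiff(names(meta), c("names", "row.names", "class", "rejected"))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  rownames(records) <- NULL
  out <- structure(records, class = c("sizing_table", "data.frame"))
  for (nm in keep) attr(out, nm) <- meta[[nm]]
  out
}

#' @export
print.sizing_table <- function(x, ...) {
  cat("Sizing table: ", nrow(x), " signal(s); role=", attr(x, "sample_role"),
      " lab=", attr(x, "lab_id"), " cycles=", attr(x, "pcr_cycles"),
      " date=", format(attr(x, "run_date")), "\n", sep = "")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

# header aliases: GeneMapper-ish column names mapped to the canonical schema
.col_aliases <- c(
  "sample" = "sample_id", "sample file" = "sample_id", "sample name" = "sample_id",
  "sample_id" = "sample_id",
  "dye" = "dye", "dye/sample peak" = "dye",
  "marker" = "marker", "allele" = "allele",
  "size" = "size_bp", "size_bp" = "size_bp",
  "height" = "height_rfu", "height_rfu" = "height_rfu",
  "area" = "area",
  "data point" = "data_point", "datapoint" = "data_point", "data_point" = "data_point"
)

normalize_header <- function(h) {
  key <- tolower(gsub("[._]+", " ", trimws(h)))
  key <- gsub("\\s+", " ", key)
  unname(.col_aliases[key])
}

#' Parse a tab-delimited sizing-table export
#'
#' Reads a GeneMapper-style "Sizing Table" export into a [sizing_table].
#' Two dialects are supported: `"long"` (one table with a dye column) and
#' `"blocks"` (per-dye blocks introduced by `# Dye=<label>` lines, each with
#' its own header, as produced by per-dye exports). Rows whose size or
#' height do not parse as numbers (or violate size > 0 / height >= 0) are
#' rejected and reported via a warning and the `"rejected"` attribute --
#' never silently dropped.
#'
#' @param path Path to the tab-delimited file.
#' @param kit A [kit_config]; every dye label in the file must belong to it.
#' @param dialect `"long"` or `"blocks"`.
#' @param ... Metadata passed to [sizing_table()] (`lab_id`, `run_date`,
#'   `pcr_cycles`, `sample_role`, ...).
#' @return A [sizing_table]; rejected rows (if any) are in
#'   `attr(x, "rejected")` as a data.frame of raw fields.
#' @export
parse_sizing_table <- function(path, kit, dialect = c("long", "blocks"), ...) {
  dialect <- match.arg(dialect)
  if (dialect == "long") {
    raw <- utils::read.delim(path, check.names = FALSE,
                             colClasses = "character", na.strings = NULL)
    df <- canonicalize_columns(raw, require_dye = TRUE)
  } else {
    lines <- readLines(path)
    hdr_idx <- grep("^#\\s*Dye=", lines)
    if (!length(hdr_idx)) stop("blocks dialect: no '# Dye=' block headers found", call. = FALSE)
    ends <- c(hdr_idx[-1] - 1, length(lines))
    chunks <- Map(function(i, e) {
      dye <- sub("^#\\s*Dye=\\s*", "", lines[i])
      body <- lines[(i + 1):e]
      body <- body[nzchar(trimws(body))]
      if (length(body) < 1) return(NULL)
      raw <- utils::read.delim(text = paste(body, collapse = "\n"),
                               check.names = FALSE, colClasses = "character",
                               na.strings = NULL)
      if (nrow(raw) == 0) return(NULL)
      raw$Dye <- dye
      canonicalize_columns(raw, require_dye = TRUE)
    }, hdr_idx, ends)
    chunks <- Filter(Negate(is.null), chunks)
    df <- if (length(chunks)) do.call(rbind, chunks) else
      canonicalize_columns(utils::read.delim(text = "Dye\tMarker\tAllele\tSize\tHeight\tArea\tData Point",
                                             check.names = FALSE, colClasses = "character"),
                           require_dye = TRUE)
  }

  if (nrow(df)) {
    bad_dye <- setdiff(unique(df$dye), kit$dyes)
    if (length(bad_dye)) {
      stop("dye label(s) absent from kit '", kit$kit_name, "': ",
           paste(bad_dye, collapse = ", "), call. = FALSE)
    }
  }

  num <- function(x) suppressWarnings(as.numeric(x))
  size <- num(df$size_bp); height <- num(df$height_rfu)
  area <- num(df$area); dp <- num(df$data_point)
  bad <- is.na(size) | is.na(height) | size <= 0 | height < 0
  rejected <- df[bad, , drop = FALSE]
  ok <- df[!bad, , drop = FALSE]
  ok$size_bp <- size[!bad]; ok$height_rfu <- height[!bad]
  ok$area <- area[!bad]; ok$data_point <- dp[!bad]

  st <- sizing_table(ok, ...)
  if (nrow(rejected)) {
    warning(nrow(rejected), " row(s) rejected (unparseable size/height); ",
            "see attr(x, 'rejected')", call. = FALSE)
    attr(st, "rejected") <- rejected
  }
  st
}

canonicalize_columns <- function(raw, require_dye = TRUE) {
  mapped <- normalize_header(names(raw))
  keep <- !is.na(mapped) & !duplicated(mapped)
  raw <- raw[, keep, drop = FALSE]
  names(raw) <- mapped[keep]
  mandatory <- c("marker", "allele", "size_bp", "height_rfu", "area", "data_point")
  if (require_dye) mandatory <- c("dye", mandatory)
  missing <- setdiff(mandatory, names(raw))
  if (length(missing)) {
    stop("sizing table is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"sample_id" %in% names(raw)) raw$sample_id <- NA_character_
  raw[, c("sample_id", "dye", "marker", "allele",
          "size_bp", "height_rfu", "area", "data_point"), drop = FALSE]
}

#' Write a sizing table in a parseable dialect
#'
#' Inverse of [parse_sizing_table()]: the written file re-parses to the same
#' records (field-by-field), enabling GeneMapper-free round trips of
#' filtered tables.
#'
#' @param table A [sizing_table].
#' @param path Output path.
#' @param dialect `"long"` or `"blocks"`.
#' @return `path`, invisibly.
#' @export
write_sizing_table <- function(table, path, dialect = c("long", "blocks")) {
  dialect <- match.arg(dialect)
  df <- as.data.frame(table)
  fmt <- function(x) {
    out <- vapply(x, function(v) {
      if (is.na(v)) "" else format(v, digits = 15, scientific = FALSE, trim = TRUE)
    }, character(1))
    out
  }
  out <- data.frame(
    Sample = ifelse(is.na(df$sample_id), "", df$sample_id),
    Dye = df$dye,
    Marker = ifelse(is.na(df$marker), "", df$marker),
    Allele = ifelse(is.na(df$allele), "", df$allele),
    Size = fmt(df$size_bp), Height = fmt(df$height_rfu),
    Area = fmt(df$area), `Data Point` = fmt(df$data_point),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  if (dialect == "long") {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (d in unique(out$Dye)) {
      writeLines(paste0("# Dye=", d), con)
      sub <- out[out$Dye == d, setdiff(names(out), "Dye"), drop = FALSE]
      utils::write.table(sub, con, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!nrow(out)) {
      writeLines("# Dye=NONE", con)
      writeLines(paste(c("Sample", "Marker", "Allele", "Size", "Height", "Area", "Data Point"),
                       collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Parse a reference genotype file
#'
#' Two-column comma-separated text: marker name, then expected allele labels
#' separated by `/` (a single label denotes a homozygote).
#'
#' @param path Path to the genotype file.
#' @param kit A [kit_config]; every marker and allele label must exist in it.
#' @return A `reference_genotype` (named list of allele-label vectors).
#' @export
parse_genotype <- function(path, kit) {
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
                         strip.white = TRUE)
  if (ncol(raw) < 2) stop("genotype file must have two columns: marker, alleles", call. = FALSE)
  gt <- lapply(raw[[2]], function(a) unique(trimws(strsplit(a, "/", fixed = TRUE)[[1]])))
  names(gt) <- trimws(raw[[1]])
  too_many <- vapply(gt, length, integer(1)) > 2
  if (any(too_many)) {
    stop("more than 2 alleles at marker(s): ",
         paste(names(gt)[too_many], collapse = ", "), call. = FALSE)
  }
  new_reference_genotype(gt, kit)
}
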