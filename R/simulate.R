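#' Configuration of the synthetic electropherogram generator
#'
#' The generator emulates the statistical structure of capillary
#' electrophoresis sizing tables, not raw traces:
#' \itemize{
#'   \item Baseline noise per analysis dye: a Poisson(`rate`) number of
#'     signals per injection, sizes uniform on the kit read region, heights
#'     lognormal(`log_mean`, `log_sd`^2). The per-dye defaults give the
#'     blue channel the lowest mean height, mirroring the consistent
#'     ordering seen across commercial kits.
#'   \item Allelic peaks: mean height `h0` RFU at reference template `t0`
#'     pg and `ref_cycles` PCR cycles; height scales linearly with template
#'     and doubles per extra cycle, with multiplicative lognormal noise
#'     (`sigma_peak` on the log scale). Homozygous alleles carry twice the
#'     template. A peak is emitted only if its drawn height is at least
#'     `min_rfu`.
#'   \item Noise amplification: extra cycles also lift the baseline; the
#'     per-dye log-mean grows by `noise_cycle_coef` per cycle above
#'     `ref_cycles`.
#'   \item Stutter: one peak per allelic peak at the n-1 repeat position,
#'     height ratio Normal(`stutter_mean`, `stutter_sd`) truncated at 0.
#'   \item Pull-up: with probability `pullup_prob` per allelic peak, a peak
#'     in a random other dye at +/- U(0, 0.3) bp and U(1, 5) percent of the
#'     parent height.
#' }
#'
#' @param kit A [kit_config] (defines the analysis dyes).
#' @param noise data.frame `dye`, `log_mean`, `log_sd`, `rate`; default:
#'   built-in per-dye values on ~10 signals per injection.
#' @param h0,t0,ref_cycles Allelic height anchor (RFU at `t0` pg,
#'   `ref_cycles` cycles).
#' @param sigma_peak SD of the log height of allelic peaks.
#' @param noise_cycle_coef Baseline log-mean increase per PCR cycle above
#'   `ref_cycles`.
#' @param stutter_mean,stutter_sd Stutter ratio model.
#' @param pullup_prob Per-peak pull-up probability.
#' @param min_rfu Detection floor in RFU (peaks below it are not emitted).
#' @param ils_height Height of ILS fragments in the ILS channel.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(kit = synth_kit(),
                              noise = NULL,
                              h0 = 48, t0 = 31.25, ref_cycles = 27,
                              sigma_peak = 0.5,
                              noise_cycle_coef = 0.05,
                              stutter_mean = 0.08, stutter_sd = 0.03,
                              pullup_prob = 0.05,
                              min_rfu = 1,
                              ils_height = 3000) {
  if (is.null(noise)) {
    defaults <- data.frame(
      dye = c("B", "G", "Y", "R", "P"),
      log_mean = c(2.00, 2.35, 2.05, 2.30, 2.40),
      log_sd = c(0.30, 0.33, 0.30, 0.32, 0.33),
      rate = rep(10, 5),
      stringsAsFactors = FALSE
    )
    dyes <- kit$analysis_dyes
    noise <- defaults[((seq_along(dyes) - 1) %% nrow(defaults)) + 1, , drop = FALSE]
    noise$dye <- dyes
    rownames(noise) <- NULL
  }
  stopifnot(all(c("dye", "log_mean", "log_sd", "rate") %in% names(noise)),
            all(noise$rate >= 0), all(noise$log_sd > 0),
            h0 > 0, t0 > 0, sigma_peak >= 0, pullup_prob >= 0, pullup_prob <= 1,
            stutter_sd >= 0, min_rfu >= 0)
  structure(list(noise = noise, h0 = h0, t0 = t0, ref_cycles = ref_cycles,
                 sigma_peak = sigma_peak, noise_cycle_coef = noise_cycle_coef,
                 stutter_mean = stutter_mean, stutter_sd = stutter_sd,
                 pullup_prob = pullup_prob, min_rfu = min_rfu,
                 ils_height = ils_height),
            class = "simulation_config")
}

# deterministic sub-seed for table i of a study seeded with `seed`
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)
}

noise_records <- function(config, kit, cycles) {
  shift <- config$noise_cycle_coef * (cycles - config$ref_cycles)
  rows <- list()
  for (i in seq_len(nrow(config$noise))) {
    nd <- config$noise[i, ]
    n <- stats::rpois(1, nd$rate)
    if (n == 0) next
    rows[[length(rows) + 1]] <- data.frame(
      dye = nd$dye,
      size_bp = stats::runif(n, kit$read_region[1], kit$read_region[2]),
      height_rfu = stats::rlnorm(n, nd$log_mean + shift, nd$log_sd),
      stringsAsFactors = FALSE
    )
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(dye = character(0), size_bp = numeric(0), height_rfu = numeric(0))
}

ils_records <- function(config, kit) {
  if (config$ils_height <= 0) {
    return(data.frame(dye = character(0), size_bp = numeric(0),
                      height_rfu = numeric(0)))
  }
  data.frame(
    dye = kit$ils_dye,
    size_bp = kit$ils_fragments,
    height_rfu = config$ils_height * stats::rlnorm(length(kit$ils_fragments), 0, 0.05),
    stringsAsFactors = FALSE
  )
}

finalize_table <- function(records, sample_id, kit, ...) {
  if (nrow(records)) {
    records$sample_id <- sample_id
    records$marker <- NA_character_
    records$allele <- NA_character_
    records$area <- round(records$height_rfu * 5)
    records$data_point <- as.integer(round(records$size_bp * 10 + 1000))
    records <- records[order(records$dye, records$size_bp), , drop = FALSE]
  }
  sizing_table(records, kit_id = kit$kit_name, ...)
}

#' Simulate a negative-control sizing table
#'
#' Baseline noise only (plus the ILS ladder in the ILS channel): per-dye
#' Poisson signal counts, uniform sizes on the read region, lognormal
#' heights. Reproducible given the seed.
#'
#' @param config A [simulation_config()].
#' @param kit A [kit_config].
#' @param seed Integer seed.
#' @param cycles PCR cycle number (shifts the baseline per the config).
#' @param lab_id,run_date,sample_id Metadata for the emitted table.
#' @return A [sizing_table] with `sample_role = "negative"`.
#' @export
simulate_negative <- function(config, kit, seed, cycles = 27,
                              lab_id = "SIM", run_date = as.Date("2023-01-15"),
                              sample_id = paste0("NEG_", seed)) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rec <- rbind(noise_records(config, kit, cycles), ils_records(config, kit))
  finalize_table(rec, sample_id, kit, lab_id = lab_id, run_date = run_date,
                 pcr_cycles = cycles, sample_role = "negative")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Simulate a low-template positive sizing table
#'
#' Emits allelic peaks at the genotype's bin centers with the
#' template/cycle-dependent height model, then stutter and pull-up
#' artifacts, superimposed on baseline noise and the ILS ladder.
#'
#' @param config A [simulation_config()].
#' @param kit A [kit_config].
#' @param genotype A `reference_genotype` over the kit's markers.
#' @param template_pg DNA input in pg (> 0).
#' @param cycles PCR cycle number (27, 29 and 31 are the study conditions;
#'   other values are allowed with a warning).
#' @param seed Integer seed.
#' @param artifacts Emit stutter/pull-up artifacts (default TRUE).
#' @param baseline Superimpose baseline noise (default TRUE).
#' @param lab_id,run_date,sample_id Metadata.
#' @return A [sizing_table] with `sample_role = "positive"` and
#'   `template_pg` metadata.
#' @export
simulate_positive <- function(config, kit, genotype, template_pg, cycles, seed,
                              artifacts = TRUE, baseline = TRUE,
                              lab_id = "SIM", run_date = as.Date("2023-01-15"),
                              sample_id = paste0("POS_", seed)) {
  stopifnot(template_pg > 0)
  if (!cycles %in% c(27, 29, 31)) {
    warning("cycle number ", cycles, " is outside the study design (27/29/31)",
            call. = FALSE)
  }
  exp_tab <- expected_allele_table(genotype, kit)  # validates genotype vs kit
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  gain <- (template_pg / config$t0) * 2^(cycles - config$ref_cycles)
  rows <- list()
  for (j in seq_len(nrow(exp_tab))) {
    m <- exp_tab$marker[j]
    copies <- if (length(genotype[[m]]) == 1) 2 else 1  # homozygote: both copies in one bin
    mu <- log(config$h0 * gain * copies)
    h <- stats::rlnorm(1, mu, config$sigma_peak)
    if (h < config$min_rfu) next
    size <- exp_tab$center_bp[j] + stats::rnorm(1, 0, 0.05)
    rows[[length(rows) + 1]] <- data.frame(
      dye = exp_tab$dye[j], size_bp = size, height_rfu = h,
      stringsAsFactors = FALSE)
    if (artifacts) {
      rep_bp <- kit$markers$repeat_bp[match(m, kit$markers$marker)]
      ratio <- max(0, stats::rnorm(1, config$stutter_mean, config$stutter_sd))
      sh <- h * ratio
      if (sh >= config$min_rfu) {
        rows[[length(rows) + 1]] <- data.frame(
          dye = exp_tab$dye[j], size_bp = size - rep_bp, height_rfu = sh,
          stringsAsFactors = FALSE)
      }
      if (stats::runif(1) < config$pullup_prob && length(kit$analysis_dyes) > 1) {
        other <- sample(setdiff(kit$analysis_dyes, exp_tab$dye[j]), 1)
        ph <- h * stats::runif(1, 0.01, 0.05)
        if (ph >= config$min_rfu) {
          rows[[length(rows) + 1]] <- data.frame(
            dye = other,
            size_bp = size + sample(c(-1, 1), 1) * stats::runif(1, 0, 0.3),
            height_rfu = ph, stringsAsFactors = FALSE)
        }
      }
    }
  }
  rec <- if (length(rows)) do.call(rbind, rows) else
    data.frame(dye = character(0), size_bp = numeric(0), height_rfu = numeric(0))
  if (baseline) rec <- rbind(rec, noise_records(config, kit, cycles))
  rec <- rbind(rec, ils_records(config, kit))
  finalize_table(rec, sample_id, kit, lab_id = lab_id, run_date = run_date,
                 pcr_cycles = cycles, sample_role = "positive",
                 template_pg = template_pg)
}

#' Generate the full low-template study design
#'
#' The full factorial of the low-template experiment: 3 template amounts
#' (31.25, 15.625, 7.8125 pg) x 3 cycle numbers (27, 29, 31) x 3 PCR
#' replicates x 3 electrophoresis replicates of the positive control, plus
#' 9 negative controls per cycle number (3 PCR x 3 CE) -- 81 positive and
#' 27 negative tables. Each table draws from its own derived sub-seed, so
#' any single table can be regenerated independently; regeneration with the
#' same study seed is byte-identical.
#'
#' @param config A [simulation_config()].
#' @param kit A [kit_config].
#' @param genotype A `reference_genotype`.
#' @param seed Integer study seed.
#' @param templates_pg Template series in pg.
#' @param cycle_numbers PCR cycle series.
#' @param n_pcr,n_ce Replicate counts.
#' @return List with `tables` (list of [sizing_table]s) and `manifest`
#'   (data.frame: one row per table with its condition).
#' @export
generate_study <- function(config, kit, genotype, seed,
                           templates_pg = c(31.25, 15.625, 7.8125),
                           cycle_numbers = c(27, 29, 31),
                           n_pcr = 3, n_ce = 3) {
  tables <- list()
  manifest <- list()
  i <- 0
  for (cyc in cycle_numbers) {
    for (tpl in templates_pg) {
      for (p in seq_len(n_pcr)) {
        for (ce in seq_len(n_ce)) {
          i <- i + 1
          sid <- sprintf("POS_t%g_c%d_p%d_e%d", tpl, cyc, p, ce)
          tables[[sid]] <- simulate_positive(
            config, kit, genotype, template_pg = tpl, cycles = cyc,
            seed = derive_seed(seed, i), sample_id = sid)
          manifest[[i]] <- data.frame(sample_id = sid, role = "positive",
                                      template_pg = tpl, cycles = cyc,
                                      pcr_rep = p, ce_rep = ce,
                                      stringsAsFactors = FALSE)
        }
      }
    }
    for (p in seq_len(n_pcr)) {
      for (ce in seq_len(n_ce)) {
        i <- i + 1
        sid <- sprintf("NEG_c%d_p%d_e%d", cyc, p, ce)
        tables[[sid]] <- simulate_negative(
          config, kit, seed = derive_seed(seed, i), cycles = cyc,
          sample_id = sid)
        manifest[[i]] <- data.frame(sample_id = sid, role = "negative",
                                    template_pg = NA_real_, cycles = cyc,
                                    pcr_rep = p, ce_rep = ce,
                                    stringsAsFactors = FALSE)
      }
    }
  }
  list(tables = tables, manifest = do.call(rbind, manifest))
}
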