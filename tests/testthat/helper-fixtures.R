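# shared fixtures, all built in code

mini_kit <- function() {
  kit_config(
    kit_name = "TestKit",
    dyes = c("B", "G", "O"),
    read_region = c(80, 480),
    ils_fragments = c(80, 120, 160, 200, 240, 280, 320, 360, 400, 440, 480),
    markers = data.frame(
      marker = c("M1", "M2", "M3"),
      dye = c("B", "B", "G"),
      min_bp = c(100, 150, 100),
      max_bp = c(140, 190, 140),
      repeat_bp = 4,
      stringsAsFactors = FALSE
    ),
    bins = rbind(
      data.frame(marker = "M1", allele = as.character(8:13),
                 size_bp = 103 + 4 * (0:5)),
      data.frame(marker = "M2", allele = as.character(6:10),
                 size_bp = 153 + 4 * (0:4)),
      data.frame(marker = "M3", allele = as.character(8:12),
                 size_bp = 104 + 4 * (0:4))
    )
  )
}

mini_genotype <- function(kit = mini_kit()) {
  strbaseline:::new_reference_genotype(
    list(M1 = c("10", "12"), M2 = "8", M3 = c("9", "11")), kit)
}

# bare records table from parallel vectors
make_records <- function(dye, size, height, marker = NA_character_,
                         allele = NA_character_, sample_id = "S1") {
  n <- length(dye)
  data.frame(sample_id = rep_len(sample_id, n), dye = dye,
             marker = rep_len(marker, n), allele = rep_len(allele, n),
             size_bp = size, height_rfu = height,
             area = height * 5, data_point = round(size * 10),
             stringsAsFactors = FALSE)
}

make_table <- function(dye, size, height, sample_id = "S1", ...) {
  sizing_table(make_records(dye, size, height, sample_id = sample_id), ...)
}

# negative tables already passed through the negative-control cascade
clean_negatives <- function(n, kit, cfg, seed0 = 100, cycles = 27) {
  lapply(seq_len(n), function(i) {
    t <- simulate_negative(cfg, kit, seed = seed0 + i, cycles = cycles)
    t <- filter_read_region(t, kit)$table
    filter_ils_adjacent(t, kit)$table
  })
}
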