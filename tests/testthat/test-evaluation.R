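# positive-profile records at given (marker, allele) bins of the mini kit
peaks_at <- function(kit, marker, allele, height, dye = NULL, offset = 0) {
  centers <- kit$bins$size_bp[match(paste(marker, allele),
                                    paste(kit$bins$marker, kit$bins$allele))]
  d <- kit$markers$dye[match(marker, kit$markers$marker)]
  make_records(d, centers + offset, height, marker = marker, allele = allele)
}

test_that("peak classification labels alleles, artifacts and dropouts", {
  kit <- mini_kit(); gt <- mini_genotype(kit)
  # full profile: M1 10/12, M2 8, M3 9/11
  rec <- rbind(peaks_at(kit, c("M1", "M1"), c("10", "12"), c(100, 90)),
               peaks_at(kit, "M2", "8", 120),
               peaks_at(kit, c("M3", "M3"), c("9", "11"), c(80, 85)))
  cls <- classify_peaks(sizing_table(rec, sample_role = "positive"), gt, kit)
  expect_equal(sum(cls$records$label == "allelic"), 5)
  expect_equal(nrow(cls$dropouts), 0)

  # missing one expected allele -> 1 dropout
  cls2 <- classify_peaks(sizing_table(rec[-1, ], sample_role = "positive"), gt, kit)
  expect_equal(nrow(cls2$dropouts), 1)
  expect_equal(cls2$dropouts$allele, "10")

  # a stutter-position peak (M1 bin 11) is non-allelic
  rec3 <- rbind(rec, peaks_at(kit, "M1", "11", 12))
  cls3 <- classify_peaks(sizing_table(rec3, sample_role = "positive"), gt, kit)
  expect_equal(sum(cls3$records$label == "allelic"), 5)
  expect_equal(sum(cls3$records$label == "non_allelic"), 1)

  # peaks at markers outside the genotype are a contract violation
  gt_partial <- strbaseline:::new_reference_genotype(list(M1 = c("10", "12")), kit)
  expect_error(classify_peaks(sizing_table(rec, sample_role = "positive"),
                              gt_partial, kit), "M2|M3")
})

test_that("classification agrees with a brute-force matcher on random fixtures", {
  kit <- mini_kit(); gt <- mini_genotype(kit)
  exp_tab <- strbaseline:::expected_allele_table(gt, kit)
  set.seed(17)
  for (rep in 1:5) {
    n <- sample(20:100, 1)
    mk <- sample(kit$markers$marker, n, TRUE)
    d <- kit$markers$dye[match(mk, kit$markers$marker)]
    lo <- kit$markers$min_bp[match(mk, kit$markers$marker)]
    sizes <- lo + runif(n, 0, 40)
    st <- sizing_table(make_records(d, sizes, runif(n, 5, 200), marker = mk),
                       sample_role = "positive")
    cls <- classify_peaks(st, gt, kit)
    brute <- vapply(seq_len(n), function(i) {
      any(exp_tab$marker == mk[i] & abs(exp_tab$center_bp - sizes[i]) <= 0.5)
    }, logical(1))
    expect_equal(cls$records$label == "allelic", brute)
    brute_drop <- vapply(seq_len(nrow(exp_tab)), function(j) {
      !any(mk == exp_tab$marker[j] &
             abs(sizes - exp_tab$center_bp[j]) <= 0.5)
    }, logical(1))
    expect_equal(nrow(cls$dropouts), sum(brute_drop))
  }
})

test_that("event counts reconcile and cover the boundary profiles", {
  kit <- mini_kit(); gt <- mini_genotype(kit)
  rec <- rbind(peaks_at(kit, c("M1", "M1"), c("10", "12"), c(100, 90)),
               peaks_at(kit, "M2", "8", 120),
               peaks_at(kit, c("M3", "M3"), c("9", "11"), c(80, 85)))
  full <- count_events(classify_peaks(sizing_table(rec, sample_role = "positive"),
                                      gt, kit))
  expect_equal(full$n_dropouts, 0)
  expect_equal(full$n_non_allelic, 0)
  expect_equal(full$tpr, 1); expect_equal(full$fpr, 0)
  expect_equal(total_error(full), 0)

  empty <- count_events(classify_peaks(
    sizing_table(make_records(character(0), numeric(0), numeric(0)),
                 sample_role = "positive"), gt, kit))
  expect_equal(empty$n_dropouts, 5)      # 5 expected alleles in mini genotype
  expect_equal(empty$tpr, 0)
  expect_equal(total_error(empty), 1.0)  # complete dropout, no artifacts

  # homozygous markers contribute one expected allele
  expect_equal(full$n_expected_alleles, 5)
  expect_equal(full$n_dropouts + full$n_true_alleles_detected,
               full$n_expected_alleles)

  # hand tally on a mixed profile: drop M3:11, add 2 artifacts in B
  rec2 <- rbind(peaks_at(kit, c("M1", "M1"), c("10", "12"), c(100, 90)),
                peaks_at(kit, "M2", "8", 120),
                peaks_at(kit, "M3", "9", 80),
                peaks_at(kit, c("M1", "M2"), c("9", "7"), c(15, 11)))
  mixed <- count_events(classify_peaks(sizing_table(rec2, sample_role = "positive"),
                                       gt, kit))
  expect_equal(mixed$n_dropouts, 1)
  expect_equal(mixed$n_non_allelic, 2)
  expect_equal(mixed$tpr, 4 / 5)
  expect_equal(mixed$fpr, 2 / 5)
  expect_equal(total_error(mixed), 0.2 + 0.4)
  b_only <- count_events(classify_peaks(sizing_table(rec2, sample_role = "positive"),
                                        gt, kit), dye = "B")
  expect_equal(b_only$n_expected_alleles, 3)
  expect_equal(b_only$n_non_allelic, 2)
})

test_that("threshold sweeps step exactly at the true-allele heights", {
  kit <- mini_kit(); gt <- mini_genotype(kit)
  heights <- c(20, 40, 60, 80, 100)  # one per expected allele, known ladder
  rec <- rbind(peaks_at(kit, c("M1", "M1"), c("10", "12"), heights[1:2]),
               peaks_at(kit, "M2", "8", heights[3]),
               peaks_at(kit, c("M3", "M3"), c("9", "11"), heights[4:5]))
  st <- sizing_table(rec, sample_role = "positive")
  sw <- sweep_thresholds(list(st), gt, kit, at_range = 1:150)
  pooled <- tapply(sw$mean_dropouts, sw$at_rfu, sum)
  # dropouts jump at h+1 for each allele height h
  for (h in heights) {
    expect_equal(unname(pooled[as.character(h)] - pooled[as.character(h + 1)]), -1)
  }
  expect_equal(unname(pooled["1"]), 0)
  expect_equal(unname(pooled["150"]), 5)

  # all heights above the sweep -> flat zero dropout curve
  rec_hi <- rbind(peaks_at(kit, c("M1", "M1"), c("10", "12"), c(300, 400)),
                  peaks_at(kit, "M2", "8", 500),
                  peaks_at(kit, c("M3", "M3"), c("9", "11"), c(600, 700)))
  sw_hi <- sweep_thresholds(list(sizing_table(rec_hi, sample_role = "positive")),
                            gt, kit, at_range = seq(1, 200, 10))
  expect_true(all(sw_hi$mean_dropouts == 0))
})

test_that("sweep curves are monotone and flatten at the raw-data dropout floor", {
  kit <- mini_kit(); gt <- mini_genotype(kit)
  cfg <- simulation_config(kit)
  tabs <- lapply(1:3, function(i) {
    t <- simulate_positive(cfg, kit, gt, template_pg = 15.625, cycles = 27,
                           seed = 300 + i)
    prepare_profile(t, gt, kit)$table
  })
  sw <- sweep_thresholds(tabs, gt, kit, at_range = 1:200)
  for (d in unique(sw$dye)) {
    s <- sw[sw$dye == d, ]
    expect_true(all(diff(s$mean_dropouts) >= 0))
    expect_true(all(diff(s$mean_non_allelic) <= 0))
    # floor at high AT = alleles absent from the raw data (height < 1 incl. absent)
    summaries <- lapply(tabs, strbaseline:::profile_summary, genotype = gt, kit = kit)
    floor_d <- mean(vapply(summaries, function(x)
      sum(x$expected$max_height[x$expected$dye == d] < 201), numeric(1)))
    expect_equal(s$mean_dropouts[s$at_rfu == 200], floor_d)
  }
})

test_that("sweep/compare shortcut equals the explicit threshold-then-classify route", {
  kit <- mini_kit(); gt <- mini_genotype(kit)
  cfg <- simulation_config(kit)
  t <- prepare_profile(simulate_positive(cfg, kit, gt, 31.25, 29, seed = 88),
                       gt, kit)$table
  sw <- sweep_thresholds(list(t), gt, kit, at_range = c(1, 10, 25, 60, 175))
  for (at in c(1, 10, 25, 60, 175)) {
    ts <- threshold_set("chk", setNames(rep(at, 2), kit$analysis_dyes))
    kept <- apply_threshold(t, ts)$table
    cls <- classify_peaks(kept, gt, kit)
    for (d in kit$analysis_dyes) {
      cnt <- count_events(cls, dye = d)
      expect_equal(sw$mean_dropouts[sw$dye == d & sw$at_rfu == at],
                   cnt$n_dropouts)
      expect_equal(sw$mean_non_allelic[sw$dye == d & sw$at_rfu == at],
                   cnt$n_non_allelic)
    }
  }
})

test_that("method comparison is monotone: raising thresholds never reduces dropouts", {
  kit <- mini_kit(); gt <- mini_genotype(kit)
  cfg <- simulation_config(kit)
  tabs <- lapply(1:4, function(i)
    prepare_profile(simulate_positive(cfg, kit, gt, 15.625, 27, seed = 400 + i),
                    gt, kit)$table)
  negs <- clean_negatives(9, kit, cfg)
  sets <- compute_all_thresholds(negs, kit)
  res <- compare_methods(sets, tabs, gt, kit)
  at2_row <- res[res$method == "AT2", ]
  at5_row <- res[res$method == "AT5", ]
  expect_lte(at2_row$mean_dropouts, at5_row$mean_dropouts)
  # the lowest threshold set reports at least as many non-allelic peaks as any other
  for (m in c("AT1", "AT3", "AT4", "AT5", "AT_ori")) {
    expect_gte(at2_row$mean_non_allelic, res$mean_non_allelic[res$method == m])
  }
  # a set below every peak height reproduces the AT = 1 analysis
  ts1 <- list(AT_all1 = threshold_set("AT_all1",
                                      setNames(rep(1, 2), kit$analysis_dyes)))
  res1 <- compare_methods(ts1, tabs, gt, kit)
  sw <- sweep_thresholds(tabs, gt, kit, at_range = 1)
  expect_equal(res1$mean_dropouts, sum(tapply(sw$mean_dropouts, sw$dye, sum)))
  expect_true(all(res$total_error >= 0 & res$total_error <= 2))
})

test_that("ROC selection minimises distance to (0,1) with the lower-fpr tie rule", {
  counts <- data.frame(method = c("A", "B"), template_pg = 10, cycles = 27,
                       tpr = c(0.6, 0.9), fpr = c(0, 0.2))
  roc <- roc_points(counts)
  expect_equal(roc$points$distance, c(0.4, sqrt(0.2^2 + 0.1^2)), tolerance = 1e-12)
  expect_equal(roc$best$method, "B")

  perfect <- data.frame(method = c("A", "B"), template_pg = 10, cycles = 27,
                        tpr = c(1, 0.5), fpr = c(0, 0))
  expect_equal(roc_points(perfect)$best$method, "A")
  expect_equal(roc_points(perfect)$best$distance, 0)

  tie <- data.frame(method = c("hi_fpr", "lo_fpr"), template_pg = 10, cycles = 27,
                    tpr = c(1, 0.5), fpr = c(0.5, 0))
  expect_equal(roc_points(tie)$best$method, "lo_fpr")  # both at distance 0.5
})

test_that("total error arithmetic covers the floor and midrange cases", {
  expect_equal(total_error(list(tpr = 1, fpr = 0)), 0)
  expect_equal(total_error(list(tpr = 0, fpr = 0)), 1)
  expect_equal(total_error(list(tpr = 0.8, fpr = 0.3)), 0.5)
})
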