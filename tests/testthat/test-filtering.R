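test_that("read-region filter keeps the closed interval boundaries", {
  kit <- mini_kit()
  st <- make_table("B", c(79.9, 80.0, 480.0, 480.1), c(10, 10, 10, 10))
  res <- filter_read_region(st, kit)
  expect_equal(res$table$size_bp, c(80.0, 480.0))
  expect_equal(res$report$n_removed, 2)
  expect_true(all(res$report$removed$reason == "out_of_read_region"))
})

test_that("read-region filter equals a brute-force comparison loop", {
  kit <- mini_kit()
  set.seed(7)
  sizes <- runif(100, 60, 500)
  st <- make_table("B", sizes, rep(5, 100))
  res <- filter_read_region(st, kit)
  oracle <- sum(vapply(sizes, function(s) s >= 80 && s <= 480, logical(1)))
  expect_equal(res$report$n_retained, oracle)
  expect_equal(sort(res$table$size_bp), sort(sizes[sizes >= 80 & sizes <= 480]))
})

test_that("ILS proximity removal uses distance <= window in bp", {
  kit <- mini_kit()  # ILS fragment at 120
  st <- make_table("B", c(120.0, 117.9, 118.1, 122.5), c(10, 10, 10, 10))
  res <- filter_ils_adjacent(st, kit)
  # distances to 120: 0, 2.1, 1.9, 2.5 -> removed 0 and 1.9
  expect_setequal(res$table$size_bp, c(117.9, 122.5))
  expect_true(all(res$report$removed$reason == "near_ILS"))
})

test_that("ILS-dye records are always excluded and far signals are identity", {
  kit <- mini_kit()
  st <- make_table(c("B", "O"), c(130.5, 120.0), c(10, 3000))
  res <- filter_ils_adjacent(st, kit)
  expect_equal(res$table$dye, "B")  # ILS channel removed, B at distance >2 kept
  st2 <- make_table("B", c(110.5, 130.5), c(5, 6))
  expect_equal(nrow(filter_ils_adjacent(st2, kit)$table), 2)
})

test_that("locus screening annotates markers and equals an interval-scan oracle", {
  kit <- mini_kit()
  st <- make_table("B", 120, 50)
  res <- screen_locus_positions(st, kit)
  expect_equal(res$table$marker, "M1")

  st2 <- make_table("B", 195, 50)  # no marker interval on B covers 195
  res2 <- screen_locus_positions(st2, kit)
  expect_equal(nrow(res2$table), 0)
  expect_equal(res2$report$removed$reason, "off_locus")

  set.seed(13)
  dyes <- sample(c("B", "G"), 10, TRUE)
  sizes <- runif(10, 90, 200)
  st3 <- make_table(dyes, sizes, rep(20, 10))
  res3 <- screen_locus_positions(st3, kit)
  mk <- kit$markers
  oracle <- vapply(seq_len(10), function(i) {
    any(mk$dye == dyes[i] & sizes[i] >= mk$min_bp & sizes[i] <= mk$max_bp)
  }, logical(1))
  expect_equal(res3$report$n_retained, sum(oracle))
  expect_setequal(res3$table$size_bp, sizes[oracle])
})

test_that("pull-up removal applies both criteria inclusively", {
  allelic <- make_records("B", 120.00, 1000)
  cand <- make_table("G", 120.20, 45)
  expect_equal(nrow(remove_pullup(cand, allelic)$table), 0)    # 0.2<=0.3, 45<=50

  cand2 <- make_table("G", 120.20, 60)
  expect_equal(nrow(remove_pullup(cand2, allelic)$table), 1)   # 60 > 50

  cand3 <- make_table("G", 120.30, 50)                          # both exactly at bound
  expect_equal(nrow(remove_pullup(cand3, allelic)$table), 0)

  # same-dye peaks never trigger pull-up removal
  cand4 <- make_table("B", 120.00, 40)
  expect_equal(nrow(remove_pullup(cand4, allelic)$table), 1)

  # tallest qualifying peak decides when several match
  allelic2 <- make_records(c("B", "Y"), c(120.0, 120.1), c(1000, 400))
  cand5 <- make_table("G", 120.1, 45)
  expect_equal(nrow(remove_pullup(cand5, allelic2)$table), 0)  # 45 <= 5% of 1000
})

test_that("thresholding is inclusive at the AT and matches a comparison oracle", {
  ts <- threshold_set("AT_test", c(B = 175, G = 175))
  st <- make_table("B", c(100, 101, 102), c(174, 175, 176))
  res <- apply_threshold(st, ts)
  expect_equal(res$table$height_rfu, c(175, 176))
  expect_true(all(res$report$removed$reason == "below_AT"))

  # AT of 1 RFU keeps everything with height >= 1
  ts1 <- threshold_set("AT_min", c(B = 1, G = 1))
  set.seed(3)
  st2 <- make_table(sample(c("B", "G"), 50, TRUE), runif(50, 80, 480),
                    runif(50, 0.2, 30))
  res2 <- apply_threshold(st2, ts1)
  expect_equal(res2$report$n_retained, sum(st2$height_rfu >= 1))

  # random thresholds vs explicit loop
  ts3 <- threshold_set("AT_rand", c(B = 12, G = 7))
  res3 <- apply_threshold(st2, ts3)
  oracle <- vapply(seq_len(50), function(i) {
    st2$height_rfu[i] >= c(B = 12, G = 7)[[st2$dye[i]]]
  }, logical(1))
  expect_equal(sort(res3$table$height_rfu), sort(st2$height_rfu[oracle]))

  expect_error(apply_threshold(st2, threshold_set("bad", c(B = 10))), "G")
})

test_that("filters are idempotent and report counts reconcile", {
  kit <- mini_kit()
  set.seed(21)
  st <- make_table(sample(c("B", "G", "O"), 60, TRUE), runif(60, 60, 500),
                   runif(60, 1, 50))
  filters <- list(
    function(t) filter_read_region(t, kit),
    function(t) filter_ils_adjacent(t, kit),
    function(t) screen_locus_positions(t, kit)
  )
  for (f in filters) {
    once <- f(st)
    expect_equal(once$report$n_input,
                 once$report$n_removed + once$report$n_retained)
    twice <- f(once$table)
    expect_equal(as.data.frame(twice$table)[, c("dye", "size_bp", "height_rfu")],
                 as.data.frame(once$table)[, c("dye", "size_bp", "height_rfu")])
    expect_equal(twice$report$n_removed, 0)
  }
})

test_that("filters are monotone in their window parameters", {
  kit <- mini_kit()
  set.seed(22)
  st <- make_table("B", runif(80, 100, 200), runif(80, 1, 100))
  allelic <- make_records("G", runif(20, 100, 200), runif(20, 500, 2000))
  prev_ils <- Inf
  for (w in c(0.5, 1, 2, 4, 8)) {
    n <- filter_ils_adjacent(st, kit, window_bp = w)$report$n_retained
    expect_lte(n, prev_ils)
    prev_ils <- n
  }
  prev_pu <- Inf
  for (hf in c(0.01, 0.05, 0.2, 0.5, 1)) {
    n <- remove_pullup(st, allelic, height_frac = hf)$report$n_retained
    expect_lte(n, prev_pu)
    prev_pu <- n
  }
})
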