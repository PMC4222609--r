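# Frequency computation, heterozygote calling, band segmentation,
# breakpoint delineation, repeat annotation, copy-model inference.

test_that("frequencies use only passing reads and respect the depth floor", {
  cfg <- profiler_config()
  tab <- make_sites(pos = c(100, 200, 300, 400),
                    n_ref = c(50, 45, 120, 0),
                    n_alt = c(50, 45, 0, 0),
                    n_mq_fail = c(0, 60, 0, 80))
  fr <- filter_and_frequency(tab, cfg)
  expect_equal(fr$f[1], 0.5)
  expect_true(fr$callable[1])          # depth exactly 100 is callable
  expect_identical(fr$depth[2], 90)    # 150 raw reads, 60 failed MQ
  expect_false(fr$callable[2])         # -> no call
  expect_equal(fr$f[3], 0)             # alt-free site: f = 0, never an error
  expect_true(is.na(fr$f[4]))          # zero effective depth: no division
  expect_false(fr$callable[4])
})

test_that("heterozygote calls use the inclusive 25-75% band and fold", {
  cfg <- profiler_config()
  tab <- make_sites(pos = c(1, 2, 3, 4, 5) * 100,
                    n_ref = c(75, 80, 30, 120, 55),
                    n_alt = c(25, 20, 70, 0, 45))
  het <- call_het_sites(filter_and_frequency(tab, cfg), cfg)
  expect_identical(het$pos, c(100, 300, 500))
  expect_equal(het$f_folded[het$pos == 100], 0.25)  # f = 0.25: inclusive
  expect_equal(het$f_folded[het$pos == 300], 0.30)  # f = 0.70 folds to 0.30
  # f = 0.20 and f = 0 are not heterozygous
  expect_false(any(het$pos %in% c(200, 400)))
})

test_that("a 50/33/50 profile segments into exactly three labelled bands", {
  set.seed(17)
  n <- c(20, 15, 25)
  f <- c(rep(0.5, n[1]), rep(1/3, n[2]), rep(0.5, n[3]))
  depth <- 300
  alt <- rbinom(sum(n), depth, f)
  tab <- make_sites(pos = seq_along(f) * 500, n_ref = depth - alt,
                    n_alt = alt)
  het <- call_het_sites(filter_and_frequency(tab))
  seg <- segment_het_profile(het)
  expect_identical(nrow(seg), 3L)
  expect_equal(seg$band, c(1/2, 1/3, 1/2))
  expect_equal(seg$n_sites, n)

  uni <- make_sites(pos = 1:20 * 100, n_ref = 150, n_alt = 150)
  seg1 <- segment_het_profile(call_het_sites(filter_and_frequency(uni)))
  expect_identical(nrow(seg1), 1L)
  expect_equal(seg1$band, 0.5)
})

test_that("segmentation matches brute-force enumeration on small profiles", {
  set.seed(23)
  cfg <- profiler_config(min_run = 2)
  for (rep in 1:40) {
    n <- sample(4:12, 1)
    f <- sample(c(0.5, 1/3), n, replace = TRUE)
    depth <- sample(c(60, 150), 1)
    alt <- rbinom(n, depth, f)
    tab <- make_sites(pos = seq_len(n) * 100, n_ref = depth - alt,
                      n_alt = alt)
    het <- call_het_sites(filter_and_frequency(tab),
                          profiler_config(min_depth = 50))
    if (nrow(het) < cfg$min_run) next
    seg <- segment_het_profile(het, cfg)
    bands <- pmin(cfg$band_means, 1 - cfg$band_means)
    ll <- vapply(bands, function(b) {
      pmax(dbinom(het$n_alt, het$depth, b, log = TRUE),
           dbinom(het$n_alt, het$depth, 1 - b, log = TRUE))
    }, numeric(nrow(het)))
    oracle <- brute_force_assign(matrix(ll, nrow = nrow(het)), cfg$min_run)
    got <- sum(vapply(seq_len(nrow(seg)), function(k) {
      idx <- seg$first_index[k]:seg$last_index[k]
      sum(ll[idx, match(seg$band[k], bands)])
    }, numeric(1)))
    expect_equal(got, oracle$score)
  }
})

test_that("segmentation is idempotent and flags underpowered profiles", {
  set.seed(5)
  alt <- rbinom(30, 300, 1/3)
  tab <- make_sites(pos = 1:30 * 50, n_ref = 300 - alt, n_alt = alt)
  het <- call_het_sites(filter_and_frequency(tab))
  seg <- segment_het_profile(het)
  expect_identical(nrow(seg), 1L)
  # re-segmenting a segment's own sites returns the same single segment
  seg2 <- segment_het_profile(het[seg$first_index:seg$last_index, ])
  expect_identical(nrow(seg2), 1L)
  expect_equal(seg2$band, seg$band)

  tiny <- segment_het_profile(het[1:2, ])
  expect_identical(nrow(tiny), 1L)
  expect_true(attr(tiny, "low_confidence"))
  none <- segment_het_profile(het[0, ])
  expect_identical(nrow(none), 0L)
})

test_that("breakpoints sit between the boundary-adjacent evidence sites", {
  # positions chosen so the distal 50% band ends at 2,694,303 and the 33%
  # band starts at 2,694,429 (the delineation rule of the studied locus)
  pos_half <- c(2694003, 2694153, 2694303)
  pos_third <- c(2694429, 2695529, 2696629)
  pos_half2 <- c(2699603, 2699703, 2699803)
  depth <- 300
  alt <- c(rep(150, 3), rep(100, 3), rep(150, 3))
  tab <- make_sites(pos = c(pos_half, pos_third, pos_half2),
                    n_ref = depth - alt, n_alt = alt)
  het <- call_het_sites(filter_and_frequency(tab))
  seg <- segment_het_profile(het)
  bp <- delineate_breakpoints(seg, het)
  expect_identical(nrow(bp), 2L)
  expect_identical(bp$left_pos[1], 2694303)
  expect_identical(bp$right_pos[1], 2694429)
  expect_equal(bp$left_band[1], 0.5)
  expect_equal(bp$right_band[1], 1/3)

  ann <- annotate_with_repeats(
    bp, data.frame(id = "LTR_A", start = 2694151, end = 2694702))
  expect_identical(ann$repeats[1], "LTR_A")   # interval overlaps the repeat
  expect_identical(ann$repeats[2], "")        # second transition is repeat-free

  # a single band yields no breakpoint call
  none <- delineate_breakpoints(seg[2, ], het)
  expect_identical(nrow(none), 0L)
})

test_that("MQ0-dominated breakpoint intervals are flagged", {
  bp <- data.frame(left_pos = 1000, right_pos = 2000,
                   left_band = 0.5, right_band = 1/3)
  inside <- make_sites(pos = c(1200, 1500, 1800),
                       n_ref = c(1, 0, 1), n_alt = c(0, 1, 0),
                       n_mq_fail = c(400, 500, 450))
  ann <- annotate_with_repeats(bp, data.frame(id = "R", start = 900,
                                              end = 2100), inside)
  expect_true(ann$mq0_flag)
  clean <- make_sites(pos = c(1200, 1500), n_ref = c(200, 210),
                      n_alt = c(190, 200), n_mq_fail = c(5, 3))
  ann2 <- annotate_with_repeats(bp, data.frame(id = "R", start = 900,
                                               end = 2100), clean)
  expect_false(ann2$mq0_flag)
})

test_that("copy models are inferred by pooled likelihood with an ambiguity flag", {
  set.seed(41)
  alt <- rbinom(15, 300, 1/3)
  tab <- make_sites(pos = 1:15 * 100, n_ref = 300 - alt, n_alt = alt)
  het <- call_het_sites(filter_and_frequency(tab))
  seg <- segment_het_profile(het)
  cm <- infer_copy_counts(seg[1, ], het)
  expect_identical(c(cm$m, cm$c), c(1L, 3L))
  expect_false(cm$ambiguous)

  alt2 <- rbinom(15, 300, 0.5)
  tab2 <- make_sites(pos = 1:15 * 100, n_ref = 300 - alt2, n_alt = alt2)
  het2 <- call_het_sites(filter_and_frequency(tab2))
  seg2 <- segment_het_profile(het2)
  cm2 <- infer_copy_counts(seg2[1, ], het2)
  expect_identical(c(cm2$m, cm2$c), c(1L, 2L))

  # folded fraction midway between 1/2 and 1/3 at low depth: tiny margin
  mid <- make_sites(pos = c(100, 200, 300), n_ref = c(7, 7, 7),
                    n_alt = c(5, 5, 5))
  het3 <- call_het_sites(filter_and_frequency(mid,
                                              profiler_config(min_depth = 10)),
                         profiler_config(min_depth = 10))
  seg3 <- segment_het_profile(het3)
  cm3 <- infer_copy_counts(seg3[1, ], het3)
  expect_lt(cm3$margin, 2)
  expect_true(cm3$ambiguous)
})

test_that("no heterozygous calls arise from hemizygous sequence at zero error", {
  pair <- build_reference(scaled_config(), with_sequences = FALSE)
  prof <- truth_copy_profile(apply_nahr(pair), "male_control")
  tab <- simulate_site_table(
    prof, pileup_config(seed = 3, base_error = 0), window = scaled_window)
  het <- call_het_sites(filter_and_frequency(tab))
  expect_false(any(het$pos >= prof$pab))
})
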