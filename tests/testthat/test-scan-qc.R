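test_that("SNR arithmetic, degenerate background, and gain invariance", {
  expect_equal(compute_snr(1000, 100, 50), 18.0)
  expect_equal(compute_snr(100, 100, 50), 0.0)
  expect_error(compute_snr(1000, 100, 0), "bg_pix_sd")
  # invariance under a common multiplicative gain
  set.seed(51)
  m <- runif(20, 200, 5000); b <- runif(20, 50, 150); s <- runif(20, 10, 60)
  for (gain in c(0.25, 3, 117))
    expect_equal(compute_snr(gain * m, gain * b, gain * s), compute_snr(m, b, s))
})

test_that("detection classes follow the conjunctive thresholds with closed bounds", {
  expect_equal(classify_detection(5.0, TRUE), "robust")
  expect_equal(classify_detection(2.0, TRUE), "cautionary")
  expect_equal(classify_detection(10.0, FALSE), "cautionary")  # fails flag gate
  expect_equal(classify_detection(3.0, TRUE), "robust")        # boundary closed
  expect_equal(classify_detection(1.5, FALSE), "cautionary")   # boundary closed
  expect_equal(classify_detection(1.49, TRUE), "low_confidence")
  # monotone in SNR at fixed flag state
  snrs <- seq(0, 6, by = 0.25)
  ranks <- c(low_confidence = 1, cautionary = 2, robust = 3)
  for (flag in c(TRUE, FALSE)) {
    cls <- ranks[classify_detection(snrs, rep(flag, length(snrs)))]
    expect_true(all(diff(cls) >= 0))
  }
})

test_that("replicate-spot collapsing uses median SNR, mean signals, any-flag", {
  one <- spot_row(1000)
  s1 <- collapse_replicate_spots(one)
  expect_equal(s1$median_snr, 18)
  expect_equal(s1$mean_signal, 1000)
  expect_equal(s1$mean_bg, 100)
  expect_false(s1$any_adverse_flag)

  two <- rbind(spot_row(100 + 4 * 50), spot_row(100 + 6 * 50))
  expect_equal(collapse_replicate_spots(two)$median_snr, 5)

  sat <- rbind(spot_row(1000), spot_row(1200, saturated = TRUE))
  expect_true(collapse_replicate_spots(sat)$any_adverse_flag)

  # commutes with spot reordering
  set.seed(52)
  many <- do.call(rbind, lapply(runif(7, 300, 3000), spot_row))
  expect_equal(collapse_replicate_spots(many),
               collapse_replicate_spots(many[sample(7), ]))
  expect_error(collapse_replicate_spots(many[0, ]), "no spots")
})

test_that("across-array summaries exclude flagged arrays but count them", {
  mk <- function(snr, flagged = FALSE, robust = TRUE) {
    data.frame(probe_id = "p1", median_snr = snr, mean_processed = 500,
               any_adverse_flag = flagged,
               detection_class = if (robust) "robust" else "cautionary")
  }
  all16 <- do.call(rbind, lapply(rep(8, 16), mk))
  expect_equal(summarize_probe(all16)$present_call_rate, 1.0)

  mix <- rbind(mk(5), mk(6), mk(7), mk(9, flagged = TRUE))
  sm <- summarize_probe(mix)
  expect_equal(sm$present_call_rate, 1.0)
  expect_equal(sm$flagged_array_count, 1L)
  expect_equal(sm$n_arrays, 4L)

  spread <- rbind(mk(2, robust = FALSE), mk(3), mk(9))
  ss <- summarize_probe(spread)
  expect_equal(ss$min_snr, 2); expect_equal(ss$median_snr, 3)
  expect_equal(ss$max_snr, 9)
  expect_true(ss$min_snr <= ss$median_snr && ss$median_snr <= ss$max_snr)

  gone <- rbind(mk(4, flagged = TRUE), mk(5, flagged = TRUE))
  sg <- summarize_probe(gone)
  expect_false(sg$snr_available)
  expect_true(is.na(sg$median_snr))
  expect_equal(sg$flagged_array_count, 2L)
})

test_that("DLRS is zero for constant ratios and recovers sigma for Gaussian noise", {
  expect_equal(compute_dlrs(rep(0.7, 100)), 0)
  expect_error(compute_dlrs(c(1, 2)), "at least 3")
  set.seed(53)
  for (sigma in c(0.1, 0.5)) {
    x <- rnorm(10000, 0, sigma)
    expect_equal(compute_dlrs(x), sigma, tolerance = 0.05)
  }
  # alternating +d/-d: first differences alternate -2d/+2d; expected value
  # computed by the independent formula (scaled IQR of diffs over sqrt 2)
  d <- 0.4
  x <- rep(c(d, -d), 25)
  diffs <- diff(x)
  expected <- (unname(quantile(diffs, 0.75) - quantile(diffs, 0.25)) / 1.349) / sqrt(2)
  expect_equal(compute_dlrs(x), expected)
  expect_gt(expected, 0)
})

test_that("spike-in regression reports slope and correlation as stated", {
  exp10 <- seq(-2, 2, length.out = 10)
  fit1 <- spike_in_check(exp10, exp10)
  expect_equal(fit1$slope, 1); expect_equal(fit1$correlation, 1)
  fit2 <- spike_in_check(exp10 + 0.3, exp10)
  expect_equal(fit2$slope, 1); expect_equal(fit2$correlation, 1)
  set.seed(54)
  obs <- sample(exp10)   # scrambled observations decorrelate
  expect_lt(abs(spike_in_check(obs, exp10)$correlation), 0.8)
  expect_error(spike_in_check(exp10, rep(1, 10)), "zero variance")
  expect_error(spike_in_check(1:2, 1:2), ">= 3")
})

test_that("FE-style tables round-trip through the reader", {
  probes <- carpoligo:::fabricate_probe_set(40, seed = 55L)
  cm <- control_manifest(control_count = 12L, spike_levels = 3L, n_corner = 2L)
  spec <- layout_spec(subarrays = 1L, features_per_subarray = 60L,
                      control_count = 12L, replicate_probe_count = 2L,
                      replicate_copies = 4L, seed = 55L, control_manifest = cm)
  layout <- build_layout(probes, spec)
  expr <- setNames(rnorm(40, 10, 1), probes$probe_id)
  truth <- list(expr_green = expr, expr_red = expr,
                spike_logratio = setNames(seq(-1, 1, length.out = 3),
                                          c("L01", "L02", "L03")))
  scan <- simulate_scan(layout, truth, seed = 56L)
  path <- tempfile(fileext = ".tsv")
  write_fe_table(scan, path)
  spots <- read_fe_table(path, array_id = "arr1")
  expect_setequal(unique(spots$channel), c("green", "red"))
  g <- spots[spots$channel == "green", ]
  expect_equal(nrow(g), 60L)
  expect_equal(g$median_signal, scan$gMedianSignal)
  expect_equal(g$well_above_bg, scan$gIsWellAboveBG == 1)
  # unknown columns are ignored with a notice
  scan$MadeUpColumn <- 1
  write_fe_table(scan, path)
  expect_message(read_fe_table(path), "MadeUpColumn")
})

test_that("qc_summarize aggregates spots per probe and array", {
  spots <- rbind(
    spot_row(100 + 4 * 50, array_id = "a1", probe_id = "p1"),
    spot_row(100 + 6 * 50, array_id = "a1", probe_id = "p1"),
    spot_row(100 + 2 * 50, array_id = "a2", probe_id = "p1"),
    spot_row(100 + 9 * 50, array_id = "a1", probe_id = "p2", saturated = TRUE)
  )
  qc <- qc_summarize(spots)
  expect_equal(nrow(qc$per_array), 3L)
  expect_equal(nrow(qc$per_probe), 2L)
  p1 <- qc$per_probe[qc$per_probe$probe_id == "p1", ]
  expect_equal(p1$flagged_array_count, 0L)
  expect_equal(p1$min_snr, 2); expect_equal(p1$max_snr, 5)
  p2 <- qc$per_probe[qc$per_probe$probe_id == "p2", ]
  expect_false(p2$snr_available)
})
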