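test_that("threshold initialisation follows the printed coefficients", {
  cfg <- detector_config()
  s <- init_threshold_state(c(100, numeric(400)), fs = 360, cfg)
  expect_equal(s$spk, 13)
  expect_equal(s$npk, 1.3)
  expect_equal(s$threshold, 4.225)
  s1 <- init_threshold_state(c(1, numeric(400)), fs = 360, cfg)
  expect_equal(s1$threshold, 0.04225)
  s0 <- init_threshold_state(numeric(400), fs = 360, cfg)
  expect_equal(c(s0$spk, s0$npk, s0$threshold), c(0, 0, 0))
  # only the first 300 samples (at 360 Hz) are examined
  x <- numeric(400); x[350] <- 999; x[10] <- 50
  expect_equal(init_threshold_state(x, fs = 360, cfg)$spk, 0.13 * 50)
})

test_that("the RR buffer is a 10-slot FIFO with an arithmetic-mean average", {
  s <- init_threshold_state(c(1, numeric(300)), fs = 360)
  s <- update_ave_rr(s, 360)
  expect_equal(s$ave_rr, 360)
  for (i in 1:10) s <- update_ave_rr(s, 300)
  s <- update_ave_rr(s, 400)
  expect_equal(length(s$rr_buffer), 10L)
  expect_equal(s$ave_rr, (9 * 300 + 400) / 10)
  s2 <- init_threshold_state(c(1, numeric(300)), fs = 360)
  for (i in 1:11) s2 <- update_ave_rr(s2, 100)
  s2 <- update_ave_rr(s2, 200)
  expect_equal(s2$rr_buffer, c(rep(100, 9), 200))
  expect_equal(s2$ave_rr, 110)
  expect_error(update_ave_rr(s2, 0), "positive")
})

test_that("clearly supra-threshold peaks are all accepted without search-back", {
  integrated <- numeric(4000); integrated[1:300] <- 1  # M_VAL = 1
  peaks <- data.frame(index = seq(300, 3000, by = 300),
                      amplitude = rep(10 * 0.04225, 10), forced = FALSE)
  res <- detect_qrs(peaks, integrated, fs = 360, trace = TRUE)
  expect_equal(nrow(res$detections), 10L)
  expect_false(any(res$detections$via_searchback))
  expect_equal(res$rr_intervals, rep(300, 9))
})

test_that("THRESHOLD equals 0.25*SPK + 0.75*NPK after every decision", {
  rec <- generate_synthetic(synthetic_spec(duration_s = 40, seed = 5))
  pre <- preprocess(rec)
  peaks <- find_candidate_peaks(pre$integrated, rec$fs)
  res <- detect_qrs(peaks, pre$integrated, rec$fs, trace = TRUE)
  tr <- res$state_trace
  expect_gt(nrow(tr), 10)
  expect_equal(tr$threshold, 0.25 * tr$spk + 0.75 * tr$npk)
  s <- res$state
  expect_equal(s$threshold, 0.25 * s$spk + 0.75 * s$npk)
  expect_true(s$spk >= 0 && s$npk >= 0)
})

test_that("a weak beat in a long gap is recovered by SPK halving search-back", {
  # 8 strong beats at RR = 300, one weak beat, then a strong beat after a
  # 600-sample gap (> max(400, 1.5 * 300)); hand-traced state expectation
  cfg <- detector_config()
  integrated <- numeric(4000); integrated[1:300] <- 10  # SPK0 = 1.3
  strong <- seq(300, by = 300, length.out = 8)
  # plain-arithmetic trace of the accepted-peak SPK recursion
  spk <- 0.13 * 10; npk <- 0.1 * spk
  for (k in seq_along(strong)) spk <- 0.125 * 10 + 0.875 * spk
  thr_after <- 0.25 * spk + 0.75 * npk
  weak_amp <- 0.4 * thr_after
  peaks <- data.frame(
    index = c(strong, 2700, 3300),
    amplitude = c(rep(10, 8), weak_amp, 10),
    forced = FALSE)
  res <- detect_qrs(peaks, integrated, fs = 360)
  expect_equal(nrow(res$detections), 10L)
  expect_equal(sum(res$detections$via_searchback), 1L)
  expect_true(res$detections$via_searchback[res$detections$integrated_index == 2700])
  expect_error(
    detect_qrs(peaks[c(2, 1, 3:10), ], integrated, fs = 360),
    "sorted")
})

test_that("empty candidate lists yield empty detections", {
  res <- detect_qrs(data.frame(index = integer(0), amplitude = numeric(0),
                               forced = logical(0)),
                    c(1, numeric(500)), fs = 360)
  expect_equal(nrow(res$detections), 0L)
  expect_equal(length(res$rr_intervals), 0L)
})

test_that("the accept/reject pattern is invariant to overall signal scale", {
  rec <- generate_synthetic(synthetic_spec(duration_s = 60, seed = 17))
  pre <- preprocess(rec)
  peaks <- find_candidate_peaks(pre$integrated, rec$fs)
  base <- detect_qrs(peaks, pre$integrated, rec$fs)
  for (c_scale in c(0.01, 7, 1000)) {
    sc_peaks <- peaks
    sc_peaks$amplitude <- peaks$amplitude * c_scale
    sc <- detect_qrs(sc_peaks, pre$integrated * c_scale, rec$fs)
    expect_equal(sc$detections$integrated_index,
                 base$detections$integrated_index)
    expect_equal(sc$detections$via_searchback,
                 base$detections$via_searchback)
  }
})

test_that("delay correction maps detections onto ground-truth beats", {
  rec <- generate_synthetic(clean_spec(duration_s = 30))
  res <- detect_record(rec)
  truth <- rec$annotations$indices
  expect_equal(nrow(res$detections), length(truth))
  expect_true(all(abs(res$detections$raw_index - truth) <= 1))
  # refine_window = 0 is pure delay subtraction
  pre <- attr(res, "preprocessed")
  raw0 <- to_raw_fiducials(res, pre, refine_n = 0L)
  expect_equal(raw0$detections$raw_index,
               pmin(pmax(res$detections$integrated_index - pre$total_delay, 0),
                    length(pre$raw) - 1))
})

test_that("translating the input translates the raw fiducials", {
  spec <- clean_spec(duration_s = 12)
  rec <- generate_synthetic(spec)
  k <- 25L
  shifted <- ecg_record(c(numeric(k), rec$channels[[1]]), fs = rec$fs)
  a <- detect_record(rec)
  b <- detect_record(shifted)
  expect_equal(b$detections$raw_index, a$detections$raw_index + k)
})
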