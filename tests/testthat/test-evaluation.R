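test_that("matching handles identity, tolerated shifts and straddles", {
  fs <- 360
  ref <- seq(360, by = 360, length.out = 20)
  m <- match_beats(ref, ref, fs)
  expect_equal(c(m$tp, m$fp, m$fn), c(20L, 0L, 0L))
  shifted <- ref + round(0.05 * fs)  # +50 ms, inside the 150 ms window
  m2 <- match_beats(shifted, ref, fs)
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(20L, 0L, 0L))
  # two detections straddling one reference: one TP, one FP
  m3 <- match_beats(c(980, 1020), 1000, fs)
  expect_equal(c(m3$tp, m3$fp, m3$fn), c(1L, 1L, 0L))
  far <- ref + round(0.2 * fs)       # +200 ms, outside the window
  m4 <- match_beats(far, ref, fs)
  expect_equal(m4$tp, 0L)
})

test_that("greedy matching attains the exhaustive-optimal pair count", {
  set.seed(404)
  fs <- 100; tol_ms <- 150; tol <- tol_ms / 1000 * fs
  for (case in 1:40) {
    ref <- sort(sample(0:400, sample(0:6, 1)))
    det <- sort(sample(0:400, sample(0:6, 1)))
    ref <- ref[!duplicated(ref)]; det <- det[!duplicated(det)]
    got <- match_beats(det, ref, fs, tol_ms)
    expect_equal(got$tp, brute_match_count(ref, det, tol))
    expect_lte(got$tp, min(length(ref), length(det)))
    expect_equal(got$tp + got$fn, length(ref))
    expect_equal(got$tp + got$fp, length(det))
  }
  # the configuration where nearest-first pairing would lose a match
  g <- match_beats(c(60, 160), c(0, 100), fs, tolerance_ms = 1000)
  expect_equal(g$tp, 2L)
})

test_that("matching is invariant under a global shift within tolerance", {
  set.seed(55)
  ref <- sort(sample(1000:20000, 30))
  det <- ref + sample(-10:10, 30, replace = TRUE)
  det <- sort(det[!duplicated(det)])
  a <- match_beats(det, ref, 360)
  b <- match_beats(det + 30, ref + 30, 360)
  expect_equal(a$tp, b$tp)
})

test_that("detection statistics reproduce the published benchmark rates", {
  f <- system.file("extdata", "mitbih_benchmark_counts.csv",
                   package = "qrsdetect")
  counts <- utils::read.csv(f)
  expect_equal(nrow(counts), 48L)
  agg <- score_detection(sum(counts$tp), sum(counts$fp), sum(counts$fn),
                         actual = sum(counts$actual))
  expect_equal(agg$actual, 109966)
  expect_equal(round(100 * agg$detection_rate, 2), 99.41)
  expect_equal(round(100 * agg$se, 2), 99.72)
  expect_equal(round(100 * agg$sp, 2), 99.69)
  expect_equal(round(100 * agg$er, 2), 0.59)
  r100 <- score_detection(2272, 0, 1, actual = 2273)
  expect_equal(round(r100$detection_rate, 5), 0.99956)
  # every published per-record detection rate recomputes to 5 decimals
  rates <- with(counts, (actual - (fp + fn)) / actual)
  published <- c(0.99956, 0.99839, 1.00000, 0.99856, 0.99282, 0.98289,
                 0.99655, 0.99719, 0.97674, 0.99763, 0.99859, 0.99921,
                 0.99944, 0.99681, 0.99898, 0.99420, 0.99870, 0.99912,
                 0.99849, 0.99839, 0.99919, 0.99671, 0.99876, 0.99885,
                 0.98726, 0.99485, 0.98993, 0.99774, 0.96398, 0.99560,
                 0.99967, 0.98038, 0.99927, 0.99754, 0.99867, 0.99851,
                 0.99728, 0.99814, 0.99902, 0.99011, 0.99758, 0.99117,
                 0.99513, 0.99911, 0.99873, 0.92191, 0.99708, 0.99782)
  expect_equal(round(rates, 5), published, tolerance = 1e-8)
  perfect <- score_detection(10, 0, 0, actual = 10)
  expect_equal(c(perfect$detection_rate, perfect$se, perfect$sp), c(1, 1, 1))
  expect_error(score_detection(5, 0, 1, actual = 5), "inconsistent")
})

test_that("batch evaluation sums counts and recomputes aggregate rates", {
  recs <- lapply(c(3, 8, 21), function(s)
    generate_synthetic(synthetic_spec(duration_s = 30, seed = s)))
  tab <- evaluate_database(recs)
  expect_equal(nrow(tab), 4L)
  agg <- tab[4, ]
  expect_equal(agg$record_id, "aggregate")
  expect_equal(agg$tp, sum(tab$tp[1:3]))
  expect_equal(agg$fp, sum(tab$fp[1:3]))
  expect_equal(agg$fn, sum(tab$fn[1:3]))
  expect_equal(agg$actual, sum(tab$actual[1:3]))
  # aggregate rates come from summed counts, not averaged per-record rates
  expect_equal(agg$se, agg$tp / (agg$tp + agg$fn))
  expect_equal(agg$sp, agg$tp / (agg$tp + agg$fp))
  # a WFDB record path works as a batch element too
  dir <- withr::local_tempdir()
  write_wfdb_record(recs[[1]], dir, gain = 1000)
  tab2 <- evaluate_database(list(file.path(dir, recs[[1]]$record_id)))
  expect_equal(tab2$actual[1], tab$actual[1])
})
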