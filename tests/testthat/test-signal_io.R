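test_that("record and annotation constructors enforce their invariants", {
  expect_error(ecg_record(list(1:10, 1:5), fs = 360), "identical length")
  expect_error(ecg_record(1:10, fs = 0), "positive")
  expect_error(beat_annotations(c(5, 5, 9)), "strictly increasing")
  expect_error(beat_annotations(c(3, 9), codes = "N"), "one entry per index")
  rec <- ecg_record(sin(1:720 / 10), fs = 360, record_id = "r1")
  expect_s3_class(rec, "ecg_record")
  expect_equal(length(rec$channels[[1]]), 720L)
})

test_that("WFDB format-16 records round-trip through write and read", {
  rec <- generate_synthetic(synthetic_spec(duration_s = 6, seed = 12))
  dir <- withr::local_tempdir()
  write_wfdb_record(rec, dir, fmt = 16, gain = 1000)
  back <- read_wfdb_record(file.path(dir, rec$record_id))
  expect_equal(back$fs, 360)
  expect_equal(back$record_id, rec$record_id)
  # quantisation at gain 1000 -> within half an ADC step
  expect_lt(max(abs(back$channels[[1]] - rec$channels[[1]])), 0.5 / 1000)
  expect_equal(back$annotations$indices, rec$annotations$indices)
  expect_equal(back$annotations$codes, rec$annotations$codes)
  expect_error(read_wfdb_record(file.path(dir, "missing")), "header not found")
})

test_that("format-212 packing decodes known byte patterns and round-trips", {
  # bytes (0xFF, 0x17, 0x80): s1 = 0x7FF = 2047, s2 = 0x180 = 384
  expect_equal(qrsdetect:::decode_fmt212(as.raw(c(0xFF, 0x17, 0x80))),
               c(2047L, 384L))
  # bytes (0x00, 0xF8, 0x00): s1 = 0x800 -> -2048, s2 = 0xF00 -> -256
  expect_equal(qrsdetect:::decode_fmt212(as.raw(c(0x00, 0xF8, 0x00))),
               c(-2048L, -256L))
  s <- c(-2048L, 2047L, 0L, -1L, 1L, 1234L, -1234L, 7L)
  expect_equal(qrsdetect:::decode_fmt212(qrsdetect:::encode_fmt212(s)), s)
  # a two-channel record through the 212 writer/reader
  x <- sin(2 * pi * 5 * (0:719) / 360)
  rec <- ecg_record(list(x, 0.5 * x), fs = 360, record_id = "fmt212",
                    channel_names = c("MLII", "V5"))
  dir <- withr::local_tempdir()
  write_wfdb_record(rec, dir, fmt = 212, gain = 200)
  back <- read_wfdb_record(file.path(dir, "fmt212"))
  expect_equal(length(back$channels), 2L)
  expect_equal(back$channel_names, c("MLII", "V5"))
  expect_lt(max(abs(back$channels[[2]] - 0.5 * x)), 0.5 / 200)
  # channel selection by name
  one <- read_wfdb_record(file.path(dir, "fmt212"), channel = "V5")
  expect_equal(length(one$channels), 1L)
  expect_equal(one$channels[[1]], back$channels[[2]])
})

test_that("annotation files survive long gaps and preserve codes", {
  ann <- beat_annotations(c(10, 500, 5000, 90000, 90360),
                          c("N", "V", "N", "/", "A"))
  dir <- withr::local_tempdir()
  f <- file.path(dir, "t.atr")
  write_wfdb_annotations(ann, f)
  back <- read_wfdb_annotations(f)
  expect_equal(back$indices, ann$indices)
  expect_equal(back$codes, ann$codes)
})

test_that("beat-code filtering keeps beats and drops non-beat annotations", {
  codes <- c("N", "+", "V", "~", "L", "x", "/", "\"")
  ann <- beat_annotations(seq(100, by = 400, length.out = length(codes)),
                          codes)
  beats <- ann$codes %in% wfdb_beat_codes()
  expect_equal(sum(beats), 4L)
  expect_equal(ann$codes[beats], c("N", "V", "L", "/"))
})

test_that("CSV signals read back with the supplied sampling rate", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "sig.csv")
  x <- round(stats::rnorm(100), 6)
  utils::write.csv(data.frame(sample_index = 0:99, value = x), f,
                   row.names = FALSE)
  rec <- read_ecg_csv(f, fs = 250)
  expect_equal(rec$fs, 250)
  expect_equal(rec$channels[[1]], x)
})

test_that("synthetic generation is a pure function of (spec, seed)", {
  spec <- synthetic_spec(duration_s = 8, seed = 33)
  a <- generate_synthetic(spec)
  b <- generate_synthetic(spec)
  expect_identical(a$channels[[1]], b$channels[[1]])
  expect_identical(a$annotations$indices, b$annotations$indices)
  c <- generate_synthetic(synthetic_spec(duration_s = 8, seed = 34))
  expect_false(identical(a$channels[[1]], c$channels[[1]]))
})

test_that("a 10 s, 60 bpm noise-free spec yields 10 beats at RR = 360", {
  rec <- generate_synthetic(clean_spec(duration_s = 10, heart_rate_bpm = 60))
  idx <- rec$annotations$indices
  expect_equal(length(idx), 10L)
  expect_true(all(diff(idx) == 360))
})

test_that("dropped and attenuated beats are applied after placement", {
  spec <- clean_spec(duration_s = 12, heart_rate_bpm = 60,
                     dropped_beats = 5L)
  rec <- generate_synthetic(spec)
  idx <- rec$annotations$indices
  expect_equal(length(idx), 11L)  # 12 placed - 1 dropped
  rr <- diff(idx)
  expect_equal(sum(rr > 1.5 * 360), 1L)
  expect_equal(rr[4], 720)        # the gap is exactly twice nominal
  att <- generate_synthetic(clean_spec(duration_s = 12, heart_rate_bpm = 60,
                                       attenuated_beats = list("3" = 0.2)))
  full <- generate_synthetic(clean_spec(duration_s = 12, heart_rate_bpm = 60))
  k <- full$annotations$indices[3] + 1
  expect_lt(att$channels[[1]][k], 0.4 * full$channels[[1]][k])
  expect_equal(att$annotations$indices, full$annotations$indices)
})
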