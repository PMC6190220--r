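curve_file <- function(df, sep = "\t") {
  f <- tempfile(fileext = ".tsv")
  write.table(df, f, sep = sep, quote = FALSE, row.names = FALSE)
  f
}

test_that("curves read from delimited text and round-trip to 1e-9", {
  f <- curve_file(data.frame(time = c(0, 0.001, 0.002), z = c(1, 1, 1),
                             force = c(5.4, 5.3, 5.2)))
  cv <- read_curve(f)
  expect_s3_class(cv, "force_curve")
  expect_length(cv$t, 3)
  expect_equal(cv$fs, 1000)
  # write -> read reproduces numeric content
  p <- table1_means("MCF-7")
  cv2 <- generate_curve(p, fs = 200, duration = 2)
  f2 <- tempfile(fileext = ".tsv")
  write_curve(cv2, f2)
  cv3 <- read_curve(f2)
  expect_equal(cv3$force, cv2$force, tolerance = 1e-9)
  expect_equal(cv3$t, cv2$t, tolerance = 1e-9)
  expect_equal(cv3$z, cv2$z, tolerance = 1e-9)
})

test_that("deflection converts to force via the spring constant", {
  # 1 um deflection at the calibrated 0.2960 N/m lever is 296 nN
  expect_equal(deflection_to_force(1, 0.2960), 296.0)
  expect_equal(deflection_to_force(0, 0.2960), 0)
  expect_equal(deflection_to_force(c(1, 2), 0.001), c(1, 2))
  expect_error(deflection_to_force(1, 0), "positive")
  # file with a deflection column requires the spring constant and converts
  f <- curve_file(data.frame(t = c(0, 0.01, 0.02), z = 1, defl = c(0.5, 0.4, 0.3)))
  cv <- read_curve(f, columns = c(time = "t", z = "z", deflection = "defl"),
                   spring_constant = 0.2960)
  expect_equal(cv$force, 296.0 * c(0.5, 0.4, 0.3))
  expect_error(read_curve(f, columns = c(time = "t", z = "z", deflection = "defl")),
               "spring constant")
})

test_that("bad input files are rejected", {
  f <- curve_file(data.frame(time = c(0, 0.002, 0.001), z = 1, force = 1:3))
  expect_error(read_curve(f), "increasing")
  f2 <- curve_file(data.frame(time = c(0, 0.001, 0.005), z = 1, force = 1:3))
  expect_error(read_curve(f2), "irregular")
  f3 <- curve_file(data.frame(time = 0:2, zz = 1, force = 1:3))
  expect_error(read_curve(f3), "missing columns")
  expect_error(read_curve(tempfile()), "no such file")
})

test_that("slightly jittered time grids are resampled", {
  t <- c(0, 0.1, 0.2001, 0.3, 0.4)
  f <- curve_file(data.frame(time = t, z = 1, force = 2 * t))
  cv <- read_curve(f)
  expect_equal(diff(cv$t), rep(0.1, 4), tolerance = 1e-9)
  expect_equal(cv$force, 2 * cv$t, tolerance = 1e-3)
})

test_that("the zero-phase low-pass has unit DC gain and kills a 50 Hz tone", {
  x <- rep(7.3, 2000)
  expect_lt(max(abs(lowpass(x, fs = 1000) - 7.3)), 1e-9)
  t <- (0:7999) / 1000
  tone <- sin(2 * pi * 50 * t)
  out <- lowpass(tone, fs = 1000)
  # 4th-order Butterworth at 5x cutoff: |H| ~ 1/sqrt(1 + 5^8), squared by the
  # forward-backward pass; spec bound is amplitude < 0.01 (> 40 dB)
  expect_lt(max(abs(out[1000:7000])), 0.01)
  # DC + tone: DC recovered within 1 %
  mix <- 2 + tone
  expect_lt(max(abs(lowpass(mix, fs = 1000)[1000:7000] - 2)) / 2, 0.01)
  expect_error(lowpass(x, fs = 15), "twice the cutoff")
})

test_that("relaxation segmentation finds the hold window", {
  p <- table1_means("MCF-7")
  rec <- generate_full_indentation(p)
  seg <- segment_relaxation(rec)
  dt <- 1 / rec$fs
  expect_lt(abs(length(seg$idx) * dt - 6), 2 * dt + 1e-9)
  expect_equal(seg$u_const, 1, tolerance = 1e-6)
  expect_equal(seg$t[1], 0)
  # pure ramp: no hold window
  t <- seq(0, 2, by = 0.001)
  ramp <- force_curve(t, z = 4 * t, force = t)
  expect_error(segment_relaxation(ramp), "hold window|shorter")
  # hold-only record: the whole record is the window
  holdonly <- force_curve(t, z = 1, force = exp(-t))
  seg2 <- segment_relaxation(holdonly)
  expect_length(seg2$idx, length(t))
})

test_that("filtering and segmentation commute away from window edges", {
  p <- table1_means("Neuro-2a")
  rec <- generate_full_indentation(p)
  seg_then_filt <- lowpass(segment_relaxation(rec)$y, rec$fs)
  filt_then_seg <- segment_relaxation(
    force_curve(rec$t, rec$z, force = lowpass(rec$force, rec$fs)))$y
  n <- min(length(seg_then_filt), length(filt_then_seg))
  margin <- round(0.5 * rec$fs)          # 0.5 s guard on both sides
  core <- seq.int(margin, n - margin)
  scale <- max(abs(seg_then_filt))
  expect_lt(max(abs(seg_then_filt[core] - filt_then_seg[core])) / scale, 1e-3)
})
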