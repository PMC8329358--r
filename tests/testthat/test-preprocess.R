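sine_rec <- function(freq, srate = 250, dur = 60, amp = 1, dc = 0,
                     channels = "F3") {
  t <- seq(0, dur - 1 / srate, by = 1 / srate)
  x <- amp * sin(2 * pi * freq * t) + dc
  dat <- matrix(rep(x, each = length(channels)), nrow = length(channels),
                dimnames = list(channels, NULL))
  eeg_recording(dat, srate)
}

interior <- function(rec, margin_s = 5) {
  n <- ncol(rec$data)
  m <- round(margin_s * rec$srate)
  rec$data[, m:(n - m), drop = FALSE]
}

test_that("band-pass passes the alpha band and stops DC and 60 Hz", {
  r10 <- bandpass_filter(sine_rec(10), 0.1, 30)
  amp10 <- sd(interior(r10)) * sqrt(2)
  expect_lt(abs(amp10 - 1), 0.01)

  r60 <- bandpass_filter(sine_rec(60, srate = 250), 0.1, 30)
  expect_lt(max(abs(interior(r60))), 0.05)
  # zero-phase squared-magnitude response of an order-4 low-pass at 30 Hz
  expected_gain <- 1 / (1 + (60 / 30)^8)
  expect_lt(abs(sd(interior(r60)) * sqrt(2) - expected_gain),
            0.1 * expected_gain)

  rdc <- bandpass_filter(sine_rec(10, dc = 10), 0.1, 30)
  expect_lt(abs(mean(interior(rdc))), 0.05)

  # the broad acquisition band is numerically healthy at a 0.01 Hz corner
  rb <- bandpass_filter(sine_rec(10, srate = 500), 0.01, 70)
  expect_lt(abs(sd(interior(rb)) * sqrt(2) - 1), 0.01)

  expect_error(bandpass_filter(sine_rec(10), 40, 200), "Nyquist")
})

test_that("downsampling keeps in-band content and rescales markers", {
  rec <- sine_rec(10, srate = 500, dur = 30)
  rec$markers <- tibble::tibble(type = "Stimulus", description = "t/r/g",
                                onset_sample = 1000L)
  dn <- downsample(rec, 2)
  expect_equal(dn$srate, 250)
  expect_equal(dn$markers$onset_sample, 500L)
  expect_equal(ncol(dn$data), ceiling(ncol(rec$data) / 2))

  sp <- power_spectrum(interior(dn)[1, 1:500], 250)
  pk <- sp$freq[which.max(sp$density)]
  expect_equal(pk, 10)

  # broadband noise above the new Nyquist is removed before decimation
  set.seed(1)
  wn <- eeg_recording(matrix(rnorm(500 * 30), 1,
                             dimnames = list("F3", NULL)), 500)
  dwn <- downsample(wn, 2)
  spw <- power_spectrum(dwn$data[1, 2001:2500], 250)
  hi <- band_auc(spw, 110, 124)
  lo <- band_auc(spw, 10, 24)
  expect_lt(hi, 0.25 * lo)

  expect_error(downsample(rec, 1.5), "integer")
})

test_that("re-referencing zeroes Cz, keeps F4-F3, and is idempotent", {
  set.seed(2)
  dat <- matrix(rnorm(4 * 1000), 4,
                dimnames = list(c("F3", "F4", "Cz", "VEOG"), NULL))
  rec <- eeg_recording(dat, 250)
  rr <- rereference(rec, "Cz")
  expect_true(all(rr$data["Cz", ] == 0))
  expect_equal(rr$data["F4", ] - rr$data["F3", ],
               rec$data["F4", ] - rec$data["F3", ])
  # EOG is left untouched
  expect_equal(rr$data["VEOG", ], rec$data["VEOG", ])
  rr2 <- rereference(rr, "Cz")
  expect_equal(rr2$data, rr$data)
  expect_error(rereference(rec, "Pz"), "not present")
})

test_that("ocular regression recovers the propagation factor on clean blinks", {
  spec <- tiny_spec(blink_rate = 12)
  rec <- synthesize_recording(flat_cells(0), tiny_events(), spec, seed = 31)
  peaks <- rec$meta$blink_log$peak_sample
  expect_gt(length(peaks), 1)

  corr <- correct_ocular(rec)
  expect_true(all(abs(corr$meta$eog_b[c("F3", "F4", "Fz")] -
                        spec$blink_propagation) < 0.01))
  # residual frontal blink amplitude < 2% of the propagated original
  resid <- max(abs(corr$data["Fz", peaks]))
  expect_lt(resid, 0.02 * spec$blink_propagation * spec$blink_amplitude)

  # zero EOG: unchanged with a note
  quiet <- synthesize_recording(flat_cells(0), tiny_events(),
                                tiny_spec(), seed = 32)
  expect_message(out <- correct_ocular(quiet), "zero variance")
  expect_equal(out$data, quiet$data)
})

test_that("propagation zero estimates a near-zero coefficient", {
  spec <- tiny_spec(blink_rate = 12, blink_propagation = 0,
                    blink_amplitude = 500, noise_rms = 1)
  rec <- synthesize_recording(flat_cells(0), tiny_events(), spec, seed = 33)
  corr <- correct_ocular(rec)
  expect_true(all(abs(corr$meta$eog_b[c("F3", "F4", "Fz")]) < 0.02))
  expect_lt(max(abs(corr$data["Fz", ] - rec$data["Fz", ])), 2)
})

test_that("the preprocessing chain records its fixed order", {
  spec <- tiny_spec(noise_rms = 1, blink_rate = 6)
  rec <- synthesize_recording(flat_cells(0), tiny_events(), spec, seed = 41)
  segs <- suppressMessages(preprocess_recording(rec))
  expect_equal(
    segs$meta$pipeline,
    c("synthesize", "bandpass(0.01-70)", "downsample(2)",
      "ocular(regression)", "rereference(Cz)", "bandpass(0.1-30)",
      "segment", "baseline", "reject(80)")
  )
})
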