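make_marked_rec <- function(n_trials = 10, srate = 250, gap_s = 2.5,
                            value = 0) {
  n <- round((n_trials * gap_s + 4) * srate)
  dat <- matrix(value, 3, n, dimnames = list(c("F3", "F4", "Cz"), NULL))
  onsets <- as.integer(round((seq_len(n_trials) - 1) * gap_s * srate)) + srate
  eeg_recording(dat, srate, markers = tibble::tibble(
    type = "Stimulus",
    description = rep(c("threat/relevant/go", "neutral/irrelevant/nogo"),
                      length.out = n_trials),
    onset_sample = onsets
  ))
}

test_that("segmentation yields one labelled 2-s segment per fitting trial", {
  rec <- make_marked_rec(10)
  segs <- segment_recording(rec)
  expect_equal(nrow(segs$info), 10L)
  expect_equal(dim(segs$data)[2], 500L)
  expect_equal(segs$n_skipped, 0L)
  expect_equal(sum(segs$info$emotion == "threat"), 5L)

  # a trial starting 1.5 s before the end is skipped and reported
  rec2 <- make_marked_rec(10)
  late <- as.integer(ncol(rec2$data) - round(1.5 * 250))
  rec2$markers <- dplyr::bind_rows(
    rec2$markers,
    tibble::tibble(type = "Stimulus", description = "threat/relevant/go",
                   onset_sample = late)
  )
  expect_message(segs2 <- segment_recording(rec2), "skipped")
  expect_equal(segs2$n_skipped, 1L)
  expect_equal(nrow(segs2$info), 10L)

  # conservation: in = kept + rejected + skipped
  segs2 <- reject_artifacts(baseline_correct(segs2))
  expect_equal(nrow(rec2$markers),
               sum(!segs2$info$rejected) + sum(segs2$info$rejected) +
                 segs2$n_skipped)
})

test_that("segment condition counts match the event plan", {
  spec <- tiny_spec()
  events <- tiny_events()
  rec <- synthesize_recording(flat_cells(0), events, spec, seed = 8)
  segs <- segment_recording(downsample(rec, 2))
  plan_counts <- dplyr::count(events, emotion, relevance, response)
  seg_counts <- dplyr::count(segs$info, emotion, relevance, response)
  expect_equal(seg_counts$n, plan_counts$n)
})

test_that("baseline correction subtracts the first-200-ms mean", {
  rec <- make_marked_rec(4, value = 5)
  segs <- baseline_correct(segment_recording(rec))
  expect_true(all(segs$data == 0))

  # a +10 uV step at 1 s survives baseline correction untouched
  rec2 <- make_marked_rec(4)
  on <- rec2$markers$onset_sample[1]
  step_start <- on + 250L
  rec2$data[, (step_start + 1):ncol(rec2$data)] <- 10
  segs2 <- baseline_correct(segment_recording(rec2))
  expect_equal(as.numeric(segs2$data[1, 400, 1]), 10)
  expect_equal(as.numeric(segs2$data[1, 10, 1]), 0)

  # already zero-mean baseline: unchanged
  rec3 <- make_marked_rec(4)
  set.seed(1)
  x <- rnorm(ncol(rec3$data))
  for (on in rec3$markers$onset_sample) {
    x[(on + 1):(on + 50)] <- x[(on + 1):(on + 50)] -
      mean(x[(on + 1):(on + 50)])
  }
  rec3$data[1, ] <- x
  raw <- segment_recording(rec3)
  segs3 <- baseline_correct(raw)
  expect_equal(segs3$data[1, , ], raw$data[1, , ], tolerance = 1e-12)
})

test_that("amplitude rejection is strict at +/- 80 uV", {
  rec <- make_marked_rec(3)
  on <- rec$markers$onset_sample
  rec$data["F3", on[1] + 100] <- 81    # strictly above
  rec$data["F4", on[2] + 100] <- 80    # exactly at the limit
  rec$data["F3", on[3] + 100] <- -81   # strictly below
  segs <- reject_artifacts(segment_recording(rec))
  expect_identical(segs$info$rejected, c(TRUE, FALSE, TRUE))
  expect_identical(segs$info$reason, c("amplitude", "none", "amplitude"))
})

test_that("uncorrected blinks are rejected; corrected blinks are retained", {
  spec <- tiny_spec(blink_rate = 20, noise_rms = 0)
  events <- tiny_events()
  rec <- synthesize_recording(flat_cells(0), events, spec, seed = 13)
  peaks <- rec$meta$blink_log$peak_sample
  expect_gt(nrow(rec$meta$blink_log), 2)

  blink_epochs <- which(vapply(seq_len(nrow(rec$markers)), function(i) {
    on <- rec$markers$onset_sample[i]
    any(peaks >= on & peaks < on + 1000)
  }, logical(1)))
  expect_gt(length(blink_epochs), 0)

  # epochs with no blink activity even near their edges stay clean
  near_epochs <- which(vapply(seq_len(nrow(rec$markers)), function(i) {
    on <- rec$markers$onset_sample[i]
    any(peaks >= on - 200 & peaks < on + 1200)
  }, logical(1)))

  # correction disabled: every blink-peak-containing epoch trips the rule
  segs_off <- suppressMessages(preprocess_recording(rec, ocular = "none"))
  expect_true(all(segs_off$info$rejected[blink_epochs]))
  expect_true(all(!segs_off$info$rejected[-near_epochs]))

  # regression correction on noiseless blinks retains >= 98% of them
  segs_on <- suppressMessages(preprocess_recording(rec, ocular = "regression"))
  retained <- mean(!segs_on$info$rejected[blink_epochs])
  expect_gte(retained, 0.98)
})
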