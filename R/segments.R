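#' Cut a continuous recording into condition-labelled 2-s segments
#'
#' Creates one segment per stimulus marker, starting at the marker (the
#' triangle onset) and extending `duration_s` seconds (half-open sample
#' interval `[onset, onset + duration * srate)`). The marker description is
#' decoded into the condition tuple (emotion, relevance, response type).
#' Trials too close to the end of the recording are skipped and counted.
#'
#' @param rec An [eeg_recording()] whose stimulus markers carry
#'   `emotion/relevance/response` descriptions.
#' @param duration_s Segment length in seconds (default 2).
#' @return An object of class `segment_set`: segment sample array
#'   (channels x samples x segments), an `info` tibble (condition tuple,
#'   onset, `rejected` flag, `reason`), the channel labels and rate, and
#'   the skip count. Pipeline provenance is carried over from the
#'   recording.
#' @export
segment_recording <- function(rec, duration_s = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  stim <- rec$markers[rec$markers$type == "Stimulus", ]
  cond <- decode_condition(stim$description)
  if (anyNA(cond$emotion)) {
    abort("Some stimulus markers do not decode to emotion/relevance/response.")
  }
  len <- round(duration_s * rec$srate)
  n <- ncol(rec$data)
  fits <- stim$onset_sample + len <= n
  n_skipped <- sum(!fits)
  if (n_skipped > 0) {
    inform(sprintf("%d trial(s) too close to the recording end were skipped.",
                   n_skipped))
  }
  stim <- stim[fits, ]
  cond <- cond[fits, ]
  arr <- array(
    0, dim = c(nrow(rec$data), len, nrow(stim)),
    dimnames = list(rec$channels, NULL, NULL)
  )
  for (i in seq_len(nrow(stim))) {
    arr[, , i] <- rec$data[, stim$onset_sample[i] + seq_len(len), drop = FALSE]
  }
  structure(
    list(
      data = arr,
      info = tibble(
        segment = seq_len(nrow(stim)),
        emotion = cond$emotion,
        relevance = cond$relevance,
        response = cond$response,
        onset_sample = stim$onset_sample,
        rejected = FALSE,
        reason = "none"
      ),
      channels = rec$channels,
      srate = rec$srate,
      n_skipped = n_skipped,
      meta = utils::modifyList(
        rec$meta, list(pipeline = c(rec$meta$pipeline, "segment"))
      )
    ),
    class = "segment_set"
  )
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf(
    "<segment_set> %d segments (%d rejected, %d skipped), %d ch x %d samples @ %g Hz\n",
    nrow(x$info), sum(x$info$rejected), x$n_skipped,
    dim(x$data)[1], dim(x$data)[2], x$srate
  ))
  invisible(x)
}

#' Baseline-correct segments to their first 200 ms
#'
#' Subtracts, per channel and segment, the mean of the samples in the
#' baseline window `[0, window_s)` at the start of the segment.
#'
#' @param segs A `segment_set`.
#' @param window_s Baseline window length in seconds (default 0.2).
#' @return The baseline-corrected `segment_set`.
#' @export
baseline_correct <- function(segs, window_s = 0.2) {
  stopifnot(inherits(segs, "segment_set"))
  nb <- round(window_s * segs$srate)
  if (nb < 1 || nb > dim(segs$data)[2]) {
    abort("Baseline window must fit inside the segment.")
  }
  base <- apply(segs$data[, seq_len(nb), , drop = FALSE], c(1, 3), mean)
  segs$data <- sweep(segs$data, c(1, 3), base, "-")
  segs$meta$pipeline <- c(segs$meta$pipeline, "baseline")
  segs
}

#' Flag segments exceeding the amplitude rejection threshold
#'
#' A segment is rejected iff any sample on any analysis channel is strictly
#' above `+limit` or strictly below `-limit` (a sample at exactly the limit
#' is kept). Analysis channels default to all EEG channels except those the
#' pipeline has excluded (the EOG after ocular correction) — whole-segment
#' rejection on all EEG channels. Rejected segments keep their data but are
#' excluded from all downstream averaging; counts per condition are
#' reported in the attribute `rejection_counts`.
#'
#' @param segs A baseline-corrected `segment_set`.
#' @param limit Threshold in uV (default 80).
#' @param channels Channels to screen (default: all except EOG/excluded).
#' @return The `segment_set` with updated `rejected`/`reason` flags.
#' @export
reject_artifacts <- function(segs, limit = 80,
                             channels = NULL) {
  stopifnot(inherits(segs, "segment_set"))
  if (is.null(channels)) {
    channels <- setdiff(segs$channels,
                        c(segs$meta$excluded_channels, "VEOG"))
  }
  sub <- segs$data[channels, , , drop = FALSE]
  mx <- apply(sub, 3, max)
  mn <- apply(sub, 3, min)
  bad <- mx > limit | mn < -limit
  segs$info$rejected <- segs$info$rejected | bad
  segs$info$reason[bad & segs$info$reason == "none"] <- "amplitude"
  counts <- dplyr::count(
    dplyr::filter(segs$info, .data$rejected),
    .data$emotion, .data$relevance,
    name = "n_rejected"
  )
  segs$meta$rejection_counts <- counts
  segs$meta$pipeline <- c(segs$meta$pipeline, sprintf("reject(%g)", limit))
  segs
}

#' Run the full preprocessing chain on a continuous recording
#'
#' Applies, in the fixed order the methodology prescribes:
#' broad band-pass 0.01–70 Hz -> downsample to 250 Hz -> ocular regression
#' correction -> re-reference to Cz -> band-pass 0.1–30 Hz -> 2-s
#' segmentation at stimulus markers -> 200-ms baseline correction ->
#' +/- 80 uV artifact rejection. The order is recorded in the provenance
#' metadata (`meta$pipeline`).
#'
#' @param rec A raw [eeg_recording()] at 500 Hz.
#' @param ocular One of "regression" (default) or "none".
#' @param reject_limit Amplitude threshold in uV (default 80).
#' @param target_srate Rate after decimation (default 250 Hz).
#' @return A `segment_set` ready for spectral analysis.
#' @export
preprocess_recording <- function(rec, ocular = c("regression", "none"),
                                 reject_limit = 80, target_srate = 250) {
  ocular <- match.arg(ocular)
  factor <- rec$srate / target_srate
  if (factor != round(factor)) {
    abort("`target_srate` must divide the sampling rate.")
  }
  rec <- bandpass_filter(rec, 0.01, 70, order = 4)
  rec <- downsample(rec, as.integer(factor))
  if (ocular == "regression" && "VEOG" %in% rec$channels) {
    rec <- correct_ocular(rec, "VEOG")
  } else {
    rec$meta$excluded_channels <- union(rec$meta$excluded_channels, "VEOG")
  }
  rec <- rereference(rec, "Cz")
  rec <- bandpass_filter(rec, 0.1, 30, order = 4,
                         channels = setdiff(rec$channels, "VEOG"))
  segs <- segment_recording(rec, duration_s = 2)
  segs <- baseline_correct(segs, window_s = 0.2)
  reject_artifacts(segs, limit = reject_limit)
}
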