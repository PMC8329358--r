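#' Zero-phase Butterworth band-pass filter
#'
#' Applies, per channel, the forward–backward (zero-phase) response of an
#' order-`order` Butterworth band-pass: the squared magnitude
#' `|H(f)|^2 = [1 + (f_lo/f)^(2n)]^-1 * [1 + (f/f_hi)^(2n)]^-1`
#' evaluated on the FFT grid and applied in the frequency domain. This is
#' the exact transfer function a forward–backward time-domain Butterworth
#' cascade realises, computed in a form that stays numerically exact even
#' for corners far below the sampling rate (e.g. 0.01 Hz at 500 Hz), where
#' transfer-function coefficient filtering breaks down. Markers are
#' unchanged. A `low_hz` of 0 gives a pure low-pass.
#'
#' @param rec An [eeg_recording()].
#' @param low_hz,high_hz Corner frequencies in Hz (`0 <= low < high <`
#'   Nyquist).
#' @param order Butterworth order of each (single-pass) edge (default 4).
#' @param channels Channels to filter (default: all).
#' @return The filtered recording.
#' @export
bandpass_filter <- function(rec, low_hz, high_hz, order = 4,
                            channels = rec$channels) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$srate / 2
  if (low_hz < 0 || low_hz >= high_hz || high_hz >= nyq) {
    abort(sprintf("Band [%g, %g] must satisfy 0 <= low < high < Nyquist (%g).",
                  low_hz, high_hz, nyq))
  }
  n <- ncol(rec$data)
  npad <- stats::nextn(n, factors = 2)
  k <- seq_len(npad) - 1
  f <- pmin(k, npad - k) * rec$srate / npad     # two-sided frequency axis
  gain <- 1 / (1 + (f / high_hz)^(2 * order))
  if (low_hz > 0) {
    fr <- f
    fr[fr == 0] <- .Machine$double.xmin
    gain <- gain / (1 + (low_hz / fr)^(2 * order))
  }
  for (ch in channels) {
    x <- rec$data[ch, ]
    # pad by edge reflection to limit circular wrap-around
    xp <- c(x, rev(x)[seq_len(npad - n)])
    y <- Re(fft(fft(xp) * gain, inverse = TRUE)) / npad
    rec$data[ch, ] <- y[seq_len(n)]
  }
  note_step(rec, sprintf("bandpass(%g-%g)", low_hz, high_hz))
}

#' Downsample a recording by an integer factor
#'
#' Applies a zero-phase anti-alias low-pass (Butterworth magnitude, corner
#' at 0.8x the new Nyquist) and keeps every `factor`-th sample. Marker
#' sample indices are rescaled by floor division (0-based).
#'
#' @param rec An [eeg_recording()].
#' @param factor Positive integer decimation factor.
#' @return The downsampled recording.
#' @export
downsample <- function(rec, factor) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (length(factor) != 1L || factor != round(factor) || factor < 1) {
    abort("`factor` must be a positive integer.")
  }
  factor <- as.integer(factor)
  if (factor == 1L) return(note_step(rec, "downsample(1)"))
  new_srate <- rec$srate / factor
  rec <- bandpass_filter(rec, 0, 0.8 * new_srate / 2, order = 8)
  keep <- seq(1, ncol(rec$data), by = factor)
  rec$data <- rec$data[, keep, drop = FALSE]
  rec$srate <- new_srate
  rec$markers$onset_sample <- rec$markers$onset_sample %/% factor
  # drop the anti-alias note; record the composite step
  rec$meta$pipeline <- head(rec$meta$pipeline, -1)
  note_step(rec, sprintf("downsample(%d)", factor))
}

#' Re-reference all channels to a single electrode
#'
#' Subtracts the reference channel's signal from every channel; the
#' reference channel itself becomes identically zero and is retained. The
#' operation is idempotent. EOG channels are left untouched (they are not
#' referenced to the scalp montage).
#'
#' @param rec An [eeg_recording()].
#' @param ref_channel Reference electrode label (default "Cz").
#' @param exclude Channels not to re-reference (default "VEOG").
#' @return The re-referenced recording.
#' @export
rereference <- function(rec, ref_channel = "Cz", exclude = "VEOG") {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!ref_channel %in% rec$channels) {
    abort(sprintf("Reference channel %s not present.", ref_channel))
  }
  ref <- rec$data[ref_channel, ]
  for (ch in setdiff(rec$channels, exclude)) {
    rec$data[ch, ] <- rec$data[ch, ] - ref
  }
  note_step(rec, sprintf("rereference(%s)", ref_channel))
}

#' Regression-based ocular artifact correction
#'
#' Removes blink activity by subtracting, per EEG channel, `b * EOG` where
#' `b` is the least-squares regression coefficient of the channel on the
#' EOG channel, estimated over blink-containing windows (samples where the
#' EOG deviates from its median by more than 3x the median absolute
#' deviation, dilated by 150 ms on each side). Estimating `b` only on
#' blink windows keeps ongoing EEG from biasing the coefficient. The EOG
#' channel is flagged in the metadata as excluded from analysis. If the
#' EOG has (near) zero variance the recording is returned unchanged with a
#' note.
#'
#' @param rec An [eeg_recording()].
#' @param eog_channel EOG channel label (default "VEOG").
#' @return The corrected recording; `meta$eog_b` stores the per-channel
#'   coefficients.
#' @export
correct_ocular <- function(rec, eog_channel = "VEOG") {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!eog_channel %in% rec$channels) {
    abort(sprintf("EOG channel %s not present.", eog_channel))
  }
  eog <- rec$data[eog_channel, ]
  s <- stats::mad(eog)
  if (s == 0 && var(eog) == 0) {
    inform("EOG channel has zero variance; no ocular correction applied.")
    rec$meta$excluded_channels <- union(rec$meta$excluded_channels, eog_channel)
    return(note_step(rec, "ocular(none)"))
  }
  dev <- abs(eog - median(eog))
  thr <- if (s > 0) 3 * s else 3 * sd(eog)
  win <- dev > thr
  if (any(win)) {
    # dilate detection by 150 ms to cover whole blink waveforms
    r <- round(0.15 * rec$srate)
    idx <- which(win)
    lo <- pmax(idx - r, 1L)
    hi <- pmin(idx + r, length(win))
    win <- logical(length(win))
    for (j in seq_along(idx)) win[lo[j]:hi[j]] <- TRUE
  } else {
    win <- rep(TRUE, length(eog))    # no blinks detected: global regression
  }
  e <- eog[win]
  e_c <- e - mean(e)
  denom <- sum(e_c^2)
  b <- numeric(0)
  for (ch in setdiff(rec$channels, eog_channel)) {
    x <- rec$data[ch, win]
    bi <- sum((x - mean(x)) * e_c) / denom
    rec$data[ch, ] <- rec$data[ch, ] - bi * eog
    b[ch] <- bi
  }
  rec$meta$eog_b <- b
  rec$meta$excluded_channels <- union(rec$meta$excluded_channels, eog_channel)
  note_step(rec, "ocular(regression)")
}
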