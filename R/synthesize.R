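#' Invert the FAA definition into a pair of alpha powers
#'
#' Given a target FAA (ln-ratio) and the alpha power to place at F3,
#' returns the F3/F4 power pair that reproduces the target exactly under
#' FAA = ln(F4) - ln(F3).
#'
#' @param target_faa Target asymmetry, a dimensionless ln-ratio (vectorised).
#' @param base_power_f3 Alpha power at F3 in uV^2 (> 0).
#' @return Tibble with columns `f3`, `f4` (uV^2).
#' @export
#' @examples
#' amplitudes_for_faa(log(2), 1)   # f4 = 2 f3
amplitudes_for_faa <- function(target_faa, base_power_f3) {
  if (any(base_power_f3 <= 0)) abort("`base_power_f3` must be > 0.")
  tibble(f3 = base_power_f3 + 0 * target_faa,
         f4 = base_power_f3 * exp(target_faa))
}

# 1/f (pink) noise with unit RMS, via spectral shaping of white noise.
pink_noise <- function(n) {
  n2 <- stats::nextn(n, factors = 2)
  x <- rnorm(n2)
  X <- fft(x)
  f <- c(1, seq_len(n2 - 1))            # avoid DC singularity
  f <- pmin(f, n2 - f + 1)              # symmetric over conjugate half
  X <- X / sqrt(f)
  X[1] <- 0
  y <- Re(fft(X, inverse = TRUE)) / n2
  y <- y[seq_len(n)]
  y / sd(y)
}

# Hann-shaped blink pulse, width in samples, unit peak.
blink_pulse <- function(width) {
  i <- seq_len(width) - 1
  0.5 - 0.5 * cos(2 * pi * i / (width - 1))
}

# Calibration factor relating a requested alpha-band AUC to the squared
# oscillation amplitude, accounting for the Hann amplitude envelope applied
# at generation and the Hann analysis taper of the periodogram:
#   AUC ~ (A^2 / 2) * sum(w^2 h^2) / sum(w^2)
# where w is the 500-sample analysis taper at 250 Hz and h the generation
# envelope restricted to the same grid. Amplitude A = sqrt(2 * P * k).
alpha_calibration_factor <- function(epoch_samples_hi = 1000L, decim = 2L) {
  h <- 0.5 - 0.5 * cos(2 * pi * (seq_len(epoch_samples_hi) - 1) /
    (epoch_samples_hi - 1))
  h_d <- h[seq(1, epoch_samples_hi, by = decim)]
  n_lo <- length(h_d)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n_lo) - 1) / (n_lo - 1))
  sum(w^2) / sum(w^2 * h_d^2)
}

#' Synthesise a continuous EEG recording for one subject
#'
#' Builds a 500 Hz recording over the minimal montage {F3, F4, Fz, Cz,
#' VEOG}. During each trial's 2-s analysis window, F3 and F4 carry an
#' alpha-frequency oscillation with a Hann amplitude envelope and random
#' per-trial phase; the per-channel amplitudes are calibrated (closed form,
#' see [amplitudes_for_faa()]) so that the analysis pipeline's alpha-band
#' area under the curve on a clean signal equals the requested power, making
#' the recovered FAA equal the cell's target. Pink noise is superposed on
#' every EEG channel; blinks are Poisson events appearing on VEOG at full
#' amplitude and on frontal channels (F3, F4, Fz) scaled by the propagation
#' factor. The marker stream encodes the event plan exactly (one marker per
#' trial, description `emotion/relevance/response`).
#'
#' @param subject_cells One subject's rows of [simulate_subject_scores()]
#'   (four emotion x relevance cells with `faa_target`), or a tibble with
#'   columns `emotion`, `relevance`, `faa_target` (a `subject_id` column is
#'   carried into the metadata when present).
#' @param events Event plan from [generate_task_events()].
#' @param spec A [cohort_spec()] supplying the signal model.
#' @param seed Integer seed for noise, phases and blinks.
#' @return An [eeg_recording()] with `meta$blink_log` (tibble of blink peak
#'   samples) and `meta$subject_id`.
#' @export
synthesize_recording <- function(subject_cells, events, spec, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  need <- c("emotion", "relevance", "faa_target")
  if (!all(need %in% names(subject_cells))) {
    abort("`subject_cells` needs columns emotion, relevance, faa_target.")
  }
  local_seed(as.integer(seed))

  srate <- 500
  epoch_n <- 2 * srate
  n <- ceiling((max(events$onset_s) + 2 + 1) * srate)
  channels <- c("F3", "F4", "Fz", "Cz", "VEOG")
  dat <- matrix(0, nrow = length(channels), ncol = n,
                dimnames = list(channels, NULL))

  # pink background on EEG channels, weaker white noise on VEOG
  if (spec$noise_rms > 0) {
    for (ch in c("F3", "F4", "Fz", "Cz")) {
      dat[ch, ] <- spec$noise_rms * pink_noise(n)
    }
    dat["VEOG", ] <- 0.25 * spec$noise_rms * rnorm(n)
  }

  # alpha bursts per trial, amplitude set by the cell's realised FAA target
  k_cal <- alpha_calibration_factor(epoch_n, 2L)
  env <- 0.5 - 0.5 * cos(2 * pi * (seq_len(epoch_n) - 1) / (epoch_n - 1))
  tvec <- (seq_len(epoch_n) - 1) / srate
  cells <- dplyr::distinct(
    subject_cells, .data$emotion, .data$relevance, .data$faa_target
  )
  pow <- amplitudes_for_faa(cells$faa_target, spec$base_power_f3)
  cells$amp_f3 <- sqrt(2 * pow$f3 * k_cal)
  cells$amp_f4 <- sqrt(2 * pow$f4 * k_cal)

  ev <- dplyr::left_join(events, cells, by = c("emotion", "relevance"))
  if (anyNA(ev$amp_f3)) abort("`subject_cells` is missing a condition cell present in `events`.")
  onset_smp <- round(ev$onset_s * srate)
  for (i in seq_len(nrow(ev))) {
    idx <- onset_smp[i] + seq_len(epoch_n)   # 1-based span of the window
    ph3 <- runif(1, 0, 2 * pi)
    ph4 <- runif(1, 0, 2 * pi)
    carrier <- 2 * pi * spec$alpha_freq * tvec
    dat["F3", idx] <- dat["F3", idx] + ev$amp_f3[i] * env * sin(carrier + ph3)
    dat["F4", idx] <- dat["F4", idx] + ev$amp_f4[i] * env * sin(carrier + ph4)
  }

  # Poisson blinks: VEOG at full amplitude, frontal channels attenuated
  blink_log <- tibble(peak_sample = integer(), peak_s = numeric())
  if (spec$blink_rate > 0) {
    n_blinks <- rpois(1, spec$blink_rate * (n / srate) / 60)
    if (n_blinks > 0) {
      width <- round(0.3 * srate)
      pulse <- blink_pulse(width)
      peaks <- sort(sample.int(n - width, n_blinks))
      for (p in peaks) {
        idx <- p + seq_len(width) - round(width / 2)
        keep <- idx >= 1 & idx <= n
        dat["VEOG", idx[keep]] <- dat["VEOG", idx[keep]] +
          spec$blink_amplitude * pulse[keep]
        for (ch in c("F3", "F4", "Fz")) {
          dat[ch, idx[keep]] <- dat[ch, idx[keep]] +
            spec$blink_propagation * spec$blink_amplitude * pulse[keep]
        }
      }
      blink_log <- tibble(peak_sample = peaks, peak_s = peaks / srate)
    }
  }

  markers <- tibble(
    type = "Stimulus",
    description = paste(ev$emotion, ev$relevance, ev$response, sep = "/"),
    onset_sample = as.integer(onset_smp)
  )
  eeg_recording(
    dat, srate,
    markers = markers,
    meta = list(
      subject_id = if ("subject_id" %in% names(subject_cells)) {
        subject_cells$subject_id[1]
      } else {
        NA_character_
      },
      blink_log = blink_log,
      seed = as.integer(seed),
      pipeline = "synthesize"
    )
  )
}

# decode "emotion/relevance/response" marker descriptions
decode_condition <- function(description) {
  parts <- strsplit(description, "/", fixed = TRUE)
  ok <- lengths(parts) == 3L
  tibble(
    emotion = ifelse(ok, vapply(parts, `[`, "", 1L), NA_character_),
    relevance = ifelse(ok, vapply(parts, `[`, "", 2L), NA_character_),
    response = ifelse(ok, vapply(parts, `[`, "", 3L), NA_character_)
  )
}
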