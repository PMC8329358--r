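#' Hann-windowed periodogram of a segment
#'
#' Single-taper periodogram with a Hann window, one-sided, normalised as a
#' power spectral density (uV^2/Hz) with the window power compensated:
#' the rectangle-rule integral of the density over `[0, Nyquist]` equals
#' `sum((w x)^2) / sum(w^2)`, the Parseval-consistent mean square of the
#' windowed signal. With a 2-s segment the frequency resolution is 0.5 Hz,
#' so the 8 and 12 Hz band edges fall exactly on grid points.
#'
#' @param x Numeric vector (one channel) or channels x samples matrix.
#' @param srate Sampling rate in Hz.
#' @return A tibble with columns `channel`, `freq` (Hz) and `density`
#'   (uV^2/Hz), of class `power_spectrum`.
#' @export
power_spectrum <- function(x, srate) {
  if (is.vector(x)) x <- matrix(x, nrow = 1, dimnames = list("x", NULL))
  assert_scalar_number(srate, "srate", positive = TRUE)
  n <- ncol(x)
  if (n < 4) abort("Segment too short for a periodogram.")
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  n_freq <- n %/% 2 + 1
  freq <- (seq_len(n_freq) - 1) * srate / n
  scale <- 1 / (srate * sum(w^2))
  chans <- rownames(x) %||% as.character(seq_len(nrow(x)))
  dens <- matrix(0, nrow(x), n_freq)
  for (i in seq_len(nrow(x))) {
    X <- fft(w * x[i, ])[seq_len(n_freq)]
    p <- scale * (Mod(X)^2)
    # one-sided: double everything except DC (and Nyquist when n is even)
    dbl <- rep(2, n_freq)
    dbl[1] <- 1
    if (n %% 2 == 0) dbl[n_freq] <- 1
    dens[i, ] <- p * dbl
  }
  out <- tibble(
    channel = rep(chans, each = n_freq),
    freq = rep(freq, times = nrow(x)),
    density = as.vector(t(dens))
  )
  class(out) <- c("power_spectrum", class(out))
  out
}

#' Alpha-band area under the curve of a power spectrum
#'
#' Trapezoidal integral of the spectral density over `[lo, hi]`, endpoints
#' included (with a 0.5 Hz grid the 8.0 and 12.0 Hz bins are in the band).
#' A degenerate band (`lo == hi`) integrates to zero.
#'
#' @param spec A `power_spectrum` tibble.
#' @param lo,hi Band edges in Hz (default 8 and 12).
#' @return Named numeric vector of band power (uV^2), one entry per channel.
#' @export
band_auc <- function(spec, lo = 8, hi = 12) {
  freqs <- unique(spec$freq)
  if (lo > hi || lo < min(freqs) || hi > max(freqs)) {
    abort("Band must lie within the frequency grid.")
  }
  out <- vapply(split(spec, factor(spec$channel, unique(spec$channel))),
    function(d) {
      inb <- d$freq >= lo & d$freq <= hi
      f <- d$freq[inb]
      p <- d$density[inb]
      if (length(f) < 2) return(0)
      sum(diff(f) * (head(p, -1) + tail(p, -1)) / 2)
    }, numeric(1)
  )
  out
}

#' Per-subject alpha power by electrode and condition
#'
#' For each electrode and emotion x relevance condition (go/nogo pooled),
#' averages the per-segment alpha-band AUC over non-rejected segments and
#' takes the natural log of the mean (log-after-average). Cells with fewer
#' than `min_segments` contributing segments are marked missing; the AUC is
#' floored at `1e-12` uV^2 before the log to guard degenerate input.
#'
#' @param segs A preprocessed `segment_set`.
#' @param electrodes Electrodes to tabulate (default F3 and F4).
#' @param band Alpha band in Hz (default `c(8, 12)`).
#' @param min_segments Minimum contributing segments per cell (default 10).
#' @param subject_id Subject label for the table (default from metadata).
#' @return Tibble: `subject`, `electrode`, `emotion`, `relevance`, `auc`,
#'   `ln_auc`, `n_segments`, `missing`.
#' @export
condition_alpha_table <- function(segs, electrodes = c("F3", "F4"),
                                  band = c(8, 12), min_segments = 10,
                                  subject_id = NULL) {
  stopifnot(inherits(segs, "segment_set"))
  miss_el <- setdiff(electrodes, segs$channels)
  if (length(miss_el) > 0) {
    abort(sprintf("Electrode(s) not in montage: %s",
                  paste(miss_el, collapse = ", ")))
  }
  subject_id <- subject_id %||% segs$meta$subject_id %||% "subject"

  kept <- which(!segs$info$rejected)
  per_seg <- purrr::map_dfr(kept, function(i) {
    x <- segs$data[electrodes, , i]
    if (is.null(dim(x))) {
      x <- matrix(x, nrow = 1, dimnames = list(electrodes, NULL))
    }
    sp <- power_spectrum(x, segs$srate)
    auc <- band_auc(sp, band[1], band[2])
    tibble(
      segment = i,
      electrode = names(auc),
      auc = unname(auc),
      emotion = segs$info$emotion[i],
      relevance = segs$info$relevance[i]
    )
  })

  grid <- tidyr::expand_grid(
    electrode = electrodes,
    emotion = sort(unique(segs$info$emotion)),
    relevance = sort(unique(segs$info$relevance))
  )
  agg <- dplyr::summarise(
    dplyr::group_by(per_seg, .data$electrode, .data$emotion, .data$relevance),
    auc = mean(.data$auc), n_segments = dplyr::n(), .groups = "drop"
  )
  out <- dplyr::left_join(grid, agg,
    by = c("electrode", "emotion", "relevance"))
  out$n_segments[is.na(out$n_segments)] <- 0L
  out$missing <- out$n_segments < min_segments
  if (any(out$missing)) {
    inform(sprintf(
      "%d condition cell(s) below the minimum segment count (%d).",
      sum(out$missing), min_segments
    ))
  }
  out$auc <- pmax(out$auc, 1e-12)
  out$ln_auc <- log(out$auc)
  dplyr::bind_cols(tibble(subject = subject_id), out)
}
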