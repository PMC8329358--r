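#' Construct a continuous EEG recording object
#'
#' The in-memory container for continuous multi-channel EEG: an ordered
#' channel set, a sampling rate, a channels x time sample matrix in uV, and
#' a marker stream. Marker onsets are 0-based sample indices (the vendor
#' file format's 1-based positions are converted at the I/O boundary).
#'
#' @param data Numeric matrix, channels x time, in uV; rownames are channel
#'   labels (or supply `channels`).
#' @param srate Sampling rate in Hz.
#' @param channels Optional character vector of channel labels.
#' @param markers Tibble with columns `type`, `description`, `onset_sample`
#'   (0-based integer, nondecreasing, within bounds). Default: empty.
#' @param meta Optional named list of provenance metadata.
#'
#' @return Object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, srate, channels = rownames(data),
                          markers = NULL, meta = list()) {
  if (!is.matrix(data) || !is.numeric(data)) abort("`data` must be a numeric matrix.")
  assert_scalar_number(srate, "srate", positive = TRUE)
  if (is.null(channels) || length(channels) != nrow(data)) {
    abort("`channels` must label every row of `data`.")
  }
  if (anyDuplicated(channels)) abort("Channel labels must be unique.")
  rownames(data) <- channels
  if (is.null(markers)) {
    markers <- tibble(
      type = character(), description = character(),
      onset_sample = integer()
    )
  }
  markers <- as_tibble(markers)
  if (!all(c("type", "description", "onset_sample") %in% names(markers))) {
    abort("`markers` needs columns type, description, onset_sample.")
  }
  if (nrow(markers) > 0) {
    if (any(markers$onset_sample < 0) || any(markers$onset_sample >= ncol(data))) {
      abort("Marker onsets must lie within the recording.")
    }
    if (is.unsorted(markers$onset_sample)) {
      abort("Marker onsets must be nondecreasing.")
    }
  }
  structure(
    list(
      channels = channels, srate = srate, data = data,
      markers = markers, meta = meta
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d markers\n",
    nrow(x$data), ncol(x$data), x$srate, ncol(x$data) / x$srate,
    nrow(x$markers)
  ))
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  if (length(x$meta$pipeline)) {
    cat("  pipeline:", paste(x$meta$pipeline, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' Tidy view of a recording's samples
#'
#' @param x An `eeg_recording`.
#' @param ... Unused.
#' @return Tibble with columns `time_s`, `channel`, `uV`.
#' @method tidy eeg_recording
#' @export
tidy.eeg_recording <- function(x, ...) {
  tibble(
    time_s = rep((seq_len(ncol(x$data)) - 1) / x$srate, each = nrow(x$data)),
    channel = rep(x$channels, times = ncol(x$data)),
    uV = as.vector(x$data)
  )
}

# append a pipeline step name to the provenance trail
note_step <- function(rec, step) {
  rec$meta$pipeline <- c(rec$meta$pipeline, step)
  rec
}
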