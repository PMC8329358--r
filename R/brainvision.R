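#' Write a recording as a BrainVision triplet
#'
#' Writes the vendor triplet: an INI-style text header (`.vhdr`,
#' `DataFormat=BINARY`, `DataOrientation=MULTIPLEXED`,
#' `BinaryFormat=IEEE_FLOAT_32`, channel resolution 1.0 uV), a marker file
#' (`.vmrk`) and a multiplexed little-endian float32 binary (`.eeg`).
#' Marker positions are written 1-based per the vendor convention; the
#' in-memory representation is 0-based.
#'
#' @param rec An [eeg_recording()].
#' @param basename Path without extension; the three files are written next
#'   to each other.
#' @return Invisibly, the `.vhdr` path.
#' @export
write_brainvision <- function(rec, basename) {
  stopifnot(inherits(rec, "eeg_recording"))
  stem <- basename(basename)
  vhdr <- paste0(basename, ".vhdr")
  vmrk <- paste0(basename, ".vmrk")
  eeg <- paste0(basename, ".eeg")

  hdr <- c(
    "BrainVision Data Exchange Header File Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", stem, ".eeg"),
    paste0("MarkerFile=", stem, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", length(rec$channels)),
    # vendor header stores the sampling interval in microseconds
    paste0("SamplingInterval=", format(1e6 / rec$srate, scientific = FALSE)),
    "",
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1.0,µV", seq_along(rec$channels), rec$channels)
  )
  writeLines(hdr, vhdr, useBytes = TRUE)

  mk <- c(
    "BrainVision Data Exchange Marker File, Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", stem, ".eeg"),
    "",
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0",
    if (nrow(rec$markers) > 0) {
      sprintf(
        "Mk%d=%s,%s,%d,1,0",
        seq_len(nrow(rec$markers)) + 1L,
        rec$markers$type, rec$markers$description,
        rec$markers$onset_sample + 1L
      )
    }
  )
  writeLines(mk, vmrk, useBytes = TRUE)

  con <- file(eeg, "wb")
  on.exit(close(con))
  # multiplexed: sample-major, channels interleaved = column-major of ch x t
  writeBin(as.vector(rec$data), con, size = 4L, endian = "little")
  invisible(vhdr)
}

# minimal INI parser: returns list(section -> named character vector)
parse_ini <- function(lines) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, ";")]
  out <- list()
  section <- NULL
  for (ln in lines) {
    if (startsWith(ln, "[")) {
      section <- gsub("^\\[|\\]$", "", ln)
      out[[section]] <- character()
    } else if (!is.null(section) && grepl("=", ln, fixed = TRUE)) {
      eq <- regexpr("=", ln, fixed = TRUE)
      key <- substr(ln, 1, eq - 1)
      out[[section]][[key]] <- substr(ln, eq + 1, nchar(ln))
    }
  }
  out
}

#' Read a BrainVision triplet
#'
#' Reads the header, marker and binary files back into an
#' [eeg_recording()]. Writing supports only the IEEE float32 multiplexed
#' dialect; reading additionally accepts `INT_16` with per-channel
#' resolutions. Unsupported binary formats or inconsistent channel counts
#' raise errors rather than guessing. Marker positions are converted to
#' 0-based sample indices; the vendor's automatic `New Segment` marker is
#' dropped.
#'
#' @param vhdr Path to the `.vhdr` header file.
#' @return An [eeg_recording()].
#' @export
read_brainvision <- function(vhdr) {
  if (!file.exists(vhdr)) abort(sprintf("Header file not found: %s", vhdr))
  ini <- parse_ini(readLines(vhdr, encoding = "UTF-8", warn = FALSE))
  ci <- ini[["Common Infos"]]
  if (is.null(ci)) abort("Malformed .vhdr: no [Common Infos] section.")
  if (!identical(ci[["DataFormat"]], "BINARY")) {
    abort(sprintf("Unsupported DataFormat: %s", ci[["DataFormat"]]))
  }
  if (!identical(ci[["DataOrientation"]], "MULTIPLEXED")) {
    abort(sprintf("Unsupported DataOrientation: %s", ci[["DataOrientation"]]))
  }
  n_ch <- as.integer(ci[["NumberOfChannels"]])
  srate <- 1e6 / as.numeric(ci[["SamplingInterval"]])
  binfmt <- ini[["Binary Infos"]][["BinaryFormat"]]
  if (!binfmt %in% c("IEEE_FLOAT_32", "INT_16")) {
    abort(sprintf("Unsupported BinaryFormat: %s", binfmt %||% "<missing>"))
  }

  chinfo <- ini[["Channel Infos"]]
  if (length(chinfo) != n_ch) {
    abort(sprintf(
      "Channel-count mismatch: NumberOfChannels=%d but %d channel entries.",
      n_ch, length(chinfo)
    ))
  }
  chparts <- strsplit(unname(chinfo), ",", fixed = TRUE)
  channels <- vapply(chparts, `[`, "", 1L)
  resolution <- vapply(chparts, function(p) {
    r <- suppressWarnings(as.numeric(p[3]))
    if (is.na(r)) 1 else r
  }, numeric(1))

  dir <- dirname(vhdr)
  eeg <- file.path(dir, ci[["DataFile"]])
  vmrk <- file.path(dir, ci[["MarkerFile"]])
  if (!file.exists(eeg)) abort(sprintf("Missing data file: %s", eeg))
  if (!file.exists(vmrk)) abort(sprintf("Missing marker file: %s", vmrk))

  sz <- file.size(eeg)
  bytes_per <- if (binfmt == "IEEE_FLOAT_32") 4L else 2L
  n_samp <- sz %/% (bytes_per * n_ch)
  con <- file(eeg, "rb")
  on.exit(close(con))
  raw <- if (binfmt == "IEEE_FLOAT_32") {
    readBin(con, "double", n = n_samp * n_ch, size = 4L, endian = "little")
  } else {
    readBin(con, "integer", n = n_samp * n_ch, size = 2L,
            signed = TRUE, endian = "little")
  }
  dat <- matrix(raw, nrow = n_ch)
  if (binfmt == "INT_16") dat <- dat * resolution

  mi <- parse_ini(readLines(vmrk, encoding = "UTF-8", warn = FALSE))[["Marker Infos"]]
  markers <- tibble(type = character(), description = character(),
                    onset_sample = integer())
  if (length(mi) > 0) {
    parts <- strsplit(unname(mi), ",")
    mtype <- vapply(parts, `[`, "", 1L)
    keep <- mtype != "New Segment"
    if (any(keep)) {
      markers <- tibble(
        type = mtype[keep],
        description = vapply(parts[keep], `[`, "", 2L),
        onset_sample = vapply(parts[keep], function(p) {
          as.integer(p[3]) - 1L
        }, integer(1))
      )
    }
  }
  eeg_recording(dat, srate, channels = channels, markers = markers,
                meta = list(source = vhdr))
}
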