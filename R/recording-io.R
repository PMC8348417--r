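# Recording input/output.
#
# Two interchange formats:
#  * delimited text - one TSV per trial (header row of channel names, one
#    column per channel) plus a YAML sidecar with fs / subject / labels;
#    lossless round-trip, convenient for human inspection.
#  * EDF (European Data Format, EDF+C) - one file per subject-session,
#    one data record per trial, trial labels carried in an
#    "EDF Annotations" signal; samples quantized to the format's 16 bits.

EDF_ANNOT_SAMPLES <- 32L  # int16 slots per record reserved for annotations

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x, type = "bytes") > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Write a recording to disk
#'
#' @param rec An `eeg_recording`.
#' @param path Output path: an `.edf` file for `format = "edf"`, a directory
#'   for `format = "delimited"`.
#' @param format `"edf"` or `"delimited"`.
#' @return `path`, invisibly.
#' @seealso [read_recording()]
#' @export
write_recording <- function(rec, path, format = c("edf", "delimited")) {
  stopifnot(inherits(rec, "eeg_recording"))
  format <- match.arg(format)
  switch(format,
    edf = write_recording_edf(rec, path),
    delimited = write_recording_delim(rec, path)
  )
  invisible(path)
}

#' Read a recording from disk
#'
#' Format is inferred: a directory is read as delimited text, a file as EDF.
#'
#' @param path Path produced by [write_recording()].
#' @return An `eeg_recording`.
#' @export
read_recording <- function(path) {
  if (dir.exists(path)) {
    read_recording_delim(path)
  } else if (file.exists(path)) {
    read_recording_edf(path)
  } else {
    abort(sprintf("No recording at '%s'.", path))
  }
}

write_recording_delim <- function(rec, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  labs <- recording_labels(rec)
  for (i in seq_along(rec$trials)) {
    m <- t(rec$trials[[i]]$samples)
    colnames(m) <- rec$channel_names
    utils::write.table(
      format(m, digits = 17, trim = TRUE, scientific = TRUE),
      file.path(path, sprintf("trial_%03d.tsv", i)),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  meta <- list(subject_id = rec$subject_id, fs = rec$fs,
               channels = as.list(rec$channel_names),
               labels = as.list(labs))
  yaml::write_yaml(meta, file.path(path, "recording.yaml"))
}

read_recording_delim <- function(path) {
  meta_path <- file.path(path, "recording.yaml")
  if (!file.exists(meta_path)) {
    abort(sprintf("Malformed delimited recording: missing sidecar '%s'.",
                  meta_path))
  }
  meta <- yaml::read_yaml(meta_path)
  files <- sort(list.files(path, pattern = "^trial_\\d+\\.tsv$",
                           full.names = TRUE))
  if (length(files) != length(meta$labels)) {
    abort(sprintf(
      "Malformed delimited recording: %d trial files but %d labels in sidecar.",
      length(files), length(meta$labels)))
  }
  channels <- unlist(meta$channels)
  trials <- lapply(seq_along(files), function(i) {
    m <- as.matrix(utils::read.table(files[i], header = TRUE, sep = "\t",
                                     check.names = FALSE))
    if (!identical(colnames(m), channels)) {
      abort(sprintf("Malformed trial file '%s': header does not match sidecar channels.",
                    files[i]))
    }
    list(label = meta$labels[[i]], samples = t(m))
  })
  new_recording(meta$subject_id, trials, meta$fs, channels)
}

# ---- EDF -------------------------------------------------------------------

write_recording_edf <- function(rec, path) {
  nch <- length(rec$channel_names)
  ns <- nch + 1L  # + annotations signal
  n_rec <- length(rec$trials)
  spr <- ncol(rec$trials[[1]]$samples)          # samples per record
  rec_dur <- spr / rec$fs
  labs <- recording_labels(rec)

  all_mat <- do.call(cbind, lapply(rec$trials, `[[`, "samples"))
  # physical range padded outward to the millivolt-precision strings that fit
  # the 8-character header fields; scaling must use exactly the header values
  phys_fmt <- function(v) {
    s <- sprintf("%.3f", v)
    if (nchar(s) > 8) s <- sprintf("%.4g", v)
    s
  }
  pmin_s <- vapply(apply(all_mat, 1, min), function(v)
    phys_fmt(floor(v * 1000) / 1000), "")
  pmax_s <- vapply(apply(all_mat, 1, max), function(v)
    phys_fmt(ceiling(v * 1000) / 1000), "")
  pmin_ <- as.numeric(pmin_s)
  pmax_ <- as.numeric(pmax_s)
  flat <- pmax_ - pmin_ < 1e-9
  pmax_[flat] <- pmin_[flat] + 1
  pmax_s[flat] <- vapply(pmax_[flat], phys_fmt, "")

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) writeBin(charToRaw(pad_field(x, w)), con)

  wr("0", 8)
  wr(rec$subject_id, 80)
  wr(sprintf("Startdate 01-JAN-2000 synthetic fs=%g", rec$fs), 80)
  wr("01.01.00", 8)
  wr("00.00.00", 8)
  wr(256L * (1L + ns), 8)
  wr("EDF+C", 44)
  wr(n_rec, 8)
  wr(format(rec_dur, digits = 8), 8)
  wr(ns, 4)

  sig_labels <- c(rec$channel_names, "EDF Annotations")
  for (s in sig_labels) wr(s, 16)
  for (s in sig_labels) wr("", 80)                         # transducer
  for (s in seq_len(ns)) wr(if (s <= nch) "uV" else "", 8) # phys dim
  for (s in seq_len(ns)) wr(if (s <= nch) pmin_s[s] else "-1", 8)
  for (s in seq_len(ns)) wr(if (s <= nch) pmax_s[s] else "1", 8)
  for (s in seq_len(ns)) wr("-32768", 8)
  for (s in seq_len(ns)) wr("32767", 8)
  for (s in seq_len(ns)) wr("", 80)                        # prefiltering
  for (s in seq_len(ns)) wr(if (s <= nch) spr else EDF_ANNOT_SAMPLES, 8)
  for (s in seq_len(ns)) wr("", 32)

  scale <- (pmax_ - pmin_) / 65535
  for (r in seq_len(n_rec)) {
    samp <- rec$trials[[r]]$samples
    for (ci in seq_len(nch)) {
      dig <- round((samp[ci, ] - pmin_[ci]) / scale[ci]) - 32768
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con, size = 2,
               endian = "little")
    }
    onset <- (r - 1) * rec_dur
    tal <- paste0(sprintf("+%g", onset), "\x14\x14",
                  sprintf("+%g", onset), "\x15",
                  sprintf("%g", rec_dur), "\x14", labs[r], "\x14")
    bytes <- charToRaw(tal)
    slot <- raw(2L * EDF_ANNOT_SAMPLES)
    if (length(bytes) > length(slot)) {
      abort(sprintf("Trial %d label too long for the annotation slot.", r))
    }
    slot[seq_along(bytes)] <- bytes
    writeBin(slot, con)
  }
}

read_edf_field <- function(raw, off, w) {
  trimws(rawToChar(raw[(off + 1):(off + w)]))
}

read_recording_edf <- function(path) {
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw_all) < 256) {
    abort(sprintf("Malformed EDF '%s': truncated header (%d bytes, need 256).",
                  path, length(raw_all)))
  }
  hdr_bytes <- suppressWarnings(as.integer(read_edf_field(raw_all, 184, 8)))
  n_rec <- suppressWarnings(as.integer(read_edf_field(raw_all, 236, 8)))
  rec_dur <- suppressWarnings(as.numeric(read_edf_field(raw_all, 244, 8)))
  ns <- suppressWarnings(as.integer(read_edf_field(raw_all, 252, 4)))
  if (anyNA(c(hdr_bytes, n_rec, rec_dur, ns)) || ns < 1) {
    abort(sprintf("Malformed EDF '%s': unreadable header counts.", path))
  }
  if (length(raw_all) < hdr_bytes) {
    abort(sprintf("Malformed EDF '%s': truncated signal header (%d of %d bytes).",
                  path, length(raw_all), hdr_bytes))
  }
  subject_id <- read_edf_field(raw_all, 8, 80)

  fld <- function(block_off, w, s) read_edf_field(raw_all, block_off + (s - 1) * w, w)
  base <- 256
  labels16 <- vapply(seq_len(ns), function(s) fld(base, 16, s), "")
  pmin_ <- as.numeric(vapply(seq_len(ns), function(s)
    fld(base + ns * (16 + 80 + 8), 8, s), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(s)
    fld(base + ns * (16 + 80 + 8 + 8), 8, s), ""))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(s)
    fld(base + ns * (16 + 80 + 8 + 8 + 8), 8, s), ""))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(s)
    fld(base + ns * (16 + 80 + 8 + 8 + 8 + 8), 8, s), ""))
  spr <- as.integer(vapply(seq_len(ns), function(s)
    fld(base + ns * (16 + 80 + 8 * 5 + 80), 8, s), ""))

  annot_idx <- which(labels16 == "EDF Annotations")
  chan_idx <- setdiff(seq_len(ns), annot_idx)
  channels <- labels16[chan_idx]
  rec_int16 <- sum(spr)
  need <- hdr_bytes + 2 * rec_int16 * n_rec
  if (length(raw_all) < need) {
    abort(sprintf("Malformed EDF '%s': data area truncated at record %d.",
                  path, (length(raw_all) - hdr_bytes) %/% (2 * rec_int16) + 1L))
  }
  fs <- spr[chan_idx[1]] / rec_dur

  offsets <- c(0, cumsum(spr))  # in int16 units within a record
  trials <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    rec_off <- hdr_bytes + 2 * rec_int16 * (r - 1)
    samples <- matrix(0, nrow = length(chan_idx), ncol = spr[chan_idx[1]],
                      dimnames = list(channels, NULL))
    for (k in seq_along(chan_idx)) {
      s <- chan_idx[k]
      from <- rec_off + 2 * offsets[s]
      dig <- readBin(raw_all[(from + 1):(from + 2 * spr[s])], "integer",
                     n = spr[s], size = 2, signed = TRUE, endian = "little")
      samples[k, ] <- pmin_[s] +
        (dig - dmin_[s]) * (pmax_[s] - pmin_[s]) / (dmax_[s] - dmin_[s])
    }
    lab <- NA_character_
    if (length(annot_idx) == 1) {
      s <- annot_idx
      from <- rec_off + 2 * offsets[s]
      tal <- raw_all[(from + 1):(from + 2 * spr[s])]
      txt <- strsplit(rawToChar(tal[tal != as.raw(0)]), "\x14")[[1]]
      txt <- txt[!grepl("^[+-]", txt) & nzchar(txt)]
      if (length(txt)) lab <- txt[1]
    }
    trials[[r]] <- list(label = lab, samples = samples)
  }
  new_recording(subject_id, trials, fs, channels)
}
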