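# Readers and writers for recordings and run configuration.

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  paste0(s, strrep(" ", width - nchar(s)))
}

#' Write a recording to a minimal EDF file
#'
#' Writes a continuous single- or multi-channel European Data Format file
#' (16-bit samples, one data record per second). Intended for small
#' fixtures and interchange; amplitudes are scaled into the signal's
#' physical range.
#'
#' @param recordings A [recording()] or list of them with equal rates and
#'   lengths (one channel each).
#' @param path Output path.
#' @param labels Channel labels (defaults to subject ids).
#' @return `path`, invisibly.
#' @export
write_edf <- function(recordings, path, labels = NULL) {
  if (inherits(recordings, "eeg_recording")) recordings <- list(recordings)
  ns <- length(recordings)
  rate <- recordings[[1]]$rate
  n <- length(recordings[[1]]$samples)
  for (r in recordings) {
    if (r$rate != rate || length(r$samples) != n) {
      stopf("all channels must share rate and length")
    }
  }
  if (is.null(labels)) labels <- vapply(recordings, `[[`, "", "subject_id")
  spr <- as.integer(rate)
  n_rec <- n %/% spr
  if (n_rec < 1) stopf("recording shorter than one data record (1 s)")
  pmin_ <- pmax_ <- numeric(ns)
  dig <- list()
  for (i in seq_len(ns)) {
    x <- recordings[[i]]$samples[seq_len(n_rec * spr)]
    a <- max(abs(x), 1e-9)
    pmin_[i] <- -a; pmax_[i] <- a
    dig[[i]] <- as.integer(round(x / a * 32767))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad_field("0", 8), pad_field("synthetic", 80),
                pad_field("bowaves", 80), pad_field("01.01.24", 8),
                pad_field("00.00.00", 8), pad_field(256 + ns * 256, 8),
                pad_field("", 44), pad_field(n_rec, 8), pad_field(1, 8),
                pad_field(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    vapply(labels, pad_field, "", width = 16),
    rep(pad_field("", 80), ns), rep(pad_field("uV", 8), ns),
    vapply(sprintf("%.6g", pmin_), pad_field, "", width = 8),
    vapply(sprintf("%.6g", pmax_), pad_field, "", width = 8),
    rep(pad_field(-32767, 8), ns), rep(pad_field(32767, 8), ns),
    rep(pad_field("HP:1Hz", 80), ns),
    rep(pad_field(spr, 8), ns), rep(pad_field("", 32), ns))
  for (f in fields) writeChar(paste(f, collapse = ""), con, eos = NULL)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      idx <- ((r - 1) * spr + 1):(r * spr)
      writeBin(dig[[i]][idx], con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

read_chars <- function(con, n) {
  trimws(rawToChar(readBin(con, "raw", n)))
}

#' Read a recording from an EDF or CSV file
#'
#' EDF: a minimal reader for continuous 16-bit EDF; the requested channel
#' is selected by index or label and samples are mapped to physical units.
#' CSV: a plain-text format with a `# rate=<Hz> subject=<id>` comment line
#' followed by a `value` column (see [write_recording_csv()]).
#'
#' @param path File path (`.edf` or `.csv`).
#' @param channel Channel index or label (EDF only).
#' @param rate Optional expected sampling rate; a mismatch with the file is
#'   an error.
#' @param subject_id Optional subject id override.
#' @return A [recording()].
#' @export
read_recording <- function(path, channel = 1, rate = NULL, subject_id = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  rec <- switch(ext,
                edf = read_edf(path, channel),
                csv = read_recording_csv(path),
                stopf("unsupported recording format '.%s' (use .edf or .csv)", ext))
  if (!is.null(rate) && rec$rate != rate) {
    stopf("file sampling rate %g Hz does not match the expected %g Hz",
          rec$rate, rate)
  }
  if (!is.null(subject_id)) rec$subject_id <- subject_id
  rec
}

read_edf <- function(path, channel = 1) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_chars(con, 8)                      # version
  read_chars(con, 80); read_chars(con, 80)
  read_chars(con, 8); read_chars(con, 8)
  read_chars(con, 8)                      # header bytes
  read_chars(con, 44)
  n_rec <- as.integer(read_chars(con, 8))
  rec_dur <- as.numeric(read_chars(con, 8))
  ns <- as.integer(read_chars(con, 4))
  labels <- vapply(seq_len(ns), function(i) read_chars(con, 16), "")
  for (i in seq_len(ns)) read_chars(con, 80)
  for (i in seq_len(ns)) read_chars(con, 8)
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(read_chars(con, 8)), 0)
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(read_chars(con, 8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(read_chars(con, 8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(read_chars(con, 8)), 0)
  for (i in seq_len(ns)) read_chars(con, 80)
  spr <- vapply(seq_len(ns), function(i) as.integer(read_chars(con, 8)), 0L)
  for (i in seq_len(ns)) read_chars(con, 32)
  ch <- if (is.character(channel)) match(channel, labels) else as.integer(channel)
  if (is.na(ch) || ch < 1 || ch > ns) {
    stopf("channel '%s' not found; available channels: %s",
          as.character(channel), paste(labels, collapse = ", "))
  }
  out <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      v <- readBin(con, "integer", spr[i], size = 2, endian = "little")
      if (i == ch) out[[r]] <- v
    }
  }
  dg <- unlist(out)
  phys <- pmin_[ch] + (dg - dmin[ch]) * (pmax_[ch] - pmin_[ch]) / (dmax[ch] - dmin[ch])
  recording(phys, rate = spr[ch] / rec_dur, subject_id = labels[ch])
}

#' Write/read a recording as plain-text CSV
#'
#' The file starts with a `# rate=<Hz> subject=<id>` comment line followed
#' by a single `value` column.
#'
#' @param rec A [recording()].
#' @param path File path.
#' @return `path` invisibly (writer); a [recording()] (reader).
#' @export
write_recording_csv <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rate=%g subject=%s", rec$rate, rec$subject_id), con)
  writeLines("value", con)
  writeLines(format(rec$samples, trim = TRUE, digits = 10), con)
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  m <- regmatches(hdr, regexec("# rate=([0-9.]+) subject=(\\S+)", hdr))[[1]]
  if (length(m) != 3) stopf("missing '# rate=... subject=...' header in %s", path)
  vals <- utils::read.csv(path, comment.char = "#")$value
  recording(vals, rate = as.numeric(m[2]), subject_id = m[3])
}

#' Run configuration profiles
#'
#' Bundles every pipeline hyperparameter with validated defaults. The
#' `"full"` profile carries the full-scale study settings (K = 200
#' waveforms of P = 256 samples for L = 512-sample windows, 40 000 training
#' windows and 480 one-hour segments per genotype-fold, a 15-point
#' hyperparameter grid, five repeated splits); the `"desk"` profile scales
#' the same pipeline to run in minutes on synthetic cohorts.
#'
#' @param profile `"desk"` or `"full"`.
#' @param ... Named overrides of any config field.
#' @return List of class `run_config`.
#' @export
run_config <- function(profile = c("desk", "full"), ...) {
  profile <- match.arg(profile)
  cfg <- if (profile == "full") {
    list(rate = 256, K = 200, P = 256, L = 512, windows_per_dict = 40000,
         segments_per_subject = 120, segment_len = 3600,
         K_CV = 3, grid = default_reg_grid(), n_splits = 5, seed = 0)
  } else {
    list(rate = 256, K = 16, P = 128, L = 256, windows_per_dict = 2000,
         segments_per_subject = 6, segment_len = 600,
         K_CV = 3, grid = default_reg_grid(), n_splits = 1, seed = 0)
  }
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stopf("unknown config field(s): %s", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  cfg$profile <- profile
  if (cfg$P >= cfg$L) stopf("waveform length P must be < window length L")
  if (length(cfg$grid) < 1 || any(cfg$grid <= 0)) stopf("invalid hyperparameter grid")
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  profile <- y$profile %||% "desk"
  y$profile <- NULL
  do.call(run_config, c(list(profile = profile), y))
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
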