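#' EEG recording container
#'
#' Bundles a single-channel EEG sample vector with its sampling rate, a
#' subject identifier, and optional exclusion intervals (e.g. peri-ictal
#' spans removed from analysis). Sample indices follow the 0-based,
#' half-open convention `[start, start + len)` used throughout the package.
#'
#' @param samples Numeric vector of amplitudes (microvolts).
#' @param rate Sampling frequency in Hz (positive scalar).
#' @param subject_id Character scalar identifying the individual.
#' @param exclusions Two-column matrix of 0-based half-open sample-index
#'   intervals to exclude, sorted and non-overlapping; may be `NULL`.
#' @return An object of class `eeg_recording` with fields `samples`, `rate`,
#'   `subject_id`, `exclusions`, and derived `duration` in seconds.
#' @export
recording <- function(samples, rate, subject_id = "subject", exclusions = NULL) {
  if (!is.numeric(samples) || length(samples) < 1) {
    stopf("`samples` must be a non-empty numeric vector")
  }
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0) {
    stopf("`rate` must be a positive scalar (Hz)")
  }
  n <- length(samples)
  if (is.null(exclusions)) {
    exclusions <- matrix(numeric(0), ncol = 2)
  } else {
    exclusions <- matrix(as.numeric(exclusions), ncol = 2)
    if (nrow(exclusions) > 0) {
      if (any(exclusions[, 2] <= exclusions[, 1])) {
        stopf("exclusion intervals must have end > start")
      }
      if (any(exclusions[, 1] < 0) || any(exclusions[, 2] > n)) {
        stopf("exclusion intervals must lie within [0, %d)", n)
      }
      o <- order(exclusions[, 1])
      exclusions <- exclusions[o, , drop = FALSE]
      if (nrow(exclusions) > 1 &&
          any(exclusions[-1, 1] < exclusions[-nrow(exclusions), 2])) {
        stopf("exclusion intervals must be non-overlapping")
      }
    }
  }
  colnames(exclusions) <- c("start", "end")
  structure(
    list(samples = as.numeric(samples), rate = rate,
         subject_id = as.character(subject_id),
         duration = n / rate, exclusions = exclusions),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject '%s': %d samples at %g Hz (%.1f min), %d exclusion interval(s)\n",
              x$subject_id, length(x$samples), x$rate,
              x$duration / 60, nrow(x$exclusions)))
  invisible(x)
}

#' Batch of equal-length signal windows
#'
#' @param windows Numeric matrix, one window per row.
#' @param source Optional data frame with one row per window giving
#'   `subject_id` and 0-based `start` sample index.
#' @return An object of class `window_batch` with fields `windows`,
#'   `window_length`, and `source`.
#' @export
window_batch <- function(windows, source = NULL) {
  windows <- as.matrix(windows)
  if (nrow(windows) < 1) stopf("a window batch needs at least one window")
  if (is.null(source)) {
    source <- data.frame(subject_id = NA_character_,
                         start = NA_real_)[rep(1, nrow(windows)), ]
    rownames(source) <- NULL
  }
  structure(list(windows = windows, window_length = ncol(windows),
                 source = source),
            class = "window_batch")
}

#' @export
print.window_batch <- function(x, ...) {
  cat(sprintf("<window_batch> %d windows of length %d\n",
              nrow(x$windows), x$window_length))
  invisible(x)
}

#' Extract a fixed-length window from a signal
#'
#' The window operator `W_tau`: returns the `P` consecutive samples of `x`
#' starting at 0-based index `tau`.
#'
#' @param x Numeric vector.
#' @param tau 0-based start index, `0 <= tau <= length(x) - P`.
#' @param P Window length.
#' @return Numeric vector of length `P`.
#' @export
extract_window <- function(x, tau, P) {
  L <- length(x)
  if (P < 1 || P > L) stopf("window length P=%d out of range for signal of length %d", P, L)
  if (tau < 0 || tau > L - P) {
    stopf("tau=%d out of range [0, %d]", tau, L - P)
  }
  x[(tau + 1):(tau + P)]
}

#' Zero-pad a short window into a longer signal at a given offset
#'
#' The adjoint `S_tau` of the window operator: places `y` at 0-based offset
#' `tau` inside an otherwise-zero vector of length `L`, so that
#' `sum(x * shift_pad(y, tau, L)) == sum(extract_window(x, tau, P) * y)`.
#'
#' @param y Numeric vector of length `P`.
#' @param tau 0-based offset, `0 <= tau <= L - P`.
#' @param L Output length, `L >= P`.
#' @return Numeric vector of length `L`.
#' @export
shift_pad <- function(y, tau, L) {
  P <- length(y)
  if (P > L) stopf("cannot pad a length-%d window into length %d", P, L)
  if (tau < 0 || tau > L - P) stopf("tau=%d out of range [0, %d]", tau, L - P)
  out <- numeric(L)
  out[(tau + 1):(tau + P)] <- y
  out
}

#' Split a segment into windows
#'
#' By default breaks a segment into `floor(length(segment)/L)` consecutive
#' non-overlapping windows of length `L`; any trailing remainder shorter
#' than `L` is discarded. A smaller `stride` (e.g. `L - P + 1`, which
#' guarantees every waveform shift is seen by some window) yields
#' overlapping windows instead.
#'
#' @param segment Numeric vector, at least `L` samples.
#' @param L Window length in samples.
#' @param stride Offset between consecutive window starts; defaults to `L`
#'   (non-overlapping).
#' @param subject_id Optional identifier recorded in the batch provenance.
#' @param start Optional 0-based start index of the segment within its
#'   recording (used for provenance).
#' @return A [window_batch()].
#' @export
segment_to_windows <- function(segment, L, stride = L,
                               subject_id = NA_character_, start = 0) {
  Q <- length(segment)
  if (Q < L) stopf("segment of length %d is shorter than the window length %d", Q, L)
  if (stride < 1) stopf("stride must be positive")
  starts <- seq(0, Q - L, by = stride)
  M <- length(starts)
  w <- matrix(0, M, L)
  for (i in seq_len(M)) w[i, ] <- segment[(starts[i] + 1):(starts[i] + L)]
  src <- data.frame(subject_id = subject_id, start = start + starts)
  window_batch(w, src)
}

#' Build merged peri-event exclusion intervals
#'
#' Expands each event by `pre_pad` seconds before its start and `post_pad`
#' seconds after its end (defaults: 5 minutes before, 60 minutes after),
#' clips to the record, and merges overlapping or adjacent expanded
#' intervals.
#'
#' @param events Data frame with columns `start` and `end` in seconds
#'   (end > start), or `NULL`/empty for no events.
#' @param record_duration Recording duration in seconds.
#' @param pre_pad,post_pad Padding in seconds applied before/after each event.
#' @return Two-column matrix of sorted, disjoint intervals in seconds.
#' @export
build_exclusion_mask <- function(events, record_duration,
                                 pre_pad = 300, post_pad = 3600) {
  if (is.null(events) || NROW(events) == 0) {
    out <- matrix(numeric(0), ncol = 2)
    colnames(out) <- c("start", "end")
    return(out)
  }
  events <- as.data.frame(events)
  if (any(events$end <= events$start)) stopf("events must have end > start")
  lo <- pmax(0, events$start - pre_pad)
  hi <- pmin(record_duration, events$end + post_pad)
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  ms <- lo[1]; me <- hi[1]
  out <- NULL
  for (i in seq_along(lo)[-1]) {
    if (lo[i] <= me) {
      me <- max(me, hi[i])
    } else {
      out <- rbind(out, c(ms, me))
      ms <- lo[i]; me <- hi[i]
    }
  }
  out <- rbind(out, c(ms, me))
  colnames(out) <- c("start", "end")
  out
}

# 0-based half-open admissible range [lo, hi) of window starts for one
# recording half. half boundary = floor(n/2) samples.
half_range <- function(rec, half = c("first", "second")) {
  half <- match.arg(half)
  n <- length(rec$samples)
  b <- n %/% 2
  if (half == "first") c(0, b) else c(b, n)
}

# TRUE if [start, start+len) intersects any exclusion interval (sample units).
hits_exclusion <- function(start, len, exclusions) {
  if (nrow(exclusions) == 0) return(rep(FALSE, length(start)))
  out <- logical(length(start))
  for (j in seq_len(nrow(exclusions))) {
    out <- out | (start < exclusions[j, 2] & (start + len) > exclusions[j, 1])
  }
  out
}

# Draw `n` admissible 0-based start indices for windows of `len` samples from
# one half of a recording, rejecting starts that intersect exclusions.
draw_starts <- function(rec, n, len, half, max_attempts = 10000) {
  rng <- half_range(rec, half)
  lo <- rng[1]; hi <- rng[2] - len
  if (hi < lo) {
    stopf("subject '%s': %s half too short for windows of %d samples",
          rec$subject_id, half, len)
  }
  starts <- numeric(0)
  attempts <- 0
  while (length(starts) < n) {
    need <- n - length(starts)
    cand <- lo + floor(stats::runif(need) * (hi - lo + 1))
    cand <- pmin(cand, hi)  # guard against runif() == 1
    keep <- !hits_exclusion(cand, len, rec$exclusions)
    starts <- c(starts, cand[keep])
    attempts <- attempts + need
    if (attempts > max_attempts && length(starts) == 0) {
      stopf("subject '%s': no admissible start positions found after %d attempts",
            rec$subject_id, max_attempts)
    }
    if (attempts > max_attempts * 10) {
      stopf("subject '%s': sampling stalled; exclusions too dense", rec$subject_id)
    }
  }
  starts[seq_len(n)]
}

#' Sample dictionary-training windows across subjects
#'
#' Draws a balanced number of windows per subject, uniformly from the
#' designated half of each recording (with replacement across draws),
#' never intersecting an exclusion interval. Each subject contributes
#' `ceiling(total / n_subjects)` windows, so the returned batch can slightly
#' exceed `total`.
#'
#' @param recordings List of [recording()] objects.
#' @param total Minimum total number of windows across subjects.
#' @param L Window length in samples.
#' @param half Which recording half to draw from (`"first"` for dictionary
#'   training in the standard protocol).
#' @param seed Integer seed; draws are deterministic given the seed.
#' @return A [window_batch()] with per-row provenance.
#' @export
sample_training_windows <- function(recordings, total, L,
                                    half = c("first", "second"), seed = 1) {
  half <- match.arg(half)
  ns <- length(recordings)
  if (ns < 1) stopf("need at least one recording")
  quota <- ceiling(total / ns)
  with_seed(seed, {
    rows <- vector("list", ns)
    for (i in seq_len(ns)) {
      rec <- recordings[[i]]
      st <- draw_starts(rec, quota, L, half)
      w <- matrix(0, quota, L)
      for (j in seq_len(quota)) w[j, ] <- extract_window(rec$samples, st[j], L)
      rows[[i]] <- list(w = w,
                        src = data.frame(subject_id = rec$subject_id, start = st))
    }
    window_batch(do.call(rbind, lapply(rows, `[[`, "w")),
                 do.call(rbind, lapply(rows, `[[`, "src")))
  })
}

#' Sample encoding segments across subjects
#'
#' Draws an equal number of segments per subject, with start times uniform
#' over the admissible range of the designated recording half; segments may
#' overlap each other but never an exclusion interval.
#'
#' @param recordings List of [recording()] objects (all with equal rates).
#' @param n_segments Total segment count; must be divisible by the number of
#'   subjects.
#' @param seg_len Segment length in seconds.
#' @param half Which recording half to draw from (`"second"` for encoding in
#'   the standard protocol).
#' @param seed Integer seed.
#' @return List of segments; each has fields `samples`, `subject_id`,
#'   `start` (0-based sample index), and `duration` (seconds).
#' @export
sample_segments <- function(recordings, n_segments, seg_len,
                            half = c("first", "second"), seed = 1) {
  half <- match.arg(half)
  ns <- length(recordings)
  if (n_segments %% ns != 0) {
    stopf("n_segments=%d is not divisible by the %d subjects", n_segments, ns)
  }
  per <- n_segments %/% ns
  with_seed(seed, {
    out <- vector("list", n_segments)
    idx <- 1
    for (i in seq_len(ns)) {
      rec <- recordings[[i]]
      len <- round(seg_len * rec$rate)
      st <- draw_starts(rec, per, len, half)
      for (j in seq_len(per)) {
        out[[idx]] <- list(samples = extract_window(rec$samples, st[j], len),
                           subject_id = rec$subject_id, start = st[j],
                           duration = seg_len)
        idx <- idx + 1
      }
    }
    out
  })
}
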