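#' Bank of canonical planted waveforms
#'
#' Generates unit-norm waveform shapes for synthetic EEG: rhythms are
#' Hann-windowed sinusoids at frequencies drawn from `freq_range`;
#' transients are compactly supported Gabor-like spikes (Gaussian-windowed
#' carriers with a short envelope). Banks are resampled until every pair of
#' waveforms has maximum absolute cosine similarity over all relative
#' shifts at most `max_pair_cosine`, guaranteeing separability for
#' recovery scoring.
#'
#' @param n_transient,n_rhythm Number of waveforms of each family.
#' @param P Waveform length in samples.
#' @param rate Sampling rate in Hz.
#' @param freq_range Carrier-frequency range in Hz (within `(1, rate/2)`).
#' @param seed Integer seed; identical seeds give identical banks.
#' @param max_pair_cosine Separability bound (default 0.8).
#' @return Object of class `waveform_bank`: `waveforms` (list of unit-norm
#'   vectors), `family` (`"transient"`/`"rhythm"`), `freq` (nominal carrier
#'   Hz), `P`, `rate`.
#' @export
make_waveform_bank <- function(n_transient, n_rhythm, P, rate = 256,
                               freq_range = c(4, 16), seed = 1,
                               max_pair_cosine = 0.8) {
  if (freq_range[1] <= 1 || freq_range[2] >= rate / 2) {
    stopf("freq_range must lie within (1, rate/2)")
  }
  n <- n_transient + n_rhythm
  tt <- (seq_len(P) - 1) / rate
  with_seed(seed, {
    for (attempt in 1:1000) {
      waveforms <- list()
      family <- character(0)
      freq <- numeric(0)
      for (i in seq_len(n_rhythm)) {
        f <- stats::runif(1, freq_range[1], freq_range[2])
        w <- hann_window(P) * sin(2 * pi * f * tt + stats::runif(1, 0, 2 * pi))
        waveforms <- c(waveforms, list(w / l2norm(w)))
        family <- c(family, "rhythm"); freq <- c(freq, f)
      }
      for (i in seq_len(n_transient)) {
        f <- stats::runif(1, freq_range[1], freq_range[2]) * 2
        f <- min(f, rate / 2 * 0.9)
        ctr <- P / (2 * rate)
        sigma <- P / (10 * rate)
        w <- exp(-(tt - ctr)^2 / (2 * sigma^2)) *
          sin(2 * pi * f * (tt - ctr) + stats::runif(1, 0, 2 * pi))
        waveforms <- c(waveforms, list(w / l2norm(w)))
        family <- c(family, "transient"); freq <- c(freq, f)
      }
      if (n < 2 || bank_separable(waveforms, max_pair_cosine)) {
        return(structure(list(waveforms = waveforms, family = family,
                              freq = freq, P = P, rate = rate),
                         class = "waveform_bank"))
      }
    }
  })
  stopf("could not draw a bank with pairwise shift-max |cosine| <= %g in 1000 attempts",
        max_pair_cosine)
}

# Maximum |cosine| between two waveforms over all relative shifts
# (each zero-padded into a common 2P-1 support).
shift_max_cosine <- function(a, b) {
  P <- length(a)
  L <- 2 * P - 1
  best <- 0
  for (tau in 0:(L - P)) {
    av <- shift_pad(a, P - 1, L)
    bv <- shift_pad(b, tau, L)
    best <- max(best, abs(sum(av * bv)) / (l2norm(a) * l2norm(b)))
  }
  best
}

bank_separable <- function(waveforms, max_pair_cosine) {
  n <- length(waveforms)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (shift_max_cosine(waveforms[[i]], waveforms[[j]]) > max_pair_cosine) {
        return(FALSE)
      }
    }
  }
  TRUE
}

#' @export
print.waveform_bank <- function(x, ...) {
  cat(sprintf("<waveform_bank> %d waveforms of length %d at %g Hz (%d transient, %d rhythm)\n",
              length(x$waveforms), x$P, x$rate,
              sum(x$family == "transient"), sum(x$family == "rhythm")))
  invisible(x)
}

#' Simulate a single-channel EEG recording with planted waveforms
#'
#' Event counts per waveform are Poisson with mean `rate_per_min *
#' duration`; events are placed uniformly without overlapping another
#' event's support, scaled by log-normal amplitude draws, and superposed on
#' additive Gaussian noise (optionally 1/f-shaped). The ground-truth event
#' list is returned for recovery scoring.
#'
#' @param bank A [make_waveform_bank()] bank.
#' @param rates_per_min Occurrence rate (events/minute) for each bank
#'   waveform.
#' @param amp_meanlog,amp_sdlog Log-normal amplitude parameters.
#' @param noise_sd Standard deviation of the additive noise.
#' @param duration Recording duration in seconds.
#' @param rate Sampling rate in Hz.
#' @param seed Integer seed.
#' @param subject_id Identifier for the returned recording.
#' @param one_over_f Optional spectral exponent; `> 0` shapes the noise as
#'   `1/f^exponent`.
#' @return List with `recording` (an [recording()]) and `events` (data
#'   frame: `waveform`, `start` 0-based sample index, `amplitude`).
#' @export
simulate_recording <- function(bank, rates_per_min, amp_meanlog = 0,
                               amp_sdlog = 0.25, noise_sd = 1,
                               duration = 7200, rate = 256, seed = 1,
                               subject_id = "sim", one_over_f = 0) {
  P <- bank$P
  n <- round(duration * rate)
  stopifnot(length(rates_per_min) == length(bank$waveforms))
  with_seed(seed, {
    counts <- stats::rpois(length(rates_per_min), rates_per_min * duration / 60)
    total <- sum(counts)
    if (total * P > 0.5 * n) {
      stopf("event density too high to place without overlap; lower the rates")
    }
    samples <- if (one_over_f > 0) {
      colored_noise(n, noise_sd, one_over_f)
    } else {
      stats::rnorm(n, 0, noise_sd)
    }
    occupied <- logical(n)
    ev_w <- integer(total); ev_st <- integer(total); ev_amp <- numeric(total)
    order_w <- rep(seq_along(counts), counts)
    if (total > 0) order_w <- sample(order_w)
    for (j in seq_along(order_w)) {
      w <- order_w[j]
      placed <- FALSE
      for (att in 1:1000) {
        st <- floor(stats::runif(1) * (n - P + 1))
        idx <- (st + 1):(st + P)
        if (!any(occupied[idx])) {
          amp <- stats::rlnorm(1, amp_meanlog, amp_sdlog)
          samples[idx] <- samples[idx] + amp * bank$waveforms[[w]]
          occupied[idx] <- TRUE
          ev_w[j] <- w; ev_st[j] <- st; ev_amp[j] <- amp
          placed <- TRUE
          break
        }
      }
      if (!placed) stopf("could not place an event without overlap; lower the rates")
    }
    events <- if (total > 0) {
      o <- order(ev_st)
      data.frame(waveform = ev_w[o], start = ev_st[o], amplitude = ev_amp[o])
    } else NULL
    list(recording = recording(samples, rate, subject_id = subject_id),
         events = events)
  })
}

# Gaussian noise shaped to a 1/f^exponent amplitude spectrum, rescaled to sd.
colored_noise <- function(n, sd, exponent) {
  f <- stats::fft(stats::rnorm(n))
  k <- c(1, seq_len(n - 1))
  shape <- 1 / (k^(exponent / 2))
  x <- Re(stats::fft(f * shape, inverse = TRUE)) / n
  x * sd / stats::sd(x)
}

#' Cohort specification for synthetic EEG generation
#'
#' @param genotypes Named list: genotype label -> list with `rates_per_min`
#'   (one rate per bank waveform) and optionally `amp_meanlog`, `amp_sdlog`.
#' @param subjects_per_genotype Subjects per genotype (scalar or named).
#' @param duration Per-subject recording duration in seconds (>= 2 h so
#'   half-splitting is meaningful).
#' @param rate Sampling rate in Hz.
#' @param noise_sd Additive noise standard deviation.
#' @param one_over_f Optional noise spectral exponent.
#' @param seed Integer seed.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(genotypes, subjects_per_genotype = 6,
                        duration = 7200, rate = 256, noise_sd = 1,
                        one_over_f = 0, seed = 1) {
  if (duration < 7200) {
    warning("durations below 2 h make half-splitting fragile")
  }
  structure(list(genotypes = genotypes,
                 subjects_per_genotype = subjects_per_genotype,
                 duration = duration, rate = rate, noise_sd = noise_sd,
                 one_over_f = one_over_f, seed = seed),
            class = "cohort_spec")
}

#' Simulate a cohort of recordings with genotype-specific waveform rates
#'
#' Subjects are assigned genotype labels (strain x disease genotype parsed
#' from the label as `strain-tsc` when possible), alternating sexes, and a
#' balanced two-fold assignment within genotype. Per-subject recordings are
#' generated with the genotype's rate vector. Deterministic given the spec
#' seed.
#'
#' @param bank A [make_waveform_bank()].
#' @param spec A [cohort_spec()].
#' @return List with `recordings` (named list of [recording()]), `cohort`
#'   (a [cohort_table()]), and `events` (named list of ground-truth event
#'   data frames).
#' @export
simulate_cohort <- function(bank, spec) {
  gt <- names(spec$genotypes)
  npg <- spec$subjects_per_genotype
  if (length(npg) == 1) npg <- stats::setNames(rep(npg, length(gt)), gt)
  recordings <- list()
  events <- list()
  rows <- NULL
  sidx <- 0
  for (g in gt) {
    cfg <- spec$genotypes[[g]]
    parts <- strsplit(g, "-", fixed = TRUE)[[1]]
    strain <- parts[1]
    tsc <- if (length(parts) > 1) parts[2] else "WT"
    for (i in seq_len(npg[[g]])) {
      sidx <- sidx + 1
      sid <- sprintf("S%02d", sidx)
      sim <- simulate_recording(
        bank, cfg$rates_per_min,
        amp_meanlog = cfg$amp_meanlog %||% 0,
        amp_sdlog = cfg$amp_sdlog %||% 0.25,
        noise_sd = spec$noise_sd, duration = spec$duration,
        rate = spec$rate, seed = spec$seed + 7919L * sidx,
        subject_id = sid, one_over_f = spec$one_over_f)
      recordings[[sid]] <- sim$recording
      events[[sid]] <- sim$events
      rows <- rbind(rows, data.frame(
        subject_id = sid, strain = strain, tsc = tsc,
        sex = if (i %% 2 == 1) "F" else "M",
        fold = (i - 1) %% 2))
    }
  }
  list(recordings = recordings, cohort = cohort_table(rows), events = events)
}

#' Planted-waveform recovery score for a learned dictionary
#'
#' For each planted waveform, the best match among the learned centroids is
#' the maximum absolute cosine similarity over all relative shifts; the
#' vector of best-match cosines (one per planted waveform) is returned.
#'
#' @param bank The generating [make_waveform_bank()].
#' @param dict A learned [waveform_dictionary()].
#' @return Numeric vector, one best-match cosine per planted waveform.
#' @export
recovery_cosines <- function(bank, dict) {
  vapply(bank$waveforms, function(w) {
    max(vapply(seq_len(dict$K), function(k) {
      shift_max_cosine(w, dict$centroids[k, ])
    }, 0))
  }, 0)
}
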