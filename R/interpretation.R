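#' Linear-model Shapley values
#'
#' Under a feature-independence assumption the Shapley value of feature `k`
#' for class `y` in a linear (logistic) model is the coefficient times the
#' feature's deviation from its training mean:
#' `phi_k = beta_k * (x_k - mean_k)`. The values decompose the log-odds
#' additively: `f_y(x) = phi0_y + sum_k phi_k`, with
#' `phi0_y = beta0_y + sum_k beta_k * mean_k`.
#'
#' @param model A `bow_classifier`.
#' @param feature_vec Transformed feature vector for one subject.
#' @param feature_means Training-set mean of each (transformed) feature.
#' @return Matrix of Shapley values, one row per class, plus an attribute
#'   `phi0` with the per-class base values.
#' @export
shapley_linear <- function(model, feature_vec, feature_means) {
  if (length(feature_vec) != ncol(model$coefficients) ||
      length(feature_means) != ncol(model$coefficients)) {
    stopf("feature vector, means, and coefficients must have matching length")
  }
  dev <- feature_vec - feature_means
  phi <- sweep(model$coefficients, 2, dev, `*`)
  rownames(phi) <- model$classes
  attr(phi, "phi0") <- model$biases +
    as.numeric(model$coefficients %*% feature_means)
  phi
}

#' Average class-signed Shapley values (ACSSV) across a fold's LOO models
#'
#' For each tested subject `s`, the Shapley values of its own pooled
#' feature vector are computed under the model trained with `s` held out
#' (using that model's training feature means), then averaged across the
#' fold's tested subjects with sign `+1` for members of the class and `-1`
#' otherwise. This equals the covariance between the Shapley value and the
#' signed class indicator because the Shapley values are mean-zero over the
#' training feature distribution.
#'
#' @param loo A `loo_result` from [loo_evaluate()] (non-factorized task).
#' @param class Class label whose indicator is used (e.g. `"Het"`).
#' @param bags_by_subject Optional named list of segment bags used to
#'   attach per-waveform occurrence rates (counts/minute) inside and
#'   outside the class.
#' @return Data frame (class `acssv_table`) with one row per feature:
#'   `feature`, `acssv`, `mean_coefficient`, and (if bags are given)
#'   `rate_in`, `rate_out`.
#' @export
acssv <- function(loo, class, bags_by_subject = NULL) {
  if (loo$task == "factorized") stopf("ACSSV is computed per component model, not on the factorized result")
  test_subjects <- loo$predictions$subject_id
  D <- ncol(loo$models[[test_subjects[1]]]$model$coefficients)
  sig <- numeric(D)
  coefs <- matrix(0, length(test_subjects), D)
  for (i in seq_along(test_subjects)) {
    s <- test_subjects[i]
    ms <- loo$models[[s]]
    beta <- ms$model$coefficients[class, ]
    phi <- beta * (ms$pooled_features[s, ] - ms$feature_means)
    sgn <- if (loo$labels[[s]] == class) 1 else -1
    sig <- sig + sgn * phi
    coefs[i, ] <- beta
  }
  out <- data.frame(feature = seq_len(D),
                    acssv = sig / length(test_subjects),
                    mean_coefficient = colMeans(coefs))
  if (!is.null(bags_by_subject)) {
    rates <- occurrence_rates(bags_by_subject, loo$labels, class)
    out$rate_in <- rates$rate_in
    out$rate_out <- rates$rate_out
  }
  class(out) <- c("acssv_table", "data.frame")
  out
}

#' Welch power spectrum of a short waveform
#'
#' Estimates the power spectral density of a waveform from two 95%-length
#' Hann-tapered sub-windows with 90% overlap (for a 256-sample waveform:
#' length 243 at offsets 0 and 13), each zero-padded to `pad_length`. The
#' peak frequency is located above the acquisition high-pass cutoff.
#'
#' @param waveform Numeric vector (canonically 256 samples = 1 s at 256 Hz).
#' @param rate Sampling rate in Hz.
#' @param pad_length FFT length after zero padding (grid spacing =
#'   `rate / pad_length`).
#' @param highpass Cutoff in Hz below which bins are excluded from the peak
#'   search.
#' @return List of class `spectrum_estimate` with `freqs` (Hz), `psd`,
#'   `peak_freq` (Hz; `NA` with a flag for a constant waveform), and
#'   `offsets` (the sub-window start indices used).
#' @export
waveform_spectrum <- function(waveform, rate = 256, pad_length = 1024,
                              highpass = 1) {
  P <- length(waveform)
  wl <- round(0.95 * P)
  overlap <- round(0.90 * P)
  stride <- max(wl - overlap, 1)
  offsets <- seq(0, P - wl, by = stride)
  h <- hann_window(wl)
  scale <- rate * sum(h^2)
  nb <- pad_length %/% 2 + 1
  psd <- numeric(nb)
  for (o in offsets) {
    seg <- waveform[(o + 1):(o + wl)] * h
    f <- stats::fft(c(seg, numeric(pad_length - wl)))
    psd <- psd + (abs(f[seq_len(nb)])^2) / scale
  }
  psd <- psd / length(offsets)
  psd[c(-1, -nb)] <- 2 * psd[c(-1, -nb)]  # one-sided
  freqs <- (seq_len(nb) - 1) * rate / pad_length
  flat <- stats::var(waveform) == 0
  peak <- NA_real_
  if (!flat) {
    sel <- which(freqs >= highpass)
    peak <- freqs[sel[which.max(psd[sel])]]
  }
  structure(list(freqs = freqs, psd = psd, peak_freq = peak,
                 offsets = offsets, flat = flat),
            class = "spectrum_estimate")
}

#' @export
print.spectrum_estimate <- function(x, ...) {
  cat(sprintf("<spectrum_estimate> %d bins, df=%.3g Hz, peak %.2f Hz\n",
              length(x$freqs), x$freqs[2] - x$freqs[1], x$peak_freq))
  invisible(x)
}

#' Per-waveform occurrence rates in counts per minute
#'
#' Sums counts over segments belonging to subjects inside the class,
#' outside it, and overall, dividing by the corresponding total minutes.
#'
#' @param bags_by_subject Named list: subject id -> list of
#'   [bag_of_waves()].
#' @param labels Named label vector by subject.
#' @param class Class defining "inside".
#' @return Data frame with one row per feature: `rate_in`, `rate_out`,
#'   `rate_all` (counts/minute).
#' @export
occurrence_rates <- function(bags_by_subject, labels, class) {
  subj <- names(bags_by_subject)
  csum <- function(ss) {
    if (length(ss) == 0) return(list(counts = 0, minutes = 0))
    bags <- unlist(lapply(ss, function(s) bags_by_subject[[s]]), recursive = FALSE)
    mins <- sum(vapply(bags, function(b) b$segment_meta$duration %||% NA_real_, 0)) / 60
    if (is.na(mins) || mins <= 0) stopf("segments must carry positive durations")
    list(counts = Reduce(`+`, lapply(bags, `[[`, "counts")), minutes = mins)
  }
  inn <- csum(subj[labels[subj] == class])
  out <- csum(subj[labels[subj] != class])
  all <- csum(subj)
  data.frame(feature = seq_along(all$counts),
             rate_in = if (inn$minutes > 0) inn$counts / inn$minutes else NA_real_,
             rate_out = if (out$minutes > 0) out$counts / out$minutes else NA_real_,
             rate_all = all$counts / all$minutes)
}

#' Ranked report of the waveforms most indicative of a class
#'
#' Filters the ACSSV table to features with positive mean coefficient,
#' ranks by ACSSV descending, and (when dictionaries are supplied) attaches
#' each waveform's shape, Welch peak frequency, and occurrence rates. An
#' empty report (all coefficients negative) is returned with a notice
#' attribute.
#'
#' @param acssv_table An `acssv_table` from [acssv()].
#' @param n_top Number of waveforms to report.
#' @param dicts Optional list of [waveform_dictionary()] objects in block
#'   order, used to attach waveform shapes and spectral peaks.
#' @param rate Sampling rate for spectra.
#' @return Data frame of the top waveforms; attribute `notice` explains an
#'   empty report. Attribute `waveforms` holds the corresponding shapes.
#' @export
top_waveform_report <- function(acssv_table, n_top = 5, dicts = NULL,
                                rate = 256) {
  tab <- acssv_table[acssv_table$mean_coefficient > 0, , drop = FALSE]
  if (nrow(tab) == 0) {
    out <- tab
    attr(out, "notice") <- "no features with positive mean coefficient"
    return(out)
  }
  tab <- tab[order(-tab$acssv), , drop = FALSE]
  tab <- utils::head(tab, n_top)
  tab$positively_correlated <- tab$acssv > 0
  if (!is.null(dicts)) {
    Cs <- do.call(rbind, lapply(dicts, `[[`, "centroids"))
    dict_of <- rep(vapply(dicts, function(d) as.character(d$class_label), ""),
                   vapply(dicts, `[[`, 0, "K"))
    tab$dictionary <- dict_of[tab$feature]
    tab$peak_freq <- vapply(tab$feature, function(f) {
      waveform_spectrum(Cs[f, ], rate = rate)$peak_freq
    }, 0)
    attr(tab, "waveforms") <- Cs[tab$feature, , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab
}
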