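# Brute-force oracles and small fixture builders shared across tests.

# Exhaustive (k, tau) search for the shift-invariant assignment: double loop
# over all waveforms and shifts computing the cosine directly.
brute_assign <- function(X, C) {
  M <- nrow(X); K <- nrow(C); P <- ncol(C); L <- ncol(X)
  out <- data.frame(k = integer(M), tau = integer(M), similarity = numeric(M))
  for (i in seq_len(M)) {
    best <- -Inf; bk <- 1L; bt <- 0L
    for (k in seq_len(K)) {
      for (tau in 0:(L - P)) {
        w <- X[i, (tau + 1):(tau + P)]
        den <- sqrt(sum(w^2)) * sqrt(sum(C[k, ]^2))
        cs <- if (den == 0) 0 else sum(w * C[k, ]) / den
        if (cs > best) { best <- cs; bk <- k; bt <- tau }
      }
    }
    out$k[i] <- bk; out$tau[i] <- bt; out$similarity[i] <- best
  }
  out
}

# Hand-coded SCW double loop over offsets.
brute_scw <- function(segment, C) {
  P <- ncol(C)
  Ct <- t(apply(C, 1, function(ck) { ck <- ck - mean(ck); ck / sum(abs(ck)) }))
  z <- numeric(nrow(C))
  for (tau in 0:(length(segment) - P)) {
    ip <- as.numeric(Ct %*% segment[(tau + 1):(tau + P)])
    k <- which.max(ip)
    z[k] <- z[k] + ip[k]
  }
  z
}

# O(n^2) pairwise AUC with ties counted one half.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (n in neg) s <- s + (p > n) + 0.5 * (p == n)
  s / (length(pos) * length(neg))
}

# A tiny bag with a single dictionary block.
toy_bag <- function(counts, subject = "s1", duration = 60) {
  bag_of_waves(counts, list(d1 = seq_along(counts)), M = sum(counts),
               segment_meta = list(subject_id = subject, start = 0,
                                   duration = duration))
}

# Planted window batch: a fraction of windows are pure noise; the rest hold
# one planted waveform at a random shift plus Gaussian noise at the
# requested SNR (event RMS over noise sd within the window).
planted_batch <- function(waveforms, M, L, snr, seed = 1, frac_noise = 0) {
  P <- length(waveforms[[1]])
  set.seed(seed)
  X <- matrix(0, M, L)
  truth <- data.frame(k = integer(M), tau = integer(M))
  rms <- sqrt(mean(waveforms[[1]]^2))
  noise_sd <- rms / snr
  for (i in seq_len(M)) {
    X[i, ] <- rnorm(L, 0, noise_sd)
    if (runif(1) >= frac_noise) {
      k <- sample(length(waveforms), 1)
      tau <- sample(0:(L - P), 1)
      X[i, ] <- X[i, ] + shift_pad(waveforms[[k]], tau, L)
      truth$k[i] <- k; truth$tau[i] <- tau
    }
  }
  list(batch = window_batch(X), truth = truth)
}
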