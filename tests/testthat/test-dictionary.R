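test_that("assignment finds exact planted copies and records negatives", {
  set.seed(2)
  C <- matrix(rnorm(8), 2, 4)
  L <- 12
  w <- shift_pad(C[2, ], 3, L)
  a <- assign_windows(window_batch(rbind(w)), waveform_dictionary(C, L = L))
  expect_equal(a$k, 2)
  expect_equal(a$tau, 3)
  expect_equal(a$similarity, 1)
  expect_equal(a$alpha, 1)

  # a negated copy of an all-positive waveform correlates negatively at
  # every shift: it is still assigned at its argmax, with alpha clamped to 0
  cpos <- abs(rnorm(4)) + 0.1
  neg <- -shift_pad(cpos, 0, 6)
  a2 <- assign_windows(window_batch(rbind(neg)),
                       waveform_dictionary(rbind(cpos), L = 6))
  expect_lt(a2$similarity, 0)
  expect_equal(a2$alpha, 0)
  expect_equal(nrow(a2), 1)
})

test_that("assignment matches the exhaustive (k, tau) search on random instances", {
  set.seed(11)
  for (trial in 1:100) {
    M <- sample(2:6, 1); L <- sample(8:32, 1)
    P <- sample(3:(L - 1), 1); K <- sample(1:4, 1)
    X <- matrix(rnorm(M * L), M)
    C <- matrix(rnorm(K * P), K)
    d <- waveform_dictionary(C, L = L)
    oracle <- brute_assign(X, C)
    for (method in c("direct", "fft")) {
      a <- assign_windows(window_batch(X), d, method = method)
      expect_equal(a$similarity, oracle$similarity, tolerance = 1e-8)
      expect_equal(a$k, oracle$k)
      expect_equal(a$tau, oracle$tau)
    }
  }
})

test_that("direct and FFT inner-product paths agree to tight relative precision", {
  set.seed(3)
  X <- matrix(rnorm(30 * 200), 30)
  C <- matrix(rnorm(3 * 80), 3)   # P >= 64 triggers the FFT path under auto
  d <- waveform_dictionary(C, L = 200)
  a1 <- assign_windows(window_batch(X), d, method = "direct")
  a2 <- assign_windows(window_batch(X), d, method = "fft")
  expect_equal(a2$similarity, a1$similarity, tolerance = 1e-8)
  expect_identical(a2$k, a1$k)
  expect_identical(a2$tau, a1$tau)
})

test_that("centroid updates average aligned sub-windows and re-seed empty clusters", {
  X <- rbind(c(1, 2, 3, 4, 5, 6), c(10, 20, 30, 40, 50, 60))
  b <- window_batch(X)
  a <- data.frame(k = c(1L, 1L), tau = c(1L, 2L), similarity = 1, alpha = 1)
  up <- update_centroids(b, a, K = 1, P = 3)
  expect_equal(up[1, ], colMeans(rbind(c(2, 3, 4), c(30, 40, 50))))

  # single window: centroid equals the extracted sub-window exactly
  a1 <- data.frame(k = 1L, tau = 2L, similarity = 1, alpha = 1)
  up1 <- update_centroids(window_batch(X[1, , drop = FALSE]), a1, K = 1, P = 3)
  expect_equal(up1[1, ], c(3, 4, 5))

  # an empty cluster is re-seeded from a training window prefix (seeded RNG)
  up2a <- bowaves:::with_seed(5, update_centroids(b, a, K = 2, P = 3))
  up2b <- bowaves:::with_seed(5, update_centroids(b, a, K = 2, P = 3))
  expect_identical(up2a, up2b)
  expect_true(any(apply(X[, 1:3, drop = FALSE], 1,
                        function(r) all(r == up2a[2, ]))))
})

test_that("shift-invariant k-means recovers identical copies in one iteration", {
  set.seed(4)
  c1 <- rnorm(4)
  X <- t(replicate(20, shift_pad(c1, 0, 10)))
  d <- fit_shift_invariant_kmeans(window_batch(X), K = 1, P = 4, seed = 1)
  expect_equal(as.numeric(d$centroids), c1, tolerance = 1e-12)
  expect_lte(d$train_meta$iterations, 2)
  expect_equal(reconstruction_objective(window_batch(X), d), 0,
               tolerance = 1e-12)
})

test_that("fits are deterministic given the batch and seed", {
  set.seed(5)
  X <- matrix(rnorm(60 * 16), 60)
  b <- window_batch(X)
  d1 <- fit_shift_invariant_kmeans(b, K = 3, P = 8, seed = 42)
  d2 <- fit_shift_invariant_kmeans(b, K = 3, P = 8, seed = 42)
  expect_identical(d1$centroids, d2$centroids)
  expect_error(fit_shift_invariant_kmeans(window_batch(X[1:2, ]), K = 3, P = 8),
               "exceeds")
})

test_that("planted waveforms are recovered from noisy planted windows", {
  # three separable bank waveforms planted in 60% of 600 windows at SNR 10,
  # learned with two slack centroids; a single k-means run can park one
  # waveform in a shift-truncated local optimum, so the frozen property is
  # median recovery >= 0.9 with at least one near-exact match, every
  # waveform >= 0.8
  bank <- make_waveform_bank(1, 2, P = 64, rate = 128,
                             freq_range = c(4, 16), seed = 5)
  waves <- bank$waveforms
  stopifnot(bowaves:::bank_separable(waves, 0.8))
  pb <- planted_batch(waves, M = 600, L = 128, snr = 10, seed = 7,
                      frac_noise = 0.4)
  d <- fit_shift_invariant_kmeans(pb$batch, K = 5, P = 64, seed = 9)
  cos <- recovery_cosines(bank, d)
  expect_gte(median(cos), 0.9)
  expect_gte(max(cos), 0.95)
  expect_true(all(cos >= 0.8))
})

test_that("reconstruction objective matches brute-force minimization over a grid", {
  set.seed(9)
  for (trial in 1:20) {
    L <- 12; P <- 5
    x <- rnorm(L); ck <- rnorm(P)
    d <- waveform_dictionary(rbind(ck), L = L)
    obj <- reconstruction_objective(window_batch(rbind(x)), d)
    # brute force over all shifts and a refined grid of non-negative scales
    best <- Inf
    for (tau in 0:(L - P)) {
      for (alpha in seq(0, 5, length.out = 2001)) {
        best <- min(best, sum((x - alpha * shift_pad(ck, tau, L))^2))
      }
    }
    expect_equal(obj, best, tolerance = 1e-4)
    expect_lte(obj, sum(x^2) + 1e-12)  # alpha = 0 always available
  }
})

test_that("the per-cluster least-squares update never increases the fixed-assignment error", {
  set.seed(10)
  for (trial in 1:20) {
    M <- 12; L <- 14; P <- 6; K <- 2
    X <- matrix(rnorm(M * L), M)
    C <- matrix(rnorm(K * P), K)
    d <- waveform_dictionary(C, L = L)
    a <- assign_windows(window_batch(X), d)
    fixed_err <- function(Cm) {
      sum(vapply(seq_len(M), function(i) {
        sum((X[i, ] - a$alpha[i] * shift_pad(Cm[a$k[i], ], a$tau[i], L))^2)
      }, 0))
    }
    # weighted least-squares optimum per cluster under fixed (k, tau, alpha)
    Copt <- C
    for (k in seq_len(K)) {
      idx <- which(a$k == k & a$alpha > 0)
      if (length(idx) == 0) next
      W <- t(vapply(idx, function(i) {
        extract_window(X[i, ], a$tau[i], P)
      }, numeric(P)))
      Copt[k, ] <- colSums(W * a$alpha[idx]) / sum(a$alpha[idx]^2)
    }
    expect_lte(fixed_err(Copt), fixed_err(C) + 1e-10)
  }
})
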