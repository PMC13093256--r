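mk_model <- function(classes, biases, coefs) {
  structure(list(classes = classes, biases = biases, coefficients = coefs,
                 reg_C = 1, transform = NULL), class = "bow_classifier")
}

test_that("linear Shapley values equal coefficient times deviation and add up", {
  m <- mk_model("pos", 0.3, rbind(c(2, -1)))
  phi <- shapley_linear(m, c(0.5, 0.2), c(0.1, 0.4))
  expect_equal(unname(phi["pos", ]), c(0.8, 0.2))

  # at the mean, every Shapley value vanishes
  mu <- c(0.1, 0.4)
  expect_equal(unname(shapley_linear(m, mu, mu)["pos", ]), c(0, 0))

  # additivity: score = phi0 + sum(phi), to 1e-10
  set.seed(1)
  for (i in 1:20) {
    D <- 5
    m2 <- mk_model(c("a", "b"), rnorm(2), matrix(rnorm(2 * D), 2))
    x <- rnorm(D); mu <- rnorm(D)
    phi <- shapley_linear(m2, x, mu)
    f <- m2$biases + as.numeric(m2$coefficients %*% x)
    expect_equal(unname(attr(phi, "phi0") + rowSums(phi)), f,
                 tolerance = 1e-10)
  }
})

# Build a minimal loo_result by hand: per-subject models with known
# coefficients, feature means, and pooled features.
mk_loo <- function(phi_rows, labels, class_of_interest = "Het") {
  subjects <- names(labels)
  models <- list()
  for (s in subjects) {
    beta <- phi_rows[[s]]$beta
    models[[s]] <- list(
      model = mk_model(c("WT", "Het"),
                       c(0, 0),
                       rbind(WT = -beta, Het = beta)),
      feature_means = phi_rows[[s]]$means,
      pooled_features = rbind(phi_rows[[s]]$x),
      reg_C = 1)
    rownames(models[[s]]$pooled_features) <- s
  }
  structure(list(
    predictions = data.frame(subject_id = subjects, true = unname(labels),
                             predicted = unname(labels), reg_C = 1),
    models = models, labels = labels, task = "tsc", dict_fold = 0),
    class = "loo_result")
}

test_that("ACSSV equals the signed average and the covariance formulation", {
  labels <- setNames(c("Het", "Het", "WT", "WT"), paste0("s", 1:4))
  set.seed(2)
  rows <- lapply(paste0("s", 1:4), function(s) {
    list(beta = c(1.5, -0.7), x = rnorm(2), means = rnorm(2))
  })
  names(rows) <- names(labels)
  res <- mk_loo(rows, labels)
  tab <- acssv(res, "Het")
  # direct computation: mean of sign * beta * (x - mean)
  direct <- Reduce(`+`, lapply(names(labels), function(s) {
    sgn <- if (labels[s] == "Het") 1 else -1
    sgn * rows[[s]]$beta * (rows[[s]]$x - rows[[s]]$means)
  })) / 4
  expect_equal(tab$acssv, direct)
  # covariance formulation: phi is deterministic per subject here, and the
  # signed indicator has zero mean across the balanced labels, so the
  # covariance between phi and the indicator equals the signed average
  phis <- t(vapply(names(labels), function(s) {
    rows[[s]]$beta * (rows[[s]]$x - rows[[s]]$means)
  }, numeric(2)))
  ysgn <- ifelse(labels == "Het", 1, -1)
  n <- length(ysgn)
  cov_form <- colMeans(phis * ysgn) - colMeans(phis) * mean(ysgn)
  # with balanced labels mean(ysgn) = 0 and the two agree exactly
  expect_equal(tab$acssv, cov_form)
  # identical Shapley values across subjects with balanced labels cancel
  rows_same <- lapply(rows, function(r) { r$x <- c(1, 1); r$means <- c(0, 0); r })
  expect_equal(acssv(mk_loo(rows_same, labels), "Het")$acssv, c(0, 0))
})

test_that("Welch spectra localize tones and use the prescribed sub-windows", {
  t <- (0:255) / 256
  tone <- sin(2 * pi * 8 * t)
  sp <- waveform_spectrum(tone, rate = 256)
  expect_equal(sp$offsets, c(0, 13))
  expect_equal(sp$freqs[2] - sp$freqs[1], 0.25)
  expect_lte(abs(sp$peak_freq - 8), 0.25)
  expect_true(all(sp$psd >= 0))

  # amplitude scaling does not change the spectral ordering
  sp2 <- waveform_spectrum(5 * tone, rate = 256)
  expect_equal(order(sp2$psd), order(sp$psd))
  expect_equal(sp2$peak_freq, sp$peak_freq)

  # white-noise waveforms have no dominant narrow peak (Monte Carlo)
  set.seed(3)
  flat_ok <- vapply(1:5, function(i) {
    spn <- waveform_spectrum(rnorm(256), rate = 256)
    sel <- spn$freqs >= 1
    max(spn$psd[sel]) < 10 * median(spn$psd[sel])
  }, TRUE)
  expect_gte(mean(flat_ok), 0.8)

  # constant waveform: flat flag set, no peak
  spc <- waveform_spectrum(rep(1, 256))
  expect_true(spc$flat)
  expect_true(is.na(spc$peak_freq))
})

test_that("occurrence rates convert counts to per-minute units", {
  bags <- list(
    s1 = list(toy_bag(c(90, 0), duration = 1800), toy_bag(c(0, 10), duration = 1800)),
    s2 = list(toy_bag(c(30, 5), duration = 3600)))
  labels <- c(s1 = "Het", s2 = "WT")
  r <- occurrence_rates(bags, labels, "Het")
  expect_equal(r$rate_in[1], 90 / 60)   # 90 events in 60 minutes
  expect_equal(r$rate_in[2], 10 / 60)
  expect_equal(r$rate_out[1], 30 / 60)
  expect_equal(r$rate_all[2], 15 / 120)
  expect_equal(r$rate_all[2][r$rate_all[2] == 0], numeric(0))  # non-zero stays
  # a rate of 0.09/min corresponds to an ~11 minute average interval
  expect_equal(round(1 / 0.09), 11)
  # zero counts give rate zero
  bags0 <- list(s1 = list(toy_bag(c(0, 0), duration = 600)))
  expect_equal(occurrence_rates(bags0, c(s1 = "Het"), "Het")$rate_in, c(0, 0))
})

test_that("top-waveform reports filter on coefficient sign and sort by ACSSV", {
  tab <- structure(data.frame(feature = 1:4,
                              acssv = c(0.5, 2, 1, -1),
                              mean_coefficient = c(1, -1, 2, 3)),
                   class = c("acssv_table", "data.frame"))
  rep_ <- top_waveform_report(tab, n_top = 3)
  # feature 2 excluded (negative coefficient); rest sorted by ACSSV
  expect_equal(rep_$feature, c(3, 1, 4))
  expect_equal(rep_$positively_correlated, c(TRUE, TRUE, FALSE))
  # ranking equals a direct sort of the filtered table
  keep <- tab[tab$mean_coefficient > 0, ]
  expect_equal(rep_$acssv, sort(keep$acssv, decreasing = TRUE))

  all_neg <- tab; all_neg$mean_coefficient <- -1
  empty <- top_waveform_report(all_neg)
  expect_equal(nrow(empty), 0)
  expect_match(attr(empty, "notice"), "no features")

  # a dominant positive-coefficient feature ranks first, with spectra attached
  set.seed(4)
  dicts <- list(waveform_dictionary(matrix(rnorm(4 * 64), 4), L = 128,
                                    class_label = "A"))
  r2 <- top_waveform_report(tab, n_top = 2, dicts = dicts, rate = 256)
  expect_equal(r2$feature[1], 3)
  expect_true(all(is.finite(r2$peak_freq)))
  expect_equal(nrow(attr(r2, "waveforms")), 2)
})
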