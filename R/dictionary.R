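#' Waveform dictionary container
#'
#' A set of `K` centroid waveforms of length `P` learned from windows of
#' length `L`, with class/fold provenance and training metadata. Centroids
#' are stored unnormalized (cluster averages); cosine-similarity matching
#' makes downstream assignment scale-free.
#'
#' @param centroids Numeric `K x P` matrix of waveform shapes (microvolts).
#' @param L Training window length in samples (`P < L`).
#' @param class_label Class (genotype) tag for provenance.
#' @param fold Fold identifier for provenance.
#' @param train_meta List of training metadata (iterations, final centroid
#'   change, seed, tolerance).
#' @return An object of class `waveform_dictionary`.
#' @export
waveform_dictionary <- function(centroids, L, class_label = NA, fold = NA,
                                train_meta = list()) {
  centroids <- as.matrix(centroids)
  if (nrow(centroids) < 1) stopf("need at least one centroid")
  if (ncol(centroids) >= L) stopf("waveform length P=%d must be < window length L=%d",
                                  ncol(centroids), L)
  if (any(rowSums(centroids^2) == 0)) stopf("no centroid may be all-zero")
  structure(list(centroids = centroids, K = nrow(centroids),
                 P = ncol(centroids), L = L, class_label = class_label,
                 fold = fold, train_meta = train_meta),
            class = "waveform_dictionary")
}

#' @export
print.waveform_dictionary <- function(x, ...) {
  cat(sprintf("<waveform_dictionary> K=%d waveforms of length P=%d (windows L=%d), class=%s fold=%s\n",
              x$K, x$P, x$L, as.character(x$class_label), as.character(x$fold)))
  if (!is.null(x$train_meta$iterations)) {
    cat(sprintf("  trained: %d iterations, final centroid change %.3g\n",
                x$train_meta$iterations, x$train_meta$final_change))
  }
  invisible(x)
}

# Rolling sub-window squared norms: M x (L-P+1) matrix of ||W_tau(x_i)||^2.
subwindow_sqnorms <- function(X, P) {
  L <- ncol(X)
  cc <- apply(X^2, 1, cumsum)              # L x M cumulative sums
  Tn <- L - P + 1
  out <- matrix(0, nrow(X), Tn)
  out[, 1] <- cc[P, ]
  if (Tn > 1) {
    for (t in 2:Tn) out[, t] <- cc[P + t - 1, ] - cc[t - 1, ]
  }
  pmax(out, 0)
}

# Streaming access to inner products <W_tau(x_i), c_k>: returns a closure
# `f(t)` (t is 1-based shift index, tau = t - 1) yielding an M x K matrix.
# Direct path: one matrix product per shift. FFT path: cross-correlation of
# every window with every centroid via the FFT, computed once up front.
# Both paths agree to high relative precision (contract tested).
ip_stream <- function(X, C, method = c("auto", "direct", "fft")) {
  method <- match.arg(method)
  P <- ncol(C); L <- ncol(X); K <- nrow(C); M <- nrow(X)
  Tn <- L - P + 1
  if (method == "auto") method <- if (P >= 64) "fft" else "direct"
  if (method == "direct") {
    function(t) X[, t:(t + P - 1), drop = FALSE] %*% t(C)
  } else {
    FX <- stats::mvfft(t(X))                          # L x M
    Cp <- rbind(t(C), matrix(0, L - P, K))            # L x K zero-padded
    FC <- stats::mvfft(Cp)
    ips <- vector("list", K)
    for (k in seq_len(K)) {
      g <- Re(stats::mvfft(FX * Conj(FC[, k]), inverse = TRUE)) / L  # L x M
      ips[[k]] <- t(g[seq_len(Tn), , drop = FALSE])                  # M x Tn
    }
    function(t) {
      out <- matrix(0, M, K)
      for (k in seq_len(K)) out[, k] <- ips[[k]][, t]
      out
    }
  }
}

#' Assign windows to dictionary waveforms with optimal shifts
#'
#' For each window finds the waveform index `k` and shift `tau` maximizing
#' the cosine similarity between the sub-window `W_tau(x)` and the centroid.
#' Ties are broken by lowest `k`, then lowest `tau`. The scale coefficient
#' `alpha = max(0, <W_tau(x), c_k> / ||c_k||^2)` is reported alongside; a
#' window whose best similarity is negative is still assigned to its argmax
#' waveform (its `alpha` is clamped to zero). Zero-norm sub-windows or
#' centroids have similarity defined as 0.
#'
#' @param batch A [window_batch()].
#' @param dict A [waveform_dictionary()] with `P <= ` window length.
#' @param method `"direct"` dot products, `"fft"` cross-correlation, or
#'   `"auto"` (FFT when `P >= 64`).
#' @return Data frame with one row per window: `k`, `tau` (0-based),
#'   `similarity`, `alpha`.
#' @export
assign_windows <- function(batch, dict, method = c("auto", "direct", "fft")) {
  method <- match.arg(method)
  X <- batch$windows
  C <- dict$centroids
  P <- dict$P
  if (P > ncol(X)) stopf("dictionary P=%d exceeds window length %d", P, ncol(X))
  M <- nrow(X); K <- nrow(C); Tn <- ncol(X) - P + 1
  cn <- sqrt(rowSums(C^2))
  sw <- sqrt(subwindow_sqnorms(X, P))
  get_ip <- ip_stream(X, C, method)
  best_cos <- rep(-Inf, M); best_k <- rep(1L, M)
  best_tau <- rep(0L, M); best_ip <- rep(0, M)
  for (t in seq_len(Tn)) {
    ip <- get_ip(t)
    cs <- sweep(ip, 2, cn, "/") / sw[, t]
    cs[sw[, t] == 0, ] <- 0
    if (any(cn == 0)) cs[, cn == 0] <- 0
    kt <- max.col(cs, ties.method = "first")
    ct <- cs[cbind(seq_len(M), kt)]
    imp <- ct > best_cos | (ct == best_cos & kt < best_k)
    if (any(imp)) {
      best_cos[imp] <- ct[imp]
      best_k[imp] <- kt[imp]
      best_tau[imp] <- t - 1L
      best_ip[imp] <- ip[cbind(seq_len(M), kt)][imp]
    }
  }
  alpha <- pmax(0, best_ip / cn[best_k]^2)
  data.frame(k = best_k, tau = best_tau, similarity = best_cos, alpha = alpha)
}

#' Update centroids as averages of their aligned assigned sub-windows
#'
#' Each centroid is replaced by the plain element-wise average of the
#' sub-windows `W_tau_i(x_i)` assigned to it. A waveform with no assigned
#' windows is re-seeded from the first `P` samples of a uniformly drawn
#' training window (draws come from the active RNG stream; wrap in a seeded
#' context for determinism).
#'
#' @param batch A [window_batch()].
#' @param assignments Data frame from [assign_windows()] covering all rows
#'   of `batch`.
#' @param K Number of waveforms.
#' @param P Waveform length.
#' @return `K x P` matrix of updated centroids.
#' @export
update_centroids <- function(batch, assignments, K, P) {
  X <- batch$windows
  M <- nrow(X)
  if (nrow(assignments) != M) stopf("assignments must cover all %d windows", M)
  cols <- outer(assignments$tau, seq_len(P), "+")      # M x P column indices
  aligned <- matrix(X[cbind(rep(seq_len(M), P), as.vector(cols))], M, P)
  rs <- rowsum(aligned, assignments$k)
  sums <- matrix(0, K, P)
  sums[as.integer(rownames(rs)), ] <- rs
  counts <- tabulate(assignments$k, nbins = K)
  newC <- sums / pmax(counts, 1)
  for (k in which(counts == 0)) {
    i <- sample.int(M, 1)
    newC[k, ] <- X[i, seq_len(P)]
  }
  newC
}

#' Fit a waveform dictionary by shift-invariant k-means
#'
#' Alternates cosine-similarity assignment (over waveforms and shifts) with
#' plain averaging of aligned sub-windows. Centroids are initialized as the
#' first `P` samples of `K` uniformly chosen windows (without replacement).
#' Iteration stops when the mean squared centroid change
#' `(1/(P K)) * sum ||c_k_old - c_k_new||^2` falls to or below
#' `tol_factor` times the pooled pointwise variance of the training
#' windows, or after `max_iter` updates.
#'
#' @param batch A [window_batch()] with at least `K` windows.
#' @param K Number of waveforms.
#' @param P Waveform length (`< ` window length).
#' @param max_iter Maximum update iterations.
#' @param tol_factor Stopping tolerance as a fraction of the pooled sample
#'   variance of the training windows.
#' @param seed Integer seed controlling initialization and empty-cluster
#'   re-seeding; fits are deterministic given `(batch, seed)`.
#' @param method Inner-product path, see [assign_windows()].
#' @param class_label,fold Provenance tags stored on the dictionary.
#' @return A [waveform_dictionary()].
#' @export
fit_shift_invariant_kmeans <- function(batch, K, P, max_iter = 300,
                                       tol_factor = 1e-4, seed = 1,
                                       method = "auto",
                                       class_label = NA, fold = NA) {
  X <- batch$windows
  M <- nrow(X); L <- ncol(X)
  if (K > M) stopf("K=%d exceeds the number of windows M=%d", K, M)
  if (P >= L) stopf("P=%d must be < window length L=%d", P, L)
  tol <- tol_factor * stats::var(as.vector(X))
  with_seed(seed, {
    idx <- sample.int(M, K)
    C <- X[idx, seq_len(P), drop = FALSE]
    it <- 0
    delta <- Inf
    while (it < max_iter) {
      d <- waveform_dictionary(C, L = L)
      a <- assign_windows(batch, d, method = method)
      Cn <- update_centroids(batch, a, K, P)
      delta <- sum((C - Cn)^2) / (P * K)
      C <- Cn
      it <- it + 1
      if (delta <= tol) break
    }
    waveform_dictionary(C, L = L, class_label = class_label, fold = fold,
                        train_meta = list(iterations = it,
                                          final_change = delta,
                                          tol = tol, seed = seed))
  })
}

#' Mean squared reconstruction error of a dictionary on a window batch
#'
#' Evaluates `(1/M) sum_i min over (alpha >= 0, k, tau) of
#' ||x_i - alpha * S_tau(c_k)||^2` using the closed form: for each `(k,
#' tau)` the optimal clamped scale gives residual `||x_i||^2 -
#' max(0, <W_tau(x_i), c_k>)^2 / ||c_k||^2`, minimized over all `(k, tau)`.
#' Note this true minimum can differ from the residual at the
#' cosine-similarity assignment, which ignores sub-window norms.
#'
#' @param batch A [window_batch()].
#' @param dict A [waveform_dictionary()].
#' @param method Inner-product path, see [assign_windows()].
#' @return Scalar mean squared error.
#' @export
reconstruction_objective <- function(batch, dict, method = "auto") {
  X <- batch$windows
  C <- dict$centroids
  P <- dict$P
  M <- nrow(X); Tn <- ncol(X) - P + 1
  cn2 <- rowSums(C^2)
  get_ip <- ip_stream(X, C, method)
  best <- rep(0, M)  # max over (k, tau) of pos-part ip^2 / ||c||^2; >= 0
  for (t in seq_len(Tn)) {
    ip <- get_ip(t)
    sc <- sweep(pmax(ip, 0)^2, 2, cn2, "/")
    m <- do.call(pmax, c(split(sc, col(sc)), list(best)))
    best <- m
  }
  mean(rowSums(X^2) - best)
}
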