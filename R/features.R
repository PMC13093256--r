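#' Bag-of-waves count vector
#'
#' Non-negative integer counts of waveform assignments over the
#' concatenation of `J` dictionaries. Each dictionary block sums to the
#' number of windows `M` in the encoded segment, so the total count is
#' `J * M`.
#'
#' @param counts Integer vector of length `D = sum(K_j)`.
#' @param block_index Named list mapping each dictionary label to its
#'   coordinate range (integer vector of positions).
#' @param M Number of windows in the encoded segment.
#' @param segment_meta List with `subject_id`, `start`, `duration` (seconds).
#' @return An object of class `bag_of_waves`.
#' @export
bag_of_waves <- function(counts, block_index, M, segment_meta = list()) {
  counts <- as.integer(counts)
  if (any(counts < 0)) stopf("counts must be non-negative")
  structure(list(counts = counts, block_index = block_index, M = M,
                 segment_meta = segment_meta),
            class = "bag_of_waves")
}

#' @export
print.bag_of_waves <- function(x, ...) {
  cat(sprintf("<bag_of_waves> D=%d features over %d dictionaries, M=%d windows, subject %s\n",
              length(x$counts), length(x$block_index), x$M,
              x$segment_meta$subject_id %||% "?"))
  invisible(x)
}

same_blocks <- function(a, b) {
  identical(names(a$block_index), names(b$block_index)) &&
    identical(unname(lapply(a$block_index, length)),
              unname(lapply(b$block_index, length)))
}

#' Encode a segment as a bag-of-waves over concatenated dictionaries
#'
#' Splits the segment into non-overlapping windows of the dictionaries'
#' training window length `L`, runs the shift-invariant assignment
#' independently against each dictionary, and concatenates the
#' per-dictionary assignment counts.
#'
#' @param segment Numeric sample vector, or a segment list as produced by
#'   [sample_segments()] (fields `samples`, `subject_id`, `start`,
#'   `duration`).
#' @param dicts List of [waveform_dictionary()] objects sharing `P` and `L`.
#' @param rate Sampling rate in Hz, used to record the segment duration when
#'   `segment` is a bare vector.
#' @param method Inner-product path, see [assign_windows()].
#' @param stride Window stride in samples; defaults to `L`
#'   (non-overlapping). `L - P + 1` covers every possible shift.
#' @return A [bag_of_waves()].
#' @export
encode_bow <- function(segment, dicts, rate = NULL, method = "auto",
                       stride = NULL) {
  meta <- list(subject_id = NA_character_, start = NA_real_, duration = NA_real_)
  if (is.list(segment) && !is.null(segment$samples)) {
    meta <- list(subject_id = segment$subject_id, start = segment$start,
                 duration = segment$duration)
    segment <- segment$samples
  } else if (!is.null(rate)) {
    meta$duration <- length(segment) / rate
  }
  Ps <- vapply(dicts, `[[`, 0, "P")
  Ls <- vapply(dicts, `[[`, 0, "L")
  if (length(unique(Ps)) != 1 || length(unique(Ls)) != 1) {
    stopf("all dictionaries must share P and L")
  }
  L <- Ls[1]
  batch <- segment_to_windows(segment, L, stride = stride %||% L,
                              subject_id = meta$subject_id)
  labels <- vapply(seq_along(dicts), function(j) {
    lb <- dicts[[j]]$class_label
    if (is.na(lb)) paste0("dict", j) else as.character(lb)
  }, "")
  counts <- integer(0)
  block_index <- list()
  off <- 0
  for (j in seq_along(dicts)) {
    a <- assign_windows(batch, dicts[[j]], method = method)
    cj <- tabulate(a$k, nbins = dicts[[j]]$K)
    counts <- c(counts, cj)
    block_index[[labels[j]]] <- off + seq_len(dicts[[j]]$K)
    off <- off + dicts[[j]]$K
  }
  bag_of_waves(counts, block_index, M = nrow(batch$windows), segment_meta = meta)
}

#' Estimate TFIDF weights from training bags
#'
#' `w_k = log((1 + N_train) / (1 + N_k)) + 1` (natural log), where `N_k` is
#' the number of training segments in which feature `k` is nonzero. Weights
#' are non-increasing in `N_k`, with `w_k = 1` iff the feature is nonzero in
#' every training segment.
#'
#' @param train_bags List of [bag_of_waves()] with identical block structure.
#' @return An object of class `tfidf_weights` with fields `w`, `N_train`,
#'   `N_k`, `block_index`.
#' @export
fit_tfidf <- function(train_bags) {
  if (length(train_bags) < 1) stopf("need at least one training bag")
  Z <- do.call(rbind, lapply(train_bags, `[[`, "counts"))
  N_k <- colSums(Z > 0)
  N <- nrow(Z)
  w <- log((1 + N) / (1 + N_k)) + 1
  structure(list(w = w, N_train = N, N_k = N_k,
                 block_index = train_bags[[1]]$block_index),
            class = "tfidf_weights")
}

#' Apply TFIDF weighting and unit-norm scaling to a bag
#'
#' Element-wise product with the weights followed by Euclidean
#' normalization. An all-zero bag yields an all-zero vector with a warning.
#' The output is invariant to any positive rescaling of the counts, so
#' counts and occurrence rates give the same feature.
#'
#' @param bag A [bag_of_waves()] or bare count vector.
#' @param weights A `tfidf_weights` object from [fit_tfidf()].
#' @return Numeric feature vector of unit Euclidean norm (or all zeros).
#' @export
apply_tfidf <- function(bag, weights) {
  z <- if (inherits(bag, "bag_of_waves")) bag$counts else as.numeric(bag)
  if (length(z) != length(weights$w)) stopf("bag length %d does not match weights length %d",
                                            length(z), length(weights$w))
  v <- weights$w * z
  n <- l2norm(v)
  if (n == 0) {
    warning("all-zero bag: returning a zero feature vector")
    return(v)
  }
  v / n
}

#' Pool bags by summing counts
#'
#' @param bags List of [bag_of_waves()] with identical block structure.
#' @return A single [bag_of_waves()]; `segment_meta` records the pooled
#'   span (total duration, subject if unique).
#' @export
pool_bags <- function(bags) {
  if (length(bags) < 1) stopf("need at least one bag")
  b1 <- bags[[1]]
  for (b in bags[-1]) {
    if (!same_blocks(b1, b)) stopf("bags have heterogeneous block structures")
  }
  counts <- Reduce(`+`, lapply(bags, `[[`, "counts"))
  subj <- unique(vapply(bags, function(b) b$segment_meta$subject_id %||% NA_character_, ""))
  dur <- sum(vapply(bags, function(b) b$segment_meta$duration %||% NA_real_, 0))
  bag_of_waves(counts, b1$block_index,
               M = sum(vapply(bags, `[[`, 0, "M")),
               segment_meta = list(
                 subject_id = if (length(subj) == 1) subj else NA_character_,
                 start = NA_real_, duration = dur, pooled_n = length(bags)))
}

# One-sided unit-norm root spectrum of each window row: squared FFT
# magnitudes normalized to sum 1, then square-rooted (equivalently the
# l2-normalized magnitude spectrum over non-negative-frequency bins).
window_root_spectra <- function(X) {
  L <- ncol(X)
  nb <- L %/% 2 + 1
  FX <- stats::mvfft(t(X))            # L x M
  mag <- abs(FX[seq_len(nb), , drop = FALSE])
  S <- t(mag)
  n <- sqrt(rowSums(S^2))
  n[n == 0] <- 1
  S / n
}

#' Fit a bag-of-spectra dictionary by k-means on window spectra
#'
#' Each window is mapped to the unit-norm square root of its normalized
#' power spectrum (one-sided FFT, length-`L` transform), and standard
#' k-means clusters these vectors. Uses the same training data and
#' hyperparameters as the waveform dictionary (the waveform length `P`
#' plays no role).
#'
#' @param batch A [window_batch()].
#' @param K Number of spectral centroids.
#' @param seed Integer seed for the k-means initialization.
#' @param max_iter Maximum k-means iterations.
#' @param class_label,fold Provenance tags.
#' @return An object of class `spectral_dictionary` with unit-norm centroid
#'   rows.
#' @export
fit_bos <- function(batch, K, seed = 1, max_iter = 300,
                    class_label = NA, fold = NA) {
  S <- window_root_spectra(batch$windows)
  km <- with_seed(seed, stats::kmeans(S, centers = K, iter.max = max_iter,
                                      nstart = 1))
  structure(list(centroids = km$centers, K = K,
                 fft_length = ncol(batch$windows), L = ncol(batch$windows),
                 class_label = class_label, fold = fold),
            class = "spectral_dictionary")
}

#' @export
print.spectral_dictionary <- function(x, ...) {
  cat(sprintf("<spectral_dictionary> K=%d spectral centroids (%d bins), class=%s\n",
              x$K, ncol(x$centroids), as.character(x$class_label)))
  invisible(x)
}

#' Encode a segment as bag-of-spectra counts
#'
#' Windows the segment (non-overlapping, length `L`), computes each
#' window's unit-norm root spectrum, assigns to the nearest centroid in
#' Euclidean distance, and counts assignments per centroid. With multiple
#' dictionaries the per-dictionary counts are concatenated.
#'
#' @param segment Numeric vector or segment list (see [encode_bow()]).
#' @param spec_dicts A `spectral_dictionary` or list of them sharing `L`.
#' @param rate Optional sampling rate for duration metadata.
#' @return A [bag_of_waves()] of spectral-centroid counts.
#' @export
encode_bos <- function(segment, spec_dicts, rate = NULL) {
  if (inherits(spec_dicts, "spectral_dictionary")) spec_dicts <- list(spec_dicts)
  meta <- list(subject_id = NA_character_, start = NA_real_, duration = NA_real_)
  if (is.list(segment) && !is.null(segment$samples)) {
    meta <- list(subject_id = segment$subject_id, start = segment$start,
                 duration = segment$duration)
    segment <- segment$samples
  } else if (!is.null(rate)) {
    meta$duration <- length(segment) / rate
  }
  L <- spec_dicts[[1]]$L
  batch <- segment_to_windows(segment, L)
  S <- window_root_spectra(batch$windows)
  counts <- integer(0)
  block_index <- list()
  off <- 0
  for (j in seq_along(spec_dicts)) {
    Cm <- spec_dicts[[j]]$centroids
    # squared Euclidean distance via expansion; S rows unit norm
    d2 <- outer(rowSums(S^2), rowSums(Cm^2), "+") - 2 * S %*% t(Cm)
    k <- max.col(-d2, ties.method = "first")
    counts <- c(counts, tabulate(k, nbins = nrow(Cm)))
    lb <- spec_dicts[[j]]$class_label
    lb <- if (is.na(lb)) paste0("dict", j) else as.character(lb)
    block_index[[lb]] <- off + seq_len(nrow(Cm))
    off <- off + nrow(Cm)
  }
  bag_of_waves(counts, block_index, M = nrow(batch$windows), segment_meta = meta)
}

#' Soft-counted waveform (SCW) features for a segment
#'
#' Transforms every dictionary waveform by mean removal and l1
#' normalization, slides it over every sample offset of the (unwindowed)
#' segment, and at each offset credits the waveform with the largest inner
#' product (ties broken by lowest waveform index). The soft count for a
#' waveform is the sum of its winning inner products. Per-dictionary
#' vectors are concatenated; the result is dense and continuous-valued.
#'
#' @param segment Numeric vector or segment list (see [encode_bow()]) of
#'   length `Q >= P`.
#' @param dicts List of [waveform_dictionary()] objects sharing `P`.
#' @return Numeric vector of length `D = sum(K_j)`.
#' @export
encode_scw <- function(segment, dicts) {
  if (is.list(segment) && !is.null(segment$samples)) segment <- segment$samples
  Ps <- vapply(dicts, `[[`, 0, "P")
  if (length(unique(Ps)) != 1) stopf("all dictionaries must share P")
  P <- Ps[1]
  Q <- length(segment)
  if (Q < P) stopf("segment length %d is shorter than waveform length %d", Q, P)
  # transformed waveforms across all dictionaries, tracking block offsets
  Ct <- NULL
  block <- integer(0)
  for (j in seq_along(dicts)) {
    C <- dicts[[j]]$centroids
    for (k in seq_len(nrow(C))) {
      ck <- C[k, ] - mean(C[k, ])
      n1 <- sum(abs(ck))
      if (n1 == 0) stopf("waveform %d of dictionary %d is constant; SCW transform undefined", k, j)
      Ct <- rbind(Ct, ck / n1)
    }
    block <- c(block, rep(j, nrow(C)))
  }
  D <- nrow(Ct)
  Tn <- Q - P + 1
  # inner products at every offset via FFT cross-correlation with the segment
  nfft <- 2^ceiling(log2(Q + P))
  fs <- stats::fft(c(segment, numeric(nfft - Q)))
  ips <- matrix(0, Tn, D)
  for (d in seq_len(D)) {
    fc <- stats::fft(c(Ct[d, ], numeric(nfft - P)))
    g <- Re(stats::fft(fs * Conj(fc), inverse = TRUE)) / nfft
    ips[, d] <- g[seq_len(Tn)]
  }
  win <- max.col(ips, ties.method = "first")
  z <- numeric(D)
  agg <- rowsum(ips[cbind(seq_len(Tn), win)], win)
  z[as.integer(rownames(agg))] <- agg[, 1]
  z
}

#' Standardizer for dense feature matrices
#'
#' Per-feature mean/sd scaling used for SCW features in place of TFIDF.
#'
#' @param X Numeric matrix, rows = segments.
#' @return Object of class `standardizer` with `mean` and `sd` fields.
#' @export
fit_standardizer <- function(X) {
  m <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  s[s == 0 | is.na(s)] <- 1
  structure(list(mean = m, sd = s), class = "standardizer")
}

#' @rdname fit_standardizer
#' @param scaler A `standardizer`.
#' @param x Feature vector or matrix to scale.
#' @export
apply_standardizer <- function(x, scaler) {
  if (is.matrix(x)) {
    sweep(sweep(x, 2, scaler$mean), 2, scaler$sd, "/")
  } else {
    (x - scaler$mean) / scaler$sd
  }
}
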