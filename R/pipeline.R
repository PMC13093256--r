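# End-to-end protocol: per-genotype dictionary learning on one fold,
# cohort-wide encoding, leave-one-individual-out classification, repeated
# splits.

#' Learn one waveform dictionary per genotype from a dictionary fold
#'
#' For every joint genotype present in the cohort, samples balanced
#' training windows from the first half of the fold's recordings and fits
#' a shift-invariant k-means dictionary.
#'
#' @param recordings Named list of [recording()] by subject id.
#' @param cohort A [cohort_table()].
#' @param dict_fold Fold whose subjects train the dictionaries.
#' @param config A [run_config()].
#' @return Named list of [waveform_dictionary()], one per genotype (sorted
#'   by label).
#' @export
learn_fold_dictionaries <- function(recordings, cohort, dict_fold, config) {
  cohort <- as.data.frame(cohort)
  gts <- sort(unique(cohort$joint))
  dicts <- list()
  for (gi in seq_along(gts)) {
    g <- gts[gi]
    subj <- cohort$subject_id[cohort$joint == g & cohort$fold == dict_fold]
    if (length(subj) == 0) stopf("genotype '%s' has no subjects in fold %s", g, dict_fold)
    batch <- sample_training_windows(recordings[subj], config$windows_per_dict,
                                     config$L, half = "first",
                                     seed = config$seed + 131L * gi + as.integer(dict_fold))
    dicts[[g]] <- fit_shift_invariant_kmeans(
      batch, K = config$K, P = config$P, seed = config$seed + 977L * gi,
      class_label = g, fold = dict_fold)
  }
  dicts
}

#' Encode every subject's segments against a set of dictionaries
#'
#' Samples `segments_per_subject` segments of `segment_len` seconds from
#' the second half of each recording and encodes each as a bag-of-waves
#' over the concatenated dictionaries.
#'
#' @inheritParams learn_fold_dictionaries
#' @param dicts Named list of dictionaries from
#'   [learn_fold_dictionaries()].
#' @return Named list: subject id -> list of [bag_of_waves()].
#' @export
encode_cohort <- function(recordings, cohort, dicts, config) {
  cohort <- as.data.frame(cohort)
  bags <- list()
  for (si in seq_len(nrow(cohort))) {
    s <- cohort$subject_id[si]
    segs <- sample_segments(recordings[s], config$segments_per_subject,
                            config$segment_len, half = "second",
                            seed = config$seed + 389L * si)
    bags[[s]] <- lapply(segs, encode_bow, dicts = dicts)
  }
  bags
}

#' Run the two-fold leave-one-out protocol for one split
#'
#' Both fold roles are evaluated: dictionaries are trained on fold 0 and
#' the fold-1 subjects are scored leave-one-out, then the roles swap, so
#' every subject receives exactly one prediction per split.
#'
#' @inheritParams learn_fold_dictionaries
#' @param task Classification task (see [loo_evaluate()]).
#' @return List of class `split_result`: `by_fold` (two `loo_result`s),
#'   `predictions` (combined data frame), `accuracy`, and the encoded bags
#'   per fold role (for interpretation).
#' @export
run_split <- function(recordings, cohort, task, config) {
  folds <- sort(unique(as.data.frame(cohort)$fold))
  if (length(folds) != 2) stopf("the protocol needs exactly two folds")
  by_fold <- list()
  bags_by_fold <- list()
  preds <- NULL
  for (df in folds) {
    dicts <- learn_fold_dictionaries(recordings, cohort, df, config)
    bags <- encode_cohort(recordings, cohort, dicts, config)
    res <- loo_evaluate(bags, cohort, dict_fold = df, task = task,
                        grid = config$grid, K_CV = config$K_CV,
                        seed = config$seed)
    key <- as.character(df)
    by_fold[[key]] <- res
    bags_by_fold[[key]] <- bags
    preds <- rbind(preds, cbind(res$predictions[, c("subject_id", "true",
                                                    "predicted", "reg_C")],
                                dict_fold = df))
  }
  structure(list(by_fold = by_fold, predictions = preds,
                 accuracy = mean(preds$predicted == preds$true),
                 bags_by_fold = bags_by_fold, task = task, config = config),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result> task=%s: %d subjects, accuracy %.1f%%\n",
              x$task, nrow(x$predictions), 100 * x$accuracy))
  invisible(x)
}

#' Repeat the two-fold protocol over random splits
#'
#' Fold assignments are redrawn for each split (seeds `0..n_splits-1` by
#' default), the two-fold LOO protocol is run, and per-split accuracies are
#' summarized with the corrected resampled t interval
#' (`n_tr = S - 1`, `n_te = S`).
#'
#' @inheritParams run_split
#' @param n_splits Number of repeated splits.
#' @param split_seeds Optional seeds, one per split.
#' @param keep_splits Keep the full per-split results (memory-heavy).
#' @return List with `accuracies` (per split), `ci` (when `n_splits >= 2`),
#'   and optionally `splits`.
#' @export
run_repeated_splits <- function(recordings, cohort, task, config,
                                n_splits = config$n_splits,
                                split_seeds = seq_len(n_splits) - 1,
                                keep_splits = FALSE) {
  accs <- numeric(0)
  splits <- list()
  for (r in seq_len(n_splits)) {
    ch <- assign_folds(cohort, seed = split_seeds[r])
    res <- run_split(recordings, ch, task, config)
    accs <- c(accs, res$accuracy)
    if (keep_splits) splits[[r]] <- res
  }
  S <- nrow(as.data.frame(cohort))
  ci <- if (n_splits >= 2) {
    corrected_resampled_ci(accs, n_tr = S - 1, n_te = S)
  } else NULL
  list(accuracies = accs, ci = ci, splits = if (keep_splits) splits else NULL)
}
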