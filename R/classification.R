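#' Cohort metadata table
#'
#' Validates a per-subject metadata table with columns `subject_id`,
#' `strain`, `tsc` (disease genotype, `"Het"`/`"WT"`), `sex` (`"F"`/`"M"`),
#' and `fold` (0/1).
#'
#' @param df Data frame with the columns above.
#' @return The validated data frame with class `cohort_table` and a derived
#'   `joint` column (`strain` x `tsc`).
#' @export
cohort_table <- function(df) {
  need <- c("subject_id", "strain", "tsc", "sex", "fold")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("cohort table missing columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df$subject_id)) stopf("duplicate subject ids")
  if (any(is.na(df$fold))) stopf("every subject needs a fold")
  df$joint <- paste(df$strain, df$tsc, sep = "-")
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Published 45-mouse TSC1 panel cohort
#'
#' The cohort composition of the mouse panel used throughout the package's
#' worked examples: 45 mice across three background strains (BXD87, DBA2,
#' C57B6), each either heterozygous for the TSC1 knockout (`Het`) or
#' wild-type (`WT`), both sexes, with the first-split two-fold assignment.
#'
#' @return A [cohort_table()] with 45 rows.
#' @export
tsc_panel_cohort <- function() {
  path <- system.file("extdata", "tsc_panel_cohort.csv", package = "bowaves")
  cohort_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Expected accuracy of naive majority leave-one-out baselines
#'
#' Combinatorial baseline classifiers computed from cohort composition
#' alone. With `loo = TRUE`, each subject is removed in turn and the
#' predicted label is the majority `target` label among the remaining
#' subjects (restricted to subjects sharing the held-out subject's
#' `covariate` value, if given); an `m`-way majority tie containing the true
#' label scores `1/m`. With `loo = FALSE` the plain majority-class
#' proportion (the chance rate) is returned.
#'
#' @param cohort A [cohort_table()].
#' @param target Label column to predict: `"strain"`, `"tsc"`, or `"joint"`.
#' @param covariate Optional covariate column (e.g. `"sex"`) conditioning
#'   the majority vote.
#' @param conditioning Optional strain name; restricts the cohort to that
#'   strain first.
#' @param loo If `FALSE`, return the majority-class proportion without
#'   leave-one-out removal.
#' @return Expected accuracy as a fraction in \[0, 1\].
#' @export
naive_majority_loo_accuracy <- function(cohort, target,
                                        covariate = NULL, conditioning = NULL,
                                        loo = TRUE) {
  df <- as.data.frame(cohort)
  if (!is.null(conditioning)) df <- df[df$strain == conditioning, , drop = FALSE]
  if (nrow(df) == 0) stopf("empty cohort after conditioning")
  y <- df[[target]]
  if (!loo) {
    return(max(table(y)) / length(y))
  }
  n <- nrow(df)
  correct <- numeric(n)
  for (i in seq_len(n)) {
    pool <- df[-i, , drop = FALSE]
    if (!is.null(covariate)) {
      pool <- pool[pool[[covariate]] == df[[covariate]][i], , drop = FALSE]
    }
    if (nrow(pool) == 0) { correct[i] <- 0; next }
    tab <- table(pool[[target]])
    winners <- names(tab)[tab == max(tab)]
    correct[i] <- if (y[i] %in% winners) 1 / length(winners) else 0
  }
  mean(correct)
}

#' Default regularization grid
#'
#' Fifteen logarithmically spaced inverse-regularization values from 1e-1
#' to 1e4 (larger = weaker penalty).
#'
#' @return Numeric vector of length 15.
#' @export
default_reg_grid <- function() 10^seq(-1, 4, length.out = 15)

#' Fit an l2-regularized (multinomial) logistic regression
#'
#' Minimizes the mean negative log-likelihood plus an l2 penalty on the
#' coefficient vectors (intercepts unpenalized). The hyperparameter
#' `reg_C` is an inverse regularization strength: the penalty weight on the
#' mean-NLL scale is `lambda = 1 / (2 * reg_C * N)`. Fitting is delegated
#' to glmnet (ridge path, exact lambda, no standardization); probabilities
#' are computed from the extracted intercepts and coefficients by this
#' package's own softmax so the model equations stay explicit.
#'
#' @param X Numeric design matrix (rows = segments/instances).
#' @param y Label vector or factor with at least two classes present.
#' @param reg_C Inverse regularization strength (> 0).
#' @param transform Optional transform object (`tfidf_weights` or
#'   `standardizer`) stored with the model for subject-level prediction.
#' @param task Optional task tag stored with the model.
#' @return An object of class `bow_classifier` with fields `classes`,
#'   `biases`, `coefficients` (one row per class), `reg_C`, `transform`,
#'   `task`.
#' @export
fit_logistic <- function(X, y, reg_C, transform = NULL, task = NULL) {
  X <- as.matrix(X)
  y <- factor(y)
  y <- droplevels(y)
  if (nlevels(y) < 2) stopf("labels contain a single class; cannot fit a classifier")
  if (any(!is.finite(X))) stopf("features must be finite")
  N <- nrow(X)
  lambda <- 1 / (reg_C * N)  # glmnet ridge: mean NLL + lambda/2 * ||beta||^2
  fam <- if (nlevels(y) == 2) "binomial" else "multinomial"
  fit <- withCallingHandlers(
    glmnet::glmnet(X, y, family = fam, alpha = 0, lambda = lambda,
                   standardize = FALSE, thresh = 1e-10, maxit = 1e6),
    warning = function(w) {
      # small validation folds are the normal regime for LOO on small
      # cohorts; the ridge problem is convex regardless of class counts
      if (grepl("fewer than 8|dangerous ground", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  D <- ncol(X)
  cls <- levels(y)
  if (fam == "binomial") {
    # glmnet parameterizes the log-odds of the second level; store the
    # symmetric two-row form (+/- beta/2) so both classes carry meaningful
    # coefficients for Shapley analysis. Probabilities are unchanged.
    cf <- as.numeric(stats::coef(fit))
    biases <- c(-cf[1], cf[1]) / 2
    coefs <- rbind(-cf[-1], cf[-1]) / 2
  } else {
    cl <- stats::coef(fit)
    biases <- vapply(cls, function(g) as.numeric(cl[[g]][1]), 0)
    coefs <- t(vapply(cls, function(g) as.numeric(cl[[g]][-1]), numeric(D)))
  }
  rownames(coefs) <- cls
  structure(list(classes = cls, biases = biases, coefficients = coefs,
                 reg_C = reg_C, transform = transform, task = task),
            class = "bow_classifier")
}

#' @export
print.bow_classifier <- function(x, ...) {
  cat(sprintf("<bow_classifier> %d classes (%s), D=%d features, C=%g\n",
              length(x$classes), paste(x$classes, collapse = ", "),
              ncol(x$coefficients), x$reg_C))
  invisible(x)
}

#' Class probabilities from a fitted classifier
#'
#' Evaluates the (multinomial) logistic model
#' `p(y|x) = softmax(beta0_y + <beta_y, x>)` at a feature vector.
#'
#' @param model A `bow_classifier`.
#' @param x Numeric feature vector (already transformed).
#' @return Named probability vector summing to 1.
#' @export
predict_probs <- function(model, x) {
  s <- model$biases + as.numeric(model$coefficients %*% x)
  s <- s - max(s)
  p <- exp(s) / sum(exp(s))
  names(p) <- model$classes
  p
}

# Transform a pooled subject representation into the model's feature space.
subject_feature <- function(model, bags) {
  tr <- model$transform
  if (inherits(tr, "tfidf_weights")) {
    apply_tfidf(pool_bags(bags), tr)
  } else if (inherits(tr, "standardizer")) {
    Xd <- if (is.matrix(bags)) bags else do.call(rbind, bags)
    apply_standardizer(colMeans(Xd), tr)
  } else {
    stopf("model has no stored transform; supply a transformed vector to predict_probs()")
  }
}

#' Predict a subject's class from its pooled segments
#'
#' Counts are summed across the subject's segments, the model's stored
#' TFIDF transform is applied, and the classifier is evaluated once on the
#' pooled feature vector. For dense (SCW-style) features the per-segment
#' vectors are mean-pooled and standardized instead. Binary decisions
#' threshold the positive-class probability at 0.5.
#'
#' @param model A `bow_classifier` with a stored transform.
#' @param bags List of [bag_of_waves()] for one subject (or a matrix of
#'   dense per-segment features).
#' @return List with `probs` (named vector) and `label` (argmax class).
#' @export
predict_subject <- function(model, bags) {
  p <- predict_probs(model, subject_feature(model, bags))
  list(probs = p, label = names(p)[which.max(p)])
}

#' Combine strain and conditional disease-genotype probabilities
#'
#' Joint factorized distribution `p(y1, y2 | x) = p1(y1|x) p2(y2|x, y1)`.
#'
#' @param p_strain Named probability vector over strains.
#' @param p_cond Named list (by strain) of probability vectors over the
#'   conditional classes.
#' @return Named joint probability vector over `strain-class` pairs,
#'   summing to 1.
#' @export
compose_factorized <- function(p_strain, p_cond) {
  if (!all(names(p_strain) %in% names(p_cond))) {
    stopf("missing conditional model for strain(s): %s",
          paste(setdiff(names(p_strain), names(p_cond)), collapse = ", "))
  }
  out <- numeric(0)
  for (g in names(p_strain)) {
    pc <- p_cond[[g]]
    v <- p_strain[[g]] * pc
    names(v) <- paste(g, names(pc), sep = "-")
    out <- c(out, v)
  }
  out
}

#' Predict the joint genotype with a factorized model
#'
#' @param fmodel List with `strain_model` (a `bow_classifier` over strains)
#'   and `conditional_models` (named list of binary `bow_classifier`s, one
#'   per strain).
#' @param bags Subject's segment bags (see [predict_subject()]).
#' @return List with `probs` (joint distribution over strain x genotype)
#'   and `label` (argmax joint class).
#' @export
predict_factorized <- function(fmodel, bags) {
  p1 <- predict_subject(fmodel$strain_model, bags)$probs
  pc <- lapply(fmodel$conditional_models, function(m) predict_subject(m, bags)$probs)
  joint <- compose_factorized(p1, pc)
  list(probs = joint, label = names(joint)[which.max(joint)])
}

#' Stratified group k-fold assignment of subjects
#'
#' Groups are whole subjects; stratification balances the task label across
#' folds. Subjects of each class are shuffled (seeded) and dealt to the
#' fold with the fewest members of that class (ties: fewest subjects
#' overall, then lowest fold index).
#'
#' @param labels Named label vector (names = subject ids).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Named integer vector of fold indices in `1:k`.
#' @export
stratified_group_kfold <- function(labels, k, seed = 1) {
  subj <- names(labels)
  if (length(subj) < k) stopf("need at least %d subjects for %d folds", k, k)
  with_seed(seed, {
    fold <- stats::setNames(integer(length(subj)), subj)
    cls_count <- matrix(0, k, length(unique(labels)),
                        dimnames = list(NULL, unique(labels)))
    tot <- integer(k)
    for (cl in names(sort(table(labels)))) {
      members <- sample(subj[labels == cl])
      for (s in members) {
        f <- order(cls_count[, cl], tot)[1]
        fold[s] <- f
        cls_count[f, cl] <- cls_count[f, cl] + 1
        tot[f] <- tot[f] + 1
      }
    }
    fold
  })
}

# Build the per-segment design matrix + labels for a set of subjects.
# bags_by_subject: named list; each element a list of bag_of_waves (bow) or a
# numeric matrix of dense per-segment features (dense).
segment_design <- function(bags_by_subject, subjects, labels) {
  first <- bags_by_subject[[subjects[1]]]
  dense <- is.matrix(first)
  if (dense) {
    X <- do.call(rbind, lapply(subjects, function(s) bags_by_subject[[s]]))
    ns <- vapply(subjects, function(s) nrow(bags_by_subject[[s]]), 0L)
  } else {
    X <- do.call(rbind, lapply(subjects, function(s) {
      do.call(rbind, lapply(bags_by_subject[[s]], `[[`, "counts"))
    }))
    ns <- vapply(subjects, function(s) length(bags_by_subject[[s]]), 0L)
  }
  list(X = X, y = rep(labels[subjects], ns),
       subject = rep(subjects, ns), dense = dense)
}

# Fit transform on training segments and return transformed design matrix.
fit_transform <- function(bags_by_subject, subjects) {
  first <- bags_by_subject[[subjects[1]]]
  if (is.matrix(first)) {
    X <- do.call(rbind, lapply(subjects, function(s) bags_by_subject[[s]]))
    sc <- fit_standardizer(X)
    list(transform = sc, transform_fun = function(z) apply_standardizer(z, sc))
  } else {
    tr_bags <- unlist(lapply(subjects, function(s) bags_by_subject[[s]]),
                      recursive = FALSE)
    tw <- fit_tfidf(tr_bags)
    list(transform = tw, transform_fun = function(z) apply_tfidf(z, tw))
  }
}

#' Select the regularization hyperparameter by nested stratified-group CV
#'
#' Validation folds are drawn only from the non-dictionary training
#' subjects (stratified by the task label, grouped by subject); the CV
#' training set for each fold is the dictionary subjects plus the other
#' folds. The TFIDF (or standardizer) transform is refit on each CV
#' training set. The grid value with the highest mean pooled per-subject
#' validation accuracy wins; ties break by mean segment-wise accuracy, then
#' by the smallest grid value (strongest regularization). A validation fold
#' containing a single class triggers regeneration with a new seed
#' (logged via `message()`).
#'
#' @param bags_by_subject Named list: subject id -> list of
#'   [bag_of_waves()] (or dense per-segment feature matrix).
#' @param labels Named task-label vector covering all subjects involved.
#' @param dict_subjects Subject ids used for dictionary training (always in
#'   the CV training side).
#' @param train0_subjects Non-dictionary training subjects to fold.
#' @param grid Candidate inverse-regularization values.
#' @param K_CV Number of internal folds.
#' @param seed Integer seed.
#' @return Selected grid value (scalar).
#' @export
select_hyperparameter <- function(bags_by_subject, labels, dict_subjects,
                                  train0_subjects, grid = default_reg_grid(),
                                  K_CV = 3, seed = 1) {
  if (length(grid) == 0) stopf("empty hyperparameter grid")
  lab0 <- labels[train0_subjects]
  folds <- NULL
  for (attempt in 0:19) {
    f <- stratified_group_kfold(lab0, K_CV, seed = seed + 1000L * attempt)
    # single-class validation folds trigger regeneration; folds of one
    # subject are exempt (they cannot be multi-class)
    ok <- all(vapply(seq_len(K_CV), function(k) {
      sum(f == k) < 2 || length(unique(lab0[names(f)[f == k]])) > 1
    }, TRUE))
    if (ok) { folds <- f; break }
    message("validation fold with a single class; regenerating folds with a new seed")
  }
  if (is.null(folds)) folds <- stratified_group_kfold(lab0, K_CV, seed = seed)
  pooled_acc <- seg_acc <- matrix(NA_real_, K_CV, length(grid))
  for (k in seq_len(K_CV)) {
    val <- names(folds)[folds == k]
    if (length(val) == 0) next
    cvtrain <- c(dict_subjects, setdiff(train0_subjects, val))
    tr <- fit_transform(bags_by_subject, cvtrain)
    des <- segment_design(bags_by_subject, cvtrain, labels)
    Xtr <- t(apply(des$X, 1, tr$transform_fun))
    vdes <- segment_design(bags_by_subject, val, labels)
    Xva <- t(apply(vdes$X, 1, tr$transform_fun))
    for (gi in seq_along(grid)) {
      m <- fit_logistic(Xtr, des$y, grid[gi], transform = tr$transform)
      pred_subj <- vapply(val, function(s) {
        predict_subject(m, bags_by_subject[[s]])$label
      }, "")
      pooled_acc[k, gi] <- mean(pred_subj == labels[val])
      pseg <- apply(Xva, 1, function(x) {
        p <- predict_probs(m, x); names(p)[which.max(p)]
      })
      seg_acc[k, gi] <- mean(pseg == vdes$y)
    }
  }
  mp <- colMeans(pooled_acc, na.rm = TRUE)
  ms <- colMeans(seg_acc, na.rm = TRUE)
  best <- which(mp == max(mp))
  if (length(best) > 1) best <- best[ms[best] == max(ms[best])]
  grid[min(best)]
}

#' Leave-one-individual-out evaluation for one dictionary fold
#'
#' For each subject outside the dictionary fold: the hyperparameter is
#' selected by nested CV on the remaining subjects, the final model is fit
#' on all subjects but the held-out one (transform refit), and the held-out
#' subject is scored by pooled prediction. Per-subject models, training
#' feature means, and pooled feature vectors of all subjects under each
#' model are retained for Shapley-based interpretation.
#'
#' @param bags_by_subject Named list: subject id -> list of
#'   [bag_of_waves()] (or dense feature matrix) from segments encoded
#'   against dictionaries trained on the `dict_fold` subjects only.
#' @param cohort A [cohort_table()].
#' @param dict_fold Fold id whose subjects trained the dictionaries.
#' @param task `"strain"`, `"tsc"`, `"joint"`,
#'   `"tsc_given_strain:<strain>"`, or `"factorized"`.
#' @param grid Hyperparameter grid.
#' @param K_CV Internal CV folds.
#' @param seed Integer seed.
#' @return An object of class `loo_result`: `predictions` data frame (one
#'   row per tested subject), `models` (per-subject fitted artifacts),
#'   `labels`, and protocol metadata.
#' @export
loo_evaluate <- function(bags_by_subject, cohort, dict_fold, task,
                         grid = default_reg_grid(), K_CV = 3, seed = 1) {
  cohort <- as.data.frame(cohort)
  cond <- NULL
  base_task <- task
  if (grepl("^tsc_given_strain:", task)) {
    cond <- sub("^tsc_given_strain:", "", task)
    cohort <- cohort[cohort$strain == cond, , drop = FALSE]
    base_task <- "tsc"
  }
  if (task == "factorized") {
    return(loo_evaluate_factorized(bags_by_subject, cohort, dict_fold,
                                   grid, K_CV, seed))
  }
  labcol <- switch(base_task, strain = "strain", tsc = "tsc", joint = "joint",
                   stopf("unknown task '%s'", task))
  labels <- stats::setNames(cohort[[labcol]], cohort$subject_id)
  subjects <- cohort$subject_id
  dict_subjects <- cohort$subject_id[cohort$fold == dict_fold]
  test_subjects <- setdiff(subjects, dict_subjects)
  preds <- NULL
  models <- list()
  for (s in test_subjects) {
    train <- setdiff(subjects, s)
    train0 <- setdiff(train, dict_subjects)
    stopifnot(!s %in% train, !s %in% dict_subjects)  # leakage guard
    C_sel <- select_hyperparameter(bags_by_subject, labels, dict_subjects,
                                   train0, grid, K_CV, seed)
    tr <- fit_transform(bags_by_subject, train)
    des <- segment_design(bags_by_subject, train, labels)
    stopifnot(!s %in% des$subject)                   # leakage guard
    Xtr <- t(apply(des$X, 1, tr$transform_fun))
    m <- fit_logistic(Xtr, des$y, C_sel, transform = tr$transform, task = task)
    # pooled feature vectors for every subject under this model (interpretation)
    pooled <- t(vapply(subjects, function(sp) {
      subject_feature(m, bags_by_subject[[sp]])
    }, numeric(ncol(Xtr))))
    rownames(pooled) <- subjects
    feature_means <- colMeans(pooled[train, , drop = FALSE])
    pr <- predict_subject(m, bags_by_subject[[s]])
    preds <- rbind(preds, data.frame(
      subject_id = s, true = unname(labels[s]), predicted = pr$label,
      reg_C = C_sel, t(pr$probs), check.names = FALSE))
    models[[s]] <- list(model = m, feature_means = feature_means,
                        pooled_features = pooled, reg_C = C_sel)
  }
  structure(list(predictions = preds, models = models, labels = labels,
                 task = task, dict_fold = dict_fold,
                 dict_subjects = dict_subjects, seed = seed),
            class = "loo_result")
}

loo_evaluate_factorized <- function(bags_by_subject, cohort, dict_fold,
                                    grid, K_CV, seed) {
  strains <- sort(unique(cohort$strain))
  labels_j <- stats::setNames(cohort$joint, cohort$subject_id)
  labels_s <- stats::setNames(cohort$strain, cohort$subject_id)
  subjects <- cohort$subject_id
  dict_subjects <- cohort$subject_id[cohort$fold == dict_fold]
  test_subjects <- setdiff(subjects, dict_subjects)
  preds <- NULL
  models <- list()
  fit_one <- function(bags, sub_cohort, labels, s, task) {
    subj <- sub_cohort$subject_id
    train <- setdiff(subj, s)
    train0 <- setdiff(train, dict_subjects)
    C_sel <- select_hyperparameter(bags, labels,
                                   intersect(dict_subjects, subj),
                                   train0, grid, K_CV, seed)
    tr <- fit_transform(bags, train)
    des <- segment_design(bags, train, labels)
    Xtr <- t(apply(des$X, 1, tr$transform_fun))
    fit_logistic(Xtr, des$y, C_sel, transform = tr$transform, task = task)
  }
  for (s in test_subjects) {
    sm <- fit_one(bags_by_subject, cohort, labels_s, s, "strain")
    cms <- list()
    for (g in strains) {
      gc <- cohort[cohort$strain == g, , drop = FALSE]
      gl <- stats::setNames(gc$tsc, gc$subject_id)
      cms[[g]] <- fit_one(bags_by_subject[gc$subject_id], gc, gl, s,
                          paste0("tsc_given_strain:", g))
    }
    fm <- list(strain_model = sm, conditional_models = cms)
    pr <- predict_factorized(fm, bags_by_subject[[s]])
    preds <- rbind(preds, data.frame(
      subject_id = s, true = unname(labels_j[s]), predicted = pr$label,
      reg_C = NA_real_, t(pr$probs), check.names = FALSE))
    models[[s]] <- list(model = fm)
  }
  structure(list(predictions = preds, models = models, labels = labels_j,
                 task = "factorized", dict_fold = dict_fold,
                 dict_subjects = dict_subjects, seed = seed),
            class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  acc <- mean(x$predictions$predicted == x$predictions$true)
  cat(sprintf("<loo_result> task=%s dict_fold=%s: %d subjects tested, accuracy %.1f%%\n",
              x$task, as.character(x$dict_fold), nrow(x$predictions), 100 * acc))
  invisible(x)
}

#' Persist a fitted classifier as JSON
#'
#' Stores class order, intercepts, coefficient matrix, the selected
#' inverse-regularization value, and the TFIDF weights (or standardizer
#' statistics) in one portable JSON file.
#'
#' @param model A `bow_classifier`.
#' @param path Output path.
#' @return `path` invisibly (writer); a `bow_classifier` (reader).
#' @export
write_classifier_json <- function(model, path) {
  tr <- model$transform
  transform <- if (inherits(tr, "tfidf_weights")) {
    list(kind = "tfidf", w = tr$w, N_train = tr$N_train, N_k = tr$N_k)
  } else if (inherits(tr, "standardizer")) {
    list(kind = "standardizer", mean = tr$mean, sd = tr$sd)
  } else NULL
  jsonlite::write_json(
    list(classes = model$classes, biases = model$biases,
         coefficients = unname(as.matrix(model$coefficients)),
         reg_C = model$reg_C, task = model$task, transform = transform),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_classifier_json
#' @export
read_classifier_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr <- NULL
  if (!is.null(j$transform)) {
    tr <- if (j$transform$kind == "tfidf") {
      structure(list(w = j$transform$w, N_train = j$transform$N_train,
                     N_k = j$transform$N_k), class = "tfidf_weights")
    } else {
      structure(list(mean = j$transform$mean, sd = j$transform$sd),
                class = "standardizer")
    }
  }
  coefs <- j$coefficients
  if (!is.matrix(coefs)) coefs <- do.call(rbind, coefs)
  rownames(coefs) <- j$classes
  structure(list(classes = j$classes, biases = j$biases,
                 coefficients = coefs, reg_C = j$reg_C,
                 transform = tr, task = j$task %||% NULL),
            class = "bow_classifier")
}

#' Assign subjects to two folds pseudo-randomly with equal odds
#'
#' Each subject lands in fold 0 or 1 with probability one half; draws are
#' repeated (deterministically) until every genotype has at least one
#' subject in each fold, so that every per-genotype dictionary can be
#' trained in both fold roles.
#'
#' @param cohort A [cohort_table()].
#' @param seed Integer seed.
#' @return The cohort with its `fold` column reassigned.
#' @export
assign_folds <- function(cohort, seed = 0) {
  df <- as.data.frame(cohort)
  with_seed(seed, {
    for (attempt in 1:1000) {
      f <- stats::rbinom(nrow(df), 1, 0.5)
      ok <- all(vapply(split(f, df$joint),
                       function(v) length(unique(v)) == 2 || length(v) < 2,
                       TRUE)) && length(unique(f)) == 2
      if (ok) break
    }
    df$fold <- f
  })
  cohort_table(df[setdiff(names(df), "joint")])
}
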