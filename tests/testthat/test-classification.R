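make_model <- function(classes, biases, coefs, transform = NULL) {
  structure(list(classes = classes, biases = biases,
                 coefficients = coefs, reg_C = 1, transform = transform),
            class = "bow_classifier")
}

test_that("probabilities are uniform at zero parameters and always sum to one", {
  m <- make_model(c("a", "b", "c"), rep(0, 3), matrix(0, 3, 4))
  expect_equal(unname(predict_probs(m, rnorm(4))), rep(1 / 3, 3))
  set.seed(1)
  m2 <- make_model(c("a", "b", "c"), rnorm(3), matrix(rnorm(12), 3))
  for (i in 1:20) expect_equal(sum(predict_probs(m2, rnorm(4))), 1)
})

test_that("a separable toy problem reaches perfect training accuracy at weak regularization", {
  set.seed(2)
  X <- rbind(matrix(rnorm(40, mean = 2), 20, 2),
             matrix(rnorm(40, mean = -2), 20, 2))
  y <- rep(c("pos", "neg"), each = 20)
  m <- fit_logistic(X, y, reg_C = 1e4)
  pred <- apply(X, 1, function(x) { p <- predict_probs(m, x); names(p)[which.max(p)] })
  expect_equal(mean(pred == y), 1)
  expect_error(fit_logistic(X, rep("pos", 40), 1), "single class")

  # the fitted parameters beat the zero solution on the penalized objective
  obj <- function(biases, coefs, C) {
    s <- sweep(X %*% t(coefs), 2, biases, "+")
    p <- exp(s - apply(s, 1, max))
    p <- p / rowSums(p)
    -mean(log(p[cbind(seq_along(y), match(y, m$classes))])) +
      1 / (2 * C * length(y)) * sum(coefs^2)
  }
  expect_lte(obj(m$biases, m$coefficients, m$reg_C),
             obj(rep(0, 2), matrix(0, 2, 2), m$reg_C))
})

test_that("multinomial fits recover class structure across three classes", {
  set.seed(3)
  mu <- rbind(c(3, 0), c(-3, 0), c(0, 3))
  X <- do.call(rbind, lapply(1:3, function(k) {
    sweep(matrix(rnorm(30), 15, 2), 2, mu[k, ], "+")
  }))
  y <- rep(c("a", "b", "c"), each = 15)
  m <- fit_logistic(X, y, reg_C = 100)
  pred <- apply(X, 1, function(x) { p <- predict_probs(m, x); names(p)[which.max(p)] })
  expect_gte(mean(pred == y), 0.95)
  expect_equal(dim(m$coefficients), c(3L, 2L))
})

test_that("subject prediction pools counts before transforming", {
  set.seed(4)
  w <- structure(list(w = c(1, 1.5, 2)), class = "tfidf_weights")
  m <- make_model(c("x", "y"), c(0, 0.2), rbind(0, c(1.5, -2, 0.5)), transform = w)
  b1 <- toy_bag(c(5, 1, 0)); b2 <- toy_bag(c(0, 3, 2))
  # single segment: identical to segment-level prediction
  p1 <- predict_subject(m, list(b1))$probs
  expect_equal(p1, predict_probs(m, apply_tfidf(b1, w)))
  expect_equal(sum(predict_subject(m, list(b1, b2))$probs), 1)

  # explicit counterexample: pooled prediction disagrees with the majority
  # vote of segment-level predictions (decision boundary z1 > z2)
  w2 <- structure(list(w = c(1, 1)), class = "tfidf_weights")
  m2 <- make_model(c("x", "y"), c(0, 0), rbind(0, c(1, -1)), transform = w2)
  segs <- list(toy_bag(c(2, 3)), toy_bag(c(2, 3)), toy_bag(c(10, 0)))
  votes <- vapply(segs, function(b) {
    p <- predict_probs(m2, apply_tfidf(b, w2)); names(p)[which.max(p)]
  }, "")
  expect_equal(votes, c("x", "x", "y"))          # majority vote: "x"
  expect_equal(predict_subject(m2, segs)$label, "y")  # pooled counts (14, 6)
})

test_that("factorized prediction multiplies strain and conditional probabilities", {
  p1 <- c(BXD87 = 0.5, DBA2 = 0.3, C57B6 = 0.2)
  pc <- list(BXD87 = c(Het = 0.8, WT = 0.2),
             DBA2 = c(Het = 0.5, WT = 0.5),
             C57B6 = c(Het = 0.1, WT = 0.9))
  joint <- compose_factorized(p1, pc)
  expect_equal(unname(joint),
               c(0.40, 0.10, 0.15, 0.15, 0.02, 0.18))
  expect_equal(sum(joint), 1)
  # one-hot strain collapses the joint onto that strain's conditional
  p_hot <- c(BXD87 = 1, DBA2 = 0, C57B6 = 0)
  j2 <- compose_factorized(p_hot, pc)
  expect_equal(unname(j2[c("BXD87-Het", "BXD87-WT")]), c(0.8, 0.2))
  expect_error(compose_factorized(p1, pc[1:2]), "missing conditional")
})

test_that("stratified group folds keep subjects whole and balance classes", {
  labels <- setNames(rep(c("a", "b"), each = 6), paste0("s", 1:12))
  f <- stratified_group_kfold(labels, 3, seed = 1)
  expect_equal(sort(unique(f)), 1:3)
  for (k in 1:3) {
    expect_equal(sum(f == k), 4)
    expect_equal(unname(table(labels[names(f)[f == k]])), c(2L, 2L),
                 ignore_attr = TRUE)
  }
  expect_identical(f, stratified_group_kfold(labels, 3, seed = 1))
  expect_false(identical(f, stratified_group_kfold(labels, 3, seed = 2)))
})

test_that("hyperparameter selection picks a dominating grid value", {
  # two well-separated classes: weak regularization dominates the pooled
  # accuracy; the selected value must be one whose CV accuracy is maximal
  set.seed(5)
  mk_subj <- function(mu) {
    lapply(1:3, function(i) toy_bag(rpois(4, lambda = mu)))
  }
  bags <- c(lapply(1:4, function(i) mk_subj(c(20, 2, 10, 10))),
            lapply(1:4, function(i) mk_subj(c(2, 20, 10, 10))))
  names(bags) <- paste0("s", 1:8)
  labels <- setNames(rep(c("A", "B"), each = 4), names(bags))
  sel <- select_hyperparameter(bags, labels, dict_subjects = character(0),
                               train0_subjects = names(bags),
                               grid = c(0.1, 10, 1000), K_CV = 2, seed = 3)
  expect_true(sel %in% c(0.1, 10, 1000))
  # strong signal: the selected value classifies the pooled subjects well
  tw <- fit_tfidf(unlist(bags, recursive = FALSE))
  X <- do.call(rbind, lapply(names(bags), function(s) {
    t(vapply(bags[[s]], function(b) apply_tfidf(b, tw), numeric(4)))
  }))
  m <- fit_logistic(X, rep(labels, each = 3), sel, transform = tw)
  acc <- mean(vapply(names(bags), function(s) {
    predict_subject(m, bags[[s]])$label == labels[s]
  }, TRUE))
  expect_gte(acc, 7 / 8)
})

test_that("naive majority baselines reproduce the published cohort arithmetic", {
  cohort <- tsc_panel_cohort()
  expect_equal(nrow(cohort), 45)
  # chance rates (majority-class proportions)
  expect_equal(naive_majority_loo_accuracy(cohort, "strain", loo = FALSE), 17 / 45)
  expect_equal(naive_majority_loo_accuracy(cohort, "joint", loo = FALSE), 10 / 45)
  expect_equal(naive_majority_loo_accuracy(cohort, "tsc", loo = FALSE), 23 / 45)
  for (st in c("BXD87", "DBA2", "C57B6")) {
    expect_equal(naive_majority_loo_accuracy(cohort, "tsc", conditioning = st,
                                             loo = FALSE),
                 c(BXD87 = 10 / 17, DBA2 = 8 / 14, C57B6 = 8 / 14)[[st]])
  }
  # sex-covariate LOO baselines
  expect_equal(naive_majority_loo_accuracy(cohort, "strain", covariate = "sex"),
               9 / 45)
  expect_equal(naive_majority_loo_accuracy(cohort, "tsc", covariate = "sex"),
               27 / 45)
  expect_equal(naive_majority_loo_accuracy(cohort, "tsc", covariate = "sex",
                                           conditioning = "BXD87"), 12 / 17)
  expect_equal(naive_majority_loo_accuracy(cohort, "tsc", covariate = "sex",
                                           conditioning = "DBA2"), 7 / 14)
  expect_equal(naive_majority_loo_accuracy(cohort, "tsc", covariate = "sex",
                                           conditioning = "C57B6"), 6 / 14)
  expect_equal(naive_majority_loo_accuracy(cohort, "joint", covariate = "sex"),
               3.5 / 45)
  # a single-class cohort is always predicted correctly
  one <- cohort_table(data.frame(subject_id = c("a", "b"), strain = "X",
                                 tsc = "Het", sex = c("F", "M"), fold = 0:1))
  expect_equal(naive_majority_loo_accuracy(one, "tsc"), 1)
})

test_that("fold assignment is seeded and keeps every genotype in both folds", {
  cohort <- tsc_panel_cohort()
  c1 <- assign_folds(cohort, seed = 0)
  c2 <- assign_folds(cohort, seed = 0)
  expect_identical(c1$fold, c2$fold)
  expect_false(identical(c1$fold, assign_folds(cohort, seed = 1)$fold))
  tab <- table(c1$joint, c1$fold)
  expect_true(all(tab > 0))
})
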