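test_that("balanced accuracy is the mean of per-class recalls", {
  expect_equal(balanced_accuracy(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_equal(balanced_accuracy(c(1, 1, 0, 0), c(1, 0, 0, 0)), 0.75)
  # constant predictor over K observed classes scores 1/K
  expect_equal(balanced_accuracy(rep(1:4, each = 3), rep(2, 12)), 1 / 4)
  # invariant to class relabeling
  y <- sample(letters[1:3], 30, replace = TRUE)
  p <- sample(letters[1:3], 30, replace = TRUE)
  relab <- c(a = "x", b = "y", c = "z")
  expect_equal(balanced_accuracy(y, p),
               balanced_accuracy(relab[y], relab[p]))
  expect_error(balanced_accuracy(c(1, 2), c(1)), "length")
})

test_that("AUC equals the exhaustive pairwise-comparison oracle", {
  pair_oracle <- function(scores, pos) {
    tot <- 0; n <- 0
    for (i in which(pos)) for (j in which(!pos)) {
      n <- n + 1
      tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    }
    tot / n
  }
  expect_equal(auc(c(0.9, 0.8, 0.7, 0.6),
                   factor(c("b", "a", "b", "a"), levels = c("a", "b"))), 0.75)
  expect_equal(auc(1:6, factor(c(0, 0, 0, 1, 1, 1))), 1)    # perfect ranking
  expect_equal(auc(6:1, factor(c(0, 0, 0, 1, 1, 1))), 0)    # inverted
  set.seed(8)
  for (rep in 1:200) {
    n <- sample(4:12, 1)
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # ties likely
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(pos) || all(pos)) next
    y <- factor(ifelse(pos, "pos", "neg"), levels = c("neg", "pos"))
    expect_equal(auc(scores, y), pair_oracle(scores, pos))
  }
  expect_error(auc(1:3, factor(c("a", "a", "a"))), "single-class")
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  for (rep in 1:10) {
    scores <- rnorm(40)
    y <- factor(sample(c("n", "p"), 40, replace = TRUE), levels = c("n", "p"))
    ref <- as.numeric(pROC::auc(pROC::roc(y, scores, levels = c("n", "p"),
                                          direction = "<", quiet = TRUE)))
    expect_equal(auc(scores, y), ref, tolerance = 1e-12)
  }
})

test_that("macro one-vs-rest AUC handles the five-group scheme", {
  set.seed(10)
  y <- factor(rep(1:5, each = 8))
  P <- matrix(runif(200), 40, 5, dimnames = list(NULL, levels(y)))
  manual <- mean(vapply(levels(y), function(cl) {
    auc(P[, cl], factor(y == cl, levels = c(FALSE, TRUE)))
  }, numeric(1)))
  expect_equal(auc(P, y), manual)
})

test_that("soft voting is the average of its members' probabilities", {
  set.seed(11)
  Xtr <- matrix(rnorm(40 * 6), 40, dimnames = list(NULL, paste0("f", 1:6)))
  ytr <- factor(rep(c("a", "b"), 20))
  Xte <- matrix(rnorm(10 * 6), 10, dimnames = list(NULL, paste0("f", 1:6)))
  spec <- classifier_spec("voting2")
  P <- tensorflavor:::predict_spec(spec, Xtr, ytr, Xte, list(), seed = 5)
  members <- lapply(seq_along(spec$members), function(i) {
    m <- spec$members[i]
    h <- if (m == "extratrees") list() else tensorflavor:::default_hyper(m)
    tensorflavor:::fit_proba(m, Xtr, ytr, Xte, h, derive_seed(5, m, i))
  })
  expect_equal(P, Reduce(`+`, members) / 3, tolerance = 1e-12)
  expect_equal(unname(rowSums(P)), rep(1, 10), tolerance = 1e-6)
})

test_that("every classifier emits valid probabilities on both label schemes", {
  set.seed(12)
  n <- 60
  X <- matrix(rnorm(n * 8), n, dimnames = list(NULL, paste0("f", 1:8)))
  gg <- rep(1:5, 12)   # interleaved so any split sees every grade
  X[, 1] <- X[, 1] + gg
  for (scheme in c("binary", "gg5")) {
    y <- code_labels(gg, scheme)
    for (cid in names(all_classifiers())) {
      P <- tensorflavor:::predict_spec(all_classifiers()[[cid]],
                                       X[1:45, ], droplevels(y[1:45]),
                                       X[46:60, ],
                                       tensorflavor:::default_hyper(cid),
                                       seed = 3)
      expect_equal(dim(P), c(15L, nlevels(droplevels(y))),
                   label = paste(cid, scheme))
      expect_true(all(P >= 0 & P <= 1 + 1e-9), label = paste(cid, scheme))
    }
  }
})

test_that("cross-validation is deterministic and detects real signal", {
  set.seed(13)
  n <- 60
  X <- matrix(rnorm(n * 15), n, dimnames = list(NULL, paste0("f", 1:15)))
  gg <- rep(c(1, 2, 3), each = 20)
  X[, 1] <- X[, 1] + 2.5 * gg
  y <- code_labels(gg, "binary")
  plan <- preprocess_plan(pca = FALSE)
  r1 <- run_cv(X, y, classifier_spec("rf"), plan, folds = 5, seed = 1)
  r2 <- run_cv(X, y, classifier_spec("rf"), plan, folds = 5, seed = 1)
  expect_identical(r1$fold_auc, r2$fold_auc)
  expect_identical(r1$fold_balacc, r2$fold_balacc)
  expect_gt(r1$auc_mean, 0.8)
  expect_true(all(r1$fold_auc >= 0 & r1$fold_auc <= 1))
  expect_gte(r1$auc_sd, 0)
  # stratification infeasible under gg5 with a tiny class
  expect_error(run_cv(X[1:21, ], code_labels(c(rep(1, 18), 2, 2, 2), "gg5"),
                      classifier_spec("rf"), plan, folds = 5, seed = 1),
               "folds")
})

test_that("mean AUC responds monotonically to the phantom signal strength", {
  means <- vapply(c(0, 1, 3), function(ss) {
    cfg <- phantom_config(n_patients = 20,
                          class_counts = c(`1` = 10, `2` = 10),
                          signal_strength = ss, seed = 77)
    rad <- radiomics_matrix(lapply(generate_cohort(cfg), build_flavor_stack))
    y <- code_labels(rad$labels, "binary")
    mean(vapply(1:3, function(s) {
      run_cv(rad$X, y, classifier_spec("svm"), preprocess_plan(pca = FALSE),
             folds = 4, seed = s)$auc_mean
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  expect_lt(means[1], 0.65)   # no-signal cohort stays near chance
  expect_gt(means[3], 0.9)    # high-signal cohort is nearly separable
})
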