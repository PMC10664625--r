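## Nine classifiers (7 base + 2 soft-voting ensembles), stratified k-fold
## cross-validation with nested grid search, balanced accuracy and ROC/AUC.

#' Balanced accuracy: unweighted mean of per-class recalls
#'
#' @param y_true,y_pred equal-length label vectors.
#' @return scalar in `[0, 1]`.
#' @export
balanced_accuracy <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  mean(vapply(unique(y_true), function(cl) {
    mean(y_pred[y_true == cl] == cl)
  }, numeric(1)))
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Equals the probability that a positive sample receives a higher score
#' than a negative one, ties counted 1/2. For more than two classes, the
#' macro average of one-vs-rest AUCs.
#'
#' @param scores numeric vector (binary; score of the positive = last level)
#'   or matrix with one column per class.
#' @param y_true labels (factor; for binary the second level is positive).
#' @return scalar in `[0, 1]`.
#' @export
auc <- function(scores, y_true) {
  y_true <- as.factor(y_true)
  if (is.matrix(scores) && ncol(scores) > 2) {
    present <- levels(y_true)[table(y_true) > 0]
    if (length(present) < 2) stop("auc: single-class input")
    return(mean(vapply(present, function(cl) {
      auc_binary(scores[, cl], y_true == cl)
    }, numeric(1))))
  }
  if (is.matrix(scores)) scores <- scores[, ncol(scores)]
  pos <- y_true == levels(droplevels(y_true))[nlevels(droplevels(y_true))]
  auc_binary(scores, pos)
}

auc_binary <- function(scores, pos) {
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("auc: single-class input")
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## empirical ROC points (FPR, TPR) for binary scores
roc_points <- function(scores, pos) {
  ord <- order(scores, decreasing = TRUE)
  tpr <- cumsum(pos[ord]) / sum(pos)
  fpr <- cumsum(!pos[ord]) / sum(!pos)
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Classifier specification
#'
#' @param id one of `"logreg"`, `"svm"`, `"gnb"`, `"knn"`, `"rf"`,
#'   `"bag_dt"`, `"gboost"`, `"voting1"`, `"voting2"`.
#' @param grid optional named list of hyperparameter vectors overriding the
#'   default grid.
#' @return a `classifier_spec`.
#' @export
classifier_spec <- function(id, grid = NULL) {
  ids <- c("logreg", "svm", "gnb", "knn", "rf", "bag_dt", "gboost",
           "voting1", "voting2")
  id <- match.arg(id, ids)
  default_grid <- switch(id,
    logreg = list(lambda = c(1, 0.1, 0.01)),       # ~ C in {0.1, 1, 10}, L2
    svm = list(cost = c(0.1, 1, 10)),
    knn = list(k = c(3, 5, 7)),
    rf = list(max_depth = c(0, 8)),                 # 0 = unlimited
    gboost = list(eta = c(0.05, 0.1)),
    list()
  )
  members <- switch(id,
    voting1 = c("logreg", "svm", "gnb", "knn", "rf", "bag_dt"),
    voting2 = c("gboost", "svm", "extratrees"),
    NULL)
  structure(list(id = id, grid = if (is.null(grid)) default_grid else grid,
                 members = members),
            class = "classifier_spec")
}

#' All nine classifier specifications
#' @return named list of `classifier_spec` objects.
#' @export
all_classifiers <- function() {
  ids <- c("logreg", "svm", "gnb", "knn", "rf", "bag_dt", "gboost",
           "voting1", "voting2")
  stats::setNames(lapply(ids, classifier_spec), ids)
}

## distance-based k-NN with full class-probability output
knn_proba <- function(Xtr, ytr, Xte, k) {
  lv <- levels(ytr)
  D <- as.matrix(stats::dist(rbind(Xte, Xtr)))[seq_len(nrow(Xte)),
                                               nrow(Xte) + seq_len(nrow(Xtr)),
                                               drop = FALSE]
  k <- min(k, nrow(Xtr))
  P <- t(apply(D, 1, function(dd) {
    nn <- ytr[order(dd)[seq_len(k)]]
    tabulate(nn, nlevels(ytr)) / k
  }))
  colnames(P) <- lv
  P
}

## fit one base model and return a probability matrix on Xte
## (columns in levels(ytr) order)
fit_proba <- function(id, Xtr, ytr, Xte, hyper, seed) {
  lv <- levels(ytr)
  binary <- length(lv) == 2
  if (ncol(Xtr) == 1) {
    ## some backends refuse single-column inputs; a zero column is inert
    Xtr <- cbind(Xtr, .pad = 0)
    Xte <- cbind(Xte, .pad = 0)
  }
  P <- switch(id,
    logreg = {
      fam <- if (binary) "binomial" else "multinomial"
      fit <- suppressWarnings(
        glmnet::glmnet(Xtr, ytr, family = fam, alpha = 0,
                       lambda = hyper$lambda, standardize = FALSE))
      pr <- stats::predict(fit, Xte, type = "response")
      if (binary) cbind(1 - pr[, 1], pr[, 1]) else pr[, , 1]
    },
    svm = {
      fit <- withr::with_seed(seed, suppressWarnings(
        e1071::svm(Xtr, ytr, kernel = "radial", cost = hyper$cost,
                   probability = TRUE)))
      pr <- attr(stats::predict(fit, Xte, probability = TRUE), "probabilities")
      pr[, lv, drop = FALSE]
    },
    gnb = {
      fit <- e1071::naiveBayes(Xtr, ytr)
      stats::predict(fit, Xte, type = "raw")[, lv, drop = FALSE]
    },
    knn = knn_proba(Xtr, ytr, Xte, hyper$k),
    rf = {
      fit <- ranger::ranger(x = Xtr, y = ytr, probability = TRUE,
                            num.trees = 200,
                            max.depth = hyper$max_depth,
                            seed = seed, num.threads = 1)
      stats::predict(fit, Xte, num.threads = 1)$predictions[, lv, drop = FALSE]
    },
    extratrees = {
      fit <- ranger::ranger(x = Xtr, y = ytr, probability = TRUE,
                            num.trees = 200, splitrule = "extratrees",
                            seed = seed, num.threads = 1)
      stats::predict(fit, Xte, num.threads = 1)$predictions[, lv, drop = FALSE]
    },
    bag_dt = {
      nb <- 50
      df_tr <- data.frame(Xtr, check.names = FALSE)
      df_te <- data.frame(Xte, check.names = FALSE)
      acc <- matrix(0, nrow(Xte), length(lv), dimnames = list(NULL, lv))
      withr::with_seed(seed, {
        for (b in seq_len(nb)) {
          ix <- sample(nrow(Xtr), replace = TRUE)
          if (nlevels(droplevels(ytr[ix])) < 2) next
          tr <- rpart::rpart(y ~ ., data = cbind(df_tr[ix, , drop = FALSE],
                                                 y = ytr[ix]),
                             method = "class",
                             control = rpart::rpart.control(cp = 0.01))
          acc <- acc + stats::predict(tr, df_te, type = "prob")[, lv, drop = FALSE]
        }
      })
      acc / pmax(rowSums(acc), 1e-12)
    },
    gboost = {
      fit <- xgboost::xgboost(Xtr, ytr, nrounds = 200,
                              learning_rate = hyper$eta, max_depth = 3,
                              nthreads = 1, seed = seed, verbosity = 0)
      pr <- stats::predict(fit, Xte)
      if (binary) cbind(1 - pr, pr) else pr[, lv, drop = FALSE]
    },
    stop("unknown classifier id: ", id)
  )
  P <- as.matrix(P)
  colnames(P) <- lv
  P
}

## mid-grid default hyperparameters (used by voting members)
default_hyper <- function(id) {
  g <- classifier_spec(id)$grid
  lapply(g, function(v) v[ceiling(length(v) / 2)])
}

predict_spec <- function(spec, Xtr, ytr, Xte, hyper, seed) {
  if (is.null(spec$members)) {
    fit_proba(spec$id, Xtr, ytr, Xte, hyper, seed)
  } else {
    ## soft voting: average member probabilities (members at default
    ## hyperparameters)
    Ps <- lapply(seq_along(spec$members), function(i) {
      m <- spec$members[i]
      hid <- if (m == "extratrees") list() else default_hyper(m)
      fit_proba(m, Xtr, ytr, Xte, hid, derive_seed(seed, m, i))
    })
    Reduce(`+`, Ps) / length(Ps)
  }
}

grid_expand <- function(grid) {
  if (!length(grid)) return(list(list()))
  gg <- do.call(expand.grid, c(grid, list(KEEP.OUT.ATTRS = FALSE)))
  lapply(seq_len(nrow(gg)), function(i) as.list(gg[i, , drop = FALSE]))
}

stratified_folds <- function(y, k, seed) {
  fa <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in levels(as.factor(y))) {
      ix <- which(y == cl)
      fa[ix] <- sample(rep_len(seq_len(k), length(ix)))
    }
  })
  fa
}

## nested grid search by balanced accuracy on inner stratified folds
grid_search <- function(spec, X, y, seed, inner_folds = 3) {
  cands <- grid_expand(spec$grid)
  if (length(cands) == 1) return(cands[[1]])
  fa <- stratified_folds(y, inner_folds, derive_seed(seed, "inner"))
  scores <- vapply(cands, function(h) {
    mean(vapply(seq_len(inner_folds), function(f) {
      te <- fa == f
      if (nlevels(droplevels(y[!te])) < 2 || !any(te)) return(NA_real_)
      P <- predict_spec(spec, X[!te, , drop = FALSE], y[!te],
                        X[te, , drop = FALSE], h, derive_seed(seed, "gs", f))
      pred <- colnames(P)[max.col(P, ties.method = "first")]
      balanced_accuracy(y[te], pred)
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  cands[[which.max(scores)]]
}

#' Cross-validated evaluation of one classifier on one feature matrix
#'
#' Stratified k-fold split; per fold the preprocessing chain is fitted via
#' [preprocess()], hyperparameters are tuned by nested 3-fold balanced
#' accuracy, the model is refitted on the whole (preprocessed) training
#' split, and the held-out fold is scored.
#'
#' @param X numeric feature matrix.
#' @param y grade-group labels (factor, see [code_labels()]).
#' @param spec a [classifier_spec()].
#' @param plan a [preprocess_plan()].
#' @param folds number of outer folds (default 5).
#' @param seed integer seed.
#' @return a `cv_result`: per-fold AUC and balanced accuracy, their
#'   mean +/- sd, per-fold ROC points, the fold assignment and seed.
#' @export
run_cv <- function(X, y, spec, plan, folds = 5, seed = 1L) {
  y <- droplevels(as.factor(y))
  if (any(table(y) < folds)) {
    stop("run_cv: every class needs at least `folds` members; use the ",
         "binary label scheme or fewer folds")
  }
  fa <- stratified_folds(y, folds, derive_seed(seed, "outer"))
  pre <- preprocess(X, y, plan, fa, seed)
  per <- lapply(seq_len(folds), function(f) {
    sp <- pre[[f]]
    hyper <- grid_search(spec, sp$X_train, sp$y_train,
                         derive_seed(seed, "cell", f))
    P <- predict_spec(spec, sp$X_train, sp$y_train, sp$X_test, hyper,
                      derive_seed(seed, "fit", f))
    pred <- colnames(P)[max.col(P, ties.method = "first")]
    ba <- balanced_accuracy(sp$y_test, pred)
    a <- if (nlevels(y) == 2) auc(P[, 2], sp$y_test) else auc(P, sp$y_test)
    roc <- if (nlevels(y) == 2) {
      roc_points(P[, 2], sp$y_test == levels(y)[2])
    } else NULL
    list(auc = a, balacc = ba, roc = roc, hyper = hyper)
  })
  aucs <- vapply(per, `[[`, numeric(1), "auc")
  bas <- vapply(per, `[[`, numeric(1), "balacc")
  structure(list(classifier = spec$id,
                 fold_auc = aucs, fold_balacc = bas,
                 auc_mean = mean(aucs), auc_sd = stats::sd(aucs),
                 balacc_mean = mean(bas), balacc_sd = stats::sd(bas),
                 roc = lapply(per, `[[`, "roc"),
                 hyper = lapply(per, `[[`, "hyper"),
                 fold_assignment = fa, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s: AUC %.3f +/- %.3f, balanced accuracy %.3f +/- %.3f (%d folds)\n",
              x$classifier, x$auc_mean, x$auc_sd, x$balacc_mean, x$balacc_sd,
              length(x$fold_auc)))
  invisible(x)
}

#' Benchmark configuration
#'
#' @param seed master seed.
#' @param labels `"binary"` or `"gg5"`.
#' @param folds outer CV folds.
#' @param leaky_mode fit preprocessing globally (paper-style) instead of
#'   fold-safe.
#' @param ae_epochs autoencoder training epochs.
#' @param ae_kfolds autoencoder monitoring folds (0 = none).
#' @param ae_train_max cap on the number of pooled flavor images used to fit
#'   the autoencoder (subsampled, seeded).
#' @param sets feature sets to evaluate (subset of 1:5).
#' @param classifiers character ids (subset of the nine).
#' @return config list.
#' @export
bench_config <- function(seed = 1L, labels = c("binary", "gg5"), folds = 5,
                         leaky_mode = FALSE, ae_epochs = 10, ae_kfolds = 0,
                         ae_train_max = 400, sets = 1:5,
                         classifiers = names(all_classifiers())) {
  list(seed = as.integer(seed), labels = match.arg(labels), folds = folds,
       leaky_mode = leaky_mode, ae_epochs = ae_epochs, ae_kfolds = ae_kfolds,
       ae_train_max = ae_train_max, sets = sets, classifiers = classifiers)
}

#' Run the full pipeline benchmark on a cohort
#'
#' Stages: read (or take) the cohort, build 52-flavor stacks, extract the
#' radiomics matrix, train the autoencoder and extract deep features,
#' assemble the five feature sets, and evaluate the requested classifiers
#' with cross-validation. Writes `results.csv`, `results.json`, per-cell ROC
#' point files and a run manifest to `out_dir`.
#'
#' @param cohort a cohort directory (as written by [write_cohort()]) or a
#'   list of `patient_case` objects.
#' @param out_dir output directory.
#' @param config see [bench_config()].
#' @return data.frame of results (one row per classifier x feature set),
#'   invisibly; also written to `out_dir`.
#' @export
run_bench <- function(cohort, out_dir, config = bench_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(s) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), s))
  cases <- if (is.character(cohort)) {
    stage(paste("reading cohort from", cohort))
    read_cohort(cohort)
  } else cohort
  stage(sprintf("building flavor stacks (%d patients)", length(cases)))
  stacks <- lapply(cases, build_flavor_stack)
  stage("extracting radiomics features")
  rad <- radiomics_matrix(stacks)
  stage("training autoencoder")
  pool <- unlist(lapply(stacks, function(s) s$flavors), recursive = FALSE)
  if (length(pool) > config$ae_train_max) {
    keep <- withr::with_seed(derive_seed(config$seed, "aepool"),
                             sample(length(pool), config$ae_train_max))
    pool <- pool[keep]
  }
  tr <- train_autoencoder(pool, k_folds = config$ae_kfolds,
                          epochs = config$ae_epochs, seed = config$seed)
  stage("encoding deep features")
  deep <- deep_feature_matrix(stacks, tr$model)
  y <- code_labels(rad$labels, config$labels)
  rows <- list()
  for (set_id in config$sets) {
    stage(paste("feature set", set_id))
    fm <- assemble_feature_set(deep, rad, set_id)
    plan <- preprocess_plan(pca = set_id %in% c(1, 3, 5),
                            leaky_mode = config$leaky_mode)
    for (cid in config$classifiers) {
      res <- run_cv(fm$X, y, classifier_spec(cid), plan,
                    folds = config$folds,
                    seed = derive_seed(config$seed, paste0("cell", set_id), 0))
      rows[[paste(cid, set_id)]] <- data.frame(
        classifier = cid, feature_set = set_id,
        auc_mean = res$auc_mean, auc_sd = res$auc_sd,
        balacc_mean = res$balacc_mean, balacc_sd = res$balacc_sd)
      for (f in seq_along(res$roc)) {
        if (!is.null(res$roc[[f]])) {
          utils::write.csv(res$roc[[f]],
                           file.path(out_dir, sprintf("roc_set%d_%s_fold%d.csv",
                                                      set_id, cid, f)),
                           row.names = FALSE)
        }
      }
      stage(sprintf("  %s set %d: AUC %.3f +/- %.3f", cid, set_id,
                    res$auc_mean, res$auc_sd))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  utils::write.csv(out, file.path(out_dir, "results.csv"), row.names = FALSE)
  jsonlite::write_json(out, file.path(out_dir, "results.json"),
                       dataframe = "rows", digits = NA)
  manifest <- list(config = config, n_patients = length(cases),
                   flavor_order = flavor_ids(),
                   package_version = as.character(utils::packageVersion("tensorflavor")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}
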