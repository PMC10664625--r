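## Five feature sets and the preprocessing chain:
## smote -> standardize -> pca -> correlation_filter -> lasso,
## fitted fold-safely by default (every statistic estimated on the training
## split only), with an explicit leaky mode that reproduces global
## preprocessing before cross-validation.

#' Code grade-group labels for classification
#'
#' @param grade_group integer vector 1..5.
#' @param scheme `"binary"` (GG 1, clinically insignificant, vs GG >= 2) or
#'   `"gg5"` (five grade groups).
#' @return a factor.
#' @export
code_labels <- function(grade_group, scheme = c("binary", "gg5")) {
  scheme <- match.arg(scheme)
  if (scheme == "binary") {
    factor(ifelse(grade_group >= 2, "csPCa", "GG1"), levels = c("GG1", "csPCa"))
  } else {
    factor(grade_group, levels = 1:5)
  }
}

## PCA via the Gram matrix when p >> n; fit on training rows only.
pca_fit <- function(X, ncomp = NULL, var_target = NULL) {
  n <- nrow(X)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  if (ncol(X) > n) {
    G <- tcrossprod(Xc)
    ev <- eigen(G, symmetric = TRUE)
    pos <- ev$values > max(ev$values, 0) * 1e-12
    d <- sqrt(pmax(ev$values[pos], 0))
    V <- crossprod(Xc, ev$vectors[, pos, drop = FALSE]) %*% diag(1 / d, sum(pos))
  } else {
    sv <- svd(Xc)
    pos <- sv$d > max(sv$d, 0) * 1e-12
    d <- sv$d[pos]
    V <- sv$v[, pos, drop = FALSE]
  }
  varex <- d^2 / sum(d^2)
  k <- if (!is.null(ncomp)) {
    if (ncomp > length(d)) {
      stop("pca: requested ", ncomp, " components but only ", length(d),
           " are available (min(rows - 1, cols))")
    }
    ncomp
  } else {
    max(1, min(which(cumsum(varex) >= var_target)))
  }
  k <- min(k, n - 1, length(d))
  list(center = ctr, rotation = V[, seq_len(k), drop = FALSE], k = k)
}

pca_apply <- function(fit, X) {
  S <- sweep(X, 2, fit$center) %*% fit$rotation
  colnames(S) <- sprintf("PC%03d", seq_len(ncol(S)))
  S
}

#' Assemble one of the five feature sets
#'
#' Set 1: all deep features (52 x 7200 = 374400 columns). Set 2: all
#' radiomics features (5564). Set 3: per-flavor PCA with 5 components on the
#' deep features, concatenated (52 x 5 = 260). Set 4: one global PCA with 107
#' components on the radiomics matrix (107). Set 5: deep and radiomics
#' concatenated (379964).
#'
#' @param deep `feature_matrix` of deep features (374400 columns).
#' @param radiomics `feature_matrix` of radiomics features (5564 columns).
#' @param set_id integer 1..5.
#' @param pca_per_flavor components per flavor for set 3.
#' @param pca_global components for set 4.
#' @return a `feature_matrix`.
#' @export
assemble_feature_set <- function(deep, radiomics, set_id,
                                 pca_per_flavor = 5, pca_global = 107) {
  need_deep <- set_id %in% c(1, 3, 5)
  need_rad <- set_id %in% c(2, 4, 5)
  if (need_deep && need_rad) {
    if (!identical(rownames(deep$X), rownames(radiomics$X)) ||
        !identical(deep$labels, radiomics$labels)) {
      stop("deep and radiomics matrices are not row-aligned")
    }
  }
  switch(as.character(set_id),
    "1" = deep,
    "2" = radiomics,
    "3" = {
      fids <- flavor_ids()
      blocks <- lapply(fids, function(fid) {
        cols <- which(deep$provenance$flavor == fid)
        S <- pca_apply(pca_fit(deep$X[, cols, drop = FALSE],
                               ncomp = pca_per_flavor),
                       deep$X[, cols, drop = FALSE])
        colnames(S) <- paste0(fid, "__", colnames(S))
        S
      })
      X <- do.call(cbind, blocks)
      rownames(X) <- rownames(deep$X)
      feature_matrix(X, deep$labels,
                     provenance = data.frame(
                       column = colnames(X),
                       flavor = rep(fids, each = pca_per_flavor),
                       source = "pca"))
    },
    "4" = {
      S <- pca_apply(pca_fit(radiomics$X, ncomp = pca_global), radiomics$X)
      rownames(S) <- rownames(radiomics$X)
      feature_matrix(S, radiomics$labels,
                     provenance = data.frame(column = colnames(S),
                                             flavor = NA, source = "pca"))
    },
    "5" = {
      X <- cbind(deep$X, radiomics$X)
      feature_matrix(X, deep$labels,
                     provenance = rbind(deep$provenance, radiomics$provenance))
    },
    stop("set_id must be 1..5")
  )
}

#' SMOTE class balancing
#'
#' Every minority class is upsampled to the majority count; a synthetic
#' sample is `x + u * (x_nn - x)` with `u ~ Uniform(0, 1)` and `x_nn` one of
#' the `k` nearest same-class neighbours (`k` truncated to class size - 1).
#' Original rows are preserved unchanged, synthetics appended.
#'
#' @param X numeric matrix.
#' @param y factor labels (length `nrow(X)`).
#' @param k_neighbors neighbourhood size.
#' @param seed integer seed.
#' @return list with balanced `X` and `y`.
#' @export
smote_balance <- function(X, y, k_neighbors = 5, seed = 1L) {
  y <- droplevels(as.factor(y))
  counts <- table(y)
  target <- max(counts)
  add_X <- list(); add_y <- list()
  withr::with_seed(derive_seed(seed, "smote"), {
    for (cl in names(counts)) {
      need <- target - counts[[cl]]
      if (need == 0) next
      idx <- which(y == cl)
      if (length(idx) < 2) {
        stop("smote_balance: class '", cl, "' has a single sample (no neighbour)")
      }
      Xc <- X[idx, , drop = FALSE]
      k <- min(k_neighbors, length(idx) - 1)
      D <- as.matrix(stats::dist(Xc))
      diag(D) <- Inf
      nn <- apply(D, 1, function(dd) order(dd)[seq_len(k)])
      nn <- matrix(nn, nrow = k)
      base_i <- sample(length(idx), need, replace = TRUE)
      pick <- vapply(base_i, function(i) nn[sample.int(k, 1), i], numeric(1))
      u <- stats::runif(need)
      syn <- Xc[base_i, , drop = FALSE] +
        u * (Xc[pick, , drop = FALSE] - Xc[base_i, , drop = FALSE])
      rownames(syn) <- sprintf("syn_%s_%03d", cl, seq_len(need))
      add_X[[cl]] <- syn
      add_y[[cl]] <- rep(cl, need)
    }
  })
  if (length(add_X)) {
    X <- rbind(X, do.call(rbind, add_X))
    y <- factor(c(as.character(y), unlist(add_y)), levels = levels(y))
  }
  list(X = X, y = y)
}

#' Column standardization with training-only statistics
#'
#' Zero mean, unit variance per column using the population convention
#' (divide by n); statistics are computed on `X_train` only and applied to
#' both matrices. Zero-variance columns map to 0.
#'
#' @param X_train training matrix (>= 2 rows).
#' @param X_apply optional matrix transformed with the training statistics.
#' @return list with `train`, `apply`, `center`, `scale`.
#' @export
standardize <- function(X_train, X_apply = NULL) {
  if (nrow(X_train) < 2) stop("standardize: need at least 2 training rows")
  ctr <- colMeans(X_train)
  sc <- sqrt(colMeans(sweep(X_train, 2, ctr)^2))
  sc[sc < 1e-12] <- Inf  # constant columns -> 0 after scaling
  tr <- sweep(sweep(X_train, 2, ctr), 2, sc, "/")
  ap <- if (!is.null(X_apply)) sweep(sweep(X_apply, 2, ctr), 2, sc, "/") else NULL
  list(train = tr, apply = ap, center = ctr, scale = sc)
}

#' Greedy correlation filter
#'
#' Scans columns in their fixed order; a column is dropped when its absolute
#' Pearson correlation with any earlier retained column exceeds the cutoff.
#' The surviving set has all pairwise `|r| <= cutoff`; the operation is
#' idempotent. Constant columns correlate 0 by convention.
#'
#' @param X numeric matrix (>= 2 rows).
#' @param cutoff correlation cutoff in (0, 1]; default 0.8.
#' @return list with filtered `X` and `kept` column names.
#' @export
correlation_filter <- function(X, cutoff = 0.8) {
  if (cutoff <= 0 || cutoff > 1) stop("cutoff must be in (0, 1]")
  p <- ncol(X)
  if (p <= 1) return(list(X = X, kept = colnames(X)))
  suppressWarnings(C <- abs(stats::cor(X)))
  C[!is.finite(C)] <- 0
  kept <- logical(p)
  kept[1] <- TRUE
  for (j in 2:p) {
    kept[j] <- !any(C[which(kept), j] > cutoff)
  }
  list(X = X[, kept, drop = FALSE],
       kept = colnames(X)[kept])
}

#' LASSO feature selection
#'
#' L1-penalized logistic regression (multinomial with grouped penalty for the
#' five-group scheme); the penalty is chosen by cross-validated deviance at
#' its minimum over glmnet's logarithmic grid. Returns the columns with
#' nonzero coefficients.
#'
#' @param X standardized numeric matrix.
#' @param y factor outcome.
#' @param cv_folds internal CV folds.
#' @param seed integer seed for the fold split.
#' @return character vector of selected column names (may be empty, with a
#'   warning; the caller decides how to proceed).
#' @export
lasso_select <- function(X, y, cv_folds = 5, seed = 1L) {
  y <- droplevels(as.factor(y))
  if (ncol(X) < 2) return(colnames(X))
  fam <- if (nlevels(y) == 2) "binomial" else "multinomial"
  foldid <- integer(length(y))
  withr::with_seed(derive_seed(seed, "lasso"), {
    for (cl in levels(y)) {
      ix <- which(y == cl)
      foldid[ix] <- sample(rep_len(seq_len(cv_folds), length(ix)))
    }
  })
  fit <- glmnet::cv.glmnet(X, y, family = fam, alpha = 1,
                           foldid = as.integer(foldid),
                           standardize = FALSE,
                           type.multinomial = if (fam == "multinomial") "grouped" else NULL)
  cf <- stats::coef(fit, s = "lambda.min")
  nz <- if (fam == "binomial") {
    rownames(cf)[-1][abs(cf[-1, 1]) > 0]
  } else {
    sel <- Reduce(`|`, lapply(cf, function(m) abs(m[-1, 1]) > 0))
    rownames(cf[[1]])[-1][sel]
  }
  if (!length(nz)) {
    warning("lasso_select: all coefficients zero at every penalty; ",
            "returning an empty selection")
  }
  nz
}

#' Preprocessing plan
#'
#' @param steps ordered subset of
#'   `c("smote", "standardize", "pca", "correlation_filter", "lasso")`.
#' @param pca if `TRUE` the plan's PCA step is active (feature sets 1, 3, 5).
#' @param corr_cutoff correlation cutoff (default 0.8).
#' @param pca_var variance fraction retained by the preprocessing PCA.
#' @param smote_k SMOTE neighbourhood size.
#' @param lasso_cv_folds internal folds for the LASSO penalty.
#' @param leaky_mode if `TRUE`, fit every step once on the full data before
#'   splitting (reproduces preprocessing-before-CV leakage); default is
#'   fold-safe fitting.
#' @return a `preprocess_plan`.
#' @export
preprocess_plan <- function(steps = c("smote", "standardize", "pca",
                                      "correlation_filter", "lasso"),
                            pca = TRUE, corr_cutoff = 0.8, pca_var = 0.95,
                            smote_k = 5, lasso_cv_folds = 3,
                            leaky_mode = FALSE) {
  allowed <- c("smote", "standardize", "pca", "correlation_filter", "lasso")
  if (!all(steps %in% allowed)) stop("unknown preprocessing step")
  if (!pca) steps <- setdiff(steps, "pca")
  structure(list(steps = steps, corr_cutoff = corr_cutoff, pca_var = pca_var,
                 smote_k = smote_k, lasso_cv_folds = lasso_cv_folds,
                 leaky_mode = leaky_mode),
            class = "preprocess_plan")
}

## fit the chain on (Xtr, ytr), apply to Xte; returns transformed splits and
## an audit of per-step column counts
fit_chain <- function(Xtr, ytr, Xte, plan, seed) {
  audit <- c(input = ncol(Xtr))
  for (st in plan$steps) {
    if (st == "smote") {
      sm <- smote_balance(Xtr, ytr, plan$smote_k, seed)
      Xtr <- sm$X; ytr <- sm$y
      audit <- c(audit, smote = ncol(Xtr))
    } else if (st == "standardize") {
      sd_ <- standardize(Xtr, Xte)
      Xtr <- sd_$train; Xte <- sd_$apply
      audit <- c(audit, standardize = ncol(Xtr))
    } else if (st == "pca") {
      fit <- pca_fit(Xtr, var_target = plan$pca_var)
      Xtr <- pca_apply(fit, Xtr)
      if (!is.null(Xte)) Xte <- pca_apply(fit, Xte)
      audit <- c(audit, pca = ncol(Xtr))
    } else if (st == "correlation_filter") {
      cf <- correlation_filter(Xtr, plan$corr_cutoff)
      Xtr <- cf$X
      if (!is.null(Xte)) Xte <- Xte[, cf$kept, drop = FALSE]
      audit <- c(audit, correlation_filter = ncol(Xtr))
    } else if (st == "lasso") {
      sel <- suppressWarnings(
        lasso_select(Xtr, ytr, plan$lasso_cv_folds, seed))
      if (length(sel)) {  # empty selection: keep the previous step's columns
        Xtr <- Xtr[, sel, drop = FALSE]
        if (!is.null(Xte)) Xte <- Xte[, sel, drop = FALSE]
      }
      audit <- c(audit, lasso = ncol(Xtr))
    }
  }
  list(X_train = Xtr, y_train = ytr, X_test = Xte, audit = audit)
}

#' Run the preprocessing chain over cross-validation folds
#'
#' Default (fold-safe): SMOTE, standardization, PCA, the correlation filter
#' and LASSO are all fitted on each fold's training split only and applied
#' to its test split; SMOTE synthetics never enter a test split. With
#' `plan$leaky_mode`, the chain is fitted once on all data (SMOTE included)
#' and folds are then sliced from the augmented, globally transformed matrix,
#' synthetics being assigned to folds stratified by class.
#'
#' @param X numeric matrix.
#' @param y factor labels.
#' @param plan a [preprocess_plan()].
#' @param fold_assignment integer fold id per row.
#' @param seed integer seed.
#' @return list of per-fold lists (`X_train`, `y_train`, `X_test`, `y_test`,
#'   `audit`).
#' @export
preprocess <- function(X, y, plan, fold_assignment, seed = 1L) {
  y <- droplevels(as.factor(y))
  folds <- sort(unique(fold_assignment))
  for (f in folds) {
    if (nlevels(droplevels(y[fold_assignment != f])) < 2) {
      stop("preprocess: a training split contains a single class")
    }
  }
  if (!plan$leaky_mode) {
    lapply(folds, function(f) {
      te <- fold_assignment == f
      out <- fit_chain(X[!te, , drop = FALSE], y[!te],
                       X[te, , drop = FALSE], plan, derive_seed(seed, "fold", f))
      out$y_test <- y[te]
      out
    })
  } else {
    global <- fit_chain(X, y, NULL, plan, derive_seed(seed, "global"))
    Xg <- global$X_train; yg <- global$y_train
    n_orig <- nrow(X)
    n_syn <- nrow(Xg) - n_orig
    fa_syn <- integer(n_syn)
    if (n_syn > 0) {
      ysyn <- yg[n_orig + seq_len(n_syn)]
      withr::with_seed(derive_seed(seed, "synfold"), {
        for (cl in levels(ysyn)) {
          ix <- which(ysyn == cl)
          if (length(ix)) fa_syn[ix] <- sample(rep_len(folds, length(ix)))
        }
      })
    }
    fa <- c(fold_assignment, fa_syn)
    lapply(folds, function(f) {
      te <- fa == f
      list(X_train = Xg[!te, , drop = FALSE], y_train = yg[!te],
           X_test = Xg[te, , drop = FALSE], y_test = yg[te],
           audit = global$audit)
    })
  }
}
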