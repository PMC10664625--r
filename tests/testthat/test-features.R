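# Synthetic deep / radiomics feature_matrix fixtures with the true pipeline
# geometry (52 flavors x 7200 deep / 107 radiomics columns per flavor).
make_deep_fm <- function(n = 8, seed = 1) {
  memo(sprintf("deepfm_%d_%d", n, seed), function() {
    fids <- flavor_ids()
    dn <- tensorflavor:::deep_feature_names()
    cn <- as.vector(vapply(fids, function(f) paste0(f, "__", dn),
                           character(length(dn))))
    X <- withr::with_seed(seed,
      matrix(stats::rnorm(n * length(cn)), n,
             dimnames = list(sprintf("P%03d", 1:n), cn)))
    feature_matrix(X, labels = rep(c(1L, 3L), length.out = n),
                   provenance = data.frame(column = cn,
                                           flavor = rep(fids, each = length(dn)),
                                           source = "deep"))
  })
}

make_rad_fm <- function(n = 8, seed = 2) {
  memo(sprintf("radfm_%d_%d", n, seed), function() {
    fids <- flavor_ids()
    fn <- radiomics_feature_classes()$name
    cn <- as.vector(t(outer(fids, fn, paste, sep = "__")))
    X <- withr::with_seed(seed,
      matrix(stats::rnorm(n * length(cn)), n,
             dimnames = list(sprintf("P%03d", 1:n), cn)))
    feature_matrix(X, labels = rep(c(1L, 3L), length.out = n),
                   provenance = data.frame(column = cn,
                                           flavor = rep(fids, each = length(fn)),
                                           source = "radiomics"))
  })
}

test_that("feature sets have the contracted widths", {
  deep <- make_deep_fm(); rad <- make_rad_fm()
  expect_equal(ncol(assemble_feature_set(deep, rad, 1)$X), 374400)
  expect_equal(ncol(assemble_feature_set(deep, rad, 2)$X), 5564)
  s3 <- assemble_feature_set(deep, rad, 3)
  expect_equal(ncol(s3$X), 260)               # 52 flavors x 5 components
  expect_equal(ncol(assemble_feature_set(deep, rad, 5)$X), 379964)
  # PCA cannot produce more components than min(rows - 1, cols)
  expect_error(assemble_feature_set(deep, rad, 4), "components")
  expect_error(assemble_feature_set(deep, rad, 6), "set_id")
  # row misalignment
  rad2 <- rad
  rownames(rad2$X)[1] <- "OTHER"
  expect_error(assemble_feature_set(deep, rad2, 5), "row-aligned")
})

test_that("SMOTE balances to the majority count and preserves originals", {
  X <- matrix(rnorm(60), 6, 10,
              dimnames = list(paste0("p", 1:6), paste0("f", 1:10)))
  y <- factor(c("A", "A", "A", "A", "B", "B"))
  sm <- smote_balance(X, y, k_neighbors = 5, seed = 1)
  expect_equal(as.vector(table(sm$y)), c(4, 4))
  expect_equal(sm$X[1:6, ], X)
  # already balanced: unchanged
  yb <- factor(rep(c("A", "B"), 3))
  smb <- smote_balance(X, yb, seed = 1)
  expect_equal(smb$X, X)
  expect_equal(smb$y, yb)
  # synthetic samples are convex combinations: 1-D class {0, 1}
  X1 <- matrix(c(0, 1, rnorm(8) + 10), ncol = 1)
  y1 <- factor(c("m", "m", rep("M", 8)))
  for (s in 1:10) {
    sm1 <- smote_balance(X1, y1, seed = s)
    syn <- sm1$X[-(1:10), 1]
    expect_true(all(syn >= 0 & syn <= 1))
  }
  expect_error(smote_balance(X, factor(c("A", "A", "A", "A", "A", "B")),
                             seed = 1), "single sample")
})

test_that("standardization uses training statistics only (population sd)", {
  tr <- matrix(c(1, 2, 3), 3, 1)
  s <- standardize(tr)
  expect_equal(s$train[, 1], c(-1, 0, 1) * sqrt(3 / 2))
  expect_equal(mean(s$train), 0)
  expect_equal(standardize(matrix(5, 4, 1))$train[, 1], rep(0, 4))
  # apply-set transformed with train statistics differs from
  # self-standardization: shifted toy set
  ap <- matrix(c(11, 12, 13), 3, 1)
  both <- standardize(tr, ap)
  expect_equal(both$apply[, 1], (c(11, 12, 13) - 2) / sqrt(2 / 3))
  expect_false(isTRUE(all.equal(both$apply, standardize(ap)$train)))
  expect_error(standardize(matrix(1, 1, 2)), "2 training rows")
})

test_that("the correlation filter keeps the earlier of correlated pairs and is idempotent", {
  set.seed(10)
  X <- cbind(a = rnorm(50), b = rnorm(50))
  X <- cbind(X, c = X[, "a"])   # duplicate of the first column
  cf <- correlation_filter(X, 0.8)
  expect_equal(cf$kept, c("a", "b"))
  C <- abs(cor(cf$X))
  expect_true(all(C[upper.tri(C)] <= 0.8))
  cf2 <- correlation_filter(cf$X, 0.8)
  expect_equal(cf2$kept, cf$kept)
  # independent columns at n = 200 all survive
  Xi <- matrix(rnorm(200 * 30), 200, dimnames = list(NULL, paste0("v", 1:30)))
  expect_length(correlation_filter(Xi, 0.8)$kept, 30)
  # constant columns correlate 0 by convention and survive
  Xc <- cbind(X[, 1:2], k = rep(1, 50))
  expect_true("k" %in% correlation_filter(Xc, 0.8)$kept)
})

test_that("LASSO recovers a strong signal and stays sparse under the null", {
  set.seed(3)
  n <- 200
  X <- matrix(rnorm(n * 11), n, dimnames = list(NULL, paste0("v", 0:10)))
  y <- factor(ifelse(X[, 1] + rnorm(n, sd = 0.3) > 0, "pos", "neg"))
  sel <- lasso_select(X, y, cv_folds = 5, seed = 1)
  expect_true("v0" %in% sel)
  # pure-noise outcome: empty or small selection in >= 90% of repeats
  hits <- vapply(1:10, function(s) {
    yn <- withr::with_seed(1000 + s, factor(sample(rep(c("a", "b"), n / 2))))
    length(suppressWarnings(lasso_select(X[, 1:10], yn, 3, seed = s)))
  }, numeric(1))
  expect_gte(mean(hits <= 2), 0.9)
  # duplicated informative column: correlation filter then LASSO keeps one
  Xd <- cbind(X, v0dup = X[, "v0"])
  kept <- correlation_filter(Xd, 0.8)$kept
  expect_false("v0dup" %in% kept)
  sel2 <- lasso_select(Xd[, kept], y, 5, seed = 1)
  expect_equal(sum(c("v0", "v0dup") %in% sel2), 1)
})

test_that("fold-safe preprocessing never leaks test rows or synthetics", {
  set.seed(4)
  X <- matrix(rnorm(40 * 12), 40, dimnames = list(paste0("p", 1:40),
                                                  paste0("f", 1:12)))
  y <- factor(rep(c("a", "a", "a", "b"), 10))
  plan <- preprocess_plan(pca = FALSE)
  fa <- integer(40)
  fa[y == "a"] <- rep(1:4, length.out = 30)
  fa[y == "b"] <- rep(1:4, length.out = 10)
  pre <- preprocess(X, y, plan, fa, seed = 1)
  for (f in 1:4) {
    # test rows are original patients only (no SMOTE synthetics)
    expect_true(all(rownames(pre[[f]]$X_test) %in% rownames(X)))
    expect_equal(nrow(pre[[f]]$X_test), sum(fa == f))
    # column counts never grow along the chain after smote
    aud <- pre[[f]]$audit
    expect_true(all(diff(aud[-1]) <= 0))
  }
  # fold-safety: fitted statistics ignore the test split entirely
  f1 <- tensorflavor:::fit_chain(X[fa != 1, ], y[fa != 1], X[fa == 1, ],
                                 plan, derive_seed(1, "fold", 1))
  expect_equal(pre[[1]]$X_train, f1$X_train)
  expect_equal(pre[[1]]$X_test, f1$X_test)
})

test_that("leaky mode equals one global application of the chain", {
  set.seed(5)
  X <- matrix(rnorm(30 * 8), 30, dimnames = list(paste0("p", 1:30),
                                                 paste0("f", 1:8)))
  y <- factor(rep(c("a", "a", "b"), 10))
  plan <- preprocess_plan(pca = FALSE, leaky_mode = TRUE)
  fa <- integer(30)
  fa[y == "a"] <- rep(1:3, length.out = 20)
  fa[y == "b"] <- rep(1:3, length.out = 10)
  pre <- preprocess(X, y, plan, fa, seed = 2)
  glob <- tensorflavor:::fit_chain(X, y, NULL, plan,
                                   derive_seed(2, "global"))
  recon <- do.call(rbind, lapply(pre, `[[`, "X_test"))
  expect_setequal(rownames(recon), rownames(glob$X_train))
  expect_equal(recon[rownames(glob$X_train), ], glob$X_train)
  expect_error(preprocess(X, factor(rep("a", 30)), plan, fa), "single class")
})
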