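methods_all <- default_fusion_methods()

test_that("every transform backend perfectly reconstructs a random image", {
  x <- random_image(1, 64)
  expect_lt(max(abs(tensorflavor:::idwt2(tensorflavor:::dwt2(x, "db2", 3)) - x)), 1e-6)
  expect_lt(max(abs(tensorflavor:::idwt2(tensorflavor:::dwt2(x, "db3", 3)) - x)), 1e-6)
  expect_lt(max(abs(tensorflavor:::iswt2(tensorflavor:::swt2(x, "db2", 2)) - x)), 1e-6)
  expect_lt(max(abs(tensorflavor:::idtcwt2(tensorflavor:::dtcwt2(x, 3)) - x)), 1e-6)
  lp <- tensorflavor:::laplacian_pyramid(x, 4)
  expect_lt(max(abs(tensorflavor:::laplacian_reconstruct(lp) - x)), 1e-6)
  rp <- tensorflavor:::ratio_pyramid(x, 4)
  expect_lt(max(abs(tensorflavor:::ratio_reconstruct(rp) - x)), 1e-6)
  bands <- tensorflavor:::fftdir2(x)
  expect_lt(max(abs(tensorflavor:::ifftdir2(bands) - x)), 1e-3)
})

test_that("fusing an image with itself returns it (identity)", {
  x <- random_image(2)
  for (mn in c("LP", "RP", "DWT", "DTCWT", "WAVELET", "WEIGHTED", "PCA")) {
    f <- fuse(x, x, methods_all[[mn]])
    expect_lt(max(abs(f - x)), 1e-6)
  }
  expect_lt(max(abs(fuse(x, x, methods_all$CVT) - x)), 1e-3)
})

test_that("weighted fusion is the stated convex combination", {
  x <- random_image(3)
  b <- random_image(4)
  expect_equal(as.vector(fuse(matrix(0, 60, 60), b,
                              fusion_method("WEIGHTED"))),
               as.vector(0.5 * b))
  m73 <- fusion_method("WEIGHTED", weights = c(0.7, 0.3))
  expect_lt(max(abs(fuse(x, b, m73) - (0.7 * x + 0.3 * b))), 1e-12)
  expect_error(fusion_method("WEIGHTED", weights = c(0.7, 0.6)), "sum")
  expect_error(fuse(x, b[1:30, 1:30], m73), "shape")
})

test_that("symmetric-rule methods commute in their arguments", {
  a <- random_image(5)
  b <- random_image(6)
  for (mn in c("LP", "DWT", "DTCWT", "CVT", "WAVELET", "RP", "WEIGHTED")) {
    expect_lt(max(abs(fuse(a, b, methods_all[[mn]]) -
                      fuse(b, a, methods_all[[mn]]))), 1e-10)
  }
})

test_that("PCA fusion weights match an independent 2x2 eigen oracle", {
  # oracle: closed-form eigenvector of a symmetric 2x2 matrix
  oracle <- function(a, b) {
    S <- stats::cov(cbind(as.vector(a), as.vector(b)))
    tr <- S[1, 1] + S[2, 2]
    disc <- sqrt(max(0, (S[1, 1] - S[2, 2])^2 + 4 * S[1, 2]^2))
    l1 <- (tr + disc) / 2
    v <- if (abs(S[1, 2]) > 1e-15) c(l1 - S[2, 2], S[1, 2]) else {
      if (S[1, 1] >= S[2, 2]) c(1, 0) else c(0, 1)
    }
    v <- abs(v)
    v / sum(v)
  }
  a <- matrix(c(1, 0, 0, 1), 2)
  b <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(pca_fusion_weights(a, b), oracle(a, b), tolerance = 1e-10)
  for (s in 1:5) {
    x <- random_image(s, 12); y <- random_image(s + 50, 12)
    expect_equal(pca_fusion_weights(x, y), oracle(x, y), tolerance = 1e-10)
  }
  # degenerate and limiting cases
  expect_equal(pca_fusion_weights(a, a), c(0.5, 0.5))
  expect_equal(pca_fusion_weights(matrix(1, 4, 4), matrix(2, 4, 4)), c(0.5, 0.5))
  big <- matrix(rnorm(400, sd = 100), 20)
  tiny <- matrix(rnorm(400, sd = 1e-4), 20)
  w <- pca_fusion_weights(big, tiny)
  expect_gt(w[1], 0.99)
  expect_equal(sum(w), 1)
})

test_that("the flavor stack holds 52 flavors (48 fused) in the fixed order", {
  fs <- tiny_stack()
  expect_length(fs$flavors, 52)
  expect_equal(sum(grepl(":", names(fs$flavors))), 48)
  expect_identical(names(fs$flavors), flavor_ids())
  expect_identical(flavor_ids()[1:4], c("ADC", "DWI", "T2Wsag", "T2Wtra"))
  # 6 unordered pairs x 8 methods
  expect_equal(length(unique(sub(":.*", "", flavor_ids()[-(1:4)]))), 6)
  expect_equal(length(unique(sub(".*:", "", flavor_ids()[-(1:4)]))), 8)
  for (f in fs$flavors) {
    expect_true(all(is.finite(f)) && min(f) >= 0 && max(f) <= 1)
  }
  cs_bad <- tiny_cohort()[[1]]
  cs_bad$modality_images$ADC <- NULL
  expect_error(build_flavor_stack(cs_bad), "ADC")
})

test_that("identical constant modalities give an all-constant stack", {
  cs <- tiny_cohort()[[1]]
  for (m in names(cs$modality_images)) {
    cs$modality_images[[m]]$pixels[] <- 0.5
  }
  fs <- build_flavor_stack(cs)
  for (f in fs$flavors) expect_equal(max(abs(f - f[1, 1])), 0)
})

test_that("clipping after fusion is rare on phantom data", {
  fs <- tiny_stack()
  fused <- fs$flavors[grepl(":", names(fs$flavors))]
  clip <- vapply(fused, function(f) {
    cf <- attr(f, "clipped_frac")
    if (is.null(cf)) 0 else cf
  }, numeric(1))
  expect_lt(mean(clip), 0.05)
})
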