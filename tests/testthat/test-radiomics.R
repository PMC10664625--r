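test_that("the feature vector has 107 features in the printed class partition", {
  fs <- tiny_stack()
  v <- extract_radiomics(fs$flavors[["ADC-DWI:LP"]], fs$mask)
  expect_length(v, 107)
  expect_true(all(is.finite(v)))
  cls <- table(attr(v, "class_of"))
  expect_equal(cls[["firstorder"]], 18)
  expect_equal(cls[["shape"]], 14)
  expect_equal(cls[["GLDM"]], 14)
  expect_equal(cls[["GLCM"]], 24)
  expect_equal(cls[["NGTDM"]], 5)
  expect_equal(cls[["GLSZM"]], 16)
  expect_equal(cls[["GLRLM"]], 16)
  expect_equal(sum(cls), 107)
})

test_that("degenerate constant regions are defined by limits, never NaN", {
  m <- matrix(TRUE, 10, 10)
  v <- extract_radiomics(matrix(0.5, 10, 10), m)
  expect_true(all(is.finite(v)))
  expect_equal(unname(v["firstorder_Variance"]), 0)
  expect_equal(unname(v["firstorder_Entropy"]), 0)
  expect_equal(unname(v["GLCM_Contrast"]), 0)
  expect_error(extract_radiomics(matrix(0.5, 10, 10), matrix(FALSE, 10, 10)),
               "empty")
  small <- matrix(FALSE, 10, 10); small[1:2, 1:2] <- TRUE
  expect_error(extract_radiomics(matrix(0.5, 10, 10), small), "9")
})

test_that("first-order features match direct computation on raw intensities", {
  img <- random_image(21, 12)
  m <- matrix(TRUE, 12, 12)
  v <- extract_radiomics(img, m, radiomics_settings(rescale = FALSE))
  x <- as.vector(img)
  expect_equal(unname(v["firstorder_Mean"]), mean(x))
  expect_equal(unname(v["firstorder_Variance"]), mean((x - mean(x))^2))
  expect_equal(unname(v["firstorder_Energy"]), sum(x^2))
  expect_equal(unname(v["firstorder_Median"]), median(x))
  expect_equal(unname(v["firstorder_RootMeanSquared"]), sqrt(mean(x^2)))
  expect_equal(unname(v["firstorder_InterquartileRange"]),
               unname(quantile(x, 0.75) - quantile(x, 0.25)))
  # intensity-shift equivariance (pre-discretization statistics)
  v2 <- extract_radiomics(img + 3, m, radiomics_settings(rescale = FALSE))
  expect_equal(unname(v2["firstorder_Mean"] - v["firstorder_Mean"]), 3)
  expect_equal(unname(v2["firstorder_Variance"]), unname(v["firstorder_Variance"]))
})

test_that("GLCM features match a brute-force co-occurrence oracle", {
  lv <- matrix(c(1L, 2L, 3L, 1L,
                 1L, 2L, 2L, 3L,
                 3L, 3L, 1L, 2L,
                 2L, 1L, 3L, 1L), 4, byrow = TRUE)
  Ng <- 3L
  offs <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  oracle <- sapply(offs, function(off) {
    P <- matrix(0, Ng, Ng)
    for (r in 1:4) for (cc in 1:4) {
      r2 <- r + off[1]; c2 <- cc + off[2]
      if (r2 >= 1 && r2 <= 4 && c2 >= 1 && c2 <= 4) {
        P[lv[r, cc], lv[r2, c2]] <- P[lv[r, cc], lv[r2, c2]] + 1
      }
    }
    P <- P + t(P)
    p <- P / sum(P)
    ii <- matrix(1:Ng, Ng, Ng); jj <- t(ii)
    c(Contrast = sum((ii - jj)^2 * p),
      Autocorrelation = sum(ii * jj * p),
      JointEnergy = sum(p^2),
      JointEntropy = -sum(p[p > 0] * log2(p[p > 0])),
      MaximumProbability = max(p))
  })
  got <- tensorflavor:::glcm_features(lv, Ng)
  for (f in rownames(oracle)) {
    expect_equal(unname(got[f]), mean(oracle[f, ]), tolerance = 1e-12,
                 label = paste("GLCM", f))
  }
})

test_that("run-length features match hand-enumerated runs", {
  # rows: (1,1,2) (2,2,3) (3,3,3) -> runs 1x2, 2x1 | 2x2, 3x1 | 3x3; Nr = 5
  lines <- list(c(1L, 1L, 2L), c(2L, 2L, 3L), c(3L, 3L, 3L))
  P <- tensorflavor:::rlm_from_lines(lines, 3L)
  f <- tensorflavor:::rlm_features_one(P, Np = 9)
  expect_equal(unname(f["ShortRunEmphasis"]),
               (1 / 4 + 1 + 1 / 4 + 1 + 1 / 9) / 5)
  expect_equal(unname(f["RunPercentage"]), 5 / 9)
  expect_equal(unname(f["GrayLevelNonUniformity"]), (1 + 4 + 4) / 5)
  expect_equal(unname(f["LongRunEmphasis"]), (4 + 1 + 4 + 1 + 9) / 5)
})

test_that("size zones are 8-connected components per gray level", {
  lv <- matrix(c(1L, 1L, 2L,
                 1L, 2L, 2L,
                 3L, 3L, 3L), 3, byrow = TRUE)
  z <- tensorflavor:::zone_sizes(lv, 3L)
  z <- z[order(z$gl), ]
  expect_equal(z$gl, c(1L, 2L, 3L))
  expect_equal(z$size, c(3L, 3L, 3L))
  f <- tensorflavor:::glszm_features(lv, 3L, Np = 9)
  expect_equal(unname(f["SmallAreaEmphasis"]), 1 / 9)
  expect_equal(unname(f["ZonePercentage"]), 3 / 9)
  expect_equal(unname(f["GrayLevelNonUniformity"]), 1)
})

test_that("dependence and neighbourhood statistics match closed forms on a constant patch", {
  lv <- matrix(1L, 3, 3)
  g <- tensorflavor:::gldm_features(lv, 1L)
  # dependences: 4 corners -> 4, 4 edges -> 6, centre -> 9
  expect_equal(unname(g["LargeDependenceEmphasis"]),
               (4 * 16 + 4 * 36 + 81) / 9)
  expect_equal(unname(g["GrayLevelNonUniformity"]), 9)
  n <- tensorflavor:::ngtdm_features(lv, 1L)
  expect_equal(unname(n["Coarseness"]), 1e6)
  expect_equal(unname(n["Contrast"]), 0)
  expect_equal(unname(n["Busyness"]), 0)
})

test_that("shape features depend only on the mask", {
  fs <- tiny_stack()
  sh <- function(img) {
    v <- extract_radiomics(img, fs$mask)
    v[grep("^shape_", names(v))]
  }
  expect_identical(sh(fs$flavors[["ADC"]]), sh(fs$flavors[["T2Wtra"]]))
  # geometry sanity on a parametric ellipse mask
  v <- extract_radiomics(fs$flavors[["ADC"]], fs$mask)
  a_px <- sum(fs$mask) * 0.25  # mm^2
  expect_equal(unname(v["shape_VoxelVolume"]), a_px * 3)
  expect_gt(unname(v["shape_Sphericity"]), 0)
  expect_lte(unname(v["shape_Sphericity"]), 1.05)
  expect_equal(unname(v["shape_LeastAxisLength"]), 0)
})

test_that("the cohort radiomics matrix is 52 x 107 wide and deterministic", {
  stacks <- list(tiny_stack(), tiny_stack())
  rm_ <- radiomics_matrix(stacks)
  expect_equal(dim(rm_$X), c(2, 52 * 107))
  expect_equal(ncol(rm_$X), 5564)
  expect_false(any(!is.finite(rm_$X)))
  expect_equal(unname(rm_$X[1, ]), unname(rm_$X[2, ]))  # identical patients
  expect_equal(colnames(rm_$X)[1], "ADC__firstorder_10Percentile")
  st_bad <- tiny_stack()
  st_bad$flavors[["ADC-DWI:LP"]] <- NULL
  expect_error(radiomics_matrix(list(st_bad)), "ADC-DWI:LP")
})
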