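## 107-feature radiomics vector: 18 first-order, 14 shape, 24 GLCM, 14 GLDM,
## 5 NGTDM, 16 GLSZM, 16 GLRLM. Feature names and the class partition follow
## the field-standard 107-feature configuration; formulas follow the IBSI
## definitions. Extraction is 2D single-slice: texture matrices are planar
## and shape descriptors treat the mask as a one-slice volume of the given
## slice thickness.

#' Pinned radiomics extraction settings
#'
#' @param bin_width gray-level bin width applied after rescaling.
#' @param rescale_max normalized `[0, 1]` images are rescaled to
#'   `[0, rescale_max]` before discretization; with the default 255 and bin
#'   width 25 this reproduces byte-range binning.
#' @param rescale set `FALSE` to take intensities as-is (un-normalized input).
#' @param pixel_spacing in-plane spacing in mm (row, col).
#' @param slice_thickness slice thickness in mm used by shape descriptors.
#' @return settings list.
#' @export
radiomics_settings <- function(bin_width = 25, rescale_max = 255,
                               rescale = TRUE,
                               pixel_spacing = c(0.5, 0.5),
                               slice_thickness = 3) {
  list(bin_width = bin_width, rescale_max = rescale_max, rescale = rescale,
       pixel_spacing = as.numeric(pixel_spacing),
       slice_thickness = slice_thickness)
}

#' The 107-feature name/class partition
#'
#' @return data.frame with columns `name` and `class`
#'   (`firstorder`, `shape`, `GLDM`, `GLCM`, `NGTDM`, `GLSZM`, `GLRLM`).
#' @export
radiomics_feature_classes <- function() {
  fo <- c("10Percentile", "90Percentile", "Energy", "Entropy",
          "InterquartileRange", "Kurtosis", "Maximum", "Mean",
          "MeanAbsoluteDeviation", "Median", "Minimum", "Range",
          "RobustMeanAbsoluteDeviation", "RootMeanSquared", "Skewness",
          "TotalEnergy", "Uniformity", "Variance")
  sh <- c("Elongation", "Flatness", "LeastAxisLength", "MajorAxisLength",
          "Maximum2DDiameterColumn", "Maximum2DDiameterRow",
          "Maximum2DDiameterSlice", "Maximum3DDiameter", "MeshVolume",
          "MinorAxisLength", "Sphericity", "SurfaceArea",
          "SurfaceVolumeRatio", "VoxelVolume")
  glcm <- c("Autocorrelation", "ClusterProminence", "ClusterShade",
            "ClusterTendency", "Contrast", "Correlation",
            "DifferenceAverage", "DifferenceEntropy", "DifferenceVariance",
            "Id", "Idm", "Idmn", "Idn", "Imc1", "Imc2", "InverseVariance",
            "JointAverage", "JointEnergy", "JointEntropy", "MCC",
            "MaximumProbability", "SumAverage", "SumEntropy", "SumSquares")
  gldm <- c("DependenceEntropy", "DependenceNonUniformity",
            "DependenceNonUniformityNormalized", "DependenceVariance",
            "GrayLevelNonUniformity", "GrayLevelVariance",
            "HighGrayLevelEmphasis", "LargeDependenceEmphasis",
            "LargeDependenceHighGrayLevelEmphasis",
            "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
            "SmallDependenceEmphasis",
            "SmallDependenceHighGrayLevelEmphasis",
            "SmallDependenceLowGrayLevelEmphasis")
  ngtdm <- c("Busyness", "Coarseness", "Complexity", "Contrast", "Strength")
  glszm <- c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
             "GrayLevelVariance", "HighGrayLevelZoneEmphasis",
             "LargeAreaEmphasis", "LargeAreaHighGrayLevelEmphasis",
             "LargeAreaLowGrayLevelEmphasis", "LowGrayLevelZoneEmphasis",
             "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
             "SmallAreaEmphasis", "SmallAreaHighGrayLevelEmphasis",
             "SmallAreaLowGrayLevelEmphasis", "ZoneEntropy",
             "ZonePercentage", "ZoneVariance")
  glrlm <- c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
             "GrayLevelVariance", "HighGrayLevelRunEmphasis",
             "LongRunEmphasis", "LongRunHighGrayLevelEmphasis",
             "LongRunLowGrayLevelEmphasis", "LowGrayLevelRunEmphasis",
             "RunEntropy", "RunLengthNonUniformity",
             "RunLengthNonUniformityNormalized", "RunPercentage",
             "RunVariance", "ShortRunEmphasis",
             "ShortRunHighGrayLevelEmphasis", "ShortRunLowGrayLevelEmphasis")
  data.frame(
    name = c(paste0("firstorder_", fo), paste0("shape_", sh),
             paste0("GLDM_", gldm), paste0("GLCM_", glcm),
             paste0("NGTDM_", ngtdm), paste0("GLSZM_", glszm),
             paste0("GLRLM_", glrlm)),
    class = rep(c("firstorder", "shape", "GLDM", "GLCM", "NGTDM",
                  "GLSZM", "GLRLM"),
                times = c(length(fo), length(sh), length(gldm), length(glcm),
                          length(ngtdm), length(glszm), length(glrlm))),
    stringsAsFactors = FALSE
  )
}

firstorder_features <- function(x, lev, settings) {
  N <- length(x)
  p <- tabulate(lev, max(lev)) / N
  p <- p[p > 0]
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  q <- stats::quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
  rob <- x[x >= q[1] & x <= q[5]]
  vox <- prod(settings$pixel_spacing) * settings$slice_thickness
  c(`10Percentile` = q[1],
    `90Percentile` = q[5],
    Energy = sum(x^2),
    Entropy = -sum(p * log2(p)),
    InterquartileRange = q[4] - q[2],
    Kurtosis = if (m2 > EPS) m4 / m2^2 else 0,
    Maximum = max(x),
    Mean = mu,
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    Median = q[3],
    Minimum = min(x),
    Range = max(x) - min(x),
    RobustMeanAbsoluteDeviation = mean(abs(rob - mean(rob))),
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (m2 > EPS) m3 / m2^1.5 else 0,
    TotalEnergy = vox * sum(x^2),
    Uniformity = sum(p^2),
    Variance = m2)
}

## marching-squares area and perimeter of the 0.5-level set of a binary mask
mask_mesh <- function(mask, spacing) {
  n <- nrow(mask); m <- ncol(mask)
  pm <- matrix(0L, n + 2, m + 2)
  pm[2:(n + 1), 2:(m + 1)] <- mask * 1L
  tl <- pm[1:(n + 1), 1:(m + 1)]; tr <- pm[1:(n + 1), 2:(m + 2)]
  bl <- pm[2:(n + 2), 1:(m + 1)]; br <- pm[2:(n + 2), 2:(m + 2)]
  code <- tl + 2L * tr + 4L * bl + 8L * br
  ncorner <- tl + tr + bl + br
  ## per-cell area of {>= 0.5}, unit cell, crossings at edge midpoints
  area_lut <- c(`0` = 0, `1` = 1 / 8, `2` = 1 / 2, `3` = 7 / 8, `4` = 1)
  perim_lut <- c(`0` = 0, `1` = sqrt(2) / 2, `3` = sqrt(2) / 2, `4` = 0)
  area <- area_lut[as.character(ncorner)]
  perim <- ifelse(ncorner == 2,
                  ifelse(code %in% c(6L, 9L), sqrt(2), 1),  # diagonal pairs
                  perim_lut[as.character(ncorner)])
  area <- ifelse(ncorner == 2 & code %in% c(6L, 9L), 1 / 4, area)
  list(area = sum(area) * prod(spacing),
       perimeter = sum(perim) * spacing[1])
}

shape_features <- function(mask, settings) {
  sp <- settings$pixel_spacing
  Z <- settings$slice_thickness
  N <- sum(mask)
  mesh <- mask_mesh(mask, sp)
  A <- mesh$area; Pm <- mesh$perimeter
  V <- A * Z
  SA <- 2 * A + Pm * Z
  ## physical in-plane coordinates of foreground pixel centres
  idx <- which(mask, arr.ind = TRUE)
  ry <- idx[, 1] * sp[1]; cx <- idx[, 2] * sp[2]
  S <- stats::cov(cbind(cx, ry)) * (N - 1) / N
  ev <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev <- pmax(ev, 0)
  ## boundary pixels suffice for diameters
  er <- cbind(ry, cx)
  if (N > 3) {
    nbfull <- rowSums(vapply(list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1)),
      function(o) {
        r2 <- idx[, 1] + o[1]; c2 <- idx[, 2] + o[2]
        inside <- r2 >= 1 & r2 <= nrow(mask) & c2 >= 1 & c2 <= ncol(mask)
        out <- logical(nrow(idx))
        out[inside] <- mask[cbind(r2[inside], c2[inside])]
        out
      }, logical(nrow(idx))))
    bd <- nbfull < 4
    if (sum(bd) >= 2) er <- er[bd, , drop = FALSE]
  }
  d2 <- as.matrix(stats::dist(er))
  dmax <- max(d2)
  row_ext <- max(er[, 1]) - min(er[, 1])
  col_ext <- max(er[, 2]) - min(er[, 2])
  sphericity <- if (SA > EPS) (36 * pi * V^2)^(1 / 3) / SA else 1
  c(Elongation = if (ev[1] > EPS) sqrt(ev[2] / ev[1]) else 1,
    Flatness = 0,                       # single slice: least axis vanishes
    LeastAxisLength = 0,
    MajorAxisLength = 4 * sqrt(ev[1]),
    Maximum2DDiameterColumn = sqrt(row_ext^2 + Z^2),
    Maximum2DDiameterRow = sqrt(col_ext^2 + Z^2),
    Maximum2DDiameterSlice = dmax,
    Maximum3DDiameter = sqrt(dmax^2 + Z^2),
    MeshVolume = V,
    MinorAxisLength = 4 * sqrt(ev[2]),
    Sphericity = sphericity,
    SurfaceArea = SA,
    SurfaceVolumeRatio = if (V > EPS) SA / V else 0,
    VoxelVolume = N * prod(sp) * Z)
}

#' Extract the 107-feature radiomics vector from one flavor image
#'
#' @param image `roi_image` or numeric matrix (normalized to `[0, 1]` unless
#'   `settings$rescale` is `FALSE`).
#' @param mask logical matrix, same shape, at least 9 foreground pixels.
#' @param settings see [radiomics_settings()].
#' @return named numeric vector of length 107 with attribute `class_of`
#'   giving the feature class partition.
#' @export
extract_radiomics <- function(image, mask, settings = radiomics_settings()) {
  img <- as_pixel_matrix(image)
  mask <- as.matrix(mask) != 0
  if (!all(dim(img) == dim(mask))) stop("image and mask shapes differ")
  nfg <- sum(mask)
  if (nfg == 0) stop("extract_radiomics: empty mask")
  if (nfg < 9) stop("extract_radiomics: mask has fewer than 9 foreground pixels")
  stopifnot_finite(img, "radiomics image")
  vals <- if (settings$rescale) img * settings$rescale_max else img
  x <- vals[mask]
  lev_all <- matrix(NA_integer_, nrow(img), ncol(img))
  lev_all[mask] <- as.integer(floor((vals[mask] - min(x)) / settings$bin_width)) + 1L
  Ng <- max(lev_all, na.rm = TRUE)
  out <- c(
    firstorder = firstorder_features(x, lev_all[mask], settings),
    shape = shape_features(mask, settings),
    GLDM = gldm_features(lev_all, Ng),
    GLCM = glcm_features(lev_all, Ng),
    NGTDM = ngtdm_features(lev_all, Ng),
    GLSZM = glszm_features(lev_all, Ng, nfg),
    GLRLM = glrlm_features(lev_all, Ng, nfg)
  )
  names(out) <- gsub("^([A-Za-z]+)\\.", "\\1_", names(out))
  spec <- radiomics_feature_classes()
  out <- out[spec$name]
  if (any(!is.finite(out))) {
    stop("non-finite radiomics feature(s): ",
         paste(spec$name[!is.finite(out)], collapse = ", "))
  }
  attr(out, "class_of") <- stats::setNames(spec$class, spec$name)
  out
}

#' Cohort radiomics matrix over all flavors
#'
#' @param stacks list of `flavor_stack` objects (52 flavors each).
#' @param settings see [radiomics_settings()].
#' @return a `feature_matrix` (patients x 5564) with column names
#'   `<flavor_id>__<feature_name>`, flavor-major order.
#' @export
radiomics_matrix <- function(stacks, settings = radiomics_settings()) {
  fids <- flavor_ids()
  spec <- radiomics_feature_classes()
  cn <- as.vector(t(outer(fids, spec$name, paste, sep = "__")))
  X <- matrix(NA_real_, length(stacks), length(cn),
              dimnames = list(vapply(stacks, `[[`, "", "patient_id"), cn))
  labels <- integer(length(stacks))
  for (i in seq_along(stacks)) {
    st <- stacks[[i]]
    miss <- setdiff(fids, names(st$flavors))
    if (length(miss)) {
      stop("patient ", st$patient_id, ": missing flavor(s) ",
           paste(miss, collapse = ", "))
    }
    row <- unlist(lapply(fids, function(fid) {
      extract_radiomics(st$flavors[[fid]], st$mask, settings)
    }), use.names = FALSE)
    X[i, ] <- row
    labels[i] <- st$grade_group
  }
  feature_matrix(X, labels,
                 provenance = data.frame(
                   column = cn,
                   flavor = rep(fids, each = nrow(spec)),
                   source = "radiomics"))
}

#' Construct a feature matrix container
#'
#' @param X numeric matrix, rows = patients (rownames = ids).
#' @param labels grade-group labels aligned to rows.
#' @param provenance data.frame with one row per column (`column`, `flavor`,
#'   `source`).
#' @return a `feature_matrix`.
#' @export
feature_matrix <- function(X, labels, provenance = NULL) {
  if (length(labels) != nrow(X)) stop("labels length must equal row count")
  if (anyDuplicated(colnames(X))) stop("duplicate column names")
  if (any(!is.finite(X))) stop("feature matrix contains non-finite values")
  structure(list(X = X, labels = labels, provenance = provenance),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d patients x %d features\n",
              nrow(x$X), ncol(x$X)))
  invisible(x)
}
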