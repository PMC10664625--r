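## Pixel-level image fusion: eight methods, and assembly of the 52-flavor
## stack (4 original modality ROIs + 8 methods x 6 unordered modality pairs).

#' Fusion method names, in canonical order
#' @return character vector of the eight method identifiers.
#' @export
fusion_method_names <- function() {
  c("LP", "RP", "DWT", "DTCWT", "CVT", "WAVELET", "WEIGHTED", "PCA")
}

#' Construct a fusion method specification
#'
#' @param name one of `fusion_method_names()`.
#' @param levels decomposition depth for pyramid/wavelet methods.
#' @param wavelet_family wavelet family for `DWT`/`WAVELET` (`"db2"`/`"db3"`).
#' @param detail_rule how detail (high-pass) coefficients of the two inputs
#'   are combined: `"max_abs"` keeps the larger-magnitude coefficient,
#'   `"average"` averages them.
#' @param approx_rule rule for approximation (low-pass) coefficients.
#' @param weights length-2 nonnegative weights summing to 1 (`WEIGHTED` only).
#' @return a `fusion_method` object.
#' @export
fusion_method <- function(name,
                          levels = NULL,
                          wavelet_family = "db2",
                          detail_rule = c("max_abs", "average"),
                          approx_rule = c("average", "max_abs"),
                          weights = c(0.5, 0.5)) {
  name <- match.arg(name, fusion_method_names())
  detail_rule <- match.arg(detail_rule)
  approx_rule <- match.arg(approx_rule)
  if (is.null(levels)) {
    levels <- switch(name, LP = 4L, RP = 4L, DWT = 3L, DTCWT = 3L,
                     CVT = 3L, WAVELET = 2L, 1L)
  }
  if (levels < 1) stop("levels must be >= 1")
  if (name == "WEIGHTED") {
    if (length(weights) != 2 || any(weights < 0) ||
        abs(sum(weights) - 1) > 1e-8) {
      stop("WEIGHTED weights must be two nonnegative values summing to 1")
    }
  }
  structure(list(name = name, levels = as.integer(levels),
                 wavelet_family = wavelet_family,
                 detail_rule = detail_rule, approx_rule = approx_rule,
                 weights = weights),
            class = "fusion_method")
}

#' Default specifications for all eight fusion methods
#' @return named list of `fusion_method` objects in canonical order.
#' @export
default_fusion_methods <- function() {
  out <- lapply(fusion_method_names(), fusion_method)
  names(out) <- fusion_method_names()
  out
}

rule_combine <- function(A, B, rule) {
  if (rule == "average") (A + B) / 2 else ifelse(abs(A) >= abs(B), A, B)
}

#' PCA fusion weights from the 2x2 covariance of two images
#'
#' Weights are the (absolute-value normalized) components of the leading
#' eigenvector of the covariance matrix of the two flattened images; the
#' fused image is the corresponding convex combination. Degenerate
#' covariance (constant or identical inputs) yields equal weights.
#'
#' @param a,b numeric matrices of identical shape.
#' @return numeric length-2: nonnegative weights summing to 1.
#' @export
pca_fusion_weights <- function(a, b) {
  a <- as_pixel_matrix(a); b <- as_pixel_matrix(b)
  if (!all(dim(a) == dim(b))) stop("images must have the same shape")
  va <- as.vector(a); vb <- as.vector(b)
  S <- stats::cov(cbind(va, vb))
  if (!all(is.finite(S)) || sum(diag(S)) < 1e-14) return(c(0.5, 0.5))
  ev <- eigen(S, symmetric = TRUE)
  v <- abs(ev$vectors[, 1])
  if (sum(v) < 1e-14) return(c(0.5, 0.5))
  v / sum(v)
}

## pad to 64x64, run f in transform space, crop back
with_pad64 <- function(a, b, f) {
  pa <- pad_reflect(a, 2); pb <- pad_reflect(b, 2)
  out <- f(pa, pb)
  out[3:62, 3:62]
}

fuse_matrices <- function(a, b, method) {
  switch(method$name,
    WEIGHTED = method$weights[1] * a + method$weights[2] * b,
    PCA = {
      w <- pca_fusion_weights(a, b)
      w[1] * a + w[2] * b
    },
    LP = with_pad64(a, b, function(pa, pb) {
      wa <- laplacian_pyramid(pa, method$levels)
      wb <- laplacian_pyramid(pb, method$levels)
      fused <- list(
        bands = Map(function(x, y) rule_combine(x, y, method$detail_rule),
                    wa$bands, wb$bands),
        base = rule_combine(wa$base, wb$base, method$approx_rule)
      )
      laplacian_reconstruct(fused)
    }),
    RP = with_pad64(a, b, function(pa, pb) {
      wa <- ratio_pyramid(pa, method$levels)
      wb <- ratio_pyramid(pb, method$levels)
      ## ratio layers encode local contrast as deviation from 1
      fused <- list(
        bands = Map(function(x, y) ifelse(abs(x - 1) >= abs(y - 1), x, y),
                    wa$bands, wb$bands),
        base = rule_combine(wa$base, wb$base, method$approx_rule)
      )
      ratio_reconstruct(fused)
    }),
    DWT = with_pad64(a, b, function(pa, pb) {
      wa <- dwt2(pa, method$wavelet_family, method$levels)
      wb <- dwt2(pb, method$wavelet_family, method$levels)
      wa$levels <- Map(function(la, lb) {
        Map(function(x, y) rule_combine(x, y, method$detail_rule), la, lb)
      }, wa$levels, wb$levels)
      wa$LL <- rule_combine(wa$LL, wb$LL, method$approx_rule)
      idwt2(wa)
    }),
    WAVELET = with_pad64(a, b, function(pa, pb) {
      ## stationary (undecimated) wavelet fusion, average rule on all bands
      wa <- swt2(pa, method$wavelet_family, method$levels)
      wb <- swt2(pb, method$wavelet_family, method$levels)
      wa$levels <- Map(function(la, lb) {
        Map(function(x, y) rule_combine(x, y, "average"), la, lb)
      }, wa$levels, wb$levels)
      wa$LL <- rule_combine(wa$LL, wb$LL, "average")
      iswt2(wa)
    }),
    DTCWT = with_pad64(a, b, function(pa, pb) {
      wa <- dtcwt2(pa, method$levels)
      wb <- dtcwt2(pb, method$levels)
      ## joint-magnitude selection across the two trees (real/imag pair)
      for (l in seq_along(wa$a$levels)) {
        for (bn in c("LH", "HL", "HH")) {
          ca_r <- wa$a$levels[[l]][[bn]]; ca_i <- wa$b$levels[[l]][[bn]]
          cb_r <- wb$a$levels[[l]][[bn]]; cb_i <- wb$b$levels[[l]][[bn]]
          pick_a <- (ca_r^2 + ca_i^2) >= (cb_r^2 + cb_i^2)
          wa$a$levels[[l]][[bn]] <- ifelse(pick_a, ca_r, cb_r)
          wa$b$levels[[l]][[bn]] <- ifelse(pick_a, ca_i, cb_i)
        }
      }
      wa$a$LL <- rule_combine(wa$a$LL, wb$a$LL, method$approx_rule)
      wa$b$LL <- rule_combine(wa$b$LL, wb$b$LL, method$approx_rule)
      idtcwt2(wa)
    }),
    CVT = with_pad64(a, b, function(pa, pb) {
      ## FFT directional multiscale bank; lowpass averaged, oriented bands
      ## by max-absolute value
      ba <- fftdir2(pa, scales = method$levels, wedges = 8)
      bb <- fftdir2(pb, scales = method$levels, wedges = 8)
      fused <- vector("list", length(ba))
      fused[[1]] <- rule_combine(ba[[1]], bb[[1]], method$approx_rule)
      for (i in seq_along(ba)[-1]) {
        fused[[i]] <- rule_combine(ba[[i]], bb[[i]], method$detail_rule)
      }
      ifftdir2(fused)
    }),
    stop("unknown fusion method: ", method$name)
  )
}

#' Fuse two normalized ROI images
#'
#' Both inputs must be normalized (values in `[0, 1]`) and share the same
#' 60x60 grid. The fused output is clipped back to `[0, 1]`; the fraction of
#' clipped pixels is attached as attribute `clipped_frac`.
#'
#' @param a,b `roi_image` objects or numeric matrices, same shape.
#' @param method a `fusion_method` object (see [fusion_method()]).
#' @return fused image, same representation as `a`.
#' @export
fuse <- function(a, b, method) {
  if (!inherits(method, "fusion_method")) stop("method must be a fusion_method")
  am <- as_pixel_matrix(a); bm <- as_pixel_matrix(b)
  if (!all(dim(am) == dim(bm))) stop("fuse: shape mismatch between inputs")
  stopifnot_finite(am, "fuse input a"); stopifnot_finite(bm, "fuse input b")
  raw <- fuse_matrices(am, bm, method)
  out <- clip01(raw)
  attr(out, "clipped_frac") <- mean(raw < 0 | raw > 1)
  if (inherits(a, "roi_image")) {
    out <- roi_image(out, spacing_mm = a$spacing_mm,
                     modality_tag = paste0(a$modality_tag, "+",
                                           if (inherits(b, "roi_image")) b$modality_tag else "b",
                                           ":", method$name),
                     patient_id = a$patient_id)
  }
  out
}

#' Canonical flavor identifiers
#'
#' The 52 flavor ids, in the fixed package-wide order: the four original
#' modalities (lexicographic), then the six unordered modality pairs in
#' lexicographic order, each crossed with the eight fusion methods in the
#' order of [fusion_method_names()]. Fused flavors are named `"pair:method"`,
#' e.g. `"ADC-DWI:LP"`.
#'
#' @return character vector of length 52.
#' @export
flavor_ids <- function() {
  pairs <- utils::combn(MODALITIES, 2, paste, collapse = "-")
  c(MODALITIES,
    as.vector(t(outer(pairs, fusion_method_names(), paste, sep = ":"))))
}

#' Build the 52-flavor image stack for one patient
#'
#' Each modality ROI is min-max normalized and resampled to the common
#' 60x60 grid (both ROI families span the same 30 mm physical extent); the
#' four originals are kept and all C(4,2) = 6 unordered modality pairs are
#' fused with each of the eight methods, giving 4 + 48 = 52 flavors.
#'
#' @param case a `patient_case` (see [generate_cohort()] / [read_case()]).
#' @param methods named list of `fusion_method` objects; defaults to
#'   [default_fusion_methods()].
#' @return a `flavor_stack`: list with `patient_id`, `flavors` (named list of
#'   52 60x60 matrices in canonical order), `mask` (lesion mask on the 60x60
#'   grid) and `grade_group`.
#' @export
build_flavor_stack <- function(case, methods = default_fusion_methods()) {
  missing <- setdiff(MODALITIES, names(case$modality_images))
  if (length(missing)) {
    stop("missing modality image(s): ", paste(missing, collapse = ", "))
  }
  base <- lapply(MODALITIES, function(m) {
    roi <- case$modality_images[[m]]
    resample_to(normalize_roi(roi), c(60, 60))
  })
  names(base) <- MODALITIES
  flavors <- lapply(base, function(r) r$pixels)
  pairs <- utils::combn(MODALITIES, 2, simplify = FALSE)
  for (pr in pairs) {
    for (mn in fusion_method_names()) {
      id <- paste0(pr[1], "-", pr[2], ":", mn)
      f <- fuse(flavors[[pr[1]]], flavors[[pr[2]]], methods[[mn]])
      flavors[[id]] <- f
    }
  }
  flavors <- flavors[flavor_ids()]
  structure(list(patient_id = case$patient_id,
                 flavors = flavors,
                 mask = mask_on_grid60(case),
                 grade_group = case$grade_group),
            class = "flavor_stack")
}

## lesion mask of the reference (T2W-transverse) grid, nearest-neighbour
## resampled to 60x60 for reuse across all flavors
mask_on_grid60 <- function(case) {
  m <- case$lesion_mask[["T2Wtra"]]
  if (is.null(m)) m <- case$lesion_mask[[1]]
  if (all(dim(m) == c(60, 60))) return(m != 0)
  idx <- floor((seq_len(60) - 0.5) * nrow(m) / 60) + 1
  (m[idx, idx] != 0)
}

#' @export
print.flavor_stack <- function(x, ...) {
  cat(sprintf("<flavor_stack> patient %s: %d flavors (grade group %s)\n",
              x$patient_id, length(x$flavors), x$grade_group))
  invisible(x)
}
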