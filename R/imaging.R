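## ROI container, normalization, resampling, window extraction, NIfTI input.
## Coordinate convention (documented + tested): gt_point = (p, q, r) are
## 0-based voxel indices with p = column, q = row, r = slice.

#' Construct an ROI image
#'
#' @param pixels numeric matrix of intensities.
#' @param spacing_mm length-2 pixel spacing (row, col) in millimetres.
#' @param modality_tag character tag (one of `"ADC"`, `"DWI"`, `"T2Wsag"`,
#'   `"T2Wtra"`, or a fused flavor id).
#' @param patient_id character patient identifier.
#' @return a `roi_image` object.
#' @export
roi_image <- function(pixels, spacing_mm = c(0.5, 0.5),
                      modality_tag = "T2Wtra", patient_id = "") {
  pixels <- as.matrix(pixels)
  stopifnot_finite(pixels, "roi pixels")
  structure(list(pixels = pixels, shape = dim(pixels),
                 spacing_mm = as.numeric(spacing_mm),
                 modality_tag = modality_tag, patient_id = patient_id),
            class = "roi_image")
}

#' @export
print.roi_image <- function(x, ...) {
  cat(sprintf("<roi_image> %s %dx%d @ %.3g mm (patient %s)\n", x$modality_tag,
              x$shape[1], x$shape[2], x$spacing_mm[1], x$patient_id))
  invisible(x)
}

as_pixel_matrix <- function(x) {
  if (inherits(x, "roi_image")) x$pixels else as.matrix(x)
}

#' Min-max normalize an ROI to [0, 1]
#'
#' Constant input maps to all zeros. Idempotent.
#'
#' @param roi `roi_image` or numeric matrix.
#' @return same representation as the input, values in `[0, 1]`.
#' @export
normalize_roi <- function(roi) {
  m <- as_pixel_matrix(roi)
  stopifnot_finite(m, "normalize input")
  rng <- range(m)
  out <- if (diff(rng) < .Machine$double.eps) {
    matrix(0, nrow(m), ncol(m))
  } else {
    (m - rng[1]) / diff(rng)
  }
  if (inherits(roi, "roi_image")) {
    roi$pixels <- out
    roi
  } else {
    out
  }
}

#' Resample an ROI to a target grid covering the same physical extent
#'
#' Bilinear interpolation between pixel centres; the two ROI families of the
#' study (60x60 at 0.5 mm, 15x15 at 2 mm) both span 30 mm, so resampling is
#' a pure grid change. Output values are convex combinations of the input
#' and therefore stay within its range.
#'
#' @param roi `roi_image` or numeric matrix.
#' @param target_shape integer length-2, typically `c(60, 60)`.
#' @return resampled ROI with updated spacing.
#' @export
resample_to <- function(roi, target_shape = c(60, 60)) {
  m <- as_pixel_matrix(roi)
  stopifnot_finite(m, "resample input")
  out <- resample_bilinear(m, target_shape[1], target_shape[2])
  if (inherits(roi, "roi_image")) {
    roi_image(out,
              spacing_mm = roi$spacing_mm * dim(m) / target_shape,
              modality_tag = roi$modality_tag, patient_id = roi$patient_id)
  } else {
    out
  }
}

#' Extract a square window centred on the ground-truth point
#'
#' The centre sits at window index `size %/% 2` (row and column); the window
#' covers the half-open index range `[c - size %/% 2, c + size - size %/% 2)`.
#' Windows crossing the volume border are padded by edge replication, keeping
#' lesions near the border usable.
#'
#' @param volume 2D matrix or 3D array.
#' @param gt_point numeric length-3 `(p, q, r)`, 0-based voxel indices
#'   (p = column, q = row, r = slice; `r` ignored for 2D input).
#' @param size window side length (15 for DWI/ADC, 60 for T2W).
#' @return numeric `size` x `size` matrix.
#' @export
extract_roi <- function(volume, gt_point, size) {
  if (length(dim(volume)) == 3) {
    r <- gt_point[3]
    if (r < 0 || r >= dim(volume)[3]) stop("gt_point slice outside volume")
    volume <- volume[, , r + 1]
  }
  n <- nrow(volume); m <- ncol(volume)
  q <- gt_point[2]; p <- gt_point[1]
  if (q < 0 || q >= n || p < 0 || p >= m) stop("gt_point outside volume")
  half <- size %/% 2
  ri <- pmin(pmax((q - half):(q + size - half - 1), 0), n - 1) + 1
  ci <- pmin(pmax((p - half):(p + size - half - 1), 0), m - 1) + 1
  volume[ri, ci, drop = FALSE]
}

#' Read one patient case from NIfTI files
#'
#' @param paths named list/vector mapping each modality (`"ADC"`, `"DWI"`,
#'   `"T2Wsag"`, `"T2Wtra"`) to a NIfTI file path.
#' @param gt_point numeric length-3 `(p, q, r)` 0-based, on the T2W grid.
#' @param lesion_mask optional named list of binary masks per modality;
#'   defaults to ellipse masks from `semi_axes_mm` when given.
#' @param semi_axes_mm optional length-2 lesion ellipse semi-axes in mm.
#' @param grade_group integer 1..5 (NA if unknown).
#' @param patient_id character id.
#' @return a `patient_case`.
#' @export
read_case <- function(paths, gt_point, lesion_mask = NULL,
                      semi_axes_mm = NULL, grade_group = NA_integer_,
                      patient_id = "case") {
  missing <- setdiff(MODALITIES, names(paths))
  if (length(missing)) {
    stop("read_case: missing modality path(s): ", paste(missing, collapse = ", "))
  }
  imgs <- lapply(MODALITIES, function(m) {
    f <- paths[[m]]
    if (dir.exists(f)) {
      stop("read_case: '", f, "' is a directory; DICOM series input is not ",
           "supported — convert to NIfTI-1 first")
    }
    if (!file.exists(f)) stop("read_case: file not found: ", f)
    nim <- RNifti::readNifti(f)
    pd <- attr(nim, "pixdim")
    if (is.null(pd)) pd <- RNifti::pixdim(nim)
    if (is.null(pd) || any(!is.finite(pd[1:2])) || any(pd[1:2] <= 0)) {
      stop("read_case: missing or invalid pixel spacing in ", f)
    }
    px <- as.matrix(nim[, , drop = TRUE])
    roi_image(px, spacing_mm = pd[1:2], modality_tag = m,
              patient_id = patient_id)
  })
  names(imgs) <- MODALITIES
  if (is.null(lesion_mask)) {
    if (is.null(semi_axes_mm)) stop("read_case: supply lesion_mask or semi_axes_mm")
    lesion_mask <- lapply(imgs, function(im) {
      ellipse_mask(nrow(im$pixels), im$spacing_mm[1],
                   semi_axes_mm[1], semi_axes_mm[2])
    })
  }
  patient_case(patient_id, imgs, gt_point, lesion_mask, grade_group,
               semi_axes_mm = semi_axes_mm)
}

patient_case <- function(patient_id, modality_images, gt_point, lesion_mask,
                         grade_group, semi_axes_mm = NULL) {
  structure(list(patient_id = patient_id, modality_images = modality_images,
                 gt_point = as.numeric(gt_point), lesion_mask = lesion_mask,
                 grade_group = grade_group, semi_axes_mm = semi_axes_mm),
            class = "patient_case")
}

#' @export
print.patient_case <- function(x, ...) {
  cat(sprintf("<patient_case> %s (grade group %s), %d modalities\n",
              x$patient_id, x$grade_group, length(x$modality_images)))
  invisible(x)
}

## axis-aligned ellipse mask centred at pixel index n %/% 2 (0-based)
ellipse_mask <- function(n, spacing, a_mm, b_mm) {
  ctr <- n %/% 2
  idx <- (seq_len(n) - 1 - ctr) * spacing
  R <- matrix(idx, n, n)          # row offsets (mm)
  C <- t(R)                        # col offsets (mm)
  (C / a_mm)^2 + (R / b_mm)^2 <= 1
}
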