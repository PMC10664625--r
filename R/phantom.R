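## Synthetic mpMRI lesion cohorts with the study geometry: 60x60 T2W ROIs at
## 0.5 mm and 15x15 DWI/ADC ROIs at 2 mm (both spanning 30 mm), grade-group
## class structure 36/40/20/8/7 by default, and a controllable grade-dependent
## signal. The texture model is a stationary Gaussian random field (FFT-
## filtered white noise) with grade-dependent correlation length, plus a
## grade-dependent additive mean shift; all four modalities share one latent
## lesion field mixed with modality-specific noise, so fusion has genuine
## shared structure.

#' Default grade-group class counts of the emulated cohort
#' @return named integer vector, groups 1..5.
#' @export
default_class_counts <- function() {
  c(`1` = 36L, `2` = 40L, `3` = 20L, `4` = 8L, `5` = 7L)
}

#' Phantom cohort configuration
#'
#' @param n_patients total cohort size; must equal `sum(class_counts)`.
#' @param class_counts named count per grade group 1..5.
#' @param signal_strength nonnegative scale of the grade-dependent signal.
#'   At 0 the images are label-independent; 1 is the default study condition.
#' @param texture_correlation_lengths per-grade correlation length of the
#'   lesion texture field, in pixels on the 60x60 grid. The default decreases
#'   with grade: higher grades get finer-grained, more heterogeneous texture.
#' @param noise_sd standard deviation of additive white acquisition noise.
#' @param seed integer seed; cohorts are bit-identical for a fixed config.
#' @return a `phantom_config`.
#' @export
phantom_config <- function(n_patients = 111L,
                           class_counts = default_class_counts(),
                           signal_strength = 1,
                           texture_correlation_lengths =
                             c(`1` = 6, `2` = 5, `3` = 4, `4` = 3, `5` = 2),
                           noise_sd = 0.04,
                           seed = 1L) {
  if (sum(class_counts) != n_patients) {
    stop("phantom_config: class_counts must sum to n_patients (",
         sum(class_counts), " != ", n_patients, ")")
  }
  if (signal_strength < 0) stop("signal_strength must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(n_patients = as.integer(n_patients),
                 class_counts = class_counts,
                 signal_strength = signal_strength,
                 texture_correlation_lengths = texture_correlation_lengths,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_config")
}

## stationary Gaussian random field: white noise low-passed in the frequency
## domain with a Gaussian kernel of width `ell` pixels, standardized
gaussian_field <- function(n, ell) {
  w <- matrix(stats::rnorm(n * n), n)
  fr <- c(0:(n / 2), (-n / 2 + 1):-1) / n
  H <- exp(-2 * pi^2 * ell^2 * outer(fr^2, fr^2, `+`))
  g <- Re(stats::fft(stats::fft(w) * H, inverse = TRUE)) / (n * n)
  (g - mean(g)) / (stats::sd(g) + 1e-12)
}

## block-average a 60x60 field to 15x15 (2 mm grid)
block4 <- function(x) {
  idx <- rep(seq_len(15), each = 4)
  t(rowsum(t(rowsum(x, idx)), idx)) / 16
}

## per-modality baseline and grade response (arbitrary tissue-like units)
phantom_modality_params <- function() {
  list(
    ADC    = list(base = 0.75, shift0 = -0.25, slope = -0.08),
    DWI    = list(base = 0.35, shift0 = +0.15, slope = +0.05),
    T2Wsag = list(base = 0.55, shift0 = -0.12, slope = -0.03),
    T2Wtra = list(base = 0.55, shift0 = -0.12, slope = -0.03)
  )
}

#' Generate a synthetic lesion cohort
#'
#' Deterministic for a fixed configuration. With `signal_strength > 0`,
#' lesion texture heterogeneity increases and mean ADC intensity decreases
#' monotonically with grade group; at `signal_strength = 0` the images carry
#' no label information.
#'
#' @param config a [phantom_config()].
#' @return list of `patient_case` objects, one per lesion.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  grades <- rep(as.integer(names(config$class_counts)), config$class_counts)
  ss <- config$signal_strength
  ells <- config$texture_correlation_lengths
  ell_mid <- mean(ells)
  pars <- phantom_modality_params()
  withr::with_seed(config$seed, {
    lapply(seq_along(grades), function(i) {
      g <- grades[i]
      pid <- sprintf("P%03d", i)
      ell <- ell_mid + min(ss, 1) * (ells[[as.character(g)]] - ell_mid)
      latent <- gaussian_field(60, ell)
      amp <- 0.10 + 0.03 * ss * (g - 1)
      a_mm <- stats::runif(1, 6, 10)
      b_mm <- stats::runif(1, 6, 10)
      mask60 <- ellipse_mask(60, 0.5, a_mm, b_mm)
      mask15 <- ellipse_mask(15, 2, a_mm, b_mm)
      imgs <- lapply(MODALITIES, function(m) {
        p <- pars[[m]]
        own <- gaussian_field(60, ell)
        tex <- amp * (0.7 * latent + 0.3 * own)
        lesion <- p$shift0 + p$slope * ss * (g - 1) + tex
        hi <- p$base + mask60 * lesion +
          config$noise_sd * matrix(stats::rnorm(3600), 60)
        if (m %in% c("DWI", "ADC")) {
          roi_image(block4(p$base + mask60 * lesion) +
                      config$noise_sd * matrix(stats::rnorm(225), 15),
                    spacing_mm = c(2, 2), modality_tag = m, patient_id = pid)
        } else {
          roi_image(hi, spacing_mm = c(0.5, 0.5), modality_tag = m,
                    patient_id = pid)
        }
      })
      names(imgs) <- MODALITIES
      masks <- list(ADC = mask15, DWI = mask15,
                    T2Wsag = mask60, T2Wtra = mask60)
      patient_case(pid, imgs, gt_point = c(30, 30, 0), lesion_mask = masks,
                   grade_group = g, semi_axes_mm = c(a_mm, b_mm))
    })
  })
}

#' Write a cohort as NIfTI files plus a labels table
#'
#' One NIfTI file per modality per patient (`<id>_<modality>.nii.gz`) and a
#' `labels.csv` with header `patient_id,p,q,r,grade_group,semi_a_mm,semi_b_mm`.
#' Lesion masks are parametric ellipses; their semi-axes travel in the CSV so
#' [read_cohort()] round-trips the full case.
#'
#' @param cases list of `patient_case` objects.
#' @param directory output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cases, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("write_cohort: cannot create ", directory)
  rows <- lapply(cases, function(cs) {
    for (m in names(cs$modality_images)) {
      im <- cs$modality_images[[m]]
      nim <- RNifti::asNifti(im$pixels)
      RNifti::pixdim(nim) <- im$spacing_mm
      f <- file.path(directory, sprintf("%s_%s.nii.gz", cs$patient_id, m))
      ok <- tryCatch(RNifti::writeNifti(nim, f), error = function(e) {
        stop("write_cohort: failed to write ", f, ": ", conditionMessage(e))
      })
      ok
    }
    data.frame(patient_id = cs$patient_id,
               p = cs$gt_point[1], q = cs$gt_point[2], r = cs$gt_point[3],
               grade_group = cs$grade_group,
               semi_a_mm = cs$semi_axes_mm[1], semi_b_mm = cs$semi_axes_mm[2])
  })
  tab <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(patient_id = character(), p = numeric(), q = numeric(),
               r = numeric(), grade_group = integer(),
               semi_a_mm = numeric(), semi_b_mm = numeric())
  }
  utils::write.csv(tab, file.path(directory, "labels.csv"), row.names = FALSE)
  invisible(directory)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param directory cohort directory containing `labels.csv` and NIfTI files.
#' @return list of `patient_case` objects.
#' @export
read_cohort <- function(directory) {
  lf <- file.path(directory, "labels.csv")
  if (!file.exists(lf)) stop("read_cohort: missing labels table: ", lf)
  tab <- utils::read.csv(lf)
  lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    paths <- lapply(MODALITIES, function(m) {
      file.path(directory, sprintf("%s_%s.nii.gz", row$patient_id, m))
    })
    names(paths) <- MODALITIES
    read_case(paths, gt_point = c(row$p, row$q, row$r),
              semi_axes_mm = c(row$semi_a_mm, row$semi_b_mm),
              grade_group = row$grade_group, patient_id = row$patient_id)
  })
}
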