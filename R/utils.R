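#' @keywords internal
"_PACKAGE"

## Canonical modality names, lexicographic. Flavor order everywhere in the
## package derives from this vector.
MODALITIES <- c("ADC", "DWI", "T2Wsag", "T2Wtra")

#' Derive a stream-specific sub-seed from a master seed
#'
#' All randomness in the package flows from one integer seed; independent
#' stages (phantom, folds, SMOTE, model fits, ...) draw their own sub-seed
#' with a labelled integer-hash scheme so that adding a stage never perturbs
#' the streams of the others.
#'
#' @param seed master integer seed.
#' @param label character stream label.
#' @param index optional integer index within the stream.
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label, index = 0L) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 48271 + h * 69621 + as.numeric(index) * 16807) %% 2147483647)
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

stopifnot_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) stop(sprintf("%s contains non-finite values", what), call. = FALSE)
  invisible(x)
}

## Reflect-pad a matrix by `p` pixels on every side (no edge duplication).
pad_reflect <- function(x, p) {
  n <- nrow(x); m <- ncol(x)
  ri <- c((p + 1):2, 1:n, (n - 1):(n - p))
  ci <- c((p + 1):2, 1:m, (m - 1):(m - p))
  x[ri, ci]
}

## Bilinear resampling between two pixel grids covering the same physical
## extent. Pixel centres sit at (i - 0.5) * spacing; coordinates outside the
## source grid replicate the edge value.
resample_bilinear <- function(x, out_rows, out_cols) {
  n <- nrow(x); m <- ncol(x)
  if (n == out_rows && m == out_cols) return(x)
  sr <- n / out_rows; sc <- m / out_cols
  # output centre k - 0.5 (in output px) -> source px coordinate
  rc <- ((seq_len(out_rows) - 0.5) * sr) + 0.5 - 1  # 0-based source row coord of centre
  cc <- ((seq_len(out_cols) - 0.5) * sc) + 0.5 - 1
  r0 <- pmin(pmax(floor(rc), 0), n - 1); r1 <- pmin(r0 + 1, n - 1)
  c0 <- pmin(pmax(floor(cc), 0), m - 1); c1 <- pmin(c0 + 1, m - 1)
  fr <- pmin(pmax(rc - r0, 0), 1); fc <- pmin(pmax(cc - c0, 0), 1)
  A <- x[r0 + 1, c0 + 1, drop = FALSE]; B <- x[r0 + 1, c1 + 1, drop = FALSE]
  C <- x[r1 + 1, c0 + 1, drop = FALSE]; D <- x[r1 + 1, c1 + 1, drop = FALSE]
  wr <- matrix(fr, out_rows, out_cols); wc <- matrix(fc, out_rows, out_cols, byrow = TRUE)
  (1 - wr) * ((1 - wc) * A + wc * B) + wr * ((1 - wc) * C + wc * D)
}
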