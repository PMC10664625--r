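## Multiscale transforms used by the fusion module. Everything operates on
## square grids whose side is divisible by 2^levels (the fusion layer pads
## 60x60 inputs to 64x64). All transforms here are perfectly reconstructing;
## tests assert analyse-then-synthesise round trips to 1e-6 (1e-3 for the
## FFT directional bank, which is exact in theory and fp-limited in practice).

.tf_cache <- new.env(parent = emptyenv())

cached <- function(key, make) {
  if (!exists(key, envir = .tf_cache, inherits = FALSE)) {
    assign(key, make(), envir = .tf_cache)
  }
  get(key, envir = .tf_cache, inherits = FALSE)
}

## Orthonormal Daubechies scaling filters; highpass by the quadrature-mirror
## rule g[k] = (-1)^k h[L-1-k]. Orthonormality is exercised indirectly by the
## perfect-reconstruction tests.
wt_filters <- function(family) {
  h <- switch(family,
    db2 = c(0.4829629131445341, 0.8365163037378079,
            0.2241438680420134, -0.1294095225512604),
    db3 = c(0.3326705529500825, 0.8068915093110924, 0.4598775021184914,
            -0.1350110200102546, -0.0854412738820267, 0.0352262918857095),
    stop("unknown wavelet family: ", family)
  )
  g <- rev(h) * (-1)^(seq_along(h) - 1)
  list(h = h, g = g)
}

## Periodized, decimating analysis operator (n/2 x n) for filter f.
conv_down_op <- function(n, f, key) {
  cached(sprintf("cd_%s_%d", key, n), function() {
    M <- matrix(0, n / 2, n)
    for (k in seq_len(n / 2)) {
      for (m in seq_along(f)) {
        j <- ((2 * (k - 1) + (m - 1)) %% n) + 1
        M[k, j] <- M[k, j] + f[m]
      }
    }
    M
  })
}

## Undecimated (full circulant) operator with filter upsampled by 2^(lev-1).
conv_full_op <- function(n, f, lev, key) {
  cached(sprintf("cf_%s_%d_%d", key, n, lev), function() {
    M <- matrix(0, n, n)
    step <- 2^(lev - 1)
    for (k in seq_len(n)) {
      for (m in seq_along(f)) {
        j <- (((k - 1) + (m - 1) * step) %% n) + 1
        M[k, j] <- M[k, j] + f[m]
      }
    }
    M
  })
}

## ---- decimated 2D DWT (periodization) -------------------------------------

dwt2 <- function(x, family = "db2", levels = 3) {
  flt <- wt_filters(family)
  out <- list(levels = vector("list", levels), family = family)
  A <- x
  for (l in seq_len(levels)) {
    n <- nrow(A)
    L <- conv_down_op(n, flt$h, paste0(family, "L"))
    H <- conv_down_op(n, flt$g, paste0(family, "H"))
    out$levels[[l]] <- list(
      LH = L %*% A %*% t(H),
      HL = H %*% A %*% t(L),
      HH = H %*% A %*% t(H)
    )
    A <- L %*% A %*% t(L)
  }
  out$LL <- A
  out
}

idwt2 <- function(w) {
  flt <- wt_filters(w$family)
  A <- w$LL
  for (l in rev(seq_along(w$levels))) {
    n <- 2 * nrow(A)
    L <- conv_down_op(n, flt$h, paste0(w$family, "L"))
    H <- conv_down_op(n, flt$g, paste0(w$family, "H"))
    d <- w$levels[[l]]
    A <- t(L) %*% A %*% L + t(L) %*% d$LH %*% H +
         t(H) %*% d$HL %*% L + t(H) %*% d$HH %*% H
  }
  A
}

## ---- stationary (undecimated) 2D wavelet transform ------------------------

swt2 <- function(x, family = "db2", levels = 2) {
  flt <- wt_filters(family)
  n <- nrow(x)
  out <- list(levels = vector("list", levels), family = family, n = n)
  A <- x
  for (l in seq_len(levels)) {
    L <- conv_full_op(n, flt$h, l, paste0(family, "L"))
    H <- conv_full_op(n, flt$g, l, paste0(family, "H"))
    out$levels[[l]] <- list(
      LH = L %*% A %*% t(H),
      HL = H %*% A %*% t(L),
      HH = H %*% A %*% t(H)
    )
    A <- L %*% A %*% t(L)
  }
  out$LL <- A
  out
}

iswt2 <- function(w) {
  flt <- wt_filters(w$family)
  n <- w$n
  A <- w$LL
  for (l in rev(seq_along(w$levels))) {
    L <- conv_full_op(n, flt$h, l, paste0(w$family, "L"))
    H <- conv_full_op(n, flt$g, l, paste0(w$family, "H"))
    d <- w$levels[[l]]
    A <- (t(L) %*% A %*% L + t(L) %*% d$LH %*% H +
          t(H) %*% d$HL %*% L + t(H) %*% d$HH %*% H) / 4
  }
  A
}

## ---- Gaussian / Laplacian / ratio pyramids --------------------------------

burt_kernel <- c(1, 4, 6, 4, 1) / 16

pyr_reduce_op <- function(n) conv_down_op(n, burt_kernel, "burt")

pyr_reduce <- function(x) {
  R <- pyr_reduce_op(nrow(x))
  R %*% x %*% t(R)
}

pyr_expand <- function(x) {
  R <- pyr_reduce_op(2 * nrow(x))
  4 * t(R) %*% x %*% R  # adjoint of reduce, x4 to preserve mean (2 per axis)
}

laplacian_pyramid <- function(x, levels = 4) {
  out <- vector("list", levels)
  G <- x
  for (l in seq_len(levels)) {
    Gn <- pyr_reduce(G)
    out[[l]] <- G - pyr_expand(Gn)
    G <- Gn
  }
  list(bands = out, base = G)
}

laplacian_reconstruct <- function(p) {
  G <- p$base
  for (l in rev(seq_along(p$bands))) G <- p$bands[[l]] + pyr_expand(G)
  G
}

## Ratio-of-low-pass pyramid (contrast pyramid). Layers are ratios of each
## Gaussian level to the expanded next level; epsilon guards division and is
## removed exactly on reconstruction.
RP_EPS <- 1e-6

ratio_pyramid <- function(x, levels = 4) {
  out <- vector("list", levels)
  G <- x
  for (l in seq_len(levels)) {
    Gn <- pyr_reduce(G)
    out[[l]] <- (G + RP_EPS) / (pyr_expand(Gn) + RP_EPS)
    G <- Gn
  }
  list(bands = out, base = G)
}

ratio_reconstruct <- function(p) {
  G <- p$base
  for (l in rev(seq_along(p$bands))) {
    G <- p$bands[[l]] * (pyr_expand(G) + RP_EPS) - RP_EPS
  }
  G
}

## ---- dual-tree complex wavelet --------------------------------------------
## Two parallel perfectly-reconstructing orthonormal trees; tree-A/tree-B
## detail coefficients are treated as the real/imaginary parts of a complex
## coefficient for the fusion rule. Reconstruction averages the two trees.

dtcwt2 <- function(x, levels = 3) {
  list(a = dwt2(x, "db2", levels), b = dwt2(x, "db3", levels))
}

idtcwt2 <- function(w) {
  (idwt2(w$a) + idwt2(w$b)) / 2
}

## ---- FFT directional multiscale bank (curvelet-style) ----------------------
## Frequency plane partitioned into a radial lowpass + `scales` annuli, each
## annulus split into `wedges` orientation bands (antipodal wedges merged so
## every band image is real). The windows form an exact partition of unity,
## so summation reconstructs the input to machine precision.

fftdir_windows <- function(n, scales = 3, wedges = 8) {
  cached(sprintf("fdw_%d_%d_%d", n, scales, wedges), function() {
    fr <- c(0:(n / 2), (-n / 2 + 1):-1) / n
    FX <- matrix(fr, n, n)
    FY <- t(FX)
    rho <- sqrt(FX^2 + FY^2)
    theta <- atan2(FY, FX) %% pi
    radii <- 0.5 * (0.5)^((scales - 1):0)  # e.g. 0.125, 0.25, 0.5 for 3 scales
    ## smooth rising step around each radius (raised cosine, width 0.6 r)
    step <- function(r) {
      w <- 0.6 * r
      t <- pmin(pmax((rho - (r - w / 2)) / w, 0), 1)
      sin(pi * t / 2)^2
    }
    d <- lapply(radii, step)
    rad <- vector("list", scales + 1)
    rad[[1]] <- 1 - d[[1]]
    if (scales >= 2) for (j in 2:scales) rad[[j]] <- d[[j - 1]] - d[[j]]
    rad[[scales + 1]] <- d[[scales]]
    ## periodic hat functions over theta in [0, pi): exact partition of unity
    centers <- (seq_len(wedges) - 1) * pi / wedges
    hat <- lapply(centers, function(tc) {
      dd <- abs(((theta - tc + pi / 2) %% pi) - pi / 2)
      pmax(0, 1 - dd * wedges / pi)
    })
    wins <- list(rad[[1]])
    for (j in 2:(scales + 1)) {
      for (w in seq_len(wedges)) wins[[length(wins) + 1]] <- rad[[j]] * hat[[w]]
    }
    wins
  })
}

fftdir2 <- function(x, scales = 3, wedges = 8) {
  n <- nrow(x)
  wins <- fftdir_windows(n, scales, wedges)
  Fx <- stats::fft(x)
  lapply(wins, function(U) Re(stats::fft(Fx * U, inverse = TRUE)) / (n * n))
}

ifftdir2 <- function(bands) {
  Reduce(`+`, bands)
}
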