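## Texture-matrix feature families (GLCM, GLRLM, GLSZM, GLDM, NGTDM),
## computed on a discretized gray-level image restricted to a lesion mask.
## Conventions: 2D single-slice matrices; GLCM/GLRLM use the 4 planar
## directions; GLSZM zones and GLDM/NGTDM neighbourhoods are 8-connected.
## Degenerate (single-gray-level) regions are defined by their limits; no
## NaN is ever returned.

EPS <- 2.2e-16

## levels matrix: integer gray levels 1..Ng inside mask, NA outside
glcm_features <- function(lv, Ng) {
  offs <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  per_angle <- lapply(offs, function(off) {
    P <- glcm_matrix(lv, Ng, off)
    if (sum(P) == 0) return(NULL)
    glcm_features_one(P / sum(P), Ng)
  })
  per_angle <- per_angle[!vapply(per_angle, is.null, logical(1))]
  if (!length(per_angle)) per_angle <- list(glcm_features_one(diag(1, 1), 1))
  Reduce(`+`, per_angle) / length(per_angle)
}

glcm_matrix <- function(lv, Ng, off) {
  n <- nrow(lv); m <- ncol(lv)
  r1 <- seq_len(n - abs(off[1]))
  if (off[1] > 0) r2 <- r1 + off[1] else r2 <- r1
  c1 <- if (off[2] >= 0) seq_len(m - off[2]) else seq(1 - off[2], m)
  c2 <- c1 + off[2]
  a <- lv[r1, c1]; b <- lv[r2, c2]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(matrix(0, Ng, Ng))
  counts <- tabulate((a[ok] - 1) * Ng + b[ok], Ng * Ng)
  P <- matrix(counts, Ng, Ng, byrow = TRUE)
  P + t(P)  # symmetric co-occurrences
}

glcm_features_one <- function(p, Ng) {
  i <- matrix(seq_len(Ng), Ng, Ng)
  j <- t(i)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(seq_len(Ng) * px); muy <- sum(seq_len(Ng) * py)
  sx <- sqrt(sum((seq_len(Ng) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(Ng) - muy)^2 * py))
  ## diagonal / cross-diagonal distributions
  pxy_sum <- tapply(as.vector(p), as.vector(i + j), sum)         # k = 2..2Ng
  k_sum <- as.numeric(names(pxy_sum))
  pxy_dif <- tapply(as.vector(p), as.vector(abs(i - j)), sum)    # k = 0..Ng-1
  k_dif <- as.numeric(names(pxy_dif))
  nz <- p > 0
  HX <- -sum(px[px > 0] * log2(px[px > 0]))
  HY <- -sum(py[py > 0] * log2(py[py > 0]))
  HXY <- -sum(p[nz] * log2(p[nz]))
  pxpy <- outer(px, py)
  okk <- pxpy > 0
  HXY1 <- -sum(p[okk] * log2(pxpy[okk]))
  HXY2 <- -sum(pxpy[okk] * log2(pxpy[okk]))
  da <- sum(k_dif * pxy_dif)
  corr <- if (sx * sy > EPS) (sum(i * j * p) - mux * muy) / (sx * sy) else 1
  imc1 <- if (max(HX, HY) > EPS) (HXY - HXY1) / max(HX, HY) else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (HXY2 - HXY))))
  off_diag <- abs(i - j) > 0
  mcc <- glcm_mcc(p, px)
  c(Autocorrelation = sum(i * j * p),
    ClusterProminence = sum((i + j - mux - muy)^4 * p),
    ClusterShade = sum((i + j - mux - muy)^3 * p),
    ClusterTendency = sum((i + j - mux - muy)^2 * p),
    Contrast = sum((i - j)^2 * p),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pxy_dif[pxy_dif > 0] * log2(pxy_dif[pxy_dif > 0])),
    DifferenceVariance = sum((k_dif - da)^2 * pxy_dif),
    Id = sum(p / (1 + abs(i - j))),
    Idm = sum(p / (1 + (i - j)^2)),
    Idmn = sum(p / (1 + ((i - j) / Ng)^2)),
    Idn = sum(p / (1 + abs(i - j) / Ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum(p[off_diag] / (i - j)[off_diag]^2),
    JointAverage = mux,
    JointEnergy = sum(p^2),
    JointEntropy = HXY,
    MCC = mcc,
    MaximumProbability = max(p),
    SumAverage = sum(k_sum * pxy_sum),
    SumEntropy = -sum(pxy_sum[pxy_sum > 0] * log2(pxy_sum[pxy_sum > 0])),
    SumSquares = sum((i - mux)^2 * p))
}

## maximal correlation coefficient: sqrt of the second-largest eigenvalue of
## Q(i,j) = sum_k p(i,k) p(j,k) / (px(i) py(k)), over gray levels with mass
glcm_mcc <- function(p, px) {
  keep <- px > 0
  if (sum(keep) < 2) return(1)
  ps <- p[keep, keep, drop = FALSE]
  pxs <- rowSums(ps); pys <- colSums(ps)
  Q <- (ps / pxs) %*% t(ps / rep(pys, each = nrow(ps)))
  ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
  sqrt(pmax(0, ev[2]))
}

## ---- run length ------------------------------------------------------------

glrlm_features <- function(lv, Ng, Np) {
  n <- nrow(lv); m <- ncol(lv)
  rows_ <- split(as.vector(t(lv)), rep(seq_len(n), each = m))
  cols_ <- split(as.vector(lv), rep(seq_len(m), each = n))
  ri <- matrix(rep(seq_len(n), m), n); ci <- t(matrix(rep(seq_len(m), n), m))
  d1 <- split(as.vector(lv), as.vector(ri + ci))       # anti-diagonals
  d2 <- split(as.vector(lv), as.vector(ri - ci))       # diagonals
  per_dir <- lapply(list(rows_, cols_, d1, d2), function(lines) {
    P <- rlm_from_lines(lines, Ng)
    if (sum(P) == 0) return(NULL)
    rlm_features_one(P, Np)
  })
  per_dir <- per_dir[!vapply(per_dir, is.null, logical(1))]
  Reduce(`+`, per_dir) / length(per_dir)
}

rlm_from_lines <- function(lines, Ng) {
  gl <- integer(0); ln <- integer(0)
  for (v in lines) {
    r <- rle(ifelse(is.na(v), -1L, v))
    keep <- r$values > 0
    gl <- c(gl, r$values[keep]); ln <- c(ln, r$lengths[keep])
  }
  if (!length(gl)) return(matrix(0, Ng, 1))
  Nr <- max(ln)
  matrix(tabulate((gl - 1) * Nr + ln, Ng * Nr), Ng, Nr, byrow = TRUE)
}

rlm_features_one <- function(P, Np) {
  Nr <- sum(P)
  i <- seq_len(nrow(P)); j <- seq_len(ncol(P))
  Pi <- rowSums(P); Pj <- colSums(P)
  p <- P / Nr
  mu_i <- sum(i * rowSums(p)); mu_j <- sum(j * colSums(p))
  pnz <- p[p > 0]
  c(ShortRunEmphasis = sum(t(P) / j^2) / Nr,
    LongRunEmphasis = sum(t(P) * j^2) / Nr,
    GrayLevelNonUniformity = sum(Pi^2) / Nr,
    GrayLevelNonUniformityNormalized = sum(Pi^2) / Nr^2,
    RunLengthNonUniformity = sum(Pj^2) / Nr,
    RunLengthNonUniformityNormalized = sum(Pj^2) / Nr^2,
    RunPercentage = Nr / Np,
    GrayLevelVariance = sum(rowSums(p) * (i - mu_i)^2),
    RunVariance = sum(colSums(p) * (j - mu_j)^2),
    RunEntropy = -sum(pnz * log2(pnz)),
    LowGrayLevelRunEmphasis = sum(P / i^2) / Nr,
    HighGrayLevelRunEmphasis = sum(P * i^2) / Nr,
    ShortRunLowGrayLevelEmphasis = sum(P / outer(i^2, j^2)) / Nr,
    ShortRunHighGrayLevelEmphasis = sum(P * outer(i^2, 1 / j^2)) / Nr,
    LongRunLowGrayLevelEmphasis = sum(P * outer(1 / i^2, j^2)) / Nr,
    LongRunHighGrayLevelEmphasis = sum(P * outer(i^2, j^2)) / Nr)
}

## ---- size zone -------------------------------------------------------------

## 8-connected component sizes per gray level (BFS flood fill)
zone_sizes <- function(lv, Ng) {
  n <- nrow(lv); m <- ncol(lv)
  res_gl <- integer(0); res_sz <- integer(0)
  visited <- matrix(FALSE, n, m)
  for (start in which(!is.na(lv))) {
    if (visited[start]) next
    g <- lv[start]
    stack <- start; visited[start] <- TRUE; size <- 0L
    while (length(stack)) {
      cur <- stack[length(stack)]; stack <- stack[-length(stack)]
      size <- size + 1L
      rr <- (cur - 1L) %% n + 1L; cc <- (cur - 1L) %/% n + 1L
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- rr + dr; c2 <- cc + dc
        if (r2 >= 1 && r2 <= n && c2 >= 1 && c2 <= m) {
          id2 <- (c2 - 1L) * n + r2
          if (!visited[id2] && !is.na(lv[id2]) && lv[id2] == g) {
            visited[id2] <- TRUE
            stack <- c(stack, id2)
          }
        }
      }
    }
    res_gl <- c(res_gl, g); res_sz <- c(res_sz, size)
  }
  data.frame(gl = res_gl, size = res_sz)
}

glszm_features <- function(lv, Ng, Np) {
  z <- zone_sizes(lv, Ng)
  if (!nrow(z)) z <- data.frame(gl = 1L, size = 1L)
  Nz <- nrow(z)
  i <- z$gl; s <- z$size
  p_gl <- tabulate(i, Ng) / Nz
  Ns <- max(s)
  p_s <- tabulate(s, Ns) / Nz
  mu_i <- sum(seq_len(Ng) * p_gl); mu_s <- sum(seq_len(Ns) * p_s)
  Pi <- tabulate(i, Ng); Ps <- tabulate(s, Ns)
  pz <- table(paste(i, s)) / Nz
  c(SmallAreaEmphasis = mean(1 / s^2),
    LargeAreaEmphasis = mean(s^2),
    GrayLevelNonUniformity = sum(Pi^2) / Nz,
    GrayLevelNonUniformityNormalized = sum(Pi^2) / Nz^2,
    SizeZoneNonUniformity = sum(Ps^2) / Nz,
    SizeZoneNonUniformityNormalized = sum(Ps^2) / Nz^2,
    ZonePercentage = Nz / Np,
    GrayLevelVariance = sum(p_gl * (seq_len(Ng) - mu_i)^2),
    ZoneVariance = sum(p_s * (seq_len(Ns) - mu_s)^2),
    ZoneEntropy = -sum(pz * log2(pz)),
    LowGrayLevelZoneEmphasis = mean(1 / i^2),
    HighGrayLevelZoneEmphasis = mean(i^2),
    SmallAreaLowGrayLevelEmphasis = mean(1 / (i^2 * s^2)),
    SmallAreaHighGrayLevelEmphasis = mean(i^2 / s^2),
    LargeAreaLowGrayLevelEmphasis = mean(s^2 / i^2),
    LargeAreaHighGrayLevelEmphasis = mean(i^2 * s^2))
}

## ---- neighbour stacks for GLDM / NGTDM -------------------------------------

neighbour_stack <- function(lv) {
  n <- nrow(lv); m <- ncol(lv)
  pad <- matrix(NA_integer_, n + 2, m + 2)
  pad[2:(n + 1), 2:(m + 1)] <- lv
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
               c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  arr <- array(NA_integer_, c(n, m, 8))
  for (k in seq_along(offs)) {
    o <- offs[[k]]
    arr[, , k] <- pad[(2 + o[1]):(n + 1 + o[1]), (2 + o[2]):(m + 1 + o[2])]
  }
  arr
}

gldm_features <- function(lv, Ng, alpha = 0) {
  nb <- neighbour_stack(lv)
  inmask <- !is.na(lv)
  dep <- matrix(0L, nrow(lv), ncol(lv))
  for (k in 1:8) {
    d <- abs(nb[, , k] - lv) <= alpha
    d[is.na(d)] <- FALSE
    dep <- dep + d
  }
  i <- lv[inmask]; j <- dep[inmask] + 1L   # dependence size >= 1
  Nz <- length(i)
  Nd <- max(j)
  P <- matrix(tabulate((i - 1) * Nd + j, Ng * Nd), Ng, Nd, byrow = TRUE)
  p <- P / Nz
  ii <- seq_len(Ng); jj <- seq_len(Nd)
  mu_i <- sum(ii * rowSums(p)); mu_j <- sum(jj * colSums(p))
  pnz <- p[p > 0]
  c(SmallDependenceEmphasis = sum(t(P) / jj^2) / Nz,
    LargeDependenceEmphasis = sum(t(P) * jj^2) / Nz,
    GrayLevelNonUniformity = sum(rowSums(P)^2) / Nz,
    DependenceNonUniformity = sum(colSums(P)^2) / Nz,
    DependenceNonUniformityNormalized = sum(colSums(P)^2) / Nz^2,
    GrayLevelVariance = sum(rowSums(p) * (ii - mu_i)^2),
    DependenceVariance = sum(colSums(p) * (jj - mu_j)^2),
    DependenceEntropy = -sum(pnz * log2(pnz)),
    LowGrayLevelEmphasis = sum(P / ii^2) / Nz,
    HighGrayLevelEmphasis = sum(P * ii^2) / Nz,
    SmallDependenceLowGrayLevelEmphasis = sum(P / outer(ii^2, jj^2)) / Nz,
    SmallDependenceHighGrayLevelEmphasis = sum(P * outer(ii^2, 1 / jj^2)) / Nz,
    LargeDependenceLowGrayLevelEmphasis = sum(P * outer(1 / ii^2, jj^2)) / Nz,
    LargeDependenceHighGrayLevelEmphasis = sum(P * outer(ii^2, jj^2)) / Nz)
}

ngtdm_features <- function(lv, Ng) {
  nb <- neighbour_stack(lv)
  inmask <- !is.na(lv)
  ssum <- matrix(0, nrow(lv), ncol(lv))
  cnt <- matrix(0L, nrow(lv), ncol(lv))
  for (k in 1:8) {
    v <- nb[, , k]
    ok <- !is.na(v)
    ssum[ok] <- ssum[ok] + v[ok]
    cnt <- cnt + ok
  }
  has_nb <- inmask & cnt > 0
  i <- lv[has_nb]
  abar <- ssum[has_nb] / cnt[has_nb]
  Np <- length(i)
  n_i <- tabulate(i, Ng)
  s_i <- vapply(seq_len(Ng), function(g) sum(abs(g - abar[i == g])), numeric(1))
  p_i <- n_i / Np
  present <- which(p_i > 0)
  Ngp <- length(present)
  ps <- sum(p_i * s_i)
  G <- outer(present, present, `-`)^2
  PP <- outer(p_i[present], p_i[present])
  contrast <- if (Ngp > 1) sum(PP * G) / (Ngp * (Ngp - 1)) * sum(s_i) / Np else 0
  ipn <- present * p_i[present]
  busy_den <- sum(abs(outer(ipn, ipn, `-`)))
  busyness <- if (busy_den > EPS) ps / busy_den else 0
  cm <- 0; st <- 0
  for (a in present) for (b in present) {
    cm <- cm + abs(a - b) * (p_i[a] * s_i[a] + p_i[b] * s_i[b]) / (p_i[a] + p_i[b])
    st <- st + (p_i[a] + p_i[b]) * (a - b)^2
  }
  c(Coarseness = if (ps > EPS) min(1 / ps, 1e6) else 1e6,
    Contrast = contrast,
    Busyness = busyness,
    Complexity = cm / Np,
    Strength = if (sum(s_i) > EPS) st / sum(s_i) else 0)
}
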