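## Convolutional autoencoder for per-flavor deep features.
## Encoder: conv(16, 3x3, stride 2) 60->30, conv(32, 3x3) 30->30,
## maxpool(2x2) 30->15, conv(32, 3x3) 15->15  => bottleneck 32 x 15 x 15.
## Decoder: tconv(16, 3x3, stride 2) 15->30, tconv(8, 3x3, stride 2) 30->60,
## conv(1, 3x3) + sigmoid => 60 x 60.
## ReLU on all hidden layers; objective J = 1/2 * sum (y_decoded - x)^2,
## minimized by Adam on exact hand-derived gradients (verified against
## numerical differentiation in the test suite).

## im2col index table: rows = output pixels, cols = 9 kernel taps; values are
## linear indices into the zero-padded (hi+2) x (wi+2) input plane.
conv_idx <- function(hi, wi, stride) {
  ho <- (hi + 2 - 3) %/% stride + 1
  wo <- (wi + 2 - 3) %/% stride + 1
  key <- sprintf("cidx_%d_%d_%d", hi, wi, stride)
  idx <- cached(key, function() {
    hp <- hi + 2
    out <- matrix(0L, ho * wo, 9)
    k <- 0L
    for (dc in 0:2) {
      for (dr in 0:2) {
        k <- k + 1L
        r <- rep(seq(1, by = stride, length.out = ho) + dr, wo)
        cc <- rep(seq(1, by = stride, length.out = wo) + dc, each = ho)
        out[, k] <- (cc - 1L) * hp + r
      }
    }
    out
  })
  list(idx = idx, ho = ho, wo = wo)
}

pad_zero1 <- function(x) {
  # x: (h, w, c); zero border of 1
  h <- dim(x)[1]; w <- dim(x)[2]; ci <- dim(x)[3]
  out <- array(0, c(h + 2, w + 2, ci))
  out[2:(h + 1), 2:(w + 1), ] <- x
  out
}

## forward conv for one image; returns list(out, col) for backprop
conv_fwd <- function(x, W, b, stride) {
  d <- dim(x)
  ci <- d[3]
  cx <- conv_idx(d[1], d[2], stride)
  P <- pad_zero1(x)
  dim(P) <- c((d[1] + 2) * (d[2] + 2), ci)
  col <- P[as.vector(cx$idx), , drop = FALSE]      # (npix*9, ci)
  dim(col) <- c(nrow(cx$idx), 9 * ci)
  out <- col %*% W + rep(b, each = nrow(col))      # (npix, co)
  dim(out) <- c(cx$ho, cx$wo, length(b))
  list(out = out, col = col, cx = cx, din = d)
}

conv_bwd <- function(fw, W, dout) {
  co <- dim(dout)[3]
  npix <- dim(dout)[1] * dim(dout)[2]
  dim(dout) <- c(npix, co)
  dW <- crossprod(fw$col, dout)
  db <- colSums(dout)
  dcol <- dout %*% t(W)                            # (npix, 9*ci)
  d <- fw$din
  ci <- d[3]
  dP <- matrix(0, (d[1] + 2) * (d[2] + 2), ci)
  dim(dcol) <- c(npix, 9, ci)
  for (k in 1:9) {
    dP[fw$cx$idx[, k], ] <- dP[fw$cx$idx[, k], ] + dcol[, k, ]
  }
  dim(dP) <- c(d[1] + 2, d[2] + 2, ci)
  list(dW = dW, db = db,
       dx = dP[2:(d[1] + 1), 2:(d[2] + 1), , drop = FALSE])
}

## zero-stuffing upsample x2 (input at odd indices), the expansion half of a
## stride-2 transposed convolution
upsample2 <- function(x) {
  d <- dim(x)
  out <- array(0, c(2 * d[1], 2 * d[2], d[3]))
  out[seq(1, 2 * d[1], 2), seq(1, 2 * d[2], 2), ] <- x
  out
}

downsample2 <- function(x) {
  d <- dim(x)
  x[seq(1, d[1], 2), seq(1, d[2], 2), , drop = FALSE]
}

maxpool_fwd <- function(x) {
  d <- dim(x)
  ho <- d[1] / 2; wo <- d[2] / 2
  x4 <- array(0, c(ho, wo, d[3], 4))
  x4[, , , 1] <- x[seq(1, d[1], 2), seq(1, d[2], 2), , drop = FALSE]
  x4[, , , 2] <- x[seq(2, d[1], 2), seq(1, d[2], 2), , drop = FALSE]
  x4[, , , 3] <- x[seq(1, d[1], 2), seq(2, d[2], 2), , drop = FALSE]
  x4[, , , 4] <- x[seq(2, d[1], 2), seq(2, d[2], 2), , drop = FALSE]
  m <- pmax(x4[, , , 1], x4[, , , 2], x4[, , , 3], x4[, , , 4])
  list(out = m, x4 = x4, din = d)
}

maxpool_bwd <- function(fw, dout) {
  d <- fw$din
  dx <- array(0, d)
  m <- fw$out
  taken <- array(FALSE, dim(m))
  slots <- list(c(1, 1), c(2, 1), c(1, 2), c(2, 2))
  for (s in 1:4) {
    is_max <- (fw$x4[, , , s] == m) & !taken
    taken <- taken | is_max
    o <- slots[[s]]
    dx[seq(o[1], d[1], 2), seq(o[2], d[2], 2), ] <-
      dx[seq(o[1], d[1], 2), seq(o[2], d[2], 2), ] + dout * is_max
  }
  dx
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

ae_layer_specs <- function() {
  list(
    conv1 = list(kin = 1, kout = 16, stride = 2),
    conv2 = list(kin = 16, kout = 32, stride = 1),
    conv3 = list(kin = 32, kout = 32, stride = 1),
    tconv1 = list(kin = 32, kout = 16, stride = 1),  # after upsample2
    tconv2 = list(kin = 16, kout = 8, stride = 1),
    convout = list(kin = 8, kout = 1, stride = 1)
  )
}

#' Initialize the convolutional autoencoder
#'
#' Architecture contract (asserted at construction): encoder bottleneck
#' 32 x 15 x 15 (flattens to 7200), decoder output 60 x 60 in (0, 1).
#'
#' @param seed integer; identical seeds give identical parameters.
#' @return an `ae_model`.
#' @export
init_autoencoder <- function(seed = 1L) {
  specs <- ae_layer_specs()
  pars <- withr::with_seed(seed, {
    lapply(specs, function(s) {
      fan_in <- 9 * s$kin
      list(W = matrix(stats::rnorm(fan_in * s$kout, sd = sqrt(2 / fan_in)),
                      fan_in, s$kout),
           b = rep(0, s$kout))
    })
  })
  model <- structure(list(pars = pars, seed = seed), class = "ae_model")
  bd <- dim(ae_encode_raw(model, matrix(0, 60, 60)))
  stopifnot(identical(bd, c(15L, 15L, 32L)))
  stopifnot(identical(dim(ae_forward(model, matrix(0, 60, 60))$y), c(60L, 60L, 1L)))
  model
}

#' @export
print.ae_model <- function(x, ...) {
  np <- sum(vapply(x$pars, function(p) length(p$W) + length(p$b), numeric(1)))
  cat(sprintf("<ae_model> conv autoencoder, %d parameters (seed %d)\n",
              np, x$seed))
  invisible(x)
}

as_image_array <- function(image) {
  m <- as_pixel_matrix(image)
  if (!all(dim(m) == c(60, 60))) stop("autoencoder input must be 60x60")
  array(m, c(60, 60, 1))
}

## full forward pass with cached intermediates
ae_forward <- function(model, image, keep = FALSE) {
  p <- model$pars
  x <- as_image_array(image)
  f1 <- conv_fwd(x, p$conv1$W, p$conv1$b, 2); a1 <- relu(f1$out)
  f2 <- conv_fwd(a1, p$conv2$W, p$conv2$b, 1); a2 <- relu(f2$out)
  mp <- maxpool_fwd(a2)
  f3 <- conv_fwd(mp$out, p$conv3$W, p$conv3$b, 1); a3 <- relu(f3$out)
  u1 <- upsample2(a3)
  f4 <- conv_fwd(u1, p$tconv1$W, p$tconv1$b, 1); a4 <- relu(f4$out)
  u2 <- upsample2(a4)
  f5 <- conv_fwd(u2, p$tconv2$W, p$tconv2$b, 1); a5 <- relu(f5$out)
  f6 <- conv_fwd(a5, p$convout$W, p$convout$b, 1)
  y <- 1 / (1 + exp(-f6$out))
  out <- list(y = y, bottleneck = a3)
  if (keep) {
    out <- c(out, list(x = x, f1 = f1, a1 = a1, f2 = f2, a2 = a2, mp = mp,
                       f3 = f3, a3 = a3, u1 = u1, f4 = f4, a4 = a4, u2 = u2,
                       f5 = f5, a5 = a5, f6 = f6))
  }
  out
}

ae_encode_raw <- function(model, image) {
  ae_forward(model, image)$bottleneck
}

## gradient of J for one image; returns per-layer dW/db and the loss
ae_backward <- function(model, image) {
  p <- model$pars
  fw <- ae_forward(model, image, keep = TRUE)
  y <- fw$y
  diff <- y - fw$x
  loss <- 0.5 * sum(diff^2)
  dz6 <- diff * y * (1 - y)
  g6 <- conv_bwd(fw$f6, p$convout$W, dz6)
  dz5 <- g6$dx * (fw$f5$out > 0)
  g5 <- conv_bwd(fw$f5, p$tconv2$W, dz5)
  ## g5$dx lives on the 60-grid; gradient w.r.t. a4 is its stuffed part
  dz4 <- downsample2(g5$dx) * (fw$f4$out > 0)
  g4 <- conv_bwd(fw$f4, p$tconv1$W, dz4)
  dz3 <- downsample2(g4$dx) * (fw$f3$out > 0)
  g3 <- conv_bwd(fw$f3, p$conv3$W, dz3)
  dmp <- maxpool_bwd(fw$mp, g3$dx)
  dz2 <- dmp * (fw$f2$out > 0)
  g2 <- conv_bwd(fw$f2, p$conv2$W, dz2)
  dz1 <- g2$dx * (fw$f1$out > 0)
  g1 <- conv_bwd(fw$f1, p$conv1$W, dz1)
  list(loss = loss,
       grads = list(conv1 = g1, conv2 = g2, conv3 = g3,
                    tconv1 = g4, tconv2 = g5, convout = g6))
}

#' Reconstruction objective J = 1/2 * sum (y_decoded - x)^2
#'
#' Summed over pixels and over the batch; nonnegative, zero iff the
#' reconstruction is exact.
#'
#' @param model an `ae_model`.
#' @param batch a 60x60 matrix, a list of them, or a 60x60xN array, values
#'   in `[0, 1]`.
#' @return scalar loss.
#' @export
reconstruction_loss <- function(model, batch) {
  imgs <- as_batch_list(batch)
  tot <- 0
  for (im in imgs) {
    if (min(im) < 0 || max(im) > 1) {
      stop("reconstruction_loss: inputs must lie in [0, 1]")
    }
    y <- ae_forward(model, im)$y
    tot <- tot + 0.5 * sum((y - array(im, c(60, 60, 1)))^2)
  }
  tot
}

as_batch_list <- function(batch) {
  if (is.list(batch)) {
    lapply(batch, as_pixel_matrix)
  } else if (length(dim(batch)) == 3) {
    lapply(seq_len(dim(batch)[3]), function(i) batch[, , i])
  } else {
    list(as_pixel_matrix(batch))
  }
}

adam_init <- function(pars) {
  lapply(pars, function(p) list(mW = p$W * 0, vW = p$W * 0,
                                mb = p$b * 0, vb = p$b * 0))
}

adam_step <- function(pars, state, grads, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(pars)) {
    g <- grads[[nm]]
    st <- state[[nm]]
    st$mW <- beta1 * st$mW + (1 - beta1) * g$dW
    st$vW <- beta2 * st$vW + (1 - beta2) * g$dW^2
    st$mb <- beta1 * st$mb + (1 - beta1) * g$db
    st$vb <- beta2 * st$vb + (1 - beta2) * g$db^2
    mhW <- st$mW / (1 - beta1^t); vhW <- st$vW / (1 - beta2^t)
    mhb <- st$mb / (1 - beta1^t); vhb <- st$vb / (1 - beta2^t)
    pars[[nm]]$W <- pars[[nm]]$W - lr * mhW / (sqrt(vhW) + eps)
    pars[[nm]]$b <- pars[[nm]]$b - lr * mhb / (sqrt(vhb) + eps)
    state[[nm]] <- st
  }
  list(pars = pars, state = state)
}

train_epochs <- function(model, imgs, epochs, lr, batch_size, seed,
                         val_imgs = NULL, patience = Inf) {
  state <- adam_init(model$pars)
  t <- 0
  n <- length(imgs)
  hist <- data.frame(epoch = integer(0), train = numeric(0), val = numeric(0))
  best_val <- Inf; bad <- 0
  withr::with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1, n, by = batch_size)) {
        ids <- ord[start:min(start + batch_size - 1, n)]
        acc <- NULL
        bl <- 0
        for (i in ids) {
          g <- ae_backward(model, imgs[[i]])
          bl <- bl + g$loss
          if (is.null(acc)) {
            acc <- g$grads
          } else {
            for (nm in names(acc)) {
              acc[[nm]]$dW <- acc[[nm]]$dW + g$grads[[nm]]$dW
              acc[[nm]]$db <- acc[[nm]]$db + g$grads[[nm]]$db
            }
          }
        }
        for (nm in names(acc)) {
          acc[[nm]]$dW <- acc[[nm]]$dW / length(ids)
          acc[[nm]]$db <- acc[[nm]]$db / length(ids)
        }
        t <- t + 1
        upd <- adam_step(model$pars, state, acc, lr, t)
        model$pars <- upd$pars
        state <- upd$state
        ep_loss <- ep_loss + bl
      }
      vl <- if (!is.null(val_imgs)) reconstruction_loss(model, val_imgs) else NA_real_
      hist <- rbind(hist, data.frame(epoch = ep, train = ep_loss, val = vl))
      if (!is.null(val_imgs)) {
        if (vl < best_val - 1e-9) {
          best_val <- vl; bad <- 0
        } else {
          bad <- bad + 1
          if (bad >= patience) break
        }
      }
    }
  })
  list(model = model, history = hist)
}

#' Train the autoencoder on a pooled flavor corpus
#'
#' Unsupervised: labels are never seen. Optional k-fold monitoring trains a
#' throwaway model per fold and records its validation objective per epoch
#' (with early-stopping patience 10); the returned model is always retrained
#' on all images.
#'
#' @param images list / 60x60xN array of images in `[0, 1]`.
#' @param k_folds monitoring folds (0 or 1 disables monitoring).
#' @param epochs training epochs (>= 1).
#' @param seed integer seed.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @return list with `model` (an `ae_model`) and `report` (fold histories,
#'   final training history, seed).
#' @export
train_autoencoder <- function(images, k_folds = 5, epochs = 30, seed = 1L,
                              lr = 1e-3, batch_size = 32) {
  if (epochs < 1) stop("epochs must be >= 1")
  imgs <- as_batch_list(images)
  for (im in imgs) {
    if (min(im) < 0 || max(im) > 1) stop("training images must lie in [0, 1]")
  }
  n <- length(imgs)
  if (k_folds > 1 && n < k_folds) stop("need at least k_folds images")
  folds_hist <- list()
  if (k_folds > 1) {
    assign_f <- withr::with_seed(derive_seed(seed, "aefolds"),
                                 sample(rep_len(seq_len(k_folds), n)))
    for (kf in seq_len(k_folds)) {
      m0 <- init_autoencoder(derive_seed(seed, "aeinit", kf))
      res <- train_epochs(m0, imgs[assign_f != kf], epochs, lr, batch_size,
                          seed = derive_seed(seed, "aetrain", kf),
                          val_imgs = imgs[assign_f == kf], patience = 10)
      folds_hist[[kf]] <- res$history
    }
  }
  final <- train_epochs(init_autoencoder(derive_seed(seed, "aeinit", 0)),
                        imgs, epochs, lr, batch_size,
                        seed = derive_seed(seed, "aetrain", 0))
  list(model = final$model,
       report = list(folds = folds_hist, final = final$history,
                     k_folds = k_folds, seed = seed))
}

#' Encode an image to its 7200-long deep feature vector
#'
#' Flattening order is channel-major: channel varies slowest, then row, then
#' column (names `ch<cc>_r<rr>_c<col>`). ReLU bottleneck, so all entries are
#' nonnegative.
#'
#' @param model an `ae_model`.
#' @param image 60x60 matrix or `roi_image`.
#' @return named numeric vector of length 7200.
#' @export
encode <- function(model, image) {
  bn <- ae_encode_raw(model, as_pixel_matrix(image))  # (15, 15, 32)
  v <- as.vector(aperm(bn, c(2, 1, 3)))               # col fastest, ch slowest
  names(v) <- deep_feature_names()
  v
}

deep_feature_names <- function() {
  cached("deepnames", function() {
    g <- expand.grid(col = 1:15, row = 1:15, ch = 1:32)
    sprintf("ch%02d_r%02d_c%02d", g$ch, g$row, g$col)
  })
}

#' Deep-feature matrix for a list of flavor stacks
#'
#' @param stacks list of `flavor_stack` objects.
#' @param model trained `ae_model`.
#' @return a `feature_matrix` (patients x 52*7200 = 374400), columns
#'   `<flavor_id>__<deep_feature>`, flavor-major order.
#' @export
deep_feature_matrix <- function(stacks, model) {
  fids <- flavor_ids()
  dn <- deep_feature_names()
  cn <- as.vector(vapply(fids, function(f) paste0(f, "__", dn),
                         character(length(dn))))
  X <- matrix(NA_real_, length(stacks), length(cn),
              dimnames = list(vapply(stacks, `[[`, "", "patient_id"), cn))
  labels <- integer(length(stacks))
  for (i in seq_along(stacks)) {
    st <- stacks[[i]]
    X[i, ] <- unlist(lapply(fids, function(fid) {
      unname(encode(model, st$flavors[[fid]]))
    }), use.names = FALSE)
    labels[i] <- st$grade_group
  }
  feature_matrix(X, labels,
                 provenance = data.frame(
                   column = cn,
                   flavor = rep(fids, each = length(dn)),
                   source = "deep"))
}
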