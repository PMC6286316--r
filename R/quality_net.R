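## ---------------------------------------------------------------------
## Fully convolutional quality-rating network.
##
## Architecture: six 3x3 convolutions with channel widths
## 32, 48, 48, 64, 64, 64, each followed by spatial batch normalization
## and an exponential-linear activation; 2x2 max pooling after every
## layer but the last, so the deepest path downsamples by 32. The head
## combines the activations of the last three layers (at downsampling
## factors 8, 16 and 32; the coarser maps are upsampled nearest-neighbor
## to the 1/8 grid) through a learned 1x1 linear combination and a
## sigmoid, yielding a score map in [0, 1]. The global score is the mean
## of the map over a foreground mask.
##
## All tensors are R arrays [batch, height, width, channels]; convolution
## is im2col + matrix product so the heavy lifting stays in BLAS.
## ---------------------------------------------------------------------

.qn_widths <- c(32L, 48L, 48L, 64L, 64L, 64L)

## zero padding of 1 pixel on both spatial axes
.pad1 <- function(A) {
  d <- dim(A)
  P <- array(0, c(d[1], d[2] + 2L, d[3] + 2L, d[4]))
  P[, 2L:(d[2] + 1L), 3L:(d[3] + 2L) - 1L, ] <- A
  P
}

## im2col for a 3x3 kernel: rows index (batch, y, x), column blocks index
## (offset dy, offset dx, input channel) in that order
.im2col3 <- function(A) {
  d <- dim(A)           # padded: N, H+2, W+2, C
  N <- d[1]; H <- d[2] - 2L; W <- d[3] - 2L; C <- d[4]
  out <- matrix(0, N * H * W, 9L * C)
  k <- 0L
  for (dx in 0:2) for (dy in 0:2) {
    slab <- A[, (1L + dy):(H + dy), (1L + dx):(W + dx), , drop = FALSE]
    dim(slab) <- c(N * H * W, C)
    out[, (k * C + 1L):((k + 1L) * C)] <- slab
    k <- k + 1L
  }
  out
}

## adjoint of .im2col3: accumulate column gradients back into the padded
## input array
.col2im3 <- function(G, N, H, W, C) {
  dP <- array(0, c(N, H + 2L, W + 2L, C))
  k <- 0L
  for (dx in 0:2) for (dy in 0:2) {
    g <- G[, (k * C + 1L):((k + 1L) * C), drop = FALSE]
    dim(g) <- c(N, H, W, C)
    dP[, (1L + dy):(H + dy), (1L + dx):(W + dx), ] <-
      dP[, (1L + dy):(H + dy), (1L + dx):(W + dx), , drop = FALSE] + g
    k <- k + 1L
  }
  dP[, 2L:(H + 1L), 2L:(W + 1L), , drop = FALSE]
}

.conv_forward <- function(A, Wmat) {
  d <- dim(A)
  P <- .pad1(A)
  M <- .im2col3(P)
  Z <- M %*% Wmat
  dim(Z) <- c(d[1], d[2], d[3], ncol(Wmat))
  list(Z = Z, M = M, in_dim = d)
}

.conv_backward <- function(cache, Wmat, dZ) {
  d <- cache$in_dim
  G <- dZ
  dim(G) <- c(d[1] * d[2] * d[3], dim(dZ)[4])
  dW <- crossprod(cache$M, G)
  dM <- tcrossprod(G, Wmat)
  dA <- .col2im3(dM, d[1], d[2], d[3], d[4])
  list(dW = dW, dA = dA)
}

.bn_forward <- function(Z, gamma, beta, running, train, eps = 1e-5,
                        momentum = 0.1) {
  d <- dim(Z)
  C <- d[4]
  Zm <- Z
  dim(Zm) <- c(prod(d[1:3]), C)
  if (train) {
    mu <- colMeans(Zm)
    xc <- sweep(Zm, 2, mu, "-")
    va <- colMeans(xc^2)
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * va
  } else {
    mu <- running$mean
    va <- running$var
    xc <- sweep(Zm, 2, mu, "-")
  }
  inv <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2, inv, "*")
  Y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  dim(Y) <- d
  list(Y = Y, xhat = xhat, inv = inv, dims = d, running = running)
}

.bn_backward <- function(cache, gamma, dY) {
  d <- cache$dims
  m <- prod(d[1:3])
  dYm <- dY
  dim(dYm) <- c(m, d[4])
  dgamma <- colSums(dYm * cache$xhat)
  dbeta <- colSums(dYm)
  dxhat <- sweep(dYm, 2, gamma, "*")
  t1 <- sweep(dxhat, 2, colMeans(dxhat), "-")
  t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), "*")
  dZ <- sweep(t1 - t2, 2, cache$inv, "*")
  dim(dZ) <- d
  list(dZ = dZ, dgamma = dgamma, dbeta = dbeta)
}

.elu_forward <- function(Z) {
  E <- Z
  neg <- Z < 0
  E[neg] <- exp(Z[neg]) - 1
  E
}

.elu_backward <- function(Z, E, dE) {
  d <- dE
  neg <- Z < 0
  d[neg] <- dE[neg] * (E[neg] + 1)
  d
}

.pool_forward <- function(A) {
  d <- dim(A)
  H2 <- d[2] %/% 2L; W2 <- d[3] %/% 2L
  i1 <- seq(1L, 2L * H2, 2L); i2 <- i1 + 1L
  j1 <- seq(1L, 2L * W2, 2L); j2 <- j1 + 1L
  s11 <- A[, i1, j1, , drop = FALSE]; s21 <- A[, i2, j1, , drop = FALSE]
  s12 <- A[, i1, j2, , drop = FALSE]; s22 <- A[, i2, j2, , drop = FALSE]
  out <- pmax(s11, s21, s12, s22)
  m11 <- s11 == out
  m21 <- (s21 == out) & !m11
  m12 <- (s12 == out) & !m11 & !m21
  m22 <- !(m11 | m21 | m12)
  list(Y = out, masks = list(m11, m21, m12, m22), in_dim = d)
}

.pool_backward <- function(cache, dY) {
  d <- cache$in_dim
  H2 <- dim(dY)[2]; W2 <- dim(dY)[3]
  i1 <- seq(1L, 2L * H2, 2L); i2 <- i1 + 1L
  j1 <- seq(1L, 2L * W2, 2L); j2 <- j1 + 1L
  dA <- array(0, d)
  dA[, i1, j1, ] <- dY * cache$masks[[1]]
  dA[, i2, j1, ] <- dY * cache$masks[[2]]
  dA[, i1, j2, ] <- dY * cache$masks[[3]]
  dA[, i2, j2, ] <- dY * cache$masks[[4]]
  dA
}

## nearest-neighbor upsample by integer factor f on axes 2 and 3
.upsample <- function(A, f) {
  d <- dim(A)
  A[, rep(seq_len(d[2]), each = f), rep(seq_len(d[3]), each = f), ,
    drop = FALSE]
}

## adjoint: sum gradient over each f x f block
.downsample_sum <- function(dA, f) {
  d <- dim(dA)
  H <- d[2] %/% f; W <- d[3] %/% f
  out <- array(0, c(d[1], H, W, d[4]))
  for (a in seq_len(f)) for (b in seq_len(f)) {
    out <- out + dA[, seq(a, by = f, length.out = H),
                    seq(b, by = f, length.out = W), , drop = FALSE]
  }
  out
}

#' Initialize a quality-rating network
#'
#' @param seed Optional integer seed for the weight initialization.
#' @return An object of class \code{quality_net} holding the convolution
#'   kernels (He initialization), batch-normalization parameters and the
#'   learned 1x1 head.
#' @export
quality_net <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  widths <- .qn_widths
  cin <- c(1L, widths[-length(widths)])
  layers <- vector("list", length(widths))
  for (l in seq_along(widths)) {
    fan_in <- 9L * cin[l]
    layers[[l]] <- list(
      W = matrix(stats::rnorm(fan_in * widths[l], 0, sqrt(2 / fan_in)),
                 fan_in, widths[l]),
      gamma = rep(1, widths[l]), beta = rep(0, widths[l]),
      running = list(mean = rep(0, widths[l]), var = rep(1, widths[l])))
  }
  nhead <- 3L * widths[length(widths)]
  structure(list(layers = layers,
                 head_W = matrix(stats::rnorm(nhead, 0, sqrt(1 / nhead)),
                                 nhead, 1),
                 head_b = 0,
                 whitening = list(mean = 0, sd = 1)),
            class = "quality_net")
}

## full forward pass over a batch array [N, H, W]; returns the score map
## [N, H/8, W/8] plus all caches when training
.qn_forward <- function(net, images, train = FALSE, keep = FALSE) {
  d <- dim(images)
  A <- array(images, c(d[1], d[2], d[3], 1L))
  caches <- list()
  taps <- list()
  for (l in seq_along(net$layers)) {
    ly <- net$layers[[l]]
    cv <- .conv_forward(A, ly$W)
    bn <- .bn_forward(cv$Z, ly$gamma, ly$beta, ly$running, train)
    if (train) net$layers[[l]]$running <- bn$running
    E <- .elu_forward(bn$Y)
    if (l >= 4L) taps[[length(taps) + 1L]] <- E
    if (l < length(net$layers)) {
      pl <- .pool_forward(E)
      A2 <- pl$Y
    } else pl <- NULL
    if (keep) caches[[l]] <- list(conv = cv, bn = bn, Z = bn$Y, E = E,
                                  pool = pl)
    if (l < length(net$layers)) A <- A2
  }
  ## taps: layer 4 (1/8 grid), layer 5 (1/16), layer 6 (1/32)
  H8 <- dim(taps[[1]])[2]; W8 <- dim(taps[[1]])[3]
  up5 <- .upsample(taps[[2]], 2L)
  up6 <- .upsample(taps[[3]], 4L)
  feats <- array(0, c(d[1], H8, W8, 3L * dim(taps[[1]])[4]))
  C <- dim(taps[[1]])[4]
  feats[, , , 1:C] <- taps[[1]]
  feats[, , , (C + 1L):(2L * C)] <- up5
  feats[, , , (2L * C + 1L):(3L * C)] <- up6
  Fm <- feats
  dim(Fm) <- c(d[1] * H8 * W8, 3L * C)
  S <- drop(Fm %*% net$head_W) + net$head_b
  map <- 1 / (1 + exp(-S))
  dim(map) <- c(d[1], H8, W8)
  out <- list(map = map, net = net)
  if (keep) {
    out$caches <- caches
    out$Fm <- Fm
    out$S <- S
    out$dims <- c(d[1], H8, W8, C)
  }
  out
}

## backward pass from dmap; returns gradients for every parameter
.qn_backward <- function(net, fwd, dmap) {
  dm <- fwd$dims
  N <- dm[1]; H8 <- dm[2]; W8 <- dm[3]; C <- dm[4]
  sig <- as.numeric(fwd$map)
  dS <- as.numeric(dmap) * sig * (1 - sig)
  dhead_W <- crossprod(fwd$Fm, dS)
  dhead_b <- sum(dS)
  dFm <- matrix(dS, ncol = 1) %*% t(net$head_W)
  dim(dFm) <- c(N, H8, W8, 3L * C)
  dtap4 <- dFm[, , , 1:C, drop = FALSE]
  dtap5 <- .downsample_sum(dFm[, , , (C + 1L):(2L * C), drop = FALSE], 2L)
  dtap6 <- .downsample_sum(dFm[, , , (2L * C + 1L):(3L * C),
                                drop = FALSE], 4L)
  dtaps <- list(dtap4, dtap5, dtap6)
  grads <- vector("list", length(net$layers))
  dA <- NULL
  for (l in rev(seq_along(net$layers))) {
    cc <- fwd$caches[[l]]
    dE <- if (l == length(net$layers)) dtaps[[3]]
          else {
            g <- .pool_backward(cc$pool, dA)
            if (l >= 4L) g <- g + dtaps[[l - 3L]]
            g
          }
    dZbn <- .elu_backward(cc$Z, cc$E, dE)
    bb <- .bn_backward(cc$bn, net$layers[[l]]$gamma, dZbn)
    cv <- .conv_backward(cc$conv, net$layers[[l]]$W, bb$dZ)
    grads[[l]] <- list(W = cv$dW, gamma = bb$dgamma, beta = bb$dbeta)
    dA <- cv$dA
  }
  list(layers = grads, head_W = dhead_W, head_b = dhead_b)
}

## learning rate halved at every 50th epoch: 0.002 up to epoch 49, 0.001
## from epoch 50, 0.0005 from epoch 100, ...
.qn_lr <- function(lr0, epoch) lr0 * 0.5^(epoch %/% 50L)

## crop both dims down to multiples of 32 (centered), error if < 32
.qn_prepare <- function(image) {
  d <- dim(image)
  if (any(d < 32L))
    stop("quality net requires image dimensions >= 32")
  h <- 32L * (d[1] %/% 32L); w <- 32L * (d[2] %/% 32L)
  r0 <- (d[1] - h) %/% 2L; c0 <- (d[2] - w) %/% 2L
  image[(r0 + 1L):(r0 + h), (c0 + 1L):(c0 + w), drop = FALSE]
}

#' Score map of an image under a quality network
#'
#' Whitens the image with the network's stored training statistics and
#' runs the forward pass in inference mode (stored batch-normalization
#' statistics). Images are center-cropped to multiples of 32 pixels; a
#' H x W input yields a H/8 x W/8 score map in [0, 1].
#'
#' @param image Numeric matrix, both dimensions >= 32.
#' @param net A \code{quality_net}.
#' @return Numeric matrix: the score map.
#' @export
quality_forward <- function(image, net) {
  stopifnot(inherits(net, "quality_net"), is.matrix(image))
  img <- .qn_prepare(image)
  img <- (img - net$whitening$mean) / net$whitening$sd
  batch <- array(img, c(1L, dim(img)))
  fwd <- .qn_forward(net, batch, train = FALSE)
  map <- fwd$map[1, , ]
  matrix(map, dim(fwd$map)[2], dim(fwd$map)[3])
}

#' Masked global quality score
#'
#' Mean of the score map over the foreground cells of the mask. With
#' \code{mask = NULL} the mask is the Otsu foreground of \code{image},
#' resized nearest-neighbor to the map grid and binarized (non-zero cells
#' become foreground). An empty mask yields an undefined-value sentinel:
#' scores over areas without content are not meaningful.
#'
#' @param map Score-map matrix.
#' @param mask Logical/numeric matrix at the map grid, or NULL.
#' @param image Original image, needed when \code{mask} is NULL.
#' @return Scalar score in [0, 1] or an undefined-value sentinel.
#' @export
masked_global_score <- function(map, mask = NULL, image = NULL) {
  if (is.null(mask)) {
    if (is.null(image)) stop("need a mask or the original image")
    fg <- otsu_foreground(.qn_prepare(image))
    mask <- resize_mask(fg, dim(map))
  }
  if (!identical(dim(mask), dim(map)))
    stop("mask and map shapes must match")
  m <- mask != 0
  if (!any(m)) return(undefined_value("empty foreground mask"))
  mean(map[m])
}

#' Nearest-neighbor resize of a mask to a target grid, then binarize
#'
#' @param mask Logical or numeric matrix.
#' @param target_dim Integer vector (rows, cols).
#' @return Logical matrix of the target size (non-zero source -> TRUE).
#' @export
resize_mask <- function(mask, target_dim) {
  src <- dim(mask)
  ri <- pmin(floor((seq_len(target_dim[1]) - 0.5) / target_dim[1] *
                     src[1]) + 1L, src[1])
  ci <- pmin(floor((seq_len(target_dim[2]) - 0.5) / target_dim[2] *
                     src[2]) + 1L, src[2])
  (mask[ri, ci, drop = FALSE] != 0)
}

#' Train the quality network
#'
#' Inputs are whitened by the training-set mean and standard deviation;
#' optional augmentation applies random 90-degree rotations, reflections
#' and intensity scaling per epoch. The loss is the root mean squared
#' error between the masked global scores and the expert targets; the
#' adaptive-moment optimizer runs with learning rate 0.002 (halved every
#' 50 epochs) and moment decays 0.9/0.999, mini-batch size 96. When a
#' validation set is supplied the weights with the best validation RMSE
#' are returned, otherwise the final weights.
#'
#' @param images List of numeric matrices (all the same size, multiples
#'   of 32).
#' @param scores Numeric targets in [0, 1], one per image.
#' @param net A \code{quality_net} (e.g. freshly initialized with a seed).
#' @param epochs Number of epochs (default 200).
#' @param lr Initial learning rate (default 0.002).
#' @param batch_size Mini-batch size (default 96).
#' @param augment Apply data augmentation (default TRUE; disable for
#'   memorization checks).
#' @param validation Optional list(images =, scores =).
#' @return The trained \code{quality_net}, with attribute
#'   \code{train_rmse} (trace of the training RMSE per epoch).
#' @export
train_quality <- function(images, scores, net = quality_net(),
                          epochs = 200L, lr = 0.002, batch_size = 96L,
                          augment = TRUE, validation = NULL) {
  stopifnot(length(images) == length(scores), length(images) > 0,
            all(scores >= 0 & scores <= 1))
  imgs <- lapply(images, .qn_prepare)
  allpix <- unlist(lapply(imgs, as.numeric))
  mu <- mean(allpix); sdv <- stats::sd(allpix)
  if (!is.finite(sdv) || sdv == 0) sdv <- 1
  net$whitening <- list(mean = mu, sd = sdv)
  white <- lapply(imgs, function(im) (im - mu) / sdv)
  masks <- lapply(imgs, function(im) {
    fg <- otsu_foreground(im)
    resize_mask(fg, dim(im) %/% 8L)
  })
  n <- length(white)
  ## Adam state over all parameters, kept as flat parallel lists
  par_get <- function(net) {
    c(lapply(net$layers, function(l) l[c("W", "gamma", "beta")]),
      list(head = list(W = net$head_W, b = net$head_b)))
  }
  zero_like <- function(p) rapply(p, function(x) x * 0, how = "replace")
  mstate <- zero_like(par_get(net)); vstate <- zero_like(par_get(net))
  tstep <- 0L
  rmse_trace <- numeric(epochs)
  best <- NULL
  batch_forward <- function(net, idx, imgs_list, train) {
    batch <- array(0, c(length(idx), dim(imgs_list[[1]])))
    for (k in seq_along(idx)) batch[k, , ] <- imgs_list[[idx[k]]]
    .qn_forward(net, batch, train = train, keep = train)
  }
  global_scores <- function(map, idx, mask_list) {
    vapply(seq_along(idx), function(k) {
      m <- mask_list[[idx[k]]]
      if (!any(m)) return(mean(map[k, , ]))
      mean(map[k, , ][m])
    }, numeric(1))
  }
  for (epoch in seq_len(epochs)) {
    lr_e <- .qn_lr(lr, epoch)
    ep_imgs <- white
    ep_masks <- masks
    if (augment) {
      for (k in seq_len(n)) {
        im <- ep_imgs[[k]]; mk <- ep_masks[[k]]
        r <- sample.int(4L, 1L) - 1L
        if (r > 0 && nrow(im) == ncol(im)) {
          for (q in seq_len(r)) {
            im <- t(im[nrow(im):1, , drop = FALSE])
            mk <- t(mk[nrow(mk):1, , drop = FALSE])
          }
        }
        if (stats::runif(1) < 0.5) {
          im <- im[nrow(im):1, , drop = FALSE]
          mk <- mk[nrow(mk):1, , drop = FALSE]
        }
        im <- im * stats::runif(1, 0.9, 1.1)
        ep_imgs[[k]] <- im; ep_masks[[k]] <- mk
      }
    }
    ord <- sample.int(n)
    ep_err2 <- 0
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      fwd <- batch_forward(net, idx, ep_imgs, train = TRUE)
      net <- fwd$net   # updated running statistics
      g <- global_scores(fwd$map, idx, ep_masks)
      err <- g - scores[idx]
      if (any(!is.finite(err))) stop("training loss diverged (non-finite)")
      rmse <- sqrt(mean(err^2))
      ep_err2 <- ep_err2 + sum(err^2)
      ## dRMSE/dg = err / (B * rmse)
      dmap <- array(0, dim(fwd$map))
      for (k in seq_along(idx)) {
        m <- ep_masks[[idx[k]]]
        w <- if (any(m)) m / sum(m) else 1 / length(fwd$map[k, , ])
        dmap[k, , ] <- (err[k] / (length(idx) * max(rmse, 1e-8))) * w
      }
      gr <- .qn_backward(net, fwd, dmap)
      grads <- c(gr$layers, list(head = list(W = gr$head_W, b = gr$head_b)))
      tstep <- tstep + 1L
      for (li in seq_along(grads)) {
        for (nm in names(grads[[li]])) {
          gmat <- grads[[li]][[nm]]
          mstate[[li]][[nm]] <- 0.9 * mstate[[li]][[nm]] + 0.1 * gmat
          vstate[[li]][[nm]] <- 0.999 * vstate[[li]][[nm]] + 0.001 * gmat^2
          mh <- mstate[[li]][[nm]] / (1 - 0.9^tstep)
          vh <- vstate[[li]][[nm]] / (1 - 0.999^tstep)
          step <- lr_e * mh / (sqrt(vh) + 1e-8)
          if (li <= length(net$layers)) {
            net$layers[[li]][[nm]] <- net$layers[[li]][[nm]] - step
          } else if (nm == "W") {
            net$head_W <- net$head_W - step
          } else {
            net$head_b <- net$head_b - as.numeric(step)
          }
        }
      }
    }
    rmse_trace[epoch] <- sqrt(ep_err2 / n)
    if (!is.null(validation)) {
      vg <- vapply(seq_along(validation$images), function(k) {
        map <- quality_forward(validation$images[[k]], net)
        s <- masked_global_score(map, image = validation$images[[k]])
        if (is.na(s)) mean(map) else as.numeric(s)
      }, numeric(1))
      vrmse <- sqrt(mean((vg - validation$scores)^2))
      if (is.null(best) || vrmse < best$rmse)
        best <- list(net = net, rmse = vrmse)
    }
  }
  out <- if (!is.null(best)) best$net else net
  attr(out, "train_rmse") <- rmse_trace
  out
}
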