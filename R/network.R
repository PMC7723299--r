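# Dual-decoder U-Net contract: a single shared encoder connected to two
# decoder paths, one per output map (cell distance, neighbor distance).
# Downsampling uses strided 3x3 convolutions instead of max pooling, every
# hidden convolution is followed by batch normalization and a rectified
# linear unit, both output heads are linear single-channel 1x1
# convolutions, and zero padding keeps feature-map sizes consistent for
# the skip concatenations. The implementation is plain R (im2col + GEMM)
# with full backpropagation and an Adam optimizer, so the contract is
# trainable at desk scale without any external framework.

#' Network architecture specification
#'
#' @param base_feature_maps feature maps at the first encoder level
#'   (doubled per level). Default 64.
#' @param max_feature_maps cap on feature maps at the deepest level.
#'   Default 1024.
#' @param depth number of resolution levels. Default 5 (64 -> 1024).
#' @param in_channels input image channels.
#' @return object of class `network_spec`.
#' @export
network_spec <- function(base_feature_maps = 64, max_feature_maps = 1024,
                         depth = 5, in_channels = 1) {
  if (depth < 1) stop("depth must be >= 1")
  if (base_feature_maps * 2^(depth - 1) > max_feature_maps) {
    stop("inconsistent spec: base_feature_maps * 2^(depth-1) exceeds ",
         "max_feature_maps")
  }
  structure(list(base_feature_maps = base_feature_maps,
                 max_feature_maps = max_feature_maps, depth = depth,
                 in_channels = in_channels),
            class = "network_spec")
}

#' Training configuration
#'
#' Batch size, Adam learning-rate schedule with plateau-based decay and
#' early stopping, and augmentation probabilities (applied in the listed
#' order: flip, scale, rotate, contrast, blur, noise).
#'
#' @param batch_size samples per gradient step.
#' @param lr_init,lr_factor,lr_min initial learning rate, plateau decay
#'   factor, and floor.
#' @param plateau_patience epochs without validation improvement before
#'   the learning rate is decayed.
#' @param early_stop_patience epochs without improvement before training
#'   stops.
#' @param max_epochs hard epoch cap.
#' @param p_flip,p_scale,p_rotate,p_contrast,p_blur,p_noise augmentation
#'   probabilities.
#' @param scale_range,rotate_range,contrast_range,blur_sigma_max,noise_sd_max
#'   augmentation magnitudes.
#' @return object of class `training_config`.
#' @export
training_config <- function(batch_size = 8, lr_init = 8e-4,
                            lr_factor = 0.25, lr_min = 6e-5,
                            plateau_patience = 12, early_stop_patience = 28,
                            max_epochs = 200,
                            p_flip = 0.75, p_scale = 0.3, p_rotate = 0.3,
                            p_contrast = 0.3, p_blur = 0.3, p_noise = 0.3,
                            scale_range = c(0.85, 1.15),
                            rotate_range = c(-45, 45),
                            contrast_range = c(0.7, 1.3),
                            blur_sigma_max = 1.5, noise_sd_max = 0.05) {
  p <- c(p_flip, p_scale, p_rotate, p_contrast, p_blur, p_noise)
  stopifnot(all(p >= 0), all(p <= 1), lr_min < lr_init)
  structure(list(batch_size = batch_size, lr_init = lr_init,
                 lr_factor = lr_factor, lr_min = lr_min,
                 plateau_patience = plateau_patience,
                 early_stop_patience = early_stop_patience,
                 max_epochs = max_epochs, p_flip = p_flip, p_scale = p_scale,
                 p_rotate = p_rotate, p_contrast = p_contrast,
                 p_blur = p_blur, p_noise = p_noise,
                 scale_range = scale_range, rotate_range = rotate_range,
                 contrast_range = contrast_range,
                 blur_sigma_max = blur_sigma_max,
                 noise_sd_max = noise_sd_max),
            class = "training_config")
}

# ---- low-level ops (arrays are [H, W, C, N]) ---------------------------

conv_param <- function(k, cin, cout) {
  sd <- sqrt(2 / (k * k * cin))
  list(W = matrix(rnorm(k * k * cin * cout, sd = sd), k * k * cin, cout),
       b = numeric(cout), k = k, cin = cin, cout = cout)
}

bn_param <- function(c) {
  list(gamma = rep(1, c), beta = numeric(c),
       run_mean = numeric(c), run_var = rep(1, c))
}

pad_hw <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
  out
}

# gather offsets for im2col: row base (one per output position x sample)
# and column base (one per kernel tap x channel), both 0-based into the
# padded array
im2col_bases <- function(dp, k, stride) {
  Hp <- dp[1]; Wp <- dp[2]; C <- dp[3]; N <- dp[4]
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  i_off <- (seq_len(Ho) - 1L) * stride
  j_off <- (seq_len(Wo) - 1L) * stride
  rbase <- rep(i_off, times = Wo * N) +
    rep(rep(j_off, each = Ho), times = N) * Hp +
    rep(seq_len(N) - 1L, each = Ho * Wo) * (Hp * Wp * C)
  cbase <- rep(seq_len(k), times = k * C) +
    rep(rep(seq_len(k) - 1L, each = k), times = C) * Hp +
    rep(seq_len(C) - 1L, each = k * k) * (Hp * Wp)
  list(rbase = rbase, cbase = cbase, Ho = Ho, Wo = Wo)
}

conv_forward <- function(x, prm, stride = 1) {
  k <- prm$k
  p <- if (k == 3) 1L else 0L
  xp <- pad_hw(x, p)
  dp <- dim(xp)
  ib <- im2col_bases(dp, k, stride)
  J <- length(ib$cbase)
  col <- matrix(0, length(ib$rbase), J)
  for (j in seq_len(J)) col[, j] <- xp[ib$rbase + ib$cbase[j]]
  out <- col %*% prm$W
  out <- sweep(out, 2, prm$b, `+`)
  N <- dp[4]
  o <- array(out, c(ib$Ho, ib$Wo, N, prm$cout))
  list(out = aperm(o, c(1, 2, 4, 3)),
       cache = list(col = col, ib = ib, dp = dp, p = p, stride = stride,
                    xdim = dim(x)))
}

conv_backward <- function(dout, prm, cache) {
  dm <- aperm(dout, c(1, 2, 4, 3))
  doutm <- matrix(dm, ncol = prm$cout)
  dW <- crossprod(cache$col, doutm)
  db <- colSums(doutm)
  dcol <- doutm %*% t(prm$W)
  dxp <- numeric(prod(cache$dp))
  ib <- cache$ib
  for (j in seq_along(ib$cbase)) {
    ii <- ib$rbase + ib$cbase[j]
    dxp[ii] <- dxp[ii] + dcol[, j]
  }
  dim(dxp) <- cache$dp
  p <- cache$p
  dx <- if (p > 0) {
    d <- cache$xdim
    dxp[p + seq_len(d[1]), p + seq_len(d[2]), , , drop = FALSE]
  } else dxp
  dim(dx) <- cache$xdim
  list(dx = dx, dW = dW, db = db)
}

bn_forward <- function(x, prm, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  m <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
  if (training) {
    mu <- colMeans(m)
    va <- colMeans(m^2) - mu^2
    prm$run_mean <- (1 - momentum) * prm$run_mean + momentum * mu
    prm$run_var <- (1 - momentum) * prm$run_var + momentum * va
  } else {
    mu <- prm$run_mean
    va <- prm$run_var
  }
  ivar <- 1 / sqrt(va + eps)
  xn <- sweep(sweep(m, 2, mu), 2, ivar, `*`)
  out <- sweep(sweep(xn, 2, prm$gamma, `*`), 2, prm$beta, `+`)
  o <- aperm(array(out, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(out = o, prm = prm,
       cache = list(xn = xn, ivar = ivar, d = d, training = training))
}

bn_backward <- function(dout, prm, cache) {
  d <- cache$d
  dm <- matrix(aperm(dout, c(1, 2, 4, 3)), ncol = d[3])
  dgamma <- colSums(dm * cache$xn)
  dbeta <- colSums(dm)
  n <- nrow(dm)
  if (cache$training) {
    t1 <- sweep(dm, 2, dbeta / n)
    t2 <- sweep(cache$xn, 2, dgamma / n, `*`)
    dxn <- sweep(t1 - t2, 2, prm$gamma * cache$ivar, `*`)
  } else {
    dxn <- sweep(dm, 2, prm$gamma * cache$ivar, `*`)
  }
  dx <- aperm(array(dxn, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
    drop = FALSE]
}

upsample2_backward <- function(dout) {
  d <- dim(dout)
  ri <- seq(1, d[1], by = 2)
  ci <- seq(1, d[2], by = 2)
  dout[ri, ci, , , drop = FALSE] + dout[ri + 1, ci, , , drop = FALSE] +
    dout[ri, ci + 1, , , drop = FALSE] + dout[ri + 1, ci + 1, , , drop = FALSE]
}

# ---- network -----------------------------------------------------------

#' Build a dual-decoder distance-prediction network
#'
#' Constructs the shared-encoder/two-decoder architecture with freshly
#' initialized (untrained) weights. The returned object is callable
#' through [net_predict()] / `predict()` and trainable with
#' [train_distance_net()].
#'
#' @param spec a [network_spec()].
#' @param seed optional seed for weight initialization.
#' @return an environment of class `distance_net`.
#' @export
build_network <- function(spec = network_spec(), seed = NULL) {
  stopifnot(inherits(spec, "network_spec"))
  build <- function() {
    f <- pmin(spec$base_feature_maps * 2^(seq_len(spec$depth) - 1),
              spec$max_feature_maps)
    par <- list()
    cin <- spec$in_channels
    for (l in seq_len(spec$depth)) {
      par[[paste0("enc", l)]] <- conv_param(3, cin, f[l])
      par[[paste0("enc", l, ".bn")]] <- bn_param(f[l])
      if (l < spec$depth) {
        par[[paste0("down", l)]] <- conv_param(3, f[l], f[l + 1])
        par[[paste0("down", l, ".bn")]] <- bn_param(f[l + 1])
        cin <- f[l + 1]
      }
    }
    for (h in 1:2) {
      for (l in seq_len(spec$depth - 1)) {
        par[[paste0("h", h, ".up", l)]] <- conv_param(3, f[l + 1], f[l])
        par[[paste0("h", h, ".up", l, ".bn")]] <- bn_param(f[l])
        par[[paste0("h", h, ".mix", l)]] <- conv_param(3, 2 * f[l], f[l])
        par[[paste0("h", h, ".mix", l, ".bn")]] <- bn_param(f[l])
      }
      par[[paste0("h", h, ".out")]] <- conv_param(1, f[1], 1)
    }
    par
  }
  par <- if (is.null(seed)) build() else with_seed(seed, build())
  net <- new.env(parent = emptyenv())
  net$spec <- spec
  net$par <- par
  net$adam <- NULL
  class(net) <- "distance_net"
  net
}

net_pad_size <- function(spec, hw) {
  m <- 2^(spec$depth - 1)
  as.integer(ceiling(hw / m) * m)
}

# Full forward pass. Returns both head outputs plus a tape of caches for
# backpropagation when `training = TRUE`.
net_forward <- function(net, x, training = FALSE) {
  spec <- net$spec
  par <- net$par
  tape <- list()
  run_conv <- function(x, name, stride = 1) {
    r <- conv_forward(x, par[[name]], stride)
    tape[[length(tape) + 1]] <<- list(op = "conv", name = name,
                                      cache = r$cache)
    r$out
  }
  run_bn <- function(x, name) {
    r <- bn_forward(x, par[[name]], training)
    net$par[[name]] <- r$prm   # running stats
    par[[name]] <<- r$prm
    tape[[length(tape) + 1]] <<- list(op = "bn", name = name,
                                      cache = r$cache)
    r$out
  }
  run_relu <- function(x) {
    tape[[length(tape) + 1]] <<- list(op = "relu", cache = x > 0)
    x * (x > 0)
  }
  enc <- list()
  for (l in seq_len(spec$depth)) {
    x <- run_relu(run_bn(run_conv(x, paste0("enc", l)), paste0("enc", l, ".bn")))
    enc[[l]] <- x
    if (l < spec$depth) {
      x <- run_relu(run_bn(run_conv(x, paste0("down", l), stride = 2),
                           paste0("down", l, ".bn")))
    }
  }
  tape[[length(tape) + 1]] <- list(op = "enc_done", depth = spec$depth)
  heads <- vector("list", 2)
  for (h in 1:2) {
    y <- enc[[spec$depth]]
    tape[[length(tape) + 1]] <- list(op = "head_start", h = h)
    if (spec$depth > 1) {
      for (l in rev(seq_len(spec$depth - 1))) {
        y <- upsample2(y)
        tape[[length(tape) + 1]] <- list(op = "up")
        y <- run_relu(run_bn(run_conv(y, paste0("h", h, ".up", l)),
                             paste0("h", h, ".up", l, ".bn")))
        nskip <- dim(enc[[l]])[3]
        y2 <- array(0, dim(y) + c(0, 0, nskip, 0))
        y2[, , seq_len(dim(y)[3]), ] <- y
        y2[, , dim(y)[3] + seq_len(nskip), ] <- enc[[l]]
        tape[[length(tape) + 1]] <- list(op = "concat", l = l,
                                         nown = dim(y)[3], nskip = nskip)
        y <- y2
        y <- run_relu(run_bn(run_conv(y, paste0("h", h, ".mix", l)),
                             paste0("h", h, ".mix", l, ".bn")))
      }
    }
    heads[[h]] <- run_conv(y, paste0("h", h, ".out"))
    tape[[length(tape) + 1]] <- list(op = "head_end", h = h)
  }
  list(cell = heads[[1]], neighbor = heads[[2]], tape = tape)
}

# Backward pass over the tape; returns gradients keyed like net$par.
net_backward <- function(net, fwd, dcell, dneighbor) {
  par <- net$par
  grads <- list()
  add_grad <- function(name, field, g) {
    key <- paste0(name, "#", field)
    grads[[key]] <<- if (is.null(grads[[key]])) g else grads[[key]] + g
  }
  tape <- fwd$tape
  i <- length(tape)
  dskip <- list()  # gradient accumulated into encoder activations
  dy <- NULL
  denc <- NULL
  while (i >= 1) {
    e <- tape[[i]]
    if (e$op == "head_end") {
      dy <- if (e$h == 1) dcell else dneighbor
    } else if (e$op == "head_start") {
      # decoder head consumed enc[[depth]] as its input
      depth <- net$spec$depth
      key <- as.character(depth)
      dskip[[key]] <- if (is.null(dskip[[key]])) dy else dskip[[key]] + dy
      dy <- NULL
    } else if (e$op == "conv") {
      r <- conv_backward(dy, par[[e$name]], e$cache)
      add_grad(e$name, "W", r$dW)
      add_grad(e$name, "b", r$db)
      dy <- r$dx
    } else if (e$op == "bn") {
      r <- bn_backward(dy, par[[e$name]], e$cache)
      add_grad(e$name, "gamma", r$dgamma)
      add_grad(e$name, "beta", r$dbeta)
      dy <- r$dx
    } else if (e$op == "relu") {
      dy <- dy * e$cache
    } else if (e$op == "up") {
      dy <- upsample2_backward(dy)
    } else if (e$op == "concat") {
      key <- as.character(e$l)
      dsk <- dy[, , e$nown + seq_len(e$nskip), , drop = FALSE]
      dskip[[key]] <- if (is.null(dskip[[key]])) dsk else dskip[[key]] + dsk
      dy <- dy[, , seq_len(e$nown), , drop = FALSE]
    } else if (e$op == "enc_done") {
      # continue backward through the encoder. Each skip activation
      # enc[[l]] feeds both the decoders (gradient collected in dskip)
      # and, for l < depth, the downsampling conv: its gradient is added
      # right after backpropagating through that conv.
      j <- i - 1
      depth <- net$spec$depth
      dcur <- dskip[[as.character(depth)]]
      while (j >= 1) {
        ee <- tape[[j]]
        if (ee$op == "relu") {
          dcur <- dcur * ee$cache
        } else if (ee$op == "bn") {
          r <- bn_backward(dcur, par[[ee$name]], ee$cache)
          add_grad(ee$name, "gamma", r$dgamma)
          add_grad(ee$name, "beta", r$dbeta)
          dcur <- r$dx
        } else if (ee$op == "conv") {
          r <- conv_backward(dcur, par[[ee$name]], ee$cache)
          add_grad(ee$name, "W", r$dW)
          add_grad(ee$name, "b", r$db)
          dcur <- r$dx
          if (grepl("^down", ee$name)) {
            l <- as.integer(sub("^down", "", ee$name))
            dsk <- dskip[[as.character(l)]]
            if (!is.null(dsk)) dcur <- dcur + dsk
          }
        }
        j <- j - 1
      }
      break
    }
    i <- i - 1
  }
  grads
}

#' Predict distance maps for one image
#'
#' Zero-pads the input so its spatial size is divisible by the network
#' stride, runs the forward pass in inference mode, and crops both outputs
#' back to the input size.
#'
#' @param net a `distance_net` from [build_network()].
#' @param image numeric matrix (a single frame).
#' @return list with numeric matrices `cell` and `neighbor`.
#' @export
net_predict <- function(net, image) {
  d <- dim(image)
  H <- net_pad_size(net$spec, d[1])
  W <- net_pad_size(net$spec, d[2])
  x <- array(0, c(H, W, net$spec$in_channels, 1))
  x[seq_len(d[1]), seq_len(d[2]), 1, 1] <- image
  fwd <- net_forward(net, x, training = FALSE)
  list(cell = fwd$cell[seq_len(d[1]), seq_len(d[2]), 1, 1],
       neighbor = fwd$neighbor[seq_len(d[1]), seq_len(d[2]), 1, 1])
}

#' @export
predict.distance_net <- function(object, newdata, ...) {
  net_predict(object, newdata)
}

#' @export
print.distance_net <- function(x, ...) {
  s <- x$spec
  cat("Dual-decoder distance-prediction network\n")
  cat(sprintf("  depth %d, feature maps %d..%d, shared encoder, 2 heads\n",
              s$depth, s$base_feature_maps,
              min(s$base_feature_maps * 2^(s$depth - 1), s$max_feature_maps)))
  cat(sprintf("  parameters: %d tensors\n", length(x$par)))
  invisible(x)
}

#' Smooth-L1 distance loss
#'
#' Huber loss with unit transition and mean reduction on each head,
#' summed over the two heads.
#'
#' @param pred,target lists with `cell` and `neighbor` arrays of equal
#'   shape.
#' @return scalar loss.
#' @export
distance_loss <- function(pred, target) {
  one <- function(p, t) {
    if (!identical(dim(p), dim(t))) stop("prediction/target shape mismatch")
    e <- abs(p - t)
    mean(ifelse(e <= 1, 0.5 * e^2, e - 0.5))
  }
  one(pred$cell, target$cell) + one(pred$neighbor, target$neighbor)
}

smooth_l1_grad <- function(p, t) {
  e <- p - t
  pmax(pmin(e, 1), -1) / length(e)
}

#' Plateau learning-rate schedule with early stopping
#'
#' Replays a validation-loss history: after `plateau_patience` consecutive
#' epochs without improvement the learning rate is multiplied by
#' `lr_factor` (floored at `lr_min`) and the plateau counter resets;
#' training stops after `early_stop_patience` consecutive epochs without
#' improvement or when `max_epochs` is reached.
#'
#' @param history numeric vector of validation losses (one per epoch).
#' @param cfg a [training_config()].
#' @return list with `lr`, `stop`, and the number of decay `cycles`.
#' @export
plateau_schedule <- function(history, cfg = training_config()) {
  if (!length(history)) stop("history must be non-empty")
  best <- Inf
  stale_lr <- 0L
  stale_stop <- 0L
  cycles <- 0L
  for (loss in history) {
    if (loss < best) {
      best <- loss
      stale_lr <- 0L
      stale_stop <- 0L
    } else {
      stale_lr <- stale_lr + 1L
      stale_stop <- stale_stop + 1L
    }
    if (stale_lr >= cfg$plateau_patience) {
      cycles <- cycles + 1L
      stale_lr <- 0L
    }
  }
  lr <- max(cfg$lr_init * cfg$lr_factor^cycles, cfg$lr_min)
  stop <- stale_stop >= cfg$early_stop_patience ||
    length(history) >= cfg$max_epochs
  list(lr = lr, stop = stop, cycles = cycles)
}

#' Min-max normalization for inference
#'
#' Maps the input range to \[-1, 1\]. A list of 2D frames is normalized
#' per frame; a 3D array is normalized once over the whole volume.
#' Constant inputs map to all zeros.
#'
#' @param x numeric matrix, 3D array, or list of matrices.
#' @return normalized data of the same structure.
#' @export
normalize_for_inference <- function(x) {
  norm1 <- function(v) {
    r <- range(v)
    if (r[1] == r[2]) return(array(0, dim(v)))
    2 * (v - r[1]) / (r[2] - r[1]) - 1
  }
  if (is.list(x)) lapply(x, norm1) else norm1(x)
}

# ---- augmentation ------------------------------------------------------

flip_array <- function(x, axis) {
  d <- dim(x)
  idx <- rep(list(quote(expr = )), length(d))
  idx[[axis]] <- rev(seq_len(d[axis]))
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

# Bilinear affine resample (same output size): rotation by `angle`
# (degrees) and isotropic `scale` about the image center; edge clamp.
affine_resample <- function(x, scale = 1, angle = 0) {
  d <- dim(x)
  th <- angle * pi / 180
  ctr <- (d + 1) / 2
  r <- matrix(seq_len(d[1]), d[1], d[2]) - ctr[1]
  c <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE) - ctr[2]
  sr <- (cos(th) * r + sin(th) * c) / scale + ctr[1]
  sc <- (-sin(th) * r + cos(th) * c) / scale + ctr[2]
  sr <- pmax(1, pmin(d[1], sr))
  sc <- pmax(1, pmin(d[2], sc))
  r0 <- floor(sr); c0 <- floor(sc)
  r1 <- pmin(r0 + 1, d[1]); c1 <- pmin(c0 + 1, d[2])
  fr <- sr - r0; fc <- sc - c0
  g <- function(ri, ci) x[cbind(as.vector(ri), as.vector(ci))]
  v <- g(r0, c0) * (1 - fr) * (1 - fc) + g(r1, c0) * fr * (1 - fc) +
    g(r0, c1) * (1 - fr) * fc + g(r1, c1) * fr * fc
  array(v, d)
}

#' Augment a training sample
#'
#' Applies, in order and with the configured probabilities: flipping
#' (each axis with half the flip probability once flipping fires),
#' scaling, rotation, contrast change, blur, and additive noise.
#' Geometric transforms are applied identically to the image and both
#' target maps; photometric transforms to the image only. Deterministic
#' for a given seed.
#'
#' @param sample list with `image`, `cell`, `neighbor` matrices.
#' @param cfg a [training_config()].
#' @param seed integer seed.
#' @return augmented sample.
#' @export
augment_sample <- function(sample, cfg = training_config(), seed = NULL) {
  run <- function() {
    geom <- function(f) {
      sample$image <<- f(sample$image)
      sample$cell <<- f(sample$cell)
      sample$neighbor <<- f(sample$neighbor)
    }
    if (runif(1) < cfg$p_flip) {
      if (runif(1) < 0.5) geom(function(x) flip_array(x, 1))
      if (runif(1) < 0.5) geom(function(x) flip_array(x, 2))
    }
    if (runif(1) < cfg$p_scale) {
      s <- runif(1, cfg$scale_range[1], cfg$scale_range[2])
      geom(function(x) affine_resample(x, scale = s))
    }
    if (runif(1) < cfg$p_rotate) {
      a <- runif(1, cfg$rotate_range[1], cfg$rotate_range[2])
      geom(function(x) affine_resample(x, angle = a))
    }
    if (runif(1) < cfg$p_contrast) {
      gain <- runif(1, cfg$contrast_range[1], cfg$contrast_range[2])
      m <- mean(sample$image)
      sample$image <- (sample$image - m) * gain + m
    }
    if (runif(1) < cfg$p_blur) {
      s <- runif(1, 0, cfg$blur_sigma_max)
      if (s > 0.01) sample$image <- gaussian_smooth(sample$image, s)
    }
    if (runif(1) < cfg$p_noise) {
      s <- runif(1, 0, cfg$noise_sd_max)
      sample$image <- sample$image + rnorm(length(sample$image), sd = s)
    }
    sample
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# ---- training ----------------------------------------------------------

adam_step <- function(net, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  if (is.null(net$adam)) net$adam <- list(t = 0, m = list(), v = list())
  st <- net$adam
  st$t <- st$t + 1
  for (key in names(grads)) {
    parts <- strsplit(key, "#", fixed = TRUE)[[1]]
    name <- parts[1]; field <- parts[2]
    g <- grads[[key]]
    m <- st$m[[key]]; v <- st$v[[key]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    st$m[[key]] <- m; st$v[[key]] <- v
    mh <- m / (1 - beta1^st$t)
    vh <- v / (1 - beta2^st$t)
    net$par[[name]][[field]] <- net$par[[name]][[field]] -
      lr * mh / (sqrt(vh) + eps)
  }
  net$adam <- st
  invisible(net)
}

stack_batch <- function(samples, field) {
  d <- dim(samples[[1]][[field]])
  array(unlist(lapply(samples, `[[`, field)), c(d[1], d[2], 1, length(samples)))
}

#' Train a distance-prediction network
#'
#' Minibatch Adam training of the summed smooth-L1 loss on both heads,
#' with the plateau learning-rate schedule and early stopping of
#' [plateau_schedule()]. Inputs are expected already normalized (see
#' [normalize_for_inference()]); image sizes must be divisible by the
#' network stride.
#'
#' @param net a `distance_net`.
#' @param samples list of training samples `list(image, cell, neighbor)`.
#' @param val_samples held-out samples used for the schedule.
#' @param cfg a [training_config()].
#' @param epochs optional cap overriding `cfg$max_epochs`.
#' @param seed seed controlling shuffling and augmentation.
#' @param augment apply [augment_sample()] to each training sample.
#' @return list with per-epoch `train_loss` and `val_loss` histories.
#' @export
train_distance_net <- function(net, samples, val_samples,
                               cfg = training_config(), epochs = NULL,
                               seed = 1, augment = FALSE) {
  max_ep <- if (is.null(epochs)) cfg$max_epochs else epochs
  val_x <- stack_batch(val_samples, "image")
  val_t <- list(cell = stack_batch(val_samples, "cell"),
                neighbor = stack_batch(val_samples, "neighbor"))
  val_hist <- numeric(0)
  train_hist <- numeric(0)
  lr <- cfg$lr_init
  with_seed(seed, {
    for (ep in seq_len(max_ep)) {
      ord <- sample(length(samples))
      ep_loss <- 0
      nb <- 0
      for (start in seq(1, length(ord), by = cfg$batch_size)) {
        idx <- ord[seq(start, min(start + cfg$batch_size - 1, length(ord)))]
        batch <- samples[idx]
        if (augment) {
          batch <- lapply(batch, function(s)
            augment_sample(s, cfg, seed = sample.int(2^30, 1)))
        }
        x <- stack_batch(batch, "image")
        tg <- list(cell = stack_batch(batch, "cell"),
                   neighbor = stack_batch(batch, "neighbor"))
        fwd <- net_forward(net, x, training = TRUE)
        loss <- distance_loss(list(cell = fwd$cell, neighbor = fwd$neighbor),
                              tg)
        grads <- net_backward(net, fwd,
                              smooth_l1_grad(fwd$cell, tg$cell),
                              smooth_l1_grad(fwd$neighbor, tg$neighbor))
        adam_step(net, grads, lr)
        ep_loss <- ep_loss + loss
        nb <- nb + 1
      }
      train_hist <- c(train_hist, ep_loss / nb)
      vf <- net_forward(net, val_x, training = FALSE)
      val_hist <- c(val_hist,
                    distance_loss(list(cell = vf$cell, neighbor = vf$neighbor),
                                  val_t))
      sch <- plateau_schedule(val_hist, cfg)
      lr <- sch$lr
      if (sch$stop) break
    }
  })
  list(train_loss = train_hist, val_loss = val_hist)
}
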