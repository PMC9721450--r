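#' Convolutional classifier configuration
#'
#' The full-scale configuration mirrors a standard ResNet-34 training recipe
#' (256 x 256 inputs, binary cross-entropy, SGD with momentum 0.9, learning
#' rate 0.001, weight decay 1e-5, a 0.1 learning-rate drop after a 10-epoch
#' validation plateau, 100 epochs, batch 64, flip augmentation). Training a
#' full ResNet-34 needs a GPU deep-learning backend and is documented
#' configuration only; the trainable `"tiny"` architecture — two 3 x 3
#' convolution/ReLU/mean-pool stages, global average pooling and a sigmoid
#' head — keeps the identical training-loop contract at desk scale.
#'
#' @param architecture `"tiny"` or `"resnet34"`
#' @param input_size square input side in pixels
#' @param filters channels of the two tiny conv stages
#' @param lr initial learning rate
#' @param momentum SGD momentum
#' @param weight_decay L2 weight decay
#' @param lr_drop_factor learning-rate multiplier on plateau
#' @param plateau_patience epochs without improvement before the drop
#' @param epochs training epochs
#' @param batch_size minibatch size (reduced with a warning if the dataset is
#'   smaller)
#' @param augment_flips random horizontal/vertical flips during training
#' @param pretrained use pretrained weights (resnet34 documentation only)
#' @param seed RNG seed for initialization and shuffling
#' @return an object of class `cnn_config`
#' @export
cnn_config <- function(architecture = c("resnet34", "tiny"), input_size = 256,
                       filters = c(8, 16), lr = 0.001, momentum = 0.9,
                       weight_decay = 1e-5, lr_drop_factor = 0.1,
                       plateau_patience = 10, epochs = 100, batch_size = 64,
                       augment_flips = TRUE, pretrained = FALSE, seed = 1) {
  architecture <- match.arg(architecture)
  stopifnot(input_size >= 8, input_size %% 4 == 0, lr > 0, momentum >= 0,
            weight_decay >= 0, lr_drop_factor > 0, plateau_patience >= 1,
            epochs >= 1, batch_size >= 1, all(filters >= 1))
  structure(list(architecture = architecture, input_size = as.integer(input_size),
                 filters = as.integer(filters), lr = lr, momentum = momentum,
                 weight_decay = weight_decay, lr_drop_factor = lr_drop_factor,
                 plateau_patience = plateau_patience, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 augment_flips = isTRUE(augment_flips),
                 pretrained = isTRUE(pretrained), seed = as.integer(seed)),
            class = "cnn_config")
}

#' Desk-scale preset of [cnn_config()]
#'
#' 32 x 32 inputs, batch 16 and learning rate 0.05 — small enough to overfit
#' a handful of phantom crops on one CPU while keeping the training loop of
#' the full recipe.
#'
#' @param ... overrides passed to [cnn_config()]
#' @export
tiny_cnn_config <- function(...) {
  args <- list(architecture = "tiny", input_size = 32, lr = 0.05,
               batch_size = 16, ...)
  do.call(cnn_config, args[!duplicated(names(args), fromLast = TRUE)])
}

# ---- minimal conv net plumbing (im2col convolutions, 3x3, zero padding) ----

im2col3 <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  xp <- array(0, c(H + 2, W + 2, C))
  xp[2:(H + 1), 2:(W + 1), ] <- x
  cols <- matrix(0, H * W, 9 * C)
  t <- 0L
  for (ch in seq_len(C)) for (dc in 0:2) for (dr in 0:2) {
    t <- t + 1L
    cols[, t] <- as.vector(xp[dr + seq_len(H), dc + seq_len(W), ch])
  }
  cols
}

col2im3 <- function(dcols, H, W, C) {
  dxp <- array(0, c(H + 2, W + 2, C))
  t <- 0L
  for (ch in seq_len(C)) for (dc in 0:2) for (dr in 0:2) {
    t <- t + 1L
    dxp[dr + seq_len(H), dc + seq_len(W), ch] <-
      dxp[dr + seq_len(H), dc + seq_len(W), ch] + matrix(dcols[, t], H, W)
  }
  dxp[2:(H + 1), 2:(W + 1), , drop = FALSE]
}

meanpool2 <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  (x[seq(1, H, 2), seq(1, W, 2), , drop = FALSE] +
     x[seq(2, H, 2), seq(1, W, 2), , drop = FALSE] +
     x[seq(1, H, 2), seq(2, W, 2), , drop = FALSE] +
     x[seq(2, H, 2), seq(2, W, 2), , drop = FALSE]) / 4
}

meanpool2_back <- function(dy) {
  H <- dim(dy)[1] * 2L; W <- dim(dy)[2] * 2L; C <- dim(dy)[3]
  dx <- array(0, c(H, W, C))
  g <- dy / 4
  dx[seq(1, H, 2), seq(1, W, 2), ] <- g
  dx[seq(2, H, 2), seq(1, W, 2), ] <- g
  dx[seq(1, H, 2), seq(2, W, 2), ] <- g
  dx[seq(2, H, 2), seq(2, W, 2), ] <- g
  dx
}

tiny_init <- function(config) {
  f <- config$filters
  he <- function(fan_in, n) stats::rnorm(n, 0, sqrt(2 / fan_in))
  list(W1 = matrix(he(9, 9 * f[1]), 9, f[1]),
       b1 = rep(0, f[1]),
       W2 = matrix(he(9 * f[1], 9 * f[1] * f[2]), 9 * f[1], f[2]),
       b2 = rep(0, f[2]),
       w = rep(0, f[2]),
       b = 0)
}

tiny_forward <- function(params, x) {
  H <- dim(x)[1]; W <- dim(x)[2]
  c1 <- im2col3(array(x, c(H, W, 1)))
  a1 <- sweep(c1 %*% params$W1, 2, params$b1, `+`)
  r1 <- pmax(a1, 0)
  p1 <- meanpool2(array(r1, c(H, W, ncol(params$W1))))
  H2 <- dim(p1)[1]; W2 <- dim(p1)[2]
  c2 <- im2col3(p1)
  a2 <- sweep(c2 %*% params$W2, 2, params$b2, `+`)
  r2 <- pmax(a2, 0)
  p2 <- meanpool2(array(r2, c(H2, W2, ncol(params$W2))))
  f <- apply(p2, 3, mean)
  list(c1 = c1, a1 = a1, p1 = p1, c2 = c2, a2 = a2, p2 = p2, f = f,
       dims = c(H, W, H2, W2))
}

# gradient of the loss w.r.t. the convolutional parameters, given the
# gradient w.r.t. the pooled feature vector
tiny_backward_conv <- function(params, fw, dfeat) {
  H <- fw$dims[1]; W <- fw$dims[2]; H2 <- fw$dims[3]; W2 <- fw$dims[4]
  K2 <- ncol(params$W2); K1 <- ncol(params$W1)
  np2 <- (H2 / 2) * (W2 / 2)
  dp2 <- array(rep(dfeat / np2, each = np2), c(H2 / 2, W2 / 2, K2))
  dr2 <- meanpool2_back(dp2)
  da2 <- matrix(dr2, H2 * W2, K2) * (fw$a2 > 0)
  dW2 <- crossprod(fw$c2, da2)
  db2 <- colSums(da2)
  dc2 <- da2 %*% t(params$W2)
  dp1 <- col2im3(dc2, H2, W2, K1)
  dr1 <- meanpool2_back(dp1)
  da1 <- matrix(dr1, H * W, K1) * (fw$a1 > 0)
  dW1 <- crossprod(fw$c1, da1)
  db1 <- colSums(da1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
}

# mean binary cross-entropy and full parameter gradient over one minibatch.
# Pooled features pass through batch normalization (batch statistics when the
# batch has >= 2 images, the supplied running statistics otherwise), the
# standard stabilizer of this architecture family; the backward pass
# differentiates through the batch statistics.
tiny_batch_grad <- function(params, xs, ys, running = NULL) {
  nb <- length(xs)
  fws <- lapply(xs, function(x) tiny_forward(params, x))
  F <- do.call(rbind, lapply(fws, `[[`, "f"))
  K <- ncol(F)
  use_batch_stats <- nb >= 2
  if (use_batch_stats) {
    mu <- colMeans(F)
    v <- colMeans(sweep(F, 2, mu)^2)
    sdv <- sqrt(v + 1e-5)
  } else {
    mu <- running$mu; sdv <- running$sd
  }
  FZ <- sweep(sweep(F, 2, mu), 2, sdv, `/`)
  logits <- as.numeric(FZ %*% params$w) + params$b
  p <- 1 / (1 + exp(-logits))
  pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  loss <- -mean(ys * log(pc) + (1 - ys) * log(1 - pc))
  dlogit <- (p - ys) / nb
  dw <- as.numeric(crossprod(FZ, dlogit))
  db <- sum(dlogit)
  dFZ <- tcrossprod(dlogit, params$w)
  dF <- if (use_batch_stats) {
    sweep(dFZ - matrix(colMeans(dFZ), nb, K, byrow = TRUE) -
            FZ * matrix(colMeans(dFZ * FZ), nb, K, byrow = TRUE),
          2, sdv, `/`)
  } else sweep(dFZ, 2, sdv, `/`)
  grads <- list(W1 = 0, b1 = 0, W2 = 0, b2 = 0)
  for (i in seq_len(nb)) {
    g <- tiny_backward_conv(params, fws[[i]], dF[i, ])
    grads <- Map(`+`, grads, g)
  }
  grads$w <- dw
  grads$b <- db
  list(loss = loss, grads = grads[names(params)], probs = p,
       mu = mu, sd = sdv)
}

flip_image <- function(x, h, v) {
  if (h) x <- x[, rev(seq_len(ncol(x)))]
  if (v) x <- x[rev(seq_len(nrow(x))), ]
  x
}

#' Train the reduced-scale convolutional classifier
#'
#' Minibatch SGD with momentum, weight decay, random flip augmentation and a
#' plateau learning-rate schedule (monitored on validation loss when a
#' validation set is given, training loss otherwise). Inputs must already be
#' prepared crops (see [cnn_prepare_crops()]): square matrices of side
#' `config$input_size`, normalized to mean 0 / sd 1.
#'
#' @param images list of input matrices
#' @param labels benign/malignant or 0/1 vector
#' @param config a [cnn_config()] with `architecture = "tiny"`
#' @param val_images,val_labels optional validation set for the scheduler
#' @return an object of class `tiny_cnn`: `params`, `config`, `history`
#'   (per-epoch loss and learning rate) and `train_accuracy` on the clean
#'   training images
#' @export
cnn_train <- function(images, labels, config = tiny_cnn_config(),
                      val_images = NULL, val_labels = NULL) {
  if (config$architecture != "tiny")
    stop("only the 'tiny' architecture is trainable here; the full ResNet-34 ",
         "recipe is a documented configuration requiring a GPU deep-learning ",
         "backend", call. = FALSE)
  y <- label_to_binary(labels)
  n <- length(images)
  stopifnot(n == length(y), n >= 1)
  batch <- config$batch_size
  if (batch > n) {
    warning(sprintf("batch size %d reduced to dataset size %d", batch, n),
            call. = FALSE)
    batch <- n
  }
  with_seed(config$seed, {
    params <- tiny_init(config)
    vel <- lapply(params, function(p) p * 0)
    running <- NULL
    lr <- config$lr
    best <- Inf; wait <- 0
    hist_loss <- hist_lr <- numeric(config$epochs)
    yv <- if (!is.null(val_images)) label_to_binary(val_labels)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1, n, by = batch)) {
        idx <- ord[start:min(start + batch - 1, n)]
        xs <- lapply(idx, function(i) {
          xi <- images[[i]]
          if (config$augment_flips)
            xi <- flip_image(xi, stats::runif(1) < 0.5, stats::runif(1) < 0.5)
          xi
        })
        bg <- tiny_batch_grad(params, xs, y[idx], running)
        running <- if (is.null(running)) list(mu = bg$mu, sd = bg$sd)
                   else list(mu = 0.9 * running$mu + 0.1 * bg$mu,
                             sd = 0.9 * running$sd + 0.1 * bg$sd)
        for (nmp in names(params)) {
          g <- bg$grads[[nmp]] + config$weight_decay * params[[nmp]]
          vel[[nmp]] <- config$momentum * vel[[nmp]] - lr * g
          params[[nmp]] <- params[[nmp]] + vel[[nmp]]
        }
        ep_loss <- ep_loss + bg$loss * length(idx)
      }
      ep_loss <- ep_loss / n
      monitor <- if (!is.null(val_images)) {
        pv <- tiny_predict_probs(params, running, val_images)
        pv <- pmin(pmax(pv, 1e-12), 1 - 1e-12)
        -mean(yv * log(pv) + (1 - yv) * log(1 - pv))
      } else ep_loss
      if (monitor < best - 1e-6) {
        best <- monitor; wait <- 0
      } else {
        wait <- wait + 1
        if (wait >= config$plateau_patience) {
          lr <- lr * config$lr_drop_factor
          wait <- 0
        }
      }
      hist_loss[epoch] <- ep_loss
      hist_lr[epoch] <- lr
    }
    # recalibrate the normalization statistics on the clean training images
    # (the usual post-training batch-norm recalibration)
    Fall <- t(vapply(images, function(x) tiny_forward(params, x)$f,
                     numeric(config$filters[2])))
    mu <- colMeans(Fall)
    running <- list(mu = mu,
                    sd = sqrt(colMeans(sweep(Fall, 2, mu)^2) + 1e-5))
    probs <- tiny_predict_probs(params, running, images)
    structure(list(params = params, norm = running, config = config,
                   history = data.frame(epoch = seq_len(config$epochs),
                                        loss = hist_loss, lr = hist_lr),
                   train_accuracy = mean((probs > 0.5) == (y == 1))),
              class = "tiny_cnn")
  })
}

tiny_predict_probs <- function(params, running, images) {
  vapply(images, function(x) {
    f <- tiny_forward(params, x)$f
    fz <- (f - running$mu) / running$sd
    1 / (1 + exp(-(sum(params$w * fz) + params$b)))
  }, numeric(1))
}

#' @exportS3Method base::print
print.tiny_cnn <- function(x, ...) {
  cat(sprintf("tiny_cnn: %d+%d filters, train accuracy %.3f\n",
              x$config$filters[1], x$config$filters[2], x$train_accuracy))
  invisible(x)
}

#' Predict malignancy probabilities with a trained tiny CNN
#'
#' @param object a `tiny_cnn`
#' @param images list of prepared input matrices
#' @param ... unused
#' @return numeric probabilities in [0, 1]
#' @export
predict.tiny_cnn <- function(object, images, ...) {
  tiny_predict_probs(object$params, object$norm, images)
}

#' Class activation map
#'
#' Weighs the final convolutional feature maps by the classifier head
#' weights, upsamples the sum to the input size and min-max normalizes to
#' [0, 1] (a constant map becomes all zeros). By default the magnitude of
#' the weighted sum is mapped: with a single sigmoid output the sign with
#' which an informative channel enters the head is arbitrary (the bias
#' absorbs the offset), so magnitude — with the zero level anchored by the
#' zeroed background whose activations vanish — is what localizes the
#' evidence; `signed = TRUE` gives the raw malignant-direction sum.
#'
#' @param model a `tiny_cnn`
#' @param image a prepared input matrix
#' @param signed keep the signed malignant-direction sum instead of its
#'   magnitude
#' @return matrix of the input spatial shape with values in [0, 1]
#' @export
cnn_cam <- function(model, image, signed = FALSE) {
  fw <- tiny_forward(model$params, image)
  maps <- fw$p2
  # baseline activations of an all-zero input: the bias-driven response of
  # empty background, subtracted so that background regions map to zero
  base <- tiny_forward(model$params, matrix(0, nrow(image), ncol(image)))$p2
  cam <- matrix(0, dim(maps)[1], dim(maps)[2])
  # the head acts on batch-normalized features, so each map contributes with
  # weight w_k / sd_k (the centering only shifts the map by a constant)
  for (k in seq_len(dim(maps)[3]))
    cam <- cam + model$params$w[k] / model$norm$sd[k] *
      (maps[, , k] - base[, , k])
  if (!signed) cam <- abs(cam)
  up <- as.matrix(EBImage::resize(cam, w = nrow(image), h = ncol(image)))
  rng <- range(up)
  if (diff(rng) == 0) return(matrix(0, nrow(image), ncol(image)))
  (up - rng[1]) / diff(rng)
}

#' Prepare region-masked CNN input crops
#'
#' For each image, pixels outside the requested region are zeroed, the
#' region bounding box (with a 2-pixel margin) is cropped, resized to the
#' configured square input and normalized to mean 0 / sd 1. The resized
#' region support is returned alongside for activation-map analyses.
#'
#' @param dataset a `phantom_dataset`
#' @param region_sets list of [build_region_set()] outputs, one per image
#' @param kind `"tumoral"`, `"peritumoral"` or `"combined"`
#' @param distance_mm ring distance for non-tumoral kinds
#' @param input_size square side of the prepared crops
#' @return list with `images` (matrices), `labels`, `patient_id`, `view`,
#'   `supports` (logical matrices: the resized region mask)
#' @export
cnn_prepare_crops <- function(dataset, region_sets, kind = "combined",
                              distance_mm = 2, input_size = 32) {
  pick <- function(rs) switch(kind,
    tumoral = rs$tumor,
    peritumoral = rs$rings[[as.character(distance_mm)]],
    combined = rs$combineds[[as.character(distance_mm)]],
    stop("unknown region kind: ", kind, call. = FALSE))
  n <- length(dataset$images)
  images <- supports <- vector("list", n)
  for (i in seq_len(n)) {
    im <- dataset$images[[i]]
    mask <- pick(region_sets[[i]])
    px <- im$pixels
    px[!mask] <- 0
    idx <- which(mask, arr.ind = TRUE)
    rr <- pmax(1, min(idx[, 1]) - 2):pmin(nrow(px), max(idx[, 1]) + 2)
    cc <- pmax(1, min(idx[, 2]) - 2):pmin(ncol(px), max(idx[, 2]) + 2)
    crop <- px[rr, cc, drop = FALSE]
    rs <- as.matrix(EBImage::resize(crop, w = input_size, h = input_size))
    s <- stats::sd(rs)
    images[[i]] <- if (s > 0) (rs - mean(rs)) / s else rs * 0
    sup <- as.matrix(EBImage::resize(matrix(as.numeric(mask[rr, cc]),
                                            length(rr)),
                                     w = input_size, h = input_size))
    supports[[i]] <- sup > 0.5
  }
  list(images = images, labels = dataset$meta$label,
       patient_id = dataset$meta$patient_id, view = dataset$meta$view,
       supports = supports)
}
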