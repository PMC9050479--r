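#' Configuration of the patch-classification CNN
#'
#' Describes the nucleus-patch classifier: nine valid-padded stride-1
#' convolutions (first kernel 5x5, the rest 3x3) with filter counts
#' 256, 256, | pool |, 384, 512, 768, | pool |, 768, 1024, 1536, 2048,
#' ReLU and per-layer dropout after every convolution, a 13x13 global
#' average pool, a 2048-unit ReLU dense layer and a 1-unit sigmoid
#' output. On a 101x101 input the spatial chain is
#' 101-97-95-47-45-43-41-21-19-17-15-13. The first max pool truncates the
#' odd edge (95 -> 47); the second pads it (41 -> 21), which the depth
#' of the remaining chain requires. The second pool keeps
#' its 768 input channels: pooling cannot change channel count.
#'
#' `width_multiplier` scales every filter count and the dense width for
#' desk-scale runs; 1.0 reproduces the full architecture. Dropout rates
#' are linearly interpolated over the conv layers between
#' `dropout_range[1]` and `dropout_range[2]`.
#'
#' @param input_channels 3 (RGB) or 87 (hyperspectral); other values need
#'   `allow_any_channels = TRUE`.
#' @param width_multiplier multiplies all filter counts (default 1).
#' @param input_size square input edge (default 101).
#' @param dropout_range length-2 range of conv dropout rates.
#' @param lr,beta1,beta2 Adam optimizer parameters (defaults 1e-5, 0.9,
#'   0.999).
#' @param batch_size minibatch size (default 16).
#' @param max_epochs training cap (default 27).
#' @param patience early-stopping patience on validation accuracy.
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout.
#' @param allow_any_channels permit nonstandard channel counts.
#' @return object of class `cnn_config`.
#' @export
cnn_config <- function(input_channels, width_multiplier = 1,
                       input_size = 101L, dropout_range = c(0.10, 0.30),
                       lr = 1e-5, beta1 = 0.9, beta2 = 0.999,
                       batch_size = 16L, max_epochs = 27L, patience = 3L,
                       seed = 1L, allow_any_channels = FALSE) {
  if (!input_channels %in% c(3L, 87L) && !allow_any_channels)
    abort("input_channels must be 3 or 87 (override with allow_any_channels)")
  base_filters <- c(256, 256, 384, 512, 768, 768, 1024, 1536, 2048)
  f <- pmax(1L, as.integer(round(base_filters * width_multiplier)))
  drop <- seq(dropout_range[1], dropout_range[2], length.out = length(f))
  layers <- list(
    list(type = "conv", k = 5L, f = f[1], dropout = drop[1]),
    list(type = "conv", k = 3L, f = f[2], dropout = drop[2]),
    list(type = "pool", ceil = FALSE),
    list(type = "conv", k = 3L, f = f[3], dropout = drop[3]),
    list(type = "conv", k = 3L, f = f[4], dropout = drop[4]),
    list(type = "conv", k = 3L, f = f[5], dropout = drop[5]),
    list(type = "pool", ceil = TRUE),
    list(type = "conv", k = 3L, f = f[6], dropout = drop[6]),
    list(type = "conv", k = 3L, f = f[7], dropout = drop[7]),
    list(type = "conv", k = 3L, f = f[8], dropout = drop[8]),
    list(type = "conv", k = 3L, f = f[9], dropout = drop[9]))
  structure(list(
    input_channels = as.integer(input_channels),
    input_size = as.integer(input_size),
    width_multiplier = width_multiplier,
    layers = layers,
    dense_units = max(4L, as.integer(round(2048 * width_multiplier))),
    lr = lr, beta1 = beta1, beta2 = beta2,
    batch_size = as.integer(batch_size),
    max_epochs = as.integer(max_epochs), patience = as.integer(patience),
    seed = as.integer(seed)), class = "cnn_config")
}

#' Layer-by-layer output shapes of the CNN
#'
#' Valid-convolution arithmetic for the configured input. On the standard
#' 101x101 input the chain reads
#' 97, 95, 47 (pool), 45, 43, 41, 21 (pool), 19, 17, 15, 13, then the
#' global average pool and the two dense layers.
#'
#' @param config a [cnn_config()].
#' @return tibble with `layer`, `type`, `out_h`, `out_w`, `out_c`.
#' @export
cnn_shapes <- function(config) {
  h <- config$input_size; c <- config$input_channels
  rows <- list(tibble(layer = "input", type = "input",
                      out_h = h, out_w = h, out_c = c))
  for (ly in config$layers) {
    if (ly$type == "conv") {
      h <- h - ly$k + 1L; c <- ly$f
      rows <- c(rows, list(tibble(layer = sprintf("conv%d", ly$k),
                                  type = "conv", out_h = h, out_w = h,
                                  out_c = c)))
    } else {
      h <- if (ly$ceil) as.integer(ceiling(h / 2)) else h %/% 2L
      rows <- c(rows, list(tibble(layer = "max_pool", type = "pool",
                                  out_h = h, out_w = h, out_c = c)))
    }
  }
  bind_rows(c(rows, list(
    tibble(layer = "global_avg_pool", type = "gap", out_h = 1L, out_w = 1L,
           out_c = c),
    tibble(layer = "dense_relu", type = "dense", out_h = 1L, out_w = 1L,
           out_c = config$dense_units),
    tibble(layer = "dense_sigmoid", type = "dense", out_h = 1L, out_w = 1L,
           out_c = 1L))))
}

glorot_normal <- function(nrow, ncol, fan_in, fan_out) {
  matrix(rnorm(nrow * ncol, sd = sqrt(2 / (fan_in + fan_out))), nrow, ncol)
}

#' Build (initialize) the CNN
#'
#' Allocates Glorot-normal weights for every layer of the configured
#' architecture. Initialization is reproducible from `config$seed`.
#'
#' @param config a [cnn_config()].
#' @return object of class `cnn_model`.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "cnn_config"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old))
  set.seed(config$seed)
  c_in <- config$input_channels
  params <- list()
  for (i in seq_along(config$layers)) {
    ly <- config$layers[[i]]
    if (ly$type != "conv") next
    fan_in <- ly$k^2 * c_in; fan_out <- ly$k^2 * ly$f
    params[[sprintf("conv_%02d", i)]] <- list(
      W = glorot_normal(ly$f, ly$k^2 * c_in, fan_in, fan_out),
      b = numeric(ly$f))
    c_in <- ly$f
  }
  params$dense1 <- list(
    W = glorot_normal(config$dense_units, c_in, c_in, config$dense_units),
    b = numeric(config$dense_units))
  params$dense2 <- list(
    W = glorot_normal(1L, config$dense_units, config$dense_units, 1L),
    b = 0)
  structure(list(config = config, params = params,
                 shapes = cnn_shapes(config)), class = "cnn_model")
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model> input %dx%dx%d, width x%.3g, %s\n",
              x$config$input_size, x$config$input_size,
              x$config$input_channels, x$config$width_multiplier,
              if (is.null(x$history)) "untrained" else "trained"))
  print(as.data.frame(x$shapes), row.names = FALSE)
  invisible(x)
}

relu <- function(x) (x > 0) * x
sigmoid <- function(x) 1 / (1 + exp(-x))

# forward pass for one sample; returns probability and (optionally) the
# per-layer caches needed for backprop
cnn_forward <- function(model, x, train = FALSE) {
  cfg <- model$config
  caches <- if (train) vector("list", length(cfg$layers))
  a <- x
  for (i in seq_along(cfg$layers)) {
    ly <- cfg$layers[[i]]
    d <- dim(a)
    if (ly$type == "conv") {
      pr <- model$params[[sprintf("conv_%02d", i)]]
      oh <- d[1] - ly$k + 1L
      npix <- oh * oh
      Xc <- cpp_im2col(as.numeric(a), d[1], d[2], d[3], ly$k)
      z <- Xc %*% t(pr$W) + rep(pr$b, each = npix)
      mask <- z > 0
      z <- z * mask
      dropmask <- NULL
      if (train && ly$dropout > 0) {
        dropmask <- (matrix(runif(length(z)), nrow(z)) >= ly$dropout) /
          (1 - ly$dropout)
        z <- z * dropmask
      }
      if (train) caches[[i]] <- list(Xc = Xc, mask = mask, drop = dropmask,
                                     in_dim = d)
      dim(z) <- c(oh, oh, ly$f)
      a <- z
    } else {
      mp <- cpp_maxpool(as.numeric(a), d[1], d[2], d[3], ly$ceil)
      if (train) caches[[i]] <- list(idx = mp$idx, in_dim = d)
      a <- mp$out
    }
  }
  d <- dim(a)
  npix <- d[1] * d[2]
  v <- colMeans(matrix(a, npix, d[3]))
  z1 <- as.vector(model$params$dense1$W %*% v + model$params$dense1$b)
  a1 <- relu(z1)
  z2 <- sum(model$params$dense2$W * a1) + model$params$dense2$b
  p <- sigmoid(z2)
  if (!train) return(p)
  list(p = p, caches = caches, v = v, z1 = z1, a1 = a1,
       gap_dim = d)
}

# backward pass; returns gradient list mirroring model$params
cnn_backward <- function(model, fwd, y) {
  cfg <- model$config
  grads <- list()
  dz2 <- fwd$p - y
  grads$dense2 <- list(W = matrix(dz2 * fwd$a1, 1), b = dz2)
  da1 <- as.vector(model$params$dense2$W) * dz2
  dz1 <- da1 * (fwd$z1 > 0)
  grads$dense1 <- list(W = outer(dz1, fwd$v), b = dz1)
  dv <- as.vector(crossprod(model$params$dense1$W, dz1))
  d <- fwd$gap_dim
  npix <- d[1] * d[2]
  da <- array(matrix(dv / npix, npix, d[3], byrow = TRUE), d)
  for (i in rev(seq_along(cfg$layers))) {
    ly <- cfg$layers[[i]]
    cache <- fwd$caches[[i]]
    if (ly$type == "pool") {
      da <- cpp_maxpool_bwd(as.numeric(da), cache$idx,
                            cache$in_dim[1], cache$in_dim[2], cache$in_dim[3])
    } else {
      dz <- matrix(da, length(da) / ly$f, ly$f)
      if (!is.null(cache$drop)) dz <- dz * cache$drop
      dz <- dz * cache$mask
      pr <- model$params[[sprintf("conv_%02d", i)]]
      grads[[sprintf("conv_%02d", i)]] <-
        list(W = crossprod(dz, cache$Xc), b = colSums(dz))
      if (i > 1L) {
        dXc <- dz %*% pr$W
        da <- cpp_col2im(dXc, cache$in_dim[1], cache$in_dim[2],
                         cache$in_dim[3], ly$k)
      }
    }
  }
  grads
}

adam_init <- function(params) {
  lapply(params, function(p)
    list(mW = p$W * 0, vW = p$W * 0, mb = p$b * 0, vb = p$b * 0))
}

adam_step <- function(params, grads, state, cfg, t) {
  eps <- 1e-8
  for (nm in names(params)) {
    g <- grads[[nm]]; s <- state[[nm]]
    s$mW <- cfg$beta1 * s$mW + (1 - cfg$beta1) * g$W
    s$vW <- cfg$beta2 * s$vW + (1 - cfg$beta2) * g$W^2
    s$mb <- cfg$beta1 * s$mb + (1 - cfg$beta1) * g$b
    s$vb <- cfg$beta2 * s$vb + (1 - cfg$beta2) * g$b^2
    mhW <- s$mW / (1 - cfg$beta1^t); vhW <- s$vW / (1 - cfg$beta2^t)
    mhb <- s$mb / (1 - cfg$beta1^t); vhb <- s$vb / (1 - cfg$beta2^t)
    params[[nm]]$W <- params[[nm]]$W - cfg$lr * mhW / (sqrt(vhW) + eps)
    params[[nm]]$b <- params[[nm]]$b - cfg$lr * mhb / (sqrt(vhb) + eps)
    state[[nm]] <- s
  }
  list(params = params, state = state)
}

rot90_arr <- function(a, k = 1L) {
  k <- k %% 4L
  if (k == 0L) return(a)
  for (i in seq_len(k)) {
    d <- dim(a)
    # 90 deg counter-clockwise: new[r, c, ] = old[c, W + 1 - r, ]
    a <- aperm(a, c(2, 1, 3))[d[2]:1, , , drop = FALSE]
  }
  a
}

flip_h <- function(a) a[, dim(a)[2]:1, , drop = FALSE]
flip_v <- function(a) a[dim(a)[1]:1, , , drop = FALSE]

#' Four-fold rotation augmentation of training patches
#'
#' Each square patch is replicated under rotations of 0, 90, 180 and 270
#' degrees with its label preserved, quadrupling the training set.
#'
#' @param patches tibble with a patch list-column and `label`.
#' @param patch_column name of the patch list-column.
#' @return tibble with 4x the rows and a `view` column.
#' @export
augment_train <- function(patches, patch_column = "hsi_patch") {
  check_square(patches[[patch_column]])
  out <- purrr::map(0:3, function(k) {
    p <- patches
    p[[patch_column]] <- purrr::map(p[[patch_column]], rot90_arr, k = k)
    p$view <- sprintf("rot%d", 90 * k)
    p
  })
  bind_rows(out)
}

#' Four deterministic evaluation views of a patch
#'
#' Identity, 90-degree rotation, horizontal reflection and vertical
#' reflection; prediction averages the network probability over these
#' views.
#'
#' @param patch square array `[h, w, c]`.
#' @return list of 4 arrays.
#' @export
augment_eval <- function(patch) {
  check_square(list(patch))
  list(identity = patch, rot90 = rot90_arr(patch, 1L),
       flip_h = flip_h(patch), flip_v = flip_v(patch))
}

check_square <- function(patches) {
  for (p in patches) {
    d <- dim(p)
    if (length(d) != 3L || d[1] != d[2])
      abort("patches must be square [h, h, c] arrays")
  }
  invisible(TRUE)
}

#' Train the CNN on nucleus patches
#'
#' Minibatch Adam with binary cross-entropy on four-fold
#' rotation-augmented training patches; after each epoch validation
#' accuracy (0.5 cut, eval-view averaging) is measured and training stops
#' early once it has not improved for `patience` epochs; the best-epoch
#' weights are kept. Training and validation patient sets must be
#' disjoint — overlap is a hard error, never a warning.
#'
#' @param model a [build_model()] result.
#' @param train_records,val_records tibbles with `patient_id`, `label`
#'   and the patch list-column.
#' @param patch_column which patch list-column to train on (`"hsi_patch"`
#'   or `"rgb_patch"`).
#' @return `cnn_model` with trained params and a `history` tibble
#'   (`epoch`, `train_loss`, `val_accuracy`).
#' @export
train <- function(model, train_records, val_records,
                  patch_column = "hsi_patch") {
  stopifnot(inherits(model, "cnn_model"))
  cfg <- model$config
  overlap <- intersect(unique(train_records$patient_id),
                       unique(val_records$patient_id))
  if (length(overlap))
    abort(sprintf("patient-level leakage: %s in both train and validation",
                  paste(overlap, collapse = ", ")))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old))
  set.seed(cfg$seed + 1L)
  aug <- augment_train(train_records, patch_column)
  y <- as.numeric(aug$label == "cancerous")
  xs <- aug[[patch_column]]
  state <- adam_init(model$params)
  best <- list(acc = -Inf, params = model$params, epoch = 0L)
  hist <- list()
  t_step <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(length(xs))
    losses <- numeric(0)
    for (b0 in seq(1, length(ord), by = cfg$batch_size)) {
      idx <- ord[b0:min(b0 + cfg$batch_size - 1, length(ord))]
      gsum <- NULL
      bl <- 0
      for (i in idx) {
        fwd <- cnn_forward(model, xs[[i]], train = TRUE)
        g <- cnn_backward(model, fwd, y[i])
        p <- min(max(fwd$p, 1e-12), 1 - 1e-12)
        bl <- bl - (y[i] * log(p) + (1 - y[i]) * log(1 - p))
        gsum <- if (is.null(gsum)) g else
          purrr::map2(gsum, g[names(gsum)], function(a, b)
            list(W = a$W + b$W, b = a$b + b$b))
      }
      gmean <- purrr::map(gsum, function(g)
        list(W = g$W / length(idx), b = g$b / length(idx)))
      t_step <- t_step + 1L
      upd <- adam_step(model$params, gmean, state, cfg, t_step)
      model$params <- upd$params; state <- upd$state
      losses <- c(losses, bl / length(idx))
    }
    val <- predict_cnn(model, val_records, patch_column)
    acc <- mean((val$probability >= 0.5) ==
                  (val_records$label == "cancerous"))
    hist[[epoch]] <- tibble(epoch = epoch, train_loss = mean(losses),
                            val_accuracy = acc)
    if (acc > best$acc + 1e-12) {
      best <- list(acc = acc, params = model$params, epoch = epoch)
    } else if (epoch - best$epoch >= cfg$patience) break
  }
  model$params <- best$params
  model$history <- bind_rows(hist)
  model$best_epoch <- best$epoch
  model
}

#' Predict nucleus probabilities with the trained CNN
#'
#' For each record the probability is the arithmetic mean over the four
#' deterministic evaluation views ([augment_eval()]). With a threshold the
#' binary decision is added.
#'
#' @param model trained `cnn_model`.
#' @param records tibble with the patch list-column.
#' @param patch_column patch list-column name.
#' @param threshold optional probability threshold for decisions.
#' @return tibble `nucleus_id`, `probability` (and `decision`,
#'   `threshold_used` when a threshold is given).
#' @export
predict_cnn <- function(model, records, patch_column = "hsi_patch",
                        threshold = NULL) {
  probs <- vapply(records[[patch_column]], function(x) {
    mean(vapply(augment_eval(x), function(v)
      cnn_forward(model, v, train = FALSE), numeric(1)))
  }, numeric(1))
  out <- tibble(
    nucleus_id = if ("nucleus_id" %in% names(records)) records$nucleus_id
                 else as.character(seq_along(probs)),
    probability = probs)
  if (!is.null(threshold))
    out <- out %>% mutate(
      decision = ifelse(.data$probability >= threshold, "cancerous",
                        "normal"),
      threshold_used = threshold)
  out
}

#' @describeIn train epoch history of a trained model.
#' @param x trained `cnn_model`.
#' @param ... unused.
#' @export
tidy.cnn_model <- function(x, ...) {
  if (is.null(x$history)) abort("model is untrained")
  x$history
}

#' @describeIn train one-row summary of a trained model.
#' @export
glance.cnn_model <- function(x, ...) {
  if (is.null(x$history)) abort("model is untrained")
  tibble(epochs_run = nrow(x$history), best_epoch = x$best_epoch,
         best_val_accuracy = max(x$history$val_accuracy),
         final_train_loss = x$history$train_loss[nrow(x$history)])
}

#' @describeIn train training-history curves.
#' @param object trained `cnn_model`.
#' @export
autoplot.cnn_model <- function(object, ...) {
  h <- tidy(object) %>%
    tidyr::pivot_longer(c("train_loss", "val_accuracy"),
                        names_to = "metric")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::theme_minimal()
}
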