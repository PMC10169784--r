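# Small native U-net engine (shared by the 3D chambers net, the coarse RoI
# net and the per-slice 2D blood-pool net).  Tensors are (X, Y, Z, C) arrays;
# 2D networks use a singleton Z with 3x3x1 kernels and in-plane pooling.
# Inputs carry the normalized intensity plus a positional encoding (the
# normalized coordinates and their squares), giving the net the positional
# context that distinguishes equal-intensity chambers at 64^3.

#' Training configuration for the U-net stages
#'
#' Defaults follow the training recipe of the segmentation stages: the
#' learning rate is 0.0002 for the first half of the epochs and 0.00002
#' afterwards; default epoch counts are 6 (2D) and 480 (3D), both
#' overridable (desk-scale runs use far fewer).
#'
#' @param epochs Number of epochs (>= 1).
#' @param lr_initial,lr_late The two learning-rate plateaus.
#' @param augment Augmentation flag (off by default at phantom scale).
#' @param seed Integer seed for weight init and data order.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 6L, lr_initial = 2e-4, lr_late = 2e-5,
                         augment = FALSE, seed = 1L) {
  epochs <- as.integer(epochs)
  if (is.na(epochs) || epochs < 1) stop("epochs must be >= 1")
  if (lr_initial <= 0 || lr_late <= 0) stop("learning rates must be positive")
  structure(list(epochs = epochs, lr_initial = lr_initial, lr_late = lr_late,
                 augment = isTRUE(augment), seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' @param epoch Epoch number (1-based).
#' @param config A [train_config()].
#' @return `lr_initial` for the first 50% of epochs, `lr_late` afterwards.
#' @export
learning_rate_at <- function(epoch, config) {
  if (epoch <= ceiling(config$epochs / 2)) config$lr_initial
  else config$lr_late
}

he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}

# levels = number of resolution levels including the bottleneck
unet_init <- function(in_ch, n_classes, levels = 2L, filters = 8L,
                      two_d = FALSE, seed = 1L) {
  old <- local_seed(seed)
  kz <- if (two_d) 1L else 3L
  layers <- list()
  f_prev <- in_ch
  conv_layer <- function(fin, fout) list(
    w = he_init(c(3, 3, kz, fin, fout), 9 * kz * fin), b = numeric(fout),
    gamma = rep(1, fout), beta = numeric(fout))
  for (l in seq_len(levels)) {
    f <- filters * 2^(l - 1)
    layers[[paste0("enc", l, "a")]] <- conv_layer(f_prev, f)
    layers[[paste0("enc", l, "b")]] <- conv_layer(f, f)
    f_prev <- f
  }
  for (l in seq_len(levels - 1)) {
    lev <- levels - l            # decoder level index
    f <- filters * 2^(lev - 1)
    f_lo <- filters * 2^lev      # channels arriving from below
    layers[[paste0("dec", lev, "a")]] <- conv_layer(f + f_lo, f)
    layers[[paste0("dec", lev, "b")]] <- conv_layer(f, f)
  }
  # the output layer reads the decoder features concatenated with the raw
  # input channels (input-to-output skip): with the quadratic positional
  # encoding the class regions are linear in the inputs, so the readout can
  # learn them directly while the conv features supply corrections
  layers[["out"]] <- list(w = he_init(c(1, 1, 1, filters + in_ch, n_classes),
                                      filters + in_ch),
                          b = numeric(n_classes))
  restore_seed(old)
  structure(list(layers = layers, levels = levels, filters = filters,
                 in_ch = in_ch, n_classes = n_classes, two_d = two_d,
                 logit_gain = 25),
            class = "unet_model")
}

# conv -> instance norm -> ReLU (norm and ReLU skipped on the output layer)
conv_block <- function(x, layer, acts, name, relu = TRUE) {
  y <- cpp_conv3d_fwd(x, dim(x), layer$w, dim(layer$w), layer$b)
  acts[[paste0(name, "_in")]] <- x
  if (relu) {
    fn <- cpp_instnorm_fwd(y, dim(y), layer$gamma, layer$beta, 1e-5)
    acts[[paste0(name, "_xhat")]] <- fn$xhat
    acts[[paste0(name, "_sg")]] <- fn$sg
    acts[[paste0(name, "_pre")]] <- fn$z
    y <- array(pmax(fn$z, 0), dim(y))
  }
  y
}

unet_forward <- function(model, x, keep_acts = FALSE) {
  acts <- new.env(parent = emptyenv())
  L <- model$levels
  pf <- if (model$two_d) c(2L, 2L, 1L) else c(2L, 2L, 2L)
  skips <- list()
  h <- x
  for (l in seq_len(L)) {
    h <- conv_block(h, model$layers[[paste0("enc", l, "a")]], acts,
                    paste0("enc", l, "a"))
    h <- conv_block(h, model$layers[[paste0("enc", l, "b")]], acts,
                    paste0("enc", l, "b"))
    if (l < L) {
      skips[[l]] <- h
      mp <- cpp_maxpool_fwd(h, dim(h), pf)
      acts[[paste0("pool", l, "_idx")]] <- mp$idx
      acts[[paste0("pool", l, "_xd")]] <- dim(h)
      h <- mp$y
    }
  }
  for (lev in rev(seq_len(L - 1))) {
    up <- cpp_upsample_fwd(h, dim(h), pf)
    acts[[paste0("up", lev, "_yd")]] <- dim(up)
    cat_in <- abind4(skips[[lev]], up)
    acts[[paste0("cat", lev, "_nskip")]] <- dim(skips[[lev]])[4]
    h <- conv_block(cat_in, model$layers[[paste0("dec", lev, "a")]], acts,
                    paste0("dec", lev, "a"))
    h <- conv_block(h, model$layers[[paste0("dec", lev, "b")]], acts,
                    paste0("dec", lev, "b"))
  }
  out_in <- abind4(h, x)                 # input-to-output skip
  logits <- conv_block(out_in, model$layers[["out"]], acts, "out",
                       relu = FALSE)
  logits <- logits * model$logit_gain
  if (keep_acts) list(logits = logits, acts = acts) else list(logits = logits)
}

abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

# gradient of combined_loss w.r.t. logits; p,g are N x C.
# The cross-entropy part is taken directly as (p - g)/(NC): routing the
# clamped -g/p derivative through the softmax jacobian would vanish for
# classes whose probability has collapsed, leaving them dead; the closed
# form keeps a constant pull that revives them.
loss_grad_logits <- function(p, g, eps = 1e-6) {
  N <- nrow(p); C <- ncol(p)
  inter <- colSums(p * g)
  denom <- colSums(p + g)
  # d(dice term)/dp, through the softmax jacobian
  dLdp <- -(1 / C) * (2 * sweep(g, 2, denom + eps, "*") -
                        sweep(matrix(1, N, C), 2, 2 * inter + eps, "*")) /
    matrix((denom + eps)^2, N, C, byrow = TRUE)
  dz <- p * (dLdp - rowSums(dLdp * p))
  dz + (p - g) / (N * C)
}

unet_backward <- function(model, fwd, dz_logits) {
  acts <- fwd$acts
  L <- model$levels
  pf <- if (model$two_d) c(2L, 2L, 1L) else c(2L, 2L, 2L)
  grads <- list()
  conv_back <- function(name, dy, relu = TRUE) {
    x <- acts[[paste0(name, "_in")]]
    layer <- model$layers[[name]]
    if (relu) {
      d <- dim(dy)
      nb <- cpp_instnorm_relu_bwd(dy, acts[[paste0(name, "_pre")]],
                                  acts[[paste0(name, "_xhat")]],
                                  acts[[paste0(name, "_sg")]],
                                  layer$gamma, d)
      bw <- cpp_conv3d_bwd(x, dim(x), layer$w, dim(layer$w), nb$dx)
      grads[[name]] <<- list(w = bw$dw, b = bw$db * 0,
                             gamma = nb$dgamma, beta = nb$dbeta)
    } else {
      bw <- cpp_conv3d_bwd(x, dim(x), layer$w, dim(layer$w), dy)
      grads[[name]] <<- list(w = bw$dw, b = bw$db)
    }
    bw$dx
  }
  dy <- conv_back("out", dz_logits * model$logit_gain, relu = FALSE)
  dy <- dy[, , , seq_len(model$filters), drop = FALSE]  # drop input-skip grad
  for (lev in seq_len(L - 1)) {
    dy <- conv_back(paste0("dec", lev, "b"), dy)
    dcat <- conv_back(paste0("dec", lev, "a"), dy)
    nskip <- acts[[paste0("cat", lev, "_nskip")]]
    dskip <- dcat[, , , seq_len(nskip), drop = FALSE]
    dup <- dcat[, , , nskip + seq_len(dim(dcat)[4] - nskip), drop = FALSE]
    dy <- cpp_upsample_bwd(dup, acts[[paste0("up", lev, "_yd")]], pf)
    # store skip grad to merge after encoder backprop reaches this level
    grads[[paste0("skipgrad", lev)]] <- dskip
  }
  for (l in rev(seq_len(L))) {
    if (l < L) {
      dy <- cpp_maxpool_bwd(acts[[paste0("pool", l, "_idx")]], dy,
                            acts[[paste0("pool", l, "_xd")]])
      dy <- dy + grads[[paste0("skipgrad", l)]]
      grads[[paste0("skipgrad", l)]] <- NULL
    }
    dy <- conv_back(paste0("enc", l, "b"), dy)
    dy <- conv_back(paste0("enc", l, "a"), dy)
  }
  grads
}

# one Adam slot per parameter array in each layer (w, b, gamma, beta)
adam_init <- function(model) {
  lapply(model$layers, function(l)
    lapply(l, function(p) list(m = array(0, dim(p) %||% length(p)),
                               v = array(0, dim(p) %||% length(p)))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# beta2 = 0.99: the variance estimate adapts within tens of steps, which
# suits the short seeded training runs used here
adam_step <- function(model, grads, state, lr, t, beta1 = 0.9, beta2 = 0.99,
                      eps = 1e-8) {
  for (name in names(model$layers)) {
    for (pn in names(grads[[name]])) {
      g <- grads[[name]][[pn]]
      s <- state[[name]][[pn]]
      s$m <- beta1 * s$m + (1 - beta1) * g
      s$v <- beta2 * s$v + (1 - beta2) * g^2
      model$layers[[name]][[pn]] <- model$layers[[name]][[pn]] -
        lr * (s$m / (1 - beta1^t)) / (sqrt(s$v / (1 - beta2^t)) + eps)
      state[[name]][[pn]] <- s
    }
  }
  list(model = model, state = state)
}

# normalized input tensor: intensity scaled to ~[0,1] plus a positional
# encoding — xyz coordinate channels in [-1, 1] and their squares. The
# squared channels make axis-aligned quadric boundaries (chamber ellipsoids)
# linearly representable, which is what lets a small net separate
# equal-intensity chambers at 64^3.
net_input <- function(intens) {
  d <- dim(intens)
  xs <- if (d[1] > 1) seq(-1, 1, length.out = d[1]) else 0
  ys <- if (d[2] > 1) seq(-1, 1, length.out = d[2]) else 0
  zs <- if (d[3] > 1) seq(-1, 1, length.out = d[3]) else 0
  x <- array(0, c(d, 7))
  x[, , , 1] <- intens / 300
  x[, , , 2] <- array(rep(xs, times = d[2] * d[3]), d)
  x[, , , 3] <- array(rep(rep(ys, each = d[1]), times = d[3]), d)
  x[, , , 4] <- array(rep(zs, each = d[1] * d[2]), d)
  x[, , , 5] <- x[, , , 2]^2
  x[, , , 6] <- x[, , , 3]^2
  x[, , , 7] <- x[, , , 4]^2
  x
}

net_in_channels <- function() 7L

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

# one optimisation pass over samples (list of list(x, g)); returns model,
# state and mean loss
train_epoch <- function(model, samples, state, lr, t0) {
  losses <- numeric(length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    fwd <- unet_forward(model, s$x, keep_acts = TRUE)
    d <- dim(fwd$logits)
    z <- matrix(fwd$logits, prod(d[1:3]), d[4])
    p <- softmax_rows(z)
    losses[i] <- combined_loss(p, s$g)
    if (!is.finite(losses[i])) stop("training diverged: non-finite loss")
    dz <- loss_grad_logits(p, s$g)
    dz_arr <- array(dz, d)
    grads <- unet_backward(model, fwd, dz_arr)
    st <- adam_step(model, grads, state, lr, t0 + i)
    model <- st$model; state <- st$state
  }
  list(model = model, state = state, loss = mean(losses))
}

#' Train a U-net backend on phantom cases
#'
#' Optimizes the combined Dice + cross-entropy loss ([combined_loss()]) with
#' Adam under the two-plateau learning-rate schedule of [train_config()].
#' `dimensionality = "3D"` trains the chambers/myocardium net on
#' RoI-cropped, 64^3-resampled volumes (classes background, LV, RV, LA, RA,
#' Myo); `"2D"` trains the per-slice blood-pool net (classes background,
#' interior, boundary). Deterministic given the config seed; data order is
#' fixed.
#'
#' @param cases List of `phantom_case`s (>= 1).
#' @param config A [train_config()].
#' @param dimensionality `"3D"` or `"2D"`.
#' @param levels,filters Network size (resolution levels incl. bottleneck,
#'   filters at the first level).
#' @param grid Edge length the 3D inputs are resampled to.
#' @param block 3D training block edge (the RoI is split into block^3
#'   patches; inference tiles with the same block).
#' @param margin RoI margin (coarse voxels) for the 3D training crops.
#' @param verbose Print per-epoch losses.
#' @return A `trained_backend` with elements `model`, `loss_history`,
#'   `config`, `dimensionality`.
#' @export
train_unet <- function(cases, config = train_config(),
                       dimensionality = c("3D", "2D"), levels = 2L,
                       filters = 8L, grid = 64L, block = 8L, margin = 2L,
                       verbose = FALSE) {
  dimensionality <- match.arg(dimensionality)
  stopifnot(length(cases) >= 1, inherits(config, "train_config"))
  two_d <- dimensionality == "2D"
  samples <- if (two_d) build_samples_2d(cases)
  else build_samples_3d(cases, grid, block = block, margin = margin)
  n_classes <- ncol(samples[[1]]$g)
  model <- unet_init(net_in_channels(), n_classes, levels, filters, two_d = two_d,
                     seed = config$seed)
  if (!two_d) model$block <- as.integer(block)
  state <- adam_init(model)
  history <- numeric(config$epochs)
  t0 <- 0
  for (e in seq_len(config$epochs)) {
    lr <- learning_rate_at(e, config)
    ep <- train_epoch(model, samples, state, lr, t0)
    model <- ep$model; state <- ep$state
    history[e] <- ep$loss
    t0 <- t0 + length(samples)
    if (verbose) message(sprintf("epoch %d  lr %.2g  loss %.5f", e, lr, ep$loss))
  }
  trained_backend(model, dimensionality, history, config)
}

chamber_net_codes <- function() c(0L, label_codes()[c("LV", "RV", "LA", "RA", "Myo")])

# Each case's RoI (tight crop, resampled to `grid`^3) is split into `block`^3
# patches: the net trains on blocks, which multiplies the optimizer steps per
# epoch at the same compute, and trained-backend inference runs block-wise
# with the same block size so instance-norm statistics match training.
# Coordinate channels are computed on the full grid before splitting so they
# stay absolute.
build_samples_3d <- function(cases, grid, block = 16L, margin = 2L) {
  codes <- chamber_net_codes()
  out <- list()
  for (case in cases) {
    truth <- if (!is.null(case$body_truth)) case$body_truth else case$truth
    roi <- crop_roi(case$image, oracle_backend(truth), margin = margin)
    x64 <- resample_linear(roi$roi$data, rep(grid, 3))
    truth_roi <- crop_volume(truth, roi$offset, dim(roi$roi$data))
    lab <- truth_roi$data
    lab[!(lab %in% codes)] <- 0L
    lab64 <- cpp_majority_downsample(array(as.integer(lab), dim(lab)),
                                     dim(lab), rep(grid, 3L), 7L)
    x <- net_input(x64)
    nb <- grid %/% block
    for (oz in seq_len(nb) - 1) for (oy in seq_len(nb) - 1)
      for (ox in seq_len(nb) - 1) {
        ix <- ox * block + seq_len(block); iy <- oy * block + seq_len(block)
        iz <- oz * block + seq_len(block)
        out[[length(out) + 1]] <- list(
          x = x[ix, iy, iz, , drop = FALSE],
          g = one_hot(lab64[ix, iy, iz], codes))
      }
  }
  out
}

build_samples_2d <- function(cases) {
  out <- list()
  for (case in cases) {
    bp <- bloodpool_oracle(case$truth)
    d <- dim(case$image$data)
    for (z in seq_len(d[3])) {
      sl <- case$image$data[, , z, drop = FALSE]
      lab <- bp[, , z, drop = FALSE]
      out[[length(out) + 1]] <- list(x = net_input(array(sl, c(d[1], d[2], 1))),
                                     g = one_hot(lab, c(0L, 1L, 2L)))
    }
  }
  out
}

#' Train-config and trained-backend serialization
#'
#' Training configurations round-trip through YAML; trained backends are
#' saved in R's native serialization with a JSON sidecar describing the
#' network (levels, filters, classes, dimensionality, block size).
#'
#' @param config A [train_config()].
#' @param path Output path (`.yaml` for configs, `.rds` for backends; the
#'   descriptor is written next to the backend as `<path>.json`).
#' @export
write_train_config <- function(config, path) {
  stopifnot(inherits(config, "train_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_train_config
#' @export
read_train_config <- function(path) {
  do.call(train_config, yaml::read_yaml(path))
}

#' @rdname write_train_config
#' @param backend A `trained_backend`.
#' @export
save_backend <- function(backend, path) {
  stopifnot(inherits(backend, "trained_backend"))
  saveRDS(backend, path)
  m <- backend$model
  jsonlite::write_json(
    list(dimensionality = backend$dimensionality, levels = m$levels,
         filters = m$filters, in_channels = m$in_ch,
         n_classes = m$n_classes, logit_gain = m$logit_gain,
         block = m$block, final_loss = unname(tail(backend$loss_history, 1))),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_train_config
#' @export
load_backend <- function(path) {
  b <- readRDS(path)
  stopifnot(inherits(b, "trained_backend"))
  b
}
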