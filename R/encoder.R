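#' Segment encoder configuration
#'
#' The first learning stage: a residual convolutional network over per-segment
#' spectrograms that scores single segments for pAF and exposes a latent
#' embedding. Each residual block is two (convolution, batch normalization,
#' ReLU) modules with an identity skip (a 1x1 projection when the channel
#' count changes); blocks are separated by 2x2 average-pool downsampling.
#' After global average pooling, two fully connected layers produce the latent
#' vector and a single logit.
#'
#' @param n_blocks Number of residual blocks (default 3).
#' @param channels Output channels per block.
#' @param kernel_size Convolution kernel (odd).
#' @param latent_dim Dimension of the latent embedding.
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param batch_size Minibatch size (default 1024; reduce for small cohorts).
#' @param max_epochs Training epoch cap.
#' @param patience Early-stopping patience on validation loss, epochs.
#' @param val_frac Fraction of training-fold patients held out for validation
#'   (patient-wise, to avoid leakage between segments of one patient).
#' @param class_weighting Weight the loss by inverse class prevalence?
#' @param seed Seed for initialisation and shuffling.
#' @return List of class `encoder_config`.
#' @export
encoder_config <- function(n_blocks = 3, channels = c(16, 32, 64),
                           kernel_size = 3, latent_dim = 32,
                           learning_rate = 1e-4, batch_size = 1024,
                           max_epochs = 30, patience = 5, val_frac = 0.2,
                           class_weighting = FALSE, seed = 1L) {
  if (n_blocks < 1) abort("n_blocks must be >= 1")
  if (length(channels) != n_blocks) abort("channels must have length n_blocks")
  if (latent_dim < 1) abort("latent_dim must be >= 1")
  if (learning_rate <= 0) abort("learning_rate must be > 0")
  if (kernel_size %% 2 != 1) abort("kernel_size must be odd")
  structure(
    list(
      n_blocks = as.integer(n_blocks), channels = as.integer(channels),
      kernel_size = as.integer(kernel_size), latent_dim = as.integer(latent_dim),
      learning_rate = learning_rate, batch_size = as.integer(batch_size),
      max_epochs = as.integer(max_epochs), patience = as.integer(patience),
      val_frac = val_frac, class_weighting = isTRUE(class_weighting),
      seed = as.integer(seed)
    ),
    class = "encoder_config"
  )
}

#' Build an untrained segment encoder
#'
#' Initialises all weights (He-normal convolutions, unit-gamma batch norm)
#' deterministically from the config seed for a given spectrogram shape.
#'
#' @param config An [encoder_config()].
#' @param input_shape Integer vector `c(F, T, channels)` of the spectrogram.
#' @return Object of class `segment_encoder`.
#' @export
build_encoder <- function(config, input_shape) {
  stopifnot(inherits(config, "encoder_config"))
  if (length(input_shape) != 3L) abort("input_shape must be c(F, T, channels)")
  k <- config$kernel_size
  h <- input_shape[1]
  w <- input_shape[2]
  c_in <- input_shape[3]
  params <- list()
  stats <- list()
  withr::with_seed(config$seed, {
    for (b in seq_len(config$n_blocks)) {
      c_out <- config$channels[b]
      if (h < 1 || w < 1) abort("spatial dimensions collapsed; too many blocks")
      for (half in c("a", "b")) {
        cin <- if (half == "a") c_in else c_out
        nm <- sprintf("conv%d%s", b, half)
        params[[paste0(nm, "_W")]] <- matrix(
          rnorm(c_out * cin * k * k, 0, sqrt(2 / (cin * k * k))),
          nrow = c_out
        )
        params[[paste0(nm, "_b")]] <- numeric(c_out)
        params[[sprintf("bn%d%s_gamma", b, half)]] <- rep(1, c_out)
        params[[sprintf("bn%d%s_beta", b, half)]] <- numeric(c_out)
        stats[[sprintf("bn%d%s", b, half)]] <- list(
          mean = numeric(c_out), var = rep(1, c_out)
        )
      }
      if (c_in != c_out) {
        params[[sprintf("proj%d_W", b)]] <- matrix(
          rnorm(c_out * c_in, 0, sqrt(2 / c_in)),
          nrow = c_out
        )
      }
      c_in <- c_out
      if (b < config$n_blocks) {
        h <- h %/% 2L
        w <- w %/% 2L
      }
    }
    params$fc1_W <- matrix(
      rnorm(config$latent_dim * c_in, 0, sqrt(2 / c_in)),
      nrow = config$latent_dim
    )
    params$fc1_b <- numeric(config$latent_dim)
    params$fc2_W <- matrix(
      rnorm(config$latent_dim, 0, sqrt(1 / config$latent_dim)),
      nrow = 1
    )
    params$fc2_b <- 0
  })
  structure(
    list(
      params = params, stats = stats, config = config,
      input_shape = as.integer(input_shape), trained = FALSE, history = NULL
    ),
    class = "segment_encoder"
  )
}

#' @export
print.segment_encoder <- function(x, ...) {
  cat(sprintf(
    "<segment_encoder> %d residual blocks (%s ch), latent %d, input %s, %s (%d params)\n",
    x$config$n_blocks, paste(x$config$channels, collapse = "/"),
    x$config$latent_dim, paste(x$input_shape, collapse = "x"),
    if (x$trained) "trained" else "untrained", n_encoder_params(x)
  ))
  invisible(x)
}

n_encoder_params <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

# Spectrograms arrive (F, T, C, N); the nn primitives use channel-first.
to_channel_first <- function(x) aperm(x, c(3, 1, 2, 4))

# Full forward pass on a channel-first (C, F, T, N) batch. Returns logits
# (1 x N), latent (latent_dim x N), caches for backprop and (in training
# mode) updated BN running stats.
encoder_forward <- function(model, x, training = FALSE) {
  cfg <- model$config
  p <- model$params
  stats <- model$stats
  caches <- list()
  h <- x
  for (b in seq_len(cfg$n_blocks)) {
    cb <- list()
    nm_a <- sprintf("conv%da", b)
    cv <- conv2d_forward(h, p[[paste0(nm_a, "_W")]], p[[paste0(nm_a, "_b")]],
      cfg$kernel_size)
    cb$conv_a <- cv$cache
    bn <- bn_forward(cv$out, p[[sprintf("bn%da_gamma", b)]],
      p[[sprintf("bn%da_beta", b)]], stats[[sprintf("bn%da", b)]], training)
    stats[[sprintf("bn%da", b)]] <- bn$running
    cb$bn_a <- bn$cache
    rl <- relu_forward(bn$out)
    cb$relu_a <- rl$cache
    nm_b <- sprintf("conv%db", b)
    cv2 <- conv2d_forward(rl$out, p[[paste0(nm_b, "_W")]], p[[paste0(nm_b, "_b")]],
      cfg$kernel_size)
    cb$conv_b <- cv2$cache
    bn2 <- bn_forward(cv2$out, p[[sprintf("bn%db_gamma", b)]],
      p[[sprintf("bn%db_beta", b)]], stats[[sprintf("bn%db", b)]], training)
    stats[[sprintf("bn%db", b)]] <- bn2$running
    cb$bn_b <- bn2$cache
    proj_nm <- sprintf("proj%d_W", b)
    if (!is.null(p[[proj_nm]])) {
      pj <- proj_forward(h, p[[proj_nm]])
      cb$proj <- pj$cache
      skip <- pj$out
    } else {
      skip <- h
    }
    summed <- bn2$out + skip
    rl2 <- relu_forward(summed)
    cb$relu_out <- rl2$cache
    h <- rl2$out
    if (b < cfg$n_blocks) {
      pl <- avgpool2_forward(h)
      cb$pool <- pl$cache
      h <- pl$out
    }
    caches[[b]] <- cb
  }
  gp <- gap_forward(h)
  fc1 <- dense_forward(gp$out, p$fc1_W, p$fc1_b)
  rl3 <- relu_forward(fc1$out)
  latent <- rl3$out
  fc2 <- dense_forward(latent, p$fc2_W, p$fc2_b)
  list(
    logits = fc2$out, latent = latent, stats = stats,
    caches = list(blocks = caches, gap = gp$cache, fc1 = fc1$cache,
      relu_latent = rl3$cache, fc2 = fc2$cache)
  )
}

encoder_backward <- function(model, fwd, dlogits) {
  cfg <- model$config
  p <- model$params
  grads <- list()
  d2 <- dense_backward(dlogits, p$fc2_W, fwd$caches$fc2)
  grads$fc2_W <- d2$dw
  grads$fc2_b <- d2$db
  dlat <- relu_backward(d2$dx, fwd$caches$relu_latent)
  d1 <- dense_backward(dlat, p$fc1_W, fwd$caches$fc1)
  grads$fc1_W <- d1$dw
  grads$fc1_b <- d1$db
  dh <- gap_backward(d1$dx, fwd$caches$gap)
  for (b in rev(seq_len(cfg$n_blocks))) {
    cb <- fwd$caches$blocks[[b]]
    if (b < cfg$n_blocks) dh <- avgpool2_backward(dh, cb$pool)
    dsum <- relu_backward(dh, cb$relu_out)
    # branch: bn_b <- conv_b <- relu_a <- bn_a <- conv_a
    bb <- bn_backward(dsum, p[[sprintf("bn%db_gamma", b)]], cb$bn_b)
    grads[[sprintf("bn%db_gamma", b)]] <- bb$dgamma
    grads[[sprintf("bn%db_beta", b)]] <- bb$dbeta
    cvb <- conv2d_backward(bb$dx, p[[sprintf("conv%db_W", b)]], cb$conv_b)
    grads[[sprintf("conv%db_W", b)]] <- cvb$dw
    grads[[sprintf("conv%db_b", b)]] <- cvb$db
    dra <- relu_backward(cvb$dx, cb$relu_a)
    ba <- bn_backward(dra, p[[sprintf("bn%da_gamma", b)]], cb$bn_a)
    grads[[sprintf("bn%da_gamma", b)]] <- ba$dgamma
    grads[[sprintf("bn%da_beta", b)]] <- ba$dbeta
    cva <- conv2d_backward(ba$dx, p[[sprintf("conv%da_W", b)]], cb$conv_a)
    grads[[sprintf("conv%da_W", b)]] <- cva$dw
    grads[[sprintf("conv%da_b", b)]] <- cva$db
    proj_nm <- sprintf("proj%d_W", b)
    if (!is.null(p[[proj_nm]])) {
      pj <- proj_backward(dsum, p[[proj_nm]], cb$proj)
      grads[[proj_nm]] <- pj$dw
      dh <- cva$dx + pj$dx
    } else {
      dh <- cva$dx + dsum
    }
  }
  grads
}

# Loss + gradients on one minibatch (training mode). Used by the training
# loop and by the finite-difference gradient checks.
encoder_loss_grads <- function(model, x, y, weights = NULL) {
  fwd <- encoder_forward(model, x, training = TRUE)
  bce <- bce_with_logits(fwd$logits, y, weights)
  grads <- encoder_backward(model, fwd, bce$dlogits)
  list(loss = bce$loss, grads = grads, stats = fwd$stats, prob = bce$prob)
}

# `x` channel-first.
encoder_eval_loss <- function(model, x, y, weights = NULL, batch_size = 256L) {
  n <- dim(x)[4]
  total <- 0
  wtot <- 0
  for (s in seq(1L, n, by = batch_size)) {
    e <- min(s + batch_size - 1L, n)
    xb <- x[, , , s:e, drop = FALSE]
    fwd <- encoder_forward(model, xb, training = FALSE)
    wb <- if (is.null(weights)) rep(1, e - s + 1L) else weights[s:e]
    bce <- bce_with_logits(fwd$logits, y[s:e], wb)
    total <- total + bce$loss * sum(wb)
    wtot <- wtot + sum(wb)
  }
  total / wtot
}

#' Train the segment encoder
#'
#' Minimises binary cross-entropy on segment-wise pAF labels with Adam.
#' Validation is patient-wise within the training data (a fraction
#' `val_frac` of patients, stratified by label, never segment-wise — segments
#' of one patient are correlated). Training stops early when validation loss
#' has not improved for `patience` epochs and returns the parameters of the
#' best validation epoch. Fully deterministic given the config seed.
#'
#' @param model An untrained [build_encoder()] model (built if `NULL`).
#' @param x Spectrogram array `F x T x channels x n_segments`
#'   (see [segment_spectrograms()]).
#' @param meta Segment metadata tibble with `patient_id` and logical `label`.
#' @param config An [encoder_config()] (used when `model` is `NULL`).
#' @return A trained `segment_encoder` with a `history` tibble
#'   (`epoch`, `train_loss`, `val_loss`).
#' @export
train_segment_model <- function(model = NULL, x, meta, config = encoder_config()) {
  if (is.null(model)) model <- build_encoder(config, dim(x)[1:3])
  cfg <- model$config
  y <- as.numeric(meta$label)
  if (length(unique(y)) < 2L) {
    abort("training data contain a single class", class = "holterpaf_single_class")
  }
  n <- dim(x)[4]
  stopifnot(nrow(meta) == n)

  withr::with_seed(cfg$seed, {
    # patient-wise stratified validation split
    pat <- dplyr::distinct(meta, .data$patient_id, .data$label)
    val_ids <- unlist(lapply(split(pat$patient_id, pat$label), function(ids) {
      n_val <- max(1L, floor(length(ids) * cfg$val_frac))
      if (length(ids) <= 1L) character(0) else sample(ids, n_val)
    }))
    is_val <- meta$patient_id %in% val_ids
    if (!any(is_val) || all(is_val)) {
      is_val <- seq_len(n) %in% sample.int(n, max(1L, floor(n * cfg$val_frac)))
    }
    tr_idx <- which(!is_val)
    va_idx <- which(is_val)
    if (length(unique(y[tr_idx])) < 2L) {
      abort("training split lost a class; provide more patients",
        class = "holterpaf_single_class")
    }
    weights <- NULL
    if (cfg$class_weighting) {
      prev <- mean(y[tr_idx])
      weights <- ifelse(y == 1, 0.5 / prev, 0.5 / (1 - prev))
    }
    xcf <- to_channel_first(x)
    xva <- xcf[, , , va_idx, drop = FALSE]
    yva <- y[va_idx]
    wva <- if (is.null(weights)) NULL else weights[va_idx]

    opt <- adam_init(model$params)
    best <- list(loss = Inf, params = model$params, stats = model$stats, epoch = 0L)
    history <- vector("list", cfg$max_epochs)
    stall <- 0L
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample(tr_idx)
      ep_loss <- 0
      n_seen <- 0L
      for (s in seq(1L, length(ord), by = cfg$batch_size)) {
        e <- min(s + cfg$batch_size - 1L, length(ord))
        bi <- ord[s:e]
        xb <- xcf[, , , bi, drop = FALSE]
        wb <- if (is.null(weights)) NULL else weights[bi]
        lg <- encoder_loss_grads(model, xb, y[bi], wb)
        model$stats <- lg$stats
        step <- adam_step(model$params, lg$grads, opt, cfg$learning_rate)
        model$params <- step$params
        opt <- step$state
        ep_loss <- ep_loss + lg$loss * length(bi)
        n_seen <- n_seen + length(bi)
      }
      val_loss <- encoder_eval_loss(model, xva, yva, wva)
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = ep_loss / n_seen, val_loss = val_loss
      )
      if (val_loss < best$loss - 1e-9) {
        best <- list(loss = val_loss, params = model$params,
          stats = model$stats, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$patience) break
      }
    }
    model$params <- best$params
    model$stats <- best$stats
    model$trained <- TRUE
    model$history <- dplyr::bind_rows(history)
    model$best_epoch <- best$epoch
    model$val_patients <- sort(unique(meta$patient_id[va_idx]))
  })
  model
}

#' Score segments with a trained encoder
#'
#' Runs the encoder in evaluation mode (batch-norm running statistics, so
#' batching does not change results) and returns, per segment, the pAF
#' probability (`sigmoid(logit)`) and the latent embedding.
#'
#' @param model A trained `segment_encoder`.
#' @param x Spectrogram array `F x T x channels x n_segments`.
#' @param batch_size Evaluation batch size (no effect on values).
#' @return Tibble with columns `probability`, `logit` and a matrix column
#'   `latent` (`n_segments x latent_dim`), in input order.
#' @export
score_segments <- function(model, x, batch_size = 256L) {
  stopifnot(inherits(model, "segment_encoder"))
  if (!all(dim(x)[1:3] == model$input_shape)) {
    abort(sprintf(
      "spectrogram shape %s does not match the model input %s",
      paste(dim(x)[1:3], collapse = "x"),
      paste(model$input_shape, collapse = "x")
    ))
  }
  n <- dim(x)[4]
  xcf <- to_channel_first(x)
  logits <- numeric(n)
  latent <- matrix(0, nrow = n, ncol = model$config$latent_dim)
  for (s in seq(1L, n, by = batch_size)) {
    e <- min(s + batch_size - 1L, n)
    fwd <- encoder_forward(model, xcf[, , , s:e, drop = FALSE], training = FALSE)
    logits[s:e] <- as.numeric(fwd$logits)
    latent[s:e, ] <- t(fwd$latent)
  }
  out <- tibble::tibble(probability = 1 / (1 + exp(-logits)), logit = logits)
  out$latent <- latent
  out
}

#' @method tidy segment_encoder
#' @export
tidy.segment_encoder <- function(x, ...) {
  if (is.null(x$history)) {
    return(tibble::tibble(epoch = integer(0), train_loss = numeric(0),
      val_loss = numeric(0)))
  }
  x$history
}

#' @method glance segment_encoder
#' @export
glance.segment_encoder <- function(x, ...) {
  tibble::tibble(
    n_params = n_encoder_params(x),
    n_blocks = x$config$n_blocks,
    latent_dim = x$config$latent_dim,
    trained = x$trained,
    best_epoch = x$best_epoch %||% NA_integer_,
    best_val_loss = if (is.null(x$history)) NA_real_ else min(x$history$val_loss)
  )
}

#' Save / load a segment encoder checkpoint
#'
#' Single-file checkpoint containing the weights, batch-norm statistics,
#' configuration, input shape and training history.
#'
#' @param model A `segment_encoder`.
#' @param path Checkpoint path.
#' @export
save_encoder <- function(model, path) {
  stopifnot(inherits(model, "segment_encoder"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_encoder
#' @export
load_encoder <- function(path) {
  structure(readRDS(path), class = "segment_encoder")
}
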