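# Toy spectrogram batches with a controllable class-mean shift: enough
# structure for the encoder to learn quickly, tiny enough to keep tests fast.
toy_batch <- function(n, shift, shape = c(12, 10, 3), seed = 1) {
  set.seed(seed)
  n_pat <- max(2L, n %/% 10L)
  meta <- tibble::tibble(
    patient_id = sprintf("T%03d", rep(seq_len(n_pat), length.out = n))
  )
  lab_pat <- rep(c(FALSE, TRUE), length.out = n_pat)
  meta$label <- lab_pat[as.integer(factor(meta$patient_id))]
  x <- array(abs(rnorm(prod(shape) * n)), dim = c(shape, n)) # (F, T, C, N)
  x[, , , meta$label] <- x[, , , meta$label] + shift
  list(x = x, meta = meta)
}

tiny_cfg <- function(...) {
  encoder_config(n_blocks = 2, channels = c(4, 6), latent_dim = 5,
    batch_size = 16, max_epochs = 4, patience = 2, learning_rate = 3e-3,
    seed = 11, ...)
}

test_that("the encoder emits one logit and a latent vector per segment", {
  m <- build_encoder(tiny_cfg(), c(26, 34, 3))
  x <- array(rnorm(3 * 26 * 34 * 7), dim = c(3, 26, 34, 7))
  fwd <- holterpaf:::encoder_forward(m, x)
  expect_equal(dim(fwd$logits), c(1L, 7L))
  expect_equal(dim(fwd$latent), c(5L, 7L))
  expect_true(all(is.finite(fwd$latent)))
})

test_that("parameter count is a pure function of the configuration", {
  m1 <- build_encoder(tiny_cfg(), c(26, 34, 3))
  m2 <- build_encoder(tiny_cfg(), c(26, 34, 3))
  expect_identical(
    holterpaf:::n_encoder_params(m1), holterpaf:::n_encoder_params(m2)
  )
  expect_identical(m1$params, m2$params) # same seed, same init
  # hand count for one conv layer: C_out x (C_in k^2) weights + C_out biases
  expect_equal(dim(m1$params$conv1a_W), c(4L, 3L * 9L))
})

test_that("degenerate encoder configurations are rejected", {
  expect_error(encoder_config(n_blocks = 0), "n_blocks")
  expect_error(encoder_config(latent_dim = 0), "latent_dim")
  expect_error(encoder_config(learning_rate = 0), "learning_rate")
  expect_error(
    encoder_config(n_blocks = 6, channels = rep(8, 6)) |>
      build_encoder(c(8, 8, 3)),
    "collapsed"
  )
})

test_that("backpropagated gradients match finite differences everywhere", {
  set.seed(42)
  m <- build_encoder(tiny_cfg(), c(8, 9, 3))
  x <- array(rnorm(3 * 8 * 9 * 5), dim = c(3, 8, 9, 5))
  y <- c(1, 0, 1, 0, 1)
  w <- c(1, 2, 1, 0.5, 1) # exercise the weighted-loss path too
  lg <- holterpaf:::encoder_loss_grads(m, x, y, w)
  eps <- 1e-5
  for (nm in names(m$params)) {
    p <- m$params[[nm]]
    idx <- sample(length(p), min(3L, length(p)))
    for (i in idx) {
      mp <- m
      mp$params[[nm]][i] <- p[i] + eps
      mm <- m
      mm$params[[nm]][i] <- p[i] - eps
      num <- (holterpaf:::encoder_loss_grads(mp, x, y, w)$loss -
        holterpaf:::encoder_loss_grads(mm, x, y, w)$loss) / (2 * eps)
      ana <- lg$grads[[nm]][i]
      expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-4,
        label = sprintf("gradient of %s[%d]", nm, i))
    }
  }
})

test_that("training reduces the loss on separable data, deterministically", {
  tb <- toy_batch(160, shift = 1.0, seed = 21)
  m1 <- train_segment_model(NULL, tb$x, tb$meta,
    tiny_cfg())
  h <- tidy(m1)
  expect_gte(nrow(h), 2L)
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1]) # loss goes down
  expect_true(m1$trained)

  m2 <- train_segment_model(NULL, tb$x, tb$meta,
    tiny_cfg())
  expect_equal(tidy(m2)$val_loss, h$val_loss, tolerance = 1e-10) # same seed

  one_class <- tb$meta
  one_class$label <- TRUE
  expect_error(
    train_segment_model(NULL, tb$x, one_class, tiny_cfg()),
    class = "holterpaf_single_class"
  )
})

test_that("label-shuffled training yields chance-level held-out discrimination", {
  tb <- toy_batch(300, shift = 0.8, seed = 33)
  x <- tb$x
  meta <- tb$meta
  set.seed(99)
  # shuffle labels patient-wise so no real signal remains
  pats <- unique(meta$patient_id)
  new_lab <- sample(rep(c(TRUE, FALSE), length.out = length(pats)))
  meta$label <- new_lab[match(meta$patient_id, pats)]
  te <- which(meta$patient_id %in% pats[1:8])
  tr <- setdiff(seq_len(nrow(meta)), te)
  m <- train_segment_model(NULL, x[, , , tr, drop = FALSE], meta[tr, ], tiny_cfg())
  sc <- score_segments(m, x[, , , te, drop = FALSE])
  expect_gt(auroc(sc$probability, meta$label[te]), 0.35)
  expect_lt(auroc(sc$probability, meta$label[te]), 0.65)
})

test_that("scoring is order-preserving, batch-invariant and sigmoid-consistent", {
  tb <- toy_batch(40, shift = 0.5, seed = 7)
  x <- tb$x
  m <- train_segment_model(NULL, x, tb$meta, tiny_cfg())

  sc_all <- score_segments(m, x, batch_size = 40)
  sc_split <- dplyr::bind_rows(
    score_segments(m, x[, , , 1:13, drop = FALSE]),
    score_segments(m, x[, , , 14:40, drop = FALSE])
  )
  expect_equal(sc_all$probability, sc_split$probability, tolerance = 1e-12)
  expect_equal(sc_all$latent, sc_split$latent, tolerance = 1e-12)

  dup <- x[, , , c(5, 5), drop = FALSE]
  sd <- score_segments(m, dup)
  expect_equal(sd$probability[1], sd$probability[2])

  expect_equal(sc_all$probability, 1 / (1 + exp(-sc_all$logit)), tolerance = 1e-12)
  expect_error(score_segments(m, x[1:10, , , , drop = FALSE]), "shape")
})

test_that("checkpoints round-trip weights, config and history", {
  tb <- toy_batch(40, shift = 0.5, seed = 3)
  x <- tb$x
  m <- train_segment_model(NULL, x, tb$meta, tiny_cfg())
  path <- withr::local_tempfile(fileext = ".rds")
  save_encoder(m, path)
  m2 <- load_encoder(path)
  expect_equal(
    score_segments(m2, x)$probability, score_segments(m, x)$probability
  )
  expect_equal(glance(m2)$n_params, glance(m)$n_params)
})
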