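# Encoder-decoder reconstruction training. The fusion block is not part of
# the training graph: the network learns to reproduce each source image
# (both modalities pooled into one reconstruction set, consistent with the
# shared siamese encoder), driven by a mixed pixel + gradient loss.

#' Training configuration
#'
#' @param mu weight of the pixel (intensity) loss term.
#' @param phi weight of the gradient (structure) loss term.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param epochs number of passes over the training set.
#' @param seed seed controlling initialization and shuffling; two runs with
#'   the same seed produce identical loss histories on CPU.
#' @param checkpoint_every write a checkpoint every this many epochs
#'   (`Inf` disables periodic checkpoints).
#' @param grad_op gradient operator of the loss: 3x3 Sobel (default) or
#'   forward differences.
#' @return A `train_config` list; the optimizer is Adam.
#' @export
train_config <- function(mu = 1, phi = 1, lr = 1e-4, batch_size = 16L,
                         epochs = 50L, seed = 1L, checkpoint_every = Inf,
                         grad_op = c("sobel", "diff")) {
  grad_op <- match.arg(grad_op)
  if (mu < 0 || phi < 0 || mu + phi <= 0) {
    stop("loss weights must be non-negative with mu + phi > 0")
  }
  structure(list(mu = mu, phi = phi, lr = lr,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 optimizer = "adam", checkpoint_every = checkpoint_every,
                 grad_op = grad_op),
            class = "train_config")
}

# fixed gradient-operator kernels as a 3x3x1x2 (or 2x2x1x2) conv weight
grad_kernels <- function(grad_op) {
  if (grad_op == "sobel") {
    gx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)        # d/dcol
    array(c(gx, t(gx)), c(3L, 3L, 1L, 2L))
  } else {
    gx <- matrix(c(0, 0, -1, 1), 2, 2)
    gy <- matrix(c(-1, 1, 0, 0), 2, 2)
    array(c(gx, gy), c(2L, 2L, 1L, 2L))
  }
}

# gradient responses of a batch, mirror-padded so spatial size is kept
grad_responses <- function(tape, x, grad_op) {
  k <- ad_const(tape, grad_kernels(grad_op))
  b <- ad_const(tape, numeric(2L))
  if (grad_op == "sobel") {
    ad_conv2d(tape, ad_pad_reflect(tape, x, 1L), k, b, 0L)
  } else {
    ad_conv2d(tape, ad_pad_reflect(tape, x, 1L), k, b, 0L) # 2x2 kernel: H+1 out
  }
}

#' Mixed pixel + gradient reconstruction loss
#'
#' `L = (1/WH) * (mu * ||I_F - I_in||^2 + phi * ||grad I_F - grad I_in||^2)`,
#' with the gradient operator's two directional responses (default: Sobel,
#' mirror-padded) stacked before the squared norm. For image batches the
#' per-image losses are averaged.
#'
#' @param i_f,i_in reconstructed and reference images: matrices, or lists
#'   of matrices of one shape.
#' @param mu,phi non-negative term weights.
#' @param grad_op `"sobel"` or `"diff"`.
#' @return A `loss_breakdown` list: `total`, `pixel_term`, `gradient_term`,
#'   where `total = mu * pixel_term + phi * gradient_term`.
#' @export
mixed_loss <- function(i_f, i_in, mu = 1, phi = 1, grad_op = "sobel") {
  if (is.matrix(i_f)) i_f <- list(i_f)
  if (is.matrix(i_in)) i_in <- list(i_in)
  if (length(i_f) != length(i_in)) stop("batch sizes differ")
  x <- as_batch(i_f)
  y <- as_batch(i_in)
  if (!identical(dim(x), dim(y))) stop("image shapes differ")
  d <- dim(x)
  wh <- d[1L] * d[2L]
  n <- d[4L]
  tape <- new_tape()
  xn <- ad_const(tape, x)
  pixel <- sum((x - y)^2) / (wh * n)
  gx <- grad_responses(tape, xn, grad_op)$value
  gy <- grad_responses(tape, ad_const(tape, y), grad_op)$value
  gradient <- sum((gx - gy)^2) / (wh * n)
  structure(list(total = mu * pixel + phi * gradient,
                 pixel_term = pixel, gradient_term = gradient),
            class = "loss_breakdown")
}

as_batch <- function(images) {
  mats <- lapply(images, function(m) unclass(as.matrix(m)))
  d <- dim(mats[[1L]])
  arr <- array(0, c(d[1L], d[2L], 1L, length(mats)))
  for (i in seq_along(mats)) {
    if (!identical(dim(mats[[i]]), d)) stop("images differ in shape")
    arr[, , 1L, i] <- mats[[i]]
  }
  arr
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# one forward/backward pass; returns loss terms and parameter gradients
train_step <- function(batch, params, net_cfg, cfg) {
  tape <- new_tape()
  P <- params_to_nodes(tape, params)
  x <- ad_const(tape, batch)
  rec <- fwd_decoder(tape, fwd_encoder(tape, x, P, net_cfg), P, net_cfg)
  wh <- dim(batch)[1L] * dim(batch)[2L]
  n <- dim(batch)[4L]
  pixel <- ad_mse(tape, rec, batch, wh * n)
  target_grad <- grad_responses(tape, x, cfg$grad_op)$value
  gradient <- ad_mse(tape, grad_responses(tape, rec, cfg$grad_op),
                     target_grad, wh * n)
  total <- ad_wsum(tape, list(pixel, gradient), c(cfg$mu, cfg$phi))
  ad_backward(tape, total)
  grads <- lapply(P, function(nd) nd$grad)
  list(total = total$value, pixel = pixel$value, gradient = gradient$value,
       grads = grads)
}

#' Train the encoder-decoder by image reconstruction
#'
#' Adam on the mixed pixel + gradient loss; the fusion rule takes no part
#' in training, so the gradient graph contains exactly the encoder and
#' decoder parameters. Fully seeded: initialization and shuffling derive
#' from `cfg$seed`, making CPU runs bit-reproducible.
#'
#' @param dataset list of training images (`[0,1]` matrices); pool the CT
#'   and MRI members of each pair, each image an independent
#'   reconstruction target.
#' @param cfg a [train_config()].
#' @param net_cfg a [net_config()].
#' @param weights optional starting `net_weights`; freshly initialized from
#'   `cfg$seed` when omitted.
#' @param checkpoint_dir directory for periodic checkpoints (optional).
#' @param verbose print one log line per epoch.
#' @return List with `weights` (trained `net_weights`) and `history`
#'   (data frame: epoch, mean_loss, pixel_term, gradient_term).
#' @export
train <- function(dataset, cfg = train_config(), net_cfg = net_config_small(),
                  weights = NULL, checkpoint_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"), inherits(net_cfg, "net_config"))
  if (length(dataset) == 0L) stop("empty training set")
  if (is.null(weights)) weights <- init_net_weights(net_cfg, cfg$seed)
  params <- weights$params
  history <- data.frame(epoch = integer(0), mean_loss = numeric(0),
                        pixel_term = numeric(0), gradient_term = numeric(0))
  if (cfg$epochs == 0L) {
    return(list(weights = weights, history = history))
  }
  state <- adam_init(params)
  n <- length(dataset)
  with_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$epochs)) {
      perm <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      tot <- pix <- grd <- 0
      for (s in starts) {
        idx <- perm[s:min(s + cfg$batch_size - 1L, n)]
        batch <- as_batch(dataset[idx])
        step <- train_step(batch, params, net_cfg, cfg)
        if (!is.finite(step$total)) {
          stop("training diverged (non-finite loss) at epoch ", epoch,
               "; lower the learning rate")
        }
        upd <- adam_step(params, step$grads, state, cfg$lr)
        params <- upd$params
        state <- upd$state
        w <- length(idx) / n
        tot <- tot + step$total * w
        pix <- pix + step$pixel * w
        grd <- grd + step$gradient * w
      }
      history[nrow(history) + 1L, ] <- list(epoch, tot, pix, grd)
      if (verbose) {
        message(sprintf("epoch %d, mean_loss %.6g, pixel_term %.6g, gradient_term %.6g",
                        epoch, tot, pix, grd))
      }
      weights$params <- params
      weights$epochs <- weights$epochs + 1L
      if (!is.null(checkpoint_dir) && is.finite(cfg$checkpoint_every) &&
          epoch %% cfg$checkpoint_every == 0L) {
        dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
        save_net_weights(weights,
                         file.path(checkpoint_dir, sprintf("epoch_%04d.rds", epoch)))
      }
    }
  })
  list(weights = weights, history = history)
}

#' Mean reconstruction PSNR of a model on held-out images
#'
#' Each image is passed through encode/decode and compared with itself by
#' peak signal-to-noise ratio; a perfect reconstruction (zero MSE) reports
#' the cap instead of infinity.
#'
#' @param weights a `net_weights` object.
#' @param heldout list of `[0,1]` image matrices.
#' @param cap sentinel PSNR (dB) for zero-error reconstructions.
#' @return Mean PSNR in dB.
#' @export
reconstruction_quality <- function(weights, heldout, cap = 100) {
  if (length(heldout) == 0L) stop("`heldout` must be nonempty")
  psnr <- vapply(heldout, function(img) {
    m <- unclass(as.matrix(img))
    rec <- decode(encode(m, weights), weights, clip = TRUE)
    mse <- mean((rec - m)^2)
    if (mse == 0) cap else min(cap, 10 * log10(1 / mse))
  }, 0)
  mean(psnr)
}
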