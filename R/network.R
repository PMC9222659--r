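# The siamese encoder (multi-scale dense convolution block + mixed
# attention block) and the five-layer convolutional decoder.
#
# All convolutions are stride 1 with zero padding chosen to preserve the
# spatial size, which the attention rescaling (elementwise products with
# per-channel and per-pixel gates) requires. The same weights object serves
# both the CT and the MRI input: the encoder is siamese by construction.

#' Network architecture configuration
#'
#' The reference architecture uses four branches of 60 channels whose
#' concatenation gives the 240-channel encoder output consumed by a decoder
#' with channel schedule 240-128-64-32-16-1; only the 240-to-1 decoder
#' schedule is fixed by the design, the branch width following from
#' 4 x 60 = 240 as the single consistent reading.
#'
#' @param shallow_channels channels of the initial 3x3 convolution.
#' @param branch_channels channels of each of the four multi-scale branches.
#' @param reduction channel-attention bottleneck ratio (output channels must
#'   be divisible by it).
#' @param sa_kernel spatial-attention kernel size (odd).
#' @param decoder_channels input channels of the five decoder layers; the
#'   last layer always outputs one channel.
#' @param dense_variant `"res2db"` (dense concatenations across all previous
#'   branches) or `"res2b"` (each branch sees only its predecessor), the
#'   ablation switch.
#' @param mc_activation activation after every MC-block convolution
#'   including the 1x1 integration layer.
#' @param ma_activation activation of the mixed-attention 1x1 fusion layer.
#' @return A `net_config` list; `n_branches` is fixed at 4 and
#'   `encoder_out_channels` at `4 * branch_channels`.
#' @export
net_config <- function(shallow_channels = 60L, branch_channels = 60L,
                       reduction = 16L, sa_kernel = 7L,
                       decoder_channels = c(240L, 128L, 64L, 32L, 16L),
                       dense_variant = c("res2db", "res2b"),
                       mc_activation = c("relu", "linear"),
                       ma_activation = c("linear", "relu")) {
  dense_variant <- match.arg(dense_variant)
  mc_activation <- match.arg(mc_activation)
  ma_activation <- match.arg(ma_activation)
  n_branches <- 4L
  out <- n_branches * as.integer(branch_channels)
  if (length(decoder_channels) != 5L) {
    stop("the decoder has exactly five convolution layers")
  }
  if (decoder_channels[1L] != out) {
    stop("decoder input channels (", decoder_channels[1L],
         ") must equal encoder output channels (", out, ")")
  }
  if (out %% reduction != 0L) {
    stop("encoder output channels must be divisible by `reduction`")
  }
  if (sa_kernel %% 2L != 1L) stop("`sa_kernel` must be odd")
  structure(list(shallow_channels = as.integer(shallow_channels),
                 branch_channels = as.integer(branch_channels),
                 n_branches = n_branches,
                 encoder_out_channels = out,
                 reduction = as.integer(reduction),
                 sa_kernel = as.integer(sa_kernel),
                 decoder_channels = as.integer(decoder_channels),
                 dense_variant = dense_variant,
                 mc_activation = mc_activation,
                 ma_activation = ma_activation),
            class = "net_config")
}

#' Reduced-width configuration for CPU-scale experiments
#'
#' Same topology as [net_config()] -- four dense branches, dual-pooling
#' mixed attention, five decoder layers -- at 6 channels per branch (24
#' encoder channels), the width this package uses for its single-core
#' training runs and tests.
#'
#' @param ... overrides passed on to [net_config()].
#' @export
net_config_small <- function(...) {
  args <- list(shallow_channels = 6L, branch_channels = 6L, reduction = 8L,
               decoder_channels = c(24L, 12L, 8L, 8L, 4L), ...)
  do.call(net_config, args[!duplicated(names(args), fromLast = TRUE)])
}

# named list of kernel shapes (kh, kw, in, out) for a configuration
layer_shapes <- function(cfg) {
  sc <- cfg$shallow_channels; bc <- cfg$branch_channels
  C <- cfg$encoder_out_channels
  sh <- list(shallow = c(3L, 3L, 1L, sc))
  for (i in 1:4) sh[[sprintf("b%d.c1", i)]] <- c(3L, 3L, sc, bc)
  for (i in 1:4) {
    cin <- if (cfg$dense_variant == "res2db") i * bc else min(i, 2L) * bc
    sh[[sprintf("b%d.c2", i)]] <- c(3L, 3L, cin, bc)
  }
  sh$integrate <- c(1L, 1L, 4L * bc, C)
  sh$ca.reduce <- c(1L, 1L, C, C %/% cfg$reduction)
  sh$ca.expand <- c(1L, 1L, C %/% cfg$reduction, C)
  sh$sa.conv <- c(cfg$sa_kernel, cfg$sa_kernel, 2L, 1L)
  sh$refine <- c(1L, 1L, 2L * C, C)
  dc <- c(cfg$decoder_channels, 1L)
  for (i in 1:5) sh[[sprintf("dec.l%d", i)]] <- c(3L, 3L, dc[i], dc[i + 1L])
  sh
}

#' Initialize network weights
#'
#' Kaiming fan-in initialization (kernels drawn from
#' `N(0, 2 / (kh*kw*c_in))`, biases zero), fully determined by `seed`.
#'
#' @param cfg a [net_config()].
#' @param seed integer seed.
#' @return A `net_weights` object: `params` (named kernel/bias arrays),
#'   the `cfg`, the `seed`, and an `epochs` counter.
#' @export
init_net_weights <- function(cfg, seed = 1L) {
  sh <- layer_shapes(cfg)
  params <- with_seed(seed, {
    p <- list()
    for (nm in names(sh)) {
      d <- sh[[nm]]
      sd <- sqrt(2 / (d[1L] * d[2L] * d[3L]))
      p[[paste0(nm, ".w")]] <- array(rnorm(prod(d), sd = sd), d)
      p[[paste0(nm, ".b")]] <- numeric(d[4L])
    }
    p
  })
  structure(list(params = params, cfg = cfg, seed = as.integer(seed),
                 epochs = 0L), class = "net_weights")
}

#' @export
print.net_weights <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0))
  cat(sprintf("<net_weights: %s variant, %d encoder channels, %s parameters, %d training epochs>\n",
              x$cfg$dense_variant, x$cfg$encoder_out_channels,
              format(np, big.mark = ","), x$epochs))
  invisible(x)
}

# wrap every parameter array in a tape node
params_to_nodes <- function(tape, params) {
  lapply(params, function(p) ad_param(tape, p))
}

mc_act <- function(tape, x, cfg) {
  if (cfg$mc_activation == "relu") ad_relu(tape, x) else x
}

conv_named <- function(tape, x, P, name, pad, need_gx = TRUE) {
  ad_conv2d(tape, x, P[[paste0(name, ".w")]], P[[paste0(name, ".b")]], pad,
            need_gx = need_gx)
}

# multi-scale dense convolution block: shallow conv, four branches of two
# 3x3 convs with dense (res2db) or chained (res2b) concatenation, then a
# 1x1 integration conv
fwd_mc <- function(tape, x, P, cfg) {
  f_in <- mc_act(tape, conv_named(tape, x, P, "shallow", 1L, need_gx = FALSE), cfg)
  f1 <- lapply(1:4, function(i) {
    mc_act(tape, conv_named(tape, f_in, P, sprintf("b%d.c1", i), 1L), cfg)
  })
  f2 <- vector("list", 4L)
  for (i in 1:4) {
    inp <- if (i == 1L) {
      f1[[1L]]
    } else if (cfg$dense_variant == "res2db") {
      ad_concat(tape, c(f2[seq_len(i - 1L)], f1[i]))
    } else {
      ad_concat(tape, list(f2[[i - 1L]], f1[[i]]))
    }
    f2[[i]] <- mc_act(tape, conv_named(tape, inp, P, sprintf("b%d.c2", i), 1L), cfg)
  }
  mc_act(tape, conv_named(tape, ad_concat(tape, f2), P, "integrate", 0L), cfg)
}

# dual-pooling channel attention: shared two-layer bottleneck on the
# spatially max- and average-pooled descriptors, summed, sigmoid-gated
fwd_ca <- function(tape, x, P) {
  bottleneck <- function(v) {
    conv_named(tape, ad_relu(tape, conv_named(tape, v, P, "ca.reduce", 0L)),
               P, "ca.expand", 0L)
  }
  mx <- bottleneck(ad_gpool_max(tape, x))
  av <- bottleneck(ad_gpool_avg(tape, x))
  m_c <- ad_sigmoid(tape, ad_add(tape, mx, av))
  ad_scale_channels(tape, x, m_c)
}

# dual-pooling spatial attention: channel max/avg maps, 7x7 conv, sigmoid
fwd_sa <- function(tape, x, P, cfg) {
  pooled <- ad_concat(tape, list(ad_cpool_max(tape, x), ad_cpool_avg(tape, x)))
  m_s <- ad_sigmoid(tape, conv_named(tape, pooled, P, "sa.conv",
                                     (cfg$sa_kernel - 1L) %/% 2L))
  ad_scale_pixels(tape, x, m_s)
}

fwd_ma <- function(tape, x, P, cfg) {
  refined <- conv_named(tape, ad_concat(tape, list(fwd_ca(tape, x, P),
                                                   fwd_sa(tape, x, P, cfg))),
                        P, "refine", 0L)
  if (cfg$ma_activation == "relu") ad_relu(tape, refined) else refined
}

fwd_encoder <- function(tape, x, P, cfg) {
  fwd_ma(tape, fwd_mc(tape, x, P, cfg), P, cfg)
}

# five 3x3 convs, ReLU on the first four, linear final layer
fwd_decoder <- function(tape, x, P, cfg) {
  h <- x
  for (i in 1:4) {
    h <- ad_relu(tape, conv_named(tape, h, P, sprintf("dec.l%d", i), 1L))
  }
  conv_named(tape, h, P, "dec.l5", 1L)
}

# ---- plain-array front ends -------------------------------------------------

as_stack4 <- function(x) {
  if (is.matrix(x)) {
    array(unclass(x), c(nrow(x), ncol(x), 1L, 1L))
  } else if (length(dim(x)) == 3L) {
    array(x, c(dim(x), 1L))
  } else if (length(dim(x)) == 4L) {
    x
  } else {
    stop("expected a matrix or a 3-d/4-d array")
  }
}

run_block <- function(x, weights, fn) {
  stopifnot(inherits(weights, "net_weights"))
  x4 <- as_stack4(x)
  tape <- new_tape()
  P <- params_to_nodes(tape, weights$params)
  out <- fn(tape, ad_const(tape, x4), P, weights$cfg)
  v <- out$value
  if (dim(v)[4L] == 1L) v <- array(v, dim(v)[1:3])
  v
}

#' Multi-scale convolution block features of a single-channel input
#'
#' @param x matrix or H x W x 1 array.
#' @param weights a `net_weights` object.
#' @return H x W x `encoder_out_channels` feature array.
#' @export
mc_block <- function(x, weights) {
  x4 <- as_stack4(x)
  if (dim(x4)[3L] != 1L) stop("MC block expects a single-channel input")
  run_block(x4, weights, fwd_mc)
}

#' Channel attention (dual-pooling squeeze-excitation) applied to a stack
#'
#' @param f_in H x W x C feature array with C equal to the encoder output
#'   channels.
#' @param weights a `net_weights` object.
#' @return Rescaled feature array of the same shape.
#' @export
channel_attention <- function(f_in, weights) {
  f4 <- as_stack4(f_in)
  if (dim(f4)[3L] != weights$cfg$encoder_out_channels) {
    stop("channel attention expects ", weights$cfg$encoder_out_channels,
         " channels, got ", dim(f4)[3L])
  }
  run_block(f4, weights, function(tape, x, P, cfg) fwd_ca(tape, x, P))
}

#' Spatial attention (channel-pooled 7x7 gate) applied to a stack
#'
#' @inheritParams channel_attention
#' @return Rescaled feature array of the same shape.
#' @export
spatial_attention <- function(f_in, weights) {
  run_block(f_in, weights, fwd_sa)
}

#' Mixed attention block: parallel channel and spatial attention, fused 1x1
#'
#' @inheritParams channel_attention
#' @return Refined feature array, channels back at the encoder width.
#' @export
ma_block <- function(f_in, weights) {
  run_block(f_in, weights, fwd_ma)
}

#' Encode an image into refined multi-scale features
#'
#' The same `weights` object encodes both modalities: the two encoder
#' branches of the fusion pipeline are one set of shared parameters.
#'
#' @param image a [gray_image] or `[0,1]` matrix.
#' @param weights a `net_weights` object.
#' @return H x W x `encoder_out_channels` feature array.
#' @export
encode <- function(image, weights) {
  run_block(as_stack4(unclass(image)), weights, fwd_encoder)
}

#' Decode a feature stack back to an image
#'
#' @param features H x W x C array with C matching the first decoder layer.
#' @param weights a `net_weights` object.
#' @param clip clip the output into `[0,1]` (export); the raw, possibly
#'   negative response of the linear final layer is returned when `FALSE`.
#' @return Numeric matrix (H x W).
#' @export
decode <- function(features, weights, clip = TRUE) {
  f4 <- as_stack4(features)
  if (dim(f4)[3L] != weights$cfg$decoder_channels[1L]) {
    stop("decoder expects ", weights$cfg$decoder_channels[1L],
         " channels, got ", dim(f4)[3L])
  }
  out <- run_block(f4, weights, fwd_decoder)
  m <- out[, , 1L]
  if (clip) pmin(pmax(m, 0), 1) else m
}

#' Save network weights with their configuration
#'
#' @param weights a `net_weights` object.
#' @param path destination file (RDS).
#' @export
save_net_weights <- function(weights, path) {
  stopifnot(inherits(weights, "net_weights"))
  saveRDS(weights, path)
  invisible(path)
}

#' Load network weights, verifying shape/configuration agreement
#'
#' @param path file written by [save_net_weights()].
#' @return A `net_weights` object.
#' @export
load_net_weights <- function(path) {
  w <- readRDS(path)
  if (!inherits(w, "net_weights")) stop("'", path, "' is not a net_weights file")
  sh <- layer_shapes(w$cfg)
  for (nm in names(sh)) {
    wk <- w$params[[paste0(nm, ".w")]]
    bk <- w$params[[paste0(nm, ".b")]]
    if (is.null(wk) || !identical(as.integer(dim(wk)), as.integer(sh[[nm]])) ||
        is.null(bk) || length(bk) != sh[[nm]][4L]) {
      stop("checkpoint layer '", nm, "' disagrees with its configuration")
    }
  }
  w
}
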