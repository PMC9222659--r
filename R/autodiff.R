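# Minimal reverse-mode automatic differentiation over 4-d feature stacks.
#
# Tensors are plain numeric arrays laid out H x W x C x N. A tape records
# nodes in creation order; ad_backward() walks it in reverse, calling each
# node's backward closure to accumulate gradients into its parents. Only the
# operations the encoder-decoder needs are provided; convolution itself is
# delegated to the compiled im2col + GEMM kernels in src/.

new_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 64L)
  t$n <- 0L
  t
}

ad_node <- function(tape, value, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backward <- backward
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) length(tape$nodes) <- 2L * length(tape$nodes)
  tape$nodes[[tape$n]] <- nd
  nd
}

# The first accumulated gradient may alias another node's buffer (ad_add
# propagates one object to both parents), so in-place addition is only safe
# once this node owns a freshly allocated sum.
ad_accum <- function(node, g) {
  if (is.null(node$grad)) {
    node$grad <- g
    node$owns_grad <- FALSE
  } else if (!isTRUE(node$owns_grad) || is.null(dim(node$grad))) {
    node$grad <- node$grad + g
    node$owns_grad <- TRUE
  } else {
    .add_into(node$grad, g)
  }
  invisible(NULL)
}

# leaf holding a constant (inputs, fixed kernels): no backward, grad ignored
ad_const <- function(tape, value) ad_node(tape, value)

# leaf holding a trainable parameter: grad is accumulated and read off after
ad_param <- function(tape, value) ad_node(tape, value)

#' @noRd
ad_backward <- function(tape, root) {
  root$grad <- 1
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd$grad)
  }
  invisible(NULL)
}

# need_gx = FALSE skips the input-gradient GEMM for constant inputs
# (the network input, fixed gradient-operator kernels)
ad_conv2d <- function(tape, x, w, b, pad, need_gx = TRUE) {
  val <- .conv2d_fwd(x$value, w$value, b$value, as.integer(pad))
  ad_node(tape, val, backward = function(g) {
    gr <- .conv2d_bwd(x$value, w$value, g, as.integer(pad), need_gx)
    if (need_gx) ad_accum(x, gr$gx)
    ad_accum(w, gr$gw)
    ad_accum(b, gr$gb)
  })
}

ad_relu <- function(tape, x) {
  v <- .relu_fwd(x$value)
  ad_node(tape, v, backward = function(g) ad_accum(x, .relu_bwd(v, g)))
}

ad_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-x$value))
  ad_node(tape, s, backward = function(g) ad_accum(x, g * s * (1 - s)))
}

ad_add <- function(tape, x, y) {
  ad_node(tape, x$value + y$value, backward = function(g) {
    ad_accum(x, g)
    ad_accum(y, g)
  })
}

# concatenate along the channel dimension
ad_concat <- function(tape, xs) {
  cs <- vapply(xs, function(x) dim(x$value)[3L], 0L)
  out <- .concat_c(lapply(xs, function(x) x$value))
  ad_node(tape, out, backward = function(g) {
    parts <- .split_c(g, cs)
    for (i in seq_along(xs)) ad_accum(xs[[i]], parts[[i]])
  })
}

# multiply H x W x C x N stack by a 1 x 1 x C x N channel descriptor
ad_scale_channels <- function(tape, x, s) {
  ad_node(tape, .scalec_fwd(x$value, s$value), backward = function(g) {
    gr <- .scalec_bwd(x$value, s$value, g)
    ad_accum(x, gr$gx)
    ad_accum(s, gr$gs)
  })
}

# multiply H x W x C x N stack by an H x W x 1 x N map, shared over channels
ad_scale_pixels <- function(tape, x, m) {
  ad_node(tape, .scalep_fwd(x$value, m$value), backward = function(g) {
    gr <- .scalep_bwd(x$value, m$value, g)
    ad_accum(x, gr$gx)
    ad_accum(m, gr$gm)
  })
}

# spatial (global) pooling: H x W x C x N -> 1 x 1 x C x N
ad_gpool_avg <- function(tape, x) {
  d <- dim(x$value)
  hw <- d[1L] * d[2L]
  v <- colMeans(matrix(x$value, hw))
  ad_node(tape, array(v, c(1L, 1L, d[3L], d[4L])), backward = function(g) {
    gv <- as.vector(g) / hw
    ad_accum(x, array(rep(gv, each = hw), d))
  })
}

ad_gpool_max <- function(tape, x) {
  d <- dim(x$value)
  hw <- d[1L] * d[2L]
  m <- matrix(x$value, hw)
  idx <- max.col(t(m), ties.method = "first")
  cols <- seq_len(ncol(m))
  v <- m[cbind(idx, cols)]
  ad_node(tape, array(v, c(1L, 1L, d[3L], d[4L])), backward = function(g) {
    gm <- matrix(0, hw, ncol(m))
    gm[cbind(idx, cols)] <- as.vector(g)
    ad_accum(x, array(gm, d))
  })
}

# channel pooling: H x W x C x N -> H x W x 1 x N
ad_cpool_avg <- function(tape, x) {
  d <- dim(x$value)
  perm <- aperm(x$value, c(1L, 2L, 4L, 3L))          # H W N C
  v <- rowMeans(matrix(perm, d[1L] * d[2L] * d[4L], d[3L]))
  ad_node(tape, array(v, c(d[1L], d[2L], 1L, d[4L])), backward = function(g) {
    gv <- as.vector(g) / d[3L]
    ga <- array(rep(gv, times = d[3L]), c(d[1L], d[2L], d[4L], d[3L]))
    ad_accum(x, aperm(ga, c(1L, 2L, 4L, 3L)))
  })
}

ad_cpool_max <- function(tape, x) {
  d <- dim(x$value)
  perm <- matrix(aperm(x$value, c(1L, 2L, 4L, 3L)), d[1L] * d[2L] * d[4L], d[3L])
  idx <- max.col(perm, ties.method = "first")
  rows <- seq_len(nrow(perm))
  v <- perm[cbind(rows, idx)]
  ad_node(tape, array(v, c(d[1L], d[2L], 1L, d[4L])), backward = function(g) {
    gm <- matrix(0, nrow(perm), d[3L])
    gm[cbind(rows, idx)] <- as.vector(g)
    ad_accum(x, aperm(array(gm, c(d[1L], d[2L], d[4L], d[3L])), c(1L, 2L, 4L, 3L)))
  })
}

reflect_idx <- function(n, p) {
  stopifnot(n > p)
  c(seq(p + 1L, 2L), seq_len(n), seq(n - 1L, n - p))
}

# mirror padding (edge not duplicated) of the two spatial dimensions
ad_pad_reflect <- function(tape, x, p) {
  d <- dim(x$value)
  ri <- reflect_idx(d[1L], p)
  ci <- reflect_idx(d[2L], p)
  val <- x$value[ri, ci, , , drop = FALSE]
  ad_node(tape, val, backward = function(g) {
    # fold padded rows back onto their sources, then padded columns
    gr <- array(0, c(d[1L], dim(g)[2L], d[3L], d[4L]))
    for (i in seq_along(ri)) {
      gr[ri[i], , , ] <- gr[ri[i], , , ] + g[i, , , ]
    }
    gx <- array(0, d)
    for (j in seq_along(ci)) {
      gx[, ci[j], , ] <- gx[, ci[j], , ] + gr[, j, , ]
    }
    ad_accum(x, gx)
  })
}

# mean squared deviation from a constant target: sum((x - t)^2) / denom
ad_mse <- function(tape, x, target, denom) {
  diffv <- x$value - target
  ad_node(tape, sum(diffv^2) / denom, backward = function(g) {
    ad_accum(x, (2 * g / denom) * diffv)
  })
}

# weighted sum of scalar nodes
ad_wsum <- function(tape, xs, w) {
  v <- sum(vapply(xs, function(x) x$value, 0) * w)
  ad_node(tape, v, backward = function(g) {
    for (i in seq_along(xs)) ad_accum(xs[[i]], g * w[i])
  })
}
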