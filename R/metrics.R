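# The six objective fusion-quality metrics: CC, MI, SF, PC, NCIE, SCD.
# All relate the fused image F to the two sources A (CT) and B (MRI),
# except SF which scores texture richness of F alone. Conventions this
# package fixes (documented because the literature varies): MI in bits from
# 256-bin joint histograms; SF divides by the number of differences, not
# pixels; NCIE uses 256 rank-based equal-population bins, base-256 logs,
# and the 3x3 nonlinear correlation matrix of (A, B, F); PC uses the
# log-Gabor phase-congruency front end with unit exponents; Pearson r of a
# constant signal is defined as 0.

# Pearson correlation with the constant-signal convention
pearson_r <- function(x, y) {
  x <- as.vector(x); y <- as.vector(y)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) return(0)
  stats::cor(x, y)
}

check_same_shape <- function(f, a, b) {
  f <- unclass(as.matrix(f)); a <- unclass(as.matrix(a)); b <- unclass(as.matrix(b))
  if (!identical(dim(f), dim(a)) || !identical(dim(f), dim(b))) {
    stop("images differ in shape")
  }
  list(f = f, a = a, b = b)
}

#' Correlation coefficient (CC) of a fused image with its sources
#'
#' Mean of the Pearson correlations `r(F, A)` and `r(F, B)`.
#'
#' @param f,a,b fused image and the two source images (equal-size matrices).
#' @return Value in `[-1, 1]`.
#' @export
metric_cc <- function(f, a, b) {
  im <- check_same_shape(f, a, b)
  (pearson_r(im$f, im$a) + pearson_r(im$f, im$b)) / 2
}

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

joint_hist256 <- function(x, y, levels = 256L) {
  qx <- quantize_levels(x, levels)
  qy <- quantize_levels(y, levels)
  counts <- tabulate(qx * levels + qy + 1L, nbins = levels * levels)
  counts / length(qx)
}

mi_bits <- function(x, y, levels = 256L) {
  pxy <- matrix(joint_hist256(x, y, levels), levels, levels) # x varies by column
  px <- colSums(pxy)
  py <- rowSums(pxy)
  entropy_bits(px) + entropy_bits(py) - entropy_bits(as.vector(pxy))
}

#' Mutual information (MI) metric
#'
#' `MI(F, A) + MI(F, B)` in bits, from 256-bin joint histograms of the
#' quantized intensities.
#'
#' @inheritParams metric_cc
#' @return Non-negative value.
#' @export
metric_mi <- function(f, a, b) {
  im <- check_same_shape(f, a, b)
  mi_bits(im$f, im$a) + mi_bits(im$f, im$b)
}

#' Spatial frequency (SF) of an image
#'
#' Root of the summed mean squared horizontal and vertical first
#' differences, each mean taken over the differences that exist
#' (`M*(N-1)` horizontally, `(M-1)*N` vertically).
#'
#' @param f image matrix, at least 2 x 2.
#' @return Non-negative value.
#' @export
metric_sf <- function(f) {
  f <- unclass(as.matrix(f))
  if (nrow(f) < 2L || ncol(f) < 2L) stop("image must be at least 2 x 2")
  dcol <- f[, -1L, drop = FALSE] - f[, -ncol(f), drop = FALSE]
  drow <- f[-1L, , drop = FALSE] - f[-nrow(f), , drop = FALSE]
  rf2 <- sum(dcol^2) / (nrow(f) * (ncol(f) - 1L))
  cf2 <- sum(drow^2) / ((nrow(f) - 1L) * ncol(f))
  sqrt(rf2 + cf2)
}

# stabilized correlation of two maps: (2 cov + eps) / (var_x + var_y + eps),
# which is 1 for identical maps (constant ones included) and lies in
# [-1, 1]; clipped to [0, 1] so the three-factor product stays in [0, 1]
map_corr <- function(x, y, eps = 1e-10) {
  x <- as.vector(x); y <- as.vector(y)
  cv <- mean((x - mean(x)) * (y - mean(y)))
  num <- 2 * cv + eps
  den <- mean((x - mean(x))^2) + mean((y - mean(y))^2) + eps
  min(1, max(0, num / den))
}

#' Phase-congruency (PC) preservation metric
#'
#' Computes phase-congruency, maximum-moment, and minimum-moment maps for
#' the fused image and both sources with the log-Gabor bank of
#' [phase_congruency()], takes for each map the better of its correlations
#' with the two sources, and multiplies the three factors (unit exponents).
#'
#' @inheritParams metric_cc
#' @param ... filter-bank parameters passed to [phase_congruency()].
#' @return Value in `[0, 1]`.
#' @export
metric_pc <- function(f, a, b, ...) {
  im <- check_same_shape(f, a, b)
  if (nrow(im$f) < 32L || ncol(im$f) < 32L) {
    stop("images must be at least 32 x 32 for the filter bank")
  }
  pf <- phase_congruency(im$f, ...)
  pa <- phase_congruency(im$a, ...)
  pb <- phase_congruency(im$b, ...)
  factor_of <- function(key) {
    max(map_corr(pa[[key]], pf[[key]]), map_corr(pb[[key]], pf[[key]]))
  }
  factor_of("pc") * factor_of("M") * factor_of("m")
}

# nonlinear correlation coefficient: joint entropy of rank-based
# equal-population 256-bin codes, base-256 logs; 1 for identical signals,
# ~0 for independent ones
ncc_rank <- function(x, y, b = 256L) {
  n <- length(x)
  bin <- function(v) {
    r <- rank(as.vector(v), ties.method = "first")
    pmin(b, ceiling(r * b / n))
  }
  bx <- bin(x); by <- bin(y)
  pj <- tabulate((bx - 1L) * b + by, nbins = b * b)
  pj <- pj[pj > 0] / n
  px <- tabulate(bx, nbins = b); px <- px[px > 0] / n
  py <- tabulate(by, nbins = b); py <- py[py > 0] / n
  hb <- function(p) -sum(p * log(p) / log(b))
  hb(px) + hb(py) - hb(pj)
}

#' Nonlinear correlation information entropy (NCIE)
#'
#' Builds the 3x3 nonlinear correlation matrix `R` of (A, B, F) with the
#' rank-binned nonlinear correlation coefficient (diagonal 1), takes its
#' eigenvalues, and returns `1 + sum_i (lambda_i / 3) log_256(lambda_i / 3)`
#' (zero eigenvalues contribute nothing).
#'
#' @inheritParams metric_cc
#' @return Value at most 1; equals 1 when the three images are identical.
#' @export
metric_ncie <- function(f, a, b) {
  im <- check_same_shape(f, a, b)
  sig <- list(im$a, im$b, im$f)
  R <- diag(3)
  for (i in 1:2) for (j in (i + 1):3) {
    R[i, j] <- R[j, i] <- ncc_rank(sig[[i]], sig[[j]])
  }
  lam <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  terms <- ifelse(lam > 0, (lam / 3) * log(lam / 3) / log(256), 0)
  1 + sum(terms)
}

#' Sum of correlations of differences (SCD)
#'
#' `r(F - B, A) + r(F - A, B)`: how much of each source's signal remains in
#' the fused image once the other source is subtracted.
#'
#' @inheritParams metric_cc
#' @return Value in `[-2, 2]`.
#' @export
metric_scd <- function(f, a, b) {
  im <- check_same_shape(f, a, b)
  pearson_r(im$f - im$b, im$a) + pearson_r(im$f - im$a, im$b)
}

#' Evaluate the six fusion metrics over a dataset
#'
#' @param triples list of `list(f=, a=, b=)` (or unnamed `list(F, A, B)`)
#'   fused/CT/MRI image triples.
#' @param pc compute the (comparatively expensive) phase-congruency metric;
#'   when `FALSE` its column is `NA`.
#' @return A `metrics_report`: `summary` (named means over the dataset),
#'   `per_image` data frame, and `n_images`.
#' @export
evaluate_dataset <- function(triples, pc = TRUE) {
  if (length(triples) == 0L) stop("`triples` must be nonempty")
  rows <- lapply(seq_along(triples), function(i) {
    tr <- triples[[i]]
    f <- tr[[1L]]; a <- tr[[2L]]; b <- tr[[3L]]
    data.frame(image_id = i,
               cc = metric_cc(f, a, b),
               mi = metric_mi(f, a, b),
               sf = metric_sf(f),
               pc = if (pc) metric_pc(f, a, b) else NA_real_,
               ncie = metric_ncie(f, a, b),
               scd = metric_scd(f, a, b))
  })
  per_image <- do.call(rbind, rows)
  structure(list(summary = colMeans(per_image[, -1L]),
                 per_image = per_image,
                 n_images = length(triples)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report over %d image(s)>\n", x$n_images))
  print(round(x$summary, 4))
  invisible(x)
}
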