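# The visual-saliency fusion rule: l1-norm activity of the CT feature
# stack, histogram-based visual saliency over quantized levels, min-max
# normalization, and the weighted combination of CT and MRI features; plus
# the elementwise baseline rules used for ablation comparisons.

#' Fusion strategy parameters
#'
#' @param gamma CT share inside the dense-structure term, in `[0,1]`. The
#'   method's description leaves its value open; 0.5 splits the dense
#'   structure evenly between modalities and is the package default.
#' @param levels histogram resolution of the saliency map (256 matches
#'   8-bit gray levels).
#' @param strategy `"vsm"` (the saliency rule) or one of the elementwise
#'   baselines `"avg"`, `"max"`, `"sum"`, `"l1norm"`.
#' @param mri_term how the MRI coefficient of the dense-structure term is
#'   read: `"scaled"` gives `(1 - gamma) * w1` so the per-pixel fusion
#'   weights form a convex combination; `"complement"` gives the literal
#'   `(1 - gamma * w1)` reading.
#' @return A `fusion_params` list.
#' @export
fusion_params <- function(gamma = 0.5, levels = 256L,
                          strategy = c("vsm", "avg", "max", "sum", "l1norm"),
                          mri_term = c("scaled", "complement")) {
  strategy <- match.arg(strategy)
  mri_term <- match.arg(mri_term)
  if (gamma < 0 || gamma > 1) stop("`gamma` must lie in [0, 1]")
  if (levels < 2L) stop("`levels` must be at least 2")
  structure(list(gamma = gamma, levels = as.integer(levels),
                 strategy = strategy, mri_term = mri_term),
            class = "fusion_params")
}

as_stack3 <- function(features) {
  if (is.matrix(features)) {
    array(unclass(features), c(dim(features), 1L))
  } else if (length(dim(features)) == 3L) {
    features
  } else {
    stop("expected an H x W x C feature stack")
  }
}

#' l1-norm activity level map of a feature stack
#'
#' The activity at a pixel is the sum over channels of the absolute feature
#' responses, the usual l1-norm activity measure of fusion pipelines.
#'
#' @param features H x W x C numeric array (C >= 1), or a matrix (C = 1).
#' @return H x W non-negative matrix.
#' @export
l1_activity <- function(features) {
  f <- as_stack3(features)
  d <- dim(f)
  if (d[3L] < 1L || length(f) == 0L) stop("empty feature stack")
  matrix(rowSums(matrix(abs(f), d[1L] * d[2L], d[3L])), d[1L], d[2L])
}

#' Min-max normalization to the unit interval
#'
#' Affinely maps a map onto `[0,1]`; a constant map normalizes to all zeros
#' ("no saliency anywhere") rather than NaN.
#'
#' @param map 2-D numeric array with finite entries.
#' @return Matrix with values in `[0,1]`.
#' @export
minmax_normalize <- function(map) {
  m <- unclass(as.matrix(map))
  if (any(!is.finite(m))) stop("map contains non-finite values")
  lo <- min(m); hi <- max(m)
  if (hi == lo) {
    matrix(0, nrow(m), ncol(m))
  } else {
    (m - lo) / (hi - lo)
  }
}

#' Histogram-based visual saliency map
#'
#' The saliency of a pixel at gray level `v` is the summed absolute
#' intensity difference to every pixel of the image,
#' `sum_m M(m) * |v - m|` with `M` the level histogram. The histogram plus
#' prefix sums evaluates this in `O(P + L)` and agrees exactly (integer
#' arithmetic) with the brute-force per-pixel sum.
#'
#' @param levels_image integer matrix with values in `0 .. L-1`
#'   (see [quantize_levels()]).
#' @param L number of gray levels.
#' @return Numeric matrix of saliency values; attribute `levels` records L.
#' @export
vsm <- function(levels_image, L = 256L) {
  v <- unclass(levels_image)
  if (anyNA(v) || min(v) < 0L || max(v) > L - 1L) {
    stop("levels must lie in 0 .. L-1")
  }
  cnt <- tabulate(as.vector(v) + 1L, nbins = L)
  csum_n <- cumsum(cnt)                       # pixels at level <= m
  csum_s <- cumsum(cnt * (seq_len(L) - 1))    # sum of levels <= m
  total_n <- csum_n[L]
  total_s <- csum_s[L]
  lev <- 0:(L - 1)
  # below-level and above-level contributions to sum_m M(m) |v - m|
  sal_by_level <- lev * csum_n - csum_s + (total_s - csum_s) - lev * (total_n - csum_n)
  out <- matrix(sal_by_level[as.vector(v) + 1L], nrow(v), ncol(v))
  attr(out, "levels") <- as.integer(L)
  out
}

#' CT-side saliency weight map
#'
#' The weight-map chain of the fusion rule: l1-norm activity of the CT
#' features, min-max normalization, quantization to `levels` gray levels,
#' histogram saliency, and a final min-max normalization so the weight map
#' lands in `[0,1]` and the fusion weights form a convex combination.
#'
#' @param f_ct H x W x C feature stack from the encoder (CT branch).
#' @param params a [fusion_params()].
#' @return H x W weight matrix in `[0,1]`.
#' @export
ct_weight_map <- function(f_ct, params = fusion_params()) {
  act <- l1_activity(f_ct)
  w_nor <- minmax_normalize(act)
  sal <- vsm(quantize_levels(w_nor, params$levels), params$levels)
  minmax_normalize(sal)
}

#' Saliency-weighted fusion of CT and MRI feature stacks
#'
#' Per channel, the dense-structure term blends both modalities under the
#' weight map and `gamma`, and the soft-tissue term takes the remaining
#' `(1 - w1)` share entirely from the MRI features:
#' `F = gamma*w1*F_CT + (1-gamma)*w1*F_MRI + (1-w1)*F_MRI` (the default
#' `"scaled"` reading, under which the three per-pixel coefficients sum
#' to one).
#'
#' @param f_ct,f_mri feature stacks of identical shape.
#' @param w1 H x W weight map in `[0,1]`, shared across channels.
#' @param gamma CT share of the dense-structure term.
#' @param mri_term see [fusion_params()].
#' @return Fused feature stack, same shape as the inputs.
#' @export
fuse_features <- function(f_ct, f_mri, w1, gamma = 0.5,
                          mri_term = c("scaled", "complement")) {
  mri_term <- match.arg(mri_term)
  a <- as_stack3(f_ct); b <- as_stack3(f_mri)
  if (!identical(dim(a), dim(b))) stop("feature stacks differ in shape")
  if (!identical(as.integer(dim(w1)), as.integer(dim(a)[1:2]))) {
    stop("weight map does not match the stacks' spatial size")
  }
  w <- as.vector(unclass(w1))
  mri_coef <- if (mri_term == "scaled") (1 - gamma) * w else 1 - gamma * w
  hw <- dim(a)[1L] * dim(a)[2L]
  am <- matrix(a, hw); bm <- matrix(b, hw)
  fds <- am * (gamma * w) + bm * mri_coef
  fst <- bm * (1 - w)
  array(fds + fst, dim(a))
}

#' Elementwise baseline fusion rules
#'
#' The comparison strategies: elementwise average, maximum, and sum, and
#' the l1-norm rule that weights each pixel by its relative channel-l1
#' activity, `w_A = |A|_1 / (|A|_1 + |B|_1)`.
#'
#' @param f_ct,f_mri feature stacks of identical shape.
#' @param strategy one of `"avg"`, `"max"`, `"sum"`, `"l1norm"`.
#' @return Fused feature stack.
#' @export
fuse_baseline <- function(f_ct, f_mri,
                          strategy = c("avg", "max", "sum", "l1norm")) {
  strategy <- match.arg(strategy)
  a <- as_stack3(f_ct); b <- as_stack3(f_mri)
  if (!identical(dim(a), dim(b))) stop("feature stacks differ in shape")
  switch(strategy,
    avg = (a + b) / 2,
    max = pmax(a, b),
    sum = a + b,
    l1norm = {
      la <- l1_activity(a); lb <- l1_activity(b)
      wa <- as.vector(la / pmax(la + lb, .Machine$double.eps))
      hw <- dim(a)[1L] * dim(a)[2L]
      array(matrix(a, hw) * wa + matrix(b, hw) * (1 - wa), dim(a))
    }
  )
}

#' Fuse encoded stacks under a named strategy
#'
#' Dispatcher used by the pipeline: the saliency rule computes the CT
#' weight map and applies [fuse_features()]; the baselines go through
#' [fuse_baseline()].
#'
#' @param f_ct,f_mri encoder outputs for the two modalities.
#' @param params a [fusion_params()].
#' @return Fused feature stack.
#' @export
fuse_stacks <- function(f_ct, f_mri, params = fusion_params()) {
  stopifnot(inherits(params, "fusion_params"))
  if (params$strategy == "vsm") {
    w1 <- ct_weight_map(f_ct, params)
    fuse_features(f_ct, f_mri, w1, params$gamma, params$mri_term)
  } else {
    fuse_baseline(f_ct, f_mri, params$strategy)
  }
}
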