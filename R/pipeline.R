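# End-to-end fusion: encode both sources with the shared encoder, fuse the
# feature stacks under the chosen rule, decode, clip for export.

#' Fuse a registered CT/MRI pair into one image
#'
#' Runs the full inference pipeline: `F_CT = encode(ct)` and
#' `F_MRI = encode(mri)` with one shared set of weights, the CT saliency
#' weight map and feature fusion (or an elementwise baseline), and the
#' decoder. Inference is fully convolutional, so any image size the
#' encoder accepts works unresized.
#'
#' @param pair an [image_pair()].
#' @param weights a `net_weights` object (see [train()] /
#'   [init_net_weights()]).
#' @param params a [fusion_params()].
#' @param clip clip the decoded image into `[0,1]` (default; export
#'   convention).
#' @return The fused image as a `[0,1]` matrix (or raw decoder output when
#'   `clip = FALSE`).
#' @export
fuse_images <- function(pair, weights, params = fusion_params(), clip = TRUE) {
  stopifnot(inherits(pair, "image_pair"), inherits(weights, "net_weights"))
  f_ct <- encode(pair$ct, weights)
  f_mri <- encode(pair$mri, weights)
  fused <- fuse_stacks(f_ct, f_mri, params)
  decode(fused, weights, clip = clip)
}

#' Fuse every pair in a list and collect metric triples
#'
#' Convenience wrapper for strategy comparisons: fuses each pair under
#' `params` and returns `(fused, ct, mri)` triples ready for
#' [evaluate_dataset()].
#'
#' @param pairs list of [image_pair()]s.
#' @param weights a `net_weights` object.
#' @param params a [fusion_params()].
#' @return List of `list(f, a, b)` triples.
#' @export
fuse_pairs <- function(pairs, weights, params = fusion_params()) {
  lapply(pairs, function(p) {
    list(f = fuse_images(p, weights, params),
         a = unclass(p$ct), b = unclass(p$mri))
  })
}
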