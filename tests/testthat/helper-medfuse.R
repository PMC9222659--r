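# shared fixtures, all generated in code

# smallest architecture that exercises every code path
tiny_cfg <- function(...) {
  net_config(shallow_channels = 2L, branch_channels = 2L, reduction = 2L,
             decoder_channels = c(8L, 4L, 3L, 2L, 2L), sa_kernel = 3L, ...)
}

rand_stack <- function(h, w, c, seed = 1L, sd = 1) {
  medfuse:::with_seed(seed, array(rnorm(h * w * c, sd = sd), c(h, w, c)))
}

rand_img <- function(h, w, seed = 1L) {
  medfuse:::with_seed(seed, matrix(runif(h * w), h, w))
}

# O(P * L) reference for the histogram saliency map
vsm_bruteforce <- function(q, L) {
  cnt <- tabulate(as.vector(q) + 1L, nbins = L)
  lev <- 0:(L - 1)
  out <- vapply(as.vector(q), function(v) sum(cnt * abs(v - lev)), 0)
  matrix(out, nrow(q), ncol(q))
}
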