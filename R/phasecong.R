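# Phase congruency via a log-Gabor filter bank (frequency-domain
# implementation in the style of Kovesi's classic construction): even and
# odd responses per scale and orientation, energy with a noise threshold
# estimated from the smallest-scale amplitude, and the moment maps of the
# oriented congruency used by the phase-congruency fusion metric.

lowpass_filter <- function(rows, cols, cutoff = 0.45, order = 15) {
  fx <- freq_axis(cols)
  fy <- freq_axis(rows)
  radius <- sqrt(outer(fy^2, fx^2, `+`))
  1 / (1 + (radius / cutoff)^(2 * order))
}

freq_axis <- function(n) {
  if (n %% 2 == 0) {
    r <- c(0:(n / 2 - 1), -(n / 2):-1) / n
  } else {
    r <- c(0:((n - 1) / 2), -((n - 1) / 2):-1) / n
  }
  r
}

#' Phase congruency maps of an image
#'
#' Returns the summed phase-congruency map and the maximum and minimum
#' moment maps of the oriented congruency covariance, computed with a
#' log-Gabor bank (default 4 scales, 6 orientations).
#'
#' @param img numeric matrix, at least 32 x 32.
#' @param nscale,norient filter bank size.
#' @param min_wavelength wavelength of the smallest-scale filter (pixels).
#' @param mult scaling between successive filter wavelengths.
#' @param sigma_onf log-Gabor bandwidth parameter.
#' @param k noise threshold in standard deviations above the mean noise
#'   energy.
#' @param cut_off,g parameters of the frequency-spread weighting sigmoid.
#' @return List of matrices `pc`, `M`, `m`.
#' @export
phase_congruency <- function(img, nscale = 4L, norient = 6L,
                             min_wavelength = 3, mult = 2.1,
                             sigma_onf = 0.55, k = 2,
                             cut_off = 0.5, g = 10) {
  img <- unclass(as.matrix(img))
  rows <- nrow(img); cols <- ncol(img)
  if (rows < 32L || cols < 32L) stop("image must be at least 32 x 32")
  eps <- 1e-4
  imfft <- stats::fft(img)

  fx <- freq_axis(cols)
  fy <- freq_axis(rows)
  radius <- sqrt(outer(fy^2, fx^2, `+`))
  radius[1L, 1L] <- 1
  theta <- atan2(outer(-fy, rep(1, cols)), outer(rep(1, rows), fx))
  sintheta <- sin(theta)
  costheta <- cos(theta)
  lp <- lowpass_filter(rows, cols)

  log_gabor <- lapply(seq_len(nscale), function(s) {
    wavelength <- min_wavelength * mult^(s - 1)
    fo <- 1 / wavelength
    lg <- exp(-(log(radius / fo))^2 / (2 * log(sigma_onf)^2)) * lp
    lg[1L, 1L] <- 0
    lg
  })

  pc_sum <- matrix(0, rows, cols)
  covx2 <- covy2 <- covxy <- matrix(0, rows, cols)

  for (o in seq_len(norient)) {
    angl <- (o - 1) * pi / norient
    ds <- sintheta * cos(angl) - costheta * sin(angl)
    dc <- costheta * cos(angl) + sintheta * sin(angl)
    dtheta <- abs(atan2(ds, dc))
    spread <- exp(-dtheta^2 / (2 * (pi / norient)^2))

    sum_e <- sum_o <- sum_an <- matrix(0, rows, cols)
    max_an <- matrix(0, rows, cols)
    tau <- 0
    for (s in seq_len(nscale)) {
      filt <- log_gabor[[s]] * spread
      eo <- stats::fft(imfft * filt, inverse = TRUE) / (rows * cols)
      re <- Re(eo); im <- Im(eo)
      an <- sqrt(re^2 + im^2)
      sum_an <- sum_an + an
      sum_e <- sum_e + re
      sum_o <- sum_o + im
      max_an <- pmax(max_an, an)
      if (s == 1L) tau <- stats::median(an) / sqrt(log(4))
    }
    x_energy <- sqrt(sum_e^2 + sum_o^2) + eps
    mean_e <- sum_e / x_energy
    mean_o <- sum_o / x_energy
    energy <- matrix(0, rows, cols)
    for (s in seq_len(nscale)) {
      filt <- log_gabor[[s]] * spread
      eo <- stats::fft(imfft * filt, inverse = TRUE) / (rows * cols)
      re <- Re(eo); im <- Im(eo)
      energy <- energy + re * mean_e + im * mean_o - abs(re * mean_o - im * mean_e)
    }
    # noise threshold from the smallest-scale amplitude distribution
    total_tau <- tau * (1 - (1 / mult)^nscale) / (1 - 1 / mult)
    noise_mean <- total_tau * sqrt(pi / 2)
    noise_sd <- total_tau * sqrt((4 - pi) / 2)
    t_thr <- noise_mean + k * noise_sd
    energy <- pmax(energy - t_thr, 0)

    width <- (sum_an / (max_an + eps)) / nscale
    weight <- 1 / (1 + exp(g * (cut_off - width)))
    pc_o <- weight * energy / (sum_an + eps)

    pc_sum <- pc_sum + pc_o
    covx <- pc_o * cos(angl)
    covy <- pc_o * sin(angl)
    covx2 <- covx2 + covx^2
    covy2 <- covy2 + covy^2
    covxy <- covxy + covx * covy
  }

  covx2 <- covx2 / (norient / 2)
  covy2 <- covy2 / (norient / 2)
  covxy <- 4 * covxy / norient
  denom <- sqrt(covxy^2 + (covx2 - covy2)^2) + 1e-12
  M <- (covy2 + covx2 + denom) / 2
  m <- (covy2 + covx2 - denom) / 2
  list(pc = pc_sum / norient, M = M, m = m)
}
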