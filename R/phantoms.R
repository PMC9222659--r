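# Synthetic registered pseudo-CT / pseudo-MRI pairs.
#
# The generator reproduces the complementarity the fusion method relies on:
# CT renders dense structure (a bright skull-like annulus) over a flat,
# detail-poor interior; MRI renders the same geometry with a dark annulus
# but a texture-rich soft-tissue interior plus bright lesions. Both members
# share one geometry mask, so registration holds by construction.

#' Phantom pair specification
#'
#' @param size square image side in pixels (at least 16).
#' @param seed integer seed; a spec is fully deterministic.
#' @param ring_radius_frac outer radius of the skull annulus as a fraction of
#'   the half-size.
#' @param ring_thickness_frac annulus thickness as a fraction of the half-size.
#' @param ct_bone_level CT intensity on the annulus (dense structure; high).
#' @param ct_tissue_level CT intensity of the interior (soft tissue; low).
#' @param mri_texture_scale spatial correlation length, in pixels, of the
#'   soft-tissue texture in the MRI member.
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @param n_lesions number of bright elliptical lesions in the MRI interior.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(size = 64L, seed = 1L,
                         ring_radius_frac = 0.78, ring_thickness_frac = 0.12,
                         ct_bone_level = 0.95, ct_tissue_level = 0.25,
                         mri_texture_scale = 6, noise_sd = 0.02,
                         n_lesions = 2L) {
  if (size < 16L) stop("`size` must be at least 16")
  if (ct_bone_level <= ct_tissue_level) {
    stop("`ct_bone_level` must exceed `ct_tissue_level`: ",
         "the dense structure is the CT-salient feature")
  }
  if (ring_radius_frac <= 0 || ring_radius_frac >= 1 ||
      ring_thickness_frac <= 0 || ring_thickness_frac >= ring_radius_frac) {
    stop("annulus must fit inside the image with positive thickness")
  }
  if (mri_texture_scale <= 0 || noise_sd < 0 || n_lesions < 0) {
    stop("invalid texture scale, noise level, or lesion count")
  }
  structure(list(size = as.integer(size), seed = as.integer(seed),
                 ring_radius_frac = ring_radius_frac,
                 ring_thickness_frac = ring_thickness_frac,
                 ct_bone_level = ct_bone_level,
                 ct_tissue_level = ct_tissue_level,
                 mri_texture_scale = mri_texture_scale,
                 noise_sd = noise_sd, n_lesions = as.integer(n_lesions)),
            class = "phantom_spec")
}

# run expr under a private RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# separable Gaussian smoothing with edge replication
gauss_smooth <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_rows <- function(x) x[c(rep(1L, r), seq_len(nrow(x)), rep(nrow(x), r)), , drop = FALSE]
  smooth1 <- function(x) {
    xp <- pad_rows(x)
    out <- matrix(0, nrow(x), ncol(x))
    for (i in seq_along(k)) out <- out + k[i] * xp[seq_len(nrow(x)) + i - 1L, , drop = FALSE]
    out
  }
  t(smooth1(t(smooth1(m))))
}

#' Annulus (dense-structure) mask of a phantom spec
#'
#' The skull mask shared by the CT and MRI members. Thresholding the
#' noiseless CT at `(ct_bone_level + ct_tissue_level)/2` recovers it, which
#' downstream tests use to check that saliency weight maps concentrate on
#' dense structure.
#'
#' @param spec a [phantom_spec()].
#' @return Logical `size x size` matrix.
#' @export
phantom_annulus_mask <- function(spec) {
  g <- phantom_geometry(spec)
  g$ring
}

phantom_geometry <- function(spec) {
  n <- spec$size
  half <- (n - 1) / 2
  ax <- (seq_len(n) - 1 - half) / half
  r <- sqrt(outer(ax^2, ax^2, `+`))
  outer_r <- spec$ring_radius_frac
  inner_r <- outer_r - spec$ring_thickness_frac
  list(r = r, ring = r <= outer_r & r >= inner_r, interior = r < inner_r,
       outside = r > outer_r)
}

#' Generate one registered pseudo-CT/pseudo-MRI pair
#'
#' @param spec a [phantom_spec()].
#' @return An [image_pair()]; identical specs give bit-identical pairs.
#' @export
make_pair <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- phantom_geometry(spec)
  n <- spec$size
  with_seed(spec$seed, {
    ct <- matrix(spec$ct_tissue_level, n, n)
    ct[g$outside] <- 0.05
    ct[g$ring] <- spec$ct_bone_level

    # band-limited soft-tissue texture: smoothed white noise, rescaled
    tex <- gauss_smooth(matrix(rnorm(n * n), n, n), spec$mri_texture_scale / 2)
    tr <- range(tex)
    tex <- if (tr[2] > tr[1]) 0.2 + 0.6 * (tex - tr[1]) / (tr[2] - tr[1]) else
      matrix(0.5, n, n)
    mri <- matrix(0.02, n, n)
    mri[g$interior] <- tex[g$interior]
    mri[g$ring] <- 0.08

    if (spec$n_lesions > 0L) {
      half <- (n - 1) / 2
      for (i in seq_len(spec$n_lesions)) {
        cx <- runif(1, -0.45, 0.45) * half + half + 1
        cy <- runif(1, -0.45, 0.45) * half + half + 1
        a <- runif(1, 0.04, 0.10) * n
        b <- runif(1, 0.04, 0.10) * n
        th <- runif(1, 0, pi)
        xs <- matrix(seq_len(n) - cx, n, n)
        ys <- matrix(seq_len(n) - cy, n, n, byrow = TRUE)
        u <- cos(th) * xs + sin(th) * ys
        v <- -sin(th) * xs + cos(th) * ys
        les <- (u / a)^2 + (v / b)^2 <= 1 & g$interior
        mri[les] <- 0.95
      }
    }

    if (spec$noise_sd > 0) {
      ct <- ct + matrix(rnorm(n * n, sd = spec$noise_sd), n, n)
      mri <- mri + matrix(rnorm(n * n, sd = spec$noise_sd), n, n)
    }
    image_pair(pmin(pmax(ct, 0), 1), pmin(pmax(mri, 0), 1))
  })
}

# counter-clockwise rotation by k*90 degrees
rot90k <- function(m, deg) {
  k <- (as.integer(deg) %/% 90L) %% 4L
  for (i in seq_len(k)) {
    m <- t(m)[seq(ncol(m), 1L), , drop = FALSE]
  }
  m
}

#' Crop-and-rotate augmentation of a registered pair
#'
#' Applies the identical crop and right-angle rotation to both members, so
#' registration is preserved. Rotations are restricted to multiples of 90
#' degrees to keep the transform interpolation-free.
#'
#' @param pair an [image_pair()].
#' @param crop_size side of the square crop.
#' @param rotation one of 0, 90, 180, 270 (degrees, counter-clockwise).
#' @param offset integer `(row, col)` of the crop's top-left corner, 0-based.
#' @param seed unused for the deterministic transform; accepted so callers
#'   can thread one seed through an augmentation schedule.
#' @return The transformed [image_pair()], `crop_size` square.
#' @export
augment_pair <- function(pair, crop_size, rotation = 0L, offset = c(0L, 0L),
                         seed = NULL) {
  stopifnot(inherits(pair, "image_pair"))
  if (!rotation %in% c(0L, 90L, 180L, 270L)) {
    stop("rotation must be one of 0, 90, 180, 270 degrees")
  }
  h <- nrow(pair$ct); w <- ncol(pair$ct)
  r0 <- offset[1L]; c0 <- offset[2L]
  if (crop_size < 8L || r0 < 0L || c0 < 0L ||
      r0 + crop_size > h || c0 + crop_size > w) {
    stop("crop of size ", crop_size, " at offset (", r0, ",", c0,
         ") does not fit inside a ", h, "x", w, " image")
  }
  tf <- function(m) {
    m <- m[r0 + seq_len(crop_size), c0 + seq_len(crop_size), drop = FALSE]
    rot90k(unclass(m), rotation)
  }
  image_pair(tf(pair$ct), tf(pair$mri))
}

#' Generate a reproducible phantom dataset with train/val/test split
#'
#' Jitters the base spec's geometry, texture scale, and lesion count per
#' pair, renders each phantom with margin, and applies a random crop and
#' right-angle rotation, mirroring a crop-and-rotate augmentation schedule
#' at desk scale.
#'
#' @param n_pairs number of pairs to generate.
#' @param base_spec the [phantom_spec()] whose `size` all pairs share.
#' @param seed dataset-level seed controlling jitter and augmentation.
#' @return List with `pairs` (list of [image_pair()]) and `split`
#'   (disjoint `train`/`val`/`test` index vectors, 70/15/15).
#' @export
make_dataset <- function(n_pairs, base_spec = phantom_spec(), seed = 1L) {
  if (n_pairs < 1L) stop("`n_pairs` must be at least 1")
  size <- base_spec$size
  big <- as.integer(ceiling(size * 1.3))
  pairs <- with_seed(seed, {
    lapply(seq_len(n_pairs), function(i) {
      sp <- base_spec
      sp$size <- big
      sp$seed <- as.integer(sample.int(2^30, 1L))
      sp$ring_radius_frac <- min(0.95, max(0.3,
        base_spec$ring_radius_frac + runif(1, -0.05, 0.05)))
      sp$ring_thickness_frac <- min(sp$ring_radius_frac - 0.05, max(0.05,
        base_spec$ring_thickness_frac + runif(1, -0.02, 0.02)))
      sp$mri_texture_scale <- base_spec$mri_texture_scale * runif(1, 0.8, 1.25)
      sp$n_lesions <- max(0L, base_spec$n_lesions + sample(-1L:1L, 1L))
      p <- make_pair(sp)
      off <- c(sample.int(big - size + 1L, 1L), sample.int(big - size + 1L, 1L)) - 1L
      rot <- sample(c(0L, 90L, 180L, 270L), 1L)
      augment_pair(p, size, rot, off)
    })
  })
  idx <- with_seed(seed + 1L, sample.int(n_pairs))
  n_train <- max(1L, floor(0.7 * n_pairs))
  n_val <- floor(0.15 * n_pairs)
  split <- list(
    train = sort(idx[seq_len(n_train)]),
    val = if (n_val > 0L) sort(idx[n_train + seq_len(n_val)]) else integer(0),
    test = if (n_train + n_val < n_pairs)
      sort(idx[(n_train + n_val + 1L):n_pairs]) else integer(0)
  )
  list(pairs = pairs, split = split)
}

#' Write a phantom dataset to disk as PNG files
#'
#' @param n_pairs,base_spec,seed forwarded to [make_dataset()].
#' @param out_dir output directory, created if missing.
#' @return Invisibly, the dataset list with a `files` element added.
#' @export
write_phantoms <- function(n_pairs, out_dir, base_spec = phantom_spec(),
                           seed = 1L) {
  ds <- make_dataset(n_pairs, base_spec, seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- lapply(seq_along(ds$pairs), function(i) {
    ct <- file.path(out_dir, sprintf("pair_%04d_ct.png", i))
    mri <- file.path(out_dir, sprintf("pair_%04d_mri.png", i))
    save_gray(ds$pairs[[i]]$ct, ct)
    save_gray(ds$pairs[[i]]$mri, mri)
    c(ct = ct, mri = mri)
  })
  ds$files <- files
  invisible(ds)
}
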