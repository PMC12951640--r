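# Synthetic multicontrast MS phantom: an ellipsoidal "brain" with randomly
# placed lesion blobs that are hyperintense on T2w/PDw/FLAIR and hypointense
# on T1w, a smooth multiplicative bias field, additive Gaussian noise, and
# two simulated raters derived from the truth by per-lesion morphological
# jitter. Not anatomy: the phantom emulates the statistical structure the
# pipeline depends on (contrast polarity, multi-lesion topology, rater
# variability, domain-shift corruptions), not brain geometry.

#' Phantom configuration
#'
#' @param shape volume extents in voxels.
#' @param n_lesions number of lesion blobs.
#' @param lesion_radius_range min/max ellipsoid semi-axis in voxels.
#' @param tissue_means per-contrast background intensity inside the brain
#'   (order T1w, T2w, PDw, FLAIR).
#' @param lesion_contrast per-contrast signed lesion offset; negative for
#'   T1w (hypointense), positive for T2w/PDw/FLAIR (hyperintense).
#' @param noise_sd additive Gaussian noise SD (intensity units).
#' @param bias_field_amplitude relative amplitude of the smooth
#'   multiplicative bias field (0 disables it).
#' @param rater_jitter probability that a rater perturbs a lesion boundary
#'   (split evenly between one-step dilation and erosion).
#' @param seed RNG seed; generation is fully reproducible from it.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(shape = c(32L, 32L, 32L), n_lesions = 5L,
                           lesion_radius_range = c(2, 5),
                           tissue_means = c(70, 50, 60, 40),
                           lesion_contrast = c(-10, 12, 8, 30),
                           noise_sd = 4, bias_field_amplitude = 0.1,
                           rater_jitter = 0.5, seed = 1L) {
  stopifnot(length(shape) == 3L, n_lesions >= 0L,
            lesion_radius_range[1L] >= 1,
            diff(lesion_radius_range) >= 0, noise_sd >= 0,
            length(tissue_means) == 4L, length(lesion_contrast) == 4L)
  structure(list(shape = as.integer(shape), n_lesions = as.integer(n_lesions),
                 lesion_radius_range = lesion_radius_range,
                 tissue_means = tissue_means, lesion_contrast = lesion_contrast,
                 noise_sd = noise_sd,
                 bias_field_amplitude = bias_field_amplitude,
                 rater_jitter = rater_jitter, seed = as.integer(seed)),
            class = "phantom_config")
}

# normalized coordinate grids in [-1, 1]
.coord_grids <- function(shape) {
  g <- lapply(shape, function(n) if (n > 1) seq(-1, 1, length.out = n) else 0)
  list(x = array(rep(g[[1L]], times = shape[2L] * shape[3L]), dim = shape),
       y = array(rep(rep(g[[2L]], each = shape[1L]), times = shape[3L]),
                 dim = shape),
       z = array(rep(g[[3L]], each = shape[1L] * shape[2L]), dim = shape))
}

.ellipsoid_mask <- function(shape, center, semi) {
  d1 <- (seq_len(shape[1L]) - center[1L]) / semi[1L]
  d2 <- (seq_len(shape[2L]) - center[2L]) / semi[2L]
  d3 <- (seq_len(shape[3L]) - center[3L]) / semi[3L]
  o <- outer(outer(d1^2, d2^2, `+`), d3^2, `+`)
  array(as.integer(o <= 1), dim = shape)
}

# one-step morphological dilation/erosion with a face (6) or full (26)
# neighborhood, via shifted copies
.shift3 <- function(a, dx, dy, dz) {
  d <- dim(a)
  out <- array(0L, dim = d)
  sx <- seq_len(d[1L]); sy <- seq_len(d[2L]); sz <- seq_len(d[3L])
  fx <- sx + dx; fy <- sy + dy; fz <- sz + dz
  ok <- list(fx >= 1L & fx <= d[1L], fy >= 1L & fy <= d[2L],
             fz >= 1L & fz <= d[3L])
  out[sx[ok[[1L]]], sy[ok[[2L]]], sz[ok[[3L]]]] <-
    a[fx[ok[[1L]]], fy[ok[[2L]]], fz[ok[[3L]]]]
  out
}

.neighborhood_offsets <- function(connectivity = 6L) {
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  man <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  keep <- if (connectivity == 6L) man == 1L else man >= 1L
  offs[keep, , drop = FALSE]
}

.dilate3 <- function(mask, connectivity = 6L) {
  offs <- .neighborhood_offsets(connectivity)
  out <- mask
  for (i in seq_len(nrow(offs)))
    out <- out | .shift3(mask, offs$dx[i], offs$dy[i], offs$dz[i])
  array(as.integer(out), dim = dim(mask))
}

.erode3 <- function(mask, connectivity = 6L) {
  offs <- .neighborhood_offsets(connectivity)
  out <- mask == 1L
  for (i in seq_len(nrow(offs)))
    out <- out & (.shift3(mask, offs$dx[i], offs$dy[i], offs$dz[i]) == 1L)
  array(as.integer(out), dim = dim(mask))
}

# low-order smooth random field, normalized to [-1, 1]
.smooth_field <- function(shape) {
  g <- .coord_grids(shape)
  co <- rnorm(9L)
  f <- co[1L] * g$x + co[2L] * g$y + co[3L] * g$z +
    co[4L] * g$x * g$y + co[5L] * g$x * g$z + co[6L] * g$y * g$z +
    co[7L] * g$x^2 + co[8L] * g$y^2 + co[9L] * g$z^2
  m <- max(abs(f))
  if (m > 0) f <- f / m
  f
}

# Per-lesion rater jitter: with probability `jitter` a lesion's boundary is
# perturbed outward or inward by a random half of its morphological shell
# (face neighborhood). Partial-shell edits keep the rater-vs-truth DSC
# above ~0.7 for default lesion sizes; an edit that would delete a lesion
# falls back to the original blob.
.rater_mask <- function(truth, jitter) {
  lab <- label_components(truth, 26L)
  n <- max(lab)
  if (n == 0L) return(truth)
  out <- array(0L, dim = dim(truth))
  for (k in seq_len(n)) {
    les <- array(as.integer(lab == k), dim = dim(truth))
    u <- runif(1)
    if (u < jitter) {
      if (u < jitter / 2) {         # outward: add half the dilation shell
        shell <- which(.dilate3(les, 6L) == 1L & les == 0L)
        les[shell[runif(length(shell)) < 0.5]] <- 1L
      } else {                      # inward: drop half the boundary layer
        rim <- which(les == 1L & .erode3(les, 6L) == 0L)
        cand <- les
        cand[rim[runif(length(rim)) < 0.5]] <- 0L
        if (sum(cand) > 0L) les <- cand
      }
    }
    out <- out | les
  }
  array(as.integer(out), dim = dim(truth))
}

#' Generate a synthetic multicontrast phantom
#'
#' Places lesion blobs (unions of random ellipsoids, so confluent lesions
#' occur) inside an ellipsoidal brain, renders the four contrasts as
#' `background + lesion offset`, times a smooth bias field, plus Gaussian
#' noise, and derives two rater masks by seeded morphological jitter of the
#' truth. Fully reproducible from `config$seed`.
#'
#' @param config a [phantom_config()].
#' @return list with `vol` ([mc_volume()]), `truth`, `rater1`, `rater2`
#'   (binary 3D masks) and `config`.
#' @export
generate_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  shape <- config$shape
  rmax <- config$lesion_radius_range[2L]
  if (config$n_lesions > 0L && any(shape < 4 * rmax))
    stop("lesions cannot fit: extents must be at least 4x the max radius")
  set.seed(config$seed)

  brain <- .ellipsoid_mask(shape, (shape + 1) / 2, 0.45 * shape)
  truth <- array(0L, dim = shape)
  if (config$n_lesions > 0L) {
    lo <- config$lesion_radius_range[1L]; hi <- rmax
    for (i in seq_len(config$n_lesions)) {
      n_parts <- sample.int(2L, 1L)
      center <- sapply(shape, function(n)
        runif(1, 1 + 1.5 * hi, n - 1.5 * hi))
      for (p in seq_len(n_parts)) {
        semi <- runif(3L, lo, hi)
        ctr <- center + if (p == 1L) 0 else rnorm(3L, sd = hi / 2)
        truth <- truth | .ellipsoid_mask(shape, ctr, semi)
      }
    }
    truth <- array(as.integer(truth & brain), dim = shape)
  }

  data <- array(0, dim = c(shape, 4L))
  for (ci in 1:4) {
    ch <- config$tissue_means[ci] * brain
    ch <- ch + config$lesion_contrast[ci] * truth
    if (config$bias_field_amplitude > 0)
      ch <- ch * (1 + config$bias_field_amplitude * .smooth_field(shape))
    if (config$noise_sd > 0) {
      noise <- array(rnorm(prod(shape), sd = config$noise_sd), dim = shape)
      ch <- ch + noise * brain
    }
    data[, , , ci] <- ch
  }

  rater1 <- .rater_mask(truth, config$rater_jitter)
  rater2 <- .rater_mask(truth, config$rater_jitter)
  list(vol = mc_volume(data, present = rep(TRUE, 4L)),
       truth = truth, rater1 = rater1, rater2 = rater2, config = config)
}

#' Corrupt a multicontrast volume
#'
#' Applies one domain-shift corruption family: additive Gaussian noise, a
#' smooth multiplicative bias field, Gaussian blur, a gamma intensity
#' transform, or dropping a contrast entirely (zeroing it and clearing its
#' presence flag). `magnitude = 0` is the identity for all kinds except
#' `drop_contrast`.
#'
#' @param vol an [mc_volume()].
#' @param kind one of `"gaussian_noise"`, `"bias_field"`, `"blur"`,
#'   `"gamma"`, `"drop_contrast"`.
#' @param magnitude corruption strength: noise SD (intensity units), bias
#'   amplitude (relative), blur sigma (voxels), log-gamma exponent.
#' @param seed optional RNG seed for the stochastic kinds.
#' @param contrasts contrast names (or indices) to corrupt; default all
#'   present contrasts, except `drop_contrast` which defaults to FLAIR.
#' @return the corrupted `mc_volume`.
#' @export
corrupt_volume <- function(vol, kind, magnitude = 1, seed = NULL,
                           contrasts = NULL) {
  stopifnot(inherits(vol, "mc_volume"))
  kind <- match.arg(kind, c("gaussian_noise", "bias_field", "blur", "gamma",
                            "drop_contrast"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(contrasts))
    contrasts <- if (kind == "drop_contrast") "FLAIR" else
      contrast_names()[vol$present]
  ci_all <- if (is.numeric(contrasts)) as.integer(contrasts) else
    match(contrasts, contrast_names())
  stopifnot(!anyNA(ci_all))

  if (kind == "drop_contrast") {
    for (ci in ci_all) {
      vol$data[, , , ci] <- 0
      vol$present[ci] <- FALSE
    }
    if (!any(vol$present)) stop("cannot drop the last present contrast")
    return(vol)
  }
  if (magnitude == 0) return(vol)
  shape <- dim(vol$data)[1:3]
  for (ci in intersect(ci_all, which(vol$present))) {
    ch <- vol$data[, , , ci]
    nz <- ch != 0
    if (kind == "gaussian_noise") {
      ch[nz] <- ch[nz] + rnorm(sum(nz), sd = magnitude)
    } else if (kind == "bias_field") {
      ch <- ch * (1 + magnitude * .smooth_field(shape))
    } else if (kind == "blur") {
      ch <- .gauss_blur3(ch, magnitude)
    } else if (kind == "gamma") {
      rng <- range(ch[nz])
      if (diff(rng) > 0) {
        u <- (ch[nz] - rng[1L]) / diff(rng)
        ch[nz] <- rng[1L] + diff(rng) * u^exp(magnitude)
      }
    }
    vol$data[, , , ci] <- ch
  }
  vol
}

# separable Gaussian blur, replicate padding
.gauss_blur3 <- function(a, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  conv_axis <- function(a, axis) {
    d <- dim(a)
    out <- array(0, dim = d)
    for (j in seq_along(k)) {
      off <- j - r - 1L
      idx <- pmin(pmax(seq_len(d[axis]) + off, 1L), d[axis])
      out <- out + k[j] * switch(axis,
        a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
        a[, , idx, drop = FALSE])
    }
    out
  }
  conv_axis(conv_axis(conv_axis(a, 1L), 2L), 3L)
}

#' Generate a phantom cohort
#'
#' Draws `n_subjects` phantoms with per-subject variation in lesion load,
#' radii and tissue intensities (about 10% around the template), each with
#' its own derived seed, and returns a train/validation split (last ~20%
#' held out, at least one subject).
#'
#' @param n_subjects number of subjects (>= 1).
#' @param config template [phantom_config()].
#' @param seed master seed; the whole cohort is reproducible from it.
#' @return list with `subjects` (each a [generate_phantom()] result),
#'   `train` and `val` (index vectors).
#' @export
make_dataset <- function(n_subjects, config = phantom_config(), seed = 1L) {
  stopifnot(n_subjects >= 1L)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max %/% 2L, n_subjects)
  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    cfg <- config
    cfg$seed <- seeds[i]
    cfg$n_lesions <- max(1L, config$n_lesions +
                           sample(-2:2, 1L) * (config$n_lesions > 2L))
    cfg$tissue_means <- config$tissue_means * runif(4L, 0.9, 1.1)
    subjects[[i]] <- generate_phantom(cfg)
  }
  n_val <- max(1L, round(0.2 * n_subjects))
  if (n_val >= n_subjects) n_val <- n_subjects - 1L
  val <- if (n_val >= 1L) seq.int(n_subjects - n_val + 1L, n_subjects)
    else integer(0)
  list(subjects = subjects, train = setdiff(seq_len(n_subjects), val),
       val = val)
}
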