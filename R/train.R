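# Training: lesion-containing 2.5D slice sampling with batch-uniform plane
# and dihedral augmentation, optional 3D elastic/affine warps, two-rater
# label sampling, contrast dropout, L2 loss on the central slice and Adam.

#' Training configuration
#'
#' Full-scale defaults follow the reference schedule (learning rate 1e-4,
#' batch 12, 150 epochs x 300 iterations, 75% elastic/affine probability,
#' last-epoch selection). The `"tiny"` preset is sized for desk-scale
#' phantom experiments on one CPU.
#'
#' @param lr Adam learning rate.
#' @param batch_size samples per iteration.
#' @param epochs,iters_per_epoch schedule; the last-epoch model is kept.
#' @param elastic_affine_prob probability of a random 3D elastic or affine
#'   warp per drawn volume.
#' @param warp_sd elastic control-point displacement SD, voxels.
#' @param seed master RNG seed for the whole run.
#' @param preset `NULL` or `"tiny"`.
#' @return a `train_config` list.
#' @export
train_config <- function(lr = 1e-4, batch_size = 12L, epochs = 150L,
                         iters_per_epoch = 300L, elastic_affine_prob = 0.75,
                         warp_sd = 1.5, seed = 1L, preset = NULL) {
  if (!is.null(preset) && match.arg(preset, "tiny") == "tiny") {
    lr <- 2e-3; batch_size <- 8L; epochs <- 4L; iters_per_epoch <- 60L
  }
  stopifnot(lr >= 0, batch_size >= 1L, epochs >= 1L, iters_per_epoch >= 1L,
            elastic_affine_prob >= 0, elastic_affine_prob <= 1)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 iters_per_epoch = as.integer(iters_per_epoch),
                 elastic_affine_prob = elastic_affine_prob,
                 warp_sd = warp_sd, loss = "L2", optimizer = "Adam",
                 model_selection = "last", seed = as.integer(seed)),
            class = "train_config")
}

# trilinear upsampling of a coarse 3D grid to `shape`: each axis is a
# linear map, applied as a matrix product
.interp_matrix <- function(n_in, n_out) {
  if (n_in == n_out) return(diag(n_out))
  x <- seq(1, n_in, length.out = n_out)
  i0 <- pmin(floor(x), n_in - 1L)
  f <- x - i0
  W <- matrix(0, n_out, n_in)
  W[cbind(seq_len(n_out), i0)] <- 1 - f
  W[cbind(seq_len(n_out), i0 + 1L)] <- f
  W
}

.interp_coarse <- function(coarse, shape) {
  up_axis <- function(a, axis, n_out) {
    d <- dim(a)
    if (d[axis] == n_out) return(a)
    perm <- c(axis, setdiff(1:3, axis))
    m <- .interp_matrix(d[axis], n_out) %*%
      matrix(aperm(a, perm), d[axis])
    dim(m) <- c(n_out, d[setdiff(1:3, axis)])
    aperm(m, order(perm))
  }
  up_axis(up_axis(up_axis(coarse, 1L, shape[1L]), 2L, shape[2L]), 3L, shape[3L])
}

# Precompute trilinear corner indices (flat, 1-based) and weights for a
# sampling grid, so the gather can be reused across channels.
.warp_plan <- function(d, sx, sy, sz) {
  sx <- pmin(pmax(sx, 1), d[1L]); sy <- pmin(pmax(sy, 1), d[2L])
  sz <- pmin(pmax(sz, 1), d[3L])
  x0 <- pmin(floor(sx), d[1L] - 1L); y0 <- pmin(floor(sy), d[2L] - 1L)
  z0 <- pmin(floor(sz), d[3L] - 1L)
  fx <- sx - x0; fy <- sy - y0; fz <- sz - z0
  b <- x0 + d[1L] * (y0 - 1) + d[1L] * d[2L] * (z0 - 1)
  dx <- 1; dy <- d[1L]; dz <- d[1L] * d[2L]
  list(
    idx = list(b, b + dx, b + dy, b + dx + dy,
               b + dz, b + dx + dz, b + dy + dz, b + dx + dy + dz),
    wt = list((1 - fx) * (1 - fy) * (1 - fz), fx * (1 - fy) * (1 - fz),
              (1 - fx) * fy * (1 - fz), fx * fy * (1 - fz),
              (1 - fx) * (1 - fy) * fz, fx * (1 - fy) * fz,
              (1 - fx) * fy * fz, fx * fy * fz),
    nearest = round(sx) + d[1L] * (round(sy) - 1) +
      d[1L] * d[2L] * (round(sz) - 1)
  )
}

.warp_trilinear <- function(a, plan) {
  v <- as.vector(a)
  out <- plan$wt[[1L]] * v[plan$idx[[1L]]]
  for (k in 2:8) out <- out + plan$wt[[k]] * v[plan$idx[[k]]]
  out
}

.warp_nearest <- function(a, plan) as.vector(a)[plan$nearest]

#' Random 3D elastic or affine augmentation
#'
#' With probability `prob`, applies one randomly chosen warp — a small
#' affine (rotation up to ~10 degrees, scaling 0.9-1.1, translation up to 2
#' voxels) or an elastic deformation (smooth displacement field from a 4^3
#' control grid with SD `warp_sd` voxels) — identically to every contrast
#' and every label mask. Intensities are resampled trilinearly; labels with
#' nearest neighbor, so they stay binary.
#'
#' @param vol an [mc_volume()].
#' @param labels list of binary 3D masks aligned with `vol`.
#' @param prob warp probability.
#' @param warp_sd elastic control-point displacement SD (voxels).
#' @return list `list(vol, labels)`.
#' @export
augment_3d <- function(vol, labels, prob = 0.75, warp_sd = 1.5) {
  stopifnot(inherits(vol, "mc_volume"))
  if (runif(1) >= prob) return(list(vol = vol, labels = labels))
  shape <- dim(vol$data)[1:3]
  g <- list(x = slice.index(array(0, shape), 1L),
            y = slice.index(array(0, shape), 2L),
            z = slice.index(array(0, shape), 3L))
  if (runif(1) < 0.5) {  # affine
    ang <- runif(3L, -10, 10) * pi / 180
    rot <- function(t, i) {
      m <- diag(3); ax <- setdiff(1:3, i)
      m[ax[1L], ax[1L]] <- cos(t); m[ax[2L], ax[2L]] <- cos(t)
      m[ax[1L], ax[2L]] <- -sin(t); m[ax[2L], ax[1L]] <- sin(t)
      m
    }
    A <- rot(ang[1L], 1L) %*% rot(ang[2L], 2L) %*% rot(ang[3L], 3L) %*%
      diag(runif(3L, 0.9, 1.1))
    ctr <- (shape + 1) / 2
    tr <- runif(3L, -2, 2)
    cx <- as.vector(g$x) - ctr[1L]; cy <- as.vector(g$y) - ctr[2L]
    cz <- as.vector(g$z) - ctr[3L]
    # inverse map: source = A^-1 (target - t)
    Ai <- solve(A)
    sx <- Ai[1, 1] * (cx - tr[1L]) + Ai[1, 2] * (cy - tr[2L]) +
      Ai[1, 3] * (cz - tr[3L]) + ctr[1L]
    sy <- Ai[2, 1] * (cx - tr[1L]) + Ai[2, 2] * (cy - tr[2L]) +
      Ai[2, 3] * (cz - tr[3L]) + ctr[2L]
    sz <- Ai[3, 1] * (cx - tr[1L]) + Ai[3, 2] * (cy - tr[2L]) +
      Ai[3, 3] * (cz - tr[3L]) + ctr[3L]
  } else {  # elastic
    disp <- lapply(1:3, function(i)
      .interp_coarse(array(rnorm(64L, sd = warp_sd), dim = c(4L, 4L, 4L)),
                     shape))
    sx <- as.vector(g$x) + as.vector(disp[[1L]])
    sy <- as.vector(g$y) + as.vector(disp[[2L]])
    sz <- as.vector(g$z) + as.vector(disp[[3L]])
  }
  plan <- .warp_plan(shape, sx, sy, sz)
  for (ci in which(vol$present))
    vol$data[, , , ci] <- array(.warp_trilinear(vol$data[, , , ci], plan),
                                dim = shape)
  labels <- lapply(labels, function(lb)
    array(as.integer(.warp_nearest(lb, plan)), dim = shape))
  list(vol = vol, labels = labels)
}

# slices (along dim 3 of the plane-permuted mask) containing >= 1 lesion voxel
.lesion_slices <- function(mask, plane) {
  m <- aperm(mask, .plane_perm(plane))
  which(apply(m, 3L, function(s) any(s == 1L)))
}

#' Sample one training batch
#'
#' Every item's central label slice contains at least one lesion voxel. One
#' plane and one dihedral operation are drawn per batch and applied
#' identically to inputs and labels; the rater is drawn uniformly per item;
#' contrast dropout (when enabled) is applied per item and the surviving
#' combination recorded for conditional normalization. Uses the current RNG
#' state.
#'
#' @param dataset a [make_dataset()] cohort (train split is used).
#' @param config a [train_config()].
#' @param use_cd apply contrast dropout.
#' @return list `x` (H x W x 12 x N), `y` (H x W x 1 x N), `combos`
#'   (integer N), `plane`, `dihedral`.
#' @export
sample_batch <- function(dataset, config = train_config(preset = "tiny"),
                         use_cd = TRUE) {
  plane <- sample(.planes, 1L)
  dihedral <- sample(.dihedrals, 1L)
  d <- tta_transform(plane, dihedral)
  n <- config$batch_size
  xs <- vector("list", n); ys <- vector("list", n)
  combos <- integer(n)
  for (i in seq_len(n)) {
    subj <- dataset$subjects[[sample(dataset$train, 1L)]]
    vol <- subj$vol
    labels <- list(subj$rater1, subj$rater2)
    aug <- augment_3d(vol, labels, config$elastic_affine_prob, config$warp_sd)
    vol <- zscore_volume(aug$vol)
    label <- aug$labels[[sample.int(2L, 1L)]]
    ks <- .lesion_slices(label, plane)
    if (length(ks) == 0L) {
      ks <- .lesion_slices(subj$truth, plane)
      if (length(ks) == 0L) stop("dataset has no lesion-containing slices")
      label <- subj$truth
      vol <- zscore_volume(subj$vol)
    }
    k <- ks[sample.int(length(ks), 1L)]
    keep <- if (use_cd) .sample_surviving(vol$present) else vol$present
    slab <- extract_25d(vol, plane, k)$channels
    for (ci in which(!keep)) slab[, , ci + c(0L, 4L, 8L)] <- 0
    tl <- apply_transform(label, d)
    xs[[i]] <- .apply_dihedral(slab, dihedral)
    ys[[i]] <- tl[, , k]
    combos[i] <- combo_index(keep)
  }
  hw <- dim(xs[[1L]])
  x <- array(unlist(xs, use.names = FALSE), dim = c(hw, n))
  y <- array(unlist(ys, use.names = FALSE), dim = c(hw[1L], hw[2L], 1L, n))
  list(x = x, y = y, combos = combos, plane = plane, dihedral = dihedral)
}

# Adam step over the flat layer list; state is kept per tensor.
.adam_step <- function(layers, grads, state, lr, t,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (ln in names(grads)) {
    gl <- grads[[ln]]
    fields <- if (!is.null(gl$gw)) c(w = "gw", b = "gb")
      else c(gamma = "ggamma", beta = "gbeta")
    for (f in names(fields)) {
      g <- gl[[fields[[f]]]]
      key <- paste0(ln, ".", f)
      if (is.null(state[[key]]))
        state[[key]] <- list(m = g * 0, v = g * 0)
      s <- state[[key]]
      s$m <- beta1 * s$m + (1 - beta1) * g
      s$v <- beta2 * s$v + (1 - beta2) * g * g
      state[[key]] <- s
      mhat <- s$m / (1 - beta1^t)
      vhat <- s$v / (1 - beta2^t)
      layers[[ln]][[f]] <- layers[[ln]][[f]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(layers = layers, state = state)
}

#' Fit the lesion segmentation model
#'
#' The fitting entry point: trains the 2.5D backbone on a phantom cohort
#' with the L2 loss between the predicted probability map of the central
#' slice and the sampled rater label, using Adam. The model from the last
#' epoch is returned. Fully seeded: weight initialization, batch sampling,
#' warps and contrast dropout all derive from `control$seed`.
#'
#' @param dataset a [make_dataset()] cohort.
#' @param backbone a [backbone_config()].
#' @param control a [train_config()].
#' @param use_cd train with contrast dropout.
#' @param verbose print per-epoch mean loss.
#' @return an object of class `ms_model` with fields `backbone` (the trained
#'   `ms_backbone`), `control`, `use_cd` and `loss` (per-iteration L2).
#' @export
train_backbone <- function(dataset, backbone = backbone_config(preset = "tiny"),
                           control = train_config(preset = "tiny"),
                           use_cd = TRUE, verbose = FALSE) {
  stopifnot(inherits(backbone, "backbone_config"),
            inherits(control, "train_config"))
  set.seed(control$seed)
  model <- build_backbone(backbone)
  adam <- list()
  losses <- numeric(0)
  t <- 0L
  for (ep in seq_len(control$epochs)) {
    for (it in seq_len(control$iters_per_epoch)) {
      b <- sample_batch(dataset, control, use_cd = use_cd)
      fw <- .backbone_forward(model, b$x, b$combos, phase = "train")
      model <- fw$model
      resid <- fw$out - b$y
      loss <- mean(resid^2)
      if (!is.finite(loss)) stop("training diverged: non-finite loss")
      losses <- c(losses, loss)
      if (control$lr > 0) {
        gout <- 2 * resid / length(resid)
        grads <- .backbone_backward(model, fw$cache, gout)
        t <- t + 1L
        st <- .adam_step(model$layers, grads, adam, control$lr, t)
        model$layers <- st$layers
        adam <- st$state
      }
    }
    if (verbose)
      message(sprintf("epoch %d/%d: mean L2 %.5f", ep, control$epochs,
                      mean(utils::tail(losses, control$iters_per_epoch))))
  }
  structure(list(backbone = model, control = control, use_cd = use_cd,
                 loss = losses),
            class = "ms_model")
}

#' @export
print.ms_model <- function(x, ...) {
  cfg <- x$backbone$config
  cat(sprintf(
    "<ms_model: %d-level backbone (%s), norm %s, CD %s, %d iterations, final L2 %.5f>\n",
    cfg$levels, paste(cfg$channels, collapse = "/"), cfg$norm_mode,
    ifelse(x$use_cd, "on", "off"), length(x$loss),
    utils::tail(x$loss, 1L)))
  invisible(x)
}

#' @export
summary.ms_model <- function(object, ...) {
  cat("Lesion segmentation model\n")
  print(object)
  n <- length(object$loss)
  k <- max(1L, n %/% 10L)
  cat(sprintf("  L2 loss: first-%d mean %.5f, last-%d mean %.5f\n",
              k, mean(object$loss[seq_len(k)]),
              k, mean(utils::tail(object$loss, k))))
  npar <- sum(vapply(object$backbone$layers, function(l)
    length(unlist(l[intersect(names(l), c("w", "b", "gamma", "beta"))])),
    numeric(1L)))
  cat(sprintf("  parameters: %d\n", as.integer(npar)))
  invisible(object)
}

#' Segment a subject with the full test-time pipeline
#'
#' Applies all 24 multi-orientation augmentations, segments each augmented
#' volume slice-wise, maps the binary masks back to the original grid,
#' aggregates them into the confidence map and fuses with the two-threshold
#' connected-growth procedure. The contrast combination is inferred from the
#' volume's presence flags.
#'
#' @param model an `ms_model` (or bare `ms_backbone`).
#' @param vol an [mc_volume()].
#' @param params a [fusion_params()].
#' @param use_ttin use test-time instance normalization (otherwise BN models
#'   fall back to their moving statistics).
#' @param augmentations descriptors to ensemble (default all 24).
#' @param return_masks also return the per-augmentation masks.
#' @return list with `mask` (fused binary mask), `confidence`
#'   ([confidence_map()]) and optionally `masks`.
#' @export
predict_subject <- function(model, vol, params = fusion_params(),
                            use_ttin = TRUE,
                            augmentations = list_augmentations(),
                            return_masks = FALSE) {
  bb <- if (inherits(model, "ms_model")) model$backbone else model
  stopifnot(inherits(bb, "ms_backbone"), inherits(vol, "mc_volume"))
  combo <- combo_index(vol$present)
  nvol <- zscore_volume(vol)
  masks <- lapply(augmentations, function(d)
    segment_volume(bb, nvol, d, combo = combo, use_ttin = use_ttin,
                   normalize = FALSE))
  fz <- fuse_masks(masks, params, return_confidence = TRUE)
  out <- list(mask = fz$mask, confidence = fz$confidence)
  if (return_masks) out$masks <- masks
  out
}

#' @export
predict.ms_model <- function(object, newdata, params = fusion_params(),
                             use_ttin = TRUE, ...) {
  predict_subject(object, newdata, params = params, use_ttin = use_ttin, ...)
}
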