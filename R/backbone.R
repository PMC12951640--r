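# Reference 2.5D encoder-decoder segmentation backbone.
# Each level holds two blocks of (3x3 convolution -> ReLU -> normalization);
# downsampling is 2x2 max pooling, upsampling is nearest-neighbor followed by
# a 3x3 convolution; skip features are concatenated ahead of the decoder
# blocks (skip channels first, upsampled channels second); the head is a 1x1
# convolution squashed to [0, 1] by a logistic sigmoid.

#' Backbone configuration
#'
#' @param levels number of resolution levels (>= 2).
#' @param channels strictly increasing feature widths, one per level. The
#'   full-size default is `c(64, 128, 256, 512, 1024)`.
#' @param norm_mode normalization mode used at training time (`"BN"`,
#'   `"IN"`, `"CondIN"`).
#' @param in_channels input channels; 12 for a 2.5D slab over four contrasts.
#' @param preset `"full"` or `"tiny"`; `"tiny"` (2 levels, 8/16 channels) is
#'   sized for desk-scale training and tests.
#' @param eps,momentum normalization constants (see [norm_state()]).
#' @return a `backbone_config` list.
#' @export
backbone_config <- function(levels = 5L, channels = c(64L, 128L, 256L, 512L, 1024L),
                            norm_mode = c("CondIN", "BN", "IN"),
                            in_channels = 12L, preset = NULL,
                            eps = 1e-5, momentum = 0.1) {
  norm_mode <- match.arg(norm_mode)
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("full", "tiny"))
    if (preset == "tiny") { levels <- 2L; channels <- c(8L, 16L) }
  }
  levels <- as.integer(levels)
  channels <- as.integer(channels)
  stopifnot(levels >= 2L, length(channels) == levels,
            all(diff(channels) > 0), in_channels >= 1L)
  structure(list(levels = levels, channels = channels, norm_mode = norm_mode,
                 in_channels = as.integer(in_channels), out_channels = 1L,
                 eps = eps, momentum = momentum),
            class = "backbone_config")
}

.conv_init <- function(kh, kw, cin, cout) {
  sd <- sqrt(2 / (kh * kw * cin))
  list(w = array(rnorm(kh * kw * cin * cout, sd = sd), dim = c(kh, kw, cin, cout)),
       b = rep(0, cout))
}

#' Build a segmentation backbone
#'
#' Instantiates the network parameters for a [backbone_config()]. Weights
#' are He-initialized from the current RNG state; seed upstream for
#' reproducibility.
#'
#' @param config a [backbone_config()].
#' @return an object of class `ms_backbone`.
#' @export
build_backbone <- function(config = backbone_config()) {
  stopifnot(inherits(config, "backbone_config"))
  L <- config$levels; ch <- config$channels
  layers <- list()
  cin <- config$in_channels
  for (l in seq_len(L)) {
    layers[[sprintf("enc%d.conv1", l)]] <- .conv_init(3L, 3L, cin, ch[l])
    layers[[sprintf("enc%d.norm1", l)]] <- norm_state(config$norm_mode, ch[l],
                                                      config$eps, config$momentum)
    layers[[sprintf("enc%d.conv2", l)]] <- .conv_init(3L, 3L, ch[l], ch[l])
    layers[[sprintf("enc%d.norm2", l)]] <- norm_state(config$norm_mode, ch[l],
                                                      config$eps, config$momentum)
    cin <- ch[l]
  }
  for (l in seq_len(L - 1L)) {
    layers[[sprintf("dec%d.up", l)]] <- .conv_init(3L, 3L, ch[l + 1L], ch[l])
    layers[[sprintf("dec%d.conv1", l)]] <- .conv_init(3L, 3L, 2L * ch[l], ch[l])
    layers[[sprintf("dec%d.norm1", l)]] <- norm_state(config$norm_mode, ch[l],
                                                      config$eps, config$momentum)
    layers[[sprintf("dec%d.conv2", l)]] <- .conv_init(3L, 3L, ch[l], ch[l])
    layers[[sprintf("dec%d.norm2", l)]] <- norm_state(config$norm_mode, ch[l],
                                                      config$eps, config$momentum)
  }
  layers[["head"]] <- .conv_init(1L, 1L, ch[1L], 1L)
  structure(list(config = config, layers = layers), class = "ms_backbone")
}

#' @export
print.ms_backbone <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<ms_backbone: %d levels (%s), norm %s, in=%d>\n",
              cfg$levels, paste(cfg$channels, collapse = "/"),
              cfg$norm_mode, cfg$in_channels))
  invisible(x)
}

# Normalization phase for a model-level phase and mode. IN/CondIN have no
# stored statistics, so their inference path is per-instance by definition.
.norm_phase <- function(phase, mode) {
  if (phase == "train") return("train")
  if (phase == "ttin") return("ttin")
  if (mode == "BN") "bn_infer" else "ttin"
}

.block_forward <- function(x, conv, norm, combo, nphase) {
  z <- cpp_conv2d(x, conv$w, conv$b)
  mask <- z > 0
  r <- z * mask
  nf <- .norm_forward(r, norm, combo, phase = nphase)
  list(y = nf$y, norm = nf$state,
       cache = list(x = x, mask = mask, ncache = nf$cache))
}

.block_backward <- function(gy, conv, norm, cache) {
  nb <- .norm_backward(gy, norm, cache$ncache)
  gr <- nb$gx * cache$mask
  cb <- cpp_conv2d_backward(cache$x, conv$w, gr)
  list(gx = cb$gx,
       grads = list(gw = cb$gw, gb = cb$gb,
                    ggamma = nb$ggamma, gbeta = nb$gbeta))
}

# Full forward pass. x: [H, W, in_channels, N]. Returns the sigmoid output
# [H, W, 1, N], caches for backward, and the model (with BN moving averages
# updated when phase == "train").
.backbone_forward <- function(model, x, combo, phase = c("train", "ttin", "stats")) {
  phase <- match.arg(phase)
  cfg <- model$config
  L <- cfg$levels
  np <- .norm_phase(phase, cfg$norm_mode)
  ly <- model$layers
  cache <- list(phase = phase)
  skips <- list()

  for (l in seq_len(L)) {
    for (blk in 1:2) {
      cv <- ly[[sprintf("enc%d.conv%d", l, blk)]]
      nm <- ly[[sprintf("enc%d.norm%d", l, blk)]]
      bf <- .block_forward(x, cv, nm, combo, np)
      ly[[sprintf("enc%d.norm%d", l, blk)]] <- bf$norm
      cache[[sprintf("enc%d.b%d", l, blk)]] <- bf$cache
      x <- bf$y
    }
    if (l < L) {
      skips[[l]] <- x
      mp <- cpp_maxpool2(x)
      cache[[sprintf("pool%d", l)]] <- list(idx = mp$idx, xdim = dim(x))
      x <- mp$y
    }
  }

  for (l in rev(seq_len(L - 1L))) {
    up <- cpp_upsample2(x)
    cv <- ly[[sprintf("dec%d.up", l)]]
    u <- cpp_conv2d(up, cv$w, cv$b)
    cache[[sprintf("up%d", l)]] <- list(x = up, xdim = dim(x))
    d <- dim(u)
    ccat <- array(0, dim = c(d[1L], d[2L], 2L * d[3L], d[4L]))
    ccat[, , seq_len(d[3L]), ] <- skips[[l]]
    ccat[, , d[3L] + seq_len(d[3L]), ] <- u
    cache[[sprintf("cat%d", l)]] <- d[3L]
    x <- ccat
    for (blk in 1:2) {
      cv2 <- ly[[sprintf("dec%d.conv%d", l, blk)]]
      nm <- ly[[sprintf("dec%d.norm%d", l, blk)]]
      bf <- .block_forward(x, cv2, nm, combo, np)
      ly[[sprintf("dec%d.norm%d", l, blk)]] <- bf$norm
      cache[[sprintf("dec%d.b%d", l, blk)]] <- bf$cache
      x <- bf$y
    }
  }

  hd <- ly[["head"]]
  z <- cpp_conv2d(x, hd$w, hd$b)
  out <- 1 / (1 + exp(-z))
  cache[["head"]] <- list(x = x, out = out)
  model$layers <- ly
  list(out = out, cache = cache, model = model)
}

# Backward pass from the gradient of the loss w.r.t. the sigmoid output.
# Returns a flat named list of parameter gradients.
.backbone_backward <- function(model, cache, gout) {
  cfg <- model$config
  L <- cfg$levels
  ly <- model$layers
  grads <- list()

  hc <- cache[["head"]]
  gz <- gout * hc$out * (1 - hc$out)
  cb <- cpp_conv2d_backward(hc$x, ly[["head"]]$w, gz)
  grads[["head"]] <- list(gw = cb$gw, gb = cb$gb)
  gx <- cb$gx

  for (l in seq_len(L - 1L)) {
    for (blk in 2:1) {
      nmname <- sprintf("dec%d.norm%d", l, blk)
      bb <- .block_backward(gx, ly[[sprintf("dec%d.conv%d", l, blk)]],
                            ly[[nmname]], cache[[sprintf("dec%d.b%d", l, blk)]])
      grads[[sprintf("dec%d.conv%d", l, blk)]] <- bb$grads[c("gw", "gb")]
      grads[[nmname]] <- bb$grads[c("ggamma", "gbeta")]
      gx <- bb$gx
    }
    cs <- cache[[sprintf("cat%d", l)]]
    gskip <- gx[, , seq_len(cs), , drop = FALSE]
    gu <- gx[, , cs + seq_len(cs), , drop = FALSE]
    uc <- cache[[sprintf("up%d", l)]]
    cb <- cpp_conv2d_backward(uc$x, ly[[sprintf("dec%d.up", l)]]$w, gu)
    grads[[sprintf("dec%d.up", l)]] <- list(gw = cb$gw, gb = cb$gb)
    gup <- cpp_upsample2_backward(cb$gx)
    cache[[sprintf("carry%d", l)]] <- list(gskip = gskip, gup = gup)
  }

  # encoder backward, deepest level first
  gx <- cache[[sprintf("carry%d", L - 1L)]]$gup
  for (l in rev(seq_len(L))) {
    if (l < L) {
      pc <- cache[[sprintf("pool%d", l)]]
      gx <- cpp_maxpool2_backward(gx, pc$idx, pc$xdim)
      gx <- gx + cache[[sprintf("carry%d", l)]]$gskip
    }
    for (blk in 2:1) {
      nmname <- sprintf("enc%d.norm%d", l, blk)
      bb <- .block_backward(gx, ly[[sprintf("enc%d.conv%d", l, blk)]],
                            ly[[nmname]], cache[[sprintf("enc%d.b%d", l, blk)]])
      grads[[sprintf("enc%d.conv%d", l, blk)]] <- bb$grads[c("gw", "gb")]
      grads[[nmname]] <- bb$grads[c("ggamma", "gbeta")]
      gx <- bb$gx
    }
  }
  grads
}

#' Predict the central slice of a 2.5D slab
#'
#' Runs the backbone on one slab and returns the probabilistic map of the
#' central slice, with values in `[0, 1]`.
#'
#' @param model an [build_backbone()] model.
#' @param slab a [extract_25d()] slab (or a bare `H x W x C` array).
#' @param combo contrast-combination index (see [combo_index()]).
#' @param use_ttin if `TRUE`, normalization statistics are recomputed from
#'   this input (test-time instance normalization); if `FALSE`, BN models use
#'   their moving averages.
#' @return an `H x W` matrix of probabilities.
#' @export
predict_slice <- function(model, slab, combo = 15L, use_ttin = TRUE) {
  stopifnot(inherits(model, "ms_backbone"))
  if (any(as.integer(combo) < 1L)) stop("contrast combination must be non-empty")
  x <- if (inherits(slab, "slab25d")) slab$channels else slab
  stopifnot(length(dim(x)) == 3L)
  if (dim(x)[3L] != model$config$in_channels)
    stop("slab channel count does not match the model configuration")
  dim(x) <- c(dim(x), 1L)
  phase <- if (use_ttin) "ttin" else "stats"
  out <- .backbone_forward(model, x, combo, phase = phase)$out
  matrix(out, dim(out)[1L], dim(out)[2L])
}

# z-score a multicontrast volume per contrast over its nonzero voxels;
# zero voxels (background / absent contrasts) stay exactly zero.
#' Intensity-normalize a multicontrast volume
#'
#' Per-contrast z-scoring over nonzero voxels, the network's expected input
#' scale. Background and absent-contrast voxels remain exactly zero.
#'
#' @param vol an [mc_volume()].
#' @return the normalized `mc_volume`.
#' @export
zscore_volume <- function(vol) {
  stopifnot(inherits(vol, "mc_volume"))
  for (ci in which(vol$present)) {
    ch <- vol$data[, , , ci]
    nz <- ch != 0
    if (any(nz)) {
      v <- ch[nz]
      s <- sd(v)
      if (!is.finite(s) || s == 0) s <- 1
      ch[nz] <- (v - mean(v)) / s
      vol$data[, , , ci] <- ch
    }
  }
  vol
}

#' Segment a volume under one multi-orientation transform
#'
#' Applies the descriptor to the volume, runs slice-wise 2.5D prediction
#' along the transformed slicing axis, thresholds the probability maps at
#' 0.5, stacks the binary slices, and maps the resulting 3D mask back to the
#' original grid.
#'
#' @param model an `ms_backbone`.
#' @param vol an [mc_volume()]; z-scored internally when `normalize = TRUE`.
#' @param d a [tta_transform()].
#' @param combo contrast-combination index; defaults to the volume's
#'   presence flags.
#' @param use_ttin see [predict_slice()].
#' @param threshold probability cut for the binary mask.
#' @param normalize apply [zscore_volume()] first.
#' @return an integer 3D mask on the original grid.
#' @export
segment_volume <- function(model, vol, d = tta_transform(), combo = NULL,
                           use_ttin = TRUE, threshold = 0.5, normalize = TRUE) {
  stopifnot(inherits(model, "ms_backbone"), inherits(vol, "mc_volume"))
  if (is.null(combo)) combo <- combo_index(vol$present)
  if (normalize) vol <- zscore_volume(vol)
  tv <- transform_volume(vol, d)
  dd <- dim(tv$data)
  nk <- dd[3L]
  nc <- 4L
  x <- array(0, dim = c(dd[1L], dd[2L], 3L * nc, nk))
  for (k in seq_len(nk)) {
    ci <- 0L
    for (s in (k - 1L):(k + 1L)) {
      for (cc in seq_len(nc)) {
        ci <- ci + 1L
        if (s >= 1L && s <= nk) x[, , ci, k] <- tv$data[, , s, cc]
      }
    }
  }
  phase <- if (use_ttin) "ttin" else "stats"
  out <- .backbone_forward(model, x, combo, phase = phase)$out
  mask <- array(as.integer(out[, , 1L, ] > threshold), dim = c(dd[1L], dd[2L], nk))
  invert_transform(mask, d)
}

# Uniformly sample a surviving non-empty subset of the present contrasts.
.sample_surviving <- function(present) {
  idx <- which(present)
  if (length(idx) <= 1L) return(present)
  subsets <- list()
  for (m in 1:(2L^length(idx) - 1L)) {
    keepbits <- as.logical(bitwAnd(m, 2L^(seq_along(idx) - 1L)))
    subsets[[length(subsets) + 1L]] <- idx[keepbits]
  }
  keep <- subsets[[sample.int(length(subsets), 1L)]]
  out <- rep(FALSE, 4L)
  out[keep] <- TRUE
  out
}

#' Contrast dropout
#'
#' Training augmentation for missing-modality robustness: a random proper
#' subset of the present contrasts is zeroed and its presence flags cleared.
#' The surviving combination is drawn uniformly from the non-empty subsets of
#' the present contrasts, so all 15 combinations are visited during
#' training; at least one contrast always survives. Uses the R RNG; seed for
#' reproducibility.
#'
#' @param vols an [mc_volume()] or a list of them.
#' @return the input with dropped contrasts zeroed and flags cleared.
#' @export
contrast_dropout <- function(vols) {
  single <- inherits(vols, "mc_volume")
  lst <- if (single) list(vols) else vols
  lst <- lapply(lst, function(v) {
    stopifnot(inherits(v, "mc_volume"))
    keep <- .sample_surviving(v$present)
    for (ci in which(v$present & !keep)) v$data[, , , ci] <- 0
    v$present <- keep
    v
  })
  if (single) lst[[1L]] else lst
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single serialized file plus a JSON sidecar describing
#' the architecture and normalization mode. Round-trips bit-identically.
#'
#' @param model an `ms_backbone`.
#' @param path checkpoint file path (`.rds`); the sidecar is `path + ".json"`.
#' @return `save_model()` returns `path` invisibly; `load_model()` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ms_backbone"))
  saveRDS(model, path)
  side <- model$config
  class(side) <- NULL
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "ms_backbone"))
  model
}
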