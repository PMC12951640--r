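# Self-ensembled lesion fusion: an integer confidence map over the
# augmented predictions, two thresholds (lesion detection at tau1, growth
# candidates at tau2 <= tau1), and 26-connected growth of the detected
# lesions into the candidate mask -- a 3D analogue of hysteresis
# thresholding.

.as_mask <- function(m) {
  if (is.logical(m)) m <- m * 1L
  if (!all(m %in% c(0L, 1L))) stop("mask must be binary (0/1)")
  storage.mode(m) <- "integer"
  m
}

#' Aggregate binary masks into a confidence map
#'
#' Voxel-wise integer sum of N aligned binary masks: `C(r)` counts how many
#' augmented predictions label voxel `r` as lesion, so `C(r)` takes integer
#' values in `[0, N]`.
#'
#' @param masks list of binary 3D arrays on a common grid.
#' @return object of class `confidence_map` with fields `C` (integer array)
#'   and `n_models`.
#' @export
confidence_map <- function(masks) {
  stopifnot(is.list(masks), length(masks) >= 1L)
  masks <- lapply(masks, .as_mask)
  d <- dim(masks[[1L]])
  if (!all(vapply(masks, function(m) identical(dim(m), d), logical(1L))))
    stop("all masks must share one grid")
  C <- Reduce(`+`, masks)
  storage.mode(C) <- "integer"
  structure(list(C = C, n_models = length(masks)), class = "confidence_map")
}

#' @export
print.confidence_map <- function(x, ...) {
  cat(sprintf("<confidence_map %s, N=%d, range %d..%d>\n",
              paste(dim(x$C), collapse = "x"), x$n_models,
              min(x$C), max(x$C)))
  invisible(x)
}

#' Threshold a confidence map
#'
#' Strict inequality: voxels with `C(r) > tau` are set. At `tau = n_models`
#' the result is empty; masks are nested (anti-monotone) in `tau`.
#'
#' @param cmap a [confidence_map()] (or bare integer array).
#' @param tau integer threshold in `[0, n_models]`.
#' @return a binary integer 3D array.
#' @export
threshold_mask <- function(cmap, tau) {
  C <- if (inherits(cmap, "confidence_map")) cmap$C else cmap
  n <- if (inherits(cmap, "confidence_map")) cmap$n_models else max(C)
  if (tau < 0 || tau > n) stop("tau must lie in [0, n_models]")
  out <- array(as.integer(C > tau), dim = dim(C))
  out
}

#' Label connected components of a 3D mask
#'
#' @param mask binary 3D array.
#' @param connectivity 6, 18 or 26 (default 26: faces, edges and corners).
#' @return integer array of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 26L) {
  cpp_label3d(.as_mask(mask), as.integer(connectivity))
}

#' Connected lesion growth
#'
#' Grows the high-confidence detections `M1` into the candidate mask `M2`:
#' the result is the union of those 26-connected components of `M2` that
#' contain at least one `M1` voxel — the fixed point of iterated one-step
#' 26-neighborhood dilation of `M1` within `M2`. Candidate components with
#' no detection are discarded.
#'
#' @param m1 binary detection mask (must satisfy `m1` a subset of `m2`).
#' @param m2 binary candidate mask.
#' @return the grown binary mask `M` with `M1` a subset of `M` a subset of
#'   `M2`.
#' @export
connected_growth <- function(m1, m2) {
  m1 <- .as_mask(m1); m2 <- .as_mask(m2)
  stopifnot(identical(dim(m1), dim(m2)))
  if (any(m1 > m2)) stop("M1 must be a subset of M2 (tau1 >= tau2)")
  lab <- cpp_label3d(m2, 26L)
  seeds <- unique(lab[m1 == 1L])
  seeds <- seeds[seeds != 0L]
  out <- array(as.integer(lab %in% seeds), dim = dim(m2))
  out
}

#' Fusion parameters
#'
#' The two thresholds of self-ensembled lesion fusion. The defaults
#' `tau1 = 16`, `tau2 = 7` are the cross-validated operating point for a
#' 24-fold augmentation ensemble with CondIN training.
#'
#' @param tau1 detection threshold (high confidence).
#' @param tau2 growth-candidate threshold, `tau2 <= tau1`.
#' @return a `fusion_params` list.
#' @export
fusion_params <- function(tau1 = 16L, tau2 = 7L) {
  tau1 <- as.integer(tau1); tau2 <- as.integer(tau2)
  if (tau2 > tau1 || tau2 < 0L) stop("need tau1 >= tau2 >= 0")
  structure(list(tau1 = tau1, tau2 = tau2), class = "fusion_params")
}

#' Fuse augmented binary predictions into a final lesion mask
#'
#' Builds the confidence map, thresholds it at `tau1` (detection) and `tau2`
#' (candidates), and applies [connected_growth()]. The result always
#' satisfies `M1` a subset of `M` a subset of `M2`.
#'
#' @param masks list of aligned binary 3D masks (any N >= 1).
#' @param params a [fusion_params()].
#' @param return_confidence also return the confidence map.
#' @return the fused binary mask, or (with `return_confidence`) a list
#'   `list(mask, confidence)`.
#' @export
fuse_masks <- function(masks, params = fusion_params(),
                       return_confidence = FALSE) {
  stopifnot(inherits(params, "fusion_params"))
  cmap <- confidence_map(masks)
  if (params$tau1 > cmap$n_models)
    stop("tau1 exceeds the number of masks")
  m1 <- threshold_mask(cmap, params$tau1)
  m2 <- threshold_mask(cmap, params$tau2)
  m <- connected_growth(m1, m2)
  if (return_confidence) list(mask = m, confidence = cmap) else m
}

#' Majority-vote fusion baseline
#'
#' Single-threshold voxel-wise voting, i.e. fusion with `tau1 = tau2 = t`.
#' The default `t = floor(N/2)` with the strict inequality `C > t` is the
#' >50% majority (13 of 24 votes for a 24-mask ensemble); other conventions
#' can be selected via `t`.
#'
#' @param masks list of aligned binary 3D masks.
#' @param t vote threshold; default `floor(N/2)`.
#' @return the voted binary mask.
#' @export
majority_vote <- function(masks, t = NULL) {
  n <- length(masks)
  if (is.null(t)) t <- n %/% 2L
  fuse_masks(masks, fusion_params(tau1 = t, tau2 = t))
}
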