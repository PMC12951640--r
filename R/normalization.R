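# Feature normalization: y_j = gamma_j * (x_j - E[x_j]) / sqrt(Var[x_j] + eps) + beta_j
# Three training modes share this form and differ only in which axes the
# statistics are pooled over and which affine set (gamma, beta) is used:
#   BN     - statistics over batch + spatial dims; moving averages stored.
#   IN     - statistics per instance over spatial dims only.
#   CondIN - as IN, with one (gamma, beta) set per input contrast combination
#            (15 sets for four contrasts).
# Test-time instance normalization (TTIN) computes per-instance statistics
# for each test input while reusing the trained affine parameters.

.N_COMBOS <- 15L

#' Create a normalization state
#'
#' Holds the learnable per-channel affine parameters (`gamma`, `beta`) of a
#' normalization layer, plus moving averages of the batch statistics in BN
#' mode. In CondIN mode a separate `(gamma, beta)` set is kept for each of
#' the 15 non-empty contrast combinations.
#'
#' @param mode `"BN"`, `"IN"` or `"CondIN"`.
#' @param channels number of feature channels.
#' @param eps variance floor in the normalization denominator.
#' @param momentum moving-average momentum (BN only).
#' @return an object of class `norm_state`.
#' @export
norm_state <- function(mode = c("IN", "BN", "CondIN"), channels,
                       eps = 1e-5, momentum = 0.1) {
  mode <- match.arg(mode)
  stopifnot(channels >= 1L, eps > 0)
  st <- list(mode = mode, channels = as.integer(channels),
             eps = eps, momentum = momentum)
  if (mode == "CondIN") {
    st$gamma <- matrix(1, .N_COMBOS, channels)
    st$beta <- matrix(0, .N_COMBOS, channels)
  } else {
    st$gamma <- rep(1, channels)
    st$beta <- rep(0, channels)
  }
  if (mode == "BN") {
    st$moving_mean <- rep(0, channels)
    st$moving_var <- rep(1, channels)
  }
  class(st) <- "norm_state"
  st
}

#' Contrast-combination index
#'
#' Encodes a set of present contrasts as a bitmask over (T1w, T2w, PDw,
#' FLAIR) = bits 1, 2, 4, 8, yielding an integer in 1..15. This index
#' selects the conditional affine set in CondIN mode.
#'
#' @param present logical(4) presence flags in storage order.
#' @return integer in 1..15.
#' @export
combo_index <- function(present) {
  stopifnot(length(present) == 4L)
  idx <- sum(2L^(0:3)[as.logical(present)])
  if (idx < 1L) stop("contrast combination must be non-empty")
  idx
}

#' Select the affine parameters for a contrast combination
#'
#' In CondIN mode returns the `(gamma, beta)` set stored at the combination's
#' bitmask index; in BN/IN modes the single shared set is returned for any
#' combination.
#'
#' @param state a [norm_state()].
#' @param combo integer combination index in 1..15 (see [combo_index()]).
#' @return list with elements `gamma` and `beta` (length-`channels` vectors).
#' @export
select_affine <- function(state, combo) {
  stopifnot(inherits(state, "norm_state"))
  if (state$mode == "CondIN") {
    combo <- as.integer(combo)
    if (length(combo) != 1L || is.na(combo) || combo < 1L || combo > .N_COMBOS)
      stop("combo must be a single integer in 1..15")
    list(gamma = state$gamma[combo, ], beta = state$beta[combo, ])
  } else {
    list(gamma = state$gamma, beta = state$beta)
  }
}

# Per-instance (column-wise) affine matrices for a batch: gamma/beta as
# C x N matrices flattened to the (c, n) column order of the feature matrix.
.affine_cols <- function(state, combo, n) {
  c_ <- state$channels
  if (state$mode == "CondIN") {
    combo <- rep_len(as.integer(combo), n)
    g <- t(state$gamma[combo, , drop = FALSE])
    b <- t(state$beta[combo, , drop = FALSE])
  } else {
    g <- matrix(state$gamma, c_, n)
    b <- matrix(state$beta, c_, n)
  }
  list(g = as.vector(g), b = as.vector(b), combo = combo)
}

# Core forward. phase: "train" (mode semantics, BN updates moving averages),
# "ttin" (per-instance statistics, trained affine), "bn_infer" (BN moving
# statistics, a pure affine map of the input).
.norm_forward <- function(x, state, combo, phase = "train") {
  d <- dim(x)
  stopifnot(length(d) == 4L, d[3L] == state$channels)
  hw <- d[1L] * d[2L]; c_ <- d[3L]; n <- d[4L]
  m <- matrix(x, nrow = hw)
  instance_stats <- phase == "ttin" || (phase == "train" && state$mode != "BN")

  if (phase == "bn_infer") {
    if (state$mode != "BN") stop("moving statistics only exist in BN mode")
    mu <- rep(state$moving_mean, n)
    va <- rep(state$moving_var, n)
  } else if (instance_stats) {
    mu <- colMeans(m)
    va <- pmax(colMeans(m * m) - mu^2, 0)
  } else {  # BN training statistics over batch + spatial dims
    a <- x; dim(a) <- c(hw, c_, n)
    mu_c <- va_c <- numeric(c_)
    for (ci in seq_len(c_)) {
      v <- a[, ci, ]
      mu_c[ci] <- mean(v)
      va_c[ci] <- max(mean(v * v) - mu_c[ci]^2, 0)
    }
    mom <- state$momentum
    state$moving_mean <- (1 - mom) * state$moving_mean + mom * mu_c
    state$moving_var <- (1 - mom) * state$moving_var + mom * va_c
    mu <- rep(mu_c, n)
    va <- rep(va_c, n)
  }

  inv_sd <- 1 / sqrt(va + state$eps)
  xhat <- (m - matrix(mu, hw, c_ * n, byrow = TRUE)) *
    matrix(inv_sd, hw, c_ * n, byrow = TRUE)
  af <- .affine_cols(state, combo, n)
  y <- xhat * matrix(af$g, hw, c_ * n, byrow = TRUE) +
    matrix(af$b, hw, c_ * n, byrow = TRUE)
  dim(y) <- d
  list(y = y, state = state,
       cache = list(xhat = xhat, inv_sd = inv_sd, g = af$g,
                    combo = af$combo, dims = d,
                    bn_stats = !instance_stats && phase != "bn_infer",
                    bn_infer = phase == "bn_infer"))
}

# Backward through the normalization. Returns the input gradient and the
# affine-parameter gradients in the same shape as the state holds them.
.norm_backward <- function(gy, state, cache) {
  d <- cache$dims
  hw <- d[1L] * d[2L]; c_ <- d[3L]; n <- d[4L]
  gm <- matrix(gy, nrow = hw)
  xhat <- cache$xhat

  gg_col <- colSums(gm * xhat)   # per (c, n) column
  gb_col <- colSums(gm)
  gxhat <- gm * matrix(cache$g, hw, c_ * n, byrow = TRUE)

  if (cache$bn_infer) {
    gx <- gxhat * matrix(cache$inv_sd, hw, c_ * n, byrow = TRUE)
  } else if (cache$bn_stats) {
    # statistics pooled over batch + spatial: reduce sums per channel
    grp <- rep(seq_len(c_), n)
    s1 <- tapply(colSums(gxhat), grp, sum)
    s2 <- tapply(colSums(gxhat * xhat), grp, sum)
    g_ <- hw * n
    gx <- (gxhat -
             matrix(rep(s1 / g_, n), hw, c_ * n, byrow = TRUE) -
             xhat * matrix(rep(s2 / g_, n), hw, c_ * n, byrow = TRUE)) *
      matrix(cache$inv_sd, hw, c_ * n, byrow = TRUE)
  } else {
    s1 <- colSums(gxhat); s2 <- colSums(gxhat * xhat)
    gx <- (gxhat -
             matrix(s1 / hw, hw, c_ * n, byrow = TRUE) -
             xhat * matrix(s2 / hw, hw, c_ * n, byrow = TRUE)) *
      matrix(cache$inv_sd, hw, c_ * n, byrow = TRUE)
  }
  dim(gx) <- d

  if (state$mode == "CondIN") {
    ggamma <- matrix(0, .N_COMBOS, c_)
    gbeta <- matrix(0, .N_COMBOS, c_)
    gg <- matrix(gg_col, c_, n)
    gb <- matrix(gb_col, c_, n)
    for (i in seq_len(n)) {
      k <- cache$combo[i]
      ggamma[k, ] <- ggamma[k, ] + gg[, i]
      gbeta[k, ] <- gbeta[k, ] + gb[, i]
    }
  } else {
    ggamma <- rowSums(matrix(gg_col, c_, n))
    gbeta <- rowSums(matrix(gb_col, c_, n))
  }
  list(gx = gx, ggamma = ggamma, gbeta = gbeta)
}

#' Normalize a feature map in training mode
#'
#' Applies the mode's training-time normalization: BN pools statistics over
#' the batch and spatial dims and updates the moving averages; IN pools per
#' instance over spatial dims only; CondIN behaves as IN with the affine set
#' selected by the contrast combination.
#'
#' @param x feature map array `H x W x C x N`.
#' @param state a [norm_state()].
#' @param combo combination index (scalar, or length-`N` vector in CondIN
#'   mode for per-instance conditioning).
#' @return list with the normalized map `y` and the (possibly updated)
#'   `state`.
#' @export
normalize_train <- function(x, state, combo = 15L) {
  stopifnot(inherits(state, "norm_state"))
  if (any(as.integer(combo) < 1L)) stop("contrast combination must be non-empty")
  r <- .norm_forward(x, state, combo, phase = "train")
  list(y = r$y, state = r$state)
}

#' Test-time instance normalization (TTIN)
#'
#' Normalizes a single test input with its own per-channel spatial
#' statistics while reusing the affine parameters learned in training
#' (combination-indexed in CondIN mode). The BN moving averages are never
#' consulted or modified. TTIN output is invariant to any per-channel affine
#' perturbation of its input.
#'
#' @param x feature map array `H x W x C x 1` (batch size must be one).
#' @param state a [norm_state()].
#' @param combo combination index in 1..15.
#' @return the normalized feature map.
#' @export
normalize_ttin <- function(x, state, combo = 15L) {
  stopifnot(inherits(state, "norm_state"))
  d <- dim(x)
  if (length(d) != 4L || d[4L] != 1L)
    stop("TTIN operates on a single instance (batch size one)")
  .norm_forward(x, state, combo, phase = "ttin")$y
}
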