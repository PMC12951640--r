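#' @useDynLib mstta, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd median cor predict approx dnorm
NULL

# Canonical axis convention: arrays are (X, Y, Z) with X the sagittal normal,
# Y the coronal normal and Z the axial normal. "Axial" slices are orthogonal
# to Z, "coronal" to Y, "sagittal" to X.

.planes <- c("axial", "sagittal", "coronal")

.dihedrals <- c("rot0", "rot90", "rot180", "rot270",
                "flipH.rot0", "flipH.rot90", "flipH.rot180", "flipH.rot270")

# rot90/rot270 are mutual inverses; every flipH.rotK is a reflection and
# therefore its own inverse.
.dihedral_inverse <- c(1L, 4L, 3L, 2L, 5L, 6L, 7L, 8L)

# Axis permutation that brings the in-plane axes of `plane` to dims 1-2 and
# the plane normal to dim 3.
.plane_perm <- function(plane) {
  switch(plane,
    axial    = c(1L, 2L, 3L),
    coronal  = c(1L, 3L, 2L),
    sagittal = c(2L, 3L, 1L),
    stop("unknown plane: ", plane)
  )
}

# Reverse array indices along dimension `which`, any rank.
.rev_dim <- function(a, which) {
  d <- dim(a)
  idx <- rep(list(quote(expr = )), length(d))
  idx[[which]] <- d[which]:1
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

# Permute dims 1-2 of an array of rank >= 2, keeping trailing dims in place.
.swap12 <- function(a) {
  p <- seq_along(dim(a))
  p[1:2] <- c(2L, 1L)
  aperm(a, p)
}

# In-plane dihedral action on dims 1-2 of an array (rank >= 2). Rotation is
# counter-clockwise in array index space.
.apply_dihedral <- function(a, op) {
  op <- match.arg(op, .dihedrals)
  base <- sub("^flipH\\.", "", op)
  out <- switch(base,
    rot0   = a,
    rot90  = .rev_dim(.swap12(a), 1L),
    rot180 = .rev_dim(.rev_dim(a, 1L), 2L),
    rot270 = .rev_dim(.swap12(a), 2L)
  )
  if (grepl("^flipH\\.", op)) out <- .rev_dim(out, 2L)
  out
}

.invert_dihedral <- function(a, op) {
  i <- match(match.arg(op, .dihedrals), .dihedrals)
  .apply_dihedral(a, .dihedrals[.dihedral_inverse[i]])
}

#' Create a test-time augmentation descriptor
#'
#' A descriptor names one of the 24 multi-orientation transforms: a cardinal
#' plane (axial, sagittal, coronal) combined with one of the 8 in-plane
#' dihedral operations (rotations by 0/90/180/270 degrees, each optionally
#' composed with a horizontal flip).
#'
#' @param plane one of `"axial"`, `"sagittal"`, `"coronal"`.
#' @param dihedral one of `"rot0"`, `"rot90"`, `"rot180"`, `"rot270"`,
#'   `"flipH.rot0"`, `"flipH.rot90"`, `"flipH.rot180"`, `"flipH.rot270"`.
#' @return an object of class `tta_transform`.
#' @export
tta_transform <- function(plane = "axial", dihedral = "rot0") {
  plane <- match.arg(plane, .planes)
  dihedral <- match.arg(dihedral, .dihedrals)
  structure(list(plane = plane, dihedral = dihedral), class = "tta_transform")
}

#' @export
print.tta_transform <- function(x, ...) {
  cat(sprintf("<tta_transform: %s / %s>\n", x$plane, x$dihedral))
  invisible(x)
}

#' Enumerate the 24 multi-orientation test-time augmentations
#'
#' Returns the full set of 3 planes x 8 dihedral operations in a fixed,
#' documented order: planes vary slowest (axial, sagittal, coronal), dihedral
#' operations fastest in the order rot0, rot90, rot180, rot270, then the same
#' four composed with a horizontal flip. The first element is the identity.
#'
#' @return a list of 24 `tta_transform` descriptors.
#' @export
list_augmentations <- function() {
  out <- vector("list", 24L)
  k <- 0L
  for (p in .planes)
    for (d in .dihedrals) {
      k <- k + 1L
      out[[k]] <- tta_transform(p, d)
    }
  out
}

#' Apply a multi-orientation transform to a 3D array
#'
#' Reorients a volume so that the descriptor's plane becomes the slicing
#' plane (in-plane axes first, plane normal third) and applies the in-plane
#' dihedral operation to every slice. Pure index permutation/reflection: no
#' interpolation, per-channel voxel multisets are conserved.
#'
#' @param a a 3D numeric/integer/logical array.
#' @param d a [tta_transform()] descriptor.
#' @return the transformed 3D array.
#' @export
apply_transform <- function(a, d) {
  stopifnot(inherits(d, "tta_transform"), length(dim(a)) == 3L)
  .apply_dihedral(aperm(a, .plane_perm(d$plane)), d$dihedral)
}

#' Invert a multi-orientation transform
#'
#' Maps an array from the augmented space of descriptor `d` back to the
#' original grid: the inverse dihedral operation followed by the inverse
#' plane permutation. `invert_transform(apply_transform(a, d), d)` is the
#' voxel-wise identity for every descriptor.
#'
#' @param a a 3D array in the augmented space of `d`.
#' @param d a [tta_transform()] descriptor.
#' @return the array on the original grid.
#' @export
invert_transform <- function(a, d) {
  stopifnot(inherits(d, "tta_transform"), length(dim(a)) == 3L)
  b <- .invert_dihedral(a, d$dihedral)
  aperm(b, order(.plane_perm(d$plane)))
}

#' Construct a multicontrast volume
#'
#' The unit consumed by every pipeline stage: a 4-channel 3D intensity stack
#' in contrast order T1w, T2w, PDw, FLAIR, with per-contrast presence flags.
#' Absent contrasts are stored as all-zero channels with `present = FALSE`.
#'
#' @param data a 4D array `X x Y x Z x 4` (contrast last), or a named list of
#'   four 3D arrays.
#' @param present logical(4) presence flags; by default a contrast is present
#'   iff its channel is not identically zero.
#' @param spacing voxel spacing in mm (length 3).
#' @param affine optional 4x4 grid-to-world matrix.
#' @return an object of class `mc_volume`.
#' @export
mc_volume <- function(data, present = NULL, spacing = c(1, 1, 1),
                      affine = NULL) {
  if (is.list(data)) {
    stopifnot(length(data) == 4L)
    data <- array(unlist(data, use.names = FALSE),
                  dim = c(dim(data[[1L]]), 4L))
  }
  stopifnot(length(dim(data)) == 4L, dim(data)[4L] == 4L)
  if (is.null(present))
    present <- apply(data, 4L, function(ch) any(ch != 0))
  stopifnot(length(present) == 4L)
  if (!any(present)) stop("at least one contrast must be present")
  for (ci in which(!present)) data[, , , ci] <- 0
  structure(
    list(data = data, present = as.logical(present),
         spacing = as.numeric(spacing), affine = affine),
    class = "mc_volume"
  )
}

#' @export
print.mc_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mc_volume %dx%dx%d, contrasts: %s>\n", d[1L], d[2L], d[3L],
              paste(contrast_names()[x$present], collapse = "+")))
  invisible(x)
}

#' Contrast channel names, in storage order
#' @return `c("T1w", "T2w", "PDw", "FLAIR")`
#' @export
contrast_names <- function() c("T1w", "T2w", "PDw", "FLAIR")

#' Apply a transform to every channel of a multicontrast volume
#'
#' @param vol an [mc_volume()].
#' @param d a [tta_transform()].
#' @return the transformed `mc_volume` (presence flags unchanged).
#' @export
transform_volume <- function(vol, d) {
  stopifnot(inherits(vol, "mc_volume"))
  chans <- lapply(seq_len(4L), function(ci)
    apply_transform(vol$data[, , , ci], d))
  out <- array(unlist(chans, use.names = FALSE),
               dim = c(dim(chans[[1L]]), 4L))
  vol$data <- out
  vol
}

#' Extract a 2.5D slab from a multicontrast volume
#'
#' Gathers the three adjacent slices `k-1, k, k+1` orthogonal to the chosen
#' plane and concatenates them along the channel dimension, zero-filling
#' slices that fall outside the volume. Channel order is slice-major,
#' contrast-minor: `(k-1: T1w,T2w,PDw,FLAIR), (k: ...), (k+1: ...)`, giving
#' 12 channels for the four-contrast configuration.
#'
#' @param vol an [mc_volume()].
#' @param plane slicing plane.
#' @param k slice index (1-based) along the plane normal.
#' @return an object of class `slab25d` with fields `channels` (H x W x 12),
#'   `plane` and `central_index`.
#' @export
extract_25d <- function(vol, plane = "axial", k) {
  stopifnot(inherits(vol, "mc_volume"))
  plane <- match.arg(plane, .planes)
  v <- aperm(vol$data, c(.plane_perm(plane), 4L))
  nk <- dim(v)[3L]
  if (k < 1L || k > nk) stop("slice index out of range: ", k)
  h <- dim(v)[1L]; w <- dim(v)[2L]
  chans <- array(0, dim = c(h, w, 12L))
  ci <- 0L
  for (s in (k - 1L):(k + 1L)) {
    for (cc in 1:4) {
      ci <- ci + 1L
      if (s >= 1L && s <= nk) chans[, , ci] <- v[, , s, cc]
    }
  }
  structure(list(channels = chans, plane = plane, central_index = k),
            class = "slab25d")
}
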