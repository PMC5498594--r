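#' 3D binary morphology primitives
#'
#' Voxel-count-parameterised morphology on logical 3D arrays, the building
#' blocks of the interruption-detection algorithm. One `steps = 1` dilation
#' with `conn = 6` adds the face-connected (L1 / diamond) neighbourhood; `k`
#' iterated steps give the L1 ball of radius `k`, so a gap of width `2k`
#' voxels is closed by dilating both of its sides `k` times. `conn = 26`
#' gives the Chebyshev ball, and `conn = 4` / `8` act within each slice along
#' the first (z) axis only. Erosion uses the zero-padded convention (the grid
#' border erodes).
#'
#' @param x logical 3D array.
#' @param steps non-negative integer number of elementary steps.
#' @param conn connectivity: 6, 26 (3D) or 4, 8 (in-plane).
#' @return Logical array of the same dimension.
#' @export
dilate3d <- function(x, steps = 1L, conn = 6L) {
  x <- as_mask(x)
  .cg_dilate(x, dim(x), as.integer(steps), as.integer(conn))
}

#' @rdname dilate3d
#' @param pad how erosion treats the region beyond the grid:
#'   `"background"` (default; the border erodes) or `"foreground"` (the
#'   object continues past the grid, e.g. inside a morphological closing
#'   after the paired dilation has been clipped at the border).
#' @export
erode3d <- function(x, steps = 1L, conn = 6L,
                    pad = c("background", "foreground")) {
  x <- as_mask(x)
  pad <- match.arg(pad)
  .cg_erode(x, dim(x), as.integer(steps), as.integer(conn),
            pad == "foreground")
}

#' Connected-component labelling of a 3D mask
#'
#' @inheritParams dilate3d
#' @param conn 6 or 26.
#' @return Integer array; 0 = background, components numbered 1..K in
#'   first-voxel scan order.
#' @export
label_components <- function(x, conn = 26L) {
  x <- as_mask(x)
  .cg_label(x, dim(x), as.integer(conn))
}

#' Geodesic (conditional) reconstruction of a seed within a mask
#'
#' Iterated dilation of `seed` constrained to `mask` until stable; recovers
#' the full extent of every mask component that contains at least one seed
#' voxel.
#'
#' @param seed,mask logical 3D arrays of equal dimension.
#' @inheritParams label_components
#' @return Logical array.
#' @export
geodesic_reconstruct <- function(seed, mask, conn = 26L) {
  seed <- as_mask(seed); mask <- as_mask(mask)
  stopifnot(identical(dim(seed), dim(mask)))
  .cg_reconstruct(seed, mask, dim(seed), as.integer(conn))
}

# Morphological closing with infinite-background border semantics: the grid
# is padded with background by the closing radius before dilate/erode, so
# neither the clipped dilation nor border erosion distorts the result.
closing3d <- function(x, steps, conn = 26L) {
  x <- as_mask(x)
  d <- dim(x)
  p <- as.integer(steps) + 1L
  padded <- array(FALSE, d + 2L * p)
  padded[p + seq_len(d[1]), p + seq_len(d[2]), p + seq_len(d[3])] <- x
  closed <- erode3d(dilate3d(padded, steps, conn), steps, conn)
  closed[p + seq_len(d[1]), p + seq_len(d[2]), p + seq_len(d[3]), drop = FALSE]
}

# Fill enclosed background voids in 3D. The background is flood-filled
# (6-connected) from the four lateral faces only: the z faces are treated as
# continuations of the scanned stack, so a marrow cavity that is open at the
# stack ends still counts as enclosed and is filled.
fill_enclosed_voids <- function(x) {
  x <- as_mask(x)
  bg <- !x
  seed <- array(FALSE, dim(x))
  seed[, 1, ] <- TRUE; seed[, dim(x)[2], ] <- TRUE
  seed[, , 1] <- TRUE; seed[, , dim(x)[3]] <- TRUE
  reached <- geodesic_reconstruct(seed & bg, bg, conn = 6L)
  x | !reached
}

# Truncated separable Gaussian; `radius` is the hard kernel support in voxels.
gaussian_filter3d <- function(x, sigma, radius = max(1L, ceiling(3 * sigma))) {
  stopifnot(length(dim(x)) == 3L)
  .cg_gaussian3d(as.double(x), dim(x), sigma, as.integer(radius))
}

as_mask <- function(x) {
  if (is.null(dim(x)) || length(dim(x)) != 3L)
    stop("expected a logical 3D array")
  if (!is.logical(x)) {
    d <- dim(x)
    x <- x != 0
    dim(x) <- d
  }
  x
}
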