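#' 3D grayscale volume with isotropic voxel geometry
#'
#' The package's central container: a 3D numeric array in the fixed internal
#' axis order (z, y, x) = (slice, row, column), together with the isotropic
#' voxel edge length in millimetres and a physical origin. All readers convert
#' into this convention on load; coordinates are voxel-centre based and
#' 0-indexed, so voxel (i, j, k) sits at `origin_mm + c(i, j, k) * voxel_size_mm`.
#'
#' @param data 3D numeric array, axis order (z, y, x).
#' @param voxel_size_mm positive scalar; isotropic voxel edge length in mm.
#' @param origin_mm numeric 3-vector, physical position (mm) of voxel (0,0,0).
#' @return An object of class `cg_volume`.
#' @examples
#' v <- gray_volume(array(0, c(4, 4, 4)), voxel_size_mm = 0.082)
#' dim(v$data)
#' @export
gray_volume <- function(data, voxel_size_mm, origin_mm = c(0, 0, 0)) {
  data <- check_grid3d(data, "data")
  storage.mode(data) <- "double"
  check_voxel_size(voxel_size_mm)
  stopifnot(is.numeric(origin_mm), length(origin_mm) == 3)
  structure(list(data = data, voxel_size_mm = voxel_size_mm,
                 origin_mm = as.numeric(origin_mm)),
            class = "cg_volume")
}

#' 3D integer label map
#'
#' Label 0 is background; foreground labels must be contiguous `1..K`
#' (enforced by [write_labels()] and checked here).
#'
#' @param data 3D non-negative integer array, axis order (z, y, x).
#' @inheritParams gray_volume
#' @param check if `TRUE`, verify label contiguity.
#' @return An object of class `cg_labels`.
#' @export
label_volume <- function(data, voxel_size_mm, origin_mm = c(0, 0, 0),
                         check = TRUE) {
  data <- check_grid3d(data, "data")
  if (any(data < 0) || any(data != round(data)))
    stop("label data must be non-negative integers")
  storage.mode(data) <- "integer"
  check_voxel_size(voxel_size_mm)
  if (check) {
    u <- sort(unique(as.integer(data[data > 0L])))
    if (length(u) && !identical(u, seq_len(max(u))))
      warning("labels are not contiguous 1..K: ",
              paste(u, collapse = ","), call. = FALSE)
  }
  structure(list(data = data, voxel_size_mm = voxel_size_mm,
                 origin_mm = as.numeric(origin_mm)),
            class = "cg_labels")
}

check_grid3d <- function(x, what) {
  if (is.null(dim(x)) || length(dim(x)) != 3L)
    stop(what, " must be a 3D array")
  if (any(dim(x) < 1L)) stop(what, " must have >= 1 voxel per axis")
  x
}

check_voxel_size <- function(vs) {
  if (!is.numeric(vs) || length(vs) != 1L || !is.finite(vs) || vs <= 0)
    stop("voxel_size_mm must be a positive scalar", call. = FALSE)
  invisible(vs)
}

# Assert that two grids share geometry (dims and voxel size).
check_same_geometry <- function(a, b, what = "volumes") {
  if (!identical(dim(grid_of(a)), dim(grid_of(b))) ||
      abs(a$voxel_size_mm - b$voxel_size_mm) > 1e-9 * a$voxel_size_mm)
    stop("geometry mismatch between ", what, call. = FALSE)
  invisible(TRUE)
}

# Pull the primary grid out of any of the package's containers.
grid_of <- function(x) {
  if (!is.null(x$data)) return(x$data)
  if (!is.null(x$inside)) return(x$inside)
  if (!is.null(x$bone)) return(x$bone)
  if (!is.null(x$region)) return(x$region)
  stop("object carries no grid")
}

#' @export
print.cg_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<cg_volume> %d x %d x %d voxels (z,y,x), %.4g mm isotropic\n",
              d[1], d[2], d[3], x$voxel_size_mm))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.cg_labels <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<cg_labels> %d x %d x %d voxels, %.4g mm, %d label(s)\n",
              d[1], d[2], d[3], x$voxel_size_mm, max(x$data)))
  invisible(x)
}
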