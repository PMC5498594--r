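#' Build the constant-thickness cortical mask
#'
#' Peels a rind of fixed thickness off the periosteal mask: the cortical
#' region is the mask minus its erosion by `thickness_voxels` face-connected
#' (6-neighbourhood) steps, where
#' `thickness_voxels = round(thickness_mm / voxel_size_mm)`. The canonical
#' settings are 4 voxels (= 0.328 mm) on the 0.082 mm grid and 18 voxels
#' (= 0.324 mm) on the 0.018 mm grid, matching the average cortical thickness
#' of metacarpophalangeal joints. The remaining core is the trabecular
#' interior; the outermost cortical shell adjacent to the outside is the
#' periosteal layer and the innermost shell adjacent to the interior is the
#' endosteal layer.
#'
#' A constant thickness is deliberate (robust, but known to misestimate
#' interruption size where the true cortex is much thinner or thicker than
#' the mask).
#'
#' @param mask a `cg_contour` periosteal mask.
#' @param thickness_mm desired cortical thickness in mm
#'   (must be `>= voxel_size_mm`).
#' @param element erosion structuring element: `"cross"` (face-connected,
#'   default — "4 voxels" means 4 single-voxel erosions) or `"ball"`
#'   (26-neighbourhood Chebyshev alternative).
#' @return A `cg_cortical_mask` with fields `region` (integer array: 0 =
#'   outside, 1 = cortical, 2 = interior), `thickness_voxels`,
#'   `periosteal_layer`, `endosteal_layer`, `voxel_size_mm`.
#' @export
build_cortical_mask <- function(mask, thickness_mm,
                                element = c("cross", "ball")) {
  stopifnot(inherits(mask, "cg_contour"))
  element <- match.arg(element)
  vs <- mask$voxel_size_mm
  if (thickness_mm < vs)
    stop("thickness_mm must be at least one voxel (", vs, " mm)")
  tv <- as.integer(round(thickness_mm / vs))
  conn <- if (element == "cross") 6L else 26L
  # The scanned stack is a crop: the bone continues beyond the first and
  # last slice, so erosion must not eat the z stack ends. Pad by replicating
  # the end slices, erode, crop.
  nz <- dim(mask$inside)[1]
  padded <- mask$inside[c(rep(1L, tv), seq_len(nz), rep(nz, tv)), , ,
                        drop = FALSE]
  interior <- erode3d(padded, tv, conn = conn)[tv + seq_len(nz), , ,
                                               drop = FALSE]
  if (!any(interior))
    warning("degenerate mask: erosion emptied the interior (object thinner ",
            "than twice the cortical thickness)", call. = FALSE)
  cortical <- mask$inside & !interior
  if (!any(cortical)) stop("empty cortical region")
  outside <- !mask$inside
  region <- array(0L, dim(mask$inside))
  region[cortical] <- 1L
  region[interior] <- 2L
  peri <- cortical & dilate3d(outside, 1L, conn = 6L)
  endo <- cortical & dilate3d(interior, 1L, conn = 6L)
  structure(list(region = region, thickness_voxels = tv,
                 periosteal_layer = peri, endosteal_layer = endo,
                 voxel_size_mm = vs, origin_mm = mask$origin_mm),
            class = "cg_cortical_mask")
}

#' Assemble a cortical mask from an explicit region grid
#'
#' For externally supplied or hand-constructed geometry: takes the ternary
#' region grid (0 = outside, 1 = cortical, 2 = interior) and derives the
#' periosteal and endosteal boundary layers.
#'
#' @param region integer 3D array with values in \{0, 1, 2\}.
#' @inheritParams gray_volume
#' @param thickness_voxels nominal mask thickness, if known.
#' @return A `cg_cortical_mask`.
#' @export
cortical_mask_from_regions <- function(region, voxel_size_mm,
                                       origin_mm = c(0, 0, 0),
                                       thickness_voxels = NA_integer_) {
  region <- check_grid3d(region, "region")
  if (!all(region %in% 0:2)) stop("region values must be 0, 1 or 2")
  storage.mode(region) <- "integer"
  check_voxel_size(voxel_size_mm)
  if (!any(region == 1L)) stop("empty cortical region")
  cortical <- region == 1L
  peri <- cortical & dilate3d(region == 0L, 1L, conn = 6L)
  endo <- cortical & dilate3d(region == 2L, 1L, conn = 6L)
  structure(list(region = region, thickness_voxels = thickness_voxels,
                 periosteal_layer = peri, endosteal_layer = endo,
                 voxel_size_mm = voxel_size_mm, origin_mm = origin_mm),
            class = "cg_cortical_mask")
}

#' @export
print.cg_cortical_mask <- function(x, ...) {
  cat(sprintf(
    "<cg_cortical_mask> thickness %d voxel(s) (%.3f mm); %s cortical, %s interior voxels\n",
    x$thickness_voxels, x$thickness_voxels * x$voxel_size_mm,
    format(sum(x$region == 1L), big.mark = ","),
    format(sum(x$region == 2L), big.mark = ",")))
  invisible(x)
}
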