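#' Specification of a synthetic cortical-interruption phantom
#'
#' Describes an analytic object — a mineralised shell (cortex) pierced by
#' cylindrical holes of known diameter — rasterised at two voxel sizes to
#' emulate a paired low-resolution (in-vivo class, 0.082 mm) and
#' high-resolution (gold-standard class, 0.018 mm) acquisition of the same
#' bone. Partial volume is produced by supersampled box averaging and noise
#' by seeded additive Gaussian intensities. Intensities are two-level before
#' degradation: background 0, bone 1000, so the maximum possible voxel value
#' is 1000 and permille thresholds are literal.
#'
#' @param shape `"tube"` (annular cylinder along z, the default — a long
#'   bone diaphysis in miniature), `"shell"` (hollow sphere) or `"slab"`
#'   (flat cortical plate normal to y).
#' @param outer_radius_mm outer radius of tube/shell (default 1.0).
#' @param cortical_thickness_mm shell wall thickness (default 0.33, the
#'   average cortical thickness the constant-thickness mask targets).
#' @param height_mm tube length / slab extent along z (default 2.0).
#' @param holes data frame of hole definitions. Tube: `angle_deg`, `z_mm`,
#'   `diameter_mm`, `through`; shell: `azimuth_deg`, `polar_deg`,
#'   `diameter_mm`, `through`; slab: `z_mm`, `x_mm`, `diameter_mm`,
#'   `through`. Blind (`through = FALSE`) holes penetrate half the wall from
#'   the periosteal side.
#' @param voxel_sizes_mm named vector `c(lowres = , highres = )`
#'   (default 0.082 / 0.018).
#' @param supersample named integer vector of supersampling factors per
#'   output (default 3 / 2); 1 disables partial-volume averaging.
#' @param noise_sd additive Gaussian noise SD as a fraction of the bone
#'   intensity (default 0).
#' @param thin_patch optional locally thinned wall region: a list with
#'   `angle_deg`, `z_mm`, `extent_mm` (patch size along the surface) and
#'   `thickness_mm` (reduced wall thickness, thinned from the endosteal
#'   side). Tube shape only.
#' @param pair_rotation_deg,pair_translation_mm rigid offset of the
#'   high-resolution acquisition relative to the low-resolution one
#'   (default none); the applied transform is stored in the ground truth.
#' @param margin_mm empty border around the object (default 0.3).
#' @param seed integer seed for the noise stream.
#' @return A `cg_phantom_spec`.
#' @export
phantom_spec <- function(shape = c("tube", "shell", "slab"),
                         outer_radius_mm = 1.0,
                         cortical_thickness_mm = 0.33,
                         height_mm = 2.0,
                         holes = NULL,
                         thin_patch = NULL,
                         voxel_sizes_mm = c(lowres = 0.082, highres = 0.018),
                         supersample = c(lowres = 3L, highres = 2L),
                         noise_sd = 0,
                         pair_rotation_deg = c(0, 0, 0),
                         pair_translation_mm = c(0, 0, 0),
                         margin_mm = 0.3,
                         seed = 1L) {
  shape <- match.arg(shape)
  if (is.null(holes))
    holes <- data.frame(angle_deg = numeric(), z_mm = numeric(),
                        diameter_mm = numeric(), through = logical())
  stopifnot(all(c("diameter_mm", "through") %in% names(holes)))
  if (any(holes$diameter_mm <= 0))
    stop("hole diameters must be positive")
  if (any(holes$diameter_mm >= 2 * outer_radius_mm))
    stop("spec error: hole diameter exceeds the object extent")
  if (any(supersample < 1)) stop("supersample factors must be >= 1")
  if (!is.null(thin_patch))
    stopifnot(shape == "tube",
              all(c("angle_deg", "z_mm", "extent_mm", "thickness_mm") %in%
                    names(thin_patch)))
  spec <- structure(list(
    shape = shape, outer_radius_mm = outer_radius_mm,
    cortical_thickness_mm = cortical_thickness_mm, height_mm = height_mm,
    holes = holes, thin_patch = thin_patch, voxel_sizes_mm = voxel_sizes_mm,
    supersample = as.integer(supersample), noise_sd = noise_sd,
    pair_rotation_deg = pair_rotation_deg,
    pair_translation_mm = pair_translation_mm,
    margin_mm = margin_mm, seed = as.integer(seed)),
    class = "cg_phantom_spec")
  names(spec$supersample) <- names(supersample)
  check_hole_overlap(spec)
  spec
}

# Reject holes whose surface footprints intersect.
check_hole_overlap <- function(spec) {
  h <- spec$holes
  if (nrow(h) < 2) return(invisible(TRUE))
  p <- hole_axes(spec)
  for (i in seq_len(nrow(h) - 1))
    for (j in seq(i + 1, nrow(h))) {
      gap <- sqrt(sum((p$anchor[i, ] - p$anchor[j, ])^2))
      if (gap < (h$diameter_mm[i] + h$diameter_mm[j]) / 2)
        stop("spec error: holes ", i, " and ", j, " overlap")
    }
  invisible(TRUE)
}

# Axis anchor point (mid-wall) and unit direction of each hole, canonical
# (z, y, x) mm coordinates.
hole_axes <- function(spec) {
  h <- spec$holes
  n <- nrow(h)
  anchor <- matrix(0, n, 3)
  dir <- matrix(0, n, 3)
  rmid <- spec$outer_radius_mm - spec$cortical_thickness_mm / 2
  for (i in seq_len(n)) {
    if (spec$shape == "tube") {
      a <- h$angle_deg[i] * pi / 180
      u <- c(0, cos(a), sin(a))
      anchor[i, ] <- c(h$z_mm[i], rmid * cos(a), rmid * sin(a))
      dir[i, ] <- u
    } else if (spec$shape == "shell") {
      az <- h$azimuth_deg[i] * pi / 180
      po <- h$polar_deg[i] * pi / 180
      u <- c(cos(po), sin(po) * cos(az), sin(po) * sin(az))
      ctr <- c(spec$height_mm / 2, 0, 0)
      anchor[i, ] <- ctr + rmid * u
      dir[i, ] <- u
    } else {                                     # slab: holes along y
      anchor[i, ] <- c(h$z_mm[i], spec$cortical_thickness_mm / 2, h$x_mm[i])
      dir[i, ] <- c(0, 1, 0)
    }
  }
  list(anchor = anchor, dir = dir)
}

#' Generate a paired synthetic phantom
#'
#' Rasterises the analytic geometry at a supersampled resolution for each
#' output voxel size, box-averages down (partial volume), and adds seeded
#' Gaussian noise. The two outputs image the same object; the
#' high-resolution one may additionally be rigidly offset, and the applied
#' transform (mapping low-resolution physical coordinates into the
#' high-resolution space, ready for [resample_labels()]) is stored with the
#' ground truth.
#'
#' @param spec a [phantom_spec()].
#' @return A list: `lowres`, `highres` ([gray_volume()]s), and `truth` with
#'   `holes` (id, true_diameter_mm, true_area_mm2, anchor), `labels_lowres`
#'   / `labels_highres` (ground-truth void-channel [label_volume()]s at each
#'   resolution) and `transform` (the applied [rigid_transform()]).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "cg_phantom_spec"))
  set.seed(spec$seed)
  fov <- phantom_fov(spec)
  centre <- (fov$lo + fov$hi) / 2
  tf <- rigid_transform(rotation_from_angles(spec$pair_rotation_deg),
                        spec$pair_translation_mm, centre)
  inv <- invert_transform(tf)
  out <- list()
  labs <- list()
  for (role in c("lowres", "highres")) {
    vs <- spec$voxel_sizes_mm[[role]]
    ss <- spec$supersample[[role]]
    to_canonical <- if (role == "highres") inv else NULL
    vol <- rasterize_phantom(spec, fov, vs, ss, to_canonical)
    if (spec$noise_sd > 0)
      vol$data <- vol$data + stats::rnorm(length(vol$data),
                                          sd = spec$noise_sd * 1000)
    out[[role]] <- vol
    labs[[role]] <- truth_labels(spec, fov, vs, to_canonical)
  }
  h <- spec$holes
  ax <- hole_axes(spec)
  truth_holes <- if (nrow(h)) {
    data.frame(id = seq_len(nrow(h)), true_diameter_mm = h$diameter_mm,
               true_area_mm2 = pi * (h$diameter_mm / 2)^2,
               anchor_z = ax$anchor[, 1], anchor_y = ax$anchor[, 2],
               anchor_x = ax$anchor[, 3], through = h$through)
  } else {
    data.frame(id = integer(), true_diameter_mm = numeric(),
               true_area_mm2 = numeric())
  }
  list(lowres = out$lowres, highres = out$highres,
       truth = list(holes = truth_holes,
                    labels_lowres = labs$lowres,
                    labels_highres = labs$highres,
                    transform = tf))
}

# Physical field of view (canonical coordinates). Tubes and slabs behave
# like a cropped scan stack: they span the full z extent of the FOV (no end
# caps inside the volume, as in a real acquisition where the bone continues
# beyond the scanned region); lateral margins only.
phantom_fov <- function(spec) {
  m <- spec$margin_mm
  R <- spec$outer_radius_mm
  if (spec$shape == "tube") {
    lo <- c(0, -R - m, -R - m); hi <- c(spec$height_mm, R + m, R + m)
  } else if (spec$shape == "shell") {
    c0 <- spec$height_mm / 2
    lo <- c(c0 - R - m, -R - m, -R - m); hi <- c(c0 + R + m, R + m, R + m)
  } else {
    w <- spec$outer_radius_mm                    # slab half-width in x
    lo <- c(0, -m, -w)
    hi <- c(spec$height_mm, spec$cortical_thickness_mm + m, w)
  }
  list(lo = lo, hi = hi)
}

# Bone indicator at canonical points (matrices of z, y, x in mm).
phantom_bone_at <- function(spec, z, y, x) {
  R <- spec$outer_radius_mm
  t <- spec$cortical_thickness_mm
  if (spec$shape == "tube") {
    r <- sqrt(y^2 + x^2)
    bone <- r <= R & r >= R - t
    if (!is.null(spec$thin_patch)) {
      tp <- spec$thin_patch
      ang0 <- tp$angle_deg * pi / 180
      dang <- atan2(x, y) - ang0
      dang <- atan2(sin(dang), cos(dang))          # wrap to (-pi, pi]
      rmid <- R - t / 2
      in_patch <- abs(dang) * rmid <= tp$extent_mm / 2 &
        abs(z - tp$z_mm) <= tp$extent_mm / 2
      bone <- bone & !(in_patch & r < R - tp$thickness_mm)
    }
  } else if (spec$shape == "shell") {
    c0 <- spec$height_mm / 2
    r <- sqrt((z - c0)^2 + y^2 + x^2)
    bone <- r <= R & r >= R - t
  } else {
    bone <- y >= 0 & y <= t
  }
  if (nrow(spec$holes)) {
    ax <- hole_axes(spec)
    for (i in seq_len(nrow(spec$holes))) {
      w1 <- z - ax$anchor[i, 1]; w2 <- y - ax$anchor[i, 2]
      w3 <- x - ax$anchor[i, 3]
      s <- w1 * ax$dir[i, 1] + w2 * ax$dir[i, 2] + w3 * ax$dir[i, 3]
      d2 <- w1^2 + w2^2 + w3^2 - s^2
      in_cyl <- d2 <= (spec$holes$diameter_mm[i] / 2)^2
      # one-sided: the hole pierces only the wall it is anchored in (for a
      # tube the infinite cylinder would otherwise also cut the far wall);
      # blind pits stop halfway through
      in_cyl <- in_cyl & (if (spec$holes$through[i]) s >= -t else s >= 0)
      bone <- bone & !in_cyl
    }
  }
  bone
}

# Hole-channel label (0 = none) at canonical points: inside a hole cylinder
# and within the cortical wall band.
phantom_hole_label_at <- function(spec, z, y, x) {
  lab <- array(0L, dim(z))
  if (!nrow(spec$holes)) return(lab)
  R <- spec$outer_radius_mm
  t <- spec$cortical_thickness_mm
  wall <- if (spec$shape == "tube") {
    r <- sqrt(y^2 + x^2)
    r <= R & r >= R - t
  } else if (spec$shape == "shell") {
    c0 <- spec$height_mm / 2
    r <- sqrt((z - c0)^2 + y^2 + x^2)
    r <= R & r >= R - t
  } else {
    y >= 0 & y <= t
  }
  ax <- hole_axes(spec)
  for (i in seq_len(nrow(spec$holes))) {
    w1 <- z - ax$anchor[i, 1]; w2 <- y - ax$anchor[i, 2]
    w3 <- x - ax$anchor[i, 3]
    s <- w1 * ax$dir[i, 1] + w2 * ax$dir[i, 2] + w3 * ax$dir[i, 3]
    d2 <- w1^2 + w2^2 + w3^2 - s^2
    in_cyl <- d2 <= (spec$holes$diameter_mm[i] / 2)^2
    in_cyl <- in_cyl & (if (spec$holes$through[i]) s >= -t else s >= 0)
    lab[wall & in_cyl & lab == 0L] <- i
  }
  lab
}

# Rasterise the bone indicator over the FOV at voxel size vs with
# supersampling ss; optional rigid map from output space to canonical space
# (for the offset high-resolution acquisition). Slice-chunked to bound
# memory.
rasterize_phantom <- function(spec, fov, vs, ss, to_canonical = NULL) {
  n <- pmax(1L, as.integer(round((fov$hi - fov$lo) / vs)))
  origin <- fov$lo + vs / 2
  vsf <- vs / ss
  nf <- n * ss
  originf <- fov$lo + vsf / 2
  yf <- originf[2] + (seq_len(nf[2]) - 1) * vsf
  xf <- originf[3] + (seq_len(nf[3]) - 1) * vsf
  ym <- matrix(rep(yf, times = nf[3]), nf[2], nf[3])
  xm <- matrix(rep(xf, each = nf[2]), nf[2], nf[3])
  out <- array(0, n)
  acc <- matrix(0, nf[2], nf[3])
  for (iz in seq_len(n[1])) {
    acc[] <- 0
    for (sub in seq_len(ss)) {
      zf <- originf[1] + ((iz - 1) * ss + sub - 1) * vsf
      zm <- matrix(zf, nf[2], nf[3])
      if (is.null(to_canonical)) {
        bone <- phantom_bone_at(spec, zm, ym, xm)
      } else {
        p <- transform_points(to_canonical, zm, ym, xm)
        bone <- phantom_bone_at(spec, p$z, p$y, p$x)
      }
      acc <- acc + bone
    }
    # average over the z-sub-slices, then block-average in-plane
    sl <- acc / ss
    dim(sl) <- c(ss, n[2], ss, n[3])
    sl <- aperm(sl, c(1, 3, 2, 4))
    dim(sl) <- c(ss * ss, n[2] * n[3])
    out[iz, , ] <- matrix(colMeans(sl), n[2], n[3]) * 1000
  }
  gray_volume(out, vs, origin_mm = origin)
}

# Ground-truth labels at voxel centres (no partial volume).
truth_labels <- function(spec, fov, vs, to_canonical = NULL) {
  n <- pmax(1L, as.integer(round((fov$hi - fov$lo) / vs)))
  origin <- fov$lo + vs / 2
  y <- origin[2] + (seq_len(n[2]) - 1) * vs
  x <- origin[3] + (seq_len(n[3]) - 1) * vs
  ym <- matrix(rep(y, times = n[3]), n[2], n[3])
  xm <- matrix(rep(x, each = n[2]), n[2], n[3])
  lab <- array(0L, n)
  for (iz in seq_len(n[1])) {
    zm <- matrix(origin[1] + (iz - 1) * vs, n[2], n[3])
    if (is.null(to_canonical)) {
      lab[iz, , ] <- phantom_hole_label_at(spec, zm, ym, xm)
    } else {
      p <- transform_points(to_canonical, zm, ym, xm)
      lab[iz, , ] <- phantom_hole_label_at(spec, p$z, p$y, p$x)
    }
  }
  label_volume(lab, vs, origin, check = FALSE)
}

# Apply a rigid transform to arrays of (z, y, x) mm coordinates.
transform_points <- function(transform, z, y, x) {
  R <- transform$rotation; tt <- transform$translation_mm
  cc <- transform$center_mm
  z0 <- z - cc[1]; y0 <- y - cc[2]; x0 <- x - cc[3]
  list(z = R[1, 1] * z0 + R[1, 2] * y0 + R[1, 3] * x0 + cc[1] + tt[1],
       y = R[2, 1] * z0 + R[2, 2] * y0 + R[2, 3] * x0 + cc[2] + tt[2],
       x = R[3, 1] * z0 + R[3, 2] * y0 + R[3, 3] * x0 + cc[3] + tt[3])
}

#' Thin-cortex demonstration phantom
#'
#' A tube of normal wall thickness carrying one patch where the cortex thins
#' to well below one coarse voxel (default 0.06 mm over a 0.5 mm square;
#' a perfectly grid-aligned cylindrical wall keeps a surviving outer voxel
#' layer down to about 0.07 mm, whereas real oblique cortices drop out at
#' larger thicknesses). At the
#' coarse resolution, partial volume and the standard filter drive the
#' thinned patch below the bone threshold, so the segmentation shows a false
#' interruption there; at the fine resolution the patch is several voxels
#' thick and segments intact. This reproduces the known failure mode of
#' coarse-grid imaging over thin cortices (thin walls visible on the
#' gold-standard modality vanish in vivo).
#'
#' @param thin_thickness_mm wall thickness inside the patch (default 0.10).
#' @param patch_extent_mm patch size along the surface and z (default 0.5).
#' @param patch_angle_deg,patch_z_mm patch centre (defaults 90 deg, half
#'   height).
#' @param height_mm tube length (default 2).
#' @param ... further arguments passed to [phantom_spec()].
#' @return As [generate_phantom()].
#' @export
thin_cortex_phantom <- function(thin_thickness_mm = 0.06,
                                patch_extent_mm = 0.5,
                                patch_angle_deg = 90,
                                patch_z_mm = NULL,
                                height_mm = 2, ...) {
  spec <- phantom_spec(shape = "tube", height_mm = height_mm,
                       thin_patch = list(angle_deg = patch_angle_deg,
                                         z_mm = patch_z_mm %||% height_mm / 2,
                                         extent_mm = patch_extent_mm,
                                         thickness_mm = thin_thickness_mm),
                       ...)
  generate_phantom(spec)
}
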