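#' Rigid transform between two scan spaces
#'
#' Maps physical (mm) points of the fixed/target space into the moving/source
#' space: `p_moving = R (p_fixed - center) + center + translation`. All
#' coordinates follow the internal (z, y, x) axis order.
#'
#' @param rotation 3x3 rotation matrix, `det = +1` (checked to 1e-9).
#' @param translation_mm numeric 3-vector, mm.
#' @param center_mm rotation centre in mm (conventionally the centre of the
#'   fixed volume).
#' @return A `cg_rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation_mm = c(0, 0, 0),
                            center_mm = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(identical(dim(rotation), c(3L, 3L)))
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation must be orthonormal")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be proper (det = +1)")
  structure(list(rotation = rotation,
                 translation_mm = as.numeric(translation_mm),
                 center_mm = as.numeric(center_mm)),
            class = "cg_rigid_transform")
}

#' @rdname rigid_transform
#' @param angles_deg rotations (degrees) about the three internal axes
#'   (z, y, x), composed in that order.
#' @export
rotation_from_angles <- function(angles_deg) {
  a <- angles_deg * pi / 180
  r1 <- rbind(c(1, 0, 0), c(0, cos(a[1]), -sin(a[1])),
              c(0, sin(a[1]), cos(a[1])))
  r2 <- rbind(c(cos(a[2]), 0, sin(a[2])), c(0, 1, 0),
              c(-sin(a[2]), 0, cos(a[2])))
  r3 <- rbind(c(cos(a[3]), -sin(a[3]), 0), c(sin(a[3]), cos(a[3]), 0),
              c(0, 0, 1))
  r1 %*% r2 %*% r3
}

#' Total rotation angle of a transform, in degrees
#' @param transform a `cg_rigid_transform`.
#' @export
rotation_angle_deg <- function(transform) {
  tr <- sum(diag(transform$rotation))
  acos(pmin(1, pmax(-1, (tr - 1) / 2))) * 180 / pi
}

#' @export
print.cg_rigid_transform <- function(x, ...) {
  cat(sprintf("<cg_rigid_transform> rotation %.3f deg, translation (%s) mm\n",
              rotation_angle_deg(x),
              paste(sprintf("%.3f", x$translation_mm), collapse = ", ")))
  invisible(x)
}

# Invert: p_f = R^T (p_m - c - t) + c.
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt,
                  translation_mm = as.numeric(
                    -Rt %*% transform$translation_mm),
                  center_mm = transform$center_mm)
}

# Affine (A, b) mapping 0-based target voxel indices to 0-based source
# (moving) voxel indices through the physical-space transform.
voxel_affine <- function(transform, target, source) {
  R <- transform$rotation
  A <- R * target$voxel_size_mm / source$voxel_size_mm
  b <- (R %*% (target$origin_mm - transform$center_mm) +
          transform$center_mm + transform$translation_mm -
          source$origin_mm) / source$voxel_size_mm
  list(A = A, b = as.numeric(b))
}

geometry_of <- function(x) {
  list(dim = dim(grid_of(x)), voxel_size_mm = x$voxel_size_mm,
       origin_mm = x$origin_mm %||% c(0, 0, 0))
}

#' Resample a volume through a rigid transform
#'
#' Pulls the moving volume onto the target grid: each target voxel centre is
#' mapped into moving space by the transform and interpolated there.
#'
#' @param vol moving [gray_volume()].
#' @param transform a [rigid_transform()] (fixed -> moving space).
#' @param target target geometry: a `cg_volume` / `cg_labels`, or a list
#'   with `dim`, `voxel_size_mm`, `origin_mm`.
#' @param interp `"linear"` or `"nearest"`.
#' @return A [gray_volume()] on the target grid (out-of-field voxels are 0).
#' @export
resample_volume <- function(vol, transform, target = vol,
                            interp = c("linear", "nearest")) {
  stopifnot(inherits(vol, "cg_volume"))
  interp <- match.arg(interp)
  tg <- if (is.list(target) && !is.null(target$dim)) target else
    geometry_of(target)
  src <- geometry_of(vol)
  ab <- voxel_affine(transform, tg, src)
  out <- .cg_resample_affine(vol$data, dim(vol$data), as.integer(tg$dim),
                             ab$A, ab$b, if (interp == "nearest") 0L else 1L)
  gray_volume(out, tg$voxel_size_mm, tg$origin_mm)
}

#' Resample an interruption label map onto another grid
#'
#' Nearest-neighbour resampling through the rigid transform. When the target
#' voxels are coarser than the source (downscaling an 18 um label map onto
#' an 82 um grid), each target voxel takes the majority source label within
#' its footprint, ties going to the lowest label; background only wins where
#' it is the majority. Out-of-field voxels are 0.
#'
#' @param labels a [label_volume()] (or the `labels` of a `cg_interruptions`).
#' @inheritParams resample_volume
#' @param mode `"auto"` (majority when downscaling by more than 1.5x, else
#'   nearest), `"majority"`, or `"nearest"`.
#' @return A [label_volume()] on the target grid.
#' @export
resample_labels <- function(labels, transform, target,
                            mode = c("auto", "majority", "nearest")) {
  if (inherits(labels, "cg_interruptions")) labels <- labels$labels
  stopifnot(inherits(labels, "cg_labels"))
  mode <- match.arg(mode)
  tg <- if (is.list(target) && !is.null(target$dim)) target else
    geometry_of(target)
  src <- geometry_of(labels)
  ab <- voxel_affine(transform, tg, src)
  ratio <- tg$voxel_size_mm / src$voxel_size_mm
  use_majority <- switch(mode, auto = ratio > 1.5, majority = TRUE,
                         nearest = FALSE)
  out <- if (use_majority) {
    .cg_resample_labels_majority(labels$data, dim(labels$data),
                                 as.integer(tg$dim), ab$A, ab$b,
                                 rep(ratio / 2, 3))
  } else {
    o <- .cg_resample_affine(as.double(labels$data), dim(labels$data),
                             as.integer(tg$dim), ab$A, ab$b, 0L)
    storage.mode(o) <- "integer"
    o
  }
  label_volume(out, tg$voxel_size_mm, tg$origin_mm, check = FALSE)
}

#' Rigid registration of a moving onto a fixed volume
#'
#' Multi-resolution (coarse-to-fine) rigid registration. The default
#' similarity metric is mean squared error between soft bone-probability
#' maps: each volume is rescaled between its Otsu background and bone class
#' means and clipped to \[0, 1\], which normalises away the two modalities'
#' intensity scales while keeping the partial-volume gradient at the bone
#' surface that drives the optimisation. Optimisation is Nelder--Mead over the six
#' rigid parameters (three rotation angles in degrees, three translations in
#' mm) with a fixed iteration budget per level; the procedure is fully
#' deterministic. Register each bone of a joint separately (different joint
#' angles between acquisitions make a single rigid map invalid).
#'
#' @param moving,fixed [gray_volume()]s covering overlapping anatomy.
#' @param init optional initial [rigid_transform()] (default identity about
#'   the fixed-volume centre).
#' @param metric `"mse_bone"` (default) or `"mse"` (raw intensities).
#' @param levels number of pyramid levels (default 3).
#' @param maxit Nelder--Mead iteration budget per level.
#' @return A `cg_rigid_transform` (fixed -> moving space) with attributes
#'   `metric_value` (final value) and `converged`.
#' @export
register_rigid <- function(moving, fixed, init = NULL,
                           metric = c("mse_bone", "mse"), levels = 3L,
                           maxit = 300L) {
  stopifnot(inherits(moving, "cg_volume"), inherits(fixed, "cg_volume"))
  metric <- match.arg(metric)
  centre <- fixed$origin_mm + (dim(fixed$data) - 1) / 2 * fixed$voxel_size_mm
  prep <- function(v) {
    if (metric == "mse") return(v)
    # soft bone-probability map: affine rescale between the Otsu class
    # means, clipped to [0, 1]. Keeps the partial-volume gradient at the
    # bone surface (a hard binarisation flattens the metric) while
    # normalising away the two modalities' intensity scales.
    thr <- otsu_threshold(v$data)
    m0 <- mean(v$data[v$data < thr])
    m1 <- mean(v$data[v$data >= thr])
    p <- pmin(1, pmax(0, (v$data - m0) / (m1 - m0)))
    dim(p) <- dim(v$data)
    gray_volume(p, v$voxel_size_mm, v$origin_mm)
  }
  mv <- prep(moving); fx <- prep(fixed)
  theta <- c(0, 0, 0, 0, 0, 0)
  if (!is.null(init)) {
    stopifnot(inherits(init, "cg_rigid_transform"))
    # fold an initial guess in through its angles/translation
    theta <- c(angles_of(init$rotation), init$translation_mm)
  }
  for (lev in seq(levels - 1L, 0L)) {
    f <- 2L^lev
    fx_l <- downsample_volume(fx, f)
    mv_l <- downsample_volume(mv, f)
    cost <- function(th) {
      tr <- rigid_transform(rotation_from_angles(th[1:3]), th[4:6], centre)
      w <- resample_volume(mv_l, tr, fx_l)
      mean((w$data - fx_l$data)^2)
    }
    # restart Nelder-Mead until it converges (a fresh simplex around the
    # previous optimum escapes premature contraction)
    for (try in 1:3) {
      opt <- stats::optim(theta, cost, method = "Nelder-Mead",
                          control = list(maxit = maxit,
                                         reltol = 1e-12,
                                         parscale = c(1, 1, 1, .1, .1, .1)))
      theta <- opt$par
      if (opt$convergence == 0L) break
    }
  }
  out <- rigid_transform(rotation_from_angles(theta[1:3]), theta[4:6], centre)
  attr(out, "metric_value") <- opt$value
  attr(out, "converged") <- opt$convergence == 0L
  if (opt$convergence != 0L)
    warning("registration did not report convergence; final metric = ",
            signif(opt$value, 6), call. = FALSE)
  out
}

# Euler angles (deg) of a rotation built by rotation_from_angles (r1 z-axis,
# r2 y-axis, r3 x-axis order); used only to warm-start the optimiser.
angles_of <- function(R) {
  a2 <- asin(pmin(1, pmax(-1, R[1, 3])))
  a1 <- atan2(-R[2, 3], R[3, 3])
  a3 <- atan2(-R[1, 2], R[1, 1])
  c(a1, a2, a3) * 180 / pi
}

# Box-average downsampling by an integer factor (pyramid construction).
# Trailing voxels that do not fill a block are dropped; the origin shifts so
# that new voxel centres sit at the mean of the old centres they average.
downsample_volume <- function(vol, factor) {
  factor <- as.integer(factor)
  if (factor <= 1L) return(vol)
  d <- dim(vol$data)
  nd <- pmax(1L, d %/% factor)
  dc <- nd * factor
  x <- vol$data[seq_len(dc[1]), seq_len(dc[2]), seq_len(dc[3]), drop = FALSE]
  dim(x) <- c(factor, nd[1], factor, nd[2], factor, nd[3])
  x <- aperm(x, c(1, 3, 5, 2, 4, 6))
  dim(x) <- c(factor^3, prod(nd))
  out <- array(colMeans(x), nd)
  gray_volume(out, vol$voxel_size_mm * factor,
              vol$origin_mm + (factor - 1) / 2 * vol$voxel_size_mm)
}

#' Match interruptions between two label maps by voxel overlap
#'
#' Records a pair (a, b) whenever components a of set A and b of set B share
#' at least `overlap_min` voxels on the common grid (default 20 voxels,
#' = 0.011 mm3 at 0.082 mm — the smallest interruption volume detectable on
#' the coarse grid at the > 0.16 mm cut-off). The threshold is strict:
#' 19-voxel overlaps do not match. `matched_A` / `matched_B` count components
#' on each side with at least one pair, so one A component overlapping two B
#' components yields one matched A and two matched B.
#'
#' @param set_A a `cg_interruptions` (or [label_volume()]) on the common grid.
#' @param set_B a [label_volume()] of the (resampled) reference set on the
#'   same grid.
#' @param overlap_min minimum shared voxel count (default 20).
#' @param mode bookkeeping tag: `"fixed_ref_diameter"` (reference detected at
#'   the fixed > 0.10 mm cut-off) or `"same_diameter"`.
#' @param n_B total component count of the reference set before resampling;
#'   defaults to the largest label present in `set_B`.
#' @return A `cg_match_report`: `pairs` data frame
#'   (`label_A`, `label_B`, `overlap_voxels`), `matched_A`, `matched_B`,
#'   `n_A`, `n_B`, `overlap_min`, `mode`.
#' @export
match_interruptions <- function(set_A, set_B, overlap_min = 20L,
                                mode = c("fixed_ref_diameter",
                                         "same_diameter"),
                                n_B = NULL) {
  mode <- match.arg(mode)
  n_A <- if (inherits(set_A, "cg_interruptions")) set_A$joint_totals$count
         else max(grid_of(set_A))
  lab_A <- if (inherits(set_A, "cg_interruptions")) set_A$labels else set_A
  stopifnot(inherits(lab_A, "cg_labels"), inherits(set_B, "cg_labels"))
  check_same_geometry(lab_A, set_B, "label maps")
  n_B <- n_B %||% max(set_B$data)
  both <- lab_A$data > 0L & set_B$data > 0L
  if (any(both)) {
    tab <- table(A = lab_A$data[both], B = set_B$data[both])
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    df <- df[df$Freq >= overlap_min, , drop = FALSE]
    pairs <- data.frame(label_A = as.integer(df$A),
                        label_B = as.integer(df$B),
                        overlap_voxels = as.integer(df$Freq))
    pairs <- pairs[order(pairs$label_A, pairs$label_B), , drop = FALSE]
    rownames(pairs) <- NULL
  } else {
    pairs <- data.frame(label_A = integer(), label_B = integer(),
                        overlap_voxels = integer())
  }
  structure(list(mode = mode, pairs = pairs,
                 matched_A = length(unique(pairs$label_A)),
                 matched_B = length(unique(pairs$label_B)),
                 n_A = n_A, n_B = n_B,
                 overlap_min = as.integer(overlap_min)),
            class = "cg_match_report")
}

#' @export
print.cg_match_report <- function(x, ...) {
  cat(sprintf(
    "<cg_match_report> [%s] %d pair(s) at >= %d voxels; matched %d/%d (A), %d/%d (B)\n",
    x$mode, nrow(x$pairs), x$overlap_min, x$matched_A, x$n_A, x$matched_B,
    x$n_B))
  invisible(x)
}

#' Physical volume of an overlap criterion
#'
#' `overlap_min * voxel_size_mm^3`: e.g. 20 voxels at 0.082 mm is
#' 0.011 mm3 (printed to 3 decimals in reports).
#'
#' @param overlap_min voxel count.
#' @inheritParams map_steps_to_diameter
#' @return Volume in mm3 (unrounded).
#' @export
overlap_volume_mm3 <- function(overlap_min, voxel_size_mm) {
  stopifnot(overlap_min > 0)
  check_voxel_size(voxel_size_mm)
  overlap_min * voxel_size_mm^3
}
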