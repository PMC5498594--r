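# Independent reference implementations (array-shift morphology, igraph
# connected components, dense convolution, exhaustive enumeration) used to
# cross-check the package's C++ / analytic code paths.

# Shift a logical 3D array by one voxel along `axis` in direction `dir`,
# padding with FALSE.
shift_mask <- function(x, axis, dir) {
  out <- array(FALSE, dim(x))
  n <- dim(x)[axis]
  if (n < 2) return(out)
  if (axis == 1) {
    if (dir > 0) out[2:n, , ] <- x[1:(n - 1), , ]
    else out[1:(n - 1), , ] <- x[2:n, , ]
  } else if (axis == 2) {
    if (dir > 0) out[, 2:n, ] <- x[, 1:(n - 1), ]
    else out[, 1:(n - 1), ] <- x[, 2:n, ]
  } else {
    if (dir > 0) out[, , 2:n] <- x[, , 1:(n - 1)]
    else out[, , 1:(n - 1)] <- x[, , 2:n]
  }
  out
}

# One 6-connected dilation by array shifts.
r_dilate6_once <- function(x) {
  y <- x
  for (a in 1:3) for (d in c(-1, 1)) y <- y | shift_mask(x, a, d)
  y
}

# One 26-connected dilation.
r_dilate26_once <- function(x) {
  y <- x
  for (a in 1:3) for (d in c(-1, 1)) y <- y | shift_mask(y, a, d)
  # sequential shifts along the three axes compose to the Chebyshev ball
  y
}

r_dilate <- function(x, k, conn = 6) {
  for (i in seq_len(k))
    x <- if (conn == 6) r_dilate6_once(x) else r_dilate26_once(x)
  x
}

# 26-connected components via igraph.
r_label26 <- function(x) {
  d <- dim(x)
  idx <- which(x)
  lab <- array(0L, d)
  if (!length(idx)) return(lab)
  pos <- arrayInd(idx, d)
  key <- (pos[, 1] - 1) + d[1] * (pos[, 2] - 1) + d[1] * d[2] * (pos[, 3] - 1)
  lookup <- integer(prod(d)); lookup[key + 1] <- seq_along(idx)
  edges <- NULL
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  for (r in seq_len(nrow(offs))) {
    q <- sweep(pos, 2, offs[r, ], `+`)
    ok <- q[, 1] >= 1 & q[, 2] >= 1 & q[, 3] >= 1 &
      q[, 1] <= d[1] & q[, 2] <= d[2] & q[, 3] <= d[3]
    qk <- (q[ok, 1] - 1) + d[1] * (q[ok, 2] - 1) + d[1] * d[2] * (q[ok, 3] - 1)
    nb <- lookup[qk + 1]
    hit <- nb > 0
    if (any(hit)) edges <- rbind(edges, cbind(which(ok)[hit], nb[hit]))
  }
  if (is.null(edges)) {
    lab[idx] <- seq_along(idx)
    return(lab)
  }
  g <- igraph::graph_from_edgelist(unique(t(apply(edges, 1, sort))),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}

# Brute-force interruption detection: morphological opening of the void by
# the k-step cross, two-boundary connectivity filter, geodesic
# reconstruction by iterated constrained dilation.
oracle_detect <- function(bone, region, k) {
  cortical <- region == 1L
  void <- cortical & !bone
  surviving <- void & !r_dilate(bone, k, conn = 6)
  lab <- r_label26(surviving)
  out_adj <- r_dilate(region == 0L, 1, conn = 26)
  in_adj <- r_dilate(region == 2L, 1, conn = 26)
  keep <- intersect(unique(lab[surviving & out_adj]),
                    unique(lab[surviving & in_adj]))
  keep <- keep[keep > 0]
  sel <- array(lab %in% keep, dim(bone))
  repeat {
    grown <- (sel | r_dilate(sel, 1, conn = 26)) & void
    if (identical(grown, sel)) break
    sel <- grown
  }
  r_label26(sel)
}

# Two integer label maps describe the same partition of the same voxel set.
same_partition <- function(a, b) {
  if (!identical(a > 0, b > 0)) return(FALSE)
  if (!any(a > 0)) return(TRUE)
  tab <- table(a[a > 0], b[b > 0])
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

# Dense truncated-Gaussian convolution (direct triple loop, edge
# renormalised), the oracle for the separable C++ filter.
dense_gauss <- function(x, sigma, radius) {
  d <- dim(x)
  w1 <- exp(-(-radius:radius)^2 / (2 * sigma^2))
  out <- array(0, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    acc <- 0; wsum <- 0
    for (a in -radius:radius) for (b in -radius:radius)
      for (cc in -radius:radius) {
        p <- i + a; q <- j + b; r <- k + cc
        if (p < 1 || q < 1 || r < 1 || p > d[1] || q > d[2] || r > d[3]) next
        w <- w1[a + radius + 1] * w1[b + radius + 1] * w1[cc + radius + 1]
        acc <- acc + w * x[p, q, r]; wsum <- wsum + w
      }
    out[i, j, k] <- acc / wsum
  }
  out
}

# Exact Wilcoxon signed-rank two-sided p by full enumeration of the 2^n
# sign assignments (ties handled through midranks).
enum_wilcoxon <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% r
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Longhand ICC(2,1) from aov() mean squares (independent of the package's
# own ANOVA arithmetic).
aov_icc21 <- function(x) {
  n <- nrow(x); k <- ncol(x)
  df <- data.frame(y = as.vector(x),
                   subj = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subj + rater, data = df))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

# A slab-cortex fixture: region grid (outside y < y0, cortical slab,
# interior beyond) plus a bone grid with cylindrical through-holes along y.
slab_fixture <- function(d = c(16, 20, 16), y_cortex = 6:14,
                         holes = list(), voxel_size_mm = 0.082) {
  region <- array(0L, d)
  region[, y_cortex, ] <- 1L
  region[, (max(y_cortex) + 1):d[2], ] <- 2L
  bone <- region == 1L
  for (h in holes) {  # h: list(z, x, diam_voxels)
    for (z in 1:d[1]) for (x in 1:d[3])
      if ((z - h$z)^2 + (x - h$x)^2 <= (h$diam / 2)^2)
        bone[z, y_cortex, x] <- FALSE
  }
  cm <- cortical_mask_from_regions(region, voxel_size_mm)
  inside <- region >= 1L
  seg <- local({
    ct <- accept_manual_contour(inside, voxel_size_mm = voxel_size_mm)
    structure(list(bone = bone & region == 1L, inside = ct$inside,
                   voxel_size_mm = voxel_size_mm, modality = "lowres",
                   bvtv = sum(bone & region == 1L) / sum(ct$inside),
                   origin_mm = c(0, 0, 0)),
              class = "cg_segmentation")
  })
  list(seg = seg, cmask = cm, region = region, bone = bone & region == 1L)
}

# Shared phantom fixtures, built once per test run.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_cache[[name]]))
    assign(name, build(), envir = .fixture_cache)
  .fixture_cache[[name]]
}

recall_phantom <- function() fixture("recall", function() {
  spec <- phantom_spec(
    holes = data.frame(angle_deg = c(0, 90, 180, 270), z_mm = 1,
                       diameter_mm = c(0.10, 0.25, 0.45, 0.65),
                       through = TRUE),
    noise_sd = 0, supersample = c(lowres = 1L, highres = 1L))
  generate_phantom(spec)
})

trend_phantom_spec <- function() phantom_spec(
  holes = data.frame(angle_deg = rep(c(0, 120, 240), 2),
                     z_mm = rep(c(0.7, 1.4), each = 3),
                     diameter_mm = c(0.30, 0.45, 0.65, 0.70, 0.32, 0.48),
                     through = TRUE),
  noise_sd = 0.05, seed = 7)
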