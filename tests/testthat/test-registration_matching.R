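test_that("rigid transforms validate rotations and invert correctly", {
  expect_error(rigid_transform(matrix(1, 3, 3)), "orthonormal")
  refl <- diag(c(-1, 1, 1))
  expect_error(rigid_transform(refl), "det")
  tf <- rigid_transform(rotation_from_angles(c(10, -5, 3)), c(1, 2, -1),
                        center_mm = c(5, 5, 5))
  inv <- cortigap:::invert_transform(tf)
  p <- c(1.2, 3.4, -0.7)
  q <- with(tf, as.numeric(rotation %*% (p - center_mm) + center_mm +
                             translation_mm))
  back <- with(inv, as.numeric(rotation %*% (q - center_mm) + center_mm +
                                 translation_mm))
  expect_equal(back, p, tolerance = 1e-12)
})

test_that("identity resampling on the same grid is exact for labels", {
  lab <- array(0L, c(8, 8, 8)); lab[2:4, 2:4, 2:4] <- 1L; lab[6, 6, 6] <- 2L
  lv <- label_volume(lab, 0.082)
  out <- resample_labels(lv, rigid_transform(), lv)
  expect_identical(out$data, lv$data)
  # a label map entirely outside the target field resamples to zero
  far <- rigid_transform(translation_mm = c(50, 50, 50))
  expect_equal(max(resample_labels(lv, far, lv)$data), 0L)
})

test_that("downscaling a fine sphere label preserves its volume", {
  d <- c(60, 60, 60)
  lab <- array(0L, d)
  ctr <- (d + 1) / 2
  r <- 20
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3])
    if ((i - ctr[1])^2 + (j - ctr[2])^2 + (k - ctr[3])^2 <= r^2)
      lab[i, j, k] <- 1L
  fine <- label_volume(lab, 0.018)
  target <- list(dim = c(14L, 14L, 14L), voxel_size_mm = 0.082,
                 origin_mm = c(0, 0, 0))
  coarse <- resample_labels(fine, rigid_transform(), target)
  vol_fine <- sum(fine$data == 1L) * 0.018^3
  vol_coarse <- sum(coarse$data == 1L) * 0.082^3
  expect_lt(abs(vol_coarse - vol_fine), 2 * 0.082^3 + 0.05 * vol_fine)
})

test_that("matching applies the strict overlap threshold", {
  base <- array(0L, c(10, 10, 10))
  a <- base; a[1:2, 1:5, 1:5] <- 1L          # 50 voxels
  b <- base; b[1:2, 1:5, 1:2] <- 1L          # overlap 20
  m <- match_interruptions(label_volume(a, 0.082), label_volume(b, 0.082))
  expect_equal(m$matched_A, 1L)
  b19 <- base; b19[1, 1:5, 1:3] <- 1L; b19[2, 1:2, 1:2] <- 1L   # overlap 19
  m19 <- match_interruptions(label_volume(a, 0.082), label_volume(b19, 0.082))
  expect_equal(nrow(m19$pairs), 0L)
  expect_equal(m19$matched_A, 0L)
})

test_that("one test component can match two reference components", {
  base <- array(0L, c(6, 10, 10))
  a <- base; a[, 2:9, 2:9] <- 1L
  b <- base; b[, 2:4, 2:9] <- 1L; b[, 7:9, 2:9] <- 2L
  m <- match_interruptions(label_volume(a, 0.082), label_volume(b, 0.082),
                           overlap_min = 25)
  expect_equal(m$matched_A, 1L)
  expect_equal(m$matched_B, 2L)
  expect_equal(nrow(m$pairs), 2L)
})

test_that("matching is symmetric and self-matching is complete", {
  set.seed(31)
  lab <- array(0L, c(12, 12, 12))
  lab[2:5, 2:5, 2:5] <- 1L              # 64 voxels
  lab[8:11, 8:11, 8:11] <- 2L           # 64 voxels
  lab[7, 1, 1] <- 3L                    # 1 voxel, below overlap_min
  lv <- label_volume(lab, 0.082)
  m <- match_interruptions(lv, lv)
  expect_equal(m$matched_A, 2L)
  expect_equal(m$matched_B, 2L)
  # symmetry of pair existence under swapped roles
  lab2 <- array(0L, c(12, 12, 12)); lab2[3:6, 3:6, 3:6] <- 1L
  lv2 <- label_volume(lab2, 0.082)
  m_ab <- match_interruptions(lv, lv2)
  m_ba <- match_interruptions(lv2, lv)
  expect_identical(m_ab$pairs$overlap_voxels, m_ba$pairs$overlap_voxels)
  expect_identical(m_ab$pairs$label_A, m_ba$pairs$label_B)
})

test_that("transform round trips lose little of each large component", {
  ph <- recall_phantom()
  det <- local({
    ct <- auto_contour(ph$lowres)
    seg <- segment_lowres(ph$lowres, ct, filter = "none",
                          threshold_permille = 500)
    detect_interruptions(seg, build_cortical_mask(ct, 0.328), 1)
  })
  big <- det$components$label[det$components$voxel_count >= 100]
  skip_if(length(big) == 0)
  ctr <- ph$lowres$origin_mm + (dim(ph$lowres$data) - 1) / 2 * 0.082
  tf <- rigid_transform(rotation_from_angles(c(4, 2, -3)), c(0.1, -0.2, 0.15),
                        ctr)
  once <- resample_labels(det$labels, tf, ph$lowres, mode = "nearest")
  back <- resample_labels(once, cortigap:::invert_transform(tf), ph$lowres,
                          mode = "nearest")
  for (l in big) {
    kept <- sum(back$data == l & det$labels$data == l)
    expect_gte(kept / sum(det$labels$data == l), 0.9)
  }
})

test_that("registration recovers a known rigid perturbation", {
  ph <- fixture("reg_phantom", function() generate_phantom(trend_phantom_spec()))
  fx <- ph$lowres
  ctr <- fx$origin_mm + (dim(fx$data) - 1) / 2 * fx$voxel_size_mm
  tf_true <- rigid_transform(rotation_from_angles(c(5, -3, 2)),
                             c(0.3, 0.1, -0.2), ctr)
  mv <- resample_volume(fx, tf_true, fx)
  tf_hat <- suppressWarnings(register_rigid(mv, fx))
  # tf_hat should invert tf_true: compose and measure the residual
  comp <- tf_true$rotation %*% tf_hat$rotation
  residual_deg <- acos(pmin(1, (sum(diag(comp)) - 1) / 2)) * 180 / pi
  expect_lt(residual_deg, 0.5)
  q <- tf_true$rotation %*% (tf_hat$rotation %*% (ctr - ctr) + ctr +
                               tf_hat$translation_mm - ctr) + ctr +
    tf_true$translation_mm
  expect_lt(sqrt(sum((q - ctr)^2)), 0.1)
})

test_that("registering a volume to itself stays at the identity", {
  ph <- fixture("reg_phantom", function() generate_phantom(trend_phantom_spec()))
  tf <- suppressWarnings(register_rigid(ph$lowres, ph$lowres, maxit = 100))
  expect_lt(rotation_angle_deg(tf), 0.1)
  expect_lt(sqrt(sum(tf$translation_mm^2)), 0.05)
})

test_that("overlap volumes convert voxel counts to printed mm3", {
  expect_equal(round(overlap_volume_mm3(20, 0.082), 3), 0.011)
  expect_equal(overlap_volume_mm3(1, 1.0), 1.0)
  expect_equal(overlap_volume_mm3(20, 0.018), 20 * 0.018^3)
})
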