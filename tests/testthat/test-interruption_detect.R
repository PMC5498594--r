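test_that("the step-to-diameter mapping reproduces the published table", {
  # 0.082 mm grid (in-vivo class)
  expect_equal(map_steps_to_diameter(1, 0.082), 0.164)
  expect_equal(map_steps_to_diameter(2, 0.082), 0.328)
  expect_equal(map_steps_to_diameter(3, 0.082), 0.492)
  # 0.018 mm grid (gold-standard class)
  expect_equal(map_steps_to_diameter(3, 0.018), 0.108)
  expect_equal(map_steps_to_diameter(5, 0.018), 0.180)
  expect_equal(map_steps_to_diameter(9, 0.018), 0.324)
  expect_equal(map_steps_to_diameter(14, 0.018), 0.504)
  expect_error(map_steps_to_diameter(0, 0.082), "positive integer")
})

test_that("step choice matches published cross-resolution pairings", {
  expect_equal(choose_steps_for_diameter(0.16, 0.082), 1L)
  expect_equal(choose_steps_for_diameter(0.33, 0.082), 2L)
  expect_equal(choose_steps_for_diameter(0.50, 0.082), 3L)
  expect_equal(choose_steps_for_diameter(0.10, 0.018), 3L)
  expect_equal(choose_steps_for_diameter(0.50, 0.018), 14L)
  # matching the enforced diameters of the coarse grid onto the fine grid
  expect_equal(choose_steps_for_diameter(0.164, 0.018), 5L)
  expect_equal(choose_steps_for_diameter(0.328, 0.018), 9L)
  expect_equal(choose_steps_for_diameter(0.492, 0.018), 14L)
  # tiny targets still need one step
  expect_equal(choose_steps_for_diameter(0.001, 0.082), 1L)
})

test_that("a slab with one through-hole is detected iff wider than 2k voxels", {
  # 9-voxel-thick slab cortex, cylindrical through-hole of diameter 3
  fx3 <- slab_fixture(holes = list(list(z = 8, x = 8, diam = 3)))
  det <- detect_interruptions(fx3$seg, fx3$cmask, 1)
  expect_equal(det$joint_totals$count, 1L)            # 3 > 2
  expect_equal(det$components$voxel_count, sum(!fx3$bone & fx3$region == 1L))
  expect_equal(det$components$surface_mm2, 9 * 0.082^2)   # 9-voxel mouth
  expect_equal(detect_interruptions(fx3$seg, fx3$cmask, 2)$joint_totals$count,
               0L)                                     # 3 < 4
  # an exactly-2k-wide gap is closed: exclusive bound
  fx2 <- slab_fixture(holes = list(list(z = 8.5, x = 8.5, diam = 2)))
  expect_equal(detect_interruptions(fx2$seg, fx2$cmask, 1)$joint_totals$count,
               0L)
})

test_that("a blind pit touching only one boundary is never an interruption", {
  fx <- slab_fixture()
  bone <- fx$seg$bone
  bone[7:9, 6:9, 7:9] <- FALSE          # pit from the periosteal side only
  seg <- fx$seg; seg$bone <- bone
  for (k in 1:2)
    expect_equal(detect_interruptions(seg, fx$cmask, k)$joint_totals$count, 0L)
})

test_that("detection equals the brute-force opening oracle on random grids", {
  skip_if_not_installed("igraph")
  set.seed(100)
  for (rep in 1:25) {
    d <- sample(8:16, 3, replace = TRUE)
    a <- sample(2:3, 1)                  # outside band
    b <- sample((a + 4):(d[2] - 2), 1)   # cortical band end
    region <- array(0L, d)
    region[, (a + 1):b, ] <- 1L
    if (b < d[2]) region[, (b + 1):d[2], ] <- 2L
    bone <- region == 1L & array(runif(prod(d)) < 0.75, d)
    cm <- cortical_mask_from_regions(region, 0.082)
    seg <- slab_fixture()$seg            # reuse class scaffolding
    seg$bone <- bone; seg$inside <- region >= 1L
    k <- sample(1:2, 1)
    det <- detect_interruptions(seg, cm, k)
    expect_true(same_partition(det$labels$data,
                               oracle_detect(bone, region, k)),
                label = sprintf("rep %d (k=%d)", rep, k))
  }
})

test_that("labelled interruption volume is non-increasing in k", {
  ph <- recall_phantom()
  ct <- auto_contour(ph$lowres)
  seg <- segment_lowres(ph$lowres, ct, filter = "none", threshold_permille = 500)
  cm <- build_cortical_mask(ct, 0.328)
  vols <- sapply(1:4, function(k)
    detect_interruptions(seg, cm, k)$joint_totals$total_volume_mm3)
  expect_true(all(diff(vols) <= 0))
})

test_that("noise-free phantom holes are found exactly above each cut-off", {
  ph <- recall_phantom()       # hole diameters 0.10, 0.25, 0.45, 0.65 mm
  ct <- auto_contour(ph$lowres)
  seg <- segment_lowres(ph$lowres, ct, filter = "none", threshold_permille = 500)
  cm <- build_cortical_mask(ct, 0.328)
  truth <- ph$truth
  for (k in 1:3) {
    det <- detect_interruptions(seg, cm, k)
    cutoff <- map_steps_to_diameter(k, 0.082)
    expected <- truth$holes$id[truth$holes$true_diameter_mm > cutoff]
    # recall: every expected hole overlaps exactly one detected component
    hit <- sapply(expected, function(i) {
      labs <- unique(det$labels$data[truth$labels_lowres$data == i])
      labs <- labs[labs > 0]
      length(labs) == 1
    })
    expect_true(all(hit), label = paste("recall at k =", k))
    # precision: no detected component without a ground-truth hole
    expect_equal(det$joint_totals$count, length(expected),
                 label = paste("count at k =", k))
  }
})

test_that("interruption surfaces are consistent across resolutions", {
  ph <- recall_phantom()
  # the 0.65 mm hole measured on both grids
  ct_l <- auto_contour(ph$lowres)
  seg_l <- segment_lowres(ph$lowres, ct_l, filter = "none",
                          threshold_permille = 500)
  det_l <- detect_interruptions(seg_l, build_cortical_mask(ct_l, 0.328), 3)
  ct_h <- auto_contour(ph$highres)
  seg_h <- segment_highres(ph$highres, ct_h, max_value = 1000)
  det_h <- detect_interruptions(seg_h, build_cortical_mask(ct_h, 0.324), 14)
  expect_equal(det_l$joint_totals$count, 1L)
  expect_equal(det_h$joint_totals$count, 1L)
  s_l <- det_l$components$surface_mm2
  s_h <- det_h$components$surface_mm2
  expect_lt(abs(s_l - s_h) / s_h, 0.15)
  # and both are near the analytic mouth area of the 0.65 mm hole
  expect_lt(abs(s_h - pi * 0.325^2) / (pi * 0.325^2), 0.15)
})

test_that("surface remeasurement and additivity agree with stored values", {
  fx <- slab_fixture(holes = list(list(z = 5, x = 5, diam = 3),
                                  list(z = 12, x = 12, diam = 3)))
  det <- detect_interruptions(fx$seg, fx$cmask, 1)
  expect_equal(det$joint_totals$count, 2L)
  again <- interruption_surface(det, fx$cmask)
  expect_equal(again$surface_mm2, det$components$surface_mm2)
  expect_equal(det$joint_totals$total_surface_mm2,
               sum(det$components$surface_mm2))
})
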