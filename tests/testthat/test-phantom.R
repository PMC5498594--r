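test_that("phantom generation is reproducible and validates its spec", {
  spec <- phantom_spec(holes = data.frame(angle_deg = 0, z_mm = 1,
                                          diameter_mm = 0.4, through = TRUE),
                       noise_sd = 0.05, height_mm = 1.0,
                       voxel_sizes_mm = c(lowres = 0.082, highres = 0.082),
                       supersample = c(lowres = 2L, highres = 2L), seed = 9)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$lowres$data, b$lowres$data)
  expect_identical(a$highres$data, b$highres$data)
  # overlapping holes are a spec error
  expect_error(phantom_spec(holes = data.frame(angle_deg = c(0, 2), z_mm = 1,
                                               diameter_mm = c(0.4, 0.4),
                                               through = TRUE)),
               "overlap")
  expect_error(phantom_spec(holes = data.frame(angle_deg = 0, z_mm = 1,
                                               diameter_mm = 5, through = TRUE)),
               "extent")
})

test_that("no noise and no supersampling give a binary two-level volume", {
  spec <- phantom_spec(noise_sd = 0, height_mm = 0.8,
                       supersample = c(lowres = 1L, highres = 1L))
  ph <- generate_phantom(spec)
  expect_setequal(unique(as.vector(ph$lowres$data)), c(0, 1000))
})

test_that("ground-truth hole areas approach the analytic disc area", {
  ph <- recall_phantom()
  truth <- ph$truth
  cm <- local({
    ct <- auto_contour(ph$highres)
    build_cortical_mask(ct, 0.324)
  })
  for (i in 2:4) {   # 0.25, 0.45, 0.65 mm (0.10 mm is ~1 voxel at low res)
    mouth <- sum(truth$labels_highres$data == i & cm$periosteal_layer) * 0.018^2
    analytic <- truth$holes$true_area_mm2[i]
    expect_lt(abs(mouth - analytic) / analytic, 0.10,
              label = paste("hole", i))
  }
})

test_that("the stored pair transform aligns the two acquisitions", {
  spec <- phantom_spec(holes = data.frame(angle_deg = 0, z_mm = 0.6,
                                          diameter_mm = 0.5, through = TRUE),
                       noise_sd = 0, height_mm = 1.2,
                       pair_rotation_deg = c(6, 0, 0),
                       pair_translation_mm = c(0.2, -0.1, 0.1))
  ph <- generate_phantom(spec)
  # resampling the high-res truth labels through the stored transform must
  # land on the low-res truth labels
  mapped <- resample_labels(ph$truth$labels_highres, ph$truth$transform,
                            ph$truth$labels_lowres)
  ref <- ph$truth$labels_lowres$data
  agree <- sum(mapped$data == 1L & ref == 1L)
  expect_gt(agree / sum(ref == 1L), 0.8)
})

test_that("a sub-voxel thin patch is a false interruption at coarse scale only", {
  ph <- fixture("thin_cortex", function()
    thin_cortex_phantom(height_mm = 1.2, outer_radius_mm = 0.8, noise_sd = 0))
  # low resolution: the thinned patch falls below the bone threshold
  ct_l <- auto_contour(ph$lowres)
  seg_l <- segment_lowres(ph$lowres, ct_l)
  cm_l <- build_cortical_mask(ct_l, 0.328)
  det_l <- detect_interruptions(seg_l, cm_l, 1)
  expect_gte(det_l$joint_totals$count, 1)
  # high resolution: the patch is several voxels thick and segments intact
  ct_h <- auto_contour(ph$highres)
  seg_h <- segment_highres(ph$highres, ct_h, max_value = 1000)
  cm_h <- build_cortical_mask(ct_h, 0.324)
  det_h <- detect_interruptions(seg_h, cm_h, 3)
  expect_equal(det_h$joint_totals$count, 0L)
})

test_that("a 0.50 mm wall produces no false interruption at either scale", {
  ph <- fixture("thick_wall", function()
    generate_phantom(phantom_spec(cortical_thickness_mm = 0.50,
                                  outer_radius_mm = 0.8, height_mm = 1.0,
                                  noise_sd = 0)))
  ct <- auto_contour(ph$lowres)
  seg <- segment_lowres(ph$lowres, ct, filter = "none",
                        threshold_permille = 500)
  det <- detect_interruptions(seg, build_cortical_mask(ct, 0.328), 1)
  expect_equal(det$joint_totals$count, 0L)
})
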