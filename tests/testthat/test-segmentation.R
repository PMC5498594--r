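# A small noise-free binary tube used across contour/segmentation tests.
tube_volume <- function() fixture("tube_binary", function() {
  spec <- phantom_spec(noise_sd = 0, supersample = c(lowres = 1L, highres = 1L),
                       height_mm = 1.0)
  generate_phantom(spec)$lowres
})

test_that("auto-contour of a hollow tube is the filled cylinder", {
  vol <- tube_volume()
  ct <- auto_contour(vol)
  bone <- vol$data >= 500
  expect_true(all(ct$inside[bone]))             # every bone voxel inside
  # the annulus interior (marrow) is included
  d <- dim(vol$data)
  centre <- round(d / 2)
  expect_true(ct$inside[centre[1], centre[2], centre[3]])
  # a single connected component
  expect_equal(max(label_components(ct$inside, 26L)), 1L)
})

test_that("auto-contour is idempotent on its own binary output", {
  vol <- tube_volume()
  ct <- auto_contour(vol)
  again <- auto_contour(gray_volume(ct$inside * 1000, vol$voxel_size_mm))
  expect_identical(again$inside, ct$inside)
})

test_that("an all-zero volume raises an empty-contour error", {
  expect_error(auto_contour(gray_volume(array(0, c(6, 6, 6)), 0.082)),
               "empty contour")
})

test_that("two separated objects yield one or two masks per split setting", {
  arr <- array(0, c(8, 30, 12))
  arr[2:7, 3:10, 3:10] <- 1000
  arr[2:7, 20:27, 3:10] <- 1000
  vol <- gray_volume(arr, 0.082)
  one <- auto_contour(vol, closing_mm = 0.082)
  expect_equal(max(label_components(one$inside, 26L)), 1L)
  both <- auto_contour(vol, closing_mm = 0.082, split_components = TRUE)
  expect_length(both, 2L)
})

test_that("manual contours are validated, filled and can reject bad masks", {
  vol <- tube_volume()
  ct <- auto_contour(vol)
  manual <- accept_manual_contour(ct$inside, vol = vol)
  expect_identical(manual$inside, ct$inside)
  holey <- ct$inside
  centre <- round(dim(holey) / 2)
  holey[centre[1], centre[2], centre[3]] <- FALSE
  expect_warning(fixed <- accept_manual_contour(holey, vol = vol), "holes")
  expect_identical(fixed$inside, ct$inside)
  small <- array(FALSE, dim(holey)); small[1:2, 1:2, 1:2] <- TRUE
  expect_error(accept_manual_contour(small, vol = vol,
                                     bone = vol$data >= 500),
               "outside the periosteal mask")
})

test_that("noise-free plain-threshold segmentation recovers the shell exactly", {
  vol <- tube_volume()
  ct <- auto_contour(vol)
  seg <- segment_lowres(vol, ct, filter = "none", threshold_permille = 500)
  expect_identical(seg$bone, (vol$data >= 500) & ct$inside)
  # threshold at the minimum marks the whole mask as bone
  all_bone <- segment_lowres(vol, ct, filter = "none", threshold_permille = 0)
  expect_equal(all_bone$bvtv, 1)
})

test_that("high-res segmentation applies the permille threshold literally", {
  ct <- accept_manual_contour(array(TRUE, c(6, 6, 6)), voxel_size_mm = 0.018)
  flat <- function(v) gray_volume(array(v, c(6, 6, 6)), 0.018)
  expect_equal(segment_highres(flat(300), ct, max_value = 1000)$bvtv, 1)
  expect_equal(segment_highres(flat(200), ct, max_value = 1000)$bvtv, 0)
  expect_error(segment_highres(flat(300), ct), "config error")
})

test_that("high-res filtering matches the dense-convolution oracle off ties", {
  set.seed(21)
  arr <- array(1000 * (runif(12^3) < 0.5), c(12, 12, 12))
  vol <- gray_volume(arr, 0.018)
  ct <- accept_manual_contour(array(TRUE, c(12, 12, 12)), voxel_size_mm = 0.018)
  seg <- segment_highres(vol, ct, max_value = 1000)
  ref <- dense_gauss(arr, 0.8, 1) >= 247
  filt <- cortigap:::gaussian_filter3d(arr, 0.8, 1L)
  off_tie <- abs(filt - 247) > 1e-9
  expect_identical(seg$bone[off_tie], ref[off_tie])
})

test_that("BV/TV is non-increasing in the threshold and recomputable", {
  vol <- tube_volume()
  ct <- auto_contour(vol)
  b <- sapply(c(100, 300, 500, 700, 900), function(tp)
    segment_lowres(vol, ct, filter = "none", threshold_permille = tp)$bvtv)
  expect_true(all(diff(b) <= 0))
  seg <- segment_lowres(vol, ct, filter = "none")
  expect_equal(bvtv(seg), seg$bvtv)
})

test_that("threshold calibration hits a target BV/TV like a quantile", {
  set.seed(22)
  vol <- gray_volume(array(runif(20^3), c(20, 20, 20)), 0.082)
  ct <- accept_manual_contour(array(TRUE, c(20, 20, 20)), voxel_size_mm = 0.082)
  thr <- calibrate_threshold_to_bvtv(vol, ct, 0.25)
  expect_lt(abs(attr(thr, "achieved_bvtv") - 0.25), 1 / length(vol$data) + 1e-12)
  expect_lt(abs(as.numeric(thr) - stats::quantile(vol$data, 0.75)), 0.01)
  # unreachable targets fail: binary image, absurd target
  halves <- gray_volume(array(rep(c(0, 1), each = 4000), c(20, 20, 20)), 0.082)
  expect_error(calibrate_threshold_to_bvtv(halves, ct, 0.999),
               "calibration error")
})
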