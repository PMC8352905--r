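test_that("overlay difference is exact set subtraction on one grid", {
  ph <- generate_labyrinth(phantom_spec(noise_sd = 0, partial_volume = FALSE))
  m <- ph$mask
  expect_equal(sum(overlay_difference(m, m)$data), 0)
  empty <- new_mask(array(0L, dim(m$data)), ph$volume)
  expect_identical(overlay_difference(m, empty)$data, m$data)
  off <- new_mask(m$data, new_volume(m$data, spacing = c(0.5, 0.5, 0.5)))
  expect_error(overlay_difference(m, off), "grid")

  # same-grid plug with no pose/drift/noise: difference is the true defect
  sp <- phantom_spec(noise_sd = 0, partial_volume = FALSE)
  ph2 <- generate_labyrinth(sp)
  pl <- apply_plug(ph2, list(canal = "sc", center_deg = 90, extent_deg = 70))
  pre_mask <- segment_fluid(ph2$volume, labyrinth_roi(ph2))
  post_mask <- segment_fluid(pl$post, labyrinth_roi(ph2))
  diff <- overlay_difference(pre_mask, post_mask)
  expect_identical(diff$data, pl$defect$data)
})

test_that("clean_defect keeps the plug blob and discards shells", {
  sp <- phantom_spec(noise_sd = 0)
  ph <- generate_labyrinth(sp)
  pl <- apply_plug(ph, list(canal = "sc", center_deg = 90, extent_deg = 70))
  keep <- plug_keep_region(ph, list(canal = "sc", center_deg = 90,
                                    extent_deg = 70))
  full <- roi_box(c(0, 0, 0), dim(ph$volume$data))

  # whole-grid keep region with a single-component diff: unchanged
  cleaned <- clean_defect(pl$defect, keep_region = full)
  expect_identical(cleaned$data, pl$defect$data)

  # defect blob plus a thin spurious surface shell away from the plug:
  # only the blob survives the keep region, within 2% of the truth
  shell <- dilate_shell <- canalvol:::dilate26(ph$mask$data) & !ph$mask$data
  shell_slab <- array(FALSE, dim(shell))
  shell_slab[, 1:22, ] <- shell[, 1:22, ]  # far from the superior canal apex
  diff2 <- new_mask(pl$defect$data | shell_slab, ph$volume)
  cleaned2 <- clean_defect(diff2, keep_region = keep)
  expect_lt(abs(sum(cleaned2$data) / sum(pl$defect$data) - 1), 0.02)

  # keep region disjoint from the difference: empty mask plus warning
  far <- roi_box(c(0, 0, 0), c(6, 6, 6))
  expect_warning(cleaned3 <- clean_defect(pl$defect, keep_region = far),
                 "empty")
  expect_equal(sum(cleaned3$data), 0)
})

test_that("relative volume change handles the boundary cases", {
  ph <- generate_labyrinth(phantom_spec(noise_sd = 0))
  m <- ph$mask
  empty <- new_mask(array(0L, dim(m$data)), ph$volume)
  expect_equal(relative_volume_change(empty, m), 0)
  expect_equal(relative_volume_change(m, m), 100)
  expect_error(relative_volume_change(m, empty), "empty")
})

test_that("the pre/post pipeline recovers the defect and survives drift", {
  # null-surgery control
  h0 <- make_pair(0, seed = 21L)
  r0 <- suppressWarnings(quantify_pre_post(h0$pair$pre, h0$pair$post, h0$roi,
                                           keep_region = h0$keep))
  expect_lt(r0$relative_pct, 0.5)

  # 5% plug under the study's noise, drift and pose conditions
  h5 <- make_pair(5, seed = 22L)
  r5 <- quantify_pre_post(h5$pair$pre, h5$pair$post, h5$roi,
                          keep_region = h5$keep)
  expect_lt(abs(r5$relative_pct - h5$pair$truth$relative_pct), 1)
  expect_s3_class(r5, "canal_defect_result")
  expect_equal(r5$defect_mm3,
               r5$defect_count * voxel_volume(h5$pair$pre), tolerance = 1e-9)
  # a voxel cannot be both defect and fluid-after
  expect_equal(sum(r5$masks$defect$data & r5$masks$post$data), 0)
  # defect lies inside the preoperative mask
  expect_true(all(r5$masks$pre$data[r5$masks$defect$data == 1] == 1))

  # intensity drift alone must not create a phantom defect
  ph <- generate_labyrinth(phantom_spec(seed = 23L))
  drifted <- simulate_scan(ph$volume, gain = 1.3, offset = 20)
  rd <- suppressWarnings(quantify_pre_post(ph$volume, drifted, labyrinth_roi(ph),
                                           keep_region = plug_keep_region(ph)))
  expect_lt(rd$relative_pct, 0.5)
})

test_that("mixed voxel spacings are harmonized toward the finer grid", {
  h <- make_pair(5, seed = 24L)
  post_coarse <- resample_to_spacing(h$pair$post, 0.7)
  r <- quantify_pre_post(h$pair$pre, post_coarse, h$roi, keep_region = h$keep)
  # looser bound: the 0.7 mm scan genuinely carries less boundary detail
  expect_lt(abs(r$relative_pct - h$pair$truth$relative_pct), 1.5)
  expect_error(quantify_pre_post(h$pair$pre, h$pair$post, h$roi,
                                 params = list(bogus = 1)), "unknown")
})

test_that("contralateral mode mirrors, aligns and flags swapped sides", {
  spb <- phantom_spec(bilateral = TRUE, seed = 31L)
  phb <- generate_labyrinth(spb)
  pose <- rigid_transform(spb$pose$angles_deg, spb$pose$translation_mm)

  # healthy symmetry control: no plug, defect < 1%
  post0 <- simulate_scan(new_volume(phb$clean, spacing = spb$spacing, lr_axis = 1L),
                         gain = 1.1, offset = 10, pose = pose,
                         noise_sd = spb$noise_sd, seed = 32L)
  rc0 <- suppressWarnings(
    quantify_contralateral(post0, "right", labyrinth_roi(phb, "operated"),
                           keep_region = plug_keep_region(phb)))
  expect_lt(rc0$relative_pct, 1)

  # 5% plug recovered within 1.5 points
  spb$plug$extent_deg <- plug_extent_for_fraction(phb, 5)
  phb2 <- generate_labyrinth(spb)
  plb <- apply_plug(phb2)
  post5 <- simulate_scan(new_volume(plb$post_clean, spacing = spb$spacing,
                                    lr_axis = 1L),
                         gain = 1.1, offset = 10, pose = pose,
                         noise_sd = spb$noise_sd, seed = 33L)
  rc5 <- quantify_contralateral(post5, "right", labyrinth_roi(phb2, "operated"),
                                keep_region = plug_keep_region(phb2))
  expect_lt(abs(rc5$relative_pct - plb$relative_pct), 1.5)
  expect_false(rc5$provenance$negative_change_warning)

  # plug on the "healthy" side by mistake: ~0 and a negative-volume warning
  roi_mirror <- labyrinth_roi(phb2, "contralateral")
  w <- testthat::capture_warnings(
    rcs <- quantify_contralateral(post5, "left", roi_mirror,
                                  keep_region = NULL))
  expect_true(any(grepl("more fluid", w)))
  expect_lt(rcs$relative_pct, 1)
  expect_true(rcs$provenance$negative_change_warning)
  expect_error(quantify_contralateral(post5, "up", roi_mirror), "left")
})

test_that("cohort summaries report with and without zero-change cases", {
  fake <- function(pct) structure(list(relative_pct = pct),
                                  class = "canal_defect_result")
  s <- summarize_cohort(list(fake(0), fake(4), fake(6)))
  expect_equal(s$mean_pct[s$subset == "all"], 10 / 3, tolerance = 1e-12)
  expect_equal(s$mean_pct[s$subset == "nonzero"], 5)
  expect_equal(s$n, c(3L, 2L))
})
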