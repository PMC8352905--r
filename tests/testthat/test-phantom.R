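test_that("noiseless binary voxelization gives exactly two intensities", {
  ph <- generate_labyrinth(phantom_spec(noise_sd = 0, partial_volume = FALSE))
  expect_true(all(ph$volume$data[ph$mask$data == 1] == 100))
  expect_true(all(ph$volume$data[ph$mask$data == 0] == 10))
  # single connected labyrinth
  lab <- canalvol:::c_label_components(array(as.integer(ph$mask$data),
                                             dim(ph$mask$data)),
                                       dim(ph$mask$data), 26L)
  expect_equal(attr(lab, "n_components"), 1L)
})

test_that("a single torus canal matches the analytic torus volume", {
  ph <- generate_labyrinth(single_torus_spec(R = 3.2, r = 0.6))
  expect_lt(abs(mask_volume_mm3(ph$mask) / (2 * pi^2 * 3.2 * 0.6^2) - 1), 0.05)
})

test_that("generation is deterministic under the seed", {
  a <- generate_labyrinth(phantom_spec(seed = 7L))
  b <- generate_labyrinth(phantom_spec(seed = 7L))
  c_ <- generate_labyrinth(phantom_spec(seed = 8L))
  expect_identical(a$volume$data, b$volume$data)
  expect_false(identical(a$volume$data, c_$volume$data))
  # and the seeding does not disturb the caller's RNG stream
  set.seed(42); x1 <- rnorm(3)
  set.seed(42); invisible(generate_labyrinth(phantom_spec(dims = c(24L, 24L, 24L),
                                                          canals = list(
    sc = list(R = 1.6, r = 0.4, normal = c(1, 1, 0) / sqrt(2), center = c(0, 0, 0.8))),
    vestibule = list(center = c(0, 0, -0.5), semi = c(0.8, 0.7, 0.6)),
    cochlea = list(center = c(0, -0.9, -0.5), semi = c(0.6, 0.5, 0.5)),
    ampulla_radius = 0.3)))
  x2 <- rnorm(3)
  expect_identical(x1, x2)
})

test_that("plugs remove exactly the arc and report the exact truth", {
  sp <- single_torus_spec(noise_sd = 2)
  ph <- generate_labyrinth(sp)

  # null plug: post identical to pre up to its own fresh noise seed
  pl0 <- apply_plug(ph, list(canal = "sc", center_deg = 90, extent_deg = 0))
  expect_equal(sum(pl0$defect$data), 0)
  expect_equal(pl0$relative_pct, 0)
  expect_identical(pl0$post_clean, ph$clean)

  # full-arc plug removes the canal's entire voxel census
  pl_full <- apply_plug(ph, list(canal = "sc", center_deg = 90,
                                 extent_deg = 360 - 1e-9))
  canal_count <- sum(ph$labels == 1L & ph$mask$data == 1)
  expect_equal(sum(pl_full$defect$data), canal_count)

  # 60-degree arc: the removed set equals an independently computed
  # angle-fraction oracle over the voxel centerline angles, and sits near
  # one sixth of the torus (voxelization of a 1.2 mm tube on a 0.35 mm
  # grid is orientation-dependent, so the fraction is only approximate)
  pl60 <- apply_plug(ph, list(canal = "sc", center_deg = 90, extent_deg = 60))
  spx <- ph$spec
  n <- c(1, 1, 0) / sqrt(2)
  e <- c(0, 0, 1)
  u <- c(e[2] * n[3] - e[3] * n[2], e[3] * n[1] - e[1] * n[3],
         e[1] * n[2] - e[2] * n[1]); u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2], n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  dir90 <- u * cos(pi / 2) + v * sin(pi / 2)   # plug-center direction
  d <- dim(ph$mask$data)
  idx <- which(ph$labels == 1L & ph$mask$data == 1)
  ijk <- arrayInd(idx, d) - 1
  P <- sweep(sweep(ijk, 2, (d - 1) / 2), 2, spx$spacing, "*")
  q <- sweep(P, 2, spx$canals$sc$center)
  q_in <- q - (q %*% n) %*% t(n)
  cosang <- (q_in %*% dir90) / sqrt(rowSums(q_in^2))
  oracle <- idx[cosang >= cos(30 * pi / 180)]
  expect_setequal(which(pl60$defect$data == 1), oracle)
  expect_lt(abs(sum(pl60$defect$data) / (canal_count / 6) - 1), 0.10)

  # defect never exceeds the fluid mask
  expect_true(all(ph$mask$data[pl60$defect$data == 1] == 1))

  expect_error(apply_plug(ph, list(canal = "nope", center_deg = 0, extent_deg = 10)),
               "unknown plug canal")
  expect_error(apply_plug(ph, list(canal = "sc", center_deg = 0, extent_deg = 400)),
               "extent")
})

test_that("true relative defect grows monotonically with plug extent", {
  ph <- generate_labyrinth(phantom_spec(noise_sd = 0))
  pct <- vapply(c(0, 20, 60, 120, 200, 300), function(e)
    apply_plug(ph, list(canal = "sc", center_deg = 90, extent_deg = e))$relative_pct,
    0)
  expect_true(all(diff(pct) >= 0))
  expect_gt(pct[6], pct[2])
})

test_that("plug_extent_for_fraction inverts the voxel-count truth", {
  ph <- generate_labyrinth(phantom_spec(noise_sd = 0))
  for (target in c(2, 5, 9)) {
    ext <- plug_extent_for_fraction(ph, target)
    got <- apply_plug(ph, list(canal = "sc", center_deg = 90,
                               extent_deg = ext))$relative_pct
    expect_lt(abs(got - target), 0.35)  # one voxel-step granularity
  }
  expect_equal(plug_extent_for_fraction(ph, 0), 0)
  expect_error(plug_extent_for_fraction(ph, 90), "exceeds")
})

test_that("simulated repeat scans apply drift, pose and noise as declared", {
  ph <- generate_labyrinth(single_torus_spec(noise_sd = 0))
  v <- ph$volume
  expect_identical(simulate_scan(v)$data, v$data)
  s2 <- simulate_scan(v, gain = 1.2, offset = 15)
  expect_equal(s2$data, 1.2 * v$data + 15, tolerance = 1e-12)
  expect_error(simulate_scan(v, gain = 0), "gain")

  # a 5-degree pose preserves the fluid volume within 3% after
  # nearest-neighbour mask transport
  pose <- rigid_transform(c(5, 0, 0), c(0.4, -0.2, 0.3))
  m_moved <- apply_transform(ph$mask, pose, mode = "nearest", fixed_grid = ph$mask)
  expect_lt(abs(sum(m_moved$data) / sum(ph$mask$data) - 1), 0.03)

  # noise is seeded
  a <- simulate_scan(v, noise_sd = 3, seed = 5L)
  b <- simulate_scan(v, noise_sd = 3, seed = 5L)
  expect_identical(a$data, b$data)
})

test_that("bilateral phantoms are mirror-symmetric in the noiseless channel", {
  ph <- generate_labyrinth(phantom_spec(bilateral = TRUE, noise_sd = 0))
  expect_identical(mirror_lr(ph$volume)$data, ph$volume$data)
  expect_identical(mirror_lr(ph$mask)$data, ph$mask$data)
  # both labyrinths present: labels on both sides of the midline
  expect_gt(sum(ph$labels > 10L), 0)
  expect_gt(sum(ph$labels > 0L & ph$labels <= 10L), 0)
})

test_that("invalid specs are rejected", {
  expect_error(phantom_spec(canals = list(sc = list(R = 0.5, r = 0.6,
                                                    normal = c(1, 0, 0),
                                                    center = c(0, 0, 0)))),
               "tube radius")
  expect_error(phantom_spec(plug = list(canal = "sc", center_deg = 0,
                                        extent_deg = 360)), "extent")
  expect_error(generate_labyrinth(phantom_spec(dims = c(24L, 24L, 24L))),
               "exceed")
})

test_that("phantom pairs serialize with a faithful ground-truth sidecar", {
  sp <- phantom_spec(seed = 11L)
  ph0 <- generate_labyrinth(sp)
  sp$plug$extent_deg <- plug_extent_for_fraction(ph0, 5)
  pair <- phantom_pair(sp)
  d <- tempfile()
  write_phantom_pair(pair, d)
  expect_true(all(file.exists(file.path(d, c("pre.nii.gz", "post.nii.gz",
                                             "fluid_mask.nii.gz",
                                             "defect_mask.nii.gz",
                                             "truth.json")))))
  truth <- jsonlite::read_json(file.path(d, "truth.json"))
  expect_equal(truth$relative_defect_pct, pair$truth$relative_pct,
               tolerance = 1e-12)
  expect_equal(truth$fluid_volume_mm3,
               mask_volume_mm3(pair$truth$fluid_mask), tolerance = 1e-9)
  # spec files round-trip; unknown keys are rejected
  sf <- tempfile(fileext = ".json")
  jsonlite::write_json(list(seed = 3, noise_sd = 2), sf, auto_unbox = TRUE)
  sp2 <- phantom_spec_from_file(sf)
  expect_equal(sp2$seed, 3L)
  expect_equal(sp2$noise_sd, 2)
  jsonlite::write_json(list(bogus_key = 1), sf, auto_unbox = TRUE)
  expect_error(phantom_spec_from_file(sf), "unknown")
})
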