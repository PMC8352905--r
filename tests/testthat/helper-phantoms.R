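# Shared fixtures, all generated in code.

# A single-torus phantom: the other structures are shrunk and submerged
# inside the tube so the canal's voxel census is uncontaminated.
single_torus_spec <- function(R = 3.2, r = 0.6, noise_sd = 0,
                              partial_volume = TRUE, seed = 1L) {
  on_circle <- function(th) {
    u <- c(-1, 1, 0) / sqrt(2); v <- c(0, 0, 1)
    c(0, 0, 2.4) + R * (u * cos(th) + v * sin(th))
  }
  phantom_spec(noise_sd = noise_sd, partial_volume = partial_volume, seed = seed,
               canals = list(sc = list(R = R, r = r,
                                       normal = c(1, 1, 0) / sqrt(2),
                                       center = c(0, 0, 2.4))),
               vestibule = list(center = on_circle(0.3), semi = rep(r / 2, 3)),
               cochlea = list(center = on_circle(1.1), semi = rep(r / 2, 3)),
               ampulla_radius = r / 3)
}

# A volume-dominated (thick-structure) phantom for band-limited resampling
# properties; thin 1.2 mm tubes are boundary-dominated and excluded here.
fat_spec <- function(noise_sd = 0, seed = 1L) {
  phantom_spec(noise_sd = noise_sd, seed = seed,
               canals = list(sc = list(R = 3.2, r = 1.2, normal = c(1, 1, 0) / sqrt(2),
                                       center = c(0, 0, 2.4)),
                             pc = list(R = 3.0, r = 1.1, normal = c(1, -1, 0) / sqrt(2),
                                       center = c(0, 0, 2.2)),
                             lc = list(R = 2.8, r = 1.0, normal = c(0, 0, 1),
                                       center = c(0, 1.2, 0.6))),
               vestibule = list(center = c(0, 0, 0), semi = c(3.0, 2.4, 2.2)))
}

# End-to-end helper: phantom pair with a plug sized to a target true
# relative defect, plus the analysis regions.
make_pair <- function(target_pct, seed = 1L, ...) {
  sp <- phantom_spec(seed = seed, ...)
  ph0 <- generate_labyrinth(sp)
  sp$plug$extent_deg <- plug_extent_for_fraction(ph0, target_pct)
  pair <- phantom_pair(sp)
  list(pair = pair, roi = labyrinth_roi(pair$phantom),
       keep = plug_keep_region(pair$phantom))
}

# Independent brute-force Otsu oracle: direct per-candidate class sums over
# the raw sample, no cumulative-sum shortcuts.
otsu_bruteforce <- function(x, nbins = 256L) {
  r <- range(x)
  edges <- seq(r[1], r[2], length.out = nbins + 1L)
  best <- -Inf; best_k <- NA_integer_
  for (k in 1:(nbins - 1L)) {
    thr <- edges[k + 1L]
    # class membership by bin, matching equal-width binning of the sample
    b <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
    lo <- b <= k
    w0 <- mean(lo); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mids <- (edges[-1] + edges[-(nbins + 1L)]) / 2
    mu0 <- mean(mids[b[lo]]); mu1 <- mean(mids[b[!lo]])
    s <- w0 * w1 * (mu0 - mu1)^2
    if (s > best + 1e-15) { best <- s; best_k <- k }
  }
  list(bin_index = best_k, threshold = edges[best_k + 1L], between_var = best)
}

expect_same_grid_mask <- function(a, b) {
  expect_identical(dim(a$data), dim(b$data))
  expect_identical(a$data, b$data)
}
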