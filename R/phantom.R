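# Synthetic labyrinth phantoms: a parametric inner ear (three torus-shell
# semicircular canals joined to a vestibule ellipsoid, a cochlea blob and an
# ampulla marker sphere) voxelized on a T2-like grid, with exactly known
# fluid masks and plug-defect ground truth. Structure ids: 1 sc, 2 pc,
# 3 lc, 4 vestibule, 5 cochlea, 6 ampulla; +10 for the mirrored
# (contralateral) labyrinth of a bilateral phantom.

#' Parametric description of a synthetic labyrinth scan pair
#'
#' Geometry defaults give a labyrinth-like (not anatomically exact) inner
#' ear: superior and posterior canals in vertical planes at +/-45 degrees to
#' the sagittal plane, a lateral canal in a near-axial plane, all joined to
#' a vestibule ellipsoid. Scan-simulation defaults emulate the study
#' conditions of a heavily T2-weighted pre/post pair: 0.35 mm isotropic
#' voxels, additive Gaussian noise at 5% of the fluid-background contrast,
#' inter-scan intensity drift of gain 1.1 / offset 10, and a 3 degree pose
#' change.
#'
#' @param dims grid dimensions (voxels); bilateral phantoms widen the
#'   left-right axis automatically if left at the default.
#' @param spacing voxel size in mm.
#' @param fluid,background fluid and background intensities.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param drift named vector `c(gain=, offset=)` applied to the post scan.
#' @param pose list with `angles_deg` and `translation_mm` applied to the
#'   post scan.
#' @param plug list: `canal` ("sc", "pc" or "lc"), `center_deg`, `extent_deg`
#'   in [0, 360). The default plug site (90 degrees) is the canal apex, the
#'   arcuate-eminence-like position.
#' @param bilateral mirror a second labyrinth across the mid-sagittal plane.
#' @param partial_volume approximate partial-volume averaging by 3x
#'   supersampled occupancy at the fluid boundary (set FALSE for exact
#'   binary voxelization).
#' @param seed integer; the same seed and spec give bit-identical output.
#' @param canals,vestibule,cochlea,ampulla_radius,lateral_offset_mm advanced
#'   geometry overrides (see source for the parameterization).
#' @return an object of class `canal_phantom_spec`.
#' @export
phantom_spec <- function(dims = c(64L, 64L, 64L), spacing = c(0.35, 0.35, 0.35),
                         fluid = 100, background = 10, noise_sd = 4.5,
                         drift = c(gain = 1.1, offset = 10),
                         pose = list(angles_deg = c(3, 0, 0),
                                     translation_mm = c(1, -0.7, 0.5)),
                         plug = list(canal = "sc", center_deg = 90,
                                     extent_deg = 0),
                         bilateral = FALSE, partial_volume = TRUE, seed = 1L,
                         canals = NULL, vestibule = NULL, cochlea = NULL,
                         ampulla_radius = 0.8, lateral_offset_mm = 7) {
  if (is.null(canals)) canals <- list(
    sc = list(R = 3.2, r = 0.60, normal = c(1, 1, 0) / sqrt(2), center = c(0, 0, 2.4)),
    pc = list(R = 3.0, r = 0.55, normal = c(1, -1, 0) / sqrt(2), center = c(0, 0, 2.2)),
    lc = list(R = 2.8, r = 0.50, normal = c(0, 0, 1), center = c(0, 1.2, 0.6)))
  if (is.null(vestibule)) vestibule <- list(center = c(0, 0, 0), semi = c(2.4, 1.8, 1.6))
  if (is.null(cochlea)) cochlea <- list(center = c(0, -2.2, -1.0), semi = c(1.6, 1.5, 1.2))
  for (cn in canals) {
    if (any(c(cn$R, cn$r) <= 0)) stop("canal radii must be positive")
    if (cn$r >= cn$R) stop("tube radius must be smaller than the canal radius")
  }
  if (plug$extent_deg < 0 || plug$extent_deg >= 360)
    stop("plug angular extent must lie in [0, 360)")
  if (!plug$canal %in% names(canals)) stop("unknown plug canal id: ", plug$canal)
  if (bilateral && identical(dims, c(64L, 64L, 64L))) dims <- c(96L, 64L, 64L)
  structure(list(dims = as.integer(dims), spacing = as.numeric(spacing),
                 fluid = fluid, background = background, noise_sd = noise_sd,
                 drift = drift, pose = pose, plug = plug,
                 bilateral = bilateral, partial_volume = partial_volume,
                 seed = as.integer(seed), canals = canals,
                 vestibule = vestibule, cochlea = cochlea,
                 ampulla_radius = ampulla_radius,
                 lateral_offset_mm = lateral_offset_mm),
            class = "canal_phantom_spec")
}

# In-plane basis (u, v) for a canal; angle 0 along u, 90 degrees along v.
canal_basis <- function(normal) {
  n <- normal / sqrt(sum(normal^2))
  e <- if (abs(n[3]) > 0.9) c(1, 0, 0) else c(0, 0, 1)
  u <- c(e[2] * n[3] - e[3] * n[2], e[3] * n[1] - e[1] * n[3],
         e[1] * n[2] - e[2] * n[1])
  u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2], n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  list(n = n, u = u, v = v)
}

# Point on a canal centerline at angle theta (degrees), labyrinth at L.
canal_point <- function(spec, canal, theta_deg, L = c(0, 0, 0)) {
  cn <- spec$canals[[canal]]
  b <- canal_basis(cn$normal)
  th <- theta_deg * pi / 180
  L + cn$center + cn$R * (b$u * cos(th) + b$v * sin(th))
}

# Signed distances (negative inside) from points P (n x 3) to the fluid
# structures of one labyrinth centered at L. Returns n x 6 matrix.
labyrinth_sdf <- function(spec, P, L = c(0, 0, 0)) {
  n <- nrow(P)
  out <- matrix(0, n, 6)
  j <- 0
  for (cn in spec$canals) {
    j <- j + 1
    b <- canal_basis(cn$normal)
    C <- L + cn$center
    qx <- P[, 1] - C[1]; qy <- P[, 2] - C[2]; qz <- P[, 3] - C[3]
    qn <- qx * b$n[1] + qy * b$n[2] + qz * b$n[3]
    px <- qx - qn * b$n[1]; py <- qy - qn * b$n[2]; pz <- qz - qn * b$n[3]
    rp <- sqrt(px * px + py * py + pz * pz)
    out[, j] <- sqrt((rp - cn$R)^2 + qn * qn) - cn$r
  }
  for (el in list(spec$vestibule, spec$cochlea)) {
    j <- j + 1
    C <- L + el$center; s <- el$semi
    qx <- (P[, 1] - C[1]) / s[1]; qy <- (P[, 2] - C[2]) / s[2]
    qz <- (P[, 3] - C[3]) / s[3]
    out[, j] <- (sqrt(qx * qx + qy * qy + qz * qz) - 1) * min(s)
  }
  A <- ampulla_center(spec, L)
  out[, 6] <- sqrt((P[, 1] - A[1])^2 + (P[, 2] - A[2])^2 + (P[, 3] - A[3])^2) -
    spec$ampulla_radius
  out
}

# Ampulla marker: on the superior canal centerline just before its anterior
# junction with the vestibule; common crus on the opposite side.
AMPULLA_DEG <- 250
COMMON_CRUS_DEG <- 290
ampulla_center <- function(spec, L = c(0, 0, 0)) canal_point(spec, "sc", AMPULLA_DEG, L)

# Evaluate with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

# World coordinates of all voxel centers for a centered axis-aligned grid.
grid_coords <- function(spec) {
  d <- spec$dims; sp <- spec$spacing
  ax <- lapply(1:3, function(a) (0:(d[a] - 1) - (d[a] - 1) / 2) * sp[a])
  list(x = rep(ax[[1]], times = d[2] * d[3]),
       y = rep(rep(ax[[2]], each = d[1]), times = d[3]),
       z = rep(ax[[3]], each = d[1] * d[2]))
}

#' Generate a synthetic labyrinth scan with exact ground truth
#'
#' Builds the noiseless fluid field (intensity `background` outside,
#' `fluid` inside, with supersampled partial-volume fractions at the
#' boundary when `partial_volume` is on), adds seeded Gaussian noise, and
#' records the exact fluid mask (occupancy >= 0.5), per-voxel structure
#' labels and landmark world coordinates. Bilateral phantoms mirror the
#' labyrinth across the mid-sagittal plane by array reflection, so the
#' noiseless channel is mirror-symmetric bit-exactly.
#'
#' @param spec a `canal_phantom_spec`.
#' @return an object of class `canal_phantom`: `volume` (noisy scan),
#'   `mask` (true fluid mask), `labels` (integer array), `occ` (occupancy),
#'   `clean` (noiseless array), `landmarks`, `spec`.
#' @export
generate_labyrinth <- function(spec) {
  d <- spec$dims; sp <- spec$spacing
  half_extent <- (d - 1) * sp / 2
  L <- if (spec$bilateral) c(spec$lateral_offset_mm, 0, 0) else c(0, 0, 0)
  reach <- max(vapply(spec$canals, function(cn) {
    sqrt(sum(cn$center^2)) + cn$R + cn$r
  }, 0), sqrt(sum(spec$vestibule$center^2)) + max(spec$vestibule$semi),
  sqrt(sum(spec$cochlea$center^2)) + max(spec$cochlea$semi))
  if (any(abs(L) + reach > half_extent))
    stop("labyrinth structures exceed the grid extent; enlarge dims")

  g <- grid_coords(spec)
  P <- cbind(g$x, g$y, g$z)
  sdf <- labyrinth_sdf(spec, P, L)
  fsd <- do.call(pmin, as.data.frame(sdf))
  lab <- max.col(-sdf, ties.method = "first")

  band <- 0.7 * max(sp)
  occ <- as.numeric(fsd < 0)
  if (spec$partial_volume) {
    bidx <- which(abs(fsd) <= band)
    if (length(bidx)) {
      offs <- as.matrix(expand.grid(dx = c(-1, 0, 1) / 3 * sp[1],
                                    dy = c(-1, 0, 1) / 3 * sp[2],
                                    dz = c(-1, 0, 1) / 3 * sp[3]))
      acc <- numeric(length(bidx))
      Pb <- P[bidx, , drop = FALSE]
      for (o in seq_len(nrow(offs))) {
        Po <- sweep(Pb, 2, offs[o, ], "+")
        so <- labyrinth_sdf(spec, Po, L)
        acc <- acc + (do.call(pmin, as.data.frame(so)) < 0)
      }
      occ[bidx] <- acc / nrow(offs)
    }
  }
  lab[occ <= 0] <- 0L

  occ_a <- array(occ, d); lab_a <- array(lab, d)
  if (spec$bilateral) {
    flip <- function(a) a[rev(seq_len(d[1])), , , drop = FALSE]
    occ_m <- flip(occ_a)
    lab_m <- flip(lab_a)
    lab_a <- ifelse(occ_m > occ_a & lab_m > 0L, lab_m + 10L, lab_a)
    lab_a[lab_a == 0L & lab_m > 0L & occ_m > 0] <- lab_m[lab_a == 0L & lab_m > 0L & occ_m > 0] + 10L
    occ_a <- pmax(occ_a, occ_m)
  }

  clean <- spec$background + (spec$fluid - spec$background) * occ_a
  noisy <- if (spec$noise_sd > 0) {
    clean + with_seed(spec$seed,
                      array(stats::rnorm(prod(d), 0, spec$noise_sd), d))
  } else clean
  vol <- new_volume(noisy, spacing = sp, lr_axis = 1L)
  mask <- new_mask(occ_a >= 0.5, vol)

  landmarks <- list(ampulla = ampulla_center(spec, L),
                    common_crus = canal_point(spec, "sc", COMMON_CRUS_DEG, L))
  if (spec$bilateral) {
    mir <- function(p) c(-p[1], p[2], p[3])
    landmarks$ampulla_contralateral <- mir(landmarks$ampulla)
    landmarks$common_crus_contralateral <- mir(landmarks$common_crus)
  }
  structure(list(volume = vol, mask = mask, labels = lab_a, occ = occ_a,
                 clean = clean, landmarks = landmarks, spec = spec),
            class = "canal_phantom")
}

# Angular position (degrees, in [0, 360)) of points around a canal's
# centerline; angular distance to a reference angle.
canal_angle_deg <- function(spec, canal, P, L = c(0, 0, 0)) {
  cn <- spec$canals[[canal]]
  b <- canal_basis(cn$normal)
  C <- L + cn$center
  qx <- P[, 1] - C[1]; qy <- P[, 2] - C[2]; qz <- P[, 3] - C[3]
  au <- qx * b$u[1] + qy * b$u[2] + qz * b$u[3]
  av <- qx * b$v[1] + qy * b$v[2] + qz * b$v[3]
  (atan2(av, au) * 180 / pi) %% 360
}

ang_dist <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Apply a surgical plug to a phantom
#'
#' Sets the canal-fluid voxels whose centerline angle falls inside the plug
#' arc to background intensity in the post volume; the exact removed mask
#' voxels are the true filling defect. The true relative defect is the
#' removed voxel count over the operated labyrinth's total fluid count.
#'
#' @param phantom a `canal_phantom`.
#' @param plug plug description (default: the phantom spec's); list with
#'   `canal`, `center_deg`, `extent_deg`.
#' @return list: `post` (plugged scan with fresh seeded noise), `defect`
#'   (true defect `canal_mask`), `relative_pct`, `post_clean` (noiseless
#'   plugged array), `ampulla_involved`.
#' @export
apply_plug <- function(phantom, plug = phantom$spec$plug) {
  spec <- phantom$spec
  if (!plug$canal %in% names(spec$canals))
    stop("unknown plug canal id: ", plug$canal)
  if (plug$extent_deg < 0 || plug$extent_deg >= 360)
    stop("plug angular extent must lie in [0, 360)")
  d <- spec$dims
  L <- if (spec$bilateral) c(spec$lateral_offset_mm, 0, 0) else c(0, 0, 0)
  cid <- match(plug$canal, names(spec$canals))
  side_total <- sum(phantom$mask$data != 0 & phantom$labels <= 10L)

  defect <- array(FALSE, d)
  post_clean <- phantom$clean
  ampulla_involved <- FALSE
  if (plug$extent_deg > 0) {
    idx <- which(phantom$labels == cid & phantom$occ > 0)
    g <- grid_coords(spec)
    P <- cbind(g$x[idx], g$y[idx], g$z[idx])
    th <- canal_angle_deg(spec, plug$canal, P, L)
    # tiny slop so a (360 - eps)-degree plug covers the antipodal voxels too
    inarc <- ang_dist(th, plug$center_deg) <= plug$extent_deg / 2 + 1e-9
    rm_idx <- idx[inarc]
    post_clean[rm_idx] <- spec$background
    defect[rm_idx] <- phantom$mask$data[rm_idx] != 0
    amp_half_angle <- (spec$ampulla_radius / spec$canals[[plug$canal]]$R) * 180 / pi
    ampulla_involved <- plug$canal == "sc" &&
      ang_dist(AMPULLA_DEG, plug$center_deg) <= plug$extent_deg / 2 + amp_half_angle
  }
  post <- if (spec$noise_sd > 0) {
    post_clean + with_seed(spec$seed + 1L,
                           array(stats::rnorm(prod(d), 0, spec$noise_sd), d))
  } else post_clean
  list(post = new_volume(post, spacing = spec$spacing, lr_axis = 1L),
       defect = new_mask(defect, phantom$volume),
       relative_pct = 100 * sum(defect) / side_total,
       post_clean = post_clean,
       ampulla_involved = ampulla_involved)
}

#' Simulate a repeat scan: intensity drift, pose change, fresh noise
#'
#' Maps intensities through `gain * x + offset`, resamples the volume under
#' the rigid pose (trilinear, out-of-field filled with the drifted
#' background mode), and adds seeded Gaussian noise.
#'
#' @param v a `canal_volume`.
#' @param gain,offset intensity drift (gain > 0).
#' @param pose a `canal_transform` moving the content (NULL for none).
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed integer noise seed.
#' @return the simulated `canal_volume` on `v`'s grid.
#' @export
simulate_scan <- function(v, gain = 1, offset = 0, pose = NULL, noise_sd = 0,
                          seed = 1L) {
  if (gain <= 0) stop("gain must be > 0")
  out <- v
  out$data <- gain * v$data + offset
  if (!is.null(pose)) {
    ident <- max(abs(pose$angles_deg)) < 1e-12 &&
      max(abs(pose$translation)) < 1e-12
    if (!ident) out <- apply_transform(out, pose, mode = "trilinear",
                                       fixed_grid = out)
  }
  if (noise_sd > 0)
    out$data <- out$data +
      with_seed(seed, array(stats::rnorm(length(out$data), 0, noise_sd),
                            dim(out$data)))
  out
}

#' Generate a complete pre/post phantom scan pair with ground truth
#'
#' Convenience wrapper: generates the labyrinth, applies the plug, and
#' simulates the post scan with the spec's intensity drift, pose change and
#' fresh noise.
#'
#' @param spec a `canal_phantom_spec`.
#' @return an object of class `canal_phantom_pair`: `pre`, `post`
#'   (`canal_volume`s), `phantom` (the `canal_phantom`), and `truth` with
#'   `fluid_mask`, `defect_mask`, `relative_pct`, `pose`
#'   (a `canal_transform` mapping pre world coordinates to post),
#'   `landmarks`, `ampulla_involved`, `seed`.
#' @export
phantom_pair <- function(spec = phantom_spec()) {
  ph <- generate_labyrinth(spec)
  pl <- apply_plug(ph)
  pose <- rigid_transform(spec$pose$angles_deg, spec$pose$translation_mm,
                          center_mm = c(0, 0, 0))
  post <- simulate_scan(new_volume(pl$post_clean, spacing = spec$spacing,
                                   lr_axis = 1L),
                        gain = unname(spec$drift["gain"]),
                        offset = unname(spec$drift["offset"]),
                        pose = pose, noise_sd = spec$noise_sd,
                        seed = spec$seed + 2L)
  structure(list(pre = ph$volume, post = post, phantom = ph,
                 truth = list(fluid_mask = ph$mask, defect_mask = pl$defect,
                              relative_pct = pl$relative_pct, pose = pose,
                              landmarks = ph$landmarks,
                              ampulla_involved = pl$ampulla_involved,
                              seed = spec$seed)),
            class = "canal_phantom_pair")
}

#' Plug extent achieving a target true relative defect
#'
#' Inverts the exact voxel-count truth: returns the angular extent whose
#' plug removes the number of canal voxels closest to `target_pct` percent
#' of the operated labyrinth's fluid volume.
#'
#' @param phantom a `canal_phantom`.
#' @param target_pct desired true relative defect (percent).
#' @param canal canal id (default the spec's plug canal).
#' @param center_deg plug center angle.
#' @return angular extent in degrees.
#' @export
plug_extent_for_fraction <- function(phantom, target_pct,
                                     canal = phantom$spec$plug$canal,
                                     center_deg = phantom$spec$plug$center_deg) {
  if (target_pct <= 0) return(0)
  spec <- phantom$spec
  L <- if (spec$bilateral) c(spec$lateral_offset_mm, 0, 0) else c(0, 0, 0)
  cid <- match(canal, names(spec$canals))
  total <- sum(phantom$mask$data != 0 & phantom$labels <= 10L)
  idx <- which(phantom$labels == cid & phantom$mask$data != 0)
  g <- grid_coords(spec)
  P <- cbind(g$x[idx], g$y[idx], g$z[idx])
  dists <- sort(ang_dist(canal_angle_deg(spec, canal, P, L), center_deg))
  k <- round(target_pct / 100 * total)
  if (k < 1) return(0)
  if (k > length(dists))
    stop("target defect exceeds the canal's total volume")
  min(2 * dists[k] + 1e-6, 360 - 1e-6)
}

#' Keep region around the plug site
#'
#' The declarative stand-in for the manual removal of voxels outside the
#' filling-defect region: the plugged canal's tube voxels within the arc
#' (padded by a small angular margin), dilated by one voxel. A mask keep
#' region follows the canal's curvature the way a freehand edit would; an
#' axis-aligned box around a curved arc would also admit the canal's
#' continuation beyond the cut ends, where surface-mismatch shells live.
#'
#' @param phantom a `canal_phantom`.
#' @param plug plug description (default the spec's).
#' @param margin_deg angular padding of the arc (degrees). Arcs shorter
#'   than `2 * min_half_deg` use that floor so a null plug still has a
#'   plausible inspection region.
#' @param min_half_deg minimum arc half-width of the region.
#' @return a `canal_mask` on the phantom's grid.
#' @export
plug_keep_region <- function(phantom, plug = phantom$spec$plug,
                             margin_deg = 5, min_half_deg = 20) {
  spec <- phantom$spec
  L <- if (spec$bilateral) c(spec$lateral_offset_mm, 0, 0) else c(0, 0, 0)
  cid <- match(plug$canal, names(spec$canals))
  idx <- which(phantom$labels == cid & phantom$occ > 0)
  g <- grid_coords(spec)
  P <- cbind(g$x[idx], g$y[idx], g$z[idx])
  th <- canal_angle_deg(spec, plug$canal, P, L)
  half <- max(plug$extent_deg / 2 + margin_deg, min_half_deg)
  sel <- idx[ang_dist(th, plug$center_deg) <= half]
  arr <- array(FALSE, spec$dims)
  arr[sel] <- TRUE
  new_mask(dilate26(arr), phantom$volume)
}

#' Default segmentation ROI around one labyrinth
#'
#' @param phantom a `canal_phantom`.
#' @param side `"operated"` or `"contralateral"` (bilateral phantoms).
#' @param margin_mm padding around the labyrinth's bounding box.
#' @return a `canal_roi`.
#' @export
labyrinth_roi <- function(phantom, side = "operated", margin_mm = 2) {
  spec <- phantom$spec
  sel <- if (side == "operated") which(phantom$occ > 0 & phantom$labels <= 10L & phantom$labels > 0L)
         else which(phantom$labels > 10L)
  ijk <- arrayInd(sel, spec$dims) - 1L
  pad <- ceiling(margin_mm / spec$spacing)
  lo <- pmax(0L, as.integer(apply(ijk, 2, min) - pad))
  hi <- pmin(spec$dims, as.integer(apply(ijk, 2, max) + pad) + 1L)
  roi_box(lo, hi)
}

#' Write a phantom pair to disk
#'
#' Writes `pre.nii.gz`, `post.nii.gz`, the true fluid and defect masks, and
#' a `truth.json` sidecar with the exact volumes, landmark world
#' coordinates and seed.
#'
#' @param pair a `canal_phantom_pair`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom_pair <- function(pair, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(pair$pre, file.path(dir, "pre.nii.gz"))
  write_volume(pair$post, file.path(dir, "post.nii.gz"))
  write_volume(pair$truth$fluid_mask, file.path(dir, "fluid_mask.nii.gz"))
  write_volume(pair$truth$defect_mask, file.path(dir, "defect_mask.nii.gz"))
  vv <- voxel_volume(pair$pre)
  truth <- list(
    fluid_volume_mm3 = sum(pair$truth$fluid_mask$data) * vv,
    defect_volume_mm3 = sum(pair$truth$defect_mask$data) * vv,
    relative_defect_pct = pair$truth$relative_pct,
    pose = list(angles_deg = pair$truth$pose$angles_deg,
                translation_mm = pair$truth$pose$translation,
                center_mm = pair$truth$pose$center,
                convention = "intrinsic ZYX about center"),
    landmarks_mm = pair$truth$landmarks,
    ampulla_involved = pair$truth$ampulla_involved,
    seed = pair$truth$seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a phantom spec from a JSON or YAML file
#'
#' Unknown keys are rejected; listed keys override [phantom_spec()]
#' defaults.
#'
#' @param path path to a .json, .yaml or .yml file.
#' @return a `canal_phantom_spec`.
#' @export
phantom_spec_from_file <- function(path) {
  if (!file.exists(path)) stop("spec file not found: ", path)
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML specs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(phantom_spec))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown phantom spec keys: ", paste(bad, collapse = ", "))
  if (!is.null(vals$drift)) vals$drift <- unlist(vals$drift)
  do.call(phantom_spec, vals)
}
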