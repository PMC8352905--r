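#' Rigid 6-DOF transform
#'
#' Parameterized by intrinsic Euler angles (degrees) applied in Z-Y-X order
#' (`R = Rz(g) Ry(b) Rx(a)`), a translation in mm, and a world-space center
#' of rotation: the transform maps a world point `x` to
#' `R (x - center) + center + translation`.
#'
#' @param angles_deg rotation angles (degrees) about the world x, y, z axes.
#' @param translation_mm translation in mm.
#' @param center_mm world center of rotation (default origin).
#' @param rotation optional 3x3 rotation matrix overriding `angles_deg`.
#' @return an object of class `canal_transform`.
#' @export
rigid_transform <- function(angles_deg = c(0, 0, 0), translation_mm = c(0, 0, 0),
                            center_mm = c(0, 0, 0), rotation = NULL) {
  R <- if (is.null(rotation)) euler_to_matrix(angles_deg) else as.matrix(rotation)
  if (max(abs(crossprod(R) - diag(3))) > 1e-9 || abs(det(R) - 1) > 1e-9)
    stop("rotation must be a proper orthonormal matrix")
  structure(list(R = R, translation = as.numeric(translation_mm),
                 center = as.numeric(center_mm),
                 angles_deg = if (is.null(rotation)) as.numeric(angles_deg)
                              else matrix_to_euler(R)),
            class = "canal_transform")
}

euler_to_matrix <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

matrix_to_euler <- function(R) {
  beta <- asin(max(-1, min(1, -R[3, 1])))
  if (abs(cos(beta)) > 1e-9) {
    alpha <- atan2(R[3, 2], R[3, 3])
    gamma <- atan2(R[2, 1], R[1, 1])
  } else {  # gimbal lock
    alpha <- atan2(-R[2, 3], R[2, 2])
    gamma <- 0
  }
  c(alpha, beta, gamma) * 180 / pi
}

#' @export
print.canal_transform <- function(x, ...) {
  cat(sprintf("<canal_transform> angles (deg): %s; translation (mm): %s; center (mm): %s\n",
              paste(signif(x$angles_deg, 4), collapse = ", "),
              paste(signif(x$translation, 4), collapse = ", "),
              paste(signif(x$center, 4), collapse = ", ")))
  invisible(x)
}

#' 4x4 homogeneous world-coordinate matrix of a rigid transform
#' @param t a `canal_transform`.
#' @return 4x4 matrix `M` with `y = M %*% c(x, 1)`.
#' @export
transform_matrix <- function(t) {
  M <- diag(4)
  M[1:3, 1:3] <- t$R
  M[1:3, 4] <- t$center + t$translation - t$R %*% t$center
  M
}

transform_from_matrix <- function(M, center = c(0, 0, 0)) {
  R <- M[1:3, 1:3]
  d <- M[1:3, 4]
  rigid_transform(rotation = R,
                  translation_mm = as.numeric(d - center + R %*% center),
                  center_mm = center)
}

#' Compose two rigid transforms (`a` after `b`)
#' @param a,b `canal_transform` objects.
#' @return the transform mapping `x` to `a(b(x))`, centered at `a`'s center.
#' @export
compose_transforms <- function(a, b) {
  transform_from_matrix(transform_matrix(a) %*% transform_matrix(b), a$center)
}

#' Invert a rigid transform
#' @param t a `canal_transform`.
#' @return the inverse transform, with the same center of rotation.
#' @export
invert_transform <- function(t) {
  transform_from_matrix(solve(transform_matrix(t)), t$center)
}

#' Apply a rigid transform to world points
#' @param t a `canal_transform`.
#' @param xyz n x 3 matrix of world mm coordinates.
#' @return n x 3 matrix of transformed coordinates.
#' @export
transform_points <- function(t, xyz) {
  xyz <- matrix(xyz, ncol = 3)
  sweep(sweep(xyz, 2, t$center) %*% t(t$R), 2,
        t$center + t$translation, "+")
}

#' Resample a volume through a rigid transform onto a fixed grid
#'
#' `t` maps the moving volume's world coordinates onto the fixed grid's
#' world coordinates (the alignment direction returned by
#' [register_rigid()]); sampling pulls each fixed voxel center back through
#' the inverse.
#'
#' @param v the moving `canal_volume`.
#' @param t a `canal_transform`.
#' @param mode `"trilinear"` (intensities) or `"nearest"` (masks).
#' @param fixed_grid a `canal_volume` supplying the output grid (default:
#'   `v`'s own grid).
#' @param fill out-of-field value; default is the histogram mode of `v`
#'   (the dark background).
#' @return a `canal_volume`/`canal_mask` on the fixed grid.
#' @export
apply_transform <- function(v, t, mode = if (inherits(v, "canal_mask")) "nearest" else "trilinear",
                            fixed_grid = v, fill = NULL) {
  mode <- match.arg(mode, c("trilinear", "nearest"))
  if (is.null(fill)) fill <- if (inherits(v, "canal_mask")) 0 else histogram_mode(v)
  tinv <- invert_transform(t)
  out <- sample_on_grid(v, dims = vol_dim(fixed_grid), affine = fixed_grid$affine,
                        mode = mode, fill = fill,
                        world_map = function(xyz) transform_points(tinv, xyz))
  if (inherits(v, "canal_mask")) {
    parent <- new_volume(out, affine = fixed_grid$affine, lr_axis = fixed_grid$lr_axis)
    new_mask(out != 0, parent)
  } else new_volume(out, affine = fixed_grid$affine, lr_axis = fixed_grid$lr_axis)
}

# Block-mean downsampling by an integer factor (pyramid levels).
downsample_volume <- function(v, f) {
  if (f <= 1L) return(v)
  d <- vol_dim(v)
  d2 <- pmax(1L, d %/% f) * f
  a <- v$data[seq_len(min(d2[1], d[1])), seq_len(min(d2[2], d[2])),
              seq_len(min(d2[3], d[3])), drop = FALSE]
  dd <- dim(a) %/% f
  out <- array(0, dd)
  for (dx in 0:(f - 1)) for (dy in 0:(f - 1)) for (dz in 0:(f - 1)) {
    out <- out + a[seq(1 + dx, dd[1] * f, f), seq(1 + dy, dd[2] * f, f),
                   seq(1 + dz, dd[3] * f, f), drop = FALSE]
  }
  out <- out / f^3
  aff <- v$affine
  lin <- aff[1:3, 1:3]
  aff[1:3, 4] <- aff[1:3, 4] + lin %*% rep((f - 1) / 2, 3)
  aff[1:3, 1:3] <- lin * f
  new_volume(out, affine = aff, lr_axis = v$lr_axis)
}

# Factory for a fast NCC evaluator: caches the fixed grid's world
# coordinates and samples the moving volume through the candidate
# transform. NCC is taken over the voxels whose pull-back lands inside the
# moving field of view.
make_ncc <- function(fixed, moving, stride = 1L) {
  d <- vol_dim(fixed)
  ii <- seq(0L, d[1] - 1L, by = stride)
  jj <- seq(0L, d[2] - 1L, by = stride)
  kk <- seq(0L, d[3] - 1L, by = stride)
  g <- expand.grid(i = ii, j = jj, k = kk)
  Wh <- cbind(as.matrix(g), 1) %*% t(fixed$affine)  # n x 4 world coords
  fvals <- as.numeric(fixed$data[ii + 1L, jj + 1L, kk + 1L])
  inv_mov <- solve(moving$affine)
  mdat <- as.numeric(moving$data)
  mdim <- as.integer(vol_dim(moving))
  function(t) {
    M <- inv_mov %*% solve(transform_matrix(t))
    X <- Wh %*% t(M)
    mv <- c_sample_trilinear(mdat, mdim, X[, 1], X[, 2], X[, 3], NA_real_)
    ok <- !is.na(mv)
    if (sum(ok) < 32) return(NA_real_)
    f <- fvals[ok]; m <- mv[ok]
    if (stats::sd(f) == 0 || stats::sd(m) == 0) return(0)
    stats::cor(f, m)
  }
}

ncc_metric <- function(fixed, moving, t) make_ncc(fixed, moving)(t)

#' Rigidly register a moving volume to a fixed volume
#'
#' Maximizes the normalized cross-correlation over the overlap region with a
#' coarse-to-fine pyramid (block-mean downsampling by 2 per level) and a
#' derivative-free Nelder-Mead search over the six rigid parameters at each
#' level. NCC is invariant under gain/offset intensity drift between the
#' scans, which same-modality pre/post pairs require. Rotation is
#' parameterized about the fixed volume's field-of-view center.
#'
#' @param fixed,moving `canal_volume` objects on comparable spacings
#'   (resample first; see [resample_to_spacing()]).
#' @param init initial `canal_transform` (default identity).
#' @param levels number of pyramid levels (default 3).
#' @param maxit Nelder-Mead iteration cap per level.
#' @return the `canal_transform` mapping `moving`'s world coordinates onto
#'   `fixed`'s, with attributes `metric` (NCC at the solution) and
#'   `metric_init`. The returned metric never falls below the metric at
#'   `init`.
#' @export
register_rigid <- function(fixed, moving, init = NULL, levels = 3L, maxit = 400L) {
  center <- as.numeric(voxel_to_world(fixed, matrix((vol_dim(fixed) - 1) / 2, 1)))
  if (is.null(init)) init <- rigid_transform(center_mm = center)
  p0 <- c(init$angles_deg, init$translation)
  # re-center the initial transform on the pyramid's rotation center
  p0_t <- transform_from_matrix(transform_matrix(init), center)
  p0 <- c(p0_t$angles_deg, p0_t$translation)
  m_init <- ncc_metric(fixed, moving, p0_t)
  if (is.na(m_init))
    stop("volumes do not overlap: similarity metric undefined at the initial transform")
  par_to_t <- function(p) rigid_transform(p[1:3], p[4:6], center)
  p <- p0
  for (lev in seq(levels, 1)) {
    f <- 2^(lev - 1)
    fx <- downsample_volume(fixed, f)
    mv <- downsample_volume(moving, f)
    ncc <- make_ncc(fx, mv, stride = if (f == 1L) 2L else 1L)
    obj <- function(p) {
      v <- ncc(par_to_t(p))
      if (is.na(v)) 1 else -v
    }
    if (lev == levels) {
      # coarse capture range: exhaustive translation search around init
      steps <- seq(-6, 6, by = max(1.5, min(fx$spacing)))
      cand <- as.matrix(expand.grid(dx = steps, dy = steps, dz = steps))
      vals <- apply(cand, 1, function(dp) obj(p + c(0, 0, 0, dp)))
      p <- p + c(0, 0, 0, cand[which.min(vals), ])
    }
    scale <- if (lev > 1) c(rep(4, 3), rep(2, 3)) else c(rep(0.5, 3), rep(0.25, 3))
    opt <- stats::optim(p, obj, method = "Nelder-Mead",
                        control = list(maxit = maxit, parscale = scale,
                                       reltol = 1e-7))
    p <- opt$par
    if (lev == 1) {
      # tight-simplex restart for subvoxel refinement
      opt <- stats::optim(p, obj, method = "Nelder-Mead",
                          control = list(maxit = maxit,
                                         parscale = rep(0.08, 6),
                                         reltol = 1e-7))
      p <- opt$par
    }
  }
  best <- par_to_t(p)
  m_best <- ncc_metric(fixed, moving, best)
  if (!is.finite(m_best) || m_best < m_init) {
    warning("registration did not improve on the initial transform; returning it")
    best <- p0_t
    m_best <- m_init
  }
  if (opt$convergence != 0)
    warning("registration search hit the iteration cap; returning best-so-far")
  attr(best, "metric") <- m_best
  attr(best, "metric_init") <- m_init
  best
}

#' Mirror a volume across its mid-sagittal plane
#'
#' Reflects the volume across the mid-plane of its own field of view along
#' the subject left-right axis, used to compare the non-operated ear with
#' the operated ear when no preoperative scan exists. The reflection keeps
#' the grid and affine fixed and reverses the data, so world left-right
#' coordinates negate about the field-of-view center; applying it twice is
#' the identity, bit-exactly.
#'
#' @param v a `canal_volume` or `canal_mask` with a known `lr_axis`.
#' @return the mirrored object, same class and grid.
#' @export
mirror_lr <- function(v) {
  ax <- v$lr_axis
  if (is.null(ax) || is.na(ax))
    stop("left-right axis unknown: supply a volume with an explicit lr_axis")
  d <- vol_dim(v)
  idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  idx[[ax]] <- rev(idx[[ax]])
  out <- v
  out$data <- v$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  out
}
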