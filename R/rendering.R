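# Mask-restricted direct volume rendering: orthographic ray casting with a
# piecewise-linear RGBA transfer function and front-to-back alpha
# compositing (emission-absorption, no shading). The segmentation mask
# gates opacity so only the labyrinth contributes; intensities are zeroed
# outside the mask so pixels are bit-independent of out-of-mask voxels.

#' Piecewise-linear RGBA transfer function
#'
#' @param intensity strictly increasing control-point intensities.
#' @param rgba length(intensity) x 4 matrix of red, green, blue, alpha in
#'   [0, 1]; interpolated linearly, clamped outside the range.
#' @return an object of class `canal_tf`.
#' @export
transfer_function <- function(intensity, rgba) {
  intensity <- as.numeric(intensity)
  rgba <- matrix(rgba, ncol = 4)
  if (any(diff(intensity) <= 0))
    stop("control-point intensities must be strictly increasing")
  if (any(rgba < 0 | rgba > 1)) stop("RGBA channels must lie in [0, 1]")
  if (nrow(rgba) != length(intensity))
    stop("one RGBA row per control point required")
  structure(list(intensity = intensity, rgba = rgba), class = "canal_tf")
}

tf_eval <- function(tf, x) {
  if (length(tf$intensity) == 1L)
    return(matrix(tf$rgba[1, ], length(x), 4, byrow = TRUE))
  vapply(1:4, function(ch)
    stats::approx(tf$intensity, tf$rgba[, ch], x, rule = 2)$y,
    numeric(length(x)))
}

#' Default transfer function from the mask-restricted histogram
#'
#' An alpha ramp rising from the Otsu threshold of the in-mask intensities
#' to their maximum, in a bone-white color: a documented stand-in for the
#' expert's histogram-guided manual choice.
#'
#' @param v a `canal_volume`.
#' @param mask a `canal_mask` on `v`'s grid.
#' @param color base RGB of the rendered structure.
#' @param max_alpha per-sample opacity at the intensity maximum.
#' @return a `canal_tf`.
#' @export
default_transfer_function <- function(v, mask, color = c(0.92, 0.87, 0.76),
                                      max_alpha = 0.08) {
  x <- v$data[mask$data != 0]
  if (length(unique(x)) < 2)
    return(transfer_function(c(0, 1), rbind(c(color, max_alpha), c(color, max_alpha))))
  thr <- otsu_threshold(x)$threshold
  hi <- max(x)
  if (thr >= hi) thr <- hi - abs(hi) * 1e-6 - 1e-6
  transfer_function(c(min(x), thr, hi),
                    rbind(c(color, 0), c(color, 0), c(color, max_alpha)))
}

#' Orthographic camera for ray casting
#'
#' @param eye,lookat,up world-mm eye position, target and up vector (up must
#'   not be parallel to the view direction).
#' @param image_size pixels, `c(width, height)`.
#' @param ortho_scale world height (mm) covered by the image.
#' @param step_mm ray sampling step; default NULL picks half the smallest
#'   voxel spacing at render time.
#' @return an object of class `canal_camera`.
#' @export
camera <- function(eye, lookat = c(0, 0, 0), up = c(0, 0, 1),
                   image_size = c(160, 160), ortho_scale = 30,
                   step_mm = NULL) {
  eye <- as.numeric(eye); lookat <- as.numeric(lookat); up <- as.numeric(up)
  w <- lookat - eye
  if (sqrt(sum(w^2)) < 1e-9) stop("degenerate camera: eye equals look-at point")
  wn <- w / sqrt(sum(w^2))
  if (abs(sum(wn * up / sqrt(sum(up^2)))) > 1 - 1e-9)
    stop("degenerate camera: up is parallel to the view direction")
  if (!is.null(step_mm) && step_mm <= 0) stop("step length must be positive")
  structure(list(eye = eye, lookat = lookat, up = up,
                 image_size = as.integer(image_size),
                 ortho_scale = ortho_scale, step_mm = step_mm),
            class = "canal_camera")
}

camera_basis <- function(cam) {
  w <- cam$lookat - cam$eye
  w <- w / sqrt(sum(w^2))
  r <- c(w[2] * cam$up[3] - w[3] * cam$up[2],
         w[3] * cam$up[1] - w[1] * cam$up[3],
         w[1] * cam$up[2] - w[2] * cam$up[1])
  r <- r / sqrt(sum(r^2))
  u <- c(r[2] * w[3] - r[3] * w[2], r[3] * w[1] - r[1] * w[3],
         r[1] * w[2] - r[2] * w[1])
  list(w = w, r = r, u = u)
}

# Per-pixel ray origins (npix x 3) and the shared direction; pixel (1,1) is
# the image's top-left, rows run down the camera up-axis.
ray_origins <- function(cam) {
  b <- camera_basis(cam)
  nx <- cam$image_size[1]; ny <- cam$image_size[2]
  pix <- cam$ortho_scale / ny
  xs <- (seq_len(nx) - (nx + 1) / 2) * pix
  ys <- ((ny + 1) / 2 - seq_len(ny)) * pix
  O <- cbind(rep(xs, each = ny), rep(ys, times = nx))
  list(origins = sweep(O[, 1] %o% b$r + O[, 2] %o% b$u, 2, cam$eye, "+"),
       dir = b$w, pix = pix)
}

#' Project world points to pixel coordinates
#'
#' @param cam a `canal_camera`.
#' @param pts n x 3 world-mm points.
#' @return n x 2 matrix of (row, col) pixel coordinates (1-based, matching
#'   the rendered image array).
#' @export
project_world_to_pixel <- function(cam, pts) {
  b <- camera_basis(cam)
  nx <- cam$image_size[1]; ny <- cam$image_size[2]
  pix <- cam$ortho_scale / ny
  pts <- matrix(pts, ncol = 3)
  s <- sweep(pts, 2, cam$eye)
  xc <- s %*% b$r; yc <- s %*% b$u
  cbind(row = (ny + 1) / 2 - yc / pix, col = xc / pix + (nx + 1) / 2)
}

# Ray parameter range covering the volume's bounding box, common to all rays.
ray_t_range <- function(cam, v) {
  d <- vol_dim(v)
  corners <- as.matrix(expand.grid(c(0, d[1] - 1), c(0, d[2] - 1), c(0, d[3] - 1)))
  w <- voxel_to_world(v, corners)
  b <- camera_basis(cam)
  proj <- sweep(w, 2, cam$eye) %*% b$w
  pad <- max(v$spacing)
  c(max(0, min(proj) - pad), max(proj) + pad)
}

composite_rays <- function(sample_rgba, cam, v, background) {
  ro <- ray_origins(cam)
  step <- if (is.null(cam$step_mm)) min(v$spacing) / 2 else cam$step_mm
  tr <- ray_t_range(cam, v)
  nsteps <- max(1L, ceiling((tr[2] - tr[1]) / step))
  npix <- nrow(ro$origins)
  Cr <- Cg <- Cb <- A <- numeric(npix)
  nsmp <- integer(npix)
  inv_aff <- solve(v$affine)
  for (s in seq_len(nsteps)) {
    tpar <- tr[1] + (s - 1) * step
    P <- sweep(ro$origins, 2, tpar * ro$dir, "+")
    ijk <- cbind(P, 1) %*% t(inv_aff)
    sm <- sample_rgba(ijk[, 1], ijk[, 2], ijk[, 3])
    alpha <- sm$alpha * (1 - A)
    Cr <- Cr + alpha * sm$rgb[, 1]
    Cg <- Cg + alpha * sm$rgb[, 2]
    Cb <- Cb + alpha * sm$rgb[, 3]
    A <- A + alpha
    nsmp <- nsmp + (sm$alpha > 0)
    if (all(A > 0.99)) break
  }
  ny <- cam$image_size[2]; nx <- cam$image_size[1]
  img <- array(0, c(ny, nx, 4))
  img[, , 1] <- matrix(Cr + (1 - A) * background[1], ny, nx)
  img[, , 2] <- matrix(Cg + (1 - A) * background[2], ny, nx)
  img[, , 3] <- matrix(Cb + (1 - A) * background[3], ny, nx)
  img[, , 4] <- matrix(A, ny, nx)
  attr(img, "in_mask_samples") <- matrix(nsmp, ny, nx)
  img
}

#' Ray-cast a mask-restricted direct volume rendering
#'
#' Orthographic front-to-back alpha compositing: at each sample,
#' `C <- C + (1 - A) * alpha * color; A <- A + (1 - A) * alpha`, with early
#' termination once every ray is saturated (A > 0.99). Samples falling on
#' voxels outside the binary mask contribute nothing, and intensities are
#' sampled from the masked volume, so the image is bit-independent of
#' out-of-mask voxels.
#'
#' @param v a `canal_volume`.
#' @param mask a `canal_mask` on `v`'s grid selecting the rendered region.
#' @param tf a `canal_tf` (default: [default_transfer_function()]).
#' @param cam a `canal_camera`.
#' @param background RGB background.
#' @return height x width x 4 array: RGB composited over the background and
#'   the accumulated alpha; attribute `in_mask_samples` counts contributing
#'   samples per pixel.
#' @export
raycast <- function(v, mask, tf = NULL, cam, background = c(0, 0, 0)) {
  if (!same_grid(v, mask)) stop("mask must live on the volume's grid")
  if (is.null(tf)) tf <- default_transfer_function(v, mask)
  vm <- v$data * (mask$data != 0)
  dims <- as.integer(vol_dim(v))
  sample_rgba <- function(x, y, z) {
    m <- c_sample_nearest(as.numeric(mask$data), dims, x, y, z, 0)
    val <- c_sample_trilinear(as.numeric(vm), dims, x, y, z, 0)
    rgba <- tf_eval(tf, val)
    list(rgb = rgba[, 1:3, drop = FALSE], alpha = rgba[, 4] * (m != 0))
  }
  composite_rays(sample_rgba, cam, v, background)
}

#' Render the labyrinth with the filling defect overlaid
#'
#' Two-material rendering in the style of the see-through defect views:
#' defect voxels take the defect color at higher opacity (defect-first
#' priority where masks overlap), the remaining labyrinth the base color at
#' lower opacity.
#'
#' @param labyrinth_mask,defect_mask `canal_mask` objects on the same grid.
#' @param cam a `canal_camera`.
#' @param colors list with RGBA vectors `labyrinth` and `defect`; the
#'   defect defaults to an opaque blue, the labyrinth to a translucent
#'   bone-white.
#' @param background RGB background.
#' @return rendered image as in [raycast()].
#' @export
render_defect_overlay <- function(labyrinth_mask, defect_mask, cam,
                                  colors = list(labyrinth = c(0.92, 0.87, 0.76, 0.04),
                                                defect = c(0.1, 0.25, 0.95, 0.35)),
                                  background = c(0, 0, 0)) {
  if (!same_grid(labyrinth_mask, defect_mask)) stop("mask grids differ")
  lab <- array(0, vol_dim(labyrinth_mask))
  lab[labyrinth_mask$data != 0] <- 1
  lab[defect_mask$data != 0] <- 2   # defect-first priority
  dims <- as.integer(vol_dim(labyrinth_mask))
  col <- rbind(c(0, 0, 0, 0), colors$labyrinth, colors$defect)
  sample_rgba <- function(x, y, z) {
    l <- c_sample_nearest(as.numeric(lab), dims, x, y, z, 0) + 1
    list(rgb = col[l, 1:3, drop = FALSE], alpha = col[l, 4])
  }
  composite_rays(sample_rgba, cam, labyrinth_mask, background)
}

#' Turntable image sequence
#'
#' Renders `n_frames` views with the camera rotated uniformly about the
#' camera up axis through the look-at point.
#'
#' @param render_fun function(cam) returning an image, e.g. a closure over
#'   [raycast()] or [render_defect_overlay()].
#' @param cam the starting `canal_camera`.
#' @param n_frames number of frames (>= 1).
#' @return list of image arrays.
#' @export
turntable <- function(render_fun, cam, n_frames = 8L) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  up <- cam$up / sqrt(sum(cam$up^2))
  lapply(seq_len(n_frames) - 1L, function(i) {
    th <- 2 * pi * i / n_frames
    K <- rbind(c(0, -up[3], up[2]), c(up[3], 0, -up[1]), c(-up[2], up[1], 0))
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
    cam_i <- cam
    cam_i$eye <- as.numeric(cam$lookat + R %*% (cam$eye - cam$lookat))
    cam_i$up <- as.numeric(R %*% up)
    render_fun(cam_i)
  })
}

#' Write a rendered image as PNG
#'
#' Straight (non-premultiplied) alpha; RGB are already composited over the
#' render background, so most viewers can ignore the alpha channel.
#'
#' @param img image array from [raycast()] or [render_defect_overlay()].
#' @param path output .png path.
#' @param opaque write alpha as 1 everywhere (default TRUE).
#' @export
write_render_png <- function(img, path, opaque = TRUE) {
  out <- img
  attr(out, "in_mask_samples") <- NULL
  if (opaque) out[, , 4] <- 1
  out[out < 0] <- 0; out[out > 1] <- 1
  png::writePNG(out, path)
  invisible(path)
}
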