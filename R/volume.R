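#' @useDynLib canalvol, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Construct a 3D volume
#'
#' A volume is a 3D scalar grid together with its voxel spacing (mm) and a
#' 4x4 affine mapping 0-based voxel indices (voxel centers) to world
#' coordinates in mm. The left-right axis label records which grid axis runs
#' along the subject's left-right direction, which the mirror-flip mode
#' needs.
#'
#' @param data numeric 3D array of intensities.
#' @param spacing numeric length-3 voxel size in mm (all > 0). Ignored if
#'   `affine` is given (then derived from its column norms).
#' @param affine 4x4 voxel-to-world matrix; default is axis-aligned with the
#'   field of view centered on the world origin.
#' @param lr_axis integer in 1:3, the grid axis along the subject's
#'   left-right direction (default 1, the NIfTI RAS convention), or NA if
#'   unknown.
#' @return an object of class `canal_volume`.
#' @export
new_volume <- function(data, spacing = c(1, 1, 1), affine = NULL, lr_axis = 1L) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("expected 3D volume, got ", length(dim(data)), "D data")
  if (is.null(affine)) {
    spacing <- as.numeric(spacing)
    if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
      stop("spacing must be three strictly positive values (mm)")
    affine <- diag(c(spacing, 1))
    affine[1:3, 4] <- -spacing * (dim(data) - 1) / 2
  } else {
    affine <- as.matrix(affine)
    if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < 1e-12)
      stop("affine must be an invertible 4x4 matrix")
    spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
    if (any(spacing <= 0)) stop("affine has a zero-length column (degenerate pixdim)")
  }
  structure(
    list(data = data, spacing = spacing, affine = affine,
         lr_axis = if (is.na(lr_axis)) NA_integer_ else as.integer(lr_axis)),
    class = "canal_volume")
}

#' Construct a binary mask on a volume's grid
#'
#' @param data logical or 0/1 array matching `parent`'s dimensions.
#' @param parent a `canal_volume` supplying grid metadata.
#' @return a `canal_mask`, which is also a `canal_volume`.
#' @export
new_mask <- function(data, parent) {
  stopifnot(inherits(parent, "canal_volume"))
  data <- array(as.integer(data != 0), dim = dim(data))
  if (!all(dim(data) == dim(parent$data)))
    stop("mask dimensions must match the parent volume")
  v <- new_volume(data, affine = parent$affine, lr_axis = parent$lr_axis)
  class(v) <- c("canal_mask", class(v))
  v
}

#' @export
print.canal_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm, voxel volume %.6f mm^3\n",
              class(x)[1], paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"), voxel_volume(x)))
  invisible(x)
}

#' Physical volume of one voxel
#'
#' @param v a `canal_volume`.
#' @return voxel volume in mm^3 (product of the spacing components).
#' @export
voxel_volume <- function(v) prod(v$spacing)

#' Physical volume of a binary mask
#'
#' @param m a `canal_mask` (or any volume with 0/1 data).
#' @return foreground volume in mm^3.
#' @export
mask_volume_mm3 <- function(m) sum(m$data != 0) * voxel_volume(m)

vol_dim <- function(v) dim(v$data)

#' Map voxel indices to world coordinates
#'
#' Indices are 0-based and refer to voxel centers, following the NIfTI
#' convention.
#'
#' @param v a `canal_volume`.
#' @param ijk n x 3 matrix of 0-based voxel indices (may be fractional).
#' @return n x 3 matrix of world coordinates in mm.
#' @export
voxel_to_world <- function(v, ijk) {
  ijk <- matrix(ijk, ncol = 3)
  t(v$affine %*% rbind(t(ijk), 1))[, 1:3, drop = FALSE]
}

#' Map world coordinates to (fractional) voxel indices
#' @param v a `canal_volume`.
#' @param xyz n x 3 matrix of world mm coordinates.
#' @return n x 3 matrix of 0-based voxel indices.
#' @export
world_to_voxel <- function(v, xyz) {
  xyz <- matrix(xyz, ncol = 3)
  t(solve(v$affine) %*% rbind(t(xyz), 1))[, 1:3, drop = FALSE]
}

#' Read a NIfTI volume
#'
#' @param path path to a .nii or .nii.gz file.
#' @param mask logical; coerce to a binary mask (values must be 0/1).
#' @return a `canal_volume` (or `canal_mask`).
#' @export
read_volume <- function(path, mask = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected 3D volume, got ", length(d), "D image in ", path)
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  sp <- sqrt(colSums(aff[1:3, 1:3]^2))
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("non-positive voxel spacing in NIfTI header (pixdim/sform) of ", path)
  lr <- lr_axis_from_affine(aff)
  v <- new_volume(array(as.numeric(img), dim = d), affine = aff, lr_axis = lr)
  if (mask) {
    if (!all(v$data %in% c(0, 1))) stop("mask file contains values other than 0/1")
    v <- new_mask(v$data, v)
  }
  v
}

# Which grid axis is most aligned with world x (the NIfTI left-right axis)?
lr_axis_from_affine <- function(aff) {
  dircos <- sweep(aff[1:3, 1:3], 2, sqrt(colSums(aff[1:3, 1:3]^2)), "/")
  ax <- which.max(abs(dircos[1, ]))
  if (abs(dircos[1, ax]) < 0.9) NA_integer_ else as.integer(ax)
}

#' Write a volume or mask as NIfTI
#'
#' Masks are stored as unsigned 8-bit integers, intensity volumes as 32-bit
#' float. The affine is written into the sform.
#'
#' @param v a `canal_volume` or `canal_mask`.
#' @param path output path (.nii or .nii.gz); parent directory must exist.
#' @export
write_volume <- function(v, path) {
  if (!dir.exists(dirname(path))) stop("directory does not exist: ", dirname(path))
  is_mask <- inherits(v, "canal_mask")
  dt <- if (is_mask) "uint8" else "float"
  img <- RNifti::asNifti(array(if (is_mask) as.integer(v$data) else as.numeric(v$data),
                               dim = dim(v$data)))
  img <- RNifti::`sform<-`(img, structure(v$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' Resample a volume to a target voxel spacing
#'
#' The world extent of the field of view is preserved (within one voxel) and
#' the first voxel center is kept fixed; intensities are interpolated
#' trilinearly, masks with nearest-neighbour.
#'
#' @param v a `canal_volume`.
#' @param target_spacing numeric length-3 (or scalar, recycled) in mm.
#' @param mode `"trilinear"` or `"nearest"`; default picks nearest for masks.
#' @return a resampled `canal_volume` of the same class.
#' @export
resample_to_spacing <- function(v, target_spacing,
                                mode = if (inherits(v, "canal_mask")) "nearest" else "trilinear") {
  target_spacing <- rep_len(as.numeric(target_spacing), 3L)
  if (any(!is.finite(target_spacing)) || any(target_spacing <= 0))
    stop("target spacing must be strictly positive")
  mode <- match.arg(mode, c("trilinear", "nearest"))
  d <- vol_dim(v)
  if (max(abs(target_spacing - v$spacing)) < 1e-9) return(v)
  nd <- pmax(2L, as.integer(round((d - 1) * v$spacing / target_spacing)) + 1L)
  dircos <- sweep(v$affine[1:3, 1:3], 2, v$spacing, "/")
  aff <- diag(4)
  aff[1:3, 1:3] <- dircos %*% diag(target_spacing)
  aff[1:3, 4] <- v$affine[1:3, 4]  # first voxel center fixed
  out <- sample_on_grid(v, dims = nd, affine = aff, mode = mode,
                        fill = histogram_mode(v))
  if (inherits(v, "canal_mask")) {
    parent <- new_volume(out, affine = aff, lr_axis = v$lr_axis)
    new_mask(out, parent)
  } else {
    new_volume(out, affine = aff, lr_axis = v$lr_axis)
  }
}

# Sample volume v at the voxel centers of the grid (dims, affine),
# optionally through a world-coordinate map fun (world -> world in v).
sample_on_grid <- function(v, dims, affine, mode, fill, world_map = NULL) {
  g <- expand.grid(i = 0:(dims[1] - 1), j = 0:(dims[2] - 1), k = 0:(dims[3] - 1))
  xyz <- t(affine %*% rbind(g$i, g$j, g$k, 1))[, 1:3, drop = FALSE]
  if (!is.null(world_map)) xyz <- world_map(xyz)
  ijk <- t(solve(v$affine) %*% rbind(t(xyz), 1))
  smp <- if (mode == "trilinear") c_sample_trilinear else c_sample_nearest
  vals <- smp(as.numeric(v$data), as.integer(vol_dim(v)),
              ijk[, 1], ijk[, 2], ijk[, 3], fill)
  array(vals, dim = dims)
}

#' Most frequent intensity (histogram mode)
#'
#' Used as the default out-of-field fill value during resampling: for
#' labyrinth MRI the modal intensity is the dark background.
#'
#' @param v a `canal_volume`.
#' @param nbins number of histogram bins.
#' @return the center of the fullest bin (exact value for near-constant data).
#' @export
histogram_mode <- function(v, nbins = 256L) {
  x <- as.numeric(v$data)
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  h <- graphics::hist(x, breaks = seq(r[1], r[2], length.out = nbins + 1L),
                      plot = FALSE)
  h$mids[which.max(h$counts)]
}
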