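#' Otsu's automatic threshold
#'
#' Finds the single intensity threshold separating a sample into two classes
#' by maximizing the between-class variance (equivalently minimizing the
#' intra-class variance) over a histogram of `nbins` equal-width bins
#' spanning the observed min-max range. Ties are broken toward the lowest
#' candidate threshold. Because the bins are recomputed from the observed
#' range, the chosen bin index is invariant under any positive affine
#' intensity map, which is what makes the method robust to inter-scan
#' intensity drift.
#'
#' @param intensities numeric vector with at least two distinct values.
#' @param nbins number of histogram bins (default 256, the classical 8-bit
#'   formulation).
#' @return a list of class `canal_otsu`: `threshold` (a bin edge; foreground
#'   is intensity > threshold), `bin_index` (number of bins below the
#'   threshold), `between_var`, `class_means`, `class_weights`, `edges`.
#' @export
otsu_threshold <- function(intensities, nbins = 256L) {
  x <- as.numeric(intensities)
  x <- x[is.finite(x)]
  nbins <- as.integer(nbins)
  if (nbins < 2L) stop("nbins must be >= 2")
  r <- range(x)
  if (length(x) < 2L || diff(r) == 0)
    stop("degenerate histogram: region contains no structure (constant intensity)")
  edges <- seq(r[1], r[2], length.out = nbins + 1L)
  bin <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(bin, nbins)
  n <- length(x)
  mids <- (edges[-1] + edges[-(nbins + 1L)]) / 2
  w0 <- cumsum(counts)[-nbins] / n            # weight of class <= candidate k
  m0 <- cumsum(counts * mids)[-nbins] / n     # unnormalized class-0 mean
  mu <- sum(counts * mids) / n
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, nbins - 1L)
  mu0 <- m0[valid] / w0[valid]
  mu1 <- (mu - m0[valid]) / w1[valid]
  sigma_b[valid] <- w0[valid] * w1[valid] * (mu0 - mu1)^2
  if (!any(is.finite(sigma_b)))
    stop("degenerate histogram: region contains no structure (constant intensity)")
  k <- which.max(sigma_b)  # which.max returns the first (lowest) maximizer
  thr <- edges[k + 1L]
  in0 <- x <= thr
  structure(list(
    threshold = thr,
    bin_index = k,
    between_var = sigma_b[k],
    class_means = c(below = mean(x[in0]), above = mean(x[!in0])),
    class_weights = c(below = mean(in0), above = mean(!in0)),
    edges = edges
  ), class = "canal_otsu")
}

#' Axis-aligned region of interest
#'
#' A half-open box in 0-based voxel indices: `lower` inclusive, `upper`
#' exclusive, matching the grid convention of [new_volume()].
#'
#' @param lower,upper integer length-3 voxel indices, `lower < upper`.
#' @return an object of class `canal_roi`.
#' @export
roi_box <- function(lower, upper) {
  lower <- as.integer(lower); upper <- as.integer(upper)
  if (length(lower) != 3L || length(upper) != 3L || any(lower >= upper) ||
      any(lower < 0L))
    stop("ROI must satisfy 0 <= lower < upper on every axis")
  structure(list(lower = lower, upper = upper), class = "canal_roi")
}

# Logical array marking the ROI (box or mask) on v's grid.
roi_indicator <- function(roi, v) {
  d <- vol_dim(v)
  if (inherits(roi, "canal_roi")) {
    if (any(roi$upper > d))
      stop("ROI box exceeds grid bounds (", paste(d, collapse = "x"), ")")
    ind <- array(FALSE, d)
    ind[(roi$lower[1] + 1):roi$upper[1],
        (roi$lower[2] + 1):roi$upper[2],
        (roi$lower[3] + 1):roi$upper[3]] <- TRUE
    ind
  } else if (inherits(roi, "canal_mask") || inherits(roi, "canal_volume")) {
    if (!all(vol_dim(roi) == d)) stop("ROI mask grid does not match the volume")
    roi$data != 0
  } else stop("roi must be a canal_roi box or a canal_mask")
}

# Map an ROI box between grids through world coordinates.
roi_on_grid <- function(roi, from, to) {
  corners <- rbind(roi$lower, roi$upper - 1L)
  w <- voxel_to_world(from, corners)
  ijk <- world_to_voxel(to, w)
  lo <- pmax(0L, as.integer(floor(apply(ijk, 2, min))))
  hi <- pmin(vol_dim(to), as.integer(ceiling(apply(ijk, 2, max))) + 1L)
  roi_box(lo, hi)
}

#' Segment the labyrinth fluid signal inside a region of interest
#'
#' Applies Otsu's threshold to the intensities inside the region (the bright
#' T2 fluid signal is the foreground), then removes connected components
#' smaller than `min_component_mm3`. Everything outside the region is
#' background.
#'
#' @param v a `canal_volume`.
#' @param roi a `canal_roi` box or a `canal_mask` on `v`'s grid.
#' @param min_component_mm3 minimum physical component volume kept (mm^3).
#' @param connectivity 6, 18 or 26 (default 26: thin canals must not split).
#' @param nbins histogram bins for the threshold.
#' @param invert set TRUE for dark-foreground modalities.
#' @return a `canal_mask` with attribute `provenance` (threshold, component
#'   counts).
#' @export
segment_fluid <- function(v, roi, min_component_mm3 = 1, connectivity = 26L,
                          nbins = 256L, invert = FALSE) {
  ind <- roi_indicator(roi, v)
  ot <- otsu_threshold(v$data[ind], nbins = nbins)
  fg <- if (invert) v$data < ot$threshold else v$data > ot$threshold
  m <- new_mask(fg & ind, v)
  before <- attr(c_label_components(array(as.integer(m$data), vol_dim(m)),
                                    as.integer(vol_dim(m)), as.integer(connectivity)),
                 "n_components")
  m <- keep_components(m, connectivity = connectivity,
                       min_component_mm3 = min_component_mm3)
  after <- attr(m, "n_components")
  if (sum(m$data) == 0)
    warning("segmentation is empty after component filtering")
  attr(m, "provenance") <- list(threshold = ot$threshold, nbins = nbins,
                                components_before = before,
                                components_after = after,
                                min_component_mm3 = min_component_mm3,
                                connectivity = connectivity)
  m
}

#' Remove small connected components from a mask
#'
#' @param m a `canal_mask`.
#' @param connectivity 6, 18 or 26.
#' @param min_component_mm3 components with physical volume below this are
#'   dropped; 0 is a no-op.
#' @return the filtered `canal_mask` with attribute `n_components`.
#' @export
keep_components <- function(m, connectivity = 26L, min_component_mm3 = 1) {
  stopifnot(inherits(m, "canal_mask"))
  if (!connectivity %in% c(6L, 18L, 26L)) stop("connectivity must be 6, 18 or 26")
  lab <- c_label_components(array(as.integer(m$data), vol_dim(m)),
                            as.integer(vol_dim(m)), as.integer(connectivity))
  ncomp <- attr(lab, "n_components")
  if (ncomp == 0L || min_component_mm3 <= 0) {
    attr(m, "n_components") <- ncomp
    return(m)
  }
  sizes <- tabulate(lab[lab > 0L], ncomp)
  keep <- which(sizes * voxel_volume(m) >= min_component_mm3)
  out <- new_mask(array(lab %in% keep, vol_dim(m)), m)
  attr(out, "n_components") <- length(keep)
  out
}

#' Keep only the largest connected component
#' @inheritParams keep_components
#' @return a `canal_mask`.
#' @export
largest_component <- function(m, connectivity = 26L) {
  lab <- c_label_components(array(as.integer(m$data), vol_dim(m)),
                            as.integer(vol_dim(m)), as.integer(connectivity))
  ncomp <- attr(lab, "n_components")
  if (ncomp <= 1L) return(m)
  sizes <- tabulate(lab[lab > 0L], ncomp)
  new_mask(array(lab == which.max(sizes), vol_dim(m)), m)
}

#' Dice overlap coefficient between two masks
#' @param a,b `canal_mask` objects on the same grid.
#' @return 2|A n B| / (|A| + |B|); 1 for two empty masks.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(all(vol_dim(a) == vol_dim(b)))
  sa <- sum(a$data != 0); sb <- sum(b$data != 0)
  if (sa + sb == 0) return(1)
  2 * sum(a$data != 0 & b$data != 0) / (sa + sb)
}
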