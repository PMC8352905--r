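# Filling-defect quantification: overlap the pre- and post-operative
# segmented labyrinths, isolate the defect, emulate the manual cleanup
# deterministically, and report the defect relative to the preoperative
# fluid volume. Because image quality and resolution differ between visits,
# the relative (not absolute) volume is the primary output.

same_grid <- function(a, b, tol = 1e-6) {
  all(vol_dim(a) == vol_dim(b)) && max(abs(a$affine - b$affine)) < tol
}

#' Overlap difference of two segmentation masks
#'
#' Voxels with fluid before surgery but not after: `pre AND NOT post`. Both
#' masks must live on the identical grid (transform the post mask first).
#'
#' @param pre_mask,post_mask `canal_mask` objects on the same grid.
#' @return the difference `canal_mask`.
#' @export
overlay_difference <- function(pre_mask, post_mask) {
  if (!same_grid(pre_mask, post_mask))
    stop("masks are not on the same grid; align the post mask first")
  new_mask(pre_mask$data != 0 & post_mask$data == 0, pre_mask)
}

# 26-neighbourhood binary dilation by one voxel.
dilate26 <- function(a) {
  d <- dim(a)
  out <- a != 0
  src <- a != 0
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    xs <- pmin(pmax(seq_len(d[1]) + dx, 1L), d[1])
    ys <- pmin(pmax(seq_len(d[2]) + dy, 1L), d[2])
    zs <- pmin(pmax(seq_len(d[3]) + dz, 1L), d[3])
    out <- out | src[xs, ys, zs, drop = FALSE]
  }
  out
}

#' Clean the overlap difference into the filling defect
#'
#' Deterministic emulation of the manual removal of voxels outside the
#' filling-defect region: intersect with a declared keep region, optionally
#' trim voxels hugging the post-operative fluid surface (thin
#' surface-mismatch shells), drop connected components below a minimum
#' physical size, and optionally keep only the largest component.
#'
#' @param diff the difference `canal_mask` from [overlay_difference()].
#' @param keep_region a `canal_roi` box or `canal_mask`; NULL keeps all.
#' @param connectivity 6, 18 or 26.
#' @param min_component_mm3 minimum surviving component volume.
#' @param largest_only keep only the largest component after filtering.
#' @param trim_shell optional post-operative fluid `canal_mask`; difference
#'   voxels 26-adjacent to it are removed (surface shells from residual
#'   misregistration hug the post surface, true plug interiors do not).
#' @return the cleaned `canal_mask`; warns if empty.
#' @export
clean_defect <- function(diff, keep_region = NULL, connectivity = 26L,
                         min_component_mm3 = 1, largest_only = FALSE,
                         trim_shell = NULL) {
  out <- diff$data != 0
  if (!is.null(keep_region)) out <- out & roi_indicator(keep_region, diff)
  if (!is.null(trim_shell)) {
    if (!same_grid(diff, trim_shell)) stop("trim_shell mask grid mismatch")
    out <- out & !dilate26(trim_shell$data)
  }
  m <- keep_components(new_mask(out, diff), connectivity = connectivity,
                       min_component_mm3 = min_component_mm3)
  if (largest_only) m <- largest_component(m, connectivity = connectivity)
  if (sum(m$data) == 0)
    warning("cleaned defect is empty: either plugging left no filling defect or the keep region is misplaced")
  m
}

#' Relative volume of the filling defect
#'
#' @param defect the defect `canal_mask`.
#' @param reference the preoperative labyrinth fluid `canal_mask` (the
#'   defect is intersected with it first, so the result is in [0, 100]).
#' @return percent of the reference volume.
#' @export
relative_volume_change <- function(defect, reference) {
  if (!same_grid(defect, reference)) stop("defect and reference grids differ")
  nref <- sum(reference$data != 0)
  if (nref == 0) stop("reference labyrinth mask is empty")
  100 * sum(defect$data != 0 & reference$data != 0) / nref
}

new_defect_result <- function(defect, reference, mode, provenance, masks) {
  cnt <- sum(defect$data != 0)
  structure(list(
    defect_count = cnt,
    defect_mm3 = cnt * voxel_volume(defect),
    reference_mm3 = sum(reference$data != 0) * voxel_volume(reference),
    relative_pct = relative_volume_change(defect, reference),
    mode = mode, provenance = provenance, masks = masks),
    class = "canal_defect_result")
}

#' @export
print.canal_defect_result <- function(x, ...) {
  cat(sprintf(paste0("<canal_defect_result> mode=%s\n",
                     "  filling defect: %d voxels = %.3f mm^3\n",
                     "  reference labyrinth fluid: %.3f mm^3\n",
                     "  relative defect: %.2f%% of the preoperative volume\n"),
              x$mode, x$defect_count, x$defect_mm3, x$reference_mm3,
              x$relative_pct))
  invisible(x)
}

default_quantify_params <- function() {
  list(min_component_mm3 = 1, connectivity = 26L, nbins = 256L,
       levels = 3L, largest_only = FALSE, trim_shell = FALSE)
}

merge_params <- function(params) {
  p <- default_quantify_params()
  bad <- setdiff(names(params), names(p))
  if (length(bad)) stop("unknown parameters: ", paste(bad, collapse = ", "))
  p[names(params)] <- params
  p
}

#' Quantify the filling defect from a pre/post scan pair
#'
#' The full workflow: harmonize voxel spacing (the lower-resolution scan is
#' upsampled to the other's spacing), rigidly register the post scan to the
#' pre scan, segment the labyrinth fluid in both with region-restricted
#' Otsu thresholds, take the overlap difference, clean it, and report the
#' defect relative to the preoperative fluid volume.
#'
#' @param pre,post `canal_volume` scans (pre is the fixed reference grid).
#' @param roi a `canal_roi` or `canal_mask` around the labyrinth, on the pre
#'   grid.
#' @param keep_region keep region for [clean_defect()] on the pre grid
#'   (NULL: whole ROI).
#' @param params named list overriding `min_component_mm3`, `connectivity`,
#'   `nbins`, `levels`, `largest_only`, `trim_shell`.
#' @param init_transform optional initial `canal_transform`.
#' @return a `canal_defect_result`; `$masks` carries the pre, post and
#'   defect masks, `$provenance` the thresholds and transform.
#' @export
quantify_pre_post <- function(pre, post, roi, keep_region = NULL,
                              params = list(), init_transform = NULL) {
  p <- merge_params(params)
  # resample the coarser scan to the finer spacing
  if (max(abs(pre$spacing - post$spacing)) > 1e-6) {
    if (voxel_volume(pre) > voxel_volume(post)) {
      old_pre <- pre
      pre <- resample_to_spacing(pre, post$spacing)
      if (!is.null(roi) && inherits(roi, "canal_roi"))
        roi <- roi_on_grid(roi, old_pre, pre)
      if (!is.null(keep_region) && inherits(keep_region, "canal_roi"))
        keep_region <- roi_on_grid(keep_region, old_pre, pre)
    } else {
      post <- resample_to_spacing(post, pre$spacing)
    }
  }
  t_post <- register_rigid(pre, post, init = init_transform, levels = p$levels)
  post_aligned <- apply_transform(post, t_post, mode = "trilinear",
                                  fixed_grid = pre)
  pre_mask <- segment_fluid(pre, roi, min_component_mm3 = p$min_component_mm3,
                            connectivity = p$connectivity, nbins = p$nbins)
  post_mask <- segment_fluid(post_aligned, roi,
                             min_component_mm3 = p$min_component_mm3,
                             connectivity = p$connectivity, nbins = p$nbins)
  diff <- overlay_difference(pre_mask, post_mask)
  defect <- clean_defect(diff, keep_region = keep_region,
                         connectivity = p$connectivity,
                         min_component_mm3 = p$min_component_mm3,
                         largest_only = p$largest_only,
                         trim_shell = if (isTRUE(p$trim_shell)) post_mask else NULL)
  prov <- list(threshold_pre = attr(pre_mask, "provenance")$threshold,
               threshold_post = attr(post_mask, "provenance")$threshold,
               transform = list(angles_deg = t_post$angles_deg,
                                translation_mm = t_post$translation,
                                center_mm = t_post$center,
                                metric = attr(t_post, "metric")),
               params = p)
  new_defect_result(defect, pre_mask, mode = "pre_post", provenance = prov,
                    masks = list(pre = pre_mask, post = post_mask,
                                 defect = defect))
}

#' Quantify the filling defect against the mirrored non-operated ear
#'
#' For patients without a preoperative scan: the volume is flipped across
#' the mid-sagittal plane, the mirrored healthy labyrinth is rigidly aligned
#' onto the operated one, both are segmented, and the difference
#' (mirrored-healthy AND NOT operated) is cleaned and reported relative to
#' the mirrored healthy labyrinth's fluid volume.
#'
#' @param post the postoperative `canal_volume` with both labyrinths in the
#'   field of view and a known left-right axis.
#' @param operated_side `"left"` or `"right"` (provenance only; the
#'   reflection is about the field-of-view center).
#' @param roi `canal_roi` or `canal_mask` around the operated labyrinth.
#' @param keep_region keep region for [clean_defect()].
#' @param params as in [quantify_pre_post()].
#' @return a `canal_defect_result` with mode `"contralateral"`; provenance
#'   gains `negative_change_warning` when the operated side holds more
#'   fluid than the mirrored healthy side (a swapped-side signature).
#' @export
quantify_contralateral <- function(post, operated_side, roi,
                                   keep_region = NULL, params = list()) {
  if (!operated_side %in% c("left", "right"))
    stop("operated side must be \"left\" or \"right\"")
  p <- merge_params(params)
  mir <- mirror_lr(post)
  t_mir <- register_rigid(post, mir, levels = p$levels)
  mir_aligned <- apply_transform(mir, t_mir, mode = "trilinear",
                                 fixed_grid = post)
  op_mask <- segment_fluid(post, roi, min_component_mm3 = p$min_component_mm3,
                           connectivity = p$connectivity, nbins = p$nbins)
  ref_mask <- segment_fluid(mir_aligned, roi,
                            min_component_mm3 = p$min_component_mm3,
                            connectivity = p$connectivity, nbins = p$nbins)
  diff <- overlay_difference(ref_mask, op_mask)
  defect <- clean_defect(diff, keep_region = keep_region,
                         connectivity = p$connectivity,
                         min_component_mm3 = p$min_component_mm3,
                         largest_only = p$largest_only,
                         trim_shell = if (isTRUE(p$trim_shell)) op_mask else NULL)
  neg <- sum(op_mask$data) > 1.01 * sum(ref_mask$data)
  if (neg)
    warning("operated side holds more fluid than the mirrored healthy side; check the operated_side flag")
  prov <- list(threshold_operated = attr(op_mask, "provenance")$threshold,
               threshold_mirrored = attr(ref_mask, "provenance")$threshold,
               operated_side = operated_side,
               transform = list(angles_deg = t_mir$angles_deg,
                                translation_mm = t_mir$translation,
                                center_mm = t_mir$center,
                                metric = attr(t_mir, "metric")),
               negative_change_warning = neg,
               params = p)
  new_defect_result(defect, ref_mask, mode = "contralateral",
                    provenance = prov,
                    masks = list(operated = op_mask, mirrored = ref_mask,
                                 defect = defect))
}

#' Write a defect result as JSON and one-row CSV
#'
#' @param x a `canal_defect_result`.
#' @param path_json,path_csv output paths (NULL to skip either).
#' @param extra named list merged into the JSON (e.g. config hash, seed).
#' @export
write_defect_result <- function(x, path_json = NULL, path_csv = NULL,
                                extra = list()) {
  rec <- c(list(defect_count = x$defect_count, defect_mm3 = x$defect_mm3,
                reference_mm3 = x$reference_mm3,
                relative_pct = x$relative_pct, mode = x$mode,
                package_version = as.character(utils::packageVersion("canalvol"))),
           extra, list(provenance = x$provenance))
  if (!is.null(path_json))
    jsonlite::write_json(rec, path_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (!is.null(path_csv))
    utils::write.csv(data.frame(mode = x$mode, defect_count = x$defect_count,
                                defect_mm3 = x$defect_mm3,
                                reference_mm3 = x$reference_mm3,
                                relative_pct = x$relative_pct),
                     path_csv, row.names = FALSE)
  invisible(x)
}

#' Cohort summary of defect results
#'
#' Mean, standard error of the mean, and range of the relative defect, with
#' and without zero-change (failure-signature) cases.
#'
#' @param results list of `canal_defect_result` objects.
#' @return a data frame with one row per summary variant.
#' @export
summarize_cohort <- function(results) {
  pct <- vapply(results, function(r) r$relative_pct, 0)
  row <- function(label, x) data.frame(
    subset = label, n = length(x), mean_pct = mean(x),
    sem_pct = if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_,
    min_pct = if (length(x)) min(x) else NA_real_,
    max_pct = if (length(x)) max(x) else NA_real_)
  rbind(row("all", pct), row("nonzero", pct[pct > 0]))
}
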