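# 3D puncta-on-process colocalization: soma removal, puncta segmentation
# on the histogram-matched channel, AND-mask connected components, and
# volume-normalised density.

#' Colocalization result
#'
#' @param n_colocalized number of puncta components overlapping processes.
#' @param process_volume soma-free process volume, um^3 (> 0).
#' @param layer_label,group_label optional annotations.
#' @return A `coloc_result` with `density = n_colocalized / process_volume`
#'   in puncta per um^3.
#' @export
coloc_result <- function(n_colocalized, process_volume,
                         layer_label = NA_character_,
                         group_label = NA_character_) {
  stopifnot(n_colocalized >= 0, is.finite(process_volume))
  if (process_volume <= 0) stop("process_volume must be > 0")
  structure(list(n_colocalized = as.integer(n_colocalized),
                 process_volume = process_volume,
                 density = n_colocalized / process_volume,
                 layer_label = layer_label, group_label = group_label),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf(
    "coloc_result: %d puncta on %.1f um^3 of process (%.4g per um^3)\n",
    x$n_colocalized, x$process_volume, x$density))
  invisible(x)
}

#' Segment somas in the cell-label channel
#'
#' Soma-scale blob enhancement (Gaussian at `sigma_um`, large enough to
#' dim thin neurites while leaving cell bodies bright), Otsu thresholding,
#' active-contour refinement, then removal of components below a
#' soma-volume floor. An empty mask (no component above the floor) is a
#' valid result.
#'
#' @param stack an [image_stack()] with a `cell` channel.
#' @param sigma_um blob-enhancement sigma, micrometres.
#' @param volume_floor_um3 minimum component volume treated as a soma.
#' @param iterations,smoothing active-contour settings.
#' @return Logical soma mask, same shape as the stack.
#' @export
segment_somas <- function(stack, sigma_um = 1.5, volume_floor_um3 = 300,
                          iterations = 35L, smoothing = 1L) {
  stopifnot(inherits(stack, "image_stack"))
  ch <- get_channel(stack, "cell")
  enh <- blob_enhance(ch, sigma_um, voxel_size = stack$voxel_size)
  init <- otsu_threshold(enh)$mask
  # contours evolve on the raw channel: the enhanced image locates the
  # somas but blurs their boundary outward. Evolution is confined to the
  # padded bounding box of the initialisation (the front cannot travel
  # far from it), which keeps the cost proportional to the somas.
  d <- dim(ch)
  idx <- which(init, arr.ind = TRUE)
  pad <- 8L
  lo <- pmax(apply(idx, 2, min) - pad, 1L)
  hi <- pmin(apply(idx, 2, max) + pad, d)
  sub <- ch[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  sub_init <- init[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  ref_sub <- refine_active_contour(sub, sub_init, iterations, smoothing)
  refined <- array(FALSE, dim = d)
  refined[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- ref_sub
  floor_vox <- ceiling(volume_floor_um3 / voxel_volume(stack))
  out <- filter_small_components(refined, floor_vox, connectivity = 26L)
  if (!any(out))
    message("segment_somas: no component above the ", volume_floor_um3,
            " um^3 floor; returning empty mask")
  out
}

#' Process mask after soma removal
#'
#' Otsu-segments the cell channel and removes soma voxels, leaving the
#' labelled neurite processes whose volume normalises the colocalization
#' count.
#'
#' @param stack an [image_stack()] with a `cell` channel.
#' @param soma_mask logical mask from [segment_somas()] (same shape).
#' @param presmooth_sigma_um optional Gaussian sigma applied before Otsu;
#'   0 disables.
#' @return Logical process mask with attribute `volume_um3`.
#' @export
make_process_mask <- function(stack, soma_mask, presmooth_sigma_um = 0) {
  stopifnot(inherits(stack, "image_stack"))
  ch <- get_channel(stack, "cell")
  if (!identical(dim(soma_mask), dim(ch)))
    stop("soma_mask shape does not match the stack")
  if (presmooth_sigma_um > 0)
    ch <- blob_enhance(ch, presmooth_sigma_um, voxel_size = stack$voxel_size)
  mask <- otsu_threshold(ch)$mask & !soma_mask
  if (!any(mask))
    stop("process mask is empty: nothing to normalise by")
  attr(mask, "volume_um3") <- mask_volume(mask, stack$voxel_size)
  mask
}

#' Segment puncta on the histogram-matched puncta channel
#'
#' The puncta channel is histogram-matched to `reference` (normalising
#' acquisitions to a common intensity scale), Otsu-thresholded, and
#' cleaned with a minimum component-size filter.
#'
#' @param puncta_channel numeric array.
#' @param reference numeric array for [match_histogram()]; pass the
#'   channel itself for self-normalisation.
#' @param min_voxels minimum puncta component size kept, in voxels.
#' @param connectivity component connectivity for the size filter.
#' @return Logical puncta mask.
#' @export
segment_puncta <- function(puncta_channel, reference, min_voxels = 4L,
                           connectivity = 26L) {
  matched <- match_histogram(puncta_channel, reference)
  mask <- otsu_threshold(matched)$mask
  filter_small_components(mask, min_voxels, connectivity)
}

#' Count puncta colocalized with processes
#'
#' Combines the process and puncta masks with a logical AND and counts
#' the 3D connected components of the intersection; the count is
#' normalised by the physical process volume.
#'
#' @param process_mask logical mask (from [make_process_mask()], carrying
#'   a `volume_um3` attribute) or any logical array if `voxel_size` is
#'   given.
#' @param puncta_mask logical mask, same shape.
#' @param voxel_size per-axis voxel size in micrometres; only needed when
#'   `process_mask` has no `volume_um3` attribute.
#' @param connectivity 3D connectivity for component counting (6/18/26).
#' @param layer_label,group_label annotations carried into the result.
#' @return A [coloc_result()].
#' @export
count_colocalized <- function(process_mask, puncta_mask, voxel_size = NULL,
                              connectivity = 26L,
                              layer_label = NA_character_,
                              group_label = NA_character_) {
  if (!identical(dim(process_mask), dim(puncta_mask)))
    stop("mask shapes differ")
  volume <- attr(process_mask, "volume_um3")
  if (is.null(volume)) {
    if (is.null(voxel_size))
      stop("need voxel_size when process_mask carries no volume")
    volume <- mask_volume(process_mask, voxel_size)
  }
  if (volume <= 0) stop("process volume is zero")
  overlap <- process_mask & puncta_mask
  n <- max(label_components(overlap, connectivity))
  coloc_result(n, volume, layer_label, group_label)
}

#' Run the full colocalization pipeline on one stack
#'
#' Soma segmentation, soma removal, puncta segmentation on the
#' histogram-matched channel, AND-mask component counting and volume
#' normalisation, with all tunables taken from a [vq_config()].
#'
#' @param stack an [image_stack()] with channels `cell` and `puncta`.
#' @param reference reference array for puncta histogram matching;
#'   defaults to the stack's own puncta channel (self-normalisation).
#' @param config a [vq_config()].
#' @param layer_label,group_label annotations for the result.
#' @return A [coloc_result()].
#' @export
run_coloc_pipeline <- function(stack, reference = NULL,
                               config = vq_config(),
                               layer_label = NA_character_,
                               group_label = NA_character_) {
  if (is.null(reference)) reference <- get_channel(stack, "puncta")
  somas <- segment_somas(stack,
                         sigma_um = config$soma_sigma_um,
                         volume_floor_um3 = config$soma_floor_um3,
                         iterations = config$ac_iterations,
                         smoothing = config$ac_smoothing)
  procs <- make_process_mask(stack, somas,
                             presmooth_sigma_um = config$process_sigma_um)
  puncta <- segment_puncta(get_channel(stack, "puncta"), reference,
                           min_voxels = config$puncta_min_voxels,
                           connectivity = config$connectivity)
  count_colocalized(procs, puncta, connectivity = config$connectivity,
                    layer_label = layer_label, group_label = group_label)
}

#' Compare colocalization densities between two groups
#'
#' Two-sided Mann-Whitney U test on the per-image densities, the group
#' statistic used for layer and genotype comparisons.
#'
#' @param results_a,results_b lists of [coloc_result()] objects (or
#'   numeric density vectors).
#' @return List with `test` (a [mann_whitney_u()] result) and the group
#'   medians `median_a`, `median_b`.
#' @export
compare_coloc_groups <- function(results_a, results_b) {
  dens <- function(x) {
    if (is.numeric(x)) return(as.numeric(x))
    vapply(x, function(r) r$density, numeric(1))
  }
  a <- dens(results_a); b <- dens(results_b)
  if (length(a) < 1 || length(b) < 1)
    stop("both groups must be non-empty")
  list(test = mann_whitney_u(a, b, two_sided = TRUE),
       median_a = median(a), median_b = median(b))
}
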