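#' Multi-channel image stack with physical voxel size
#'
#' Container for a 2D image or 3D stack acquired in one or more channels on a
#' common (possibly anisotropic) voxel grid. Channels are stored as plain
#' numeric arrays indexed `[z, y, x]` (3D) or `[y, x]` (2D); `voxel_size`
#' gives the physical edge length of a voxel along each axis in micrometres,
#' in the same axis order.
#'
#' @param channels named list of numeric arrays, all with identical
#'   dimensions. Intensities must be finite and non-negative.
#' @param voxel_size numeric vector of per-axis voxel sizes in micrometres
#'   (length equal to the number of array dimensions).
#' @return An object of class `image_stack`: a list with elements `channels`,
#'   `voxel_size` and `dim`.
#' @examples
#' ch <- array(runif(8 * 8 * 4), dim = c(4, 8, 8))
#' stk <- image_stack(list(cell = ch), voxel_size = c(0.3, 0.1, 0.1))
#' voxel_volume(stk)
#' @export
image_stack <- function(channels, voxel_size) {
  stopifnot(is.list(channels), length(channels) >= 1)
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("channels must be a named list")
  dims <- lapply(channels, function(ch) dim(ch) %||% length(ch))
  d0 <- dims[[1]]
  for (d in dims) if (!identical(d, d0)) stop("all channels must share shape")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != length(d0))
    stop("voxel_size must have one entry per array dimension")
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("voxel sizes must be positive and finite")
  for (ch in channels) {
    if (any(!is.finite(ch))) stop("channel intensities must be finite")
    if (any(ch < 0)) stop("channel intensities must be non-negative")
  }
  structure(list(channels = channels, voxel_size = voxel_size, dim = d0),
            class = "image_stack")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.image_stack <- function(x, ...) {
  cat("image_stack:", paste(x$dim, collapse = " x "), "voxels;",
      length(x$channels), "channel(s):",
      paste(names(x$channels), collapse = ", "), "\n")
  cat("  voxel size (um):", paste(signif(x$voxel_size, 4), collapse = " x "),
      "\n")
  invisible(x)
}

#' Physical volume of one voxel
#'
#' @param x an `image_stack`, or a numeric vector of per-axis voxel sizes.
#' @return Voxel volume in cubic micrometres (square micrometres for 2D).
#' @export
voxel_volume <- function(x) {
  vs <- if (inherits(x, "image_stack")) x$voxel_size else as.numeric(x)
  prod(vs)
}

#' Extract one channel from an image stack
#'
#' @param stack an `image_stack`.
#' @param name channel name or integer position.
#' @return The channel's numeric array.
#' @export
get_channel <- function(stack, name) {
  stopifnot(inherits(stack, "image_stack"))
  ch <- stack$channels[[name]]
  if (is.null(ch)) stop("no channel named '", name, "'")
  ch
}

# pad a dim vector to length 3 (trailing singleton axes) so the compiled
# kernels can treat 2D images as single-slice volumes
dim3 <- function(x) {
  d <- dim(x) %||% length(x)
  c(d, rep(1L, 3 - length(d)))
}

# mask helpers -----------------------------------------------------------

#' Volume (or area) of a binary mask in physical units
#'
#' @param mask logical array.
#' @param voxel_size per-axis voxel sizes in micrometres.
#' @return `sum(mask)` times the voxel volume, in um^3 (um^2 for 2D).
#' @export
mask_volume <- function(mask, voxel_size) {
  stopifnot(is.logical(mask))
  sum(mask) * prod(as.numeric(voxel_size))
}

#' Label connected components of a binary mask
#'
#' Components are found under face (6), face+edge (18) or full (26)
#' neighbour connectivity in 3D; for 2D input these reduce to 4- and
#' 8-connectivity.
#'
#' @param mask logical array (2D or 3D).
#' @param connectivity 6, 18 or 26.
#' @return Integer array of the same shape; 0 = background, components
#'   numbered from 1.
#' @export
label_components <- function(mask, connectivity = 26L) {
  stopifnot(is.logical(mask))
  d <- dim3(mask)
  lab <- cpp_label_components(as.logical(mask), as.integer(d),
                              as.integer(connectivity))
  dim(lab) <- dim(mask) %||% length(mask)
  lab
}

#' Component sizes of a labelled array
#'
#' @param labels integer array from [label_components()].
#' @return Named integer vector of voxel counts per label.
#' @export
component_sizes <- function(labels) {
  tab <- tabulate(labels[labels > 0L])
  setNames(tab, seq_along(tab))
}

#' Dilate or erode a mask by a physical radius
#'
#' Binary dilation (or erosion, via complement) of a 2D/3D mask by a
#' ball of the given physical radius, honouring anisotropic voxels.
#'
#' @param mask logical array.
#' @param radius_um ball radius in micrometres.
#' @param voxel_size per-axis voxel size in micrometres.
#' @param erode if `TRUE`, erode instead of dilate.
#' @return Logical array of the same shape.
#' @export
dilate_mask <- function(mask, radius_um, voxel_size, erode = FALSE) {
  stopifnot(is.logical(mask), radius_um >= 0)
  nd <- length(dim(mask) %||% 1L)
  vs <- rep_len(as.numeric(voxel_size), nd)
  vs3 <- c(vs, rep(1, 3 - nd))
  r_vox <- ceiling(radius_um / vs3)
  g <- expand.grid(d1 = -r_vox[1]:r_vox[1], d2 = -r_vox[2]:r_vox[2],
                   d3 = -r_vox[3]:r_vox[3])
  keep <- (g$d1 * vs3[1])^2 + (g$d2 * vs3[2])^2 + (g$d3 * vs3[3])^2 <=
    radius_um^2
  off <- as.matrix(g[keep, , drop = FALSE])
  storage.mode(off) <- "integer"
  out <- if (erode)
    cpp_erode_offsets(as.logical(mask), as.integer(dim3(mask)), off)
  else cpp_dilate_offsets(as.logical(mask), as.integer(dim3(mask)), off)
  dim(out) <- dim(mask) %||% length(mask)
  out
}

#' Drop small connected components from a mask
#'
#' @param mask logical array.
#' @param min_voxels minimum component size (in voxels) to keep.
#' @param connectivity passed to [label_components()].
#' @return Filtered logical mask.
#' @export
filter_small_components <- function(mask, min_voxels, connectivity = 26L) {
  if (min_voxels <= 1) return(mask)
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) return(mask)
  keep <- which(component_sizes(lab) >= min_voxels)
  out <- array(lab %in% keep, dim = dim(mask) %||% length(mask))
  out
}
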