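#' Match the intensity histogram of one channel to a reference
#'
#' Classic histogram specification: each intensity in `image` is mapped,
#' through its empirical quantile, onto the intensity with the same quantile
#' in `reference`. The mapping is monotone, so segmentation thresholds keep
#' their ordering; after matching, the empirical CDF of the output equals
#' that of the reference at the matched quantiles (up to intensity-tie
#' granularity). Used to normalise channels across acquisitions before
#' Otsu segmentation.
#'
#' @param image numeric array to transform.
#' @param reference numeric array providing the target intensity
#'   distribution; need not have the same shape as `image`.
#' @return Numeric array shaped like `image` with the reference's histogram.
#' @examples
#' img <- matrix(runif(100), 10)
#' ref <- matrix(runif(100) * 50 + 10, 10)
#' out <- match_histogram(img, ref)
#' range(out)
#' @export
match_histogram <- function(image, reference) {
  if (length(image) == 0 || length(reference) == 0)
    stop("image and reference must be non-empty")
  rref <- range(reference)
  if (rref[1] == rref[2])
    stop("constant-valued reference: histogram mapping undefined")

  src_vals <- sort(unique(as.vector(image)))
  src_cdf <- cumsum(tabulate(match(as.vector(image), src_vals),
                             nbins = length(src_vals))) / length(image)
  ref_sorted <- sort(as.vector(reference))
  ref_cdf <- seq_along(ref_sorted) / length(ref_sorted)

  mapped <- approx(x = ref_cdf, y = ref_sorted, xout = src_cdf,
                   method = "linear", rule = 2, ties = "ordered")$y
  out <- mapped[match(as.vector(image), src_vals)]
  dim(out) <- dim(image)
  out
}

#' Blob enhancement by Gaussian convolution
#'
#' Convolves a channel with an anisotropy-aware Gaussian kernel to raise the
#' signal-to-noise ratio of blob-like structures before thresholding. With a
#' physical `voxel_size`, `sigma` is interpreted in micrometres and converted
#' per axis, honouring anisotropic grids; otherwise `sigma` is in voxels.
#' Boundary handling is symmetric reflection, which avoids the border
#' darkening that would bias a subsequent Otsu threshold; the kernel is
#' normalised so the image mean is conserved.
#'
#' @param channel numeric 2D or 3D array.
#' @param sigma Gaussian standard deviation: a scalar, or one value per axis.
#'   In micrometres when `voxel_size` is given, else in voxels.
#' @param voxel_size optional per-axis voxel size in micrometres.
#' @return Smoothed array of the same shape.
#' @export
blob_enhance <- function(channel, sigma, voxel_size = NULL) {
  nd <- length(dim(channel) %||% 1L)
  if (any(sigma <= 0)) stop("sigma must be > 0")
  sigma <- rep_len(as.numeric(sigma), nd)
  if (!is.null(voxel_size)) {
    voxel_size <- rep_len(as.numeric(voxel_size), nd)
    sigma <- sigma / voxel_size
  }
  d <- dim3(channel)
  out <- cpp_gauss_blur(as.numeric(channel), as.integer(d),
                        c(sigma, rep(0, 3 - nd)))
  dim(out) <- dim(channel) %||% length(channel)
  out
}

#' Difference-of-Gaussians feature enhancement
#'
#' Band-pass enhancement used ahead of cell-body segmentation in 2D ISH
#' images: the channel is smoothed at two scales and the coarse version
#' subtracted from the fine one, suppressing both pixel noise and slowly
#' varying background while keeping features at the intermediate scale.
#'
#' @param channel numeric 2D (or 3D) array.
#' @param sigma_small,sigma_large the two Gaussian scales,
#'   `sigma_small < sigma_large`. Voxels by default, micrometres if
#'   `voxel_size` is given.
#' @param voxel_size optional per-axis voxel size in micrometres.
#' @return Array of the same shape; values may be negative.
#' @export
dog_enhance <- function(channel, sigma_small = 1, sigma_large = 4,
                        voxel_size = NULL) {
  if (!(sigma_small < sigma_large))
    stop("sigma_small must be < sigma_large")
  blob_enhance(channel, sigma_small, voxel_size) -
    blob_enhance(channel, sigma_large, voxel_size)
}

#' Rolling-ball style background subtraction
#'
#' Estimates the local background of a 2D channel as its morphological
#' opening with a disk-shaped structuring element and subtracts it.
#' Structures narrower than the disk survive with their amplitude; any
#' background varying on scales broader than the disk is removed. The
#' result is non-negative by the anti-extensivity of opening.
#'
#' @param channel numeric matrix.
#' @param disk_radius structuring-element radius in pixels (>= 1).
#' @return Background-subtracted matrix, same shape, all values >= 0.
#' @export
subtract_background <- function(channel, disk_radius) {
  if (!is.matrix(channel)) stop("subtract_background expects a 2D channel")
  disk_radius <- as.integer(disk_radius)
  if (disk_radius < 1) stop("disk_radius must be >= 1")
  side <- 2L * disk_radius + 1L
  if (side > min(dim(channel)))
    stop("structuring disk larger than the image")
  kern <- EBImage::makeBrush(side, shape = "disc")
  # EBImage grayscale morphology assumes intensities in [0, 1]
  scale <- max(channel, 1)
  bg <- EBImage::opening(channel / scale, kern) * scale
  out <- channel - bg
  out[out < 0] <- 0  # guard against float round-off
  out
}

#' Otsu threshold of an intensity channel
#'
#' Computes the threshold maximising the between-class variance of the
#' channel's intensity histogram (256 bins over the channel's min-max range
#' by default) and the corresponding foreground mask. Voxels strictly
#' greater than the threshold are foreground. The mask is invariant to
#' monotone affine rescaling of the intensities, up to binning granularity.
#'
#' @param channel numeric array with at least two distinct values.
#' @param nbins number of histogram bins.
#' @return List with `threshold` (in the channel's intensity units) and
#'   `mask` (logical array, `channel > threshold`).
#' @examples
#' img <- matrix(c(rep(10, 60), rep(200, 40)), 10)
#' ot <- otsu_threshold(img)
#' sum(ot$mask)  # the 40 bright pixels
#' @export
otsu_threshold <- function(channel, nbins = 256L) {
  v <- as.numeric(channel)
  lo <- min(v); hi <- max(v)
  if (!is.finite(lo) || !is.finite(hi)) stop("intensities must be finite")
  if (lo == hi) stop("constant channel: Otsu threshold undefined")
  nbins <- as.integer(nbins)
  breaks <- seq(lo, hi, length.out = nbins + 1L)
  bin <- pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE), 1L),
              nbins)
  counts <- tabulate(bin, nbins)
  p <- counts / sum(counts)
  mids <- (breaks[-1] + breaks[-(nbins + 1L)]) / 2
  w0 <- cumsum(p)[-nbins]
  mu0 <- cumsum(p * mids)[-nbins]
  mu_t <- sum(p * mids)
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, nbins - 1L)
  sigma_b[valid] <- (mu_t * w0[valid] - mu0[valid])^2 /
    (w0[valid] * w1[valid])
  cut <- which.max(sigma_b)  # first maximum on ties: lowest threshold
  thr <- breaks[cut + 1L]
  mask <- array(channel > thr, dim = dim(channel) %||% length(channel))
  list(threshold = thr, mask = mask)
}

#' Refine a segmentation with region-based active contours
#'
#' Evolves an initial mask with a morphological active-contour scheme
#' without edges: interface voxels move toward whichever of the inside /
#' outside region means their intensity is closer to, with a majority-vote
#' smoothing pass approximating curvature regularisation. The front moves
#' at most one voxel per iteration plus one per smoothing pass, so the
#' result stays within a bounded dilation of the initial components.
#'
#' @param channel numeric array the contour evolves on.
#' @param init_mask non-empty logical array, same shape.
#' @param iterations evolution steps; 0 returns `init_mask` unchanged.
#' @param smoothing majority-vote smoothing passes per iteration.
#' @return Refined logical mask.
#' @export
refine_active_contour <- function(channel, init_mask, iterations = 35L,
                                  smoothing = 1L) {
  if (!identical(dim(channel) %||% length(channel),
                 dim(init_mask) %||% length(init_mask)))
    stop("channel and init_mask must have the same shape")
  if (!any(init_mask)) stop("init_mask is empty")
  iterations <- as.integer(iterations)
  if (iterations < 0) stop("iterations must be >= 0")
  if (iterations == 0L) return(init_mask)
  d <- dim3(channel)
  out <- cpp_morph_acwe(as.numeric(channel), as.logical(init_mask),
                        as.integer(d), iterations, as.integer(smoothing))
  dim(out) <- dim(channel) %||% length(channel)
  out
}
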