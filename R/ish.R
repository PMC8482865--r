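# Per-cell multiplexed ISH quantification: cell-body segmentation,
# background-subtracted intensity measurement, layer assignment, the
# prior-matched CR+ classifier, and genotype comparisons.

#' Region / layer specification
#'
#' Polygons delimiting the analysed region and the ordered cortical
#' layers (pia first). Polygons are `n x 2` matrices of `(y, x)` pixel
#' coordinates; they must have at least three finite vertices.
#'
#' @param layers named list of layer polygons ordered pia to white
#'   matter.
#' @param region optional polygon for the overall region of interest.
#' @return A `region_spec` object.
#' @export
region_spec <- function(layers, region = NULL) {
  check_poly <- function(p, nm) {
    if (!is.matrix(p) || ncol(p) != 2 || nrow(p) < 3 || any(!is.finite(p)))
      stop("malformed polygon '", nm, "': need an n x 2 matrix (n >= 3) ",
           "of finite (y, x) coordinates")
  }
  stopifnot(is.list(layers), length(layers) >= 1,
            !is.null(names(layers)), all(nzchar(names(layers))))
  for (nm in names(layers)) check_poly(layers[[nm]], nm)
  if (!is.null(region)) check_poly(region, "region")
  structure(list(layers = layers, region = region), class = "region_spec")
}

#' Build layer rectangles from horizontal boundary rows
#'
#' Convenience for images where layers are horizontal bands: `k` strictly
#' increasing boundary rows yield `k + 1` full-width rectangles. With four
#' boundaries the canonical labels L1, L2/3, L4, L5, L6 are used.
#'
#' @param image_shape pixels (rows, cols).
#' @param boundaries strictly increasing pixel rows.
#' @return A [region_spec()].
#' @export
layers_from_boundaries <- function(image_shape, boundaries) {
  b <- as.numeric(boundaries)
  if (is.unsorted(b, strictly = TRUE)) stop("boundaries must increase")
  edges <- c(0.5, b + 0.5, image_shape[1] + 0.5)
  k <- length(edges) - 1
  labels <- if (k == 5) c("L1", "L2/3", "L4", "L5", "L6")
  else paste0("L", seq_len(k))
  polys <- lapply(seq_len(k), function(i) {
    cbind(y = c(edges[i], edges[i + 1], edges[i + 1], edges[i]),
          x = c(0.5, 0.5, image_shape[2] + 0.5, image_shape[2] + 0.5))
  })
  names(polys) <- labels
  region_spec(layers = polys)
}

# crossing-number point-in-polygon; points on an edge count as inside,
# which feeds the pia-proximal tie rule in assign_regions
point_in_poly <- function(py, px, poly) {
  n <- nrow(poly)
  yi <- poly[, 1]; xi <- poly[, 2]
  yj <- yi[c(n, seq_len(n - 1))]; xj <- xi[c(n, seq_len(n - 1))]
  inside <- rep(FALSE, length(py))
  on_edge <- rep(FALSE, length(py))
  for (e in seq_len(n)) {
    y1 <- yi[e]; x1 <- xi[e]; y2 <- yj[e]; x2 <- xj[e]
    # edge membership: collinear and within the bounding segment
    cross <- (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
    within <- py >= pmin(y1, y2) - 1e-9 & py <= pmax(y1, y2) + 1e-9 &
      px >= pmin(x1, x2) - 1e-9 & px <= pmax(x1, x2) + 1e-9
    on_edge <- on_edge | (abs(cross) < 1e-9 & within)
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  inside | on_edge
}

#' Segment cell bodies in a 2D cell-label channel
#'
#' Difference-of-Gaussians feature enhancement, Otsu thresholding for an
#' initial segmentation, per-component active-contour refinement, and an
#' area filter. Returns a cell table (data frame of per-cell records with
#' the label mask attached as an attribute).
#'
#' @param cell_channel numeric matrix.
#' @param pixel_size_um physical pixel size, micrometres.
#' @param sigma_small,sigma_large DoG scales in pixels.
#' @param area_bounds_um2 admissible cell-body area range, um^2.
#' @param iterations,smoothing active-contour settings.
#' @param image_id,genotype annotations stored on the table.
#' @return A `cell_table`: data frame with columns `label`, `y`, `x`,
#'   `area_px`, `area_um2`; attributes `label_mask`, `pixel_size_um`,
#'   `image_id`, `genotype`. Zero detected cells gives an empty table.
#' @export
segment_cells <- function(cell_channel, pixel_size_um = 1,
                          sigma_small = 1, sigma_large = 4,
                          area_bounds_um2 = c(20, 400),
                          iterations = 35L, smoothing = 1L,
                          image_id = NA_character_,
                          genotype = NA_character_) {
  if (!is.matrix(cell_channel)) stop("segment_cells expects a 2D channel")
  enh <- dog_enhance(cell_channel, sigma_small, sigma_large)
  init <- tryCatch(otsu_threshold(enh)$mask,
                   error = function(e) NULL)
  empty <- function() {
    df <- data.frame(label = integer(0), y = numeric(0), x = numeric(0),
                     area_px = integer(0), area_um2 = numeric(0))
    as_cell_table(df, matrix(0L, nrow(cell_channel), ncol(cell_channel)),
                  pixel_size_um, image_id, genotype)
  }
  if (is.null(init) || !any(init)) {
    message("segment_cells: no foreground found")
    return(empty())
  }
  lab <- label_components(init, connectivity = 26L)
  nlab <- max(lab)
  out_mask <- matrix(0L, nrow(cell_channel), ncol(cell_channel))
  pad <- 8L  # the front stays within a few pixels of a near-correct seed
  next_label <- 0L
  rows <- list()
  for (l in seq_len(nlab)) {
    idx <- which(lab == l, arr.ind = TRUE)
    y0 <- max(1L, min(idx[, 1]) - pad); y1 <- min(nrow(lab), max(idx[, 1]) + pad)
    x0 <- max(1L, min(idx[, 2]) - pad); x1 <- min(ncol(lab), max(idx[, 2]) + pad)
    sub <- enh[y0:y1, x0:x1]
    sub_init <- matrix(FALSE, nrow(sub), ncol(sub))
    sub_init[cbind(idx[, 1] - y0 + 1L, idx[, 2] - x0 + 1L)] <- TRUE
    ref <- refine_active_contour(sub, sub_init, iterations, smoothing)
    # refinement may split or vanish; keep the component overlapping the seed
    rl <- label_components(ref, connectivity = 26L)
    seed_labels <- unique(rl[sub_init & rl > 0L])
    if (length(seed_labels) == 0) next
    keep <- array(rl %in% seed_labels, dim = dim(rl))
    area_px <- sum(keep)
    area_um2 <- area_px * pixel_size_um^2
    if (area_um2 < area_bounds_um2[1] || area_um2 > area_bounds_um2[2]) next
    next_label <- next_label + 1L
    kidx <- which(keep, arr.ind = TRUE)
    gy <- kidx[, 1] + y0 - 1L; gx <- kidx[, 2] + x0 - 1L
    vacant <- out_mask[cbind(gy, gx)] == 0L
    out_mask[cbind(gy[vacant], gx[vacant])] <- next_label
    rows[[next_label]] <- data.frame(label = next_label,
                                     y = mean(gy), x = mean(gx),
                                     area_px = area_px,
                                     area_um2 = area_um2)
  }
  if (next_label == 0L) {
    message("segment_cells: no cell within the area bounds")
    return(empty())
  }
  as_cell_table(do.call(rbind, rows), out_mask, pixel_size_um,
                image_id, genotype)
}

as_cell_table <- function(df, label_mask, pixel_size_um,
                          image_id = NA_character_,
                          genotype = NA_character_,
                          cr_threshold = NA_real_) {
  attr(df, "label_mask") <- label_mask
  attr(df, "pixel_size_um") <- pixel_size_um
  attr(df, "image_id") <- image_id
  attr(df, "genotype") <- genotype
  attr(df, "cr_threshold") <- cr_threshold
  class(df) <- c("cell_table", "data.frame")
  df
}

keep_ct_attrs <- function(df, template) {
  as_cell_table(as.data.frame(df),
                attr(template, "label_mask"),
                attr(template, "pixel_size_um"),
                attr(template, "image_id"),
                attr(template, "genotype"),
                attr(template, "cr_threshold"))
}

#' Cell boundary polygon
#'
#' Traces the boundary contour of one segmented cell from the table's
#' label mask.
#'
#' @param table a `cell_table`.
#' @param label cell label.
#' @return `n x 2` matrix of `(y, x)` boundary coordinates.
#' @export
cell_boundary <- function(table, label) {
  mask <- attr(table, "label_mask")
  if (is.null(mask)) stop("cell_table carries no label mask")
  oc <- EBImage::ocontour(EBImage::Image(mask == label))
  if (length(oc) == 0) stop("no cell with label ", label)
  # EBImage contours are 0-based (first-dim, second-dim)
  cbind(y = oc[[1]][, 1] + 1, x = oc[[1]][, 2] + 1)
}

#' Measure per-cell channel intensities
#'
#' Each channel is background-subtracted with a disk structuring element
#' ([subtract_background()]) and then averaged over each segmented cell's
#' pixels, adding one `mean_<channel>` column per channel.
#'
#' @param table a `cell_table` from [segment_cells()].
#' @param channels named list of numeric matrices, same shape as the
#'   segmentation.
#' @param background_disk_radius disk radius in pixels; 0 skips
#'   background subtraction.
#' @return The table with `mean_<channel>` columns appended.
#' @export
measure_cell_intensities <- function(table, channels,
                                     background_disk_radius = 10L) {
  stopifnot(inherits(table, "cell_table"), is.list(channels),
            !is.null(names(channels)))
  mask <- attr(table, "label_mask")
  out <- table
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!identical(dim(ch), dim(mask)))
      stop("channel '", nm, "' shape does not match the segmentation")
    if (background_disk_radius > 0)
      ch <- subtract_background(ch, background_disk_radius)
    means <- if (nrow(out) == 0) numeric(0)
    else as.numeric(tapply(ch[mask > 0L], mask[mask > 0L], mean)[
      as.character(out$label)])
    out[[paste0("mean_", nm)]] <- means
  }
  keep_ct_attrs(out, table)
}

#' Assign cells to region and layer polygons
#'
#' Each cell is labelled by the layer polygon containing its centroid;
#' centroids on a shared boundary go to the pia-proximal layer (the first
#' containing polygon in the ordered layer list). Cells outside every polygon
#' are labelled `"unassigned"`.
#'
#' @param table a `cell_table`.
#' @param regions a [region_spec()].
#' @return The table with `layer` (and, if a region polygon is present,
#'   `region`) columns.
#' @export
assign_regions <- function(table, regions) {
  stopifnot(inherits(table, "cell_table"), inherits(regions, "region_spec"))
  out <- table
  layer <- rep("unassigned", nrow(out))
  for (nm in names(regions$layers)) {  # pia-proximal first: first hit wins
    hit <- point_in_poly(out$y, out$x, regions$layers[[nm]])
    layer[layer == "unassigned" & hit] <- nm
  }
  out$layer <- layer
  if (!is.null(regions$region)) {
    out$region <- ifelse(point_in_poly(out$y, out$x, regions$region),
                         "region", "unassigned")
  }
  keep_ct_attrs(out, table)
}

#' Prior-matched CR-positive classification
#'
#' Implements the prior-matched thresholding rule: assuming a fraction
#' `prior` of VIP cells express CR, the per-cell CR means within one image
#' are thresholded at their empirical `(1 - prior)` quantile (linear
#' interpolation between order statistics), so that approximately
#' `prior` of the cells are classified CR-positive. Cells at or above
#' the threshold are positive, so tied means classify the closest
#' attainable fraction from above.
#'
#' @param table a `cell_table` with a `mean_cr` column (see `channel`),
#'   or a list of tables for pooled thresholding.
#' @param prior expected CR-positive fraction, in (0, 1); default 0.8.
#' @param channel intensity column prefix used for classification.
#' @param pooled if `TRUE` and `table` is a list, one threshold is
#'   computed from all cells pooled across images and applied to each
#'   image; default classifies each image with its own threshold.
#' @return The table (or list of tables) with a logical `cr_positive`
#'   column and the threshold in `attr(, "cr_threshold")`.
#' @export
classify_cr <- function(table, prior = 0.8, channel = "cr",
                        pooled = FALSE) {
  if (!(prior > 0 && prior < 1)) stop("prior must be in (0, 1)")
  col <- paste0("mean_", channel)
  # interpolated quantile, clamped into the bracket of order statistics
  # whose >= cut classifies the attainable fraction closest to the prior
  # (ties toward more positives); keeps the limiting priors exact
  thr_value <- function(vals) {
    n <- length(vals)
    srt <- sort(vals)
    dev <- abs((0:n) / n - prior)
    k_star <- max((0:n)[dev == min(dev)])
    thr <- quantile(vals, probs = 1 - prior, names = FALSE, type = 7)
    if (k_star == 0) return(srt[n] * (1 + 1e-9) + 1e-12)
    hi <- srt[n - k_star + 1]
    lo <- if (k_star == n) -Inf else srt[n - k_star]
    if (!(thr > lo && thr <= hi)) thr <- hi
    thr
  }
  apply_thr <- function(tb, thr) {
    tb$cr_positive <- tb[[col]] >= thr
    out <- keep_ct_attrs(tb, tb)
    attr(out, "cr_threshold") <- thr
    out
  }
  if (is.list(table) && !inherits(table, "data.frame")) {
    vals <- unlist(lapply(table, function(tb) tb[[col]]))
    if (length(vals) < 5) stop("need at least 5 cells to classify")
    if (length(unique(vals)) == 1)
      stop("all CR means identical: classification undefined")
    if (!pooled) return(lapply(table, classify_cr, prior = prior,
                               channel = channel))
    thr <- thr_value(vals)
    return(lapply(table, apply_thr, thr = thr))
  }
  stopifnot(is.data.frame(table))  # cell_table or any per-cell data frame
  if (is.null(table[[col]]))
    stop("no column '", col, "': run measure_cell_intensities first")
  vals <- table[[col]]
  if (length(vals) < 5) stop("need at least 5 cells to classify")
  if (length(unique(vals)) == 1)
    stop("all CR means identical: classification undefined")
  apply_thr(table, thr_value(vals))
}

#' Compare expression between two sets of images
#'
#' Two-sided Mann-Whitney U test on a transcript channel between two
#' groups of cell tables (e.g. genotypes), optionally restricted to the
#' CR+ or CR- subpopulation and/or one layer or region stratum. The
#' statistical unit defaults to the image (the mean over that image's
#' cells); per-cell testing is available.
#'
#' @param tables_a,tables_b lists of `cell_table`s (a bare table is
#'   accepted for a single image).
#' @param channel intensity column prefix, e.g. `"elfn1"`.
#' @param subset `"all"`, `"cr_pos"` or `"cr_neg"` (the latter two need
#'   [classify_cr()] to have run).
#' @param stratum optional named value such as `c(layer = "L2/3")`.
#' @param unit `"image"` or `"cell"`.
#' @return List with `test` (a [mann_whitney_u()] result), `median_a`,
#'   `median_b`, `n_a`, `n_b`, and the settings used.
#' @export
compare_expression <- function(tables_a, tables_b, channel = "elfn1",
                               subset = c("all", "cr_pos", "cr_neg"),
                               stratum = NULL,
                               unit = c("image", "cell")) {
  subset <- match.arg(subset)
  unit <- match.arg(unit)
  col <- paste0("mean_", channel)
  as_list <- function(x) if (inherits(x, "data.frame")) list(x) else x
  pick <- function(tb) {
    keep <- rep(TRUE, nrow(tb))
    if (subset != "all") {
      if (is.null(tb$cr_positive))
        stop("subset '", subset, "' needs classify_cr to have run")
      keep <- keep & (if (subset == "cr_pos") tb$cr_positive
                      else !tb$cr_positive)
    }
    if (!is.null(stratum)) {
      for (nm in names(stratum)) {
        if (is.null(tb[[nm]]))
          stop("stratum column '", nm, "' missing; run assign_regions")
        keep <- keep & tb[[nm]] == stratum[[nm]]
      }
    }
    tb[[col]][keep]
  }
  collect <- function(tables) {
    per_img <- lapply(as_list(tables), pick)
    if (unit == "image")
      unlist(lapply(per_img, function(v) if (length(v)) mean(v) else NULL))
    else unlist(per_img)
  }
  a <- collect(tables_a); b <- collect(tables_b)
  if (length(a) < 1 || length(b) < 1)
    stop("empty sample after subsetting",
         if (!is.null(stratum)) paste0(" (stratum ",
                                       paste(names(stratum), stratum,
                                             sep = " = ", collapse = ", "),
                                       ")") else "")
  list(test = mann_whitney_u(a, b, two_sided = TRUE),
       median_a = median(a), median_b = median(b),
       n_a = length(a), n_b = length(b),
       channel = channel, subset = subset, unit = unit)
}
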