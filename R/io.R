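# Disk formats: channel-major multi-page TIFF with a JSON sidecar for
# stacks, long-format CSV for sweeps, JSON for results and ground truth.

#' Write an image stack as channel-major multi-page TIFF
#'
#' Pages are ordered channel-major (all z-planes of channel 1, then
#' channel 2, ...). Intensities are scaled into [0, 1] for 32-bit float
#' storage; the scale factor, channel names, shape and voxel size go to a
#' `<path>.json` sidecar so [read_stack_tiff()] restores the stack
#' losslessly (up to float precision).
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  scale <- max(1e-12, max(vapply(stack$channels, max, numeric(1))))
  pages <- list()
  for (ch in stack$channels) {
    if (length(dim(ch)) == 2) {
      pages <- c(pages, list(ch / scale))
    } else {
      for (z in seq_len(dim(ch)[1]))
        pages <- c(pages, list(ch[z, , ] / scale))
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  meta <- list(channel_names = names(stack$channels),
               dim = stack$dim, voxel_size = stack$voxel_size,
               intensity_scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a channel-major multi-page TIFF written by [write_stack_tiff()]
#'
#' @param path TIFF path (expects the `<path>.json` sidecar).
#' @return An [image_stack()].
#' @export
read_stack_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(meta$dim)
  nz <- if (length(d) == 3) d[1] else 1L
  chans <- list()
  for (i in seq_along(meta$channel_names)) {
    if (length(d) == 2) {
      ch <- pages[[i]] * meta$intensity_scale
    } else {
      ch <- array(0, dim = d)
      for (z in seq_len(nz))
        ch[z, , ] <- pages[[(i - 1L) * nz + z]] * meta$intensity_scale
    }
    chans[[meta$channel_names[i]]] <- ch
  }
  image_stack(chans, voxel_size = as.numeric(meta$voxel_size))
}

#' Write sweeps as long-format CSV
#'
#' Columns `sweep`, `time_s`, `current_pA`; stimulus times and sampling
#' rate go to a `<path>.json` sidecar.
#'
#' @param sweeps a [sweep_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sweeps_csv <- function(sweeps, path) {
  stopifnot(inherits(sweeps, "sweep_set"))
  n <- ncol(sweeps$current)
  df <- data.frame(sweep = rep(seq_len(n), each = nrow(sweeps$current)),
                   time_s = rep(sweeps$time, n),
                   current_pA = as.vector(sweeps$current))
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(sampling_rate = sweeps$sampling_rate,
                            stim_times = sweeps$stim_times,
                            holding_potential = sweeps$holding_potential),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read sweeps from CSV
#'
#' @param path CSV path from [write_sweeps_csv()]. Stimulus times are
#'   taken from the sidecar unless given.
#' @param stim_times optional override, seconds.
#' @return A [sweep_set()].
#' @export
read_sweeps_csv <- function(path, stim_times = NULL) {
  df <- read.csv(path)
  stopifnot(all(c("sweep", "time_s", "current_pA") %in% names(df)))
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar))
    jsonlite::read_json(sidecar, simplifyVector = TRUE) else list()
  ids <- sort(unique(df$sweep))
  time <- df$time_s[df$sweep == ids[1]]
  cur <- vapply(ids, function(i) df$current_pA[df$sweep == i],
                numeric(length(time)))
  sweep_set(cur, time,
            sampling_rate = meta$sampling_rate %||% 1 / diff(time[1:2]),
            stim_times = stim_times %||% as.numeric(meta$stim_times),
            holding_potential = meta$holding_potential %||% -70)
}

#' Write ground truth as JSON plus mask TIFFs
#'
#' Scalars and center tables go to `<prefix>.json`; binary masks are
#' written as single-channel stacks `<prefix>_<name>.tif`.
#'
#' @param truth ground-truth list from a generator.
#' @param prefix output path prefix.
#' @param voxel_size voxel size for the mask TIFFs.
#' @return The JSON path, invisibly.
#' @export
write_ground_truth <- function(truth, prefix, voxel_size) {
  is_mask <- vapply(truth, function(x) is.logical(x) && !is.null(dim(x)),
                    logical(1))
  for (nm in names(truth)[is_mask]) {
    stk <- image_stack(setNames(list(array(as.numeric(truth[[nm]]),
                                           dim = dim(truth[[nm]]))), nm),
                       voxel_size = voxel_size)
    write_stack_tiff(stk, paste0(prefix, "_", nm, ".tif"))
  }
  jsonlite::write_json(truth[!is_mask], paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paste0(prefix, ".json"))
}

#' Write a cell table to CSV
#'
#' @param table a `cell_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table_csv <- function(table, path) {
  stopifnot(inherits(table, "cell_table"))
  df <- as.data.frame(table)
  df$image_id <- attr(table, "image_id")
  df$genotype <- attr(table, "genotype")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a test result (or list of results) as JSON
#'
#' @param x a [test_result()] or a named list of them.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_test_result_json <- function(x, path) {
  strip <- function(r) if (inherits(r, "test_result")) unclass(r) else r
  out <- if (inherits(x, "test_result")) strip(x) else lapply(x, strip)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
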