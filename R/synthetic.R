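# Ground-truthed synthetic data generators. Each generator consumes a
# validated parameter object carrying a single integer seed, which fans out
# to per-stage substreams so stages stay independently reproducible.

derive_seed <- function(seed, stage) {
  offsets <- c(geometry = 101L, placement = 211L, intensity = 307L,
               noise = 401L, population = 503L)
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483587)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# parameter objects -------------------------------------------------------

#' Parameters for the synthetic colocalization stack generator
#'
#' Defines a two-channel anisotropic 3D stack: channel `cell` holds tubular
#' neurite processes (random-walk tubes) plus brighter ellipsoidal somas,
#' channel `puncta` holds Gaussian-profile puncta placed on process voxels
#' (outside somas) at a known density, plus off-process distractors.
#'
#' @param shape_zyx voxel counts per axis (z, y, x).
#' @param voxel_size_zyx physical voxel size in micrometres (z, y, x); the
#'   default grid is 2x coarser axially than laterally, mirroring confocal
#'   anisotropy.
#' @param n_processes number of neurite tubes.
#' @param process_radius tube radius in micrometres.
#' @param n_somas number of somas.
#' @param soma_radii ellipsoid semi-axes in micrometres (z, y, x).
#' @param puncta_on_density mean puncta per um^3 of (soma-free) process;
#'   the actual count is Poisson-drawn and recorded in the ground truth.
#' @param puncta_off_count puncta placed well away from any process.
#' @param puncta_radius Gaussian sigma of a punctum, micrometres.
#' @param snr peak-signal to noise-sigma ratio; `Inf` disables noise.
#' @param seed integer seed.
#' @return A validated `coloc_sim_params` list.
#' @export
coloc_sim_params <- function(shape_zyx = c(128L, 128L, 128L),
                             voxel_size_zyx = c(0.5, 0.25, 0.25),
                             n_processes = 10L,
                             process_radius = 0.5,
                             n_somas = 2L,
                             soma_radii = c(4, 5, 5),
                             puncta_on_density = 0.15,
                             puncta_off_count = 2500L,
                             puncta_radius = 0.5,
                             snr = 10,
                             seed = 1L) {
  p <- list(shape_zyx = as.integer(shape_zyx),
            voxel_size_zyx = as.numeric(voxel_size_zyx),
            n_processes = as.integer(n_processes),
            process_radius = as.numeric(process_radius),
            n_somas = as.integer(n_somas),
            soma_radii = as.numeric(soma_radii),
            puncta_on_density = as.numeric(puncta_on_density),
            puncta_off_count = as.integer(puncta_off_count),
            puncta_radius = as.numeric(puncta_radius),
            snr = as.numeric(snr),
            seed = as.integer(seed))
  stopifnot(length(p$shape_zyx) == 3, all(p$shape_zyx >= 1),
            length(p$voxel_size_zyx) == 3, all(p$voxel_size_zyx > 0),
            p$n_processes >= 0, p$process_radius > 0,
            p$n_somas >= 0, length(p$soma_radii) == 3,
            all(p$soma_radii > 0),
            p$puncta_on_density >= 0, p$puncta_off_count >= 0,
            p$puncta_radius > 0, p$snr > 0)
  class(p) <- "coloc_sim_params"
  p
}

#' Parameters for the synthetic ISH image generator
#'
#' Defines a 2D multi-channel ISH field: non-overlapping disk-shaped cells
#' in a cell-label channel, a calretinin (CR) channel whose per-cell mean
#' intensity follows a two-component mixture (fraction `cr_pos_fraction`
#' high-expressing, emulating the ~80/20 CR+/CR- split of VIP cells), an
#' Elfn1 channel whose per-cell mean depends on (genotype, CR class), and a
#' nuclear channel. Horizontal rows in `layer_boundaries` delimit cortical
#' layers for region assignment.
#'
#' @param image_shape pixels (rows, cols).
#' @param pixel_size_um physical pixel size, micrometres.
#' @param n_cells number of cells to place.
#' @param cr_pos_fraction expected fraction of CR-positive cells.
#' @param cr_intensity_means per-class CR channel means `c(low, high)`, a.u.
#' @param elfn1_means_by_group nested list
#'   `list(<genotype> = c(cr_pos = , cr_neg = ))` of Elfn1 channel means.
#' @param genotype which entry of `elfn1_means_by_group` this image uses.
#' @param cell_cv between-cell coefficient of variation of the per-cell
#'   class means.
#' @param noise_sigma additive pixel noise sigma, a.u.
#' @param layer_boundaries strictly increasing pixel rows separating layers
#'   (pia at row 1).
#' @param cell_radius_px min/max cell radius, pixels.
#' @param seed integer seed.
#' @return A validated `ish_sim_params` list.
#' @export
ish_sim_params <- function(image_shape = c(256L, 256L),
                           pixel_size_um = 1,
                           n_cells = 30L,
                           cr_pos_fraction = 0.8,
                           cr_intensity_means = c(low = 40, high = 120),
                           elfn1_means_by_group = list(
                             control = c(cr_pos = 100, cr_neg = 60),
                             cko = c(cr_pos = 50, cr_neg = 30)),
                           genotype = "control",
                           cell_cv = 0.12,
                           noise_sigma = 6,
                           layer_boundaries = c(50L, 110L, 160L, 210L),
                           cell_radius_px = c(4L, 6L),
                           seed = 1L) {
  p <- list(image_shape = as.integer(image_shape),
            pixel_size_um = as.numeric(pixel_size_um),
            n_cells = as.integer(n_cells),
            cr_pos_fraction = as.numeric(cr_pos_fraction),
            cr_intensity_means = as.numeric(cr_intensity_means),
            elfn1_means_by_group = elfn1_means_by_group,
            genotype = as.character(genotype),
            cell_cv = as.numeric(cell_cv),
            noise_sigma = as.numeric(noise_sigma),
            layer_boundaries = as.integer(layer_boundaries),
            cell_radius_px = as.integer(cell_radius_px),
            seed = as.integer(seed))
  stopifnot(length(p$image_shape) == 2, all(p$image_shape >= 16),
            p$pixel_size_um > 0, p$n_cells >= 0,
            p$cr_pos_fraction >= 0, p$cr_pos_fraction <= 1,
            length(p$cr_intensity_means) == 2,
            p$cr_intensity_means[2] > p$cr_intensity_means[1],
            p$genotype %in% names(p$elfn1_means_by_group),
            p$cell_cv >= 0, p$noise_sigma >= 0,
            !is.unsorted(p$layer_boundaries, strictly = TRUE),
            length(p$cell_radius_px) == 2,
            all(p$cell_radius_px >= 2))
  class(p) <- "ish_sim_params"
  p
}

#' Parameters for the synthetic evoked-sweep generator
#'
#' Each sweep is a baseline-zero current trace with two stereotyped inward
#' synaptic transients (difference-of-exponentials kinetics) at
#' `stim_times`, the second summating on the decaying first, plus white
#' noise. Defaults emulate a 50 Hz paired-pulse protocol averaged over 12
#' sweeps.
#'
#' @param n_sweeps number of sweeps (default 12).
#' @param sampling_rate Hz.
#' @param duration_s trace length, seconds.
#' @param stim_times two strictly increasing stimulus times, seconds;
#'   default 20 ms apart (50 Hz).
#' @param amp1,amp2 transient amplitudes in pA (negative = inward). `amp2`
#'   is the amplitude of the second transient itself, i.e. measured
#'   relative to the extrapolated decay of the first.
#' @param tau_rise,tau_decay kinetic time constants, seconds.
#' @param noise_sigma white-noise sigma, pA.
#' @param seed integer seed.
#' @return A validated `sweep_sim_params` list.
#' @export
sweep_sim_params <- function(n_sweeps = 12L,
                             sampling_rate = 20000,
                             duration_s = 0.35,
                             stim_times = c(0.1, 0.12),
                             amp1 = -100,
                             amp2 = -130,
                             tau_rise = 5e-4,
                             tau_decay = 6e-3,
                             noise_sigma = 5,
                             seed = 1L) {
  p <- list(n_sweeps = as.integer(n_sweeps),
            sampling_rate = as.numeric(sampling_rate),
            duration_s = as.numeric(duration_s),
            stim_times = as.numeric(stim_times),
            amp1 = as.numeric(amp1), amp2 = as.numeric(amp2),
            tau_rise = as.numeric(tau_rise),
            tau_decay = as.numeric(tau_decay),
            noise_sigma = as.numeric(noise_sigma),
            seed = as.integer(seed))
  stopifnot(p$n_sweeps >= 1, p$sampling_rate > 0, p$duration_s > 0,
            length(p$stim_times) == 2,
            p$stim_times[1] < p$stim_times[2],
            p$stim_times[2] < p$duration_s,
            p$tau_rise > 0, p$tau_decay > p$tau_rise,
            p$noise_sigma >= 0)
  class(p) <- "sweep_sim_params"
  p
}

# geometry helpers --------------------------------------------------------

# voxel offsets (z,y,x) whose physical ellipsoidal distance is <= 1 for
# semi-axes `radii_um` on grid `vs`
ellipsoid_offsets <- function(radii_um, vs) {
  r_vox <- ceiling(radii_um / vs)
  g <- expand.grid(dz = -r_vox[1]:r_vox[1], dy = -r_vox[2]:r_vox[2],
                   dx = -r_vox[3]:r_vox[3])
  d2 <- (g$dz * vs[1] / radii_um[1])^2 + (g$dy * vs[2] / radii_um[2])^2 +
    (g$dx * vs[3] / radii_um[3])^2
  m <- as.matrix(g[d2 <= 1, , drop = FALSE])
  storage.mode(m) <- "integer"
  m
}

# set mask voxels covered by stamping `offsets` at integer centers (z,y,x)
stamp_offsets <- function(mask, centers, offsets) {
  d <- dim(mask)
  for (i in seq_len(nrow(centers))) {
    z <- centers[i, 1] + offsets[, 1]
    y <- centers[i, 2] + offsets[, 2]
    x <- centers[i, 3] + offsets[, 3]
    ok <- z >= 1 & z <= d[1] & y >= 1 & y <= d[2] & x >= 1 & x <= d[3]
    mask[cbind(z[ok], y[ok], x[ok])] <- TRUE
  }
  mask
}

# greedy selection of candidate voxel centers with a minimum pairwise
# physical separation; returns row indices into `cand`
pick_separated <- function(cand, n, min_sep_um, vs) {
  if (n == 0) return(integer(0))
  if (nrow(cand) == 0) stop("placement failure: no candidate voxels")
  ord <- sample.int(nrow(cand))
  storage.mode(cand) <- "integer"
  chosen <- cpp_pick_separated(cand, ord, as.numeric(vs), min_sep_um,
                               as.integer(n))
  if (length(chosen) < n)
    stop("placement failure: could only place ", length(chosen), " of ", n,
         " objects at the requested separation")
  chosen
}

# generators ---------------------------------------------------------------

#' Generate a ground-truthed two-channel colocalization stack
#'
#' Renders tubular processes and ellipsoidal somas into the `cell` channel
#' (somas twice as bright as processes) and Gaussian puncta into the
#' `puncta` channel. The Poisson-drawn number of on-process puncta is
#' placed on voxels inside the process mask and outside the soma mask —
#' the same definition the measurement pipeline uses after soma removal —
#' and recorded exactly in the ground truth; `puncta_off_count` distractor
#' puncta are kept well clear of any process. Additive Gaussian noise with
#' sigma = 1/snr (object peak = 1) is applied last.
#'
#' @param params a [coloc_sim_params()] object.
#' @return List with `stack` (an [image_stack()] with channels `cell`,
#'   `puncta`) and `truth`: `true_on_process_count`, `true_process_volume`
#'   (um^3, soma-free), `process_mask_true`, `soma_mask_true`,
#'   `puncta_centers_on`, `puncta_centers_off` (voxel coordinates, z/y/x).
#' @export
generate_coloc_stack <- function(params) {
  stopifnot(inherits(params, "coloc_sim_params"))
  d <- params$shape_zyx
  vs <- params$voxel_size_zyx
  fov_um <- d * vs

  if (params$n_somas > 0 && any(2 * params$soma_radii >= fov_um))
    stop("placement failure: soma larger than the field of view")
  if (params$n_processes > 0 && any(2 * params$process_radius >= fov_um))
    stop("placement failure: process diameter exceeds the field of view")

  process_mask <- array(FALSE, dim = d)
  soma_mask <- array(FALSE, dim = d)

  # tubular processes as persistent random walks, stamped with a
  # physically round cross-section on the anisotropic grid
  with_seed(derive_seed(params$seed, "geometry"), {
    if (params$n_processes > 0) {
      tube_off <- ellipsoid_offsets(rep(params$process_radius, 3), vs)
      step_um <- min(vs)
      n_steps <- ceiling(1.2 * max(fov_um) / step_um)
      for (k in seq_len(params$n_processes)) {
        pos <- runif(3, 0.15, 0.85) * fov_um
        # mostly in-plane orientation, like neurites in a thin section
        dir <- c(rnorm(1, 0, 0.2), rnorm(2))
        dir <- dir / sqrt(sum(dir^2))
        centers <- matrix(0L, nrow = n_steps, ncol = 3)
        for (s in seq_len(n_steps)) {
          pos <- pos + dir * step_um
          # reflect at the walls
          for (ax in 1:3) {
            if (pos[ax] < 0) { pos[ax] <- -pos[ax]; dir[ax] <- -dir[ax] }
            if (pos[ax] > fov_um[ax]) {
              pos[ax] <- 2 * fov_um[ax] - pos[ax]; dir[ax] <- -dir[ax]
            }
          }
          dir <- dir + c(rnorm(1, 0, 0.05), rnorm(2, 0, 0.1))
          dir <- dir / sqrt(sum(dir^2))
          centers[s, ] <- pmin(pmax(round(pos / vs + 0.5), 1L), d)
        }
        centers <- unique(centers)
        process_mask <- stamp_offsets(process_mask, centers, tube_off)
      }
    }
    if (params$n_somas > 0) {
      soma_off <- ellipsoid_offsets(params$soma_radii, vs)
      margin <- params$soma_radii / fov_um
      if (any(margin >= 0.5))
        stop("placement failure: soma does not fit inside the stack")
      sc <- matrix(0L, nrow = 0, ncol = 3)
      sep <- 2.2 * max(params$soma_radii)  # somas must not merge
      tries <- 0L
      while (nrow(sc) < params$n_somas) {
        tries <- tries + 1L
        if (tries > 200L * params$n_somas)
          stop("placement failure: cannot place ", params$n_somas,
               " separated somas in the field of view")
        u <- runif(3, margin, 1 - margin)
        cand <- pmin(pmax(round(u * fov_um / vs + 0.5), 1L), d)
        if (nrow(sc) == 0 ||
            min(sqrt(colSums((t(sc * rep(vs, each = nrow(sc))) -
                                cand * vs)^2))) >= sep)
          sc <- rbind(sc, cand)
      }
      soma_mask <- stamp_offsets(soma_mask, sc, soma_off)
    }
  })

  vox_vol <- prod(vs)
  on_support <- process_mask & !soma_mask
  true_volume <- sum(on_support) * vox_vol

  # puncta placement: Poisson count on soma-free process voxels, fixed
  # count of distractors away from processes; all puncta mutually
  # separated so each renders as its own component when noise-free
  min_sep <- max(5 * params$puncta_radius, 2 * max(vs))
  centers_on <- matrix(integer(0), ncol = 3)
  centers_off <- matrix(integer(0), ncol = 3)
  with_seed(derive_seed(params$seed, "placement"), {
    n_on <- if (params$puncta_on_density > 0)
      rpois(1, params$puncta_on_density * true_volume) else 0L
    if (n_on > 0) {
      cand_on <- which(on_support, arr.ind = TRUE)
      centers_on <- cand_on[pick_separated(cand_on, n_on, min_sep, vs), ,
                            drop = FALSE]
    }
    if (params$puncta_off_count > 0) {
      # keep distractors clear of the process surface
      clear_off <- ellipsoid_offsets(
        rep(params$process_radius + 3 * params$puncta_radius, 3), vs)
      near_process <- cpp_dilate_offsets(process_mask | soma_mask,
                                         as.integer(d), clear_off)
      dim(near_process) <- d
      cand_off <- which(!near_process, arr.ind = TRUE)
      keep <- pick_separated(cand_off, params$puncta_off_count,
                             min_sep, vs)
      centers_off <- cand_off[keep, , drop = FALSE]
      # respect separation from on-process puncta too
      if (nrow(centers_on) > 0 && nrow(centers_off) > 0) {
        pos_on <- centers_on * rep(vs, each = nrow(centers_on))
        ok <- vapply(seq_len(nrow(centers_off)), function(i) {
          p <- centers_off[i, ] * vs
          min(sqrt(colSums((t(pos_on) - p)^2))) >= min_sep
        }, logical(1))
        centers_off <- centers_off[ok, , drop = FALSE]
      }
    }
  })

  # render channels
  ch_cell <- array(0, dim = d)
  ch_cell[process_mask] <- 1
  ch_cell[soma_mask] <- 2
  ch_puncta <- array(0, dim = d)
  if (nrow(centers_on) + nrow(centers_off) > 0) {
    r_vox <- ceiling(3 * params$puncta_radius / vs)
    g <- expand.grid(dz = -r_vox[1]:r_vox[1], dy = -r_vox[2]:r_vox[2],
                     dx = -r_vox[3]:r_vox[3])
    d2 <- (g$dz * vs[1])^2 + (g$dy * vs[2])^2 + (g$dx * vs[3])^2
    keep <- d2 <= (3 * params$puncta_radius)^2
    g <- g[keep, , drop = FALSE]
    amp <- exp(-0.5 * d2[keep] / params$puncta_radius^2)
    all_centers <- rbind(centers_on, centers_off)
    for (i in seq_len(nrow(all_centers))) {
      z <- all_centers[i, 1] + g$dz
      y <- all_centers[i, 2] + g$dy
      x <- all_centers[i, 3] + g$dx
      ok <- z >= 1 & z <= d[1] & y >= 1 & y <= d[2] & x >= 1 & x <= d[3]
      idx <- cbind(z[ok], y[ok], x[ok])
      ch_puncta[idx] <- pmax(ch_puncta[idx], amp[ok])
    }
  }

  if (is.finite(params$snr)) {
    sigma <- 1 / params$snr
    with_seed(derive_seed(params$seed, "noise"), {
      ch_cell <- ch_cell + rnorm(length(ch_cell), 0, sigma)
      ch_puncta <- ch_puncta + rnorm(length(ch_puncta), 0, sigma)
    })
    ch_cell[ch_cell < 0] <- 0
    ch_puncta[ch_puncta < 0] <- 0
    dim(ch_cell) <- d
    dim(ch_puncta) <- d
  }

  stack <- image_stack(list(cell = ch_cell, puncta = ch_puncta),
                       voxel_size = vs)
  truth <- list(true_on_process_count = nrow(centers_on),
                true_process_volume = true_volume,
                process_mask_true = process_mask,
                soma_mask_true = soma_mask,
                puncta_centers_on = centers_on,
                puncta_centers_off = centers_off)
  list(stack = stack, truth = truth)
}

#' Simulate a per-cell ISH expression population
#'
#' Draws the per-cell CR / Elfn1 mean intensities that
#' [generate_ish_image()] renders: each cell is CR-positive with
#' probability `cr_pos_fraction`; its CR mean comes from the high (CR+) or
#' low (CR-) mixture component and its Elfn1 mean from the
#' (genotype, CR class) entry of `elfn1_means_by_group`, both with
#' log-normal between-cell scatter of coefficient of variation `cell_cv`.
#'
#' @param params an [ish_sim_params()] object.
#' @param n_cells optionally override `params$n_cells`.
#' @return Data frame with columns `cell`, `cr_true` (logical),
#'   `cr_mean`, `elfn1_mean`.
#' @export
simulate_cell_population <- function(params, n_cells = params$n_cells) {
  stopifnot(inherits(params, "ish_sim_params"))
  n <- as.integer(n_cells)
  em <- params$elfn1_means_by_group[[params$genotype]]
  with_seed(derive_seed(params$seed, "population"), {
    cr_true <- runif(n) < params$cr_pos_fraction
    cr_base <- ifelse(cr_true, params$cr_intensity_means[2],
                      params$cr_intensity_means[1])
    el_base <- ifelse(cr_true, em[["cr_pos"]], em[["cr_neg"]])
    sdlog <- sqrt(log(1 + params$cell_cv^2))
    cr_mean <- cr_base * exp(rnorm(n, -sdlog^2 / 2, sdlog))
    elfn1_mean <- el_base * exp(rnorm(n, -sdlog^2 / 2, sdlog))
    data.frame(cell = seq_len(n), cr_true = cr_true,
               cr_mean = cr_mean, elfn1_mean = elfn1_mean)
  })
}

#' Generate a ground-truthed multi-channel ISH image
#'
#' Places `n_cells` non-overlapping disk cells, then renders four channels:
#' `cell` (uniform label, amplitude 100), `cr` and `elfn1` (each cell
#' filled with its simulated per-cell mean from
#' [simulate_cell_population()]), and `dapi` (nuclei at half the cell
#' radius). Additive Gaussian noise (`noise_sigma`) is applied to every
#' channel. Layer rectangles derived from `layer_boundaries` are returned
#' as a region specification for [assign_regions()].
#'
#' @param params an [ish_sim_params()] object.
#' @return List with `image` (an [image_stack()] of 2D channels `cell`,
#'   `cr`, `elfn1`, `dapi`), `regions` (a [region_spec()]) and `truth`:
#'   per-cell data frame (`y`, `x`, `radius_px`, `cr_true`, `cr_mean`,
#'   `elfn1_mean`), `true_labels`, and `label_mask_true`.
#' @export
generate_ish_image <- function(params) {
  stopifnot(inherits(params, "ish_sim_params"))
  d <- params$image_shape
  n <- params$n_cells
  pop <- simulate_cell_population(params)

  with_seed(derive_seed(params$seed, "placement"), {
    radii <- if (n > 0)
      sample(seq(params$cell_radius_px[1], params$cell_radius_px[2]),
             n, replace = TRUE) else integer(0)
    centers <- matrix(0, nrow = 0, ncol = 2)
    tries <- 0L
    max_tries <- 400L * max(n, 1L)
    for (i in seq_len(n)) {
      placed <- FALSE
      while (!placed) {
        tries <- tries + 1L
        if (tries > max_tries)
          stop("placement failure: cannot place ", n,
               " non-overlapping cells in a ",
               paste(d, collapse = "x"), " image")
        r <- radii[i]
        c_i <- c(runif(1, r + 2, d[1] - r - 1), runif(1, r + 2, d[2] - r - 1))
        if (nrow(centers) == 0 ||
            all(sqrt(rowSums(sweep(centers, 2, c_i)^2)) >
                radii[seq_len(i - 1L)] + r + 2)) {
          centers <- rbind(centers, c_i)
          placed <- TRUE
        }
      }
    }
  })

  render_disks <- function(values, rad) {
    img <- matrix(0, d[1], d[2])
    lbl <- matrix(0L, d[1], d[2])
    for (i in seq_len(nrow(centers))) {
      r <- rad[i]
      ys <- max(1, floor(centers[i, 1] - r)):min(d[1], ceiling(centers[i, 1] + r))
      xs <- max(1, floor(centers[i, 2] - r)):min(d[2], ceiling(centers[i, 2] + r))
      gg <- expand.grid(y = ys, x = xs)
      inside <- (gg$y - centers[i, 1])^2 + (gg$x - centers[i, 2])^2 <= r^2
      idx <- cbind(gg$y[inside], gg$x[inside])
      img[idx] <- values[i]
      lbl[idx] <- i
    }
    list(img = img, lbl = lbl)
  }

  cellr <- render_disks(rep(100, n), radii)
  crr <- render_disks(pop$cr_mean, radii)
  elr <- render_disks(pop$elfn1_mean, radii)
  dapir <- render_disks(rep(80, n), pmax(radii %/% 2L, 2L))

  chans <- list(cell = cellr$img, cr = crr$img, elfn1 = elr$img,
                dapi = dapir$img)
  if (params$noise_sigma > 0) {
    with_seed(derive_seed(params$seed, "noise"), {
      chans <- lapply(chans, function(ch) {
        ch <- ch + rnorm(length(ch), 0, params$noise_sigma)
        ch[ch < 0] <- 0
        matrix(ch, d[1], d[2])
      })
    })
  }

  image <- image_stack(chans, voxel_size = rep(params$pixel_size_um, 2))
  regions <- layers_from_boundaries(d, params$layer_boundaries)
  cells_df <- data.frame(cell = seq_len(n),
                         y = centers[, 1], x = centers[, 2],
                         radius_px = radii,
                         cr_true = pop$cr_true,
                         cr_mean = pop$cr_mean,
                         elfn1_mean = pop$elfn1_mean)
  truth <- list(cells = cells_df, true_labels = pop$cr_true,
                label_mask_true = cellr$lbl)
  list(image = image, regions = regions, truth = truth)
}

#' Generate ground-truthed evoked paired-pulse sweeps
#'
#' Each sweep is `amp1 * g(t - t1) + amp2 * g(t - t2)` plus white noise,
#' where `g` is a difference-of-exponentials transient normalised to unit
#' peak. The second transient rides on the decay of the first, so `amp2`
#' is by construction the amplitude relative to the extrapolated decay —
#' the quantity the summation-corrected measurement recovers.
#'
#' @param params a [sweep_sim_params()] object.
#' @return List with `sweeps` (a [sweep_set()]) and `truth` containing
#'   `true_amps = c(amp1, amp2)` and `true_ppr = amp2/amp1`.
#' @export
generate_sweeps <- function(params) {
  stopifnot(inherits(params, "sweep_sim_params"))
  isi <- diff(params$stim_times)
  if (params$tau_decay >= 10 * isi)
    warning("decay constant >= 10x the interstimulus interval: ",
            "summation makes the second amplitude ill-defined")
  dt <- 1 / params$sampling_rate
  time <- seq(0, params$duration_s - dt, by = dt)
  kern <- function(t) {
    g <- ifelse(t < 0, 0,
                exp(-t / params$tau_decay) - exp(-t / params$tau_rise))
    tpk <- params$tau_rise * params$tau_decay /
      (params$tau_decay - params$tau_rise) *
      log(params$tau_decay / params$tau_rise)
    g / (exp(-tpk / params$tau_decay) - exp(-tpk / params$tau_rise))
  }
  clean <- params$amp1 * kern(time - params$stim_times[1]) +
    params$amp2 * kern(time - params$stim_times[2])
  mat <- matrix(0, nrow = length(time), ncol = params$n_sweeps)
  with_seed(derive_seed(params$seed, "noise"), {
    for (s in seq_len(params$n_sweeps))
      mat[, s] <- clean + if (params$noise_sigma > 0)
        rnorm(length(time), 0, params$noise_sigma) else 0
  })
  sweeps <- sweep_set(current = mat, time = time,
                      sampling_rate = params$sampling_rate,
                      stim_times = params$stim_times)
  truth <- list(true_amps = c(params$amp1, params$amp2),
                true_ppr = params$amp2 / params$amp1)
  list(sweeps = sweeps, truth = truth)
}
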