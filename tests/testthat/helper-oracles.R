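# Independent brute-force oracles used to freeze / verify expected values.

# exhaustive Otsu: maximise between-class variance over every cut of an
# nbins histogram on the min-max range
oracle_otsu_threshold <- function(values, nbins = 256L) {
  v <- as.numeric(values)
  lo <- min(v); hi <- max(v)
  breaks <- seq(lo, hi, length.out = nbins + 1L)
  bin <- pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE), 1L),
              nbins)
  counts <- tabulate(bin, nbins)
  mids <- (breaks[-1] + breaks[-(nbins + 1L)]) / 2
  best <- -Inf; best_cut <- NA
  for (cut in seq_len(nbins - 1L)) {
    n0 <- sum(counts[1:cut]); n1 <- sum(counts) - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(counts[1:cut] * mids[1:cut]) / n0
    mu1 <- sum(counts[(cut + 1):nbins] * mids[(cut + 1):nbins]) / n1
    sb <- (n0 / sum(counts)) * (n1 / sum(counts)) * (mu0 - mu1)^2
    if (sb > best) { best <- sb; best_cut <- cut }
  }
  breaks[best_cut + 1L]
}

# full permutation enumeration of the two-sided Mann-Whitney p value
# (tie-free samples only)
oracle_mw_exact <- function(a, b) {
  n_a <- length(a); n_b <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  idx <- utils::combn(n_a + n_b, n_a)
  us <- apply(idx, 2, function(ii) sum(rank(pooled)[ii]) -
                n_a * (n_a + 1) / 2)
  p_le <- mean(us <= u_obs); p_ge <- mean(us >= u_obs)
  list(U = u_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# winding-number point-in-polygon (different algorithm from the
# implementation's crossing-number test); boundary points count inside
oracle_point_in_poly <- function(py, px, poly) {
  vapply(seq_along(py), function(i) {
    dy <- poly[, 1] - py[i]; dx <- poly[, 2] - px[i]
    ang <- atan2(dy, dx)
    n <- length(ang)
    d <- diff(c(ang, ang[1]))
    d <- ((d + pi) %% (2 * pi)) - pi
    r2 <- dy^2 + dx^2
    if (any(r2 < 1e-18)) return(TRUE)   # on a vertex
    # on an edge: collinear within the segment
    j <- c(2:n, 1)
    cross <- dx * (poly[j, 1] - py[i]) - dy * (poly[j, 2] - px[i])
    dot <- dx * (poly[j, 2] - px[i]) + dy * (poly[j, 1] - py[i])
    if (any(abs(cross) < 1e-9 & dot < 1e-9)) return(TRUE)
    abs(sum(d)) > pi
  }, logical(1))
}

# small, quick-to-generate colocalization stack for unit tests
small_coloc_params <- function(seed = 1L, snr = Inf, n_somas = 0L,
                               n_processes = 6L,
                               puncta_on_density = 0.05,
                               puncta_off_count = 60L,
                               shape_zyx = c(32L, 96L, 96L), ...) {
  coloc_sim_params(shape_zyx = shape_zyx,
                   n_processes = n_processes, n_somas = n_somas,
                   puncta_on_density = puncta_on_density,
                   puncta_off_count = puncta_off_count,
                   snr = snr, seed = seed, ...)
}

# stamp unit-amplitude Gaussian puncta into a channel at voxel centers
# (independent re-implementation of the generator's renderer)
stamp_gaussians <- function(channel, centers, sigma_um, voxel_size) {
  d <- dim(channel)
  r_vox <- ceiling(3 * sigma_um / voxel_size)
  g <- expand.grid(dz = -r_vox[1]:r_vox[1], dy = -r_vox[2]:r_vox[2],
                   dx = -r_vox[3]:r_vox[3])
  d2 <- (g$dz * voxel_size[1])^2 + (g$dy * voxel_size[2])^2 +
    (g$dx * voxel_size[3])^2
  keep <- d2 <= (3 * sigma_um)^2
  g <- g[keep, , drop = FALSE]; amp <- exp(-0.5 * d2[keep] / sigma_um^2)
  for (i in seq_len(nrow(centers))) {
    z <- centers[i, 1] + g$dz; y <- centers[i, 2] + g$dy
    x <- centers[i, 3] + g$dx
    ok <- z >= 1 & z <= d[1] & y >= 1 & y <= d[2] & x >= 1 & x <= d[3]
    idx <- cbind(z[ok], y[ok], x[ok])
    channel[idx] <- pmax(channel[idx], amp[ok])
  }
  channel
}
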