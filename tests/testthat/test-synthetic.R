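test_that("colocalization generator truth is self-consistent", {
  g <- generate_coloc_stack(small_coloc_params(seed = 21, snr = 10,
                                               n_somas = 1L))
  tr <- g$truth

  # every recorded on-process center lies on soma-free process voxels,
  # and their count is the recorded truth (exact self-consistency)
  support <- tr$process_mask_true & !tr$soma_mask_true
  expect_identical(sum(support[tr$puncta_centers_on]),
                   tr$true_on_process_count)
  expect_identical(nrow(tr$puncta_centers_on), tr$true_on_process_count)
  # off-process centers never touch the process mask
  if (nrow(tr$puncta_centers_off) > 0)
    expect_false(any(tr$process_mask_true[tr$puncta_centers_off]))

  # volume bookkeeping
  expect_equal(tr$true_process_volume,
               sum(support) * voxel_volume(g$stack))

  # Poisson-drawn count sits near density * volume
  lam <- 0.05 * tr$true_process_volume
  expect_lt(abs(tr$true_on_process_count - lam), 5 * sqrt(lam) + 3)
})

test_that("colocalization generator honours empty and degenerate settings", {
  p0 <- small_coloc_params(seed = 3, snr = 10, puncta_on_density = 0,
                           puncta_off_count = 0L)
  g0 <- generate_coloc_stack(p0)
  expect_identical(g0$truth$true_on_process_count, 0L)
  # channel 2 is pure noise at sigma = 1/snr
  ch2 <- get_channel(g0$stack, "puncta")
  expect_lt(max(ch2), 8 * (1 / p0$snr))
  expect_false(any(g0$truth$soma_mask_true))  # n_somas = 0 default here

  # objects that cannot fit raise a placement failure
  expect_error(generate_coloc_stack(
    coloc_sim_params(shape_zyx = c(8L, 16L, 16L), n_somas = 1L)),
    "placement failure")
})

test_that("generators are bit-reproducible under a fixed seed", {
  p <- small_coloc_params(seed = 17, snr = 10)
  expect_identical(generate_coloc_stack(p), generate_coloc_stack(p))
  g2 <- generate_coloc_stack(small_coloc_params(seed = 18, snr = 10))
  expect_false(identical(generate_coloc_stack(p)$stack$channels,
                         g2$stack$channels))

  pi1 <- ish_sim_params(seed = 9)
  expect_identical(generate_ish_image(pi1), generate_ish_image(pi1))

  ps <- sweep_sim_params(seed = 5)
  expect_identical(generate_sweeps(ps), generate_sweeps(ps))
})

test_that("ISH population mixture matches the requested CR prior", {
  pall <- ish_sim_params(cr_pos_fraction = 1, seed = 2)
  expect_true(all(simulate_cell_population(pall, 50)$cr_true))

  p <- ish_sim_params(seed = 31)
  pop <- simulate_cell_population(p, 500)
  expect_equal(nrow(pop), 500)
  # binomial tolerance around 400
  expect_lt(abs(sum(pop$cr_true) - 400), 4 * sqrt(500 * 0.8 * 0.2))
  # high component means exceed low on average
  expect_gt(mean(pop$cr_mean[pop$cr_true]), mean(pop$cr_mean[!pop$cr_true]))
})

test_that("ISH image renders each cell with its population intensities", {
  p <- ish_sim_params(n_cells = 12L, noise_sigma = 0, seed = 13)
  g <- generate_ish_image(p)
  expect_identical(length(g$truth$true_labels), 12L)
  expect_equal(max(g$truth$label_mask_true), 12)
  # noise-free: pixel value inside cell i equals its drawn CR mean
  lbl <- g$truth$label_mask_true
  cr <- get_channel(g$image, "cr")
  for (i in c(1, 5, 12)) {
    expect_equal(unname(mean(cr[lbl == i])), g$truth$cells$cr_mean[i],
                 tolerance = 1e-9)
  }
  # overcrowding errors out as a placement failure
  expect_error(generate_ish_image(
    ish_sim_params(image_shape = c(32L, 32L), n_cells = 30L)),
    "placement failure")
})

test_that("equal Elfn1 means across genotypes yield mostly non-significant comparisons", {
  base <- ish_sim_params(elfn1_means_by_group = list(
    control = c(cr_pos = 80, cr_neg = 80), cko = c(cr_pos = 80, cr_neg = 80)))
  hits <- 0L
  for (s in 1:20) {
    a <- vapply(1:8, function(i) mean(simulate_cell_population(
      ish_sim_params(genotype = "control",
                     elfn1_means_by_group = base$elfn1_means_by_group,
                     seed = 100 * s + i), 10)$elfn1_mean), numeric(1))
    b <- vapply(1:8, function(i) mean(simulate_cell_population(
      ish_sim_params(genotype = "cko",
                     elfn1_means_by_group = base$elfn1_means_by_group,
                     seed = 100 * s + 50 + i), 10)$elfn1_mean), numeric(1))
    if (mann_whitney_u(a, b)$p_value < 0.05) hits <- hits + 1L
  }
  expect_lte(hits, 3L)   # ~5 % type-I rate over 20 null draws
})

test_that("sweep generator produces the injected amplitude structure", {
  # single sweep: the average is that sweep
  g1 <- generate_sweeps(sweep_sim_params(n_sweeps = 1L, seed = 2))
  expect_equal(average_sweeps(g1$sweeps), as.vector(g1$sweeps$current[, 1]))

  # noise-free equal amplitudes measure to PPR 1 after summation correction
  g0 <- generate_sweeps(sweep_sim_params(noise_sigma = 0, amp1 = -100,
                                         amp2 = -100))
  expect_equal(measure_ppr(g0$sweeps)$ppr, 1, tolerance = 1e-6)

  # injected (-100, -151) pA gives PPR 1.51
  gf <- generate_sweeps(sweep_sim_params(noise_sigma = 0, amp1 = -100,
                                         amp2 = -151))
  expect_equal(gf$truth$true_ppr, 1.51)
  expect_equal(measure_ppr(gf$sweeps)$ppr, 1.51, tolerance = 0.005)

  # decay comparable to 10x the interstimulus interval warns
  expect_warning(generate_sweeps(sweep_sim_params(tau_decay = 0.25,
                                                  duration_s = 0.6)),
                 "interstimulus")
})
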