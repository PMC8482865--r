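test_that("soma segmentation finds each soma and nothing else", {
  # noise-free stack with two somas: exactly two components, each
  # matching its true ellipsoid closely
  g <- generate_coloc_stack(coloc_sim_params(
    shape_zyx = c(64L, 96L, 96L), n_somas = 2L, n_processes = 6L,
    puncta_on_density = 0.02, puncta_off_count = 100L, snr = Inf,
    seed = 41))
  somas <- segment_somas(g$stack)
  lab <- label_components(somas)
  expect_identical(max(lab), 2L)
  lab_true <- label_components(g$truth$soma_mask_true)
  for (l in seq_len(2)) {
    tm <- lab_true == l
    ious <- vapply(seq_len(max(lab)), function(m) {
      em <- lab == m
      sum(tm & em) / sum(tm | em)
    }, numeric(1))
    expect_gt(max(ious), 0.9)
  }

  # processes alone never create soma components (volume floor)
  g0 <- generate_coloc_stack(small_coloc_params(seed = 42, snr = 10))
  expect_message(s0 <- segment_somas(g0$stack), "empty mask")
  expect_false(any(s0))
})

test_that("process mask removes somas and reports physical volume", {
  g <- generate_coloc_stack(small_coloc_params(seed = 43, snr = 10))
  ch <- get_channel(g$stack, "cell")
  no_soma <- array(FALSE, dim = dim(ch))

  pm <- make_process_mask(g$stack, no_soma)
  expect_identical(unname(pm[seq_along(pm)]),
                   unname(otsu_threshold(ch)$mask[seq_along(pm)]))
  # volume recovered within 15 % of truth at snr 10
  expect_lt(abs(attr(pm, "volume_um3") / g$truth$true_process_volume - 1),
            0.15)

  expect_error(make_process_mask(g$stack, !no_soma), "empty")
})

test_that("colocalization counting follows the AND + components rule", {
  vs <- c(0.5, 0.25, 0.25)
  d <- c(16L, 32L, 32L)
  puncta <- array(FALSE, dim = d)
  puncta[4, 5:6, 5:6] <- TRUE       # component 1
  puncta[10, 12:13, 8] <- TRUE      # component 2
  puncta[14, 28, 28] <- TRUE        # component 3
  procs <- array(FALSE, dim = d)
  procs[1:16, 1:16, 1:16] <- TRUE   # covers components 1-2 only

  # disjoint masks: zero
  far <- array(FALSE, dim = d); far[1, 1, 1] <- TRUE
  expect_identical(count_colocalized(far, puncta,
                                     voxel_size = vs)$n_colocalized, 0L)

  # all-true process mask reduces to the puncta component count
  allp <- array(TRUE, dim = d)
  expect_identical(count_colocalized(allp, puncta,
                                     voxel_size = vs)$n_colocalized, 3L)
  expect_identical(count_colocalized(procs, puncta,
                                     voxel_size = vs)$n_colocalized, 2L)

  # duplicating the stack along an axis doubles count and volume,
  # leaving density unchanged (objects clear of the seam)
  procs2 <- array(FALSE, dim = d * c(2L, 1L, 1L))
  procs2[1:16, , ] <- procs; procs2[17:32, , ] <- procs
  # remove the seam plane so copies stay disjoint
  procs2[16:17, , ] <- FALSE
  puncta2 <- array(FALSE, dim = d * c(2L, 1L, 1L))
  puncta2[1:16, , ] <- puncta; puncta2[17:32, , ] <- puncta
  r1 <- count_colocalized(procs & !(slice.index(procs, 1) %in% 16:17),
                          puncta, voxel_size = vs)
  r2 <- count_colocalized(procs2, puncta2, voxel_size = vs)
  expect_identical(r2$n_colocalized, 2L * r1$n_colocalized)
  expect_equal(r2$process_volume, 2 * r1$process_volume)
  expect_equal(r2$density, r1$density)

  # degenerate volume errors
  expect_error(count_colocalized(array(FALSE, d), puncta, voxel_size = vs),
               "zero")
})

test_that("puncta segmentation recovers isolated puncta and self-matching is neutral", {
  g <- generate_coloc_stack(small_coloc_params(seed = 44))  # noise-free
  ch2 <- get_channel(g$stack, "puncta")
  mask <- segment_puncta(ch2, ch2)
  placed <- nrow(g$truth$puncta_centers_on) + nrow(g$truth$puncta_centers_off)
  expect_identical(max(label_components(mask)), as.integer(placed))

  # histogram matching against itself leaves the Otsu mask unchanged
  expect_identical(mask, filter_small_components(otsu_threshold(ch2)$mask, 4L))
})

test_that("on-process puncta counting recovers generator truth on a noisy stack", {
  g <- generate_coloc_stack(small_coloc_params(
    seed = 45, snr = 20, puncta_on_density = 0.12, n_somas = 1L,
    shape_zyx = c(48L, 96L, 96L)))
  res <- run_coloc_pipeline(g$stack)
  truth_density <- g$truth$true_on_process_count / g$truth$true_process_volume
  expect_lt(abs(res$density / truth_density - 1), 0.2)

  # adding one extra on-process punctum never decreases the count
  tr <- g$truth
  support <- tr$process_mask_true & !tr$soma_mask_true
  cand <- which(support, arr.ind = TRUE)
  # pick a candidate far from existing puncta
  vs <- g$stack$voxel_size
  pos_on <- tr$puncta_centers_on * rep(vs, each = nrow(tr$puncta_centers_on))
  dmin <- vapply(seq_len(nrow(cand)), function(i) {
    p <- cand[i, ] * vs
    min(sqrt(colSums((t(pos_on) - p)^2)))
  }, numeric(1))
  extra <- cand[which.max(dmin), , drop = FALSE]
  ch2b <- stamp_gaussians(get_channel(g$stack, "puncta"), extra,
                          sigma_um = 0.5, voxel_size = vs)
  stack2 <- image_stack(list(cell = get_channel(g$stack, "cell"),
                             puncta = ch2b), voxel_size = vs)
  res2 <- run_coloc_pipeline(stack2)
  expect_gte(res2$n_colocalized, res$n_colocalized)
})

test_that("group comparison of densities uses the exact Mann-Whitney test", {
  a <- lapply(c(1, 2, 3), function(v) coloc_result(v, 1))
  b <- lapply(c(10, 11, 12), function(v) coloc_result(v, 1))
  cmp <- compare_coloc_groups(a, b)
  expect_equal(cmp$test$statistic, 0)
  expect_equal(cmp$test$p_value, 0.1)
  expect_equal(cmp$median_a, 2)

  same <- compare_coloc_groups(c(4, 5, 6), c(4, 5, 6))
  expect_equal(same$test$p_value, 1)
  expect_error(compare_coloc_groups(list(), b), "non-empty")
})
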