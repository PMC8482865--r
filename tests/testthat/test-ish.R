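test_that("cell segmentation recovers every synthetic cell", {
  p <- ish_sim_params(n_cells = 14L, noise_sigma = 0, seed = 51)
  g <- generate_ish_image(p)
  ch <- get_channel(g$image, "cell")
  ct <- segment_cells(ch, pixel_size_um = p$pixel_size_um)
  expect_identical(nrow(ct), 14L)

  # mean IoU against the true label mask
  lbl <- attr(ct, "label_mask")
  true_lbl <- g$truth$label_mask_true
  ious <- vapply(seq_len(nrow(ct)), function(i) {
    em <- lbl == ct$label[i]
    ovl <- table(true_lbl[em & true_lbl > 0])
    tl <- as.integer(names(ovl)[which.max(ovl)])
    tm <- true_lbl == tl
    sum(tm & em) / sum(tm | em)
  }, numeric(1))
  expect_gt(mean(ious), 0.85)

  # doubling all intensities changes no segmentation (Otsu scale property)
  ct2 <- segment_cells(2 * ch, pixel_size_um = p$pixel_size_um)
  expect_identical(attr(ct2, "label_mask"), lbl)

  # blank image: empty table, no error
  expect_message(e <- segment_cells(matrix(0, 64, 64)), "no foreground")
  expect_identical(nrow(e), 0L)
})

test_that("per-cell intensity measurement averages background-subtracted channels", {
  p <- ish_sim_params(n_cells = 10L, noise_sigma = 0, seed = 52)
  g <- generate_ish_image(p)
  ct <- segment_cells(get_channel(g$image, "cell"))

  # uniform channel of value v on zero background: every mean = v
  v <- 77
  uni <- matrix(0, 256, 256)
  uni[attr(ct, "label_mask") > 0] <- v
  m1 <- measure_cell_intensities(ct, list(probe = uni),
                                 background_disk_radius = 10)
  expect_equal(m1$mean_probe, rep(v, nrow(ct)), tolerance = 1e-9)

  # constant image: all means 0 after background subtraction
  m0 <- measure_cell_intensities(ct, list(probe = matrix(9, 256, 256)),
                                 background_disk_radius = 10)
  expect_equal(m0$mean_probe, rep(0, nrow(ct)))

  # measured CR means preserve the true class ordering
  mcr <- measure_cell_intensities(ct, list(cr = get_channel(g$image, "cr")))
  truth <- g$truth$cells
  match_i <- vapply(seq_len(nrow(mcr)), function(i)
    which.min((truth$y - mcr$y[i])^2 + (truth$x - mcr$x[i])^2), integer(1))
  expect_gt(mean(mcr$mean_cr[truth$cr_true[match_i]]),
            mean(mcr$mean_cr[!truth$cr_true[match_i]]))

  expect_error(measure_cell_intensities(ct, list(bad = matrix(0, 10, 10))),
               "shape")
})

test_that("region assignment matches a brute-force point-in-polygon oracle", {
  rs <- layers_from_boundaries(c(100L, 80L), c(20L, 45L, 60L, 80L))
  expect_identical(names(rs$layers), c("L1", "L2/3", "L4", "L5", "L6"))

  df <- data.frame(label = 1:4, y = c(10, 30, 50, 99), x = c(5, 40, 10, 79),
                   area_px = 1L, area_um2 = 1)
  ct <- vipquant:::as_cell_table(df, matrix(0L, 100, 80), 1)
  out <- assign_regions(ct, rs)
  expect_identical(out$layer, c("L1", "L2/3", "L4", "L6"))
  # the row-20.5 centroid sits on the shared L1|L2/3 boundary: the
  # pia-proximal layer wins
  ct_b <- vipquant:::as_cell_table(
    data.frame(label = 1L, y = 20.5, x = 10, area_px = 1L, area_um2 = 1),
    matrix(0L, 100, 80), 1)
  expect_identical(assign_regions(ct_b, rs)$layer, "L1")

  # oracle equivalence on random points against an irregular polygon
  set.seed(6)
  poly <- cbind(y = c(10, 60, 80, 50, 20), x = c(10, 5, 50, 70, 40))
  py <- runif(300, 0, 90); px <- runif(300, 0, 80)
  mine <- vipquant:::point_in_poly(py, px, poly)
  expect_identical(mine, oracle_point_in_poly(py, px, poly))

  # every cell receives exactly one label
  expect_true(all(out$layer != "" & !is.na(out$layer)))
  expect_error(region_spec(list(L1 = cbind(1, 1))), "malformed")
})

test_that("prior-matched CR classification hits the requested fraction", {
  # 10 cells with means 1..10 at prior 0.8: threshold at the 20th
  # percentile, cells 3..10 positive
  tb <- data.frame(mean_cr = 1:10)
  out <- classify_cr(tb, prior = 0.8)
  expect_identical(sum(out$cr_positive), 8L)
  expect_equal(attr(out, "cr_threshold"), quantile(1:10, 0.2, names = FALSE))
  expect_identical(which(out$cr_positive), 3:10)

  # prior -> 1 classifies everything positive
  out1 <- classify_cr(tb, prior = 1 - 1e-9)
  expect_true(all(out1$cr_positive))

  # achieved fraction within 1/n of the prior for tie-free data
  set.seed(7)
  for (pr in c(0.5, 0.7, 0.8, 0.9)) {
    vals <- data.frame(mean_cr = rlnorm(137))
    frac <- mean(classify_cr(vals, prior = pr)$cr_positive)
    expect_lte(abs(frac - pr), 1 / 137 + 1e-12)
  }

  # threshold is antitone in the prior
  v <- data.frame(mean_cr = rlnorm(60))
  th <- vapply(c(0.3, 0.5, 0.8, 0.95), function(pr)
    attr(classify_cr(v, prior = pr), "cr_threshold"), numeric(1))
  expect_true(all(diff(th) <= 0))

  # mixture classification accuracy against generator truth
  pop <- simulate_cell_population(ish_sim_params(seed = 77), 200)
  pop$mean_cr <- pop$cr_mean
  cls <- classify_cr(pop)
  expect_gte(mean(cls$cr_positive == pop$cr_true), 0.95)

  expect_error(classify_cr(data.frame(mean_cr = rep(4, 9))), "identical")
  expect_error(classify_cr(data.frame(mean_cr = 1:3)), "at least 5")
  expect_error(classify_cr(tb, prior = 1.2), "prior")
})

test_that("expression comparison respects subsets, strata and the image unit", {
  mk_table <- function(seed, genotype) {
    pop <- simulate_cell_population(
      ish_sim_params(seed = seed, genotype = genotype), 12)
    df <- data.frame(label = pop$cell, y = seq_len(12), x = seq_len(12),
                     area_px = 1L, area_um2 = 1,
                     mean_cr = pop$cr_mean, mean_elfn1 = pop$elfn1_mean)
    vipquant:::as_cell_table(df, matrix(0L, 4, 4), 1)
  }
  ctrl <- lapply(1:6, function(i) mk_table(300 + i, "control"))
  cko <- lapply(1:6, function(i) mk_table(400 + i, "cko"))

  # identical groups: p = 1
  same <- compare_expression(ctrl, ctrl, "elfn1")
  expect_equal(same$test$p_value, 1)

  # a 2x reduction at image unit is detected
  cmp <- compare_expression(ctrl, cko, "elfn1")
  expect_lt(cmp$test$p_value, 0.05)
  expect_gt(cmp$median_a / cmp$median_b, 1.5)
  expect_identical(cmp$n_a, 6L)

  # CR- subset excludes every CR+ cell
  ctrl_cls <- classify_cr(ctrl)
  neg <- compare_expression(ctrl_cls, ctrl_cls, "elfn1", subset = "cr_neg",
                            unit = "cell")
  n_neg <- sum(vapply(ctrl_cls, function(tb) sum(!tb$cr_positive),
                      integer(1)))
  expect_identical(neg$n_a, n_neg)

  # unknown stratum errors by name
  expect_error(compare_expression(ctrl, cko, "elfn1",
                                  stratum = c(layer = "L2/3")),
               "layer")
})
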