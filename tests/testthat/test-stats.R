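test_that("exact Mann-Whitney p equals full permutation enumeration", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)   # 2 * 1/20 over all C(6,3) arrangements

  set.seed(10)
  for (na in c(1, 3, 5, 7)) {
    for (nb in c(2, 4, 7)) {
      vals <- sample(1000, na + nb)   # tie-free
      a <- vals[seq_len(na)]; b <- vals[-seq_len(na)]
      mine <- mann_whitney_u(a, b)
      orac <- oracle_mw_exact(a, b)
      expect_equal(mine$statistic, orac$U)
      expect_equal(mine$p_value, orac$p, tolerance = 1e-12)
    }
  }

  # and the independent library implementation agrees
  set.seed(11)
  a <- sample(500, 6); b <- sample(setdiff(1:500, a), 5)
  expect_equal(mann_whitney_u(a, b)$p_value,
               wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-12)

  # ties fall back to the corrected normal approximation
  ta <- c(1, 2, 2, 3, 5); tb <- c(2, 3, 3, 4, 6)
  expect_equal(mann_whitney_u(ta, tb)$p_value,
               suppressWarnings(wilcox.test(ta, tb, exact = FALSE,
                                            correct = TRUE)$p.value),
               tolerance = 1e-12)
  expect_equal(mann_whitney_u(1:5, 1:5)$p_value, 1)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
  expect_error(mann_whitney_u(ta, tb, exact = TRUE), "ties")
})

test_that("t tests match closed forms and handle degenerate variances", {
  # Welch on the textbook pair: t = -sqrt(3), hand-computed
  w <- t_tests(c(1, 2, 3, 4), c(2, 4, 6, 8))
  expect_equal(w$statistic, -sqrt(3), tolerance = 1e-12)
  expect_equal(w$df, 1875 / 425, tolerance = 1e-12)
  ref <- t.test(c(1, 2, 3, 4), c(2, 4, 6, 8))
  expect_equal(w$p_value, ref$p.value, tolerance = 1e-12)

  p <- t_tests(c(1, 2, 3), c(0, 2, 5), paired = TRUE)
  refp <- t.test(c(1, 2, 3), c(0, 2, 5), paired = TRUE)
  expect_equal(p$statistic, unname(refp$statistic), tolerance = 1e-12)
  expect_equal(p$p_value, refp$p.value, tolerance = 1e-12)

  # unit change leaves t and p alone
  a <- c(3.2, 4.1, 5.0, 2.8); b <- c(6.0, 5.5, 7.2, 8.1)
  expect_equal(t_tests(10 * a, 10 * b)$statistic, t_tests(a, b)$statistic,
               tolerance = 1e-12)
  expect_equal(t_tests(10 * a, 10 * b)$p_value, t_tests(a, b)$p_value,
               tolerance = 1e-12)

  # degenerate conventions
  expect_equal(t_tests(c(2, 2, 2), c(2, 2, 2), paired = TRUE)$p_value, 1)
  expect_equal(t_tests(c(5, 5), c(5, 5))$p_value, 1)
  expect_error(t_tests(c(1, 1), c(2, 2)), "zero variance")
  expect_error(t_tests(c(1, 2), c(1, 2, 3), paired = TRUE), "equal length")
})

test_that("one-way ANOVA and Bonferroni adjustment match hand computation", {
  g <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(5, 6, 7))
  res <- anova_bonferroni(g)
  # hand decomposition: group means 2,3,6, grand 11/3;
  # SSB = 3*((2-11/3)^2+(3-11/3)^2+(6-11/3)^2) = 26, SSW = 6
  # F = (26/2)/(6/6) = 13
  expect_equal(res$omnibus$statistic, 13, tolerance = 1e-12)
  ref <- summary(stats::aov(v ~ grp,
                            data.frame(v = unlist(g),
                                       grp = rep(names(g), each = 3))))[[1]]
  expect_equal(res$omnibus$p_value, ref[["Pr(>F)"]][1], tolerance = 1e-12)

  # k = 3 pairwise tests: adjusted p = min(1, 3 * raw)
  expect_equal(res$pairwise$p_adjusted,
               pmin(1, 3 * res$pairwise$p_raw))
  expect_true(all(res$pairwise$p_adjusted >= res$pairwise$p_raw))
  expect_true(all(res$pairwise$p_adjusted <= 1))

  # identical groups: F = 0, all adjusted p = 1
  same <- anova_bonferroni(list(x = c(1, 2), y = c(1, 2), z = c(1, 2)))
  expect_equal(same$omnibus$statistic, 0)
  expect_equal(same$omnibus$p_value, 1)
  expect_true(all(same$pairwise$p_adjusted == 1))

  expect_error(anova_bonferroni(list(a = 1, b = c(1, 2))), "n >= 2")
})

test_that("the candidate filter applies the inclusive thresholds", {
  empty <- data.frame(gene = character(0), log2ratio = numeric(0),
                      p_value = numeric(0))
  expect_identical(nrow(filter_candidates(empty)), 0L)

  de <- data.frame(gene = c("g1", "g2", "g3"),
                   log2ratio = c(0.6, 0.4, -0.9),
                   p_value = c(0.005, 0.001, 0.02))
  expect_identical(filter_candidates(de)$gene, "g1")

  # a row exactly at the printed thresholds is kept
  edge <- data.frame(gene = "gx", log2ratio = 0.5, p_value = 0.01)
  expect_identical(nrow(filter_candidates(edge)), 1L)

  # column selector switches between raw and adjusted p
  de$adjusted_p <- c(0.2, 0.001, 0.001)
  expect_identical(nrow(filter_candidates(de, p_column = "adjusted_p")), 1L)
  expect_identical(filter_candidates(de, p_column = "adjusted_p")$gene, "g3")

  expect_error(filter_candidates(data.frame(gene = c("a", "a"),
                                            log2ratio = 1,
                                            p_value = 0.001)), "unique")
})
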