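# Group statistics implemented from closed forms: exact / tie-corrected
# Mann-Whitney U, paired and Welch t tests, one-way ANOVA with
# Bonferroni post hoc, and the differential-expression candidate filter.

#' Two-sample test result
#'
#' @param statistic test statistic.
#' @param p_value p value in [0, 1].
#' @param n_a,n_b sample sizes.
#' @param method description.
#' @param two_sided logical.
#' @param df degrees of freedom where applicable.
#' @return A `test_result` object.
#' @export
test_result <- function(statistic, p_value, n_a, n_b, method,
                        two_sided = TRUE, df = NA_real_) {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-12, n_a >= 1, n_b >= 1)
  structure(list(statistic = statistic, p_value = min(p_value, 1),
                 n_a = n_a, n_b = n_b, method = method,
                 two_sided = two_sided, df = df),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %d, %d)%s\n",
              x$method, x$statistic, x$p_value, x$n_a, x$n_b,
              if (x$two_sided) ", two-sided" else ", one-sided"))
  invisible(x)
}

# exact null distribution of the Mann-Whitney U statistic: counts of
# rank-sum subsets via dynamic programming over the pooled ranks
u_null_counts <- function(n, m) {
  N <- n + m
  maxw <- sum((m + 1):N)            # largest rank sum of a size-n subset
  dp <- matrix(0, nrow = n + 1, ncol = maxw + 1)
  dp[1, 1] <- 1
  for (i in seq_len(N)) {
    for (j in rev(seq_len(min(i, n)))) {
      nz <- which(dp[j, ] > 0)
      dp[j + 1, nz + i] <- dp[j + 1, nz + i] + dp[j, nz]
    }
  }
  w <- dp[n + 1, ]
  minw <- n * (n + 1) / 2
  # index k+1 = count of arrangements with U = k, k = 0..n*m
  w[(minw + 1):(minw + n * m + 1)]
}

#' Mann-Whitney U test
#'
#' Rank-sum test with midranks for ties. The p value is exact (from the
#' full permutation distribution of U, computed by dynamic programming)
#' when there are no ties and `n_a * n_b <= 400`; otherwise the normal
#' approximation with tie correction and continuity correction is used.
#' Two-sided exact p uses the doubled-tail convention
#' `min(1, 2 * min(P(U <= u), P(U >= u)))`.
#'
#' @param sample_a,sample_b numeric samples.
#' @param two_sided logical; one-sided tests the alternative that
#'   `sample_a` tends larger.
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact p value;
#'   `NULL` decides by the rule above. Exact with ties is unavailable.
#' @return A [test_result()]; `statistic` is U for `sample_a`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p_value  # exact 0.1
#' @export
mann_whitney_u <- function(sample_a, sample_b, two_sided = TRUE,
                           exact = NULL) {
  a <- as.numeric(sample_a); b <- as.numeric(sample_b)
  n_a <- length(a); n_b <- length(b)
  if (n_a < 1 || n_b < 1) stop("both samples must be non-empty")
  pooled <- c(a, b)
  r <- rank(pooled)                       # midranks on ties
  U <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0
  use_exact <- if (is.null(exact)) !has_ties && n_a * n_b <= 400 else exact
  if (use_exact && has_ties)
    stop("exact p value is unavailable with ties")

  if (use_exact) {
    counts <- u_null_counts(n_a, n_b)
    tot <- sum(counts)
    p_le <- sum(counts[seq_len(U + 1)]) / tot
    p_ge <- sum(counts[(U + 1):length(counts)]) / tot
    p <- if (two_sided) min(1, 2 * min(p_le, p_ge)) else p_ge
    method <- "Mann-Whitney U (exact)"
  } else {
    N <- n_a + n_b
    mu <- n_a * n_b / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n_a * n_b / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
      z <- 0
    } else {
      cc <- sign(U - mu) * 0.5            # continuity correction
      z <- (U - mu - cc) / sqrt(sigma2)
      p <- if (two_sided) 2 * pnorm(-abs(z)) else pnorm(z, lower.tail = FALSE)
    }
    p <- min(1, p)
    method <- "Mann-Whitney U (normal approximation, tie-corrected)"
  }
  test_result(U, p, n_a, n_b, method, two_sided)
}

#' Paired or Welch two-sample t test
#'
#' Paired: one-sample t on the differences. Unpaired: Welch t assuming
#' unequal variances with Welch-Satterthwaite degrees of freedom. Both
#' two-sided. Degenerate zero-variance inputs with equal means return
#' p = 1 by convention; zero variance with unequal means is an error
#' (the difference is certain, no test applies).
#'
#' @param sample_a,sample_b numeric samples; equal length when paired.
#' @param paired logical.
#' @return A [test_result()] with the t statistic and df.
#' @export
t_tests <- function(sample_a, sample_b, paired = FALSE) {
  a <- as.numeric(sample_a); b <- as.numeric(sample_b)
  if (paired) {
    if (length(a) != length(b)) stop("paired samples must have equal length")
    if (length(a) < 2) stop("need n >= 2")
    d <- a - b
    sdd <- sd(d)
    if (sdd == 0) {
      if (mean(d) == 0)
        return(test_result(0, 1, length(a), length(b),
                           "paired t test (degenerate)", TRUE,
                           df = length(a) - 1))
      stop("zero variance of differences with nonzero mean difference")
    }
    tstat <- mean(d) / (sdd / sqrt(length(d)))
    df <- length(d) - 1
    method <- "paired t test"
  } else {
    if (length(a) < 2 || length(b) < 2) stop("need n >= 2 in each sample")
    v1 <- var(a); v2 <- var(b)
    if (v1 == 0 && v2 == 0) {
      if (mean(a) == mean(b))
        return(test_result(0, 1, length(a), length(b),
                           "Welch t test (degenerate)", TRUE, df = NA_real_))
      stop("zero variance in both samples with unequal means")
    }
    se2 <- v1 / length(a) + v2 / length(b)
    tstat <- (mean(a) - mean(b)) / sqrt(se2)
    df <- se2^2 / (v1^2 / (length(a)^2 * (length(a) - 1)) +
                     v2^2 / (length(b)^2 * (length(b) - 1)))
    method <- "Welch t test"
  }
  p <- 2 * pt(-abs(tstat), df)
  test_result(tstat, p, length(a), length(b), method, TRUE, df = df)
}

#' One-way ANOVA with Bonferroni post hoc tests
#'
#' Computes the one-way F statistic from the between/within variance
#' decomposition, then all pairwise Welch t tests with
#' Bonferroni-multiplied p values capped at 1.
#'
#' @param groups named list of numeric samples (>= 2 groups, each n >= 2;
#'   the omnibus F is conventional for >= 3).
#' @return List with `omnibus` (a [test_result()] holding F) and
#'   `pairwise`, a data frame of pair labels, t, raw and adjusted p.
#' @export
anova_bonferroni <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group", seq_along(groups))
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 2)) stop("every group needs n >= 2")
  k <- length(groups)
  N <- sum(ns)
  grand <- mean(unlist(groups))
  ssb <- sum(ns * (vapply(groups, mean, numeric(1)) - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1; df2 <- N - k
  if (ssw == 0 && ssb == 0) {
    Fstat <- 0; p <- 1
  } else if (ssw == 0) {
    Fstat <- Inf; p <- 0
  } else {
    Fstat <- (ssb / df1) / (ssw / df2)
    p <- pf(Fstat, df1, df2, lower.tail = FALSE)
  }
  omnibus <- test_result(Fstat, p, ns[1], N - ns[1],
                         sprintf("one-way ANOVA F(%d, %d)", df1, df2))
  pairs <- utils::combn(names(groups), 2)
  K <- ncol(pairs)
  pw <- lapply(seq_len(K), function(i) {
    tr <- t_tests(groups[[pairs[1, i]]], groups[[pairs[2, i]]],
                  paired = FALSE)
    data.frame(group_a = pairs[1, i], group_b = pairs[2, i],
               t = tr$statistic, df = tr$df, p_raw = tr$p_value,
               p_adjusted = min(1, K * tr$p_value))
  })
  list(omnibus = omnibus, pairwise = do.call(rbind, pw))
}

#' Filter a differential-expression table for candidate genes
#'
#' Keeps genes with `|log2ratio| >= lfc_min` and p value `<= p_max`
#' (inclusive bounds), preserving row order. The p value column is
#' selectable (raw vs adjusted).
#'
#' @param table data frame with columns `gene`, `log2ratio` and the
#'   chosen p column; gene ids must be unique and p values in [0, 1].
#' @param lfc_min minimum absolute log2 ratio (default 0.5).
#' @param p_max maximum p value (default 0.01).
#' @param p_column which column carries the filtering p value.
#' @return The filtered data frame.
#' @examples
#' de <- data.frame(gene = c("g1", "g2", "g3"),
#'                  log2ratio = c(0.6, 0.4, -0.9),
#'                  p_value = c(0.005, 0.001, 0.02))
#' filter_candidates(de)  # keeps only g1
#' @export
filter_candidates <- function(table, lfc_min = 0.5, p_max = 0.01,
                              p_column = "p_value") {
  stopifnot(is.data.frame(table))
  if (nrow(table) == 0) return(table)
  need <- c("gene", "log2ratio", p_column)
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(table$gene)) stop("gene ids must be unique")
  p <- table[[p_column]]
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must be in [0, 1]")
  keep <- abs(table$log2ratio) >= lfc_min & p <= p_max
  keep[is.na(keep)] <- FALSE
  table[keep, , drop = FALSE]
}
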