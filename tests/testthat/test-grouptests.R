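test_that("Kruskal-Wallis on the hand-computable example gives H = 7.2", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(kw$H, 7.2, tolerance = 1e-12)
  expect_equal(kw$df, 2)
})

test_that("identical groups give H = 0 and p = 1", {
  kw <- kruskal_wallis(list(c(2, 2, 2), c(2, 2, 2)))
  expect_equal(kw$H, 0)
  expect_equal(kw$p_value, 1)
  expect_error(kruskal_wallis(list(1:3)), "2 groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "non-empty")
})

test_that("Kruskal-Wallis matches stats::kruskal.test with and without ties", {
  set.seed(97)
  for (i in 1:30) {
    k <- sample(2:5, 1)
    gr <- lapply(seq_len(k), function(j)
      round(rnorm(sample(3:12, 1)), sample(0:2, 1)))  # rounding makes ties
    mine <- kruskal_wallis(gr)
    ref <- stats::kruskal.test(gr)
    expect_equal(mine$H, unname(ref$statistic), tolerance = 1e-6)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-6)
  }
})

test_that("rank-based tests are invariant under monotone transforms", {
  set.seed(101)
  gr <- lapply(1:3, function(i) rnorm(8, i / 2))
  tr <- lapply(gr, function(x) exp(3 * x) + 1)
  expect_equal(kruskal_wallis(gr)$H, kruskal_wallis(tr)$H, tolerance = 1e-12)
  d1 <- dunn_bonferroni(gr); d2 <- dunn_bonferroni(tr)
  expect_equal(d1$pairs$z, d2$pairs$z, tolerance = 1e-12)
})

test_that("Dunn grid: degenerate pairs, the Bonferroni cap, and the
           two-group equivalence with the KW statistic", {
  same <- dunn_bonferroni(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$pairs$z, 0)
  expect_equal(same$pairs$p_adjusted, 1)

  set.seed(103)
  for (i in 1:20) {
    gr <- list(x = rnorm(sample(3:10, 1)), y = rnorm(sample(3:10, 1), 0.8))
    d <- dunn_bonferroni(gr)
    ref <- stats::kruskal.test(gr)
    # with two groups the squared Dunn z equals the tie-corrected H
    expect_equal(d$pairs$z^2, unname(ref$statistic), tolerance = 1e-6)
    expect_true(all(d$pairs$p_adjusted >= d$pairs$p_raw))
    expect_true(all(d$pairs$p_adjusted <= 1))
  }
  singleton <- dunn_bonferroni(list(a = 1, b = c(2, 3, 4)))
  expect_true(singleton$pairs$low_power)
})

test_that("Dunn z matches an independently coded reference on k groups", {
  dunn_ref <- function(groups) {
    x <- unlist(groups); g <- rep(seq_along(groups), lengths(groups))
    N <- length(x)
    r <- rank(x)
    tie <- table(r)
    correction <- sum(tie^3 - tie) / (12 * (N - 1))
    v <- N * (N + 1) / 12 - correction
    out <- c()
    for (a in 1:(length(groups) - 1)) for (b in (a + 1):length(groups)) {
      num <- mean(r[g == a]) - mean(r[g == b])
      out <- c(out, num / sqrt(v * (1 / sum(g == a) + 1 / sum(g == b))))
    }
    out
  }
  set.seed(107)
  for (i in 1:20) {
    gr <- lapply(1:4, function(j) round(rnorm(sample(4:9, 1), j / 3), 1))
    expect_equal(dunn_bonferroni(gr)$pairs$z, dunn_ref(gr), tolerance = 1e-9)
  }
})

test_that("two-sample t: hand example, symmetry, and agreement with t.test", {
  tt <- two_sample_t(c(0, 2), c(1, 3))
  expect_equal(tt$t, -1 / sqrt(2), tolerance = 1e-12)
  expect_equal(tt$df, 2)

  x <- c(1.2, 0.8, 1.4); y <- c(0.9, 1.1, 1.0, 1.3)
  expect_equal(two_sample_t(x, y)$t, -two_sample_t(y, x)$t, tolerance = 1e-12)
  same <- two_sample_t(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  set.seed(109)
  for (i in 1:30) {
    a <- rnorm(sample(3:15, 1)); b <- rnorm(sample(3:15, 1), 0.4)
    mine_p <- two_sample_t(a, b, "pooled")
    ref_p <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(mine_p$t, unname(ref_p$statistic), tolerance = 1e-6)
    expect_equal(mine_p$p_value, ref_p$p.value, tolerance = 1e-6)
    mine_w <- two_sample_t(a, b, "welch")
    ref_w <- stats::t.test(a, b)
    expect_equal(mine_w$t, unname(ref_w$statistic), tolerance = 1e-6)
    expect_equal(mine_w$df, unname(ref_w$parameter), tolerance = 1e-6)
  }
  expect_error(two_sample_t(1, c(1, 2)), ">= 2")
})

test_that("contact comparison summarises groups and drops missing sCF", {
  scf_tab <- data.frame(marker = paste0("m", 1:8),
                        scf_main = c(60, 55, 58, NA, 35, 30, 40, 33))
  cmap <- data.frame(marker = paste0("m", 1:8),
                     contact = c(rep("contact", 4), rep("non-contact", 4)))
  r <- compare_contact_groups(scf_tab, cmap)
  expect_equal(r$n_dropped_missing, 1)
  expect_equal(r$groups$n, c(3, 4))
  expect_lt(r$p_value, 0.05)
  expect_gt(r$groups$mean_scf[1], r$groups$mean_scf[2])
  # identical groups: p = 1
  flat <- data.frame(marker = paste0("m", 1:4), scf_main = c(40, 50, 40, 50))
  fmap <- data.frame(marker = paste0("m", 1:4),
                     contact = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(compare_contact_groups(flat, fmap)$p_value, 1)
  # emptied group errors
  gone <- data.frame(marker = paste0("m", 1:4), scf_main = c(NA, NA, 40, 50))
  expect_error(compare_contact_groups(gone, fmap), "emptied")
})
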