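# Rank-based clade comparisons and the contact/non-contact marker
# test, implemented from first principles (base R's kruskal.test and
# t.test serve as independent cross-checks in the test suite).

rank_setup <- function(groups) {
  if (length(groups) < 2) stopf("need at least 2 groups")
  if (any(vapply(groups, length, 1L) == 0)) stopf("every group must be non-empty")
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(x)
  ties <- table(x)
  list(x = x, g = g, r = r, N = length(x),
       tie_term = sum(ties^3 - ties))
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic with the chi-square approximation on
#' k - 1 degrees of freedom. When every observation is identical the
#' statistic is defined as 0 (p = 1).
#'
#' @param groups list of numeric vectors, one per group.
#' @return list with `H`, `df`, `p_value`, and the per-group mean
#'   ranks.
#' @export
kruskal_wallis <- function(groups) {
  s <- rank_setup(groups)
  k <- length(groups)
  Rg <- tapply(s$r, s$g, sum)
  ng <- lengths(groups)
  H <- 12 / (s$N * (s$N + 1)) * sum(Rg^2 / ng) - 3 * (s$N + 1)
  C <- 1 - s$tie_term / (s$N^3 - s$N)
  H <- if (C <= 0) 0 else H / C
  H <- max(H, 0)
  list(H = H, df = k - 1,
       p_value = if (H == 0) 1 else stats::pchisq(H, k - 1, lower.tail = FALSE),
       mean_ranks = as.numeric(Rg / ng))
}

#' Dunn's post-hoc test with Bonferroni correction
#'
#' Pairwise z statistics from mean-rank differences with the
#' tie-corrected variance, two-sided p-values, and Bonferroni
#' adjustment over all k(k-1)/2 pairs. Pairs involving a singleton
#' group are computed but flagged low-power.
#'
#' @param groups named list of numeric vectors.
#' @return list of class `pairwise_test_grid`: `pairs` data frame
#'   (`group1`, `group2`, `z`, `p_raw`, `p_adjusted`, `low_power`),
#'   plus the omnibus `H`, `df`, `p_value` from [kruskal_wallis()].
#' @export
dunn_bonferroni <- function(groups) {
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  kw <- kruskal_wallis(groups)
  s <- rank_setup(groups)
  k <- length(groups)
  ng <- lengths(groups)
  mr <- tapply(s$r, s$g, mean)
  var_base <- s$N * (s$N + 1) / 12 - s$tie_term / (12 * (s$N - 1))
  pairs <- utils::combn(k, 2)
  n_pairs <- ncol(pairs)
  rows <- lapply(seq_len(n_pairs), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se <- sqrt(var_base * (1 / ng[a] + 1 / ng[b]))
    z <- if (se == 0) 0 else (mr[a] - mr[b]) / se
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(group1 = names(groups)[a], group2 = names(groups)[b],
               z = as.numeric(z), p_raw = p,
               p_adjusted = min(1, p * n_pairs),
               low_power = ng[a] < 2 || ng[b] < 2)
  })
  structure(list(pairs = do.call(rbind, rows), H = kw$H, df = kw$df,
                 p_value = kw$p_value),
            class = "pairwise_test_grid")
}

#' @export
print.pairwise_test_grid <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis H = %.4g (df = %d, p = %.3g); Dunn/Bonferroni pairs:\n",
              x$H, x$df, x$p_value))
  print(x$pairs, row.names = FALSE)
  invisible(x)
}

#' Two-sample t test
#'
#' Pooled-variance Student t by default (df = n1 + n2 - 2); Welch's
#' unequal-variance variant optionally. Two-sided. When both samples
#' have zero variance and equal means the statistic is defined as 0
#' (p = 1).
#'
#' @param x,y numeric samples (each of size >= 2).
#' @param variant `"pooled"` or `"welch"`.
#' @return list with `t`, `df`, `p_value`, `mean_x`, `mean_y`.
#' @export
two_sample_t <- function(x, y, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stopf("each sample needs >= 2 observations")
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- if (se == 0) n1 + n2 - 2 else
      (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tt <- if (se == 0) { if (mean(x) == mean(y)) 0 else Inf * sign(mean(x) - mean(y)) }
        else (mean(x) - mean(y)) / se
  p <- if (is.infinite(tt)) 0 else 2 * stats::pt(-abs(tt), df)
  list(t = tt, df = df, p_value = p, mean_x = mean(x), mean_y = mean(y))
}

#' Compare sCF between contact and non-contact markers
#'
#' Two-sample t test (pooled Student by default) of the per-marker
#' focal-branch sCF values of markers in direct physical contact with
#' the mitochondrial subunits versus those that are not, with group
#' summaries and the 1/3 plurality threshold annotated.
#'
#' @param scf_table data frame from [scf_per_marker()] (needs columns
#'   `marker` and `scf_main`).
#' @param contact_map data frame with columns `marker` and `contact`
#'   (logical, or the strings "contact"/"non-contact").
#' @param variant passed to [two_sample_t()].
#' @return list with the test result (`t`, `df`, `p_value`), a
#'   `groups` summary data frame (n, mean, median per group), the
#'   number of markers dropped for missing sCF, and
#'   `threshold` = 100/3.
#' @export
compare_contact_groups <- function(scf_table, contact_map,
                                   variant = c("pooled", "welch")) {
  m <- merge(scf_table, contact_map, by = "marker")
  if (!nrow(m)) stopf("no markers shared between sCF table and contact map")
  flag <- m$contact
  if (!is.logical(flag)) flag <- tolower(as.character(flag)) %in% c("contact", "true", "yes", "1")
  dropped <- sum(is.na(m$scf_main))
  keep <- !is.na(m$scf_main)
  x <- m$scf_main[keep & flag]; y <- m$scf_main[keep & !flag]
  if (length(x) < 2 || length(y) < 2)
    stopf("a contact group was emptied by missing sCF values")
  tt <- two_sample_t(x, y, variant)
  summ <- data.frame(group = c("contact", "non-contact"),
                     n = c(length(x), length(y)),
                     mean_scf = c(mean(x), mean(y)),
                     median_scf = c(stats::median(x), stats::median(y)))
  list(t = tt$t, df = tt$df, p_value = tt$p_value, groups = summ,
       n_dropped_missing = dropped, threshold = 100 / 3)
}
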