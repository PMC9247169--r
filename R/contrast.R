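# Sitewise topology contrasts: per-site log-likelihood differences
# between two candidate topologies, strong-site classification,
# aggregation by marker group, and the Shimodaira-Hasegawa test.

#' Per-site log-likelihood difference between two topologies
#'
#' `delta_sls[i] = ll_mt[i] - ll_nuc[i]`: positive values favor the
#' mt-topology, negative the nuc-topology.
#'
#' @param scores a [site_score_table()] data frame, or a list/data
#'   frame holding one numeric log-likelihood vector per label.
#' @param label_mt,label_nuc the two topology labels (columns
#'   `ll_<label>` in a score table).
#' @return numeric vector of per-site differences, with the `partition`
#'   attribute carried over when present.
#' @export
delta_sls <- function(scores, label_mt = "mt", label_nuc = "nuc") {
  get_col <- function(lab) {
    for (nm in c(paste0("ll_", lab), lab))
      if (nm %in% names(scores)) return(scores[[nm]])
    stopf("label '%s' not found in scores", lab)
  }
  a <- get_col(label_mt); b <- get_col(label_nuc)
  if (length(a) != length(b)) stopf("score vectors differ in length")
  out <- a - b
  if (!is.null(scores[["partition"]])) attr(out, "partition") <- scores[["partition"]]
  out
}

#' Classify sites by strength of topology support
#'
#' Sites with a contrast strictly above `threshold` strongly support
#' the mt-topology; strictly below `-threshold`, the nuc-topology;
#' everything else (the boundary included) is weak.
#'
#' @param dsls per-site contrast vector from [delta_sls()].
#' @param threshold positive cutoff (default 0.5 nats).
#' @return list with counts `n_strong_mt`, `n_strong_nuc`, `n_weak`,
#'   `n_sites` and percentages `pct_strong_mt`, `pct_strong_nuc`
#'   (relative to all sites in scope).
#' @export
classify_sites <- function(dsls, threshold = 0.5) {
  if (!length(dsls)) stopf("empty contrast vector")
  if (threshold <= 0) stopf("threshold must be positive")
  n_mt <- sum(dsls > threshold)
  n_nuc <- sum(dsls < -threshold)
  n <- length(dsls)
  list(n_strong_mt = n_mt, n_strong_nuc = n_nuc, n_weak = n - n_mt - n_nuc,
       n_sites = n, pct_strong_mt = 100 * n_mt / n,
       pct_strong_nuc = 100 * n_nuc / n)
}

#' Aggregate sitewise contrasts by marker group
#'
#' Sums the per-site contrast over all sites of each group (markers, or
#' OXPHOS complexes via `group_map`) into a groupwise log-likelihood
#' score, its per-site average, and the strong-site percentages -- the
#' shape of the per-complex signal table.
#'
#' @param dsls contrast vector from [delta_sls()].
#' @param site_partition per-site partition name (defaults to the
#'   `partition` attribute of `dsls`).
#' @param group_map optional data frame with columns `marker`, `group`
#'   mapping partitions to groups; by default every partition is its
#'   own group.
#' @param threshold strong-site cutoff, as in [classify_sites()].
#' @return data frame with one row per group: `group`, `delta_cls`,
#'   `avg_delta_cls`, `pct_strong_mt`, `pct_strong_nuc`, `n_sites`.
#'   Groups with zero sites are dropped with a warning.
#' @export
complex_scores <- function(dsls, site_partition = NULL, group_map = NULL,
                           threshold = 0.5) {
  site_partition <- site_partition %||% attr(dsls, "partition")
  if (is.null(site_partition)) stopf("no site-to-partition map available")
  if (length(site_partition) != length(dsls))
    stopf("site partition map and contrast vector differ in length")
  group <- if (is.null(group_map)) site_partition else {
    g <- group_map$group[match(site_partition, group_map$marker)]
    if (anyNA(g[!is.na(site_partition)]))
      stopf("group_map does not cover every partition")
    g
  }
  keep <- !is.na(group)
  if (!all(keep)) warning("sites without a group were excluded", call. = FALSE)
  dsls <- dsls[keep]; group <- group[keep]
  want <- if (is.null(group_map)) unique(group) else unique(group_map$group)
  empty <- setdiff(want, unique(group))
  if (length(empty))
    warning(sprintf("groups with zero sites excluded: %s",
                    paste(empty, collapse = ", ")), call. = FALSE)
  rows <- lapply(intersect(want, unique(group)), function(g) {
    d <- dsls[group == g]
    cl <- classify_sites(d, threshold)
    data.frame(group = g, delta_cls = sum(d), avg_delta_cls = mean(d),
               pct_strong_mt = cl$pct_strong_mt,
               pct_strong_nuc = cl$pct_strong_nuc, n_sites = length(d))
  })
  do.call(rbind, rows)
}

#' Shimodaira-Hasegawa test from sitewise log-likelihoods
#'
#' RELL implementation: site log-likelihood vectors are resampled with
#' replacement, each tree's resampled deviations are centered at its
#' own mean, and the p-value of a tree is the fraction of resamples in
#' which the centered gap to the (resampled) best tree is at least the
#' observed gap. The best tree has p = 1 by construction. One-sided.
#'
#' @param site_lls matrix (sites x trees) or named list of equal-length
#'   per-site log-likelihood vectors for k >= 2 trees.
#' @param n_resamples RELL bootstrap replicates (default 1000).
#' @param seed integer seed for the resampling.
#' @return data frame with columns `tree`, `loglik`, `delta` (gap to
#'   the best tree) and `p_value`.
#' @export
sh_test <- function(site_lls, n_resamples = 1000L, seed = 1L) {
  if (is.list(site_lls)) {
    if (length(site_lls) < 2) stopf("need at least 2 trees")
    L <- do.call(cbind, site_lls)
  } else L <- as.matrix(site_lls)
  if (ncol(L) < 2) stopf("need at least 2 trees")
  if (is.null(colnames(L))) colnames(L) <- paste0("tree", seq_len(ncol(L)))
  n <- nrow(L); k <- ncol(L)
  tot <- colSums(L)
  best <- which.max(tot)
  delta <- tot[best] - tot
  with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_resamples, replace = TRUE), n)
    # resampled totals per tree: trees x resamples
    R <- vapply(seq_len(k), function(j) colSums(matrix(L[idx, j], n)),
                numeric(n_resamples))
    Rc <- sweep(R, 2, colMeans(R))         # center each tree at its mean
    best_rc <- do.call(pmax.int, lapply(seq_len(k), function(j) Rc[, j]))
    p <- vapply(seq_len(k), function(j)
      mean(best_rc - Rc[, j] >= delta[j]), numeric(1))
    data.frame(tree = colnames(L), loglik = tot, delta = as.numeric(delta),
               p_value = p, row.names = NULL)
  })
}
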