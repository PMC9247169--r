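# Independent oracles and small fixture builders shared across tests.
# The oracles deliberately avoid the package's pruning/sampling code
# paths: likelihoods by explicit enumeration of internal-state
# assignments, sCF by exhaustive iteration over all quartets.

# random unrooted tree with n tips labelled t1..tn
random_tree <- function(n, min_bl = 0.05, max_bl = 0.6) {
  tr <- ape::rtree(n, rooted = FALSE, tip.label = paste0("t", seq_len(n)))
  tr$edge.length <- stats::runif(nrow(tr$edge), min_bl, max_bl)
  tr
}

random_aa_alignment <- function(tree, n_sites) {
  m <- matrix(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]],
                     length(tree$tip.label) * n_sites, replace = TRUE),
              length(tree$tip.label), n_sites,
              dimnames = list(tree$tip.label, NULL))
  alignment(m, "aa")
}

# Brute-force sitewise log-likelihood: sum over every assignment of
# states to internal nodes, averaged over gamma categories.
brute_force_site_ll <- function(tree, model, aln) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  ns <- length(model$states)
  internal <- (ntip + 1):nn
  root <- tree$edge[nrow(tree$edge), 1]
  grid <- as.matrix(expand.grid(rep(list(seq_len(ns)), length(internal))))
  n_sites <- ncol(aln$matrix)
  out <- numeric(n_sites)
  tipsidx <- match(tree$tip.label, rownames(aln$matrix))
  per_cat <- matrix(0, length(model$rates), n_sites)
  for (ci in seq_along(model$rates)) {
    Ps <- lapply(seq_len(nrow(tree$edge)), function(k)
      transition_matrix(model, tree$edge.length[k], model$rates[ci]))
    for (s in seq_len(n_sites)) {
      tipstates <- match(aln$matrix[tipsidx, s], model$states)
      full <- matrix(0L, nrow(grid), nn)
      full[, seq_len(ntip)] <- matrix(tipstates, nrow(grid), ntip, byrow = TRUE)
      full[, internal] <- grid
      p <- model$pi[full[, root]]
      for (k in seq_len(nrow(tree$edge))) {
        e <- tree$edge[k, ]
        p <- p * Ps[[k]][cbind(full[, e[1]], full[, e[2]])]
      }
      per_cat[ci, s] <- sum(p)
    }
  }
  log(colMeans(per_cat))
}

# Exhaustive single-branch sCF: iterate over every (a, b, c, d) quartet
# around the branch and average the per-quartet supporting fractions.
exhaustive_scf <- function(aln, A, B, C, D) {
  fr <- matrix(NA_real_, 0, 3)
  base_ok <- function(x) x %in% strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]] |
    x %in% c("A", "C", "G", "T")
  for (a in A) for (b in B) for (cc in C) for (d in D) {
    s1 <- aln$matrix[a, ]; s2 <- aln$matrix[b, ]
    s3 <- aln$matrix[cc, ]; s4 <- aln$matrix[d, ]
    ok <- base_ok(s1) & base_ok(s2) & base_ok(s3) & base_ok(s4)
    main <- ok & s1 == s2 & s3 == s4 & s1 != s3
    alt1 <- ok & s1 == s3 & s2 == s4 & s1 != s2
    alt2 <- ok & s1 == s4 & s2 == s3 & s1 != s2
    nd <- sum(main | alt1 | alt2)
    if (nd > 0) fr <- rbind(fr, c(sum(main), sum(alt1), sum(alt2)) / nd)
  }
  if (!nrow(fr)) return(rep(NA_real_, 3))
  100 * colMeans(fr)
}

# four-clade leaf map used by most topology fixtures
clade_map_2x4 <- function() list(
  Heterodonta = c("Het_1", "Het_2"), Pteriomorphia = c("Pte_1", "Pte_2"),
  Palaeoheterodonta = c("Pal_1", "Pal_2"), Outgroup = c("Out_1", "Out_2"))
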