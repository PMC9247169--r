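# Site and gene concordance factors around internal branches, by
# seeded quartet sampling over the alignment and by bipartition
# matching over gene trees.

# tips below each edge's child, as a list over edge rows
edge_tip_sets <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  below <- vector("list", ntip + tree$Nnode)
  for (tp in seq_len(ntip)) below[[tp]] <- tree$tip.label[tp]
  for (k in seq_len(nrow(tree$edge)))
    below[[tree$edge[k, 1]]] <- c(below[[tree$edge[k, 1]]],
                                  below[[tree$edge[k, 2]]])
  list(tree = tree, below = below)
}

# For one internal branch (parent u, child v) of an unrooted tree,
# the four surrounding subtree leaf sets: the two clades hanging off v
# and the remaining neighborhoods of u.  Leaf sets are sorted so the
# seeded quartet draws are invariant to input order.
branch_subtrees <- function(tree) {
  et <- edge_tip_sets(tree)
  tree <- et$tree; below <- et$below
  ntip <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  root <- tree$edge[nrow(tree$edge), 1]
  out <- list()
  for (k in seq_len(nrow(tree$edge))) {
    v <- tree$edge[k, 2]
    if (v <= ntip) next                       # pendant edge
    u <- tree$edge[k, 1]
    ck <- kids[[as.character(v)]]
    if (length(ck) != 2) next                 # polytomy below: skip branch
    C <- sort(below[[tree$edge[ck[1], 2]]])
    D <- sort(below[[tree$edge[ck[2], 2]]])
    # the u side: siblings of v plus (unless u is the root) everything above u
    sibs <- setdiff(kids[[as.character(u)]], k)
    side <- lapply(sibs, function(s) below[[tree$edge[s, 2]]])
    if (u != root)
      side <- c(side, list(setdiff(tree$tip.label,
                                   c(below[[v]], unlist(side)))))
    if (length(side) != 2) next
    A <- sort(side[[1]]); B <- sort(side[[2]])
    key <- paste(sort(c(below[[v]], recursive = TRUE))[1],
                 length(below[[v]]), sep = "_")
    out[[length(out) + 1L]] <- list(edge = k, split = sort(below[[v]]),
                                    A = A, B = B, C = C, D = D)
  }
  out
}

# concordance of one branch by quartet sampling; returns the
# BranchConcordance row or NULL when no quartet has a decisive site
sample_branch_scf <- function(mat, br, n_quartets, state_ok) {
  fr <- matrix(NA_real_, 0, 3)
  n_dec <- integer(0)
  for (q in seq_len(n_quartets)) {
    a <- br$A[sample.int(length(br$A), 1)]
    b <- br$B[sample.int(length(br$B), 1)]
    cc <- br$C[sample.int(length(br$C), 1)]
    d <- br$D[sample.int(length(br$D), 1)]
    S <- mat[c(a, b, cc, d), , drop = FALSE]
    ok <- state_ok[S[1, ]] & state_ok[S[2, ]] & state_ok[S[3, ]] & state_ok[S[4, ]]
    s1 <- S[1, ]; s2 <- S[2, ]; s3 <- S[3, ]; s4 <- S[4, ]
    # decisive: exactly two states, each twice (2+2 pattern)
    m12 <- s1 == s2; m34 <- s3 == s4; m13 <- s1 == s3; m24 <- s2 == s4
    m14 <- s1 == s4; m23 <- s2 == s3
    sup_main <- ok & m12 & m34 & !m13
    sup_alt1 <- ok & m13 & m24 & !m12
    sup_alt2 <- ok & m14 & m23 & !m12
    dec <- sup_main | sup_alt1 | sup_alt2
    nd <- sum(dec)
    if (nd == 0) next
    fr <- rbind(fr, c(sum(sup_main), sum(sup_alt1), sum(sup_alt2)) / nd)
    n_dec <- c(n_dec, nd)
  }
  if (!nrow(fr)) return(NULL)
  list(scf = 100 * colMeans(fr), n_used = nrow(fr),
       n_decisive_mean = mean(n_dec))
}

#' Site concordance factors by quartet sampling
#'
#' For every internal branch of `reference_tree` (binary around the
#' branch), quartets are drawn -- one leaf from each of the four
#' surrounding subtrees, uniformly with replacement, seeded -- and each
#' alignment site that shows an unambiguous 2+2 state pattern across
#' the quartet is decisive for one of the three resolutions: the
#' branch itself (`scf_main`) or the two nearest-neighbor alternatives
#' (`scf_alt1` = first-with-third pairing, `scf_alt2` =
#' first-with-fourth). Factors are means over quartets of the
#' percentage of decisive sites supporting each resolution, so the
#' three sum to 100 wherever defined. Quartet identities depend on
#' sorted leaf labels, not input order.
#'
#' @param aln an [alignment()].
#' @param reference_tree a `phylo` whose internal branches are scored.
#' @param n_quartets quartets per branch (default 100).
#' @param seed integer seed.
#' @return data frame, one row per internal branch: `branch` (edge
#'   index in the postorder tree), `split` (semicolon-joined tips of
#'   the branch's child side), `scf_main`, `scf_alt1`, `scf_alt2`,
#'   `n_quartets_used`, `n_decisive_sites_mean`. Branches with no
#'   decisive site in any quartet have `NA` factors.
#' @export
scf <- function(aln, reference_tree, n_quartets = 100L, seed = 1L) {
  if (n_quartets < 1) stopf("n_quartets must be >= 1")
  brs <- branch_subtrees(reference_tree)
  miss <- setdiff(reference_tree$tip.label, rownames(aln$matrix))
  if (length(miss)) stopf("tree taxon absent from alignment: %s", miss[1])
  sets <- state_sets(aln$alphabet)
  unambig <- vapply(names(sets), function(s) length(sets[[s]]) == 1L, TRUE)
  chars <- unique(as.vector(aln$matrix))
  state_ok <- stats::setNames(chars %in% names(sets)[unambig], chars)
  rows <- list()
  {
    for (br in brs) {
      # the quartet draw sequence restarts per branch, so results for a
      # branch do not depend on which other branches are evaluated
      r <- with_seed(seed,
                     sample_branch_scf(aln$matrix, br, n_quartets, state_ok))
      rows[[length(rows) + 1L]] <- data.frame(
        branch = br$edge, split = paste(br$split, collapse = ";"),
        scf_main = if (is.null(r)) NA_real_ else r$scf[1],
        scf_alt1 = if (is.null(r)) NA_real_ else r$scf[2],
        scf_alt2 = if (is.null(r)) NA_real_ else r$scf[3],
        n_quartets_used = if (is.null(r)) 0L else r$n_used,
        n_decisive_sites_mean = if (is.null(r)) NA_real_ else r$n_decisive_mean)
    }
  }
  do.call(rbind, rows)
}

# locate the internal branch whose child-side tip set equals (either
# side of) the given split; errors if absent
find_branch <- function(brs, tree, split_tips) {
  all_tips <- tree$tip.label
  for (i in seq_along(brs)) {
    s <- brs[[i]]$split
    if (setequal(s, split_tips) || setequal(setdiff(all_tips, s), split_tips))
      return(i)
  }
  stopf("focal split not present in the reference tree")
}

#' Per-marker site concordance factor at a focal branch
#'
#' Restricts the quartet-sampled sCF computation to each marker's
#' columns at one focal branch. A marker with no decisive site in any
#' quartet gets `NA` (missing, not zero). The 1/3 reference line --
#' above which a resolution is the plurality choice among the three --
#' is reported in the `threshold` attribute.
#'
#' @inheritParams scf
#' @param focal_split tip labels on one side of the focal branch.
#' @return data frame with columns `marker`, `scf_main`, `scf_alt1`,
#'   `scf_alt2`, `n_quartets_used`; attribute `threshold` = 100/3.
#' @export
scf_per_marker <- function(aln, reference_tree, focal_split,
                           n_quartets = 100L, seed = 1L) {
  if (is.null(aln$partitions)) stopf("alignment has no partition map")
  brs <- branch_subtrees(reference_tree)
  bi <- find_branch(brs, reference_tree, focal_split)
  br <- brs[[bi]]
  sets <- state_sets(aln$alphabet)
  unambig <- vapply(names(sets), function(s) length(sets[[s]]) == 1L, TRUE)
  chars <- unique(as.vector(aln$matrix))
  state_ok <- stats::setNames(chars %in% names(sets)[unambig], chars)
  p <- aln$partitions
  rows <- list()
  {
    for (i in seq_len(nrow(p))) {
      sub <- aln$matrix[, p$start[i]:p$end[i], drop = FALSE]
      # same seed per marker: identical markers get identical quartets
      r <- with_seed(seed, sample_branch_scf(sub, br, n_quartets, state_ok))
      rows[[i]] <- data.frame(
        marker = p$name[i],
        scf_main = if (is.null(r)) NA_real_ else r$scf[1],
        scf_alt1 = if (is.null(r)) NA_real_ else r$scf[2],
        scf_alt2 = if (is.null(r)) NA_real_ else r$scf[3],
        n_quartets_used = if (is.null(r)) 0L else r$n_used)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- 100 / 3
  out
}

#' Gene concordance factors over a set of gene trees
#'
#' For every internal branch of the reference tree, a gene tree is
#' decisive when it contains at least one taxon from each of the four
#' subtrees around the branch, and concordant when its induced
#' bipartition on those taxa reproduces the reference grouping (an
#' unresolved gene tree is decisive but never concordant). gcf = 100 x
#' concordant / decisive; no decisive tree gives `NA`.
#'
#' @param gene_trees list (or `multiPhylo`) of `phylo` objects; taxa
#'   may be subsets of the reference taxa.
#' @param reference_tree a `phylo`.
#' @return data frame with columns `branch`, `split`, `gcf`,
#'   `n_decisive_trees`, `n_concordant_trees`.
#' @export
gcf <- function(gene_trees, reference_tree) {
  if (length(gene_trees) == 0) stopf("empty gene-tree list")
  brs <- branch_subtrees(reference_tree)
  gt_splits <- lapply(gene_trees, function(gt) {
    et <- edge_tip_sets(gt)
    ntip <- length(et$tree$tip.label)
    sp <- lapply(which(et$tree$edge[, 2] > ntip),
                 function(k) sort(et$below[[et$tree$edge[k, 2]]]))
    list(tips = et$tree$tip.label, splits = sp)
  })
  rows <- lapply(brs, function(br) {
    n_dec <- 0L; n_con <- 0L
    for (g in gt_splits) {
      inA <- intersect(br$A, g$tips); inB <- intersect(br$B, g$tips)
      inC <- intersect(br$C, g$tips); inD <- intersect(br$D, g$tips)
      if (!length(inA) || !length(inB) || !length(inC) || !length(inD)) next
      n_dec <- n_dec + 1L
      want1 <- sort(intersect(g$tips, br$split))          # the C+D side
      want2 <- sort(setdiff(g$tips, want1))
      hit <- any(vapply(g$splits, function(s) {
        setequal(s, want1) || setequal(s, want2)
      }, TRUE))
      if (hit) n_con <- n_con + 1L
    }
    data.frame(branch = br$edge, split = paste(br$split, collapse = ";"),
               gcf = if (n_dec == 0) NA_real_ else 100 * n_con / n_dec,
               n_decisive_trees = n_dec, n_concordant_trees = n_con)
  })
  do.call(rbind, rows)
}
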