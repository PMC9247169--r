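# a fixed 4-taxon tree: one internal branch, AB | CD
quartet_tree <- function()
  ape::read.tree(text = "((A:0.1,B:0.1):0.05,C:0.1,D:0.1);")

test_that("perfect branch-matching sites give sCF 100 and closure holds", {
  tr <- quartet_tree()
  m <- matrix(rep(c("A", "A", "R", "R"), 20), 4, 20,
              dimnames = list(c("A", "B", "C", "D"), NULL))
  r <- scf(alignment(m, "aa"), tr, n_quartets = 10, seed = 1)
  expect_equal(nrow(r), 1)
  expect_equal(r$scf_main, 100)
  expect_equal(r$scf_main + r$scf_alt1 + r$scf_alt2, 100, tolerance = 1e-6)
})

test_that("constant alignments have no decisive sites", {
  tr <- quartet_tree()
  m <- matrix("A", 4, 10, dimnames = list(c("A", "B", "C", "D"), NULL))
  r <- scf(alignment(m, "aa"), tr, n_quartets = 5, seed = 1)
  expect_true(is.na(r$scf_main))
  expect_equal(r$n_quartets_used, 0L)
})

test_that("single-quartet sampling equals the exhaustive computation", {
  set.seed(53)
  tr <- quartet_tree()
  m <- matrix(sample(c("A", "R", "N", "-"), 4 * 120, TRUE,
                     prob = c(0.4, 0.3, 0.2, 0.1)), 4, 120,
              dimnames = list(c("A", "B", "C", "D"), NULL))
  aln <- alignment(m, "aa")
  r <- scf(aln, tr, n_quartets = 7, seed = 2)
  ex <- exhaustive_scf(aln, "A", "B", "C", "D")
  expect_equal(c(r$scf_main, r$scf_alt1, r$scf_alt2), ex, tolerance = 1e-10)
})

test_that("sampled sCF converges to the exhaustive value on larger trees", {
  tp <- make_topology_pair(clade_map_2x4(), seed = 61)
  m <- build_model("wag", alpha = 1)
  aln <- simulate_alignment(tp$tree_a, m, 400, seed = 61)
  r <- scf(aln, tp$tree_a, n_quartets = 3000, seed = 3)
  brs <- phylodiscord:::branch_subtrees(tp$tree_a)
  for (i in seq_along(brs)) {
    ex <- exhaustive_scf(aln, brs[[i]]$A, brs[[i]]$B, brs[[i]]$C, brs[[i]]$D)
    expect_equal(r$scf_main[i], ex[1], tolerance = 1.5)
    expect_equal(r$scf_main[i] + r$scf_alt1[i] + r$scf_alt2[i], 100,
                 tolerance = 1e-6)
  }
})

test_that("concordance values ignore alignment row order", {
  tp <- make_topology_pair(clade_map_2x4(), seed = 67)
  m <- build_model("wag", alpha = 1)
  aln <- simulate_alignment(tp$tree_a, m, 150, seed = 67)
  perm <- alignment(aln$matrix[rev(rownames(aln$matrix)), ], "aa")
  r1 <- scf(aln, tp$tree_a, n_quartets = 50, seed = 5)
  r2 <- scf(perm, tp$tree_a, n_quartets = 50, seed = 5)
  expect_equal(r1, r2)
})

test_that("per-marker sCF flags markers without decisive sites as missing", {
  # a clearly planted focal signal, so the branch's own resolution is
  # the plurality choice among the three
  tp <- make_topology_pair(clade_map_2x4(), seed = 71, focal_length = 0.3)
  m <- build_model("wag", alpha = 1)
  a1 <- simulate_alignment(tp$tree_a, m, 300, seed = 71)
  taxa <- rownames(a1$matrix)
  const <- matrix("A", length(taxa), 1, dimnames = list(taxa, NULL))
  mat <- cbind(a1$matrix, const, a1$matrix)
  parts <- data.frame(name = c("strong", "flat", "strong2"),
                      start = c(1L, 301L, 302L), end = c(300L, 301L, 601L))
  aln <- alignment(mat, "aa", parts)
  r <- scf_per_marker(aln, tp$tree_a, tp$focal_split_a,
                      n_quartets = 200, seed = 7)
  expect_true(is.na(r$scf_main[r$marker == "flat"]))
  # duplicated marker content gives identical values
  expect_equal(r$scf_main[r$marker == "strong"],
               r$scf_main[r$marker == "strong2"], tolerance = 1e-10)
  expect_gt(r$scf_main[r$marker == "strong"], 100 / 3)
  expect_equal(attr(r, "threshold"), 100 / 3)
})

test_that("gene concordance counts decisive and concordant trees", {
  tp <- make_topology_pair(clade_map_2x4(), seed = 73)
  ref <- tp$tree_a
  # all gene trees equal to the reference
  g1 <- gcf(rep(list(ref), 6), ref)
  expect_true(all(g1$gcf == 100))
  # half the reference, half the NNI alternative: the focal branch
  # drops to 50, fully shared branches stay at 100
  g2 <- gcf(c(rep(list(tp$tree_a), 3), rep(list(tp$tree_b), 3)), ref)
  focal <- vapply(strsplit(g2$split, ";"), setequal, TRUE, y = tp$focal_split_a)
  expect_equal(g2$gcf[focal], 50)
  expect_true(all(g2$gcf[!focal] == 100))
  # star polytomies are decisive but never concordant
  star <- ape::read.tree(text = paste0("(", paste(ref$tip.label, collapse = ","), ");"))
  g3 <- gcf(list(star, star), ref)
  expect_true(all(g3$gcf == 0))
  expect_true(all(g3$n_decisive_trees == 2))
  expect_error(gcf(list(), ref), "empty")
})

test_that("gene trees missing whole subtrees are not decisive", {
  tp <- make_topology_pair(clade_map_2x4(), seed = 79)
  ref <- tp$tree_a
  pruned <- ape::drop.tip(ref, c("Pal_1", "Pal_2"))
  g <- gcf(list(pruned), ref)
  focalish <- grepl("Pal", g$split)
  expect_true(any(is.na(g$gcf[focalish])))
})
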