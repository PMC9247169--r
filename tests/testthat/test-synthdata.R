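test_that("topology pairs differ by exactly one NNI and share leaves", {
  tp <- make_topology_pair(clade_map_2x4(), seed = 2)
  expect_equal(phangorn::RF.dist(tp$tree_a, tp$tree_b), 2)
  expect_setequal(tp$tree_a$tip.label, tp$tree_b$tip.label)
  # focal resolutions: (Het+Pte) in tree_a, (Het+Pal) in tree_b
  expect_setequal(tp$focal_split_a, c("Het_1", "Het_2", "Pte_1", "Pte_2"))
  expect_setequal(tp$focal_split_b, c("Het_1", "Het_2", "Pal_1", "Pal_2"))
})

test_that("topology construction is deterministic and validates input", {
  t1 <- make_topology_pair(clade_map_2x4(), seed = 9)
  t2 <- make_topology_pair(clade_map_2x4(), seed = 9)
  expect_identical(ape::write.tree(t1$tree_a), ape::write.tree(t2$tree_a))
  expect_identical(ape::write.tree(t1$tree_b), ape::write.tree(t2$tree_b))
  expect_error(make_topology_pair(clade_map_2x4()[1:3]), "4 clades")
  expect_error(make_topology_pair(list(a = "x", b = "y", c = "z", d = "w")),
               "6 leaves")
})

test_that("more than four clades chain as successive outgroups", {
  cl <- c(clade_map_2x4(), list(Extra = c("Ex_1", "Ex_2")))
  tp <- make_topology_pair(cl, seed = 4)
  expect_equal(phangorn::RF.dist(tp$tree_a, tp$tree_b), 2)
  expect_equal(length(tp$tree_a$tip.label), 10)
})

test_that("zero-length branches copy states and simulation is seeded", {
  m <- build_model("poisson", n_categories = 1)
  tr <- ape::read.tree(text = "(A:0.0,B:0.5);")
  # the A branch has length 0, so A must equal the root states; with
  # a two-tip tree, comparing two simulations with the same seed but
  # different B lengths isolates the copy behaviour
  a1 <- simulate_alignment(tr, m, 50, seed = 3)
  tr0 <- ape::read.tree(text = "(A:0.0,B:0.0);")
  a0 <- simulate_alignment(tr0, m, 50, seed = 3)
  expect_identical(a0$matrix["A", ], a0$matrix["B", ])
  a2 <- simulate_alignment(tr, m, 50, seed = 3)
  expect_identical(a1$matrix, a2$matrix)
  tr_neg <- tr; tr_neg$edge.length[2] <- -0.1
  expect_error(simulate_alignment(tr_neg, m, 10), "negative branch")
})

test_that("long branches reach model equilibrium", {
  m <- build_model("wag", alpha = 1, n_categories = 1)
  tr <- ape::read.tree(text = "(A:0.0,B:100);")
  a <- simulate_alignment(tr, m, 10000, seed = 19)
  obs <- table(factor(a$matrix["B", ], levels = m$states))
  gof <- suppressWarnings(stats::chisq.test(obs, p = m$pi))
  expect_gt(gof$p.value, 0.01)
})

test_that("clade shift arithmetic and validation", {
  m <- build_model("gtr-like")
  expect_equal(apply_clade_shift(m, 0)$pi, m$pi)
  m2 <- apply_clade_shift(m, 0.2)
  expect_equal(sum(m2$pi[3:4]), 0.7, tolerance = 1e-12)
  expect_equal(sum(m2$pi), 1, tolerance = 1e-12)
  expect_error(apply_clade_shift(m, 0.6), "0.5")
  skewed <- build_model("gtr-like", pi = c(0.05, 0.05, 0.45, 0.45))
  expect_error(apply_clade_shift(skewed, 0.2), "negative")
})

test_that("shifted-clade simulation raises GT-analog content", {
  tp <- make_topology_pair(clade_map_2x4(), seed = 8)
  m <- build_model("wag", alpha = 1)
  shift <- apply_clade_shift(m, 0.15)
  aln <- simulate_alignment(tp$tree_a, m, 3000, seed = 8,
                            shift_tips = c("Pal_1", "Pal_2"),
                            shift_model = shift)
  targets <- c("F", "L", "V", "C", "W", "G")
  frac <- apply(aln$matrix, 1, function(x) mean(x %in% targets))
  expect_gt(mean(frac[c("Pal_1", "Pal_2")]),
            mean(frac[setdiff(names(frac), c("Pal_1", "Pal_2"))]))
})

test_that("CDS simulation is in-frame, stop-free, and GT-shiftable", {
  code <- genetic_code(5)
  cds <- simulate_cds_alignment(c("x", "y", "z"), 200, default_pos_freqs(),
                                code = code, shift_taxa = "z",
                                shift_delta = 0.2, seed = 5)
  expect_equal(ncol(cds$matrix), 600)
  seqs <- apply(cds$matrix, 1, paste, collapse = "")
  cods <- substring(seqs, seq(1, 598, 3), seq(3, 600, 3))
  expect_false(any(cods %in% code$stops))
  expect_gt(gt_content(seqs["z"]), gt_content(seqs["x"]))
  cds2 <- simulate_cds_alignment(c("x", "y", "z"), 200, default_pos_freqs(),
                                 code = code, shift_taxa = "z",
                                 shift_delta = 0.2, seed = 5)
  expect_identical(cds$matrix, cds2$matrix)
})

test_that("study fixtures carry the six complex groups and round-trip", {
  cfg <- sim_config(n_taxa_per_clade = c(Heterodonta = 2, Pteriomorphia = 2,
                                         Palaeoheterodonta = 2, Outgroup = 2),
                    seed = 21)
  dir1 <- withr::local_tempdir()
  fx <- make_study_fixture(cfg, dir1)
  cmap <- read_tsv(fx$paths$complex_map)
  expect_setequal(unique(cmap$group),
                  c("CV", "CIV", "CIII", "CII", "CI-ms", "CI-ps"))
  parts <- read_partitions(fx$paths$partitions)
  aln <- read_fasta_alignment(fx$paths$concat, "aa",
                              partitions = parts[c("name", "start", "end")])
  expect_identical(aln$matrix, fx$concat$matrix)
  tr <- read_newick(fx$paths$tree_a)
  expect_equal(phangorn::RF.dist(tr, fx$topology$tree_a), 0)
  ann <- read_tsv(fx$paths$annotation)
  expect_true(all(c("taxon", "feature", "start", "end", "strand") %in% names(ann)))

  # same seed, fresh run: identical manifests and identical data files
  dir2 <- withr::local_tempdir()
  fx2 <- make_study_fixture(cfg, dir2)
  expect_identical(readLines(fx$paths$manifest), readLines(fx2$paths$manifest))
  expect_identical(readLines(fx$paths$concat), readLines(fx2$paths$concat))
  expect_identical(readLines(fx$paths$genomes), readLines(fx2$paths$genomes))
})
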