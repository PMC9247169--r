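test_that("FASTA alignments round-trip losslessly", {
  dir <- withr::local_tempdir()
  m <- matrix(sample(c("A", "R", "-", "N"), 3 * 25, TRUE), 3, 25,
              dimnames = list(c("tax3", "tax_two", "tax_1"), NULL))
  aln <- alignment(m, "aa")
  f <- file.path(dir, "a.faa")
  write_fasta_alignment(aln, f)
  back <- read_fasta_alignment(f, "aa")
  expect_identical(back$matrix, aln$matrix)

  writeLines(c(">dup", "ACGT", ">dup", "ACGT"), file.path(dir, "dup.fna"))
  expect_error(read_fasta_alignment(file.path(dir, "dup.fna"), "dna"),
               "duplicate taxon label.*dup")
  writeLines(c(">a", "ACGT", ">b", "ACG"), file.path(dir, "rag.fna"))
  expect_error(read_fasta_alignment(file.path(dir, "rag.fna"), "dna"), "ragged")
})

test_that("Newick parsing keeps branch lengths and internal labels", {
  dir <- withr::local_tempdir()
  txt <- "((A:0.1234567891,B:0.2)inner:0.05,C:0.3);"
  f <- file.path(dir, "t.nwk")
  writeLines(txt, f)
  tr <- read_newick(f)
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  expect_true(any(abs(tr$edge.length - 0.1234567891) < 1e-10))
  plain <- ape::read.tree(text = "((A:0.1,B:0.2):0.05,C:0.3);")
  f2 <- file.path(dir, "t2.nwk")
  write_newick(plain, f2)
  expect_equal(phangorn::RF.dist(read_newick(f2), plain), 0)
})

test_that("partition files use 1-based inclusive ranges", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "p.txt")
  writeLines(c("GENE1 = 1-300", "WAG, GENE2 = 301-450"), f)
  p <- read_partitions(f)
  expect_equal(p$name, c("GENE1", "GENE2"))
  expect_equal(p$start, c(1L, 301L))
  expect_equal(p$end, c(300L, 450L))
  expect_equal(p$model, c(NA, "WAG"))
  write_partitions(p, f)
  expect_identical(read_partitions(f), p)
  writeLines("not a partition line", f)
  expect_error(read_partitions(f), "cannot parse")
})

test_that("alignment container validates its invariants", {
  expect_error(alignment(c("ACGT", "ACG")), "named")
  expect_error(alignment(c(a = "ACGT", b = "ACG"), "dna"), "ragged")
  m <- matrix("A", 2, 4, dimnames = list(c("x", "x"), NULL))
  expect_error(alignment(m, "dna"), "duplicate taxon")
  bad <- data.frame(name = c("p1", "p2"), start = c(1, 3), end = c(3, 4))
  m2 <- matrix("A", 2, 4, dimnames = list(c("x", "y"), NULL))
  expect_error(alignment(m2, "dna", bad), "overlap")
})

test_that("simple indel coding follows the exact-span rules", {
  m <- rbind(t1 = strsplit("ACDE---KLM", "")[[1]],
             t2 = strsplit("ACDE---KLM", "")[[1]],
             t3 = strsplit("ACDEFGHKLM", "")[[1]])
  r <- simple_indel_coding(alignment(m, "aa"))
  expect_equal(nrow(r$characters), 1)
  expect_equal(r$characters$start, 5)
  expect_equal(r$characters$end, 7)
  expect_equal(unname(r$matrix[, 1]), c(1L, 1L, 0L))

  gapless <- alignment(matrix("A", 2, 5, dimnames = list(c("a", "b"), NULL)), "aa")
  expect_equal(ncol(simple_indel_coding(gapless)$matrix), 0)

  # a wider gap spanning the character is inapplicable, not absent
  m2 <- rbind(t1 = strsplit("ACDE---KLM", "")[[1]],
              t2 = strsplit("ACD------M", "")[[1]],
              t3 = strsplit("ACDEFGHKLM", "")[[1]])
  r2 <- simple_indel_coding(alignment(m2, "aa"))
  expect_equal(nrow(r2$characters), 2)
  i57 <- which(r2$characters$start == 5 & r2$characters$end == 7)
  expect_equal(unname(r2$matrix[, i57]), c(1L, NA_integer_, 0L))
  i49 <- which(r2$characters$start == 4 & r2$characters$end == 9)
  expect_equal(unname(r2$matrix[, i49]), c(NA_integer_, 1L, 0L))
})

test_that("the pipeline runs end to end and is deterministic", {
  cfg <- sim_config(n_taxa_per_clade = c(Heterodonta = 2, Pteriomorphia = 2,
                                         Palaeoheterodonta = 2, Outgroup = 2),
                    partitions = {
                      p <- default_oxphos_partitions()
                      p$n_sites <- pmax(40L, as.integer(p$n_sites / 5))
                      p
                    },
                    seed = 5)
  fdir <- withr::local_tempdir()
  fx <- make_study_fixture(cfg, fdir)
  odir <- withr::local_tempdir()
  pc <- pipeline_config(fdir, odir, seed = 5, n_quartets = 40,
                        optimize = TRUE, opt_passes = 2L, opt_tol = 0.1)
  res <- run_pipeline(pc)
  expect_setequal(res$by_complex$group,
                  c("CV", "CIV", "CIII", "CII", "CI-ms", "CI-ps"))
  expect_true(all(file.exists(res$paths)))
  expect_true(all(c("scf_mt", "scf_nuc") %in% names(res$by_complex)))
  expect_equal(nrow(res$sh), 2)
  expect_false(any(is.na(res$sh$p_value)))
  expect_equal(sum(res$by_marker$delta_cls), sum(res$delta_sls), tolerance = 1e-9)

  odir2 <- withr::local_tempdir()
  pc2 <- pipeline_config(fdir, odir2, seed = 5, n_quartets = 40,
                         optimize = TRUE, opt_passes = 2L, opt_tol = 0.1)
  run_pipeline(pc2)
  for (f in c("scores.tsv", "contrast_by_complex.tsv", "scf_per_marker.tsv",
              "composition_tests.tsv"))
    expect_identical(readLines(file.path(odir, f)),
                     readLines(file.path(odir2, f)))
})

test_that("the command-line interface drives the simulate subcommand", {
  cli <- system.file("cli", "phylodiscord.R", package = "phylodiscord")
  expect_true(nzchar(cli))
  out <- file.path(withr::local_tempdir(), "fix")
  r <- system2(file.path(R.home("bin"), "Rscript"),
               c(cli, "simulate", "--out", shQuote(out), "--seed", "3",
                 "--taxa-per-clade", "2"),
               stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(out, "concat.faa")))
  expect_true(file.exists(file.path(out, "manifest.json")))
})
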