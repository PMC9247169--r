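# Indel coding and end-to-end orchestration of the discordance
# analysis: score -> contrast -> concordance -> composition -> tests.

#' Simple indel coding of alignment gaps
#'
#' Every distinct gap (identical start and end columns in at least one
#' taxon) becomes one binary character. A taxon scores 1 when it
#' carries exactly that gap, 0 when it has residues across the span,
#' and missing (`NA`) when a different, overlapping gap makes the
#' character inapplicable.
#'
#' @param aln an [alignment()] (gap character `-`).
#' @return list with `matrix` (taxa x characters; 1/0/`NA`) and
#'   `characters` (data frame of `start`, `end` column spans). A
#'   gapless alignment yields zero characters.
#' @export
simple_indel_coding <- function(aln) {
  m <- aln$matrix
  runs <- lapply(seq_len(nrow(m)), function(i) {
    r <- rle(m[i, ] == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    data.frame(start = starts[r$values], end = ends[r$values])
  })
  chars <- unique(do.call(rbind, runs))
  if (is.null(chars) || nrow(chars) == 0)
    return(list(matrix = matrix(integer(0), nrow(m), 0,
                                dimnames = list(rownames(m), NULL)),
                characters = data.frame(start = integer(0), end = integer(0))))
  chars <- chars[order(chars$start, chars$end), , drop = FALSE]
  rownames(chars) <- NULL
  sc <- matrix(0L, nrow(m), nrow(chars),
               dimnames = list(rownames(m),
                               sprintf("gap_%d_%d", chars$start, chars$end)))
  for (i in seq_len(nrow(m))) {
    ri <- runs[[i]]
    for (j in seq_len(nrow(chars))) {
      exact <- any(ri$start == chars$start[j] & ri$end == chars$end[j])
      if (exact) { sc[i, j] <- 1L; next }
      overlap <- any(ri$start <= chars$end[j] & ri$end >= chars$start[j])
      if (overlap) sc[i, j] <- NA_integer_
    }
  }
  list(matrix = sc, characters = chars)
}

#' Assemble a pipeline configuration from a fixture directory
#'
#' Maps the file layout written by [make_study_fixture()] onto the
#' [run_pipeline()] configuration, with the analysis parameters
#' exposed.
#'
#' @param fixture_dir directory written by [make_study_fixture()].
#' @param out_dir where the pipeline reports go.
#' @param threshold strong-site cutoff for [classify_sites()].
#' @param n_quartets quartets per branch for the concordance stage.
#' @param seed integer seed for every stochastic stage.
#' @param optimize optimize branch lengths on both topologies before
#'   scoring (recommended; the alternative scores the trees as given).
#' @param opt_tol,opt_passes convergence tolerance (nats) and maximum
#'   sweeps for the branch-length optimization.
#' @param code_id genetic code for the composition stage.
#' @return a named list accepted by [run_pipeline()].
#' @export
pipeline_config <- function(fixture_dir, out_dir,
                            threshold = 0.5, n_quartets = 100L, seed = 1L,
                            optimize = TRUE, opt_tol = 0.01, opt_passes = 10L,
                            code_id = 5L) {
  fp <- function(...) file.path(fixture_dir, ...)
  list(aln = fp("concat.faa"), partitions = fp("partitions.txt"),
       tree_mt = fp("tree_a.nwk"), tree_nuc = fp("tree_b.nwk"),
       gene_trees = if (file.exists(fp("gene_trees.nwk"))) fp("gene_trees.nwk"),
       complex_map = fp("marker_complex.tsv"),
       contact_map = fp("marker_contact.tsv"),
       clade_map = fp("clades.tsv"), cds_dir = fp("cds"),
       genomes = fp("genomes.fna"), annotation = fp("annotation.tsv"),
       manifest = if (file.exists(fp("manifest.json"))) fp("manifest.json"),
       out_dir = out_dir, threshold = threshold, n_quartets = n_quartets,
       seed = as.integer(seed), optimize = optimize, opt_tol = opt_tol,
       opt_passes = as.integer(opt_passes), code_id = code_id,
       model_name = "wag", alpha = 0.8)
}

# sCF of one focal branch restricted to a column subset
scf_for_columns <- function(aln, cols, tree, focal_split, n_quartets, seed) {
  brs <- branch_subtrees(tree)
  br <- brs[[find_branch(brs, tree, focal_split)]]
  sets <- state_sets(aln$alphabet)
  unambig <- vapply(names(sets), function(s) length(sets[[s]]) == 1L, TRUE)
  chars <- unique(as.vector(aln$matrix))
  state_ok <- stats::setNames(chars %in% names(sets)[unambig], chars)
  with_seed(seed, {
    r <- sample_branch_scf(aln$matrix[, cols, drop = FALSE], br, n_quartets,
                           state_ok)
    if (is.null(r)) NA_real_ else r$scf[1]
  })
}

#' Run the full discordance analysis
#'
#' Executes, in order: branch-length optimization on both candidate
#' topologies, sitewise scoring, the per-site contrast with strong-site
#' classification and aggregation by marker and by complex (joined
#' with per-complex focal-branch sCF under each topology), the SH test,
#' per-marker sCF with the contact / non-contact comparison, gene
#' concordance when gene trees are supplied, and the composition
#' profile with Kruskal-Wallis + Dunn/Bonferroni clade tests on the
#' coding sequences and the unassigned regions. Every stage writes its
#' TSV/JSON report under `config$out_dir`; a stage failure aborts with
#' the stage name, keeping the reports already written.
#'
#' @param config list from [pipeline_config()] (or hand-built with the
#'   same fields).
#' @return invisibly, a list with every stage's in-memory result and
#'   the report paths.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  res <- list()

  stage("read", {
    parts <- read_partitions(cfg$partitions)
    cmap <- read_tsv(cfg$complex_map)
    aln <- read_fasta_alignment(cfg$aln, "aa",
                                partitions = parts[c("name", "start", "end")])
    tree_mt <- read_newick(cfg$tree_mt)
    tree_nuc <- read_newick(cfg$tree_nuc)
    clade_map <- read_tsv(cfg$clade_map)
    contact_map <- read_tsv(cfg$contact_map)
    res$inputs <- list(parts = parts, aln = aln)
  })

  model <- build_model(cfg$model_name %||% "wag", alpha = cfg$alpha %||% 0.8)

  if (isTRUE(cfg$optimize)) stage("optimize", {
    tree_mt <- optimize_branch_lengths(aln, tree_mt, model,
                                       max_passes = cfg$opt_passes %||% 10L,
                                       tol = cfg$opt_tol %||% 0.01)
    tree_nuc <- optimize_branch_lengths(aln, tree_nuc, model,
                                        max_passes = cfg$opt_passes %||% 10L,
                                        tol = cfg$opt_tol %||% 0.01)
  })

  stage("score", {
    scores <- site_score_table(aln, list(mt = tree_mt, nuc = tree_nuc), model)
    write_tsv(scores, file.path(cfg$out_dir, "scores.tsv"))
    res$scores <- scores
  })

  # focal split of each topology: the resolution of the deep branch
  # distinguishing the two candidates (largest non-shared split)
  focal_mt <- focal_split_between(tree_mt, tree_nuc)
  focal_nuc <- focal_split_between(tree_nuc, tree_mt)

  stage("contrast", {
    d <- delta_sls(scores, "mt", "nuc")
    by_marker <- complex_scores(d, threshold = cfg$threshold %||% 0.5)
    gm <- data.frame(marker = cmap$marker, group = cmap$group)
    by_complex <- complex_scores(d, group_map = gm,
                                 threshold = cfg$threshold %||% 0.5)
    # per-complex sCF under each topology
    sp <- site_partition(aln)
    grp <- gm$group[match(sp, gm$marker)]
    scfs <- vapply(by_complex$group, function(g) {
      cols <- which(!is.na(grp) & grp == g)
      c(scf_for_columns(aln, cols, tree_mt, focal_mt,
                        cfg$n_quartets %||% 100L, cfg$seed + 11L),
        scf_for_columns(aln, cols, tree_nuc, focal_nuc,
                        cfg$n_quartets %||% 100L, cfg$seed + 12L))
    }, numeric(2))
    by_complex$scf_mt <- scfs[1, ]
    by_complex$scf_nuc <- scfs[2, ]
    write_tsv(by_marker, file.path(cfg$out_dir, "contrast_by_marker.tsv"))
    write_tsv(by_complex, file.path(cfg$out_dir, "contrast_by_complex.tsv"))
    res$delta_sls <- d
    res$by_marker <- by_marker
    res$by_complex <- by_complex
  })

  stage("sh_test", {
    sh <- sh_test(list(mt = res$scores$ll_mt, nuc = res$scores$ll_nuc),
                  seed = cfg$seed + 21L)
    write_tsv(sh, file.path(cfg$out_dir, "sh_test.tsv"))
    res$sh <- sh
  })

  stage("concord", {
    per_marker <- scf_per_marker(aln, tree_mt, focal_mt,
                                 n_quartets = cfg$n_quartets %||% 100L,
                                 seed = cfg$seed + 31L)
    write_tsv(per_marker, file.path(cfg$out_dir, "scf_per_marker.tsv"))
    contact <- compare_contact_groups(per_marker, contact_map)
    jsonlite::write_json(contact, file.path(cfg$out_dir, "contact_test.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    res$scf_per_marker <- per_marker
    res$contact <- contact
    if (!is.null(cfg$gene_trees)) {
      gt <- read_newick(cfg$gene_trees)
      if (inherits(gt, "phylo")) gt <- list(gt)
      g <- gcf(gt, tree_mt)
      write_tsv(g, file.path(cfg$out_dir, "gcf.tsv"))
      res$gcf <- g
    }
  })

  stage("compose", {
    code <- genetic_code(cfg$code_id %||% 5L)
    cds_files <- list.files(cfg$cds_dir, pattern = "\\.(fna|fasta|fa)$",
                            full.names = TRUE)
    cds <- lapply(cds_files, read_fasta_alignment, alphabet = "dna")
    names(cds) <- sub("\\.[^.]*$", "", basename(cds_files))
    prof <- composition_table(cds, clade_map, code)
    write_tsv(prof, file.path(cfg$out_dir, "composition.tsv"))
    res$composition <- prof

    stats_cols <- c("at_skew", "gt_content", "gt_rich_codon_freq", "fourfold_gt3")
    grids <- lapply(stats_cols, function(sc) {
      v <- prof[[sc]]
      ok <- !is.na(v)
      gr <- split(v[ok], prof$clade[ok])
      gr <- gr[lengths(gr) > 0]
      dg <- dunn_bonferroni(gr)
      cbind(statistic = sc, dg$pairs,
            H = dg$H, H_p_value = dg$p_value)
    })
    tests <- do.call(rbind, grids)
    write_tsv(tests, file.path(cfg$out_dir, "composition_tests.tsv"))
    res$composition_tests <- tests

    genomes <- as.character(Biostrings::readBStringSet(cfg$genomes))
    names(genomes) <- sub("\\s.*$", "", names(genomes))
    ann <- read_tsv(cfg$annotation)
    ur <- data.frame(taxon = names(genomes),
                     clade = clade_map$clade[match(names(genomes), clade_map$taxon)],
                     ur_gt = vapply(names(genomes), function(tx)
                       ur_gt_content(genomes[[tx]], ann[ann$taxon == tx, ]),
                       numeric(1)))
    write_tsv(ur, file.path(cfg$out_dir, "ur_gt.tsv"))
    ok <- !is.na(ur$ur_gt) & !is.na(ur$clade)
    urg <- split(ur$ur_gt[ok], ur$clade[ok])
    if (length(urg) >= 2 && all(lengths(urg) >= 1)) {
      urt <- dunn_bonferroni(urg)
      write_tsv(cbind(statistic = "ur_gt", urt$pairs, H = urt$H,
                      H_p_value = urt$p_value),
                file.path(cfg$out_dir, "ur_tests.tsv"))
      res$ur_tests <- urt
    }
    res$ur <- ur
  })

  stage("manifest", {
    cfg_json <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE,
                                 null = "null")
    h <- sum(utf8ToInt(cfg_json) * (seq_len(nchar(cfg_json)) %% 97 + 1))
    manifest <- list(seed = cfg$seed, threshold = cfg$threshold,
                     n_quartets = cfg$n_quartets,
                     package_version = as.character(utils::packageVersion("phylodiscord")),
                     config_hash = sprintf("%x", h %% .Machine$integer.max),
                     config = cfg)
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })

  res$paths <- file.path(cfg$out_dir,
                         c("scores.tsv", "contrast_by_marker.tsv",
                           "contrast_by_complex.tsv", "sh_test.tsv",
                           "scf_per_marker.tsv", "contact_test.json",
                           "composition.tsv", "composition_tests.tsv",
                           "ur_gt.tsv", "manifest.json"))
  invisible(res)
}

# tips on the candidate-specific side of the one branch that `tree` has
# and `other` lacks (the focal resolution distinguishing the pair)
focal_split_between <- function(tree, other) {
  et <- edge_tip_sets(tree)
  eo <- edge_tip_sets(other)
  ntip <- length(et$tree$tip.label)
  all_tips <- sort(et$tree$tip.label)
  canon <- function(s) {
    s <- sort(s)
    comp <- sort(setdiff(all_tips, s))
    if (paste(s, collapse = ";") <= paste(comp, collapse = ";")) s else comp
  }
  splits_of <- function(e) {
    idx <- which(e$tree$edge[, 2] > length(e$tree$tip.label))
    lapply(idx, function(k) canon(e$below[[e$tree$edge[k, 2]]]))
  }
  st <- splits_of(et); so <- splits_of(eo)
  keys_o <- vapply(so, paste, "", collapse = ";")
  uniq <- st[!vapply(st, function(s) paste(s, collapse = ";") %in% keys_o, TRUE)]
  if (!length(uniq)) stopf("trees are identical: no focal branch")
  uniq[[1]]
}
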