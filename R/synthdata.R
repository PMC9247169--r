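# Seeded synthetic study fixtures: two candidate resolutions of one
# deep branch, partitioned alignments with planted per-marker signal,
# a clade-specific GT compositional shift, and mock annotated
# mitogenomes with unassigned regions.

#' Build a pair of topologies differing by one NNI at a focal branch
#'
#' Constructs two trees on the same leaves that differ only in the
#' resolution of one deep internal branch: in `tree_a` the focal branch
#' groups the first two clades (the analog of Heterodonta +
#' Pteriomorphia, the "mt-topology"), in `tree_b` it groups the first
#' and third (Heterodonta + Palaeoheterodonta, the "nuc-topology").
#' All other branches, and all branch lengths outside the rearranged
#' branch, are shared, so the unrooted Robinson-Foulds distance between
#' the two trees is exactly 2.
#'
#' @param leaf_labels_by_clade named list (>= 4 clades, each >= 1 leaf,
#'   >= 6 leaves in total) mapping clade label to its tip labels. The
#'   first three clades play the Heterodonta / Pteriomorphia /
#'   Palaeoheterodonta roles; remaining clades are attached as
#'   successive outgroups.
#' @param seed integer seed for the branch-length and subtree draws.
#' @param focal_length length of the focal internal branch (default
#'   0.05, short enough that discrimination is nontrivial).
#' @param mean_branch_length mean of the exponential draw for all other
#'   branches (default 0.1 substitutions/site).
#' @return list with elements `tree_a`, `tree_b` (unrooted `phylo`),
#'   `focal_split_a`, `focal_split_b` (tip sets defining the focal
#'   branch in each tree), and `clades` (the input map).
#' @export
make_topology_pair <- function(leaf_labels_by_clade, seed = 1L,
                               focal_length = 0.05,
                               mean_branch_length = 0.1) {
  cl <- leaf_labels_by_clade
  if (length(cl) < 4) stopf("need at least 4 clades")
  if (any(vapply(cl, length, 1L) < 1)) stopf("every clade needs >= 1 leaf")
  labs <- unlist(cl, use.names = FALSE)
  if (length(labs) < 6) stopf("need at least 6 leaves in total")
  if (anyDuplicated(labs)) stopf("duplicate leaf label across clades")

  with_seed(seed, {
    rlen <- function() stats::rexp(1, 1 / mean_branch_length)
    fmt <- function(x) sprintf("%.10g", x)
    # random binary subtree over a label set; returns "(...)" without
    # an outer branch length
    subtree <- function(tips) {
      nodes <- as.list(tips)
      while (length(nodes) > 1) {
        i <- sample.int(length(nodes), 2)
        merged <- sprintf("(%s:%s,%s:%s)", nodes[[i[1]]], fmt(rlen()),
                          nodes[[i[2]]], fmt(rlen()))
        nodes <- c(nodes[-i], list(merged))
      }
      nodes[[1]]
    }
    sub <- lapply(cl, subtree)
    stems <- replicate(3, rlen())
    # backbone lengths joining outgroup clades
    n_out <- length(cl) - 3L
    back <- replicate(n_out, rlen())
    olen <- replicate(n_out, rlen())

    assemble <- function(first, second, third) {
      focal <- sprintf("(%s:%s,%s:%s):%s", sub[[first]], fmt(stems[1]),
                       sub[[second]], fmt(stems[2]), fmt(focal_length))
      cur <- sprintf("(%s,%s:%s)", focal, sub[[third]], fmt(stems[3]))
      for (i in seq_len(n_out)) {
        cur <- sprintf("(%s:%s,%s:%s)", cur, fmt(back[i]),
                       sub[[3L + i]], fmt(olen[i]))
      }
      ape::unroot(ape::read.tree(text = paste0(cur, ";")))
    }
    tree_a <- assemble(1L, 2L, 3L)
    tree_b <- assemble(1L, 3L, 2L)
    list(tree_a = tree_a, tree_b = tree_b,
         focal_split_a = c(cl[[1]], cl[[2]]),
         focal_split_b = c(cl[[1]], cl[[3]]),
         clades = cl)
  })
}

#' Shift equilibrium mass onto the GT-associated states of a model
#'
#' Returns a model whose equilibrium frequency mass on G and T (for
#' nucleotides) or on the residues encoded by GT-rich codon families
#' (F, L, V, C, W, G; for amino acids) is increased by exactly
#' `shift_delta`, with the remaining states rescaled so the vector
#' still sums to one. Used to emulate a clade-specific compositional
#' shift (the Palaeoheterodonta pattern) as a nonstationary model swap
#' on the shifted clade's branches.
#'
#' @param model a [build_model()] object.
#' @param shift_delta total mass added to the target states, in
#'   `[0, 0.5)`.
#' @return a new `subst_model` with the shifted frequencies.
#' @export
apply_clade_shift <- function(model, shift_delta) {
  if (shift_delta < 0 || shift_delta >= 0.5)
    stopf("shift_delta must be in [0, 0.5)")
  targets <- gt_target_states(model$alphabet)
  pi2 <- shift_gt_mass(model$pi, match(targets, model$states), shift_delta)
  finalize_model(model$alphabet, model$states, model$S, pi2,
                 model$alpha, model$n_categories, model$name)
}

gt_target_states <- function(alphabet) {
  if (alphabet == "dna") c("G", "T") else c("F", "L", "V", "C", "W", "G")
}

# scale target states to mass m + delta and the rest to 1 - m - delta
shift_gt_mass <- function(p, idx, delta) {
  m <- sum(p[idx])
  if (delta == 0) return(p)
  if (m <= 0) stopf("target states have zero mass; cannot shift")
  if (m + delta >= 1) stopf("shift_delta leaves non-target frequencies negative")
  out <- p
  out[idx] <- p[idx] * (m + delta) / m
  out[-idx] <- p[-idx] * (1 - m - delta) / (1 - m)
  out / sum(out)
}

#' Simulate an alignment along a tree
#'
#' Root states are drawn from the model's equilibrium frequencies and
#' evolved down every branch through the model's transition matrices; a
#' discrete-gamma rate category (category means, equal weights) is
#' drawn per site and applied to every branch. Optionally, branches
#' whose descendant tips all lie inside `shift_tips` (including the
#' clade's stem) evolve under `shift_model` instead, giving a
#' nonstationary clade-specific composition shift.
#'
#' @inheritParams site_log_likelihoods
#' @param model substitution model for the background branches.
#' @param n_sites number of columns to simulate.
#' @param seed integer seed.
#' @param shift_tips optional tip labels of the shifted clade.
#' @param shift_model model used on the shifted clade's branches
#'   (defaults to `apply_clade_shift(model, 0.1)` when `shift_tips` is
#'   given).
#' @return an [alignment()] in the model's alphabet.
#' @export
simulate_alignment <- function(tree, model, n_sites, seed = 1L,
                               shift_tips = NULL, shift_model = NULL) {
  if (length(tree$tip.label) < 2) stopf("tree needs at least 2 leaves")
  if (n_sites < 1) stopf("n_sites must be >= 1")
  if (is.null(tree$edge.length)) stopf("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stopf("negative branch length in tree")
  if (!is.null(shift_tips) && is.null(shift_model))
    shift_model <- apply_clade_shift(model, 0.1)

  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  root <- tree$edge[nrow(tree$edge), 1]
  # an edge is inside the shifted clade iff all tips below it are
  shifted_edge <- rep(FALSE, nrow(tree$edge))
  if (!is.null(shift_tips)) {
    below <- vector("list", nn)
    for (tp in seq_len(ntip)) below[[tp]] <- tree$tip.label[tp]
    for (k in seq_len(nrow(tree$edge)))
      below[[tree$edge[k, 1]]] <- c(below[[tree$edge[k, 1]]],
                                    below[[tree$edge[k, 2]]])
    shifted_edge <- vapply(seq_len(nrow(tree$edge)), function(k)
      all(below[[tree$edge[k, 2]]] %in% shift_tips), TRUE)
  }

  ns <- length(model$states)
  with_seed(seed, {
    cats <- sample.int(model$n_categories, n_sites, replace = TRUE)
    st <- matrix(NA_integer_, nn, n_sites)
    st[root, ] <- sample.int(ns, n_sites, replace = TRUE, prob = model$pi)
    for (k in rev(seq_len(nrow(tree$edge)))) {   # preorder
      p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
      mod_k <- if (shifted_edge[k]) shift_model else model
      for (cc in seq_len(model$n_categories)) {
        idx <- which(cats == cc)
        if (!length(idx)) next
        P <- transition_matrix(mod_k, tree$edge.length[k], model$rates[cc])
        for (s in unique(st[p, idx])) {
          ii <- idx[st[p, idx] == s]
          st[ch, ii] <- sample.int(ns, length(ii), replace = TRUE, prob = P[s, ])
        }
      }
    }
    m <- matrix(model$states[st[seq_len(ntip), , drop = FALSE]], ntip, n_sites)
    rownames(m) <- tree$tip.label
    alignment(m, model$alphabet)
  })
}

#' Simulate in-frame coding sequences from positional frequencies
#'
#' Codons are drawn as independent triplets from position-specific
#' nucleotide frequencies; draws that hit a stop codon of `code` are
#' rejected and redrawn. Taxa listed in `shift_taxa` have
#' `shift_delta` of frequency mass moved onto G and T at every codon
#' position before drawing.
#'
#' @param taxa character vector of sequence names.
#' @param n_codons codons per sequence.
#' @param pos_freqs 3 x 4 matrix of nucleotide frequencies (rows =
#'   codon positions, columns = A, C, G, T).
#' @param code a [genetic_code()] (default table 5, invertebrate
#'   mitochondrial).
#' @param shift_taxa taxa receiving the GT shift.
#' @param shift_delta total G+T mass added for shifted taxa.
#' @param seed integer seed.
#' @return an [alignment()] with `alphabet = "dna"`.
#' @export
simulate_cds_alignment <- function(taxa, n_codons, pos_freqs,
                                   code = genetic_code(5L),
                                   shift_taxa = character(), shift_delta = 0.1,
                                   seed = 1L) {
  stopifnot(nrow(pos_freqs) == 3, ncol(pos_freqs) == 4)
  nt <- dna_states()
  with_seed(seed, {
    draw_seq <- function(freqs) {
      n_need <- n_codons
      out <- character(0)
      while (n_need > 0) {
        cod <- paste0(sample(nt, n_need, TRUE, prob = freqs[1, ]),
                      sample(nt, n_need, TRUE, prob = freqs[2, ]),
                      sample(nt, n_need, TRUE, prob = freqs[3, ]))
        keep <- !(cod %in% code$stops)
        out <- c(out, cod[keep])
        n_need <- n_codons - length(out)
      }
      paste(out, collapse = "")
    }
    seqs <- vapply(taxa, function(tx) {
      f <- pos_freqs
      if (tx %in% shift_taxa)
        for (r in 1:3) f[r, ] <- shift_gt_mass(f[r, ], c(3L, 4L), shift_delta)
      draw_seq(f)
    }, character(1))
    alignment(seqs, "dna")
  })
}

#' Default synthetic-study configuration
#'
#' The defaults emulate the structure of a bivalve mt/nu-OXPHOS study:
#' four clades of three taxa (Heterodonta, Pteriomorphia,
#' Palaeoheterodonta, and outgroups), the thirteen mitochondrial OXPHOS
#' markers plus two nuclear CII markers at realistic protein lengths,
#' grouped into the six complex groups CV, CIV, CIII, CII, CI-ms and
#' CI-ps, all simulated on `tree_a` with a stronger focal-branch signal
#' in the contact-labelled markers, and a Palaeoheterodonta-specific GT
#' shift of 0.1 in both the amino-acid and nucleotide generators.
#'
#' @param n_taxa_per_clade taxa per clade (named or unnamed length-4+).
#' @param partitions data frame with columns `name`, `n_sites`,
#'   `group`, `contact`, `focal_scale`, `tree`; `NULL` for the default
#'   OXPHOS marker set.
#' @param alpha gamma shape used by the amino-acid simulator.
#' @param model_name amino-acid model for simulation/scoring.
#' @param shift_clade clade label receiving the GT shift.
#' @param shift_delta total GT mass added in the shifted clade.
#' @param seed integer seed controlling every draw.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_taxa_per_clade = c(Heterodonta = 3, Pteriomorphia = 3,
                                            Palaeoheterodonta = 3, Outgroup = 3),
                       partitions = NULL, alpha = 0.8, model_name = "wag",
                       shift_clade = "Palaeoheterodonta", shift_delta = 0.1,
                       seed = 1L) {
  if (is.null(names(n_taxa_per_clade)))
    names(n_taxa_per_clade) <- paste0("clade", seq_along(n_taxa_per_clade))
  if (length(n_taxa_per_clade) < 4) stopf("need at least 4 clades")
  if (is.null(partitions)) partitions <- default_oxphos_partitions()
  need <- c("name", "n_sites", "group", "contact", "focal_scale", "tree")
  if (!all(need %in% names(partitions)))
    stopf("partitions must have columns %s", paste(need, collapse = ", "))
  if (any(partitions$n_sites < 1)) stopf("all partition lengths must be positive")
  if (!shift_clade %in% names(n_taxa_per_clade))
    stopf("shift_clade must be one of the clade labels")
  if (shift_delta < 0 || shift_delta >= 0.5)
    stopf("shift_delta must be in [0, 0.5)")
  structure(list(n_taxa_per_clade = n_taxa_per_clade, partitions = partitions,
                 alpha = alpha, model_name = model_name,
                 shift_clade = shift_clade, shift_delta = shift_delta,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default mitochondrial-OXPHOS marker panel
#'
#' Thirteen mitochondrial OXPHOS markers plus two nuclear CII markers
#' at realistic protein lengths, grouped into the six complex groups
#' CV, CIV, CIII, CII, CI-ms (nadh1, 2, 6) and CI-ps (nadh3, 4, 4l, 5).
#'
#' @return a partitions data frame accepted by [sim_config()].
#' @export
default_oxphos_partitions <- function() {
  mk <- function(name, n, group, contact, scale = 1)
    data.frame(name = name, n_sites = n, group = group, contact = contact,
               focal_scale = scale, tree = "a")
  rbind(
    mk("atp6", 220, "CV", TRUE), mk("atp8", 55, "CV", TRUE),
    mk("cox1", 510, "CIV", TRUE), mk("cox2", 225, "CIV", TRUE),
    mk("cox3", 260, "CIV", TRUE),
    mk("cytb", 370, "CIII", TRUE),
    mk("nadh1", 310, "CI-ms", TRUE), mk("nadh2", 330, "CI-ms", TRUE),
    mk("nadh6", 160, "CI-ms", TRUE),
    mk("nadh3", 115, "CI-ps", FALSE, 0.25),
    mk("nadh4", 450, "CI-ps", FALSE, 0.25),
    mk("nadh4l", 95, "CI-ps", FALSE, 0.25),
    mk("nadh5", 560, "CI-ps", FALSE, 0.25),
    mk("sdha", 600, "CII", FALSE, 0.25), mk("sdhb", 270, "CII", FALSE, 0.25))
}

#' Nuclear-OXPHOS-like marker panel for contact analyses
#'
#' A marker panel mirroring the structure of the nuclear OXPHOS
#' dataset used for the contact / non-contact comparison: 24 markers in
#' direct physical contact with the mitochondrial subunits, simulated
#' with a strong focal-branch signal, and 31 non-contact markers with a
#' weak one. Complex labels rotate over CI and CIII-CV for the contact
#' set (CII, the all-nuclear complex, is non-contact by definition).
#'
#' @param n_contact,n_noncontact marker counts per group.
#' @param n_sites amino-acid sites per marker.
#' @param contact_scale,noncontact_scale multipliers applied to the
#'   focal branch when simulating each group.
#' @return a partitions data frame accepted by [sim_config()].
#' @export
default_nuox_partitions <- function(n_contact = 24, n_noncontact = 31,
                                    n_sites = 150, contact_scale = 2,
                                    noncontact_scale = 0.25) {
  cx_contact <- rep(c("CI", "CIII", "CIV", "CV"), length.out = n_contact)
  cx_non <- rep(c("CI", "CII", "CIII", "CIV", "CV"), length.out = n_noncontact)
  rbind(
    data.frame(name = sprintf("nuc%02d", seq_len(n_contact)),
               n_sites = n_sites, group = cx_contact, contact = TRUE,
               focal_scale = contact_scale, tree = "a"),
    data.frame(name = sprintf("nun%02d", seq_len(n_noncontact)),
               n_sites = n_sites, group = cx_non, contact = FALSE,
               focal_scale = noncontact_scale, tree = "a"))
}

#' Default mitochondrial-like positional nucleotide frequencies
#'
#' A 3 x 4 matrix (codon position x A, C, G, T) of AT-rich,
#' GT-leaning frequencies used by the CDS simulator.
#'
#' @return numeric matrix consumed by [simulate_cds_alignment()].
#' @export
default_pos_freqs <- function()
  matrix(c(0.25, 0.12, 0.28, 0.35,
           0.19, 0.20, 0.16, 0.45,
           0.30, 0.10, 0.20, 0.40),
         nrow = 3, byrow = TRUE,
         dimnames = list(paste0("pos", 1:3), c("A", "C", "G", "T")))

#' Generate the complete on-disk study fixture
#'
#' Simulates every partition of `config` on its designated topology
#' (with the focal branch scaled per marker and the GT shift applied on
#' the shifted clade's branches), plus per-marker coding sequences and
#' one mock annotated mitogenome per taxon, and writes the whole file
#' set: per-marker FASTA, concatenated matrix + partition file, Newick
#' trees, gene trees, marker-to-complex and marker-to-contact TSVs,
#' taxon-to-clade TSV, CDS FASTA, genome FASTA + annotation table, and
#' a JSON manifest recording the seed and the generating truth.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with the in-memory objects (`concat`
#'   alignment, `topology` pair, `cds` alignments, `genomes`,
#'   `annotation`) and `paths` to everything written.
#' @export
make_study_fixture <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stopf("cannot create output directory %s", out_dir)

  clades <- lapply(seq_along(config$n_taxa_per_clade), function(i)
    sprintf("%s_%d", names(config$n_taxa_per_clade)[i],
            seq_len(config$n_taxa_per_clade[i])))
  names(clades) <- names(config$n_taxa_per_clade)
  topo <- make_topology_pair(clades, seed = config$seed)
  shift_tips <- clades[[config$shift_clade]]

  base <- build_model(config$model_name, alpha = config$alpha)
  shifted <- apply_clade_shift(base, config$shift_delta)

  parts <- config$partitions
  focal_edge_scaled <- function(tree, split_tips, scale) {
    scale_focal_branch(tree, split_tips, scale)
  }
  alns <- vector("list", nrow(parts))
  for (i in seq_len(nrow(parts))) {
    tr <- if (parts$tree[i] == "a") topo$tree_a else topo$tree_b
    split_tips <- if (parts$tree[i] == "a") topo$focal_split_a else topo$focal_split_b
    tr <- focal_edge_scaled(tr, split_tips, parts$focal_scale[i])
    alns[[i]] <- simulate_alignment(tr, base, parts$n_sites[i],
                                    seed = config$seed * 1000L + i,
                                    shift_tips = shift_tips,
                                    shift_model = shifted)
  }
  names(alns) <- parts$name

  taxa <- rownames(alns[[1]]$matrix)
  concat_mat <- do.call(cbind, lapply(alns, function(a) a$matrix[taxa, , drop = FALSE]))
  ends <- cumsum(parts$n_sites)
  pmap <- data.frame(name = parts$name, start = c(1L, utils::head(ends, -1) + 1L),
                     end = ends, group = parts$group)
  concat <- alignment(concat_mat, "aa", pmap)

  code <- genetic_code(5L)
  cds <- lapply(seq_len(nrow(parts)), function(i)
    simulate_cds_alignment(taxa, parts$n_sites[i], default_pos_freqs(),
                           code = code, shift_taxa = shift_tips,
                           shift_delta = config$shift_delta,
                           seed = config$seed * 2000L + i))
  names(cds) <- parts$name

  gen <- simulate_genomes(taxa, cds, parts, shift_tips, config)

  # write everything
  p <- list()
  mdir <- file.path(out_dir, "markers"); dir.create(mdir, showWarnings = FALSE)
  cdir <- file.path(out_dir, "cds"); dir.create(cdir, showWarnings = FALSE)
  for (nm in parts$name) {
    write_fasta_alignment(alns[[nm]], file.path(mdir, paste0(nm, ".faa")))
    write_fasta_alignment(cds[[nm]], file.path(cdir, paste0(nm, ".fna")))
  }
  p$concat <- file.path(out_dir, "concat.faa")
  write_fasta_alignment(concat, p$concat)
  p$partitions <- file.path(out_dir, "partitions.txt")
  write_partitions(pmap, p$partitions)
  p$tree_a <- file.path(out_dir, "tree_a.nwk"); write_newick(topo$tree_a, p$tree_a)
  p$tree_b <- file.path(out_dir, "tree_b.nwk"); write_newick(topo$tree_b, p$tree_b)
  p$gene_trees <- file.path(out_dir, "gene_trees.nwk")
  gts <- lapply(parts$tree, function(w) if (w == "a") topo$tree_a else topo$tree_b)
  class(gts) <- "multiPhylo"
  write_newick(gts, p$gene_trees)
  p$complex_map <- file.path(out_dir, "marker_complex.tsv")
  write_tsv(data.frame(marker = parts$name, group = parts$group), p$complex_map)
  p$contact_map <- file.path(out_dir, "marker_contact.tsv")
  write_tsv(data.frame(marker = parts$name,
                       contact = ifelse(parts$contact, "contact", "non-contact")),
            p$contact_map)
  p$clade_map <- file.path(out_dir, "clades.tsv")
  clade_df <- data.frame(taxon = unlist(clades, use.names = FALSE),
                         clade = rep(names(clades), lengths(clades)))
  write_tsv(clade_df, p$clade_map)
  p$genomes <- file.path(out_dir, "genomes.fna")
  write_fasta_alignment(gen$sequences, p$genomes)
  p$annotation <- file.path(out_dir, "annotation.tsv")
  write_tsv(gen$annotation, p$annotation)
  p$manifest <- file.path(out_dir, "manifest.json")
  manifest <- list(seed = config$seed,
                   generating_tree = "tree_a",
                   shift_clade = config$shift_clade,
                   shift_delta = config$shift_delta,
                   alpha = config$alpha, model = config$model_name,
                   clades = clades,
                   partitions = parts)
  jsonlite::write_json(manifest, p$manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  invisible(list(concat = concat, alignments = alns, topology = topo,
                 cds = cds, genomes = gen$sequences,
                 annotation = gen$annotation, clade_map = clade_df,
                 paths = p))
}

# multiply the focal internal branch (the split separating `split_tips`
# from the rest) by `scale`
scale_focal_branch <- function(tree, split_tips, scale) {
  if (scale == 1) return(tree)
  ntip <- length(tree$tip.label)
  below <- vector("list", ntip + tree$Nnode)
  tr <- ape::reorder.phylo(tree, "postorder")
  for (tp in seq_len(ntip)) below[[tp]] <- tr$tip.label[tp]
  for (k in seq_len(nrow(tr$edge)))
    below[[tr$edge[k, 1]]] <- c(below[[tr$edge[k, 1]]], below[[tr$edge[k, 2]]])
  hit <- FALSE
  for (k in seq_len(nrow(tr$edge))) {
    tips_below <- below[[tr$edge[k, 2]]]
    if (setequal(tips_below, split_tips) ||
        setequal(setdiff(tr$tip.label, tips_below), split_tips)) {
      tr$edge.length[k] <- tr$edge.length[k] * scale
      hit <- TRUE
      break
    }
  }
  if (!hit) stopf("focal split not found in tree")
  tr
}

# one mock circular-genome-like sequence per taxon: gene regions filled
# with that taxon's simulated CDS, separated by unassigned spacers drawn
# from the taxon's (possibly shifted) background frequencies
simulate_genomes <- function(taxa, cds, parts, shift_tips, config) {
  nt <- dna_states()
  bg <- colMeans(default_pos_freqs())
  bg <- bg / sum(bg)
  bg_shift <- shift_gt_mass(bg, c(3L, 4L), config$shift_delta)
  minus_strand <- c("cytb", "nadh1", "nadh2", "nadh6")
  with_seed(config$seed * 3000L + 7L, {
    ur_len <- function() 60L + stats::rgeom(1, 1 / 120)
    seqs <- character(length(taxa)); names(seqs) <- taxa
    ann <- list()
    for (tx in taxa) {
      f <- if (tx %in% shift_tips) bg_shift else bg
      pieces <- character(0); feats <- list(); pos <- 0L
      for (i in seq_len(nrow(parts))) {
        spacer <- paste(sample(nt, ur_len(), TRUE, prob = f), collapse = "")
        pieces <- c(pieces, spacer); pos <- pos + nchar(spacer)
        gene_seq <- paste(cds[[parts$name[i]]]$matrix[tx, ], collapse = "")
        strand <- if (parts$name[i] %in% minus_strand && tx %in% shift_tips)
          "-" else "+"
        feats[[length(feats) + 1L]] <- data.frame(
          taxon = tx, feature = parts$name[i],
          start = pos + 1L, end = pos + nchar(gene_seq), strand = strand)
        pieces <- c(pieces, gene_seq); pos <- pos + nchar(gene_seq)
      }
      tail_sp <- paste(sample(nt, ur_len(), TRUE, prob = f), collapse = "")
      pieces <- c(pieces, tail_sp)
      seqs[tx] <- paste(pieces, collapse = "")
      ann[[tx]] <- do.call(rbind, feats)
    }
    list(sequences = seqs, annotation = do.call(rbind, unname(ann)))
  })
}
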