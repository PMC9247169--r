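# Strand and codon composition statistics: AT/GC skew, GT content,
# GT-rich codons, four-fold degenerate third positions, and
# unassigned-region composition of annotated genomes.

#' Genetic code table with derived four-fold degenerate families
#'
#' Wraps [Biostrings::getGeneticCode()] and derives the set of
#' four-fold degenerate codon families: first-two-position prefixes for
#' which all four third-position variants encode the same amino acid.
#' Table 1 is the standard code; table 5 the invertebrate mitochondrial
#' code, the default for mitochondrial protein-coding genes.
#'
#' @param id NCBI translation table id (e.g. 1 or 5).
#' @return list of class `genetic_code`: `id`, `codons` (named
#'   codon-to-residue map, DNA alphabet), `stops`, `fourfold_prefixes`.
#' @export
genetic_code <- function(id = 5L) {
  tab <- Biostrings::getGeneticCode(as.character(id))
  codons <- stats::setNames(as.character(tab), names(tab))
  stops <- names(codons)[codons == "*"]
  pref <- unique(substr(names(codons), 1, 2))
  ff <- pref[vapply(pref, function(p) {
    aa <- codons[paste0(p, c("A", "C", "G", "T"))]
    length(unique(aa)) == 1L && aa[1] != "*"
  }, TRUE)]
  structure(list(id = as.integer(id), codons = codons, stops = stops,
                 fourfold_prefixes = ff),
            class = "genetic_code")
}

#' @export
print.genetic_code <- function(x, ...) {
  cat(sprintf("genetic_code table %d: %d stop codons, %d four-fold families\n",
              x$id, length(x$stops), length(x$fourfold_prefixes)))
  invisible(x)
}

# counted bases of a sequence: uppercase A/C/G/T only (gaps and
# ambiguity codes excluded everywhere)
base_counts <- function(seq) {
  ch <- strsplit(toupper(paste(seq, collapse = "")), "")[[1]]
  c(A = sum(ch == "A"), C = sum(ch == "C"), G = sum(ch == "G"),
    T = sum(ch == "T"))
}

#' Strand-composition statistics of a nucleotide sequence
#'
#' `at_skew` = (A - T)/(A + T), `gc_skew` = (G - C)/(G + C),
#' `gt_content` = (G + T)/(A + C + G + T), computed over unambiguous
#' bases only (case-insensitive; gaps and IUPAC ambiguity codes are
#' ignored). A zero denominator yields `NA`.
#'
#' @param seq character scalar or vector of single characters.
#' @return a real number, or `NA` when undefined.
#' @export
at_skew <- function(seq) {
  n <- base_counts(seq)
  d <- n["A"] + n["T"]
  if (d == 0) return(NA_real_)
  unname((n["A"] - n["T"]) / d)
}

#' @rdname at_skew
#' @export
gc_skew <- function(seq) {
  n <- base_counts(seq)
  d <- n["G"] + n["C"]
  if (d == 0) return(NA_real_)
  unname((n["G"] - n["C"]) / d)
}

#' @rdname at_skew
#' @export
gt_content <- function(seq) {
  n <- base_counts(seq)
  if (sum(n) == 0) return(NA_real_)
  unname((n["G"] + n["T"]) / sum(n))
}

# split an in-frame CDS into codons, dropping gap characters first;
# codons containing anything outside ACGT are dropped entirely
clean_codons <- function(cds) {
  ch <- strsplit(toupper(paste(cds, collapse = "")), "")[[1]]
  ch <- ch[ch != "-" & ch != "." & ch != "?"]
  if (length(ch) %% 3 != 0)
    stopf("CDS length (%d after gap removal) is not a multiple of 3", length(ch))
  if (!length(ch)) return(character(0))
  cod <- apply(matrix(ch, nrow = 3), 2, paste, collapse = "")
  cod[!grepl("[^ACGT]", cod)]
}

#' Frequency of GT-rich codons in an in-frame CDS
#'
#' A codon counts as GT-rich when its first and second positions are
#' each G or T (the conjunctive reading; set
#' `positions = "either"` for the disjunctive variant, G or T at
#' first or second position). Codons containing gaps or ambiguity are
#' excluded from numerator and denominator alike.
#'
#' @param cds in-frame nucleotide sequence (length divisible by 3 after
#'   gap removal).
#' @param code a [genetic_code()] (kept for interface symmetry; the
#'   statistic itself is code-independent).
#' @param positions `"both"` (default) or `"either"`.
#' @return fraction of counted codons, or `NA` if none countable.
#' @export
gt_rich_codon_freq <- function(cds, code = genetic_code(5L),
                               positions = c("both", "either")) {
  positions <- match.arg(positions)
  cod <- clean_codons(cds)
  if (!length(cod)) return(NA_real_)
  p1 <- substr(cod, 1, 1) %in% c("G", "T")
  p2 <- substr(cod, 2, 2) %in% c("G", "T")
  hit <- if (positions == "both") p1 & p2 else p1 | p2
  mean(hit)
}

#' GT content at third positions of four-fold degenerate codons
#'
#' Only codons belonging to a four-fold degenerate family of `code`
#' (third position free to vary without changing the residue) are
#' counted; the statistic is the fraction of those codons carrying G or
#' T at the third position.
#'
#' @inheritParams gt_rich_codon_freq
#' @return fraction in `[0, 1]`, or `NA` when the CDS contains no
#'   four-fold degenerate codon.
#' @export
fourfold_gt3 <- function(cds, code = genetic_code(5L)) {
  cod <- clean_codons(cds)
  cod <- cod[substr(cod, 1, 2) %in% code$fourfold_prefixes]
  if (!length(cod)) return(NA_real_)
  mean(substr(cod, 3, 3) %in% c("G", "T"))
}

#' Unassigned regions of an annotated genome
#'
#' The complement of the union of all annotated features (strand is
#' ignored), as merged, sorted, 1-based inclusive intervals.
#'
#' @param annotation data frame with columns `start`, `end` (1-based
#'   inclusive; other columns ignored).
#' @param genome_length total sequence length.
#' @return data frame with columns `start`, `end`; zero rows when the
#'   features cover the whole genome.
#' @export
unassigned_regions <- function(annotation, genome_length) {
  if (nrow(annotation) == 0)
    return(data.frame(start = 1L, end = as.integer(genome_length)))
  if (any(annotation$start < 1 | annotation$end > genome_length |
          annotation$start > annotation$end))
    stopf("annotation feature outside genome bounds [1, %d]", genome_length)
  ir <- IRanges::reduce(IRanges::IRanges(annotation$start, annotation$end))
  gaps <- IRanges::gaps(ir, start = 1L, end = as.integer(genome_length))
  data.frame(start = IRanges::start(gaps), end = IRanges::end(gaps))
}

#' GT content of a genome's unassigned regions
#'
#' Concatenates the plus-strand subsequences of every unassigned region
#' (see [unassigned_regions()]) and returns their [gt_content()].
#'
#' @param genome character scalar, the full plus-strand sequence.
#' @param annotation feature table as in [unassigned_regions()].
#' @return GT fraction of the URs, or `NA` when there are none.
#' @export
ur_gt_content <- function(genome, annotation) {
  urs <- unassigned_regions(annotation, nchar(genome))
  if (nrow(urs) == 0) return(NA_real_)
  gt_content(paste(substring(genome, urs$start, urs$end), collapse = ""))
}

#' Per-taxon, per-marker composition profile
#'
#' Computes the five composition statistics for every sequence of every
#' marker and attaches clade labels, producing the tidy table consumed
#' by the clade-comparison tests.
#'
#' @param cds_by_marker named list of in-frame nucleotide alignments
#'   ([alignment()] objects or named character vectors), one per marker.
#' @param clade_map data frame with columns `taxon`, `clade`; taxa
#'   absent from the map are labelled `"unassigned"` and retained.
#' @param code a [genetic_code()] applied to every marker, or a named
#'   list of codes per marker.
#' @param markers optional restriction to a subset of marker names
#'   (e.g. the shared-strand set atp6, atp8, cox1-3, nadh3-5).
#' @return data frame with one row per taxon x marker and columns
#'   `taxon`, `clade`, `marker`, `at_skew`, `gc_skew`, `gt_content`,
#'   `gt_rich_codon_freq`, `fourfold_gt3`.
#' @export
composition_table <- function(cds_by_marker, clade_map = NULL,
                              code = genetic_code(5L), markers = NULL) {
  if (!is.null(markers)) cds_by_marker <- cds_by_marker[intersect(names(cds_by_marker), markers)]
  rows <- list()
  for (mk in names(cds_by_marker)) {
    x <- cds_by_marker[[mk]]
    seqs <- if (inherits(x, "phylo_alignment"))
      apply(x$matrix, 1, paste, collapse = "") else x
    cd <- if (inherits(code, "genetic_code")) code else code[[mk]]
    for (tx in names(seqs)) {
      s <- seqs[[tx]]
      rows[[length(rows) + 1L]] <- data.frame(
        taxon = tx, marker = mk,
        at_skew = at_skew(s), gc_skew = gc_skew(s), gt_content = gt_content(s),
        gt_rich_codon_freq = gt_rich_codon_freq(s, cd),
        fourfold_gt3 = fourfold_gt3(s, cd))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(taxon = character(0), marker = character(0),
               at_skew = numeric(0), gc_skew = numeric(0),
               gt_content = numeric(0), gt_rich_codon_freq = numeric(0),
               fourfold_gt3 = numeric(0))
  clade <- if (is.null(clade_map)) rep("unassigned", nrow(out)) else
    clade_map$clade[match(out$taxon, clade_map$taxon)]
  clade[is.na(clade)] <- "unassigned"
  out <- cbind(out[, "taxon", drop = FALSE], clade = clade,
               out[, setdiff(names(out), "taxon"), drop = FALSE])
  rownames(out) <- NULL
  out
}
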