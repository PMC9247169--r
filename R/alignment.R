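#' Multiple sequence alignment container
#'
#' A light container for a rectangular character matrix of aligned
#' sequences, tagged with an alphabet and an optional partition map.
#' Partitions follow the file convention of 1-based inclusive column
#' ranges, one named marker per range.
#'
#' @param x character matrix (taxa in rows, aligned columns) or a named
#'   character vector of equal-length sequence strings.
#' @param alphabet `"aa"` or `"dna"`.
#' @param partitions optional data frame with columns `name`, `start`,
#'   `end` (1-based inclusive) and optionally `group` (e.g. OXPHOS
#'   complex label).
#' @return an object of class `phylo_alignment`.
#' @export
alignment <- function(x, alphabet = c("aa", "dna"), partitions = NULL) {
  alphabet <- match.arg(alphabet)
  if (is.character(x) && !is.matrix(x)) {
    if (is.null(names(x))) stopf("sequence vector must be named by taxon")
    n <- unique(nchar(x))
    if (length(n) != 1L) stopf("ragged alignment: sequence lengths differ")
    taxa <- names(x)
    x <- matrix(unlist(strsplit(toupper(x), "")), nrow = length(x),
                byrow = TRUE, dimnames = list(taxa, NULL))
  }
  if (!is.matrix(x) || !is.character(x)) stopf("x must be a character matrix")
  if (is.null(rownames(x))) stopf("alignment rows must be named by taxon")
  if (anyDuplicated(rownames(x))) {
    dup <- rownames(x)[duplicated(rownames(x))][1]
    stopf("duplicate taxon label: %s", dup)
  }
  x[] <- toupper(x)
  if (!is.null(partitions)) validate_partitions(partitions, ncol(x))
  structure(list(matrix = x, alphabet = alphabet, partitions = partitions),
            class = "phylo_alignment")
}

validate_partitions <- function(p, n_col) {
  need <- c("name", "start", "end")
  if (!all(need %in% names(p))) stopf("partitions need columns name, start, end")
  if (anyDuplicated(p$name)) stopf("duplicate partition name")
  if (any(p$start < 1 | p$end > n_col | p$start > p$end))
    stopf("partition ranges out of bounds")
  cov <- unlist(Map(seq.int, p$start, p$end))
  if (anyDuplicated(cov)) stopf("partition ranges overlap")
  invisible(p)
}

#' @export
print.phylo_alignment <- function(x, ...) {
  cat(sprintf("phylo_alignment: %d taxa x %d sites (%s)\n",
              nrow(x$matrix), ncol(x$matrix), x$alphabet))
  if (!is.null(x$partitions))
    cat(sprintf("  %d partitions: %s\n", nrow(x$partitions),
                paste(utils::head(x$partitions$name, 6), collapse = ", ")))
  invisible(x)
}

#' @export
dim.phylo_alignment <- function(x) dim(x$matrix)

#' Per-site partition index of an alignment
#'
#' @param aln a [alignment()] object with a partition map.
#' @return character vector, length `ncol(aln)`, of partition names
#'   (`NA` for unassigned columns).
#' @export
site_partition <- function(aln) {
  out <- rep(NA_character_, ncol(aln$matrix))
  p <- aln$partitions
  if (!is.null(p))
    for (i in seq_len(nrow(p))) out[p$start[i]:p$end[i]] <- p$name[i]
  out
}

#' Extract the columns of one partition
#' @param aln a [alignment()] object.
#' @param name partition name.
#' @return a `phylo_alignment` restricted to that marker (no partition map).
#' @export
extract_partition <- function(aln, name) {
  p <- aln$partitions
  if (is.null(p) || !name %in% p$name) stopf("unknown partition: %s", name)
  i <- match(name, p$name)
  alignment(aln$matrix[, p$start[i]:p$end[i], drop = FALSE], aln$alphabet)
}

## alphabets ----------------------------------------------------------------

aa_states <- function() strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
dna_states <- function() c("A", "C", "G", "T")

model_states <- function(alphabet)
  if (alphabet == "aa") aa_states() else dna_states()

# character -> compatible state-index set; anything unknown is fully missing
state_sets <- function(alphabet) {
  st <- model_states(alphabet)
  sets <- as.list(seq_along(st))
  names(sets) <- st
  all_idx <- seq_along(st)
  if (alphabet == "dna") {
    amb <- list(U = "T", R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"))
    for (a in names(amb)) sets[[a]] <- match(amb[[a]], st)
  } else {
    sets[["B"]] <- match(c("N", "D"), st)
    sets[["Z"]] <- match(c("Q", "E"), st)
    sets[["J"]] <- match(c("I", "L"), st)
  }
  for (a in c("X", "N"[alphabet == "dna"], "-", "?", ".", "*"))
    sets[[a]] <- all_idx
  if (alphabet == "dna") sets[["N"]] <- all_idx
  sets
}

## FASTA --------------------------------------------------------------------

#' Read / write FASTA alignments
#'
#' Thin wrappers over [Biostrings::readBStringSet()] and
#' [Biostrings::writeXStringSet()] that move between files and
#' [alignment()] objects losslessly (labels, gaps, case-normalised
#' residues).
#'
#' @param path file path.
#' @param alphabet `"aa"` or `"dna"`.
#' @param partitions optional partition map to attach (see [alignment()]).
#' @return `read_fasta_alignment()` returns a `phylo_alignment`.
#' @export
read_fasta_alignment <- function(path, alphabet = c("aa", "dna"),
                                 partitions = NULL) {
  alphabet <- match.arg(alphabet)
  ss <- Biostrings::readBStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(names(seqs)))
    stopf("duplicate taxon label in %s: %s", path,
          names(seqs)[duplicated(names(seqs))][1])
  if (length(unique(nchar(seqs))) != 1L)
    stopf("ragged alignment in %s", path)
  alignment(seqs, alphabet, partitions)
}

#' @param aln a `phylo_alignment` (or named character vector of sequences).
#' @rdname read_fasta_alignment
#' @export
write_fasta_alignment <- function(aln, path) {
  seqs <- if (inherits(aln, "phylo_alignment"))
    apply(aln$matrix, 1, paste, collapse = "") else aln
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

## trees --------------------------------------------------------------------

#' Read / write Newick trees
#'
#' Wrappers over [ape::read.tree()] / [ape::write.tree()]. Multi-tree
#' files (one Newick per line) come back as a list of `phylo` objects.
#'
#' @param path file path.
#' @return `read_newick()`: a `phylo` or (for several trees) `multiPhylo`.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' @param tree a `phylo` or list of `phylo`.
#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

## partition files ----------------------------------------------------------

#' Read / write RAxML-style partition files
#'
#' Lines of the form `"WAG, GENE1 = 1-300"` or `"GENE1 = 1-300"`;
#' 1-based inclusive column ranges. The optional leading model token is
#' kept in a `model` column.
#'
#' @param path file path.
#' @return data frame with columns `name`, `start`, `end`, `model`.
#' @export
read_partitions <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  m <- regmatches(lines, regexec(
    "^(?:([^,=]+),)?\\s*([^=,]+?)\\s*=\\s*(\\d+)\\s*-\\s*(\\d+)\\s*$", lines))
  bad <- vapply(m, length, 1L) != 5L
  if (any(bad)) stopf("cannot parse partition line: %s", lines[bad][1])
  out <- data.frame(
    name  = trimws(vapply(m, `[`, "", 3L)),
    start = as.integer(vapply(m, `[`, "", 4L)),
    end   = as.integer(vapply(m, `[`, "", 5L)),
    model = trimws(vapply(m, `[`, "", 2L)),
    stringsAsFactors = FALSE)
  out$model[!nzchar(out$model)] <- NA_character_
  out
}

#' @param parts data frame with columns `name`, `start`, `end` and
#'   optionally `model`.
#' @rdname read_partitions
#' @export
write_partitions <- function(parts, path) {
  model <- if ("model" %in% names(parts)) parts$model else NA
  model <- ifelse(is.na(model), "", paste0(model, ", "))
  writeLines(sprintf("%s%s = %d-%d", model, parts$name,
                     parts$start, parts$end), path)
  invisible(path)
}

## TSV ----------------------------------------------------------------------

#' Read / write tab-separated tables with explicit NA sentinels
#' @param path file path.
#' @return `read_tsv()`: a data frame.
#' @export
read_tsv <- function(path)
  utils::read.delim(path, sep = "\t", na.strings = "NA",
                    stringsAsFactors = FALSE, check.names = FALSE)

#' @param x data frame.
#' @rdname read_tsv
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE)
  invisible(path)
}
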