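#' Read a grouped alignment from FASTA + metadata
#'
#' Reads an aligned, gapped FASTA and a tab-separated metadata table with
#' header `haplotype_id<TAB>population<TAB>paralog` mapping every FASTA id to
#' its (population, paralog) group.
#'
#' @param fasta_path Path to the aligned FASTA.
#' @param metadata_path Path to the TSV metadata.
#' @return A [GroupedAlignment-class].
#' @export
readGroupedAlignment <- function(fasta_path, metadata_path) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE,
                            colClasses = "character")
  need <- c("haplotype_id", "population", "paralog")
  if (!all(need %in% names(meta)))
    stop("metadata error: header must contain ", paste(need, collapse = ", "))
  groupedAlignment(as.character(seqs), meta)
}

#' Write a grouped alignment to FASTA + metadata
#'
#' Inverse of [readGroupedAlignment()]; a write/read round trip reproduces
#' residues and labels exactly.
#'
#' @param x A [GroupedAlignment-class].
#' @param fasta_path,metadata_path Output paths.
#' @return Invisibly, `x`.
#' @export
writeGroupedAlignment <- function(x, fasta_path, metadata_path) {
  stopifnot(is(x, "GroupedAlignment"))
  Biostrings::writeXStringSet(x@seqs, fasta_path)
  utils::write.table(
    x@info[, c("haplotype_id", "population", "paralog")],
    metadata_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' Read / write a coding annotation
#'
#' The on-disk format is a GFF-like TSV with header
#' `start<TAB>end<TAB>frame`: one row per exon with 1-based inclusive column
#' intervals; the frame offset is taken from the first row.
#'
#' @param path File path.
#' @return [readCodingMap()] returns a [CodingMap-class].
#' @export
readCodingMap <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("start", "end") %in% names(tab)))
    stop("coding map file must have columns start, end")
  fo <- if ("frame" %in% names(tab)) as.integer(tab$frame[1]) else 0L
  codingMap(tab$start, tab$end, fo)
}

#' @rdname readCodingMap
#' @param x A [CodingMap-class].
#' @export
writeCodingMap <- function(x, path) {
  stopifnot(is(x, "CodingMap"))
  utils::write.table(
    data.frame(start = IRanges::start(x@exons), end = IRanges::end(x@exons),
               frame = x@frameOffset),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

## character matrix of the alignment (internal shorthand)
.chm <- function(x, idx = NULL) {
  m <- seqMatrix(x)
  if (!is.null(idx)) m <- m[idx, , drop = FALSE]
  m
}

## deterministic consensus ordering: nucleotides lexicographically, then N,
## then gap (ties at equal counts resolved by this order)
.cons_order <- c("A", "C", "G", "T", "N", "-")

.majority <- function(states) {
  tb <- table(factor(states, levels = .cons_order))
  names(tb)[which.max(tb)]   # which.max takes the first maximum => lexicographic
}

#' Per-column site classification
#'
#' Classifies each alignment column: gap content, overall polymorphism and
#' (optionally, via [fixedBetween()]) fixed differences between paralogs
#' within a population. `N` is treated as missing: it never makes a column
#' polymorphic and never counts as a difference.
#'
#' @param x A [GroupedAlignment-class].
#' @param gap_policy `"listwise"` (default): any column with a gap in any
#'   included sequence is flagged and excluded from site counts.
#'   `"pairwise"`: columns are kept and gap handling is deferred to the
#'   pairwise statistics.
#' @return A `data.frame` with one row per column: `column`, `has_gap`,
#'   `included`, `n_states` (distinct non-gap, non-N states) and
#'   `polymorphic` (`n_states >= 2`).
#' @export
classifySites <- function(x, gap_policy = c("listwise", "pairwise")) {
  gap_policy <- match.arg(gap_policy)
  if (nHap(x) == 0L || alnLength(x) == 0L) stop("empty alignment")
  m <- .chm(x)
  has_gap <- apply(m == "-", 2, any)
  n_states <- apply(m, 2, function(col) {
    s <- col[col %in% c("A", "C", "G", "T")]
    length(unique(s))
  })
  data.frame(column = seq_len(alnLength(x)),
             has_gap = has_gap,
             included = if (gap_policy == "listwise") !has_gap
                        else rep(TRUE, alnLength(x)),
             n_states = n_states,
             polymorphic = n_states >= 2L)
}

#' Columns fixed between two paralogs within a population
#'
#' A column is "fixed between" when each paralog group is monomorphic
#' (one non-gap, non-N state) and the two groups carry different states.
#'
#' @param x A [GroupedAlignment-class].
#' @param population Population label.
#' @param paralog_a,paralog_b The two paralog labels.
#' @return Logical vector over alignment columns.
#' @export
fixedBetween <- function(x, population, paralog_a, paralog_b) {
  ia <- selectGroup(x, population = population, paralog = paralog_a)
  ib <- selectGroup(x, population = population, paralog = paralog_b)
  if (!length(ia) || !length(ib))
    stop("both paralog groups must be present in population ", population)
  ma <- .chm(x, ia); mb <- .chm(x, ib)
  one_state <- function(col) {
    s <- unique(col[col %in% c("A", "C", "G", "T")])
    if (length(s) == 1L) s else NA_character_
  }
  sa <- apply(ma, 2, one_state)
  sb <- apply(mb, 2, one_state)
  !is.na(sa) & !is.na(sb) & sa != sb
}

## majority-rule consensus per codon for a set of rows; returns character
## vector of codons (one per codon position)
.codon_consensus <- function(m, coding_cols) {
  ncod <- length(coding_cols) %/% 3L
  vapply(seq_len(ncod), function(k) {
    cols <- coding_cols[(3L * k - 2L):(3L * k)]
    codons <- apply(m[, cols, drop = FALSE], 1, paste, collapse = "")
    tb <- sort(table(codons), decreasing = TRUE)
    cand <- names(tb)[tb == max(tb)]
    sort(cand)[1]           # lexicographic tie-break
  }, character(1))
}

#' Percent amino-acid identity between two group consensus translations
#'
#' Builds a majority-rule consensus codon sequence for each group (ties
#' broken lexicographically), translates with the standard code, and returns
#' 100 x matches / compared positions. Positions where either consensus
#' codon contains a gap or `N` are skipped; internal stop codons are
#' excluded with a warning.
#'
#' @param x A [GroupedAlignment-class].
#' @param cmap A [CodingMap-class].
#' @param group_a,group_b Integer record indices (see [selectGroup()]).
#' @return Percent identity (numeric scalar).
#' @export
translateIdentity <- function(x, cmap, group_a, group_b) {
  cols <- codingColumns(cmap)
  if (length(cols) %% 3L != 0L)
    stop("coding length must be divisible by 3 after frame adjustment")
  ca <- .codon_consensus(.chm(x, group_a), cols)
  cb <- .codon_consensus(.chm(x, group_b), cols)
  ok <- !grepl("[-N]", ca) & !grepl("[-N]", cb)
  aa_a <- .translate_codons(ca[ok])
  aa_b <- .translate_codons(cb[ok])
  stops <- which(aa_a == "*" | aa_b == "*")
  if (length(stops)) {
    warning(sprintf("%d internal stop codon position(s) excluded",
                    length(stops)))
    aa_a <- aa_a[-stops]; aa_b <- aa_b[-stops]
  }
  if (!length(aa_a)) stop("undefined result: all positions excluded")
  100 * sum(aa_a == aa_b) / length(aa_a)
}

.translate_codons <- function(codons) {
  if (!length(codons)) return(character(0))
  unname(Biostrings::GENETIC_CODE[codons])
}
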