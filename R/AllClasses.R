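#' @import methods
#' @importFrom Biostrings DNAStringSet readBStringSet writeXStringSet width
#' @importFrom IRanges IRanges start end width
#' @importFrom S4Vectors isSorted
NULL

#' Grouped haplotype alignment
#'
#' A multiple-sequence alignment of haplotypes, each tagged with a population
#' and a paralog label. This is the central container consumed by every
#' analysis stage: polymorphism statistics are computed within
#' (population, paralog) groups, divergence and the conversion scan across
#' them.
#'
#' @slot seqs A [Biostrings::DNAStringSet] of equal-width aligned sequences
#'   over the alphabet \{A, C, G, T, -, N\}; names are haplotype ids.
#' @slot info A `data.frame` with one row per sequence and columns
#'   `haplotype_id`, `population`, `paralog`.
#'
#' @seealso [readGroupedAlignment()], [selectGroup()], [classifySites()]
#' @export
setClass("GroupedAlignment",
  representation(seqs = "DNAStringSet", info = "data.frame"))

setValidity("GroupedAlignment", function(object) {
  msgs <- character()
  n <- length(object@seqs)
  if (n == 0L) msgs <- c(msgs, "alignment has no sequences")
  if (!identical(nrow(object@info), n))
    msgs <- c(msgs, "info must have one row per sequence")
  need <- c("haplotype_id", "population", "paralog")
  if (!all(need %in% names(object@info))) {
    msgs <- c(msgs, sprintf("info must have columns %s",
                            paste(need, collapse = ", ")))
    return(msgs)
  }
  if (n > 0L) {
    w <- Biostrings::width(object@seqs)
    if (length(unique(w)) > 1L)
      msgs <- c(msgs, "all sequences must have identical aligned length")
    ids <- object@info$haplotype_id
    if (anyDuplicated(ids)) msgs <- c(msgs, "haplotype ids must be unique")
    if (!identical(names(object@seqs), ids))
      msgs <- c(msgs, "names(seqs) must equal info$haplotype_id")
    if (any(!nzchar(object@info$population)) ||
        any(is.na(object@info$population)))
      msgs <- c(msgs, "every record needs a non-empty population label")
    if (any(!nzchar(object@info$paralog)) || any(is.na(object@info$paralog)))
      msgs <- c(msgs, "every record needs a non-empty paralog label")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a GroupedAlignment
#'
#' @param seqs Aligned sequences: a character vector or
#'   [Biostrings::DNAStringSet]. Residues are upper-cased; characters outside
#'   \{A, C, G, T, -, N\} are mapped to `N` with a warning reporting the count.
#' @param info `data.frame` with columns `haplotype_id`, `population`,
#'   `paralog` (extra columns kept). Order is matched to `names(seqs)` when
#'   sequences are named, otherwise positional.
#' @return A [GroupedAlignment-class] object.
#' @export
groupedAlignment <- function(seqs, info) {
  if (is(seqs, "XStringSet")) seqs <- as.character(seqs)
  if (!is.character(seqs)) stop("seqs must be character or an XStringSet")
  seqs <- toupper(seqs)
  bad <- sum(vapply(seqs,
    function(s) sum(!strsplit(s, "")[[1]] %in% c("A", "C", "G", "T", "-", "N")),
    integer(1)))
  if (bad > 0L) {
    warning(sprintf("%d residues outside {A,C,G,T,-,N} mapped to N", bad))
    seqs <- vapply(seqs, function(s) {
      ch <- strsplit(s, "")[[1]]
      ch[!ch %in% c("A", "C", "G", "T", "-", "N")] <- "N"
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = TRUE)
  }
  info <- as.data.frame(info, stringsAsFactors = FALSE)
  info$haplotype_id <- as.character(info$haplotype_id)
  info$population <- as.character(info$population)
  info$paralog <- as.character(info$paralog)
  if (!is.null(names(seqs)) && all(nzchar(names(seqs)))) {
    missing_ids <- setdiff(names(seqs), info$haplotype_id)
    if (length(missing_ids))
      stop("metadata error: no metadata for id(s): ",
           paste(missing_ids, collapse = ", "))
    info <- info[match(names(seqs), info$haplotype_id), , drop = FALSE]
  } else {
    names(seqs) <- info$haplotype_id
  }
  rownames(info) <- NULL
  w <- nchar(seqs)
  if (length(unique(w)) > 1L) {
    ref <- as.integer(names(sort(table(w), decreasing = TRUE))[1])
    off <- names(seqs)[w != ref][1]
    stop(sprintf("alignment error: record '%s' has length %d, expected %d",
                 off, nchar(seqs[[off]]), ref))
  }
  new("GroupedAlignment", seqs = Biostrings::DNAStringSet(seqs), info = info)
}

#' @describeIn GroupedAlignment-class number of aligned columns
#' @param x,object A `GroupedAlignment`.
#' @export
alnLength <- function(x) {
  stopifnot(is(x, "GroupedAlignment"))
  if (length(x@seqs) == 0L) 0L else Biostrings::width(x@seqs)[1]
}

#' @describeIn GroupedAlignment-class number of haplotypes
#' @export
nHap <- function(x) length(x@seqs)

#' @describeIn GroupedAlignment-class haplotype ids
#' @export
haplotypeIds <- function(x) x@info$haplotype_id

#' @describeIn GroupedAlignment-class per-record metadata data.frame
#' @export
groupInfo <- function(x) x@info

#' @describeIn GroupedAlignment-class alignment as a character matrix
#'   (rows = haplotypes, columns = alignment columns)
#' @export
seqMatrix <- function(x) {
  m <- do.call(rbind, strsplit(as.character(x@seqs), ""))
  dimnames(m) <- list(haplotypeIds(x), NULL)
  m
}

#' Select records of a GroupedAlignment by label
#'
#' @param x A [GroupedAlignment-class].
#' @param population,paralog Optional label filters (vectors allowed).
#' @param ids Optional haplotype ids.
#' @return Integer indices of the matching records.
#' @export
selectGroup <- function(x, population = NULL, paralog = NULL, ids = NULL) {
  keep <- rep(TRUE, nHap(x))
  if (!is.null(population)) keep <- keep & x@info$population %in% population
  if (!is.null(paralog)) keep <- keep & x@info$paralog %in% paralog
  if (!is.null(ids)) keep <- keep & x@info$haplotype_id %in% ids
  which(keep)
}

#' @export
setMethod("[", "GroupedAlignment", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, haplotypeIds(x))
  new("GroupedAlignment", seqs = x@seqs[i],
      info = x@info[i, , drop = FALSE])
})

setMethod("show", "GroupedAlignment", function(object) {
  cat(sprintf("GroupedAlignment: %d haplotypes x %d columns\n",
              nHap(object), alnLength(object)))
  tab <- table(object@info$population, object@info$paralog)
  cat("haplotypes per (population, paralog) group:\n")
  print(tab)
})

#' Coding annotation for an aligned gene
#'
#' Describes which alignment columns are coding: an ordered set of exon
#' intervals (1-based, inclusive), a reading-frame offset into the
#' concatenated exons, and the genetic code used for translation.
#'
#' @slot exons An [IRanges::IRanges] of disjoint, ascending exon intervals.
#' @slot frameOffset Integer 0-2: columns of the first exon to skip before
#'   the first complete codon.
#' @slot codeTable Genetic code identifier; only `"standard"` is supported.
#' @export
setClass("CodingMap",
  representation(exons = "IRanges", frameOffset = "integer",
                 codeTable = "character"))

setValidity("CodingMap", function(object) {
  msgs <- character()
  ex <- object@exons
  if (length(ex)) {
    if (is.unsorted(IRanges::start(ex), strictly = TRUE))
      msgs <- c(msgs, "exons must be in ascending order")
    if (length(ex) > 1L &&
        any(IRanges::start(ex)[-1] <= IRanges::end(ex)[-length(ex)]))
      msgs <- c(msgs, "exons must be disjoint")
    if ((sum(IRanges::width(ex)) - object@frameOffset) %% 3L != 0L)
      msgs <- c(msgs, "coding length minus frame offset must be divisible by 3")
  }
  if (object@frameOffset < 0L || object@frameOffset > 2L)
    msgs <- c(msgs, "frameOffset must be 0, 1 or 2")
  if (!identical(object@codeTable, "standard"))
    msgs <- c(msgs, "only the standard genetic code is supported")
  if (length(msgs)) msgs else TRUE
})

#' Construct a CodingMap
#'
#' @param starts,ends 1-based inclusive exon boundaries (equal length).
#' @param frame_offset Integer 0-2 (default 0).
#' @return A [CodingMap-class].
#' @export
codingMap <- function(starts, ends, frame_offset = 0L) {
  new("CodingMap",
      exons = IRanges::IRanges(start = as.integer(starts),
                               end = as.integer(ends)),
      frameOffset = as.integer(frame_offset), codeTable = "standard")
}

#' @describeIn CodingMap-class alignment columns that fall in complete codons,
#'   in codon order (length divisible by 3)
#' @param x A `CodingMap`.
#' @export
codingColumns <- function(x) {
  stopifnot(is(x, "CodingMap"))
  cols <- unlist(lapply(seq_along(x@exons), function(i)
    seq(IRanges::start(x@exons)[i], IRanges::end(x@exons)[i])))
  if (x@frameOffset > 0L) cols <- cols[-seq_len(x@frameOffset)]
  cols
}

setMethod("show", "CodingMap", function(object) {
  cat(sprintf("CodingMap: %d exon(s), frame offset %d, %d coding columns\n",
              length(object@exons), object@frameOffset,
              length(codingColumns(object))))
})
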