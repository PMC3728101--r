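#' Jukes-Cantor distance correction
#'
#' `d = -(3/4) * log(1 - 4p/3)`, applied to proportions of synonymous /
#' nonsynonymous differences. Undefined at saturation (`p >= 3/4`).
#'
#' @param p Proportion of differences per site, in `[0, 3/4)`.
#' @return Corrected substitutions per site.
#' @export
jukesCantor <- function(p) {
  if (any(p >= 0.75)) stop("saturation: Jukes-Cantor correction undefined for p >= 3/4")
  -0.75 * log(1 - 4 * p / 3)
}

.BASES <- c("A", "C", "G", "T")

## synonymous/nonsynonymous site counts per codon (Nei-Gojobori 1986):
## at each position, the fraction of the three alternative bases whose
## substitution is synonymous. Changes to stop codons count as nonsynonymous;
## stop codons themselves carry no sites.
.ng_site_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    gc <- Biostrings::GENETIC_CODE
    codons <- names(gc)
    res <- matrix(NA_real_, nrow = length(codons), ncol = 2,
                  dimnames = list(codons, c("syn", "nonsyn")))
    for (cod in codons) {
      if (gc[[cod]] == "*") next
      s <- 0
      for (pos in 1:3) {
        ref <- substr(cod, pos, pos)
        for (b in setdiff(.BASES, ref)) {
          mut <- cod
          substr(mut, pos, pos) <- b
          if (gc[[mut]] == gc[[cod]]) s <- s + 1 / 3
        }
      }
      res[cod, ] <- c(s, 3 - s)
    }
    tab <<- res
    res
  }
})

## average synonymous/nonsynonymous differences between two codons over all
## minimal substitution pathways with equal weight; pathways through stop
## codons are excluded (if every pathway passes a stop, all are used).
.ng_path_diffs <- function(ca, cb) {
  if (ca == cb) return(c(syn = 0, nonsyn = 0))
  gc <- Biostrings::GENETIC_CODE
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  perms <- .permutations(pos)
  paths <- lapply(perms, function(ord) {
    cur <- ca
    steps <- matrix(NA_real_, nrow = length(ord), ncol = 2)
    via_stop <- FALSE
    for (k in seq_along(ord)) {
      nxt <- cur
      substr(nxt, ord[k], ord[k]) <- substr(cb, ord[k], ord[k])
      if (gc[[nxt]] == "*" && k < length(ord)) via_stop <- TRUE
      steps[k, ] <- if (gc[[cur]] == gc[[nxt]]) c(1, 0) else c(0, 1)
      cur <- nxt
    }
    list(sd = sum(steps[, 1]), nd = sum(steps[, 2]), via_stop = via_stop)
  })
  ok <- !vapply(paths, `[[`, logical(1), "via_stop")
  if (!any(ok)) ok <- rep(TRUE, length(paths))
  sd <- mean(vapply(paths[ok], `[[`, numeric(1), "sd"))
  nd <- mean(vapply(paths[ok], `[[`, numeric(1), "nd"))
  c(syn = sd, nonsyn = nd)
}

.permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(.permutations(v[-i]), function(p) c(v[i], p)))
  out
}

## split a nucleotide string into codons
.codons <- function(s) {
  n <- nchar(s) %/% 3L
  substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

## raw Nei-Gojobori counts for a pair of codon vectors; codons containing
## gaps, N, or coding for stop in either sequence are excluded pairwise
.ng_pair_counts <- function(cod_a, cod_b) {
  stopifnot(length(cod_a) == length(cod_b))
  st <- .ng_site_table()
  clean <- !grepl("[^ACGT]", cod_a) & !grepl("[^ACGT]", cod_b)
  clean[clean] <- !is.na(st[cod_a[clean], "syn"]) &
                  !is.na(st[cod_b[clean], "syn"])
  ca <- cod_a[clean]; cb <- cod_b[clean]
  if (!length(ca))
    return(list(S = 0, N = 0, Sd = 0, Nd = 0, n_codons = 0L))
  S <- (sum(st[ca, "syn"]) + sum(st[cb, "syn"])) / 2
  N <- (sum(st[ca, "nonsyn"]) + sum(st[cb, "nonsyn"])) / 2
  d <- c(syn = 0, nonsyn = 0)
  for (k in which(ca != cb)) d <- d + .ng_path_diffs(ca[k], cb[k])
  list(S = S, N = N, Sd = unname(d["syn"]), Nd = unname(d["nonsyn"]),
       n_codons = length(ca))
}

.pairwise_divergence <- function(counts) {
  ps <- if (counts$S > 0) counts$Sd / counts$S else NA_real_
  pn <- if (counts$N > 0) counts$Nd / counts$N else NA_real_
  ks <- if (is.na(ps)) NA_real_ else jukesCantor(ps)
  ka <- if (is.na(pn)) NA_real_ else jukesCantor(pn)
  ratio <- if (!is.na(ks) && ks > 0 && !is.na(ka)) ka / ks else NA_real_
  structure(list(S = counts$S, N = counts$N, Sd = counts$Sd, Nd = counts$Nd,
                 n_codons = counts$n_codons, ps = ps, pn = pn,
                 ks = ks, ka = ka, ka_ks = ratio),
            class = "PairwiseDivergence")
}

#' @export
print.PairwiseDivergence <- function(x, ...) {
  cat(sprintf(paste0("Nei-Gojobori pairwise divergence (%d codons)\n",
                     "  sites     S = %.2f   N = %.2f\n",
                     "  diffs    Sd = %.2f  Nd = %.2f\n",
                     "  ks = %.4f  ka = %.4f  ka/ks = %s\n"),
              x$n_codons, x$S, x$N, x$Sd, x$Nd, x$ks, x$ka,
              ifelse(is.na(x$ka_ks), "-", sprintf("%.4f", x$ka_ks))))
  invisible(x)
}

#' Nei-Gojobori synonymous / nonsynonymous divergence for a sequence pair
#'
#' Counts synonymous and nonsynonymous sites and differences following
#' Nei & Gojobori (1986): site counts averaged over the two sequences,
#' multi-difference codons averaged over all minimal substitution pathways
#' with equal weight (pathways through stop codons excluded), and
#' Jukes-Cantor correction of the resulting proportions.
#'
#' @param seq_a,seq_b In-frame coding nucleotide strings of equal length
#'   (divisible by 3). Codons containing gaps or `N` are excluded pairwise.
#' @return A `PairwiseDivergence` list: site counts `S`, `N`; difference
#'   counts `Sd`, `Nd`; proportions `ps`, `pn`; corrected rates `ks`, `ka`;
#'   and `ka_ks` (`NA` when `ks` is 0 or undefined).
#' @export
neiGojoboriPair <- function(seq_a, seq_b) {
  seq_a <- toupper(as.character(seq_a)); seq_b <- toupper(as.character(seq_b))
  if (nchar(seq_a) != nchar(seq_b))
    stop("sequences must have equal length")
  if (nchar(seq_a) %% 3L != 0L)
    stop("coding length must be divisible by 3")
  counts <- .ng_pair_counts(.codons(seq_a), .codons(seq_b))
  if (counts$n_codons == 0L) stop("no comparable codons")
  .pairwise_divergence(counts)
}

## group consensus with non-fixed columns masked to N (for fixed_only mode)
.fixed_consensus <- function(m) {
  apply(m, 2, function(col) {
    s <- unique(col[col %in% .BASES])
    if (length(s) == 1L) s
    else if (length(s) == 0L) .majority(col)   # all gap/N: keep majority char
    else "N"                                   # polymorphic -> masked
  })
}

#' Between-group coding divergence
#'
#' Computes Nei-Gojobori divergence between two (population, paralog) groups.
#' In `"fixed_only"` mode (fixed genetic divergence), each group is reduced
#' to its consensus with sites polymorphic inside the group masked out, so
#' only fixed differences contribute. In `"mean_pairwise"` mode, Nei-Gojobori
#' counts are averaged over all between-group sequence pairs.
#'
#' @param x A [GroupedAlignment-class].
#' @param cmap A [CodingMap-class].
#' @param group_a,group_b Integer record indices (see [selectGroup()]).
#' @param mode `"fixed_only"` (default) or `"mean_pairwise"`.
#' @return A `PairwiseDivergence` (see [neiGojoboriPair()]).
#' @export
divergenceBetweenGroups <- function(x, cmap, group_a, group_b,
                                    mode = c("fixed_only", "mean_pairwise")) {
  mode <- match.arg(mode)
  if (!length(group_a) || !length(group_b))
    stop("both groups must be non-empty")
  cols <- codingColumns(cmap)
  ma <- .chm(x, group_a); mb <- .chm(x, group_b)
  if (mode == "fixed_only") {
    ca <- .fixed_consensus(ma); cb <- .fixed_consensus(mb)
    if (any(ca[cols] == "-") || any(cb[cols] == "-"))
      stop("frame error: group consensus contains gaps inside the coding region")
    neiGojoboriPair(paste(ca[cols], collapse = ""),
                    paste(cb[cols], collapse = ""))
  } else {
    acc <- list(S = 0, N = 0, Sd = 0, Nd = 0, n_codons = 0L)
    npair <- 0L
    for (i in seq_len(nrow(ma))) for (j in seq_len(nrow(mb))) {
      cnt <- .ng_pair_counts(.codons(paste(ma[i, cols], collapse = "")),
                             .codons(paste(mb[j, cols], collapse = "")))
      acc <- Map(`+`, acc, cnt)
      npair <- npair + 1L
    }
    acc <- lapply(acc, function(v) v / npair)
    acc$n_codons <- as.integer(round(acc$n_codons))
    .pairwise_divergence(acc)
  }
}

#' Tajima's D
#'
#' `D = (k - S/a1) / sqrt(e1*S + e2*S*(S-1))` with the standard constants of
#' Tajima (1989). Undefined (returned as `NA` with an `undefined_reason`
#' attribute) when `S = 0` or fewer than 4 haplotypes.
#'
#' @param n_hap Number of haplotypes.
#' @param S Number of segregating sites.
#' @param mean_pairwise_k Mean number of pairwise differences (a count, not
#'   per site).
#' @return Numeric `D`, or flagged `NA` when undefined.
#' @export
tajimaD <- function(n_hap, S, mean_pairwise_k) {
  if (n_hap < 4L)
    return(structure(NA_real_, undefined_reason = "fewer than 4 haplotypes"))
  if (S < 1L)
    return(structure(NA_real_, undefined_reason = "no segregating sites"))
  n <- n_hap
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (mean_pairwise_k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Polymorphism summary for one group, partitioned by site class
#'
#' Nucleotide diversity (Nei's estimator: mean pairwise differences per
#' comparable site, no small-sample scaling), segregating-site counts and
#' Tajima's D for one (population, paralog) group, partitioned into
#' synonymous, nonsynonymous and silent (synonymous + noncoding) classes via
#' Nei-Gojobori site counting. Columns with a gap in any group member are
#' excluded from segregating-site counts (listwise); pairwise diversities
#' exclude gap/N codons per pair.
#'
#' A segregating coding column is classed synonymous when all codon variants
#' observed at its codon translate to the same amino acid, otherwise
#' nonsynonymous.
#'
#' @param x A [GroupedAlignment-class].
#' @param cmap A [CodingMap-class], or `NULL` for fully noncoding input
#'   (all diversity is then silent).
#' @param group Integer record indices (>= 2 required; see [selectGroup()]).
#' @return A `PolymorphismSummary` list: `n_hap`, `pi_syn`, `s_syn`,
#'   `pi_nonsyn`, `s_nonsyn`, `pi_silent`, `s_silent`, `pi_total`, `s_total`,
#'   `mean_k`, `tajima_d` (flagged `NA` when undefined).
#' @export
piByClass <- function(x, cmap = NULL, group) {
  if (length(group) < 2L) stop("at least 2 haplotypes required")
  m <- .chm(x, group)
  L <- ncol(m)
  cod_cols <- if (is.null(cmap)) integer(0) else codingColumns(cmap)
  nc_cols <- setdiff(seq_len(L), cod_cols)
  n <- nrow(m)
  pairs <- utils::combn(n, 2)

  ## pairwise diversities
  ps_syn <- ps_non <- ps_sil <- ps_tot <- rep(NA_real_, ncol(pairs))
  k_tot <- rep(NA_real_, ncol(pairs))
  incl <- !apply(m == "-", 2, any)   # listwise columns for S and k
  for (p in seq_len(ncol(pairs))) {
    a <- m[pairs[1, p], ]; b <- m[pairs[2, p], ]
    cnt <- if (length(cod_cols))
      .ng_pair_counts(.codons(paste(a[cod_cols], collapse = "")),
                      .codons(paste(b[cod_cols], collapse = "")))
    else list(S = 0, N = 0, Sd = 0, Nd = 0, n_codons = 0L)
    comp_nc <- a[nc_cols] %in% .BASES & b[nc_cols] %in% .BASES
    d_nc <- sum(comp_nc & a[nc_cols] != b[nc_cols])
    n_nc <- sum(comp_nc)
    if (cnt$S > 0) ps_syn[p] <- cnt$Sd / cnt$S
    if (cnt$N > 0) ps_non[p] <- cnt$Nd / cnt$N
    if (cnt$S + n_nc > 0) ps_sil[p] <- (cnt$Sd + d_nc) / (cnt$S + n_nc)
    comp <- a %in% .BASES & b %in% .BASES & incl
    if (any(comp)) ps_tot[p] <- sum(a[comp] != b[comp]) / sum(comp)
    k_tot[p] <- sum(comp & a != b)
  }
  avg <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)

  ## segregating sites on listwise-included columns
  seg <- vapply(seq_len(L), function(j) {
    if (!incl[j]) return(FALSE)
    length(unique(m[m[, j] %in% .BASES, j])) >= 2L
  }, logical(1))
  seg_cols <- which(seg)
  s_nc <- sum(seg_cols %in% nc_cols)
  s_syn <- s_non <- 0L
  if (length(cod_cols)) {
    gc <- Biostrings::GENETIC_CODE
    col2codon <- match(seq_len(L), cod_cols)
    for (j in intersect(seg_cols, cod_cols)) {
      k <- (col2codon[j] - 1L) %/% 3L + 1L
      ccols <- cod_cols[(3L * k - 2L):(3L * k)]
      codons <- apply(m[, ccols, drop = FALSE], 1, paste, collapse = "")
      codons <- codons[!grepl("[^ACGT]", codons)]
      if (!length(codons)) next
      aas <- unique(unname(gc[unique(codons)]))
      if (length(aas) == 1L) s_syn <- s_syn + 1L else s_non <- s_non + 1L
    }
  }
  S_tot <- length(seg_cols)
  kbar <- mean(k_tot, na.rm = TRUE)
  structure(list(
    n_hap = n,
    pi_syn = if (length(cod_cols)) avg(ps_syn) else NA_real_,
    s_syn = s_syn,
    pi_nonsyn = if (length(cod_cols)) avg(ps_non) else NA_real_,
    s_nonsyn = s_non,
    pi_silent = avg(ps_sil),
    s_silent = s_syn + s_nc,
    pi_total = avg(ps_tot),
    s_total = S_tot,
    mean_k = kbar,
    tajima_d = tajimaD(n, S_tot, kbar)),
    class = "PolymorphismSummary")
}

#' @export
print.PolymorphismSummary <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.5f", v))
  cat(sprintf(paste0("PolymorphismSummary (%d haplotypes)\n",
                     "  pi_syn = %s (S = %d)   pi_nonsyn = %s (S = %d)\n",
                     "  pi_silent = %s (S = %d)   pi_total = %s (S = %d)\n",
                     "  Tajima's D = %s\n"),
              x$n_hap, fmt(x$pi_syn), x$s_syn, fmt(x$pi_nonsyn), x$s_nonsyn,
              fmt(x$pi_silent), x$s_silent, fmt(x$pi_total), x$s_total,
              ifelse(is.na(x$tajima_d), "undefined",
                     sprintf("%.3f", x$tajima_d))))
  invisible(x)
}

#' @export
as.data.frame.PolymorphismSummary <- function(x, ...) {
  data.frame(n_hap = x$n_hap, pi_syn = x$pi_syn, s_syn = x$s_syn,
             pi_nonsyn = x$pi_nonsyn, s_nonsyn = x$s_nonsyn,
             pi_silent = x$pi_silent, s_silent = x$s_silent,
             tajima_d = as.numeric(x$tajima_d))
}

#' Sliding-window between-group divergence (Dxy)
#'
#' For each window, `Dxy` is the mean across all between-group sequence
#' pairs of (differences / comparable sites) within the window, with
#' pairwise exclusion of gaps and `N`. Windows are emitted only while
#' `start + window - 1 <= L` (no ragged final window). Windows where no pair
#' has comparable sites are `NA`, and windows averaging fewer than 10
#' comparable sites are flagged low-confidence.
#'
#' @param x A [GroupedAlignment-class].
#' @param group_a,group_b Integer record indices.
#' @param window Window size in bp.
#' @param step Step size in bp (>= 1).
#' @return A `data.frame` (`WindowProfile`): `start`, `end`, `mid`, `dxy`,
#'   `n_sites` (mean comparable sites per pair), `low_conf`. Window and step
#'   are recorded as attributes.
#' @export
slidingDxy <- function(x, group_a, group_b, window, step) {
  L <- alnLength(x)
  if (window > L) stop("window larger than alignment")
  if (step < 1L) stop("step must be >= 1")
  ma <- .chm(x, group_a); mb <- .chm(x, group_b)
  starts <- seq.int(1L, L - window + 1L, by = step)
  npair <- nrow(ma) * nrow(mb)
  dmat <- matrix(0L, nrow = npair, ncol = L)
  cmat <- matrix(0L, nrow = npair, ncol = L)
  p <- 0L
  for (i in seq_len(nrow(ma))) for (j in seq_len(nrow(mb))) {
    p <- p + 1L
    comp <- ma[i, ] %in% .BASES & mb[j, ] %in% .BASES
    cmat[p, ] <- as.integer(comp)
    dmat[p, ] <- as.integer(comp & ma[i, ] != mb[j, ])
  }
  cd <- t(apply(dmat, 1, cumsum)); cc <- t(apply(cmat, 1, cumsum))
  wsum <- function(cs, s, e) cs[, e] - (if (s > 1) cs[, s - 1] else 0)
  out <- lapply(starts, function(s) {
    e <- s + window - 1L
    dw <- wsum(cd, s, e); cw <- wsum(cc, s, e)
    ok <- cw > 0
    dxy <- if (any(ok)) mean(dw[ok] / cw[ok]) else NA_real_
    data.frame(start = s, end = e, mid = (s + e) / 2, dxy = dxy,
               n_sites = mean(cw), low_conf = mean(cw) < 10)
  })
  res <- do.call(rbind, out)
  attr(res, "window") <- window
  attr(res, "step") <- step
  class(res) <- c("WindowProfile", "data.frame")
  res
}

#' Per-column Shannon entropy of a protein alignment
#'
#' `H = -sum(p_a * log2(p_a))` over non-gap residues in each column, the
#' conservation measure used for protein-alignment variability profiles.
#' All-gap columns are `NA`.
#'
#' @param x Aligned proteins: a character vector of equal-length strings, a
#'   character matrix (rows = sequences), or an `AAStringSet`.
#' @return Numeric vector of per-column entropies in bits.
#' @export
columnEntropy <- function(x) {
  if (is(x, "XStringSet")) x <- as.character(x)
  if (is.character(x)) x <- do.call(rbind, strsplit(toupper(x), ""))
  stopifnot(is.matrix(x))
  apply(x, 2, function(col) {
    col <- col[col != "-"]
    if (!length(col)) return(NA_real_)
    p <- table(col) / length(col)
    -sum(p * log2(p))
  })
}
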