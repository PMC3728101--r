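#' @useDynLib paraconv, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.STATE_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L)

#' Project an alignment onto its polymorphic sites
#'
#' Restricts the alignment, within one population (both paralogs), to the
#' columns that are polymorphic among the in-scope sequences. Columns
#' containing a gap in any in-scope sequence are excluded (a column is
#' droppable, never a match); `N` is kept but treated as missing.
#' Original alignment coordinates are preserved.
#'
#' @param x A [GroupedAlignment-class].
#' @param population Population label defining the scope (>= 4 sequences
#'   required).
#' @return A `PolymorphicProjection` list: `columns` (original coordinates),
#'   `states` (integer matrix, rows = sequences, 0 = missing), `ids`,
#'   `paralog`, `population`.
#' @export
projectPolymorphic <- function(x, population) {
  idx <- selectGroup(x, population = population)
  if (length(idx) < 4L)
    stop("at least 4 sequences required in population ", population)
  m <- .chm(x, idx)
  keep <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    if (any(col == "-")) return(FALSE)
    length(unique(col[col %in% .BASES])) >= 2L
  }, logical(1))
  cols <- which(keep)
  if (length(cols) < 2L)
    warning("fewer than 2 polymorphic columns in population ", population,
            "; conversion scan will be skipped")
  states <- matrix(0L, nrow = nrow(m), ncol = length(cols),
                   dimnames = list(rownames(m), NULL))
  if (length(cols)) {
    sub <- m[, cols, drop = FALSE]
    states[] <- ifelse(sub %in% .BASES, .STATE_CODE[sub], 0L)
  }
  structure(list(columns = cols, states = states,
                 ids = groupInfo(x)$haplotype_id[idx],
                 paralog = groupInfo(x)$paralog[idx],
                 population = population),
            class = "PolymorphicProjection")
}

## Ruzzo-Tompa maximal scoring segments (used when mismatch penalty g > 0)
.rt_segments <- function(sc) {
  cum <- c(0, cumsum(sc))
  I <- vector("list", length(sc))
  k <- 0L
  for (i in seq_along(sc)) {
    if (sc[i] <= 0) next
    seg <- list(s = i, e = i, Ls = cum[i], Rs = cum[i + 1])
    repeat {
      j <- k
      while (j >= 1L && I[[j]]$Ls >= seg$Ls) j <- j - 1L
      if (j == 0L || I[[j]]$Rs >= seg$Rs) {
        k <- k + 1L
        I[[k]] <- seg
        break
      }
      seg <- list(s = I[[j]]$s, e = seg$e, Ls = I[[j]]$Ls, Rs = seg$Rs)
      k <- j - 1L
    }
  }
  I[seq_len(k)]
}

#' Candidate conversion fragments for one sequence pair
#'
#' With the default mismatch penalty `g = 0`, fragments are maximal runs of
#' consecutive polymorphic sites at which the two sequences are identical,
#' terminated by any mismatch (or missing state). With `g > 0`, fragments
#' are the maximal scoring segments of the +1 (match) / -g (mismatch) score
#' sequence (Ruzzo-Tompa). Fragments supported by fewer than 2 polymorphic
#' sites are discarded.
#'
#' @param proj A [projectPolymorphic()] result.
#' @param seq_i,seq_j Haplotype ids (or row indices into the projection).
#' @param g Mismatch penalty (>= 0, default 0).
#' @return `data.frame` with `start`, `end` (original alignment coordinates
#'   of the first/last supporting site), `n_poly_sites`, `score`.
#' @export
pairFragments <- function(proj, seq_i, seq_j, g = 0) {
  ri <- if (is.character(seq_i)) match(seq_i, proj$ids) else seq_i
  rj <- if (is.character(seq_j)) match(seq_j, proj$ids) else seq_j
  if (is.na(ri) || is.na(rj)) stop("sequence not in projection")
  a <- proj$states[ri, ]; b <- proj$states[rj, ]
  if (!length(a))
    return(data.frame(start = integer(0), end = integer(0),
                      n_poly_sites = integer(0), score = numeric(0)))
  match_v <- a > 0L & a == b
  if (g == 0) {
    r <- rle(match_v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= 2L
    segs <- Map(function(s, e) list(s = s, e = e, score = e - s + 1),
                starts[keep], ends[keep])
  } else {
    sc <- ifelse(match_v, 1, -g)
    segs <- Filter(function(sg) sum(match_v[sg$s:sg$e]) >= 2L,
                   lapply(.rt_segments(sc), function(sg)
                     list(s = sg$s, e = sg$e, score = sg$Rs - sg$Ls)))
  }
  if (!length(segs))
    return(data.frame(start = integer(0), end = integer(0),
                      n_poly_sites = integer(0), score = numeric(0)))
  data.frame(
    start = proj$columns[vapply(segs, `[[`, numeric(1), "s")],
    end = proj$columns[vapply(segs, `[[`, numeric(1), "e")],
    n_poly_sites = vapply(segs, function(sg) sum(match_v[sg$s:sg$e]),
                          numeric(1)),
    score = vapply(segs, `[[`, numeric(1), "score"))
}

.all_permutations <- function(n) {
  perms <- .permutations(seq_len(n))
  do.call(rbind, perms)
}

#' Permutation p-values for candidate fragments
#'
#' The null distribution is the maximum fragment score over all allowed
#' pairs when the polymorphic columns are randomly re-ordered (states move
#' together as whole columns). A fragment's global
#' `sim_p = (1 + #\{perm max >= observed score\}) / (n_perm + 1)`, which
#' controls the family-wise error across pairs without a separate
#' Bonferroni step. With `exhaustive = TRUE` all `n!` column orders are
#' enumerated (only feasible for small projections) and the exact
#' proportion is returned.
#'
#' @param proj A [projectPolymorphic()] result.
#' @param allowed_pairs Two-column matrix of haplotype ids (or row indices):
#'   the pairs in which conversion is allowed.
#' @param n_perm Number of permutations (>= 1000 recommended).
#' @param seed Optional integer seed (set once before sampling).
#' @param g Mismatch penalty; the permutation null is implemented for the
#'   default `g = 0` scan.
#' @param exhaustive Enumerate all column orders instead of sampling.
#' @return `data.frame` of fragments (`seq_i`, `seq_j`, `start`, `end`,
#'   `n_poly_sites`, `score`, `sim_p`), with the null maxima in attribute
#'   `null_max`.
#' @export
permutationPvalues <- function(proj, allowed_pairs, n_perm = 10000,
                               seed = NULL, g = 0, exhaustive = FALSE) {
  if (is.null(allowed_pairs) || nrow(allowed_pairs) == 0L)
    stop("allowed_pairs must be non-empty")
  if (g != 0)
    stop("the permutation null is implemented for the default g = 0 scan")
  if (!is.null(seed)) set.seed(seed)
  ap <- allowed_pairs
  if (is.character(ap)) {
    ap <- cbind(match(ap[, 1], proj$ids), match(ap[, 2], proj$ids))
    if (anyNA(ap)) stop("allowed pair sequence not in projection")
  }
  ap <- matrix(as.integer(ap), ncol = 2)
  frags <- do.call(rbind, lapply(seq_len(nrow(ap)), function(q) {
    f <- pairFragments(proj, ap[q, 1], ap[q, 2], g = g)
    if (nrow(f))
      cbind(data.frame(seq_i = proj$ids[ap[q, 1]],
                       seq_j = proj$ids[ap[q, 2]]), f)
    else NULL
  }))
  nsite <- ncol(proj$states)
  if (nsite < 2L) {
    if (!is.null(frags)) frags$sim_p <- NA_real_
    return(frags)
  }
  if (exhaustive) {
    if (nsite > 8L) stop("exhaustive enumeration limited to <= 8 sites")
    perms <- .all_permutations(nsite)
  } else {
    perms <- t(vapply(seq_len(n_perm), function(i) sample.int(nsite),
                      integer(nsite)))
  }
  null_max <- .perm_max_run(proj$states, ap, perms)
  if (is.null(frags))
    frags <- data.frame(seq_i = character(0), seq_j = character(0),
                        start = integer(0), end = integer(0),
                        n_poly_sites = integer(0), score = numeric(0))
  frags$sim_p <- if (nrow(frags) == 0L) numeric(0)
    else if (exhaustive)
      vapply(frags$score, function(s) mean(null_max >= s), numeric(1))
    else
      vapply(frags$score,
             function(s) (1 + sum(null_max >= s)) / (nrow(perms) + 1),
             numeric(1))
  attr(frags, "null_max") <- null_max
  frags
}

#' Gene-conversion scan with population x paralog group structure
#'
#' For each population with at least 4 sequenced haplotypes, projects the
#' alignment onto its polymorphic sites, enumerates candidate fragments for
#' every within-population sequence pair (conversion is only allowed within
#' populations), and assigns global permutation p-values
#' ([permutationPvalues()]). Fragments are classed `inter_paralog` when the
#' two sequences carry different paralog labels, else `intra_paralog`.
#'
#' @param x A [GroupedAlignment-class].
#' @param n_perm Permutations per population (default 10000).
#' @param alpha Significance level for reporting (default 0.05).
#' @param g Mismatch penalty (default 0).
#' @param seed Integer seed (one seed drives all populations).
#' @param populations Optional subset of populations to scan.
#' @return A `ConversionScan` list: `fragments` data.frame (`population`,
#'   `category`, `seq_i`, `seq_j`, `start`, `end`, `n_poly_sites`, `score`,
#'   `sim_p`, `significant`), plus `alpha`, `n_perm`, and per-population
#'   null maxima.
#' @export
scanConversion <- function(x, n_perm = 10000, alpha = 0.05, g = 0,
                           seed = NULL, populations = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pops <- populations
  if (is.null(pops)) pops <- unique(groupInfo(x)$population)
  all_frags <- list()
  nulls <- list()
  for (pop in pops) {
    idx <- selectGroup(x, population = pop)
    if (length(idx) < 4L) {
      warning("population ", pop, " has fewer than 4 sequences; skipped")
      next
    }
    proj <- withCallingHandlers(projectPolymorphic(x, pop),
                                warning = function(w) invokeRestart("muffleWarning"))
    if (length(proj$columns) < 2L) {
      warning("population ", pop,
              " has fewer than 2 polymorphic columns; scan skipped")
      next
    }
    pr <- t(utils::combn(length(proj$ids), 2))
    fr <- permutationPvalues(proj, pr, n_perm = n_perm, g = g)
    nulls[[pop]] <- attr(fr, "null_max")
    if (nrow(fr)) {
      par_i <- proj$paralog[match(fr$seq_i, proj$ids)]
      par_j <- proj$paralog[match(fr$seq_j, proj$ids)]
      fr <- cbind(data.frame(population = pop,
                             category = ifelse(par_i != par_j,
                                               "inter_paralog",
                                               "intra_paralog")),
                  fr)
      all_frags[[pop]] <- fr
    }
  }
  frags <- if (length(all_frags)) do.call(rbind, all_frags) else
    data.frame(population = character(0), category = character(0),
               seq_i = character(0), seq_j = character(0),
               start = integer(0), end = integer(0),
               n_poly_sites = integer(0), score = numeric(0),
               sim_p = numeric(0))
  rownames(frags) <- NULL
  frags$significant <- frags$sim_p < alpha
  structure(list(fragments = frags, alpha = alpha, n_perm = n_perm,
                 null_max = nulls),
            class = "ConversionScan")
}

#' @export
print.ConversionScan <- function(x, ...) {
  sig <- x$fragments[x$fragments$significant, , drop = FALSE]
  cat(sprintf(paste0("ConversionScan: %d candidate fragment(s), ",
                     "%d significant at alpha = %g (n_perm = %d)\n"),
              nrow(x$fragments), nrow(sig), x$alpha, x$n_perm))
  if (nrow(sig)) print(utils::head(sig, 20))
  invisible(x)
}

#' Minimum non-overlapping conversion events
#'
#' Groups significant fragments by (population, category) and merges
#' overlap-connected fragments into event clusters; the number of clusters
#' per group is the reported minimum number of gene conversion events.
#'
#' @param fragments Fragment `data.frame` from [scanConversion()] (or a
#'   `ConversionScan`).
#' @param alpha Significance level (fragments with `sim_p < alpha` enter
#'   clustering).
#' @return `data.frame` of clusters: `population`, `category`,
#'   `merged_start`, `merged_end`, `n_fragments`.
#' @export
classifyAndCluster <- function(fragments, alpha = 0.05) {
  if (is(fragments, "ConversionScan")) fragments <- fragments$fragments
  sig <- fragments[!is.na(fragments$sim_p) & fragments$sim_p < alpha, ,
                   drop = FALSE]
  out <- list()
  if (nrow(sig)) {
    for (key in unique(paste(sig$population, sig$category, sep = "\r"))) {
      parts <- strsplit(key, "\r")[[1]]
      sub <- sig[sig$population == parts[1] & sig$category == parts[2], ,
                 drop = FALSE]
      sub <- sub[order(sub$start, sub$end), , drop = FALSE]
      cs <- sub$start[1]; ce <- sub$end[1]; nf <- 1L
      for (r in seq_len(nrow(sub))[-1]) {
        if (sub$start[r] <= ce) {
          ce <- max(ce, sub$end[r]); nf <- nf + 1L
        } else {
          out[[length(out) + 1L]] <- data.frame(
            population = parts[1], category = parts[2],
            merged_start = cs, merged_end = ce, n_fragments = nf)
          cs <- sub$start[r]; ce <- sub$end[r]; nf <- 1L
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        population = parts[1], category = parts[2],
        merged_start = cs, merged_end = ce, n_fragments = nf)
    }
  }
  if (!length(out))
    return(data.frame(population = character(0), category = character(0),
                      merged_start = integer(0), merged_end = integer(0),
                      n_fragments = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$population, res$category, res$merged_start), , drop = FALSE]
}
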