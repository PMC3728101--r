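#' Shared-paralog sites
#'
#' A footprint of within-population gene conversion: a column where both
#' paralogs of one population share a state (fixed or polymorphic in each)
#' that occurs in no sequence of any other population. The "not across
#' populations" clause is read strictly: the shared state must be absent
#' from every sequence (both paralogs) of every other population.
#'
#' @param x A [GroupedAlignment-class] with at least two populations and
#'   both paralogs present in each focal population.
#' @return `data.frame` of calls: `column`, `population`, `shared_state`,
#'   `status_a`, `status_b` (`"fixed"`/`"polymorphic"` within each paralog),
#'   `paralog_a`, `paralog_b`.
#' @export
sharedParalogSites <- function(x) {
  info <- groupInfo(x)
  pops <- unique(info$population)
  if (length(pops) < 2L)
    stop("shared-paralog sites are undefined for a single-population alignment")
  m <- .chm(x)
  out <- list()
  for (pop in pops) {
    pars <- unique(info$paralog[info$population == pop])
    if (length(pars) < 2L) next
    pa <- pars[1]; pb <- pars[2]
    ia <- selectGroup(x, population = pop, paralog = pa)
    ib <- selectGroup(x, population = pop, paralog = pb)
    iother <- which(info$population != pop)
    for (j in seq_len(ncol(m))) {
      sa <- m[ia, j]; sa <- sa[sa %in% .BASES]
      sb <- m[ib, j]; sb <- sb[sb %in% .BASES]
      if (!length(sa) || !length(sb)) next
      shared <- intersect(unique(sa), unique(sb))
      if (!length(shared)) next
      others <- m[iother, j]
      for (s in shared) {
        if (s %in% others) next
        out[[length(out) + 1L]] <- data.frame(
          column = j, population = pop, shared_state = s,
          status_a = if (length(unique(sa)) == 1L) "fixed" else "polymorphic",
          status_b = if (length(unique(sb)) == 1L) "fixed" else "polymorphic",
          paralog_a = pa, paralog_b = pb)
      }
    }
  }
  if (!length(out))
    return(data.frame(column = integer(0), population = character(0),
                      shared_state = character(0), status_a = character(0),
                      status_b = character(0), paralog_a = character(0),
                      paralog_b = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Haplotype classes by single-linkage clustering
#'
#' Clusters a group's haplotypes on pairwise difference counts within a
#' region (single linkage, cut at `max_within_class_diff`), the procedure
#' used to delimit allele classes such as "1-like" vs "2-like" haplotypes of
#' a converted paralog. Classes are labelled deterministically by their
#' lexicographically smallest member id; single-member classes are flagged.
#'
#' @param x A [GroupedAlignment-class].
#' @param group Integer record indices (see [selectGroup()]).
#' @param region `c(start, end)` 1-based inclusive columns (default: whole
#'   alignment).
#' @param max_within_class_diff Haplotypes closer than or equal to this many
#'   differences (via single linkage) join one class.
#' @return `data.frame`: `haplotype_id`, `class` (label of smallest member),
#'   `singleton`.
#' @export
classHaplotypes <- function(x, group, region = NULL,
                            max_within_class_diff = 0) {
  if (!length(group)) stop("group must be non-empty")
  L <- alnLength(x)
  if (is.null(region)) region <- c(1L, L)
  if (region[1] < 1L || region[2] > L) stop("region outside alignment")
  m <- .chm(x, group)[, region[1]:region[2], drop = FALSE]
  ids <- groupInfo(x)$haplotype_id[group]
  n <- nrow(m)
  if (n == 1L)
    return(data.frame(haplotype_id = ids, class = ids, singleton = TRUE))
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    comp <- m[i, ] %in% .BASES & m[j, ] %in% .BASES
    d[i, j] <- d[j, i] <- sum(comp & m[i, ] != m[j, ])
  }
  hc <- stats::hclust(stats::as.dist(d), method = "single")
  cl <- stats::cutree(hc, h = max_within_class_diff)
  lab <- vapply(unique(cl), function(k) sort(ids[cl == k])[1], character(1))
  names(lab) <- unique(cl)
  cls <- lab[as.character(cl)]
  sizes <- table(cls)
  data.frame(haplotype_id = ids, class = unname(cls),
             singleton = unname(sizes[cls] == 1L))
}

#' Donor profile of a putatively chimeric haplotype class
#'
#' Contrasts, in sliding windows, the divergence of a focal haplotype class
#' to its own orthologs (same paralog, other populations) against its
#' divergence to the other paralog. Windows where the focal class is closer
#' to the other paralog than to its own orthologs by more than
#' `call_threshold` are flagged as putatively converted; breakpoints are
#' called where the delta track changes sign with magnitude above the
#' threshold on both sides, at the midpoint between the two flanking window
#' midpoints.
#'
#' @param x A [GroupedAlignment-class].
#' @param focal Integer indices of the focal class.
#' @param own_refs Integer indices of the same-paralog reference sequences.
#' @param other_refs Integer indices of the other-paralog references. Both
#'   reference sets must be disjoint from the focal class.
#' @param window,step Window/step in bp (defaults 60/12).
#' @param call_threshold Minimum |delta| (substitutions/site) to flag a
#'   window or support a breakpoint (default 0.05).
#' @return A `DonorProfile` list: `windows` data.frame (`start`, `end`,
#'   `mid`, `dxy_own`, `dxy_other`, `delta`, `flagged`) and `breakpoints`
#'   (numeric positions).
#' @export
donorProfile <- function(x, focal, own_refs, other_refs,
                         window = 60, step = 12, call_threshold = 0.05) {
  if (!length(own_refs) || !length(other_refs))
    stop("reference groups must be non-empty")
  if (length(intersect(focal, c(own_refs, other_refs))))
    stop("reference groups must be disjoint from the focal class")
  own <- slidingDxy(x, focal, own_refs, window, step)
  oth <- slidingDxy(x, focal, other_refs, window, step)
  delta <- own$dxy - oth$dxy
  win <- data.frame(start = own$start, end = own$end, mid = own$mid,
                    dxy_own = own$dxy, dxy_other = oth$dxy, delta = delta,
                    flagged = !is.na(delta) & delta > call_threshold)
  bps <- numeric(0)
  ok <- which(!is.na(delta) & abs(delta) > call_threshold)
  if (length(ok) > 1L) {
    for (k in seq_len(length(ok) - 1L)) {
      i <- ok[k]; j <- ok[k + 1L]
      if (sign(delta[i]) != sign(delta[j]) &&
          all(is.na(delta[seq(i, j)][-c(1, j - i + 1)]) |
              abs(delta[seq(i, j)][-c(1, j - i + 1)]) <= call_threshold))
        bps <- c(bps, (win$mid[i] + win$mid[j]) / 2)
    }
  }
  structure(list(windows = win, breakpoints = bps,
                 window = window, step = step,
                 call_threshold = call_threshold),
            class = "DonorProfile")
}

#' @export
print.DonorProfile <- function(x, ...) {
  cat(sprintf(paste0("DonorProfile: %d windows (%d/%d bp), %d flagged as ",
                     "putatively converted\n  breakpoints: %s\n"),
              nrow(x$windows), x$window, x$step, sum(x$windows$flagged),
              if (length(x$breakpoints))
                paste(round(x$breakpoints, 1), collapse = ", ")
              else "none"))
  invisible(x)
}
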