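#' @importFrom ape read.tree write.tree root unroot consensus prop.clades
#'   bind.tree reorder.phylo dist.nodes Ntip
#' @importFrom phangorn nni RF.dist
NULL

.FITCH_CODE <- c(A = 1L, C = 2L, G = 4L, T = 8L)

## encode a character matrix (rows = taxa) as Fitch state bitmasks with
## site-pattern compression; gaps and N are missing (any state = 15)
.fitch_bits <- function(m) {
  bits <- matrix(15L, nrow = nrow(m), ncol = ncol(m),
                 dimnames = dimnames(m))
  known <- m %in% names(.FITCH_CODE)
  bits[known] <- .FITCH_CODE[m[known]]
  key <- apply(bits, 2, paste, collapse = ",")
  tab <- table(key)
  first <- match(names(tab), key)
  list(bits = bits[, first, drop = FALSE], weights = as.numeric(tab))
}

## Fitch parsimony length of `tree` given compressed patterns
.fitch_eval <- function(tree, bits, weights) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  npat <- ncol(bits)
  nn <- ntip + tr$Nnode
  states <- matrix(0L, nrow = nn, ncol = npat)
  states[seq_len(ntip), ] <- bits[tr$tip.label, , drop = FALSE]
  seen <- logical(nn)
  seen[seq_len(ntip)] <- TRUE
  score <- 0
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    if (!seen[par]) {
      states[par, ] <- states[child, ]
      seen[par] <- TRUE
    } else {
      tmp <- bitwAnd(states[par, ], states[child, ])
      empty <- tmp == 0L
      if (any(empty)) {
        score <- score + sum(weights[empty])
        tmp[empty] <- bitwOr(states[par, empty], states[child, empty])
      }
      states[par, ] <- tmp
    }
  }
  score
}

.partition_cols <- function(x, partition) {
  L <- alnLength(x)
  if (is.null(partition)) return(seq_len(L))
  if (is.list(partition)) partition <- c(partition$start, partition$end)
  stopifnot(length(partition) == 2L)
  if (partition[1] < 1L || partition[2] > L || partition[1] > partition[2])
    stop("partition interval outside alignment")
  seq.int(partition[1], partition[2])
}

#' Fitch parsimony score of a tree
#'
#' Sum over columns of the Fitch set-intersection cost, with site-pattern
#' compression. Gaps and `N` are scored as missing data (any state), not as
#' a fifth state. Multifurcations are folded pairwise in child order, which
#' is exact for the basal trichotomy of an unrooted binary tree.
#'
#' @param tree An [ape::phylo] tree whose tips are haplotype ids of `x`.
#' @param x A [GroupedAlignment-class].
#' @param partition Optional `c(start, end)` 1-based inclusive column
#'   interval (default: whole alignment).
#' @return Integer parsimony length.
#' @export
fitchScore <- function(tree, x, partition = NULL) {
  missing_tips <- setdiff(tree$tip.label, haplotypeIds(x))
  if (length(missing_tips))
    stop("tip(s) absent from alignment: ",
         paste(missing_tips, collapse = ", "))
  cols <- .partition_cols(x, partition)
  m <- .chm(x, match(tree$tip.label, haplotypeIds(x)))[, cols, drop = FALSE]
  fb <- .fitch_bits(m)
  .fitch_eval(tree, fb$bits, fb$weights)
}

.tip_phylo <- function(label) {
  structure(list(edge = matrix(c(2L, 1L), 1, 2), tip.label = label,
                 edge.length = 1, Nnode = 1L),
            class = "phylo")
}

## greedy random-addition starting tree followed by NNI hill climbing;
## returns list(tree, score, plateau = equal-score NNI neighbours)
.one_search <- function(taxa, bits, weights) {
  ord <- sample(taxa)
  tree <- ape::read.tree(text = sprintf("(%s,%s,%s);", ord[1], ord[2], ord[3]))
  tree$edge.length <- rep(1, nrow(tree$edge))
  for (t in ord[-(1:3)]) {
    best <- NULL; best_sc <- Inf
    for (e in seq_len(nrow(tree$edge))) {
      cand <- ape::bind.tree(tree, .tip_phylo(t),
                             where = tree$edge[e, 2], position = 0.5)
      cand$edge.length <- rep(1, nrow(cand$edge))
      sc <- .fitch_eval(cand, bits, weights)
      if (sc < best_sc) { best <- cand; best_sc <- sc }
    }
    tree <- best
  }
  sc <- .fitch_eval(tree, bits, weights)
  repeat {
    nbs <- phangorn::nni(tree)
    nsc <- vapply(nbs, .fitch_eval, numeric(1), bits = bits,
                  weights = weights)
    if (min(nsc) < sc) {
      tree <- nbs[[which.min(nsc)]]
      sc <- min(nsc)
    } else break
  }
  ## [[ extraction decompresses multiPhylo tip labels
  plateau <- lapply(which(nsc == sc), function(i) nbs[[i]])
  list(tree = tree, score = sc, plateau = plateau)
}

.dedupe_trees <- function(trees) {
  keep <- list()
  for (tr in trees) {
    dup <- any(vapply(keep, function(k)
      phangorn::RF.dist(ape::unroot(k), ape::unroot(tr)) == 0, logical(1)))
    if (!dup) keep[[length(keep) + 1L]] <- tr
  }
  class(keep) <- "multiPhylo"
  keep
}

.mp_search_mat <- function(m, n_starts, collect_ties = TRUE) {
  taxa <- rownames(m)
  fb <- .fitch_bits(m)
  pool <- list(); pool_sc <- numeric(0)
  for (s in seq_len(n_starts)) {
    res <- .one_search(taxa, fb$bits, fb$weights)
    pool[[length(pool) + 1L]] <- res$tree
    pool_sc <- c(pool_sc, res$score)
    if (collect_ties && length(res$plateau)) {
      for (tr in res$plateau) {
        pool[[length(pool) + 1L]] <- tr
        pool_sc <- c(pool_sc, res$score)
      }
    }
  }
  best <- min(pool_sc)
  trees <- .dedupe_trees(pool[pool_sc == best])
  list(trees = trees, score = best)
}

#' Heuristic maximum-parsimony search
#'
#' Random-addition starting trees followed by nearest-neighbour-interchange
#' (NNI) hill climbing under the Fitch criterion. All distinct topologies
#' attaining the best score found (including equal-score NNI neighbours of
#' the local optima) are returned.
#'
#' @param x A [GroupedAlignment-class].
#' @param partition Optional `c(start, end)` column interval.
#' @param n_starts Number of random-addition starts (default 10).
#' @param seed Optional integer seed.
#' @param taxa Optional subset of haplotype ids (default: all records).
#' @return List with `trees` (a `multiPhylo` of the best topologies) and
#'   `score` (best parsimony length).
#' @export
searchMP <- function(x, partition = NULL, n_starts = 10, seed = NULL,
                     taxa = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(taxa)) taxa <- haplotypeIds(x)
  cols <- .partition_cols(x, partition)
  m <- .chm(x, match(taxa, haplotypeIds(x)))[, cols, drop = FALSE]
  rownames(m) <- taxa
  if (length(taxa) < 4L) {
    warning("fewer than 4 taxa: returning the trivial topology")
    tree <- ape::read.tree(text = paste0("(", paste(taxa, collapse = ","), ");"))
    fb <- .fitch_bits(m)
    trees <- list(tree); class(trees) <- "multiPhylo"
    return(list(trees = trees, score = .fitch_eval(tree, fb$bits, fb$weights)))
  }
  .mp_search_mat(m, n_starts)
}

#' Bootstrap majority-rule consensus tree under parsimony
#'
#' Resamples alignment columns with replacement, runs a reduced parsimony
#' search per replicate, builds the 50% majority-rule consensus of the
#' per-replicate best trees, attaches bipartition frequencies (0-100) as
#' node labels, and roots the consensus on the outgroup.
#'
#' @param x A [GroupedAlignment-class].
#' @param partition Optional `c(start, end)` column interval.
#' @param n_reps Number of bootstrap replicates (default 1000).
#' @param seed Optional integer seed.
#' @param outgroup Haplotype id used to root the consensus.
#' @param n_starts Random-addition starts per replicate (default 1).
#' @param taxa Optional subset of haplotype ids.
#' @return A rooted [ape::phylo] with integer support values in
#'   `node.label`.
#' @export
bootstrapConsensus <- function(x, partition = NULL, n_reps = 1000,
                               seed = NULL, outgroup, n_starts = 1,
                               taxa = NULL) {
  if (n_reps < 1L) stop("n_reps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(taxa)) taxa <- haplotypeIds(x)
  if (!outgroup %in% taxa) stop("outgroup '", outgroup, "' not among taxa")
  cols <- .partition_cols(x, partition)
  m <- .chm(x, match(taxa, haplotypeIds(x)))[, cols, drop = FALSE]
  rownames(m) <- taxa
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    bs <- m[, sample.int(ncol(m), replace = TRUE), drop = FALSE]
    reps[[r]] <- .mp_search_mat(bs, n_starts, collect_ties = FALSE)$trees[[1]]
  }
  class(reps) <- "multiPhylo"
  cons <- ape::consensus(reps, p = 0.5)
  cons <- ape::root(cons, outgroup = outgroup, resolve.root = TRUE)
  counts <- ape::prop.clades(cons, reps, rooted = FALSE)
  cons$node.label <- ifelse(is.na(counts), NA_integer_,
                            as.integer(round(100 * counts / n_reps)))
  cons
}

## mean topological (nodal) distance from one tip to a set of tips
.mean_nodal <- function(dn, tree, tip, def) {
  ti <- match(tip, tree$tip.label)
  di <- match(def, tree$tip.label)
  mean(dn[ti, di])
}

#' Partition incongruence report
#'
#' Compares the placement of focal (putatively chimeric) tips between two
#' trees estimated from different gene partitions. Each focal tip is
#' assigned, per tree, to the defined clade (a or b) whose members it is
#' topologically closest to (mean nodal distance); the Robinson-Foulds
#' distance between the two trees is also reported.
#'
#' @param tree_a,tree_b Two [ape::phylo] trees over the same tip set.
#' @param focal_tips Character vector of focal tip ids (may be empty).
#' @param clade_a_def,clade_b_def Character vectors of tips defining the two
#'   reference clades (must be present in both trees and disjoint from the
#'   focal tips).
#' @return List with `rf` (Robinson-Foulds distance) and `assignments`
#'   (`data.frame`: `tip`, `tree_a`, `tree_b` with values `"clade_a"` /
#'   `"clade_b"` / `"tie"`).
#' @export
partitionIncongruence <- function(tree_a, tree_b, focal_tips = character(0),
                                  clade_a_def, clade_b_def) {
  if (!setequal(tree_a$tip.label, tree_b$tip.label))
    stop("trees must share the same tip set")
  missing <- setdiff(c(clade_a_def, clade_b_def), tree_a$tip.label)
  if (length(missing))
    stop("clade definition tips missing from trees: ",
         paste(missing, collapse = ", "))
  rf <- phangorn::RF.dist(ape::unroot(tree_a), ape::unroot(tree_b))
  assign_one <- function(tree, tip) {
    tr <- tree
    tr$edge.length <- rep(1, nrow(tr$edge))
    dn <- ape::dist.nodes(tr)
    da <- .mean_nodal(dn, tr, tip, clade_a_def)
    db <- .mean_nodal(dn, tr, tip, clade_b_def)
    if (da < db) "clade_a" else if (db < da) "clade_b" else "tie"
  }
  assignments <- data.frame(
    tip = focal_tips,
    tree_a = vapply(focal_tips, assign_one, character(1), tree = tree_a),
    tree_b = vapply(focal_tips, assign_one, character(1), tree = tree_b),
    row.names = NULL)
  list(rf = rf, assignments = assignments)
}
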