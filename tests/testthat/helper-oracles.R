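# Independent brute-force implementations used as oracles. These are written
# directly from the definitions (double loops, exhaustive enumeration) and
# share no code with the package internals they check.

BASES <- c("A", "C", "G", "T")

oracle_pi <- function(mat) {
  n <- nrow(mat)
  vals <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    comp <- mat[i, ] %in% BASES & mat[j, ] %in% BASES
    if (sum(comp) > 0)
      vals <- c(vals, sum(mat[i, comp] != mat[j, comp]) / sum(comp))
  }
  mean(vals)
}

oracle_S <- function(mat) {
  s <- 0L
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    if (any(col == "-")) next
    if (length(unique(col[col %in% BASES])) >= 2) s <- s + 1L
  }
  s
}

oracle_mean_k <- function(mat) {
  n <- nrow(mat)
  keep <- apply(mat, 2, function(col) all(col != "-"))
  ks <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    comp <- keep & mat[i, ] %in% BASES & mat[j, ] %in% BASES
    ks <- c(ks, sum(mat[i, comp] != mat[j, comp]))
  }
  mean(ks)
}

oracle_dxy <- function(mat_a, mat_b, start, end) {
  vals <- c()
  for (i in seq_len(nrow(mat_a))) for (j in seq_len(nrow(mat_b))) {
    a <- mat_a[i, start:end]; b <- mat_b[j, start:end]
    comp <- a %in% BASES & b %in% BASES
    if (sum(comp) > 0) vals <- c(vals, sum(a[comp] != b[comp]) / sum(comp))
  }
  if (!length(vals)) NA_real_ else mean(vals)
}

oracle_tajima <- function(n, S, k) {
  a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n * n + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (k - S / a1) / sqrt((c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1))
}

# Nei-Gojobori counts from first principles (codon-by-codon enumeration)
oracle_ng <- function(seq_a, seq_b) {
  gc <- Biostrings::GENETIC_CODE
  split_codons <- function(s)
    substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  site_count <- function(codon) {
    if (gc[[codon]] == "*") return(NULL)
    syn <- 0
    for (pos in 1:3) for (b in BASES) {
      if (b == substr(codon, pos, pos)) next
      mut <- codon; substr(mut, pos, pos) <- b
      if (gc[[mut]] == gc[[codon]]) syn <- syn + 1 / 3
    }
    c(syn, 3 - syn)
  }
  perms_of <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms_of(v[-i])) out <- c(out, list(c(v[i], rest)))
    out
  }
  path_diffs <- function(ca, cb) {
    pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
    if (!length(pos)) return(c(0, 0))
    all_paths <- list(); stopfree <- list()
    for (ord in perms_of(pos)) {
      cur <- ca; sd <- 0; nd <- 0; stopped <- FALSE
      for (k in seq_along(ord)) {
        nxt <- cur; substr(nxt, ord[k], ord[k]) <- substr(cb, ord[k], ord[k])
        if (gc[[nxt]] == "*" && k < length(ord)) stopped <- TRUE
        if (gc[[cur]] == gc[[nxt]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      all_paths <- c(all_paths, list(c(sd, nd)))
      if (!stopped) stopfree <- c(stopfree, list(c(sd, nd)))
    }
    use <- if (length(stopfree)) stopfree else all_paths
    Reduce(`+`, use) / length(use)
  }
  ca <- split_codons(seq_a); cb <- split_codons(seq_b)
  S <- N <- Sd <- Nd <- 0
  for (k in seq_along(ca)) {
    if (grepl("[^ACGT]", ca[k]) || grepl("[^ACGT]", cb[k])) next
    sa <- site_count(ca[k]); sb <- site_count(cb[k])
    if (is.null(sa) || is.null(sb)) next
    S <- S + (sa[1] + sb[1]) / 2
    N <- N + (sa[2] + sb[2]) / 2
    d <- path_diffs(ca[k], cb[k])
    Sd <- Sd + d[1]; Nd <- Nd + d[2]
  }
  list(S = S, N = N, Sd = Sd, Nd = Nd)
}

# exhaustive Fitch: minimize over all labelings of internal nodes (and of
# missing-data tips) the number of state-changing edges, per column
oracle_fitch <- function(tree, mat) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  total <- 0
  for (col in seq_len(ncol(mat))) {
    obs <- mat[tree$tip.label, col]
    known <- obs %in% BASES
    free <- c(which(!known), ntip + seq_len(nnode))
    best <- Inf
    grid <- rep(list(BASES), length(free))
    combos <- expand.grid(grid, stringsAsFactors = FALSE)
    for (r in seq_len(nrow(combos))) {
      lab <- character(ntip + nnode)
      lab[which(known)] <- obs[known]
      lab[free] <- unlist(combos[r, ])
      cost <- sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]])
      if (cost < best) best <- cost
    }
    total <- total + best
  }
  total
}

# all unrooted topologies over a taxon set (15 trees for 5 taxa)
oracle_all_topologies <- function(taxa) {
  stopifnot(length(taxa) >= 3, length(taxa) <= 6)
  tip1 <- function(label) {
    structure(list(edge = matrix(c(2L, 1L), 1, 2), tip.label = label,
                   edge.length = 1, Nnode = 1L), class = "phylo")
  }
  trees <- list(ape::read.tree(text = sprintf("(%s,%s,%s);",
                                              taxa[1], taxa[2], taxa[3])))
  trees[[1]]$edge.length <- rep(1, nrow(trees[[1]]$edge))
  for (t in taxa[-(1:3)]) {
    nxt <- list()
    for (tr in trees) for (e in seq_len(nrow(tr$edge))) {
      cand <- ape::bind.tree(tr, tip1(t), where = tr$edge[e, 2],
                             position = 0.5)
      cand$edge.length <- rep(1, nrow(cand$edge))
      nxt <- c(nxt, list(cand))
    }
    trees <- nxt
  }
  trees
}

# exact permutation distribution of the max matching-run score, enumerating
# all column orders of a small projection
oracle_exact_perm_p <- function(states, pairs, obs_score) {
  ncols <- ncol(states)
  perms_of <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms_of(v[-i])) out <- c(out, list(c(v[i], rest)))
    out
  }
  maxrun <- function(ord) {
    best <- 0
    for (q in seq_len(nrow(pairs))) {
      a <- states[pairs[q, 1], ord]; b <- states[pairs[q, 2], ord]
      run <- 0
      for (c in seq_along(a)) {
        if (a[c] > 0 && a[c] == b[c]) { run <- run + 1; best <- max(best, run) }
        else run <- 0
      }
    }
    best
  }
  maxima <- vapply(perms_of(seq_len(ncols)), maxrun, numeric(1))
  mean(maxima >= obs_score)
}
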