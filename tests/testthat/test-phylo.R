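test_that("Fitch score matches hand-worked four-taxon cases", {
  ga <- mk_aln(c(t1 = "AAAAA", t2 = "AAAAA", t3 = "TTTTT", t4 = "TTTTT"))
  good <- ape::read.tree(text = "((t1,t2),(t3,t4));")
  bad <- ape::read.tree(text = "((t1,t3),(t2,t4));")
  expect_equal(fitchScore(good, ga), 5L)   # one step per column
  expect_equal(fitchScore(bad, ga), 10L)   # two steps per column
  ## a column pattern requiring 2 steps on the wrong tree: t1=t2=A, t3=t4=T
  ## with two characters, second grouping t1=t3
  ga2 <- mk_aln(c(t1 = "AA", t2 = "AT", t3 = "TA", t4 = "TT"))
  expect_equal(fitchScore(good, ga2), 3L)  # col1: 1, col2: 2
  expect_equal(fitchScore(bad, ga2), 3L)
  ## monomorphic partition scores zero on any tree
  ga3 <- mk_aln(c(t1 = "CCCC", t2 = "CCCC", t3 = "CCCC", t4 = "CCCC"))
  expect_equal(fitchScore(good, ga3), 0L)
  expect_error(fitchScore(ape::read.tree(text = "((t1,t9),(t3,t4));"), ga),
               "t9")
})

test_that("Fitch score equals exhaustive ancestral-labelling minimum and
           phangorn on random small alignments", {
  set.seed(55)
  for (rep in 1:6) {
    n <- sample(4:6, 1)
    ga <- random_aln(n, 12)
    ids <- haplotypeIds(ga)
    tree <- ape::rtree(n, tip.label = sample(ids), rooted = FALSE)
    m <- seqMatrix(ga)
    expect_equal(fitchScore(tree, ga), oracle_fitch(tree, m))
    ## independent cross-check against phangorn's sankoff/fitch
    pd <- phangorn::phyDat(m, type = "DNA")
    expect_equal(fitchScore(tree, ga),
                 as.integer(phangorn::parsimony(tree, pd, method = "fitch")))
  }
  ## gaps score as missing data: never add steps
  ga_gap <- mk_aln(c(t1 = "A-", t2 = "AA", t3 = "TA", t4 = "T-"))
  tree <- ape::read.tree(text = "((t1,t2),(t3,t4));")
  expect_equal(fitchScore(tree, ga_gap), oracle_fitch(tree, seqMatrix(ga_gap)))
})

test_that("parsimony search finds the optimum verified by exhaustive
           topology enumeration, including ties", {
  set.seed(66)
  ## 5 taxa with a perfectly compatible planted signal
  seqs <- c(a = "AAAAAAAAAACCCCC", b = "AAAAAAAAAACCCCC",
            c = "TTTTTAAAAACCCCC", d = "TTTTTTTTTTCCCCC",
            e = "TTTTTTTTTTTTTTT")
  ga <- mk_aln(seqs)
  mp <- searchMP(ga, n_starts = 10, seed = 8)
  topos <- oracle_all_topologies(names(seqs))
  scores <- vapply(topos, fitchScore, numeric(1), x = ga)
  expect_equal(mp$score, min(scores))
  ## the true ladder is among (and resolved by) the best trees
  best_oracle <- topos[scores == min(scores)]
  expect_equal(length(mp$trees), length(best_oracle))
  for (tr in mp$trees)
    expect_true(any(vapply(best_oracle, function(b)
      phangorn::RF.dist(ape::unroot(b), ape::unroot(tr)) == 0, logical(1))))
  ## two planted equally parsimonious resolutions are both returned
  seqs2 <- c(a = "AAAAACCCCC", b = "AAAAAGGGGG", c = "TTTTTCCCCC",
             d = "TTTTTGGGGG", e = "AATTAACGCG")
  ga2 <- mk_aln(seqs2)
  mp2 <- searchMP(ga2, n_starts = 20, seed = 9)
  topos2 <- oracle_all_topologies(names(seqs2))
  scores2 <- vapply(topos2, fitchScore, numeric(1), x = ga2)
  expect_equal(mp2$score, min(scores2))
  expect_equal(length(mp2$trees), sum(scores2 == min(scores2)))
  ## more starts can only improve (or match) the best score
  mp_one <- searchMP(ga2, n_starts = 1, seed = 10)
  expect_lte(mp2$score, mp_one$score)
})

test_that("bootstrap consensus recovers clean clades with high support and
           rooting preserves unrooted bipartitions", {
  ## zero-homoplasy ladder with 12 supporting columns per internal edge
  blocks <- function(pattern) strrep(pattern, 12)
  seqs <- c(o = paste0(blocks("A"), blocks("A"), blocks("A")),
            a = paste0(blocks("T"), blocks("A"), blocks("A")),
            b = paste0(blocks("T"), blocks("C"), blocks("A")),
            c = paste0(blocks("T"), blocks("C"), blocks("G")),
            d = paste0(blocks("T"), blocks("C"), blocks("G")))
  ga <- mk_aln(seqs)
  bc <- bootstrapConsensus(ga, n_reps = 100, seed = 12, outgroup = "o")
  expect_true(all(bc$node.label[!is.na(bc$node.label)] >= 95))
  expect_true("o" %in% bc$tip.label)
  ## every reported bipartition has majority frequency
  expect_true(all(bc$node.label[!is.na(bc$node.label)] > 50))
  expect_error(bootstrapConsensus(ga, n_reps = 0, outgroup = "o"), "n_reps")
  expect_error(bootstrapConsensus(ga, n_reps = 10, outgroup = "zz"),
               "outgroup")
  ## rooting on the outgroup does not change unrooted bipartitions
  mp <- searchMP(ga, n_starts = 3, seed = 3)
  tr <- mp$trees[[1]]
  rooted <- ape::root(tr, outgroup = "o", resolve.root = TRUE)
  expect_equal(phangorn::RF.dist(ape::unroot(rooted), ape::unroot(tr)), 0)
})

test_that("partition incongruence reports chimera reattachment and RF
           distance", {
  t1 <- ape::read.tree(text = "((a1,(a2,x)),(b1,b2));")
  t2 <- ape::read.tree(text = "((a1,a2),((b1,x),b2));")
  inc <- partitionIncongruence(t1, t2, focal_tips = "x",
                               clade_a_def = c("a1", "a2"),
                               clade_b_def = c("b1", "b2"))
  expect_equal(inc$assignments$tree_a, "clade_a")
  expect_equal(inc$assignments$tree_b, "clade_b")
  expect_gt(inc$rf, 0)
  ## identical trees: RF 0 and same assignment
  inc0 <- partitionIncongruence(t1, t1, "x", c("a1", "a2"), c("b1", "b2"))
  expect_equal(inc0$rf, 0)
  expect_equal(inc0$assignments$tree_a, inc0$assignments$tree_b)
  ## empty focal set: RF only
  incE <- partitionIncongruence(t1, t2, character(0),
                                c("a1", "a2"), c("b1", "b2"))
  expect_equal(nrow(incE$assignments), 0L)
  expect_error(partitionIncongruence(t1, t2, "x", c("a1", "zz"),
                                     c("b1", "b2")), "missing")
  t3 <- ape::read.tree(text = "((a1,a2),(b1,b2));")
  expect_error(partitionIncongruence(t1, t3, "x", c("a1", "a2"),
                                     c("b1", "b2")), "tip set")
})
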