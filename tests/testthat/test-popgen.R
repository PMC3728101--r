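test_that("Nei-Gojobori counts match hand-derived examples", {
  d0 <- neiGojoboriPair("ATGGCT", "ATGGCT")
  expect_equal(d0$Sd, 0); expect_equal(d0$Nd, 0)
  expect_equal(d0$ks, 0); expect_equal(d0$ka, 0)

  ## TTT -> TTA is Phe -> Leu: nonsynonymous; TTT has 1/3 synonymous site
  ## at position 3, TTA (Leu) has 2/3, so averaged S = 0.5
  d <- neiGojoboriPair("TTT", "TTA")
  expect_equal(d$Sd, 0); expect_equal(d$Nd, 1)
  expect_equal(d$S, 0.5)
  expect_equal(d$S + d$N, 3)

  ## closed-form JC at ps = 0.3
  expect_equal(jukesCantor(0.3), -0.75 * log(0.6), tolerance = 1e-12)
  expect_error(jukesCantor(0.8), "saturation")
})

test_that("Nei-Gojobori is symmetric, sites sum to 3 per codon, and matches
           the enumeration oracle on random codon pairs", {
  set.seed(31)
  for (rep in 1:15) {
    a <- paste(sample(c("A", "C", "G", "T"), 9, replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 9, replace = TRUE), collapse = "")
    dab <- tryCatch(neiGojoboriPair(a, b), error = function(e) NULL)
    if (is.null(dab)) next                     # all-stop or saturated draw
    dba <- neiGojoboriPair(b, a)
    expect_equal(dab$Sd, dba$Sd); expect_equal(dab$S, dba$S)
    expect_equal(dab$S + dab$N, 3 * dab$n_codons)
    o <- oracle_ng(a, b)
    expect_equal(dab$S, o$S); expect_equal(dab$N, o$N)
    expect_equal(dab$Sd, o$Sd); expect_equal(dab$Nd, o$Nd)
  }
  ## JC correction dominates p and converges to p at small p
  p <- seq(0.01, 0.7, by = 0.05)
  expect_true(all(jukesCantor(p) >= p))
  expect_equal(jukesCantor(1e-6), 1e-6, tolerance = 1e-4)
})

test_that("fixed-only divergence uses only sites fixed within groups", {
  cm <- codingMap(1, 90)
  base <- paste(rep("ATG", 30), collapse = "")
  ## three planted fixed synonymous differences (3rd codon positions,
  ## ATG->ATA is Met->Ile: nonsynonymous, so use codons with 4-fold sites)
  a <- paste(rep("CTA", 30), collapse = "")
  bvec <- strsplit(a, "")[[1]]
  bvec[c(3, 33, 63)] <- "G"                # CTA->CTG: Leu->Leu, synonymous
  b <- paste(bvec, collapse = "")
  ga <- mk_aln(c(a1 = a, a2 = a, b1 = b, b2 = b),
               paralog = c("p1", "p1", "p2", "p2"))
  d <- divergenceBetweenGroups(ga, cm, 1:2, 3:4, mode = "fixed_only")
  expect_equal(d$Sd, 3); expect_equal(d$Nd, 0)
  ## a site polymorphic inside group_a contributes nothing in fixed_only
  avec2 <- strsplit(a, "")[[1]]; avec2[6] <- "G"
  ga2 <- mk_aln(c(a1 = a, a2 = paste(avec2, collapse = ""), b1 = b, b2 = b),
                paralog = c("p1", "p1", "p2", "p2"))
  d2 <- divergenceBetweenGroups(ga2, cm, 1:2, 3:4, mode = "fixed_only")
  expect_equal(d2$Sd, 3)
  ## identical groups in both modes
  gaid <- mk_aln(c(a1 = a, a2 = a, b1 = a, b2 = a),
                 paralog = c("p1", "p1", "p2", "p2"))
  for (mode in c("fixed_only", "mean_pairwise")) {
    dd <- divergenceBetweenGroups(gaid, cm, 1:2, 3:4, mode = mode)
    expect_equal(dd$ks, 0); expect_equal(dd$ka, 0)
  }
})

test_that("pi by class matches the hand-enumerated noncoding example", {
  ga <- mk_aln(c(a = "AAAA", b = "AAAT", c = "AATT", d = "ATTT"))
  ps <- piByClass(ga, NULL, 1:4)
  ## all 6 pairs: 1+2+3+1+2+1 = 10 diffs, /6 pairs /4 sites
  expect_equal(ps$pi_total, (10 / 6) / 4, tolerance = 1e-12)
  expect_equal(ps$s_total, 3L)
  expect_equal(ps$pi_silent, ps$pi_total)
  ## identical haplotypes: everything zero
  ga0 <- mk_aln(c(a = "ACGT", b = "ACGT", c = "ACGT"))
  ps0 <- piByClass(ga0, NULL, 1:3)
  expect_equal(ps0$pi_total, 0); expect_equal(ps0$s_total, 0L)
  expect_true(is.na(ps0$tajima_d))
  expect_error(piByClass(ga, NULL, 1L), "at least 2")
})

test_that("pi, S and mean k match the brute-force oracle on random
           alignments and are stable under haplotype duplication", {
  set.seed(77)
  for (rep in 1:8) {
    ga <- random_aln(sample(4:8, 1), 60)
    idx <- seq_len(nHap(ga))
    ps <- piByClass(ga, NULL, idx)
    m <- seqMatrix(ga)
    expect_equal(ps$pi_total, oracle_pi(m), tolerance = 1e-12)
    expect_equal(ps$s_total, oracle_S(m))
    expect_equal(ps$mean_k, oracle_mean_k(m), tolerance = 1e-12)
  }
  ## doubling every haplotype leaves pi unchanged (Nei's estimator)
  ga <- random_aln(5, 40)
  m <- seqMatrix(ga)
  dup <- mk_aln(stats::setNames(rep(apply(m, 1, paste, collapse = ""), 2),
                                sprintf("s%d", 1:10)))
  pi_dup <- piByClass(dup, NULL, 1:10)$pi_total
  expect_equal(pi_dup, oracle_pi(seqMatrix(dup)), tolerance = 1e-12)
  ## identical copies add zero-distance pairs: change is O(1/n)
  expect_equal(pi_dup, piByClass(ga, NULL, 1:5)$pi_total, tolerance = 0.15)
})

test_that("segregating coding sites are partitioned by amino-acid effect", {
  cm <- codingMap(1, 6)
  ## site 3: CTA/CTG Leu/Leu synonymous; site 4: GCT/TCT Ala/Ser nonsyn
  ga <- mk_aln(c(a = "CTAGCT", b = "CTGGCT", c = "CTATCT", d = "CTGTCT"))
  ps <- piByClass(ga, cm, 1:4)
  expect_equal(ps$s_syn, 1L)
  expect_equal(ps$s_nonsyn, 1L)
})

test_that("Tajima's D matches the published-constants oracle and flags
           undefined cases", {
  expect_equal(tajimaD(4, 3, 10 / 6), oracle_tajima(4, 3, 10 / 6),
               tolerance = 1e-12)
  expect_equal(round(tajimaD(4, 3, 10 / 6), 2), 0.17)
  ## numerator zero exactly when k equals S/a1
  a1 <- sum(1 / (1:9))
  expect_equal(tajimaD(10, 5, 5 / a1), 0)
  expect_true(is.na(tajimaD(3, 5, 1)))
  expect_true(is.na(tajimaD(10, 0, 0)))
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(4:20, 1); S <- sample(1:40, 1); k <- runif(1, 0, S)
    expect_equal(tajimaD(n, S, k), oracle_tajima(n, S, k), tolerance = 1e-12)
  }
})

test_that("sliding Dxy matches the per-window oracle and saturates correctly", {
  ## identical groups: all zero
  ga <- mk_aln(c(a = strrep("ACGT", 30), b = strrep("ACGT", 30),
                 c = strrep("ACGT", 30), d = strrep("ACGT", 30)),
               paralog = c("p1", "p1", "p2", "p2"))
  wp <- slidingDxy(ga, 1:2, 3:4, 60, 12)
  expect_true(all(wp$dxy == 0))
  ## fully divergent 60 bp: Dxy = 1
  ga1 <- mk_aln(c(a = strrep("A", 60), b = strrep("A", 60),
                  c = strrep("T", 60), d = strrep("T", 60)),
                paralog = c("p1", "p1", "p2", "p2"))
  expect_equal(slidingDxy(ga1, 1:2, 3:4, 60, 12)$dxy, 1)
  ## planted divergent block peaks over the block and is 0 elsewhere
  left <- strrep("G", 130); block <- strrep("C", 30); right <- strrep("G", 140)
  ga2 <- mk_aln(c(a = paste0(left, block, right),
                  b = paste0(left, strrep("A", 30), right)),
                paralog = c("p1", "p2"))
  wp2 <- slidingDxy(ga2, 1, 2, 30, 10)
  expect_true(all(wp2$dxy[wp2$end < 131 | wp2$start > 160] == 0))
  expect_equal(max(wp2$dxy), 1)   # the window aligned with the block
  ## brute-force oracle on random data, plus whole-sequence consistency
  set.seed(13)
  ga3 <- random_aln(6, 60, n_par = 2)
  ia <- selectGroup(ga3, paralog = "p1"); ib <- selectGroup(ga3, paralog = "p2")
  wp3 <- slidingDxy(ga3, ia, ib, 20, 7)
  m <- seqMatrix(ga3)
  for (r in seq_len(nrow(wp3)))
    expect_equal(wp3$dxy[r],
                 oracle_dxy(m[ia, , drop = FALSE], m[ib, , drop = FALSE],
                            wp3$start[r], wp3$end[r]), tolerance = 1e-12)
  whole <- slidingDxy(ga3, ia, ib, 60, 60)
  expect_equal(whole$dxy,
               oracle_dxy(m[ia, , drop = FALSE], m[ib, , drop = FALSE], 1, 60),
               tolerance = 1e-12)
  expect_error(slidingDxy(ga3, ia, ib, 100, 10), "window")
})

test_that("column entropy follows the Shannon definition", {
  prot <- c("MKA-", "MRA-", "MKC-", "MRW-")
  H <- columnEntropy(prot)
  expect_equal(H[1], 0)                  # monomorphic
  expect_equal(H[2], 1)                  # 50/50 two residues
  expect_true(is.na(H[4]))               # all-gap
  expect_equal(columnEntropy(c("A", "C", "D", "E"))[1], 2)  # 4 equal residues
})
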