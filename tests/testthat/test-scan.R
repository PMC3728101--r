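test_that("polymorphic-site projection keeps coordinates and drops gaps", {
  ## monomorphic alignment: empty projection
  ga0 <- mk_aln(c(a = "ACGT", b = "ACGT", c = "ACGT", d = "ACGT"))
  expect_warning(pr0 <- projectPolymorphic(ga0, "pop1"), "skipped")
  expect_length(pr0$columns, 0)
  ## one variable column: length-1 projection, scan skipped downstream
  ga1 <- mk_aln(c(a = "ACGT", b = "ACGT", c = "ACGT", d = "TCGT"))
  expect_warning(pr1 <- projectPolymorphic(ga1, "pop1"), "skipped")
  expect_equal(pr1$columns, 1L)
  ## planted variable columns keep original coordinates; gap columns drop
  set.seed(4)
  base <- strrep("A", 300)
  vary <- sort(sample(300, 10))
  seqs <- vapply(1:4, function(i) {
    v <- strsplit(base, "")[[1]]
    v[vary] <- sample(c("C", "T"), 10, replace = TRUE)
    paste(v, collapse = "")
  }, character(1))
  ## force every vary column to actually vary
  m <- do.call(rbind, strsplit(seqs, ""))
  m[1, vary] <- "C"; m[2, vary] <- "T"
  ga2 <- mk_aln(apply(m, 1, paste, collapse = ""))
  pr2 <- projectPolymorphic(ga2, "pop1")
  expect_equal(pr2$columns, vary)
  expect_error(projectPolymorphic(mk_aln(c(a = "AC", b = "AC")), "pop1"),
               "at least 4")
})

test_that("pair fragments are maximal runs terminated by mismatches", {
  states <- rbind(c(1L, 2L, 3L, 1L, 1L, 2L, 4L),
                  c(1L, 2L, 1L, 1L, 1L, 2L, 3L),
                  c(4L, 4L, 4L, 4L, 4L, 4L, 4L),
                  c(3L, 3L, 3L, 3L, 3L, 3L, 3L))
  proj <- structure(list(columns = c(5L, 10L, 20L, 30L, 40L, 50L, 60L),
                         states = states, ids = c("a", "b", "c", "d"),
                         paralog = rep("p1", 4), population = "pop1"),
                    class = "PolymorphicProjection")
  ## pattern M M X M M M X -> fragments of score 2 and 3
  fr <- pairFragments(proj, "a", "b", g = 0)
  expect_equal(fr$score, c(2, 3))
  expect_equal(fr$start, c(5L, 30L))
  expect_equal(fr$end, c(10L, 50L))
  ## a large penalty cannot join runs: identical to g = 0
  fr_big <- pairFragments(proj, "a", "b", g = 100)
  expect_equal(fr_big[, c("start", "end", "n_poly_sites")],
               fr[, c("start", "end", "n_poly_sites")])
  ## identical at all sites: one fragment spanning first to last column
  fr_id <- pairFragments(proj, "c", "c", g = 0)
  expect_equal(nrow(fr_id), 1L)
  expect_equal(c(fr_id$start, fr_id$end), c(5L, 60L))
})

test_that("sim_p follows the (1+x)/(1+N) rule and matches exhaustive
           enumeration on a toy projection", {
  set.seed(21)
  states <- rbind(c(1L, 1L, 1L, 1L, 1L, 1L),
                  c(1L, 1L, 1L, 1L, 1L, 1L),
                  c(2L, 2L, 2L, 1L, 2L, 2L),
                  c(3L, 2L, 2L, 2L, 4L, 2L))
  proj <- structure(list(columns = 1:6, states = states,
                         ids = c("a", "b", "c", "d"),
                         paralog = c("p1", "p1", "p2", "p2"),
                         population = "pop1"),
                    class = "PolymorphicProjection")
  pairs <- t(utils::combn(4, 2))
  fr <- permutationPvalues(proj, pairs, n_perm = 999, seed = 99)
  nm <- attr(fr, "null_max")
  expect_length(nm, 999)
  ## the reported p obeys the conservative (1+x)/(1+N) estimator exactly
  for (r in seq_len(nrow(fr)))
    expect_equal(fr$sim_p[r], (1 + sum(nm >= fr$score[r])) / 1000)
  ## a pair identical at every site ties every permutation: sim_p = 1
  top <- fr[fr$score == 6, ]
  expect_equal(unique(top$sim_p), 1)
  ## exhaustive enumeration equals the independent oracle
  fx <- permutationPvalues(proj, pairs, exhaustive = TRUE)
  for (r in seq_len(nrow(fx))) {
    expect_equal(fx$sim_p[r],
                 oracle_exact_perm_p(states, pairs, fx$score[r]),
                 tolerance = 1e-12)
  }
  expect_error(permutationPvalues(proj, pairs[0, , drop = FALSE]),
               "non-empty")
})

test_that("scan output is invariant to record order and reproducible", {
  fx <- get_fixtures()
  aln <- fx$planted$aln
  sc1 <- scanConversion(aln, n_perm = 99, seed = 7, populations = "pop1")
  sc2 <- scanConversion(aln, n_perm = 99, seed = 7, populations = "pop1")
  expect_identical(sc1$fragments, sc2$fragments)
  ## permute records: same fragment set, same p-values
  perm <- sample(seq_len(nHap(aln)))
  sc3 <- scanConversion(aln[perm], n_perm = 99, seed = 7,
                        populations = "pop1")
  key <- function(f) {
    sig <- f$fragments[f$fragments$significant, ]
    sig$pair <- paste(pmin(sig$seq_i, sig$seq_j), pmax(sig$seq_i, sig$seq_j))
    sig <- sig[order(sig$pair, sig$start), c("pair", "start", "end", "score")]
    rownames(sig) <- NULL
    sig
  }
  expect_equal(key(sc3), key(sc1))
})

test_that("fragment clustering counts minimum non-overlapping events", {
  fr <- data.frame(
    population = "sd", category = "inter_paralog",
    seq_i = "x", seq_j = "y",
    start = c(10, 40, 100), end = c(50, 80, 120),
    n_poly_sites = 5, score = 5, sim_p = 0.01)
  cl <- classifyAndCluster(fr, alpha = 0.05)
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$merged_start, c(10, 100))
  expect_equal(cl$merged_end, c(80, 120))
  ## disjoint fragments stay separate
  fr2 <- transform(fr, start = c(1, 20, 40), end = c(10, 30, 50))
  expect_equal(nrow(classifyAndCluster(fr2)), 3L)
  ## same coordinates, different category: counted per category
  fr3 <- rbind(fr, transform(fr, category = "intra_paralog"))
  cl3 <- classifyAndCluster(fr3)
  expect_equal(as.vector(table(cl3$category)), c(2L, 2L))
  ## non-significant fragments never cluster
  fr4 <- transform(fr, sim_p = 0.5)
  expect_equal(nrow(classifyAndCluster(fr4)), 0L)
})

test_that("the planted inter-paralog tract is recovered as a significant
           overlapping cluster", {
  fx <- get_fixtures()
  pl <- fx$planted
  sc <- scanConversion(pl$aln, n_perm = 499, seed = 42,
                       populations = "pop1")
  cl <- classifyAndCluster(sc)
  inter <- cl[cl$category == "inter_paralog", ]
  expect_gte(nrow(inter), 1L)
  tr <- pl$truth
  expect_true(any(inter$merged_start <= tr$end[1] &
                  inter$merged_end >= tr$start[1]))
})
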