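# Small builders shared across test files; the seed-pinned worked fixtures
# are generated once per test run and memoised.

mk_aln <- function(seqs, population = NULL, paralog = NULL) {
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("s%d", seq_along(seqs))
  if (is.null(population)) population <- rep("pop1", length(seqs))
  if (is.null(paralog)) paralog <- rep("p1", length(seqs))
  groupedAlignment(stats::setNames(seqs, ids),
                   data.frame(haplotype_id = ids, population = population,
                              paralog = paralog))
}

random_aln <- function(n_seq, len, n_pop = 1, n_par = 1) {
  seqs <- vapply(seq_len(n_seq), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
  mk_aln(stats::setNames(seqs, sprintf("s%d", seq_len(n_seq))),
         population = rep_len(paste0("pop", seq_len(n_pop)), n_seq),
         paralog = rep_len(paste0("p", seq_len(n_par)), n_seq))
}

.fixture_env <- new.env()
get_fixtures <- function() {
  if (is.null(.fixture_env$fx)) .fixture_env$fx <- makeWorkedFixtures()
  .fixture_env$fx
}
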