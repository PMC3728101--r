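#' Simulation configuration for duplicate-gene evolution
#'
#' Validated parameter set for [simulateDataset()]. Defaults emulate a pair
#' of intronless paralogs sampled in four diverged populations: paralog
#' synonymous divergence around 0.25 substitutions/site, population splits
#' an order of magnitude shallower, and within-population diversity at the
#' level observed for conversion-affected paralogs.
#'
#' @param n_populations Number of tip populations (1-4; default 4).
#' @param haplotypes_per_group Haplotypes sampled per (population, paralog)
#'   group (default 6).
#' @param seq_length Gene length in bp, divisible by 3 (default 1224).
#' @param duplication_height Age of the duplication in expected
#'   substitutions/site (default 0.125, i.e. ~0.25 between paralogs).
#' @param split_heights Heights of the population splits, descending
#'   (default `c(0.03, 0.015)`).
#' @param theta_within Expected pairwise diversity per site within a tip
#'   population (default 0.04).
#' @param conv_rate Expected number of conversion events per branch
#'   (default 1).
#' @param tract_mean Mean conversion tract length in bp (geometric;
#'   default 150).
#' @param donor_bias Probability that the donor of an inter-paralog event is
#'   paralog 1 (default 0.5 = undirected).
#' @param meps_divergence_cutoff Local divergence above which a proposed
#'   tract is rejected, emulating the suppression of homologous conversion
#'   between diverged sequences (default 0.25).
#' @param island_intervals List of `c(start, end)` column intervals where
#'   inter-paralog conversion is disallowed (selection-maintained divergence
#'   islands; default none).
#' @param seed Integer seed (mandatory).
#' @param forced_events List of planted events; each a list with `branch`
#'   (e.g. `"tip:pop1"`), `donor`/`recipient` (`"p1"`/`"p2"`), `start`,
#'   `end`, `scope` (`"lineage"` or `"tip_subset"`), and for tip-subset
#'   events `population`, `haplotypes` (recipient indices) and `donor_hap`.
#'   Planted events bypass island/divergence rejection.
#' @param pseudogene_groups Character vector of `"pop_paralog"` keys to
#'   carry a pseudogenization annotation flag (no effect on the alignment).
#' @return A validated `SimConfig` list.
#' @export
simConfig <- function(n_populations = 4, haplotypes_per_group = 6,
                      seq_length = 1224, duplication_height = 0.125,
                      split_heights = c(0.03, 0.015), theta_within = 0.04,
                      conv_rate = 1, tract_mean = 150, donor_bias = 0.5,
                      meps_divergence_cutoff = 0.25,
                      island_intervals = list(), seed,
                      forced_events = list(),
                      pseudogene_groups = character(0)) {
  if (missing(seed) || is.null(seed)) stop("config error: seed is mandatory")
  cfg <- list(n_populations = as.integer(n_populations),
              haplotypes_per_group = as.integer(haplotypes_per_group),
              seq_length = as.integer(seq_length),
              duplication_height = duplication_height,
              split_heights = split_heights,
              theta_within = theta_within, conv_rate = conv_rate,
              tract_mean = tract_mean, donor_bias = donor_bias,
              meps_divergence_cutoff = meps_divergence_cutoff,
              island_intervals = island_intervals,
              seed = as.integer(seed), forced_events = forced_events,
              pseudogene_groups = pseudogene_groups)
  if (cfg$n_populations < 1L || cfg$n_populations > 4L)
    stop("config error: n_populations must be 1-4")
  if (cfg$haplotypes_per_group < 1L)
    stop("config error: haplotypes_per_group must be >= 1")
  if (cfg$seq_length %% 3L != 0L)
    stop("config error: seq_length must be divisible by 3")
  if (any(c(cfg$theta_within, cfg$conv_rate, cfg$tract_mean,
            cfg$duplication_height) < 0))
    stop("config error: rates and heights must be >= 0")
  if (cfg$donor_bias < 0 || cfg$donor_bias > 1)
    stop("config error: donor_bias must be in [0, 1]")
  if (cfg$n_populations > 1L) {
    hs <- c(cfg$duplication_height, cfg$split_heights)
    if (any(diff(hs) >= 0) || any(cfg$split_heights < 0))
      stop("config error: split_heights must descend below duplication_height")
  }
  for (isl in cfg$island_intervals)
    if (isl[1] < 1 || isl[2] > cfg$seq_length || isl[1] > isl[2])
      stop("config error: island interval outside sequence")
  structure(cfg, class = "SimConfig")
}

.sim_mutate <- function(seq, expected_subs_per_site) {
  n <- stats::rpois(1, expected_subs_per_site * length(seq))
  if (n == 0L) return(seq)
  pos <- sample.int(length(seq), n, replace = TRUE)
  shift <- sample.int(3L, n, replace = TRUE)
  seq[pos] <- ((seq[pos] - 1L + shift) %% 4L) + 1L
  seq
}

.sim_tract <- function(cfg) {
  len <- if (cfg$tract_mean > 1) 1L + stats::rgeom(1, 1 / cfg$tract_mean)
         else 1L
  len <- min(len, cfg$seq_length)
  start <- sample.int(cfg$seq_length - len + 1L, 1)
  c(start, start + len - 1L)
}

.overlaps_island <- function(tract, islands) {
  for (isl in islands)
    if (tract[1] <= isl[2] && tract[2] >= isl[1]) return(TRUE)
  FALSE
}

## evolve the (p1, p2) paralog pair along one branch: substitutions on both
## copies, Poisson-many conversion attempts, plus any planted lineage events
.sim_branch <- function(state, h_top, h_bot, branch_id, cfg, truth_env) {
  forced <- Filter(function(ev)
    identical(ev$branch, branch_id) &&
      (is.null(ev$scope) || ev$scope == "lineage"),
    cfg$forced_events)
  n_ev <- if (cfg$conv_rate > 0) stats::rpois(1, cfg$conv_rate) else 0L
  ev_h <- if (n_ev > 0L) stats::runif(n_ev, h_bot, h_top) else numeric(0)
  sched <- data.frame(
    h = c(ev_h, vapply(forced, function(ev)
      if (is.null(ev$time)) h_bot else ev$time, numeric(1))),
    forced = c(rep(FALSE, n_ev), rep(TRUE, length(forced))),
    idx = c(rep(NA_integer_, n_ev), seq_along(forced)))
  sched <- sched[order(-sched$h), , drop = FALSE]
  cur_h <- h_top
  for (r in seq_len(nrow(sched))) {
    dt <- cur_h - sched$h[r]
    state$p1 <- .sim_mutate(state$p1, dt)
    state$p2 <- .sim_mutate(state$p2, dt)
    cur_h <- sched$h[r]
    if (sched$forced[r]) {
      ev <- forced[[sched$idx[r]]]
      src <- state[[ev$donor]]
      state[[ev$recipient]][ev$start:ev$end] <- src[ev$start:ev$end]
      .truth_add(truth_env, branch_id, cur_h, ev$donor, ev$recipient,
                 "lineage", ev$start, ev$end)
    } else {
      donor <- if (stats::runif(1) < cfg$donor_bias) "p1" else "p2"
      recip <- setdiff(c("p1", "p2"), donor)
      tract <- .sim_tract(cfg)
      if (.overlaps_island(tract, cfg$island_intervals)) next
      span <- tract[1]:tract[2]
      if (mean(state[[donor]][span] != state[[recip]][span]) >
          cfg$meps_divergence_cutoff) next
      state[[recip]][span] <- state[[donor]][span]
      .truth_add(truth_env, branch_id, cur_h, donor, recip, "lineage",
                 tract[1], tract[2])
    }
  }
  state$p1 <- .sim_mutate(state$p1, cur_h - h_bot)
  state$p2 <- .sim_mutate(state$p2, cur_h - h_bot)
  state
}

.truth_add <- function(env, branch, time, donor, recipient, scope,
                       start, end) {
  env$rows[[length(env$rows) + 1L]] <- data.frame(
    branch = branch, time = time, donor = donor, recipient = recipient,
    scope = scope, start = start, end = end)
}

## population-tree branch plan (id, parent node, top and bottom heights,
## populations below); shapes: 1 tip, 2 = (1,2), 3 = (1,(2,3)),
## 4 = ((1,2),(3,4))
.sim_branch_plan <- function(cfg) {
  Hd <- cfg$duplication_height
  h1 <- if (cfg$n_populations > 1L) cfg$split_heights[1] else 0
  h2 <- if (cfg$n_populations > 2L) cfg$split_heights[2] else 0
  tip <- function(p, parent, top)
    list(id = paste0("tip:", p), parent = parent, top = top, bot = 0,
         node = p)
  switch(as.character(cfg$n_populations),
    "1" = list(tip("pop1", "dup", Hd)),
    "2" = list(list(id = "stem", parent = "dup", top = Hd, bot = h1,
                    node = "A"),
               tip("pop1", "A", h1), tip("pop2", "A", h1)),
    "3" = list(list(id = "stem", parent = "dup", top = Hd, bot = h1,
                    node = "A"),
               tip("pop1", "A", h1),
               list(id = "anc23", parent = "A", top = h1, bot = h2,
                    node = "B"),
               tip("pop2", "B", h2), tip("pop3", "B", h2)),
    "4" = list(list(id = "stem", parent = "dup", top = Hd, bot = h1,
                    node = "A"),
               list(id = "anc12", parent = "A", top = h1, bot = h2,
                    node = "B"),
               list(id = "anc34", parent = "A", top = h1, bot = h2,
                    node = "C"),
               tip("pop1", "B", h2), tip("pop2", "B", h2),
               tip("pop3", "C", h2), tip("pop4", "C", h2)))
}

#' Simulate a duplicate-gene dataset with known conversion history
#'
#' Forward simulation under a Jukes-Cantor-like substitution model (uniform
#' per-site replacement to a uniformly chosen different base): an ancestral
#' gene is duplicated at `duplication_height`, the paralog pair then evolves
#' down the population tree; on each branch, conversion events copy a
#' geometric-length tract from one paralog to the other (nonreciprocal,
#' instantaneous, whole-tract), rejected when the tract overlaps a
#' configured divergence island or when local divergence exceeds the
#' minimal-efficient-processing-segment (MEPS) cutoff. Tip haplotypes are
#' drawn on a star genealogy with per-lineage mutation at `theta_within/2`.
#' Planted (`forced_events`) tracts are applied deterministically and
#' recorded alongside the accepted stochastic events.
#'
#' All randomness flows from `set.seed(cfg$seed)`; a given configuration is
#' bit-reproducible.
#'
#' @param cfg A [simConfig()] object.
#' @return List with `aln` (a [GroupedAlignment-class]), `cmap` (a
#'   single-exon [CodingMap-class]), `truth` (accepted-event `data.frame`:
#'   `branch`, `time`, `donor`, `recipient`, `scope`, `start`, `end`),
#'   `annotations`, and `config`.
#' @export
simulateDataset <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  set.seed(cfg$seed)
  L <- cfg$seq_length
  truth_env <- new.env()
  truth_env$rows <- list()
  anc <- sample.int(4L, L, replace = TRUE)
  states <- list(dup = list(p1 = anc, p2 = anc))
  plan <- .sim_branch_plan(cfg)
  for (br in plan)
    states[[br$node]] <- .sim_branch(states[[br$parent]], br$top, br$bot,
                                     br$id, cfg, truth_env)
  pops <- paste0("pop", seq_len(cfg$n_populations))
  seqs <- list(); info <- list()
  haps <- list()
  for (pop in pops) {
    tipstate <- states[[pop]]
    for (par in c("p1", "p2")) {
      for (h in seq_len(cfg$haplotypes_per_group)) {
        id <- sprintf("%s_%s_h%d", pop, par, h)
        haps[[id]] <- .sim_mutate(tipstate[[par]], cfg$theta_within / 2)
        info[[id]] <- data.frame(haplotype_id = id, population = pop,
                                 paralog = par)
      }
    }
  }
  ## planted tip-subset events: copy a tract from a contemporary donor
  ## haplotype into selected recipient haplotypes (a chimera-making event)
  for (ev in cfg$forced_events) {
    if (is.null(ev$scope) || ev$scope != "tip_subset") next
    dh <- if (is.null(ev$donor_hap)) 1L else ev$donor_hap
    donor_id <- sprintf("%s_%s_h%d", ev$population, ev$donor, dh)
    for (h in ev$haplotypes) {
      rid <- sprintf("%s_%s_h%d", ev$population, ev$recipient, h)
      haps[[rid]][ev$start:ev$end] <- haps[[donor_id]][ev$start:ev$end]
    }
    .truth_add(truth_env, paste0("tip_subset:", ev$population), 0,
               ev$donor, ev$recipient, "tip_subset", ev$start, ev$end)
  }
  chars <- vapply(haps, function(s) paste(.BASES[s], collapse = ""),
                  character(1))
  aln <- groupedAlignment(chars, do.call(rbind, info))
  truth <- if (length(truth_env$rows)) do.call(rbind, truth_env$rows) else
    data.frame(branch = character(0), time = numeric(0),
               donor = character(0), recipient = character(0),
               scope = character(0), start = integer(0), end = integer(0))
  rownames(truth) <- NULL
  annotations <- if (length(cfg$pseudogene_groups))
    data.frame(group = cfg$pseudogene_groups, flag = "pseudogenized")
  else data.frame(group = character(0), flag = character(0))
  list(aln = aln, cmap = codingMap(1L, L), truth = truth,
       annotations = annotations, config = cfg)
}

#' Neutral coalescent summary statistics
#'
#' Samples a Kingman coalescent genealogy for `n_hap` lineages and drops
#' infinite-sites mutations at rate `theta/2` per lineage, returning the
#' segregating-site count and mean pairwise difference count. Used as the
#' neutral oracle for Tajima's D and for theta-recovery checks.
#'
#' @param n_hap Number of sampled lineages.
#' @param theta Population-scaled mutation rate for the locus.
#' @return List with `n`, `S`, `k` (mean pairwise differences).
#' @export
simulateCoalescent <- function(n_hap, theta) {
  act <- lapply(seq_len(n_hap), identity)   # tip sets of active lineages
  S <- 0L
  pairsum <- 0
  k <- n_hap
  while (k > 1L) {
    t <- stats::rexp(1, k * (k - 1) / 2)
    for (ln in act) {
      m <- stats::rpois(1, theta / 2 * t)
      if (m > 0L) {
        S <- S + m
        i <- length(ln)
        pairsum <- pairsum + m * i * (n_hap - i)
      }
    }
    pick <- sample.int(k, 2)
    act[[pick[1]]] <- c(act[[pick[1]]], act[[pick[2]]])
    act[[pick[2]]] <- NULL
    k <- k - 1L
  }
  list(n = n_hap, S = S, k = pairsum / choose(n_hap, 2))
}

#' Bundled worked datasets
#'
#' Deterministic, seed-pinned toy datasets exercising every pipeline stage:
#' \describe{
#'   \item{null}{single-population, no-conversion dataset for scan
#'     calibration;}
#'   \item{planted}{default four-population conditions with one planted
#'     300 bp inter-paralog tract (donor paralog 1) carried by half the
#'     recipient haplotypes of pop1;}
#'   \item{chimera}{two populations; half of pop1's paralog-2 haplotypes
#'     carry a paralog-1-derived block over columns 924-1224, reproducing
#'     the chimeric-haplotype pattern;}
#'   \item{island}{two populations under frequent conversion everywhere
#'     except two protected divergence islands.}
#' }
#'
#' @param seed Base integer seed (default 101); sub-seeds are derived
#'   deterministically.
#' @return Named list of [simulateDataset()] results.
#' @export
makeWorkedFixtures <- function(seed = 101L) {
  null_cfg <- simConfig(n_populations = 1, conv_rate = 0, seed = seed + 1L)
  planted_cfg <- simConfig(
    conv_rate = 0, seed = seed + 2L,
    forced_events = list(list(scope = "tip_subset", population = "pop1",
                              donor = "p1", recipient = "p2",
                              haplotypes = 1:3, donor_hap = 1L,
                              start = 451L, end = 750L)))
  chimera_cfg <- simConfig(
    n_populations = 2, conv_rate = 0, seed = seed + 3L,
    forced_events = list(list(scope = "tip_subset", population = "pop1",
                              donor = "p1", recipient = "p2",
                              haplotypes = 1:3, donor_hap = 1L,
                              start = 924L, end = 1224L)))
  island_cfg <- simConfig(
    n_populations = 2, conv_rate = 6, seed = seed + 4L,
    island_intervals = list(c(181L, 360L), c(841L, 960L)))
  list(null = simulateDataset(null_cfg),
       planted = simulateDataset(planted_cfg),
       chimera = simulateDataset(chimera_cfg),
       island = simulateDataset(island_cfg))
}
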