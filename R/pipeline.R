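#' @importFrom jsonlite read_json write_json
NULL

.fmt_num <- function(x, digits) {
  ifelse(is.na(x), "NA", formatC(x, format = "f", digits = digits))
}

.stage <- function(name, expr, manifest_env) {
  manifest_env$stages[[name]] <- "RUNNING"
  res <- tryCatch(expr, error = function(e) {
    manifest_env$stages[[name]] <- "FAILED"
    .write_manifest(manifest_env)
    stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE)
  })
  manifest_env$stages[[name]] <- "OK"
  res
}

.write_manifest <- function(env) {
  man <- list(package = "paraconv",
              version = as.character(utils::packageVersion("paraconv")),
              seed = env$config$seed,
              config = env$config,
              stages = env$stages)
  jsonlite::write_json(man, file.path(env$config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
}

.default_run_config <- function(config) {
  defaults <- list(window = 60L, step = 12L,
                   scan = list(n_perm = 10000L, alpha = 0.05, g = 0),
                   phylo = list(n_starts = 3L),
                   partitions = NULL, outgroup = NULL)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  for (nm in names(defaults$scan))
    if (is.null(config$scan[[nm]])) config$scan[[nm]] <- defaults$scan[[nm]]
  if (is.null(config$phylo$n_starts)) config$phylo$n_starts <- 3L
  if (is.null(config$seed)) stop("config error: seed is mandatory")
  if (is.null(config$outdir)) stop("config error: outdir is required")
  config
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages in analysis order — load (or simulate),
#' divergence and polymorphism statistics, window profiles, the conversion
#' scan with event clustering, shared-site signatures, and partitioned
#' parsimony trees — writing TSV/Newick outputs and a JSON manifest to the
#' output directory. Any stage failure aborts with a stage-named error and
#' a `FAILED` marker in the manifest; outputs written so far are retained.
#' Two runs with identical config and seed produce byte-identical outputs.
#'
#' @param config A named list (or path to a JSON file) with entries:
#'   `input` (list with `fasta`, `metadata`, optional `coding`) or
#'   `simulate` (arguments for [simConfig()]); `window`/`step` (default
#'   60/12); `scan` (`n_perm`, `alpha`, `g`); `partitions` (optional list of
#'   `list(name, start, end)`); `outgroup` (optional haplotype id);
#'   `phylo` (`n_starts`); `seed` (mandatory); `outdir`.
#' @return Invisibly, a list with the in-memory results of every stage.
#' @export
runAll <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  config <- .default_run_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  env <- new.env()
  env$config <- config
  env$stages <- list()
  set.seed(config$seed)

  dat <- .stage("seq_model", {
    if (!is.null(config$simulate)) {
      cfg <- do.call(simConfig, c(config$simulate, list(seed = config$seed)))
      sim <- simulateDataset(cfg)
      utils::write.table(sim$truth, file.path(config$outdir, "truth.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      sim
    } else {
      inp <- config$input
      if (is.null(inp$fasta) || is.null(inp$metadata) ||
          !file.exists(inp$fasta) || !file.exists(inp$metadata))
        stop("input fasta/metadata missing")
      list(aln = readGroupedAlignment(inp$fasta, inp$metadata),
           cmap = if (!is.null(inp$coding)) readCodingMap(inp$coding)
                  else NULL,
           truth = NULL)
    }
  }, env)
  aln <- dat$aln; cmap <- dat$cmap
  info <- groupInfo(aln)
  pops <- unique(info$population)
  pars <- unique(info$paralog)

  stats_res <- .stage("popgen_stats", {
    poly_rows <- list(); div_rows <- list()
    for (pop in pops) for (par in pars) {
      idx <- selectGroup(aln, population = pop, paralog = par)
      if (length(idx) < 2L) next
      ps <- piByClass(aln, cmap, idx)
      poly_rows[[paste(pop, par)]] <- cbind(
        data.frame(population = pop, paralog = par),
        as.data.frame(ps))
    }
    cmp <- function(label, ia, ib) {
      d <- divergenceBetweenGroups(aln, cmap, ia, ib, mode = "fixed_only")
      data.frame(comparison = label, ks = d$ks, ka = d$ka, ka_ks = d$ka_ks)
    }
    if (!is.null(cmap)) {
      for (pop in pops) {
        ia <- selectGroup(aln, population = pop, paralog = pars[1])
        ib <- selectGroup(aln, population = pop, paralog = pars[2])
        if (length(ia) && length(ib))
          div_rows[[paste0(pop, ":paralogs")]] <-
            cmp(sprintf("%s %s/%s", pop, pars[1], pars[2]), ia, ib)
      }
      if (length(pops) > 1L) for (par in pars) {
        for (q in 2:length(pops)) {
          ia <- selectGroup(aln, population = pops[1], paralog = par)
          ib <- selectGroup(aln, population = pops[q], paralog = par)
          if (length(ia) && length(ib))
            div_rows[[paste(par, pops[q])]] <-
              cmp(sprintf("%s %s/%s %s", pops[1], par, pops[q], par), ia, ib)
        }
      }
    }
    poly <- do.call(rbind, poly_rows)
    if (!is.null(poly)) {
      out <- poly
      for (cc in c("pi_syn", "pi_nonsyn", "pi_silent"))
        out[[cc]] <- .fmt_num(out[[cc]], 5)
      out$tajima_d <- .fmt_num(as.numeric(poly$tajima_d), 3)
      utils::write.table(out, file.path(config$outdir, "polymorphism.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    div <- do.call(rbind, div_rows)
    if (!is.null(div)) {
      outd <- div
      for (cc in c("ks", "ka", "ka_ks")) outd[[cc]] <- .fmt_num(div[[cc]], 3)
      utils::write.table(outd, file.path(config$outdir, "divergence.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    for (pop in pops) {
      ia <- selectGroup(aln, population = pop, paralog = pars[1])
      ib <- selectGroup(aln, population = pop, paralog = pars[2])
      if (!length(ia) || !length(ib)) next
      wp <- slidingDxy(aln, ia, ib, config$window, config$step)
      wpo <- wp
      wpo$dxy <- .fmt_num(wp$dxy, 5)
      utils::write.table(wpo,
        file.path(config$outdir, sprintf("windows_%s.tsv", pop)),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(polymorphism = poly, divergence = div)
  }, env)

  scan_res <- .stage("conversion_scan", {
    sc <- scanConversion(aln, n_perm = config$scan$n_perm,
                         alpha = config$scan$alpha, g = config$scan$g,
                         seed = config$seed)
    fr <- sc$fragments
    fro <- fr
    fro$sim_p <- .fmt_num(fr$sim_p, 5)
    utils::write.table(fro, file.path(config$outdir, "fragments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cl <- classifyAndCluster(fr, alpha = config$scan$alpha)
    utils::write.table(cl, file.path(config$outdir, "clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(scan = sc, clusters = cl)
  }, env)

  sig_res <- .stage("signatures", {
    if (length(pops) >= 2L) {
      ss <- sharedParalogSites(aln)
      utils::write.table(ss, file.path(config$outdir, "shared_sites.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      ss
    } else NULL
  }, env)

  phylo_res <- .stage("phylo_partition", {
    out <- list()
    if (!is.null(config$partitions)) {
      for (p in config$partitions) {
        mp <- searchMP(aln, partition = c(p$start, p$end),
                       n_starts = config$phylo$n_starts)
        tree <- mp$trees[[1]]
        if (!is.null(config$outgroup) &&
            config$outgroup %in% tree$tip.label)
          tree <- ape::root(tree, outgroup = config$outgroup,
                            resolve.root = TRUE)
        ape::write.tree(tree,
          file.path(config$outdir, sprintf("tree_%s.nwk", p$name)))
        out[[p$name]] <- mp
      }
    }
    out
  }, env)

  .write_manifest(env)
  invisible(list(data = dat, stats = stats_res, scan = scan_res,
                 signatures = sig_res, phylo = phylo_res,
                 config = config))
}
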