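## End-to-end orchestration: a single YAML (or list) config drives
## simulate/load -> filter -> normalize -> batch -> model -> calibrate ->
## enrichment/clustering -> networks, with one global seed from which the
## stage seeds are derived and a JSON run log sufficient to replay any
## stage.

#' @noRd
.cfg_get <- function(config, key, default = NULL) {
  v <- config[[key]]
  if (is.null(v)) default else v
}

#' Run the full analysis pipeline from a config
#'
#' The config names either a `simulate` block (arguments to
#' [effect_spec()]) or an `input` block (`probe_profile` path plus a
#' `manifest` TSV with `sample_id`, `sex`, `genotype`, `batch`), never
#' both.  Optional blocks `filter`, `normalize`, `batch`, `fdr`,
#' `calibrate`, `enrich` (a `gmt` path), and `network` (`sif` and `roles`
#' paths) override stage parameters, which default to the conventional
#' thresholds (detection alpha 0.05, FDR 0.05, 20 permutations).  Identical
#' config and seed give byte-identical outputs.
#'
#' @param config Path to a YAML file, or an equivalent named list.
#' @param out_dir Output directory (default: `output` config key, else a
#'   temp directory).
#' @return Invisibly, a list with the fit, calibration, enrichment and
#'   network results plus the run-log list; files are written to `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  seed <- as.integer(.cfg_get(config, "seed", 1L))
  if (is.null(out_dir)) out_dir <- .cfg_get(config, "output", tempfile("run"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage_seed <- function(i) seed + 1000L * i
  log_stages <- list()
  note <- function(name, params, outputs = character(0), status = "done",
                   sseed = NA) {
    files <- file.path(out_dir, outputs)
    log_stages[[length(log_stages) + 1L]] <<- list(
      stage = name, status = status, seed = sseed, params = params,
      outputs = if (length(files))
        as.list(stats::setNames(unname(tools::md5sum(files)), outputs))
      else NULL)
  }

  ## stage 1: simulate or load -------------------------------------------
  sim_cfg <- config$simulate; in_cfg <- config$input
  if (!is.null(sim_cfg) && !is.null(in_cfg))
    stop("config error: specify either simulate or input, not both")
  if (!is.null(sim_cfg)) {
    sim_cfg$seed <- .cfg_get(sim_cfg, "seed", stage_seed(1L))
    spec <- do.call(effect_spec, sim_cfg)
    sim <- simulate_experiment(spec)
    expr_raw <- sim$expr; det <- sim$det; design <- sim$design
    features <- sim$features
    utils::write.table(sim$truth, file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note("simulate", sim_cfg, "truth.tsv", sseed = sim_cfg$seed)
  } else if (!is.null(in_cfg)) {
    if (is.null(in_cfg$probe_profile) || !file.exists(in_cfg$probe_profile))
      stop("pipeline error in stage 'load': probe_profile missing")
    prof <- read_probe_profile(in_cfg$probe_profile)
    expr_raw <- prof$expr; det <- prof$det; features <- prof$features
    if (is.null(in_cfg$manifest) || !file.exists(in_cfg$manifest))
      stop("pipeline error in stage 'load': manifest missing")
    design <- .as_design(utils::read.delim(in_cfg$manifest,
                                           stringsAsFactors = FALSE))
    note("load", in_cfg)
  } else stop("config error: config needs a simulate or input block")

  ## stage 2: detection filter -------------------------------------------
  fcfg <- .cfg_get(config, "filter", list())
  flt <- detection_filter(expr_raw, det, design,
                          min_detected = .cfg_get(fcfg, "min_detected", 3),
                          alpha = .cfg_get(fcfg, "alpha", 0.05))
  note("filter", list(min_detected = .cfg_get(fcfg, "min_detected", 3),
                      alpha = .cfg_get(fcfg, "alpha", 0.05),
                      retained = sum(flt$mask), total = length(flt$mask)))

  ## stage 3: log2 + cubic-spline normalization --------------------------
  ncfg <- .cfg_get(config, "normalize", list())
  n_anchors <- .cfg_get(ncfg, "n_anchors", 13)
  expr <- cubic_spline_normalize(log2_transform(flt$expr),
                                 n_anchors = n_anchors)
  note("normalize", list(n_anchors = n_anchors))

  ## stage 4: batch assessment / adjustment ------------------------------
  bcfg <- .cfg_get(config, "batch", list())
  ba <- assess_and_adjust_batch(expr, design,
                                force = .cfg_get(bcfg, "mode", "auto"))
  expr <- ba$expr
  note("batch", list(mode = ba$report$mode, adjusted = ba$report$adjusted,
                     fraction = ba$report$fraction,
                     threshold = ba$report$threshold))

  ## stage 5: factorial model, contrasts, FDR ----------------------------
  fdr_level <- .cfg_get(.cfg_get(config, "fdr", list()), "level", 0.05)
  fit <- bead_anova(expr, design, features = features)
  res <- probe_results(fit)
  write_results(res, file.path(out_dir, "results.tsv"))
  sig_files <- character(0)
  probe_counts <- gene_counts <- c(genotype = 0, sex = 0)
  for (fam in c("genotype", "sex")) {
    sig <- call_significant(fit, fam, fdr_level)
    fn <- paste0("significant_", fam, ".tsv")
    utils::write.table(sig, file.path(out_dir, fn), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    sig_files <- c(sig_files, fn)
    probe_counts[fam] <- sum(fit$table[[paste0(fam, "_q")]] < fdr_level)
    gene_counts[fam] <- nrow(sig)
  }
  note("model", list(fdr = fdr_level, include_batch = fit$include_batch,
                     significant_probe_sets = as.list(probe_counts),
                     significant_genes = as.list(gene_counts)),
       c("results.tsv", sig_files))

  ## stage 6: permutation calibration ------------------------------------
  ccfg <- .cfg_get(config, "calibrate", list())
  k <- .cfg_get(ccfg, "permutations", 20)
  ens <- permutation_ensemble(expr, design, k = k, seed = stage_seed(6L),
                              features = features)
  hist_files <- character(0)
  for (fam in c("genotype", "sex")) {
    h <- fc_histogram(ens, fam, p_cut = .cfg_get(ccfg, "p_cut", 0.05))
    fn <- paste0("fc_histogram_", fam, ".tsv")
    utils::write.table(h, file.path(out_dir, fn), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    hist_files <- c(hist_files, fn)
  }
  grid <- .cfg_get(ccfg, "grid", c(0.01, 0.05, 0.10, 0.15, 0.20, 0.25))
  sweep <- fdr_sweep(ens, grid = grid)
  sweep_tab <- do.call(rbind, lapply(names(sweep$families), function(fam)
    data.frame(factor = fam, level = sweep$grid,
               real = unname(sweep$families[[fam]]$real),
               perm_mean = unname(colMeans(sweep$families[[fam]]$perm)),
               perm_max = unname(apply(sweep$families[[fam]]$perm, 2, max)))))
  utils::write.table(sweep_tab, file.path(out_dir, "fdr_sweep.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("calibrate",
       list(permutations = k, grid = grid, recommended = sweep$recommended),
       c(hist_files, "fdr_sweep.tsv"), sseed = stage_seed(6L))

  ## stage 7: enrichment + clustering ------------------------------------
  ecfg <- .cfg_get(config, "enrich", list())
  enr <- NULL
  universe <- unique(fit$table$symbol)
  sig_syms <- unique(unlist(lapply(c("genotype", "sex"), function(fam)
    call_significant(fit, fam, fdr_level)$symbol)))
  outputs7 <- character(0)
  if (!is.null(ecfg$gmt)) {
    sets <- read_gmt(ecfg$gmt)
    enr <- hypergeometric_enrichment(sig_syms, sets, universe)
    utils::write.table(enr, file.path(out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    outputs7 <- "enrichment.tsv"
  }
  sig_probes <- unique(unlist(lapply(c("genotype", "sex"), function(fam) {
    q <- fit$table[[paste0(fam, "_q")]]
    fit$table$probe_id[q < fdr_level]
  })))
  if (length(sig_probes) >= 2) {
    cl <- hcl_cluster(expr[sig_probes, , drop = FALSE], axis = "probes")
    hcl_newick(cl, file.path(out_dir, "dendrogram_probes.nwk"))
    outputs7 <- c(outputs7, "dendrogram_probes.nwk")
  }
  note("enrich_cluster",
       list(gmt = .cfg_get(ecfg, "gmt", NA), n_query = length(sig_syms),
            n_universe = length(universe),
            n_clustered = length(sig_probes)),
       outputs7,
       status = if (is.null(ecfg$gmt)) "partial" else "done")

  ## stage 8: networks ----------------------------------------------------
  ncfg2 <- .cfg_get(config, "network", list())
  nets <- NULL; outputs8 <- character(0); status8 <- "skipped"
  if (!is.null(ncfg2$sif)) {
    graph <- read_sif(ncfg2$sif, roles = ncfg2$roles)
    root <- sig_syms
    tfs <- tf_subnetworks(graph, root)
    uni <- igraph::V(graph)$name
    tf_tab <- do.call(rbind, lapply(tfs, function(s)
      data.frame(tf = s$tf, d = s$d,
                 receptors = paste(s$receptors, collapse = ","),
                 n_nodes = length(s$nodes),
                 root_overlap = length(intersect(s$nodes,
                                                 .norm_symbol(root))),
                 p = if (s$unreachable) NA_real_
                     else score_subnetwork(s$nodes, root, uni),
                 stringsAsFactors = FALSE)))
    if (!is.null(tf_tab)) tf_tab <- tf_tab[order(tf_tab$p), , drop = FALSE]
    else tf_tab <- data.frame(tf = character(0))
    utils::write.table(tf_tab, file.path(out_dir, "tf_subnetworks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    rec <- receptor_network(graph, root, results = res)
    utils::write.table(rec$nodes,
                       file.path(out_dir, "receptor_network_nodes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(rec$edges,
                       file.path(out_dir, "receptor_network_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    nets <- list(tf = tfs, tf_table = tf_tab, receptor = rec)
    outputs8 <- c("tf_subnetworks.tsv", "receptor_network_nodes.tsv",
                  "receptor_network_edges.tsv")
    status8 <- "done"
  }
  note("network", list(sif = .cfg_get(ncfg2, "sif", NA)), outputs8,
       status = status8)

  run_log <- list(seed = seed, stages = log_stages)
  jsonlite::write_json(run_log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(fit = fit, filter = flt, batch = ba$report,
                 ensemble = ens, sweep = sweep, enrichment = enr,
                 networks = nets, run_log = run_log, out_dir = out_dir))
}

#' Two-way phenotype ANOVA (sex, genotype, interaction)
#'
#' Applies the same linear-model machinery as the expression fit, without
#' the chip term, to phenotype measurements (echocardiographic or substrate
#' data, already indexed to body weight where appropriate).  Each
#' measurement gets per-factor p-values and the conventional significance
#' codes: `a` sex, `b` genotype, `c` interaction, at p < 0.05.
#'
#' @param table Data frame or matrix of numeric measurements, one row per
#'   sample (rows in design order or named by sample id).
#' @param design Sample design (batch ignored).
#' @param alpha Significance level for the codes.
#' @return Data frame: `measurement`, `p_sex`, `p_genotype`,
#'   `p_interaction`, `codes`.
#' @export
phenotype_anova <- function(table, design, alpha = 0.05) {
  design <- .as_design(design)
  tab <- as.data.frame(table)
  if (!all(vapply(tab, is.numeric, logical(1))))
    stop("data error: non-numeric measurement column(s)")
  mat <- t(as.matrix(tab))
  colnames(mat) <- design$sample_id
  eng <- .anova_engine(mat, design, include_batch = FALSE)
  p <- eng$p
  codes <- apply(p < alpha, 1L, function(s)
    paste(c("a", "b", "c")[c(s["sex"], s["genotype"], s["interaction"])],
          collapse = ","))
  data.frame(measurement = rownames(mat),
             p_sex = p[, "sex"], p_genotype = p[, "genotype"],
             p_interaction = p[, "interaction"],
             codes = codes, row.names = NULL, stringsAsFactors = FALSE)
}
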