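#' Validate a bundle of input files
#'
#' Checks sample-id alignment across tables, count integrality and
#' non-negativity, enrichment positivity and spectral grid consistency.
#' Returns a machine-readable issue list instead of stopping at the first
#' problem.
#'
#' @param paths named list/vector with entries `counts`, `metadata` and
#'   optionally `enrichment`, `covariates`, `spectra`.
#' @return data.frame with columns severity, where, issue; zero rows when
#'   the bundle is consistent.
#' @export
validate_inputs <- function(paths) {
  issues <- list()
  add <- function(severity, where, issue)
    issues[[length(issues) + 1]] <<- data.frame(
      severity = severity, where = where, issue = issue,
      stringsAsFactors = FALSE)

  for (need in c("counts", "metadata"))
    if (is.null(paths[[need]]) || !file.exists(paths[[need]]))
      stopf("cannot read %s file: %s", need,
            if (is.null(paths[[need]])) "<missing>" else paths[[need]])

  counts <- tryCatch(read_counts(paths[["counts"]]), error = function(e) {
    add("error", "counts", conditionMessage(e)); NULL
  })
  md <- read_tsv_plain(paths[["metadata"]])
  if (!"sample_id" %in% names(md))
    add("error", "metadata", "no sample_id column")

  if (!is.null(counts) && "sample_id" %in% names(md)) {
    missing_md <- setdiff(rownames(counts), md$sample_id)
    for (s in missing_md)
      add("error", "metadata", sprintf("sample '%s' missing from metadata", s))
    extra_md <- setdiff(md$sample_id, rownames(counts))
    for (s in extra_md)
      add("warning", "metadata", sprintf("sample '%s' has no counts", s))
    neg <- which(unclass(counts) < 0, arr.ind = TRUE)
    for (k in seq_len(nrow(neg)))
      add("error", "counts", sprintf("negative count at sample '%s', taxon '%s'",
                                     rownames(counts)[neg[k, 1]],
                                     colnames(counts)[neg[k, 2]]))
  }

  if (!is.null(paths[["enrichment"]]) && file.exists(paths[["enrichment"]])) {
    enr <- read_tsv_plain(paths[["enrichment"]])
    for (col in c("residue_e", "sab_e", "nh3_e")) {
      if (!col %in% names(enr)) {
        add("error", "enrichment", sprintf("missing column '%s'", col))
        next
      }
      bad <- which(enr[[col]] < 0)
      for (k in bad)
        add("error", "enrichment",
            sprintf("negative %s in row %d (vessel %s)", col, k, enr$vessel[k]))
      if (col != "residue_e")
        for (k in which(enr[[col]] == 0))
          add("error", "enrichment",
              sprintf("zero %s in row %d: tracer ratios undefined", col, k))
    }
  }

  if (!is.null(paths[["covariates"]]) && file.exists(paths[["covariates"]])) {
    cov <- read_tsv_plain(paths[["covariates"]])
    if (!"sample_id" %in% names(cov)) add("error", "covariates", "no sample_id column")
    else if (!is.null(counts))
      for (s in setdiff(rownames(counts), cov$sample_id))
        add("warning", "covariates", sprintf("sample '%s' missing", s))
  }

  if (!is.null(paths[["spectra"]]) && file.exists(paths[["spectra"]])) {
    spc <- tryCatch(read_spectra(paths[["spectra"]]), error = function(e) {
      add("error", "spectra", conditionMessage(e)); NULL
    })
    if (!is.null(spc) && "sample_id" %in% names(md))
      for (s in setdiff(spc$samples, md$sample_id))
        add("warning", "spectra", sprintf("spectrum '%s' not in metadata", s))
  }

  if (!length(issues))
    return(data.frame(severity = character(), where = character(),
                      issue = character(), stringsAsFactors = FALSE))
  do.call(rbind, issues)
}

#' Run the full colonization analysis pipeline
#'
#' Executes, in order: synthetic-data generation (or input loading and
#' validation), tracer colonization profiles, rarefaction and alpha
#' diversity, Bray-Curtis / UPGMA / PCoA, PERMANOVA (full factorial plus
#' per-time forage strata), CCA with per-variable permutation tests,
#' co-occurrence networks per forage x time stratum, and the FTIR chain
#' (derivative, normalization, spectral PERMANOVA). Every artifact is
#' written to `out_dir` with a header recording package version, config
#' hash and seed; a rerun with identical config is byte-identical.
#'
#' @param config list with exactly one of `simulate` (arguments to
#'   [sim_config()], or a `sim_config`) or `inputs` (named file paths as in
#'   [validate_inputs()]); optional elements `n_perm` (default 999), `seed`
#'   (required), `terms` (PERMANOVA terms), `rho_threshold`, `alpha`,
#'   `prevalence`, `couplings`, `peak_effects`.
#' @param out_dir output directory, created if needed.
#' @return invisibly, named list of artifact paths.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!is.null(config$simulate) && !is.null(config$inputs))
    stopf("config error: give either 'simulate' or 'inputs', not both")
  if (is.null(config$simulate) && is.null(config$inputs))
    stopf("config error: one of 'simulate' or 'inputs' is required")
  if (is.null(config$seed)) stopf("config error: seed is mandatory")
  n_perm <- config$n_perm %||% 999
  terms <- config$terms %||%
    c("forage", "vitE", "time_h", "forage:vitE", "forage:time_h",
      "vitE:time_h", "forage:vitE:time_h", "donor")
  rho_thr <- config$rho_threshold %||% 0.7
  alpha <- config$alpha %||% 0.05
  prevalence <- config$prevalence %||% 0.75
  seed <- as.integer(config$seed)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf("rumicol %s | config %s | seed %d",
                 as.character(utils::packageVersion("rumicol")),
                 config_hash(config), seed)
  log_lines <- character()
  logmsg <- function(...) {
    line <- sprintf(...)
    message("[rumicol] ", line)
    log_lines <<- c(log_lines, line)
  }
  art <- list()
  emit <- function(name, fname) {
    art[[name]] <<- file.path(out_dir, fname)
    art[[name]]
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  # ---- inputs -------------------------------------------------------------
  if (!is.null(config$simulate)) {
    sc <- if (inherits(config$simulate, "sim_config")) config$simulate else
      do.call(sim_config, c(config$simulate, list(seed = seed)))
    logmsg("simulate: %d taxa, %d replicates, seed %d", sc$n_taxa,
           sc$n_replicates, sc$seed)
    sim <- stage("simulate", simulate_counts(sc))
    counts <- sim$counts; md <- sim$metadata
    enr <- stage("simulate", simulate_enrichment(sc))
    cov <- stage("simulate", simulate_covariates(
      sc, sim$truth, couplings = config$couplings %||% list()))
    spc <- stage("simulate", simulate_spectra(
      sc, sim$truth, peak_effects = config$peak_effects %||% list()))
    write_counts(counts, emit("counts", "counts.tsv"), header = hdr)
    write_tsv_plain(md, emit("metadata", "metadata.tsv"), header = hdr)
    write_tsv_plain(enr, emit("enrichment", "enrichment.tsv"), header = hdr)
    write_tsv_plain(cov, emit("covariates", "covariates.tsv"), header = hdr)
    write_spectra(spc, emit("spectra", "spectra.csv"), header = hdr)
  } else {
    logmsg("loading inputs")
    issues <- stage("validate", validate_inputs(config$inputs))
    if (any(issues$severity == "error"))
      stopf("input validation failed:\n%s",
            paste(sprintf("  [%s] %s: %s", issues$severity, issues$where,
                          issues$issue), collapse = "\n"))
    counts <- read_counts(config$inputs$counts)
    md <- read_tsv_plain(config$inputs$metadata)
    enr <- if (!is.null(config$inputs$enrichment))
      read_tsv_plain(config$inputs$enrichment)
    cov <- if (!is.null(config$inputs$covariates))
      read_tsv_plain(config$inputs$covariates)
    spc <- if (!is.null(config$inputs$spectra))
      read_spectra(config$inputs$spectra)
  }

  # ---- tracer -------------------------------------------------------------
  if (!is.null(enr)) {
    prof <- stage("tracer", colonization_profile(enr))
    write_tsv_plain(prof, emit("profile", "colonization_profile.tsv"),
                    header = hdr)
    logmsg("tracer: %d vessel profiles", length(unique(prof$vessel)))
  }

  # ---- diversity ----------------------------------------------------------
  depth <- min(rowSums(counts))
  rare <- stage("rarefy", rarefy(counts, depth, seed = seed))
  logmsg("rarefied to %d reads/sample", depth)
  div <- stage("diversity", diversity(rare))
  write_tsv_plain(div, emit("diversity", "diversity.tsv"),
                  header = c(hdr, sprintf("rarefaction depth %d", depth)))

  # ---- beta diversity -----------------------------------------------------
  d <- stage("bray-curtis", bray_curtis(rare, normalize = "relative"))
  write_tsv_plain(data.frame(sample_id = rownames(d), unclass(d),
                             check.names = FALSE),
                  emit("distance", "bray_curtis.tsv"), header = hdr)
  tr <- stage("upgma", upgma(d))
  writeLines(tr$newick, emit("upgma", "upgma.nwk"))
  ord <- stage("pcoa", pcoa(d))
  write_tsv_plain(data.frame(sample_id = rownames(ord$scores), ord$scores,
                             check.names = FALSE),
                  emit("pcoa", "pcoa_scores.tsv"), header = hdr)

  # ---- PERMANOVA ----------------------------------------------------------
  pr <- stage("permanova",
              permanova(d, md, terms = terms, n_perm = n_perm, seed = seed))
  write_tsv_plain(as.data.frame(pr), emit("permanova", "permanova.tsv"),
                  header = hdr)
  logmsg("permanova: %d terms, %d permutations", length(terms), n_perm)
  strata_rows <- list()
  for (tt in sort(unique(md$time_h))) {
    ids <- md$sample_id[md$time_h == tt]
    if (length(unique(md$forage[md$time_h == tt])) < 2) next
    sr <- stage("stratum-permanova",
                stratum_effect(d, md, "forage",
                               stratum = list(column = "time_h", value = tt),
                               n_perm = n_perm, seed = seed))
    srf <- as.data.frame(sr)[1, ]
    srf$stratum <- sprintf("time_h=%g", tt)
    strata_rows[[length(strata_rows) + 1]] <- srf
  }
  if (length(strata_rows))
    write_tsv_plain(do.call(rbind, strata_rows),
                    emit("strata", "permanova_strata.tsv"), header = hdr)

  # ---- CCA ----------------------------------------------------------------
  if (!is.null(cov)) {
    env <- cov[match(rownames(rare), cov$sample_id), -1, drop = FALSE]
    ccares <- stage("cca", cca(rare, env))
    envp <- stage("cca", env_significance(rare, env, n_perm = n_perm,
                                          seed = seed))
    write_tsv_plain(envp, emit("cca_env", "cca_env_significance.tsv"),
                    header = c(hdr, sprintf(
                      "constrained inertia %.6f of total %.6f",
                      ccares$constrained_inertia, ccares$total_inertia)))
    write_tsv_plain(data.frame(sample_id = rownames(ccares$site_lc),
                               ccares$site_lc, check.names = FALSE),
                    emit("cca_sites", "cca_site_scores.tsv"), header = hdr)
  }

  # ---- networks -----------------------------------------------------------
  traj <- stage("network", network_trajectory(
    rare, md, group_by = "forage", min_prevalence = prevalence,
    rho_threshold = rho_thr, alpha = alpha))
  if (!is.null(traj$metrics))
    write_tsv_plain(traj$metrics, emit("network_metrics", "network_metrics.tsv"),
                    header = hdr)
  all_edges <- do.call(rbind, lapply(names(traj$networks), function(nm) {
    e <- traj$networks[[nm]]$edges
    if (nrow(e)) cbind(stratum = nm, e) else NULL
  }))
  if (!is.null(all_edges))
    write_tsv_plain(all_edges, emit("network_edges", "network_edges.tsv"),
                    header = hdr)
  logmsg("networks: %d strata", length(traj$networks))

  # ---- FTIR ---------------------------------------------------------------
  if (!is.null(spc)) {
    proc <- stage("ftir", normalize_spectra(savgol_first_derivative(spc)))
    write_spectra(proc, emit("spectra_processed", "spectra_processed.csv"),
                  header = hdr)
    fres <- stage("ftir", spectra_permanova(
      proc, md, terms = c("forage", "vitE", "time_h"), n_perm = n_perm,
      seed = seed))
    write_tsv_plain(as.data.frame(fres), emit("ftir", "ftir_permanova.tsv"),
                    header = hdr)
  }

  # ---- summary ------------------------------------------------------------
  writeLines(c(paste0("# ", hdr), log_lines),
             emit("log", "run_log.txt"))
  smry <- data.frame(artifact = names(art),
                     file = basename(unlist(art)),
                     stringsAsFactors = FALSE)
  write_tsv_plain(smry, emit("summary", "summary.tsv"), header = hdr)
  invisible(art)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a co-occurrence network as GraphML
#'
#' @param network a `co_network`.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_network_graphml <- function(network, path) {
  g <- igraph::graph_from_data_frame(
    network$edges[, c("a", "b", "rho", "q", "sign")], directed = FALSE,
    vertices = network$nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
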