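#' Simulate a genus count table with planted structure
#'
#' Generates one sample per treatment x time x replicate x community fraction
#' under a logistic-normal multinomial model: latent log-abundances are
#' multivariate normal with correlation blocks planted via a factor model,
#' shifted by configured treatment/time effects, softmax-transformed and
#' sampled multinomially at a depth drawn uniformly from `depth_range`.
#'
#' A small per-donor intercept (sd 0.2 on the latent scale) creates the
#' repeated-measures structure of an inoculum-donor random effect.
#'
#' @param config a [sim_config()] object.
#' @return list with elements `counts` (a `count_table`, samples x taxa),
#'   `metadata` (data.frame of design factors per sample) and `truth`
#'   (planted edges, true colonization curves, true effects, and the latent
#'   log-abundance matrix used for generation).
#' @export
simulate_counts <- function(config) {
  validate_sim_config(config)
  md <- design_grid(config)
  n <- nrow(md)
  p <- config$n_taxa
  taxa <- sprintf("g__Genus%03d", seq_len(p))

  with_seed(config$seed, {
    mu <- rnorm(p, 0, 1.5)                       # rank-abundance baseline
    # inoculum-donor signature: latent shifts on ~10% of taxa, drawn outside
    # the planted blocks so that declared block correlations are delivered
    # exactly (a shift common to ALL taxa would cancel in the softmax)
    free <- setdiff(seq_len(p),
                    unlist(lapply(config$planted_blocks, `[[`, "taxa")))
    donor_taxa <- if (length(free))
      sample(free, min(max(1, round(0.1 * p)), length(free))) else integer()
    donor_shift <- matrix(rnorm(config$n_replicates * length(donor_taxa),
                                0, 0.5), config$n_replicates)

    # latent residuals with planted correlation blocks (single-factor model
    # per block: loading s_j * sqrt(|rho|), sign pattern keeps PSD)
    eps <- matrix(rnorm(n * p), n, p)
    for (b in config$planted_blocks) {
      s <- if (identical(b$sign, "-")) rep_len(c(1, -1), length(b$taxa)) else
        rep(1, length(b$taxa))
      f <- rnorm(n)
      r <- abs(b$rho)
      for (k in seq_along(b$taxa)) {
        j <- b$taxa[k]
        eps[, j] <- s[k] * sqrt(r) * f + sqrt(1 - r) * rnorm(n)
      }
    }

    z <- matrix(mu, n, p, byrow = TRUE) + config$noise_sd * eps
    if (length(donor_taxa))
      z[, donor_taxa] <- z[, donor_taxa] + donor_shift[md$donor, , drop = FALSE]

    tmin <- min(config$time_points_h); tmax <- max(config$time_points_h)
    for (e in config$effect_sizes) {
      active <- rep(TRUE, n)
      if (!is.null(e$times)) active <- md$time_h %in% e$times
      w <- switch(e$factor,
        forage = as.numeric(md$forage == "GRA"),
        vitE   = as.numeric(md$vitE == "+"),
        time   = if (tmax > tmin) (md$time_h - tmin) / (tmax - tmin) else 0)
      w <- w * active
      z[, e$taxa] <- z[, e$taxa] + outer(w, rep(e$logfc, length(e$taxa)))
    }

    depths <- if (config$depth_range[1] == config$depth_range[2])
      rep(config$depth_range[1], n) else
      sample(seq(config$depth_range[1], config$depth_range[2]), n, replace = TRUE)

    counts <- matrix(0L, n, p, dimnames = list(md$sample_id, taxa))
    for (i in seq_len(n)) {
      pr <- exp(z[i, ] - max(z[i, ]))
      counts[i, ] <- as.integer(rmultinom(1, depths[i], pr / sum(pr)))
    }

    truth <- list(
      planted_edges = planted_edge_list(config, taxa),
      true_m = lapply(config$colonization_params, colonization_curve,
                      t = config$time_points_h),
      true_effects = config$effect_sizes,
      latent = structure(z, dimnames = list(md$sample_id, taxa))
    )
    list(counts = count_table(counts, rank = "genus"),
         metadata = md, truth = truth)
  })
}

design_grid <- function(config) {
  g <- expand.grid(
    fraction = config$fractions,
    replicate = seq_len(config$n_replicates),
    vitE = c("-", "+"),
    forage = c("GRA", "HAY"),
    time_h = config$time_points_h,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  g <- g[order(g$forage, g$vitE, g$replicate, g$time_h, g$fraction), ]
  g$vessel <- sprintf("%s%s.V%d", g$forage, ifelse(g$vitE == "+", "p", "m"),
                      g$replicate)
  g$donor <- g$replicate   # donor l inoculates vessel l of every treatment
  g$sample_id <- sprintf("%s.T%02d.%s", g$vessel, as.integer(g$time_h), g$fraction)
  rownames(g) <- NULL
  g[, c("sample_id", "forage", "vitE", "time_h", "replicate", "vessel",
        "donor", "fraction")]
}

planted_edge_list <- function(config, taxa) {
  out <- list()
  for (b in config$planted_blocks) {
    s <- if (identical(b$sign, "-")) rep_len(c(1, -1), length(b$taxa)) else
      rep(1, length(b$taxa))
    prs <- utils::combn(seq_along(b$taxa), 2)
    for (k in seq_len(ncol(prs))) {
      i <- prs[1, k]; j <- prs[2, k]
      out[[length(out) + 1]] <- data.frame(
        a = taxa[b$taxa[i]], b = taxa[b$taxa[j]],
        sign = ifelse(s[i] * s[j] > 0, "+", "-"),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame(a = character(), b = character(),
                                      sign = character()))
  do.call(rbind, out)
}

#' Simulate 15N enrichment records
#'
#' Residue enrichment is generated so that the tracer ratio
#' residue / SAB-pellet enrichment equals the configured colonization curve
#' m(t): `residue_e(t) = m(t) * sab_enrichment + noise`, truncated at zero.
#' The implied ammonia-derived fraction of microbial N is
#' `sab_enrichment / nh3_enrichment`.
#'
#' @param config a [sim_config()].
#' @param sab_enrichment atom\% 15N excess of the isolated SAB pellet (> 0).
#' @param nh3_enrichment atom\% 15N excess of the ammonia pool (> 0).
#' @param noise_sd Gaussian noise on residue enrichment (atom\% excess).
#' @return data.frame with vessel, forage, vitE, time_h, residue_e, sab_e,
#'   nh3_e; one row per vessel x time.
#' @export
simulate_enrichment <- function(config, sab_enrichment = 0.5,
                                nh3_enrichment = 2.0, noise_sd = 0) {
  validate_sim_config(config)
  if (sab_enrichment <= 0) stopf("sab_enrichment must be > 0")
  if (nh3_enrichment <= 0) stopf("nh3_enrichment must be > 0")
  md <- design_grid(config)
  md <- md[!duplicated(paste(md$vessel, md$time_h)), ]
  m <- numeric(nrow(md))
  for (f in unique(md$forage)) {
    sel <- md$forage == f
    spec <- config$colonization_params[[f]]
    if (is.null(spec)) stopf("no colonization_params for forage '%s'", f)
    m[sel] <- colonization_curve(spec, md$time_h[sel])
  }
  with_seed(config$seed + 3L, {
    res <- m * sab_enrichment + if (noise_sd > 0)
      rnorm(nrow(md), 0, noise_sd) else 0
    data.frame(vessel = md$vessel, forage = md$forage, vitE = md$vitE,
               time_h = md$time_h,
               residue_e = pmax(res, 0),
               sab_e = sab_enrichment, nh3_e = nh3_enrichment,
               stringsAsFactors = FALSE)
  })
}

#' Simulate fermentation covariates
#'
#' Ammonia and lactate peak 2-4 h post-feeding, total VFA accumulate, and pH
#' dips reciprocally; optional couplings add (standardized) latent
#' log-abundances of designated taxa so that community structure and
#' fermentation covary, as the constrained ordination expects.
#'
#' @param config a [sim_config()].
#' @param truth the `truth` element returned by [simulate_counts()] (same
#'   config); supplies the latent matrix for couplings.
#' @param couplings list of `list(covariate =, taxon =, weight =)` entries.
#' @param noise_sd Gaussian measurement noise added to every covariate.
#' @return data.frame with sample_id and columns ammonia, lactate, vfa, ph.
#' @export
simulate_covariates <- function(config, truth, couplings = list(),
                                noise_sd = 0.1) {
  validate_sim_config(config)
  md <- design_grid(config)
  t <- md$time_h
  bump <- function(t, tp) exp(-(log((t + 0.5) / (tp + 0.5)))^2 / (2 * 0.35))
  cov <- data.frame(
    sample_id = md$sample_id,
    ammonia = 8 + 12 * bump(t, 3),
    lactate = 0.5 + 4 * bump(t, 2),
    vfa = 40 + 30 * (1 - exp(-t / 8)),
    ph = 6.8 - 0.6 * bump(t, 3),
    stringsAsFactors = FALSE
  )
  for (cp in couplings) {
    if (!cp$covariate %in% names(cov)) stopf("unknown covariate '%s'", cp$covariate)
    zk <- truth$latent[md$sample_id, cp$taxon]
    cov[[cp$covariate]] <- cov[[cp$covariate]] +
      cp$weight * as.numeric(scale(zk))
  }
  with_seed(config$seed + 1L, {
    for (nm in c("ammonia", "lactate", "vfa", "ph"))
      cov[[nm]] <- cov[[nm]] + if (noise_sd > 0)
        rnorm(nrow(cov), 0, noise_sd) else 0
    cov
  })
}

# Canonical FTIR peak set (wavenumber cm-1, width, base amplitude): lipid CH,
# ester carbonyl, amide I, amide II, phosphate/carboxyl, carbohydrate C-O.
ftir_peaks <- function() {
  data.frame(center = c(2920, 1735, 1650, 1540, 1240, 1030),
             width  = c(40, 20, 30, 25, 35, 45),
             amp    = c(0.25, 0.10, 0.45, 0.30, 0.15, 0.50))
}

#' Simulate FTIR spectra
#'
#' Each spectrum is a smooth baseline plus Gaussian peaks on the fixed
#' 4000-600 cm-1 grid (2 cm-1 steps, descending). The carbohydrate band at
#' 1030 cm-1 declines with colonization m(t) (substrate consumption);
#' `peak_effects` impose treatment contrasts on chosen peak amplitudes.
#'
#' @param config a [sim_config()].
#' @param truth `truth` from [simulate_counts()] (colonization curves).
#' @param peak_effects list of `list(factor = "forage"|"vitE", wavenumber =,
#'   delta =)`: amplitude of the nearest canonical peak is multiplied by
#'   `(1 + delta)` for GRA (resp. vitamin E "+") samples.
#' @param noise_sd absorbance noise sd (default 0.002 AU).
#' @return a `spectrum_set` (see [spectrum_set()]); one spectrum per sample.
#' @export
simulate_spectra <- function(config, truth, peak_effects = list(),
                             noise_sd = 0.002) {
  validate_sim_config(config)
  md <- design_grid(config)
  wn <- seq(4000, 600, by = -2)
  pk <- ftir_peaks()
  baseline <- 0.05 + 0.25 * exp(-((wn - 3300) / 500)^2) +
    0.02 * (4000 - wn) / 3400
  shapes <- sapply(seq_len(nrow(pk)), function(i)
    exp(-((wn - pk$center[i]) / pk$width[i])^2))   # n_wn x n_peaks

  m_at <- function(forage, t) {
    spec <- config$colonization_params[[forage]]
    if (is.null(spec)) 0 else colonization_curve(spec, t)
  }
  with_seed(config$seed + 2L, {
    vals <- matrix(0, length(wn), nrow(md))
    for (i in seq_len(nrow(md))) {
      amp <- pk$amp
      carb <- which(pk$center == 1030)
      amp[carb] <- amp[carb] * (1 - 0.5 * m_at(md$forage[i], md$time_h[i]))
      for (pe in peak_effects) {
        j <- which.min(abs(pk$center - pe$wavenumber))
        on <- switch(pe$factor,
                     forage = md$forage[i] == "GRA",
                     vitE = md$vitE[i] == "+",
                     stopf("unknown peak_effects factor '%s'", pe$factor))
        if (on) amp[j] <- amp[j] * (1 + pe$delta)
      }
      vals[, i] <- baseline + as.numeric(shapes %*% amp)
    }
    if (noise_sd > 0)
      vals <- vals + matrix(rnorm(length(vals), 0, noise_sd), nrow(vals))
    spectrum_set(wn, vals, md$sample_id, fraction = "residue",
                 provenance = "raw")
  })
}

#' Write a complete synthetic bundle to disk
#'
#' Emits the interchange files every pipeline stage consumes: counts TSV
#' (taxa rows, first column lineage), metadata TSV, enrichment TSV,
#' covariates TSV, spectra CSV (first column wavenumber) and truth JSON.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @param couplings,peak_effects passed to the respective simulators.
#' @return invisibly, named vector of file paths.
#' @export
write_simulation <- function(config, dir, couplings = list(),
                             peak_effects = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_counts(config)
  enr <- simulate_enrichment(config)
  cov <- simulate_covariates(config, sim$truth, couplings = couplings)
  spc <- simulate_spectra(config, sim$truth, peak_effects = peak_effects)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             enrichment = file.path(dir, "enrichment.tsv"),
             covariates = file.path(dir, "covariates.tsv"),
             spectra = file.path(dir, "spectra.csv"),
             truth = file.path(dir, "truth.json"))
  write_counts(sim$counts, paths["counts"])
  write_tsv_plain(sim$metadata, paths["metadata"])
  write_tsv_plain(enr, paths["enrichment"])
  write_tsv_plain(cov, paths["covariates"])
  write_spectra(spc, paths["spectra"])
  truth_json <- list(
    planted_edges = sim$truth$planted_edges,
    true_m = sim$truth$true_m,
    true_effects = sim$truth$true_effects
  )
  jsonlite::write_json(truth_json, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
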