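#' Canonical correspondence analysis
#'
#' Relates a chi-square-standardized community table to environmental
#' covariates: the standardized matrix Qbar is regressed on the covariates
#' (weighted by sample totals) and the fitted values are eigen-decomposed
#' (ter Braak's algorithm). Taxon scores are chi-square-metric unit scores
#' and site WA scores are weighted averages of taxon scores.
#'
#' @param table `count_table` or non-negative matrix (samples x taxa).
#' @param env data.frame/matrix of numeric covariates, rows aligned with the
#'   samples of `table`; columns must be non-constant and not collinear, and
#'   there must be fewer columns than samples - 1.
#' @return list of class `cca_result`: `eigenvalues` (constrained,
#'   nonincreasing), `site_lc` (linear-combination site scores), `site_wa`
#'   (weighted-average site scores), `taxon_scores`, `biplot` (weighted
#'   correlations of covariates with LC axes), `total_inertia`,
#'   `constrained_inertia`.
#' @export
cca <- function(table, env) {
  Y <- unclass(as.matrix(table)) * 1.0
  env <- as.matrix(env)
  storage.mode(env) <- "double"
  if (nrow(env) != nrow(Y)) stopf("env rows must align with samples")
  if (any(!is.finite(env))) stopf("env contains non-finite values")
  cs <- apply(env, 2, function(v) var(v) < 1e-24)
  if (any(cs))
    stopf("constant env column(s): %s",
          paste(colnames(env)[cs], collapse = ", "))
  if (ncol(env) > nrow(Y) - 1) stopf("more env columns than samples - 1")
  Y <- Y[, colSums(Y) > 0, drop = FALSE]
  if (any(rowSums(Y) == 0)) stopf("all-zero sample in table")

  P <- Y / sum(Y)
  r <- rowSums(P); cc <- colSums(P)
  Qbar <- diag(1 / sqrt(r)) %*% (P - outer(r, cc)) %*% diag(1 / sqrt(cc))
  total_inertia <- sum(Qbar^2)

  # weighted (by r) centering of env, then projection in the sqrt(r) metric
  Ec <- sweep(env, 2, colSums(env * r), "-")     # weighted means (sum r = 1)
  Xs <- Ec * sqrt(r)
  q <- qr(Xs)
  if (q$rank < ncol(Xs))
    stopf("collinear env columns (rank %d < %d)", q$rank, ncol(Xs))
  Qx <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  fitted <- Qx %*% crossprod(Qx, Qbar)

  sv <- svd(fitted)
  keep <- which(sv$d^2 > max(sv$d^2, 1e-300) * 1e-12 & sv$d > 0)
  lambda <- sv$d[keep]^2
  Vsc <- diag(1 / sqrt(cc)) %*% sv$v[, keep, drop = FALSE]   # taxon scores
  site_lc <- diag(1 / sqrt(r)) %*% sv$u[, keep, drop = FALSE] %*%
    diag(sv$d[keep], length(keep))
  site_wa <- diag(1 / r) %*% P %*% Vsc                       # WA of taxa
  bip <- suppressWarnings(
    stats::cor(Ec * sqrt(r), sv$u[, keep, drop = FALSE]))

  dimnames(site_lc) <- list(rownames(Y), paste0("CCA", seq_along(keep)))
  dimnames(site_wa) <- dimnames(site_lc)
  rownames(Vsc) <- colnames(Y)
  colnames(Vsc) <- colnames(site_lc)
  rownames(bip) <- colnames(env)

  structure(list(eigenvalues = lambda, site_lc = site_lc, site_wa = site_wa,
                 taxon_scores = Vsc, biplot = bip,
                 total_inertia = total_inertia,
                 constrained_inertia = sum(lambda)),
            class = "cca_result")
}

#' @export
print.cca_result <- function(x, ...) {
  cat(sprintf("CCA: constrained inertia %.4f of total %.4f (%.1f%%), %d axes\n",
              x$constrained_inertia, x$total_inertia,
              100 * x$constrained_inertia / x$total_inertia,
              length(x$eigenvalues)))
  invisible(x)
}

#' Permutation significance of individual environmental variables
#'
#' For each covariate, the observed statistic is its marginal constrained
#' inertia (CCA on that variable alone); its values are permuted across
#' samples and the inertia recomputed; p = (#{null >= observed} + 1) /
#' (n_perm + 1).
#'
#' @param table community table as in [cca()].
#' @param env covariate matrix/data.frame.
#' @param n_perm permutations (>= 99, default 999).
#' @param seed RNG seed.
#' @return data.frame: variable, inertia, p.
#' @export
env_significance <- function(table, env, n_perm = 999, seed = 1L) {
  if (n_perm < 99) stopf("n_perm must be >= 99")
  env <- as.data.frame(env)
  n <- nrow(env)
  res <- with_seed(seed, {
    lapply(names(env), function(v) {
      e1 <- env[, v, drop = FALSE]
      obs <- cca(table, e1)$constrained_inertia
      null <- replicate(n_perm, {
        e1p <- e1
        e1p[[1]] <- e1[[1]][sample.int(n)]
        cca(table, e1p)$constrained_inertia
      })
      data.frame(variable = v, inertia = obs,
                 p = (sum(null >= obs - 1e-12) + 1) / (n_perm + 1))
    })
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
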