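#' Benjamini-Hochberg step-up adjustment
#'
#' q_(i) = min_{j >= i} p_(j) * m / j, capped at 1 (monotonicity enforced by
#' the running minimum from the largest p downwards).
#'
#' @param pvalues numeric vector in \[0,1\]; NAs propagate.
#' @return q-values in the original order.
#' @export
adjust_bh <- function(pvalues) {
  p <- as.numeric(pvalues)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stopf("p-values must lie in [0,1]")
  q <- rep(NA_real_, length(p))
  pp <- p[ok]
  m <- length(pp)
  if (m) {
    o <- order(pp, decreasing = TRUE)
    ro <- order(o)
    q[ok] <- pmin(1, cummin(pp[o] * m / (m:1)))[ro]
  }
  q
}

#' Per-taxon differential abundance with FDR control
#'
#' Tests each taxon's log10 relative abundance (pseudocount of 1 read added
#' before the relative-abundance transform) between the levels of a design
#' factor by a permutation test: mean difference for two levels, one-way F
#' statistic for more. P-values are BH-adjusted across taxa.
#'
#' @param table a `count_table`.
#' @param metadata data.frame with `sample_id` and the factor column, one row
#'   per sample of `table`.
#' @param factor name of the metadata column to test (at least 2 levels,
#'   each with at least 2 samples).
#' @param n_perm number of label permutations (default 999).
#' @param seed RNG seed.
#' @return data.frame: taxon, statistic, p, q, constant (flag: taxon had zero
#'   variance, p set to 1 by convention).
#' @export
differential_abundance <- function(table, metadata, factor, n_perm = 999,
                                   seed = 1L) {
  md <- metadata[match(rownames(table), metadata$sample_id), ]
  if (any(is.na(md$sample_id))) stopf("metadata missing samples from table")
  g <- base::factor(md[[factor]])
  if (nlevels(g) < 2) stopf("factor '%s' needs >= 2 levels", factor)
  if (any(table(g) < 2)) stopf("every level of '%s' needs >= 2 samples", factor)

  tot <- rowSums(table)
  y <- log10((unclass(table) + 1) / tot)   # samples x taxa

  stat_fun <- if (nlevels(g) == 2) {
    i1 <- g == levels(g)[1]
    function(v) mean(v[i1]) - mean(v[!i1])
  } else {
    function(v) {                           # one-way F
      mg <- tapply(v, g, mean)
      ng <- tabulate(g)
      ssb <- sum(ng * (mg - mean(v))^2)
      ssw <- sum((v - mg[g])^2)
      (ssb / (nlevels(g) - 1)) / (ssw / (length(v) - nlevels(g)))
    }
  }

  obs <- apply(y, 2, stat_fun)
  constant <- apply(y, 2, function(v) var(v) < 1e-24)
  p <- rep(1, ncol(y))
  with_seed(seed, {
    perms <- replicate(n_perm, sample(nrow(y)))
    for (j in which(!constant)) {
      null <- apply(perms, 2, function(ix) stat_fun(y[ix, j]))
      p[j] <- (sum(abs(null) >= abs(obs[j]) - 1e-12) + 1) / (n_perm + 1)
    }
  })
  data.frame(taxon = colnames(table), statistic = obs, p = p,
             q = adjust_bh(p), constant = constant, row.names = NULL,
             stringsAsFactors = FALSE)
}
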