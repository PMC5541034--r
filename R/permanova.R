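#' Distance-based permutational multivariate ANOVA
#'
#' Partitions the total sum of squares of a distance matrix among design
#' terms via the Gower-centered inner-product matrix (McArdle-Anderson):
#' sequential (Type I) sums of squares in the order the terms are given,
#' pseudo-F per term against the residual mean square, and significance by
#' permutation of residuals under the reduced model that excludes the tested
#' term (Freedman-Lane). A Monte Carlo p-value is obtained by matching
#' mean, variance and skewness of the permutation null to a shifted-gamma
#' (Pearson type III) distribution.
#'
#' @param d a `dist_matrix`, samples aligned with `metadata`.
#' @param metadata data.frame with `sample_id` and the design columns.
#' @param terms character vector of model terms in testing order, e.g.
#'   `c("forage", "vitE", "time_h", "forage:vitE")`. Variables are coerced to
#'   factors.
#' @param n_perm number of random permutations (>= 99), or use
#'   `exact = TRUE`.
#' @param seed RNG seed for the permutations.
#' @param exact enumerate all n! permutations instead of sampling (n <= 8).
#' @param strata optional metadata column name; permutations are then
#'   restricted to exchanges within its levels (e.g. inoculum donor).
#' @return data.frame of class `permanova_result`: term, df, SS, pseudo_F,
#'   p_perm, p_mc, n_perm, plus Residual and Total rows. Attribute
#'   `degenerate` flags SS_total == 0.
#' @export
permanova <- function(d, metadata, terms, n_perm = 999, seed = 1L,
                      exact = FALSE, strata = NULL) {
  md <- metadata[match(rownames(d), metadata$sample_id), , drop = FALSE]
  if (any(is.na(md$sample_id)))
    stopf("metadata does not cover all samples in the distance matrix")
  n <- nrow(d)
  if (!exact && n_perm < 99) stopf("n_perm must be >= 99")

  G <- gower_center(unclass(d))
  ss_total <- sum(diag(G))
  if (ss_total < 1e-12) {
    out <- data.frame(term = c(terms, "Residual", "Total"), df = NA, SS = 0,
                      pseudo_F = NA, p_perm = NA, p_mc = NA, n_perm = 0)
    attr(out, "degenerate") <- TRUE
    class(out) <- c("permanova_result", "data.frame")
    return(out)
  }

  X <- build_design(md, terms)          # list: per-term column blocks
  # incremental orthonormal bases per term (sequential SS)
  ones <- matrix(1 / sqrt(n), n, 1)
  basis <- ones
  U <- vector("list", length(terms))
  df <- integer(length(terms))
  for (k in seq_along(terms)) {
    B <- resid_basis(X[[k]], basis)
    if (ncol(B) == 0)
      stopf("singular design: term '%s' is aliased with earlier terms",
            terms[k])
    U[[k]] <- B
    df[k] <- ncol(B)
    basis <- cbind(basis, B)
  }
  H_full <- tcrossprod(basis)
  df_res <- n - ncol(basis)
  if (df_res <= 0) stopf("residual degrees of freedom are 0")

  ss_term <- vapply(U, function(u) sum(crossprod(u, G) * t(u)), 0)
  ss_res <- ss_total - sum(ss_term)
  Fobs <- (ss_term / df) / (ss_res / df_res)

  perms <- make_perms(n, n_perm, seed, exact,
                      strata = if (!is.null(strata)) md[[strata]])
  m <- nrow(perms)

  p_perm <- p_mc <- rep(NA_real_, length(terms))
  I_n <- diag(n)
  for (k in seq_along(terms)) {
    # reduced model: intercept + all terms but k
    Br <- cbind(ones, resid_basis(do.call(cbind, X[-k]), ones))
    H_red <- tcrossprod(Br)
    R <- I_n - H_red
    Fstar <- numeric(m)
    for (b in seq_len(m)) {
      M <- H_red + R[perms[b, ], , drop = FALSE]
      Gs <- M %*% G %*% t(M)
      sst <- vapply(U, function(u) sum(crossprod(u, Gs) * t(u)), 0)
      ssr <- sum(diag(Gs)) - sum(sst)
      Fstar[b] <- (sst[k] / df[k]) / (ssr / df_res)
    }
    p_perm[k] <- (sum(Fstar >= Fobs[k] - 1e-12) + 1) / (m + 1)
    p_mc[k] <- mc_pvalue(Fstar, Fobs[k])
  }

  out <- data.frame(
    term = c(terms, "Residual", "Total"),
    df = c(df, df_res, n - 1),
    SS = c(ss_term, ss_res, ss_total),
    pseudo_F = c(Fobs, NA, NA),
    p_perm = c(p_perm, NA, NA),
    p_mc = c(p_mc, NA, NA),
    n_perm = c(rep(m, length(terms)), NA, NA),
    stringsAsFactors = FALSE
  )
  attr(out, "degenerate") <- FALSE
  class(out) <- c("permanova_result", "data.frame")
  out
}

# model-matrix column block for each term, in the caller's order
build_design <- function(md, terms) {
  vars <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  for (v in vars) {
    if (!v %in% names(md)) stopf("design variable '%s' not in metadata", v)
    md[[v]] <- base::factor(md[[v]])
    if (nlevels(md[[v]]) < 2)
      stopf("design variable '%s' has a single level", v)
  }
  f <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  mm <- stats::model.matrix(f, data = md)
  asg <- attr(mm, "assign")
  labs <- attr(stats::terms(f), "term.labels")
  lapply(seq_along(terms), function(k) {
    j <- which(asg == match(terms[k], labs))
    mm[, j, drop = FALSE]
  })
}

# orthonormal basis of the part of X orthogonal to `current` basis;
# rank decided relative to the scale of X itself, so columns aliased with
# `current` (residual ~ 1e-16) are dropped rather than kept as noise
resid_basis <- function(X, current) {
  if (is.null(X) || ncol(X) == 0) return(matrix(0, nrow(current), 0))
  R <- X - current %*% crossprod(current, X)
  s <- svd(R)
  keep <- s$d > 1e-8 * max(1, max(abs(X))) * sqrt(nrow(X))
  if (!any(keep)) return(matrix(0, nrow(X), 0))
  s$u[, keep, drop = FALSE]
}

# permutation index matrix: rows are permutations of 1..n
make_perms <- function(n, n_perm, seed, exact = FALSE, strata = NULL) {
  if (exact) {
    if (!is.null(strata)) stopf("exact enumeration not supported with strata")
    if (n > 8) stopf("exact enumeration limited to n <= 8")
    return(all_permutations(n))
  }
  with_seed(seed, {
    if (is.null(strata)) {
      t(replicate(n_perm, sample.int(n)))
    } else {
      s <- as.integer(base::factor(strata))
      t(replicate(n_perm, {
        ix <- seq_len(n)
        for (lev in unique(s)) {
          w <- which(s == lev)
          ix[w] <- w[sample.int(length(w))]
        }
        ix
      }))
    }
  })
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0
  for (pos in seq_len(n)) {
    blk <- matrix(0L, nrow(sub), n)
    blk[, pos] <- n
    blk[, -pos] <- sub
    out[r + seq_len(nrow(sub)), ] <- blk
    r <- r + nrow(sub)
  }
  out
}

# Monte Carlo p: shifted-gamma (Pearson III) matched to the permutation null's
# mean/variance/skewness; normal fallback for non-positive skewness.
mc_pvalue <- function(null, obs) {
  mu <- mean(null); v <- var(null)
  if (!is.finite(v) || v <= 0) return(NA_real_)
  g1 <- mean((null - mu)^3) / v^1.5
  if (is.finite(g1) && g1 > 0.05) {
    shape <- 4 / g1^2
    scale <- sqrt(v / shape)
    shift <- mu - shape * scale
    stats::pgamma(obs - shift, shape = shape, scale = scale,
                  lower.tail = FALSE)
  } else {
    stats::pnorm(obs, mean = mu, sd = sqrt(v), lower.tail = FALSE)
  }
}

#' @export
print.permanova_result <- function(x, ...) {
  cat("PERMANOVA (sequential SS, residual permutation under reduced model)\n")
  if (isTRUE(attr(x, "degenerate"))) cat("  ** degenerate: SS_total = 0 **\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' One-factor PERMANOVA within a stratum
#'
#' Tests a single factor on the sub-matrix of samples belonging to one
#' stratum (e.g. the forage effect at 2 h post-feeding).
#'
#' @param d `dist_matrix`; `metadata` as in [permanova()].
#' @param metadata sample metadata.
#' @param factor design column to test.
#' @param stratum either NULL (whole data set) or `list(column =, value =)`.
#' @param ... passed to [permanova()].
#' @return a `permanova_result`.
#' @export
stratum_effect <- function(d, metadata, factor, stratum = NULL, ...) {
  md <- metadata[match(rownames(d), metadata$sample_id), , drop = FALSE]
  keep <- rep(TRUE, nrow(md))
  if (!is.null(stratum)) keep <- md[[stratum$column]] == stratum$value
  if (length(unique(md[[factor]][keep])) < 2)
    stopf("stratum has < 2 levels of '%s'", factor)
  ids <- md$sample_id[keep]
  permanova(dist_matrix(unclass(d)[ids, ids],
                        metric = attr(d, "metric")),
            md[keep, , drop = FALSE], terms = factor, ...)
}
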