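# shared fixtures and independent oracles

# small deterministic count table with named samples/taxa
toy_counts <- function(m, samples = NULL, taxa = NULL) {
  m <- as.matrix(m)
  rownames(m) <- samples %||% paste0("S", seq_len(nrow(m)))
  colnames(m) <- taxa %||% paste0("t", seq_len(ncol(m)))
  count_table(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a tiny simulation config that keeps tests fast
tiny_config <- function(...) {
  sim_config(n_taxa = 20, depth_range = c(800, 1200),
             time_points_h = c(0, 2, 8), ...)
}

# metadata frame for d simple two-group design
two_group_md <- function(n_per = 3, values = NULL) {
  data.frame(sample_id = paste0("S", seq_len(2 * n_per)),
             grp = rep(c("A", "B"), each = n_per),
             stringsAsFactors = FALSE)
}

# Euclidean dist_matrix from a numeric matrix (rows = samples)
euclid_d <- function(X) {
  rownames(X) <- rownames(X) %||% paste0("S", seq_len(nrow(X)))
  dist_matrix(as.matrix(dist(X)), metric = "euclidean")
}

# classical one-way ANOVA F (closed-form oracle)
anova_F <- function(y, g) {
  g <- factor(g)
  mg <- tapply(y, g, mean)
  ng <- tabulate(g)
  ssb <- sum(ng * (mg - mean(y))^2)
  ssw <- sum((y - mg[g])^2)
  (ssb / (nlevels(g) - 1)) / (ssw / (length(y) - nlevels(g)))
}

# brute-force BH step-up (independent of adjust_bh's cummin formulation)
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- p[o][i:m] * m / (i:m)
    q[o[i]] <- min(1, min(cand))
  }
  q
}

# Newman-Girvan modularity of a partition on an unweighted undirected graph
modularity_of <- function(edges, membership) {
  m <- nrow(edges)
  if (m == 0) return(0)
  deg <- table(factor(c(edges$a, edges$b), levels = names(membership)))
  q <- 0
  for (ci in unique(membership)) {
    nodes <- names(membership)[membership == ci]
    e_in <- sum(edges$a %in% nodes & edges$b %in% nodes)
    d_in <- sum(deg[nodes])
    q <- q + e_in / m - (d_in / (2 * m))^2
  }
  q
}

# exhaustive max-modularity partition over ALL set partitions (n <= 8)
all_set_partitions <- function(items) {
  if (length(items) == 1) return(list(list(items)))
  rest <- all_set_partitions(items[-1])
  out <- list()
  for (p in rest) {
    for (k in seq_along(p)) {
      q <- p
      q[[k]] <- c(items[1], q[[k]])
      out[[length(out) + 1]] <- q
    }
    out[[length(out) + 1]] <- c(list(items[1]), p)
  }
  out
}

best_modularity <- function(edges, nodes) {
  parts <- all_set_partitions(nodes)
  best <- -Inf
  for (p in parts) {
    mem <- setNames(rep(seq_along(p), lengths(p)), unlist(p))[nodes]
    q <- modularity_of(edges, mem)
    if (q > best) best <- q
  }
  best
}

# Procrustes residual after optimal rotation/reflection + translation
procrustes_error <- function(A, B) {
  A <- scale(A, scale = FALSE); B <- scale(B, scale = FALSE)
  s <- svd(crossprod(B, A))
  R <- s$u %*% t(s$v)
  # allow a global scale (distances recovered up to none; scale should be 1)
  sqrt(sum((B %*% R - A)^2) / sum(A^2))
}

# membership vectors equal up to relabelling?
same_partition <- function(m1, m2) {
  m1 <- m1[sort(names(m1))]; m2 <- m2[sort(names(m2))]
  length(m1) == length(m2) &&
    all(outer(m1, m1, "==") == outer(m2, m2, "=="))
}
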