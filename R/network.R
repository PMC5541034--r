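# cache of exact Spearman null distributions, one entry per sample size
.spearman_cache <- new.env(parent = emptyenv())

#' Exact two-sided Spearman p-value
#'
#' For tie-free samples of size n <= 10, the p-value is computed from the
#' full permutation distribution of the rank statistic (n! enumerated once
#' per n and cached); otherwise the t approximation
#' t = rho sqrt((n-2)/(1-rho^2)) is used.
#'
#' @param rho observed Spearman correlation.
#' @param n sample size.
#' @param exact use the enumeration when possible (default TRUE).
#' @return two-sided p-value.
#' @export
spearman_pvalue <- function(rho, n, exact = TRUE) {
  if (exact && n >= 2 && n <= 10) {
    key <- as.character(n)
    if (is.null(.spearman_cache[[key]]))
      .spearman_cache[[key]] <- spearman_null_counts(n)
    counts <- .spearman_cache[[key]]
    d <- seq_along(counts) - 1
    rho_null <- 1 - 6 * d / (n * (n^2 - 1))
    sum(counts[abs(rho_null) >= abs(rho) - 1e-12]) / sum(counts)
  } else {
    if (abs(rho) >= 1) return(2 / gamma(n + 1))   # beyond-t floor
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(t), df = n - 2)
  }
}

#' Prevalence filter for network construction
#'
#' Keeps taxa detected (count > 0) in strictly more than `min_prevalence` of
#' the stratum's samples — the "present in more than 75\% of the samples"
#' rule, read strictly: 6/8 = 75\% is excluded, 7/8 is kept.
#'
#' @param table a `count_table`.
#' @param samples optional sample ids defining the stratum (default: all).
#' @param min_prevalence proportion in (0,1), default 0.75.
#' @return filtered `count_table` restricted to the stratum samples; empty
#'   result gives a warning and a zero-column table.
#' @export
filter_prevalence <- function(table, samples = NULL, min_prevalence = 0.75) {
  if (min_prevalence <= 0 || min_prevalence >= 1)
    stopf("min_prevalence must be in (0,1)")
  if (is.null(samples)) samples <- rownames(table)
  if (!length(samples)) stopf("empty stratum")
  x <- unclass(table)[samples, , drop = FALSE]
  prev <- colMeans(x > 0)
  keep <- prev > min_prevalence
  if (!any(keep)) warnf("prevalence filter removed every taxon")
  structure(x[, keep, drop = FALSE], rank = attr(table, "rank"),
            class = c("count_table", "matrix", "array"))
}

#' Spearman co-occurrence edges
#'
#' All genus pairs are correlated on ranks of log10(relative abundance +
#' pseudocount) — the ranks make the monotone log transform a no-op
#' safeguard. Two-sided p-values use the exact permutation distribution for
#' n <= 10 without ties, else the t approximation; BH adjustment is applied
#' across all pairs of the stratum. Edges with |rho| > `rho_threshold` and
#' q < `alpha` are retained, with sign.
#'
#' @param table stratum `count_table` with >= 5 samples.
#' @param rho_threshold retain |rho| strictly greater (default 0.7).
#' @param alpha FDR level on adjusted p (default 0.05).
#' @param pseudocount added to relative abundances before log (default 1e-6).
#' @return data.frame: a, b, rho, p, q, sign; attribute `skipped` lists
#'   constant genera whose pairs were not tested.
#' @export
infer_edges <- function(table, rho_threshold = 0.7, alpha = 0.05,
                        pseudocount = 1e-6) {
  x <- unclass(table)
  if (nrow(x) < 5) stopf("infer_edges needs >= 5 samples (got %d)", nrow(x))
  tot <- rowSums(x)
  if (any(tot == 0)) stopf("all-zero sample in stratum")
  y <- log10(x / tot + pseudocount)
  keep <- apply(y, 2, function(v) var(v) > 1e-24)
  skipped <- colnames(y)[!keep]
  if (length(skipped))
    message("infer_edges: skipping constant genera: ",
            paste(skipped, collapse = ", "))
  y <- y[, keep, drop = FALSE]
  p <- ncol(y)
  empty <- data.frame(a = character(), b = character(), rho = numeric(),
                      p = numeric(), q = numeric(), sign = character(),
                      stringsAsFactors = FALSE)
  if (p < 2) return(structure(empty, skipped = skipped))

  rk <- apply(y, 2, rank)                       # ties averaged
  tied <- apply(y, 2, function(v) anyDuplicated(v) > 0)
  n <- nrow(y)
  rho_m <- suppressWarnings(stats::cor(rk))
  prs <- utils::combn(p, 2)
  res <- data.frame(
    a = colnames(y)[prs[1, ]], b = colnames(y)[prs[2, ]],
    rho = rho_m[t(prs)], stringsAsFactors = FALSE)
  res$p <- vapply(seq_len(ncol(prs)), function(k) {
    i <- prs[1, k]; j <- prs[2, k]
    spearman_pvalue(res$rho[k], n, exact = !(tied[i] || tied[j]))
  }, 0)
  res$q <- adjust_bh(res$p)
  res <- res[abs(res$rho) > rho_threshold & res$q < alpha, , drop = FALSE]
  res$sign <- ifelse(res$rho >= 0, "+", "-")
  res <- res[order(res$a, res$b), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, skipped = skipped)
}

#' Assemble a co-occurrence network for one stratum
#'
#' Applies the prevalence filter, infers signed Spearman edges, detects
#' edge-betweenness communities, and computes the complexity metrics.
#'
#' @param table `count_table` of the whole experiment (or stratum).
#' @param samples stratum sample ids (default: all samples of `table`).
#' @param stratum label for the stratum (e.g. "GRA.T8").
#' @param min_prevalence,rho_threshold,alpha,pseudocount see
#'   [filter_prevalence()] and [infer_edges()].
#' @return object of class `co_network`: stratum, nodes (genus + mean
#'   relative abundance over the stratum), edges, communities (membership),
#'   metrics.
#' @export
co_network <- function(table, samples = NULL, stratum = "all",
                       min_prevalence = 0.75, rho_threshold = 0.7,
                       alpha = 0.05, pseudocount = 1e-6) {
  if (is.null(samples)) samples <- rownames(table)
  sub <- unclass(table)[samples, , drop = FALSE]
  rel <- sub / rowSums(sub)
  filt <- filter_prevalence(table, samples, min_prevalence)
  edges <- infer_edges(filt, rho_threshold, alpha, pseudocount)
  node_ids <- sort(unique(c(edges$a, edges$b)))
  nodes <- data.frame(genus = node_ids,
                      mean_rel_abund = colMeans(rel)[node_ids],
                      row.names = NULL, stringsAsFactors = FALSE)
  net <- structure(list(stratum = stratum, nodes = nodes, edges = edges,
                        communities = NULL, metrics = NULL),
                   class = "co_network")
  net$communities <- detect_communities(net)
  net$metrics <- network_metrics(net, table[samples, , drop = FALSE])
  net
}

#' Edge-betweenness (Girvan-Newman) communities
#'
#' Iteratively removes the edge of highest betweenness and returns the
#' partition of maximum modularity along the removal sequence (igraph's
#' `cluster_edge_betweenness` on the unweighted graph, edges in lexicographic
#' order for a deterministic tie-break). Isolated nodes form singleton
#' communities.
#'
#' @param network a `co_network` (or list with `nodes`/`edges`).
#' @return named integer membership vector, one entry per node.
#' @export
detect_communities <- function(network) {
  nodes <- network$nodes$genus
  if (!length(nodes)) return(setNames(integer(0), character(0)))
  e <- network$edges[order(network$edges$a, network$edges$b), , drop = FALSE]
  g <- igraph::graph_from_data_frame(e[, c("a", "b")], directed = FALSE,
                                     vertices = data.frame(name = nodes))
  if (igraph::ecount(g) == 0)
    return(setNames(seq_along(nodes), nodes))
  cl <- igraph::cluster_edge_betweenness(g, weights = NULL, directed = FALSE)
  setNames(as.integer(igraph::membership(cl)),
           names(igraph::membership(cl)))
}

#' Network complexity metrics
#'
#' The four descriptors of network complexity: number of nodes (genera),
#' number of edges split by sign, average number of neighbors (mean degree
#' = 2E/N), and the percentage of the total community accounted for by the
#' network's genera (summed mean relative abundance).
#'
#' @param network a `co_network`.
#' @param table the stratum's `count_table` (full community, for coverage).
#' @return list: n_nodes, n_edges, n_pos_edges, n_neg_edges,
#'   pct_negative_edges, avg_neighbors, community_coverage_pct.
#' @export
network_metrics <- function(network, table) {
  ne <- nrow(network$edges)
  nn <- nrow(network$nodes)
  npos <- sum(network$edges$sign == "+")
  rel <- unclass(table) / rowSums(unclass(table))
  cov <- if (nn) 100 * sum(colMeans(rel)[network$nodes$genus]) else 0
  list(n_nodes = nn, n_edges = ne, n_pos_edges = npos,
       n_neg_edges = ne - npos,
       pct_negative_edges = if (ne) 100 * (ne - npos) / ne else 0,
       avg_neighbors = if (nn) 2 * ne / nn else 0,
       community_coverage_pct = cov)
}

#' @export
print.co_network <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "co_network [%s]: %d nodes, %d edges (%d+/%d-), avg neighbors %.2f, coverage %.1f%%\n",
    x$stratum, m$n_nodes, m$n_edges, m$n_pos_edges, m$n_neg_edges,
    m$avg_neighbors, m$community_coverage_pct))
  invisible(x)
}

#' Network complexity over time
#'
#' Builds one co-occurrence network per (group x time) stratum and collects
#' the complexity metrics into a tidy long table. Default strata pool
#' vitamin E levels within forage so each time point has n = 8 samples.
#'
#' @param table `count_table` of the experiment.
#' @param metadata sample metadata with `sample_id`, `time_h` and the
#'   grouping column.
#' @param group_by metadata column defining groups (default "forage").
#' @param min_n minimum samples per stratum; smaller strata are skipped with
#'   a warning (default 5, the edge-inference floor).
#' @param ... passed to [co_network()].
#' @return list with `metrics` (data.frame: group, time_h, n_samples +
#'   metric columns) and `networks` (named list of `co_network`s).
#' @export
network_trajectory <- function(table, metadata, group_by = "forage",
                               min_n = 5, ...) {
  md <- metadata[match(rownames(table), metadata$sample_id), , drop = FALSE]
  combos <- unique(md[, c(group_by, "time_h")])
  combos <- combos[order(combos[[group_by]], combos$time_h), , drop = FALSE]
  nets <- list()
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    grp <- combos[[group_by]][i]; tt <- combos$time_h[i]
    ids <- md$sample_id[md[[group_by]] == grp & md$time_h == tt]
    lab <- sprintf("%s.T%02d", grp, as.integer(tt))
    if (length(ids) < min_n) {
      warnf("stratum %s has %d samples (< %d); skipped", lab, length(ids), min_n)
      next
    }
    nt <- co_network(table, samples = ids, stratum = lab, ...)
    nets[[lab]] <- nt
    rows[[lab]] <- data.frame(group = grp, time_h = tt,
                              n_samples = length(ids),
                              as.data.frame(nt$metrics),
                              stringsAsFactors = FALSE)
  }
  metrics <- do.call(rbind, rows)
  if (!is.null(metrics)) rownames(metrics) <- NULL
  list(metrics = metrics, networks = nets)
}
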