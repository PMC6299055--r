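#' Node-level social network metrics
#'
#' Computes, for every individual in a weighted association network:
#' mean index, strength (`s_i = sum_j a_ij`), eigenvector centrality
#' (leading eigenvector by power iteration, unit Euclidean norm,
#' non-negative), reach (`sum_j a_ij * s_j`), affinity (`reach/strength`,
#' the strength-weighted mean strength of associates), the weighted
#' clustering coefficient
#' `C_i = sum_{j!=k} a_ij a_jk a_ki / (max(a) * sum_{j!=k} a_ij a_ik)`,
#' and betweenness and closeness on the graph whose edge lengths are
#' `1/a_ij` over positive associations. Closeness is scaled as
#' `100 * (n_comp - 1) / sum_j dist(i, j)` within an individual's
#' connected component; disconnected networks are flagged.
#'
#' @param m An `assoc_matrix`.
#' @return A `metrics_table` data frame, one row per individual, with
#'   columns `individual_id`, `mean_index`, `strength`,
#'   `eigenvector_centrality`, `reach`, `affinity`,
#'   `clustering_coefficient`, `betweenness`, `closeness`, `component`.
#' @export
node_metrics <- function(m) {
  stopifnot(inherits(m, "assoc_matrix"))
  a <- unclass(m)
  n <- nrow(a)
  if (n < 2) stop("need at least 2 individuals", call. = FALSE)
  ids <- attr(m, "ids")
  s <- rowSums(a)
  reach <- as.vector(a %*% s)
  affinity <- ifelse(s > 0, reach / s, NA_real_)

  ec <- power_eigenvector(a)

  amax <- max(a)
  num <- diag(a %*% a %*% a)
  den <- amax * (s^2 - rowSums(a^2))
  cc <- ifelse(den > 0, num / den, 0)

  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  wl <- 1 / igraph::E(g)$weight
  btw <- igraph::betweenness(g, weights = wl, directed = FALSE)
  dm <- igraph::distances(g, weights = wl)
  comp <- igraph::components(g)$membership
  clo <- vapply(seq_len(n), function(i) {
    peers <- which(comp == comp[i] & seq_len(n) != i)
    if (!length(peers)) return(NA_real_)
    100 * length(peers) / sum(dm[i, peers])
  }, 1.0)
  if (max(comp) > 1) {
    warning("association network is disconnected; closeness computed ",
            "within components")
  }

  out <- data.frame(individual_id = ids,
                    mean_index = s / (n - 1),
                    strength = s,
                    eigenvector_centrality = ec,
                    reach = reach,
                    affinity = affinity,
                    clustering_coefficient = cc,
                    betweenness = as.numeric(btw),
                    closeness = clo,
                    component = as.integer(comp),
                    row.names = NULL)
  class(out) <- c("metrics_table", "data.frame")
  out
}

# leading eigenvector of a non-negative symmetric matrix by power
# iteration; unit Euclidean norm, non-negative orientation
power_eigenvector <- function(a, tol = 1e-12, max_iter = 10000) {
  n <- nrow(a)
  v <- rep(1 / sqrt(n), n)
  for (i in seq_len(max_iter)) {
    w <- as.vector(a %*% v)
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(v)
    w <- w / nw
    if (sum(abs(w - v)) < tol) { v <- w; break }
    v <- w
  }
  if (sum(v) < 0) v <- -v
  pmax(v, 0)
}

#' Per-cluster and overall summary of node metrics
#'
#' Means and standard deviations of each network metric per cluster plus
#' an overall column, the usual per-cluster metrics table of social
#' network studies.
#'
#' @param t A `metrics_table` from [node_metrics()].
#' @param labels Named vector mapping individual id to cluster.
#' @return A data frame with one row per metric and columns
#'   `mean_<cluster>`, `sd_<cluster>`, `mean_overall`, `sd_overall`.
#' @export
cluster_summary <- function(t, labels) {
  stopifnot(inherits(t, "metrics_table"))
  lab <- align_labels(labels, t$individual_id)
  metrics <- c("mean_index", "strength", "eigenvector_centrality", "reach",
               "affinity", "clustering_coefficient", "betweenness",
               "closeness")
  cls <- sort(unique(lab))
  if (any(table(lab) == 0)) stop("empty cluster", call. = FALSE)
  out <- data.frame(metric = metrics)
  for (cl in cls) {
    idx <- lab == cl
    out[[paste0("mean_", cl)]] <- vapply(metrics, function(mm)
      mean(t[[mm]][idx], na.rm = TRUE), 1.0)
    out[[paste0("sd_", cl)]] <- vapply(metrics, function(mm)
      stats::sd(t[[mm]][idx], na.rm = TRUE), 1.0)
  }
  out$mean_overall <- vapply(metrics, function(mm)
    mean(t[[mm]], na.rm = TRUE), 1.0)
  out$sd_overall <- vapply(metrics, function(mm)
    stats::sd(t[[mm]], na.rm = TRUE), 1.0)
  rownames(out) <- NULL
  out
}

#' Export the association network as GraphML
#'
#' Writes the weighted association network with all node metrics as
#' vertex attributes. Optionally also writes an edge-filtered variant
#' keeping only associations greater than twice the mean index, the
#' conventional "meaningful associations" display.
#'
#' @param m An `assoc_matrix`.
#' @param path Output GraphML path.
#' @param labels Optional cluster labels, stored as a vertex attribute.
#' @param filtered_path Optional path for the `> 2 * mean` filtered
#'   network.
#' @return Invisibly, the paths written.
#' @export
write_graphml <- function(m, path, labels = NULL, filtered_path = NULL) {
  stopifnot(inherits(m, "assoc_matrix"))
  a <- unclass(m)
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  t <- node_metrics(m)
  for (col in setdiff(names(t), "individual_id")) {
    g <- igraph::set_vertex_attr(g, col, value = t[[col]])
  }
  if (!is.null(labels)) {
    lab <- align_labels(labels, attr(m, "ids"))
    g <- igraph::set_vertex_attr(g, "cluster", value = lab)
  }
  igraph::write_graph(g, path, format = "graphml")
  written <- path
  if (!is.null(filtered_path)) {
    thr <- 2 * mean(a[upper.tri(a)])
    gf <- igraph::delete_edges(g, igraph::E(g)[igraph::E(g)$weight <= thr])
    igraph::write_graph(gf, filtered_path, format = "graphml")
    written <- c(written, filtered_path)
  }
  invisible(written)
}
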