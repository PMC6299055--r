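#' Average-linkage hierarchical clustering of an association matrix
#'
#' Agglomerative average-linkage clustering on the dissimilarity
#' `1 - index`, with merge heights reported back on the association-index
#' scale. The cophenetic correlation coefficient (CCC) -- the Pearson
#' correlation between the input indices and the dendrogram-implied
#' (cophenetic) indices -- measures how faithfully the tree represents
#' the association structure; values near 1 support a hierarchical
#' reading.
#'
#' @param m An `assoc_matrix`.
#' @return An object of class `assoc_dendrogram`: the underlying
#'   [stats::hclust] tree (`hclust`), `merge_index` (merge heights on the
#'   index scale, non-increasing), and `ccc`.
#' @export
average_linkage <- function(m) {
  stopifnot(inherits(m, "assoc_matrix"))
  if (nrow(m) < 2) stop("need at least 2 individuals", call. = FALSE)
  d <- stats::as.dist(1 - unclass(m))
  hc <- stats::hclust(d, method = "average")
  coph <- stats::cophenetic(hc)
  ccc <- stats::cor(as.vector(d), as.vector(coph))
  structure(list(hclust = hc, merge_index = 1 - hc$height, ccc = ccc,
                 ids = attr(m, "ids")),
            class = "assoc_dendrogram")
}

#' @export
print.assoc_dendrogram <- function(x, ...) {
  cat("Average-linkage dendrogram:", length(x$ids), "individuals, CCC =",
      formatC(x$ccc, digits = 3, format = "f"), "\n")
  invisible(x)
}

#' @export
plot.assoc_dendrogram <- function(x, cut_index = NULL, ...) {
  graphics::plot(stats::as.dendrogram(x$hclust), horiz = TRUE,
                 xlab = "1 - association index", ...)
  if (!is.null(cut_index)) graphics::abline(v = 1 - cut_index, lty = 3)
  invisible(x)
}

#' Export a dendrogram as Newick
#'
#' Branch lengths are on the `1 - index` (dissimilarity) scale.
#'
#' @param d An `assoc_dendrogram`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(d, path) {
  stopifnot(inherits(d, "assoc_dendrogram"))
  ape::write.tree(ape::as.phylo(d$hclust), file = path)
  invisible(path)
}

#' Weighted Newman modularity of a partition
#'
#' `Q = sum_c [W_c/T - (S_c/(2T))^2]`, where `W_c` is the summed
#' association within cluster c, `S_c` the summed strength of its
#' members and `T` the total association. The default null (`"strength"`)
#' is Newman's configuration expectation `s_i*s_j/(2T)`; because the
#' expectation is a normalised row-strength product this is also the
#' gregariousness-corrected modularity used on association indices
#' ("modularity-G"). `null = "uniform"` instead uses a constant expected
#' association (the overall mean). Values above about 0.3 conventionally
#' indicate a meaningful division.
#'
#' @param m An `assoc_matrix`.
#' @param labels Named vector mapping individual id to cluster label, or
#'   a vector in matrix order.
#' @param null `"strength"` (default) or `"uniform"`.
#' @return Numeric Q (at most 1).
#' @export
modularity_q <- function(m, labels, null = c("strength", "uniform")) {
  stopifnot(inherits(m, "assoc_matrix"))
  null <- match.arg(null)
  lab <- align_labels(labels, attr(m, "ids"))
  a <- unclass(m)
  total <- sum(a) / 2
  if (total <= 0) stop("association matrix has zero total weight",
                       call. = FALSE)
  s <- rowSums(a)
  q <- 0
  for (cl in unique(lab)) {
    idx <- which(lab == cl)
    w_c <- sum(a[idx, idx]) / 2
    if (null == "strength") {
      q <- q + w_c / total - (sum(s[idx]) / (2 * total))^2
    } else {
      n <- nrow(a)
      ebar <- 2 * total / (n * (n - 1))
      k <- length(idx)
      q <- q + (w_c - ebar * k * (k - 1) / 2) / total
    }
  }
  q
}

align_labels <- function(labels, ids) {
  if (!is.null(names(labels))) {
    lab <- labels[ids]
    if (anyNA(lab)) stop("labels missing for: ",
                         paste(ids[is.na(lab)], collapse = ", "),
                         call. = FALSE)
  } else {
    if (length(labels) != length(ids)) {
      stop("labels must be named or match matrix order", call. = FALSE)
    }
    lab <- labels
  }
  as.character(lab)
}

# leading eigenvector of the generalized modularity matrix restricted to
# a vertex subset (Newman's B^(g))
modularity_submatrix <- function(a, s, total, idx) {
  b <- a[idx, idx, drop = FALSE] - outer(s[idx], s[idx]) / (2 * total)
  # B^(g): subtract each row's total over the subgroup from the diagonal
  diag(b) <- diag(b) - (rowSums(a[idx, idx, drop = FALSE]) -
                          s[idx] * sum(s[idx]) / (2 * total))
  (b + t(b)) / 2
}

#' Social cluster delineation by Newman's eigenvector method
#'
#' Recursive spectral bisection of the weighted modularity matrix
#' `B = A - s s'/(2T)`: each candidate community is split by the sign of
#' the leading eigenvector of the generalized modularity matrix, the
#' split is fine-tuned by greedy single-node moves (Kernighan-Lin style),
#' and splitting stops when no division increases Q.
#'
#' @param m An `assoc_matrix`.
#' @return An object of class `cluster_assignment` with elements
#'   `labels` (named cluster ids), `modularity_q`, `method`
#'   (`"eigenvector"`), and `gregariousness_corrected = TRUE` (the
#'   strength-based null).
#' @export
eigenvector_communities <- function(m) {
  stopifnot(inherits(m, "assoc_matrix"))
  ids <- attr(m, "ids")
  a <- unclass(m)
  n <- nrow(a)
  total <- sum(a) / 2
  if (total <= 0) stop("association matrix has zero total weight",
                       call. = FALSE)
  s <- rowSums(a)

  groups <- list(seq_len(n))
  final <- list()
  while (length(groups)) {
    idx <- groups[[1]]
    groups <- groups[-1]
    if (length(idx) < 2) { final <- c(final, list(idx)); next }
    b <- modularity_submatrix(a, s, total, idx)
    ev <- eigen(b, symmetric = TRUE)
    lead <- ev$vectors[, 1]
    side <- lead >= 0
    if (all(side) || !any(side)) {
      # spectrally indivisible: still give the KL sweep a chance from
      # the single most favourable exclusion
      gains <- 4 * diag(b) - 4 * rowSums(b)
      side <- rep(TRUE, length(idx))
      side[which.max(gains)] <- FALSE
    }
    side <- finetune_split(b, side)
    dq <- split_delta_q(b, side, total)
    if (dq <= 1e-12 || all(side) || !any(side)) {
      final <- c(final, list(idx))
    } else {
      groups <- c(groups, list(idx[side]), list(idx[!side]))
    }
  }
  lab <- integer(n)
  for (i in seq_along(final)) lab[final[[i]]] <- i
  labels <- stats::setNames(as.character(lab), ids)
  structure(list(labels = labels,
                 modularity_q = modularity_q(m, labels),
                 method = "eigenvector",
                 cut_index = NA_real_,
                 modularity_curve = NULL,
                 gregariousness_corrected = TRUE),
            class = "cluster_assignment")
}

# contribution of a bisection (s in {+1,-1}) to Q: (1/4T) s' B s
split_delta_q <- function(b, side, total) {
  sv <- ifelse(side, 1, -1)
  as.numeric(sv %*% b %*% sv) / (4 * total)
}

# Kernighan-Lin style sweep (Newman's fine-tuning): each round moves
# every vertex exactly once, always taking the currently best move even
# if it lowers the objective, then reverts to the best state seen in the
# round; rounds repeat until no net improvement. Flipping vertex i
# changes s'Bs by -4*s_i*(Bs)_i + 4*B_ii, which is updated incrementally.
finetune_split <- function(b, side) {
  n <- length(side)
  sv <- ifelse(side, 1, -1)
  val <- as.numeric(sv %*% b %*% sv)
  repeat {
    bs <- as.vector(b %*% sv)
    free <- rep(TRUE, n)
    seq_vals <- numeric(n)
    seq_moves <- integer(n)
    cur_sv <- sv; cur_val <- val; cur_bs <- bs
    for (step in seq_len(n)) {
      gains <- -4 * cur_sv * cur_bs + 4 * diag(b)
      gains[!free] <- -Inf
      i <- which.max(gains)
      cur_val <- cur_val + gains[i]
      cur_bs <- cur_bs - 2 * cur_sv[i] * b[, i]
      cur_sv[i] <- -cur_sv[i]
      free[i] <- FALSE
      seq_vals[step] <- cur_val
      seq_moves[step] <- i
    }
    k <- which.max(seq_vals)
    if (seq_vals[k] > val + 1e-12) {
      flip <- seq_moves[seq_len(k)]
      sv[flip] <- -sv[flip]
      val <- as.numeric(sv %*% b %*% sv)
    } else {
      break
    }
  }
  sv > 0
}

#' Best dendrogram cut by modularity
#'
#' Evaluates every candidate cut of an average-linkage dendrogram (the
#' midpoints between consecutive merge heights on the association-index
#' scale), computes the modularity of each induced partition, and
#' returns the cut maximising Q (ties broken towards fewer clusters).
#' Singleton clusters are reported as their own cluster together with a
#' nearest-cluster suggestion by mean index (never silently reassigned).
#'
#' @param d An `assoc_dendrogram`.
#' @param m The `assoc_matrix` it was built from.
#' @param null Modularity null, see [modularity_q()].
#' @return A `cluster_assignment` with `method = "dendrogram_cut"`,
#'   `cut_index` (the association-index threshold), the full
#'   `modularity_curve` (threshold, Q) and, if singletons exist, an
#'   attribute `singleton_suggestions`.
#' @export
best_dendrogram_cut <- function(d, m, null = "strength") {
  stopifnot(inherits(d, "assoc_dendrogram"), inherits(m, "assoc_matrix"))
  h_index <- sort(unique(d$merge_index), decreasing = TRUE)
  cand <- (h_index[-1] + h_index[-length(h_index)]) / 2
  # also consider cutting below all merges (single cluster) and above all
  cand <- unique(c(max(h_index) + (1 - max(h_index)) / 2, cand,
                   min(h_index) / 2))
  ids <- d$ids
  curve <- data.frame(threshold = cand, q = NA_real_, k = NA_integer_)
  best <- NULL
  for (i in seq_along(cand)) {
    lab <- stats::cutree(d$hclust, h = 1 - cand[i])
    labels <- stats::setNames(as.character(lab), ids)
    q <- modularity_q(m, labels, null = null)
    curve$q[i] <- q
    curve$k[i] <- length(unique(lab))
    if (is.null(best) || q > best$q + 1e-12 ||
        (abs(q - best$q) <= 1e-12 && curve$k[i] < best$k)) {
      best <- list(q = q, k = curve$k[i], labels = labels,
                   threshold = cand[i])
    }
  }
  out <- structure(list(labels = best$labels,
                        modularity_q = best$q,
                        method = "dendrogram_cut",
                        cut_index = best$threshold,
                        modularity_curve = curve,
                        gregariousness_corrected = (null == "strength")),
                   class = "cluster_assignment")
  sizes <- table(best$labels)
  singles <- names(sizes)[sizes == 1]
  if (length(singles)) {
    sugg <- lapply(singles, function(cl) {
      id <- names(best$labels)[best$labels == cl]
      others <- setdiff(unique(best$labels), cl)
      mi <- vapply(others, function(o) {
        mean(unclass(m)[id, names(best$labels)[best$labels == o]])
      }, 1.0)
      list(id = id, nearest_cluster = others[which.max(mi)],
           mean_index = max(mi))
    })
    names(sugg) <- singles
    attr(out, "singleton_suggestions") <- sugg
  }
  out
}

#' @export
print.cluster_assignment <- function(x, ...) {
  sizes <- sort(table(x$labels), decreasing = TRUE)
  cat("Cluster assignment (", x$method, "): ", length(sizes),
      " clusters of sizes ", paste(sizes, collapse = "/"), "\n", sep = "")
  cat(sprintf("  modularity Q = %.4f%s\n", x$modularity_q,
              if (isTRUE(x$gregariousness_corrected))
                " (strength/gregariousness null)" else " (uniform null)"))
  if (is.finite(x$cut_index)) {
    cat(sprintf("  cut at association index %.4f\n", x$cut_index))
  }
  sugg <- attr(x, "singleton_suggestions")
  if (!is.null(sugg)) {
    for (s in sugg) {
      cat(sprintf("  singleton %s: nearest cluster %s (mean index %.4f)\n",
                  s$id, s$nearest_cluster, s$mean_index))
    }
  }
  invisible(x)
}

#' Write cluster labels and a modularity curve to CSV
#'
#' @param x A `cluster_assignment`.
#' @param labels_csv Path for the per-individual labels CSV.
#' @param curve_csv Optional path for the (threshold, Q) modularity curve.
#' @return Invisibly, the paths written.
#' @export
write_clusters <- function(x, labels_csv, curve_csv = NULL) {
  stopifnot(inherits(x, "cluster_assignment"))
  utils::write.csv(data.frame(individual_id = names(x$labels),
                              cluster = unname(x$labels)),
                   labels_csv, row.names = FALSE)
  written <- labels_csv
  if (!is.null(curve_csv) && !is.null(x$modularity_curve)) {
    utils::write.csv(x$modularity_curve, curve_csv, row.names = FALSE)
    written <- c(written, curve_csv)
  }
  invisible(written)
}
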