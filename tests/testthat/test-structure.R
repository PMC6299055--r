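test_that("average linkage agglomerates a hand case and flags fit", {
  m <- am_make(matrix(c(0, 0.9, 0.1,
                        0.9, 0, 0.1,
                        0.1, 0.1, 0), 3, 3, byrow = TRUE,
                      dimnames = list(c("A", "B", "C"),
                                      c("A", "B", "C"))))
  d <- average_linkage(m)
  expect_equal(sort(d$merge_index, decreasing = TRUE), c(0.9, 0.1))
  # this input is exactly ultrametric -> CCC = 1
  expect_equal(d$ccc, 1, tolerance = 1e-12)
})

test_that("CCC matches an independent path-through-tree oracle", {
  set.seed(13)
  m <- am_random(9, blocks = c(5, 4))
  d <- average_linkage(m)
  hc <- d$hclust
  n <- nrow(m)
  # oracle: cophenetic distance = merge height of the smallest tree node
  # containing both leaves, found by walking the merge table
  members <- list()
  coph <- matrix(0, n, n)
  for (k in seq_len(nrow(hc$merge))) {
    left <- hc$merge[k, 1]; right <- hc$merge[k, 2]
    lm <- if (left < 0) -left else members[[left]]
    rm <- if (right < 0) -right else members[[right]]
    for (a in lm) for (b in rm) coph[a, b] <- coph[b, a] <- hc$height[k]
    members[[k]] <- c(lm, rm)
  }
  ccc_oracle <- stats::cor(as.vector(stats::as.dist(1 - unclass(m))),
                           as.vector(stats::as.dist(coph)))
  expect_equal(d$ccc, ccc_oracle, tolerance = 1e-12)
})

test_that("dendrogram is invariant to leaf order of the input", {
  set.seed(2)
  m <- am_random(7, blocks = c(4, 3))
  d1 <- average_linkage(m)
  perm <- sample(7)
  m2 <- am_make(unclass(m)[perm, perm])
  d2 <- average_linkage(m2)
  expect_equal(sort(d1$merge_index), sort(d2$merge_index))
  expect_equal(d1$ccc, d2$ccc, tolerance = 1e-12)
})

test_that("modularity obeys its closed forms", {
  set.seed(6)
  m <- am_random(8, blocks = c(4, 4), w = 0.4, b = 0, noise = 0)
  one <- stats::setNames(rep("all", 8), rownames(m))
  expect_equal(modularity_q(m, one), 0, tolerance = 1e-12)
  split <- stats::setNames(rep(c("u", "v"), each = 4), rownames(m))
  # two equal disconnected cliques -> Q = 1/2
  expect_equal(modularity_q(m, split), 0.5, tolerance = 1e-12)
  # invariant under uniform scaling
  m2 <- am_make(unclass(m) * 0.31)
  expect_equal(modularity_q(m2, split), modularity_q(m, split),
               tolerance = 1e-12)
})

test_that("modularity agrees with igraph on weighted graphs", {
  set.seed(14)
  m <- am_random(9, blocks = c(5, 4))
  lab <- stats::setNames(rep(c(1, 2), c(5, 4)), rownames(m))
  g <- igraph::graph_from_adjacency_matrix(unclass(m), mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  q_ig <- igraph::modularity(g, membership = lab,
                             weights = igraph::E(g)$weight)
  expect_equal(modularity_q(m, stats::setNames(as.character(lab),
                                               names(lab))),
               q_ig, tolerance = 1e-12)
})

test_that("eigenvector communities match exhaustive maximisation (N<=8)", {
  set.seed(91)
  hits <- 0; total <- 0
  for (rep in 1:6) {
    n <- sample(6:8, 1)
    k <- sample(2:3, 1)
    sizes <- diff(round(seq(0, n, length.out = k + 1)))
    m <- am_random(n, blocks = sizes, w = 0.5, b = 0.03, noise = 0.02)
    oracle <- best_partition_oracle(m)
    if (!oracle$unique) next
    total <- total + 1
    ec <- eigenvector_communities(m)
    if (abs(ec$modularity_q - oracle$q) < 1e-9) hits <- hits + 1
  }
  expect_gte(total, 3)
  expect_equal(hits, total)
})

test_that("uniform association yields a single community", {
  m <- am_make(matrix(0.2, 6, 6))
  ec <- eigenvector_communities(m)
  expect_equal(length(unique(ec$labels)), 1)
  expect_equal(ec$modularity_q, 0, tolerance = 1e-12)
})

test_that("the best dendrogram cut lands between the two cliques", {
  set.seed(23)
  m <- am_random(10, blocks = c(6, 4), w = 0.4, b = 0.02, noise = 0.01)
  d <- average_linkage(m)
  cut <- best_dendrogram_cut(d, m)
  expect_equal(length(unique(cut$labels)), 2)
  expect_gt(cut$cut_index, 0.05)
  expect_lt(cut$cut_index, 0.35)
  # argmax property over the evaluated curve
  expect_equal(cut$modularity_q, max(cut$modularity_curve$q))
  # eigenvector Q at least as good as any dendrogram cut
  ec <- eigenvector_communities(m)
  expect_gte(ec$modularity_q, cut$modularity_q - 1e-9)
})

test_that("singleton clusters are surfaced with a nearest suggestion", {
  mm <- matrix(0.02, 7, 7)
  mm[1:3, 1:3] <- 0.6; mm[4:6, 4:6] <- 0.6
  mm[7, ] <- 0.008; mm[, 7] <- 0.008      # near-isolate
  mm[7, 1:3] <- 0.012; mm[1:3, 7] <- 0.012  # slightly closer to block 1
  m <- am_make(mm)
  d <- average_linkage(m)
  cut <- best_dendrogram_cut(d, m)
  # the loner must not be silently folded into a block
  expect_equal(sum(cut$labels == cut$labels[["i07"]]), 1)
  sugg <- attr(cut, "singleton_suggestions")
  expect_false(is.null(sugg))
  s <- sugg[[1]]
  expect_equal(s$id, "i07")
  expect_equal(s$nearest_cluster, unname(cut$labels[["i01"]]))
})

test_that("Newick export reproduces the tree topology", {
  set.seed(3)
  m <- am_random(6, blocks = c(3, 3))
  d <- average_linkage(m)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(d, path)
  tr <- ape::read.tree(path)
  expect_setequal(tr$tip.label, rownames(m))
})
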