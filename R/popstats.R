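#' Social differentiation by beta-binomial maximum likelihood
#'
#' Estimates the coefficient of variation `S` of the true dyadic
#' association probabilities -- the standard measure of how
#' differentiated a society is (values near 0: homogeneous; near 1 or
#' above: well differentiated) -- together with `r`, the correlation
#' between true and estimated association indices, which measures how
#' well the sampled data represent the true social network. Each dyad's
#' joint-sighting count is modelled as
#' `x_ab ~ BetaBinomial(round(d_ab), mu, theta)`; `S` is the CV of the
#' fitted Beta and
#' `r = sqrt(Var(p) / (Var(p) + E[p(1-p)/d]))`
#' follows from the variance decomposition of the index estimator.
#' Standard errors come from a bootstrap over dyads.
#'
#' @param counts A `dyad_counts` object.
#' @param n_bootstrap Bootstrap replications for the SEs (default 10000).
#' @param seed Optional integer seed.
#' @return An object of class `social_differentiation` with `S`, `S_se`,
#'   `r`, `r_se`, the fitted `mu` and `theta`, and `n_bootstrap`.
#' @export
social_differentiation <- function(counts, n_bootstrap = 10000,
                                   seed = NULL) {
  stopifnot(inherits(counts, "dyad_counts"))
  if (!is.null(seed)) set.seed(seed)
  ut <- upper.tri(counts$d)
  d <- round(counts$d[ut])
  x <- counts$x[ut]
  keep <- d > 0
  d <- d[keep]; x <- pmin(x[keep], d)
  if (length(d) < 10) stop("need at least 10 dyads with d > 0",
                           call. = FALSE)
  fit <- betabinom_fit(x, d)
  if (!fit$converged) {
    stop("beta-binomial optimiser failed to converge (code ", fit$code, ")",
         call. = FALSE)
  }
  est <- differentiation_from_fit(fit$mu, fit$theta, d)

  boot <- matrix(NA_real_, n_bootstrap, 2)
  for (b in seq_len(n_bootstrap)) {
    idx <- sample.int(length(d), replace = TRUE)
    bf <- betabinom_fit(x[idx], d[idx], start = c(fit$mu, fit$theta))
    if (bf$converged) {
      e <- differentiation_from_fit(bf$mu, bf$theta, d[idx])
      boot[b, ] <- c(e$S, e$r)
    }
  }
  structure(list(S = est$S, S_se = stats::sd(boot[, 1], na.rm = TRUE),
                 r = est$r, r_se = stats::sd(boot[, 2], na.rm = TRUE),
                 mu = fit$mu, theta = fit$theta,
                 logL = fit$logL, n_dyads = length(d),
                 n_bootstrap = n_bootstrap, seed = seed),
            class = "social_differentiation")
}

#' Beta-binomial differentiation estimate from raw dyadic counts
#'
#' Lower-level interface to the estimator behind
#' [social_differentiation()]: given per-dyad joint-sighting counts `x`
#' and (integer) denominators `d`, fits the beta-binomial by maximum
#' likelihood and returns the social differentiation `S` and the
#' true-vs-estimated index correlation `r` without bootstrapping.
#'
#' @param x Integer vector of per-dyad joint counts.
#' @param d Integer vector of per-dyad denominators (same length).
#' @return A list with `S`, `r`, `mu`, `theta`, `logL`.
#' @export
differentiation_ml <- function(x, d) {
  stopifnot(length(x) == length(d), all(d > 0), all(x >= 0), all(x <= d))
  fit <- betabinom_fit(x, d)
  if (!fit$converged) {
    stop("beta-binomial optimiser failed to converge", call. = FALSE)
  }
  est <- differentiation_from_fit(fit$mu, fit$theta, d)
  list(S = est$S, r = est$r, mu = fit$mu, theta = fit$theta,
       logL = fit$logL)
}

differentiation_from_fit <- function(mu, theta, d) {
  v <- mu * (1 - mu) * theta / (1 + theta)
  s_cv <- sqrt(v) / mu
  ep1p <- mu * (1 - mu) / (1 + theta)        # E[p(1-p)] under the Beta
  noise <- mean(ep1p / d)
  list(S = s_cv, r = sqrt(v / (v + noise)))
}

# beta-binomial log-likelihood, parameters (mu, theta) with
# alpha = mu/theta, beta = (1-mu)/theta; theta -> 0 is the binomial limit
betabinom_loglik <- function(mu, theta, x, n) {
  if (theta < 1e-10) {
    return(sum(stats::dbinom(x, n, mu, log = TRUE)))
  }
  a <- mu / theta
  b <- (1 - mu) / theta
  sum(lchoose(n, x) + lbeta(x + a, n - x + b) - lbeta(a, b))
}

betabinom_fit <- function(x, n, start = NULL) {
  if (is.null(start)) {
    p <- x / n
    mu0 <- max(min(mean(p), 0.99), 0.01)
    v0 <- max(stats::var(p) - mean(mu0 * (1 - mu0) / n), 1e-6)
    th0 <- max(v0 / max(mu0 * (1 - mu0) - v0, 1e-6), 1e-4)
    start <- c(mu0, th0)
  }
  obj <- function(par) {
    mu <- stats::plogis(par[1]); theta <- exp(par[2])
    -betabinom_loglik(mu, theta, x, n)
  }
  th0 <- c(stats::qlogis(min(max(start[1], 1e-6), 1 - 1e-6)),
           log(max(start[2], 1e-8)))
  fit <- tryCatch(
    stats::optim(th0, obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(converged = FALSE, code = NA_integer_))
  }
  list(mu = stats::plogis(fit$par[1]), theta = exp(fit$par[2]),
       logL = -fit$value, converged = TRUE, code = fit$convergence)
}

#' @export
print.social_differentiation <- function(x, ...) {
  cat("Social differentiation (beta-binomial ML,", x$n_dyads, "dyads)\n")
  cat(sprintf("  S = %.3f (SE %.3f)\n", x$S, x$S_se))
  cat(sprintf("  r = %.3f (SE %.3f), bootstrap with %d replications\n",
              x$r, x$r_se, x$n_bootstrap))
  invisible(x)
}

#' Mantel test of class structure in an association matrix
#'
#' Matrix correlation between the dyadic association matrix and the
#' same-class indicator matrix, tested by simultaneous row/column
#' permutation of individuals. Reports the t-like standardised statistic
#' `t = (r_obs - mean(r_perm)) / sd(r_perm)`, the two-tailed p-value
#' (proportion of permuted correlations at least as extreme) and both
#' one-tailed proportions.
#'
#' @param m An `assoc_matrix`.
#' @param classes Named class labels; individuals with `NA` are dropped,
#'   classes with fewer than 2 members are excluded with a warning.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional integer seed.
#' @return An object of class `mantel_class_test` with `r_obs`, `t`,
#'   `p_two_sided`, `p_greater`, `p_less`, `n_perm`.
#' @export
mantel_class_test <- function(m, classes, n_perm = 10000, seed = NULL) {
  stopifnot(inherits(m, "assoc_matrix"))
  if (!is.null(seed)) set.seed(seed)
  ids <- attr(m, "ids")
  cl <- as.character(classes)[match(ids, names(classes))]
  keep <- !is.na(cl)
  sizes <- table(cl[keep])
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("class(es) with < 2 members excluded: ",
            paste(small, collapse = ", "))
    keep <- keep & !cl %in% small
  }
  if (length(unique(cl[keep])) < 2) {
    stop("need at least 2 classes with >= 2 members", call. = FALSE)
  }
  a <- unclass(m)[keep, keep, drop = FALSE]
  cl <- cl[keep]
  same <- outer(cl, cl, "==") * 1
  ut <- upper.tri(a)
  r_obs <- stats::cor(a[ut], same[ut])
  n <- nrow(a)
  r_perm <- vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    stats::cor(a[ut], same[p, p][ut])
  }, 1.0)
  mu <- mean(r_perm); sg <- stats::sd(r_perm)
  structure(list(r_obs = r_obs,
                 t = (r_obs - mu) / sg,
                 p_two_sided = mean(abs(r_perm - mu) >= abs(r_obs - mu)),
                 p_greater = mean(r_perm >= r_obs),
                 p_less = mean(r_perm <= r_obs),
                 null_mean = mu, null_sd = sg, n_perm = n_perm,
                 seed = seed),
            class = "mantel_class_test")
}

#' @export
print.mantel_class_test <- function(x, ...) {
  cat("Mantel matrix-correlation test (", x$n_perm, " permutations)\n",
      sep = "")
  cat(sprintf("  r = %.4f, t = %.3f\n", x$r_obs, x$t))
  cat(sprintf("  two-tailed P = %.4g (greater %.4g, less %.4g)\n",
              x$p_two_sided, x$p_greater, x$p_less))
  invisible(x)
}

#' Assign an encounter to a social cluster by strict majority
#'
#' A group is assigned to the cluster to which the strict majority of its
#' retained members belong; an exact tie yields `"mixed-tie"` and a group
#' with no retained members `"unassigned"`.
#'
#' @param members Character vector of individual ids in the encounter.
#' @param labels Named cluster labels for retained individuals.
#' @return A single character: a cluster id, `"mixed-tie"` or
#'   `"unassigned"`.
#' @export
classify_encounter_cluster <- function(members, labels) {
  lab <- labels[intersect(members, names(labels))]
  if (!length(lab)) return("unassigned")
  tab <- table(lab)
  top <- names(tab)[tab == max(tab)]
  if (length(top) > 1) "mixed-tie" else top
}

#' Diel partitioning of encounters between social clusters
#'
#' Classifies encounters to clusters by majority membership, buckets them
#' by start time into morning \[07:00, 13:00\], afternoon (13:00, 18:00\]
#' and evening (18:00, 21:00\] bins, and tests whether two clusters use
#' the area at different times of day with a two-tailed Fisher's exact
#' test on their morning vs evening counts.
#'
#' @param x An `encounter_table`.
#' @param labels Named cluster labels.
#' @param scope `"entire"` (all encounters) or `"core"` (core study area
#'   only).
#' @param test_clusters Length-2 character vector naming the clusters to
#'   contrast (default: the two with most classified encounters).
#' @return An object of class `diel_table`: the cluster x bin count
#'   table, the scope, the 2x2 test table and `fisher_p`.
#' @export
diel_partition_test <- function(x, labels, scope = c("entire", "core"),
                                test_clusters = NULL) {
  stopifnot(inherits(x, "encounter_table"))
  scope <- match.arg(scope)
  enc <- x$encounters
  if (scope == "core") enc <- enc[enc$area == "core", , drop = FALSE]
  mem <- x$memberships
  cl <- vapply(enc$encounter_id, function(e) {
    classify_encounter_cluster(mem$individual_id[mem$encounter_id == e],
                               labels)
  }, "")
  hh <- as.integer(substr(enc$time_start, 1, 2)) +
    as.integer(substr(enc$time_start, 4, 5)) / 60
  bin <- rep(NA_character_, length(hh))
  bin[hh >= 7 & hh <= 13] <- "morning"
  bin[hh > 13 & hh <= 18] <- "afternoon"
  bin[hh > 18 & hh <= 21] <- "evening"
  ok <- !is.na(bin) & !cl %in% c("unassigned", "mixed-tie")
  counts <- table(cluster = cl[ok],
                  bin = factor(bin[ok],
                               levels = c("morning", "afternoon", "evening")))
  if (is.null(test_clusters)) {
    if (nrow(counts) < 2) stop("fewer than 2 clusters with classifiable ",
                               "encounters", call. = FALSE)
    test_clusters <- rownames(counts)[order(rowSums(counts),
                                            decreasing = TRUE)][1:2]
  }
  if (any(rowSums(counts[test_clusters, , drop = FALSE]) == 0)) {
    stop("a tested cluster has no classifiable encounters", call. = FALSE)
  }
  tt <- counts[test_clusters, c("morning", "evening")]
  p <- stats::fisher.test(tt)$p.value
  structure(list(counts = counts, scope = scope,
                 test_clusters = test_clusters, test_table = tt,
                 fisher_p = p),
            class = "diel_table")
}

#' @export
print.diel_table <- function(x, ...) {
  cat("Diel partitioning (", x$scope, " study area)\n", sep = "")
  print(x$counts)
  cat(sprintf("Fisher's exact test, %s vs %s (morning vs evening): P = %.4g\n",
              x$test_clusters[1], x$test_clusters[2], x$fisher_p))
  invisible(x)
}

#' Sex composition of encountered groups
#'
#' Among groups with at least two known-sex members (the restriction that
#' avoids biasing composition estimates), classifies each as male-only,
#' female-only or mixed-sex; unsexed members are ignored in the
#' classification.
#'
#' @param x An `encounter_table`.
#' @param cluster_labels Optional named cluster labels; if given together
#'   with `cluster`, restricts to groups composed only of members of that
#'   cluster.
#' @param cluster Optional cluster id to restrict to.
#' @return A list with `n_groups`, counts and percentages of
#'   `male_only`, `female_only`, `mixed`.
#' @export
sex_composition <- function(x, cluster_labels = NULL, cluster = NULL) {
  stopifnot(inherits(x, "encounter_table"))
  sex <- stats::setNames(as.character(x$individuals$sex),
                         x$individuals$individual_id)
  mem <- x$memberships
  groups <- split(mem$individual_id, mem$encounter_id)
  if (!is.null(cluster)) {
    stopifnot(!is.null(cluster_labels))
    groups <- Filter(function(g) {
      lab <- cluster_labels[intersect(g, names(cluster_labels))]
      length(lab) > 0 && all(lab == cluster)
    }, groups)
  }
  klass <- vapply(groups, function(g) {
    s <- sex[g]
    s <- s[s %in% c("F", "M")]
    if (length(s) < 2) return(NA_character_)
    if (all(s == "M")) "male_only"
    else if (all(s == "F")) "female_only"
    else "mixed"
  }, "")
  klass <- klass[!is.na(klass)]
  n <- length(klass)
  cnt <- function(k) sum(klass == k)
  list(n_groups = n,
       male_only = cnt("male_only"), female_only = cnt("female_only"),
       mixed = cnt("mixed"),
       pct_male_only = if (n) 100 * cnt("male_only") / n else NA_real_,
       pct_female_only = if (n) 100 * cnt("female_only") / n else NA_real_,
       pct_mixed = if (n) 100 * cnt("mixed") / n else NA_real_)
}

#' Summarise fishery (trawler) interactions by individual and cluster
#'
#' For encounters flagged as trawler interactions: each individual's
#' count and share of all interaction events, per-cluster mean, SD
#' and range of interaction counts, and the gear-type breakdown. An
#' encounter with both gear types counts as one event per gear, so the
#' gear counts sum to the total number of interactions.
#'
#' @param x An `encounter_table`.
#' @param labels Named cluster labels.
#' @return An object of class `fishery_report` with `n_interactions`
#'   (gear events; an encounter with both gears contributes one event per
#'   gear), `n_interaction_encounters`, `pct_of_encounters`, `gear`
#'   (counts and percentages for pair and bottom trawlers),
#'   `individuals` (data frame) and `clusters` (data frame).
#' @export
fishery_interaction_summary <- function(x, labels) {
  stopifnot(inherits(x, "encounter_table"))
  enc <- x$encounters
  mem <- x$memberships
  inter <- enc[enc$trawler != "none", , drop = FALSE]
  n_pair <- sum(inter$trawler %in% c("pair", "both"))
  n_bottom <- sum(inter$trawler %in% c("bottom", "both"))
  # an encounter with both gears is one event per gear
  events <- stats::setNames(ifelse(inter$trawler == "both", 2L, 1L),
                            inter$encounter_id)
  n_int <- n_pair + n_bottom

  ids <- sort(unique(mem$individual_id))
  cnt <- vapply(ids, function(id) {
    sum(events[intersect(mem$encounter_id[mem$individual_id == id],
                         inter$encounter_id)])
  }, 1L)
  indiv <- data.frame(individual_id = ids, n_interactions = cnt,
                      proportion = if (n_int) cnt / n_int else 0,
                      cluster = unname(labels[ids]),
                      row.names = NULL)
  cls <- sort(unique(stats::na.omit(indiv$cluster)))
  clus <- do.call(rbind, lapply(cls, function(cl) {
    v <- indiv$n_interactions[indiv$cluster %in% cl]
    data.frame(cluster = cl, n_individuals = length(v), mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else 0,
               min = min(v), max = max(v))
  }))
  structure(list(n_interactions = n_int,
                 n_interaction_encounters = nrow(inter),
                 pct_of_encounters = if (nrow(enc))
                   100 * nrow(inter) / nrow(enc) else NA_real_,
                 gear = list(pair = n_pair, bottom = n_bottom,
                             pct_pair = if (n_int) 100 * n_pair / n_int
                                        else NA_real_,
                             pct_bottom = if (n_int) 100 * n_bottom / n_int
                                          else NA_real_),
                 individuals = indiv, clusters = clus),
            class = "fishery_report")
}

#' @export
print.fishery_report <- function(x, ...) {
  cat("Fishery interactions:", x$n_interactions, "events in",
      x$n_interaction_encounters, "encounters (",
      sprintf("%.1f%%", x$pct_of_encounters), "of all encounters)\n")
  cat(sprintf("  gear: %d pair (%.1f%%), %d bottom (%.1f%%)\n",
              x$gear$pair, x$gear$pct_pair, x$gear$bottom,
              x$gear$pct_bottom))
  if (!is.null(x$clusters) && nrow(x$clusters)) {
    for (i in seq_len(nrow(x$clusters))) {
      r <- x$clusters[i, ]
      cat(sprintf("  cluster %s: mean %.1f (SD %.1f, range %d-%d)\n",
                  r$cluster, r$mean, r$sd, r$min, r$max))
    }
  }
  top <- x$individuals[order(-x$individuals$proportion), ][1, ]
  if (x$n_interactions > 0) {
    cat(sprintf("  most involved: %s in %.1f%% of interactions\n",
                top$individual_id, 100 * top$proportion))
  }
  invisible(x)
}

#' Bar chart of per-individual fishery-interaction proportions
#'
#' @param x A `fishery_report`.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, `x`.
#' @export
plot.fishery_report <- function(x, ...) {
  d <- x$individuals[order(-x$individuals$proportion), ]
  d <- d[d$n_interactions > 0, ]
  graphics::barplot(d$proportion, names.arg = d$individual_id, las = 2,
                    ylab = "Proportion of all fishery interactions", ...)
  invisible(x)
}

#' Bar chart of diel occurrence by cluster
#'
#' @param x A `diel_table`.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, `x`.
#' @export
plot.diel_table <- function(x, ...) {
  graphics::barplot(t(x$counts), beside = TRUE,
                    legend.text = colnames(x$counts),
                    xlab = "Cluster", ylab = "Encounters", ...)
  invisible(x)
}
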