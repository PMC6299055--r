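#' Run the full social-structure analysis pipeline
#'
#' Orchestrates every stage on one data set: restriction filtering,
#' period matrices, association indices, the within-sample permutation
#' test, SLAR with jackknife errors, null rate and exponential model
#' fits, average-linkage clustering with CCC, eigenvector modularity
#' clusters and the best dendrogram cut, node and cluster network
#' metrics, social differentiation, Mantel class tests, diel partitioning
#' and the fishery-interaction report. Stage outputs are written to
#' `out_dir` as CSV/JSON/Newick/GraphML plus one `summary.json` holding
#' the headline numbers. A single seed is fanned out deterministically to
#' every stochastic stage, so each stage can be reproduced in isolation.
#'
#' @param input Either an `encounter_table`, a directory containing the
#'   three-CSV contract, or a `society_config` to simulate from.
#' @param out_dir Output directory (`NULL`: nothing written).
#' @param period_length_days Sampling-period length (default 1 day).
#' @param index Association index for downstream stages, `"HWI"` or
#'   `"HWIG"`.
#' @param n_perm,flips_between_saves Permutation-test settings.
#' @param moving_average_size SLAR moving-average window target.
#' @param n_null SLAR null-rate randomizations.
#' @param n_bootstrap Bootstrap replications for social differentiation.
#' @param n_mantel Mantel-test permutations.
#' @param min_occasions,min_years Restriction thresholds.
#' @param seed Integer master seed.
#' @return A list of class `podnet_run` with every stage result and
#'   `summary` (the content of `summary.json`).
#' @export
run_pipeline <- function(input,
                         out_dir = NULL,
                         period_length_days = 1,
                         index = c("HWI", "HWIG"),
                         n_perm = 20000,
                         flips_between_saves = NULL,
                         moving_average_size = 8000,
                         n_null = 100,
                         n_bootstrap = 10000,
                         n_mantel = 10000,
                         min_occasions = 4,
                         min_years = 2,
                         seed = 1) {
  index <- match.arg(index)
  seeds <- derive_seeds(seed)
  truth <- NULL
  if (inherits(input, "society_config")) {
    sim <- simulate_society(input)
    table <- sim$encounters
    truth <- sim$truth
  } else if (inherits(input, "encounter_table")) {
    table <- input
  } else if (is.character(input) && length(input) == 1) {
    if (!dir.exists(input)) stop("input directory not found: ", input,
                                 call. = FALSE)
    table <- read_encounters(file.path(input, "encounters.csv"),
                             file.path(input, "memberships.csv"),
                             file.path(input, "individuals.csv"))
  } else {
    stop("input must be an encounter_table, a directory, or a ",
         "society_config", call. = FALSE)
  }

  restricted <- apply_restrictions(table, min_occasions = min_occasions,
                                   min_years = min_years)
  pm <- build_period_matrices(restricted, period_length_days)
  counts <- dyad_counts(pm)
  h <- hwi(counts)
  m <- if (index == "HWIG") hwig(h) else h

  perm <- permutation_test(pm, n_perm = n_perm,
                           flips_between_saves = flips_between_saves,
                           seed = seeds["perm"])
  curve <- slar(pm, moving_average_size = moving_average_size)
  curve <- jackknife_se(curve)
  curve <- null_rate(curve, pm, n_randomizations = n_null,
                     seed = seeds["null"])
  fits <- fit_social_models(curve)

  dend <- average_linkage(m)
  clusters <- eigenvector_communities(m)
  cut <- best_dendrogram_cut(dend, m)
  metrics <- node_metrics(m)
  metr_by_cluster <- cluster_summary(metrics, clusters$labels)
  diff <- social_differentiation(counts, n_bootstrap = n_bootstrap,
                                 seed = seeds["boot"])
  mantel_clusters <- mantel_class_test(m, clusters$labels,
                                       n_perm = n_mantel,
                                       seed = seeds["mantel1"])
  sex <- stats::setNames(as.character(restricted$individuals$sex),
                         restricted$individuals$individual_id)
  sex[sex == "U"] <- NA
  mantel_sex <- tryCatch(
    mantel_class_test(m, sex, n_perm = n_mantel, seed = seeds["mantel2"]),
    error = function(e) NULL)
  diel_entire <- tryCatch(
    diel_partition_test(restricted, clusters$labels, scope = "entire"),
    error = function(e) NULL)
  diel_core <- tryCatch(
    diel_partition_test(restricted, clusters$labels, scope = "core"),
    error = function(e) NULL)
  sexcomp <- sex_composition(restricted)
  fishery <- fishery_interaction_summary(restricted, clusters$labels)

  summary <- list(
    n_individuals = length(attr(restricted, "retained_ids")),
    n_encounters = nrow(restricted$encounters),
    pct_seen_ge_5 = restriction_summary(restricted)$pct_ge_5,
    index = index,
    observed_sd = unname(perm$observed["sd"]),
    random_sd = unname(perm$null_mean["sd"]),
    p_sd = unname(perm$p_value["sd"]),
    observed_cv = unname(perm$observed["cv"]),
    random_cv = unname(perm$null_mean["cv"]),
    p_cv = unname(perm$p_value["cv"]),
    S = diff$S, S_se = diff$S_se, r = diff$r, r_se = diff$r_se,
    ccc = dend$ccc,
    modularity_q = clusters$modularity_q,
    n_clusters = length(unique(clusters$labels)),
    cut_index = cut$cut_index,
    cut_modularity_q = cut$modularity_q,
    best_model = fits$best,
    qaic = as.list(stats::setNames(fits$table$QAIC, fits$table$model)),
    mantel_clusters = list(t = mantel_clusters$t,
                           p_two_sided = mantel_clusters$p_two_sided,
                           p_greater = mantel_clusters$p_greater),
    mantel_sex = if (!is.null(mantel_sex))
      list(t = mantel_sex$t, p_two_sided = mantel_sex$p_two_sided)
      else NULL,
    diel_fisher_p = list(
      entire = if (!is.null(diel_entire)) diel_entire$fisher_p else NULL,
      core = if (!is.null(diel_core)) diel_core$fisher_p else NULL),
    pct_mixed_sex_groups = sexcomp$pct_mixed,
    fishery = list(n_interactions = fishery$n_interactions,
                   pct_of_encounters = fishery$pct_of_encounters,
                   pct_pair = fishery$gear$pct_pair,
                   pct_bottom = fishery$gear$pct_bottom),
    seed = seed)

  run <- structure(list(
    table = restricted, period_matrices = pm, counts = counts,
    hwi = h, assoc = m, perm = perm, slar = curve, fits = fits,
    dendrogram = dend, clusters = clusters, dendrogram_cut = cut,
    metrics = metrics, cluster_metrics = metr_by_cluster,
    differentiation = diff, mantel_clusters = mantel_clusters,
    mantel_sex = mantel_sex, diel_entire = diel_entire,
    diel_core = diel_core, sex_composition = sexcomp, fishery = fishery,
    truth = truth, summary = summary, seed = seed),
    class = "podnet_run")

  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

# one master seed fanned out to named per-stage seeds (< 2^31)
derive_seeds <- function(seed) {
  stages <- c("perm", "null", "boot", "mantel1", "mantel2")
  stats::setNames((seed * 7919 + 104729 * seq_along(stages)) %%
                    .Machine$integer.max, stages)
}

write_run <- function(run, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  fp <- function(...) file.path(out_dir, ...)
  write_encounters(run$table, fp("restricted"))
  write_assoc_matrix(run$assoc, fp("association_matrix.csv"),
                     fp("association_edges.csv"))
  write_perm_test(run$perm, fp("permutation_test.json"))
  write_slar(run$slar, fp("slar_curve.csv"))
  write_model_fits(run$fits, fp("slar_models.json"))
  write_newick(run$dendrogram, fp("dendrogram.nwk"))
  write_clusters(run$clusters, fp("clusters.csv"))
  write_clusters(run$dendrogram_cut, fp("dendrogram_cut_clusters.csv"),
                 fp("modularity_curve.csv"))
  utils::write.csv(run$metrics, fp("node_metrics.csv"), row.names = FALSE)
  utils::write.csv(run$cluster_metrics, fp("cluster_metrics.csv"),
                   row.names = FALSE)
  write_graphml(run$assoc, fp("network.graphml"),
                labels = run$clusters$labels,
                filtered_path = fp("network_strong.graphml"))
  jsonlite::write_json(run$summary, fp("summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  grDevices::pdf(fp("slar.pdf"), width = 7, height = 5)
  try(plot(run$slar, fits = run$fits), silent = TRUE)
  grDevices::dev.off()
  grDevices::pdf(fp("dendrogram.pdf"), width = 7, height = 8)
  try(plot(run$dendrogram, cut_index = run$dendrogram_cut$cut_index),
      silent = TRUE)
  grDevices::dev.off()
  if (!is.null(run$diel_core)) {
    grDevices::pdf(fp("diel_core.pdf"), width = 6, height = 5)
    try(plot(run$diel_core), silent = TRUE)
    grDevices::dev.off()
  }
  grDevices::pdf(fp("fishery.pdf"), width = 7, height = 5)
  try(plot(run$fishery), silent = TRUE)
  grDevices::dev.off()
  invisible(out_dir)
}

#' @export
print.podnet_run <- function(x, ...) {
  s <- x$summary
  cat("podnet pipeline run (seed", s$seed, ")\n")
  cat("  ", s$n_individuals, "individuals,", s$n_encounters,
      "encounters\n")
  cat(sprintf("  permutation SD: obs %.4f vs random %.4f (P = %.4g)\n",
              s$observed_sd, s$random_sd, s$p_sd))
  cat(sprintf("  S = %.3f (SE %.3f), r = %.3f (SE %.3f)\n",
              s$S, s$S_se, s$r, s$r_se))
  cat(sprintf("  CCC = %.3f; %d clusters, Q = %.3f (cut index %.4f)\n",
              s$ccc, s$n_clusters, s$modularity_q, s$cut_index))
  cat("  best SLAR model:", s$best_model, "\n")
  invisible(x)
}
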