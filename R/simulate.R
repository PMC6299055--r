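#' Configuration for a simulated fission-fusion society
#'
#' Builds the parameter set for [simulate_society()]. The defaults
#' describe a small resident coastal dolphin population of the kind
#' studied with long-term photo-ID: three social clusters of 19, 13 and 6
#' individuals surveyed over 9 years (roughly 115 usable encounters),
#' strong within-cluster and weak between-cluster association, two large
#' clusters that use the core study area at opposite ends of the day
#' (morning vs evening), a loosely associated third cluster, a stream of
#' transient visitors seen in a single year, a few mother-dependent
#' calves, imperfect identification, and cluster-specific trawler
#' interaction propensities concentrated in the morning cluster.
#'
#' @param clusters Named integer vector of cluster sizes.
#' @param within_propensity Probability that a cluster member attends an
#'   occasion at which its cluster is present.
#' @param between_propensity Probability that an individual joins a group
#'   of another cluster present at the same occasion.
#' @param grouping_concentration Probability that a cluster's attendees
#'   fuse into a single group (otherwise they split into 2-4 subgroups).
#' @param n_years,survey_days_per_year Survey effort structure.
#' @param bin_survey_prob Probability each diel bin (morning, afternoon,
#'   evening) of a survey day is covered.
#' @param presence Cluster x bin matrix of availability probabilities.
#' @param core_prob Cluster x bin matrix of probabilities that a present
#'   cluster is in the core study area.
#' @param detection_prob Probability an existing group is encountered.
#' @param identification_probability Per-member identification
#'   probability within an encountered group.
#' @param transients_per_year Poisson mean number of one-year transient
#'   individuals entering per year.
#' @param transient_sighting_prob Per-occasion sighting probability of an
#'   active transient.
#' @param n_calves Number of mother-dependent calves.
#' @param calf_accompany_prob Probability a calf is recorded alongside
#'   its identified mother.
#' @param sex_known_fraction,female_fraction Sexing coverage and sex
#'   ratio among sexed residents.
#' @param trawler_interact Named per-cluster probability that an
#'   encounter of a cluster-majority group is a trawler interaction.
#' @param trawler_gear Length-3 probabilities of pair / bottom / both
#'   gear given an interaction.
#' @param start_year First survey year.
#' @param seed Integer seed; the same seed yields byte-identical output.
#' @return A list of class `society_config`.
#' @export
society_config <- function(clusters = c(A = 19, B = 13, C = 6),
                           within_propensity = 0.3,
                           between_propensity = 0.01,
                           grouping_concentration = 0.7,
                           n_years = 9,
                           survey_days_per_year = 14,
                           bin_survey_prob = c(morning = 0.95,
                                               afternoon = 0.5,
                                               evening = 0.6),
                           presence = NULL,
                           core_prob = NULL,
                           detection_prob = 0.7,
                           identification_probability = 0.95,
                           transients_per_year = 5,
                           transient_sighting_prob = 0.08,
                           n_calves = 4,
                           calf_accompany_prob = 0.8,
                           sex_known_fraction = 0.66,
                           female_fraction = 0.52,
                           trawler_interact = NULL,
                           trawler_gear = c(pair = 0.6, bottom = 0.35,
                                            both = 0.05),
                           start_year = 2003,
                           seed = 1) {
  k <- length(clusters)
  if (is.null(names(clusters))) names(clusters) <- LETTERS[seq_len(k)]
  bins <- c("morning", "afternoon", "evening")
  if (is.null(presence)) {
    presence <- matrix(0.25, k, 3, dimnames = list(names(clusters), bins))
    if (k >= 1) presence[1, ] <- c(0.5, 0.15, 0)
    if (k >= 2) presence[2, ] <- c(0.1, 0.05, 0.4)
    if (k >= 3) presence[3, ] <- c(0.25, 0.15, 0.1)
  }
  if (is.null(core_prob)) {
    core_prob <- matrix(0.5, k, 3, dimnames = list(names(clusters), bins))
    if (k >= 1) core_prob[1, ] <- c(0.9, 0, 0)
    if (k >= 2) core_prob[2, ] <- c(0, 0, 0.9)
    if (k >= 3) core_prob[3, ] <- c(0.6, 0.6, 0.6)
  }
  if (is.null(trawler_interact)) {
    trawler_interact <- stats::setNames(rep(0.05, k), names(clusters))
    if (k >= 1) trawler_interact[1] <- 0.5
    if (k >= 2) trawler_interact[2] <- 0.02
    if (k >= 3) trawler_interact[3] <- 0.08
  }
  stopifnot(all(presence >= 0 & presence <= 1),
            all(core_prob >= 0 & core_prob <= 1),
            within_propensity >= 0, within_propensity <= 1,
            between_propensity >= 0, between_propensity <= 1)
  if (all(presence == 0)) stop("infeasible config: empty diel schedule",
                               call. = FALSE)
  structure(list(clusters = clusters,
                 within_propensity = within_propensity,
                 between_propensity = between_propensity,
                 grouping_concentration = grouping_concentration,
                 n_years = n_years,
                 survey_days_per_year = survey_days_per_year,
                 bin_survey_prob = bin_survey_prob,
                 presence = presence, core_prob = core_prob,
                 detection_prob = detection_prob,
                 identification_probability = identification_probability,
                 transients_per_year = transients_per_year,
                 transient_sighting_prob = transient_sighting_prob,
                 n_calves = n_calves,
                 calf_accompany_prob = calf_accompany_prob,
                 sex_known_fraction = sex_known_fraction,
                 female_fraction = female_fraction,
                 trawler_interact = trawler_interact,
                 trawler_gear = trawler_gear,
                 start_year = start_year,
                 seed = seed),
            class = "society_config")
}

#' Load a scenario preset for the society simulator
#'
#' Presets ship with the package as YAML: `"paper-like"` (the default
#' three-cluster society described in [society_config()]),
#' `"null-random"` (one undifferentiated cluster, uniform diel schedule;
#' association is random) and `"two-clique-toy"` (two small, well
#' separated clusters, useful for quick structural checks).
#'
#' @param name Preset name.
#' @param ... Overrides passed on to [society_config()].
#' @return A `society_config`.
#' @export
society_preset <- function(name = c("paper-like", "null-random",
                                    "two-clique-toy"), ...) {
  name <- match.arg(name)
  path <- system.file("extdata", "presets", paste0(name, ".yaml"),
                      package = "podnet")
  if (path == "") stop("preset file not found: ", name, call. = FALSE)
  spec <- yaml::read_yaml(path)
  for (f in c("clusters", "bin_survey_prob", "trawler_interact",
              "trawler_gear")) {
    if (!is.null(spec[[f]])) spec[[f]] <- unlist(spec[[f]])
  }
  for (f in c("presence", "core_prob")) {
    if (!is.null(spec[[f]])) {
      spec[[f]] <- do.call(rbind, lapply(spec[[f]], unlist))
      colnames(spec[[f]]) <- c("morning", "afternoon", "evening")
    }
  }
  over <- list(...)
  spec[names(over)] <- over
  do.call(society_config, spec)
}

#' Simulate a fission-fusion society and its photo-ID record
#'
#' Generates encounter data with known ground truth. For every surveyed
#' (day, diel bin) occasion, each cluster is present according to its
#' diel schedule; present members attend independently with the
#' within-cluster propensity and either fuse into one group or split into
#' 2-4 subgroups; individuals from other clusters spill into those groups
#' at the (small) between-cluster propensity, so mixed groups have a
#' clear majority cluster plus a few outsiders. Each group is
#' independently detected, each member independently identified, and
#' cluster-majority groups pick up trawler-interaction flags at the
#' cluster's propensity. Transient individuals appear in a single year;
#' mother-dependent calves accompany their mothers. The output passes
#' [as_encounter_table()] validation and feeds straight into the
#' analysis pipeline.
#'
#' @param config A `society_config`.
#' @return A list with `encounters` (an `encounter_table`) and `truth`
#'   (class `society_truth`): true cluster labels, the approximate true
#'   dyadic association probability matrix for residents, its CV
#'   (`S_true`), the diel schedule and trawler propensities.
#' @export
simulate_society <- function(config = society_config()) {
  stopifnot(inherits(config, "society_config"))
  set.seed(config$seed)
  cf <- config
  cl_names <- names(cf$clusters)
  k <- length(cf$clusters)
  bins <- c("morning", "afternoon", "evening")
  bin_hours <- list(morning = 7:12, afternoon = 13:17, evening = 18:20)

  members <- list()
  for (i in seq_len(k)) {
    members[[cl_names[i]]] <-
      sprintf("%s%02d", cl_names[i], seq_len(cf$clusters[i]))
  }
  residents <- unlist(members, use.names = FALSE)

  # transients: one active year each
  trans_ids <- character(0)
  trans_year <- integer(0)
  for (y in seq_len(cf$n_years)) {
    nt <- stats::rpois(1, cf$transients_per_year)
    if (nt > 0) {
      ids <- sprintf("T%02d%02d", y, seq_len(nt))
      trans_ids <- c(trans_ids, ids)
      trans_year <- c(trans_year, rep(y, nt))
    }
  }

  # calves and their mothers (mothers from the larger clusters)
  calf_ids <- if (cf$n_calves > 0) sprintf("K%02d", seq_len(cf$n_calves))
              else character(0)
  pool <- unlist(members[seq_len(min(2, k))], use.names = FALSE)
  mothers <- if (cf$n_calves > 0) sample(pool, cf$n_calves) else character(0)

  enc_rows <- list()
  mem_rows <- list()
  eno <- 0L

  for (y in seq_len(cf$n_years)) {
    year <- cf$start_year + y - 1
    # survey days: mostly summer, a few spread over spring/autumn
    n_summer <- round(cf$survey_days_per_year * 0.8)
    summer <- as.Date(sprintf("%d-07-01", year)) +
      sort(sample.int(92, n_summer))
    other <- as.Date(sprintf("%d-03-01", year)) +
      sort(sample.int(120, cf$survey_days_per_year - n_summer))
    days <- sort(unique(c(summer, other)))
    active_trans <- trans_ids[trans_year == y]

    for (day in seq_along(days)) {
      surveyed <- stats::runif(3) < cf$bin_survey_prob
      for (bi in which(surveyed)) {
        assigned <- character(0)
        groups <- list()     # each: list(ids, cluster, area)
        for (ci in sample.int(k)) {
          if (stats::runif(1) >= cf$presence[ci, bi]) next
          att <- members[[ci]][stats::runif(cf$clusters[ci]) <
                                 cf$within_propensity]
          att <- setdiff(att, assigned)
          if (!length(att)) next
          area <- if (stats::runif(1) < cf$core_prob[ci, bi]) "core"
                  else "other"
          if (stats::runif(1) < cf$grouping_concentration ||
              length(att) == 1) {
            parts <- list(att)
          } else {
            ng <- sample(2:4, 1)
            gi <- sample.int(ng, length(att), replace = TRUE)
            parts <- split(att, gi)
          }
          assigned <- c(assigned, att)
          # spillover from other clusters into each group
          for (p in seq_along(parts)) {
            outsiders <- setdiff(residents, c(members[[ci]], assigned))
            joiners <- outsiders[stats::runif(length(outsiders)) <
                                   cf$between_propensity]
            if (length(joiners)) {
              parts[[p]] <- c(parts[[p]], joiners)
              assigned <- c(assigned, joiners)
            }
            groups <- c(groups, list(list(ids = parts[[p]],
                                          cluster = cl_names[ci],
                                          area = area)))
          }
        }
        for (tid in setdiff(active_trans, assigned)) {
          if (stats::runif(1) < cf$transient_sighting_prob) {
            groups <- c(groups, list(list(
              ids = tid, cluster = NA_character_,
              area = if (stats::runif(1) < 0.5) "core" else "other")))
            assigned <- c(assigned, tid)
          }
        }
        for (g in groups) {
          if (stats::runif(1) >= cf$detection_prob) next
          idd <- g$ids[stats::runif(length(g$ids)) <
                         cf$identification_probability]
          if (!length(idd)) next
          # dependent calves ride along with identified mothers
          for (ki in seq_along(calf_ids)) {
            if (mothers[ki] %in% idd &&
                stats::runif(1) < cf$calf_accompany_prob) {
              idd <- c(idd, calf_ids[ki])
            }
          }
          hrs <- bin_hours[[bi]]
          hour <- hrs[sample.int(length(hrs), 1)]
          minute <- sample.int(59, 1)
          trW <- "none"
          if (!is.na(g$cluster) &&
              stats::runif(1) < cf$trawler_interact[g$cluster]) {
            trW <- sample(c("pair", "bottom", "both"), 1,
                          prob = cf$trawler_gear)
          }
          eno <- eno + 1L
          enc_rows[[eno]] <- data.frame(
            encounter_id = sprintf("E%04d", eno),
            date = format(days[day], "%Y-%m-%d"),
            time_start = sprintf("%02d:%02d", hour, minute),
            area = g$area, trawler = trW, stringsAsFactors = FALSE)
          mem_rows[[eno]] <- data.frame(
            encounter_id = sprintf("E%04d", eno),
            individual_id = sort(idd), stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (eno == 0L) stop("simulation produced no encounters; ",
                      "check the schedule and effort settings",
                      call. = FALSE)
  enc <- do.call(rbind, enc_rows)
  mem <- do.call(rbind, mem_rows)

  # registry with sexes
  n_res <- length(residents)
  sexed <- sample(residents, round(cf$sex_known_fraction * n_res))
  sex <- stats::setNames(rep("U", n_res), residents)
  nf <- round(cf$female_fraction * length(sexed))
  sex[sample(sexed, nf)] <- "F"
  sex[setdiff(sexed, names(sex)[sex == "F"])] <- "M"
  all_ids <- c(residents, trans_ids, calf_ids)
  ind <- data.frame(
    individual_id = all_ids,
    sex = c(sex[residents], rep("U", length(trans_ids)),
            rep("U", length(calf_ids))),
    is_calf = c(rep(0L, n_res + length(trans_ids)),
                rep(1L, length(calf_ids))),
    stringsAsFactors = FALSE)
  # only registered individuals may appear
  mem <- mem[mem$individual_id %in% all_ids, , drop = FALSE]
  table <- as_encounter_table(enc, mem, ind)

  truth <- society_truth(cf, members, residents, trans_ids, calf_ids)
  list(encounters = table, truth = truth)
}

society_truth <- function(cf, members, residents, trans_ids, calf_ids) {
  k <- length(cf$clusters)
  # probability two attendees of the same present cluster share a group
  q_same <- cf$grouping_concentration +
    (1 - cf$grouping_concentration) * mean(1 / (2:4))
  n <- length(residents)
  p_true <- matrix(0, n, n, dimnames = list(residents, residents))
  lab <- stats::setNames(rep(names(cf$clusters), cf$clusters), residents)
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      # expected half-weight index: joint attendance and co-grouping,
      # relative to half the summed attendance (w^2 q / w = w q)
      p <- if (lab[residents[a]] == lab[residents[b]]) {
        cf$within_propensity * q_same
      } else {
        cf$between_propensity
      }
      p_true[a, b] <- p_true[b, a] <- p
    }
  }
  v <- p_true[upper.tri(p_true)]
  labels <- c(lab,
              stats::setNames(rep("transient", length(trans_ids)), trans_ids),
              stats::setNames(rep("calf", length(calf_ids)), calf_ids))
  structure(list(labels = labels, resident_labels = lab, p_true = p_true,
                 S_true = stats::sd(v) / mean(v),
                 q_same = q_same,
                 presence = cf$presence, core_prob = cf$core_prob,
                 trawler_interact = cf$trawler_interact),
            class = "society_truth")
}

#' Score pipeline outputs against simulation ground truth
#'
#' Compares recovered structure with the generating truth: adjusted Rand
#' index of cluster labels, bias of the social-differentiation estimate,
#' whether the permutation test detected (or, on random data, correctly
#' failed to detect) non-random association, and whether QAIC selection
#' picked a given model.
#'
#' @param truth A `society_truth`.
#' @param clusters Optional `cluster_assignment`.
#' @param differentiation Optional `social_differentiation`.
#' @param perm Optional `assoc_perm_test`.
#' @param fits Optional `slar_fits`.
#' @param alpha Significance level for the permutation decision.
#' @return A list scorecard with whichever of `ari`, `s_hat`, `s_true`,
#'   `s_bias`, `perm_significant`, `best_model` applies.
#' @export
recovery_report <- function(truth, clusters = NULL, differentiation = NULL,
                            perm = NULL, fits = NULL, alpha = 0.05) {
  stopifnot(inherits(truth, "society_truth"))
  out <- list()
  if (!is.null(clusters)) {
    ids <- intersect(names(clusters$labels), names(truth$resident_labels))
    if (!length(ids)) stop("mismatched individual sets", call. = FALSE)
    out$ari <- mclust::adjustedRandIndex(truth$resident_labels[ids],
                                         clusters$labels[ids])
    out$n_matched <- length(ids)
  }
  if (!is.null(differentiation)) {
    out$s_hat <- differentiation$S
    out$s_true <- truth$S_true
    out$s_bias <- differentiation$S - truth$S_true
  }
  if (!is.null(perm)) {
    out$perm_p_sd <- unname(perm$p_value["sd"])
    out$perm_significant <- unname(perm$p_value["sd"] < alpha)
  }
  if (!is.null(fits)) out$best_model <- fits$best
  out
}
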