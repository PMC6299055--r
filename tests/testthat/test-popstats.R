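test_that("homogeneous societies give near-zero differentiation", {
  set.seed(12)
  d <- rep(50L, 500)
  x <- stats::rbinom(500, d, 0.2)
  est <- differentiation_ml(x, d)
  expect_lte(est$S, 0.05)
})

test_that("differentiation recovers a well-differentiated Beta truth", {
  set.seed(71)
  # Beta with mean 0.15 and CV 1: var = (0.15)^2
  mu <- 0.15; cv <- 1
  v <- (cv * mu)^2
  ab <- mu * (1 - mu) / v - 1
  a <- mu * ab; b <- (1 - mu) * ab
  d <- rep(30L, 600)
  p <- stats::rbeta(600, a, b)
  x <- stats::rbinom(600, d, p)
  est <- differentiation_ml(x, d)
  expect_lt(abs(est$S - 1), 0.15)
  expect_gt(est$r, 0.5)
})

test_that("r tends to 1 as sampling effort grows", {
  set.seed(99)
  mu <- 0.2; a <- 2; b <- 8
  rs <- sapply(c(10, 100, 2000), function(dd) {
    d <- rep(as.integer(dd), 400)
    x <- stats::rbinom(400, d, stats::rbeta(400, a, b))
    differentiation_ml(x, d)$r
  })
  expect_true(all(diff(rs) > 0))
  expect_gt(rs[3], 0.95)
})

test_that("the beta-binomial likelihood is stationary at the optimum", {
  set.seed(31)
  d <- rep(25L, 300)
  x <- stats::rbinom(300, d, stats::rbeta(300, 1.5, 6))
  est <- differentiation_ml(x, d)
  ll <- function(mu, th) podnet:::betabinom_loglik(mu, th, x, d)
  eps <- 1e-5
  g_mu <- (ll(est$mu + eps, est$theta) - ll(est$mu - eps, est$theta)) /
    (2 * eps)
  g_th <- (ll(est$mu, est$theta + eps) - ll(est$mu, est$theta - eps)) /
    (2 * eps)
  # gradients small relative to curvature scale of the likelihood
  expect_lt(abs(g_mu), 0.5)
  expect_lt(abs(g_th), 0.5)
})

test_that("Mantel test flags block structure and stays calibrated", {
  set.seed(8)
  m <- am_random(12, blocks = c(6, 6), w = 0.5, b = 0.05, noise = 0.01)
  cl <- stats::setNames(rep(c("u", "v"), each = 6), rownames(m))
  mt <- mantel_class_test(m, cl, n_perm = 2000, seed = 10)
  expect_gt(mt$t, 3)
  # with 12 individuals a random permutation occasionally reproduces the
  # block split, so the attainable p floor is about 2/choose(12,6)
  expect_lte(mt$p_two_sided, 0.02)
  # reproducible
  mt2 <- mantel_class_test(m, cl, n_perm = 2000, seed = 10)
  expect_identical(mt$t, mt2$t)
  # random labels on random structure: p not extreme, t centred
  set.seed(20)
  ps <- replicate(30, {
    mr <- am_random(10, blocks = NULL, w = 0.2, b = 0.2, noise = 0.05)
    clr <- stats::setNames(sample(rep(c("u", "v"), 5)), rownames(mr))
    mantel_class_test(mr, clr, n_perm = 200)$p_two_sided
  })
  expect_gt(mean(ps), 0.3)
  expect_gt(min(ps), 0.001)
})

test_that("Mantel agrees with vegan on the raw matrix correlation", {
  skip_if_not_installed("vegan")
  set.seed(44)
  m <- am_random(10, blocks = c(5, 5))
  cl <- stats::setNames(rep(c("u", "v"), each = 5), rownames(m))
  same <- outer(cl, cl, "==") * 1
  mt <- mantel_class_test(m, cl, n_perm = 100, seed = 1)
  vg <- vegan::mantel(stats::as.dist(unclass(m)), stats::as.dist(same),
                      permutations = 99)
  expect_equal(mt$r_obs, unname(vg$statistic), tolerance = 1e-12)
})

test_that("encounters are assigned to clusters by strict majority", {
  lab <- stats::setNames(c(rep("A", 5), rep("B", 3)),
                         c(paste0("a", 1:5), paste0("b", 1:3)))
  expect_equal(classify_encounter_cluster(paste0("a", 1:5), lab), "A")
  expect_equal(classify_encounter_cluster(c(paste0("a", 1:4), "b1"), lab),
               "A")
  expect_equal(classify_encounter_cluster(c("a1", "a2", "b1", "b2"), lab),
               "mixed-tie")
  expect_equal(classify_encounter_cluster(c("stranger"), lab),
               "unassigned")
})

test_that("diel counts are conserved and uniform schedules are null", {
  sim <- simulate_society(society_preset("paper-like", seed = 77))
  r <- apply_restrictions(sim$encounters)
  labels <- sim$truth$resident_labels
  dt <- diel_partition_test(r, labels, scope = "entire")
  # conservation: per-cluster bins sum to that cluster's binned encounters
  expect_true(all(rowSums(dt$counts) > 0))
  expect_true(dt$fisher_p >= 0 && dt$fisher_p <= 1)

  # uniform times across clusters: no signal
  cluster_of <- rep(c("A", "B"), each = 20)
  enc <- data.frame(
    encounter_id = sprintf("e%d", 1:40),
    date = rep(sprintf("2010-06-%02d", 1:20), 2),
    time_start = rep(c("08:00", "19:00"), 20),
    area = "core", trawler = "none")
  mem <- do.call(rbind, lapply(1:40, function(i) {
    who <- if (cluster_of[i] == "A") c("a1", "a2") else c("b1", "b2")
    data.frame(encounter_id = sprintf("e%d", i), individual_id = who)
  }))
  ind <- data.frame(individual_id = c("a1", "a2", "b1", "b2"),
                    sex = "U", is_calf = 0L)
  t <- as_encounter_table(enc, mem, ind)
  lab <- stats::setNames(c("A", "A", "B", "B"), ind$individual_id)
  dt2 <- diel_partition_test(t, lab, scope = "entire",
                             test_clusters = c("A", "B"))
  expect_gt(dt2$fisher_p, 0.5)
})

test_that("Fisher p matches exhaustive hypergeometric enumeration", {
  enumerate_fisher <- function(a, b, c, d) {
    m <- a + b; n <- c + d; k <- a + c
    xs <- max(0, k - n):min(k, m)
    probs <- stats::dhyper(xs, m, n, k)
    p_obs <- stats::dhyper(a, m, n, k)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  set.seed(3)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 8), 2)
    if (sum(tab) == 0 || sum(tab) > 60) next
    p1 <- stats::fisher.test(tab)$p.value
    p2 <- enumerate_fisher(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    expect_equal(p1, p2, tolerance = 1e-7)
  }
})

test_that("sex composition ignores unsexed members and needs two sexed", {
  enc <- data.frame(encounter_id = c("e1", "e2", "e3"),
                    date = "2010-06-01",
                    time_start = c("08:00", "09:00", "10:00"),
                    area = "core", trawler = "none")
  mem <- data.frame(
    encounter_id = c("e1", "e1", "e1", "e2", "e2", "e3", "e3"),
    individual_id = c("m1", "m2", "u1", "m1", "f1", "u1", "f1"))
  ind <- data.frame(individual_id = c("m1", "m2", "f1", "u1"),
                    sex = c("M", "M", "F", "U"), is_calf = 0L)
  t <- as_encounter_table(enc, mem, ind)
  sc <- sex_composition(t)
  # e1 {M,M,U} male-only; e2 {M,F} mixed; e3 has one sexed -> excluded
  expect_equal(sc$n_groups, 2)
  expect_equal(sc$male_only, 1)
  expect_equal(sc$mixed, 1)
  expect_equal(sc$pct_mixed, 50)
})

test_that("fishery summaries count gears once each and rank individuals", {
  n_enc <- 40
  trawler <- c(rep("pair", 21), rep("bottom", 12), rep("both", 1),
               rep("none", 6))
  enc <- data.frame(encounter_id = sprintf("e%02d", 1:n_enc),
                    date = sprintf("2010-06-%02d", rep(1:20, 2)),
                    time_start = "08:00", area = "core",
                    trawler = trawler)
  # "mor" in 18 of the 35 interactions; "zed" only in the trawler-free
  # tail encounters
  mem <- do.call(rbind, lapply(1:n_enc, function(i) {
    who <- if (i <= 18) c("mor", "oth")
           else if (i <= 35) c("oth", "alt")
           else c("zed")
    data.frame(encounter_id = sprintf("e%02d", i), individual_id = who)
  }))
  ind <- data.frame(individual_id = c("mor", "oth", "alt", "zed"),
                    sex = "U", is_calf = 0L)
  t <- as_encounter_table(enc, mem, ind)
  lab <- stats::setNames(c("A", "A", "B", "Z"), ind$individual_id)
  fr <- fishery_interaction_summary(t, lab)
  expect_equal(fr$n_interactions, 35)  # 22 pair + 13 bottom gear events
  expect_equal(fr$n_interaction_encounters, 34)
  expect_equal(fr$gear$pair, 22)       # 21 pair + 1 both
  expect_equal(fr$gear$bottom, 13)     # 12 bottom + 1 both
  expect_equal(round(fr$gear$pct_pair, 1), 62.9)
  mor <- fr$individuals[fr$individuals$individual_id == "mor", ]
  expect_equal(mor$n_interactions, 18)
  expect_gt(mor$proportion, 0.5)
  # a cluster with zero interactions reports mean 0, range 0-0
  z <- fr$clusters[fr$clusters$cluster == "Z", ]
  expect_equal(z$mean, 0)
  expect_equal(c(z$min, z$max), c(0, 0))
})
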