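test_that("encounter tables round-trip through CSV field for field", {
  f <- enc_fixture()
  dir <- withr::local_tempdir()
  t1 <- as_encounter_table(f$enc, f$mem, f$ind)
  write_encounters(t1, dir)
  t2 <- read_encounters(file.path(dir, "encounters.csv"),
                        file.path(dir, "memberships.csv"),
                        file.path(dir, "individuals.csv"))
  expect_equal(t2$encounters, t1$encounters)
  expect_equal(t2$memberships, t1$memberships)
  expect_equal(t2$individuals, t1$individuals)
  expect_equal(nrow(t1$encounters), 5)
  expect_equal(nrow(t1$memberships), 10)
})

test_that("validation rejects broken inputs with informative errors", {
  f <- enc_fixture()
  enc_dup <- rbind(f$enc, f$enc[1, ])
  expect_error(as_encounter_table(enc_dup, f$mem, f$ind),
               "duplicate encounter id")
  mem_bad <- rbind(f$mem, data.frame(encounter_id = "e1",
                                     individual_id = "ghost"))
  expect_error(as_encounter_table(f$enc, mem_bad, f$ind), "ghost")
  enc_bad <- f$enc; enc_bad$date[2] <- "01/06/2010"
  expect_error(as_encounter_table(enc_bad, f$mem, f$ind),
               "unparseable date.*2")
  enc_bad2 <- f$enc; enc_bad2$time_start[3] <- "25:99"
  expect_error(as_encounter_table(enc_bad2, f$mem, f$ind),
               "time_start")
  mem_twice <- rbind(f$mem, f$mem[1, ])
  expect_error(as_encounter_table(f$enc, mem_twice, f$ind),
               "more than once")
})

test_that("restriction keeps residents, drops transients and calves", {
  f <- enc_fixture()
  # calf k rides along on e1
  f$mem <- rbind(f$mem, data.frame(encounter_id = "e1",
                                   individual_id = "k"))
  t <- as_encounter_table(f$enc, f$mem, f$ind)
  r <- apply_restrictions(t, min_occasions = 4, min_years = 2)
  ret <- attr(r, "retained_ids")
  # a and b: 4 encounters across 2010 and 2011 -> retained
  expect_setequal(ret, c("a", "b"))
  # c, d: a single sighting; k: calf -> all gone
  expect_false(any(c("c", "d", "k") %in% r$memberships$individual_id))
  # e2 (c,d only) dropped entirely
  expect_false("e2" %in% r$encounters$encounter_id)
})

test_that("individuals seen often but in a single year are removed", {
  enc <- data.frame(
    encounter_id = sprintf("e%d", 1:12),
    date = c(sprintf("2010-06-%02d", 1:10), "2010-07-01", "2011-07-01"),
    time_start = rep("08:00", 12), area = rep("core", 12),
    trawler = rep("none", 12))
  # v: 10 sightings all in 2010; a,b: spread over both years
  mem <- rbind(
    data.frame(encounter_id = sprintf("e%d", 1:10), individual_id = "v"),
    data.frame(encounter_id = sprintf("e%d", c(1:3, 11, 12)),
               individual_id = "a"),
    data.frame(encounter_id = sprintf("e%d", c(4:6, 11, 12)),
               individual_id = "b"))
  ind <- data.frame(individual_id = c("v", "a", "b"),
                    sex = "U", is_calf = 0L)
  r <- apply_restrictions(as_encounter_table(enc, mem, ind))
  expect_setequal(attr(r, "retained_ids"), c("a", "b"))
})

test_that("same-day duplicates are merged only when membership matches", {
  enc <- data.frame(
    encounter_id = c("x1", "x2", "x3", sprintf("y%d", 1:6)),
    date = c("2010-06-01", "2010-06-01", "2010-06-01",
             sprintf("2010-07-%02d", 1:3), sprintf("2011-07-%02d", 1:3)),
    time_start = c("08:00", "10:00", "12:00", rep("09:00", 6)),
    area = "core", trawler = "none")
  mem <- rbind(
    data.frame(encounter_id = c("x1", "x1"), individual_id = c("a", "b")),
    data.frame(encounter_id = c("x2", "x2"), individual_id = c("a", "b")),
    data.frame(encounter_id = c("x3"), individual_id = c("a")),
    do.call(rbind, lapply(c(sprintf("y%d", 1:6)), function(e)
      data.frame(encounter_id = e, individual_id = c("a", "b")))))
  ind <- data.frame(individual_id = c("a", "b"), sex = "U", is_calf = 0L)
  r <- apply_restrictions(as_encounter_table(enc, mem, ind))
  # x2 duplicates x1 (same retained membership, same day, later) -> gone;
  # x3 has a different membership set -> kept
  expect_false("x2" %in% r$encounters$encounter_id)
  expect_true(all(c("x1", "x3") %in% r$encounters$encounter_id))
})

test_that("restriction is idempotent and errors when nothing survives", {
  sim <- simulate_society(society_preset("paper-like", seed = 42))
  r1 <- apply_restrictions(sim$encounters)
  r2 <- apply_restrictions(r1)
  expect_identical(attr(r2, "retained_ids"), attr(r1, "retained_ids"))
  expect_equal(r2$encounters$encounter_id, r1$encounters$encounter_id)
  expect_equal(r2$memberships, r1$memberships)

  f <- enc_fixture()
  t <- as_encounter_table(f$enc, f$mem, f$ind)
  expect_error(apply_restrictions(t, min_occasions = 100),
               "no individuals retained")
})

test_that("period matrices tile days correctly and conserve sightings", {
  f <- enc_fixture()
  t <- as_encounter_table(f$enc, f$mem, f$ind)
  r <- apply_restrictions(t, min_occasions = 2, min_years = 1)
  pm1 <- build_period_matrices(r, 1)
  # e1/e3 on separate days in 2010, e4, e5 in 2011 -> 4 day-periods
  expect_length(pm1$matrices, 4)
  pm5 <- build_period_matrices(r, 5)
  expect_lt(length(pm5$matrices), 4)
  # total column sums across periods equal per-individual sightings
  tot <- Reduce(`+`, lapply(pm1$matrices, colSums))
  sightings <- table(r$memberships$individual_id)
  expect_equal(unname(tot[names(sightings)]), as.numeric(sightings))
  expect_error(build_period_matrices(r, 0), "period_length_days")
})

test_that("an individual in two groups in one period has column sum 2", {
  pm <- pm_make(list(list(c("a", "b"), c("a", "c"))))
  expect_equal(colSums(pm$matrices[[1]])[["a"]], 2)
  expect_equal(colSums(pm$matrices[[1]])[["b"]], 1)
})
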