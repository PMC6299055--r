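#' Read photo-identification encounter records
#'
#' Reads the three-file encounter contract used throughout the package:
#' an encounter table, a group-membership table and an individual registry,
#' and validates their referential integrity. Every downstream analysis
#' starts from the object this function returns.
#'
#' @param encounters Path to `encounters.csv` with columns
#'   `encounter_id`, `date` (ISO-8601), `time_start` (`HH:MM`),
#'   `area` (`core`/`other`) and `trawler` (`none`/`pair`/`bottom`/`both`).
#' @param memberships Path to `memberships.csv` with columns
#'   `encounter_id`, `individual_id`.
#' @param individuals Path to `individuals.csv` with columns
#'   `individual_id`, `sex` (`F`/`M`/`U`) and `is_calf` (`0`/`1`).
#' @return An object of class `encounter_table`: a list with elements
#'   `encounters`, `memberships` and `individuals` (data frames).
#' @seealso [apply_restrictions()], [build_period_matrices()],
#'   [write_encounters()]
#' @export
read_encounters <- function(encounters, memberships, individuals) {
  for (p in c(encounters, memberships, individuals)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  enc <- utils::read.csv(encounters, colClasses = "character",
                         fileEncoding = "UTF-8")
  mem <- utils::read.csv(memberships, colClasses = "character",
                         fileEncoding = "UTF-8")
  ind <- utils::read.csv(individuals, colClasses = "character",
                         fileEncoding = "UTF-8")
  as_encounter_table(enc, mem, ind)
}

#' Assemble and validate an encounter table from data frames
#'
#' @param encounters,memberships,individuals Data frames matching the CSV
#'   schema documented in [read_encounters()].
#' @return A validated `encounter_table`.
#' @export
as_encounter_table <- function(encounters, memberships, individuals) {
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      stop(what, ": missing column(s) ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
  }
  need(encounters, c("encounter_id", "date", "time_start", "area", "trawler"),
       "encounters")
  need(memberships, c("encounter_id", "individual_id"), "memberships")
  need(individuals, c("individual_id", "sex", "is_calf"), "individuals")

  enc <- encounters
  enc$encounter_id <- as.character(enc$encounter_id)
  if (anyDuplicated(enc$encounter_id)) {
    dup <- unique(enc$encounter_id[duplicated(enc$encounter_id)])
    stop("duplicate encounter id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  d <- as.Date(as.character(enc$date), format = "%Y-%m-%d")
  if (anyNA(d)) {
    bad <- which(is.na(d))
    stop("unparseable date(s) in encounters row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  enc$date <- d
  tm <- as.character(enc$time_start)
  ok <- grepl("^([01][0-9]|2[0-3]):[0-5][0-9]$", tm)
  if (!all(ok)) {
    stop("unparseable time_start in encounters row(s) ",
         paste(which(!ok), collapse = ", "), call. = FALSE)
  }
  enc$time_start <- tm
  enc$area <- match_levels(enc$area, c("core", "other"), "area")
  enc$trawler <- match_levels(enc$trawler, c("none", "pair", "bottom", "both"),
                              "trawler")

  ind <- individuals
  ind$individual_id <- as.character(ind$individual_id)
  if (anyDuplicated(ind$individual_id)) {
    dup <- unique(ind$individual_id[duplicated(ind$individual_id)])
    stop("duplicate individual id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  ind$sex <- match_levels(ind$sex, c("F", "M", "U"), "sex")
  calf <- as.character(ind$is_calf)
  if (!all(calf %in% c("0", "1", "TRUE", "FALSE"))) {
    stop("is_calf must be 0/1", call. = FALSE)
  }
  ind$is_calf <- calf %in% c("1", "TRUE")

  mem <- memberships
  mem$encounter_id <- as.character(mem$encounter_id)
  mem$individual_id <- as.character(mem$individual_id)
  bad_enc <- setdiff(mem$encounter_id, enc$encounter_id)
  if (length(bad_enc)) {
    stop("membership references unknown encounter id(s): ",
         paste(bad_enc, collapse = ", "), call. = FALSE)
  }
  bad_ind <- setdiff(mem$individual_id, ind$individual_id)
  if (length(bad_ind)) {
    stop("membership references unknown individual id(s): ",
         paste(bad_ind, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(mem[c("encounter_id", "individual_id")])) {
    stop("an individual appears more than once in the same encounter",
         call. = FALSE)
  }

  structure(list(encounters = enc, memberships = mem, individuals = ind),
            class = "encounter_table")
}

match_levels <- function(x, levels, what) {
  x <- as.character(x)
  bad <- !x %in% levels
  if (any(bad)) {
    stop(what, ": invalid value(s) ",
         paste(unique(x[bad]), collapse = ", "),
         " (expected one of ", paste(levels, collapse = "/"), ")",
         call. = FALSE)
  }
  factor(x, levels = levels)
}

#' Write an encounter table back to the three-CSV contract
#'
#' @param x An `encounter_table`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the three file paths written.
#' @export
write_encounters <- function(x, dir) {
  stopifnot(inherits(x, "encounter_table"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  enc <- x$encounters
  enc$date <- format(enc$date, "%Y-%m-%d")
  ind <- x$individuals
  ind$is_calf <- as.integer(ind$is_calf)
  paths <- file.path(dir, c("encounters.csv", "memberships.csv",
                            "individuals.csv"))
  utils::write.csv(enc, paths[1], row.names = FALSE, quote = FALSE)
  utils::write.csv(x$memberships, paths[2], row.names = FALSE, quote = FALSE)
  utils::write.csv(ind, paths[3], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' @export
print.encounter_table <- function(x, ...) {
  cat("Encounter table:", nrow(x$encounters), "encounters,",
      nrow(x$memberships), "memberships,",
      nrow(x$individuals), "individuals\n")
  cat("  dates:", format(min(x$encounters$date)), "to",
      format(max(x$encounters$date)), "\n")
  ret <- attr(x, "retained_ids")
  if (!is.null(ret)) {
    cat("  restricted:", length(ret), "retained individuals\n")
  }
  invisible(x)
}

#' Apply sighting-frequency restrictions to an encounter table
#'
#' Restricts the data to regularly seen ("resident") individuals before
#' association analysis, because rarely seen transients bias association
#' indices. Mother-dependent calves are removed first (their presence is
#' not independent of the mother's). An individual is retained only if it
#' was encountered on at least `min_occasions` occasions *and* in at least
#' `min_years` distinct calendar years. Same-day encounters whose retained
#' membership is identical are treated as repeat records of one group and
#' deduplicated (the earliest is kept); encounters left without retained
#' members are dropped. Because deduplication can lower sighting counts,
#' the filter is iterated to a fixed point, which makes it idempotent.
#'
#' @param x An `encounter_table`.
#' @param min_occasions Minimum number of encounters (default 4).
#' @param min_years Minimum number of distinct years (default 2).
#' @return The restricted `encounter_table`, with attribute
#'   `retained_ids` (character vector) and attribute `restriction`
#'   (a summary list, see [restriction_summary()]).
#' @export
apply_restrictions <- function(x, min_occasions = 4, min_years = 2) {
  stopifnot(inherits(x, "encounter_table"))
  enc <- x$encounters
  mem <- x$memberships
  ind <- x$individuals

  calves <- ind$individual_id[ind$is_calf]
  mem <- mem[!mem$individual_id %in% calves, , drop = FALSE]

  repeat {
    yr <- as.integer(format(enc$date, "%Y"))
    names(yr) <- enc$encounter_id
    occ <- table(mem$individual_id)
    yrs <- tapply(yr[mem$encounter_id], mem$individual_id,
                  function(v) length(unique(v)))
    keep_ids <- names(occ)[occ >= min_occasions & yrs[names(occ)] >= min_years]
    mem2 <- mem[mem$individual_id %in% keep_ids, , drop = FALSE]

    # same-day duplicates: identical retained-membership sets, keep earliest
    sets <- tapply(mem2$individual_id, mem2$encounter_id,
                   function(v) paste(sort(v), collapse = "|"))
    enc2 <- enc[enc$encounter_id %in% names(sets), , drop = FALSE]
    key <- paste(format(enc2$date), sets[enc2$encounter_id], sep = "@")
    ord <- order(enc2$date, enc2$time_start)
    enc2 <- enc2[ord, , drop = FALSE]
    enc2 <- enc2[!duplicated(key[ord]), , drop = FALSE]
    mem2 <- mem2[mem2$encounter_id %in% enc2$encounter_id, , drop = FALSE]

    stable <- identical(sort(unique(mem2$individual_id)),
                        sort(unique(mem$individual_id))) &&
      nrow(enc2) == nrow(enc)
    enc <- enc2[order(enc2$date, enc2$time_start), , drop = FALSE]
    mem <- mem2
    if (stable) break
    if (nrow(mem) == 0L) break
  }

  retained <- sort(unique(mem$individual_id))
  if (length(retained) == 0L) {
    stop("no individuals retained after restriction", call. = FALSE)
  }
  rownames(enc) <- NULL
  rownames(mem) <- NULL
  out <- structure(list(encounters = enc, memberships = mem,
                        individuals = ind),
                   class = "encounter_table")
  attr(out, "retained_ids") <- retained
  attr(out, "restriction") <- restriction_summary_(out, retained)
  out
}

restriction_summary_ <- function(x, retained) {
  occ <- table(factor(x$memberships$individual_id, levels = retained))
  n <- as.integer(occ)
  list(
    n_individuals = length(retained),
    n_encounters = nrow(x$encounters),
    sightings = stats::setNames(n, retained),
    mean_sightings = mean(n),
    sd_sightings = stats::sd(n),
    range_sightings = range(n),
    pct_ge_5 = 100 * mean(n >= 5),
    pct_ge_10 = 100 * mean(n >= 10)
  )
}

#' Sighting-frequency summary of a restricted encounter table
#'
#' Reports per-individual sighting counts and the proportions of retained
#' individuals seen at least 5 and at least 10 times, the figures usually
#' quoted when describing a restricted photo-ID data set.
#'
#' @param x An `encounter_table` returned by [apply_restrictions()].
#' @return A list with `n_individuals`, `n_encounters`, `sightings`,
#'   `mean_sightings`, `sd_sightings`, `range_sightings`, `pct_ge_5`,
#'   `pct_ge_10`.
#' @export
restriction_summary <- function(x) {
  s <- attr(x, "restriction")
  if (is.null(s)) stop("x has not been through apply_restrictions()",
                       call. = FALSE)
  s
}

#' Build per-period group-by-individual incidence matrices
#'
#' Divides the study into sampling periods of `period_length_days` days
#' (tiled from the first observation date, day periods anchored at local
#' midnight) and builds, for each period, a binary group x individual
#' incidence matrix. Two individuals are taken to be associated within a
#' period if and only if they share at least one group in that period
#' ("gambit of the group"). Columns cover exactly the individuals present
#' in the (restricted) membership table, in a fixed sorted order shared by
#' all periods.
#'
#' @param x An `encounter_table`, normally restricted.
#' @param period_length_days Length of a sampling period in days
#'   (default 1, i.e. calendar day).
#' @return An object of class `period_matrices`: a list with `matrices`
#'   (one binary matrix per non-empty period), `period_start` (`Date`),
#'   `period_mid` (numeric days, used for lags), `ids`,
#'   `period_length_days`.
#' @export
build_period_matrices <- function(x, period_length_days = 1) {
  stopifnot(inherits(x, "encounter_table"))
  if (period_length_days < 1) {
    stop("period_length_days must be >= 1", call. = FALSE)
  }
  mem <- x$memberships
  enc <- x$encounters
  ids <- sort(unique(mem$individual_id))
  if (length(ids) == 0L) stop("no memberships to build matrices from",
                              call. = FALSE)
  day0 <- min(enc$date)
  pidx <- as.integer(floor(as.numeric(enc$date - day0) / period_length_days))
  names(pidx) <- enc$encounter_id
  periods <- sort(unique(pidx[mem$encounter_id]))

  mats <- vector("list", length(periods))
  for (i in seq_along(periods)) {
    eids <- enc$encounter_id[pidx == periods[i]]
    eids <- intersect(eids, unique(mem$encounter_id))
    m <- matrix(0L, nrow = length(eids), ncol = length(ids),
                dimnames = list(eids, ids))
    sub <- mem[mem$encounter_id %in% eids, , drop = FALSE]
    m[cbind(match(sub$encounter_id, eids), match(sub$individual_id, ids))] <- 1L
    mats[[i]] <- m
  }
  start <- day0 + periods * period_length_days
  mid <- as.numeric(start - day0) + (period_length_days - 1) / 2
  structure(list(matrices = mats, period_start = start, period_mid = mid,
                 ids = ids, period_length_days = period_length_days),
            class = "period_matrices")
}

#' @export
print.period_matrices <- function(x, ...) {
  cat("Period matrices:", length(x$matrices), "periods of",
      x$period_length_days, "day(s),", length(x$ids), "individuals\n")
  cat("  groups per period:",
      paste(range(vapply(x$matrices, nrow, 1L)), collapse = "-"), "\n")
  invisible(x)
}

# Per-period binary association matrices (share >= 1 group) and
# identification indicators; the common substrate for indices, the
# permutation chain and SLAR.
period_joint <- function(pm) {
  n <- length(pm$ids)
  lapply(pm$matrices, function(m) {
    j <- crossprod(m) > 0
    diag(j) <- FALSE
    storage.mode(j) <- "integer"
    j
  })
}

period_seen <- function(pm) {
  do.call(rbind, lapply(pm$matrices, function(m) as.integer(colSums(m) > 0)))
}
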