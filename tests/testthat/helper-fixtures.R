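# Fixture builders shared across the suite. Everything is constructed in
# code; no data files.

# period_matrices from a list of periods, each a list of groups
# (character vectors of individual ids). Days default to consecutive.
pm_make <- function(periods, ids = NULL, days = seq_along(periods),
                    period_length = 1) {
  if (is.null(ids)) ids <- sort(unique(unlist(periods)))
  mats <- lapply(seq_along(periods), function(p) {
    groups <- periods[[p]]
    m <- matrix(0L, nrow = length(groups), ncol = length(ids),
                dimnames = list(sprintf("g%d_%d", p, seq_along(groups)),
                                ids))
    for (g in seq_along(groups)) m[g, groups[[g]]] <- 1L
    m
  })
  day0 <- as.Date("2010-01-01")
  structure(list(matrices = mats,
                 period_start = day0 + (days - 1) * period_length,
                 period_mid = (days - 1) * period_length +
                   (period_length - 1) / 2,
                 ids = ids, period_length_days = period_length),
            class = "period_matrices")
}

# a bare assoc_matrix from a symmetric numeric matrix
am_make <- function(m, flavor = "HWI") {
  ids <- rownames(m)
  if (is.null(ids)) {
    ids <- sprintf("i%02d", seq_len(nrow(m)))
    dimnames(m) <- list(ids, ids)
  }
  diag(m) <- 0
  podnet:::assoc_matrix(m, flavor, ids)
}

# random symmetric association matrix with planted block structure
am_random <- function(n, blocks = NULL, w = 0.4, b = 0.05, noise = 0.02) {
  m <- matrix(0, n, n)
  lab <- if (is.null(blocks)) rep(1, n) else rep(seq_along(blocks), blocks)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      base <- if (lab[i] == lab[j]) w else b
      v <- max(0, min(1, base + stats::rnorm(1, 0, noise)))
      m[i, j] <- m[j, i] <- v
    }
  }
  am_make(m)
}

# small encounter table as three data frames (valid input for
# as_encounter_table)
enc_fixture <- function() {
  enc <- data.frame(
    encounter_id = c("e1", "e2", "e3", "e4", "e5"),
    date = c("2010-06-01", "2010-06-01", "2010-06-02", "2011-07-10",
             "2011-07-11"),
    time_start = c("08:00", "19:30", "09:15", "08:45", "10:00"),
    area = c("core", "core", "other", "core", "core"),
    trawler = c("none", "pair", "none", "bottom", "none"),
    stringsAsFactors = FALSE)
  mem <- data.frame(
    encounter_id = c("e1", "e1", "e2", "e2", "e3", "e3", "e4", "e4",
                     "e5", "e5"),
    individual_id = c("a", "b", "c", "d", "a", "b", "a", "b", "a", "b"),
    stringsAsFactors = FALSE)
  ind <- data.frame(
    individual_id = c("a", "b", "c", "d", "k"),
    sex = c("F", "M", "M", "U", "U"),
    is_calf = c(0L, 0L, 0L, 0L, 1L),
    stringsAsFactors = FALSE)
  list(enc = enc, mem = mem, ind = ind)
}

# independent per-period double-loop oracle for HWI
hwi_oracle <- function(pm) {
  ids <- pm$ids
  n <- length(ids)
  x <- matrix(0, n, n); seen <- rep(0, n)
  for (m in pm$matrices) {
    inp <- colSums(m) > 0
    seen <- seen + inp
    for (a in seq_len(n - 1)) {
      for (b in (a + 1):n) {
        tog <- any(m[, a] == 1 & m[, b] == 1)
        if (tog) { x[a, b] <- x[a, b] + 1; x[b, a] <- x[b, a] + 1 }
      }
    }
  }
  h <- matrix(0, n, n)
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      d <- (seen[a] + seen[b]) / 2
      h[a, b] <- h[b, a] <- if (d > 0) x[a, b] / d else 0
    }
  }
  dimnames(h) <- list(ids, ids)
  h
}

# random period_matrices: n individuals, P periods, random groups
pm_random <- function(n = 8, P = 12, p_attend = 0.6, max_groups = 3) {
  ids <- sprintf("i%02d", seq_len(n))
  periods <- lapply(seq_len(P), function(p) {
    present <- ids[stats::runif(n) < p_attend]
    if (length(present) < 1) present <- sample(ids, 1)
    ng <- sample.int(max_groups, 1)
    gi <- sample.int(ng, length(present), replace = TRUE)
    unname(split(present, gi))
  })
  pm_make(periods, ids = ids)
}

# exhaustive maximum-modularity partition for small n (Bell-number scan)
best_partition_oracle <- function(m) {
  n <- nrow(m)
  parts <- list(list(1L))
  for (i in 2:n) {
    parts <- unlist(lapply(parts, function(p) {
      c(lapply(seq_along(p), function(k) {
        p2 <- p; p2[[k]] <- c(p2[[k]], i); p2
      }), list(c(p, list(i))))
    }), recursive = FALSE)
  }
  best_q <- -Inf; best <- NULL; n_best <- 0L
  for (p in parts) {
    lab <- integer(n)
    for (k in seq_along(p)) lab[p[[k]]] <- k
    q <- modularity_q(m, stats::setNames(as.character(lab), rownames(m)))
    if (q > best_q + 1e-12) { best_q <- q; best <- lab; n_best <- 1L }
    else if (abs(q - best_q) <= 1e-12) n_best <- n_best + 1L
  }
  list(q = best_q, labels = best, unique = n_best == 1L)
}
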