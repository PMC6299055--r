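#' One checkerboard flip on period incidence matrices
#'
#' Attempts a single 2x2 checkerboard swap (`[1,0;0,1] <-> [0,1;1,0]`)
#' across two groups and two individuals within one sampling period. The
#' move preserves every group size and every per-period identification
#' count, and never moves an individual across periods; it is the
#' elementary step of the within-sample permutation null.
#'
#' @param pm A `period_matrices` object.
#' @param max_tries Number of uniformly drawn candidate submatrices to
#'   examine before giving up (default 1000).
#' @return A list with `pm` (flipped, or the input if no candidate was
#'   found), `flipped` (logical) and `period` (index flipped, or `NA`).
#' @export
checkerboard_flip <- function(pm, max_tries = 1000) {
  stopifnot(inherits(pm, "period_matrices"))
  sizes <- vapply(pm$matrices, nrow, 1L)
  n <- length(pm$ids)
  w <- ifelse(sizes >= 2, sizes * n, 0)
  if (all(w == 0) || n < 2) {
    return(list(pm = pm, flipped = FALSE, period = NA_integer_))
  }
  for (t in seq_len(max_tries)) {
    p <- sample.int(length(w), 1, prob = w)
    m <- pm$matrices[[p]]
    r <- sample.int(nrow(m), 2)
    cc <- sample.int(n, 2)
    sub <- m[r, cc]
    if (all(diag(sub) == 1L) && sub[1, 2] == 0L && sub[2, 1] == 0L ||
        all(diag(sub) == 0L) && sub[1, 2] == 1L && sub[2, 1] == 1L) {
      m[r, cc] <- 1L - sub
      pm$matrices[[p]] <- m
      return(list(pm = pm, flipped = TRUE, period = p))
    }
  }
  list(pm = pm, flipped = FALSE, period = NA_integer_)
}

#' Permutation test for preferred and avoided companionship
#'
#' Manly-Bejder within-sample permutation test. A Markov chain of
#' checkerboard flips randomises group membership within sampling periods
#' while holding group sizes and individual identification frequencies
#' fixed; every `flips_between_saves` flips the half-weight index matrix
#' is recomputed and the standard deviation and coefficient of variation
#' of the dyadic indices are saved. Observed SD/CV larger than the
#' permuted distribution indicates preferred or avoided companions.
#'
#' @param pm A `period_matrices` object.
#' @param n_perm Number of saved permutations (default 20000).
#' @param flips_between_saves Chain steps between saves. The default
#'   (`NULL`) adapts to the data: five times the number of occupied
#'   incidence cells, at least 1000; saves taken more often than the
#'   chain mixes under-disperse the null and inflate the test.
#' @param burn_in Steps discarded before the first save (default: ten
#'   times `flips_between_saves`).
#' @param seed Optional integer seed for reproducibility.
#' @param alternative `"greater"` (default, the directional test for
#'   preferred/avoided companions) or `"two.sided"`.
#' @return An object of class `assoc_perm_test`: observed and null
#'   SD/CV, p-values, the p-value trace after each save, and the chain
#'   settings.
#' @export
permutation_test <- function(pm, n_perm = 20000,
                             flips_between_saves = NULL,
                             burn_in = NULL, seed = NULL,
                             alternative = c("greater", "two.sided")) {
  stopifnot(inherits(pm, "period_matrices"))
  alternative <- match.arg(alternative)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  if (is.null(flips_between_saves)) {
    occupied <- sum(vapply(pm$matrices, sum, 1))
    flips_between_saves <- max(1000, 5 * occupied)
  }
  if (is.null(burn_in)) burn_in <- 10 * flips_between_saves
  if (!is.null(seed)) set.seed(seed)

  counts <- dyad_counts(pm)
  h <- hwi(counts)
  v <- h[upper.tri(h)]
  obs <- c(sd = stats::sd(v), cv = stats::sd(v) / mean(v))
  if (!is.finite(obs["cv"]) || obs["sd"] == 0) {
    stop("degenerate data: dyadic indices have no variation ",
         "(all individuals always together?); test refused", call. = FALSE)
  }
  sizes <- vapply(pm$matrices, nrow, 1L)
  if (all(sizes < 2)) {
    stop("no period contains two groups; within-sample flips impossible",
         call. = FALSE)
  }

  seen <- colSums(period_seen(pm))
  res <- .perm_chain(pm$matrices, as.integer(seen), as.integer(n_perm),
                     as.integer(flips_between_saves), as.integer(burn_in),
                     FALSE)
  null_sd <- res$stats[, 1]
  null_cv <- res$stats[, 2]

  pval <- function(null, o) {
    if (alternative == "greater") mean(null >= o)
    else mean(abs(null - mean(null)) >= abs(o - mean(null)))
  }
  trace_p <- function(null, o) {
    if (alternative == "greater") cumsum(null >= o) / seq_along(null)
    else {
      # two-sided trace uses the running null mean
      sapply(seq_along(null), function(k) {
        nn <- null[1:k]
        mean(abs(nn - mean(nn)) >= abs(o - mean(nn)))
      })
    }
  }
  structure(list(
    observed = obs,
    null_mean = c(sd = mean(null_sd), cv = mean(null_cv)),
    null_distribution = list(sd = null_sd, cv = null_cv),
    p_value = c(sd = pval(null_sd, obs["sd"]), cv = pval(null_cv, obs["cv"])),
    p_trace = list(sd = trace_p(null_sd, obs["sd"]),
                   cv = trace_p(null_cv, obs["cv"])),
    n_permutations = n_perm,
    flips_between_saves = flips_between_saves,
    burn_in = burn_in,
    accepted_flips = res$accepted,
    alternative = alternative,
    seed = seed), class = "assoc_perm_test")
}

#' @export
print.assoc_perm_test <- function(x, ...) {
  cat("Within-sample permutation test (", x$n_permutations,
      " permutations, ", x$flips_between_saves, " flips between saves)\n",
      sep = "")
  cat(sprintf("  SD: observed %.4f, random %.4f, P = %.4g\n",
              x$observed["sd"], x$null_mean["sd"], x$p_value["sd"]))
  cat(sprintf("  CV: observed %.4f, random %.4f, P = %.4g\n",
              x$observed["cv"], x$null_mean["cv"], x$p_value["cv"]))
  cat("  alternative:", x$alternative, "\n")
  invisible(x)
}

#' Write a permutation-test result to JSON (and optionally CSV)
#'
#' @param x An `assoc_perm_test`.
#' @param path JSON output path.
#' @param null_csv Optional CSV path for the saved null distribution.
#' @return Invisibly, the paths written.
#' @export
write_perm_test <- function(x, path, null_csv = NULL) {
  stopifnot(inherits(x, "assoc_perm_test"))
  out <- list(observed = as.list(x$observed),
              null_mean = as.list(x$null_mean),
              p_value = as.list(x$p_value),
              n_permutations = x$n_permutations,
              flips_between_saves = x$flips_between_saves,
              burn_in = x$burn_in,
              alternative = x$alternative,
              seed = x$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  written <- path
  if (!is.null(null_csv)) {
    utils::write.csv(data.frame(sd = x$null_distribution$sd,
                                cv = x$null_distribution$cv),
                     null_csv, row.names = FALSE)
    written <- c(written, null_csv)
  }
  invisible(written)
}
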