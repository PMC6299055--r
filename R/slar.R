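#' Standardized lagged association rate (SLAR)
#'
#' Estimates the probability that, given two individuals were associated
#' in some sampling period, a randomly chosen current associate of the
#' first is the second individual again after a time lag. For every
#' ordered pair of periods (j, k) with k later than j, the estimator
#' accumulates, over individuals A and partners B:
#' numerator `a_j(A,B) * a_k(A,B)` and denominator
#' `a_j(A,B) * 1[A identified in k] * n_k(A)`, where `a_j` is
#' within-period association and `n_k(A)` the number of identified
#' associates of A in period k. Pair terms are sorted by lag (measured
#' between period midpoints, in days) and pooled into non-overlapping
#' moving-average windows whose summed denominator reaches
#' `moving_average_size`; each window yields one estimate plotted at the
#' denominator-weighted mean lag.
#'
#' @param pm A `period_matrices` object (at least 2 periods).
#' @param moving_average_size Target summed denominator per window
#'   (default 8000 associations).
#' @return An object of class `slar_curve`: `bins` (data frame with
#'   `tau`, `g`, `se`, `num`, `den`, `null`), the per-period-pair term
#'   table used for jackknifing and nulls, and settings.
#' @seealso [jackknife_se()], [null_rate()], [fit_social_models()]
#' @export
slar <- function(pm, moving_average_size = 8000) {
  stopifnot(inherits(pm, "period_matrices"))
  P <- length(pm$matrices)
  if (P < 2) stop("need at least 2 periods", call. = FALSE)
  terms <- slar_terms(pm)
  if (all(terms$den == 0)) {
    warning("all SLAR denominators are zero; empty curve")
    bins <- data.frame(tau = numeric(0), g = numeric(0), se = numeric(0),
                       num = numeric(0), den = numeric(0), null = numeric(0))
    return(structure(list(bins = bins, terms = terms,
                          moving_average_size = moving_average_size,
                          n_periods = P, ids = pm$ids),
                     class = "slar_curve"))
  }
  terms <- terms[terms$den > 0, , drop = FALSE]
  terms <- terms[order(terms$lag), , drop = FALSE]

  # greedy non-overlapping windows on the lag-sorted terms
  bin <- integer(nrow(terms))
  acc <- 0; b <- 1L
  for (i in seq_len(nrow(terms))) {
    bin[i] <- b
    acc <- acc + terms$den[i]
    if (acc >= moving_average_size && i < nrow(terms)) {
      b <- b + 1L
      acc <- 0
    }
  }
  # a short trailing window is pooled with its neighbour
  if (b > 1L) {
    last_den <- sum(terms$den[bin == b])
    if (last_den < moving_average_size / 2) bin[bin == b] <- b - 1L
  }
  terms$bin <- bin

  bins <- bin_slar_terms(terms)
  structure(list(bins = bins, terms = terms,
                 moving_average_size = moving_average_size,
                 n_periods = P, ids = pm$ids),
            class = "slar_curve")
}

# per ordered period pair (j earlier, k later): lag, numerator and
# denominator totals of the SLAR estimator
slar_terms <- function(pm) {
  joint <- period_joint(pm)
  seen <- period_seen(pm)              # P x N identification indicators
  P <- length(joint)
  n <- length(pm$ids)
  V <- matrix(0, P, n * n)
  DEG <- matrix(0, P, n)
  for (p in seq_len(P)) {
    V[p, ] <- as.numeric(joint[[p]])
    DEG[p, ] <- rowSums(joint[[p]])
  }
  num_all <- tcrossprod(V)             # sum over ordered (A,B) of a_j * a_k
  den_all <- tcrossprod(DEG * seen)    # sum over A of deg_j * seen_k * deg_k
  jk <- which(upper.tri(num_all), arr.ind = TRUE)
  data.frame(j = jk[, 1], k = jk[, 2],
             lag = pm$period_mid[jk[, 2]] - pm$period_mid[jk[, 1]],
             num = num_all[jk], den = den_all[jk])
}

bin_slar_terms <- function(terms) {
  f <- factor(terms$bin, levels = sort(unique(terms$bin)))
  num <- tapply(terms$num, f, sum)
  den <- tapply(terms$den, f, sum)
  tau <- tapply(terms$lag * terms$den, f, sum) / den
  data.frame(tau = as.numeric(tau), g = as.numeric(num / den),
             se = NA_real_, num = as.numeric(num), den = as.numeric(den),
             null = NA_real_, row.names = NULL)
}

#' Temporal jackknife standard errors for a SLAR curve
#'
#' Omits one sampling period at a time, recomputes the lagged association
#' rate in each moving-average window (window boundaries held fixed), and
#' reports `SE = sqrt(((n-1)/n) * sum((g_(i) - mean(g_(i)))^2))` per
#' window, where n is the number of periods. Windows whose denominator
#' vanishes when a period is dropped get a missing SE and a warning.
#'
#' @param curve A `slar_curve`.
#' @return The curve with `bins$se` filled in.
#' @export
jackknife_se <- function(curve) {
  stopifnot(inherits(curve, "slar_curve"))
  P <- curve$n_periods
  if (P < 3) stop("need at least 3 periods to jackknife", call. = FALSE)
  tm <- curve$terms
  nb <- nrow(curve$bins)
  if (nb == 0) return(curve)
  ub <- sort(unique(tm$bin))
  g_i <- matrix(NA_real_, P, nb)
  for (i in seq_len(P)) {
    keep <- tm$j != i & tm$k != i
    num <- tapply(tm$num[keep], factor(tm$bin[keep], levels = ub), sum,
                  default = 0)
    den <- tapply(tm$den[keep], factor(tm$bin[keep], levels = ub), sum,
                  default = 0)
    g_i[i, ] <- ifelse(den > 0, num / den, NA_real_)
  }
  se <- apply(g_i, 2, function(v) {
    if (anyNA(v)) return(NA_real_)
    sqrt((P - 1) / P * sum((v - mean(v))^2))
  })
  if (anyNA(se)) warning("some windows vanish under period omission; ",
                         "their SE is missing")
  curve$bins$se <- se
  curve
}

#' Null association rate under random within-period association
#'
#' The SLAR expected if individuals associated at random, computed by
#' permuting individual identities uniformly within every sampling period
#' (preserving group sizes and identification counts), recomputing the
#' lagged association rate with the observed window boundaries, and
#' averaging over randomizations.
#'
#' @param curve A `slar_curve`.
#' @param pm The `period_matrices` the curve was computed from.
#' @param n_randomizations Number of identity randomizations (default 100).
#' @param seed Optional integer seed.
#' @return The curve with `bins$null` filled in.
#' @export
null_rate <- function(curve, pm, n_randomizations = 100, seed = NULL) {
  stopifnot(inherits(curve, "slar_curve"), inherits(pm, "period_matrices"))
  if (n_randomizations < 1) stop("n_randomizations must be >= 1",
                                 call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  joint <- period_joint(pm)
  seen <- period_seen(pm)
  P <- length(joint)
  n <- length(pm$ids)
  tm <- curve$terms
  ub <- sort(unique(tm$bin))
  pairs <- cbind(tm$j, tm$k)
  acc <- matrix(0, n_randomizations, length(ub))
  for (r in seq_len(n_randomizations)) {
    V <- matrix(0, P, n * n)
    DS <- matrix(0, P, n)
    for (p in seq_len(P)) {
      perm <- sample.int(n)
      jp <- joint[[p]][perm, perm, drop = FALSE]
      V[p, ] <- as.numeric(jp)
      DS[p, ] <- rowSums(jp) * seen[p, perm]
    }
    num_all <- tcrossprod(V)
    den_all <- tcrossprod(DS)
    num <- tapply(num_all[pairs], factor(tm$bin, levels = ub), sum,
                  default = 0)
    den <- tapply(den_all[pairs], factor(tm$bin, levels = ub), sum,
                  default = 0)
    acc[r, ] <- ifelse(den > 0, num / den, NA_real_)
  }
  curve$bins$null <- colMeans(acc, na.rm = TRUE)
  curve
}

#' @export
print.slar_curve <- function(x, ...) {
  cat("SLAR curve:", nrow(x$bins), "moving-average windows (target",
      x$moving_average_size, "associations),", x$n_periods, "periods\n")
  if (nrow(x$bins)) {
    cat(sprintf("  lag range %.1f-%.1f days, g' range %.4f-%.4f\n",
                min(x$bins$tau), max(x$bins$tau),
                min(x$bins$g), max(x$bins$g)))
  }
  invisible(x)
}

#' Plot a SLAR curve
#'
#' Estimate with jackknife error bars, the best-fitting social-organisation
#' model (dotted) and the null association rate (dashed), on a log lag axis.
#'
#' @param x A `slar_curve`.
#' @param fits Optional `slar_fits` object; the best model is drawn.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.slar_curve <- function(x, fits = NULL, ...) {
  b <- x$bins
  if (!nrow(b)) stop("empty curve", call. = FALSE)
  ylim <- range(c(b$g, b$null, b$g + b$se, pmax(b$g - b$se, 0)), na.rm = TRUE)
  graphics::plot(b$tau, b$g, log = "x", type = "b", pch = 16,
                 xlab = "Lag (days)",
                 ylab = "Standardized lagged association rate",
                 ylim = ylim, ...)
  if (any(is.finite(b$se))) {
    graphics::arrows(b$tau, b$g - b$se, b$tau, b$g + b$se,
                     angle = 90, code = 3, length = 0.03)
  }
  if (any(is.finite(b$null))) {
    graphics::lines(b$tau, b$null, lty = 2)
  }
  if (!is.null(fits)) {
    best <- fits$fits[[fits$best]]
    tt <- exp(seq(log(min(b$tau)), log(max(b$tau)), length.out = 200))
    graphics::lines(tt, slar_model_value(best$model, best$par, tt), lty = 3)
  }
  invisible(x)
}

#' Write a SLAR curve to CSV
#'
#' @param curve A `slar_curve`.
#' @param path Output CSV path (columns `tau,ghat,se,num,den,null`).
#' @return Invisibly, `path`.
#' @export
write_slar <- function(curve, path) {
  b <- curve$bins
  utils::write.csv(data.frame(tau = b$tau, ghat = b$g, se = b$se,
                              num = b$num, den = b$den, null = b$null),
                   path, row.names = FALSE)
  invisible(path)
}

# --- exponential models of social organisation --------------------------

slar_model_value <- function(model, par, tau) {
  switch(model,
         "CC" = rep(par[["a"]], length(tau)),
         "CA" = par[["a"]] * exp(-par[["b"]] * tau),
         "CC+CA" = par[["a"]] + par[["c"]] * exp(-par[["b"]] * tau),
         "2CA" = par[["a"]] * exp(-par[["b"]] * tau) +
           par[["c"]] * exp(-par[["d"]] * tau),
         stop("unknown model ", model))
}

slar_model_formula <- function(model, par) {
  f <- function(v) formatC(v, digits = 6, format = "g")
  switch(model,
         "CC" = f(par[["a"]]),
         "CA" = paste0(f(par[["a"]]), "*exp(-", f(par[["b"]]), "*tau)"),
         "CC+CA" = paste0(f(par[["a"]]), " + ", f(par[["c"]]),
                          "*exp(-", f(par[["b"]]), "*tau)"),
         "2CA" = paste0(f(par[["a"]]), "*exp(-", f(par[["b"]]), "*tau) + ",
                        f(par[["c"]]), "*exp(-", f(par[["d"]]), "*tau)"))
}

slar_model_npar <- c("CC" = 1L, "CA" = 2L, "CC+CA" = 3L, "2CA" = 4L)

slar_loglik <- function(model, par, bins) {
  p <- slar_model_value(model, par, bins$tau)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(bins$num * log(p) + (bins$den - bins$num) * log1p(-p))
}

fit_one_slar_model <- function(model, bins) {
  mbar <- sum(bins$num) / sum(bins$den)
  if (model == "CC") {
    # the pooled proportion is the exact MLE of a constant rate
    par <- c(a = mbar)
    return(list(model = model, par = par,
                logL = slar_loglik(model, par, bins), converged = TRUE))
  }
  lag_scale <- stats::median(bins$tau)
  qq <- function(x) stats::qlogis(pmin(pmax(x, 1e-8), 1 - 1e-8))
  to_par <- switch(model,
    "CA" = function(th) c(a = stats::plogis(th[1]), b = exp(th[2])),
    "CC+CA" = function(th) c(a = stats::plogis(th[1]),
                             c = stats::plogis(th[2]), b = exp(th[3])),
    "2CA" = function(th) c(a = stats::plogis(th[1]), b = exp(th[2]),
                           c = stats::plogis(th[3]), d = exp(th[4])))
  starts <- switch(model,
    "CA" = list(c(qq(mbar), log(1 / lag_scale)),
                c(qq(mbar), log(1e-5)),
                c(qq(min(1, 2 * mbar)), log(0.1))),
    "CC+CA" = list(c(qq(bins$g[nrow(bins)]),
                     qq(max(bins$g[1] - bins$g[nrow(bins)], 1e-4)),
                     log(1 / lag_scale)),
                   c(qq(mbar / 2), qq(mbar / 2), log(0.1)),
                   c(qq(mbar), qq(1e-3), log(1e-3))),
    "2CA" = list(c(qq(max(bins$g[1] - bins$g[nrow(bins)], 1e-4)),
                   log(1 / lag_scale), qq(bins$g[nrow(bins)]), log(1e-7)),
                 c(qq(mbar), log(1e-5), qq(mbar / 2), log(0.5)),
                 c(qq(mbar / 2), log(0.01), qq(mbar / 2), log(1e-4))))
  best <- NULL
  for (th0 in starts) {
    fit <- tryCatch(
      stats::optim(th0, function(th) -slar_loglik(model, to_par(th), bins),
                   method = "Nelder-Mead",
                   control = list(maxit = 5000, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    return(list(model = model, par = NULL, logL = -Inf, converged = FALSE))
  }
  par <- to_par(best$par)
  list(model = model, par = par, logL = -best$value,
       converged = best$convergence == 0)
}

#' Fit exponential models of social organisation to a SLAR curve
#'
#' Fits the four classical fission-fusion models of the lagged association
#' rate -- constant companions (`CC`, `g = a`), casual acquaintances
#' (`CA`, `g = a*exp(-b*tau)`), constant companions plus casual
#' acquaintances (`CC+CA`, `g = a + c*exp(-b*tau)`) and two levels of
#' casual acquaintances (`2CA`, `g = a*exp(-b*tau) + c*exp(-d*tau)`) --
#' by maximising a binomial likelihood in which each moving-average
#' window contributes `num ~ Binomial(den, model(tau))`. Overdispersion
#' `c_hat` is the Pearson chi-square of the most general model (`2CA`)
#' divided by its residual degrees of freedom, floored at 1, and model
#' selection minimises `QAIC = -2*logL/c_hat + 2*K`.
#'
#' @param curve A `slar_curve`.
#' @param models Subset of `c("CC", "CA", "CC+CA", "2CA")`.
#' @return An object of class `slar_fits`: per-model parameter estimates,
#'   log-likelihoods, `c_hat`, QAIC and delta-QAIC, plus `best`, the name
#'   of the minimum-QAIC model.
#' @export
fit_social_models <- function(curve, models = c("CC", "CA", "CC+CA", "2CA")) {
  stopifnot(inherits(curve, "slar_curve"))
  models <- match.arg(models, several.ok = TRUE)
  bins <- curve$bins
  if (nrow(bins) < 2) stop("need at least 2 SLAR windows to fit models",
                           call. = FALSE)
  fits <- lapply(models, fit_one_slar_model, bins = bins)
  names(fits) <- models

  # overdispersion from the most general model available
  ref <- if ("2CA" %in% models) "2CA" else models[[which.max(
    slar_model_npar[models])]]
  rf <- fits[[ref]]
  p <- pmin(pmax(slar_model_value(rf$model, rf$par, bins$tau), 1e-12),
            1 - 1e-12)
  pearson <- sum((bins$num - bins$den * p)^2 / (bins$den * p * (1 - p)))
  df <- nrow(bins) - slar_model_npar[[ref]]
  c_hat <- max(1, if (df > 0) pearson / df else pearson)

  ok <- vapply(fits, function(f) is.finite(f$logL), TRUE)
  if (!all(ok)) warning("model(s) failed to converge and were excluded: ",
                        paste(models[!ok], collapse = ", "))
  qaic <- vapply(fits, function(f) {
    if (!is.finite(f$logL)) return(NA_real_)
    -2 * f$logL / c_hat + 2 * slar_model_npar[[f$model]]
  }, 1.0)
  dq <- qaic - min(qaic, na.rm = TRUE)
  for (i in seq_along(fits)) {
    fits[[i]]$K <- slar_model_npar[[fits[[i]]$model]]
    fits[[i]]$QAIC <- qaic[[i]]
    fits[[i]]$delta_QAIC <- dq[[i]]
  }
  structure(list(fits = fits, c_hat = c_hat,
                 best = names(fits)[which.min(qaic)],
                 table = data.frame(
                   model = names(fits),
                   formula = vapply(fits, function(f)
                     if (is.null(f$par)) NA_character_
                     else slar_model_formula(f$model, f$par), ""),
                   K = vapply(fits, function(f) f$K, 1L),
                   logL = vapply(fits, function(f) f$logL, 1.0),
                   QAIC = qaic, delta_QAIC = dq, row.names = NULL)),
            class = "slar_fits")
}

#' @export
print.slar_fits <- function(x, ...) {
  cat("Social-organisation models fitted to SLAR (c_hat =",
      formatC(x$c_hat, digits = 4, format = "g"), ")\n")
  tb <- x$table
  tb$QAIC <- round(tb$QAIC, 2)
  tb$delta_QAIC <- round(tb$delta_QAIC, 2)
  tb$logL <- round(tb$logL, 2)
  print(tb, row.names = FALSE)
  cat("Best model:", x$best, "\n")
  invisible(x)
}

#' @export
coef.slar_fits <- function(object, model = object$best, ...) {
  object$fits[[model]]$par
}

#' Predicted lagged association rate from a fitted model
#'
#' @param object A `slar_fits` object.
#' @param tau Lags (days) at which to evaluate.
#' @param model Model name (default: the QAIC-best model).
#' @param ... Unused.
#' @return Numeric vector of predicted rates.
#' @export
predict.slar_fits <- function(object, tau, model = object$best, ...) {
  f <- object$fits[[model]]
  slar_model_value(f$model, f$par, tau)
}

#' Write fitted SLAR models to JSON
#'
#' @param fits A `slar_fits` object.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_model_fits <- function(fits, path) {
  out <- list(c_hat = fits$c_hat, best = fits$best,
              models = lapply(fits$fits, function(f) {
                list(model = f$model,
                     formula = if (is.null(f$par)) NULL
                               else slar_model_formula(f$model, f$par),
                     parameters = as.list(f$par), K = f$K, logL = f$logL,
                     QAIC = f$QAIC, delta_QAIC = f$delta_QAIC)
              }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
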