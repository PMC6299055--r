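#' Dyadic sighting counts for association indices
#'
#' For every unordered pair of individuals, tallies over sampling periods:
#' `x`, periods in which the pair was associated (shared a group);
#' `y_ab`, periods in which both were identified but never together;
#' `y_a` / `y_b`, periods in which only one of the two was identified; and
#' the half-weight denominator `d = x + y_ab + (y_a + y_b)/2`.
#'
#' @param pm A `period_matrices` object.
#' @return An object of class `dyad_counts`: a list of symmetric matrices
#'   `x`, `y_ab`, `y_a`, `y_b`, `d` (with `y_a[i, j]` the count for the
#'   row individual), the per-individual identification counts `seen`, and
#'   `ids`.
#' @export
dyad_counts <- function(pm) {
  stopifnot(inherits(pm, "period_matrices"))
  n <- length(pm$ids)
  if (n < 2) stop("need at least 2 individuals", call. = FALSE)
  joint <- period_joint(pm)
  seen <- period_seen(pm)
  x <- Reduce(`+`, joint)
  both <- crossprod(seen)
  diag(both) <- 0
  y_ab <- both - x
  tot <- colSums(seen)
  y_a <- outer(tot, rep(1, n)) - both
  y_b <- t(y_a)
  diag(y_a) <- 0
  diag(y_b) <- 0
  d <- x + y_ab + (y_a + y_b) / 2
  dimnames(x) <- dimnames(y_ab) <- dimnames(y_a) <- dimnames(y_b) <-
    dimnames(d) <- list(pm$ids, pm$ids)
  structure(list(x = x, y_ab = y_ab, y_a = y_a, y_b = y_b, d = d,
                 seen = stats::setNames(tot, pm$ids), ids = pm$ids,
                 n_periods = length(pm$matrices)),
            class = "dyad_counts")
}

#' Half-weight association index (HWI)
#'
#' `HWI = x / (x + y_ab + (y_a + y_b)/2)`, the association index least
#' biased when not every member of an encountered group is identified.
#' Dyads never co-identified in any period (`d = 0`) are set to 0 and
#' flagged with a warning.
#'
#' @param counts A `dyad_counts` object.
#' @return A symmetric `assoc_matrix` with entries in \[0, 1\], zero
#'   diagonal and attribute `flavor = "HWI"`.
#' @export
hwi <- function(counts) {
  stopifnot(inherits(counts, "dyad_counts"))
  d <- counts$d
  m <- counts$x / ifelse(d > 0, d, 1)
  if (any(d[upper.tri(d)] == 0)) {
    warning("some dyads were never co-identified (d = 0); their index is 0")
  }
  m[d == 0] <- 0
  diag(m) <- 0
  assoc_matrix(m, "HWI", counts$ids)
}

#' Gregariousness-corrected half-weight index (HWIG)
#'
#' Rescales each HWI by the total association relative to the product of
#' the dyad's gregariousness (row sums of the HWI matrix):
#' `HWIG_ab = HWI_ab * sum(HWI) / (s_a * s_b)` with `s_i` the row sum over
#' all partners. Removes the tendency of gregarious individuals to have
#' inflated indices with everyone. Values can exceed 1.
#'
#' @param m An `assoc_matrix` of flavor `"HWI"`.
#' @return An `assoc_matrix` with attribute `flavor = "HWIG"`.
#' @export
hwig <- function(m) {
  stopifnot(inherits(m, "assoc_matrix"))
  if (!identical(attr(m, "flavor"), "HWI")) {
    stop("hwig() expects an HWI matrix", call. = FALSE)
  }
  s <- rowSums(m)
  tot <- sum(m)
  denom <- outer(s, s)
  g <- ifelse(denom > 0, unclass(m) * tot / denom, 0)
  diag(g) <- 0
  assoc_matrix(g, "HWIG", attr(m, "ids"))
}

assoc_matrix <- function(m, flavor, ids) {
  m <- as.matrix(m)
  dimnames(m) <- list(ids, ids)
  structure(m, class = c("assoc_matrix", "matrix"),
            flavor = flavor, ids = ids)
}

#' @export
print.assoc_matrix <- function(x, ...) {
  v <- x[upper.tri(x)]
  cat(attr(x, "flavor"), "association matrix:", nrow(x), "individuals\n")
  cat(sprintf("  mean %.3f, sd %.3f, max %.3f, nonzero dyads %d/%d\n",
              mean(v), stats::sd(v), max(v), sum(v > 0), length(v)))
  invisible(x)
}

#' Mean association index within and between classes
#'
#' Averages the dyadic index over every unordered pair of class labels
#' (e.g. sexes or social clusters), giving the usual
#' "mean HWI +/- SD for male-male / male-female / female-female pairs"
#' style of summary. Within-class cells need at least two members,
#' otherwise the mean is reported missing.
#'
#' @param m An `assoc_matrix`.
#' @param classes Named character vector (or factor) mapping individual id
#'   to class label; individuals with `NA` class are dropped.
#' @return A data frame with columns `class_a`, `class_b`, `n_dyads`,
#'   `mean`, `sd`.
#' @export
class_mean_index <- function(m, classes) {
  stopifnot(inherits(m, "assoc_matrix"))
  ids <- attr(m, "ids")
  cl <- as.character(classes)[match(ids, names(classes))]
  keep <- !is.na(cl)
  ids <- ids[keep]; cl <- cl[keep]
  mm <- unclass(m)[keep, keep, drop = FALSE]
  labs <- sort(unique(cl))
  out <- NULL
  for (i in seq_along(labs)) {
    for (j in i:length(labs)) {
      a <- which(cl == labs[i]); b <- which(cl == labs[j])
      if (i == j) {
        if (length(a) < 2) {
          vals <- numeric(0)
        } else {
          sub <- mm[a, a, drop = FALSE]
          vals <- sub[upper.tri(sub)]
        }
      } else {
        vals <- as.vector(mm[a, b, drop = FALSE])
      }
      out <- rbind(out, data.frame(
        class_a = labs[i], class_b = labs[j], n_dyads = length(vals),
        mean = if (length(vals)) mean(vals) else NA_real_,
        sd = if (length(vals) > 1) stats::sd(vals) else NA_real_,
        stringsAsFactors = FALSE))
    }
  }
  out
}

#' Write an association matrix as square CSV and edge list
#'
#' @param m An `assoc_matrix`.
#' @param square Path for the labelled square CSV (`NULL` to skip).
#' @param edges Path for the edge-list CSV with columns
#'   `id_a,id_b,index` (`NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_assoc_matrix <- function(m, square = NULL, edges = NULL) {
  stopifnot(inherits(m, "assoc_matrix"))
  ids <- attr(m, "ids")
  written <- character(0)
  if (!is.null(square)) {
    utils::write.csv(as.data.frame(unclass(m)), square, row.names = TRUE)
    written <- c(written, square)
  }
  if (!is.null(edges)) {
    ut <- which(upper.tri(m), arr.ind = TRUE)
    df <- data.frame(id_a = ids[ut[, 1]], id_b = ids[ut[, 2]],
                     index = m[ut])
    utils::write.csv(df, edges, row.names = FALSE)
    written <- c(written, edges)
  }
  invisible(written)
}
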