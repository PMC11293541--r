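#' Per-region method weights from CpG coverage
#'
#' For each region and each of the methylation technologies being
#' integrated, the proportion \eqn{P_{n,i} = C_{n,i} / \sum_m C_{m,i}}
#' normalises method i's CpG coverage of region n by the method's coverage
#' over all analysis regions, and the weight
#' \eqn{W_{n,i} = P_{n,i} / \sum_j P_{n,j}} renormalises the proportions
#' within the region, so each row of W sums to one. Doubling every coverage
#' of a method leaves W unchanged.
#'
#' @param coverage Numeric matrix or data.frame, regions x methods, of CpG
#'   coverages (>= 0). Region names may be carried as rownames.
#' @return Matrix of weights with the same dimnames; rows sum to 1. Regions
#'   whose proportions are all zero are dropped with a warning.
#' @export
method_weights <- function(coverage) {
  cmat <- as.matrix(coverage)
  if (any(cmat < 0)) stop("coverage must be non-negative")
  col_tot <- colSums(cmat)
  if (any(col_tot == 0)) stop("every method needs at least one region with positive coverage")
  p <- sweep(cmat, 2L, col_tot, "/")
  row_tot <- rowSums(p)
  zero <- row_tot == 0
  if (any(zero)) {
    warning(sum(zero), " region(s) with all-zero coverage excluded")
    p <- p[!zero, , drop = FALSE]
    row_tot <- row_tot[!zero]
  }
  sweep(p, 1L, row_tot, "/")
}

# index pairs among k measurements, ordered as the spec's (1,2),(1,3),(2,3)
pair_index <- function(k) {
  idx <- utils::combn(k, 2L)
  list(i = idx[1L, ], j = idx[2L, ])
}

#' Benchmarked consensus methylation per region
#'
#' Integrates the per-region methylation levels measured by (typically
#' three) independent technologies into one benchmarked level BM: the two
#' measurements with the closest values are selected,
#' \eqn{(\hat i,\hat j) = \arg\min_{i,j} |M_{n,i} - M_{n,j}|}, and averaged
#' with the [method_weights()] weights,
#' \eqn{BM_n = (W_{\hat i} M_{\hat i} + W_{\hat j} M_{\hat j}) /
#' (W_{\hat i} + W_{\hat j})}. BM always lies between the two selected
#' values. An exact tie in the argmin is broken towards the pair with the
#' larger combined weight (deterministic).
#'
#' @param meth Numeric matrix/data.frame, regions x methods, of methylation
#'   levels in [0, 1].
#' @param weights Weight matrix from [method_weights()], same shape.
#' @return data.frame with per-region selected pair indices \code{i},
#'   \code{j} and the benchmarked level \code{bm}.
#' @export
benchmark_methylation <- function(meth, weights) {
  m <- as.matrix(meth)
  w <- as.matrix(weights)
  stopifnot(identical(dim(m), dim(w)), ncol(m) >= 2L)
  if (any(m < 0 | m > 1)) stop("methylation levels must lie in [0, 1]")
  pr <- pair_index(ncol(m))
  n <- nrow(m)
  sel_i <- integer(n)
  sel_j <- integer(n)
  bm <- numeric(n)
  for (r in seq_len(n)) {
    d <- abs(m[r, pr$i] - m[r, pr$j])
    cw <- w[r, pr$i] + w[r, pr$j]
    best <- which(d == min(d))
    if (length(best) > 1L) best <- best[which.max(cw[best])]
    i <- pr$i[best]
    j <- pr$j[best]
    sel_i[r] <- i
    sel_j[r] <- j
    bm[r] <- (w[r, i] * m[r, i] + w[r, j] * m[r, j]) / (w[r, i] + w[r, j])
  }
  data.frame(name = rownames(m) %||% paste0("region_", seq_len(n)),
             i = sel_i, j = sel_j, bm = bm, stringsAsFactors = FALSE)
}

#' Filter regions by per-method coverage thresholds
#'
#' Pre-filter applied before benchmarking: a region is kept only when every
#' method reaches its minimum CpG coverage there (e.g. >= 50 for WGBS and
#' EM-seq, >= 20 for Nanopore). Monotone in the thresholds.
#'
#' @param coverage Regions x methods coverage matrix.
#' @param min_cov Numeric vector of per-method minima, recycled to the
#'   number of methods.
#' @return Logical vector: region passes.
#' @export
coverage_pass <- function(coverage, min_cov) {
  cmat <- as.matrix(coverage)
  min_cov <- rep_len(min_cov, ncol(cmat))
  rowSums(sweep(cmat, 2L, min_cov, ">=")) == ncol(cmat)
}

#' Bin regions by benchmarked methylation and pool counts
#'
#' Partitions [0, 1] into \code{n_bin} equal-width bins with bounds
#' \eqn{LB_k = (k-1)/N}, \eqn{UB_k = k/N}; region n joins bin k when
#' \eqn{BM_n \in [LB_k, UB_k)} (final bin closed at 1). Per bin, the average
#' benchmarked methylation \eqn{ABM_k} is the mean BM over members, and the
#' pooled transition rate \eqn{R_k = \sum Error_n / \sum Total_n} sums the
#' member regions' counts before dividing (not a mean of per-region rates),
#' so high-coverage regions dominate as they should.
#'
#' @param benchmarks data.frame with columns \code{name} and \code{bm}
#'   (e.g. from [benchmark_methylation()], or assigned truth in
#'   simulations).
#' @param counts Region transition counts with columns \code{name},
#'   \code{error}, \code{total} (from [aggregate_regions()]).
#' @param n_bin Number of equal-width bins (default 10).
#' @return data.frame, one row per bin: \code{bin}, \code{lb}, \code{ub},
#'   \code{n} (member regions), \code{abm}, \code{error}, \code{total},
#'   \code{rate}. Empty bins have \code{n = 0} and NA \code{abm}/\code{rate}.
#' @export
bin_and_pool <- function(benchmarks, counts, n_bin = 10L) {
  stopifnot(n_bin >= 1L, all(c("name", "bm") %in% names(benchmarks)),
            all(c("name", "error", "total") %in% names(counts)))
  idx <- match(benchmarks$name, counts$name)
  if (anyNA(idx)) {
    stop("regions missing from counts: ",
         paste(utils::head(benchmarks$name[is.na(idx)], 5L), collapse = ", "))
  }
  bm <- benchmarks$bm
  if (any(bm < 0 | bm > 1)) stop("benchmarked methylation must lie in [0, 1]")
  k <- pmin(n_bin, floor(bm * n_bin) + 1L)
  err <- counts$error[idx]
  tot <- counts$total[idx]
  out <- data.frame(bin = seq_len(n_bin),
                    lb = (seq_len(n_bin) - 1L) / n_bin,
                    ub = seq_len(n_bin) / n_bin,
                    n = 0L, abm = NA_real_, error = 0, total = 0,
                    stringsAsFactors = FALSE)
  for (b in seq_len(n_bin)) {
    member <- k == b
    out$n[b] <- sum(member)
    if (any(member)) {
      out$abm[b] <- mean(bm[member])
      out$error[b] <- sum(err[member])
      out$total[b] <- sum(tot[member])
    }
  }
  out$rate <- ifelse(out$total > 0, out$error / out$total, NA_real_)
  out
}

#' Fit the transition-rate versus methylation linear model
#'
#' Ordinary least squares of the pooled binned transition rate on the
#' binned methylation level, \eqn{R_k = \alpha + \beta \cdot ABM_k +
#' \varepsilon_k}. Under the limited-deamination signal model the intercept
#' estimates the background transition rate and the slope the per-unit-
#' methylation deamination rate, which is why two internal calibration
#' points suffice in production use.
#'
#' @param bins Bin table from [bin_and_pool()]; empty bins are dropped.
#' @param min_bins Minimum number of non-empty bins required (default 3).
#' @return List of class \code{raml_fit}: \code{intercept}, \code{slope},
#'   \code{r_squared}, \code{p_slope}, \code{p_intercept}, \code{n_bins},
#'   and the underlying \code{lm} object as \code{model}.
#' @export
fit_linear_model <- function(bins, min_bins = 3L) {
  use <- bins[bins$n > 0L & !is.na(bins$rate) & !is.na(bins$abm), , drop = FALSE]
  if (nrow(use) < min_bins) {
    stop("insufficient data: ", nrow(use), " non-empty bin(s), need >= ", min_bins)
  }
  fit <- stats::lm(rate ~ abm, data = use)
  # an exactly collinear input (e.g. a noiseless two-point calibration) is a
  # legitimate degenerate case here, not a modelling accident
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
  coefs <- stats::coef(sm)
  r2 <- if (stats::var(use$rate) == 0) 0 else sm$r.squared
  p_slope <- if (nrow(coefs) >= 2L && ncol(coefs) >= 4L) coefs["abm", 4L] else NA_real_
  p_int <- if (ncol(coefs) >= 4L) coefs["(Intercept)", 4L] else NA_real_
  structure(list(intercept = unname(stats::coef(fit)[1L]),
                 slope = unname(stats::coef(fit)[2L]),
                 r_squared = r2, p_slope = unname(p_slope),
                 p_intercept = unname(p_int), n_bins = nrow(use),
                 model = fit),
            class = "raml_fit")
}

#' @export
print.raml_fit <- function(x, ...) {
  cat("Transition-rate ~ methylation linear fit (", x$n_bins, " bins)\n", sep = "")
  cat(sprintf("  intercept: %.3g (p = %.3g)\n", x$intercept, x$p_intercept))
  cat(sprintf("  slope:     %.3g (p = %.3g)\n", x$slope, x$p_slope))
  cat(sprintf("  R-squared: %.4f\n", x$r_squared))
  invisible(x)
}

#' Quadrant consistency between two methylation measurements
#'
#' Both axes are cut into three intervals (default cuts 0.3 and 0.7,
#' matching the usual <30 percent hypomethylation boundary), forming nine
#' cells; the statistic is the fraction of regions falling in the same cell
#' index on both axes. A complement to the correlation coefficient that is
#' insensitive to within-cell calibration differences.
#'
#' @param x,y Paired per-region methylation levels in [0, 1].
#' @param cuts Two strictly increasing thresholds in (0, 1).
#' @return Fraction in [0, 1].
#' @export
quadrant_consistency <- function(x, y, cuts = c(0.3, 0.7)) {
  if (length(x) == 0L || length(x) != length(y)) {
    stop("x and y must be non-empty and of equal length")
  }
  stopifnot(length(cuts) == 2L, cuts[1] < cuts[2], all(cuts > 0 & cuts < 1))
  if (any(x < 0 | x > 1 | y < 0 | y > 1)) stop("values must lie in [0, 1]")
  mean(findInterval(x, cuts) == findInterval(y, cuts))
}
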