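#' Pool replicate methylation estimates per region
#'
#' Within one condition, the per-region estimates from (typically three)
#' replicates are pooled the same way cross-technology measurements are
#' benchmarked: the two closest estimates are selected, averaged with the
#' coverage-derived [method_weights()] weights, and their totals summed,
#' giving the condition's \eqn{BM_n} and \eqn{Total_n}. With two replicates
#' both are used; with one it is passed through with a warning. An exact
#' tie in the closest-pair argmin is broken towards the pair containing the
#' replicate with the largest total (deterministic).
#'
#' @param meth Regions x replicates matrix of methylation estimates in
#'   [0, 1] (e.g. the \code{meth} column of [estimate_raml()] per
#'   replicate).
#' @param total Regions x replicates matrix of the matching totals.
#' @return data.frame with per-region \code{bm}, \code{total} and the
#'   selected replicate indices \code{i}, \code{j}.
#' @export
pool_replicates <- function(meth, total) {
  m <- as.matrix(meth)
  tot <- as.matrix(total)
  stopifnot(identical(dim(m), dim(tot)), ncol(m) >= 1L)
  name <- rownames(m) %||% paste0("region_", seq_len(nrow(m)))
  if (ncol(m) == 1L) {
    warning("single replicate: estimates used directly, no pooling possible")
    return(data.frame(name = name, bm = m[, 1L], total = tot[, 1L],
                      i = 1L, j = NA_integer_, stringsAsFactors = FALSE))
  }
  w <- method_weights(tot)
  if (ncol(m) == 2L) {
    bm <- (w[, 1L] * m[, 1L] + w[, 2L] * m[, 2L]) / (w[, 1L] + w[, 2L])
    return(data.frame(name = name, bm = bm, total = tot[, 1L] + tot[, 2L],
                      i = 1L, j = 2L, stringsAsFactors = FALSE))
  }
  pr <- pair_index(ncol(m))
  n <- nrow(m)
  out <- data.frame(name = name, bm = NA_real_, total = NA_real_,
                    i = NA_integer_, j = NA_integer_, stringsAsFactors = FALSE)
  for (r in seq_len(n)) {
    d <- abs(m[r, pr$i] - m[r, pr$j])
    best <- which(d == min(d))
    if (length(best) > 1L) {
      # prefer the pair containing the highest-coverage replicate
      has_max <- vapply(best, function(b) {
        which.max(tot[r, ]) %in% c(pr$i[b], pr$j[b])
      }, logical(1))
      best <- if (any(has_max)) best[has_max][1L] else best[1L]
    }
    i <- pr$i[best]
    j <- pr$j[best]
    out$bm[r] <- (w[r, i] * m[r, i] + w[r, j] * m[r, j]) / (w[r, i] + w[r, j])
    out$total[r] <- tot[r, i] + tot[r, j]
    out$i[r] <- i
    out$j[r] <- j
  }
  out
}

#' Coverage-weighted mean methylation of two groups
#'
#' \deqn{Mean\_BM_n = \frac{BM_a Total_a + BM_b Total_b}{Total_a + Total_b}}
#' used as the pooled proportion in the variance of the z-statistics.
#'
#' @param bm_a,total_a,bm_b,total_b Vectors of group methylation levels and
#'   totals (recycled to a common length).
#' @return Vector of weighted means; NA where both totals are zero.
#' @export
mean_bm <- function(bm_a, total_a, bm_b, total_b) {
  n <- max(length(bm_a), length(bm_b))
  bm_a <- rep_len(bm_a, n); total_a <- rep_len(total_a, n)
  bm_b <- rep_len(bm_b, n); total_b <- rep_len(total_b, n)
  denom <- total_a + total_b
  ifelse(denom > 0, (bm_a * total_a + bm_b * total_b) / denom, NA_real_)
}

#' Margin z-test for differential methylation between two conditions
#'
#' Tests, per region, whether the methylation difference between condition
#' A (e.g. tumor) and condition B (e.g. matched tissue) exceeds a margin
#' \eqn{\delta} (default 0.1, i.e. a 10 percent difference) in either
#' direction, using one-sided two-proportion z-statistics:
#' \deqn{z_> = \frac{BM_a - (BM_b + \delta)}{\sqrt{\bar p (1-\bar p)
#' (1/Total_a + 1/Total_b)}}, \quad
#' z_< = \frac{BM_a - (BM_b - \delta)}{\sqrt{\bar p (1-\bar p)
#' (1/Total_a + 1/Total_b)}}}
#' with \eqn{\bar p} the coverage-weighted [mean_bm()]. The one-sided
#' p-value is \eqn{\min(1 - \Phi(z_>), \Phi(z_<))} and a region is called
#' differential when it falls below \code{alpha}. Regions with
#' \eqn{\bar p \in \{0, 1\}} have zero variance and are flagged
#' untestable. No multiple-testing correction is applied by default;
#' set \code{adjust = "BH"} for Benjamini-Hochberg on the p-values.
#'
#' @param a,b data.frames with columns \code{bm} and \code{total} (and
#'   optionally \code{name}) for the two conditions, rows aligned by
#'   region.
#' @param delta Methylation-difference margin (default 0.1).
#' @param alpha Significance level for the call (default 0.05).
#' @param adjust \code{"none"} (default) or \code{"BH"}.
#' @return data.frame with \code{name}, \code{mean_bm}, \code{z_greater},
#'   \code{z_less}, \code{p_greater}, \code{p_less}, \code{p},
#'   \code{direction} (\code{"gain"}/\code{"loss"}/\code{"none"}),
#'   \code{call} (logical), \code{untestable}.
#' @export
dmr_z_test <- function(a, b, delta = 0.1, alpha = 0.05,
                       adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(delta >= 0, nrow(a) == nrow(b),
            all(c("bm", "total") %in% names(a)),
            all(c("bm", "total") %in% names(b)))
  name <- a$name %||% paste0("region_", seq_len(nrow(a)))
  mbm <- mean_bm(a$bm, a$total, b$bm, b$total)
  untestable <- is.na(mbm) | mbm <= 0 | mbm >= 1 | a$total <= 0 | b$total <= 0
  se <- sqrt(mbm * (1 - mbm) * (1 / a$total + 1 / b$total))
  se[untestable] <- NA_real_
  z_gt <- (a$bm - (b$bm + delta)) / se
  z_lt <- (a$bm - (b$bm - delta)) / se
  p_gt <- 1 - stats::pnorm(z_gt)
  p_lt <- stats::pnorm(z_lt)
  p <- pmin(p_gt, p_lt)
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  call <- !untestable & !is.na(p) & p < alpha
  direction <- ifelse(!call, "none", ifelse(p_gt <= p_lt, "gain", "loss"))
  data.frame(name = name, mean_bm = mbm, z_greater = z_gt, z_less = z_lt,
             p_greater = p_gt, p_less = p_lt, p = p,
             direction = direction, call = call, untestable = untestable,
             stringsAsFactors = FALSE)
}

#' Confusion counts against a reference DMR set
#'
#' Scores the package's differential calls against an external reference
#' label set (e.g. DMRs called on EM-seq data) over the evaluable regions:
#' TP = called by both, FP = called here only, FN = called by the reference
#' only, TN = called by neither. Regions failing the evaluable filter (for
#' instance reference differences below the margin) are counted as
#' \code{not_evaluated}.
#'
#' @param calls data.frame with \code{name} and logical \code{call}.
#' @param reference data.frame with \code{name} and logical \code{is_dmr}.
#' @param evaluable Optional logical vector aligned with \code{calls} rows
#'   (default: all evaluable).
#' @return List of class \code{confusion_counts} with \code{TP}, \code{FP},
#'   \code{FN}, \code{TN}, \code{not_evaluated}.
#' @export
classify_confusion <- function(calls, reference, evaluable = NULL) {
  stopifnot(all(c("name", "call") %in% names(calls)),
            all(c("name", "is_dmr") %in% names(reference)))
  idx <- match(calls$name, reference$name)
  if (anyNA(idx)) {
    stop("regions missing from reference: ",
         paste(utils::head(calls$name[is.na(idx)], 5L), collapse = ", "))
  }
  ref <- reference$is_dmr[idx]
  ev <- if (is.null(evaluable)) rep(TRUE, nrow(calls)) else evaluable
  stopifnot(length(ev) == nrow(calls))
  got <- calls$call[ev]
  want <- ref[ev]
  structure(list(TP = sum(got & want), FP = sum(got & !want),
                 FN = sum(!got & want), TN = sum(!got & !want),
                 not_evaluated = sum(!ev)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("DMR confusion counts\n")
  cat(sprintf("  TP %d  FP %d  FN %d  TN %d  (not evaluated: %d)\n",
              x$TP, x$FP, x$FN, x$TN, x$not_evaluated))
  invisible(x)
}
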