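#' Background transition rate R0 from non-CpG cytosines
#'
#' Unmethylated cytosines deaminate at a negligible rate under the limited
#' protocol, so the C-to-T rate observed at non-CpG cytosines inside the
#' control regions estimates the pure sequencing/processing background:
#' \eqn{R_0 = \sum Error / \sum Total} pooled over all non-CpG cytosine
#' observations.
#'
#' @param counts data.frame with \code{error} and \code{total} columns
#'   restricted to non-CpG cytosines (site- or region-level; e.g.
#'   \code{aggregate_regions(sites, controls, context = c("CpA","CpT","CpC"))}).
#' @return The pooled background rate (scalar).
#' @export
estimate_R0 <- function(counts) {
  tot <- sum(counts$total)
  if (tot <= 0) stop("calibration error: zero total non-CpG observations")
  sum(counts$error) / tot
}

#' Fully-methylated transition rate R100 from control regions
#'
#' Estimates the C-to-T rate at fully methylated CpG from stably
#' hypermethylated control regions, adjusting each region's transition
#' count for its true methylation level WM (the mean methylation of the
#' region across public WGBS compendia, typically slightly below 1):
#' \deqn{R_{100} = \frac{\sum_n Error_n / WM_n}{\sum_n Total_n}.}
#' Only the numerator is WM-adjusted, matching the published calibration.
#'
#' @param counts Per-control-region CpG counts: data.frame with
#'   \code{error}, \code{total} and (if \code{wm} is a table) \code{name}.
#' @param wm Per-region true methylation: either a numeric vector aligned
#'   with \code{counts} rows (recycled, so \code{wm = 1} disables the
#'   adjustment) or a data.frame with \code{name} and \code{wm} columns.
#' @return The adjusted fully-methylated rate (scalar). Regions with
#'   \code{wm = 0} are excluded with a warning.
#' @export
estimate_R100 <- function(counts, wm = 1) {
  if (is.data.frame(wm)) {
    stopifnot(all(c("name", "wm") %in% names(wm)), "name" %in% names(counts))
    idx <- match(counts$name, wm$name)
    if (anyNA(idx)) {
      stop("control regions missing from WM table: ",
           paste(utils::head(counts$name[is.na(idx)], 5L), collapse = ", "))
    }
    wm <- wm$wm[idx]
  }
  wm <- rep_len(wm, nrow(counts))
  if (any(wm < 0 | wm > 1)) stop("WM must lie in [0, 1]")
  bad <- wm == 0
  if (any(bad)) {
    warning(sum(bad), " control region(s) with WM = 0 excluded")
    counts <- counts[!bad, , drop = FALSE]
    wm <- wm[!bad]
  }
  if (nrow(counts) == 0L) stop("calibration error: no usable control regions")
  tot <- sum(counts$total)
  if (tot <= 0) stop("calibration error: zero total CpG observations in controls")
  sum(counts$error / wm) / tot
}

#' Calibration constants
#'
#' Validates and bundles the two internal calibration points: the
#' background rate \code{r0} at unmethylated cytosines and the
#' fully-methylated rate \code{r100} at CpG in stably hypermethylated
#' regions.
#'
#' @param r0,r100 Rates with \code{0 <= r0 < r100 <= 1}.
#' @return List of class \code{calibration_constants}.
#' @export
calibration_constants <- function(r0, r100) {
  if (r0 < 0 || r100 > 1) stop("calibration rates must lie in [0, 1]")
  if (r100 <= r0) stop("calibration error: R100 (", r100, ") must exceed R0 (", r0, ")")
  structure(list(r0 = r0, r100 = r100), class = "calibration_constants")
}

#' Regional aggregated methylation level (RAML)
#'
#' Converts regional transition counts into bounded methylation estimates
#' via the two-point calibration:
#' \deqn{Meth = \min(1, \max(0, \frac{Error - Total \cdot R_0}
#' {(R_{100} - R_0) \cdot Total})).}
#' A binomial standard error is attached,
#' \eqn{se = \sqrt{R(1-R)/Total} / (R_{100} - R_0)} with \eqn{R =
#' Error/Total}, giving the differential-methylation test a variance
#' notion on the same scale. Estimates from fewer than
#' \code{min_sites} combined CpG sites are flagged low-confidence rather
#' than suppressed (regional estimates stabilise at about 100 combined
#' CpG sites).
#'
#' @param counts Region counts from [aggregate_regions()] (columns
#'   \code{error}, \code{total}; optional \code{name}, \code{n_sites}).
#' @param cal A [calibration_constants()] object.
#' @param min_sites Reliability threshold on \code{n_sites} (default 100).
#' @return data.frame with \code{name}, \code{error}, \code{total},
#'   \code{meth} (clamped to [0,1], NA when uncovered), \code{se},
#'   \code{clamped}, \code{low_confidence}.
#' @export
estimate_raml <- function(counts, cal, min_sites = 100L) {
  stopifnot(inherits(cal, "calibration_constants"))
  name <- if ("name" %in% names(counts)) counts$name else paste0("region_", seq_len(nrow(counts)))
  err <- counts$error
  tot <- counts$total
  raw <- ifelse(tot > 0, (err - tot * cal$r0) / ((cal$r100 - cal$r0) * tot), NA_real_)
  meth <- pmin(1, pmax(0, raw))
  r <- ifelse(tot > 0, err / tot, NA_real_)
  se <- ifelse(tot > 0, sqrt(r * (1 - r) / tot) / (cal$r100 - cal$r0), NA_real_)
  n_sites <- if ("n_sites" %in% names(counts)) counts$n_sites else NA_integer_
  data.frame(name = name, error = err, total = tot, n_sites = n_sites,
             meth = meth, se = se,
             clamped = !is.na(raw) & (raw < 0 | raw > 1),
             low_confidence = !is.na(n_sites) & n_sites < min_sites,
             stringsAsFactors = FALSE)
}

#' Signal-to-background fold increase
#'
#' Ratio of the fully-methylated to the background transition rate,
#' \eqn{R_{100}/R_0}; around 1000 under the standard protocol (about 1
#' percent deamination at m5C over a 1e-5 sequencing background).
#'
#' @param cal A [calibration_constants()] object.
#' @return The fold ratio; \code{Inf} when \code{r0 = 0}.
#' @export
fold_increase <- function(cal) {
  stopifnot(inherits(cal, "calibration_constants"))
  if (cal$r0 == 0) Inf else cal$r100 / cal$r0
}

#' Read a control-region table
#'
#' Tab-separated control-region table with columns \code{chrom},
#' \code{start}, \code{end}, \code{name}, \code{wm} (0-based half-open
#' coordinates). A synthetic 24-region example mirroring the structure of
#' published stably-hypermethylated control sets ships in
#' \code{system.file("extdata", "control_regions_synthetic.tsv",
#' package = "ramlseq")}.
#'
#' @param path File path.
#' @return data.frame with the columns above and \code{kind = "control"}.
#' @export
read_control_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end", "name", "wm") %in% names(df)))
  if (any(df$wm <= 0 | df$wm > 1)) stop("WM must lie in (0, 1]")
  df$kind <- "control"
  df
}
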