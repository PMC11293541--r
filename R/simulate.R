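#' Simulator configuration
#'
#' Defines the study conditions for the synthetic deamination datasets: the
#' per-observation deamination rate at methylated CpG (default 0.01, the ~1
#' percent the limited heat-alkaline protocol targets), the background
#' C-to-T error per cytosine observation (default 1e-5, the short-read
#' background, a 1000-fold lower), coverage, read geometry, region layout
#' and the methylation assignment. A seed is mandatory: all simulator
#' output is a deterministic function of the configuration.
#'
#' @param n_regions Number of analysis regions.
#' @param cpg_per_region CpG sites per region (default 100, the scale at
#'   which regional estimates stabilise).
#' @param methylation Region methylation assignment: \code{NULL} for a
#'   uniform draw on [0, 1], or a scalar/vector in [0, 1] recycled across
#'   regions.
#' @param deamination_rate Per-read C-to-T conversion probability at a
#'   methylated CpG cytosine (default 0.01).
#' @param background_rate Per-observation background C-to-T error at any
#'   cytosine (default 1e-5). Must be below \code{deamination_rate}.
#' @param coverage Read observations per cytosine site (per strand).
#' @param read_length,fragment_length Read geometry for SAM output; mates
#'   overlap by \code{2*read_length - fragment_length} bases (40 by
#'   default), exercising the overlap-trimming step.
#' @param spacer_len Non-CpG spacer bases between consecutive CpG sites,
#'   drawn from {A, C, T} so the spacer contributes non-CpG cytosines (for
#'   background calibration) but no accidental CpG.
#' @param n_control Additional fully methylated control regions appended
#'   after the analysis regions, with a WM table (\code{control_wm}).
#' @param control_wm True methylation of the control regions (default 1).
#' @param snp_rate Per-spacer-position probability of planting a homozygous
#'   SNP (default 0).
#' @param hmc_fraction Fraction of methylated CpG sites flagged as
#'   hydroxymethylated; the signal model treats them identically to m5C
#'   (the deamination chemistry does not discriminate), so the flag only
#'   annotates the truth.
#' @param seed Integer seed (required).
#' @return List of class \code{sim_config}.
#' @export
sim_config <- function(n_regions = 10L, cpg_per_region = 100L,
                       methylation = NULL, deamination_rate = 0.01,
                       background_rate = 1e-5, coverage = 30L,
                       read_length = 100L, fragment_length = 160L,
                       spacer_len = 8L, n_control = 0L, control_wm = 1,
                       snp_rate = 0, hmc_fraction = 0, seed) {
  if (missing(seed)) stop("a seed is required for reproducibility")
  stopifnot(deamination_rate >= 0, deamination_rate <= 1,
            background_rate >= 0, background_rate <= 1,
            deamination_rate > background_rate || deamination_rate == 0,
            coverage >= 1, cpg_per_region >= 1, spacer_len >= 1,
            read_length >= 1, fragment_length >= read_length,
            fragment_length <= 2L * read_length,
            snp_rate >= 0, snp_rate <= 1, hmc_fraction >= 0, hmc_fraction <= 1,
            control_wm > 0, control_wm <= 1)
  if (!is.null(methylation) && any(methylation < 0 | methylation > 1)) {
    stop("assigned methylation must lie in [0, 1]")
  }
  structure(list(n_regions = as.integer(n_regions),
                 cpg_per_region = as.integer(cpg_per_region),
                 methylation = methylation,
                 deamination_rate = deamination_rate,
                 background_rate = background_rate,
                 coverage = as.integer(coverage),
                 read_length = as.integer(read_length),
                 fragment_length = as.integer(fragment_length),
                 spacer_len = as.integer(spacer_len),
                 n_control = as.integer(n_control),
                 control_wm = control_wm,
                 snp_rate = snp_rate, hmc_fraction = hmc_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

SIM_CHROM <- "chrSim"
SIM_PAD <- 200L
SIM_GAP <- 100L

#' Simulate a reference genome with regions of known methylation
#'
#' Builds one synthetic chromosome containing \code{n_regions} analysis
#' regions (plus \code{n_control} fully methylated control regions), each
#' with exactly \code{cpg_per_region} CpG dinucleotides separated by
#' {A,C,T} spacers; spacer cytosines are the non-CpG background sites used
#' for calibration. Each CpG site's methylation status is drawn Bernoulli
#' with the region's assigned level, and the full ground truth (assignment,
#' site draws, SNPs, configuration) is returned. Output is byte-identical
#' for identical configurations.
#'
#' @param config A [sim_config()].
#' @return List of class \code{raml_sim}: \code{config}, \code{chrom},
#'   \code{sequence} (character), \code{ref} (named character vector usable
#'   as a reference by the counting functions), \code{regions} (BED-style
#'   data.frame with assigned \code{methylation}), \code{controls} (WM
#'   table for the control subset), \code{cpg_sites} (per-site region,
#'   0-based position of the CpG cytosine, \code{status}, \code{hmc}),
#'   \code{snps}.
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_all <- config$n_regions + config$n_control
  if (n_all < 1L) stop("no regions configured")
  meth <- if (is.null(config$methylation)) {
    stats::runif(config$n_regions)
  } else {
    rep_len(config$methylation, config$n_regions)
  }
  meth <- c(meth, rep(1, config$n_control))
  kind <- c(rep("cgi", config$n_regions), rep("control", config$n_control))
  name <- c(sprintf("region_%03d", seq_len(config$n_regions)),
            if (config$n_control > 0L) sprintf("control_%03d", seq_len(config$n_control)))
  unit_len <- config$spacer_len + 2L
  region_len <- config$cpg_per_region * unit_len
  chunks <- character(2L * n_all + 1L)
  chunks[1L] <- strrep("A", SIM_PAD)
  cursor <- SIM_PAD
  region_start <- integer(n_all)
  cpg <- vector("list", n_all)
  for (r in seq_len(n_all)) {
    spacers <- matrix(sample(c("A", "C", "T"), config$cpg_per_region * config$spacer_len,
                             replace = TRUE),
                      nrow = config$cpg_per_region)
    units <- paste0(apply(spacers, 1L, paste, collapse = ""), "CG")
    chunks[2L * r] <- paste(units, collapse = "")
    region_start[r] <- cursor
    cpg[[r]] <- cursor + (seq_len(config$cpg_per_region) - 1L) * unit_len + config$spacer_len
    cursor <- cursor + region_len
    chunks[2L * r + 1L] <- strrep("A", SIM_GAP)
    cursor <- cursor + SIM_GAP
  }
  sequence <- paste(chunks, collapse = "")
  regions <- data.frame(chrom = SIM_CHROM, start = region_start,
                        end = region_start + region_len, name = name,
                        kind = kind, methylation = meth,
                        stringsAsFactors = FALSE)
  cpg_sites <- data.frame(region = rep(name, each = config$cpg_per_region),
                          pos = unlist(cpg),
                          stringsAsFactors = FALSE)
  cpg_sites$status <- stats::rbinom(nrow(cpg_sites), 1L,
                                    rep(meth, each = config$cpg_per_region))
  cpg_sites$hmc <- cpg_sites$status == 1L &
    stats::rbinom(nrow(cpg_sites), 1L, config$hmc_fraction) == 1L
  snps <- data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                     alt = character(0), stringsAsFactors = FALSE)
  if (config$snp_rate > 0) {
    chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
    in_region <- unlist(lapply(seq_len(n_all), function(r) {
      seq.int(region_start[r], region_start[r] + region_len - 1L)
    }))
    spacer_pos <- setdiff(in_region, c(cpg_sites$pos, cpg_sites$pos + 1L))
    hit <- spacer_pos[stats::runif(length(spacer_pos)) < config$snp_rate]
    if (length(hit) > 0L) {
      ref_b <- chars[hit + 1L]
      alt_b <- vapply(ref_b, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                      character(1))
      snps <- data.frame(chrom = SIM_CHROM, pos = hit, ref = unname(ref_b),
                         alt = unname(alt_b), stringsAsFactors = FALSE)
    }
  }
  controls <- regions[regions$kind == "control",
                      c("chrom", "start", "end", "name"), drop = FALSE]
  if (nrow(controls) > 0L) controls$wm <- config$control_wm
  rownames(controls) <- NULL
  ref <- stats::setNames(sequence, SIM_CHROM)
  structure(list(config = config, chrom = SIM_CHROM, sequence = sequence,
                 ref = ref, regions = regions, controls = controls,
                 cpg_sites = cpg_sites, snps = snps),
            class = "raml_sim")
}

# Redraw per-site methylation status for given region levels (used for
# replicate simulation, where each replicate resamples the molecule pool).
resample_site_status <- function(sim, methylation, seed) {
  set.seed(seed)
  meth <- rep(rep_len(methylation, nrow(sim$regions)),
              each = sim$config$cpg_per_region)
  stats::rbinom(nrow(sim$cpg_sites), 1L, meth)
}

#' Simulate per-site pileup transition counts
#'
#' The fast simulation path: instead of emitting reads, observation counts
#' are drawn binomially per cytosine site and channel, matching the schema
#' of [count_transitions()] output exactly. Each cytosine site (top-strand
#' reference C, and the bottom-strand cytosine at each CpG's reference G)
#' receives \code{coverage} observations, split Binomial(1/2) between the
#' two mates. The deamination signal lands on the channels the counting
#' scheme reads, Read1 C-to-T and Read2 G-to-A, where the transition
#' probability is \code{deamination_rate * status + background_rate}; the
#' mirror channels (Read2 C-to-T, Read1 G-to-A) see background error only.
#' Planted C-to-T SNPs appear as always-transition sites (they must be
#' masked via [snp_mask()] to keep calibration honest); SNPs that change
#' the base away from C/T remove the site.
#'
#' @param sim A [simulate_reference()] result.
#' @param coverage Observations per cytosine site per strand (default from
#'   the configuration).
#' @param seed RNG seed (default \code{config$seed + 1}).
#' @param channels \code{"signal"} rows, \code{"background"} rows, or both
#'   (default signal only, i.e. what the standard counting scheme emits).
#' @param status Optional replacement per-site methylation status vector
#'   (see \code{resample} in [simulate_paired_conditions()]).
#' @return Site-count data.frame (\code{chrom}, \code{pos}, \code{strand},
#'   \code{context}, \code{upstream}, \code{read}, \code{error},
#'   \code{total}).
#' @export
simulate_pileup_counts <- function(sim, coverage = sim$config$coverage,
                                   seed = sim$config$seed + 1L,
                                   channels = "signal", status = NULL) {
  stopifnot(inherits(sim, "raml_sim"),
            all(channels %in% c("signal", "background")))
  set.seed(seed)
  cfg <- sim$config
  d <- cfg$deamination_rate
  e <- cfg$background_rate
  chars <- strsplit(sim$sequence, "", fixed = TRUE)[[1]]
  if (is.null(status)) status <- sim$cpg_sites$status
  stopifnot(length(status) == nrow(sim$cpg_sites))

  # top-strand cytosines within regions: every C in the sequence
  c_pos <- which(chars == "C") - 1L
  snp_drop <- integer(0)
  snp_forced <- integer(0)
  if (nrow(sim$snps) > 0L) {
    at_c <- sim$snps[sim$snps$ref == "C", , drop = FALSE]
    snp_forced <- at_c$pos[at_c$alt == "T"]
    snp_drop <- at_c$pos[at_c$alt != "T"]
  }
  c_pos <- setdiff(c_pos, snp_drop)
  is_cpg_c <- c_pos %in% sim$cpg_sites$pos
  st <- numeric(length(c_pos))
  st[is_cpg_c] <- status[match(c_pos[is_cpg_c], sim$cpg_sites$pos)]
  p_sig_top <- pmin(1, d * st + e)
  p_sig_top[c_pos %in% snp_forced] <- 1
  nb <- ifelse(c_pos + 2L <= length(chars), chars[c_pos + 2L], "N")
  ctx_top <- context_from_next(nb)
  up_top <- ifelse(c_pos >= 1L, chars[c_pos], "N")
  n1 <- stats::rbinom(length(c_pos), coverage, 0.5)
  n2 <- coverage - n1
  rows <- list()
  if ("signal" %in% channels) {
    rows$r1_top <- data.frame(chrom = sim$chrom, pos = c_pos, strand = "+",
                              context = ctx_top, upstream = up_top, read = 1L,
                              error = stats::rbinom(length(c_pos), n1, p_sig_top),
                              total = n1, stringsAsFactors = FALSE)
  }
  if ("background" %in% channels) {
    rows$r2_top <- data.frame(chrom = sim$chrom, pos = c_pos, strand = "+",
                              context = ctx_top, upstream = up_top, read = 2L,
                              error = stats::rbinom(length(c_pos), n2, e),
                              total = n2, stringsAsFactors = FALSE)
  }

  # bottom-strand cytosines: reference G of each CpG
  g_pos <- sim$cpg_sites$pos + 1L
  p_sig_bot <- pmin(1, d * status + e)
  up_bot <- comp_base(ifelse(g_pos + 2L <= length(chars), chars[g_pos + 2L], "N"))
  n1b <- stats::rbinom(length(g_pos), coverage, 0.5)
  n2b <- coverage - n1b
  if ("signal" %in% channels) {
    rows$r2_bot <- data.frame(chrom = sim$chrom, pos = g_pos, strand = "-",
                              context = "CpG", upstream = up_bot, read = 2L,
                              error = stats::rbinom(length(g_pos), n2b, p_sig_bot),
                              total = n2b, stringsAsFactors = FALSE)
  }
  if ("background" %in% channels) {
    rows$r1_bot <- data.frame(chrom = sim$chrom, pos = g_pos, strand = "-",
                              context = "CpG", upstream = up_bot, read = 1L,
                              error = stats::rbinom(length(g_pos), n1b, e),
                              total = n1b, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$pos, out$strand, out$read), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate deaminated paired-end reads (SAM)
#'
#' The full-fidelity simulation path: emits proper paired-end read pairs
#' over the synthetic reference. Fragments of \code{fragment_length} are
#' placed uniformly across each region; Read1 covers the fragment start on
#' the forward strand, Read2 the fragment end on the reverse strand, so
#' mates overlap by \code{2*read_length - fragment_length} bases. Each
#' methylated CpG cytosine covered by Read1 is converted C-to-T with
#' probability \code{deamination_rate}; each covered CpG guanine in Read2
#' becomes G-to-A likewise (the deaminated bottom-strand cytosine seen in
#' reverse complement). Background error converts any C to T and any G to A
#' with probability \code{background_rate} in both mates. Planted SNPs are
#' substituted in every read. Base qualities are constant Q37, optionally
#' degraded to Q2 over the first and last two cycles to exercise the
#' cycle-exclusion filter.
#'
#' @param sim A [simulate_reference()] result.
#' @param coverage Target per-base read coverage (default from config).
#' @param seed RNG seed (default \code{config$seed + 2}).
#' @param degrade_ends Lower the first/last two cycles to Q2 (default
#'   FALSE).
#' @param status Optional replacement per-site methylation status.
#' @return A \code{sam_file} list (see [read_sam()]), coordinate-sorted.
#' @export
simulate_sam_reads <- function(sim, coverage = sim$config$coverage,
                               seed = sim$config$seed + 2L,
                               degrade_ends = FALSE, status = NULL) {
  stopifnot(inherits(sim, "raml_sim"))
  set.seed(seed)
  cfg <- sim$config
  lr <- cfg$read_length
  lf <- cfg$fragment_length
  chars <- strsplit(sim$sequence, "", fixed = TRUE)[[1]]
  if (nrow(sim$snps) > 0L) chars[sim$snps$pos + 1L] <- sim$snps$alt
  if (is.null(status)) status <- sim$cpg_sites$status
  meth_c <- sim$cpg_sites$pos[status == 1L]       # deaminatable top-strand C
  meth_g <- sim$cpg_sites$pos[status == 1L] + 1L  # deaminatable bottom-strand C (ref G)
  meth_c_set <- logical(length(chars))
  meth_c_set[meth_c + 1L] <- TRUE
  meth_g_set <- logical(length(chars))
  meth_g_set[meth_g + 1L] <- TRUE
  d <- cfg$deamination_rate
  e <- cfg$background_rate
  qual <- strrep("F", lr)
  if (degrade_ends) {
    q <- strsplit(qual, "")[[1]]
    q[c(1L, 2L, lr - 1L, lr)] <- "#"
    qual <- paste(q, collapse = "")
  }
  recs <- vector("list", nrow(sim$regions))
  for (r in seq_len(nrow(sim$regions))) {
    start <- sim$regions$start[r]
    end <- sim$regions$end[r]
    n_frag <- ceiling(coverage * (end - start) / (2L * lr))
    fs <- sample(seq.int(max(0L, start - (lf - lr)), end - lr), n_frag, replace = TRUE)
    r1_pos <- fs
    r2_pos <- fs + lf - lr
    make_read <- function(pos0, signal_set, ref_b, alt_b) {
      idx <- (pos0 + 1L):(pos0 + lr)
      s <- chars[idx]
      hit <- signal_set[idx] & stats::runif(lr) < d
      s[hit & s == ref_b] <- alt_b
      if (e > 0) {
        bg <- stats::runif(lr) < e
        s[bg & s == "C"] <- "T"
        s[bg & s == "G"] <- "A"
      }
      paste(s, collapse = "")
    }
    r1_seq <- vapply(r1_pos, make_read, character(1), meth_c_set, "C", "T")
    r2_seq <- vapply(r2_pos, make_read, character(1), meth_g_set, "G", "A")
    qname <- sprintf("frag_%s_%05d", sim$regions$name[r], seq_len(n_frag))
    recs[[r]] <- data.frame(
      qname = rep(qname, 2L),
      flag = rep(c(99L, 147L), each = n_frag),
      rname = sim$chrom,
      pos0 = c(r1_pos, r2_pos),
      mapq = 60L,
      cigar = paste0(lr, "M"),
      rnext = "=",
      pnext = c(r2_pos, r1_pos) + 1L,
      tlen = rep(c(lf, -lf), each = n_frag),
      seq = c(r1_seq, r2_seq),
      qual = qual,
      tags = "",
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  records <- records[order(records$pos0, records$qname), , drop = FALSE]
  rownames(records) <- NULL
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              paste0("@SQ\tSN:", sim$chrom, "\tLN:", length(chars)))
  structure(list(header = header, records = records), class = "sam_file")
}

#' Simulate observations from a synthetic reference
#'
#' Dispatcher over the two simulation paths: \code{"counts"} draws per-site
#' pileup counts directly ([simulate_pileup_counts()], ~100x faster, used
#' by most tests), \code{"sam"} emits full read pairs
#' ([simulate_sam_reads()], exercising the trim/count path end to end).
#' With both paths, zero deamination and zero background yield zero
#' transitions anywhere.
#'
#' @param sim A [simulate_reference()] result.
#' @param mode \code{"counts"} or \code{"sam"}.
#' @param ... Passed to the underlying simulator.
#' @return A site-count data.frame or a \code{sam_file}.
#' @export
simulate_observations <- function(sim, mode = c("counts", "sam"), ...) {
  mode <- match.arg(mode)
  if (mode == "counts") simulate_pileup_counts(sim, ...) else simulate_sam_reads(sim, ...)
}

#' Simulate two conditions with known differentially methylated regions
#'
#' Builds one shared synthetic reference, then shifts the assigned
#' methylation of a designated fraction of regions by \code{effect} in
#' condition A (clipping to [0, 1] with a warning, recorded in the truth),
#' and draws \code{n_reps} replicate pileup-count datasets per condition.
#' Replicates share the reference and region assignment but resample the
#' per-site methylation status and counts with offset seeds, emulating
#' independent library preparations from the same two specimen pools.
#'
#' @param config A [sim_config()].
#' @param dmr_fraction Fraction of regions shifted in condition A.
#' @param effect Methylation shift in (0, 1].
#' @param n_reps Replicates per condition (default 3).
#' @param coverage Observations per site per strand (default from config).
#' @return List: \code{sim} (the shared reference), \code{truth}
#'   (data.frame with per-region \code{name}, \code{meth_a},
#'   \code{meth_b}, \code{is_dmr}, \code{clipped}), \code{cond_a} and
#'   \code{cond_b} (lists of \code{n_reps} site-count data.frames).
#' @export
simulate_paired_conditions <- function(config, dmr_fraction = 0.2, effect = 0.3,
                                       n_reps = 3L, coverage = config$coverage) {
  stopifnot(inherits(config, "sim_config"), effect > 0, effect <= 1,
            dmr_fraction >= 0, dmr_fraction <= 1, n_reps >= 1L)
  sim <- simulate_reference(config)
  base <- sim$regions$methylation
  n <- length(base)
  # control regions stay fully methylated in both conditions: they are the
  # calibration anchor, so only analysis regions are eligible for a shift
  eligible <- which(sim$regions$kind != "control")
  n_shift <- round(dmr_fraction * length(eligible))
  shifted <- if (n_shift > 0L) sort(sample(eligible, n_shift)) else integer(0)
  meth_a <- base
  meth_a[shifted] <- base[shifted] + effect
  clipped <- meth_a > 1 | meth_a < 0
  if (any(clipped)) {
    warning(sum(clipped), " shifted region(s) clipped to [0, 1]")
    meth_a <- pmin(1, pmax(0, meth_a))
  }
  draw <- function(meth, offset) {
    lapply(seq_len(n_reps), function(k) {
      st <- resample_site_status(sim, meth, seed = config$seed + offset + 2L * k)
      simulate_pileup_counts(sim, coverage = coverage,
                             seed = config$seed + offset + 2L * k + 1L,
                             status = st)
    })
  }
  list(sim = sim,
       truth = data.frame(name = sim$regions$name, base_meth = base,
                          meth_a = meth_a, meth_b = base,
                          is_dmr = seq_len(n) %in% shifted,
                          clipped = clipped, stringsAsFactors = FALSE),
       cond_a = draw(meth_a, offset = 1000L),
       cond_b = draw(base, offset = 5000L))
}
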