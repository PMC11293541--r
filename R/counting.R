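#' Counting filters for transition counting
#'
#' Bundles the mpileup-style observation filters used by
#' [count_base_transitions()]: minimum mapping quality, minimum base
#' quality, read-cycle exclusion at both read ends (deamination-like
#' artifacts concentrate in the first and last sequencing cycles), and a
#' SNP mask (variant positions masquerade as transitions). Defaults follow
#' the values that maximise methylation-call accuracy for short-read
#' alignments: MAPQ >= 10, BQ >= 30, first two and last two cycles dropped.
#'
#' @param min_mapq Minimum mapping quality (default 10).
#' @param min_baseq Minimum base quality (default 30).
#' @param exclude_cycles Integer pair \code{c(head, tail)}: number of cycles
#'   ignored at the start and end of every read (default \code{c(2, 2)}).
#' @param snp_mask Optional [snp_mask()] of positions to exclude.
#' @return List of class \code{counting_filters}.
#' @export
counting_filters <- function(min_mapq = 10L, min_baseq = 30L,
                             exclude_cycles = c(2L, 2L), snp_mask = NULL) {
  stopifnot(min_mapq >= 0, min_baseq >= 0, length(exclude_cycles) == 2L,
            all(exclude_cycles >= 0))
  structure(list(min_mapq = as.integer(min_mapq),
                 min_baseq = as.integer(min_baseq),
                 exclude_cycles = as.integer(exclude_cycles),
                 snp_mask = snp_mask),
            class = "counting_filters")
}

# Coerce a reference (DNAStringSet, named character vector of sequences, or
# FASTA path) to a list of per-chromosome character vectors.
ref_chars <- function(reference) {
  if (is.character(reference) && length(reference) == 1L && file.exists(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
  }
  if (methods::is(reference, "DNAStringSet")) {
    seqs <- as.character(reference)
    names(seqs) <- sub("\\s.*$", "", names(reference))
  } else if (is.character(reference)) {
    if (is.null(names(reference))) stop("character reference must be named by chromosome")
    seqs <- reference
  } else {
    stop("unsupported reference type: ", class(reference)[1])
  }
  lapply(seqs, function(s) strsplit(toupper(s), "", fixed = TRUE)[[1]])
}

comp_base <- function(x) chartr("ACGTN", "TGCAN", x)

context_from_next <- function(nb) {
  ifelse(nb %in% c("A", "C", "G", "T"), paste0("Cp", nb), "CpN")
}

empty_site_counts <- function(by_cycle = FALSE) {
  df <- data.frame(chrom = character(0), pos = integer(0), strand = character(0),
                   context = character(0), upstream = character(0),
                   read = integer(0), error = integer(0), total = integer(0),
                   stringsAsFactors = FALSE)
  if (by_cycle) df$cycle <- integer(0)
  df
}

#' Count reference-base to alternate-base transitions per site
#'
#' The generic per-read pileup counter behind [count_transitions()]. For the
#' selected mate it walks each alignment against the reference and, at every
#' reference position equal to \code{ref_base}, classifies the read base:
#' \code{ref_base} increments \code{total} only, \code{alt_base} increments
#' \code{error} and \code{total}, and any other base is ignored (so the
#' denominator is the count of cytosine-informative observations,
#' C + C-to-T). Observations failing the mapping-quality, base-quality,
#' read-cycle or SNP-mask filters, or aligned adjacent to an indel, are
#' skipped.
#'
#' Context is assigned on the cytosine's own strand: for \code{ref_base =
#' "C"} the CpN partner is the reference base 3' of the cytosine
#' (position + 1); for \code{ref_base = "G"} (the cytosine seen in reverse
#' complement) it is the complement of the base at position - 1. The
#' trinucleotide upstream base is recorded analogously.
#'
#' @param records SAM record data.frame (\code{read_sam()$records}),
#'   normally after [trim_overlap_sam()].
#' @param reference Reference genome: FASTA path, \code{DNAStringSet}, or
#'   named character vector of sequences.
#' @param filters A [counting_filters()] object.
#' @param ref_base,alt_base Single reference/observed bases, e.g. C/T for
#'   Read1 and G/A for Read2.
#' @param read_number 1 or 2; which mate to count (SAM first/second-in-pair
#'   flags).
#' @param by_cycle If TRUE, counts are kept per sequencing cycle instead of
#'   summed per site (used for imbalance profiles).
#' @return data.frame with columns \code{chrom}, \code{pos} (0-based
#'   position of the cytosine on its strand), \code{strand}, \code{context},
#'   \code{upstream}, \code{read}, \code{error}, \code{total} (and
#'   \code{cycle} when \code{by_cycle}).
#' @export
count_base_transitions <- function(records, reference, filters = counting_filters(),
                                   ref_base = "C", alt_base = "T",
                                   read_number = 1L, by_cycle = FALSE) {
  stopifnot(ref_base %in% c("A", "C", "G", "T"), alt_base %in% c("A", "C", "G", "T"),
            read_number %in% c(1L, 2L))
  ref <- ref_chars(reference)
  mask <- snp_keys(filters$snp_mask)
  sel <- if (read_number == 1L) is_read1(records$flag) else is_read2(records$flag)
  sel <- sel & !is_unmapped(records$flag) & !is_secondary_or_supp(records$flag) &
    records$mapq >= filters$min_mapq & records$cigar != "*"
  rec <- records[sel, , drop = FALSE]
  obs <- vector("list", nrow(rec))
  head_ex <- filters$exclude_cycles[1]
  tail_ex <- filters$exclude_cycles[2]
  rnames <- rec$rname
  cigars <- rec$cigar
  positions <- rec$pos0
  seqs <- rec$seq
  quals <- rec$qual
  flags <- rec$flag
  for (i in seq_len(nrow(rec))) {
    chrom <- rnames[i]
    if (is.null(ref[[chrom]])) stop("reference sequence missing for chromosome ", chrom)
    rseq <- ref[[chrom]]
    if (grepl("^\\d+M$", cigars[i])) {
      len <- as.integer(sub("M$", "", cigars[i]))
      qpos <- seq_len(len)
      rpos <- positions[i] + qpos - 1L
    } else {
      w <- aligned_walk(cigars[i], positions[i])
      if (nrow(w) == 0L) next
      aligned <- w$op %in% c("M", "=", "X")
      # indel adjacency: aligned bases whose walk neighbour is an I/D/N base
      indel <- w$op %in% c("I", "D", "N")
      near_indel <- aligned & (c(FALSE, indel[-nrow(w)]) | c(indel[-1], FALSE))
      keep <- aligned & !near_indel
      qpos <- w$qpos[keep]
      rpos <- w$rpos[keep]
    }
    if (length(qpos) == 0L) next
    if (any(rpos >= length(rseq))) stop("alignment beyond reference end on ", chrom)
    at_ref <- rseq[rpos + 1L] == ref_base
    qpos <- qpos[at_ref]
    rpos <- rpos[at_ref]
    if (length(qpos) == 0L) next
    read_len <- nchar(seqs[i])
    cycle <- if (is_reverse(flags[i])) read_len - qpos + 1L else qpos
    ok <- cycle > head_ex & cycle <= read_len - tail_ex
    bq <- utf8ToInt(quals[i]) - 33L
    ok <- ok & bq[qpos] >= filters$min_baseq
    if (length(mask) > 0L) ok <- ok & !(paste0(chrom, ":", rpos) %in% mask)
    qpos <- qpos[ok]; rpos <- rpos[ok]; cycle <- cycle[ok]
    if (length(qpos) == 0L) next
    base <- strsplit(seqs[i], "", fixed = TRUE)[[1]][qpos]
    informative <- base %in% c(ref_base, alt_base)
    qpos <- qpos[informative]; rpos <- rpos[informative]
    cycle <- cycle[informative]; base <- base[informative]
    if (length(qpos) == 0L) next
    if (ref_base == "C") {
      nb <- ifelse(rpos + 2L <= length(rseq), rseq[rpos + 2L], "N")
      up <- ifelse(rpos >= 1L, rseq[rpos], "N")
    } else {
      nb <- comp_base(ifelse(rpos >= 1L, rseq[rpos], "N"))
      up <- comp_base(ifelse(rpos + 2L <= length(rseq), rseq[rpos + 2L], "N"))
    }
    obs[[i]] <- list(chrom = chrom, pos = rpos, context = context_from_next(nb),
                     upstream = up, cycle = cycle,
                     err = as.integer(base == alt_base))
  }
  strand <- if (ref_base == "C") "+" else "-"
  obs <- obs[!vapply(obs, is.null, logical(1))]
  if (length(obs) == 0L) return(empty_site_counts(by_cycle))
  o <- data.frame(
    chrom = rep(vapply(obs, `[[`, character(1), "chrom"),
                vapply(obs, function(x) length(x$pos), integer(1))),
    pos = unlist(lapply(obs, `[[`, "pos")),
    strand = strand,
    context = unlist(lapply(obs, `[[`, "context")),
    upstream = unlist(lapply(obs, `[[`, "upstream")),
    cycle = unlist(lapply(obs, `[[`, "cycle")),
    err = unlist(lapply(obs, `[[`, "err")),
    stringsAsFactors = FALSE)
  key_cols <- c("chrom", "pos", "strand", "context", "upstream",
                if (by_cycle) "cycle")
  key <- do.call(paste, c(o[key_cols], sep = "\r"))
  err <- rowsum(o$err, key)
  tot <- rowsum(rep(1L, nrow(o)), key)
  parts <- strsplit(rownames(err), "\r", fixed = TRUE)
  out <- data.frame(chrom = vapply(parts, `[[`, character(1), 1L),
                    pos = as.integer(vapply(parts, `[[`, character(1), 2L)),
                    strand = vapply(parts, `[[`, character(1), 3L),
                    context = vapply(parts, `[[`, character(1), 4L),
                    upstream = vapply(parts, `[[`, character(1), 5L),
                    read = as.integer(read_number),
                    error = as.integer(err[, 1L]), total = as.integer(tot[, 1L]),
                    stringsAsFactors = FALSE)
  if (by_cycle) out$cycle <- as.integer(vapply(parts, `[[`, character(1), 6L))
  out <- out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count deamination-induced transitions at cytosines
#'
#' Applies the standard two-channel counting scheme for limited-deamination
#' libraries: C-to-T at reference C positions in Read1 and G-to-A at
#' reference G positions in Read2 (the deaminated strand seen in reverse
#' complement). With \code{all_channels = TRUE} the two mirror channels
#' (Read2 C-to-T, Read1 G-to-A), which carry only background error, are
#' counted as well; these are needed for [compute_imbalance()].
#'
#' Alignments should first pass through [trim_overlap_sam()] so mate
#' overlaps are not double-counted; this function trusts the masked base
#' qualities.
#'
#' @inheritParams count_base_transitions
#' @param all_channels Also count the background-only mirror channels.
#' @return Site-count data.frame (see [count_base_transitions()]); rows with
#'   \code{strand == "+"} are top-strand cytosines (reference C), rows with
#'   \code{strand == "-"} bottom-strand cytosines (reference G).
#' @export
count_transitions <- function(records, reference, filters = counting_filters(),
                              all_channels = FALSE, by_cycle = FALSE) {
  out <- rbind(
    count_base_transitions(records, reference, filters, "C", "T", 1L, by_cycle),
    count_base_transitions(records, reference, filters, "G", "A", 2L, by_cycle))
  if (all_channels) {
    out <- rbind(out,
      count_base_transitions(records, reference, filters, "C", "T", 2L, by_cycle),
      count_base_transitions(records, reference, filters, "G", "A", 1L, by_cycle))
  }
  rownames(out) <- NULL
  out
}

#' Aggregate site transition counts over regions
#'
#' Sums per-site \code{error} and \code{total} over all cytosine sites of
#' the requested context whose position falls inside each region
#' \code{[start, end)}; the regional transition rate is the pooled ratio
#' \code{sum(error) / sum(total)}. Regions containing no informative site
#' are flagged \code{uncovered} with an undefined (NA) rate.
#'
#' @param sites Site-count data.frame from [count_transitions()] or the
#'   simulator.
#' @param regions Region data.frame (\code{chrom,start,end,name}).
#' @param context Character vector of contexts to include (default
#'   \code{"CpG"}; use e.g. \code{c("CpA","CpT","CpC")} for the non-CpG
#'   background). \code{NULL} includes every context.
#' @param reads Which read channels to pool (default both mates).
#' @return data.frame: one row per region with \code{chrom,start,end,name},
#'   \code{n_sites} (distinct cytosine sites), \code{error}, \code{total},
#'   \code{rate}, \code{uncovered}.
#' @export
aggregate_regions <- function(sites, regions, context = "CpG", reads = c(1L, 2L)) {
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
  if (!is.null(context)) sites <- sites[sites$context %in% context, , drop = FALSE]
  sites <- sites[sites$read %in% reads, , drop = FALSE]
  name <- if ("name" %in% names(regions)) regions$name else paste0("region_", seq_len(nrow(regions)))
  out <- data.frame(chrom = regions$chrom, start = regions$start, end = regions$end,
                    name = name, n_sites = 0L, error = 0L, total = 0L,
                    stringsAsFactors = FALSE)
  if (nrow(sites) > 0L && nrow(regions) > 0L) {
    q <- GenomicRanges::GRanges(sites$chrom,
                                IRanges::IRanges(start = sites$pos + 1L, width = 1L))
    s <- GenomicRanges::GRanges(regions$chrom,
                                IRanges::IRanges(start = regions$start + 1L,
                                                 end = regions$end))
    hits <- GenomicRanges::findOverlaps(q, s)
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    if (length(qi) > 0L) {
      err <- rowsum(sites$error[qi], si)
      tot <- rowsum(sites$total[qi], si)
      nsite <- rowsum(rep(1L, length(qi)), si)
      idx <- as.integer(rownames(err))
      out$error[idx] <- as.integer(err[, 1L])
      out$total[idx] <- as.integer(tot[, 1L])
      out$n_sites[idx] <- as.integer(nsite[, 1L])
    }
  }
  out$rate <- ifelse(out$total > 0L, out$error / out$total, NA_real_)
  out$uncovered <- out$total == 0L
  out
}

#' Read1 versus Read2 transition-rate imbalance
#'
#' The deamination signal appears as C-to-T in Read1 but not in Read2's
#' C-to-T channel, whereas symmetric sequencing error affects both equally.
#' The excess rate \code{rate_R1 - rate_R2} per (context, cycle) cell
#' therefore isolates the deamination signal from shared background error.
#'
#' @param r1_sites,r2_sites By-cycle site counts for the C-to-T channel of
#'   Read1 and Read2 respectively, i.e.
#'   \code{count_base_transitions(..., "C", "T", read_number = 1, by_cycle = TRUE)}
#'   and the same with \code{read_number = 2}.
#' @param by Grouping columns (default context and cycle).
#' @return data.frame with per-cell Read1 and Read2 pooled rates and their
#'   difference \code{imbalance}; cells with zero total in either channel
#'   have \code{NA} imbalance.
#' @export
compute_imbalance <- function(r1_sites, r2_sites, by = c("context", "cycle")) {
  if (nrow(r1_sites) == 0L || nrow(r2_sites) == 0L) {
    stop("both read channels must contain observations")
  }
  pool <- function(df) {
    key <- do.call(paste, c(df[by], sep = "\r"))
    err <- rowsum(df$error, key)
    tot <- rowsum(df$total, key)
    data.frame(key = rownames(err), error = err[, 1L], total = tot[, 1L],
               stringsAsFactors = FALSE)
  }
  a <- pool(r1_sites)
  b <- pool(r2_sites)
  keys <- sort(union(a$key, b$key))
  ai <- match(keys, a$key)
  bi <- match(keys, b$key)
  tot1 <- ifelse(is.na(ai), 0, a$total[ai])
  tot2 <- ifelse(is.na(bi), 0, b$total[bi])
  rate1 <- ifelse(tot1 > 0, ifelse(is.na(ai), 0, a$error[ai]) / tot1, NA_real_)
  rate2 <- ifelse(tot2 > 0, ifelse(is.na(bi), 0, b$error[bi]) / tot2, NA_real_)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(out) <- by
  if ("cycle" %in% by) out$cycle <- as.integer(out$cycle)
  out$total_r1 <- tot1
  out$total_r2 <- tot2
  out$rate_r1 <- rate1
  out$rate_r2 <- rate2
  out$imbalance <- rate1 - rate2
  rownames(out) <- NULL
  out
}
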