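#' Mask the mate-overlap portion of Read2
#'
#' When paired-end mates overlap, the overlapping bases observe the same
#' original molecule position twice; counting both would double-count every
#' deamination event. This removes the overlap from Read2: every Read2 base
#' whose reference position falls inside Read1's reference span (and every
#' Read2 inserted base within that span) has its base quality set to
#' \code{!} (Q0), below any counting threshold, so downstream counting
#' ignores it. Read1 is never modified, the SAM records stay valid, and the
#' operation is idempotent.
#'
#' @param r1,r2 Single SAM records (one-row data.frames in the shape of
#'   \code{read_sam()$records}) for the first and second mate of one pair.
#' @return List with elements \code{r1} (unchanged) and \code{r2} (masked).
#'   Errors with class \code{improper_pair} if the mates are on different
#'   chromosomes, unmapped, or not flagged as a proper pair.
#' @export
trim_overlap <- function(r1, r2) {
  if (nrow(r1) != 1L || nrow(r2) != 1L) stop("trim_overlap expects single records")
  if (is_unmapped(r1$flag) || is_unmapped(r2$flag) ||
      !is_proper_pair(r1$flag) || !is_proper_pair(r2$flag) ||
      r1$rname != r2$rname) {
    stop(structure(class = c("improper_pair", "error", "condition"),
                   list(message = paste0("improper pair: ", r1$qname), call = NULL)))
  }
  r2$qual <- trim_overlap_core(r1$pos0, r1$cigar, r2$pos0, r2$cigar, r2$qual)
  list(r1 = r1, r2 = r2)
}

# Mask (Q0) the Read2 base qualities whose reference positions fall inside
# Read1's reference span; shared by trim_overlap and trim_overlap_sam.
trim_overlap_core <- function(pos1, cigar1, pos2, cigar2, qual2) {
  span1 <- ref_span(cigar1, pos1)
  span2 <- ref_span(cigar2, pos2)
  if (span2["end"] <= span1["start"] || span2["start"] >= span1["end"]) {
    return(qual2)
  }
  if (grepl("^\\d+M$", cigar2)) {
    # contiguous query range for a gapless alignment
    lo <- max(1L, span1[["start"]] - pos2 + 1L)
    hi <- min(nchar(qual2), span1[["end"]] - pos2)
    if (lo > hi) return(qual2)
    return(paste0(substr(qual2, 1L, lo - 1L), strrep("!", hi - lo + 1L),
                  substr(qual2, hi + 1L, nchar(qual2))))
  }
  w <- aligned_walk(cigar2, pos2)
  in_overlap <- (!is.na(w$rpos) & w$rpos >= span1["start"] & w$rpos < span1["end"]) |
    (w$op == "I" & !is.na(w$ref_at) & w$ref_at > span1["start"] & w$ref_at <= span1["end"])
  mask_q <- w$qpos[in_overlap & !is.na(w$qpos)]
  if (length(mask_q) > 0L) {
    qual <- strsplit(qual2, "", fixed = TRUE)[[1]]
    qual[mask_q] <- "!"
    qual2 <- paste(qual, collapse = "")
  }
  qual2
}

#' Trim mate overlaps across a whole SAM file
#'
#' Pairs records by query name, applies [trim_overlap()] to each proper
#' pair, and writes the result, preserving input record order and appending
#' a \code{@PG} header line. Pairs that are improperly mapped (different
#' chromosome, unmapped mate, missing proper-pair flag) and reads without a
#' usable mate are dropped, with a message reporting the counts.
#'
#' @param infile Input SAM path (any record order; pairing is by name).
#' @param outfile Output SAM path.
#' @return Invisibly, a list with counts: \code{pairs_kept},
#'   \code{pairs_rejected}, \code{unpaired_dropped}.
#' @export
trim_overlap_sam <- function(infile, outfile) {
  sam <- read_sam(infile)
  rec <- sam$records
  keep <- rep(FALSE, nrow(rec))
  rejected <- 0L
  unpaired <- 0L
  if (nrow(rec) > 0L) {
    primary <- !is_secondary_or_supp(rec$flag)
    idx_by_name <- split(seq_len(nrow(rec))[primary], rec$qname[primary])
    quals <- rec$qual
    for (idx in idx_by_name) {
      i1 <- idx[is_read1(rec$flag[idx])]
      i2 <- idx[is_read2(rec$flag[idx])]
      if (length(i1) != 1L || length(i2) != 1L) {
        unpaired <- unpaired + length(idx)
        next
      }
      if (is_unmapped(rec$flag[i1]) || is_unmapped(rec$flag[i2]) ||
          !is_proper_pair(rec$flag[i1]) || !is_proper_pair(rec$flag[i2]) ||
          rec$rname[i1] != rec$rname[i2]) {
        rejected <- rejected + 1L
        next
      }
      quals[i2] <- trim_overlap_core(rec$pos0[i1], rec$cigar[i1],
                                     rec$pos0[i2], rec$cigar[i2], quals[i2])
      keep[c(i1, i2)] <- TRUE
    }
    rec$qual <- quals
  }
  header <- c(sam$header,
              "@PG\tID:ramlseq_trim\tPN:ramlseq\tDS:mate overlap masked in Read2 (Q0)")
  write_sam(list(header = header, records = rec[keep, , drop = FALSE]), outfile)
  if (rejected > 0L || unpaired > 0L) {
    message("trim_overlap_sam: ", rejected, " improper pair(s) rejected, ",
            unpaired, " unpaired record(s) dropped")
  }
  invisible(list(pairs_kept = sum(keep) %/% 2L, pairs_rejected = rejected,
                 unpaired_dropped = unpaired))
}
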