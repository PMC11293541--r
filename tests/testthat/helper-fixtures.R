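# Shared fixture builders: SAM records, minimal VCFs, contributed-position
# bookkeeping for overlap tests. Everything is generated in code.

make_rec <- function(qname = "q1", flag = 99L, rname = "chr1", pos0 = 0L,
                     mapq = 60L, cigar = NULL, seq = "ACGT", qual = NULL,
                     rnext = "=", pnext = 1L, tlen = 0L, tags = "") {
  if (is.null(cigar)) cigar <- paste0(nchar(seq), "M")
  if (is.null(qual)) qual <- strrep("F", nchar(seq))
  data.frame(qname = qname, flag = as.integer(flag), rname = rname,
             pos0 = as.integer(pos0), mapq = as.integer(mapq), cigar = cigar,
             rnext = rnext, pnext = as.integer(pnext), tlen = as.integer(tlen),
             seq = seq, qual = qual, tags = tags, stringsAsFactors = FALSE)
}

# a read pair of gapless 'len'-length mates
make_pair <- function(qname, pos1, pos2, len = 100L, rname = "chr1",
                      seq1 = NULL, seq2 = NULL) {
  rbind(
    make_rec(qname, flag = 99L, rname = rname, pos0 = pos1,
             seq = seq1 %||% strrep("A", len)),
    make_rec(qname, flag = 147L, rname = rname, pos0 = pos2,
             seq = seq2 %||% strrep("A", len)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_test_vcf <- function(path, chrom, pos1, dp = NULL, filter = "PASS",
                           ref = "C", alt = "T") {
  n <- length(pos1)
  chrom <- rep_len(chrom, n)
  filter <- rep_len(filter, n)
  ref <- rep_len(ref, n)
  alt <- rep_len(alt, n)
  info <- if (is.null(dp)) rep(".", n) else ifelse(is.na(dp), ".", paste0("DP=", dp))
  header <- c("##fileformat=VCFv4.2",
              '##INFO=<ID=DP,Number=1,Type=Integer,Description="Total Depth">',
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (n > 0) paste(chrom, pos1, ".", ref, alt, "60", filter, info,
                           sep = "\t") else character(0)
  writeLines(c(header, body), path)
  path
}

# reference positions a record still contributes after quality masking
contributed_positions <- function(rec, min_baseq = 30L) {
  w <- ramlseq:::aligned_walk(rec$cigar, rec$pos0)
  w <- w[w$op %in% c("M", "=", "X"), , drop = FALSE]
  bq <- utf8ToInt(rec$qual) - 33L
  w$rpos[bq[w$qpos] >= min_baseq]
}
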