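#' Read a SAM file
#'
#' Reads a text SAM file into a header (character vector of \code{@} lines)
#' and a record table. The 11 mandatory fields are split out; any optional
#' tag fields are kept verbatim in a single \code{tags} column so records
#' round-trip byte-for-byte through [write_sam()]. \code{POS} is converted
#' to the package's 0-based convention (\code{pos0}).
#'
#' @param path SAM file path.
#' @return List of class \code{sam_file} with elements \code{header}
#'   (character) and \code{records} (data.frame with columns \code{qname},
#'   \code{flag}, \code{rname}, \code{pos0}, \code{mapq}, \code{cigar},
#'   \code{rnext}, \code{pnext}, \code{tlen}, \code{seq}, \code{qual},
#'   \code{tags}).
#' @export
read_sam <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  is_hdr <- grepl("^@", lines)
  header <- lines[is_hdr]
  body <- lines[!is_hdr & nzchar(lines)]
  if (length(body) == 0L) {
    return(structure(list(header = header, records = empty_sam_records()),
                     class = "sam_file"))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(fields) < 11L)) {
    stop("malformed SAM record (fewer than 11 fields) at body line ",
         which(lengths(fields) < 11L)[1L])
  }
  f <- function(i) vapply(fields, `[[`, character(1), i)
  tags <- vapply(fields, function(x) {
    if (length(x) > 11L) paste(x[-(1:11)], collapse = "\t") else ""
  }, character(1))
  records <- data.frame(
    qname = f(1), flag = as.integer(f(2)), rname = f(3),
    pos0 = as.integer(f(4)) - 1L, mapq = as.integer(f(5)), cigar = f(6),
    rnext = f(7), pnext = as.integer(f(8)), tlen = as.integer(f(9)),
    seq = f(10), qual = f(11), tags = tags, stringsAsFactors = FALSE)
  structure(list(header = header, records = records), class = "sam_file")
}

empty_sam_records <- function() {
  data.frame(qname = character(0), flag = integer(0), rname = character(0),
             pos0 = integer(0), mapq = integer(0), cigar = character(0),
             rnext = character(0), pnext = integer(0), tlen = integer(0),
             seq = character(0), qual = character(0), tags = character(0),
             stringsAsFactors = FALSE)
}

#' Write a SAM file
#'
#' @param sam A \code{sam_file} list as returned by [read_sam()], or a list
#'   with elements \code{header} and \code{records} in the same shape.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_sam <- function(sam, path) {
  r <- sam$records
  body <- character(0)
  if (!is.null(r) && nrow(r) > 0L) {
    body <- paste(r$qname, r$flag, r$rname, r$pos0 + 1L, r$mapq, r$cigar,
                  r$rnext, r$pnext, r$tlen, r$seq, r$qual, sep = "\t")
    has_tags <- nzchar(r$tags)
    body[has_tags] <- paste(body[has_tags], r$tags[has_tags], sep = "\t")
  }
  writeLines(c(sam$header, body), path)
  invisible(path)
}

# Split a CIGAR string into op lengths and codes.
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*") {
    return(data.frame(len = integer(0), op = character(0), stringsAsFactors = FALSE))
  }
  m <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  if (sum(nchar(m)) != nchar(cigar)) stop("malformed CIGAR: ", cigar)
  data.frame(len = as.integer(sub("[MIDNSHP=X]$", "", m)),
             op = sub("^\\d+", "", m), stringsAsFactors = FALSE)
}

# Reference span [start0, end0) consumed by an alignment; soft/hard clips
# and insertions consume no reference.
ref_span <- function(cigar, pos0) {
  ops <- parse_cigar(cigar)
  consumed <- sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")])
  c(start = pos0, end = pos0 + consumed)
}

# Per-base walk of an alignment: one row per query or reference base touched.
# qpos: 1-based index into SEQ (NA for D/N); rpos: 0-based reference position
# (NA for I/S); for insertions, ref_at records the reference position the
# inserted bases precede. Hard clips are ignored (not present in SEQ).
aligned_walk <- function(cigar, pos0) {
  # fast path for the ubiquitous single-M alignment
  if (grepl("^\\d+M$", cigar)) {
    len <- as.integer(sub("M$", "", cigar))
    return(data.frame(op = "M", qpos = seq_len(len),
                      rpos = pos0 + seq_len(len) - 1L, ref_at = NA_integer_,
                      stringsAsFactors = FALSE))
  }
  ops <- parse_cigar(cigar)
  q <- 1L
  r <- pos0
  rows <- vector("list", nrow(ops))
  for (i in seq_len(nrow(ops))) {
    len <- ops$len[i]
    op <- ops$op[i]
    if (op %in% c("M", "=", "X")) {
      rows[[i]] <- data.frame(op = op, qpos = q:(q + len - 1L),
                              rpos = r:(r + len - 1L), ref_at = NA_integer_,
                              stringsAsFactors = FALSE)
      q <- q + len; r <- r + len
    } else if (op == "I") {
      rows[[i]] <- data.frame(op = op, qpos = q:(q + len - 1L),
                              rpos = NA_integer_, ref_at = r,
                              stringsAsFactors = FALSE)
      q <- q + len
    } else if (op == "S") {
      q <- q + len
    } else if (op %in% c("D", "N")) {
      rows[[i]] <- data.frame(op = op, qpos = NA_integer_,
                              rpos = r:(r + len - 1L), ref_at = NA_integer_,
                              stringsAsFactors = FALSE)
      r <- r + len
    }
    # H and P consume nothing relevant here
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(op = character(0), qpos = integer(0), rpos = integer(0),
                      ref_at = integer(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

# SAM flag helpers
flag_has <- function(flag, bit) bitwAnd(flag, bit) > 0L
is_read1 <- function(flag) flag_has(flag, 64L)
is_read2 <- function(flag) flag_has(flag, 128L)
is_reverse <- function(flag) flag_has(flag, 16L)
is_unmapped <- function(flag) flag_has(flag, 4L)
is_proper_pair <- function(flag) flag_has(flag, 2L)
is_secondary_or_supp <- function(flag) bitwAnd(flag, 256L + 2048L) > 0L
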