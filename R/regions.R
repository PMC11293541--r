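#' Read genomic regions from a BED file
#'
#' Parses a BED3+ file into the package's region table. Coordinates are kept
#' verbatim in the BED convention: 0-based, half-open \code{[start, end)}.
#' That convention is used for every coordinate inside this package;
#' conversion to 1-based systems happens only at format boundaries.
#'
#' @param path Path to a BED file (plain text or gzip). Lines starting with
#'   \code{track}, \code{browser} or \code{#} are skipped.
#' @param kind Region kind label attached to every record, one of
#'   \code{"cgi"}, \code{"promoter"}, \code{"exon"}, \code{"control"},
#'   \code{"window"}, \code{"custom"}.
#' @return A data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{name}, \code{kind}. Records without a name column are auto-named
#'   \code{region_<i>}.
#' @export
read_regions_bed <- function(path, kind = "custom") {
  kind <- match.arg(kind, c("cgi", "promoter", "exon", "control", "window", "custom"))
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(empty_regions(kind))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- lengths(fields)
  if (any(n_col < 3L)) {
    stop("malformed BED line (fewer than 3 tab-separated columns) at line ",
         which(n_col < 3L)[1L])
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  if (anyNA(start) || anyNA(end)) {
    stop("malformed BED line (non-integer coordinate) at line ",
         which(is.na(start) | is.na(end))[1L])
  }
  if (any(start < 0L)) stop("negative start coordinate at line ", which(start < 0L)[1L])
  if (any(start >= end)) {
    stop("invalid region (start >= end) at line ", which(start >= end)[1L])
  }
  name <- ifelse(n_col >= 4L, vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else "", character(1)),
                 paste0("region_", seq_along(fields)))
  name[!nzchar(name)] <- paste0("region_", which(!nzchar(name)))
  data.frame(chrom = chrom, start = start, end = end, name = name,
             kind = kind, stringsAsFactors = FALSE)
}

empty_regions <- function(kind = "custom") {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             name = character(0), kind = character(0), stringsAsFactors = FALSE)
}

#' Write regions to a BED file
#'
#' Inverse of [read_regions_bed()]: writes \code{chrom}, \code{start},
#' \code{end}, \code{name} as tab-separated columns, coordinates verbatim.
#'
#' @param regions Region data.frame (columns \code{chrom,start,end,name}).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
  name <- if ("name" %in% names(regions)) regions$name else paste0("region_", seq_len(nrow(regions)))
  lines <- paste(regions$chrom, regions$start, regions$end, name, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Derive promoter regions from transcription start sites
#'
#' A promoter is defined as a fixed span around the annotated TSS: \code{up}
#' bases upstream of and \code{down} bases downstream from the TSS,
#' strand-aware. For a plus-strand TSS at position p the promoter is
#' \code{[p - up, p + down)}; for a minus-strand TSS it is the mirror
#' \code{[p - down, p + up)}. Regions are clipped at the chromosome origin so
#' edge TSSs remain usable. Defaults follow the common 1000 bp upstream /
#' 100 bp downstream definition.
#'
#' @param tss data.frame with columns \code{chrom}, \code{pos} (0-based TSS
#'   position) and \code{strand} (\code{"+"} or \code{"-"}); an optional
#'   \code{name} column is propagated.
#' @param up,down Non-negative extents in bases.
#' @return Region data.frame of kind \code{"promoter"}.
#' @export
promoters_from_tss <- function(tss, up = 1000L, down = 100L) {
  stopifnot(up >= 0, down >= 0, all(c("chrom", "pos", "strand") %in% names(tss)))
  bad <- !tss$strand %in% c("+", "-")
  if (any(bad)) stop("unknown strand symbol: ", paste(unique(tss$strand[bad]), collapse = ", "))
  plus <- tss$strand == "+"
  start <- ifelse(plus, tss$pos - up, tss$pos - down)
  end <- ifelse(plus, tss$pos + down, tss$pos + up)
  start <- pmax(start, 0L)
  name <- if ("name" %in% names(tss)) tss$name else paste0("promoter_", seq_len(nrow(tss)))
  data.frame(chrom = tss$chrom, start = as.integer(start), end = as.integer(end),
             name = name, kind = "promoter", stringsAsFactors = FALSE)
}

#' Tile fixed-width windows around anchor positions
#'
#' Tiles contiguous, non-overlapping windows of width \code{width} across
#' \code{[p - flank, p + flank)} for each anchor (for example a TSS), the
#' layout used for methylation meta-profiles around transcription start
#' sites (e.g. 100 bp windows within 2 kb of the TSS). Each window carries a
#' signed, strand-aware \code{distance}: the offset of the window's
#' upstream-most edge from the anchor (negative upstream of the anchor).
#'
#' @param anchors data.frame with columns \code{chrom}, \code{pos},
#'   \code{strand}; optional \code{name}.
#' @param flank Half-span in bases; \code{width} must divide \code{2*flank}.
#' @param width Window width in bases, > 0.
#' @return Region data.frame of kind \code{"window"} with an extra
#'   \code{distance} column. Windows that would start before the chromosome
#'   origin are dropped with a warning.
#' @export
sliding_window_regions <- function(anchors, flank = 2000L, width = 100L) {
  if (width <= 0) stop("width must be > 0")
  if (flank %% width != 0L) {
    stop("width (", width, ") must divide flank (", flank,
         ") so windows align with the anchor")
  }
  stopifnot(all(c("chrom", "pos", "strand") %in% names(anchors)))
  bad <- !anchors$strand %in% c("+", "-")
  if (any(bad)) stop("unknown strand symbol: ", paste(unique(anchors$strand[bad]), collapse = ", "))
  offsets <- seq.int(-flank, flank - width, by = width)
  n_win <- length(offsets)
  anchor_name <- if ("name" %in% names(anchors)) anchors$name else paste0("anchor_", seq_len(nrow(anchors)))
  out <- do.call(rbind, lapply(seq_len(nrow(anchors)), function(i) {
    p <- anchors$pos[i]
    starts <- p + offsets
    dist <- if (anchors$strand[i] == "+") starts - p else p - (starts + width)
    data.frame(chrom = anchors$chrom[i], start = as.integer(starts),
               end = as.integer(starts + width),
               name = paste0(anchor_name[i], "_", dist),
               kind = "window", distance = as.integer(dist),
               stringsAsFactors = FALSE)
  }))
  drop <- out$start < 0L
  if (any(drop)) {
    warning(sum(drop), " window(s) before the chromosome origin dropped")
    out <- out[!drop, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Read a SNP mask from a VCF file
#'
#' Builds the set of variant positions to exclude from transition counting.
#' Records must pass FILTER (\code{PASS} or \code{.}) and have read depth
#' \code{DP >= min_depth}; the depth filter removes low-coverage SNP calls.
#' DP is taken from the INFO field, falling back to the first sample's
#' FORMAT field. VCF 1-based positions are converted to the package's
#' 0-based convention.
#'
#' @param path VCF file path (plain or bgzip).
#' @param min_depth Minimum DP; records lacking DP when \code{min_depth > 0}
#'   are skipped with a warning. Default 5, the usual low-coverage cutoff.
#' @return data.frame of class \code{snp_mask} with columns \code{chrom} and
#'   \code{pos} (0-based), unique rows.
#' @export
read_snp_mask <- function(path, min_depth = 5L) {
  stopifnot(file.exists(path), min_depth >= 0)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0L) return(snp_mask(character(0), integer(0)))
  filt <- fix[, "FILTER"]
  pass <- is.na(filt) | filt %in% c(".", "PASS")
  dp <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "DP")))
  if (all(is.na(dp)) && nrow(vcf@gt %||% matrix(nrow = 0, ncol = 0)) > 0 && ncol(vcf@gt) > 1L) {
    gdp <- suppressWarnings(vcfR::extract.gt(vcf, "DP", as.numeric = TRUE))
    if (!is.null(gdp) && ncol(gdp) >= 1L) dp <- gdp[, 1L]
  }
  keep <- pass
  if (min_depth > 0L) {
    missing_dp <- is.na(dp) & pass
    if (any(missing_dp)) {
      warning(sum(missing_dp), " VCF record(s) without DP skipped (min_depth > 0)")
    }
    keep <- pass & !is.na(dp) & dp >= min_depth
  }
  snp_mask(fix[keep, "CHROM"], as.integer(fix[keep, "POS"]) - 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a SNP mask from positions
#'
#' @param chrom Character vector of reference names.
#' @param pos Integer vector of 0-based positions.
#' @return data.frame of class \code{snp_mask}; rows unique.
#' @export
snp_mask <- function(chrom = character(0), pos = integer(0)) {
  stopifnot(length(chrom) == length(pos))
  df <- unique(data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                          stringsAsFactors = FALSE))
  rownames(df) <- NULL
  class(df) <- c("snp_mask", "data.frame")
  df
}

# fast membership key shared by the counting code
snp_keys <- function(mask) {
  if (is.null(mask) || nrow(mask) == 0L) character(0) else paste0(mask$chrom, ":", mask$pos)
}
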