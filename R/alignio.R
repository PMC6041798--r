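## Stage 1: ingest per-haplotype alignments and apply read-level filters.
##
## Alignment tables are data.tables with one row per mapped record:
##   qname, mate (1L/2L, 0L unpaired), haplotype, pos (0-based), end
##   (0-based exclusive reference end), qlen (query length), mapq, nm, cigar,
##   reverse (logical).

ALN_COLS <- c("qname", "mate", "haplotype", "pos", "end", "qlen", "mapq",
              "nm", "cigar", "reverse")

sam_to_bam <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) return(path)
  dest <- tempfile(fileext = "")
  Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE)
}

#' Read and filter a per-haplotype alignment file
#'
#' Parses SAM or BAM and applies the read filters: secondary/supplementary
#' records, duplicate-flagged reads (and their mates), records below the
#' mapping-quality cutoff, and reads with multiple primary loci are removed.
#' Surviving records carry their edit distance from the NM tag.
#'
#' @param path SAM or BAM file of one read set aligned to one haplotype.
#' @param haplotype haplotype name the file belongs to.
#' @param min_mapq mapping-quality cutoff; records strictly below are removed
#'   (default 20).
#' @return list with `alignments` (data.table, see package internals) and
#'   `stats` (named integer vector of removal counts; categories sum to the
#'   number of mapped input records).
#' @export
read_alignments <- function(path, haplotype, min_mapq = 20L) {
  if (!file.exists(path)) stopf("alignment file not found: %s", path)
  bam <- sam_to_bam(path)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "pos", "mapq", "cigar"), tag = "NM")
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  mapped <- !bitwAnd(x$flag, 4L)
  dt <- data.table::data.table(
    qname = x$qname[mapped], flag = x$flag[mapped], pos = x$pos[mapped] - 1L,
    mapq = as.integer(x$mapq[mapped]), cigar = x$cigar[mapped],
    nm = as.integer(x$tag$NM[mapped]))
  no_nm <- is.na(dt$nm)
  if (any(no_nm)) {
    warnf("%d mapped records missing NM tag in %s; dropped", sum(no_nm), path)
    dt <- dt[!no_nm]
  }
  filter_alignment_records(dt, haplotype, min_mapq = min_mapq)
}

## Core Stage-1 filter shared by file and in-memory routes.  `dt` needs
## qname, flag, pos, mapq, cigar, nm.
filter_alignment_records <- function(dt, haplotype, min_mapq = 20L) {
  n_in <- nrow(dt)
  cat_count <- c(duplicate = 0L, multimapped = 0L, low_mapq = 0L,
                 retained = 0L)
  is_dup <- bitwAnd(dt$flag, 1024L) > 0L
  dup_names <- unique(dt$qname[is_dup])
  dup <- dt$qname %in% dup_names        # whole pair removed with its mate
  cat_count["duplicate"] <- sum(dup)
  dt <- dt[!dup]
  sec <- bitwAnd(dt$flag, 256L) > 0L | bitwAnd(dt$flag, 2048L) > 0L
  cat_count["multimapped"] <- sum(sec)
  dt <- dt[!sec]
  low <- dt$mapq < min_mapq
  cat_count["low_mapq"] <- sum(low)
  dt <- dt[!low]
  mate_v <- data.table::fifelse(bitwAnd(dt$flag, 1L) == 0L, 0L,
                                data.table::fifelse(bitwAnd(dt$flag, 64L) > 0L,
                                                    1L, 2L))
  dt[, mate := mate_v]
  multi <- dt[, .N, by = .(qname, mate)][N > 1L]
  if (nrow(multi)) {
    key <- paste(dt$qname, dt$mate)
    drop <- key %in% paste(multi$qname, multi$mate)
    cat_count["multimapped"] <- cat_count["multimapped"] + sum(drop)
    dt <- dt[!drop]
  }
  cat_count["retained"] <- nrow(dt)
  stopifnot(sum(cat_count) == n_in)
  rlen_v <- GenomicAlignments::cigarWidthAlongReferenceSpace(dt$cigar)
  qlen_v <- GenomicAlignments::cigarWidthAlongQuerySpace(dt$cigar)
  out <- dt[, .(qname, mate, haplotype = haplotype, pos, mapq, nm, cigar)]
  out[, end := pos + rlen_v]
  out[, qlen := qlen_v]
  out[, reverse := bitwAnd(dt$flag, 16L) > 0L]
  data.table::setcolorder(out, ALN_COLS)
  list(alignments = out[], stats = cat_count)
}

#' Combined edit distance of a read pair
#'
#' Edit distances of the two mates of a pair aligned to the same haplotype
#' are added.
#'
#' @param mate1,mate2 single-row alignment records (lists or data.table rows)
#'   with fields `haplotype` and `nm`.
#' @return integer combined edit distance.
#' @export
pair_edit_distance <- function(mate1, mate2) {
  if (!identical(as.character(mate1$haplotype),
                 as.character(mate2$haplotype)))
    stopf("mates aligned to different haplotypes (%s vs %s)",
          mate1$haplotype, mate2$haplotype)
  as.integer(mate1$nm + mate2$nm)
}

#' Extract reads of a target region plus unmapped reads
#'
#' Returns the identifiers of reads overlapping a region of the primary
#' reference together with all unmapped reads; when either mate of a pair
#' qualifies the whole pair is included (the returned ids are pair-level
#' qnames).
#'
#' @param path SAM or BAM aligned to the primary reference.
#' @param region region string `chrom:start-end` (1-based inclusive).
#' @return character vector of read ids.
#' @export
extract_target_reads <- function(path, region) {
  if (!file.exists(path)) stopf("alignment file not found: %s", path)
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4L) stopf("malformed region string: %s", region)
  chrom <- m[2]; from <- as.integer(m[3]); to <- as.integer(m[4])
  bam0 <- sam_to_bam(path)
  sorted <- Rsamtools::sortBam(bam0, tempfile())
  Rsamtools::indexBam(sorted)
  hdr <- Rsamtools::scanBamHeader(sorted)[[1]]$targets
  if (!chrom %in% names(hdr))
    stopf("region chromosome '%s' absent from alignment header", chrom)
  which <- GenomicRanges::GRanges(chrom, IRanges::IRanges(from, to))
  in_region <- Rsamtools::scanBam(
    sorted, param = Rsamtools::ScanBamParam(what = "qname",
                                            which = which))[[1]]$qname
  unmapped <- Rsamtools::scanBam(
    sorted, param = Rsamtools::ScanBamParam(
      what = "qname",
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = TRUE)))[[1]]$qname
  sort(unique(c(in_region, unmapped)))
}
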