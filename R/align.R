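## Exhaustive small-scale aligner: a desk-scale stand-in for a third-party
## splice-aware mapper.  Reads are aligned to every haplotype's transcript
## set (exact k-mer seeding + banded edit-distance verification, see
## src/align.cpp), alignments are projected to genomic coordinates with
## spliced CIGARs, and per-haplotype alignment tables (or SAM files) are
## produced with correct NM and a mapping quality reflecting within-
## haplotype uniqueness.

#' Align reads exhaustively against every haplotype
#'
#' Each mate is aligned independently to the transcript set of every
#' haplotype; the best alignment per haplotype is reported with its edit
#' distance (NM), spliced genomic CIGAR and a mapping quality of 50 when
#' the best locus is unique within the haplotype or 1 when several loci tie
#' (so the downstream MAPQ filter removes within-haplotype multimappers).
#' A mate whose best edit distance on a haplotype exceeds `max_nm` is
#' unmapped there, as with a real mapper's mismatch ceiling.
#'
#' @param reads list with `reads1`/`reads2` named character vectors (as
#'   from [simulate_reads()]), or a single named vector for single-end
#'   reads.
#' @param panel a `haplotype_panel`.
#' @param models exon data.table.
#' @param k seed k-mer length (default 15).
#' @param band band half-width of the verification DP (default 5).
#' @param max_nm per-mate edit-distance ceiling (default 2).
#' @return named list (one entry per haplotype) of alignment data.tables
#'   with columns `qname`, `mate`, `haplotype`, `pos`, `end`, `qlen`,
#'   `mapq`, `nm`, `cigar`, `reverse`.
#' @export
align_exhaustive <- function(reads, panel, models, k = 15L, band = 5L,
                             max_nm = 2L) {
  if (is.character(reads)) reads <- list(reads1 = reads, reads2 = NULL)
  r1 <- reads$reads1; r2 <- reads$reads2
  allreads <- c(r1, r2)
  qname <- c(names(r1), names(r2))
  mate <- c(rep(if (is.null(r2)) 0L else 1L, length(r1)),
            rep(2L, length(r2 %||% character(0))))
  tx_all <- transcript_seqs(panel, models)
  haps <- intersect(panel$haplotypes, unique(tx_all$haplotype))
  tx_list <- lapply(haps, function(h) tx_all[haplotype == h])
  names(tx_list) <- haps
  res <- .align_reads_cpp(unname(allreads), lapply(tx_list, `[[`, "seq"),
                          as.integer(k), as.integer(band),
                          as.integer(max_nm))
  out <- list()
  qlen_all <- nchar(allreads)
  for (i in seq_along(haps)) {
    h <- haps[i]
    sel <- res$hap == i
    if (!any(sel)) next
    tx <- tx_list[[i]]
    tid <- res$tid[sel]
    proj <- .project_alignments_cpp(res$pos[sel], res$cigar[sel], tid,
                                    tx$strand[tid] == "-",
                                    tx$ex_start, tx$ex_len)
    dt <- data.table::data.table(
      qname = qname[res$read[sel]], mate = mate[res$read[sel]],
      haplotype = h, pos = proj$pos, end = proj$end,
      qlen = qlen_all[res$read[sel]], nm = res$nm[sel], cigar = proj$cigar,
      reverse = xor(res$strand[sel] == 1L, tx$strand[tid] == "-"))
    data.table::setorder(dt, qname, mate, pos)
    loci <- dt[, .(n_loci = data.table::uniqueN(paste0(pos, "/", reverse))),
               by = .(qname, mate)]
    dt <- dt[!duplicated(dt[, .(qname, mate)])]
    dt <- merge(dt, loci, by = c("qname", "mate"))
    dt[, mapq := data.table::fifelse(n_loci > 1L, 1L, 50L)]
    dt[, n_loci := NULL]
    data.table::setcolorder(dt, ALN_COLS)
    out[[h]] <- dt[]
  }
  out
}

#' Write a per-haplotype alignment table as SAM
#'
#' Emits a valid minimal SAM: `@SQ` header for the haplotype sequence,
#' paired flags, spliced CIGARs and `NM` tags.  Read sequences are included
#' when supplied, otherwise written as `*`.
#'
#' @param aln alignment data.table for one haplotype (from
#'   [align_exhaustive()]).
#' @param panel a `haplotype_panel`.
#' @param haplotype haplotype name (reference sequence of the file).
#' @param path output SAM path.
#' @param reads optional list with `reads1`/`reads2` to embed sequences.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, panel, haplotype, path, reads = NULL) {
  a <- data.table::as.data.table(aln)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", haplotype,
                   panel$lengths[[haplotype]]))
  if (nrow(a) == 0L) { writeLines(hdr, path); return(invisible(path)) }
  data.table::setorder(a, qname, mate)
  ## mate lookup for pairing flags
  key <- paste0(a$qname, "\r", a$mate)
  other <- paste0(a$qname, "\r", data.table::fifelse(a$mate == 1L, 2L, 1L))
  mate_row <- match(other, key)
  paired <- a$mate > 0L
  flag <- data.table::fifelse(paired, 1L, 0L) +
    data.table::fifelse(paired & !is.na(mate_row), 2L, 0L) +
    data.table::fifelse(a$reverse, 16L, 0L) +
    data.table::fifelse(paired & is.na(mate_row), 8L, 0L) +
    data.table::fifelse(!is.na(mate_row) & a$reverse[pmax(mate_row, 1L)] &
                          !is.na(mate_row), 32L, 0L) +
    data.table::fifelse(a$mate == 1L, 64L, 0L) +
    data.table::fifelse(a$mate == 2L, 128L, 0L)
  seqs <- rep("*", nrow(a)); quals <- rep("*", nrow(a))
  if (!is.null(reads)) {
    pick <- data.table::fifelse(a$mate == 2L,
                                reads$reads2[a$qname], reads$reads1[a$qname])
    ## reported SEQ is on the reference strand
    seqs <- data.table::fifelse(a$reverse, rev_comp(pick), pick)
    quals <- strrep("I", nchar(seqs))
  }
  rnext <- data.table::fifelse(is.na(mate_row), "*", "=")
  pnext <- data.table::fifelse(is.na(mate_row), 0L,
                               a$pos[pmax(mate_row, 1L)] + 1L)
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t0\t%s\t%s\tNM:i:%d",
                   a$qname, flag, haplotype, a$pos + 1L, a$mapq, a$cigar,
                   rnext, pnext, seqs, quals, a$nm)
  writeLines(c(hdr, lines), path)
  invisible(path)
}
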