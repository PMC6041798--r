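## Stage 2a: assign filtered read pairs to genes on every haplotype and
## enforce the cross-haplotype consistency rules.

#' Assign read pairs to genes across haplotypes
#'
#' A pair is assigned to gene g on haplotype h iff both mates' aligned
#' intervals overlap g's span on h (any base of either mate counts; the
#' overlap is judged against the gene span, not individual exons).  Pairs
#' overlapping two or more genes on any haplotype are discarded
#' (`multi-gene`), as are pairs assigned to different genes on different
#' haplotypes (`cross-haplotype-conflict`).  Each surviving pair yields one
#' assignment: its gene plus the combined edit distance on every haplotype
#' where it aligns to that gene.
#'
#' @param alignments a single alignment data.table or a list of them (one
#'   per haplotype), as produced by [read_alignments()] or
#'   [align_exhaustive()].
#' @param models exon data.table (see [read_gene_models()]).
#' @return list with `assignments` (data.table: `read_pair_id`, `gene_id`,
#'   `haplotype`, `d` combined edit distance, `qlen` combined mate length)
#'   and `discards` (data.table: `read_pair_id`, `reason`).
#' @export
assign_read_pairs <- function(alignments, models) {
  if (is.data.frame(alignments)) alignments <- list(alignments)
  aln <- data.table::rbindlist(alignments, use.names = TRUE)
  spans <- gene_spans(models)
  if (nrow(aln) == 0L)
    return(list(assignments = empty_assignments(),
                discards = data.table::data.table(read_pair_id = character(0),
                                                  reason = character(0))))
  paired <- aln[, .(paired = any(mate > 0L)), by = qname]

  ol <- vector("list", length(unique(aln$haplotype)))
  haps <- unique(aln$haplotype)
  for (i in seq_along(haps)) {
    a <- aln[haplotype == haps[i]]
    s <- spans[haplotype == haps[i]]
    if (nrow(s) == 0L) next  # haplotype without annotation: contributes nothing
    hits <- IRanges::findOverlaps(IRanges::IRanges(a$pos + 1L, a$end),
                                  IRanges::IRanges(s$start + 1L, s$end))
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    ol[[i]] <- data.table::data.table(
      qname = a$qname[qi], mate = a$mate[qi], haplotype = haps[i],
      gene_id = s$gene_id[si], nm = a$nm[qi], qlen = a$qlen[qi])
  }
  ol <- data.table::rbindlist(ol)
  if (nrow(ol) == 0L)
    return(list(assignments = empty_assignments(),
                discards = data.table::data.table(
                  read_pair_id = unique(aln$qname), reason = "unassigned")))

  ## multi-gene on any haplotype (one ol row per record x overlapped gene,
  ## so distinct genes per (pair, haplotype) = rows of the deduped table)
  ngene <- unique(ol[, .(qname, haplotype, gene_id)])[
    , .(n = .N), by = .(qname, haplotype)]
  multi <- unique(ngene[n > 1L, qname])
  ol2 <- ol[!qname %in% multi]

  ## pair completeness per (pair, haplotype, gene); each mate contributes at
  ## most one row per group after Stage-1 filtering
  cand <- ol2[, .(n_mates = .N, d = sum(nm), qlen = sum(qlen)),
              by = .(qname, haplotype, gene_id)]
  cand <- merge(cand, paired, by = "qname")
  cand <- cand[(paired & n_mates == 2L) | (!paired & n_mates == 1L)]

  ## cross-haplotype gene identity
  xgene <- unique(cand[, .(qname, gene_id)])[, .(n = .N), by = qname]
  conflict <- xgene[n > 1L, qname]
  cand <- cand[!qname %in% conflict]

  assigned <- cand[, .(read_pair_id = qname, gene_id, haplotype,
                       d = as.integer(d), qlen = as.integer(qlen))]
  data.table::setorder(assigned, read_pair_id, haplotype)

  all_q <- unique(aln$qname)
  disc <- data.table::rbindlist(list(
    data.table::data.table(read_pair_id = multi, reason = "multi-gene"),
    data.table::data.table(read_pair_id = conflict,
                           reason = "cross-haplotype-conflict"),
    data.table::data.table(
      read_pair_id = setdiff(all_q, c(multi, conflict,
                                      unique(assigned$read_pair_id))),
      reason = "unassigned")))
  data.table::setorder(disc, read_pair_id)
  list(assignments = assigned[], discards = disc[])
}

empty_assignments <- function() {
  data.table::data.table(read_pair_id = character(0), gene_id = character(0),
                         haplotype = character(0), d = integer(0),
                         qlen = integer(0))
}

#' Write the discard log
#'
#' @param discards discard data.table from [assign_read_pairs()].
#' @param path output path (tab-separated, with header).
#' @return `path`, invisibly.
#' @export
write_discard_log <- function(discards, path) {
  utils::write.table(discards, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
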