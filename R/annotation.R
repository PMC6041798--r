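## Gene-model handling.  Models are held as a data.table of exons with one
## row per (haplotype, transcript, exon), using 0-based half-open coordinates
## internally; GTF input/output is 1-based closed per the format standard.

MODEL_COLS <- c("gene_id", "gene_name", "transcript_id", "haplotype",
                "strand", "start", "end", "gene_type", "transcript_type",
                "level")

#' Validate a gene-model exon table
#'
#' Checks the structural invariants of a model table: required columns,
#' strand in {+,-}, exons of a transcript sorted and non-overlapping, and
#' (when a panel is supplied) intervals within the haplotype sequence.
#'
#' @param models data.table of exons (see [read_gene_models()] for columns).
#' @param panel optional `haplotype_panel` for bounds checking.
#' @return the validated table, invisibly keyed by haplotype/gene.
#' @export
validate_gene_models <- function(models, panel = NULL) {
  models <- data.table::as.data.table(models)
  miss <- setdiff(MODEL_COLS, names(models))
  if (length(miss)) stopf("gene models missing columns: %s",
                          paste(miss, collapse = ", "))
  if (!all(models$strand %in% c("+", "-")))
    stopf("strand must be '+' or '-'")
  if (any(models$end <= models$start))
    stopf("empty or inverted exon interval")
  bad <- models[, {
    o <- order(start)
    s <- start[o]; e <- end[o]
    .(ok = all(s[-1] >= e[-length(e)]) || .N == 1L)
  }, by = .(haplotype, transcript_id)][ok == FALSE]
  if (nrow(bad)) stopf("overlapping exons within transcript %s on %s",
                       bad$transcript_id[1], bad$haplotype[1])
  if (!is.null(panel)) {
    unknown <- setdiff(unique(models$haplotype), panel$haplotypes)
    if (length(unknown)) stopf("annotation names unknown haplotype: %s",
                               unknown[1])
    lim <- panel$lengths[models$haplotype]
    if (any(models$end > lim))
      stopf("exon beyond haplotype sequence end (gene %s on %s)",
            models$gene_id[which(models$end > lim)[1]],
            models$haplotype[which(models$end > lim)[1]])
  }
  invisible(models)
}

#' Read and filter gene annotation (GTF, GENCODE attribute dialect)
#'
#' Parses exon records from one or more GTF files and applies the inclusion
#' filters: only transcripts whose type is in `gene_types` and whose
#' annotation `level` is at most `max_level` are kept, and genes with no
#' surviving transcript are dropped.  The genomic span of a gene is thereby
#' restricted to the span of its retained transcripts.
#'
#' @param gtf_paths one GTF whose seqnames are haplotype names, or a named
#'   character vector of per-haplotype GTF paths (names = haplotypes).
#' @param panel optional `haplotype_panel` used for validation.
#' @param gene_types character vector of types to keep (default
#'   "protein_coding").
#' @param max_level maximum annotation level to keep (default 2).
#' @return a data.table of exons with columns `gene_id`, `gene_name`,
#'   `transcript_id`, `haplotype`, `strand`, `start`, `end` (0-based
#'   half-open), `gene_type`, `transcript_type`, `level`.
#' @export
read_gene_models <- function(gtf_paths, panel = NULL,
                             gene_types = "protein_coding", max_level = 2L) {
  missing <- gtf_paths[!file.exists(gtf_paths)]
  if (length(missing)) stopf("GTF file not found: %s", missing[1])
  per_file_hap <- names(gtf_paths)
  out <- vector("list", length(gtf_paths))
  for (i in seq_along(gtf_paths)) {
    has_records <- any(!startsWith(readLines(gtf_paths[i], n = 100L), "#"))
    if (!has_records) {
      out[[i]] <- data.table::data.table(
        gene_id = character(0), gene_name = character(0),
        transcript_id = character(0), haplotype = character(0),
        strand = character(0), start = integer(0), end = integer(0),
        gene_type = character(0), transcript_type = character(0),
        level = integer(0))
      next
    }
    gr <- tryCatch(rtracklayer::import(gtf_paths[i], format = "gtf"),
                   error = function(e) stopf("cannot parse GTF %s: %s",
                                             gtf_paths[i], conditionMessage(e)))
    gr <- gr[gr$type == "exon"]
    dt <- data.table::data.table(
      gene_id = as.character(gr$gene_id),
      gene_name = if (!is.null(gr$gene_name)) as.character(gr$gene_name)
                  else as.character(gr$gene_id),
      transcript_id = as.character(gr$transcript_id),
      haplotype = if (!is.null(per_file_hap) && nzchar(per_file_hap[i]))
                    per_file_hap[i] else as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(BiocGenerics::strand(gr)),
      start = BiocGenerics::start(gr) - 1L,   # to 0-based half-open
      end = BiocGenerics::end(gr),
      gene_type = if (!is.null(gr$gene_type)) as.character(gr$gene_type)
                  else NA_character_,
      transcript_type = if (!is.null(gr$transcript_type))
                          as.character(gr$transcript_type)
                        else NA_character_,
      level = if (!is.null(gr$level)) as.integer(as.character(gr$level))
              else NA_integer_
    )
    if (!is.null(per_file_hap) && nzchar(per_file_hap[i])) {
      nseq <- length(unique(as.character(GenomicRanges::seqnames(gr))))
      if (nseq > 1L)
        stopf("GTF %s spans %d sequence records but is mapped to one haplotype",
              gtf_paths[i], nseq)
    }
    out[[i]] <- dt
  }
  models <- data.table::rbindlist(out)
  models <- filter_gene_models(models, gene_types = gene_types,
                               max_level = max_level)
  validate_gene_models(models, panel)
  models[]
}

#' Apply transcript inclusion filters to a model table
#'
#' Keeps transcripts whose type matches `gene_types` and whose level is at
#' most `max_level`; drops genes left with no transcript.  Idempotent.
#'
#' @inheritParams read_gene_models
#' @param models exon data.table.
#' @return the filtered exon table.
#' @export
filter_gene_models <- function(models, gene_types = "protein_coding",
                               max_level = 2L) {
  models <- data.table::as.data.table(models)
  type <- ifelse(is.na(models$transcript_type), models$gene_type,
                 models$transcript_type)
  gtype_ok <- is.na(models$gene_type) | models$gene_type %in% gene_types
  keep <- (is.na(type) | type %in% gene_types) & gtype_ok &
    (is.na(models$level) | models$level <= max_level)
  models[keep][order(haplotype, gene_id, transcript_id, start)]
}

#' Gene spans per haplotype
#'
#' The span of a gene on a haplotype is the union (min start, max end) of its
#' retained transcript spans.
#'
#' @param models exon data.table.
#' @return data.table with `gene_id`, `haplotype`, `strand`, `start`, `end`.
#' @export
gene_spans <- function(models) {
  data.table::as.data.table(models)[
    , .(strand = strand[1], start = min(start), end = max(end)),
    by = .(gene_id, haplotype)]
}

#' Gene order per haplotype and globally
#'
#' Genes are ordered by start coordinate on each haplotype (ties broken by
#' `gene_id`).  The global order is the order on the primary haplotype; a
#' gene absent from the primary is inserted after its nearest preceding
#' neighbour on a haplotype that carries it.
#'
#' @param models exon data.table.
#' @param panel `haplotype_panel` (supplies the primary haplotype), or a
#'   character scalar naming the primary haplotype.
#' @return list with `per_haplotype` (named list of gene-id vectors) and
#'   `global` (character vector over all genes).
#' @export
gene_order <- function(models, panel) {
  spans <- gene_spans(models)
  primary <- if (is.character(panel)) panel else panel$primary
  haps <- sort(unique(spans$haplotype))
  if (!primary %in% haps)
    stopf("primary haplotype '%s' carries no annotated gene", primary)
  per <- lapply(haps, function(h) {
    s <- spans[haplotype == h][order(start, gene_id)]
    s$gene_id
  })
  names(per) <- haps
  global <- per[[primary]]
  missing <- setdiff(unique(spans$gene_id), global)
  carriers <- split(spans$haplotype, spans$gene_id)
  progress <- TRUE
  while (length(missing) && progress) {
    progress <- FALSE
    for (g in sort(missing)) {
      for (h in sort(carriers[[g]])) {
        ord <- per[[h]]
        i <- match(g, ord)
        anchor <- NA_character_
        if (i > 1L) {
          preds <- ord[seq_len(i - 1L)]
          placed <- preds[preds %in% global]
          if (length(placed)) anchor <- placed[length(placed)]
        }
        at_front <- i == 1L || (i > 1L && !any(ord[seq_len(i - 1L)] %in% global) &&
                                any(ord[-seq_len(i)] %in% global))
        if (!is.na(anchor)) {
          j <- match(anchor, global)
          global <- append(global, g, after = j)
        } else if (at_front) {
          global <- c(g, global)
        } else next
        missing <- setdiff(missing, g)
        progress <- TRUE
        break
      }
    }
  }
  if (length(missing)) global <- c(global, sort(missing))
  list(per_haplotype = per, global = global)
}

#' Gene reliability from a simulation truth set
#'
#' Quantifies, per gene, how trustworthy read assignment is: the fraction of
#' the gene's reads that align to exactly one haplotype location
#' (`unique_fraction`) and the fraction of reads assigned to the gene whose
#' true source gene differs (`mismap_fraction`).  A gene is retained iff
#' `unique_fraction >= min_unique` and `mismap_fraction <= max_mismap`; a
#' gene with no reads is flagged `no-data` and not retained.
#'
#' @param assignments long assignment table (`read_pair_id`, `gene_id`,
#'   `haplotype`, `d`) as produced by [assign_read_pairs()].
#' @param truth data.table with `read_pair_id` and true `gene_id` per read
#'   pair.
#' @param min_unique minimum unique fraction (default 0.8).
#' @param max_mismap maximum mismapped fraction (default 0.2).
#' @param genes optional gene universe; genes with no reads are reported
#'   with a `no-data` note instead of being omitted.
#' @return data.table with `gene_id`, `n_reads`, `unique_fraction`,
#'   `mismap_fraction`, `retained`, `note`.
#' @export
gene_reliability <- function(assignments, truth, min_unique = 0.8,
                             max_mismap = 0.2, genes = NULL) {
  truth <- data.table::as.data.table(truth)
  a <- data.table::as.data.table(assignments)
  per_read <- a[, .(assigned_gene = gene_id[1], n_hap = .N),
                by = read_pair_id]
  tr <- merge(truth[, .(read_pair_id, true_gene = gene_id)], per_read,
              by = "read_pair_id", all.x = TRUE)
  uf <- tr[, .(n_reads = .N,
               unique_fraction = mean(!is.na(n_hap) & n_hap == 1L)),
           by = .(gene_id = true_gene)]
  mm <- merge(per_read, truth[, .(read_pair_id, true_gene = gene_id)],
              by = "read_pair_id", all.x = TRUE)
  mm <- mm[, .(mismap_fraction = mean(is.na(true_gene) |
                                        true_gene != assigned_gene)),
           by = .(gene_id = assigned_gene)]
  out <- merge(uf, mm, by = "gene_id", all = TRUE)
  if (!is.null(genes)) {
    extra <- setdiff(genes, out$gene_id)
    if (length(extra))
      out <- rbind(out, data.table::data.table(
        gene_id = extra, n_reads = 0L, unique_fraction = NA_real_,
        mismap_fraction = NA_real_), fill = TRUE)
  }
  out[is.na(n_reads), n_reads := 0L]
  out[is.na(unique_fraction), unique_fraction := 0]
  out[is.na(mismap_fraction), mismap_fraction := 0]
  out[, note := ifelse(n_reads == 0L, "no-data", "")]
  out[, retained := n_reads > 0L & unique_fraction >= min_unique &
        mismap_fraction <= max_mismap]
  out[order(gene_id)][]
}

#' Write gene models as GTF (GENCODE attribute dialect)
#'
#' Emits transcript and exon records with `gene_id`, `gene_name`,
#' `transcript_id`, `gene_type`, `transcript_type` and `level` attributes.
#' Coordinates are written 1-based closed; seqname is the haplotype name.
#'
#' @param models exon data.table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  m <- data.table::as.data.table(models)[order(haplotype, start, gene_id,
                                               transcript_id)]
  attrs <- function(d)
    sprintf(paste0('gene_id "%s"; transcript_id "%s"; gene_type "%s"; ',
                   'gene_name "%s"; transcript_type "%s"; level %d;'),
            d$gene_id, d$transcript_id,
            ifelse(is.na(d$gene_type), "protein_coding", d$gene_type),
            d$gene_name,
            ifelse(is.na(d$transcript_type), "protein_coding",
                   d$transcript_type),
            ifelse(is.na(d$level), 2L, d$level))
  tx <- m[, .(strand = strand[1], start = min(start), end = max(end),
              gene_id = gene_id[1], gene_name = gene_name[1],
              gene_type = gene_type[1], transcript_type = transcript_type[1],
              level = level[1]),
          by = .(haplotype, transcript_id)]
  tx_lines <- sprintf("%s\thapquant\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                      tx$haplotype, tx$start + 1L, tx$end, tx$strand,
                      attrs(tx))
  ex_lines <- sprintf("%s\thapquant\texon\t%d\t%d\t.\t%s\t.\t%s",
                      m$haplotype, m$start + 1L, m$end, m$strand, attrs(m))
  ## interleave: transcript line before its exons, in file order
  key <- c(paste0(tx$haplotype, ":", tx$transcript_id, ":0"),
           paste0(m$haplotype, ":", m$transcript_id, ":1"))
  starts <- c(tx$start, m$start)
  lines <- c(tx_lines, ex_lines)[order(c(tx$haplotype, m$haplotype),
                                       c(tx$start, m$start), key)]
  writeLines(lines, path)
  invisible(path)
}
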