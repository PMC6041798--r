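## Synthetic data: haplotype panels derived from a common ancestral
## sequence, transcript-level paired-end read simulation with designed
## haplotype mixture ratios, and truth bookkeeping.  All randomness flows
## from a single seed, so identical seeds give byte-identical outputs.

#' Specification of a synthetic haplotype panel
#'
#' @param n_haplotypes number of haplotypes (default 8, emulating the MHC
#'   reference panel).
#' @param n_genes number of genes (default 30).
#' @param gene_length genomic gene-span range in bp (default 1800-3200).
#' @param exons_per_gene candidate exon counts per gene (default 2:4).
#' @param snp_rate per-base substitution rate of each haplotype relative to
#'   the ancestral sequence (default 0.005).
#' @param indel_rate per-base indel initiation rate (sizes 1-3 bp, default
#'   2e-4).
#' @param presence_prob probability that a gene is annotated (and present in
#'   sequence) on a given haplotype (default 0.95); every gene is forced
#'   onto at least two haplotypes.
#' @param presence optional logical matrix (genes x haplotypes) overriding
#'   random presence.
#' @param intergenic intergenic gap length range (default 300-800).
#' @param second_transcript_prob probability that a gene with >= 3 exons
#'   carries a second, exon-skipping transcript (default 0.5).
#' @param read_len read length the panel is meant for; gene spans must be at
#'   least twice this (default 100).
#' @param seed RNG seed fixing all panel randomness.
#' @return an object of class `panel_spec`.
#' @export
panel_spec <- function(n_haplotypes = 8L, n_genes = 30L,
                       gene_length = c(1800L, 3200L), exons_per_gene = 2:4,
                       snp_rate = 0.005, indel_rate = 2e-4,
                       presence_prob = 0.95, presence = NULL,
                       intergenic = c(300L, 800L),
                       second_transcript_prob = 0.5, read_len = 100L,
                       seed = 1L) {
  if (n_haplotypes < 2L) stopf("need at least 2 haplotypes")
  for (r in c(snp_rate, indel_rate, presence_prob, second_transcript_prob))
    if (r < 0 || r > 1) stopf("rates must be in [0,1]")
  if (gene_length[1] < 2L * read_len)
    stopf("gene length %d below twice the read length", gene_length[1])
  if (any(exons_per_gene < 1L)) stopf("exons_per_gene must be >= 1")
  structure(list(n_haplotypes = as.integer(n_haplotypes),
                 n_genes = as.integer(n_genes),
                 gene_length = as.integer(gene_length),
                 exons_per_gene = as.integer(exons_per_gene),
                 snp_rate = snp_rate, indel_rate = indel_rate,
                 presence_prob = presence_prob, presence = presence,
                 intergenic = as.integer(intergenic),
                 second_transcript_prob = second_transcript_prob,
                 read_len = as.integer(read_len), seed = as.integer(seed)),
            class = "panel_spec")
}

## Mutate one sequence block: substitutions at snp_rate, 1-3 bp indels at
## indel_rate.  Returns the new sequence, a boundary map (old 0-based
## boundary -> new boundary) and the event list.
mutate_block <- function(seq, snp_rate, indel_rate) {
  L <- nchar(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  events <- list()
  sub_pos <- which(stats::runif(L) < snp_rate)
  if (length(sub_pos)) {
    chars[sub_pos] <- vapply(chars[sub_pos], function(b)
      sample(setdiff(bases, b), 1L), "")
    events[[1]] <- data.table::data.table(type = "sub", pos = sub_pos - 1L,
                                          len = 1L)
  }
  keep <- rep(1L, L); ins <- integer(L); ins_seq <- character(L)
  ipos <- which(stats::runif(L) < indel_rate)
  for (p in ipos) {
    len <- sample(1:3, 1L)
    if (stats::runif(1) < 0.5) {
      idx <- p:min(p + len - 1L, L)
      keep[idx] <- 0L
      events[[length(events) + 1L]] <-
        data.table::data.table(type = "del", pos = p - 1L, len = length(idx))
    } else {
      ins[p] <- ins[p] + len
      ins_seq[p] <- paste0(random_dna(len), ins_seq[p])
      events[[length(events) + 1L]] <-
        data.table::data.table(type = "ins", pos = p - 1L, len = len)
    }
  }
  pieces <- chars
  pieces[keep == 0L] <- ""
  has_ins <- which(ins > 0L)
  if (length(has_ins))
    pieces[has_ins] <- paste0(ins_seq[has_ins], pieces[has_ins])
  list(seq = paste(pieces, collapse = ""),
       bmap = c(0L, cumsum(keep + ins)),
       events = data.table::rbindlist(events))
}

#' Simulate a haplotype panel with per-haplotype annotation
#'
#' Draws an ancestral region (genes with exon/intron structure separated by
#' intergenic gaps), then derives each haplotype by mutating every block
#' independently at the specified substitution and indel rates.  Gene ids
#' and structures are shared across haplotypes; coordinates shift with
#' indels; genes absent from a haplotype are omitted from both its sequence
#' and its annotation.
#'
#' @param spec a [panel_spec()].
#' @return list with `panel` (a `haplotype_panel`), `models` (exon
#'   data.table), `variants` (truth list of injected mutations) and `spec`.
#' @export
simulate_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  set.seed(spec$seed)
  nh <- spec$n_haplotypes; ng <- spec$n_genes
  haps <- sprintf("h%02d", seq_len(nh))

  ## ancestral gene structures
  genes <- sprintf("G%03d", seq_len(ng))
  struct <- vector("list", ng)
  anc_gene <- character(ng)
  for (i in seq_len(ng)) {
    n_ex <- if (length(spec$exons_per_gene) == 1L) spec$exons_per_gene
            else sample(spec$exons_per_gene, 1L)
    introns <- if (n_ex > 1L) sample(100:300, n_ex - 1L, replace = TRUE)
               else integer(0)
    L <- sample(spec$gene_length[1]:spec$gene_length[2], 1L)
    exonic <- max(L - sum(introns), max(450L, n_ex * 220L))
    base_len <- exonic %/% n_ex
    ex_len <- base_len + sample(-40:40, n_ex, replace = TRUE)
    ex_len[n_ex] <- exonic - sum(ex_len[-n_ex])
    ## local exon starts (0-based within the gene block)
    starts <- cumsum(c(0L, head(ex_len, -1L) + introns))
    struct[[i]] <- list(n_ex = n_ex, ex_start = starts, ex_len = ex_len,
                        L = sum(ex_len) + sum(introns),
                        strand = sample(c("+", "-"), 1L))
    anc_gene[i] <- random_dna(struct[[i]]$L)
    ## transcripts: t1 = all exons; optionally t2 skips one internal exon
    tset <- list(seq_len(n_ex))
    if (n_ex >= 3L && stats::runif(1) < spec$second_transcript_prob) {
      drop <- sample(2:(n_ex - 1L), 1L)
      if (sum(ex_len[-drop]) >= 450L) tset <- c(tset, list(setdiff(seq_len(n_ex), drop)))
    }
    struct[[i]]$transcripts <- tset
    struct[[i]]$level <- sample(1:2, 1L)
  }
  anc_gap <- vapply(seq_len(ng + 1L), function(i)
    random_dna(sample(spec$intergenic[1]:spec$intergenic[2], 1L)), "")

  ## presence matrix
  pres <- spec$presence
  if (is.null(pres)) {
    pres <- matrix(stats::runif(ng * nh) < spec$presence_prob, ng, nh)
    for (i in seq_len(ng)) if (sum(pres[i, ]) < 2L)
      pres[i, sample(nh, 2L)] <- TRUE
  }
  dimnames(pres) <- list(genes, haps)

  seqs <- character(nh); names(seqs) <- haps
  model_rows <- list(); var_rows <- list()
  for (h in seq_len(nh)) {
    parts <- character(0); offset <- 0L
    for (i in seq_len(ng)) {
      gap <- mutate_block(anc_gap[i], spec$snp_rate, spec$indel_rate)
      parts <- c(parts, gap$seq); offset <- offset + nchar(gap$seq)
      if (!pres[i, h]) next
      mb <- mutate_block(anc_gene[i], spec$snp_rate, spec$indel_rate)
      st <- struct[[i]]
      if (nrow(mb$events))
        var_rows[[length(var_rows) + 1L]] <- data.table::data.table(
          haplotype = haps[h], gene_id = genes[i], mb$events)
      for (ti in seq_along(st$transcripts)) {
        ex_idx <- st$transcripts[[ti]]
        s0 <- st$ex_start[ex_idx]; e0 <- s0 + st$ex_len[ex_idx]
        s1 <- mb$bmap[s0 + 1L]; e1 <- pmax(mb$bmap[e0 + 1L], s1 + 1L)
        model_rows[[length(model_rows) + 1L]] <- data.table::data.table(
          gene_id = genes[i], gene_name = genes[i],
          transcript_id = sprintf("%s.t%d", genes[i], ti),
          haplotype = haps[h], strand = st$strand,
          start = offset + s1, end = offset + e1,
          gene_type = "protein_coding", transcript_type = "protein_coding",
          level = st$level)
      }
      parts <- c(parts, mb$seq); offset <- offset + nchar(mb$seq)
    }
    gap <- mutate_block(anc_gap[ng + 1L], spec$snp_rate, spec$indel_rate)
    parts <- c(parts, gap$seq)
    seqs[h] <- paste(parts, collapse = "")
  }
  panel <- haplotype_panel(seqs, primary = haps[1])
  models <- data.table::rbindlist(model_rows)
  validate_gene_models(models, panel)
  list(panel = panel, models = models,
       variants = data.table::rbindlist(var_rows), presence = pres,
       spec = spec)
}

#' Spliced transcript sequences of a panel
#'
#' @param panel a `haplotype_panel`.
#' @param models exon data.table.
#' @return data.table with one row per (haplotype, transcript):
#'   `haplotype`, `gene_id`, `transcript_id`, `strand`, `seq`, `tlen`, and
#'   list columns `ex_start`, `ex_len` (genomic, ascending).
#' @export
transcript_seqs <- function(panel, models) {
  m <- data.table::as.data.table(models)
  tx <- m[order(haplotype, transcript_id, start),
          .(gene_id = gene_id[1], strand = strand[1],
            ex_start = list(start), ex_len = list(end - start)),
          by = .(haplotype, transcript_id)]
  seqs <- character(nrow(tx)); tlen <- integer(nrow(tx))
  for (i in seq_len(nrow(tx))) {
    s <- panel$sequences[[tx$haplotype[i]]]
    st <- tx$ex_start[[i]]; le <- tx$ex_len[[i]]
    sq <- paste(substring(s, st + 1L, st + le), collapse = "")
    if (tx$strand[i] == "-") sq <- rev_comp(sq)
    seqs[i] <- sq; tlen[i] <- nchar(sq)
  }
  tx[, `:=`(seq = seqs, tlen = tlen)]
  tx[]
}

#' Simulate paired-end reads from a panel at a designed mixture ratio
#'
#' Per gene one or two haplotypes and one transcript are selected; for each
#' design unit (gene, haplotype) read pairs are generated by drawing insert
#' sizes uniformly from `insert_range` and start positions uniformly along
#' the transcript.  In a heterozygous design the minor haplotype receives
#' `n_pairs` pairs and the major `round(n_pairs * ratio)`; homozygous genes
#' receive `n_pairs`.  Base-call errors are injected i.i.d. at
#' `error_rate`.
#'
#' @param panel a `haplotype_panel`.
#' @param models exon data.table.
#' @param ratio designed major/minor expression ratio for heterozygous
#'   genes (default 1).
#' @param n_pairs pairs per design unit (default 2000).
#' @param insert_range fragment-length range in bp (default 150-350).
#' @param read_len mate length in bp (default 100).
#' @param error_rate i.i.d. substitution error rate per sequenced base
#'   (default 0).
#' @param prob_het probability a gene is simulated heterozygous (default
#'   0.5; requires two carrier haplotypes).
#' @param design optional explicit design data.table (`gene_id`,
#'   `haplotype`, `transcript_id`, `n_pairs`, `role`, `ratio`) overriding
#'   the random design.
#' @param seed RNG seed.
#' @return list with `reads1`, `reads2` (named character vectors; names are
#'   read-pair ids), `truth` (per-pair data.table) and `design`.
#' @export
simulate_reads <- function(panel, models, ratio = 1, n_pairs = 2000L,
                           insert_range = c(150L, 350L), read_len = 100L,
                           error_rate = 0, prob_het = 0.5, design = NULL,
                           seed = 1L) {
  set.seed(seed)
  if (insert_range[1] < read_len)
    stopf("minimum insert %d below read length %d", insert_range[1], read_len)
  tx <- transcript_seqs(panel, models)
  if (is.null(design)) {
    design <- make_design(tx, ratio, n_pairs, prob_het)
  }
  design <- data.table::as.data.table(design)
  r1 <- list(); r2 <- list(); truths <- list()
  for (i in seq_len(nrow(design))) {
    g <- design$gene_id[i]; h <- design$haplotype[i]
    t <- design$transcript_id[i]; n <- design$n_pairs[i]
    trow <- tx[haplotype == h & transcript_id == t]
    if (nrow(trow) != 1L)
      stopf("design names transcript %s absent from haplotype %s", t, h)
    tlen <- trow$tlen
    imax <- insert_range[2]
    if (tlen < imax) {
      warnf("transcript %s on %s shorter (%d) than max insert; truncating",
            t, h, tlen)
      imax <- tlen
    }
    if (tlen < insert_range[1]) stopf("transcript %s shorter than min insert", t)
    ins <- sample(insert_range[1]:imax, n, replace = TRUE)
    start <- floor(stats::runif(n) * (tlen - ins + 1L))
    tseq <- trow$seq
    m1 <- substring(tseq, start + 1L, start + read_len)
    m2 <- rev_comp(substring(tseq, start + ins - read_len + 1L, start + ins))
    e1 <- integer(n); e2 <- integer(n)
    if (error_rate > 0) {
      err <- inject_errors(m1, error_rate); m1 <- err$reads; e1 <- err$n_err
      err <- inject_errors(m2, error_rate); m2 <- err$reads; e2 <- err$n_err
    }
    ids <- sprintf("%s|%s|%05d", g, h, seq_len(n))
    names(m1) <- ids; names(m2) <- ids
    r1[[i]] <- m1; r2[[i]] <- m2
    truths[[i]] <- data.table::data.table(
      read_pair_id = ids, gene_id = g, haplotype = h, transcript_id = t,
      tstart = start, insert = ins, n_err1 = e1, n_err2 = e2,
      role = design$role[i], ratio = design$ratio[i])
  }
  list(reads1 = unlist(r1), reads2 = unlist(r2),
       truth = data.table::rbindlist(truths), design = design)
}

## random design: per gene pick zygosity, haplotype(s), transcript
make_design <- function(tx, ratio, n_pairs, prob_het) {
  rows <- list()
  for (g in unique(tx$gene_id)) {
    carriers <- sort(unique(tx[gene_id == g, haplotype]))
    tlist <- sort(unique(tx[gene_id == g, transcript_id]))
    tsel <- if (length(tlist) == 1L) tlist else sample(tlist, 1L)
    het <- length(carriers) >= 2L && stats::runif(1) < prob_het
    if (het) {
      hs <- if (length(carriers) == 2L) carriers else sample(carriers, 2L)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        gene_id = g, haplotype = hs,
        transcript_id = tsel,
        n_pairs = c(n_pairs, as.integer(round(n_pairs * ratio))),
        role = c("minor", "major"), ratio = ratio)
    } else {
      hs <- if (length(carriers) == 1L) carriers else sample(carriers, 1L)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        gene_id = g, haplotype = hs, transcript_id = tsel,
        n_pairs = n_pairs, role = "hom", ratio = 1)
    }
  }
  data.table::rbindlist(rows)
}

inject_errors <- function(reads, rate) {
  n_err <- stats::rbinom(length(reads), nchar(reads), rate)
  bases <- c("A", "C", "G", "T")
  idx <- which(n_err > 0L)
  for (i in idx) {
    ch <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    pos <- sample(length(ch), n_err[i])
    ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(bases, b), 1L), "")
    reads[i] <- paste(ch, collapse = "")
  }
  list(reads = reads, n_err = n_err)
}

#' Write reads as a FASTQ pair
#'
#' @param sim result of [simulate_reads()].
#' @param prefix output prefix; writes `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq` with constant quality 'I'.
#' @return the two paths, invisibly.
#' @export
write_fastq <- function(sim, prefix) {
  emit <- function(reads, path) {
    lines <- as.vector(rbind(paste0("@", names(reads)), unname(reads), "+",
                             strrep("I", nchar(reads))))
    writeLines(lines, path)
    path
  }
  p1 <- emit(sim$reads1, paste0(prefix, "_1.fastq"))
  p2 <- emit(sim$reads2, paste0(prefix, "_2.fastq"))
  invisible(c(p1, p2))
}
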