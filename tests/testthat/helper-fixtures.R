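## Shared fixtures, built in code.

## Two-haplotype toy panel with one single-exon gene each at a known locus.
toy_panel <- function() {
  set.seed(99)
  base <- random_dna_str(600)
  a <- base
  b <- paste0(substr(base, 1, 299), flip_base(substr(base, 300, 300)),
              substr(base, 301, 600))
  haplotype_panel(c(A = a, B = b), primary = "A")
}

random_dna_str <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                           replace = TRUE), collapse = "")

flip_base <- function(b) c(A = "C", C = "G", G = "T", T = "A")[[b]]

## Minimal exon table builder.
exon_row <- function(gene, tx, hap, start, end, strand = "+", level = 1L,
                     gene_type = "protein_coding",
                     transcript_type = "protein_coding") {
  data.table::data.table(gene_id = gene, gene_name = gene,
                         transcript_id = tx, haplotype = hap,
                         strand = strand, start = as.integer(start),
                         end = as.integer(end), gene_type = gene_type,
                         transcript_type = transcript_type,
                         level = as.integer(level))
}

## Hand-written SAM file with given records; header for one reference.
write_test_sam <- function(path, ref = "A", len = 600L, records = list()) {
  hdr <- c("@HD\tVN:1.6", sprintf("@SQ\tSN:%s\tLN:%d", ref, len))
  lines <- vapply(records, function(r) {
    paste(r$qname, r$flag, r$rname %||% ref, r$pos, r$mapq %||% 60L,
          r$cigar %||% "50M", r$rnext %||% "*", r$pnext %||% 0L, 0L,
          r$seq %||% "*", r$qual %||% "*",
          paste0("NM:i:", r$nm %||% 0L), sep = "\t")
  }, "")
  writeLines(c(hdr, lines), path)
  path
}

## Build a pair-score table directly (for graph tests).
score_row <- function(gene, h1, h2, M, D = 0, n = 10L) {
  data.table::data.table(gene_id = gene, h1 = pmin(h1, h2),
                         h2 = pmax(h1, h2), pair = pair_label(h1, h2),
                         M = M, D = D, n_reads = n)
}

## Random layered gene-graph instance for oracle tests.
random_graph_instance <- function(n_genes, n_states, haps = LETTERS[1:4],
                                  penalty = 0.0028) {
  cand <- data.table::rbindlist(lapply(seq_len(n_genes), function(i) {
    k <- sample(n_states, 1L)
    pairs <- unique(data.table::data.table(
      h1 = sample(haps, k, replace = TRUE),
      h2 = sample(haps, k, replace = TRUE)))
    pairs[, `:=`(a = pmin(h1, h2), b = pmax(h1, h2))]
    data.table::data.table(gene_id = sprintf("G%02d", i), h1 = pairs$a,
                           h2 = pairs$b, pair = pair_label(pairs$a, pairs$b),
                           M = round(stats::runif(nrow(pairs)), 3),
                           D = 0, n_reads = 5L)
  }))
  build_gene_graph(sprintf("G%02d", seq_len(n_genes)), cand,
                   penalty = penalty)
}

## hapquant internal helpers reused in tests
pair_label <- hapquant:::pair_label
random_dna <- hapquant:::random_dna
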