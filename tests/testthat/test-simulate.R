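test_that("panel simulation is deterministic and respects rates", {
  spec <- panel_spec(n_haplotypes = 3, n_genes = 4, seed = 11)
  s1 <- simulate_panel(spec)
  s2 <- simulate_panel(spec)
  expect_identical(s1$panel$sequences, s2$panel$sequences)
  expect_identical(s1$models, s2$models)

  ## SNP rate zero, indel rate zero: all haplotypes identical
  s0 <- simulate_panel(panel_spec(n_haplotypes = 3, n_genes = 3,
                                  snp_rate = 0, indel_rate = 0,
                                  presence_prob = 1, seed = 12))
  expect_equal(length(unique(unname(s0$panel$sequences))), 1L)

  ## substitution counts are binomial at the configured rate
  rate <- 0.01
  sp <- simulate_panel(panel_spec(n_haplotypes = 4, n_genes = 6,
                                  snp_rate = rate, indel_rate = 0,
                                  presence_prob = 1, seed = 13))
  L <- unname(sp$panel$lengths[1])
  subs <- sp$variants[type == "sub", .N, by = haplotype]
  ## genic blocks only carry recorded variants; use genic length
  genic <- sum(gene_spans(sp$models)[haplotype == "h01", end - start])
  for (n in subs$N)
    expect_lt(abs(n - genic * rate), 3 * sqrt(genic * rate * (1 - rate)) + 3)
})

test_that("panel round-trips through FASTA and GTF", {
  sim <- simulate_panel(panel_spec(n_haplotypes = 3, n_genes = 4, seed = 14))
  fa <- tempfile(fileext = ".fa"); gtf <- tempfile(fileext = ".gtf")
  write_haplotype_panel(sim$panel, fa)
  write_gtf(sim$models, gtf)
  p2 <- read_haplotype_panel(fa, primary = "h01")
  expect_identical(p2$sequences, sim$panel$sequences)
  m2 <- read_gene_models(gtf, p2)
  key <- function(m) data.table::setorder(
    data.table::as.data.table(m)[, .(gene_id, transcript_id, haplotype,
                                     strand, start, end)],
    haplotype, gene_id, transcript_id, start)
  expect_equal(key(m2), key(sim$models))
})

test_that("read simulation hits the designed counts with inserts in range", {
  sim <- simulate_panel(panel_spec(n_haplotypes = 3, n_genes = 3, seed = 15))
  rd <- simulate_reads(sim$panel, sim$models, ratio = 2, n_pairs = 200,
                       prob_het = 1, seed = 16)
  per_unit <- rd$truth[, .N, by = .(gene_id, haplotype, role)]
  expect_true(all(per_unit[role == "minor", N] == 200L))
  expect_true(all(per_unit[role == "major", N] == 400L))
  expect_true(all(rd$truth$insert >= 150L & rd$truth$insert <= 350L))
  ## designed counts are exact per (gene, haplotype)
  des <- merge(per_unit, rd$design,
               by = c("gene_id", "haplotype", "role"))
  expect_equal(des$N, des$n_pairs)
})

test_that("error-free reads are exact transcript substrings up to reverse complement", {
  sim <- simulate_panel(panel_spec(n_haplotypes = 2, n_genes = 3, seed = 17))
  rd <- simulate_reads(sim$panel, sim$models, ratio = 1, n_pairs = 30,
                       error_rate = 0, seed = 18)
  tx <- transcript_seqs(sim$panel, sim$models)
  tr <- merge(rd$truth, tx, by = c("haplotype", "transcript_id"))
  for (i in sample(nrow(tr), 25)) {
    expect_true(grepl(rd$reads1[[tr$read_pair_id[i]]], tr$seq[i],
                      fixed = TRUE))
    expect_true(grepl(hapquant:::rev_comp(rd$reads2[[tr$read_pair_id[i]]]),
                      tr$seq[i], fixed = TRUE))
  }
})

test_that("identical seeds give identical FASTQ and SAM bytes", {
  spec <- panel_spec(n_haplotypes = 2, n_genes = 2, seed = 19)
  mk <- function() {
    sim <- simulate_panel(spec)
    rd <- simulate_reads(sim$panel, sim$models, ratio = 1.5, n_pairs = 40,
                         seed = 20)
    fq <- tempfile()
    write_fastq(rd, fq)
    aln <- align_exhaustive(rd, sim$panel, sim$models)
    sam <- tempfile(fileext = ".sam")
    write_sam(aln[[1]], sim$panel, names(aln)[1], sam, reads = rd)
    list(fq = readLines(paste0(fq, "_1.fastq")), sam = readLines(sam))
  }
  a <- mk(); b <- mk()
  expect_identical(a$fq, b$fq)
  expect_identical(a$sam, b$sam)
  ## a different seed changes the reads
  sim <- simulate_panel(spec)
  rd1 <- simulate_reads(sim$panel, sim$models, seed = 20)
  rd2 <- simulate_reads(sim$panel, sim$models, seed = 21)
  expect_false(identical(rd1$reads1, rd2$reads1))
})

test_that("simulated alignments agree between the SAM route and the in-memory route", {
  sim <- simulate_panel(panel_spec(n_haplotypes = 3, n_genes = 3, seed = 22))
  rd <- simulate_reads(sim$panel, sim$models, ratio = 1, n_pairs = 50,
                       seed = 23)
  aln <- align_exhaustive(rd, sim$panel, sim$models)
  for (h in names(aln)[1:2]) {
    sam <- tempfile(fileext = ".sam")
    write_sam(aln[[h]], sim$panel, h, sam, reads = rd)
    back <- read_alignments(sam, h, min_mapq = 0L)$alignments
    cols <- c("qname", "mate", "haplotype", "pos", "end", "qlen", "nm")
    a <- data.table::setorder(aln[[h]][, cols, with = FALSE], qname, mate)
    b <- data.table::setorder(back[, cols, with = FALSE], qname, mate)
    expect_equal(as.data.frame(a), as.data.frame(b))
  }
})

test_that("spliced CIGARs restore the read from the genome", {
  ## alignment projection must reproduce each read by walking M/N/I/D ops
  sim <- simulate_panel(panel_spec(n_haplotypes = 2, n_genes = 3,
                                   exons_per_gene = 3:4, seed = 24))
  rd <- simulate_reads(sim$panel, sim$models, ratio = 1, n_pairs = 40,
                       seed = 25)
  aln <- align_exhaustive(rd, sim$panel, sim$models)
  a <- aln[[1]][nm == 0L & grepl("N", cigar)]
  expect_gt(nrow(a), 0L)  # some junction reads exist
  gseq <- sim$panel$sequences[[a$haplotype[1]]]
  for (i in seq_len(min(nrow(a), 20L))) {
    read <- if (a$mate[i] == 1L) rd$reads1[[a$qname[i]]]
            else rd$reads2[[a$qname[i]]]
    if (a$reverse[i]) read <- hapquant:::rev_comp(read)
    ops <- regmatches(a$cigar[i], gregexpr("[0-9]+[MIDN]", a$cigar[i]))[[1]]
    pos <- a$pos[i]
    rebuilt <- ""
    for (op in ops) {
      n <- as.integer(sub("[MIDN]", "", op))
      type <- sub("[0-9]+", "", op)
      if (type == "M") {
        rebuilt <- paste0(rebuilt, substr(gseq, pos + 1, pos + n))
        pos <- pos + n
      } else if (type %in% c("D", "N")) pos <- pos + n
      ## I consumes read only; with nm == 0 there are none
    }
    expect_identical(rebuilt, read)
    expect_equal(pos, a$end[i])
  }
})

test_that("a homozygous high-divergence simulation is called homozygous everywhere", {
  ## divergence at the level of classical HLA alleles: reads from one
  ## haplotype fail to map to any other, all pairs containing the true
  ## haplotype tie, and the parsimony tie-break yields {A,A} at every gene
  sim <- simulate_panel(panel_spec(n_haplotypes = 4, n_genes = 6,
                                   snp_rate = 0.08, presence_prob = 1,
                                   seed = 26))
  tx <- transcript_seqs(sim$panel, sim$models)
  src <- "h03"
  design <- data.table::data.table(
    gene_id = unique(sim$models$gene_id), haplotype = src,
    transcript_id = paste0(unique(sim$models$gene_id), ".t1"),
    n_pairs = 80L, role = "hom", ratio = 1)
  rd <- simulate_reads(sim$panel, sim$models, design = design, seed = 27)
  aln <- align_exhaustive(rd, sim$panel, sim$models)
  fit <- hapquant(aln, sim$panel, sim$models)
  with_reads <- fit$calls[wildcard == FALSE]
  expect_true(all(with_reads$zygosity == "hom"))
  expect_true(all(with_reads$h1 == src))
})
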