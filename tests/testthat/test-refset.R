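test_that("panel construction validates names, sequences and primary", {
  p <- haplotype_panel(c(A = "ACGT", B = "ACGTT"), primary = "A")
  expect_s3_class(p, "haplotype_panel")
  expect_equal(p$haplotypes, c("A", "B"))
  expect_equal(unname(p$lengths), c(4L, 5L))
  expect_error(haplotype_panel(c(A = "ACGT", A = "ACGT")), "duplicate")
  expect_error(haplotype_panel(c(A = "ACGT", B = "")), "non-empty")
  expect_error(haplotype_panel(c(A = "ACGT"), primary = "Z"), "primary")
})

test_that("FASTA panel round-trips through write and load", {
  sim <- simulate_panel(panel_spec(n_haplotypes = 3, n_genes = 3, seed = 5))
  fa <- tempfile(fileext = ".fasta")
  write_haplotype_panel(sim$panel, fa)
  p2 <- read_haplotype_panel(fa, primary = sim$panel$primary)
  expect_identical(p2$sequences, sim$panel$sequences)
  expect_identical(p2$haplotypes, sim$panel$haplotypes)
  expect_error(read_haplotype_panel("/nonexistent/x.fa"), "not found")
})

test_that("annotation filtering keeps protein-coding transcripts at level <= 2", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("A\tsrc\texon\t101\t200\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "g1.t1"; gene_type "protein_coding"; ',
           'gene_name "g1"; transcript_type "protein_coding"; level 1;'),
    paste0("A\tsrc\texon\t301\t400\t.\t+\t.\t",
           'gene_id "g2"; transcript_id "g2.t1"; gene_type "lincRNA"; ',
           'gene_name "g2"; transcript_type "lincRNA"; level 1;')
  ), gtf)
  m <- read_gene_models(gtf)
  expect_equal(unique(m$gene_id), "g1")
  expect_equal(m$start, 100L)  # 0-based internally
  expect_equal(m$end, 200L)

  ## empty GTF gives an empty model set
  gtf2 <- tempfile(fileext = ".gtf")
  writeLines(character(0), gtf2)
  expect_equal(nrow(suppressWarnings(read_gene_models(gtf2))), 0L)
})

test_that("gene span is restricted to transcripts passing the level filter", {
  ## 3-exon toy gene: level-1 transcript covers exons 1-2, level-3 covers 1-3
  m <- rbind(
    exon_row("g1", "g1.t1", "A", 100, 200, level = 1),
    exon_row("g1", "g1.t1", "A", 300, 400, level = 1),
    exon_row("g1", "g1.t3", "A", 100, 200, level = 3),
    exon_row("g1", "g1.t3", "A", 300, 400, level = 3),
    exon_row("g1", "g1.t3", "A", 500, 700, level = 3))
  f <- filter_gene_models(m, max_level = 2)
  sp <- gene_spans(f)
  expect_equal(sp$start, 100L)
  expect_equal(sp$end, 400L)  # level-1 transcript span only
  ## idempotence
  expect_equal(filter_gene_models(f, max_level = 2), f)
})

test_that("gene order sorts by start, breaks ties by id, interpolates absentees", {
  m <- rbind(
    exon_row("g1", "g1.t", "A", 100, 200),
    exon_row("g2", "g2.t", "A", 500, 600),
    exon_row("g3", "g3.t", "A", 900, 950),
    ## gene present only on B, between g1 and g2 there
    exon_row("g1", "g1.t", "B", 100, 200),
    exon_row("gX", "gX.t", "B", 300, 400),
    exon_row("g2", "g2.t", "B", 500, 600))
  ord <- gene_order(m, "A")
  expect_equal(ord$per_haplotype$A, c("g1", "g2", "g3"))
  expect_equal(ord$per_haplotype$B, c("g1", "gX", "g2"))
  expect_equal(ord$global, c("g1", "gX", "g2", "g3"))

  ## equal starts resolved by gene id
  m2 <- rbind(exon_row("gB", "gB.t", "A", 100, 200),
              exon_row("gA", "gA.t", "A", 100, 150))
  expect_equal(gene_order(m2, "A")$global, c("gA", "gB"))
})

test_that("global order restricted to one haplotype preserves its coordinate order", {
  sim <- simulate_panel(panel_spec(n_haplotypes = 4, n_genes = 12,
                                   presence_prob = 0.7, seed = 21))
  ord <- gene_order(sim$models, sim$panel)
  for (h in names(ord$per_haplotype)) {
    own <- ord$per_haplotype[[h]]
    expect_equal(ord$global[ord$global %in% own], own)
  }
})

test_that("gene reliability reproduces thresholds exactly at the boundary", {
  mk_assign <- function(n_unique, n_total, gene = "g1") {
    ids <- sprintf("r%03d", seq_len(n_total))
    rows <- lapply(seq_len(n_total), function(i) {
      nh <- if (i <= n_unique) 1L else 2L
      data.table::data.table(read_pair_id = ids[i], gene_id = gene,
                             haplotype = c("A", "B")[seq_len(nh)], d = 0L,
                             qlen = 200L)
    })
    data.table::rbindlist(rows)
  }
  truth <- data.table::data.table(read_pair_id = sprintf("r%03d", 1:100),
                                  gene_id = "g1")
  ## exactly 80% unique: retained
  rel <- gene_reliability(mk_assign(80, 100), truth)
  expect_equal(rel$unique_fraction, 0.8)
  expect_true(rel$retained)
  ## 79% unique: removed
  rel <- gene_reliability(mk_assign(79, 100), truth)
  expect_false(rel$retained)
  ## 70% unique (as in a mapper comparison): removed
  rel <- gene_reliability(mk_assign(70, 100), truth)
  expect_equal(rel$unique_fraction, 0.7)
  expect_false(rel$retained)
})

test_that("mismapped-read fraction above 20% removes a gene", {
  ## 100 reads assigned to g1; 25 of them truly from g2
  a <- data.table::data.table(read_pair_id = sprintf("r%03d", 1:100),
                              gene_id = "g1", haplotype = "A", d = 0L,
                              qlen = 200L)
  truth <- data.table::data.table(
    read_pair_id = sprintf("r%03d", 1:100),
    gene_id = c(rep("g1", 75), rep("g2", 25)))
  rel <- gene_reliability(a, truth)
  g1 <- rel[gene_id == "g1"]
  expect_equal(g1$mismap_fraction, 0.25)
  expect_false(g1$retained)
  ## at exactly 20% the gene is kept
  truth2 <- data.table::data.table(
    read_pair_id = sprintf("r%03d", 1:100),
    gene_id = c(rep("g1", 80), rep("g2", 20)))
  expect_true(gene_reliability(a, truth2)[gene_id == "g1", retained])
  ## a gene with no reads at all is flagged "no-data", not an error
  rel3 <- gene_reliability(a, truth2, genes = c("g1", "g2", "g9"))
  g9 <- rel3[gene_id == "g9"]
  expect_false(g9$retained)
  expect_equal(g9$note, "no-data")
})
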