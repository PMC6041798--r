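## assignment-table builder: reads x (gene, haplotypes with distances)
asg_rows <- function(ids, gene, haps, d = 0L, qlen = 200L) {
  data.table::rbindlist(lapply(ids, function(id)
    data.table::data.table(read_pair_id = id, gene_id = gene,
                           haplotype = haps, d = d, qlen = qlen)))
}

call_row <- function(gene, h1, h2) {
  data.table::data.table(gene_id = gene, h1 = h1, h2 = h2,
                         pair = pair_label(h1, h2), M = 0.9,
                         zygosity = ifelse(h1 == h2, "hom", "het"),
                         wildcard = FALSE)
}

test_that("gene counts count pairs touching the predicted pair exactly once", {
  calls <- call_row("g1", "A", "B")
  ## 10 pairs aligning to both A and B: counted once each
  a <- asg_rows(sprintf("r%02d", 1:10), "g1", c("A", "B"))
  expect_equal(gene_counts(a, calls)$count, 10L)
  ## 6 only on A, 4 only on B: still 10
  a2 <- rbind(asg_rows(sprintf("a%02d", 1:6), "g1", "A"),
              asg_rows(sprintf("b%02d", 1:4), "g1", "B"))
  expect_equal(gene_counts(a2, calls)$count, 10L)
  ## 2 pairs aligning only to a non-predicted haplotype are excluded
  a3 <- rbind(a2, asg_rows(c("x1", "x2"), "g1", "C"))
  expect_equal(gene_counts(a3, calls)$count, 8L + 2L)
  expect_equal(gene_counts(a3[!read_pair_id %in% c("a01", "a02")],
                           calls)$count, 8L)
})

test_that("haplotype counts split het genes by unique reads and halve hom genes", {
  ## het: unique A = 30, unique B = 10, shared = 40 -> count 80 split 60/20
  calls <- call_row("g1", "A", "B")
  a <- rbind(asg_rows(sprintf("u%02d", 1:30), "g1", "A"),
             asg_rows(sprintf("v%02d", 1:10), "g1", "B"),
             asg_rows(sprintf("s%02d", 1:40), "g1", c("A", "B")))
  hc <- haplotype_counts(a, calls)
  expect_equal(hc[haplotype == "A", count], 80 * 30 / 40)
  expect_equal(hc[haplotype == "B", count], 80 * 10 / 40)
  expect_equal(sum(hc$count), 80)  # split sums to the gene count
  expect_equal(hc[haplotype == "A", unique_count], 30L)

  ## hom gene: halved
  calls_h <- call_row("g2", "A", "A")
  ah <- asg_rows(sprintf("h%03d", 1:100), "g2", "A")
  hch <- haplotype_counts(ah, calls_h)
  expect_equal(hch$count, c(50, 50))
  expect_equal(unique(hch$haplotype), "A")

  ## het with zero unique reads: flagged undefined
  a0 <- asg_rows(sprintf("z%02d", 1:10), "g1", c("A", "B"))
  hc0 <- haplotype_counts(a0, calls)
  expect_false(any(hc0$defined))
  expect_true(all(is.na(hc0$count)))
})

test_that("ratio table orients major/minor and applies the depth filter", {
  hc <- data.table::data.table(
    gene_id = c("g1", "g1", "g2", "g2", "g3", "g3"),
    haplotype = c("A", "B", "A", "B", "A", "B"),
    count = c(60, 30, 29, 290, 40, 40),
    unique_count = 10L, defined = TRUE, zygosity = "het")
  rt <- haplotype_ratios(hc, min_depth = 30)
  expect_equal(rt[gene_id == "g1", ratio], 2.0)
  expect_equal(rt[gene_id == "g1", hap_major], "A")
  expect_false("g2" %in% rt$gene_id)  # 29 < depth 30 in one haplotype
  expect_equal(rt[gene_id == "g3", ratio], 1.0)
})

test_that("mismatch rate is summed edit distance over aligned bases", {
  calls <- call_row("g1", "A", "B")
  a <- data.table::data.table(
    read_pair_id = c("r1", "r2"), gene_id = "g1", haplotype = "A",
    d = c(1L, 3L), qlen = 200L)
  mm <- mismatch_rates(a, calls)
  expect_equal(mm[haplotype == "A", mismatch_rate], (1 + 3) / 400)
  expect_true(is.na(mm[haplotype == "B", mismatch_rate]))
  ## all-zero distances give rate zero
  a0 <- data.table::copy(a)[, d := 0L]
  expect_equal(mismatch_rates(a0, calls)[haplotype == "A", mismatch_rate], 0)
})

test_that("mismatch rate approximates the injected sequencing error rate", {
  sim <- simulate_panel(panel_spec(n_haplotypes = 2, n_genes = 4, seed = 61))
  err <- 0.004
  rd <- simulate_reads(sim$panel, sim$models, ratio = 1, n_pairs = 400,
                       error_rate = err, prob_het = 0, seed = 62)
  aln <- align_exhaustive(rd, sim$panel, sim$models, max_nm = 4L)
  fit <- hapquant(aln, sim$panel, sim$models)
  tp <- rd$truth[, .(hap = haplotype[1]), by = gene_id]
  mm <- merge(fit$mismatch, tp, by = "gene_id")
  mm <- mm[haplotype == hap]
  n_bases <- 400 * 400  # pairs x pair length per gene
  se <- sqrt(err * (1 - err) / n_bases)
  expect_true(all(abs(mm$mismatch_rate - err) < 3 * se + 1e-4))
})

test_that("outputs round-trip through files", {
  sim <- simulate_panel(panel_spec(n_haplotypes = 3, n_genes = 4, seed = 71))
  rd <- simulate_reads(sim$panel, sim$models, ratio = 1.5, n_pairs = 60,
                       seed = 72)
  aln <- align_exhaustive(rd, sim$panel, sim$models)
  fit <- hapquant(aln, sim$panel, sim$models)
  out <- tempfile()
  paths <- write_quant_outputs(fit, out, per_read = TRUE)
  expect_true(all(file.exists(paths)))
  ps <- data.table::fread(paths[["pair_scores"]])
  expect_equal(nrow(ps), nrow(fit$pair_scores))
  expect_equal(ps$combined_rate, fit$pair_scores$M)
  ann <- data.table::fread(paths[["per_read"]])
  ## per-read annotation rows equal surviving assignment rows
  expect_equal(nrow(ann), nrow(fit$assignments))
  expect_equal(data.table::uniqueN(ann$read_pair_id),
               data.table::uniqueN(fit$assignments$read_pair_id))
  hc <- data.table::fread(paths[["hap_counts"]])
  expect_equal(hc$count, fit$hap_counts$count)

  ## empty gene set still writes header-only tables
  fit0 <- fit
  fit0$pair_scores <- fit$pair_scores[0]
  fit0$hap_counts <- fit$hap_counts[0]
  fit0$calls <- fit$calls[0]
  fit0$gene_counts <- fit$gene_counts[0]
  p0 <- write_quant_outputs(fit0, tempfile())
  expect_true(all(file.exists(p0)))
  expect_equal(nrow(data.table::fread(p0[["pair_scores"]])), 0L)
})
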