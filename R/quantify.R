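## Output stage: gene counts, unique-read haplotype splits, ratio tables,
## mismatch rates, and the tabular output files.

#' Gene counts from haplotype calls
#'
#' A gene's count is the number of read pairs assigned to it that align to
#' at least one haplotype of the predicted pair; each pair is counted once.
#'
#' @param assignments assignment data.table from [assign_read_pairs()].
#' @param calls haplotype-call table from [best_haplotype_path()].
#' @return data.table with `gene_id`, `count`.
#' @export
gene_counts <- function(assignments, calls) {
  a <- data.table::as.data.table(assignments)
  cl <- data.table::as.data.table(calls)
  m <- merge(a, cl[, .(gene_id, ch1 = h1, ch2 = h2)], by = "gene_id")
  m <- m[haplotype == ch1 | haplotype == ch2]
  cnt <- unique(m[, .(gene_id, read_pair_id)])[, .(count = .N), by = gene_id]
  out <- merge(cl[, .(gene_id)], cnt, by = "gene_id", all.x = TRUE)
  out[is.na(count), count := 0L]
  out[]
}

## per-gene unique-read counts within the predicted pair (or globally)
unique_read_counts <- function(assignments, calls, scope = "pair") {
  a <- data.table::as.data.table(assignments)
  cl <- data.table::as.data.table(calls)[!is.na(h1)]
  a <- merge(a, cl[, .(gene_id, ch1 = h1, ch2 = h2)], by = "gene_id")
  if (scope == "global") {
    nh <- a[, .(n_hap = .N), by = .(gene_id, read_pair_id)]
    a <- merge(a, nh, by = c("gene_id", "read_pair_id"))
    a <- a[n_hap == 1L & (haplotype == ch1 | haplotype == ch2)]
  } else {
    a <- a[haplotype == ch1 | haplotype == ch2]
    nh <- a[, .(n_hap = .N), by = .(gene_id, read_pair_id)]
    a <- merge(a, nh, by = c("gene_id", "read_pair_id"))
    a <- a[n_hap == 1L]
  }
  a[, .(unique_count = data.table::uniqueN(read_pair_id)),
    by = .(gene_id, haplotype)]
}

#' Haplotype counts by unique-read split
#'
#' For a heterozygous call the (normalized) gene count is split between the
#' two haplotypes in proportion to the reads uniquely mapped to each (reads
#' of the pair aligning to exactly one of its two haplotypes); for a
#' homozygous call each haplotype receives half the count.  A heterozygous
#' gene with no unique reads has an undefined split and is flagged.
#'
#' @param assignments assignment data.table.
#' @param calls haplotype-call table.
#' @param counts gene counts (from [gene_counts()], or a normalized count
#'   column to be split); defaults to raw gene counts.
#' @param scope `"pair"` (default) or `"global"`, see [hq_config()].
#' @return data.table with `gene_id`, `haplotype`, `count` (real),
#'   `unique_count`, `defined` (FALSE when the split is undefined).
#' @export
haplotype_counts <- function(assignments, calls, counts = NULL,
                             scope = "pair") {
  cl <- data.table::as.data.table(calls)[!is.na(h1)]
  if (is.null(counts)) counts <- gene_counts(assignments, calls)
  uc <- unique_read_counts(assignments, calls, scope)
  out <- list()
  for (i in seq_len(nrow(cl))) {
    g <- cl$gene_id[i]; h1 <- cl$h1[i]; h2 <- cl$h2[i]
    gc <- counts[gene_id == g, count]
    if (length(gc) == 0L) gc <- 0
    if (h1 == h2) {
      out[[length(out) + 1L]] <- data.table::data.table(
        gene_id = g, haplotype = h1, count = gc / 2, unique_count = NA_integer_,
        defined = TRUE, zygosity = "hom")
      out[[length(out) + 1L]] <- data.table::data.table(
        gene_id = g, haplotype = h2, count = gc / 2, unique_count = NA_integer_,
        defined = TRUE, zygosity = "hom")
    } else {
      u1 <- uc[gene_id == g & haplotype == h1, unique_count]
      u2 <- uc[gene_id == g & haplotype == h2, unique_count]
      u1 <- if (length(u1)) u1 else 0L
      u2 <- if (length(u2)) u2 else 0L
      def <- (u1 + u2) > 0L
      f1 <- if (def) u1 / (u1 + u2) else NA_real_
      out[[length(out) + 1L]] <- data.table::data.table(
        gene_id = g, haplotype = c(h1, h2), count = gc * c(f1, 1 - f1),
        unique_count = c(u1, u2), defined = def, zygosity = "het")
    }
  }
  data.table::rbindlist(out)
}

#' Major/minor haplotype expression ratios
#'
#' Heterozygous genes with a defined unique-read split and at least
#' `min_depth` in both haplotype counts enter the table; the ratio is
#' major/minor (>= 1) with the orientation recorded.
#'
#' @param hap_counts table from [haplotype_counts()].
#' @param min_depth minimum per-haplotype count (default 30).
#' @return data.table with `gene_id`, `hap_major`, `hap_minor`, `major`,
#'   `minor`, `ratio`.
#' @export
haplotype_ratios <- function(hap_counts, min_depth = 30) {
  hc <- data.table::as.data.table(hap_counts)
  hc <- hc[zygosity == "het" & defined == TRUE]
  if (nrow(hc) == 0L)
    return(data.table::data.table(gene_id = character(0),
                                  hap_major = character(0),
                                  hap_minor = character(0),
                                  major = numeric(0), minor = numeric(0),
                                  ratio = numeric(0)))
  out <- hc[, {
    o <- order(-count, haplotype)
    .(hap_major = haplotype[o[1]], hap_minor = haplotype[o[2]],
      major = count[o[1]], minor = count[o[2]])
  }, by = gene_id]
  out <- out[minor >= min_depth & major >= min_depth]
  out[, ratio := major / minor]
  out[]
}

#' Mismatch mapping rate of predicted haplotypes
#'
#' For each haplotype of a gene's predicted pair, the mean per-base edit
#' distance of the reads aligned to it: summed combined edit distance over
#' summed aligned read bases.
#'
#' @param assignments assignment data.table.
#' @param calls haplotype-call table.
#' @return data.table with `gene_id`, `haplotype`, `mismatch_rate`,
#'   `n_reads`.
#' @export
mismatch_rates <- function(assignments, calls) {
  a <- data.table::as.data.table(assignments)
  cl <- data.table::as.data.table(calls)[!is.na(h1)]
  pred <- data.table::rbindlist(list(cl[, .(gene_id, haplotype = h1)],
                                     cl[, .(gene_id, haplotype = h2)]))
  pred <- unique(pred)
  m <- merge(a, pred, by = c("gene_id", "haplotype"))
  out <- m[, .(mismatch_rate = sum(d) / sum(qlen), n_reads = .N),
           by = .(gene_id, haplotype)]
  out <- merge(pred, out, by = c("gene_id", "haplotype"), all.x = TRUE)
  out[is.na(n_reads), `:=`(mismatch_rate = NA_real_, n_reads = 0L)]
  data.table::setorder(out, gene_id, haplotype)
  out[]
}

#' Write the pipeline's output files
#'
#' Writes (1) the pair-score table (combined mapping rates and relative
#' edit distances of all haplotype pairs), (2) the expression table (gene
#' counts, predicted pair, haplotype counts), (3) optionally the per-read
#' annotation table, and (4) the report data (per gene x haplotype mapping
#' rates with the predicted pair marked) as JSON for plotting.
#'
#' @param fit a `hapquant` fit object.
#' @param dir output directory (created if absent).
#' @param per_read also write the per-read annotation table (default
#'   FALSE).
#' @return named character vector of the written paths, invisibly.
#' @export
write_quant_outputs <- function(fit, dir, per_read = FALSE) {
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE))
      stopf("cannot create output directory %s", dir)
  tsv <- function(x, f) {
    p <- file.path(dir, f)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(
    pair_scores = tsv(fit$pair_scores[, .(gene_id, h1, h2, combined_rate = M,
                                          relative_edit_distance = D)],
                      "pair_scores.tsv"),
    expression = tsv(expression_table(fit), "expression.tsv"),
    hap_counts = tsv(fit$hap_counts, "haplotype_counts.tsv"))
  if (per_read) {
    cl <- fit$calls[!is.na(h1)]
    ann <- merge(fit$assignments,
                 cl[, .(gene_id, ch1 = h1, ch2 = h2)], by = "gene_id",
                 all.x = TRUE)
    ann <- ann[, .(read_pair_id, gene_id, haplotype, edit_distance = d,
                   in_predicted_pair = !is.na(ch1) &
                     (haplotype == ch1 | haplotype == ch2))]
    data.table::setorder(ann, read_pair_id, haplotype)
    paths <- c(paths, per_read = tsv(ann, "read_annotations.tsv"))
  }
  report <- list(
    rates = fit$rates,
    calls = fit$calls,
    gene_counts = fit$gene_counts)
  rp <- file.path(dir, "report.json")
  jsonlite::write_json(report, rp, dataframe = "columns", na = "null",
                       digits = NA)
  paths <- c(paths, report = rp)
  invisible(paths)
}

## flat per-gene expression summary used by write_quant_outputs and summary()
expression_table <- function(fit) {
  cl <- data.table::as.data.table(fit$calls)
  gc <- fit$gene_counts
  hc <- fit$hap_counts
  wide <- if (nrow(hc)) {
    hc2 <- data.table::copy(hc)
    hc2[, slot := paste0("count_h", seq_len(.N)), by = gene_id]
    data.table::dcast(hc2, gene_id ~ slot, value.var = "count")
  } else data.table::data.table(gene_id = character(0))
  out <- merge(cl[, .(gene_id, pair, zygosity, M, wildcard)], gc,
               by = "gene_id", all.x = TRUE)
  out <- merge(out, wide, by = "gene_id", all.x = TRUE)
  data.table::setorder(out, gene_id)
  out[]
}
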