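## Stage 2b: edit-distance read weighting, per-gene mapping-rate matrices,
## haplotype-pair combined rates and relative edit distances, and the
## candidate-pair shortlist.

score_fun <- function(score = c("exp2", "inverse")) {
  score <- match.arg(score)
  switch(score,
         exp2 = function(d) 2^(-d),
         inverse = function(d) 1 / (1 + d))
}

#' Per-read haplotype weights from edit distances
#'
#' Each read (pair) is weighted on every haplotype it aligns to by a
#' monotone score of its combined edit distance, s(d) = 2^(-d) by default;
#' the weights across haplotypes are normalized to sum to 1.  Haplotypes the
#' read does not align to receive weight 0.
#'
#' @param d named numeric vector of combined edit distances (names =
#'   haplotypes the read aligns to).
#' @param score score function name, see [hq_config()].
#' @return named numeric weights summing to 1 over `names(d)`.
#' @export
read_weights <- function(d, score = "exp2") {
  if (length(d) == 0L) stopf("read_weights: empty distance map")
  if (any(d < 0)) stopf("read_weights: negative edit distance")
  s <- score_fun(score)(d)
  s / sum(s)
}

#' Per-gene mapping-rate matrix
#'
#' For each gene g and haplotype h the mapping rate R(g,h) is the sum of the
#' normalized per-read weights on h divided by the total number of reads
#' mapped to the gene on any haplotype, so that sum_h R(g,h) = 1.
#'
#' @param assignments assignment data.table from [assign_read_pairs()].
#' @param haplotypes character vector of all panel haplotypes (haplotypes
#'   without reads get rate 0).
#' @param score score function name.
#' @return data.table with `gene_id`, `haplotype`, `rate`, `n_reads`.
#' @export
mapping_rates <- function(assignments, haplotypes, score = "exp2") {
  a <- data.table::as.data.table(assignments)
  if (nrow(a) == 0L)
    return(data.table::data.table(gene_id = character(0),
                                  haplotype = character(0),
                                  rate = numeric(0), n_reads = integer(0)))
  sf <- score_fun(score)
  a <- a[, .(read_pair_id, gene_id, haplotype, w = sf(d))]
  a[, w := w / sum(w), by = read_pair_id]
  wsum <- a[, .(wsum = sum(w)), by = .(gene_id, haplotype)]
  ## each read pair belongs to exactly one gene, so distinct reads per gene
  ## can be counted on the deduplicated table
  nrd <- a[!duplicated(read_pair_id)][, .(n_reads = .N), by = gene_id]
  grid <- data.table::CJ(gene_id = nrd$gene_id, haplotype = haplotypes,
                         unique = TRUE)
  out <- merge(grid, wsum, by = c("gene_id", "haplotype"), all.x = TRUE)
  out[is.na(wsum), wsum := 0]
  out <- merge(out, nrd, by = "gene_id")
  out[, rate := wsum / n_reads]
  out[, wsum := NULL]
  data.table::setorder(out, gene_id, haplotype)
  out[]
}

#' Combined mapping rates and relative edit distances of all haplotype pairs
#'
#' For every gene and every unordered haplotype pair \{h1,h2\} (h1 = h2 is
#' the homozygous hypothesis) the combined mapping rate is M = R(g,h1) +
#' R(g,h2) (M = R(g,h) for homozygous pairs; weights are not renormalized
#' within the pair).  The relative edit distance D is the summed per-read
#' minimum edit distance over the pair, divided by the total read bases of
#' the pairs that map to at least one member, making D a per-base rate.
#'
#' @param assignments assignment data.table.
#' @param rates mapping-rate table from [mapping_rates()].
#' @return data.table with `gene_id`, `h1`, `h2`, `pair`, `M`, `D`,
#'   `n_reads` (reads mapping to at least one member).
#' @export
pair_mapping_rates <- function(assignments, rates) {
  a <- data.table::as.data.table(assignments)
  r <- data.table::as.data.table(rates)
  haps <- sort(unique(r$haplotype))
  genes <- unique(r$gene_id)
  combs <- data.table::CJ(h1 = haps, h2 = haps)[h1 <= h2]
  data.table::setorder(combs, h1, h2)
  out <- vector("list", length(genes))
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    ag <- a[gene_id == g]
    rg <- r[gene_id == g]
    rv <- stats::setNames(rg$rate, rg$haplotype)
    ## reads x haplotypes edit-distance matrix
    reads <- unique(ag$read_pair_id)
    dmat <- matrix(NA_real_, length(reads), length(haps),
                   dimnames = list(reads, haps))
    dmat[cbind(match(ag$read_pair_id, reads), match(ag$haplotype, haps))] <- ag$d
    qv <- ag[!duplicated(read_pair_id)]
    qlen <- stats::setNames(as.numeric(qv$qlen), qv$read_pair_id)[reads]
    M <- rv[combs$h1] + rv[combs$h2]
    M[combs$h1 == combs$h2] <- rv[combs$h1[combs$h1 == combs$h2]]
    M <- pmin(pmax(M, 0), 1)   # guard float round-off in the rate sums
    D <- numeric(nrow(combs)); nr <- integer(nrow(combs))
    for (i in seq_len(nrow(combs))) {
      md <- pmin(dmat[, combs$h1[i]], dmat[, combs$h2[i]], na.rm = TRUE)
      inc <- !is.na(md)
      nr[i] <- sum(inc)
      D[i] <- if (nr[i] > 0L) sum(md[inc]) / sum(qlen[inc]) else NA_real_
    }
    out[[gi]] <- data.table::data.table(
      gene_id = g, h1 = combs$h1, h2 = combs$h2,
      pair = pair_label(combs$h1, combs$h2), M = unname(M), D = D,
      n_reads = nr)
  }
  data.table::rbindlist(out)
}

#' Candidate haplotype pairs per gene
#'
#' The shortlist consists of the pairs whose combined mapping rate reaches
#' the configured percentile of the gene's M distribution (default the 95th,
#' linear-interpolation definition, ties included); among the shortlist the
#' pairs attaining the minimum relative edit distance are the candidates
#' (all ties kept).
#'
#' @param pair_scores table from [pair_mapping_rates()].
#' @param percentile shortlist percentile (default 0.95).
#' @param tol numeric tolerance for rate/distance ties.
#' @return data.table of candidate rows (same columns as `pair_scores`).
#' @export
candidate_haplotype_pairs <- function(pair_scores, percentile = 0.95,
                                      tol = 1e-12) {
  ps <- data.table::as.data.table(pair_scores)
  ps <- ps[n_reads > 0L]
  if (nrow(ps) == 0L) return(ps)
  ps[, {
    q <- stats::quantile(M, percentile, type = 7, names = FALSE)
    short <- M >= q - tol
    dmin <- min(D[short])
    keep <- short & D <= dmin + tol
    .SD[keep]
  }, by = gene_id]
}
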