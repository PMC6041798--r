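#' Pipeline configuration
#'
#' Collects every tunable constant of the pipeline with its default.  All
#' values are validated against their documented range at construction time,
#' so a bad setting fails at load rather than mid-pipeline.
#'
#' @param min_mapq minimum mapping quality for a record to survive alignment
#'   filtering (default 20).
#' @param score read-weight score function applied to the combined edit
#'   distance d: `"exp2"` for 2^(-d) (default) or `"inverse"` for 1/(1+d).
#' @param percentile combined-mapping-rate percentile defining the candidate
#'   shortlist per gene (default 0.95, i.e. pairs at or above the 95th
#'   percentile).
#' @param penalty additive cost per switched haplotype between adjacent genes
#'   in the gene graph (default 0.0028, the standard error of the mean
#'   combined mapping rate between true and predicted haplotypes in
#'   simulation).
#' @param eps clamp applied to the combined mapping rate before the edge
#'   weight transform so weights stay finite at M = 0 or 1 (default 1e-9).
#' @param min_depth minimum per-haplotype read depth for a heterozygous gene
#'   to enter the haplotype-ratio table (default 30).
#' @param gene_types annotation types retained when parsing gene models
#'   (default "protein_coding").
#' @param max_level maximum annotation confidence level retained (default 2 =
#'   verified or manually annotated).
#' @param min_unique_fraction,max_mismap_fraction gene reliability thresholds:
#'   a gene is retained iff its uniquely-mapped read fraction is at least
#'   `min_unique_fraction` (default 0.8) and its fraction of incorrectly
#'   attracted reads is at most `max_mismap_fraction` (default 0.2).
#' @param unique_scope how "uniquely mapped to a single haplotype" is judged
#'   when splitting a heterozygous gene count: `"pair"` (default; unique
#'   within the predicted pair) or `"global"` (unique across the whole
#'   panel).
#' @param stranded honour strand when assigning reads to genes (default
#'   FALSE, unstranded protocol).
#' @param band band half-width of the exhaustive aligner's edit-distance
#'   verification (default 5).
#' @param max_nm per-mate edit-distance ceiling of the exhaustive aligner; a
#'   mate whose best alignment on a haplotype exceeds this is reported
#'   unmapped there (default 2, the common short-read mapper ceiling).
#' @param seed_k seed k-mer length of the exhaustive aligner (default 15).
#' @return an object of class `hq_config` (a validated named list).
#' @export
hq_config <- function(min_mapq = 20L, score = c("exp2", "inverse"),
                      percentile = 0.95, penalty = 0.0028, eps = 1e-9,
                      min_depth = 30, gene_types = "protein_coding",
                      max_level = 2L, min_unique_fraction = 0.8,
                      max_mismap_fraction = 0.2,
                      unique_scope = c("pair", "global"), stranded = FALSE,
                      band = 5L, max_nm = 2L, seed_k = 15L) {
  score <- match.arg(score)
  unique_scope <- match.arg(unique_scope)
  chk <- function(ok, what) if (!ok) stopf("invalid config: %s", what)
  chk(is.numeric(min_mapq) && min_mapq >= 0 && min_mapq <= 255,
      "min_mapq must be in [0,255]")
  chk(is.numeric(percentile) && percentile > 0 && percentile < 1,
      "percentile must be in (0,1)")
  chk(is.numeric(penalty) && penalty >= 0, "penalty must be >= 0")
  chk(is.numeric(eps) && eps > 0 && eps < 0.5, "eps must be in (0,0.5)")
  chk(is.numeric(min_depth) && min_depth >= 0, "min_depth must be >= 0")
  chk(is.character(gene_types) && length(gene_types) >= 1,
      "gene_types must name at least one type")
  chk(is.numeric(max_level) && max_level >= 1, "max_level must be >= 1")
  chk(min_unique_fraction >= 0 && min_unique_fraction <= 1,
      "min_unique_fraction must be in [0,1]")
  chk(max_mismap_fraction >= 0 && max_mismap_fraction <= 1,
      "max_mismap_fraction must be in [0,1]")
  chk(is.logical(stranded), "stranded must be logical")
  chk(band >= 1, "band must be >= 1")
  chk(max_nm >= 0, "max_nm must be >= 0")
  chk(seed_k >= 8 && seed_k <= 31, "seed_k must be in [8,31]")
  structure(list(
    min_mapq = as.integer(min_mapq), score = score, percentile = percentile,
    penalty = penalty, eps = eps, min_depth = min_depth,
    gene_types = gene_types, max_level = as.integer(max_level),
    min_unique_fraction = min_unique_fraction,
    max_mismap_fraction = max_mismap_fraction, unique_scope = unique_scope,
    stranded = stranded, band = as.integer(band), max_nm = as.integer(max_nm),
    seed_k = as.integer(seed_k)
  ), class = "hq_config")
}

#' Read a configuration file
#'
#' Accepts YAML or JSON with keys matching [hq_config()] arguments; unknown
#' keys are rejected.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return an `hq_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(hq_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stopf("unknown config keys: %s", paste(bad, collapse = ", "))
  do.call(hq_config, vals)
}

#' @export
print.hq_config <- function(x, ...) {
  cat("hapquant configuration\n")
  for (k in names(x)) cat(sprintf("  %-20s %s\n", k, paste(x[[k]], collapse = ",")))
  invisible(x)
}
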