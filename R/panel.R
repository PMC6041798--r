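#' Construct a haplotype reference panel
#'
#' A panel is the multi-reference universe the pipeline maps against: one
#' nucleotide sequence per alternate haplotype, with exactly one haplotype
#' flagged as the primary reference (the one embedded in the standard genome
#' build).
#'
#' @param sequences named character vector (or `DNAStringSet`) of haplotype
#'   sequences; names are the haplotype identifiers (e.g. PGF, COX).
#' @param primary name of the primary reference haplotype.
#' @param region optional genomic interval of the region on the primary
#'   reference, a list with `chrom`, `start`, `end` (0-based half-open).
#' @return an object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(sequences, primary = NULL, region = NULL) {
  if (methods::is(sequences, "DNAStringSet"))
    sequences <- as.character(sequences)
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stopf("haplotype sequences must be named")
  if (anyDuplicated(names(sequences)))
    stopf("duplicate haplotype names: %s",
          paste(unique(names(sequences)[duplicated(names(sequences))]),
                collapse = ", "))
  if (any(!nzchar(sequences))) stopf("every haplotype sequence must be non-empty")
  primary <- primary %||% names(sequences)[1]
  if (!primary %in% names(sequences))
    stopf("primary haplotype '%s' is not in the panel", primary)
  structure(list(
    haplotypes = names(sequences),
    sequences = sequences,
    lengths = stats::setNames(nchar(sequences), names(sequences)),
    primary = primary,
    region = region
  ), class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype panel: %d haplotypes (primary: %s)\n",
              length(x$haplotypes), x$primary))
  for (h in x$haplotypes)
    cat(sprintf("  %-10s %8d bp%s\n", h, x$lengths[[h]],
                if (h == x$primary) "  [primary]" else ""))
  invisible(x)
}

#' Load a haplotype panel from FASTA
#'
#' Either one multi-record FASTA (record names become haplotype names) or one
#' single-record FASTA per haplotype.
#'
#' @param fasta_paths character vector of FASTA paths.
#' @param names optional haplotype names, one per path (required when several
#'   single-record files are given and their record names are unusable).
#' @param primary name of the primary reference haplotype.
#' @return a `haplotype_panel`.
#' @export
read_haplotype_panel <- function(fasta_paths, names = NULL, primary = NULL) {
  missing <- fasta_paths[!file.exists(fasta_paths)]
  if (length(missing)) stopf("FASTA file not found: %s", missing[1])
  seqs <- character(0)
  for (i in seq_along(fasta_paths)) {
    ss <- Biostrings::readDNAStringSet(fasta_paths[i])
    v <- as.character(ss)
    names(v) <- sub("\\s.*$", "", names(ss))
    if (!is.null(names)) {
      if (length(fasta_paths) == 1L) {
        if (length(names) != length(v))
          stopf("%d names given for %d FASTA records", length(names), length(v))
        names(v) <- names
      } else {
        if (length(v) != 1L)
          stopf("file %s has %d records; with explicit names give one record per file",
                fasta_paths[i], length(v))
        names(v) <- names[i]
      }
    }
    seqs <- c(seqs, v)
  }
  haplotype_panel(seqs, primary = primary)
}

#' Write a haplotype panel to FASTA
#'
#' @param panel a `haplotype_panel`.
#' @param path output FASTA path (one record per haplotype).
#' @return `path`, invisibly.
#' @export
write_haplotype_panel <- function(panel, path) {
  ss <- Biostrings::DNAStringSet(panel$sequences)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}
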