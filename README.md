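# hapquant

Haplotype-aware estimation of gene- and haplotype-level RNA-seq expression
in highly polymorphic genomic regions.

## The problem

Mapping RNA-seq reads to a single reference haplotype under-counts reads
that carry non-reference alleles.  In regions like the human MHC — gene
dense, hyper-polymorphic, with several complete alternate reference
haplotypes available — this reference bias distorts expression estimates of
exactly the genes (classical HLA loci) people most want to quantify, and
makes allele-specific expression unrecoverable.

`hapquant` quantifies against a *panel* of alternate haplotypes instead.
The same read set is aligned to every haplotype independently; each read
pair is weighted on each haplotype h by its combined edit distance d via
s(d) = 2^(−d), normalized across haplotypes.  Per gene g this yields a
mapping-rate matrix R(g,h) with Σ_h R(g,h) = 1, and for every unordered
haplotype pair {h1,h2} a combined rate M = R(g,h1) + R(g,h2) plus a
per-base relative edit distance D.  Candidate pairs (top-5 % M, minimal D)
are then resolved jointly along the region by a minimum-cost path through a
layered gene-adjacency graph with edge weight

    w(g1,g2) = 1 / (−log(1 − M̄)) + 0.0028 × (haplotype switches)

so that well-supported pairs are cheap and switching haplotypes between
adjacent genes is penalized.  The selected pair per gene gives the gene
count (pairs hitting either member) and, for heterozygous calls, a
unique-read-based split into per-haplotype counts and expression ratios.

The package also ships the benchmark machinery: a seeded simulator of
haplotype panels (ancestral sequence + per-haplotype SNPs/indels,
presence/absence of genes, multi-exon transcripts) and paired-end reads at
designed mixture ratios (2000 pairs per gene/haplotype unit, inserts
150–350 bp, 50 or 100 bp mates), plus a desk-scale exhaustive aligner
(k-mer seeding + banded edit-distance DP with spliced CIGARs), so the whole
pipeline runs and is tested with no external data.

## Worked example

```r
library(hapquant)

sim <- simulate_panel(panel_spec(n_haplotypes = 4, n_genes = 6, seed = 7))
rd  <- simulate_reads(sim$panel, sim$models, ratio = 2, n_pairs = 500, seed = 8)
aln <- align_exhaustive(rd, sim$panel, sim$models)

fit <- hapquant(aln, sim$panel, sim$models)
fit
#> hapquant fit: 6 genes, 4 haplotypes
#>   read pairs assigned: 5000
#>   calls: 6 het, 0 hom, 0 no-read
#>   path cost: 5.4358 (switch penalty 0.0028)

coef(fit)          # gene counts (read pairs on the predicted pair)
#> G001 G002 G003 G004 G005 G006
#> 1500  500  500 1500  500  500

fit$ratios         # major/minor haplotype expression ratios (depth >= 30)
#>    gene_id hap_major hap_minor    major    minor    ratio
#> 1:    G001       h03       h04 998.9362 501.0638 1.993631
#> 2:    G004       h02       h04 980.6094 519.3906 1.888000
```

Here genes G001 and G004 were simulated heterozygous at a 1:2 mixture
(minor 500, major 1000 pairs): their gene counts of 1500 are recovered
exactly and the estimated haplotype ratios sit near the designed 2.0.
Homozygous genes (500 pairs) are likewise counted exactly.  `summary(fit)`
prints the per-gene expression table, `plot(fit)` draws the mapping-rate
heatmap with predicted pairs outlined, and `write_quant_outputs(fit, dir)`
writes the pair-score, expression and per-read annotation tables.

Real data enters the same way: pass per-haplotype SAM/BAM paths (any
splice-aware mapper, NM tags required) as `alignments`, a FASTA panel via
`read_haplotype_panel()`, and GENCODE-dialect GTF annotation via
`read_gene_models()` (protein-coding, level ≤ 2 filters applied).  A thin
command-line wrapper with `simulate` / `quantify` / `evaluate` subcommands
is installed at `inst/cli/hapquant.R`.

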