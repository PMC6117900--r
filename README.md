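# metabarcoder

Multilocus metabarcode construction and metagenomic read binning for
bacterial genomes, in R.

Most metagenomic binning stops at the genus or family level. When the
question is *which strain or species* is in a sample — a pathogenic
*Escherichia* among commensals, one *Lactobacillus* among its relatives —
a single marker gene rarely discriminates. `metabarcoder` builds
genome-specific **metabarcodes**: concatenations of many marker genes
selected from a user-supplied panel of complete annotated genomes, chosen
so that they are conserved enough to be found by alignment yet variable
enough to tell the panel members apart. Shotgun reads are then aligned
against the barcodes and aggregated into per-barcode detection scores that
are compared with cut-offs to call each genome present or absent.

## The method in brief

**Marker selection.** Genes are clustered across genomes into clusters of
orthologous genes (COGs) by reciprocal best hits (affine-gap
Smith–Waterman on proteins, BLOSUM62, e-value ≤ 1e-4) with union–find
closure. Clusters with exactly one gene in every genome form the core
genome; each core cluster is codon-aligned, and for every genome pair
three divergence axes are measured: X, the fraction of sense
(non-synonymous) substitutions among nucleotide substitutions; Y, one
minus protein identity; Z, (positives − identities)/identities under
BLOSUM62. Clusters are ranked by the suitability score

    score = X (1 − X) (1 − Y) / (Z + 1)

and concatenated, best first, into one barcode per genome until the
requested length is reached; by default 30% of the barcode is filled with
accessory genes chosen by a greedy cover of the panel.

**Read binning.** Reads are aligned to barcodes with a seeded local
aligner (match +1, mismatch −2, gap open 5, gap extend 2). Alignments
below the adaptive threshold

    S' = S + (L − S)/(1 + e^{3(L−S)/(S·lg N)}) − 10(ln((2S+100)/(L+100)) − 1)

are discarded (S, L, N: mean score, mean length and count of aligned
reads). Each read is weighted by its specificity (1 if it hits one
barcode, 0 if it hits all) and a vicinity coefficient in [0, 10] computed
from a Jaccard distance matrix over the barcodes' read sets, which spares
reads shared among close relatives. Two read scores (presence-oriented
ReadScore1, abundance-oriented ReadScore2) are aggregated per barcode:

    BarcodeScore_i = (1 + Σ ReadScore) / (1 + 3 L_i T / (4 Σ_j L_j)) − 1

and a genome is called present when BarcodeScore1 ≥ 2.3 and
BarcodeScore2 ≥ 0.5 (both configurable).

**Validation tools.** A simulator generates genome families with
controlled protein divergence and metagenomes with known composition
(read lengths normally distributed in 200–350 bp), and the evaluation
module computes confusion counts, sensitivity/specificity, TP/(FP+FN),
ROC curves with trapezoid AUC, and cut-off grid searches.

## Worked example

Simulate a 4-genome family, build 8-kbp barcodes, and bin a 10,000-read
metagenome containing two of the genomes (15% and 5%) plus background:

```r
library(metabarcoder)

fam   <- simulate_genome_family(n_genomes = 4, n_core = 20,
                                n_accessory = 8, seed = 42)
cogs  <- cluster_cogs(fam$genomes)
stats <- score_core_cogs(cogs, fam$genomes)
head(stats, 3)
#> # A tibble: 3 × 8
#>   cog_id       X     Y      Z score n_pairs degenerate product
#>   <chr>    <dbl> <dbl>  <dbl> <dbl>   <int> <lgl>      <chr>
#> 1 COG00011 0.543 0.167 0.0508 0.197       6 FALSE      simulated CORE006 protein
#> 2 COG00019 0.525 0.178 0.0472 0.196       6 FALSE      simulated CORE014 protein
#> 3 COG00015 0.527 0.179 0.0596 0.193       6 FALSE      simulated CORE010 protein

bs <- build_barcode_set(fam$genomes, requested_length = 8000,
                        cogs = cogs, stats = stats)
bs
#> <barcode_set> 4 barcodes, 8496-9195 bp (requested 8000, accessory fraction 0.3)

mg  <- simulate_metagenome(fam$genomes, c(G01 = 0.15, G02 = 0.05),
                           n_reads = 10000, seed = 7)
res <- bin_reads(mg$reads, bs)
res
#> <binning_result> 4 barcodes, 409 aligned reads, cut-offs 2.3/0.5, 2 present
#> # A tibble: 4 × 6
#>   barcode_id barcode_length n_reads score1 score2 present
#>   <chr>               <dbl>   <int>  <dbl>  <dbl> <lgl>
#> 1 G01                  8616     289   4.31  2.76  TRUE
#> 2 G02                  8550     120   4.24  0.569 TRUE
#> 3 G03                  9195       0   0     0     FALSE
#> 4 G04                  8496       0   0     0     FALSE
```

Both genomes actually present are called present — BarcodeScore1 reports
their presence at similar strength while BarcodeScore2 tracks their
abundance (2.76 vs 0.569) — and the two absent genomes score zero.
`glance(res)` returns the pool statistics (409 aligned reads, alignment
specificity 1, S′ ≈ 256), `tidy(res)` the table above, and
`autoplot(res)` a bar chart of BarcodeScore2 per barcode.
`write_text_report()`, `render_barcode_chart()` (optionally ordered by a
Newick/PHYLIP tree via `tree_leaf_order()`) and `render_cog_scatter()`
produce the file outputs.

A thin command-line interface over the same functions is installed at
`inst/scripts/barcoder` (subcommands `generate-barcodes`, `bin-reads`,
`simulate-family`, `simulate-metagenome`, `evaluate`).

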