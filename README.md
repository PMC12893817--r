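# pansv

Pangenome construction and population structural-variant (SV) analysis
for sets of annotated plant genomes, with a synthetic-data module that
plants ground truth so the whole pipeline is testable end to end.

Crop resequencing studies increasingly build *three* pangenome views from
the same assemblies and this package implements all of them as one
pipeline:

* **Syntelog-based** — genes clustered across genomes by translated-CDS
  homology *plus* collinear position into syntelog groups (SGs),
  classified core (present in all genomes), dispensable (2..n−1) or
  private (1), with presence/absence (PAV) matrices, pan/core
  accumulation curves and Nei–Gojobori (1986) Ka/Ks.
* **Graph-based** — a backbone-anchored variation graph built from
  MUM-anchor chains (MUMmer-style parameters `-maxgap 500 -mincluster
  1000 -diagdiff 20`) and Assemblytics-style gap classification; SV sites
  pop out as bubbles (biallelic Ins/Del/Div by the two-path rule,
  multiallelic beyond), emitted as rGFA-tagged GFA and VCF 4.2.
* **Linear** — a growing reference built by iteratively splicing in ≥50 bp
  insertions with a registry and exact coordinate liftover; catalogues
  DEL / BND / INS / DUP / INV including the inversions and translocations
  the backbone-stable graph omits.

Downstream, read sets are genotyped against graph bubbles with
allele-distinctive k-mers, filtered on missingness (≤ 0.3) and minor
allele frequency (≥ 0.01), and analysed with PCA, neighbour-joining trees
(100 site-resampling bootstraps), a wild-vs-cultivated allele-frequency
difference scan (Δf > 0.5), per-site Weir–Cockerham (1984) Fst and
windowed nucleotide diversity π.

At the core sit a handful of standard statistics, implemented per their
original definitions. Per SV site with two populations of diploids, the
Weir–Cockerham estimator is the ratio of variance components
`Fst = a / (a + b + c)` with the usual unequal-sample-size corrections;
NG86 counts synonymous/nonsynonymous sites per codon, averages
multi-substitution codons over minimal mutational pathways and applies
the Jukes–Cantor correction `d = −(3/4) ln(1 − (4/3) p)`.

## Worked example

Simulate a backbone and two derived accessions with planted SVs, build
the graph, and pop bubbles:

```r
library(pansv)

anc <- simulate_ancestor(n_chrom = 1, chrom_len = 250000, n_genes = 8,
                         seed = 5)
events <- sample_sv_events(anc, 8, types = c("INS", "DEL", "DIV"),
                           max_len = 2000, seed = 101)
acc1 <- derive_accession(anc, events[1:4, ],  snp_rate = 5e-4, seed = 201,
                         genome_id = "acc1")$genome
acc2 <- derive_accession(anc, events[5:8, ],  snp_rate = 5e-4, seed = 202,
                         genome_id = "acc2")$genome

graph <- build_graph(anc, list(acc1, acc2))
graph
#> <pan_graph> backbone ancestor: 22 nodes, 30 edges, 3 genomes, 9 variant sites

bubbles <- pop_bubbles(graph)
table(bubbles$sv_type)
#>
#> Del Div Ins
#>   3   3   3
```

Eight planted events, nine bubbles — all eight planted SVs are recovered
with their subtype, and the ninth is a ~50 bp divergent segment called
where several SNPs happened to cluster (real aligners report the same
kind of record). Each row holds the backbone span,
the number of traversing paths (2 = biallelic here) and the subtype — a
`Del` bubble's reference span is the deleted interval, an `Ins` bubble's
alternative allele carries the inserted sequence. `node_classes(graph)`
splits the graph into core nodes (traversed by all three genomes) and
variable nodes; `write_gfa()` / `write_bubble_vcf()` emit the standard
formats. The same genome set drives the linear pangenome
(`build_linear_pan()`, `collect_linear_svs()`), the syntelog pangenome
(`build_syntelog_pangenome()` on annotated genomes), and — via
`simulate_sv_panel()` and `genotype_panel()` — population genotype
matrices for `pca_genotypes()`, `nj_tree()`, `freq_diff_scan()`,
`fst_wc()` and `pi_window()`.

See the methods vignette (`vignettes/pansv-methods.Rmd`) for the models,
parameter meanings and the design decisions behind them.

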