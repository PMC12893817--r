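---
title: "Pangenome construction and population SV analysis with pansv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pangenome construction and population SV analysis with pansv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pansv)
```

# Overview

`pansv` implements, as one tested pipeline, the three complementary
pangenome representations used in crop structural-variation studies and
the population analyses that sit downstream of them:

* a **syntelog-based pangenome**: genes clustered across genomes by
  homology *and* collinear position into syntelog groups (SGs), labelled
  core / dispensable / private;
* a **graph-based pangenome**: a backbone-anchored sequence graph in which
  every structural variant (SV) of at least 50 bp appears as a bubble with
  one path per allele;
* a **linear pangenome**: a single growing reference into which novel
  insertions are spliced iteratively, with a registry and coordinate
  liftover, able to catalogue the inversions and translocations a
  backbone-stable graph deliberately omits.

Population-scale genotypes over the SV sites feed PCA, neighbour-joining
trees with site-resampling bootstrap, a wild-vs-cultivated allele-frequency
difference scan, per-site Weir–Cockerham Fst and windowed nucleotide
diversity.

Because real multi-assembly panels are large and external, every stage is
validated against a first-class synthetic-data module that plants SVs,
gene gain/loss and population structure with known truth.

# The alignment core

All sequence comparison rests on maximal exact matches seeded by k-mers
that are unique in the reference (MUM-like; a MEM mode that tolerates
repeated seeds is available). Anchors are chained with the MUMmer-style
cluster parameters familiar from whole-genome alignment practice:

| parameter | default | meaning |
|---|---|---|
| `k` | 19 bp | seed size; `k < 8` is refused as a spurious-match guard |
| `min_anchor_len` | 50 bp | shortest reported exact match |
| `max_gap` | 500 bp | largest gap between anchors joined into one chain |
| `min_cluster` | 1000 bp | minimum summed anchor length of a chain |
| `diag_diff` | 20 bp | largest diagonal change within a chain |

Two consecutive anchors join a chain only when their gap on both
sequences is at most `max_gap` **and** their diagonals differ by at most
`diag_diff`. A consequence worth stating explicitly: any indel larger
than `diag_diff` splits chains, so SVs are classified from the gaps
*between* consecutive collinear chains (the analogue of
between-alignment variant calls in Assemblytics-style analysis), while
within-chain gaps only ever yield small divergent segments. Gap
classification is the standard rule table on the reference gap $r$ and
query gap $q$:

* $r = 0,\, q > 0$: insertion of length $q$;
* $r > 0,\, q = 0$: deletion of length $r$;
* $r > 0,\, q > 0$: divergent allele of length $\max(r, q)$.

Only variants of at least `min_sv = 50` bp are emitted. Breakpoint
micro-homology makes maximal matches overhang true junctions by a few
bases; chains are therefore allowed to overlap by up to 100 bp on the
query, and the overhang is trimmed off the left chain before a gap is
classified so that emitted junctions are sequence-consistent (this
matters downstream, where genotyping builds junction k-mers from the
called breakpoints).

Rearrangements come from chain topology rather than gaps: a
minus-orientation chain embedded in plus context is an inversion; a chain
whose query belongs to a different chromosome (or sits further than 10 kb
from where the collinear backbone maps it) is a translocation, reported
as a breakend (BND) pair; two query-adjacent chains overlapping on the
reference are a tandem duplication. Gaps already explained by a
rearrangement are suppressed, so a translocation is not double-counted as
a deletion plus an insertion.

# Graph pangenome

Genomes are integrated one at a time against the backbone's stable
coordinates only — alternative alleles never become anchoring targets, which
reproduces the backbone-stable behaviour of incremental graph builders
without full graph alignment. Alleles whose breakpoints coincide within
`breakpoint_tol = 10` bp merge into one site; distinct allele sequences at
a site become distinct paths. Popping a bubble reports one record per
site: two traversing paths make it biallelic (subtyped Ins / Del / Div by
which allele is empty), more than two make it multiallelic. Inversions
are deliberately **not** added to the graph; they are the linear module's
job. Nodes traversed by every genome's path are core, the rest variable;
lengths and counts are conserved by construction. The graph is emitted as
GFA 1.0 with rGFA-like SN/SO/SR stable tags, bubbles as VCF 4.2.

One consequence of backbone-stable integration is that node counts are a
function of this builder's segmentation, not comparable across tools;
only the definitions (core vs variable) and the conservation laws are
meaningful invariants, and those are what the tests pin down.

# Linear pangenome

Starting from the backbone (`ref0`), each genome is chained against the
current pan; insertions of at least 50 bp are spliced in at their
breakpoints to form the next reference, and the registry records every
inserted interval with its source genome and iteration. Because later
genomes align against the *updated* pan, a shared insertion is integrated
exactly once — the second carrier simply aligns across it. Divergent
alleles contribute their novel sequence as an insertion and their
reference span as a catalogued deletion; deletions, duplications,
inversions and breakends are catalogued but never spliced, so removing
all registry intervals reproduces the backbone byte-exactly — the
package's central reconstruction invariant. An insertion whose breakpoint
falls inside a previously registered interval is skipped for that
iteration rather than nested (alignment against the updated pan makes
this the natural policy; it is also the only one under which the
reconstruction invariant stays trivially checkable).

Liftover between any intermediate reference and the final pan is pure
coordinate arithmetic over the registry: strictly monotone, with
positions inside later-inserted intervals flagged unmappable on the way
back. Genes lifted to the pan extract byte-identical sequences, which the
tests verify.

# Syntelog pangenome

Homology is scored by local alignment of translated CDS (BLOSUM62, gap
open 10, extend 0.5), emitted at identity ≥ 0.5 over ≥ 0.5 of the shorter
protein, top 5 hits per gene, after a shared 12-mer prescreen that keeps
the all-vs-all search tractable. Pairs are then restricted to collinear
chains over gene ranks (either orientation, at least 5 pairs per chain,
rank gaps at most 10) — dispersed homologs do not join SGs by default,
which is the stricter of the two readings of "syntelog"; a caller can
relax it by passing a custom `pair_fun` to `merge_syntelogs()`.

Merging is iterative: framework genes seed SGs; each later genome's genes
join the SG of their best-scoring syntenic partner among *all* previously
merged genes (ties: highest alignment score, then lowest SG id — a purely
deterministic rule), or seed new SGs. This gives the familiar
transitivity: A–B and B–C pairs with no direct A–C pair still produce one
SG containing A, B and C. Multiple genes of one genome may share an SG,
so tandem paralogs do not break the partition invariant (every gene in
exactly one SG).

Classification is by occupancy: present in all genomes = core, exactly
one = private, anything between = dispensable. Accumulation curves sample
genomes without replacement (100 replicates per sample size by default)
and report pan and core counts; on a toy matrix the replicate means match
exhaustive subset enumeration, which the acceptance tests assert.

Ka/Ks uses the Nei–Gojobori (1986) counting method: synonymous site
fractions per codon averaged over both sequences, multi-substitution
codons averaged over all minimal mutational pathways (pathways through
stop codons excluded, mutations to stops counted as nonsynonymous), and
the Jukes–Cantor correction $d = -\tfrac34 \log(1 - \tfrac43 p)$.
Proportions at or beyond the 3/4 ceiling are reported as undefined and
flagged, never fabricated; a ratio with $K_s = 0$ is undefined.

# SV genotyping

Graph bubbles are genotyped from short reads by allele-distinctive
k-mers: each allele, flanked by $k - 1$ bp of backbone context (so
junction k-mers exist even for pure deletions), is decomposed into
31-mers; k-mers shared between alleles of a site — or between sites — are
discarded. Read support is counted in one pass over all reads and
normalized to a per-k-mer depth, making a deletion junction (about 30
distinctive k-mers) comparable to a kilobase insertion (about a thousand).
Diploid calls use conventional thresholds: alternative fraction ≤ 0.2 is
0/0, ≥ 0.8 is 1/1, otherwise 0/1; total depth below `min_depth = 4` — or
an allele with no distinctive k-mer at all — yields a missing call. At
multiallelic sites the best-supported pair of alleles is called,
matching VCF allele-index semantics.

Site filters run in a fixed order: missingness first (fraction of missing
genotypes strictly above 0.3 removes the site), then minor allele
frequency (below 0.01, computed over non-missing alleles only; at
multiallelic sites the minimum allele frequency). The filter report
accounts for every input site exactly once, and re-filtering a filtered
matrix removes nothing.

SV-to-gene annotation uses precedence coding > intron > regulatory
(within 2 kb of a gene, labelled upstream/downstream strand-aware) >
intergenic.

# Population analyses

* **PCA** — dosages mean-imputed per site, centred by $2p$ and scaled by
  $\sqrt{2p(1-p)}$, then SVD; explained variances are non-increasing and
  eigenvalues match a dense eigendecomposition oracle to 1e-8 in tests.
* **NJ tree** — allele-sharing distance ($1 - \mathrm{IBS}$ over shared
  non-missing sites; a pair with no shared sites is an error, not a
  guess), Saitou–Nei NJ via `ape`, bootstrap by resampling SV sites with
  replacement (character resampling, the convention for genotype
  matrices); node labels carry replicate counts containing each internal
  bipartition.
* **Δf scan** — per-group allele frequencies from non-missing alleles;
  hits strictly exceed the 0.5 threshold (a site at exactly 0.5 is not a
  hit), annotated with genes overlapped by the SV ± 2 kb.
* **Fst** — the per-site Weir–Cockerham (1984) variance-components
  estimator for diploid individuals with unequal sample sizes and no
  inbreeding component (the estimator VCFtools popularized). Monomorphic
  sites are undefined, not zero — averaging zeros into windows is a
  classic bias. Windowed values are ratios of summed numerators to summed
  denominators.
* **π** — per window, $\sum_\text{sites} 2p(1-p)\,n/(n-1)$ divided by the
  window width in bp, with $n$ the non-missing allele count per site.

Model-based ancestry inference (ADMIXTURE/STRUCTURE-style) is out of
scope by design: it is an off-the-shelf model with heavy fitting
machinery and nothing package-specific to test.

# The synthetic-data module

The generator is the package's study design, not a test hack, and its
defaults are fixed accordingly:

* **Ancestor**: uniform-GC random chromosomes; genes of 80–250 codons in
  2–4 exons (introns 80–400 bp), ATG start, stop codon, CDS divisible by
  three, non-overlapping placement with 500 bp margins (overfull packing
  is an explicit capacity error).
* **SV events**: log-uniform lengths between 50 bp and 10 kb (a desk-scale
  ceiling that preserves the heavy tail of real SV length distributions;
  the observed range in crop panels runs to hundreds of kb), inversions
  and translocations at least 1 kb, all events in intergenic space with
  at least 2 kb separation so truth sets have unique flanks. DIV events
  are length-neutral replacements; DUP is tandem; TRA is cut-and-paste
  with two breakends. The length distribution is a free modelling choice
  (the field reports ranges, not laws) and is exposed in the sampler's
  arguments.
* **SNP noise**: iid substitutions, never within 100 bp of a planted
  breakpoint. The guard exists because a SNP closer to the junction than
  the minimum anchor length erodes the flanking anchor and shifts called
  breakpoints; keeping truth sets unambiguous is precisely what the
  recall tests need. Outside the guard, SNPs exercise the pipeline's
  robustness (chains must join across them).
* **Gene PAV panels**: a shared pool of gene templates in one global
  collinear order, occupancy planted per class (dispensable genes in 2 to
  n−1 genomes, private in exactly one), per-genome SNP divergence at
  2 × 10⁻³ per bp.
* **Populations**: diploid genotypes drawn Binomial(2, f) per accession
  from per-population allele frequencies, missingness applied
  independently. Sweep sites in the acceptance panels are drawn with
  wild frequencies in [0.9, 1] against cultivated [0, 0.1] — a parametric
  Δf of at least 0.8, far enough from the 0.5 scan threshold that
  finite-sample wobble (SE ≈ 0.05 at n = 50 diploids) cannot cross it.
* **Read sets**: uniform single-end reads from both strands, iid
  substitution errors, fold-coverage exact up to rounding per chromosome.

Every generator is byte-deterministic per seed, and restores the caller's
RNG state.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: repeat and TE landscapes (anchors face far more
ambiguity in real plant genomes), indel sequencing errors, library
insert-size structure, reference bias in read sampling, gene families
with deep paralogy, and LD between SV sites. Recall numbers on synthetic
panels are upper bounds, not forecasts.

# Numerical and design choices

* Coordinates are 0-based half-open internally; GFF3/VCF emission is
  1-based. GFF3 CDS phase is computed in translation order, so
  minus-strand multi-exon genes round-trip correctly.
* Chain scoring is summed anchor length minus gap/100, ties broken by
  leftmost reference start; site merging and SV deduplication both use
  ±10 bp, the anchors' breakpoint resolution.
* Nested or overlapping variant sites during graph integration: the
  outermost (leftmost-starting) site wins; the overlapped one is dropped
  rather than nested — bubbles stay disjoint on the backbone.
* Two insertions at one breakpoint in one linear-pan iteration are
  spliced longest-first, deterministically.
* The graph holds events down to `min_variant` (default 50 bp; it can be
  lowered to 10 bp to mirror graph builders that keep smaller events —
  SV tables still report from 50 bp).
* Genotyping thresholds (0.2 / 0.8, depth 4) are conventional diploid
  values, exposed as arguments.
* The acceptance-scale study conditions are: a 2 Mb, 2-chromosome
  backbone with 30 genes and 4 derived genomes sharing a pool of 60
  planted SVs; a 300-SG, 4-genome gene panel (200 core / 60 dispensable /
  40 private); and a 20-accession, 20× read panel at 0.2% error. These
  sizes make the full pipeline a few minutes of CPU while keeping every
  recall and concordance statistic estimable.

# Known limitations

* DUP detection is tandem-only; an interspersed duplication is
  indistinguishable from a translocation plus copy at anchor resolution.
* MUM-mode anchor symmetry (swap of reference and query) holds on
  repeat-free sequence; uniqueness is enforced in the reference only, as
  in standard whole-genome aligners, so heavy repeats break the symmetry.
* SVs within `min_cluster` (1 kb) of a chromosome end cannot be anchored
  on both sides and are not called.
* Linear-pan genotyping against reads is reduced to the graph module's
  junction/k-mer machinery; read-pair and split-read evidence modelling
  is out of scope.
* Path fidelity of the graph is exact only down to the variant size floor:
  substitutions and sub-threshold indels live on the paths' sequence but
  not in the graph.
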