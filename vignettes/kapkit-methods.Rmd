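---
title: "Models and methods behind kapkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind kapkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

kapkit implements an end-to-end analysis of tandem KRTAP (keratin-associated
protein) gene families: mining them from genomic scaffolds, classifying them,
and quantifying the evolutionary forces — gene conversion, pseudogenization,
positive selection — that shape their repertoires. This vignette records the
models, the tunable parameters and their defaults, the numerical choices, and
the known limitations, in the package's own words.

## The synthetic-genome generator

`simulate_repertoire()` is first-class, tested code, not a fixture. It
emulates the statistical structure the downstream analyses assume, and its
defaults define the study conditions used throughout the test suite:

* **Geometry.** Five tandem clusters (`n_clusters = 5`), one subfamily each,
  4–8 genes per cluster, gene length 60–300 codons (KRTAPs are small, ~1 kb
  loci), intergenic spacers of 2–8 kb at GC 0.45. 80% of clusters are
  cysteine-rich (HS), the rest glycine/tyrosine-rich (HGT), mirroring the
  24/6 split of recognized subfamilies.
* **Sequences.** The ancestral protein of a cluster is tandem copies of a
  class-specific repeat unit (`CCQPSCCQTS` for HS, `GGYGGLGSYG` for HGT) with
  25% residue turnover from a background pool; it is back-translated
  uniformly over synonymous codons. Paralogs descend from the ancestor along
  a random gene tree with exponential branch lengths (mean
  `branch_scale = 0.04` substitutions/site) under HKY with κ = 2. The start
  codon, terminal stop and reading frame are preserved during evolution:
  substitutions that would create an in-frame stop are reverted, so that the
  planted lesions alone decide a gene's status and the truth table stays
  exact.
* **Gene conversion.** Tract counts per ordered gene pair are Poisson
  (`conversion_rate`, default 0), tract lengths geometric
  (`tract_mean = 100` nt). Within a tract the acceptor copies the donor,
  except at weak/strong (A/T vs G/C) heterologies, which resolve to G/C with
  probability `gbgc_bias` (default 0.7). This is the minimal standard model
  of GC-biased gene conversion; the magnitudes are exposed, not fitted — no
  published tract-length or rate estimates are asserted.
* **Pseudogenization.** Each gene independently acquires lesions with
  probability `pseudo_prob = 0.2` (close to the 19% pooled pseudogene
  fraction of the packaged 22-species table). Lesions are drawn uniformly
  from 1-nt insertion, 1-nt deletion and point mutation to a premature stop,
  never in the first or last codon.
* **Fragmentation.** `fragmentation` is the expected number of scaffold
  breaks per cluster (Poisson, default 0). Genes cut by a break are
  truncated; a truncated, lesion-free gene is recorded as *partial* —
  the package's operational definition of a partial gene, chosen because
  missing sequence in low-coverage assemblies is the stated cause of
  partial models.

What the generator does **not** emulate: repeats and isochore structure in
the intergenic background, selection during sequence evolution, indel
mutation outside conversion/lesions, and real KRTAP motif diversity. Passing
tests therefore demonstrate the correctness and calibration of the methods
under the generative model, not mining performance on real assemblies.

## Mining

`seed_extend_search()` finds exact 11-mer seeds on both strands, chains
seeds within a ±30 diagonal band, requires at least two chained seeds (a
two-hit heuristic that suppresses isolated chance 11-mers), and extends each
chain by banded local alignment (+1/−2, gaps −5/−2). E-values use the
ungapped Karlin–Altschul approximation: λ is solved from
Σ pᵢpⱼ e^{λ sᵢⱼ} = 1 with uniform base frequencies and K defaults to 0.46
(the conventional value for the +1/−2 scheme); the cutoff is E ≤ 10.
`merge_hits()` extends hits by 500 bp, merges transitively at gaps ≤ 10 kb
(configurable; within-cluster spacing is a few kb, between-cluster distances
far larger), and splits anything over 0.3 Mbp at its largest internal gap.

`translated_align()` is a frameshift-aware local DP of a reference protein
against fragment DNA: codon moves consume 1–5 nt per residue, with non-3
moves penalized at −12 (protein scale); gaps are linear at −10; in-frame
stop codons score as BLOSUM62 `*` and are recorded. When a lesion-free local
alignment fails to cover the whole reference, a protein-global rescue pass
(free DNA ends, residue skips costlier than a frameshift) re-examines the
termini. **Known limitation:** a lesion within the terminal two codons is
parsimony-indistinguishable from one or two diverged terminal residues, and
a frameshift inside a sequence repeat can admit an equally parsimonious
in-frame reading; such genes fall to *partial*, never *intact*. The test
suite asserts 100% detection for interior premature stops and ≥ 95%
pseudogene detection overall.

`call_candidates()` groups a fragment's hits into gene windows, assigns each
window to its best-scoring panel reference, prefers a complete ORF model
(≥ 40 codons) when the alignment is lesion-free, and confirms every
candidate by a reciprocal best hit of the extracted sequence against the
full panel (score floor 100, ≥ 30 aligned residues).

## Classification

*Pseudogene* ⇔ at least one frameshift or internal stop. *Partial* ⇔
lesion-free but missing start/stop or abutting a scaffold end. Compositional
classes: gly+tyr ≥ 30% with cys < 30% → HGT; cys > 30% → ultrahigh-sulfur;
else high-sulfur. A cysteine content of exactly 30% falls in high-sulfur
(the published definitions use strict inequalities and leave the boundary
unhoused). The HGT threshold default of 30% was set from the family-mean
compositions the classification must reproduce: the HGT subfamily lowest in
gly+tyr sits at 32.0% while the highest HS subfamily eligible for HGT (cys
< 30%) sits at 18.4%, so any threshold in that gap separates the classes;
30% is mid-gap. Subfamily assignment uses global-alignment identity against
the panel with a 60% floor, lexical tie-break, and an optional motif library
that can veto an assignment. Genomic clusters are single-linkage groups at
gaps ≤ 200 kb.

## Phylogenetics

Progressive alignment builds a k-mer-distance NJ guide tree, then merges
profiles with global affine profile–profile alignment under BLOSUM62 (gap
open −10, extend −1); profile columns are residue-frequency vectors and gaps
carry zero weight. Distances are p-distances with pairwise deletion by
default (complete deletion available); pairwise deletion preserves signal in
length-polymorphic families. Neighbor joining is the canonical Saitou–Nei
agglomeration (via ape); negative branch estimates are clamped to zero and
counted in a `clamped_branches` attribute. Interior-branch support is
implemented as bootstrap bipartition frequency over column resamples
(default 1,000): the package deliberately labels it as a bootstrap variant,
since the classical interior-branch test is a z-test on branch length and
the choice between them is not decidable from the analyses this package
reproduces. In degenerate resamples where a pair shares no comparable
column, the bootstrap distance falls back to 1.

## Divergence statistics

`nei_gojobori()` implements the modified Nei–Gojobori method in its
p-distance form. Site counting weights transitions R (default 2) and
transversions 1, normalized per position; mutations to stop codons count as
nonsynonymous, so S + N = 3 × compared codons exactly. Differences are
averaged over all shortest mutational paths between codons, excluding paths
through stop codons (all paths are kept if every path is blocked — the
standard convention, unstated in most descriptions). No multiple-hit
correction is applied. Codons containing gaps or ambiguity codes in either
sequence are skipped pairwise; a shared terminal stop codon is stripped.
The implementation is validated against an exhaustive enumeration oracle on
all 61 × 61 sense-codon pairs and on random 300-codon pairs.

Subfamily summaries take mean pairwise dS over intact members, with GC% over
the full CDS and GC3% at third positions (Ns excluded from numerator and
denominator). The diagnostic correlation — Pearson r of mean dS against
GC3% across subfamilies, pooled and per class — is negative when gene
conversion with GC bias homogenizes some subfamilies: conversion lowers
within-subfamily dS while biased resolution raises GC3.

## Conversion and recombination scans

`geneconv_scan()` works on the polymorphic (gap-free, >1 state) columns of
an alignment. For each sequence pair the statistic is the maximal run of
consecutive polymorphic columns at which the pair agrees; with a positive
`mismatch_penalty` it generalizes to maximal positive-scoring segments
(Kadane). The default penalty of 0 (exact runs) mirrors the classical
default behaviour. The null distribution comes from permuting polymorphic
column order (10,000 permutations by default; p = (1 + #{null ≥ obs}) /
(n_perm + 1)), and a global Bonferroni correction multiplies by the number
of pairs. Only pairwise ("inner") fragments are computed. The test suite
calibrates the family-wise false-positive rate under 200 null alignments and
the detection rate on planted 30-site tracts.

`maxchi_scan()` slides a breakpoint over the polymorphic sites of each pair
and computes a 2×2 chi-square of matches/mismatches in flanking half-windows
(window default 30 sites, 1,000 permutations, Bonferroni-corrected α = 0.01).
Pairs are scanned rather than triplets; subfamilies with fewer than four
genes are not informative for either scan.

## Codon site models

`fit_site_model()` maximizes the Goldman–Yang codon-model likelihood over
the 61 sense codons with F3x4 frequencies (equal-frequency mode available
for hand-checkable cases). The reversible rate matrix is eigendecomposed via
the π^{1/2} symmetrization; branch lengths enter as a single optimized scale
on the input tree, normalized by the mixture-average substitution rate.
Models: M0 (one ω), M1a (ω₀ < 1, ω₁ = 1), M2a (adds ω₂ ≥ 1), M7 (beta),
M8 (beta plus ω ≥ 1 class). The beta is discretized into 10
equal-probability categories at bin-median quantiles. The ω ≥ 1 constraint
is applied to the positive classes of M2a and M8 via a 1 + e^x transform.
Optimization is BFGS on unconstrained transforms (proportions via softmax,
rates via log) with a Nelder–Mead fallback, tolerance 1e-6 on the
log-likelihood, and jittered restarts; `site_model_lrt()` warm-starts the
alternative model from the null optimum (mapping the M1a solution onto M2a
with a small positive class), floors 2ΔlnL at 0, and uses χ² with df = 2.
NEB posteriors identify sites in the positive class above 0.95.

Numerical notes: likelihoods are computed on unique codon-site patterns;
pruning uses dense 61 × n matrix products without per-node rescaling, which
is ample for the tree depths used here (site likelihoods stay far above the
double-precision floor for tens of sequences); identical-sequence inputs
drive the tree scale to its lower bound and reproduce the closed-form
stationary likelihood. Cold-started nested fits can differ by up to ~0.01
lnL from the true ordering; the LRT's warm start plus flooring guarantees a
non-negative statistic.

The calibration experiments run at 8 sequences × 200 codons on a ladder
tree with all branches 0.25 — sizes chosen so 200 null replicates and 50
power replicates fit comfortably in a routine test run — with
`n_restarts = 0` and `tol = 1e-5`, settings verified to reproduce the
default-setting optima on these data. Under the null (70% of sites at
ω = 0.2, 30% neutral) the M1a-vs-M2a rejection rate at p < 0.05 is
conservative, as expected when the true parameter lies on the boundary of
the null space; with 20% of sites at ω = 3 the test's power exceeds 0.8.

## Repertoire statistics

Count tables use the `total(pseudo)` cell convention. Pseudogenization
rates are reported per species (full precision and nearest-integer), pooled
over all species, and as the mean of per-species rates — the "pooled vs
mean" distinction matters (19.5% vs 21.7% on the packaged table) and both
are always emitted rather than asserting either as the canonical "average".
Presence uses total ≥ 1 out of the 30 recognized subfamilies even though 6
of them are absent from all 22 packaged species. Dollo mapping gains each
subfamily once at the MRCA of its possessing species and takes as losses the
maximal subtrees below the gain containing no possessor; this minimizes
losses under the single-gain constraint (checked against exhaustive
assignment on small trees). The packaged species tree encodes the standard
mammalian topology for the 22 species; users may substitute their own.

The packaged count table reproduces its printed per-species marginals for 17
of the 22 species; for two species the printed totals appear column-swapped
and three have one-off pseudogene sums. The body cells are treated as
authoritative, and the worked-example species (dolphin, sloth, wallaby,
guinea pig) are all internally consistent.

## Design choices made where the design was open

* Internal coordinates are 0-based half-open everywhere; GFF3 output is the
  single 1-based surface.
* Fragment extension before merging is symmetric (±500 bp); the alternative
  (asymmetric extension to the cap) is not recoverable from the method
  descriptions this package follows.
* `cluster_gap = 10 kb` for hit merging and 200 kb for genomic cluster
  assignment; both configurable.
* The "interior branch test" is the bootstrap variant, labelled as such.
* The exact modified-NG site-counting formula of legacy software is not
  published; the R-weighted NG86 scheme implemented here is validated
  against the in-repo enumeration oracle instead.
* χ² with df = 2 is used for both LRT comparisons; boundary-corrected
  mixture distributions are not.

## Known limitations

* Terminal-lesion blind zone in pseudogene detection (two codons at each
  end), and frameshifts inside perfect repeats (see Mining).
* The simulator's partial genes arise only from scaffold breaks, not from
  assembly gaps inside scaffolds.
* Gene-conversion detection operates on equal-length (gap-free) paralog
  alignments of ≥ 3 sequences; outer-sequence fragments and
  phylogenetic-incongruence detectors are out of scope.
* Published per-species conversion pair counts are not reproducible without
  the original mined sequences; the statistics are validated on synthetic
  tracts instead.
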