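---
title: "Diversity, differentiation and sweep scans on KASP panels: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diversity, differentiation and sweep scans on KASP panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kaspdiv)
```

`kaspdiv` analyses a germplasm panel typed at a few dozen biallelic
functional markers — one diagnostic SNP per cloned gene — stratified by
agro-ecological zone (I–X), breeding-era group (CL = landraces,
MCC = modern cultivars) and, for modern cultivars, release decade. This
vignette is the package's account of the statistics it implements, the
parameters that matter, what the synthetic panel generator does and does
not emulate, and the design decisions taken where conventions genuinely
diverge.

## The data model

A panel is a tibble of accessions × markers with calls in
{`AA`, `BB`, `AB`, missing} plus metadata columns, and a marker manifest
(gene, favorable allele, trait class) carried as an attribute. Calls are
normalized from a declared token dialect (`kasp_dialect()`): single-letter
tokens mean homozygous, the inbred-line convention; `H` is heterozygous;
`NA`, `-`, `.` and the empty string are missing. Missingness is kept as an
explicit state and never imputed at I/O time — each statistic decides
locally (frequencies exclude missing calls; PCA mean-imputes; pairwise
distances drop the locus for the affected pair only).

Two frequency notions coexist deliberately. *Allele-copy frequency* `p`
counts B alleles over scored copies (a heterozygote contributes one copy
of each). *Carrier frequency* counts accessions with at least one copy of
a named allele. Breeding literature reports percentages of accessions, so
the survey, fixed-variant and rare-allele outputs are carrier-based, with
`p` always reported alongside.

Heterozygotes contribute one allele copy each; lines are treated as
ordinary diploids with no inbreeding coefficient, because the estimators
below depend on frequencies only.

## Diversity, differentiation, distance

**Site diversity.** Per marker, π = 2*p*(1−*p*) (Nei gene diversity). The
default is *uncorrected*, matching the legacy population-genetics tools
this style of analysis descends from; `corrected = TRUE` applies
*n*/(*n*−1), which equals the mean pairwise difference over all C(*n*,2)
sampled allele copies (the package tests this identity by brute-force
enumeration up to *n* = 60). Group diversity is the arithmetic mean over
loci with a defined frequency.

**Differentiation.** Per locus, with group frequencies *p*₁, *p*₂:
*H*S is the mean of the within-group diversities (equal weights by
default; size weighting available), *H*T = 2*p̄*(1−*p̄*), and
*F*st = (*H*T−*H*S)/*H*T where *H*T > 0. With equal weights Jensen's
inequality guarantees per-locus *F*st ∈ [0, 1], zero exactly at equal
frequencies. The multilocus value is the ratio of sums Σ(*H*T−*H*S)/Σ*H*T
over loci defined in both groups and polymorphic in the pool; monomorphic
pooled loci are excluded from the sums and reported as undefined, not
silently dropped. The mean of per-locus values is also reported: printed
"mean Fst" figures in this literature do not always satisfy the island
model identity against the printed gene flow, and the averaging scheme
behind them is typically unstated, so the package exposes both variants
rather than forcing agreement. Weir–Cockerham θ is deliberately not
implemented — the analyses this package reproduces use Nei-style indices.

**Gene flow.** *N*m = (1−*F*st)/(4 *F*st), the island-model conversion,
computed from the multilocus ratio-of-sums value. Outside (0, 1) the
quantity is undefined and returned as `NA` with a warning (e.g. grid
diagonals). The identity *N*m·4·*F*st + *F*st = 1 holds to machine
precision for every computed pair and is asserted in the test suite.

**Nei (1972) distance.** *J*xy = mean over shared defined loci of
Σ alleles *x·y*; *I* = *J*xy/√(*J*x·*J*y); *D* = −ln *I*, with *I* = 0
reported as +∞. For accession-level trees each accession's "frequency"
vector is its dosage/2 (0, ½, 1) — the standard device for inbred panels.
Zone-level trees use zone frequency vectors; both modes exist because
published per-subpopulation trees are sometimes over accessions and
sometimes over zone centroids.

## Trees and PCA

Neighbor joining is implemented in-package (classic Saitou–Nei): at each
step the pair minimizing Q(i,j) = (r−2)d(i,j) − Σd(i,·) − Σd(j,·) is
joined, branch lengths come from the standard split formula, negative
estimates are clamped to zero, and Q-ties break deterministically toward
the lowest (row, column) index, so identical inputs give byte-identical
Newick output. On additive metrics the generating topology and branch
lengths are recovered exactly; the test suite verifies this on 200 random
trees (4–12 leaves) and cross-checks the topology against an exhaustive
least-squares search over all unrooted topologies at ≤ 6 leaves and
against `ape::nj` on noisy matrices. The final three clusters join at a
trifurcating root (unrooted convention). Newick serialization uses fixed
6-decimal branch lengths and single-quotes labels containing reserved
characters.

PCA encodes calls as B-allele dosage {0, 1, 2}, imputes missing entries
with the locus mean, mean-centers columns without variance scaling, and
reports projections on the leading eigenvectors plus explained-variance
fractions. Dosage-with-mean-imputation is adopted as the standard
convention since the upstream tools used for published panels do not state
theirs. Each component's sign is fixed by making its largest-magnitude
loading positive, so scores are invariant to accession order.

## Sweep scans

Per zone, two statistics per marker: the per-locus *F*st between CL and
MCC within the zone, and the diversity ratio π_CL/π_MCC (uncorrected π).
"Significant at the 5% level" is interpreted as the *empirical top-5%*
rule — the dashed-line convention of sweep-scan figures — not a parametric
test. The threshold is the nearest-rank quantile, i.e. the ⌈0.95·L⌉-th
order statistic of the L finite defined values, and a signal must
*strictly* exceed it; nearest-rank with strict exceedance was chosen for
determinism (an interpolated variant is available via `type =
"interpolated"`). Consequences worth knowing:

* at most L − ⌈0.95·L⌉ finite values can ever be flagged per statistic
  (2 when L ≈ 40–52), and with all values tied nothing is;
* π-ratio degeneracies are explicit: 0/0 is undefined (`zero_zero`),
  *x*/0 is `infinite`. Infinite ratios never enter threshold estimation
  but do count as signals — they exceed any finite threshold, and
  biologically they are the strongest possible sweep signature (diversity
  erased in modern cultivars while landraces segregate);
* if a statistic has fewer than two finite values in a (small) panel its
  threshold is undefined and nothing is flagged for it.

Thresholds are computed per zone by default, matching per-panel dashed
lines; a pooled scan (`global_scan()`) recomputes them on the pooled
statistics. Signal counting defaults to one signal per (zone, marker,
statistic) exceedance — a marker can legitimately contribute through both
statistics in a zone, which is how published per-zone signal totals exceed
the count of distinct markers — with `counting = "per_marker"` collapsing
the two statistics.

## The synthetic panel generator

`simulate_panel()` draws truth-known panels under the Balding–Nichols
model: per locus an ancestral frequency *p*₀, then per stratum
(zone × group) a latent frequency from
Beta(*p*₀(1−F)/F, (1−*p*₀)(1−F)/F), then inbred-like diploid genotypes.
Defaults are the study conditions the package targets: 10 zones, 22 CL +
22 MCC per zone with zone IX at 20 MCC (438 accessions), 52 loci, 2%
missing calls and 2% residual heterozygosity — realistic for inbred wheat
panels. Two values are not dictated by the design and were fixed once:

* **F = 0.13**, the printed landrace-vs-cultivar differentiation this
  kind of panel exhibits;
* **ancestral frequencies ~ Beta(0.5, 0.5)**, U-shaped, reproducing the
  "uneven" allele-frequency distributions functional markers show (many
  near-fixed loci, few balanced ones).

Heterozygosity is thinned by inbreeding-style redistribution:
P(AB) = h·2*p*(1−*p*) with the removed mass returned to the homozygotes
in proportion to allele frequency, so E[dosage]/2 = *p* exactly and
frequency-based estimators are unbiased by the thinning. Selection is
injected by shifting a stratum's MCC latent frequency by δ (clipped to
[0, 1]) before genotypes are drawn; `inject_selection()` does the same
post hoc, redrawing only the affected cells from a seed derived from the
panel seed and the cell coordinates, so everything stays reproducible.
`null_panel()` shares one latent frequency between CL and MCC per zone for
false-positive calibration. An optional hierarchical mode draws a zone
pool first and the two groups around it, giving zone-level gene-flow
structure for grid testing.

What the generator does *not* emulate: linkage between markers, pedigree
or breeding-program structure, temporal dynamics across decades (decade
labels are metadata only), genotyping error beyond missingness, and
ascertainment of markers toward favorable alleles. Tests passing on
simulated panels therefore validate the estimators and the pipeline
plumbing, not claims about any real germplasm collection.

Because strata are drawn independently around *p*₀, differentiation lives
*between strata*: the k-stratum estimator `gst_strata()` recovers the
configured F (up to the (1−1/k) factor of k-group Gst, ~5% at k = 20),
and the package's recovery experiments use it. Pooled CL vs pooled MCC
across 10 zones averages the zone draws and is an order of magnitude
smaller — expected model behaviour, not an estimator defect.

## Numerical choices and degenerate inputs

* Frequencies are undefined below `min_calls = 5` non-missing accessions
  per (group, locus); entries are flagged, never dropped, and undefined
  loci propagate explicit `NA`s.
* Fixed variants use the *inclusive* bound (carrier ≥ 0.95), rare alleles
  the *strict* one (< 0.05), tested exactly at the boundaries. Each
  marker contributes two classifiable alleles, so stratum totals use
  2 × (defined markers) as denominator — a fixed marker's minor allele is
  usually also rare, and both classifications are reported.
* Ancestral frequencies are clipped to [10⁻⁴, 1−10⁻⁴] before the Beta
  draw (the shape parameters must be positive).
* Nei identity is clamped to ≤ 1 against floating-point excess; NJ input
  must be symmetric (tolerance 10⁻⁸) with a zero diagonal.
* All simulation and pipeline outputs are byte-reproducible from the
  seed; scan tie-breaks inherit determinism from the nearest-rank rule.

## Scales used by the verification experiments

The acceptance experiments run at: F-recovery — 200 accessions/stratum,
500 loci, 50 replicates per F ∈ {0.05, 0.1, 0.2, 0.3}; NJ — 200 random
additive trees of 4–12 leaves plus exhaustive topology enumeration at 5–6
leaves; scan calibration — 50 null single-zone panels; scan power — 200
replicates of a single zone with three δ = 0.6 sweeps injected against a
modest F = 0.05 background. These sizes give Monte-Carlo error comfortably
below the tolerances being asserted.

## Known limitations

* Single diagnostic SNPs per gene: no haplotype-based sweep statistics
  (iHS, XP-EHH) and no sequence-level π.
* Point estimates only — no permutation *p*-values or bootstrap supports,
  matching the analyses the package reproduces.
* The top-5% rule is an outlier scan, not a test with controlled error
  rates; with ~52 loci it can flag at most 2 finite values per statistic
  per scan, which bounds the recall of multi-locus sweep scenarios (the
  package's power experiment measures ~0.75–0.77 recall for three δ = 0.6
  sweeps injected into one zone, with the shortfall concentrated in
  injected loci whose modern-cultivar diversity is reduced but not
  erased).
* Gene-flow *N*m inherits every caveat of the island model; treat it as a
  monotone transform of *F*st, not a demographic estimate.
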