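---
title: "Methods: phenotypic and SSR-based germplasm diversity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotypic and SSR-based germplasm diversity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germdiv)
```

## Scope and data model

`germdiv` characterises a crop germplasm collection from two sides: a
phenotype table (accessions by traits, each trait quantitative in a stated
unit or qualitative as small integer class codes) and a codominant SSR
marker table derived from electrophoresis band scores. The package treats
the band matrix as the primary molecular observation: every primer
contributes exactly two band slots, one per allele of a biallelic locus,
and the slot pair maps one-to-one onto genotype calls — (1,0) is the AA
homozygote, (0,1) the BB homozygote, (1,1) the heterozygote, and (0,0) is a
missing call, never a genotype. This codominant reading is forced by the
statistics downstream: observed heterozygosity is undefined under dominant
scoring. Missing phenotype cells are `NA` throughout and are never encoded
as zero, because zero is a legitimate measurement for many traits.

Hyphenated and plain spellings of the same primer (`BLF-79` / `BLF79`) are
normalised to one identifier, since both conventions occur in practice for
the same primer set.

## Phenotypic diversity

Diversity of a qualitative trait is the Shannon–Weaver index
$H' = -\sum_i p_i \ln p_i$ over its class frequencies, in nats. Natural
logarithms are used everywhere: the frequently quoted minimum of 0.15 for a
two-class trait split 96.5 % / 3.5 % is reproduced exactly in nats, whereas
base-2 logs would give 0.22.

Quantitative traits are binned into ten classes before the index is taken,
with boundaries at mean $+ k\,\mathrm{sd}$ for $k = -2, -1.5, \dots, +2$
(first and last classes open). This is the standard grid of the
germplasm-diversity literature, and its maximum $\ln 10 \approx 2.30$ is
consistent with the indices slightly above 2 reported for quantitative
traits in published proso millet panels. Source studies rarely state their
binning rule, so this grid is a documented package choice rather than a
reproduction. Two numerical notes: the analytic index of a normal
distribution over this grid is 2.088 (obtained by integrating the normal
density over the ten bins), which is the oracle the tests check sampling
estimates against; and a symmetric two-point distribution necessarily sits
at $\pm 1$ sample sd, so at most two (interior) classes can be occupied —
no data set can occupy only the open extreme classes, because at most a
quarter of the mass can lie beyond two standard deviations.

The coefficient of variation is $100\,\mathrm{sd}/\mathrm{mean}$ and is
reported only for quantitative traits; a dispersion ratio over arbitrary
class codes has no meaning, so qualitative rows carry `NA` there.
Correlations (`trait_correlations()`) are pairwise-complete Pearson by
default with Spearman behind a flag; graded qualitative traits enter as
their integer codes, which mirrors how mixed trait panels are usually
correlated. Pairs with fewer than three complete observations are flagged
undefined rather than estimated. Significance wording follows the usual
convention: p < 0.05 significant, p < 0.01 highly significant.

## PCA scoring and representative selection

`pheno_pca()` mean-imputes missing cells, z-score standardises, and
eigendecomposes the correlation matrix. Components with eigenvalue above 1
are retained by default (Kaiser rule), overridable. Eigenvector signs are
pinned by making each component's largest-magnitude loading positive, so
scores are reproducible across platforms. By default only quantitative
traits enter; whether coded qualitative traits belong in a trait PCA is
genuinely contestable, so they are excluded unless
`include_qualitative = TRUE`.

The comprehensive score is
$F = \sum_i w_i\, s_i$ over the retained components, with $w_i$ the
explained-variance proportions renormalised over those components. Higher
F means a better overall phenotype and is the ranking key for selection.

Phenotype clustering is Ward linkage (`ward.D2`) on Euclidean distances
over the standardised quantitative traits. Published panels typically name
no algorithm for this step; Ward is the standard choice for morphological
matrices and produces the compact, unbalanced group structures such panels
report. Representative selection then works per cluster: quotas
proportional to cluster size (largest-remainder rounding with a minimum of
one), accessions taken in descending F within each cluster, and a repair
pass that guarantees every qualitative class present in the collection
survives into the selection — the highest-F carrier of a missing class is
swapped in for the lowest-F selected accession whose removal keeps coverage
intact. The quota rule and repair pass are deterministic package choices;
the selection principle ("rank by F, compare against qualitative traits")
is usually stated in prose without an algorithm.

## SSR population genetics

All statistics are computed from allele frequencies
$p(A) = (2 n_{AA} + n_{AB}) / (2n)$ over non-missing calls:

* effective alleles $N_e = 1 / \sum p_i^2$;
* Shannon index $I = -\sum p_i \ln p_i$;
* Nei's gene diversity $h = 1 - \sum p_i^2$ (so $N_e = 1/(1-h)$ exactly,
  an identity the tests assert to machine precision);
* unbiased expected heterozygosity $He = \frac{2n}{2n-1} h$ (Levene), with
  per-locus $n$ from non-missing calls;
* PIC $= 1 - \sum p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2$ (Botstein), evaluated
  through the closed form $1 - S_2 - S_2^2 + S_4$ and cross-checked in the
  tests against an explicit pair loop.

Note that for a biallelic locus the Botstein PIC cannot exceed 0.375; PIC
columns in some published SSR tables exceed this even at two alleles per
locus, which implies a different (unstated) formula there. Such columns are
therefore audited only where self-consistent; this package always reports
the frequency-based Botstein value.

Between populations, Nei's (1972) identity averages $\sum x_i y_i$,
$\sum x_i^2$ and $\sum y_i^2$ across loci *before* forming
$I_N = J_{XY} / \sqrt{J_X J_Y}$, and $D = -\ln I_N$. This
average-then-ratio order is the convention of the classic population
genetics software, and it is the one under which published regional
identity/distance tables are internally consistent: applying $-\ln$ to the
bundled published identities reproduces every printed distance to four
decimals (one pair off by 1 in the fourth decimal from rounding of the
printed identity). The recomputed mean identity is 0.929 where the source
prints 0.92 — compatible with truncation — and the mean distance rounds to
0.08 exactly.

For auditing published per-locus tables, `invert_nei_biallelic()`
reconstructs biallelic frequencies from a printed gene diversity via
$p = (1 + \sqrt{1 - 2h})/2$; recomputing $N_e$ and $I$ from those
frequencies reproduces the bundled published columns within ±0.002 (the
printed $h$ is rounded to four decimals).

## Band distances, UPGMA and marker PCA

The default accession distance is Dice (Nei & Li) on band presence,
$d = 1 - 2a/(2a+b+c)$, the standard choice for fingerprint band data;
simple matching is available. UPGMA is implemented directly: merge the
closest pair, set the merge height to $d/2$ (so leaf-to-leaf path lengths
reproduce the input distances when the input is ultrametric), and update
distances by size-weighted averaging. Exact ties are broken
lexicographically by each cluster's smallest leaf label, making trees
reproducible; the tests verify exact reconstruction of ultrametric inputs
and agreement with an independent average-linkage reference on random
matrices. Trees serialise to Newick with six-decimal branch lengths and
convert to `ape` phylo objects for plotting. Marker PCA column-centres the
binary band matrix and eigendecomposes its covariance — bands are not
standardised because slot variances carry information.

## Admixture model and delta-K

Population structure is estimated with the admixture likelihood: accession
$i$ has ancestry fractions $q_{ik}$ over $K$ source populations with
allele frequencies $p_{kl}$, and its allele dosage at locus $l$ is
binomial$(2, \sum_k q_{ik} p_{kl})$. The package maximises this likelihood
by EM from a seeded random start — a deliberate substitution of
maximum-likelihood point estimation for the Bayesian MCMC of the classic
structure software: the generative model is the same, the estimates are
deterministic given a seed, and desk-scale panels converge in seconds.
Frequencies are clamped to $[10^{-6}, 1-10^{-6}]$; missing genotypes
contribute nothing to the likelihood; the log-likelihood is asserted
monotone at every iteration and $Q$ rows remain on the simplex. At $K=1$
the fit collapses to the closed-form binomial likelihood at pooled
frequencies, which the tests check to $10^{-8}$.

Model selection uses the Evanno second-difference statistic over replicate
runs: $\Delta K = |\bar L(K{+}1) - 2\bar L(K) + \bar L(K{-}1)| /
\mathrm{sd}(L(K))$, with per-K replicate means in the numerator and the
replicate standard deviation in the denominator. $\Delta K$ is undefined at
the boundary K values, with fewer than two replicates, or with zero
replicate sd (which genuinely occurs at $K=1$, where every start converges
to the same closed form); such entries are `NA`, not zero. Replicate seeds
derive deterministically from one base seed. Defaults: 10 replicates,
`max_iter` 2000, `tol` 1e-6. Because components are identifiable only up to
label permutation, comparisons between fits go through
`match_admixture_labels()` (exhaustive permutation matching; K is small).

## Fingerprints and molecular IDs

A fingerprint is the concatenation of each primer's two band bits in a
fixed primer order — 12 primers give the 24-character codes used for
variety identification. `minimal_primer_set()` makes the
"maximum discrimination with minimum primers" principle executable as a
greedy rule: repeatedly add the primer splitting the most currently
indistinguishable pairs, stop when nothing improves. Exact minimisation is
exponential; at test scale the greedy set is checked against an exhaustive
oracle and required to be within one primer of optimal (the classic greedy
set-cover guarantee pattern). Molecular-ID payloads are deterministic
five-line `Field: value` texts (Name, Unicode, Source, Classification,
Code) suitable for any QR encoder; rendering the QR image is outside the
package's contract, the payload text is the testable artifact.

## Synthetic data: what it emulates and what it does not

The generator exists because raw germplasm matrices are rarely published;
it reproduces the *statistical shape* of a study so the pipeline is
testable end to end.

Phenotypes: quantitative traits are multivariate normal with requested
means, sds and correlations; qualitative traits are categorical draws. The
bundled default specification reproduces a published 1,582-accession proso
millet panel: 12 quantitative traits with printed means and CVs (stem
height 129.57 cm / 20.09 %, straw weight 32.15 g / 60.03 %, ...), 10
qualitative traits with printed class frequencies where available
(inflorescence colour 96.5/3.5, panicle type 23.6/52.6/23.8, ...), and the
printed correlation structure among the eight quantitative traits it
covers. Where a source prints only the modal class share (trichome: dense
59.5 %), the remainder is split once over the remaining classes and not
revisited. Truncation at zero is off by default: clipping a normal with CV
60 % shifts the mean by about 2 g and deflates the CV to about 51 %, which
would silently break the moment fidelity the generator promises; the flag
exists for users who need strictly non-negative values and accept the
bias. What the generator does not emulate: multi-year/location effects,
measurement error structure, skewness (several real yield traits have
30-fold ranges and are right-skewed), and trait-qualitative dependence. A
passing pipeline on synthetic data therefore demonstrates statistical
correctness of the methods, not agreement with any particular field trial.

Genotypes: the Balding–Nichols model — ancestral frequency per locus from
Uniform(0.05, 0.95), population frequencies Beta-distributed around it with
variance $F_{div}\, p(1-p)$ — with optional Dirichlet admixture and an
inbreeding knob, $P(AB) = 2f(1-f)(1-F_{is})$. Defaults are the emulated
study conditions: 147 accessions in six regional populations of sizes
14/30/10/25/63/5, 15 biallelic loci, $F_{div} = 0.15$ (which yields
between-region Nei distances spanning roughly 0.01–0.21, the published
range), and $F_{is} = 0.8$, because proso millet is predominantly
self-pollinating and published panels show zero observed heterozygosity at
most loci alongside occasional heterozygote-excess loci. The ancestral
range is wider than the central (0.1, 0.9) band one might first pick:
with the narrow band, pooled locus gene diversities never fall below about
0.07, whereas real SSR panels include near-monomorphic loci with
diversities down to 0.03; the wider range restores that low tail. All
randomness flows from one seed through a deterministic stream-splitting
helper, so every artifact is byte-reproducible.

`gen_fixture_suite()` writes the full bundle (traits + schema, genotypes +
populations + bands, a 20-accession screening panel, metadata, and an MD5
manifest) for use as on-disk fixtures.

## Problem sizes and numerical choices

The shipped tests run the full stack at the emulated study sizes where that
is cheap (1,582-accession phenotype tables, 147 x 15 genotype panels) and
at reduced sizes for the EM scan (three populations of 25 at 60 loci,
K = 1–5, five replicates), which recovers the true K by $\Delta K$ in
seconds. Frequency vectors are validated to sum to 1 within $10^{-9}$ and
renormalised; $0 \ln 0$ is defined as 0; distance matrices are symmetrised
to machine precision on construction; Dice distance between two all-zero
band rows is defined as 0 (identical observations). Degenerate inputs
(constant traits, all-missing loci, single-leaf trees, K exceeding the
panel size) raise errors naming the offending object rather than
propagating `NaN`.

## Known limitations

* The EM admixture fit gives point estimates only; no credible intervals,
  no linkage model, no prior population information.
* The quantitative-trait binning rule is a convention, not a reconstruction
  of any particular study's unstated rule; absolute diversity indices for
  quantitative traits are comparable within this package only.
* Selection repair optimises qualitative-class coverage greedily; it can
  shift per-cluster counts by a few accessions from exact proportionality.
* The greedy primer set is within one of optimal on all tested instances
  but carries no global optimality certificate at scale.
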