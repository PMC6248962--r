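---
title: "Dominant-marker population genetics with dompopgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dominant-marker population genetics with dompopgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dompopgen)
```

## The data type and its ambiguity

A dominant-marker survey scores each gel band as a presence/absence locus:
the observable at locus *l* in a population is the band frequency
*p*, the fraction of individuals showing the band. Because a band-present
individual may be either homozygous or heterozygous for the underlying
amplifiable allele, allele frequencies are not observable, and two
conventions coexist in the field's software:

* **band_state** treats the two phenotype classes themselves as the "alleles",
  with frequencies (*p*, 1 − *p*). This is what GenAlEx's binary pipeline
  computes, and it is the package default: it makes no genetic assumptions
  and keeps every statistic a deterministic function of the observed matrix.
* **dominant_hwe** assumes a diploid locus in Hardy–Weinberg equilibrium
  with the band allele dominant, so the null phenotype frequency
  *x* = 1 − *p* estimates *q*² and *q̂* = √*x*. This is the convention behind
  POPGene-style "Nei gene diversity" for dominant data. The Lynch–Milligan
  small-sample Taylor correction *q̂* = √*x* / (1 − Var(*x*)/(8*x*²)) is
  available as an option (`estimator = "lynch_milligan"`); it needs the
  scored sample count and reduces to the square root as *n* → ∞.

Both models are exposed through `locus_state_freqs()` and accepted by every
frequency-based statistic. They genuinely differ — a survey reporting
H<sub>e</sub> = 0.258 next to a gene diversity of 0.254 for the same
population is showing exactly this model difference — which is why the
package carries both rather than privileging one.

The square-root estimator is biased for small samples and undefined
uncertainty at *p* = 1; the Zhivotovsky Bayesian estimator for dominant data
is out of scope.

## Marker informativeness

Per primer, over its scored bands (pooled band frequencies *p*):

* PIC per locus = 1 − *p*² − (1 − *p*)² = 2*p*(1 − *p*), maximum 0.5 for a
  two-state marker; the primer PIC is the unweighted mean over **all** scored
  bands (monomorphic bands contribute 0, keeping means comparable across
  primers with different polymorphism rates).
* Band informativeness I<sub>b</sub> = 1 − 2|0.5 − *p*|, resolving power
  RP = Σ I<sub>b</sub> over the primer's bands, MRP = RP/PB.
* Marker index MI = PIC × EMR. The effective multiplex ratio is taken as the
  polymorphic-band count PB: this is the definition under which the identity
  MI/PIC = PB holds exactly for every primer, and it reproduces published
  per-primer MI values computed from their printed PIC and PB
  (e.g. 0.42 × 19 = 7.98 → 8.0), which PB²/SB does not.
* Shannon H′ per locus = −[*p* ln *p* + (1 − *p*) ln(1 − *p*)] with
  0·ln 0 := 0, natural logarithm throughout; the primer value is the mean
  over its loci.

`primer_table()` adds an Average row (column means) and Pearson correlations
between the MI–PIC and PIC–RP columns via `cor.test`. Both *r* and *r*²
are reported: published primer tables sometimes print the correlation
coefficient under an *r*² label, so having both avoids guessing. The
algebraic bound 2*p*(1 − *p*) ≤ 1 − 2|0.5 − *p*| (PIC never exceeds
I<sub>b</sub>) is asserted on a grid in the test suite.

A locus is polymorphic iff 0 < *p* < 1 (strict criterion). No 95% rule is
applied by default because gel-scored ISSR panels conventionally count every
non-fixed band; `poly_criterion = 0.95` switches to the commoner-state
threshold when comparison with SNP-style conventions is wanted.

## Within-population diversity

With state frequencies (*f*₁, *f*₂) per locus under the chosen model:
N<sub>a</sub> counts states with *f* > 0; N<sub>e</sub> = 1/Σ*f*²;
I = −Σ*f* ln *f*; H<sub>e</sub> = 1 − Σ*f*²;
uH<sub>e</sub> = H<sub>e</sub>·2N/(2N − 1). All are unweighted means over
loci, **including** loci monomorphic within the population — dropping them
would inflate every mean and is detectably inconsistent with published
tables whose diversity means fall below 0.3. The 2N/(2N − 1) correction (not
N/(N − 1)) is the one that reproduces published H<sub>e</sub>→uH<sub>e</sub>
pairs such as 0.258→0.264 at N = 20, and the ratio identity
uH<sub>e</sub>/H<sub>e</sub> = 2N/(2N − 1) is asserted on every dataset in
the tests. `%P` uses the strict within-population criterion.

## AMOVA

The squared-distance input is the band-mismatch count between profiles (the
squared Euclidean distance on 0/1 data, the Arlequin convention for
RFLP/AFLP-type data). With missing scores, the mismatch count over loci
scored in both samples is rescaled by n<sub>loci</sub>/n<sub>shared</sub>,
which leaves complete data untouched.

The one-level decomposition follows Excoffier: SS<sub>total</sub> =
(1/N)Σ<sub>i<j</sub>d(i,j); SS<sub>within</sub> = Σ<sub>k</sub>(1/n<sub>k</sub>)
Σ<sub>i<j∈k</sub>d(i,j); df = (K − 1, N − K); σ²<sub>b</sub> =
SS<sub>within</sub>/df<sub>within</sub>; σ²<sub>a</sub> =
(SS<sub>among</sub>/df<sub>among</sub> − σ²<sub>b</sub>)/n₀ with
n₀ = (N − Σn<sub>k</sub>²/N)/(K − 1); Φ<sub>ST</sub> =
σ²<sub>a</sub>/(σ²<sub>a</sub> + σ²<sub>b</sub>). The permutation test
reassigns individuals to populations with sizes held fixed; the observed
statistic is counted in the tail, so the smallest attainable p is
1/(n<sub>perm</sub> + 1) — a printed "P = 0.000" is representable only as
p < 10⁻³ at the default 10100 permutations. Negative among-population
variance components are reported as-is (Φ<sub>ST</sub> may be negative) and
flagged; `clamp_negative = TRUE` zeroes them instead. A 4-sample
hand-worked decomposition (Φ<sub>ST</sub> = 1/3 exactly) and exhaustive
enumeration of all label assignments on 6 samples serve as oracles in the
tests.

`pairwise_fst()` runs the two-population AMOVA per pair; a two-population
`amova()` call and the corresponding pairwise entry are asserted equal.

## Differentiation and distance

Per locus, *h*<sub>k</sub> = 1 − Σ*f*² within population *k*; H<sub>S</sub>
averages over populations then loci with **equal population weights** (the
POPGene convention; `weighted = TRUE` uses census weights), and
H<sub>T</sub> = 1 − Σ*f̄*² on the equally-weighted mean frequencies. Then
G<sub>ST</sub> = (H<sub>T</sub> − H<sub>S</sub>)/H<sub>T</sub>, Hedrick's
G′<sub>ST</sub> = G<sub>ST</sub>(K − 1 + H<sub>S</sub>)/[(K − 1)(1 − H<sub>S</sub>)],
and Jost's D = [(H<sub>T</sub> − H<sub>S</sub>)/(1 − H<sub>S</sub>)]·K/(K − 1).
G′<sub>ST</sub> ≥ G<sub>ST</sub> always; D is not ordered against
G<sub>ST</sub> in general. All-monomorphic input (H<sub>T</sub> = 0) is an
error rather than a silent 0/0.

Gene flow uses the island-model inversion N<sub>M</sub> =
(1/F<sub>ST</sub> − 1)/4, applied to the AMOVA Φ<sub>ST</sub> (the pairing
used in published abstracts, e.g. F<sub>ST</sub> = 0.221 → N<sub>M</sub> =
0.881); F<sub>ST</sub> ≤ 0 yields `NA` with a warning. Nei's distance is
the 1972 standard distance D<sub>s</sub> = −ln I on the model's state
frequencies (the 1978 small-sample correction is not implemented; the
binary pipelines this package mirrors do not document using it). Slatkin's
linearization F<sub>ST</sub>/(1 − F<sub>ST</sub>) maps 1 to `NA`.

## Ordination and isolation by distance

`pcoa()` double-centers B = −½ J A J and eigendecomposes. Two dialects are
deliberately carried:

* `gower_squared` (default): A = D∘D, the classical Torgerson/Gower PCoA —
  correct when D is a metric distance; cross-checked against `cmdscale` in
  the tests.
* `gower_raw`: A = D itself. Population-genetic software applies this form
  when ordinating fixation-index matrices, which are already on a squared
  (variance-ratio) scale; it is the dialect that reproduces published axis
  percentages for a 6×6 pairwise-F<sub>ST</sub> matrix (43.6/26.7/15.1),
  while the squared dialect gives a very different spectrum (65.8/24.3/7.7).
  Reports produced by `run_all()` therefore use `gower_raw`.

Axis percentages are eigenvalue shares of the positive-eigenvalue total;
negative eigenvalues (common for non-Euclidean inputs) are excluded from the
denominator and never yield coordinates.

Geographic distances are haversine great-circle distances between population
centroids (arithmetic means of per-sample WGS84 coordinates, no projection),
Earth radius 6371.0088 km, via `geosphere`. The Mantel statistic is the
Pearson correlation of upper triangles; p is one-tailed (upper) from jointly
permuting rows and columns of the second matrix, observed included. The
genetic input for isolation-by-distance reports is the Slatkin-linearized
pairwise Φ<sub>ST</sub>, at the population level (a 6×6 problem in the
emulated survey); with K populations there are only K! distinct
relabellings, so permutation p values are coarse at small K and the test
warns below K = 4.

## Admixture model

`fit_admixture()` implements the STRUCTURE-style admixture model on binary
bands coded as haploid observations — the common convention for dominant
data, and the one that keeps every conditional conjugate:

* Z<sub>il</sub> | q<sub>i</sub> ~ Categorical(q<sub>i</sub>);
  X<sub>il</sub> | Z<sub>il</sub> = k ~ Bernoulli(F<sub>kl</sub>)
* F<sub>kl</sub> ~ Beta(λ₁, λ₂) (default 1,1);
  q<sub>i</sub> ~ Dirichlet(α) (default α = 1)

The Gibbs sweep (latent origins, then F, then q; Rcpp, R's RNG, so a seed
gives bit-identical output) records the marginal log-likelihood
Σ log Σ<sub>k</sub> q<sub>ik</sub>P(x|F<sub>kl</sub>) each iteration, and
the evidence is summarised as lnP = mean(lnL) − var(lnL)/2. Two properties
of this estimator matter in practice: it is **not** an unbiased estimate of
ln P(X|K) (it sits a few percent low, the more so the smaller the dataset),
but at K = 1 its exact expectation has a digamma/trigamma closed form
because the sampler then draws F from the true posterior — that closed form
is the oracle the test suite asserts against, with the true Beta-Bernoulli
marginal kept as a neighbourhood check. Evanno's ΔK consumes only
differences and across-run spreads of lnP, so the bias largely cancels.

Model-choice deviations worth knowing: the "correlated allele frequencies"
F-model prior is simplified to independent Beta priors per cluster
(affecting prior shrinkage only), and α is fixed by default with an optional
random-walk Metropolis update (`sample_alpha = TRUE`, Uniform(0,10) prior).
Cluster labels are not identifiable; comparisons in the tests align labels
by the best permutation before scoring. Defaults (burn-in 1000, 100000
replications, 10 runs per K over K = 1..10) mirror common survey practice;
the test suite runs reduced lengths (burn-in 100–200, 300–800 replications,
2 runs per K over K = 1..5), which the recovery experiments show are ample
for well-separated clusters.

`evanno()` computes L′(K), |L″(K)| (mean over runs of the absolute per-run
second difference), and ΔK = |L″(K)|/sd(lnP(K)); interior K only, `NA` with
a warning where the across-run sd is zero.

## The simulator and what passing tests mean

`simulate_markers()` draws per-population band frequencies around a uniform
ancestral frequency under the Balding–Nichols model
p<sub>kl</sub> ~ Beta(p(1−F)/F, (1−p)(1−F)/F) — variance F·p(1−p) — and
emits bands directly (haploid) or through a dominant diploid locus
(1 − (1 − p)², so the √ estimators can be validated against a model where
they are correct). Optional features: a row-stochastic admixture matrix
mixing source populations per emitted sample, a count of fixed
(band-in-everyone) loci emulating the invariant bands of real primer
panels, GPS centroids with isotropic km-scale scatter, and a missing-cell
rate. The truth record carries ancestral and realized frequencies,
emission probabilities, and the parametric differentiation of the realized
frequencies (size-weighted among-variance over total), which is the
quantity the AMOVA estimator targets.

`haloxylon_preset()` fixes the design of the emulated survey: 6 populations
of 20/20/20/25/10/13 samples, 195 loci on 16 primers with the survey's
per-primer band counts, 28 fixed loci (≈86% polymorphic), F = 0.25
(realized Φ<sub>ST</sub> ≈ 0.22–0.28 on emitted matrices), centroids
spanning roughly 100 km. Calibration over 20 seeds puts PPB in 84–86% and
estimated Φ<sub>ST</sub> in 0.23–0.28.

What the generator does **not** emulate: linkage between bands of one
primer (loci are independent), scoring error and band co-migration,
spatially autocorrelated frequencies (all populations are exchangeable
given F — a uniform per-population F gradient changes drift magnitude, not
spatial structure, and demonstrably produces no isolation-by-distance
signal; the IBD validation therefore uses a neighbour-mixing admixture
gradient along a line of centroids), and any mutation process. Passing
tests therefore demonstrate estimator correctness under the F-model, not
robustness to gel-scoring artefacts.

## Numerical conventions

* Natural logs everywhere; 0·ln 0 := 0.
* Permutation p values always include the observed statistic: p ∈ (0, 1].
* Cluster band frequencies are clamped to [10⁻¹², 1 − 10⁻¹²] inside the
  sampler to keep the likelihood finite.
* PCoA treats eigenvalues above max|λ|·10⁻¹⁰ as positive.
* Reports round statistics to 3 decimals and percentages to 1; computations
  are never rounded internally.
* Master seed → stage seeds by fixed offsets (+1 AMOVA, +2 pairwise,
  +3 Mantel, +1000 admixture; per-run seeds increment from there), recorded
  in the run manifest. All seeds stay below 2³¹.

## Interfaces

Plain TSV (`sample`, `pop`, loci columns; optional `#primer` row; `NA`
missing), the GenAlEx binary-CSV dialect (metadata header cross-checked
against content on read), and STRUCTURE haploid export (−9 missing) are
supported through `read_marker_matrix()`/`write_marker_matrix()`/
`write_structure()`. `run_all()` writes the full TSV report bundle plus a
JSON manifest; the exported stage functions are the intended programmatic
interface.

## Known limitations

Single-level AMOVA only (no among-group hierarchy); no bootstrap CIs on
differentiation indices; no Bayesian dominant-frequency estimation; Nei
1972 (not 1978) distance; the admixture sampler has no CLUMPP-style
multi-run Q averaging. For very small K, Mantel and permutation p values
are coarse by construction.
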