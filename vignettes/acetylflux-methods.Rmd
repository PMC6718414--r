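---
title: "Models and methods behind acetylflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind acetylflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acetylflux)
```

acetylflux converts four kinds of quantitative measurements — paired
light/heavy fragment-ion areas, 4-plex reporter-ion PSM intensities,
¹³C isotopologue intensities, and oxygen-consumption traces — into
site-level acetylation occupancies, differential protein abundances,
pathway enrichments, labeled-carbon fractions, and a fatty-acid-oxidation
capacity. This vignette explains the underlying models, the parameters
that matter, the numerical decisions, and what the synthetic cohort does
and does not establish.

## Stoichiometry of lysine acetylation

The experimental design behind the stoichiometry model chemically
acetylates every unmodified lysine with a deuterated (d3-acetyl)
reagent, so that each copy of a site carries either the endogenous light
acetyl or the chemical heavy acetyl and the two species differ by
3.0188 Da per site (three ²H-for-¹H substitutions; the constant is
computed from monoisotopic masses, `heavy_pair_mass_shift()`). Occupancy
is the light share of the total:

$$\theta = \frac{L}{L + H^\*}, \qquad
  H^\* = \max\!\left(0,\; H - L\,\frac{a_3}{a_0}\right),$$

where $a_3/a_0$ is the M+3 : M+0 abundance ratio of the light species'
theoretical isotope envelope. The correction exists because the light
peptide's natural M+3 isotopologue (mostly ¹³C₃, plus ³⁴S + ¹³C
combinations) is co-measured with the heavy peak; without it, occupancy
estimates are biased low, most visibly for large peptides and high
occupancies. The model assumes:

* the envelope of the light species is predictable from its elemental
  composition (no unresolved co-eluting interference);
* the heavy-label deuteriums are isotopically pure — no back-exchange
  model is applied;
* a fragment is attributable to exactly one lysine site. Multi-site
  fragments are outside the model and the generator never emits them.

Envelopes are computed by truncated multinomial convolution of
per-element natural-abundance distributions (binomial shortcut for the
two-isotope elements C, H, N; +1/+2 convolution for O and S). The
abundance table (`isotope_abundances()`: ¹³C 0.0107, ²H 0.000115,
¹⁵N 0.00364, ¹⁷O 0.00038, ¹⁸O 0.00205, ³³S 0.0075, ³⁴S 0.0421) is a
single overridable constant table. Convolution uses exponentiation by
squaring, so cost grows with `log(atom count)`, and abundances are left
unnormalised: truncation at `n_peaks` discards only mass above the
window, so the retained entries are exact.

Peptide context comes from an in-silico digestion engine: trypsin cleaves
C-terminal of K/R, GluC C-terminal of E, with up to five missed cleavages
by default. Three conventions are configurable because the field varies
on them:

* **Proline suppression** (trypsin does not cut before P) is on by
  default — the standard convention.
* **GluC specificity** defaults to E only; in ammonium-bicarbonate
  buffers GluC also cleaves after D, so `gluc_cleaves_d = TRUE` enables
  that mode. Nothing in the data model depends on the choice.
* **Acetyl blocking**: a lysine carrying either acetyl mark is not a
  trypsin substrate (`acetyl_blocks_trypsin = TRUE`). In a chemically
  per-acetylated sample essentially every K is blocked, which is why
  GluC is needed at all; blocking is applied for both marks because the
  enzyme cannot distinguish them.

Coordinates are 1-based inclusive throughout, matching K123-style site
names.

### Fragment aggregation and testing

Fragments are aggregated to a site × animal record by the **median**
(mean available via `aggregate = "mean"`): with ~6 fragments per site a
single mis-integrated transition should not move the site value. Records
below `min_fragments` (default 1) are dropped and logged in the fit
object. Each site is then tested across genotype groups by one-way
fixed-effects ANOVA on the per-animal records (n = 4 per group in the
emulated design); with two groups this is exactly the squared
pooled-variance t-test, which the test suite verifies. The reported
effect, `percent_change`, is the **percentage-point difference** of
group means (×100), not a relative percent — percentage points are what
a [−100, 100] occupancy axis displays, and relative change explodes for
low-occupancy sites. Degenerate inputs: a site with zero variance in
every record gets p = 1 (no evidence), and a group with fewer than two
records excludes the site with a log entry. Significance is p < 0.05
everywhere the pipeline filters; α is a parameter but 0.05 is the design
default.

Negative corrected heavy areas (noise larger than the leakage estimate)
are clamped to zero and counted (`n_clamped` on the fit); pairs with
zero total area are undefined and dropped with a logged reason.

## Two-batch isobaric differential proteome

Each batch is a 4-plex with two mutant and two control channels. The
chain is: keep only PSMs with all four reporter channels positive; sum
unique-PSM intensities per protein and channel (razor/shared peptide
assignment is out of scope — the generator emits unique assignments
only); form `log2 FC = log2(mean MUT / mean WT)`; test per protein with
a variance-gated t-test on the per-channel protein values. The gate is a
two-sided F-test of variance equality at α = 0.05: not rejected →
pooled-variance Student test, rejected → Welch test. With n = 2 per
group the t-test is at the edge of validity (1–2 degrees of freedom);
this is a faithful rendering of the biological-duplicate design rather
than a recommendation, and the Monte-Carlo calibration in the test suite
confirms the type-I error is still near nominal. The two batch p-values
are combined by Fisher's method ($X = -2\sum\ln p_i$ against
$\chi^2_{2k}$; zero p-values are clamped to the smallest positive
double), and batch fold changes are averaged on the log2 scale. t-tests
are two-sided by default (`alternative` is exposed for one-tailed
designs). No cross-channel normalization is applied before ratio
formation; ratios are scale-invariant per batch, which the suite checks,
and any further normalization is the caller's decision.

## Enrichment, localization, overlap, clustering

Over-representation uses the hypergeometric **upper** tail
$P(X \ge k)$ — strictly over-representation, not depletion — with gene
sets restricted to the universe and filtered to 5–500 members, and
Benjamini–Hochberg adjustment at FDR 0.05. The universe is by default
the identifiers in the caller's annotation (`universe`); an explicit
`universe_size` reproduces the convention where N is the full
protein-coding gene count. Both modes exist because reference tools
differ and the choice changes p-values materially; the default is the
conservative, data-driven one.

Subcellular binning maps primary annotation terms into four bins —
secretory (endoplasmic reticulum, Golgi, proteasome, lysosome,
extracellular, secreted), mitochondria, nucleus (including chromosome),
cytoplasm (cytoskeleton, cytosol, ribosomes) — with unmatched terms
falling to cytoplasm as the all-other-organelles catch-all, with a
warning. The dictionary ships as data
(`extdata/localization_bins.tsv`), not code, so it can be extended
without touching the package.

Cross-model structure: signed per-site changes from the two genotype
fits are intersected; shared sites with equal signs are concordant,
opposite signs discordant; zero changes are excluded (they carry no
direction). Distribution comparisons use the two-sample
Kolmogorov–Smirnov test with the asymptotic p-value (the common package
default; `exact = TRUE` is available for small samples). Heat-map row
ordering is complete-linkage agglomerative clustering on Euclidean
distances; missing values are imputed as 0 with a warning (a log2 FC of
0 is the neutral value), ties resolve deterministically by input row
order, and the dendrogram can be written as Newick.

## Tracer correction and FAO capacity

For a metabolite with $n$ skeleton carbons, natural ¹³C spreads a
molecule with $j$ tracer-labeled carbons upward in mass:
$M_{ij} = \binom{n-j}{i-j} p^{\,i-j} (1-p)^{\,n-i}$ for $i \ge j$, with
$p = 0.0107$ by default. Columns sum to 1 (probability conservation,
tested to 1e−12). The observed vector is inverted by non-negative least
squares (`pracma::lsqnonneg`) rather than naive triangular solve: the
matrix is well conditioned for $p < 1$, but with measurement noise an
unconstrained solve can return small negative pools, and the
non-negativity constraint is the physically meaningful estimator. The
solution is rescaled to the observed total. The default corrects over
the carbon skeleton only; `correction_matrix_formula()` corrects over a
full molecular formula for derivatized species (TMS/MOX derivatives add
natural-abundance carbons), since conventions differ between tools —
both modes are exposed and the skeleton mode is the default. Batch
correction (e.g. empirical-Bayes methods) is deliberately out of scope;
the pipeline accepts pre-corrected intensities.

Fractional labeling is the mean labeled-carbon share
$\sum_i i\,x_i / (n \sum_i x_i)$ plus the labeled pool $\sum_{i\ge1}x_i$.

FAO capacity from the fuel-flex assay is
$1 - (\mathrm{OCR_{base}} - \mathrm{OCR_{UK/BPTES}})/(\mathrm{OCR_{base}} -
\mathrm{OCR_{all}})$: the fraction of inhibitor-sensitive respiration
that survives blocking glucose (UK5099) and glutamine (BPTES) oxidation
and is only removed once fatty-acid oxidation is inhibited too
(etomoxir). The value lies in [0, 1] whenever the phase plateaus are
ordered `all ≤ UK/BPTES ≤ baseline`; violations are **reported, not
clipped**, because an out-of-range capacity flags a failed assay, and a
baseline equal to the fully-inhibited rate is an error, not a zero.
Phase plateaus are cycle means per sample.

## What the synthetic cohort emulates — and what it does not

`cohort_config()` defaults are the emulated study conditions: 4 animals
per genotype group; 600 acetyl sites on 300 proteins with baseline
occupancies Uniform(0.01, 0.99); stoichiometry shift magnitudes
|N(0.15, 0.05)| with signs arranged so that sites shifted in *both*
genotypes are opposite-signed with probability 0.95 (hyperacetylation in
the haploinsufficient-like model, hypoacetylation in the
overexpressing-like model); 10 % of sites shifted in both genotypes and
20 % in each single genotype; 10 % of proteins with |log2 FC| ~
N(1, 0.25); 6 fragments per site with 10 % CV lognormal multiplicative
noise and envelope leakage on; 3 unique PSMs per protein per batch with
10 % CV and a 5 % zero-channel rate; 1 % CV isotopologue noise; and
TCA-metabolite labeled fractions and group FAO capacities (0.30 / 0.45 /
0.60) chosen as plausible hepatocyte values. Every stage derives an
independent substream from the single seed, so stages can be regenerated
in isolation and outputs are bit-identical for identical (config, seed).
These sizes keep full-cohort generation plus analysis in the
tens-of-seconds range on one core, which is also the problem size used
throughout the test suite.

Features of real data the generator deliberately lacks — so passing
tests bound algorithmic correctness, not real-data performance:

* **Partial detection overlap.** Every site is measured in both
  genotype cohorts. In real paired studies the two models' detected-site
  lists overlap only partially, which makes the shared-significant set
  both smaller and purer. Consequence: in the simulation, singly-shifted
  sites that cross α = 0.05 in the other genotype by chance enter the
  shared set with a random sign and dilute the discordant fraction from
  the true 0.95 to roughly 0.88 — the end-to-end check therefore applies
  a binomial tolerance around the 0.9 headline at the realized shared
  count.
* No missingness-not-at-random, no chromatographic or m/z-domain
  artifacts, no interference/co-isolation in reporter channels, no
  razor-peptide ambiguity, no site-localization uncertainty.
* Noise is purely multiplicative lognormal; real peak areas also carry
  additive background at the low end.

## Numerical conventions in one place

* Envelope truncation window: `shift_index + 1` peaks (4 for one heavy
  acetyl); untruncated envelopes sum to 1 within 1e−9 in tests.
* Corrected heavy areas: clamped at 0, clamps counted.
* Zero-variance test inputs: ANOVA p = 1; gated t-test p = 1 (equal
  means) or 0 (unequal); Fisher clamps p = 0 inputs to
  `.Machine$double.xmin`.
* BH adjustment: standard step-up, monotone, capped at 1.
* NNLS inversion rescaled to observed totals; exact round trip to 1e−9
  noiseless.
* Clustering ties: deterministic by input row order.
* All randomness flows from one integer seed through fixed per-stage
  offsets (`seed × 1009 + stage`, mod 2³¹ − 1).
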