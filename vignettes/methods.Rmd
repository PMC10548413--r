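---
title: "Models and methods behind climadapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind climadapt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

climadapt analyses local climate adaptation in structured plant
populations from three directions — neutral population structure,
selection scans, and forward-looking genomic offset — and ships a
synthetic-data generator that makes the whole chain testable without
external downloads. This vignette records the models, the parameters
that matter, and the design choices made where the design was genuinely
open. It states no empirical result that the package's tests and
`scripts/acceptance.R` do not themselves compute.

## The synthetic study system

The generator emulates the processed products of a reduced-
representation sequencing study of 13 wild kiwifruit populations:
`landscape_spec()` defaults to 13 populations of 12 diploids placed at
the study's sampling coordinates (`kiwifruit_sites()`), five WorldClim
bioclimatic variables (BIO2 mean diurnal range, BIO4 temperature
seasonality, BIO8 mean temperature of the wettest quarter, BIO16/BIO19
precipitation of the wettest/coldest quarter), 5,000 neutral and 50
climate-clinal loci, and a global differentiation target of 0.193.

*Climate* is a linear function of centred longitude and latitude plus
Gaussian site noise; slopes and noise scales are fixed at values typical
of subtropical China (e.g. BIO16 ≈ 650 mm ± 30, +25 mm per degree of
longitude). Future scenarios add nested multiples (1×, 2×, 3×) of one
RCP-like displacement per variable — warmer, more seasonal, drier — so
scenario severity is ordered by construction, which is what the offset
monotonicity checks exercise.

*Neutral loci* draw an ancestral frequency p ~ U(0.05, 0.95) and
per-population frequencies from the Balding–Nichols Beta
(p(1−F)/F, (1−p)(1−F)/F) at F = `fst_target`; genotypes are
Binomial(2, freq) per individual. This island-model approximation,
rather than an explicit coalescent, is deliberate: it is desk-scale and
reproduces exactly the F_ST–heterozygosity relationship the outlier
scan conditions on, so the generator and the scan's null are two
implementations of the same law — which the calibration tests exploit.

*Adaptive loci* take Balding–Nichols draws around a logistic clinal
mean, logit⁻¹(a + s·z), where z is the standardized driver variable
(default BIO16) and s = `cline_strength` (default 2 per SD). Drift
around the cline matters: a deterministic cline would make
`cline_strength = 0` collapse all populations onto one frequency,
whereas with drift it reduces exactly to the neutral law (a property the
test suite checks by Kolmogorov–Smirnov). Clines act on population
frequencies, not individual phenotypes — matching what frequency-based
GEA and gradient forest can actually detect. An optional admixture event
mixes a fraction f of a donor population's frequencies into a recipient,
giving the ABBA-BABA tests a planted positive.

*Methylation* is simulated for one individual per population (the
bsRADseq design): site baselines logit-normal around 30% methylation, a
population random effect with exponential spatial decay of correlation
(half range at the median inter-site distance) of SD `sigma_g`, residual
noise `noise_sd`, negative-binomial depths, and binomial read sampling;
associated sites shift the latent mean by `effect` per SD of the driver.

What the generator does **not** emulate: linkage disequilibrium between
loci, callable-site totals (so π is per-SNP), sequencing error,
reference bias, and non-equilibrium demography (range expansion,
bottlenecks). Passing tests therefore demonstrate correctness of the
estimators and calibration of the decision rules under an island-model
world, not robustness to demographic confounding in real data.

## Diversity and differentiation

Per locus, π uses the unbiased 2p̂q̂·2n/(2n−1); per population, π and
H_O are averaged over loci genotyped in that population, and
F_IS = 1 − ΣH_O/ΣH_E as a ratio of means (stable at low MAF). The
Weir–Cockerham variance components a, b, c are computed per locus from
per-population sample sizes, allele frequencies and heterozygote
fractions, with multilocus θ as the ratio of sums — standard practice,
stated here because mean-of-ratios is also seen in the wild. Populations
with no data at a locus drop out of that locus; a pair's locus is
skipped when either member is empty. The test suite holds the
implementation to a separate scalar transcription of the component
formulas at 10⁻¹⁰ on randomized fixtures including missing data.

PCoA is classical scaling (`cmdscale`): axes with negative eigenvalues
are reported and dropped, and the population-level ordination uses
linearized F_ST/(1−F_ST); entries ≥ 1 clamp to the largest
representable value with a warning, negative estimates pass through
(monotone, so Mantel r is unaffected).

## Mantel machinery

`mantel()` correlates upper-off-diagonal vectors and permutes rows and
columns of the second matrix jointly; p = (1 + #{r* ≥ r})/(1 + n_perm),
one-sided upper tail by default (the ecological convention; a two-sided
flag exists). `partial_mantel()` correlates the residuals of A ~ C and
B ~ C and permutes the **raw** first matrix, not residuals — the
simpler, standard null; documented because the method name alone does
not pin down the scheme. A constant control matrix degrades to the
simple test with a warning. Geographic distance is haversine on radius
6371.0088 km, log-transformed off-diagonals on request, with an explicit
error (suggesting jitter) for coincident sites. Climate variables are
pre-selected greedily to pairwise |r| < 0.8, dropping the member of the
worst pair with the larger mean absolute correlation (ties keep the
earlier column); environmental distance is Euclidean on the first three
standardized principal components.

## ABBA-BABA

With population derived-allele frequencies p1, p2, p3 and the outgroup
ancestral, per-locus weights are abba = (1−p1)p2p3 and
baba = p1(1−p2)p3; D sums these over loci, and the standard error is a
delete-one jackknife over contiguous blocks (default sized for ~20
blocks). Without outgroup data, polarization defaults to
global-minor-allele-as-derived and is recorded on the result — D's sign
then only distinguishes which pair shares drift, which is exactly how
the trio tests are interpreted. `dmin()` reports the arrangement with
minimal |D| (ties keep canonical order), the conservative
topology-agnostic variant. |Z| ≥ 3 is the significance convention.

## The outlier scan

`calibrate_null()` bisects the Balding–Nichols F so that the simulated
trimmed-mean per-locus θ (matched sample sizes, 10,000 loci per
evaluation) matches the observed trimmed mean (5% per tail by default,
so planted outliers do not inflate the neutral target). Each bisection
evaluation reuses the same random stream (common random numbers), making
the simulated mean a deterministic monotone function of F — bisection
then converges cleanly; tolerance 0.005, 30 iterations before a hard
failure with the trace.

`simulate_null()` works at genotype-count level (two nested binomials
reproduce exact Hardy–Weinberg multinomial sampling), which is what
makes million-locus clouds cheap. `fdist_outliers()` bins the null into
20 equal-count He bins (equal-count, not equal-width: stabilizes tail
quantiles), computes an empirical upper-tail probability per observed
locus, flags at p_upper ≤ 1 − confidence (upper tail only — divergent
selection), and attaches Benjamini–Hochberg q-values. One caveat
verified empirically: at 12 diploids per population the per-locus θ
estimator is unbiased but noisy, so even at F → 0 its 99th percentile
is ≈ 0.05; tail behaviour sharpens with sample size, and the
conditioning-on-He design is what keeps the flagging rate calibrated
(the suite checks the 1% rate on matched null data within its binomial
band).

## The mixed model

The association engine is the exact spectral linear mixed model
y = μ + xβ + g + e, Var(g) = Kσ_g², Var(e) = Iσ_e², with kinship
K = ZZᵀ/m from standardized markers (mean-imputed, zero-variance
columns dropped, negative eigenvalues clipped). K is eigendecomposed
once; the variance ratio δ = σ_e²/σ_g² is profiled on a 100-point log
grid over [10⁻⁵, 10⁵] refined by golden-section search, then reused for
every marker (the EMMAX/"P3D" approximation — orders of magnitude
faster, negligible difference at these n), where each marker gets a GLS
Wald t-test on n − 2 degrees of freedom.

One numerical point decided the likelihood form: kinship built from
column-centred markers annihilates the intercept direction (K·1 = 0),
so the full-spectrum ML profile is unbounded as δ → 0 — the mean
absorbs the zero-eigenvalue component exactly while −½log δ diverges —
and a grid-bounded ML estimate collapses to the floor and makes the scan
anti-conservative. δ is therefore profiled by **REML on the
intercept-orthogonal (n−1)-space**, the standard EMMA practice; with
that choice null p-values are uniform (checked by KS at n = 60 across
seeds). p-values are clamped to ≥ the smallest positive double so the
documented invariant p ∈ (0, 1] survives perfect fits at tiny n.

Permutation thresholds permute the response across samples with K fixed
(the scheme is an interpretation, recorded here: the alternative of
permuting markers or refitting kinship is not implemented), draw a
marker subset per repeat, and take the empirical α-quantile of the 200
per-repeat minimum p-values. The orientation follows the study design:
climate is the response, marker state the explanatory variable.

The EWAS front end first calls SMVs: depths below `min_depth` become
missing, then sites with > 10% missingness or < 10% level range are
dropped, in that order, with a per-rule filter log. GEA significance
defaults to BH q ≤ 0.05; EWAS uses the per-variable permutation
thresholds. Hits are annotated against features within 10 kb, boundary
inclusive (a hit exactly 10 kb beyond a feature end is kept; one bp
further is not) — the window is the distance at which linkage
disequilibrium plateaus in data of this kind.

## Gradient forest and genomic offset

Per locus, a regression random forest (bootstrap per tree, ⌈P/3⌉
predictors per split, variance-reduction splits, leaves ≥ 2 samples —
small-n settings chosen because no reference values exist for 13
populations) predicts population allele frequency from climate;
out-of-bag R² is the fit quality. Every split contributes its impurity
decrease to a bin at its split value along the predictor's observed
range (201 uniform bins by default); per locus the binned profile is
normalized and weighted by R², and profiles are averaged over loci with
R² > 0 — averaging, rather than summing, makes the turnover functions
invariant to duplicating loci. Cumulative sums give each predictor's
non-decreasing turnover function, zero at the range minimum. Conditional
importance for correlated predictors (the reference implementation's
`corr.threshold` machinery) is intentionally not implemented — marginal
split importance only — and the model reports raw cumulative importance
without per-predictor renormalization, so high-importance predictors
dominate offsets, as in the reference method.

`transform_climate()` maps points through the turnover functions by
linear interpolation, clamping beyond the fitted range (clamp events
counted — extrapolation is a known failure mode of offset methods).
Local offset is the Euclidean distance between transformed current and
future climate at a site; forward offset minimizes that distance over
all destination sites (staying put included, so forward ≤ local
identically). The forest core is compiled (Rcpp) with its own seeded
generator, so fits are bit-reproducible for a given seed on a given
build.

## Problem sizes and determinism

Default analysis sizes — 5,000 + 50 loci, 13 × 12 samples, 10⁶-locus
null clouds, 200 permutation repeats over 500-marker subsets, 500 trees
per locus — were chosen so each driver and the whole test suite run in
seconds to a few minutes on one CPU; they are package defaults, fully
parameterized through `landscape_spec()` and the function arguments.
All generators are pure functions of (spec, seed); `run_pipeline()`
derives per-stage seeds from a master seed by a fixed affine rule and
records them in its manifest, so identical configs produce identical
outputs.

## Known limitations

Single-level island null (an optional hierarchical refinement would
need per-group F); no LD between simulated loci, so block-jackknife
blocks understate real-data autocorrelation; GEA/EWAS power at 13
populations (and especially 13 methylation samples) is intrinsically
modest, and structure correction absorbs part of any clinal signal —
the planted-recovery tests quantify this trade-off rather than hide it;
offsets are site-level (no raster interpolation) and share the usual
caveat that genomic offset is a mismatch measure, not a demographic
prediction.
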