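# climadapt

Landscape genomics and epigenomics of local climate adaptation, as a
tested R pipeline.

Wild plant populations spread across a heterogeneous climate — here
modelled on wild kiwifruit (*Actinidia eriantha*) sampled at 13 sites
across subtropical China — carry three signals that this package
extracts and connects:

1. **Neutral structure.** Per-population diversity (π, H_O, F_IS),
   global and pairwise Weir–Cockerham differentiation
   θ = Σa / Σ(a + b + c) from the per-locus variance components
   *a* (among populations), *b* (among individuals) and *c* (within
   individuals), PCoA, and Mantel / partial-Mantel tests of isolation
   by distance (linearized F_ST/(1−F_ST) against log great-circle
   distance) and by environment (climate-PC distances, controlling for
   geography). Gene flow between specific populations is tested with
   frequency-weighted ABBA-BABA statistics,
   D = (nABBA − nBABA)/(nABBA + nBABA) with block-jackknife
   Z = D/se(D), and the topology-agnostic minimum-|D| variant.
2. **Selection.** An FDIST-style outlier scan compares each locus's
   θ to a simulated island-model (Balding–Nichols) null conditioned on
   expected heterozygosity, with the null differentiation calibrated to
   the observed trimmed-mean θ; and a kinship-corrected linear mixed
   model y = μ + xβ + g + e with Var(g) = Kσ_g², Var(e) = Iσ_e²
   (exact spectral fit, EMMAX-style fixed δ = σ_e²/σ_g²) scans
   genotype dosages (GEA) and methylation levels (EWAS) against the
   bioclimatic variables BIO2, BIO4, BIO8, BIO16, BIO19, with
   permutation-derived genome-wide thresholds.
3. **Vulnerability.** A gradient-forest turnover model (regression
   random forests per locus; split-impurity binned along each climate
   gradient into cumulative-importance functions) maps climate into
   genomic-composition space, where the **local genomic offset** is the
   Euclidean distance between a site's transformed present and future
   climate, and the **forward offset** (migration load) is the minimum
   such distance over all candidate destination sites.

Because the original study's raw sequencing data are not desk-scale
inputs, the package ships a first-class synthetic-data generator
(`landscape_spec()`, `simulate_landscape()`, `simulate_genotypes()`,
`simulate_methylation()`) that reproduces the data structure those
analyses assume — island-model drift at a target F_ST, logistic
climate clines, spatially structured methylation, planted ground truth
— so every stage is testable end to end.

## Worked example

The numbered drivers under `analysis/` run the whole study on the
default synthetic design and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R     # data + ground truth
Rscript analysis/02_popgen.R      # diversity, F_ST, PCoA
Rscript analysis/03_ibd_ibe.R     # Mantel IBD / partial IBE
Rscript analysis/04_introgression.R
Rscript analysis/05_outliers.R
Rscript analysis/06_gea_ewas.R
Rscript analysis/07_offset.R
```

A run prints, among others:

```
global F_ST = 0.1981 (generator target 0.193)
IBD: r = 0.601, p = 2e-04; partial IBE: r = 0.376, p = 0.0021
planted trio (LiS, LY; YP): D = 0.0631, Z = 7.95  -> gene flow detected
control trios |Z|: 0.2, 0.63, 1.79
calibrated null F = 0.2005 in 7 bisection steps
GEA hits per variable: BIO2=50, BIO4=0, BIO8=19, BIO16=50, BIO19=50
power on planted BIO16-clinal loci: 98%
12 EWAS hits; planted-site recovery 80%
predictor importance ranking: BIO19 > BIO16 > BIO2 > BIO8 > BIO4
per-site offsets monotone across RCP4.5 < RCP6.0 < RCP8.5: 100% of sites
```

Reading: realized differentiation matches the generator target; genetic
distance increases with geographic distance (IBD); the planted
gene-flow trio — and only it — exceeds |Z| ≥ 3; the mixed-model GEA
recovers nearly all planted clinal loci with BH-controlled false
positives; precipitation variables dominate the turnover model (the
clines were planted on BIO16, and BIO19 is spatially correlated with
it); and genomic offset grows monotonically with emission severity at
every site.

In code, the core loop is three calls:

```r
library(climadapt)
spec <- landscape_spec(seed = 1)            # 13 pops x 12, F_ST 0.193
land <- simulate_landscape(spec)
sim  <- simulate_genotypes(spec, land$popmap, land$current)
wc_fst(sim$genotypes, land$popmap)$global_theta
#> [1] 0.1966
```

Real data enter through `read_vcf()` (biallelic SNPs, missing-rate <
20%, MAF > 0.01, heterozygosity ≤ 0.5 filters, in that order),
`read_popmap()`, `read_climate()`, `read_methylation()` and
`read_features()`; `run_pipeline(config)` orchestrates all stages with
per-stage seeds and a reproducibility manifest.

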