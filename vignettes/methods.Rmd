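---
title: "Joint-spectrum demographic inference for a three-lineage divergence: models, engine and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint-spectrum demographic inference: models, engine and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfsinfer)
```

## The inference problem

`sfsinfer` estimates the demographic history of three recently diverged
desert-tortoise lineages — Mojave (*Gopherus agassizii*), Sonoran and
Sinaloan (*G. morafkai*) — from the folded joint allele-frequency spectrum
(AFS) of synonymous transcriptome variants genotyped in two diploids per
lineage. The central scientific questions are (i) whether divergence
occurred with or without gene flow, and (ii) the relative sizes and split
times of the three populations.

The data enter as a per-site table of biallelic genotypes with contig
identifiers, Phred site qualities and functional annotations. Only sites
that pass a quality threshold (default Phred 20), are genotyped in all six
individuals and are unambiguously synonymous are used: AFS inference is
sensitive to genotyping error and to direct selection, and synonymous
sites are the standard compromise for transcriptome data. Because the
ancestral allele is unknown, all likelihood work uses the folded
(minor-allele) spectrum; unfolded spectra exist in the package for testing
only. With four chromosomes per population, the data structure is a masked
5×5×5 array whose two fixed corners (no minor allele anywhere, or all
chromosomes derived) carry no information and stay masked.

## Demographic models

All models live in coalescent units scaled by the ancestral effective size
`Na`: population sizes `nu = N/Na`, epoch durations `T` in units of `2 Na`
generations (measured backward from the present), and migration rates
`M = 2 Na m`, where `m` is the per-generation fraction of the receiving
population replaced by migrants. The mutation scale `theta = 4 Na mu L`
multiplies every expected spectrum; it is profiled analytically at each
likelihood evaluation and never optimised numerically.

The registry (`list_models()`) covers the families needed for the
divergence analysis:

* `split2_noMig(nu1, nu2, T)` — two populations diverging in isolation
  (the allopatric-speciation null);
* `split2_IM(..., M12, M21)` — continuous gene flow throughout divergence
  (parapatric speciation with persistent contact);
* `split2_SC(..., T_c, M12, M21)` — secondary contact: isolation followed
  by migration during only the most recent `T_c` (refugial cycling). The
  contact time is a free parameter, clipped to `T`; with `T_c = T` the
  model reduces exactly to `split2_IM`, with `M = 0` to `split2_noMig`
  (both identities are asserted in the test suite);
* `trio_5param` / `trio_6param` / `trio_6param_IM` — the three-population
  models on the fixed topology ((SIN, SON), MOJ): Mojave splits from the
  common ancestor `T1 + T2` ago, the Sinaloan and Sonoran lineages split
  `T2` ago. Between the splits the Sinaloan/Sonoran ancestral branch has
  size `nu_sinson`, which the contemporary Sinaloan population inherits —
  the minimal parameterisation in which one size parameter covers both
  that internal branch and the Sinaloan tip, consistent with reporting a
  single Sinaloan size. The 6-parameter variant frees the contemporary
  Mojave size; the 5-parameter variant pins it to the ancestral size
  (`nu_moj = 1`). The `_IM` variant adds one symmetric
  Sinaloan–Sonoran migration rate for the gene-flow hypothesis test.

The topology is fixed rather than searched: the pairwise divergence-time
estimates from the two-population stage (and the package's pipeline
report) reproduce the topology evidence, and the species tree from
multilocus analyses independently supports Sinaloan+Sonoran as sisters.

A note on parameter counting: the trio models are conventionally *named*
by a count that includes the implicit `theta` (equivalently the ancestral
size, which physical-unit tables report as a row), so `trio_6param` has
`df = 6` but five optimised shape parameters. The two-population models
are counted by shape parameters only. `model$n_free` is always the
optimiser's dimension; likelihood-ratio degrees of freedom always come
from the number of constrained parameters, so this naming convention never
affects a test.

Default bounds are `nu` in `[1e-3, 1e3]`, `T` in `[0, 10]`, `M` in
`[0, 20]`. Sizes and times are optimised on the log scale (with a floor of
`1e-4` for log-transformed parameters); migration rates stay linear
because their zero boundary is itself a hypothesis of interest.

## The expectation engine

`expected_sfs()` returns, for entry `c`, half the expected total genealogy
branch length (in `2 Na`-generation units) subtending exactly the allele
configuration `c`, so the expected count of sites in cell `c` is `theta`
times the entry. The method is an exact Markov-chain expectation over
ancestral lineage configurations — no diffusion grids and no simulation
noise, which matters because the optimiser and the Godambe machinery both
differentiate the likelihood numerically.

Two regimes are handled differently:

* **Migration-free (tree) demographies.** Within a panmictic epoch the
  ancestral process factorises into the lineage-count death chain (whose
  level occupancies come from a small bidiagonal matrix exponential — at
  most 24×24) and the parameter-free uniform pair-merge jump chain. For
  the jump chain, the probability that a fixed subset of `b` of `j`
  entering lineages forms one block when `k` ancestors remain is given by
  the exchangeable-partition formula, with subset counts per allele
  configuration accumulated by a small dynamic programme. Epoch-exit
  multiset distributions are enumerated once per entering multiset and
  cached; everything parameter-independent (partition weights, subset
  tables, exit distributions, final-epoch contributions) is computed on
  first use and reused, so a warm likelihood evaluation for the trio is a
  few small matrix products (~5–10 ms).
* **Epochs with migration.** The engine enumerates the full
  continuous-time Markov chain over multisets of (deme, descendant-vector)
  lineages (1,431 states for two populations with four chromosomes each),
  and integrates the probability mass together with per-configuration
  occupancy accumulators as one linear ODE (`deSolve`, Runge–Kutta 4/5 by
  default, `rtol = 1e-8`). The generator's sparse structure is cached and
  only rescaled when parameters change.

The engine is validated two ways in the test suite: against closed forms
(the equilibrium `theta/i` spectrum; the hypergeometric redistribution of
a panmictic spectrum at `T = 0`; the strong-migration island limit), and
against `mc_expected_sfs()`, an independent in-package structured-
coalescent simulator that shares only the demography description. The
oracle comparison runs at five random parameter points per registered
model with 10^4 genealogies per point. Two calibration details keep that
comparison statistically meaningful. First, with roughly 4,000 correlated
cell comparisons a strict "every cell within 3 SE" rule fails by chance in
a few cells, so the suite asserts at least 97% of cells within 3 SE and
every cell within 6 SE. Second, the SE denominator is floored at
`sqrt(mu / R)`: allele configurations so rare that they occur a handful of
times (or never) among the `R` genealogies have essentially unestimable
empirical SEs, and the floor is the sampling scale of a mean whose
per-event contribution is a branch length of order one. A genuine engine
error still fails the calibrated test, because its deviation grows in SE
units as the replicate count rises (checked at 3–5×10^4 during
development).

Similarly, the "no gene flow" conclusion on no-migration data is asserted
statistically: the boundary maximum-likelihood estimate of `M` on finite
data scatters near zero rather than landing exactly on it, so the checks
require both a negligible estimate (`2 Na m < 0.5`, far below one migrant
per two generations) and no significant likelihood gain from adding
migration (chi-squared 99% bound on the likelihood-ratio statistic).

## Fitting

The objective is the Poisson composite log-likelihood: independent Poisson
cells with mean `theta * m_c(params)`, summed over unmasked cells, with
`theta` profiled analytically (`optimal_theta()` is the mass ratio). The
Poisson form (rather than the multinomial conditional on the total) is
used because the bootstrap confidence intervals on physical sizes need the
`theta` estimate itself.

`fit_model()` runs `n_starts` local optimisations (default 20), each a
Nelder–Mead simplex refined by bounded L-BFGS-B on the transformed scale,
from starts perturbed log-uniformly by up to a factor of two around the
initial values. Convergence tolerance is ~1e-6 in log-likelihood;
likelihood ties between starts are broken by the smaller L2 distance to
the median start, making results deterministic given the seed. All starts'
endpoints are kept for multimodality diagnostics.

## Uncertainty under linkage

Sites within a contig share one genealogy, so the composite likelihood
overstates information. Two corrections are implemented, both resampling
at the contig level:

* **Conventional bootstrap over contigs** (`bootstrap_by_contig()`):
  contigs drawn with replacement to the original count, spectra rebuilt,
  the model refitted per replicate from the full-data optimum plus three
  perturbed restarts; per-parameter intervals are `mean ± 1.96 sd`
  (`param_ci()`), with `B = 100` by default.
* **Godambe-corrected LRT** (`godambe_adjusted_lrt()`): the raw statistic
  `D = 2 (ll_full − ll_nested)` is rescaled by `df / tr(J H^{-1})`
  evaluated in the constrained directions at the nested optimum, where `H`
  is the negative finite-difference Hessian on the full data and `J` is
  the variance of the bootstrap-replicate score vectors. The scores are
  centred before the outer product: away from the full-model optimum the
  replicate scores share a large nonzero mean (it is exactly the signal
  that drives `D`), and an uncentred outer product would be dominated by
  it, breaking the unlinked-data identity `J ≈ H`. With the centred form
  the adjustment is ~1 for unlinked data and shrinks `D` in proportion to
  the effective within-contig correlation. The adjusted statistic is
  referred to chi-squared with `df` = number of constrained parameters —
  plain `df`, no boundary-mixture correction, even for migration
  parameters tested at zero; the mixture alternative would halve the
  p-value at most and is deliberately not applied so that reported
  p-values stay conservative and comparable (`adjust = FALSE` gives the
  naive test for comparison).

Finite-difference steps are relative (default 1e-2) with the stencil
shifted inward at parameter bounds (with a warning), and one automatic
step shrink before erroring on a non-finite likelihood.

## Physical units

The data contain no absolute mutation-rate information, so the time scale
is anchored externally: the scaled Mojave divergence `T1 + T2` is equated
to 5.9 Ma (the vicariant divergence of the Mojave lineage across the
Colorado River) with a 25-year generation time. Then
`Na = anchor / (2 g T_anchor)`, `muL = theta / (4 Na)`, sizes scale as
`nu Na` and times as `T · 2 Na g`. By construction the converted anchor
divergence is exactly 5.9 Ma for any fit (asserted as an identity in the
tests). Bootstrap replicates are converted differently, exactly because
the anchor is a calibration and not data: `muL` is fixed from the
full-data fit and each replicate's `Na` comes from its own `theta`, so the
anchored divergence *varies* across replicates and its interval brackets,
rather than equals, 5.9 Ma.

## The synthetic-data generator

`simulate_variants()` emulates the statistical structure the analysis
assumes: per contig one structured-coalescent genealogy (full within-
contig linkage — the simplest structure consistent with bootstrapping over
contigs; recombination between contigs is free), Poisson mutation counts
with intensity calibrated so the *retained* synonymous SNP count matches
the configured mean (default 20,126/7,665 ≈ 2.63 per contig across 7,665
contigs), genotypes for two diploids per population (chromosomes paired
into individuals), and configurable fractions of non-synonymous (15%) and
ambiguous (5%) annotations, sub-threshold qualities (5%) and missing
genotypes (2%) so the filters have realistic work to do. Passing
qualities are `20 + Exp(mean 60)` and failing ones uniform on `(2, 20)` —
Phred-like in range; the exact quality distribution only needs to straddle
the threshold. Per-contig SNP counts are Poisson; the real data's
dispersion in SNPs per contig (driven by contig length and expression
variation) is not emulated, and neither are genotyping errors, so passing
tests demonstrate correctness of the inference machinery under the model's
own assumptions, not robustness to annotation or calling errors.

The default generating demography is the published best-fit six-parameter
trio (`tortoise_trio_params()`): ancestral size 336,200; Mojave 128,400,
Sinaloan 149,600, Sonoran 600,000 individuals; splits at 5.9 and 5.65 Ma
(25-year generations). One text/table discrepancy in the source estimates
(600,084 vs 600,000 for the Sonoran size) is resolved in favour of the
tabulated 600,000.

`sample_sfs_poisson()` is the linkage-free counterpart (independent
Poisson draws per cell); the two generators share cellwise expectations
and differ only in dispersion, which is what the bootstrap and Godambe
machinery are about.

## Pipeline and experiment scale

`run_full_inference()` chains the stages: filter → folded 5×5×5 AFS →
two-population fits for every pair (isolation fitted with full
multistarts; gene-flow variants warm-started from it — the H-MS and H-SS
isolation/gene-flow hypothesis pairs are reported per population pair) →
trio fits → Godambe LRT (6- vs 5-parameter) → contig bootstrap on the
winning model → physical units. Every stage seed derives from the single
config seed, and rerunning with identical inputs and config is
byte-identical.

Problem sizes used by the shipped checks were chosen once as a
compromise between statistical resolution and desk-scale runtimes: the
simulate-and-refit experiment runs at full study scale (7,665 contigs,
~20k retained SNPs, 20 multistarts, 100 bootstraps); the generator-vs-
engine moment check uses 12 replicates of 400 contigs; the type-I-error
comparison uses 200 replicates of 120 contigs with 30 bootstrap score
replicates each; oracle validation uses 10^4 genealogies per point. The
null-calibration fits are warm-started single-start optimisations —
adequate for a likelihood-ratio null distribution, where only the
difference of optima matters.

## Known limitations

* Sample sizes are small (4 chromosomes per population); the engine is
  exact at any size but state spaces grow quickly with migration, so the
  CTMC path is practical only for few-chromosome designs like this one.
* The composite likelihood treats sites as independent; linkage enters
  only through the bootstrap and the Godambe correction, not the
  likelihood itself.
* No selection, no recombination within contigs in the expectation
  engine; tri-allelic and indel records are rejected at parsing rather
  than reconciled.
* The secondary-contact model's contact time `T_c` is weakly identified
  when `M` is small; it is exposed as a free parameter with a config pin
  rather than estimated with confidence.
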