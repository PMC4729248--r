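# sfsinfer

Joint site-frequency-spectrum (SFS) demographic inference for a
three-population divergence, built for the desert-tortoise system: the
Mojave (*Gopherus agassizii*), Sonoran and Sinaloan (*G. morafkai*)
lineages, genotyped by RNA-seq at two diploids per lineage.

The package asks the classic speciation question — did these lineages
diverge with or without gene flow? — by fitting demographic models to the
folded joint allele-frequency spectrum of synonymous variants:

* **Spectra.** Filter biallelic SNPs (Phred quality ≥ 20, complete
  genotypes, unambiguously synonymous), and tabulate them into a masked,
  folded 5×5×5 joint SFS; pairwise marginals, Anscombe residuals and the
  flat-file SFS format are included.
* **Models.** Two-population divergence with no migration, continuous
  migration (IM) or secondary contact, and three-population models on the
  fixed ((SIN, SON), MOJ) topology with 5 or 6 conventional parameters
  (the 6th frees the contemporary Mojave size). Parameters are scaled by
  the ancestral size: `nu = N/Na`, `T` in `2 Na` generations,
  `M = 2 Na m`, `theta = 4 Na mu L`.
* **Engine.** Expected spectra by exact coalescent Markov-chain
  expectation (no diffusion grids, no simulation noise), validated
  against closed forms and an independent Monte-Carlo coalescent oracle.
* **Fitting.** Poisson composite likelihood with analytically profiled
  `theta`, multi-start bounded optimisation (simplex + L-BFGS-B on log
  scale).
* **Uncertainty.** Conventional bootstrap over contigs (linkage-aware
  CIs) and a Godambe-information-corrected likelihood-ratio test for
  nested models.
* **Units.** Conversion to individuals and years via the 5.9 Ma Mojave
  divergence anchor and 25-year generation time.
* **Synthetic data.** A linked-site coalescent generator that emulates
  the study's scale (7,665 contigs, ~20,126 retained synonymous SNPs), so
  the whole pipeline is testable without any downloads.

## Worked example

Simulate a small transcriptome-like dataset under the published best-fit
demography, build the folded spectrum and refit the six-parameter model:

```r
library(sfsinfer)

cfg <- sim_config(n_contigs = 800, seed = 11)
vt  <- simulate_variants(cfg)
flt <- filter_variants(vt)          # quality >= 20, complete, synonymous
#> filter_variants: retained 2072 of 2783 records (quality >= 20, complete genotypes, synonymous only)

afs <- build_joint_sfs(flt, c("MOJ", "SON", "SIN"), fold = TRUE)
afs
#> joint_sfs: folded spectrum, shape (5 x 5 x 5), pops [MOJ, SON, SIN]
#>   unmasked mass: 2072 over 62 cells (63 masked)

fit <- fit_model(afs, "trio_6param", n_starts = 4, seed = 3)
fit
#> fit_result: model trio_6param, composite log-likelihood -196.5509, theta 526.4
#>    nu_moj nu_sinson    nu_son        T1        T2
#>  0.390661  0.450124  1.700927  0.009966  0.357317
```

The generating values were `nu_moj = 0.382`, `nu_sinson = 0.445`,
`nu_son = 1.785`, `T1 = 0.0149`, `T2 = 0.336`: with ~2,000 SNPs the fit
recovers sizes to a few percent and the recent Sinaloan/Sonoran split time
`T2` well; the short internal branch `T1` is the hardest parameter at this
scale. `calibrate_physical(fit$params, fit$theta, "trio_6param")` converts
the fit to individuals and years (the Mojave divergence is anchored at
5.9 Ma by construction); `run_full_inference()` chains everything —
pairwise gene-flow tests, trio model ranking, corrected LRT, bootstrap
CIs — into one reproducible report.

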