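# montgen

Population-genomic inference of divergence between montane populations
separated by dispersal barriers — the comparative setting of tropical
"sky-island" birds, where populations of the same species occupy different
mountain ranges (or different islands) and the questions are how strongly
they are differentiated, how long ago they split, and how much gene flow
still connects them.

The package implements the full analysis chain on called SNP genotypes:

* **Site filtering** of multi-sample VCFs (depth in [10, 100], QUAL ≥ 20,
  indel proximity, biallelic and complete genotypes).
* **Kinship screening** with the KING-robust estimator
  φ̂ = (N_Aa,Aa − 2 N_AA,aa) / (N_Aa(i) + N_Aa(j)) and greedy exclusion of
  pairs above φ = 0.06 (half-sibs ≈ 0.125, duplicates ≈ 0.5).
* **Population structure**: LD pruning (window 100 variants, step 5,
  r² > 0.5), Weir–Cockerham FST as the ratio of summed variance components
  θ̂ = Σa / Σ(a+b+c) (with elevation-stratum contrasts), genotype PCA, and
  maximum-likelihood admixture proportions whose replicate fits feed the
  Evanno ΔK choice of cluster number.
* **Demographic inference**: 1–3 population joint site-frequency spectra
  (folded by default, fastsimcoal2-style `.obs` I/O), expected spectra by
  structured-coalescent simulation (branch-length weighting, common random
  numbers), the composite multinomial likelihood lnCL = Σ m_i ln p_i, a
  ten-model isolation-with-migration catalogue fitted by multi-start
  bounded optimization, AIC selection, parametric-bootstrap intervals, and
  derived quantities: divergence time in years (T × generation time) and
  effective migrants per generation (Nm = Ne_source × M).
* **Elevation regression**: Spearman rank correlation between per-species
  FST and altitudinal floor with exact-permutation p-values at n ≤ 10.
* **A coalescent synthetic-data generator** (independent non-recombining
  loci, planted half-sib pairs, sequencing-noise models, an
  elevation-to-migration covariate panel) so the whole pipeline is testable
  at desk scale without resequencing data.

## A worked example

Simulate two populations that split 100,000 generations ago with asymmetric
gene flow, run the structure statistics, and fit two competing demographic
models:

```r
library(montgen)

truth <- im_model(ne1 = 5e4, ne2 = 2e4, ne_anc = 4e4, t_div = 1e5,
                  m12 = 5e-5, m21 = 1e-5)
sim <- simulate_dataset(simulation_config(
  truth, samples_per_pop = c(10, 10), callable_length = 1e7, seed = 101,
  mutation_mode = "poisson", n_loci = 5000))

filtered <- filter_sites(sim$geno)
wc_fst(filtered$geno)
#> <mg_fst> pop1 vs pop2: multilocus theta = 0.1254 (28085 sites used, 0 excluded)

kin <- kinship_matrix(filtered$geno)
flag_related(kin)          # character(0): no planted relatives here

obs <- joint_sfs(filtered$geno, folded = TRUE, callable_length = 1e7)
obs
#> <mg_sfs> pop1 x pop2 (2n = 20, 20), folded, 28085 segregating sites, 9971915 monomorphic

fit_ii <- fit_model(obs, "ii", n_starts = 20, seed = 1)
fit_iv <- fit_model(obs, "iv", n_starts = 20, seed = 1)
select_model(list(fit_ii, fit_iv))
tidy(fit_iv)               # parameter estimates
glance(fit_iv)             # lnCL, k, AIC
fit_iv$derived$nm          # Ne_source x M per direction
```

The FST printed above is what this model regime produces: clear
differentiation of the same order as montane taxon pairs separated by an
oceanic barrier. The fitted model's `derived` block converts
the estimates to years (generation time 2) and to migrants per generation.

Published summary estimates for the eighteen-species Indo-Pacific study
system ship with the package:

```r
divergence_summary()       # long-format table of Ne, T, M, printed Nm
summary_nm_table()         # recomputed Nm = Ne_source x M vs printed values
mean_divergence_time(region = "New Guinea")
#> $n [1] 13   $mean_my [1] 1.188462   $mean_my_display [1] 1.2
```

`run_pipeline()` composes every stage from one YAML configuration (see
`inst/cli/montgen.R` for the thin command-line wrapper), writing per-stage
TSVs, a JSON report, and a demographic summary table.

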