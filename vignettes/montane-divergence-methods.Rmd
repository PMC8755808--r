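---
title: "Methods: population-genomic inference of montane divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-genomic inference of montane divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

montgen implements a complete desk-scale pipeline for asking how strongly
populations of montane species are differentiated across dispersal barriers,
and what demographic history (split times, sizes, gene flow) produced that
differentiation. This vignette explains the models and procedures, the
parameters that matter, the choices made where the design was genuinely open,
and what the synthetic-data tests do and do not demonstrate.

## The inference problem

The motivating study design is comparative: for each of many bird species,
whole-genome resequencing of two or three populations (9-18 diploids per
species) separated by an ocean channel or a lowland valley. For every species
the pipeline computes population structure (Weir-Cockerham FST, PCA,
model-based admixture proportions with the Evanno delta-K choice of cluster
number) and then fits an explicit catalogue of isolation-with-migration
coalescent models to the joint site-frequency spectrum (SFS), selecting among
them by AIC and converting the winning model's parameters into divergence
times in years and effective numbers of migrants per generation.

## The coalescent engine

All demographic machinery rests on one structured Hudson coalescent
(implemented in C++ for speed, as is usual for coalescent simulators):

* Loci are independent and non-recombining. The pruned SNP panels the
  statistics consume are approximately unlinked, so nothing downstream needs
  within-locus recombination.
* Time is counted in generations; sizes are diploid effective sizes, so a
  lineage pair in a population of size $N$ coalesces at rate $1/2N$.
* Migration is specified forward in time: $M_{i \to j}$ is the
  per-generation probability that an individual in population $j$ originates
  from population $i$. This number is identically the backward jump rate of
  a coalescent lineage from $j$ into $i$, so the engine uses it directly,
  and the effective number of migrants per generation into $j$ is
  $N_i\,M_{i\to j}$ — an identity the tests assert exactly.
* Demography is an ordered event list: divergence joins (all lineages of a
  daughter move into the surviving lineage) and instantaneous size changes;
  exponential growth within an epoch is handled by closed-form inversion of
  the time-varying coalescence hazard.

Two consumers share the engine. `simulate_dataset()` realizes genotype
matrices. In the default `"fixed"` mutation mode each locus carries exactly
one SNP; a genealogy's chance of contributing a site is made proportional to
its total branch length by rejection against a pilot-calibrated envelope,
which is what makes the realized SFS match the mutation-driven expectation
(without the length weighting, one-SNP-per-tree sampling visibly inflates
singletons). In `"poisson"` mode each locus receives
$\mathrm{Poisson}(\mu L_{\mathrm{locus}} T_{\mathrm{total}})$ mutations, so
the segregating-site count is itself an outcome of the model — this is the
mode used when the monomorphic mass matters, e.g. for demographic fitting
experiments, and it reproduces Watterson's $E[S]$.

`expected_sfs()` accumulates, over replicate genealogies, the expected branch
length subtending every joint-SFS cell; under infinite sites the probability
that a segregating site shows configuration $(i, j)$ is proportional to that
length. With the seed fixed the output is bit-reproducible, which turns the
composite-likelihood surface into a deterministic function during
optimization (common random numbers).

A per-batch event budget guards the pathological corner of parameter space
(very large sizes with near-panmictic migration) where a single genealogy can
demand millions of migration events; the optimizer treats a budget overrun as
a very poor likelihood and moves on. This clips only a region whose fit to
structured data is hopeless anyway.

## Site filtering and kinship

`filter_sites()` applies the standard resequencing filters: per-sample read
depth in $[10, 100]$, site quality $\ge 20$, exclusion of sites within 5 bp
of an indel record, biallelic SNPs only, and complete genotypes. Two points
were genuinely open and are settled as follows: the depth rule is per sample
(any individual outside the bounds fails the site), consistent with the
requirement that every individual be genotyped; and "in proximity to indels"
is quantified as a symmetric 5 bp window, the convention adjacent variant
callers use. Both are configurable. Removal counts attribute each dropped
site to every rule it violates, so the per-rule counts are a diagnostic, not
a partition.

Close relatives bias both structure and demographic estimates, so before any
of those stages the pipeline estimates pairwise kinship with the KING-robust
estimator built from shared-heterozygote and opposite-homozygote counts:

$$\hat\phi_{ij} = \frac{N_{Aa,Aa} - 2 N_{AA,aa}}{N_{Aa}(i) + N_{Aa}(j)}.$$

It needs no allele-frequency model, is exactly invariant to ref/alt label
swaps, and has the familiar calibration (duplicates 0.5, parent-offspring
and full sibs 0.25, half-sibs 0.125, unrelated 0). Note that between-population
pairs can be strongly negative — that is expected estimator behavior, and the
0.06 exclusion threshold only looks at the upper tail. Exclusion is greedy:
repeatedly drop the sample in the most flagged pairs (ties: more missing
data, then the lexicographically larger id), which removes exactly one member
of an isolated related pair and matches the minimal vertex cover on small
graphs.

## Population structure

LD pruning follows the indep-pairwise semantics (window 100 variants, step
5, $r^2 > 0.5$ on genotype dosages, i.e. composite LD; the earlier site of an
offending pair is kept). PCA operates on centered, variance-standardized
dosages with axis signs fixed by convention. Admixture proportions come from
the maximum-likelihood admixture model — dosages binomial in $q_i^\top p_l$ —
fitted by EM (block relaxation), whose log-likelihood is non-decreasing every
iteration; at $K = 1$ it equals the closed-form binomial likelihood at pooled
frequencies. A Bayesian MCMC sampler would add nothing downstream here: the
Evanno statistic only consumes replicate dispersion of the data
log-likelihood across runs, and that role is played by multi-start
variation of the EM fits. This is a deliberate, documented divergence from
STRUCTURE's machinery that preserves the model and the downstream statistic.

Weir-Cockerham FST is computed from the per-site variance components
$(a, b, c)$ with the multilocus estimate as the ratio of sums
$\sum a / \sum(a+b+c)$, never the mean of per-site ratios; pooled-monomorphic
sites are excluded and counted. Negative multilocus estimates are reported as
computed, with a clamped convenience column. One behavior worth knowing:
populations with *identical* genotype tables are reported negative (toward
$-1/(2n{-}2)$-scale values), because the estimator measures differentiation
relative to independent sampling from a panmictic pool — "identical tables
give 0" is not a property of this estimator. Elevation-stratum contrasts
reuse the same estimator across strata pairs, reporting undersized strata as
undefined rather than dropping them.

## Joint SFS and the composite likelihood

`joint_sfs()` tabulates complete, filtered genotypes into a 1-3 dimensional
spectrum. Spectra are folded (minor-allele) by default: the study system has
no stated outgroup polarization, and folding is the safe summary; unfolded
mode exists for simulation work. When a callable genome length is supplied,
the monomorphic mass $L - S$ rides along; this is what makes absolute sizes
identifiable given $\mu$. Without it, fits report scaled parameters only.
Observed spectra round-trip bit-exactly through the fastsimcoal2-style text
dialect (`write_obs()`/`read_obs()`).

The fit criterion is the composite multinomial likelihood
$\ln CL = \sum_c m_c \ln p_c$ over SFS cells (plus the monomorphic cell when
present, with $p_c = \mu\,E[\ell_c]$ and
$p_0 = 1 - \sum_c p_c$). Expected cell probabilities are floored at
$\varepsilon = 1/(10\,R\,C)$ for $R$ replicates and $C$ cells so a finite
sample of genealogies never produces $\ln 0$.

## The model catalogue and fitting

The two-population catalogue contains ten scenarios: (i) no growth, no
migration; (ii) migration only; (iii) exponential growth only; (iv) growth
and migration; a historical size-change event producing a bottleneck
(v with / vi without migration) or a sudden expansion (vii with / viii
without); and the mixed scenarios (ix: bottleneck in population 1, expansion
in population 2; x: the reverse). Where the event scenarios were undetermined
— which population the event touches, and whether ix/x carry migration — the
package gives both daughters a shared event time with per-population
historical sizes in v-viii, one population each in ix/x, and includes
migration in ix/x (migration-bearing models dominate these data in practice,
so excluding it would make ix/x strawmen). Event direction is enforced
through bounds on the ratio of current to historical size (ratio < 1 is a
decline toward the present, i.e. a bottleneck; > 1 a sudden expansion).
Three-population variants (`3pop_null`, `3pop_mig`) nest two divergence
times $T_1 \le T_2$ with topology `((pop1, pop3), pop2)`.

Search bounds default to log-uniform $N_e \in [10^3, 10^7]$,
$T \in [10^2, 10^7]$ generations, $m \in [10^{-10}, 10^{-2}]$, growth
$\in [-10^{-3}, 10^{-3}]$ per generation — brackets that enclose every
published estimate this package targets by at least an order of magnitude —
and are overridable.

`fit_model()` maximizes the composite likelihood by multi-start bounded
Nelder-Mead on logit-transformed coordinates. Four design elements matter:

1. **Common random numbers.** The expected-SFS seed is fixed per fit, so the
   objective is a deterministic function of the parameters and optimization
   is meaningful despite Monte-Carlo noise.
2. **Profiled global scale.** When the observed spectrum carries monomorphic
   mass, the overall coalescent scale is profiled out analytically at every
   evaluation: scaling all sizes and times by $c$ multiplies every expected
   branch length by $c$, so the likelihood-maximizing scale is
   $c^* = S / ((S + m_0)\,\mu\,T_{\mathrm{total}})$ in closed form (the
   same optimal-rescaling device diffusion-based SFS fitters use). The
   optimizer then searches only the shape manifold, and reported estimates
   are the rescaled parameters.
3. **Moment-based warm grid.** Deterministic starts are appended to the
   random ones: per-population sizes from Watterson's estimator against the
   callable length, ancestral size at the geometric mean, and a grid of
   split times around the heterozygosity-based FST relation
   $T = -2 N_e \ln(1 - F_{ST})$ crossed with a migration-rate ladder. The
   grid deliberately spans the classic divergence-time/migration degeneracy:
   isolated random starts essentially never land in the right basin of this
   surface, and the growth dimensions open a long curved valley (small
   present size compensated by growth) that traps simplex descent. The best
   grid point per time multiplier is always refined. All starts, warm or
   random, are refined by the same local search and compete on likelihood
   only.
4. **Restarted simplices with escalating replicates.** Every start gets a
   short refinement at a reduced replicate count; promising candidates are
   refined with restarted Nelder-Mead rounds (a fresh simplex around the
   incumbent recovers from simplex collapse, the standard failure mode in
   6-8 dimensions); the best candidate is polished at the full replicate
   count and finally at `final_replicates` (default four times more). The
   escalation matters because the Monte-Carlo noise of the expected
   spectrum, frozen by common random numbers, flattens and displaces the
   shallow valley around the optimum; at typical polish replicate counts
   this displacement is of order tens of percent in divergence time, and
   the high-replicate round walks part of it back. Residual scatter at this
   scale is a genuine precision limit of simulation-based composite
   likelihood at desk-scale replicate counts, and point estimates near a
   tolerance boundary should be read accordingly.

AIC selection is exact arithmetic ($AIC = 2k - 2\ln CL$; ties to smaller
$k$, then catalogue order). Derived quantities are $T_{\mathrm{years}} =
T_{\mathrm{gen}} \times g$ (generation time default 2 years) and
$Nm_{A\to B} = N_A \times M_{A\to B}$, reported at full precision plus the
conventional display rounding (sizes to the nearest $10^4$; $Nm$ to one
decimal, half away from zero). Mutation rates default to
$3 \times 10^{-9}$ per site per generation (the passerine rate; kingfishers
use $2 \times 10^{-9}$).

Confidence intervals use a parametric bootstrap: multinomial resampling of
the fitted expected spectrum at the observed total site count (including the
monomorphic cell when present), reduced-start refits, percentile intervals.

## Elevation regression

`spearman_fst_floor()` correlates per-species FST with the altitudinal floor
(the lowest elevation at which the species occurs) by Spearman rank
correlation with average-rank ties. The p-value is a permutation p: exact
enumeration of all $n!$ orderings for $n \le 10$ (a compiled Heap's-algorithm
enumerator), seeded Monte-Carlo otherwise. The default alternative is
one-sided positive, matching the directional hypothesis that higher-floor
species are more differentiated; the empirical correlations from any given
study are validated only qualitatively here, because published per-species
floors are typically shown graphically rather than as numbers. Exclusion
lists are plain configuration, never hard-coded species names.

## The synthetic-data generator as a study stand-in

`simulate_dataset()` emulates the statistical structure the analysis
assumes: 2-3 diploid populations of realistic sample sizes under the same
model class the fitting stage searches, negative-binomial per-sample read
depth (mean 30, dispersion 15) and Gaussian site quality (mean 50, sd 12) —
calibrated once so that roughly 5-10% of sites fail the default filters —
plus planted half-sibling pairs by explicit gamete dropping from population
allele frequencies, and a multi-species covariate panel in which the
elevational floor maps monotonically to migration.

What it does not emulate: sequencing reads themselves (depth and quality are
summaries, not alignments), genotyping error and allele-dropout structure,
linked selection, recombination gradients, or reference bias. Passing tests
therefore demonstrate the correctness of the estimators and of the inference
machinery on data satisfying the model assumptions — not robustness of the
statistics to the full messiness of real resequencing data.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at deliberately desk-scale
sizes, chosen as the package's own validation design: statistic oracles on
hundreds of random small instances; kinship on ~50,000 SNPs; neutral-theory
checks at $2 \times 10^4$ genealogies; model selection on ten 8+8-diploid
datasets over 4 Mb; and parameter recovery on ten 10+10-diploid datasets
over 10 Mb of callable sequence with 20 starts, 1,000-replicate search,
10,000-replicate polish and a 30,000-replicate final round per fit. Tolerances on stochastic checks are stated
in Monte-Carlo standard errors wherever a closed form exists.

Degenerate inputs are first-class: zero-variance sites are skipped (PCA) or
treated as uncorrelated (pruning); zero replicate dispersion gets a recorded
floor (Evanno); pairs with no shared called sites are undefined rather than
zero (kinship); single strata and undersized strata are reported, not
dropped (stratum FST); and folding an already folded spectrum warns and
returns the input.

## Known limitations

* The coalescent engine supports at most three populations and 64 haploid
  genomes in site-simulation mode — the study design's scale, not a general
  coalescent machine.
* Composite likelihood treats linked SNPs as independent; in `"poisson"`
  mode sites within a locus share a genealogy, so likelihood-ratio scales
  are overdispersed relative to true independence (as with any SFS composite
  likelihood). AIC differences should be read at effect-size scale, not as
  calibrated tests.
* Growth-bearing models have a genuinely weakly-identified direction (small
  present size + strong historical growth); the warm starts make the global
  optimum reachable, but interval estimates for growth rates remain wide.
* The admixture fit uses uncorrelated cluster allele frequencies; the
  correlated-frequencies prior of Bayesian implementations is out of scope.
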