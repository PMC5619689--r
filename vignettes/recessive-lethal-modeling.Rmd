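---
title: "Modeling the population frequencies of recessive lethal disease alleles"
author: "reclethal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the population frequencies of recessive lethal disease alleles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reclethal)
```

## The problem

Mutations that cause recessive, lethal Mendelian diseases are under the
strongest form of selection in homozygotes (selection coefficient $s = 1$)
and, nominally, none in heterozygotes (dominance $h = 0$). How frequent
should such alleles be in a present-day human sample? The naive
mutation-selection-balance answer for an infinite population,
$q = \sqrt{u/s}$, is around $10^{-4}$ for a per-base-pair mutation rate $u
\approx 10^{-8}$ — but finite population size, non-equilibrium demography,
mutation-rate heterogeneity, compound heterozygosity and the way disease
mutations are discovered all push the observable frequencies away from that
figure, mostly downwards. This package implements each of those ingredients
as a tested, reusable component: closed-form theory, a forward Wright-Fisher
simulator under a two-population out-of-Africa history, an
ascertainment-bias model for discovery in inbred populations, resampling
comparison statistics, and a synthetic variant-catalog generator.

## Analytic mutation-selection balance

For a fully recessive allele with genotype fitnesses $1$, $1 - hs$, $1 - s$
and one-way mutation at rate $u$:

* infinite population: $q = \sqrt{u/s}$ (`eqFreqInfinite`);
* finite constant diploid size $N$ (Nei's diffusion result):
  $\bar q = \Gamma(2Nu + 1/2) \,/\, \big(\sqrt{2Ns}\,\Gamma(2Nu)\big)$
  (`meanFreqFinite`) with variance $\sigma^2_q = u/s - \bar q^2$
  (`varFreqFinite`);
* in the human regime $2Nu \ll 1$ this reduces to
  $\bar q \approx u\sqrt{2\pi N / s}$ (`meanFreqLowMut`), so for a lethal
  ($s=1$) the variance is $\approx u$: the distribution is extremely
  dispersed relative to its mean.

`meanFreqFinite` is evaluated with log-gamma arithmetic because $2Nu$ spans
many orders of magnitude across use cases; both limits ($2Nu \to 0$ and
$2Nu \to \infty$) are covered by tests. The closed forms deliberately raise
an error for $h \neq 0$ rather than silently approximating — no closed form
for partial dominance is implemented, and the simulator is the correct tool
there. `equivalentConstantN` inverts the low-mutation mean,
$N = \bar q^2 s / (2\pi u^2)$, to express a simulated non-equilibrium mean
as the constant population size that would produce it.

```{r analytic}
eqFreqInfinite(1.5e-8)                     # infinite population
meanFreqFinite(1.5e-8, N = 20000)          # long-term human effective size
eqFreqInfinite(1.5e-8) / meanFreqFinite(1.5e-8, N = 20000)
```

## The demographic model

`rescaledTennessen()` builds the two-population (African/European)
out-of-Africa history of Tennessen et al. (2012) (with Gravel et al. (2011)
migration rates), rescaled for a pedigree-based mutation rate roughly half
the one the model was inferred with. Rescaling multiplies diploid sizes and
epoch durations by a factor close to 1.97 and divides per-generation rates
(growth, migration) by it. The published anchor values of the rescaled
history pin the factors exactly: the burn-in size 14,328 fixes the size
factor at $14328/7310 \approx 1.9601$, and the African size change 11,643
generations ago fixes the time factor at $2.36/1.2 \approx 1.9667$. We use
those two factors as defaults rather than a single rounded 1.97, so the
default model reproduces the anchors; passing `c = 1` recovers the original
parameterisation, and any other single factor may be forced via `c`.
Migration rates are not independently constrained here, so the defaults are
the Gravel et al. values divided by the time factor
($1.5\times10^{-4}$ between the split and the bottleneck exit,
$2.5\times10^{-5}$ afterwards, both before division), exposed in the model
object and its JSON serialisation.

Epochs are half-open intervals of generations before present; exponential
epochs are parameterised by their boundary sizes, with the per-generation
size rounded to the nearest integer (the rounding is part of the model, not
a display convenience: drift at small sizes is sensitive to it).
`variantModel()` produces the growth variants used for sensitivity analysis:
a 2-/4-/10-fold larger present European size with epoch boundaries
preserved, or a single exponential expansion starting immediately at the
bottleneck exit. `constantModel(N)` wraps a single constant-size population
with a $10N$-generation burn-in for equilibrium studies.

## The Wright-Fisher simulator

Each replicate is an independent bi-allelic site (or pooled gene). Every
generation applies, in order: recurrent one-way mutation on the gamete
frequency, $q_m = q + (1-q)M$; viability selection on random-union
genotypes; deterministic two-way migration after the population split; and
binomial drift at the next generation's size. The order is a convention
(the differences between orders are $O(u)$ per generation); mutation is
applied deterministically to the gamete frequency rather than as a sampled
count because $2NM \ll 1$ and the immediately following binomial drift makes
the two schemes distributionally indistinguishable. There is no back
mutation. The corner case $q_m = 1, s = 1$ (every survivor would be a dead
homozygote) resolves to loss of the allele in the next generation.

Replicates start with the wild-type allele fixed and run a burn-in of
$10 N_e$ generations at the constant ancestral size, which the constant-size
oracle tests show is ample to reach mutation-selection-drift equilibrium;
the demographic history follows. At the split the European lineage inherits
the ancestral frequency and the two populations then evolve jointly under
migration. Mutation-rate heterogeneity within a mutation class follows a
log10-normal: $\log_{10} M \sim \mathcal N(\log_{10} u - \tfrac{\sigma^2}{2}
\ln 10,\ \sigma^2)$ with $\sigma = 0.57$, an offset that makes
$\mathbb E[M] = u$; each replicate draws its own rate. Gene-level runs
(`simulateGene`) model compound heterozygosity without complementation by
summing per-site draws into a gene-wide rate $U$ and running the same
single-locus machinery. A treatment scenario (`treatmentGenerations`)
forces $s = 0$ for the final generations to mimic fully effective modern
medicine.

### Numerical implementation

The default history is ~155,000 generations, and at human mutation rates a
replicate is fixed for the wild type in the large majority of generations.
The engine therefore advances only segregating replicates generation by
generation. For replicates currently at frequency zero, the waiting time
until the next non-zero binomial draw is geometric with a per-replicate
success probability $p_0 = 1 - (1 - q_s^{(0)})^{2N}$, so the engine samples
that waiting time directly into a calendar queue and, at the scheduled
generation, draws the conditional positive count from the truncated
binomial via the inverse CDF. Within any stretch of constant sizes,
migration and selection this is *exactly* the dense process, and at every
stretch boundary (demographic events, per-generation growth, the treatment
window) the waiting times are re-drawn, which is exact by memorylessness;
during time-varying epochs the zero-state updates fall back to
per-generation Bernoulli draws. After the split, a joint seeding event
chooses which population(s) the first copies appear in with the correct
conditional probabilities. Tests verify the engine against a dense
`wfStep()` reference loop, against the finite-population closed forms at
two population sizes, and against the stationary distribution of the exact
21-state Markov chain of a $2N = 20$ population, where the simulated mean
agrees within 2%.

All randomness flows from the configuration seed; identical configurations
reproduce bit-identical outputs. Because the zero-state fast path consumes
randomness state-dependently, results are reproducible but not comparable
draw-for-draw with a dense implementation; comparisons are distributional.

## Ascertainment bias in disease-mutation discovery

A recessive lethal mutation can only be recognised once at least one
affected homozygote is observed. In a discovery survey of $n_a$ individuals
with average inbreeding coefficient $F_a$, homozygotes arise with
probability $P(aa) = F_a q + (1 - F_a) q^2$, so the mutation is ascertained
with probability $P_{asc} = 1 - (1 - P(aa))^{n_a}$, increasing in $q$, $F_a$
and $n_a$. `ascertainmentExperiment()` applies this to a pool of simulated
population frequencies: each mutation is marked ascertained by a single
Bernoulli draw with that probability — exactly the distribution of "at
least one homozygote among $n_a$ sampled genotypes", and orders of magnitude
faster; an explicit genotype-sampling mode is retained behind the `method`
argument for validation. Sample frequencies for the ascertained/unbiased
comparison are generated by the same Poisson scheme as the comparison
statistics. Because ascertainment weights the upper tail of the frequency
distribution, the mean frequency of ascertained mutations can exceed the
class-wide mean many-fold, and the inflation is strongest for the least
mutable classes — the package's synthetic ascertained-world catalogs
reproduce that inverse ordering.

These statistics probe the far upper tail of the frequency distribution
and are therefore much more sensitive to the demographic parameterisation
than the mean is: smaller effective sizes imply stronger drift, a more
dispersed frequency distribution, and (for a fixed mean) lower
ascertainment probabilities with higher fold inflation. The ascertainment
module is model-agnostic — it consumes any frequency pool — and the
reproduction script runs its discovery-bias illustration on pools from the
original (unrescaled) Tennessen parameterisation, the dispersed regime in
which the package's reference values for inbred discovery studies were
established; under the rescaled variant the ascertainment probabilities
come out roughly 1.7-fold higher.

## Comparison statistics

`sampleAlleleCount` approximates sampling $2n$ chromosomes by
Poisson($q \cdot 2n$) truncated at $2n$; the default $2n = 65{,}762$
corresponds to an assumed mean of 32,881 sequenced individuals.
`meanFreqTest` builds the null distribution of the mean sample frequency of
$K$ mutations by resampling the simulated pool $R$ times and reports the
two-tailed empirical p-value $p = 2(r+1)/(R+1)$, where $r$ counts null
means at least as large as the observed mean (ties count as extreme). The
printed formula can exceed 1 when the observed mean is low, so p-values are
capped at 1; a consequence, verified by a calibration test, is that the
test is one-sided-conservative — its type-I error at level $\alpha$ is
about $\alpha/2$ and never exceeds $\alpha$. `geneLevelTest` applies the
same definition to a gene's combined frequency against (typically 1000)
gene-level simulations and additionally reports the fraction of simulations
in which no deleterious allele appeared in the sampled chromosomes.
`fisherCombined` combines independent p-values with $-2\sum\ln p$ against
$\chi^2_{2k}$. Fold changes divide the observed mean by the *mean* of the
null means; using the median instead moves folds by only a few percent
because the null mean distribution is nearly symmetric at large $R$.

## Synthetic variant catalogs

`generateCatalog()` emulates the statistical structure of a hand-curated
disease-variant table joined to exome-aggregation frequencies: per mutation
class it draws population frequencies from a simulated pool (or from the
ascertained subset, for an "ascertained world"), Poisson-samples allele
counts, generates flanking contexts consistent with the class label
(classification is strand-symmetric, and `classifyMutationType` is
property-tested over all 192 contexts), and injects configurable fractions
of QC artifacts — homozygote observations, low-coverage sites, CpG-island
flags — that `applySiteFilters()` removes with a per-rule report. The
default composition (417 records, 29.3% CpG transitions of which 12 carry
the island flag, artifact rates 3/417 and 29/417) mirrors the scale of a
curated recessive-lethal study set; the per-class split of the remaining
295 records (32/104/159) is a configured default, not an estimate. The
catalogs are synthetic throughout: they reproduce class composition,
frequency structure and filter yields, not real variants, genome positions
or linkage, and carry no guarantee about the literature provenance of any
real mutation. Passing null-world catalogs through `meanFreqTest` yields
conservative p-values; ascertained-world catalogs show inflated folds
ordered inversely with the class mutation rate.

## Problem sizes and limitations

The test suite runs the full two-population history with $3\times10^5$
replicates for the mean-frequency reproduction, $2\times3\times10^4$
replicates for the dominance contrast, ten paired runs of $5\times10^3$
replicates for the treatment scenario, and a $10^5$-replicate
CpG-transition pool for the ascertainment table; the constant-size oracles use $10^4$ replicates at
$N = 5\times10^3$ and $2\times10^4$ with the mutation rate chosen so
$2Nu = 0.01$. These sizes keep Monte-Carlo standard errors a few-fold below
each assertion's tolerance.

Known limitations: single-locus dynamics only (no linkage, recombination,
or interference between genes); compound heterozygosity is modeled as
complete non-complementation; the ascertainment model covers homozygote
discovery only, not discovery through compound heterozygotes or pedigree
structure; and the analytic results cover $h = 0$ only. Migration defaults
are literature values passed through the rescaling, not re-inferred.
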