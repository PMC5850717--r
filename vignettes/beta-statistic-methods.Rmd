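---
title: "Detecting long-term balancing selection with the beta statistic"
author: "balsel maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting long-term balancing selection with the beta statistic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(balsel)
```

## The signature: allelic-class build-up

Long-term balancing selection — classically heterozygote advantage, as at
the haemoglobin-beta locus in malaria-endemic regions — maintains two
allelic classes at a locus far longer than genetic drift would.  A neutral
mutation arising in linkage with one of the balanced alleles can drift up
to, but not beyond, the frequency of the allelic class it sits on: it can
fix *within its class* while the class frequency itself is pinned near the
selective equilibrium.  Given enough time, and before recombination
decouples it, such variants therefore accumulate at frequencies nearly
identical to that of the balanced variant.  The local time to the most
recent common ancestor is also much deeper than background, so these
regions carry an overall excess of polymorphism.

Classical scans pick up parts of this signal — Tajima's D detects the
excess of intermediate-frequency alleles, HKA the excess diversity — but
neither uses the sharpest feature: the *clustering of allele frequencies
around the balanced allele's frequency*.

## The statistic

For a candidate ("core") SNP at derived count $f_0$ out of $n$ sampled
chromosomes, fold counts as $g(f) = \min(f, n-f)$ and let
$m = \max\!\big(g(f_0),\, n/2 - g(f_0)\big)$ be the largest folded
difference any site can have from the core.  The similarity of a second
SNP at count $f_i$ is

$$d_i = \left(\frac{m - |g(f_0) - g(f_i)|}{m}\right)^{p},$$

which runs from 0 (maximum possible folded difference) to 1 (identical
folded frequency) and is symmetric in the derived/ancestral labelling of
either site.  Folding makes $d_i$ usable without knowing which allele of
the neighbour is linked to which allele of the core.

Each unfolded frequency class $i \in \{1, \dots, n-1\}$ yields an
unbiased estimator of the population mutation rate,
$\hat\theta_i = i\, S_i$, where $S_i$ counts window SNPs at class $i$
(core excluded).  The statistic contrasts a $d$-weighted average of these
per-class estimators against Watterson's estimator:

$$\beta = \hat\theta_\beta - \hat\theta_w, \qquad
\hat\theta_\beta = \frac{\sum_{i=1}^{n-1} i\, d_i\, S_i}{\sum_{i=1}^{n-1} d_i},
\qquad
\hat\theta_w = \frac{\sum_i S_i}{\sum_{i=1}^{n-1} 1/i}.$$

Under neutrality both estimators target the same $\theta$, so $\beta$ is
near zero; when variants cluster at the core's frequency,
$\hat\theta_\beta$ is inflated and $\beta > 0$.  Note that the
$\hat\theta_\beta$ denominator sums $d_i$ over *all* $n-1$ classes,
occupied or not — this is the only reading under which it is a genuine
weighted average of per-class estimators, and the one this package
implements.

```{r closed-form}
spec <- windowSpectrum(4, c(`1` = 1, `2` = 1), coreCount = 2)
c(thetaBeta = thetaBeta(spec, p = 2), thetaW = thetaWatterson(spec),
  beta = betaScore(spec, p = 2)$beta)
```

### The folded form

When no ancestral states are available at all, the same contrast is
computed on the folded spectrum $S^*_i$, $i = 1, \dots, \lfloor n/2
\rfloor$.  The per-folded-class unbiased estimator used here is

$$\hat\theta^*_i = \frac{S^*_i\,(1 + \delta_{i,\,n-i})}{1/i + 1/(n-i)},$$

since $E[S^*_i] = \theta\,(1/i + 1/(n-i))/(1+\delta_{i,n-i})$ under
neutrality; $\hat\theta_{\beta,\text{folded}}$ is the $d$-weighted
average of these over the folded classes, and $\hat\theta_w$ is
fold-invariant.  The folded score is by construction invariant to
flipping derived/ancestral labels of any subset of sites.

### Tunable parameters

* **`p` (default 2)** — the similarity exponent.  Larger `p` concentrates
  weight on sites very close to the core frequency; power is fairly
  insensitive to it over moderate values, and smaller `p` is preferable
  when per-site sample sizes vary.
* **`windowBp` (default 1000)** — total window span (bp), half-open
  $[x - w/2,\, x + w/2)$ around the core.  1 kb matches the expected span
  of the ancestral, recombination-free segment around a balanced site in
  human-like parameter regimes; the optimum shrinks as the recombination
  rate grows.
* **`minFoldedFreq` (default 0.15)** — cores below 15% folded frequency
  in every population are not scored: balanced polymorphism with a rarer
  minor class is barely maintainable (the rare allele drifts out), so
  low-frequency cores mostly contribute false positives.
* **`percentile` (default 0.01) and `sharingFraction` (default 0.5)** —
  empirical outlier calling: the top 1% of scores per population, kept as
  a shared signal when flagged in at least half of the populations
  (ceil-rounded, e.g. 13 of 26), which focuses the scan on selection
  predating the split of modern populations.

### Numerical conventions

* Site positions are 1-based; BED mask records $(s, e)$ mask the
  coordinates $s \le x < e$ compared directly against site positions, and
  the default masking policy drops a core whenever *any* base of its
  window is masked (`maskLevel = "site"` relaxes this).
* Empty windows return `beta = NA` rather than 0, so SNP deserts do not
  distort percentile calling.
* Odd $n$: folded classes run to $\lfloor n/2 \rfloor$ and $m$ uses $n/2$
  as a real number.
* Ties in top-percentile calling are broken by genomic position, making
  scans bit-reproducible.
* Mixed per-site sample sizes (e.g. from missing genotypes) switch
  similarity to the proportion scale $g(f)/n$ and accumulate
  $\hat\theta_w$ as $\sum_j 1/a_{n_j - 1}$; windows with a uniform $n$
  use the exact count-scale spectrum path, and the two agree when sample
  sizes coincide.
* Sites without a usable ancestral-allele (`AA`) call are dropped in
  unfolded scans rather than polarised by REF — systematic mispolarising
  would be worse than the lost sites — and retained in folded scans.

## The simulators

### Wright–Fisher forward model with overdominance

`runForward()` implements the two-population protocol used to study the
statistic: a burn-in of an ancestral diploid population (default 100,000
generations, $N_e = 10{,}000$, $\mu = r = 2.5\times10^{-8}$ per bp per
generation over 10-kb regions) to mutation–drift equilibrium, a split
into focal and outgroup populations evolved for 250,000 further
generations, and sampling of 100 focal chromosomes plus one outgroup
chromosome.  Substitutions are variants at which the outgroup
chromosome's allele does not occur among the sampled focal chromosomes.

Balanced runs insert a single mutation at the region centre `tSel`
generations before sampling with genotype fitnesses $1$, $1 + hs$,
$1 + s$; the deterministic interior equilibrium $q^* = h/(2h-1)$ is
stable exactly when the heterozygote is fittest ($hs > 0$, $hs > s$).
The run is conditioned on maintenance of the polymorphism: on loss (or
degenerate fixation) the simulation restarts from a snapshot taken at the
introduction generation.  Because the two populations evolve
independently after the split, only the focal population is replayed.

Internally, haplotypes are bit rows over a registry of segregating
mutation slots (continuous infinite-sites positions, rounded to integer
bp only on output), with single-crossover recombination at rate $rL$ per
meiosis and Poisson($\mu L$) new mutations per gamete; lost slots are
recycled and fixed mutations moved to a per-population fixed list.  The
`rescaleQ` factor applies the standard population-genetic rescaling
($N_e$ and generation counts divided by $Q$; $\mu$, $r$, $s$ multiplied
by $Q$), which preserves $\theta$, $\rho$ and $2N_e s$; the suite checks
that rescaled and unscaled runs agree on diversity summaries within
Monte-Carlo error.  The simulator's RNG is seeded from `SimConfig@seed`
and is independent of R's RNG, so a fixed seed reproduces a replicate
bit-for-bit.

### Coalescent null

`runNeutralCoalescent()` is a Hudson-style coalescent with recombination
(ancestral recombination graph) at the matched $\theta = 4N_e\mu L$ and
$\rho = 4N_e r L$.  It is the fast, exchangeable null for the forward
simulator's neutral arm: mutations are placed as a Poisson process on the
graph and each lands with exactly the descendant set of the ancestral
segment it hits, so sample frequencies come out directly.  The suite
cross-validates its segregating-site counts against both Watterson's
expectation and the forward simulator's neutral arm.

### Frequency matching and power

Mirroring the simulation design, each balanced replicate's score (at the
balanced variant) is compared against scores of neutral core SNPs matched
to within 10% of the balanced equilibrium frequency
(`matchNeutralCores()`; the band is relative by default, with an
`relative = FALSE` absolute-band option since either reading of "within
10%" is defensible).  `powerAnalysis()` sweeps an empirical ROC and
reports power at fixed false-positive rates (defaults 0.01 and 0.05 —
explicit operating points rather than a figure-derived one).

## What the synthetic data do and do not show

The generator reproduces the equilibrium-demography study conditions:
constant population size, a clean species split with no migration, a
single balanced variant at the region centre, uniform mutation and
recombination rates, and perfect genotypes.  Real data add demographic
history (bottlenecks, expansion, structure, admixture), rate
heterogeneity, genotyping error, and imperfect ancestral calls; passing
tests here therefore validate the estimators and the machinery, not
robustness to those complications.  Population substructure in
particular can mimic the frequency-clustering signature, which is why
scans are run per population and intersected.  Non-equilibrium
demographies are out of scope (a `popSchedule` hook exists in
`SimConfig` but is deliberately unused and untested).

### Problem sizes in the shipped checks

The test-suite calibration uses 1,500 neutral coalescent replicates of
10-kb regions with $n = 100$, and the power comparison 300 balanced
forward replicates ($h = 1.5$, $s = 0.01$, `rescaleQ = 10`, introduction
at the split) against 300 neutral coalescent replicates with cores
matched at the 0.75 equilibrium — sizes chosen so that Monte-Carlo error
is small relative to the effects being demonstrated while a full run
stays comfortably interactive.  Unit-level Monte-Carlo checks use
smaller populations ($N_e$ of a few hundred, $n = 20$, 2-kb regions)
where expectations are still sharp.  The balanced arm of the shipped
power run skips the outgroup population: substitutions enter neither
$\beta$ nor Tajima's D, and the focal population's trajectory is
unaffected.  The full two-population path with substitution calling is
exercised by its own tests.

## Design choices that were genuinely open

* **Neutral mean of beta.**  Conditioned on a core SNP segregating at an
  intermediate frequency, the neutral mean of $\beta$ is not exactly
  zero: requiring such a core selects windows with locally deeper
  genealogies, inducing a small positive offset (about $0.5$–$1$ at
  $\theta = 10$ per 10 kb) that grows with the matched frequency.  This
  is an order of magnitude below the balanced-arm signal and two orders
  below genome-scan significance cutoffs; the suite therefore tests the
  *contrast* between arms (stochastic dominance, ROC ordering) rather
  than asserting a zero mean.
* **Window-level masking** is the default because one bad base in a
  window can inflate every score in it; site-level masking is offered
  for sparse masks.
* **Mask boundary convention.**  BED records are compared directly
  against site coordinates as the half-open set $[s, e)$; a site at
  exactly $e$ is retained.
* **Raw beta is reported** — no per-window normalisation by SNP count or
  variance — keeping scores on the same scale as published cutoffs;
  percentile calling downstream is scale-free anyway.
* **Fixation counts as loss** for the restart conditioning: the
  polymorphism, not the derived allele, is what selection must maintain.
  Under protected polymorphism parameters fixation is vanishingly rare,
  so this choice is about degenerate parameter sets.
* **`p = 2` by default**; exposed everywhere as a parameter.

## Known limitations

Only biallelic SNPs are scored; no liftover, phasing, imputation or
multiallelic decomposition.  The composite-likelihood statistics (T1/T2)
and HKA are not implemented — Tajima's D is the only comparator — and the
substitution-rate-augmented variant of the statistic is deliberately
omitted.  The scanner holds each population's sites in memory, which is
fine for per-chromosome scans of current reference panels but not tuned
for whole-genome single-pass runs.
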