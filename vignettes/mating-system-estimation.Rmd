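---
title: "Estimating visitor-specific self-pollination from inserted pollinia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating visitor-specific self-pollination from inserted pollinia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollmate)
```

## The problem

Milkweeds and other asclepiads disperse pollen in pollinia: discrete sacs
of grains that all descend from a single donor flower. Genotyping an
inserted pollinium at a handful of microsatellite loci therefore recovers
its donor's diploid multilocus genotype, and comparing it with the genotype
of the maternal stem tells you directly whether an insertion was self or
outcross. Aggregated per visitor taxon, that classification gives a
*direct* self-pollination rate $S_d$ — the most powerful mating-system
estimate available for these systems, but a biased one, for two reasons
this package corrects:

1. **Chance genotype matches.** Two plants can share a multilocus genotype
   through chance or relatedness, so an outcross pollinium is sometimes
   misclassified as self. In a strongly clonal population with few genets
   this is not a rare event.
2. **Through-bag contamination.** Focal inflorescences are bagged until the
   watched visit begins, but insects occasionally insert pollinia through
   the bags, so the pollinia recovered from a focal inflorescence are a
   mixture of visitor-inserted and through-bag insertions. Permanently
   bagged control inflorescences measure the bag process.

## The estimator chain

Write $P_{ik}$ for the pollen-pool frequency of the unordered diploid
genotype that pollinium $i$ carries at locus $k$. The probability that a
random pool member matches pollinium $i$ at all $n$ scored loci, assuming
independence across loci, is $\prod_k P_{ik}$, and the erroneous-assignment
probability over a set of inserted pollinia is the weighted mean

$$\alpha_d = \sum_{i} w_i \prod_{k=1}^{n} P_{ik},$$

with $w_i$ the pollinium's weight (each genotyped pollinium counts once by
default; see below). Genotype frequencies here are *observed counted*
frequencies, not Hardy–Weinberg products: clonal structure violates HWE,
and the pool of interest is the realized pollen pool.

With $r_p$ the proportion of a taxon's insertions attributable to the
visitor (as opposed to the bags), the mixture partitions as

$$\alpha_{dp} = \frac{\alpha_{dT} - (1 - r_p)\,\alpha_{dc}}{r_p},
\qquad
S_{dp} = 1 - \frac{t_{dT} - (1 - r_p)\,t_{dc}}{r_p},$$

where subscript $T$ denotes the taxon's focal pollinia (the mixture),
subscript $c$ the control pollinia, and $t = 1 - S$ the direct outcrossing
rates. Both partitions are defined only when the total rate exceeds the
control-attributable share ($\alpha_{dT} > \alpha_{dc}(1-r_p)$ and
likewise for $t$); small samples can breach these conditions, and the
package then clamps into $[0,1]$ and flags the estimate (default) or
aborts (`clamp_policy = "error"`).

Finally, because an outcross pollinium is misclassified self with
probability $\alpha$, the observed self fraction satisfies
$S_{dp} = S + (1 - S)\,\alpha_{dp}$, and the method-of-moments estimate
inverts it:

$$S_{mp} = \frac{S_{dp} - \alpha_{dp}}{1 - \alpha_{dp}}.$$

The source describing this estimator family cites the correction without
printing its final form; the formula above is the unique misclassification
inversion consistent with the two stated limits ($S_{mp} = S_{dp}$ when
$\alpha_{dp} = 0$; $S_{mp} = 0$ when $S_{dp} = \alpha_{dp}$), and those
limits are pinned in the test suite. The correction can only lower the
estimate.

### How $r_p$ is constructed

$r_p$ is "the proportion of insertions attributed to the visitor taxon".
The package estimates it from the visit table: the per-flower through-bag
insertion rate on controls, times the total flower count of the taxon's
focal inflorescences, gives the expected number of bag-origin insertions
among the taxon's observed insertions, and

$$r_p = 1 - \frac{\hat\lambda_c \sum_j I_j}{\sum_j \text{insertions}_j}$$

over the taxon's focal inflorescences $j$ with inflorescence sizes $I_j$.
A per-flower (rather than per-inflorescence) control rate is used because
focal and control inflorescences differ in size. If the expected bag
insertions meet or exceed the observed insertions the partition is
undefined and the fit aborts with an explanation. With no genotyped
control pollinia at all, the fit proceeds under an explicit, loudly logged
zero-contamination assumption ($r_p = 1$).

### Round-robin frequency estimation

Clonal plants can present thousands of stems per genet. Counting every
stem overstates the clone's alleles; collapsing to unique genotypes first
overstates rare alleles. The round-robin estimator threads between the
two: for each locus $k$, distinct-genotype classes are formed over all
loci *except* $k$, and locus-$k$ frequencies are then tabulated over one
representative per class, so the left-out locus cannot bias its own
collapsing. It requires at least two loci and equals naive counting
whenever no two samples share a multilocus genotype.

Missing calls complicate the collapsing. The rule adopted: a sample with
missing calls joins a class only if it matches it at every co-genotyped
locus (at least one) and the match is unique; otherwise it founds its own
class. This is deliberately conservative against over-collapsing, which
would re-inflate exactly the rare-allele frequencies the round-robin
method exists to deflate.

The pool whose frequencies enter $\alpha$ is configurable
(`freq_basis`): the default is the genotyped inserted pollinia themselves
(the realized pollen pool, pooled across taxa and controls); the maternal
stems are available as an alternative basis since both pools are
legitimate summaries of the same population and the choice is not settled
by first principles. Control pollinia are scored against the same pool
table as visitor pollinia.

### Weighting

The weight $w_i$ is per-pollinium by default: every genotyped pollinium
counts once, matching the bootstrap's resampling unit. The alternative
reading — every *inflorescence's* array counting once, its pollinia
sharing the unit weight — is available as
`alpha_weighting = "per_inflorescence"`. Most inflorescences carry a
single insertion (the modal array size is one pollinium), so the two
weightings rarely differ materially.

## Uncertainty

All uncertainty is resampling-based:

* **Bootstrap** (default $B = 1000$) with the inserted pollinium as the
  unit, the taxon's focal set and the control set resampled independently
  at their original sizes. The replicate standard deviation is reported as
  the SE and the 2.5th/97.5th percentile ranks (the 25th and 975th of
  1000 ranked values) as the confidence interval. Replicates that breach a
  partition domain are **dropped and counted**, not clamped: clamping
  inside the loop would shrink the SE toward zero and hide instability,
  whereas the reported drop count surfaces it.
* The pool frequency table and $r_p$ are treated as plug-in population
  parameters and held fixed across replicates. Re-estimating the
  round-robin table inside every replicate would conflate
  frequency-estimation noise with the array-resampling scheme; the
  dominant noise source at these sample sizes is the pollinium draw
  itself.
* **Pairwise bootstrap comparison**: two taxa differ (two-tailed) if more
  than 97.5% or fewer than 2.5% of $B$ randomly paired replicate
  differences are positive. Pairs are independent index draws — the two
  taxa's bootstraps resample different record sets, so no alignment
  exists to exploit. Ties count as not-greater.
* **Permutation tests** for per-visit effectiveness (zero-inflated,
  continuous, no distributional assumptions): absolute mean difference
  for two groups, size-weighted between-group sum of squares for more,
  with the add-one Monte-Carlo p-value $(1 + \#\{\text{perm} \ge
  \text{obs}\})/(B+1)$, which cannot return zero at finite $B$.
* **Products of estimates** (importance = effectiveness × abundance;
  SICPI adds the selfing rate): component bootstrap distributions are
  combined replicate-wise and the percentile interval taken on the
  combined replicates. If a selfing bootstrap arrives with dropped
  replicates, it is resampled with replacement up to $B$ before
  combination.

## Pollinator metrics

Effectiveness (PE) is pollinia inserted (female function) or removed
(male function) per focal-inflorescence flower per visit, minus the mean
per-flower control rate, floored at zero; it is computed per visit and
then averaged per taxon, because the permutation machinery operates on
the per-visit vector. The per-flower control subtraction (rather than
per-inflorescence) matches PE's own per-flower units. Relative abundance
is the taxon's share of included visits, with nocturnal visit counts
multiplied by the sampling-effort ratio (diurnal hours / nocturnal hours)
first; the ratio is study-specific and must be supplied — there is no
defensible universal default beyond 1. Importance is
$PI = PE \times \text{abundance}$, and the self-incompatibility-controlled
variants discount the selfed share that a self-incompatible plant wastes:

$$SICPI_I = PI_I\,(1 - S_{mp}\,SI), \qquad
SICPI_R = PI_R - PI_I\,S_{mp}\,SI,$$

with $SI = 1 - \text{self-compatibility}$ and self-compatibility
defaulting to 0.05, a conservative literature value for a strongly
self-incompatible milkweed. The multiplicative form for insertions is the
only parenthesisation under which SICPI reduces exactly to PI when either
selfing or self-incompatibility vanishes, consistent with the subtractive
male-function form; both identities are pinned in the tests. $SICPI_R$ is
clamped at zero with a flag if the subtraction goes negative.

## The synthetic-study generator

`simulate_study()` generates complete studies with ground truth attached,
so every estimator is testable without any field data:

* **Population**: `n_genets` (default 20) genets with multilocus
  genotypes drawn from per-locus Dirichlet allele frequencies
  (concentration 0.5 by default, giving most-common-genotype frequencies
  per locus around 0.5–0.65 — the skew typical of microsatellite panels
  in clonal populations), each genet replicated over a geometric number
  of ramets (mean 10). Four loci and six alleles per locus by default.
* **Visits**: three default taxa patterned after a milkweed visitor
  assemblage — an efficient, high-selfing honeybee (75 visits), an
  abundant low-deposition bumblebee (271), and sparse nocturnal
  lepidopterans (43). Flowers visited are negative binomial; insertions
  and removals are binomial per flower visited, capped at five per open
  flower (five stigmatic slits and five pollinaria per flower).
* **Selfing**: each inserted pollinium is self with probability
  $\text{logit}^{-1}(\beta_0 + \beta_1 (I - I_0) + \beta_2 (Z - Z_0))$ in
  centred inflorescence size $I$ and stem size $Z$, so the exported
  per-genotype table has a known display-size signal. Outcross donors are
  drawn genet-uniformly by default; the `"ramet"` option draws stems
  instead, and a draw landing in the focal genet counts as self —
  modelling high geitonogamous carryover within spatially aggregated
  clones.
* **Contamination**: every bagged inflorescence — control *and* focal —
  receives Poisson through-bag insertions (default rate 0.3 per
  inflorescence, 100 controls) whose selfing follows a display-size-free
  control model. This makes the control partition genuinely necessary:
  with distinct visitor and bag selfing levels the uncorrected rate is
  visibly pulled toward the bag process, and the corrected $S_{dp}$
  recovers the visitor-only truth (asserted in the acceptance suite).
* **Truth**: per-pollinium origin and self labels, per-taxon visitor-only
  selfing rates, and an exhaustive chance-match probability (per locus,
  the share of genets carrying the donor's single-locus genotype,
  multiplied across loci).

What the generator does **not** emulate: spatial foraging paths and
clonal spatial autocorrelation, nectar dynamics, pollinium-load feedback
on behaviour, genotyping error (as opposed to missingness), and
between-family heterogeneity within the lepidopteran group. Passing the
recovery suites therefore demonstrates the estimators are correct under
the stated generative model, not that field data meet that model.

## Validation problem sizes

The acceptance suite runs recovery at 500 genotyped pollinia per taxon
across ten seeds (four loci, six alleles: maximum absolute $S_{mp}$ error
below 0.05; two alleles: raw $S_d$ upward bias of at least 0.05 on
average), contamination correction at rate 0.3 with 100 controls and
$B = 1000$, pairwise-bootstrap calibration over 200 null repetitions, and
permutation calibration over 500 null runs — sizes at which the checks
are sharp while the whole suite stays comfortably under a coffee break.

## Worked example

```{r example, eval = FALSE}
study <- simulate_study(simulation_config(seed = 1))
cfg <- run_config(n_bootstrap = 1000, rng_seed = 2)
run <- run_pipeline(study$visits, study$genotypes, cfg,
                    out_dir = "results")
print(run$selfing)
coef(run$selfing)            # named per-taxon S_mp
confint(run$selfing)         # percentile bootstrap intervals
summary(run$importance)      # PE / PI / SICPI table with CIs
```

## Known limitations

* The method-of-moments inversion assumes the chance-match probability is
  well estimated by the pool product form; strong linkage between loci or
  genotyping error would bias it, and neither is modelled.
* $r_p$ relies on controls and focal inflorescences sharing the same
  through-bag exposure; differing bagging durations would require an
  exposure adjustment the visit table does not carry.
* Maternal-genotype grouping treats identical multilocus genotypes as one
  genet; with weak markers this can merge distinct genets (the same
  limitation the round-robin estimator mitigates for frequencies).
* No likelihood-based mating-system estimation, paternity assignment, or
  GLM/GLMM fitting: the per-genotype $S_{dp}$ table is exported for
  external regression tooling instead.
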