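---
title: "Latent class trajectories from an accelerated longitudinal design: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent class trajectories from an accelerated longitudinal design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aldlca)
```

## The problem

Aging panels such as the Mexican Health and Aging Study (MHAS) interview
adults aged 50+ a handful of times over 10--15 years, far short of the 30+
years over which living arrangements evolve. An accelerated longitudinal
(cohort-sequential) design stretches the observation window by linking the
short, temporally overlapping age segments contributed by different birth
cohorts: a cohort first seen at ages 50--53 and a cohort first seen at ages
62--65 jointly cover ages 50--69 after a decade of follow-up. `aldlca`
implements that rearrangement, a multigroup latent class model estimated on
the rearranged array, class-enumeration statistics, and per-class trajectory
profiles, together with a synthetic panel generator that stands in for the
restricted survey micro-data.

## The design bookkeeping

The default `design_schedule()` uses four waves (2001, 2003, 2012, 2015),
nine age columns ([50--53], [54--57], ..., [82+], with nominal mean ages
52, 55, ..., 86) and twelve birth cohorts from 1909--1919 (cohort 1) to
1959--1962 (cohort 12). Cohorts 10--12 enter with the 2012 refreshment
sample. A person's cohort is fixed by their birth year (entry wave year minus
age at first interview); their baseline column is the bracket containing
their entry age; later waves advance the column by a per-entry-stream offset
(+0, +1, +3, +4 from 2001; +0, +1 from 2012), mirroring the roughly 2-, 11-
and 14-year gaps between waves. Two conventions deserve comment:

* **Cell-to-cohort rule.** Within a wave, the cohort occupying age column
  $j$ is `anchor + 1 + offset(wave) - j` (anchor = cohort 9, the youngest
  2001 cohort). This single staircase rule reproduces every non-empty cell
  of the published cohort-by-age-column table from the published
  wave-by-age-column counts -- including the refreshment cohorts 10--12,
  which fall out of the same formula -- and is verified exactly in the test
  suite. Records that would advance beyond column 9 return no column rather
  than being clamped: the oldest cohorts genuinely leave the design, which
  is why their rows terminate early.
* **Cohort bins.** The published bins overlap at 1951 (cohort 9 ends in
  1951, cohort 10 is printed as starting in 1951) and some printed per-cohort
  age ranges disagree with the bins. The package requires disjoint bins and
  resolves the overlap in favour of cohort 9, relying on birth years only.

Panel members keep their cohort at every follow-up even when their exact age
drifts out of the column's nominal bracket; this keeps each person on their
cohort's diagonal, which is what makes the staircase exact.

## The model

For person $n$ with latent class $X = s$ ($s = 1, \dots, S$), binary
indicators $M_{it}$ (items $i = 1, \dots, 10$: nine household markers plus
respondent sex; time points $t = 1, \dots, 9$) are conditionally
independent:

$$P(\mathbf{M} = \mathbf{m}) \;=\; \sum_{s=1}^{S} \pi_s \prod_{(i,t)\ \mathrm{observed}} p_{sit}^{\,m_{it}} (1 - p_{sit})^{1 - m_{it}}.$$

Cohorts enter as groups, but under the fully invariant ("completely
equivalent") specification both the class proportions $\pi_s$ and the item
probabilities $p_{sit}$ are restricted equal across cohorts, so the
parameter set carries no group index and class membership cannot be
predicted from cohort. The product runs over each person's *observed* cells
only: the staircase missingness is determined entirely by cohort and entry
wave, hence missing at random by design, and enters the likelihood through
omission alone. Estimation is by EM; the M step pools all cohorts in one
posterior-weighted update, which *is* the equality restriction.

Key numerical choices:

* **Initialisation**: item probabilities start at the observed marginal
  means perturbed by Uniform($-0.15, 0.15$), clamped to $[0.05, 0.95]$;
  class proportions start uniform; `n_starts = 20` by default (small,
  well-separated problems need far fewer).
* **Convergence**: relative log-likelihood change below `tol = 1e-6`
  (default), `max_iter = 1000`; the best converged start wins, and a run
  where no start converges is returned flagged rather than hidden.
* **Clamping**: probabilities live in $[10^{-6}, 1 - 10^{-6}]$, preventing
  boundary divergence of the log-likelihood; cells observed for no person
  keep their previous value and are flagged (`empty_cells`), since their
  thresholds are not identified.
* **Label switching**: classes are reported by descending proportion;
  recovery experiments additionally align labels to the generating truth by
  exact search over all $S!$ permutations of the item-probability profiles
  (optimal, and trivially cheap for $S \le 6$; an assignment-problem solver
  would be overkill at this size).
* **Degeneracy**: a class whose posterior mass falls below $10^{-8}$ aborts
  the chain; other starts continue.

## Class enumeration

`enumerate_classes()` fits $S = 1, 2, \dots$ with shared settings and
reports $-2\log L$, BIC, relative entropy
$1 - \sum_{n,s}(-p_{ns}\log p_{ns}) / (N \log S)$, relative class sizes, and
the range across classes of the average posterior among assigned members.
Two parameter-counting modes are printed, because the published deviance/BIC
gaps do not settle which thresholds the original analysis counted: `all`
($(S-1) + 90S$) and `observed` (only data-supported cells). The BIC sample
size is the number of persons contributing at least one observed cell -- the
unit of analysis is the individual. A Lo--Mendell--Rubin test is deliberately
not provided.

Two honest caveats about enumeration on synthetic data. First, BIC reliably
finds the generating class count when classes are well separated (the test
suite checks 9 of 10 replicate panels at the default scale), but
this says nothing about weakly separated real data. Second, the relative
entropy of an *overfitted* model ($S$ above the generating count) is
intrinsically low: the extra class must split a true class on sampling
noise, and that split is diffuse. On an exactly-3-class population we
measure entropy $\approx 0.92$ at $S = 2, 3$ but 0.78--0.93 at $S = 4$ --
more EM starts make it *lower*, because the better optimum is the genuinely
fuzzier split. Uniformly high entropy across a whole enumeration table, as
published analyses of real aging panels report, therefore indicates
structure beyond a clean small-$S$ mixture, and is not a behaviour a
correctly specified 3-class simulation can or should reproduce.

## The synthetic generator

`generate_population()` emulates an MHAS-like panel: `n_baseline = 8000`
persons enter at wave 1 with birth years uniform on 1909--1951 (age
$\ge 50$ at entry), `n_refresh = 2000` enter at wave 3 with birth years
1952--1962 (the newly age-eligible refreshment cohorts); both scales are the
same order as the real survey while staying desk-friendly. Class membership
is drawn once per person (defaults: proportions 0.40/0.35/0.25); each of
the nine markers follows a class-specific logistic-in-age prevalence curve;
attrition removes persons permanently before each follow-up with
probabilities 0.06/0.35/0.11 (calibrated to the published wave totals'
retention pattern, with the big loss across the nine-year gap), increasing
with age on the logit scale (0.03/year around age 70) and independent of
class by default -- missing at random by design; a per-class hazard shift is
available for robustness experiments.

The default curves encode three archetypes -- a large multigenerational
household class, a couple/emptying-nest class, and a small household class
without a partner -- with endpoints at ages 52 and 86 calibrated loosely to
published marginal trends (partner presence falling from about 78% to 35%,
grandchildren rising from about 21% to 34%, children present falling from
82% to 55%) and with class contrasts chosen large enough that the classes
are well separated (relative entropy above 0.9 at the generating $S$),
which is the regime the enumeration checks assume.
`separated_item_curves()` provides the flat two-level (0.1/0.9) patterns
used in recovery experiments.

One deliberate deviation from a tempting realism: respondent sex is drawn
*independently at each observed wave* given class (class-conditional
probabilities 0.80/0.15/0.90 -- the classes are strongly gendered), not once
per person. Replicating a time-constant, non-degenerate Bernoulli across
2--4 time points is within-person dependence that the conditional-
independence model cannot express, and it is strong enough to make BIC
prefer a fourth class that splits on sex -- we measured exactly that for
every sex probability tried, including nearly degenerate ones. Since the
generator's purpose is a clean test of the estimator, its default satisfies
the model's independence structure at every cell;
`sex_time_constant = TRUE` switches the realistic violation back on for
robustness work. More generally the generator does *not* emulate household
size counts, mortality as distinct from dropout, serial correlation in
markers, or cohort-skewed class membership -- so passing tests demonstrate
correctness of the estimator under its own assumptions, not robustness to
the dependence structures real household rosters contain.

## Trajectory profiles

`marker_prevalence()` tabulates observed-cell prevalences by item and time
point; `class_profiles()` does the same per class, weighting persons by
posterior membership (default) or modal assignment, carrying per-cell
effective sample sizes, and distinguishing never-observed cells (`NA`) from
zero prevalence. For posterior weighting, averaging the class profiles with
each class's posterior mass in a cell recovers the overall prevalence as an
exact identity (`mixture_check()`). Profiles are reported as prevalences --
shares of households exhibiting a marker -- against the columns' nominal
mean ages; average member *counts* per household are not reconstructable
from dichotomous indicators and are out of scope.

## Problem sizes used in the checks

The test suite exercises the full default scale (10,000 persons) for class
enumeration (10 replicate panels, $S = 1$--4, 3 EM starts -- ample for
well-separated classes), 4,000 persons for recovery (10 replicates), and
complete enumeration of all two-item, two-class instances with up to 10
persons (173 after symmetry reduction) against a multi-stage dense
grid-search oracle with final step $10^{-3}$ on the same clamped parameter
cube. These sizes were chosen so the whole suite documents the estimator's
behaviour at the survey's own order of magnitude.

## A worked run

```{r example, eval = FALSE}
sch <- design_schedule()
cfg <- synthetic_config(seed = 1)
pop <- generate_population(cfg, sch)
ald <- rearrange(pop$panel, sch)
sel <- enumerate_classes(ald, 1:4, n_starts = 3, seed = 2)
print(sel)
best <- attr(sel, "models")[[paste0("S", attr(sel, "best_bic_S"))]]
prof <- class_profiles(best, ald)
head(profile_report(prof, sch))
```

## Known limitations

* Full invariance only: partial measurement invariance (cohort-specific
  item probabilities for some cells) is not implemented.
* No standard errors or bootstrap intervals for the fitted parameters.
* Ordinal/count indicators, covariates on class membership, and hidden
  Markov transition structure are out of scope.
* The published mean consecutive-wave overlap statistic has no stated
  definition recoverable from the printed tables; `overlap_statistics()`
  reports the share of wave-$w$ participants reappearing at wave $w+1$ and
  their mean, which need not match other definitions.
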