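---
title: "Scoring developmental surveillance data: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring developmental surveillance data: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(devsurv)
```

## The problem

Developmental surveillance records whether a child attains discrete,
age-appropriate milestones ("walks alone", "says two words") at routine
well-child visits. Unlike physical growth, where a weight percentile is
immediately interpretable, a milestone result is binary, and a visit
produces a handful of them across four developmental domains (gross motor,
fine motor, language, personal-social). devsurv turns these binary results
into a single quantitative score per child, time window and domain group,
and summarises a child's longitudinal development as a seven-entry
trajectory vector that can be clustered into interpretable patterns.

## The score

The backbone is an age-normed developmental scale: for each milestone,
the ages `t75`, `t90`, `t95` by which 75%, 90% and 95% of the reference
population attain it, bracketed by `t0` and `t100`, the minimal and maximal
assessed ages. These thresholds cut the assessed range into four severity
brackets

\[
b_1 = [t_0, t_{75}],\quad b_2 = (t_{75}, t_{90}],\quad
b_3 = (t_{90}, t_{95}],\quad b_4 = (t_{95}, t_{100}].
\]

An attained milestone scores 0. A failed milestone scores the index of the
bracket containing the evaluation age — the **discrete milestone attainment
score (DMAS)**: failing a milestone most peers haven't attained yet costs 1;
failing one that over 95% of same-age peers attain costs 4.

The discrete score jumps at bracket boundaries, so the package's default is
the **linearized score (LMAS)**: the unique continuous piecewise-linear
function of age that is 0 at `t0`, reaches `i` at the upper end of bracket
`i`, and is linear in between,

\[
\mathrm{LMAS}(a) = (i - 1) + \frac{a - a_{\min}}{a_{\max} - a_{\min}},
\qquad a \in b_i = (a_{\min}, a_{\max}].
\]

Two consequences of the construction are worth stating. First, a failure
exactly at `t0` scores 0 even though its discrete score is 1 — forced by
continuity. Second, within a zero-width bracket (step-like attainment
curves can make consecutive thresholds coincide) the right-limit value `i`
is returned, and bracket lookup resolves a boundary age to the
highest-index bracket whose closed upper bound equals it, keeping the map
total. Ages outside `[t0, t100]` are clamped to the nearest endpoint before
lookup, because real visit records can fall slightly outside the assessed
range. Ages are fractional months (days / 30.4375) throughout.

The **developmental surveillance score (DSS)** for a query — an age window
crossed with a set of domains — is the plain arithmetic mean of the
per-attempt scores of all matching attempts. Every attempt counts, including
re-attempts of a previously failed milestone, each scored at its own
evaluation age. When no attempt matches, the DSS is *undefined* and returned
as `NA`, never 0: a zero score asserts that everything attempted was
attained, which is a materially different statement. Attainments documented
by parent report count exactly like clinic-observed ones.

## Trajectories

A child's trajectory for a domain group (`motor` = gross + fine motor,
`language_social` = language + personal-social) is the vector of DSS values
over seven age steps: 1-3, 3-6, 6-9, 9-12, 12-18, 18-24 and 24-36 months.
Conventions the data force us to fix:

* steps are half-open `[low, high)`, the last closed at 36 months, so a
  boundary age (exactly 12 months) bins deterministically into the later
  step;
* ages in `[0, 1)` month (the post-discharge contact) fold into step 1;
* an attempt is binned by the age at which it was evaluated, not by the
  step its milestone nominally belongs to — the score is age-dependent by
  construction, so a re-attempt at a later visit belongs to the later step.

Children missing any step are excluded from clustering (no imputation);
`filter_complete()` reports how many.

## Clustering and pattern labels

Complete vectors are partitioned with k-means (default `k = 4`). Because
one step per domain group contains a single milestone (step 5 for motor,
step 3 for language-social in the generated battery), that entry is noisy
and is dropped from the clustered features — six of the seven entries —
while centroids are reported over all seven. Initialization is k-means++
with `n_init = 10` restarts under a fixed seed, keeping the best
within-cluster sum of squares; results are reproducible bitwise. A
full-covariance Gaussian mixture (`method = "gmm"`, via mclust with a
conjugate prior regularizing the covariances — many children share the
exact all-zero vector) is available for sensitivity analysis. Validity is
the Calinski-Harabasz index, between- over within-cluster dispersion each
divided by its degrees of freedom.

Centroids are labelled with a quantification of the qualitative patterns
seen in clustered surveillance cohorts:

* **adequate** — every entry below `theta_low` (default 0.15);
* **catching up** — first entry at least `theta_high` (default 0.5) and the
  last two entries below `theta_low`;
* **worsening** — last entry at least `theta_high` and above the first;
* **other** — anything else, e.g. a mid-trajectory bump that resolves.

The defaults were chosen so that published example centroids of each
pattern type label correctly; they are configurable. Under the defaults the
catching-up and worsening rules are mutually exclusive (`theta_low <
theta_high`); the tie-break to `other` matters only for custom thresholds.

## Subgroup statistics

Group comparisons use the Mann-Whitney U test computed from midranks.
Surveillance scores are heavily tied at 0, which dictates two choices: the
exact path (combined n of at most 20) enumerates assignments of the pooled
midranks, and the large-sample path uses the tie-corrected variance with a
continuity correction; p-values are two-sided and unadjusted (stars at
.05/.01/.001). Stratified summaries report every stratum, including empty
ones, and a child missing the stratifying covariate is dropped from that
stratification only. All subgroup analyses exclude children born before 37
gestational weeks — except the stratification by gestational age itself,
which is the one analysis that keeps them; the pipeline driver enforces
this. Postpartum depression is flagged from the EPDS as total ≥ 10 or a
nonzero self-harm item, and prematurity strata are <27, 27-31, 32-36,
37-38, ≥39 weeks.

## The synthetic cohort

No surveillance registry ships with the package, so a generator produces a
cohort with the statistical structure the analyses assume.

**Scale.** 59 milestones across the four domains, each with a logistic
attainment curve anchored to the visit schedule (1, 2, 4, 6, 9, 12, 18, 24,
36 months): the curve reaches 99.3-99.9% attainment at the milestone's
scheduled visit, so a typical child passes what is expected at their age
and sporadic failures are rare; curve width grows with age (≈0.17 months at
the 1-month visit to ≈1.7 months at 36 months). Thresholds are derived from
the curves by `thresholds_from_curve()`, and the allocation leaves exactly
one single-milestone step per domain group to mirror the battery structure
the clustering must cope with.

**Children.** Covariates are drawn from marginals resembling a population
registry (48.8% female; gestational age 23-42 weeks with ≈6.9% preterm;
birth weight correlated with gestational age; maternal age with ≈14% aged
40-50; education normalized from registry proportions with 8% missing;
EPDS-based PPD positivity ≈4%). Each child has a latent *ability* curve, an
age shift in months: attainment of milestone $m$ at age $a$ is Bernoulli
with probability $\mathrm{curve}_m(a + \mathrm{ability}(a)\,s_m)$, where
$s_m$ scales with the milestone's curve width so that one unit of ability
moves every milestone by the same number of curve widths. Covariate effects
(male sex, prematurity per week, a U-shaped birth-weight effect, a maternal
education gradient, maternal age 40+, PPD, birth order) add months of
ability; the defaults produce the monotone subgroup orderings the score is
meant to surface, at magnitudes detectable around n = 10,000.

**Archetypes.** A mixture (defaults 75/13/4%, remainder a mid-trajectory
bump) plants trajectory shapes: catching-up children start ≈2-3 months
behind and resolve by 12 months; worsening children fall progressively
behind from 6 months; the bump peaks between 6 and 10 months and resolves.
The deltas are drawn per child (truncated normals around 2-3 months) and
were set so that the three archetypes are recoverable from a cohort of
2,000 children — the scale at which the package's end-to-end checks run —
with at least 90% agreement after label matching. That separation is
stronger than what a million-child registry needs, and the resulting
centroid magnitudes are correspondingly larger than published ones; the
generator emulates the *structure* of such data, not its effect sizes.

**Visits.** Each visit is attended independently with probability 0.95 and
happens at its scheduled age plus a uniform delay of up to a quarter month
at day resolution — a delay, not symmetric jitter, because visits at step
boundaries (6, 9, 12, 18, 24 months) must stay inside their scheduled age
step. A failed milestone is re-attempted once at the child's next attended
visit. With nine visits this yields ≈73% of children with complete
trajectory vectors.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: real age-norm thresholds (the generator's curves
are parametric logistics); joint covariate distributions (only univariate
marginals); informative dropout (attendance is independent of development);
assessment error and milestone-specific reporting quirks; visits beyond 36
months. Recovery results on this cohort demonstrate that the pipeline's
machinery is correct, not that real trajectories separate this cleanly.

## Numerical choices and degenerate inputs

* Undefined scores propagate as `NA`, never silently as 0.
* Zero within-cluster dispersion yields an infinite validity index.
* All-identical trajectory vectors cannot be meaningfully partitioned: the
  children are spread evenly so every centroid equals the common vector;
  more generally, fewer distinct vectors than clusters is an error.
* Degenerate (zero-width) brackets are permitted and flagged; scoring at
  their boundary uses the right-limit convention described above.
* Every stochastic step takes an explicit integer seed; the pipeline
  derives per-stage seeds from one master seed, and reruns are
  byte-identical.

## Problem sizes used by the test suite

End-to-end archetype recovery and pattern counting run at n = 2,000
children; covariate-effect recovery at n = 10,000; the attainment-curve
coverage check at n = 5,000 with ≥ 30 observations per (milestone, age)
bin; rank-sum calibration uses 5,000 null replicates of two samples of 100.
These sizes were chosen as the smallest at which the planted structure is
comfortably resolvable, so the whole suite runs in a few minutes on one
CPU.

## Limitations

The score is a surveillance summary, not a screening instrument: it has no
calibrated cut-offs against evaluation tools, and the package deliberately
does not provide any. Pattern labels quantify qualitative descriptions and
depend on two thresholds; clusters themselves depend on `k`, which the
package reports validity for but does not select. The Mann-Whitney exact
path is limited to combined samples of 20 and the comparisons are
unadjusted for multiplicity, mirroring standard practice in the field's
descriptive tables.
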