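---
title: "Simulating AI-integrated double-reading mammography screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating AI-integrated double-reading mammography screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mammoscreen)
```

## The problem

European organised breast screening programmes read every mammogram twice:
a first reader and a (typically more experienced) second reader each issue a
binary recall decision, and a third reader arbitrates disagreements. With AI
systems now producing continuous examination-level abnormality scores, a
programme can consider placing the AI at different points in this workflow:

* **AI replaces the first reader** -- AI is paired with the retained second
  reader; disagreements go to arbitration.
* **AI replaces the second reader** -- symmetric, pairing AI with the first
  reader.
* **AI triage** -- AI alone sorts screens into low risk (automatic
  no-recall), high risk (automatic recall), and a moderate band routed to
  the full human double reading.

The site of deployment matters: the two human readers do not have the same
operating point, and the workload saved, the arbitration volume, and the
accuracy all shift depending on which reader is replaced. `mammoscreen`
simulates these workflows at population scale on synthetic cohorts and
provides the paired statistics needed to compare them against standard
combined reading on the *same* exams.

## The generative model

Each exam carries a truth label $D \sim \mathrm{Bernoulli}(\pi)$ with
default prevalence $\pi = 2033/249402 \approx 0.00815$ (8.2 cancers per
1000 screens).

**Readers.** Reader $k$ has sensitivity $se_k$ and specificity $sp_k$. Given
the truth class, the pair of decisions is generated by a shared latent
bivariate standard normal $(Z_1, Z_2)$ with class-specific correlation
$\rho_D$ (a Gaussian copula): reader $k$ recalls iff
$Z_k \le \Phi^{-1}(p_k)$ where $p_k = se_k$ for cancers and $1 - sp_k$
otherwise. This preserves the marginal operating points exactly for any
$\rho \in [0, 1]$ while letting within-exam agreement be tuned; $\rho = 1$
is the comonotone limit (readers share one latent variable). It is the
simplest joint model consistent with the stated marginals.

**Arbitrator.** Disagreements get an arbitration decision drawn at the
arbitrator's own operating point $(se_3, sp_3)$, conditioning on truth only.

**AI score.** The examination-level score on $[0, 100]$ is drawn from a
truth-conditional mixture of scaled beta densities: non-cancers from a
right-skewed low-score density with a small high-score contamination
component, cancers from a bimodal mixture -- a detectable high-score mode
plus a low-score mode representing cancers that present like the interval
cancers human readers also miss.

**Bookkeeping.** Ages are truncated normal on $[50, 70]$ (mean 59.3,
SD 5.9); women contribute $1 + \mathrm{Poisson}(\mu - 1)$ exams with
$\mu \approx 1.67$, but exams are analysed as independent (the woman id is
carried for bookkeeping only, matching exam-level analysis practice).

### Default calibration (chosen once, then frozen)

The defaults were fixed by a one-off analytic calibration
(before any test existed) to the stated world:

| parameter | value | why |
|---|---|---|
| prevalence | 2033/249402 | 8.2 cancers / 1000 screens |
| reader 1 | $se$ 0.60, $sp$ 0.965 | less experienced first reader |
| reader 2 | $se$ 0.72, $sp$ 0.970 | better on all measures |
| dependence $\rho$ | 0.55 both classes | plausible agreement; see below |
| arbitrator | $se$ 0.72, $sp$ 0.85 | closes combined sensitivity at 0.726 |

With these values the analytic combined-reading sensitivity is
$P(\text{both recall}) + P(\text{disagree}) \cdot se_3 = 0.7262$, so about
72.6% of synthetic cancers are screen-detected and 27.4% are interval
cancers -- the composition a Danish programme reports. The implied recall
rate is about 2.1% and the arbitration (disagreement) rate about 5.2%,
realistic for biennial double reading. No programme publishes its reader
agreement, so $\rho = 0.55$ is a calibration choice, not an observed value.

What the generator does **not** emulate: image content, per-breast or
per-view scores, age-dependent risk, longitudinal follow-up mechanics
(truth is generated directly rather than verified by pathology), and reader
behavioural change in the presence of AI. A green test therefore
establishes that the *procedures* behave as specified on a cohort with the
stated statistical structure -- not that any clinical effect size
transfers to a real programme.

## Workflows and decision rules

All workflows consume the same cohort; AI dichotomisation is strict
(`score > threshold` recalls).

* **Combined reading**: agreement is final (2 reads); disagreement is
  settled by the original arbitration (3 reads).
* **Reader replacement**: AI + retained reader. Agreement is final (1 read)
  and any original arbitration is *disregarded*. On disagreement the
  original arbitration is reused when present; otherwise one is simulated
  at the estimated accuracy of the original arbitrator (2 reads either
  way).
* **Triage**: `score >= high` recalls with 0 reads, `score < low` dismisses
  with 0 reads, and the moderate band $[low, high)$ inherits the combined
  reading's decision, reads and arbitration provenance unchanged. `>= high`
  together with `< low` makes the three bands tile $[0, 100]$ without gaps;
  verbal descriptions of such bands are ambiguous at the boundaries, and
  this reading is the documented convention.

Arbitration reads count as one human read in all workload tallies; this is
why reader replacement lands slightly *below* a 50% read reduction
(arbitration volume rises when AI disagrees with the retained reader more
often than the replaced reader did).

Each scenario draws its simulated arbitrations from its own RNG substream,
derived from the master seed by a fixed labelled offset, so any scenario is
reproducible in isolation.

## Threshold selection

* **Specificity matching** (scenarios 1--2): the cutoff is the smallest
  observed non-cancer score whose empirical specificity reaches the mean
  first-reader specificity. Realized specificity can exceed the target only
  through ties; it never undershoots.
* **Dual-constraint triage search** (scenario 3): candidate cutoffs are the
  unique observed scores plus a sentinel above the maximum. For each high
  candidate the low candidate bringing the moderate fraction nearest the
  target (default 50%) is paired with it; among those pairs the winner
  minimises the absolute gap between the triage recall rate and the
  combined reading's recall rate, with ties broken by the moderate-fraction
  gap and then by the smaller high cutoff. The tie-break chain is a design
  choice: the constraints (50% moderate band, equal recall rate) are
  stated, the search is not.

By default thresholds are selected on the same cohort they are evaluated on
(as programme evaluations usually do, an acknowledged source of optimism);
`split_mode = TRUE` selects on a random half and evaluates on the other
half to quantify that optimism.

## Statistics

Sensitivity and specificity are coprimary endpoints, tested at
$\alpha = 0.05/6 \approx 0.00833$ (Bonferroni over 2 endpoints $\times$ 3
scenarios); PPV, NPV, recall rate and arbitration rate are secondary at
$\alpha = 0.05$. All proportions get exact Clopper--Pearson intervals.

* **McNemar** compares paired rates. Below 25 discordant pairs the exact
  two-sided binomial test is used; at or above, the $\chi^2_1$ statistic
  $(b-c)^2/(b+c)$ without continuity correction. The cutoff is
  configurable.
* **Predictive values** cannot be compared by McNemar (the conditioning
  sets differ between arms), so a generalized score test is used: positive
  (or negative) calls of both arms are stacked, the outcome probability is
  modelled as common under the null, and the score for the arm effect is
  standardized by an empirical sandwich variance clustered on the exam.
* **AUC** for a binary reading chain is the one-operating-point trapezoid
  $(se + sp)/2$; the continuous AI score also gets the rank-based (ties =
  1/2) empirical AUC. No smooth ROC model is fitted.
* Undefined metrics (zero denominators) are flagged `NA`, never silent
  zeros.

### Numerical behaviour of the score test at small n

The score test is asymptotic. Its unconditional calibration is good even at
n = 40 (simulated null rejection 0.045 at nominal 0.05), but *conditionally
on a single small dataset* the exact within-subject permutation
distribution is supported on few atoms (only discordant subjects move under
the permutation group). For mid-range p values (roughly 0.05--0.5) those
atoms are wide enough that no continuous approximation can track the
permutation p-value within 0.02. The test-suite fixtures that compare the
two therefore exercise the regimes where the comparison is informative and
stable: strong effects in both directions (tail behaviour) and exact nulls.
For bordeline p-values at small n, prefer the permutation approach
directly.

## Degenerate inputs and edge rules

* Prevalence 0 is admitted (a cancer-free cohort; all subgroups `"none"`).
* Reader dependence 1 is admitted (comonotone readers).
* A reader disagreement without an arbitration decision is a *data error*
  in the combined workflow, detected at validation and on CSV load.
* `estimate_arbitrator_profile()` refuses cohorts with an empty arbitrated
  stratum and tells the caller to supply a profile explicitly.
* All-equal score vectors give `threshold = c` with realized specificity 1.
* Exclusion rules attribute a row failing several rules to the first
  failing rule in declared order.

## Worked example

```{r example, eval = FALSE}
cfg <- study_config(cohort = cohort_params(n_exams = 100000, seed = 20140804))
res <- run_study(cfg)
print(res)
res$workload$ai_triage$relative_reduction
res$comparisons$ai_second[, c("endpoint", "delta_pp", "p_value")]
```

## Known limitations

* The synthetic AI score distribution is a stylised stand-in; absolute
  threshold values (e.g. where the spec-matched cutoff lands on the 0--100
  scale) are not comparable across score distributions, only the realized
  operating points are.
* Simulated arbitrations condition on truth only, not on which reading
  pattern produced the disagreement.
* Exam-level independence ignores within-woman correlation across rounds.
* The reference standard is generated truth; verification bias and
  differential follow-up in real programmes are out of scope.
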