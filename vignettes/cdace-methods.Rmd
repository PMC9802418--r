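---
title: "Scoring small-bowel Crohn's disease activity with CDACE: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring small-bowel Crohn's disease activity with CDACE: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdace)
```

## The scoring model

Small-bowel capsule endoscopy (SBCE) produces a time-ordered image stream of
the small intestine. In Crohn's disease the readings of interest are mucosal
inflammatory lesions and stenoses. CDACE (Crohn's Disease Activity in Capsule
Endoscopy) summarises one capsule session in three components:

* **Li (location inflammation, 0–16).** Small-bowel transit is divided into
  four equal quartiles. Each quartile is graded 0–4 by its *worst* finding:
  0 normal mucosa, 1 edematous/reddish mucosa, 2 erosion (< 0.5 cm),
  3 irregular/circular ulcer (0.5–2 cm), 4 longitudinal/large ulcer or
  cobblestone appearance. Li is the sum of the four grades. Grading by the
  characteristic worst feature — not by lesion count — makes the score
  insensitive to frame-rate differences between capsule models (SB2 vs SB3),
  which is why `capsule_model` is metadata only.
* **R (range, 0–4).** The number of quartiles containing any inflammatory
  lesion.
* **S (stenosis, 0–3).** For the whole small bowel: 0 none, 1 a single
  traversed stenosis, 2 multiple traversed stenoses, 3 no passage.

The composite is positional:

$$\mathrm{CDACE} = 100\,\mathrm{Li} + 10\,R + S \in [0, 1643],$$

so the zero-padded four-digit rendering is directly readable: first two
digits Li, third digit R, fourth digit S. `Li/R` — the mean grade of the
inflamed quartiles — is the severity-of-inflammation index; we define it as
0 for a lesion-free study so that cohort summaries stay total functions. The
ratio is stored as a double: with Li ≤ 16 and R ≤ 4 every attainable ratio
is exactly representable for ranking purposes.

The encoding is *sparse*: only 140 (Li, R, S) triples are consistent
(R = 0 ⇔ Li = 0, and R ≤ Li ≤ 4R when R > 0, since each inflamed quartile
contributes between 1 and 4 points). `decode_cdace()` therefore validates
rather than accepting any integer ≤ 1643, and `cdace_triples()` enumerates
the full codomain. Because different quartile profiles can share one
composite (e.g. 1241 can be two quartiles of grade-4 ulcers or four of
grade 3 with one traversed stenosis), `score_cdace()` always emits the
components alongside the composite.

### Conventions the source description leaves open

* **Quartile boundaries.** Thumbnail positions at 25/50/75% of transit do
  not fix which side of a boundary a lesion belongs to. We use half-open
  intervals — a boundary timestamp belongs to the *later* quartile — and
  clamp the terminal timestamp into quartile 4. Any fixed convention would
  do; this one is deterministic and exhaustively tested
  (`assign_quartile()`, `tertile_of()`).
* **Lesions spanning a boundary** are assigned by their single annotated
  timestamp; the annotation model carries no lesion extent.
* **Incomplete studies.** When the capsule never reaches the colon, the
  small bowel is still quartiled over entry → last image. If any stenosis
  was annotated, S = 3 (no passage). If *no* stenosis was annotated (e.g.
  battery exhaustion), forcing S = 3 would silently conflate device failure
  with obstruction, so S keeps its annotation-derived value and the study is
  flagged `incomplete_no_stenosis` with a warning. The flag is part of the
  score row and of reports.

## Comparator scores

Cross-validation of a new index is done against the two established SBCE
scores, computed on the same annotation model:

* **Lewis Score.** Transit is divided into *tertiles*. Per tertile, a
  villous-edema subscore (number × longitudinal extent × descriptor points)
  and an ulcer subscore (number × extent × size points) are summed; the
  score is the worst tertile plus an independent whole-study stenosis
  product (number × ulcerated × traversed). The descriptor point tables are
  shipped as a plain-text file (`lewis_points()`), transcribed from the
  original publication of the score, so the transcription is auditable
  rather than buried in code.
* **CECDAI.** Proximal/distal segments by transit time; per segment
  inflammation A (0–5) × extent B (0–3) + stricture C (0–3); total is the
  sum, range 0–36.

`as_lewis_findings()` and `as_cecdai_findings()` map the annotation model
onto native findings objects. These adapters are deliberately labelled
*approximate*: a 0–4 categorical grade per lesion carries no villous-edema
extent or ulcer longitudinal extent, so fixed conservative conventions are
used (documented in the function help). They exist so simulated cohorts can
be scored by all three systems; native findings tables should be preferred
for real readings.

## Statistics

* **Spearman rank correlation** (`spearman_rho()`): average ranks for ties,
  large-sample two-sided p-value, delegated to `stats::cor.test()`.
* **Multilevel bowel lesion** (`multilevel_lesion()`): the per-score ground
  truth for "inflammation in several bowel regions". LS: more than 2 of 3
  tertiles inflamed. CECDAI: both segments inflamed. CDACE: at least two
  inflamed quartiles, excluding exactly two *consecutive* quartiles —
  adjacency means consecutive indices 1-2, 2-3, 3-4 with no wraparound,
  which has no anatomical meaning in an open tube.
* **ROC cutoff** (`roc_cutoff()`): empirical ROC with trapezoidal AUC
  (equal to the Mann–Whitney normalisation), cutoff maximising Youden's
  J = sensitivity + specificity − 1. The reported threshold is the midpoint
  between adjacent distinct score values; a positive test is score ≥ cutoff
  (all three indices increase with disease burden); ties in J are broken
  toward higher specificity, i.e. the larger cutoff. Youden maximisation and
  the midpoint convention are standard practice adopted as documented
  assumptions — the original analyses do not state their threshold rule.
  PPV and NPV are reported at the selected cutoff and therefore reflect the
  sample prevalence.
* **ICC(2,1)** (`icc_2_1()`): two-way random-effects, absolute-agreement,
  single-rater intraclass correlation (Shrout–Fleiss),
  $(MS_R - MS_E)/(MS_R + (k-1)MS_E + k(MS_C - MS_E)/n)$ from the two-way
  ANOVA mean squares, with the F-based 95% confidence interval
  (Satterthwaite degrees of freedom). p-values and intervals are reported,
  never used for automated decisions inside the package.
* **Shapiro–Wilk** (`normality_check()`): delegated to
  `stats::shapiro.test()`; re-deriving W would be re-implementing a solved
  problem.

## The synthetic cohort generator

Clinical SBCE datasets cannot ship with a package, so every statistical
operation is exercised on simulated cohorts with known ground truth
(`cohort_spec()`, `simulate_cohort()`, `simulate_reader_matrix()`).

Per study, the four quartile grades are drawn through a **Gaussian copula**:
a latent severity $z \sim N(0,1)$ is shared by the quartiles,
$v_q = \sqrt{\rho}\,z + \sqrt{1-\rho}\,\varepsilon_q$, and each $v_q$ is
binned by the cumulative grade probabilities. This preserves the requested
marginal grade distribution *exactly* at any inter-quartile correlation
$\rho$ (`latent_correlation`), and the same latent raises stenosis odds on
the logit scale — so CDACE, Lewis and CECDAI computed on one simulated
cohort correlate strongly, mirroring the strong inter-score correlations
observed clinically without claiming any particular coefficient. Lesion
timestamps are uniform within their quartile; each study draws from its own
stream derived from `(seed, index)`, so cohorts are bitwise reproducible
and any single study can be regenerated in isolation.

Defaults were chosen once to emulate a realistic referral cohort: 196
sessions; grade distribution (0.50, 0.18, 0.14, 0.11, 0.07) over grades
0–4, which puts the mean composite in the low-to-mid 400s as observed in
practice; stenosis prevalence 0.25 (about the fraction of stricturing
disease behaviour); probability 0.10 that a stenosis is not traversed
(intestinal patency is confirmed with a patency capsule before SBCE, so
most stenoses pass); incomplete-study rate 0.08; log-normal transit time
with median 4 h.

Reader matrices use the additive two-way model
$y_{ij} = \mu + s_i + r_j + e_{ij}$ with independent normal components —
the simplest model with a closed-form population ICC
$\sigma^2_s/(\sigma^2_s+\sigma^2_r+\sigma^2_e)$ against which the estimator
is checked. Optional rounding snaps cells onto the valid composite grid.

**What the simulator does not emulate:** real grade profiles are not
exchangeable along the bowel (terminal-ileal predominance is common);
reader disagreement on real images is not additive Gaussian noise on the
composite scale; lesion counts, capsule dwell and retention dynamics are
not modelled. Passing tests therefore demonstrate that the scoring and
statistical machinery is correct and well-calibrated under a known
generative model — not that CDACE has any particular operating
characteristic on clinical data.

## Problem sizes and numerical choices

The test suite works at sizes where exhaustive oracles are feasible: all
$5^4$ quartile profiles × 4 stenosis grades for encoding soundness (140
consistent triples), all 16 inflamed-quartile subsets for the multilevel
rule, full CECDAI segment grids, ROC instances of n ≤ 30 against
exhaustive-threshold enumeration, 1000 small random vectors for Spearman,
and ICC recovery on 500-subject × 3-reader matrices averaged over 20 seeds
(population ICC 0.8 recovered within ±0.03). End-to-end plumbing is
demonstrated on a 196-study cohort, the scale of the motivating clinical
series. Integer arithmetic is used throughout the composite; all validation
errors name the offending value or row.

## Known limitations

* Cohort-level clinical quantities (specific correlation coefficients,
  cutoffs such as 316 or 9, a particular ICC) depend on the clinical score
  distribution and are not reproducible from simulation; the package
  validates its machinery by parameter recovery and oracle agreement
  instead.
* The comparator adapters compress information the Lewis and CECDAI systems
  expect (extent descriptors); comparator scores derived from annotations
  are for pipeline exercises, not clinical reporting.
* CDACE itself is undefined for patients whose stenosis blocks the patency
  capsule — such studies never produce a reading to annotate.
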