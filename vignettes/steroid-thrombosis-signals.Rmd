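---
title: "Detecting steroid-associated thrombosis signals in spontaneous reports"
author: "steroidror"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting steroid-associated thrombosis signals in spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steroidror)
```

## The problem

Spontaneous adverse-event databases such as FAERS collect case reports in
which each case lists the drugs a patient received and the adverse events
(MedDRA preferred terms, PTs) that were reported. Disproportionality
analysis asks, for each drug, whether a class of events — here thrombotic
events — is reported *more often than expected* relative to all other
drugs in the database. The workhorse statistic is the reporting odds
ratio (ROR). This package implements a complete, testable version of that
workflow for drugs carrying a steroid backbone: ingestion and cleaning of
FAERS-dialect tables, chemical cohort selection, SMQ-scoped event
aggregation, ROR/Fisher screening, stratified and class-level summaries,
and multivariate profiling of the flagged drugs by PCA and Ward
clustering.

Because spontaneous-report extracts are huge and the MedDRA dictionary is
licensed, the package also ships a synthetic report generator with known
ground truth, so that every stage can be exercised, calibrated and
regression-tested offline.

## The statistical model

For a drug $g$ and an event set $S$ (a set of preferred terms), the
integrated report table — one row per (case, drug, PT) combination — is
cross-tabulated as

|                        | event in $S$ | event not in $S$ |
|------------------------|:---:|:---:|
| rows with drug $g$     | $a$ | $b$ |
| rows with other drugs  | $c$ | $d$ |

and the reporting odds ratio is
$\mathrm{ROR} = \dfrac{a/b}{c/d} = \dfrac{a\,d}{b\,c}.$

Three conventions matter and are fixed throughout:

* **Haldane correction.** When any cell is zero, 0.5 is added to *all
  four* cells before computing the ROR and its interval, keeping the
  estimate finite. The correction applies to the estimate only — never to
  the exact test. (An all-zero table is also admitted and regularizes to
  ROR = 1.)
* **Woolf interval.** The $1-\alpha$ confidence interval is
  $\exp\!\big(\ln \mathrm{ROR} \pm z \sqrt{1/a + 1/b + 1/c + 1/d}\big)$.
  The literature this pipeline serves reports 95% intervals without
  naming a method; the Woolf log interval is the standard
  pharmacovigilance choice and is the package's documented one.
* **Fisher's exact test** on the raw integer cells, two-sided by the
  point-probability (minimum-likelihood) rule: the p-value sums all
  hypergeometric point probabilities not exceeding the observed one.
  Two-sided conventions differ between implementations, so the rule is
  stated and pinned by an enumeration oracle in the test suite.

A drug is **flagged** as a signal when $\ln \mathrm{ROR} > 0$, $p <
\alpha$ (default 0.05, raw p-values — no multiplicity correction, which
is the screening convention; a Benjamini–Hochberg switch exists but is
off) and the drug has at least `min_drug_reports` adverse-event rows
(default 1000, a database-scale eligibility bound).

## From raw tables to the report table

`read_faers()` ingests the `$`-delimited quarterly dialect (DRUG, REAC,
DEMO, THER). Drug names and PTs are matched as normalized keys
(uppercase, collapsed whitespace); no salt stripping is attempted. Ages
convert to years from the FAERS unit code and values outside [0, 130]
years are kept but marked invalid. `integrate_reports()` inner-joins
DRUG and REAC on the case identifier, so a case with $k$ drugs and $m$
PTs contributes $k \times m$ rows. `dedup_reports()` removes duplicate
(case, drug, PT) triples — row-level deduplication, which reproduces a
row-unique integrated table; when a `caseversion` column is present only
each case's highest version survives. `monotherapy_filter()` then keeps
only cases whose distinct drug set has size one, so events are
attributable to a single drug; by default every reported drug counts
toward polypharmacy regardless of role code (a `suspect_only` switch
restricts the count to suspect drugs, since the convention is genuinely
ambiguous in practice).

## Cohort selection by scaffold

The steroid cohort is selected structurally: a drug belongs when its
SMILES representation contains the tetracyclic 6-6-6-5 gonane carbon
skeleton. The SMARTS pattern (`steroid_scaffold()`) uses element-only
atoms (`[#6]`) and any-order bonds (`~`), so saturated skeletons,
$\Delta^4$-ene A rings and the aromatic estrane A ring all match; no
stereochemistry or charge constraints are imposed. Matching runs through
OpenBabel (ChemmineR/ChemmineOB), is invariant to SMILES
canonicalization, and an unparseable SMILES is a distinct `NA` outcome
rather than a silent non-match. Name-to-structure resolution comes from
a local TSV dictionary so the stage runs offline; an allowlist
force-includes names with no usable structure (group labels such as
"STEROIDS") that an analysis may still need to carry. The test suite
pins the matcher against a 20-molecule hand-labelled fixture and
cross-checks every molecule against an independent engine (RDKit).

## Event terms

Thrombotic events are scoped by three SMQs — arterial, venous, and
unspecified/mixed embolism and thrombosis. MedDRA is licensed and is not
bundled; term sets are flat TSVs of (PT, scope). The packaged set
(`thrombosis_terms()`) carries 52 preferred terms; its per-term
arterial/venous/mixed labels are this package's curation from SMQ
membership — ambiguous terms default to *mixed* — and can be overridden
by supplying a user file.

## Multivariate profiling

Flagged drugs are profiled against well-reported thrombosis terms
(default: terms with at least 2000 rows) through a drug-by-term matrix
of $\ln \mathrm{ROR}$ values, each cell a single-PT 2×2 table with the
Haldane correction applied on zero cells, so all entries are finite.
PCA runs on the correlation scale (standardized columns) by default —
event columns have very different reporting volumes — with a
covariance-scale flag; component signs are fixed so each component's
largest-magnitude loading is positive. Whether to standardize was a
genuinely open choice; correlation-scale is the package's documented
default. Ward clustering (`hclust` method `ward.D2` on Euclidean
distances, merge heights $\sqrt{2\,\Delta\mathrm{ESS}}$) runs on the
first three component scores, and trees export as nested JSON, Newick
and a flat cluster table. The venous-versus-arterial contrast on a
chosen component compares *term loadings* grouped by SMQ scope with
Welch's t test, excluding mixed-scope terms; terms (not drugs) are the
unit of analysis because the scope annotation lives on terms.

## The synthetic generator

`sim_config()`/`simulate_reports()` emulate the FAERS structure the
pipeline ingests: per-case drug lists with polypharmacy and role codes,
per-case PT lists, sex/age/route demographics, therapy start dates, and
exact duplicate case submissions. The event model is deliberately the
simplest under which the ROR is identifiable: conditional on a case's
drugs, each term $t$ is included independently with probability
$p = \sigma\!\big(\mathrm{logit}(p_{0t}) + \textstyle\sum_d \ln
\theta_{dt}\big)$, where $p_{0t}$ is the baseline reporting probability
and $\theta_{dt}$ the configured reporting-odds multiplier. Expected
2×2 cells — and hence the expected ROR — follow in closed form
(`expected_contingency()`), which is what the calibration tests recover.
Ages are truncated-normal on [0, 110] years; duplicates are exact row
copies (fuzzy duplicates with new identifiers are out of scope).

What the generator does *not* emulate — within-case correlation between
terms, drug-name misspellings, time-varying reporting, confounding by
indication — bounds what passing tests show: they validate the
estimation machinery, not robustness to real-world reporting artifacts.

### Calibration conditions

Two fixed calibration settings back the quantitative guarantees:

* **Null:** $\theta \equiv 1$, 100 drugs, 20,000 cases, 100 seeds. The
  flag rate at $\alpha = 0.05$ must stay within binomial noise of the
  nominal level (it lands well below it, near 0.02, because the flag
  rule is one-directional and the exact test is conservative at small
  counts), and each drug's 95% interval must cover ROR = 1 in at least
  90% of seeds.
* **Recovery:** $\theta = 3$ planted at baseline 0.01 with 50,000 cases;
  the mean estimated ROR over 100 seeds must land within 10% of the
  closed-form expectation.

### The demonstration study

`example_study_config()` is the packaged worked example used by the
`analysis/` scripts: 50,000 cases over the 20-molecule fixture catalog
(10 steroids, 10 non-steroid comparators), nine thrombosis terms (four
venous, three arterial, two mixed) plus six background terms, 10%
polypharmacy, 5% duplicates, 60% female, ages $\mathcal{N}(58, 18^2)$
truncated to [0, 110]. Venous multipliers of 4 are planted on the three
sex-hormone drugs (testosterone, estradiol, norethisterone) and 2.5 on
estrone and progesterone; arterial multipliers of 3 on spironolactone
and 2.5 on dexamethasone. The strong effects are sized to be detected
with essentially unit power at this scale; the weakest (dexamethasone)
sits near the detection boundary by design, so runs illustrate both
detection and the boundary. Demonstration-scale thresholds
(`min_drug_reports = 200`, `min_pt_reports = 50`) replace the
database-scale defaults, which are proportioned to extracts three
orders of magnitude larger.

## Numerical choices and degenerate inputs

* p-values are floored at $10^{-300}$ before $-\log_{10}$ for volcano
  coordinates.
* Zero-variance matrix columns are dropped (with a warning) before PCA.
* `hclust`'s deterministic tie handling is used for Ward merges; on
  continuous scores exact ties have probability zero, and the
  identical-point case merges at height 0.
* Stratified RORs compare each stratum against *all other labelled
  strata*; unlabelled cases are excluded. This comparator is an explicit
  documented choice — spontaneous-report tables leave many cases
  unlabelled, and including them would silently change the question.
* The age contrast between event and non-event cases uses a two-sided
  Wilcoxon rank-sum test, matching a median-based summary.
* Class summaries pool member drugs' cells into a single 2×2
  ($\sum a$, $\sum b$ against all non-member reports); the pooling
  scheme is a documented choice.

## Known limitations

The pipeline inherits every epistemic limit of disproportionality
analysis: reporting bias, no denominators, no causality. Dose and
duration are not modelled. The monotherapy filter discards most of a
real database. Scope labels of the packaged term set are a curation, not
a licensed SMQ export. The generator's independence assumptions are a
simplification; parameter recovery under correlated reporting is not
tested.

## Reproducing the numbers

The `analysis/` scripts run the three stages end to end
(`01_simulate.R`, `02_run_pipeline.R`, `03_calibration.R`), and
`scripts/acceptance.R --seed 1 --out results/acceptance.json` recomputes
the package's headline quantities — worked arithmetic examples, the
Fisher-versus-enumeration and Ward-versus-exhaustive-search agreements,
closed-form PCA checks, null calibration, effect recovery and the
demonstration pipeline — from scratch against the installed package.
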