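---
title: "Methods: disproportionality signal detection, prioritization and time-to-onset"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality signal detection, prioritization and time-to-onset}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

Spontaneous reporting systems such as the FDA Adverse Event Reporting
System (FAERS) collect voluntary safety reports: a patient, the drugs
they took (with a *primary suspect* role code), the adverse events coded
as MedDRA Preferred Terms (PTs), outcomes, and therapy dates. Because
there is no denominator of exposed patients, risk cannot be estimated;
instead, *disproportionality analysis* asks whether a drug--event pair is
reported more often than the rest of the database would predict.
`faersignal` implements that workflow end to end for a single suspect
drug and a target System Organ Class (SOC), the motivating case being
cardiac disorders (SOC 10007541) after an antiepileptic sodium-channel
modulator.

## Data model and cohort construction

FAERS ships as `$`-delimited quarterly ASCII tables (DEMO, DRUG, REAC,
OUTC, THER, INDI, RPSR) linked by `primaryid`. The reader maps columns by
header name so quarterly schema revisions (extra columns, the
`gndr_cod`/`sex` rename) are absorbed, skips malformed rows with a
warning, and keeps raw units: ages are stored with their unit codes and
converted only when summarized (DEC ×10, YR ×1, MON ÷12, WK ÷52.18, DY
÷365.25, HR ÷8766; weights LBS ×0.4536).

A `caseid` can appear as several report versions. Deduplication follows
FDA practice: keep the version with the largest `fda_dt`, breaking ties
by the higher `primaryid` (numeric comparison, falling back to
lexicographic with a warning when ids do not parse). The operation is
idempotent and independent of input row order.

Suspect-drug selection is a case-insensitive substring match of the
generic name in `drugname`/`prod_ai` or the trade name in `drugname`,
restricted to the configured role (default PS). Substring rather than
exact matching is deliberate: FAERS verbatim drug names carry dose and
formulation suffixes. The background ("all other drugs") excludes every
report in which the target drug appears in *any* role, so concomitant
mentions cannot contaminate the comparator.

Exclusions mirror standard practice: PT classes for off-label use,
product issues, medication errors, and the indication's own disease
terms are removed from reaction lists (the lists are configurable; a
miniature fixture ships with the package because the full MedDRA
dictionary is licensed). Cases whose `event_dt` precedes the suspect
drug's `start_dt` are dropped as input errors -- only when both dates are
full-precision calendar days, since partial dates (`YYYY`, `YYYYMM`)
carry no day-level evidence. Cases whose whole PT list was excluded
leave the cohort denominator.

Counting is *event-level*: each distinct (case, PT) pair is one event,
so a case reporting three cardiac PTs contributes three events to the
SOC tally but remains one case. Both counts are reported, since
descriptive tables use cases while the 2×2 screens use events.

## The reporting odds ratio screen

For each PT, the 2×2 table is

|                   | PT of interest | all other PTs |
|-------------------|---------------|---------------|
| suspect drug      | a             | b             |
| all other drugs   | c             | d             |

with ROR $= ad/bc$ and the Wald interval
$\exp(\log \mathrm{ROR} \pm 1.96\sqrt{1/a+1/b+1/c+1/d})$, the universal
convention for spontaneous-report screens. When any cell is zero the
Haldane--Anscombe correction adds 0.5 to every cell and the estimate is
flagged. A PT is a *signal* when the lower CI bound (ROR$_{025}$)
strictly exceeds 1 **and** at least 5 events were reported. No
multiple-testing adjustment is applied -- none is conventional in this
screen; the event-count floor is the only guard, and downstream
prioritization exists precisely because the screen is permissive.

The SOC-level estimate pools all member-PT events into the a-cell.
Subgroup screens (sex, age band \<18/18--64/\>64 years, weight band
\<80/80--100/\>100 kg, reporter class) rebuild the event tallies within
each stratum; cases missing the stratum variable are excluded from that
stratum only. Case counts with and without target-SOC events (`n`,
`nl`) accompany each stratum row for forest-plot rendering.

## Serious versus nonserious comparison

A case is serious iff it has any OUTC row (codes DE, LT, HO, DS, CA, RI,
OT). Per-PT serious/nonserious counts are tested against the rest of the
cohort with a fixed selection rule: Fisher's exact test when any
expected cell is below 5, otherwise the continuity-corrected (Yates)
chi-squared. The continuity correction is used throughout because the
published statistics this module was validated against are reproducible
only with it. Continuous variables (age, weight) get both the
pooled-variance two-sample t statistic and the two-sided Mann--Whitney
p-value (exact for small tie-free samples, tie-corrected normal
approximation otherwise); both are emitted because practice mixes them.

## Clinical priority score

Significant signals are ranked with a five-feature semi-quantitative
score (0--10; 0--4 weak, 5--7 moderate, 8--10 strong): event count,
ROR$_{025}$, mortality proportion (distinct cases with a DE outcome
mentioning the PT, counted once per case), IME/DME importance (DME takes
precedence), and a literature evidence grade (`+`/`++`) supplied as an
annotation, not computed. The shipped default thresholds --

* count: ≥10 → 1 point, ≥50 → 2;
* ROR$_{025}$: ≥2 → 1, ≥5 → 2;
* mortality: ≥25% → 1, ≥50% → 2;
* importance: IME 1, DME 2; evidence: `+` 1, `++` 2

-- are a **calibrated reconstruction**: they were chosen to reproduce the
published 17-signal reference set shipped in
`calibration_signals.csv`, and they reproduce 16 of its 17 printed
scores and its complete weak/moderate banding. They are not an official
scale. One reference row ("atrioventricular block second degree") is
provably inconsistent with *any* additive rubric that is monotone in
every feature: it weakly dominates "sinus arrest" on all five features
yet carries a lower printed score. The reconstruction scores it 6
(printed: 5); its band is moderate either way. Note also that because
the evidence grades in use are `+` and `++` (worth 1 and 2), the minimum
attainable score is 1, not 0. The rubric is a YAML config
(`rubric.yaml`), so users can substitute their own point maps; loading
validates that per-feature maxima sum to 10.

Novelty flags compare each signal against a configurable drug-label PT
list; PTs absent from the label are marked new/unexpected.

## Time-to-onset and the Weibull shape-parameter test

TTO is `event_dt − start_dt` in whole days (earliest full-precision
suspect-drug start when several therapy rows exist); 0 means onset on
the first day of therapy. Partial dates are excluded rather than
imputed -- the data carry no day-level information, and imputation would
bias the short-onset mass that the analysis is about.

Signals are pooled by priority band (all TTO values of distinct cases
mentioning any PT of the band), matching the two-row moderate/weak
structure of the motivating analysis. Medians and quartiles use linear
interpolation on the raw values. The two-parameter Weibull is fitted by
maximum likelihood: the shape $\beta$ solves the profile score equation
$1/\beta + \overline{\log x} - \sum x^\beta \log x / \sum x^\beta = 0$
(bracketed root, tolerance $10^{-8}$; the score is strictly decreasing
so the root is unique), and the scale has the closed form $\alpha =
(\overline{x^\beta})^{1/\beta}$. Confidence intervals are Wald on the
log-parameter scale from the observed information, back-transformed --
they respect positivity, at the cost of slight asymmetry. The fit
requires $n \ge 10$ positive values and refuses degenerate (all-equal)
samples.

Zero-day onsets have zero Weibull density for $\beta < 1$, so they are
shifted to 0.5 days before fitting by default (`zero_policy = "shift"`);
a `"drop"` switch exists. Raw values are always used for the
median/IQR. The hazard classification is the Weibull shape-parameter
(WSP) test: *early failure* when $\beta < 1$ with CI upper bound \< 1
(decreasing hazard), *wear-out* when $\beta > 1$ with CI lower bound \>
1, *random* when the CI includes 1.

## The synthetic FAERS generator

Because the real database is a multi-gigabyte download, the package
ships a generator that emits schema-faithful quarterly file sets with
known ground truth. Its defaults are the package's study conditions:
a background cohort of 20,000 reports against 2,000 suspect-drug
reports, ~74% serious with 18% of serious cases fatal (typical of a
targeted SOC cohort), a PT catalog mixing cardiac terms with a long
tail of common non-cardiac terms, injected signals spanning strong
conduction-disorder RORs (12--16), intermediate (2.5--6) and near-null
(1.6) strengths, early-failure onset profiles (Weibull scale ≈100
days, shape ≈0.5) for the strong signals, demographics with realistic
missingness (25% age, 60% weight), ~35% therapy-date availability, 5%
partial event dates, and a 10% duplicate-version rate.

Signals are injected on the odds scale -- the drug cohort's per-event
probability for PT $i$ solves
$\frac{q_i/(1-q_i)}{p_i/(1-p_i)} = \rho_i$ -- so the expected
event-level 2×2 reproduces the target ROR exactly, with the remaining
probability mass spread over non-signal PTs proportionally to their
background rates (which pushes null PTs slightly *below* 1, a
conservative direction for false-positive checks). Duplicates are extra
case versions with strictly older `fda_dt` (or equal `fda_dt` and a
lower `primaryid`), so the deduplication rule provably recovers the
pre-duplication truth. Everything is deterministic under the config
seed, to the byte.

What the generator does *not* emulate -- and what passing tests
therefore do not establish about real data: free-text drug-name noise
beyond dose suffixes, true duplicate reports with *differing* content,
co-prescription correlation structure, reporting-rate drift over
calendar time, and informative missingness (availability of therapy
dates is independent of onset time here; in real FAERS it is not).

## Numerical and design choices

* All text matching is case-insensitive on trimmed strings.
* Ties in the weight/age band edges are closed on the middle band
  (64 years is 18--64; 100 kg is 80--100), matching the stated
  "18 ≤ and ≤ 64" style bounds.
* The profile-likelihood root is bracketed in $[10^{-3}, 10^4]$ and
  expanded geometrically before solving; the observed information is
  checked for positive definiteness and the fit errors out with
  diagnostics otherwise.
* Percentages in cohort summaries always use the available (non-missing)
  denominator of their variable, reported alongside.
* Problem sizes in the test suite were chosen so that sampling error is
  small relative to each assertion (e.g. the ROR-recovery check runs
  150,000 background + 40,000 drug cases, giving ~4% standard errors on
  the high-count signals); the fixture set is ~200 cases so the
  end-to-end path stays fast.

## Known limitations

Disproportionality is reporting-rate inference, not risk estimation;
nothing here supports causal claims. The severity module's test
selection reproduces common practice but any fixed rule is a
convention. The Wald CI for the ROR is anti-conservative at very small
cells even with the Haldane correction. The Weibull fit ignores
censoring: cases that never report an onset date are simply absent,
which the generator mirrors but real data may not. The shipped IME/DME,
label and exclusion lists are miniature synthetic stand-ins for the
licensed originals and must be replaced for production use.
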