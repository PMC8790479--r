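---
title: "Expanded newborn screening by MS/MS: models, rules and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expanded newborn screening by MS/MS: models, rules and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbscreen)
```

`nbscreen` models a population expanded newborn-screening programme for
inherited metabolic disorders (IMDs): dried-blood-spot amino acid and
acylcarnitine panels measured by tandem mass spectrometry, threshold-rule
classification into suspected disorders, a two-tier recall workflow, and the
incidence and mutation-spectrum reports a programme publishes. This vignette
is the package's account of the underlying models, the parameters that
matter, and the design decisions taken where more than one reasonable choice
existed.

## The marker panel

The panel has 74 indicators: 39 single measured channels, 4 *combined
channels*, and 31 derived ratios. Combined channels (`C3DC + C4OH`,
`C4DC + C5OH`, `C5DC + C6OH`, `LEU + ILE + PRO-OH`) are isobaric species
that a non-derivatized MS/MS kit reports as one quantity; the package treats
them as atomic markers and never synthesizes them by addition. Ratio markers
are the opposite: they are *always* derived from the measured channels via
the formula spelled out by their printed name
(e.g. `(C0 + C2 + C3 + C16 + C18:1 + C18)/CIT`), never sampled or entered
independently — with one deliberate exception: if a record supplies a ratio
value whose operands are absent, that reported value is kept, because
partially transcribed clinical records often list an abnormal ratio without
its operands.

Marker names are matched after whitespace normalization, so `C3DC+C4OH` and
`C3DC + C4OH` are the same marker. Concentrations are in µmol/L; ratios are
dimensionless.

Each marker carries a laboratory reference ("cut-off") range. The closed
interval `[low, high]` is *normal*: `flag_out_of_range()` only reports
values strictly outside it. Disorder calls never use these ranges directly —
they use the positive rules, whose comparators are defined separately.

One note on provenance: the panel's published listing is garbled at one row
(the numbering skips an entry), while the rule set references the ratio
`(C4DC + C5OH)/C0`, which only that missing row can define. The shipped
panel therefore includes `(C4DC + C5OH)/C0` with range 0–0.03, consistent
with its rule threshold (`>= 0.03`) and with sibling hydroxyacylcarnitine
ratios; this is a reconstruction, not a printed value.

## The rule engine

Each of the 26 rule rows screens for one disorder or for a set of disorders
sharing a biochemical signature (the flag carries every OMIM code of the
row; differential diagnosis is confirmatory work, not screening). A rule is
a **disjunction of groups**; each group is a **conjunction of threshold
conditions** `marker ⋛ threshold`. Two structural conventions:

* a comma-separated cell of conditions is a conjunction, alternative
  columns are disjuncts — the PCD rule only makes sense this way, since its
  second group (`C0 < 9.0 ∧ ratio ≤ 1.3`) must be conjunctive to add
  anything to the stricter first group (`C0 < 8.5`);
* printed comparators are honoured exactly: `PHE = 100` does **not**
  satisfy `PHE > 100`, while `C5:1 = 0.01` does satisfy `C5:1 ≥ 0.01`.

Conditions on absent markers (including non-computable ratios) evaluate
false. This is fail-safe in both directions for ratio-dependent groups — a
missing ratio can neither fire nor veto a group — while single-marker groups
on measured channels still fire. The propionylcarnitine rule row has five
printed alternatives; the ratio-only cells (`C3/C0 > 0.3`, `C3/C2 > 0.29`,
`C3/MET > 0.4`) are implemented as standalone disjuncts, the reading that
maximizes detection and matches how the cells are laid out.

### Triage

The programme refers newborns with *clearly aberrant* first screens straight
to confirmatory testing; everyone else who flags is recalled for a second
specimen. "Clearly aberrant" is not quantified anywhere authoritative, so
the package implements a configurable *k-fold policy* (`k > 1`, default 2):
a record is `clear_aberrant` if any satisfied condition's value is beyond
`k`-fold its threshold (`value > k·threshold` for upper rules,
`value < threshold/k` for lower ones). This is an operational
interpretation, not a laboratory fact, and `k` is a tunable policy knob.

## The synthetic cohort generator

The generator defines the study conditions the package's stochastic tests
run under. It emulates a five-year programme of 300,849 newborns with the
confirmed-disorder incidences, yearly volume weights and male fraction
(59.25%) of the programme the package models.

**Reference variation.** Each measured channel is log-normal — the standard
choice for non-negative, right-skewed metabolite concentrations. The
parameters are solved in closed form so that chosen quantiles of the
distribution coincide with the cut-off bounds:
`sigma = (log high − log low)/(z_high − z_low)`, `mu = log low − z_low·sigma`.
Markers with a zero lower bound substitute `eps = min(high/1000, 0.001)`.
`calibrate_normal_distributions()` defaults to the 0.5%/99.5% quantiles;
the *cohort* default anchors at 0.1%/99.9% (`q_low = 0.001`,
`q_high = 0.999`). The wider anchor reflects how screening laboratories
actually set cut-offs — far enough out that only ~1–2% of healthy newborns
flag on any rule. Anchoring at 0.5%/99.5% would force 1% of newborns outside
*every* marker's range, and single-marker rules at or inside the range
(notably `PRO > 340` against a 75–420 µmol/L range, and `GLY > 1000` exactly
at its bound) would alone flag several percent of healthy newborns — more
than the entire suspected-positive volume the programme reports (1.64%).

**Correlation.** Metabolite channels in blood-spot panels co-vary strongly
(blood volume, hematocrit, extraction efficiency, global metabolic state).
The generator uses a single-factor model on the log scale: each marker loads
on one shared per-newborn factor with weight `sqrt(rho)·sigma_m`
(`rho = 0.85` by default), plus an independent residual. Marginals keep
their calibrated quantiles exactly, while every ratio's log-variance shrinks
from `sigma_i² + sigma_j²` to `rho·(sigma_i − sigma_j)² +
(1 − rho)(sigma_i² + sigma_j²)`. Fully independent sampling is not a viable
alternative here: it gives ratio markers absurdly heavy dispersion, to the
point that the standalone `C3/C2 > 0.29` rule alone would flag several
percent of healthy newborns. The single factor is the weakest correlation
structure that keeps ratio rules meaningful; no pairwise covariance data
exist to fit anything richer.

**Disease cases.** True labels are assigned per newborn at the configured
incidences. An affected newborn's rule-relevant markers are drawn uniformly
between the rule threshold and an anchor equal to the most extreme abnormal
level observed among that disorder's confirmed cases (falling back to
3× the threshold when no level was recorded); ratio conditions of the
targeted group are enforced after derivation by rescaling the numerator
operands jointly. Each profile has a `sensitivity` (default 1): with
probability `1 − sensitivity` the affected panel stays at reference levels,
a biochemical screening miss of the kind programmes document (e.g. citrin
deficiency with normal first-screen citrulline). The per-disorder screening
sensitivity is a free parameter of the simulation, not an estimate.

**False positives.** Beyond reference-tail variation, a per-newborn
`fp_rate` displaces one randomly chosen rule-relevant measured marker just
past its most lenient rule threshold (uniformly within 20% beyond),
emulating pre-analytical and analytical error; displaced panels are
borderline and may or may not flag. The default `fp_rate = 0.0139` is
calibrated so the first-screen suspected-positive fraction is ≈1.64%
(4,923/300,849), the volume the modelled programme reports.

**What the generator does not emulate:** analytical noise models,
gestational-age/birth-weight/feeding covariates, batch effects, seasonal
drift, and any marker-marker correlation beyond the single shared factor.
Passing tests therefore demonstrate the pipeline's internal consistency
under the stated statistical model, not the false-positive structure of any
real laboratory.

## The two-tier workflow

`run_two_tier()` composes: screen → triage → recall (mild positives return
with probability `recall_prob`; the rest are lost and never diagnosed) →
retest (truly affected re-flag with `tp_persist`, default 1; unaffected with
`fp_persist`, default 0.05, of the order seen in elevated-C3 recall series)
→ referral (retest positives plus direct clear-aberrant referrals) →
confirmation (Bernoulli `confirm_sens` for the truly affected, probability
0 otherwise: the combined confirmatory work-up — urine organic acids,
pterin analysis, DHPR activity, sequencing — is treated as perfectly
specific, since no per-test operating characteristics are available).
Funnel monotonicity (`screened ≥ suspected ≥ recalled + direct referrals`,
`recalled ≥ retest-positive`, `confirmed ≤ referred`, confirmed ⊆ affected)
is asserted on every run.

The default `recall_prob = 0.8765` is the recall fraction the modelled
programme reports. The **recall rate** in `summarize_by_year()` is an
operational quantity: for simulated outcomes it is
`recalled / recall-eligible` — clear-aberrant newborns are referred
directly and cannot be "recalled", so they do not belong in the
denominator; for a bare year table without a triage breakdown it falls back
to `recalled / suspected`, which is how published totals such as
4,315/4,923 = 87.65% are formed.

## Report arithmetic

Two rounding conventions coexist in programme reports, and the package
implements both explicitly:

* **Frequencies** `1:N`, `N = screened/cases`: cumulative disorder tables
  round half-up (300,849/2 = 150,424.5 → `1:150,425`; 300,849/28 →
  `1:10,745`), while yearly report tables truncate (59,439/20 = 2,971.95 →
  `1:2,971`; 66,399/13 → `1:5,107`). `incidence_ratio()` takes a `rounding`
  argument; `build_summary()` uses half-up, `summarize_by_year()` uses
  truncation. Base R's `round()` (half-to-even) reproduces neither, hence
  `round_half_up()`.
* **Percentages** are half-up to 2 dp. Category percentages are computed
  from counts over the 71 confirmed cases (28/71 = 39.44%, 12/71 = 16.90%,
  31/71 = 43.66%). Published category percentages that disagree with their
  own printed counts are not reproduced — the package always computes from
  counts.

One published yearly recall-rate cell (1,302/1,444 → 90.17 at 2 dp half-up,
printed as 90.16) cannot be reproduced under the same convention as its own
column total (87.6498 → 87.65, which *is* half-up); the package keeps
half-up throughout.

## The confirmed-case fixtures

The shipped `nbs_case_panels()` table transcribes the printed abnormal
marker levels of the 71 confirmed cases (63 with full work-up, 8 diagnosed
clinically elsewhere). The rule-engine regression suite completes each
record with reference-range midpoints for unprinted markers, derives
ratios, overlays printed ratio values, and checks the case flags a rule row
containing its diagnosis. Nine of the 63 records *cannot* flag from their
printed values alone — borderline citrulline elevations below the
`CIT > 65` disjunct whose `ALA/CIT < 9.5` conjunct fails at midpoint
alanine, a phenylalanine of 105.43 µmol/L under the `PHE > 120` disjunct,
C5 and C3 elevations short of their single-marker thresholds, and two cases
whose printed markers do not appear in their disorder's rule at all. These
nine are asserted *non-flaggable*: the fixture documents that their actual
screens must have relied on marker values that were not printed, and the
test suite pins the exact partition (54 flag, 9 do not).

## Mutation-spectrum accounting

Alleles are counted as reported: one count per filled allele slot, grouped
by `(gene, nucleotide HGVS)`; HGVS strings are folded only for whitespace
and the case of the `c.` prefix, never normalized or validated, and the
pathogenicity column is carried as annotation, never computed. A
configurable gene → disease-group map pools genes that present as one
screened condition (hyperphenylalaninemia = PAH + PTS, a 24-allele
denominator); within-group relative frequencies and hotspot summaries use
the group denominator, and cumulative hotspot percentages are computed from
summed counts, not summed rounded percentages. The shipped canonical count
table (118 alleles) is the consolidated accounting; the raw per-case
genotype table differs from it by single alleles for two genes (one
SLC22A5 allele and one PAH allele more in the consolidated table), a
transcription-level discrepancy preserved as shipped data rather than
resolved.

## Numerical choices and degenerate inputs

* Zero denominators and missing operands leave a ratio absent (with a
  warning), never `Inf`/`NaN`; absent ratios make rule conditions false.
* `low = high` or `low > high` ranges are calibration errors, not silent
  degeneracies.
* A value of exactly 0 under a lower-threshold rule has infinite severity
  (always clear-aberrant) — free carnitine of 0 is an emergency.
* Empty cohorts return empty outcomes with a warning; zero suspected
  positives report an absent recall rate, not 0/0; zero confirmed cases
  report an absent frequency (a frequency for zero cases is an error in
  `incidence_ratio()`).
* Hotspot ties are broken by nucleotide-HGVS lexicographic order, making
  reports deterministic.

## Problem sizes used by the test suite

Property-style tests run 100 random panels against straight-line oracles;
calibration checks use 1e5 draws; end-to-end parameter recovery runs one
full-scale cohort (n = 300,849) through a lossless workflow and checks
every disorder's confirmed count against its 95% Poisson band; the
recall-rate calibration check averages 20 full-scale cohorts. The
acceptance script averages 5 full-scale cohorts. These sizes were chosen to
keep Monte-Carlo error well inside the assertion bands.

## Known limitations

* The positive rules are transcriptions of one programme's laboratory
  policy; other laboratories use different cut-offs and the configs are
  meant to be replaced wholesale.
* Confirmatory testing is a single perfectly specific Bernoulli step; real
  confirmatory cascades have their own error structure.
* The generator's false-positive layer is a caricature (one displaced
  marker per affected draw); real analytical error is correlated across
  channels and batches.
* Incidence estimation is a point ratio; no interval estimates are
  produced, matching the reports the package emulates.
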