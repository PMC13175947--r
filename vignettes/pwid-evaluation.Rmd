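---
title: "Evaluating PWID identification from discharge summaries: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating PWID identification from discharge summaries: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwideval)
```

# The problem

Hospital admissions of people who inject drugs (PWID) are under-counted by
administrative ICD-10 coding, which is highly specific but insensitive for
injecting drug use. Evaluating text classifiers that read discharge
summaries instead requires a complete measurement apparatus: a multi-label
gold standard, ICD proxy baselines, per-label diagnostic metrics with
uncertainty, an aggregate statistic for model selection, and a subgroup
fairness audit. Because real discharge summaries cannot be shared, the
package is driven by a synthetic cohort generator that emulates the
statistical structure of an Australian tertiary-hospital infectious
diseases cohort; user-supplied predictions and cohorts of the same file
shapes can be evaluated identically.

# The synthetic cohort model

Each admission is drawn independently. The PWID indicator is Bernoulli with
prevalence 0.171 (default cohort size n = 859, matching 149/859). All other
quantities are conditional on that indicator.

**Gold labels.** Twelve binary labels (`pwid_labels()`). Conditional
prevalences (`default_label_prevalences()`) mirror the emulated cohort's
gold-standard frequencies: e.g. heroin 36/149 among PWID and 0 among
non-PWID, methamphetamine 47/149 vs 14/710, methadone 60/149 vs 28/710.
Within PWID, current injection has probability 98/149 and historical 28/149
— these two conditional rates are not printed directly in the emulated
study's descriptive table; they are backed out of its recency confusion
tables (sensitivity/specificity/PPV admit a unique integer reconstruction).
Benzodiazepine gold prevalence is likewise absent from the descriptive
table; the defaults (0.10 / 0.0085) give roughly the 21 gold positives its
per-label metrics imply. Substance and OAT labels are drawn independently
given PWID status: the marginal counts identify no joint distribution, and
independence is the minimal assumption. `idu_any` is forced true whenever a
recency label is true, so the schema invariant holds by construction;
current and historical are deliberately not mutually exclusive.

**Demographics.** Age is log-normal by PWID status, tuned to medians 45
(PWID) and 54 (non-PWID) with log-SDs 0.244 / 0.412 matched to the reported
IQRs ((36, 50) and (39, 68)); a log-normal was chosen for positivity and
right skew, the emulated study stating only median and IQR. Length of stay
is 1 + negative binomial with (size, mu) = (0.8, 8.5) for PWID and
(0.9, 5.0) otherwise, reproducing medians (IQRs) 6 (3, 13) and 4 (2, 8)
days exactly at the distribution level. Sex, Indigenous status and
discharge status are categorical draws at the emulated frequencies (e.g.
patient-directed discharge 22% vs 4.6%; unknown Indigenous status only
among non-PWID).

**Note text.** Word counts are log-normal with means 350 (PWID) / 290
(non-PWID) and a common log-scale SD of 0.56, chosen so the mixture
reproduces the overall mean 300 / SD 182; counts are truncated at 20 words.
The note itself is assembled from a fragment bank
(`note_template_bank()`): every true gold label is asserted by at least one
fragment; distractor fragments (negated injecting, third-party heroin use,
charted opioids/benzodiazepines, hepatitis-C serology) are injected at
configurable rates (`default_distractor_rates()`); neutral clinical filler
pads to the target length, with filler always separating content fragments
so keyword context windows cannot bleed between fragments. Synthetic PHI
(name, two dates, MRN, IHI, phone, address) is embedded with exact spans
recorded in half-open `[start, end)` coordinates.

**ICD coding.** Administrative coding is modelled per code group: when the
group's triggering condition holds (PWID status for HIV/hepatitis
C/homelessness; any relevant substance or PWID status for the SUD and
substance-related groups) a syntactically valid member code is emitted with
the group's coding sensitivity, otherwise spuriously at its false-positive
rate. The defaults (`default_icd_model()`) were set so that the composite
hepatitis-C-and-SUD rule has joint sensitivity 0.60 × 0.525 ≈ 0.315 and
joint false-positive rate ≈ 0.031 under independent emission — the
qualitative low-sensitivity/high-specificity pattern of administrative
coding. The generative model itself is the package's own construction; only
the resulting operating characteristics are anchored.

**Simulated classifier.** Predictions are drawn per label: true with
probability `sensitivity` given a true gold label, with `1 - specificity`
otherwise, independently across labels
(`default_prediction_error()` carries the per-label operating points of the
emulated study's best text model, e.g. 0.819/0.999 for any injecting).
Cocaine and fentanyl operating points are unreported there (three gold
cases each); the package uses 0.667/0.999 and excludes both labels from
default reports (`default_report_labels()`), keeping them configurable.

**Randomness.** Every record derives its own substream seed from
(config seed, record index), so cohorts are bit-reproducible and individual
records are invariant to the cohort size.

# De-identification

`deidentify_text()` replaces identifiers with bracketed placeholder tokens
and collapses whitespace; nothing else is altered (case, clinical numbers
and spelling pass through). The pattern dialects are the package's own
definitions, since only the identifier categories — not regexes — are
specified by the emulated pipeline: dates as dd/mm/yyyy, yyyy-mm-dd or
"d Month yyyy"; Australian phone formats; MRNs as standalone 7-digit
integers; IHIs as 16-digit numbers beginning 800360; addresses as
number + street + suffix; names from a caller-supplied roster (free-text
name recognition is out of scope). Longer numeric identifiers are matched
first (IHI before MRN before phone) so no partial replacement can occur;
the operation is idempotent. The residual-PHI audit is exact on generator
output because the generator records every embedded span; on real notes the
guarantee extends only to these pattern families.

# The keyword reference classifier

`keyword_rule_classifier()` is a deterministic lexicon classifier standing
behind the same prediction interface as any external model. A hit is
suppressed by a negation cue within five tokens before it (a NegEx-style
window, configurable). Injection hits carry recency context: a historical
cue ("former", "previous", "history", ...) in the ±5-token window marks
historical use; a hit with neither a historical nor an unclear-recency cue
marks current use. The unclear-recency cue class exists so that notes
documenting injecting without recency information round-trip exactly —
without it, any injection mention lacking a historical cue would be forced
to "current". Prescription-opioid and benzodiazepine hits are suppressed by
prescribed-context cues ("charted", "for pain", ...), so documented
analgesia does not count as misuse. With distractors disabled the
classifier recovers the generator's gold labels exactly (a round-trip
invariant tested in the suite); with default distractor rates it makes the
characteristic contextual errors (third-party use, prescribed-context
confusion) on purpose. On synthetic text it is therefore an upper-bound
oracle, not a realistic model — rankings that include it should be read
accordingly.

# Metrics, bootstrap and model selection

Diagnostic metrics follow the standard definitions; any zero denominator
yields NA, and F1 — the harmonic mean of PPV and sensitivity — is NA
whenever either constituent is undefined (a rule predicting zero positives
reports NA F1 and NA PPV, not 0). Confidence intervals are percentile
bootstrap with 1000 iterations by default: the simplest method consistent
with the reported intervals, with resampling at the admission level so
cross-label correlation is preserved. Replicates where a statistic is
undefined are dropped from the percentile computation; if more than half
are undefined the summary is flagged rather than silently reported.

The model-selection statistic is the prevalence-weighted average F1:
per-label F1 weighted by each label's share of gold-positive counts.
Undefined per-label F1s contribute 0 with a flag — low-prevalence labels
stay in the aggregate instead of silently inflating it. Macro F1
(unweighted mean) is reported alongside; ties in model ranking break by
macro F1, then name. Reports render estimates to three decimal places;
internal values keep full precision.

# Fairness audit

For each protected attribute — age dichotomised at the cohort median
(computed from the data, not hard-coded), sex, and Indigenous status with
"Unknown" omitted and counted — the audit reports per group: demographic
parity, TPR, TNR, PPV, NPV and the Matthews correlation coefficient, each
with within-group bootstrap CIs. **Demographic parity is computed as the
proportion of the group predicted negative** (one minus the
predicted-positive rate). This is an interpretive choice: with the paired
group sizes and operating characteristics of the emulated study it is the
unique direction that reproduces all six of its printed parity values, and
it is recorded prominently here because the opposite convention (predicted
positive rate) appears elsewhere in the fairness literature. Parity ratios
are min/max across groups, flagged below 0.80 (the "80% rule"); equalised
odds is read as the pair of TPR and TNR ratios, both required to pass.
Undefined group values are excluded from a ratio with a warning; a metric
undefined everywhere is omitted.

# Numerical and scale choices

The test suite runs every stage at reduced but statistically meaningful
sizes: binomial-convergence checks at n = 5000 with 3-binomial-SD bands
derived from the configured rates; note-length checks on ~1000 notes per
group; bootstrap coverage with 50 simulation replicates of 1000 bootstrap
iterations each at the study scale n = 859. These sizes keep the default
suite around a minute while leaving each assertion's error budget explicit.
Exact reproduction checks use integer confusion tables reconstructed from
published group sizes and metrics, verified to reproduce every printed
value to three decimals before being frozen into the tests. One published
row (heroin ICD codes: n = 36 with sensitivity 0.757) admits no integer
true-positive count and is deliberately not matched; the package reports
exact fractions.

# Limitations

Synthetic notes are template prose with a controlled vocabulary: passing
round-trip and audit tests demonstrates the correctness of the evaluation
machinery, not classifier performance on real clinical language, which is
fragmented, abbreviated and idiosyncratic. Substance labels are independent
given PWID status, so co-use correlation structure is absent. The
de-identification guarantees are scoped to the defined pattern families.
Readmissions are not modelled (the emulated design analyses first
admissions only), and HIV prevalence enters only through a coding-model
knob. None of the hypothesis tests that typically accompany a baseline
characteristics table are reimplemented; the cohort summary is descriptive.
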