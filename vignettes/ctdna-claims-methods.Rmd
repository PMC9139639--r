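---
title: "Methods: claims-based analysis of ctDNA-guided therapy in mCRC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: claims-based analysis of ctDNA-guided therapy in mCRC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctdnaRWE)
```

## The problem

When metastatic colorectal cancer (mCRC) progresses on first- or second-line
therapy, a circulating tumor DNA (ctDNA) panel can identify patients who are
candidates for targeted therapy — EGFR antibodies for RAS-wild-type disease,
BRAF inhibitors for *BRAF* V600E, ERBB2-directed agents for *ERBB2*
amplification, NTRK inhibitors for *NTRK1* fusions, immune checkpoint
inhibitors (ICIs) for MSI-high tumors — and patients for whom a class should
be avoided (RAS-mutant or right-sided disease for EGFR antibodies). Payer
claims databases linked to ctDNA test results allow this decision process to
be observed at population scale, but everything clinical must be
reconstructed from claim streams: treatment lines, eligibility, the therapy
actually chosen after testing, and time-to-event outcomes. This package
implements that reconstruction as a tested pipeline and ships a calibrated
synthetic-cohort generator, because real claims databases of this kind are
proprietary.

All dates are integer day indices; months convert at 30.4375 days/month, so
the "6-month" clean window is 183 days. These constants keep every filter
reproducible at claim (day) granularity.

## Lines of therapy from claims

`derive_lines()` walks a patient's systemic-therapy claims date by date and
maintains a current line under four rules, applied in this order of
precedence at each administration date:

1. The *regimen signature* ignores fluorouracil- and bevacizumab-class
   agents: changes involving either never define a new regimen.
2. A **new targeted agent** (including non-bevacizumab VEGF agents such as
   ramucirumab) appearing strictly more than **60 days** after line start
   opens a new line.
3. A **new chemotherapy agent** appearing strictly more than **15 days**
   after line start opens a new line.
4. Otherwise, a claim more than **90 days** (strict) after the last
   administration opens a new line: the same regimen resuming within 90 days
   merges into the current line. The gap is measured last administration to
   next administration; estimated exposure windows play no role here.

Pure discontinuation never opens a line. The 60/15-day thresholds are read
as strict ("more than") and the 90-day gap as inclusive ("within"). When one
date both resumes a lapsed regimen and adds a new agent, the new-agent rules
win: an addition is stronger evidence of progression than a resumption.
Whether swapping one EGFR antibody for another counts as a targeted
modification was an open design point; we treat any change to the
non-exempt agent set as a modification.

The estimated end of a line is the last administration date plus a per-class
exposure window (default 28 days for every class, the maximum over classes
present). Claims data in this schema carry no days-supply field, so a
one-cycle constant is the minimal auditable proxy. Line numbering starts at
1 at the first observed therapy claim; the clean-window filter below is what
makes "first observed" trustworthy as "first line".

These rules are validated two ways: unit tests of the canonical scenarios,
and an equivalence test against an independent brute-force implementation
that re-derives every line attribute from scratch at each claim date, run on
10,000 random claim streams of up to 8 claims over 5 agents.

## Cohort selection

Three filters are applied in a fixed order, and attrition is always reported
in that order, each step's percentage using the previous step's survivors as
denominator:

1. **Testing window**: a ctDNA test reported within 90 days (inclusive on
   both ends, so a test on the line-start day qualifies) before the start of
   that patient's second- or third-line therapy.
2. **Clean window**: at least two claims of any kind and no systemic-therapy
   claim in the 183 days before the first observed therapy start. Claims
   that also establish metastasis may count toward the activity requirement.
3. **Metastatic disease**: at least one claim whose diagnosis code belongs
   to a configurable secondary-malignancy set, at any date (the timing of
   metastasis coding relative to testing is not constrained).

When several tests qualify, the index test is the one conducted immediately
after the *earliest* line containing targeted therapy; with no prior
targeted exposure, the earliest test (ties break by report date, then test
id). The prior-therapy arm (`prior_targeted`) is defined by the line
immediately before the index test only, not any earlier line.

## Actionability and informed therapy

A detected sample without *KRAS*/*NRAS* mutations has an actionable profile.
The indicated-therapy set is: EGFR if RAS-wild-type without *BRAF* V600E in
a non-right-sided tumor (MIXED and UNSPECIFIED sidedness stay eligible — only
the right colon is named as a contraindication; this is policy-overridable);
BRAF/ERBB2/NTRK/ICI for their respective biomarkers regardless of RAS
status. Fusions outside *NTRK1* and *MET* exon 14 skipping are carried for
reporting only and never confer actionability. Whether a right-sided
RAS-wild-type-only profile counts as *actionable* (it indicates no therapy)
is governed by `actionability_policy(ras_wt_right_actionable=)`, default
`TRUE` (the sample-level reading); such patients can never be
matched-targeted either way, so matched accounting is unaffected.

The post-test line is labeled by `classify_informed()`:

- With undetected ctDNA, nothing is informed.
- An administered targeted class is **matched** only against its own
  biomarker; `OTHER_TARGETED` agents never match.
- Chemotherapy/VEGF-only treatment is **informed** when no
  biomarker-positive indication (BRAF/ERBB2/NTRK/ICI) exists and there is no
  usable EGFR option (i.e. RAS is mutant, or the tumor is right-sided).
- When targeted therapy was given, the overall call additionally requires
  that no biomarker-positive indication was left unused by the administered
  classes. The unused-EGFR penalty applies only to non-targeted treatment:
  a matched ICI with an unused EGFR option remains informed, while a matched
  EGFR with an unused MSI-high indication does not. This asymmetry is what
  reconciles all four published per-class breakdowns simultaneously (e.g.
  the one EGFR-treated MSI-high patient counted as not informed, but
  MSI-high ICI patients counted as matched).

Every cohort patient lands in exactly one of four outcome groups: matched
actionable, unmatched actionable, not actionable, ctDNA not detected. The
classifiers are total deterministic functions and are tested against a
committed truth table over all 2^6 biomarker-flag combinations × 4 sides,
generated once by an independent transcription of the rules.

## Outcomes

**TTD** (time to treatment discontinuation, a progression-free-survival
surrogate) runs from the first day of a line to the earliest of the
estimated end of therapy, the last claim activity date, or death. It is an
observed event when the endpoint is death, or when it is the estimated end
and at least 90 further days of claims confirm no resumption; otherwise the
record is censored — at the estimated end when follow-up is merely too short
(the discontinuation time itself is observed; only its interpretation is
uncertain), or at the last claim when claims stop before therapy ends.
**OS** runs from the index ctDNA report date to death, censored at the last
claim date; the death registry is authoritative, so a death after the last
claim is still an event.

Kaplan–Meier estimation, the log-rank test, and Cox proportional-hazards
models (Breslow tie handling, Wald intervals, all pairwise group contrasts;
contrasts with an event-free level flagged non-estimable) stand on the
`survival` package behind this module's interface. Proportions are compared
with a pooled two-proportion z-test, or Fisher's exact test when any
expected cell is below 5 — the conventional threshold; the source analysis
did not state its own.

Test oracles are independent of those library calls: a hand product-limit
estimator, a direct O−E/V log-rank statistic checked on every relabeling of
six-record instances plus its exact permutation p (the asymptotic χ² p
differs from the exact p by up to ~0.3 at that size, a known small-sample
property, so the exact check is on the statistic), direct optimisation of
the Breslow partial likelihood, full hypergeometric enumeration for Fisher,
and a parameter-recovery simulation showing |bias of log-HR| < 0.05 at
n = 2000 over 200 replicates.

## The synthetic cohort

`generate_cohort()` emits what the analysis consumes: pre-treatment activity
claims, a metastasis code, one or two derivable prior lines, an index test
timed 7–60 days before the next line start, a post-test line whose class is
chosen from the profile, and death/loss-of-follow-up processes. Its defaults
are the study conditions the pipeline is meant to reproduce: detection
93.7%; per-arm alteration prevalences conditional on detection (e.g. KRAS
21.5% after targeted therapy vs 45.8% after non-targeted); sidedness
44.5/18.9/25.8/10.8; 13% prior-targeted; a 642:422 second:third-line split;
and treatment-assignment rates (46.9% targeted given actionable, 81.1%
of those matched, 18% targeted otherwise) taken from the published flow.

Choices the source did not pin down, made once and documented here:

- **BRAF/RAS near-exclusivity**: alterations are otherwise independent
  Bernoulli draws, but BRAF V600E is down-weighted by a factor of 0.9 given
  a RAS mutation, with the RAS-wild-type conditional rate raised so the
  configured *marginal* prevalence is preserved (the calibration invariant
  tests marginals). The joint distribution with sidedness is independent —
  real BRAF V600E is enriched in right-sided tumors; this generator does not
  model that.
- **Outcome model**: true discontinuation times are exponential with
  group-specific medians 5.3/3.9/3.5/3.5 months (a soft calibration of the
  simulator only — the published medians are not desk-reproducible and are
  not acceptance targets); death and last-claim processes are independent
  exponentials with 15- and 24-month medians, plausible for 2nd/3rd-line
  mCRC. Death is conditioned on surviving to the post-test line start,
  which is exact for the exponential clock. Administrations recur every 14
  days; trailing office-visit claims every 45 days maintain claim activity
  until loss of follow-up.
- **Eligibility violators**: 5% of patients per filter are planted to fail
  exactly one filter (a late test, a single clean-window claim, a missing
  metastasis code), so attrition accounting can be checked against known
  truth.
- The MSI-era flag (assay added MSI calling mid-period) zeroes MSI calls
  before a cutoff date and is off by default.

What passing tests on this generator shows — and does not. The generator
reproduces the *statistical structure* the pipeline assumes: marginal rates,
arm differences, filter violations, derivable line sequences. It does not
emulate real claims vocabulary, billing noise, regimen idiosyncrasies,
clinical response, or trial participation, so green tests here demonstrate
correctness of the reconstruction and classification logic, not fidelity of
any particular clinical estimate to the real-world population.

## Problem sizes and numerics

The test suite uses 10,000 random streams for the line-engine oracle, 10,000
triples for the TTD/OS oracle, n = 5000 for generator calibration (3
binomial standard errors around each configured rate), and 200 × n = 2000
replicates for Cox recovery — sizes chosen so each property is sharply
testable while the whole suite stays quick. Display percentages round half
away from zero to one decimal (13/16 prints as 81.3); full precision is
retained in the JSON report. Degenerate inputs are defined, not errors: an
empty claim stream derives zero lines, an empty cohort produces a zero-count
report, an all-censored KM curve has no median.

## A worked example

```{r example}
study <- run_pipeline(sim_config(n_patients = 300), seed = 7)
print(study)
study$km_ttd$medians
```

## Known limitations

Regimen exposure is a fixed 28-day window, not days-supply; claims carry a
single sentinel metastasis code rather than a diagnosis vocabulary; the
informed-therapy rule set is the fixed six-biomarker panel, not a live
knowledge-base lookup; and the published cohort-level results that require
the proprietary source database (the 18,875 → 1064 attrition, 47.7%
actionable, the printed medians and hazard ratios) are reproduced in *form*
on synthetic data, never asserted numerically.
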