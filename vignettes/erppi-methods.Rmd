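---
title: "Measuring emergency room process performance from event logs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring emergency room process performance from event logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erppi)
```

## The problem

Emergency departments generate event logs as a by-product of care: every
registration, treatment, test, consultation and disposition decision is
written to the hospital information system with a case identifier, an
activity label, a timestamp, and usually a resource, a triage level and a
patient identifier. `erppi` turns such logs into a panel of sixteen process
performance indicators organised along the devil's quadrangle — time, cost,
quality and flexibility — so that ER managers and health-informatics
researchers can quantify how a department actually operates rather than how
its protocol says it should.

The sixteen indicators are:

| Perspective | Indicator | What it measures |
|---|---|---|
| Time | T1 | length of stay (LOS) per case |
| | T2 | LOS restricted to a variant (e.g. hospitalized vs discharged) |
| | T3 | LOS by KTAS emergency level |
| | T4 | cycle time of a clinical activity |
| | T5 | initial response time after arrival |
| | T6 | door-to-doctor time |
| Cost | C1 | total cost per case (cost-attached logs) |
| | C2 | number of originators (indirect cost, cost-detached logs) |
| Quality | Q1 | standard deviation of LOS |
| | Q2 | resource workload over time |
| | Q3 | earth-mover's matching rate against a reference language |
| | Q4 | triage accuracy against a rule table |
| | Q5 | triage-based patient response rate |
| | Q6 | revisit rate within a window |
| Flexibility | F1 | number of trace variants |
| | F2 | number of directly-follows relations |

## The event-log model

A log is a multiset of traces. Each event is a tuple of activity,
originator, timestamp and event type (`start` or `complete`); each case
carries a patient identifier and a KTAS emergency level 1–5 (lower = more
urgent). Internally timestamps are numeric seconds since the epoch,
timezone-naive; reports convert to hours for the LOS family and minutes for
the cycle-time family.

Three representational choices deserve explanation.

**Timestamp dialect.** ER extracts commonly print day-first dates such as
`01/02/2018 19:05`. A silently swapped month and day is the worst failure
mode a log reader can have, so `read_erlog_csv()` requires an explicit
format (defaulting to `"%d/%m/%Y %H:%M"`) and auto-detects ISO 8601, which
is unambiguous. Ties at equal timestamps keep stable input order because
logs define no secondary sort key.

**The occurrence view.** Most hospital logs are complete-only, but a log
may contain `start` events. A `start` event that is followed by a
`complete` of the same case and activity is lifecycle metadata: the pair is
one activity occurrence whose interval is recorded explicitly. An
*unpaired* `start` event (an activity that began but whose completion was
never written, like a consultation under way when the extract was cut)
still represents an occurrence and is kept at its own timestamp. Variants,
LOS, cycle times and the DFG are all computed on this occurrence view; with
complete-only logs it is the identity.

**Inferred start times.** Where only completions are recorded, the start of
an event is taken as the completion of the immediately preceding event in
the same case; the first event of a case gets duration zero. This is the
standard single-queue reading of a complete-only trace and is what the
workload and staffing profiles consume. It cannot distinguish waiting from
service, so per-resource workload in complete-only logs is an upper bound
on true busy time.

## Preprocessing remedies

Four imperfection patterns that occur in ER extracts are handled, mirroring
remedies used in practice:

* **Collateral events** — the same (case, activity, timestamp, type,
  originator) recorded more than once. Only the first copy is kept.
* **Inadvertent time travel** — an event timestamped strictly before the
  case's ER-entry event (e.g. a diagnostic test "before" arrival, from
  back-dated form entry). The whole case is deleted.
* **Form-based event capture** — at least `form_threshold` (default 3)
  events with *distinct* activities at one identical instant, the signature
  of a form that writes several rows at save time. The case is deleted.
* **Exclusive case** — the raw case key is the patient, so same-day
  revisits collapse into one case. `build_cases(strategy = "patient_visit")`
  re-segments a patient's events into visits whenever the gap between
  consecutive events exceeds `visit_gap` (default 24 h) and keys the new
  case as patient id + first timestamp.

Deletion rather than repair is deliberate: the patterns affect few cases
and any repair would have to invent timestamps. Both deleting operations
are idempotent and conserve cases (kept + removed = input).

## Indicator semantics where the definitions leave room

* **Aggregation.** Sample-valued indicators report average, median, min
  and max plus n. The standard deviation (Q1) is the population form
  (divide by *n*), configurable to the sample form.
* **Door-to-doctor (T6)** pairs the *first* entry with the *first*
  consultation of a case — the door-to-doctor reading — with a switch for
  first-to-last.
* **Response rate (Q5).** Cases are ordered by first-event completion; a
  consecutive pair violates when the earlier arrival was served later
  *and* the urgency comparison holds. The default comparison treats the
  earlier case being numerically higher on KTAS (less urgent) as the
  violating configuration; because one can also read the policy as "more
  urgent patients may overtake", the flipped comparison is available via
  `direction = "urgency"`. The denominator uses evaluable cases (those
  with a KTAS value and a second event) per period, and periods with
  fewer than two such cases are reported absent rather than as 1.0.
* **Revisit rate (Q6)** counts same-patient case pairs whose gap from the
  end of the earlier case to the start of the later one is at most the
  window (inclusive), divided by distinct patients — returning *after
  leaving* is what signals a problematic discharge. Start-to-start
  measurement is available as a mode.
* **Workload (Q2)** follows the started-minus-completed recursion per
  time bin. Bins are half-open, left-closed; an instant on a boundary
  belongs to the later bin. Where per-event resources are unreliable, the
  `patient_census` mode substitutes the number of patients present, the
  fallback used in practice when event-level attribution is missing.
* **F2** counts directly-follows relations (immediate succession within a
  case). The unfiltered count is canonical; frequency filtering is a
  display option only, since any threshold choice would be arbitrary.

## The matching rate (Q3)

The conformance indicator compares the log's *stochastic language* — each
variant weighted by its case frequency — against a reference language for
the intended process. The ground distance between two variants is the
Levenshtein distance of their activity sequences normalized by the longer
length, so it lies in [0, 1]. Moving the log's probability mass onto the
reference's at minimal total cost is a balanced transportation problem;
the matching rate is one minus the optimal cost, hence also in [0, 1],
equal to 1 exactly for identical languages, and symmetric.

The transportation problem is solved exactly by successive shortest
augmenting paths on the bipartite residual graph (Bellman–Ford label
correction, since reduced costs on backward arcs can be negative). Each
augmentation saturates a supply, a demand or a residual arc, so the
algorithm terminates after finitely many steps; the test suite verifies
optimality against an exhaustive enumeration of all spanning-tree bases of
the transportation polytope on two hundred random instances with up to
four variants per side, at 10⁻⁹ tolerance. The solver is exact but dense:
it is intended for reference languages of up to a few hundred variants,
not for comparing two raw 25 000-variant logs against each other. The
ground distance is pluggable for users who want, say, a cost-sensitive
substitution matrix.

The reference is consumed as a variant/probability table
(`read_stoch_lang()`), not as a Petri net: playing out arbitrary models is
delegated to dedicated process-mining tools, and a stochastic language is
the exchange format they can all emit.

## Triage quality (Q4)

Q4 is the fraction of cases whose recorded KTAS equals the level an
explicit rule table assigns from vital signs (GCS, SpO₂, systolic blood
pressure, pulse, respiration, temperature, pain score). The package ships
`triage_rules_synthetic()`, a deterministic most-urgent-first table that
is **a synthetic placeholder** — the actual Korean Ministry of Health and
Welfare decision rule is not publicly printed — so real assessments must
supply their own table as JSON. The classifier contract is deliberately
simple: levels 1–4 are checked in order, the first level with any matching
condition wins, and level 5 is the fallback, which makes the assignment
deterministic and every level reachable.

## The synthetic-data generator

Because hospital EHR logs cannot be redistributed, every indicator is
validated against a discrete-event simulator with known ground truth. The
default scenario emulates the structure of a year of tertiary-hospital ER
data: the 15 canonical ER activities; eight care pathways averaging ~14.6
activities per case (so 30 000 patients produce ~440 000 events), 36% of
pathway mass ending in hospitalization; a KTAS mix of
(0.01, 0.07, 0.35, 0.42, 0.15) with service-time multipliers
(1.5, 1.3, 1.0, 0.8, 0.7) so severe patients occupy the process longer; a
day-peaked arrival profile; five day-shift and three night-shift doctors;
exponential service times whose means were chosen once, analytically, so
the expected LOS is ≈5.5 h for discharged and ≈11 h for hospitalized
pathways (the scale reported for tertiary-hospital ERs); and a 0.4%
revisit probability. These defaults define the study conditions — they
are inputs, never test oracles.

Ground truth is computed analytically from the configuration: expected LOS
overall, per KTAS group and per terminal activity; the occurrence-weighted
expected cycle time per activity; the expected initial response time;
variant probabilities; staffing per hour. Recovery tests then check that
the estimators land within three standard errors of these expectations on
a 5 000-case log. One global seed spawns per-patient sub-seeds, so a given
patient's trace is reproducible regardless of cohort size and identical
seeds give byte-identical logs.

`simulate_vitals()` samples vital signs that the rule table maps back to
each case's KTAS level and then, with probability `noise`, re-draws the
*recorded* level to disagree — making the expected triage accuracy exactly
1 − noise. `inject_imperfections()` plants the four imperfection patterns
on disjoint cases with a manifest, so preprocessing can be verified to
remove exactly what was planted, with no false positives on clean logs.

What the generator does **not** emulate: queueing interaction between
patients (service times are drawn independently, so congestion does not
lengthen stays), resource contention, case-mix drift over the year,
incomplete KTAS recording, or free-text activity noise. Passing the
recovery tests therefore shows the estimators are correct for the data
model, not that any real department behaves like the scenario.

## Numerical choices and degenerate inputs

* Simulated timestamps are rounded to whole seconds, which is both what
  hospital systems record and what makes the telescoping identity
  (per-case cycle times summing exactly to LOS) hold without floating
  tolerance.
* Stochastic-language probabilities must sum to 1 within 10⁻⁹; the
  transport solver treats masses below 10⁻¹² as zero.
* Empty selections are values, not errors (a variant selector matching no
  case returns an empty sample); truly undefined quantities error (a
  standard deviation of fewer than two cases, aggregation of an empty
  sample, the total cost of a cost-detached log).
* Activity labels are matched case-insensitively after trimming; `entry`
  and `consultation` are configuration, not constants.
* `erppi_report()` degrades gracefully: indicators whose inputs are
  missing are reported as `not computable` with a reason, because real
  case studies routinely lack cost columns or vitals.

## Problem sizes used in the validation suite

The test suite exercises: 200 random transportation instances against the
exhaustive oracle; 100 random logs each for the telescoping and DFG
equivalences; 50 logs for the workload identities; a 5 000-case recovery
run; a 2 000-case triage-noise run; and one full 30 000-case /
~440 000-event report, which completes in well under a minute per stage on
a single CPU. These sizes were chosen to make sampling error small
relative to the three-standard-error bands while keeping the suite quick
to run.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_erlog(er_scenario(n_patients = 1000, seed = 42))
log <- simulate_vitals(sim$log, noise = 0.3, seed = 42)
ref <- stoch_lang(names(sim$truth$variant_probs),
                  as.numeric(sim$truth$variant_probs))
report <- erppi_report(log, reference = ref)
report
summary(report)
plot(log)   # dotted chart coloured by urgency group
```

## Known limitations

* The exact transport solver is dense; huge log-to-log comparisons should
  first truncate to the most frequent variants.
* Workload from complete-only logs conflates waiting and service.
* No survival treatment of censored stays: every case is assumed complete,
  so a log cut mid-stay biases LOS downward.
* The shipped triage table is synthetic; Q4 values against it characterise
  the machinery, not Korean triage practice.
* `build_cases()` offers deletion-style remedies only; partial repair of
  corrupted cases is out of scope.
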