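---
title: "Modeling radiotherapy pre-treatment workflow control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling radiotherapy pre-treatment workflow control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtflowsim)
```

## The system being modeled

Between the first consultation with a radiation oncologist and the first
irradiation session, a radiotherapy patient passes through a chain of
preparation steps: a planning CT (sometimes preceded by a medically intended
delay of one to eight weeks), optional MRI and PET-CT scans, image
post-processing (motion-compensation warping for 4DCT and registration of
multiple image sets), contouring of the target and organs at risk by a
doctor of the matching specialty followed by an on-site peer review, and
treatment planning by a planning radiotherapy technologist (RTT). The
calendar time this chain takes is the patient's *waiting time*, the primary
key performance indicator, compared against national targets of 1 calendar
day for acute, 10 for subacute and 28 for regular patients.

The first-fraction date can be fixed at two different moments, and that
choice is the workflow-control question this package exists to study:

* **pull** — the date is fixed right after consultation. Acute and subacute
  patients are always pull (their start must be guaranteed), as are regular
  patients whose radiotherapy is combined with surgery or chemotherapy
  (the other modality has to be coordinated). If the pre-treatment chain is
  not finished in time, the start is postponed — a *rebook*.
* **push** — the date is only fixed once contouring is done and planning has
  started, so work flows freely and rebooks cannot occur, but nothing pins
  the chain to a deadline.

`simulate_rt()` executes this system as a discrete-event simulation;
`run_pull_sweep()` promotes tumor sites to pull one group at a time
(baseline roughly 40% pull up to 100% pull) and `run_experiment()` applies
capacity and scheduling interventions to the baseline, both under common
random numbers.

## What the synthetic department emulates

No patient-level hospital data ships with this package. `default_config()`
builds a synthetic department calibrated so that every published summary
statistic of the system the model is patterned on is reproduced *exactly in
expectation*:

* weekday-dependent Poisson arrivals with means 17.5 (Mon), 20.9, 23.2,
  21.7 and 15.5 (Fri) patients per day, split over eight tumor sites
  (bone metastasis, breast, lung, brain, prostate, head-and-neck, chest
  wall, others);
* urgency mix 1.3% acute / 30.8% subacute / 67.9% regular;
* step prevalences: MRI 18.5%, PET-CT 3.9%, warping 12.4%, image
  registration 29.7%, beam set-up 34.7%; planned delay 13% (uniform 1–8
  weeks); baseline pull share 40.8%; 93% of bone-metastasis patients get
  the simple beam set-up (P2) planning.

The calibration works by giving each site a propensity weight for each
attribute and rescaling the weights so the site-share-weighted mixture hits
the published marginal; `config_marginals()` returns the implied values in
closed form and is the oracle the sampling tests check against. Two pieces
are genuinely invented, because only their existence, not their values, is
published:

* the per-site shares of arrivals (row sums of the rate matrix) and their
  weekday clustering. Site-specific consultation clinics concentrate on
  fixed weekdays (lung on Wednesdays, prostate on Tuesdays, head-and-neck
  on Mondays/Thursdays); breast and "others" absorb the residual so the
  weekday column totals stay exact. The clustering strength is a realism
  choice — it is what the spread-consultations intervention removes;
* the catalogue structure: two care plans per site (a palliative/urgent
  plan holding the site's acute and subacute mass with a reduced
  probability of extra imaging steps, and a standard regular plan whose
  step probabilities are raised so the site mixture stays exact). Real
  departments distinguish of the order of sixty trajectories; collapsing
  them to sixteen preserves every checkable marginal while keeping the
  configuration readable and overridable.

Time-to-treatment tables are published only through their supports (0–1
days acute, 1–8 subacute, 3–21 regular pull, 1–7 push planning-to-start
gap). The defaults use truncated-geometric masses over those supports,
with decay rates chosen once so that pull waiting times sit plausibly near
the published validation means; draws are conditioned on landing on an
admissible start day, which is what makes a Tuesday head-and-neck consult
(Monday starts only) come out at 6 or 13 days. Because the real tables are
feasibility-aware in a way a parametric stand-in cannot be, simulated
rebook *counts* run well above the published ones; the package therefore
treats rebooks (and all headline outcome magnitudes) as directional
quantities, and the acceptance checks assert directions, not magnitudes.

## Resources

Machine capacity follows the published numbers: 26 CT slots of 25 min per
day across 2 scanners, 37 weekly MRI slots of 45 min, 5 weekly PET-CT
slots of 45 min, all inside the 07:30–17:30 department day. The first two
morning CT slots of each scanner exclude IV-contrast patients and one CT
slot per day is reserved for acute patients (an unused reservation expires
at the end of the day). MRI/PET-CT slots are spread over the week
(8/7/8/7/7 and 1 per day) since their placement is unpublished.

Doctors follow the published team sizes (Lung 7, Head-and-neck 9, Breast 9,
CNS 3, Gynecology 4, GI 5, Urology 7; 44 in total; the breast team also
covers chest wall, "others" split between gynecology and GI). Real agendas
are not available, so each doctor gets a synthetic weekly template leaving
35% of a 08:00–17:00 shift available for contouring: roughly 70% of that on
two weekly "contouring days" and a short daily block otherwise, so urgent
(90-min) contours fit any day but regular (120-min) ones usually wait for
a heavy day. Absences are drawn at 25 days/year. The balancing
intervention redistributes exactly the same weekly minutes into equal
daily blocks of at least two hours.

Planning RTTs hold skill levels with downward compatibility (P4 ⊃ P3 ⊃
P2); P3/P4 planners run two plans concurrently, P2 planners one. The
published total is 24 planners but the published enumeration (3 P2, 7 P3,
10 P4) sums to 20; the default keeps the stated total with 3/7/14 and
`default_config(planner_preset = "enumerated")` provides the 3/7/10
alternative.

## Scheduling and dispatch rules

* Imaging is booked at consultation on a first-come-first-planned basis:
  the chronologically first admissible unbooked slot at or after the
  earliest date (arrival plus planned delay), CT before MRI before PET-CT.
* Contouring and planning queues are served in earliest-due-date (EDD)
  order — due date = scheduled start for pull patients, arrival plus the
  national target for push patients — with ties broken by arrival order.
  Palliative tasks (acute or bone metastasis) may go to any doctor or
  planner; other contours wait for the patient's assigned specialist,
  drawn uniformly within the team at consultation.
* A contouring task needs one contiguous free block covering contouring
  plus the 60-min peer review (the reviewing colleague is modeled as
  costless, as an on-site double-check); it never splits across days.
  Planning tasks do split overnight — a 960-min head-and-neck plan cannot
  fit a single 10-hour day, and planning is software-driven — resuming the
  next working morning.
* Image post-processing lags are pure elapsed time (lognormal,
  moment-matched to mean 0.4/SD 0.6 days for CT-to-warping and 0.1/1.0 for
  scan-to-registration); no staff resource is consumed, since the
  published measurements are elapsed times with no resource named.
* Push patients get their start date when planning starts: a 1–7 day gap
  conditioned on an admissible weekday (any weekday constraint is
  reachable within 7 days). If the plan somehow finishes after the
  scheduled day, the start slides forward without counting as a rebook.
* Pull rebooks are decided at a 17:30 checkpoint the day before the
  scheduled start and again at the start instant (16:00): an unfinished
  plan postpones the start to the next admissible day and increments the
  rebook count. Two refinements keep the rule from double-counting: at
  most one postponement decision is taken per patient per day, and the
  day-ahead checkpoint does not apply to acute patients, whose entire
  pathway by design fits inside the start day itself.

## Numerical and engine choices

Simulation time is integer minutes from a configurable origin Monday; all
published durations are exact multiples of a minute, so schedules carry no
floating-point drift. Events are ordered by (time, priority tier,
insertion sequence), a strict total order that makes every run a
deterministic function of the configuration and seed; completion events
use a lower tier than request events so freed capacity is visible to
requests at the same instant. Every stochastic component draws from its
own named substream seeded from (base seed, stream name, replication), so
a scenario edit perturbs only the draws it touches — the common-random-
numbers setup used by the scenario comparisons and verified by a
stream-audit test. The event calendar is an indexed binary heap in C++
with O(1) observable cancellation; handlers are plain R.

Dispatch happens only at decision instants — block openings, task
completions, tasks becoming ready — so the EDD rule is applied to the set
of tasks actually ready, and a free resource is never held idle while an
eligible task waits (work conservation, checked against a brute-force
queue simulation on one-doctor instances).

## Replication analysis

`replication_relative_error()` implements the t-based halfwidth of the
confidence interval of replication means divided by the mean;
`required_replications()` grows the replication count until that relative
error clears the 0.05 threshold at a 95% confidence level, and
`warmup_curve()` estimates the warm-up length as the day after which the
cumulative mean waiting time stays inside a ±2% band of its final value.
Experiments default to 15 replications of a 130-day warm-up plus a
365-day measured horizon (about 5,000 patients per replication); the
acceptance checks run the pull sweep at three nested points (baseline,
four sites promoted, all eight) plus the spread-consultations scenario at
those full sizes, and the input-distribution checks use 10^5-patient
draws. Waiting times exclude the planned-delay weeks by default (a
medically intended 1–8-week delay is not waiting; the switch
`kpi$waiting_time_excludes_planned_delay` restores raw differences), and
breaches are strict: "within 10 days" means day 10 is on time. Rebook and
breach counts are attributed to patients whose *arrival* falls inside the
measured window.

## What passing tests do and do not show

The test suite demonstrates that the generator reproduces the published
input distributions, that the statistics follow their closed forms, that
single-patient trajectories match hand-traced schedules, and that the
workflow-control directions (waiting times and rebooks rising with the
pull share, target breaches falling, consultation spreading lowering the
mean waiting time) emerge on the synthetic department. It does not show
that outcome *magnitudes* transfer to any real department: those depend
on the empirical per-trajectory distributions, real staff agendas and
feasibility-aware booking practices that are not publicly available. The
model also deliberately omits behavior outside the published mechanism:
overtime, skipped meetings, physicist plan checks and plan rework, the
referral-to-consultation stage, and irradiation sessions beyond the first.
A backward-scheduling variant for pull imaging (booking backwards from the
fixed start date) is a recognized alternative reading of pull control; the
single forward flow is what is implemented, and the configuration carries
a placeholder flag for the variant.
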