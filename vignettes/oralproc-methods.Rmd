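---
title: "Methods: measuring oral food processing efficiency and its robustness to discontinuous observation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring oral food processing efficiency and its robustness to discontinuous observation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Primate feeding studies in the wild suffer from interrupted visibility: an
animal turns away, moves, or is occluded, so the observer records only part
of a feeding bout.  Experimental settings allow the opposite: complete
("continuous") feeding sequences, coded behavior by behavior from the
moment a food item enters the oral cavity to the last swallow or discard.
`oralproc` operationalizes a developmental question — do younger tufted
capuchins process food less efficiently than older ones, and how do food
size and mechanical properties modulate this? — and a methodological one:
if only a *part* of each feeding sequence had been observed, would the
same statistical conclusions have been drawn?

The package works on event-level ethogram logs with a closed behavior set
of three categories: anterior ingestion (bites on incisors and canines),
posterior ingestion (bites on premolars and molars), and chewing.  A chew
*bout* is one continuous chewing episode and carries its own count of
individual chews.  Event times are stored as integer video frames
(30 frames per second by default) and converted to seconds only inside the
metrics, so no floating-point drift enters the stored data.

## Efficiency measures

Four sequence-level responses operationalize oral food processing
efficiency (six model responses once behavioral frequency is split by
behavior type):

* **Duration (s)** — from the start of the first event to the end of the
  last.  Pauses between coded behaviors are part of the sequence, so the
  default is the full span; a `sum_of_events` mode (coded event time only)
  is available for sensitivity analysis.  The distinction only matters
  when the coding leaves gaps between events, which the file format
  permits.
* **Behavioral frequency** — the count of events per behavior type; a
  chew bout counts once however many chews it contains.
* **Chew number** — total individual chews summed over bouts.  Chewing
  may occur twice in a sequence yet consist of ten chews; the two
  quantities are deliberately distinct.
* **Unique behavior patterns** — consecutive behaviors are grouped into
  ordered sets of three and the number of *distinct* patterns is counted.
  We read "sets of three" as overlapping sliding windows (stride 1) and
  "unique" as a distinct-type count, because a type count is the natural
  reading of a number of unique patterns; both alternative readings
  (disjoint windows via `stride = 3`, token counts via
  `count = "tokens"`) are exposed as arguments since the published
  wording does not fully disambiguate.  Sequences with fewer than three
  events contain no complete pattern and score 0; shorter patterns are
  not back-filled.

## Discontinuous observation schemes

Three schemes map a continuous sequence to a partial record:

* **first half** — the first ⌈n/2⌉ events;
* **last half** — the remaining ⌊n/2⌋ events (exact complement);
* **random** — a random-length contiguous run of at least four events
  (the whole sequence when it is shorter than four).

Halves are defined by event *count*, not elapsed time, and an odd-length
sequence gives its extra event to the first half; this reproduces the
canonical 7-behavior worked example, which splits 4 + 3.  The last half of
a single-event sequence returns that event rather than an empty sequence,
so downstream metrics never see empty input.  Random subsamples default to
contiguous runs — an interrupted observation is a window, and the
published example draw is a contiguous slice — but an order-preserving
arbitrary-subset mode (`contiguous = FALSE`) exists for sensitivity
analysis.  Sequences shorter than the minimum are used whole rather than
dropped; a field observer would still record a short bout.

Random draws are seeded per `(base seed, iteration, sequence)` via a
deterministic string hash, so results are independent of iteration order
and of any parallel execution layout, and every draw is exactly
reproducible.  `iterate_random()` streams iterations through a reducing
function — the study design calls for 10,000 iterations, and materializing
10,000 datasets of fitted models would be both pointless and memory-hostile.

## The mixed-model battery

Each hypothesis fixes a fixed-effect structure fitted separately per
response with Gaussian linear mixed models (REML, `lme4`):

| id  | fixed effects                 | question                      |
|-----|-------------------------------|-------------------------------|
| H1  | age class × sex               | sex differences by age        |
| H2  | age class                     | ontogenetic change            |
| H3  | age class × volume            | food geometric properties     |
| H4a | age class × toughness         | food toughness (R, J m⁻²)     |
| H4b | age class × elastic modulus   | food stiffness (E, MPa)       |

Pooled (all-foods) models carry crossed random intercepts for food type
and animal identity; within-food models keep only the animal intercept.
With five food levels the food variance component is inherently noisy —
that is a property of the design, not a defect, and convergence failures
are expected for models where a food property is nearly confounded with
the food intercept (the toughness models are the canonical case).
Count-valued responses are modeled as Gaussian deliberately: the analysis
this package operationalizes did so, and matching that choice is the point;
a Poisson GLMM alternative is out of scope.

Numerical choices:

* Continuous food properties are z-standardized before fitting
  (raw-scale columns remain in the table); large raw scales
  (toughness spans 116–2979 J m⁻²) otherwise destabilize the optimizer.
* Omnibus tests are type-III F tests on sum-coded factors.  Denominator
  degrees of freedom default to containment-style residual df
  (`n − rank(X)`), the convention of the `nlme` family; Satterthwaite is
  available via `df_method`.  Simulation under the null generator shows
  the residual-df test holds its nominal size on the design sizes used
  here, while Satterthwaite is mildly conservative for the low-count
  responses.
* Non-convergence is caught (optimizer status and convergence warnings),
  flagged on the result, and never raised; singular fits (a variance
  component at zero) are *not* treated as failures — a zero variance
  estimate is a legitimate boundary estimate.
* A factor with fewer than two observed levels, or a covariate constant
  in the fitted subset (any food property within a single food), raises a
  structured `oralproc_degenerate_design` error; the battery runner skips
  such cells with a warning.

Pairwise comparisons use estimated marginal means with Tukey's
studentized-range adjustment.  For interaction hypotheses both
conventions are emitted under distinct factor keys: marginal age and sex
contrasts (averaged over the companion factor at balanced weights) and
joint cell-by-cell contrasts (e.g. subadult/adult male vs juvenile
female), since published tables mix within- and cross-level cells.
Contrasts from two-level factors are unadjusted by construction (the
studentized range with k = 2 reduces to the t test), which the tests
verify.

## Replication scoring

A test decision is three-valued: significant (p < α, strictly — p = α
counts as non-significant under "significance was set at 0.05"),
non-significant, or failed (non-converged).  A key replicates when its
decision from a discontinuous analysis matches the continuous one;
effect direction and magnitude are reported but not scored.  A fit that
failed on either side removes its whole hypothesis × response × scope
cell from the denominator — the term keys of an unfitted model are
unknowable, and failed cells are reported separately, mirroring how
published tables mark them.  Because the ambiguity of whether published
replication denominators count omnibus terms, contrasts, or both cannot
be resolved from the text, `significance_vector()` scores at either or
both levels (`level = "term" | "contrast" | "both"`).

## The synthetic-data generator

No raw data accompany the study this package operationalizes (videos are
available only on request), so the generator is a first-class module: it
emulates the study design closely enough that every pipeline stage is
testable, and its defaults *are* the study conditions.

* **Roster**: the 29-animal study roster (2 infants, 12 juveniles, 4
  older juveniles, 11 subadults/adults with the published sexes, body
  masses and origins), with the observed per-animal-per-food trial counts
  (`trials = "table2"`).  Those printed counts sum to 494 while the
  continuous analysis is described as 488 sequences — a 6-trial
  discrepancy in the source that we surface rather than resolve; with the
  infant–popcorn cell forced empty (infants never consumed popcorn) the
  generator yields 493.  Uniform or fixed trial counts are available for
  reduced designs.
* **Chew model**: expected total chews per sequence follow a
  multiplicative power law in food volume, elastic modulus and toughness,
  with lognormal animal, food and residual effects and a Poisson
  realization.  Effects are multiplicative because counts and durations
  are positive and right-skewed; the Gaussian LME is then an
  approximation for the synthetic data exactly as it is for real data.
  The exponents (volume 0.641, modulus 0.091, toughness −0.026) and the
  baseline (48.26 chews at the geometric-mean food) were calibrated once,
  by weighted least squares, so that juvenile and subadult/adult per-food
  mean chew numbers fall centrally inside the observed per-food ranges
  (16.9–21.8 for sunflower seed up to 83.5–149 for almond); the narrow
  sunflower band dominates the weighting.  A mean-correction term keeps
  configured multipliers on the arithmetic-mean scale.
* **Age and sex effects**: chew-count multipliers (infant 1.22, juvenile
  1.12, older juvenile 1.05, subadult/adult 1) and tempo multipliers
  (1.45/1.25/1.10/1) on event durations.  Jointly these give an
  infant-to-adult duration ratio near 1.8 for a fixed food, consistent
  with the observation that infants take roughly twice as long as adults
  on the same item.  A male chew multiplier of 0.97 encodes the weak,
  inconsistent sex effects reported.  `age_effect_scale` scales all log
  age effects (0 = none, 2 = doubled) and defines the `strong_effects`
  preset used for parameter-recovery tests; the `null` preset removes all
  effects and all between-unit variance for type-I-error calibration.
* **Grammar**: every sequence opens with an ingestion bite (anterior
  with probability 0.85), followed by chew bouts of mean size 6 with
  further bites (40% anterior) interposed with probability 0.35.
  Variances: animal SD 0.10, food SD 0.02, residual SD 0.20 on the log
  scale — between-animal and within-animal coefficients of variation of
  roughly 10% and 20%, typical of repeated behavioral counts.

What the generator does **not** emulate: tongue-palatal processing and
limb pulls (excluded from the ethogram), learning across trials, social
or competitive context, food texture dimensions beyond the three measured
properties, and any biomechanically realistic chewing kinematics.
Passing tests therefore show that the *pipeline* recovers what it assumes
the data contain — they do not validate the behavioral model against real
capuchins.

## Problem sizes and reproducibility

The shipped tests run the null calibration with 500 simulated reduced
designs (12 animals, 2 foods, 3 trials), the recovery study with 200
paper-scale generations plus a 3-point effect-size curve at 50 runs per
point, and the end-to-end reproducibility check at 200 random iterations;
`scripts/acceptance.R` runs the full battery on a paper-scale dataset
with 100 random iterations.  These sizes keep a complete run comfortably
interactive while leaving Monte-Carlo error well below the effect sizes
being checked; all of them are arguments, and the 10,000-iteration study
design is one `n_random_iterations = 10000` away.  Every random stage —
generation, subsampling, iteration — is seed-deterministic, and
`run_all()` writes a manifest (seed, config hash, package versions) with
byte-reproducible outputs.

## Known limitations

* Gaussian models on counts are faithful to the operationalized analysis
  but statistically crude for rare behaviors (posterior ingestion
  frequency can be mostly 0–3); simulated type-I error stays near nominal,
  power comparisons against a count GLMM were not attempted.
* The food variance component rests on five levels; its estimate is
  noisy by design, and within-food models quietly lose all food-property
  hypotheses (they are degenerate there and are skipped with a warning).
* Replication percentages depend on the decision-level convention
  (terms vs contrasts); both are computed, neither is privileged.
* The generator's bout grammar is the simplest structure consistent with
  the coding scheme; it reproduces means and dispersions, not serial
  dependence within sequences beyond the bite–chew alternation.
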