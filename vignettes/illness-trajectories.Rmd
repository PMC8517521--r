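---
title: "Modelling post-sepsis illness trajectories as a discrete-time Markov chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling post-sepsis illness trajectories as a discrete-time Markov chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(illnesschain)
```

## The model

Children in a pediatric intensive care unit (PICU) with suspected sepsis can
be monitored with a continuous risk score — the fold increase in the risk of
developing sepsis relative to the unit average, on a scale of roughly 0 to 8.
This package models the 72 hours following the sepsis event as a
discrete-time Markov chain over **illness states** obtained by binning that
score: state 0 for scores in $[0, 1)$, state 1 for $[1, 2)$, state 2 for
$[2, 3)$, and state 3 for all scores of 3 or higher. Observations are taken
every 30 minutes, so the chain's transition matrix $P$ has entries

$$p_{ij} = \Pr(S_{t+1} = j \mid S_t = i),$$

the probability of moving from illness state $i$ to state $j$ over one
30-minute step, estimated by counting observed adjacent transitions and
dividing each row by its total. Two variants are estimated: a states-only
$4 \times 4$ matrix, and a $5 \times 5$ absorbing matrix whose last row and
column represent death (once entered, never left; its unobservable row is
fixed to the absorbing identity rather than estimated).

The chain is first-order ("memoryless": the next state depends only on the
current one) and assumed time-homogeneous over the analysis window. Both
assumptions are checked rather than taken on faith — see *Assumption
checks* below.

### The entropy matrix

Row-normalized probabilities hide where transition *activity* concentrates.
The **entropy matrix** therefore divides every transition count by the total
number of observed transitions, so all cells sum to one, and summarizes the
joint distribution with Shannon entropy in nats,

$$H = -\sum_{i,j} q_{ij} \ln q_{ij}, \qquad 0 \cdot \ln 0 = 0 .$$

$H = 0$ when all transitions sit in a single cell; $H = \ln 16 \approx 2.77$
when a $4 \times 4$ matrix is uniformly occupied. Comparing $H$ between
strata (ventilated vs not; age $\le 1$ year vs older) quantifies differences
in the *structure* of transition activity. Entropies are computed on the
states-only matrix: stratum comparisons are made against the 16-cell
reference scale, and death-terminal rows are excluded from the denominators.
No pseudocounts are added anywhere — unobserved rows stay empty and are
flagged, because imputation would silently change entropies.

### Mean first passage times

For an irreducible states-only chain, the expected number of steps to first
reach state $j$ from state $i$ solves the linear system

$$m_{ij} = 1 + \sum_{k \ne j} p_{ik}\, m_{kj},$$

solved per destination as $(I - P_{-j,-j})\,m = \mathbf{1}$ and converted to
hours at 0.5 h per step. Diagonal entries are reported as 0 by convention:
re-entry times are not calculated. Passage times are computed on the
non-absorbing chain; with death included, hitting times to transient states
would be infinite with positive probability. Reducibility is detected by
reachability analysis on the positive-probability digraph *before* solving,
so a disconnected chain produces a diagnostic naming the unreachable
(source, destination) pairs instead of garbage from a singular system.

## The synthetic cohort generator

Because the clinical dataset cannot be redistributed, every analysis here
runs on synthetic cohorts with *known* ground truth, generated by
`generate_cohort()` from a `chain_spec`. The default spec
(`default_chain_spec()`) encodes the study conditions of the modelled
cohort:

* 157 admissions observed every 30 min for 72 h after the sepsis event;
* four illness states with strong diagonal persistence (staying
  probabilities 0.77–0.95);
* an initial state distribution proportional to the cohort's observed state
  occupancy (3878 / 6433 / 4129 / 4226);
* ventilation in 129/157 admissions and age 0–1 in 78/157, assigned
  independently;
* a distinct kernel for non-ventilated admissions, concentrating transitions
  in the highest illness state (staying probability 0.95 there) — so the
  ventilation strata differ in entropy while the age strata, which mix both
  kernels equally, do not;
* per-state per-step death hazards of $10^{-4}$ to $2 \times 10^{-3}$,
  increasing with severity, chosen so that roughly one admission in ten dies
  within the window (the modelled cohort had 16 in-window deaths of 157);
* a per-observation gap probability of 0.004, matching the observed fraction
  of nonconsecutive scores (71 of ~18.7k).

Scores are emitted uniformly within the current state's bin (top bin
uniform on $[3, 8]$), which guarantees that equal-width binning inverts
generation exactly — the discretization stage can be tested against the
generator's latent states. A death replaces the next observation: no score
is emitted at or after the recorded death time, making the absorbing
transition count unambiguous.

**What the generator does not emulate.** Real risk-score series are
autocorrelated *within* a bin (a score of 3.1 is likelier to be followed by
3.3 than by 7.9); the uniform-within-bin rule destroys that sub-bin memory.
Consequently, refining the binning to 5 or 6 states splits the former top
bin into sub-states that mix freely among themselves, and those rows are not
diagonal-dominant on synthetic data even though the coarse 4-state structure
is preserved. Passing tests therefore validate the pipeline's arithmetic and
its estimators, not the clinical claim that finer binnings stay
diagonal-dominant on real data. The marginal within-bin distribution of real
model output is unknown; uniform is a deliberate stand-in, not a claim.

## Data shaping rules

* **Grid and window.** Observation times are minutes since the sepsis event.
  15-min series are thinned to the 30-min grid by keeping times divisible by
  30, anchored at t = 0. A transition pair belongs to the 3-day analysis
  when its two observations are exactly 30 min apart and its destination
  lies in (0, 4320] minutes; the t = 0 observation participates only as a
  pair's origin.
* **Discards.** Observations isolated by gaps on both sides form no
  exact-gap pair and are counted as discarded — discard accounting counts
  observations, not pairs. The exact identity
  `observations = pairs + run_heads + discarded` (where a run head is the
  first observation of each consecutive run of length ≥ 2) is asserted on
  every cohort.
* **Death binning.** The terminal absorbing row attaches after the last
  on-grid observation preceding death, regardless of any gap before the
  death time, and only for deaths inside the window. This maximizes the use
  of observed deaths; no published rule exists for the gap case, so the
  choice is made explicit here and exercised in tests.
* **Interval closure.** Bins are half-open $[a, b)$ with the top bin
  unbounded. Published bin descriptions overlap at integer boundaries; the
  half-open convention partitions the line and is consistent with the top
  state containing "all scores 3 or higher". A boundary score of exactly 1.0
  lands in state 1.

## Numerical and design choices

* **Estimation is deterministic**; only trajectory simulation consumes
  randomness. Each simulated trajectory in a panel uses a sub-seed derived
  from (master seed, trajectory index), so panels are reproducible as a
  whole and per member.
* **Zero-support rows** are reported all-zero with a `row_support` flag.
  Simulation entering such a row truncates with an explicit flag; an
  absorbing state instead holds to the horizon with the absorption step
  recorded, keeping panel output fixed-length for plotting and occupancy
  arithmetic.
* **Equal-count binning** places edges at the $k/K$ quantiles (type 7) of
  the pooled scores; ties at an edge may unbalance counts by the number of
  tied values, and fitting fails loudly when fewer than $K$ distinct scores
  exist.
* **Time-homogeneity check.** The 3-day and 7-day estimates are compared
  cell-wise; a cell is flagged when the difference exceeds 3 binomial
  standard errors of the pooled estimate with each window's row totals
  (conservative, since the windows nest). The check reports differences and
  flags without declaring a model winner — the published criterion for
  "modelled better" was not stated, so this package deliberately reports
  rather than adjudicates.
* **Occupancy fit** is the concrete realization of a per-state model-fit
  display: the empirical distribution of states among admissions observed at
  each step is compared with the initial distribution propagated through the
  fitted matrix. Admissions leave the at-risk denominator after death or
  their last observation, so censoring is never treated as a state.
* **Problem sizes.** Tests use cohorts of 40–500 admissions, Monte-Carlo
  hitting-time oracles with $10^5$ chains, and single trajectories of
  $10^5$ steps — sizes at which binomial noise is far below the asserted
  tolerances (e.g. kernel recovery to $L_\infty$ 0.02–0.05).

## A worked example

```{r example, eval = FALSE}
spec <- default_chain_spec()
cohort <- generate_cohort(spec, n_admissions = 157, seed = 1)
tab <- as_cohort_tables(cohort)

scheme <- binning_scheme("equal_width", 4)
pairs <- make_transition_pairs(assign_states(tab$observations, scheme),
                               tab$covariates)
counts <- count_transitions(pairs, 4)
P <- row_normalize(counts)
attr(make_entropy_matrix(counts), "entropy_nats")  # ~1.95 nats
mean_first_passage(P)                              # hours, diagonal 0
```

The numbered scripts under `analysis/` run the same pipeline end to end and
write their tables under `results/`.

## Known limitations

* The generator's kernels are plausible inventions consistent with the
  published summary structure, not estimates from clinical data; quantities
  computed on synthetic cohorts are analogues, not reproductions, of the
  cohort-specific published values.
* Only first-order, time-homogeneous chains are fitted; second-order
  dependence is out of scope by design.
* One sepsis event per admission at t = 0 is assumed by the reader.
* No confidence intervals accompany transition probabilities or entropies;
  the analysis is descriptive, matching its scope.
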