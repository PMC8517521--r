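# illnesschain

Discrete-time Markov chain analysis of pediatric-sepsis illness
trajectories.

Children in a PICU with suspected sepsis can be followed with a continuous
risk score (fold increase in sepsis risk, scale ~0–8) computed every 30
minutes. `illnesschain` turns those score series into discrete **illness
states** (state 0: scores in [0,1), … state 3: scores ≥ 3) and models the
72 hours after the sepsis event as a discrete-time Markov chain, for
clinical researchers studying post-diagnosis disease dynamics:

- **Transition matrices** `P[i,j] = Pr(next = j | current = i)` per 30-min
  step, estimated from adjacent observation pairs, with and without death as
  an absorbing fifth state;
- **Entropy matrix**: all transition counts divided by the grand total
  (cells sum to 1), summarized by Shannon entropy `H = -Σ q ln q` in nats —
  0 for a point mass, ln 16 ≈ 2.77 for a uniform 4×4 matrix — to compare
  transition structure between strata (ventilated vs not, age ≤ 1 y vs
  older);
- **Mean first passage times** in hours, solving
  `m_ij = 1 + Σ_{k≠j} p_ik m_kj` per destination (diagonal 0 by
  convention);
- **Trajectory simulation** from any fitted matrix (multinomial draws per
  row, reproducible sub-streams);
- **Assumption checks**: 3-day vs 7-day window comparison with per-cell
  noise bounds, 5/6-state and equal-count binning sensitivity, and
  occupancy-curve goodness of fit.

Because the clinical data cannot be redistributed, the package ships a
**synthetic cohort generator** (`generate_cohort()` + `default_chain_spec()`)
that emulates the study conditions — 157 admissions, 30-min sampling over
72 h, strong diagonal persistence, stratum-dependent kernels, occasional
observation gaps, and death absorption in a minority of admissions — with
known ground truth, so every stage is testable by parameter recovery.

## Worked example

```r
library(illnesschain)
spec   <- default_chain_spec()
cohort <- generate_cohort(spec, n_admissions = 157, seed = 1)
tab    <- as_cohort_tables(cohort)
pairs  <- make_transition_pairs(
            assign_states(tab$observations, binning_scheme("equal_width", 4)),
            tab$covariates)
counts <- count_transitions(pairs, 4)
P      <- row_normalize(counts)
round(unclass(P), 3)
#>     to
#> from     0     1     2     3
#>    0 0.857 0.124 0.016 0.003
#>    1 0.092 0.812 0.078 0.019
#>    2 0.011 0.112 0.777 0.100
#>    3 0.004 0.014 0.098 0.884
attr(make_entropy_matrix(counts), "entropy_nats")
#> [1] 1.952899
round(unclass(mean_first_passage(P)), 1)
#>     to
#> from    0    1    2    3
#>    0  0.0  4.5 11.1 19.5
#>    1 11.8  0.0  8.6 17.0
#>    2 17.2  7.2  0.0 11.8
#>    3 20.3 10.5  5.7  0.0
```

Reading the output: each admission most likely stays in its current illness
state over 30 minutes (diagonal 0.78–0.88; an 81% chance of remaining in
state 1). The joint-transition entropy 1.95 nats sits well below the
uniform maximum 2.77 — transition activity is concentrated, mostly on the
diagonal. A patient in the lowest illness state needs about 19.5 h on
average to first reach the highest state; the reverse passage takes about
20.3 h.

The numbered scripts in `analysis/` (`01_simulate_cohort.R` …
`06_sensitivity.R`) run the full workflow — simulate, discretize, estimate,
simulate trajectories, passage times, sensitivity checks — and write their
tables under `results/`.

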