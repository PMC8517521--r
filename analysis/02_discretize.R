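#!/usr/bin/env Rscript
# Stage 2: discretize risk scores into illness states and extract the
# adjacent 30-min transition pairs for the 3-day analysis window.
#
# Scores below 1 are state 0, [1,2) state 1, [2,3) state 2, and all scores
# of 3 or higher state 3. Only pairs of observations exactly 30 min apart
# enter the analysis; isolated (nonconsecutive) observations are discarded
# and counted. In-window deaths append one terminal absorbing row after the
# last observed state.

library(illnesschain)

cohort <- read_cohort("results/cohort/observations.csv",
                      "results/cohort/covariates.csv")
tab <- as_cohort_tables(cohort)
scheme <- binning_scheme("equal_width", n_states = 4)
state_obs <- assign_states(tab$observations, scheme)
pairs <- make_transition_pairs(state_obs, tab$covariates,
                               step_minutes = 30, window_minutes = 72 * 60)
bk <- attr(pairs, "bookkeeping")

dir.create("results", showWarnings = FALSE)
write.csv(pairs, "results/pairs_3day.csv", row.names = FALSE, na = "")
cat(sprintf("state occupancy: %s\n",
            paste(table(state_obs$state), collapse = " / ")))
cat(sprintf(
  "%d in-window observations -> %d pairs, %d discarded (nonconsecutive), %d deaths absorbed\n",
  bk$n_obs_in_window, bk$n_pairs, bk$n_discarded, bk$n_absorbing))
stopifnot(bk$n_obs_in_window == bk$n_pairs + bk$n_run_heads + bk$n_discarded)
cat("wrote results/pairs_3day.csv\n")
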