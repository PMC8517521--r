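#!/usr/bin/env Rscript
# Stage 5: mean first passage times between illness states, in hours,
# overall and stratified by ventilation and age group.
#
# For destination j the expected steps solve m_ij = 1 + sum_{k!=j} p_ik
# m_kj; steps convert to hours at 0.5 h per 30-min step. Diagonal entries
# are 0 by convention (re-entry times are not calculated). Computed on the
# states-only chain.

library(illnesschain)

pairs <- read.csv("results/pairs_3day.csv", na.strings = "")
P <- row_normalize(count_transitions(pairs, n_states = 4))
M <- mean_first_passage(P, step_hours = 0.5)
cat("mean first passage times (hours):\n")
print(round(unclass(M), 1))
write.csv(data.frame(state = rownames(M), unclass(M), units = "hours",
                     check.names = FALSE),
          "results/mfpt_hours.csv", row.names = FALSE)

for (sc in c("ventilated", "age_group")) {
  strat <- stratified_mfpt(pairs, sc, n_states = 4)
  for (lv in names(strat)) {
    if (is.list(strat[[lv]])) {
      cat(sprintf("%s = %s: %s\n", sc, lv, strat[[lv]]$error))
      next
    }
    cat(sprintf("\n%s = %s:\n", sc, lv))
    print(round(unclass(strat[[lv]]), 1))
    write.csv(data.frame(state = rownames(strat[[lv]]),
                         unclass(strat[[lv]]), units = "hours",
                         check.names = FALSE),
              sprintf("results/mfpt_hours_%s_%s.csv", sc, lv),
              row.names = FALSE)
  }
}
cat("\nwrote results/mfpt_hours*.csv\n")
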