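#!/usr/bin/env Rscript
# Stage 4: simulate illness trajectories from the fitted chain.
#
# Three days of transitions (144 sequential 30-min steps) are simulated
# from initial illness states 3, 0 and 1, each on its own reproducible
# random sub-stream.

library(illnesschain)

pairs <- read.csv("results/pairs_3day.csv", na.strings = "")
P <- row_normalize(count_transitions(pairs, n_states = 4))
panel <- simulate_panel(P, initial_states = c(3, 0, 1), n_steps = 144,
                        seed = 11)
tab <- panel_to_table(panel)
write.csv(tab, "results/simulated_trajectories.csv", row.names = FALSE)

for (i in seq_along(panel)) {
  st <- panel[[i]]$states
  cat(sprintf("start %d: time in states 0/1/2/3 = %s of 145 steps\n",
              panel[[i]]$initial_state,
              paste(tabulate(st + 1L, 4), collapse = "/")))
}

png("results/simulated_trajectories.png", width = 900, height = 600)
op <- par(mfrow = c(3, 1), mar = c(4, 4, 2, 1))
for (i in seq_along(panel))
  plot(tab$t_minutes[tab$trajectory_id == i] / 60,
       tab$state[tab$trajectory_id == i], type = "s", ylim = c(0, 3),
       xlab = "hours since sepsis event", ylab = "illness state",
       main = sprintf("initial state %d", panel[[i]]$initial_state))
par(op)
invisible(dev.off())
cat("wrote results/simulated_trajectories.{csv,png}\n")
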