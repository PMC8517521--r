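#' Simulate one illness-state trajectory from a transition matrix
#'
#' Starting from `initial_state`, each 30-min step draws the next state from
#' the multinomial distribution in the current state's row. An absorbing
#' state (probability 1 of self-transition, e.g. death) holds to the horizon
#' with the absorption step recorded; entering a state whose row has no
#' observed support terminates the trajectory with a truncation flag.
#'
#' @param P a `transition_matrix` (or any row-stochastic matrix).
#' @param initial_state integer state label in `0 .. K-1` (or the death
#'   index for an absorbing matrix).
#' @param n_steps number of transitions to simulate (>= 1).
#' @param seed integer seed; the trajectory is deterministic given the seed.
#' @return list of class `simulated_trajectory`: `states` (length
#'   `n_steps + 1` unless truncated), `initial_state`, `seed`, `truncated`,
#'   and `absorbed_at` (step index of absorption, or `NA`).
#' @export
simulate_trajectory <- function(P, initial_state, n_steps, seed) {
  stopifnot(n_steps >= 1)
  K <- nrow(P)
  s <- as.integer(initial_state)
  if (s < 0 || s >= K)
    stop("initial_state out of range", call. = FALSE)
  row_ok <- rowSums(P) > 0
  if (!row_ok[s + 1L])
    stop(sprintf("initial state %d has an empty (unobserved) row", s),
         call. = FALSE)
  set.seed(as.integer(seed))
  states <- integer(n_steps + 1L)
  states[1L] <- s
  truncated <- FALSE
  absorbed_at <- NA_integer_
  for (k in seq_len(n_steps)) {
    if (P[s + 1L, s + 1L] == 1) {            # absorbing: hold to horizon
      absorbed_at <- k - 1L
      states[(k + 1L):(n_steps + 1L)] <- s
      break
    }
    if (!row_ok[s + 1L]) {                   # unobserved row: truncate
      truncated <- TRUE
      states <- states[seq_len(k)]
      break
    }
    s <- sample.int(K, 1L, prob = P[s + 1L, ]) - 1L
    states[k + 1L] <- s
  }
  structure(list(states = states,
                 initial_state = as.integer(initial_state),
                 seed = as.integer(seed),
                 truncated = truncated,
                 absorbed_at = absorbed_at),
            class = "simulated_trajectory")
}

#' Simulate a panel of trajectories from several starting states
#'
#' One trajectory per requested initial state (the cohort analysis uses
#' starts 3, 0 and 1 over 144 sequential 30-min transitions, i.e. 3 days).
#' Each trajectory consumes its own sub-stream derived deterministically
#' from `(seed, index)`, so the panel is reproducible as a whole and
#' per-trajectory.
#'
#' @param P transition matrix.
#' @param initial_states vector of starting states.
#' @param n_steps transitions per trajectory (default 144).
#' @param seed integer master seed.
#' @return list of `simulated_trajectory` objects.
#' @export
simulate_panel <- function(P, initial_states, n_steps = 144L, seed = 1L) {
  lapply(seq_along(initial_states), function(i)
    simulate_trajectory(P, initial_states[i], n_steps,
                        seed = sub_seed(seed, i)))
}

# deterministic sub-stream seed, kept inside 32-bit integer range
sub_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + index * 104729) %% 2147483647)
}

#' Flatten a trajectory panel to a tidy table
#'
#' @param panel list of `simulated_trajectory` objects.
#' @param step_minutes minutes per step (default 30).
#' @return data frame with `trajectory_id`, `step`, `t_minutes`, `state`.
#' @export
panel_to_table <- function(panel, step_minutes = 30L) {
  do.call(rbind, lapply(seq_along(panel), function(i) {
    st <- panel[[i]]$states
    data.frame(trajectory_id = i,
               step = seq_along(st) - 1L,
               t_minutes = (seq_along(st) - 1L) * step_minutes,
               state = st)
  }))
}
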