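# shared fixtures: small kernels, compact specs, and oracles

linf <- function(a, b) max(abs(unclass(a) - unclass(b)))

k_identity <- diag(4)

# strongly diagonal 4-state kernel (typical illness persistence)
k_strong <- matrix(c(
  0.85, 0.13, 0.015, 0.005,
  0.09, 0.80, 0.09,  0.02,
  0.01, 0.12, 0.77,  0.10,
  0.005, 0.015, 0.12, 0.86), 4, 4, byrow = TRUE)

# weakly diagonal counterpart used for monotonicity checks
k_weak <- matrix(c(
  0.40, 0.30, 0.20, 0.10,
  0.25, 0.35, 0.25, 0.15,
  0.15, 0.25, 0.35, 0.25,
  0.10, 0.20, 0.30, 0.40), 4, 4, byrow = TRUE)

small_spec <- function(kernel = k_strong, ...) {
  chain_spec(n_states = 4L, kernel = kernel,
             initial_distribution = c(0.25, 0.25, 0.25, 0.25), ...)
}

# random strictly positive (hence irreducible) kernel with a boosted diagonal
random_kernel <- function(K = 4, diag_weight = 0.4) {
  raw <- matrix(stats::runif(K * K, 0.1, 1), K, K)
  P <- raw / rowSums(raw)
  (1 - diag_weight) * P + diag_weight * diag(K)
}

# stationary distribution via the leading left eigenvector
stationary_dist <- function(P) {
  e <- eigen(t(unclass(P)))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

# Monte-Carlo mean hitting time oracle: simulates n independent chains from
# `from` until each first reaches `to`, vectorized over chains
mc_hitting_mean <- function(P, from, to, n, seed, max_steps = 50000L) {
  set.seed(seed)
  K <- nrow(P)
  cur <- rep.int(from + 1L, n)
  steps <- integer(n)
  alive <- rep(TRUE, n)
  t <- 0L
  while (any(alive) && t < max_steps) {
    t <- t + 1L
    idx <- which(alive)
    cs <- cur[idx]
    for (s in unique(cs)) {
      ii <- idx[cs == s]
      cur[ii] <- sample.int(K, length(ii), replace = TRUE, prob = P[s, ])
    }
    hit <- alive & cur == to + 1L
    steps[hit] <- t
    alive[hit] <- FALSE
  }
  stopifnot(!any(alive))
  mean(steps)
}

# turn one simulated trajectory into a transition-pair table
trajectory_to_pairs <- function(traj, step_minutes = 30L) {
  st <- traj$states
  n <- length(st)
  data.frame(admission_id = "sim",
             t_from = (seq_len(n - 1L) - 1L) * step_minutes,
             state_from = st[-n],
             state_to = st[-1L],
             absorbing = FALSE)
}

expect_row_stochastic <- function(P) {
  sup <- attr(P, "row_support")
  sums <- rowSums(unclass(P))
  expect_true(all(abs(sums[sup > 0] - 1) < 1e-9))
}
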