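pairs_from_sequence <- function(states, step = 30L) {
  n <- length(states)
  data.frame(admission_id = "a",
             t_from = (seq_len(n - 1L) - 1L) * step,
             state_from = states[-n], state_to = states[-1L],
             absorbing = FALSE)
}

test_that("transition counting tabulates adjacent pairs cell by cell", {
  p <- pairs_from_sequence(c(0, 1, 0, 1, 0))
  cnt <- count_transitions(p, n_states = 2)
  expect_equal(unclass(cnt), matrix(c(0L, 2L, 2L, 0L), 2, 2,
               dimnames = list(from = c("0", "1"), to = c("0", "1"))),
               ignore_attr = TRUE)
  expect_equal(attr(cnt, "total"), 4L)
})

test_that("death-terminal rows count into the absorbing column", {
  p <- rbind(pairs_from_sequence(c(2, 2), step = 30L),
             data.frame(admission_id = "a", t_from = 30L, state_from = 2L,
                        state_to = NA_integer_, absorbing = TRUE))
  cnt <- count_transitions(p, n_states = 4, include_death = TRUE)
  expect_equal(cnt["2", "2"], 1L)
  expect_equal(cnt["2", "death"], 1L)
  expect_equal(sum(cnt["death", ]), 0L)
  # excluded entirely from the states-only matrix
  cnt2 <- count_transitions(p, n_states = 4, include_death = FALSE)
  expect_equal(attr(cnt2, "total"), 1L)
  # the normalized absorbing matrix fixes the death row to identity
  P <- row_normalize(cnt)
  expect_equal(P["death", "death"], 1)
  expect_equal(sum(P["death", ]), 1)
})

test_that("row normalization divides by row sums and flags empty rows", {
  cnt <- structure(matrix(c(3L, 0L, 1L, 0L), 2, 2,
                          dimnames = list(from = c("0", "1"),
                                          to = c("0", "1"))),
                   class = c("transition_counts", "matrix", "array"))
  P <- row_normalize(cnt)
  expect_equal(unclass(P)[1, ], c("0" = 0.75, "1" = 0.25))
  expect_equal(unclass(P)[2, ], c("0" = 0, "1" = 0))
  expect_equal(attr(P, "row_support"), c(4, 0))
  sym <- count_transitions(pairs_from_sequence(c(0, 0, 1, 0, 1, 1, 0, 1, 1, 0)),
                           n_states = 2)
  # symmetric counts normalize to uniform rows
  sym[,] <- 2L
  expect_equal(unclass(row_normalize(sym)),
               matrix(0.5, 2, 2, dimnames = dimnames(sym)),
               ignore_attr = TRUE)
})

test_that("entropy matrix normalizes cells jointly and hits analytic values", {
  uni <- structure(matrix(3L, 4, 4), class = c("transition_counts", "matrix"))
  em <- make_entropy_matrix(uni)
  expect_equal(sum(em), 1)
  expect_equal(attr(em, "entropy_nats"), log(16))
  point <- matrix(0L, 4, 4); point[2, 2] <- 50L
  expect_equal(attr(make_entropy_matrix(point), "entropy_nats"), 0)
  two <- matrix(c(2L, 0L, 0L, 2L), 2, 2)
  em2 <- make_entropy_matrix(two)
  expect_equal(unclass(em2), matrix(c(0.5, 0, 0, 0.5), 2, 2),
               ignore_attr = TRUE)
  expect_equal(attr(em2, "entropy_nats"), log(2))
  expect_error(make_entropy_matrix(matrix(0L, 2, 2)), "no observed")
})

test_that("entropy stays within its analytic bounds on random counts", {
  set.seed(4)
  for (i in 1:25) {
    K <- sample(2:6, 1)
    cnt <- matrix(rpois(K * K, lambda = sample(c(0.5, 2, 10), 1)), K, K)
    if (sum(cnt) == 0) cnt[1, 1] <- 1
    em <- make_entropy_matrix(cnt)
    H <- attr(em, "entropy_nats")
    expect_gte(H, 0)
    expect_lte(H, log(K^2) + 1e-12)
    expect_equal(sum(em), 1)
  }
})

test_that("joint-distribution entropy obeys the chain rule", {
  # H(joint) = H(pi) + sum_i pi_i H(P[i, ]) when joint_ij = pi_i p_ij
  set.seed(11)
  for (i in 1:10) {
    P <- random_kernel(4)
    pi <- stationary_dist(P)
    joint <- pi * P                     # row i scaled by pi_i
    lhs <- shannon_entropy(joint)
    rhs <- shannon_entropy(pi) + sum(pi * apply(P, 1, shannon_entropy))
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("counts are additive across strata", {
  spec <- default_chain_spec()
  coh <- generate_cohort(spec, 60, seed = 13)
  tab <- as_cohort_tables(coh)
  so <- assign_states(tab$observations, binning_scheme("equal_width", 4))
  p <- make_transition_pairs(so, tab$covariates)
  whole <- count_transitions(p, 4)
  by_strat <- lapply(split(p, p$ventilated), count_transitions, n_states = 4)
  expect_equal(unclass(Reduce(`+`, by_strat)), unclass(whole),
               ignore_attr = TRUE)
})

test_that("stratified estimation partitions correctly and recovers kernels", {
  spec <- default_chain_spec()
  spec$gap_probability <- 0
  spec$death_hazard <- rep(0, 4)
  coh <- generate_cohort(spec, 500, seed = 17)
  tab <- as_cohort_tables(coh)
  so <- assign_states(tab$observations, binning_scheme("equal_width", 4))
  p <- make_transition_pairs(so, tab$covariates)
  est <- estimate_stratified(p, "ventilated", 4)
  expect_setequal(names(est), c("TRUE", "FALSE"))
  expect_lt(linf(est[["TRUE"]]$matrix, spec$kernel), 0.05)
  expect_lt(linf(est[["FALSE"]]$matrix, spec$kernel_overrides$non_ventilated),
            0.05)
  for (e in est) expect_row_stochastic(e$matrix)
  # one homogeneous stratum reproduces the unstratified estimate
  p1 <- p; p1$ventilated <- TRUE
  est1 <- estimate_stratified(p1, "ventilated", 4)
  expect_equal(unclass(est1[["TRUE"]]$matrix),
               unclass(row_normalize(count_transitions(p1, 4))))
  expect_error(estimate_stratified(p, "no_such_column"), "unknown")
})

test_that("estimates converge to the generating kernel with more pairs", {
  err_at <- function(n, seed) {
    coh <- generate_cohort(small_spec(), n, seed = seed)
    tab <- as_cohort_tables(coh)
    so <- assign_states(tab$observations, binning_scheme("equal_width", 4))
    p <- make_transition_pairs(so, tab$covariates)
    linf(row_normalize(count_transitions(p, 4)), k_strong)
  }
  expect_lt(err_at(700, 31), err_at(50, 31))
  for (seed in 31:33) expect_lt(err_at(700, seed), 0.02)  # ~1e5 pairs each
})
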