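test_that("degenerate kernels produce the trajectories they force", {
  # identity kernel, all mass on state 0: every score stays in the bottom bin
  spec <- chain_spec(n_states = 4L, kernel = diag(4),
                     initial_distribution = c(1, 0, 0, 0),
                     step_minutes = 30L, horizon_minutes = 150L)
  coh <- generate_cohort(spec, 20, seed = 42)
  for (r in coh) {
    expect_equal(nrow(r$observations), 6L)   # 5 steps + initial
    expect_true(all(r$observations$score >= 0 & r$observations$score < 1))
  }
  # certain death at the first step truncates every series at the initial obs
  spec2 <- small_spec(death_hazard = rep(1, 4))
  coh2 <- generate_cohort(spec2, 15, seed = 1)
  for (r in coh2) {
    expect_true(r$died)
    expect_equal(nrow(r$observations), 1L)
    expect_equal(r$death_time_minutes, 30L)
  }
})

test_that("gap-free deathless cohorts have a full observation grid", {
  spec <- small_spec()
  coh <- generate_cohort(spec, 10, seed = 3)
  n_expected <- spec$horizon_minutes / spec$step_minutes + 1
  expect_true(all(vapply(coh, function(r) nrow(r$observations), 0) == n_expected))
  for (r in coh) {
    expect_true(all(diff(r$observations$t_minutes) > 0))
    expect_true(all(r$observations$t_minutes %% spec$step_minutes == 0))
    expect_true(all(r$observations$score >= 0))
  }
})

test_that("empirical per-step death fraction matches the configured hazard", {
  h <- 0.002
  spec <- small_spec(death_hazard = rep(h, 4))
  coh <- generate_cohort(spec, 400, seed = 7)
  # every fully observed step is one Bernoulli(h) trial for death
  n_steps <- vapply(coh, function(r) {
    if (r$died) nrow(r$observations) else nrow(r$observations) - 1L
  }, 0L)
  n_deaths <- sum(vapply(coh, function(r) r$died, TRUE))
  p_hat <- n_deaths / sum(n_steps)
  se <- sqrt(h * (1 - h) / sum(n_steps))
  expect_lt(abs(p_hat - h), 3 * se)
})

test_that("generation is deterministic in the seed", {
  spec <- default_chain_spec()
  a <- generate_cohort(spec, 25, seed = 11)
  b <- generate_cohort(spec, 25, seed = 11)
  c <- generate_cohort(spec, 25, seed = 12)
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("invalid generative parameters are rejected with the offending row", {
  bad <- k_strong
  bad[2, ] <- bad[2, ] * 1.5
  expect_error(small_spec(kernel = bad), "row 2")
  expect_error(small_spec(death_hazard = c(0, 0, 0, 1.2)), "death_hazard")
  expect_error(chain_spec(kernel = k_strong,
                          initial_distribution = c(0.5, 0.5, 0.5, -0.5)),
               "simplex")
  expect_error(small_spec(horizon_minutes = 100L), "divisible")
})

test_that("cohorts round-trip losslessly through CSV", {
  spec <- small_spec(death_hazard = c(0.001, 0.002, 0.005, 0.01),
                     gap_probability = 0.01)
  coh <- generate_cohort(spec, 30, seed = 5)
  dir <- withr::local_tempdir()
  paths <- write_cohort(coh, dir)
  expect_true(all(file.exists(paths)))
  back <- read_cohort(paths["obs"], paths["cov"])
  expect_equal(length(back), length(coh))
  for (i in seq_along(coh)) {
    expect_equal(back[[i]]$observations, coh[[i]]$observations)
    expect_identical(back[[i]]$died, coh[[i]]$died)
    expect_identical(back[[i]]$ventilated, coh[[i]]$ventilated)
    expect_equal(back[[i]]$death_time_minutes, coh[[i]]$death_time_minutes)
  }
  # observation file rows = sum of per-admission series lengths
  obs <- utils::read.csv(paths["obs"])
  expect_equal(nrow(obs), sum(vapply(coh, function(r) nrow(r$observations), 0)))
  # a death's covariate row carries its time
  cov <- utils::read.csv(paths["cov"], na.strings = "")
  died_ids <- cov$admission_id[cov$died]
  expect_true(all(!is.na(cov$death_time_minutes[cov$died])))
  expect_true(all(is.na(cov$death_time_minutes[!cov$died])))
})

test_that("stratum labels follow the configured proportions", {
  spec <- default_chain_spec()
  coh <- generate_cohort(spec, 1000, seed = 9)
  tab <- as_cohort_tables(coh)
  p_vent <- mean(tab$covariates$ventilated)
  p_age <- mean(tab$covariates$age_group == "0-1")
  expect_lt(abs(p_vent - spec$p_ventilated), 3 * sqrt(0.25 / 1000))
  expect_lt(abs(p_age - spec$p_age_0_1), 3 * sqrt(0.25 / 1000))
})

test_that("a YAML spec file reproduces the constructor", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_states: 2",
    "kernel:",
    "  - [0.9, 0.1]",
    "  - [0.2, 0.8]",
    "initial_distribution: [0.5, 0.5]",
    "score_edges: [0, 1]",
    "score_max: 8",
    "gap_probability: 0.01",
    "horizon_minutes: 600"), path)
  spec <- read_chain_spec(path)
  expect_s3_class(spec, "chain_spec")
  expect_equal(spec$kernel, matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE))
  expect_equal(spec$horizon_minutes, 600L)
  ex <- read_chain_spec(system.file("extdata", "example_chain_spec.yaml",
                                    package = "illnesschain"))
  expect_s3_class(ex, "chain_spec")
  expect_equal(ex$n_states, 4L)
})
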