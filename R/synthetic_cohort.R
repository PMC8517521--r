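#' Generate a synthetic cohort of risk-score time series
#'
#' Each admission draws stratum labels (ventilation, age group), samples an
#' initial illness state at t = 0 from the spec's initial distribution, and
#' evolves on the 30-min grid under its stratum's transition kernel. At each
#' step the admission may instead transition to death with the current
#' state's per-step hazard; a death replaces the next observation (no score
#' is emitted at or after death) and its time is recorded. Every visited
#' state emits a continuous risk score drawn uniformly within that state's
#' score bin, so that equal-width binning recovers the latent states exactly.
#' Finally each observation is independently dropped with the spec's gap
#' probability, creating nonconsecutive score pairs.
#'
#' @param spec a [chain_spec()].
#' @param n_admissions number of admissions to simulate (>= 1).
#' @param seed integer seed; output is deterministic given the seed.
#' @return a list of admission records (class `illness_cohort`). Each record
#'   has `admission_id`, `age_group` (`"0-1"` or `"over-1"`), `ventilated`,
#'   `died`, `death_time_minutes` (`NA` unless died), and `observations`, a
#'   data frame of strictly increasing `t_minutes` and nonnegative `score`.
#' @export
generate_cohort <- function(spec, n_admissions, seed) {
  validate_chain_spec(spec)
  stopifnot(n_admissions >= 1)
  set.seed(as.integer(seed))
  K <- spec$n_states
  times <- seq(0L, spec$horizon_minutes, by = spec$step_minutes)
  n_steps <- length(times) - 1L
  cohort <- vector("list", n_admissions)
  for (a in seq_len(n_admissions)) {
    ventilated <- stats::runif(1) < spec$p_ventilated
    age_group <- if (stats::runif(1) < spec$p_age_0_1) "0-1" else "over-1"
    kern <- admission_kernel(spec, ventilated, age_group)
    states <- integer(0)
    states[1] <- sample.int(K, 1, prob = spec$initial_distribution) - 1L
    died <- FALSE
    death_time <- NA_integer_
    for (k in seq_len(n_steps)) {
      s <- states[k]
      if (stats::runif(1) < spec$death_hazard[s + 1L]) {
        died <- TRUE
        death_time <- times[k + 1L]
        break
      }
      P <- if (!is.null(spec$switch_minutes) && times[k] >= spec$switch_minutes)
        spec$post_switch_kernel else kern
      states[k + 1L] <- sample.int(K, 1, prob = P[s + 1L, ]) - 1L
    }
    n_obs <- length(states)
    scores <- score_within_bin(states, spec)
    keep <- stats::runif(n_obs) >= spec$gap_probability
    cohort[[a]] <- structure(
      list(admission_id = sprintf("adm%04d", a),
           age_group = age_group,
           ventilated = ventilated,
           died = died,
           death_time_minutes = death_time,
           observations = data.frame(t_minutes = times[seq_len(n_obs)][keep],
                                     score = scores[keep])),
      class = "admission_record")
  }
  structure(cohort, class = "illness_cohort", spec = spec)
}

# Kernel governing one admission: a ventilation override takes precedence
# over an age override; otherwise the spec's default kernel.
admission_kernel <- function(spec, ventilated, age_group) {
  ov <- spec$kernel_overrides
  key_vent <- if (ventilated) "ventilated" else "non_ventilated"
  key_age <- if (age_group == "0-1") "age_0_1" else "age_over_1"
  if (!is.null(ov[[key_vent]])) return(ov[[key_vent]])
  if (!is.null(ov[[key_age]])) return(ov[[key_age]])
  spec$kernel
}

# Uniform draw within the state's score bin; top bin spans
# [max(score_edges), score_max].
score_within_bin <- function(states, spec) {
  lo <- spec$score_edges[states + 1L]
  hi <- c(spec$score_edges[-1L], spec$score_max)[states + 1L]
  stats::runif(length(states), lo, hi)
}

#' Flatten a cohort into observation and covariate tables
#'
#' @param cohort an `illness_cohort`.
#' @return a list with `observations` (admission_id, t_minutes, score) and
#'   `covariates` (admission_id, age_group, ventilated, died,
#'   death_time_minutes) data frames.
#' @export
as_cohort_tables <- function(cohort) {
  obs <- do.call(rbind, lapply(cohort, function(r)
    data.frame(admission_id = r$admission_id, r$observations)))
  cov <- do.call(rbind, lapply(cohort, function(r)
    data.frame(admission_id = r$admission_id,
               age_group = r$age_group,
               ventilated = r$ventilated,
               died = r$died,
               death_time_minutes = r$death_time_minutes)))
  rownames(obs) <- rownames(cov) <- NULL
  list(observations = obs, covariates = cov)
}

#' Write a cohort as observation and covariate CSV files
#'
#' Scores are formatted with 17 significant digits so that reading the files
#' back reproduces the cohort exactly. Missing death times are written blank.
#'
#' @param cohort an `illness_cohort`.
#' @param dir output directory (created if absent).
#' @return invisibly, the two file paths (`obs`, `cov`).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(length(cohort) >= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- as_cohort_tables(cohort)
  tab$observations$score <- formatC(tab$observations$score, digits = 17,
                                    format = "g")
  paths <- c(obs = file.path(dir, "observations.csv"),
             cov = file.path(dir, "covariates.csv"))
  utils::write.csv(tab$observations, paths["obs"], row.names = FALSE,
                   quote = FALSE, na = "")
  utils::write.csv(tab$covariates, paths["cov"], row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(paths)
}

#' Read a cohort from observation and covariate CSV files
#'
#' Accepts the schema written by [write_cohort()] (and the same schema for
#' real exported data): observations with columns admission_id, t_minutes,
#' score; covariates with admission_id, age_group, ventilated, died,
#' death_time_minutes (blank when absent). Assumes one sepsis event per
#' admission at t = 0.
#'
#' @param obs_csv,cov_csv file paths.
#' @return an `illness_cohort` (without a generating spec attached).
#' @export
read_cohort <- function(obs_csv, cov_csv) {
  obs <- utils::read.csv(obs_csv)
  cov <- utils::read.csv(cov_csv, na.strings = "")
  cov$ventilated <- as.logical(cov$ventilated)
  cov$died <- as.logical(cov$died)
  cohort <- lapply(seq_len(nrow(cov)), function(i) {
    id <- cov$admission_id[i]
    o <- obs[obs$admission_id == id, c("t_minutes", "score")]
    o <- o[order(o$t_minutes), ]
    rownames(o) <- NULL
    structure(
      list(admission_id = id,
           age_group = cov$age_group[i],
           ventilated = cov$ventilated[i],
           died = cov$died[i],
           death_time_minutes = if (is.na(cov$death_time_minutes[i]))
             NA_integer_ else as.integer(cov$death_time_minutes[i]),
           observations = o),
      class = "admission_record")
  })
  structure(cohort, class = "illness_cohort")
}
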