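#' Binning scheme mapping risk scores to illness states
#'
#' Illness states partition the nonnegative score line into half-open
#' intervals `[edge_i, edge_{i+1})`, the top interval closed above at +Inf,
#' so every score belongs to exactly one state. `equal_width` uses unit-width
#' bins with edges `0, 1, ..., n_states - 1` (the four-state default puts
#' state 0 at scores below 1 and state 3 at all scores of 3 or higher);
#' `equal_count` derives edges from score quantiles via
#' [fit_equal_count_edges()].
#'
#' @param mode `"equal_width"` or `"equal_count"`.
#' @param n_states number of states (4, 5 or 6).
#' @param edges explicit edges (required for `equal_count` unless fitted).
#' @return object of class `binning_scheme`.
#' @export
binning_scheme <- function(mode = c("equal_width", "equal_count"),
                           n_states = 4L, edges = NULL) {
  mode <- match.arg(mode)
  n_states <- as.integer(n_states)
  if (!n_states %in% c(4L, 5L, 6L))
    stop("n_states must be 4, 5 or 6", call. = FALSE)
  if (mode == "equal_width" && is.null(edges))
    edges <- as.numeric(seq_len(n_states) - 1)
  if (is.null(edges))
    stop("equal_count mode needs edges; use fit_equal_count_edges()",
         call. = FALSE)
  if (length(edges) != n_states || is.unsorted(edges, strictly = TRUE))
    stop("edges must be strictly increasing, one per state", call. = FALSE)
  if (edges[1] != 0)
    stop("first edge must be 0", call. = FALSE)
  structure(list(mode = mode, n_states = n_states, edges = edges),
            class = "binning_scheme")
}

#' Fit equal-count bin edges from pooled scores
#'
#' Places interior edges at the `1/n_states, ..., (n_states-1)/n_states`
#' quantiles of the pooled score distribution, so each state receives (up to
#' ties at an edge) an equal share of the observations.
#'
#' @param scores pooled nonnegative scores.
#' @param n_states number of states.
#' @return a `binning_scheme` with mode `"equal_count"`.
#' @export
fit_equal_count_edges <- function(scores, n_states = 4L) {
  scores <- scores[!is.na(scores)]
  if (length(unique(scores)) < n_states)
    stop("need at least n_states distinct scores to place quantile edges",
         call. = FALSE)
  qs <- stats::quantile(scores, probs = seq_len(n_states - 1) / n_states,
                        names = FALSE, type = 7)
  edges <- c(0, qs)
  if (is.unsorted(edges, strictly = TRUE) == TRUE || anyDuplicated(edges))
    stop("quantile edges are not distinct; scores too concentrated",
         call. = FALSE)
  binning_scheme("equal_count", n_states, edges)
}

#' Subsample a score series to a coarser regular grid
#'
#' Retains observations whose times are congruent to 0 modulo `step_minutes`,
#' anchored at the sepsis event (t = 0). Used to thin 15-min model output to
#' the 30-min analysis grid.
#'
#' @param series data frame with a `t_minutes` column.
#' @param step_minutes target interval (default 30).
#' @return the subsetted series (possibly empty).
#' @export
subsample_to_step <- function(series, step_minutes = 30L) {
  out <- series[series$t_minutes %% step_minutes == 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign illness states to scores
#'
#' Each score maps to the index of the half-open interval containing it;
#' scores at a bin edge land in the upper bin, and all scores at or above the
#' top edge land in the top state.
#'
#' @param series data frame with a `score` column (and typically
#'   `admission_id`, `t_minutes`).
#' @param scheme a [binning_scheme()].
#' @return the series with an integer `state` column in `0 .. n_states - 1`.
#' @export
assign_states <- function(series, scheme) {
  if (any(series$score < 0, na.rm = TRUE))
    stop("negative risk scores are invalid", call. = FALSE)
  series$state <- findInterval(series$score, scheme$edges) - 1L
  series
}

#' Extract adjacent 30-min transition pairs
#'
#' Walks each admission's state sequence and emits one row per adjacent pair
#' of observations whose time gap is exactly `step_minutes`, with the
#' destination time inside the analysis window `(0, window_minutes]` (the
#' t = 0 observation participates only as a pair's origin). Observations that
#' form no exact-gap pair (isolated by gaps on both sides) are counted as
#' discarded, mirroring the removal of nonconsecutive scores. If the
#' admission died within the window, one terminal absorbing row (last
#' observed state to death, `state_to = NA`) is appended after the last
#' in-window observation preceding death, regardless of any gap before the
#' death time.
#'
#' @param state_obs data frame of binned observations: `admission_id`,
#'   `t_minutes`, `state`.
#' @param covariates covariate table as from [as_cohort_tables()]; stratum
#'   columns (`age_group`, `ventilated`) are joined onto the pairs.
#' @param step_minutes grid interval.
#' @param window_minutes analysis window length (default 4320 = 72 h).
#' @return a data frame of pairs (`admission_id`, `t_from`, `state_from`,
#'   `state_to`, `absorbing`, stratum columns) with a `bookkeeping` attribute:
#'   `n_obs_in_window`, `n_pairs` (non-absorbing), `n_absorbing`,
#'   `n_discarded`, and `n_run_heads` (first observations of consecutive
#'   runs, which begin a pair but are no pair's destination). These satisfy
#'   `n_obs_in_window = n_pairs + n_run_heads + n_discarded`.
#' @export
make_transition_pairs <- function(state_obs, covariates,
                                  step_minutes = 30L,
                                  window_minutes = 4320L) {
  stopifnot(all(c("admission_id", "t_minutes", "state") %in% names(state_obs)))
  keep <- state_obs$t_minutes >= 0 & state_obs$t_minutes <= window_minutes
  obs <- state_obs[keep, ]
  obs <- obs[order(obs$admission_id, obs$t_minutes), ]
  by_adm <- split(obs, obs$admission_id, drop = TRUE)
  n_pairs <- n_disc <- n_heads <- n_abs <- 0L
  rows <- vector("list", length(by_adm))
  for (i in seq_along(by_adm)) {
    o <- by_adm[[i]]
    id <- o$admission_id[1]
    n <- nrow(o)
    # run structure on the exact-gap grid: a new run starts wherever the
    # gap to the previous observation is not exactly one step
    new_run <- c(TRUE, diff(o$t_minutes) != step_minutes)
    run_id <- cumsum(new_run)
    run_len <- tabulate(run_id)
    n_disc <- n_disc + sum(run_len == 1L)
    n_heads <- n_heads + sum(run_len > 1L)
    pair_from <- which(!new_run) - 1L      # origin indices of exact-gap pairs
    adm_pairs <- if (length(pair_from))
      data.frame(admission_id = id,
                 t_from = o$t_minutes[pair_from],
                 state_from = o$state[pair_from],
                 state_to = o$state[pair_from + 1L],
                 absorbing = FALSE)
    else NULL
    n_pairs <- n_pairs + length(pair_from)
    cv <- covariates[covariates$admission_id == id, ]
    if (nrow(cv) == 1 && isTRUE(cv$died) &&
        !is.na(cv$death_time_minutes) &&
        cv$death_time_minutes <= window_minutes) {
      before <- which(o$t_minutes < cv$death_time_minutes)
      if (length(before)) {
        last <- max(before)
        adm_pairs <- rbind(adm_pairs,
                           data.frame(admission_id = id,
                                      t_from = o$t_minutes[last],
                                      state_from = o$state[last],
                                      state_to = NA_integer_,
                                      absorbing = TRUE))
        n_abs <- n_abs + 1L
      }
    }
    rows[[i]] <- adm_pairs
  }
  pairs <- do.call(rbind, rows)
  if (is.null(pairs))
    pairs <- data.frame(admission_id = character(), t_from = integer(),
                        state_from = integer(), state_to = integer(),
                        absorbing = logical())
  strat <- covariates[, intersect(c("admission_id", "age_group", "ventilated"),
                                  names(covariates)), drop = FALSE]
  pairs <- merge(pairs, strat, by = "admission_id", sort = FALSE)
  pairs <- pairs[order(pairs$admission_id, pairs$t_from, pairs$absorbing), ]
  rownames(pairs) <- NULL
  attr(pairs, "bookkeeping") <- list(n_obs_in_window = nrow(obs),
                                     n_pairs = n_pairs,
                                     n_absorbing = n_abs,
                                     n_discarded = n_disc,
                                     n_run_heads = n_heads)
  pairs
}
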