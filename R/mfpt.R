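#' Mean first passage times between illness states
#'
#' For each destination state j, the expected number of steps for the chain
#' started in state i to first reach j satisfies the linear system
#' `m_ij = 1 + sum_{k != j} p_ik m_kj`, solved here as
#' `(I - P[-j, -j]) m = 1`. Steps convert to hours at `step_hours` per step
#' (30-min grid: 0.5 h). Diagonal entries are fixed to 0 by convention: the
#' time to re-enter the same state is not calculated. Computed on the
#' states-only (non-absorbing) chain; the chain must be irreducible, which
#' is checked by reachability on the positive-probability digraph before
#' solving so that a reducible input fails with a diagnosis instead of a
#' singular system.
#'
#' @param P states-only `transition_matrix` with no empty rows.
#' @param step_hours hours per step (default 0.5).
#' @return matrix of class `mfpt_matrix`, entries in hours, diagonal 0.
#' @export
mean_first_passage <- function(P, step_hours = 0.5) {
  K <- nrow(P)
  support <- rowSums(P)
  if (any(support == 0))
    stop("empty transition rows for states: ",
         paste(which(support == 0) - 1L, collapse = ", "), call. = FALSE)
  unreach <- unreachable_pairs(P)
  if (nrow(unreach))
    stop("chain is reducible; unreachable (source -> destination) pairs: ",
         paste(sprintf("%d->%d", unreach$from, unreach$to), collapse = ", "),
         call. = FALSE)
  M <- matrix(0, K, K, dimnames = dimnames(P))
  for (j in seq_len(K)) {
    Q <- P[-j, -j, drop = FALSE]
    m <- solve(diag(K - 1L) - Q, rep(1, K - 1L))
    M[-j, j] <- m * step_hours
  }
  structure(M, class = c("mfpt_matrix", class(M)), step_hours = step_hours)
}

# Pairs (i, j), i != j, with no directed path of positive-probability
# transitions from i to j. Transitive closure by boolean matrix powers.
unreachable_pairs <- function(P) {
  K <- nrow(P)
  A <- P > 0
  R <- A | diag(TRUE, K)
  for (step in seq_len(K)) R <- R | (R %*% R) > 0
  idx <- which(!R & !diag(TRUE, K), arr.ind = TRUE)
  data.frame(from = idx[, 1] - 1L, to = idx[, 2] - 1L)
}

#' Mean first passage times per stratum
#'
#' Estimates a states-only transition matrix within each stratum and
#' computes its MFPT matrix. A stratum whose estimated chain is reducible
#' (or has empty rows) is reported as an error entry without aborting the
#' other strata.
#'
#' @param pairs transition-pair table with the stratum column joined.
#' @param stratum_column admission-level covariate to stratify on.
#' @param n_states number of transient states.
#' @param step_hours hours per step.
#' @return named list per stratum: either an `mfpt_matrix` or a list with an
#'   `error` message.
#' @export
stratified_mfpt <- function(pairs, stratum_column, n_states = 4L,
                            step_hours = 0.5) {
  est <- estimate_stratified(pairs, stratum_column, n_states)
  lapply(est, function(e)
    tryCatch(mean_first_passage(e$matrix, step_hours),
             error = function(err) list(error = conditionMessage(err))))
}
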