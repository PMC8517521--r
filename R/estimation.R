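#' Count illness-state transitions
#'
#' Tabulates the transition-pair table into a square count matrix. With
#' `include_death = TRUE` the matrix gains a final row and column labelled
#' `"death"`; terminal absorbing rows contribute to the death column (the
#' death row itself is never observed). With `include_death = FALSE`
#' absorbing rows are excluded.
#'
#' @param pairs a transition-pair table from [make_transition_pairs()].
#' @param n_states number of transient states.
#' @param include_death append death as an absorbing state?
#' @return integer matrix of class `transition_counts` with state labels as
#'   dimnames and attribute `total` (sum of all cells).
#' @export
count_transitions <- function(pairs, n_states = 4L, include_death = FALSE) {
  labels <- as.character(seq_len(n_states) - 1L)
  if (include_death) {
    labels <- c(labels, "death")
    to <- pairs$state_to
    to[pairs$absorbing] <- n_states          # death index
    counts <- table(from = factor(pairs$state_from, levels = 0:(n_states - 1)),
                    to = factor(to, levels = 0:n_states))
    counts <- rbind(unclass(counts), death = 0L)
  } else {
    p <- pairs[!pairs$absorbing, ]
    counts <- table(from = factor(p$state_from, levels = 0:(n_states - 1)),
                    to = factor(p$state_to, levels = 0:(n_states - 1)))
    counts <- unclass(counts)
  }
  counts <- matrix(as.integer(counts), nrow(counts), ncol(counts),
                   dimnames = list(from = labels, to = labels))
  structure(counts, class = c("transition_counts", class(counts)),
            total = sum(counts))
}

#' Row-normalize transition counts into a stochastic matrix
#'
#' Divides each row by its sum. Rows with no observed transitions are left
#' all-zero and flagged via the `row_support` attribute rather than imputed.
#' When death is included, its (unobservable) row is fixed to the absorbing
#' convention: probability 1 of remaining dead.
#'
#' @param counts a `transition_counts` matrix.
#' @return matrix of class `transition_matrix` with attributes `row_support`
#'   (observed transitions per row) and `states` (labels).
#' @export
row_normalize <- function(counts) {
  support <- rowSums(counts)
  P <- counts / ifelse(support > 0, support, 1)
  P[support == 0, ] <- 0
  labels <- rownames(counts)
  if (!is.null(labels) && labels[length(labels)] == "death") {
    P["death", ] <- 0
    P["death", "death"] <- 1
  }
  P <- matrix(as.numeric(P), nrow(P), ncol(P), dimnames = dimnames(counts))
  structure(P, class = c("transition_matrix", class(P)),
            row_support = as.numeric(support), states = labels)
}

#' Shannon entropy of a probability distribution, in nats
#'
#' `H = -sum(p * log(p))` with the continuous-extension convention
#' `0 * log(0) = 0`; natural logarithms throughout.
#'
#' @param p probabilities (any shape); must be nonnegative and sum to 1.
#' @return entropy in nats.
#' @export
shannon_entropy <- function(p) {
  p <- as.numeric(p)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("p must be a probability distribution", call. = FALSE)
  nz <- p[p > 0]
  max(-sum(nz * log(nz)), 0)   # guards the -0 of a point mass
}

#' Build the entropy matrix of joint transition frequencies
#'
#' Divides every cell of the count matrix by the total number of observed
#' transitions, so all cells sum to one; the Shannon entropy of this joint
#' distribution (in nats) measures how dispersed transition activity is
#' across the cells. A point mass gives 0; a uniform 16-cell matrix gives
#' ln(16), about 2.77.
#'
#' @param counts a `transition_counts` matrix with positive total.
#' @return matrix of class `entropy_matrix` with attribute `entropy_nats`.
#' @export
make_entropy_matrix <- function(counts) {
  total <- sum(counts)
  if (total <= 0)
    stop("no observed transitions: cannot normalize", call. = FALSE)
  E <- matrix(as.numeric(counts) / total, nrow(counts), ncol(counts),
              dimnames = dimnames(counts))
  structure(E, class = c("entropy_matrix", class(E)),
            entropy_nats = shannon_entropy(E), total = total)
}

#' Estimate transition structure within each stratum
#'
#' Partitions the pair table by an admission-level covariate and estimates,
#' independently per stratum, the states-only transition matrix, the
#' absorbing (death-appended) matrix, and the entropy matrix. Entropy is
#' computed on the states-only joint distribution, the scale on which
#' stratum entropies are compared.
#'
#' @param pairs transition-pair table with the stratum column joined.
#' @param stratum_column name of the column to stratify on
#'   (e.g. `"ventilated"`, `"age_group"`).
#' @param n_states number of transient states.
#' @return named list (one element per stratum level) of lists with
#'   `counts`, `matrix`, `absorbing_matrix`, `entropy_matrix`,
#'   `entropy_nats`, and `n_pairs`.
#' @export
estimate_stratified <- function(pairs, stratum_column, n_states = 4L) {
  if (!stratum_column %in% names(pairs))
    stop("unknown stratum column: ", stratum_column, call. = FALSE)
  lv <- pairs[[stratum_column]]
  if (all(is.na(lv)))
    stop("stratum column has no nonmissing levels", call. = FALSE)
  lapply(split(pairs, lv, drop = TRUE), function(p) {
    counts <- count_transitions(p, n_states, include_death = FALSE)
    em <- make_entropy_matrix(counts)
    list(counts = counts,
         matrix = row_normalize(counts),
         absorbing_matrix = row_normalize(
           count_transitions(p, n_states, include_death = TRUE)),
         entropy_matrix = em,
         entropy_nats = attr(em, "entropy_nats"),
         n_pairs = sum(counts))
  })
}
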