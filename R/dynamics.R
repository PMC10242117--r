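#' Map a state sequence to major/minor labels
#'
#' Each time point inherits the label of the basin its pattern belongs to,
#' so the whole recording is described by the three-state alphabet
#' MAJOR1/MAJOR2/MINOR.
#'
#' @param states Integer vector of state indices.
#' @param labeling A [classify_states()] result.
#' @return A factor of length `length(states)` with levels MAJOR1, MAJOR2,
#'   MINOR.
#' @export
label_states <- function(states, labeling) {
  stopifnot(inherits(labeling, "state_labeling"))
  states <- check_states(states, log2(length(labeling$state_labels)))
  labeling$state_labels[states + 1L]
}

state_levels <- c("MAJOR1", "MAJOR2", "MINOR")

check_labels <- function(labels) {
  labels <- factor(labels, levels = state_levels)
  if (anyNA(labels)) stop("Labels must be MAJOR1, MAJOR2 or MINOR.", call. = FALSE)
  labels
}

#' Appearance frequency of each labeled state
#'
#' The fraction of time points spent in each of the three states; sums to 1.
#'
#' @param labels A label sequence (factor or character over
#'   MAJOR1/MAJOR2/MINOR).
#' @return Named numeric vector of length 3.
#' @export
appearance_frequency <- function(labels) {
  labels <- check_labels(labels)
  if (length(labels) < 1L) stop("Need at least one time point.", call. = FALSE)
  table(labels) / length(labels)
}

#' Transition counts and frequencies between labeled states
#'
#' Counts ordered transitions between consecutive time points, including
#' self-transitions, so counts total `T - 1`. Frequencies divide by `T - 1`.
#'
#' @inheritParams appearance_frequency
#' @return List with `counts` and `freq`, both `3 x 3` matrices (row =
#'   from, column = to).
#' @export
transition_matrix <- function(labels) {
  labels <- check_labels(labels)
  if (length(labels) < 2L) stop("Need at least two time points.", call. = FALSE)
  counts <- table(from = labels[-length(labels)], to = labels[-1L])
  counts <- unclass(counts)
  list(counts = counts, freq = counts / (length(labels) - 1L))
}

#' Direct and indirect transitions between the major states
#'
#' After compressing the label sequence into runs, a *direct* event is an
#' immediate switch between different major states; an *indirect* event is a
#' switch between different major states bridged only by minor-state runs.
#' An excursion to the minor state that returns to the same major state
#' counts as neither. Frequencies are reported per time step (`/(T - 1)`)
#' and per run boundary (`/(number of run changes)`), since printed
#' transition percentages in the literature do not pin down the denominator.
#'
#' @inheritParams appearance_frequency
#' @return A one-row tibble with `direct_count`, `indirect_count`,
#'   `direct_freq`, `indirect_freq` (per time step), `direct_freq_events`
#'   and `indirect_freq_events` (per run boundary; `NA` when the sequence
#'   never changes state).
#' @export
major_transitions <- function(labels) {
  labels <- check_labels(labels)
  if (length(labels) < 2L) stop("Need at least two time points.", call. = FALSE)
  runs <- rle(as.character(labels))$values
  is_major <- runs != "MINOR"
  direct <- sum(is_major[-length(runs)] & is_major[-1L] &
                  runs[-length(runs)] != runs[-1L])
  indirect <- 0L
  major_pos <- which(is_major)
  if (length(major_pos) >= 2L) {
    gap <- diff(major_pos)
    changed <- runs[major_pos[-length(major_pos)]] != runs[major_pos[-1L]]
    indirect <- sum(gap > 1L & changed)
  }
  n_steps <- length(labels) - 1L
  n_boundaries <- length(runs) - 1L
  tibble::tibble(
    direct_count = direct,
    indirect_count = indirect,
    direct_freq = direct / n_steps,
    indirect_freq = indirect / n_steps,
    direct_freq_events = if (n_boundaries > 0L) direct / n_boundaries else NA_real_,
    indirect_freq_events = if (n_boundaries > 0L) indirect / n_boundaries else NA_real_)
}

#' Mean dwell time of each labeled state
#'
#' The mean length of maximal runs of each label, in sampling steps (TR
#' units for fMRI). A label that never occurs gets duration 0.
#'
#' @inheritParams appearance_frequency
#' @return Named numeric vector of length 3.
#' @export
mean_durations <- function(labels) {
  labels <- check_labels(labels)
  if (length(labels) < 1L) stop("Need at least one time point.", call. = FALSE)
  runs <- rle(as.character(labels))
  out <- stats::setNames(numeric(3), state_levels)
  means <- tapply(runs$lengths, factor(runs$values, levels = state_levels), mean)
  out[!is.na(means)] <- means[!is.na(means)]
  out
}

#' All dynamic indicators for one subject
#'
#' Bundles appearance frequencies, the transition structure (including
#' direct/indirect major-state transitions) and mean dwell times for one
#' state-index sequence on a given labeled landscape.
#'
#' @param states Integer state-index sequence of one subject (never a pooled
#'   sequence: temporal statistics must not straddle subject boundaries).
#' @param labeling A [classify_states()] result for the subject's group.
#' @param subject_id Optional identifier carried into the output.
#' @return A one-row tibble with columns `subject_id`, `freq_major1`,
#'   `freq_major2`, `freq_minor`, `direct_count`, `indirect_count`,
#'   `direct_freq`, `indirect_freq`, `direct_freq_events`,
#'   `indirect_freq_events`, `dur_major1`, `dur_major2`, `dur_minor`.
#' @export
subject_metrics <- function(states, labeling, subject_id = NA_character_) {
  labels <- label_states(states, labeling)
  freq <- appearance_frequency(labels)
  trans <- major_transitions(labels)
  dur <- mean_durations(labels)
  tibble::tibble(
    subject_id = subject_id,
    freq_major1 = as.numeric(freq["MAJOR1"]),
    freq_major2 = as.numeric(freq["MAJOR2"]),
    freq_minor = as.numeric(freq["MINOR"]),
    direct_count = trans$direct_count,
    indirect_count = trans$indirect_count,
    direct_freq = trans$direct_freq,
    indirect_freq = trans$indirect_freq,
    direct_freq_events = trans$direct_freq_events,
    indirect_freq_events = trans$indirect_freq_events,
    dur_major1 = as.numeric(dur["MAJOR1"]),
    dur_major2 = as.numeric(dur["MAJOR2"]),
    dur_minor = as.numeric(dur["MINOR"]))
}

#' Names of the per-subject dynamic metrics
#'
#' The metric columns produced by [subject_metrics()], in the order used by
#' group comparisons.
#'
#' @return Character vector.
#' @export
dynamic_metric_names <- function() {
  c("freq_major1", "freq_major2", "freq_minor",
    "direct_freq", "indirect_freq",
    "dur_major1", "dur_major2", "dur_minor")
}
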