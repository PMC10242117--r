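#' Metropolis random walk on an energy landscape
#'
#' Simulates discrete-time single-flip dynamics: at each step one of the `N`
#' neighbors of the current pattern is proposed uniformly and accepted with
#' probability `min(1, exp(-(E_new - E_old)))`; a rejected proposal repeats
#' the current pattern (the repeat counts toward dwell times). The
#' stationary distribution of this chain is exactly the Boltzmann
#' distribution of the fitted model, which makes the simulation
#' self-consistent with the landscape it runs on.
#'
#' @param landscape An [energy_landscape()].
#' @param n_steps Number of retained steps (default `1e5`).
#' @param seed Optional integer seed; with a fixed seed the trajectory is
#'   reproducible. `NULL` uses the current RNG state.
#' @param burn_in Steps discarded before recording starts.
#' @param init Initial state index, or `"random"` for a uniform draw.
#' @return Integer vector of `n_steps` state indices, with attribute
#'   `acceptance_rate` (fraction of proposals accepted over the whole run,
#'   burn-in included).
#' @examples
#' l <- energy_landscape(mem_params(c(0, 0), matrix(c(0, 1, 1, 0), 2)))
#' w <- simulate_walk(l, n_steps = 100, seed = 1)
#' attr(w, "acceptance_rate")
#' @export
simulate_walk <- function(landscape, n_steps = 100000L, seed = NULL,
                          burn_in = 0L, init = "random") {
  stopifnot(inherits(landscape, "energy_landscape"))
  if (n_steps < 1L) stop("`n_steps` must be at least 1.", call. = FALSE)
  if (burn_in < 0L) stop("`burn_in` must be non-negative.", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  E <- landscape$energies
  NB <- neighbor_table(landscape$n_rois)
  total <- n_steps + burn_in
  if (identical(init, "random")) {
    cur <- sample.int(length(E), 1L) - 1L
  } else {
    cur <- check_states(init, landscape$n_rois)
    stopifnot(length(cur) == 1L)
  }
  proposals <- sample.int(landscape$n_rois, total, replace = TRUE)
  log_u <- log(stats::runif(total))
  out <- integer(total)
  accepted <- 0L
  e_cur <- E[cur + 1L]
  for (t in seq_len(total)) {
    cand <- NB[cur + 1L, proposals[t]]
    e_cand <- E[cand + 1L]
    if (log_u[t] < e_cur - e_cand) {
      cur <- cand
      e_cur <- e_cand
      accepted <- accepted + 1L
    }
    out[t] <- cur
  }
  res <- out[(burn_in + 1L):total]
  attr(res, "acceptance_rate") <- accepted / total
  res
}

#' Dynamic metrics of a simulated trajectory
#'
#' Runs [simulate_walk()] and feeds the trajectory through the same
#' dynamics computations used for empirical recordings, so simulated and
#' empirical indicators are directly comparable.
#'
#' @inheritParams simulate_walk
#' @param labeling A [classify_states()] result for the same landscape.
#' @param ... Passed on to [simulate_walk()].
#' @return A one-row tibble as from [subject_metrics()], with
#'   `subject_id = "simulation"` and an extra `acceptance_rate` column.
#' @export
simulated_metrics <- function(landscape, labeling, ...) {
  walk <- simulate_walk(landscape, ...)
  out <- subject_metrics(walk, labeling, subject_id = "simulation")
  out$acceptance_rate <- attr(walk, "acceptance_rate")
  out
}
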