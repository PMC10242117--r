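#' Empirical first and second moments of binarized activity
#'
#' Computes the per-channel temporal means `<sigma_i>` and the pairwise
#' products `<sigma_i sigma_j>` that the pairwise maximum-entropy model is
#' constrained to reproduce.
#'
#' @param b A `T x N` matrix with entries -1/+1.
#' @return An object of class `mem_moments`: a list with `mean` (length N)
#'   and `corr` (`N x N`, unit diagonal).
#' @export
empirical_moments <- function(b) {
  b <- check_binary_matrix(b)
  if (nrow(b) < 1L) stop("Need at least one time point.", call. = FALSE)
  m <- colMeans(b)
  C <- crossprod(b) / nrow(b)
  new_moments(m, C)
}

new_moments <- function(mean, corr) {
  structure(list(mean = as.numeric(mean), corr = unname(as.matrix(corr))),
            class = "mem_moments")
}

check_moments <- function(x) {
  if (!inherits(x, "mem_moments")) stop("Expected an `mem_moments` object.", call. = FALSE)
  n <- length(x$mean)
  stopifnot(is.matrix(x$corr), nrow(x$corr) == n, ncol(x$corr) == n)
  if (max(abs(x$corr - t(x$corr))) > 1e-8) stop("Moment matrix must be symmetric.", call. = FALSE)
  if (max(abs(x$mean)) > 1 + 1e-8 || max(abs(x$corr)) > 1 + 1e-8) {
    stop("Moments of ±1 data lie in [-1, 1].", call. = FALSE)
  }
  x
}

#' Empirical distribution over activity patterns
#'
#' The occurrence frequency of each of the `2^N` patterns in a state-index
#' sequence.
#'
#' @param states Integer vector of state indices (see [encode_states()]).
#' @param n_rois Number of channels.
#' @return Numeric vector of length `2^N` summing to 1; entry `k + 1` is the
#'   frequency of pattern `k`.
#' @export
empirical_distribution <- function(states, n_rois) {
  n_rois <- check_n_rois(n_rois)
  states <- check_states(states, n_rois)
  if (length(states) == 0L) stop("Empty state sequence.", call. = FALSE)
  tabulate(states + 1L, nbins = 2^n_rois) / length(states)
}

#' Pairwise maximum-entropy parameters
#'
#' Bundles the channel biases `h` (the tendency of a channel to be active in
#' isolation) and the symmetric pairwise couplings `J` (zero diagonal).
#'
#' @param h Numeric vector of length N.
#' @param J Symmetric numeric `N x N` matrix with zero diagonal.
#' @return An object of class `mem_params`.
#' @export
mem_params <- function(h, J) {
  h <- as.numeric(h)
  J <- as.matrix(J)
  n <- length(h)
  stopifnot(nrow(J) == n, ncol(J) == n)
  if (any(!is.finite(h)) || any(!is.finite(J))) stop("Parameters must be finite.", call. = FALSE)
  if (max(abs(J - t(J))) > 1e-10) stop("`J` must be symmetric.", call. = FALSE)
  if (max(abs(diag(J))) > 1e-12) stop("`J` must have a zero diagonal.", call. = FALSE)
  J <- (J + t(J)) / 2
  diag(J) <- 0
  structure(list(h = h, J = unname(J), n_rois = check_n_rois(n)), class = "mem_params")
}

#' @export
print.mem_params <- function(x, ...) {
  cat("Pairwise maximum-entropy parameters (", x$n_rois, " channels)\n", sep = "")
  cat("h:", format(signif(x$h, 3)), "\n")
  cat("|J| range:", format(signif(range(abs(x$J[upper.tri(x$J)])), 3)), "\n")
  invisible(x)
}

#' Energy of activity patterns
#'
#' Evaluates `E(V) = -sum_i h_i sigma_i - 1/2 sum_{i != j} J_ij sigma_i
#' sigma_j` for the given states. Low energy corresponds to high probability
#' under the fitted Boltzmann distribution.
#'
#' @param states Integer vector of state indices.
#' @param params An [mem_params()] object.
#' @return Numeric vector of energies.
#' @export
state_energy <- function(states, params) {
  stopifnot(inherits(params, "mem_params"))
  sig <- decode_states(states, params$n_rois)
  as.numeric(-(sig %*% params$h) - 0.5 * rowSums((sig %*% params$J) * sig))
}

energy_vector <- function(params, patterns = state_patterns(params$n_rois)) {
  as.numeric(-(patterns %*% params$h) -
               0.5 * rowSums((patterns %*% params$J) * patterns))
}

#' Boltzmann distribution of a pairwise maximum-entropy model
#'
#' Exact enumeration of `P(V_k) = exp(-E(V_k)) / sum_j exp(-E(V_j))` over all
#' `2^N` patterns, normalized in log space for numerical stability.
#'
#' @param params An [mem_params()] object with at most 15 channels.
#' @return Numeric probability vector of length `2^N`.
#' @export
boltzmann_distribution <- function(params) {
  stopifnot(inherits(params, "mem_params"))
  loge <- -energy_vector(params)
  loge <- loge - max(loge)
  p <- exp(loge)
  p / sum(p)
}

#' Model-expected moments under a pairwise maximum-entropy model
#'
#' First and second moments of the Boltzmann distribution, computed by exact
#' enumeration.
#'
#' @inheritParams boltzmann_distribution
#' @return An `mem_moments` object.
#' @export
model_moments <- function(params) {
  stopifnot(inherits(params, "mem_params"))
  S <- state_patterns(params$n_rois)
  p <- boltzmann_distribution(params)
  new_moments(as.numeric(crossprod(S, p)), crossprod(S, S * p))
}

#' Base-2 Kullback-Leibler divergence between state distributions
#'
#' `D2 = sum_k P(k) log2(P(k) / Q(k))`, the information loss (in bits) from
#' describing the empirical pattern distribution `P` by the model
#' distribution `Q`. Terms with `P(k) = 0` contribute nothing; a pattern with
#' `P(k) > 0` but `Q(k) = 0` yields `Inf`.
#'
#' @param p,q Probability vectors of equal length.
#' @return A non-negative number (possibly `Inf`).
#' @export
kl_divergence <- function(p, q) {
  if (length(p) != length(q)) stop("Distributions must have equal length.", call. = FALSE)
  if (any(p < -1e-12) || any(q < -1e-12)) stop("Probabilities must be non-negative.", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6) {
    stop("Probabilities must sum to 1.", call. = FALSE)
  }
  on <- p > 0
  if (any(q[on] == 0)) return(Inf)
  sum(p[on] * log2(p[on] / q[on]))
}

#' Fit a pairwise maximum-entropy model by moment matching
#'
#' Iteratively adjusts `h` and `J` from a zero start with the gradient
#' updates `h_i <- h_i + alpha (<sigma_i> - <sigma_i>_m)` and
#' `J_ij <- J_ij + alpha (<sigma_i sigma_j> - <sigma_i sigma_j>_m)`, where
#' `<.>_m` are the model expectations under the current Boltzmann
#' distribution, until the largest absolute moment mismatch drops below
#' `tol`. The objective is the (convex) KL divergence between data and model,
#' so the fixed point is the unique maximum-entropy fit; the start point only
#' affects the iteration count.
#'
#' @param x A -1/+1 data matrix (`T x N`) or an `mem_moments` object. With a
#'   data matrix the empirical pattern distribution and the fit quality
#'   `d2_bits` are also computed.
#' @param step_alpha Positive learning rate of the moment updates.
#' @param tol Convergence threshold on the maximum absolute moment mismatch.
#' @param max_iter Iteration cap; hitting it returns `converged = FALSE`
#'   rather than an error.
#' @param pairwise If `FALSE`, couplings are held at zero and only the
#'   biases are fitted (the independent model used as a baseline for fit
#'   quality).
#' @return An object of class `mem_fit` with elements `params`
#'   ([mem_params()]), `target_moments`, `model_moments`, `d2_bits` (NA when
#'   fitting from moments alone), `n_iter`, `converged` and `config`.
#' @examples
#' set.seed(1)
#' b <- matrix(sample(c(-1L, 1L), 200, TRUE), ncol = 2)
#' fit <- fit_mem(b)
#' glance(fit)
#' @export
fit_mem <- function(x, step_alpha = 0.2, tol = 1e-5, max_iter = 500000L,
                    pairwise = TRUE) {
  if (step_alpha <= 0 || tol <= 0 || max_iter < 1) {
    stop("`step_alpha`, `tol` and `max_iter` must be positive.", call. = FALSE)
  }
  emp_dist <- NULL
  if (inherits(x, "mem_moments")) {
    target <- check_moments(x)
    n_rois <- length(target$mean)
    check_n_rois(n_rois)
  } else {
    b <- check_binary_matrix(x)
    target <- empirical_moments(b)
    n_rois <- ncol(b)
    emp_dist <- empirical_distribution(encode_states(b), n_rois)
  }
  S <- state_patterns(n_rois)
  h <- numeric(n_rois)
  J <- matrix(0, n_rois, n_rois)
  tC <- target$corr
  diag(tC) <- 1
  converged <- FALSE
  it <- 0L
  repeat {
    loge <- as.numeric(S %*% h) + 0.5 * rowSums((S %*% J) * S)
    loge <- loge - max(loge)
    p <- exp(loge)
    p <- p / sum(p)
    mm <- as.numeric(crossprod(S, p))
    mC <- crossprod(S, S * p)
    gh <- target$mean - mm
    gJ <- tC - mC
    diag(gJ) <- 0
    if (!pairwise) gJ[] <- 0
    mismatch <- max(abs(gh), abs(gJ))
    if (!is.finite(mismatch)) {
      stop("Moment matching diverged (non-finite parameters); ",
           "try a smaller `step_alpha`.", call. = FALSE)
    }
    if (mismatch <= tol) { converged <- TRUE; break }
    if (it >= max_iter) break
    h <- h + step_alpha * gh
    J <- J + step_alpha * gJ
    it <- it + 1L
  }
  params <- mem_params(h, J)
  d2 <- NA_real_
  if (!is.null(emp_dist)) {
    d2 <- kl_divergence(emp_dist, boltzmann_distribution(params))
  }
  structure(
    list(params = params,
         target_moments = target,
         model_moments = new_moments(mm, mC),
         empirical_distribution = emp_dist,
         d2_bits = d2,
         n_iter = it,
         converged = converged,
         config = list(step_alpha = step_alpha, tol = tol,
                       max_iter = max_iter, pairwise = pairwise)),
    class = "mem_fit")
}

#' @export
print.mem_fit <- function(x, ...) {
  cat("Pairwise maximum-entropy fit: ", x$params$n_rois, " channels, ",
      x$n_iter, " iterations, ",
      if (x$converged) "converged" else "NOT converged", "\n", sep = "")
  if (!is.na(x$d2_bits)) cat("D2 (bits):", signif(x$d2_bits, 4), "\n")
  invisible(x)
}

#' Serialize a fit to JSON
#'
#' @param fit An `mem_fit` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mem_fit <- function(fit, path) {
  stopifnot(inherits(fit, "mem_fit"))
  jsonlite::write_json(
    list(h = fit$params$h, J = fit$params$J, d2_bits = fit$d2_bits,
         n_iter = fit$n_iter, converged = fit$converged, config = fit$config),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
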