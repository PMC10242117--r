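# Independent brute-force oracles, deliberately naive implementations that
# never share code paths with the package internals they check.

# random small model parameters
random_params <- function(n_rois, seed, h_sd = 0.4, j_sd = 0.4) {
  set.seed(seed)
  h <- rnorm(n_rois, 0, h_sd)
  J <- matrix(0, n_rois, n_rois)
  J[upper.tri(J)] <- rnorm(n_rois * (n_rois - 1) / 2, 0, j_sd)
  J <- J + t(J)
  mem_params(h, J)
}

# per-state energy by explicit double loop over channels
oracle_energy <- function(state, h, J) {
  n <- length(h)
  sigma <- integer(n)
  for (i in seq_len(n)) {
    sigma[i] <- if (bitwAnd(state, bitwShiftL(1L, i - 1L)) > 0L) 1L else -1L
  }
  e <- 0
  for (i in seq_len(n)) e <- e - h[i] * sigma[i]
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) e <- e - 0.5 * J[i, j] * sigma[i] * sigma[j]
  }
  e
}

# Boltzmann law by direct term-by-term summation
oracle_boltzmann <- function(h, J) {
  n <- length(h)
  e <- vapply(0:(2^n - 1L), oracle_energy, numeric(1), h = h, J = J)
  w <- exp(-e)
  w / sum(w)
}

# local minima by explicit neighbor comparison
oracle_minima <- function(energies, n_rois) {
  out <- integer(0)
  for (k in 0:(2^n_rois - 1L)) {
    nb <- bitwXor(k, bitwShiftL(1L, seq_len(n_rois) - 1L))
    if (all(energies[k + 1L] < energies[nb + 1L])) out <- c(out, k)
  }
  out
}

# steepest-descent basin of one state, recursive definition
oracle_basin <- function(state, energies, n_rois) {
  repeat {
    nb <- bitwXor(state, bitwShiftL(1L, seq_len(n_rois) - 1L))
    e_nb <- energies[nb + 1L]
    if (min(e_nb) >= energies[state + 1L]) return(state)
    state <- min(nb[e_nb == min(e_nb)])
  }
}

# minimax path energies by Floyd-Warshall on the hypercube:
# cost(a, b) over a->b paths of the maximum state energy encountered,
# endpoints included
oracle_minimax <- function(energies, n_rois) {
  n_states <- 2^n_rois
  M <- matrix(Inf, n_states, n_states)
  for (k in 0:(n_states - 1L)) {
    M[k + 1L, k + 1L] <- energies[k + 1L]
    for (nb in bitwXor(k, bitwShiftL(1L, seq_len(n_rois) - 1L))) {
      M[k + 1L, nb + 1L] <- max(energies[k + 1L], energies[nb + 1L])
    }
  }
  for (mid in seq_len(n_states)) {
    via <- pmax(M[, mid], rep(M[mid, ], each = n_states))
    dim(via) <- c(n_states, n_states)
    M <- pmin(M, via)
  }
  M
}

# disconnection threshold by literal threshold deletion: lower the threshold
# through the sorted energies and report the first value at which a and b
# sit in different connected components of the surviving subgraph
oracle_threshold_barrier <- function(a, b, energies, n_rois) {
  n_states <- 2^n_rois
  connected_at <- function(eth) {
    alive <- which(energies <= eth) - 1L
    if (!(a %in% alive) || !(b %in% alive)) return(FALSE)
    seen <- a
    frontier <- a
    while (length(frontier)) {
      nxt <- unique(unlist(lapply(frontier, function(k) {
        bitwXor(k, bitwShiftL(1L, seq_len(n_rois) - 1L))
      })))
      nxt <- setdiff(intersect(nxt, alive), seen)
      if (b %in% nxt) return(TRUE)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    FALSE
  }
  for (eth in sort(unique(energies))) {
    if (connected_at(eth)) return(eth)
  }
  stop("states never connect")
}

# random label sequences over the three-state alphabet
random_labels <- function(t_points, seed, p_minor = 0.2) {
  set.seed(seed)
  sample(c("MAJOR1", "MAJOR2", "MINOR"), t_points, replace = TRUE,
         prob = c((1 - p_minor) / 2, (1 - p_minor) / 2, p_minor))
}

# small ready-made landscape: 2-channel ferromagnet
ferro2_landscape <- function(j = 1) {
  energy_landscape(mem_params(c(0, 0), matrix(c(0, j, j, 0), 2)))
}

# moments of independent spins with given means (corr_ij = m_i * m_j)
new_moments_for_test <- function(m) {
  C <- outer(m, m)
  diag(C) <- 1
  fit0 <- empirical_moments(rbind(rep(1L, length(m)), rep(-1L, length(m))))
  fit0$mean <- m
  fit0$corr <- C
  fit0
}
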