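#' Build the full energy landscape of a fitted model
#'
#' Enumerates the energy of every one of the `2^N` activity patterns under a
#' pairwise maximum-entropy model. The landscape is the object all
#' topographic analyses (minima, basins, barriers) operate on.
#'
#' @param params An [mem_params()] object, or an `mem_fit` whose parameters
#'   are used.
#' @return An object of class `energy_landscape`: list with `energies`
#'   (length `2^N`), `n_rois` and `params`.
#' @export
energy_landscape <- function(params) {
  if (inherits(params, "mem_fit")) params <- params$params
  stopifnot(inherits(params, "mem_params"))
  structure(list(energies = energy_vector(params),
                 n_rois = params$n_rois,
                 params = params),
            class = "energy_landscape")
}

#' @export
print.energy_landscape <- function(x, ...) {
  cat("Energy landscape over ", 2^x$n_rois, " patterns (",
      x$n_rois, " channels)\n", sep = "")
  cat("Energy range: [", signif(min(x$energies), 4), ", ",
      signif(max(x$energies), 4), "]\n", sep = "")
  invisible(x)
}

#' Locate local minima of the landscape
#'
#' A pattern is a local minimum when its energy is strictly lower than that
#' of all `N` single-flip neighbors; such patterns are the stable activity
#' states of the system. Plateau states tied with their best neighbor do not
#' qualify.
#'
#' @param landscape An [energy_landscape()].
#' @return A tibble with columns `state` (index, ascending) and `energy`.
#' @export
find_local_minima <- function(landscape) {
  stopifnot(inherits(landscape, "energy_landscape"))
  E <- landscape$energies
  NB <- neighbor_table(landscape$n_rois)
  best_nb <- row_mins(matrix(E[NB + 1L], nrow = nrow(NB)))
  idx <- which(E < best_nb) - 1L
  if (length(idx) == 0L) {
    stop("Degenerate landscape: no strict local minimum exists.", call. = FALSE)
  }
  tibble::tibble(state = idx, energy = E[idx + 1L])
}

## vectorized row minima via pmin
row_mins <- function(m) {
  do.call(pmin, as.data.frame(m))
}

#' Assign every pattern to a basin of attraction
#'
#' From each state, steepest descent repeatedly moves to the lowest-energy
#' neighbor while that neighbor is strictly lower than the current state
#' (ties among equally lowest neighbors go to the smallest state index). The
#' terminal state is a local minimum and defines the basin.
#'
#' @param landscape An [energy_landscape()].
#' @param minima Optional result of [find_local_minima()] (recomputed if
#'   missing); used for validation.
#' @return Integer vector of length `2^N`: entry `k + 1` is the state index
#'   of the minimum whose basin contains state `k`.
#' @export
assign_basins <- function(landscape, minima = find_local_minima(landscape)) {
  stopifnot(inherits(landscape, "energy_landscape"))
  E <- landscape$energies
  NB <- neighbor_table(landscape$n_rois)
  n_states <- length(E)
  Emat <- matrix(E[NB + 1L], nrow = n_states)
  ## lowest-energy neighbor; ties resolved to the smallest state index by
  ## scanning candidates in increasing index order
  nxt <- integer(n_states)
  row_min <- row_mins(Emat)
  for (k in seq_len(n_states)) {
    if (row_min[k] < E[k]) {
      cand <- NB[k, Emat[k, ] == row_min[k]]
      nxt[k] <- min(cand)
    } else {
      nxt[k] <- k - 1L
    }
  }
  ## pointer jumping: energy strictly decreases along `nxt`, so this
  ## converges to the terminal minima in O(log T) sweeps
  repeat {
    nn <- nxt[nxt + 1L]
    if (identical(nn, nxt)) break
    nxt <- nn
  }
  terminal <- sort(unique(nxt))
  if (!all(terminal %in% minima$state)) {
    stop("Internal error: descent terminated outside the minima set.", call. = FALSE)
  }
  nxt
}

#' Disconnectivity graph of the landscape
#'
#' Computes, for every pair of local minima, the energy barrier `E_th`: the
#' lowest threshold at which the two minima fall into separate connected
#' components when all patterns with energy above the threshold are removed
#' from the hypercube adjacency graph. This equals the minimax path energy
#' (the smallest possible value, over paths connecting the minima, of the
#' highest energy met along the path). The merge hierarchy is recorded as a
#' tree.
#'
#' Implemented by sweeping states in increasing energy order with a
#' union-find structure: when a state first connects two components that
#' each already contain a minimum, its energy is the barrier for all pairs
#' across the two components. The resulting barrier matrix is symmetric and
#' ultrametric.
#'
#' @param landscape An [energy_landscape()].
#' @param minima Optional [find_local_minima()] result.
#' @return An object of class `disconnectivity`: list with `minima` (tibble),
#'   `barrier` (symmetric matrix, `NA`-free for >= 2 minima; `0 x 0` for a
#'   single minimum), and `merges` (tibble of merge events with the barrier
#'   height and member minima of the two merged components).
#' @export
build_disconnectivity <- function(landscape, minima = find_local_minima(landscape)) {
  stopifnot(inherits(landscape, "energy_landscape"))
  E <- landscape$energies
  n_states <- length(E)
  NB <- neighbor_table(landscape$n_rois)
  n_min <- nrow(minima)
  if (n_min == 1L) {
    return(structure(list(minima = minima,
                          barrier = matrix(numeric(0), 0, 0),
                          merges = tibble::tibble(barrier = numeric(0),
                                                  left = list(), right = list())),
                     class = "disconnectivity"))
  }
  B <- matrix(NA_real_, n_min, n_min)
  parent <- seq_len(n_states)
  find_root <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  members <- vector("list", n_states)  # minima (row of `minima`) per component
  is_min <- logical(n_states)
  min_row <- integer(n_states)
  is_min[minima$state + 1L] <- TRUE
  min_row[minima$state + 1L] <- seq_len(n_min)
  added <- logical(n_states)
  merges <- list()
  ## ascending energy, ties broken by state index (order() is stable)
  for (k1 in order(E)) {
    added[k1] <- TRUE
    if (is_min[k1]) members[[k1]] <- min_row[k1]
    for (nb1 in NB[k1, ] + 1L) {
      if (!added[nb1]) next
      r1 <- find_root(k1)
      r2 <- find_root(nb1)
      if (r1 == r2) next
      m1 <- members[[r1]]
      m2 <- members[[r2]]
      if (length(m1) && length(m2)) {
        B[m1, m2] <- E[k1]
        B[m2, m1] <- E[k1]
        merges[[length(merges) + 1L]] <-
          tibble::tibble(barrier = E[k1], left = list(sort(m1)), right = list(sort(m2)))
      }
      parent[r2] <- r1
      members[[r1]] <- c(m1, m2)
      members[[r2]] <- integer(0)
    }
  }
  diag(B) <- minima$energy
  structure(list(minima = minima, barrier = B,
                 merges = dplyr::bind_rows(merges)),
            class = "disconnectivity")
}

#' @export
print.disconnectivity <- function(x, ...) {
  cat("Disconnectivity graph with", nrow(x$minima), "local minima\n")
  if (nrow(x$minima) > 1L) {
    off <- x$barrier[upper.tri(x$barrier)]
    cat("Barrier range: [", signif(min(off), 4), ", ", signif(max(off), 4), "]\n", sep = "")
  }
  invisible(x)
}

#' Classify minima into two major states and a minor class
#'
#' Reproduces the grouping used for resting-state landscapes: among the four
#' lowest-energy minima, the two disjoint pairs with the smallest total
#' mutual barrier are formed (with an ultrametric barrier matrix this equals
#' greedy pairing by the smallest barrier); the pair containing the global
#' minimum is major state 1, the other pair major state 2, and every
#' remaining minimum is a minor state. With 2-3 minima the two lowest are
#' the (singleton) major states; with a single minimum it is major state 1
#' alone. Labels extend from minima to all patterns through the basin map.
#'
#' @param disconnectivity A [build_disconnectivity()] result.
#' @param landscape The matching [energy_landscape()].
#' @param basins Optional [assign_basins()] result (recomputed if missing).
#' @return An object of class `state_labeling`: list with `minima` (tibble
#'   with `state`, `energy`, `label`), `state_labels` (factor of length
#'   `2^N` over MAJOR1/MAJOR2/MINOR), `basins`, and `degenerate` (TRUE when
#'   fewer than 4 minima forced a fallback rule).
#' @export
classify_states <- function(disconnectivity, landscape,
                            basins = assign_basins(landscape, disconnectivity$minima)) {
  stopifnot(inherits(disconnectivity, "disconnectivity"),
            inherits(landscape, "energy_landscape"))
  minima <- disconnectivity$minima
  n_min <- nrow(minima)
  lab <- rep("MINOR", n_min)
  degenerate <- n_min < 4L
  if (n_min == 1L) {
    lab[1L] <- "MAJOR1"
  } else if (n_min <= 3L) {
    ord <- order(minima$energy, minima$state)
    lab[ord[1L]] <- "MAJOR1"
    lab[ord[2L]] <- "MAJOR2"
  } else {
    low4 <- order(minima$energy, minima$state)[1:4]
    B <- disconnectivity$barrier
    pairings <- list(c(1L, 2L, 3L, 4L), c(1L, 3L, 2L, 4L), c(1L, 4L, 2L, 3L))
    totals <- vapply(pairings, function(p) {
      B[low4[p[1L]], low4[p[2L]]] + B[low4[p[3L]], low4[p[4L]]]
    }, numeric(1))
    best <- pairings[[which.min(totals)]]
    pair1 <- low4[best[1:2]]
    pair2 <- low4[best[3:4]]
    global_min <- order(minima$energy, minima$state)[1L]
    if (global_min %in% pair1) {
      lab[pair1] <- "MAJOR1"; lab[pair2] <- "MAJOR2"
    } else {
      lab[pair2] <- "MAJOR1"; lab[pair1] <- "MAJOR2"
    }
  }
  minima$label <- lab
  state_labels <- factor(lab[match(basins, minima$state)],
                         levels = c("MAJOR1", "MAJOR2", "MINOR"))
  structure(list(minima = minima, state_labels = state_labels,
                 basins = basins, degenerate = degenerate),
            class = "state_labeling")
}

#' @export
print.state_labeling <- function(x, ...) {
  cat("State labeling:", sum(x$minima$label == "MAJOR1"), "MAJOR1,",
      sum(x$minima$label == "MAJOR2"), "MAJOR2,",
      sum(x$minima$label == "MINOR"), "minor minima\n")
  print(table(x$state_labels))
  invisible(x)
}

#' Align major-state labels by pattern activation
#'
#' The classification rule names the pair containing the global minimum
#' "major state 1". When the two major states are near-mirror activity
#' patterns with almost equal depth — the typical resting-state geometry —
#' fitting noise decides which pair holds the global minimum, so the
#' MAJOR1/MAJOR2 names can swap between independently fitted landscapes
#' (e.g. the two groups of a cohort). This helper renames the majors by a
#' fit-independent convention: the pair whose minima patterns have the
#' higher mean activation becomes MAJOR1. Group-level contrasts of
#' per-major metrics then compare like with like. Exact activation ties
#' keep the energy-based names.
#'
#' @param labeling A [classify_states()] result.
#' @param n_rois Number of channels of the underlying landscape.
#' @return The labeling, possibly with MAJOR1 and MAJOR2 exchanged.
#' @export
align_major_labels <- function(labeling, n_rois) {
  stopifnot(inherits(labeling, "state_labeling"))
  act <- function(lbl) {
    st <- labeling$minima$state[labeling$minima$label == lbl]
    if (!length(st)) return(NA_real_)
    mean(decode_states(st, n_rois))
  }
  a1 <- act("MAJOR1")
  a2 <- act("MAJOR2")
  if (is.na(a1) || is.na(a2) || a1 >= a2) return(labeling)
  swap <- c(MAJOR1 = "MAJOR2", MAJOR2 = "MAJOR1", MINOR = "MINOR")
  labeling$minima$label <- unname(swap[labeling$minima$label])
  labeling$state_labels <- factor(
    unname(swap[as.character(labeling$state_labels)]),
    levels = c("MAJOR1", "MAJOR2", "MINOR"))
  labeling
}

#' Serialize a landscape analysis to JSON
#'
#' @param landscape An [energy_landscape()].
#' @param disconnectivity A [build_disconnectivity()] result.
#' @param labeling A [classify_states()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_landscape <- function(landscape, disconnectivity, labeling, path) {
  jsonlite::write_json(
    list(n_rois = landscape$n_rois,
         energies = landscape$energies,
         minima = list(state = disconnectivity$minima$state,
                       energy = disconnectivity$minima$energy,
                       pattern = decode_states(disconnectivity$minima$state,
                                               landscape$n_rois),
                       label = labeling$minima$label),
         barrier = disconnectivity$barrier,
         merges = list(barrier = disconnectivity$merges$barrier,
                       left = disconnectivity$merges$left,
                       right = disconnectivity$merges$right),
         basins = labeling$basins),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
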