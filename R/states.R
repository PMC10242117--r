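#' State-space utilities for binary activity patterns
#'
#' An activity pattern over `n_rois` channels is a vector in \{-1, +1\}^N.
#' Patterns are indexed by integers in `[0, 2^N)`: ROI 1 maps to the least
#' significant bit and an active channel (+1) maps to bit value 1, so index 0
#' is the all-inactive pattern and `2^N - 1` the all-active one.
#'
#' @name state-space
#' @keywords internal
NULL

MAX_N_ROIS <- 15L

check_n_rois <- function(n_rois) {
  if (!is.numeric(n_rois) || length(n_rois) != 1L || n_rois < 1L || n_rois != round(n_rois)) {
    stop("`n_rois` must be a single positive integer.", call. = FALSE)
  }
  if (n_rois > MAX_N_ROIS) {
    stop("Exhaustive state enumeration supports at most ", MAX_N_ROIS,
         " channels (got ", n_rois, ").", call. = FALSE)
  }
  as.integer(n_rois)
}

#' Enumerate all activity patterns
#'
#' Returns the full `2^N x N` matrix of activity patterns in \{-1, +1\},
#' row `k + 1` holding the pattern with state index `k`.
#'
#' @param n_rois Number of channels (at most 15).
#' @return An integer matrix with entries -1/+1.
#' @examples
#' state_patterns(2)
#' @export
state_patterns <- function(n_rois) {
  n_rois <- check_n_rois(n_rois)
  k <- 0:(2^n_rois - 1L)
  vapply(seq_len(n_rois), function(i) {
    ifelse(bitwAnd(k, bitwShiftL(1L, i - 1L)) > 0L, 1L, -1L)
  }, integer(length(k)))
}

#' Hamming-1 neighbor table
#'
#' For every state index, the `N` states reachable by flipping a single
#' channel. Two patterns are adjacent exactly when they differ in one element.
#'
#' @param n_rois Number of channels.
#' @return Integer matrix `2^N x N`; entry `[k + 1, i]` is the index of state
#'   `k` with channel `i` flipped.
#' @export
neighbor_table <- function(n_rois) {
  n_rois <- check_n_rois(n_rois)
  k <- 0:(2^n_rois - 1L)
  vapply(seq_len(n_rois), function(i) bitwXor(k, bitwShiftL(1L, i - 1L)),
         integer(length(k)))
}

#' Neighbors of a single state
#'
#' @param state State index in `[0, 2^N)`.
#' @param n_rois Number of channels.
#' @return Integer vector of the `N` single-flip neighbor indices.
#' @examples
#' state_neighbors(0, 3) # 1, 2, 4
#' @export
state_neighbors <- function(state, n_rois) {
  n_rois <- check_n_rois(n_rois)
  state <- check_states(state, n_rois)
  bitwXor(state, bitwShiftL(1L, seq_len(n_rois) - 1L))
}

check_states <- function(states, n_rois) {
  if (any(!is.finite(states)) || any(states != round(states)) ||
      any(states < 0L) || any(states >= 2^n_rois)) {
    stop("State indices must be integers in [0, 2^", n_rois, ").", call. = FALSE)
  }
  as.integer(states)
}

#' Encode binary activity rows as state indices
#'
#' Bijectively maps each row of a -1/+1 matrix to its pattern index
#' (ROI 1 = least significant bit, +1 = bit 1).
#'
#' @param b A `T x N` matrix with entries in \{-1, +1\}, e.g. from
#'   [binarize()].
#' @return Integer vector of length `T` with values in `[0, 2^N)`.
#' @seealso [decode_states()] for the inverse map.
#' @examples
#' encode_states(rbind(c(-1, -1), c(1, -1), c(1, 1))) # 0, 1, 3
#' @export
encode_states <- function(b) {
  b <- check_binary_matrix(b)
  n_rois <- ncol(b)
  bits <- (b + 1L) / 2L
  as.integer(bits %*% bitwShiftL(1L, seq_len(n_rois) - 1L))
}

#' Decode state indices back to activity patterns
#'
#' @param states Integer vector of state indices.
#' @param n_rois Number of channels.
#' @return Integer matrix `length(states) x N` with entries -1/+1.
#' @export
decode_states <- function(states, n_rois) {
  n_rois <- check_n_rois(n_rois)
  states <- check_states(states, n_rois)
  vapply(seq_len(n_rois), function(i) {
    ifelse(bitwAnd(states, bitwShiftL(1L, i - 1L)) > 0L, 1L, -1L)
  }, integer(length(states)))
}

check_binary_matrix <- function(b) {
  b <- as.matrix(b)
  if (!all(b %in% c(-1L, 1L))) {
    stop("Binary activity matrices must contain only -1 and +1.", call. = FALSE)
  }
  if (ncol(b) < 1L || ncol(b) > MAX_N_ROIS) {
    stop("Binary activity matrices must have between 1 and ", MAX_N_ROIS,
         " columns.", call. = FALSE)
  }
  storage.mode(b) <- "integer"
  b
}
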