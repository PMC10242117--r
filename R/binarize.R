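#' Binarize continuous ROI time series
#'
#' Converts a continuous `T x N` multichannel recording to a -1/+1 activation
#' matrix. Each channel is thresholded at its own temporal mean: a sample is
#' active (+1) when it strictly exceeds the channel mean, inactive (-1)
#' otherwise (values exactly at the mean map to -1). With roughly symmetric
#' signals each channel is therefore active about half of the time, which is
#' the operating point the pairwise maximum-entropy model assumes.
#'
#' @param x A numeric matrix or data frame, one row per time point, one
#'   column per ROI. All values must be finite; at least 2 rows and between
#'   2 and 15 columns.
#' @return An integer matrix of the same dimension with entries -1/+1,
#'   keeping column names.
#' @examples
#' binarize(cbind(a = c(1, 3), b = c(0, 2)))
#' @export
binarize <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("`x` must be numeric.", call. = FALSE)
  if (any(!is.finite(x))) {
    stop("`x` contains non-finite values; clean the recording first.", call. = FALSE)
  }
  if (nrow(x) < 2L) stop("Need at least 2 time points.", call. = FALSE)
  if (ncol(x) < 2L || ncol(x) > MAX_N_ROIS) {
    stop("Need between 2 and ", MAX_N_ROIS, " channels.", call. = FALSE)
  }
  mu <- colMeans(x)
  b <- ifelse(sweep(x, 2L, mu, `>`), 1L, -1L)
  storage.mode(b) <- "integer"
  dimnames(b) <- dimnames(x)
  b
}

#' Pool binarized subjects into one group matrix
#'
#' Concatenates per-subject -1/+1 matrices row-wise, in the order given, for
#' group-level model fitting. Subject boundaries are recorded so that
#' temporal statistics (transitions, run lengths) are never computed across
#' the seam between two subjects; moment and state-frequency computations use
#' all rows.
#'
#' @param subjects A list of -1/+1 matrices sharing the same number of
#'   columns (and ideally the same column names).
#' @return An integer matrix with attributes `boundaries` (row index of the
#'   last sample of each subject) and `subject_ids` (names of `subjects`,
#'   if any).
#' @examples
#' b1 <- matrix(c(1L, -1L, 1L, -1L), 2)
#' b2 <- matrix(1L, 3, 2)
#' attr(pool_group(list(b1, b2)), "boundaries")
#' @export
pool_group <- function(subjects) {
  if (!is.list(subjects) || length(subjects) == 0L) {
    stop("`subjects` must be a non-empty list of binary matrices.", call. = FALSE)
  }
  subjects <- lapply(subjects, check_binary_matrix)
  ncols <- vapply(subjects, ncol, integer(1))
  if (length(unique(ncols)) != 1L) {
    stop("All subjects must share the same number of channels; got ",
         paste(unique(ncols), collapse = ", "), ".", call. = FALSE)
  }
  pooled <- do.call(rbind, subjects)
  attr(pooled, "boundaries") <- unname(cumsum(vapply(subjects, nrow, integer(1))))
  attr(pooled, "subject_ids") <- names(subjects)
  pooled
}

#' Split a pooled matrix back into per-subject blocks
#'
#' @param pooled A matrix with a `boundaries` attribute as produced by
#'   [pool_group()].
#' @return A list of matrices.
#' @keywords internal
split_pooled <- function(pooled) {
  bnd <- attr(pooled, "boundaries")
  if (is.null(bnd)) return(list(pooled))
  starts <- c(1L, utils::head(bnd, -1L) + 1L)
  out <- Map(function(s, e) pooled[s:e, , drop = FALSE], starts, bnd)
  names(out) <- attr(pooled, "subject_ids")
  out
}

#' Read a per-subject ROI time-series file
#'
#' Expects a delimited text file with a header row of ROI labels and one row
#' per time point (comma- or tab-separated, inferred from the file).
#'
#' @param path Path to a CSV/TSV file.
#' @return A numeric matrix with ROI labels as column names.
#' @export
read_roi_ts <- function(path) {
  df <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("Non-numeric columns in ", path, call. = FALSE)
  m
}

#' Read a cohort manifest
#'
#' The manifest is a CSV with one row per subject and columns `subject_id`,
#' `group`, `score`, `path` and optionally `tr_seconds`. Paths are resolved
#' relative to the manifest location.
#'
#' @param path Path to the manifest CSV.
#' @return A tibble with one row per subject.
#' @export
read_manifest <- function(path) {
  man <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("subject_id", "group", "score", "path")
  missing <- setdiff(needed, names(man))
  if (length(missing)) {
    stop("Manifest is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  man$path <- file.path(dirname(path), man$path)
  man
}
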