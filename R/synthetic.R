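#' Default group-level model of the synthetic cohort
#'
#' A frozen 8-channel pairwise maximum-entropy parameter set used as the
#' ground truth of the synthetic cohort generator. The couplings carry an
#' exact symmetry under jointly swapping the two 4-channel blocks and
#' flipping all signs (`h_{i+4} = -h_i`, `J = [[K, L], [L, K]]` with `L`
#' symmetric), so the landscape's two dominant attractors are mirror-image
#' activity patterns — the structure reported for resting-state networks,
#' where the major states are a mostly-active and a mostly-inactive pattern
#' pair and minima occur in complementary pairs. At full depth the
#' landscape has a handful of local minima, two low-energy major pairs,
#' minor-state occupancy of a few percent and major-state dwell times of a
#' few sampling steps; scaling the couplings down (a flatter, patient-like
#' landscape) raises minor-state occupancy and indirect switching.
#'
#' @return An [mem_params()] object with 8 channels.
#' @export
default_cohort_params <- function() {
  K <- matrix(c(
     0.0000,  0.0099, 0.1338,  0.0023,
     0.0099,  0.0000, 0.1838, -0.0233,
     0.1338,  0.1838, 0.0000,  0.0840,
     0.0023, -0.0233, 0.0840,  0.0000), 4, 4, byrow = TRUE)
  L <- matrix(c(
     0.1162, -0.1032, 0.0023, -0.0424,
    -0.1032,  0.0183, 0.1675,  0.0713,
     0.0023,  0.1675, 0.1035,  0.0753,
    -0.0424,  0.0713, 0.0753, -0.1247), 4, 4, byrow = TRUE)
  hA <- c(-0.0442, 0.1177, -0.1058, 0.0153)
  mem_params(c(hA, -hA), rbind(cbind(K, L), cbind(L, K)))
}

#' Specification of a synthetic two-group cohort
#'
#' Describes a cohort of subjects whose binarized activity follows a
#' group-level pairwise maximum-entropy model with group-specific landscape
#' depth. Each subject `s` gets a depth factor `beta_s` (group depth plus
#' Gaussian jitter); the subject's couplings are `beta_s * J`, so a smaller
#' depth factor yields a flatter, less stable landscape. Clinical scores
#' are a linear function of `beta_s` plus noise, clipped to the declared
#' range, mimicking a 0-30 cognition scale on which patients score lower.
#'
#' @param n_rois Number of channels (the default parameters use 8).
#' @param groups Two-row data frame with columns `group`, `n_subjects` and
#'   `depth_factor`. The defaults plant a patient-like group with a
#'   flattened landscape (depth 0.6) against a control-like group at full
#'   depth (1.0), 20 subjects each.
#' @param t_points Time points per subject (190 samples at a 3 s sampling
#'   interval, a typical resting-state run length).
#' @param tr_seconds Sampling interval, carried into manifests.
#' @param jitter_sd SD of the per-subject jitter on the depth factor.
#' @param noise_sd SD of the Gaussian observation noise added when turning
#'   binary states into continuous signals.
#' @param score_intercept,score_slope,score_sd Linear score model
#'   `score = intercept + slope * beta_s + N(0, score_sd)`.
#' @param score_range Clipping bounds of the score.
#' @param base_params Ground-truth [mem_params()] shared by both groups
#'   before depth scaling.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_rois = 8L,
                        groups = tibble::tibble(
                          group = c("patient", "control"),
                          n_subjects = c(20L, 20L),
                          depth_factor = c(0.6, 1.0)),
                        t_points = 190L,
                        tr_seconds = 3,
                        jitter_sd = 0.05,
                        noise_sd = 0.5,
                        score_intercept = 14,
                        score_slope = 15,
                        score_sd = 1.5,
                        score_range = c(0, 30),
                        base_params = default_cohort_params()) {
  stopifnot(inherits(base_params, "mem_params"),
            base_params$n_rois == n_rois,
            nrow(groups) >= 1L,
            all(c("group", "n_subjects", "depth_factor") %in% names(groups)),
            all(groups$n_subjects >= 1L), all(groups$depth_factor > 0),
            t_points >= 2L, jitter_sd >= 0, noise_sd >= 0, score_sd >= 0)
  structure(list(n_rois = check_n_rois(n_rois), groups = groups,
                 t_points = as.integer(t_points), tr_seconds = tr_seconds,
                 jitter_sd = jitter_sd, noise_sd = noise_sd,
                 score_intercept = score_intercept, score_slope = score_slope,
                 score_sd = score_sd, score_range = score_range,
                 base_params = base_params),
            class = "cohort_spec")
}

#' Sample a binarized activity sequence from a pairwise model
#'
#' Ground-truth generator for the Boltzmann law. `mode = "iid"` draws
#' independent patterns from the exact distribution (useful for
#' moment-recovery checks); `mode = "walk"` runs the Metropolis chain,
#' giving temporally correlated sequences with realistic dwell and
#' transition structure.
#'
#' @param params An [mem_params()] object.
#' @param t_points Number of time points.
#' @param mode `"walk"` (default) or `"iid"`.
#' @param seed Optional seed for reproducibility.
#' @param burn_in Burn-in steps for the walk mode.
#' @return Integer `t_points x N` matrix with entries -1/+1.
#' @export
sample_mem_sequence <- function(params, t_points, mode = c("walk", "iid"),
                                seed = NULL, burn_in = 50L) {
  stopifnot(inherits(params, "mem_params"), t_points >= 1L)
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  if (mode == "iid") {
    p <- boltzmann_distribution(params)
    states <- sample.int(length(p), t_points, replace = TRUE, prob = p) - 1L
  } else {
    states <- simulate_walk(energy_landscape(params), n_steps = t_points,
                            burn_in = burn_in, init = "random")
  }
  decode_states(states, params$n_rois)
}

#' Add Gaussian observation noise to a binary sequence
#'
#' Produces a continuous recording `value = sigma + N(0, noise_sd)` so that
#' the binarization step can be exercised end-to-end. At zero noise,
#' [binarize()] recovers the binary matrix exactly whenever each channel
#' visits both states.
#'
#' @param b A -1/+1 matrix.
#' @param noise_sd Noise standard deviation (>= 0).
#' @param seed Optional seed.
#' @return A numeric matrix of the same dimension.
#' @export
to_continuous <- function(b, noise_sd = 0.5, seed = NULL) {
  b <- check_binary_matrix(b)
  stopifnot(noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  b + matrix(stats::rnorm(length(b), 0, noise_sd), nrow(b), ncol(b))
}

#' Generate a synthetic cohort
#'
#' Draws every subject of a [cohort_spec()]: per-subject depth factors,
#' Metropolis-sampled binary sequences under the subject's scaled
#' couplings, continuous observations, and clinical scores tied to the
#' depth factor. The entire cohort is a deterministic function of `seed`.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer master seed.
#' @return A list of class `synthetic_cohort` with `manifest` (tibble:
#'   `subject_id`, `group`, `score`, `tr_seconds`), `series` (named list of
#'   continuous `T x N` matrices), and `ground_truth` (list with the cohort
#'   specification,
#'   per-subject depth factors and the base parameters).
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  roi_labels <- paste0("ROI", seq_len(spec$n_rois))
  rows <- list()
  series <- list()
  betas <- list()
  for (g in seq_len(nrow(spec$groups))) {
    grp <- spec$groups$group[g]
    for (s in seq_len(spec$groups$n_subjects[g])) {
      sid <- sprintf("%s_%02d", grp, s)
      beta_s <- max(0.05, stats::rnorm(1, spec$groups$depth_factor[g], spec$jitter_sd))
      params_s <- mem_params(spec$base_params$h, beta_s * spec$base_params$J)
      b <- sample_mem_sequence(params_s, spec$t_points, mode = "walk")
      x <- to_continuous(b, spec$noise_sd)
      colnames(x) <- roi_labels
      score <- spec$score_intercept + spec$score_slope * beta_s +
        stats::rnorm(1, 0, spec$score_sd)
      score <- min(max(score, spec$score_range[1]), spec$score_range[2])
      rows[[sid]] <- tibble::tibble(subject_id = sid, group = grp,
                                    score = score, tr_seconds = spec$tr_seconds)
      series[[sid]] <- x
      betas[[sid]] <- beta_s
    }
  }
  structure(list(manifest = dplyr::bind_rows(rows),
                 series = series,
                 ground_truth = list(seed = seed, spec = spec,
                                     beta = unlist(betas))),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$manifest), "subjects,",
      ncol(x$series[[1]]), "channels,", nrow(x$series[[1]]), "time points each\n")
  print(dplyr::count(x$manifest, .data$group))
  invisible(x)
}

#' Write a cohort to disk
#'
#' One CSV per subject (header = ROI labels), a `manifest.csv`, and a
#' `ground_truth.json` with the per-subject depth factors and base
#' parameters for use as test oracles.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  man$path <- paste0(man$subject_id, ".csv")
  for (sid in names(cohort$series)) {
    readr::write_csv(tibble::as_tibble(cohort$series[[sid]]),
                     file.path(dir, paste0(sid, ".csv")))
  }
  readr::write_csv(man, file.path(dir, "manifest.csv"))
  gt <- cohort$ground_truth
  jsonlite::write_json(
    list(seed = gt$seed, beta = as.list(gt$beta),
         h = gt$spec$base_params$h, J = gt$spec$base_params$J,
         depth_factors = stats::setNames(as.list(gt$spec$groups$depth_factor),
                                         gt$spec$groups$group)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.csv` and per-subject CSVs.
#' @return A list with `manifest` and `series`, as in [generate_cohort()].
#' @export
read_cohort <- function(dir) {
  man <- read_manifest(file.path(dir, "manifest.csv"))
  series <- lapply(man$path, read_roi_ts)
  names(series) <- man$subject_id
  list(manifest = dplyr::select(man, -"path"), series = series)
}
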