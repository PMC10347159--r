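#' Smooth order-preserving retention-time drift model
#'
#' Emulates run-to-run drift under nominally identical conditions: a
#' near-unity linear rescaling, a smooth quadratic term, and a seeded
#' low-frequency wobble, giving deviations from sub-second to tens of
#' seconds that are non-linear in retention time yet strictly
#' order-preserving.  The drifted time is
#' `RT' = linear_scale * RT + curvature * RT^2 / span + wobble(RT)`, where
#' `wobble` is a fixed small basis of low-frequency sinusoids with
#' seed-drawn coefficients, normalized so `|wobble| <= wobble_amplitude`.
#'
#' @param linear_scale dimensionless, near 1 (e.g. 0.98-1.02).
#' @param curvature dimensionless; contributes `curvature * span` seconds at
#'   the end of the span.
#' @param wobble_amplitude seconds, bound on the smooth non-linear
#'   perturbation.
#' @param seed integer seed for the wobble coefficients.
#' @param span chromatogram span in seconds the model must be monotone over.
#' @return A `drift_model`; construction fails if the induced map is not
#'   strictly increasing on `[0, span]`.
#' @export
drift_model <- function(linear_scale = 1, curvature = 0, wobble_amplitude = 0,
                        seed = 1L, span = 600) {
  stopifnot(linear_scale > 0, wobble_amplitude >= 0, span > 0)
  n_basis <- 4L
  coef <- withr::with_seed(as.integer(seed), {
    list(amp = stats::runif(n_basis, -1, 1),
         phase = stats::runif(n_basis, 0, 2 * pi))
  })
  freq <- c(0.5, 1, 1.5, 2.5) / span  # cycles per second, low frequency
  model <- structure(list(linear_scale = linear_scale, curvature = curvature,
                          wobble_amplitude = wobble_amplitude,
                          seed = as.integer(seed), span = span,
                          freq = freq, coef = coef),
                     class = "drift_model")
  grid <- seq(0, span, length.out = 2048L)
  if (any(diff(drift_warp(model, grid)) <= 0))
    stop("drift model is not strictly increasing over the span", call. = FALSE)
  model
}

# the induced map RT -> RT'
drift_warp <- function(model, rt) {
  w <- 0
  norm <- sum(abs(model$coef$amp))
  if (model$wobble_amplitude > 0 && norm > 0)
    for (b in seq_along(model$freq))
      w <- w + model$coef$amp[b] *
        sin(2 * pi * model$freq[b] * rt + model$coef$phase[b])
  if (is.numeric(w) && length(w) && norm > 0)
    w <- w * model$wobble_amplitude / norm
  model$linear_scale * rt + model$curvature * rt^2 / model$span + w
}

#' @export
print.drift_model <- function(x, ...) {
  cat(sprintf("<drift_model> scale %.4f, curvature %.4f, wobble %.2f s (seed %d, span %.0f s)\n",
              x$linear_scale, x$curvature, x$wobble_amplitude, x$seed, x$span))
  invisible(x)
}

#' Apply a drift model to a trajectory
#'
#' @param traj an [rtt_trajectory()].
#' @param model a [drift_model()].
#' @param label label for the drifted trajectory.
#' @return An [rtt_trajectory()] with drifted retention times; an
#'   order-violating model is rejected.
#' @export
apply_drift <- function(traj, model, label = paste0(traj$label, "'")) {
  rts <- drift_warp(model, unname(traj$rts))
  if (any(diff(rts) <= 0) || any(rts <= 0))
    stop("drift model rejected: drifted trajectory violates elution order or positivity",
         call. = FALSE)
  structure(list(label = label, rts = stats::setNames(rts, names(traj$rts)),
                 provenance = traj$provenance),
            class = "rtt_trajectory")
}

#' Simulate a compound roster and its reference trajectory
#'
#' Draws `n_tgt` target retention times over `span` seconds with minimum
#' spacing `min_gap`, then places the `n_std` internal standards at the
#' midpoints of the widest remaining gaps (standards are best placed in
#' low-peak-density sections of the chromatogram).
#'
#' @param n_tgt number of target compounds.
#' @param n_std number of internal standards.
#' @param span chromatogram span, seconds.
#' @param min_gap minimum spacing between adjacent compounds, seconds.
#' @param seed integer seed.
#' @return `list(roster = compound_roster, base = rtt_trajectory)`; `base`
#'   holds the reference retention times of all compounds.
#' @export
simulate_roster <- function(n_tgt = 20, n_std = 2, span = 600, min_gap = 5,
                            seed = 1L) {
  n <- n_tgt + n_std
  if (n * min_gap >= span)
    stop("infeasible spacing: (n_tgt + n_std) * min_gap must be below span",
         call. = FALSE)
  lo <- 0.03 * span; hi <- 0.97 * span
  slack <- (hi - lo) - (n_tgt - 1) * min_gap
  if (slack <= 0) stop("infeasible spacing for the target compounds", call. = FALSE)
  tgt <- withr::with_seed(as.integer(seed),
                          sort(stats::runif(n_tgt, 0, slack))) +
    lo + min_gap * (seq_len(n_tgt) - 1)
  std <- numeric(0)
  if (n_std > 0) {
    gaps_lo <- tgt[-n_tgt]; gaps_hi <- tgt[-1]
    width <- gaps_hi - gaps_lo
    ok <- which(width >= 2 * min_gap)
    if (length(ok) < n_std)
      stop("infeasible spacing: not enough wide gaps for the standards",
           call. = FALSE)
    pick <- ok[order(-width[ok])][seq_len(n_std)]
    std <- (gaps_lo[pick] + gaps_hi[pick]) / 2
  }
  rt <- c(tgt, std)
  role <- c(rep("target", n_tgt), rep("standard", n_std))
  o <- order(rt)
  roster <- compound_roster(role[o])
  list(roster = roster,
       base = rtt_trajectory("base", rt[o], roster))
}

#' Simulate a library of drifted trajectories
#'
#' Applies one [drift_model()] per condition to a reference trajectory.
#'
#' @param base the reference [rtt_trajectory()].
#' @param roster the [compound_roster()].
#' @param conditions data frame with columns `linear_scale`, `curvature`,
#'   `wobble_amplitude`, `seed` (one row per condition), e.g.
#'   [default_drift_conditions()].
#' @param labels condition labels; default `cond_1, ...`.
#' @return An [rtt_library()] of experimental trajectories.
#' @export
simulate_library <- function(base, roster, conditions = default_drift_conditions(),
                             labels = sprintf("cond_%d", seq_len(nrow(conditions)))) {
  span <- max(base$rts) * 1.05
  trajectories <- lapply(seq_len(nrow(conditions)), function(i) {
    mod <- drift_model(conditions$linear_scale[i], conditions$curvature[i],
                       conditions$wobble_amplitude[i],
                       seed = conditions$seed[i], span = span)
    apply_drift(base, mod, label = labels[i])
  })
  rtt_library(roster, trajectories)
}

#' Default library drift conditions
#'
#' Six conditions spanning linear scales 0.98-1.02 with alternating smooth
#' curvature and 1 s wobble: retention-time deviations from a few seconds
#' early in the chromatogram to tens of seconds at the end, mirroring a
#' six-chromatogram characterization run.
#'
#' @param n number of conditions.
#' @param base_seed wobble seeds are `base_seed + 1:n`.
#' @return Data frame of drift parameters.
#' @export
default_drift_conditions <- function(n = 6, base_seed = 100L) {
  curv <- 0.008 * rep_len(c(1, -0.75, 0.375, -0.375, 0.75, -1), n)
  data.frame(linear_scale = seq(0.98, 1.02, length.out = n),
             curvature = curv,
             wobble_amplitude = rep(1, n),
             seed = as.integer(base_seed) + seq_len(n))
}

#' Draw interferent retention times with clearance
#'
#' Uniform over the span, rejecting positions closer than `clearance` to any
#' retention time in `drifted` (targets and standards) or to each other.
#'
#' @param n number of interferents.
#' @param drifted the drifted sample [rtt_trajectory()].
#' @param clearance minimum distance, seconds.
#' @param seed integer seed.
#' @return Numeric retention times.
#' @export
draw_interferent_rts <- function(n, drifted, clearance = 3, seed = 1L) {
  span <- range(drifted$rts)
  withr::with_seed(as.integer(seed), {
    out <- numeric(0)
    tries <- 0L
    while (length(out) < n) {
      tries <- tries + 1L
      if (tries > 10000L) stop("cannot place interferents with the requested clearance",
                               call. = FALSE)
      rt <- stats::runif(1, span[1], span[2])
      if (min(abs(c(drifted$rts, out) - rt)) >= clearance) out <- c(out, rt)
    }
    out
  })
}

#' Simulate a sample peak list with known ground truth
#'
#' Takes the sample condition's trajectory (already drifted, or drifted here
#' via `model`), keeps the chosen subset of targets plus all standards, adds
#' bounded uniform apex jitter, and appends interferent peaks.
#'
#' @param traj the sample condition's [rtt_trajectory()].
#' @param roster the [compound_roster()].
#' @param subset integer vector of target compound ids present in the sample.
#' @param interferent_rts retention times of interferent peaks (on the
#'   drifted time axis); must clear every drifted compound by `clearance`.
#' @param model optional [drift_model()] applied to `traj` first.
#' @param apex_jitter bound (seconds) of the uniform apex measurement noise.
#' @param clearance minimum interferent distance, seconds.
#' @param seed integer seed for the jitter.
#' @return `list(peaks = peak_list, truth = assignment, drifted =
#'   rtt_trajectory)`; `truth` maps each unlabeled peak to its target id or
#'   [INTERFERENT].
#' @export
simulate_sample <- function(traj, roster, subset, interferent_rts = numeric(0),
                            model = NULL, apex_jitter = 0.15, clearance = 3,
                            seed = 1L) {
  assert_roster(roster)
  if (!is.null(model)) traj <- apply_drift(traj, model)
  subset <- sort(as.integer(subset))
  if (length(setdiff(subset, target_ids(roster))))
    stop("subset contains non-target ids", call. = FALSE)
  if (length(interferent_rts) &&
      min(vapply(interferent_rts, function(rt) min(abs(traj$rts - rt)),
                 numeric(1))) < clearance)
    stop(sprintf("interferent closer than %.3g s to a drifted compound", clearance),
         call. = FALSE)
  sids <- standard_ids(roster)
  ids <- c(subset, sids)
  rt <- traj_rt(traj, ids)
  m <- length(rt) + length(interferent_rts)
  jit <- if (apex_jitter > 0)
    withr::with_seed(as.integer(seed), stats::runif(m, -apex_jitter, apex_jitter))
  else rep(0, m)
  rt_all <- c(rt, interferent_rts) + jit
  truth_all <- c(subset, rep(NA_integer_, length(sids)),
                 rep(INTERFERENT, length(interferent_rts)))
  std_all <- c(rep(NA_integer_, length(subset)), sids,
               rep(NA_integer_, length(interferent_rts)))
  o <- order(rt_all)
  peaks <- peak_list(rt_all[o], std_id = std_all[o], roster = roster)
  truth <- truth_all[o][is.na(std_all[o])]
  list(peaks = peaks, truth = validate_assignment(truth, roster),
       drifted = traj)
}

#' Simulate a Gaussian-bump detector trace
#'
#' Writes a sum of Gaussian peaks (apex positions `rts`, common width
#' `sigma`) on a uniform time grid, with optional Gaussian noise — the sole
#' peak-shape facility, provided for exercising the apex detector.
#'
#' @param rts apex retention times, seconds.
#' @param heights peak heights; recycled.
#' @param sigma Gaussian width, seconds.
#' @param span trace end time, seconds.
#' @param dt sampling interval, seconds.
#' @param noise_sd standard deviation of additive noise.
#' @param baseline constant detector offset added to the trace.
#' @param seed integer seed for the noise.
#' @return A [chrom_trace()].
#' @export
simulate_trace <- function(rts, heights = 1, sigma = 2, span = max(rts) + 10 * sigma,
                           dt = 0.2, noise_sd = 0, baseline = 0, seed = 1L) {
  heights <- rep_len(heights, length(rts))
  t <- seq(0, span, by = dt)
  y <- rep(baseline, length(t))
  for (i in seq_along(rts))
    y <- y + heights[i] * exp(-(t - rts[i])^2 / (2 * sigma^2))
  if (noise_sd > 0)
    y <- y + withr::with_seed(as.integer(seed),
                              stats::rnorm(length(t), 0, noise_sd))
  chrom_trace(t, y)
}
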