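#' Flag a peak outside every library retention-time window
#'
#' First interferent criterion: if no retention time value in any library
#' trajectory (targets or standards) lies within `peak_rt ± delta_t`, the
#' peak cannot be a target compound and is an interferent.  The interval is
#' closed: a peak at distance exactly `delta_t` is not flagged.
#'
#' @param peak_rt peak retention time, seconds.
#' @param library an [rtt_library()].
#' @param delta_t cutoff half-window, seconds (> 0).
#' @return Logical.
#' @export
flag_out_of_range <- function(peak_rt, library, delta_t) {
  assert_library(library)
  stopifnot(delta_t > 0)
  all_rt <- unlist(lapply(library$trajectories, `[[`, "rts"), use.names = FALSE)
  vapply(peak_rt, function(rt) min(abs(all_rt - rt)) > delta_t, logical(1))
}

#' Refine a match result by relabeling interferents
#'
#' Second interferent criterion, applied greedily: among the assigned peaks
#' that lie farther than `cfg$min_interferent_distance` from every retention
#' time of the achieving trajectory, the one with the largest squared
#' residual is relabeled [INTERFERENT] if that residual exceeds
#' `cfg$interferent_factor` times the current mean squared residual; the MSR
#' is then recomputed with the residual removed and the denominator reduced
#' (`N_std + N_sample - N_interf`), and the rule repeats.  Each relabeling
#' strictly decreases the MSR, and refining a refined result changes nothing.
#'
#' The distance gate keeps measurement noise on genuine targets from
#' triggering relabeling: a peak sitting on the trajectory is never an
#' interferent, however its residual compares to the mean.  If more than half
#' the unlabeled peaks would be relabeled, refinement stops and the result is
#' demoted with a warning (a sample dominated by interferents is outside the
#' method's stated domain).
#'
#' @param result an `rtt_match` from [match_sample()].
#' @param peaks the [peak_list()] the result was computed from.
#' @param traj the achieving [rtt_trajectory()].
#' @param cfg a [match_config()].
#' @return A refined `rtt_match`.
#' @export
refine_interferents <- function(result, peaks, traj, cfg = match_config()) {
  assert_peaks(peaks)
  a <- result$assignment
  m <- length(a)
  n_std <- nrow(std_peaks(peaks))
  urt <- sample_rt(peaks)
  gate <- vapply(urt, function(rt) min(abs(traj$rts - rt)), numeric(1)) >
    cfg$min_interferent_distance
  demoted <- result$demoted
  repeat {
    rs <- residual_summary(traj, a, peaks)
    cur_msr <- rs$ssr / rs$denom
    cand <- which(a != INTERFERENT & gate &
                    rs$res2 > cfg$interferent_factor * cur_msr)
    if (!length(cand)) break
    worst <- cand[which.max(rs$res2[cand])]
    if (rs$denom - 1L <= 0L) {
      warning("relabeling would leave no residual pairs; keeping assignment",
              call. = FALSE)
      break
    }
    if (sum(a == INTERFERENT) + 1L > floor(m / 2)) {
      warning("more than half the peaks qualify as interferents; result demoted",
              call. = FALSE)
      demoted <- TRUE
      break
    }
    a[worst] <- INTERFERENT
  }
  rs <- residual_summary(traj, a, peaks)
  new_match_result(a, result$lib_label, rs$ssr, rs$ssr / rs$denom,
                   n_interferents(a), result$rank, demoted)
}
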