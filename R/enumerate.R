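#' Size of the unconstrained candidate space
#'
#' With no cutoff window, no standards and no interferents, the admissible
#' assignments of `n_sample` peaks to `n_tgt` target compounds (injective and
#' elution-order preserving) are exactly the `n_sample`-subsets of the
#' targets, so the count is the binomial coefficient `C(n_tgt, n_sample)`.
#'
#' @param n_tgt number of target compounds.
#' @param n_sample number of peaks to identify, `0 <= n_sample <= n_tgt`.
#' @return The binomial coefficient as a double.
#' @examples
#' count_candidates(20, 10)  # 184756
#' @export
count_candidates <- function(n_tgt, n_sample) {
  if (n_sample < 0 || n_tgt < 0 || n_sample > n_tgt)
    stop("need 0 <= n_sample <= n_tgt", call. = FALSE)
  choose(n_tgt, n_sample)
}

# --- admissibility machinery shared by enumeration and matching -------------

#' Partition peaks by the internal-standard anchors
#'
#' Elution order is preserved through the labeled standard peaks, so the
#' trajectory diagram splits into regions: a peak eluting between two labeled
#' standard peaks can only be a compound eluting between those standards
#' (library-side) in every retained trajectory.  Trajectories share the
#' roster's elution order, so the per-trajectory intervals coincide; peaks
#' before the first / after the last standard get open-ended intervals, and
#' with no labeled standards every peak maps to the full target range.
#'
#' @param peaks a [peak_list()].
#' @param library an [rtt_library()] (its retained trajectories).
#' @return Integer matrix with one row per unlabeled peak and columns
#'   `lo`, `hi`: the admissible closed interval of target compound ids
#'   (`lo > hi` denotes an empty interval).
#' @export
partition_by_standards <- function(peaks, library) {
  assert_peaks(peaks); assert_library(library)
  roster <- library$roster
  tid <- target_ids(roster)
  trank <- roster_rank(roster, tid)
  m <- n_sample_peaks(peaks)
  lo <- rep(if (length(tid)) min(tid) else 1L, m)
  hi <- rep(if (length(tid)) max(tid) else 0L, m)
  sp <- std_peaks(peaks)
  if (nrow(sp)) {
    srank <- roster_rank(roster, sp$std_id)
    urt <- sample_rt(peaks)
    for (j in seq_len(m)) {
      before <- srank[sp$rt < urt[j]]
      after  <- srank[sp$rt > urt[j]]
      ok <- trank > (if (length(before)) max(before) else -Inf) &
            trank < (if (length(after)) min(after) else Inf)
      if (any(ok)) {
        lo[j] <- min(tid[ok]); hi[j] <- max(tid[ok])
      } else {
        lo[j] <- 1L; hi[j] <- 0L
      }
    }
  }
  cbind(lo = as.integer(lo), hi = as.integer(hi))
}

# Per-peak admissible target positions, interferent gating, and diagnostics.
# Positions index target_ids(roster); a (peak, compound) pair is admissible
# when ANY retained trajectory has the compound within delta_t of the peak
# and the compound lies in the peak's standard-partition interval.
build_admissibility <- function(peaks, library, cfg) {
  roster <- library$roster
  tid <- target_ids(roster)
  n_tgt <- length(tid)
  rtm <- lib_rt_matrix(library, tid)      # n_tgt x L
  L <- ncol(rtm)
  urt <- sample_rt(peaks)
  m <- length(urt)
  dmin <- matrix(Inf, n_tgt, m)
  for (l in seq_len(L))
    dmin <- pmin(dmin, abs(outer(rtm[, l], urt, "-")))
  # per-trajectory interferent eligibility: peak j may carry a voluntary
  # interferent label in a candidate scored against trajectory l only if it
  # is farther than min_interferent_distance from every value of l
  # (targets and standards)
  int_ok <- matrix(TRUE, max(m, 1L), L)[seq_len(m), , drop = FALSE]
  for (l in seq_len(L)) {
    all_rt <- library$trajectories[[l]]$rts
    for (j in seq_len(m))
      int_ok[j, l] <- min(abs(all_rt - urt[j])) > cfg$min_interferent_distance
  }
  part <- partition_by_standards(peaks, library)
  adm <- vector("list", m)
  dt_empty <- logical(m)
  for (j in seq_len(m)) {
    in_dt <- dmin[, j] <= cfg$delta_t
    dt_empty[j] <- !any(in_dt)
    adm[[j]] <- which(in_dt & tid >= part[j, "lo"] & tid <= part[j, "hi"])
  }
  nearest <- if (m) apply(dmin, 2, min) else numeric(0)
  force_int <- lengths(adm) == 0L
  allow_int <- cfg$allow_interferents &
    (force_int | rowSums(int_ok) > 0)
  list(adm = adm, force_int = force_int, allow_int = allow_int,
       int_ok = int_ok, dt_empty = dt_empty, nearest = nearest,
       n_tgt = n_tgt, tid = tid, rtm = rtm, urt = urt)
}

# diagnostic for an empty candidate stream
empty_stream_diagnostic <- function(ad) {
  if (any(ad$dt_empty))
    sprintf("no candidates: delta_t too small (peak at %.3f s is %.3f s from the nearest library retention time)",
            ad$urt[which(ad$dt_empty)[1]], ad$nearest[which(ad$dt_empty)[1]])
  else
    "no candidates: order conflict between the cutoff window and the standard partition"
}

#' Enumerate admissible candidate assignments
#'
#' Generates every assignment of the unlabeled sample peaks to target
#' compounds satisfying (1) injectivity, (2) strict elution-order
#' preservation, (3) the `delta_t` cutoff window against the retained
#' trajectories, and (4) the internal-standard partition.  When
#' `cfg$allow_interferents`, a peak with no library retention time within
#' `delta_t` (or no admissible compound) must carry the [INTERFERENT] label,
#' and a peak farther than `cfg$min_interferent_distance` from every value of
#' at least one retained trajectory may carry it as an alternative
#' hypothesis.  (During scoring, [match_sample()] additionally requires the
#' achieving trajectory itself to satisfy that distance for every voluntary
#' interferent label.)
#'
#' The walk is depth-first with pruning at every step, so the unconstrained
#' `C(N_tgt, N_sample)` set is never materialized unless it survives the
#' filters and `collect = TRUE`.
#'
#' @param peaks a [peak_list()].
#' @param library an [rtt_library()]; screened per `cfg` before use.
#' @param cfg a [match_config()].
#' @param collect return the assignments (`TRUE`) or only count them.
#' @param max_collect safety cap on the number of collected assignments.
#' @return With `collect = TRUE`, an integer matrix (one row per candidate,
#'   one column per unlabeled peak; entries are target compound ids or
#'   [INTERFERENT]) with attribute `count`; otherwise the count.  An empty
#'   stream carries a `diagnostic` attribute distinguishing a too-small
#'   `delta_t` from an order conflict.
#' @export
enumerate_candidates <- function(peaks, library, cfg = match_config(),
                                 collect = TRUE, max_collect = 1e6) {
  assert_peaks(peaks); assert_library(library)
  m <- n_sample_peaks(peaks)
  n_tgt <- n_targets(library$roster)
  if (!cfg$allow_interferents && m > n_tgt)
    stop(sprintf("%d peaks but only %d target compounds; enable allow_interferents",
                 m, n_tgt), call. = FALSE)
  retained <- screen_libraries(library, peaks, cfg)
  ad <- build_admissibility(peaks, retained, cfg)
  if (any(ad$force_int) && !cfg$allow_interferents) {
    res <- if (collect) matrix(integer(0), 0, m) else 0
    attr(res, "diagnostic") <- empty_stream_diagnostic(ad)
    return(res)
  }
  raw <- .rtt_dfs_enumerate(m, lapply(ad$adm, as.integer),
                            as.logical(ad$allow_int), as.logical(ad$force_int),
                            collect, max_collect)
  if (!collect) {
    res <- raw$count
  } else {
    res <- raw$assign
    pos <- res > 0L
    res[pos] <- ad$tid[res[pos]]   # positions -> compound ids
    attr(res, "count") <- raw$count
  }
  if (raw$count == 0) attr(res, "diagnostic") <- empty_stream_diagnostic(ad)
  res
}
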