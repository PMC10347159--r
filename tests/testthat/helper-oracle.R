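# Brute-force oracles, independent of the package's DFS path.

# all injective, order-preserving assignments of n_sample peaks to the given
# target ids (no interferents): the n_sample-subsets in ascending order
oracle_assignments <- function(tgt_ids, n_sample) {
  if (n_sample == 0L) return(matrix(integer(0), 1, 0))
  t(utils::combn(sort(tgt_ids), n_sample))
}

# exhaustive minimum-MSR match over all assignment x trajectory pairs,
# computed with plain R arithmetic on the displayed formulas
oracle_match <- function(peaks, library) {
  roster <- library$roster
  urt <- peaks$rt[is.na(peaks$std_id)]
  sp <- peaks[!is.na(peaks$std_id), , drop = FALSE]
  cands <- oracle_assignments(roster$id[roster$role == "target"], length(urt))
  best <- NULL
  for (li in seq_along(library$trajectories)) {
    tr <- library$trajectories[[li]]
    sstd <- if (nrow(sp)) sum((tr$rts[as.character(sp$std_id)] - sp$rt)^2) else 0
    for (ci in seq_len(nrow(cands))) {
      a <- cands[ci, ]
      ssr <- sstd + sum((tr$rts[as.character(a)] - urt)^2)
      m <- ssr / (nrow(sp) + length(urt))
      key <- list(msr = m, a = a, lib = li)
      if (is.null(best) || m < best$msr ||
          (m == best$msr && (paste(a, collapse = ",") < paste(best$a, collapse = ",") ||
                             (identical(a, best$a) && li < best$lib))))
        best <- c(key, list(label = tr$label, ssr = ssr))
    }
  }
  best
}

# deterministic tiny world: explicit retention times, no randomness
tiny_roster <- function(n_tgt = 4, std_after = integer(0)) {
  role <- rep("target", n_tgt)
  for (pos in rev(sort(std_after))) role <- append(role, "standard", after = pos)
  compound_roster(role)
}

# library with one trajectory per row of `shift`: base rts plus a per-lib
# constant or vector shift
tiny_library <- function(base_rts, roster, shifts = list(0)) {
  trs <- lapply(seq_along(shifts), function(i)
    rtt_trajectory(sprintf("lib_%d", i), base_rts + shifts[[i]], roster))
  rtt_library(roster, trs)
}

# random small instance for oracle-equivalence checks
random_instance <- function(seed) {
  withr::with_seed(seed, {
    n_tgt <- sample(2:8, 1)
    n_std <- sample(0:2, 1)
    n_sample <- sample(max(0, 1 - n_std):min(5, n_tgt), 1)
    n_lib <- sample(1:5, 1)
    base <- sort(round(runif(n_tgt + n_std, 10, 500), 3))
    while (any(diff(base) < 2)) base <- sort(round(runif(n_tgt + n_std, 10, 500), 3))
    roster <- compound_roster(sample(rep(c("target", "standard"),
                                         c(n_tgt, n_std))))
    trs <- lapply(seq_len(n_lib), function(i)
      rtt_trajectory(sprintf("lib_%d", i),
                     base + runif(1, -3, 3) + cumsum(runif(length(base), 0, 0.4)),
                     roster))
    library <- rtt_library(roster, trs)
    tgt <- roster$id[roster$role == "target"]
    subset <- sort(sample(tgt, n_sample))
    sids <- roster$id[roster$role == "standard"]
    ids <- c(subset, sids)
    rts <- base[match(ids, roster$id)] + rnorm(length(ids), 0, 0.5)
    o <- order(rts)
    ok <- !is.unsorted(rts[o], strictly = TRUE)
    peaks <- if (ok) try(peak_list(rts[o],
                                   std_id = c(rep(NA, n_sample), sids)[o],
                                   roster = roster), silent = TRUE)
             else NULL
    if (is.null(peaks) || inherits(peaks, "try-error")) return(NULL)
    list(peaks = peaks, library = library, truth = subset)
  })
}

# config used for exhaustive comparisons: no screening, no window, no
# interferent hypotheses
exhaustive_config <- function(...)
  match_config(delta_t = Inf, screen_rule = "keep_all",
               allow_interferents = FALSE, ...)
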