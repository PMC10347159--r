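#' Internal-standard sum of squared residuals
#'
#' For a candidate trajectory, the sum over labeled internal standards of the
#' squared difference between the standard's library retention time and its
#' retention time in the sample.  All candidate assignments share the
#' standard coordinates, so this statistic screens trajectories before any
#' target pairing is considered.  Zero when no standards are labeled.
#'
#' @param traj an [rtt_trajectory()].
#' @param peaks a [peak_list()] with labeled standard peaks.
#' @return Squared seconds.
#' @export
ssr_std <- function(traj, peaks) {
  assert_peaks(peaks)
  sp <- std_peaks(peaks)
  if (!nrow(sp)) return(0)
  lib <- traj_rt(traj, sp$std_id)
  if (anyNA(lib))
    stop(sprintf("trajectory '%s' lacks standard(s): %s", traj$label,
                 paste(sp$std_id[is.na(lib)], collapse = ", ")), call. = FALSE)
  sum((lib - sp$rt)^2)
}

#' Screen library trajectories by internal-standard residuals
#'
#' Trajectories are sorted by ascending [ssr_std()] (ties broken by library
#' order) and truncated per the screening rule; at least
#' `min(n_lib, screen_floor)` are always retained.  With no labeled
#' standards, screening is vacuous and the library is returned in input
#' order.
#'
#' @param library an [rtt_library()].
#' @param peaks a [peak_list()].
#' @param cfg a [match_config()].
#' @return An [rtt_library()] of the retained trajectories (attribute
#'   `ssr_std` holds their screening statistic).
#' @export
screen_libraries <- function(library, peaks, cfg = match_config()) {
  assert_library(library); assert_peaks(peaks)
  n <- n_trajectories(library)
  if (!nrow(std_peaks(peaks))) {
    out <- library
    attr(out, "ssr_std") <- rep(0, n)
    return(out)
  }
  s <- vapply(library$trajectories, ssr_std, numeric(1), peaks = peaks)
  o <- order(s)  # stable: ties keep library (label) order
  keep <- switch(cfg$screen_rule,
                 keep_all = n,
                 keep_fraction = ceiling(cfg$screen_value * n),
                 keep_top_k = min(as.integer(cfg$screen_value), n))
  keep <- max(keep, min(n, cfg$screen_floor))
  o <- o[seq_len(keep)]
  out <- rtt_library(library$roster, library$trajectories[o])
  attr(out, "ssr_std") <- s[o]
  out
}

# SSR/MSR bookkeeping for one (trajectory, assignment) pair
residual_summary <- function(traj, assignment, peaks) {
  m <- n_sample_peaks(peaks)
  if (length(assignment) != m)
    stop("assignment length must equal the number of unlabeled peaks", call. = FALSE)
  urt <- sample_rt(peaks)
  assigned <- assignment != INTERFERENT
  res2 <- rep(NA_real_, m)
  if (any(assigned)) {
    lib <- traj_rt(traj, assignment[assigned])
    if (anyNA(lib))
      stop(sprintf("trajectory '%s' lacks assigned compound(s)", traj$label),
           call. = FALSE)
    res2[assigned] <- (lib - urt[assigned])^2
  }
  n_std <- nrow(std_peaks(peaks))
  denom <- n_std + m - sum(!assigned)
  list(ssr = ssr_std(traj, peaks) + sum(res2[assigned]),
       res2 = res2, denom = denom)
}

#' Mean squared residual of an assignment against a trajectory
#'
#' `(SSR_std + sum of squared target residuals) / (N_std + N_sample -
#' N_interf)`.  Interferent-labeled peaks contribute no residual and are
#' excluded from the normalization, so results with and without interferents
#' are comparable on one scale.
#'
#' @param traj an [rtt_trajectory()].
#' @param assignment integer vector per unlabeled peak: target compound id or
#'   [INTERFERENT].
#' @param peaks a [peak_list()].
#' @return Squared seconds.
#' @export
msr <- function(traj, assignment, peaks) {
  assert_peaks(peaks)
  rs <- residual_summary(traj, assignment, peaks)
  if (rs$denom <= 0)
    stop("vacuous assignment: no standards and all peaks interferent", call. = FALSE)
  rs$ssr / rs$denom
}

new_match_result <- function(assignment, lib_label, ssr, msr, n_interf,
                             rank = NA_integer_, demoted = FALSE) {
  structure(list(assignment = as.integer(assignment), lib_label = lib_label,
                 ssr = ssr, msr = msr, n_interf = as.integer(n_interf),
                 rank = as.integer(rank), demoted = isTRUE(demoted)),
            class = "rtt_match")
}

#' @export
print.rtt_match <- function(x, ...) {
  cat(sprintf("<rtt_match> rank %s  MSR %.4g s^2  lib '%s'%s\n  peaks: %s\n",
              ifelse(is.na(x$rank), "?", x$rank), x$msr, x$lib_label,
              if (x$demoted) "  [demoted]" else "",
              format_assignment(x$assignment)))
  invisible(x)
}

# ordering key shared by ranking and refinement re-ranking
order_results <- function(results) {
  if (!length(results)) return(integer(0))
  key <- vapply(results, function(r)
    paste(sprintf("%025.12f", r$msr), sprintf("%06d", r$n_interf),
          paste(sprintf("%06d", r$assignment), collapse = ""), r$lib_label),
    character(1))
  demoted <- vapply(results, `[[`, logical(1), "demoted")
  order(demoted, key)
}

#' Match a sample peak list against a trajectory library
#'
#' The identification procedure: screen trajectories by internal-standard
#' residuals, enumerate admissible candidate assignments depth-first, score
#' every candidate by its minimal [msr()] over the retained trajectories
#' (branch-and-bound pruned, which preserves exactness since residuals are
#' non-negative), and rank ascending.  The rank-1 result is the
#' identification.  When interferents are allowed, each reported result is
#' additionally refined with [refine_interferents()] and the list re-ranked,
#' so results with and without interferent labels compete on one MSR scale.
#'
#' @param peaks a [peak_list()].
#' @param library an [rtt_library()].
#' @param cfg a [match_config()].
#' @return An `rtt_matches` list of ranked match results, with attributes
#'   `n_candidates`, `retained` (screened trajectory labels) and, when empty,
#'   `diagnostic`.
#' @export
match_sample <- function(peaks, library, cfg = match_config()) {
  assert_peaks(peaks); assert_library(library)
  m <- n_sample_peaks(peaks)
  n_tgt <- n_targets(library$roster)
  if (!cfg$allow_interferents && m > n_tgt)
    stop(sprintf("%d peaks but only %d target compounds; enable allow_interferents",
                 m, n_tgt), call. = FALSE)
  retained <- screen_libraries(library, peaks, cfg)
  ad <- build_admissibility(peaks, retained, cfg)
  empty <- function() {
    structure(list(), n_candidates = 0, retained = lib_labels(retained),
              diagnostic = empty_stream_diagnostic(ad), class = "rtt_matches")
  }
  if (any(ad$force_int) && !cfg$allow_interferents) return(empty())
  sstd <- vapply(retained$trajectories, ssr_std, numeric(1), peaks = peaks)
  raw <- .rtt_dfs_match(ad$urt, lapply(ad$adm, as.integer),
                        as.logical(ad$allow_int), as.logical(ad$force_int),
                        ad$int_ok, ad$rtm, sstd, nrow(std_peaks(peaks)),
                        as.integer(cfg$max_results))
  k <- length(raw$lib)
  if (k == 0L) return(empty())
  results <- lapply(seq_len(k), function(i) {
    a <- raw$assign[i, ]
    pos <- a > 0L
    a[pos] <- ad$tid[a[pos]]
    # a labeling dominated by interferents is outside the method's domain:
    # rank it after all majority-target results
    new_match_result(a, lib_labels(retained)[raw$lib[i]],
                     raw$ssr[i], raw$msr[i], raw$n_interf[i],
                     demoted = raw$n_interf[i] > floor(m / 2))
  })
  if (cfg$allow_interferents) {
    results <- lapply(results, function(r) {
      tr <- retained$trajectories[[match(r$lib_label, lib_labels(retained))]]
      refine_interferents(r, peaks, tr, cfg)
    })
    # refinement can collapse distinct raw candidates onto one labeling
    sig <- vapply(results, function(r)
      paste(r$lib_label, paste(r$assignment, collapse = ",")), character(1))
    results <- results[!duplicated(sig)]
  }
  results <- results[order_results(results)]
  for (i in seq_along(results)) results[[i]]$rank <- i
  structure(results, n_candidates = raw$n_candidates,
            retained = lib_labels(retained), class = "rtt_matches")
}

#' @export
print.rtt_matches <- function(x, ...) {
  cat(sprintf("<rtt_matches> %d result(s) from %s candidate assignment(s)\n",
              length(x), format(attr(x, "n_candidates"), big.mark = ",")))
  if (!length(x) && !is.null(attr(x, "diagnostic")))
    cat(" ", attr(x, "diagnostic"), "\n")
  for (r in x)
    cat(sprintf("  %2d  MSR %8.4g  %-12s  %s\n", r$rank, r$msr, r$lib_label,
                format_assignment(r$assignment)))
  invisible(x)
}

#' Write ranked match results as delimited text
#'
#' Columns: rank, msr, ssr, n_interf, lib_label, identification (space
#' separated compound ids, `INTERFERENT` for flagged peaks).
#'
#' @param results an `rtt_matches` object from [match_sample()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_match_report <- function(results, path) {
  df <- data.frame(
    rank = vapply(results, `[[`, integer(1), "rank"),
    msr = vapply(results, `[[`, numeric(1), "msr"),
    ssr = vapply(results, `[[`, numeric(1), "ssr"),
    n_interf = vapply(results, `[[`, integer(1), "n_interf"),
    lib_label = vapply(results, `[[`, character(1), "lib_label"),
    identification = vapply(results, function(r) format_assignment(r$assignment),
                            character(1)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
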