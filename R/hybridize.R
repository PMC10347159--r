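#' Hybridize retention time trajectories
#'
#' Builds a new trajectory as a per-compound linear combination of two or
#' three parent trajectories.  Retention-time drift between nearby
#' experimental conditions is locally linear per compound, so coefficient
#' sets summing to one interpolate (or extrapolate) plausible intermediate
#' conditions without new measurements.
#'
#' @param parents list of 2 or 3 [rtt_trajectory()] objects sharing a roster.
#' @param coeffs numeric coefficients, one per parent.  Must sum to 1 (the
#'   scale-preserving affine family) unless `enforce_affine = FALSE`.
#' @param label optional label; defaults to a deterministic
#'   `hyb(<coef>*<parent>...)` string.
#' @param enforce_affine require `sum(coeffs) == 1`.
#' @return An [rtt_trajectory()] with hybridized provenance.  A combination
#'   violating elution order or positivity is rejected with a diagnostic
#'   naming the first offending compound pair.
#' @export
hybridize <- function(parents, coeffs, label = NULL, enforce_affine = TRUE) {
  if (inherits(parents, "rtt_trajectory")) parents <- list(parents)
  if (!length(parents) %in% c(2L, 3L))
    stop("hybridization takes 2 or 3 parent trajectories", call. = FALSE)
  if (length(coeffs) != length(parents))
    stop("need one coefficient per parent", call. = FALSE)
  nm <- names(parents[[1]]$rts)
  for (p in parents[-1])
    if (!identical(names(p$rts), nm))
      stop("parent trajectories must share a roster", call. = FALSE)
  if (enforce_affine && abs(sum(coeffs) - 1) > 1e-8)
    stop(sprintf("coefficients sum to %.6g, not 1; set enforce_affine = FALSE to override",
                 sum(coeffs)), call. = FALSE)
  rts <- Reduce(`+`, Map(function(p, c) c * p$rts, parents, coeffs))
  plabs <- vapply(parents, `[[`, character(1), "label")
  if (is.null(label))
    label <- sprintf("hyb(%s)",
                     paste(sprintf("%+g*%s", coeffs, plabs), collapse = ""))
  if (any(rts <= 0))
    stop(sprintf("hybrid '%s' has non-positive retention time for compound %s",
                 label, nm[which(rts <= 0)[1]]), call. = FALSE)
  bad <- which(diff(rts) <= 0)
  if (length(bad))
    stop(sprintf("hybrid '%s' violates elution order between compounds %s and %s",
                 label, nm[bad[1]], nm[bad[1] + 1L]), call. = FALSE)
  structure(list(label = label, rts = rts,
                 provenance = list(kind = "hybridized", parents = plabs,
                                   coefficients = as.numeric(coeffs))),
            class = "rtt_trajectory")
}

#' Standard two-trajectory hybridization formulas
#'
#' `mid` is the midpoint `(a + b) / 2`; `extrap_ab` and `extrap_ba` are the
#' symmetric extrapolations `2a - b` and `2b - a`.
#' @return Named list of coefficient pairs.
#' @export
hybridization_formulas <- function() {
  list(mid = c(0.5, 0.5), extrap_ab = c(2, -1), extrap_ba = c(-1, 2))
}

#' Expand a library by pairwise hybridization
#'
#' Applies each coefficient formula to every unordered pair of
#' *experimental* trajectories (hybrids are never re-hybridized, which keeps
#' the expansion idempotent and bounded).  Hybrids violating elution order or
#' positivity are skipped and counted; hybrids identical to an existing
#' trajectory within `dedup_tol` per compound are dropped.
#'
#' @param library an [rtt_library()] with at least 2 experimental
#'   trajectories.
#' @param formulas named list of 2-coefficient vectors; defaults to
#'   [hybridization_formulas()].
#' @param dedup_tol per-compound tolerance (seconds) for deduplication.
#' @return The expanded [rtt_library()], with attributes `n_added`,
#'   `n_skipped_invalid`, `n_skipped_duplicate`.
#' @export
expand_library <- function(library, formulas = hybridization_formulas(),
                           dedup_tol = 0.05) {
  assert_library(library)
  exp_idx <- which(vapply(library$trajectories, is_experimental, logical(1)))
  if (length(exp_idx) < 2L)
    stop("library expansion needs at least 2 experimental trajectories",
         call. = FALSE)
  trajectories <- library$trajectories
  existing <- function(tr)
    any(vapply(trajectories, function(x) max(abs(x$rts - tr$rts)) < dedup_tol,
               logical(1)))
  n_added <- n_invalid <- n_dup <- 0L
  for (i in seq_along(exp_idx)) for (j in seq_along(exp_idx)) {
    if (j <= i) next
    pair <- trajectories[c(exp_idx[i], exp_idx[j])]
    for (f in names(formulas)) {
      hyb <- tryCatch(hybridize(pair, formulas[[f]]), error = function(e) NULL)
      if (is.null(hyb)) { n_invalid <- n_invalid + 1L; next }
      if (existing(hyb)) { n_dup <- n_dup + 1L; next }
      trajectories <- c(trajectories, list(hyb))
      n_added <- n_added + 1L
    }
  }
  out <- rtt_library(library$roster, trajectories)
  attr(out, "n_added") <- n_added
  attr(out, "n_skipped_invalid") <- n_invalid
  attr(out, "n_skipped_duplicate") <- n_dup
  out
}
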