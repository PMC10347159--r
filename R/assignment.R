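#' Interferent sentinel
#'
#' Assignment vectors map each unlabeled sample peak either to a target
#' compound id or to `INTERFERENT` (`0L`), meaning the peak belongs to no
#' target compound.
#' @export
INTERFERENT <- 0L

#' Validate a peak-to-compound assignment
#'
#' An admissible assignment is injective over compound ids (one target
#' compound maps to at most one peak) and elution-order preserving (assigned
#' ids strictly increase with peak retention time).  Interferent-labeled
#' peaks carry the sentinel [INTERFERENT] and are exempt from both rules.
#'
#' @param assignment integer vector, one entry per unlabeled peak in
#'   retention-time order: a target compound id or [INTERFERENT].
#' @param roster the [compound_roster()].
#' @return `assignment`, invisibly; errors describe the violated rule.
#' @export
validate_assignment <- function(assignment, roster) {
  assert_roster(roster)
  a <- as.integer(assignment)
  if (anyNA(a)) stop("assignment contains NA", call. = FALSE)
  assigned <- a[a != INTERFERENT]
  bad <- setdiff(assigned, target_ids(roster))
  if (length(bad))
    stop(sprintf("assignment references non-target compound id(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  if (anyDuplicated(assigned))
    stop("assignment maps one compound to several peaks", call. = FALSE)
  if (length(assigned) > 1L && is.unsorted(assigned, strictly = TRUE))
    stop("assignment violates elution-order preservation", call. = FALSE)
  invisible(a)
}

n_interferents <- function(assignment) sum(assignment == INTERFERENT)

format_assignment <- function(assignment) {
  s <- as.character(assignment)
  s[assignment == INTERFERENT] <- "INTERFERENT"
  paste(s, collapse = " ")
}

#' Matching configuration
#'
#' @param delta_t retention-time cutoff half-window in seconds: a peak may be
#'   paired with a compound only if some retained library trajectory places
#'   the compound within `delta_t` of the peak.  Choose it larger than the
#'   typical drift range of the library; default 30 s.
#' @param screen_rule library screening rule applied to the
#'   internal-standard residuals (`SSR_std`): `"keep_all"`,
#'   `"keep_fraction"` or `"keep_top_k"`.
#' @param screen_value fraction in (0, 1] or top-k count for the respective
#'   rule; the conventional choices are 0.5 and 20.
#' @param screen_floor retain at least `min(n_lib, screen_floor)`
#'   trajectories regardless of the rule (default 20), so small libraries are
#'   never over-pruned.
#' @param allow_interferents whether peaks may be labeled [INTERFERENT].
#' @param interferent_factor a peak's squared residual must exceed
#'   `interferent_factor` times the current mean squared residual to be
#'   relabeled an interferent (default 2).
#' @param min_interferent_distance a peak can carry a voluntary [INTERFERENT]
#'   label against a trajectory — during candidate scoring or residual-based
#'   relabeling — only when it lies farther than this distance (seconds) from
#'   every retention time of that trajectory (default 1.5 s, the scale of
#'   within-envelope drift mismatch): a peak sitting on the trajectory cannot
#'   be an interferent there, no matter how its residual compares to the
#'   mean.  Peaks with no library value within `delta_t` (or no admissible
#'   compound at all) are forced interferents and exempt.
#' @param max_results number of ranked identification results to return
#'   (default 4).
#' @return A `match_config` list.
#' @export
match_config <- function(delta_t = 30,
                         screen_rule = c("keep_fraction", "keep_all", "keep_top_k"),
                         screen_value = 0.5,
                         screen_floor = 20L,
                         allow_interferents = TRUE,
                         interferent_factor = 2,
                         min_interferent_distance = 1.5,
                         max_results = 4L) {
  screen_rule <- match.arg(screen_rule)
  stopifnot(is.numeric(delta_t), length(delta_t) == 1L, delta_t > 0)
  if (screen_rule == "keep_fraction" &&
      (screen_value <= 0 || screen_value > 1))
    stop("keep_fraction requires screen_value in (0, 1]", call. = FALSE)
  if (screen_rule == "keep_top_k" && screen_value < 1)
    stop("keep_top_k requires screen_value >= 1", call. = FALSE)
  if (interferent_factor <= 1)
    stop("interferent_factor must exceed 1", call. = FALSE)
  if (max_results < 1) stop("max_results must be positive", call. = FALSE)
  structure(list(delta_t = delta_t,
                 screen_rule = screen_rule,
                 screen_value = screen_value,
                 screen_floor = as.integer(screen_floor),
                 allow_interferents = isTRUE(allow_interferents),
                 interferent_factor = interferent_factor,
                 min_interferent_distance = min_interferent_distance,
                 max_results = as.integer(max_results)),
            class = "match_config")
}

#' @export
print.match_config <- function(x, ...) {
  cat("<match_config>\n")
  for (nm in names(x)) cat(sprintf("  %s: %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read/write a matching configuration (JSON)
#'
#' @param path file path.
#' @return `read_config` returns a [match_config()]; `write_config` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(match_config, vals[names(vals) %in% names(formals(match_config))])
}

#' @rdname read_config
#' @param cfg a [match_config()].
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
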