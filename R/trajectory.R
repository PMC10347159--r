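#' A single retention time trajectory
#'
#' One trajectory records, for every roster compound, its peak-apex retention
#' time (seconds) in a chromatogram obtained under one experimental condition.
#' Pairing these values against the reference chromatogram's retention times
#' forms the 2D trajectory that uniquely characterizes the condition; since
#' the reference axis is fixed by the roster, storing the per-compound times
#' is sufficient.
#'
#' @param label condition identifier (unique within a library).
#' @param rts numeric retention times in seconds, one per roster compound, in
#'   roster (elution) order, or named by compound id.
#' @param roster the [compound_roster()] the trajectory covers.
#' @param provenance either `"experimental"` or a list
#'   `list(kind = "hybridized", parents = <labels>, coefficients = <numeric>)`.
#' @return An `rtt_trajectory` object.
#' @export
rtt_trajectory <- function(label, rts, roster, provenance = "experimental") {
  assert_roster(roster)
  label <- as.character(label)
  if (length(label) != 1L || is.na(label) || !nzchar(label))
    stop("trajectory label must be a non-empty string", call. = FALSE)
  rts <- unlist(rts)
  if (!is.null(names(rts))) {
    idx <- match(as.character(roster$id), names(rts))
    if (anyNA(idx))
      stop(sprintf("trajectory '%s' is missing compound(s): %s", label,
                   paste(roster$id[is.na(idx)], collapse = ", ")),
           call. = FALSE)
    rts <- as.numeric(rts[idx])
  }
  if (length(rts) != nrow(roster))
    stop(sprintf("trajectory '%s' must have one retention time per roster compound",
                 label), call. = FALSE)
  if (anyNA(rts) || any(rts <= 0))
    stop(sprintf("trajectory '%s' has missing or non-positive retention times",
                 label), call. = FALSE)
  bad <- which(diff(rts) <= 0)
  if (length(bad))
    stop(sprintf(
      "trajectory '%s' violates elution order: compound %d (%.4f s) does not elute before compound %d (%.4f s)",
      label, roster$id[bad[1]], rts[bad[1]], roster$id[bad[1] + 1L], rts[bad[1] + 1L]),
      call. = FALSE)
  if (is.character(provenance))
    provenance <- list(kind = match.arg(provenance, "experimental"))
  if (!is.list(provenance) || is.null(provenance$kind) ||
      !provenance$kind %in% c("experimental", "hybridized"))
    stop("provenance must be 'experimental' or a hybridized() record", call. = FALSE)
  if (provenance$kind == "hybridized" &&
      (is.null(provenance$parents) || is.null(provenance$coefficients) ||
       length(provenance$parents) != length(provenance$coefficients)))
    stop("hybridized provenance needs matching parents and coefficients",
         call. = FALSE)
  names(rts) <- as.character(roster$id)
  structure(list(label = label, rts = rts, provenance = provenance),
            class = "rtt_trajectory")
}

#' @export
print.rtt_trajectory <- function(x, ...) {
  cat(sprintf("<rtt_trajectory> '%s' (%s), %d compounds, RT %.1f-%.1f s\n",
              x$label, x$provenance$kind, length(x$rts),
              min(x$rts), max(x$rts)))
  invisible(x)
}

is_experimental <- function(traj) identical(traj$provenance$kind, "experimental")

# retention times of a trajectory for a set of compound ids
traj_rt <- function(traj, ids) unname(traj$rts[as.character(ids)])

#' A library of retention time trajectories
#'
#' @param roster the shared [compound_roster()].
#' @param trajectories list of [rtt_trajectory()] objects with unique labels.
#' @return An `rtt_library` object.
#' @export
rtt_library <- function(roster, trajectories) {
  assert_roster(roster)
  if (inherits(trajectories, "rtt_trajectory")) trajectories <- list(trajectories)
  if (!length(trajectories))
    stop("a trajectory library must contain at least one trajectory", call. = FALSE)
  ok <- vapply(trajectories, inherits, logical(1), "rtt_trajectory")
  if (!all(ok)) stop("all library entries must be rtt_trajectory objects", call. = FALSE)
  for (tr in trajectories)
    if (length(tr$rts) != nrow(roster) ||
        !identical(names(tr$rts), as.character(roster$id)))
      stop(sprintf("trajectory '%s' does not cover the shared roster", tr$label),
           call. = FALSE)
  labels <- vapply(trajectories, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    stop("trajectory labels must be unique", call. = FALSE)
  structure(list(roster = roster, trajectories = trajectories),
            class = "rtt_library")
}

#' @export
print.rtt_library <- function(x, ...) {
  kinds <- vapply(x$trajectories, function(t) t$provenance$kind, character(1))
  cat(sprintf("<rtt_library> %d trajectories (%d experimental, %d hybridized), %d targets + %d standards\n",
              length(x$trajectories), sum(kinds == "experimental"),
              sum(kinds == "hybridized"),
              n_targets(x$roster), n_standards(x$roster)))
  invisible(x)
}

n_trajectories <- function(library) length(library$trajectories)
lib_labels <- function(library)
  vapply(library$trajectories, `[[`, character(1), "label")

assert_library <- function(library) {
  if (!inherits(library, "rtt_library"))
    stop("expected an 'rtt_library'", call. = FALSE)
  invisible(library)
}

# matrix of retention times, compounds (given ids) x trajectories
lib_rt_matrix <- function(library, ids) {
  vapply(library$trajectories, traj_rt, numeric(length(ids)), ids = ids)
}

#' Read a trajectory library from a JSON file
#'
#' The on-disk document has a roster block and one block per condition
#' (label, provenance, compound id -> retention time map), as written by
#' [write_library()].
#'
#' @param path file path.
#' @return An [rtt_library()].
#' @export
read_library <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$format, "rtt-library"))
    stop(sprintf("'%s' is not an rtt-library file", path), call. = FALSE)
  pick <- function(rows, field, cast)
    cast(sapply(rows, function(r) if (is.null(r[[field]])) NA else r[[field]]))
  roster <- compound_roster(pick(doc$roster, "role", as.character),
                            id = pick(doc$roster, "id", as.integer),
                            name = pick(doc$roster, "name", as.character))
  trajectories <- lapply(doc$trajectories, function(b) {
    prov <- b$provenance
    prov$kind <- as.character(prov$kind)
    if (!is.null(prov$coefficients))
      prov$coefficients <- as.numeric(unlist(prov$coefficients))
    if (!is.null(prov$parents))
      prov$parents <- as.character(unlist(prov$parents))
    rts <- vapply(b$rts, as.numeric, numeric(1))
    rtt_trajectory(as.character(b$label), rts, roster, provenance = prov)
  })
  rtt_library(roster, unname(trajectories))
}

#' Write a trajectory library to a JSON file
#'
#' Deterministic field order; inverse of [read_library()].  Hybridized
#' provenance (parents and coefficients) round-trips.
#'
#' @param library an [rtt_library()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_library <- function(library, path) {
  assert_library(library)
  doc <- list(
    format = "rtt-library",
    version = 1L,
    roster = as.data.frame(library$roster),
    trajectories = lapply(library$trajectories, function(tr) {
      list(label = tr$label,
           provenance = tr$provenance,
           rts = as.list(tr$rts))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
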