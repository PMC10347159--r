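#' Compound roster
#'
#' A roster lists the compounds of a targeted analysis in the elution order of
#' the reference chromatogram.  Each compound is either a `target` (a member of
#' the predefined list the analysis aims to detect) or a `standard` (an
#' internal standard spiked into every sample to anchor trajectories).
#'
#' Target ids must be strictly increasing along the elution order, so that
#' "assigned ids increase with retention time" is exactly elution-order
#' preservation.  Standard ids only need to be unique.
#'
#' @param role character vector, one of `"target"`/`"standard"` per compound,
#'   in elution order of the reference chromatogram.
#' @param id optional integer ids.  Defaults to numbering the targets
#'   `1..N_tgt` in elution order and the standards `N_tgt+1, ...` in elution
#'   order.
#' @param name optional character names.
#' @return A `compound_roster`: a data frame with columns `id`, `role`,
#'   `name`, one row per compound in elution order, and attributes `n_tgt`,
#'   `n_std`.
#' @examples
#' compound_roster(c("target", "target", "standard", "target"))
#' @export
compound_roster <- function(role, id = NULL, name = NULL) {
  role <- as.character(role)
  if (!length(role) || !all(role %in% c("target", "standard")))
    stop("roles must be 'target' or 'standard'", call. = FALSE)
  n_tgt <- sum(role == "target")
  n_std <- sum(role == "standard")
  if (n_tgt < 1L) stop("roster needs at least one target compound", call. = FALSE)
  if (is.null(id)) {
    id <- integer(length(role))
    id[role == "target"] <- seq_len(n_tgt)
    id[role == "standard"] <- n_tgt + seq_len(n_std)
  }
  id <- as.integer(id)
  if (length(id) != length(role) || anyNA(id))
    stop("ids must be integers, one per compound", call. = FALSE)
  if (anyDuplicated(id)) stop("compound ids must be unique", call. = FALSE)
  tgt_id <- id[role == "target"]
  if (is.unsorted(tgt_id, strictly = TRUE))
    stop("target ids must be strictly increasing in elution order", call. = FALSE)
  if (is.null(name)) name <- NA_character_
  out <- data.frame(id = id, role = role, name = as.character(name),
                    stringsAsFactors = FALSE)
  structure(out, n_tgt = n_tgt, n_std = n_std,
            class = c("compound_roster", "data.frame"))
}

#' @export
print.compound_roster <- function(x, ...) {
  cat(sprintf("<compound_roster> %d targets, %d standards\n",
              attr(x, "n_tgt"), attr(x, "n_std")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

n_targets   <- function(roster) attr(roster, "n_tgt")
n_standards <- function(roster) attr(roster, "n_std")
target_ids   <- function(roster) roster$id[roster$role == "target"]
standard_ids <- function(roster) roster$id[roster$role == "standard"]

# elution rank (row position) of a compound id within the roster
roster_rank <- function(roster, ids) match(ids, roster$id)

assert_roster <- function(roster) {
  if (!inherits(roster, "compound_roster"))
    stop("expected a 'compound_roster'", call. = FALSE)
  invisible(roster)
}

#' Read a compound roster from a CSV file
#'
#' Expected columns: `id`, `role` and optionally `name`; rows in elution
#' order.
#'
#' @param path file path.
#' @return A [compound_roster()].
#' @export
read_roster <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "role")
  if (!all(need %in% names(df)))
    stop(sprintf("roster file '%s' must have columns id, role", path),
         call. = FALSE)
  compound_roster(df$role, id = df$id,
                  name = if ("name" %in% names(df)) df$name else NULL)
}

#' Write a compound roster to a CSV file
#'
#' @param roster a [compound_roster()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_roster <- function(roster, path) {
  assert_roster(roster)
  utils::write.csv(as.data.frame(roster), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
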