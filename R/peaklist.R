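#' Sample peak list
#'
#' The detected peak apex retention times of one chromatogram, sorted by
#' retention time.  Peaks corresponding to internal standards are labeled
#' with their standard compound id (standards are recognized upstream, during
#' preprocessing); the remaining `N_sample` unlabeled peaks are the peaks to
#' be identified.
#'
#' @param rt numeric retention times in seconds.
#' @param height optional non-negative peak heights (arbitrary units).
#' @param std_id optional integer vector, `NA` for unlabeled peaks, or the id
#'   of the internal standard the peak corresponds to.
#' @param roster optional [compound_roster()]; when supplied, standard labels
#'   are checked against it (unknown ids are an error) and the labeled
#'   standard peaks must elute in the standards' roster order.
#' @return A `peak_list`: data frame with columns `rt`, `height`, `std_id`,
#'   attribute `n_sample` (number of unlabeled peaks).
#' @export
peak_list <- function(rt, height = NULL, std_id = NULL, roster = NULL) {
  rt <- as.numeric(rt)
  if (anyNA(rt) || any(rt <= 0))
    stop("peak retention times must be positive numbers", call. = FALSE)
  n <- length(rt)
  if (is.null(height)) height <- rep(NA_real_, n)
  if (is.null(std_id)) std_id <- rep(NA_integer_, n)
  height <- as.numeric(height); std_id <- as.integer(std_id)
  if (length(height) != n || length(std_id) != n)
    stop("rt, height and std_id must have equal length", call. = FALSE)
  if (any(!is.na(height) & height < 0))
    stop("peak heights must be non-negative", call. = FALSE)
  o <- order(rt)
  rt <- rt[o]; height <- height[o]; std_id <- std_id[o]
  if (any(diff(rt) < 1e-9))
    stop(sprintf("duplicate retention times at %.4f s; collapse peaks upstream",
                 rt[which(diff(rt) < 1e-9)[1]]), call. = FALSE)
  lab <- std_id[!is.na(std_id)]
  if (anyDuplicated(lab))
    stop("each internal standard may label at most one peak", call. = FALSE)
  if (!is.null(roster)) {
    assert_roster(roster)
    bad <- setdiff(lab, standard_ids(roster))
    if (length(bad))
      stop(sprintf("unknown internal standard id(s): %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    # labeled standards must appear in their roster elution order
    if (length(lab) > 1L && is.unsorted(roster_rank(roster, lab), strictly = TRUE))
      stop("labeled standard peaks contradict the roster's elution order",
           call. = FALSE)
  }
  structure(data.frame(rt = rt, height = height, std_id = std_id),
            n_sample = sum(is.na(std_id)),
            class = c("peak_list", "data.frame"))
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("<peak_list> %d peaks (%d to identify, %d standard-labeled)\n",
              nrow(x), attr(x, "n_sample"), sum(!is.na(x$std_id))))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

n_sample_peaks <- function(peaks) attr(peaks, "n_sample")
sample_rt <- function(peaks) peaks$rt[is.na(peaks$std_id)]
std_peaks <- function(peaks) peaks[!is.na(peaks$std_id), , drop = FALSE]

assert_peaks <- function(peaks) {
  if (!inherits(peaks, "peak_list")) stop("expected a 'peak_list'", call. = FALSE)
  invisible(peaks)
}

#' Read a peak list from a delimited text file
#'
#' Expected CSV columns: `rt_seconds`, optionally `height` and `standard_id`
#' (empty for unlabeled peaks).
#'
#' @param path file path.
#' @param roster a [compound_roster()] used to resolve standard labels.
#' @return A [peak_list()] sorted by retention time.
#' @export
read_peak_list <- function(path, roster = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"rt_seconds" %in% names(df))
    stop(sprintf("peak list '%s' must have an rt_seconds column", path),
         call. = FALSE)
  rt <- suppressWarnings(as.numeric(df$rt_seconds))
  if (anyNA(rt))
    stop(sprintf("peak list '%s' has unparseable retention times", path),
         call. = FALSE)
  peak_list(rt,
            height = if ("height" %in% names(df)) df$height else NULL,
            std_id = if ("standard_id" %in% names(df))
              suppressWarnings(as.integer(df$standard_id)) else NULL,
            roster = roster)
}

#' Write a peak list to a delimited text file
#'
#' @param peaks a [peak_list()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_peak_list <- function(peaks, path) {
  assert_peaks(peaks)
  df <- data.frame(rt_seconds = peaks$rt, height = peaks$height,
                   standard_id = peaks$std_id)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Label internal-standard peaks automatically
#'
#' Fallback for inputs whose preprocessing did not label the standards: each
#' roster standard is attached to the nearest peak within `delta_t` of its
#' retention time in `reference`.  Ambiguity (two standards competing for one
#' peak, or no peak in range) is an error; labeling is a preprocessing
#' convention, not part of the matching statistics.
#'
#' @param peaks a [peak_list()] without standard labels.
#' @param reference an [rtt_trajectory()] giving nominal standard retention
#'   times.
#' @param roster the [compound_roster()].
#' @param delta_t search half-window, seconds.
#' @return A relabeled [peak_list()].
#' @export
auto_label_standards <- function(peaks, reference, roster, delta_t) {
  assert_peaks(peaks); assert_roster(roster)
  sids <- standard_ids(roster)
  std_id <- peaks$std_id
  taken <- integer(0)
  for (s in sids) {
    d <- abs(peaks$rt - traj_rt(reference, s))
    d[!is.na(std_id)] <- Inf
    j <- which.min(d)
    if (!length(j) || d[j] > delta_t)
      stop(sprintf("no peak within %.3g s of standard %d", delta_t, s), call. = FALSE)
    if (sum(d <= delta_t) > 1L)
      stop(sprintf("ambiguous labeling: %d peaks within %.3g s of standard %d",
                   sum(d <= delta_t), delta_t, s), call. = FALSE)
    if (j %in% taken)
      stop(sprintf("standards compete for the peak at %.3f s", peaks$rt[j]),
           call. = FALSE)
    taken <- c(taken, j)
    std_id[j] <- s
  }
  peak_list(peaks$rt, peaks$height, std_id, roster = roster)
}
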