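#' Chromatogram trace
#'
#' A raw detector trace: time versus intensity, strictly increasing time,
#' uniform or non-uniform spacing.
#'
#' @param t time in seconds.
#' @param y intensity, arbitrary units.
#' @return A `chrom_trace` data frame.
#' @export
chrom_trace <- function(t, y) {
  t <- as.numeric(t); y <- as.numeric(y)
  if (length(t) != length(y) || anyNA(t) || anyNA(y))
    stop("t and y must be equal-length numeric vectors", call. = FALSE)
  if (length(t) < 3L) stop("a trace needs at least 3 samples", call. = FALSE)
  if (is.unsorted(t, strictly = TRUE))
    stop("trace times must be strictly increasing", call. = FALSE)
  structure(data.frame(t = t, y = y), class = c("chrom_trace", "data.frame"))
}

#' Read a two-column trace file
#'
#' Expected CSV columns: `t_seconds`, `intensity`.
#'
#' @param path file path.
#' @return A [chrom_trace()].
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("t_seconds", "intensity") %in% names(df)))
    stop(sprintf("trace '%s' must have columns t_seconds, intensity", path),
         call. = FALSE)
  chrom_trace(df$t_seconds, df$intensity)
}

#' Detect peak apexes by local-maximum scanning
#'
#' Scans the trace for local maxima and returns the apex retention times.
#' Only the apexes are extracted — no baseline removal, interpolation or
#' peak-shape fitting — so broad background variation drops out of the
#' downstream analysis by construction.  A maximum is kept when its
#' prominence (height above the higher of the two flanking minima, walking
#' out to the nearest taller sample on each side) reaches `min_prominence`;
#' maxima closer than `min_separation` to a taller kept maximum are
#' suppressed.  The leftmost sample of a flat plateau is its apex.
#'
#' @param trace a [chrom_trace()].
#' @param min_prominence minimal prominence, intensity units (>= 0).
#' @param min_separation minimal apex spacing, seconds (>= 0).
#' @return A [peak_list()] of apex times (heights = apex intensities); apex
#'   times are a subset of the trace's sample times.
#' @export
detect_peaks <- function(trace, min_prominence = 0, min_separation = 0) {
  if (!inherits(trace, "chrom_trace")) trace <- chrom_trace(trace[[1]], trace[[2]])
  stopifnot(min_prominence >= 0, min_separation >= 0)
  y <- trace$y; t <- trace$t; n <- length(y)
  # compress plateaus: keep the leftmost index of each run of equal values
  keep <- c(TRUE, diff(y) != 0)
  idx <- which(keep); yc <- y[idx]; nc <- length(yc)
  apex <- integer(0)
  if (nc >= 3L) {
    interior <- 2:(nc - 1L)
    is_max <- yc[interior] > yc[interior - 1L] & yc[interior] > yc[interior + 1L]
    apex <- idx[interior[is_max]]
  }
  if (length(apex) && min_prominence > 0) {
    prom <- vapply(apex, function(i) {
      l <- i; minl <- y[i]
      while (l > 1L && y[l] <= y[i]) { l <- l - 1L; minl <- min(minl, y[l]) }
      r <- i; minr <- y[i]
      while (r < n && y[r] <= y[i]) { r <- r + 1L; minr <- min(minr, y[r]) }
      y[i] - max(minl, minr)
    }, numeric(1))
    apex <- apex[prom >= min_prominence]
  }
  if (length(apex) > 1L && min_separation > 0) {
    o <- order(-y[apex], t[apex])  # taller first, earlier first on ties
    kept <- integer(0)
    for (i in apex[o])
      if (!length(kept) || all(abs(t[kept] - t[i]) >= min_separation))
        kept <- c(kept, i)
    apex <- sort(kept)
  }
  if (!length(apex))
    return(structure(data.frame(rt = numeric(0), height = numeric(0),
                                std_id = integer(0)),
                     n_sample = 0L, class = c("peak_list", "data.frame")))
  peak_list(t[apex], height = y[apex])
}
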