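#' Peak detection and matching configuration
#'
#' @param tol_cm1 Matching window half-width in cm^-1 (default 8, about 8
#'   grid steps on the canonical 564-1681/1117 axis).
#' @param min_prominence_frac Minimum peak prominence as a fraction of the
#'   spectrum maximum, in (0, 1).
#' @param min_separation_cm1 Minimum distance between reported peaks.
#' @param direction Matching direction: `"a_in_b"` (fraction of A's peaks
#'   found in B), `"b_in_a"`, or `"symmetric"` (mean of both).
#' @return List of class `match_config`.
#' @export
match_config <- function(tol_cm1 = 8, min_prominence_frac = 0.05,
                         min_separation_cm1 = 10,
                         direction = c("a_in_b", "b_in_a", "symmetric")) {
  stopifnot(tol_cm1 > 0, min_prominence_frac > 0, min_prominence_frac < 1,
            min_separation_cm1 >= 0)
  structure(list(tol_cm1 = tol_cm1,
                 min_prominence_frac = min_prominence_frac,
                 min_separation_cm1 = min_separation_cm1,
                 direction = match.arg(direction)),
            class = "match_config")
}

# Topographic prominence of local maxima (scipy-compatible definition):
# walk out from the peak to the nearest higher point on each side (or the
# signal edge); prominence = height - max(lowest valley left, lowest right).
.peak_prominences <- function(y, idx) {
  n <- length(y)
  vapply(idx, function(i) {
    h <- y[i]
    j <- i; lmin <- h
    while (j > 1L && y[j - 1L] <= h) { j <- j - 1L; lmin <- min(lmin, y[j]) }
    j <- i; rmin <- h
    while (j < n && y[j + 1L] <= h) { j <- j + 1L; rmin <- min(rmin, y[j]) }
    h - max(lmin, rmin)
  }, 0)
}

#' Detect peaks in a spectrum
#'
#' Local maxima with topographic prominence at least
#' `min_prominence_frac * max(intensity)` and pairwise separation at least
#' `min_separation_cm1`. When two candidates are closer than the separation,
#' the more prominent one wins. A flat spectrum yields an empty peak list.
#'
#' @param s Baseline-corrected `sers_spectrum`.
#' @param cfg A [match_config()].
#' @return `data.frame` of class `peak_list` with columns `position`
#'   (cm^-1, ascending), `height`, `prominence`.
#' @export
detect_peaks <- function(s, cfg = match_config()) {
  stopifnot(inherits(s, "sers_spectrum"), inherits(cfg, "match_config"))
  y <- s$intensities
  w <- wavenumbers(s)
  n <- length(y)
  empty <- structure(data.frame(position = numeric(0), height = numeric(0),
                                prominence = numeric(0)),
                     class = c("peak_list", "data.frame"))
  if (n < 3L || diff(range(y)) == 0) return(empty)
  is_max <- which(y[2:(n - 1L)] > y[1:(n - 2L)] &
                  y[2:(n - 1L)] >= y[3:n]) + 1L
  if (!length(is_max)) return(empty)
  prom <- .peak_prominences(y, is_max)
  keep <- prom >= cfg$min_prominence_frac * max(y)
  is_max <- is_max[keep]; prom <- prom[keep]
  if (!length(is_max)) return(empty)
  # enforce separation, most prominent first
  ord <- order(prom, decreasing = TRUE)
  chosen <- integer(0)
  for (k in ord) {
    if (!length(chosen) ||
        all(abs(w[is_max[k]] - w[is_max[chosen]]) >= cfg$min_separation_cm1))
      chosen <- c(chosen, k)
  }
  chosen <- chosen[order(is_max[chosen])]
  structure(data.frame(position = w[is_max[chosen]],
                       height = y[is_max[chosen]],
                       prominence = prom[chosen]),
            class = c("peak_list", "data.frame"))
}

# Greedy one-to-one assignment by ascending |distance|; each reference peak
# absorbs at most one query peak, so a broad band cannot soak up several.
.greedy_match <- function(a, b, tol) {
  if (!length(a) || !length(b))
    return(data.frame(a = numeric(0), b = numeric(0), dist = numeric(0)))
  pairs <- expand.grid(i = seq_along(a), j = seq_along(b))
  pairs$dist <- abs(a[pairs$i] - b[pairs$j])
  pairs <- pairs[pairs$dist <= tol, , drop = FALSE]
  pairs <- pairs[order(pairs$dist), , drop = FALSE]
  used_a <- logical(length(a)); used_b <- logical(length(b))
  keep <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    if (!used_a[i] && !used_b[j]) {
      keep[k] <- TRUE; used_a[i] <- TRUE; used_b[j] <- TRUE
    }
  }
  m <- pairs[keep, , drop = FALSE]
  data.frame(a = a[m$i], b = b[m$j], dist = m$dist)
}

#' Peak-location matching rate between two peak lists
#'
#' Percentage of one list's peaks that have a counterpart within
#' `tol_cm1` in the other, under greedy one-to-one nearest-first
#' assignment. Direction `"a_in_b"` reads as "fraction of A's predicted
#' peaks found in measurement B"; `"symmetric"` averages both directions.
#' The matched-pair table is attached as attribute `"pairs"`.
#'
#' @param a,b `peak_list`s (from [detect_peaks()]) or plain numeric vectors
#'   of peak positions in cm^-1.
#' @param cfg A [match_config()].
#' @return Scalar percent in `[0, 100]`.
#' @export
matching_rate <- function(a, b, cfg = match_config()) {
  stopifnot(inherits(cfg, "match_config"))
  pa <- if (is.data.frame(a)) a$position else as.numeric(a)
  pb <- if (is.data.frame(b)) b$position else as.numeric(b)
  dir <- cfg$direction
  if ((dir %in% c("a_in_b", "symmetric")) && !length(pa))
    stop("matching direction a_in_b: peak list A is empty")
  if ((dir %in% c("b_in_a", "symmetric")) && !length(pb))
    stop("matching direction b_in_a: peak list B is empty")
  m <- .greedy_match(pa, pb, cfg$tol_cm1)
  rate_ab <- if (length(pa)) 100 * nrow(m) / length(pa) else NA_real_
  rate_ba <- if (length(pb)) 100 * nrow(m) / length(pb) else NA_real_
  out <- switch(dir, a_in_b = rate_ab, b_in_a = rate_ba,
                symmetric = mean(c(rate_ab, rate_ba)))
  attr(out, "pairs") <- m
  out
}

#' Matching rate between two spectra
#'
#' Detects peaks in both spectra with the same configuration and reports
#' [matching_rate()] on the resulting positions. The conventional reading is
#' `a` = simulated/fitted spectrum, `b` = measured average.
#'
#' @param a,b `sers_spectrum` objects.
#' @param cfg A [match_config()].
#' @return Scalar percent; peak lists attached as attributes `"peaks_a"`,
#'   `"peaks_b"`.
#' @export
spectrum_matching_rate <- function(a, b, cfg = match_config()) {
  pa <- detect_peaks(a, cfg)
  pb <- detect_peaks(b, cfg)
  out <- matching_rate(pa, pb, cfg)
  attr(out, "peaks_a") <- pa
  attr(out, "peaks_b") <- pb
  out
}
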