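#' Preprocessing configuration
#'
#' Bundles the knobs applied to raw spectra before unmixing or LDA:
#' asymmetric-least-squares baseline parameters, normalization mode, and the
#' target analysis grid.
#'
#' @param baseline_lambda Smoothness weight of the baseline (> 0). Larger
#'   values give stiffer baselines; 1e5 suits broad PBS/substrate backgrounds
#'   under Raman linewidths of 6-20 cm^-1.
#' @param baseline_p Asymmetry weight in (0, 1); small values force the
#'   baseline under the peaks.
#' @param normalization One of `"l2"`, `"max1"`, `"none"`.
#' @param grid Target [wavenumber_grid()].
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(baseline_lambda = 1e5, baseline_p = 0.01,
                              normalization = c("l2", "max1", "none"),
                              grid = wavenumber_grid()) {
  stopifnot(baseline_lambda > 0, baseline_p > 0, baseline_p < 1)
  structure(list(baseline_lambda = baseline_lambda, baseline_p = baseline_p,
                 normalization = match.arg(normalization), grid = grid),
            class = "preprocess_config")
}

#' Resample a spectrum onto a target grid by linear interpolation
#'
#' @param s A `sers_spectrum` whose axis spans the target grid.
#' @param grid Target [wavenumber_grid()].
#' @return Spectrum on `grid`, metadata preserved.
#' @export
resample_to_grid <- function(s, grid) {
  stopifnot(inherits(s, "sers_spectrum"), inherits(grid, "sers_grid"))
  w <- wavenumbers(s)
  if (w[1L] > grid$start + 1e-9 || w[length(w)] < grid$end - 1e-9)
    stop(sprintf("spectrum axis [%g, %g] does not cover grid [%g, %g]",
                 w[1L], w[length(w)], grid$start, grid$end))
  y <- stats::approx(w, s$intensities, xout = grid$axis, rule = 1)$y
  new_spectrum(y, grid, s$meta)
}

# Eilers asymmetric-least-squares baseline; sparse second-difference penalty.
.als_baseline <- function(y, lambda, p, niter = 10L) {
  n <- length(y)
  D <- Matrix::bandSparse(n - 2L, n,
                          k = 0:2,
                          diagonals = list(rep(1, n - 2L), rep(-2, n - 2L),
                                           rep(1, n - 2L)))
  P <- lambda * Matrix::crossprod(D)
  w <- rep(1, n)
  z <- y
  for (it in seq_len(niter)) {
    W <- Matrix::Diagonal(n, w)
    z <- as.numeric(Matrix::solve(W + P, w * y))
    w_new <- ifelse(y > z, p, 1 - p)
    if (all(w_new == w)) break
    w <- w_new
  }
  z
}

#' Subtract an asymmetric-least-squares baseline
#'
#' Estimates a smooth background under the spectrum (asymmetric least
#' squares: points above the current estimate get weight `p`, points below
#' get `1 - p`) and returns the spectrum minus the estimate. The fitted
#' baseline is attached as attribute `"baseline"` so it can be inspected.
#'
#' @param s A `sers_spectrum`, length >= 10.
#' @param cfg A [preprocess_config()]; only the baseline fields are used.
#' @return Baseline-corrected `sers_spectrum`.
#' @export
correct_baseline <- function(s, cfg = preprocess_config()) {
  stopifnot(inherits(s, "sers_spectrum"))
  if (s$grid$n_points < 10L) stop("baseline correction needs >= 10 points")
  z <- .als_baseline(s$intensities, cfg$baseline_lambda, cfg$baseline_p)
  out <- new_spectrum(s$intensities - z, s$grid, s$meta)
  attr(out, "baseline") <- z
  out
}

#' Normalize a spectrum
#'
#' @param s A `sers_spectrum`.
#' @param mode `"max1"` (peak maximum scaled to 1), `"l2"` (unit Euclidean
#'   norm), or `"none"` (identity).
#' @return Normalized spectrum.
#' @export
normalize_spectrum <- function(s, mode = c("l2", "max1", "none")) {
  mode <- match.arg(mode)
  stopifnot(inherits(s, "sers_spectrum"))
  if (mode == "none") return(s)
  sc <- switch(mode, max1 = max(s$intensities),
               l2 = sqrt(sum(s$intensities^2)))
  if (sc <= 0) stop("cannot normalize an all-zero (or non-positive-max) spectrum")
  new_spectrum(s$intensities / sc, s$grid, s$meta)
}

#' Pointwise average of a spectrum set
#'
#' @param set Non-empty `sers_set` on a shared grid.
#' @return A `sers_spectrum`; metadata records the number averaged.
#' @export
average_spectra <- function(set) {
  stopifnot(inherits(set, "sers_set"))
  if (!length(set)) stop("cannot average an empty spectrum set")
  m <- colMeans(as.matrix(set))
  new_spectrum(m, set$grid, meta = list(n_averaged = length(set)))
}

#' Signal-to-noise ratio of a spectrum
#'
#' SNR is the maximum intensity divided by a robust noise scale estimated
#' from first differences: `sigma = median(|diff(y)|) / (0.6745 * sqrt(2))`.
#' The ratio is used as the per-substance SERS-activity indicator. It is
#' invariant under positive rescaling of the spectrum. An exactly noiseless
#' spectrum returns `Inf` with attribute `noiseless = TRUE` rather than
#' dividing by zero silently.
#'
#' @param s Baseline-corrected `sers_spectrum`, length >= 10.
#' @return Non-negative scalar SNR (possibly `Inf`, flagged).
#' @export
estimate_snr <- function(s) {
  stopifnot(inherits(s, "sers_spectrum"))
  y <- s$intensities
  if (length(y) < 10L) stop("SNR estimation needs >= 10 points")
  sigma <- stats::median(abs(diff(y))) / (0.6745 * sqrt(2))
  if (sigma == 0) {
    out <- Inf
    attr(out, "noiseless") <- TRUE
    return(out)
  }
  max(y) / sigma
}

#' Apply full preprocessing to every spectrum in a set
#'
#' Resamples (when the axis differs from `cfg$grid`), subtracts the
#' asymmetric-least-squares baseline, and normalizes. Spectra below
#' `min_snr` are flagged in their metadata (`low_snr = TRUE`), never
#' dropped.
#'
#' @param set A `sers_set`.
#' @param cfg A [preprocess_config()].
#' @param min_snr Optional SNR gate; `NULL` disables flagging.
#' @return Preprocessed `sers_set`.
#' @export
preprocess_set <- function(set, cfg = preprocess_config(), min_snr = NULL) {
  stopifnot(inherits(set, "sers_set"))
  out <- lapply(set$spectra, function(s) {
    if (!same_grid(s$grid, cfg$grid)) s <- resample_to_grid(s, cfg$grid)
    s <- correct_baseline(s, cfg)
    if (!is.null(min_snr)) {
      snr <- estimate_snr(s)
      if (is.finite(snr) && snr < min_snr) s$meta$low_snr <- TRUE
    }
    normalize_spectrum(s, cfg$normalization)
  })
  spectrum_set(out)
}
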