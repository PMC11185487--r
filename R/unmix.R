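#' Construct an amino-acid basis
#'
#' The mixing dictionary of the forward model: one reference SERS spectrum
#' per amino acid (shared grid) plus a per-amino-acid SERS-activity value
#' (the spectrum's signal-to-noise ratio, used as the relative propensity of
#' that substance to produce SERS signal). Basis spectra are max-normalized
#' on construction so that activities alone carry the intensity scale.
#'
#' @param spectra Named list of `sers_spectrum` on one grid. Names are the
#'   component labels; the standard basis uses the 20 codes of
#'   [amino_acids()], but smaller toy bases are permitted.
#' @param activity Named positive numeric vector, same names as `spectra`.
#'   Defaults to 1 for every component.
#' @return Object of class `aa_basis` with fields `spectra`, `activity`,
#'   `grid`.
#' @export
amino_acid_basis <- function(spectra, activity = NULL) {
  if (is.null(names(spectra)) || any(!nzchar(names(spectra))))
    stop("basis spectra must be named")
  if (length(spectra) < 2L) stop("a basis needs at least 2 components")
  g <- spectra[[1L]]$grid
  spectra <- lapply(spectra, function(s) {
    if (!same_grid(g, s$grid)) stop("basis spectra are not on a shared grid")
    normalize_spectrum(s, "max1")
  })
  if (is.null(activity))
    activity <- stats::setNames(rep(1, length(spectra)), names(spectra))
  activity <- unlist(activity)[names(spectra)]
  if (any(is.na(activity)) || any(activity <= 0))
    stop("every basis component needs a positive activity")
  structure(list(spectra = spectra, activity = activity, grid = g),
            class = "aa_basis")
}

#' @export
print.aa_basis <- function(x, ...) {
  cat(sprintf("<aa_basis> %d components on %g..%g cm^-1 (%d points)\n",
              length(x$spectra), x$grid$start, x$grid$end, x$grid$n_points))
  invisible(x)
}

#' Basis matrix (grid points x components)
#' @param basis An `aa_basis`.
#' @return Numeric matrix, columns named by component.
#' @export
basis_matrix <- function(basis) {
  stopifnot(inherits(basis, "aa_basis"))
  m <- vapply(basis$spectra, function(s) s$intensities,
              numeric(basis$grid$n_points))
  colnames(m) <- names(basis$spectra)
  m
}

.match_basis_weights <- function(w, basis) {
  w <- unlist(w)
  if (is.null(names(w))) {
    if (length(w) != length(basis$spectra))
      stop("unnamed weights must match the basis size")
    names(w) <- names(basis$spectra)
  }
  missing <- setdiff(names(basis$spectra), names(w))
  if (length(missing))
    stop("weights missing for: ", paste(missing, collapse = ", "))
  w[names(basis$spectra)]
}

#' Derive spectral mixing coefficients from composition and SERS activity
#'
#' A vesicle's expected SERS spectrum is not weighted by molar composition
#' alone: substances with higher SERS activity contribute disproportionately.
#' The mixing coefficient of amino acid `a` is
#' `c(a) = f(a) * activity(a) / sum_b f(b) * activity(b)`.
#'
#' @param freq A [composition_vector()] (or named weights matching the basis).
#' @param basis An `aa_basis` supplying the activities.
#' @return Named non-negative coefficients summing to 1, class
#'   `composition_vector` when the basis is the standard 20-amino-acid one.
#' @export
derive_coefficients <- function(freq, basis) {
  f <- .match_basis_weights(freq, basis)
  prod <- as.numeric(f) * as.numeric(basis$activity)
  if (sum(prod) <= 0) stop("all composition x activity products are zero")
  out <- stats::setNames(prod / sum(prod), names(basis$spectra))
  if (identical(sort(names(out)), amino_acids()))
    out <- composition_vector(out, normalize = FALSE)
  out
}

#' Forward-simulate a vesicle SERS spectrum
#'
#' Linear combination of the basis spectra: `S(v) = sum_a c(a) * B_a(v)`.
#'
#' @param coef Named non-negative weights over the basis components.
#' @param basis An `aa_basis`.
#' @return A `sers_spectrum` on the basis grid.
#' @export
simulate_spectrum <- function(coef, basis) {
  w <- .match_basis_weights(coef, basis)
  y <- as.numeric(basis_matrix(basis) %*% as.numeric(w))
  new_spectrum(y, basis$grid, meta = list(simulated = TRUE))
}

# Deterministic stagewise forward fit: each round the single basis spectrum
# that most reduces the residual is added with a shrunken non-negative step.
.boosted_fit <- function(B, y, rounds = 200L, shrinkage = 0.5) {
  p <- ncol(B)
  nrm2 <- colSums(B^2)
  w <- rep(0, p)
  r <- y
  for (t in seq_len(rounds)) {
    proj <- as.numeric(crossprod(B, r)) / nrm2
    proj[proj < 0] <- 0
    gain <- proj^2 * nrm2
    j <- which.max(gain)
    if (gain[j] <= 1e-30) break
    step <- shrinkage * proj[j]
    w[j] <- w[j] + step
    r <- r - step * B[, j]
  }
  w
}

#' Unmix a measured spectrum into amino-acid coefficients
#'
#' Inverts the forward model: finds non-negative weights `w` minimizing
#' `|target - sum_a w_a B_a|_2`. The reference method is non-negative least
#' squares (`method = "nnls"`, active-set solver). `method = "boosted"` runs
#' a deterministic stagewise (boosting-style) fit with single-basis-spectrum
#' weak learners and shrinkage, provided for compatibility with
#' ensemble-of-weak-regressors fitting; NNLS is the well-posed convex
#' formulation and the default. Negative intensities left by baseline
#' correction are permitted in the target (no clipping).
#'
#' @param target A `sers_spectrum` on the basis grid, baseline-corrected and
#'   normalized.
#' @param basis An `aa_basis`.
#' @param method `"nnls"` or `"boosted"`.
#' @param seed Integer recorded with the result; both methods are
#'   deterministic, so it only documents the configuration.
#' @param rounds,shrinkage Boosted-method controls.
#' @return Object of class `sers_fit`: `coefficients` (normalized to sum 1),
#'   `raw_weights`, `residual_norm`, `method`.
#' @export
fit_composition <- function(target, basis, method = c("nnls", "boosted"),
                            seed = 1L, rounds = 200L, shrinkage = 0.5) {
  method <- match.arg(method)
  stopifnot(inherits(target, "sers_spectrum"), inherits(basis, "aa_basis"))
  if (!same_grid(target$grid, basis$grid))
    stop("target spectrum is not on the basis grid")
  y <- target$intensities
  if (all(y == 0)) stop("cannot fit an all-zero target spectrum")
  B <- basis_matrix(basis)
  # warn on (near-)duplicate basis columns: weights are then non-identifiable
  nb <- sweep(B, 2, sqrt(colSums(B^2)), "/")
  cs <- crossprod(nb)
  diag(cs) <- 0
  if (max(cs) > 1 - 1e-12)
    warning("degenerate basis: near-identical spectra; weights not unique")
  w <- switch(method,
    nnls = as.numeric(pracma::lsqnonneg(B, y)$x),
    boosted = .boosted_fit(B, y, rounds = rounds, shrinkage = shrinkage))
  names(w) <- colnames(B)
  resid <- sqrt(sum((y - as.numeric(B %*% w))^2))
  if (sum(w) <= 0)
    stop("fit collapsed to all-zero weights; is the target a spectrum?")
  coefs <- w / sum(w)
  if (identical(sort(names(coefs)), amino_acids()))
    coefs <- composition_vector(coefs, normalize = FALSE)
  structure(list(coefficients = coefs, raw_weights = w,
                 residual_norm = resid, method = method, seed = seed),
            class = "sers_fit")
}

#' @export
print.sers_fit <- function(x, ...) {
  cat(sprintf("<sers_fit> method=%s, residual norm %.4g\n",
              x$method, x$residual_norm))
  top <- sort(x$coefficients, decreasing = TRUE)[1:min(5, length(x$coefficients))]
  cat("top coefficients:",
      paste(sprintf("%s=%.3f", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Mean deviation between fitted and reference coefficients
#'
#' @param fit,ref Named weight vectors over the same components (e.g. fitted
#'   coefficients vs MS-derived coefficients).
#' @param mode `"relative"` (default): mean over components with `ref > 0` of
#'   `|fit - ref| / ref`, in percent. `"absolute"`: mean `|fit - ref|`, in
#'   percentage points.
#' @return Scalar percent.
#' @export
mean_deviation <- function(fit, ref, mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  fit <- unlist(fit); ref <- unlist(ref)
  if (!is.null(names(fit)) && !is.null(names(ref))) {
    if (!setequal(names(fit), names(ref)))
      stop("fit and ref cover different components")
    fit <- fit[names(ref)]
  }
  if (length(fit) != length(ref)) stop("fit and ref lengths differ")
  if (mode == "relative") {
    pos <- ref > 0
    if (!any(pos)) stop("relative deviation undefined: all reference entries zero")
    mean(abs(fit[pos] - ref[pos]) / ref[pos]) * 100
  } else {
    mean(abs(fit - ref)) * 100
  }
}
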