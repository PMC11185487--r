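# shared fixtures built in code

tiny_grid <- function(n = 201L, start = 564, end = 1681)
  wavenumber_grid(start, end, n)

# a smooth analytic spectrum: sum of sines, bounded second derivative
smooth_spectrum <- function(grid) {
  w <- wavenumbers(grid)
  x <- (w - grid$start) / (grid$end - grid$start)
  new_spectrum(2 + sin(2 * pi * x) + 0.5 * sin(6 * pi * x), grid)
}

lorentzian_spectrum <- function(grid, centers, fwhm = 15, amps = NULL) {
  w <- wavenumbers(grid)
  if (is.null(amps)) amps <- rep(1, length(centers))
  y <- rep(0, length(w))
  for (i in seq_along(centers))
    y <- y + amps[i] / (1 + ((w - centers[i]) / (fwhm / 2))^2)
  new_spectrum(y, grid)
}

# toy 3-component basis with well-separated peaks, on a small grid
toy_basis <- function(grid = tiny_grid(301L)) {
  s <- list(
    A = lorentzian_spectrum(grid, c(700, 1500), 20),
    G = lorentzian_spectrum(grid, c(900, 1200), 20),
    V = lorentzian_spectrum(grid, c(1050, 1600), 20))
  amino_acid_basis(s, c(A = 1, G = 2, V = 3))
}

uniform_composition <- function()
  composition_vector(stats::setNames(rep(0.05, 20), amino_acids()),
                     normalize = FALSE)

random_composition <- function()
  composition_vector(stats::setNames(stats::runif(20, 0.2, 1), amino_acids()))

# small default study spec: three SEC-fraction-like groups
small_study_spec <- function(seed = 11L, n = c(12L, 12L, 12L),
                             noise_sd = 0.02, baseline_amplitude = 0.2,
                             concentration = 300, grid = wavenumber_grid()) {
  means <- local_study_means(seed)
  synthetic_spec(
    seed = seed, grid = grid, noise_sd = noise_sd,
    baseline_amplitude = baseline_amplitude,
    groups = list(
      synthetic_group("F7", n[1L], means[[1L]], concentration, "HEK293"),
      synthetic_group("F8", n[2L], means[[2L]], concentration, "HEK293"),
      synthetic_group("F9", n[3L], means[[3L]], concentration, "HEK293")))
}

# distinct per-fraction mean compositions: perturbations of the human
# background composition
local_study_means <- function(seed) {
  base <- as.numeric(human_aa_frequencies())
  lapply(1:3, function(k) {
    f <- base * exp(sin(seq_len(20) * k * 0.9) * 0.8)
    composition_vector(stats::setNames(f, amino_acids()))
  })
}
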