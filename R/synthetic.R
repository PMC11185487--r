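# run code under a fixed seed without disturbing the caller's RNG stream
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

.rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(0, n, k)
  pos <- alpha > 0
  x[, pos] <- matrix(stats::rgamma(n * sum(pos), shape = alpha[pos]),
                     n, sum(pos), byrow = TRUE)
  x / rowSums(x)
}

#' Define a synthetic vesicle-SERS study
#'
#' Full parameterization of a generated dataset: 20 smooth amino-acid basis
#' spectra (sums of Lorentzian lines, the natural Raman line profile), and
#' per-group single-vesicle spectrum collections built as non-negative linear
#' combinations of the activity-scaled bases plus a polynomial background and
#' Gaussian noise. Group structure emulates SEC-fraction subpopulations:
#' each group has a mean composition and Dirichlet within-group variability
#' (biological vesicle-to-vesicle heterogeneity on the simplex).
#'
#' @param seed Master seed; the whole dataset is a pure function of the spec.
#' @param grid Wavenumber grid (default the canonical 564-1681/1117 axis).
#' @param n_basis_peaks Integer range of Lorentzian lines per amino acid.
#' @param peak_width_cm1 Range of Lorentzian FWHMs (cm^-1).
#' @param groups List of [synthetic_group()] entries.
#' @param noise_sd Gaussian noise standard deviation as a fraction of each
#'   spectrum's maximum signal.
#' @param baseline_order Polynomial order of the additive background.
#' @param baseline_amplitude Background amplitude as a fraction of the
#'   maximum signal (PBS-crystal-like broad background).
#' @param activity_range Range of per-amino-acid SERS activities (relative
#'   SNR ratios; Raman cross sections differ by about an order of magnitude
#'   between substances).
#' @return List of class `synth_spec`.
#' @export
synthetic_spec <- function(seed = 1L,
                           grid = wavenumber_grid(),
                           n_basis_peaks = c(4L, 8L),
                           peak_width_cm1 = c(6, 20),
                           groups = list(),
                           noise_sd = 0.02,
                           baseline_order = 2L,
                           baseline_amplitude = 0.2,
                           activity_range = c(1, 10)) {
  stopifnot(length(n_basis_peaks) == 2L, n_basis_peaks[1L] >= 1L,
            length(peak_width_cm1) == 2L, peak_width_cm1[1L] > 0,
            noise_sd >= 0, baseline_order >= 0, baseline_amplitude >= 0,
            activity_range[1L] > 0)
  if (grid$end - grid$start < 80)
    stop("grid too narrow for distinct basis peak sets")
  structure(list(seed = as.integer(seed), grid = grid,
                 n_basis_peaks = as.integer(n_basis_peaks),
                 peak_width_cm1 = peak_width_cm1, groups = groups,
                 noise_sd = noise_sd, baseline_order = as.integer(baseline_order),
                 baseline_amplitude = baseline_amplitude,
                 activity_range = activity_range),
            class = "synth_spec")
}

#' Define one synthetic group (e.g. an SEC fraction)
#'
#' @param name Group label (e.g. `"F7"`).
#' @param n_spectra Number of vesicle spectra (>= 1).
#' @param mean_composition Group-mean [composition_vector()].
#' @param concentration Dirichlet concentration of within-group variability
#'   (> 0); large values give tight groups. Default 300 gives per-amino-acid
#'   relative spreads of a few percent, a moderate level of biological
#'   vesicle-to-vesicle heterogeneity.
#' @param cell_line Optional cell-line label carried into metadata.
#' @return Named list.
#' @export
synthetic_group <- function(name, n_spectra, mean_composition,
                            concentration = 300, cell_line = NA_character_) {
  stopifnot(n_spectra >= 1L, concentration > 0)
  list(name = name, n_spectra = as.integer(n_spectra),
       mean_composition = composition_vector(mean_composition),
       concentration = concentration, cell_line = cell_line)
}

.lorentzian <- function(w, center, fwhm) 1 / (1 + ((w - center) / (fwhm / 2))^2)

.random_basis_spectrum <- function(spec, w) {
  k <- sample(spec$n_basis_peaks[1L]:spec$n_basis_peaks[2L], 1L)
  centers <- stats::runif(k, spec$grid$start + 20, spec$grid$end - 20)
  widths <- stats::runif(k, spec$peak_width_cm1[1L], spec$peak_width_cm1[2L])
  amps <- stats::runif(k, 0.3, 1)
  y <- rep(0, length(w))
  for (i in seq_len(k)) y <- y + amps[i] * .lorentzian(w, centers[i], widths[i])
  y / max(y)
}

#' Generate a synthetic 20-amino-acid basis
#'
#' Each basis spectrum is a sum of 4-8 Lorentzian lines with seeded random
#' centers and widths, max-normalized. Pairs with cosine similarity of 0.95
#' or above are regenerated so the dictionary stays identifiable. Activities
#' are drawn uniformly from the spec's `activity_range`.
#'
#' @param spec A [synthetic_spec()].
#' @return An [amino_acid_basis()] with 20 components.
#' @export
generate_basis <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  local_seed(spec$seed, {
    w <- wavenumbers(spec$grid)
    aa <- amino_acids()
    mat <- matrix(0, length(w), 20L)
    for (i in 1:20) {
      for (try in 1:100) {
        y <- .random_basis_spectrum(spec, w)
        if (i == 1L) break
        prev <- mat[, 1:(i - 1L), drop = FALSE]
        cs <- as.numeric(crossprod(prev, y)) /
          (sqrt(colSums(prev^2)) * sqrt(sum(y^2)))
        if (max(cs) < 0.95) break
        if (try == 100L) stop("could not generate a sufficiently distinct basis")
      }
      mat[, i] <- y
    }
    activity <- stats::setNames(
      stats::runif(20L, spec$activity_range[1L], spec$activity_range[2L]), aa)
    spectra <- stats::setNames(lapply(1:20, function(i)
      new_spectrum(mat[, i], spec$grid, meta = list(amino_acid = aa[i]))), aa)
    amino_acid_basis(spectra, activity)
  })
}

.random_baseline <- function(w, order, amplitude, scale) {
  if (amplitude <= 0 || order < 0) return(rep(0, length(w)))
  x <- (w - w[1L]) / (w[length(w)] - w[1L])
  coefs <- stats::runif(order + 1L, 0, 1)
  y <- rep(0, length(w))
  for (d in 0:order) y <- y + coefs[d + 1L] * x^d
  amplitude * scale * y / max(y)
}

#' Generate a synthetic single-vesicle spectrum set with ground truth
#'
#' For every group, per-spectrum compositions are drawn from
#' `Dirichlet(concentration * mean_composition)`; each spectrum is the
#' composition-and-activity-weighted combination of the basis spectra
#' (`coefficients = derive_coefficients(composition, basis)`), plus a random
#' polynomial background and Gaussian noise scaled to the maximum signal.
#'
#' @param spec A [synthetic_spec()] with at least one group.
#' @param basis An `aa_basis` on `spec$grid` (typically [generate_basis()]).
#' @return List: `set` (a `sers_set` with `sample_id`, `fraction`,
#'   `cell_line` metadata), `composition` (n x 20 truth matrix), and
#'   `coefficients` (n x 20 matrix of the generating mixing coefficients --
#'   what [fit_composition()] estimates).
#' @export
generate_vesicle_set <- function(spec, basis) {
  stopifnot(inherits(spec, "synth_spec"), inherits(basis, "aa_basis"))
  if (!length(spec$groups)) stop("spec defines no groups")
  if (!same_grid(spec$grid, basis$grid)) stop("basis is not on the spec grid")
  local_seed(spec$seed + 1L, {
    B <- basis_matrix(basis)
    w <- wavenumbers(spec$grid)
    spectra <- list()
    comp_rows <- list()
    coef_rows <- list()
    idx <- 0L
    for (gdef in spec$groups) {
      comps <- .rdirichlet(gdef$n_spectra,
                           gdef$concentration * as.numeric(gdef$mean_composition))
      colnames(comps) <- amino_acids()
      for (i in seq_len(gdef$n_spectra)) {
        idx <- idx + 1L
        ci <- derive_coefficients(
          stats::setNames(comps[i, ], amino_acids()), basis)
        signal <- as.numeric(B %*% as.numeric(ci))
        top <- max(signal)
        y <- signal +
          .random_baseline(w, spec$baseline_order, spec$baseline_amplitude, top) +
          stats::rnorm(length(w), 0, spec$noise_sd * top)
        spectra[[idx]] <- new_spectrum(y, spec$grid, meta = list(
          sample_id = sprintf("%s_%03d", gdef$name, i),
          fraction = gdef$name, cell_line = gdef$cell_line))
        comp_rows[[idx]] <- comps[i, ]
        coef_rows[[idx]] <- as.numeric(ci)
      }
    }
    comp <- do.call(rbind, comp_rows)
    coefs <- do.call(rbind, coef_rows)
    colnames(comp) <- colnames(coefs) <- amino_acids()
    rownames(comp) <- rownames(coefs) <-
      vapply(spectra, function(s) s$meta$sample_id, "")
    list(set = spectrum_set(spectra), composition = comp, coefficients = coefs)
  })
}

.wrap_fasta <- function(id, seq, width = 60L) {
  starts <- seq(1L, nchar(seq), by = width)
  lines <- substring(seq, starts, pmin(starts + width - 1L, nchar(seq)))
  c(paste0(">", id), lines)
}

#' Generate a protein table + FASTA whose amino-acid frequencies are exact
#'
#' Builds `n_proteins` synthetic protein sequences (length 100-600, residues
#' sampled from `comp`) with random abundances, then appends one homopolymer
#' "adjustment" protein per represented residue whose abundance is solved in
#' closed form so that [amino_acid_frequencies()] of the output reproduces
#' `comp` to machine precision. Exactness therefore needs
#' `n_proteins >= number of residues with positive weight`; below that the
#' generator falls back to integer residue counts (approximate) and warns.
#'
#' @param comp Target [composition_vector()].
#' @param n_proteins Total number of table rows (>= 1).
#' @param seed Seed; output (including FASTA text) is byte-deterministic.
#' @return List: `table` (a `protein_table` with sequences attached),
#'   `fasta` (character vector of FASTA lines).
#' @export
generate_ms_fixture <- function(comp, n_proteins = 90L, seed = 1L) {
  comp <- composition_vector(comp)
  stopifnot(n_proteins >= 1L)
  aa <- amino_acids()
  support <- aa[as.numeric(comp) > 0]
  local_seed(seed, {
    ids <- sprintf("SYNPROT%04d", seq_len(n_proteins))
    if (n_proteins < length(support)) {
      warning("n_proteins below the number of represented residues; ",
              "frequencies are approximate")
      L <- 600L
      seqs <- replicate(n_proteins, {
        k <- round(as.numeric(comp) * L)
        paste(rep(aa, k), collapse = "")
      })
      wts <- rep(1 / n_proteins, n_proteins)
    } else {
      n_sample <- n_proteins - length(support)
      seqs <- character(0)
      wts <- numeric(0)
      if (n_sample > 0L) {
        lens <- sample(100:600, n_sample, replace = TRUE)
        seqs <- vapply(lens, function(L)
          paste(sample(support, L, replace = TRUE,
                       prob = as.numeric(comp)[match(support, aa)]),
                collapse = ""), "")
        wts <- stats::runif(n_sample, 0.2, 1)
      }
      # closed-form homopolymer adjustment: with sampled residue mass
      # S_a = sum w_p n_pa and T = sum w_p L_p, adding mass m_a of pure
      # residue a with total added mass W = sum m_a gives frequencies
      # (S_a + m_a) / (T + W); solving for f = comp yields
      # m_a = comp_a * (T + W) - S_a, feasible for W large enough.
      counts <- if (length(seqs))
        t(vapply(seqs, .residue_counts, numeric(20L), USE.NAMES = FALSE))
      else matrix(0, 0L, 20L)
      S <- if (nrow(counts)) colSums(counts * wts) else rep(0, 20L)
      T_mass <- sum(S)
      cpos <- as.numeric(comp)[match(support, aa)]
      Spos <- S[match(support, aa)]
      W <- max(1, 1.5 * max(Spos / cpos) - T_mass)
      m <- cpos * (T_mass + W) - Spos
      m[m < 0] <- 0                      # guard against rounding
      adj_len <- sample(100:600, length(support), replace = TRUE)
      adj_seqs <- vapply(seq_along(support), function(k)
        strrep(support[k], adj_len[k]), "")
      adj_wts <- m / adj_len
      seqs <- c(seqs, adj_seqs)
      wts <- c(wts, adj_wts)
    }
    wts <- wts / sum(wts)
    tab <- data.frame(protein_id = ids, rel_abundance = wts,
                      sequence = seqs, stringsAsFactors = FALSE)
    tab$nonstandard <- 0L
    class(tab) <- c("protein_table", "data.frame")
    fasta <- unlist(lapply(seq_len(nrow(tab)),
                           function(i) .wrap_fasta(ids[i], seqs[i])))
    list(table = tab, fasta = fasta)
  })
}

#' Write a complete synthetic bundle to disk
#'
#' Materializes a [synthetic_spec()] as the on-disk layout the pipeline
#' consumes: per-amino-acid basis spectrum CSVs plus an activity CSV, a
#' long-format vesicle map TSV with metadata sidecar, truth CSVs
#' (per-spectrum compositions and mixing coefficients), a protein abundance
#' CSV + FASTA consistent with the first group's mean composition, and a
#' YAML manifest tying the files together.
#'
#' @param spec A [synthetic_spec()] with groups.
#' @param dir Output directory (created if needed).
#' @param n_proteins Rows of the MS fixture.
#' @return Named list of file paths (class `synth_bundle`), invisibly
#'   usable as [run_pipeline()] input via the manifest.
#' @export
write_synthetic_bundle <- function(spec, dir, n_proteins = 90L) {
  stopifnot(inherits(spec, "synth_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  basis <- generate_basis(spec)
  ves <- generate_vesicle_set(spec, basis)

  basis_dir <- file.path(dir, "basis")
  dir.create(basis_dir, showWarnings = FALSE)
  w <- wavenumbers(spec$grid)
  for (a in names(basis$spectra)) {
    utils::write.csv(data.frame(wavenumber_cm1 = w,
                                intensity = basis$spectra[[a]]$intensities),
                     file.path(basis_dir, paste0(a, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  utils::write.csv(data.frame(amino_acid = names(basis$activity),
                              activity = as.numeric(basis$activity)),
                   file.path(dir, "activity.csv"), row.names = FALSE,
                   quote = FALSE)

  map_path <- file.path(dir, "vesicles.tsv")
  write_spectrum_set(ves$set, map_path, dialect = "tsv")
  utils::write.csv(data.frame(sample_id = rownames(ves$composition),
                              ves$composition, check.names = FALSE),
                   file.path(dir, "truth_composition.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(sample_id = rownames(ves$coefficients),
                              ves$coefficients, check.names = FALSE),
                   file.path(dir, "truth_coefficients.csv"),
                   row.names = FALSE, quote = FALSE)

  ms <- generate_ms_fixture(spec$groups[[1L]]$mean_composition,
                            n_proteins = n_proteins, seed = spec$seed + 2L)
  ms_path <- file.path(dir, "proteins.csv")
  utils::write.csv(ms$table[, c("protein_id", "rel_abundance")], ms_path,
                   row.names = FALSE, quote = FALSE)
  fasta_path <- file.path(dir, "proteins.fasta")
  writeLines(ms$fasta, fasta_path)

  manifest <- list(
    grid = list(start = spec$grid$start, end = spec$grid$end,
                n_points = spec$grid$n_points),
    seed = spec$seed,
    vesicle_map = basename(map_path),
    basis_dir = "basis",
    activity = "activity.csv",
    ms_table = basename(ms_path),
    fasta = basename(fasta_path),
    reference_group = spec$groups[[1L]]$name,
    groups = lapply(spec$groups, function(g)
      list(name = g$name, n_spectra = g$n_spectra, cell_line = g$cell_line)))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(structure(list(dir = dir,
                           manifest = file.path(dir, "manifest.yaml")),
                      class = "synth_bundle"))
}
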