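test_that("basis generation is deterministic, normalized and identifiable", {
  spec <- synthetic_spec(seed = 33L, grid = tiny_grid(401L))
  b1 <- generate_basis(spec)
  b2 <- generate_basis(spec)
  expect_identical(basis_matrix(b1), basis_matrix(b2))
  expect_identical(b1$activity, b2$activity)
  M <- basis_matrix(b1)
  expect_equal(ncol(M), 20L)
  expect_equal(unname(apply(M, 2, max)), rep(1, 20))
  # pairwise cosine similarity below the identifiability ceiling
  nb <- sweep(M, 2, sqrt(colSums(M^2)), "/")
  cs <- crossprod(nb); diag(cs) <- 0
  expect_lt(max(cs), 0.95)
  expect_true(all(b1$activity >= spec$activity_range[1] &
                    b1$activity <= spec$activity_range[2]))
})

test_that("single-line bases yield exactly one detected peak each", {
  spec <- synthetic_spec(seed = 34L, grid = tiny_grid(601L),
                         n_basis_peaks = c(1L, 1L))
  b <- generate_basis(spec)
  for (a in amino_acids())
    expect_equal(nrow(detect_peaks(b$spectra[[a]])), 1L)
})

test_that("vesicle sets are deterministic with labeled ground truth", {
  spec <- small_study_spec(seed = 35L, n = c(5L, 4L, 3L),
                           grid = tiny_grid(301L))
  basis <- generate_basis(spec)
  v1 <- generate_vesicle_set(spec, basis)
  v2 <- generate_vesicle_set(spec, basis)
  expect_identical(as.matrix(v1$set), as.matrix(v2$set))
  expect_identical(v1$composition, v2$composition)
  expect_equal(length(v1$set), 12L)
  expect_equal(set_meta(v1$set, "fraction", NA_character_),
               rep(c("F7", "F8", "F9"), times = c(5, 4, 3)))
  expect_equal(unname(rowSums(v1$composition)), rep(1, 12), tolerance = 1e-9)
  expect_equal(unname(rowSums(v1$coefficients)), rep(1, 12), tolerance = 1e-9)
  expect_error(generate_vesicle_set(synthetic_spec(seed = 1), basis),
               "no groups")
})

test_that("near-degenerate Dirichlet concentration pins compositions to the mean", {
  means <- local_study_means(36L)
  spec <- synthetic_spec(seed = 36L, grid = tiny_grid(301L), noise_sd = 0,
                         baseline_amplitude = 0,
                         groups = list(synthetic_group("G", 6L, means[[1]],
                                                       concentration = 1e6)))
  basis <- generate_basis(spec)
  v <- generate_vesicle_set(spec, basis)
  expected_coef <- derive_coefficients(means[[1]], basis)
  for (i in 1:6) {
    fit <- fit_composition(v$set[[i]], basis)
    expect_lt(max(abs(fit$coefficients - expected_coef)), 1e-3)
  }
})

test_that("groups with disjoint amino-acid support separate with zero overlap", {
  aa <- amino_acids()
  c1 <- composition_vector(setNames(c(rep(1, 10), rep(0, 10)), aa))
  c2 <- composition_vector(setNames(c(rep(0, 10), rep(1, 10)), aa))
  spec <- synthetic_spec(seed = 37L, grid = tiny_grid(401L), noise_sd = 0.01,
                         baseline_amplitude = 0,
                         groups = list(synthetic_group("g1", 10L, c1, 500),
                                       synthetic_group("g2", 10L, c2, 500)))
  basis <- generate_basis(spec)
  v <- generate_vesicle_set(spec, basis)
  emb <- fit_lda(v$set, set_meta(v$set, "fraction", NA_character_))
  expect_equal(emb$dims, 1L)
  s1 <- emb$scores[1:10, 1]; s2 <- emb$scores[11:20, 1]
  expect_equal(overlap_rate_range1d(s1, s2), 0)
  expect_equal(overlap_rate_range1d(s2, s1), 0)
})

test_that("MS fixtures reproduce arbitrary compositions exactly", {
  # delta composition: every sequence is a homopolymer
  delta <- composition_vector(setNames(c(rep(0, 5), 1, rep(0, 14)),
                                       amino_acids()))  # G
  ms <- generate_ms_fixture(delta, n_proteins = 5L, seed = 40L)
  expect_true(all(grepl("^G+$", ms$table$sequence)))
  expect_equal(as.numeric(amino_acid_frequencies(ms$table)["G"]), 1)
  # uniform composition at the study's 90 proteins
  u <- uniform_composition()
  msu <- generate_ms_fixture(u, n_proteins = 90L, seed = 41L)
  expect_equal(nrow(msu$table), 90L)
  expect_lt(max(abs(amino_acid_frequencies(msu$table) - u)), 1e-6)
  # byte-determinism of the FASTA text
  msu2 <- generate_ms_fixture(u, n_proteins = 90L, seed = 41L)
  expect_identical(msu$fasta, msu2$fasta)
  expect_false(identical(
    generate_ms_fixture(u, n_proteins = 90L, seed = 42L)$fasta, msu$fasta))
})

test_that("MS fixture survives the file round trip through the loaders", {
  set.seed(43)
  comp <- random_composition()
  ms <- generate_ms_fixture(comp, n_proteins = 30L, seed = 43L)
  csv <- tempfile(fileext = ".csv")
  write.csv(ms$table[, c("protein_id", "rel_abundance")], csv,
            row.names = FALSE, quote = FALSE)
  fa <- tempfile(fileext = ".fasta")
  writeLines(ms$fasta, fa)
  tab <- attach_sequences(load_protein_abundances(csv), fa)
  expect_lt(max(abs(amino_acid_frequencies(tab) - comp)), 1e-6)
})

test_that("the full forward chain is recovered end to end at zero noise", {
  # composition -> MS fixture -> frequencies -> coefficients -> spectrum ->
  # unmixing, exercising every in-scope computation
  set.seed(44)
  comp <- random_composition()
  spec <- synthetic_spec(seed = 44L, grid = tiny_grid(601L))
  basis <- generate_basis(spec)
  ms <- generate_ms_fixture(comp, n_proteins = 60L, seed = 45L)
  freq <- amino_acid_frequencies(ms$table)
  coefs <- derive_coefficients(freq, basis)
  fit <- fit_composition(simulate_spectrum(coefs, basis), basis)
  expect_lt(max(abs(fit$coefficients - coefs)), 1e-6)
})

test_that("range-rule overlap of Gaussian scores matches its conditional closed form", {
  # given B's observed range, each A point falls inside independently with
  # p = F(max B) - F(min B); the observed rate must sit within 3 binomial
  # standard errors
  set.seed(46)
  n <- 1000L
  b <- rnorm(n, 0, 1)
  a <- rnorm(n, 1, 1.5)
  p_in <- pnorm(max(b), 1, 1.5) - pnorm(min(b), 1, 1.5)
  got <- overlap_rate_range1d(a, b) / 100
  se <- sqrt(p_in * (1 - p_in) / n)
  expect_lt(abs(got - p_in), 3 * se)
})

test_that("written bundles contain every pipeline input", {
  spec <- small_study_spec(seed = 47L, n = c(4L, 4L, 4L),
                           grid = tiny_grid(201L))
  dir <- tempfile("bundle_")
  bundle <- write_synthetic_bundle(spec, dir, n_proteins = 25L)
  expect_true(file.exists(file.path(dir, "manifest.yaml")))
  expect_true(file.exists(file.path(dir, "vesicles.tsv")))
  expect_true(file.exists(file.path(dir, "proteins.fasta")))
  expect_equal(length(list.files(file.path(dir, "basis"))), 20L)
  truth <- read.csv(file.path(dir, "truth_coefficients.csv"),
                    check.names = FALSE)
  expect_equal(nrow(truth), 12L)
  back <- read_map_table(file.path(dir, "vesicles.tsv"))
  expect_equal(length(back), 12L)
  expect_equal(set_meta(back, "fraction", NA_character_),
               rep(c("F7", "F8", "F9"), each = 4))
})
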