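write_protein_csv <- function(df) {
  p <- tempfile(fileext = ".csv")
  write.csv(df, p, row.names = FALSE, quote = FALSE)
  p
}

write_fasta <- function(named, wrap = NULL) {
  p <- tempfile(fileext = ".fasta")
  lines <- unlist(lapply(names(named), function(id) {
    s <- named[[id]]
    body <- if (is.null(wrap)) s else {
      starts <- seq(1, nchar(s), by = wrap)
      substring(s, starts, pmin(starts + wrap - 1, nchar(s)))
    }
    c(paste0(">", id), body)
  }))
  writeLines(lines, p)
  p
}

test_that("abundance loading renormalizes and validates", {
  p <- write_protein_csv(data.frame(protein_id = c("P1", "P2", "P3"),
                                    rel_abundance = c(2, 3, 5)))
  tab <- load_protein_abundances(p)
  expect_equal(tab$rel_abundance, c(0.2, 0.3, 0.5))
  p1 <- write_protein_csv(data.frame(protein_id = "P1", rel_abundance = 7))
  expect_equal(load_protein_abundances(p1)$rel_abundance, 1)
  pneg <- write_protein_csv(data.frame(protein_id = "P1", rel_abundance = -1))
  expect_error(load_protein_abundances(pneg), "negative")
  pbad <- write_protein_csv(data.frame(protein_id = "P1", foo = 1))
  expect_error(load_protein_abundances(pbad), "abundance column")
})

test_that("sequence attachment matches ids and reports missing ones", {
  p <- write_protein_csv(data.frame(protein_id = c("P1", "P2"),
                                    rel_abundance = c(1, 1)))
  tab <- load_protein_abundances(p)
  fa <- write_fasta(list(P1 = "ACDG", P2 = "GGGG"))
  out <- attach_sequences(tab, fa)
  expect_equal(out$sequence, c("ACDG", "GGGG"))
  fa_missing <- write_fasta(list(P1 = "ACDG"))
  expect_error(attach_sequences(tab, fa_missing), "P2")
  # line-wrapped sequences concatenate
  long <- paste(rep("ACDEFGHIKL", 13), collapse = "")
  fa_wrap <- write_fasta(list(P1 = long, P2 = "GG"), wrap = 60)
  out2 <- attach_sequences(tab, fa_wrap)
  expect_equal(nchar(out2$sequence[1]), 130L)
})

test_that("amino-acid frequencies follow the abundance-weighted molar formula", {
  mk <- function(ids, ab, seqs) {
    tab <- load_protein_abundances(
      write_protein_csv(data.frame(protein_id = ids, rel_abundance = ab)))
    attach_sequences(tab, write_fasta(setNames(as.list(seqs), ids)))
  }
  f1 <- amino_acid_frequencies(mk("P1", 1, "GG"))
  expect_equal(as.numeric(f1["G"]), 1)
  expect_equal(sum(f1), 1, tolerance = 1e-12)
  f2 <- amino_acid_frequencies(mk(c("P1", "P2"), c(.5, .5), c("A", "V")))
  expect_equal(as.numeric(f2[c("A", "V")]), c(0.5, 0.5))
  # hand count: "AV" (w=.5) + "A" (w=.5): A = (.5*1+.5*1)/(.5*2+.5*1) = 2/3
  f3 <- amino_acid_frequencies(mk(c("P1", "P2"), c(.5, .5), c("AV", "A")))
  expect_equal(as.numeric(f3["A"]), 2 / 3, tolerance = 1e-12)
  expect_equal(as.numeric(f3["V"]), 1 / 3, tolerance = 1e-12)
})

test_that("frequencies are invariant to common rescaling and row duplication", {
  mk_tab <- function(ab) {
    tab <- load_protein_abundances(write_protein_csv(
      data.frame(protein_id = paste0("P", seq_along(ab)),
                 rel_abundance = ab)))
    seqs <- c("ACDE", "GGKL", "VVVY", "MNPQ")[seq_along(ab)]
    attach_sequences(tab, write_fasta(setNames(as.list(seqs),
                                               tab$protein_id)))
  }
  f_base <- amino_acid_frequencies(mk_tab(c(1, 2, 3)))
  f_scaled <- amino_acid_frequencies(mk_tab(c(10, 20, 30)))
  expect_equal(as.numeric(f_base), as.numeric(f_scaled), tolerance = 1e-12)
  # duplicating a protein while halving its abundance changes nothing
  tab <- load_protein_abundances(write_protein_csv(
    data.frame(protein_id = c("P1", "P2"), rel_abundance = c(2, 4))))
  tab <- attach_sequences(tab, write_fasta(list(P1 = "ACDE", P2 = "GGKL")))
  tab_dup <- load_protein_abundances(write_protein_csv(
    data.frame(protein_id = c("P1", "P2", "P3"),
               rel_abundance = c(2, 2, 2))))
  tab_dup <- attach_sequences(tab_dup, write_fasta(
    list(P1 = "ACDE", P2 = "GGKL", P3 = "GGKL")))
  expect_equal(as.numeric(amino_acid_frequencies(tab)),
               as.numeric(amino_acid_frequencies(tab_dup)),
               tolerance = 1e-12)
})

test_that("comparison statistics match an independent recomputation", {
  idn <- compare_to_reference(human_aa_frequencies(), human_aa_frequencies())
  expect_equal(idn$pearson, 1)
  expect_equal(idn$mean_rel_dev_pct, 0)
  u <- uniform_composition()
  expect_equal(compare_to_reference(u, u)$mean_rel_dev_pct, 0)
  # two fixed hand-written vectors, spreadsheet-style recomputation
  set.seed(3)
  a <- random_composition()
  b <- random_composition()
  cmpr <- compare_to_reference(a, b)
  av <- as.numeric(a); bv <- as.numeric(b)
  r_manual <- sum((av - mean(av)) * (bv - mean(bv))) /
    sqrt(sum((av - mean(av))^2) * sum((bv - mean(bv))^2))
  dev_manual <- 100 * sum(abs(av - bv) / bv) / 20
  expect_equal(cmpr$pearson, r_manual, tolerance = 1e-12)
  expect_equal(cmpr$mean_rel_dev_pct, dev_manual, tolerance = 1e-12)
  expect_equal(unname(cmpr$differences), av - bv)
})

test_that("composition vectors validate keys, sign and sum", {
  expect_error(composition_vector(c(A = 1)), "missing amino acids")
  x <- setNames(rep(0.05, 20), amino_acids())
  expect_silent(composition_vector(x, normalize = FALSE))
  x[1] <- -0.01
  expect_error(composition_vector(x), "non-negative")
  y <- setNames(runif(21), c(amino_acids(), "Z"))
  expect_error(composition_vector(y), "unknown")
  p <- tempfile(fileext = ".csv")
  write_composition(human_aa_frequencies(), p)
  expect_equal(as.numeric(read_composition(p)),
               as.numeric(human_aa_frequencies()), tolerance = 1e-9)
})
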