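make_clouds <- function(n = 50, p = 1117, sep = 10, sigma = 1, seed = 23) {
  set.seed(seed)
  mu <- rep(0, p)
  x1 <- matrix(rnorm(n * p, 0, sigma), n, p)
  x2 <- matrix(rnorm(n * p, 0, sigma), n, p)
  x2[, 1] <- x2[, 1] + sep * sigma
  list(x = rbind(x1, x2), labels = rep(c("a", "b"), each = n))
}

test_that("well-separated high-dimensional clouds give non-overlapping scores", {
  cl <- make_clouds()
  emb <- fit_lda(cl$x, cl$labels)
  expect_equal(emb$dims, 1L)
  sa <- emb$scores[cl$labels == "a", 1]
  sb <- emb$scores[cl$labels == "b", 1]
  expect_true(max(sa) < min(sb) || max(sb) < min(sa))
  expect_equal(overlap_rate_range1d(sa, sb), 0)
  # permutation control: shuffled labels shrink the centroid separation
  sep_true <- abs(diff(range(emb$class_means[, 1])))
  set.seed(9)
  emb_perm <- fit_lda(cl$x, sample(cl$labels))
  sep_perm <- abs(diff(range(emb_perm$class_means[, 1])))
  expect_lt(sep_perm, sep_true)
})

test_that("embedding dimension is min(groups - 1, 2) and errors are raised", {
  set.seed(41)
  x <- matrix(rnorm(30 * 50), 30, 50)
  expect_equal(fit_lda(x, rep(c("a", "b"), 15))$dims, 1L)
  expect_equal(fit_lda(x, rep(c("a", "b", "c"), 10))$dims, 2L)
  expect_equal(fit_lda(x, rep(c("a", "b", "c", "d", "e"), 6))$dims, 2L)
  expect_error(fit_lda(x, rep("a", 30)), "2 groups")
  expect_error(fit_lda(x, c("a", rep("b", 29))), "2 spectra")
})

test_that("transform reproduces training scores and maps class means to centroids", {
  set.seed(6)
  spec <- small_study_spec(seed = 6, n = c(8L, 8L, 8L),
                           grid = tiny_grid(301L))
  basis <- generate_basis(spec)
  ves <- generate_vesicle_set(spec, basis)
  labels <- set_meta(ves$set, "fraction", NA_character_)
  emb <- fit_lda(ves$set, labels)
  re <- transform_lda(emb, ves$set)
  expect_equal(unname(re), unname(emb$scores), tolerance = 1e-9)
  # the mean spectrum of a class scores at (approximately) its centroid:
  # exact because the projection is linear
  xm <- colMeans(as.matrix(ves$set)[labels == "F7", , drop = FALSE])
  sc <- transform_lda(emb, matrix(xm, 1))
  expect_equal(unname(sc[1, ]), unname(emb$class_means["F7", ]),
               tolerance = 1e-9)
  # zero spectrum projects the offset term, finite
  z <- transform_lda(emb, matrix(0, 1, 301))
  expect_true(all(is.finite(z)))
  wrong_grid <- spectrum_set(list(new_spectrum(rep(1, 100), tiny_grid(100L))))
  expect_error(transform_lda(emb, wrong_grid), "grid")
})

test_that("LDA agrees with a reference implementation on well-posed data", {
  skip_if_not_installed("MASS")
  set.seed(15)
  n <- 60; p <- 5
  x <- matrix(rnorm(n * p), n, p)
  lab <- rep(c("a", "b"), each = n / 2)
  x[lab == "b", 2] <- x[lab == "b", 2] + 2
  ours <- fit_lda(x, lab, shrinkage = 0)$scores[, 1]
  theirs <- as.numeric(predict(MASS::lda(x, grouping = lab))$x[, 1])
  # discriminant axes are defined up to affine scale: scores must be
  # perfectly correlated
  expect_gt(abs(cor(ours, theirs)), 1 - 1e-9)
})

test_that("1-D range overlap matches hand enumeration and affine invariance", {
  expect_equal(overlap_rate_range1d(c(1, 2, 3), c(1, 2, 3)), 100)
  expect_equal(overlap_rate_range1d(c(10, 11), c(1, 2)), 0)
  expect_equal(overlap_rate_range1d(c(0, 1, 2, 3), c(0.5, 2.5)), 50)
  set.seed(44)
  a <- rnorm(100); b <- rnorm(100, 1)
  r0 <- overlap_rate_range1d(a, b)
  expect_equal(overlap_rate_range1d(3 * a + 7, 3 * b + 7), r0)
  expect_error(overlap_rate_range1d(numeric(0), b), "non-empty")
})

test_that("hull-rule overlap handles separation, duplication and planting", {
  # two disjoint clusters: 0% both directions
  set.seed(50)
  s1 <- cbind(rnorm(30), rnorm(30))
  s2 <- cbind(rnorm(30) + 50, rnorm(30))
  rep0 <- overlap_rate_groups(rbind(s1, s2),
                              rep(c("a", "b"), each = 30), "hull2d")
  expect_equal(unname(rep0$pairwise["a", "b"]), 0)
  expect_equal(unname(rep0$pairwise["b", "a"]), 0)
  # identical coordinates: boundary counts as inside -> 100%
  dup <- overlap_rate_groups(rbind(s1, s1), rep(c("a", "b"), each = 30),
                             "hull2d")
  expect_equal(unname(dup$pairwise["a", "b"]), 100)
  # planted 10% overlap: 90% of group a far away, 10% at b's centroid
  set.seed(51)
  b_pts <- cbind(rnorm(200), rnorm(200))
  a_far <- cbind(rnorm(180) + 40, rnorm(180))
  a_in <- cbind(rnorm(20, 0, 0.05), rnorm(20, 0, 0.05))
  planted <- overlap_rate_groups(rbind(b_pts, a_far, a_in),
                                 c(rep("b", 200), rep("a", 200)), "hull2d")
  expect_lt(abs(planted$pairwise["a", "b"] - 10), 4)
})

test_that("classify-rule overlaps for one group sum to at most 100", {
  set.seed(52)
  x <- rbind(cbind(rnorm(40), rnorm(40)),
             cbind(rnorm(40, 2), rnorm(40)),
             cbind(rnorm(40), rnorm(40, 2)))
  lab <- rep(c("a", "b", "c"), each = 40)
  rep1 <- overlap_rate_groups(x, lab, "classify")
  for (i in c("a", "b", "c"))
    expect_lte(sum(rep1$pairwise[i, ], na.rm = TRUE), 100 + 1e-9)
})

test_that("widely separated 3-group synthetic data shows zero overlap under all rules", {
  set.seed(53)
  centers <- rbind(c(0, 0), c(30, 0), c(0, 30))
  x <- do.call(rbind, lapply(1:3, function(k)
    cbind(rnorm(40, centers[k, 1]), rnorm(40, centers[k, 2]))))
  lab <- rep(c("a", "b", "c"), each = 40)
  for (rule in c("hull2d", "classify")) {
    pw <- overlap_rate_groups(x, lab, rule)$pairwise
    expect_true(all(pw[!is.na(pw)] == 0))
  }
})

test_that("pooled two-cell-type analysis recovers per-fraction overlap ordering", {
  # construct 1117-dim data where the two cell types differ along one axis
  # and the query fractions are planted with increasing overlap
  set.seed(54)
  p <- 300
  ref <- matrix(rnorm(120 * p), 120, p)
  mk_frac <- function(n, n_in, shift) {
    m <- matrix(rnorm(n * p), n, p)
    m[, 1] <- m[, 1] + shift          # far from ref along axis 1
    if (n_in > 0) m[seq_len(n_in), 1] <- rnorm(n_in)  # planted common
    m
  }
  q7 <- mk_frac(40, 2, 25); q8 <- mk_frac(40, 4, 25); q9 <- mk_frac(40, 6, 25)
  g <- tiny_grid(p)
  as_set <- function(m, frac, cell) spectrum_set(lapply(seq_len(nrow(m)),
    function(i) new_spectrum(m[i, ], g, meta = list(
      fraction = frac[i], cell_line = cell))))
  set_ref <- as_set(ref, rep("F0", 120), "HEK293")
  set_q <- as_set(rbind(q7, q8, q9),
                  rep(c("F7", "F8", "F9"), each = 40), "HEK293+HRAS")
  rep2 <- pooled_fraction_overlap(set_ref, set_q)
  per <- rep2$per_fraction
  expect_equal(names(per), c("F7", "F8", "F9"))
  expect_true(per[["F7"]] <= per[["F8"]] && per[["F8"]] <= per[["F9"]])
  expect_equal(rep2$embedding$dims, 1L)
})
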