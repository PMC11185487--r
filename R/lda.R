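#' Fisher linear discriminant analysis for high-dimensional spectra
#'
#' Supervised dimensionality reduction of a spectrum collection where the
#' feature dimension (grid points, canonically 1117) far exceeds the number
#' of spectra per group. The within-class scatter is therefore singular, so
#' the discriminant directions are computed in the span of the data via SVD
#' and a tolerance-based pseudo-inverse -- the standard n << p route. The
#' embedding dimension is `min(n_groups - 1, 2)`: one LD axis for a binary
#' system, two for three or more groups. Conventions are fixed for
#' reproducibility: axes ordered by decreasing discriminant eigenvalue, and
#' each loading's first non-negligible element made positive.
#'
#' @param x A `sers_set` (preprocessed: baseline-corrected and normalized)
#'   or a numeric matrix with one row per spectrum.
#' @param labels Group label per spectrum; at least 2 groups with at least 2
#'   members each.
#' @param shrinkage Within-class scatter shrinkage in `[0, 1)`: the scatter
#'   is blended with a spherical target,
#'   `(1 - shrinkage) * Sw + shrinkage * mean(eigenvalue) * I`. With far
#'   fewer spectra than grid points an unshrunk discriminant can separate
#'   any labeling perfectly by exploiting noise dimensions; the default 0.1
#'   keeps the direction anchored to reproducible spectral structure.
#'   `shrinkage = 0` gives the pure pseudo-inverse solution.
#' @return Object of class `sers_lda`: `scores` (n x dims), `labels`,
#'   `loadings` (p x dims), `center`, `eigenvalues`, `class_means` (group
#'   centroids in score space), `dims`, `grid` (when fitted on a set).
#' @export
fit_lda <- function(x, labels, shrinkage = 0.1) {
  stopifnot(shrinkage >= 0, shrinkage < 1)
  grid <- NULL
  if (inherits(x, "sers_set")) {
    grid <- x$grid
    x <- as.matrix(x)
  }
  x <- as.matrix(x)
  labels <- factor(labels)
  if (nrow(x) != length(labels)) stop("labels length must match spectra count")
  tabn <- table(labels)
  if (length(tabn) < 2L) stop("LDA needs at least 2 groups")
  if (any(tabn < 2L))
    stop("every group needs >= 2 spectra; offending: ",
         paste(names(tabn)[tabn < 2L], collapse = ", "))
  g <- length(tabn)
  dims <- min(g - 1L, 2L)

  center <- colMeans(x)
  xc <- sweep(x, 2L, center)
  sv <- svd(xc)
  tol <- max(dim(xc)) * max(sv$d) * .Machine$double.eps
  r <- sum(sv$d > tol)
  if (r < 1L) stop("degenerate data: zero variance")
  V <- sv$v[, seq_len(r), drop = FALSE]
  z <- xc %*% V                                  # n x r, full data span

  # scatter matrices in the reduced space
  Sw <- matrix(0, r, r)
  Sb <- matrix(0, r, r)
  for (lv in levels(labels)) {
    zi <- z[labels == lv, , drop = FALSE]
    mu <- colMeans(zi)
    zi_c <- sweep(zi, 2L, mu)
    Sw <- Sw + crossprod(zi_c)
    Sb <- Sb + nrow(zi) * tcrossprod(mu)         # global mean of z is 0
  }
  if (shrinkage > 0) {
    tr_mean <- sum(diag(Sw)) / r
    Sw <- (1 - shrinkage) * Sw
    diag(Sw) <- diag(Sw) + shrinkage * tr_mean
  }
  ew <- eigen(Sw, symmetric = TRUE)
  wtol <- max(r, 1) * max(ew$values, 0) * .Machine$double.eps
  # ridge floor keeps perfectly separable groups (Sw rank-deficient along the
  # discriminant) from producing unbounded directions
  lam <- pmax(ew$values, max(wtol, 1e-10 * max(ew$values, 1)))
  Wi <- ew$vectors %*% (t(ew$vectors) / sqrt(lam)) # Sw^(-1/2), pseudo
  M <- Wi %*% Sb %*% Wi
  em <- eigen((M + t(M)) / 2, symmetric = TRUE)
  A <- Wi %*% em$vectors[, seq_len(dims), drop = FALSE]
  loadings <- V %*% A                             # p x dims

  # sign convention: first element exceeding 1e-8 of the column max is positive
  for (k in seq_len(dims)) {
    v <- loadings[, k]
    i <- which(abs(v) > 1e-8 * max(abs(v)))[1L]
    if (v[i] < 0) { loadings[, k] <- -v; A[, k] <- -A[, k] }
  }
  scores <- xc %*% loadings
  colnames(scores) <- paste0("LD", seq_len(dims))
  cm <- do.call(rbind, lapply(levels(labels), function(lv)
    colMeans(scores[labels == lv, , drop = FALSE])))
  rownames(cm) <- levels(labels)
  structure(list(scores = scores, labels = labels, loadings = loadings,
                 center = center,
                 eigenvalues = em$values[seq_len(dims)],
                 class_means = cm, dims = dims, grid = grid),
            class = "sers_lda")
}

#' @export
print.sers_lda <- function(x, ...) {
  cat(sprintf("<sers_lda> %d spectra, %d groups -> %d dim(s)\n",
              nrow(x$scores), nlevels(x$labels), x$dims))
  invisible(x)
}

#' Project spectra with a fitted discriminant model
#'
#' @param embedding A `sers_lda` from [fit_lda()].
#' @param x A `sers_set` (grid must match the training grid) or matrix.
#' @return Score matrix (n x dims). Transforming the training data
#'   reproduces the stored scores.
#' @export
transform_lda <- function(embedding, x) {
  stopifnot(inherits(embedding, "sers_lda"))
  if (inherits(x, "sers_set")) {
    if (!is.null(embedding$grid) && !same_grid(x$grid, embedding$grid))
      stop("spectrum grid does not match the LDA training grid")
    x <- as.matrix(x)
  }
  x <- matrix(as.numeric(x), ncol = length(embedding$center))
  s <- sweep(x, 2L, embedding$center) %*% embedding$loadings
  colnames(s) <- colnames(embedding$scores)
  s
}

#' Plot a discriminant embedding
#' @param x A `sers_lda`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.sers_lda <- function(x, ...) {
  cols <- as.integer(x$labels)
  if (x$dims == 1L) {
    graphics::stripchart(split(x$scores[, 1L], x$labels), method = "jitter",
                         pch = 19, col = seq_len(nlevels(x$labels)),
                         xlab = "LD1", ...)
  } else {
    graphics::plot(x$scores[, 1L], x$scores[, 2L], col = cols, pch = 19,
                   xlab = "LD1", ylab = "LD2", ...)
    graphics::legend("topright", legend = levels(x$labels),
                     col = seq_len(nlevels(x$labels)), pch = 19, bty = "n")
  }
  invisible(x)
}

#' One-dimensional range overlap rate
#'
#' Percentage of group A's LD scores lying within the score range spanned by
#' group B -- the "common vesicle" measure for a binary (1-D) discriminant
#' map. Invariant under any common positive-scale affine map of both sets.
#'
#' @param a,b Numeric score vectors; both non-empty.
#' @return Percent in `[0, 100]`.
#' @export
overlap_rate_range1d <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("overlap needs non-empty score sets")
  100 * mean(a >= min(b) & a <= max(b))
}

# Inclusive point-in-convex-hull test; degenerate hulls (collinear or
# coincident points) fall back to segment / point membership with tolerance.
.in_hull <- function(pts, hull_pts, tol_frac = 1e-9) {
  scale <- max(1, max(abs(hull_pts)))
  tol <- tol_frac * scale
  spread <- apply(hull_pts, 2L, function(v) diff(range(v)))
  if (all(spread <= tol)) {                      # single point
    c0 <- colMeans(hull_pts)
    return(sqrt((pts[, 1L] - c0[1L])^2 + (pts[, 2L] - c0[2L])^2) <= tol)
  }
  h <- grDevices::chull(hull_pts)
  hp <- hull_pts[h, , drop = FALSE]
  if (nrow(hp) >= 3L) {
    # force clockwise orientation (negative shoelace area)
    xs <- hp[, 1L]; ys <- hp[, 2L]
    area2 <- sum(xs * c(ys[-1L], ys[1L]) - c(xs[-1L], xs[1L]) * ys)
    if (area2 > 0) hp <- hp[rev(seq_len(nrow(hp))), , drop = FALSE]
  }
  if (nrow(hp) <= 2L || {
    # collinearity check on the hull vertices
    v1 <- hp[2L, ] - hp[1L, ]
    all(abs((hp[, 1L] - hp[1L, 1L]) * v1[2L] -
            (hp[, 2L] - hp[1L, 2L]) * v1[1L]) <= tol * sqrt(sum(v1^2)))
  }) {                                           # segment membership
    d <- hull_pts[which.max(rowSums(sweep(hull_pts, 2L, hull_pts[1L, ])^2)), ] -
      hull_pts[1L, ]
    len2 <- sum(d^2)
    t0 <- (sweep(pts, 2L, hull_pts[1L, ]) %*% d) / len2
    proj <- outer(as.numeric(t0), d) + rep(hull_pts[1L, ], each = nrow(pts))
    dist <- sqrt(rowSums((pts - proj)^2))
    return(dist <= tol & t0 >= -tol & t0 <= 1 + tol)
  }
  nh <- nrow(hp)
  inside <- rep(TRUE, nrow(pts))
  for (k in seq_len(nh)) {
    p1 <- hp[k, ]; p2 <- hp[if (k == nh) 1L else k + 1L, ]
    e <- p2 - p1
    # cross = e x (q - p1); with clockwise vertices the interior lies to the
    # right of each edge, i.e. cross <= 0
    cr <- e[1L] * (pts[, 2L] - p1[2L]) - e[2L] * (pts[, 1L] - p1[1L])
    inside <- inside & (cr <= tol * sqrt(sum(e^2)))
  }
  inside
}

#' Pairwise group overlap rates in a discriminant embedding
#'
#' For every ordered group pair (i, j), the percentage of group i's points
#' "common" with group j. Rules: `"hull2d"` (default for 2-D scores) counts
#' a point as common if it lies inside (boundary inclusive) the convex hull
#' of group j's scores; `"classify"` if the nearest group centroid in score
#' space is j's; `"range1d"` applies [overlap_rate_range1d()] on the first
#' LD axis.
#'
#' @param x A `sers_lda`, or a score matrix/vector with `labels` supplied.
#' @param labels Group labels (ignored when `x` is a `sers_lda`).
#' @param rule `"hull2d"`, `"classify"`, or `"range1d"`.
#' @return Object of class `overlap_report`: `pairwise` percent matrix (rows
#'   = group i, columns = group j), `any_other` (percent of group i common
#'   with at least one other group, hull/range rules) and `rule`.
#' @export
overlap_rate_groups <- function(x, labels = NULL,
                                rule = c("hull2d", "classify", "range1d")) {
  rule <- match.arg(rule)
  if (inherits(x, "sers_lda")) {
    scores <- x$scores
    labels <- x$labels
  } else {
    scores <- as.matrix(x)
    if (is.null(labels)) stop("labels required with raw scores")
  }
  labels <- factor(labels)
  lv <- levels(labels)
  if (length(lv) < 2L) stop("overlap needs >= 2 groups")
  if (rule == "hull2d" && ncol(scores) < 2L)
    stop("hull2d rule needs 2-D scores; use range1d for 1-D embeddings")
  pw <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  common_any <- stats::setNames(rep(0, length(lv)), lv)
  if (rule == "classify") {
    cm <- do.call(rbind, lapply(lv, function(l)
      colMeans(scores[labels == l, , drop = FALSE])))
    d2 <- sapply(seq_along(lv), function(k)
      rowSums(sweep(scores, 2L, cm[k, ])^2))
    assigned <- lv[max.col(-d2, ties.method = "first")]
    for (i in lv) for (j in lv) if (i != j)
      pw[i, j] <- 100 * mean(assigned[labels == i] == j)
    common_any <- vapply(lv, function(i)
      100 * mean(assigned[labels == i] != i), 0)
  } else {
    for (i in lv) {
      pi <- scores[labels == i, , drop = FALSE]
      hit_any <- rep(FALSE, nrow(pi))
      for (j in lv) {
        if (i == j) next
        pj <- scores[labels == j, , drop = FALSE]
        hits <- if (rule == "hull2d") {
          if (nrow(pj) < 3L)
            stop("hull2d: group '", j, "' has fewer than 3 points")
          .in_hull(pi[, 1:2, drop = FALSE], pj[, 1:2, drop = FALSE])
        } else {
          pi[, 1L] >= min(pj[, 1L]) & pi[, 1L] <= max(pj[, 1L])
        }
        pw[i, j] <- 100 * mean(hits)
        hit_any <- hit_any | hits
      }
      common_any[i] <- 100 * mean(hit_any)
    }
  }
  structure(list(pairwise = pw, any_other = common_any, rule = rule),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> rule = %s\n", x$rule))
  print(round(x$pairwise, 1))
  if (!is.null(x$per_fraction)) {
    cat("per-fraction overlap (%):\n")
    print(round(x$per_fraction, 1))
  }
  invisible(x)
}

#' Pooled two-cell-type overlap per fraction
#'
#' Pools the spectra of two cell types (each spanning several SEC
#' fractions), fits a binary one-dimensional discriminant on cell type, and
#' reports, for each fraction of the query cell type, the percentage of that
#' fraction's LD scores falling within the score range of the reference cell
#' type -- the per-fraction "common vesicle" rate of the pooled map.
#'
#' @param set_ref Reference cell type's `sers_set` (e.g. the control line).
#' @param set_query Query cell type's `sers_set` (e.g. the perturbed line).
#' @param fractions_query Fraction label per query spectrum; defaults to the
#'   `fraction` metadata field.
#' @return `overlap_report` with a `per_fraction` percent vector and the
#'   fitted `sers_lda` attached as `embedding`.
#' @export
pooled_fraction_overlap <- function(set_ref, set_query,
                                    fractions_query = NULL,
                                    shrinkage = 0.1) {
  stopifnot(inherits(set_ref, "sers_set"), inherits(set_query, "sers_set"))
  if (!same_grid(set_ref$grid, set_query$grid))
    stop("the two sets are not on a shared grid")
  if (is.null(fractions_query))
    fractions_query <- set_meta(set_query, "fraction", NA_character_)
  if (any(is.na(fractions_query)))
    stop("query fractions missing; supply fractions_query")
  x <- rbind(as.matrix(set_ref), as.matrix(set_query))
  cell <- c(rep("ref", length(set_ref)), rep("query", length(set_query)))
  emb <- fit_lda(x, cell, shrinkage = shrinkage)
  s_ref <- emb$scores[cell == "ref", 1L]
  s_query <- emb$scores[cell == "query", 1L]
  fr <- factor(fractions_query)
  per <- vapply(levels(fr), function(f)
    overlap_rate_range1d(s_query[fr == f], s_ref), 0)
  structure(list(pairwise = NULL, any_other = NULL,
                 per_fraction = per, rule = "range1d",
                 embedding = emb),
            class = "overlap_report")
}
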