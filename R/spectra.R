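#' Amino-acid one-letter codes
#'
#' The 20 standard amino acids in alphabetical one-letter order. This is the
#' canonical key order of every composition vector and amino-acid basis in the
#' package.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' amino_acids()
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Construct a wavenumber grid
#'
#' A grid is the shared Raman-shift axis (cm^-1) of a spectrum collection.
#' The default reproduces the acquisition axis used throughout the package:
#' 564 to 1681 cm^-1 sampled at 1117 points (about 1.0009 cm^-1 spacing).
#' A grid may also be built from an explicit, possibly non-uniform, strictly
#' increasing axis via `axis=`; uniform construction is the canonical form.
#'
#' @param start First wavenumber (cm^-1).
#' @param end Last wavenumber (cm^-1); must exceed `start`.
#' @param n_points Number of samples (>= 2).
#' @param axis Optional explicit axis; overrides the other arguments.
#' @return An object of class `sers_grid`.
#' @export
#' @examples
#' g <- wavenumber_grid()
#' length(wavenumbers(g))
wavenumber_grid <- function(start = 564, end = 1681, n_points = 1117,
                            axis = NULL) {
  if (!is.null(axis)) {
    axis <- as.numeric(axis)
    if (length(axis) < 2L) stop("grid axis needs at least 2 points")
    if (any(!is.finite(axis))) stop("grid axis must be finite")
    if (any(diff(axis) <= 0)) stop("grid axis must be strictly increasing")
    g <- list(start = axis[1L], end = axis[length(axis)],
              n_points = length(axis), axis = axis)
  } else {
    stopifnot(is.finite(start), is.finite(end), n_points >= 2L)
    if (start >= end) stop("grid start must be below end")
    g <- list(start = start, end = end, n_points = as.integer(n_points),
              axis = seq(start, end, length.out = n_points))
  }
  class(g) <- "sers_grid"
  g
}

#' Wavenumber axis of a grid or spectrum
#' @param x A `sers_grid` or `sers_spectrum`.
#' @return Numeric vector of wavenumbers (cm^-1), strictly increasing.
#' @export
wavenumbers <- function(x) {
  if (inherits(x, "sers_spectrum")) return(x$grid$axis)
  if (inherits(x, "sers_grid")) return(x$axis)
  stop("wavenumbers() expects a sers_grid or sers_spectrum")
}

#' @export
print.sers_grid <- function(x, ...) {
  cat(sprintf("<sers_grid> %g..%g cm^-1, %d points\n",
              x$start, x$end, x$n_points))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-9) {
  a$n_points == b$n_points &&
    max(abs(a$axis - b$axis)) <= tol * max(1, max(abs(a$axis)))
}

#' Construct a single SERS spectrum
#'
#' @param intensities Numeric intensity vector (arbitrary units), finite,
#'   length `grid$n_points`.
#' @param grid A `sers_grid`.
#' @param meta Named list of metadata (e.g. `sample_id`, `cell_line`,
#'   `fraction`, `map_x`, `map_y`).
#' @return Object of class `sers_spectrum` with fields `grid`, `intensities`,
#'   `meta`.
#' @export
#' @examples
#' s <- new_spectrum(sin(seq_len(1117) / 50), wavenumber_grid())
new_spectrum <- function(intensities, grid, meta = list()) {
  if (!inherits(grid, "sers_grid")) stop("grid must be a sers_grid")
  intensities <- as.numeric(intensities)
  if (length(intensities) != grid$n_points)
    stop(sprintf("intensity length %d does not match grid (%d points)",
                 length(intensities), grid$n_points))
  if (any(!is.finite(intensities))) stop("intensities must be finite")
  structure(list(grid = grid, intensities = intensities, meta = meta),
            class = "sers_spectrum")
}

#' @export
print.sers_spectrum <- function(x, ...) {
  cat(sprintf("<sers_spectrum> %d points, %g..%g cm^-1",
              x$grid$n_points, x$grid$start, x$grid$end))
  if (length(x$meta)) {
    kv <- vapply(names(x$meta), function(k)
      paste0(k, "=", format(x$meta[[k]])), "")
    cat(" [", paste(kv, collapse = ", "), "]", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Construct a spectrum collection on a shared grid
#'
#' @param spectra List of `sers_spectrum` objects; all must share one grid.
#' @return Object of class `sers_set`.
#' @export
spectrum_set <- function(spectra = list()) {
  if (length(spectra)) {
    ok <- vapply(spectra, inherits, TRUE, what = "sers_spectrum")
    if (!all(ok)) stop("all elements must be sers_spectrum objects")
    g <- spectra[[1L]]$grid
    for (s in spectra[-1L])
      if (!same_grid(g, s$grid)) stop("spectra are not on a shared grid")
  }
  structure(list(spectra = spectra,
                 grid = if (length(spectra)) spectra[[1L]]$grid else NULL),
            class = "sers_set")
}

#' @export
length.sers_set <- function(x) length(x$spectra)

#' @export
`[[.sers_set` <- function(x, i) x$spectra[[i]]

#' @export
`[.sers_set` <- function(x, i) spectrum_set(x$spectra[i])

#' @export
print.sers_set <- function(x, ...) {
  cat(sprintf("<sers_set> %d spectra", length(x)))
  if (!is.null(x$grid))
    cat(sprintf(" on %g..%g cm^-1 (%d points)",
                x$grid$start, x$grid$end, x$grid$n_points))
  cat("\n")
  invisible(x)
}

#' Intensity matrix of a spectrum set
#'
#' @param x A `sers_set`.
#' @param ... Unused.
#' @return Numeric matrix, one row per spectrum, one column per grid point.
#' @export
as.matrix.sers_set <- function(x, ...) {
  if (!length(x)) stop("empty spectrum set")
  do.call(rbind, lapply(x$spectra, function(s) s$intensities))
}

#' Metadata field across a spectrum set
#' @param set A `sers_set`.
#' @param key Metadata key, e.g. `"fraction"`.
#' @param default Value used where a spectrum lacks the key.
#' @return Vector of the field, one element per spectrum.
#' @export
set_meta <- function(set, key, default = NA) {
  vapply(set$spectra, function(s) {
    v <- s$meta[[key]]
    if (is.null(v)) default else v
  }, FUN.VALUE = default)
}

# ---- file IO ---------------------------------------------------------------

.read_numeric_table <- function(path, sep) {
  raw <- utils::read.table(path, sep = sep, header = FALSE,
                           colClasses = "character", comment.char = "",
                           strip.white = TRUE, blank.lines.skip = TRUE)
  first <- suppressWarnings(as.numeric(unlist(raw[1L, ])))
  has_header <- any(is.na(first))
  header <- if (has_header) as.character(unlist(raw[1L, ])) else NULL
  body <- if (has_header) raw[-1L, , drop = FALSE] else raw
  out <- matrix(NA_real_, nrow(body), ncol(body))
  for (j in seq_len(ncol(body))) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(v) & nzchar(body[[j]]))
    if (length(bad)) {
      line <- bad[1L] + as.integer(has_header)
      stop(sprintf("non-numeric value '%s' at line %d, column %d of %s",
                   body[[j]][bad[1L]], line, j, path))
    }
    out[, j] <- v
  }
  list(values = out, header = header)
}

.sidecar_path <- function(path) paste0(path, ".meta.yaml")

#' Read a long-format Raman map table
#'
#' Reads a hyperspectral map export with one row per (position, wavenumber)
#' sample: columns `x_um, y_um, wavenumber_cm1, intensity` (header optional,
#' column order fixed). Every unique (x, y) position becomes one spectrum;
#' rows may appear in any order and any wavenumber direction -- the axis is
#' canonicalized to ascending on read. If a metadata sidecar written by
#' [write_spectrum_set()] sits next to the file it is reattached.
#'
#' @param path Path to the table.
#' @param dialect `"tsv"`, `"csv"`, or `"auto"` (by file extension).
#' @return A [spectrum_set()] with `map_x`/`map_y` in each spectrum's meta.
#' @export
read_map_table <- function(path, dialect = c("auto", "tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- switch(dialect,
                tsv = "\t", csv = ",",
                auto = if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t")
  tab <- .read_numeric_table(path, sep)$values
  if (ncol(tab) < 4L)
    stop("map table needs 4 columns (x_um, y_um, wavenumber_cm1, intensity)")
  pos_key <- paste(format(tab[, 1L], digits = 15),
                   format(tab[, 2L], digits = 15))
  split_idx <- split(seq_len(nrow(tab)), factor(pos_key, levels = unique(pos_key)))
  # canonical position order: ascending x, then y (row order in the file is
  # immaterial)
  first_rows <- vapply(split_idx, `[`, 0L, 1L)
  split_idx <- split_idx[order(tab[first_rows, 1L], tab[first_rows, 2L])]
  counts <- lengths(split_idx)
  if (length(unique(counts)) != 1L) {
    off <- names(split_idx)[which(counts != counts[1L])[1L]]
    stop(sprintf("ragged map: position (%s) has %d points, expected %d",
                 off, counts[counts != counts[1L]][1L], counts[1L]))
  }
  meta_list <- if (file.exists(.sidecar_path(path)))
    yaml::read_yaml(.sidecar_path(path)) else NULL
  spectra <- vector("list", length(split_idx))
  grid <- NULL
  for (k in seq_along(split_idx)) {
    rows <- tab[split_idx[[k]], , drop = FALSE]
    ord <- order(rows[, 3L])
    w <- rows[ord, 3L]
    if (any(diff(w) <= 0))
      stop(sprintf("duplicate wavenumbers at position (%s)",
                   names(split_idx)[k]))
    if (is.null(grid)) {
      grid <- wavenumber_grid(axis = w)
    } else if (!same_grid(grid, wavenumber_grid(axis = w), tol = 1e-9)) {
      stop(sprintf("position (%s) has a different wavenumber axis",
                   names(split_idx)[k]))
    }
    meta <- list(map_x = rows[1L, 1L], map_y = rows[1L, 2L])
    if (!is.null(meta_list) && k <= length(meta_list))
      meta <- utils::modifyList(meta_list[[k]], meta)
    spectra[[k]] <- new_spectrum(rows[ord, 4L], grid, meta)
  }
  spectrum_set(spectra)
}

#' Read a two-column spectrum CSV
#'
#' @param path Path to a CSV/TSV with columns (wavenumber_cm1, intensity);
#'   a header line is detected and skipped.
#' @return A `sers_spectrum` with strictly increasing axis (sorted on read).
#' @export
read_spectrum_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- .read_numeric_table(path, sep)$values
  if (ncol(tab) < 2L) stop("spectrum file needs 2 columns")
  if (nrow(tab) < 2L) stop("spectrum file needs at least 2 rows")
  ord <- order(tab[, 1L])
  w <- tab[ord, 1L]
  if (any(diff(w) == 0)) {
    dup <- w[which(diff(w) == 0)[1L]]
    stop(sprintf("duplicate wavenumber %g in %s", dup, path))
  }
  new_spectrum(tab[ord, 2L], wavenumber_grid(axis = w),
               meta = list(source = basename(path)))
}

#' Write a spectrum set as a long-format map table
#'
#' Inverse of [read_map_table()]. Positions come from `map_x`/`map_y`
#' metadata where present, else the spectrum index is used as `x` with
#' `y = 0`. Per-spectrum metadata is serialized to a `<path>.meta.yaml`
#' sidecar so the numeric table stays a plain four-column export.
#'
#' @param set Non-empty `sers_set` on a shared grid.
#' @param path Output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_spectrum_set <- function(set, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!inherits(set, "sers_set")) stop("set must be a sers_set")
  if (!length(set)) stop("refusing to write an empty spectrum set")
  sep <- if (dialect == "tsv") "\t" else ","
  w <- wavenumbers(set$grid)
  rows <- lapply(seq_len(length(set)), function(i) {
    s <- set[[i]]
    x <- if (!is.null(s$meta$map_x)) s$meta$map_x else i
    y <- if (!is.null(s$meta$map_y)) s$meta$map_y else 0
    data.frame(x_um = x, y_um = y, wavenumber_cm1 = w,
               intensity = s$intensities)
  })
  tab <- do.call(rbind, rows)
  utils::write.table(format(tab, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = sep, row.names = FALSE, col.names = TRUE,
                     quote = FALSE)
  meta <- lapply(set$spectra, function(s) if (length(s$meta)) s$meta else list())
  yaml::write_yaml(meta, .sidecar_path(path))
  invisible(path)
}
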