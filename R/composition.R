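#' Construct a composition vector
#'
#' A composition vector holds the relative molar abundances of the 20
#' standard amino acids: non-negative weights, one per one-letter code,
#' summing to 1.
#'
#' @param x Named numeric vector covering all 20 codes of [amino_acids()]
#'   (order-insensitive), or an unnamed length-20 vector taken in that order.
#' @param normalize If `TRUE` (default) rescale to sum 1; otherwise the sum
#'   must already be 1 within 1e-9.
#' @return Named numeric vector of class `composition_vector`, in
#'   [amino_acids()] order.
#' @export
#' @examples
#' composition_vector(setNames(rep(1, 20), amino_acids()))
composition_vector <- function(x, normalize = TRUE) {
  aa <- amino_acids()
  x <- unlist(x)
  if (is.null(names(x))) {
    if (length(x) != 20L) stop("unnamed composition must have length 20")
    names(x) <- aa
  }
  missing <- setdiff(aa, names(x))
  if (length(missing))
    stop("composition is missing amino acids: ", paste(missing, collapse = ", "))
  extra <- setdiff(names(x), aa)
  if (length(extra))
    stop("unknown amino-acid codes: ", paste(extra, collapse = ", "))
  x <- as.numeric(x[aa])
  names(x) <- aa
  if (any(!is.finite(x)) || any(x < 0))
    stop("composition weights must be finite and non-negative")
  s <- sum(x)
  if (s <= 0) stop("composition weights sum to zero")
  if (normalize) x <- x / s
  else if (abs(s - 1) > 1e-9) stop("composition weights must sum to 1")
  structure(x, class = "composition_vector")
}

#' @export
print.composition_vector <- function(x, ...) {
  cat("<composition_vector>\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Approximate amino-acid frequencies of human proteins
#'
#' Background composition of the 20 amino acids across well-characterized
#' human/vertebrate proteins (UniProtKB/Swiss-Prot summary statistics,
#' rounded). Used as the natural-abundance reference when judging whether an
#' MS-derived composition looks physiological, and as the anchor for the
#' synthetic generator's group means.
#'
#' @return A [composition_vector()].
#' @export
human_aa_frequencies <- function() {
  composition_vector(c(
    A = 0.0826, C = 0.0139, D = 0.0546, E = 0.0672, F = 0.0387,
    G = 0.0708, H = 0.0228, I = 0.0593, K = 0.0580, L = 0.0965,
    M = 0.0241, N = 0.0406, P = 0.0475, Q = 0.0393, R = 0.0553,
    S = 0.0665, T = 0.0536, V = 0.0687, W = 0.0110, Y = 0.0292))
}

#' Load a protein relative-abundance table
#'
#' Reads the MS output table (CSV or TSV) listing proteins and their relative
#' abundances. Abundances are renormalized to sum 1; their original metric
#' (iBAQ, LFQ, spectral counts, ...) is taken as given weights.
#'
#' @param path CSV/TSV file.
#' @param id_col,abundance_col Column names holding the protein accession and
#'   the abundance. Defaults `"protein_id"` and `"rel_abundance"`.
#' @return A `data.frame` of class `protein_table` with columns
#'   `protein_id`, `rel_abundance` (summing to 1), `sequence` (NA until
#'   [attach_sequences()]).
#' @export
load_protein_abundances <- function(path, id_col = "protein_id",
                                    abundance_col = "rel_abundance") {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!id_col %in% names(df)) stop("no id column '", id_col, "' in ", path)
  if (!abundance_col %in% names(df))
    stop("no abundance column '", abundance_col, "' in ", path)
  ab <- as.numeric(df[[abundance_col]])
  if (any(!is.finite(ab))) stop("non-numeric abundance values")
  if (any(ab < 0)) stop("negative abundance values are not allowed")
  if (sum(ab) <= 0) stop("all abundances are zero")
  out <- data.frame(protein_id = as.character(df[[id_col]]),
                    rel_abundance = ab / sum(ab),
                    sequence = NA_character_,
                    stringsAsFactors = FALSE)
  class(out) <- c("protein_table", "data.frame")
  out
}

#' Attach protein sequences from a local FASTA file
#'
#' Replaces online sequence lookup with a versioned local file. FASTA record
#' names are matched on the first whitespace-delimited token of the header;
#' UniProt-style `db|ACCESSION|NAME` headers also match on the accession.
#' Non-standard residue letters (B, J, O, U, X, Z) found in each sequence are
#' counted into a `nonstandard` column; they are excluded later from
#' frequency computation.
#'
#' @param tab A `protein_table` from [load_protein_abundances()].
#' @param fasta_path Path to a FASTA file containing every table id.
#' @return The table with `sequence` filled in.
#' @export
attach_sequences <- function(tab, fasta_path) {
  stopifnot(inherits(tab, "protein_table"))
  if (!file.exists(fasta_path)) stop("file not found: ", fasta_path)
  seqs <- Biostrings::readAAStringSet(fasta_path)
  nm <- sub("\\s.*$", "", names(seqs))
  lookup <- as.character(seqs)
  names(lookup) <- nm
  # also index UniProt-style accessions: sp|P12345|NAME -> P12345
  bar <- grepl("\\|", nm)
  if (any(bar)) {
    acc <- vapply(strsplit(nm[bar], "|", fixed = TRUE),
                  function(p) if (length(p) >= 2L) p[2L] else p[1L], "")
    extra <- lookup[bar]
    names(extra) <- acc
    lookup <- c(lookup, extra[!acc %in% names(lookup)])
  }
  missing <- setdiff(tab$protein_id, names(lookup))
  if (length(missing))
    stop("ids missing from FASTA: ", paste(missing, collapse = ", "))
  tab$sequence <- toupper(unname(lookup[tab$protein_id]))
  tab$nonstandard <- vapply(tab$sequence, function(s) {
    r <- strsplit(s, "")[[1L]]
    sum(!r %in% amino_acids())
  }, 0L, USE.NAMES = FALSE)
  tab
}

.residue_counts <- function(seq) {
  r <- strsplit(seq, "")[[1L]]
  tab <- table(factor(r, levels = amino_acids()))
  as.numeric(tab)
}

#' Amino-acid frequencies implied by a protein abundance table
#'
#' Computes the molar fraction of each amino acid across the proteome,
#' weighting each protein's residue counts by its relative abundance:
#' `f(a) = sum_p w_p * n_pa / sum_p w_p * L_p`, where `n_pa` counts residue
#' `a` in protein `p` and `L_p` counts its standard residues. Non-standard
#' residues are excluded from numerator and denominator.
#'
#' @param tab A `protein_table` with sequences attached.
#' @return A [composition_vector()].
#' @export
amino_acid_frequencies <- function(tab) {
  stopifnot(inherits(tab, "protein_table"))
  if (any(is.na(tab$sequence)))
    stop("sequences missing; run attach_sequences() first")
  counts <- t(vapply(tab$sequence, .residue_counts,
                     numeric(20L), USE.NAMES = FALSE))
  L <- rowSums(counts)
  if (any(L == 0 & tab$rel_abundance > 0))
    stop("a weighted protein has no standard residues")
  w <- tab$rel_abundance
  num <- colSums(counts * w)
  den <- sum(L * w)
  if (den <= 0) stop("zero total weighted residue count")
  composition_vector(stats::setNames(num / den, amino_acids()),
                     normalize = FALSE)
}

#' Compare a composition vector to a reference
#'
#' @param comp,ref Two [composition_vector()]s (e.g. a fitted composition and
#'   the natural human abundance from [human_aa_frequencies()]).
#' @return List of class `composition_comparison`: per-amino-acid
#'   differences (`comp - ref`), Pearson correlation of the two 20-vectors,
#'   and the mean relative absolute deviation in percent (over reference
#'   entries > 0).
#' @export
compare_to_reference <- function(comp, ref) {
  comp <- composition_vector(comp, normalize = FALSE)
  ref <- composition_vector(ref, normalize = FALSE)
  diffs <- unclass(comp) - unclass(ref)
  pos <- unclass(ref) > 0
  # Pearson is undefined when either vector is constant (e.g. two uniform
  # compositions); report NA rather than warning
  r <- if (stats::sd(unclass(comp)) == 0 || stats::sd(unclass(ref)) == 0)
    NA_real_ else stats::cor(unclass(comp), unclass(ref))
  structure(list(
    differences = diffs,
    pearson = r,
    mean_rel_dev_pct = mean(abs(diffs[pos]) / unclass(ref)[pos]) * 100),
    class = "composition_comparison")
}

#' @export
print.composition_comparison <- function(x, ...) {
  cat(sprintf("<composition_comparison> r = %.4f, mean relative deviation = %.2f%%\n",
              x$pearson, x$mean_rel_dev_pct))
  invisible(x)
}

#' Write a composition vector as a two-column CSV
#' @param comp A [composition_vector()].
#' @param path Output CSV (`amino_acid, fraction`).
#' @return `path`, invisibly.
#' @export
write_composition <- function(comp, path) {
  comp <- composition_vector(comp, normalize = FALSE)
  utils::write.csv(data.frame(amino_acid = names(comp),
                              fraction = as.numeric(comp)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a composition vector from a two-column CSV
#' @param path CSV written by [write_composition()].
#' @return A [composition_vector()].
#' @export
read_composition <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  composition_vector(stats::setNames(df[[2L]], df[[1L]]), normalize = FALSE)
}
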