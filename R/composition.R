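#' Position-wise amino-acid composition profile
#'
#' Computes, for every reference-mapped column, the percent abundance of each
#' of the 20 amino acids among the non-gap residues at that column. Gaps are
#' excluded from the denominator (residue preferences are reported among
#' observed residues); the gap fraction is reported separately. Columns that
#' are entirely gapped have undefined abundance and are flagged as excluded.
#'
#' @param alignment An `AlignedDomainSet`.
#' @param map A `LandmarkMap`; profiling is restricted to its
#'   reference-mapped columns.
#' @return Object of class `CompositionProfile`: `group_label`, `columns`
#'   (alignment columns), `ref_numbers`, `abundance` (20 x n matrix of
#'   percents; columns named by reference number), `gap_fraction`,
#'   `excluded` (logical, all-gap columns).
#' @export
composition_profile <- function(alignment, map) {
  n <- n_sequences(alignment)
  if (n == 0L) stop("no sequences", call. = FALSE)
  cols <- mapped_columns(map)
  refs <- map$ref_numbers[cols]
  codes <- encode_residues(alignment$residues[, cols, drop = FALSE])
  counts <- vapply(seq_along(cols), function(j) {
    tabulate(codes[, j], nbins = 20L)
  }, numeric(20L))
  counts <- matrix(counts, nrow = 20L,
                   dimnames = list(AMINO_ACIDS, refs))
  nongap <- colSums(counts)
  excluded <- nongap == 0
  abundance <- sweep(counts, 2L, pmax(nongap, 1), "/") * 100
  abundance[, excluded] <- NA_real_
  structure(
    list(group_label = alignment$group_label,
         columns = cols, ref_numbers = refs,
         abundance = abundance,
         gap_fraction = setNames(1 - nongap / n, refs),
         excluded = setNames(excluded, refs),
         n_sequences = n),
    class = "CompositionProfile"
  )
}

#' @export
print.CompositionProfile <- function(x, ...) {
  cat(sprintf("CompositionProfile '%s': %d columns, %d sequences\n",
              x$group_label, length(x$columns), x$n_sequences))
  invisible(x)
}

#' Receiver-minus-PsR composition difference
#'
#' Subtracts one profile from another position by position. For heatmap
#' rendering the differences are clipped to `+/- clip_limit` percent (raw
#' values are retained), so the display saturates at positions where an
#' amino acid differs in absolute abundance by the clip limit or more.
#' Positive values mean higher abundance in the first (receiver) profile.
#'
#' @param receiver_profile,psr_profile `CompositionProfile`s over the same
#'   reference columns.
#' @param clip_limit Display clip, in percent (default 20).
#' @return Object of class `CompositionDiff`: `columns`, `ref_numbers`,
#'   `diff` (raw signed percents), `clipped`, `clip_limit`, `excluded`.
#' @export
composition_difference <- function(receiver_profile, psr_profile,
                                   clip_limit = 20) {
  if (!identical(receiver_profile$ref_numbers, psr_profile$ref_numbers)) {
    stop("profiles not comparable", call. = FALSE)
  }
  d <- receiver_profile$abundance - psr_profile$abundance
  excluded <- receiver_profile$excluded | psr_profile$excluded
  structure(
    list(columns = receiver_profile$columns,
         ref_numbers = receiver_profile$ref_numbers,
         diff = d,
         clipped = pmin(pmax(d, -clip_limit), clip_limit),
         clip_limit = clip_limit,
         excluded = excluded,
         labels = c(receiver_profile$group_label, psr_profile$group_label)),
    class = "CompositionDiff"
  )
}

#' @export
print.CompositionDiff <- function(x, ...) {
  cat(sprintf("CompositionDiff (%s - %s): %d columns, clip %.0f%%\n",
              x$labels[1], x$labels[2], length(x$columns), x$clip_limit))
  invisible(x)
}

#' Abundance of a residue class at a named position
#'
#' Sums the percent abundance of a set of amino acids (e.g., `{A, G}` at
#' T+1, or `{F, Y}` at K-3) at the column a landmark-relative label resolves
#' to.
#'
#' @param profile A `CompositionProfile`.
#' @param label A position label (string or `PositionLabel`).
#' @param residue_class Character vector of amino acids.
#' @param map The `LandmarkMap` the profile was built with.
#' @return Percent abundance (scalar).
#' @export
class_abundance <- function(profile, label, residue_class, map) {
  col <- resolve_position(label, map)
  j <- match(col, profile$columns)
  if (is.na(j)) stop("position outside reference span", call. = FALSE)
  if (!all(residue_class %in% AMINO_ACIDS)) {
    stop("residue_class must contain amino-acid letters only", call. = FALSE)
  }
  sum(profile$abundance[match(residue_class, AMINO_ACIDS), j])
}

#' Per-sequence retention of residue-class pairs
#'
#' Fraction of sequences that satisfy *all* of a list of (position, residue
#' class) criteria simultaneously. The default criteria are the two Y-T
#' coupling requirements: Ser/Thr at the conserved T and an aromatic
#' (Phe/Tyr) at K-3. A gap at a criterion position fails that criterion.
#'
#' @param alignment An `AlignedDomainSet`.
#' @param map A `LandmarkMap`.
#' @param pairs List of `list(label =, class =)` criteria.
#' @return Proportion of sequences satisfying every criterion.
#' @export
paired_retention <- function(alignment, map,
                             pairs = list(
                               list(label = "T", class = c("S", "T")),
                               list(label = "K-3", class = c("F", "Y")))) {
  if (length(pairs) == 0L) stop("no criteria", call. = FALSE)
  if (n_sequences(alignment) == 0L) stop("no sequences", call. = FALSE)
  ok <- rep(TRUE, n_sequences(alignment))
  for (p in pairs) {
    col <- resolve_position(p$label, map)
    ok <- ok & alignment$residues[, col] %in% p$class
  }
  mean(ok)
}

#' Write a composition profile or difference as TSV
#'
#' Rows are amino acids, columns are reference-numbered positions.
#'
#' @param x A `CompositionProfile` or `CompositionDiff`.
#' @param path Output path.
#' @param what For differences, `"raw"` or `"clipped"`.
#' @return `path`, invisibly.
#' @export
write_composition_tsv <- function(x, path, what = c("raw", "clipped")) {
  what <- match.arg(what)
  m <- if (inherits(x, "CompositionProfile")) {
    x$abundance
  } else if (what == "raw") x$diff else x$clipped
  out <- data.frame(amino_acid = rownames(m), m, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
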