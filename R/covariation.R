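# internal: MI (bits) between two integer-coded columns (1..20, gap = 0),
# pairwise deletion of rows gapped at either column.
mi_from_codes <- function(ci, cj, pseudocount = 0) {
  keep <- ci > 0L & cj > 0L
  n <- sum(keep)
  if (n < 2L) return(NA_real_)
  joint <- tabulate((ci[keep] - 1L) * 20L + cj[keep], nbins = 400L)
  jm <- matrix(joint, nrow = 20L, ncol = 20L, byrow = TRUE)
  if (pseudocount > 0) jm <- jm + pseudocount
  p <- jm / sum(jm)
  pi <- rowSums(p)
  pj <- colSums(p)
  nz <- which(p > 0)
  prod <- outer(pi, pj)
  sum(p[nz] * log2(p[nz] / prod[nz]))
}

#' Mutual information between two alignment columns
#'
#' Computes MI = sum over residue pairs (a, b) of
#' p(a,b) log2( p(a,b) / (p(a) p(b)) ), in bits, over the rows where neither
#' column is gapped (pairwise deletion). An optional additive pseudocount is
#' applied to every cell of the 20 x 20 joint table before normalization.
#'
#' @param col_i,col_j Character vectors of residues (single letters), equal
#'   length.
#' @param pseudocount Additive count per joint cell (default 0).
#' @return MI in bits (non-negative when `pseudocount = 0`).
#' @examples
#' column_mi(c("A", "A", "C", "C"), c("G", "G", "W", "W")) # 1 bit
#' @export
column_mi <- function(col_i, col_j, pseudocount = 0) {
  if (length(col_i) != length(col_j)) {
    stop("columns must have equal length", call. = FALSE)
  }
  check_residue_chars(c(col_i, col_j))
  ci <- match(col_i, AMINO_ACIDS)
  cj <- match(col_j, AMINO_ACIDS)
  ci[is.na(ci)] <- 0L
  cj[is.na(cj)] <- 0L
  mi <- mi_from_codes(as.integer(ci), as.integer(cj), pseudocount)
  if (is.na(mi)) stop("insufficient coverage", call. = FALSE)
  mi
}

# internal: full symmetric raw-MI matrix over the given code columns
mi_matrix_from_codes <- function(codes, pseudocount = 0) {
  p <- ncol(codes)
  m <- matrix(NA_real_, p, p)
  for (i in seq_len(p - 1L)) {
    ci <- codes[, i]
    for (j in (i + 1L):p) {
      m[i, j] <- m[j, i] <- mi_from_codes(ci, codes[, j], pseudocount)
    }
  }
  m
}

#' Average-product correction of a mutual-information matrix
#'
#' Subtracts the average-product background APC(i, j) =
#' mean_i x mean_j / overall_mean from each off-diagonal entry, where
#' `mean_i` is the mean MI of column i to all other columns and
#' `overall_mean` is the mean over all off-diagonal pairs. This removes the
#' shared background (phylogenetic and entropic) component of raw MI;
#' corrected values may be negative. If the matrix is identically zero the
#' corrected matrix is defined as all zeros.
#'
#' @param raw_mi Symmetric non-negative matrix; the diagonal is ignored.
#' @return Symmetric corrected matrix with `NA` diagonal. Entries that were
#'   `NA` off-diagonal (excluded pairs) stay `NA`.
#' @export
product_correction <- function(raw_mi) {
  m <- as.matrix(raw_mi)
  if (nrow(m) != ncol(m)) stop("matrix must be square", call. = FALSE)
  diag(m) <- NA_real_
  row_mean <- rowMeans(m, na.rm = TRUE)
  overall <- mean(m[upper.tri(m)], na.rm = TRUE)
  if (!is.finite(overall) || overall == 0) {
    corrected <- m
    corrected[!is.na(m)] <- 0
    return(corrected)
  }
  corrected <- m - outer(row_mean, row_mean) / overall
  corrected[is.na(m)] <- NA_real_
  diag(corrected) <- NA_real_
  corrected
}

#' Z-scores and significance of corrected covariation scores
#'
#' Standardizes every off-diagonal corrected score against the global mean
#' and sample standard deviation of all off-diagonal scores; a pair is
#' significant when its z-score meets the threshold (default 6.5).
#'
#' @param corrected Symmetric corrected-MI matrix (`NA` diagonal allowed).
#' @param threshold Significance threshold on z (default 6.5).
#' @return List with `zscores` (symmetric matrix), `significant` (symmetric
#'   logical matrix), `threshold`. With zero spread across pairs a
#'   "degenerate score distribution" warning is raised and no pair is
#'   significant.
#' @export
mi_significance <- function(corrected, threshold = 6.5) {
  m <- as.matrix(corrected)
  diag(m) <- NA_real_
  vals <- m[upper.tri(m)]
  vals <- vals[!is.na(vals)]
  if (length(vals) < 2L) stop("need at least 2 off-diagonal pairs", call. = FALSE)
  s <- sd(vals)
  if (!is.finite(s) || s == 0) {
    warning("degenerate score distribution", call. = FALSE)
    z <- m
    z[!is.na(m)] <- NA_real_
    sig <- !is.na(m) & FALSE
    return(list(zscores = z, significant = sig, threshold = threshold))
  }
  z <- (m - mean(vals)) / s
  sig <- !is.na(z) & z >= threshold
  list(zscores = z, significant = sig, threshold = threshold)
}

#' Percentile ranks of covariation scores
#'
#' Ranks all off-diagonal pairs by corrected score (higher score = higher
#' rank; ties share their mean rank) and converts to percentiles,
#' 100 x rank / number_of_pairs, so the strongest pair sits at 100.
#'
#' @param corrected Symmetric corrected-MI matrix.
#' @return Symmetric matrix of percentile ranks (0-100], `NA` where input
#'   was `NA`.
#' @export
rank_pairs <- function(corrected) {
  m <- as.matrix(corrected)
  diag(m) <- NA_real_
  ut <- which(upper.tri(m) & !is.na(m))
  pct <- matrix(NA_real_, nrow(m), ncol(m))
  if (length(ut) > 0L) {
    r <- rank(m[ut], ties.method = "average")
    pct[ut] <- 100 * r / length(ut)
    pct[lower.tri(pct)] <- t(pct)[lower.tri(pct)]
  }
  pct
}

# internal: indices (into a pair data frame) of the top `fraction` rows by
# `score`, using ceiling and including all rows tied at the boundary.
top_fraction_idx <- function(score, fraction) {
  n <- length(score)
  if (n == 0L || fraction <= 0) return(integer(0))
  k <- min(n, ceiling(fraction * n))
  cutoff <- sort(score, decreasing = TRUE)[k]
  which(score >= cutoff)
}

#' Covariation analysis of one alignment
#'
#' Runs the full within-group pipeline: raw mutual information for every
#' retained column pair (pairwise gap deletion), average-product correction,
#' global z-scores with a significance threshold, and percentile ranks.
#' Columns with more than `max_gap_fraction` gaps are dropped from the
#' column set before analysis.
#'
#' @param alignment An `AlignedDomainSet`.
#' @param map Optional `LandmarkMap`; when supplied, analysis is restricted
#'   to reference-mapped columns and output is labeled with reference
#'   numbers. Without a map, all columns are used with identity numbering.
#' @param max_gap_fraction Columns gapped in more than this fraction of
#'   sequences are excluded (default 0.5).
#' @param pseudocount Additive pseudocount per joint cell (default 0).
#' @param threshold Significance threshold on z (default 6.5).
#' @return Object of class `CovariationResult`: `group_label`, `columns`
#'   (alignment columns retained), `ref_numbers`, `raw_mi`, `corrected_mi`,
#'   `zscores`, `percentile_rank` (all symmetric, dimnames = reference
#'   numbers), `significant`, `significance_threshold`, `unit` (`"bits"`),
#'   `n_sequences`.
#' @export
covariation_analysis <- function(alignment, map = NULL,
                                 max_gap_fraction = 0.5, pseudocount = 0,
                                 threshold = 6.5) {
  if (n_sequences(alignment) < 2L) stop("insufficient coverage", call. = FALSE)
  cols <- if (is.null(map)) seq_len(alignment$n_columns) else mapped_columns(map)
  refs <- if (is.null(map)) cols else map$ref_numbers[cols]
  codes <- encode_residues(alignment$residues[, cols, drop = FALSE])
  gap_frac <- colMeans(codes == 0L)
  keep <- gap_frac <= max_gap_fraction
  cols <- cols[keep]
  refs <- refs[keep]
  codes <- codes[, keep, drop = FALSE]
  if (ncol(codes) < 2L) stop("fewer than 2 usable columns", call. = FALSE)
  raw <- mi_matrix_from_codes(codes, pseudocount)
  corrected <- product_correction(raw)
  sig <- mi_significance(corrected, threshold)
  pct <- rank_pairs(corrected)
  dn <- list(refs, refs)
  dimnames(raw) <- dimnames(corrected) <- dimnames(sig$zscores) <-
    dimnames(sig$significant) <- dimnames(pct) <- dn
  structure(
    list(group_label = alignment$group_label,
         columns = cols, ref_numbers = refs,
         raw_mi = raw, corrected_mi = corrected,
         zscores = sig$zscores, percentile_rank = pct,
         significant = sig$significant,
         significance_threshold = threshold,
         unit = "bits", pseudocount = pseudocount,
         max_gap_fraction = max_gap_fraction,
         n_sequences = n_sequences(alignment)),
    class = "CovariationResult"
  )
}

#' @export
print.CovariationResult <- function(x, ...) {
  np <- length(x$ref_numbers) * (length(x$ref_numbers) - 1) / 2
  cat(sprintf(
    "CovariationResult '%s': %d columns (%d pairs), %d sequences, %d significant (z >= %.1f)\n",
    x$group_label, length(x$ref_numbers), np, x$n_sequences,
    sum(x$significant[upper.tri(x$significant)], na.rm = TRUE),
    x$significance_threshold))
  invisible(x)
}

#' Pairwise covariation table
#'
#' Flattens a `CovariationResult` into one row per unordered column pair.
#'
#' @param cov A `CovariationResult`.
#' @return Data frame with `pos_i`, `pos_j` (reference numbers, i < j),
#'   `raw_mi`, `corrected_mi`, `z`, `percentile`, `significant`.
#' @export
pair_table <- function(cov) {
  p <- length(cov$ref_numbers)
  ut <- which(upper.tri(cov$corrected_mi), arr.ind = TRUE)
  df <- data.frame(
    pos_i = cov$ref_numbers[ut[, 1L]],
    pos_j = cov$ref_numbers[ut[, 2L]],
    raw_mi = cov$raw_mi[ut],
    corrected_mi = cov$corrected_mi[ut],
    z = cov$zscores[ut],
    percentile = cov$percentile_rank[ut],
    significant = cov$significant[ut]
  )
  df[!is.na(df$corrected_mi), , drop = FALSE]
}

#' Rank-shift comparison between two covariation analyses
#'
#' Mutual-information scores are not directly comparable between alignments,
#' so each pair's within-group percentile rank is compared instead: shift =
#' rank in the first (receiver) group minus rank in the second (PsR) group.
#' Positive shifts mean the interaction ranks higher (is "stronger") in
#' receivers; negative means stronger in PsRs. Pairs are restricted to those
#' significant (z >= threshold) in at least one group, and the selection
#' keeps the top `top_fraction` of those by absolute shift (ceiling,
#' boundary ties included).
#'
#' @param cov_receiver,cov_psr `CovariationResult`s over the identical
#'   column set.
#' @param top_fraction Fraction of significant pairs to keep by |shift|
#'   (default 0.02).
#' @return Object of class `RankShiftTable`: `pairs` (all significant-in-
#'   either pairs with `rank_receiver`, `rank_psr`, `shift`,
#'   `significant_in`, and logical `selected`), `top` (selected rows,
#'   ordered by |shift| descending), `top_fraction`, `n_significant`.
#' @export
rank_shift <- function(cov_receiver, cov_psr, top_fraction = 0.02) {
  if (!identical(cov_receiver$ref_numbers, cov_psr$ref_numbers)) {
    stop("alignments not comparable", call. = FALSE)
  }
  ut <- which(upper.tri(cov_receiver$corrected_mi), arr.ind = TRUE)
  ok <- !is.na(cov_receiver$percentile_rank[ut]) &
    !is.na(cov_psr$percentile_rank[ut])
  ut <- ut[ok, , drop = FALSE]
  sig_r <- cov_receiver$significant[ut]
  sig_p <- cov_psr$significant[ut]
  df <- data.frame(
    pos_i = cov_receiver$ref_numbers[ut[, 1L]],
    pos_j = cov_receiver$ref_numbers[ut[, 2L]],
    rank_receiver = cov_receiver$percentile_rank[ut],
    rank_psr = cov_psr$percentile_rank[ut],
    significant_in = ifelse(sig_r & sig_p, "both",
                            ifelse(sig_r, "receiver",
                                   ifelse(sig_p, "psr", "none")))
  )
  df$shift <- df$rank_receiver - df$rank_psr
  df <- df[df$significant_in != "none", , drop = FALSE]
  rownames(df) <- NULL
  df$selected <- FALSE
  idx <- top_fraction_idx(abs(df$shift), top_fraction)
  idx <- idx[abs(df$shift[idx]) > 0]  # an unshifted pair is not a change
  df$selected[idx] <- TRUE
  top <- df[df$selected, , drop = FALSE]
  top <- top[order(-abs(top$shift), top$pos_i, top$pos_j), , drop = FALSE]
  structure(
    list(pairs = df, top = top, top_fraction = top_fraction,
         n_significant = nrow(df),
         labels = c(cov_receiver$group_label, cov_psr$group_label)),
    class = "RankShiftTable"
  )
}

#' @export
print.RankShiftTable <- function(x, ...) {
  cat(sprintf(
    "RankShiftTable (%s vs %s): %d significant pairs, %d selected (top %.1f%% by |shift|)\n",
    x$labels[1], x$labels[2], x$n_significant, nrow(x$top),
    100 * x$top_fraction))
  invisible(x)
}

#' Write covariation pair tables as TSV
#'
#' @param x A `CovariationResult` or `RankShiftTable`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pair_tsv <- function(x, path) {
  df <- if (inherits(x, "CovariationResult")) {
    pair_table(x)
  } else if (inherits(x, "RankShiftTable")) {
    x$pairs
  } else stop("unsupported object", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(x, "RankShiftTable")) {
    writeLines(c("# rank shift = receiver percentile - PsR percentile;",
                 "# positive = stronger in receivers, negative = stronger in PsRs"),
               con)
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
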