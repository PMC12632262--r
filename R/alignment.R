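#' Construct an aligned domain set
#'
#' An `AlignedDomainSet` holds one labeled group of equal-length aligned
#' amino-acid sequences (e.g., all receivers, or all PsRs). Residues are
#' stored as a character matrix with one aligned column per matrix column;
#' the only characters permitted are the 20 standard amino acids and `"-"`.
#'
#' @param sequences Character vector of aligned sequences (all the same
#'   length), or a character matrix of single residues (rows = sequences).
#' @param ids Sequence identifiers, unique within the set. Defaults to names
#'   of `sequences`, or `seq1`, `seq2`, ... when unnamed.
#' @param group_label Free-text label for the group (e.g., `"receiver"`).
#' @param n_columns Required only when `sequences` is empty, so that empty
#'   partitions keep a well-defined alignment width.
#' @return An object of class `AlignedDomainSet` with fields `group_label`,
#'   `ids`, `residues` (character matrix), `n_columns`.
#' @examples
#' aln <- aligned_domain_set(c(a = "ADKT", b = "AD-T"), group_label = "toy")
#' n_sequences(aln)
#' @export
aligned_domain_set <- function(sequences, ids = NULL, group_label = "",
                               n_columns = NULL) {
  if (is.matrix(sequences)) {
    mat <- sequences
    if (is.null(ids)) ids <- rownames(mat)
  } else {
    if (is.null(ids)) ids <- names(sequences)
    sequences <- as.character(sequences)
    if (length(sequences) > 0L) {
      lens <- nchar(sequences)
      if (length(unique(lens)) > 1L) stop("unequal sequence lengths", call. = FALSE)
      mat <- matrix(unlist(strsplit(sequences, "", fixed = TRUE), use.names = FALSE),
                    nrow = length(sequences), byrow = TRUE)
    } else {
      if (is.null(n_columns)) stop("n_columns required for an empty set", call. = FALSE)
      mat <- matrix(character(0), nrow = 0L, ncol = n_columns)
    }
  }
  if (ncol(mat) < 1L) stop("alignment must have at least one column", call. = FALSE)
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(mat)))
  if (anyDuplicated(ids)) stop("duplicate sequence ids", call. = FALSE)
  mat <- toupper(mat)
  mat[mat == "."] <- GAP_CHAR
  check_residue_chars(mat)
  dimnames(mat) <- NULL
  structure(
    list(group_label = group_label, ids = as.character(ids),
         residues = mat, n_columns = ncol(mat)),
    class = "AlignedDomainSet"
  )
}

#' @export
print.AlignedDomainSet <- function(x, ...) {
  cat(sprintf("AlignedDomainSet '%s': %d sequences x %d columns\n",
              x$group_label, nrow(x$residues), x$n_columns))
  invisible(x)
}

#' Number of sequences in an aligned set
#' @param x An `AlignedDomainSet`.
#' @return Integer count.
#' @export
n_sequences <- function(x) nrow(x$residues)

#' Extract aligned sequences as strings
#' @param x An `AlignedDomainSet`.
#' @return Named character vector of aligned sequences.
#' @export
alignment_strings <- function(x) {
  setNames(apply(x$residues, 1L, paste, collapse = ""), x$ids)
}

#' Read a multiple sequence alignment
#'
#' Reads an aligned FASTA or Stockholm file into an [aligned_domain_set()].
#' Residues are uppercased and `"."` gaps are normalized to `"-"`; any
#' character outside the 20 standard amino acids and the gap is rejected.
#'
#' @param path Path to the alignment file.
#' @param format `"fasta"` (aligned FASTA) or `"stockholm"`.
#' @param group_label Label stored on the returned set.
#' @return An `AlignedDomainSet`.
#' @export
read_alignment <- function(path, format = c("fasta", "stockholm"),
                           group_label = "") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    seqs <- as.character(set)
    if (length(seqs) == 0L) stop("no sequences", call. = FALSE)
    if (length(unique(nchar(seqs))) > 1L) {
      stop("unequal sequence lengths", call. = FALSE)
    }
    # FASTA headers: keep the first whitespace-delimited token as the id
    ids <- sub("\\s.*$", "", names(seqs))
  } else {
    msa <- Biostrings::readAAMultipleAlignment(path, format = "stockholm")
    seqs <- as.character(Biostrings::unmasked(msa))
    ids <- names(seqs)
  }
  aligned_domain_set(unname(seqs), ids = ids, group_label = group_label)
}

#' Write a multiple sequence alignment
#'
#' @param x An `AlignedDomainSet`.
#' @param path Output path.
#' @param format `"fasta"` or `"stockholm"`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(x, path, format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  seqs <- alignment_strings(x)
  if (format == "fasta") {
    Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), filepath = path)
  } else {
    pad <- max(nchar(x$ids)) + 2L
    lines <- c("# STOCKHOLM 1.0",
               sprintf(paste0("%-", pad, "s%s"), x$ids, seqs),
               "//")
    writeLines(lines, path)
  }
  invisible(path)
}

# internal: encode a residue matrix as integer codes 1..20, gap = 0
encode_residues <- function(mat) {
  codes <- match(mat, AMINO_ACIDS)
  codes[is.na(codes)] <- 0L
  matrix(as.integer(codes), nrow = nrow(mat), ncol = ncol(mat))
}
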