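#' Landmark-relative position labels
#'
#' Positions in receiver domains are named relative to the five conserved
#' active-site landmarks: DD1 and DD2 (the acidic metal-binding pair), D (the
#' Asp phosphorylation site), T (the conserved Ser/Thr), and K (the conserved
#' Lys). `"T+1"` is the position one reference residue C-terminal of T,
#' `"K-3"` three residues N-terminal of K, and so on. Offsets count reference
#' residues, not raw alignment columns, so insertion columns relative to the
#' reference are skipped. Labels written `"DD+k"`/`"DD-k"` are anchored at
#' DD1 (the N-terminal residue of the acidic pair).
#'
#' @param landmark One of `"DD1"`, `"DD2"`, `"D"`, `"T"`, `"K"`.
#' @param offset Signed integer offset in reference residues (|offset| <= 30).
#' @return An object of class `PositionLabel`.
#' @seealso [parse_position_label()], [resolve_position()]
#' @export
position_label <- function(landmark, offset = 0L) {
  landmark <- as.character(landmark)
  if (!landmark %in% LANDMARK_NAMES) {
    stop("unknown landmark '", landmark, "'", call. = FALSE)
  }
  offset <- as.integer(offset)
  if (is.na(offset) || abs(offset) > 30L) {
    stop("offset magnitude must be <= 30", call. = FALSE)
  }
  structure(list(landmark = landmark, offset = offset), class = "PositionLabel")
}

#' Parse a position label string
#'
#' Accepts strings such as `"T+1"`, `"K-3"`, `"D"`, `"DD2"`, or `"DD+5"`.
#' A bare `"DD"` (with or without an offset) is anchored at DD1. Unicode
#' minus signs are accepted as hyphens.
#'
#' @param label A single label string (or an existing `PositionLabel`,
#'   returned unchanged).
#' @return A `PositionLabel`.
#' @examples
#' parse_position_label("K-3")
#' parse_position_label("DD+5") # anchored at DD1
#' @export
parse_position_label <- function(label) {
  if (inherits(label, "PositionLabel")) return(label)
  s <- gsub("−|–", "-", trimws(as.character(label)))
  m <- regmatches(s, regexec("^(DD1|DD2|DD|D|T|K)([+-][0-9]+)?$", s))[[1L]]
  if (length(m) == 0L) stop("cannot parse position label '", label, "'", call. = FALSE)
  lm <- if (m[[2L]] == "DD") "DD1" else m[[2L]]
  off <- if (nzchar(m[[3L]])) as.integer(m[[3L]]) else 0L
  position_label(lm, off)
}

#' @export
print.PositionLabel <- function(x, ...) {
  off <- if (x$offset == 0L) "" else sprintf("%+d", x$offset)
  cat(sprintf("PositionLabel: %s%s\n", x$landmark, off))
  invisible(x)
}

new_landmark_map <- function(landmark_columns, ref_numbers, reference_id) {
  landmark_columns <- vapply(LANDMARK_NAMES, function(l) {
    as.integer(landmark_columns[[l]])
  }, integer(1))
  if (anyNA(landmark_columns)) stop("landmark outside reference", call. = FALSE)
  if (anyDuplicated(landmark_columns)) {
    stop("landmark columns must be distinct", call. = FALSE)
  }
  if (is.unsorted(landmark_columns, strictly = TRUE)) {
    stop("landmark columns must be ordered DD1 < DD2 < D < T < K", call. = FALSE)
  }
  mapped <- ref_numbers[!is.na(ref_numbers)]
  if (length(mapped) == 0L || is.unsorted(mapped, strictly = TRUE)) {
    stop("reference numbering must be strictly increasing", call. = FALSE)
  }
  structure(
    list(landmark_columns = landmark_columns,
         ref_numbers = as.integer(ref_numbers),
         reference_id = reference_id,
         n_columns = length(ref_numbers)),
    class = "LandmarkMap"
  )
}

#' Anchor alignment columns to reference (CheY) numbering
#'
#' Walks the reference row of the alignment, assigning consecutive reference
#' residue numbers (1, 2, ...) to its non-gap columns; columns where the
#' reference row is gapped (insertions relative to the reference) carry no
#' reference number. The five landmark columns are the columns holding the
#' stated reference residues.
#'
#' @param alignment An `AlignedDomainSet` containing the reference row.
#' @param reference_id Id of the reference sequence (e.g., E. coli CheY).
#' @param reference_landmarks Named vector/list giving, for each of DD1, DD2,
#'   D, T, K, the landmark's residue number in ungapped reference coordinates
#'   (for CheY: DD1 = 12, DD2 = 13, D = 57, T = 87, K = 109).
#' @return A `LandmarkMap` with fields `landmark_columns` (named, 1-based
#'   alignment columns), `ref_numbers` (per alignment column; `NA` at
#'   insertion columns), `reference_id`, `n_columns`.
#' @export
build_landmark_map <- function(alignment, reference_id, reference_landmarks) {
  row <- match(reference_id, alignment$ids)
  if (is.na(row)) stop("reference not in alignment", call. = FALSE)
  if (!all(LANDMARK_NAMES %in% names(reference_landmarks))) {
    stop("reference_landmarks must name all of DD1, DD2, D, T, K", call. = FALSE)
  }
  res <- alignment$residues[row, ]
  ref_numbers <- rep(NA_integer_, alignment$n_columns)
  ref_numbers[res != GAP_CHAR] <- seq_len(sum(res != GAP_CHAR))
  cols <- lapply(LANDMARK_NAMES, function(l) {
    col <- match(as.integer(reference_landmarks[[l]]), ref_numbers)
    if (is.na(col)) stop("landmark outside reference", call. = FALSE)
    col
  })
  names(cols) <- LANDMARK_NAMES
  new_landmark_map(cols, ref_numbers, reference_id)
}

#' Build a landmark map for alignments with identity numbering
#'
#' For synthetic alignments (and any alignment whose columns already are
#' reference coordinates), every column `i` carries reference number `i`.
#'
#' @param landmark_columns Named vector giving the DD1/DD2/D/T/K columns.
#' @param n_columns Alignment width.
#' @param reference_id Label recorded on the map.
#' @return A `LandmarkMap`.
#' @export
landmark_map_from_columns <- function(landmark_columns, n_columns,
                                      reference_id = "identity") {
  new_landmark_map(as.list(landmark_columns), seq_len(n_columns), reference_id)
}

#' @export
print.LandmarkMap <- function(x, ...) {
  cat(sprintf("LandmarkMap (%s): %d columns, %d mapped to reference\n",
              x$reference_id, x$n_columns, sum(!is.na(x$ref_numbers))))
  print(x$landmark_columns)
  invisible(x)
}

#' Resolve a landmark-relative label to an alignment column
#'
#' @param label A `PositionLabel` or a label string such as `"T+1"`.
#' @param map A `LandmarkMap`.
#' @return The 1-based alignment column whose reference residue number equals
#'   the landmark's reference number plus the offset.
#' @examples
#' map <- landmark_map_from_columns(
#'   c(DD1 = 12, DD2 = 13, D = 57, T = 87, K = 109), 129, "CheY")
#' resolve_position("K-3", map) # 106
#' @export
resolve_position <- function(label, map) {
  label <- parse_position_label(label)
  lm_col <- map$landmark_columns[[label$landmark]]
  target <- map$ref_numbers[lm_col] + label$offset
  col <- match(target, map$ref_numbers)
  if (is.na(col)) stop("position outside reference span", call. = FALSE)
  col
}

#' Reference residue numbers of mapped columns
#'
#' @param map A `LandmarkMap`.
#' @return Integer vector of alignment columns that carry a reference number.
#' @export
mapped_columns <- function(map) which(!is.na(map$ref_numbers))

#' Read a landmark fixture file
#'
#' The fixture is a two-column tab-separated key/value file (comment lines
#' start with `#`) holding a reference id, its ungapped sequence, and the
#' five landmark residue numbers. The packaged CheY fixture is at
#' `system.file("extdata", "chey_landmarks.tsv", package = "psrcov")`.
#'
#' @param path Path to the fixture file. Defaults to the packaged E. coli
#'   CheY fixture.
#' @return List with `reference_id`, `sequence`, and `landmarks` (named
#'   integer vector over DD1, DD2, D, T, K).
#' @export
read_landmark_fixture <- function(path = system.file("extdata",
                                                     "chey_landmarks.tsv",
                                                     package = "psrcov")) {
  tab <- read.table(path, sep = "\t", comment.char = "#",
                    col.names = c("key", "value"),
                    colClasses = "character", quote = "")
  kv <- setNames(tab$value, tab$key)
  needed <- c("reference_id", "sequence", LANDMARK_NAMES)
  missing <- setdiff(needed, names(kv))
  if (length(missing)) stop("fixture missing key(s): ",
                            paste(missing, collapse = ", "), call. = FALSE)
  list(reference_id = unname(kv[["reference_id"]]),
       sequence = unname(kv[["sequence"]]),
       landmarks = setNames(as.integer(kv[LANDMARK_NAMES]), LANDMARK_NAMES))
}
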