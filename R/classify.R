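#' Default conserved-residue rules
#'
#' The five active-site landmarks and the residues that count as "present".
#' DD1 and DD2 accept either acidic residue (Asp/Glu) because both positions
#' are essentially 100% acidic in true receivers; D accepts only Asp, so the
#' hallmark ALR substitution (Glu at D) counts as missing; T accepts Ser or
#' Thr; K accepts only Lys. A gap at a landmark column always counts as
#' missing regardless of the rule.
#'
#' @return Named list mapping each landmark to its allowed residue set.
#' @export
default_residue_rules <- function() {
  list(DD1 = c("D", "E"), DD2 = c("D", "E"),
       D = "D", T = c("S", "T"), K = "K")
}

# internal: validate a rules list covering exactly the five landmarks
check_rules <- function(rules) {
  if (!setequal(names(rules), LANDMARK_NAMES)) {
    stop("rules must cover exactly DD1, DD2, D, T, K", call. = FALSE)
  }
  for (l in LANDMARK_NAMES) {
    allowed <- rules[[l]]
    if (length(allowed) == 0L || !all(allowed %in% AMINO_ACIDS)) {
      stop("allowed set for ", l,
           " must be a non-empty subset of the 20 amino acids", call. = FALSE)
    }
  }
  rules[LANDMARK_NAMES]
}

#' Classify one aligned domain as receiver or pseudo-receiver
#'
#' A domain is a receiver iff all five landmark columns hold an allowed
#' residue; otherwise it is a pseudo-receiver (PsR). PsRs missing the D
#' phosphorylation site are additionally flagged as aspartate-less receivers
#' (ALRs). Gaps count as missing: a domain that fails to align a landmark
#' cannot present the catalytic residue.
#'
#' @param sequence One aligned row: a single string or a character vector of
#'   residues, the full alignment width.
#' @param map A `LandmarkMap`.
#' @param rules Named list of allowed residue sets; see
#'   [default_residue_rules()].
#' @param id Optional sequence id recorded on the call.
#' @return A list of class `DomainCall` with `sequence_id`, `call`
#'   (`"receiver"` or `"pseudo_receiver"`), `missing_landmarks`, `is_ALR`.
#' @export
classify_domain <- function(sequence, map, rules = default_residue_rules(),
                            id = NA_character_) {
  rules <- check_rules(rules)
  if (length(sequence) == 1L && is.character(sequence)) {
    sequence <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  }
  if (max(map$landmark_columns) > length(sequence)) {
    stop("malformed alignment row", call. = FALSE)
  }
  res <- toupper(sequence[map$landmark_columns])
  present <- mapply(function(r, allowed) r %in% allowed, res, rules)
  missing <- LANDMARK_NAMES[!present]
  structure(
    list(sequence_id = id,
         call = if (length(missing) == 0L) "receiver" else "pseudo_receiver",
         missing_landmarks = missing,
         is_ALR = "D" %in% missing),
    class = "DomainCall"
  )
}

#' @export
print.DomainCall <- function(x, ...) {
  cat(sprintf("DomainCall %s: %s%s%s\n", x$sequence_id, x$call,
              if (length(x$missing_landmarks))
                paste0(" (missing ", paste(x$missing_landmarks, collapse = ","), ")")
              else "",
              if (x$is_ALR) " [ALR]" else ""))
  invisible(x)
}

#' Partition an alignment into receivers and pseudo-receivers
#'
#' Applies [classify_domain()] to every row and splits the set, emulating the
#' sorting of PsR domains away from true receiver domains.
#'
#' @param alignment An `AlignedDomainSet`.
#' @param map A `LandmarkMap`.
#' @param rules Conserved-residue rules; see [default_residue_rules()].
#' @return List with `receivers` and `psrs` (both `AlignedDomainSet`s; group
#'   labels get `.receiver` / `.psr` suffixes) and `calls`, a data frame with
#'   one row per sequence (`sequence_id`, `call`, `missing_landmarks`
#'   comma-joined, `is_ALR`).
#' @export
partition_set <- function(alignment, map, rules = default_residue_rules()) {
  n <- n_sequences(alignment)
  if (n == 0L) stop("no sequences", call. = FALSE)
  rules <- check_rules(rules)
  # vectorized classification over rows (same semantics as classify_domain)
  lm_res <- alignment$residues[, map$landmark_columns, drop = FALSE]
  present <- vapply(seq_along(LANDMARK_NAMES), function(k) {
    lm_res[, k] %in% rules[[k]]
  }, logical(n))
  present <- matrix(present, nrow = n)
  missing_str <- apply(present, 1L, function(p) {
    paste(LANDMARK_NAMES[!p], collapse = ",")
  })
  is_receiver <- rowSums(present) == length(LANDMARK_NAMES)
  calls <- data.frame(
    sequence_id = alignment$ids,
    call = ifelse(is_receiver, "receiver", "pseudo_receiver"),
    missing_landmarks = missing_str,
    is_ALR = !present[, match("D", LANDMARK_NAMES)],
    stringsAsFactors = FALSE
  )
  subset_aln <- function(keep, suffix) {
    aligned_domain_set(alignment$residues[keep, , drop = FALSE],
                       ids = alignment$ids[keep],
                       group_label = paste0(alignment$group_label, suffix),
                       n_columns = alignment$n_columns)
  }
  list(receivers = subset_aln(is_receiver, ".receiver"),
       psrs = subset_aln(!is_receiver, ".psr"),
       calls = calls)
}

#' Fraction of sequences missing a conserved residue
#'
#' Counts, over every row of an alignment, how often a given position fails
#' to hold an allowed residue (gaps count as missing). Used both for
#' receiver-domain landmarks and for single-landmark domain families such as
#' HisKA / HisKA_3 / Hpt, where the one landmark is the conserved His
#' phosphorylation site (`allowed = "H"`).
#'
#' @param alignment An `AlignedDomainSet`.
#' @param allowed Character vector of residues that count as present.
#' @param at Position to examine: either an alignment column number, or a
#'   label string / `PositionLabel` resolved through `map`.
#' @param map A `LandmarkMap`; required when `at` is a label.
#' @return List with `missing_count`, `total`, `fraction_missing`.
#' @examples
#' aln <- aligned_domain_set(c("H", "H", "H", "Q"), group_label = "HisKA-toy")
#' landmark_presence_fraction(aln, allowed = "H", at = 1)
#' @export
landmark_presence_fraction <- function(alignment, allowed, at, map = NULL) {
  if (n_sequences(alignment) == 0L) stop("no sequences", call. = FALSE)
  if (length(allowed) == 0L || !all(allowed %in% AMINO_ACIDS)) {
    stop("allowed must be a non-empty subset of the 20 amino acids",
         call. = FALSE)
  }
  col <- if (is.numeric(at)) {
    as.integer(at)
  } else {
    if (is.null(map)) stop("map required to resolve a position label", call. = FALSE)
    resolve_position(at, map)
  }
  if (col < 1L || col > alignment$n_columns) {
    stop("position outside alignment", call. = FALSE)
  }
  res <- alignment$residues[, col]
  missing_count <- sum(!res %in% allowed)
  total <- length(res)
  list(missing_count = missing_count, total = total,
       fraction_missing = missing_count / total)
}

#' Summarize domain calls
#'
#' @param calls The `calls` data frame from [partition_set()].
#' @return List of counts and fractions: `n`, `n_receiver`, `n_psr`, `n_alr`,
#'   `fraction_psr`, `fraction_alr`, and per-landmark missing fractions.
#' @export
summarize_calls <- function(calls) {
  n <- nrow(calls)
  missing <- strsplit(calls$missing_landmarks, ",", fixed = TRUE)
  per_landmark <- vapply(LANDMARK_NAMES, function(l) {
    sum(vapply(missing, function(m) l %in% m, logical(1))) / n
  }, numeric(1))
  list(n = n,
       n_receiver = sum(calls$call == "receiver"),
       n_psr = sum(calls$call == "pseudo_receiver"),
       n_alr = sum(calls$is_ALR),
       fraction_psr = mean(calls$call == "pseudo_receiver"),
       fraction_alr = mean(calls$is_ALR),
       fraction_missing_by_landmark = as.list(per_landmark))
}

#' Write a classification report
#'
#' Writes the per-sequence calls as TSV and, optionally, a JSON summary of
#' counts and fractions next to it.
#'
#' @param calls The `calls` data frame from [partition_set()].
#' @param path Output TSV path.
#' @param summary_path Optional JSON path for [summarize_calls()] output.
#' @return `path`, invisibly.
#' @export
write_domain_calls <- function(calls, path, summary_path = NULL) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(summary_path)) {
    jsonlite::write_json(summarize_calls(calls), summary_path,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
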