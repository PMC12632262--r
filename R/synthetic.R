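#' Per-column background distributions with named biases
#'
#' Builds the 20 x n_columns background matrix for [synthetic_spec()].
#' Unbiased columns are uniform over the 20 amino acids. A bias is a named
#' probability vector (summing to at most 1) for one column; the remaining
#' mass is spread uniformly over the unnamed letters.
#'
#' @param n_columns Alignment width.
#' @param bias Named list: `bias[["88"]] = c(A = 0.45, G = 0.29)` biases
#'   column 88.
#' @return A 20 x `n_columns` column-stochastic matrix (rows = amino acids).
#' @export
make_background <- function(n_columns, bias = list()) {
  bg <- matrix(1 / 20, nrow = 20L, ncol = n_columns,
               dimnames = list(AMINO_ACIDS, NULL))
  for (col_name in names(bias)) {
    j <- as.integer(col_name)
    b <- bias[[col_name]]
    if (!all(names(b) %in% AMINO_ACIDS)) stop("bias letters must be amino acids", call. = FALSE)
    if (any(b < 0) || sum(b) > 1 + 1e-9) stop("bias probabilities must be in [0,1]", call. = FALSE)
    p <- rep(0, 20L)
    names(p) <- AMINO_ACIDS
    p[names(b)] <- b
    rest <- setdiff(AMINO_ACIDS, names(b))
    if (length(rest) > 0L) p[rest] <- (1 - sum(b)) / length(rest)
    bg[, j] <- p
  }
  bg
}

#' Landmark site specification for the generator
#'
#' @param column Alignment column of the landmark.
#' @param class Conserved residue class (e.g., `c("D", "E")`).
#' @param prob Conservation probability: chance a sequence draws its residue
#'   from `class`.
#' @param fallback Named probability vector over the residues drawn when the
#'   site is *not* conserved; letters must lie outside `class`. Default:
#'   uniform over the non-class amino acids.
#' @param class_weights Optional named weights within `class` (default
#'   uniform).
#' @return A validated list for use in `synthetic_spec(landmarks = ...)`.
#' @export
landmark_site <- function(column, class, prob, fallback = NULL,
                          class_weights = NULL) {
  if (prob < 0 || prob > 1) stop("prob must be in [0,1]", call. = FALSE)
  if (!all(class %in% AMINO_ACIDS)) stop("class letters must be amino acids", call. = FALSE)
  if (is.null(fallback)) {
    rest <- setdiff(AMINO_ACIDS, class)
    fallback <- setNames(rep(1 / length(rest), length(rest)), rest)
  }
  if (!all(names(fallback) %in% setdiff(AMINO_ACIDS, class))) {
    stop("fallback letters must be amino acids outside the conserved class",
         call. = FALSE)
  }
  fallback <- fallback / sum(fallback)
  if (is.null(class_weights)) {
    class_weights <- setNames(rep(1 / length(class), length(class)), class)
  }
  if (!setequal(names(class_weights), class)) {
    stop("class_weights must cover the class", call. = FALSE)
  }
  class_weights <- class_weights / sum(class_weights)
  list(column = as.integer(column), class = class, prob = prob,
       fallback = fallback, class_weights = class_weights)
}

#' Coupled column block for the generator
#'
#' A block of two or more columns drawn jointly: with probability `coupling`
#' a sequence takes one of two designated letter combinations (each with
#' probability 1/2) across all block columns simultaneously; otherwise every
#' block column is drawn independently from the background. A two-column
#' block is a coupled pair. The mixture makes the planted mutual information
#' analytically tractable and monotone in `coupling`.
#'
#' @param columns Integer vector (length >= 2) of distinct columns.
#' @param coupling Mixture weight of the coupled component, in \[0, 1\].
#' @param combos List of exactly two character vectors, each of
#'   `length(columns)` amino-acid letters.
#' @return A validated list for use in `synthetic_spec(coupled = ...)`.
#' @export
coupled_block <- function(columns, coupling,
                          combos = list(rep("W", length(columns)),
                                        rep("C", length(columns)))) {
  columns <- as.integer(columns)
  if (length(columns) < 2L || anyDuplicated(columns)) {
    stop("columns must be >= 2 distinct columns", call. = FALSE)
  }
  if (coupling < 0 || coupling > 1) stop("coupling must be in [0,1]", call. = FALSE)
  if (length(combos) != 2L) stop("exactly two letter combinations required", call. = FALSE)
  for (cmb in combos) {
    if (length(cmb) != length(columns) || !all(cmb %in% AMINO_ACIDS)) {
      stop("combo letters must be amino acids, one per block column", call. = FALSE)
    }
  }
  list(columns = columns, coupling = coupling, combos = combos)
}

#' Specification for a synthetic aligned domain set
#'
#' Defines everything [generate_alignment()] needs: per-column background
#' distributions, landmark columns with tunable conservation, coupled column
#' blocks with tunable strength, per-column gap rates, and the seed.
#' Generation is a pure function of the spec (including its seed).
#'
#' @param n_sequences,n_columns Alignment dimensions.
#' @param background 20 x `n_columns` matrix from [make_background()]
#'   (default uniform).
#' @param landmarks Optional named list of [landmark_site()]s; names from
#'   DD1, DD2, D, T, K.
#' @param coupled Optional list of [coupled_block()]s; block columns must be
#'   distinct across blocks and must not touch landmark columns.
#' @param gap_rate Per-cell gap probability: scalar or per-column vector.
#' @param group_label Label for the generated set.
#' @param seed Integer seed.
#' @return Object of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(n_sequences, n_columns, background = NULL,
                           landmarks = NULL, coupled = NULL, gap_rate = 0,
                           group_label = "synthetic", seed = 1L) {
  if (n_sequences < 1L || n_columns < 1L) stop("empty spec", call. = FALSE)
  if (is.null(background)) background <- make_background(n_columns)
  stopifnot(nrow(background) == 20L, ncol(background) == n_columns)
  if (any(background < 0) || any(abs(colSums(background) - 1) > 1e-8)) {
    stop("background columns must be probability distributions", call. = FALSE)
  }
  lm_cols <- integer(0)
  if (!is.null(landmarks)) {
    if (!all(names(landmarks) %in% LANDMARK_NAMES)) {
      stop("landmark names must be among DD1, DD2, D, T, K", call. = FALSE)
    }
    lm_cols <- vapply(landmarks, `[[`, integer(1), "column")
    if (anyDuplicated(lm_cols) || any(lm_cols < 1L) || any(lm_cols > n_columns)) {
      stop("landmark columns must be distinct and inside the alignment", call. = FALSE)
    }
  }
  if (!is.null(coupled)) {
    all_cols <- unlist(lapply(coupled, `[[`, "columns"))
    if (anyDuplicated(all_cols)) stop("coupled blocks must not share columns", call. = FALSE)
    if (any(all_cols %in% lm_cols)) stop("coupled columns must not be landmark columns", call. = FALSE)
    if (any(all_cols < 1L) || any(all_cols > n_columns)) {
      stop("coupled columns outside the alignment", call. = FALSE)
    }
  }
  gap_rate <- rep_len(gap_rate, n_columns)
  if (any(gap_rate < 0) || any(gap_rate > 1)) stop("gap_rate must be in [0,1]", call. = FALSE)
  structure(
    list(n_sequences = as.integer(n_sequences),
         n_columns = as.integer(n_columns),
         background = background, landmarks = landmarks, coupled = coupled,
         gap_rate = gap_rate, group_label = group_label,
         seed = as.integer(seed)),
    class = "SyntheticSpec"
  )
}

# internal: run code with a private RNG stream, restoring global state after
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic aligned domain set
#'
#' Draws residues column-wise from the background, overwrites landmark
#' columns (conserved-class draw with the site's conservation probability,
#' fallback distribution otherwise), overwrites coupled blocks (joint
#' two-combination mixture), then injects gaps independently per cell. The
#' truth record keeps everything needed to score downstream recovery.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `alignment` (an `AlignedDomainSet`), `map` (a
#'   `LandmarkMap` with identity numbering when all five landmarks are
#'   specified, else `NULL`), and `truth`: `landmark_intact` (sequence x
#'   landmark logical: conserved draw and not gapped), `call` (planted
#'   receiver/pseudo_receiver when all landmarks present), `is_ALR`, and
#'   `coupled_rows` (per block, which sequences drew the coupled component).
#' @export
generate_alignment <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  n <- spec$n_sequences
  p <- spec$n_columns
  with_local_seed(spec$seed, {
    res <- matrix("", nrow = n, ncol = p)
    for (j in seq_len(p)) {
      res[, j] <- sample(AMINO_ACIDS, n, replace = TRUE,
                         prob = spec$background[, j])
    }
    lm_names <- names(spec$landmarks)
    conserved <- matrix(TRUE, nrow = n, ncol = length(lm_names),
                        dimnames = list(NULL, lm_names))
    for (l in lm_names) {
      site <- spec$landmarks[[l]]
      cons <- stats::runif(n) < site$prob
      conserved[, l] <- cons
      if (any(cons)) {
        res[cons, site$column] <- sample(site$class, sum(cons), replace = TRUE,
                                         prob = site$class_weights)
      }
      if (any(!cons)) {
        res[!cons, site$column] <- sample(names(site$fallback), sum(!cons),
                                          replace = TRUE, prob = site$fallback)
      }
    }
    coupled_rows <- vector("list", length(spec$coupled))
    for (b in seq_along(spec$coupled)) {
      blk <- spec$coupled[[b]]
      rows <- stats::runif(n) < blk$coupling
      if (any(rows)) {
        combo <- sample(c(1L, 2L), sum(rows), replace = TRUE)
        for (k in seq_along(blk$columns)) {
          res[rows, blk$columns[k]] <- ifelse(combo == 1L,
                                              blk$combos[[1L]][k],
                                              blk$combos[[2L]][k])
        }
      }
      coupled_rows[[b]] <- rows
    }
    gaps <- matrix(stats::runif(n * p) <
                     matrix(spec$gap_rate, n, p, byrow = TRUE), n, p)
    res[gaps] <- GAP_CHAR

    intact <- conserved
    for (l in lm_names) {
      intact[, l] <- conserved[, l] & !gaps[, spec$landmarks[[l]]$column]
    }
    full <- all(LANDMARK_NAMES %in% lm_names)
    truth <- list(
      landmark_intact = intact,
      call = if (full) {
        ifelse(rowSums(intact[, LANDMARK_NAMES, drop = FALSE]) == 5L,
               "receiver", "pseudo_receiver")
      } else NULL,
      is_ALR = if (full) !intact[, "D"] else NULL,
      coupled_rows = coupled_rows
    )
    aln <- aligned_domain_set(res, ids = sprintf("syn%05d", seq_len(n)),
                              group_label = spec$group_label)
    map <- if (full) {
      cols <- vapply(spec$landmarks[LANDMARK_NAMES], `[[`, integer(1), "column")
      landmark_map_from_columns(cols, p, reference_id = "synthetic")
    } else NULL
    list(alignment = aln, map = map, truth = truth)
  })
}

#' Generate a matched two-group fixture
#'
#' Generates two alignments over an identical column map (same width, same
#' landmark columns) so their covariation analyses are directly comparable
#' in [rank_shift()]. The truth records list each group's planted blocks.
#'
#' @param spec_receiver,spec_psr [synthetic_spec()]s with equal `n_columns`
#'   (and identical landmark columns when landmarks are specified).
#' @return List with `receiver`, `psr` (`AlignedDomainSet`s), `map` (shared
#'   `LandmarkMap` or `NULL`), `truth_receiver`, `truth_psr`.
#' @export
make_two_group_fixture <- function(spec_receiver, spec_psr) {
  if (spec_receiver$n_columns != spec_psr$n_columns) {
    stop("mismatched columns", call. = FALSE)
  }
  cols_of <- function(s) {
    if (is.null(s$landmarks)) integer(0)
    else sort(vapply(s$landmarks, `[[`, integer(1), "column"))
  }
  if (!identical(cols_of(spec_receiver), cols_of(spec_psr))) {
    stop("mismatched columns", call. = FALSE)
  }
  r <- generate_alignment(spec_receiver)
  p <- generate_alignment(spec_psr)
  list(receiver = r$alignment, psr = p$alignment,
       map = if (!is.null(r$map)) r$map else p$map,
       truth_receiver = r$truth, truth_psr = p$truth)
}
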