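#' Synthetic study specifications for the receiver vs. PsR comparison
#'
#' Builds the pair of generator specs used throughout the analysis scripts:
#' two CheY-width (129-column) alignments, one emulating a representative
#' receiver-domain database and one emulating the PsR database of 9,153
#' sequences. The planted conditions follow the published group contrasts:
#'
#' * landmark conservation (receivers ~100% at all five sites; PsRs 80% at
#'   DD1, 20% at DD2, 65% at D, 70% Ser/Thr at T, 65% at K, with
#'   characteristic substitutions: Asn at DD2, Glu at D, Ala at T, Arg at K);
#' * composition biases at named positions: Ala+Gly at T+1 (74% vs 43%),
#'   Phe/Tyr at K-3 (86% vs 65%), Phe vs Ala/Ile/Leu/Val at K+2 (40/39 vs
#'   20/55), Pro at D+4 and Gly at D+8 (reduced in PsRs);
#' * coupled column blocks shared by both groups (the strongest link placed
#'   on the same pair in both, echoing DD+5/D-22), one receiver-only block
#'   and one PsR-only block so the rank-shift comparison has signal in both
#'   directions, and one block much stronger in PsRs;
#' * 3% gaps per cell away from the landmark columns.
#'
#' Landmark columns sit at the CheY positions (12, 13, 57, 87, 109) so the
#' identity column map doubles as CheY numbering.
#'
#' @param n_receiver,n_psr Group sizes (default 9,153 each: the PsR database
#'   size, with an equal-size receiver group so MI sampling bias is matched
#'   between groups).
#' @param seed Integer seed; the two groups derive distinct sub-seeds.
#' @return List with `receiver` and `psr` [synthetic_spec()]s.
#' @export
psr_study_specs <- function(n_receiver = 9153, n_psr = 9153, seed = 20251001) {
  n_columns <- 129L
  lm_cols <- c(DD1 = 12L, DD2 = 13L, D = 57L, T = 87L, K = 109L)

  receiver_landmarks <- list(
    DD1 = landmark_site(lm_cols[["DD1"]], c("D", "E"), 1,
                        class_weights = c(D = 0.9, E = 0.1)),
    DD2 = landmark_site(lm_cols[["DD2"]], c("D", "E"), 1,
                        class_weights = c(D = 0.95, E = 0.05)),
    D = landmark_site(lm_cols[["D"]], "D", 1),
    T = landmark_site(lm_cols[["T"]], c("S", "T"), 1,
                      class_weights = c(T = 0.8, S = 0.2)),
    K = landmark_site(lm_cols[["K"]], "K", 1)
  )
  psr_landmarks <- list(
    DD1 = landmark_site(lm_cols[["DD1"]], c("D", "E"), 0.80,
                        class_weights = c(D = 0.85, E = 0.15)),
    DD2 = landmark_site(lm_cols[["DD2"]], c("D", "E"), 0.20,
                        fallback = c(N = 0.5, S = 0.15, A = 0.1, G = 0.1,
                                     H = 0.08, Q = 0.07),
                        class_weights = c(D = 0.9, E = 0.1)),
    D = landmark_site(lm_cols[["D"]], "D", 0.65,
                      fallback = c(E = 0.6, N = 0.12, A = 0.1, S = 0.1,
                                   G = 0.08)),
    T = landmark_site(lm_cols[["T"]], c("S", "T"), 0.70,
                      fallback = c(A = 0.4, V = 0.18, G = 0.16, E = 0.14,
                                   D = 0.12),
                      class_weights = c(T = 0.75, S = 0.25)),
    K = landmark_site(lm_cols[["K"]], "K", 0.65,
                      fallback = c(R = 0.5, Q = 0.2, A = 0.1, E = 0.1,
                                   T = 0.1))
  )

  receiver_bias <- list(
    "88" = c(A = 0.45, G = 0.29),                          # T+1: Ala+Gly 74%
    "106" = c(Y = 0.50, F = 0.36),                         # K-3: aromatic 86%
    "111" = c(F = 0.40, A = 0.12, I = 0.09, L = 0.09, V = 0.09), # K+2
    "61" = c(P = 0.80),                                    # D+4 Pro (gamma turn)
    "65" = c(G = 0.75)                                     # D+8 Gly
  )
  psr_bias <- list(
    "88" = c(A = 0.30, G = 0.13, D = 0.12, E = 0.12),      # T+1: Ala+Gly 43%
    "106" = c(Y = 0.40, F = 0.25),                         # K-3: aromatic 65%
    "111" = c(F = 0.20, A = 0.17, I = 0.13, L = 0.13, V = 0.12),
    "61" = c(P = 0.30, D = 0.15, E = 0.15),
    "65" = c(G = 0.35)
  )

  shared_combos <- list(c("W", "C"), c("H", "M"))
  receiver_coupled <- list(
    coupled_block(c(17L, 35L), 0.95, shared_combos),  # strongest in both groups
    coupled_block(c(59L, 89L), 0.85, shared_combos),  # active-site adjacent, both
    coupled_block(c(66L, 96L), 0.80, shared_combos),  # receiver-only linkage
    coupled_block(c(110L, 115L), 0.60, shared_combos) # weak in receivers
  )
  psr_coupled <- list(
    coupled_block(c(17L, 35L), 0.95, shared_combos),
    coupled_block(c(59L, 89L), 0.85, shared_combos),
    coupled_block(c(21L, 101L), 0.80, shared_combos), # PsR-only linkage
    coupled_block(c(110L, 115L), 0.90, shared_combos) # strong in PsRs
  )

  gap_rate <- rep(0.03, n_columns)
  gap_rate[lm_cols] <- 0

  list(
    receiver = synthetic_spec(
      n_sequences = n_receiver, n_columns = n_columns,
      background = make_background(n_columns, receiver_bias),
      landmarks = receiver_landmarks, coupled = receiver_coupled,
      gap_rate = gap_rate, group_label = "receiver",
      seed = seed),
    psr = synthetic_spec(
      n_sequences = n_psr, n_columns = n_columns,
      background = make_background(n_columns, psr_bias),
      landmarks = psr_landmarks, coupled = psr_coupled,
      gap_rate = gap_rate, group_label = "psr",
      seed = seed + 1L)
  )
}

#' Synthetic single-landmark kinase-family alignment
#'
#' Emulates a HisKA / HisKA_3 / Hpt-style domain alignment in which a single
#' conserved His phosphorylation site is present in most sequences. Used to
#' exercise [landmark_presence_fraction()] at database scale.
#'
#' @param n_sequences Number of sequences.
#' @param missing_rate Planted probability that a sequence lacks the
#'   conserved His (default 0.009, the published HisKA rate).
#' @param n_columns Alignment width (default 25; the His sits mid-alignment).
#' @param seed Integer seed.
#' @return List with `alignment` (an `AlignedDomainSet`), `his_column`, and
#'   `missing_rate`.
#' @export
his_domain_fixture <- function(n_sequences, missing_rate = 0.009,
                               n_columns = 25L, seed = 1L) {
  his_col <- as.integer(ceiling(n_columns / 2))
  bias <- list()
  bias[[as.character(his_col)]] <- c(H = 1 - missing_rate)
  spec <- synthetic_spec(
    n_sequences = n_sequences, n_columns = n_columns,
    background = make_background(n_columns, bias),
    group_label = "hiska", seed = seed)
  list(alignment = generate_alignment(spec)$alignment,
       his_column = his_col, missing_rate = missing_rate)
}
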