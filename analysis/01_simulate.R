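#!/usr/bin/env Rscript
# Generate the synthetic receiver / PsR study alignments.
#
# The study set emulates the published comparison: a PsR database of 9,153
# bacterial pseudo-receiver domains and an equally sized receiver
# counterpart, both 129 columns wide on CheY numbering, with planted
# landmark conservation, composition contrasts at named positions, and
# coupled column pairs. Generation is deterministic for a given seed, so
# the later scripts regenerate the same alignments instead of re-reading
# the FASTA copies written here.

suppressMessages(library(psrcov))

STUDY_SEED <- 20251001
dir.create("results", showWarnings = FALSE)
dir.create("scratch/study", showWarnings = FALSE, recursive = TRUE)

specs <- psr_study_specs(seed = STUDY_SEED)
fix <- make_two_group_fixture(specs$receiver, specs$psr)

cat("Generated study alignments (seed", STUDY_SEED, "):\n")
print(fix$receiver)
print(fix$psr)
cat("Landmark columns (CheY numbering):\n")
print(fix$map$landmark_columns)

# full alignments are bulky; they land in scratch/, not results/
write_alignment(fix$receiver, "scratch/study/receiver_pool.fasta")
write_alignment(fix$psr, "scratch/study/psr_pool.fasta")

truth <- list(
  seed = STUDY_SEED,
  n_receiver_pool = n_sequences(fix$receiver),
  n_psr_pool = n_sequences(fix$psr),
  n_columns = fix$receiver$n_columns,
  planted_receiver_fraction_in_psr_pool =
    mean(fix$truth_psr$call == "receiver"),
  planted_alr_fraction_in_psr_pool = mean(fix$truth_psr$is_ALR),
  coupled_blocks_receiver = lapply(specs$receiver$coupled, function(b) {
    list(columns = b$columns, coupling = b$coupling)
  }),
  coupled_blocks_psr = lapply(specs$psr$coupled, function(b) {
    list(columns = b$columns, coupling = b$coupling)
  })
)
jsonlite::write_json(truth, "results/01_truth_summary.json",
                     auto_unbox = TRUE, digits = NA)

cat(sprintf("\nPlanted composition of the PsR pool: %.1f%% PsR, %.1f%% ALR.\n",
            100 * mean(fix$truth_psr$call == "pseudo_receiver"),
            100 * mean(fix$truth_psr$is_ALR)))
cat("Wrote scratch/study/*.fasta and results/01_truth_summary.json\n")
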