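---
title: "Methods: comparative composition and covariation analysis of receiver and pseudo-receiver domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative composition and covariation analysis of receiver and pseudo-receiver domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scientific setting

Receiver domains are the phospho-accepting modules of bacterial
two-component signaling: a (βα)~5~ fold whose active site is built from five
conserved residues — an acidic pair (DD1, DD2) that coordinates the Mg^2+^
ion, the aspartate phosphorylation site (D), a Ser/Thr (T) and a Lys (K)
that contact the phosphoryl group. Pseudo-receiver (PsR) domains are
sequences that profile-based domain detection recognizes as receivers but
that lack at least one of these five residues, and therefore cannot run
normal His→Asp phosphotransfer chemistry; the PsR subset lacking D is the
aspartate-less receiver (ALR) class. `psrcov` implements the sequence-level
comparisons used to contrast the two groups: landmark-based classification,
position-wise amino-acid composition and its between-group differences,
corrected mutual-information covariation with significance and network
extraction, and a between-group percentile rank-shift comparison. A
synthetic alignment generator with fully known planted structure makes
every stage testable without external data.

All positional bookkeeping is anchored to *E. coli* CheY: the packaged
reference fixture (`inst/extdata/chey_landmarks.tsv`) carries the CheY
sequence and its landmark residue numbers (DD1 = Asp12, DD2 = Asp13,
D = Asp57, T = Thr87, K = Lys109), and `build_landmark_map()` walks the
reference row of an alignment to assign CheY numbers to columns. Relative
labels such as `T+1` or `K-3` count *reference residues*, skipping columns
where the reference is gapped. Labels written `DD±k` are anchored at DD1:
the two acidic residues need not be adjacent in every alignment, and the
N-terminal member of the pair is the stable anchor for α1-proximal
positions. Column indices are 1-based internally, following the R
convention; everything user-facing is reported in CheY numbers.

## Classification

`classify_domain()` applies one allowed-residue set per landmark. The
defaults are DD1, DD2 ∈ {D, E} (both positions are essentially 100% acidic
in true receivers), D ∈ {D} only — so the hallmark ALR substitution,
Glu at D, counts as missing — T ∈ {S, T}, and K ∈ {K}. A gap at a landmark
column always counts as missing: a domain that fails to align a landmark
cannot present the catalytic residue. Classification is binary
(receiver / pseudo-receiver) with the ALR flag defined as "D missing"; all
sets are overridable for sensitivity analyses. The same counting machinery
(`landmark_presence_fraction()`) applied to a single conserved His
reproduces missing-phosphorylation-site surveys for HisKA / HisKA_3 /
Hpt-style alignments.

## Composition profiles and differences

`composition_profile()` reports percent abundance of each amino acid per
reference-mapped column **among non-gap residues**, with the gap fraction
reported separately. The gap-exclusive denominator is a deliberate choice:
the statements the profiles support are about residue preferences (e.g.,
"the DD pair is 100% acidic in receivers"), which are only well defined
among observed residues. Entirely gapped columns are flagged and excluded.
Sequences are weighted uniformly: the intended input is a
redundancy-reduced representative set, so no additional down-weighting of
similar sequences is assumed.

`composition_difference()` subtracts profiles position-by-position
(receiver minus PsR). For display the differences are clipped to ±20
percentage points — the scale at which group differences saturate
visually — while raw values are always retained and exported.
`paired_retention()` evaluates per-sequence conjunctions such as the Y-T
coupling requirement (Ser/Thr at T *and* Phe/Tyr at K−3); a gap fails its
criterion.

## Corrected mutual-information covariation

For columns *i*, *j*, the raw score is mutual information in bits,

MI(i,j) = Σ~a,b~ p(a,b) log~2~ [ p(a,b) / (p(a) p(b)) ],

computed over rows where neither column is gapped (pairwise deletion).
Treating the gap as a 21st symbol inflates MI with alignment artifacts
(gap–gap co-occurrence is mostly a statement about indel placement, not
coevolution), so it is not the default. No pseudocount is applied by
default; a small additive pseudocount per joint cell is available behind a
flag. Columns gapped in more than half the sequences
(`max_gap_fraction = 0.5`) are dropped before analysis — covariation over
sparsely populated columns is dominated by coverage, not signal.

Raw MI carries a large shared background (entropy and phylogeny). The
correction is the average-product correction:

APC(i,j) = MI(i,·) × MI(·,j) / ⟨MI⟩,  corrected = MI − APC,

where MI(i,·) is column *i*'s mean off-diagonal MI and ⟨MI⟩ the overall
off-diagonal mean. Corrected values may be negative; an identically zero
matrix corrects to zero by convention. Significance is a global z-score:
each corrected score standardized against the mean and sample standard
deviation of all off-diagonal corrected scores, significant at z ≥ 6.5.
This construction has a practical consequence worth knowing: with *k*
near-equal strong pairs among *P* pairs, the attainable z is bounded near
√(P/k), so a dense block of equally strong couplings in a small column set
can saturate below threshold. The test suite sizes its planted examples
with this in mind.

Within-alignment strength is expressed as percentile ranks: off-diagonal
pairs ranked by corrected score (ties share their mean rank), scaled to
(0, 100]. Between groups, MI magnitudes are not directly comparable —
they depend on alignment depth and diversity — so `rank_shift()` compares
each pair's percentile *within its own group*: shift = receiver percentile
− PsR percentile, over pairs significant in at least one group, keeping
the top 2% by |shift| (ceiling, boundary ties included; exact-zero shifts
are never selected, so identical inputs yield an empty selection).
Positive shifts mean the interaction ranks higher in receivers.

## Networks, clusters, and hubs

`build_networks()` tiers the significant pairs: *core* edges fall in the
top 1% of corrected MI, *extended* edges in the top 1–2%. The percentile
pool is the significant set by default (`percentile_basis = "all"` computes
the thresholds over all pairs and then intersects with the significant
set). Clusters are connected components of the core graph with at least
three members; extended edges attach to a cluster when incident on a
member (first-order neighbors only).

The best-neighbor filter — keep an edge iff it is the maximum-scoring edge
of at least one endpoint — is implemented (`best_neighbor_filter()`) and
annotated on every core edge as a display backbone, but it does *not*
define cluster membership by default. The reason is structural: within a
tightly coupled block the edge scores are exchangeable up to sampling
noise, and the union of per-node best edges then degenerates to a perfect
matching with appreciable probability (about 1/5 for a 4-clique), splitting
one real cluster into sub-minimum fragments. Filtering is the right tool
for de-cluttering a drawing, not for deciding membership, so membership
defaults to components of the full core graph; `cluster_on =
"best_neighbor"` restores filter-based components for comparison.

`hub_report()` sums, per position, the corrected-MI scores of its
significant incident pairs (each edge credits both endpoints, so total
cumulative score is twice the edge-score sum) and reports degree and the
top-k positions, ties broken toward smaller CheY numbers.

## The synthetic generator and what it does (not) emulate

`generate_alignment()` draws each column independently from a per-column
categorical background, then overwrites landmark columns (conserved-class
draw with probability `prob`, else a fallback distribution outside the
class), then coupled blocks, then injects gaps per cell. A coupled block
draws, with probability `coupling`, all block columns jointly from one of
two designated letter combinations (each with probability 1/2); otherwise
columns are independent background draws. The mixture is analytically
tractable: with the background restricted to the two combo letters the
planted MI has the closed form used in the tests and is strictly monotone
in `coupling`. With a wide background it is *not* monotone near strong
coupling — marginal entropy collapses as the mixture concentrates — which
is why planted "strengths" are statements about the mixture weight, not
about the resulting MI ordering. All draws derive from one seeded PRNG
stream per generation call, so output is a pure function of (spec, seed),
and the caller's RNG state is left untouched.

The default study conditions (`psr_study_specs()`) emulate the published
group contrast: a PsR pool of 9,153 sequences (the size of the published
representative PsR database) and an equal-size receiver pool — the
receiver database size is not printed, and matching the group sizes keeps
MI sampling bias symmetric in the rank-shift comparison. The 129-column
width equals the CheY reference length, so the identity column map doubles
as CheY numbering. Planted marginals follow the published percentages:
landmark conservation (receivers ~100% at all five; PsRs 80% at DD1, 20%
at DD2, 65% at D, 70% Ser/Thr at T, 65% at K, with the characteristic
substitutions Asn at DD2, Glu at D, Ala at T, Arg at K), T+1 Ala+Gly 74%
vs 43%, K−3 Phe/Tyr 86% vs 65%, K+2 Phe 40% vs 20% against
Ala/Ile/Leu/Val 39% vs 55%, and reduced Pro at D+4 / Gly at D+8 in PsRs.
Gaps are injected at 3% per cell away from the landmark columns (kept
gap-free so planted conservation rates are exactly the classification
rates). Four coupled pairs per group share two links across groups, one is
receiver-only, one PsR-only, and one is much stronger in PsRs, giving the
rank-shift comparison signal in both directions.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: phylogenetic correlation between sequences
(every row is independent), insertion/deletion structure (gaps are
independent per cell), multi-way epistasis beyond the planted blocks, and
the long-tailed background covariation of real alignments (the synthetic
background is independent across columns, so the significant fraction on
synthetic data is far below the ~9% seen in real PsR alignments, and only
planted pairs reach z ≥ 6.5). Consequently, cluster recovery on synthetic
data demonstrates correctness of the extraction machinery, not that real
networks will be as crisp.

## Numerical conventions and degenerate inputs

* MI is computed in bits over the exact 20-letter alphabet; ambiguity
  codes are rejected at parse time rather than recoded.
* Pairs with fewer than two ungapped shared rows are flagged
  ("insufficient coverage") and excluded from ranks and significance.
* Zero spread across corrected scores raises "degenerate score
  distribution" and marks nothing significant.
* Top-fraction selections use ceiling and include all boundary ties, so
  reported counts are reproducible; percentile ties share mean ranks.
* Classification, partitioning, and cluster extraction are deterministic
  and invariant to row and edge ordering.

## Problem sizes

The analysis scripts run the full study conditions (two 9,153 × 129
alignments; ~8.3k column pairs per group; a 76,471-row single-landmark
alignment for the His-site survey). The test suite works at reduced sizes
chosen so every statistical check retains comfortable power: 500 × 60
alignments for planted-pair, rank-shift, and network recovery (20, 20, and
10 fixed seeds respectively), n = 2,000 for the classification closed loop
against binomial 99% intervals, and n = 5,000 for generator convergence
checks.

## Known limitations

* The exact corrected-MI variant and z-score construction used upstream of
  the published numbers are not printed in the source text; average-product
  correction with a global sample-sd z is the declared interpretation here,
  and quantities that depend on that choice (the significant-pair fraction,
  exact network memberships, the count of significant rank shifts) are
  reported for comparison rather than promised.
* Composition percentages use gap-exclusive denominators; if the upstream
  convention included gaps, percentages at gappy columns shift by the gap
  fraction.
* No sequence weighting or phylogenetic correction is applied by default;
  both matter for alignments that are not redundancy-reduced.
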