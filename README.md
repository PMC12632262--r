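# psrcov

Comparative sequence analysis of bacterial **receiver** and
**pseudo-receiver (PsR)** domains.

Receiver domains are the phospho-accepting modules of two-component
signaling: a (βα)₅ fold whose active site is formed by five conserved
residues — the acidic metal-binding pair (DD1, DD2), the Asp
phosphorylation site (D), a Ser/Thr (T), and a Lys (K) — numbered here on
the *E. coli* CheY reference (Asp12, Asp13, Asp57, Thr87, Lys109).
Pseudo-receivers are domains that profile-based detection calls receivers
but that lack one or more of the five residues; the subset lacking D is
the aspartate-less receiver (ALR) class. `psrcov` is for sequence analysts
who want to contrast these groups from multiple sequence alignments: it
classifies domains, profiles amino-acid composition position by position,
measures residue covariation with corrected mutual information, extracts
covariation networks, and compares covariation between groups by rank
shifts — plus a synthetic alignment generator with known planted structure
so the whole pipeline is testable without downloads.

## Methods at a glance

* **Classification** — a domain is a receiver iff every landmark column
  holds an allowed residue (defaults: DD1, DD2 ∈ {D,E}; D ∈ {D}; T ∈ {S,T};
  K ∈ {K}; gaps count as missing). PsRs missing D are flagged ALR.
* **Composition** — percent abundance of each amino acid per CheY-numbered
  column among non-gap residues; group differences (receiver − PsR) with a
  ±20-point display clip; named-position statistics (`T+1`, `K-3`, `K+2`,
  …) and per-sequence conjunctions such as Y-T coupling retention (Ser/Thr
  at T *and* Phe/Tyr at K−3).
* **Covariation** — MI(i,j) = Σ p(a,b) log₂[p(a,b)/(p(a)p(b))] in bits
  with pairwise gap deletion, corrected by the average-product term
  APC(i,j) = MI(i,·)·MI(·,j)/⟨MI⟩; global z-scores (significant at
  z ≥ 6.5); within-group percentile ranks.
* **Networks** — core (top 1%) and extended (top 1–2%) significant edges;
  clusters are connected components of the core graph with ≥ 3 members;
  best-neighbor backbone annotation; per-position cumulative-MI hub scores.
* **Rank shift** — for each pair significant in at least one group,
  receiver percentile − PsR percentile; the top 2% by |shift| flags
  interactions whose putative importance differs between groups
  (positive = stronger in receivers).

## Worked example

```r
library(psrcov)

# classify three CheY variants against the packaged CheY landmark fixture
fx <- read_landmark_fixture()
aln <- aligned_domain_set(
  c(CheY = fx$sequence,
    psr1 = sub("^(.{56})D", "\\1E", fx$sequence),   # Glu at D57
    psr2 = sub("^(.{108})K", "\\1R", fx$sequence)), # Arg at K109
  group_label = "demo")
map <- build_landmark_map(aln, "CheY", fx$landmarks)
partition_set(aln, map)$calls
#>   sequence_id            call missing_landmarks is_ALR
#> 1        CheY        receiver                    FALSE
#> 2        psr1 pseudo_receiver                 D   TRUE
#> 3        psr2 pseudo_receiver                 K  FALSE
```

The Glu-for-Asp variant is called a pseudo-receiver and an ALR; the
Arg-for-Lys variant is a PsR but not an ALR.

```r
# a small synthetic receiver/PsR study set with planted group contrasts
specs <- psr_study_specs(n_receiver = 2000, n_psr = 2000, seed = 42)
fix <- make_two_group_fixture(specs$receiver, specs$psr)
receivers <- partition_set(fix$receiver, fix$map)$receivers
psrs <- partition_set(fix$psr, fix$map)$psrs

prof <- composition_profile(psrs, fix$map)
class_abundance(prof, "T+1", c("A", "G"), fix$map)
#> [1] 44.4   # percent Ala+Gly at T+1 in PsRs (planted: 43)
paired_retention(receivers, fix$map); paired_retention(psrs, fix$map)
#> [1] 0.81   # receivers retaining both Y-T coupling residues
#> [1] 0.42   # PsRs

cov_r <- covariation_analysis(receivers, fix$map)
cov_p <- covariation_analysis(psrs, fix$map)
rank_shift(cov_r, cov_p)$top[, 1:6]
#>  pos_i pos_j rank_receiver rank_psr  shift significant_in
#>     21   101         83.71    99.98 -16.27            psr
```

The top rank shift is the pair planted only in the PsR group (columns
21/101): near the top of the PsR ranking, unremarkable in receivers, so
its shift is negative — "stronger in PsRs".

## Analysis workflow

The `analysis/` scripts run the full study conditions (9,153 sequences per
group, 129 CheY-numbered columns) and write tables under `results/`
(alignment FASTAs go to `scratch/`):

1. `01_simulate.R` — generate the two pools and the planted-truth summary
2. `02_classify.R` — receiver/PsR/ALR sorting; missing-site survey for
   single-His domain families at published sampling depths
3. `03_composition.R` — profiles, difference matrix (+ heatmap),
   named-position table, Y-T retention
4. `04_covariation.R` — corrected-MI analyses and the rank-shift table
5. `05_networks.R` — network tiers, clusters, hub scores

```sh
Rscript analysis/01_simulate.R   # then 02..05 in order
```

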