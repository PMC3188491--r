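---
title: "Structure-guided sampling of alignment space: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-guided sampling of alignment space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the science inside `subalign`: the sampling
model and its assumptions, every tunable parameter with its default and
rationale, what the synthetic fixture generator does and does not
emulate, the numerical choices, and the places where the design was
genuinely open and a decision had to be made.

## The sampling model

Pairwise alignment of a query sequence to a structural template is a
path through the dynamic-programming (DP) matrix. For remote homologs
the similarity-score optimum is often not the alignment that produces
the best model, so a single optimal path is insufficient and a
*diverse, structurally plausible* ensemble is needed.

The sampler assembles alignments from short ungapped fragments confined
to the template's secondary structure elements (SSEs). The underlying
assumptions are:

* whatever sequence signal survives at low identity is concentrated in
  SSEs, not loops;
* a useful alignment pairs SSEs of the query with SSEs of the template,
  so alignment space can be coarse-grained into fragment combinations;
* template geometry vetoes most wrong combinations cheaply (loop reach,
  compactness, sheet topology, hydrophobic core preservation,
  statistical energies), so the surviving ensemble is small enough to
  enumerate yet broad enough to contain a near-correct member.

The six pipeline stages and the formulas they apply are described in
the README; this vignette concentrates on choices and caveats.

## Tunable parameters

All parameters live in `s4_config()`. Score-dimension quantities are in
the units of the active scorer (half-bits for the bundled BLOSUM62).

| parameter | default | meaning and rationale |
|---|---|---|
| `min_fragment_len` | 3 | minimum fragment length; matches the minimum SSE length |
| `k_per_sse` | 4 | primary fragments per SSE column; keeps pools at the tens-to-~120-fragment scale that makes exhaustive enumeration tractable while retaining the correct diagonal in practice |
| `adjacent_diagonal_tol` | 5 | residues; how far a secondary fragment's diagonal may sit from a flanking fragment's and still count as "adjacent" |
| `score_extra` | 2 | additional score-selected secondary fragments per intervening SSE |
| `max_total_alignments` | 1e7 | pool growth stops when the DAG path count would exceed this |
| `max_enumerated` | 2e4 | hard cap on explicitly enumerated chains (deterministic order), sized so the measure and redundancy stages stay fast on single domains |
| `min_coverage_frac` | 0.10 | fraction of the shorter sequence that must be aligned (SSE residues only) |
| `contact_order_ratio_min` | 0.65 | pseudomodel/template contact-order ratio |
| `loop_stretch_factor` | 3.3 | Å of template Cα–Cα distance bridged per query loop residue |
| `cb_contact_cutoff` | 6 | Å; Cβ–Cβ contact distance (contact order, core contacts) |
| `burial_min` | 0.6 | relative burial for a core-contact residue |
| `lower_percentile`, `upper_percentile` | 66, 90 | the two-tier percentile gate over the three measures |
| `redundancy_shift`, `redundancy_iad` | 4, 1.0 | fragment-shift and IAD thresholds for redundancy |
| `redundancy_pool_max` | 2000 | gate survivors (by score) entering the quadratic redundancy sweep |
| `corridor_margin` | 3 | half-width (residues) of the finishing band around fragments |
| `finish_delta` | 6 | initial score slack for in-corridor sampling; doubled until the candidate set spans `finish_max_n` distinct SSE-pairings |
| `finish_max_n` | 20 | distinct candidates the energy selection sees per corridor |
| `insertion_penalty` | 1.0 | flat penalty per internal inserted query residue; terminal insertions free; deletions unpenalized |
| `energy_score_weight` | 0 | weight of the similarity score in the finishing selection objective (`energy − weight · score`); 0 = pure lowest-energy selection |
| `gap_open`, `gap_extend` | 10, 1 | affine penalties for the DP baselines |

`s4_align()` additionally refuses templates longer than 350 residues by
default (`max_template_len`): exhaustive fragment-combination
enumeration is the point of the method, and it stops being exhaustive
on very long chains.

## The loop-stretch rule

A loop of `q_f − q_p` query residues must bridge the template Cα–Cα
distance `d(t_p, t_f)` between the fragments it connects; the rule
`3.3 · (q_f − q_p) ≥ d` reflects the ~3 Å of span an extended residue
contributes, with headroom so that slightly over-stretched pairings
survive to the finishing stage (which can repair them). Fragments that
are directly contiguous in both sequences enclose no loop at all and
pass unconditionally — without this case the literal inequality would
reject two abutting fragments whose endpoints sit one peptide bond
(~3.8 Å) apart.

## The statistical potential

Energies use a distance-dependent potential over Cα and Cβ atoms of
SSE residues, with the finite-ideal-gas style reference state
`e(i,j,r) = −η ln[N(i,j,r) / ((r/r_cut)^α · N(i,j,r_cut))]`, bins of
0.5 Å up to a 14.5 Å cutoff, α = 1.61, η = 1, and zero energy at and
beyond the cutoff bin. Three choices matter:

* **Inter-element pairs only.** Pairs within one SSE are excluded from
  both training and evaluation: on (idealized) regular backbones their
  distances are fixed by the geometry and carry no packing information,
  yet they would dominate the counts and dilute the burial signal.
* **Bonded-neighbor exclusion in both numberings.** A pair is counted
  only if separated by ≥ 2 positions in the template *and* in the
  query. With a query-only rule, a candidate that shifts its query
  numbering by one would win extra pair terms purely by escaping the
  exclusion — an artifact, not physics.
* **Shape-distributed pseudocounts.** `pseudocount = 5` pseudo-observations
  are distributed along the reference shape, so sparsely observed type
  pairs regularize to zero energy instead of acquiring large spurious
  values; with abundant counts the estimator converges to the plain
  count ratio. The cutoff-bin anchor (energy exactly zero) is preserved.

No table is bundled: `default_potential()` trains deterministically on
a fixed set of generated folds in a few seconds and is cached per
session; `train_potential()`/`write_potential()`/`read_potential()`
support user-supplied structure sets and table files.

## Finishing and the branch rule

Finishing runs a constrained δ-suboptimal DP inside the corridor.
Branching to an alternate path is allowed while *moving between SSE and
loop regions* — concretely, at any DP node not strictly interior to an
SSE. An earlier, narrower reading (branch points only at the first/last
column of each SSE) was abandoned: insertion runs immediately before an
SSE entry sit one column outside it, so whole-element shift variants —
exactly the alternatives the sampler exists to produce — were
unreachable. A template without SSEs has no SSE/loop transitions and
hence no branch points at all, so the constrained sampler degenerates
to the single optimal path there.

Within a corridor, paths that differ only in loop placement produce
essentially equivalent models; candidates are therefore deduplicated on
their SSE-restricted residue pairs, and δ doubles until `finish_max_n`
*distinct* pairings are available (or δ reaches 64). The fragment
alignment's own implied path is always included as a candidate, so
corridor sampling can refine the fragments but never silently replace
them with something the energy ranks worse. Selection minimizes
`energy − energy_score_weight · dp_score`; the default weight 0 is the
plain lowest-energy choice, and the weight exists as a regularizer for
scorers/potentials whose relative resolution differs from the defaults.

In-corridor gap costs follow the emission score convention: internal
insertions cost `insertion_penalty` per residue (linear), deletions and
terminal overhangs are free.

## The percentile gate

Energies are negated so "above the percentile" uniformly means better.
Percentile ranks use the linear `rank/(n−1)` definition with ties
sharing the mean rank. Two degenerate cases pass a candidate
unconditionally: sets with fewer than two candidates, and measures that
are constant across the whole candidate set (a measure that does not
discriminate cannot gate — without this rule an all-helix template
whose preserved-contact counts are all equal would reject every
candidate). The gate population is all candidates surviving the
enumeration-stage checks. If strongly anti-correlated measures leave
the two-tier gate empty, the pipeline falls back to the
all-above-lower arm and, failing that, to the candidates with the best
summed percentile rank, so a run always produces an ensemble.

## The synthetic fixture generator

`make_fold()` builds idealized folds: helices with 1.5 Å rise and 100°
twist per residue at 2.3 Å radius, strands as planar zigzags with 3.4 Å
rise, elements packed side-by-side antiparallel (helix–helix 10 Å,
strand–strand 4.8 Å, mixed 8 Å), connected by seeded coil-like random
walks with ~3.8 Å Cα steps. Backbone N/C and Cβ atoms are synthesized
with ideal tetrahedral geometry (the same construction reproduces real
Cβ positions to ~0.1 Å median on an experimental lysozyme structure).
Sequences are designed self-consistently: hydrophobic residues are
placed at positions whose *computed* burial in the assembled fold is
≥ 0.5, polar residues on exposed faces, flexible types in loops. This
self-consistency matters: an earlier design used the Cβ direction
relative to the fold centroid as a burial proxy, which mislabels
element termini and leaves the "native" sequence energetically
non-optimal — no statistical potential can then prefer the correct
alignment at single-residue resolution.

`make_homolog()` derives remote homologs by similarity-biased
substitution (replacement probabilities ∝ `exp(0.5·BLOSUM62)`) to an
exact target identity on aligned positions, planted insertions and
deletions confined to internal loops, and optional deletion of terminal
elements. Deletions shrink automatically until the ground-truth path
satisfies the loop-stretch rule on the template geometry, so every
generated truth is modelable. `make_benchmark()` draws 4–6-element
archetypes (helix bundles, β-sheets, mixed folds) with element lengths
of 6–13 residues — the scale of the small single domains the method
targets — at identities sampled within requested bins, 1–3 loop indels,
and a 0.3 probability of one terminal-element deletion.

What the fixtures do *not* emulate: real side-chain packing (only
Cβ-level geometry), β-bulges and strand twist, conformational change
between homolog pairs (the truth alignment is exact by construction),
and profile-level sequence signal (scoring uses BLOSUM62, far noisier
than profile–profile scorers at low identity). Passing tests therefore
demonstrate the machinery — exhaustive enumeration, correct filters,
broad sampling, energy-guided selection — at a fidelity where the
correct answer is knowable; they do not certify accuracy levels on
real remote-homolog pairs, which depend on scorer and potential
quality.

## Numerical and convention choices

* Indices are 1-based with closed intervals throughout, matching R;
  all formulas depend only on index differences.
* The DP kernels use a 3-state affine machine with canonical gap
  ordering (no deletion directly after an insertion), so each residue
  pairing corresponds to exactly one state path and δ-ensembles contain
  no duplicates. Suboptimality checks use an absolute tolerance of
  1e-9 on scores; enumeration is depth-first in a fixed deterministic
  order, and ties in the final score ordering preserve discovery order
  (shorter alignments before their extensions at equal score).
* Geometric SSE assignment (the DSSP-free fallback) requires two
  consecutive qualifying windows — helix: `d(i,i+4) ≈ 6.2 ± 0.5` Å with
  helical `d(i,i+2)`; strand: `d(i,i+2) ≈ 6.7 ± 0.6` Å with low
  curvature over `i→i+3` and near-planar Cα pseudo-dihedrals — because
  single windows straddling a loop boundary pass by chance. When a
  DSSP file is supplied, its codes, accessibility, and β-bridge
  partners are used instead.
* Burial from geometry normalizes each residue's Shrake–Rupley SASA
  (probe 1.4 Å, 100 deterministic spiral points) by the same residue's
  SASA in isolation, so the reduced N/Cα/C/Cβ representation yields
  exactly 0 for an isolated residue and a well-defined fraction
  otherwise. Burial from DSSP accessibility uses the published
  theoretical maxima (Tien et al. 2013) appropriate for full-atom ACC
  values.
* Chains with consecutive Cα–Cα distances above 4.5 Å are split and
  only the first segment kept (with a warning): all downstream geometry
  assumes a continuous chain.
* IAD extends paths to continuous functions of template position
  (aligned pairs exact, gaps linearly interpolated, unaligned termini
  extrapolated at constant diagonal offset) and averages |Δq| over the
  full template length; an empty path scores the sentinel value
  `template_len`. FDS2's denominator is the set of template SSE
  positions aligned in the reference path — a "correct position" must
  exist for the ±2 test to be meaningful.

## Open design points and how they were resolved

* **Fragment extent.** Fragments span the full SSE column width
  (truncated at matrix edges, floor 3): sub-element fragments would
  explode the pool without adding reachable alignments, since the
  finishing corridor can locally shorten any fragment.
* **Pool growth order and cap.** Secondary fragments are added with
  priority adjacent > core > score; if the enumerable-combination count
  would exceed `max_total_alignments`, additions are trimmed from the
  lowest priority upward (then excess primaries), never below one
  primary per SSE.
* **Completion-time versus extension-time filters.** Monotonicity and
  loop stretch prune prefixes during the depth-first enumeration;
  coverage, strand rules, and contact order apply to completed chains
  (they are not prefix-monotone).
* **Uniqueness of emitted alignments.** Two full alignments are "the
  same" when they agree on all template-SSE residue pairs; loop-only
  variation does not create a new ensemble member.
* **Constrained-baseline δ selection.** `delta = "auto"` doubles a
  small δ until the ensemble reaches the requested size, then keeps the
  top scores — the same recipe used inside finishing.

## Problem sizes used by the tests

The shipped suite exercises folds of 2–9 elements (roughly 40–120
residues), DP oracle instances up to 6×6 (exhaustive all-paths
enumeration), 100 random pools for the enumeration oracle, and a fixed
50-pair remote-homolog benchmark at 15–30% identity for the statistical
recovery, diversity, and energy-ranking properties; the potential used
by the tests trains on 12–24 generated folds. These sizes keep the
whole suite within a few minutes while leaving every code path
exercised at full fidelity.

## Known limitations

* BLOSUM62 is the default scorer; at very low identity a
  profile–profile scorer (supported via the PSSM backend or any custom
  `score_model`) is the realistic choice, and all score-dimension
  thresholds are interpreted in the active scorer's units.
* The potential is trained on idealized geometry; it ranks placements
  at element-shift resolution reliably, at single-residue resolution
  only when sequence design and energies are self-consistent (as in the
  shipped generator).
* The sampler requires at least one SSE; it refuses unannotated or
  SSE-free templates rather than degenerate silently.
* Enumeration is exhaustive by design; the caps make worst-case cost
  predictable, at the price that extremely fragment-rich pools are
  truncated in deterministic rather than score-global order.
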