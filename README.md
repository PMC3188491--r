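# subalign

Suboptimal sequence alignment ensembles guided by template structure.

## The problem

Homology modeling needs an accurate residue-level alignment between a
query sequence and a structural template. For remote homologs (sequence
identity well below 30%), the single dynamic-programming (DP) optimum is
frequently wrong: the alignment that would produce the best model scores
worse than the DP optimum under any sequence-similarity objective.
Classical suboptimal-alignment schemes (enumerate all alignments within
δ of the optimum) stay trapped near the optimum — by the time δ is large
enough to reach the correct alignment, the ensemble is astronomically
large.

`subalign` implements a structure-driven sampler that approaches the
problem from the template's side. Instead of perturbing a DP optimum,
it:

1. splits the DP matrix into columns bounded by the template's secondary
   structure elements (SSEs) and scores every ungapped diagonal
   ("fragment") in every column;
2. keeps the top fragments per column ("primary") plus gap-filling
   "secondary" fragments (diagonal-adjacent to a flank, required by
   β-sheet topology, or simply high-scoring);
3. exhaustively enumerates N→C-ordered, mutually consistent fragment
   combinations ("fragment alignments"), pruning with modelability
   rules — a loop of `q` query residues can bridge at most `3.3·q` Å of
   template Cα–Cα distance; at least 10% of the shorter sequence must be
   aligned; paired template strands must not become unpaired and core
   strands must stay present; the pseudomodel's contact order (fraction
   of SSE residues with a Cβ within 6 Å of another element's Cβ) must be
   ≥ 65% of the template's;
4. scores each survivor with three measures — preserved hydrophobic core
   contacts, and two distance-dependent statistical energies (query
   residues on template geometry; aligned template subset) — and keeps
   candidates above the 66th percentile on all three with at least one
   above the 90th, then removes redundant candidates (same SSEs,
   fragment shifts ≤ 4, inter-alignment distance < 1);
5. finishes each surviving fragment alignment into a full alignment with
   a corridor-restricted constrained-Waterman DP (fragments ± 3
   residues; loops free; uncovered SSEs deleted), selecting the
   candidate with the lowest statistical energy;
6. emits alignments in descending fragment-alignment score until N
   unique alignments (distinct on SSE residues) are found.

The package also provides the DP baselines (optimal, δ-suboptimal
Waterman, SSE-constrained Waterman), the evaluation metrics IAD
(inter-alignment distance: area between two alignment paths divided by
template length, in residues) and FDS2 (percentage of template-SSE
residues aligned within ±2 of their reference partner), ensemble
diversity statistics, a trainable distance-dependent statistical
potential, and a deterministic generator of idealized folds and derived
remote-homolog queries with known ground truth.

## Worked example

```r
library(subalign)

# deterministic fixture: a 4-element alpha/beta fold and a remote
# homolog at ~25% identity with two loop indels
fold <- make_fold(fold_spec("HEEH", c(10, 7, 7, 10)), seed = 5)
hm   <- make_homolog(fold, identity = 0.25, indels = 2, seed = 4)

pot <- default_potential()          # trained on synthetic folds, cached
ens <- s4_align(fold$template, hm$query, N = 100, potential = pot)
ens
#> Alignment ensemble (s4): 49 member(s)
#>   top members:
#>  rank fa_score dp_score query_energy preserved
#>     1       34       34    -95.92742        11
#>     2       29       29    -70.27078         7
#>     3       29       29    -62.94783         7
#>     4       29       29    -66.73888         6
#>     5       28       28    -89.62991         8

st <- ensemble_stats(ens, hm$truth, fold$template)
round(c(best_iad = min(st$iad), best_fds2 = st$best_fds2,
        mean_unique = st$mean_unique), 2)
#>    best_iad   best_fds2 mean_unique
#>        0.05      100.00        6.35

# single-optimum DP baseline on the same pair
opt <- optimal_align(hm$query, fold$template)
fds2(opt, hm$truth, !is.na(fold$template$sse_id))
#> [1] 50
```

On this pair the single DP optimum places only half of the SSE residues
within ±2 of their correct partners (`FDS2 = 50`), while the 49-member
ensemble contains an essentially exact alignment (`best_iad = 0.05`
residues of average deviation, `best_fds2 = 100`). `mean_unique` is the
average number of distinct query residues sampled per template
position — the sampler's breadth, which is what lets it contain a
near-correct member even when the DP optimum is wrong.

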