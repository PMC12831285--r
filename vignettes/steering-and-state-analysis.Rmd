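---
title: "Steering predictions and analysing conformational states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Steering predictions and analysing conformational states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldsteer)
```

## The model of the method

An AlphaFold2-style predictor is, for the purposes of this package, a
black box consuming a single input container — query features, an
integer-encoded MSA, and a stack of aligned templates — and emitting
models with per-residue confidence.  The premise of `foldsteer` is
that the container, not the network, is the interface through which
prior knowledge enters a prediction: if the container carries only the
evidence consistent with one functional state, the prediction is
steered toward that state.  The predictor still arbitrates — templates
guide, they do not immobilize — so steering works by *tilting* the
balance of evidence: a polyalanine template supplies geometry with a
weak sequence tie, a query-labeled template a strong one, a masked MSA
window silences the covariation that would otherwise rebuild the
competing interaction, and a point variant changes local residue
propensity outright.

All editing operations preserve the container's invariants (checked by
`validate_features()`): the MSA width always equals the query length,
row 1 of the MSA is always the gapless query, template positions not
covered carry the gap index 21 with a zeroed atom mask, and every edit
appends one provenance record.

## Encoding conventions

Residues use the fixed predictor ordering A,R,N,D,C,Q,E,G,H,I,L,K,M,
F,P,S,T,W,Y,V at indices 0–19, X at 20, and a shared gap/mask index at
21.  Gap and mask deliberately share one code: masking is performed by
substitution, exactly as a gap would appear, so no separate mask
channel is needed.  Heavy atoms live in the fixed 37-slot layout.
Internally every index is 0-based (matching the predictor's arrays);
every user-facing coordinate — regions, variant positions, residue
numbers on output chains — is 1-based.

The native on-disk format is a single JSON file of named arrays plus
the provenance log; real values are serialized as `%.17g` strings
because bare JSON numbers do not round-trip doubles bit-exactly.  The
stock AlphaFold2 v2.2 field layout (one-hot `aatype`,
`deletion_matrix_int`, `template_all_atom_positions`, ...) is accepted
as an import/export dialect carried in JSON; the original Python
pickle container cannot be read from R, so converting pickle to JSON
is left to a one-line numpy script on the producing side.

## Tunable parameters that matter

| parameter | default | meaning |
|---|---|---|
| `index_gap` | 200 residues | residue-index jump between concatenated chains; anything larger than the network's relative-position window acts as a chain break without polluting the sequence |
| `min_identity` | 20 % | auto-alignment floor below which a template must be supplied with an explicit `align_map()` — remote homologs (down to ~11 % identity) are usable, but only deliberately |
| `template sum_prob` | 1.0 | confidence weight of a manually injected template; search pipelines would supply a score, manual injection has none, so full weight with user override |
| mask / merge dedup | exact integer-row equality | predictable, order-stable row deduplication on MSA merge |
| `tol` (hinges) | 1.5 Å | maximum mean difference-distance within a rigid group; at the noise levels of real ensembles (~0.2 Å coordinate noise, whose distance-space maxima reach ~1.2 Å) this cleanly separates noise from domain motion |
| `min_segment` | 5 residues | smallest rigid group; shorter segments are absorbed into the cheaper neighbor |
| mosaic `overlap` | ≥ 30 residues | smallest anchor on which two segment predictions can be superposed meaningfully |
| anchor threshold | 5 Å CA RMSD | beyond domain-level flexibility, merging mosaic segments is meaningless and is refused |
| mock backend σ | 0.2 Å | per-coordinate noise of the deterministic test backend |

## Design choices where the design was open

**Linkers.** The multimer-as-monomer route requires some linker
device; the residue-index gap (default) leaves the sequence
unpolluted, while physical linker residues (flagged in
`between_segment_flags`, dropped on disengage) are offered as an
option.  Both are recorded in provenance rather than guessing a single
intent.

**Masking the query row.** MSA masking touches non-query rows only:
row 1 must remain the query for the container to be valid, and the
query sequence channel has its own editing operation (variants).
Deletion counts in masked windows are zeroed — a gap cannot carry
insertions.

**The structural correlation dialect.** The correlation coefficient
between two ensemble members is taken as the cosine between their
deviation vectors from the iteratively superposed ensemble mean.  The
embedding then fits dot products, not distances, because the angle
between embedded vectors is the discriminating quantity: anticorrelated
systematic motions land on opposite sides of the origin, random noise
lands near it.  The optimizer (multi-start quasi-Newton with norm
clipping, best of 10 seeded starts) is validated against a gauge-fixed
brute-force grid oracle on 3-member problems; the formula itself is
the package's documented dialect and is swappable behind the
`cc_matrix()` contract.

**The hinge decomposition.** Rigid groups are found from
difference-distance matrices — |d_ab(i) − d_ab(j)| aggregated as a
maximum over member pairs — because distances are superposition-free.
Adjacent contiguous segments are merged while their mean aggregated
difference stays within `tol`; with `tol = Inf` everything collapses
to one group, the correct limit.  Groups are unions of sequence
segments (minimum 5) rather than arbitrary residue sets: hinge motion
in folded proteins separates sequence-contiguous domains.

**Ranking.** The composite order is lexicographic — declared
interfaces present, mean pLDDT, Ramachandran outliers, compactness
distance from 1, name — because the components are incommensurable
and a weighted sum would bury the interaction-presence requirement
that motivated the run.  All components are reported so users can
re-weight.

**Energies.** No interface or potential energy is ever computed
internally; an externally produced interface-energy XML can be
ingested (`pisa_xml`), null-safe.  The internal proxy for interface
significance is Shrake–Rupley buried area (probe 1.4 Å, 100
points/atom) plus geometric hydrogen bonds (N donor, O acceptor,
heavy-atom distance ≤ 3.5 Å, D–H···A angle ≥ 120° when the amide H is
inferable from the backbone).

**Ramachandran regions.** Coarse documented rectangles (alpha and
beta basins plus the left-handed helix region; glycine exempt;
proline restricted to its phi band).  This is a soundness heuristic
for ranking, not validation-grade statistics.

**Compactness.** Radius of gyration of the CA trace over an expected
globular `2.0 · N^0.4` Å power law; ≈1 compact, ≫1 extended, 0 for a
degenerate collapsed model.

## What the synthetic generators emulate — and what they do not

The fixtures are geometric stand-ins built from ideal backbone
torsions (helix −57/−47, strand −120/+120, extended −150/+150, NeRF
construction with Engh–Huber-style bond geometry, C&beta; at the ideal
tetrahedral position):

- `two_block_hinge` — two helical blocks (default 40+40) joined by a
  5-residue extended linker, the distal block rotated rigidly about
  the linker midpoint.  This emulates inter-domain hinge motion with
  exactly known block membership.
- `make_two_state_ensemble` — members split between two hinge angles
  with seeded per-coordinate Gaussian noise: a two-state conformational
  ensemble with known labels, the ground truth for the
  correlation/embedding/classification recovery suites.
- `toy_complex` — two identical helices packed at 9 Å axis
  separation: a genuine, measurable contact interface.
- `strand_pair` — an antiparallel strand pair constructed *at*
  canonical hydrogen-bond geometry: chain B is a rigid copy placed by
  least-squares fit of its four bonding atoms onto ideal targets
  (acceptor O 2.9 Å along the amide-H bisector, donor N 2.9 Å along
  the extended C=O), realizing exactly four inter-chain bonds at its
  canonical length of 5 residues.
- `make_toy_msa` — per-column resampling around the query at a given
  conservation level.

They are deterministic given their seed, down to the written bytes.
What they do **not** emulate: real side-chain packing (only CB is
placed), realistic sequence–structure covariation in the MSAs, the
statistics of real search-derived templates, or any energetics.  A
green recovery test therefore establishes that the analytics recover
*planted geometric signal at stated noise levels* — not that they
match any particular experimental system.  Similarly, the mock
backend makes runs reproducible and the pipeline testable; it does
not predict structure, so published accuracy numbers for real systems
are out of reach by construction and are not claimed.

## Numerical choices

- Iterative frame superposition converges when the mean moves < 1e-6 Å
  RMSD (or 50 iterations); the first member initializes the mean, so
  the result is deterministic.
- Kabsch superposition enforces a proper rotation (determinant +1) via
  the SVD sign correction.
- A member identical to the ensemble mean has a zero deviation vector;
  its correlations are defined as 1 with other such members and 0
  elsewhere, and the member is flagged rather than silently dropped.
- Embedding ties and cluster counts: complete linkage on angles is cut
  at the requested k; in auto mode the largest gap between successive
  merge heights decides, with a 0.3 rad floor below which everything
  is one cluster.
- Mosaic overlap conflicts resolve to the segment with the higher mean
  confidence over the overlap, earlier segment on ties.
- Every stochastic routine takes an explicit seed; identical inputs
  and seeds give bit-identical outputs, including written files (no
  timestamps in any artifact).

## Known limitations

- No homology search, no template search, no MSA generation: all
  inputs are supplied or harvested from existing feature containers.
- No automatic secondary-structure-based template extension: remote
  templates beyond sequence alignability enter through an explicit
  user-supplied `align_map()`.
- Multi-source composite templates keep each source's own frame;
  relative placement across sources is the user's responsibility
  (the intended sources are structures that already contain the
  interface being encoded).
- The real-predictor backend is an external adapter by design; absence
  degrades to the mock backend with a loud warning.
- mmCIF is read (minimal `_atom_site` loop) but output is PDB only.
- Run configurations are JSON; no YAML parser is available in the
  supported dependency set.
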