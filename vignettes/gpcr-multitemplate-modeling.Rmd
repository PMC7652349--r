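---
title: "Multi-template modeling of 7TM receptors: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-template modeling of 7TM receptors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixforge)
```

## The modeling problem

G protein-coupled receptors (GPCRs) share a seven-transmembrane-helix
(7TM) architecture, but most receptors of pharmacological interest have
no experimental structure and no close structural relative: the templates
available for comparative modeling often sit below 40% sequence identity.
At that distance, automated sequence alignments misplace helix registers
and loop residues, and a single template rarely captures every region of
the target well. helixforge implements a pipeline built around two ideas:

1. **Knowledge-based blended alignment.** Template structures are aligned
   to each other using both sequence and structure: each transmembrane
   helix is anchored at its most conserved residue (the
   Ballesteros-Weinstein x.50 position) and extended outwards, with
   insertions and deletions placed where a residue's C-alpha deviates
   from the family consensus; loops are aligned by the agreement of their
   C-alpha to C-beta vectors after global superposition. A target without
   structure is then inserted into this alignment with a fixed set of
   rules (x.50 anchoring with sequence-motif fallback, half-splitting of
   ICL3, cysteine-anchored splitting of ECL2).

2. **Multi-template recombination.** The target is threaded onto several
   low-identity templates and the partial threads are recombined by a
   Metropolis Monte Carlo search that swaps template segments and inserts
   short backbone fragments, so that each region of the final model can
   come from whichever template describes it best.

## Pipeline anatomy

| Stage | Function(s) | Purpose |
|---|---|---|
| Template MSA | `build_template_msa()` (`align_tm_segments()`, `align_loops_structural()`, `place_unalignable_residues()`) | blended structure/sequence alignment of template structures |
| Target alignment | `align_target_to_msa()` | knowledge-based insertion of a structure-less sequence |
| Template choice | `pairwise_identity()`, `rank_templates()`, `select_top_n()`, `bin_templates()` | identity ranking below the 40% ceiling; five templates by default |
| Threading | `partial_thread()` | copy template backbone through the alignment; gaps stay unmodeled |
| Hybridization | `hybridize()`, `build_fragment_library()`, `score_model()`, `select_best()` | Monte Carlo recombination into complete models |
| Evaluation | `region_rmsd()`, `fold_change()`, `experiment_harness()` | region RMSD reports and benchmark statistics |
| Synthetic data | `make_ideal_bundle()`, `evolve_family()` | ground-truth families for testing every stage |

## Alignment rules and their parameters

**TM helices.** All x.50 anchors of a helix share one column. Scanning
outwards from the anchor, each row contributes its next residue to the
next column; a residue whose C-alpha deviates more than `d_max` from the
column consensus (coordinate-wise median) is either deferred (a deletion
in that row — it is retried at the next column) or, if the row's
*following* residue matches the current consensus, emitted as a
one-row insertion column (a helix bulge). The default `d_max = 2.0` Å
separates a one-residue register shift (at least ~1.5 Å per residue along
the helix axis, in practice ~3.8 Å for the next-residue position) from
coordinate noise; it is an argument of `align_tm_segments()`.

**Loops.** After a global superposition on the anchor windows, two loop
residues may share a column only when their C-alpha atoms are within
`d_loop = 3.0` Å *and* their C-alpha to C-beta unit vectors agree within
`theta_max = 60` degrees. The first entry's loop residues define the
column spine; other rows are assigned greedily in sequence order
(monotone, nearest compatible column). Disulfide-bonded cysteines take
precedence over the vector criterion, and runs of helix or strand
detected inside loops move as blocks. Where the rules conflict the
precedence is: disulfide > secondary structure > vector criterion. That
order is this package's choice — with curated manual alignments the
judgment call is the curator's, and no single published rule exists.

**Unalignable residues** are packed against the nearer flanking column of
defined structure (ties toward the N-terminus), so that peptide-fragment
insertion later sees unmodeled stretches abutting ordered regions rather
than floating between them. The operation is idempotent.

**Target rules.** The target's TM stretches are placed outward from each
x.50 column; when a helix lacks an annotated anchor, the motif table
(`default_motifs()`: DRY for TM3, CWxP for TM6, NPxxY for TM7, with
xWxxG anchoring ECL1) supplies one — the match nearest the expected
position wins, ties toward the N-terminus, and a helix with neither
anchor nor motif is a hard error naming the helix. ICL3 is split at its
halfway point and the halves adjoined to the end of TM5 and the start of
TM6; ECL2 is split at the conserved cysteine (aligned to the template
disulfide column), and each sub-loop is halved onto its nearest fixed
feature. Odd-length splits give the extra residue to the N-terminal
half — the halfway-split rule does not specify a side, so one had to be
fixed. A target whose sequence exactly equals a template's adopts that
template's row.

**Percent identity** is computed over mutually non-gap masked columns
(the usual percent-identity convention); the mask covers the TM bundle
and loops plus `termini_pad = 10` columns on either side, excluding long
termini. The alternative denominator (masked alignment length) would
penalise coverage rather than divergence; both the mask and the pad are
arguments of `pairwise_identity()`.

## Template selection

Templates at or above 40% identity are removed before ranking — the
regime of interest is precisely the one where no close homolog exists —
and the remainder is ranked by identity with lexicographic tie-breaks.
Five templates is the default set size. Identity bins
(15–19, 20–24, 25–29, 30–39) assign on the integer-truncated percentage,
since the bin edges are integers and no rounding convention is implied
by ranges alone. An optional same-class flag restricts the pool to the
target's GPCR class; it is off by default because cross-class templates,
while inadvisable, are what an automated benchmark below 40% identity
actually encounters.

## The hybridization score

Rosetta's hybridization treats its energy function as the arbiter of
which template segments to keep. This package does not attempt parity
with a molecular-mechanics force field; `score_model()` is an explicit,
documented composite with six terms:

* `clash` — soft-sphere overlap, $\sum_{|i-j|>1} \max(0, 4.0 - d_{ij})^2$
  over C-alpha pairs (Å);
* `chainbreak` — $\sum_i (d_{i,i+1} - 3.8)^2$, the virtual C-alpha bond;
* `ss_agreement` — fraction of residues whose C-alpha-trace geometry
  class (virtual torsion + i,i+3 distance) contradicts the predicted
  secondary structure;
* `disulfide` — $\sum \max(0, d_{CB,CB} - 5.0)^2$ over restraint pairs;
* `rg` — $\max(0, R_g - R_g^{ref})^2$, a compactness guard;
* `template_consensus` — the **sum** over residues of the C-alpha
  deviation from the per-residue median of the superposed templates.

Weights default to 1, 10, 5, 10, 0.1 and 1 respectively and are
arguments. The consensus term is deliberately extensive (a sum, not a
mean): the chain-geometry terms grow with protein length, and an
intensive consensus restraint is numerically invisible next to them —
in testing, a mean-based term let the search converge to smooth
conformations several Å from the template consensus, inverting the
multi-template benefit. Summing per-residue deviations mirrors the
per-residue coordinate restraints that fragment-assembly programs apply
and restores the intended behaviour.

## The Monte Carlo search

The highest-identity thread seeds the state; unmodeled stretches are
filled by linear C-alpha interpolation plus an ideal fragment insertion,
so scoring never sees missing atoms. Each step applies one of two moves
with equal probability:

* **template-segment swap** — a contiguous region of 5–30 residues
  (uniform) copied from another thread after a local superposition on up
  to three flanking residues per side (a single flank at the termini);
* **fragment insertion** — a 3- or 9-residue window's local geometry
  replaced by a library fragment, superposed onto the current window.

Fragments are harvested from the templates at windows whose geometric
secondary structure matches the prediction, with ideal helix/strand/coil
fragments appended everywhere as a fallback, so every `(position,
length)` key is populated. Acceptance follows the Metropolis criterion
with geometric cooling from T = 2 to T = 0.25 over the trajectory
(default 5,000 steps per model, 100 models per run; the best-scoring
state visited is returned, so a model's reported score never exceeds its
starting score). Each model's RNG stream is seeded `seed + model_index`,
making runs bit-reproducible. All Monte Carlo hyper-parameters (step
count, temperatures, move mix) are this package's own choices, tuned
only for desk-scale runtime, and are exposed as arguments.

## Evaluation conventions

`region_rmsd()` reports C-alpha RMSD for the TM bundle (union of the
seven helices), ECL2 and the full model. The default convention
superposes on the evaluated region itself — the strictest self-contained
choice; `fit = "global"` instead superposes once on the TM region and
measures other regions without refitting. Both are offered because
published region-RMSD numbers rarely state the convention, and the two
can differ by Å for mobile loops; neither is labeled canonical.
Residues unresolved in either structure are excluded pairwise — imputing
coordinates for missing residues would silently bias RMSD downwards.
`fold_change()` divides a method's per-target mean RMSD by a reference
method's and averages the ratios; a method against itself is exactly 1.

## What the synthetic generator does and does not emulate

`make_ideal_bundle()` builds an idealized 7TM receptor: helices with
1.5 Å rise and 100°/residue twist on an 11 Å circle with alternating
up/down direction, smooth-arc loops with 3.8 Å C-alpha spacing (solved so
loop length matches endpoint separation, then de-clashed), short curved
termini, anchors at helix midpoints, class-A anchor motifs planted in the
sequence (GN, D, DRY, W, P, CWxP, NPxxY; xWxxG in ECL1), and one
TM3–ECL2 disulfide whose cysteine side chains are oriented toward each
other. The default scale (18-residue helices, 171 residues total) is
roughly two-thirds of a real receptor, chosen so that a full
Monte Carlo benchmark runs in minutes on one CPU; real receptor
geometry is reproduced qualitatively, not atom-for-atom.

`evolve_family()` derives members by point mutations at unprotected
sites (anchor motifs and disulfide cysteines are conserved, as they are
in real families — they are precisely what the aligner keys on), rare
single-residue indels restricted to loops (a flag-free simplification of
the observation that TM bundles are structurally conserved; helix-bulge
members can be built by hand from the bundle), per-atom Gaussian noise
with chain-connectivity repair, and optional rigid loop displacement.
Mutation rates are calibrated analytically to a requested identity
(`mutation_rate_for_identity()`); realized identities land within a few
points of the target. Deletions re-lay the loop on its original arc, so
deleted loops are marked structurally unconserved and excluded from
loop-recovery ground truth.

Two details of the noise model matter for experiments that plant an
accuracy gradient. First, half of the atomic displacement is
chain-correlated (moving-average-filtered white noise): purely
independent per-atom noise above roughly 0.8 Å is clipped away by the
connectivity repair, capping the divergence that can actually be
planted. Second, `helix_shift_frac` applies part of a member's noise
budget as independent rigid translations and small tilts of each TM
helix (loops re-evened between the displaced ends). Helix-packing
shifts are how remote homologs genuinely diverge in the TM bundle, and
they are the only perturbation that survives both the connectivity
repair (they preserve local geometry) and rigid superposition (they are
not collective).

The identity-bin experiment uses a composed divergence law,
`sigma(id) = 0.3 exp((34.5 - id)/11.6) + 5 / (1 + exp((id - 19.5)/0.8))`
with `helix_shift_frac = 0.3`: gradual noise through the range where the
hybridizer's output still responds to template quality (the response is
strongly compressive — fragment regularisation and the template
consensus pull models toward a common floor), plus a sharp rigid-shift
component below ~20% identity where, in reality as in this model,
template usefulness collapses. Bin summaries are averaged over three
independent families, mirroring a three-receptor experimental design;
with a single family, family-level sampling flukes can invert
neighbouring bins.

What it does **not** emulate: realistic amino-acid substitution
statistics (the alphabet is uniform — identity, not similarity, drives
the method under test), side-chain packing, membrane physics,
kinks/ bulges present in real helices, and the conformational
heterogeneity of crystal structures. Passing the recovery tests
therefore shows the alignment rules recover planted structural
correspondence under noise and indels — not that they reproduce a
curator's judgment on real receptors.

## Numerical choices and degenerate inputs

* Kabsch superposition uses the SVD formulation with the determinant
  sign correction (always a proper rotation); collinear point sets are
  flagged `degenerate` but still scored. The test suite cross-checks it
  against an independent quaternion implementation at 1e-8 Å.
* Glycines (and every synthetic residue) get an ideal C-beta from fixed
  tetrahedral geometry so C-alpha/C-beta vector diagnostics are defined
  uniformly; in the generator the C-beta direction comes from a stable
  tangent/curvature frame, because the chord-based construction
  degenerates on locally straight traces.
* Threading never invents coordinates: template gaps leave residues
  unmodeled, and written PDB files simply omit them.
* Ties: ranking ties break lexicographically; equal-score models by
  model index; motif matches toward the N-terminus.
* The span-file writer's default dialect is a minimal
  `count length` header plus `start end` lines, with a Rosetta-style
  layout behind `rosetta = TRUE`.

## Problem sizes used by the shipped tests

The packaged test-and-acceptance runs use a 10-member family at ~30%
identity for alignment recovery, 5 regionally-accurate templates with 3–20
models of 800–5,000 Monte Carlo steps for the hybridization properties,
and a 20-member family (5 per identity bin, noise tied monotonically to
realized identity) for the identity-bin experiment. These sizes are the
package's default desk-scale study conditions; all of them are arguments
that scale up directly.

## Known limitations

* The composite score is not a physical energy; model *ranking* within a
  run is meaningful, absolute values are not transferable between
  targets.
* Loop alignment requires a spine row (the first entry); families whose
  loops share no structure with the spine degrade to the packing rule.
* `align_target_to_msa()` handles one target at a time and does not
  propagate family-level gap patterns between multiple targets.
* ECL2 ligand-type-specific alignment subrules (aminergic/peptide/lipid
  receptor classes) are collapsed into the cysteine-split rule, the
  general case for unknown ligand type.
* No side chains beyond C-beta, no membrane-embedded scoring term; the
  span-file machinery feeds external tools rather than the internal
  score.
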