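---
title: "Methods: the four-TRUC evidence chain on synthetic truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the four-TRUC evidence chain on synthetic truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trucphylo)
```

## The question and the chain of evidence

Whether giant viruses form a fourth branch of microbes alongside archaea,
bacteria and eukaryotes is not settled by any single gene tree: individual
genes of giant viruses have visibly different histories. The argument is
instead cumulative, and `trucphylo` implements each of its links:

1. a **maximum parsimony tree of proteomes** built from the
   presence/absence of protein fold superfamilies shared by all four
   groups, with bootstrap support and a-posteriori rooting;
2. **homoplasy-versus-age diagnostics** showing that the characters
   carrying the deepest signal (the most ancient domains) fit the tree
   best, i.e. vertical signal dominates;
3. an **age-weighted ordination** in which the four groups occupy separated
   temporal clouds;
4. **phyletic clustering** of informational gene repertoires recovering the
   same four-branch structure by a phenetic route;
5. **pangenome arithmetic** quantifying how much of a giant virus's gene
   content overlaps with cellular microbes of comparable genome size;
6. **rhizome classification** showing that genes — and intragenic
   fragments — have heterogeneous best-match donors, so the proper
   representation of these genomes is a rhizome rather than a single tree.

The full-scale published analyses depend on external downloads (hundreds
of proteomes, the NCBI nr database). The package therefore treats the
*machinery* as the deliverable and validates it on synthetic data with
known ground truth: every stage must recover what was planted.

## The synthetic study conditions

`sim_config()` fixes the conditions used throughout the tests and the
acceptance script, chosen once to emulate fold-superfamily-style data:

* **8 taxa per group, 200 binary characters.** Large enough that the
  four-clade signal can be supported by dozens of independent characters,
  small enough that a full run (search, 100 bootstrap replicates,
  ordination, clustering) completes in about two minutes on one CPU.
* **Balanced truth tree** per group joined by an ((A,B),(E,V)) backbone.
  A guaranteed four-clade truth is the point: the recovery checks are
  meaningful only if the signal is actually in the data.
* **Character model.** Each character originates as a gain at one internal
  node (uniformly drawn; optionally the root) and is inherited downward;
  per-branch flip noise converts absences with `gain_rate` (convergent
  gain) and presences with `loss_rate`. The defaults
  `gain_rate = loss_rate = 0.01` reflect how strongly conserved structural
  domains are — homoplasy exists but is moderate, so retention indices
  stay high for old characters, which is also the regime the diagnostics
  of stage 2 are designed to reveal. Both rates may be raised to 0.05
  before recovery degrades materially.
* **Ages.** A character's age `nd` is its gain node's depth scaled to
  [0, 1] (root = 0 = most ancient), jittered with Gaussian noise of sd
  `age_noise = 0.05` and clipped. With zero noise, ages are exactly
  monotone in gain depth — a tested invariant.
* **Genomes.** Planted families draw one ancestral random protein and emit
  independently diverged copies (per-site substitution probability
  `divergence`, substitutions always changing the residue). Members
  diverge independently, so within-family pairwise identity is
  approximately `(1-p)^2 + p^2/19`; the default `p = 0.2` gives ~64%
  pairwise identity, comfortably above the 20% threshold, while `p = 0.37`
  probes the neighbourhood of 40%.
* **Hit tables.** Donor classes are sampled from `donor_props` (default:
  the Tupanvirus-like mix 51 / 11 / 8 / 0.2% for virus / eukaryote /
  bacterium / archaeon, remainder ORFan); the top-scoring hit of each
  non-ORFan gene carries the planted donor's taxonomy. ORFans are, by
  default, genes with *no* emitted hits; `orfan_mode = "below_threshold"`
  instead emits hits that fail the thresholds, exercising the filtering
  path. `decoy_self_hits` plants a same-family top hit above the true
  donor to exercise self-relative exclusion.

What the generator does **not** emulate: realistic protein evolution
(no substitution-matrix-informed mutation, no indels within families),
rate variation across lineages, correlated character loss in reduced
genomes, HMM-level noise in domain detection, or database bias in hit
tables. Passing tests therefore demonstrate that the machinery is correct
and that the planted signal is recoverable — not that real proteome data
will behave this cleanly.

## Parsimony machinery

**Fitch engine.** Binary characters are encoded as state-set bitmasks and
all characters are counted in one vectorised post-order pass per tree;
identical columns are collapsed to weighted patterns first. The pass is
rooted at an arbitrary tip, which leaves the count invariant. Correctness
is anchored two independent ways: a unit-cost Sankoff dynamic program
(`sankoff_steps()`, written directly on the `phylo` edge table) and
exhaustive enumeration of all unrooted topologies for up to 8 taxa
(`exhaustive_mp()`); the test suite also cross-checks against
`phangorn::fitch()`.

**Search.** The published analysis used PAUP* with parsimony as the
optimality criterion but does not state the heuristic settings. The
package uses stepwise random addition (ties broken by first-encountered
edge) followed by first-improvement hill-climbing over NNI or SPR
neighbourhoods, with restarts; SPR is the default for final searches, NNI
for bootstrap replicates where speed matters. All distinct topologies
found at the best length are retained (canonical-form deduplication, a
documented deterministic tie-break), and supports are attached to the
reference best tree rather than a consensus — whether the original supports
were drawn on a consensus is unstated, and the single-best-tree choice is
the more conservative one to test against.

**Rooting.** `lundberg_root()` attaches a hypothetical ancestor to every
branch in turn and keeps the placement minimising total length. The
ancestor defaults to all-absent, treating domain absence as ancestral;
this reproduces a generality-criterion style polarity, reconciling the
two rooting descriptions that accompany the original tree. Ties are
broken by branch enumeration order and flagged.

**Fit indices.** For a binary character with `a` presences and `b`
absences, `m = 1` if both states occur (else 0) and `g = min(a, b)`; `s`
is the Fitch count on the evaluated tree. CI, RI, RC and HI follow their
standard definitions; RI is undefined (`NA`) when `g = m`. The "G-fit"
plotted in the original diagnostics is not defined in the text, so the
package implements Goloboff's concave fit `G = k/(k + s - m)` with the
concavity `k` exposed (default 2, a common choice) and documents the
formula rather than guessing PAUP*'s.

## Ordination, clustering, pangenome, rhizome

**evo-PCoA.** Feature vectors are weighted `1 - nd` when present. Absent
features contribute 0 rather than missing values — Euclidean distance
needs complete vectors, and 0 is the natural "no contribution" weight;
with all ages 0 the method provably reduces to PCoA of raw
presence/absence distances (tested limit). Classical PCoA is computed by
double-centring and eigendecomposition via `stats::cmdscale()`; the full
positive spectrum must reproduce Euclidean input distances to near
machine precision, and negative eigenvalues beyond numerical tolerance
are rejected unless the Cailliez correction is explicitly requested for
ingested non-Euclidean matrices. Axis signs are fixed by making each
axis's largest-magnitude coordinate positive, so plots are reproducible.
Group separation is the mean silhouette width per group
(`cluster::silhouette`), in [-1, 1].

**Phyletic clustering.** "Pearson distance" is read literally:
`1 - cor()` on the 0/1 profiles (the correlation centres them), giving
distances in [0, 2]; constant profiles are an error naming the offending
taxon. The clustering software used originally does not document its
linkage; average linkage (UPGMA) is the default, with complete and single
available. The published COG counts disagree between sections (726 versus
727 informational COGs); the package takes no side — it clusters whatever
matrix it is given — and the discrepancy is recorded here rather than
"fixed". Whether the original clustered raw 0/1 or score-derived values
is likewise unstated; presence/absence is what the methods describe and
what is implemented.

**Pangenome.** Hits must pass e-value ≤ 1e-3, identity ≥ 20% and coverage
≥ 30% (the ProteinOrtho-style thresholds), with coverage required on both
sides and a family edge requiring hits in *both* directions — the
reciprocity rule is not restated in the original, and the symmetric
choice is the stricter one. Families are connected components
(`igraph`) rather than spectral partitions: exact and transparent at desk
scale. E-values use Karlin–Altschul statistics with standard gapped
BLOSUM62 parameters (lambda = 0.267, K = 0.041); ingested tabular hits keep
their own e-values. Percentages are reported to one decimal, rounding
half away from zero, matching how the published percentage tables read.
One published figure — 68 genes given as "5.4%" of the archaeon's 2,533 —
is arithmetically inconsistent (it computes to 2.7%) and is deliberately
not reproduced as a target; the reporting operation recomputes
percentages from counts instead.

**Rhizome.** Donor classes come from the first element of a
semicolon-separated taxonomy path (superkingdom, or the Viruses root),
with family and genus read from the last two elements. Hits matching the
query at the exclusion rank are removed before taking the best hit;
`family` is the default rank because the original excluded "relatives
from the same family or genus" without choosing — family is the broader,
more conservative exclusion, and both are supported. Score ties are
broken by higher identity then lexicographic subject id, and flagged;
hits with missing taxonomy are skipped with a warning. The 40-aa/20-aa
sliding windows start at multiples of the step; the final window is
truncated at the sequence end and kept only if at least `min_len = 20`
residues remain — end handling is unstated in the original, and this rule
guarantees (window ≥ step + min_len) that every residue of any sequence
of at least `min_len` residues is covered, a property tested for all
lengths 20–500.

## Numerical and degenerate-input conventions

* Fixed seeds make every generator, the search, and the bootstrap
  byte-reproducible; the acceptance script threads a single `--seed`
  through all of them.
* Degenerate inputs fail loudly and early: empty assignment files, absent
  group labels, constant profiles under Pearson distance, asymmetric or
  negative "distance" matrices, ancestors of the wrong length, hits
  referencing unknown genes, fewer than four taxa for tree search.
* An all-constant matrix makes every Lundberg placement tie; the first
  branch in enumeration order is chosen and the tie is flagged rather
  than hidden.
* Sharing-pattern counts partition the feature set by construction;
  features occurring in no taxon cannot be assigned a non-empty pattern
  and are dropped with a warning.

## Problem sizes

The test suite and acceptance script run at desk scale by design: 32
taxa × 200 characters for recovery checks (about two minutes including a
100-replicate bootstrap), 1,000 random Fitch/Sankoff instances at up to 8
taxa, exhaustive search comparisons at 6–7 taxa (105 and 945 topologies),
four genomes of roughly a dozen genes for alignment-based family
recovery, and 1,269 genes — Tupanvirus's gene count — for donor-proportion
recovery. These sizes were chosen so the whole chain, not a cut-down
version of it, runs in a few minutes; nothing in the machinery is
specific to them.

## Known limitations

* The heuristic search is not guaranteed to find the global optimum on
  hard matrices; its guarantees are empirical (exhaustive agreement on
  small instances, truth recovery under the study conditions).
* Internal alignment statistics are asymptotic Karlin–Altschul values
  without BLAST's finite-length edge corrections; at 100-residue scale an
  occasional random pair can slip under e = 1e-3, which is what an
  e-value means, but worth remembering when interpreting single hits.
* Binary characters only; multistate characters, branch lengths beyond
  step counts, and likelihood/distance tree methods are out of scope.
* The rhizome stage classifies and aggregates; it does not render
  circular figures (the Circos tableviewer matrix is emitted for that).
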