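---
title: "Methods: character mapping, ITS2 barcoding and divergence estimation in Caenorhabditis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: character mapping, ITS2 barcoding and divergence estimation in Caenorhabditis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caenophylo)
```

# Scope

`caenophylo` implements three connected analyses on a fixed phylogeny of the
26 cultured *Caenorhabditis* species:

1. **Character evolution** — parsimony mapping of discrete phenotypic
   characters (reproductive mode, spicule and male-tail morphology, RNAi
   competence) on the species tree, including ACCTRAN resolution,
   root-state constraints and constrained single-origin counting.
2. **ITS2 barcoding** — classification of pairwise sequence differences into
   transitions, transversions and indel events; simple indel coding; MP
   branch lengths on a species-constrained strain tree; and the barcode-gap
   report that asks whether intra-specific variation stays below
   inter-specific divergence.
3. **Genetic divergence** — GTR+Γ+I log-likelihood by Felsenstein pruning
   and maximum-likelihood branch lengths on the fixed topology, yielding
   patristic divergences in expected substitutions per site.

Tree search, bootstrap/jackknife resampling, multiple sequence alignment
construction and Bayesian sampling are out of scope: aligned input is
consumed, never produced, and the topology is always given.

# The fixture phylogeny and character matrix

The packaged topology (`load_fixture_tree()`) is a transcription of the
genus-wide maximum-likelihood tree: *C.* sp. 1 branches first, *C. plicata*
second, and the remaining species form the *Elegans* super-group (the
*Elegans* group, the *Japonica* group, and *C.* sp. 15 as the latter's
sister) and the *Drosophilae* super-group (the *Drosophilae* group, the
*Angaria* group, the pair *C.* sp. 6 + *C.* sp. 13, and *C.* sp. 20 as the
first branch). Where the published description under-determines an internal
arrangement (inside the briggsae and brenneri subclades and within the
*Japonica* group), the packaged arrangement is the one consistent with
*every* published character-mapping step count simultaneously; the test
suite recomputes all of those counts, so any transcription error in the
topology would surface as a failing count, not as a silent discrepancy. The
`"caenorhabditis26+outgroup"` variant attaches a *Protorhabditis* tip whose
character states (short spicules, open oval fan, middle dorsal ray in
position 5, no hook) root the character reconstructions.

The character matrix (`load_fixture_characters()`) re-encodes the published
descriptions as 15 discrete characters, with `"?"` wherever the source does
not state a species' condition (notably RNAi competence for *C.* sp. 1 and
the outgroup). States are unordered and changes cost one step by default;
weighted analyses (e.g. transversions costing twice transitions) go through
`dna_cost_matrix()` and `sankoff()`.

# Parsimony engines

`fitch_length()` uses Fitch set operations on binary nodes and falls back to
Sankoff dynamic programming on polytomies (the two agree on binary trees;
the fixture is fully binary). Missing states carry the full alphabet, the
standard convention. `sankoff()` accepts an arbitrary non-negative cost
matrix with zero diagonal.

**ACCTRAN.** Most-parsimonious reconstructions are generally ambiguous. The
package resolves them with accelerated transformation implemented as a
deterministic preorder backtrace of the Sankoff cost vectors: at the root
the cost-minimal state is chosen (alphabet order on ties); descending, each
node takes a state minimising `cost(parent, s) + subtree_cost(s)`, and
among cost-minimal states one *different* from the parent is preferred —
i.e. a change is pulled onto the current (more rootward) branch whenever
an optimal completion allows it. Because nodes are visited in preorder,
equally early placements resolve to the smallest preorder node id. The
property test enumerates all MP labelings on random trees and checks both
that the chosen reconstruction is cost-minimal and that no MP labeling
agreeing with it above a node places a change the backtrace declined.

**Root constraints.** "The stem species already had this state" is modelled
as a virtual stem branch above the root carrying the fixed state; a change
on the stem is recorded against the root node. This keeps the constrained
count meaningful even when the constraint forces one extra change (a
uniform character constrained to the other state costs exactly one step).

**Single-origin counting.** For a binary character,
`constrained_single_origin_steps()` places the gain on each branch of the
root path of the derived tips' MRCA in turn (including the virtual stem),
forbids further gains below it (infinite cost), counts minimal reversals by
asymmetric-cost Sankoff, and returns the overall minimum. This reproduces
the published "one gain plus five reversals" alternative scenario for
hermaphroditism (six steps against three for independent origins).

# ITS2 barcode analysis

**Pairwise differences.** Columns where both sequences are gapped are
removed first (they are artifacts of the multiple alignment, not of the
pair). Remaining one-sided gap columns are grouped into maximal runs per
gapped sequence; each run is **one** indel event regardless of length,
matching the "one change per gap" convention. Adjacent runs gapped in
opposite sequences are two events (one insertion in each lineage).
Base–base columns count as transition (A↔G, C↔T) or transversion;
columns involving IUPAC ambiguity codes are never guessed — they are
tallied separately. The barcode-gap verdict uses substitutions + indel
events, with the components reported so users can apply substitution-only
thresholds.

**Indel coding.** `indel_characters()` creates one binary presence/absence
character per distinct maximal gap run (start, end); a sequence scores
present only if gapped across exactly that run. Coordinates are 1-based
inclusive alignment columns.

**Strain tree.** `strain_tree_branch_lengths()` replaces each species tip
with the MP-optimal resolved subtree of its strains — an exhaustive search
over all rooted resolutions for up to 7 strains per species (there are at
most 10,395), greedy stepwise addition beyond — scoring only characters
variable within the species (characters constant within a species
contribute identically to every resolution under unit costs). Ties break
by enumeration order with strains added lexicographically, a documented
deterministic rule in place of an arbitrary choice among co-optimal trees.
Branch lengths are ACCTRAN change counts summed over all substitution
columns and indel characters, so the total tree length equals the sum of
per-character parsimony lengths.

**Trimming.** `trim_to_marker()` locates two conserved anchor motifs (the
3' end of the 5.8S gene and the 5' start of the LSU gene, for ITS2) in a
reference row, skipping that row's gaps and tolerating a configurable
number of mismatches (default 2), and returns the columns strictly between
the matches.

# GTR+Γ+I divergence

The rate matrix is built from exchangeabilities `f` and stationary
frequencies π as `q_ij = f_ij π_j`, normalised to mean rate 1 at
stationarity, so branch lengths are expected substitutions per (variable)
site. Gamma rate variation uses equal-probability categories at their
conditional mean rates (the common discretisation; 4 categories by
default, 25 when reproducing the published setting, shape α as printed,
0.44081). The site likelihood is
`p_inv · I(site) + (1 − p_inv) · mean over categories`, where `I` is the
stationary probability of the site being invariant and is non-zero only
when all observed bases agree; gaps and ambiguity codes are missing data
(partial likelihood 1 for compatible bases). Pruning uses per-node
rescaling, and log-space mixing of the invariant and variable components,
so 50 kb alignments on 26 taxa are handled without underflow.

**Branch-length optimization.** Under a reversible model the likelihood
does not depend on root placement, and only the sum of the two
root-adjacent branch lengths is identifiable; trees with three or more
tips are therefore collapsed to unrooted-equivalent form before fitting
(patristic distances are unchanged). Each branch is then optimised by
bounded golden-section/parabolic search on [1e-8, 10] with all conditional
likelihoods cached: subtree partials are updated only along the path to
the root after each branch moves, and the per-branch objective reuses the
cached "rest of tree" context, so one sweep costs a small multiple of one
full pruning pass. Sweeps repeat until the log-likelihood improves by less
than `tol` (absolute, default 1e-6); exceeding `max_sweeps` raises an
error carrying the best tree found. With `estimate_params = TRUE` an outer
Nelder–Mead loop refits exchangeabilities, α and p_inv on log/logit scale
with π fixed at empirical frequencies — full ML estimation of π is
deliberately out of scope, matching common practice.

# Synthetic data

Simulators provide ground truth the real study cannot:

- `simulate_character()` evolves a symmetric-rates Markov character with an
  explicit event log, so parsimony can be checked as a lower bound on the
  true number of changes.
- `simulate_alignment()` runs GTR+Γ+I by explicit per-site jump chains
  (event counts per branch are exact, not approximated) plus an indel
  process: events uniform on branches, insertion:deletion 1:1, geometric
  lengths (mean 3 by default), insertions creating fresh columns so the
  returned object is the true multiple alignment. Substitutions are applied
  along a branch before its indels; at the rates used here the interaction
  is negligible.
- `simulate_strain_dataset()` grafts Yule-shaped strain subtrees with
  exponential branch lengths scaled by `intra_scale` onto the species tips
  — shape-agnostic by design, since only the intra/inter scale contrast
  matters for the barcode gap.

All simulators consume one integer seed (R's Mersenne-Twister; the
algorithm name is recorded in every `simulation_record`) and are
bit-reproducible for equal seeds.

For recovery experiments the fixture topology needs branch lengths; none
are published in machine-readable form, so `fixture_branch_lengths()`
draws them with the described phylogram structure — terminal branches
(uniform 0.05–0.30) longer than internal ones (uniform 0.02–0.12), spans
comparable to the printed species divergences (0.057–0.566).

# Problem sizes, tolerances and what the tests show

The test suite validates each engine against an independent oracle rather
than against itself: exhaustive parsimony over all ancestral labelings
(≥200 random ≤8-tip instances), full enumeration of the GTR+Γ+I
likelihood over internal assignments and categories (≤5 tips, 1e-8), the
Jukes–Cantor closed forms for both the likelihood (1e-10) and the two-tip
distance MLE (1e-6), and cross-checks against an independent phylogenetics
library where available. Pipeline closure runs 20 seeded strain panels in
two decisive regimes — tight strains under well-separated species, and one
deeply split species over near-zero species branches — chosen to stay far
from distance saturation, where observed differences track true event
counts; the report's violation list is compared with the list recomputed
from the simulator's true per-branch event log.

Branch-length recovery is assessed on the 26-taxon fixture with a 50 kb
simulated alignment under the published model parameters (α = 0.44081).
One statistical limitation deserves emphasis: with rate heterogeneity this
strong, the maximum-likelihood estimate of the shortest deep internal
branches (~0.02 substitutions/site) has a standard error of roughly 8% of
the branch length at 50 kb — the conditional curvature of the
log-likelihood gives ±0.0019 on a branch of 0.022 — so the *largest*
relative error across all ~49 branches typically lands between 10% and
25% even though the median error is about 2% and the optimizer verifiably
reaches the optimum (restarting from the truth returns the same fit, with
higher likelihood than the truth itself). A uniform 10% per-branch claim
at this problem size is therefore beyond the information the data
contain; the package reports both the median and the maximum so users can
judge the two regimes separately.

# Known limitations

- The synthetic ITS2-like data do not emulate the tandem-repeat expansions
  seen in real spacer regions (the study's most divergent strain pair
  differs by a 199-column repeat-length difference), intra-individual
  polymorphism, or alignment error; passing the pipeline tests shows the
  counting and reporting machinery is correct, not that real spacer
  alignments are unambiguous.
- Parsimony branch lengths underestimate superimposed changes on deep
  branches; ACCTRAN partially offsets this, which is exactly why it is the
  default resolution here.
- No heterotachy, codon or amino-acid models; no likelihood-based
  ancestral state reconstruction; DELTRAN resolution is a possible
  extension but is not implemented.
- The phenotypic matrix is a re-encoding of prose and figures; characters
  the source describes only qualitatively (e.g. fan shape of the one
  squarish-fanned species) are coded conservatively as their own state or
  as missing.
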