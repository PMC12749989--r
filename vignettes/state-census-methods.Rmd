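---
title: "Counting conformational states in RND efflux-pump trimers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting conformational states in RND efflux-pump trimers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rndcensus)
```

## The problem

Resistance–nodulation–division (RND) multidrug efflux pumps such as
*E. coli* AcrB and *K. pneumoniae* OqxB are homotrimers whose three
protomers cycle through the loose (L), tight (T) and open (O)
conformations during functional rotation. Single-particle cryo-EM can
resolve, for each particle, which conformation each protomer adopts; the
scientific quantity of interest is then a *census*: the distribution of
monomer states (how many L, T, O) and of trimer compositions (how many
LTO, TTO, TTT, ... particles). Shifts of this distribution — e.g. loss of
the L state after a deep-binding-pocket substitution, or a homogeneous
closed-exit O\*O\*O\* population — carry the mechanistic signal.

`rndcensus` implements the coordinate-space part of that analysis as a
tested pipeline: pseudo-C3 symmetry expansion of trimer coordinates into
aligned monomers, monomer state classification against reference
protomers, census reconstruction with uncertainty, a simplified
exit-channel bottleneck estimator that distinguishes O from the
closed-exit O\*, and the accompanying phenotype arithmetic
(plate-dilution and MIC scoring). A synthetic-data generator stands in
for the raw particle stacks, which are far beyond desk scale
(the experimental datasets have on the order of 10^5 particles per
sample).

## Symmetry expansion

A trimer's pseudo-C3 axis is estimated from coordinates alone: the axis
direction is the rotation axis of the least-squares proper rotation
(Kabsch) mapping chain 1 onto chain 2, and the axis point is the mean of
the three chain centroids over their shared atoms. The axis sign follows
the right-hand rule for the chain-1-to-chain-2 rotation, which makes the
chains appear counter-clockwise viewed down the +axis; any fixed
convention would do, this one is documented and stable. We derive the
axis from the chain-pair rotation rather than from an inertia tensor
because hetero-conformer trimers (e.g. LTO) have no useful inertial
symmetry. If the chain-to-chain rotation deviates from 120° by more than
a tolerance (default 15°) the result carries a pseudo-symmetry-violation
warning rather than an error — real particles are only approximately
symmetric.

Expansion then rotates chain *k* by −*k*·120° about the axis, so all
three monomers land on the same position, mirroring the symmetry
expansion used on particle images. For an exactly symmetric trimer the
three expanded copies coincide; for i.i.d. Gaussian coordinate noise of
σ per coordinate the expected pairwise RMSD between expanded copies is
σ·√6, a closed form the test suite checks by simulation.

## State assignment

Each monomer is superposed onto each reference protomer over the *core*
anchor (the transmembrane domain) and classified by the porter-domain
Cα RMSD — not whole-chain RMSD, because the states differ by rigid-body
motions of the porter subdomains (PN1, PN2, PC1, PC2) and whole-chain
RMSD dilutes exactly that signal. Both statistics are available via
`run_config(statistic =)`. The winner is the minimum-RMSD state; exact
ties (at numerical tolerance) go to the fixed precedence L < T < O < O\*
and a tie flag is raised when the margin falls below 0.05 Å. Monomers
sharing less than half of the library correspondence atoms are returned
`UNASSIGNED` with a reason, never guessed.

The O\* state — O-architecture with a closed exit channel — is handled
as an *override of O only*: L or T winners are never O\*-checked, because
O\* is by definition an O-like conformation. When enabled, an O winner's
exit channel is searched from the scheme's seed residues and the monomer
is relabelled O\* if the bottleneck radius falls below the threshold
(default 1.5 Å, motivated by the 1.1–1.5 Å bottleneck range that
characterises closed exit channels). Because published O assignments for
partially-open pockets could fall on either side of any fixed threshold,
assignments report both the label and the bottleneck so users can
re-threshold.

Supporting features mirror the structural criteria used to identify
states: per-subdomain rigid-body displacements (translation magnitude and
rotation angle after core superposition, with the rotation angle taken
from the trace formula with its argument clamped to [−1, 1]), and the
proton-network side-chain orientation (lysine NZ closer to the
asparagine side chain than to any aspartate carboxylate oxygen counts as
flipped, with a strict inequality so the symmetric case is not flipped).
Truncated side chains yield a missing-feature record, not an error.

Subdomain residue ranges for AcrB and OqxB numbering ship as editable
TSV files under `extdata/schemes/`; they are curation, not ground truth,
since subdomain boundaries are nowhere printed to the residue.

## Census statistics

A trimer composition is an unordered multiset of three state labels; the
canonical name sorts labels by the precedence order (so "OTT" and "TTO"
are one key, rendered "TTO"), and aliases are accepted on input because
both spellings occur in the literature. Particles with exactly three
assigned monomers enter the census; particles with unassigned monomers
are dropped *and reported* rather than imputed — partial counting would
require assumptions about why the third monomer failed classification,
and dropping is conservative and visible. Monomer frequencies are
computed from the composition counts (`f_s = Σ_c p_c · n_s(c) / 3`), so
the monomer and trimer panels are consistent by construction — this
identity is the package's structural invariant, not a numerical
coincidence.

Uncertainty comes from a particle-level nonparametric bootstrap:
resampling whole particles keeps the three labels of a particle
together, preserving intra-trimer correlation, which a monomer-level
bootstrap would destroy. Percentile 95% intervals are reported for every
frequency. A G-test asks whether compositions are consistent with the
three monomer states being independent draws from the observed monomer
frequencies: expected composition probabilities are multinomial,
categories with expected count below 1 are pooled, and the degrees of
freedom are the (pooled) number of composition categories with nonzero
expectation minus the number of states with nonzero frequency (the
category count reflects pooling; with no pooling this is C − S, e.g.
10 − 3 = 7 for three states). Printed percentages round to one decimal
to match reporting conventions; JSON output keeps full precision.

## Channel bottlenecks

The channel module is a deliberate simplification of Voronoi-based
channel finders (MOLE, CAVER): a regular clearance grid (clearance =
distance to the nearest atom surface under a Bondi radius table, unknown
elements falling back to 1.7 Å with a warning) and a maximin
(widest-path) search over the 26-connected grid graph from an interior
seed to the solvent exterior. The bottleneck radius — the quantity the
O\*/O distinction needs — has identical semantics under both
formulations, but the maximin objective is verifiable against an
independent brute-force oracle, which the test suite does on small
grids. Quantitative agreement with published MOLE radii on deposited
models is a validation experiment, not a promise; the defaults (0.8 Å
spacing, 6 Å padding, 3.0 Å exterior probe) resolve bottlenecks on the
1.1–1.5 Å scale at tolerable cost and are all configurable. Grid
estimates carry an inherent ±(one spacing) uncertainty because the seed
and channel axis need not pass through grid nodes; the refinement
property (halving the spacing moves fixture estimates by less than the
coarser spacing) bounds this in the tests.

Determinism: among equal-bottleneck paths the search returns a shortest
one, with remaining ties broken by node index order, so results are
bit-reproducible.

## The synthetic generator

Templates are abstract labelled point clouds, not real protein geometry:
tests must not depend on downloads, and real structures plug into the
same interfaces. The default monomer has a 30-atom helical core (the
superposition anchor), four 12-atom porter subdomain clusters, and — when
an exit pore is requested — a capped tube of wall atoms with a known
clear radius (2.5 Å open, constricted to 1.2 Å for O\*). States differ by
rigid subdomain shifts of 4–5 Å, chosen once so that pairwise porter
RMSDs (2.8–4.3 Å) exceed the 2 Å floor the classifier assumes; a
separability warning fires when requested noise approaches the
inter-state distance (minimum separation below four times the expected
noise RMSD σ√6). The engineered pore and the cone fixture are *blind*
(sealed at one end): with a through-hole, a widest-path search would
escape through the wide mouth and the engineered narrow radius would
never be the bottleneck.

Particle simulation draws a composition per particle, assigns its states
to copy indices uniformly at random (matching the census's permutation
invariance), places the templates at 0°/120°/240° about a common axis,
applies a random global rigid transform, and adds i.i.d. Gaussian
coordinate noise. All generators are pure functions of (spec, seed).

What the generator does *not* emulate: image formation, CTF, density
maps, or the 3D classification step itself — the label-confusion matrix
is the entire abstraction of classification error. Passing tests
therefore demonstrate that the geometry, classification and counting
machinery is correct, and that parameters are recovered under the stated
noise models; they do not certify performance on real maps with
flexibility, preferred orientation or misalignment.

## Problem sizes and numerical choices

Recovery simulations use 10,000 particles (running in seconds to a
minute), the scale at which three multinomial standard errors are about
1.5 percentage points for the published mid-range frequencies; bootstrap
coverage checks use 500 replicates of 150–200 particles with 150–200
bootstrap resamples. Tolerances: orthogonality and unit-norm checks at
1e-9; classification tie tolerance 1e-9 Å with the tie *flag* at
0.05 Å; the census consistency identity is exact to 1e-12. Alternate
locations resolve to the highest-occupancy conformer (ties by altloc
identifier) so downstream RMSD arithmetic sees a single-conformer model;
residues keep author numbering throughout because structural literature
cites residues by author numbers (V612, K946); hydrogens are ignored in
all geometry since deposited models are heavy-atom.

Degenerate inputs have defined behaviour: empty structures, label
vocabularies outside {L, T, O, O\*, UNASSIGNED}, duplicate
(particle, copy) keys, non-increasing concentration series and
mismatched time grids all error with typed conditions; sealed cavities
report `reached_exterior = FALSE` with the best achievable clearance;
a composition table that does not sum to 1 is refused rather than
silently renormalised.

## Phenotype arithmetic

Plate-dilution scores are replicate means of the last visible 10-fold
dilution step, normalised as variant − wildtype (wildtype exactly 0).
MIC calling uses the OD threshold 0.18 (configurable): the MIC is the
lowest concentration with no growth there *and at every higher
concentration* — the conservative reading for non-monotone series, where
"lowest concentration with no growth" would be ambiguous under growth
rebounds. Out-of-range MICs propagate through wildtype normalisation as
inequalities (">= ratio"), never as numbers, matching microbiology
convention. Replicate-averaged scores keep full precision (no rounding
of step differences). Time courses are summarised pointwise as mean and
sample standard deviation (n − 1).

## Known limitations

* The classifier operates on coordinates; it substitutes a
  coordinate-space decision rule for map-space class curation, and
  cannot model density-level ambiguity.
* The channel estimator's absolute radii differ from Voronoi-based tools
  by up to a grid spacing; only relative open/closed decisions near the
  threshold should be trusted at default settings, and the threshold is
  exposed.
* The state-to-chain mapping of deposited asymmetric models is not
  standardised; chain mappings must be supplied by the user.
* Bootstrap intervals are percentile intervals; for frequencies at 0 or
  1 they degenerate to points.

## Reproducing the numbers

`scripts/acceptance.R` recomputes the headline quantities from scratch:
the implied T-monomer percentage from the published V612F composition
distribution, and zero-noise pipeline recoveries of the V612F TTO and
V612W TTT frequencies at n = 10,000. See the README for invocation.
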