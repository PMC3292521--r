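---
title: "The twobead model: scoring, specificity, and simulated evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The twobead model: scoring, specificity, and simulated evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twobead)
```

## The coarse-grained representation

Each residue is reduced to two beads: a backbone bead centered on the
C&alpha; atom (radius 1.8 &Aring;) and a side-chain bead (C&beta;) whose
center is the geometric centroid of the side-chain heavy atoms together
with the C&alpha; atom, carrying a residue-dependent radius. Glycine
keeps only its C&alpha; bead. Two internal coordinates summarize local
backbone geometry: the bend angle &theta;~i~ between
C&alpha;~i-1~&ndash;C&alpha;~i~&ndash;C&beta;~i~ (defined from the
second residue on, for residues with a side-chain bead), and the
torsion &phi;~i~ over C&alpha;~i-1..i+2~ (defined for
2 &le; i &le; N&minus;2).

The per-residue parameter tables ship as plain-text files under
`inst/extdata/params/` and are assembled by `residue_params()`:

* **Bead geometry** (`b`, `r`, `theta0`): derived once from idealized
  side-chain templates; the bead radius is the radius of gyration of
  the side-chain atoms about the centroid with proportionality
  constant 1.0. The same templates drive `make_all_atom_fixture()`, so
  coarse-graining a rendered fixture recovers the bead geometry
  exactly.
* **Hydropathy** `h`: the Kyte&ndash;Doolittle scale shifted so its
  minimum is zero. `h` doubles as the like-pair Lennard-Jones well
  depth, and the polarity index is the reflection
  `p = (h_max - h_min) - h`. Unlike pairs use the geometric mean of
  the like-pair depths; C&alpha; beads carry a single backbone depth
  (default 1.0).
* **Helix/beta propensities**: the helix scale is a free-energy cost
  inverted into a positive force constant (strong helix formers are
  pulled hardest toward ideal helix geometry); the beta scale is
  affinely rescaled onto the numeric range of the inverted helix scale
  so the two propensity terms act on comparable magnitudes.
* **Charges**: Asp/Glu &minus;1, Lys/Arg +1, histidine neutral (a
  deliberate choice: at typical pH its average protonation is
  fractional, and the ionic term is too coarse to resolve it).

All tables are overridable by path, and every numeric constant of the
scoring function is exposed in `physics_constants()`.

## The physics-based scoring function

`score_fold_physics()` evaluates seven raw terms and a weighted total
(lower is better):

* **bend**: harmonic in (&theta; &minus; &theta;~0t~) with
  K~&theta;~ = 10 kJ mol^-1^ rad^-2^, written as two half-sums so that
  interior angles contribute twice &mdash; the printed double-sum form is
  implemented literally.
* **lj**: 4&Sigma;&epsilon;~ij~[(&sigma;~ij~/r~ij~)^12^ &minus;
  (&sigma;~ij~/r~ij~)^6^] over all C&alpha;/C&beta; bead pairs with
  &sigma;~ij~ the sum of radii. Same-residue pairs and bonded
  C&alpha;&ndash;C&alpha; neighbors are excluded so the term carries no
  constant bonded-geometry offset.
* **helix**: harmonic restraints of the i,i+2 and i,i+3 C&alpha;
  distances to r~h~ = 5.5 &Aring;, force constants averaged over the
  spanned 3 or 4 residues.
* **beta**: harmonic restraint of the backbone torsion to 210&deg;
  with scaling constant 0.01 and 4-residue averaged propensities.
  Torsion arithmetic is circular (differences wrapped to
  (&minus;180&deg;, 180&deg;]); the beta term works in degrees, the
  bend term in radians, matching the units their constants are quoted
  in.
* **ion**: Coulomb sum 1000&thinsp;q~i~q~j~/(3&thinsp;r~ij~) over
  charged pairs whose exposure fractions are both below 0.25 &mdash; the
  burial filter is a crude but cheap stand-in for solvent screening.
* **solv**: &Sigma;~i~ h~i~&thinsp;SASA(i) + p~i~(1 &minus; SASA(i)),
  an implicit-solvent term that rewards burying hydrophobic and
  exposing polar residues.
* **ss**: &minus;1 for every cysteine C&beta; pair closer than
  4.5 &Aring;. All pairs count (three mutually close cysteines score
  &minus;3); restricting to a matching would require an assignment
  step the printed sum does not contain.

Binding is scored with the non-covalent subset evaluated across the
interface: inter-molecular `blj` and `bion` (burial judged in the
complex frame) plus the solvation change
`bdsolv = V_solv(A) + V_solv(B) - V_solv(AB)`, which enters the total
with a negative weight so hydrophobic burial is favorable.

### Solvent exposure

Exposure is approximated from bead geometry alone: unit vectors from a
residue's interaction center (C&beta;, C&alpha; for glycine) to all
neighbor centers within 10 &Aring; are summed with linear distance
weights 1 &minus; d/cutoff, and the norm of the weighted mean vector is
mapped onto [0, 1]. An isotropically surrounded bead scores near 0
(buried); a bead with all neighbors to one side scores near 1
(exposed); no neighbors at all means fully exposed. The cutoff and the
mapping endpoints are configuration constants. Because the measure is
*directional*, a residue in a locally flat, symmetric environment (an
isolated strand, say) can look "buried" even though it is solvent
accessible &mdash; a known artifact that matters for synthetic flat
geometries more than for compact folds, and the reason the
solvation-change test fixture uses half-shell geometries rather than
flat slabs.

## The informational potential

`score_fold_info()` is a residue-contact potential: E = &Sigma;
U~ab~C(i,j) over pairs whose C&beta; interaction centers lie within
4.5 &Aring; and that are more than four positions apart in sequence
(binding uses the rectangular inter-molecular map with no separation
filter). The published interaction matrix this family of scores is
normally used with is not reprinted here; the packaged default is a
documented synthetic hydrophobic-attraction matrix,
U~ab~ = &minus;h~a~h~b~/h~max~^2^ + 0.1&thinsp;q~a~q~b~, and any
20&times;20 labeled matrix file can be supplied by path. Contact
distance is center-to-center by default; surface-to-surface is
available via `mode = "surface"` in `contact_map()`.

## Threading

`thread()` places side-chain beads for an arbitrary sequence on a
fixed backbone. Bond length and bend angle are held at their table
values; the azimuth of each C&beta; about the incoming backbone
direction is the single refined degree of freedom, optimized by
Metropolis MCMC (Gaussian proposals, &sigma; = 0.3 rad, T = 0.1 in LJ
units, 50 sweeps by default) against the Lennard-Jones energy of the
placed bead versus all other beads. This is side-chain *replacement*:
where the template conformation carries a side-chain bead, its azimuth
is inherited as the starting point, so refinement perturbs the
existing packing instead of rebuilding it from an arbitrary direction
&mdash; re-threading an unclashed native sequence onto its own backbone
barely moves the beads. The best configuration visited is
returned, so the objective is monotone in the best-so-far sense and
backbone coordinates are bit-identical to the input. An optional
`context` structure adds fixed obstacle beads, which is how the toy
complex's native peptide is shape-optimized into its groove &mdash;
mimicking the complementarity a real bound peptide has evolved.

## Specificity: decoys and robust Z-scores

Fold specificity is the gap between the native score and the score
distribution **G** of alternative states, in units of that
distribution's dispersal. Alternative conformations follow the
random-energy-model recipe: each class of measurement consumed by the
terms (bend angles, torsions, helix distances, the three bead-pair
distance classes, exposure fractions) is independently permuted;
undefined entries (chain termini, glycine) stay in place so decoys
preserve exactly the multiset of defined measurements. For the
informational model, decoy contact maps redraw the native number of
contacts uniformly among admissible pairs. Random-sequence
alternatives are threaded through the native backbone.

Because threading random sequences into a fixed fold produces heavy
right tails (steric clashes), location and dispersal are estimated
robustly: location = median, dispersal = median &minus; first
quartile, with type-7 (linear interpolation) quantiles &mdash; Z values
depend on the quartile convention, so it is fixed and documented.
During sequence sampling and evolution the dispersal is frozen at the
starting sequence's value, making S~gap~ &prop; Z.

## Choosing term weights

`build_reference_scores()` caches per-state term vectors for the
native, 1000 shuffled-measurement decoys and 1000 threaded random
sequences (desk-scale runs use hundreds), so any weight vector can be
evaluated as a reweighting. Each term column is affinely mapped to
[0, 1] over all states *including the native* before optimization;
including the native keeps its row on the same scale as the states it
is compared against. `optimize_weights()` runs Metropolis-Hastings in
the open unit hypercube: proposals perturb every coordinate with a
Gaussian of mean 0.1 and variance 0.1 &mdash; a biased random walk,
reproduced as printed, with a switch for mean-zero proposals &mdash; at
T = 0.1, rejecting out-of-bounds proposals outright (reflecting
boundaries would interact badly with the positive proposal mean). The
best-Z weight set over the chain is retained. A constant-score table
has zero gap and zero dispersal; the cached-table objective treats
that as Z = 0 so the chain simply wanders, while the user-facing
`z_fold()` raises an error on zero dispersal.

## Sampling sequence space

`sample_sequences()` runs Metropolis over single substitutions
(uniform position, uniform different residue &mdash; the simplest
symmetric kernel) with acceptance 1 for improving moves and
exp(&Delta;S~gap~/T) otherwise. Divergence caps are counted against
the fixed start sequence. Default temperatures follow the study
conditions: 10 (high) and 0.1 (low) for the informational score, 50
and 1.5 for the physics score. `find_stable_optima()` runs replicate
low-temperature chains without divergence caps and thins each to every
fourth unique sample, keeping the final 100 per chain. Uniqueness is
exact sequence identity, first occurrence kept.

Temperature calibration matches the physics sampler's acceptance to an
informational-model trace. The empirical acceptance of a *wandering*
chain is not monotone in temperature (hotter chains drift into worse
regions, changing the proposal mix), so bisection on it is ill-posed.
`calibrate_temperature()` instead collects the proposal ensemble once
under accept-all (near-unbiased) sampling and bisects the expected
acceptance A(T) = mean(min(1, e^&Delta;/T^)), which is strictly
increasing in T; the returned temperature reproduces the target
expected acceptance to the requested tolerance.

Sammon projection of sampled sequence sets (Hamming distances) is
delegated to the standard iterative stress minimizer with a
classical-scaling initialization; exact duplicates are collapsed with
multiplicities first, since the stress is undefined at zero distance.
`information_content()` reports log~2~20 &minus; H per column, without
small-sample correction by default.

## Forward evolution under truncation selection

A population of organisms each carries one coding DNA copy. Per
generation every base mutates with probability &mu;; conditional on
mutating, the transition is drawn with probability r/(1+r) and each
transversion with probability 1/(2(1+r)), so the aggregate
transition:transversion count ratio equals r (default 2). Mutated DNA
is translated (standard code); any truncating stop &mdash; internal or in
the final codon &mdash; is lethal, since a truncated chain cannot satisfy
the fold threshold. Fitness is the three-way truncation rule: 0 if the
fold gap falls below the starting gap or binding weakens past the
starting score, 0.9 if both hold but the decoy ligand also binds, 1
otherwise; propagation is fitness-weighted sampling with replacement
at constant population size.

The 100 decoys behind S~gap~ are generated once at generation 0 and
held fixed (a config switch regenerates them), keeping scores
comparable across generations; the decoy ligand is the printed
motif-variant sequence threaded through the native ligand
conformation. Scores are cached at both the genotype and the protein
level, with the full-recompute path available by clearing the caches
(each `evolve()` call starts fresh). Checkpoints store the most common
allele, its frequency, allele counts and population-mean scores, plus
the RNG state for bitwise resumption.

Simulations start from a *sampled stability optimum*, not from the
designed native sequence: a low-temperature chain first climbs the
fold-gap landscape, and the best sampled sequence whose decoy ligand
does not out-bind the native ligand is reverse-translated into the
starting genotype. Starting at an optimum matters for the evolutionary
signatures: from a non-optimal start, early gap-improving fixations
open slack under the fixed thresholds and trigger bursts of correlated
near-neutral substitutions (conspicuously in the epistatically coupled
core); from an optimum the improvement channel is largely closed and
purifying selection acts from generation one.

Full-scale defaults mirror the study conditions (N = 1000, 200000
generations, &mu; = 10^-5^ per bp per generation, 10 replicates); the
package's tests and the acceptance script run the scaled-down
conditions N = 100, 2000 generations, &mu; = 10^-4^ with 3&ndash;5
replicates, which preserve N&mu;L while keeping runs interactive.

## Post-simulation analytics

Site classes partition positions: *binding* = any inter-molecular
interaction-center distance below 4.5 &Aring; (overriding everything
else), *core* = non-binding with exposure below the same 0.25 burial
constant the ionic term uses, *surface* = the rest. Burial for
classification is computed on the protein alone, so the fold's core is
defined independently of the ligand pose.

dN/dS uses the Pamilo&ndash;Bianchi&ndash;Li framework: sites are
classified 0-/2-/4-fold degenerate (3-fold counted as 2-fold), site
totals averaged over the two sequences; transitional and
transversional differences are counted by averaging over all minimal
substitution pathways (stop-codon pathways excluded), each step's site
class split equally between its two flanking codons; Kimura
two-parameter corrections per class combine into dN and dS. An
undefined or zero dS yields an `NA` ratio, never an infinity. The
estimator is symmetric in its two sequences, and agrees with the
related Li-style estimator in `seqinr` up to pathway-weighting
conventions.

Rate heterogeneity is assessed on per-site substitution counts across
replicate lineages (the replicate design is star-shaped, so a full
phylogenetic likelihood would add a tree that does not exist):
single-rate Poisson, discrete-gamma (4 equal-probability categories,
quantile-median rates normalized to mean one) Poisson mixture, and
Poisson-plus-invariant-class models are fit by maximum likelihood and
compared by information-criterion weights. AIC is the default
"support"; AICc and BIC are selectable, and BIC (being consistent) is
the natural choice for model-recovery checks, where AIC retains a
~15% irreducible false-selection rate for nested alternatives. The
hydrophobic set for Table-style partitions is the positive-hydropathy
set {A, V, L, I, M, F, W, C}, overridable because the percentages
depend on it.

## The synthetic study system

`make_fixture()` provides ideal helices (pitch and radius solved so
both the i,i+2 and i,i+3 C&alpha; distances equal 5.5 &Aring;), ideal
sheets (every torsion at 210&deg;), seeded random coils, a serpentine
multi-strand fold with pleated strands, designed hydrophobic
groove-facing positions and polar outward positions, and a toy complex
whose 11-residue peptide lies in the first groove with its hydrophobic
face buried and its side-chain beads shape-optimized against the
protein. All fixtures are deterministic given their seed, and
`make_all_atom_fixture()` renders them as parseable single-chain PDB
text that round-trips through `coarse_grain()`.

What the fixtures do *not* emulate: real side-chain rotamer
distributions, backbone flexibility, long-range electrostatics beyond
the screened Coulomb term, and realistic packing density &mdash; the
vector-based exposure measure behaves differently on these sparse
geometries than on compact globular proteins. Tests passing on
fixtures therefore demonstrate the internal correctness and the
qualitative selection signatures of the machinery, not quantitative
agreement with any particular experimental system; for real systems
the same pipeline ingests PDB files via `coarse_grain()`.

## Numerical choices and degenerate inputs

* Quantiles: type-7 everywhere.
* Angle wrap: (&minus;180&deg;, 180&deg;] for the beta term.
* Coincident beads make the LJ term error rather than return Inf.
* Zero-dispersal alternative distributions: error in `z_fold()`,
  Z = 0 inside the weight optimizer for the zero-gap case.
* Isolated beads (no neighbor within the exposure cutoff) are fully
  exposed, with a warning.
* Chain breaks on ingestion (C&alpha; steps > 4.5 &Aring;) warn and are
  recorded in the structure's provenance tag.
* All stochastic operations take explicit seeds; replicate and stage
  seeds are derived from a base seed by small fixed offsets.

## Known limitations

The threading move set is a minimal single-azimuth reconstruction of a
side-chain replacement procedure whose full move set is not public;
the exposure adaptation to two beads is likewise a declared
approximation. The binding score has no hydrogen-bond, cation-&pi; or
entropic terms. The evolution engine models a single haploid locus
without recombination or demography. The informational default matrix
is synthetic &mdash; conclusions about real proteins should use a
published contact matrix supplied by file.
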