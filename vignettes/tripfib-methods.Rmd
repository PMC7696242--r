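---
title: "Conformational fingerprinting and packing analysis of tripeptide assemblies: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational fingerprinting and packing analysis of tripeptide assemblies: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tripfib)
```

## Scope and data model

`tripfib` analyses ensembles of capped Phe/Ile tripeptides — the
acetyl/amide-terminated three-residue model whose self-assembly into
hydrogen-bonded filaments and laterally bundled nanofibers is the object of
study. Every analysis consumes a `structure_frame`: an atom table (name,
residue index 0–4 with the caps at 0 and 4, residue name, peptide id,
coordinates in nm) plus an optional orthorhombic box. Frames group into
`trajectory` objects (one simulation run) and `tripfib_ensemble` objects
(independent runs). All summary statistics report a mean and a standard
deviation *across runs*, the usual error-bar convention for independent
simulations.

Coordinates are held in nm everywhere; angles are degrees; superposition
RMSD and filament rise are *reported* in Å because those are the units the
field prints for backbone RMSD and cross-β spacings. Only orthorhombic
boxes are supported — minimum-image arithmetic is exact and cheap there,
and the systems this package targets are cubic. Triclinic boxes are
rejected with an error rather than silently mishandled.

## Backbone rotamer states and conformation codes

Each residue's $(\phi, \psi)$ is assigned to one of four Ramachandran
basins: right-handed helical ($\alpha_R$, letter `R`), left-handed helical
($\alpha_L$, `L`), extended $\beta$ (`B`) and left-handed polyproline II
(`P`). The default region map is a rectangular partition of the torus:

* `R`: $\phi \in [-180, 0)$, $\psi \in [-120, 50)$
* `L`: $\phi \in [0, 180]$, any $\psi$
* `B`: $\phi \in [-180, -100)$, $\psi \in [50, 180] \cup [-180, -120)$
* `P`: $\phi \in [-100, 0)$, $\psi \in [50, 180] \cup [-180, -120)$

The regions are disjoint and cover the torus, so classification is a total
function; every region is closed on its lower $\phi$/$\psi$ edge and open
on the upper edge, which makes boundary points deterministic. The map is a
plain R object, serialisable to YAML and fully overridable.

A tripeptide is summarised by the ordered three-letter code of its
residues (`BBB`, `RRB`, …). With four states per residue the raw code
space has $4^3 = 64$ members. The scheme this package implements defines
48 distinct states; the only reduction of the form $4 \times 4 \times k$
consistent with that count merges one pair of states at one position, and
the geometrically closest pair is $\beta$/PP$_{II}$ (they share the
extended upper-left quadrant and differ only in $\phi$). The default
therefore merges `P` into `B` at the C-terminal position,
$4 \times 4 \times 3 = 48$. Because this derivation is an inference, the
reduction is a switch: `default_region_map(reduce_terminal = FALSE)`
restores the full 64-code space, and reports state which convention was
used.

### Representative basin points

The structure builder realises a code at one representative
$(\phi, \psi)$ point per state: `R` $(-95, -45)$, `L` $(95, 45)$,
`B` $(-135, 135)$, `P` $(-75, 150)$. Two of these deserve comment, because
they were genuinely open choices:

* **The helical points sit deep in their basins.** The sidechain rotation
  angle between two helical neighbours is, to a good approximation, a
  linear function of $\psi_i + \phi_{i+1}$; at the textbook helix center
  $(-60, -45)$ the angle comes out near $68°$ — inside the excluded
  $60$–$115°$ band — whereas the canonical conformational chart places
  helical–helical neighbours firmly in the *syn* group. At $(-95, -45)$
  (still a right-handed helical conformation in the broad basin) the angle
  is $\approx 29°$, *syn* with a wide margin that survives $\pm 10°$
  perturbations of the representative points.
* **The $\beta$ point is the textbook antiparallel-extended value
  $(-135, 135)$** rather than a point nearer the `B`/`P` border. The
  builder's default coordinate noise ($\sigma = 0.01$ nm, below) induces
  roughly $7°$ of dihedral jitter; $(-135, 135)$ keeps the realised
  dihedrals at least five jitter standard deviations away from every
  region boundary, so a built conformation classifies back to its own code
  essentially always. A representative point $20°$ from a boundary would
  alias a few percent of observations into the neighbouring state and
  contaminate population estimates.

## Sidechain rotation angles and the five-group taxonomy

The relative orientation of adjacent sidechains is measured by the
rotation angle $\theta$, realised as the torsion
$C_\beta^{(i)}$–$C_\alpha^{(i)}$–$C_\alpha^{(i+1)}$–$C_\beta^{(i+1)}$: the
rotation of one $C_\alpha \to C_\beta$ vector relative to the other about
the $C_\alpha$–$C_\alpha$ axis. A tripeptide has two such angles
$(\theta_1, \theta_2)$. Grouping uses $|\theta|$ with two thresholds:
above $115°$ the sidechains sit on opposite sides of the backbone
(*anti*), below $60°$ on the same side (*syn*). The five groups are
all-*anti*, all-*syn*, N-*syn* ($|\theta_1| < 60$, $|\theta_2| > 115$:
the N-terminal sidechain points with the middle one), C-*syn* (the
mirror case), and *other* for any $|\theta|$ in the closed band
$[60, 115]$. The source thresholds are strict inequalities, so exact
boundary values belong to the excluded band. Signed $\theta$ values are
reported (they flip sign under mirror reflection, which is occasionally
informative); only magnitudes enter the grouping. A projected-vector
realisation of $\theta$ is available (`method = "projected"`) as a
sensitivity check; it agrees with the torsion on all tested scaffolds.

`reference_theta_map()` rebuilds the ideal fixture for every enumerated
code and records its $(\theta_1, \theta_2)$ and group — a computed
analogue of the classic scatter chart of sidechain orientations over the
whole state space. The two anchor assignments — `BBB` all-*anti*, `RRB`
all-*syn* — are asserted in the test suite and are stable under $\pm 10°$
center perturbations.

## Interaction accounting

All thresholds live in one `interaction_criteria` object:

| parameter | default | meaning |
|---|---|---|
| `contact_cutoff` | 0.65 nm | two particles in contact |
| `hb_da_cutoff` | 0.35 nm | donor–acceptor (N–O) distance |
| `hb_angle_min` | 120° | donor–hydrogen–acceptor angle |
| `core_radius` | 1.0 nm | fiber-core filter |

Contacts are counted between sidechain particles only (everything beyond
the backbone vocabulary N/H/CA/C/O plus cap atoms), with minimum-image
distances when a box is present, each unordered pair once, intra-residue
pairs excluded. Solvent exposure counts coarse-water beads (single `W`
particles) within the contact cutoff of any sidechain particle of a
residue; no separate solvent cutoff is defined, so the contact cutoff is
reused (overridable). Hydrogen-bond donors are backbone and cap amide N–H
groups, acceptors backbone and cap carbonyl oxygens; cap amides are
ordinary amides, so they participate by default (switchable). Hydrogens
absent from the input are reconstructed at the planar trans-amide
position (0.1 nm from N, external bisector of the two heavy-atom bonds;
for the C-terminal cap, trans to the carbonyl oxygen) — necessary because
the bond criterion involves the hydrogen. Only interpeptide bonds enter
the `hb` metric: chain stacking, not intramolecular structure, is what it
measures.

The per-peptide interaction profile reports six families: Phe and Ile
sidechain water counts, the three sidechain–sidechain contact families
(Phe–Phe, Ile–Ile, Phe–Ile) and the interchain hydrogen-bond count.
Contact families are normalised per residue of the relevant type (a
Phe–Phe count for an FFF peptide is divided by 3), which makes bars
comparable across sequences; the normalisation is switchable
(`per_residue = FALSE`). The hydrogen-bond count is per peptide, not per
residue.

**Core filter.** Only peptides near the fiber interior are profiled. The
"center of the fibrous segment" is realised as the principal axis of the
largest aggregate's peptide-centroid cloud, and peptides whose centroid
lies within `core_radius` of that axis are retained. A literal
point-centroid reading would empty the ends of any long fiber, which is
why distance-to-axis is the default; `mode = "point"` restores the
literal reading.

## Aggregates, filaments, rise, reference matching

The peptide contact graph (edge: any interchain particle pair within the
contact cutoff, backbone included) defines aggregates as connected
components. Within a component, two peptides are stacked neighbours when
their in-register mean $C_\alpha$–$C_\alpha$ distance (residue $i$
against residue $i$, parallel mapping) lies in $[0.40, 0.60]$ nm — a
window bracketing the 4.6–4.9 Å cross-β rise — *and* they share at least
one interchain backbone hydrogen bond. Connected chains of two or more
stacked peptides are filaments; the rise of a filament is the mean
in-register $C_\alpha$–$C_\alpha$ distance over adjacent pairs, in Å.
Antiparallel registry detection is out of scope; the in-register mapping
is parallel by construction.

Reference comparison follows the minimum-RMSD convention: every sampled
conformer is superposed onto the reference (Kabsch, SVD with determinant
correction) over the backbone N/CA/C/O + CB atoms of the three residues
(caps excluded; the selection is an argument), and the smallest RMSD wins,
ties going to the first conformer in input order.

## The synthetic generator

No simulation trajectories are distributed with the problem, so the
package carries a first-class generator that emulates the *structural*
features the analyses consume:

* `build_tripeptide()` constructs a capped tripeptide by sequential
  internal-coordinate (NeRF) placement: bonds N–CA 1.46 Å, CA–C 1.52 Å,
  C–N 1.33 Å, C=O 1.23 Å, N–H 1.0 Å, CA–CB 1.53 Å; standard sp²/sp³
  angles; $\omega$ fixed at 180°; CB on the L-amino-acid branch at
  $\phi - 122.6°$ about the N–CA axis (checked against L-residue geometry
  in experimental structures). The six measured backbone dihedrals equal
  the targets to better than $10^{-6}$ degrees at zero noise. Gaussian
  coordinate noise ($\sigma$ in nm) is applied last and is reproducible
  from a seed. The default $\sigma = 0.01$ nm gives visible jitter while
  staying far below every classification threshold.
* `build_filament()` stacks rigid copies along $z$ at a fixed rise
  (default 4.8 Å, the typical cross-β spacing; the printed range is
  4.6–4.9 Å) with an optional per-step twist. Because a rigid translation
  cannot in general place donors over acceptors, the monomer is first
  rotated — conformation untouched — into the orientation that maximises
  the number of geometric hydrogen bonds between adjacent copies
  (deterministic Fibonacci-grid search over rotations, clash-penalised,
  followed by a local Nelder–Mead refinement of a soft bond-geometry
  score). The twist sign is configurable and not asserted anywhere.
* `build_bundle()` places filaments at lateral offsets (default: a circle
  of radius 0.7 nm, putting three filament axes ≈1.2 nm apart, i.e. a
  fiber ≈2–2.5 nm across) and renumbers peptide ids. Steric collapse
  (interchain pairs under 0.05 nm) warns rather than errors.
* `add_solvent_shell()` fills the box with single-bead coarse water at a
  Poisson-distributed count, rejecting positions within an exclusion
  radius of the solute.
* `make_mixture_trajectory()` draws each peptide's conformation code
  independently from a weighted mixture per frame, realises it at the
  representative basin points plus noise, orients it randomly and places
  it on a dispersed grid (1.5 nm spacing) in a 6 nm box. Defaults mirror
  the study conditions: 30 peptides, 3 independent runs, and 200 frames
  per run as the analysis sample size.

What the generator does **not** emulate: physical dynamics, force-field
energetics, relaxed sidechain packing (sidechains are represented by CB
only unless richer input is supplied), fiber twist handedness, or any
thermodynamic preference among conformations. Tests passing on synthetic
data therefore demonstrate that the *measurement* pipeline is correct —
classification, counting and geometry recover exactly what was
constructed — not that real assemblies behave any particular way.

## Numerical choices

* Vectors shorter than $10^{-9}$ nm are degenerate; dihedrals and angles
  on degenerate geometry raise a classed error instead of returning a
  number.
* Dihedrals use the polymer sign convention (all-trans = $+180°$) with
  range $(-180, 180]$.
* Classification edge ownership is lower-closed/upper-open; exact
  $|\theta| = 60$ or $115$ fall into the excluded band (the quoted
  thresholds are strict).
* Population argmax ties break lexicographically by code; minimum-RMSD
  ties break to the first conformer in input order.
* All randomness (builder noise, solvent placement, mixture draws) is
  driven by explicit integer seeds; run $r$ of an ensemble uses
  `seed + 7919 (r - 1)`. Generation is bitwise reproducible, and the
  global RNG state is saved and restored around every seeded operation.

## Problem sizes and limitations

The test suite exercises the full pipeline at sizes chosen to finish in
about a minute: oracle-equivalence checks run 100 random instances per
kernel; the parameter-recovery check uses the full study geometry (3 runs
of 30 peptides × 200 frames, 18 000 observations) for the 70/30 mixture;
morphology recovery uses a 3 × 6-peptide bundle at $\sigma = 0.01$ nm.

Known limitations: XTC trajectories are not readable (GRO, multi-model
PDB and DCD are); only orthorhombic boxes are supported; antiparallel
filament registry is not detected; sidechain $\chi$ rotamers and
orientation-resolved aromatic stacking are out of scope — aromatic
interaction strength is approximated by sidechain contact counts, which
is exactly the approximation the interaction profile is designed around.
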