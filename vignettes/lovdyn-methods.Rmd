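---
title: "Methods: dark/light trajectory analysis for dimeric LOV proteins"
author: "lovdyn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dark/light trajectory analysis for dimeric LOV proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lovdyn)
```

## Scope and scientific background

Light-oxygen-voltage (LOV) domains are blue-light sensors built on a PAS
fold around a flavin mononucleotide (FMN) chromophore. Illumination forms
a covalent cysteinyl-FMN adduct and protonates FMN-N5; in dimeric "short"
LOV proteins such as PpSB1-LOV, the interesting downstream question is
how this local event changes the behaviour of the dimer: the hydrogen
bonding of the conserved glutamine beside the flavin (Q116 in PpSB1-LOV
numbering), a lysine-glutamate salt-bridge network across the dimer
interface (K117/E96), the orientation of the N- and C-terminal helices
(A'&alpha;, J&alpha;) that form the coiled-coil interface, and the
correlation structure of residue motions within and between the two
chains.

`lovdyn` implements the trajectory-analysis layer of such a study: given
molecular dynamics trajectories of the dark- and light-adapted dimer (as
multi-model PDB files), it computes chain-selective superpositions and
RMSD/RMSF profiles, geometric hydrogen-bond and salt-bridge occupancies,
helix crossing-angle distributions, and dynamic cross-correlation
matrices (DCCMs) with state averages and light-minus-dark differences.
It deliberately does **not** run or wrap any MD engine, assign secondary
structure, render figures, or infer hydrogens; trajectories arrive with
their hydrogens, and regions arrive from configuration.

Because production MD trajectories are large and rarely shipped with
papers, the package also contains a first-class synthetic trajectory
generator that plants known ground truth (correlated modes, interaction
schedules, helix-orientation distributions, noise), so that every
analysis stage is validated against constructed or closed-form answers
rather than against another black box.

## Superposition and RMSD/RMSF profiling

Rigid-body fitting uses the Kabsch algorithm: the rotation is obtained
from the SVD of the cross-covariance matrix of the centred point sets,
with the sign of the smallest singular vector flipped whenever the raw
optimum is a reflection, so the returned rotation always has determinant
+1. Degenerate inputs (fewer than 3 points, collinear clouds) are
rejected rather than silently fitted. The brute-force oracle used in the
tests searches rotation space on a coarse Euler grid and polishes with a
simplex optimiser; the two agree to better than 1e-3 Angstrom on random
6-point sets.

Three profiling conventions matter and are all exposed:

* **Per-residue RMSD** (fit on one selection, measure another): frames
  are fitted on the backbone of chain A and residues of chain B are
  scored against a reference structure. This turns relative subunit
  motion into a per-residue signal while removing global tumbling. The
  value for a residue is the square root of the mean squared deviation
  over its atoms and all frames.
* **Region RMSD summaries** (time average of frame-wise RMSD against the
  run's starting structure). Published tables of this kind rarely state
  whether regions were fitted locally or measured after one global fit,
  so both modes exist: `fit = "region"` (each frame fitted on the
  region's own backbone; the default) and `fit = "global"` (one fit on a
  configurable selection, regions measured without refitting).
  Per-state "Average" rows are arithmetic means across runs.
* **RMSF** about the time-average structure. With fitting enabled the
  trajectory is superposed onto its own mean (fit to frame 1, average,
  refit to that average - one refinement iteration); the reference is
  the time-average structure, not frame 1, which keeps the definition
  consistent with the displacement vectors used by the DCCM.

The standard region set (`lovRegions()`) uses PpSB1-LOV numbering:
A'&alpha; 3-13, J&alpha; 120-132, H&beta; 94-104, I&beta; 109-117, and a
configurable "core" (default 20-119). The helix and strand ranges are
fixed by the protein's topology; the core boundary is a convention and
therefore a parameter.

## Hydrogen bonds and salt bridges

A hydrogen bond is counted in a frame iff the donor-acceptor distance is
at most 3.2 Angstrom **and** the donor-hydrogen...acceptor angle (at the
hydrogen) lies in 130-180 degrees. Both bounds are inclusive: the
literature convention "130-180" does not state openness, and the
inclusive reading is the natural one for a "moderate cutoff"; the
synthetic fixtures keep a wide margin from the boundaries (satisfied
template 2.9 Angstrom / 165 degrees, violated 3.5 Angstrom / 120
degrees) so rounding can never flip a label. Each hydrogen is a separate
specification - an amide NE2 contributes distinct 1HE and 2HE specs with
separately reported occupancies.

Salt bridges use a single cation-anion distance with a 5.0 Angstrom
cutoff, measured at the carboxylate **carbon** (e.g. K117-NZ against
E96-CD): the larger cutoff at the carbon is insensitive to OE1/OE2
rotation of the carboxylate. Intra- and inter-subunit bridges are
distinct specs (K117(A)-E96(A) vs K117(A)-E96(B)).

Occupancy is the percentage of analysed frames satisfying the criterion,
reported at 0.1 precision together with the raw satisfied-frame count.
By default every saved frame is analysed; `skipFrames` can exclude an
equilibration prefix but is 0 unless requested, since no principled
default exists. Interactions that hover **above** the H-bond cutoff but
still matter electrostatically (the classic glutamine-amide to backbone
contact) are not binarised into a pseudo H-bond: the occupancy table
carries the mean distance and the fraction of frames under a clearly
labelled secondary contact threshold (default 4.0 Angstrom) instead.

## Helix crossing angles

Each helix is summarised per frame by a unit axis vector oriented from
its N- to its C-terminal end (residue numbering defines N to C), and the
crossing angle is the arc-cosine of the dot product of the two axes -
orientation-aware, so anti-parallel helices read 180 degrees and the
range is [0, 180], not folded to [0, 90] (dark-state dimers genuinely
sample angles approaching 100 degrees, which folding would alias).

The axis estimator deserves a note. The obvious estimator - the leading
principal component of the helix atom cloud - is strongly biased for
short helices: for an ideal alpha-helix the azimuthal (radial) variance
rivals the axial variance once the segment is shorter than about three
turns, and we measured errors of tens of degrees for 4-6 residue
segments. `lovdyn` instead uses the classic bisector construction:
per-residue centroids are formed, the curvature bisectors
f_i = c_(i-1) + c_(i+1) - 2 c_i of consecutive centroid triples are
exactly perpendicular to the axis for a uniform-rise helix, and cross
products of successive bisectors recover the axis exactly for ideal
helices of four residues and up, at any radius and twist. Estimates from
all bisector pairs are sign-aligned with the N-to-C chord and averaged;
a curvature-free (straight) segment falls back to the principal axis of
the centroids, which is exact in that degenerate case. Four residues is
therefore also the enforced minimum helix length.

Angles are computed on raw frames - no superposition, since the angle
between two axes of the same frame is invariant under rigid motions of
that frame. Mean and SD are taken from the raw per-frame series;
statistics recomputed from the binned frequency distribution (default
bin width 1 degree) are carried alongside, because published summaries
are sometimes derived from the histogram rather than the series.

## Dynamic cross-correlation matrices

For residues i, j with displacement vectors d_i(t) from their
time-average positions,

DCCM_ij = <d_i . d_j> / sqrt(<d_i^2> <d_j^2>),

averaging over frames. The square root in the denominator is essential:
it is the only normalisation under which the advertised range [-1, +1]
and the unit diagonal hold (Cauchy-Schwarz). Residues are represented by
their CA atom by default (a backbone-centroid mode exists). Before the
analysis each frame is fitted to the trajectory's time-average structure
over the fit selection, with one refinement iteration, so that global
drift is not reported as spurious correlation; a single rigid motion
applied to an entire trajectory leaves the matrix unchanged.

Residues with exactly zero fluctuation have an undefined correlation
(0/0); they are masked as `NA` with a warning, never silently written as
0, and masks propagate through averaging (a cell averages over the
inputs where it is defined and stays masked only if masked everywhere).
State-averaged matrices are element-wise means over replicate runs;
the difference matrix is light minus dark, so positive entries mean
higher correlation in the light state (or stronger anti-correlation in
the dark state), and swapping the states negates the matrix.
Block extraction (`subMatrix`) reproduces the usual inter-chain panels,
e.g. rows = chain A residues 90-134 against columns = all of chain B.

## The synthetic generator: what it emulates, and what it does not

`buildDimerTopology()` lays out two chains (A and B) with backbone
N/CA/C/O per residue and optional probe side chains; the geometry in
`generateTrajectory()` is one continuous ideal alpha-helix per chain
(rise 1.5 Angstrom, 100 degrees per residue), so every helical
sub-segment is an ideal helix and the axis ground truth is known by
construction. Displacements are applied in a fixed order - helix
orientation rotation of chain B, planted modes, interaction-geometry
overrides, then noise - so every stage has an analytic or constructed
expectation:

* **Modes** add `a(t) * u` to selected atoms, with `a(t)` constant,
  sinusoidal, or Gaussian. Two atoms sharing one mode have planted
  correlation equal to the dot product of their unit directions:
  +1 (equal), -1 (opposite), 0 (orthogonal), exactly, at zero noise.
* **Interaction schedules** realise a target occupancy fraction exactly:
  the first `round(fraction x nFrames)` frames receive the satisfied
  template, the rest the violated one. Noise is applied afterwards, so
  exactness is guaranteed only at (near-)zero noise - the margins
  (0.3 Angstrom, 35 degrees) tolerate small jitter.
* **Helix orientation** rotates chain B rigidly per frame so the two
  axes cross at the scheduled angle (constant or Gaussian); the manifest
  records the realised sample mean and SD.
* **Noise** is isotropic Gaussian, per atom and coordinate, drawn from a
  single generator seeded from the spec; without fitting, per-atom RMSF
  converges to sigma * sqrt(3).

The generator's frame interval metadata is fixed at 25 ps, a typical
snapshot cadence for nanosecond-scale protein MD; no analysis depends on
it. What the generator does **not** emulate: bonded geometry and sterics
(atoms may pass through each other), solvent, anisotropic or
time-correlated fluctuations, secondary-structure transitions, and
side-chain rotamer dynamics. Tests passing on these fixtures therefore
validate the *estimators* - superposition, occupancy counting, axis and
correlation recovery - not any claim about real protein energetics.

Default study conditions used by the validation suite and the acceptance
script: planted-mode amplitude 2 Angstrom against noise sigma 0.1
Angstrom (collective modes comfortably above the noise floor, as in real
trajectories of stable folds), occupancy schedules at fractions 0.5/0.3
over 100 frames, crossing angles N(40 deg, 5 deg) over 2000 frames
(matching the magnitude and spread a stable light-state coiled-coil
samples), RMSF noise sigma 0.5 Angstrom over 10000 frames, DCCM noise
checks at 5000 frames with the 3/sqrt(n) sampling bound. Problem sizes
(12-20 residues per chain, tens to thousands of frames) are chosen so
the whole suite runs in seconds while keeping sampling error well inside
the stated tolerances.

## Numerical choices and degenerate inputs

* Kabsch: collinearity is detected via the second singular value of the
  centred cloud (threshold 1e-8 relative); reflections are excluded by
  the determinant sign correction.
* DCCM: the diagonal is set to exactly +1 for unmasked residues (it is
  mathematically exact; floating point would leave ~1e-16 residue), the
  matrix is symmetrised as (M + t(M))/2, and values are clipped to
  [-1, 1] against last-ulp overshoot. Zero-fluctuation detection is
  exact (variance == 0), not threshold-based, so genuinely tiny motions
  are never masked.
* Angle series: frames where the hydrogen coincides with donor or
  acceptor give `NA` with a warning naming the frames - reported, never
  dropped, so occupancy denominators stay honest.
* Histogram binning: right-closed bins over [0, 180] with the lowest bin
  closed on both sides; counts always sum to the number of measured
  frames.
* PDB I/O: parsing and formatting are delegated to `bio3d`; the wrappers
  enforce this pipeline's contracts (per-model atom-count validation
  naming the offending model, insertion-code rejection, first-altLoc
  retention with a warning, duplicate-key detection). Coordinates
  round-trip at the format's three-decimal precision. Residue numbering
  is taken verbatim from the file, 1-based, as in the protein numbering
  used throughout (V19, C53, E96, S98, Q116, K117).

## Design decisions that were genuinely open

* **Region-RMSD fitting convention**: published region tables do not
  always say whether regions were fitted locally or globally; both modes
  are provided and the local fit is the default (see above).
* **Helix-axis estimator**: principal axis of the raw atom cloud was
  rejected after measurement (tens of degrees of bias for short
  helices); the bisector construction was adopted instead, with PCA as
  the degenerate-case fallback. This is the package's own choice of
  estimator for a method usually described only as "a vector along the
  backbone atoms".
* **DCCM normalisation**: implemented with the square root in the
  denominator - the only reading consistent with a [-1, +1] range and
  unit diagonal.
* **Angle statistics**: raw-series mean/SD are authoritative; binned
  statistics are reported for comparability with frequency-distribution
  summaries.
* **Equilibration discard**: none by default; `skipFrames` exists for
  users who want one.
* **Occupancy reporting**: percentages at 0.1 precision; counts are kept
  alongside so no information is lost to rounding.
* **Interfaces**: the package's functions are the primary interface; a
  thin command-line wrapper (`inst/scripts/lovdyn.R`) exposes
  generate/run/compare for shell use, and `runAnalysis()` drives the
  whole study from one YAML configuration with per-stage error isolation
  (a failing DCCM stage cannot disturb occupancy outputs).

## Known limitations

* Only multi-model PDB is read and written; binary trajectory formats
  (DCD/XTC) would need external conversion.
* Hydrogens must be present for H-bond analysis; nothing is inferred.
* The DCCM is a linear, isotropic correlation measure; generalised
  (mutual-information) correlations and network analyses are out of
  scope.
* The synthetic generator's limitations listed above mean that
  validation does not certify behaviour on pathological real-world
  inputs (chain breaks, missing residues, alternate conformer
  ensembles).
* Crystal-structure cross-checks against deposited coordinates require
  those files locally; no downloading is performed.
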