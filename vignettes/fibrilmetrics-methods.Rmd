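---
title: "Methods: fibril mechanics, helical geometry, sequence profiles and cavities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fibril mechanics, helical geometry, sequence profiles and cavities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrilmetrics)
```

fibrilmetrics is a desk-scale toolkit for the quantitative questions that
come up when an amyloid fibril — here modelled on a patient-derived
immunoglobulin light-chain (AL) fibril — has been imaged and its atomic
structure solved: how stiff is the fibril, what screw symmetry stacks its
subunits, which parts of the sequence drive aggregation, how does the
fibril fold differ from the native fold, and what voids does the packing
leave behind. Every stage runs offline: a synthetic-data module generates
statistically controlled stand-ins for each input, which is also how the
test suite derives its expectations.

## Worm-like-chain mechanics

A fibril deposited and equilibrated on a support film before imaging is
well described by a two-dimensional worm-like chain (WLC). For contour
length $L$ and persistence length $P$, the mean squared end-to-end
distance of the in-plane equilibrated chain is

$$\langle D^2 \rangle \;=\; 4PL\left[1 - \frac{2P}{L}\left(1 -
e^{-L/2P}\right)\right],$$

which tends to $L^2$ for stiff/short fibrils ($L \ll P$) and to $4PL$ in
the flexible limit. The persistence length converts to a bending
rigidity via $B = P\,k_B\,T$ with $k_B$ the exact CODATA Boltzmann
constant ($1.380649\times10^{-23}$ J/K) and $T = 300$ K by default.
Unit conversions (traces in nm, fits in um, $B$ in SI) are centralized
so no $10^6$-scale factor can leak into user code.

**Generator.** `generate_wlc_trace()` discretizes the 2D WLC as a
polyline of equal-length segments whose tangent angles perform a
Gaussian random walk with increment variance $\Delta s / P$; this gives
the exact tangent autocorrelation $e^{-s/2P}$ of the 2D chain. The
discretization-validity guard (`step <= P/50`) keeps each turning angle
small. Two numerical facts worth knowing:

* the polyline's contour length is exactly `n_segments * step`;
* a polyline of straight segments has no intra-segment bending, so its
  $\langle D^2\rangle$ exceeds the continuum value by a relative
  $O(\mathrm{step}/P)$ term. At the default `step = P/335`
  (0.02 um at $P = 6.7$ um) this is far below Monte-Carlo resolution;
  the property test that compares ensemble means against the closed form
  uses `step = P/200` for the same reason.

**Estimation.** `fit_persistence_length()` fits $D^2$ against $L$, one
point per fibril, with Levenberg-Marquardt least squares. $D^2$ is
strongly heteroscedastic — empirically $\mathrm{Var}(D^2\,|\,L)$ grows
like $L^{5.8}$ over the 1-8 um range at $P = 6.7$ um — so the default is
*relative* least squares: weights $1/\hat\mu(L)^2$ refreshed from the
fitted curve over two reweighting passes. An unweighted fit of the raw
$D^2$-vs-$L$ plot (`weights = "none"`) is retained for comparability
with the plain plot-fit reading, but it lets the few longest, noisiest
fibrils dominate: across 200 simulated 124-fibril surveys the unweighted
estimator showed a +2.4% mean bias and a standard deviation of 0.77 um,
versus +1.0% and 0.59 um for the weighted default. The starting value is
$D^2_{\max} / (4 L_{\max})$ clipped to [0.01, 100] um; all-straight
fibrils ($D = L$) have no finite optimum, so the fit is capped at
1000 um and flagged as non-converged at the cap.

Because the published uncertainty convention for such fits varies, the
fit reports both the asymptotic standard error and a seeded bootstrap
standard deviation over fibrils (default 1000 resamples).

**What the simulation shows — and does not.** With 124 fibrils of
uniform 1-8 um contour length at $P = 6.7$ um, the per-fibril Fisher
information about $P$ contained in an $(L, D^2)$ pair is nearly flat in
$L$, and the resulting sampling spread of the fitted $P$ is irreducibly
about 0.5-0.6 um for any length distribution at this sample size. A
single 124-fibril survey therefore pins $P$ to roughly +/-10%, not
better; claims of tighter precision at this design would require several
hundred fibrils or per-fibril information beyond the end-to-end
distance. The generator emulates equilibrated, independently sampled
ideal chains; it does not model digitization noise, incomplete surface
equilibration, or fibril-fibril crowding, all of which would widen (not
narrow) the spread on real micrographs.

## Helical geometry

Consecutive fibril layers are related by a screw operation: rise
(A per subunit) along the axis and signed twist (degrees) about it,
negative twist meaning left-handed. Pitch follows as
$\mathrm{rise}\times 360/|\mathrm{twist}|$ and the cross-over distance
as half the pitch. With the cryo-EM values for this fibril (rise 4.8 A,
twist 0.58 degrees, left-handed) the pitch is about 298 nm.

`build_stack()` applies the screw operation exactly, so
`estimate_symmetry()` — Kabsch superposition of consecutive chains,
decomposed into rotation about and translation along the rotation axis —
must invert it to floating-point accuracy; the tests check this over a
grid of rises and twists. The axis is oriented so the rise is positive,
and the twist sign then encodes handedness by the right-hand rule. For
deposited models the same decomposition supplies the axis used by
`axial_height_span()` and `measure_width()`.

Width is reported in two documented modes: atom-centre extent and
extent plus van der Waals radii. An experimental density-map width is an
envelope measurement, so only approximate agreement with either mode
should be expected.

Contacts: `interlayer_contacts()` records residue pairs with minimum
heavy-atom distance within 4.5 A (a standard heavy-atom contact
cutoff), annotated by layer offset, and flags salt bridges when
Arg/Lys side-chain nitrogens meet Asp/Glu side-chain oxygens within
4.0 A. Neither cutoff is prescribed by the source study; both are
conventional and configurable.

## Sequence profiles

`hydropathy_profile()` is a centred sliding-window mean of the
Kyte-Doolittle scale with truncated windows at the termini; the default
window of 1 reports per-residue values, matching how such profiles are
usually plotted for fibril cores.

The consensus amyloidogenicity score counts, per residue, how many of
five aggregation predictors (WALTZ, TANGO, FoldAmyloid, Aggrescan,
AmylPred) mark it: 0 = none, 5 = all. WALTZ and TANGO are
statistical-mechanics models in their own right and are *not*
reimplemented; their per-residue outputs are ingested from TSV with the
documented thresholds (values strictly above 0.00). FoldAmyloid values
are ingested the same way with its published rule (above 21.4 in runs of
at least five residues); its packing-density scale itself is not shipped
because its values could not be verified against the original
publication to transcription accuracy, and shipping unverifiable
constants as published data seemed worse than requiring the predictor's
own output file. The Aggrescan a4v residue scale *is* packaged
(`aggrescan_a4v()`), so Aggrescan-style hot-spot scans can run entirely
in-package via `scale_scan()` with the published threshold of -0.02.

Mutations: `list_mutations()` compares aligned equal-length sequences
and reports differing positions; `apply_mutations()` guards numbering
conventions by requiring the stated wild-type residue to match before
substituting. `classify_mutation()` annotates charge changes (side-chain
formal charge at pH 7), CDR membership (ranges are a configuration
input, since CDR numbering schemes differ), cavity lining (from the
cavity module), and burial. Burial uses a neighbour-count proxy — heavy
atoms within 10 A of the residue's C-beta, buried at a count of 24 or
more — rather than a solvent-accessible-surface computation; the proxy
is crude but monotone with accessibility and works on backbone-only
models.

**The sequence template is synthetic.** The actual patient and germline
sequences behind the modelled fibril are not published; only the ten
substitutions and several landmark residues are. `germline_template()`
is a synthetic lambda-V_L-like 110-residue sequence constructed to carry
the documented residue identities at the documented positions (the
Cys22/Cys89 disulfide pair, Gly15 and Thr105 bounding the 91-residue
ordered core, the wild-type residues at all ten mutated positions, and
the named landmarks such as Glu84, Asp86, Trp99). Tests that count
mutations or span the core exercise real package logic on this template;
they do not certify any real patient sequence.

## Conformational comparison

Strand assignment uses a backbone-dihedral heuristic: maximal runs
(length >= 2) of residues with phi in [-180, -45] and psi in [45, 180]
or [-180, -170]. The region is configurable because published
assignment methods (DSSP, STRIDE, author judgment) differ; the
defaults cover the canonical beta basin including the polyproline
fringe. Synthetic backbones built by `build_backbone()` from ideal
phi/psi (NeRF-style internal-coordinate chain growth with standard bond
geometry) provide exact test cases: ideal extended chains yield one
strand, ideal helices none.

The rotational switch around the intramolecular disulfide is
operationalized as a vector angle: for each structure the principal
C-alpha direction of each segment (defaults 16-23 and 86-93, the
disulfide-flanking segments), oriented N to C, and the angle between
them. Below 90 degrees is parallel, above is antiparallel, and a switch
is flagged when the two structures classify differently. The principal
direction is used instead of a first-to-last vector for robustness to
strand curvature (both are simple to compute; only the principal
direction is exposed). This vector-angle definition is this package's
operationalization of a pictorial concept, and is recorded as such.

Disulfide geometry: S-gamma to S-gamma distance, bonded within
[1.8, 2.5] A around the 2.05 A canonical S-S bond.

## Cavity detection

`find_cavities()` rasterizes the model onto a regular grid (default
spacing 0.5 A), marks voxels within van der Waals radius (Bondi: C
1.70, N 1.55, O 1.52, S 1.80 A) plus probe radius (default 1.4 A,
water) of any atom as occupied, floods the exterior from the grid
boundary with 6-connectivity, and reports the remaining free connected
components of at least `min_volume` (default 20 A^3) as cavities. The
grid is padded by twice the largest occupancy radius so no cavity can
touch the boundary; 6-connectivity makes the flood fill deterministic
and conservative (a diagonal gap does not leak). The flood fill and
sphere stamping are implemented in C++ since they dominate runtime at
fine spacings.

Validation relies on phantoms with analytically known voids:
`generate_cavity_phantom()` builds a sealed Fibonacci-lattice shell of
pseudo-atoms whose innermost centres sit at `void_radius + vdW + probe`
from the centre, so detection with the matching probe recovers a free
sphere of exactly `void_radius`. The tests check convergence of the
measured volume to $\tfrac43\pi r^3$ as the grid is refined (1.0, 0.5,
0.25 A), monotonicity of total cavity volume in the probe radius, and
that a bored channel (wider than the occupancy radius) abolishes the
sealed void. Polarity classification is the fraction of polar
side-chain atoms (N, O, plus Cys/Met S) among lining side-chain atoms
within 4.5 A of a cavity voxel, hydrophilic at 0.5 or above; the
threshold absorbs the genuinely ambiguous polarity of sulfur.

## Pipeline and problem sizes

`run_config()` / `run_pipeline()` tie the stages together behind one
serializable configuration (YAML-compatible), writing a single JSON
report with fixed key order so identical configurations produce
byte-identical reports. Every stage falls back to the synthetic
generators when no input file is given, which is how the package's
examples and tests run without network access.

Default problem sizes are chosen to mirror the modelled study where it
states them (124 fibrils per survey; 91-residue layers; five-layer
stacks; rise 4.8 A and twist -0.58 degrees) and to keep a full run in
seconds otherwise (10^4-trace ensembles for distributional checks,
0.5 A default grids, 50-replicate recovery studies). The bootstrap
default of 1000 resamples reflects common practice for a one-parameter
fit.

## Known limitations

* The WLC module is strictly 2D; 3D chains or projections of 3D chains
  are out of scope, as are kinetic (tip-tracking) analyses.
* Strand assignment is dihedral-only: it sees local backbone geometry,
  not hydrogen bonding, so isolated extended residues in loops can be
  grouped into short strands that DSSP would reject.
* The burial proxy is coordination-number based and should not be read
  as a calibrated relative accessibility.
* Cavity volumes are voxel counts: they converge from one side at the
  default spacing and carry a few percent discretization error.
* The polarity class of a cavity depends on the lining cutoff and on
  how sulfur is counted; borderline cavities (polar fraction near 0.5)
  should be inspected, not trusted.
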