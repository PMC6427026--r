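# fibrilmetrics

Quantitative analysis of amyloid fibril structure at desk scale, built
around the measurements that matter for patient-derived immunoglobulin
light-chain (AL) amyloid fibrils:

* **Mechanics** — estimate the persistence length *P* of fibrils from
  digitized contour traces via the two-dimensional worm-like-chain
  relation
  ⟨D²⟩ = 4PL·[1 − (2P/L)(1 − e^(−L/2P))],
  and convert it to a bending rigidity B = P·k_B·T.
* **Helical geometry** — relate the per-subunit rise and signed twist of
  a fibril stack to its pitch and cross-over distance
  (pitch = rise·360/|twist|), build stacks by the screw operation,
  recover the symmetry from atomic models, and map inter-layer residue
  contacts and salt bridges.
* **Sequence profiles** — Kyte–Doolittle hydropathy, a per-residue 0–5
  consensus amyloidogenicity score from five aggregation predictors
  (WALTZ, TANGO, FoldAmyloid, Aggrescan, AmylPred), and
  germline-vs-patient mutation listing with structural classification
  (charge change, burial, CDR membership, cavity lining).
* **Conformational comparison** — dihedral-based β-strand assignment,
  strand-registry overlap, disulfide geometry, and detection of the
  rotational switch of the disulfide-flanking segments between a native
  and a fibril conformation.
* **Cavity detection** — sealed interior voids by occupancy-grid flood
  fill (C++ kernel), with volumes, lining residues and a
  hydrophilic/hydrophobic classification.

A synthetic-data module generates every input the pipeline needs —
worm-like-chain trace ensembles with known *P*, idealized flat protomer
layers, cavity phantoms with analytically known void volumes, and
germline/patient sequence pairs — so all analyses, examples and tests
run offline and reproducibly under explicit seeds.

## Worked example

Simulate a 124-fibril survey at a persistence length of 6.7 μm, fit the
WLC relation, and inspect the helical geometry and mutation list:

```r
library(fibrilmetrics)

traces <- generate_trace_ensemble(6.7, 124, length_range = c(1, 8),
                                  step = 0.02, seed = 42)
fit <- fit_persistence_length(measure_traces(traces),
                              temperature = 300, n_bootstrap = 500)
print(fit)
#> worm-like-chain fit (n = 124 fibrils)
#>   P = 6.72 um (fit se 0.61, bootstrap se 0.79)
#>   B = 2.785e-26 N m^2 at T = 300 K
```

The fitted *P* of 6.72 μm recovers the simulation truth of 6.7 μm within
the fit's own uncertainty (about ±0.6 μm at this sample size — a single
124-fibril survey pins *P* to roughly ±10%); the bending rigidity
follows as P·k_B·T at 300 K.

```r
geom <- pitch_and_crossover(helical_symmetry(rise = 4.8, twist = -0.58))
#> pitch 2979 A (298 nm), crossover 1490 A, left-handed
```

A rise of 4.8 Å with a left-handed twist of 0.58° per subunit gives a
~298 nm helical pitch, i.e. a cross-over roughly every 149 nm.

```r
list_mutations(patient_sequence(), germline_template())
#>    pos germline patient
#> 1   25        S       R
#> 2   31        S       R
#> ...
#> 10  98        G       A
```

Ten substitutions at positions 25, 31, 33, 35, 40, 53, 76, 94, 95 and
98 distinguish the (synthetic, landmark-faithful) patient sequence from
its germline template.

```r
cavs <- find_cavities(generate_cavity_phantom(phantom_spec(3)))
cavs[[1]]$volume
#> 116.2  # A^3; analytic sphere volume 4/3*pi*27 = 113.1
```

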