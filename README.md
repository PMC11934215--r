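# groovedyn

Trajectory analysis of allosteric groove opening in helical proteins.

14-3-3 proteins bind phosphorylated partners in an amphipathic groove
between helices H3/H5/H7/H9, and the accessibility of that groove is set
by transient opening/closing of the C-terminal lobe. Whether — and how —
residues far from the groove gate this motion is a question about
*correlated dynamics*: it is answered not from a single structure but
from trajectories, by asking which residue pairs move together, which
contact events precede which, and what the free-energy landscape of the
collective motion looks like. `groovedyn` packages that workflow for R
users in structural bioinformatics: people with Cα trajectories (from
MD or from ensemble models) who want a reproducible, tested pipeline
from coordinates to mechanism.

## What it computes

Given frames `r(t)` superposed on a reference structure `r^ref`:

* **Displacement correlation (DCCM)** between residues *i, j*:

  `C_ij = <Δr_i · Δr_j> / sqrt(<|Δr_i|²> <|Δr_j|²>)`,  `Δr_i(t) = r_i(t) − r_i^ref`

* **Correlation network / shortest path map (SPM).** Residues are
  nodes; an edge joins *i, j* when their Cα–Cα distance stays below a
  cutoff (6 Å default, 8 Å optional) for at least a fraction (0.3) of
  frames, weighted `l_ij = −ln |C_ij|` (sign kept as metadata). Dijkstra
  shortest paths accumulated over all residue pairs give per-edge and
  per-node usage scores; high-usage nodes are the residues mediating
  correlated motion.

* **Lagged cross-correlation** of distance time series, standardized,
  `r(k) = corr(x(t+k), y(t))`: a negative extremum lag means `x` leads
  `y`, so a gating contact that *precedes* groove opening shows its
  strongest anti-correlation at negative lag. `event_order()` ranks
  several series against a reference and flags simultaneity.

* **Essential dynamics.** PCA of the 3N×3N covariance of superposed Cα
  coordinates; projections, cumulative variance, extreme-conformation
  interpolation, and Hess's cosine content `c_i` as a convergence
  diagnostic (`c_i → 1` for diffusive, unconverged sampling).

* **Free-energy landscape.** 2D histogram of (PC1, PC2) Boltzmann-
  inverted as `Δε_i = −k_B T ln(n_i/n_max)` (kJ/mol, 300 K default),
  with persistence-based minima detection and representative-frame
  extraction.

* **Synthetic generators with known ground truth**: Gaussian ensembles
  from an elastic-network (Kirchhoff pseudo-inverse) covariance, a
  reversible two-state groove opener with designed populations and an
  injected gate→groove lead, and lag-injected series pairs — so every
  stage is testable without MD data.

## Worked example

Run the full pipeline on the built-in two-state opener (a 4-bead
reporter system with a known allosteric chain: groove edges communicate
only through a gate contact pair that leads the opening by 40 frames,
open fraction 0.3):

```r
library(groovedyn)
cfg <- pipeline_config(
  synthetic = two_state_opener_spec(n_frames = 20000),
  cutoff = 40, max_lag = 100, seed = 7)
report <- run_pipeline(cfg)
report
#> groove-opening pipeline report
#>   pairs: groove, gate
#>   coupling vs 'groove':
#>     gate: r* = -0.918 at lag -40 frames
#>   PC1+PC2 capture 65.5 % of variance; cosine contents: 4.52e-05, 1.56e-05, 6.05e-07, 0.001, 2.92e-05
#>   FEL minima: 2 (energies 0, 1.55 kJ/mol)
#>   config hash: 09c62053
```

Reading the output: the gate–groove cross-correlation peaks at
r\* = −0.918 at lag −40 frames — the gate contact is strongly
anti-correlated with the groove distance (contact formed ⇔ groove open)
and *precedes* it by exactly the injected 40-frame lead. Cosine contents
near zero say the sampling is converged, and the landscape resolves the
designed closed/open basins as two minima. The distance histogram and
the shortest path map recover the rest of the design:

```r
report$histograms$groove
#> histogram of 20000 values: mean 21.91 A, sd 2.28 A
#>   mean +/- 2 sigma: [ 17.35 , 26.47 ] A;  2.5-97.5% quantiles: [ 19.09 , 26.32 ] A
#>   peaks at 20.62, 25.38 A
report$network$spm
#> shortest path map: 6 edges
#>   top-usage residues: A:G3 (7), A:G4 (7), A:G1 (3), A:G2 (3)
#>   backbone path (3 residues, length 1.126): A:G1 > A:G3 > A:G4
```

The two histogram peaks sit at the designed closed (20.5 Å) and open
(25.2 Å) groove distances, and the SPM's top-usage nodes are the two
gate beads (residues 3 and 4): the groove-to-groove shortest path runs
through the gate, which is the allosteric statement the method is built
to make.

For real data, point `pipeline_config()` at a PDB structure plus
trajectory files (multi-model PDB or DCD) and define pairs with
selection strings such as `c("resid 53 and name CA", "resid 220 and
name CA")`. A command-line wrapper over the same function lives in
`inst/scripts/run_pipeline.R`.

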