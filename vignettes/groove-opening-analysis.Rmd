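---
title: "Dissecting allosteric groove opening from trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting allosteric groove opening from trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groovedyn)
```

## The scientific problem

14-3-3 proteins recognize phosphorylated partners in an amphipathic
groove framed by helices H3, H5, H7 and H9. The groove breathes: the
C-terminal lobe transiently opens and closes, and the H3–H9 Cα distance
is a natural order parameter for that motion. The analytical question
this package addresses is *mechanistic*: which residues, possibly far
from the groove, gate the opening, and in what temporal order do the
gating events and the opening occur? None of this is visible in a
single structure; it lives in the correlation structure of a
trajectory. `groovedyn` implements the complete chain of analyses —
distance distributions, displacement-correlation networks with
shortest-path maps, lagged cross-correlation of contact time series,
essential dynamics with convergence diagnostics, and Boltzmann-inverted
free-energy landscapes — together with synthetic generators whose
ground truth exercises every stage.

## Data model and conventions

Coordinates are always Å, time ns, temperature K, energies kJ/mol.
A `topology` maps contiguous internal residue indices (1-based, the R
idiom) to chain + PDB residue number, so results are reported with the
labels structural biologists use (`A:G53`). Trajectories are
`frames × atoms × 3` arrays; PDB and multi-model PDB are read through
bio3d (DCD likewise), alternate locations are resolved to the
highest-occupancy copy (ties to the first record), and waters/hetero
records never enter the residue list. A small selection grammar
(`"resid 53 and name CA"`, `"calpha"`, `"chain B and resid 153 and
name CZ"`) resolves atoms deterministically; every selection in a
pipeline config is resolved before any computation starts.

## Displacement correlation and the shortest path map

The correlation between residues is the normalized inner product of
displacement vectors *relative to a reference structure* (by
convention the X-ray/start frame, after least-squares superposition):

$$C_{ij} = \frac{\langle \Delta r_i \cdot \Delta r_j\rangle}
{\sqrt{\langle \Delta r_i^2\rangle\langle \Delta r_j^2\rangle}},
\qquad \Delta r_i(t) = r_i(t) - r_i^{\mathrm{ref}}.$$

A residue graph is then built with a *contact-persistence gate*: an
edge joins residues *i, j* only if their Cα–Cα distance is below a
cutoff in at least a fraction of frames (strict inequality per frame).
Defaults are 6 Å and 0.3, with 8 Å the conventional looser setting for
reaching more distant couplings; both are plain arguments. Edges carry
weight $l_{ij} = -\ln|C_{ij}|$, so strongly correlated pairs are close.
Two numerical choices deserve note:

* The weight uses $|C_{ij}|$ with the sign retained as an edge
  attribute. A signed $-\ln C_{ij}$ is undefined for anti-correlated
  pairs, and anti-correlations are precisely the interesting couplings
  when a contact forms as a groove opens — discarding them would
  remove the mechanism from the network.
* Natural log. Shortest paths are invariant under any positive
  rescaling of all weights, hence under the choice of log base; the
  base affects only reported path lengths. This invariance is asserted
  on random graphs in the test suite.

Dijkstra shortest paths (via igraph, with a lexicographic tie-break
layered on top so results are deterministic) are accumulated over **all
residue pairs** of the connected component: each edge's *usage* is the
number of source–sink pairs whose shortest path traverses it, and node
usage is the sum over incident edges. This all-pairs accumulation is
reported as the shortest path map, alongside the single backbone path
joining the first and last residue; both are exposed because published
maps vary in which set they draw, and the node-usage score is what
sizes the map's spheres. Zero-variance residues have no defined
correlation; they are flagged, excluded from the graph, and never
silently imputed.

## Lagged coupling and event order

Gating hypotheses are statements about *order in time*: the contact
event precedes the opening. For two distance series the package
computes, after standardization, the Pearson correlation of the
overlapping segments at every lag,

$$r(k) = \mathrm{corr}\,(x(t+k),\, y(t)),$$

so that a **negative extremum lag means the first series leads**.
The convention is arbitrary in principle and consequential in
practice, so it is fixed, documented, and pinned by tests (a copy of
`x` delayed by 5 frames produces the extremum at lag −5 with
r = 1 exactly). Standardization first — rather than raw covariance —
lets r values be compared across pairs with different distance scales.
Pearson-on-overlap guarantees $|r|\le 1$ at every lag, and extremum
ties break toward lag 0, then toward negative lag. Couplings whose
extremum magnitude stays below the white-noise bound $3/\sqrt{n}$ are
flagged "no significant coupling"; no stronger significance theory is
attempted. Concatenated replicas are handled by excluding frame pairs
that straddle a replica boundary (recorded by `replicate_concat()`),
because naive concatenation manufactures correlations at the seams; a
flag disables the exclusion.

## Essential dynamics and convergence

PCA is performed on the 3N×3N covariance of superposed coordinates
about their mean, unweighted (Cα selections are conventionally
analyzed with unit masses; heavier-atom selections are just a
different selection string). The symmetric eigensolver branch is used
for stability, eigenvalues are clipped at zero, and eigenvector signs
are fixed by making each vector's largest-magnitude coordinate
positive so that resampled fits agree. Projection variance equals the
eigenvalue by construction — the identity is tested at 1e-10 — and
cumulative variance against analytic elastic-network spectra is tested
at the 5% level. Sampling convergence uses Hess's cosine content with
midpoint time sampling,

$$c_i = \frac{2}{n\sum_j p_j^2}\Bigl(\sum_j \cos(i\pi t_j)\,p_j\Bigr)^2,
\qquad t_j = \frac{j - 1/2}{n},$$

which is exactly ≤ 1 on this grid, reaches 1 for a matching cosine and
0 for orthogonal orders, and stays near 0 for well-sampled multi-state
dynamics while approaching 1 for random diffusion. Extreme-conformation
sweeps interpolate the mean structure linearly along one eigenvector
between the minimum and maximum observed projections, which renders a
mode readable as a motion (for the opener, a monotone groove-opening
movie).

## Free-energy landscapes

The 2D histogram of (PC1, PC2) is Boltzmann-inverted,

$$\Delta\varepsilon_i = -k_B T\,\ln\frac{n_i}{n_\max},
\qquad k_B = 0.0083145\ \mathrm{kJ\,mol^{-1}\,K^{-1}},$$

with the most populated bin at exactly zero and empty bins masked
rather than given pseudo-counts. Defaults: 64×64 bins over the
observed range padded 5%, 300 K. Minima detection is a topological
persistence merge: basins grow in order of increasing energy, and when
two meet, the shallower minimum survives only if its barrier exceeds a
depth threshold (default $1\,k_BT$ — the scale below which basins are
kinetically indistinct at the simulation temperature). Two guards keep
sampling noise out of the report: masked bins join the connectivity
pass at a ceiling energy corresponding to half a count (the
histogram's resolution floor), so isolated single-sample islands at
the sparse rim are absorbed rather than counted; and only a bin whose
full 8-neighborhood is populated may seed a minimum, since a genuine
basin floor is locally well sampled (the global minimum is always
reported). Representative frames are the frames nearest each minimum's
bin center in PC space, earliest frame on ties.

## What the synthetic generators emulate

The generators define the study conditions under which the pipeline is
validated; their defaults were chosen once, from the physics they
emulate, and are not tuning knobs.

**Elastic-network ensembles.** `chain_gnm_covariance()` builds the
Kirchhoff (contact Laplacian) matrix of a 3.8 Å-spaced bead chain,
removes rigid-body null modes via the Moore–Penrose pseudo-inverse,
and applies the result isotropically per coordinate. Ensembles drawn
from it have fully analytic correlation matrices, RMSF profiles and
PCA spectra — the oracles behind the correlation-recovery and
spectrum tests. Frames are i.i.d. by default; an AR(1) option
(`ar_tau`, preserving the marginal covariance) provides temporally
structured input where convergence diagnostics need it.

**Two-state opener.** A hidden reversible Markov chain with stationary
open fraction 0.3 and per-frame switch rate 0.05 drives a 4-bead
reporter: bead 2 carries the groove distance (means 20.5/25.2 Å — the
two peaks of the flexible paralog's distance distribution — with
within-state SD 0.8 Å), and beads 3–4 realize the gate contact
(3.8 Å formed in the open state, 8.0 Å broken, SD 0.3 Å). The gate
responds to the state immediately; the groove follows 40 frames later,
so the gate *leads* and the two series are anti-correlated, mirroring
the proposed trigger. Crucially, the groove beads share no direct
correlated motion: each is coupled to its adjacent gate bead through a
1 Å shared contact-noise component, so in the correlation network all
groove-to-groove communication is forced through the gate pair. That
is the designed ground truth the SPM must recover, and it encodes the
allosteric chain H3–gate(H6/H7)–H9 in the smallest system that can
express it. Rates were set by an up-front power consideration: 0.05
per frame yields ~500 transitions in a 10⁴-frame series, enough for
exact lag recovery, while keeping dwell times (~20–50 frames) long
compared to the frame step.

What these generators do **not** emulate: solvent, force-field
anharmonicity, rotational diffusion (frames are drawn in a common lab
frame, which is why validation analyses run with `fit = FALSE`),
side-chain torsional dynamics, and the sequence heterogeneity of a
real 230-residue monomer. Passing tests therefore demonstrate that the
*estimators* are correct and that designed signal is recovered at
realistic noise levels — not that any particular protein behaves like
the generator.

**Synthetic open/closed dimer.** `synthetic_open_closed_structure()`
builds a two-chain stand-in for an apo dimer crystallized with one
monomer closed and one open: the open chain carries a 25.0 Å groove
and a 3.8 Å ring–methyl gate contact, the closed chain 19.2 Å and
5.5 Å. It is labelled synthetic throughout: distances measured from it
validate the structure-reading and measurement path, not any deposited
crystal structure.

## Problem sizes and reproducibility

The validation suite uses 10⁴–2×10⁵-frame synthetic ensembles over
4–20 beads and 10⁶-sample histograms — sizes at which the tested
tolerances (3% on variances, 5% on spectra, 3 SE on the free-energy
gap, exact lag recovery) are comfortably powered while the whole suite
runs in about a minute. Every generator is a pure function of its
seed: the RNG state is saved and restored around sampling, identical
configs byte-reproduce every output table, and the pipeline manifest
records a config hash and package versions.

## Known limitations

* Eq-style displacement correlations are scalar (dot-product)
  correlations; fully anisotropic 3×3 covariance couplings are not
  resolved.
* The SPM usage score is the published node-size convention as best it
  can be pinned down; both the all-pairs accumulation and the single
  first-to-last path are reported because the published method does
  not fully specify which subset its maps draw.
* Significance of lagged couplings is a white-noise bound, not a
  block-bootstrap; for strongly autocorrelated series the bound is
  optimistic.
* Structure input assumes complete models: missing-loop repair is out
  of scope, and residues without a Cα are flagged rather than rebuilt.
* `±2σ` bands are reported alongside raw 2.5/97.5% quantiles because
  the band convention is misleading for the multimodal distributions
  this field routinely summarizes with it.
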