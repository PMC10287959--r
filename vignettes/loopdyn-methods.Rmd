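---
title: "Methods: ensemble analysis of RNA internal loops"
author: "loopdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble analysis of RNA internal loops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopdyn)
```

## The problem

RNA duplexes formed by G4C2 and G2C4 repeat expansions carry tandem
internal loops (2×2 GG/GG and 2×2 CC/CC) whose bases interconvert between
*syn* and *anti* glycosidic orientations. Characterising such an ensemble
from molecular dynamics output raises three coupled problems that this
package addresses as one pipeline:

1. assigning discrete conformational states from the glycosidic torsion χ;
2. clustering snapshots under the exact C2 strand-swap symmetry of a
   self-complementary duplex, where plain RMSD double-counts states; and
3. deciding whether the sampled populations have converged.

The package consumes single-temperature ensembles that have already been
extracted from an enhanced-sampling run; replica-exchange bookkeeping
itself is out of scope.

## States from the glycosidic torsion

χ is computed as the signed dihedral O4′–C1′–N9–C4 for purines and
O4′–C1′–N1–C2 for pyrimidines (IUPAC atom convention, one fixed set per
base type). A residue is *syn* (`"s"`) iff χ ∈ [−90°, +90°), otherwise
*anti* (`"a"`). The literature rarely states numeric windows; this
two-region convention with half-open boundaries is declared once so that
classification is total and deterministic, and no intermediate
("high-anti") class is used because the state vocabulary downstream is
binary.

A 2×N loop state is written `s₁/s₂` with each strand read 5′→3′. For a
self-complementary duplex the strand labels are arbitrary, so with
symmetry on, a label is identified with its strand-swapped reading and
the lexicographic minimum (with `"a" < "s"`) is reported. Consequently
`sa/as` and `as/sa` name the same canonical class; two *distinct
geometric basins* can share a canonical label (see the generator below),
which is why clustering operates on coordinates and uses labels only as
annotation.

## Symmetry-corrected clustering

The frame metric is the minimum over the registered symmetry
permutations of the proper-rotation (Kabsch) least-squares RMSD,
computed on one atom selection used for both superposition and
measurement — by default all heavy atoms of the loop residues, including
backbone and sugar atoms (the convention is a config choice; nothing
downstream assumes base-only atoms). Ties between permutations go to the
identity.

Two procedures are provided:

* **Greedy leader** (cutoff 1.0 Å, the method behind all reported
  populations). Frames are scanned in file order; a frame joins the
  existing cluster whose *founding frame* is within the cutoff (the
  lowest-RMSD one if several qualify) or founds a new cluster. Leader
  clustering admits several variants (running centroids, re-scanning,
  different tie-breaks); this package fixes first-frame representatives,
  lowest-RMSD assignment and an in-order scan as the declared algorithm
  because it is the simplest fully deterministic scheme — given frame
  order, which is file order, never shuffled, results are exact.
* **Average-linkage hierarchical** (cut at 1.2 Å) on the full
  symmetry-corrected distance matrix, with the dendrogram cut at a
  distance threshold rather than a cluster count (the method is
  naturally parameterised by an RMSD value, not a K), and the medoid as
  representative. The matrix is O(n²); a cap (default 20,000 frames)
  asks the user to stride rather than silently thrash.

Populations are cluster sizes over total frames (×100, summing to 100
before filtering); reports aggregate clusters under `min_pct` (default
1%) into an explicit `"other"` row so that conservation stays visible.
Both methods take the same `symmetry` switch, default on.

## Convergence diagnostics

**KLD.** The ensemble is split into two segments treated as independent
runs. A single PCA basis is fit on the *combined* trajectory: each frame
is RMS-fit to an average structure (two passes: fit to frame 1, average,
re-fit to the average, re-average) and the covariance of the fitted
Cartesian coordinates is diagonalised. Giving each segment its own basis
is the main design alternative; a common basis is chosen here because
per-segment bases make the two projection histograms incomparable, and
the choice lives in one place in the code. At each evaluation time both segments are
truncated to the same cumulative fraction, Gaussian-KDE histograms with
300 bins are built on one fixed grid spanning the union of the full data
ranges, normalised to unit mass, and

KLD(t) = Σᵢ P(t,i) ln(P(t,i)/Q(t,i))

is reported (P = first segment; the statistic is asymmetric by
definition and is not symmetrised). Two numerical choices are fixed
explicitly: the KDE bandwidth is Scott's rule,
h = sd(x)·n^(−1/5), recorded in the output; and ε = 10⁻¹⁰ is added to
every bin of both histograms before the log-ratio, with renormalisation,
so finite-sample empty bins cannot produce infinities — after this
regularisation both vectors are proper distributions on a common support
and Gibbs' inequality guarantees KLD ≥ 0, which the tests assert at
every computed point. The evaluation grid is 200 equispaced cumulative
fractions by default (per-frame evaluation is configurable but rarely
worth the cost).

**Population traces.** Per-cluster percentages inside a trailing window
after discarding a burn-in, both given in frames; a configuration layer
maps physical time (e.g. a 500 ns window, 10 μs burn-in) to frames when
a frame→time calibration exists. Synthetic data has no physical clock,
which is why the core API is frame-based.

## Free-energy landscapes

The 2D PMF over two reaction coordinates (normally PC1/PC2) is a plain
histogram Boltzmann inversion, F = −kT ln(N/N_max), on a 100×100 grid by
default; KDE smoothing is deliberately *not* applied here because the
smoothing convention above is defined for the 1D KLD histograms only.
Empty bins are masked; surfaces are stored in kT with
k_B = 0.0019872041 kcal/(mol·K) conversion as metadata. The minimum is 0
by construction, but note that anchoring at N_max carries a small
selection bias (the max of many noisy bins), so comparisons of profile
*shape* should anchor at a reference coordinate — the quadratic-well
test anchors the radial profile at r = 0 for exactly this reason.

Basins are local minima over the 8-neighbourhood, merged by persistence:
flooding bins in ascending F, a minimum whose depth below its lowest
connecting saddle is less than `depth_threshold` (default 0.5 kT,
suppressing shot-noise minima; there is no universal criterion for
"distinct") is absorbed into the deeper basin. Masked bins
are traversable at a level just above the highest occupied bin so that
occupied islands disconnected by unsampled regions can meet; a basin
that first meets another across such an unsampled saddle while holding
less than `min_share_pct` (default 1%, mirroring the cluster filter) of
the population is absorbed regardless of depth — a handful of outlier
frames cannot claim a distinct free-energy minimum. Basin populations
are catchment counts over total frames and may sum to slightly less
than 100% only through explicit masking.

## Hydrogen-bond classification of C/C mismatches

Geometric criteria: heavy-atom donor–acceptor distance ≤ 3.5 Å and,
when an explicit hydrogen is bonded to the donor (same residue, element
H, < 1.25 Å), ∠D–H···A ≥ 135°; topologies without hydrogens fall back to
the distance criterion alone. These are the common MD-analysis defaults;
they are parameters, not constants, and are echoed in the output. For a
C/C mismatch the candidate set is fixed to the cytosine Watson–Crick
face — N4 as donor, N3 and O2 as acceptors, no sugar or phosphate
donors — and the ensemble summary is the fraction of frames with 0, 1
and ≥2 inter-residue bonds, which sums to 1 exactly. The classifier
reports which donor–acceptor pairs occurred; it does not assert that one
pairing dominates.

## The synthetic generator

The generator exists to give every stage inputs with known ground truth;
it makes no claim of thermodynamic realism. `build_duplex()` places a
rigid ribose/phosphate fragment per residue on an A-form-like helix
(rise 2.81 Å, twist 32.7°) and rotates each base about its glycosidic
bond so the computed χ equals the target to machine precision
(construction inverse, tested at 10⁻⁶ degrees). The second strand is the
proper C2 image of the first, so a palindromic duplex with a
swap-symmetric χ pattern is *exactly* strand-swap symmetric — the
property the symmetry machinery is tested against. Geometry is
internally consistent (correct atom names, bond-scale distances, planar
bases) but idealized: sugar pucker, base pairing geometry and sterics
are not modelled, so passing tests demonstrate correctness of the
analysis code, not force-field realism, and real trajectories will show
broader intra-state spread than the isotropic Gaussian noise used here.

The default four-state template set for the GG/GG duplex uses χ targets
syn = +25°, anti = −160° (the centres of the conventional regions). The
minor `as/sa`-class state is the one subtlety: its letter pattern is the
exact strand-swap image of the major state's, so templates built from
identical χ values would be C2 images with symmetry-corrected RMSD 0 and
would merge into one cluster. Physically the two are distinct basins, so
the minor state is built at different within-region targets
(syn = −60°, anti = +130°), giving pairwise symmetry-corrected
inter-template separations of ~1.9–2.1 Å over loop heavy atoms — about
twice the 1.0 Å cutoff, which is what guarantees exact recovery at noise
σ = 0.15 Å (intra-state frame-to-representative distances ≈ 0.26 Å).

Unclustered "noise" frames are generated by large per-atom Gaussian
distortion (σ = 3 Å) of a template rather than by rigid displacement:
superposition removes rigid transforms exactly, so rigidly shifted
copies would be RMSD-0 duplicates of their template, whereas heavy
distortion guarantees mutual separations ≫ cutoff and hence singleton
clusters that fall under the 1% filter — structurally emulating the long
tail of rare conformations.

All stochastic draws (frame order, then per-frame noise in frame order)
come from one generator stream seeded by the mandatory `seed`, making
ensembles bit-reproducible.

## Problem sizes and numerical conventions

The validation suite runs at desk scale by design: the recovery
experiment uses 1,000 frames (425/358/40/34 state frames at the
reference population ratios plus 143 noise frames) and completes in
seconds; clustering oracles use ≤ 20 frames where brute-force
verification is exhaustive; KLD closed-form checks use 5×10⁴ samples per
segment (the Gaussian KL of N(0,1) vs N(1,1) is 0.5 nat; KDE smoothing
shrinks it by 1/(1+h²) ≈ 1.3%, well inside the tolerance); PMF checks
use 2×10⁵ samples. Internal residue indexing is 1-based contiguous (the
R convention) with author PDB numbering kept as metadata; coordinates
are always Å; times default to frame indices. Percentage sums are exact
to 10⁻⁹; torsion invariance under rigid transforms is tested at 10⁻⁹
degrees; eigenvector orthonormality at 10⁻⁸.

## Known limitations

Backbone torsions, sugar pucker and base-pair step parameters are not
computed; binary trajectory formats (DCD/XTC/NetCDF) and AMBER
topologies are not read; clustering is O(n²) in the hierarchical path;
the greedy scheme is order-dependent by design (determinism over
order-invariance); and the basin detector's masked-saddle rule means
genuinely distinct but barely-populated minima (< `min_share_pct`) in
unconnected regions are deliberately absorbed.
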