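---
title: "Quantifying how an ALPS motif filters vesicles by size and lipid packing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying how an ALPS motif filters vesicles by size and lipid packing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alpscan)
```

## The scientific problem

Amphipathic lipid-packing sensor (ALPS) motifs are 20–40 residue
stretches that are unfolded in solution and fold into an amphipathic
helix only on membranes whose interface is loosely packed — that is, on
highly curved or highly unsaturated bilayers. The golgin GMAP-210
carries such a motif at its N terminus and uses it to capture small
transport vesicles at the *cis* face of the Golgi. Dissecting this
behaviour quantitatively involves four kinds of computation, each a
module of this package:

1. **`helix_physchem`** — sequence physics of the motif itself:
   hydrophobic moment, helical-turn statistics, the sparse-versus-paired
   layout of hydrophobic residues, and the sequence surgeries (inversion,
   condensation, point mutations, truncations) used to perturb them.
2. **`synthetic_membranes` / `defect_scan`** — bead-model bilayers of
   flat, tubular and spherical geometry and a scanner that measures
   interfacial lipid-packing defects: their area distribution, the
   exponential decay constant $A_c$, and the curved/flat enrichment of
   defects large enough (> 20 Å$^2$) to accept a bulky hydrophobic side
   chain.
3. **`capture_quant`** — the calibration that turns a Golgi-region
   fluorescence signal into a captured-liposome count.
4. **`image_quant`** — mask-based image quantification conventions
   (marker masks, background-subtracted Golgi/cytosol ratios, Pearson
   colocalization) exercised on synthetic micrographs with known ground
   truth.

## Helix sequence physics

The hydrophobic moment places residue $j$ at angle $(j-1)\cdot 100°$
around an ideal $\alpha$-helix and computes

$$\mu_H = \frac{1}{N}\left|\sum_{j=1}^{N} h_j e^{i j \delta}\right|,
\qquad \delta = 100°,$$

with $h_j$ from the Fauchère–Pliska octanol/water scale (the Heliquest
convention; the scale is a pluggable argument). Reversing a sequence
conjugates the phasor sum and multiplies it by a unit phase, so $\mu_H$
and the mean hydrophobicity $\langle H\rangle$ are *exactly* preserved
under inversion — the computational content of the observation that an
inverted ALPS motif keeps its amphipathic character while sharing
almost no positional identity with the original. Note that a
homopolymer has $\mu_H = 0$ only when $N\delta$ is a multiple of 360°
(e.g. $N = 18$ or $36$): for other lengths the geometric phasor sum is
small but nonzero. Tests therefore pin the exact zero at full-wheel
lengths and rely on reversal invariance as the general property.

Helical turns are defined by the tiling rule: turn $k$ spans positions
$\lfloor 3.6(k-1)\rfloor + 1$ through $\lfloor 3.6 k\rfloor$ (last turn
clipped at $N$). This is a documented convention, not a claim about any
particular reference implementation; under it the native 38-residue
GMAP-210 ALPS motif (initiator methionine restored — the synthesized
peptide replaces M1 by C for 280 nm quantification) has 11 turns of
which 9 contain exactly one hydrophobic residue:

```{r}
partition_turns(alps_native())
count_single_hydrophobic_turns(alps_native())
```

The hydrophobic set is `{W, L, V, I, F, M}` — exactly the residues that
drive membrane insertion of the motif; alanine and cysteine are
excluded. The sparse/paired classifier reports the fraction of
hydrophobic residues with a sequence-adjacent hydrophobic neighbour;
the thresholds (sparse < 0.25 < mixed < 0.75 < paired) are package
conventions chosen to put the canonical patterns `LxxxLxxxL` (fraction
0) and `IFxxLFxxLF` (fraction 1) unambiguously at the extremes.

Condensation deletes polar positions so that every formerly sparse
hydrophobic residue gains an adjacent hydrophobic partner, refusing to
delete a hydrophobic residue. The shipped 14-position deletion set
turns the 38-aa ALPS peptide into the 24-aa condALPS peptide exactly:

```{r}
as.character(condense(alps_peptide(), alps_condensation_deletions()))
```

Positional identity is strictly position-by-position with no alignment.
For ALPS against its own inversion this gives 4 matches over 38
positions (identity ≈ 0.105). Published descriptions of the same
comparison quote "30 mutations over 38 positions" and "≈ 25% identity"
without defining the comparison (possibly counting conservative
matches); we report the strict count and deliberately do not force
agreement.

`Ins20AA` is interpreted as inserting `AA` after position 20 (the
middle of the 38-residue sequence); it is expressed as an explicit edit
string, not hard-coded. Substitution edits carry the wild-type letter
(`L12D`) and are rejected on mismatch, which guards 1-based
bookkeeping. Every edit is logged with enough material to be undone;
`invert_edit_log()` round-trips any edit list.

## Bead-model membranes

Each lipid contributes one *polar* occlusion disc at the interfacial
surface plus two aliphatic beads stacked beneath it (one for sterols).
The default disc radius is 6.0 Å for phospholipids and 4.5 Å for
cholesterol, interpreted as the in-plane footprint of the stacked
headgroup + glycerol + upper-chain beads. The value is a generator
calibration: it is chosen so that a defect-free flat bilayer at
70 Å$^2$ per lipid is almost fully covered — as real flat bilayers are,
where interfacial voids occupy a few percent of the area — so that
defects arise from thermal jitter, composition and curvature rather
than from trivial undercoverage. With substantially smaller discs the
uncovered area percolates into one system-spanning void and component
counting loses meaning.

Lattice-plus-jitter placement replaces molecular dynamics: the package
validates the defect *analysis*, not a force field. Gaussian in-plane
jitter (default $\sigma = 1.5$ Å) emulates thermal disorder. All
stochastic operations take an explicit integer seed and scope it with
`withr::with_seed`; no global RNG state is touched.

The built-in `copi_composition()` encodes the COPI-vesicle-like
*cis*-Golgi mixture: 60 mol% PC, 30 mol% PE, 10 mol% cholesterol, with
PC/PE chains split 6% di-saturated (16:0–16:0), 59% mixed (16:0–18:1)
and 35% di-monounsaturated (18:1–18:1). In the current generator the
species differ only through their occlusion radii (sterol versus
phospholipid); the chain profile is carried as metadata so that
chain-specific occlusion models can be layered on without changing the
interfaces.

**Leaflet counts on curved geometries.** A vesicle of mid-bilayer
radius $R$ has leaflet surfaces at $R \pm h$ ($h$ = half-thickness,
default 20 Å; bilayer thickness 40 Å). Two conventions are exposed:

* `leaflet_mode = "midplane"` (default): both leaflets get
  $4\pi R^2/a$ lipids — the equal-radius approximation used in the
  liposome arithmetic ($R = 30$ nm, $s = 0.7$ nm$^2$ gives
  $2\cdot 4\pi R^2/s \approx 3.2\times 10^4$ lipids). Because those
  lipids sit on the *larger* outer surface, the outer leaflet is
  geometrically dilated by $(R/(R+h))^2$ — which is precisely the
  packing stress that makes highly curved membranes defect-rich, so
  this mode is also the generator's physical model of curvature.
* `leaflet_mode = "interfacial"`: counts proportional to the true
  leaflet areas $4\pi(R\pm h)^2/a$; use this for strict area
  bookkeeping (e.g. the outer:inner count ratio equals
  $(R_{out}/R_{in})^2$ exactly).

The area per lipid (70 Å$^2$) and bilayer thickness (40 Å) are exposed
configuration with documented defaults, not asserted literature values
for any particular simulated system.

**Ground-truth voids.** `implant_voids()` removes every polar bead
whose occlusion disc intersects a void footprint. The carved hole
therefore exceeds the footprint by up to the bead-lattice granularity:
beads within `cover_radius` of the footprint edge are removed, and the
surviving beads cover back to the edge only in the dense-lattice limit.
Scanner-validation fixtures consequently use dense lattices (1.5–2 Å
spacing) and void separations larger than
`2 * (void radius + cover_radius)` so that no bead-free corridor
connects two voids.

## Defect scanning

The scanner rasterizes one leaflet surface into cells of ~1 Å (default)
and marks a cell *covered* iff at least one polar occlusion disc
reaches the cell centre — by periodic in-plane distance on flat
patches, by unrolled-plane distance on tubules (which is the exact
geodesic), and by great-circle distance on vesicles. Aliphatic beads
never cover: the package deliberately implements a single geometric
coverage rule rather than a deep/shallow chemical taxonomy, so absolute
$A_c$ values are tied to this rule while ratios and orderings between
geometries are the validated surface.

Spheres are handled by a cube-sphere atlas: six gnomonic faces with
per-cell spherical area weights $R^2\,du\,dv/(1+u^2+v^2)^{3/2}$
(midpoint rule; total area within well under 1% of $4\pi R^2$ at 1 Å
cells) and cross-face adjacency computed geometrically by stepping over
a face edge and relocating the stepped point. Because coverage is
decided by true geodesic distance, the projection only rasterizes — it
never distorts the coverage rule; a lat-long grid was avoided because
its polar cells degenerate. Defect *areas* are sums of member-cell
weights, so area bookkeeping is exact under the atlas.

Connected components of uncovered cells (4-connectivity by default;
8-connectivity available on planar/cylindrical grids) are found by a
vectorized minimum-label propagation with pointer doubling, which
handles periodic wrap and cross-face adjacency uniformly; the test
suite checks it cell-for-cell against an exhaustive flood-fill oracle.
4-connectivity is the default because corner-sharing contact would
chain distinct voids through single points.

Defect-area histograms use 5 Å$^2$ bins from zero and are normalized to
defects per $10^4$ Å$^2$ of scanned leaflet area per frame, making
curved/flat comparisons size-independent. (Whether published
distributions normalize per frame, per leaflet or per area is generally
not stated; the normalization used here is recorded in the object.) The
decay constant of the abundance law $e^{-A/A_c}$ is fitted by weighted
least squares of $\log(\mathrm{count})$ on bin mid-area with Poisson
(count) weights over a 15–100 Å$^2$ window, requiring at least 4 bins
with ≥ 5 counts — below ~15 Å$^2$ the histogram is raster-dominated,
above ~100 Å$^2$ tail-sparse. Degenerate inputs return an explicit
`"unfittable"` status, never a silent number. Because the binned
exponential is exactly log-linear in the bin edge, the estimator is
unbiased up to sampling noise; parameter-recovery tests require the
fitted $A_c$ within 10% of truth at $5\times 10^4$ samples for
$A_c \in \{5, 10, 15, 25\}$ Å$^2$.

The large-defect density counts components with area strictly above
20 Å$^2$ — the area needed to accommodate a bulky ALPS hydrophobic
residue — per $10^4$ Å$^2$, and `enrichment_ratio()` compares a curved
against a flat membrane at matched threshold and normalization,
flagging an infinite ratio when the flat density is zero.

**Study conditions for the curvature-ordering check.** The suite
compares flat (1000 lipids per leaflet), tubule ($R = 150$ Å,
$L = 300$ Å) and vesicle ($R = 150$ Å) at the COPI composition,
70 Å$^2$ per lipid, 1.5 Å jitter, 1 Å cells and the 20 Å$^2$ threshold.
These sizes keep a full three-geometry comparison within seconds to
minutes on one core while leaving hundreds of defects per surface; at
these conditions the large-defect density orders vesicle ≥ tubule ≥
flat with vesicle/flat ratios around 3–4 and tubule/flat around 1.5–2.
The *quantitative* enrichment of full coarse-grained MD trajectories
(tubules 2–3×, vesicles 3–5×) requires hours of many-core simulation
and is out of scope here: the scanner consumes such trajectories via
the GRO/PDB interface when they exist, and its correctness is covered
by the oracle, recovery and ordering tests.

What the generator does *not* emulate: force-field energetics, lipid
flip-flop, chain-resolved occlusion differences, deep versus shallow
defect chemistry, or temporal correlation between frames. Passing tests
therefore validate the measurement pipeline — rasterization, component
labeling, normalization, fitting — not any force field.

## Fluorescence calibration

The captured-liposome count chains four printed scalars: fluorescence
to concentration ($C = F/k$, $k \approx 100$ FU·µM$^{-1}$), lipids in
the Golgi region ($C V N_{av}$, $V = 3\times 10^{-13}$ L), and lipids
per liposome ($2\cdot 4\pi R^2/s$, both leaflets at equal radius,
$s \approx 0.7$ nm$^2$, $R = 30$ nm). The printed result (120–300
liposomes for 2000–5000 FU) depends on rounding the intermediates as
printed — the lipid count to two significant figures
($3.6\times 10^6$, $9\times 10^6$) and the per-liposome count to one
($3\times 10^4$) — so the rounding mode is an explicit argument:
`rounding = "paper"` reproduces that arithmetic, `rounding = "exact"`
keeps full precision (≈112 and ≈280); the two agree within 10%.

```{r}
captured_liposome_count(2000)
```

$V$ is an order-of-magnitude estimate of the Golgi region
(10 × 10 × 3 µm$^3$); every count object carries a provenance note
saying the result inherits that uncertainty. An optional
`bilayer_thickness` refinement counts the inner leaflet at its true
radius; it is off by default to match the equal-radius formula.
Nominal extrusion pore sizes (200/100/50/30 nm) are metadata only — all
geometry uses the measured hydrodynamic radius.

## Image quantification

`make_cell_image()` generates a three-channel synthetic micrograph —
Golgi marker, punctate liposome signal, and a diffuse construct channel
with a planted Golgi/cytosol enrichment $\rho$ — over elliptical cell
and Golgi regions, with uniform background plus optional Gaussian and
Poisson noise, all ground truth recorded. It emulates single-Z-plane
images only; real acquisitions mix Z planes and projections, so
recovery results here bound only the quantification conventions, not
acquisition physics.

The conventions mirror mask-based practice: the organelle mask comes
from the marker channel (Otsu via EBImage, or a fixed threshold) and is
applied to the signal channel; the Golgi/cytosol ratio subtracts the
mean of a declared background ROI (never a global minimum) from two
equal-area ROIs and takes the quotient, clamping negative numerators or
denominators to zero with a flag and reporting an `"undefined"` status
when the cytosol mean equals the background. ROIs are explicit pixel
sets (`roi_rect()` or any logical mask) because manual ROI placement is
not reproducible. Pearson colocalization is the standard correlation
over in-mask pixels; whether to use whole frames or a cell mask is an
exposed choice, recorded by the caller. The recovery test plants
$\rho \in \{1, 2, 5, 10\}$ at the default noise level and requires the
estimate within 10%; Pearson limits (+1, −1, ≈0) are pinned on
constructed channel pairs. A published Pearson value on real
micrographs (~0.75 between two ALPS-construct channels) is not a
recovery target: raw images are not available, and the synthetic
generator makes no claim to emulate them.

## Known limitations

* Absolute $A_c$ values depend on the documented coverage rule and
  occlusion radii; only orderings and ratios across geometries at fixed
  settings should be compared with other implementations.
* The mid-plane leaflet convention dilutes the outer leaflet on curved
  geometries by construction; with `leaflet_mode = "interfacial"` the
  generator produces curvature-neutral densities, which is the correct
  null for scanner-validation fixtures but removes the curvature
  signal.
* GRO files carry no leaflet field; leaflet labels on read are
  reconstructed geometrically (side of the mid-plane, or radial
  distance), which is exact for alpscan-written files and reasonable
  for externally generated bilayers without extreme undulations.
* The synthetic image generator does not model the point-spread
  function, photobleaching or detector offsets beyond a uniform
  background.
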