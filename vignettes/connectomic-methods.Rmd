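---
title: "Quantifying inhibitory input to the AII amacrine cell from annotated EM skeletons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying inhibitory input to the AII amacrine cell from annotated EM skeletons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retconn)
```

## The problem

In serial block-face EM (SBEM) volumes of retina, neurons are reconstructed
by hand as *skeletons*: trees of nodes traced through the image stack, with
chemical synapses marked as node annotations. A recurring analysis pattern
in this field is to start from a small set of fully annotated target cells —
here, AII amacrine cells, the hub interneuron of the rod bipolar (RB)
pathway — and quantify their synaptic partners: who contacts them, where on
the cell, at what laminar depth, and with what spatial relationship to other
inputs. `retconn` packages that accounting as a reusable, tested pipeline:

1. **skeleton I/O** — read/write Knossos-style NML, with validation;
2. **geometry** — fit the ON and OFF starburst amacrine cell (SAC/ChAT)
   dendritic planes, tilt-correct the volume, and express positions as
   normalized IPL depth;
3. **connectome** — pair pre- and postsynaptic annotation marks into typed
   synapse records and tally them per cell, partner type, and compartment;
4. **spatial statistics** — nearest-neighbour synapse distances,
   stratification-depth profiles, and a depth-based ON cone bipolar (CB)
   subtype classifier;
5. **synthetic data** — a seeded generator with ground truth, so every stage
   is testable without any image data.

## Annotation grammar

Tracing tools store synapse marks as free-text node comments and published
datasets do not share a single convention. The package adopts one explicit
grammar, `syn:<kind>:<dir>:<ptype>[:<pid>]` with `kind ∈ {ribbon, conv}`,
`dir ∈ {in, out}`, a partner type from the closed vocabulary `cell_types()`,
and an optional partner skeleton id. The regex is pluggable
(`parse_annotation(pattern =)`) so other dialects can be mapped onto the same
records. Comments that do not match are preserved verbatim and itemized in
the parse log — the parser never drops information silently. A bare `soma`
comment declares the soma node.

## Depth normalization

Laminar position in the inner plexiform layer (IPL) is only comparable
across volumes after normalizing to anatomical landmarks. The two SAC
plexuses form near-parallel planes and are the landmarks this package uses:
each is fitted by total least squares (the plane normal is the direction of
smallest variance of the node cloud), and normalized depth is the signed
distance to the OFF plane divided by the inter-plane separation, mapped so
the OFF plane is depth 0 and the ON plane depth 1, increasing toward the
ganglion cell layer (GCL). Three numerical choices matter:

* **Orientation is declared, never guessed.** The frame requires an
  `orientation_ref` point on the GCL side; a reference inconsistent with the
  plane labels is an error rather than a silent sign flip.
* **Non-parallel planes.** Fitted normals rarely agree exactly. Separation
  is measured along the mean normal through the axis line at the
  orientation reference — an anchor that moves rigidly with the volume —
  which makes normalized depth exactly invariant under the tilt correction
  (the package asserts 1e-6). Normal disagreement beyond 5° warns and beyond
  15° errors.
* **Tilt correction** is one global rigid rotation about the volume centroid
  mapping the mean SAC normal to the z axis. Per-slab or nonrigid models are
  deliberately out of scope; the landmark model is a pair of flat planes.

Depths are dimensionless SAC units by default (`depth_at_off = 0`,
`depth_at_on = 1`). Percent-IPL conventions can be obtained by supplying
different anchor depths when the INL/GCL boundaries are known; SAC units are
the default because the SAC tracings are the landmark the data guarantees.

## From marks to synapses

An annotated synapse appears twice — an `out` mark on the presynaptic cell
and an `in` mark on the postsynaptic cell. `build_synapse_table()` pairs
them in two passes: first by declared partner ids (closest first when a pair
of cells shares several synapses), then by proximity — same kind, different
cells, within ε = 500 nm, greedily by ascending distance, each mark used at
most once. ε reflects EM synapse geometry (apposed membranes are tens of nm
apart; 500 nm tolerates annotation placement slack while staying below
typical inter-synapse spacing) and is configurable. Marks left unpaired
become one-sided records that still count in tallies, because expert
single-observer marks are evidence of a synapse even when the partner was
not traced; a `strict` mode restricts tallies to two-sided records. Ribbon
records whose presynaptic cell is not a bipolar type are flagged, not
dropped.

Compartments follow the conventions of AII input tables: `soma` within a
5 µm geodesic radius of the declared soma node, `distal_dendrite` at or
vitreal to the ON SAC plane (depth ≥ 0.9, i.e. a 0.1 slack below the plane),
otherwise `proximal_dendrite`. Tally percentages are rounded half-up to one
decimal, dropping a trailing `.0` for display; sub-rows splitting the AC
input by compartment are percentages of the AC total, matching the published
table layout. Convergence reports two means — total synapses divided by the
number of presynaptic skeletons (the "~130 synapses / 61 axons ≈ 2"
convention) and divided by the number of connected pairs — because the two
answer different questions.

Rod bipolar dyads are recovered by single-linkage clustering of ribbon
records sharing a presynaptic cell at a 300 nm radius (a ribbon's two
postsynaptic densities flank one release site; 300 nm comfortably covers a
ribbon's span and stays far below inter-ribbon spacing). Sites with more
than two partners are flagged as triads and excluded from composition
percentages.

## Spatial statistics

Nearest-neighbour distances between conventional (AC) inputs and ribbon
inputs on the same postsynaptic cell are the package's measure of how
closely inhibition tracks excitation. Both a Euclidean and an along-arbor
(geodesic) metric are implemented; Euclidean is the default and the one used
in acceptance checks, since the published figure does not state its metric —
the geodesic result can be reported alongside and is always an upper bound
on the chord. The empirical CDF is right-continuous with a closed boundary
(`fraction_within(r)` counts distances ≤ r) and the median at even n is the
lower middle order statistic; both conventions are fixed and tested.
Histogram bin width is a display parameter only: all acceptance statistics
are bin-free (median, fraction-within).

Stratification profiles apportion each edge's cable length over half-open
depth bins by linear interpolation of its endpoint depths, so total profile
mass equals cable length exactly. The ON-CB subtype classifier is a
rule-based decision on the profile: peak-density depth relative to the ON
SAC plane and the fraction of cable at inner-IPL depths, with shipped
windows placing type 5 at/just sclerad to the plane (peak in [0.80, 1.05)),
type 6 just vitreal ([1.05, 1.35)), and types 7/8 progressively deeper.
These windows are *configuration defaults mirroring the cited stratification
scheme*, not anatomical claims; every decision reports the rule that fired,
and the classifier's acceptance surface is recovery of synthetic templates,
not any real cell's label.

## The synthetic world

`generate_connectome()` emits a stylized volume whose defaults are the
stated conditions of the accounting it emulates: 3 AII cells, 61 presynaptic
axons pooling 1425 output synapses in mixture 85/12/2/1 %
(AII/RB/ON-CB/unidentified), a mean of 173 ribbon inputs per AII (SD 3), 17
soma-basket inputs per AII, 100 RB dyads containing the focal AC in mixture
75/18/7 %, SAC planes tilted 5° against the voxel grid with 50 nm node
scatter, and conventional AC inputs placed at an exponential arc-length
offset from a ribbon with scale 2.3/ln 2 µm — the distribution whose median
is the published 2.3 µm. Quota allocation realizes mixtures exactly by
largest-remainder rounding (ties by listed order); multinomial allocation
draws them. Generation is fully deterministic per seed, down to the NML
bytes.

The geometry is deliberately stylized — radial distal branches at a fixed
tuft depth, stick-figure partner cells, annotation marks offset 150 nm
across the synaptic cleft — which is sufficient for everything under test:
plane fitting, tilt recovery, pairing, tallies, dyads, NN statistics,
profiles. It does **not** emulate real morphology, tracing errors, boundary
truncation, observer disagreement, or depth-dependent synapse density, so a
green synthetic test establishes the correctness of the *computation*, not
the biology. Ribbon sites are spaced 20 µm along branches so that the
distance from an AC input to its *assigned* ribbon is, with ≥ 95 %
probability, also its distance to the *nearest* ribbon; the residual
truncation is far below the bootstrap error of the median. The
`perturb()` harness adds jitter and annotation dropout for robustness
sweeps.

One published measurement — the 2.3 µm median itself — can only be verified
on the original supplementary tracings, which require a download and are
not redistributed here. The acceptance report therefore computes it on the
generator's stated world and labels it a synthetic stand-in; the
corresponding qualitative claim (zero AC input between the SAC planes) is
asserted on generator output.

## Known limitations

* Planes only: curved or locally warped laminae are not modelled.
* Cell types come from annotations or skeleton names; no morphology-based
  type inference beyond the ON-CB depth classifier.
* The published AII input table contains an internal inconsistency (one
  cell's ON-layer percentage does not match its own counts) and the
  presynaptic-cell table has a one-count total mismatch; the affected
  percentages are excluded from acceptance checks, which otherwise
  reproduce every printed count, percentage, and mean ± SD exactly.
* One-sided records count in default tallies; use `strict = TRUE` for
  two-sided-only accounting.

## A worked example

```{r example, eval = FALSE}
gen <- generate_connectome(synth_params(seed = 1))
res <- run_pipeline(gen$forest,
                    orientation_ref = gen$truth$orientation_ref_nm,
                    types = gen$truth$types)
res$output_tally          # pooled axon outputs: 85/12/2/1 % recovered exactly
nn_median(res$nn)         # ~2.3 um
dyad_composition(gen$truth$rb_ids, res$synapses)$percent  # 75/18/7
```
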