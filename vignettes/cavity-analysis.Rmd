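---
title: "Voids and channels from the Voronoi diagram of atoms: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voids and channels from the Voronoi diagram of atoms: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vorocav)
```

## The model

A molecule is a set of spherical atoms $a_i = (c_i, r_i)$ with van der
Waals radii. A spherical solvent probe of radius $\delta \ge 0$ defines the
*offset model* $A^O$ (all radii grown by $\delta$), whose boundary is the
Lee--Richards solvent accessible surface; $\delta = 0$ gives the van der
Waals surface. Cavities are features of the space the probe can occupy:

* a **void** is a bounded component of the probe-accessible space, not
  connected to the bulk solvent;
* a **channel** is a passage through the molecular body with two or more
  openings the probe can pass through;
* a **pocket** has exactly one opening; it is computed but reported apart
  from channels.

Everything is driven by the *additively weighted Voronoi diagram*: space is
partitioned by the distance-to-surface $d(x, c_i) - r_i$ (the *clearance*
of $x$ is the minimum of this over atoms). This diagram is different from
both the ordinary point Voronoi diagram and the power diagram, and it is
*offset invariant*: growing every radius by the same $\delta$ leaves
vertices, edges, faces and their incidences unchanged, which is why one
diagram serves every probe radius and why the quasi-triangulation can be
cached (the QTF file) across analyses.

## Computing the diagram

At the package's target scale (tens of atoms; the hard guard is
`max_atoms = 120`) the diagram is built by enumeration rather than by a
spatial-grid candidate search, which only pays off at much larger sizes:

1. **Vertices.** Every atom quadruple is passed through a vectorized
   Apollonius solver: subtracting tangency equations linearizes the system,
   $x = a + \rho b$, and back-substitution leaves a quadratic in $\rho$, so
   a quadruple carries 0, 1 or 2 tangent spheres. Closed-form roots are
   Newton-polished when the residual exceeds the $10^{-9}$ relative
   tolerance and accepted as Voronoi vertices when the tangent sphere is
   empty (no atom's weighted distance below $\rho$, slack $10^{-7}$).
   Cospherical degeneracies -- a symmetric cage has many quadruples sharing
   one tangent sphere -- are resolved by merging coincident spheres (within
   $10^{-6}$ Å) into a single degenerate vertex carrying the union of
   defining atoms. This replaces symbolic perturbation: geometry stays
   exact, combinatorial decisions are deterministic, and the symmetric
   fixtures reproduce bit-identically.
2. **Edges.** The equidistant curve of an atom triple is a conic in a plane
   whose first coordinate is the clearance $\rho$ itself: solving the two
   linearized tangency differences gives $x = a + \rho b + s u$, and the
   remaining tangency is a quadratic $C(\rho, s) = 0$ with unit $s^2$
   coefficient. Components are classified by the discriminant (closed
   loops, folds, monotone branches) and parametrized so that $\rho(t)$ is
   closed form -- minimum clearance along an edge and probe clip points are
   solved, never searched. The curve splits at the vertices lying on it;
   an arc is a Voronoi edge iff the triple is nearest there, a predicate
   that can only change at a vertex, so testing three interior samples per
   arc decides it. Vertex-free closed-loop edges fall out of the same
   per-triple scan.
3. **Faces and cells.** A pair's bisector is a face when its closest
   point to the pair is empty or when some edge carries the pair. Pairs
   whose closest bisector point merely ties with a third atom (degenerate
   point-contact faces of symmetric cages) are flagged and excluded from
   area-carrying roles. Unbounded entities are kept symbolically and
   clipped only for sampling, at the molecule bounding sphere + maximum
   radius + 10 Å. Entity *inclusion* uses a radius that depends on radii
   only through max − min, so the retained combinatorics are offset
   invariant, as the theory requires.

## From diagram to cavities

The **Voronoi complement** retains the portions of vertices, edges and
faces with clearance $> \delta$; it is homotopy equivalent to the
probe-accessible exterior. Edge portions are exact (clearance is a
parameter coordinate). Face portions are resolved on a per-face grid in
(off-axis distance $h$, azimuth $\varphi$) coordinates of the bisector
sheet, where clearance depends on $h$ alone through a closed form; the
default grid is 48 radial × 60 azimuthal cells, with the radial range
ending just past the largest vertex clearance (a bounded component's
maximum clearance is always attained at a Voronoi vertex, so anything
reaching the last ring belongs to the exterior). Connectivity glues edge
portions to their end vertices, edges to the face portions they bound, and
every unbounded portion to a single point at infinity. Components are then
classified: the one touching infinity is the exterior; every other
component is a void -- except that a bounded "component" consisting solely
of face-grid cells (no vertex, no edge portion) is a tolerance sliver and
is discarded, since a genuine void holds its maximal inscribed probe ball
centered on a vertex (or, for symmetric toroidal voids, a closed edge).

**Channels.** Following the trimming rule for the unbounded component,
entities intersecting the offset surface are removed entirely and the rest
contracts to the Voronoi graph (faces contribute cycle-killing relations
only when their full boundary survives as a closed cycle; faces glued
along a path are flaps and collapse freely). The delimiting solid is the
**envelope**: the convex hull of the offset model, realized through ~4000
support directions (an outer approximation; boundary positions are
accurate to about 0.01--0.02 Å at fixture scale, far below the opening
merge radius). The beta-shape at $\beta = \delta$ was the first candidate
for this role, but it is degenerate -- measure zero, with no interior --
precisely for thin ring-like structures whose through-holes are the
clearest channels (an 8-atom ring's beta-complex at 1.4 Å is a
1-complex), so the envelope is used instead and the choice is recorded
here. Consequences worth knowing: a probe-permeable cage (walls the probe
passes through) still has envelope-interior graph and is reported as a
multi-opening channel system rather than suppressed; shallow surface
grooves are removed with the crossing entities and do not produce spurious
channels.

Interior subgraphs are the connected parts of the graph inside the
envelope; subgraphs are merged when they touch the same retained face
portion (the face interior connects them even when the 1-skeleton misses
it, as in braided near-degenerate bundles) or when their envelope
crossings coincide within the opening merge radius
$\max(2\delta, 0.01)$ Å -- two crossings closer than a probe diameter are
one mouth. A subgraph with $\ge 2$ openings is a channel; with one, a
pocket.

Per channel:

* **openings**: clustered envelope crossings (position and clearance);
* **handles**: the number of geometrically substantial independent cycles.
  Each non-tree edge of the interior subgraph closes a fundamental cycle;
  a cycle whose nodes all lie within 0.05 Å of their best-fit line is a
  braid artifact of near-degenerate geometry (its bounding face slivers
  are below grid resolution) and is not counted. Real handles enclose
  area and escape every line.
* **spine**: the union of maximum-bottleneck (widest) paths between
  opening pairs, found on the maximum spanning tree of the interior
  subgraph; each sample carries its exact sweep radius (distance to the
  nearest atom surface).
* **bottleneck**: the minimum clearance along the spine, with its attained
  position; ties break toward the lexicographically smallest position.

The jittered ring fixture reproduces the closed forms: bottleneck
$R - r$ at the ring center, two openings on the axis, no handles.

## Measurement

**Union of balls.** When no three balls share volume and no two caps
overlap on any sphere, volume and area are exact (lens and cap closed
forms; tagged `analytic`, error bound $10^{-6}$ relative). Otherwise exact
radial ray casting over Voronoi cells is used: cells partition space, and
within its own cell an atom is nearest, so the union is the disjoint union
of (cell ∩ ball) pieces; along a ray from $c_i$ the cell exit parameter
past each neighbor's bisector is closed form, and a deterministic
Fibonacci-sphere quadrature (default 40 000 directions per atom)
integrates the radial terms. The reported error is the observed change
under 4× quadrature refinement (tag `adaptive`).

**Void metrics.** The void region is measured the same way, restricted to
its component: along a ray from a contributing atom, clearance grows
monotonically inside the cell, so the accessible interval is
$(r_i + \delta,\ t_{\text{exit}})$, and the exit face portion's component
label (from the trimmed complement's face grids) decides membership.
Boundary area is the matching solid angle on the offset spheres -- by
construction those points lie on the Lee--Richards surface -- and the
"buried area" is the same solid angle on the van der Waals spheres. That
reading of buried area is an interpretation, flagged as such in the
documentation. The independent cross-check is a seeded hit-or-miss
Monte-Carlo estimator (`mc_region_volume`); the test-suite's ground truth
for void *counts* is a 0.05 Å flood fill with 26-connectivity, written in
C++ and never used by the production path.

**Channel metrics.** Channel volume is the volume of the radius-varying
ball swept along the spine (the standard channel visualization), estimated
by seeded Monte-Carlo; areas count the offset/vdW surface patches facing
the swept region. Delimiting a channel's volume exactly at its openings is
a convention, and this one is stated rather than hidden.

## The fixture generator

`make_fixture()` provides the study conditions used throughout the tests,
each with closed-form geometry: `tetra_cage` (central tangent radius
$\sqrt6/2 - 1$), `octa_cage` (center clearance $d - r$, escape bottleneck
$2\sqrt6/3 - 1 \approx 0.633$ for the defaults, so the probe sweep
0.5 → 0.8 crosses the void transition), `ring` (through-hole bottleneck
$R - r$; positional jitter 10⁻⁴ Å, seeded, breaks the exact cocircular
degeneracy), `chain` (encloses nothing), and `random_blob` (30 atoms by
default, radii uniform in 1.2--1.9 Å, centers in a 3.5 Å ball with 0.8 Å
minimum separation -- dense enough that voids appear for solvent-scale
probes). These emulate packing and cavity topology, not chemistry: no
bonding geometry, no element composition, no conformational flexibility.
Passing tests therefore certify the geometry engine, not force-field
realism; real structures enter through `read_pdb()` with a Bondi-style
radius table (C 1.70, N 1.55, O 1.52, S 1.80, H 1.20, P 1.80 Å,
overridable by file), waters excluded by default, altLoc B+ dropped,
hydrogens kept if present, no protonation.

## Problem sizes and tolerances

The quadruple enumeration is quartic and the per-triple scan cubic in atom
count; the package targets desk-scale structures (fixtures of 4--30 atoms;
the test-suite's largest runs are 20 seeded 30-atom blobs against the
flood-fill oracle) and refuses more than 120 atoms rather than silently
crawling. Key tolerances: algebraic solves $10^{-9}$ relative, acceptance
residual $10^{-6}$, empty-sphere slack $10^{-7}$, vertex merge $10^{-6}$ Å,
near-critical probe warning at $10^{-6}$ Å. Classification is inherently
unstable when $\delta$ sits within grid resolution of a passage bottleneck;
the test suite excludes comparisons where the void count changes within
±0.02 Å of $\delta$ or the oracle changes under grid refinement.

## Known limitations

* The exterior component's *global* cycle rank can overcount on
  near-degenerate inputs: sliver faces thinner than the face-grid
  resolution contribute no cycle-killing relations. Per-cavity handle
  counts use the thin-cycle filter above and are robust on the fixtures.
* Face-portion connectivity is grid-based (48 × 60 per face); necks
  narrower than the grid can break a face portion in two. Components are
  glued through edges and vertices as well, which covers the generic case.
* The envelope-based channel criterion reports geometric passages of
  probe-permeable shells and tiny hull-grazing subgraphs as channels or
  pockets; callers interested only in biologically meaningful channels
  should filter by bottleneck radius or volume.
* The QTF cache stores atoms, combinatorics and per-simplex thresholds;
  downstream cavity geometry is recomputed deterministically from the atom
  section, so cached and uncached runs give identical reports, and the
  cache accelerates only the dual-construction stage.
* One probe radius per run; no trajectories, no user-seeded channel
  search, no mmCIF, first NMR model only.
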