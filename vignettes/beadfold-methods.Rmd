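---
title: "Bayesian 3D genome reconstruction from single-cell Hi-C: model and methods"
author: "beadfold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian 3D genome reconstruction from single-cell Hi-C: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beadfold)
```

## The inference problem

A single-cell Hi-C experiment reports, for one nucleus, a sparse list of
locus pairs that were cross-linked and ligated — typically well under one
read per 10-kb bin genome-wide. `beadfold` treats structure determination
as Bayesian inference: each chromosome is a chain of contiguous beads of
diameter $a$ (the unit length throughout), and we seek coordinates
$\mathbf{R}$ maximising the posterior $P(\mathbf{R} \mid \mathbf{C})$
given the binned contact counts $\mathbf{C}$.

Three ingredients define the posterior, all written as a potential energy
$E(\mathbf{R}) = -\ln P + \text{const}$:

**Backbone.** Adjacent beads of the same chromosome are tied by a harmonic
bond $\varepsilon_{\mathrm{phys}}(r) = \tfrac{k}{2}(r-a)^2$ with
$k = 100/a^2$. Beads at the ends of different chromosomes are never bonded.

**Contacted pairs** ($c_{ij} \neq 0$). A detected contact means the pair
was within the contact threshold $r_0 = 2a$. The likelihood of observing
$c$ contacts falls off as $((r_0-r)/(r_0+r))^{c/2}$ inside $r_0$ and
vanishes beyond it; with the uninformative $r^2$ volume prior this gives

$$\varepsilon_{\mathrm{cont}}(r, c) = -2\ln r -
  \frac{c}{2}\ln\frac{r_0-r}{r_0+r}, \qquad r < 0.995\,r_0 .$$

This diverges to $+\infty$ at $r_0$, which would make the very first
descent steps from a random (far-flung) start ill-defined, so beyond the
anchor $0.995\,r_0$ the energy is continued by its first-order Taylor
expansion — a straight line with the anchor's slope. Value and slope are
continuous at the anchor (tested to $10^{-6}$), and the restraint then
pulls any separated contacted pair inward with a constant force. Note the
sign of the $c/2$ term: the energy must *rise* toward $r_0$ so that
contacted pairs are attracted inside the threshold; this is exactly
$-\ln$ of the posterior stated above. Setting
$\mathrm{d}\varepsilon/\mathrm{d}r = 0$ gives the closed-form optimum
$r^*(c) = r_0(-c+\sqrt{c^2+16})/4$, decreasing in $c$ — pairs with more
reads are held tighter; for $c = 1$, $r^* \approx 1.5616\,a$.

**Non-contacted pairs** ($c_{ij} = 0$). Absence of a contact is weak
evidence of separation — the pair may simply have escaped detection — so
the no-contact likelihood is a gentle sigmoid raised to the small power
0.075 (an arbitrary flattening constant inherited with the model),
giving

$$\varepsilon_{\mathrm{cont}}(r, 0) = -2\ln r +
  0.075 \ln\!\left(1+e^{-4(r-r_0)}\right),$$

a strictly decreasing (repulsive) profile. Because almost all of the
$O(N^2)$ bead pairs carry $c=0$, the term is frozen at its $r = 3a$ value
beyond $3a$: distant pairs contribute a constant to the energy and no
force. This cap makes a cell-list neighbour search with cells of side
$3a$ exact, not approximate: the grid-accelerated forces equal the dense
double loop to machine precision (asserted in the tests at every use).
The plateau constant of far pairs is added analytically from the pair
count, so reported energies are comparable across the steps of one run.

## Optimisation protocol

Steepest descent with a force-normalised step: with
$\vec f_i = -\partial E/\partial \vec r_i$ computed analytically, every
bead moves by $\vec d_i = (0.1a/f_{\max})\vec f_i$, so the most-forced
bead moves exactly $0.1a$ and all displacements stay bounded regardless of
how steep the landscape is. During the first 2000 steps the structure is
shrunk after every 10th step by the factor
$\left(\sum a / \sum r_{ij}\right)^{0.05}$, the sums running over
contacted pairs — a gentle global rescaling whose fixed point is a mean
contacted-pair distance of exactly $a$, and which herds an initially
diffuse random coil into the basin where the restraints engage. A further
8000 steps without shrinking polish the coarse structure.

Resolution is then refined hierarchically. Each bead is split into two
half-size beads: child 1 at the parent position, child 2 at the midpoint
of the parent and its successor. The terminal parent of a chromosome has
no successor; its second child is placed at the parent position, where the
harmonic backbone relaxes it within a few steps (any extrapolation scheme
converges to the same refined structure, so the simplest rule is used; the
exactly coincident pair is separated by a deterministic $10^{-6}a$ nudge
before forces are evaluated). After each split, 10,000 no-shrink steps
re-optimise the finer chain. The ladder of resolutions is generated by
halving: the start is the smallest power-of-two multiple of the target
reaching the 1000-kb floor, so a 10-kb target runs
1280, 640, 320, 160, 80, 40, 20, 10 kb, a 100-kb target starts at 1600 kb
and a 1-kb target at 1024 kb. Contacts for every level are re-merged from
a single 1-kb base map rather than from the previous level, so each level
sees exactly the counts it would get by direct binning (the two routes are
oracle-tested equal).

The whole calculation is repeated from independent random initial
conformations — 20 replicas by default, replica $r$ seeded with
$\texttt{seed} + r - 1$ — and the ensemble spread is the measure of how
well the data determine the structure.

## Data preparation

Input contact lists (minimal TSV, 4DN-style `.pairs`, or a column-mapped
NCC-like dialect) are validated against a `chrom.sizes` assembly.
Positions are 1-based; bins are half-open after 0-based conversion, so
position $10{,}000$ at 10-kb resolution falls in bead 0 and $10{,}001$ in
bead 1. Before binning, isolated contacts are removed: both loci of every
record are assigned to fixed 2-Mb windows (grid anchored at coordinate 0)
and a record is kept only if at least one other read observation shares
its unordered window pair. A fixed grid rather than a sliding
neighbourhood keeps the filter deterministic and $O(n)$; a read of count
$k$ counts as $k$ observations, so duplicates support each other.
Contacts are binned once at 1 kb and merged to every working resolution;
reads whose two ends fall in one bead carry no structural information and
are dropped (and tallied, so kept + dropped always equals the raw total).

## Validation statistics

* **Violation percentage** — the fraction of restrained bead pairs (each
  pair counted once, whatever its read count, since a pair with $c=5$ is
  a single restraint) whose model distance exceeds 2 bead diameters
  (strictly; $r = 2a$ satisfies the restraint).
* **Pairwise RMSD** — after the optimal rigid superposition, also
  evaluated under reflection and taking the smaller value, because
  contact data cannot distinguish a structure from its mirror image. The
  superposition solves the orthogonal Procrustes problem by SVD and
  evaluates the RMSD from explicit residuals (numerically exact for
  identical inputs). Optionally normalised by the nuclear radius of the
  first conformation, defined here as the radius of the smallest
  centroid-centred sphere containing all beads — a documented surrogate,
  configurable, since reasonable alternatives (e.g. an envelope fit)
  differ only by a few percent.
* **Ensemble reliability** — the median of all-pairs RMSD within an
  ensemble; below 4 bead diameters the ensemble is flagged reliable. The
  rationale: a contacted bead can wander within a sphere of diameter 4
  bd relative to its partner while satisfying the 2-bd threshold, so
  agreement tighter than that is as much as the restraints can enforce.
* **Separation score** — for position $i$ on a distance matrix, the mean
  distance between the $w$ beads upstream and the $w$ beads downstream
  ($w = 20$ beads by default, the 200-kb scale at 10 kb). Peaks mark
  boundaries between spatially segregated domains; peaks are called at
  local maxima with topographic prominence at least $0.5a$, ties to the
  lower index. This mean-cross-distance form is the package's own
  surrogate for insulation-style boundary scores; it is validated on
  planted two-domain structures, where it recovers the planted linker.
* **Gyration-radius profile** — for every bead as the midpoint of a
  200-kb fragment, the RMS distance of the fragment's beads from their
  centroid; extended linkers appear as peaks, compact globules as
  valleys. Windows truncated by a chromosome end are reported missing.
* **Contacts per bead** — usable (post-binning) reads divided by bead
  count at the working resolution; above 0.2 the resolution is considered
  supported. The arithmetic worked example shipped with the acceptance
  script: 110,623 reads over 658,453 beads (one haploid mouse cell binned
  at 4 kb) gives 0.168 — just under the threshold, which is why that cell
  supports 10-kb but not 4-kb structures reliably.

## The synthetic generator

Tests and the acceptance script run on synthetic cells, so every stage is
checkable against a known truth without downloads. `simulate_truth` lays
each chromosome down as a confined random walk with unit steps; planted
domains are collapsed sub-walks biased toward their running centroid
(strength = `compactness`, default 0.8), joined by persistent, extended
linkers. `sample_contacts` then emits every bead pair within the capture
radius (default $2a$, matching $r_0$) independently with probability
`detection_prob`, with record positions drawn uniformly inside each
bead's genomic bin; an optional Poisson multiplicity knob (off by
default) produces duplicate reads. The default `detection_prob` of 0.5
gives a comfortably determined toy (about 10 contacts per bead on the
standard 100-bead, 2-Mb two-domain system); the reliability-trend
experiments instead start at 0.04 and halve three times, chosen so the
ladder spans the 0.2-contacts-per-bead regime where ensembles are
expected to stop being reliable.

What the generator does *not* emulate: polymer physics beyond
connectivity (no loop extrusion, no lamina attachment), genomic distance
biases in detection, ligation artefacts or mapping noise. Passing the
recovery tests therefore shows the estimator inverts its own observation
model at realistic sparsity — a necessary check, silent on biases real
Hi-C protocols add.

## Numerical choices and degenerate inputs

* Problem sizes in the shipped tests and acceptance script: 20–120-bead
  systems for the force/energy oracles, the standard 100-bead toy for
  end-to-end recovery (full 2000 + 8000 protocol plus one refinement
  level) and for the 5-replica reliability trend. These sizes make every
  behaviour visible while keeping the whole suite a few minutes long;
  nothing in the method is size-specific, and the kernels are
  single-threaded C++ for bit-reproducibility.
* Coincident beads: random initialisation adds a uniform $10^{-6}a$
  jitter; if an interacting pair nevertheless reaches $r = 0$ during
  optimisation the kernels raise an error naming the beads (repulsion
  makes this unreachable in practice).
* A zero-force configuration is a fixed point of the descent (the step
  rule would divide by $f_{\max} = 0$, so the step is skipped).
* Shrinking with no contacted pairs is the identity, with a warning.
* Sub-resolution terminal bins are kept as short beads with the same
  diameter $a$; bead counts use ceiling division, so halving the
  resolution at most doubles, and may slightly less than double, the
  bead count.
* Within each 10-step shrink block, shrinking is applied after steps
  10, 20, …; applying it before would only relabel the trace.
* The isolated-contact filter's minimal reading — at least one *other*
  observation in the same 2-Mb window pair — is deliberately permissive;
  raise `min_support` for noisier data.

## Known limitations

Haploid genomes only (no allele phasing); intact-genome inference keeps
inter-chromosomal contacts but there is no nuclear-envelope confinement
term; chirality is undetermined by construction; the separation score and
nuclear radius are surrogates, documented above, not canonical
definitions; and gradient descent finds one posterior mode per replica
rather than sampling the posterior — ensemble spread understates full
posterior uncertainty when modes are far apart.
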