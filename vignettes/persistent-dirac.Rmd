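---
title: "Persistent Dirac operators as molecular fingerprints: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Persistent Dirac operators as molecular fingerprints: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdirac)
```

## The model

`pdirac` turns a 3D atomic point cloud into a fixed-length numeric
fingerprint by tracking the eigenspectrum of discrete Dirac operators over a
growing family of simplicial complexes.

A simplicial complex $K$ built on the atoms has $n_p$ oriented
$p$-simplices; orientation is induced by vertex labels, so a simplex is a
strictly increasing tuple and the signed boundary matrix
$\mathbf{B}_p \in \mathbb{R}^{n_{p-1}\times n_p}$ has the alternating
entries $(-1)^i$ over each column's face sequence, with
$\mathbf{B}_{p-1}\mathbf{B}_p = 0$. The Dirac matrix of structural index
$p$ is the block-tridiagonal symmetric matrix

$$
\mathbf{D}_p \;=\;
\begin{bmatrix}
0 & \mathbf{B}_1 & & \\
\mathbf{B}_1^\top & 0 & \ddots & \\
 & \ddots & 0 & \mathbf{B}_{p+1} \\
 & & \mathbf{B}_{p+1}^\top & 0
\end{bmatrix},
$$

of side $\sum_{k=0}^{p+1} n_k$. Its square is block diagonal with the Hodge
Laplacians $\mathbf{L}_k = \mathbf{B}_k^\top\mathbf{B}_k +
\mathbf{B}_{k+1}\mathbf{B}_{k+1}^\top$ for $k \le p$ and the down Laplacian
$\mathbf{B}_{p+1}^\top\mathbf{B}_{p+1}$ of the top block, so one
eigendecomposition of $\mathbf{D}_p$ exposes every Laplacian spectrum up to
dimension $p+1$ at once. The block sign matrix $\mathbf{Q}_p$ (sign
$(-1)^k$ on the dimension-$k$ block) anticommutes with $\mathbf{D}_p$,
which forces the nonzero eigenvalues into $\pm\lambda$ pairs, and the
kernel dimension satisfies the exact identity

$$
\dim\ker \mathbf{D}_p \;=\; \operatorname{rank}\mathbf{B}_{p+2}^\top
 + \sum_{k=0}^{p+1}\beta_k ,
$$

with $\beta_k$ the Betti numbers. Kernel eigenvectors split blockwise into
harmonic representatives of homology classes (components, loops, voids);
eigenvectors of the smallest positive eigenvalues are the Fiedler-type
non-homology generators used for spectral clustering of simplices. Both are
exposed by `homology_eigenvectors()` and `non_homology_eigenvectors()`.

## Filtrations

Two filtrations are provided, both parameterized in Angstrom:

* **Vietoris–Rips** (`rips_filtration()`): a simplex enters at the maximum
  pairwise distance among its vertices (diameter convention), so an edge
  appears exactly at its bond length. A cutoff of 1.2 Å on a covalent
  structure therefore recovers the bond graph. The diameter reading of the
  cutoff is a deliberate choice — the radius convention would halve every
  threshold — and can be emulated by rescaling the grid.
* **Alpha** (`alpha_filtration()`): simplices are restricted to the 3D
  Delaunay triangulation and enter at their own circumradius. Because the
  circumsphere of a coface passes through the vertices of each face, the
  face's (minimal) circumradius never exceeds the coface's, so the values
  are face-monotone without post-hoc repair beyond floating-point clamping.

The Delaunay triangulation is computed by an exhaustive empty-circumsphere
test over all vertex quadruples. This is $O(N^5)$ and entirely adequate for
the intended inputs (molecules and fragments of tens of atoms); it is not a
replacement for a computational-geometry library at protein scale. Point
sets with fewer than five points take their full simplex directly.
Degenerate clouds — planar or collinear molecules, which are common — are
jittered by `jitter_eps` (default $10^{-9}$ Å) with a fixed internal seed,
announced via a `message()`, so results stay reproducible run to run.

## Weighted complexes and the metric Dirac matrix

Positive simplex weights $w_\sigma$ induce diagonal metric matrices by the
descending coface recursion

$$
\mathbf{G}_p(\sigma,\sigma) = w_\sigma +
\sum_{\sigma < \tau^{p+1}} \mathbf{G}_{p+1}(\tau,\tau),
\qquad \mathbf{G}_d = w .
$$

The weighted Dirac matrix uses subdiagonal blocks $a_p\mathbf{B}_p^\top$
and superdiagonal blocks $a_p\mathbf{G}_{p-1}^{-1}\mathbf{B}_p\mathbf{G}_p$
with $a_p = (p+1)^{-1/2}$. Two consequences drive the implementation:

* its square is block diagonal with the metric Hodge Laplacians
  $\mathbf{L}_{[p]} = \mathbf{B}_p^\top\mathbf{G}_{p-1}^{-1}\mathbf{B}_p
  \mathbf{G}_p/(p+1) + \mathbf{G}_p^{-1}\mathbf{B}_{p+1}\mathbf{G}_{p+1}
  \mathbf{B}_{p+1}^\top/(p+2)$ (checked to $10^{-10}$ in the tests); and
* conjugating by the block-diagonal square root
  $S = \operatorname{diag}(\mathbf{G}_k^{1/2})$ yields an exactly symmetric
  matrix, so the spectrum is real and is computed with a symmetric
  eigensolver rather than a general nonsymmetric one. Under the coface
  metric and the $a_p$ above, all eigenvalues lie in $[-1, 1]$, which the
  property tests assert on randomized complexes.

Smaller weights produce larger harmonic-eigenvector magnitudes on the
corresponding simplices (for a cycle with edge weights $w_e$ the harmonic
edge block is proportional to $w_e^{-1}$), which is the qualitative
weight-inversion behaviour the test suite pins down on a weighted 4-cycle.

The physicochemical weighting scheme (`physchem_weights()`) assigns
$|$partial charge$|$ to atoms, Euclidean length (Å) to edges and Heron area
(Å²) to triangles, clamped below by `floor = 1e-6` so the metric stays
positive definite when charges vanish or triangles degenerate. Charges are
consumed from input files (SDF charge lines or a sidecar CSV); no charge
model is bundled, since assigning charges is a chemistry decision outside
this package's scope.

## Persistence

For $a \le b$ the persistent $p$-chains
$C_p^{a,b} = \{x \in C_p^b : \partial_p^b x \in C_{p-1}^a\}$ are computed as
the SVD null space of the rows of $\mathbf{B}_p^b$ lying outside $K_a$,
with rank tolerance $10^{-10}$ times the largest singular value; the
persistent boundary operator is the restriction to those chains, expressed
over that orthonormal basis (nonzero singular values are
basis-independent, and the tests verify this under random orthogonal
changes of basis).

The persistent Hodge Laplacian $\mathbf{L}_k^{a,b}$ is assembled on the
$k$-chains of $K_a$: the down term is $K_a$'s own down Laplacian and the up
term comes from the persistent operator of dimension $k+1$. Its kernel
dimension is the persistent Betti number, and the persistent Dirac nullity
is reported as $\sum_{k\le p}\dim\ker\mathbf{L}_k^{a,b} +
\dim\ker(\mathbf{L}_{p+1}^{\mathrm{down}})^{a,b}$. A rectangular persistent
Dirac block matrix is deliberately not assembled: its adjacent blocks would
act between spaces ($C_k^{a,b}$ versus $C_k^a$) that need not coincide, so
the kernel characterization is the well-defined object. At $a = b$ the
machinery collapses to the snapshot operators, which the tests check
against direct eigendecompositions, and the persistent Betti numbers are
validated against an independent GF(2) column-reduction barcode
implementation that shares no code with the production path.

Featurization uses snapshot ($a = b$) spectra; the general $(a, b)$
machinery is exported for analysis and testing.

## The twelve attributes

From the positive eigenvalues $\{\lambda_1,\dots,\lambda_n\}$ of a snapshot
Dirac matrix, `attribute_vector()` computes, in order: the Fiedler value
(smallest positive eigenvalue), the largest eigenvalue, mean, population
standard deviation, the graph energy $\zeta(-1)$, the signless
Euler–Poincaré number $\ell = (\text{side} - \text{nullity})/2$, the
generalized mean energy $\sum|\lambda_i-\bar\lambda|/n$, the second moment
$\zeta(-2)$, $\zeta(2) = 2\sum\lambda_j^{-2}$, the quasi-Wiener index
$(n+1)\zeta(1)$, the spanning-tree number
$t = \tfrac12\log c_1 - \log(\ell+1)$, and the persistent multiplicity
(nullity). Conventions that the source formulas leave open were fixed once:

* all statistics run over the positive eigenvalues, and $n$ in the mean,
  generalized energy and quasi-Wiener prefactor is their count ($= \ell$) —
  the only reading under which "energy $= \zeta(-1)$" and "$\ell$ counts
  pairs" cohere;
* $c_1$ is the product of **all** nonzero eigenvalues taken in magnitude
  ($(-1)^\ell\prod\lambda_j^2$ in sign), stored in the log domain, so the
  filled triangle gives $c_1 = 3^3 = 27$ and
  $t = \tfrac12\ln 27 - \ln 4 \approx 0.2616$;
* logarithms are natural; the standard deviation is the population form;
* an all-zero matrix (early filtration, isolated atoms) produces zeros for
  attributes (i)–(xi) and the matrix side as multiplicity, so features are
  finite from the first grid value.

The factor 2 in $\zeta(2)$ follows the alternative zeta convention
$(1+e^{-i\pi s})|\lambda|^{-s}$ at $s = 2$; it is kept verbatim even though
it differs from $\zeta$ at other arguments, because the attribute list
defines it that way.

## Feature assembly

`featurize()` concatenates attributes in the fixed order atom subset →
grid value → Dirac index → attribute, with stable column labels
`subset_f<value>_D<p>_<name>`. The two canned configurations are

* `oihp_config()`: alpha complex, grid 1–6.5 Å by 0.25 (23 values), Dirac
  indices 0 and 1 — 552 features, or 1104 with the with/without-hydrogen
  subset pair;
* `freesolv_config()`: subsets A (all atoms, alpha complex), B (no H) and C
  (no H, no C), both with the Rips complex; 120 grid values 0.1–12.0 Å by
  0.1 — 8640 features. The grid excludes 0 Å: a 120-step count is only
  consistent with the half-open grid, and at 0 Å the complex is vertex-only,
  carrying no information beyond the atom count (a 121-value inclusive grid
  remains available through `featurize_config()`).

## Synthetic data

`generate_fixture()` provides the deterministic structures the tests and
examples run on: `isolated` (points 100 Å apart — no simplices at any
molecular scale, the all-zero-matrix regime), `cycle` (regular unit-edge
n-gon, the minimal loop), `guanine_like` (16 atoms, 1.35 Å
nearest-neighbour spacing on a compact 2×2×4 grid, diameter 4.48 Å — so the
Rips filtration passes from 16 isolated atoms through bond-scale edges to
the complete complex below 4.7 Å, the regime in which all worked-example
integers are checked), `random_cloud` (uniform points in a 6 Å box) and
`toy_molecule` (9 atoms with element labels and synthetic charges for the
weighted pipeline). The spacing and diameter values are chosen to mimic
covalent-bond scales in small organic molecules; these fixtures exercise
the combinatorial and spectral machinery, not chemistry — they contain no
realistic bond-angle, element-composition or charge distributions, so green
tests certify the operators and attributes, not predictive performance on
real molecular datasets, which additionally depends on external structure
quality and learning pipelines that are out of scope here.

## Numerical choices

* **Eigensolvers.** All spectra use dense symmetric LAPACK solvers. The
  largest matrix in routine use is the 2516² Dirac matrix of the complete
  3-skeleton on 16 vertices (about two seconds on one core). No sparse
  iterative eigensolver is used: iterative methods miscount zero-eigenvalue
  multiplicities, which are exactly the quantity of interest. For larger
  systems, `kernel_decomposition(..., spectral = FALSE)` provides nullities
  by boundary-matrix ranks through the kernel identity instead.
* **Zero threshold.** $|\lambda| \le 10^{-8}\max(1, |\lambda|_{\max})$,
  relative so it survives the $a_p$ and metric rescalings; every nullity
  asserted in the tests is an exact integer under this threshold.
* **Ranks** use singular values with the standard
  $\max(\text{dim})\cdot\varepsilon$ relative cutoff.
* **Tie-breaking and ordering.** Simplices are kept in lexicographic order
  per dimension; every matrix row/column meaning is fixed by that ordering,
  making runs bit-reproducible.
* **Degenerate inputs.** Duplicate points are allowed in Rips (zero-length
  edges); degenerate Alpha inputs are jittered as described; empty
  dimensions yield 0-sized blocks, so vertex-only complexes give all-zero
  Dirac matrices of side $n_0$.

## Problem sizes in the test suite

The suite is sized for a single CPU: property tests draw Rips complexes on
6–8 random points (up to a few hundred simplices), persistence oracles run
on 30+ random filtrations of 6–7 points, and the complete-complex
worked example (sides 136, 696, 2516) runs once. The full suite completes
in well under a minute; `scripts/acceptance.R` in a few seconds.

## Known limitations

* The brute-force Delaunay stage limits Alpha filtrations to small point
  clouds (tens of atoms); Rips has the usual combinatorial blow-up with
  `max_dim` and radius.
* The complex-parameter Dirac family $\mathbf{D}_p(z)$ is implemented only
  at $z = 1$; Čech, cubical and Morse complexes are out of scope.
* The weighted spectral bound $|\lambda| \le 1$ is asserted under the
  coface metric with $a_p = (p+1)^{-1/2}$ only; no claim is made for other
  weight conventions.
* Barcodes/persistence diagrams are not a deliverable; the reduction
  algorithm exists in the test suite purely as an oracle.
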