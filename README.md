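# pdirac

Topological fingerprints of molecules from the spectra of discrete Dirac
operators over filtrations of simplicial complexes.

## The problem

Machine-learning models for molecular property prediction and structure
clustering need fixed-length numeric representations of 3D atomic
structures that capture both geometry (distances, scales) and topology
(connected components, rings, cavities). Persistent spectral methods supply
this by building a growing family of simplicial complexes on the atoms and
tracking operator spectra along the way. `pdirac` implements the persistent
**Dirac** variant for computational chemists and structural
bioinformaticians: one operator whose single eigendecomposition exposes the
Hodge Laplacian spectra of every dimension at once, plus a 12-number
spectral summary per filtration step that stacks into a molecular feature
vector.

## The operator

For a simplicial complex with signed boundary matrices **B**₁, …, **B**ₚ₊₁
(orientation induced by vertex labels), the discrete Dirac matrix is the
block-tridiagonal symmetric matrix

    D_p = [ 0      B_1                ]
          [ B_1ᵀ   0     B_2          ]
          [        B_2ᵀ  0    ...     ]
          [              ...  B_{p+1} ]
          [            B_{p+1}ᵀ  0    ]

of side Σₖ nₖ (k = 0..p+1). Its square is block diagonal with the Hodge
Laplacians Lₖ = BₖᵀBₖ + Bₖ₊₁Bₖ₊₁ᵀ, its nonzero eigenvalues come in ±λ pairs
(supersymmetry), and its nullity obeys the exact identity

    dim ker D_p = rank B_{p+2}ᵀ + Σ_{k=0}^{p+1} β_k

with βₖ the Betti numbers. A weighted variant replaces the blocks by
aₚ Bₚᵀ and aₚ G₍ₚ₋₁₎⁻¹ Bₚ Gₚ, where the diagonal metrics Gₚ come from a
coface recursion over positive simplex weights and aₚ = (p+1)^(−1/2); its
spectrum is real and lies in [−1, 1].

At each value of a Vietoris–Rips or Alpha filtration (in Å), the positive
eigenvalues {λ₁..λₙ} of D₀, D₁ (optionally D₂) are condensed into 12
attributes: Fiedler value, max, mean, standard deviation, graph energy
ζ(−1), signless Euler–Poincaré number ℓ, generalized mean energy, second
moment ζ(−2), ζ(2) = 2Σλ⁻², quasi-Wiener index (n+1)ζ(1), spanning-tree
number ½log c₁ − log(ℓ+1), and the zero-eigenvalue multiplicity.

## Worked example

The filled triangle (complete complex on 3 vertices) has Dirac matrix D₁
of side 7 and spectrum {0} ∪ {±√3 each three times}:

```r
library(pdirac)
tri <- complete_complex(3, 2)
D   <- assemble_dirac(tri, 1)
D
#> Discrete Dirac matrix D_1: 7 x 7
#>   block sizes: 3, 3, 1
sp <- dirac_spectrum(D)
round(sp$values, 4)
#> [1] -1.7321 -1.7321 -1.7321  0.0000  1.7321  1.7321  1.7321
round(attribute_vector(sp), 4)
#>         fiedler             max            mean             std          energy
#>          1.7321          1.7321          1.7321          0.0000          5.1962
#>  euler_poincare gen_mean_energy         moment2           zeta2    quasi_wiener
#>          3.0000          0.0000          9.0000          2.0000          6.9282
#>   spanning_tree    multiplicity
#>          0.2616          1.0000
```

Reading the numbers: the three-fold eigenvalue √3 ≈ 1.7321 fills the first
three slots with zero spread; the energy is 3√3; three ±pairs give ℓ = 3;
the single zero eigenvalue (multiplicity 1) is the one connected component;
and the spanning-tree number is ½ln 27 − ln 4 ≈ 0.2616.

A 16-atom synthetic molecule with ~1.35 Å spacing becomes a complete
simplicial complex below 4.7 Å, where the Dirac matrices stop growing:

```r
g <- generate_fixture("guanine_like")
f <- rips_filtration(g$coords, max_dim = 3, max_radius = 5)
K <- sublevel_complex(f, 4.7)
K
#> Simplicial complex: max dimension 3
#>   simplex counts: 16, 120, 560, 1820 (dims 0..3)
kernel_decomposition(K, 2, spectral = FALSE)$identity   # nullity of D_2
#> [1] 1366
```

Featurizing a point cloud with the perovskite-style configuration (alpha
complex, 23 grid values from 1 to 6.5 Å, D₀ and D₁) gives 552 labeled
features per structure:

```r
fv <- featurize(generate_fixture("random_cloud", n = 20, seed = 1), oihp_config())
length(fv)
#> [1] 552
```

A thin command-line interface wraps the same functions:

```sh
Rscript inst/cli/pdirac.R featurize --input structures/ --complex alpha \
    --fmin 1 --fmax 6.5 --step 0.25 --dims 0,1 --out features.csv
Rscript inst/cli/pdirac.R spectrum --input mol.xyz --complex rips --at 1.2 --dim 1
Rscript inst/cli/pdirac.R selftest
```

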