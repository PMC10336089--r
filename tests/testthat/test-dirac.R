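test_that("discrete Dirac matrices have the documented block structure", {
  tri <- filled_triangle()
  D <- assemble_dirac(tri, 1)
  expect_equal(D$side, 7L)
  expect_equal(D$block_n, c(3L, 3L, 1L))
  M <- as.matrix(D$matrix)
  expect_equal(M, t(M))
  expect_equal(M[1:3, 4:6], as.matrix(boundary_matrix(tri, 1)),
               ignore_attr = TRUE)
  expect_equal(M[4:6, 7, drop = FALSE], as.matrix(boundary_matrix(tri, 2)),
               ignore_attr = TRUE)
  expect_equal(M[1:3, 1:3], matrix(0, 3, 3))

  iso <- simplicial_complex(list(matrix(0:15, ncol = 1)))
  for (p in 0:2) {
    Dp <- assemble_dirac(iso, p)
    expect_equal(Dp$side, 16L)
    expect_equal(max(abs(Dp$matrix)), 0)
  }
})

test_that("metric matrices follow the coface recursion", {
  tri <- filled_triangle()
  mw <- metric_matrices(tri, 1)
  expect_equal(mw$G[[3]], 1)
  expect_equal(mw$G[[2]], rep(2, 3))
  expect_equal(mw$G[[1]], rep(5, 3))

  edge <- simplicial_complex(list(matrix(0:1, ncol = 1), rbind(c(0, 1))))
  mw <- metric_matrices(edge, 1)
  expect_equal(mw$G[[2]], 1)
  expect_equal(mw$G[[1]], c(2, 2))

  iso <- simplicial_complex(list(matrix(0:3, ncol = 1)))
  w <- list(c(4, 3, 2, 1))
  expect_equal(metric_matrices(iso, w)$G[[1]], w[[1]])

  expect_error(metric_matrices(tri, list(rep(1, 3), c(1, -1, 1), 1)),
               "non-positive weight")
})

test_that("weighted Dirac reduces to the discrete Dirac for identity metrics", {
  for (K in list(filled_triangle(), tetrahedron(),
                 sublevel_complex(random_rips(7, 3), 2.2))) {
    mw <- metric_matrices(K, 1)
    mw$G <- lapply(K$n, function(nk) rep(1, nk))
    for (p in 0:2) {
      D <- assemble_dirac(K, p)
      Dw <- assemble_weighted_dirac(K, p, mw, a = rep(1, K$max_dim))
      expect_identical(as.matrix(Dw$matrix), as.matrix(D$matrix))
    }
  }
})

test_that("weighted Dirac spectra are real, bounded by one, and match the similarity oracle", {
  for (seed in 1:8) {
    f <- random_rips(n = 7, seed = seed, max_dim = 2, radius = 2.6)
    K <- f$complex
    set.seed(seed + 1000)
    w <- lapply(K$n, function(nk) runif(nk, 0.2, 3))
    mw <- metric_matrices(K, w)
    Dw <- assemble_weighted_dirac(K, 1, mw)
    sp <- dirac_spectrum(Dw)
    expect_lte(max(abs(sp$values)), 1 + 1e-9)
    # oracle: eigenvalues of the raw non-symmetric matrix
    raw <- eigen(as.matrix(Dw$matrix), only.values = TRUE)$values
    expect_lt(max(abs(Im(raw))), 1e-8)
    expect_equal(sort(Re(raw)), sp$values, tolerance = 1e-8)
  }
})

test_that("Dirac spectra pair about zero and have the documented nullities", {
  tri_sp <- dirac_spectrum(assemble_dirac(filled_triangle(), 1))
  expect_equal(tri_sp$values, c(-sqrt(3) * c(1, 1, 1), 0, sqrt(3) * c(1, 1, 1)),
               tolerance = 1e-10)
  expect_equal(tri_sp$nullity, 1L)

  for (seed in 1:5) {
    K <- sublevel_complex(random_rips(8, seed), 2.4)
    for (p in 0:2) {
      sp <- dirac_spectrum(assemble_dirac(K, p))
      if (sp$side == 0) next
      expect_equal(sp$values, -rev(sp$values), tolerance = 1e-9)
      expect_equal(sp$nullity + 2 * length(sp$positive), sp$side)
    }
  }
})

test_that("squared Dirac blocks equal Hodge Laplacians from the entrywise rules", {
  for (K in list(filled_triangle(), tetrahedron(), four_cycle_complex(),
                 sublevel_complex(random_rips(7, 21), 2.4))) {
    p <- min(1, K$max_dim)
    D <- assemble_dirac(K, p)
    D2 <- as.matrix(D$matrix %*% D$matrix)
    blocks <- hodge_blocks(K, p)
    off <- D$offsets
    for (k in seq_along(blocks)) {
      idx <- seq_len(D$block_n[k]) + off[k]
      expect_lte(max(abs(D2[idx, idx] - as.matrix(blocks[[k]])), 0), 1e-10)
    }
    # entrywise oracle for the full Laplacians L_0..L_p
    for (k in 0:p) {
      expect_equal(as.matrix(blocks[[k + 1]]), entrywise_laplacian(K, k),
                   ignore_attr = TRUE)
    }
  }
})

test_that("metric Hodge Laplacian formulas match the squared weighted Dirac", {
  K <- filled_triangle()
  mw <- metric_matrices(K, 1)
  Dw <- assemble_weighted_dirac(K, 1, mw)
  D2 <- as.matrix(Dw$matrix %*% Dw$matrix)
  blocks <- hodge_blocks(K, 1, metrics = mw)
  off <- Dw$offsets
  for (k in seq_along(blocks)) {
    idx <- seq_len(Dw$block_n[k]) + off[k]
    expect_lte(max(abs(D2[idx, idx] - as.matrix(blocks[[k]]))), 1e-10)
  }
})

test_that("supersymmetry residual vanishes on exact integer Dirac matrices", {
  expect_identical(supersymmetry_check(assemble_dirac(filled_triangle(), 1)),
                   list(ok = TRUE, residual = 0))
  expect_equal(supersymmetry_check(assemble_dirac(tetrahedron(), 2))$residual, 0)
  K <- sublevel_complex(random_rips(8, 7), 2.4)
  expect_equal(supersymmetry_check(assemble_dirac(K, 1))$residual, 0)
})

test_that("the kernel decomposition identity holds exactly", {
  kd <- kernel_decomposition(two_disjoint_edges(), 0)
  expect_identical(kd$nullity, kd$identity)
  expect_equal(kd$nullity, 2L)

  for (seed in 1:10) {
    K <- sublevel_complex(random_rips(8, seed, max_dim = 3), 2.6)
    kd <- kernel_decomposition(K, 1)
    expect_identical(kd$nullity, kd$identity)
  }
})

test_that("homology generators split into blockwise harmonic components", {
  # 4-cycle: the edge block of the loop generator has equal magnitudes
  D <- assemble_dirac(four_cycle_complex(), 1)
  hg <- homology_eigenvectors(D)
  expect_equal(ncol(hg$vectors), 2L)
  edge_blocks <- hg$blocks[[2]]
  loop <- edge_blocks[, which.max(colSums(edge_blocks^2)), drop = TRUE]
  expect_equal(abs(loop), rep(max(abs(loop)), 4), tolerance = 1e-9)

  # filled triangle: kernel is the constant vertex block
  Dt <- assemble_dirac(filled_triangle(), 1)
  hgt <- homology_eigenvectors(Dt)
  expect_equal(ncol(hgt$vectors), 1L)
  v <- hgt$blocks[[1]][, 1]
  expect_equal(abs(v), rep(1 / sqrt(3), 3), tolerance = 1e-9)
  expect_lt(max(abs(hgt$blocks[[2]][, 1])), 1e-9)

  # kernel blocks are harmonic: L_k w_k = 0
  K <- sublevel_complex(random_rips(7, 9), 2.4)
  Dk <- assemble_dirac(K, 1)
  hk <- homology_eigenvectors(Dk)
  blocks <- hodge_blocks(K, 1)
  for (k in seq_along(blocks)) {
    if (ncol(hk$vectors) == 0 || nrow(hk$blocks[[k]]) == 0) next
    expect_lt(max(abs(as.matrix(blocks[[k]]) %*% hk$blocks[[k]])), 1e-8)
  }
})

test_that("non-homology generators are returned in ascending eigenvalue order", {
  D <- assemble_dirac(filled_triangle(), 1)
  nh <- non_homology_eigenvectors(D, 2)
  expect_equal(nh$values, rep(sqrt(3), 2), tolerance = 1e-10)
  expect_warning(non_homology_eigenvectors(D, 10), "positive eigenpairs")
})

test_that("decreasing an edge weight increases its harmonic-generator magnitude", {
  rel_mag <- function(w_edge) {
    mw <- weighted_four_cycle(w_edge)
    Dw <- assemble_weighted_dirac(four_cycle_complex(), 0, mw)
    hg <- homology_eigenvectors(Dw)
    eb <- hg$blocks[[2]]
    loop <- eb[, which.max(colSums(eb^2))]
    abs(loop[1]) / sqrt(sum(loop^2))
  }
  mags <- vapply(c(10, 1, 0.01), rel_mag, numeric(1))
  expect_lt(mags[1], mags[2])
  expect_lt(mags[2], mags[3])
})

test_that("Dirac matrices export to MatrixMarket", {
  path <- tempfile(fileext = ".mtx")
  export_matrix_market(assemble_dirac(filled_triangle(), 1), path)
  M <- Matrix::readMM(path)
  expect_equal(dim(M), c(7L, 7L))
})
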