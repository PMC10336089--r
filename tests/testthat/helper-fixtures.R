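# small complexes and random inputs shared across test files

filled_triangle <- function() complete_complex(3, 2)

tetrahedron <- function() complete_complex(4, 3)

four_cycle_complex <- function() {
  simplicial_complex(list(
    matrix(0:3, ncol = 1),
    rbind(c(0, 1), c(0, 3), c(1, 2), c(2, 3))))
}

two_disjoint_edges <- function() {
  simplicial_complex(list(
    matrix(0:3, ncol = 1),
    rbind(c(0, 1), c(2, 3))))
}

# random Rips complex from a uniform cloud; small by construction
random_rips <- function(n = 7, seed = 1, max_dim = 2, radius = 2.5) {
  pts <- generate_fixture("random_cloud", n = n, seed = seed)$coords
  rips_filtration(pts, max_dim = max_dim, max_radius = radius)
}

# weighted 4-cycle with one tunable edge weight (edge {0,1})
weighted_four_cycle <- function(w_edge) {
  K <- four_cycle_complex()
  w <- list(rep(1, 4), c(w_edge, 1, 1, 1))
  metric_matrices(K, w)
}
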