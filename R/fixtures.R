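## Deterministic synthetic structures for tests, examples and self-checks.

## run expr with a private RNG stream seeded by `seed`
with_fixture_seed <- function(seed, expr) {
  state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(state)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", state, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic molecular fixture
#'
#' Deterministic point clouds and toy molecules:
#' * `isolated` — n points 100 Angstrom apart along a line (no simplices
#'   beyond vertices at any molecular scale);
#' * `cycle` — regular n-gon with unit edge length in the z = 0 plane;
#' * `guanine_like` — 16 atoms on a compact 2 x 2 x 4 grid with 1.35
#'   Angstrom nearest-neighbour spacing and diameter below 4.7 Angstrom,
#'   emulating a small planar-ish heterocycle's filtration regimes;
#' * `random_cloud` — n uniform points in a 6 Angstrom box;
#' * `toy_molecule` — a 9-atom branched structure with element labels and
#'   synthetic partial charges, for the weighted pipeline.
#'
#' @param kind fixture kind.
#' @param n number of points (ignored where the kind fixes it).
#' @param seed RNG seed for the random kinds.
#' @return a [molecule()].
#' @export
generate_fixture <- function(kind = c("isolated", "cycle", "guanine_like",
                                      "random_cloud", "toy_molecule"),
                             n = 16, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(n >= 1)
  switch(kind,
    isolated = {
      coords <- cbind(100 * (seq_len(n) - 1), 0, 0)
      molecule(coords, rep("C", n), name = "isolated")
    },
    cycle = {
      r <- 1 / (2 * sin(pi / n))
      th <- 2 * pi * (seq_len(n) - 1) / n
      molecule(cbind(r * cos(th), r * sin(th), 0), rep("C", n),
               name = "cycle")
    },
    guanine_like = {
      g <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:3)) * 1.35
      molecule(g, rep(c("C", "N"), 8), name = "guanine_like")
    },
    random_cloud = with_fixture_seed(seed, {
      molecule(matrix(runif(3 * n, 0, 6), n, 3), rep("C", n),
               name = "random_cloud")
    }),
    toy_molecule = with_fixture_seed(seed, {
      coords <- rbind(
        c(0.00, 0.00, 0.00), c(1.43, 0.00, 0.00), c(2.10, 1.25, 0.10),
        c(2.05, -1.20, -0.15), c(-0.55, 0.90, 0.40), c(-0.50, -0.85, -0.55),
        c(3.45, 1.30, 0.05), c(1.55, 2.35, 0.30), c(2.95, -1.35, 0.55))
      elements <- c("C", "C", "N", "O", "H", "H", "H", "H", "H")
      charges <- round(rnorm(9, 0, 0.3), 3)
      molecule(coords, elements, charges = charges, name = "toy_molecule")
    })
  )
}
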