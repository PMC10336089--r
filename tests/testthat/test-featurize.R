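extdata <- function(f) system.file("extdata", f, package = "pdirac")

test_that("structure readers parse XYZ, PDB and SDF fixtures", {
  w <- read_structure(extdata("water.xyz"))
  expect_equal(nrow(w$coords), 3L)
  expect_equal(w$elements, c("O", "H", "H"))
  expect_equal(w$coords[2, 1], 0.9572)

  skip_if_not_installed("bio3d")
  p <- read_structure(extdata("calpha.pdb"))
  expect_equal(nrow(p$coords), 4L)
  expect_equal(p$elements, rep("C", 4))

  skip_if_not_installed("ChemmineR")
  s <- read_structure(extdata("toy.sdf"))
  expect_equal(s$elements, c("O", "H", "H"))
  expect_equal(s$charges, c(-1, 0, 0))
})

test_that("malformed and unknown inputs are rejected with useful errors", {
  bad <- tempfile(fileext = ".xyz")
  writeLines(c("2", "comment", "O 0 0 0", "H 0 0"), bad)
  expect_error(read_structure(bad), "malformed XYZ record")
  expect_error(read_structure(tempfile(fileext = ".xyz")), "not found")
})

test_that("a sidecar charge table attaches charges to any format", {
  csv <- tempfile(fileext = ".csv")
  write.csv(data.frame(charge = c(-0.8, 0.4, 0.4)), csv, row.names = FALSE)
  w <- read_structure(extdata("water.xyz"), charges = csv)
  expect_equal(w$charges, c(-0.8, 0.4, 0.4))
  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(charge = 1:2), bad, row.names = FALSE)
  expect_error(read_structure(extdata("water.xyz"), charges = bad), "3 atoms")
})

test_that("atom subsets drop hydrogens and carbons as configured", {
  methane <- molecule(rbind(c(0, 0, 0), c(1, 1, 1), c(1, -1, -1),
                            c(-1, 1, -1), c(-1, -1, 1)) * 0.63,
                      c("C", "H", "H", "H", "H"), name = "methane")
  expect_equal(subset_atoms(methane, "B")$elements, "C")
  expect_error(subset_atoms(methane, "C"), "no atoms")
  water <- read_structure(extdata("water.xyz"))
  expect_equal(subset_atoms(water, "B")$elements, "O")
  # A is the identity, B is idempotent
  toy <- generate_fixture("toy_molecule")
  expect_identical(subset_atoms(toy, "A"), toy)
  expect_identical(subset_atoms(subset_atoms(toy, "B"), "B"),
                   subset_atoms(toy, "B"))
})

test_that("physicochemical weights are geometric with a positive floor", {
  coords <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 3, 0), c(4, 3, 0))
  mol <- molecule(coords, rep("C", 4), charges = c(0.5, -0.25, 0, 1))
  K <- simplicial_complex(list(
    matrix(0:3, ncol = 1),
    rbind(c(0, 1), c(0, 2), c(1, 2), c(2, 3)),
    rbind(c(0, 1, 2))))
  w <- physchem_weights(mol, K)
  expect_equal(w[[1]], c(0.5, 0.25, 1e-6, 1))       # |charge|, clamped
  expect_equal(w[[2]][1], 1.5)                       # edge length
  # triangle on sides 1.5 / 3 / sqrt(1.5^2+3^2): right triangle, area 2.25
  expect_equal(w[[3]], 1.5 * 3 / 2)
  # a 3-4-5 triangle has Heron area 6
  tri345 <- molecule(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0)),
                     rep("C", 3), charges = rep(0.1, 3))
  K345 <- complete_complex(3, 2)
  expect_equal(physchem_weights(tri345, K345)[[3]], 6)
  # collinear triangle clamps to the floor
  flat <- molecule(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                   rep("C", 3), charges = rep(0.1, 3))
  expect_equal(physchem_weights(flat, K345)[[3]], 1e-6)
  expect_error(physchem_weights(molecule(coords, rep("C", 4)), K), "charges")
})

test_that("feature lengths follow |subsets| x |grid| x |dims| x 12", {
  mol <- generate_fixture("random_cloud", n = 12, seed = 2)
  expect_length(featurize(mol, oihp_config()), 552L)
  expect_length(featurize(mol, oihp_config(atom_subsets = c("A", "B"))), 1104L)
  set.seed(4)
  for (rep in 1:4) {
    cfg <- featurize_config(
      complex_type = sample(c("rips", "alpha"), 1),
      grid = sort(runif(sample(2:6, 1), 0.5, 5)),
      dirac_indices = sort(sample(0:2, sample(1:2, 1))),
      atom_subsets = "A")
    fv <- featurize(mol, cfg)
    expect_length(fv, length(cfg$grid) * length(cfg$dirac_indices) * 12L)
  }
})

test_that("featurization is deterministic with stable label bijections", {
  mol <- generate_fixture("random_cloud", n = 10, seed = 9)
  cfg <- featurize_config(grid = c(1, 4, 0.5), dirac_indices = c(0, 1))
  f1 <- featurize(mol, cfg)
  f2 <- featurize(mol, cfg)
  expect_identical(f1, f2)
  expect_false(anyDuplicated(names(f1)) > 0)
  expect_match(names(f1)[1], "^A_f1\\.00_D0_fiedler$")
  tab <- featurize_table(list(mol, generate_fixture("toy_molecule")), cfg)
  expect_equal(names(tab)[1], "name")
  expect_equal(ncol(tab), 1 + length(f1))
})

test_that("weighted featurization produces finite features on charged molecules", {
  toy <- generate_fixture("toy_molecule")
  cfg <- featurize_config(complex_type = "rips", grid = c(1, 3, 0.5),
                          dirac_indices = c(0, 1), weighting = "physchem")
  fv <- featurize(toy, cfg)
  expect_true(all(is.finite(fv)))
  expect_length(fv, 5 * 2 * 12)
  # multiplicities never exceed the matrix side and are integers
  mult <- fv[grepl("multiplicity", names(fv))]
  expect_true(all(mult == round(mult)))
})

test_that("fixture generators produce the advertised regimes", {
  iso <- generate_fixture("isolated", 16)
  f <- rips_filtration(iso$coords, 2, 6.5)
  sp <- snapshot_series(f, 1.0, p_list = 0:2)$spectra[[1]]
  expect_equal(vapply(sp, function(s) s$nullity, integer(1)),
               c(D0 = 16L, D1 = 16L, D2 = 16L))

  cyc <- generate_fixture("cycle", 4)
  fc <- rips_filtration(cyc$coords, 2, 2)
  expect_equal(betti_numbers(sublevel_complex(fc, 1.05)), c(1L, 1L))

  r1 <- generate_fixture("random_cloud", 12, 7)
  r2 <- generate_fixture("random_cloud", 12, 7)
  expect_identical(r1$coords, r2$coords)

  g <- generate_fixture("guanine_like")
  expect_equal(nrow(g$coords), 16L)
  expect_lt(max(dist(g$coords)), 4.7)
  nn <- apply(as.matrix(dist(g$coords)) + diag(Inf, 16), 1, min)
  expect_true(all(nn >= 1.2 & nn <= 1.5))
})
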