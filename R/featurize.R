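## Feature-vector assembly: atom subsets x filtration grid x Dirac indices
## x 12 attributes, in a fixed order with stable column labels.

#' Featurization configuration
#'
#' @param complex_type `"rips"` or `"alpha"`, or a named character vector
#'   mapping atom subsets to complex types (e.g.
#'   `c(A = "alpha", B = "rips", C = "rips")`).
#' @param grid increasing positive filtration values in Angstrom, or a
#'   length-3 vector `c(start, stop, step)` expanded with `seq()`.
#' @param dirac_indices subset of `c(0, 1, 2)`.
#' @param atom_subsets subset schemes from `"A"`, `"B"`, `"C"`.
#' @param weighting `"none"` or `"physchem"` (atom charge / edge length /
#'   triangle area weights, see [physchem_weights()]).
#' @param zero_tol zero-eigenvalue threshold.
#' @return object of class `featurize_config`.
#' @export
featurize_config <- function(complex_type = "alpha",
                             grid = c(1, 6.5, 0.25),
                             dirac_indices = c(0, 1),
                             atom_subsets = "A",
                             weighting = c("none", "physchem"),
                             zero_tol = 1e-8) {
  weighting <- match.arg(weighting)
  if (length(grid) == 3L && grid[3L] < grid[2L] - grid[1L])
    grid <- seq(grid[1L], grid[2L], by = grid[3L])
  if (any(grid <= 0) || any(diff(grid) <= 0))
    stop("grid values must be positive and strictly increasing")
  stopifnot(all(dirac_indices %in% 0:2), length(atom_subsets) >= 1L,
            all(atom_subsets %in% c("A", "B", "C")))
  if (is.null(names(complex_type))) {
    stopifnot(all(complex_type %in% c("rips", "alpha")))
    complex_type <- setNames(rep(complex_type[1L], length(atom_subsets)),
                             atom_subsets)
  } else {
    if (!all(atom_subsets %in% names(complex_type)))
      stop("complex_type must name every atom subset")
    stopifnot(all(complex_type %in% c("rips", "alpha")))
  }
  structure(list(complex_type = complex_type, grid = grid,
                 dirac_indices = sort(unique(dirac_indices)),
                 atom_subsets = atom_subsets, weighting = weighting,
                 zero_tol = zero_tol),
            class = "featurize_config")
}

#' @export
print.featurize_config <- function(x, ...) {
  cat("Featurize config:\n")
  cat("  subsets:", paste(x$atom_subsets, collapse = ", "),
      " complex:", paste(unique(x$complex_type[x$atom_subsets]), collapse = "/"),
      "\n")
  cat(sprintf("  grid: %d values, %.3g .. %.3g Angstrom\n",
              length(x$grid), min(x$grid), max(x$grid)))
  cat("  Dirac indices:", paste(x$dirac_indices, collapse = ", "),
      " weighting:", x$weighting, "\n")
  cat("  feature length:",
      length(x$atom_subsets) * length(x$grid) * length(x$dirac_indices) * 12L,
      "\n")
  invisible(x)
}

#' Configuration used for perovskite MD frame fingerprints
#'
#' Alpha complex, grid 1 to 6.5 Angstrom in steps of 0.25 (23 values),
#' Dirac indices 0 and 1, one atom subset: 552 features per structure
#' (1104 with `atom_subsets = c("A", "B")`, i.e. with and without
#' hydrogens).
#'
#' @param atom_subsets subset schemes (default `"A"`).
#' @return a [featurize_config()].
#' @export
oihp_config <- function(atom_subsets = "A") {
  featurize_config(complex_type = "alpha", grid = seq(1, 6.5, by = 0.25),
                   dirac_indices = c(0, 1), atom_subsets = atom_subsets)
}

#' Configuration used for small-molecule solvation fingerprints
#'
#' Subsets A (alpha complex), B and C (Rips), grid of 120 values
#' 0.1 to 12 Angstrom in steps of 0.1, Dirac indices 0 and 1:
#' 120 x 12 x 3 x 2 = 8640 features.
#'
#' @param weighting `"none"` or `"physchem"`.
#' @return a [featurize_config()].
#' @export
freesolv_config <- function(weighting = "none") {
  featurize_config(complex_type = c(A = "alpha", B = "rips", C = "rips"),
                   grid = seq(0.1, 12, by = 0.1), dirac_indices = c(0, 1),
                   atom_subsets = c("A", "B", "C"), weighting = weighting)
}

#' Physicochemical simplex weights
#'
#' Vertex weight is the magnitude of the atom's partial charge, edge weight
#' the Euclidean length in Angstrom, triangle weight the Heron area in
#' squared Angstrom; higher-dimensional simplices get weight 1. All weights
#' are clamped below by `floor` so the metric matrices stay positive.
#'
#' @param mol a [molecule()] with charges.
#' @param K a [simplicial_complex()] built on `mol`'s atoms (0-based labels
#'   indexing the atom order).
#' @param floor positive lower clamp (default `1e-6`).
#' @return per-dimension weight list suitable for [metric_matrices()].
#' @export
physchem_weights <- function(mol, K, floor = 1e-6) {
  stopifnot(inherits(mol, "molecule"), inherits(K, "simplicial_complex"),
            floor > 0)
  if (is.null(mol$charges))
    stop("physchem weighting needs per-atom charges; supply a charge table ",
         "or use weighting = 'none'")
  coords <- mol$coords
  lapply(seq_along(K$simplices), function(d) {
    m <- K$simplices[[d]]
    w <- if (d == 1L) {
      abs(mol$charges)[m[, 1L] + 1L]
    } else if (d == 2L) {
      sqrt(rowSums((coords[m[, 1L] + 1L, , drop = FALSE] -
                    coords[m[, 2L] + 1L, , drop = FALSE])^2))
    } else if (d == 3L) {
      vapply(seq_len(nrow(m)), function(r) {
        v <- coords[m[r, ] + 1L, , drop = FALSE]
        a <- sqrt(sum((v[1L, ] - v[2L, ])^2))
        b <- sqrt(sum((v[1L, ] - v[3L, ])^2))
        cc <- sqrt(sum((v[2L, ] - v[3L, ])^2))
        s <- (a + b + cc) / 2
        sqrt(max(s * (s - a) * (s - b) * (s - cc), 0))
      }, numeric(1))
    } else {
      rep(1, nrow(m))
    }
    pmax(w, floor)
  })
}

#' Persistent Dirac feature vector of a molecule
#'
#' For each atom subset the configured filtration is built, the Dirac
#' spectra computed at every grid value, and the 12 attributes concatenated
#' in the fixed order subset, then grid value, then Dirac index, then
#' attribute. The output length is
#' `|subsets| * |grid| * |dirac_indices| * 12`.
#'
#' @param mol a [molecule()] (or a bare coordinate matrix, treated as one
#'   subset-A point cloud).
#' @param cfg a [featurize_config()].
#' @return named numeric vector; names encode
#'   `subset_f<value>_D<p>_<attribute>`.
#' @examples
#' cloud <- generate_fixture("random_cloud", n = 12, seed = 1)
#' length(featurize(cloud, oihp_config()))  # 552
#' @export
featurize <- function(mol, cfg = oihp_config()) {
  stopifnot(inherits(cfg, "featurize_config"))
  if (!inherits(mol, "molecule"))
    mol <- molecule(mol, rep("C", nrow(as.matrix(mol))), name = "points")
  max_dim <- max(cfg$dirac_indices) + 1L
  out <- list()
  for (s in cfg$atom_subsets) {
    mol_s <- subset_atoms(mol, s)
    filt <- switch(cfg$complex_type[[s]],
      rips = rips_filtration(mol_s$coords, max_dim = max_dim,
                             max_radius = max(cfg$grid)),
      alpha = alpha_filtration(mol_s$coords, max_dim = max_dim))
    weights <- if (cfg$weighting == "physchem")
      function(K) physchem_weights(mol_s, K)
    series <- tryCatch(
      snapshot_series(filt, cfg$grid, p_list = cfg$dirac_indices,
                      weights = weights, tol = cfg$zero_tol),
      error = function(e) stop("featurize failed for subset ", s, ": ",
                               conditionMessage(e)))
    for (g in seq_along(cfg$grid)) {
      for (j in seq_along(cfg$dirac_indices)) {
        sp <- series$spectra[[g]][[j]]
        att <- attribute_vector(sp, sp$side)
        names(att) <- sprintf("%s_f%.2f_D%d_%s", s, cfg$grid[g],
                              cfg$dirac_indices[j], attribute_names())
        out[[length(out) + 1L]] <- att
      }
    }
  }
  unlist(out)
}

#' Feature table for several molecules
#'
#' @param mols list of [molecule()] objects.
#' @param cfg a [featurize_config()].
#' @return data frame with a `name` column followed by the labeled feature
#'   columns.
#' @export
featurize_table <- function(mols, cfg = oihp_config()) {
  rows <- lapply(mols, function(m) featurize(m, cfg))
  tab <- as.data.frame(do.call(rbind, rows))
  cbind(name = vapply(mols, function(m) m$name, character(1)), tab,
        row.names = NULL)
}
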