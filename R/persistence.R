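## Persistent boundary operators, persistent Hodge Laplacians, and the
## filtration snapshot engine that drives featurization.
##
## For a nested pair K_a <= K_b, the persistent p-chains C_p^{a,b} are the
## p-chains of K_b whose boundary is supported on K_a. The persistent
## boundary operator is the restriction of the big boundary map to that
## subspace, represented over an orthonormal SVD basis; persistent Hodge
## Laplacians combine the down Laplacian of K_a with the persistent up term,
## and their kernels give persistent Betti numbers.

#' Nested pair of sublevel complexes
#'
#' @param filt a `filtration`.
#' @param a,b filtration values with `a <= b`.
#' @return object of class `nested_pair` with `K_a`, `K_b`, `a`, `b`.
#' @export
nested_pair <- function(filt, a, b) {
  stopifnot(inherits(filt, "filtration"), a <= b)
  structure(list(K_a = sublevel_complex(filt, a),
                 K_b = sublevel_complex(filt, b), a = a, b = b),
            class = "nested_pair")
}

## indices of K_a's p-simplices within K_b's canonical ordering
inclusion_index <- function(K_a, K_b, p) {
  if (p > K_a$max_dim) return(integer())
  if (p > K_b$max_dim) stop("K_a is not contained in K_b")
  idx <- match(simplex_keys(K_a$simplices[[p + 1L]]),
               simplex_keys(K_b$simplices[[p + 1L]]))
  if (anyNA(idx)) stop("K_a is not contained in K_b")
  idx
}

## orthonormal null-space basis of a dense matrix (SVD); identity-like basis
## for a matrix with no rows
nullspace_basis <- function(M, tol = 1e-10) {
  n <- ncol(M)
  if (n == 0L) return(matrix(numeric(), 0L, 0L))
  if (nrow(M) == 0L) return(diag(n))
  sv <- svd(M, nu = 0, nv = n)
  pos <- sum(sv$d > tol * max(sv$d, 1))
  sv$v[, seq_len(n - pos) + pos, drop = FALSE]
}

#' Persistent boundary operator of a nested pair
#'
#' Computes an orthonormal basis of `C_p^{a,b}` (the p-chains of `K_b` whose
#' boundary has no support outside `K_a`) as the null space of the
#' outside-rows block of `B_p^b`, and represents the restricted boundary map
#' into the (p-1)-chains of `K_a` over that basis. The nonzero singular
#' values of the returned matrix are basis-independent.
#'
#' @param pair a [nested_pair()].
#' @param p chain dimension (>= 1).
#' @param tol relative rank tolerance for the SVD null space.
#' @return object of class `persistent_operator`: `matrix`
#'   (`n_{p-1}^a x dim C_p^{a,b}`), `domain_basis` (columns over the
#'   p-simplices of `K_b`), `dim` (= `n_p^{a,b}`), and the pair metadata.
#' @export
persistent_boundary <- function(pair, p, tol = 1e-10) {
  stopifnot(inherits(pair, "nested_pair"), p >= 1)
  K_a <- pair$K_a; K_b <- pair$K_b
  n_b <- n_simplices(K_b, p)
  n_am1 <- n_simplices(K_a, p - 1L)
  if (n_b == 0L) {
    return(structure(list(matrix = matrix(numeric(), n_am1, 0L),
                          domain_basis = matrix(numeric(), 0L, 0L),
                          dim = 0L, p = p, pair = pair),
                     class = "persistent_operator"))
  }
  B_b <- as.matrix(boundary_matrix(K_b, p))
  in_rows <- inclusion_index(K_a, K_b, p - 1L)
  out_rows <- setdiff(seq_len(nrow(B_b)), in_rows)
  Z <- nullspace_basis(B_b[out_rows, , drop = FALSE], tol = tol)
  M <- B_b[in_rows, , drop = FALSE] %*% Z
  structure(list(matrix = M, domain_basis = Z, dim = ncol(Z), p = p,
                 pair = pair),
            class = "persistent_operator")
}

#' @export
print.persistent_operator <- function(x, ...) {
  cat(sprintf("Persistent boundary operator, p = %d: %d x %d (dim C^{a,b} = %d)\n",
              x$p, nrow(x$matrix), ncol(x$matrix), x$dim))
  invisible(x)
}

#' Persistent Hodge Laplacian
#'
#' `L_k^{a,b}` acts on the k-chains of `K_a`: the down term is the ordinary
#' down Laplacian of `K_a` (absent for k = 0) and the up term is
#' `B_{k+1}^{a,b} (B_{k+1}^{a,b})'` built from the persistent boundary
#' operator. Its kernel dimension is the (a,b)-persistent Betti number.
#'
#' @inheritParams persistent_boundary
#' @param k chain dimension (>= 0).
#' @return dense square matrix of side `n_k^a`.
#' @export
persistent_laplacian <- function(pair, k, tol = 1e-10) {
  stopifnot(inherits(pair, "nested_pair"), k >= 0)
  K_a <- pair$K_a
  n_k <- n_simplices(K_a, k)
  L <- matrix(0, n_k, n_k)
  if (k >= 1L && k <= K_a$max_dim) {
    B <- as.matrix(boundary_matrix(K_a, k))
    L <- L + crossprod(B)
  }
  up <- persistent_boundary(pair, k + 1L, tol = tol)
  if (ncol(up$matrix) > 0L) L <- L + tcrossprod(up$matrix)
  L
}

## kernel dimension of a PSD matrix via its singular values
psd_nullity <- function(L, tol = 1e-8) {
  if (length(L) == 0L) return(ncol(L))
  d <- svd(L, nu = 0, nv = 0)$d
  ncol(L) - sum(d > tol * max(d, 1))
}

#' Persistent Betti number
#'
#' @inheritParams persistent_laplacian
#' @param tol zero threshold for the kernel dimension.
#' @return `dim ker L_k^{a,b}`, the number of k-dimensional homology classes
#'   alive at `a` that survive to `b`.
#' @export
persistent_betti <- function(pair, k, tol = 1e-8) {
  psd_nullity(persistent_laplacian(pair, k), tol = tol)
}

#' Nullity of the persistent Dirac operator
#'
#' The kernel of `D_p^{a,b}` decomposes blockwise into the kernels of the
#' persistent Hodge Laplacians `L_k^{a,b}` for `k = 0..p` plus the kernel of
#' the persistent down Laplacian of the top block, so the nullity is
#' computed as that sum without assembling a rectangular block matrix.
#'
#' @inheritParams persistent_boundary
#' @param tol zero threshold.
#' @return list with `nullity` and `breakdown` (per-dimension kernel
#'   dimensions; the last entry is the top down-Laplacian term).
#' @export
persistent_dirac_nullity <- function(pair, p, tol = 1e-8) {
  stopifnot(inherits(pair, "nested_pair"), p >= 0)
  parts <- vapply(0:p, function(k) persistent_betti(pair, k, tol = tol),
                  numeric(1))
  top <- persistent_boundary(pair, p + 1L)
  down_ker <- top$dim - rank_mat(top$matrix)
  breakdown <- c(parts, down_ker)
  names(breakdown) <- c(paste0("ker_L", 0:p), paste0("ker_L", p + 1L, "_down"))
  list(nullity = sum(breakdown), breakdown = breakdown)
}

#' Spectra of Dirac matrices along a filtration grid
#'
#' For every grid value the sublevel complex is extracted, the Dirac matrix
#' of every requested index assembled (weighted when a weighting function is
#' supplied) and its spectrum stored. Matrices are rebuilt per grid value;
#' sides are non-decreasing along the grid.
#'
#' @param filt a `filtration`.
#' @param grid increasing filtration values in Angstrom.
#' @param p_list Dirac structural indices, e.g. `c(0, 1)`.
#' @param weights optional function `K -> simplex weight list` (see
#'   [metric_matrices()]); `NULL` gives the discrete Dirac matrix.
#' @param tol zero threshold for the spectra.
#' @return object of class `snapshot_series`: `grid`, `p_list`, `spectra`
#'   (list over grid values of lists over `p_list`), `sides` matrix.
#' @export
snapshot_series <- function(filt, grid, p_list = c(0, 1), weights = NULL,
                            tol = 1e-8) {
  stopifnot(inherits(filt, "filtration"), all(diff(grid) > 0))
  spectra <- vector("list", length(grid))
  sides <- matrix(0L, length(grid), length(p_list),
                  dimnames = list(NULL, paste0("D", p_list)))
  for (g in seq_along(grid)) {
    K <- sublevel_complex(filt, grid[g])
    metrics <- if (!is.null(weights)) metric_matrices(K, weights(K))
    per_p <- vector("list", length(p_list))
    for (j in seq_along(p_list)) {
      D <- if (is.null(metrics)) assemble_dirac(K, p_list[j])
           else assemble_weighted_dirac(K, p_list[j], metrics)
      per_p[[j]] <- dirac_spectrum(D, tol = tol)
      sides[g, j] <- D$side
    }
    names(per_p) <- paste0("D", p_list)
    spectra[[g]] <- per_p
  }
  structure(list(grid = grid, p_list = p_list, spectra = spectra,
                 sides = sides),
            class = "snapshot_series")
}

#' @export
print.snapshot_series <- function(x, ...) {
  cat(sprintf("Snapshot series: %d grid values (%.3g .. %.3g Angstrom), Dirac indices %s\n",
              length(x$grid), min(x$grid), max(x$grid),
              paste(x$p_list, collapse = ", ")))
  invisible(x)
}

#' Tabulate a snapshot series as one row per grid value and Dirac index
#'
#' @param x a `snapshot_series`.
#' @param ... unused.
#' @return data frame with columns `filtration`, `dirac`, `side` and the 12
#'   persistent attributes (see [attribute_vector()]).
#' @export
as.data.frame.snapshot_series <- function(x, ...) {
  rows <- list()
  for (g in seq_along(x$grid)) {
    for (j in seq_along(x$p_list)) {
      sp <- x$spectra[[g]][[j]]
      att <- attribute_vector(sp, sp$side)
      rows[[length(rows) + 1L]] <-
        data.frame(filtration = x$grid[g], dirac = x$p_list[j],
                   side = sp$side, as.list(att))
    }
  }
  do.call(rbind, rows)
}
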