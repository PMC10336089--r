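## Simplicial complexes, boundary matrices, Betti numbers.
##
## A p-simplex is stored as a strictly increasing integer row of 0-based
## vertex labels; increasing label order is the positive orientation. Within
## each dimension simplices are kept in lexicographic order, and every matrix
## in the package indexes rows/columns by that canonical ordering.

#' Construct a simplicial complex from explicit simplex tables
#'
#' @param simplices list indexed by dimension + 1; element `d + 1` is an
#'   integer matrix with `d + 1` columns whose rows are the d-simplices
#'   (strictly increasing 0-based vertex labels). `NULL`/empty elements give
#'   empty dimensions.
#' @param check validate face closure and simplex shape (default `TRUE`).
#' @return an object of class `simplicial_complex` with fields `simplices`
#'   (lexicographically sorted per dimension), `n` (simplex counts per
#'   dimension) and `max_dim`.
#' @export
simplicial_complex <- function(simplices, check = TRUE) {
  if (length(simplices) == 0L)
    stop("a simplicial complex needs at least one vertex")
  simplices <- lapply(seq_along(simplices), function(i) {
    m <- simplices[[i]]
    if (is.null(m) || length(m) == 0L)
      return(matrix(integer(), 0L, i))
    m <- matrix(as.integer(m), ncol = i)
    m[lex_order(m), , drop = FALSE]
  })
  ## drop trailing empty dimensions
  while (length(simplices) > 1L && nrow(simplices[[length(simplices)]]) == 0L)
    simplices[[length(simplices)]] <- NULL
  K <- structure(
    list(simplices = simplices,
         n = vapply(simplices, nrow, integer(1)),
         max_dim = length(simplices) - 1L),
    class = "simplicial_complex")
  if (check) validate_complex(K)
  K
}

#' @export
print.simplicial_complex <- function(x, ...) {
  cat("Simplicial complex: max dimension", x$max_dim, "\n")
  cat("  simplex counts:", paste(x$n, collapse = ", "),
      sprintf("(dims 0..%d)\n", x$max_dim))
  invisible(x)
}

## lexicographic row order of a simplex table
lex_order <- function(m) {
  if (nrow(m) <= 1L) return(seq_len(nrow(m)))
  do.call(order, lapply(seq_len(ncol(m)), function(j) m[, j]))
}

## "0,3,7" keys used to match faces against the canonical tables
simplex_keys <- function(m) {
  if (nrow(m) == 0L) return(character())
  if (ncol(m) == 1L) return(as.character(m[, 1]))
  do.call(paste, c(lapply(seq_len(ncol(m)), function(j) m[, j]), sep = ","))
}

validate_complex <- function(K) {
  for (d in seq_along(K$simplices)) {
    m <- K$simplices[[d]]
    if (nrow(m) == 0L) next
    if (ncol(m) > 1L && any(m[, -1L, drop = FALSE] <= m[, -ncol(m), drop = FALSE]))
      stop("simplex vertices must be strictly increasing")
    if (anyDuplicated(simplex_keys(m)))
      stop("duplicate simplices in dimension ", d - 1L)
    if (d > 1L) {
      lower <- simplex_keys(K$simplices[[d - 1L]])
      for (i in seq_len(ncol(m))) {
        face <- simplex_keys(m[, -i, drop = FALSE])
        if (!all(face %in% lower))
          stop("complex is not closed under faces in dimension ", d - 1L)
      }
    }
  }
  invisible(K)
}

#' Complete simplicial complex on n vertices
#'
#' Every subset of `{0, ..., n - 1}` of size at most `max_dim + 1` is a
#' simplex, so the p-simplex count is `choose(n, p + 1)`.
#'
#' @param n number of vertices (>= 1).
#' @param max_dim highest simplex dimension to include.
#' @return a [simplicial_complex()].
#' @examples
#' complete_complex(16, 1)$n   # 16 vertices, 120 edges
#' @export
complete_complex <- function(n, max_dim) {
  stopifnot(n >= 1, max_dim >= 0)
  top <- min(max_dim, n - 1L)
  simplices <- lapply(0:top, function(d) {
    t(combn(0:(n - 1L), d + 1L))
  })
  simplicial_complex(simplices, check = FALSE)
}

## indices (into the canonical (p-1)-table) of the p+1 faces of each
## p-simplex, as a (p+1) x n_p matrix; row i removes vertex i (1-based)
face_index_matrix <- function(K, p) {
  cols <- K$simplices[[p + 1L]]
  rows_keys <- simplex_keys(K$simplices[[p]])
  out <- matrix(NA_integer_, p + 1L, nrow(cols))
  for (i in seq_len(p + 1L)) {
    keys <- simplex_keys(cols[, -i, drop = FALSE])
    idx <- match(keys, rows_keys)
    if (anyNA(idx)) stop("complex is not closed under faces")
    out[i, ] <- idx
  }
  out
}

#' Signed boundary matrix
#'
#' The `n_{p-1} x n_p` incidence matrix of the (weighted) boundary operator:
#' column j holds the alternating signs `(-1)^i a_p` of the faces of the j-th
#' p-simplex, rows and columns in the canonical lexicographic ordering.
#' `a_p = 1` gives the unweighted matrix; consecutive matrices compose to
#' zero.
#'
#' @param K a [simplicial_complex()].
#' @param p chain dimension, `1 <= p <= max_dim`.
#' @param a_p positive scale of the weighted boundary operator.
#' @return a sparse `Matrix` of dimension `n_{p-1} x n_p`.
#' @export
boundary_matrix <- function(K, p, a_p = 1) {
  stopifnot(inherits(K, "simplicial_complex"), a_p > 0)
  if (p < 1L || p > K$max_dim)
    stop("p must be between 1 and the complex dimension (", K$max_dim, ")")
  n_row <- K$n[p]
  n_col <- K$n[p + 1L]
  if (n_col == 0L)
    return(sparseMatrix(i = integer(), j = integer(), x = numeric(),
                        dims = c(n_row, 0L)))
  faces <- face_index_matrix(K, p)
  i <- as.vector(faces)
  j <- rep(seq_len(n_col), each = p + 1L)
  x <- rep_len(c(1, -1), p + 1L)[rep(seq_len(p + 1L), n_col)] * a_p
  sparseMatrix(i = i, j = j, x = x, dims = c(n_row, n_col))
}

## numerical rank via dense LAPACK QR; empty matrices have rank 0
rank_mat <- function(M) {
  if (is.null(M) || any(dim(M) == 0L)) return(0L)
  M <- as.matrix(M)
  d <- svd(M, nu = 0, nv = 0)$d
  sum(d > max(dim(M)) * max(d, 0) * .Machine$double.eps)
}

#' Betti numbers from boundary-matrix ranks
#'
#' `beta_p = n_p - rank(B_p) - rank(B_{p+1})`, with the boundary maps at the
#' ends of the chain complex treated as zero.
#'
#' @param K a [simplicial_complex()].
#' @param p_max highest dimension to report (default the complex dimension).
#' @return integer vector `(beta_0, ..., beta_{p_max})`.
#' @export
betti_numbers <- function(K, p_max = K$max_dim) {
  stopifnot(p_max >= 0)
  p_eff <- min(p_max, K$max_dim)
  ranks <- vapply(seq_len(K$max_dim), function(p) rank_mat(boundary_matrix(K, p)),
                  integer(1))
  rank_at <- function(p) if (p >= 1L && p <= K$max_dim) ranks[p] else 0L
  beta <- vapply(0:p_eff, function(p) {
    K$n[p + 1L] - rank_at(p) - rank_at(p + 1L)
  }, integer(1))
  if (p_max > K$max_dim) beta <- c(beta, rep(0L, p_max - K$max_dim))
  beta
}

## count of p-simplices, 0 when the dimension is absent
n_simplices <- function(K, p) {
  if (p < 0L || p > K$max_dim) 0L else K$n[p + 1L]
}
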