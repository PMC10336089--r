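## Discrete and weighted Dirac matrices, Hodge Laplacian blocks, spectra.
##
## The Dirac matrix of structural index p is the block-tridiagonal square
## matrix over chains of dimension 0..p+1 whose off-diagonal blocks are the
## boundary maps; its square is block diagonal with the Hodge Laplacians
## L_0, ..., L_p and the down Laplacian of the top block. Dimensions absent
## from the complex contribute blocks of size zero, so the Dirac matrix of a
## vertex-only complex is the all-zero n_0 x n_0 matrix.

## per-dimension block sizes n_0..n_{p+1} actually present in K
dirac_block_sizes <- function(K, p) {
  kmax <- min(p + 1L, K$max_dim)
  vapply(0:kmax, function(k) n_simplices(K, k), integer(1))
}

new_dirac_matrix <- function(matrix, p, block_n, weighted, sym_scale = NULL) {
  offsets <- cumsum(c(0L, block_n))
  structure(
    list(matrix = matrix, p = p, block_n = block_n, offsets = offsets,
         side = sum(block_n), weighted = weighted, sym_scale = sym_scale),
    class = "dirac_matrix")
}

#' @export
print.dirac_matrix <- function(x, ...) {
  cat(sprintf("%s Dirac matrix D_%d: %d x %d\n",
              if (x$weighted) "Weighted" else "Discrete", x$p, x$side, x$side))
  cat("  block sizes:", paste(x$block_n, collapse = ", "), "\n")
  invisible(x)
}

## assemble a block-tridiagonal sparse matrix from lists of upper and lower
## off-diagonal blocks (upper[[k]] maps dimension k chains to k-1)
assemble_blocks <- function(block_n, upper, lower) {
  side <- sum(block_n)
  offsets <- cumsum(c(0L, block_n))
  ijx <- list(i = integer(), j = integer(), x = numeric())
  add <- function(M, roff, coff) {
    M <- as(as(M, "CsparseMatrix"), "generalMatrix")
    tm <- methods::as(M, "TsparseMatrix")
    if (length(tm@x)) {
      ijx$i <<- c(ijx$i, tm@i + 1L + roff)
      ijx$j <<- c(ijx$j, tm@j + 1L + coff)
      ijx$x <<- c(ijx$x, tm@x)
    }
  }
  for (k in seq_along(upper)) {
    if (is.null(upper[[k]])) next
    add(upper[[k]], offsets[k], offsets[k + 1L])
    add(lower[[k]], offsets[k + 1L], offsets[k])
  }
  sparseMatrix(i = ijx$i, j = ijx$j, x = ijx$x, dims = c(side, side))
}

#' Discrete Dirac matrix
#'
#' Assembles the symmetric block-tridiagonal matrix with the unweighted
#' boundary matrices `B_1, ..., B_{p+1}` on the superdiagonal blocks and
#' their transposes below. Side length is the total number of simplices of
#' dimension at most `p + 1`.
#'
#' @param K a [simplicial_complex()].
#' @param p structural index (>= 0).
#' @return a `dirac_matrix` object holding a sparse symmetric matrix, the
#'   block sizes and offsets.
#' @examples
#' tri <- complete_complex(3, 2)     # filled triangle
#' assemble_dirac(tri, 1)            # 7 x 7
#' @export
assemble_dirac <- function(K, p) {
  stopifnot(inherits(K, "simplicial_complex"), p >= 0)
  block_n <- dirac_block_sizes(K, p)
  nb <- length(block_n) - 1L
  upper <- lower <- vector("list", max(nb, 0L))
  for (k in seq_len(nb)) {
    B <- boundary_matrix(K, k)
    upper[[k]] <- B
    lower[[k]] <- Matrix::t(B)
  }
  new_dirac_matrix(assemble_blocks(block_n, upper, lower), p, block_n,
                   weighted = FALSE)
}

#' Metric matrices from simplex weights
#'
#' Builds the diagonal metric matrices `G_p` by the descending coface
#' recursion: at the top dimension `G_d` equals the simplex weights, and for
#' `p < d` the metric of a p-simplex is its own weight plus the metric sum
#' of its (p+1)-dimensional cofaces.
#'
#' @param K a [simplicial_complex()].
#' @param w simplex weights: a list indexed by dimension + 1 of positive
#'   numeric vectors aligned with the canonical simplex ordering, or a
#'   single number recycled to every simplex.
#' @return an object of class `metric_weights`: list with `w` and `G`
#'   (per-dimension diagonal vectors).
#' @export
metric_matrices <- function(K, w = 1) {
  stopifnot(inherits(K, "simplicial_complex"))
  d <- K$max_dim
  if (!is.list(w))
    w <- lapply(seq_len(d + 1L), function(i) rep(as.numeric(w), K$n[i]))
  if (length(w) != d + 1L)
    stop("weights must cover dimensions 0..", d)
  for (i in seq_len(d + 1L)) {
    if (length(w[[i]]) != K$n[i])
      stop("dimension ", i - 1L, ": expected ", K$n[i], " weights")
    bad <- which(w[[i]] <= 0)
    if (length(bad))
      stop("non-positive weight on simplex {",
           paste(K$simplices[[i]][bad[1L], ], collapse = ","), "}")
  }
  G <- w
  if (d >= 1L) {
    for (p in (d - 1L):0L) {
      faces <- face_index_matrix(K, p + 1L)
      if (ncol(faces)) {
        contrib <- rep(G[[p + 2L]], each = nrow(faces))
        sums <- rowsum(contrib, as.vector(faces))
        idx <- as.integer(rownames(sums))
        G[[p + 1L]][idx] <- G[[p + 1L]][idx] + sums[, 1L]
      }
      if (p == 0L) break
    }
  }
  structure(list(w = w, G = G), class = "metric_weights")
}

#' Weighted Dirac matrix
#'
#' Assembles the weighted Dirac matrix whose subdiagonal blocks are
#' `a_p B_p'` and whose superdiagonal blocks are
#' `a_p G_{p-1}^{-1} B_p G_p`, with scale `a_p = (p + 1)^{-1/2}` by default.
#' With identity metrics and unit scales it reduces exactly to
#' [assemble_dirac()]. The matrix is generally non-symmetric, but conjugation
#' by the block-diagonal square-root metric yields a symmetric matrix with
#' the same (real) spectrum; the scaling vector is stored for the
#' eigensolver.
#'
#' @inheritParams assemble_dirac
#' @param metrics a `metric_weights` object from [metric_matrices()].
#' @param a per-dimension boundary scales `a_1, ..., a_{p+1}`; default
#'   `(k + 1)^{-1/2}` for dimension k.
#' @return a `dirac_matrix` with `weighted = TRUE`.
#' @export
assemble_weighted_dirac <- function(K, p, metrics, a = NULL) {
  stopifnot(inherits(K, "simplicial_complex"), p >= 0,
            inherits(metrics, "metric_weights"))
  block_n <- dirac_block_sizes(K, p)
  nb <- length(block_n) - 1L
  if (length(metrics$G) < nb + 1L)
    stop("metrics cover dimensions 0..", length(metrics$G) - 1L,
         " but the Dirac matrix needs 0..", nb)
  if (is.null(a)) a <- (seq_len(max(nb, 1L)) + 1)^(-1 / 2)
  if (length(a) < nb) stop("need boundary scales a_1..a_", nb)
  upper <- lower <- vector("list", max(nb, 0L))
  for (k in seq_len(nb)) {
    B <- boundary_matrix(K, k)
    Gk <- metrics$G[[k + 1L]]
    Gk1 <- metrics$G[[k]]
    upper[[k]] <- a[k] * (Diagonal(x = 1 / Gk1) %*% B %*% Diagonal(x = Gk))
    lower[[k]] <- a[k] * Matrix::t(B)
  }
  sym_scale <- sqrt(unlist(lapply(seq_along(block_n), function(i)
    metrics$G[[i]][seq_len(block_n[i])])))
  new_dirac_matrix(assemble_blocks(block_n, upper, lower), p, block_n,
                   weighted = TRUE, sym_scale = sym_scale)
}

## symmetric matrix sharing the spectrum of D (identity for unweighted)
dirac_symmetrized <- function(D) {
  M <- as.matrix(D$matrix)
  if (D$weighted && D$side > 0L) {
    s <- D$sym_scale
    M <- M * outer(s, 1 / s)
    M <- (M + t(M)) / 2
  }
  M
}

#' Eigenspectrum of a Dirac matrix
#'
#' Dense symmetric eigendecomposition. Weighted Dirac matrices are first
#' conjugated by the block-diagonal square-root metric, which makes them
#' symmetric and guarantees a real spectrum; eigenvectors are mapped back to
#' the original coordinates. Eigenvalues of any Dirac matrix are symmetric
#' about zero, so the spectrum is summarized by its nullity and its positive
#' part.
#'
#' @param D a `dirac_matrix`.
#' @param tol relative zero threshold: eigenvalues with
#'   `|lambda| <= tol * max(1, |lambda|_max)` count as zero.
#' @param vectors also return eigenvectors.
#' @return an object of class `dirac_spectrum`: sorted `values`, `nullity`,
#'   `positive` eigenvalues, the absolute threshold `tol` used, the matrix
#'   `side`, block structure, and optionally `vectors` (columns aligned with
#'   `values`).
#' @export
dirac_spectrum <- function(D, tol = 1e-8, vectors = FALSE) {
  stopifnot(inherits(D, "dirac_matrix"), tol > 0)
  if (D$side == 0L) {
    return(structure(list(values = numeric(), nullity = 0L,
                          positive = numeric(), tol = tol, side = 0L,
                          block_n = D$block_n, offsets = D$offsets,
                          vectors = if (vectors) matrix(numeric(), 0, 0)),
                     class = "dirac_spectrum"))
  }
  M <- dirac_symmetrized(D)
  eig <- eigen(M, symmetric = TRUE, only.values = !vectors)
  ord <- order(eig$values)
  values <- eig$values[ord]
  thr <- tol * max(1, abs(values))
  V <- NULL
  if (vectors) {
    V <- eig$vectors[, ord, drop = FALSE]
    if (D$weighted) V <- V / D$sym_scale
  }
  structure(
    list(values = values, nullity = sum(abs(values) <= thr),
         positive = values[values > thr], tol = thr, side = D$side,
         block_n = D$block_n, offsets = D$offsets, vectors = V),
    class = "dirac_spectrum")
}

#' @export
print.dirac_spectrum <- function(x, ...) {
  cat(sprintf("Dirac spectrum: side %d, nullity %d, %d positive eigenvalues\n",
              x$side, x$nullity, length(x$positive)))
  if (length(x$positive))
    cat(sprintf("  positive range: %.6g .. %.6g\n",
                min(x$positive), max(x$positive)))
  invisible(x)
}

#' Hodge Laplacian blocks of a Dirac matrix
#'
#' Returns the diagonal blocks of the squared Dirac matrix, assembled
#' directly from boundary matrices: the full Hodge Laplacians
#' `L_k = B_k' B_k + B_{k+1} B_{k+1}'` for `k = 0..p` and the down Laplacian
#' of the top block. With `metrics`, the metric Laplacians
#' `L_[k] = B_k' G_{k-1}^{-1} B_k G_k / (k+1) +
#' G_k^{-1} B_{k+1} G_{k+1} B_{k+1}' / (k+2)` are returned instead.
#'
#' @inheritParams assemble_dirac
#' @param metrics optional `metric_weights`.
#' @return list of square sparse matrices, one per block present in `D_p`.
#' @export
hodge_blocks <- function(K, p, metrics = NULL) {
  stopifnot(inherits(K, "simplicial_complex"), p >= 0)
  block_n <- dirac_block_sizes(K, p)
  nb <- length(block_n) - 1L
  B <- lapply(seq_len(nb), function(k) boundary_matrix(K, k))
  lapply(seq_along(block_n) - 1L, function(k) {
    down <- NULL
    up <- NULL
    if (k >= 1L) {
      if (is.null(metrics)) {
        down <- Matrix::t(B[[k]]) %*% B[[k]]
      } else {
        down <- Matrix::t(B[[k]]) %*% Diagonal(x = 1 / metrics$G[[k]]) %*%
          B[[k]] %*% Diagonal(x = metrics$G[[k + 1L]]) / (k + 1)
      }
    }
    if (k < nb) {
      if (is.null(metrics)) {
        up <- B[[k + 1L]] %*% Matrix::t(B[[k + 1L]])
      } else {
        up <- Diagonal(x = 1 / metrics$G[[k + 1L]]) %*% B[[k + 1L]] %*%
          Diagonal(x = metrics$G[[k + 2L]]) %*% Matrix::t(B[[k + 1L]]) / (k + 2)
      }
    }
    if (is.null(down) && is.null(up))
      return(sparseMatrix(i = integer(), j = integer(), x = numeric(),
                          dims = c(block_n[k + 1L], block_n[k + 1L])))
    if (is.null(down)) up else if (is.null(up)) down else down + up
  })
}

#' Supersymmetry residual of a discrete Dirac matrix
#'
#' The block sign matrix `Q_p` (sign `(-1)^k` on the dimension-k block)
#' anticommutes with `D_p`; the max-norm of `D Q + Q D` is reported.
#'
#' @param D an unweighted `dirac_matrix`.
#' @return list with `ok` (residual `<= 1e-12`) and `residual`.
#' @export
supersymmetry_check <- function(D) {
  stopifnot(inherits(D, "dirac_matrix"))
  q <- rep((-1)^(seq_along(D$block_n) - 1L), D$block_n)
  Q <- Diagonal(x = q)
  res <- if (D$side == 0L) 0 else max(abs(D$matrix %*% Q + Q %*% D$matrix))
  list(ok = res <= 1e-12, residual = res)
}

#' Kernel decomposition of the Dirac matrix
#'
#' The kernel dimension of `D_p` decomposes as
#' `rank(B_{p+2}') + sum_{k=0}^{p+1} beta_k`. Both sides are computed
#' independently: the nullity from the eigenspectrum (when `spectral`), the
#' right-hand side from boundary-matrix ranks.
#'
#' @inheritParams assemble_dirac
#' @param tol zero threshold passed to [dirac_spectrum()].
#' @param spectral also eigendecompose (set `FALSE` to use ranks only for
#'   large complexes).
#' @return list with `nullity` (spectral, `NA` when `spectral = FALSE`),
#'   `betti` (`beta_0..beta_{p+1}`), `rank_next` (rank of `B_{p+2}'`) and
#'   `identity` (= `rank_next + sum(betti)`).
#' @export
kernel_decomposition <- function(K, p, tol = 1e-8, spectral = TRUE) {
  beta <- betti_numbers(K, min(p + 1L, K$max_dim))
  if (p + 1L > K$max_dim) beta <- c(beta, rep(0L, p + 1L - K$max_dim))
  rank_next <- if (p + 2L <= K$max_dim)
    rank_mat(boundary_matrix(K, p + 2L)) else 0L
  nullity <- NA_integer_
  if (spectral)
    nullity <- dirac_spectrum(assemble_dirac(K, p), tol = tol)$nullity
  list(nullity = nullity, betti = beta, rank_next = rank_next,
       identity = rank_next + sum(beta))
}

## split a vector (or matrix columns) into per-dimension blocks
split_blocks <- function(v, block_n) {
  offsets <- cumsum(c(0L, block_n))
  lapply(seq_along(block_n), function(k) {
    idx <- seq_len(block_n[k]) + offsets[k]
    if (is.matrix(v)) v[idx, , drop = FALSE] else v[idx]
  })
}

#' Homology generators (kernel eigenvectors) of a Dirac matrix
#'
#' Kernel eigenvectors split into per-dimension blocks `w_0, ..., w_{p+1}`.
#' Each block of a kernel vector lies in the kernel of the corresponding
#' Hodge Laplacian block.
#'
#' @param D a `dirac_matrix`.
#' @param tol zero threshold passed to [dirac_spectrum()].
#' @return list with `vectors` (side x nullity matrix) and `blocks` (list of
#'   per-dimension row blocks of that matrix).
#' @export
homology_eigenvectors <- function(D, tol = 1e-8) {
  sp <- dirac_spectrum(D, tol = tol, vectors = TRUE)
  keep <- abs(sp$values) <= sp$tol
  V <- sp$vectors[, keep, drop = FALSE]
  list(vectors = V, blocks = split_blocks(V, D$block_n))
}

#' Non-homology generators of a Dirac matrix
#'
#' Eigenvectors of the smallest positive eigenvalues (the first is the
#' Fiedler vector), split into per-dimension blocks.
#'
#' @param D a `dirac_matrix`.
#' @param count number of eigenpairs requested; truncated with a warning if
#'   fewer positive eigenvalues exist.
#' @param tol zero threshold passed to [dirac_spectrum()].
#' @return list with `values`, `vectors` and `blocks` as in
#'   [homology_eigenvectors()].
#' @export
non_homology_eigenvectors <- function(D, count = 1L, tol = 1e-8) {
  sp <- dirac_spectrum(D, tol = tol, vectors = TRUE)
  pos <- which(sp$values > sp$tol)
  if (length(pos) < count) {
    warning("only ", length(pos), " positive eigenpairs available")
    count <- length(pos)
  }
  take <- pos[seq_len(count)]
  V <- sp$vectors[, take, drop = FALSE]
  list(values = sp$values[take], vectors = V,
       blocks = split_blocks(V, D$block_n))
}

#' Export a Dirac or boundary matrix in MatrixMarket format
#'
#' @param M a `dirac_matrix` or any `Matrix` object.
#' @param file output path (conventionally `.mtx`).
#' @return the file path, invisibly.
#' @export
export_matrix_market <- function(M, file) {
  if (inherits(M, "dirac_matrix")) M <- M$matrix
  writeMM(as(M, "CsparseMatrix"), file)
  invisible(file)
}
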