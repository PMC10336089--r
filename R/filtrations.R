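## Vietoris-Rips and Alpha filtrations from 3D point clouds.

new_filtration <- function(K, values) {
  structure(list(complex = K, values = values), class = "filtration")
}

#' @export
print.filtration <- function(x, ...) {
  rng <- range(unlist(x$values))
  cat("Filtration over a complex of dimension", x$complex$max_dim, "\n")
  cat("  simplex counts:", paste(x$complex$n, collapse = ", "), "\n")
  cat(sprintf("  filtration values: %.4g .. %.4g Angstrom\n", rng[1], rng[2]))
  invisible(x)
}

check_points <- function(points) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (nrow(points) < 1L) stop("need at least one point")
  if (!all(is.finite(points))) stop("non-finite coordinates in input")
  points
}

#' Vietoris-Rips filtration of a point cloud
#'
#' A simplex enters the filtration at the maximum pairwise distance among its
#' vertices (the diameter convention), so an edge appears at its Euclidean
#' length. All simplices up to `max_dim` whose value does not exceed
#' `max_radius` are enumerated by clique expansion of the distance graph.
#'
#' @param points numeric `N x 3` matrix of coordinates in Angstrom (any
#'   ambient dimension is accepted).
#' @param max_dim highest simplex dimension to build.
#' @param max_radius diameter cutoff in Angstrom.
#' @return a `filtration` object: the complex at `max_radius` plus a
#'   per-dimension list of entry values (vertices enter at 0).
#' @examples
#' square <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
#' rips_filtration(square, max_dim = 1, max_radius = 1.1)
#' @export
rips_filtration <- function(points, max_dim, max_radius) {
  stopifnot(max_dim >= 0, max_radius > 0)
  points <- check_points(points)
  n <- nrow(points)
  dmat <- as.matrix(dist(points))
  simplices <- list(matrix(0:(n - 1L), ncol = 1L))
  values <- list(rep(0, n))
  if (max_dim >= 1L && n >= 2L) {
    pairs <- which(upper.tri(dmat) & dmat <= max_radius, arr.ind = TRUE)
    if (nrow(pairs) > 0L) {
      edges <- cbind(pairs[, 1L], pairs[, 2L]) - 1L
      ord <- lex_order(edges)
      simplices[[2L]] <- edges[ord, , drop = FALSE]
      values[[2L]] <- dmat[pairs][ord]
      d <- 2L
      while (d <= max_dim && nrow(simplices[[d]]) > 0L) {
        prev <- simplices[[d]]
        prev_val <- values[[d]]
        new_rows <- vector("list", nrow(prev))
        new_vals <- vector("list", nrow(prev))
        for (r in seq_len(nrow(prev))) {
          s <- prev[r, ]
          cand <- which(seq_len(n) - 1L > s[d])
          if (length(cand) == 0L) next
          dd <- dmat[cand, s + 1L, drop = FALSE]
          ok <- rowSums(dd <= max_radius) == d
          cand <- cand[ok]
          if (length(cand) == 0L) next
          new_rows[[r]] <- cbind(matrix(s, length(cand), d, byrow = TRUE),
                                 cand - 1L)
          new_vals[[r]] <- pmax(prev_val[r],
                                apply(dd[ok, , drop = FALSE], 1L, max))
        }
        rows <- do.call(rbind, new_rows)
        if (is.null(rows) || nrow(rows) == 0L) break
        vals <- unlist(new_vals)
        ord <- lex_order(rows)
        simplices[[d + 1L]] <- rows[ord, , drop = FALSE]
        values[[d + 1L]] <- vals[ord]
        d <- d + 1L
      }
    }
  }
  K <- simplicial_complex(simplices, check = FALSE)
  new_filtration(K, values[seq_along(K$simplices)])
}

## circumradius of the rows of V (a k-simplex in ambient 3D), computed in
## the affine hull; returns +Inf for a numerically degenerate simplex
circumradius <- function(V) {
  if (nrow(V) == 1L) return(0)
  E <- sweep(V[-1L, , drop = FALSE], 2L, V[1L, ])
  A <- 2 * tcrossprod(E)
  b <- rowSums(E^2)
  y <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(y)) return(Inf)
  sqrt(max(sum((crossprod(E, y))^2), 0))
}

## circumcenter + radius of a tetrahedron; NULL if degenerate
circumsphere3 <- function(V) {
  E <- sweep(V[-1L, , drop = FALSE], 2L, V[1L, ])
  det3 <- det(E)
  if (!is.finite(det3) || abs(det3) < 1e-12 * max(abs(E), 1)^3) return(NULL)
  x <- solve(2 * E, rowSums(E^2))
  list(center = V[1L, ] + x, radius = sqrt(sum(x^2)))
}

## Brute-force Delaunay tetrahedra: empty-circumsphere test over all C(N,4)
## vertex quadruples. Intended for small molecular point clouds.
delaunay_tetrahedra <- function(points) {
  n <- nrow(points)
  quads <- combn(n, 4L)
  keep <- logical(ncol(quads))
  for (q in seq_len(ncol(quads))) {
    idx <- quads[, q]
    cs <- circumsphere3(points[idx, , drop = FALSE])
    if (is.null(cs)) next
    others <- setdiff(seq_len(n), idx)
    if (length(others) == 0L) {
      keep[q] <- TRUE
    } else {
      d2 <- rowSums(sweep(points[others, , drop = FALSE], 2L, cs$center)^2)
      keep[q] <- all(d2 >= cs$radius^2 * (1 - 1e-9))
    }
  }
  t(quads[, keep, drop = FALSE]) - 1L
}

## all d-faces (0-based rows) of a table of simplices
faces_of <- function(m, d) {
  k <- ncol(m)
  out <- do.call(rbind, lapply(combn(k, d + 1L, simplify = FALSE), function(ix)
    m[, ix, drop = FALSE]))
  unique(out)
}

#' Alpha filtration of a point cloud
#'
#' Simplices are restricted to the 3D Delaunay triangulation (computed by an
#' exhaustive empty-circumsphere test) and enter the filtration at their own
#' circumradius in Angstrom: an isolated pair of points spans an edge at half
#' their distance, a triangle enters at `abc / (4 Area)`. A face's
#' circumsphere radius never exceeds its coface's, so the values are
#' face-monotone; residual floating-point violations are clamped.
#'
#' Degenerate clouds (all points affinely dependent, e.g. planar molecules)
#' are jittered by `jitter_eps` with a fixed internal seed before the
#' Delaunay stage, and a message is emitted.
#'
#' @inheritParams rips_filtration
#' @param max_dim highest simplex dimension (capped at 3).
#' @param jitter_eps jitter amplitude in Angstrom for degenerate inputs.
#' @return a `filtration` object.
#' @export
alpha_filtration <- function(points, max_dim = 3, jitter_eps = 1e-9) {
  stopifnot(max_dim >= 0)
  points <- check_points(points)
  n <- nrow(points)
  max_dim <- min(max_dim, 3L, n - 1L)
  work <- points
  if (n >= 2L) {
    arank <- rank_mat(sweep(points, 2L, colMeans(points)))
    if (n >= 4L && arank < min(3L, n - 1L)) {
      message("alpha_filtration: degenerate point set, jittering by ",
              format(jitter_eps), " Angstrom")
      work <- points + jittered_noise(dim(points), jitter_eps)
    }
  }
  simplices <- list(matrix(0:(n - 1L), ncol = 1L))
  if (n >= 2L && max_dim >= 1L) {
    if (n <= 4L) {
      top <- t(matrix(0:(n - 1L)))
    } else {
      top <- delaunay_tetrahedra(work)
      if (nrow(top) == 0L) {
        message("alpha_filtration: no Delaunay cells, jittering by ",
                format(jitter_eps), " Angstrom")
        work <- points + jittered_noise(dim(points), jitter_eps)
        top <- delaunay_tetrahedra(work)
      }
    }
    top_dim <- ncol(top) - 1L
    for (d in seq_len(min(top_dim, 3L))) {
      simplices[[d + 1L]] <- faces_of(top, d)
    }
    simplices <- simplices[seq_len(min(max_dim, top_dim) + 1L)]
  }
  K <- simplicial_complex(simplices, check = FALSE)
  values <- lapply(seq_along(K$simplices), function(d) {
    m <- K$simplices[[d]]
    if (d == 1L) return(rep(0, nrow(m)))
    vapply(seq_len(nrow(m)), function(r)
      circumradius(work[m[r, ] + 1L, , drop = FALSE]), numeric(1))
  })
  ## clamp tiny monotonicity violations from floating point
  for (d in seq_along(values)[-1L]) {
    faces <- face_index_matrix(K, d - 1L)
    if (ncol(faces) == 0L) next
    face_max <- apply(matrix(values[[d - 1L]][faces], nrow(faces)), 2L, max)
    values[[d]] <- pmax(values[[d]], face_max)
  }
  new_filtration(K, values)
}

## deterministic jitter that leaves the caller's RNG stream untouched
jittered_noise <- function(dims, eps) {
  state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(state)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", state, envir = globalenv())
  })
  set.seed(285714L)
  matrix(runif(prod(dims), -eps, eps), dims[1L], dims[2L])
}

#' Sublevel complex of a filtration
#'
#' @param filt a `filtration`.
#' @param threshold filtration value in Angstrom.
#' @return the [simplicial_complex()] of all simplices with entry value
#'   `<= threshold`.
#' @export
sublevel_complex <- function(filt, threshold) {
  stopifnot(inherits(filt, "filtration"))
  simplices <- lapply(seq_along(filt$values), function(d) {
    keep <- filt$values[[d]] <= threshold
    filt$complex$simplices[[d]][keep, , drop = FALSE]
  })
  if (nrow(simplices[[1L]]) == 0L)
    stop("no vertices below threshold ", threshold)
  simplicial_complex(simplices, check = FALSE)
}

## per-dimension filtration values restricted to a sublevel complex
sublevel_values <- function(filt, threshold) {
  vals <- lapply(filt$values, function(v) v[v <= threshold])
  vals[vapply(vals, length, integer(1)) > 0L | seq_along(vals) == 1L]
}
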