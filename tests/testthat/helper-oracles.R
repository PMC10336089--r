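# Independent oracles used to cross-check the package implementation.
# Everything here deliberately avoids the package's own linear algebra
# paths: union-find over edges, GF(2) column reduction for persistence,
# and an entrywise adjacency-rule constructor for Hodge Laplacians.

# number of connected components of the 1-skeleton, by union-find
uf_components <- function(K) {
  n <- K$n[1]
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (K$max_dim >= 1) {
    edges <- K$simplices[[2]]
    for (r in seq_len(nrow(edges))) {
      a <- find(edges[r, 1] + 1L)
      b <- find(edges[r, 2] + 1L)
      if (a != b) parent[a] <- b
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

# flatten a filtration into one global simplex list sorted by
# (value, dimension, lexicographic order)
flatten_filtration <- function(filt) {
  simp <- list()
  vals <- numeric()
  dims <- integer()
  for (d in seq_along(filt$values)) {
    m <- filt$complex$simplices[[d]]
    for (r in seq_len(nrow(m))) {
      simp[[length(simp) + 1L]] <- m[r, ]
      vals <- c(vals, filt$values[[d]][r])
      dims <- c(dims, d - 1L)
    }
  }
  keys <- vapply(simp, paste, character(1), collapse = ",")
  ord <- order(vals, dims, keys, method = "radix")
  list(simplices = simp[ord], values = vals[ord], dims = dims[ord])
}

# classic persistence barcode by GF(2) column reduction; returns a data
# frame with columns dim, birth, death (Inf for essential classes)
gf2_barcode <- function(filt) {
  fl <- flatten_filtration(filt)
  m <- length(fl$simplices)
  keys <- vapply(fl$simplices, paste, character(1), collapse = ",")
  index_of <- function(s) match(paste(s, collapse = ","), keys)
  cols <- vector("list", m)
  for (j in seq_len(m)) {
    s <- fl$simplices[[j]]
    if (length(s) == 1L) {
      cols[[j]] <- integer()
    } else {
      faces <- vapply(seq_along(s), function(i)
        index_of(s[-i]), integer(1))
      cols[[j]] <- sort(faces)
    }
  }
  low_owner <- integer(m)          # 0 = unclaimed
  death_of <- rep(Inf, m)          # death value per birth simplex index
  paired <- logical(m)
  for (j in seq_len(m)) {
    col <- cols[[j]]
    while (length(col) > 0L) {
      low <- col[length(col)]
      if (low_owner[low] == 0L) break
      other <- cols[[low_owner[low]]]
      col <- sort(setdiff(union(col, other), intersect(col, other)))
    }
    cols[[j]] <- col
    if (length(col) > 0L) {
      low <- col[length(col)]
      low_owner[low] <- j
      death_of[low] <- fl$values[j]
      paired[j] <- TRUE            # j is a death, not a birth
    }
  }
  births <- which(!paired)
  data.frame(dim = fl$dims[births], birth = fl$values[births],
             death = death_of[births])
}

# persistent Betti number from a barcode: classes alive at a surviving to b
barcode_betti <- function(bars, k, a, b = a) {
  sum(bars$dim == k & bars$birth <= a & bars$death > b)
}

# unweighted Hodge Laplacian of dimension p from the entrywise adjacency
# rules: diagonal = coface count (+ p + 1 for p > 0); off-diagonal 0 when
# upper adjacent, else the product of the signs of the shared face in the
# two boundaries when lower adjacent
entrywise_laplacian <- function(K, p) {
  keyrows <- function(m) apply(m, 1, paste, collapse = ",")
  simp <- K$simplices[[p + 1]]
  n <- nrow(simp)
  L <- matrix(0, n, n)
  cofaces <- if (p + 1 <= K$max_dim) K$simplices[[p + 2]] else
    matrix(integer(), 0, p + 2)
  coface_sets <- lapply(seq_len(nrow(cofaces)), function(r) cofaces[r, ])
  upper_count <- integer(n)
  skeys <- if (n > 0) keyrows(simp) else character()
  upper_pairs <- new.env()
  for (cf in coface_sets) {
    facets <- vapply(seq_along(cf), function(i)
      match(paste(cf[-i], collapse = ","), skeys), integer(1))
    upper_count[facets] <- upper_count[facets] + 1L
    for (a in facets) for (b in facets) if (a != b)
      assign(paste(a, b), TRUE, envir = upper_pairs)
  }
  diag(L) <- upper_count + if (p > 0) p + 1 else 0
  if (p == 0 && n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (!is.null(upper_pairs[[paste(i, j)]])) {
        L[i, j] <- -1
        L[j, i] <- -1
      }
    }
  }
  if (p > 0 && n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      shared <- intersect(simp[i, ], simp[j, ])
      if (length(shared) != p) next               # not lower adjacent
      if (!is.null(upper_pairs[[paste(i, j)]])) next  # upper adjacent
      sgn <- function(s, face) (-1)^(which(!(s %in% face)) - 1)
      v <- sgn(simp[i, ], shared) * sgn(simp[j, ], shared)
      L[i, j] <- v
      L[j, i] <- v
    }
  }
  L
}
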