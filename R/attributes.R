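## Persistent spectral attributes of a Dirac spectrum.
##
## All statistics are taken over the positive eigenvalues only: the nonzero
## eigenvalues of any Dirac matrix come in +/- pairs, so the negative half
## carries no extra information, and the pair count is the signless
## Euler-Poincare number.

#' Dirac zeta function
#'
#' `zeta(s) = sum_j lambda_j^{-s}` over the positive eigenvalues. Negative
#' arguments give spectral moments (`zeta(-1)` is the Laplacian graph
#' energy, `zeta(-2)` the second spectral moment); `zeta(0)` counts the
#' positive eigenvalues. The empty spectrum gives 0.
#'
#' @param positive_eigenvalues numeric vector of positive eigenvalues.
#' @param s exponent.
#' @return the zeta value.
#' @export
dirac_zeta <- function(positive_eigenvalues, s) {
  if (length(positive_eigenvalues) == 0L) return(0)
  if (any(positive_eigenvalues <= 0)) stop("eigenvalues must be positive")
  sum(positive_eigenvalues^(-s))
}

#' Signless Euler-Poincare number
#'
#' The number of nonzero eigenvalue pairs of a Dirac matrix:
#' `(side - nullity) / 2`.
#'
#' @param matrix_side side length of the Dirac matrix.
#' @param nullity multiplicity of the zero eigenvalue.
#' @return a non-negative integer.
#' @export
euler_poincare <- function(matrix_side, nullity) {
  stopifnot(matrix_side >= nullity)
  diff <- matrix_side - nullity
  if (diff %% 2L != 0L)
    stop("side minus nullity is odd; the zero tolerance upstream is off")
  as.integer(diff / 2L)
}

#' q-Dirac complexity (log scale)
#'
#' `c_q` is the product of `lambda^q` over all nonzero eigenvalues, taken in
#' magnitude: the nonzero eigenvalues come in +/- pairs, so each pair
#' contributes `lambda_j^{2q}` and `|c_q| = prod_j lambda_j^{2q}` over the
#' positive eigenvalues (for the filled triangle, `c_1 = 3^3 = 27`).
#' Returned as `log c_q` to avoid overflow; the empty spectrum gives 0
#' (`c_q = 1`).
#'
#' @inheritParams dirac_zeta
#' @param q exponent.
#' @return `log c_q` (natural logarithm).
#' @export
dirac_complexity <- function(positive_eigenvalues, q) {
  if (length(positive_eigenvalues) == 0L) return(0)
  if (any(positive_eigenvalues <= 0)) stop("eigenvalues must be positive")
  q * sum(log(positive_eigenvalues^2))
}

#' Spanning-tree number
#'
#' `t(D_p) = log(c_1) / 2 - log(l + 1)` with `l` the Euler-Poincare number
#' and `c_1` the 1-Dirac complexity in magnitude; natural logarithms. The
#' empty spectrum gives 0.
#'
#' @inheritParams dirac_zeta
#' @param ell Euler-Poincare number (defaults to the count of positive
#'   eigenvalues).
#' @return the spanning-tree number.
#' @export
spanning_tree_number <- function(positive_eigenvalues,
                                 ell = length(positive_eigenvalues)) {
  dirac_complexity(positive_eigenvalues, 1) / 2 - log(ell + 1)
}

#' Names of the 12 persistent attributes
#'
#' Stable column labels, in the canonical order.
#' @return character vector of length 12.
#' @export
attribute_names <- function() {
  c("fiedler", "max", "mean", "std", "energy", "euler_poincare",
    "gen_mean_energy", "moment2", "zeta2", "quasi_wiener", "spanning_tree",
    "multiplicity")
}

#' The ordered 12-attribute vector of a Dirac spectrum
#'
#' From the positive eigenvalues `{lambda_1..lambda_n}` of a Dirac matrix:
#' (i) Fiedler value (smallest positive eigenvalue), (ii) largest
#' eigenvalue, (iii) mean, (iv) population standard deviation, (v) Laplacian
#' graph energy `zeta(-1)`, (vi) signless Euler-Poincare number, (vii)
#' generalized mean graph energy `sum |lambda_i - mean| / n`, (viii)
#' spectral second moment `zeta(-2)`, (ix) `zeta(2) = 2 sum lambda_j^{-2}`,
#' (x) quasi-Wiener index `(n + 1) zeta(1)`, (xi) spanning-tree number,
#' (xii) persistent multiplicity (nullity). An empty positive spectrum
#' (all-zero matrix) gives zeros for (i)-(xi) and the matrix side for (xii).
#'
#' @param spec a `dirac_spectrum` (or a list with `positive` and `nullity`).
#' @param matrix_side side of the Dirac matrix the spectrum came from.
#' @return named numeric vector of length 12 (names [attribute_names()]).
#' @export
attribute_vector <- function(spec, matrix_side = spec$side) {
  lam <- spec$positive
  out <- numeric(12L)
  names(out) <- attribute_names()
  out["multiplicity"] <- spec$nullity
  if (length(lam) == 0L) return(out)
  n <- length(lam)
  lbar <- mean(lam)
  out["fiedler"] <- min(lam)
  out["max"] <- max(lam)
  out["mean"] <- lbar
  out["std"] <- sqrt(mean((lam - lbar)^2))
  out["energy"] <- dirac_zeta(lam, -1)
  out["euler_poincare"] <- euler_poincare(matrix_side, spec$nullity)
  out["gen_mean_energy"] <- sum(abs(lam - lbar)) / n
  out["moment2"] <- dirac_zeta(lam, -2)
  out["zeta2"] <- 2 * dirac_zeta(lam, 2)
  out["quasi_wiener"] <- (n + 1) * dirac_zeta(lam, 1)
  out["spanning_tree"] <- spanning_tree_number(lam, out["euler_poincare"])
  out
}
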