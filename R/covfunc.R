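#' Standardize days in milk to the Legendre domain
#'
#' Maps days in milk (DIM) linearly onto \[-1, 1\], the domain on which the
#' Legendre polynomial basis is orthonormal. The default range is the edit
#' window of the test-day data, DIM 5 to 365.
#'
#' @param t numeric vector of DIM values.
#' @param dim_range length-2 numeric, the DIM window \code{c(t_min, t_max)}.
#' @return numeric vector of standardized values in \[-1, 1\].
#' @examples
#' standardize_dim(c(5, 185, 365))
#' @export
standardize_dim <- function(t, dim_range = c(5, 365)) {
  stopifnot(length(dim_range) == 2, dim_range[1] < dim_range[2])
  if (any(t < dim_range[1] - 1e-9 | t > dim_range[2] + 1e-9)) {
    stop("DIM value outside the standardization range [", dim_range[1], ", ",
         dim_range[2], "]; apply the data edits first")
  }
  2 * (t - dim_range[1]) / (dim_range[2] - dim_range[1]) - 1
}

#' Legendre polynomial basis
#'
#' Evaluates the Legendre polynomial basis of a given order at standardized
#' time points. By default the polynomials are normalized to be orthonormal
#' on \[-1, 1\]: \eqn{\phi_b(x) = \sqrt{(2b+1)/2}\, P_b(x)} with \eqn{P_b}
#' the classical Legendre polynomials, the convention dominant in random
#' regression test-day software. The classical (unnormalized) basis is
#' available with \code{normalized = FALSE}; using it only rescales the
#' coefficient covariance matrices.
#'
#' @param x numeric vector of standardized time points in \[-1, 1\].
#' @param order integer >= 0, the polynomial order (basis has order + 1
#'   columns).
#' @param normalized logical, use the orthonormal scaling (default TRUE).
#' @return numeric matrix, \code{length(x)} rows by \code{order + 1} columns;
#'   column \code{b + 1} holds \eqn{\phi_b(x)}.
#' @examples
#' legendre_basis(0, order = 2)
#' @export
legendre_basis <- function(x, order, normalized = TRUE) {
  stopifnot(order >= 0)
  if (any(abs(x) > 1 + 1e-9)) stop("standardized time outside [-1, 1]")
  n <- length(x)
  P <- matrix(0, n, order + 1)
  P[, 1] <- 1
  if (order >= 1) P[, 2] <- x
  if (order >= 2) {
    for (b in 2:order) {
      # three-term recurrence: b P_b = (2b-1) x P_{b-1} - (b-1) P_{b-2}
      P[, b + 1] <- ((2 * b - 1) * x * P[, b] - (b - 1) * P[, b - 1]) / b
    }
  }
  if (normalized) P <- sweep(P, 2, sqrt((2 * seq(0, order) + 1) / 2), `*`)
  P
}

#' Legendre basis evaluated on a DIM grid
#'
#' Convenience wrapper combining [standardize_dim()] and [legendre_basis()].
#'
#' @inheritParams standardize_dim
#' @inheritParams legendre_basis
#' @return matrix with \code{length(t)} rows and \code{order + 1} columns.
#' @export
dim_basis <- function(t, order, dim_range = c(5, 365), normalized = TRUE) {
  legendre_basis(standardize_dim(t, dim_range), order, normalized)
}

#' Evaluate a covariance function at pairs of days in milk
#'
#' Computes \eqn{\phi(t)' K \phi(s)} for a random-regression coefficient
#' covariance matrix \code{K}. For a multiple-trait \code{K} laid out in
#' trait blocks of size \code{order + 1}, the trait-block bilinear form is
#' returned: element \code{[j, k]} of the result is the covariance between
#' trait j at DIM \code{t} and trait k at DIM \code{s}.
#'
#' @param K symmetric coefficient covariance matrix of dimension
#'   \code{n_traits * (order + 1)}.
#' @param t,s days in milk (scalars). \code{s} defaults to \code{t}, giving
#'   variances on the diagonal.
#' @param order polynomial order of the random regression (default 2).
#' @param dim_range DIM window used for standardization.
#' @param normalized logical, orthonormal Legendre scaling.
#' @return an \code{n_traits} by \code{n_traits} matrix (a scalar matrix for
#'   one trait).
#' @examples
#' evaluate_covariance(diag(3), t = 100)          # single trait variance
#' @export
evaluate_covariance <- function(K, t, s = t, order = 2,
                                dim_range = c(5, 365), normalized = TRUE) {
  q <- order + 1
  d <- nrow(K)
  if (is.null(d) || d != ncol(K) || d %% q != 0) {
    stop("K must be square with dimension a multiple of order + 1 = ", q)
  }
  n_traits <- d %/% q
  phi_t <- drop(dim_basis(t, order, dim_range, normalized))
  phi_s <- drop(dim_basis(s, order, dim_range, normalized))
  # Phi is block-diagonal (I_traits x phi'): result = Phi_t K Phi_s'
  Pt <- kronecker(diag(n_traits), matrix(phi_t, nrow = 1))
  Ps <- kronecker(diag(n_traits), matrix(phi_s, nrow = 1))
  Pt %*% K %*% t(Ps)
}

# Variance trajectories for every trait over a DIM grid.
# Returns a length(grid) x n_traits matrix of phi(t)' K_jj phi(t).
variance_grid <- function(K, grid, order = 2, dim_range = c(5, 365)) {
  q <- order + 1
  n_traits <- nrow(K) %/% q
  Phi <- dim_basis(grid, order, dim_range)
  out <- matrix(NA_real_, length(grid), n_traits)
  for (j in seq_len(n_traits)) {
    idx <- (j - 1) * q + seq_len(q)
    out[, j] <- rowSums((Phi %*% K[idx, idx, drop = FALSE]) * Phi)
  }
  out
}

# Cross-covariance trajectory between two trait blocks over a DIM grid.
covariance_grid <- function(K, grid, j, k, order = 2, dim_range = c(5, 365)) {
  q <- order + 1
  Phi <- dim_basis(grid, order, dim_range)
  ij <- (j - 1) * q + seq_len(q)
  ik <- (k - 1) * q + seq_len(q)
  rowSums((Phi %*% K[ij, ik, drop = FALSE]) * Phi)
}
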