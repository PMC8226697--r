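#' Model specification for the random regression test-day model
#'
#' Declares the trait columns treated as model traits and the structure of
#' the fixed and random parts: a herd-test-day(-parity) class effect (the
#' overall mean is absorbed into it), an age-season fixed regression of
#' order \code{fixed_order}, and additive-genetic plus permanent-environment
#' random regressions of order \code{rr_order}. Traits recorded on the same
#' test-day share a full residual covariance block; residuals are
#' independent across test-days.
#'
#' @param traits character vector of trait column names. When parities are
#'   analyzed as separate traits, pre-split the columns (one model trait per
#'   trait-parity combination).
#' @param rr_order order of the random regressions (default 2).
#' @param fixed_order order of the age-season regression (default 4).
#' @param dim_range DIM window for basis standardization.
#' @param use_as include the age-season regression (default TRUE).
#' @return list of class \code{model_spec}.
#' @export
model_spec <- function(traits, rr_order = 2, fixed_order = 4,
                       dim_range = c(5, 365), use_as = TRUE) {
  stopifnot(length(traits) >= 1, rr_order >= 0)
  structure(list(traits = traits, rr_order = rr_order,
                 fixed_order = fixed_order, dim_range = dim_range,
                 use_as = use_as),
            class = "model_spec")
}

#' Build design structures for the sampler
#'
#' Indexes every record against dense, contiguous effect levels:
#' herd-test-day classes keyed by (herd, test_date, parity), age-season
#' classes by the \code{as_class} column (see [assign_age_season()]), animal
#' effects over all pedigree animals (phenotyped or not), and permanent
#' environment effects over phenotyped cows only (one coefficient vector per
#' cow per model trait, shared across parities). Also evaluates the Legendre
#' bases at each record's DIM.
#'
#' @param records edited test-day data.frame; must contain the spec's trait
#'   columns and, when \code{use_as} is TRUE, an \code{as_class} column.
#' @param pedigree a \code{pedigree_table} covering every record's cow.
#' @param spec a [model_spec()].
#' @return list of class \code{design_index} with elements \code{Y},
#'   \code{Phi_a}, \code{Phi_f}, index vectors \code{animal}, \code{pe},
#'   \code{htd}, \code{as_cls}, level tables, \code{n_equations}, and a
#'   \code{diagnostics} list (e.g. single-record HTD classes).
#' @export
build_design <- function(records, pedigree, spec) {
  stopifnot(inherits(spec, "model_spec"))
  miss <- setdiff(spec$traits, names(records))
  if (length(miss)) stop("trait columns absent from records: ",
                         paste(miss, collapse = ", "))
  Y <- as.matrix(records[spec$traits])
  if (anyNA(Y)) stop("missing trait values; run apply_edits() first ",
                     "(the model requires complete test-days)")

  anim <- match(as.character(records$cow), pedigree$animal)
  if (anyNA(anim)) stop("records reference cows absent from the pedigree")

  htd_key <- paste(records$herd, records$test_date, records$parity,
                   sep = "\r")
  htd_levels <- unique(htd_key)
  htd <- match(htd_key, htd_levels)

  pe_levels <- unique(as.character(records$cow))
  pe <- match(as.character(records$cow), pe_levels)

  if (spec$use_as) {
    if (is.null(records$as_class)) {
      stop("records lack as_class; call assign_age_season() first")
    }
    as_levels <- unique(as.character(records$as_class))
    as_cls <- match(as.character(records$as_class), as_levels)
    Phi_f <- dim_basis(records$dim, spec$fixed_order, spec$dim_range)
  } else {
    as_levels <- character(0)
    as_cls <- integer(0)
    Phi_f <- matrix(0, nrow(records), 0)
  }
  Phi_a <- dim_basis(records$dim, spec$rr_order, spec$dim_range)

  T <- length(spec$traits)
  q <- spec$rr_order + 1
  p <- if (spec$use_as) spec$fixed_order + 1 else 0
  n_eq <- T * (length(htd_levels) + p * length(as_levels)) +
    q * T * (nrow(pedigree) + length(pe_levels))
  htd_counts <- tabulate(htd)
  structure(list(
    Y = Y, Phi_a = Phi_a, Phi_f = Phi_f,
    animal = anim, pe = pe, htd = htd, as_cls = as_cls,
    htd_levels = htd_levels, as_levels = as_levels, pe_levels = pe_levels,
    n_animals = nrow(pedigree), n_traits = T, q = q, p = p,
    rr_order = spec$rr_order, fixed_order = spec$fixed_order,
    dim_range = spec$dim_range, trait_names = spec$traits,
    dim = records$dim,
    n_equations = n_eq,
    diagnostics = list(
      n_single_record_htd = sum(htd_counts == 1L),
      htd_counts = htd_counts)),
    class = "design_index")
}

#' Dense mixed-model-equation solve (small-instance oracle)
#'
#' Assembles and solves the full mixed model equations with all covariance
#' components held fixed, by generalized least squares on the dense system.
#' This is the independent cross-check for the sampler's conditional means
#' and Gauss-Seidel mode; it refuses systems above \code{max_eq} equations.
#'
#' @param design a \code{design_index}.
#' @param Ainv sparse A-inverse over the design's animals.
#' @param K_a,K_pe,R covariance components to condition on.
#' @param ridge_fixed optional ridge added to fixed-effect diagonal blocks
#'   (resolves the HTD/age-season level confounding in the dense solve;
#'   default 0).
#' @param max_eq refusal threshold (default 2000).
#' @return list with effect solutions \code{H}, \code{AS}, \code{U},
#'   \code{P} shaped like the sampler's posterior means, and \code{fitted},
#'   the n x T matrix of fitted values.
#' @export
solve_mme_dense <- function(design, Ainv, K_a, K_pe, R, ridge_fixed = 0,
                            max_eq = 2000) {
  d <- design
  T <- d$n_traits; q <- d$q; p <- d$p
  n <- nrow(d$Y)
  n_htd <- length(d$htd_levels); n_as <- length(d$as_levels)
  n_anim <- d$n_animals; n_pe <- length(d$pe_levels)
  n_eq <- n_htd * T + n_as * p * T + (n_anim + n_pe) * q * T
  if (n_eq > max_eq) stop("system has ", n_eq, " equations; oracle cap is ",
                          max_eq)
  off_as <- n_htd * T
  off_u <- off_as + n_as * p * T
  off_p <- off_u + n_anim * q * T

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (r in seq_len(n)) {
    rows <- (r - 1) * T + seq_len(T)
    for (j in seq_len(T)) {
      ii <- c(ii, rows[j]); jj <- c(jj, (d$htd[r] - 1) * T + j); xx <- c(xx, 1)
      if (p > 0) {
        cols <- off_as + (d$as_cls[r] - 1) * p * T + (j - 1) * p + seq_len(p)
        ii <- c(ii, rep(rows[j], p)); jj <- c(jj, cols)
        xx <- c(xx, d$Phi_f[r, ])
      }
      colsU <- off_u + (d$animal[r] - 1) * q * T + (j - 1) * q + seq_len(q)
      ii <- c(ii, rep(rows[j], q)); jj <- c(jj, colsU); xx <- c(xx, d$Phi_a[r, ])
      colsP <- off_p + (d$pe[r] - 1) * q * T + (j - 1) * q + seq_len(q)
      ii <- c(ii, rep(rows[j], q)); jj <- c(jj, colsP); xx <- c(xx, d$Phi_a[r, ])
    }
  }
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n * T, n_eq))
  Om <- Matrix::kronecker(Matrix::Diagonal(n), solve(R))
  LHS <- Matrix::t(W) %*% Om %*% W
  Kainv <- solve(K_a); Kpeinv <- solve(K_pe)
  G <- Matrix::bdiag(
    Matrix::Diagonal(off_as, ridge_fixed),
    Matrix::Diagonal(off_u - off_as, ridge_fixed),
    Matrix::kronecker(Ainv, Kainv),
    Matrix::kronecker(Matrix::Diagonal(n_pe), Kpeinv))
  LHS <- LHS + G
  yv <- as.vector(t(d$Y))
  RHS <- Matrix::t(W) %*% Om %*% yv
  sol <- as.vector(Matrix::solve(LHS, RHS))
  H <- matrix(sol[seq_len(off_as)], n_htd, T, byrow = TRUE)
  AS <- if (n_as > 0) matrix(sol[(off_as + 1):off_u], n_as, p * T,
                             byrow = TRUE) else matrix(0, 0, p * T)
  U <- matrix(sol[(off_u + 1):off_p], n_anim, q * T, byrow = TRUE)
  P <- matrix(sol[(off_p + 1):n_eq], n_pe, q * T, byrow = TRUE)
  fitted <- matrix(as.vector(W %*% sol), n, T, byrow = TRUE)
  list(H = H, AS = AS, U = U, P = P, fitted = fitted)
}

#' Fitted values from effect solutions
#'
#' Evaluates the model at each record given effect matrices shaped as the
#' sampler returns them (posterior means or any fixed solution).
#'
#' @param design a \code{design_index}.
#' @param effects list with elements \code{H}, \code{AS}, \code{U}, \code{P}.
#' @return n x T matrix of fitted values.
#' @export
fitted_values <- function(design, effects) {
  d <- design
  T <- d$n_traits; q <- d$q; p <- d$p
  n <- nrow(d$Y)
  out <- matrix(0, n, T)
  for (j in seq_len(T)) {
    out[, j] <- effects$H[cbind(d$htd, j)]
    iu <- (j - 1) * q + seq_len(q)
    out[, j] <- out[, j] +
      rowSums(d$Phi_a * effects$U[d$animal, iu, drop = FALSE]) +
      rowSums(d$Phi_a * effects$P[d$pe, iu, drop = FALSE])
    if (p > 0) {
      ia <- (j - 1) * p + seq_len(p)
      out[, j] <- out[, j] +
        rowSums(d$Phi_f * effects$AS[d$as_cls, ia, drop = FALSE])
    }
  }
  out
}
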