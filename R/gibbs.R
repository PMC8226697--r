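#' Default priors and starting values for the variance components
#'
#' Weakly informative inverted-Wishart priors centered on a phenotypic
#' variance split: the additive and permanent environment coefficient
#' covariances start with a DIM-average variance of 20% of the observed
#' phenotypic variance of each trait, the residual covariance at 60%.
#' Degrees of freedom are \code{dim + 2} and the prior scale is the starting
#' matrix, so the prior mean equals the start.
#'
#' @param Y n x T matrix of responses.
#' @param q number of random-regression coefficients per trait.
#' @return list with \code{Ka0}, \code{Kpe0}, \code{R0} (starting values =
#'   prior scales) and \code{nu_a}, \code{nu_pe}, \code{nu_r}.
#' @export
default_priors <- function(Y, q) {
  T <- ncol(Y)
  vp <- apply(Y, 2, stats::var)
  # DIM-average of phi_b(t)^2 is 1/2 for each b, so a coefficient diagonal
  # of 0.4 vp / q gives a 0.2 vp average variance
  dka <- rep(0.4 * vp / q, each = q)
  Ka0 <- diag(dka, T * q)
  Kpe0 <- Ka0
  R0 <- diag(0.6 * vp, T)
  list(Ka0 = Ka0, Kpe0 = Kpe0, R0 = R0,
       nu_a = T * q + 2, nu_pe = T * q + 2, nu_r = T + 2)
}

#' Run the Gibbs sampler for the random regression test-day model
#'
#' Alternates blocked draws of all location effects (herd-test-day classes,
#' age-season regressions, per-animal additive and per-cow permanent
#' environment coefficient vectors) with inverted-Wishart draws of the three
#' covariance components. Additive effects are linked across relatives
#' through the sparse A-inverse.
#'
#' @param design a \code{design_index} from [build_design()].
#' @param Ainv sparse A-inverse over the design's animals (see
#'   [a_inverse()]).
#' @param n_iter total iterations.
#' @param burn_in discarded initial iterations.
#' @param thin store every thin-th post-burn-in covariance sample
#'   (default 10; thinning is storage pragmatism, the estimators use all
#'   stored samples).
#' @param seed integer seed; the chain is exactly reproducible.
#' @param priors optional list as returned by [default_priors()].
#' @param sample_effects draw effects stochastically (TRUE) or set them to
#'   their conditional means, a Gauss-Seidel sweep (FALSE; for oracle
#'   comparisons).
#' @param sample_cov update covariance components (TRUE) or hold them at
#'   their starting values (FALSE).
#' @param n_realloc sweeps per iteration of the additive/PE scaled
#'   reallocation moves that speed mixing of the variance split (0
#'   disables them; the stationary distribution is the same either way).
#' @return object of class \code{posterior_chain}: list with sample matrices
#'   \code{Ka}, \code{Kpe}, \code{R} (one row per retained sample, matrices
#'   vectorized column-major), posterior-mean effects, and metadata.
#' @export
run_chain <- function(design, Ainv, n_iter, burn_in, thin = 10, seed = 1,
                      priors = NULL, sample_effects = TRUE,
                      sample_cov = TRUE, n_realloc = 5) {
  stopifnot(inherits(design, "design_index"))
  if (n_iter <= burn_in) stop("n_iter must exceed burn_in")
  if ((n_iter - burn_in) %/% thin < 1) {
    stop("chain would retain 0 samples; lower thin or raise n_iter")
  }
  if (is.null(priors)) priors <- default_priors(design$Y, design$q)
  Ag <- methods::as(methods::as(Ainv, "generalMatrix"), "CsparseMatrix")
  set.seed(seed)
  res <- .gibbs_rrtdm(design$Y, design$Phi_a, design$Phi_f,
                      design$animal, design$pe, design$htd,
                      as.integer(design$as_cls), Ag,
                      priors$Ka0, priors$Kpe0, priors$R0,
                      priors$Ka0, priors$Kpe0, priors$R0,
                      priors$nu_a, priors$nu_pe, priors$nu_r,
                      as.integer(n_iter), as.integer(burn_in),
                      as.integer(thin), sample_effects, sample_cov,
                      as.integer(n_realloc))
  structure(list(
    Ka = res$Ka, Kpe = res$Kpe, R = res$R,
    effects = list(H = res$H_mean, AS = res$AS_mean,
                   U = res$U_mean, P = res$P_mean),
    n_kept = res$n_kept,
    n_iter = n_iter, burn_in = burn_in, thin = thin, seed = seed,
    n_traits = design$n_traits, q = design$q,
    rr_order = design$rr_order, dim_range = design$dim_range,
    trait_names = design$trait_names, priors = priors),
    class = "posterior_chain")
}

#' @method print posterior_chain
#' @export
print.posterior_chain <- function(x, ...) {
  cat("Posterior chain:", x$n_kept, "retained samples (",
      x$n_iter, "iterates,", x$burn_in, "burn-in, thin", x$thin, ")\n")
  cat("  traits:", paste(x$trait_names, collapse = ", "),
      "| RR order:", x$rr_order, "\n")
  Km <- matrix(colMeans(x$Ka), x$n_traits * x$q)
  cat("  posterior mean trace(K_a):", signif(sum(diag(Km)), 4), "\n")
  invisible(x)
}

# reshape one retained sample row into its matrix
chain_matrix <- function(chain, component, s) {
  M <- chain[[component]]
  d <- as.integer(sqrt(ncol(M)))
  matrix(M[s, ], d, d)
}

#' Posterior mean of a covariance component
#'
#' @param chain a \code{posterior_chain}.
#' @param component one of "Ka", "Kpe", "R".
#' @return the posterior-mean matrix.
#' @export
posterior_mean <- function(chain, component = c("Ka", "Kpe", "R")) {
  component <- match.arg(component)
  M <- chain[[component]]
  d <- as.integer(sqrt(ncol(M)))
  matrix(colMeans(M), d, d)
}

#' Effective sample size of a chain
#'
#' Autocorrelation-time estimate using Geyer's initial positive sequence:
#' \code{ESS = n / (1 + 2 sum(rho_k))} with the sum truncated at the first
#' non-positive pair of consecutive autocorrelations.
#'
#' @param x numeric chain.
#' @return the effective sample size; NA (with a warning) for a constant
#'   chain.
#' @export
effective_size <- function(x) {
  n <- length(x)
  if (stats::sd(x) == 0 || !is.finite(stats::sd(x))) {
    warning("constant or degenerate chain; ESS undefined")
    return(NA_real_)
  }
  rho <- stats::acf(x, lag.max = min(n - 1, 10 * ceiling(sqrt(n))),
                    plot = FALSE)$acf[-1]
  s <- 0
  k <- 1
  while (k + 1 <= length(rho)) {
    pair <- rho[k] + rho[k + 1]
    if (pair <= 0) break
    s <- s + pair
    k <- k + 2
  }
  n / (1 + 2 * s)
}

#' Geweke convergence diagnostic
#'
#' z-score comparing the mean of the first 10% against the last 50% of the
#' chain, with spectral-density-at-zero variance estimates from an AR fit.
#'
#' @param x numeric chain.
#' @param frac1,frac2 window fractions (defaults 0.1 and 0.5).
#' @return the z statistic.
#' @export
geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  a <- x[seq_len(floor(frac1 * n))]
  b <- x[(n - floor(frac2 * n) + 1):n]
  s0 <- function(v) {
    if (stats::sd(v) == 0) return(0)
    fit <- try(stats::ar(v, order.max = min(20, length(v) - 1),
                         aic = TRUE), silent = TRUE)
    if (inherits(fit, "try-error") || length(fit$ar) == 0) return(stats::var(v))
    fit$var.pred / (1 - sum(fit$ar))^2
  }
  (mean(a) - mean(b)) / sqrt(s0(a) / length(a) + s0(b) / length(b))
}

#' Chain diagnostics for every covariance element
#'
#' @param chain a \code{posterior_chain} (>= 100 retained samples).
#' @return data.frame with component, element, posterior mean, ESS and
#'   Geweke z per stored covariance element (diagonals only for brevity).
#' @export
chain_diagnostics <- function(chain) {
  if (chain$n_kept < 100) stop("need at least 100 retained samples")
  out <- list()
  for (comp in c("Ka", "Kpe", "R")) {
    M <- chain[[comp]]
    d <- as.integer(sqrt(ncol(M)))
    for (i in seq_len(d)) {
      x <- M[, (i - 1) * d + i]
      out[[length(out) + 1]] <- data.frame(
        component = comp, element = paste0("[", i, ",", i, "]"),
        mean = mean(x),
        ess = suppressWarnings(effective_size(x)),
        geweke_z = geweke_z(x))
    }
  }
  do.call(rbind, out)
}

#' Stream retained covariance samples to CSV
#'
#' Long format: iteration, component, row, col, value.
#'
#' @param chain a \code{posterior_chain}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_chain <- function(chain, path) {
  rows <- list()
  for (comp in c("Ka", "Kpe", "R")) {
    M <- chain[[comp]]
    d <- as.integer(sqrt(ncol(M)))
    idx <- expand.grid(row = seq_len(d), col = seq_len(d))
    keep <- idx$row <= idx$col
    for (s in seq_len(nrow(M))) {
      rows[[length(rows) + 1]] <- data.frame(
        iteration = chain$burn_in + (s - 1) * chain$thin + 1,
        component = comp, row = idx$row[keep], col = idx$col[keep],
        value = M[s, keep])
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
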