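# Daily parameter surfaces: variances, heritabilities and correlations by
# DIM, computed either from a single set of covariance components (truth or
# point estimate) or per posterior sample then averaged.

surface_from_components <- function(K_a, K_pe, R, dims, order = 2,
                                    dim_range = c(5, 365),
                                    trait_names = NULL) {
  q <- order + 1
  T <- nrow(as.matrix(R))
  if (is.null(trait_names)) trait_names <- paste0("trait", seq_len(T))
  R <- as.matrix(R)
  G <- length(dims)
  vg <- variance_grid(K_a, dims, order, dim_range)
  vpe <- variance_grid(K_pe, dims, order, dim_range)
  vr <- matrix(rep(diag(R), each = G), G, T)
  vp <- vg + vpe + vr
  h2 <- vg / vp
  pairs <- if (T > 1) utils::combn(T, 2) else matrix(integer(0), 2, 0)
  np <- ncol(pairs)
  gcor <- pcor <- pecor <- matrix(NA_real_, G, np)
  pair_names <- character(np)
  for (m in seq_len(np)) {
    j <- pairs[1, m]; k <- pairs[2, m]
    pair_names[m] <- paste(trait_names[j], trait_names[k], sep = ":")
    cg <- covariance_grid(K_a, dims, j, k, order, dim_range)
    cpe <- covariance_grid(K_pe, dims, j, k, order, dim_range)
    ce <- R[j, k]
    gcor[, m] <- cg / sqrt(vg[, j] * vg[, k])
    pecor[, m] <- cpe / sqrt(vpe[, j] * vpe[, k])
    pcor[, m] <- (cg + cpe + ce) / sqrt(vp[, j] * vp[, k])
  }
  est <- list(genetic_var = vg, pe_var = vpe, residual_var = vr,
              phenotypic_var = vp, h2 = h2,
              genetic_cor = gcor, pe_cor = pecor, phenotypic_cor = pcor)
  for (nm in c("genetic_var", "pe_var", "residual_var", "phenotypic_var",
               "h2")) colnames(est[[nm]]) <- trait_names
  for (nm in c("genetic_cor", "pe_cor", "phenotypic_cor")) {
    colnames(est[[nm]]) <- pair_names
  }
  structure(list(dim = dims, trait_names = trait_names,
                 pair_names = pair_names, pairs = pairs, est = est,
                 lo = NULL, hi = NULL),
            class = "daily_surface")
}

#' Posterior daily parameter surfaces
#'
#' For every retained Gibbs sample, evaluates the genetic, permanent
#' environmental, residual and phenotypic variance at each DIM of the grid
#' via the covariance function, forms the daily heritability and the
#' trait-pair genetic, permanent environmental and phenotypic correlations,
#' and then averages over samples (the ratio is computed per sample, then
#' averaged). 95% equal-tailed credible bounds accompany every quantity.
#'
#' @param chain a \code{posterior_chain} from [run_chain()].
#' @param dims integer DIM grid; defaults to every day in the chain's DIM
#'   range.
#' @return object of class \code{daily_surface}: list with the grid, the
#'   posterior-mean surfaces in \code{$est} (matrices, one column per trait
#'   or trait pair) and bounds in \code{$lo}, \code{$hi}.
#' @export
daily_surfaces <- function(chain, dims = NULL) {
  stopifnot(inherits(chain, "posterior_chain"))
  if (is.null(dims)) dims <- seq(chain$dim_range[1], chain$dim_range[2])
  if (any(dims < chain$dim_range[1] | dims > chain$dim_range[2])) {
    stop("DIM grid outside the basis range")
  }
  S <- chain$n_kept
  acc <- NULL
  store <- list()
  for (s in seq_len(S)) {
    surf <- surface_from_components(
      chain_matrix(chain, "Ka", s), chain_matrix(chain, "Kpe", s),
      chain_matrix(chain, "R", s), dims, order = chain$rr_order,
      dim_range = chain$dim_range, trait_names = chain$trait_names)
    if (is.null(acc)) {
      acc <- surf$est
      store <- lapply(surf$est, function(m) {
        a <- array(NA_real_, c(S, nrow(m), ncol(m)))
        a[1, , ] <- m
        a
      })
    } else {
      for (nm in names(acc)) {
        acc[[nm]] <- acc[[nm]] + surf$est[[nm]]
        store[[nm]][s, , ] <- surf$est[[nm]]
      }
    }
  }
  est <- lapply(acc, function(m) m / S)
  qs <- function(a, pr) {
    if (dim(a)[3] == 0) return(matrix(NA_real_, dim(a)[2], 0))
    apply(a, c(2, 3), stats::quantile, probs = pr, na.rm = TRUE)
  }
  lo <- lapply(store, qs, pr = 0.025)
  hi <- lapply(store, qs, pr = 0.975)
  tmpl <- surface_from_components(
    chain_matrix(chain, "Ka", 1), chain_matrix(chain, "Kpe", 1),
    chain_matrix(chain, "R", 1), dims, order = chain$rr_order,
    dim_range = chain$dim_range, trait_names = chain$trait_names)
  for (nm in names(est)) {
    dimnames(est[[nm]]) <- dimnames(tmpl$est[[nm]])
    dimnames(lo[[nm]]) <- dimnames(hi[[nm]]) <- dimnames(tmpl$est[[nm]])
  }
  structure(list(dim = dims, trait_names = chain$trait_names,
                 pair_names = tmpl$pair_names, pairs = tmpl$pairs,
                 est = est, lo = lo, hi = hi),
            class = "daily_surface")
}

#' Mean and range over DIM of every surface quantity
#'
#' Arithmetic (unweighted) mean over the DIM grid of the posterior-mean
#' trajectory of each quantity, with its (min, max) range, the summary
#' format used for lactation-average heritabilities and correlations.
#'
#' @param surface a \code{daily_surface}.
#' @return data.frame with columns quantity, name, mean, min, max.
#' @export
summarize_mean_range <- function(surface) {
  stopifnot(inherits(surface, "daily_surface"))
  out <- list()
  for (nm in names(surface$est)) {
    M <- surface$est[[nm]]
    if (!ncol(M)) next
    out[[nm]] <- data.frame(
      quantity = nm, name = colnames(M),
      mean = colMeans(M),
      min = apply(M, 2, min), max = apply(M, 2, max),
      row.names = NULL)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Residual standard deviation by days in milk
#'
#' Homogeneity diagnostic: the SD of observed-minus-fitted residuals within
#' DIM bins (optionally per group, e.g. parity), plus a flatness summary,
#' the max/min SD ratio across bins. Bins with fewer than \code{min_records}
#' records are flagged and excluded from the table and the ratio.
#'
#' @param dim integer vector of record DIM.
#' @param observed,fitted numeric vectors (or single-column matrices) of
#'   observed and fitted values for one trait.
#' @param group optional grouping vector (e.g. parity).
#' @param bin_width DIM bin width in days (default 30).
#' @param min_records minimum records per reported bin (default 5).
#' @return data.frame (group, bin_lo, bin_hi, n, sd) with attribute
#'   \code{flatness}, a named vector of max/min SD ratios per group.
#' @export
residual_sd_by_dim <- function(dim, observed, fitted, group = NULL,
                               bin_width = 30, min_records = 5) {
  resid <- as.numeric(observed) - as.numeric(fitted)
  if (is.null(group)) group <- rep(1L, length(resid))
  bin <- floor((dim - min(dim)) / bin_width)
  out <- list()
  flat <- c()
  for (g in sort(unique(group))) {
    sel <- group == g
    tab <- tapply(resid[sel], bin[sel], function(x)
      c(n = length(x), sd = stats::sd(x)))
    tab <- do.call(rbind, tab)
    bins <- as.integer(rownames(tab))
    keep <- tab[, "n"] >= min_records
    tab <- tab[keep, , drop = FALSE]
    bins <- bins[keep]
    out[[as.character(g)]] <- data.frame(
      group = g, bin_lo = min(dim) + bins * bin_width,
      bin_hi = min(dim) + (bins + 1) * bin_width - 1,
      n = tab[, "n"], sd = tab[, "sd"], row.names = NULL)
    flat[as.character(g)] <- max(tab[, "sd"]) / min(tab[, "sd"])
  }
  structure(do.call(rbind, c(out, make.row.names = FALSE)),
            flatness = flat)
}

#' Format a mean with its range
#'
#' @param mean,min,max numbers.
#' @param digits decimal places (default 2).
#' @return character like \code{"-0.21 (-0.27 to -0.04)"}.
#' @export
format_mean_range <- function(mean, min, max, digits = 2) {
  f <- function(x) formatC(round(x, digits), format = "f", digits = digits)
  sprintf("%s (%s to %s)", f(mean), f(min), f(max))
}

#' Correlation summary table between a focal trait and the others
#'
#' Builds the mean (range) correlation table: one row per partner trait,
#' one column per parity (element of \code{surfaces}), cells formatted as
#' \code{"mean (min to max)"}. Symmetric pairs give identical cells; a pair
#' absent from a surface leaves an empty cell with a warning.
#'
#' @param surfaces named list of \code{daily_surface} objects (e.g. one per
#'   parity).
#' @param focal focal trait name (e.g. "SCS").
#' @param component one of "genetic_cor", "pe_cor", "phenotypic_cor".
#' @param digits decimal places.
#' @return data.frame, rows = partner traits, columns = names of
#'   \code{surfaces}.
#' @export
correlation_table <- function(surfaces, focal = "SCS",
                              component = "genetic_cor", digits = 2) {
  partners <- unique(unlist(lapply(surfaces, function(s)
    setdiff(s$trait_names, focal))))
  out <- data.frame(trait = partners, stringsAsFactors = FALSE)
  for (cn in names(surfaces)) {
    s <- surfaces[[cn]]
    col <- character(length(partners))
    for (i in seq_along(partners)) {
      m <- which((s$trait_names[s$pairs[1, ]] == focal &
                    s$trait_names[s$pairs[2, ]] == partners[i]) |
                   (s$trait_names[s$pairs[2, ]] == focal &
                      s$trait_names[s$pairs[1, ]] == partners[i]))
      if (!length(m)) {
        warning("pair ", focal, ":", partners[i], " absent from surface ",
                cn)
        col[i] <- ""
      } else {
        x <- s$est[[component]][, m[1]]
        col[i] <- format_mean_range(mean(x), min(x), max(x), digits)
      }
    }
    out[[cn]] <- col
  }
  out
}

#' Export a daily surface as tidy CSV
#'
#' Long format: dim, quantity, name, value, lo95, hi95.
#'
#' @param surface a \code{daily_surface}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_surface <- function(surface, path) {
  utils::write.csv(as.data.frame(surface), path, row.names = FALSE)
  invisible(path)
}

#' @export
as.data.frame.daily_surface <- function(x, ...) {
  rows <- list()
  for (nm in names(x$est)) {
    M <- x$est[[nm]]
    if (!ncol(M)) next
    for (j in seq_len(ncol(M))) {
      rows[[paste(nm, j)]] <- data.frame(
        dim = x$dim, quantity = nm, name = colnames(M)[j], value = M[, j],
        lo95 = if (!is.null(x$lo)) x$lo[[nm]][, j] else NA_real_,
        hi95 = if (!is.null(x$hi)) x$hi[[nm]][, j] else NA_real_)
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
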