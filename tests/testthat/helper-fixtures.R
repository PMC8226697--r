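# Shared fixtures built in code; nothing is stored on disk.

trio_ped <- function() {
  ped_validate_sort(data.frame(animal = 3, sire = 1, dam = 2))
}

# random pedigree via repeated random matings; allows unknown parents
random_ped <- function(n, seed, p_unknown = 0.1) {
  set.seed(seed)
  sire <- dam <- integer(n)
  for (i in 3:n) {
    pool <- seq_len(i - 1)
    sire[i] <- if (stats::runif(1) < p_unknown) 0L else sample(pool, 1)
    dam[i] <- if (stats::runif(1) < p_unknown) 0L else sample(pool, 1)
    if (sire[i] == dam[i]) dam[i] <- 0L
  }
  ped_validate_sort(data.frame(animal = seq_len(n), sire = sire, dam = dam))
}

# small simulated single-trait dataset for pipeline tests
small_dataset <- function(seed = 42, n_herds = 1, cows_per_herd = 30,
                          n_tests = 8, truth = truth_scs()) {
  ped <- simulate_pedigree(30, 2, 2, seed = seed, n_sires = 5)
  simulate_records(ped, truth,
                   sim_design(n_herds = n_herds,
                              cows_per_herd = cows_per_herd,
                              n_tests = n_tests),
                   seed = seed + 1)
}

# flat-curve truth: no age-season signal, no herd-test-day noise, so
# analytic variance identities hold exactly in expectation
flat_truth <- function(K_a, K_pe, R, n_traits = nrow(as.matrix(R))) {
  truth_parameters(K_a = K_a, K_pe = K_pe, R = R,
                   fixed_curves = array(0, c(1, 5, n_traits)),
                   htd_sd = 0)
}

# independent Legendre evaluation written from the explicit polynomials,
# used as an oracle against the package recurrence
legendre_explicit <- function(x, b) {
  P <- switch(as.character(b),
              "0" = rep(1, length(x)),
              "1" = x,
              "2" = (3 * x^2 - 1) / 2,
              "3" = (5 * x^3 - 3 * x) / 2,
              "4" = (35 * x^4 - 30 * x^2 + 3) / 8,
              stop("order too high for the explicit oracle"))
  sqrt((2 * b + 1) / 2) * P
}
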