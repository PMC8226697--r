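test_that("smallest pedigree is a trio with the founders as parents", {
  ped <- simulate_pedigree(2, 1, 1, seed = 1)
  expect_equal(nrow(ped), 3)
  kid <- ped[ped$generation == 1, ]
  expect_equal(sort(c(ped$animal[kid$sire_i], ped$animal[kid$dam_i])),
               c("1", "2"))
})

test_that("non-founder parents always belong to the previous generation", {
  ped <- simulate_pedigree(100, 3, 2, seed = 7)
  for (g in 1:3) {
    kids <- which(ped$generation == g)
    parents <- c(ped$sire_i[kids], ped$dam_i[kids])
    expect_true(all(ped$generation[parents] == g - 1))
  }
})

test_that("pedigree simulation is deterministic in the seed", {
  p1 <- simulate_pedigree(50, 4, 2, seed = 3)
  p2 <- simulate_pedigree(50, 4, 2, seed = 3)
  expect_identical(p1, p2)
  expect_error(simulate_pedigree(0, 1, 1, seed = 1), "need")
})

test_that("founder breeding values are iid N(0, K)", {
  ped <- ped_validate_sort(data.frame(animal = 1:10000, sire = 0, dam = 0))
  a <- simulate_breeding_values(ped, diag(3), seed = 1)
  expect_equal(cov(a), diag(3), tolerance = 0.06)
  expect_equal(colMeans(a), rep(0, 3), tolerance = 0.04)
})

test_that("gene dropping reproduces A (x) K on the trio", {
  ped <- trio_ped()
  K <- matrix(2)
  set.seed(99)
  drops <- replicate(8000, simulate_breeding_values(ped, K))
  # cov(offspring) = K, cov(offspring, parent) = K/2
  expect_equal(var(drops[3, 1, ]), 2, tolerance = 0.15)
  expect_equal(cov(drops[3, 1, ], drops[1, 1, ]), 1, tolerance = 0.12)
  expect_equal(cov(drops[1, 1, ], drops[2, 1, ]), 0, tolerance = 0.1)
})

test_that("gene-dropping covariance matches A (x) K on a small pedigree", {
  ped <- random_ped(15, seed = 21, p_unknown = 0.2)
  A <- a_matrix_dense(ped)
  K <- matrix(1.5)
  set.seed(7)
  drops <- replicate(6000, simulate_breeding_values(ped, K)[, 1])
  emp <- cov(t(drops))
  expect_lt(max(abs(emp - A * 1.5)), 0.25)
})

test_that("non-positive-definite K is rejected", {
  expect_error(simulate_breeding_values(trio_ped(), matrix(0, 3, 3)),
               "positive definite")
})

test_that("null genetics leaves fixed curve plus iid noise", {
  eps <- 1e-10
  truth <- truth_parameters(K_a = diag(eps, 3), K_pe = diag(eps, 3),
                            R = matrix(1), htd_sd = 0,
                            fixed_curves = array(
                              rep(c(3 / sqrt(0.5), 0.5, 0, 0, 0), each = 1),
                              c(1, 5, 1)))
  ped <- simulate_pedigree(30, 1, 2, seed = 5)
  ds <- simulate_records(ped, truth,
                         sim_design(n_herds = 1, cows_per_herd = 10,
                                    n_tests = 10), seed = 6)
  phi <- dim_basis(ds$records$dim, 4)
  curve <- phi %*% truth$fixed_curves[1, , 1]
  resid <- ds$records$SCS - drop(curve)
  expect_equal(mean(resid), 0, tolerance = 0.15)
  expect_equal(sd(resid), 1, tolerance = 0.12)
})

test_that("phenotypic variance decomposes per the orthonormal identity", {
  K_a <- diag(c(1.48, 0.02, 0.01))
  K_pe <- diag(c(1.86, 0.04, 0.02))
  truth <- flat_truth(K_a, K_pe, matrix(2.44))
  # many founder families to keep the family-sampling noise small
  ped <- simulate_pedigree(2400, 1, 1, seed = 31, n_sires = 400)
  ds <- simulate_records(ped, truth,
                         sim_design(n_herds = 2, cows_per_herd = 300,
                                    n_tests = 12), seed = 32)
  expected <- 0.5 * sum(diag(K_a)) + 0.5 * sum(diag(K_pe)) + 2.44
  expect_equal(var(ds$records$SCS), expected, tolerance = 0.1 * expected)
})

test_that("half-sib same-day phenotypic covariance is quarter genetic", {
  truth <- flat_truth(diag(c(4, 0.002, 0.001)), diag(1e-4, 3), matrix(0.5))
  ped <- simulate_pedigree(2000, 1, 2, seed = 41, n_sires = 60)
  ds <- simulate_records(ped, truth,
                         sim_design(n_herds = 1, cows_per_herd = 800,
                                    n_tests = 12), seed = 42)
  rec <- ds$records
  sire_of <- ped$sire[match(rec$cow, ped$animal)]
  # pair half-sib records on the same test date
  by_day <- split(seq_len(nrow(rec)), rec$test_date)
  xs <- c(); ys <- c(); ts <- c()
  for (idx in by_day) {
    s <- sire_of[idx]
    for (ss in unique(s)) {
      rows <- idx[s == ss]
      if (length(rows) >= 2) {
        pairs <- utils::combn(rows, 2)
        xs <- c(xs, rec$SCS[pairs[1, ]])
        ys <- c(ys, rec$SCS[pairs[2, ]])
        ts <- c(ts, rec$dim[pairs[1, ]])
      }
    }
  }
  emp <- cov(xs, ys)
  expected <- mean(sapply(ts, function(t)
    0.25 * drop(evaluate_covariance(truth$K_a, t))))
  expect_equal(emp, expected, tolerance = 0.35 * expected)
})

test_that("record simulation is reproducible and structurally valid", {
  d1 <- small_dataset(seed = 7)
  d2 <- small_dataset(seed = 7)
  expect_identical(d1$records, d2$records)
  rec <- d1$records
  expect_true(all(rec$dim >= 5 & rec$dim <= 365))
  expect_true(all(rec$cow %in% d1$pedigree$animal))
  expect_true(all(diff(order(rec$cow, rec$test_date)) > 0) ||
                !is.unsorted(order(rec$cow, rec$test_date)))
  expect_error(simulate_records(d1$pedigree[0, ], truth_scs(),
                                sim_design(), seed = 1), "empty|candidate")
})

test_that("truth surface reproduces closed-form daily parameters", {
  truth <- truth_scs()
  ts <- truth_surface(truth, dims = 5:365)
  # independent oracle: explicit polynomials on the standardized grid
  x <- 2 * (5:365 - 5) / 360 - 1
  vg <- 1.48 * legendre_explicit(x, 0)^2 + 0.02 * legendre_explicit(x, 1)^2 +
    0.01 * legendre_explicit(x, 2)^2
  vpe <- 1.86 * legendre_explicit(x, 0)^2 + 0.04 * legendre_explicit(x, 1)^2 +
    0.02 * legendre_explicit(x, 2)^2
  h2 <- vg / (vg + vpe + 2.44)
  expect_equal(drop(ts$est$h2), h2, tolerance = 1e-10)
  expect_equal(mean(ts$est$h2), 0.18, tolerance = 0.02)

  tw <- truth_surface(truth_twotrait(), dims = seq(5, 365, by = 5))
  expect_equal(unname(tw$est$genetic_cor[, 1]),
               rep(-0.21, nrow(tw$est$genetic_cor)), tolerance = 1e-10)

  lim <- truth_parameters(K_a = diag(c(1.48, 0.02, 0.01)),
                          K_pe = diag(1e-12, 3), R = matrix(1e-12))
  expect_equal(unname(truth_surface(lim, dims = c(5, 100, 365))$est$h2[, 1]),
               rep(1, 3), tolerance = 1e-6)
})

test_that("truth surfaces always give valid heritabilities and correlations", {
  set.seed(8)
  for (rep in 1:5) {
    Z1 <- matrix(rnorm(36), 6); Z2 <- matrix(rnorm(36), 6)
    truth <- truth_parameters(K_a = crossprod(Z1) + diag(6) * 0.05,
                              K_pe = crossprod(Z2) + diag(6) * 0.05,
                              R = diag(2) * runif(1, 0.5, 3))
    ts <- truth_surface(truth, dims = seq(5, 365, by = 20))
    expect_true(all(ts$est$h2 >= 0 & ts$est$h2 <= 1))
    expect_true(all(abs(ts$est$genetic_cor) <= 1 + 1e-12))
    expect_true(all(abs(ts$est$phenotypic_cor) <= 1 + 1e-12))
    expect_equal(ts$est$phenotypic_var,
                 ts$est$genetic_var + ts$est$pe_var + ts$est$residual_var,
                 tolerance = 1e-12)
  }
})

test_that("dataset files are written as plain text and round-trip", {
  ds <- small_dataset(seed = 13)
  dir <- tempfile()
  paths <- write_dataset(ds, dir)
  expect_true(all(file.exists(paths)))
  rec <- read_testday(paths["records"])
  expect_equal(nrow(rec), nrow(ds$records))
  ped <- read_pedigree(paths["pedigree"])
  expect_equal(nrow(ped), nrow(ds$pedigree))
  tr <- yaml::read_yaml(paths["truth"])
  expect_equal(matrix(tr$K_a, 3), ds$truth$K_a)
  unlink(dir, recursive = TRUE)
})
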