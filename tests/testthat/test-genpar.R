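# build a posterior_chain-shaped object from explicit covariance samples
fake_chain <- function(Ka_list, Kpe_list, R_list, trait_names = "SCS",
                       order = 2) {
  structure(list(
    Ka = do.call(rbind, lapply(Ka_list, as.vector)),
    Kpe = do.call(rbind, lapply(Kpe_list, as.vector)),
    R = do.call(rbind, lapply(R_list, as.vector)),
    n_kept = length(Ka_list),
    n_traits = length(trait_names), q = order + 1, rr_order = order,
    dim_range = c(5, 365), trait_names = trait_names),
    class = "posterior_chain")
}

test_that("single-sample surface reproduces the closed-form heritability", {
  ch <- fake_chain(list(diag(c(1.48, 0.02, 0.01))),
                   list(diag(c(1.86, 0.04, 0.02))),
                   list(matrix(2.44)))
  surf <- daily_surfaces(ch, dims = 5:365)
  # independent quadrature oracle on the explicit polynomials
  x <- 2 * (5:365 - 5) / 360 - 1
  vg <- 1.48 * legendre_explicit(x, 0)^2 + 0.02 * legendre_explicit(x, 1)^2 +
    0.01 * legendre_explicit(x, 2)^2
  vpe <- 1.86 * legendre_explicit(x, 0)^2 + 0.04 * legendre_explicit(x, 1)^2 +
    0.02 * legendre_explicit(x, 2)^2
  expect_equal(unname(surf$est$h2[, 1]), vg / (vg + vpe + 2.44),
               tolerance = 1e-10)
  expect_equal(mean(surf$est$h2), 0.18, tolerance = 0.02)
})

test_that("proportional-block samples give a constant genetic correlation", {
  K1 <- diag(c(1.48, 0.02, 0.01))
  T0 <- rbind(c(1, -0.42), c(-0.42, 4))
  ch <- fake_chain(list(kronecker(T0, K1)),
                   list(kronecker(diag(2), K1)),
                   list(diag(2)), trait_names = c("SCS", "MY"))
  surf <- daily_surfaces(ch, dims = seq(5, 365, by = 5))
  expect_equal(unname(surf$est$genetic_cor[, 1]),
               rep(-0.21, 73), tolerance = 1e-10)
})

test_that("heritability is one when PE and residual vanish", {
  ch <- fake_chain(list(diag(c(1.48, 0.02, 0.01))),
                   list(diag(1e-14, 3)), list(matrix(1e-14)))
  surf <- daily_surfaces(ch, dims = c(5, 100, 200, 365))
  expect_equal(unname(surf$est$h2[, 1]), rep(1, 4), tolerance = 1e-6)
})

test_that("per-sample summaries stay in valid ranges and add up", {
  set.seed(7)
  Ka_l <- Kpe_l <- R_l <- list()
  for (s in 1:25) {
    Ka_l[[s]] <- .riwishart(10, diag(6) * 3)
    Kpe_l[[s]] <- .riwishart(10, diag(6) * 3)
    R_l[[s]] <- .riwishart(6, diag(2) * 3)
  }
  ch <- fake_chain(Ka_l, Kpe_l, R_l, trait_names = c("A", "B"))
  surf <- daily_surfaces(ch, dims = seq(5, 365, by = 15))
  expect_true(all(surf$est$h2 >= 0 & surf$est$h2 <= 1))
  expect_true(all(abs(surf$est$genetic_cor) <= 1))
  expect_true(all(abs(surf$est$pe_cor) <= 1))
  expect_true(all(abs(surf$est$phenotypic_cor) <= 1))
  expect_equal(surf$est$phenotypic_var,
               surf$est$genetic_var + surf$est$pe_var + surf$est$residual_var,
               tolerance = 1e-10)
  expect_true(all(surf$lo$h2 <= surf$est$h2 + 1e-12) &&
                all(surf$hi$h2 >= surf$est$h2 - 1e-12))
  expect_error(daily_surfaces(ch, dims = c(1, 50)), "outside")
})

test_that("posterior mean of the ratio is averaged per sample", {
  # two samples with very different variance scales: the mean heritability
  # must be the average of the two per-sample curves, not the curve of the
  # averaged components
  ch <- fake_chain(list(diag(c(1, 0, 0) + 1e-12), diag(c(4, 0, 0) + 1e-12)),
                   list(diag(1e-12, 3), diag(1e-12, 3)),
                   list(matrix(1), matrix(1)))
  surf <- daily_surfaces(ch, dims = 185)
  h1 <- 0.5 / (0.5 + 1)       # phi_0^2 = 1/2 at the midpoint
  h2v <- 2 / (2 + 1)
  expect_equal(unname(surf$est$h2[1, 1]), (h1 + h2v) / 2, tolerance = 1e-6)
})

test_that("mean and range summaries follow the surface", {
  ch <- fake_chain(list(diag(c(2, 0, 0) + 1e-13)),
                   list(diag(c(2, 0, 0) + 1e-13)), list(matrix(2)))
  surf <- daily_surfaces(ch, dims = 5:365)
  sm <- summarize_mean_range(surf)
  h <- sm[sm$quantity == "h2", ]
  # constant surface: variance 1 everywhere for each component
  expect_equal(h$mean, 0.25, tolerance = 1e-10)
  expect_equal(h$min, 0.25, tolerance = 1e-10)
  expect_equal(h$max, 0.25, tolerance = 1e-10)
  gv <- sm[sm$quantity == "genetic_var", ]
  expect_equal(gv$mean, 1, tolerance = 1e-10)

  # non-constant: mean over the grid matches independent quadrature
  ch2 <- fake_chain(list(diag(c(1.48, 0.02, 0.01))),
                    list(diag(c(1.86, 0.04, 0.02))), list(matrix(2.44)))
  surf2 <- daily_surfaces(ch2, dims = 5:365)
  sm2 <- summarize_mean_range(surf2)
  x <- 2 * (5:365 - 5) / 360 - 1
  vg <- 1.48 * legendre_explicit(x, 0)^2 + 0.02 * legendre_explicit(x, 1)^2 +
    0.01 * legendre_explicit(x, 2)^2
  vpe <- 1.86 * legendre_explicit(x, 0)^2 + 0.04 * legendre_explicit(x, 1)^2 +
    0.02 * legendre_explicit(x, 2)^2
  hcurve <- vg / (vg + vpe + 2.44)
  expect_equal(sm2$mean[sm2$quantity == "h2"], mean(hcurve),
               tolerance = 1e-3)
  expect_equal(sm2$min[sm2$quantity == "h2"], min(hcurve), tolerance = 1e-6)
  expect_equal(sm2$max[sm2$quantity == "h2"], max(hcurve), tolerance = 1e-6)
})

test_that("residual SD by DIM is flat under homogeneity", {
  set.seed(9)
  n <- 6000
  dim <- sample(5:365, n, replace = TRUE)
  resid <- rnorm(n, sd = sqrt(2.44))
  tab <- residual_sd_by_dim(dim, resid, fitted = rep(0, n))
  expect_lt(max(attr(tab, "flatness")), 1.3)
  expect_true(all(tab$n >= 5))
})

test_that("residual SD by DIM detects an injected variance shift", {
  set.seed(10)
  n <- 6000
  dim <- sample(5:365, n, replace = TRUE)
  sdv <- ifelse(dim > 200, sqrt(2 * 2.44), sqrt(2.44))
  resid <- rnorm(n, sd = sdv)
  tab <- residual_sd_by_dim(dim, resid, fitted = rep(0, n))
  expect_gt(max(attr(tab, "flatness")), sqrt(2) * 0.9)
})

test_that("sparse DIM cells are flagged out of the residual table", {
  dim <- c(rep(10, 50), rep(300, 3))
  resid <- rnorm(53)
  tab <- residual_sd_by_dim(dim, resid, fitted = rep(0, 53), bin_width = 30)
  expect_equal(nrow(tab), 1)
  expect_lt(tab$bin_hi[1], 300)
})

test_that("mean (range) cells format like the reported tables", {
  expect_equal(format_mean_range(-0.213, -0.27, -0.04),
               "-0.21 (-0.27 to -0.04)")
  expect_equal(format_mean_range(0.18, 0.11, 0.2), "0.18 (0.11 to 0.20)")
})

test_that("correlation tables are symmetric and warn on missing pairs", {
  K1 <- diag(c(1.48, 0.02, 0.01))
  T0 <- rbind(c(1, -0.42), c(-0.42, 4))
  ch <- fake_chain(list(kronecker(T0, K1)), list(kronecker(diag(2), K1)),
                   list(diag(2)), trait_names = c("SCS", "MY"))
  surf <- daily_surfaces(ch, dims = seq(5, 365, by = 10))
  tab <- correlation_table(list(parity1 = surf), focal = "SCS")
  expect_equal(tab$trait, "MY")
  expect_match(tab$parity1, "^-0\\.21 \\(")
  tab2 <- correlation_table(list(parity1 = surf), focal = "MY")
  expect_equal(tab2$parity1, tab$parity1)
  chA <- fake_chain(list(diag(3) + 0), list(diag(3)), list(matrix(1)),
                    trait_names = "SCS")
  surfA <- daily_surfaces(chA, dims = c(50, 100))
  expect_warning(correlation_table(list(p1 = surfA, p2 = surf),
                                   focal = "SCS"), "absent")
})

test_that("tidy export covers every quantity with bounds", {
  ch <- fake_chain(list(diag(3), 2 * diag(3)), list(diag(3), diag(3)),
                   list(matrix(1), matrix(1.5)))
  surf <- daily_surfaces(ch, dims = c(5, 100, 365))
  df <- as.data.frame(surf)
  expect_setequal(unique(df$quantity),
                  c("genetic_var", "pe_var", "residual_var",
                    "phenotypic_var", "h2"))
  expect_true(all(df$lo95 <= df$value + 1e-12))
  f <- tempfile(fileext = ".csv")
  write_surface(surf, f)
  expect_equal(nrow(utils::read.csv(f)), nrow(df))
  unlink(f)
})
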