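#' True parameters for a synthetic test-day herd
#'
#' Bundles the data-generating parameters of the random regression test-day
#' model: additive-genetic and permanent-environmental coefficient covariance
#' matrices on the Legendre scale, the within-test-day residual covariance,
#' the fixed age-season lactation curves, and the herd-test-day effect SD.
#'
#' @param K_a symmetric positive definite additive genetic coefficient
#'   covariance, dimension n_traits * (order + 1), trait-block layout.
#' @param K_pe permanent environment coefficient covariance, same layout.
#' @param R residual covariance between traits recorded on the same test-day
#'   (n_traits x n_traits).
#' @param order random-regression order (default 2).
#' @param fixed_order order of the fixed age-season regression (default 4).
#' @param dim_range DIM window, default \code{c(5, 365)}.
#' @param trait_names character vector, defaults to trait1..traitT (or "SCS"
#'   for a single trait).
#' @param fixed_curves array \code{[n_classes, fixed_order + 1, n_traits]} of
#'   Legendre coefficients of the age-season class curves; a smooth default
#'   lactation-shaped set is built when NULL.
#' @param n_as_classes number of age-season classes for the default curves.
#' @param htd_sd SD of the herd-test-day effects (simulated iid normal; the
#'   fitting module still treats HTD as a fixed class effect).
#' @return object of class \code{truth_parameters}.
#' @export
truth_parameters <- function(K_a, K_pe, R, order = 2, fixed_order = 4,
                             dim_range = c(5, 365), trait_names = NULL,
                             fixed_curves = NULL, n_as_classes = 4,
                             htd_sd = 0.3) {
  K_a <- as.matrix(K_a); K_pe <- as.matrix(K_pe); R <- as.matrix(R)
  q <- order + 1
  n_traits <- nrow(R)
  if (nrow(K_a) != n_traits * q || nrow(K_pe) != n_traits * q) {
    stop("K_a and K_pe must be ", n_traits * q, " x ", n_traits * q)
  }
  for (nm in c("K_a", "K_pe", "R")) {
    M <- get(nm)
    if (!isSymmetric(M, tol = 1e-8)) stop(nm, " must be symmetric")
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop(nm, " must be positive definite")
  }
  if (is.null(trait_names)) {
    trait_names <- if (n_traits == 1) "SCS" else paste0("trait", seq_len(n_traits))
  }
  if (is.null(fixed_curves)) {
    fixed_curves <- default_fixed_curves(n_as_classes, fixed_order, n_traits)
  }
  structure(list(K_a = K_a, K_pe = K_pe, R = R, order = order,
                 fixed_order = fixed_order, dim_range = dim_range,
                 trait_names = trait_names, fixed_curves = fixed_curves,
                 n_as_classes = dim(fixed_curves)[1], htd_sd = htd_sd,
                 n_traits = n_traits),
            class = "truth_parameters")
}

# Deterministic lactation-shaped age-season curves on the normalized
# Legendre scale: a base level with a gentle rise across DIM plus a
# class-specific level shift. Units follow the trait (SCS-like defaults).
default_fixed_curves <- function(n_classes, fixed_order, n_traits,
                                 base_level = 2.4, slope = 0.35,
                                 curvature = -0.2, class_spread = 0.25) {
  p <- fixed_order + 1
  curves <- array(0, dim = c(n_classes, p, n_traits))
  for (j in seq_len(n_traits)) {
    for (k in seq_len(n_classes)) {
      shift <- class_spread * (k - (n_classes + 1) / 2)
      # divide by phi_0 = sqrt(1/2) so the curve's DIM-average is level+shift
      curves[k, 1, j] <- (base_level + shift) / sqrt(0.5)
      curves[k, 2, j] <- slope
      if (p >= 3) curves[k, 3, j] <- curvature
    }
  }
  curves
}

#' Single-trait somatic cell score truth fixture
#'
#' The package's reference single-trait condition: an SCS-like trait with
#' additive coefficient covariance diag(1.48, 0.02, 0.01), permanent
#' environment diag(1.86, 0.04, 0.02) and residual variance 2.44, which
#' implies a DIM-average heritability close to 0.18.
#'
#' @param htd_sd herd-test-day SD, default 0.3.
#' @return a \code{truth_parameters} object.
#' @export
truth_scs <- function(htd_sd = 0.3) {
  truth_parameters(K_a = diag(c(1.48, 0.02, 0.01)),
                   K_pe = diag(c(1.86, 0.04, 0.02)),
                   R = matrix(2.44), htd_sd = htd_sd)
}

#' Two-trait proportional-block truth fixture
#'
#' Genetic covariance \code{T0 \%x\% K1} with \code{K1 = diag(1.48, 0.02,
#' 0.01)} and \code{T0 = rbind(c(1, -0.42), c(-0.42, 4))}: the genetic
#' correlation between the two traits is \code{-0.42 / sqrt(4) = -0.21} at
#' every DIM. PE and residual blocks are uncorrelated across traits, with
#' the second trait's magnitudes scaled by 4 so both traits have similar
#' heritability trajectories.
#'
#' @param htd_sd herd-test-day SD, default 0.3.
#' @return a \code{truth_parameters} object.
#' @export
truth_twotrait <- function(htd_sd = 0.3) {
  K1 <- diag(c(1.48, 0.02, 0.01))
  T0 <- rbind(c(1, -0.42), c(-0.42, 4))
  truth_parameters(K_a = kronecker(T0, K1),
                   K_pe = kronecker(diag(c(1, 4)), diag(c(1.86, 0.04, 0.02))),
                   R = diag(c(2.44, 9.76)),
                   trait_names = c("SCS", "MY"), htd_sd = htd_sd)
}

#' Simulate a closed multi-generation pedigree
#'
#' Founders (generation 0, unknown parents, alternating sex) are followed by
#' \code{n_generations} discrete generations: every female of the previous
#' generation is mated to a sire drawn from that generation's males and
#' produces \code{offspring_per_mating} offspring of alternating sex. Parents
#' of non-founders therefore always belong to the previous generation.
#'
#' @param n_founders number of founder animals (>= 2).
#' @param n_generations number of offspring generations (>= 1).
#' @param offspring_per_mating offspring per dam (>= 1).
#' @param seed integer RNG seed.
#' @param n_sires number of males of each generation used as active sires
#'   (default 25, or all males if fewer). Heavy sire use produces the large
#'   paternal half-sib families typical of dairy AI breeding, which carry
#'   most of the information separating additive from permanent
#'   environmental variance.
#' @return a \code{pedigree_table} with extra columns \code{sex} ("M"/"F")
#'   and \code{generation}.
#' @examples
#' simulate_pedigree(2, 1, 1, seed = 1)
#' @export
simulate_pedigree <- function(n_founders, n_generations, offspring_per_mating,
                              seed, n_sires = 25) {
  if (n_founders < 2 || n_generations < 1 || offspring_per_mating < 1) {
    stop("need n_founders >= 2, n_generations >= 1, offspring_per_mating >= 1")
  }
  set.seed(seed)
  sex <- rep(c("M", "F"), length.out = n_founders)
  animal <- seq_len(n_founders)
  sire <- dam <- rep(0L, n_founders)
  generation <- rep(0L, n_founders)
  prev <- animal
  for (g in seq_len(n_generations)) {
    males <- prev[sex[prev] == "M"]
    females <- prev[sex[prev] == "F"]
    if (length(males) > n_sires) {
      males <- if (n_sires == 1) males[1] else sample(males, n_sires)
    }
    if (!length(males) || !length(females)) {
      stop("generation ", g - 1, " has no animals of one sex; increase ",
           "n_founders or offspring_per_mating")
    }
    kids <- integer(0)
    for (f in females) {
      s <- if (length(males) == 1) males else sample(males, 1)
      for (k in seq_len(offspring_per_mating)) {
        id <- length(animal) + 1L
        animal <- c(animal, id)
        sire <- c(sire, s)
        dam <- c(dam, f)
        generation <- c(generation, g)
        sex <- c(sex, if (length(animal) %% 2L) "M" else "F")
        kids <- c(kids, id)
      }
    }
    prev <- kids
  }
  ped <- ped_validate_sort(data.frame(animal = animal, sire = sire, dam = dam))
  m <- match(ped$animal, as.character(animal))
  ped$sex <- sex[m]
  ped$generation <- generation[m]
  ped
}

#' Gene-drop random regression breeding values down a pedigree
#'
#' Realizes per-animal additive coefficient vectors \code{a ~ N(0, A (x) K)}
#' by gene dropping: founders are drawn iid N(0, K); a non-founder receives
#' the mean of its parents' vectors plus a Mendelian-sampling deviation with
#' covariance \code{d_i K}, \code{d_i = 1/2 - (F_s + F_d)/4} (3/4 - F_p/4
#' with one known parent, 1 with none).
#'
#' @param ped a \code{pedigree_table}.
#' @param K positive definite coefficient covariance matrix.
#' @param seed optional RNG seed; when NULL the current RNG stream is used.
#' @return numeric matrix, one row per animal in pedigree order.
#' @export
simulate_breeding_values <- function(ped, K, seed = NULL) {
  K <- as.matrix(K)
  L <- tryCatch(chol(K), error = function(e)
    stop("K is not positive definite: ", conditionMessage(e)))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ped)
  q <- nrow(K)
  si <- ped$sire_i; di <- ped$dam_i; F <- ped$F
  Z <- matrix(stats::rnorm(n * q), n, q) %*% L
  a <- matrix(0, n, q)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    mu <- numeric(q)
    if (s > 0L) mu <- mu + 0.5 * a[s, ]
    if (d > 0L) mu <- mu + 0.5 * a[d, ]
    dd <- if (s > 0L && d > 0L) 0.5 - 0.25 * (F[s] + F[d])
          else if (s > 0L) 0.75 - 0.25 * F[s]
          else if (d > 0L) 0.75 - 0.25 * F[d]
          else 1
    a[i, ] <- mu + sqrt(dd) * Z[i, ]
  }
  a
}

#' Default simulation design
#'
#' Herd structure and test calendar for [simulate_records()]: herds with a
#' shared monthly visit calendar (so herd-test-day is a genuine contemporary
#' group), each cow's first visit falling at a DIM uniform on \[5, 35\].
#'
#' @param n_herds number of herds.
#' @param cows_per_herd phenotyped cows per herd.
#' @param n_tests monthly visits per parity (default 12, spanning DIM 5-365
#'   given a first-visit DIM in \[5, 35\]).
#' @param test_interval days between visits (default 30).
#' @param n_parities parities to simulate (1-3).
#' @param parity_retention probability a cow reaches each parity (cumulative,
#'   non-increasing, first element 1).
#' @param afc_range age at first calving window in days.
#' @return a list of class \code{sim_design}.
#' @export
sim_design <- function(n_herds = 2, cows_per_herd = 250, n_tests = 12,
                       test_interval = 30, n_parities = 1,
                       parity_retention = c(1, 0.6, 0.3),
                       afc_range = c(700, 1100)) {
  stopifnot(n_herds >= 1, cows_per_herd >= 1, n_tests >= 1,
            n_parities >= 1, n_parities <= 3)
  structure(list(n_herds = n_herds, cows_per_herd = cows_per_herd,
                 n_tests = n_tests, test_interval = test_interval,
                 n_parities = n_parities,
                 parity_retention = parity_retention,
                 afc_range = afc_range),
            class = "sim_design")
}

#' Simulate test-day records from known truth
#'
#' Draws a complete test-day dataset from the random regression model: each
#' record is the sum of a herd-test-day effect, the age-season fixed curve at
#' its DIM, the cow's additive and permanent environmental random regressions
#' evaluated at its DIM, and an iid multivariate normal residual across the
#' traits of that test-day.
#'
#' @param ped a \code{pedigree_table}, preferably from [simulate_pedigree()]
#'   (its sex/generation columns choose the phenotyped females; otherwise
#'   non-founders are used).
#' @param truth a \code{truth_parameters} object.
#' @param design a \code{sim_design}.
#' @param seed integer RNG seed.
#' @return object of class \code{simulated_dataset}: list with elements
#'   \code{records} (data.frame: cow, herd, parity, birth_date, calving_date,
#'   test_date, dim, as_class, one column per trait), \code{pedigree},
#'   \code{truth}, \code{true_effects} (list a, pe), \code{seed},
#'   \code{design}.
#' @export
simulate_records <- function(ped, truth, design = sim_design(), seed) {
  stopifnot(inherits(truth, "truth_parameters"))
  if (nrow(ped) == 0) stop("empty pedigree")
  set.seed(seed)
  n_needed <- design$n_herds * design$cows_per_herd
  cand <- if (!is.null(ped$sex) && !is.null(ped$generation)) {
    which(ped$sex == "F" & ped$generation > 0)
  } else {
    which(ped$sire_i > 0 | ped$dam_i > 0)
  }
  if (length(cand) < n_needed) {
    stop("pedigree supplies only ", length(cand),
         " candidate cows; need ", n_needed)
  }
  cows <- sort(sample(cand, n_needed))
  herd <- rep(seq_len(design$n_herds), each = design$cows_per_herd)

  n_traits <- truth$n_traits
  q <- truth$order + 1
  p <- truth$fixed_order + 1
  a <- simulate_breeding_values(ped, truth$K_a)
  pe <- matrix(stats::rnorm(n_needed * nrow(truth$K_pe)), n_needed) %*%
    chol(truth$K_pe)
  Re_chol <- chol(truth$R)

  # per herd x parity: a shared monthly visit calendar
  origin <- as.Date("2015-01-15")
  max_par <- sapply(seq_len(n_needed), function(i) {
    pr <- design$parity_retention
    pr <- pr[seq_len(design$n_parities)]
    u <- stats::runif(1)
    max(which(u <= pr / pr[1]))
  })

  rows <- vector("list", n_needed)
  # age at first calving; birth date fixed per cow
  afc <- round(stats::runif(n_needed, design$afc_range[1], design$afc_range[2]))
  for (ci in seq_len(n_needed)) {
    h <- herd[ci]
    cow_rows <- list()
    birth <- NULL
    for (par in seq_len(max_par[ci])) {
      visit1 <- origin + (h - 1) * 7 + (par - 1) * 395
      visits <- visit1 + (seq_len(design$n_tests) - 1) * design$test_interval
      first_dim <- round(stats::runif(1, 5, 35))
      calving <- visits[1] - first_dim
      if (par == 1) birth <- calving - afc[ci]
      dims <- as.integer(visits - calving)
      keep <- dims >= truth$dim_range[1] & dims <= truth$dim_range[2]
      if (!any(keep)) next
      cow_rows[[par]] <- data.frame(
        cow = ped$animal[cows[ci]], herd = h, parity = par,
        birth_date = birth,
        calving_date = calving, test_date = visits[keep],
        dim = dims[keep], visit = which(keep),
        stringsAsFactors = FALSE)
    }
    rows[[ci]] <- do.call(rbind, cow_rows)
  }
  rec <- do.call(rbind, rows)
  rec$cow_i <- rep(seq_len(n_needed),
                   times = vapply(rows, function(x) if (is.null(x)) 0L else nrow(x),
                                  integer(1)))

  # age-season class from calving season (quarters), recycled over the
  # configured number of classes
  month <- as.integer(format(rec$calving_date, "%m"))
  season <- (month - 1) %/% 3 + 1
  rec$as_class <- ((season - 1) %% truth$n_as_classes) + 1

  # herd-test-day effects: iid normal per (herd, visit, parity, trait)
  htd_key <- paste(rec$herd, rec$parity, rec$visit, sep = "_")
  htd_levels <- unique(htd_key)
  htd_eff <- matrix(stats::rnorm(length(htd_levels) * n_traits,
                                 sd = truth$htd_sd),
                    length(htd_levels), n_traits)
  hidx <- match(htd_key, htd_levels)

  Phi_a <- dim_basis(rec$dim, truth$order, truth$dim_range)
  Phi_f <- dim_basis(rec$dim, truth$fixed_order, truth$dim_range)
  nrec <- nrow(rec)
  E <- matrix(stats::rnorm(nrec * n_traits), nrec) %*% Re_chol
  Y <- matrix(0, nrec, n_traits)
  anim_row <- cows[rec$cow_i]
  for (j in seq_len(n_traits)) {
    idx <- (j - 1) * q + seq_len(q)
    fc <- truth$fixed_curves[, , j, drop = FALSE][, , 1]
    if (is.null(dim(fc))) fc <- matrix(fc, nrow = truth$n_as_classes)
    Y[, j] <- htd_eff[cbind(hidx, j)] +
      rowSums(Phi_f * fc[rec$as_class, , drop = FALSE]) +
      rowSums(Phi_a * a[anim_row, idx, drop = FALSE]) +
      rowSums(Phi_a * pe[rec$cow_i, idx, drop = FALSE]) +
      E[, j]
  }
  colnames(Y) <- truth$trait_names
  rec <- cbind(rec[c("cow", "herd", "parity", "birth_date", "calving_date",
                     "test_date", "dim", "as_class")], Y)
  rec <- rec[order(rec$cow, rec$test_date), ]
  rownames(rec) <- NULL
  structure(list(records = rec, pedigree = ped, truth = truth,
                 true_effects = list(
                   a = a, pe = pe,
                   cow_animal = ped$animal[cows]),
                 seed = seed, design = design),
            class = "simulated_dataset")
}

#' True daily parameter surface implied by truth parameters
#'
#' Evaluates the variance, heritability and correlation trajectories that a
#' \code{truth_parameters} object implies over a DIM grid, via
#' \eqn{\phi(t)' K \phi(t)}. Used as the recovery reference for the Gibbs
#' sampler.
#'
#' @param truth a \code{truth_parameters} object.
#' @param dims integer DIM grid (default 5:365).
#' @return a \code{daily_surface} object (see [daily_surfaces()]).
#' @export
truth_surface <- function(truth, dims = NULL) {
  stopifnot(inherits(truth, "truth_parameters"))
  if (is.null(dims)) dims <- seq(truth$dim_range[1], truth$dim_range[2])
  surface_from_components(truth$K_a, truth$K_pe, truth$R, dims,
                          order = truth$order, dim_range = truth$dim_range,
                          trait_names = truth$trait_names)
}

#' Write a simulated dataset to plain-text files
#'
#' Records go to \code{records.csv}, the pedigree to \code{pedigree.csv}
#' (animal, sire, dam; 0 = unknown) and the truth to \code{truth.yaml}.
#'
#' @param dataset a \code{simulated_dataset}.
#' @param dir output directory (created if absent).
#' @return named character vector of the three paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "simulated_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rp <- file.path(dir, "records.csv")
  pp <- file.path(dir, "pedigree.csv")
  tp <- file.path(dir, "truth.yaml")
  utils::write.csv(dataset$records, rp, row.names = FALSE)
  ped <- dataset$pedigree
  par <- ped_parent_ids(ped)
  utils::write.csv(data.frame(animal = ped$animal, sire = par$sire,
                              dam = par$dam),
                   pp, row.names = FALSE)
  tr <- dataset$truth
  yaml::write_yaml(list(
    K_a = as.vector(tr$K_a), K_pe = as.vector(tr$K_pe), R = as.vector(tr$R),
    order = tr$order, fixed_order = tr$fixed_order,
    dim_range = tr$dim_range, trait_names = tr$trait_names,
    htd_sd = tr$htd_sd, n_traits = tr$n_traits), tp)
  invisible(c(records = rp, pedigree = pp, truth = tp))
}
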