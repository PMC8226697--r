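test_that("somatic cell score transform follows the log2 definition", {
  expect_equal(transform_scs(100000), 3)
  expect_equal(transform_scs(200000), 4)
  expect_equal(transform_scs(50000), 2)
  expect_error(transform_scs(0), "positive")
  expect_error(transform_scs(-5), "positive")
  expect_error(transform_scs(NA), "positive")
})

test_that("transform is strictly increasing and round-trips to 1e-9", {
  set.seed(3)
  scc <- sort(10^runif(200, 3, 7))
  scs <- transform_scs(scc)
  expect_true(all(diff(scs) > 0))
  expect_equal(scs_to_scc(scs) / scc, rep(1, 200), tolerance = 1e-9)
})

test_that("calving season follows quarter boundaries", {
  expect_equal(as.character(calving_season(as.Date("2015-02-10"))), "winter")
  expect_equal(as.character(calving_season(as.Date("2015-10-01"))), "autumn")
  expect_equal(as.character(calving_season(as.Date("2015-03-31"))), "winter")
  expect_equal(as.character(calving_season(as.Date("2015-04-01"))), "spring")
  expect_equal(as.character(calving_season(as.Date("2015-07-15"))), "summer")
})

test_that("age bins use supplied cutpoints with the lower-bin rule", {
  rec <- data.frame(cow = 1:6, parity = 1,
                    birth_date = as.Date("2012-01-01"),
                    calving_date = as.Date("2012-01-01") +
                      c(700, 800, 850, 900, 1000, 1150))
  cuts <- c(800, 870, 950, 1100)
  out <- assign_age_season(rec, age_bins = list("1" = cuts))
  # 800 sits exactly on the first cutpoint -> lower bin
  expect_equal(out$age_bin, c(1L, 1L, 2L, 3L, 4L, 5L))
})

test_that("default bins are within-parity age quintiles", {
  rec <- data.frame(cow = 1:100, parity = rep(1:2, 50),
                    birth_date = as.Date("2011-06-01"))
  set.seed(1)
  rec$calving_date <- rec$birth_date + round(runif(100, 650, 1190))
  out <- assign_age_season(rec)
  tab <- table(out$parity, out$age_bin)
  expect_true(all(tab > 0))
  expect_equal(ncol(tab), 5)
})

test_that("DIM and AFC windows are inclusive at their boundaries", {
  base <- data.frame(
    cow = "c1", herd = 1, parity = 1,
    birth_date = as.Date("2010-01-01"),
    calving_date = as.Date("2012-01-01"),
    test_date = as.Date("2012-02-01"),
    SCS = 3, stringsAsFactors = FALSE)
  rec <- base[rep(1, 4), ]
  rec$dim <- c(4, 5, 365, 366)
  # AFC here is 730 d, inside the window
  out <- apply_edits(rec)
  expect_equal(out$records$dim, c(5, 365))
  expect_equal(out$report$removed$dim_window, 2)

  afc <- rbind(
    transform(base, cow = "a639", birth_date = calving_date - 639, dim = 50),
    transform(base, cow = "a640", birth_date = calving_date - 640, dim = 50),
    transform(base, cow = "a1200", birth_date = calving_date - 1200, dim = 50),
    transform(base, cow = "a1201", birth_date = calving_date - 1201, dim = 50))
  out <- apply_edits(afc)
  expect_setequal(out$records$cow, c("a640", "a1200"))
  expect_equal(out$report$removed$afc_window, 2)
})

test_that("edit report reconciles counts on a mixed toy file", {
  base <- data.frame(
    cow = rep(c("c1", "c2", "c3"), c(4, 3, 3)), herd = 1,
    parity = 1,
    birth_date = as.Date("2010-01-01"),
    calving_date = as.Date("2012-01-01"),
    test_date = as.Date("2012-03-01"),
    dim = 60, SCS = 3, MY = 30, stringsAsFactors = FALSE)
  base$dim[c(1, 5)] <- c(2, 400)      # two DIM violations
  base$SCS[8] <- NA                   # one incomplete test-day
  out <- apply_edits(base)
  expect_equal(nrow(out$records), 7)
  expect_equal(out$report$n_input,
               out$report$n_retained + sum(unlist(out$report$removed)))
  expect_output(print(out$report), "retained")
})

test_that("parity cap and the lactation nesting rule are enforced", {
  mk <- function(cow, parity) data.frame(
    cow = cow, herd = 1, parity = parity,
    birth_date = as.Date("2010-01-01"),
    calving_date = as.Date("2012-01-01") + (parity - 1) * 400,
    test_date = as.Date("2012-01-01") + (parity - 1) * 400 + 60,
    dim = 60, SCS = 3)
  rec <- rbind(mk("A", 1), mk("A", 2), mk("A", 3),
               mk("B", 1), mk("B", 3),      # parity 2 missing: 3 dropped
               mk("C", 2),                  # parity 1 missing: dropped
               mk("D", 4),                  # above parity cap
               mk("D", 1))
  out <- apply_edits(rec)
  kept <- paste(out$records$cow, out$records$parity)
  expect_setequal(kept, c("A 1", "A 2", "A 3", "B 1", "D 1"))
  expect_equal(out$report$removed$parity_above_max, 1)
  # cow C has no first lactation, so her age at first calving is unknown
  # and the AFC rule removes her before the nesting rule sees parity 2
  expect_equal(out$report$removed$afc_window, 1)
  expect_equal(out$report$removed$lactation_nesting, 1)
})

test_that("editing is idempotent", {
  ds <- small_dataset(seed = 19)
  rec <- ds$records
  rec$SCS[3] <- NA
  rec$dim[10] <- 2
  once <- apply_edits(rec)
  twice <- apply_edits(once$records)
  expect_equal(once$records, twice$records)
  expect_equal(sum(unlist(twice$report$removed)), 0)
})

test_that("cows with records but no pedigree row become founders", {
  ds <- small_dataset(seed = 23)
  ped <- ds$pedigree
  drop_cow <- unique(ds$records$cow)[1]
  ped2 <- ped_validate_sort(
    data.frame(animal = ped$animal[ped$animal != drop_cow],
               sire = "0", dam = "0"))
  expect_warning(out <- apply_edits(ds$records, ped2), "founder")
  expect_true(all(unique(out$records$cow) %in% out$pedigree$animal))
})

test_that("unparseable dates are reported and dropped", {
  rec <- data.frame(
    cow = c("x", "y"), herd = 1, parity = 1,
    birth_date = as.Date(c("2010-01-01", NA)),
    calving_date = as.Date("2012-01-01"),
    test_date = as.Date("2012-03-01"),
    dim = 60, SCS = 3)
  out <- apply_edits(rec)
  expect_equal(out$records$cow, "x")
  expect_equal(out$report$removed$invalid_dates_or_parity, 1)
})

test_that("descriptive statistics reproduce mean/SD/CV relationships", {
  # exact two-point construction: mean m, sample SD s
  two_point <- function(m, s) c(m - s / sqrt(2), m + s / sqrt(2))
  rec <- data.frame(parity = 1,
                    MY = two_point(31.6, 7.6),
                    SCS = two_point(2.39, 1.97))
  st <- descriptive_stats(rec, traits = c("MY", "SCS"))
  expect_equal(st$mean[st$trait == "MY"], 31.6)
  expect_equal(st$sd[st$trait == "MY"], 7.6)
  expect_equal(round(st$cv[st$trait == "MY"]), 24)
  expect_equal(round(st$cv[st$trait == "SCS"]), 82)

  cst <- descriptive_stats(data.frame(parity = 1, X = rep(5, 4)),
                           traits = "X")
  expect_equal(cst$sd, 0)
  expect_equal(cst$cv, 0)
  zm <- descriptive_stats(data.frame(parity = 1, X = c(-1, 1)), traits = "X")
  expect_true(is.na(zm$cv))
  expect_error(descriptive_stats(data.frame()), "no records")
})
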