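#' Somatic cell score transformation
#'
#' Transforms a somatic cell count (cells/mL) to the somatic cell score
#' scale: \code{SCS = log2(SCC / 100000) + 3}. An SCC of 100,000 maps to
#' SCS 3; doubling SCC adds exactly one score unit.
#'
#' @param scc numeric vector of somatic cell counts, cells/mL, strictly
#'   positive.
#' @return numeric vector of somatic cell scores.
#' @examples
#' transform_scs(100000)   # 3
#' transform_scs(200000)   # 4
#' @export
transform_scs <- function(scc) {
  if (any(!is.finite(scc) | scc <= 0)) {
    stop("SCC must be positive and finite; flag and exclude such records ",
         "rather than transforming them")
  }
  log2(scc / 1e5) + 3
}

#' Inverse somatic cell score transformation
#'
#' @param scs numeric vector of somatic cell scores.
#' @return somatic cell counts, cells/mL.
#' @export
scs_to_scc <- function(scs) 1e5 * 2^(scs - 3)

#' Read test-day records from CSV
#'
#' Expects columns \code{cow, herd, parity, birth_date, calving_date,
#' test_date, dim} plus one column per trait; dates ISO-8601. Unparseable
#' dates become NA (they are removed and reported by [apply_edits()]).
#'
#' @param path CSV path.
#' @return data.frame of test-day records.
#' @export
read_testday <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cow", "herd", "parity", "birth_date", "calving_date",
            "test_date", "dim")
  miss <- setdiff(need, names(rec))
  if (length(miss)) stop("records file missing columns: ",
                         paste(miss, collapse = ", "))
  for (cl in c("birth_date", "calving_date", "test_date")) {
    rec[[cl]] <- as.Date(rec[[cl]], format = "%Y-%m-%d")
  }
  rec
}

#' Read a pedigree CSV
#'
#' Three columns animal, sire, dam; 0 or blank marks an unknown parent.
#'
#' @param path CSV path.
#' @return sorted \code{pedigree_table} (see [ped_validate_sort()]).
#' @export
read_pedigree <- function(path) {
  ped_validate_sort(utils::read.csv(path, stringsAsFactors = FALSE,
                                    colClasses = "character"))
}

#' Calving season from calving date
#'
#' Winter is January-March, spring April-June, summer July-September,
#' autumn October-December.
#'
#' @param calving_date Date vector.
#' @return factor with levels winter, spring, summer, autumn.
#' @export
calving_season <- function(calving_date) {
  month <- as.integer(format(as.Date(calving_date), "%m"))
  factor(c("winter", "spring", "summer", "autumn")[(month - 1) %/% 3 + 1],
         levels = c("winter", "spring", "summer", "autumn"))
}

#' Assign age-season of calving classes
#'
#' Each record receives a class combining its calving season with one of
#' five within-parity age-at-calving bins (up to 20 classes per parity).
#' Bins are half-open \code{(lo, hi]}: an age exactly at a cutpoint falls
#' in the lower bin. Ages outside the bin range are clamped to the edge bins
#' with a warning. When no cutpoints are supplied they are the within-parity
#' age quintiles of the data.
#'
#' @param records test-day data.frame with \code{parity}, \code{birth_date},
#'   \code{calving_date}.
#' @param age_bins optional named list: per parity (as character), the 4
#'   interior cutpoints (days) separating the 5 bins.
#' @return \code{records} with added columns \code{age_days},
#'   \code{age_bin}, \code{season}, \code{as_class} (factor
#'   parity:age_bin:season).
#' @export
assign_age_season <- function(records, age_bins = NULL) {
  records$age_days <- as.integer(as.Date(records$calving_date) -
                                   as.Date(records$birth_date))
  records$season <- calving_season(records$calving_date)
  records$age_bin <- NA_integer_
  for (par in sort(unique(records$parity))) {
    sel <- records$parity == par
    ages <- records$age_days[sel]
    cuts <- if (!is.null(age_bins)) {
      age_bins[[as.character(par)]]
    } else {
      unique(stats::quantile(ages, probs = c(0.2, 0.4, 0.6, 0.8),
                             type = 1, names = FALSE))
    }
    bin <- findInterval(ages, cuts, left.open = TRUE) + 1L
    if (!is.null(age_bins) &&
        (any(ages < min(cuts) - 365) || any(ages >= max(cuts) + 365))) {
      warning("ages far outside the supplied cutpoints in parity ", par,
              "; assigned to edge bins")
    }
    bin <- pmin(pmax(bin, 1L), 5L)
    records$age_bin[sel] <- bin
  }
  records$as_class <- interaction(records$parity, records$age_bin,
                                  records$season, drop = TRUE)
  records
}

#' Default edit configuration
#'
#' @param dim_window inclusive DIM window, default \code{c(5, 365)}.
#' @param afc_window inclusive age-at-first-calving window in days,
#'   default \code{c(640, 1200)}.
#' @param max_parity highest retained parity, default 3.
#' @param required_traits traits that must be present (non-missing) on every
#'   retained test-day.
#' @return list of class \code{edit_config}.
#' @export
edit_config <- function(dim_window = c(5, 365), afc_window = c(640, 1200),
                        max_parity = 3, required_traits = NULL) {
  structure(list(dim_window = dim_window, afc_window = afc_window,
                 max_parity = max_parity, required_traits = required_traits),
            class = "edit_config")
}

#' Apply the test-day editing rules
#'
#' Applies, in a fixed documented order, the standard edits for a
#' random-regression test-day analysis:
#' \enumerate{
#'   \item records with unparseable or missing dates, or missing parity, or
#'     cows with any such record, are removed;
#'   \item parities above \code{max_parity} are removed;
#'   \item test-days missing any required trait are removed;
#'   \item DIM outside the (inclusive) window is removed;
#'   \item cows whose age at first calving falls outside the window lose all
#'     their records;
#'   \item the lactation-nesting rule: a parity-k lactation is kept only if
#'     parities 1..k-1 are also present for that cow;
#'   \item when a pedigree is supplied, cows absent from it are appended to
#'     it as founders (with a warning), so every retained record's cow is
#'     pedigreed.
#' }
#' The edit report reconciles counts: input = retained + sum(removed).
#'
#' @param records test-day data.frame (see [read_testday()]).
#' @param pedigree optional \code{pedigree_table}.
#' @param config an [edit_config()].
#' @return list with elements \code{records}, \code{pedigree} (possibly
#'   augmented), and \code{report} (class \code{edit_report}).
#' @export
apply_edits <- function(records, pedigree = NULL, config = edit_config()) {
  n_in <- nrow(records)
  removed <- c()
  drop_step <- function(rec, keep, rule) {
    removed[rule] <<- sum(!keep)
    rec[keep, , drop = FALSE]
  }

  ok_dates <- !is.na(records$birth_date) & !is.na(records$calving_date) &
    !is.na(records$test_date) & !is.na(records$parity)
  bad_cows <- unique(records$cow[!ok_dates])
  records <- drop_step(records, ok_dates & !(records$cow %in% bad_cows),
                       "invalid_dates_or_parity")

  records <- drop_step(records, records$parity <= config$max_parity,
                       "parity_above_max")

  req <- config$required_traits
  if (is.null(req)) {
    req <- setdiff(names(records),
                   c("cow", "herd", "parity", "birth_date", "calving_date",
                     "test_date", "dim", "as_class", "age_days", "age_bin",
                     "season", "visit"))
  }
  complete <- rep(TRUE, nrow(records))
  for (tr in req) complete <- complete & !is.na(records[[tr]])
  if ("SCC" %in% req) complete <- complete & records$SCC > 0
  records <- drop_step(records, complete, "incomplete_traits")

  records <- drop_step(records,
                       records$dim >= config$dim_window[1] &
                         records$dim <= config$dim_window[2],
                       "dim_window")

  # AFC applies to the whole cow
  first <- records[records$parity == 1, ]
  afc_by_cow <- tapply(as.integer(as.Date(first$calving_date) -
                                    as.Date(first$birth_date)),
                       first$cow, min)
  afc_ok_cows <- names(afc_by_cow)[afc_by_cow >= config$afc_window[1] &
                                     afc_by_cow <= config$afc_window[2]]
  records <- drop_step(records, records$cow %in% afc_ok_cows, "afc_window")

  # nesting: parity k requires parities 1..k-1 present for the cow
  pres <- unique(records[c("cow", "parity")])
  keep_pair <- rep(TRUE, nrow(pres))
  for (i in seq_len(nrow(pres))) {
    k <- pres$parity[i]
    if (k > 1) {
      keep_pair[i] <- all(seq_len(k - 1) %in%
                            pres$parity[pres$cow == pres$cow[i]])
    }
  }
  ok_pairs <- pres[keep_pair, ]
  records <- drop_step(records,
                       paste(records$cow, records$parity) %in%
                         paste(ok_pairs$cow, ok_pairs$parity),
                       "lactation_nesting")

  if (!is.null(pedigree)) {
    missing_cows <- setdiff(unique(as.character(records$cow)),
                            pedigree$animal)
    if (length(missing_cows)) {
      warning(length(missing_cows), " cows with records absent from the ",
              "pedigree; added as founders")
      par <- ped_parent_ids(pedigree)
      pedigree <- ped_validate_sort(data.frame(
        animal = c(pedigree$animal, missing_cows),
        sire = c(par$sire, rep("0", length(missing_cows))),
        dam = c(par$dam, rep("0", length(missing_cows)))))
    }
  }

  report <- structure(list(n_input = n_in, n_retained = nrow(records),
                           removed = as.list(removed)),
                      class = "edit_report")
  stopifnot(report$n_input == report$n_retained + sum(unlist(removed)))
  list(records = records, pedigree = pedigree, report = report)
}

#' @method print edit_report
#' @export
print.edit_report <- function(x, ...) {
  cat("Test-day edit report\n")
  cat("  records in: ", x$n_input, "\n", sep = "")
  for (nm in names(x$removed)) {
    cat(sprintf("  removed by %-28s %d\n", paste0(nm, ":"), x$removed[[nm]]))
  }
  cat("  retained:   ", x$n_retained, "\n", sep = "")
  invisible(x)
}

#' Write an edit report as JSON
#'
#' @param report an \code{edit_report}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_edit_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Descriptive statistics per trait and parity
#'
#' Mean, sample SD and coefficient of variation (CV% = 100 SD / mean) over
#' test-day records. A zero mean leaves the CV undefined (NA).
#'
#' @param records test-day data.frame.
#' @param traits character vector of trait columns (default: all non-id
#'   numeric columns).
#' @param by grouping column, default \code{"parity"}.
#' @return data.frame with columns group, trait, n, mean, sd, cv.
#' @examples
#' descriptive_stats(data.frame(parity = 1, MY = c(25, 32, 38)))
#' @export
descriptive_stats <- function(records, traits = NULL, by = "parity") {
  if (!nrow(records)) stop("no records")
  if (is.null(traits)) {
    traits <- setdiff(names(records)[vapply(records, is.numeric, TRUE)],
                      c("cow", "herd", "parity", "dim", "age_days",
                        "age_bin", "visit"))
  }
  groups <- sort(unique(records[[by]]))
  out <- expand.grid(group = groups, trait = traits,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  names(out)[1] <- by
  out$n <- NA_integer_; out$mean <- out$sd <- out$cv <- NA_real_
  for (i in seq_len(nrow(out))) {
    x <- records[[out$trait[i]]][records[[by]] == out[[by]][i]]
    x <- x[!is.na(x)]
    out$n[i] <- length(x)
    out$mean[i] <- mean(x)
    out$sd[i] <- if (length(x) > 1) stats::sd(x) else 0
    out$cv[i] <- if (abs(out$mean[i]) > 0) 100 * out$sd[i] / out$mean[i]
                 else NA_real_
  }
  out
}
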