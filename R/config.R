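# Pipeline drivers: a YAML run configuration and three stage functions
# (simulate -> fit -> summarize) that read and write plain-text files, so a
# whole analysis is reproducible from one config and one seed.

#' Load and validate a run configuration
#'
#' The configuration is a YAML file (or an equivalent list) with blocks:
#' \describe{
#'   \item{paths}{\code{records}, \code{pedigree}, \code{out_dir}}
#'   \item{model}{\code{traits}, \code{rr_order}, \code{fixed_order},
#'     \code{dim_range}, \code{use_as}}
#'   \item{edits}{\code{dim_window}, \code{afc_window}, \code{max_parity}}
#'   \item{chain}{\code{n_iter}, \code{burn_in}, \code{thin}, \code{seed}}
#'   \item{simulation}{\code{n_founders}, \code{n_generations},
#'     \code{offspring_per_mating}, \code{n_herds}, \code{cows_per_herd},
#'     \code{n_tests}, \code{truth} ("scs" or "twotrait")}
#' }
#' Unknown blocks are an error; every run echoes the resolved configuration
#' next to its outputs.
#'
#' @param config path to a YAML file, or a list.
#' @return validated configuration list of class \code{run_config}.
#' @export
load_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  known <- c("paths", "model", "edits", "chain", "simulation")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config blocks: ", paste(bad, collapse = ", "))
  ch <- cfg$chain
  if (!is.null(ch)) {
    for (f in c("n_iter", "burn_in")) {
      if (is.null(ch[[f]])) stop("chain block needs ", f)
    }
    if (ch$n_iter <= ch$burn_in) stop("chain: n_iter must exceed burn_in")
  }
  structure(cfg, class = "run_config")
}

echo_config <- function(cfg, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "run_config.yaml"))
}

#' Simulate a dataset from a run configuration
#'
#' Writes \code{records.csv}, \code{pedigree.csv} and \code{truth.yaml} to
#' the output directory. Byte-identical outputs for identical seeds.
#'
#' @param config a \code{run_config} (or path / list, see [load_config()]).
#' @param seed integer seed; overrides \code{chain$seed} if given.
#' @return the \code{simulated_dataset}, invisibly.
#' @export
tdm_simulate <- function(config, seed = NULL) {
  cfg <- load_config(config)
  sim <- cfg$simulation
  if (is.null(sim)) stop("config has no simulation block")
  if (is.null(seed)) seed <- if (!is.null(cfg$chain$seed)) cfg$chain$seed else 1
  out_dir <- cfg$paths$out_dir
  if (is.null(out_dir)) stop("config needs paths$out_dir")
  truth <- switch(if (is.null(sim$truth)) "scs" else sim$truth,
                  scs = truth_scs(), twotrait = truth_twotrait(),
                  stop("unknown simulation truth: ", sim$truth))
  ped <- simulate_pedigree(
    n_founders = if (is.null(sim$n_founders)) 340 else sim$n_founders,
    n_generations = if (is.null(sim$n_generations)) 3 else sim$n_generations,
    offspring_per_mating =
      if (is.null(sim$offspring_per_mating)) 2 else sim$offspring_per_mating,
    seed = seed)
  des <- sim_design(
    n_herds = if (is.null(sim$n_herds)) 2 else sim$n_herds,
    cows_per_herd = if (is.null(sim$cows_per_herd)) 250 else sim$cows_per_herd,
    n_tests = if (is.null(sim$n_tests)) 12 else sim$n_tests)
  ds <- simulate_records(ped, truth, des, seed = seed + 1)
  echo_config(cfg, out_dir)
  write_dataset(ds, out_dir)
  invisible(ds)
}

#' Fit the model from a run configuration
#'
#' Reads records and pedigree, applies the edits, builds the design and
#' A-inverse, and runs the Gibbs chain. Writes the retained covariance
#' samples (\code{chain.csv}), the edit report (\code{edit_report.json})
#' and convergence diagnostics (\code{diagnostics.csv}).
#'
#' @inheritParams tdm_simulate
#' @return the \code{posterior_chain}, invisibly.
#' @export
tdm_fit <- function(config, seed = NULL) {
  cfg <- load_config(config)
  if (is.null(cfg$paths$records) || is.null(cfg$paths$pedigree)) {
    stop("config needs paths$records and paths$pedigree")
  }
  out_dir <- cfg$paths$out_dir
  if (is.null(out_dir)) stop("config needs paths$out_dir")
  if (is.null(seed)) seed <- if (!is.null(cfg$chain$seed)) cfg$chain$seed else 1
  records <- read_testday(cfg$paths$records)
  pedigree <- read_pedigree(cfg$paths$pedigree)
  ed_cfg <- edit_config(
    dim_window = if (is.null(cfg$edits$dim_window)) c(5, 365)
                 else cfg$edits$dim_window,
    afc_window = if (is.null(cfg$edits$afc_window)) c(640, 1200)
                 else cfg$edits$afc_window,
    max_parity = if (is.null(cfg$edits$max_parity)) 3
                 else cfg$edits$max_parity)
  ed <- apply_edits(records, pedigree, ed_cfg)
  md <- cfg$model
  traits <- if (!is.null(md$traits)) md$traits else {
    setdiff(names(records), c("cow", "herd", "parity", "birth_date",
                              "calving_date", "test_date", "dim",
                              "as_class", "visit"))
  }
  spec <- model_spec(
    traits = traits,
    rr_order = if (is.null(md$rr_order)) 2 else md$rr_order,
    fixed_order = if (is.null(md$fixed_order)) 4 else md$fixed_order,
    dim_range = if (is.null(md$dim_range)) ed_cfg$dim_window else md$dim_range,
    use_as = if (is.null(md$use_as)) TRUE else md$use_as)
  rec <- ed$records
  if (spec$use_as && is.null(rec$as_class)) rec <- assign_age_season(rec)
  design <- build_design(rec, ed$pedigree, spec)
  Ainv <- a_inverse(ed$pedigree)
  chain <- run_chain(design, Ainv,
                     n_iter = cfg$chain$n_iter, burn_in = cfg$chain$burn_in,
                     thin = if (is.null(cfg$chain$thin)) 10
                            else cfg$chain$thin,
                     seed = seed)
  echo_config(cfg, out_dir)
  write_edit_report(ed$report, file.path(out_dir, "edit_report.json"))
  write_chain(chain, file.path(out_dir, "chain.csv"))
  utils::write.csv(chain_diagnostics(chain),
                   file.path(out_dir, "diagnostics.csv"), row.names = FALSE)
  saveRDS_path <- file.path(out_dir, "chain_meta.yaml")
  yaml::write_yaml(list(n_iter = chain$n_iter, burn_in = chain$burn_in,
                        thin = chain$thin, seed = chain$seed,
                        traits = chain$trait_names,
                        rr_order = chain$rr_order,
                        dim_range = chain$dim_range), saveRDS_path)
  invisible(chain)
}

#' Summarize a fitted chain from a run configuration
#'
#' Computes the daily parameter surfaces and mean (range) summaries and
#' writes \code{surfaces.csv} and \code{summary.csv} to the output
#' directory.
#'
#' @param chain a \code{posterior_chain} (as returned by [tdm_fit()]).
#' @param config a \code{run_config} providing \code{paths$out_dir}.
#' @return the \code{daily_surface}, invisibly.
#' @export
tdm_summarize <- function(chain, config) {
  cfg <- load_config(config)
  out_dir <- cfg$paths$out_dir
  if (is.null(out_dir)) stop("config needs paths$out_dir")
  surface <- daily_surfaces(chain)
  echo_config(cfg, out_dir)
  write_surface(surface, file.path(out_dir, "surfaces.csv"))
  utils::write.csv(summarize_mean_range(surface),
                   file.path(out_dir, "summary.csv"), row.names = FALSE)
  invisible(surface)
}

#' Fit the model to a simulated dataset
#'
#' Convenience wrapper chaining [assign_age_season()], [build_design()],
#' [a_inverse()] and [run_chain()] for a \code{simulated_dataset}, the
#' standard path of parameter-recovery studies.
#'
#' @param dataset a \code{simulated_dataset} from [simulate_records()].
#' @param n_iter,burn_in,thin,seed chain settings (see [run_chain()]).
#' @param use_as include the age-season fixed regression (default TRUE).
#' @return a \code{posterior_chain}.
#' @export
fit_dataset <- function(dataset, n_iter, burn_in, thin = 10, seed = 1,
                        use_as = TRUE) {
  stopifnot(inherits(dataset, "simulated_dataset"))
  truth <- dataset$truth
  rec <- assign_age_season(dataset$records)
  spec <- model_spec(truth$trait_names, rr_order = truth$order,
                     fixed_order = truth$fixed_order,
                     dim_range = truth$dim_range, use_as = use_as)
  design <- build_design(rec, dataset$pedigree, spec)
  run_chain(design, a_inverse(dataset$pedigree), n_iter = n_iter,
            burn_in = burn_in, thin = thin, seed = seed)
}
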