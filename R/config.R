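#' Read a run configuration
#'
#' A single YAML or JSON document drives the command-line pipeline. Top
#' level sections: `simulate` (fields of [simulation_config()] or
#' `preset`), `input` (paths `contacts`, `covariates` or `fasta`/`te`/`acc`
#' plus `region` with `chrom`, `length_bp`, `bin_size`), `prior` (fields of
#' [prior_config()] or `mode: empirical_bayes`), `mcmc` (fields of
#' [mcmc_config()] plus `K`, scalar or vector of candidates) and `call`
#' (`threshold`, `tads`, `genes_promoters`). Every defaulted value is
#' written back into the echoed config so a run is reconstructible from the
#' echo alone.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON (`.json`) file.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file `%s` not found", path), class = "hicmrf_usage")
  }
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  structure(as.list(cfg), class = "run_config")
}

resolve_sim_config <- function(sc, seed = NULL) {
  if (!is.null(sc$preset)) {
    out <- simulation_preset(sc$preset, seed = seed %||% sc$seed %||% 1)
  } else {
    args <- sc[intersect(names(sc), names(formals(simulation_config)))]
    if (!is.null(seed)) args$seed <- seed
    if (!is.null(args$betas)) args$betas <- do.call(rbind, args$betas)
    out <- do.call(simulation_config, args)
  }
  out
}

echo_config <- function(cfg, path) {
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}

#' Pipeline commands
#'
#' Thin drivers behind the `hicmrf` command-line script (see
#' `system.file("scripts", "hicmrf.R", package = "hicmrf")`).
#' `cmd_simulate()` writes a simulated dataset (contact triplets, covariate
#' table, ground-truth labels); `cmd_fit()` assembles observations, runs the
#' sampler for each candidate K (writing a DIC table when there are
#' several) and serializes chains and posterior summaries; `cmd_call()`
#' turns a fitted chain into BEDPE calls plus characterization tables.
#' Every command echoes its fully-resolved configuration as JSON and is
#' deterministic given a seed.
#'
#' @param config A `run_config` (or path to one).
#' @param out_dir Output directory.
#' @param seed Overrides the config seed when not `NULL`.
#' @param quiet Suppress the one-line summaries.
#' @return Invisibly, a named list of the files written.
#' @export
cmd_simulate <- function(config, out_dir, seed = NULL, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(config$simulate)) {
    abort("config has no `simulate` section", class = "hicmrf_usage")
  }
  sc <- resolve_sim_config(config$simulate, seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_hic(sc)
  paths <- write_simulated_dataset(
    sim,
    file.path(out_dir, "contacts.tsv"),
    file.path(out_dir, "truth.tsv")
  )
  cov_path <- file.path(out_dir, "covariates.tsv")
  cov <- sim$observations[, c("site", "i", "j", "D", "GC", "TE", "ACC")]
  cov$bin_i <- cov$i - 1L
  cov$bin_j <- sc$lattice_shape[1] + cov$j - 1L
  readr::write_tsv(cov, cov_path, progress = FALSE)
  echo <- unclass(sc)
  echo$covariate_specs <- purrr::map(echo$covariate_specs, unclass)
  echo_config(echo, file.path(out_dir, "config_echo.json"))
  if (!quiet) {
    message(sprintf("simulated n=%d K=%d alphas=(%s) seed=%d",
                    sc$n_pairs, sc$K,
                    paste(format(sc$alphas), collapse = ", "), sc$seed))
  }
  invisible(list(contacts = paths[["contacts"]], truth = paths[["truth"]],
                 covariates = cov_path,
                 config = file.path(out_dir, "config_echo.json")))
}

load_run_data <- function(config) {
  inp <- config$input
  if (is.null(inp)) abort("config has no `input` section", class = "hicmrf_usage")
  if (!is.null(inp$covariates)) {
    # simulated-path inputs: triplet contacts + covariate table
    cov <- readr::read_tsv(inp$covariates, show_col_types = FALSE,
                           progress = FALSE)
    contacts <- readr::read_tsv(inp$contacts, col_names = c("i", "j", "y"),
                                show_col_types = FALSE, progress = FALSE)
    obs <- mutate(cov, y = as.integer(contacts$y[match(
      paste(cov$bin_i, cov$bin_j), paste(contacts$i, contacts$j))]))
    if (anyNA(obs$y)) abort("contacts and covariates tables do not match",
                            class = "hicmrf_format")
    lat <- pair_lattice(sites = obs[, c("i", "j")])
    structure(list(observations = obs, lattice = lat), class = "hic_dataset")
  } else {
    reg <- inp$region
    if (is.null(reg)) abort("`input` needs a `region`", class = "hicmrf_usage")
    bins <- genomic_bins(reg$chrom, reg$length_bp, reg$bin_size)
    pairs <- read_contact_matrix(inp$contacts, bins = bins,
                                 bin_size = reg$bin_size)
    gc <- compute_gc_track(inp$fasta, bins)
    te <- compute_interval_track(inp$te, bins)
    acc <- compute_signal_track(inp$acc, bins)
    ds <- assemble_observations(pairs, gc, te, acc, bins,
                                pseudocount = inp$pseudocount %||% 0.5)
    ds
  }
}

#' @rdname cmd_simulate
#' @export
cmd_fit <- function(config, out_dir, seed = NULL, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  data <- load_run_data(config)
  mc <- config$mcmc %||% list()
  Ks <- as.integer(mc$K %||% 2)
  mc$K <- NULL
  no_covariates <- isTRUE(mc$no_covariates)
  mc$no_covariates <- NULL
  args <- mc[intersect(names(mc), names(formals(mcmc_config)))]
  if (!is.null(seed)) args$seed <- seed
  cfg <- do.call(mcmc_config, args)
  if (no_covariates) {
    # intercept-only ablation: constant covariates make all slope terms 0
    data$observations <- mutate(data$observations, D = 1, GC = 1, TE = 1,
                                ACC = 1)
  }
  prior_spec <- config$prior %||% list()
  prior_for <- function(K) {
    if (identical(prior_spec$mode, "empirical_bayes")) {
      empirical_bayes_hyperpriors(data$observations, K)
    } else if (length(prior_spec) > 0 && !is.null(prior_spec$beta_prior_means)) {
      args <- prior_spec
      args$K <- K
      args$beta_prior_means <- do.call(rbind, args$beta_prior_means)
      if (is.list(args$beta_prior_sds)) {
        args$beta_prior_sds <- do.call(rbind, args$beta_prior_sds)
      }
      do.call(prior_config, args[intersect(names(args),
                                           names(formals(prior_config)))])
    } else {
      prior_config(K)
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- list()
  if (length(Ks) > 1) {
    sel <- select_K(data, candidate_Ks = Ks, prior = prior_for, config = cfg,
                    keep_chains = TRUE)
    readr::write_tsv(sel$table, file.path(out_dir, "dic_table.tsv"),
                     progress = FALSE)
    written$dic_table <- file.path(out_dir, "dic_table.tsv")
    chains <- sel$chains
    if (!quiet) message(sprintf("selected K = %d by DIC", sel$best_K))
  } else {
    chains <- list(run_mcmc(data, K = Ks, prior = prior_for(Ks),
                            config = cfg))
    names(chains) <- paste0("K", Ks)
  }
  for (nm in names(chains)) {
    cd <- file.path(out_dir, paste0("chain_", nm))
    write_chain(chains[[nm]], cd)
    readr::write_tsv(posterior_summaries(chains[[nm]]),
                     file.path(cd, "summaries.tsv"), progress = FALSE)
    written[[nm]] <- cd
    if (!quiet) {
      g <- glance(chains[[nm]])
      message(sprintf("%s: %d draws, beta acc %.2f, gamma acc %.2f", nm,
                      g$retained, g$accept_beta, g$accept_gamma))
    }
  }
  echo <- list(input = config$input, prior = prior_spec,
               mcmc = c(unclass(cfg), list(K = Ks,
                                           no_covariates = no_covariates)))
  echo_config(echo, file.path(out_dir, "config_echo.json"))
  written$config <- file.path(out_dir, "config_echo.json")
  invisible(written)
}

#' @rdname cmd_simulate
#' @param chain_dir Directory written by `cmd_fit()` for one chain.
#' @export
cmd_call <- function(config, chain_dir, out_dir, seed = NULL, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  cc <- config$call %||% list()
  chain <- read_chain(chain_dir)
  if (is.null(chain$role_map)) {
    abort("chain has no role map; refit with covariate data",
          class = "hicmrf_format")
  }
  calls <- call_interactions(chain, threshold = cc$threshold %||% 0.5)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- list()
  reg <- config$input$region
  bins <- if (!is.null(reg)) {
    genomic_bins(reg$chrom, reg$length_bp, reg$bin_size)
  } else {
    # simulated data: lattice coordinates stand in for bins
    m <- max(calls$i, calls$j, calls$bin_i %||% 0, calls$bin_j %||% 0) + 1L
    genomic_bins("sim", m * 1000, 1000)
  }
  if (!"bin_i" %in% names(calls)) {
    calls$bin_i <- calls$i - 1L
    calls$bin_j <- calls$j - 1L
  }
  bedpe <- file.path(out_dir, "calls.bedpe")
  write_calls_bedpe(calls, bins, bedpe)
  written$bedpe <- bedpe
  char <- withCallingHandlers(
    characterize_calls(calls, bins, tads = cc$tads,
                       genes_promoters = cc$genes_promoters,
                       distance_breaks = cc$distance_breaks %||%
                         c(0, 1e4, 1e5, 1e6, 1e7, Inf)),
    warning = function(w) invokeRestart("muffleWarning")
  )
  readr::write_tsv(char$distance_histogram,
                   file.path(out_dir, "distance_histogram.tsv"),
                   progress = FALSE)
  written$distance_histogram <- file.path(out_dir, "distance_histogram.tsv")
  if (!is.null(char$tad_partition)) {
    readr::write_tsv(char$tad_partition,
                     file.path(out_dir, "tad_partition.tsv"), progress = FALSE)
    written$tad_partition <- file.path(out_dir, "tad_partition.tsv")
  }
  if (!is.null(char$promoter_partition)) {
    readr::write_tsv(char$promoter_partition,
                     file.path(out_dir, "promoter_partition.tsv"),
                     progress = FALSE)
    written$promoter_partition <- file.path(out_dir, "promoter_partition.tsv")
  }
  if (!quiet) {
    message(sprintf("%d significant calls written to %s",
                    sum(calls$significant), bedpe))
  }
  invisible(written)
}
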