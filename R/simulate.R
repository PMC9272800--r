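#' Covariate distribution specification
#'
#' The generator draws each bias covariate from a declared distribution.
#' Supported distributions: `"grid_uniform"` (uniform over a vector of
#' `values`, used for genomic distance on a grid of bin-unit distances),
#' `"uniform"` (`min`, `max`), `"poisson_shift"` (`lambda`, `shift`; a
#' shifted Poisson keeps TE counts strictly positive), `"lognormal"`
#' (`meanlog`, `sdlog`) and `"constant"` (`value`). Draws are lower-truncated
#' at `floor` so that every covariate is strictly positive before the log
#' transform.
#'
#' @param dist Distribution name.
#' @param ... Distribution parameters (see above).
#' @param floor Lower truncation bound (default 1e-6).
#' @return A list of class `covariate_spec`.
#' @export
covariate_spec <- function(dist, ..., floor = 1e-6) {
  dist <- match.arg(dist, c("grid_uniform", "uniform", "poisson_shift",
                            "lognormal", "constant"))
  structure(list(dist = dist, params = list(...), floor = floor),
            class = "covariate_spec")
}

draw_covariate <- function(spec, n) {
  p <- spec$params
  x <- switch(spec$dist,
    grid_uniform  = sample(p$values, n, replace = TRUE),
    uniform       = runif(n, p$min, p$max),
    poisson_shift = rpois(n, p$lambda) + p$shift,
    lognormal     = rlnorm(n, p$meanlog, p$sdlog),
    constant      = rep(p$value, n)
  )
  pmax(x, spec$floor)
}

#' Simulation configuration
#'
#' Declares every quantity of the generative model: mixture proportions,
#' zero inflation, per-component bias-regression coefficients, Potts
#' interaction, covariate distributions and the pair-lattice shape. Defaults
#' reproduce the two-component simulation design used throughout the
#' package's validation: n = 2500 pairs on a 50 x 50 lattice, 70% noise /
#' 30% signal, and coefficient vectors chosen so that both components are
#' well informed by the data (see the methods vignette).
#'
#' @param n_pairs Number of pair observations (default 2500).
#' @param lattice_shape Two positive integers; their product must be at
#'   least `n_pairs`.
#' @param K Number of components (>= 2).
#' @param alphas K proportions summing to 1 (default `c(0.7, 0.3)`).
#' @param tau Extra-zero probability of the noise component (default 0.3).
#' @param betas K x 5 coefficient matrix, rows = components, columns =
#'   (intercept, log D, log GC, log TE, log ACC).
#' @param gamma Potts interaction parameter (default 0.4); used when
#'   `use_potts_labels = TRUE` and echoed into fits either way.
#' @param covariate_specs Named list of [covariate_spec()] for `D`, `GC`,
#'   `TE`, `ACC`. The default distance grid is in bin units (multiples of
#'   the bin size), 1..50.
#' @param use_potts_labels Draw labels from the Potts field (`TRUE`) or
#'   i.i.d. multinomial(`alphas`) (`FALSE`, default: proportions then hold
#'   exactly in expectation).
#' @param potts_sweeps Gibbs sweeps used to draw the Potts label field
#'   (default 200).
#' @param seed Integer seed; the same config is bit-reproducible.
#' @return A validated list of class `simulation_config`.
#' @examples
#' cfg <- simulation_config(n_pairs = 100, lattice_shape = c(10, 10), seed = 1)
#' @export
simulation_config <- function(n_pairs = 2500,
                              lattice_shape = c(50, 50),
                              K = 2,
                              alphas = c(0.7, 0.3),
                              tau = 0.3,
                              betas = default_betas(K),
                              gamma = 0.4,
                              covariate_specs = default_covariate_specs(),
                              use_potts_labels = FALSE,
                              potts_sweeps = 200,
                              seed = 1) {
  n_pairs <- check_count(n_pairs, "n_pairs")
  K <- check_count(K, "K", min = 2L)
  if (length(lattice_shape) != 2 || any(lattice_shape < 1)) {
    abort("`lattice_shape` must be two positive integers")
  }
  lattice_shape <- as.integer(lattice_shape)
  if (prod(lattice_shape) < n_pairs) {
    abort("lattice too small: prod(lattice_shape) < n_pairs")
  }
  if (length(alphas) != K || any(alphas < 0) || abs(sum(alphas) - 1) > 1e-12) {
    abort("`alphas` must be K non-negative proportions summing to 1")
  }
  check_prob(tau, "tau")
  betas <- rbind(betas)
  if (nrow(betas) != K || ncol(betas) != 5) abort("`betas` must be K x 5")
  if (gamma < 0) abort("`gamma` must be non-negative")
  need <- c("D", "GC", "TE", "ACC")
  if (!all(need %in% names(covariate_specs))) {
    abort("`covariate_specs` must name D, GC, TE and ACC")
  }
  structure(
    list(n_pairs = n_pairs, lattice_shape = lattice_shape, K = K,
         alphas = as.numeric(alphas), tau = tau, betas = unname(betas),
         gamma = gamma, covariate_specs = covariate_specs[need],
         use_potts_labels = isTRUE(use_potts_labels),
         potts_sweeps = check_count(potts_sweeps, "potts_sweeps"),
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Default generating coefficients
#'
#' Component coefficient vectors used by the default simulation design. The
#' components are ordered by their average fitted mean (noise lowest); for
#' K = 3 a high-mean false-signal component is appended.
#'
#' @param K Number of components.
#' @return K x 5 matrix.
#' @export
default_betas <- function(K = 2) {
  b <- rbind(
    noise  = c(7.0, -0.7, 0.30, -0.20, -0.30),
    signal = c(9.5, -0.9, 0.36, -0.10, 0.15)
  )
  if (K >= 3) b <- rbind(b, false_signal = c(12.0, -1.1, 0.30, 0.10, -0.20))
  if (K > 3) abort("default betas provided only for K in {2, 3}")
  unname(b[seq_len(K), , drop = FALSE])
}

#' @rdname simulation_config
#' @export
default_covariate_specs <- function() {
  list(
    D   = covariate_spec("grid_uniform", values = 1:50),
    GC  = covariate_spec("uniform", min = 0.3, max = 0.7),
    TE  = covariate_spec("poisson_shift", lambda = 2, shift = 1),
    ACC = covariate_spec("lognormal", meanlog = 0, sdlog = 0.5)
  )
}

#' Named simulation presets
#'
#' `"standard"` is the headline parameter-recovery design: n = 2500, K = 2,
#' proportions 0.7 noise / 0.3 signal. `"equal"` uses proportions 0.5/0.5.
#'
#' @param name Preset name.
#' @param seed Seed stored into the config.
#' @return A [simulation_config()].
#' @export
simulation_preset <- function(name = c("standard", "equal"), seed = 1) {
  name <- match.arg(name)
  switch(name,
    "standard" = simulation_config(seed = seed),
    "equal"     = simulation_config(alphas = c(0.5, 0.5), seed = seed)
  )
}

#' Draw a label field
#'
#' Labels are drawn either by Gibbs sweeps from the Potts distribution on
#' the configured lattice (starting from an i.i.d. uniform field) or i.i.d.
#' from multinomial(`alphas`). The full rectangular lattice is used and the
#' first `n_pairs` sites in row-major order are kept.
#'
#' @param config A [simulation_config()].
#' @return Integer labels of length `config$n_pairs`. The lattice used is
#'   attached as attribute `"lattice"`.
#' @export
simulate_labels <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  full <- pair_lattice(config$lattice_shape[1], config$lattice_shape[2])
  lat <- pair_lattice(config$lattice_shape[1], config$lattice_shape[2],
                      n_keep = config$n_pairs)
  if (config$use_potts_labels) {
    init <- sample.int(config$K, full$n_sites, replace = TRUE)
    z <- cpp_potts_gibbs(full$nbr, config$K, config$gamma,
                         config$potts_sweeps, as.integer(init))
    z <- z[seq_len(config$n_pairs)]
  } else {
    z <- sample.int(config$K, config$n_pairs, replace = TRUE,
                    prob = config$alphas)
  }
  attr(z, "lattice") <- lat
  z
}

#' Draw covariates and counts given labels
#'
#' Covariates are drawn from the configured distributions; counts follow the
#' mixture's emissions: zero-inflated Poisson for label 1, Poisson
#' otherwise, with means from the bias regression.
#'
#' @param config A [simulation_config()].
#' @param labels Integer labels as returned by [simulate_labels()].
#' @return A list of class `hic_dataset`: `observations` (tibble with
#'   `site`, `i`, `j`, `y`, `D`, `GC`, `TE`, `ACC`), `lattice`,
#'   `true_labels` and `config`.
#' @export
simulate_observations <- function(config, labels) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_pairs
  if (length(labels) != n) abort("labels drawn for a different lattice/config")
  lat <- attr(labels, "lattice")
  if (is.null(lat)) {
    lat <- pair_lattice(config$lattice_shape[1], config$lattice_shape[2],
                        n_keep = n)
  }
  set.seed(config$seed + 1L)
  covs <- purrr::map(config$covariate_specs, draw_covariate, n = n)
  obs <- tibble(
    site = seq_len(n), i = lat$sites$i, j = lat$sites$j,
    y = 0L, D = covs$D, GC = covs$GC, TE = covs$TE, ACC = covs$ACC
  )
  y <- integer(n)
  z <- as.integer(labels)
  for (k in seq_len(config$K)) {
    sel <- z == k
    if (!any(sel)) next
    lam <- component_mean(config$betas[k, ], obs[sel, ])
    if (k == 1) {
      extra <- rbinom(sum(sel), 1, config$tau) == 1
      yk <- rpois(sum(sel), lam)
      yk[extra] <- 0L
      y[sel] <- yk
    } else {
      y[sel] <- rpois(sum(sel), lam)
    }
  }
  obs$y <- as.integer(y)
  structure(
    list(observations = obs, lattice = lat, true_labels = z, config = config),
    class = "hic_dataset"
  )
}

#' Simulate a full dataset
#'
#' Convenience wrapper: [simulate_labels()] then [simulate_observations()].
#'
#' @param config A [simulation_config()].
#' @return A `hic_dataset` (see [simulate_observations()]).
#' @examples
#' sim <- simulate_hic(simulation_config(n_pairs = 64,
#'                                       lattice_shape = c(8, 8), seed = 7))
#' table(sim$true_labels)
#' @export
simulate_hic <- function(config) {
  simulate_observations(config, simulate_labels(config))
}

#' @export
print.hic_dataset <- function(x, ...) {
  cat("<hic_dataset> ", nrow(x$observations), " pair observations",
      if (!is.null(x$true_labels)) sprintf(", K = %d (with ground truth)",
                                           max(x$true_labels)),
      "\n", sep = "")
  print(head(x$observations, 5))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits the triplet contact text the reader consumes (`i j count`, 0-based
#' bin indices) plus a ground-truth TSV (`site`, `i`, `j`, `true_label`).
#' Lattice rows and columns are mapped to disjoint bin axes (`bin_i = i -
#' 1`, `bin_j = rows + j - 1`) so that every pair is upper-triangular and
#' the triplet file is a valid sparse contact matrix.
#'
#' @param sim A `hic_dataset` from [simulate_hic()].
#' @param contacts_path,truth_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_simulated_dataset <- function(sim, contacts_path, truth_path) {
  stopifnot(inherits(sim, "hic_dataset"))
  obs <- sim$observations
  rows <- sim$config$lattice_shape[1]
  readr::write_tsv(
    tibble(i = obs$i - 1L, j = rows + obs$j - 1L, count = obs$y),
    contacts_path, col_names = FALSE
  )
  readr::write_tsv(
    tibble(site = obs$site, i = obs$i, j = obs$j,
           bin_i = obs$i - 1L, bin_j = rows + obs$j - 1L,
           true_label = sim$true_labels),
    truth_path
  )
  invisible(c(contacts = contacts_path, truth = truth_path))
}
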