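#' Prior configuration
#'
#' Fixed (informative) priors for the sampler: independent normals on every
#' regression coefficient, a Beta prior on the extra-zero probability, and a
#' Beta prior on the Potts interaction scaled to `[0, gamma_max]`. Defaults
#' follow the package's standard analysis settings: coefficient priors
#' centred on [default_betas()] with sd 1, `gamma ~ Beta(10, 5)` and
#' `pi0 = 0.6` (the prior expected noise proportion used to initialize
#' labels).
#'
#' @param K Number of components.
#' @param beta_prior_means K x 5 matrix of prior means.
#' @param beta_prior_sds K x 5 matrix (or scalar) of prior sds (> 0).
#' @param gamma_prior Beta shape pair for gamma / gamma_max.
#' @param tau_prior Beta shape pair for tau.
#' @param pi0 Prior expected noise proportion in (0, 1).
#' @param mode `"fixed"` or `"empirical_bayes"` (label only; see
#'   [empirical_bayes_hyperpriors()] which returns a ready-made config).
#' @return A list of class `prior_config`.
#' @export
prior_config <- function(K = 2,
                         beta_prior_means = default_betas(K),
                         beta_prior_sds = 1,
                         gamma_prior = c(10, 5),
                         tau_prior = c(1, 1),
                         pi0 = 0.6,
                         mode = "fixed") {
  K <- check_count(K, "K", min = 2L)
  beta_prior_means <- rbind(beta_prior_means)
  if (nrow(beta_prior_means) != K || ncol(beta_prior_means) != 5) {
    abort("`beta_prior_means` must be K x 5")
  }
  if (length(beta_prior_sds) == 1) {
    beta_prior_sds <- matrix(beta_prior_sds, K, 5)
  }
  beta_prior_sds <- rbind(beta_prior_sds)
  if (any(beta_prior_sds <= 0)) abort("`beta_prior_sds` must be > 0")
  if (length(gamma_prior) != 2 || any(gamma_prior <= 0)) {
    abort("`gamma_prior` must be two positive Beta shapes")
  }
  if (length(tau_prior) != 2 || any(tau_prior <= 0)) {
    abort("`tau_prior` must be two positive Beta shapes")
  }
  if (pi0 <= 0 || pi0 >= 1) abort("`pi0` must lie in (0, 1)")
  structure(
    list(K = K, mode = mode,
         beta_prior_means = unname(beta_prior_means),
         beta_prior_sds = unname(beta_prior_sds),
         gamma_prior = as.numeric(gamma_prior),
         tau_prior = as.numeric(tau_prior),
         pi0 = pi0),
    class = "prior_config"
  )
}

#' Empirical-Bayes hyperprior construction
#'
#' Deterministic moment-based priors estimated from the data: observations
#' are split into K provisional strata by count quantiles; within each
#' stratum an ordinary least-squares fit of `log(y + 1)` on the four log
#' covariates gives the coefficient prior means, with prior sds set to the
#' fit's coefficient standard errors inflated tenfold. The tau prior comes
#' from the overall zero fraction, `Beta(1 + #zeros * w, 1 + #nonzeros * w)`
#' with `w = 0.01`; the gamma prior is kept at `Beta(10, 5)`.
#'
#' @param obs Observation tibble (or `hic_dataset`) with >= 50 rows.
#' @param K Number of components.
#' @param weight Zero-fraction prior weight `w` (default 0.01).
#' @return A [prior_config()] with `mode = "empirical_bayes"`.
#' @export
empirical_bayes_hyperpriors <- function(obs, K = 2, weight = 0.01) {
  if (inherits(obs, "hic_dataset")) obs <- obs$observations
  K <- check_count(K, "K", min = 2L)
  if (nrow(obs) < 50) abort("empirical Bayes needs at least 50 observations")
  if (length(unique(obs$y)) == 1) {
    abort("all counts identical: quantile strata undefined")
  }
  X <- obs_design(obs)
  for (p in 2:5) {
    if (sd(X[, p]) == 0) {
      abort(sprintf("degenerate covariate `%s` (zero variance)",
                    c("D", "GC", "TE", "ACC")[p - 1]))
    }
  }
  qs <- quantile(obs$y, probs = seq(0, 1, length.out = K + 1), type = 7)
  stratum <- cut(obs$y, breaks = unique(qs), include.lowest = TRUE,
                 labels = FALSE)
  if (length(unique(qs)) - 1 < K) {
    # heavy ties collapse quantile breaks; fall back to rank-based strata
    stratum <- as.integer(cut(rank(obs$y, ties.method = "first"),
                              breaks = K, labels = FALSE))
  }
  means <- matrix(NA_real_, K, 5)
  sds <- matrix(NA_real_, K, 5)
  for (k in seq_len(K)) {
    sel <- stratum == k
    # zeros carry tau (zero-inflation) information, not coefficient
    # information; keeping them attenuates the stratum fit badly
    if (sum(sel & obs$y > 0) > 20) sel <- sel & obs$y > 0
    fit <- lm(log(obs$y[sel] + 1) ~ X[sel, -1])
    cf <- coef(fit)
    se <- sqrt(diag(vcov(fit)))
    if (anyNA(cf) || anyNA(se)) {
      abort("degenerate covariates within a count stratum")
    }
    means[k, ] <- cf
    sds[k, ] <- pmax(se * 10, 1e-3)
  }
  nz <- sum(obs$y == 0)
  prior_config(
    K = K, beta_prior_means = means, beta_prior_sds = sds,
    gamma_prior = c(10, 5),
    tau_prior = c(1 + nz * weight, 1 + (nrow(obs) - nz) * weight),
    mode = "empirical_bayes"
  )
}

#' Sampler configuration
#'
#' @param iterations Total MCMC iterations (default 20000).
#' @param burn_in Discarded initial iterations (default 10000; must be less
#'   than `iterations`).
#' @param thinning Keep every `thinning`-th post-burn-in draw (default 1).
#' @param seed Integer seed; runs are bit-reproducible.
#' @param beta_proposal_sd Initial random-walk proposal sd for every
#'   coefficient (default 0.05).
#' @param adapt Adapt proposal scales during burn-in only (default TRUE;
#'   frozen afterwards so detailed balance holds on retained draws).
#' @param abc_quantile Tolerance quantile for the ABC step (default 0.01;
#'   `>= 1` disables the constraint).
#' @param abc_distance `"absolute"` or `"euclidean"` discrepancy on the
#'   Potts sufficient statistic (identical for a scalar summary; both names
#'   accepted).
#' @param abc_pilot_draws Pilot simulations used to set the tolerance,
#'   refreshed at every gamma update (default 20).
#' @param abc_sweeps Gibbs sweeps used to simulate each ABC pseudo-field
#'   from a random start (default 5).
#' @param gamma_max Upper end of the gamma support; gamma = gamma_max *
#'   Beta draw (default 1).
#' @param cap Bound on |log lambda| (default 50); proposals beyond it are
#'   rejected and a state beyond it is an error.
#' @param likelihood_weight Internal switch scaling the data log-likelihood
#'   (default 1; 0 turns the sampler into a prior sampler for validation).
#' @param progress_every Log a progress line every so many iterations
#'   (0 = silent).
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(iterations = 20000, burn_in = 10000, thinning = 1,
                        seed = 1, beta_proposal_sd = 0.05, adapt = TRUE,
                        abc_quantile = 0.01,
                        abc_distance = c("absolute", "euclidean"),
                        abc_pilot_draws = 20, abc_sweeps = 5, gamma_max = 1,
                        cap = 50, likelihood_weight = 1, progress_every = 0) {
  iterations <- check_count(iterations, "iterations")
  burn_in <- check_count(burn_in, "burn_in", min = 0L)
  if (burn_in >= iterations) abort("`burn_in` must be < `iterations`")
  structure(
    list(iterations = iterations, burn_in = burn_in,
         thinning = check_count(thinning, "thinning"),
         seed = as.integer(seed),
         beta_proposal_sd = beta_proposal_sd, adapt = isTRUE(adapt),
         abc_quantile = abc_quantile,
         abc_distance = match.arg(abc_distance),
         abc_pilot_draws = check_count(abc_pilot_draws, "abc_pilot_draws"),
         abc_sweeps = check_count(abc_sweeps, "abc_sweeps"),
         gamma_max = gamma_max, cap = cap,
         likelihood_weight = likelihood_weight,
         progress_every = progress_every),
    class = "mcmc_config"
  )
}
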