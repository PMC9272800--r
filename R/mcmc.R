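#' One Gibbs sweep over the label field
#'
#' Systematic-scan update of every site: the full conditional combines the
#' Potts neighbour term \eqn{\exp(\gamma \#\{t \in N_s : z_t = k\})} with
#' the component emission (zero-inflated Poisson for component 1, Poisson
#' otherwise).
#'
#' @param state A [model_state()] with labels `z`.
#' @param obs Observation tibble.
#' @param lattice A [pair_lattice()].
#' @param likelihood_weight Scale on the emission log-likelihood (default 1).
#' @param cap Bound on |log lambda|.
#' @return Integer vector of new labels.
#' @export
update_labels <- function(state, obs, lattice, likelihood_weight = 1,
                          cap = 50) {
  stopifnot(inherits(state, "model_state"))
  le <- emission_log_matrix(obs, state$betas, state$tau, cap = cap)
  cpp_label_sweep(lattice$nbr, le * likelihood_weight, state$gamma,
                  as.integer(state$z))
}

# component log-likelihood of sites `sel` under linear predictor eta
comp_loglik <- function(y, eta, tau, is_noise) {
  lam <- exp(eta)
  if (is_noise) sum(zip_log_pmf(y, tau, lam)) else sum(dpois(y, lam, log = TRUE))
}

#' Random-walk Metropolis update of the regression coefficients
#'
#' Per component and per coefficient: only sites currently labelled with
#' that component contribute to the likelihood (through the zero-inflated
#' Poisson for the noise component), with an independent normal prior on
#' each coefficient. Proposals taking |log lambda| over `cap` are rejected.
#'
#' @inheritParams update_labels
#' @param prior A [prior_config()].
#' @param proposal_sd K x 5 matrix (or scalar) of proposal sds.
#' @return List with `betas` (K x 5) and `accepted` (K x 5, 0/1).
#' @export
update_betas <- function(state, obs, prior, proposal_sd = 0.05,
                         likelihood_weight = 1, cap = 50) {
  stopifnot(inherits(state, "model_state"))
  K <- state$K
  if (length(proposal_sd) == 1) proposal_sd <- matrix(proposal_sd, K, 5)
  betas <- state$betas
  accepted <- matrix(0, K, 5)
  X <- obs_design(obs)
  for (k in seq_len(K)) {
    sel <- state$z == k
    yk <- obs$y[sel]
    Xk <- X[sel, , drop = FALSE]
    eta <- drop(Xk %*% betas[k, ])
    ll <- if (likelihood_weight == 0 || !any(sel)) 0 else
      likelihood_weight * comp_loglik(yk, eta, state$tau, k == 1)
    for (p in 1:5) {
      prop <- betas[k, p] + rnorm(1, 0, proposal_sd[k, p])
      eta_prop <- eta + (prop - betas[k, p]) * Xk[, p]
      if (length(eta_prop) > 0 && max(abs(eta_prop)) > cap) next  # reject
      ll_prop <- if (likelihood_weight == 0 || !any(sel)) 0 else
        likelihood_weight * comp_loglik(yk, eta_prop, state$tau, k == 1)
      lr <- (ll_prop - ll) +
        dnorm(prop, prior$beta_prior_means[k, p], prior$beta_prior_sds[k, p],
              log = TRUE) -
        dnorm(betas[k, p], prior$beta_prior_means[k, p],
              prior$beta_prior_sds[k, p], log = TRUE)
      if (is.finite(lr) && log(runif(1)) < lr) {
        betas[k, p] <- prop
        eta <- eta_prop
        ll <- ll_prop
        accepted[k, p] <- 1
      }
    }
  }
  list(betas = betas, accepted = accepted)
}

#' Gibbs update of the extra-zero probability
#'
#' Data augmentation: each zero count currently labelled noise gets an
#' extra-zero indicator drawn from its conditional Bernoulli, then tau is
#' drawn from its conjugate Beta posterior restricted to noise-labelled
#' sites.
#'
#' @inheritParams update_betas
#' @return New tau.
#' @export
update_tau <- function(state, obs, prior, likelihood_weight = 1, cap = 50) {
  stopifnot(inherits(state, "model_state"))
  a <- prior$tau_prior[1]
  b <- prior$tau_prior[2]
  sel <- state$z == 1L
  if (!any(sel) || likelihood_weight == 0) return(rbeta(1, a, b))
  y1 <- obs$y[sel]
  lam <- component_mean(state$betas[1, ], obs[sel, , drop = FALSE], cap = cap)
  zero <- y1 == 0
  n_extra <- 0L
  if (any(zero)) {
    p_extra <- state$tau / (state$tau + (1 - state$tau) * exp(-lam[zero]))
    n_extra <- sum(rbinom(sum(zero), 1, p_extra))
  }
  rbeta(1, a + n_extra, b + sum(sel) - n_extra)
}

#' ABC update of the Potts interaction parameter
#'
#' Likelihood-free accept/reject sidestepping the intractable Potts
#' partition function: a proposal gamma* is drawn from the prior, a
#' pseudo-field is simulated at gamma* by Gibbs sweeps from a random start,
#' and gamma* is accepted when the discrepancy between the pseudo-field's
#' and the current label field's sufficient statistic (concordant-pair
#' count) falls below a tolerance. The tolerance is the `abc_quantile`
#' empirical quantile of the discrepancies of `abc_pilot_draws` pilot
#' simulations drawn from the prior, refreshed at each call.
#'
#' @inheritParams update_labels
#' @param prior A [prior_config()] (`gamma_prior` Beta shapes are used).
#' @param config An [mcmc_config()].
#' @return List with `gamma` and logical `accepted`.
#' @export
update_gamma_abc <- function(state, lattice, prior, config = mcmc_config()) {
  stopifnot(inherits(state, "model_state"))
  a <- prior$gamma_prior[1]
  b <- prior$gamma_prior[2]
  gmax <- config$gamma_max
  s_obs <- cpp_concordant_pairs(lattice$nbr, as.integer(state$z))
  dist_fun <- function(s_sim) {
    if (config$abc_distance == "euclidean") sqrt((s_sim - s_obs)^2)
    else abs(s_sim - s_obs)
  }
  gamma_star <- gmax * rbeta(1, a, b)
  if (config$abc_quantile >= 1) {
    eps <- Inf
  } else {
    pilot <- numeric(config$abc_pilot_draws)
    for (r in seq_len(config$abc_pilot_draws)) {
      g <- gmax * rbeta(1, a, b)
      pilot[r] <- dist_fun(cpp_potts_sim_stat(lattice$nbr, state$K, g,
                                              config$abc_sweeps))
    }
    eps <- quantile(pilot, config$abc_quantile, names = FALSE, type = 7)
  }
  d_star <- dist_fun(cpp_potts_sim_stat(lattice$nbr, state$K, gamma_star,
                                        config$abc_sweeps))
  if (d_star < eps || is.infinite(eps)) {
    list(gamma = gamma_star, accepted = TRUE)
  } else {
    list(gamma = state$gamma, accepted = FALSE)
  }
}

beta_col_names <- function(K) {
  as.vector(t(outer(seq_len(K), 0:4,
                    function(k, p) sprintf("beta_k%d_p%d", k, p))))
}

#' Run the Metropolis-within-Gibbs sampler
#'
#' Initializes labels by count quantiles (the lowest `pi0` fraction starts
#' in the noise component, the remainder split evenly among the others),
#' coefficients at their prior means, tau and gamma at their prior means,
#' then loops label sweep, coefficient Metropolis, tau Gibbs and gamma ABC
#' updates. Fully reproducible under `config$seed`.
#'
#' @param data A `hic_dataset` (from [simulate_hic()] or
#'   [assemble_observations()]), or an observation tibble if `lattice` is
#'   given.
#' @param K Number of mixture components.
#' @param prior A [prior_config()], `"empirical_bayes"` to construct one
#'   from the data, or `NULL` for the default fixed prior.
#' @param config An [mcmc_config()].
#' @param lattice Required when `data` is a bare tibble.
#' @return An object of class `hic_chain`: `draws` (tibble of retained
#'   samples: `.draw`, `tau`, `gamma`, `loglik`, per-component `alpha_k` and
#'   `beta_k*_p*` columns), `label_freq` (n x K matrix of per-site label
#'   relative frequencies), `acceptance` (per-block rates), `role_map`,
#'   echoed configs and the final state.
#' @examples
#' sim <- simulate_hic(simulation_config(n_pairs = 100,
#'                                       lattice_shape = c(10, 10), seed = 2))
#' ch <- run_mcmc(sim, K = 2, config = mcmc_config(iterations = 200,
#'                                                 burn_in = 100))
#' tidy(ch)
#' @export
run_mcmc <- function(data, K = 2, prior = NULL, config = mcmc_config(),
                     lattice = NULL) {
  if (inherits(data, "hic_dataset")) {
    obs <- data$observations
    lattice <- data$lattice
  } else {
    obs <- data
    if (is.null(lattice)) abort("supply `lattice` with a bare observation tibble")
  }
  K <- check_count(K, "K", min = 2L)
  stopifnot(inherits(config, "mcmc_config"))
  if (is.null(prior)) prior <- prior_config(K)
  if (identical(prior, "empirical_bayes")) {
    prior <- empirical_bayes_hyperpriors(obs, K)
  }
  stopifnot(inherits(prior, "prior_config"))
  if (prior$K != K) abort("prior built for a different K")
  n <- nrow(obs)
  set.seed(config$seed)

  # deterministic initialization: lowest-count fraction pi0 -> component 1,
  # the remainder -> component 2; components >= 3 start empty and only fill
  # where the data demand them (pre-splitting the signal stratum plants a
  # spurious high-count cluster that a K too large then keeps)
  ord <- order(obs$y, obs$site %||% seq_len(n))
  z <- rep(2L, n)
  n1 <- max(1L, round(prior$pi0 * n))
  z[ord[seq_len(n1)]] <- 1L

  betas <- prior$beta_prior_means
  tau <- prior$tau_prior[1] / sum(prior$tau_prior)
  gamma <- config$gamma_max * prior$gamma_prior[1] / sum(prior$gamma_prior)
  state <- model_state(K, rep(1 / K, K), tau, betas, gamma, z)

  prop_sd <- matrix(config$beta_proposal_sd, K, 5)
  acc_beta <- matrix(0, K, 5)
  acc_window <- matrix(0, K, 5)
  acc_gamma <- 0
  n_gamma <- 0
  n_beta <- 0
  window <- 0

  n_keep <- floor((config$iterations - config$burn_in) / config$thinning)
  bcols <- beta_col_names(K)
  draw_mat <- matrix(NA_real_, n_keep, 3 + K + 5 * K)
  colnames(draw_mat) <- c("tau", "gamma", "loglik",
                          paste0("alpha_", seq_len(K)), bcols)
  freq <- matrix(0, n, K)
  kept <- 0L

  for (it in seq_len(config$iterations)) {
    res <- withCallingHandlers(
      {
        state$z <- update_labels(state, obs, lattice,
                                 likelihood_weight = config$likelihood_weight,
                                 cap = config$cap)
        ub <- update_betas(state, obs, prior, proposal_sd = prop_sd,
                           likelihood_weight = config$likelihood_weight,
                           cap = config$cap)
        state$betas <- ub$betas
        state$tau <- update_tau(state, obs, prior,
                                likelihood_weight = config$likelihood_weight,
                                cap = config$cap)
        ug <- update_gamma_abc(state, lattice, prior, config)
        state$gamma <- ug$gamma
        list(ub = ub, ug = ug)
      },
      error = function(e) {
        abort(sprintf("numerical failure at iteration %d: %s", it,
                      conditionMessage(e)), class = "hicmrf_numerical")
      }
    )
    acc_beta <- acc_beta + res$ub$accepted
    acc_window <- acc_window + res$ub$accepted
    n_beta <- n_beta + 1
    acc_gamma <- acc_gamma + res$ug$accepted
    n_gamma <- n_gamma + 1
    window <- window + 1

    if (config$adapt && it <= config$burn_in && window == 50) {
      rate <- acc_window / window
      prop_sd <- prop_sd * exp(0.3 * (rate - 0.44))
      acc_window[] <- 0
      window <- 0
    }

    if (it > config$burn_in &&
        (it - config$burn_in) %% config$thinning == 0 && kept < n_keep) {
      kept <- kept + 1L
      le <- emission_log_matrix(obs, state$betas, state$tau, cap = config$cap)
      ll <- sum(le[cbind(seq_len(n), state$z)])
      draw_mat[kept, ] <- c(state$tau, state$gamma, ll,
                            tabulate(state$z, K) / n,
                            as.vector(t(state$betas)))
      freq[cbind(seq_len(n), state$z)] <- freq[cbind(seq_len(n), state$z)] + 1
    }

    if (config$progress_every > 0 && it %% config$progress_every == 0) {
      message(sprintf("iteration %d/%d (beta acc %.2f, gamma acc %.2f)",
                      it, config$iterations, mean(acc_beta / n_beta),
                      acc_gamma / n_gamma))
    }
  }

  draws <- as_tibble(draw_mat[seq_len(kept), , drop = FALSE])
  draws <- mutate(draws, .draw = dplyr::row_number(), .before = 1)
  label_freq <- freq / max(kept, 1L)

  chain <- structure(
    list(
      draws = draws,
      label_freq = label_freq,
      acceptance = list(beta = acc_beta / n_beta,
                        gamma = acc_gamma / n_gamma),
      K = K, n = n,
      sites = obs[, intersect(c("site", "i", "j", "bin_i", "bin_j"),
                              names(obs))],
      prior = prior, config = config,
      final_state = state
    ),
    class = "hic_chain"
  )
  chain$role_map <- tryCatch(label_components(chain, obs),
                             error = function(e) NULL)
  chain
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.hic_chain <- function(x, ...) {
  cat(sprintf("<hic_chain> K = %d, %d sites, %d retained draws\n",
              x$K, x$n, nrow(x$draws)))
  cat(sprintf("  beta acceptance %.2f, gamma(ABC) acceptance %.2f\n",
              mean(x$acceptance$beta), x$acceptance$gamma))
  if (!is.null(x$role_map)) {
    cat("  roles:", paste(sprintf("%s (mean %.3g)", x$role_map$role,
                                  x$role_map$lambda_bar), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Map mixture components to biological roles
#'
#' Components are ordered by their average fitted mean over all sites,
#' computed from the posterior-mean coefficients: the smallest mean is
#' noise, the intermediate mean (K = 3) is the true signal and the largest
#' is the false signal. This ordering rule resolves label switching.
#'
#' @param chain A `hic_chain`.
#' @param obs Observation tibble (or `hic_dataset`) the chain was fitted to.
#' @return Tibble with `component`, `role` and `lambda_bar`, ordered by
#'   `lambda_bar`.
#' @export
label_components <- function(chain, obs) {
  stopifnot(inherits(chain, "hic_chain"))
  if (inherits(obs, "hic_dataset")) obs <- obs$observations
  K <- chain$K
  bhat <- posterior_mean_betas(chain)
  lam_bar <- vapply(seq_len(K), function(k) {
    mean(component_mean(bhat[k, ], obs, cap = Inf))
  }, 0)
  if (any(diff(sort(lam_bar)) < 1e-9)) {
    abort("component means tie within 1e-9: roles unidentifiable")
  }
  ord <- order(lam_bar)
  roles <- role_names(K)
  tibble(component = ord, role = roles, lambda_bar = lam_bar[ord])
}

role_names <- function(K) {
  if (K == 2) c("noise", "signal")
  else c("noise", "signal", "false_signal",
         if (K > 3) paste0("false_signal", seq_len(K - 3) + 1))[seq_len(K)]
}

posterior_mean_betas <- function(chain) {
  K <- chain$K
  out <- matrix(NA_real_, K, 5)
  for (k in seq_len(K)) {
    for (p in 0:4) {
      out[k, p + 1] <- mean(chain$draws[[sprintf("beta_k%d_p%d", k, p)]])
    }
  }
  out
}

#' Posterior means and credible intervals
#'
#' Equal-tailed 95% intervals per scalar parameter; a parameter is flagged
#' significant when its interval excludes zero.
#'
#' @param chain A `hic_chain` with at least 100 retained draws.
#' @param level Credible level (default 0.95).
#' @return Tibble with `term`, `component`, `role`, `estimate`, `conf.low`,
#'   `conf.high`, `significant`.
#' @export
posterior_summaries <- function(chain, level = 0.95) {
  stopifnot(inherits(chain, "hic_chain"))
  if (nrow(chain$draws) < 100) {
    abort("need at least 100 retained draws for posterior summaries")
  }
  a <- (1 - level) / 2
  roles <- rep(NA_character_, chain$K)
  if (!is.null(chain$role_map)) {
    roles[chain$role_map$component] <- chain$role_map$role
  }
  terms <- setdiff(names(chain$draws), c(".draw", "loglik"))
  rows <- purrr::map(terms, function(tm) {
    v <- chain$draws[[tm]]
    comp <- NA_integer_
    if (grepl("^beta_k", tm)) comp <- as.integer(sub("^beta_k(\\d+)_.*$", "\\1", tm))
    if (grepl("^alpha_", tm)) comp <- as.integer(sub("^alpha_", "", tm))
    qs <- quantile(v, c(a, 1 - a), names = FALSE, type = 7)
    tibble(term = tm, component = comp,
           role = if (!is.na(comp)) roles[comp] else NA_character_,
           estimate = mean(v), conf.low = qs[1], conf.high = qs[2],
           significant = qs[1] > 0 | qs[2] < 0)
  })
  bind_rows(rows)
}

#' @rdname posterior_summaries
#' @param x A `hic_chain`.
#' @param ... Unused.
#' @export
tidy.hic_chain <- function(x, ...) posterior_summaries(x, ...)

#' One-line chain summary
#'
#' @param x A `hic_chain`.
#' @param ... Unused.
#' @return One-row tibble with dimensions and acceptance rates.
#' @export
glance.hic_chain <- function(x, ...) {
  tibble(
    K = x$K, n_sites = x$n, retained = nrow(x$draws),
    iterations = x$config$iterations, burn_in = x$config$burn_in,
    accept_beta = mean(x$acceptance$beta),
    accept_gamma = x$acceptance$gamma,
    mean_loglik = mean(x$draws$loglik)
  )
}

#' Serialize a chain to plain-text files
#'
#' Writes `draws.tsv`, `label_freq.tsv`, `sites.tsv` and `chain.json`
#' (scalars + configs) under `dir`, and [read_chain()] restores the chain.
#'
#' @param chain A `hic_chain`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_chain <- function(chain, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(chain$draws, file.path(dir, "draws.tsv"), progress = FALSE)
  lf <- as_tibble(as.data.frame(chain$label_freq),
                  .name_repair = ~ paste0("comp_", seq_along(.x)))
  readr::write_tsv(lf, file.path(dir, "label_freq.tsv"), progress = FALSE)
  readr::write_tsv(chain$sites, file.path(dir, "sites.tsv"), progress = FALSE)
  meta <- list(K = chain$K, n = chain$n,
               acceptance = list(beta = as.vector(chain$acceptance$beta),
                                 gamma = chain$acceptance$gamma),
               role_map = chain$role_map,
               prior = unclass(chain$prior),
               config = unclass(chain$config))
  jsonlite::write_json(meta, file.path(dir, "chain.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_chain
#' @return `read_chain()` returns a `hic_chain`.
#' @export
read_chain <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "chain.json"),
                              simplifyVector = TRUE)
  draws <- readr::read_tsv(file.path(dir, "draws.tsv"),
                           show_col_types = FALSE, progress = FALSE)
  lf <- as.matrix(readr::read_tsv(file.path(dir, "label_freq.tsv"),
                                  show_col_types = FALSE, progress = FALSE))
  sites <- readr::read_tsv(file.path(dir, "sites.tsv"),
                           show_col_types = FALSE, progress = FALSE)
  structure(
    list(draws = draws, label_freq = unname(lf),
         acceptance = list(beta = matrix(meta$acceptance$beta, meta$K, 5),
                           gamma = meta$acceptance$gamma),
         K = meta$K, n = meta$n, sites = as_tibble(sites),
         role_map = if (!is.null(meta$role_map)) as_tibble(meta$role_map),
         prior = meta$prior, config = meta$config),
    class = "hic_chain"
  )
}
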