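test_that("empirical-Bayes hyperpriors are deterministic and calibrated", {
  sim <- simulate_hic(simulation_config(n_pairs = 400,
                                        lattice_shape = c(20, 20), seed = 4))
  p1 <- empirical_bayes_hyperpriors(sim$observations, K = 2)
  p2 <- empirical_bayes_hyperpriors(sim$observations, K = 2)
  expect_identical(p1, p2)
  expect_equal(p1$mode, "empirical_bayes")
  expect_true(all(p1$beta_prior_sds > 0))

  # degenerate inputs are refused
  obs_const <- make_obs(100, y = rep(3L, 100))
  expect_error(empirical_bayes_hyperpriors(obs_const, 2), "identical")
  obs_degcov <- make_obs(100, y = rpois(100, 4))
  expect_error(empirical_bayes_hyperpriors(obs_degcov, 2), "degenerate")
  expect_error(empirical_bayes_hyperpriors(make_obs(10), 2), "50")

  # calibration: prior means land within 2 prior sds of truth for >= 80%
  # of coefficients across seeds (the EB fit is on log(y+1), so only rough
  # agreement is expected; the x10 sd inflation encodes that)
  hits <- 0; total <- 0
  for (s in 1:20) {
    cfg <- simulation_config(seed = 100 + s)
    simc <- simulate_hic(cfg)
    eb <- empirical_bayes_hyperpriors(simc$observations, K = 2)
    within <- abs(eb$beta_prior_means - cfg$betas) <= 2 * eb$beta_prior_sds
    hits <- hits + sum(within); total <- total + length(within)
  }
  expect_gte(hits / total, 0.8)
})

test_that("label updates respect degenerate limits", {
  lat <- pair_lattice(10, 10)
  obs <- make_obs(100, y = rpois(100, 3))
  # gamma = 0, equal lambdas, tau = 0: flat conditional, labels uniform
  st <- model_state(2, c(0.5, 0.5), 0,
                    rbind(c(1, 0, 0, 0, 0), c(1, 0, 0, 0, 0)), 0,
                    z = rep(1L, 100))
  set.seed(1)
  zs <- replicate(200, update_labels(st, obs, lat))
  expect_lt(abs(mean(zs == 1) - 0.5), 0.02)

  # zero counts with tau near 1 go to the noise component when the other
  # component expects large counts
  obs0 <- make_obs(100, y = rep(0L, 100))
  st2 <- model_state(2, c(0.5, 0.5), 0.99,
                     rbind(c(1, 0, 0, 0, 0), c(4, 0, 0, 0, 0)), 0,
                     z = rep(2L, 100))
  z2 <- update_labels(st2, obs0, lat)
  expect_gt(mean(z2 == 1), 0.98)
})

test_that("coefficient Metropolis honours degenerate priors and proposals", {
  obs <- make_obs(60, y = rpois(60, 5))
  st <- model_state(2, c(0.5, 0.5), 0.1,
                    rbind(c(2, 0, 0, 0, 0), c(3, 0, 0, 0, 0)), 0.2,
                    z = rep(1:2, 30))
  # near-point-mass prior pins the chain at the prior mean
  tight <- prior_config(2, beta_prior_means = st$betas,
                        beta_prior_sds = 1e-8)
  set.seed(2)
  cur <- st
  for (r in 1:50) {
    cur$betas <- update_betas(cur, obs, tight, proposal_sd = 0.3)$betas
  }
  expect_lt(max(abs(cur$betas - st$betas)), 1e-3)

  # zero proposal sd: chain constant with acceptance 1
  res <- update_betas(st, obs, prior_config(2), proposal_sd = 0)
  expect_equal(res$betas, st$betas)
  expect_true(all(res$accepted == 1))
})

test_that("tau updates draw from the prior without noise sites and recover truth", {
  obs <- make_obs(50, y = rpois(50, 5))
  st <- model_state(2, c(0.5, 0.5), 0.5,
                    rbind(c(1, 0, 0, 0, 0), c(2, 0, 0, 0, 0)), 0,
                    z = rep(2L, 50))
  prior <- prior_config(2, tau_prior = c(3, 7))
  set.seed(3)
  draws <- replicate(3000, update_tau(st, obs, prior))
  # no component-1 sites: conjugate update reduces to the Beta(3, 7) prior
  expect_lt(abs(mean(draws) - 0.3), 0.02)
  expect_gt(stats::ks.test(draws, stats::pbeta, 3, 7)$p.value, 0.01)

  # all-zero noise counts with huge lambda: everything is an extra zero
  obs0 <- make_obs(200, y = rep(0L, 200))
  st0 <- model_state(2, c(1, 0), 0.5,
                     rbind(c(6, 0, 0, 0, 0), c(7, 0, 0, 0, 0)), 0,
                     z = rep(1L, 200))
  d0 <- replicate(500, update_tau(st0, obs0, prior_config(2)))
  expect_gt(mean(d0), 0.95)

  # recovery: true tau = 0.4 given true labels and means, n = 2500
  errs <- sapply(1:10, function(s) {
    cfg <- simulation_config(tau = 0.4, seed = 200 + s)
    simt <- simulate_hic(cfg)
    stt <- model_state(2, cfg$alphas, 0.5, cfg$betas, 0,
                       z = simt$true_labels)
    set.seed(s)
    mean(replicate(400, update_tau(stt, simt$observations, prior_config(2))))
  })
  expect_true(all(abs(errs - 0.4) < 0.05))
})

test_that("ABC gamma step: prior recovery at infinite tolerance, point-mass stasis", {
  lat <- pair_lattice(12, 12)
  st <- model_state(2, c(0.5, 0.5), 0.2, default_betas(2), 0.5,
                    z = sample(1:2, 144, replace = TRUE))
  prior <- prior_config(2)
  cfg <- mcmc_config(iterations = 10, burn_in = 5, abc_quantile = 1.0)
  set.seed(4)
  draws <- replicate(5000, update_gamma_abc(st, lat, prior, cfg)$gamma)
  expect_gt(stats::ks.test(draws, stats::pbeta, 10, 5)$p.value, 0.01)

  # gamma_max = 0 collapses the prior to a point mass at 0: gamma never moves
  cfg0 <- mcmc_config(iterations = 10, burn_in = 5, gamma_max = 0)
  st0 <- st; st0$gamma <- 0
  g0 <- replicate(50, update_gamma_abc(st0, lat, prior, cfg0)$gamma)
  expect_true(all(g0 == 0))
})

test_that("chains are bit-reproducible and sized by the thinning rule", {
  sim <- simulate_hic(simulation_config(n_pairs = 100,
                                        lattice_shape = c(10, 10), seed = 6))
  cfg <- mcmc_config(iterations = 120, burn_in = 40, thinning = 3, seed = 9)
  c1 <- run_mcmc(sim, K = 2, config = cfg)
  c2 <- run_mcmc(sim, K = 2, config = cfg)
  expect_identical(c1$draws, c2$draws)
  expect_identical(c1$label_freq, c2$label_freq)
  expect_equal(nrow(c1$draws), floor((120 - 40) / 3))
  expect_true(all(abs(rowSums(c1$label_freq) - 1) < 1e-9))
})

test_that("with the likelihood switched off every block reproduces its prior", {
  sim <- simulate_hic(simulation_config(n_pairs = 100,
                                        lattice_shape = c(10, 10), seed = 7))
  prior <- prior_config(2, beta_prior_means = matrix(0, 2, 5),
                        beta_prior_sds = 0.7, tau_prior = c(4, 6))
  cfg <- mcmc_config(iterations = 3000, burn_in = 500, seed = 10,
                     beta_proposal_sd = 0.6, abc_quantile = 1.0,
                     likelihood_weight = 0, adapt = FALSE)
  ch <- run_mcmc(sim, K = 2, prior = prior, config = cfg)
  expect_gt(stats::ks.test(ch$draws$tau, stats::pbeta, 4, 6)$p.value, 0.01)
  expect_gt(stats::ks.test(ch$draws$gamma, stats::pbeta, 10, 5)$p.value, 0.01)
  # thin the autocorrelated Metropolis chain before the KS check
  b <- ch$draws$beta_k1_p2[seq(1, 2500, by = 25)]
  expect_gt(stats::ks.test(b, stats::pnorm, 0, 0.7)$p.value, 0.01)
})

test_that("role mapping orders components by fitted mean and survives permutation", {
  obs <- make_obs(50, y = rpois(50, 5))
  betas <- rbind(c(log(0.5), 0, 0, 0, 0), c(log(20), 0, 0, 0, 0))
  ch <- make_constant_chain(betas, 0.2, 0.3, rep(1:2, 25), obs = obs)
  rm2 <- label_components(ch, obs)
  expect_equal(rm2$role, c("noise", "signal"))
  expect_equal(rm2$component, c(1L, 2L))

  betas3 <- rbind(c(log(20), 0, 0, 0, 0), c(log(900), 0, 0, 0, 0),
                  c(log(0.5), 0, 0, 0, 0))
  ch3 <- make_constant_chain(betas3, 0.2, 0.3, rep(1:3, length.out = 50),
                             obs = obs)
  rm3 <- label_components(ch3, obs)
  expect_equal(rm3$role[match(c(3, 1, 2), rm3$component)],
               c("noise", "signal", "false_signal"))

  # permuting component indices leaves role-mapped calls unchanged
  perm <- c(2L, 3L, 1L)  # new index of old component k
  z3 <- rep(1:3, length.out = 50)
  chp <- make_constant_chain(betas3[order(perm), ], 0.2, 0.3, perm[z3],
                             obs = obs)
  calls_orig <- call_interactions(ch3)
  calls_perm <- call_interactions(chp)
  expect_equal(calls_perm$label, calls_orig$label)
  expect_equal(calls_perm$p_signal, calls_orig$p_signal)

  # tied means are unidentifiable
  cht <- make_constant_chain(rbind(c(1, 0, 0, 0, 0), c(1, 0, 0, 0, 0)),
                             0.2, 0.3, rep(1:2, 25))
  expect_error(label_components(cht, obs), "tie")
})

test_that("posterior summaries report equal-tailed intervals and significance", {
  obs <- make_obs(20, y = rpois(20, 3))
  ch <- make_constant_chain(default_betas(2), 0.25, 0.4, rep(1:2, 10),
                            obs = obs)
  s <- posterior_summaries(ch)
  expect_equal(s$estimate[s$term == "tau"], 0.25)
  expect_equal(s$conf.low[s$term == "tau"], 0.25)

  # quantile oracle: standard normal draws give approximately (-1.96, 1.96)
  set.seed(11)
  ch$draws <- ch$draws[rep(1, 1e5), ]
  ch$draws$.draw <- seq_len(1e5)
  ch$draws$gamma <- rnorm(1e5)
  s2 <- posterior_summaries(ch)
  expect_lt(abs(s2$conf.low[s2$term == "gamma"] + 1.96), 0.05)
  expect_lt(abs(s2$conf.high[s2$term == "gamma"] - 1.96), 0.05)
  expect_false(s2$significant[s2$term == "gamma"])

  # an interval like (-0.40, 1.03) covers zero: not significant
  ch$draws$gamma <- runif(1e5, -0.40, 1.03)
  s3 <- posterior_summaries(ch)
  expect_false(s3$significant[s3$term == "gamma"])

  chs <- make_constant_chain(default_betas(2), 0.25, 0.4, rep(1:2, 10))
  chs$draws <- chs$draws[1:50, ]
  expect_error(posterior_summaries(chs), "100")
})

test_that("tidy and glance expose broom-style summaries", {
  sim <- simulate_hic(simulation_config(n_pairs = 100,
                                        lattice_shape = c(10, 10), seed = 12))
  ch <- run_mcmc(sim, K = 2, config = mcmc_config(iterations = 250,
                                                  burn_in = 100, seed = 12))
  td <- tidy(ch)
  expect_true(all(c("term", "estimate", "conf.low", "conf.high",
                    "significant") %in% names(td)))
  expect_true(any(grepl("^beta_k2", td$term)))
  g <- glance(ch)
  expect_equal(g$retained, 150)
  expect_equal(g$K, 2)
  # chain serialization round-trips
  dir <- withr::local_tempdir()
  write_chain(ch, dir)
  back <- read_chain(dir)
  expect_equal(back$draws, ch$draws)
  expect_equal(back$label_freq, ch$label_freq, tolerance = 1e-12)
  expect_equal(back$role_map$role, ch$role_map$role)
})
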