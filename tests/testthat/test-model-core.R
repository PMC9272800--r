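test_that("zero-inflated Poisson pmf: closed forms, normalization and moments", {
  # closed form at zero: tau + (1 - tau) e^(-lambda)
  expect_equal(zip_log_pmf(0, 0.3, 2), log(0.3 + 0.7 * exp(-2)),
               tolerance = 1e-12)
  expect_equal(exp(zip_log_pmf(0, 0.3, 2)), 0.3947347, tolerance = 1e-6)
  # boundary cases
  expect_equal(zip_log_pmf(c(0L, 3L), 1, 5), c(0, -Inf))
  expect_equal(zip_log_pmf(4, 0, 5), dpois(4, 5, log = TRUE))
  # normalization and mean over the support
  y <- 0:500
  pmf <- exp(zip_log_pmf(y, 0.5, 10))
  expect_lt(abs(sum(pmf) - 1), 1e-10)
  pmf2 <- exp(zip_log_pmf(0:200, 0.2, 5))
  expect_equal(sum((0:200) * pmf2), (1 - 0.2) * 5, tolerance = 1e-10)
  expect_error(zip_log_pmf(1, 0.5, -1), "positive")
  expect_error(zip_log_pmf(1, 1.5, 1), "probability")
})

test_that("component mean evaluates the log-linear bias regression", {
  obs <- make_obs(3, D = c(1, exp(2), 10), GC = c(0.5, 1, 0.4),
                  TE = c(1, 1, 2), ACC = c(1, 1, 0.5))
  expect_equal(component_mean(rep(0, 5), obs), rep(1, 3))
  expect_equal(component_mean(c(2, 0, 0, 0, 0), obs), rep(exp(2), 3))
  # beta = (1, -0.5, 0, 0, 0) at D = e^2: lambda = e^(1 - 1) = 1
  expect_equal(component_mean(c(1, -0.5, 0, 0, 0), obs)[2], 1)
  expect_error(component_mean(c(60, 0, 0, 0, 0), obs), "cap")
  expect_error(component_mean(rep(0, 5), make_obs(1, GC = 0)), "positive")
  # monotone in each covariate with the sign of its coefficient
  for (p in 2:5) {
    b <- rep(0, 5); b[p] <- 0.7
    lo <- make_obs(1); hi <- make_obs(1)
    hi[[c("D", "GC", "TE", "ACC")[p - 1]]] <- 3
    expect_gt(component_mean(b, hi), component_mean(b, lo))
    b[p] <- -0.7
    expect_lt(component_mean(b, hi), component_mean(b, lo))
  }
})

test_that("mixture log density collapses correctly and matches a term sum", {
  obs <- make_obs(4, y = c(0, 2, 5, 9), D = c(1, 2, 3, 4))
  s1 <- model_state(2, c(1, 0), 0.3, rbind(c(1, 0, 0, 0, 0),
                                           c(3, 0, 0, 0, 0)), 0.5)
  expect_equal(mixture_log_density(obs, s1),
               zip_log_pmf(obs$y, 0.3, component_mean(s1$betas[1, ], obs)))
  # equal lambdas, tau = 0: mixture is plain Poisson
  s2 <- model_state(2, c(0.5, 0.5), 0, rbind(c(1, 0, 0, 0, 0),
                                             c(1, 0, 0, 0, 0)), 0)
  expect_equal(mixture_log_density(obs, s2),
               dpois(obs$y, exp(1), log = TRUE))
  # K = 3 against an independently coded term-by-term sum
  set.seed(42)
  for (r in 1:12) {
    betas <- matrix(rnorm(15, 0, 0.5), 3, 5)
    alphas <- as.vector(rmultinom(1, 30, rep(1, 3)) / 30)
    if (any(alphas == 0)) next
    tau <- runif(1)
    st <- model_state(3, alphas, tau, betas, 0.2)
    lam <- sapply(1:3, function(k) component_mean(betas[k, ], obs))
    direct <- log(alphas[1] * exp(zip_log_pmf(obs$y, tau, lam[, 1])) +
                  alphas[2] * dpois(obs$y, lam[, 2]) +
                  alphas[3] * dpois(obs$y, lam[, 3]))
    expect_equal(mixture_log_density(obs, st), direct, tolerance = 1e-12)
  }
})

test_that("mixture density sums to 1 over the count support", {
  set.seed(7)
  obs <- make_obs(1, y = 0)
  for (r in 1:5) {
    alphas <- runif(2); alphas <- alphas / sum(alphas)
    st <- model_state(2, alphas, runif(1),
                      rbind(c(runif(1, 0, 2), 0, 0, 0, 0),
                            c(runif(1, 0, 3), 0, 0, 0, 0)), 0.1)
    total <- sum(sapply(0:400, function(yy) {
      obs$y <- yy
      exp(mixture_log_density(obs, st))
    }))
    expect_lt(abs(total - 1), 1e-8)
  }
})

test_that("Potts unnormalized log probability counts concordant edges", {
  lat <- pair_lattice(2, 2)
  expect_equal(potts_log_unnormalized(c(1, 2, 2, 1), 0, lat), 0)
  expect_equal(potts_log_unnormalized(rep(1, 4), 0.7, lat), 0.7 * 4)
  expect_equal(potts_log_unnormalized(c(1, 2, 2, 1), 1.3, lat), 0)
})

test_that("brute-force partition function matches closed forms", {
  lat1 <- pair_lattice(1, 1)
  expect_equal(potts_partition_bruteforce(lat1, 2.5, 3), 3)  # no edges
  lat <- pair_lattice(2, 2)
  expect_equal(potts_partition_bruteforce(lat, 0, 2), 2^4)
  # hand enumeration for the 2x2, K=2 case: C = 2 e^(4g) + 12 e^(2g) + 2
  for (g in c(0.3, 1)) {
    expect_equal(potts_partition_bruteforce(lat, g, 2),
                 2 * exp(4 * g) + 12 * exp(2 * g) + 2, tolerance = 1e-12)
  }
  expect_error(potts_partition_bruteforce(pair_lattice(5, 5), 1, 2), "16")
})

test_that("Potts full conditional is a proper distribution matching joint ratios", {
  lat <- pair_lattice(2, 2)
  expect_equal(potts_full_conditional(1, c(1, 2, 2, 1), 0, lat, 4),
               rep(0.25, 4))
  # all neighbours share one label at large gamma
  lat33 <- pair_lattice(3, 3)
  z <- rep(1L, 9); z[5] <- 2L
  p <- potts_full_conditional(5, z, 5, lat33, 2)
  expect_equal(p[1], exp(20) / (exp(20) + 1), tolerance = 1e-12)
  expect_gt(p[1], 0.999)
  # conditional equals renormalized joint over the site's label
  for (g in c(0.4, 1.1)) {
    for (rep_i in 1:5) {
      z <- sample(1:2, 4, replace = TRUE)
      joint <- sapply(1:2, function(k) {
        zz <- z; zz[2] <- k
        exp(potts_log_unnormalized(zz, g, lat))
      })
      expect_equal(potts_full_conditional(2, z, g, lat, 2),
                   joint / sum(joint), tolerance = 1e-12)
    }
  }
  expect_equal(sum(potts_full_conditional(3, c(1, 1, 2, 2), 0.8, lat, 2)), 1)
})
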