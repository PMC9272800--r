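# Small programmatic fixtures shared across test files.

# observation tibble with fixed covariates (no randomness)
make_obs <- function(n, y = rep(1L, n), D = rep(2, n), GC = rep(0.5, n),
                     TE = rep(1, n), ACC = rep(1, n)) {
  tibble::tibble(site = seq_len(n), i = 1L, j = seq_len(n),
                 y = as.integer(y), D = D, GC = GC, TE = TE, ACC = ACC)
}

# manual hic_chain with constant draws; used for collapsed-chain properties
make_constant_chain <- function(betas, tau, gamma, z, n_draws = 200,
                                obs = NULL) {
  K <- nrow(betas)
  n <- length(z)
  draws <- tibble::tibble(.draw = seq_len(n_draws), tau = tau, gamma = gamma,
                          loglik = NA_real_)
  for (k in seq_len(K)) draws[[paste0("alpha_", k)]] <- mean(z == k)
  for (k in seq_len(K)) for (p in 0:4) {
    draws[[sprintf("beta_k%d_p%d", k, p)]] <- betas[k, p + 1]
  }
  lf <- matrix(0, n, K)
  lf[cbind(seq_len(n), z)] <- 1
  ch <- structure(
    list(draws = draws, label_freq = lf,
         acceptance = list(beta = matrix(0.3, K, 5), gamma = 0.1),
         K = K, n = n,
         sites = tibble::tibble(site = seq_len(n), i = 1L, j = seq_len(n)),
         prior = prior_config(K), config = mcmc_config(iterations = 2,
                                                       burn_in = 1)),
    class = "hic_chain"
  )
  if (!is.null(obs)) {
    ll <- numeric(n)
    le <- sapply(seq_len(K), function(k) {
      lam <- component_mean(betas[k, ], obs)
      if (k == 1) zip_log_pmf(obs$y, tau, lam) else dpois(obs$y, lam, log = TRUE)
    })
    ch$draws$loglik <- sum(le[cbind(seq_len(n), z)])
    ch$role_map <- label_components(ch, obs)
  }
  ch
}

# write a small FASTA file, returning its path
write_test_fasta <- function(seqs, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "test.fa")
  con <- file(path, "w")
  for (nm in names(seqs)) writeLines(c(paste0(">", nm), seqs[[nm]]), con)
  close(con)
  path
}

# exact Potts configuration distribution on a small lattice (independent
# enumeration, optionally with per-site emission terms), indexed like
# cpp_gibbs_config_tally: config id = sum (z_s - 1) * K^(s-1)
exact_config_probs <- function(lattice, gamma, K, log_emission = NULL) {
  n <- lattice$n_sites
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  lw <- apply(grid, 1, function(z) {
    v <- gamma * concordant_pairs(z, lattice)
    if (!is.null(log_emission)) {
      v <- v + sum(log_emission[cbind(seq_len(n), z)])
    }
    v
  })
  # expand.grid varies the FIRST factor fastest -> row r encodes id r-1
  w <- exp(lw - max(lw))
  w / sum(w)
}

total_variation <- function(p, q) 0.5 * sum(abs(p - q))

`%||%` <- function(a, b) if (is.null(a)) b else a
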