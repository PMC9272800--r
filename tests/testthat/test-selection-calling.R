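test_that("a collapsed chain reduces the DIC to -2 x complete log-likelihood", {
  obs <- make_obs(40, y = rpois(40, c(1, 20)))
  z <- rep(1:2, 20)
  betas <- rbind(c(0, 0, 0, 0, 0), c(3, 0, 0, 0, 0))
  ch <- make_constant_chain(betas, 0.2, 0.3, z, obs = obs)
  ll_em <- ch$draws$loglik[1]
  # complete likelihood adds the multinomial label term sum_s log alpha_{z_s}
  ll_lab <- sum(log(c(0.5, 0.5)[z]))
  expect_equal(compute_dic(ch, obs), -2 * (ll_em + ll_lab), tolerance = 1e-10)
  # the emissions-only conditional variant drops the label term
  expect_equal(compute_dic(ch, obs, include_label_prior = FALSE), -2 * ll_em,
               tolerance = 1e-10)
  chs <- ch; chs$draws <- chs$draws[1:50, ]
  expect_error(compute_dic(chs, obs), "100")
})

test_that("select_K returns the single candidate trivially with a full table", {
  sim <- simulate_hic(simulation_config(n_pairs = 100,
                                        lattice_shape = c(10, 10), seed = 14))
  cfg <- mcmc_config(iterations = 250, burn_in = 100, seed = 14,
                     abc_pilot_draws = 5, abc_sweeps = 3)
  sel <- select_K(sim, candidate_Ks = 2, config = cfg)
  expect_equal(sel$best_K, 2L)
  expect_equal(nrow(sel$table), 1)
  expect_true(is.finite(sel$table$DIC))
  expect_error(select_K(sim, candidate_Ks = 1:2), ">= 2")
})

test_that("calls apply the argmax + threshold rule with conservative ties", {
  obs <- make_obs(4, y = c(0L, 10L, 5L, 5L))
  betas3 <- rbind(c(log(0.5), 0, 0, 0, 0), c(log(20), 0, 0, 0, 0),
                  c(log(900), 0, 0, 0, 0))
  ch <- make_constant_chain(betas3, 0.2, 0.3, c(1L, 2L, 3L, 1L), obs = obs)
  ch$label_freq <- rbind(
    c(1, 0, 0),          # certain noise
    c(0.2, 0.8, 0),      # significant signal
    c(0.3, 0.35, 0.35),  # signal/false-signal tie -> signal (lower mean)
    c(0.5, 0.5, 0)       # noise/signal tie -> noise (conservative)
  )
  calls <- call_interactions(ch, threshold = 0.5)
  expect_equal(calls$label, c("noise", "signal", "signal", "noise"))
  expect_equal(calls$significant, c(FALSE, TRUE, FALSE, FALSE))
  expect_true(all(abs(rowSums(as.matrix(
    calls[, c("p_noise", "p_signal", "p_false_signal")])) - 1) < 1e-9))

  # threshold sweeps
  expect_equal(sum(call_interactions(ch, threshold = 1.01)$significant), 0)
  low <- call_interactions(ch, threshold = 0)
  expect_equal(sum(low$significant), sum(low$label == "signal"))
})

test_that("characterization partitions significant calls exhaustively", {
  dir <- withr::local_tempdir()
  bins <- genomic_bins("chr3", 10 * 2000, 2000)
  calls <- tibble::tibble(
    site = 1:4, bin_i = c(0L, 2L, 5L, 0L), bin_j = c(1L, 3L, 8L, 9L),
    p_noise = 0.1, p_signal = 0.9,
    label = "signal", significant = c(TRUE, TRUE, TRUE, FALSE)
  )
  tads <- file.path(dir, "tads.bed")
  # TAD1 holds bins 0-3; TAD2 holds bins 4-6: call 3 spans TAD2/outside
  writeLines(c("chr3\t0\t8000\tTAD1", "chr3\t8000\t14000\tTAD2"), tads)
  ann <- file.path(dir, "ann.bed")
  writeLines(c("chr3\t0\t2500\tpromoter",     # bin 0 (and 1 partially)
               "chr3\t2000\t8000\tgene",      # bins 1-3
               "chr3\t10000\t12000\tgene"),   # bin 5
             ann)
  char <- characterize_calls(calls, bins, tads = tads, genes_promoters = ann)
  expect_equal(char$n_significant, 3)
  expect_equal(sum(char$distance_histogram$n), 3)
  expect_equal(sum(char$tad_partition$n), 3)
  expect_equal(char$tad_partition$n[char$tad_partition$category == "inside_tad"], 2)
  expect_equal(sum(char$promoter_partition$n), 3)
  # bin 0 overlaps promoter AND (via 2000-2500) nothing else; bin 1 overlaps
  # both promoter and gene -> P by precedence
  expect_true("P-P" %in% char$promoter_partition$pair_category)
  # bin 8 overlaps nothing -> O
  expect_true(any(grepl("O", char$promoter_partition$pair_category)))

  expect_warning(expect_warning(characterize_calls(calls, bins), "TAD"),
                 "promoter")
})

test_that("well-separated simulations are called with >= 90% accuracy", {
  # signal intercept raised so the fitted-mean ratio exceeds 10
  betas_sep <- rbind(c(7, -0.7, 0.3, -0.2, -0.3), c(10, -0.9, 0.36, -0.1, 0.15))
  acc <- sapply(1:3, function(s) {
    cfg <- simulation_config(betas = betas_sep, seed = 300 + s)
    sim <- simulate_hic(cfg)
    ch <- run_mcmc(sim, K = 2,
                   config = mcmc_config(iterations = 250, burn_in = 100,
                                        seed = s, abc_pilot_draws = 5,
                                        abc_sweeps = 3))
    calls <- call_interactions(ch, threshold = 0.5)
    mean((calls$label == "signal") == (sim$true_labels == 2))
  })
  expect_true(all(acc >= 0.9))
})
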