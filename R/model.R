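#' Zero-inflated Poisson log probability mass
#'
#' The noise component of the contact-count mixture is a zero-inflated
#' Poisson: with probability `tau` an extra zero is observed, otherwise a
#' Poisson(`lam`) draw. The distribution has mean \eqn{(1-\tau)\lambda} and
#' variance \eqn{\lambda(1-\tau)(1+\tau\lambda)}.
#'
#' @param y Non-negative integer count(s).
#' @param tau Extra-zero probability in \[0, 1\].
#' @param lam Positive Poisson mean(s); recycled against `y`.
#' @return Log probability, computed stably in log space.
#' @examples
#' zip_log_pmf(0, 0.3, 2)  # log(0.3 + 0.7 * exp(-2))
#' @export
zip_log_pmf <- function(y, tau, lam) {
  check_prob(tau, "tau")
  if (any(lam <= 0)) abort("`lam` must be positive")
  if (any(y < 0) || any(y != floor(y))) abort("`y` must be non-negative integers")
  lp <- dpois(y, lam, log = TRUE) + log1p(-tau)
  if (tau > 0) {
    zero <- y == 0
    if (any(zero)) {
      lam0 <- rep_len(lam, length(y))[zero]
      if (tau == 1) {
        lp[zero] <- 0
      } else {
        # log(tau + (1 - tau) exp(-lam)) via log-sum-exp
        a <- log(tau)
        b <- log1p(-tau) - lam0
        m <- pmax(a, b)
        lp[zero] <- m + log(exp(a - m) + exp(b - m))
      }
    }
    if (tau == 1) lp[y > 0] <- -Inf
  }
  lp
}

#' Component mean from the bias regression
#'
#' Each mixture component models its mean contact count through a
#' log-linear regression on the four bias covariates:
#' \deqn{\log \lambda_s = \beta_0 + \beta_1 \log D_s + \beta_2 \log GC_s +
#'       \beta_3 \log TE_s + \beta_4 \log ACC_s}
#'
#' @param beta Numeric vector of 5 coefficients
#'   (intercept, distance, GC, TE, accessibility).
#' @param obs Data frame with positive columns `D`, `GC`, `TE`, `ACC`.
#' @param cap Error when any \eqn{|\log\lambda|} exceeds this bound
#'   (default 50); guards against numeric overflow.
#' @return Positive vector of means, one per observation row.
#' @export
component_mean <- function(beta, obs, cap = 50) {
  if (length(beta) != 5 || !all(is.finite(beta))) {
    abort("`beta` must be 5 finite coefficients")
  }
  X <- obs_design(obs)
  eta <- drop(X %*% beta)
  if (any(abs(eta) > cap)) {
    worst <- which.max(abs(eta))
    abort(sprintf(
      "|log lambda| exceeds cap %g at observation %d (log lambda = %.2f); check beta and covariate scales",
      cap, worst, eta[worst]
    ))
  }
  exp(eta)
}

# Design matrix (1, log D, log GC, log TE, log ACC); covariates must already
# be pseudocounted strictly positive.
obs_design <- function(obs) {
  need <- c("D", "GC", "TE", "ACC")
  if (!all(need %in% names(obs))) {
    abort("observations need columns D, GC, TE, ACC")
  }
  for (v in need) {
    if (any(obs[[v]] <= 0)) abort(sprintf("covariate `%s` must be strictly positive (apply a pseudocount)", v))
  }
  cbind(1, log(obs$D), log(obs$GC), log(obs$TE), log(obs$ACC))
}

#' Construct and validate a mixture model state
#'
#' Bundles all unknowns of the model: component weights, the extra-zero
#' probability of the noise component, per-component regression coefficients,
#' the Potts interaction strength and the latent label field.
#'
#' @param K Number of mixture components (>= 2).
#' @param alphas K component proportions summing to 1.
#' @param tau Extra-zero probability of component 1.
#' @param betas K x 5 matrix of regression coefficients (rows = components).
#' @param gamma Non-negative Potts interaction parameter.
#' @param z Optional integer label vector in 1..K.
#' @return A list of class `model_state`.
#' @export
model_state <- function(K, alphas, tau, betas, gamma, z = NULL) {
  K <- check_count(K, "K", min = 2L)
  if (length(alphas) != K || any(alphas < 0) ||
      abs(sum(alphas) - 1) > 1e-12) {
    abort("`alphas` must be K non-negative proportions summing to 1")
  }
  check_prob(tau, "tau")
  betas <- rbind(betas)
  if (!is.matrix(betas) || nrow(betas) != K || ncol(betas) != 5 ||
      !all(is.finite(betas))) {
    abort("`betas` must be a finite K x 5 matrix")
  }
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma < 0) {
    abort("`gamma` must be a single non-negative real")
  }
  if (!is.null(z)) {
    z <- as.integer(z)
    if (any(z < 1L) || any(z > K)) abort("labels must lie in 1..K")
  }
  structure(list(K = K, alphas = as.numeric(alphas), tau = tau,
                 betas = unname(betas), gamma = gamma, z = z),
            class = "model_state")
}

# n x K matrix of log emission probabilities: column 1 is ZIP, columns >= 2
# Poisson, with component means from the bias regression.
emission_log_matrix <- function(obs, betas, tau, cap = 50) {
  K <- nrow(betas)
  out <- matrix(0, nrow(obs), K)
  for (k in seq_len(K)) {
    lam <- component_mean(betas[k, ], obs, cap = cap)
    out[, k] <- if (k == 1) zip_log_pmf(obs$y, tau, lam)
                else dpois(obs$y, lam, log = TRUE)
  }
  out
}

#' Log density of the count mixture
#'
#' Evaluates \eqn{\log f(y_s)} under the K-component mixture: a
#' zero-inflated Poisson noise component plus Poisson components, weighted by
#' the component proportions, via a numerically stable log-sum-exp.
#'
#' @param obs Data frame of observations with columns `y`, `D`, `GC`, `TE`,
#'   `ACC`.
#' @param state A [model_state()].
#' @return Numeric vector of per-observation log densities.
#' @export
mixture_log_density <- function(obs, state) {
  stopifnot(inherits(state, "model_state"))
  le <- emission_log_matrix(obs, state$betas, state$tau)
  lw <- sweep(le, 2, log(state$alphas), "+")
  lw[, state$alphas == 0] <- -Inf
  m <- apply(lw, 1, max)
  m + log(rowSums(exp(lw - m)))
}

#' Unnormalized Potts log probability
#'
#' \eqn{\gamma \times} the number of unordered neighbour pairs sharing a
#' label; adding the log partition function gives the Potts log density.
#'
#' @param z Integer labels over lattice sites.
#' @param gamma Interaction parameter.
#' @param lattice A [pair_lattice()].
#' @return A single real.
#' @export
potts_log_unnormalized <- function(z, gamma, lattice) {
  gamma * concordant_pairs(z, lattice)
}

#' Exact Potts partition function by enumeration
#'
#' Sums \eqn{\exp(\gamma \sum_{(s\sim t)} \delta_{z_s z_t})} over all
#' \eqn{K^{n}} label configurations. This is a test oracle for small
#' lattices, not a production path; it refuses lattices with more than 16
#' sites.
#'
#' @inheritParams potts_log_unnormalized
#' @param K Number of label states.
#' @return The normalizing constant \eqn{C(\gamma)}.
#' @export
potts_partition_bruteforce <- function(lattice, gamma, K) {
  stopifnot(inherits(lattice, "pair_lattice"))
  K <- check_count(K, "K", min = 2L)
  n <- lattice$n_sites
  if (n > 16) abort("brute-force partition function limited to <= 16 sites")
  configs <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  total <- 0
  for (r in seq_len(nrow(configs))) {
    total <- total + exp(potts_log_unnormalized(configs[r, ], gamma, lattice))
  }
  total
}

#' Potts full conditional at one site
#'
#' \eqn{P(z_s = k \mid z_{-s}) \propto \exp(\gamma \cdot \#\{t \in N_s :
#' z_t = k\})}.
#'
#' @param site Site index (1-based).
#' @inheritParams potts_partition_bruteforce
#' @param z Current labels.
#' @return K-vector of probabilities summing to 1.
#' @export
potts_full_conditional <- function(site, z, gamma, lattice, K) {
  stopifnot(inherits(lattice, "pair_lattice"))
  site <- check_count(site, "site")
  if (site > lattice$n_sites) abort("site index out of range")
  nb <- lattice$nbr[site, ]
  nb <- nb[nb > 0]
  cnt <- tabulate(z[nb], nbins = K)
  w <- exp(gamma * cnt)
  w / sum(w)
}
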