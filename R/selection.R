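#' Modified deviance information criterion for the latent-label model
#'
#' The complete-likelihood DIC variant for latent-variable models:
#' \deqn{DIC = -4\,E_{\theta,z}[\log f(y, z \mid \theta)] +
#'       2 \log f(y, \hat z \mid \hat\theta)}
#' with the complete likelihood of the mixture,
#' \eqn{f(y, z \mid \theta) = \prod_s \alpha_{z_s} f_{z_s}(y_s \mid
#' \theta)}: component emissions (zero-inflated Poisson for the noise
#' component, Poisson otherwise) times the multinomial label term with the
#' component proportions implied by the label field. The expectation
#' averages over retained draws (labels included); the plug-in term uses
#' the posterior-mean parameters with labels set to the per-site modal
#' label. The label term is what charges an extra, sparsely occupied
#' component for its added complexity; `include_label_prior = FALSE` gives
#' the emissions-only conditional form instead. Smaller is better.
#'
#' @param chain A `hic_chain` with at least 100 retained draws.
#' @param data The `hic_dataset` (or observation tibble) the chain was
#'   fitted to.
#' @param include_label_prior Include the multinomial label term (default
#'   TRUE).
#' @return A single DIC value.
#' @export
compute_dic <- function(chain, data, include_label_prior = TRUE) {
  stopifnot(inherits(chain, "hic_chain"))
  if (nrow(chain$draws) < 100) {
    abort("need at least 100 retained draws to compute the DIC")
  }
  obs <- if (inherits(data, "hic_dataset")) data$observations else data
  n <- nrow(obs)
  e_ll <- mean(chain$draws$loglik)
  bhat <- posterior_mean_betas(chain)
  tau_hat <- mean(chain$draws$tau)
  z_mode <- max.col(chain$label_freq, ties.method = "first")
  le <- emission_log_matrix(obs, bhat, tau_hat, cap = Inf)
  ll_plug <- sum(le[cbind(seq_len(n), z_mode)])
  if (include_label_prior) {
    # sum_s log alpha_{z_s} = n * sum_k alpha_k log alpha_k, computable
    # from the stored per-draw label frequencies
    A <- as.matrix(chain$draws[, paste0("alpha_", seq_len(chain$K))])
    ent <- rowSums(ifelse(A > 0, A * log(A), 0))
    e_ll <- e_ll + mean(n * ent)
    a_hat <- colMeans(A)
    n_mode <- tabulate(z_mode, chain$K)
    if (any(n_mode > 0 & a_hat == 0)) {
      ll_plug <- -Inf
    } else {
      ll_plug <- ll_plug + sum(n_mode[n_mode > 0] * log(a_hat[n_mode > 0]))
    }
  }
  -4 * e_ll + 2 * ll_plug
}

#' Choose the number of mixture components by DIC
#'
#' Fits the model once per candidate K and returns the DIC table with the
#' argmin-DIC candidate.
#'
#' @param data A `hic_dataset` (or tibble plus `lattice`).
#' @param candidate_Ks Integer vector of component counts (subset of 2, 3,
#'   ...).
#' @param prior `NULL` (default fixed prior per K), `"empirical_bayes"`, or
#'   a function of K returning a [prior_config()].
#' @param config An [mcmc_config()] shared across fits.
#' @param lattice Needed when `data` is a bare tibble.
#' @param keep_chains Keep the fitted chains in the result (default FALSE).
#' @return List with `best_K`, `table` (tibble of `K`, `DIC`) and
#'   optionally `chains`.
#' @export
select_K <- function(data, candidate_Ks = c(2, 3), prior = NULL,
                     config = mcmc_config(), lattice = NULL,
                     keep_chains = FALSE) {
  if (any(candidate_Ks < 2)) abort("candidate K values must be >= 2")
  fits <- purrr::map(candidate_Ks, function(K) {
    pk <- if (is.function(prior)) prior(K) else prior
    run_mcmc(data, K = K, prior = pk, config = config, lattice = lattice)
  })
  dics <- purrr::map_dbl(fits, compute_dic, data = data)
  tab <- tibble(K = as.integer(candidate_Ks), DIC = dics)
  out <- list(best_K = tab$K[which.min(tab$DIC)], table = tab)
  if (keep_chains) out$chains <- setNames(fits, paste0("K", candidate_Ks))
  out
}

#' Convert a chain into interaction calls
#'
#' Per site, the posterior component probabilities are the role-mapped label
#' frequencies across retained draws; the call label is the maximum-
#' probability role (ties broken toward the lower-mean role, which is
#' conservative), and a call is significant when it is labelled `signal`
#' with probability at least `threshold`.
#'
#' @param chain A `hic_chain`.
#' @param role_map Optional role mapping from [label_components()]; defaults
#'   to the one stored on the chain.
#' @param threshold Posterior-probability cutoff for significance
#'   (default 0.5).
#' @return Tibble with site coordinates, `p_<role>` columns, `label` and
#'   `significant`.
#' @export
call_interactions <- function(chain, role_map = NULL, threshold = 0.5) {
  stopifnot(inherits(chain, "hic_chain"))
  role_map <- role_map %||% chain$role_map
  if (is.null(role_map)) abort("no role map available; run label_components()")
  probs <- chain$label_freq[, role_map$component, drop = FALSE]
  colnames(probs) <- paste0("p_", role_map$role)
  # argmax with ties toward the lower-mean role (role_map is mean-ordered)
  lab_idx <- apply(probs, 1, which.max)  # first max = lower-mean role
  labels <- role_map$role[lab_idx]
  out <- dplyr::bind_cols(chain$sites, as_tibble(probs))
  out$label <- labels
  out$significant <- labels == "signal" &
    probs[, "p_signal"] >= threshold
  out
}

#' Characterize significant calls
#'
#' Tallies significant interactions by genomic-distance class, by TAD
#' co-membership (a call is inside a TAD only when both bins lie within one
#' common TAD interval) and by the promoter/gene/other category pair of its
#' two bins (precedence P > G > O: a bin overlapping a promoter is P even if
#' it also overlaps a gene).
#'
#' @param calls Call tibble from [call_interactions()] with `bin_i`/`bin_j`
#'   (or `i`/`j`) columns.
#' @param bins Bin tibble from [genomic_bins()].
#' @param tads Optional TAD intervals: a BED path or a data frame with
#'   `chrom`, `start`, `end` (0-based half-open).
#' @param genes_promoters Optional annotation: BED path or data frame with
#'   `chrom`, `start`, `end` and a category column (`extra`/`category`)
#'   containing `"promoter"` or `"gene"`.
#' @param distance_breaks Breakpoints (bp) for the distance histogram.
#' @return List of class `call_characterization` with `distance_histogram`,
#'   `tad_partition` and `promoter_partition` tibbles (the latter two `NULL`
#'   with a warning when annotation is missing).
#' @export
characterize_calls <- function(calls, bins, tads = NULL,
                               genes_promoters = NULL,
                               distance_breaks = c(0, 1e4, 1e5, 1e6, 1e7,
                                                   Inf)) {
  sig <- filter(calls, .data$significant)
  bi <- if ("bin_i" %in% names(sig)) sig$bin_i else sig$i - 1L
  bj <- if ("bin_j" %in% names(sig)) sig$bin_j else sig$j - 1L
  mid <- (bins$start + bins$end) / 2
  D <- abs(mid[bj + 1L] - mid[bi + 1L])
  dist_class <- cut(D, breaks = distance_breaks, include.lowest = TRUE)
  dist_hist <- as_tibble(table(class = dist_class), n = "n")

  tad_partition <- NULL
  if (!is.null(tads)) {
    tad_df <- if (is.character(tads)) read_bed_intervals(tads) else as_tibble(tads)
    tad_gr <- intervals_to_granges(tad_df)
    inside <- rep(FALSE, nrow(sig))
    if (nrow(sig) > 0 && length(tad_gr) > 0) {
      gr_i <- bins_to_granges(bins[bi + 1L, ])
      gr_j <- bins_to_granges(bins[bj + 1L, ])
      hi <- GenomicRanges::findOverlaps(gr_i, tad_gr, type = "within")
      hj <- GenomicRanges::findOverlaps(gr_j, tad_gr, type = "within")
      # a pair is inside iff some TAD contains both of its bins
      common <- merge(
        data.frame(q = S4Vectors::queryHits(hi), t = S4Vectors::subjectHits(hi)),
        data.frame(q = S4Vectors::queryHits(hj), t = S4Vectors::subjectHits(hj))
      )
      inside[unique(common$q)] <- TRUE
    }
    tad_partition <- tibble(category = c("inside_tad", "outside_tad"),
                            n = c(sum(inside), sum(!inside)))
  } else {
    warn("no TAD intervals supplied; TAD characterization skipped")
  }

  promoter_partition <- NULL
  if (!is.null(genes_promoters)) {
    ann <- if (is.character(genes_promoters)) {
      read_bed_intervals(genes_promoters, n_fields = 4)
    } else {
      as_tibble(genes_promoters)
    }
    if (!"extra" %in% names(ann) && "category" %in% names(ann)) {
      ann$extra <- ann$category
    }
    cat_of_bin <- function(b) {
      gr <- bins_to_granges(bins[b + 1L, , drop = FALSE])
      pg <- intervals_to_granges(filter(ann, .data$extra == "promoter"))
      gg <- intervals_to_granges(filter(ann, .data$extra == "gene"))
      ifelse(GenomicRanges::countOverlaps(gr, pg) > 0, "P",
             ifelse(GenomicRanges::countOverlaps(gr, gg) > 0, "G", "O"))
    }
    if (nrow(sig) > 0) {
      ci <- cat_of_bin(bi)
      cj <- cat_of_bin(bj)
      pair <- paste(pmin(ci, cj), pmax(ci, cj), sep = "-")
      promoter_partition <- as_tibble(table(pair_category = pair), n = "n")
    } else {
      promoter_partition <- tibble(pair_category = character(), n = integer())
    }
  } else {
    warn("no gene/promoter annotation supplied; promoter characterization skipped")
  }

  structure(
    list(n_significant = nrow(sig), distance_histogram = dist_hist,
         tad_partition = tad_partition,
         promoter_partition = promoter_partition),
    class = "call_characterization"
  )
}

#' @export
print.call_characterization <- function(x, ...) {
  cat("<call_characterization>", x$n_significant, "significant calls\n")
  print(x$distance_histogram)
  if (!is.null(x$tad_partition)) print(x$tad_partition)
  if (!is.null(x$promoter_partition)) print(x$promoter_partition)
  invisible(x)
}
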