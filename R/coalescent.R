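#' Simulation configuration for expected-SFS estimation
#'
#' @param n_sims Number of simulated genealogies per expected-spectrum
#'   estimate. The default (100,000) matches the full-fidelity estimation
#'   protocol; reduced values trade Monte-Carlo precision for speed.
#' @param seed Optional integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_sims = 100000L, seed = NULL) {
  n_sims <- as.integer(n_sims)
  if (n_sims < 1) stop("n_sims must be >= 1")
  structure(list(n_sims = n_sims, seed = seed), class = "sim_config")
}

#' Monte-Carlo expected folded multiSFS under a demographic model
#'
#' Estimates the expected polymorphic folded multiSFS by simulating
#' `cfg$n_sims` independent serially-sampled coalescent genealogies under
#' the model and accumulating every branch's length onto its folded entry
#' (the per-cohort leaf counts it subtends, folded by the pooled minor
#' allele). Under the infinite-sites model at low mutation rate the
#' probability that a random segregating site shows configuration `e` is
#' `E[l_e] / E[l_tot]`, which this length accumulation estimates directly;
#' conditioning on polymorphism is automatic because every branch subtends
#' a proper, non-empty subset of the pooled sample. Probabilities sum to 1
#' over the simulated support; entries never hit by simulation are handled
#' by the zero-probability floor inside [composite_loglik()].
#'
#' @param params A [param_vector()].
#' @param samples A [sample_spec()].
#' @param cfg A [sim_config()].
#' @param t_anc Passed to [build_timeline()].
#' @return An expected-kind folded `multisfs` (reproducible under
#'   `cfg$seed`).
#' @export
expected_sfs <- function(params, samples, cfg = sim_config(),
                         t_anc = .TANC_DEFAULT) {
  tl <- build_timeline(params, t_anc = t_anc)
  expected_sfs_timeline(tl, samples, cfg)
}

#' @rdname expected_sfs
#' @param timeline An `epoch_timeline` (alternative entry point used when
#'   the timeline is already built).
#' @export
expected_sfs_timeline <- function(timeline, samples, cfg = sim_config()) {
  stopifnot(inherits(timeline, "epoch_timeline"),
            inherits(samples, "sample_spec"))
  if (sum(samples$n_haploid) < 2) stop("need at least 2 haploid samples")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  res <- .cpp_expected_folded_sfs(unclass(timeline), samples$times,
                                  samples$n_haploid, cfg$n_sims)
  s <- multisfs(NULL, numeric(0), samples$n_haploid, kind = "expected",
                folded = TRUE, labels = samples$labels,
                times = samples$times, n_sims = cfg$n_sims)
  s$index <- res$index
  s$value <- res$weight
  s
}

#' Draw folded SFS entries for independent single-SNP loci
#'
#' Draws `n` independent per-locus entries from the model's expected
#' folded spectrum (estimated with `cfg$n_sims` genealogies), mirroring a
#' one-SNP-per-locus design in which each polymorphic locus contributes
#' one site drawn from the stationary site distribution.
#'
#' @param timeline An [build_timeline()] epoch timeline.
#' @param samples A [sample_spec()].
#' @param n Number of loci to draw.
#' @param cfg A [sim_config()] controlling the expected-spectrum estimate.
#' @param seed Optional integer seed (governs both the spectrum estimate
#'   and the entry draws).
#' @return Integer matrix (`n` x n_cohorts) of folded minor-allele counts,
#'   columns named by cohort label.
#' @export
simulate_entries <- function(timeline, samples, n = 1L, cfg = sim_config(),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  es <- expected_sfs_timeline(timeline, samples, sim_config(cfg$n_sims))
  draw <- sample(seq_along(es$index), size = n, replace = TRUE,
                 prob = es$value)
  ent <- index_to_entries(es$index[draw], es$dims)
  colnames(ent) <- samples$labels
  ent
}

#' Simulate a pseudo-observed spectrum under a model
#'
#' Draws `L` loci as a multinomial sample from the model's expected folded
#' spectrum (one-SNP-per-locus independence): the expected spectrum is
#' estimated with `cfg$n_sims` genealogy simulations and `L` entry draws
#' are tallied as counts. Used by the power analyses.
#'
#' @param params A [param_vector()].
#' @param samples A [sample_spec()].
#' @param L Number of polymorphic loci.
#' @param cfg A [sim_config()].
#' @param seed Optional integer seed.
#' @return An observed-kind folded `multisfs` with total `L`.
#' @export
simulate_observed_sfs <- function(params, samples, L, cfg = sim_config(),
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  es <- expected_sfs(params, samples, sim_config(cfg$n_sims))
  draw <- as.numeric(stats::rmultinom(1, size = L, prob = es$value))
  keep <- draw > 0
  s <- es
  s$kind <- "observed"
  s$index <- es$index[keep]
  s$value <- draw[keep]
  s$n_sims <- NULL
  s
}

# internal: plug-in composite log-likelihood from a probability vector at
# the observed support, with the zero-probability floor and renormalization
.plugin_loglik <- function(O, p, n_sims) {
  eps <- 1 / (10 * n_sims)
  zero <- p <= 0
  p[zero] <- eps
  z <- 1 + eps * sum(zero)
  sum(O * (log(p) - log(z)))
}

# internal: composite log-likelihood of obs under params, using the
# support-restricted accumulator (same estimator as expected_sfs +
# composite_loglik, but only the observed entries and the total length are
# tracked). sim_seed fixes the genealogy stream (common random numbers).
# The O(1/n_sims) Monte-Carlo bias of the plug-in log-likelihood is
# removed by Richardson extrapolation against the half-stream estimate.
.loglik_fast <- function(obs, params, samples, cfg, sim_seed,
                         t_anc = .TANC_DEFAULT) {
  tl <- build_timeline(params, t_anc = t_anc)
  set.seed(sim_seed)
  p <- .cpp_expected_probs_at(unclass(tl), samples$times, samples$n_haploid,
                              cfg$n_sims, obs$index)
  full <- .plugin_loglik(obs$value, p[1, ], cfg$n_sims)
  if (cfg$n_sims < 20) return(full)
  half <- .plugin_loglik(obs$value, p[2, ], cfg$n_sims %/% 2)
  2 * full - half
}
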