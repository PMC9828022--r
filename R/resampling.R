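#' Nonparametric bootstrap confidence intervals for fitted parameters
#'
#' Resamples the observed spectrum over loci `B` times
#' ([sfs_bootstrap_resample()]); for each bootstrap spectrum runs
#' `reps_per_sfs` local searches initialized at the observed-data ML
#' values jittered by +/- `jitter` on the log scale, retains the ML
#' parameter set, and reports 95% percentile intervals (linear
#' interpolation) per parameter.
#'
#' @param obs Observed folded `multisfs` the fit was made on.
#' @param best A completed [fit_model()] result on `obs`.
#' @param B Number of bootstrap spectra (>= 2; 100 at full fidelity).
#' @param reps_per_sfs Restarts per bootstrap spectrum (30 at full
#'   fidelity).
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @param jitter Relative log-scale jitter applied to the starting values.
#' @param max_cycles Cap on local-search iterations.
#' @return An object of class `bootstrap_result`: list with `estimates`
#'   (B x n_params matrix) and `ci` (data frame with 2.5/97.5 percentile
#'   bounds per parameter).
#' @export
bootstrap_ci <- function(obs, best, B = 100L, reps_per_sfs = 30L,
                         cfg = sim_config(), seed = 1L, jitter = 0.1,
                         max_cycles = 40L) {
  if (B < 2) stop("B must be >= 2")
  stopifnot(inherits(best, "fit_result"))
  set.seed(seed)
  boot_seeds <- sample.int(2^31 - 2, B)
  start0 <- best$params$params
  free <- .free_params(best$model_id, best$ranges)
  start0 <- start0[free]
  est <- matrix(NA_real_, B, length(start0),
                dimnames = list(NULL, names(start0)))
  for (b in seq_len(B)) {
    set.seed(boot_seeds[b])
    sb <- sfs_bootstrap_resample(obs, seed = NULL)
    rep_seeds <- sample.int(2^31 - 2, reps_per_sfs)
    bb <- NULL
    for (r in seq_len(reps_per_sfs)) {
      set.seed(rep_seeds[r])
      start <- start0 * exp(stats::runif(length(start0), -jitter, jitter))
      res <- .local_search(sb, best$model_id, start, best$ranges, cfg,
                           max_cycles, rep_seeds[r], best$samples)
      if (is.null(bb) || res$lnL > bb$lnL) bb <- res
    }
    est[b, ] <- bb$par[names(start0)]
  }
  ci <- data.frame(
    parameter = colnames(est),
    lower = apply(est, 2, stats::quantile, probs = 0.025, names = FALSE),
    upper = apply(est, 2, stats::quantile, probs = 0.975, names = FALSE),
    row.names = NULL
  )
  structure(list(estimates = est, ci = ci, B = B), class = "bootstrap_result")
}

#' Percentile interval from injected estimates
#'
#' Helper exposing the interval arithmetic used by [bootstrap_ci()]:
#' 2.5/97.5 percentiles with linear interpolation.
#'
#' @param x Numeric vector of bootstrap estimates.
#' @return Length-2 vector `c(lower, upper)`.
#' @export
percentile_ci <- function(x) {
  stats::quantile(x, c(0.025, 0.975), names = FALSE)
}

#' Re-evaluate fitted likelihoods under common random numbers
#'
#' Replaces each fit's search-time composite log-likelihood with a fresh
#' evaluation at its best parameters using a single shared simulation seed
#' and (by default) a larger number of simulations. This removes the
#' winner's-curse inflation of the retained restart's likelihood and pairs
#' the Monte-Carlo error across models, which stabilizes AIC comparisons.
#'
#' @param fits List of [fit_model()] results on the same observed
#'   spectrum.
#' @param obs The observed folded `multisfs` the fits were made on.
#' @param eval_cfg A [sim_config()] for the re-evaluation (defaults to ten
#'   times the first fit's `n_sims`, capped at 100,000).
#' @param seed Shared simulation seed.
#' @param n_seeds Number of shared seeds to average over (averaging
#'   reduces the Monte-Carlo spread of the comparison).
#' @return The list of fits with updated `lnL`.
#' @export
reeval_loglik <- function(fits, obs, eval_cfg = NULL, seed = 1L,
                          n_seeds = 2L) {
  if (is.null(eval_cfg)) {
    eval_cfg <- sim_config(min(10L * fits[[1]]$cfg$n_sims, 100000L))
  }
  seeds <- ((seed + 7919 * seq_len(n_seeds)) %% 2147483646) + 1
  lapply(fits, function(f) {
    f$lnL <- mean(vapply(seeds, function(s) {
      .loglik_fast(obs, f$params, f$samples, eval_cfg, sim_seed = s)
    }, numeric(1)))
    f
  })
}

# internal: fit several candidate models to one observed spectrum and
# return the AIC-selected model id. All fits share one candidate
# re-evaluation seed, so their returned likelihoods form one paired
# common-random-number measurement and are directly comparable.
.fit_and_select <- function(obs, candidate_models, ranges, n_restarts,
                            max_cycles, cfg, seed, samples, polish = TRUE,
                            refine_contenders = 0L) {
  fits <- lapply(candidate_models, function(m) {
    fit_model(obs, m, ranges = ranges, n_restarts = n_restarts,
              max_cycles = max_cycles, cfg = cfg, polish = polish,
              seed = (seed + m) %% 2147483646 + 1,
              eval_seed = seed, samples = samples)
  })
  if (refine_contenders > 0)
    fits <- refine_fits(fits, obs, cycles = refine_contenders)
  attr(select_model(fits), "best")
}

#' Model-selection confusion matrix from pseudo-observed data
#'
#' For each generating model, simulates `n_datasets` pseudo-observed
#' spectra at the study's sampling design and `L` polymorphic loci, fits
#' every candidate model with `reps` restarts each, selects by AIC and
#' tallies the selected against the generating model.
#'
#' @param generating_params Named list of [param_vector()]s (names are
#'   model ids as characters); each is used as the truth for its row.
#' @param samples A [sample_spec()].
#' @param L Polymorphic loci per pseudo-observed spectrum.
#' @param n_datasets Pseudo-observed datasets per generating model.
#' @param reps Restarts per model fit.
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @param candidate_models Candidate model ids (default 1-7).
#' @param ranges A [search_ranges()].
#' @param max_cycles Cap on local-search iterations.
#' @param polish Passed to [fit_model()].
#' @param refine_contenders If > 0, apply [refine_fits()] with this many
#'   coordinate cycles to each dataset's contending fits before selection.
#' @return An object of class `confusion_matrix`: list with `counts`
#'   (generating x selected) and `fractions` (row-stochastic).
#' @export
power_confusion <- function(generating_params, samples = sample_spec(),
                            L = 1068L, n_datasets = 10L, reps = 10L,
                            cfg = sim_config(), seed = 1L,
                            candidate_models = 1:7,
                            ranges = search_ranges(), max_cycles = 40L,
                            polish = TRUE, refine_contenders = 0L) {
  if (length(generating_params) == 0) stop("no generating parameters")
  gen_ids <- names(generating_params)
  counts <- matrix(0L, length(gen_ids), length(candidate_models),
                   dimnames = list(generating = gen_ids,
                                   selected = as.character(candidate_models)))
  set.seed(seed)
  data_seeds <- matrix(sample.int(2^31 - 2, length(gen_ids) * n_datasets),
                       nrow = length(gen_ids))
  fit_seeds <- matrix(sample.int(2^31 - 2, length(gen_ids) * n_datasets),
                      nrow = length(gen_ids))
  for (gi in seq_along(gen_ids)) {
    for (d in seq_len(n_datasets)) {
      pobs <- simulate_observed_sfs(generating_params[[gi]], samples, L,
                                    cfg, seed = data_seeds[gi, d])
      sel <- .fit_and_select(pobs, candidate_models, ranges, reps,
                             max_cycles, cfg, fit_seeds[gi, d], samples,
                             polish = polish,
                             refine_contenders = refine_contenders)
      counts[gi, as.character(sel)] <- counts[gi, as.character(sel)] + 1L
    }
  }
  structure(list(counts = counts, fractions = counts / n_datasets,
                 n_datasets = n_datasets),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Model-selection confusion matrix (rows = generating, cols = selected):\n")
  print(x$fractions)
  invisible(x)
}

#' Power to recover a model with equal cohort sample sizes
#'
#' Repeats the pseudo-observed-data power analysis for a single generating
#' model with the same number of diploids sampled in every cohort
#' (disentangling serial sampling from unequal sample sizes).
#'
#' @param params Generating [param_vector()].
#' @param model_id The generating model id.
#' @param n_datasets Number of pseudo-observed datasets (50 at full
#'   fidelity).
#' @param diploids_per_cohort Diploids per cohort (80 at full fidelity).
#' @param L Loci per dataset.
#' @param reps Restarts per model fit.
#' @param cfg,seed,candidate_models,ranges,max_cycles,polish,refine_contenders
#'   As in [power_confusion()].
#' @param times Sampling times of the cohorts (generations before the most
#'   recent).
#' @return The fraction of datasets in which `model_id` is selected.
#' @export
equal_sampling_power <- function(params, model_id = 6L, n_datasets = 50L,
                                 diploids_per_cohort = 80L, L = 1068L,
                                 reps = 10L, cfg = sim_config(), seed = 1L,
                                 candidate_models = 1:7,
                                 ranges = search_ranges(), max_cycles = 40L,
                                 times = c(7, 5.5, 0), polish = TRUE,
                                 refine_contenders = 0L) {
  samples <- sample_spec(rep(2L * diploids_per_cohort, length(times)), times,
                         labels = as.character(seq_along(times)))
  gp <- stats::setNames(list(params), as.character(model_id))
  cm <- power_confusion(gp, samples = samples, L = L,
                        n_datasets = n_datasets, reps = reps, cfg = cfg,
                        seed = seed, candidate_models = candidate_models,
                        ranges = ranges, max_cycles = max_cycles,
                        polish = polish,
                        refine_contenders = refine_contenders)
  cm$fractions[1, as.character(model_id)]
}

#' Averaged expected marginal spectra at the ML parameters
#'
#' Averages `n_spectra` independently simulated expected spectra at the
#' fitted (or supplied) parameters and returns the per-cohort folded
#' marginal SFS, for comparison against the observed marginals.
#'
#' @param best A [fit_model()] result, or a [param_vector()] (then
#'   `samples` must be given).
#' @param n_spectra Number of spectra to average.
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @param samples A [sample_spec()] (defaulting to the fit's).
#' @return Named list of per-cohort marginal SFS vectors (each sums to 1).
#' @export
expected_marginals_at_ml <- function(best, n_spectra = 100L,
                                     cfg = sim_config(), seed = 1L,
                                     samples = NULL) {
  if (inherits(best, "fit_result")) {
    params <- best$params
    samples <- samples %||% best$samples
  } else {
    params <- best
    if (is.null(samples)) stop("samples required when passing a param_vector")
  }
  set.seed(seed)
  seeds <- sample.int(2^31 - 2, n_spectra)
  acc <- NULL
  for (i in seq_len(n_spectra)) {
    es <- expected_sfs(params, samples, sim_config(cfg$n_sims, seed = seeds[i]))
    marg <- lapply(seq_along(samples$labels), function(c) sfs_marginalize(es, c))
    if (is.null(acc)) acc <- marg
    else acc <- Map(`+`, acc, marg)
  }
  out <- lapply(acc, function(v) v / n_spectra)
  names(out) <- samples$labels
  out
}

#' Plot observed versus expected marginal spectra
#'
#' Side-by-side barplot of each cohort's observed folded marginal SFS
#' (as proportions) against the averaged expected marginal under fitted
#' parameters, for visual assessment of model fit.
#'
#' @param obs Observed folded `multisfs`.
#' @param marginals Output of [expected_marginals_at_ml()].
#' @param max_count Largest minor-allele count to display.
#' @param file Optional path (.svg or .png chooses the device); `NULL`
#'   draws on the active device.
#' @return Invisibly, the plotted proportions per cohort.
#' @export
plot_marginal_comparison <- function(obs, marginals, max_count = 10L,
                                     file = NULL) {
  if (!is.null(file)) {
    if (grepl("\\.svg$", file)) grDevices::svg(file, width = 9, height = 4)
    else grDevices::png(file, width = 900, height = 400)
    on.exit(grDevices::dev.off())
  }
  k <- length(marginals)
  graphics::par(mfrow = c(1, k), mar = c(4, 4, 2, 1))
  out <- vector("list", k)
  for (c in seq_len(k)) {
    mo <- sfs_marginalize(obs, c)
    mo <- mo / sum(mo)
    me <- marginals[[c]]
    counts <- as.character(seq_len(min(max_count, length(mo) - 1)))
    m <- rbind(observed = mo[counts], expected = me[counts])
    graphics::barplot(m, beside = TRUE, names.arg = counts,
                      col = c("grey30", "grey70"),
                      xlab = "minor allele count", ylab = "proportion",
                      main = names(marginals)[c])
    if (c == 1) graphics::legend("topright", legend = rownames(m),
                                 fill = c("grey30", "grey70"), bty = "n")
    out[[c]] <- m
  }
  invisible(out)
}
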