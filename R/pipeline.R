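#' Configuration for a full analysis run
#'
#' Collects every input path, design choice and scale knob of the full
#' pipeline (filter, build SFS, fit models, select, bootstrap, optional
#' power analysis, diversity, census) in one declarative object.
#'
#' @param vcf,cohorts Paths to the genotype VCF and sample-to-cohort TSV
#'   (alternative to `obs`).
#' @param obs Path to a folded observed multiSFS in .obs format
#'   (alternative to `vcf` + `cohorts`).
#' @param age_table_path Optional path to an age-structured TSV for the
#'   census stage.
#' @param samples A [sample_spec()] describing the cohort design (sizes
#'   are taken from the data when a VCF is given).
#' @param models Candidate model ids to fit.
#' @param ranges A [search_ranges()].
#' @param cfg A [sim_config()].
#' @param n_restarts,max_cycles Search effort per model.
#' @param bootstrap_B,bootstrap_reps Bootstrap effort (`bootstrap_B = 0`
#'   skips the stage).
#' @param power_datasets Pseudo-observed datasets per generating model for
#'   the confusion stage (0 skips it).
#' @param out_dir Output directory (created if absent).
#' @param seed Master seed; every stage seed derives from it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(vcf = NULL, cohorts = NULL, obs = NULL,
                       age_table_path = NULL, samples = sample_spec(),
                       models = 1:7, ranges = search_ranges(),
                       cfg = sim_config(), n_restarts = 50L,
                       max_cycles = 40L, bootstrap_B = 0L,
                       bootstrap_reps = 30L, power_datasets = 0L,
                       out_dir = tempfile("serialSFS_run_"), seed = 1L) {
  if (is.null(obs) && (is.null(vcf) || is.null(cohorts)))
    stop("either 'obs' or both 'vcf' and 'cohorts' must be given")
  for (p in c(vcf, cohorts, obs, age_table_path))
    if (!file.exists(p)) stop("input file not found: ", p)
  if (n_restarts < 1 || max_cycles < 1) stop("counts must be >= 1")
  structure(list(vcf = vcf, cohorts = cohorts, obs = obs,
                 age_table_path = age_table_path, samples = samples,
                 models = models, ranges = ranges, cfg = cfg,
                 n_restarts = n_restarts, max_cycles = max_cycles,
                 bootstrap_B = bootstrap_B, bootstrap_reps = bootstrap_reps,
                 power_datasets = power_datasets,
                 out_dir = out_dir, seed = seed),
            class = "run_config")
}

# internal: run one stage, prefixing any error with the stage name
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage [", name, "]: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes, in order: genotype filtering (when a VCF is given), observed
#' multiSFS construction, per-model composite-likelihood fits, AIC model
#' selection, optional nonparametric bootstrap on the best model, optional
#' pseudo-observed-data confusion analysis, diversity statistics and the
#' census computations (when an age table is given). All outputs are
#' written under `cfg$out_dir` as TSV/JSON plus a manifest recording every
#' derived seed; reruns with the same master seed are reproducible.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`obs`, `fits`,
#'   `selection`, and the optional `bootstrap`, `confusion`, `diversity`,
#'   `census`).
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  stage_seeds <- stats::setNames(as.list(sample.int(2^31 - 2, 6)),
                                 c("fit", "bootstrap", "power", "diversity",
                                   "census", "spare"))
  manifest <- list(seed = config$seed, stage_seeds = stage_seeds,
                   n_restarts = config$n_restarts,
                   max_cycles = config$max_cycles,
                   n_sims = config$cfg$n_sims,
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  out <- list()

  g <- NULL
  if (!is.null(config$vcf)) {
    g <- .stage("filter", {
      g0 <- read_genotypes_vcf(config$vcf, config$cohorts)
      filter_chain(g0)
    })
    utils::write.table(
      data.frame(individuals = nrow(g$geno), loci = ncol(g$geno)),
      file.path(config$out_dir, "filter_summary.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }

  obs <- .stage("build-sfs", {
    if (!is.null(g)) {
      s <- sfs_from_genotypes(g, cohort_levels = config$samples$labels,
                              times = config$samples$times)
      write_obs(s, file.path(config$out_dir, "observed_MSFS.obs"))
      s
    } else {
      read_obs(config$obs)
    }
  })
  obs <- remove_monomorphic(obs)
  out$obs <- obs
  samples <- sample_spec(obs$n_haploid, config$samples$times, obs$labels)

  out$fits <- .stage("fit", {
    lapply(config$models, function(m) {
      fit_model(obs, m, ranges = config$ranges,
                n_restarts = config$n_restarts,
                max_cycles = config$max_cycles, cfg = config$cfg,
                seed = (stage_seeds$fit + m) %% 2147483646 + 1,
                eval_seed = stage_seeds$fit, samples = samples)
    })
  })
  out$selection <- .stage("select", select_model(out$fits))
  utils::write.table(as.data.frame(out$selection),
                     file.path(config$out_dir, "model_selection.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  best <- out$fits[[which(vapply(out$fits, `[[`, 0L, "model_id") ==
                          attr(out$selection, "best"))]]
  jsonlite::write_json(
    list(model_id = best$model_id, lnL = best$lnL,
         params = as.list(best$params$params)),
    file.path(config$out_dir, "best_fit.json"), auto_unbox = TRUE, digits = NA)

  if (config$bootstrap_B >= 2) {
    out$bootstrap <- .stage("bootstrap", {
      bootstrap_ci(obs, best, B = config$bootstrap_B,
                   reps_per_sfs = config$bootstrap_reps, cfg = config$cfg,
                   seed = stage_seeds$bootstrap,
                   max_cycles = config$max_cycles)
    })
    utils::write.table(out$bootstrap$ci,
                       file.path(config$out_dir, "bootstrap_ci.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  if (config$power_datasets >= 1) {
    out$confusion <- .stage("power", {
      gp <- stats::setNames(list(best$params), as.character(best$model_id))
      power_confusion(gp, samples = samples, L = sum(obs$value),
                      n_datasets = config$power_datasets,
                      reps = max(1L, config$n_restarts %/% 5L),
                      cfg = config$cfg, seed = stage_seeds$power,
                      ranges = config$ranges,
                      max_cycles = config$max_cycles)
    })
    utils::write.table(out$confusion$counts,
                       file.path(config$out_dir, "confusion_counts.tsv"),
                       sep = "\t", quote = FALSE)
  }

  if (!is.null(g)) {
    out$diversity <- .stage("diversity", {
      list(het = heterozygosity_stats(g), pi = windowed_pi(g))
    })
    utils::write.table(out$diversity$het$summary,
                       file.path(config$out_dir, "diversity_summary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  if (!is.null(config$age_table_path)) {
    out$census <- .stage("census", {
      tbl <- read_age_table(config$age_table_path)
      yrs <- sort(unique(tbl$data$year))
      list(peak_spawning = stats::setNames(
             vapply(yrs, function(y) peak_spawning_abundance(tbl, y),
                    numeric(1)), yrs),
           generation_length = generation_length(tbl))
    })
  }

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}
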