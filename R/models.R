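#' @useDynLib serialSFS, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim runif quantile rmultinom sd setNames rbinom
#' @importFrom utils read.table write.table
NULL

# Time (backward, generations) at which the ancestral exponential segment of
# models 4, 6 and 7 ends; beyond it the size is the constant NANC.  With a
# 2-year generation this corresponds to roughly the end of the Last Glacial
# Maximum (~20 kya).
.TANC_DEFAULT <- 10000

#' Demographic model registry
#'
#' Seven single-population demographic model topologies for a population
#' sampled serially through time, indexed by `model_id` 1-7:
#'
#' 1. Constant size (`NANC`).
#' 2. Bottleneck followed by an instantaneous size change
#'    (`NPREBOT`, `NBOT`, `NPOP08`, `TLEN`, `TBOT`).
#' 3. Bottleneck followed by exponential change to the present size.
#' 4. Ancestral exponential change, bottleneck, instantaneous change
#'    (adds `NANC`, `TCAR`).
#' 5. Two bottlenecks with instantaneous changes (`NBOT1`/`TLEN1`/`TBOT1`
#'    for the older event, `NBOT2`/`TLEN2`/`TBOT2` for the recent one and
#'    intermediate size `NINT`; `TBOT1` is the gap in generations between
#'    the end of the older bottleneck and the start of the recent one).
#' 6. Ancestral exponential change, bottleneck, exponential recovery.
#' 7. Ancestral exponential change up to a carrying capacity reached `TCAR`
#'    generations before present (`NANC`, `NPOP08`, `TCAR`).
#'
#' All sizes are in haploid units, all times in generations before the most
#' recent sampling. The free-parameter counts returned by
#' [free_param_count()] are the registry defaults and may be overridden via
#' the `k` argument of [select_model()].
#'
#' @return A named list, one entry per model, with elements `params`
#'   (character vector of parameter names) and `k` (free-parameter count).
#' @export
model_registry <- function() {
  list(
    `1` = list(params = c("NANC"), k = 1L),
    `2` = list(params = c("NPREBOT", "NBOT", "NPOP08", "TLEN", "TBOT"), k = 5L),
    `3` = list(params = c("NPREBOT", "NBOT", "NPOP08", "TLEN", "TBOT"), k = 5L),
    `4` = list(params = c("NANC", "NPREBOT", "NBOT", "NPOP08",
                          "TLEN", "TBOT", "TCAR"), k = 7L),
    `5` = list(params = c("NPREBOT", "NBOT1", "TLEN1", "TBOT1", "NINT",
                          "NBOT2", "TLEN2", "TBOT2", "NPOP08"), k = 9L),
    `6` = list(params = c("NANC", "NPREBOT", "NBOT", "NPOP08",
                          "TLEN", "TBOT", "TCAR"), k = 7L),
    `7` = list(params = c("NANC", "NPOP08", "TCAR"), k = 3L)
  )
}

#' Construct and validate a demographic parameter vector
#'
#' @param model_id Integer 1-7, the model topology (see [model_registry()]).
#' @param ... Named parameters in haploid units (sizes) and generations
#'   (times). Exactly the parameters of the model's registry entry must be
#'   supplied.
#' @return An object of class `param_vector`.
#' @examples
#' param_vector(1, NANC = 2000)
#' param_vector(2, NPREBOT = 64000, NBOT = 1800, NPOP08 = 20000,
#'              TLEN = 2, TBOT = 12)
#' @export
param_vector <- function(model_id, ...) {
  reg <- model_registry()
  key <- as.character(as.integer(model_id))
  if (!key %in% names(reg)) stop("unknown model_id: ", model_id)
  vals <- c(...)
  want <- reg[[key]]$params
  if (!setequal(names(vals), want))
    stop("model ", key, " requires exactly parameters: ",
         paste(want, collapse = ", "))
  vals <- vals[want]
  sizes <- grepl("^N", names(vals))
  if (any(vals[sizes] <= 0)) stop("all population sizes must be > 0")
  times <- grepl("^T", names(vals))
  if (any(vals[times] <= 0)) stop("all durations/times must be > 0")
  if (all(c("TCAR", "TBOT", "TLEN") %in% names(vals)) &&
      vals[["TCAR"]] <= vals[["TBOT"]] + vals[["TLEN"]])
    stop("TCAR must exceed TBOT + TLEN")
  structure(list(model_id = as.integer(model_id), params = vals),
            class = "param_vector")
}

#' @export
print.param_vector <- function(x, ...) {
  cat("Demographic model", x$model_id, "\n")
  print(x$params)
  invisible(x)
}

#' Exponential growth rate between two sizes
#'
#' Per-generation exponential rate `ln(n_end/n_start)/duration` implied by a
#' size change from `n_start` to `n_end` over `duration` generations.
#'
#' @param n_start,n_end Positive population sizes.
#' @param duration Positive duration in generations.
#' @return Rate per generation (positive for growth).
#' @examples
#' growth_rate_between(910, 10212, 12)  # ~0.20 per generation
#' @export
growth_rate_between <- function(n_start, n_end, duration) {
  if (any(n_start <= 0) || any(n_end <= 0)) stop("sizes must be positive")
  if (any(duration <= 0)) stop("duration must be positive")
  log(n_end / n_start) / duration
}

#' Convert calendar years to generations before a reference year
#'
#' @param year Calendar year (<= `reference_year`).
#' @param reference_year Calendar year taken as time 0.
#' @param gen_time Generation time in years (> 0).
#' @return Generations before the reference year.
#' @examples
#' years_to_generations(1984, 2008, 2)  # 12
#' @export
years_to_generations <- function(year, reference_year, gen_time) {
  if (gen_time <= 0) stop("gen_time must be positive")
  if (any(year > reference_year)) stop("year must not exceed reference_year")
  (reference_year - year) / gen_time
}

#' Free-parameter count of a demographic model
#'
#' Registry default counts used for AIC; see [model_registry()].
#'
#' @param model_id Integer 1-7.
#' @return Integer count of free parameters.
#' @export
free_param_count <- function(model_id) {
  reg <- model_registry()
  key <- as.character(as.integer(model_id))
  if (!key %in% names(reg)) stop("unknown model_id: ", model_id)
  reg[[key]]$k
}

# internal: one epoch row
.epoch <- function(start, size, rate = 0) c(start = start, size = size, rate = rate)

#' Build a backward-time epoch timeline from a parameter vector
#'
#' Converts a [param_vector()] into the piecewise-exponential epoch list the
#' coalescent engine consumes. Epochs are rows `(start, size_at_start,
#' growth_rate)` in backward time with `N(t) = size * exp(rate * (t -
#' start))`; instantaneous size changes are adjacent epoch boundaries. The
#' ancestral exponential segment of models 4, 6 and 7 runs from `TCAR` back
#' to `t_anc` generations (default 10000), beyond which the size is `NANC`.
#'
#' @param params A `param_vector`.
#' @param t_anc Backward time at which the ancestral exponential segment
#'   ends (generations).
#' @return An object of class `epoch_timeline`: a numeric matrix with
#'   columns `start`, `size`, `rate`, rows ordered by `start`, the last
#'   epoch unbounded.
#' @export
build_timeline <- function(params, t_anc = .TANC_DEFAULT) {
  stopifnot(inherits(params, "param_vector"))
  p <- as.list(params$params)
  m <- params$model_id
  rows <- switch(as.character(m),
    "1" = list(.epoch(0, p$NANC)),
    "2" = list(
      .epoch(0, p$NPOP08),
      .epoch(p$TBOT, p$NBOT),
      .epoch(p$TBOT + p$TLEN, p$NPREBOT)
    ),
    "3" = list(
      .epoch(0, p$NPOP08, growth_rate_between(p$NPOP08, p$NBOT, p$TBOT)),
      .epoch(p$TBOT, p$NBOT),
      .epoch(p$TBOT + p$TLEN, p$NPREBOT)
    ),
    "4" = {
      tb <- p$TBOT + p$TLEN
      if (p$TCAR <= tb) stop("inconsistent times: TCAR <= TBOT + TLEN")
      list(
        .epoch(0, p$NPOP08),
        .epoch(p$TBOT, p$NBOT),
        .epoch(tb, p$NPREBOT),
        .epoch(p$TCAR, p$NPREBOT,
               growth_rate_between(p$NPREBOT, p$NANC, t_anc - p$TCAR)),
        .epoch(t_anc, p$NANC)
      )
    },
    "5" = {
      t2 <- p$TBOT2 + p$TLEN2              # end of recent bottleneck epoch
      t1 <- t2 + p$TBOT1                   # start of older bottleneck
      list(
        .epoch(0, p$NPOP08),
        .epoch(p$TBOT2, p$NBOT2),
        .epoch(t2, p$NINT),
        .epoch(t1, p$NBOT1),
        .epoch(t1 + p$TLEN1, p$NPREBOT)
      )
    },
    "6" = {
      tb <- p$TBOT + p$TLEN
      if (p$TCAR <= tb) stop("inconsistent times: TCAR <= TBOT + TLEN")
      list(
        .epoch(0, p$NPOP08, growth_rate_between(p$NPOP08, p$NBOT, p$TBOT)),
        .epoch(p$TBOT, p$NBOT),
        .epoch(tb, p$NPREBOT),
        .epoch(p$TCAR, p$NPREBOT,
               growth_rate_between(p$NPREBOT, p$NANC, t_anc - p$TCAR)),
        .epoch(t_anc, p$NANC)
      )
    },
    "7" = {
      if (p$TCAR >= t_anc) stop("TCAR must be below t_anc")
      list(
        .epoch(0, p$NPOP08),
        .epoch(p$TCAR, p$NPOP08,
               growth_rate_between(p$NPOP08, p$NANC, t_anc - p$TCAR)),
        .epoch(t_anc, p$NANC)
      )
    },
    stop("unknown model_id: ", m)
  )
  tl <- do.call(rbind, rows)
  rownames(tl) <- NULL
  structure(tl, class = c("epoch_timeline", "matrix", "array"))
}

#' Evaluate a timeline's haploid size at backward time t
#'
#' @param timeline An `epoch_timeline`.
#' @param t Backward time(s) in generations.
#' @return Haploid population size(s) at `t`.
#' @export
timeline_size_at <- function(timeline, t) {
  vapply(t, function(tt) {
    j <- max(which(timeline[, "start"] <= tt))
    timeline[j, "size"] * exp(timeline[j, "rate"] * (tt - timeline[j, "start"]))
  }, numeric(1))
}

#' Serial sampling specification
#'
#' Per-cohort haploid sample sizes and sampling times in generations before
#' the most recent cohort. Defaults are the three larval cohorts of the
#' study system: 26, 103 and 150 diploids sampled in 1994, 1997 and 2008,
#' with a 2-year generation (so 7 and 5.5 generations before 2008).
#'
#' @param n_haploid Integer vector of haploid sample sizes (>= 2 each... at
#'   least 2 in total).
#' @param times Numeric vector of sampling times, generations before the
#'   most recent cohort; at least one cohort must be at time 0.
#' @param labels Cohort labels.
#' @return An object of class `sample_spec`.
#' @export
sample_spec <- function(n_haploid = c(52L, 206L, 300L),
                        times = c(7, 5.5, 0),
                        labels = c("1994", "1997", "2008")) {
  if (length(n_haploid) != length(times)) stop("length mismatch")
  if (any(n_haploid < 2)) stop("each cohort needs >= 2 haploids")
  if (any(times < 0)) stop("sampling times must be >= 0")
  if (!any(times == 0)) stop("at least one cohort must be sampled at time 0")
  structure(list(n_haploid = as.integer(n_haploid), times = as.numeric(times),
                 labels = as.character(labels)),
            class = "sample_spec")
}

#' Table-style maximum-likelihood parameters for the recovery model
#'
#' Convenience constructor for the best-fitting model (model 6: ancestral
#' exponential growth, bottleneck, exponential recovery) at the reported
#' maximum-likelihood estimates, converted from diploid to haploid units:
#' NANC = 1052, NPREBOT = 32209, NBOT = 910, NPOP08 = 10212 diploids,
#' TLEN = 2, TBOT = 12 generations. `TCAR` is never reported; the default
#' here (20 generations) places the end of ancestral growth just before the
#' bottleneck.
#'
#' @param TCAR End of the ancestral size change, generations before present.
#' @return A `param_vector` for model 6 in haploid units.
#' @export
ml_params_model6 <- function(TCAR = 20) {
  param_vector(6, NANC = 2 * 1052, NPREBOT = 2 * 32209, NBOT = 2 * 910,
               NPOP08 = 2 * 10212, TLEN = 2, TBOT = 12, TCAR = TCAR)
}
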