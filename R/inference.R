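#' Parameter search ranges for the maximum-likelihood search
#'
#' Initial values are drawn log-uniformly for sizes (100 to 100,000 haploid
#' units) and `TCAR` (1 to 5000 generations), and uniformly for `TLEN`
#' (1 to 5) and `TBOT` (1 to 12). The lower limits bound the search space;
#' the upper limits constrain initialization only.
#'
#' @param wide Use the widened sensitivity ranges (`TBOT` 1-30, `TLEN`
#'   1-15).
#' @param fix_tlen `NULL`, or a value (generations) at which `TLEN` is
#'   fixed (removed from the free parameter set; the sensitivity analysis
#'   fixes it at 3).
#' @return An object of class `search_ranges`.
#' @export
search_ranges <- function(wide = FALSE, fix_tlen = NULL) {
  structure(list(
    size = c(100, 100000),
    TLEN = if (wide) c(1, 15) else c(1, 5),
    TBOT = if (wide) c(1, 30) else c(1, 12),
    TCAR = c(1, 5000),
    fix_tlen = fix_tlen
  ), class = "search_ranges")
}

# internal: range for a named parameter
.param_range <- function(name, ranges) {
  if (grepl("^N", name)) return(list(r = ranges$size, log = TRUE))
  if (grepl("^TLEN", name)) return(list(r = ranges$TLEN, log = FALSE))
  if (grepl("^TBOT", name)) return(list(r = ranges$TBOT, log = FALSE))
  if (grepl("^TCAR", name)) return(list(r = ranges$TCAR, log = TRUE))
  stop("no range for parameter ", name)
}

# internal: free parameter names of a model under the ranges (TLEN may be
# fixed by the sensitivity mode)
.free_params <- function(model_id, ranges) {
  nm <- model_registry()[[as.character(model_id)]]$params
  if (!is.null(ranges$fix_tlen)) nm <- setdiff(nm, "TLEN")
  nm
}

# internal: draw one initial parameter vector (natural scale)
.draw_init <- function(model_id, ranges) {
  nm <- .free_params(model_id, ranges)
  v <- vapply(nm, function(p) {
    pr <- .param_range(p, ranges)
    if (pr$log) exp(stats::runif(1, log(pr$r[1]), log(pr$r[2])))
    else stats::runif(1, pr$r[1], pr$r[2])
  }, numeric(1))
  # keep the epoch ordering constraint satisfiable at the start
  if (all(c("TCAR", "TBOT") %in% c(nm, if (!is.null(ranges$fix_tlen)) "TLEN"))) {
    tl <- if (!is.null(ranges$fix_tlen)) ranges$fix_tlen else v[["TLEN"]]
    tb <- v[["TBOT"]]
    lo <- max(ranges$TCAR[1], tb + tl + 0.5)
    if (v[["TCAR"]] <= tb + tl)
      v[["TCAR"]] <- exp(stats::runif(1, log(lo), log(max(ranges$TCAR[2], lo * 2))))
  }
  v
}

# internal: assemble a param_vector from free values + fixed TLEN
.assemble_params <- function(model_id, free_vals, ranges) {
  vals <- as.list(free_vals)
  if (!is.null(ranges$fix_tlen)) vals$TLEN <- ranges$fix_tlen
  do.call(param_vector, c(list(model_id = model_id), vals))
}

#' Composite log-likelihood of an observed multiSFS
#'
#' `sum_e O_e * ln p_e` over polymorphic entries, the multinomial
#' log-probability of the observed entry counts with the combinatorial
#' coefficient omitted. Observed entries absent from the expected
#' spectrum's simulated support receive the floor probability
#' `1 / (10 * n_sims)`; all probabilities used are then renormalized over
#' the union of the simulated support and the floored entries so they sum
#' to one.
#'
#' @param obs Observed-kind folded `multisfs` (counts).
#' @param exp Expected-kind folded `multisfs` (probabilities) with matching
#'   dimensions.
#' @return The composite log-likelihood (natural log, always <= 0).
#' @export
composite_loglik <- function(obs, exp) {
  if (obs$kind != "observed" || exp$kind != "expected")
    stop("need observed counts and expected probabilities")
  if (!identical(obs$dims, exp$dims)) stop("dimension mismatch")
  if (!identical(obs$folded, exp$folded)) stop("folding mismatch")
  if (is.null(exp$n_sims)) stop("expected spectrum lacks its Monte-Carlo size")
  eps <- 1 / (10 * exp$n_sims)
  m <- match(obs$index, exp$index)
  p <- exp$value[m]
  n_missing <- sum(is.na(m))
  p[is.na(m)] <- eps
  z <- 1 + eps * n_missing
  if (any(p <= 0 & obs$value > 0)) stop("zero probability at observed entry")
  sum(obs$value * (log(p) - log(z)))
}

#' Convert log10-likelihoods to natural-log likelihoods
#'
#' @param l10 Finite log10-likelihood value(s).
#' @return `l10 * ln(10)`.
#' @export
ln_from_log10 <- function(l10) {
  if (any(!is.finite(l10))) stop("input must be finite")
  l10 * log(10)
}

# internal: local direct search from a given start (natural scale), on
# log-transformed parameters, with common random numbers (one simulation
# seed reused for every evaluation). Lower bounds enforced by penalty.
# In models with a pre-bottleneck ancestral change, TCAR is optimized as
# log(TCAR - TBOT - TLEN) so the epoch-order constraint TCAR > TBOT + TLEN
# holds by construction instead of through a penalty wall.
.local_search <- function(obs, model_id, start, ranges, cfg, max_cycles,
                          sim_seed, samples) {
  nm <- names(start)
  lower <- vapply(nm, function(p) .param_range(p, ranges)$r[1], numeric(1))
  offset_tcar <- all(c("TCAR", "TBOT") %in% nm)
  tlen_of <- function(v) {
    if (!is.null(ranges$fix_tlen)) ranges$fix_tlen else v[["TLEN"]]
  }
  eval_count <- 0L
  objective <- function(theta) {
    v <- exp(theta)
    names(v) <- nm
    if (offset_tcar) {
      pen <- sum(pmax(lower[nm != "TCAR"] - v[nm != "TCAR"], 0) /
                   lower[nm != "TCAR"])
      v[nm != "TCAR"] <- pmax(v[nm != "TCAR"], lower[nm != "TCAR"])
      v[["TCAR"]] <- v[["TBOT"]] + tlen_of(v) + exp(theta[[match("TCAR", nm)]])
    } else {
      pen <- sum(pmax(lower - v, 0) / lower)
      v <- pmax(v, lower)
    }
    if ("TCAR" %in% nm && v[["TCAR"]] >= .TANC_DEFAULT * 0.99)
      v[["TCAR"]] <- .TANC_DEFAULT * 0.99
    params <- .assemble_params(model_id, v, ranges)
    eval_count <<- eval_count + 1L
    -.loglik_fast(obs, params, samples, cfg, sim_seed) + 1000 * pen
  }
  recover_par <- function(theta) {
    v <- exp(theta)
    names(v) <- nm
    if (offset_tcar) {
      v[nm != "TCAR"] <- pmax(v[nm != "TCAR"], lower[nm != "TCAR"])
      v[["TCAR"]] <- v[["TBOT"]] + tlen_of(v) + exp(theta[[match("TCAR", nm)]])
    } else {
      v <- pmax(v, lower)
    }
    if ("TCAR" %in% nm) v[["TCAR"]] <- min(v[["TCAR"]], .TANC_DEFAULT * 0.99)
    v
  }
  theta0 <- log(start)
  if (offset_tcar) {
    gap <- start[["TCAR"]] - start[["TBOT"]] - tlen_of(start)
    theta0[[match("TCAR", nm)]] <- log(max(gap, 0.5))
  }
  if (length(theta0) == 1) {
    # golden-section search in a wide window around the start (the window,
    # not the start point, is what a 1-D bracketing search uses)
    opt <- stats::optimize(function(x) objective(x),
                           interval = c(max(log(lower), theta0 - log(64)),
                                        theta0 + log(64)), tol = 1e-3)
    list(par = setNames(exp(opt$minimum), nm), lnL = -opt$objective,
         evals = eval_count)
  } else {
    opt <- stats::optim(theta0, objective, method = "Nelder-Mead",
                        control = list(maxit = max_cycles))
    list(par = recover_par(opt$par), lnL = -opt$value,
         evals = eval_count)
  }
}

#' Fit a demographic model to an observed multiSFS
#'
#' Multi-start maximum composite-likelihood search. Each restart draws
#' initial values from the [search_ranges()] distributions and runs a
#' derivative-free (Nelder-Mead) local search on log-transformed
#' parameters, re-estimating the expected spectrum (`cfg$n_sims`
#' simulations) at every evaluation with a fixed per-restart simulation
#' seed (common random numbers). Restart endpoints are then compared
#' afresh under shared higher-precision simulation seeds, the winner is
#' polished by conditional-maximization cycles, and the better of the two
#' (under the same shared seeds) is returned with its re-evaluated
#' likelihood. Lower bounds bound the search space; parameters are
#' unbounded above.
#'
#' @param obs Observed folded polymorphic `multisfs`.
#' @param model_id Model topology 1-7.
#' @param ranges A [search_ranges()].
#' @param n_restarts Number of independent restarts (50 at full fidelity).
#' @param max_cycles Cap on local-search iterations per restart (40 at
#'   full fidelity).
#' @param cfg A [sim_config()].
#' @param seed Integer seed controlling restart draws and per-restart
#'   simulation seeds.
#' @param polish After the candidate comparison, refine the winner by
#'   conditional-maximization (coordinate) cycles — one golden-section
#'   line search per parameter in turn — and keep the refinement only if
#'   it improves the shared-seed evaluation (default `TRUE`).
#' @param refine_cycles Number of coordinate cycles in the polish stage.
#' @param eval_cfg A [sim_config()] for the candidate re-evaluation
#'   (default: ten times the fitting `n_sims`, capped at 100,000).
#' @param eval_seed Base seed for the candidate re-evaluation; pass the
#'   same value to fits of different models to make their returned `lnL`
#'   directly comparable (default: derived from `seed`).
#' @param samples A [sample_spec()]; defaults to the cohort design carried
#'   by `obs`.
#' @return An object of class `fit_result` with the best `param_vector`,
#'   its composite log-likelihood `lnL`, the free-parameter count `k` and
#'   per-restart summaries.
#' @export
fit_model <- function(obs, model_id, ranges = search_ranges(),
                      n_restarts = 50L, max_cycles = 40L,
                      cfg = sim_config(), seed = 1L, polish = TRUE,
                      refine_cycles = 1L, eval_cfg = NULL, eval_seed = NULL,
                      samples = sample_spec(obs$n_haploid, obs$times, obs$labels)) {
  if (n_restarts < 1) stop("n_restarts must be >= 1")
  if (length(obs$index) == 0) stop("observed spectrum is empty")
  # per-restart seeds are a pure function of (seed, restart index) so that
  # enlarging n_restarts nests the smaller run's restarts
  init_seed <- function(r) ((seed * 7 + r * 1000003) %% 2147483646) + 1
  sim_seed <- function(r) ((seed * 11 + r * 2000003) %% 2147483646) + 1
  cand <- vector("list", n_restarts)
  log <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    set.seed(init_seed(r))
    start <- .draw_init(model_id, ranges)
    res <- .local_search(obs, model_id, start, ranges, cfg, max_cycles,
                         sim_seed(r), samples)
    log[[r]] <- data.frame(restart = r, lnL = res$lnL, evals = res$evals)
    cand[[r]] <- res
  }
  # Each candidate's search likelihood is the maximum of its own noisy
  # surface, so candidates are compared afresh under shared
  # higher-precision simulation seeds before the winner is retained.
  # Passing the same eval_seed to fits of different models makes their
  # returned lnL values directly comparable (one paired measurement).
  if (is.null(eval_cfg)) eval_cfg <- sim_config(min(10L * cfg$n_sims, 100000L))
  if (is.null(eval_seed)) eval_seed <- ((seed * 13 + 3000017) %% 2147483646) + 1
  eval_seeds <- ((eval_seed + 7919 * 1:2) %% 2147483646) + 1
  cand_lnl <- function(cd) {
    p <- .assemble_params(model_id, cd$par, ranges)
    mean(vapply(eval_seeds, function(s) {
      .loglik_fast(obs, p, samples, eval_cfg, s)
    }, numeric(1)))
  }
  relnl <- vapply(cand, cand_lnl, numeric(1))
  best <- cand[[which.max(relnl)]]
  best$lnL <- max(relnl)
  # polish: conditional-maximization (coordinate) cycles from the winner,
  # kept only if it improves the shared-seed evaluation
  if (polish && length(best$par) > 1) {
    ref <- .coord_refine(obs, model_id, best$par, ranges, cfg,
                         cycles = refine_cycles, sim_seed = sim_seed(0),
                         samples = samples)
    ref_lnl <- cand_lnl(ref)
    if (ref_lnl > best$lnL) {
      best <- list(par = ref$par, lnL = ref_lnl, evals = NA_integer_)
    }
  }
  k <- length(.free_params(model_id, ranges))
  structure(list(model_id = as.integer(model_id),
                 params = .assemble_params(model_id, best$par, ranges),
                 lnL = best$lnL, k = k,
                 restarts = do.call(rbind, log),
                 ranges = ranges, cfg = cfg, seed = seed,
                 eval_cfg = eval_cfg, eval_seeds = eval_seeds,
                 samples = samples),
            class = "fit_result")
}

#' Refine the contending fits by conditional maximization
#'
#' Applies coordinate (conditional-maximization) refinement cycles to every
#' fit whose AIC lies within `within` units of the provisional best, keeps
#' each refinement only if it improves that fit's shared-seed evaluated
#' likelihood, and returns the updated fits. Models far behind the leader
#' cannot change the selection and are left untouched, which concentrates
#' search effort where it matters.
#'
#' @param fits List of [fit_model()] results on the same observed spectrum.
#' @param obs The observed folded `multisfs` the fits were made on.
#' @param cycles Coordinate cycles per refined fit.
#' @param within AIC window (relative to the provisional best) defining
#'   the contenders.
#' @return The list of fits with contenders refined in place.
#' @export
refine_fits <- function(fits, obs, cycles = 2L, within = 40) {
  tab <- select_model(fits)
  ids <- vapply(fits, `[[`, 0L, "model_id")
  contenders <- tab$model_id[tab$dAIC <= within]
  for (m in contenders) {
    i <- which(ids == m)
    f <- fits[[i]]
    free <- .free_params(f$model_id, f$ranges)
    if (length(free) < 2) next
    ref <- .coord_refine(obs, f$model_id, f$params$params[free], f$ranges,
                         f$cfg, cycles = cycles,
                         sim_seed = ((f$seed * 23 + 5000011) %% 2147483646) + 1,
                         samples = f$samples)
    ref_lnl <- mean(vapply(f$eval_seeds, function(s) {
      .loglik_fast(obs, .assemble_params(f$model_id, ref$par, f$ranges),
                   f$samples, f$eval_cfg, s)
    }, numeric(1)))
    if (ref_lnl > f$lnL) {
      f$params <- .assemble_params(f$model_id, ref$par, f$ranges)
      f$lnL <- ref_lnl
      fits[[i]] <- f
    }
  }
  fits
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result: model %d, lnL = %.3f (k = %d, %d restart(s))\n",
              x$model_id, x$lnL, x$k, nrow(x$restarts)))
  print(round(x$params$params, 3))
  invisible(x)
}

#' Select among fitted models by AIC
#'
#' `AIC = 2k - 2 lnL` with natural-log composite likelihoods; ties broken
#' in favour of the smaller `k` (parsimony).
#'
#' @param fits List of [fit_model()] results with distinct `model_id`s.
#' @param k Optional named numeric vector overriding the free-parameter
#'   counts (names = model ids).
#' @return A `model_selection` data frame with columns `model_id`, `k`,
#'   `lnL`, `AIC`, `dAIC`, ordered best first; the selected model id is in
#'   `attr(, "best")`.
#' @export
select_model <- function(fits, k = NULL) {
  if (length(fits) == 0) stop("no fits supplied")
  ids <- vapply(fits, function(f) f$model_id, integer(1))
  if (anyDuplicated(ids)) stop("duplicate model_id in fits")
  kk <- vapply(fits, function(f) f$k, numeric(1))
  if (!is.null(k)) {
    m <- match(as.character(ids), names(k))
    kk[!is.na(m)] <- k[m[!is.na(m)]]
  }
  lnL <- vapply(fits, function(f) f$lnL, numeric(1))
  aic <- 2 * kk - 2 * lnL
  o <- order(aic, kk)
  tab <- data.frame(model_id = ids[o], k = kk[o], lnL = lnL[o],
                    AIC = aic[o], dAIC = aic[o] - min(aic))
  class(tab) <- c("model_selection", "data.frame")
  attr(tab, "best") <- tab$model_id[1]
  tab
}

# internal: ECM-style coordinate refinement. Starting from a parameter
# vector, cycles through the free parameters and maximizes each in turn by
# a 1-D golden-section search on its log (TCAR on the log of its offset
# above TBOT + TLEN), holding the others fixed, on the common-random-
# number surface given by sim_seed. Mirrors conditional-maximization
# cycles and converges on ridges where a simplex stalls.
.coord_refine <- function(obs, model_id, par, ranges, cfg, cycles,
                          sim_seed, samples, window = 8) {
  nm <- names(par)
  lower <- vapply(nm, function(p) .param_range(p, ranges)$r[1], numeric(1))
  offset_tcar <- all(c("TCAR", "TBOT") %in% nm)
  tlen_of <- function(v) {
    if (!is.null(ranges$fix_tlen)) ranges$fix_tlen else v[["TLEN"]]
  }
  value <- function(v) {
    params <- .assemble_params(model_id, v, ranges)
    .loglik_fast(obs, params, samples, cfg, sim_seed)
  }
  best_lnl <- value(par)
  for (cyc in seq_len(cycles)) {
    for (p in nm) {
      cur <- par
      if (offset_tcar && p == "TCAR") {
        gap0 <- max(par[["TCAR"]] - par[["TBOT"]] - tlen_of(par), 0.25)
        f <- function(lg) {
          cur[["TCAR"]] <- min(par[["TBOT"]] + tlen_of(par) + exp(lg),
                               .TANC_DEFAULT * 0.99)
          -value(cur)
        }
        o <- stats::optimize(f, c(log(gap0) - log(window),
                                  log(gap0) + log(window)), tol = 0.05)
        cand <- par
        cand[["TCAR"]] <- min(par[["TBOT"]] + tlen_of(par) + exp(o$minimum),
                              .TANC_DEFAULT * 0.99)
      } else {
        clampp <- function(x) {
          x <- max(x, lower[[p]])
          if (p == "TCAR") x <- min(x, .TANC_DEFAULT * 0.99)
          x
        }
        f <- function(lg) {
          cur[[p]] <- clampp(exp(lg))
          if (offset_tcar && p %in% c("TBOT", "TLEN")) {
            # keep the ancestral-change boundary above the bottleneck
            cur[["TCAR"]] <- max(cur[["TCAR"]],
                                 cur[["TBOT"]] + tlen_of(cur) + 0.25)
          }
          -value(cur)
        }
        o <- stats::optimize(f, c(max(log(par[[p]]) - log(window),
                                      log(lower[[p]])),
                                  log(par[[p]]) + log(window)), tol = 0.05)
        cand <- par
        cand[[p]] <- clampp(exp(o$minimum))
        if (offset_tcar && p %in% c("TBOT", "TLEN")) {
          cand[["TCAR"]] <- max(cand[["TCAR"]],
                                cand[["TBOT"]] + tlen_of(cand) + 0.25)
        }
      }
      cand_lnl <- -o$objective
      if (cand_lnl > best_lnl) { par <- cand; best_lnl <- cand_lnl }
    }
  }
  list(par = par, lnL = best_lnl)
}
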