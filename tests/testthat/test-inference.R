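test_that("composite log-likelihood matches hand arithmetic", {
  n_hap <- c(4L, 4L)
  obs1 <- multisfs(rbind(c(1, 0)), 5, n_hap, kind = "observed", folded = TRUE)
  exp1 <- multisfs(rbind(c(1, 0)), 1, n_hap, kind = "expected", folded = TRUE,
                   n_sims = 1000)
  expect_equal(composite_loglik(obs1, exp1), 0)
  # 3 loci split over 2 entries with p = 0.5 each
  obs2 <- multisfs(rbind(c(1, 0), c(0, 1)), c(2, 1), n_hap,
                   kind = "observed", folded = TRUE)
  exp2 <- multisfs(rbind(c(1, 0), c(0, 1)), c(0.5, 0.5), n_hap,
                   kind = "expected", folded = TRUE, n_sims = 1000)
  expect_equal(composite_loglik(obs2, exp2), 3 * log(0.5), tolerance = 1e-12)
  expect_error(composite_loglik(obs2, obs2), "observed counts and expected")
})

test_that("composite log-likelihood equals the multinomial log-pmf oracle", {
  set.seed(21)
  for (rep in 1:20) {
    k <- sample(3:6, 1)
    ent <- cbind(sample(0:5, k), sample(0:5, k))
    O <- rpois(k, 4) + 1
    p <- runif(k); p <- p / sum(p)
    obs <- multisfs(ent, O, c(10L, 10L), kind = "observed", folded = TRUE)
    ex <- multisfs(ent, p, c(10L, 10L), kind = "expected", folded = TRUE,
                   n_sims = 1e6)
    # oracle: dmultinom minus its log coefficient, aligned to stored order
    o <- order(serialSFS:::entries_to_index(ent, c(11L, 11L)))
    lhs <- composite_loglik(obs, ex)
    log_coef <- lgamma(sum(O) + 1) - sum(lgamma(O + 1))
    rhs <- dmultinom(O[o], prob = p[o], log = TRUE) - log_coef
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
})

test_that("log10 likelihoods convert to natural logs", {
  expect_equal(ln_from_log10(0), 0)
  expect_equal(ln_from_log10(1), 2.302585, tolerance = 1e-6)
  expect_equal(ln_from_log10(-100), -230.2585, tolerance = 1e-4)
  expect_error(ln_from_log10(Inf), "finite")
})

test_that("empirical frequencies bound any model's composite likelihood", {
  set.seed(33)
  for (rep in 1:100) {
    k <- sample(2:12, 1)
    ent <- unique(cbind(sample(0:8, k, TRUE), sample(0:8, k, TRUE)))
    O <- rpois(nrow(ent), 3) + 1
    obs <- multisfs(ent, O, c(16L, 16L), kind = "observed", folded = TRUE)
    emp <- sfs_as_expected(obs)
    q <- runif(length(obs$value)); q <- q / sum(q)
    model <- obs; model$kind <- "expected"; model$value <- q
    model$n_sims <- 1e6
    expect_gte(composite_loglik(obs, emp) + 1e-9,
               composite_loglik(obs, model))
  }
})

test_that("AIC selection orders models and breaks ties by parsimony", {
  mkfit <- function(id, k, lnL) {
    structure(list(model_id = id, k = k, lnL = lnL), class = "fit_result")
  }
  tab <- select_model(list(mkfit(6L, 7, -100), mkfit(2L, 5, -110)))
  expect_equal(tab$AIC, c(214, 230))
  expect_equal(tab$dAIC, c(0, 16))
  expect_equal(attr(tab, "best"), 6L)
  # equal lnL: smaller k wins
  tab2 <- select_model(list(mkfit(4L, 5, -50), mkfit(7L, 3, -50)))
  expect_equal(attr(tab2, "best"), 7L)
  # three models against hand computation
  tab3 <- select_model(list(mkfit(1L, 1, -120), mkfit(2L, 5, -100),
                            mkfit(3L, 5, -99)))
  expect_equal(tab3$model_id, c(3L, 2L, 1L))
  expect_equal(tab3$AIC, c(208, 210, 242))
  expect_equal(tab3$dAIC, c(0, 2, 34))
  expect_error(select_model(list()), "no fits")
  expect_error(select_model(list(mkfit(1L, 1, -1), mkfit(1L, 1, -2))),
               "duplicate")
})

test_that("search ranges widen and TLEN can be fixed", {
  r <- search_ranges()
  expect_equal(r$TLEN, c(1, 5))
  expect_equal(r$TBOT, c(1, 12))
  rw <- search_ranges(wide = TRUE)
  expect_equal(rw$TLEN, c(1, 15))
  expect_equal(rw$TBOT, c(1, 30))
  # fixing TLEN removes it from the free set; k drops by one
  rf <- search_ranges(fix_tlen = 3)
  expect_false("TLEN" %in% serialSFS:::.free_params(6, rf))
  expect_equal(length(serialSFS:::.free_params(6, rf)),
               free_param_count(6) - 1L)
})

test_that("initial draws respect the prescribed ranges", {
  set.seed(8)
  r <- search_ranges()
  for (i in 1:50) {
    v <- serialSFS:::.draw_init(6, r)
    expect_true(all(v[c("NANC", "NPREBOT", "NBOT", "NPOP08")] >= 100))
    expect_true(all(v[c("NANC", "NPREBOT", "NBOT", "NPOP08")] <= 1e5))
    expect_true(v[["TLEN"]] >= 1 && v[["TLEN"]] <= 5)
    expect_true(v[["TBOT"]] >= 1 && v[["TBOT"]] <= 12)
    expect_true(v[["TCAR"]] > v[["TBOT"]] + v[["TLEN"]])
  }
})

test_that("model fitting recovers a strong bottleneck signal", {
  # a two-size history fitted under its own model: the fitted bottleneck
  # depth ratio should approach the truth within the noise of a reduced
  # search (small design keeps this fast)
  ss <- small_design()
  truth <- param_vector(2, NPREBOT = 40000, NBOT = 400, NPOP08 = 10000,
                        TLEN = 3, TBOT = 5)
  obs <- simulate_observed_sfs(truth, ss, L = 1000, sim_config(50000),
                               seed = 60)
  f <- fit_model(obs, 2, n_restarts = 3, max_cycles = 40,
                 cfg = sim_config(5000), seed = 61)
  expect_s3_class(f, "fit_result")
  expect_lte(f$lnL, 0)
  expect_true(is.finite(f$lnL))
  # the fitted history must be a deep decline (ratio within an order of
  # magnitude of the truth 0.01)
  r <- f$params$params[["NBOT"]] / f$params$params[["NPREBOT"]]
  expect_lt(r, 0.1)
  # likelihood at the truth does not beat the optimum by more than noise
  lt <- serialSFS:::.loglik_fast(obs, truth, ss, sim_config(5000), 991)
  expect_gt(f$lnL, lt - 30)
})

test_that("fixing TLEN removes it from the fit and reduces k", {
  ss <- small_design()
  truth <- param_vector(2, NPREBOT = 20000, NBOT = 500, NPOP08 = 8000,
                        TLEN = 3, TBOT = 5)
  obs <- simulate_observed_sfs(truth, ss, L = 300, sim_config(10000),
                               seed = 70)
  f <- fit_model(obs, 2, ranges = search_ranges(fix_tlen = 3),
                 n_restarts = 1, max_cycles = 10, cfg = sim_config(2000),
                 seed = 71)
  expect_equal(f$k, 4L)
  expect_equal(f$params$params[["TLEN"]], 3)
})

test_that("more restarts never lower the returned likelihood", {
  ss <- small_design()
  obs <- simulate_observed_sfs(param_vector(1, NANC = 3000), ss, L = 200,
                               sim_config(5000), seed = 80)
  f2 <- fit_model(obs, 2, n_restarts = 2, max_cycles = 10,
                  cfg = sim_config(2000), seed = 81, polish = FALSE)
  f4 <- fit_model(obs, 2, n_restarts = 4, max_cycles = 10,
                  cfg = sim_config(2000), seed = 81, polish = FALSE)
  expect_gte(f4$lnL, f2$lnL)
})

test_that("contender refinement never worsens a fit's evaluated likelihood", {
  ss <- small_design()
  truth <- param_vector(2, NPREBOT = 10000, NBOT = 300, NPOP08 = 3000,
                        TLEN = 3, TBOT = 3)
  obs <- simulate_observed_sfs(truth, ss, L = 400, sim_config(5000),
                               seed = 130)
  fits <- lapply(c(1, 2), function(m)
    fit_model(obs, m, n_restarts = 2, max_cycles = 10, polish = FALSE,
              cfg = sim_config(1500), seed = 130 + m,
              eval_cfg = sim_config(8000), eval_seed = 131))
  before <- vapply(fits, `[[`, 0, "lnL")
  ref <- refine_fits(fits, obs, cycles = 1, within = 1000)
  after <- vapply(ref, `[[`, 0, "lnL")
  expect_true(all(after >= before))
  # model ids and structure preserved
  expect_equal(vapply(ref, `[[`, 0L, "model_id"), c(1L, 2L))
  expect_s3_class(select_model(ref), "model_selection")
})
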