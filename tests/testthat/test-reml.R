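ctl <- reml_control()

test_that("REML equals the closed-form ANOVA estimator on balanced one-way layouts", {
  for (seed in c(1, 7, 23)) {
    d <- oneway_data(g = 15, r = 4, vg = 1.2, ve = 0.6, seed = seed)
    spec <- model_spec("y", fixed = character(), random = "line",
                       scope = "single_environment")
    fit <- fit_reml(d, spec, ctl)
    oracle <- oneway_anova_components(d$y, factor(d$line_id), r = 4)
    expect_equal(fit$components$variance, oracle$sigma2_g, tolerance = 1e-8)
    expect_equal(fit$residual, oracle$sigma2_e, tolerance = 1e-8)
  }
})

test_that("REML equals the closed-form estimators on balanced two-way layouts", {
  set.seed(5)
  g <- 12; e <- 3; r <- 3
  grid <- expand.grid(gen = sprintf("G%02d", 1:g),
                      env = sprintf("E%d", 1:e), rep = 1:r)
  ge <- rnorm(g * e, 0, sqrt(0.8))
  names(ge) <- paste(rep(sprintf("G%02d", 1:g), e),
                     rep(sprintf("E%d", 1:e), each = g))
  grid$y <- rnorm(g, 0, sqrt(1.5))[as.integer(factor(grid$gen))] +
    c(E1 = 0.5, E2 = -0.2, E3 = 0)[grid$env] +
    ge[paste(grid$gen, grid$env)] + rnorm(nrow(grid), 0, sqrt(0.5))
  d <- tibble::tibble(
    environment = as.character(grid$env), regime = "drought",
    replicate = grid$rep, block = "B1",
    entry_id = as.character(grid$gen), entry_kind = "testcross",
    line_id = as.character(grid$gen), tester_id = "T1", y = grid$y
  )
  spec <- model_spec("y", fixed = "env", random = c("line", "line:env"))
  fit <- fit_reml(d, spec, ctl)
  oracle <- twoway_anova_components(d$y, factor(d$line_id),
                                    factor(d$environment), r = r)
  got <- setNames(fit$components$variance, fit$components$term)
  expect_equal(unname(got["line"]), oracle$sigma2_g, tolerance = 1e-8)
  expect_equal(unname(got["line:env"]), oracle$sigma2_ge, tolerance = 1e-8)
  expect_equal(fit$residual, oracle$sigma2_e, tolerance = 1e-8)
})

test_that("a constant response pins all components to the boundary", {
  d <- oneway_data(g = 6, r = 2)
  d$y <- 3.5
  spec <- model_spec("y", random = "line", scope = "single_environment")
  fit <- fit_reml(d, spec)
  expect_equal(fit$components$variance, 0)
  expect_lt(fit$residual, 1e-10)
  expect_match(fit$note, "degenerate")
})

test_that("estimates are invariant to row permutation and level relabelling", {
  d <- oneway_data(g = 10, r = 3, seed = 3)
  spec <- model_spec("y", random = "line", scope = "single_environment")
  fit1 <- fit_reml(d, spec, ctl)
  set.seed(99)
  fit2 <- fit_reml(d[sample(nrow(d)), ], spec, ctl)
  # row order only perturbs floating-point summation order
  expect_equal(fit1$components$variance, fit2$components$variance,
               tolerance = 1e-7)
  expect_equal(fit1$logLik, fit2$logLik, tolerance = 1e-9)
  relab <- d
  relab$line_id <- paste0("zz_", relab$line_id)
  relab$entry_id <- relab$line_id
  fit3 <- fit_reml(relab, spec, ctl)
  expect_equal(sort(fit1$ranef$line$blup), sort(fit3$ranef$line$blup),
               tolerance = 1e-8)
  expect_equal(fit1$components$variance, fit3$components$variance,
               tolerance = 1e-10)
})

test_that("BLUPs of a balanced random term sum to zero", {
  d <- oneway_data(g = 14, r = 3, seed = 11)
  spec <- model_spec("y", random = "line", scope = "single_environment")
  fit <- fit_reml(d, spec, ctl)
  expect_equal(sum(fit$ranef$line$blup), 0, tolerance = 1e-8)
})

test_that("the genotype model drops the GxE term for a single environment", {
  sim <- simulate_trial(sim_config(
    regime = "drought", n_lines = c(A = 4, B = 6), n_env = 1,
    block_size = 10, n_checks = 2, traits = "GY", seed = 2
  ))
  expect_warning(fit <- fit_genotype_model(sim$data, "GY", ctl),
                 "Single environment")
  expect_false("genotype:env" %in% fit$components$term)
  expect_true("genotype" %in% fit$components$term)
})

test_that("line-by-tester fits exclude checks and carry the declared terms", {
  sim <- simulate_trial(sim_config(
    regime = "drought", n_lines = c(A = 5, B = 7), n_env = 2,
    block_size = 10, n_checks = 2, traits = "GY", seed = 4
  ))
  expect_message(fit <- fit_lxt_across_env(sim$data, "GY", ctl), "check")
  expect_setequal(
    fit$components$term,
    c("block%in%rep%in%env", "line", "tester", "line:tester",
      "line:env", "tester:env", "line:tester:env")
  )
  expect_equal(fit$nobs, 12 * 3 * 2 * 2) # testcross plots only
  one_env <- dplyr::filter(sim$data, environment == "E1")
  fit1 <- suppressMessages(fit_lxt_single_env(one_env, "GY", ctl))
  expect_setequal(fit1$components$term,
                  c("block%in%rep", "line", "tester", "line:tester"))
  expect_error(fit_lxt_single_env(sim$data, "GY"), "exactly one environment")
  expect_error(fit_lxt_across_env(one_env, "GY"), "at least two")
})

test_that("near-noise-free line-by-tester data recover the injected effect variances", {
  set.seed(8)
  lines <- sprintf("L%02d", 1:8)
  testers <- sprintf("T%d", 1:4)
  g <- rnorm(8, 0, 1.4)
  t <- rnorm(4, 0, 0.7)
  d <- expand.grid(line_id = lines, tester_id = testers, replicate = 1:2,
                   stringsAsFactors = FALSE)
  d$y <- 10 + g[match(d$line_id, lines)] + t[match(d$tester_id, testers)] +
    rnorm(nrow(d), 0, 1e-4)
  d <- tibble::tibble(
    environment = "E1", regime = "drought", replicate = d$replicate,
    block = "B1", entry_id = paste(d$line_id, d$tester_id, sep = ":"),
    entry_kind = "testcross", line_id = d$line_id, tester_id = d$tester_id,
    y = d$y
  )
  fit <- fit_lxt_single_env(d, "y", ctl)
  got <- setNames(fit$components$variance, fit$components$term)
  # REML on a complete factorial recovers the sample variance of the
  # injected effects up to the df convention (the SCA component sits at the
  # zero boundary, which perturbs the other components slightly)
  expect_equal(unname(got["line"]), var(g), tolerance = 0.1)
  expect_equal(unname(got["tester"]), var(t), tolerance = 0.1)
  expect_lt(unname(got["line:tester"]), 1e-4)
})

test_that("a zero SCA variance concentrates at the boundary", {
  # with a true variance of zero the REML estimate lies exactly on the
  # boundary in about half the realisations and close to it otherwise
  v_sca <- sapply(seq_len(100), function(s) {
    sim <- simulate_trial(sim_config(
      regime = "drought", n_lines = c(A = 5, B = 5), n_env = 1,
      n_rep = 2, block_size = 12, n_checks = 0, traits = "GY",
      variance_overrides = list(GY = c(sca = 0)), seed = 1000 + s
    ))
    fit <- suppressMessages(fit_lxt_single_env(sim$data, "GY", ctl))
    fit$components$variance[fit$components$term == "line:tester"]
  })
  expect_gte(mean(v_sca < 1e-6), 0.45)
  expect_equal(median(v_sca), 0)
  # departures from the boundary stay well below the residual variance
  expect_lt(mean(v_sca), 0.15 * 1.01)
})

test_that("the boundary-mixture LRT behaves at its edge cases", {
  d <- oneway_data(g = 12, r = 3, seed = 21)
  spec <- model_spec("y", random = "line", scope = "single_environment")
  full <- fit_reml(d, spec, ctl)
  expect_equal(lrt_variance_component(full, full)$statistic, 0)
  expect_equal(lrt_variance_component(full, full)$p_value, 1)

  reduced <- fit_reml(d, model_spec("y", random = character(),
                                    scope = "single_environment"), ctl)
  res <- lrt_variance_component(full, reduced)
  expect_gt(res$statistic, 0)
  expect_lt(res$p_value, 1)

  # invariance to positive rescaling of the response
  d2 <- d
  d2$y <- 7.3 * d2$y
  full2 <- fit_reml(d2, spec, ctl)
  red2 <- fit_reml(d2, model_spec("y", random = character(),
                                  scope = "single_environment"), ctl)
  res2 <- lrt_variance_component(full2, red2)
  expect_equal(res2$statistic, res$statistic, tolerance = 1e-6)

  # non-nested specifications are a usage error
  other <- fit_reml(d, model_spec("y", random = "rep",
                                  scope = "single_environment"), ctl)
  expect_error(lrt_variance_component(full, other), "exactly one")
})

test_that("drop-one component tests cover every random term", {
  sim <- simulate_trial(sim_config(
    regime = "drought", n_lines = c(A = 4, B = 4), n_env = 2,
    block_size = 8, n_checks = 0, traits = "GY", seed = 6
  ))
  fit <- suppressMessages(fit_lxt_across_env(sim$data, "GY", ctl))
  tab <- suppressMessages(test_variance_components(
    dplyr::filter(sim$data, entry_kind == "testcross"), fit, ctl))
  expect_setequal(tab$term, fit$spec$random)
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
})

test_that("adjusted entry means equal raw means on a balanced complete block design", {
  sim <- simulate_trial(sim_config(
    regime = "drought", n_lines = c(A = 4, B = 4), n_env = 2,
    block_size = 1000, # one block per replicate -> RCBD
    n_checks = 2, traits = "GY", block_var_frac = 0, seed = 9
  ))
  adj <- entry_blues(sim$data, "GY", method = "adjusted")
  raw <- entry_blues(sim$data, "GY", method = "raw")
  expect_equal(adj$blue, raw$blue, tolerance = 1e-8)
  expect_true(is.finite(attr(adj, "sed")))
  expect_gt(attr(adj, "sigma2"), 0)
  expect_equal(adj$n_plots, rep(4L, nrow(adj)))
})

test_that("fits are serialised to JSON losslessly enough to re-read", {
  d <- oneway_data(g = 6, r = 2, seed = 13)
  fit <- fit_reml(d, model_spec("y", random = "line",
                                scope = "single_environment"), ctl)
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$logLik, fit$logLik, tolerance = 1e-10)
  expect_equal(back$components$variance, fit$components$variance,
               tolerance = 1e-10)
})
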