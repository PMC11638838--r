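sim_small <- simulate_trial(sim_config(
  regime = "drought", n_lines = c(A = 8, B = 10), n_env = 2,
  block_size = 12, n_checks = 3, traits = c("GY", "AD", "SD", "ASI"),
  seed = 17
))
report <- suppressMessages(suppressWarnings(run_full_analysis(
  sim_small$data, plan = sim_small$plan, traits = c("GY", "ASI"),
  do_lrt = TRUE, do_loo = TRUE
)))

test_that("the report covers every stage for every analysed trait", {
  for (tr in c("GY", "ASI")) {
    gc <- dplyr::filter(report$genotype_components, trait == tr)
    expect_setequal(gc$term, c("block%in%rep%in%env", "genotype",
                               "genotype:env", "residual"))
    lx <- dplyr::filter(report$variance_components, trait == tr)
    expect_setequal(lx$term, c("block%in%rep%in%env", "line", "tester",
                               "line:tester", "line:env", "tester:env",
                               "line:tester:env", "residual"))
    expect_true(tr %in% report$baker$trait)
    expect_true(tr %in% report$prediction$trait)
    expect_true(!is.null(report$combining$drought[[tr]]))
  }
  expect_true("drought" %in% names(report$correlations))
})

test_that("reported heritability and CV are consistent with the report's own components", {
  for (tr in c("GY", "ASI")) {
    gc <- dplyr::filter(report$genotype_components, trait == tr)
    v <- setNames(gc$variance, gc$term)
    row <- dplyr::filter(report$trait_summary, trait == tr)
    expect_equal(
      row$heritability,
      heritability_broad(v[["genotype"]], v[["genotype:env"]],
                         v[["residual"]], row$n_env, row$n_rep)
    )
    expect_equal(row$cv_pct, cv_percent(v[["residual"]], row$grand_mean))
    lx <- dplyr::filter(report$variance_components, trait == tr)
    lv <- setNames(lx$variance, lx$term)
    bk <- dplyr::filter(report$baker, trait == tr)
    expect_equal(
      bk$bakers_ratio,
      suppressWarnings(bakers_ratio(lv[["line"]], lv[["tester"]],
                                    lv[["line:tester"]]))
    )
  }
})

test_that("two runs on the same input are identical", {
  rep2 <- suppressMessages(suppressWarnings(run_full_analysis(
    sim_small$data, plan = sim_small$plan, traits = c("GY", "ASI"),
    do_lrt = TRUE, do_loo = TRUE
  )))
  expect_identical(report$trait_summary, rep2$trait_summary)
  expect_identical(report$variance_components, rep2$variance_components)
  expect_identical(report$prediction, rep2$prediction)
})

test_that("contributions in the report sum to 100 per trait", {
  sums <- rowSums(as.matrix(
    report$contributions[, c("line", "tester", "line_x_tester")]
  ))
  expect_equal(unname(sums), rep(100, nrow(report$contributions)))
})

test_that("entry ranking obeys the trait order and ASI tie-break", {
  em <- tibble::tibble(
    entry_id = c("H1", "H2", "H3", "H4", "CHK1"),
    entry_kind = c(rep("testcross", 4), "check"),
    GY = c(5, 7, 7, 4, 6), ASI = c(1, 3, 0.5, 2, 1)
  )
  ranked <- top_entries(em, k = 10, trait = "GY")
  # equal GY 7: the lower-ASI entry comes first
  expect_equal(ranked$entry_id[1:2], c("H3", "H2"))
  # checks appended unranked
  expect_equal(ranked$entry_id[nrow(ranked)], "CHK1")
  expect_true(is.na(ranked$rank[nrow(ranked)]))
  # full ranking is stable and complete
  expect_equal(sum(ranked$entry_kind == "testcross"), 4)
  expect_error(top_entries(em, trait = "XX"), "Unknown trait")
})

test_that("a dominant simulated hybrid ranks first", {
  sim <- simulate_trial(sim_config(
    regime = "drought", n_lines = c(A = 4, B = 4), n_env = 2,
    n_checks = 0, block_size = 8, traits = c("GY", "AD", "SD", "ASI"),
    seed = 30
  ))
  best <- sim$truth$entry_value$entry_id[which.max(sim$truth$entry_value$GY)]
  d <- sim$data
  d$GY[d$entry_id == best] <- d$GY[d$entry_id == best] + 50 # dominate noise
  em <- entry_blues(d, "GY")
  ranked <- top_entries(em |> dplyr::rename(GY = blue), k = 5, trait = "GY")
  expect_equal(ranked$entry_id[1], best)
})

test_that("reports serialise to CSV and JSON and round-trip key numbers", {
  dir <- withr::local_tempdir()
  write_report(report, dir)
  expect_true(file.exists(file.path(dir, "trait_summary.csv")))
  expect_true(file.exists(file.path(dir, "bakers_ratio.csv")))
  back <- readr::read_csv(file.path(dir, "trait_summary.csv"),
                          show_col_types = FALSE)
  expect_equal(back$heritability, report$trait_summary$heritability,
               tolerance = 1e-9)
  js <- jsonlite::read_json(file.path(dir, "summary.json"),
                            simplifyVector = TRUE)
  expect_equal(js$baker$bakers_ratio, report$baker$bakers_ratio,
               tolerance = 1e-9)
})

test_that("autoplot methods return ggplot objects", {
  expect_s3_class(autoplot(report$correlations$drought), "ggplot")
  expect_s3_class(autoplot(report$combining$drought$GY), "ggplot")
  cv <- suppressWarnings(loo_gca_cv(
    dplyr::filter(report$entry_means, entry_kind == "testcross") |>
      dplyr::rename(blue = GY),
    value = "blue"
  ))
  expect_s3_class(autoplot(cv), "ggplot")
  expect_s3_class(plot_trait_distributions(sim_small$data), "ggplot")
})
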