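test_that("heritability reproduces the reference worked examples", {
  expect_equal(round(heritability_broad(0.06, 0.28, 0.50, 3, 2), 2), 0.25)
  expect_equal(round(heritability_broad(4.71, 0.97, 2.90, 3, 2), 2), 0.85)
  expect_equal(heritability_broad(1.7, 0, 0, 4, 2), 1)
  expect_equal(heritability_broad(0, 0.3, 0.6, 4, 2), 0)
  expect_warning(h <- heritability_broad(0, 0, 0, 3, 2), "undefined")
  expect_true(is.na(h))
})

test_that("heritability is monotone in environments, replications and genetic variance", {
  base <- heritability_broad(0.5, 0.4, 0.8, 3, 2)
  expect_gt(heritability_broad(0.5, 0.4, 0.8, 6, 2), base)
  expect_gt(heritability_broad(0.5, 0.4, 0.8, 3, 4), base)
  expect_gt(heritability_broad(0.9, 0.4, 0.8, 3, 2), base)
  # vectorised over components
  expect_length(heritability_broad(c(0.1, 0.2), c(0.1, 0.1), c(1, 1), 3, 2), 2)
})

test_that("Baker's ratio reproduces the reference worked examples", {
  expect_equal(round(bakers_ratio(6.18, 0.06, 0.09), 2), 0.99)
  expect_equal(bakers_ratio(1.3, 0.2, 0), 1)
  expect_equal(bakers_ratio(0.5, 0.5, 2), 0.5)
  expect_warning(b <- bakers_ratio(0, 0, 0), "undefined")
  expect_true(is.na(b))
})

test_that("Baker's ratio is scale invariant", {
  for (k in c(0.01, 1, 250)) {
    expect_equal(bakers_ratio(0.36 * k, 0.02 * k, 0.09 * k),
                 bakers_ratio(0.36, 0.02, 0.09))
  }
})

test_that("proportional contributions sum to 100 and match hand arithmetic", {
  pc <- proportional_contribution(0.36, 0, 0)
  expect_equal(unlist(pc), c(line = 100, tester = 0, line_x_tester = 0))
  pc2 <- proportional_contribution(1, 1, 2)
  expect_equal(unlist(pc2), c(line = 25, tester = 25, line_x_tester = 50))
  # hand arithmetic on a 0.228 / 0.015 / 0.01 split
  pc3 <- proportional_contribution(0.228, 0.015, 0.01)
  expect_equal(round(unlist(pc3), 1),
               c(line = 90.1, tester = 5.9, line_x_tester = 4.0))
  expect_equal(rowSums(as.matrix(pc3)), 100)
})

test_that("a purely additive complete table yields zero SCA and marginal-mean GCA", {
  lines <- c("A", "B", "C")
  testers <- c("X", "Y")
  g <- c(A = -1, B = 0.25, C = 0.75)
  t <- c(X = 0.5, Y = -0.5)
  tbl <- expand.grid(line_id = lines, tester_id = testers,
                     stringsAsFactors = FALSE)
  tbl$blue <- 10 + g[tbl$line_id] + t[tbl$tester_id]
  ca <- estimate_gca_sca(tbl, value = "blue")
  expect_equal(ca$grand_mean, 10)
  expect_equal(setNames(ca$gca_line$effect, ca$gca_line$line_id), g,
               tolerance = 1e-12)
  expect_equal(setNames(ca$gca_tester$effect, ca$gca_tester$tester_id), t,
               tolerance = 1e-12)
  expect_equal(ca$sca$effect, rep(0, 6), tolerance = 1e-12)
  # textbook marginal-mean formulas on the complete factorial
  marg <- tapply(tbl$blue, tbl$line_id, mean) - mean(tbl$blue)
  expect_equal(setNames(ca$gca_line$effect, ca$gca_line$line_id),
               c(marg[names(g)]), tolerance = 1e-12)
})

test_that("the estimator matches the bordered normal-equations oracle on incomplete plans", {
  plan <- small_plan()
  sm <- sim_entry_means(plan, v_line = 1, v_tester = 0.3, v_sca = 0.15,
                        v_err = 0.05, seed = 14)
  ca <- suppressMessages(estimate_gca_sca(sm$tbl, value = "blue", plan = plan,
                                          error_variance = 0.05,
                                          residual_df = 50))
  oracle <- gca_kkt_oracle(sm$tbl$line_id, sm$tbl$tester_id, sm$tbl$blue,
                           error_variance = 0.05)
  expect_equal(ca$grand_mean, unname(oracle$mu), tolerance = 1e-8)
  expect_equal(setNames(ca$gca_line$effect, ca$gca_line$line_id),
               oracle$gca_line, tolerance = 1e-8)
  expect_equal(setNames(ca$gca_tester$effect, ca$gca_tester$tester_id),
               oracle$gca_tester, tolerance = 1e-8)
  expect_equal(ca$sca$effect, oracle$sca, tolerance = 1e-8)
  # standard errors from the same constrained covariance
  L <- nrow(ca$gca_line)
  expect_equal(ca$gca_line$se, oracle$se[1 + seq_len(L)], tolerance = 1e-8)
  expect_equal(ca$gca_tester$se, oracle$se[1 + L + seq_len(6)],
               tolerance = 1e-8)
})

test_that("effects are invariant to translating every entry mean", {
  plan <- small_plan()
  sm <- sim_entry_means(plan, seed = 20)
  shifted <- sm$tbl
  shifted$blue <- shifted$blue + 42
  ca0 <- suppressMessages(estimate_gca_sca(sm$tbl, value = "blue"))
  ca1 <- suppressMessages(estimate_gca_sca(shifted, value = "blue"))
  expect_equal(ca1$grand_mean, ca0$grand_mean + 42, tolerance = 1e-10)
  expect_equal(ca1$gca_line$effect, ca0$gca_line$effect, tolerance = 1e-10)
  expect_equal(ca1$gca_tester$effect, ca0$gca_tester$effect,
               tolerance = 1e-10)
  expect_equal(ca1$sca$effect, ca0$sca$effect, tolerance = 1e-10)
})

test_that("constraint-system invariants hold on incomplete plans", {
  plan <- small_plan()
  sm <- sim_entry_means(plan, v_sca = 0.2, seed = 31)
  ca <- suppressMessages(estimate_gca_sca(sm$tbl, value = "blue"))
  expect_equal(sum(ca$gca_line$effect), 0, tolerance = 1e-10)
  expect_equal(sum(ca$gca_tester$effect), 0, tolerance = 1e-10)
  # SCA effects of each line's crosses sum to zero (residual orthogonality)
  per_line <- tapply(ca$sca$effect, ca$sca$line_id, sum)
  expect_true(all(abs(per_line) < 1e-10))
  per_tester <- tapply(ca$sca$effect, ca$sca$tester_id, sum)
  expect_true(all(abs(per_tester) < 1e-10))
})

test_that("a line with a single cross has its SCA flagged inestimable", {
  tbl <- tibble::tibble(
    line_id = c("A", "A", "B", "B", "C"),
    tester_id = c("X", "Y", "X", "Y", "X"),
    blue = c(5, 6, 4, 5, 7)
  )
  ca <- suppressMessages(estimate_gca_sca(tbl, value = "blue",
                                          error_variance = 0.1,
                                          residual_df = 10))
  sca_c <- dplyr::filter(ca$sca, line_id == "C")
  expect_false(sca_c$estimable)
  expect_equal(sca_c$effect, 0)
})

test_that("SCA effects shrink toward zero as replication grows under additivity", {
  plan <- small_plan()
  mean_abs_sca <- sapply(c(1, 4, 16, 64), function(r) {
    vals <- sapply(1:12, function(s) {
      sm <- sim_entry_means(plan, v_line = 1, v_tester = 0.3, v_sca = 0,
                            v_err = 0.8 / r, seed = 100 * r + s)
      ca <- suppressMessages(estimate_gca_sca(sm$tbl, value = "blue"))
      mean(abs(ca$sca$effect))
    })
    mean(vals)
  })
  expect_true(all(diff(mean_abs_sca) < 0))
})

test_that("summary statistics follow the sign-count conventions", {
  tbl <- tibble::tibble(
    line_id = rep(c("A", "B"), each = 2),
    tester_id = rep(c("X", "Y"), 2),
    blue = c(6, 6.5, 4, 4.5)
  )
  ca <- suppressMessages(estimate_gca_sca(tbl, value = "blue"))
  st <- gca_summary_stats(ca)
  expect_setequal(st$group, c("line", "tester", "sca"))
  expect_equal(st$pct_positive + st$pct_negative,
               c(100, 100, 0)) # SCA exactly zero on additive data
  # effects {+1, -1}: half positive, extremes consistent
  ca2 <- ca
  ca2$gca_line$effect <- c(1, -1)
  st2 <- gca_summary_stats(ca2)
  line_row <- st2[st2$group == "line", ]
  expect_equal(line_row$pct_positive, 50)
  expect_equal(line_row$min_positive, 1)
  expect_equal(line_row$min_negative, -1)
})
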