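#' Coefficient of variation of a trial
#'
#' `CV% = 100 * sqrt(residual variance) / grand mean`.
#'
#' @param residual_variance Residual variance from the fitted model.
#' @param grand_mean Trait grand mean.
#' @return CV in percent.
#' @export
cv_percent <- function(residual_variance, grand_mean) {
  100 * sqrt(residual_variance) / grand_mean
}

#' Rank entries on a trait
#'
#' Entries are sorted in decreasing order of the trait; ties are broken by
#' lower ASI (earlier silk emergence relative to pollen shed is favourable,
#' especially under drought), then by entry label for stability. Check
#' entries are not ranked but appended below the testcrosses for comparison.
#'
#' @param entry_means Wide entry-mean table (one row per entry, trait
#'   columns), e.g. from [run_full_analysis()] or built from
#'   [entry_blues()].
#' @param k Number of top entries to keep; `Inf` for the full ranking.
#' @param trait Trait column to rank on.
#' @return A tibble of the `k` best testcrosses followed by the checks, with
#'   a `rank` column (`NA` for checks).
#' @export
top_entries <- function(entry_means, k = 20L, trait = "GY") {
  entry_means <- as_tibble(entry_means)
  if (!trait %in% names(entry_means)) {
    abort(sprintf("Unknown trait `%s`.", trait))
  }
  if (!"entry_kind" %in% names(entry_means)) {
    entry_means$entry_kind <- "testcross"
  }
  has_asi <- "ASI" %in% names(entry_means)
  tc <- dplyr::filter(entry_means, .data$entry_kind == "testcross")
  ord <- order(-tc[[trait]],
               if (has_asi) tc$ASI else seq_len(nrow(tc)),
               tc$entry_id)
  tc <- tc[ord, ]
  tc$rank <- seq_len(nrow(tc))
  tc <- head(tc, k)
  chk <- dplyr::filter(entry_means, .data$entry_kind == "check")
  if (nrow(chk)) chk$rank <- NA_integer_
  dplyr::bind_rows(tc, chk)
}

#' Run the full line-by-tester analysis pipeline
#'
#' For each management regime and trait: fits the combined genotype model
#' (checks included) for variance components, heritability and CV; fits the
#' across-environment (or single-environment) line-by-tester model for the
#' GCA/SCA variance partition, Baker's ratio and proportional contributions;
#' computes entry means, GCA and SCA effects with significance tests;
#' summarises the effects; and runs leave-one-hybrid-out GCA prediction.
#' Trait-trait correlations are computed on entry means within each regime
#' and, when two regimes are present, across regimes. Checks are retained in
#' the genotype-model stage (they were grown in the trials) but excluded
#' from all line-by-tester stages. The pipeline is deterministic given its
#' inputs.
#'
#' @param data A plot table covering one or two regimes.
#' @param plan Optional [crossing_plan()]; reconstructed from the records
#'   when absent.
#' @param traits Traits to analyse; defaults to the standard six present in
#'   the data.
#' @param do_lrt Test each variance component by drop-one LRT (slower).
#' @param do_loo Run leave-one-hybrid-out cross-validation.
#' @param control A [reml_control()].
#' @return An object of class `lxt_report` with tidy component tables
#'   (`variance_components`, `genotype_components`, `trait_summary`,
#'   `baker`, `contributions`, `prediction`), per-regime correlation
#'   matrices, and the full `lxt_ca` objects under `$combining`.
#' @export
run_full_analysis <- function(data, plan = NULL, traits = NULL,
                              do_lrt = TRUE, do_loo = TRUE,
                              control = reml_control()) {
  data <- as_tibble(data)
  validate_plot_table(data)
  if (is.null(plan)) plan <- plan_from_records(data)
  if (is.null(traits)) {
    traits <- intersect(c("GY", "AD", "SD", "ASI", "PH", "EH"), names(data))
  }
  if (!"regime" %in% names(data)) data$regime <- "unspecified"
  regimes <- unique(data$regime)

  geno_rows <- list(); lxt_rows <- list(); summ_rows <- list()
  baker_rows <- list(); contrib_rows <- list(); pred_rows <- list()
  combining <- list(); entry_mean_tbls <- list()

  for (rg in regimes) {
    d <- dplyr::filter(data, .data$regime == rg)
    n_env <- dplyr::n_distinct(d$environment)
    n_rep <- max(d$replicate)
    combining[[rg]] <- list()

    for (tr in traits) {
      if (all(is.na(d[[tr]]))) next

      # stage 1a: combined genotype model (checks included)
      gfit <- withCallingHandlers(
        fit_genotype_model(d, tr, control),
        warning = function(w) {
          if (grepl("Single environment", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        }
      )
      gc_tab <- if (do_lrt) {
        test_variance_components(d, gfit, control)
      } else {
        dplyr::mutate(gfit$components, statistic = NA_real_,
                      p_value = NA_real_, signif = NA_character_)
      }
      s2g <- gfit$components$variance[gfit$components$term == "genotype"]
      s2ge <- if ("genotype:env" %in% gfit$components$term) {
        gfit$components$variance[gfit$components$term == "genotype:env"]
      } else 0
      h2 <- heritability_broad(s2g, s2ge, gfit$residual, n_env, n_rep)

      # stage 1b: entry means on a common scale
      em <- entry_blues(d, tr)
      gm <- mean(em$blue)
      geno_rows[[length(geno_rows) + 1L]] <- dplyr::bind_rows(
        dplyr::mutate(gc_tab, regime = rg, trait = tr),
        tibble(term = "residual", variance = gfit$residual,
               statistic = NA_real_, p_value = NA_real_,
               signif = NA_character_, regime = rg, trait = tr)
      )
      summ_rows[[length(summ_rows) + 1L]] <- tibble(
        regime = rg, trait = tr, n_env = n_env, n_rep = n_rep,
        grand_mean = gm, minimum = min(em$blue), maximum = max(em$blue),
        sed = attr(em, "sed"),
        cv_pct = cv_percent(gfit$residual, gm),
        heritability = h2
      )

      # stage 2: line-by-tester variance partition (checks excluded)
      lfit <- withCallingHandlers(
        if (n_env >= 2L) fit_lxt_across_env(d, tr, control)
        else fit_lxt_single_env(d, tr, control),
        message = function(m) invokeRestart("muffleMessage")
      )
      lx_tab <- if (do_lrt) {
        test_variance_components(
          dplyr::filter(d, .data$entry_kind == "testcross"), lfit, control)
      } else {
        dplyr::mutate(lfit$components, statistic = NA_real_,
                      p_value = NA_real_, signif = NA_character_)
      }
      lxt_rows[[length(lxt_rows) + 1L]] <- dplyr::bind_rows(
        dplyr::mutate(lx_tab, regime = rg, trait = tr),
        tibble(term = "residual", variance = lfit$residual,
               statistic = NA_real_, p_value = NA_real_,
               signif = NA_character_, regime = rg, trait = tr)
      )
      vl <- lfit$components$variance[lfit$components$term == "line"]
      vt <- lfit$components$variance[lfit$components$term == "tester"]
      vs <- lfit$components$variance[lfit$components$term == "line:tester"]
      baker_rows[[length(baker_rows) + 1L]] <- tibble(
        regime = rg, trait = tr,
        bakers_ratio = suppressWarnings(bakers_ratio(vl, vt, vs))
      )
      contrib_rows[[length(contrib_rows) + 1L]] <- dplyr::mutate(
        suppressWarnings(proportional_contribution(vl, vt, vs)),
        regime = rg, trait = tr
      )

      # stage 3: GCA/SCA effects from testcross entry means
      em_tc <- dplyr::filter(em, .data$entry_kind == "testcross")
      err_var <- s2ge / n_env + gfit$residual / (n_rep * n_env)
      ca <- estimate_gca_sca(em_tc, value = "blue", plan = plan,
                             error_variance = err_var,
                             residual_df = gfit$residual_df)
      combining[[rg]][[tr]] <- ca

      # stage 4: GCA-only prediction, leave-one-hybrid-out
      if (do_loo) {
        cvr <- withCallingHandlers(
          loo_gca_cv(em_tc, value = "blue", plan = plan),
          warning = function(w) invokeRestart("muffleWarning")
        )
        pred_rows[[length(pred_rows) + 1L]] <- tibble(
          regime = rg, trait = tr, r = cvr$r, n = cvr$n_predicted
        )
      }

      entry_mean_tbls[[length(entry_mean_tbls) + 1L]] <- dplyr::mutate(
        dplyr::select(em, "entry_id", "entry_kind", "line_id", "tester_id",
                      "blue"),
        regime = rg, trait = tr
      )
    }
  }

  entry_means <- dplyr::bind_rows(entry_mean_tbls) |>
    tidyr::pivot_wider(names_from = "trait", values_from = "blue")
  correlations <- list()
  for (rg in regimes) {
    em_rg <- dplyr::filter(entry_means, .data$regime == rg)
    if (sum(vapply(traits, function(tr) tr %in% names(em_rg), logical(1))) >= 2) {
      correlations[[rg]] <- correlate_traits(em_rg, mode = "within_regime")
    }
  }
  if (length(regimes) >= 2L) {
    correlations[["across"]] <- correlate_traits(entry_means,
                                                 mode = "across_regimes")
  }

  structure(
    list(
      genotype_components = dplyr::bind_rows(geno_rows),
      variance_components = dplyr::bind_rows(lxt_rows),
      trait_summary = dplyr::bind_rows(summ_rows),
      baker = dplyr::bind_rows(baker_rows),
      contributions = dplyr::bind_rows(contrib_rows),
      prediction = dplyr::bind_rows(pred_rows),
      combining = combining,
      correlations = correlations,
      entry_means = entry_means,
      summary_stats = purrr::map_dfr(names(combining), function(rg) {
        purrr::map_dfr(names(combining[[rg]]), function(tr) {
          dplyr::mutate(gca_summary_stats(combining[[rg]][[tr]]),
                        regime = rg, trait = tr)
        })
      })
    ),
    class = "lxt_report"
  )
}

#' @export
print.lxt_report <- function(x, ...) {
  cat("<lxt_report>\n")
  cat("\nTrait summary (grand mean, CV%, heritability):\n")
  print(x$trait_summary, n = nrow(x$trait_summary))
  cat("\nBaker's ratio:\n")
  print(x$baker, n = nrow(x$baker))
  if (nrow(x$prediction)) {
    cat("\nLeave-one-hybrid-out r(GCA, TCP):\n")
    print(x$prediction, n = nrow(x$prediction))
  }
  invisible(x)
}

#' Write a report to a directory of CSV files and a JSON summary
#'
#' @param report An `lxt_report`.
#' @param dir Output directory; created if needed.
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "lxt_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(tbl, name) {
    readr::write_csv(tbl, file.path(dir, paste0(name, ".csv")), na = "NA",
                     progress = FALSE)
  }
  wr(report$genotype_components, "genotype_components")
  wr(report$variance_components, "lxt_components")
  wr(report$trait_summary, "trait_summary")
  wr(report$baker, "bakers_ratio")
  wr(report$contributions, "contributions")
  wr(report$summary_stats, "gca_sca_summary")
  if (nrow(report$prediction)) wr(report$prediction, "prediction")
  wr(report$entry_means, "entry_means")
  for (rg in names(report$correlations)) {
    write_cormat_csv(report$correlations[[rg]],
                     file.path(dir, paste0("correlations_", rg, ".csv")))
  }
  for (rg in names(report$combining)) {
    for (tr in names(report$combining[[rg]])) {
      write_ca_csv(report$combining[[rg]][[tr]],
                   file.path(dir, sprintf("ca_%s_%s.csv", rg, tr)))
    }
  }
  jsonlite::write_json(
    list(trait_summary = report$trait_summary, baker = report$baker,
         prediction = report$prediction),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "columns"
  )
  invisible(dir)
}
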