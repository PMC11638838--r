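#' Tidy a REML fit into a variance-component tibble
#'
#' @param x An `lxt_fit`.
#' @param effects One of `"varcomp"` (variance components, the default),
#'   `"fixed"` (fixed-effect estimates) or `"ran_vals"` (BLUPs).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.lxt_fit <- function(x, effects = c("varcomp", "fixed", "ran_vals"), ...) {
  effects <- match.arg(effects)
  switch(effects,
    varcomp = dplyr::bind_rows(
      x$components,
      tibble(term = "residual", variance = x$residual)
    ),
    fixed = x$fixed_effects,
    ran_vals = purrr::imap_dfr(x$ranef, function(tbl, term) {
      dplyr::mutate(tbl, term = term, .before = 1)
    })
  )
}

#' One-row summary of a REML fit
#'
#' @param x An `lxt_fit`.
#' @param ... Unused.
#' @return A tibble with the log-likelihood, residual variance, sample size
#'   and convergence flag.
#' @export
glance.lxt_fit <- function(x, ...) {
  tibble(
    logLik = x$logLik, sigma2 = x$residual, nobs = x$nobs,
    residual_df = x$residual_df, converged = x$converged
  )
}

#' Tidy a combining-ability table into one long tibble
#'
#' @param x An `lxt_ca`.
#' @param ... Unused.
#' @return A tibble with columns `role` (`gca_line`, `gca_tester`, `sca`),
#'   ids, `effect`, `se`, `t_value`, `p_value`, `signif`.
#' @export
tidy.lxt_ca <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$gca_line, role = "gca_line", .before = 1),
    dplyr::mutate(x$gca_tester, role = "gca_tester", .before = 1),
    dplyr::mutate(dplyr::select(x$sca, -"estimable"), role = "sca",
                  .before = 1)
  )
}

#' One-row summary of a combining-ability table
#'
#' @param x An `lxt_ca`.
#' @param ... Unused.
#' @return A tibble with the grand mean and the table dimensions.
#' @export
glance.lxt_ca <- function(x, ...) {
  tibble(
    grand_mean = x$grand_mean,
    n_lines = nrow(x$gca_line), n_testers = nrow(x$gca_tester),
    n_crosses = x$n_crosses,
    error_variance = x$error_variance %||% NA_real_,
    residual_df = x$residual_df
  )
}

#' Tidy leave-one-hybrid-out predictions
#'
#' @param x An `lxt_cv`.
#' @param ... Unused.
#' @return The per-hybrid tibble of observed and predicted values.
#' @export
tidy.lxt_cv <- function(x, ...) x$predictions

#' One-row summary of a cross-validation
#'
#' @param x An `lxt_cv`.
#' @param ... Unused.
#' @return A tibble with `r`, `n_predicted` and `n_skipped`.
#' @export
glance.lxt_cv <- function(x, ...) {
  tibble(r = x$r, n_predicted = x$n_predicted, n_skipped = x$n_skipped)
}

#' Tidy a correlation matrix into pair rows
#'
#' @param x An `lxt_cormat`.
#' @param ... Unused.
#' @return A tibble with one row per unordered trait pair: `r`, `p_value`,
#'   `n`, `signif`.
#' @export
tidy.lxt_cormat <- function(x, ...) {
  labs <- rownames(x$r)
  pairs <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble(
    trait1 = labs[pairs[, 1]], trait2 = labs[pairs[, 2]],
    r = x$r[pairs], p_value = x$p[pairs], n = as.integer(x$n[pairs]),
    signif = star_signif(x$p[pairs])
  )
}
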