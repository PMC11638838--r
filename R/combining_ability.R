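#' Broad-sense heritability on an entry-mean basis
#'
#' `H2 = s2_g / (s2_g + s2_ge / e + s2_e / (r * e))`, where `s2_g`, `s2_ge`
#' and `s2_e` are the genotype, genotype-by-environment and residual variance
#' components and `e` and `r` the numbers of environments and replications.
#' Full precision is returned; round to 2 decimals for reporting.
#'
#' @param sigma2_g Genotypic variance (trait units squared). Vectorised.
#' @param sigma2_ge Genotype-by-environment variance. Vectorised.
#' @param sigma2_e Residual variance. Vectorised.
#' @param n_env Number of environments, `e`.
#' @param n_rep Number of replications, `r`.
#' @return Heritability in `[0, 1]`; `NA` with a warning when all variance
#'   components are zero.
#' @examples
#' heritability_broad(0.06, 0.28, 0.50, n_env = 3, n_rep = 2) # ~0.25
#' @export
heritability_broad <- function(sigma2_g, sigma2_ge, sigma2_e, n_env, n_rep) {
  assert_number(sigma2_g, "sigma2_g", lower = 0)
  assert_number(sigma2_ge, "sigma2_ge", lower = 0)
  assert_number(sigma2_e, "sigma2_e", lower = 0)
  n_env <- assert_count(n_env, "n_env")
  n_rep <- assert_count(n_rep, "n_rep")
  denom <- sigma2_g + sigma2_ge / n_env + sigma2_e / (n_rep * n_env)
  out <- sigma2_g / denom
  if (any(denom == 0)) {
    warn("Heritability undefined: all variance components are zero.")
    out[denom == 0] <- NA_real_
  }
  out
}

#' Baker's ratio of combining-ability variances
#'
#' `2 * (s2_GCA_line + s2_GCA_tester) /
#'  (2 * (s2_GCA_line + s2_GCA_tester) + s2_SCA)`. A ratio near 1 means
#' hybrid performance is predictable from GCA effects alone (additive gene
#' action dominates). The GCA term sums the line and tester components.
#'
#' @param sigma2_gca_line Line GCA variance. Vectorised.
#' @param sigma2_gca_tester Tester GCA variance. Vectorised.
#' @param sigma2_sca Line-by-tester SCA variance. Vectorised.
#' @return Ratio in `(0, 1]`; `NA` with a warning when all components are 0.
#' @examples
#' bakers_ratio(6.18, 0.06, 0.09) # ~0.99
#' @export
bakers_ratio <- function(sigma2_gca_line, sigma2_gca_tester, sigma2_sca) {
  assert_number(sigma2_gca_line, "sigma2_gca_line", lower = 0)
  assert_number(sigma2_gca_tester, "sigma2_gca_tester", lower = 0)
  assert_number(sigma2_sca, "sigma2_sca", lower = 0)
  num <- 2 * (sigma2_gca_line + sigma2_gca_tester)
  denom <- num + sigma2_sca
  out <- num / denom
  if (any(denom == 0)) {
    warn("Baker's ratio undefined: all variance components are zero.")
    out[denom == 0] <- NA_real_
  }
  out
}

#' Proportional contributions to the total combining-ability variance
#'
#' Each of the line GCA, tester GCA and SCA variance components expressed as
#' a percentage of their sum.
#'
#' @inheritParams bakers_ratio
#' @return A tibble with columns `line`, `tester` and `line_x_tester`
#'   (percentages summing to 100), one row per input element.
#' @examples
#' proportional_contribution(0.228, 0.015, 0.01)
#' @export
proportional_contribution <- function(sigma2_gca_line, sigma2_gca_tester,
                                      sigma2_sca) {
  assert_number(sigma2_gca_line, "sigma2_gca_line", lower = 0)
  assert_number(sigma2_gca_tester, "sigma2_gca_tester", lower = 0)
  assert_number(sigma2_sca, "sigma2_sca", lower = 0)
  total <- sigma2_gca_line + sigma2_gca_tester + sigma2_sca
  if (any(total == 0)) {
    warn("Proportional contribution undefined: all components are zero.")
  }
  tibble(
    line = 100 * sigma2_gca_line / total,
    tester = 100 * sigma2_gca_tester / total,
    line_x_tester = 100 * sigma2_sca / total
  )
}

# design matrices of the additive decomposition mean(i,j) = mu + g_i + t_j
# over the realised crosses. The model matrix of (mu, g, t) has a null space
# of dimension (number of connected components of the line-tester graph) + 1,
# so the effects are identified by one sum-to-zero constraint on the line
# effects of each component plus one overall sum-to-zero constraint on the
# tester effects. K is an orthonormal basis of the constraint null space;
# beta = K alpha is unique and independent of the basis.
ca_design <- function(line, tester) {
  Lf <- factor(line)
  Tf <- factor(tester)
  L <- nlevels(Lf)
  Tn <- nlevels(Tf)
  if (L < 2L || Tn < 2L) {
    abort("Need at least two lines and two testers to decompose GCA/SCA.")
  }
  g <- crosses_graph(as.character(Lf), as.character(Tf))
  memb <- igraph::components(g)$membership
  line_comp <- unname(memb[paste0("L.", levels(Lf))])
  ncomp <- max(memb)
  p <- 1L + L + Tn
  Z <- cbind(1, model.matrix(~ 0 + Lf), model.matrix(~ 0 + Tf))
  C <- matrix(0, ncomp + 1L, p)
  for (cc in seq_len(ncomp)) C[cc, 1L + which(line_comp == cc)] <- 1
  C[ncomp + 1L, 1L + L + seq_len(Tn)] <- 1
  K <- qr.Q(qr(t(C)), complete = TRUE)[, (ncomp + 2L):p, drop = FALSE]
  list(M = Z %*% K, K = K, lines = levels(Lf), testers = levels(Tf),
       L = L, T = Tn, n_components = ncomp)
}

#' Estimate GCA and SCA effects from entry means
#'
#' Decomposes testcross entry means over the realised crosses as
#' `mean(i, j) = mu + g_i + g_j + s_ij` by least squares under sum-to-zero
#' constraints on line and tester effects (the mean-based procedure of the
#' classical line-by-tester analysis). SCA effects are the residuals of the
#' additive fit; on a complete factorial they reduce to the textbook
#' marginal-mean formulas. Standard errors come from the constrained
#' normal-equations covariance evaluated at the supplied error variance of
#' an entry mean, and each effect is tested as `t = effect / SE` against a
#' t distribution at `residual_df` degrees of freedom.
#'
#' @param entry_means Data frame of testcross means with columns `line_id`,
#'   `tester_id` and the value column (typically from [entry_blues()]).
#' @param value Name of the value column (default `"blue"`).
#' @param plan Optional [crossing_plan()]; when supplied, the means must
#'   cover a subset of its crosses. When the line-tester graph has several
#'   connected components (as in a two-heterotic-group plan with disjoint
#'   tester sets), line GCA effects are centred within each component and a
#'   message is emitted.
#' @param error_variance Variance of an entry mean, e.g.
#'   `s2_ge / e + s2_e / (r * e)` from the stage-one fit. When `NULL`,
#'   effects are returned without standard errors or tests.
#' @param residual_df Degrees of freedom for the t tests (stage-one residual
#'   df).
#' @return An object of class `lxt_ca`: grand mean plus tibbles `gca_line`,
#'   `gca_tester` and `sca` with effects, standard errors, t values,
#'   p-values and significance stars. SCA rows whose leverage makes the
#'   deviation unidentifiable (for example a line with a single cross) are
#'   flagged `estimable = FALSE`.
#' @export
estimate_gca_sca <- function(entry_means, value = "blue", plan = NULL,
                             error_variance = NULL, residual_df = Inf) {
  entry_means <- as_tibble(entry_means)
  stopifnot(all(c("line_id", "tester_id") %in% names(entry_means)))
  if (!value %in% names(entry_means)) {
    abort(sprintf("Value column `%s` not found in `entry_means`.", value))
  }
  entry_means <- dplyr::filter(entry_means, !is.na(.data[[value]]),
                               !is.na(.data$line_id), !is.na(.data$tester_id))
  if (anyDuplicated(entry_means[c("line_id", "tester_id")])) {
    abort("`entry_means` must have one row per line x tester cross.")
  }
  if (!is.null(plan)) {
    stopifnot(inherits(plan, "crossing_plan"))
    known <- paste(plan$crosses$line_id, plan$crosses$tester_id)
    got <- paste(entry_means$line_id, entry_means$tester_id)
    if (!all(got %in% known)) {
      abort("`entry_means` contains crosses absent from the crossing plan.")
    }
  }
  mini_plan <- crossing_plan(
    lines = tibble(line_id = unique(entry_means$line_id),
                   heterotic_group = NA_character_),
    testers = tibble(tester_id = unique(entry_means$tester_id),
                     heterotic_group = NA_character_),
    crosses = entry_means[, c("line_id", "tester_id")],
    check_groups = FALSE
  )

  y <- entry_means[[value]]
  des <- ca_design(entry_means$line_id, entry_means$tester_id)
  if (des$n_components > 1L) {
    inform(sprintf(
      "Line-tester graph has %d components; line GCA effects are centred within each component.",
      des$n_components
    ))
  }
  M <- des$M
  A <- crossprod(M)
  Ainv <- tryCatch(chol2inv(chol(A)), error = function(e) {
    abort("Estimability error: the additive design is singular.")
  })
  alpha <- Ainv %*% crossprod(M, y)
  beta <- as.numeric(des$K %*% alpha)
  fitted_add <- as.numeric(M %*% alpha)
  sca_eff <- y - fitted_add
  lev <- rowSums((M %*% Ainv) * M) # leverage of the additive fit

  if (!is.null(error_variance)) {
    assert_number(error_variance, "error_variance", lower = 0)
    Vbeta <- error_variance * (des$K %*% Ainv %*% t(des$K))
    se_beta <- sqrt(pmax(0, diag(Vbeta)))
    se_sca <- sqrt(pmax(0, error_variance * (1 - lev)))
  } else {
    se_beta <- rep(NA_real_, length(beta))
    se_sca <- rep(NA_real_, length(sca_eff))
  }

  mk_tbl <- function(ids, eff, se, id_col) {
    t_val <- eff / se
    p <- 2 * pt(-abs(t_val), df = residual_df)
    out <- tibble(id = ids, effect = eff, se = se, t_value = t_val,
                  p_value = p, signif = star_signif(p))
    names(out)[1] <- id_col
    out
  }
  gca_line <- mk_tbl(des$lines, beta[1 + seq_len(des$L)],
                     se_beta[1 + seq_len(des$L)], "line_id")
  gca_tester <- mk_tbl(des$testers, beta[1 + des$L + seq_len(des$T)],
                       se_beta[1 + des$L + seq_len(des$T)], "tester_id")
  sca <- tibble(
    line_id = entry_means$line_id, tester_id = entry_means$tester_id,
    effect = sca_eff, se = se_sca,
    t_value = sca_eff / se_sca,
    p_value = 2 * pt(-abs(sca_eff / se_sca), df = residual_df),
    estimable = (1 - lev) > 1e-8
  )
  sca$signif <- star_signif(sca$p_value)
  sca$effect[!sca$estimable] <- 0
  sca$t_value[!sca$estimable] <- NA_real_
  sca$p_value[!sca$estimable] <- NA_real_
  sca$signif[!sca$estimable] <- NA_character_

  structure(
    list(grand_mean = beta[1], gca_line = gca_line, gca_tester = gca_tester,
         sca = sca, error_variance = error_variance,
         residual_df = residual_df, n_crosses = nrow(entry_means),
         plan = mini_plan),
    class = "lxt_ca"
  )
}

#' @export
print.lxt_ca <- function(x, ...) {
  cat(sprintf(
    "<lxt_ca> grand mean %.4g; %d lines, %d testers, %d crosses\n",
    x$grand_mean, nrow(x$gca_line), nrow(x$gca_tester), x$n_crosses
  ))
  cat("line GCA range:",
      sprintf("[%.4g, %.4g]", min(x$gca_line$effect), max(x$gca_line$effect)),
      "\n")
  invisible(x)
}

#' Summary statistics of GCA and SCA effects
#'
#' For lines, testers and crosses separately: the share of positive and
#' negative effects and the extreme positive/negative values, in the layout
#' breeders use to scan a combining-ability analysis. `min_positive` is the
#' smallest positive effect, `max_negative` the negative effect closest to
#' zero, `min_negative` the most negative effect.
#'
#' @param ca An `lxt_ca` from [estimate_gca_sca()].
#' @return A tibble with one row per group (`line`, `tester`, `sca`).
#' @export
gca_summary_stats <- function(ca) {
  stopifnot(inherits(ca, "lxt_ca"))
  one <- function(eff, group, n_label) {
    eff[abs(eff) < 1e-10] <- 0 # numerically-zero effects have no sign
    pos <- eff[eff > 0]
    neg <- eff[eff < 0]
    tibble(
      group = group,
      n = length(eff),
      pct_positive = 100 * length(pos) / length(eff),
      pct_negative = 100 * length(neg) / length(eff),
      min_positive = if (length(pos)) min(pos) else NA_real_,
      max_positive = if (length(pos)) max(pos) else NA_real_,
      min_negative = if (length(neg)) min(neg) else NA_real_,
      max_negative = if (length(neg)) max(neg) else NA_real_
    )
  }
  dplyr::bind_rows(
    one(ca$gca_line$effect, "line"),
    one(ca$gca_tester$effect, "tester"),
    one(ca$sca$effect, "sca")
  )
}

#' Write a combining-ability table to CSV
#'
#' @param ca An `lxt_ca`.
#' @param path Output path; three files are written with suffixes
#'   `_gca_line.csv`, `_gca_tester.csv`, `_sca.csv` replacing the extension.
#' @return The paths, invisibly.
#' @export
write_ca_csv <- function(ca, path) {
  stopifnot(inherits(ca, "lxt_ca"))
  stub <- sub("\\.csv$", "", path)
  paths <- paste0(stub, c("_gca_line.csv", "_gca_tester.csv", "_sca.csv"))
  readr::write_csv(ca$gca_line, paths[1], na = "NA", progress = FALSE)
  readr::write_csv(ca$gca_tester, paths[2], na = "NA", progress = FALSE)
  readr::write_csv(ca$sca, paths[3], na = "NA", progress = FALSE)
  invisible(paths)
}
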