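#' Optimiser settings for REML fits
#'
#' Variance-component estimates are required to be reproducible and to agree
#' with closed-form estimators on balanced designs to high precision, so the
#' default optimiser is BOBYQA run to a very tight trust-region radius.
#'
#' @param optimizer Optimiser name passed to [lme4::lmerControl()].
#' @param rhoend Final BOBYQA trust-region radius; smaller is more precise.
#' @param maxfun Maximum number of function evaluations.
#' @param polish Run a Newton refinement of the variance parameters after
#'   the optimiser returns. Brings balanced-design estimates to ~1e-9
#'   relative agreement with closed-form estimators; can be disabled for
#'   large simulation studies where optimiser precision suffices.
#' @return An [lme4::lmerControl()] object carrying the polish flag.
#' @export
reml_control <- function(optimizer = "bobyqa", rhoend = 1e-13, maxfun = 2e5,
                         polish = TRUE) {
  ctl <- lme4::lmerControl(
    optimizer = optimizer,
    optCtrl = if (optimizer == "bobyqa") {
      list(rhoend = rhoend, maxfun = maxfun)
    } else {
      list(maxfun = maxfun)
    },
    calc.derivs = FALSE,
    check.conv.singular = "ignore"
  )
  attr(ctl, "polish") <- isTRUE(polish)
  ctl
}

#' Declare a mixed model for a trial trait
#'
#' Terms are written in a compact grammar over the design factors of a plot
#' table: `env`, `rep`, `block`, `line`, `tester`, `genotype` (entry), with
#' `:` for crossing and `%in%` for nesting (`"rep%in%env"` is replication
#' within environment; `"block%in%rep%in%env"` is the incomplete block within
#' replication within environment).
#'
#' @param response Trait column name, e.g. `"GY"`.
#' @param fixed Character vector of fixed terms.
#' @param random Character vector of random terms.
#' @param scope `"single_environment"` or `"across_environments"`.
#' @return An object of class `lxt_model_spec`.
#' @examples
#' model_spec("GY",
#'   fixed = c("env", "rep%in%env"),
#'   random = c("block%in%rep%in%env", "line", "tester", "line:tester",
#'              "line:env", "tester:env", "line:tester:env"),
#'   scope = "across_environments"
#' )
#' @export
model_spec <- function(response, fixed = character(), random = character(),
                       scope = c("across_environments", "single_environment")) {
  scope <- match.arg(scope)
  stopifnot(is.character(response), length(response) == 1L)
  overlap <- intersect(fixed, random)
  if (length(overlap)) {
    abort(paste0("Term(s) declared both fixed and random: ",
                 paste(overlap, collapse = ", ")))
  }
  structure(list(response = response, fixed = fixed, random = random,
                 scope = scope),
            class = "lxt_model_spec")
}

#' @export
print.lxt_model_spec <- function(x, ...) {
  cat(sprintf("<lxt_model_spec> %s ~ fixed(%s) + random(%s) [%s]\n",
              x$response,
              paste(x$fixed, collapse = " + "),
              paste(x$random, collapse = " + "),
              x$scope))
  invisible(x)
}

# split a term written in the grammar into canonical component columns;
# "A%in%B" nests A in B, i.e. the identifying factor is the B:A combination
parse_term <- function(term, data) {
  if (grepl("%in%", term, fixed = TRUE)) {
    parts <- rev(trimws(strsplit(term, "%in%", fixed = TRUE)[[1]]))
  } else {
    parts <- trimws(strsplit(term, ":", fixed = TRUE)[[1]])
  }
  vapply(parts, resolve_term_column, character(1), data = data)
}

# model frame with the response in `.y`, fixed factors as `.f_*` columns and
# one composite grouping factor `.g_<i>` per random term
build_model_frame <- function(data, spec) {
  if (!spec$response %in% names(data)) {
    abort(sprintf("Response `%s` is not a column of the data.", spec$response))
  }
  frame <- tibble(.y = as.numeric(data[[spec$response]]))
  fixed_terms <- character(0)
  for (term in spec$fixed) {
    cols <- parse_term(term, data)
    nms <- paste0(".f_", cols)
    for (k in seq_along(cols)) {
      frame[[nms[k]]] <- factor(data[[cols[k]]])
    }
    fixed_terms <- c(fixed_terms, paste(nms, collapse = ":"))
  }
  group_names <- character(length(spec$random))
  for (i in seq_along(spec$random)) {
    cols <- parse_term(spec$random[i], data)
    g <- if (length(cols) == 1L) {
      factor(data[[cols]])
    } else {
      interaction(lapply(cols, function(cc) data[[cc]]), drop = TRUE,
                  sep = ":")
    }
    gname <- paste0(".g_", i)
    frame[[gname]] <- g
    group_names[i] <- gname
  }
  keep <- !is.na(frame$.y)
  if (!all(keep)) frame <- frame[keep, , drop = FALSE]
  frame <- droplevels(frame)
  list(frame = frame, fixed_terms = fixed_terms, group_names = group_names)
}

new_lxt_fit <- function(spec, components, residual, logLik, converged,
                        fixed_effects, ranef, residual_df, nobs,
                        model = NULL, note = NULL) {
  structure(
    list(spec = spec, components = components, residual = residual,
         logLik = logLik, converged = converged,
         fixed_effects = fixed_effects, ranef = ranef,
         residual_df = residual_df, nobs = nobs, model = model, note = note),
    class = "lxt_fit"
  )
}

#' @export
print.lxt_fit <- function(x, ...) {
  cat(sprintf("<lxt_fit> %s (%s), n = %d, REML logLik = %s\n",
              x$spec$response, x$spec$scope, x$nobs,
              formatC(x$logLik, format = "f", digits = 2)))
  comp <- dplyr::bind_rows(x$components,
                           tibble(term = "residual", variance = x$residual))
  print(comp, n = nrow(comp))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

# One damped Newton step on the profiled REML deviance, with derivatives
# taken by central differences wide enough to average out the deviance's
# machine-noise floor. The optimiser alone stalls ~1e-8 away from the true
# optimum in relative terms; this polish brings balanced-design estimates to
# agreement with closed-form estimators at ~1e-10. Coordinates already on
# the zero boundary are left there.
polish_theta <- function(m, iterations = 4L) {
  th <- lme4::getME(m, "theta")
  free <- which(th > 1e-8)
  if (!length(free)) return(m)
  dv <- tryCatch(stats::update(m, devFunOnly = TRUE),
                 error = function(e) NULL)
  if (is.null(dv)) return(m)
  # the finite-difference gradient carries an O(h^2) bias, so the step width
  # shrinks across iterations to move its fixed point onto the true optimum
  for (iter in seq_len(iterations)) {
    res <- newton_step(dv, th, free, h_scale = 10^(-3 - iter))
    if (is.null(res)) break
    th <- res
  }
  f_new <- dv(th)
  opt <- list(par = th, fval = f_new, conv = 0L, feval = NA_integer_)
  reTrms <- list(flist = m@flist, cnms = m@cnms, Gp = m@Gp, lower = m@lower)
  out <- tryCatch(
    lme4::mkMerMod(environment(dv), opt, reTrms, fr = m@frame),
    error = function(e) NULL
  )
  if (is.null(out)) m else out
}

newton_step <- function(dv, th, free, h_scale = 1e-4) {
  f0 <- dv(th)
  h <- pmax(1e-6, abs(th[free]) * h_scale)
  k <- length(free)
  g <- numeric(k)
  H <- matrix(0, k, k)
  step_of <- function(i, s) {
    out <- th
    out[free[i]] <- out[free[i]] + s
    out
  }
  fp <- fm <- numeric(k)
  for (i in seq_len(k)) {
    fp[i] <- dv(step_of(i, h[i]))
    fm[i] <- dv(step_of(i, -h[i]))
    g[i] <- (fp[i] - fm[i]) / (2 * h[i])
    H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / h[i]^2
  }
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        thij <- th
        thij[free[i]] <- thij[free[i]] + h[i]
        thij[free[j]] <- thij[free[j]] + h[j]
        H[i, j] <- H[j, i] <-
          (dv(thij) - fp[i] - fp[j] + f0) / (h[i] * h[j])
      }
    }
  }
  delta <- tryCatch(-solve(H, g), error = function(e) NULL)
  if (is.null(delta) || !all(is.finite(delta))) return(NULL)
  th_new <- th
  th_new[free] <- pmax(0, th[free] + delta)
  # a micro-step cannot worsen the deviance beyond the evaluation noise, and
  # its genuine improvement sits below that noise: accept it blindly
  if (max(abs(delta)) < 1e-6 * (1 + max(abs(th)))) return(th_new)
  f_new <- dv(th_new)
  if (!is.finite(f_new) || f_new > f0 + 1e-11) return(NULL)
  th_new
}

# REML log-likelihood of a fixed-effects-only Gaussian model, on the same
# scale as lme4's REML logLik (checked against lmer at a boundary fit)
reml_loglik_fixed <- function(y, X) {
  qrX <- qr(X)
  keep <- qrX$pivot[seq_len(qrX$rank)]
  X <- X[, keep, drop = FALSE]
  n <- length(y)
  p <- ncol(X)
  fit <- lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  s2 <- rss / (n - p)
  ld <- determinant(crossprod(X), logarithm = TRUE)$modulus[1]
  ll <- -0.5 * ((n - p) * (log(2 * pi) + 1) + (n - p) * log(s2) + ld)
  list(logLik = ll, sigma2 = s2, residual_df = n - p, coef = fit$coefficients)
}

#' Fit a declared mixed model by REML
#'
#' Variance components are estimated by restricted maximum likelihood with
#' non-negativity enforced at the zero boundary. The fit is deterministic:
#' no randomised initialisation is used, and estimates are invariant to the
#' row order of the input. A model with no random terms falls back to
#' ordinary least squares with the REML log-likelihood evaluated on the same
#' scale, so nested models with and without a single random term can be
#' compared by [lrt_variance_component()].
#'
#' @param data A plot table (see [read_plot_table()] / [simulate_trial()]).
#' @param spec A [model_spec()].
#' @param control A [reml_control()].
#' @return An object of class `lxt_fit` with elements `components` (tibble of
#'   term/variance), `residual`, `logLik`, `fixed_effects`, `ranef` (BLUPs
#'   per random term), `residual_df`, `converged`.
#' @export
fit_reml <- function(data, spec, control = reml_control()) {
  stopifnot(inherits(spec, "lxt_model_spec"))
  mf <- build_model_frame(data, spec)
  frame <- mf$frame
  n <- nrow(frame)
  if (n == 0L) abort("No non-missing observations for the response.")
  for (i in seq_along(mf$group_names)) {
    if (nlevels(frame[[mf$group_names[i]]]) < 2L) {
      abort(sprintf("Random term `%s` has fewer than 2 levels.",
                    spec$random[i]))
    }
  }
  fixed_rhs <- if (length(mf$fixed_terms)) {
    paste(mf$fixed_terms, collapse = " + ")
  } else "1"

  # degenerate input: a constant response pins every component to the boundary
  if (var(frame$.y) < .Machine$double.eps) {
    comps <- tibble(term = spec$random,
                    variance = rep(0, length(spec$random)))
    return(new_lxt_fit(
      spec, comps, residual = .Machine$double.eps, logLik = NA_real_,
      converged = TRUE,
      fixed_effects = tibble(term = "(Intercept)", estimate = frame$.y[1],
                             se = 0),
      ranef = setNames(
        lapply(mf$group_names,
               function(g) tibble(level = levels(frame[[g]]), blup = 0)),
        spec$random),
      residual_df = n - 1L, nobs = n, note = "degenerate: constant response"
    ))
  }

  if (length(spec$random) == 0L) {
    X <- model.matrix(stats::as.formula(paste("~", fixed_rhs)), frame)
    out <- reml_loglik_fixed(frame$.y, X)
    return(new_lxt_fit(
      spec, tibble(term = character(), variance = numeric()),
      residual = out$sigma2, logLik = out$logLik, converged = TRUE,
      fixed_effects = tibble(term = names(out$coef),
                             estimate = unname(out$coef), se = NA_real_),
      ranef = list(), residual_df = out$residual_df, nobs = n
    ))
  }

  form <- stats::as.formula(paste(
    ".y ~", fixed_rhs, "+",
    paste(sprintf("(1 | %s)", mf$group_names), collapse = " + ")
  ))
  m <- withCallingHandlers(
    lme4::lmer(form, data = frame, REML = TRUE, control = control),
    message = function(m) invokeRestart("muffleMessage")
  )
  if (!isFALSE(attr(control, "polish"))) m <- polish_theta(m)
  vc <- as.data.frame(lme4::VarCorr(m))
  grp_var <- setNames(vc$vcov, vc$grp)
  comps <- tibble(term = spec$random,
                  variance = unname(grp_var[mf$group_names]))
  fe <- lme4::fixef(m)
  fe_se <- sqrt(Matrix::diag(as.matrix(stats::vcov(m))))
  re <- lme4::ranef(m, condVar = FALSE)
  ranef_tbl <- setNames(
    lapply(mf$group_names, function(g) {
      df <- re[[g]]
      tibble(level = rownames(df), blup = df[["(Intercept)"]])
    }),
    spec$random
  )
  new_lxt_fit(
    spec, comps,
    residual = unname(grp_var["Residual"]),
    logLik = as.numeric(logLik(m)),
    converged = isTRUE(m@optinfo$conv$opt == 0),
    fixed_effects = tibble(term = names(fe), estimate = unname(fe),
                           se = unname(fe_se)),
    ranef = ranef_tbl,
    residual_df = nrow(frame) - length(fe),
    nobs = nrow(frame),
    model = m
  )
}

#' Fit the combined genotype model of a multi-environment trial
#'
#' Entries (testcrosses and checks alike) are modelled as
#' `trait ~ env + rep%in%env` (fixed) plus random incomplete block within
#' replication within environment, genotype, and genotype-by-environment.
#' The genotype and genotype-by-environment components feed
#' [heritability_broad()]. With a single environment the
#' genotype-by-environment term is dropped with a warning.
#'
#' @param data A plot table.
#' @param trait Trait column name.
#' @param control A [reml_control()].
#' @return An `lxt_fit`.
#' @export
fit_genotype_model <- function(data, trait, control = reml_control()) {
  n_env <- dplyr::n_distinct(data$environment)
  if (n_env >= 2L) {
    spec <- model_spec(
      trait,
      fixed = c("env", "rep%in%env"),
      random = c("block%in%rep%in%env", "genotype", "genotype:env"),
      scope = "across_environments"
    )
  } else {
    warn("Single environment: the genotype-by-environment term is dropped.")
    spec <- model_spec(
      trait,
      fixed = "rep",
      random = c("block%in%rep", "genotype"),
      scope = "single_environment"
    )
  }
  fit_reml(data, spec, control)
}

drop_checks <- function(data) {
  if (any(data$entry_kind == "check")) {
    inform(sprintf("Excluding %d check plot(s) from the line-by-tester analysis.",
                   sum(data$entry_kind == "check")))
    data <- dplyr::filter(data, .data$entry_kind == "testcross")
  }
  data
}

#' Fit the single-environment line-by-tester model
#'
#' `trait ~ rep` (fixed) plus random incomplete block within replication,
#' line GCA, tester GCA and line-by-tester SCA. Check entries are excluded.
#'
#' @inheritParams fit_genotype_model
#' @return An `lxt_fit`.
#' @export
fit_lxt_single_env <- function(data, trait, control = reml_control()) {
  if (dplyr::n_distinct(data$environment) != 1L) {
    abort("fit_lxt_single_env() needs exactly one environment; use fit_lxt_across_env().")
  }
  data <- drop_checks(data)
  spec <- model_spec(
    trait,
    fixed = "rep",
    random = c("block%in%rep", "line", "tester", "line:tester"),
    scope = "single_environment"
  )
  fit_reml(data, spec, control)
}

#' Fit the across-environment line-by-tester model
#'
#' `trait ~ env + rep%in%env` (fixed; environment and replication within
#' environment are treated as fixed) plus random incomplete block, line GCA,
#' tester GCA, line-by-tester SCA, and the interactions of line, tester and
#' line-by-tester with environment. Check entries are excluded.
#'
#' @inheritParams fit_genotype_model
#' @return An `lxt_fit` carrying all seven variance components.
#' @export
fit_lxt_across_env <- function(data, trait, control = reml_control()) {
  if (dplyr::n_distinct(data$environment) < 2L) {
    abort("fit_lxt_across_env() needs at least two environments.")
  }
  data <- drop_checks(data)
  spec <- model_spec(
    trait,
    fixed = c("env", "rep%in%env"),
    random = c("block%in%rep%in%env", "line", "tester", "line:tester",
               "line:env", "tester:env", "line:tester:env"),
    scope = "across_environments"
  )
  fit_reml(data, spec, control)
}

#' Likelihood-ratio test of a single variance component
#'
#' Compares two REML fits of the same data and fixed effects where the
#' reduced model omits exactly one random term. Because the null value lies
#' on the boundary of the parameter space, the statistic is referred to the
#' 50:50 mixture of a point mass at zero and a chi-squared with one degree of
#' freedom.
#'
#' @param full,reduced `lxt_fit` objects, with `reduced` nested in `full`.
#' @return A one-row tibble: dropped term, statistic, p-value, significance.
#' @export
lrt_variance_component <- function(full, reduced) {
  stopifnot(inherits(full, "lxt_fit"), inherits(reduced, "lxt_fit"))
  if (full$spec$response != reduced$spec$response ||
      full$nobs != reduced$nobs) {
    abort("Models must be fitted to the same response and data.")
  }
  if (!identical(full$spec$fixed, reduced$spec$fixed)) {
    abort("Models must share the same fixed effects.")
  }
  dropped <- setdiff(full$spec$random, reduced$spec$random)
  if (!all(reduced$spec$random %in% full$spec$random) ||
      length(dropped) > 1L) {
    abort("`reduced` must omit exactly one random term of `full`.")
  }
  # identical specifications are allowed and give a null test
  stat <- max(0, 2 * (full$logLik - reduced$logLik))
  p <- if (stat <= 0) 1 else 0.5 * pchisq(stat, df = 1, lower.tail = FALSE)
  tibble(term = if (length(dropped)) dropped else NA_character_,
         statistic = stat, p_value = p, signif = star_signif(p))
}

#' Test every variance component of a fitted model by drop-one LRT
#'
#' Refits the model without each random term in turn and applies
#' [lrt_variance_component()].
#'
#' @param data The plot table the model was fitted to.
#' @param fit An `lxt_fit`.
#' @param control A [reml_control()].
#' @return A tibble with one row per random term: variance, LRT statistic,
#'   p-value and significance stars.
#' @export
test_variance_components <- function(data, fit, control = reml_control()) {
  stopifnot(inherits(fit, "lxt_fit"))
  purrr::map_dfr(fit$spec$random, function(term) {
    red_spec <- model_spec(fit$spec$response, fit$spec$fixed,
                           setdiff(fit$spec$random, term), fit$spec$scope)
    red <- fit_reml(data, red_spec, control)
    res <- lrt_variance_component(fit, red)
    res$variance <- fit$components$variance[fit$components$term == term]
    res[, c("term", "variance", "statistic", "p_value", "signif")]
  })
}

#' Entry means (BLUEs) on a common scale
#'
#' Stage one of the two-stage combining-ability analysis: per-entry adjusted
#' means with environment, replication and incomplete block effects removed
#' by sparse least squares (`method = "adjusted"`), or raw arithmetic plot
#' means (`method = "raw"`). Attributes carry the residual variance, the
#' residual degrees of freedom and the average standard error of a
#' difference (SED) between two entry means.
#'
#' @param data A plot table.
#' @param trait Trait column name.
#' @param method `"adjusted"` (default) or `"raw"`.
#' @return A tibble with columns `entry_id`, `entry_kind`, `line_id`,
#'   `tester_id`, `blue`, `n_plots`, plus attributes `sigma2`,
#'   `residual_df`, `sed`.
#' @export
entry_blues <- function(data, trait, method = c("adjusted", "raw")) {
  method <- match.arg(method)
  if (!trait %in% names(data)) {
    abort(sprintf("Trait `%s` is not a column of the data.", trait))
  }
  d <- dplyr::filter(data, !is.na(.data[[trait]]))
  if (nrow(d) == 0L) abort("No non-missing observations for the trait.")
  y <- as.numeric(d[[trait]])
  entry <- factor(d$entry_id)
  meta <- dplyr::distinct(d, .data$entry_id, .data$entry_kind,
                          .data$line_id, .data$tester_id)
  nplots <- dplyr::count(d, .data$entry_id, name = "n_plots")

  if (method == "raw") {
    means <- tapply(y, entry, mean)
    res <- y - means[as.integer(entry)]
    rdf <- length(y) - nlevels(entry)
    s2 <- if (rdf > 0) sum(res^2) / rdf else NA_real_
    blue <- tibble(entry_id = levels(entry), blue = as.numeric(means))
  } else {
    blockg <- interaction(d$environment, d$replicate, d$block, drop = TRUE)
    frame <- data.frame(.y = y, .entry = entry, .blockg = blockg)
    X <- if (nlevels(blockg) > 1L) {
      Matrix::sparse.model.matrix(~ 0 + .entry + .blockg, frame)
    } else {
      Matrix::sparse.model.matrix(~ 0 + .entry, frame)
    }
    beta <- tryCatch({
      ch <- Matrix::Cholesky(Matrix::crossprod(X), perm = TRUE)
      as.numeric(Matrix::solve(ch, Matrix::crossprod(X, y)))
    }, error = function(e) {
      qr.coef(qr(as.matrix(X)), y)
    })
    if (anyNA(beta)) {
      abort("Entry means are not estimable (aliased design columns).")
    }
    fittedv <- as.numeric(X %*% beta)
    rdf <- length(y) - ncol(X)
    s2 <- if (rdf > 0) sum((y - fittedv)^2) / rdf else NA_real_
    is_entry <- startsWith(colnames(X), ".entry")
    block_eff <- c(0, beta[!is_entry]) # reference block at zero
    blue <- tibble(
      entry_id = sub("^\\.entry", "", colnames(X)[is_entry]),
      blue = beta[is_entry] + mean(block_eff)
    )
  }
  out <- blue |>
    dplyr::left_join(meta, by = "entry_id") |>
    dplyr::left_join(nplots, by = "entry_id") |>
    dplyr::select("entry_id", "entry_kind", "line_id", "tester_id",
                  "blue", "n_plots") |>
    dplyr::arrange(.data$entry_id)
  attr(out, "sigma2") <- s2
  attr(out, "residual_df") <- max(0L, rdf)
  attr(out, "sed") <- sqrt(2 * s2 / mean(out$n_plots))
  out
}

#' Serialise a fit to JSON
#'
#' Writes the variance components, REML log-likelihood, fixed-effect
#' estimates and BLUPs of an `lxt_fit` to a JSON file.
#'
#' @param fit An `lxt_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  obj <- list(
    response = fit$spec$response,
    scope = fit$spec$scope,
    components = fit$components,
    residual = fit$residual,
    logLik = fit$logLik,
    converged = fit$converged,
    fixed_effects = fit$fixed_effects,
    blups = fit$ranef,
    residual_df = fit$residual_df,
    nobs = fit$nobs
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
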