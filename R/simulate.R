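#' Variance-regime presets for the trial generator
#'
#' Returns the per-trait variance components and grand means that define the
#' two management regimes the generator emulates: managed drought stress
#' (irrigation withdrawn before flowering) and optimum conditions. The
#' `components` table carries the line GCA, tester GCA, SCA, their
#' environment interactions and the residual variance of the line-by-tester
#' decomposition; the `genotype` table carries the genotype,
#' genotype-by-environment and residual variances of the combined entry
#' model. Values are immutable constants of the preset.
#'
#' @param name `"drought"` or `"optimum"`.
#' @return An object of class `lxt_regime` with elements `name`,
#'   `components`, `genotype`, `means` and `n_env`.
#' @examples
#' regime_presets("drought")$components
#' @export
regime_presets <- function(name = c("drought", "optimum")) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("drought", "optimum")) {
    abort('Unknown regime preset; use "drought" or "optimum".')
  }
  traits <- c("GY", "AD", "SD", "ASI", "PH", "EH")
  if (name == "drought") {
    components <- tibble(
      trait = traits,
      gca_line   = c(0.36, 5.31, 6.18, 0.47, 187.18, 101.59),
      gca_tester = c(0.00, 0.00, 0.06, 0.02, 3.22, 1.74),
      sca        = c(0.00, 0.00, 0.09, 0.00, 0.00, 0.00),
      line_env   = c(0.02, 0.88, 1.32, 0.55, 60.10, 27.36),
      tester_env = c(0.00, 0.17, 0.08, 0.06, 4.58, 1.72),
      sca_env    = c(0.00, 0.13, 0.00, 0.00, 0.00, 0.00),
      residual   = c(1.01, 1.99, 3.51, 1.54, 187.48, 76.65)
    )
    genotype <- tibble(
      trait = traits,
      genotype     = c(0.06, 4.71, 4.98, 0.49, 140.23, 86.29),
      genotype_env = c(0.28, 0.97, 1.68, 0.69, 56.48, 28.48),
      residual     = c(0.50, 2.90, 5.40, 2.20, 260.30, 103.40)
    )
    means <- c(GY = 2.15, AD = 67.56, SD = 70.36, ASI = 2.78,
               PH = 214.71, EH = 116.88)
    n_env <- 3L
  } else {
    components <- tibble(
      trait = traits,
      gca_line   = c(0.228, 4.417, 3.92, 0.203, 129.31, 49.14),
      gca_tester = c(0.015, 0.050, 0.009, 0.000, 4.36, 10.75),
      sca        = c(0.01, 0.00, 0.00, 0.00, 1.07, 0.58),
      line_env   = c(1.031, 3.467, 3.93, 0.252, 208.37, 82.91),
      tester_env = c(0.046, 0.081, 0.23, 0.037, 4.32, 10.45),
      sca_env    = c(0.00, 0.00, 0.00, 0.00, 0.00, 0.00),
      residual   = c(1.85, 4.90, 6.26, 1.38, 199.64, 102.23)
    )
    genotype <- tibble(
      trait = traits,
      genotype     = c(0.31, 4.35, 3.69, 0.21, 127.61, 53.21),
      genotype_env = c(0.58, 1.06, 1.38, 0.19, 133.33, 74.36),
      residual     = c(2.6, 7.5, 9.5, 1.5, 316.6, 121.5)
    )
    means <- c(GY = 7.39, AD = 68.34, SD = 66.05, ASI = 0.70,
               PH = 226.39, EH = 112.16)
    n_env <- 4L
  }
  structure(list(name = name, components = components, genotype = genotype,
                 means = means, n_env = n_env),
            class = "lxt_regime")
}

#' Configuration of a synthetic line-by-tester trial
#'
#' Dimensions default to the reference testcross experiment the generator
#' emulates: 93 + 172 candidate lines in heterotic groups A and B, three
#' single-cross testers per group, each line crossed to the three
#' opposite-group testers (795 testcrosses), six commercial checks, two
#' replications in an alpha-lattice layout, and three drought or four
#' optimum environments. Variance components come from [regime_presets()]
#' and can be overridden per trait.
#'
#' @param regime `"drought"` or `"optimum"`; selects the variance preset and
#'   trait means.
#' @param n_lines Named vector, lines per heterotic group.
#' @param n_testers Named vector, testers per heterotic group.
#' @param testers_per_line Opposite-group testers each line is crossed to.
#' @param n_env Number of environments (default 3 drought / 4 optimum).
#' @param n_rep Replications per environment.
#' @param n_checks Number of check hybrids interconnecting the trials.
#' @param block_size Plots per incomplete block within a replication.
#' @param traits Traits to simulate (subset of GY, AD, SD, ASI, PH, EH).
#'   When both AD and ASI are simulated, SD is built as AD + ASI.
#' @param structure `"line_tester"` draws line, tester, SCA and interaction
#'   effects (the generative counterpart of the across-environment
#'   line-by-tester model); `"genotype"` draws one genotypic effect per
#'   entry plus genotype-by-environment, matching the combined entry model.
#' @param stress_coupling Loading in `[0, 1)` of a shared per-line latent
#'   drought-susceptibility factor on the GY (negatively) and ASI
#'   (positively) line effects; marginal variances are preserved and the
#'   induced genetic correlation is `-stress_coupling^2`.
#' @param env_sd Named vector of the SD of fixed environment shifts per
#'   trait; defaults to the residual SD of each trait.
#' @param rep_var_frac,block_var_frac Replication and incomplete-block
#'   variances as fractions of the residual variance.
#' @param variance_overrides Named list `trait -> named numeric` replacing
#'   preset components, e.g. `list(GY = c(sca = 0.2))`.
#' @param trait_means Optional named vector overriding the preset means.
#' @param seed Master seed; all draws use substreams derived from it.
#' @return An object of class `lxt_sim_config`.
#' @export
sim_config <- function(regime = c("drought", "optimum"),
                       n_lines = c(A = 93L, B = 172L),
                       n_testers = c(A = 3L, B = 3L),
                       testers_per_line = 3L,
                       n_env = NULL, n_rep = 2L, n_checks = 6L,
                       block_size = 30L,
                       traits = c("GY", "AD", "SD", "ASI", "PH", "EH"),
                       structure = c("line_tester", "genotype"),
                       stress_coupling = NULL,
                       env_sd = NULL,
                       rep_var_frac = 0.05, block_var_frac = 0.05,
                       variance_overrides = NULL,
                       trait_means = NULL,
                       seed = 1L) {
  regime <- match.arg(regime)
  structure_kind <- match.arg(structure)
  preset <- regime_presets(regime)
  n_env <- if (is.null(n_env)) preset$n_env else assert_count(n_env, "n_env")
  n_rep <- assert_count(n_rep, "n_rep")
  n_checks <- assert_count(n_checks, "n_checks", min = 0L)
  block_size <- assert_count(block_size, "block_size")
  stopifnot(all(traits %in% preset$components$trait))
  if (is.null(stress_coupling)) {
    stress_coupling <- if (regime == "drought") 0.5 else 0.3
  }
  assert_number(stress_coupling, "stress_coupling", lower = 0, upper = 1)

  components <- preset$components[preset$components$trait %in% traits, ]
  genotype <- preset$genotype[preset$genotype$trait %in% traits, ]
  if (!is.null(variance_overrides)) {
    for (tr in names(variance_overrides)) {
      ov <- variance_overrides[[tr]]
      for (cn in names(ov)) {
        if (cn %in% names(components)) {
          components[components$trait == tr, cn] <- ov[[cn]]
        } else if (cn %in% names(genotype)) {
          genotype[genotype$trait == tr, cn] <- ov[[cn]]
        } else {
          abort(sprintf("Unknown variance component `%s`.", cn))
        }
      }
    }
  }
  means <- preset$means[traits]
  if (!is.null(trait_means)) means[names(trait_means)] <- trait_means
  if (is.null(env_sd)) {
    env_sd <- setNames(sqrt(components$residual), components$trait)
  }

  structure(
    list(regime = regime, n_lines = n_lines, n_testers = n_testers,
         testers_per_line = assert_count(testers_per_line, "testers_per_line"),
         n_env = n_env, n_rep = n_rep, n_checks = n_checks,
         block_size = block_size, traits = traits,
         structure = structure_kind,
         stress_coupling = stress_coupling, env_sd = env_sd,
         rep_var_frac = rep_var_frac, block_var_frac = block_var_frac,
         components = components, genotype = genotype, means = means,
         seed = as.integer(seed)),
    class = "lxt_sim_config"
  )
}

#' Read a simulation configuration from a YAML file
#'
#' @param path Path to a YAML file whose keys match the arguments of
#'   [sim_config()].
#' @return An `lxt_sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  for (key in c("n_lines", "n_testers", "env_sd", "trait_means")) {
    if (!is.null(vals[[key]])) vals[[key]] <- unlist(vals[[key]])
  }
  if (!is.null(vals$variance_overrides)) {
    vals$variance_overrides <- lapply(vals$variance_overrides, unlist)
  }
  do.call(sim_config, vals)
}

#' Simulate a multi-environment line-by-tester trial
#'
#' Draws all random effects independently from zero-mean normal
#' distributions at the configured variances and assembles plot values as
#' `grand mean + environment shift + replication + block + genotypic effects
#' + interactions + residual` — exactly the additive structure the
#' line-by-tester mixed models assume. Entries are laid out in consecutive
#' incomplete blocks of `block_size` plots within each replication, with the
#' plot order re-randomised per replication as in an alpha-lattice. The
#' output is fully reproducible from the master seed via deterministic
#' per-component substreams.
#'
#' @param config An [sim_config()].
#' @return A list of class `lxt_sim`: `data` (a plot table in the
#'   [read_plot_table()] schema), `truth` (the injected effects, the
#'   per-entry genetic values and the variance components used) and
#'   `plan` (the [crossing_plan()]).
#' @export
simulate_trial <- function(config) {
  stopifnot(inherits(config, "lxt_sim_config"))
  ss_counter <- 0L
  ss <- function() {
    ss_counter <<- ss_counter + 1L
    set.seed(substream_seed(config$seed, ss_counter))
  }

  lines <- tibble(
    line_id = sprintf("L%03d", seq_len(sum(config$n_lines))),
    heterotic_group = rep(names(config$n_lines), config$n_lines)
  )
  testers <- tibble(
    tester_id = sprintf("T%d", seq_len(sum(config$n_testers))),
    heterotic_group = rep(names(config$n_testers), config$n_testers)
  )
  plan <- build_crossing_plan(lines, testers, config$testers_per_line)
  crosses <- plan$crosses
  cross_id <- paste(crosses$line_id, crosses$tester_id, sep = ":")
  checks <- if (config$n_checks > 0) {
    sprintf("CHK%d", seq_len(config$n_checks))
  } else character(0)
  entries <- tibble(
    entry_id = c(cross_id, checks),
    entry_kind = rep(c("testcross", "check"),
                     c(length(cross_id), length(checks))),
    line_id = c(crosses$line_id, rep(NA_character_, length(checks))),
    tester_id = c(crosses$tester_id, rep(NA_character_, length(checks)))
  )
  envs <- sprintf("E%d", seq_len(config$n_env))
  n_entry <- nrow(entries)

  # field layout: per environment x replication, a fresh entry order cut
  # into consecutive incomplete blocks
  layout <- purrr::map_dfr(envs, function(e) {
    purrr::map_dfr(seq_len(config$n_rep), function(r) {
      ss()
      ord <- sample.int(n_entry)
      tibble(
        environment = e, replicate = r,
        entry_idx = ord,
        block = sprintf("B%02d", ceiling(seq_len(n_entry) / config$block_size))
      )
    })
  })
  data <- dplyr::bind_cols(
    layout[, c("environment", "replicate", "block")],
    entries[layout$entry_idx, ]
  )
  data$regime <- config$regime
  n_plot <- nrow(data)

  # per-line latent drought susceptibility shared by GY (down) and ASI (up)
  ss()
  u_latent <- rnorm(sum(config$n_lines))
  names(u_latent) <- lines$line_id
  rho <- config$stress_coupling

  want_sd_derived <- all(c("AD", "ASI", "SD") %in% config$traits)
  sim_traits <- if (want_sd_derived) setdiff(config$traits, "SD") else config$traits

  truth_effects <- list()
  entry_value <- tibble(entry_id = entries$entry_id)
  trait_cols <- list()

  for (tr in sim_traits) {
    vc <- config$components[config$components$trait == tr, ]
    gvc <- config$genotype[config$genotype$trait == tr, ]
    mu <- unname(config$means[tr])

    coupled <- config$structure == "line_tester" && rho > 0 &&
      tr %in% c("GY", "ASI")
    draw_line <- function(v) {
      ss()
      z <- rnorm(nrow(lines), 0, 1)
      if (coupled) {
        sgn <- if (tr == "GY") -1 else 1
        sqrt(v) * (sqrt(1 - rho^2) * z + sgn * rho * u_latent)
      } else {
        sqrt(v) * z
      }
    }

    if (config$structure == "line_tester") {
      g_line <- setNames(draw_line(vc$gca_line), lines$line_id)
      ss(); g_tester <- setNames(rnorm(nrow(testers), 0, sqrt(vc$gca_tester)),
                                 testers$tester_id)
      ss(); s_lt <- setNames(rnorm(length(cross_id), 0, sqrt(vc$sca)),
                             cross_id)
      ss(); le <- matrix(rnorm(nrow(lines) * config$n_env, 0,
                               sqrt(vc$line_env)),
                         nrow(lines), config$n_env,
                         dimnames = list(lines$line_id, envs))
      ss(); te <- matrix(rnorm(nrow(testers) * config$n_env, 0,
                               sqrt(vc$tester_env)),
                         nrow(testers), config$n_env,
                         dimnames = list(testers$tester_id, envs))
      ss(); lte <- matrix(rnorm(length(cross_id) * config$n_env, 0,
                                sqrt(vc$sca_env)),
                          length(cross_id), config$n_env,
                          dimnames = list(cross_id, envs))
      g_total <- sqrt(vc$gca_line + vc$gca_tester + vc$sca)
      ge_total <- sqrt(vc$line_env + vc$tester_env + vc$sca_env)
      ss(); chk_g <- setNames(rnorm(length(checks), 0, g_total), checks)
      ss(); chk_ge <- matrix(rnorm(length(checks) * config$n_env, 0, ge_total),
                             length(checks), config$n_env,
                             dimnames = list(checks, envs))
      gen_main <- c(g_line[crosses$line_id] + g_tester[crosses$tester_id] +
                      s_lt, chk_g)
      names(gen_main) <- entries$entry_id
      gen_env <- function(entry, env) {
        is_chk <- is.na(entries$line_id[match(entry, entries$entry_id)])
        out <- numeric(length(entry))
        tc <- !is_chk
        out[tc] <- le[cbind(entries$line_id[match(entry[tc], entries$entry_id)],
                            env[tc])] +
          te[cbind(entries$tester_id[match(entry[tc], entries$entry_id)],
                   env[tc])] +
          lte[cbind(entry[tc], env[tc])]
        if (any(is_chk)) out[is_chk] <- chk_ge[cbind(entry[is_chk], env[is_chk])]
        out
      }
      resid_sd <- sqrt(vc$residual)
      truth_effects[[tr]] <- list(
        line = tibble(line_id = lines$line_id, effect = unname(g_line)),
        tester = tibble(tester_id = testers$tester_id,
                        effect = unname(g_tester)),
        sca = tibble(line_id = crosses$line_id,
                     tester_id = crosses$tester_id, effect = unname(s_lt))
      )
    } else {
      ss(); gmain <- setNames(rnorm(n_entry, 0, sqrt(gvc$genotype)),
                              entries$entry_id)
      ss(); gemat <- matrix(rnorm(n_entry * config$n_env, 0,
                                  sqrt(gvc$genotype_env)),
                            n_entry, config$n_env,
                            dimnames = list(entries$entry_id, envs))
      if (coupled) {
        # re-draw the testcross part with the latent factor on the line parent
        ss()
        z <- rnorm(n_entry)
        sgn <- if (tr == "GY") -1 else 1
        u_entry <- c(u_latent[crosses$line_id],
                     rep(0, length(checks)))
        gmain <- setNames(
          sqrt(gvc$genotype) * (sqrt(1 - rho^2) * z + sgn * rho * u_entry),
          entries$entry_id
        )
      }
      gen_main <- gmain
      gen_env <- function(entry, env) gemat[cbind(entry, env)]
      resid_sd <- sqrt(gvc$residual)
      truth_effects[[tr]] <- list(
        genotype = tibble(entry_id = entries$entry_id, effect = unname(gmain))
      )
    }

    ss(); env_shift <- setNames(rnorm(config$n_env, 0,
                                      unname(config$env_sd[tr])), envs)
    ss(); rep_eff <- matrix(rnorm(config$n_env * config$n_rep, 0,
                                  sqrt(config$rep_var_frac) * resid_sd),
                            config$n_env, config$n_rep,
                            dimnames = list(envs, as.character(seq_len(config$n_rep))))
    blocks <- unique(data[, c("environment", "replicate", "block")])
    ss(); blk_eff <- setNames(
      rnorm(nrow(blocks), 0, sqrt(config$block_var_frac) * resid_sd),
      paste(blocks$environment, blocks$replicate, blocks$block)
    )
    ss(); resid <- rnorm(n_plot, 0, resid_sd)

    vals <- mu + env_shift[data$environment] +
      rep_eff[cbind(data$environment, as.character(data$replicate))] +
      blk_eff[paste(data$environment, data$replicate, data$block)] +
      gen_main[data$entry_id] +
      gen_env(data$entry_id, data$environment) +
      resid
    trait_cols[[tr]] <- unname(vals)
    entry_value[[tr]] <- unname(gen_main[entry_value$entry_id]) +
      (if (tr %in% names(config$means)) mu else 0)
  }

  for (tr in names(trait_cols)) data[[tr]] <- trait_cols[[tr]]
  if (want_sd_derived) {
    data$SD <- data$AD + data$ASI
    entry_value$SD <- entry_value$AD + entry_value$ASI
  }
  data <- data[, c("environment", "regime", "replicate", "block", "entry_id",
                   "entry_kind", "line_id", "tester_id",
                   intersect(config$traits, names(data)))]

  structure(
    list(data = as_tibble(data),
         truth = list(effects = truth_effects, entry_value = entry_value,
                      components = config$components,
                      genotype = config$genotype, means = config$means),
         plan = plan, config = config),
    class = "lxt_sim"
  )
}

#' @export
print.lxt_sim <- function(x, ...) {
  cat(sprintf(
    "<lxt_sim> %s regime: %d plots (%d entries x %d env x %d rep), traits: %s\n",
    x$config$regime, nrow(x$data),
    dplyr::n_distinct(x$data$entry_id), x$config$n_env, x$config$n_rep,
    paste(x$config$traits, collapse = ", ")
  ))
  invisible(x)
}
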