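# Independent oracles used to check the package implementations.
# These deliberately avoid the code paths they verify: closed-form ANOVA
# method-of-moments estimators, a profile-likelihood grid search evaluated
# from the REML density directly, a bordered (KKT) normal-equations solve
# with explicit constraint rows, and a hand-rolled breadth-first search.

# --- balanced-design ANOVA estimators -------------------------------------

# one-way random genotype layout: g genotypes x r reps
oneway_anova_components <- function(y, gen, r) {
  a <- anova(lm(y ~ gen))
  msg <- a["gen", "Mean Sq"]
  mse <- a["Residuals", "Mean Sq"]
  list(sigma2_g = max(0, (msg - mse) / r), sigma2_e = mse)
}

# genotype x environment with r reps per cell; env fixed, genotype and
# genotype-by-environment random
twoway_anova_components <- function(y, gen, env, r) {
  ne <- nlevels(factor(env))
  a <- anova(lm(y ~ env + gen + gen:env))
  msg <- a["gen", "Mean Sq"]
  msge <- a["env:gen", "Mean Sq"]
  mse <- a["Residuals", "Mean Sq"]
  list(
    sigma2_g = max(0, (msg - msge) / (r * ne)),
    sigma2_ge = max(0, (msge - mse) / r),
    sigma2_e = mse
  )
}

# --- REML profile-likelihood grid oracle ----------------------------------

# REML log-likelihood profiled over the residual variance, as a function of
# the variance ratios phi_k = sigma2_k / sigma2_e
reml_profile_ll <- function(phi, y, X, Zs) {
  n <- length(y)
  p <- ncol(X)
  V0 <- diag(n)
  for (k in seq_along(Zs)) V0 <- V0 + phi[k] * tcrossprod(Zs[[k]])
  ch <- chol(V0)
  ldV <- 2 * sum(log(diag(ch)))
  Vi <- chol2inv(ch)
  XtVX <- crossprod(X, Vi %*% X)
  ldX <- determinant(XtVX, logarithm = TRUE)$modulus[1]
  ViX <- Vi %*% X
  P0y <- Vi %*% y - ViX %*% solve(XtVX, crossprod(X, Vi %*% y))
  ypy <- sum(y * P0y)
  -0.5 * ((n - p) * log(2 * pi) + ldV + ldX +
            (n - p) * log(ypy / (n - p)) + (n - p))
}

# iteratively refined grid search over the variance ratios; returns the
# variance components at the grid optimum
reml_grid_oracle <- function(y, X, Zs, upper, n_grid = 13, n_refine = 7) {
  k <- length(Zs)
  lo <- rep(0, k)
  hi <- upper
  best <- NULL
  for (it in seq_len(n_refine)) {
    grids <- lapply(seq_len(k), function(i) seq(lo[i], hi[i],
                                                length.out = n_grid))
    pts <- as.matrix(expand.grid(grids))
    lls <- apply(pts, 1, function(p) reml_profile_ll(p, y, X, Zs))
    best <- pts[which.max(lls), ]
    step <- (hi - lo) / (n_grid - 1)
    lo <- pmax(0, best - step)
    hi <- best + step
  }
  # residual variance at the optimum
  n <- length(y)
  p <- ncol(X)
  V0 <- diag(n)
  for (j in seq_len(k)) V0 <- V0 + best[j] * tcrossprod(Zs[[j]])
  Vi <- chol2inv(chol(V0))
  XtVX <- crossprod(X, Vi %*% X)
  P0y <- Vi %*% y - Vi %*% X %*% solve(XtVX, crossprod(X, Vi %*% y))
  s2e <- sum(y * P0y) / (n - p)
  list(phi = unname(best), sigma2 = unname(best) * s2e, sigma2_e = s2e,
       logLik = reml_profile_ll(best, y, X, Zs))
}

# --- bordered KKT solve for the GCA/SCA decomposition ----------------------

# hand-rolled BFS over the bipartite line-tester graph; returns component
# membership for every line and tester label
bfs_components <- function(line, tester) {
  nodes <- c(paste0("L.", unique(line)), paste0("T.", unique(tester)))
  adj <- list()
  for (i in seq_along(line)) {
    a <- paste0("L.", line[i])
    b <- paste0("T.", tester[i])
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  comp <- setNames(rep(NA_integer_, length(nodes)), nodes)
  cid <- 0L
  for (start in nodes) {
    if (!is.na(comp[start])) next
    cid <- cid + 1L
    queue <- start
    comp[start] <- cid
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      for (w in adj[[v]]) {
        if (is.na(comp[w])) {
          comp[w] <- cid
          queue <- c(queue, w)
        }
      }
    }
  }
  comp
}

# explicit constraint-row (bordered) least squares for
# mean(i, j) = mu + g_i + t_j over realised crosses, with per-component
# sum-to-zero constraints on lines and one overall tester constraint
gca_kkt_oracle <- function(line, tester, y, error_variance = NULL) {
  Lf <- factor(line)
  Tf <- factor(tester)
  L <- nlevels(Lf)
  Tn <- nlevels(Tf)
  p <- 1L + L + Tn
  Z <- cbind(1, model.matrix(~ 0 + Lf), model.matrix(~ 0 + Tf))
  comp <- bfs_components(as.character(Lf), as.character(Tf))
  line_comp <- unname(comp[paste0("L.", levels(Lf))])
  ncomp <- max(comp)
  C <- matrix(0, ncomp + 1L, p)
  for (cc in seq_len(ncomp)) C[cc, 1L + which(line_comp == cc)] <- 1
  C[ncomp + 1L, 1L + L + seq_len(Tn)] <- 1
  A <- rbind(cbind(crossprod(Z), t(C)),
             cbind(C, matrix(0, nrow(C), nrow(C))))
  rhs <- c(crossprod(Z, y), rep(0, nrow(C)))
  sol <- solve(A, rhs)
  beta <- sol[seq_len(p)]
  fitted <- as.numeric(Z %*% beta)
  out <- list(
    mu = beta[1],
    gca_line = setNames(beta[1 + seq_len(L)], levels(Lf)),
    gca_tester = setNames(beta[1 + L + seq_len(Tn)], levels(Tf)),
    sca = y - fitted
  )
  if (!is.null(error_variance)) {
    B <- solve(A)[seq_len(p), seq_len(p)]
    Vb <- error_variance * (B %*% crossprod(Z) %*% t(B))
    out$se <- sqrt(pmax(0, diag(Vb)))
  }
  out
}

# brute-force leave-one-out: independently re-solve the bordered system per
# fold and predict the held-out cross from GCA alone
loo_bruteforce <- function(line, tester, y) {
  n <- length(y)
  pred <- rep(NA_real_, n)
  for (h in seq_len(n)) {
    ok <- setdiff(seq_len(n), h)
    # skip folds whose deletion isolates the held-out line or tester side
    fit <- tryCatch(gca_kkt_oracle(line[ok], tester[ok], y[ok]),
                    error = function(e) NULL)
    if (is.null(fit)) next
    if (!line[h] %in% names(fit$gca_line) ||
        !tester[h] %in% names(fit$gca_tester)) next
    comp_full <- bfs_components(line[ok], tester[ok])
    if (comp_full[paste0("L.", line[h])] !=
        comp_full[paste0("T.", tester[h])]) next
    pred[h] <- fit$mu + fit$gca_line[line[h]] + fit$gca_tester[tester[h]]
  }
  pred
}

# --- small fixtures --------------------------------------------------------

make_lines <- function(nA, nB) {
  tibble::tibble(
    line_id = sprintf("L%03d", seq_len(nA + nB)),
    heterotic_group = rep(c("A", "B"), c(nA, nB))
  )
}

make_testers <- function(nA = 3, nB = 3) {
  tibble::tibble(
    tester_id = sprintf("T%d", seq_len(nA + nB)),
    heterotic_group = rep(c("A", "B"), c(nA, nB))
  )
}

# entry means simulated directly at the mean level: mu + g_i + t_j + s_ij + e
sim_entry_means <- function(plan, v_line = 1, v_tester = 0.2, v_sca = 0,
                            v_err = 0.1, mu = 5, seed = 1) {
  set.seed(seed)
  lines <- plan$lines$line_id
  testers <- plan$testers$tester_id
  g <- setNames(rnorm(length(lines), 0, sqrt(v_line)), lines)
  t <- setNames(rnorm(length(testers), 0, sqrt(v_tester)), testers)
  s <- rnorm(nrow(plan$crosses), 0, sqrt(v_sca))
  e <- rnorm(nrow(plan$crosses), 0, sqrt(v_err))
  tbl <- tibble::tibble(
    line_id = plan$crosses$line_id,
    tester_id = plan$crosses$tester_id,
    blue = mu + g[plan$crosses$line_id] + t[plan$crosses$tester_id] + s + e
  )
  list(tbl = tbl, g = g, t = t, s = s, mu = mu)
}

# paper-style small plan: two heterotic groups with disjoint tester sets
small_plan <- function(nA = 6, nB = 9, seed = NULL) {
  build_crossing_plan(make_lines(nA, nB), make_testers(), 3L)
}

# quick balanced one-way dataset in plot-table form
oneway_data <- function(g = 12, r = 4, vg = 1, ve = 0.5, seed = 1) {
  set.seed(seed)
  gen <- factor(rep(sprintf("G%02d", seq_len(g)), each = r))
  y <- rnorm(g, 0, sqrt(vg))[as.integer(gen)] + rnorm(g * r, 0, sqrt(ve))
  tibble::tibble(
    environment = "E1", regime = "drought",
    replicate = rep(seq_len(r), times = g),
    block = "B1",
    entry_id = as.character(gen), entry_kind = "testcross",
    line_id = as.character(gen), tester_id = "T1",
    y = y
  )
}
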