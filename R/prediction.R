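#' GCA-based prediction of a hybrid's performance
#'
#' `prediction = grand_mean + gca(line) + gca(tester)` — no SCA term, so the
#' prediction reflects what the parents' general combining abilities alone
#' say about the cross.
#'
#' @param ca An `lxt_ca` from [estimate_gca_sca()].
#' @param line_id,tester_id Parent identifiers; vectorised in parallel.
#' @return Predicted trait value(s).
#' @export
predict_hybrid <- function(ca, line_id, tester_id) {
  stopifnot(inherits(ca, "lxt_ca"))
  gl <- setNames(ca$gca_line$effect, ca$gca_line$line_id)
  gt <- setNames(ca$gca_tester$effect, ca$gca_tester$tester_id)
  bad_l <- setdiff(unique(line_id), names(gl))
  bad_t <- setdiff(unique(tester_id), names(gt))
  if (length(bad_l) || length(bad_t)) {
    abort(paste0("Unknown parent(s): ",
                 paste(c(bad_l, bad_t), collapse = ", ")))
  }
  ca$grand_mean + unname(gl[line_id]) + unname(gt[tester_id])
}

#' Leave-one-hybrid-out cross-validation of GCA-based prediction
#'
#' For each testcross hybrid in turn, the additive decomposition
#' `mean(i, j) = mu + g_i + g_j` is re-estimated from all remaining hybrids
#' and the held-out hybrid is predicted as `mu + g_i + g_j`. The pooled
#' Pearson correlation between observed and predicted values, r(GCA, TCP),
#' measures how far hybrid performance is predictable from general combining
#' ability alone. Hybrids whose removal disconnects the line-tester graph
#' (bridge crosses) are skipped with a warning rather than imputed. The
#' procedure is deterministic.
#'
#' @inheritParams estimate_gca_sca
#' @param min_hybrids Minimum number of hybrids required (default 10).
#' @return An object of class `lxt_cv`: a tibble of per-hybrid observed and
#'   predicted values, the pooled Pearson `r`, the number of predicted
#'   hybrids and the number skipped.
#' @export
loo_gca_cv <- function(entry_means, value = "blue", plan = NULL,
                       min_hybrids = 10L) {
  entry_means <- as_tibble(entry_means)
  entry_means <- dplyr::filter(entry_means, !is.na(.data[[value]]),
                               !is.na(.data$line_id), !is.na(.data$tester_id))
  n <- nrow(entry_means)
  if (n < min_hybrids) {
    abort(sprintf("Need at least %d hybrids; got %d.", min_hybrids, n))
  }
  if (!is.null(plan)) stopifnot(inherits(plan, "crossing_plan"))

  y <- entry_means[[value]]
  des <- ca_design(entry_means$line_id, entry_means$tester_id)
  M <- des$M
  A <- crossprod(M)
  b <- crossprod(M, y)

  # crosses that are bridges of the bipartite graph cannot be left out
  edges <- rbind(paste0("L.", entry_means$line_id),
                 paste0("T.", entry_means$tester_id))
  g <- igraph::make_graph(as.vector(edges), directed = FALSE)
  bridge_idx <- as.integer(igraph::bridges(g))
  if (length(bridge_idx)) {
    warn(sprintf(
      "%d hybrid(s) skipped: removing them disconnects the crossing design.",
      length(bridge_idx)
    ))
  }
  folds <- setdiff(seq_len(n), bridge_idx)
  if (length(folds) < 3L) {
    abort("Insufficient data: fewer than 3 hybrids are predictable.")
  }

  pred <- rep(NA_real_, n)
  for (h in folds) {
    m_h <- M[h, ]
    A_h <- A - tcrossprod(m_h)
    b_h <- b - m_h * y[h]
    alpha_h <- tryCatch(solve(A_h, b_h), error = function(e) NULL)
    if (is.null(alpha_h)) next
    pred[h] <- sum(m_h * alpha_h)
  }
  ok <- !is.na(pred)
  res <- tibble(
    line_id = entry_means$line_id, tester_id = entry_means$tester_id,
    observed = y, predicted = pred
  )
  structure(
    list(predictions = res,
         r = cor(y[ok], pred[ok]),
         n_predicted = sum(ok),
         n_skipped = n - sum(ok),
         value = value),
    class = "lxt_cv"
  )
}

#' @export
print.lxt_cv <- function(x, ...) {
  cat(sprintf("<lxt_cv> r(GCA, TCP) = %.3f over %d hybrids (%d skipped)\n",
              x$r, x$n_predicted, x$n_skipped))
  invisible(x)
}

#' Write cross-validation results to CSV and JSON
#'
#' @param cv An `lxt_cv`.
#' @param csv_path,json_path Output paths; either may be `NULL` to skip.
#' @return Invisibly, the paths written.
#' @export
write_cv_results <- function(cv, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(cv, "lxt_cv"))
  if (!is.null(csv_path)) {
    readr::write_csv(cv$predictions, csv_path, na = "NA", progress = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(r = cv$r, n_predicted = cv$n_predicted, n_skipped = cv$n_skipped),
      json_path, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(c(csv_path, json_path))
}
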