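#' Pearson correlations among traits, within or across management regimes
#'
#' Computes the trait-trait Pearson correlation matrix over entry means with
#' pairwise-complete handling of missing cells, two-sided t-test p-values and
#' the conventional significance stars. In `"across_regimes"` mode each
#' trait appears once per regime (suffixed `_DS` for drought and `_OPT` for
#' optimum), so correlations between the same trait under stress and
#' non-stress management are available — the comparison breeders use to
#' judge whether secondary traits are reliable selection indices.
#'
#' @param data Entry means, one row per entry (and per regime when a
#'   `regime` column is present), with trait columns.
#' @param traits Character vector of trait columns; defaults to those of
#'   `GY`, `AD`, `SD`, `ASI`, `PH`, `EH` present in the data.
#' @param mode `"within_regime"` or `"across_regimes"`.
#' @param regime When `mode = "within_regime"` and the data hold several
#'   regimes, which one to use.
#' @return An object of class `lxt_cormat` with symmetric matrices `r`, `p`
#'   and `n`.
#' @export
correlate_traits <- function(data, traits = NULL,
                             mode = c("within_regime", "across_regimes"),
                             regime = NULL) {
  mode <- match.arg(mode)
  data <- as_tibble(data)
  if (is.null(traits)) {
    traits <- intersect(c("GY", "AD", "SD", "ASI", "PH", "EH"), names(data))
  }
  if (length(traits) < 2L && mode == "within_regime") {
    abort("Need at least two trait columns.")
  }
  missing_traits <- setdiff(traits, names(data))
  if (length(missing_traits)) {
    abort(paste0("Trait column(s) not found: ",
                 paste(missing_traits, collapse = ", ")))
  }

  if (mode == "within_regime") {
    if ("regime" %in% names(data) && dplyr::n_distinct(data$regime) > 1L) {
      if (is.null(regime)) {
        abort("Several regimes present: supply `regime` or use mode = \"across_regimes\".")
      }
      data <- dplyr::filter(data, .data$regime == !!regime)
    }
    wide <- data[, traits, drop = FALSE]
  } else {
    if (!"regime" %in% names(data) || dplyr::n_distinct(data$regime) < 2L) {
      abort("mode = \"across_regimes\" needs a `regime` column with >= 2 regimes.")
    }
    if (!"entry_id" %in% names(data)) {
      abort("mode = \"across_regimes\" needs an `entry_id` column to match entries.")
    }
    suffix <- function(x) {
      dplyr::case_match(x, "drought" ~ "DS", "optimum" ~ "OPT",
                        .default = toupper(x))
    }
    long <- data |>
      dplyr::select("entry_id", "regime", dplyr::all_of(traits)) |>
      tidyr::pivot_longer(dplyr::all_of(traits), names_to = "trait") |>
      dplyr::mutate(label = paste0(.data$trait, "_", suffix(.data$regime)))
    wide <- long |>
      dplyr::select("entry_id", "label", "value") |>
      tidyr::pivot_wider(names_from = "label", values_from = "value") |>
      dplyr::select(-"entry_id")
  }

  labs <- names(wide)
  k <- length(labs)
  r <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  warned_constant <- FALSE
  for (i in seq_len(k)) {
    for (j in i:k) {
      x <- wide[[i]]
      y <- wide[[j]]
      ok <- !is.na(x) & !is.na(y)
      nn <- sum(ok)
      nmat[i, j] <- nmat[j, i] <- nn
      if (i == j) r[i, j] <- 1 # unit diagonal by convention
      if (nn < 3L) next
      if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
        if (i != j && !warned_constant) {
          warn("Constant trait encountered; its correlations are undefined.")
          warned_constant <- TRUE
        }
        next
      }
      rr <- cor(x[ok], y[ok])
      r[i, j] <- r[j, i] <- rr
      if (i == j) {
        p[i, j] <- 0
      } else {
        tt <- rr * sqrt((nn - 2) / max(1 - rr^2, .Machine$double.eps))
        pp <- 2 * pt(-abs(tt), df = nn - 2)
        p[i, j] <- p[j, i] <- pp
      }
    }
  }
  structure(list(r = r, p = p, n = nmat, mode = mode), class = "lxt_cormat")
}

#' @export
print.lxt_cormat <- function(x, digits = 2, ...) {
  cat(sprintf("<lxt_cormat> %s, %d variables\n", x$mode, ncol(x$r)))
  print(round(x$r, digits))
  invisible(x)
}

#' Write a correlation matrix to CSV
#'
#' @param cm An `lxt_cormat`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cormat_csv <- function(cm, path) {
  stopifnot(inherits(cm, "lxt_cormat"))
  out <- as_tibble(cm$r, rownames = "trait")
  readr::write_csv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}
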