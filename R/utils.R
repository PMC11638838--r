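# internal helpers shared across modules

# significance stars at the conventional 0.05 / 0.01 / 0.001 cut points
star_signif <- function(p) {
  out <- rep("", length(p))
  out[!is.na(p) & p < 0.05] <- "*"
  out[!is.na(p) & p < 0.01] <- "**"
  out[!is.na(p) & p < 0.001] <- "***"
  out[is.na(p)] <- NA_character_
  out
}

assert_number <- function(x, name, lower = -Inf, upper = Inf, strict = FALSE) {
  if (!is.numeric(x) || anyNA(x)) {
    abort(sprintf("`%s` must be numeric and non-missing.", name))
  }
  bad <- if (strict) x <= lower | x >= upper else x < lower | x > upper
  if (any(bad)) {
    abort(sprintf(
      "`%s` must be %s %s and %s %s (got %s).",
      name, if (strict) ">" else ">=", format(lower),
      if (strict) "<" else "<=", format(upper),
      paste(format(x[bad]), collapse = ", ")
    ))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

# canonical plot-table column behind each short model-term token
.term_aliases <- c(
  env = "environment", environment = "environment",
  rep = "replicate", replicate = "replicate",
  block = "block",
  line = "line_id", tester = "tester_id",
  genotype = "entry_id", entry = "entry_id", hybrid = "entry_id"
)

resolve_term_column <- function(token, data) {
  col <- unname(.term_aliases[token])
  if (is.na(col)) col <- token
  if (!col %in% names(data)) {
    abort(sprintf("Model term `%s` does not resolve to a column of the data.", token))
  }
  col
}

# deterministic substream seeds derived from one master seed (kept < 2^31)
substream_seed <- function(master, k) {
  as.integer((as.double(master) + 7919 * as.double(k)) %% 2147483629)
}
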