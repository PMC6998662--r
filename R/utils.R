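# internal helpers shared across modules

# Derive a reproducible 31-bit child seed from a global seed and a label, so
# each module / window / bootstrap iteration gets an independent stream.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, min, max))
  }
  invisible(x)
}

check_enum <- function(x, levels, col, allow_na = FALSE) {
  bad <- !(x %in% levels)
  if (allow_na) bad <- bad & !is.na(x)
  if (any(bad)) {
    abort(sprintf(
      "column `%s` has invalid value(s): %s (allowed: %s)",
      col, paste(unique(x[bad]), collapse = ", "),
      paste(levels, collapse = ", ")
    ))
  }
  invisible(x)
}

# standardized mean difference for a numeric covariate between two groups
smd <- function(x_case, x_control) {
  s <- sqrt((var(x_case) + var(x_control)) / 2)
  if (!is.finite(s) || s == 0) return(0)
  (mean(x_case) - mean(x_control)) / s
}

is_smoker <- function(smoking) smoking %in% c("current", "former")
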