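# Internal helpers shared across modules.

# Run `code` with the RNG seeded to `seed`, restoring the caller's RNG state
# afterwards so package functions never disturb the user's random stream.
local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer.")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seeds (kept below 2^31) derived from one master seed.
derive_seeds <- function(master, n) {
  local_seed(master, sample.int(.Machine$integer.max - 1L, n))
}

# Right-continuous step-function evaluation: value of the cumulative curve
# at each t.  `left = TRUE` evaluates the left limit (value just before t).
step_eval <- function(times, values, t, left = FALSE, init = 0) {
  if (length(times) == 0L) return(rep(init, length(t)))
  idx <- findInterval(t, times, left.open = left)
  out <- c(init, values)[idx + 1L]
  out
}

# CSV writer that round-trips doubles exactly (%.17g), so a stage re-run
# from persisted intermediates reproduces downstream outputs bit-identically.
write_csv_precise <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      x <- sprintf("%.17g", out[[j]])
      x[is.na(out[[j]])] <- NA_character_
      out[[j]] <- x
    }
  }
  write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

# Validation helper: raise a classed error naming the offending config field.
abort_field <- function(field, msg) {
  abort(sprintf("Invalid configuration field `%s`: %s", field, msg),
        class = "landmarker_config_error", field = field)
}

assert_prob <- function(x, field) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    abort_field(field, "must be a probability in [0, 1].")
  }
}

assert_nonneg <- function(x, field) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0)) {
    abort_field(field, "must be non-negative.")
  }
}

# Signalled when a patient has no usable pre-landmark measurement history.
missing_history <- function(vars) {
  structure(
    class = c("landmarker_missing_history", "error", "condition"),
    list(message = sprintf("no pre-landmark measurement for: %s",
                           paste(vars, collapse = ", ")),
         call = NULL, vars = vars)
  )
}
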