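# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single non-missing integer.")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a small stream index, keeping the
# result inside the 32-bit integer range expected by set.seed().
child_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 2039L + as.integer(stream)
}

assert_scalar_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(paste0("`", name, "` must be a single number."))
  }
  ok <- if (strict) x > min else x >= min
  if (!ok) {
    abort(paste0("`", name, "` must be ", if (strict) "> " else ">= ", min, "."))
  }
  invisible(x)
}

assert_data_frame <- function(x, name, cols = character()) {
  if (!is.data.frame(x)) abort(paste0("`", name, "` must be a data frame."))
  missing <- setdiff(cols, names(x))
  if (length(missing)) {
    abort(paste0(
      "`", name, "` is missing required column(s): ",
      paste(missing, collapse = ", "), "."
    ))
  }
  invisible(x)
}

# Full-precision numeric formatting so written tracks survive a read round-trip.
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (v == trunc(v) && abs(v) < 2^53) {
      sprintf("%.0f", v)
    } else {
      sprintf("%.17g", v)
    }
  }, character(1))
  out
}
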