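# Classed conditions so callers (and the CLI) can distinguish bad arguments
# from violated physical preconditions and malformed files.

abort_input <- function(msg, ...) {
  abort(msg, class = c("gtpasekin_input_error", "gtpasekin_error"), ...)
}

abort_validity <- function(msg, ...) {
  abort(msg, class = c("gtpasekin_validity_error", "gtpasekin_error"), ...)
}

abort_format <- function(msg, ...) {
  abort(msg, class = c("gtpasekin_format_error", "gtpasekin_error"), ...)
}

abort_mode <- function(msg, ...) {
  abort(msg, class = c("gtpasekin_mode_error", "gtpasekin_error"), ...)
}

abort_affinity <- function(msg, ...) {
  abort(msg, class = c("gtpasekin_affinity_error", "gtpasekin_error"), ...)
}

abort_placement <- function(msg, ...) {
  abort(msg, class = c("gtpasekin_placement_error", "gtpasekin_error"), ...)
}

check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE,
                         allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    abort_input(sprintf("`%s` must be supplied.", name))
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_input(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_min && x <= min) {
    abort_input(sprintf("`%s` must be > %g (got %g).", name, min, x))
  }
  if (!strict_min && x < min) {
    abort_input(sprintf("`%s` must be >= %g (got %g).", name, min, x))
  }
  if (x > max) {
    abort_input(sprintf("`%s` must be <= %g (got %g).", name, max, x))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x)) {
    abort_input(sprintf("`%s` must be a whole number.", name))
  }
  if (x < min) abort_input(sprintf("`%s` must be >= %d.", name, min))
  invisible(as.integer(x))
}

# Seeded RNG scope: a generator called twice with the same seed must return
# bitwise-identical output, and must not disturb the caller's RNG stream.
with_seed_scope <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  check_count(seed, "seed", min = 0L)
  withr::with_seed(as.integer(seed), code)
}
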