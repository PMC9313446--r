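# Internal helpers: classed conditions and small validators.

stop_param <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("drivelapse_param_error", "drivelapse_error")))
}

stop_io <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("drivelapse_io_error", "drivelapse_error")))
}

stop_format <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("drivelapse_format_error", "drivelapse_error")))
}

stop_lookup <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("drivelapse_lookup_error", "drivelapse_error")))
}

stop_empty_group <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("drivelapse_empty_group_error", "drivelapse_error")))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

is_scalar_count <- function(x) {
  is_scalar_number(x) && x >= 0 && abs(x - round(x)) < 1e-9
}

# Deterministic child seed for participant `index` under cohort seed `seed`.
# Plain 32-bit-safe arithmetic so the mapping is portable and documented.
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483629)
}

# Evaluate `expr` under a local RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  if (!is_scalar_count(seed)) stop_param("seed must be a single non-negative integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
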