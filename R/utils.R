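# Internal helpers: structured error conditions and local RNG scoping.

#' @keywords internal
fs_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "fibroscore_error"),
                      call = call))
}

# Evaluate `code` under a fixed seed without disturbing the caller's RNG
# stream.  All exported generators route their randomness through this.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    fs_stop("`seed` must be a single integer", "invalid_argument")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a per-stage child seed from a run seed; keeps results < 2^31 so the
# value is always a valid R integer.
#' @keywords internal
child_seed <- function(seed, stage) {
  (as.integer(seed) * 1009L + as.integer(stage) * 97L) %% 2147483629L
}

#' @keywords internal
is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == round(x) && x >= min
}
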