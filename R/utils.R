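#' @importFrom rlang abort warn
NULL

# Internal validation helper: abort with a classed condition so callers and
# tests can distinguish configuration vs validation vs IO failures.
stop_punctate <- function(msg, class) {
  rlang::abort(msg, class = c(class, "punctate_error"))
}

assert_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop_punctate(sprintf("`%s` must be a positive scalar, got %s", name,
                          paste(format(x), collapse = ",")),
                  "punctate_validation_error")
  }
  invisible(x)
}

# Derive a stream-specific child seed from a master seed. Kept below 2^31-1.
child_seed <- function(seed, stream) {
  (as.integer(seed) * 7919L + as.integer(stream) * 104729L) %% 2147483647L
}

# Population (divide-by-n) standard deviation; the control-threshold rule is
# defined on the full voxel population of the control stacks.
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}
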