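# Internal helpers: seeded evaluation that does not disturb the caller's RNG
# stream, deterministic sub-seed derivation, and condition constructors used
# by the command-line layer to map error classes to exit codes.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Deterministic integer sub-seed in [1, 2^31 - 2]; exact in double arithmetic
# because all intermediates stay below 2^53.
derive_seed <- function(base_seed, salt) {
  base_seed <- as.numeric(base_seed) %% 2147483647
  salt <- as.numeric(salt) %% 2147483647
  as.integer(((base_seed * 48271 + salt * 16807 + 1) %% 2147483646) + 1)
}

stop_validation <- function(msg, call = sys.call(-1)) {
  stop(structure(class = c("aucpr_validation_error", "error", "condition"),
                 list(message = msg, call = call)))
}

stop_numerical <- function(msg, data = list(), call = sys.call(-1)) {
  stop(structure(class = c("aucpr_numerical_error", "error", "condition"),
                 c(list(message = msg, call = call), data)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
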