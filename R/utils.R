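`%||%` <- function(a, b) if (is.null(a)) b else a

# population-variance convention (divide by n), used for standardization
# and for scaling simulated variance components
pop_var <- function(x) mean((x - mean(x))^2)

pop_sd <- function(x) sqrt(pop_var(x))

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}

stop2 <- function(...) stop(..., call. = FALSE)

warn2 <- function(...) warning(..., call. = FALSE)

# deterministic sub-seed derivation: keeps every derived seed a valid
# 32-bit integer whatever the user seed is
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000003 * offset) %% 2147483629)
}
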