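# Internal numeric helpers shared across the package.

logit <- function(p) log(p / (1 - p))

invlogit <- function(x) 1 / (1 + exp(-x))

# log10(x + 1): covariate transform for abundances, defined at zero.
log10p1 <- function(x) log10(x + 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mr <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn_mr <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
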