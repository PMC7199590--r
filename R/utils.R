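# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Classed error constructors
#'
#' Validation, schema, configuration and degeneracy failures are raised as
#' classed conditions so callers (and tests) can distinguish them from
#' programming errors.
#' @noRd
stop_rdw <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "rdwards_error")))
}
stop_validation <- function(fmt, ...) stop_rdw("rdwards_validation_error", fmt, ...)
stop_schema     <- function(fmt, ...) stop_rdw("rdwards_schema_error", fmt, ...)
stop_config     <- function(fmt, ...) stop_rdw("rdwards_config_error", fmt, ...)
stop_degenerate <- function(fmt, ...) stop_rdw("rdwards_degenerate_error", fmt, ...)

# Deterministic substream seed derived from a master seed.  Each sampling
# block of the generator owns one substream so that enlarging the cohort
# appends draws instead of perturbing earlier patients.  Constants are
# arbitrary odd multipliers; all arithmetic stays below 2^53 so the result is
# exact in double precision.
substream_seed <- function(seed, stage, index = 0L) {
  s <- ((as.double(seed) %% 100003) * 2654435761 +
          as.double(stage) * 40503 +
          as.double(index) * 97561) %% 2147483647
  as.integer(s)
}

# Inverse-CDF draw from a truncated normal: exactly one uniform per variate,
# which keeps the generator's draw count per patient fixed.
rtruncnorm_inv <- function(u, mean, sd, lower, upper) {
  pa <- pnorm(lower, mean, sd)
  pb <- pnorm(upper, mean, sd)
  qnorm(pa + u * (pb - pa), mean, sd)
}

# Probabilities strictly inside (0, 1); guards downstream logs and odds.
clamp_prob <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
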