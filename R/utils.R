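#' @keywords internal
"_PACKAGE"

#' @importFrom stats ave cor dbinom pbinom phyper prcomp rbinom rnorm runif
#'   sd setNames var
#' @importFrom utils read.delim write.table
NULL

# Validation helper: stop with a classed condition so callers/tests can
# distinguish user-input errors (exit code 2 in the CLI) from stage failures.
abort_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("ploidyStrata_validation_error", "error")))
}

assert_that <- function(ok, msg, ...) {
  if (!isTRUE(ok)) abort_validation(msg, ...)
  invisible(TRUE)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic derived seeds that stay inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + as.numeric(offset)) %% 2147483647)
}

# Numerically stable log(sum(exp(x))).
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# One-sided exact binomial tail computed in log space.
# direction = "greater": P(X >= k); "less": P(X <= k), X ~ Binomial(n, p0).
# Returns the tail probability together with its log10, which stays finite
# far below the double underflow limit (the sub-1e-300 regime).
binom_tail <- function(k, n, p0, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  assert_that(k >= 0 && k <= n, "k must lie in [0, n], got k=%s n=%s", k, n)
  assert_that(p0 >= 0 && p0 <= 1, "p0 must lie in [0, 1], got %s", p0)
  log_p <- if (direction == "greater") {
    if (k == 0) 0 else pbinom(k - 1, n, p0, lower.tail = FALSE, log.p = TRUE)
  } else {
    pbinom(k, n, p0, lower.tail = TRUE, log.p = TRUE)
  }
  list(p = exp(log_p), log10_p = log_p / log(10))
}
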