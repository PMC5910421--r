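# Internal helpers: error conditions, seeded RNG scopes, small validators.

ct_config_error <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("ct_config_error", "error", "condition")))
}

ct_input_error <- function(msg) {
  stop(errorCondition(msg, class = c("ct_input_error", "error", "condition")))
}

#' @noRd
#' Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
#' the caller's RNG stream afterwards. All generators route their randomness
#' through this so that independent stages do not perturb each other.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    ct_config_error("seed must be a single non-missing number")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1) {
    ct_config_error(sprintf("%s must be a single number in (0, 1)", name))
  }
}

#' @noRd
#' Largest-remainder apportionment of `n` items to `props` (sums to 1).
#' Deterministic: planted category counts are exact, not multinomial draws.
apportion <- function(n, props) {
  raw <- n * props
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

geomean <- function(x) exp(mean(log(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a
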