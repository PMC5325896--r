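# internal helpers: conditions, rounding, seed hygiene

#' @importFrom stats qnorm pnorm rnorm runif rbinom lm glm confint coef
#'   binom.test setNames complete.cases qlogis binomial
#' @importFrom utils read.csv write.csv
NULL

tirc_error <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(paste0("tircval_", class, "_error"), "tircval_error",
              "error", "condition"),
    list(message = msg, call = call)
  ))
}

abort_config     <- function(msg) tirc_error(msg, "config")
abort_schema     <- function(msg) tirc_error(msg, "schema")
abort_parse      <- function(msg) tirc_error(msg, "parse")
abort_validation <- function(msg) tirc_error(msg, "validation")
abort_alignment  <- function(msg) tirc_error(msg, "alignment")
abort_undefined  <- function(msg) tirc_error(msg, "undefined")
abort_feasible   <- function(msg) tirc_error(msg, "feasibility")
abort_io         <- function(msg) tirc_error(msg, "io")

#' Round half away from zero
#'
#' Display rounding used throughout the package: exact halves round up
#' (10.05 -> 10.1), unlike [base::round()]'s round-half-to-even.  Internal
#' computation is always at full precision; this is applied only when a
#' value is reported at the printed precision.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @export
#' @examples
#' round_half_up(c(0.25, 0.35), 1)   # 0.3 0.4, where round() gives 0.2 0.4
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Run `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# Inverse-CDF sampling from a normal truncated to [lo, hi]; deterministic
# under the current RNG stream, no rejection loop.
rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# Largest-remainder apportionment of `total` integer slots proportionally
# to non-negative `weights`; ties broken by position.
apportion <- function(total, weights) {
  stopifnot(total >= 0, all(weights >= 0))
  if (sum(weights) == 0) {
    if (total > 0) abort_feasible("cannot apportion slots: all weights are zero")
    return(rep(0L, length(weights)))
  }
  quota <- total * weights / sum(weights)
  base <- floor(quota)
  left <- total - sum(base)
  if (left > 0) {
    ord <- order(quota - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
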