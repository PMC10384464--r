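# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-stream seed
#'
#' Hashes an operator name (and optional qualifiers such as a node id) together
#' with a master seed into a new 31-bit seed, so that each stochastic operator
#' draws from its own stream: changing one injection never perturbs another.
#'
#' @param seed Master integer seed.
#' @param ... Character qualifiers (operator name, node id, attribute name...).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @examples
#' substreamSeed(1, "missing", "node2")
#' @export
substreamSeed <- function(seed, ...) {
  key <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- 0
  for (cp in utf8ToInt(key)) h <- (h * 31 + cp) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483647)
}

# Evaluate expr under a temporary RNG state; restores the caller's stream.
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Most frequent non-missing value; ties broken by the smallest value, so the
# result is invariant to row order.
statMode <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA)
  ux <- sort(unique(x))
  ux[which.max(tabulate(match(x, ux)))]
}

# Numeric text serialization used by the XML writer (>= 12 significant digits;
# %.17g round-trips IEEE doubles exactly).
fmtNum <- function(x) sprintf("%.17g", x)

isMissingScalar <- function(x) is.null(x) || (length(x) == 1L && is.na(x))

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
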