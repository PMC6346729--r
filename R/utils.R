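# Shared internal helpers.

# Donor population labels, in the fixed order used throughout:
# Meishan, Bamaxiang, European wild boar.
DONORS <- c("MS", "BMX", "EUW")

# Five Animal QTLdb trait classes (closed set).
TRAIT_GROUPS <- c("meat and carcass", "production", "reproduction",
                  "health", "exterior")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a local random seed
#'
#' Runs \code{code} with the RNG seeded to \code{seed}, then restores the
#' session's RNG state, so seeded operations never leak global RNG state.
#' With \code{seed = NULL} the expression runs on the current stream.
#'
#' @param seed integer seed, or NULL to use the current RNG stream.
#' @param code expression to evaluate.
#' @return The value of \code{code}.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == floor(x) && x >= 0
}

is_prob <- function(x) is.numeric(x) && !anyNA(x) && all(x >= 0 & x <= 1)
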