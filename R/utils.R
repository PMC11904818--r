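# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Evaluate an expression under a fixed RNG seed, restoring global RNG state
#' @noRd
local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stopf("seed must be a single integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a reproducible sub-seed from a parent seed and a stage name.
#'
#' Polynomial string hash folded into \[1, 2^31 - 2\] so each pipeline stage
#' gets its own stream but everything is determined by one global seed.
#' @param seed parent integer seed
#' @param name stage name (character scalar)
#' @return a single integer seed
#' @export
derive_seed <- function(seed, name) {
  stopifnot(is.character(name), length(name) == 1L)
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- as.double(seed %% m)
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% m
  as.integer(h %% (m - 1) + 1)
}

# check a numeric scalar
num1 <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)

# check a positive integerish count
count1 <- function(x) num1(x) && x >= 1 && abs(x - round(x)) < 1e-8
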