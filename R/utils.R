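# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the R RNG locally and restores the caller's \code{.Random.seed}
#' afterwards, so no exported function mutates global random state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @noRd
withLocalSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a per-stage seed from a master seed; kept below 2^31.
deriveSeed <- function(master, stage) {
  offsets <- c(simulate = 101L, preprocess = 211L, diffexpr = 307L,
               network = 401L, reclassify = 503L, validate = 601L,
               fcm = 701L)
  off <- offsets[[stage]]
  if (is.null(off)) off <- sum(utf8ToInt(stage))
  as.integer((as.double(master) * 48271 + off) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# Population (denominator N) standard deviation.
popSd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

# Standardize rows of a matrix to mean 0, sd 1 (sample sd); constant rows
# are left at 0 with a warning from callers that care.
rowStandardize <- function(x) {
  mu <- rowMeans(x)
  s <- apply(x, 1L, sd)
  s[s == 0] <- 1
  (x - mu) / s
}
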