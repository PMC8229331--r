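# internal helpers shared across modules

REGIONS <- c("source_chamber", "microchannel", "target_chamber", "reference")
MODULES <- c("source", "target")
PROTOCOLS <- c("test1", "test2", "test3", "tetanus")

msToS <- function(ms) ms / 1000
sToMs <- function(s) s * 1000

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# rejection sampler for Normal(mean, sd) truncated to (lower, upper)
rtruncnorm <- function(n, mean, sd, lower = 0, upper = Inf) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) {
    x <- rep(mean, n)
    if (any(x <= lower | x >= upper))
      stop("degenerate truncated normal: mean outside (lower, upper)")
    return(x)
  }
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2L * (n - length(out)) + 8L, mean, sd)
    out <- c(out, x[x > lower & x < upper])
  }
  out[seq_len(n)]
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
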