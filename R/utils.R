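# Internal helpers shared across the package.

# Classed error conditions so callers can distinguish failure modes
# (topology vs schema vs numerical) with tryCatch/expect_error.
sn_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "streamnet_error", "error", "condition")))
}

sn_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "streamnet_warning", "warning", "condition")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Cholesky with escalating jitter. Returns the upper factor R (Sigma = R'R)
# with the jitter used as an attribute, or NULL if the matrix is still not
# numerically positive definite at the largest jitter.
chol_jitter <- function(S, start = 1e-10, max_jitter = 1e-6) {
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (!is.null(R)) {
    attr(R, "jitter") <- 0
    return(R)
  }
  md <- mean(diag(S))
  if (!is.finite(md) || md <= 0) md <- 1
  j <- start
  while (j <= max_jitter) {
    R <- tryCatch(chol(S + diag(j * md, nrow(S))), error = function(e) NULL)
    if (!is.null(R)) {
      attr(R, "jitter") <- j * md
      return(R)
    }
    j <- j * 10
  }
  NULL
}

# Run code with a temporarily seeded RNG, restoring (or removing) the global
# .Random.seed afterwards -- the stats::simulate convention.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}
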