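#' Evaluate code under a temporary RNG state
#'
#' Runs \code{code} with the RNG seeded at \code{seed} and restores the
#' caller's RNG state afterwards, so seeded generators never perturb global
#' random state. A \code{NULL} seed runs the code under the current stream.
#'
#' @param seed integer scalar or NULL.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' Stable log-sum-exp
#' @param x numeric vector of log-scale values.
#' @return log(sum(exp(x))) computed without overflow.
#' @keywords internal
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Draw one multivariate normal vector with covariance S (chol-based; used by
# the GWAS summary simulator where S is an LD matrix, possibly rank-deficient).
rmvnorm1 <- function(mu, S) {
  L <- tryCatch(chol(S), error = function(e) {
    chol(S + diag(1e-8, nrow(S)))
  })
  as.vector(mu + crossprod(L, stats::rnorm(nrow(S))))
}

# Derive a sub-seed for a pipeline stage from a master seed, kept under 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) * 1009L + as.integer(offset)) %% 2147483629L
}
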