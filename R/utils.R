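# numerically stable log-sum-exp over rows of a matrix
rowLogSumExp <- function(m) {
  mx <- apply(m, 1L, max)
  bad <- !is.finite(mx)
  out <- mx + log(rowSums(exp(m - mx)))
  out[bad] <- mx[bad]
  out
}

logSumExp <- function(v) {
  mx <- max(v)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(v - mx)))
}

#' Clamp probabilities away from 0 and 1
#'
#' Keeps one probability branch from permanently zeroing the geometric-mean
#' fusion.
#' @param p numeric vector.
#' @param eps clamp margin (default 1e-6).
#' @return p clamped to [eps, 1 - eps].
#' @export
clampProbs <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

# evaluate expr under a fixed RNG seed without disturbing the caller's stream
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# full-precision (roundtrip-exact) text rendering of doubles
fmtFull <- function(x) formatC(x, digits = 17, format = "g", width = -1)

logmsg <- function(level, ...) {
  message(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [", level, "] ", ...)
}
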