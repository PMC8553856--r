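# Seed substreams: all randomness in the package flows from one root seed,
# with a named substream per stage so regenerating one stage never perturbs
# another.  The derived value stays inside 32-bit integer range.
.substream <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes)) %% 1000003
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729 + 1) %% 2147483629)
}

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Fisher z transform of correlation coefficients
#'
#' \code{atanh(r)}, with \code{|r|} clamped at \code{1 - 1e-12} so that
#' degenerate perfect correlations stay finite.
#'
#' @param r numeric vector of correlations in \code{[-1, 1]}.
#' @return numeric vector of Fisher z values.
#' @export
fisherZ <- function(r) {
  r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  atanh(r)
}
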