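#' @importFrom rlang abort warn
#' @importFrom stats rnorm runif integrate binom.test t.test sd
#' @importFrom utils head tail
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never disturbs user RNG.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream seed from a master seed and a stream index, keeping the
# result inside the 32-bit integer range. Streams for distinct indices are
# distinct, and adding a stream never perturbs earlier ones.
derive_seed <- function(seed, stream) {
  s <- (as.double(seed) %% 1000003) * 2017 + as.double(stream) * 7919
  as.integer(s %% 2147483647)
}

stopf <- function(fmt, ..., class = "msmda_error") {
  rlang::abort(sprintf(fmt, ...), class = c(class, "msmda_error"))
}

check_finite_matrix <- function(X, what = "feature matrix") {
  if (!is.matrix(X) || !is.numeric(X)) {
    stopf("%s must be a numeric matrix", what, class = "msmda_schema_error")
  }
  if (anyNA(X) || any(!is.finite(X))) {
    stopf("%s contains non-finite values", what, class = "msmda_data_error")
  }
  invisible(X)
}
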