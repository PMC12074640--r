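#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor pnorm qnorm quantile rnorm rexp rpois runif sd var
#'   median setNames complete.cases pchisq
#' @importFrom utils read.delim write.table head
NULL

# Laplace(0, b) via inverse CDF; used for heavy-tailed source weights.
rlaplace <- function(n, scale = 1) {
  u <- runif(n) - 0.5
  -scale * sign(u) * log(1 - 2 * abs(u))
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so generators do not clobber user code.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

stop_ <- function(...) stop(..., call. = FALSE)

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop_(msg)
  invisible(TRUE)
}

# column-standardize a matrix to mean 0, sd 1; zero-variance columns -> 0
standardize_cols <- function(x) {
  x <- sweep(x, 2L, colMeans(x), "-")
  s <- sqrt(colSums(x^2) / (nrow(x) - 1L))
  s[s == 0] <- 1
  sweep(x, 2L, s, "/")
}
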