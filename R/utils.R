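#' @useDynLib cjscommunity, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats dnorm dlogis rnorm runif quantile sd var cor lm pchisq
#'   coef pnorm setNames complete.cases aggregate approx median qnorm
#' @importFrom utils read.csv write.csv head
NULL

#' Inverse-logit and logit transforms
#'
#' Numerically safe logistic link helpers used throughout the package.
#' `invlogit()` maps the real line to (0,1); `logit()` is its inverse.
#'
#' @param x numeric vector.
#' @param p numeric vector of probabilities in (0,1).
#' @return numeric vector of the same length.
#' @examples
#' invlogit(0)      # 0.5
#' logit(0.81)      # about 1.45
#' @export
invlogit <- function(x) 1 / (1 + exp(-x))

#' @rdname invlogit
#' @export
logit <- function(p) log(p / (1 - p))

# Package-level logging: quiet by default, enable with
# options(cjscommunity.verbose = TRUE)
cjs_log <- function(fmt, ...) {
  if (isTRUE(getOption("cjscommunity.verbose", FALSE)))
    message(sprintf(fmt, ...))
  invisible(NULL)
}

# standardize to mean 0, sample SD 1; errors on zero variance
zstd <- function(x, what = "covariate") {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("zero-variance ", what, ": cannot standardize", call. = FALSE)
  (x - mean(x)) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
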