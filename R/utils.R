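#' @useDynLib irclusters, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats pnorm dnorm qf rnorm rpois rexp runif rbinom rgamma
#'   rgeom sd t.test complete.cases
#' @importFrom utils head tail write.csv read.csv
#' @importFrom graphics hist
#' @importFrom data.table as.data.table data.table setorderv :=
#' @keywords internal
"_PACKAGE"

# Validation helpers ----------------------------------------------------------

stop_param <- function(...) {
  stop(structure(class = c("irclusters_param_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop_param(...)
  invisible(TRUE)
}

is_count <- function(x, min = 0L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= min && x == floor(x)
}

is_number <- function(x, min = -Inf, strict = FALSE) {
  length(x) == 1L && is.numeric(x) && is.finite(x) &&
    (if (strict) x > min else x >= min)
}

#' Derive a per-stage child seed from a master seed
#'
#' One master seed is expanded into per-stage seeds by a fixed affine scheme
#' so that stages draw from independent streams but the whole pipeline is
#' reproducible from a single integer. Child seeds stay below 2^31 - 1.
#'
#' @param seed master seed (single integer).
#' @param stage stage name (character) or index.
#' @return an integer seed.
#' @export
child_seed <- function(seed, stage) {
  check_that(is_count(seed), "seed must be a non-negative integer")
  k <- if (is.character(stage)) {
    sum(as.integer(charToRaw(stage)) * seq_along(charToRaw(stage)))
  } else {
    as.integer(stage)
  }
  as.integer((as.numeric(seed) * 48271 + k * 10007 + 12345) %% 2147483647)
}

# 1D centred Gaussian kernel, truncated at radius r, unnormalised tail kept
gaussian_kernel <- function(sigma, radius = ceiling(4 * sigma)) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Negated Laplacian-of-Gaussian kernel (bright blobs -> positive response)
log_kernel <- function(sigma, radius = max(2L, ceiling(4 * sigma))) {
  x <- seq(-radius, radius)
  g <- outer(x, x, function(a, b) exp(-(a^2 + b^2) / (2 * sigma^2)))
  r2 <- outer(x, x, function(a, b) a^2 + b^2)
  k <- -(1 / (pi * sigma^4)) * (1 - r2 / (2 * sigma^2)) * g
  -(k - mean(k))  # zero-mean so flat regions respond 0; negate for bright spots
}
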