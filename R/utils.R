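#' @importFrom stats pnorm qnorm quantile rnorm runif sd var acf coef dnorm
#'   median rbinom vcov lm setNames complete.cases
#' @importFrom rlang .data abort warn
#' @importFrom utils read.csv write.csv head
NULL

# Truncated normal draws by inverse-CDF; adequate for the mild truncations
# used here (bounds within ~6 SD of the mean).
rtruncnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  if (any(phi - plo < 1e-12)) {
    abort("truncation bounds leave no probability mass")
  }
  qnorm(runif(n, plo, phi), mean, sd)
}

#' Split-\eqn{\hat{R}} convergence diagnostic
#'
#' Potential scale reduction factor computed on chains split in half, so a
#' single long chain still yields a meaningful diagnostic. Values near 1
#' indicate convergence; fits in this package flag parameters whose
#' \eqn{\hat{R}} exceeds the configured threshold (default 1.05).
#'
#' @param x numeric matrix of posterior draws, one column per chain, or a
#'   numeric vector (treated as one chain).
#' @return scalar \eqn{\hat{R}} estimate.
#' @export
split_rhat <- function(x) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  halves <- do.call(cbind, lapply(seq_len(ncol(x)), function(j) {
    cbind(x[seq_len(half), j], x[(n - half + 1):n, j])
  }))
  m <- ncol(halves)
  nh <- nrow(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, var)
  w <- mean(vars)
  b <- nh * var(means)
  if (w < .Machine$double.eps) return(1)
  sqrt(((nh - 1) / nh * w + b / nh) / w)
}

# Effective sample size from the initial positive sequence of autocorrelation
# estimates, summed over chains.
ess_basic <- function(x) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  per_chain <- vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    n <- length(v)
    if (var(v) < .Machine$double.eps) return(n)
    rho <- acf(v, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
    pos <- which(rho < 0.05)
    cutoff <- if (length(pos)) pos[1] - 1 else length(rho)
    n / (1 + 2 * sum(rho[seq_len(cutoff)]))
  }, numeric(1))
  sum(per_chain)
}

# Central credible interval helper.
cred_int <- function(x, level = 0.95) {
  a <- (1 - level) / 2
  unname(quantile(x, c(a, 1 - a)))
}

# Stable short hash of an R object (for output provenance headers).
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2147483647
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
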