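#' Simulate capture-recapture growth series
#'
#' Generates snout-vent-length (SVL) series under the Fabens
#' capture-recapture form of the von Bertalanffy growth curve. Each
#' individual is assigned a sex and plot (configurable proportions), an
#' initial SVL drawn uniformly on `svl_range`, and then grows between
#' captures according to
#' \deqn{SVL_{t} = SVL_{t-1} + (L_{sex} - SVL_{t-1})\,(1 - e^{-K I/365}),}
#' where \eqn{I} is the interval in days and \eqn{K} the plot-by-sex growth
#' coefficient. Independent Gaussian measurement noise of SD `sigma_obs`
#' (from `truth`) is added to every recorded SVL; set it to 0 in
#' [growth_params()] for noiseless series.
#'
#' @param truth a [truth_params()] or [growth_params()] object.
#' @param n_individuals number of individuals.
#' @param capture_schedule numeric vector of between-capture intervals in
#'   days (so `length(capture_schedule) + 1` captures per individual).
#' @param seed integer seed.
#' @param p_female,p_successional assignment probabilities for sex and plot.
#' @param svl_range range for the uniform initial-SVL draw; must lie within
#'   10-60 mm. The default 18-40 mm spans juvenile-to-adult entry sizes
#'   while staying below the male asymptote, so simulated increments are
#'   informative about K.
#' @return tibble in long format, one row per capture: `individual_id`,
#'   `sex`, `plot`, `capture`, `interval_days` (days since previous
#'   capture, 0 at first), `svl` (observed, mm), `svl_true` (noiseless,
#'   mm). Attribute `"truth"` records the generating parameters.
#' @examples
#' g <- simulate_growth_series(growth_params(), 5, c(180, 185), seed = 1)
#' g
#' @export
simulate_growth_series <- function(truth, n_individuals,
                                   capture_schedule,
                                   seed,
                                   p_female = 0.5,
                                   p_successional = 0.5,
                                   svl_range = c(18, 40)) {
  p <- if (inherits(truth, "truth_params")) truth$growth else truth
  stopifnot(inherits(p, "growth_params"), n_individuals >= 1)
  if (length(capture_schedule) < 1) abort("`capture_schedule` must be non-empty")
  if (any(capture_schedule < 0)) abort("capture intervals must be non-negative")
  if (svl_range[1] < 10 || svl_range[2] > 60 || svl_range[1] > svl_range[2]) {
    abort("`svl_range` must be an increasing range within [10, 60] mm")
  }
  set.seed(as.integer(seed))

  n <- as.integer(n_individuals)
  sex <- ifelse(runif(n) < p_female, "female", "male")
  plot <- ifelse(runif(n) < p_successional, "successional", "mature")
  l <- ifelse(sex == "male", p$l_male, p$l_female)
  k <- p$k[paste(plot, sex, sep = "_")]
  svl0 <- runif(n, svl_range[1], svl_range[2])

  n_cap <- length(capture_schedule) + 1L
  true_svl <- matrix(NA_real_, n, n_cap)
  true_svl[, 1] <- svl0
  for (j in seq_along(capture_schedule)) {
    prev <- true_svl[, j]
    true_svl[, j + 1] <- prev + (l - prev) * (1 - exp(-k * capture_schedule[j] / 365))
  }
  obs <- true_svl + rnorm(n * n_cap, 0, p$sigma_obs)

  out <- tibble::tibble(
    individual_id = rep(seq_len(n), each = n_cap),
    sex = rep(sex, each = n_cap),
    plot = rep(plot, each = n_cap),
    capture = rep(seq_len(n_cap), n),
    interval_days = rep(c(0, capture_schedule), n),
    svl = as.vector(t(obs)),
    svl_true = as.vector(t(true_svl))
  )
  attr(out, "truth") <- list(params = p, sex = sex, plot = plot, k = k,
                             svl0 = svl0, seed = as.integer(seed))
  out
}

#' Synthetic clutch-size table
#'
#' Builds a stand-in for a published clutch-size-versus-SVL dataset: rows
#' `(svl, clutch)` with `clutch = intercept + slope * svl + N(0,
#' residual_sd)`, floored at 1 egg. SVLs are drawn uniformly on
#' `svl_range`. The generating parameters are attached for recovery tests.
#'
#' @param n number of females (>= 3 so a line is fittable).
#' @param intercept,slope,residual_sd linear-model parameters (eggs, eggs
#'   per mm, eggs).
#' @param svl_range SVL range of gravid females, mm.
#' @param seed integer seed.
#' @return tibble with columns `svl`, `clutch`.
#' @examples
#' make_clutch_table(10, seed = 1)
#' @export
make_clutch_table <- function(n = 50, intercept = -6, slope = 0.3,
                              residual_sd = 1.5, svl_range = c(34, 52),
                              seed = 1L) {
  if (n < 3) abort("`n` must be at least 3 to fit a line")
  if (slope < 0) warn("negative clutch-size slope requested")
  set.seed(as.integer(seed))
  svl <- runif(n, svl_range[1], svl_range[2])
  clutch <- pmax(1, intercept + slope * svl + rnorm(n, 0, residual_sd))
  out <- tibble::tibble(svl = svl, clutch = clutch)
  attr(out, "truth") <- list(intercept = intercept, slope = slope,
                             residual_sd = residual_sd, seed = as.integer(seed))
  out
}
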