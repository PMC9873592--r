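#' Lifetime-projection configuration
#'
#' Constants of the lifetime-fecundity projection: hatch size 13.5 mm SVL;
#' sexual maturity first reached at 34 mm; females of 34-43 mm have a 56%
#' chance of being gravid in a year and females above 43 mm a 94% chance;
#' eggs hatch at 90%; annual survival probability is drawn once per
#' individual from Normal(0.836, 0.07) truncated to [0.4, 1.0]; the
#' projection horizon is 20 years. `pre_growth_lag` (default 1 year)
#' shifts the onset of post-hatching growth relative to the projection
#' clock (see the methods vignette).
#'
#' `survival_truncation` selects how the survival distribution is
#' truncated: `"clip"` (default) clamps normal draws to the bounds,
#' leaving point mass at the endpoints; `"renormalize"` draws from the
#' renormalized truncated normal. Both are standard readings of a
#' "truncated" normal; the choice is discussed in the methods vignette.
#'
#' @param hatch_svl,maturity_svl SVL landmarks, mm.
#' @param gravid_p_small gravidity probability on `[maturity_svl, gravid_threshold]`.
#' @param gravid_p_large gravidity probability above `gravid_threshold`.
#' @param gravid_threshold mm.
#' @param hatch_rate egg hatching success.
#' @param survival_mean,survival_sd,survival_bounds truncated-normal annual
#'   survival distribution.
#' @param horizon projection horizon, years.
#' @param n_sims simulated females per projection.
#' @param pre_growth_lag years.
#' @return list of class `projection_config`.
#' @export
projection_config <- function(hatch_svl = 13.5, maturity_svl = 34,
                              gravid_p_small = 0.56, gravid_p_large = 0.94,
                              gravid_threshold = 43,
                              hatch_rate = 0.90,
                              survival_mean = 0.836, survival_sd = 0.07,
                              survival_bounds = c(0.4, 1.0),
                              horizon = 20L, n_sims = 100000L,
                              pre_growth_lag = 1.0,
                              survival_truncation = c("clip", "renormalize")) {
  survival_truncation <- match.arg(survival_truncation)
  probs <- c(gravid_p_small, gravid_p_large, hatch_rate, survival_mean)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (survival_bounds[1] >= survival_bounds[2]) abort("survival bounds must be ordered")
  if (horizon < 1) abort("`horizon` must be at least 1 year")
  if (maturity_svl <= hatch_svl) abort("maturity size must exceed hatch size")
  structure(
    list(hatch_svl = hatch_svl, maturity_svl = maturity_svl,
         gravid_p_small = gravid_p_small, gravid_p_large = gravid_p_large,
         gravid_threshold = gravid_threshold, hatch_rate = hatch_rate,
         survival_mean = survival_mean, survival_sd = survival_sd,
         survival_bounds = survival_bounds, horizon = as.integer(horizon),
         n_sims = as.integer(n_sims), pre_growth_lag = pre_growth_lag,
         survival_truncation = survival_truncation),
    class = "projection_config"
  )
}

# per-individual annual survival probabilities under the configured
# truncation convention
draw_survival <- function(cfg, n) {
  if (identical(cfg$survival_truncation, "renormalize")) {
    rtruncnorm(n, cfg$survival_mean, cfg$survival_sd,
               cfg$survival_bounds[1], cfg$survival_bounds[2])
  } else {
    pmin(pmax(rnorm(n, cfg$survival_mean, cfg$survival_sd),
              cfg$survival_bounds[1]), cfg$survival_bounds[2])
  }
}

#' Size-dependent gravidity probability
#'
#' 0 below the maturity size, `gravid_p_small` between the maturity size
#' and the gravidity threshold (inclusive), `gravid_p_large` above it.
#' Vectorized over `svl`.
#'
#' @param svl snout-vent length, mm.
#' @param cfg a [projection_config()].
#' @return probability vector.
#' @examples
#' gravid_probability(c(30, 40, 45), projection_config())
#' @export
gravid_probability <- function(svl, cfg = projection_config()) {
  stopifnot(all(svl > 0))
  ifelse(svl < cfg$maturity_svl, 0,
         ifelse(svl <= cfg$gravid_threshold, cfg$gravid_p_small,
                cfg$gravid_p_large))
}

#' Fit the clutch-size linear model
#'
#' Gaussian linear regression of clutch size on SVL, the model used to
#' predict per-clutch egg numbers in the projection. Returns point
#' estimates, standard errors and the coefficient covariance so
#' posterior-style draws can be taken.
#'
#' @param table data frame with columns `svl`, `clutch` (>= 3 rows).
#' @return object of class `clutch_model` with `intercept`, `slope`,
#'   `residual_sd`, `se`, `vcov`, `n`.
#' @examples
#' fit_clutch_model(make_clutch_table(100, seed = 1))
#' @export
fit_clutch_model <- function(table) {
  stopifnot(is.data.frame(table), all(c("svl", "clutch") %in% names(table)))
  if (nrow(table) < 3) abort("need at least 3 rows to fit the clutch model")
  if (var(table$svl) < .Machine$double.eps) {
    abort("constant SVL column: clutch-size slope is unidentifiable")
  }
  fit <- lm(clutch ~ svl, data = table)
  cf <- coef(fit)
  structure(
    list(intercept = unname(cf[1]), slope = unname(cf[2]),
         residual_sd = summary(fit)$sigma,
         se = unname(sqrt(diag(vcov(fit)))), vcov = vcov(fit),
         n = nrow(table)),
    class = "clutch_model"
  )
}

#' @rdname fit_clutch_model
#' @param intercept,slope,residual_sd known clutch-model parameters (eggs,
#'   eggs per mm, eggs), for building a `clutch_model` without data.
#' @export
clutch_model <- function(intercept, slope, residual_sd = 0) {
  if (residual_sd < 0) abort("`residual_sd` must be non-negative")
  structure(
    list(intercept = intercept, slope = slope, residual_sd = residual_sd,
         se = c(0, 0), vcov = matrix(0, 2, 2), n = NA_integer_),
    class = "clutch_model"
  )
}

#' @export
print.clutch_model <- function(x, ...) {
  cat(sprintf("<clutch_model> clutch = %.3f + %.3f * SVL (residual SD %.3f)\n",
              x$intercept, x$slope, x$residual_sd))
  invisible(x)
}

# von Bertalanffy size-at-age from the hatch size, with the pre-growth lag
svl_at_age <- function(age, l, k, cfg) {
  t_growth <- pmax(0, age - cfg$pre_growth_lag)
  cfg$hatch_svl + (l - cfg$hatch_svl) * (1 - exp(-k * t_growth))
}

#' Simulate one female's life history
#'
#' One draw of the lifetime projection: a single annual survival
#' probability is drawn from the truncated normal survival distribution
#' and held for life (between-individual heterogeneity); each year the
#' female survives as an independent Bernoulli trial, up to the horizon.
#' Her SVL at each whole year of age follows the von Bertalanffy
#' trajectory from the hatch size (after the pre-growth lag); in each year
#' survived she is gravid with the size-dependent probability, and if so
#' produces a clutch drawn from the Normal clutch-size model (floored at
#' 0), of which `hatch_rate` hatch. Hatched offspring accumulate without
#' rounding.
#'
#' @param growth_draw named list or vector with `l` and `k` (one posterior
#'   draw of the growth parameters).
#' @param clutch a `clutch_model`.
#' @param cfg a [projection_config()].
#' @param seed optional integer seed.
#' @return tibble (one row): `lifespan_years`, `age_at_maturity`,
#'   `n_clutches`, `lifetime_fecundity`.
#' @export
simulate_life <- function(growth_draw, clutch, cfg = projection_config(),
                          seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  l <- growth_draw[["l"]]; k <- growth_draw[["k"]]
  if (l <= cfg$hatch_svl) abort("asymptotic size must exceed the hatch size")
  p_surv <- draw_survival(cfg, 1)
  age_mat <- cfg$pre_growth_lag +
    time_to_length(l, k, cfg$hatch_svl, cfg$maturity_svl)
  lifespan <- 0L
  n_clutches <- 0L
  fec <- 0
  for (t in seq_len(cfg$horizon)) {
    if (runif(1) > p_surv) break
    lifespan <- t
    svl_t <- svl_at_age(t, l, k, cfg)
    if (runif(1) < gravid_probability(svl_t, cfg)) {
      n_clutches <- n_clutches + 1L
      eggs <- max(0, rnorm(1, clutch$intercept + clutch$slope * svl_t,
                           clutch$residual_sd))
      fec <- fec + eggs * cfg$hatch_rate
    }
  }
  tibble::tibble(lifespan_years = lifespan, age_at_maturity = age_mat,
                 n_clutches = n_clutches, lifetime_fecundity = fec)
}

#' Project lifetime fecundity for a population
#'
#' Runs `cfg$n_sims` independent life-history simulations, one posterior
#' draw of the growth parameters per simulated female (draws recycled if
#' fewer than `n_sims`), with clutch-model coefficients drawn from their
#' sampling distribution per female. Internally vectorized; statistically
#' identical to repeated [simulate_life()] calls.
#'
#' @param growth_draws data frame with columns `l`, `k`: posterior draws
#'   for the plot-by-sex group being projected (see
#'   [growth_group_draws()], [draw_growth_summaries()]).
#' @param clutch a `clutch_model`.
#' @param cfg a [projection_config()].
#' @param seed integer seed.
#' @param keep_records return per-female records as attribute
#'   `"records"`.
#' @return one-row tibble: means and SDs of lifespan, clutches and
#'   lifetime fecundity, plus the mean age at maturity.
#' @export
project_population <- function(growth_draws, clutch,
                               cfg = projection_config(), seed = 1L,
                               keep_records = FALSE) {
  stopifnot(is.data.frame(growth_draws),
            all(c("l", "k") %in% names(growth_draws)))
  if (cfg$n_sims <= 0) abort("`n_sims` must be positive")
  set.seed(as.integer(seed))
  n <- cfg$n_sims
  idx <- if (nrow(growth_draws) >= n) {
    sample.int(nrow(growth_draws), n)
  } else {
    sample.int(nrow(growth_draws), n, replace = TRUE)
  }
  l <- growth_draws$l[idx]
  k <- growth_draws$k[idx]

  p_surv <- draw_survival(cfg, n)
  H <- cfg$horizon
  # alive[t, i]: survived through year t
  surv_draw <- matrix(runif(n * H), H, n)
  alive <- matrix(apply(surv_draw < rep(p_surv, each = H), 2, cumprod),
                  H, n) == 1
  lifespan <- colSums(alive)

  # clutch coefficients per female (sampling-uncertainty draws)
  ab <- draw_clutch_coefs(clutch, n)

  fec <- numeric(n)
  n_clutches <- integer(n)
  for (t in seq_len(H)) {
    svl_t <- svl_at_age(t, l, k, cfg)
    gravid <- alive[t, ] & (runif(n) < gravid_probability(svl_t, cfg))
    eggs <- pmax(0, rnorm(n, ab$a + ab$b * svl_t, clutch$residual_sd))
    fec <- fec + ifelse(gravid, eggs * cfg$hatch_rate, 0)
    n_clutches <- n_clutches + gravid
  }
  age_mat <- cfg$pre_growth_lag +
    time_to_length(l, k, cfg$hatch_svl, cfg$maturity_svl)

  out <- tibble::tibble(
    n_sims = n,
    lifespan_mean = mean(lifespan), lifespan_sd = sd(lifespan),
    clutches_mean = mean(n_clutches), clutches_sd = sd(n_clutches),
    fecundity_mean = mean(fec), fecundity_sd = sd(fec),
    age_at_maturity_mean = mean(age_mat[is.finite(age_mat)])
  )
  if (keep_records) {
    attr(out, "records") <- tibble::tibble(
      lifespan_years = lifespan, age_at_maturity = age_mat,
      n_clutches = n_clutches, lifetime_fecundity = fec
    )
  }
  out
}

draw_clutch_coefs <- function(clutch, n) {
  if (all(clutch$se == 0)) {
    return(list(a = rep(clutch$intercept, n), b = rep(clutch$slope, n)))
  }
  # bivariate normal draws from the coefficient sampling distribution
  ch <- chol(clutch$vcov)
  z <- matrix(rnorm(2 * n), n, 2) %*% ch
  list(a = clutch$intercept + z[, 1], b = clutch$slope + z[, 2])
}

#' Mean lifespan under truncated-normal survival heterogeneity
#'
#' Simulates the survival process alone: one annual survival probability
#' per female from the truncated normal distribution, annual Bernoulli
#' survival, lifespan capped at the horizon. This isolates the lifespan
#' statistic of the projection from reproduction.
#'
#' @param cfg a [projection_config()].
#' @param seed integer seed.
#' @return one-row tibble: `lifespan_mean`, `lifespan_sd`, `n_sims`.
#' @export
project_lifespan <- function(cfg = projection_config(), seed = 1L) {
  set.seed(as.integer(seed))
  n <- cfg$n_sims
  p <- draw_survival(cfg, n)
  H <- cfg$horizon
  alive <- matrix(apply(matrix(runif(n * H), H, n) < rep(p, each = H), 2,
                        cumprod), H, n) == 1
  lifespan <- colSums(alive)
  tibble::tibble(lifespan_mean = mean(lifespan), lifespan_sd = sd(lifespan),
                 n_sims = n)
}
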