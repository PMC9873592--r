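#' Remove shrinking SVL series
#'
#' Drops individuals whose SVL at the final capture is strictly less than
#' at the first capture; such series are attributed to measurement error.
#' Equality is retained. The number of removed individuals is reported via
#' a message and the `"n_removed"` attribute.
#'
#' @param obs long-format growth tibble as produced by
#'   [simulate_growth_series()] or [read_growth_csv()]: columns
#'   `individual_id`, `svl`, plus any others.
#' @return filtered tibble (possibly empty).
#' @export
filter_negative_growth <- function(obs) {
  obs <- tibble::as_tibble(obs)
  keep_ids <- obs |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::summarise(ok = dplyr::last(.data$svl) >= dplyr::first(.data$svl),
                     .groups = "drop") |>
    dplyr::filter(.data$ok) |>
    dplyr::pull("individual_id")
  n_removed <- length(unique(obs$individual_id)) - length(keep_ids)
  if (n_removed > 0) {
    message(sprintf("filter_negative_growth: removed %d individual(s)", n_removed))
  }
  out <- dplyr::filter(obs, .data$individual_id %in% keep_ids)
  attr(out, "n_removed") <- n_removed
  out
}

#' Priors for the growth model
#'
#' Asymptotic sizes get Normal(48, precision 0.01) priors (precision =
#' inverse variance, so SD 10); growth-coefficient regression terms get
#' Normal(0, precision 0.01); the SVL observation noise SD gets a
#' Half-Normal(0, 5 mm) prior.
#'
#' @param l_mean,l_sd asymptotic-size prior (mm).
#' @param beta_sd SD of the growth-coefficient priors.
#' @param sigma_obs_scale Half-Normal scale for observation noise (mm).
#' @return named list.
#' @export
growth_priors <- function(l_mean = 48, l_sd = 10, beta_sd = 10,
                          sigma_obs_scale = 5) {
  list(l_mean = l_mean, l_sd = l_sd, beta_sd = beta_sd,
       sigma_obs_scale = sigma_obs_scale)
}

# Consecutive-capture pairs from the long table (Markov-in-size likelihood).
growth_pairs <- function(obs) {
  obs <- tibble::as_tibble(obs)
  need <- c("individual_id", "sex", "plot", "interval_days", "svl")
  missing <- setdiff(need, names(obs))
  if (length(missing)) {
    abort(paste("growth data lack column(s):", paste(missing, collapse = ", ")))
  }
  if (any(is.na(obs$sex))) abort("unsexed individuals cannot enter the growth model")
  if (!all(obs$sex %in% c("male", "female"))) abort("`sex` must be 'male' or 'female'")
  if (!all(obs$plot %in% c("mature", "successional"))) {
    abort("`plot` must be 'mature' or 'successional'")
  }
  pairs <- obs |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::arrange(.data$capture, .by_group = TRUE) |>
    dplyr::mutate(svl_prev = dplyr::lag(.data$svl)) |>
    dplyr::filter(!is.na(.data$svl_prev)) |>
    dplyr::ungroup()
  if (nrow(pairs) == 0) abort("no recapture pairs: each individual needs >= 2 captures")
  if (any(pairs$interval_days < 0)) abort("negative capture interval")
  pairs
}

#' Fit the Fabens von Bertalanffy growth model
#'
#' Bayesian fit of the capture-recapture growth model
#' \deqn{SVL_t = SVL_{t-1} + (L_{sex} - SVL_{t-1})(1 - e^{-K_{i} I/365})}
#' with sex-specific asymptotic size and the growth coefficient modelled as
#' \eqn{K_i = \beta_0 + \beta_1 POS_i + \beta_2 SEX_i (+ \beta_3 POS_i
#' SEX_i)}, where `POS = 1` for successional plots and `SEX = 1` for males.
#'
#' The model is fitted in state-space form: each individual's size at
#' first capture is a latent quantity with a Uniform(10, 60) mm prior,
#' true sizes propagate deterministically along the growth curve, and
#' every recorded SVL is the true size plus Gaussian measurement noise
#' with estimated SD (Half-Normal(0, 5 mm) prior). Treating the first
#' size as latent rather than conditioning on its observed value avoids
#' the errors-in-variables bias that a regression on observed previous
#' SVL would introduce.
#'
#' By default the plot-by-sex interaction term \eqn{\beta_3} is included,
#' making the four group coefficients a saturated reparameterization (the
#' purely additive model is available with `interaction = FALSE`); derived
#' per-group K draws are emitted either way. Sampling is by adaptive
#' random-walk Metropolis (global parameters component-wise; all latent
#' initial sizes jointly, with per-individual acceptance); convergence is
#' summarized by split-Rhat per parameter and flagged against the
#' configured threshold.
#'
#' @param obs long-format growth tibble: columns `individual_id`, `sex`,
#'   `plot`, `capture`, `interval_days`, `svl`. Shrinking series are
#'   removed via [filter_negative_growth()] before fitting; individuals
#'   with a single capture are dropped.
#' @param priors a [growth_priors()] list.
#' @param mcmc an [mcmc_config()].
#' @param interaction include the POS x SEX interaction in K.
#' @param seed integer seed.
#' @return object of class `growth_fit` with elements `draws` (tibble:
#'   `chain`, `draw`, parameters and derived group Ks), `rhat`, `ess`,
#'   `converged`, `n_pairs`, `n_individuals`, `n_removed`, `svl0_mean`
#'   (posterior-mean latent initial sizes).
#' @examples
#' g <- simulate_growth_series(growth_params(), 40, c(180, 185), seed = 2)
#' fit <- fit_growth(g, mcmc = mcmc_config(chains = 2, iter = 2000, burnin = 500),
#'                   seed = 2)
#' tidy(fit)
#' @export
fit_growth <- function(obs, priors = growth_priors(),
                       mcmc = mcmc_config(), interaction = TRUE,
                       seed = 1L) {
  obs <- filter_negative_growth(obs)
  pairs <- growth_pairs(obs)          # validates schema, needs recaptures
  one_sex <- length(unique(pairs$sex)) < 2
  one_plot <- length(unique(pairs$plot)) < 2
  if (one_sex) warn("single-sex data: sex terms are prior-dominated")
  if (one_plot) warn("single-plot data: plot terms are prior-dominated")
  if (all(pairs$interval_days == 0)) {
    warn("all capture intervals are zero: K is unidentified; posterior follows the prior")
  }

  # wide matrices, one row per individual, NA-padded over captures
  keep_ids <- unique(pairs$individual_id)
  obs2 <- obs |>
    dplyr::filter(.data$individual_id %in% keep_ids) |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::arrange(.data$capture, .by_group = TRUE) |>
    dplyr::mutate(capture_idx = dplyr::row_number()) |>
    dplyr::ungroup()
  n <- length(keep_ids)
  ncap <- max(obs2$capture_idx)
  row_of <- match(obs2$individual_id, keep_ids)
  obs_mat <- matrix(NA_real_, n, ncap)
  obs_mat[cbind(row_of, obs2$capture_idx)] <- obs2$svl
  int_mat <- matrix(NA_real_, n, ncap)
  int_mat[cbind(row_of, obs2$capture_idx)] <- obs2$interval_days
  int_mat <- int_mat[, -1, drop = FALSE] / 365
  info <- obs2 |>
    dplyr::distinct(.data$individual_id, .data$sex, .data$plot) |>
    dplyr::arrange(match(.data$individual_id, keep_ids))
  pos <- as.numeric(info$plot == "successional")
  sexm <- as.numeric(info$sex == "male")
  obs_isna <- is.na(obs_mat)
  int_filled <- ifelse(is.na(int_mat), 0, int_mat)

  par_names <- c("l_male", "l_female", "b0", "b1", "b2",
                 if (interaction) "b3", "log_sigma_obs")
  npar <- length(par_names)
  b3_idx <- if (interaction) 6L else NA_integer_

  # per-individual log-likelihood given latent initial sizes and globals
  ind_ll <- function(th, svl0) {
    l <- ifelse(sexm == 1, th[1], th[2])
    k <- th[3] + th[4] * pos + th[5] * sexm
    if (interaction) k <- k + th[b3_idx] * pos * sexm
    sig <- exp(th[npar])
    s <- matrix(NA_real_, n, ncap)
    s[, 1] <- svl0
    for (j in seq_len(ncap - 1)) {
      s[, j + 1] <- s[, j] + (l - s[, j]) * (1 - exp(-k * int_filled[, j]))
    }
    ll <- dnorm(obs_mat, s, sig, log = TRUE)
    ll[obs_isna] <- 0
    rowSums(ll)
  }
  prior_ll <- function(th) {
    sig <- exp(th[npar])
    dnorm(th[1], priors$l_mean, priors$l_sd, log = TRUE) +
      dnorm(th[2], priors$l_mean, priors$l_sd, log = TRUE) +
      sum(dnorm(th[3:(npar - 1)], 0, priors$beta_sd, log = TRUE)) +
      dnorm(sig, 0, priors$sigma_obs_scale, log = TRUE) + th[npar]
  }

  set.seed(as.integer(seed))
  n_keep <- floor((mcmc$iter - mcmc$burnin) / mcmc$thin)
  chains_out <- vector("list", mcmc$chains)
  svl0_acc <- numeric(n)
  for (ch in seq_len(mcmc$chains)) {
    th <- c(45 + rnorm(1, 0, 2), 50 + rnorm(1, 0, 2),
            runif(1, 0.1, 0.8), rnorm(if (interaction) 3 else 2, 0, 0.2),
            log(runif(1, 0.3, 2)))
    svl0 <- pmin(59.9, pmax(10.1, obs_mat[, 1]))
    step <- rep(0.1, npar)
    step0 <- 0.5
    ll_i <- ind_ll(th, svl0)
    lp <- sum(ll_i) + prior_ll(th)
    keep <- matrix(NA_real_, n_keep, npar)
    kept <- 0L
    acc <- rep(0, npar); tries <- rep(0, npar)
    acc0 <- 0; tries0 <- 0
    for (it in seq_len(mcmc$iter)) {
      for (j in seq_len(npar)) {
        prop <- th
        prop[j] <- th[j] + rnorm(1, 0, step[j])
        ll_prop <- ind_ll(prop, svl0)
        lp_prop <- sum(ll_prop) + prior_ll(prop)
        tries[j] <- tries[j] + 1
        if (log(runif(1)) < lp_prop - lp) {
          th <- prop; lp <- lp_prop; ll_i <- ll_prop; acc[j] <- acc[j] + 1
        }
      }
      # latent initial sizes: joint proposal, per-individual acceptance
      s0_prop <- svl0 + rnorm(n, 0, step0)
      ok <- s0_prop > 10 & s0_prop < 60
      s0_try <- ifelse(ok, s0_prop, svl0)
      ll_try <- ind_ll(th, s0_try)
      take <- ok & (log(runif(n)) < ll_try - ll_i)
      svl0[take] <- s0_prop[take]
      ll_i[take] <- ll_try[take]
      lp <- sum(ll_i) + prior_ll(th)
      tries0 <- tries0 + 1
      acc0 <- acc0 + mean(take)
      if (it <= mcmc$burnin && it %% 50 == 0) {
        rate <- acc / pmax(tries, 1)
        step <- step * exp(rate - 0.44)
        step0 <- step0 * exp(acc0 / tries0 - 0.44)
        acc[] <- 0; tries[] <- 0; acc0 <- 0; tries0 <- 0
      }
      if (it > mcmc$burnin && (it - mcmc$burnin) %% mcmc$thin == 0 &&
          kept < n_keep) {
        kept <- kept + 1L
        keep[kept, ] <- th
        svl0_acc <- svl0_acc + svl0 / (n_keep * mcmc$chains)
      }
    }
    colnames(keep) <- par_names
    chains_out[[ch]] <- tibble::as_tibble(keep) |>
      dplyr::mutate(chain = ch, draw = dplyr::row_number(), .before = 1)
  }
  draws <- dplyr::bind_rows(chains_out) |>
    dplyr::mutate(
      b3 = if (interaction) .data$b3 else 0,
      sigma_obs = exp(.data$log_sigma_obs),
      k_mature_female = .data$b0,
      k_successional_female = .data$b0 + .data$b1,
      k_mature_male = .data$b0 + .data$b2,
      k_successional_male = .data$b0 + .data$b1 + .data$b2 + .data$b3
    ) |>
    dplyr::select(-"log_sigma_obs")

  track <- setdiff(names(draws), c("chain", "draw"))
  by_chain <- function(v) {
    matrix(draws[[v]], ncol = mcmc$chains)
  }
  rhat <- vapply(track, function(v) split_rhat(by_chain(v)), numeric(1))
  ess <- vapply(track, function(v) ess_basic(by_chain(v)), numeric(1))
  converged <- all(rhat < mcmc$rhat_threshold, na.rm = TRUE)
  if (!converged) {
    warn(sprintf("growth model not converged: max Rhat = %.3f",
                 max(rhat, na.rm = TRUE)))
  }

  structure(
    list(draws = draws, rhat = rhat, ess = ess, converged = converged,
         mcmc = mcmc, priors = priors, interaction = interaction,
         n_pairs = nrow(pairs),
         n_individuals = n,
         n_removed = attr(obs, "n_removed") %||% 0L,
         svl0_mean = tibble::tibble(individual_id = keep_ids,
                                    svl0 = svl0_acc)),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> %d individuals, %d capture pairs (%d removed by the negative-growth filter)\n",
              x$n_individuals, x$n_pairs, x$n_removed))
  cat(sprintf("  %d chains, %d kept draws; max Rhat %.3f (%s)\n",
              x$mcmc$chains, nrow(x$draws),
              max(x$rhat, na.rm = TRUE),
              if (x$converged) "converged" else "NOT converged"))
  print(tidy(x))
  invisible(x)
}

#' Posterior contrast between two growth-coefficient groups
#'
#' Per-draw difference `K[group_a] - K[group_b]`, the posterior probability
#' that the difference is positive, and a significance flag: the contrast
#' is called significant when more than 97.5% of the posterior density
#' falls on one side of zero.
#'
#' @param fit a [fit_growth()] result.
#' @param group_a,group_b group labels among `mature_female`,
#'   `mature_male`, `successional_female`, `successional_male`.
#' @return list with `draws` (difference per draw), `prob_positive`,
#'   `significant`, `mean`.
#' @export
contrast_k <- function(fit, group_a, group_b) {
  stopifnot(inherits(fit, "growth_fit"))
  if (identical(group_a, group_b)) abort("contrast requires two distinct groups")
  ka <- fit$draws[[paste0("k_", group_a)]]
  kb <- fit$draws[[paste0("k_", group_b)]]
  if (is.null(ka) || is.null(kb)) abort("unknown group label")
  d <- ka - kb
  p <- mean(d > 0)
  list(draws = d, prob_positive = p, significant = p > 0.975 || p < 0.025,
       mean = mean(d))
}

#' Time to grow between two lengths
#'
#' Closed-form travel time along the von Bertalanffy curve:
#' \eqn{t = -\ln((L - target)/(L - start))/K} years. Returns 0 when the
#' target has already been reached, `Inf` when the target is at or beyond
#' the asymptote, and `NA` when `K <= 0` with growth still required.
#' Vectorized over all arguments.
#'
#' @param l asymptotic SVL, mm.
#' @param k growth coefficient, yr^-1.
#' @param start,target SVL, mm (`start < l`).
#' @return years, possibly `Inf` or `NA`.
#' @examples
#' time_to_length(52.164, 0.339, 13.5, 34)
#' @export
time_to_length <- function(l, k, start, target) {
  n <- max(length(l), length(k), length(start), length(target))
  l <- rep_len(l, n); k <- rep_len(k, n)
  start <- rep_len(start, n); target <- rep_len(target, n)
  if (any(start >= l)) abort("`start` must be below the asymptote `l`")
  t <- suppressWarnings(-log((l - target) / (l - start)) / k)
  t[target <= start] <- 0
  t[target >= l] <- Inf
  bad <- k <= 0 & target > start & target < l
  if (any(bad)) {
    warn("K <= 0 with growth required: returning NA")
    t[bad] <- NA_real_
  }
  t
}

#' Cumulative maturity curve from posterior draws
#'
#' For each posterior draw of (L, K), computes the age at which an
#' individual starting at `start` mm reaches `threshold` mm:
#' `pre_growth_lag` plus the closed-form [time_to_length()]. Returns the
#' empirical cumulative proportion mature as a function of age and the
#' median maturation age (the age by which 50% of draws have matured).
#'
#' The `pre_growth_lag` (default 1 year) represents time between the start
#' of the projection clock and the onset of post-hatching growth (e.g. egg
#' development plus the first inactive season); it is a reconstruction
#' choice, not an estimated parameter, and is documented in the methods
#' vignette.
#'
#' @param draws data frame with columns `l` and `k`, e.g. from
#'   [growth_group_draws()] or [draw_growth_summaries()].
#' @param start,threshold SVL, mm (`threshold > start`).
#' @param pre_growth_lag years added to every maturation age.
#' @param age_grid ages (years) at which the cumulative curve is evaluated.
#' @return object of class `maturity_curve`: list with `ages` (per-draw
#'   maturation ages), `curve` (tibble `age`, `prop_mature`), `median_age`
#'   (NA with a warning if the curve never reaches 50%).
#' @examples
#' d <- draw_growth_summaries(52.164, 2.856, 0.339, 0.073, n = 1000,
#'                            l_above = 34, seed = 1)
#' maturity_curve(d)$median_age
#' @export
maturity_curve <- function(draws, start = 13.5, threshold = 34,
                           pre_growth_lag = 1,
                           age_grid = seq(0, 20, by = 0.01)) {
  stopifnot(is.data.frame(draws), all(c("l", "k") %in% names(draws)))
  if (threshold <= start) abort("`threshold` must exceed `start`")
  ages <- pre_growth_lag + time_to_length(draws$l, draws$k, start, threshold)
  finite <- is.finite(ages)
  curve <- tibble::tibble(
    age = age_grid,
    prop_mature = vapply(age_grid, function(a) mean(ages <= a, na.rm = FALSE),
                         numeric(1))
  )
  med <- if (mean(finite) < 0.5) {
    warn("fewer than half of draws ever reach the threshold; median age undefined")
    NA_real_
  } else {
    median(ages)
  }
  structure(list(ages = ages, curve = curve, median_age = med,
                 start = start, threshold = threshold,
                 pre_growth_lag = pre_growth_lag),
            class = "maturity_curve")
}

#' @export
print.maturity_curve <- function(x, ...) {
  cat(sprintf("<maturity_curve> %.1f -> %.1f mm, lag %.2f yr; median age %.3f yr\n",
              x$start, x$threshold, x$pre_growth_lag, x$median_age))
  invisible(x)
}

#' Posterior draws of (L, K) for one plot-by-sex group
#'
#' @param fit a [fit_growth()] result.
#' @param plot `"mature"` or `"successional"`.
#' @param sex `"female"` or `"male"`.
#' @return tibble with columns `l`, `k`, one row per posterior draw.
#' @export
growth_group_draws <- function(fit, plot, sex) {
  stopifnot(inherits(fit, "growth_fit"),
            plot %in% c("mature", "successional"),
            sex %in% c("female", "male"))
  tibble::tibble(
    l = fit$draws[[paste0("l_", sex)]],
    k = fit$draws[[paste0("k_", plot, "_", sex)]]
  )
}

#' Draws of (L, K) from published posterior summaries
#'
#' Emulates posterior draws from printed mean/SD summaries by sampling L
#' and K as independent normals, optionally truncating L above a size
#' threshold and K to positive values. Used when only summary tables, not
#' raw posterior draws, are available.
#'
#' @param l_mean,l_sd,k_mean,k_sd summary statistics.
#' @param n number of draws.
#' @param l_above if non-`NULL`, truncate L to be greater than this (mm).
#' @param k_positive truncate K to be positive.
#' @param seed integer seed.
#' @return tibble with columns `l`, `k`.
#' @export
draw_growth_summaries <- function(l_mean, l_sd, k_mean, k_sd, n = 100000,
                                  l_above = NULL, k_positive = TRUE,
                                  seed = 1L) {
  set.seed(as.integer(seed))
  l <- if (is.null(l_above)) rnorm(n, l_mean, l_sd) else {
    rtruncnorm(n, l_mean, l_sd, lower = l_above)
  }
  k <- if (k_positive) rtruncnorm(n, k_mean, k_sd, lower = 0) else {
    rnorm(n, k_mean, k_sd)
  }
  tibble::tibble(l = l, k = k)
}
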