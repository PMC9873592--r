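make_obs <- function(svl_series) {
  purrr::imap_dfr(svl_series, function(svl, i) {
    tibble::tibble(
      individual_id = i, sex = "female", plot = "mature",
      capture = seq_along(svl),
      interval_days = c(0, rep(180, length(svl) - 1)),
      svl = svl
    )
  })
}

test_that("negative-growth filter drops shrinking series only", {
  obs <- make_obs(list(c(30, 33), c(40, 38), c(36, 36, 41)))
  out <- suppressMessages(filter_negative_growth(obs))
  expect_setequal(unique(out$individual_id), c(1, 3))
  expect_equal(attr(out, "n_removed"), 1)
  # boundary: equality is retained; shrinking pair removed
  eq <- suppressMessages(filter_negative_growth(make_obs(list(c(35, 35),
                                                              c(35, 34)))))
  expect_equal(unique(eq$individual_id), 1)
  # idempotence (up to the removal-count bookkeeping attribute)
  out2 <- suppressMessages(filter_negative_growth(out))
  attr(out, "n_removed") <- attr(out2, "n_removed") <- NULL
  expect_identical(as.data.frame(out2), as.data.frame(out))
})

test_that("time_to_length matches the closed form and its flags", {
  # evaluated at published female successional values
  expect_equal(time_to_length(52.164, 0.339, 13.5, 34), 2.229,
               tolerance = 5e-4)
  expect_equal(time_to_length(50, 0.5, 30, 30), 0)
  expect_equal(time_to_length(50, 0.5, 30, 55), Inf)
  expect_warning(out <- time_to_length(50, 0, 30, 40), "NA")
  expect_true(is.na(out))
  # strictly decreasing in K and in L
  t_k <- time_to_length(50, c(0.2, 0.3, 0.4), 20, 40)
  expect_true(all(diff(t_k) < 0))
  t_l <- time_to_length(c(45, 50, 55), 0.3, 20, 40)
  expect_true(all(diff(t_l) < 0))
  # additivity through an intermediate size
  expect_equal(time_to_length(50, 0.3, 20, 35) + time_to_length(50, 0.3, 35, 45),
               time_to_length(50, 0.3, 20, 45))
})

test_that("the Fabens update has L as attracting fixed point", {
  fab <- function(s, l, k, frac) s + (l - s) * (1 - exp(-k * frac))
  expect_equal(fab(52, 52, 0.4, 1), 52)
  s <- 20
  path <- numeric(30)
  for (i in 1:30) path[i] <- s <- fab(s, 52, 0.4, 1)
  expect_true(all(diff(path) > 0))
  expect_true(all(path < 52))
  expect_equal(path[30], 52, tolerance = 1e-4)
})

test_that("maturity curve median follows the closed form for point draws", {
  d1 <- tibble::tibble(l = 52.164, k = 0.339)
  mc <- maturity_curve(d1, start = 13.5, threshold = 34, pre_growth_lag = 0)
  expect_equal(mc$median_age, 2.229, tolerance = 5e-4)
  mc_lag <- maturity_curve(d1, pre_growth_lag = 1)
  expect_equal(mc_lag$median_age, 3.229, tolerance = 5e-4)
  expect_warning(
    mc_bad <- maturity_curve(tibble::tibble(l = 30, k = 0.3), threshold = 34),
    "median age undefined")
  expect_true(is.na(mc_bad$median_age))
  expect_error(maturity_curve(d1, start = 40, threshold = 34), "exceed")
})

test_that("posterior contrasts follow the 97.5% rule", {
  fake <- structure(list(draws = tibble::tibble(
    k_mature_male = rnorm(500, 0.6, 0.01),
    k_successional_male = rnorm(500, 0.6, 0.01) + 10
  )), class = "growth_fit")
  cs <- contrast_k(fake, "successional_male", "mature_male")
  expect_equal(cs$prob_positive, 1)
  expect_true(cs$significant)
  same <- structure(list(draws = tibble::tibble(
    k_mature_male = rnorm(2000, 0.6, 0.05),
    k_successional_male = rnorm(2000, 0.6, 0.05)
  )), class = "growth_fit")
  cs2 <- contrast_k(same, "successional_male", "mature_male")
  expect_gt(cs2$prob_positive, 0.3)
  expect_lt(cs2$prob_positive, 0.7)
  expect_false(cs2$significant)
  expect_error(contrast_k(fake, "mature_male", "mature_male"), "distinct")
})

test_that("degenerate growth inputs are flagged", {
  one_sex <- simulate_growth_series(table4_growth(), 20, c(180, 180),
                                    seed = 1, p_female = 1)
  expect_warning(
    suppressMessages(fit_growth(one_sex,
                                mcmc = mcmc_config(chains = 1, iter = 400,
                                                   burnin = 100, thin = 1))),
    "single-sex")
  unsexed <- one_sex
  unsexed$sex[1] <- NA
  expect_error(suppressMessages(fit_growth(unsexed)), "unsexed")
})

test_that("growth fit recovers simulated parameters (small run)", {
  g <- simulate_growth_series(table4_growth(), 120, survey_schedule(),
                              seed = 21)
  fit <- suppressWarnings(suppressMessages(
    fit_growth(g, mcmc = mcmc_config(chains = 2, iter = 3000, burnin = 800,
                                     thin = 2), seed = 21)))
  s <- tidy(fit)
  get <- function(term) s[s$term == term, ]
  for (tt in c("l_male", "l_female")) {
    row <- get(tt)
    truth <- if (tt == "l_male") 43.569 else 52.164
    expect_lt(abs(row$mean - truth), 4 * row$sd)
  }
  expect_lt(abs(get("sigma_obs")$mean - 0.5), 0.1)
  # the Rhat diagnostic is reported for every tracked parameter
  expect_true(all(is.finite(fit$rhat)))
})

test_that("growth fit agrees with an independent JAGS fit", {
  g <- simulate_growth_series(table4_growth(), 80, c(180, 185), seed = 31)
  fit <- suppressWarnings(suppressMessages(
    fit_growth(g, mcmc = mcmc_config(chains = 2, iter = 3000, burnin = 800,
                                     thin = 2), seed = 31)))
  wide <- tidyr::pivot_wider(g, id_cols = c("individual_id", "sex", "plot"),
                             names_from = "capture", values_from = "svl")
  obs <- as.matrix(wide[, c("1", "2", "3")])
  model_str <- "
    model {
      for (i in 1:n) {
        svl0[i] ~ dunif(10, 60)
        s[i, 1] <- svl0[i]
        for (j in 2:ncap) {
          s[i, j] <- s[i, j - 1] +
            (l[i] - s[i, j - 1]) * (1 - exp(-k[i] * int[j - 1]))
        }
        for (j in 1:ncap) { y[i, j] ~ dnorm(s[i, j], prec) }
        l[i] <- lm * sexm[i] + lf * (1 - sexm[i])
        k[i] <- b0 + b1 * pos[i] + b2 * sexm[i] + b3 * pos[i] * sexm[i]
      }
      lm ~ dnorm(48, 0.01); lf ~ dnorm(48, 0.01)
      b0 ~ dnorm(0, 0.01); b1 ~ dnorm(0, 0.01)
      b2 ~ dnorm(0, 0.01); b3 ~ dnorm(0, 0.01)
      sig ~ dnorm(0, 0.04) T(0, )
      prec <- 1 / (sig * sig)
    }"
  jm <- rjags::jags.model(
    textConnection(model_str),
    data = list(y = obs, n = nrow(obs), ncap = 3,
                int = c(180, 185) / 365,
                sexm = as.numeric(wide$sex == "male"),
                pos = as.numeric(wide$plot == "successional")),
    n.chains = 2, n.adapt = 500, quiet = TRUE)
  post <- rjags::coda.samples(jm, c("lm", "lf", "b0", "b1", "b2", "b3",
                                    "sig"),
                              n.iter = 3000, thin = 3)
  jsum <- summary(post)$statistics
  s <- summarize_posterior(fit)
  pick <- function(term) s[s$term == term, ]
  # posterior means agree within combined Monte-Carlo + posterior scatter
  expect_lt(abs(pick("l_male")$mean - jsum["lm", "Mean"]),
            3 * max(pick("l_male")$sd, jsum["lm", "SD"]))
  expect_lt(abs(pick("l_female")$mean - jsum["lf", "Mean"]),
            3 * max(pick("l_female")$sd, jsum["lf", "SD"]))
  expect_lt(abs(pick("k_mature_female")$mean - jsum["b0", "Mean"]),
            3 * max(pick("k_mature_female")$sd, jsum["b0", "SD"]))
  expect_lt(abs(pick("sigma_obs")$mean - jsum["sig", "Mean"]),
            3 * max(pick("sigma_obs")$sd, jsum["sig", "SD"]))
})

test_that("group K posterior tightens with more individuals", {
  fit_n <- function(n) {
    g <- simulate_growth_series(table4_growth(sigma_obs = 0.2), n,
                                c(180, 185), seed = 7)
    suppressWarnings(suppressMessages(
      fit_growth(g, mcmc = mcmc_config(chains = 1, iter = 1500,
                                       burnin = 500, thin = 1), seed = 7)))
  }
  sd_small <- sd(fit_n(40)$draws$k_mature_female)
  sd_large <- sd(fit_n(160)$draws$k_mature_female)
  expect_lt(sd_large, sd_small)
})
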