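test_that("the detection likelihood matches a base-R binomial oracle", {
  bx <- c(0, 2); by <- c(0, 0)
  y <- c(2L, 0L); K <- 3L
  sigma <- 1.5; lam <- 0.4
  ours <- scr_detect_loglik_cpp(0.7, 0.4, y, K, bx, by, sigma, lam)
  p <- lam * exp(-((0.7 - bx)^2 + (0.4 - by)^2) / (2 * sigma^2))
  oracle <- sum(dbinom(y, K, p, log = TRUE)) -
    sum(lchoose(K, y))   # the model has no occasion-ordering constant
  expect_equal(ours, oracle, tolerance = 1e-10)
})

test_that("marginal toy likelihood equals numerical integration over ACs", {
  # 2-board, 1-individual toy: marginalize the Bernoulli product over a
  # fine grid of activity centers, comparing the sampler's likelihood
  # kernel against an independent base-R evaluation
  bx <- c(0, 2); by <- c(0, 0)
  y <- c(1L, 1L); K <- 2L
  sigma <- 1; lam <- 0.3
  gx <- seq(-4, 6, by = 0.02)
  gy <- seq(-4, 4, by = 0.02)
  grid <- expand.grid(x = gx, y = gy)
  lik_cpp <- vapply(seq_len(nrow(grid)), function(r) {
    exp(scr_detect_loglik_cpp(grid$x[r], grid$y[r], y, K, bx, by, sigma,
                              lam))
  }, numeric(1))
  p1 <- lam * exp(-((grid$x - 0)^2 + grid$y^2) / 2)
  p2 <- lam * exp(-((grid$x - 2)^2 + grid$y^2) / 2)
  lik_r <- p1 * (1 - p1) * p2 * (1 - p2)   # one success of K=2 per board
  expect_equal(lik_cpp, as.numeric(lik_r), tolerance = 1e-10)
  # marginal over the (uniform) AC prior: grid-average of both routes
  expect_equal(mean(lik_cpp), mean(lik_r), tolerance = 1e-10)
})

test_that("single-capture-only data are refused", {
  d <- tiny_design()
  cap <- tibble::tibble(individual_id = 1:3, plot_id = "p",
                        primary = 1L, secondary = 1L,
                        board_id = c(1L, 5L, 9L))
  expect_error(fit_scr(cap, d), "unidentifiable|recaptured")
})

test_that("captures outside the design are rejected", {
  d <- tiny_design()
  cap <- tibble::tibble(individual_id = c(1, 1), primary = c(1, 2),
                        secondary = 1L, board_id = c(1L, 999L))
  expect_error(fit_scr(cap, d), "outside the design")
  cap2 <- tibble::tibble(individual_id = c(1, 1), primary = c(1, 9),
                         secondary = 1L, board_id = c(1L, 2L))
  expect_error(fit_scr(cap2, d), "outside the design")
})

test_that("the likelihood is closed within primaries", {
  # permuting secondary-occasion labels within a primary must not change
  # the fit: the likelihood depends only on per-primary detection counts
  d <- tiny_design()
  cap <- simulate_scr_history(d, tiny_scr_truth(), seed = 13)
  perm <- cap |>
    dplyr::group_by(primary) |>
    dplyr::mutate(secondary = dplyr::recode(secondary, `1` = 2L, `2` = 1L)) |>
    dplyr::ungroup()
  mc <- mcmc_config(chains = 1, iter = 400, burnin = 100, thin = 1)
  f1 <- suppressWarnings(fit_scr(cap, d, mcmc = mc, seed = 3))
  f2 <- suppressWarnings(fit_scr(perm, d, mcmc = mc, seed = 3))
  expect_equal(f1$draws$sigma, f2$draws$sigma)
  expect_equal(f1$draws$density, f2$draws$density)
})

test_that("the likelihood and fit are invariant to coordinate translation", {
  # exact property at the likelihood level (up to float rounding)
  bx <- c(0, 2); by <- c(1, 3)
  y <- c(1L, 2L)
  base_ll <- scr_detect_loglik_cpp(0.7, 1.4, y, 3L, bx, by, 1.5, 0.3)
  shift_ll <- scr_detect_loglik_cpp(0.7 + 50, 1.4 - 30, y, 3L, bx + 50,
                                    by - 30, 1.5, 0.3)
  expect_equal(base_ll, shift_ll, tolerance = 1e-9)
  # fit level: same data shifted by 100 m gives the same posterior up to
  # Monte-Carlo noise (trajectories diverge through float rounding, so the
  # comparison is statistical, not bitwise)
  d <- tiny_design()
  cap <- simulate_scr_history(d, tiny_scr_truth(), seed = 14)
  shift <- 100
  boards2 <- d$boards
  boards2$x <- boards2$x + shift
  boards2$y <- boards2$y + shift
  d2 <- study_design(boards = boards2[c("x", "y")], n_primary = d$n_primary,
                     secondaries = d$secondaries,
                     primary_dates = d$primary_dates, buffer = d$buffer)
  cap2 <- cap
  cap2$board_x <- cap2$board_x + shift
  cap2$board_y <- cap2$board_y + shift
  cap2$board_id <- NULL
  mc <- mcmc_config(chains = 1, iter = 1200, burnin = 400, thin = 1)
  f1 <- suppressWarnings(fit_scr(cap, d, mcmc = mc, seed = 5))
  f2 <- suppressWarnings(fit_scr(cap2, d2, mcmc = mc, seed = 5))
  expect_lt(abs(mean(f1$draws$density) - mean(f2$draws$density)) /
              mean(f1$draws$density), 0.3)
})


test_that("inflating lambda in simulation raises the posterior detection rate", {
  d <- tiny_design()
  mc <- mcmc_config(chains = 1, iter = 800, burnin = 300, thin = 1)
  fit_at <- function(lam, seed) {
    cap <- simulate_scr_history(
      d, scr_params(phi = 0.95, sigma = 2, lam = lam, density = 0.08,
                    tau = 0.8), seed = seed)
    suppressWarnings(fit_scr(cap, d, mcmc = mc, seed = seed))
  }
  lo <- fit_at(0.03, 17)
  hi <- fit_at(0.2, 17)
  expect_gt(mean(hi$draws$lam), mean(lo$draws$lam))
})

test_that("compare_plots reproduces shift, exchangeability and the normal oracle", {
  base <- list(draws = tibble::tibble(density = rnorm(2000, 0.432, 0.072)))
  shifted <- list(draws = tibble::tibble(density = base$draws$density + 10))
  expect_equal(compare_plots(base, shifted, "density"), 1.0)
  expect_equal(compare_plots(base, base, "density"), 0.5, tolerance = 0.01)
  # closed-form Gaussian oracle: Pr(N(0.432,.072) > N(0.613,.089))
  set.seed(8)
  a <- list(draws = tibble::tibble(density = rnorm(4000, 0.613, 0.089)))
  b <- list(draws = tibble::tibble(density = rnorm(4000, 0.432, 0.072)))
  oracle <- pnorm((0.432 - 0.613) / sqrt(0.072^2 + 0.089^2))
  expect_equal(compare_plots(a, b, "density"), oracle, tolerance = 0.02)
  expect_error(compare_plots(a, b, "no_such"), "not present")
})

test_that("posterior summaries follow the quantile rules", {
  fake <- structure(list(
    draws = tibble::tibble(sigma = rep(3, 50)),
    rhat = c(sigma = 1), ess = c(sigma = 50)), class = "scr_fit")
  s <- summarize_posterior(fake)
  expect_equal(s$mean, 3)
  expect_equal(s$sd, 0)
  expect_equal(c(s$lower, s$upper), c(3, 3))
  fake2 <- structure(list(
    draws = tibble::tibble(sigma = as.numeric(1:100)),
    rhat = c(sigma = 1), ess = c(sigma = 100)), class = "scr_fit")
  s2 <- summarize_posterior(fake2)
  expect_equal(s2$mean, 50.5)
  expect_equal(s2$lower, unname(quantile(1:100, 0.025)))
  expect_equal(s2$upper, unname(quantile(1:100, 0.975)))
  empty <- structure(list(draws = tibble::tibble(),
                          rhat = numeric(0), ess = numeric(0)),
                     class = "scr_fit")
  expect_error(summarize_posterior(empty), "empty")
})
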