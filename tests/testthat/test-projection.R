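test_that("gravidity probability is a size-threshold step function", {
  cfg <- projection_config()
  expect_equal(gravid_probability(30, cfg), 0)
  expect_equal(gravid_probability(40, cfg), 0.56)
  expect_equal(gravid_probability(45, cfg), 0.94)
  expect_equal(gravid_probability(c(34, 43, 43.01), cfg),
               c(0.56, 0.56, 0.94))
  expect_error(gravid_probability(-1, cfg))
})

test_that("projection config validates its invariants", {
  expect_error(projection_config(hatch_rate = 1.2), "probabilities")
  expect_error(projection_config(survival_bounds = c(1, 0.4)), "ordered")
  expect_error(projection_config(horizon = 0), "at least 1")
  expect_error(projection_config(maturity_svl = 10), "exceed")
})

test_that("clutch model recovers noiseless and noisy generating lines", {
  noiseless <- tibble::tibble(svl = seq(34, 52, length.out = 30),
                              clutch = -4 + 0.3 * seq(34, 52,
                                                      length.out = 30))
  cm <- suppressWarnings(fit_clutch_model(noiseless))
  expect_equal(cm$slope, 0.3, tolerance = 1e-10)
  expect_equal(cm$intercept, -4, tolerance = 1e-8)
  expect_lt(cm$residual_sd, 1e-8)
  noisy <- make_clutch_table(200, slope = 0.3, residual_sd = 1.2, seed = 5)
  cm2 <- fit_clutch_model(noisy)
  expect_lt(abs(cm2$slope - 0.3), 2 * cm2$se[2])
  flat <- make_clutch_table(200, slope = 0, residual_sd = 1, seed = 6)
  cm3 <- fit_clutch_model(flat)
  expect_lt(abs(cm3$slope), 2 * cm3$se[2])
  expect_error(fit_clutch_model(tibble::tibble(svl = rep(40, 5),
                                               clutch = 1:5)),
               "unidentifiable")
  expect_error(fit_clutch_model(noiseless[1:2, ]), "at least 3")
})

test_that("single lives behave deterministically at the survival edges", {
  cl <- clutch_model(-4, 0.3, 0)
  # survival pinned to 1: lifespan equals the 20-year horizon
  cfg1 <- projection_config(survival_mean = 1, survival_sd = 0,
                            survival_bounds = c(0.999999, 1))
  life <- simulate_life(list(l = 52, k = 0.34), cl, cfg1, seed = 1)
  expect_equal(life$lifespan_years, 20)
  # certain first-year death: no reproduction possible
  cfg0 <- projection_config(survival_mean = 0, survival_sd = 0,
                            survival_bounds = c(0, 1e-9))
  life0 <- simulate_life(list(l = 52, k = 0.34), cl, cfg0, seed = 2)
  expect_equal(life0$lifespan_years, 0)
  expect_equal(life0$lifetime_fecundity, 0)
  expect_error(simulate_life(list(l = 10, k = 0.3), cl,
                             projection_config()), "exceed")
})

test_that("a noiseless always-gravid life matches the closed-form tally", {
  # instant growth to L, certain survival and gravidity, noiseless clutch:
  # every year from age 2 (lag 1 + first growth year) reproduces at SVL = L
  cl <- clutch_model(-4, 0.3, 0)
  cfg <- projection_config(survival_mean = 1, survival_sd = 0,
                           survival_bounds = c(0.999999, 1),
                           gravid_p_small = 1, gravid_p_large = 1)
  l <- 52
  life <- simulate_life(list(l = l, k = 1000), cl, cfg, seed = 3)
  clutch_at_l <- -4 + 0.3 * l
  expect_equal(life$n_clutches, 19)
  expect_equal(life$lifetime_fecundity, 19 * 0.9 * clutch_at_l,
               tolerance = 1e-9)
})

test_that("population projection matches the capped geometric expectation", {
  cfg <- projection_config(survival_mean = 0.836, survival_sd = 0,
                           n_sims = 60000)
  dr <- tibble::tibble(l = 52, k = 0.34)
  out <- project_population(dr, clutch_model(-4, 0.3, 0), cfg, seed = 4)
  expect_equal(out$lifespan_mean, sum(0.836^(1:20)), tolerance = 0.05)
})

test_that("fecundity responds monotonically to survival, hatch rate and gravidity", {
  dr <- tibble::tibble(l = rnorm(500, 52, 2), k = rnorm(500, 0.34, 0.05))
  cl <- clutch_model(-4, 0.3, 1)
  fec <- function(...) {
    cfg <- projection_config(n_sims = 20000, ...)
    project_population(dr, cl, cfg, seed = 11)$fecundity_mean
  }
  expect_gt(fec(survival_mean = 0.9), fec(survival_mean = 0.7))
  expect_gt(fec(hatch_rate = 0.9), fec(hatch_rate = 0.5))
  expect_gt(fec(gravid_p_small = 0.9, gravid_p_large = 0.99),
            fec(gravid_p_small = 0.3, gravid_p_large = 0.5))
})

test_that("life-history records satisfy their accounting invariants", {
  dr <- tibble::tibble(l = rnorm(300, 52, 2), k = abs(rnorm(300, 0.3, 0.1)))
  out <- project_population(dr, clutch_model(-4, 0.3, 1),
                            projection_config(n_sims = 5000), seed = 12,
                            keep_records = TRUE)
  rec <- attr(out, "records")
  expect_true(all(rec$n_clutches <= pmax(0, rec$lifespan_years -
                                              ceiling(rec$age_at_maturity) + 1)))
  expect_true(all(rec$lifetime_fecundity[rec$lifespan_years <
                                           rec$age_at_maturity] == 0))
  expect_true(all(rec$lifespan_years <= 20))
})

test_that("vectorized projection agrees with repeated single-life simulation", {
  cl <- clutch_model(-4, 0.3, 1)
  cfg <- projection_config(n_sims = 4000)
  dr <- tibble::tibble(l = 52, k = 0.34)
  pop <- project_population(dr, cl, cfg, seed = 21)
  set.seed(22)
  singles <- purrr::map_dfr(1:4000, function(i) {
    simulate_life(list(l = 52, k = 0.34), cl, cfg)
  })
  expect_lt(abs(pop$lifespan_mean - mean(singles$lifespan_years)), 0.2)
  expect_lt(abs(pop$fecundity_mean - mean(singles$lifetime_fecundity)), 1.5)
})

test_that("projections are bit-reproducible for a fixed seed", {
  dr <- tibble::tibble(l = rnorm(200, 52, 2), k = rnorm(200, 0.34, 0.05))
  cl <- clutch_model(-4, 0.3, 1)
  cfg <- projection_config(n_sims = 5000)
  a <- project_population(dr, cl, cfg, seed = 31)
  b <- project_population(dr, cl, cfg, seed = 31)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("faster growth brings earlier maturity and at least as many clutches", {
  cl <- clutch_model(-4, 0.3, 1)
  cfg <- projection_config(n_sims = 30000)
  slow <- project_population(tibble::tibble(l = 52.164, k = 0.237), cl,
                             cfg, seed = 41)
  fast <- project_population(tibble::tibble(l = 52.164, k = 0.339), cl,
                             cfg, seed = 41)
  expect_lt(fast$age_at_maturity_mean, slow$age_at_maturity_mean)
  expect_gte(fast$clutches_mean, slow$clutches_mean)
})
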