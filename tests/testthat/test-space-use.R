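test_that("use surfaces normalize and peak at the activity center", {
  r <- make_raster(c(0, 20), c(0, 20), 0.1)
  for (kern in c("halfnormal", "negexp")) {
    surf <- use_surface(c(10, 10), 2, r, kernel = kern)
    expect_equal(sum(surf$p), 1, tolerance = 1e-9)
    peak <- which(surf$p == max(surf$p), arr.ind = TRUE)
    expect_equal(surf$x[peak[1]], 10, tolerance = 0.1)
    expect_equal(surf$y[peak[2]], 10, tolerance = 0.1)
  }
  expect_error(use_surface(c(1, 1), 2, r), "margin")
  expect_error(use_surface(c(10, 10), 0, r), "positive")
})

test_that("tiny toy grids give the hand-computed weights", {
  r1 <- make_raster(c(0, 1), c(0, 1), 1)
  s1 <- use_surface(c(0.5, 0.5), 1, r1, check_margin = FALSE)
  expect_equal(as.numeric(s1$p), 1)
  # two cells equidistant from the AC split mass equally under any kernel
  r2 <- make_raster(c(0, 2), c(0, 1), 1)
  for (kern in c("halfnormal", "negexp")) {
    s2 <- use_surface(c(1, 0.5), 1, r2, kernel = kern,
                      check_margin = FALSE)
    expect_equal(as.numeric(s2$p), c(0.5, 0.5))
  }
  # 1-D 3-cell toy, distances 0, 1, 2 m, half-normal weights
  r3 <- make_raster(c(0, 3), c(0, 1), 1)
  s3 <- use_surface(c(0.5, 0.5), 1, r3, check_margin = FALSE)
  w <- c(1, exp(-0.5), exp(-2))
  expect_equal(as.numeric(s3$p), w / sum(w), tolerance = 1e-12)
})

test_that("multinomial use points match the surface frequencies", {
  r3 <- make_raster(c(0, 3), c(0, 1), 1)
  s3 <- use_surface(c(0.5, 0.5), 1, r3, check_margin = FALSE)
  # degenerate surface: all points in the single massive cell
  r1 <- make_raster(c(0, 1), c(0, 1), 1)
  s1 <- use_surface(c(0.5, 0.5), 1, r1, check_margin = FALSE)
  pts1 <- sample_use_points(s1, 100, seed = 1)
  expect_true(all(pts1$x >= 0 & pts1$x <= 1))
  # chi-square goodness of fit across seeded runs
  stat_below <- vapply(1:40, function(sd) {
    pts <- sample_use_points(s3, 1000, seed = sd)
    counts <- as.numeric(table(factor(floor(pts$x) + 1, levels = 1:3)))
    pr <- as.numeric(s3$p)
    sum((counts - 1000 * pr)^2 / (1000 * pr)) < qchisq(0.99, df = 2)
  }, logical(1))
  expect_gte(mean(stat_below), 0.95)
  expect_error(sample_use_points(s3, 0), "positive")
})

test_that("kernel UDs are normalized, mode-centred and translation-equivariant", {
  r <- make_raster(c(0, 30), c(0, 30), 0.1)
  set.seed(2)
  pts <- tibble::tibble(x = rnorm(800, 12, 1), y = rnorm(800, 12, 1))
  ud <- kernel_ud(pts, r)
  expect_equal(sum(ud$p), 1, tolerance = 1e-9)
  peak <- which(ud$p == max(ud$p), arr.ind = TRUE)
  expect_equal(ud$x[peak[1]], 12, tolerance = 0.3)
  ud2 <- kernel_ud(dplyr::mutate(pts, x = x + 5), r)
  peak2 <- which(ud2$p == max(ud2$p), arr.ind = TRUE)
  expect_equal(ud2$x[peak2[1]] - ud$x[peak[1]], 5, tolerance = 0.2)
  expect_warning(kernel_ud(tibble::tibble(x = rep(3, 10), y = rep(3, 10)),
                           r), "degenerate")
  expect_error(kernel_ud(pts[1:3, ], r), "at least 5")
})

test_that("Gaussian UDs obey the closed-form 50% contour", {
  r <- make_raster(c(0, 30), c(0, 30), 0.1)
  sigma <- 2
  surf <- use_surface(c(15, 15), sigma, r)
  core <- core_isopleth(surf, 0.5)
  expect_equal(core$area, pi * 2 * log(2) * sigma^2, tolerance = 0.02)
  # KDE route: mass of a large-sample UD inside the true 50% circle
  pts <- sample_use_points(surf, 50000, seed = 3)
  ud <- kernel_ud(pts, r)
  inside <- outer((ud$x - 15)^2, (ud$y - 15)^2, "+") <=
    2 * log(2) * sigma^2
  expect_equal(sum(ud$p[inside]), 0.5, tolerance = 0.02)
})

test_that("core isopleths take the smallest prefix and respect levels", {
  r4 <- make_raster(c(0, 2), c(0, 2), 1)
  ud <- new_ud_grid(r4, 1:2, 1:2, matrix(0.25, 2, 2))
  core <- core_isopleth(ud, 0.5)
  expect_equal(sum(core$mask), 2)
  core9 <- core_isopleth(ud, 0.999)
  expect_equal(sum(core9$mask), 4)
  expect_error(core_isopleth(ud, 1.2), "inside")
  # shrinking sigma shrinks the core (monotone)
  r <- make_raster(c(0, 30), c(0, 30), 0.1)
  areas <- vapply(c(1, 2, 3), function(sg) {
    core_isopleth(use_surface(c(15, 15), sg, r), 0.5)$area
  }, numeric(1))
  expect_true(all(diff(areas) > 0))
})

test_that("PHR identities hold and match a Monte-Carlo integration oracle", {
  r <- make_raster(c(0, 30), c(0, 30), 0.1)
  surf <- use_surface(c(15, 15), 2, r)
  for (lv in c(0.3, 0.5, 0.7)) {
    expect_equal(phr(surf, core_isopleth(surf, lv)), lv, tolerance = 0.02)
  }
  # two ACs 2 m apart, sigma 1: compare with direct integration of j's
  # continuous Gaussian UD over i's core cells (10^6 samples)
  s_i <- use_surface(c(14, 15), 1, r)
  s_j <- use_surface(c(16, 15), 1, r)
  core_i <- core_isopleth(s_i, 0.5)
  got <- phr(s_j, core_i)
  set.seed(4)
  mx <- rnorm(1e6, 16, 1); my <- rnorm(1e6, 15, 1)
  ix <- floor((mx - r$xlim[1]) / r$res) + 1
  iy <- floor((my - r$ylim[1]) / r$res) + 1
  gx <- match(ix, core_i$ix); gy <- match(iy, core_i$iy)
  ok <- !is.na(gx) & !is.na(gy)
  mc <- mean(ok & core_i$mask[cbind(pmax(gx, 1, na.rm = TRUE),
                                    pmax(gy, 1, na.rm = TRUE))])
  expect_equal(got, mc, tolerance = 0.01)
  # far-separated individuals do not overlap
  s_far <- use_surface(c(27, 27), 1, r)
  expect_lt(phr(s_far, core_i), 1e-6)
  # raster mismatch is an error
  r2 <- make_raster(c(0, 30), c(0, 30), 0.2)
  expect_error(phr(use_surface(c(15, 15), 2, r2), core_i), "raster")
})

test_that("overlap summaries match brute-force enumeration on a toy set", {
  r <- make_raster(c(0, 40), c(0, 40), 0.2)
  acs <- tibble::tibble(individual_id = 1:5,
                        x = c(10, 11, 12, 30, 31),
                        y = c(10, 10, 10, 30, 30))
  uds <- lapply(seq_len(5), function(i) {
    use_surface(c(acs$x[i], acs$y[i]), 1.5, r, check_margin = FALSE)
  })
  cores <- lapply(uds, core_isopleth, level = 0.5)
  out <- overlap_summary(uds, cores, acs)
  # brute-force pairwise mask intersection
  brute <- sapply(1:5, function(i) {
    sum(sapply(setdiff(1:5, i), function(j) {
      cores_intersect(cores[[i]], cores[[j]])
    }))
  })
  expect_equal(out$overlap_count, as.numeric(brute))
  # core radius ~1.77 m: the 1-2 m neighbours overlap, the 20-m gap does not
  expect_equal(out$overlap_count, c(2, 2, 2, 1, 1))
  expect_equal(out$nn_dist, c(1, 1, 1, 1, 1))
  expect_true(all(out$mean_phr >= 0 & out$mean_phr <= 1))
  expect_error(overlap_summary(uds[1], cores[1], acs[1, ]), "at least 2")
})

test_that("coincident activity centers give zero NN distance with a warning", {
  r <- make_raster(c(0, 20), c(0, 20), 0.2)
  acs <- tibble::tibble(individual_id = 1:2, x = c(10, 10), y = c(10, 10))
  uds <- lapply(1:2, function(i) use_surface(c(10, 10), 1, r))
  cores <- lapply(uds, core_isopleth)
  expect_warning(out <- overlap_summary(uds, cores, acs), "coincident")
  expect_equal(out$nn_dist, c(0, 0))
  expect_equal(out$overlap_count, c(1, 1))
})

test_that("the space-use pipeline is deterministic given a seed", {
  r <- make_raster(c(0, 20), c(0, 20), 0.25)
  acs <- tibble::tibble(individual_id = 1:3, x = c(8, 10, 12),
                        y = c(10, 10, 10))
  a <- space_use_analysis(acs, 2, r, n_points = 300, seed = 99)
  b <- space_use_analysis(acs, 2, r, n_points = 300, seed = 99)
  expect_identical(as.data.frame(a), as.data.frame(b))
})
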