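#' Raster specification for space-use grids
#'
#' Regular grid of square cells covering a rectangle; cell centers are at
#' `xlim[1] + (i - 0.5) * res`. All utilization distributions that are
#' compared (PHR, core intersection) must share one raster.
#'
#' @param xlim,ylim extents, meters.
#' @param res cell side, meters (default 0.1).
#' @return object of class `ud_raster`.
#' @export
make_raster <- function(xlim, ylim, res = 0.1) {
  nx <- max(1L, round(diff(xlim) / res))
  ny <- max(1L, round(diff(ylim) / res))
  structure(list(xlim = c(xlim[1], xlim[1] + nx * res),
                 ylim = c(ylim[1], ylim[1] + ny * res),
                 res = res, nx = nx, ny = ny),
            class = "ud_raster")
}

#' @rdname make_raster
#' @param design a [study_design()]; the raster covers its state space.
#' @export
raster_from_design <- function(design, res = 0.1) {
  make_raster(design$xlim, design$ylim, res)
}

same_raster <- function(a, b) {
  isTRUE(all.equal(a$raster[c("xlim", "ylim", "res")],
                   b$raster[c("xlim", "ylim", "res")], tolerance = 1e-9))
}

# windowed grid constructor: global indices ix, iy into the raster
new_ud_grid <- function(raster, ix, iy, p, what = "ud") {
  structure(
    list(raster = raster, ix = ix, iy = iy, p = p,
         x = raster$xlim[1] + (ix - 0.5) * raster$res,
         y = raster$ylim[1] + (iy - 0.5) * raster$res,
         what = what),
    class = "ud_grid"
  )
}

#' @export
print.ud_grid <- function(x, ...) {
  cat(sprintf("<ud_grid:%s> %d x %d cells at %.2g m; mass %.4f\n",
              x$what, length(x$ix), length(x$iy), x$raster$res, sum(x$p)))
  invisible(x)
}

#' Probability-of-use surface around an activity center
#'
#' Evaluates a distance-decay kernel at cell centers and normalizes to a
#' discrete probability-of-use surface summing to 1. The kernel is
#' selectable: `"halfnormal"` gives \eqn{\exp(-d^2/2\sigma^2)} (consistent
#' with the SCR detection model, the default), `"negexp"` gives the
#' negative-exponential \eqn{\exp(-d/\sigma)}.
#'
#' Computation is restricted to a window of `window_sigma` \eqn{\times
#' \sigma} around the activity center (mass beyond is negligible), so many
#' individuals can share one fine raster cheaply.
#'
#' @param ac length-2 numeric activity center (m) or one-row data frame
#'   with `x`, `y`.
#' @param sigma space-use scale, meters (> 0); typically one posterior
#'   draw of the SCR \eqn{\sigma}.
#' @param raster a [make_raster()] spec.
#' @param kernel `"halfnormal"` or `"negexp"`.
#' @param window_sigma window half-width in \eqn{\sigma} units.
#' @param check_margin error if the raster does not cover the activity
#'   center with a 3\eqn{\sigma} margin (disable for deliberately tiny toy
#'   grids).
#' @return a `ud_grid` of type `"use"`.
#' @export
use_surface <- function(ac, sigma, raster,
                        kernel = c("halfnormal", "negexp"),
                        window_sigma = 4, check_margin = TRUE) {
  kernel <- match.arg(kernel)
  if (is.data.frame(ac)) ac <- c(ac$x[1], ac$y[1])
  if (sigma <= 0) abort("`sigma` must be positive")
  if (check_margin) {
    if (ac[1] - 3 * sigma < raster$xlim[1] || ac[1] + 3 * sigma > raster$xlim[2] ||
        ac[2] - 3 * sigma < raster$ylim[1] || ac[2] + 3 * sigma > raster$ylim[2]) {
      abort("raster too small: it must cover the activity center with a 3-sigma margin")
    }
  }
  half <- window_sigma * sigma
  ix <- index_range(raster$xlim, raster$res, raster$nx, ac[1], half)
  iy <- index_range(raster$ylim, raster$res, raster$ny, ac[2], half)
  cx <- raster$xlim[1] + (ix - 0.5) * raster$res
  cy <- raster$ylim[1] + (iy - 0.5) * raster$res
  d2 <- outer((cx - ac[1])^2, (cy - ac[2])^2, "+")
  w <- switch(kernel,
    halfnormal = exp(-d2 / (2 * sigma^2)),
    negexp = exp(-sqrt(d2) / sigma)
  )
  g <- new_ud_grid(raster, ix, iy, w / sum(w), what = "use")
  g$ac <- ac
  g$sigma <- sigma
  g$kernel <- kernel
  g
}

index_range <- function(lim, res, nmax, center, half) {
  lo <- max(1L, as.integer(floor((center - half - lim[1]) / res)) + 1L)
  hi <- min(nmax, as.integer(ceiling((center + half - lim[1]) / res)))
  lo:hi
}

#' Multinomial use points from a use surface
#'
#' Distributes `n` hypothetical use points over the landscape: cells are
#' drawn from a multinomial with the surface probabilities, then jittered
#' uniformly within each cell to continuous coordinates (so downstream
#' kernel bandwidth estimation is non-degenerate).
#'
#' @param surface a [use_surface()] result.
#' @param n number of points (default 1000).
#' @param seed optional integer seed.
#' @return tibble with columns `x`, `y`.
#' @export
sample_use_points <- function(surface, n = 1000, seed = NULL) {
  stopifnot(inherits(surface, "ud_grid"))
  if (n <= 0) abort("`n` must be positive")
  if (!is.null(seed)) set.seed(as.integer(seed))
  cells <- sample.int(length(surface$p), n, replace = TRUE,
                      prob = as.vector(surface$p))
  nx <- length(surface$ix)
  cix <- (cells - 1L) %% nx + 1L
  ciy <- (cells - 1L) %/% nx + 1L
  res <- surface$raster$res
  tibble::tibble(
    x = surface$x[cix] + runif(n, -res / 2, res / 2),
    y = surface$y[ciy] + runif(n, -res / 2, res / 2)
  )
}

#' Reference bandwidth for a bivariate kernel density
#'
#' The ad hoc ("href") rule for bivariate kernel home-range estimation:
#' \eqn{h = \sqrt{(s_x^2 + s_y^2)/2}\, n^{-1/6}}.
#'
#' @param x,y point coordinates.
#' @return bandwidth (kernel SD), meters.
#' @export
href_bandwidth <- function(x, y) {
  sqrt(0.5 * (var(x) + var(y))) * length(x)^(-1 / 6)
}

#' Kernel utilization distribution from use points
#'
#' Bivariate Gaussian kernel density of the use points, evaluated on the
#' shared raster (windowed to the point cloud plus a 3-bandwidth pad) and
#' normalized to a discrete UD summing to 1. Bandwidth defaults to the
#' reference ("href") rule; degenerate point sets (all identical) fall
#' back to one cell width with a warning.
#'
#' @param points data frame with `x`, `y` (>= 5 points).
#' @param raster shared [make_raster()] spec.
#' @param bandwidth `"href"` or a numeric kernel SD in meters.
#' @return a `ud_grid` of type `"ud"`.
#' @export
kernel_ud <- function(points, raster, bandwidth = "href") {
  stopifnot(is.data.frame(points), all(c("x", "y") %in% names(points)))
  if (nrow(points) < 5) abort("kernel UD needs at least 5 points")
  h <- if (identical(bandwidth, "href")) {
    href_bandwidth(points$x, points$y)
  } else {
    as.numeric(bandwidth)
  }
  if (!is.finite(h) || h < raster$res / 10) {
    warn("degenerate point set: falling back to a one-cell-wide bandwidth")
    h <- raster$res
  }
  pad <- 3 * h + raster$res
  cxr <- range(points$x); cyr <- range(points$y)
  ix <- index_range(raster$xlim, raster$res, raster$nx,
                    mean(cxr), diff(cxr) / 2 + pad)
  iy <- index_range(raster$ylim, raster$res, raster$ny,
                    mean(cyr), diff(cyr) / 2 + pad)
  cx <- raster$xlim[1] + (ix - 0.5) * raster$res
  cy <- raster$ylim[1] + (iy - 0.5) * raster$res
  dens <- MASS::kde2d(points$x, points$y, h = 4 * h,
                      n = c(length(ix), length(iy)),
                      lims = c(range(cx), range(cy)))
  p <- dens$z / sum(dens$z)
  new_ud_grid(raster, ix, iy, p, what = "ud")
}

#' Core isopleth of a utilization distribution
#'
#' The minimal-area cell set holding at least `level` of the UD mass:
#' cells are ranked by density (ties broken by stable cell order) and the
#' smallest prefix reaching the target cumulative mass is kept.
#'
#' @param ud a `ud_grid`.
#' @param level isopleth level in (0, 1); 0.5 gives the 50% core.
#' @return object of class `ud_core`: the grid window plus a logical
#'   `mask`, the attained `mass`, and `area` in m^2.
#' @export
core_isopleth <- function(ud, level = 0.5) {
  stopifnot(inherits(ud, "ud_grid"))
  if (level <= 0 || level >= 1) abort("`level` must be inside (0, 1)")
  o <- order(ud$p, decreasing = TRUE)
  cum <- cumsum(ud$p[o])
  ncore <- which(cum >= level)[1]
  mask <- matrix(FALSE, nrow(ud$p), ncol(ud$p))
  mask[o[seq_len(ncore)]] <- TRUE
  structure(
    list(raster = ud$raster, ix = ud$ix, iy = ud$iy, mask = mask,
         level = level, mass = cum[ncore],
         area = ncore * ud$raster$res^2),
    class = "ud_core"
  )
}

#' Probability of home-range overlap (PHR)
#'
#' The PHR of individual `j` with respect to individual `i`'s core area:
#' the total mass of `j`'s UD falling inside `i`'s core isopleth cells.
#' Both grids must live on the same raster.
#'
#' @param ud_j a `ud_grid` (individual j's UD).
#' @param core_i a [core_isopleth()] result (individual i's core).
#' @return probability in `[0, 1]`.
#' @export
phr <- function(ud_j, core_i) {
  stopifnot(inherits(ud_j, "ud_grid"), inherits(core_i, "ud_core"))
  if (!same_raster(ud_j, core_i)) abort("UD and core are on different rasters")
  ix <- intersect(ud_j$ix, core_i$ix)
  iy <- intersect(ud_j$iy, core_i$iy)
  if (!length(ix) || !length(iy)) return(0)
  pj <- ud_j$p[match(ix, ud_j$ix), match(iy, ud_j$iy), drop = FALSE]
  mi <- core_i$mask[match(ix, core_i$ix), match(iy, core_i$iy), drop = FALSE]
  sum(pj[mi])
}

cores_intersect <- function(core_i, core_j) {
  ix <- intersect(core_i$ix, core_j$ix)
  iy <- intersect(core_i$iy, core_j$iy)
  if (!length(ix) || !length(iy)) return(FALSE)
  a <- core_i$mask[match(ix, core_i$ix), match(iy, core_i$iy), drop = FALSE]
  b <- core_j$mask[match(ix, core_j$ix), match(iy, core_j$iy), drop = FALSE]
  any(a & b)
}

#' Pairwise overlap and nearest-neighbour summary
#'
#' For every individual: the mean and maximum PHR of all other
#' individuals' UDs over its core area, the number of other individuals
#' whose core isopleth intersects its own (binary mask intersection), and
#' the distance to the nearest other activity center.
#'
#' @param uds list of `ud_grid`s, one per individual, on a shared raster.
#' @param cores list of matching [core_isopleth()] results.
#' @param acs data frame with `individual_id`, `x`, `y` activity centers
#'   (posterior means or per-draw values), same order as `uds`.
#' @return tibble with one row per individual: `individual_id`,
#'   `mean_phr`, `max_phr`, `overlap_count`, `nn_dist`. Coincident
#'   activity centers yield `nn_dist = 0` with a warning.
#' @export
overlap_summary <- function(uds, cores, acs) {
  n <- length(uds)
  if (n < 2) abort("overlap and nearest-neighbour statistics need at least 2 individuals")
  stopifnot(length(cores) == n, nrow(acs) == n)
  # window prefilter: grids with disjoint windows have PHR 0, no intersection
  xr <- vapply(uds, function(u) range(u$x), numeric(2))
  yr <- vapply(uds, function(u) range(u$y), numeric(2))
  phr_mat <- matrix(0, n, n)
  olap <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (xr[1, j] > xr[2, i] || xr[2, j] < xr[1, i] ||
          yr[1, j] > yr[2, i] || yr[2, j] < yr[1, i]) next
      phr_mat[i, j] <- phr(uds[[j]], cores[[i]])
      if (j > i) {
        olap[i, j] <- olap[j, i] <- cores_intersect(cores[[i]], cores[[j]])
      }
    }
  }
  d <- as.matrix(stats::dist(cbind(acs$x, acs$y)))
  diag(d) <- Inf
  nn <- unname(apply(d, 1, min))
  if (any(nn == 0)) warn("coincident activity centers: nearest-neighbour distance 0")
  out <- tibble::tibble(
    individual_id = acs$individual_id,
    mean_phr = rowSums(phr_mat) / (n - 1),
    max_phr = apply(phr_mat + diag(-Inf, n), 1, max),
    overlap_count = rowSums(olap),
    nn_dist = nn
  )
  attr(out, "phr") <- phr_mat
  out
}

#' Plot-level space-use summary
#'
#' Means and SDs across individuals of the per-individual overlap
#' statistics, in the shape of a published summary table.
#'
#' @param x an [overlap_summary()] tibble.
#' @return one-row tibble of means with `_sd` companions.
#' @export
summarize_overlap <- function(x) {
  tibble::tibble(
    mean_phr = mean(x$mean_phr), mean_phr_sd = sd(x$mean_phr),
    max_phr = mean(x$max_phr), max_phr_sd = sd(x$max_phr),
    overlap = mean(x$overlap_count), overlap_sd = sd(x$overlap_count),
    nn = mean(x$nn_dist), nn_sd = sd(x$nn_dist)
  )
}

#' End-to-end space-use analysis for one plot
#'
#' Builds, for every individual, the probability-of-use surface at its
#' activity center, then a utilization distribution, the 50% core
#' isopleth, and finally the pairwise overlap summary. With `method =
#' "kde"` the UD is a kernel density of `n_points` multinomial use points
#' sampled from the surface (the full published procedure); with
#' `method = "surface"` the normalized use surface itself is taken as the
#' UD (the deterministic large-`n_points` limit, cheaper and exact for
#' qualitative comparisons).
#'
#' `sigma` may be a vector of posterior draws, in which case the analysis
#' is repeated per draw and the per-individual statistics are averaged
#' across draws.
#'
#' @param acs data frame with `individual_id`, `x`, `y`.
#' @param sigma scalar or vector of space-use scale draws, meters.
#' @param raster shared [make_raster()] spec.
#' @inheritParams use_surface
#' @param method `"kde"` or `"surface"`.
#' @param n_points use points per individual for `"kde"`.
#' @param level core isopleth level.
#' @param seed integer seed.
#' @return [overlap_summary()] tibble (averaged over draws when `sigma`
#'   has length > 1), with the plot-level [summarize_overlap()] row as
#'   attribute `"plot_summary"`.
#' @export
space_use_analysis <- function(acs, sigma, raster,
                               kernel = c("halfnormal", "negexp"),
                               method = c("kde", "surface"),
                               n_points = 1000, level = 0.5, seed = 1L) {
  kernel <- match.arg(kernel)
  method <- match.arg(method)
  acs <- tibble::as_tibble(acs)
  set.seed(as.integer(seed))
  per_draw <- purrr::map(sigma, function(sg) {
    uds <- purrr::map(seq_len(nrow(acs)), function(i) {
      surf <- use_surface(c(acs$x[i], acs$y[i]), sg, raster, kernel = kernel,
                          check_margin = FALSE)
      if (method == "surface") return(surf)
      pts <- sample_use_points(surf, n = n_points)
      kernel_ud(pts, raster)
    })
    cores <- purrr::map(uds, core_isopleth, level = level)
    overlap_summary(uds, cores, acs)
  })
  out <- if (length(per_draw) == 1) per_draw[[1]] else {
    dplyr::bind_rows(per_draw) |>
      dplyr::group_by(.data$individual_id) |>
      dplyr::summarise(dplyr::across(dplyr::everything(), mean),
                       .groups = "drop")
  }
  attr(out, "plot_summary") <- summarize_overlap(out)
  out
}
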