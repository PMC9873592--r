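#' Priors for the SCR model
#'
#' Survival, baseline detection and the inclusion probability get
#' Uniform(0, 1) priors; the space-use scale and dispersal SD get
#' Uniform(0, `sigma_max`) / Uniform(0, `tau_max`) priors (meters);
#' activity centers are uniform over the state space at entry.
#'
#' @param sigma_max,tau_max upper prior bounds, meters.
#' @return named list.
#' @export
scr_priors <- function(sigma_max = 20, tau_max = 20) {
  list(sigma_max = sigma_max, tau_max = tau_max)
}

#' Fit the robust-design spatial capture-recapture model
#'
#' Bayesian fit, by Markov chain Monte Carlo with data augmentation, of an
#' open-population SCR model: `M` augmented individuals enter the
#' superpopulation with probability \eqn{\psi}; all included individuals
#' are present from the first primary session and thereafter survive each
#' between-primary interval with probability \eqn{\Phi^{\Delta/365}};
#' activity centers are uniform over the state space at entry and follow a
#' bivariate normal random walk with per-axis SD \eqn{\tau} between
#' primaries; within the closed secondary occasions of each primary,
#' detection at board \eqn{j} is Bernoulli with half-normal probability
#' \eqn{\lambda \exp(-d^2/2\sigma^2)}.
#'
#' Density is reported per posterior draw as the included superpopulation
#' divided by the state-space area (all included individuals are present
#' at the first primary, so this is the entry density -- the quantity the
#' simulator's `density` parameter controls); the alive count averaged
#' over primaries is kept as the `density_avg_alive` draw column. Mean
#' between-primary dispersal is \eqn{\tau\sqrt{\pi/2}}.
#' Convergence is summarized by split-Rhat and flagged (never silently
#' dropped) against `mcmc$rhat_threshold`.
#'
#' @param data capture tibble as from [simulate_scr_history()] or
#'   [read_capture_csv()]: columns `individual_id`, `primary`, `secondary`,
#'   `board_id` (or `board_x`/`board_y` matching the design).
#' @param design the [study_design()] that generated the data; must cover
#'   every capture board.
#' @param mcmc an [mcmc_config()]; the default is a desk-scale
#'   configuration (2 chains x 4,500 iterations) adequate for
#'   simulation-recovery work.
#' @param priors an [scr_priors()] list.
#' @param M data-augmentation size; default 4 x the number of observed
#'   individuals. The fit warns if the posterior superpopulation
#'   approaches `M`.
#' @param kernel_cut detection-kernel truncation radius in units of
#'   \eqn{\sigma} used inside the sampler (contributions beyond
#'   `kernel_cut * sigma` are numerically negligible at the default 4).
#' @param w_frac fraction of augmented individuals whose inclusion
#'   indicator is refreshed per iteration (random-scan Gibbs).
#' @param seed integer seed.
#' @return object of class `scr_fit`: `draws` (tibble with `chain`,
#'   `draw`, `phi`, `sigma`, `lam`, `tau`, `psi`, `density`,
#'   `mean_dispersal`, `n_super`), `rhat`, `ess`, `converged`, `ac`
#'   (posterior-mean activity centers of observed individuals per
#'   primary), `design`, `M`, `n_obs`.
#' @export
fit_scr <- function(data, design,
                    mcmc = mcmc_config(chains = 2, iter = 4500,
                                       burnin = 1800, thin = 3),
                    priors = scr_priors(),
                    M = NULL, kernel_cut = 4, w_frac = 0.5,
                    seed = 1L) {
  stopifnot(inherits(design, "study_design"))
  data <- tibble::as_tibble(data)
  need <- c("individual_id", "primary", "secondary")
  if (!all(need %in% names(data))) {
    abort(paste("capture data need columns:", paste(need, collapse = ", ")))
  }
  if (nrow(data) == 0) abort("empty capture table: nothing to fit")
  if (!"board_id" %in% names(data)) {
    data <- dplyr::left_join(
      data, design$boards,
      by = c(board_x = "x", board_y = "y")
    )
  }
  if (any(!data$board_id %in% design$boards$board_id) ||
      any(is.na(data$board_id))) {
    abort("capture at a board outside the design")
  }
  if (any(data$primary < 1 | data$primary > design$n_primary)) {
    abort("primary index outside the design")
  }
  if (any(data$secondary < 1 |
          data$secondary > design$secondaries[data$primary])) {
    abort("secondary index outside the design")
  }
  if (anyDuplicated(data[c("individual_id", "primary", "secondary",
                           "board_id")]) > 0) {
    abort("duplicate (individual, primary, secondary, board) rows")
  }

  ids <- sort(unique(data$individual_id))
  n_obs <- length(ids)
  n_dets <- table(data$individual_id)
  if (max(n_dets) < 2) {
    abort(paste("no recaptured individuals: the spatial scale sigma is",
                "unidentifiable from single captures"))
  }
  counts <- data |>
    dplyr::count(.data$individual_id, .data$primary, .data$board_id,
                 name = "n_det") |>
    dplyr::mutate(i = match(.data$individual_id, ids) - 1L,
                  p = .data$primary - 1L,
                  j = match(.data$board_id, design$boards$board_id) - 1L)

  M <- as.integer(M %||% (4L * n_obs))
  if (M <= n_obs) abort("`M` must exceed the number of observed individuals")

  # data-driven starting values
  det_xy <- dplyr::left_join(data, design$boards, by = "board_id")
  spread <- det_xy |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::summarise(s = sqrt(var(.data$x) + var(.data$y)), .groups = "drop")
  sigma0 <- max(1, mean(spread$s, na.rm = TRUE), na.rm = TRUE)
  if (!is.finite(sigma0)) sigma0 <- 2
  occ_total <- sum(design$secondaries)
  lam0 <- min(0.5, max(0.005, nrow(data) / (n_obs * occ_total * 10)))

  set.seed(as.integer(seed))

  # observed-individual AC starts: mean detection location per primary,
  # falling back to the individual's overall mean
  mean_all <- det_xy |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::summarise(mx = mean(.data$x), my = mean(.data$y), .groups = "drop")
  mean_pp <- det_xy |>
    dplyr::group_by(.data$individual_id, .data$primary) |>
    dplyr::summarise(mx = mean(.data$x), my = mean(.data$y), .groups = "drop")
  P <- design$n_primary
  init_sx <- matrix(runif(M * P, design$xlim[1], design$xlim[2]), M, P)
  init_sy <- matrix(runif(M * P, design$ylim[1], design$ylim[2]), M, P)
  for (r in seq_len(n_obs)) {
    init_sx[r, ] <- mean_all$mx[mean_all$individual_id == ids[r]]
    init_sy[r, ] <- mean_all$my[mean_all$individual_id == ids[r]]
  }
  pp_i <- match(mean_pp$individual_id, ids)
  init_sx[cbind(pp_i, mean_pp$primary)] <- mean_pp$mx
  init_sy[cbind(pp_i, mean_pp$primary)] <- mean_pp$my

  chains_out <- vector("list", mcmc$chains)
  ac_x <- ac_y <- 0
  for (ch in seq_len(mcmc$chains)) {
    inits <- c(
      phi = min(0.98, max(0.5, 0.9 + runif(1, -0.05, 0.05))),
      sigma = sigma0 * exp(runif(1, -0.2, 0.2)),
      lam = lam0 * exp(runif(1, -0.3, 0.3)),
      tau = 1 * exp(runif(1, -0.2, 0.2)),
      psi = min(0.9, (2 * n_obs) / M)
    )
    res <- scr_mcmc_cpp(
      det_i = counts$i, det_p = counts$p, det_j = counts$j,
      det_n = counts$n_det,
      M = M, n_obs = n_obs, P = P,
      K_sec = design$secondaries,
      board_x = design$boards$x, board_y = design$boards$y,
      intervals = as.numeric(design$intervals),
      state_xlim = design$xlim, state_ylim = design$ylim,
      sigma_max = priors$sigma_max, tau_max = priors$tau_max,
      n_iter = mcmc$iter, n_burn = mcmc$burnin, thin = mcmc$thin,
      kernel_cut = kernel_cut, w_frac = w_frac,
      inits = unname(inits),
      init_sx = as.vector(t(init_sx)), init_sy = as.vector(t(init_sy))
    )
    chains_out[[ch]] <- tibble::tibble(
      chain = ch, draw = seq_along(res$phi),
      phi = res$phi, sigma = res$sigma, lam = res$lam, tau = res$tau,
      psi = res$psi,
      density = res$n_super / design$area,
      density_avg_alive = res$density,
      mean_dispersal = res$tau * sqrt(pi / 2), n_super = res$n_super
    )
    ac_x <- ac_x + res$ac_mean_x / mcmc$chains
    ac_y <- ac_y + res$ac_mean_y / mcmc$chains
  }
  draws <- dplyr::bind_rows(chains_out)

  track <- c("phi", "sigma", "lam", "tau", "density", "mean_dispersal")
  by_chain <- function(v) matrix(draws[[v]], ncol = mcmc$chains)
  rhat <- vapply(track, function(v) split_rhat(by_chain(v)), numeric(1))
  ess <- vapply(track, function(v) ess_basic(by_chain(v)), numeric(1))
  converged <- all(rhat < mcmc$rhat_threshold, na.rm = TRUE)
  if (!converged) {
    warn(sprintf("SCR model not converged: max Rhat = %.3f",
                 max(rhat, na.rm = TRUE)))
  }
  if (mean(draws$n_super) > 0.9 * M) {
    warn("posterior superpopulation is close to the augmentation size M; increase M")
  }

  ac <- tibble::tibble(
    individual_id = rep(ids, each = P),
    primary = rep(seq_len(P), n_obs),
    x = ac_x, y = ac_y
  )
  structure(
    list(draws = draws, rhat = rhat, ess = ess, converged = converged,
         ac = ac, design = design, M = M, n_obs = n_obs, mcmc = mcmc,
         priors = priors),
    class = "scr_fit"
  )
}

#' @export
print.scr_fit <- function(x, ...) {
  cat(sprintf("<scr_fit> %d observed individuals, M = %d, %d chains x %d draws (max Rhat %.3f%s)\n",
              x$n_obs, x$M, x$mcmc$chains, nrow(x$draws) / x$mcmc$chains,
              max(x$rhat, na.rm = TRUE),
              if (x$converged) "" else ", NOT converged"))
  print(tidy(x))
  invisible(x)
}

#' Posterior probability that a parameter differs between two fits
#'
#' Computes `Pr(parameter_b > parameter_a)` by comparing posterior samples
#' from two independently fitted models: every draw of `fit_b` is paired
#' with every draw of `fit_a` (the exact expectation of random pairing).
#'
#' @param fit_a,fit_b two `scr_fit` (or `growth_fit`) objects.
#' @param parameter parameter name present in both draw tables.
#' @param max_draws cap on draws per fit before the all-pairs comparison.
#' @return probability in `[0, 1]`.
#' @export
compare_plots <- function(fit_a, fit_b, parameter, max_draws = 2000) {
  da <- fit_a$draws[[parameter]]
  db <- fit_b$draws[[parameter]]
  if (is.null(da) || is.null(db)) {
    abort(sprintf("parameter '%s' not present in both posteriors", parameter))
  }
  if (length(da) > max_draws) da <- da[seq(1, length(da), length.out = max_draws)]
  if (length(db) > max_draws) db <- db[seq(1, length(db), length.out = max_draws)]
  mean(outer(db, da, ">"))
}

#' Posterior summary table
#'
#' Mean, SD and central 95% credible interval for every tracked parameter,
#' with the split-Rhat and effective-sample-size diagnostics.
#'
#' @param x an `scr_fit` or `growth_fit`.
#' @param level credible-interval level.
#' @return tibble with columns `term`, `mean`, `sd`, `lower`, `upper`,
#'   `rhat`, `ess`.
#' @export
summarize_posterior <- function(x, level = 0.95) {
  draws <- x$draws
  if (nrow(draws) == 0) abort("empty posterior")
  terms <- names(x$rhat)
  purrr::map_dfr(terms, function(v) {
    d <- draws[[v]]
    ci <- cred_int(d, level)
    tibble::tibble(term = v, mean = mean(d), sd = sd(d),
                   lower = ci[1], upper = ci[2],
                   rhat = x$rhat[[v]], ess = x$ess[[v]])
  })
}
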