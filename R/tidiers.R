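#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @rdname tidy_plethodem
#' @export
tidy.scr_fit <- function(x, level = 0.95, ...) {
  summarize_posterior(x, level)
}

#' Tidy and glance methods for fitted objects
#'
#' `tidy()` returns one row per parameter (posterior mean, SD, central
#' credible interval, Rhat, ESS); `glance()` returns a one-row model
#' summary.
#'
#' @param x a fitted object from [fit_scr()], [fit_growth()] or
#'   [fit_clutch_model()].
#' @param level credible-interval level.
#' @param ... unused.
#' @name tidy_plethodem
#' @export
tidy.growth_fit <- function(x, level = 0.95, ...) {
  keep <- c("l_male", "l_female", "k_mature_male", "k_mature_female",
            "k_successional_male", "k_successional_female", "sigma_obs")
  summarize_posterior(x, level) |>
    dplyr::filter(.data$term %in% keep) |>
    dplyr::arrange(match(.data$term, keep))
}

#' @rdname tidy_plethodem
#' @export
glance.scr_fit <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs, M = x$M, chains = x$mcmc$chains,
    draws = nrow(x$draws), max_rhat = max(x$rhat, na.rm = TRUE),
    converged = x$converged
  )
}

#' @rdname tidy_plethodem
#' @export
glance.growth_fit <- function(x, ...) {
  tibble::tibble(
    n_individuals = x$n_individuals, n_pairs = x$n_pairs,
    n_removed = x$n_removed, chains = x$mcmc$chains,
    draws = nrow(x$draws), max_rhat = max(x$rhat, na.rm = TRUE),
    converged = x$converged
  )
}

#' @rdname tidy_plethodem
#' @export
tidy.clutch_model <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope", "residual_sd"),
    estimate = c(x$intercept, x$slope, x$residual_sd),
    std.error = c(x$se[1], x$se[2], NA_real_)
  )
}
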