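#' Ground-truth parameter bundles
#'
#' Constructors for the parameter sets used by the simulators and recovered
#' by the fitters.
#'
#' `scr_params()` holds the robust-design SCR parameters: annual survival
#' \eqn{\Phi}, space-use scale \eqn{\sigma} (m), baseline detection
#' \eqn{\lambda} (per board-occasion), density (individuals per m\eqn{^2}),
#' and the per-axis SD \eqn{\tau} of the between-season activity-center
#' random walk. The derived mean dispersal distance is
#' \eqn{\tau\sqrt{\pi/2}} (the mean of a Rayleigh step).
#'
#' `growth_params()` holds the von Bertalanffy quantities: sex-specific
#' asymptotic sizes `l_male`, `l_female` (mm SVL), per plot-by-sex growth
#' coefficients `k` (yr\eqn{^{-1}}), and SVL measurement noise `sigma_obs`
#' (mm).
#'
#' @param phi annual survival probability.
#' @param sigma space-use scale, meters.
#' @param lam baseline detection probability per board-occasion.
#' @param density individuals per square meter.
#' @param tau per-axis between-primary dispersal SD, meters.
#' @return a named list with class `scr_params` / `growth_params` /
#'   `truth_params`.
#' @export
scr_params <- function(phi = 0.996, sigma = 3.496, lam = 0.019,
                       density = 0.613, tau = 0.99) {
  stopifnot(phi >= 0, phi <= 1, sigma >= 0, lam >= 0, lam <= 1,
            density > 0, tau >= 0)
  structure(
    list(phi = phi, sigma = sigma, lam = lam, density = density, tau = tau,
         mean_dispersal = tau * sqrt(pi / 2)),
    class = "scr_params"
  )
}

#' @rdname scr_params
#' @param l_male,l_female asymptotic SVL, mm.
#' @param k named numeric of growth coefficients (yr^-1) for the four
#'   plot-by-sex groups: `mature_female`, `mature_male`,
#'   `successional_female`, `successional_male`.
#' @param sigma_obs SVL measurement noise SD, mm.
#' @export
growth_params <- function(l_male = 43.569, l_female = 52.164,
                          k = c(mature_female = 0.237, mature_male = 0.671,
                                successional_female = 0.339,
                                successional_male = 0.97),
                          sigma_obs = 0.5) {
  need <- c("mature_female", "mature_male", "successional_female",
            "successional_male")
  if (!all(need %in% names(k))) {
    abort(paste("`k` must name all four groups:", paste(need, collapse = ", ")))
  }
  stopifnot(l_male > 0, l_female > 0, all(k[need] >= 0), sigma_obs >= 0)
  structure(
    list(l_male = l_male, l_female = l_female, k = k[need],
         sigma_obs = sigma_obs),
    class = "growth_params"
  )
}

#' @rdname scr_params
#' @param scr an `scr_params` object.
#' @param growth a `growth_params` object.
#' @param seed integer master seed recorded alongside the truth.
#' @export
truth_params <- function(scr = scr_params(), growth = growth_params(),
                         seed = 1L) {
  stopifnot(inherits(scr, "scr_params"), inherits(growth, "growth_params"))
  structure(list(scr = scr, growth = growth, seed = as.integer(seed)),
            class = "truth_params")
}

#' Published demographic estimates for a central Ohio population
#'
#' Posterior summaries (mean, SD, 95% credible bounds) reported for Eastern
#' Red-backed Salamanders occupying paired mature and successional forest
#' plots in central Ohio: the fitted SCR parameters per plot and the fitted
#' growth-model parameters. Useful as realistic defaults for simulation
#' studies and as inputs to [maturity_curve()] and [project_population()]
#' when only published summaries (not raw posterior draws) are available.
#'
#' @format tibbles with columns `parameter` (and `plot` where applicable),
#'   `mean`, `sd`, `lower`, `upper`.
#' @name ohio_estimates
NULL

#' @rdname ohio_estimates
#' @export
ohio_scr_estimates <- function() {
  tibble::tribble(
    ~parameter,        ~plot,          ~mean,  ~sd,   ~lower, ~upper,
    "phi",             "mature",       0.996, 0.002, 0.990, 0.999,
    "phi",             "successional", 0.993, 0.004, 0.984, 0.999,
    "mean_dispersal",  "mature",       1.241, 0.146, 0.961, 1.534,
    "mean_dispersal",  "successional", 1.376, 0.202, 0.995, 1.784,
    "sigma",           "mature",       3.496, 0.164, 3.189, 3.839,
    "sigma",           "successional", 3.823, 0.221, 3.419, 4.286,
    "density",         "mature",       0.613, 0.089, 0.558, 0.800,
    "density",         "successional", 0.432, 0.072, 0.380, 0.580,
    "lam",             "mature",       0.019, 0.002, 0.016, 0.023,
    "lam",             "successional", 0.015, 0.002, 0.012, 0.019
  )
}

#' @rdname ohio_estimates
#' @export
ohio_growth_estimates <- function() {
  tibble::tribble(
    ~parameter,        ~plot,          ~sex,     ~mean,  ~sd,   ~lower, ~upper,
    "l",               NA,             "male",   43.569, 1.319, 41.721, 46.782,
    "l",               NA,             "female", 52.164, 2.856, 47.958, 59.062,
    "k",               "mature",       "male",    0.671, 0.176, 0.360,  1.049,
    "k",               "mature",       "female",  0.237, 0.056, 0.137,  0.357,
    "k",               "successional", "male",    0.970, 0.266, 0.506,  1.547,
    "k",               "successional", "female",  0.339, 0.073, 0.205,  0.489
  )
}
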