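#' MCMC run configuration
#'
#' Bundles chain count, total iterations (including burn-in), burn-in,
#' thinning and the Rhat acceptance threshold. `scale = "test"` gives a
#' desk-scale configuration (4 chains x 20,000 iterations, burn-in 2,500,
#' thin 5) suitable for simulation-recovery checks; `scale = "full"`
#' mirrors a production run (5 chains x 200,000, burn-in 25,000, thin 5).
#'
#' @param chains,iter,burnin,thin integers; `iter` counts all iterations
#'   including burn-in.
#' @param rhat_threshold flag parameters whose split-Rhat exceeds this.
#' @param scale shortcut preset; explicit arguments override it.
#' @return list of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = NULL, iter = NULL, burnin = NULL,
                        thin = NULL, rhat_threshold = 1.05,
                        scale = c("test", "full")) {
  scale <- match.arg(scale)
  preset <- switch(scale,
    test = list(chains = 4L, iter = 20000L, burnin = 2500L, thin = 5L),
    full = list(chains = 5L, iter = 200000L, burnin = 25000L, thin = 5L)
  )
  cfg <- list(
    chains = as.integer(chains %||% preset$chains),
    iter = as.integer(iter %||% preset$iter),
    burnin = as.integer(burnin %||% preset$burnin),
    thin = as.integer(thin %||% preset$thin),
    rhat_threshold = rhat_threshold
  )
  stopifnot(cfg$chains >= 1, cfg$iter > cfg$burnin, cfg$thin >= 1)
  structure(cfg, class = "mcmc_config")
}
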