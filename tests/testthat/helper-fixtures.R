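# Shared fixtures, built in code at test time.

# small design: fewer secondaries keeps toy fits quick
tiny_design <- function(buffer = 6) {
  study_design(n_primary = 3, secondaries = 2,
               primary_dates = as.Date(c("2017-04-15", "2017-10-01",
                                         "2018-04-15")),
               buffer = buffer)
}

# low-density SCR truth for fast fits
tiny_scr_truth <- function() {
  scr_params(phi = 0.95, sigma = 2, lam = 0.05, density = 0.08, tau = 0.8)
}

# published posterior summaries used as simulation ground truth
table3_mature <- function() {
  scr_params(phi = 0.996, sigma = 3.496, lam = 0.019, density = 0.613,
             tau = 1.241 / sqrt(pi / 2))
}
table3_successional <- function() {
  scr_params(phi = 0.993, sigma = 3.823, lam = 0.015, density = 0.432,
             tau = 1.376 / sqrt(pi / 2))
}
table4_growth <- function(sigma_obs = 0.5) {
  growth_params(l_male = 43.569, l_female = 52.164,
                k = c(mature_female = 0.237, mature_male = 0.671,
                      successional_female = 0.339,
                      successional_male = 0.97),
                sigma_obs = sigma_obs)
}

# spring/fall capture schedule in days (three survey years)
survey_schedule <- function() c(169, 196, 169, 196, 169)

covered <- function(lower, upper, truth) lower <= truth && truth <= upper
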