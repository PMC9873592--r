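#' Read and write capture tables
#'
#' Capture CSVs use the long schema of [simulate_scr_history()]: one row
#' per detection with columns `individual_id`, `plot_id`, `primary`,
#' `secondary`, `board_id` (or `board_x`/`board_y`), optional `sex`,
#' `svl`. Files written by the package carry a provenance comment line
#' (`# plethodem config=<hash> seed=<seed>`) which readers skip.
#'
#' @param path file path.
#' @param design a [study_design()]; rows referencing boards or session
#'   indices outside it are rejected with their row numbers.
#' @return validated capture tibble.
#' @export
read_capture_csv <- function(path, design) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  df <- tibble::as_tibble(read.csv(path, comment.char = "#"))
  need <- c("individual_id", "primary", "secondary")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(paste("capture file lacks column(s):",
                paste(missing_cols, collapse = ", ")))
  }
  if (nrow(df) == 0) {
    return(tibble::tibble(individual_id = integer(), plot_id = character(),
                          primary = integer(), secondary = integer(),
                          board_id = integer(), board_x = numeric(),
                          board_y = numeric(), sex = character(),
                          svl = numeric()))
  }
  if (!"board_id" %in% names(df)) {
    if (!all(c("board_x", "board_y") %in% names(df))) {
      abort("capture file needs `board_id` or `board_x`/`board_y`")
    }
    df <- dplyr::left_join(df, design$boards,
                           by = c(board_x = "x", board_y = "y"))
  }
  bad <- which(is.na(df$board_id) |
                 !df$board_id %in% design$boards$board_id)
  if (length(bad)) {
    abort(paste("capture row(s) reference boards outside the design:",
                paste(head(bad, 5), collapse = ", ")))
  }
  bad <- which(df$primary < 1 | df$primary > design$n_primary |
                 df$secondary < 1 |
                 df$secondary > design$secondaries[pmax(1, pmin(
                   design$n_primary, df$primary))])
  if (length(bad)) {
    abort(paste("capture row(s) have session indices outside the design:",
                paste(head(bad, 5), collapse = ", ")))
  }
  if (anyDuplicated(df[c("individual_id", "primary", "secondary",
                         "board_id")]) > 0) {
    abort("duplicate (individual, primary, secondary, board) rows")
  }
  df <- dplyr::left_join(df,
                         dplyr::rename(design$boards, board_x2 = "x",
                                       board_y2 = "y"),
                         by = "board_id")
  df$board_x <- df$board_x2
  df$board_y <- df$board_y2
  if (!"plot_id" %in% names(df)) df$plot_id <- "plot1"
  if (!"sex" %in% names(df)) df$sex <- NA_character_
  if (!"svl" %in% names(df)) df$svl <- NA_real_
  df$plot_id <- as.character(df$plot_id)
  df$sex <- as.character(df$sex)
  df$svl <- as.numeric(df$svl)
  df |>
    dplyr::select("individual_id", "plot_id", "primary", "secondary",
                  "board_id", "board_x", "board_y", "sex", "svl")
}

#' @rdname read_capture_csv
#' @param x table to write.
#' @param seed,config provenance recorded in the header comment.
#' @export
write_capture_csv <- function(x, path, seed = NA, config = NULL) {
  write_csv_provenance(x, path, seed, config)
  invisible(path)
}

write_csv_provenance <- function(x, path, seed = NA, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# plethodem config=%s seed=%s",
                     config_hash(config), as.character(seed)), con)
  write.csv(as.data.frame(x), con, row.names = FALSE)
  invisible(path)
}

read_csv_provenance <- function(path) {
  tibble::as_tibble(read.csv(path, comment.char = "#"))
}

#' @rdname read_capture_csv
#' @export
read_growth_csv <- function(path) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  df <- tibble::as_tibble(read.csv(path, comment.char = "#"))
  need <- c("individual_id", "sex", "plot", "capture", "interval_days", "svl")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(paste("growth file lacks column(s):",
                paste(missing_cols, collapse = ", ")))
  }
  df
}

#' Write / read ground-truth parameters as YAML
#'
#' Sidecar files pairing a simulated dataset with the parameters that
#' generated it, for recovery tests.
#'
#' @param truth a [truth_params()].
#' @param path file path.
#' @export
write_truth_yaml <- function(truth, path) {
  yaml::write_yaml(list(
    scr = unclass(truth$scr),
    growth = list(l_male = truth$growth$l_male,
                  l_female = truth$growth$l_female,
                  k = as.list(truth$growth$k),
                  sigma_obs = truth$growth$sigma_obs),
    seed = truth$seed
  ), path)
  invisible(path)
}

#' @rdname write_truth_yaml
#' @export
read_truth_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  truth_params(
    scr = scr_params(phi = y$scr$phi, sigma = y$scr$sigma, lam = y$scr$lam,
                     density = y$scr$density, tau = y$scr$tau),
    growth = growth_params(l_male = y$growth$l_male,
                           l_female = y$growth$l_female,
                           k = unlist(y$growth$k),
                           sigma_obs = y$growth$sigma_obs),
    seed = y$seed
  )
}

#' Pipeline configuration
#'
#' Everything [run_pipeline()] needs: the study design, per-plot
#' ground-truth (or expected) SCR parameters, growth truth, MCMC settings,
#' raster resolution, kernel choice, projection constants, master seed and
#' output directory. `scale = "test"` keeps a full pipeline run small.
#'
#' @param out_dir output directory (created if needed).
#' @param seed master seed; every stage derives its stream from it.
#' @param simulate generate inputs from `truth` (otherwise `capture_csv`
#'   per plot and `growth_csv` must point at files).
#' @param design a [study_design()].
#' @param truth a [truth_params()]; per-plot densities/sigma come from
#'   `plot_scr`.
#' @param plot_scr named list of [scr_params()] per plot.
#' @param capture_csv named list of per-plot capture CSV paths (when
#'   `simulate = FALSE`).
#' @param growth_csv growth CSV path (when `simulate = FALSE`).
#' @param scr_mcmc,growth_mcmc [mcmc_config()]s.
#' @param raster_res UD raster resolution, meters.
#' @param kernel use-surface kernel.
#' @param ud_method `"surface"` or `"kde"` (see [space_use_analysis()]).
#' @param projection a [projection_config()].
#' @param n_growth,growth_schedule synthetic growth-series size.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("plethodem_run_"),
                            seed = 1L,
                            simulate = TRUE,
                            design = study_design(),
                            truth = truth_params(),
                            plot_scr = list(
                              mature = scr_params(),
                              successional = scr_params(phi = 0.993,
                                                        sigma = 3.823,
                                                        lam = 0.015,
                                                        density = 0.432,
                                                        tau = 1.098)
                            ),
                            capture_csv = NULL,
                            growth_csv = NULL,
                            scr_mcmc = mcmc_config(chains = 2, iter = 1500,
                                                   burnin = 500, thin = 2),
                            growth_mcmc = mcmc_config(chains = 2,
                                                      iter = 4000,
                                                      burnin = 1000,
                                                      thin = 2),
                            raster_res = 0.25,
                            kernel = "halfnormal",
                            ud_method = "surface",
                            projection = projection_config(n_sims = 20000L),
                            n_growth = 120,
                            growth_schedule = c(169, 196, 169)) {
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), simulate = simulate,
         design = design, truth = truth, plot_scr = plot_scr,
         capture_csv = capture_csv, growth_csv = growth_csv,
         scr_mcmc = scr_mcmc, growth_mcmc = growth_mcmc,
         raster_res = raster_res, kernel = kernel, ud_method = ud_method,
         projection = projection, n_growth = n_growth,
         growth_schedule = growth_schedule),
    class = "pipeline_config"
  )
}

#' Run the full demographic pipeline
#'
#' Executes simulate (optional) -> SCR fit per plot -> growth fit ->
#' space-use summary per plot -> lifetime projection per plot, writing the
#' summary tables (`scr_summary.csv`, `growth_summary.csv`,
#' `spaceuse_summary.csv`, `projection_summary.csv`,
#' `maturity_curve.csv`) into `config$out_dir`. Any stage failure halts
#' with a stage-named error. Outputs carry the config hash and master
#' seed in a header comment, so two runs with the same config are
#' byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return invisible list with the fitted objects, summary tables and
#'   output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  seed <- config$seed
  plots <- names(config$plot_scr)

  captures <- stage("simulate", {
    if (config$simulate) {
      out <- purrr::imap(config$plot_scr, function(p, nm) {
        simulate_scr_history(config$design, p,
                             seed = seed + match(nm, plots), plot_id = nm)
      })
      purrr::iwalk(out, function(tab, nm) {
        write_capture_csv(tab, file.path(config$out_dir,
                                         paste0("captures_", nm, ".csv")),
                          seed = seed, config = config[c("seed", "simulate")])
      })
      out
    } else {
      if (is.null(config$capture_csv)) {
        abort("`simulate = FALSE` but no `capture_csv` supplied")
      }
      purrr::map(config$capture_csv, read_capture_csv,
                 design = config$design)
    }
  })

  scr_fits <- stage("fit-scr", {
    purrr::imap(captures, function(tab, nm) {
      fit_scr(tab, config$design, mcmc = config$scr_mcmc,
              seed = seed + 10 + match(nm, plots))
    })
  })
  scr_summary <- purrr::imap_dfr(scr_fits, function(f, nm) {
    dplyr::mutate(tidy(f), plot = nm, .before = 1)
  })

  growth_obs <- stage("simulate-growth", {
    if (config$simulate) {
      simulate_growth_series(config$truth, config$n_growth,
                             config$growth_schedule, seed = seed + 20)
    } else {
      if (is.null(config$growth_csv)) {
        abort("`simulate = FALSE` but no `growth_csv` supplied")
      }
      read_growth_csv(config$growth_csv)
    }
  })
  growth_fit <- stage("fit-growth", {
    fit_growth(growth_obs, mcmc = config$growth_mcmc, seed = seed + 21)
  })
  growth_summary <- tidy(growth_fit)

  spaceuse <- stage("space-use", {
    purrr::imap_dfr(scr_fits, function(f, nm) {
      acs <- f$ac |>
        dplyr::group_by(.data$individual_id) |>
        dplyr::summarise(x = mean(.data$x), y = mean(.data$y),
                         .groups = "drop")
      sg <- mean(f$draws$sigma)
      raster <- raster_from_design(config$design, config$raster_res)
      res <- space_use_analysis(acs, sg, raster, kernel = config$kernel,
                                method = config$ud_method,
                                seed = seed + 30 + match(nm, plots))
      dplyr::mutate(attr(res, "plot_summary"), plot = nm, .before = 1)
    })
  })

  maturity <- stage("maturity", {
    purrr::map_dfr(plots, function(nm) {
      dr <- growth_group_draws(growth_fit, nm, "female")
      mc <- maturity_curve(dr,
                           start = config$projection$hatch_svl,
                           threshold = config$projection$maturity_svl,
                           pre_growth_lag = config$projection$pre_growth_lag)
      dplyr::mutate(mc$curve, plot = nm, sex = "female", .before = 1)
    })
  })

  projection <- stage("project", {
    clutch <- fit_clutch_model(make_clutch_table(seed = seed + 40))
    purrr::map_dfr(plots, function(nm) {
      dr <- growth_group_draws(growth_fit, nm, "female")
      dplyr::mutate(
        project_population(dr, clutch, config$projection,
                           seed = seed + 50 + match(nm, plots)),
        plot = nm, .before = 1)
    })
  })

  tables <- list(scr_summary = scr_summary, growth_summary = growth_summary,
                 spaceuse_summary = spaceuse, maturity_curve = maturity,
                 projection_summary = projection)
  paths <- purrr::imap_chr(tables, function(tab, nm) {
    p <- file.path(config$out_dir, paste0(nm, ".csv"))
    write_csv_provenance(tab, p, seed = seed,
                         config = config[c("seed", "simulate")])
    p
  })
  invisible(list(captures = captures, scr_fits = scr_fits,
                 growth_fit = growth_fit, tables = tables, paths = paths))
}

#' @rdname pipeline_config
#' @export
show_config <- function(config = pipeline_config()) {
  drop <- c("design", "truth", "plot_scr", "projection", "scr_mcmc",
            "growth_mcmc")
  flat <- c(config[setdiff(names(config), drop)],
            list(projection = unclass(config$projection),
                 scr_mcmc = unclass(config$scr_mcmc),
                 growth_mcmc = unclass(config$growth_mcmc)))
  yaml::as.yaml(flat)
}
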