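#' Pipeline configuration
#'
#' Assembles every tunable of the trace-to-report pipeline into one
#' nested list that round-trips losslessly through YAML
#' ([write_config()] / [read_config()]).  Every downstream default is
#' overridable here.
#'
#' @param simulation NULL to load traces from `traces_path`, or a list
#'   with `rates` (k12, k21, k23, k32), `conc_list`, `n_traces`,
#'   `duration` (s), and optionally `start_state`.
#' @param emission List with `e_high`, `e_low`, `noise_sd`, `frame_time`.
#' @param traces_path CSV of traces (used when `simulation` is NULL).
#' @param idealization List: `method` ("hmm"/"threshold"), `tol`,
#'   `max_iter`, optional `max_duration` and `bleach_detection` for
#'   truncation.
#' @param dwell List: `bootstrap_reps`, `alpha`, `use_censored`.
#' @param fitting List: `weights`, `bootstrap_reps`.
#' @param titration NULL, or a list with either `path` (CSV) or
#'   generation parameters (`s_values`, `amplitudes`, `e0`, `noise_sd`,
#'   `replicates`), plus `n_events` to force a model (otherwise both are
#'   fitted and F-test selected).
#' @param landscape NULL, or a list with `values` (data frame: label,
#'   inner_bp, value, se), `reference`, `calibration_bp`, and optionally
#'   `table_path` (TSV; the synthetic landscape is used when absent).
#' @param seed Master seed; all stage seeds derive from it.
#' @param label Construct label.
#' @return A list of class `se_config`.
#' @export
exposure_config <- function(simulation = NULL,
                            emission = list(),
                            traces_path = NULL,
                            idealization = list(),
                            dwell = list(),
                            fitting = list(),
                            titration = NULL,
                            landscape = NULL,
                            seed = 1L,
                            label = "construct") {
  cfg <- list(
    simulation = simulation,
    emission = modifyList(list(e_high = 0.75, e_low = 0.15,
                               noise_sd = 0.08, frame_time = 0.1),
                          emission),
    traces_path = traces_path,
    idealization = modifyList(list(method = "hmm", tol = 1e-6,
                                   max_iter = 500,
                                   bleach_detection = FALSE,
                                   max_duration = Inf),
                              idealization),
    dwell = modifyList(list(bootstrap_reps = 200, alpha = 0.05,
                            use_censored = TRUE), dwell),
    fitting = modifyList(list(weights = "inverse_variance",
                              bootstrap_reps = 500), fitting),
    titration = titration,
    landscape = landscape,
    seed = as.integer(seed),
    label = label
  )
  class(cfg) <- c("se_config", "list")
  cfg
}

#' @rdname exposure_config
#' @param config An `se_config` object.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$idealization$max_duration <-
    if (is.finite(x$idealization$max_duration)) {
      x$idealization$max_duration
    } else {
      ".inf"
    }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname exposure_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (identical(x$idealization$max_duration, ".inf")) {
    x$idealization$max_duration <- Inf
  }
  do.call(exposure_config, x[setdiff(names(x), character())])
}

#' Write / load a tidy trace cohort
#'
#' Traces are stored as tidy CSV with columns `trace_id`, `conc_nM`,
#' `frame`, `time_s`, `fret_e`, plus a JSON sidecar
#' (`<path>.params.json`) holding the generation parameters when
#' present.  [load_trace_table()] also accepts `donor`/`acceptor`
#' intensity columns in place of `fret_e`, converting with
#' `E = acceptor / (donor + acceptor)`, and validates uniform frame
#' spacing per trace (tolerance 1%).
#'
#' @param cohort A tidy cohort tibble (see [simulate_experiment()]).
#' @param path CSV path.
#' @return `load_trace_table()`: the cohort tibble.
#' @export
write_trace_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path)
  params <- attr(cohort, "params")
  if (!is.null(params)) {
    jsonlite::write_json(params, paste0(path, ".params.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_trace_cohort
#' @export
load_trace_table <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  base <- c("trace_id", "conc_nM", "frame", "time_s")
  missing <- setdiff(base, names(out))
  if (length(missing) > 0) {
    abort(paste0("trace table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!"fret_e" %in% names(out)) {
    if (all(c("donor", "acceptor") %in% names(out))) {
      out$fret_e <- out$acceptor / (out$donor + out$acceptor)
    } else {
      abort("trace table is missing column(s): fret_e (or donor+acceptor)")
    }
  }
  bad <- out |>
    dplyr::group_by(.data$trace_id) |>
    dplyr::summarise(uneven = {
      dt <- diff(.data$time_s)
      length(dt) > 1 && (max(dt) - min(dt)) > 0.01 * stats::median(dt)
    }) |>
    dplyr::filter(.data$uneven)
  if (nrow(bad) > 0) {
    abort(paste0("non-uniform frame spacing (>1%) in trace(s): ",
                 paste(head(bad$trace_id, 5), collapse = ", ")))
  }
  out <- dplyr::select(out, dplyr::all_of(c(base, "fret_e")))
  out$frame <- as.integer(out$frame)
  class(out) <- c("se_cohort", class(out))
  out
}

#' Write / load a titration table
#'
#' CSV with columns `conc_nM`, `fret_e`, `replicate`.
#'
#' @param titration A titration tibble.
#' @param path CSV path.
#' @export
write_titration_table <- function(titration, path) {
  readr::write_csv(titration, path)
  invisible(path)
}

#' @rdname write_titration_table
#' @export
load_titration_table <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("conc_nM", "fret_e")
  missing <- setdiff(need, names(out))
  if (length(missing) > 0) {
    abort(paste0("titration table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!"replicate" %in% names(out)) out$replicate <- 1L
  class(out) <- c("se_titration", class(out))
  out
}

#' Run the full site-exposure analysis pipeline
#'
#' Stages: simulate (or load) a trace cohort, truncate, idealize,
#' extract dwells, aggregate per-concentration transition rates,
#' globally fit the three-state closed forms (plus the simple linear
#' two-state fit), optionally fit an ensemble titration, and optionally
#' build and compare a ddG occupancy profile against an unwrapping
#' landscape.  Fully deterministic given the config's master seed; each
#' stage draws its seed from a fixed counter scheme.
#'
#' @param config An [exposure_config()] object.
#' @param verbose Print per-stage log lines?
#' @return A list of class `se_report` with entries `label`, `rate_series`,
#'   `global_fit`, `linear_fit`, `isotherm_fit`, `profile`, `comparison`,
#'   `log` (tibble), `provenance` (config hash, seed, package version).
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "se_config"))
  seed <- config$seed
  logs <- list()
  note <- function(stage, ...) {
    msg <- sprintf(...)
    if (verbose) message(sprintf("[%s] %s", stage, msg))
    logs[[length(logs) + 1]] <<- tibble(stage = stage, message = msg)
  }

  em <- do.call(emission_model, config$emission)

  # -- traces ---------------------------------------------------------
  if (!is.null(config$simulation)) {
    sim <- config$simulation
    rates <- do.call(rate_set, sim$rates[c("k12", "k21", "k23", "k32")])
    cohort <- simulate_experiment(
      rates, conc_list = unlist(sim$conc_list), n_traces = sim$n_traces,
      duration = sim$duration, emission = em,
      seed = derive_seed(seed, 1L),
      start_state = sim$start_state %||% 1L
    )
    note("simulate", "%d trace/concentration series at %d concentration(s)",
         nrow(dplyr::distinct(cohort, .data$trace_id, .data$conc_nM)),
         length(unique(cohort$conc_nM)))
  } else if (!is.null(config$traces_path)) {
    cohort <- load_trace_table(config$traces_path)
    note("load", "loaded %d traces", length(unique(cohort$trace_id)))
  } else {
    abort("config must provide either `simulation` or `traces_path`")
  }

  # -- truncation -----------------------------------------------------
  idl_cfg <- config$idealization
  if (isTRUE(idl_cfg$bleach_detection) || is.finite(idl_cfg$max_duration)) {
    cohort <- cohort |>
      dplyr::group_by(.data$trace_id) |>
      dplyr::group_modify(function(df, key) {
        idx <- truncate_trace(df,
                              bleach_detection = isTRUE(idl_cfg$bleach_detection),
                              max_duration = idl_cfg$max_duration,
                              emission = em)
        df[seq_len(idx), ]
      }) |>
      dplyr::ungroup()
    note("truncate", "applied truncation rules")
  }

  # -- idealization ---------------------------------------------------
  ideal <- idealize_cohort(cohort, method = idl_cfg$method,
                           tol = idl_cfg$tol, max_iter = idl_cfg$max_iter)
  note("idealize", "idealized %d traces (%s)",
       length(unique(ideal$trace_id)), idl_cfg$method)

  # -- dwells and rates -----------------------------------------------
  dwells <- extract_dwells_cohort(ideal, frame_time = em$frame_time)
  note("dwell", "%d dwells (%d censored)", nrow(dwells),
       sum(dwells$censored))
  series <- rate_series(dwells,
                        bootstrap_reps = config$dwell$bootstrap_reps,
                        seed = derive_seed(seed, 2L),
                        alpha = config$dwell$alpha,
                        use_censored = config$dwell$use_censored)
  note("rates", "rate series over %d concentrations", nrow(series))

  # -- fits -----------------------------------------------------------
  gfit <- global_fit_site_exposure(
    series, weights = config$fitting$weights,
    bootstrap_reps = config$fitting$bootstrap_reps,
    seed = derive_seed(seed, 3L), label = config$label
  )
  note("global_fit", "k12=%.3g k32=%.3g kon_eff=%.3g",
       gfit$params$estimate[1], gfit$params$estimate[2],
       gfit$params$estimate[3])
  lfit <- linear_two_state_fit(series)

  # -- optional titration ---------------------------------------------
  iso <- NULL
  if (!is.null(config$titration)) {
    tt <- config$titration
    curve <- if (!is.null(tt$path)) {
      load_titration_table(tt$path)
    } else {
      generate_titration(
        s_values = unlist(tt$s_values), amplitudes = unlist(tt$amplitudes),
        e0 = tt$e0 %||% 0.7, noise_sd = tt$noise_sd %||% 0.02,
        replicates = tt$replicates %||% 3,
        seed = derive_seed(seed, 4L)
      )
    }
    if (!is.null(tt$n_events)) {
      iso <- fit_isotherm(curve, n_events = tt$n_events)
    } else {
      f1 <- fit_isotherm(curve, 1)
      f2 <- tryCatch(fit_isotherm(curve, 2), error = function(e) NULL)
      iso <- if (is.null(f2)) f1 else select_isotherm_model(f1, f2)
    }
    note("titration", "isotherm fit with %d event(s)", iso$n_events)
  }

  # -- optional landscape ---------------------------------------------
  profile <- comparison <- NULL
  if (!is.null(config$landscape)) {
    ls_cfg <- config$landscape
    vals <- as_tibble(ls_cfg$values)
    profile <- ddg_profile(vals, reference = ls_cfg$reference,
                           source = ls_cfg$source %||% "ensemble")
    table <- if (!is.null(ls_cfg$table_path)) {
      read_landscape_table(ls_cfg$table_path)
    } else {
      synthetic_unwrap_landscape()
    }
    comparison <- compare_to_landscape(
      profile, table, calibration_bp = ls_cfg$calibration_bp %||% 29
    )
    note("landscape", "KS statistic %.3g (p = %.3g)",
         comparison$statistic, comparison$p_value)
  }

  out <- list(
    label = config$label,
    rate_series = series,
    global_fit = gfit,
    linear_fit = lfit,
    isotherm_fit = iso,
    profile = profile,
    comparison = comparison,
    log = dplyr::bind_rows(logs),
    provenance = list(
      config_hash = rlang::hash(unclass(config)),
      seed = seed,
      package_version = as.character(utils::packageVersion("siteexposure"))
    )
  )
  class(out) <- "se_report"
  out
}

#' @export
print.se_report <- function(x, ...) {
  cat("Site-exposure pipeline report:", x$label, "\n\n")
  print(x$global_fit)
  if (!is.null(x$isotherm_fit)) print(x$isotherm_fit)
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}
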