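# End-to-end pipeline: validated config, stage wiring with derived seeds,
# and provenance-stamped delimited outputs.

# Allowed config schema: section -> known keys.
pipeline_schema <- function() {
  list(
    seed = NULL, out_dir = NULL,
    cohort = c("n_molecules", "sensors", "weights", "fraction_dynamic",
               "n_frames", "dt", "red_laser_start"),
    emission = c("i_total", "noise_sd", "bg", "t_bleach_mean",
                 "t_bleach_cy5_mean"),
    classify = c("r_max", "dE_min", "min_transitions", "min_window"),
    hmm = c("window_frames", "max_iter", "tol"),
    tdp = c("bin"),
    multiplex = c("max_dist", "margin", "denominator")
  )
}

#' Validate a pipeline run configuration
#'
#' Checks the nested config against the known schema; any unknown key is
#' rejected by name before any stage runs.
#'
#' @param config Nested list (e.g. from [read_run_config()]).
#' @return The config, invisibly, with defaults filled in.
#' @export
validate_config <- function(config) {
  schema <- pipeline_schema()
  unknown_top <- setdiff(names(config), names(schema))
  if (length(unknown_top))
    stop("unknown config key(s): ", paste(unknown_top, collapse = ", "))
  for (sec in names(schema)) {
    if (is.null(schema[[sec]]) || is.null(config[[sec]])) next
    unknown <- setdiff(names(config[[sec]]), schema[[sec]])
    if (length(unknown))
      stop(sprintf("unknown config key(s) in '%s': %s", sec,
                   paste(unknown, collapse = ", ")))
  }
  defaults <- list(
    seed = 1L,
    cohort = list(n_molecules = 100, sensors = c("HJ1", "HJ2", "HJ3", "HJ4"),
                  fraction_dynamic = 0.87, n_frames = 1200, dt = 0.1,
                  red_laser_start = 1000),
    emission = list(),
    classify = list(),
    hmm = list(window_frames = 200),
    tdp = list(bin = 0.02),
    multiplex = list()
  )
  cfg <- modifyList(defaults, config)
  if (is.null(cfg$cohort$weights))
    cfg$cohort$weights <- rep(1 / length(cfg$cohort$sensors),
                              length(cfg$cohort$sensors))
  invisible(cfg)
}

#' Read a pipeline config from YAML
#'
#' @param path YAML file.
#' @return Validated config list.
#' @export
read_run_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

provenance_header <- function(seed, cfg) {
  c(package = paste0("hjfret ", as.character(utils::packageVersion("hjfret"))),
    seed = as.character(seed),
    config_hash = config_hash(cfg))
}

write_stage_table <- function(tab, file, hdr) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s=%s", names(hdr), unname(hdr)), con)
  suppressWarnings(write.table(tab, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(file)
}

#' Run the full analysis pipeline
#'
#' Wires simulate -> trace tables -> FRET/QC -> dynamic classification ->
#' truncate/stitch -> HMM -> dwell rates -> TDP -> multiplex summary, with
#' per-stage seeds derived from the single global seed so every stage can
#' be rerun in isolation and the whole run is byte-reproducible. Every
#' output file carries a provenance header (package version, seed, config
#' hash); per-stage molecule counts are logged via `message()`.
#'
#' @param config Config list (see [validate_config()]) or a YAML path.
#' @param out_dir Output directory (created if needed); overrides
#'   `config$out_dir`.
#' @return Invisibly, a list with the output directory, the mixture
#'   summary, the rate estimate (when enough dynamic molecules) and the
#'   per-molecule results table.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  cfg <- if (is.character(config)) read_run_config(config)
         else validate_config(config)
  out_dir <- out_dir %||% cfg$out_dir %||% stop("no output directory given")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- provenance_header(cfg$seed, cfg)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  panel <- hj_sensor_panel()
  sensors <- stage("simulate", {
    stopifnot(all(cfg$cohort$sensors %in% names(panel)))
    panel[cfg$cohort$sensors]
  })
  em <- do.call(emission_spec, cfg$emission)
  cohort <- stage("simulate", simulate_cohort(
    sensors, n_molecules = cfg$cohort$n_molecules,
    weights = cfg$cohort$weights,
    fraction_dynamic = cfg$cohort$fraction_dynamic, em = em,
    n_frames = cfg$cohort$n_frames, dt = cfg$cohort$dt,
    red_laser_start = cfg$cohort$red_laser_start,
    seed = derive_seed(cfg$seed, "simulate")))
  write_traces(cohort, file.path(out_dir, "traces.tsv"),
               extra_header = hdr)
  write_stage_table(cohort$truth, file.path(out_dir, "truth.tsv"), hdr)
  message(sprintf("simulate: %d molecules (%d dynamic in truth)",
                  nrow(cohort$truth), sum(cohort$truth$dynamic)))

  results <- stage("classify", do.call(multiplex_cohort, c(
    list(cohort, refs = sensor_refs(sensors)),
    cfg$multiplex[intersect(names(cfg$multiplex), c("max_dist", "margin"))],
    cfg$classify)))
  write_stage_table(results, file.path(out_dir, "calls.tsv"), hdr)
  n_dyn <- sum(results$call == "dynamic")
  message(sprintf("classify: %d analyzed, %d rejected, %d dynamic",
                  sum(results$call != "rejected"),
                  sum(results$call == "rejected"), n_dyn))

  smry <- stage("multiplex", summarize_mixture(
    results, refs = sensor_refs(sensors),
    denominator = cfg$multiplex$denominator %||% "all"))
  write_stage_table(smry$sensors, file.path(out_dir, "summary.tsv"), hdr)

  rates_tab <- NULL
  rate_list <- list()
  stage("fit-hmm", {
    for (sn in names(sensors)) {
      ids <- results$molecule_id[results$call == "dynamic" &
                                   results$sensor == sn]
      ids <- ids[!is.na(ids)]
      traces <- Filter(function(tr) tr$molecule_id %in% ids, cohort$traces)
      if (length(traces) == 0) next
      fr <- lapply(traces, compute_fret)
      st <- try(truncate_and_stitch(fr, cfg$hmm$window_frames),
                silent = TRUE)
      if (inherits(st, "try-error")) next
      fit <- fit_hmm2(st, max_iter = cfg$hmm$max_iter %||% 500,
                      tol = cfg$hmm$tol %||% 1e-6)
      dw <- extract_dwells(predict(fit), fit$boundaries, dt = st$dt)
      rt <- try(estimate_rates(dw, seed = derive_seed(cfg$seed, paste0("boot", sn))),
                silent = TRUE)
      if (inherits(rt, "try-error")) next
      rate_list[[sn]] <- list(fit = fit, rates = rt, stitched = st)
      rates_tab <- rbind(rates_tab, data.frame(
        sensor = sn, n_traces = length(st$trace_ids),
        mu_low = unname(fit$mu[1]), mu_high = unname(fit$mu[2]),
        k_lh = rt$k_lh, sd_lh = rt$sd_lh, k_hl = rt$k_hl,
        sd_hl = rt$sd_hl, n_transitions = rt$n_transitions,
        keq = rt$keq))
    }
    if (!is.null(rates_tab))
      write_stage_table(rates_tab, file.path(out_dir, "rates.tsv"), hdr)
  })
  message(sprintf("fit-hmm: rates for %d sensor(s)", length(rate_list)))

  stage("tdp", {
    for (sn in names(rate_list)) {
      rl <- rate_list[[sn]]
      tdp <- build_tdp(predict(rl$fit), rl$stitched$e, rl$fit$boundaries,
                       bin = cfg$tdp$bin)
      write_stage_table(as.data.frame(tdp$transitions),
                        file.path(out_dir, paste0("tdp_", sn, ".tsv")), hdr)
    }
  })

  invisible(list(out_dir = out_dir, summary = smry, rates = rate_list,
                 results = results, truth = cohort$truth))
}

#' One-call kinetic characterization of a sensor
#'
#' Convenience wrapper reproducing the single-plex kinetic workflow:
#' simulate `n_traces` dynamic molecules of one sensor, compute FRET with
#' QC windows, truncate to the stitch window, fit the global two-state
#' HMM, extract Viterbi dwells, estimate rates and Keq, and build the TDP.
#'
#' @param sensor An [hj_sensor()].
#' @param n_traces Number of dynamic molecules to simulate (default 250).
#' @param n_frames Frames per simulated trace (default 2000).
#' @param dt Frame interval, s (default 0.1).
#' @param em An [emission_spec()].
#' @param window_frames Stitch window (default 200 frames = 20 s).
#' @param red_laser_start Red-laser frame (default 1000).
#' @param rate_method Estimator passed to [estimate_rates()].
#' @param seed Integer seed.
#' @return List with `fit` (`"hj_hmm"`), `rates` (`"rate_estimate"`),
#'   `tdp` (`"fret_tdp"`), `stitched`, `dwells`.
#' @examples
#' \donttest{
#' res <- characterize_sensor(hj_sensor_panel()$HJ2, n_traces = 50,
#'                            n_frames = 600, seed = 1)
#' res$rates
#' }
#' @export
characterize_sensor <- function(sensor, n_traces = 250, n_frames = 2000,
                                dt = 0.1, em = emission_spec(),
                                window_frames = 200,
                                red_laser_start = 1000,
                                rate_method = "mle", seed = NULL) {
  cohort <- simulate_cohort(list(sensor), n_molecules = n_traces,
                            weights = 1, fraction_dynamic = 1, em = em,
                            n_frames = n_frames, dt = dt,
                            red_laser_start = red_laser_start, seed = seed)
  fr <- lapply(cohort$traces, compute_fret)
  fr <- Filter(function(f) isTRUE(f$qc_ok), fr)
  st <- truncate_and_stitch(fr, window_frames)
  fit <- fit_hmm2(st)
  v <- predict(fit)
  dw <- extract_dwells(v, fit$boundaries, dt = dt)
  rates <- estimate_rates(dw, method = rate_method,
                          seed = if (is.null(seed)) NULL
                                 else derive_seed(seed, "boot"))
  tdp <- build_tdp(v, st$e, fit$boundaries)
  list(fit = fit, rates = rates, tdp = tdp, stitched = st, dwells = dw)
}
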