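# Multiplexed detection: assign each dynamic molecule to a sensor by its
# fitted FRET-state pair, summarize the Type 1-4 mixture, and the target
# omission (specificity) design.

#' Sensor reference centroids for multiplex assignment
#'
#' @param sensors Optional list of [hj_sensor()] (default
#'   [hj_sensor_panel()]).
#' @return Data frame `name`, `e_low`, `e_high`, `target`.
#' @export
sensor_refs <- function(sensors = hj_sensor_panel()) {
  do.call(rbind, lapply(sensors, function(s)
    data.frame(name = s$name, e_low = s$e_low, e_high = s$e_high,
               target = s$target, stringsAsFactors = FALSE)))
}

#' Read sensor references from a YAML config
#'
#' Expects a list of entries with `name`, `e_low`, `e_high` and optional
#' `target`, as used by the `multiplex` command-line stage.
#'
#' @param path YAML file path.
#' @return Data frame as [sensor_refs()].
#' @export
read_sensor_refs <- function(path) {
  y <- yaml::read_yaml(path)
  refs <- do.call(rbind, lapply(y, function(s)
    data.frame(name = s$name, e_low = as.numeric(s$e_low),
               e_high = as.numeric(s$e_high),
               target = s$target %||% NA_character_,
               stringsAsFactors = FALSE)))
  stopifnot(!anyDuplicated(refs$name), all(refs$e_low < refs$e_high))
  refs
}

#' Assign a dynamic molecule to a sensor from its FRET-state pair
#'
#' The fitted `(mu_low, mu_high)` pair is compared to each sensor centroid
#' by Euclidean distance in the FRET-pair plane. The molecule is assigned
#' to the nearest sensor when that distance is at most `max_dist` and the
#' second-nearest centroid is at least `margin` further away; otherwise it
#' is `"unassigned"`. Assignment is invariant to the order of the
#' references.
#'
#' @param fit An `"hj_hmm"` fit of the molecule's FRET trace, or a numeric
#'   `c(mu_low, mu_high)` pair.
#' @param refs Sensor references ([sensor_refs()]).
#' @param max_dist Maximum assignment distance (default 0.16). The
#'   smallest inter-centroid distance of the default panel is 0.2; the
#'   radius leaves room for the upward bias that frame integration puts on
#'   the fitted low state of junctions switching faster than the frame
#'   rate (HJ3), while the margin rule still rejects ambiguous fits.
#' @param margin Required gap between nearest and second-nearest distances
#'   (default 0.03).
#' @return Sensor name, or `"unassigned"`.
#' @examples
#' classify_trace(c(0.21, 0.39), sensor_refs())  # "HJ1"
#' @export
classify_trace <- function(fit, refs = sensor_refs(), max_dist = 0.16,
                           margin = 0.03) {
  mu <- if (inherits(fit, "hj_hmm")) unname(fit$mu) else as.numeric(fit)
  stopifnot(length(mu) == 2)
  d <- sqrt((refs$e_low - mu[1])^2 + (refs$e_high - mu[2])^2)
  o <- order(d, refs$name)               # name tie-break: order-invariant
  if (d[o[1]] > max_dist) return("unassigned")
  if (length(d) > 1 && d[o[2]] - d[o[1]] < margin) return("unassigned")
  refs$name[o[1]]
}

#' Analyze a cohort for multiplexed detection
#'
#' Runs the full per-molecule chain: FRET computation and QC, the
#' dynamic/static digital call, and for dynamic molecules a per-trace
#' two-state HMM fit followed by sensor assignment.
#'
#' @param x An `"sm_cohort"` or list of `"sm_trace"`.
#' @param refs Sensor references.
#' @param max_dist,margin Passed to [classify_trace()].
#' @param ... Passed to [classify_dynamic()].
#' @return Data frame per molecule: `molecule_id`, `call`, `r`,
#'   `evidence`, `sensor` (`NA` unless dynamic), `mu_low`, `mu_high`.
#' @export
multiplex_cohort <- function(x, refs = sensor_refs(), max_dist = 0.16,
                             margin = 0.03, ...) {
  traces <- as_trace_list(x)
  rows <- lapply(traces, function(tr) {
    f <- compute_fret(tr)
    call <- classify_dynamic(tr, fret = f, ...)
    sensor <- NA_character_; mu <- c(NA_real_, NA_real_)
    if (call$call == "dynamic") {
      idx <- (f$window[1] + 1L):f$window[2]
      e <- f$e[idx][is.finite(f$e[idx])]
      fit <- fit_hmm2(e, init = list(mu = unname(quantile(e, c(0.05, 0.95)))),
                      min_len = 50L)
      mu <- unname(fit$mu)
      sensor <- classify_trace(fit, refs, max_dist, margin)
    }
    cbind(call, data.frame(sensor = sensor, mu_low = mu[1], mu_high = mu[2],
                           stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}

#' Summarize a multiplexed mixture into sensor types
#'
#' Counts dynamic molecules per sensor ("Type 1..4"), static and
#' unassigned molecules, with percentages. The default denominator is all
#' analyzed (non-rejected) molecules, matching how mixed-sensor
#' experiments report type percentages; `denominator = "dynamic"`
#' normalizes by dynamic molecules only.
#'
#' @param results Data frame from [multiplex_cohort()].
#' @param refs Sensor references (fixes the row order).
#' @param denominator `"all"` (default) or `"dynamic"`.
#' @return A `"mixture_summary"`: per-sensor `n` and `pct`, plus `static`,
#'   `unassigned`, `rejected`, `n_analyzed`, `n_dynamic`.
#' @export
summarize_mixture <- function(results, refs = sensor_refs(),
                              denominator = c("all", "dynamic")) {
  denominator <- match.arg(denominator)
  analyzed <- results[results$call != "rejected", , drop = FALSE]
  dyn <- analyzed[analyzed$call == "dynamic", , drop = FALSE]
  denom <- if (denominator == "all") nrow(analyzed) else max(nrow(dyn), 1L)
  n_sensor <- vapply(refs$name, function(s)
    sum(dyn$sensor == s, na.rm = TRUE), integer(1))
  unassigned <- sum(dyn$sensor == "unassigned", na.rm = TRUE)
  structure(list(
    sensors = data.frame(name = refs$name, n = unname(n_sensor),
                         pct = 100 * unname(n_sensor) / denom,
                         stringsAsFactors = FALSE),
    static = sum(analyzed$call == "static"),
    unassigned = unassigned,
    rejected = sum(results$call == "rejected"),
    n_analyzed = nrow(analyzed), n_dynamic = nrow(dyn),
    denominator = denominator),
    class = "mixture_summary")
}

#' @export
print.mixture_summary <- function(x, ...) {
  cat(sprintf("Mixture of %d analyzed molecules (%d dynamic, %d static, %d rejected)\n",
              x$n_analyzed, x$n_dynamic, x$static, x$rejected))
  for (i in seq_len(nrow(x$sensors)))
    cat(sprintf("  %s: %d (%.1f%% of %s)\n", x$sensors$name[i],
                x$sensors$n[i], x$sensors$pct[i], x$denominator))
  if (x$unassigned)
    cat(sprintf("  unassigned dynamic: %d\n", x$unassigned))
  invisible(x)
}

#' Target-omission specificity test
#'
#' Simulates the mixed-sensor experiment with one target left out: the
#' omitted sensor's junctions are present but stay static
#' (`fraction_dynamic = 0`), all other sensors respond normally. The
#' cohort is then analyzed blind and the per-sensor dynamic counts
#' reported. The design passes when the omitted sensor draws zero dynamic
#' calls while every other sensor draws at least one.
#'
#' @param omit Name of the omitted sensor, or `NULL` (positive control) or
#'   `"all"` (no targets at all).
#' @param sensors Sensor list (default [hj_sensor_panel()]).
#' @param n_molecules Cohort size (default 400).
#' @param fraction_dynamic Dynamic fraction for non-omitted sensors
#'   (default 0.87, the saturating-target regime).
#' @param seed Integer seed.
#' @param ... Passed to [simulate_cohort()].
#' @return An `"omission_result"`: `summary` (a `"mixture_summary"`),
#'   `omitted`, `pass`.
#' @export
omission_test <- function(omit = NULL, sensors = hj_sensor_panel(),
                          n_molecules = 400, fraction_dynamic = 0.87,
                          seed = NULL, ...) {
  nm <- vapply(sensors, `[[`, "", "name")
  frac <- rep(fraction_dynamic, length(sensors))
  if (identical(omit, "all")) frac[] <- 0
  else if (!is.null(omit)) {
    stopifnot(omit %in% nm)
    frac[nm == omit] <- 0
  }
  cohort <- simulate_cohort(sensors, n_molecules = n_molecules,
                            fraction_dynamic = frac, seed = seed, ...)
  res <- multiplex_cohort(cohort, refs = sensor_refs(sensors))
  smry <- summarize_mixture(res, refs = sensor_refs(sensors))
  counts <- setNames(smry$sensors$n, smry$sensors$name)
  pass <- if (identical(omit, "all")) all(counts == 0)
          else if (is.null(omit)) all(counts > 0)
          else counts[omit] == 0 && all(counts[nm != omit] > 0)
  structure(list(summary = smry, omitted = omit %||% "none",
                 counts = counts, pass = unname(pass)),
            class = "omission_result")
}

#' @export
print.omission_result <- function(x, ...) {
  cat(sprintf("Omission test (omitted: %s): %s\n", x$omitted,
              if (x$pass) "PASS" else "FAIL"))
  print(x$summary)
  invisible(x)
}
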