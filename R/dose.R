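# Dose-response calibration by digital counting: per-concentration
# percentages with a 3-group uncertainty, a Hill fit of the saturation
# curve, and the presence/absence limit-of-detection call.

#' Three-group split mean and standard deviation
#'
#' The per-concentration uncertainty of a digital count is estimated by
#' randomly partitioning the molecules (static and dynamic alike) into
#' three near-equal groups, computing the dynamic percentage per group,
#' and reporting the mean and sample standard deviation over the three
#' group percentages.
#'
#' @param calls Data frame of dynamic calls ([classify_cohort()]) or a
#'   logical vector (`TRUE` = dynamic); rejected molecules are excluded
#'   first.
#' @param seed Integer seed for the random partition.
#' @return List with `pct_mean`, `pct_sd`, `n_total`, `n_dynamic`.
#' @export
three_group_sd <- function(calls, seed = NULL) {
  dyn <- if (is.logical(calls)) calls
         else {
           cl <- calls$call
           (cl == "dynamic")[cl != "rejected"]
         }
  n <- length(dyn)
  if (n < 3) stop("need at least 3 analyzable molecules for a 3-group split")
  with_local_seed(seed, {
    grp <- sample(rep_len(1:3, n))
    pct <- vapply(1:3, function(g) 100 * mean(dyn[grp == g]), numeric(1))
    list(pct_mean = mean(pct), pct_sd = sd(pct),
         n_total = n, n_dynamic = sum(dyn))
  })
}

#' Tabulate a dose-response experiment
#'
#' Applies the digital classification to each per-concentration cohort and
#' assembles the calibration table of dose-response points.
#'
#' @param dose A `"dose_sim"` ([simulate_dose_response()]), or a list of
#'   cohorts plus `concentrations`.
#' @param concentrations Molar concentrations (taken from `dose` when it
#'   is a `"dose_sim"`).
#' @param seed Seed for the per-point 3-group splits.
#' @param ... Passed to [classify_dynamic()].
#' @return Data frame: `concentration`, `n_total`, `n_dynamic`,
#'   `pct_mean`, `pct_sd`.
#' @export
tabulate_dose_response <- function(dose, concentrations = NULL, seed = NULL,
                                   ...) {
  if (inherits(dose, "dose_sim")) {
    concentrations <- dose$concentration
    cohorts <- dose$cohorts
  } else cohorts <- dose
  stopifnot(length(cohorts) == length(concentrations))
  rows <- lapply(seq_along(cohorts), function(i) {
    calls <- classify_cohort(cohorts[[i]], ...)
    g <- three_group_sd(calls,
                        seed = if (is.null(seed)) NULL
                               else derive_seed(seed, paste0("grp", i)))
    data.frame(concentration = concentrations[i], n_total = g$n_total,
               n_dynamic = g$n_dynamic, pct_mean = g$pct_mean,
               pct_sd = g$pct_sd)
  })
  out <- do.call(rbind, rows)
  out[order(out$concentration), ]
}

#' Fit the saturation (calibration) curve
#'
#' Least-squares Hill fit of the dynamic percentage against concentration,
#' `pct(c) = 100 * f_max * c^h / (c^h + c50^h)`, over points with `c > 0`.
#' The linear range is reported as the concentration interval over which
#' the local log-log slope is at least half the maximal local slope. If
#' the nonlinear fit fails (e.g. all-zero points), the raw points are kept
#' and the result flagged.
#'
#' @param points Calibration table ([tabulate_dose_response()]); needs at
#'   least 4 nonzero concentrations spanning at least 3 decades.
#' @return A `"calibration_fit"`: `f_max`, `c50`, `h` (with s.d. when
#'   available), `linear_range` (molar `c(lo, hi)` or `NA`), `flagged`,
#'   `points`.
#' @export
fit_calibration <- function(points) {
  pos <- points[points$concentration > 0, , drop = FALSE]
  stopifnot(nrow(pos) >= 4)
  span <- log10(max(pos$concentration) / min(pos$concentration))
  if (span < 3) stop("concentrations must span at least 3 decades")
  start <- list(f_max = max(pos$pct_mean, 1) / 100,
                lc50 = log(pos$concentration[
                  which.min(abs(pos$pct_mean - max(pos$pct_mean) / 2))]),
                h = 1)
  fit <- try(minpack.lm::nlsLM(
    pct_mean ~ 100 * f_max * concentration^h /
      (concentration^h + exp(lc50)^h),
    data = pos, start = start,
    lower = c(f_max = 0, lc50 = log(min(pos$concentration)) - 20, h = 0.1),
    upper = c(f_max = 1, lc50 = log(max(pos$concentration)) + 20, h = 5),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  flagged <- inherits(fit, "try-error")
  if (!flagged) {
    cf <- coef(fit)
    se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 3))
    f_max <- unname(cf["f_max"]); c50 <- exp(unname(cf["lc50"]))
    h <- unname(cf["h"])
    sds <- c(f_max = unname(se[1]), c50 = exp(unname(cf["lc50"])) * unname(se[2]),
             h = unname(se[3]))
    flagged <- f_max < 1e-3             # flat response: no real saturation
  } else {
    f_max <- NA_real_; c50 <- NA_real_; h <- NA_real_
    sds <- c(f_max = NA_real_, c50 = NA_real_, h = NA_real_)
  }
  # linear range from local log-log slopes between adjacent points
  lr <- c(NA_real_, NA_real_)
  nz <- pos[pos$pct_mean > 0, , drop = FALSE]
  if (nrow(nz) >= 3) {
    lx <- log10(nz$concentration); ly <- log10(nz$pct_mean)
    sl <- diff(ly) / diff(lx)
    keep <- which(sl >= max(sl) / 2)
    if (length(keep))
      lr <- c(nz$concentration[min(keep)], nz$concentration[max(keep) + 1L])
  }
  structure(list(f_max = f_max, c50 = c50, h = h, sd = sds,
                 linear_range = lr, flagged = flagged, points = points),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  if (x$flagged) cat("Calibration fit flagged (flat or failed); raw points retained\n")
  cat(sprintf("Hill calibration: f_max = %.3g, c50 = %.3g M, h = %.3g\n",
              x$f_max, x$c50, x$h))
  if (all(is.finite(x$linear_range)))
    cat(sprintf("  linear range: %.3g - %.3g M\n",
                x$linear_range[1], x$linear_range[2]))
  invisible(x)
}

#' @export
plot.calibration_fit <- function(x, ...) {
  p <- x$points[x$points$concentration > 0, ]
  plot(p$concentration, p$pct_mean, log = "x", pch = 19,
       xlab = "target concentration (M)", ylab = "% dynamic molecules", ...)
  if (!x$flagged) {
    cc <- 10^seq(log10(min(p$concentration)), log10(max(p$concentration)),
                 length.out = 200)
    lines(cc, 100 * x$f_max * cc^x$h / (cc^x$h + x$c50^x$h), col = "firebrick")
  }
  invisible(x)
}

#' Call the limit of detection
#'
#' Operational LOD of the digital assay: the lowest tested concentration
#' that still yields at least one dynamic molecule, valid only when the
#' zero-target blank shows none. A blank with dynamic molecules signals
#' contamination or a false-positive regime and is an error; no dynamic
#' molecules at any concentration returns `NA` ("not detected"). Adding
#' detections at lower concentrations can only lower the LOD.
#'
#' @param points Calibration table including a `concentration == 0` blank.
#' @return LOD in molar, or `NA` if not detected.
#' @export
call_lod <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("concentration", "n_dynamic") %in% colnames(points)))
  blank <- points[points$concentration == 0, , drop = FALSE]
  if (nrow(blank) == 0) stop("a zero-target blank point is required")
  if (any(blank$n_dynamic > 0))
    stop("blank shows dynamic molecules: contamination / false-positive regime")
  pos <- points[points$concentration > 0 & points$n_dynamic >= 1, ,
                drop = FALSE]
  if (nrow(pos) == 0) return(NA_real_)
  min(pos$concentration)
}

#' Moles of target in a sample
#'
#' `amount (mol) = concentration (mol/L) x volume (L)`; e.g. 50 fM in
#' 100 uL is 5e-18 mol (5 attomoles).
#'
#' @param concentration Molar concentration.
#' @param volume_L Sample volume in litres.
#' @return Amount in moles.
#' @export
sample_amount_mol <- function(concentration, volume_L) {
  stopifnot(concentration >= 0, volume_L >= 0)
  concentration * volume_L
}
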