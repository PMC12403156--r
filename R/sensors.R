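#' Two-state switching kinetics of a junction sensor
#'
#' A four-way DNA junction with its target bound interconverts between two
#' stacked conformers (iso-I, high FRET; iso-II, low FRET). Following the
#' field's convention, state 1 is the high-FRET state and state 2 the
#' low-FRET state, so `k_lh` is the low-to-high rate (k2->1) and `k_hl` the
#' high-to-low rate (k1->2). The equilibrium constant is Keq = k_lh / k_hl.
#'
#' @param k_lh Low-to-high transition rate, 1/s. Must be >= 0.
#' @param k_hl High-to-low transition rate, 1/s. Must be >= 0.
#' @return An object of class `"hj_kinetics"`.
#' @examples
#' hj_kinetics(0.25, 0.06)  # HJ1-like: Keq ~ 4
#' @export
hj_kinetics <- function(k_lh, k_hl) {
  stopifnot(is.numeric(k_lh), is.numeric(k_hl), length(k_lh) == 1L,
            length(k_hl) == 1L, k_lh >= 0, k_hl >= 0)
  structure(list(k_lh = k_lh, k_hl = k_hl), class = "hj_kinetics")
}

#' @export
print.hj_kinetics <- function(x, ...) {
  cat(sprintf("two-state kinetics: k(low->high) = %.3g /s, k(high->low) = %.3g /s, Keq = %.3g\n",
              x$k_lh, x$k_hl, if (x$k_hl > 0) x$k_lh / x$k_hl else NA_real_))
  invisible(x)
}

#' Define a junction FRET sensor
#'
#' Each sensor is a four-way junction whose two dye-carrying arms set a pair
#' of FRET states explored when the target completes the junction, and a
#' single static FRET level for the incomplete (target-free) junction.
#'
#' @param name Sensor label, e.g. `"HJ1"`.
#' @param e_low,e_high Mean FRET efficiency of the low and high state,
#'   dimensionless, with `0 <= e_low < e_high <= 1`.
#' @param e_static Mean FRET efficiency of the incomplete junction, in
#'   `[0, 1]`.
#' @param kinetics An [hj_kinetics()] object (switching rates with target
#'   bound).
#' @param target Optional label of the nucleic-acid target the sensor reads.
#' @return An object of class `"hj_sensor"`.
#' @export
hj_sensor <- function(name, e_low, e_high, e_static, kinetics,
                      target = NA_character_) {
  stopifnot(is.character(name), length(name) == 1L,
            e_low >= 0, e_low < e_high, e_high <= 1,
            e_static >= 0, e_static <= 1,
            inherits(kinetics, "hj_kinetics"))
  structure(list(name = name, e_low = e_low, e_high = e_high,
                 e_static = e_static, kinetics = kinetics, target = target),
            class = "hj_sensor")
}

#' @export
print.hj_sensor <- function(x, ...) {
  cat(sprintf("<hj_sensor %s> FRET %.2f <-> %.2f (static %.2f), target %s\n",
              x$name, x$e_low, x$e_high, x$e_static, x$target))
  print(x$kinetics)
  invisible(x)
}

#' The four-sensor reference panel
#'
#' The default multiplex panel: four junctions with distance-tuned FRET
#' pairs (HJ1 0.2<->0.4, HJ2 0.2<->0.6, HJ3 0.3<->0.7, HJ4 0.4<->0.9),
#' incomplete-junction static levels 0.2/0.3/0.4/0.6, and the published
#' interconversion rates for each junction with its miRNA-mimic target
#' bound.
#'
#' @return A named list of four [hj_sensor()] objects.
#' @examples
#' names(hj_sensor_panel())
#' @export
hj_sensor_panel <- function() {
  list(
    HJ1 = hj_sensor("HJ1", 0.2, 0.4, 0.2, hj_kinetics(0.25, 0.06),
                    target = "DNA mimic of miR-107"),
    HJ2 = hj_sensor("HJ2", 0.2, 0.6, 0.3, hj_kinetics(0.7, 0.8),
                    target = "DNA mimic of miR-342-3p"),
    HJ3 = hj_sensor("HJ3", 0.3, 0.7, 0.4, hj_kinetics(6, 0.11),
                    target = "DNA mimic of miR-18b-5p"),
    HJ4 = hj_sensor("HJ4", 0.4, 0.9, 0.6, hj_kinetics(1.5, 1.2),
                    target = "DNA mimic of miR-92a-3p")
  )
}

#' Camera / photophysics model for synthetic traces
#'
#' Intensity and noise are in arbitrary camera counts; the defaults give a
#' FRET-efficiency noise of about 0.05 s.d. at the default total intensity,
#' which keeps states 0.2 apart visually separable, matching typical EMCCD
#' smFRET data. Photobleach times are exponential; use `Inf` means to
#' disable bleaching.
#'
#' @param i_total Mean total (donor + acceptor) intensity above background,
#'   counts.
#' @param noise_sd Additive per-channel Gaussian noise s.d., counts.
#' @param bg Per-channel background offset, counts.
#' @param t_bleach_mean Mean Cy3 (donor) photobleach time, s.
#' @param t_bleach_cy5_mean Mean Cy5 (acceptor) photobleach time, s.
#' @return An object of class `"emission_spec"`.
#' @export
emission_spec <- function(i_total = 1000, noise_sd = 60, bg = 100,
                          t_bleach_mean = 150, t_bleach_cy5_mean = 300) {
  stopifnot(i_total > 0, noise_sd >= 0, bg >= 0,
            t_bleach_mean > 0, t_bleach_cy5_mean > 0)
  structure(list(i_total = i_total, noise_sd = noise_sd, bg = bg,
                 t_bleach_mean = t_bleach_mean,
                 t_bleach_cy5_mean = t_bleach_cy5_mean),
            class = "emission_spec")
}
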