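#' Maximal shear stress at the bottom of an orbitally shaken well
#'
#' Classic estimate for the maximal fluid shear stress experienced by cells
#' on the bottom of a culture vessel on an orbital shaker:
#' `tau_max = a * sqrt(rho * eta * (2 * pi * f)^3)`, with `a` the orbital
#' radius (half the orbital diameter), `rho` the medium density, `eta` its
#' dynamic viscosity and `f` the rotation frequency. Defaults for density
#' and viscosity describe culture medium at 37 C.
#'
#' @param orbital_diameter_m orbital (throw) diameter of the shaker, m.
#' @param rotations_per_s rotation frequency, revolutions per second
#'   (rpm / 60).
#' @param density_kg_m3 medium density, kg/m^3.
#' @param viscosity_pa_s medium dynamic viscosity, Pa s.
#' @return shear stress in Pa. Multiply by 10 (see [pa_to_dynes_cm2()]) for
#'   dynes/cm^2.
#' @examples
#' orbital_shear_stress(0.025, 55 / 60)  # ~0.17 Pa at 55 rpm, 25 mm orbit
#' @export
orbital_shear_stress <- function(orbital_diameter_m,
                                 rotations_per_s,
                                 density_kg_m3 = 1000,
                                 viscosity_pa_s = 9.5e-4) {
  stopifnot(is_scalar_num(orbital_diameter_m), orbital_diameter_m > 0,
            is_scalar_num(rotations_per_s), rotations_per_s >= 0,
            is_scalar_num(density_kg_m3), density_kg_m3 > 0,
            is_scalar_num(viscosity_pa_s), viscosity_pa_s > 0)
  a <- orbital_diameter_m / 2
  a * sqrt(density_kg_m3 * viscosity_pa_s *
             (2 * pi * rotations_per_s)^3)
}

#' @rdname orbital_shear_stress
#' @param tau_pa stress in Pa.
#' @export
pa_to_dynes_cm2 <- function(tau_pa) tau_pa * 10

#' Apparent permeability coefficient from a receiver time series
#'
#' `P_app = K * Vr / A` (cm/s), where `K` (1/s) is the steady-state rate of
#' change of the receiver-chamber concentration, expressed as a fraction of
#' the donor concentration, `Vr` the receiver volume and `A` the membrane
#' area. Measured receiver concentrations are first corrected for the
#' dilution introduced by periodic sampling with buffer replacement, by
#' cumulative mass accounting: the mass withdrawn in all earlier samples is
#' added back, `C_corr(t_k) = C(t_k) + (Vs / Vr) * sum_{j<k} C(t_j)`.
#' Omitting this correction biases `K` low. `K` is then the least-squares
#' slope of the corrected concentration fraction against time over the
#' steady-state window (by default the final two-thirds of time points).
#'
#' @param times_s sampling times, s, strictly increasing.
#' @param receiver_conc measured receiver concentrations at `times_s` (any
#'   concentration unit; divided by `donor_conc`).
#' @param Vr_ml receiver chamber volume, mL.
#' @param A_cm2 membrane surface area, cm^2.
#' @param sample_volume_ml volume withdrawn (and replaced with buffer) at
#'   each sampling, mL.
#' @param donor_conc donor-compartment concentration in the same units as
#'   `receiver_conc` (1 if `receiver_conc` is already a fraction).
#' @param K steady-state rate, 1/s; skip the fit and use this value
#'   directly if supplied.
#' @param window_frac start of the steady-state window as a fraction of the
#'   time points (default `1/3`: the final two-thirds are fitted).
#' @return list with `K_per_s`, `papp_cm_per_s`, `corrected_fraction`, and
#'   `status` (`"ok"`, or `"negative-K"` with a warning).
#' @export
papp <- function(times_s = NULL, receiver_conc = NULL, Vr_ml = 1.5,
                 A_cm2 = 1.12, sample_volume_ml = 0.1, donor_conc = 1,
                 K = NULL, window_frac = 1 / 3) {
  stopifnot(Vr_ml > 0, A_cm2 > 0, sample_volume_ml >= 0, donor_conc > 0)
  corrected <- NULL
  if (is.null(K)) {
    stopifnot(!is.null(times_s), !is.null(receiver_conc),
              length(times_s) == length(receiver_conc), length(times_s) >= 3L)
    if (any(diff(times_s) <= 0)) stop("times must be strictly increasing")
    frac <- receiver_conc / donor_conc
    lag_cum <- c(0, cumsum(frac)[-length(frac)])
    corrected <- frac + sample_volume_ml / Vr_ml * lag_cum
    n <- length(times_s)
    win <- seq.int(max(1L, floor(window_frac * n) + 1L), n)
    fit <- stats::lm.fit(cbind(1, times_s[win]), corrected[win])
    K <- unname(fit$coefficients[2L])
  }
  status <- "ok"
  if (K < 0) {
    warning("fitted K is negative; barrier leak-back or noise dominates")
    status <- "negative-K"
  }
  list(K_per_s = K,
       papp_cm_per_s = K * Vr_ml / A_cm2,  # 1 mL = 1 cm^3
       corrected_fraction = corrected,
       status = status)
}

#' Forward-simulate a Transwell sampling-with-replacement series
#'
#' Generates the receiver-concentration series a permeability assay would
#' measure under sink conditions: between samplings the receiver fraction
#' grows linearly at rate `K_per_s`; at each sampling, `sample_volume_ml`
#' is withdrawn and replaced with blank buffer, diluting the receiver by
#' `(Vr - Vs) / Vr`. The default schedule matches a 3 h assay sampled every
#' 20 min.
#'
#' @param K_per_s true steady-state rate, 1/s.
#' @param duration_s,interval_s assay length and sampling interval, s.
#' @param Vr_ml,sample_volume_ml receiver and sample volumes, mL.
#' @param donor_conc donor concentration (output units).
#' @param noise_sd relative measurement noise (multiplicative Gaussian).
#' @return data frame with `time_s` and `conc` (measured at each sampling,
#'   before replacement).
#' @export
simulate_receiver_series <- function(K_per_s, duration_s = 3 * 3600,
                                     interval_s = 1200, Vr_ml = 1.5,
                                     sample_volume_ml = 0.1, donor_conc = 1,
                                     noise_sd = 0) {
  times <- seq(interval_s, duration_s, by = interval_s)
  conc <- numeric(length(times))
  c_now <- 0
  for (k in seq_along(times)) {
    c_now <- c_now + K_per_s * donor_conc * interval_s
    conc[k] <- c_now
    c_now <- c_now * (Vr_ml - sample_volume_ml) / Vr_ml
  }
  if (noise_sd > 0)
    conc <- conc * (1 + rnorm(length(conc), sd = noise_sd))
  data.frame(time_s = times, conc = conc)
}

#' Trapezoidal area under a flux time series
#'
#' @param times strictly increasing time vector (>= 2 points).
#' @param values flux (or any) values at `times`.
#' @return AUC in `values * times` units.
#' @export
flux_auc <- function(times, values) {
  stopifnot(length(times) >= 2L, length(times) == length(values))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  pracma::trapz(times, values)
}

#' Blank-corrected, area-normalized TEER
#'
#' `(measured - blank) * area`: the resistance of a cell-free insert is
#' subtracted and the result normalized to the membrane area, giving
#' ohm cm^2.
#'
#' @param measured_ohm measured resistance, ohm.
#' @param blank_ohm cell-free insert resistance, ohm.
#' @param area_cm2 membrane area, cm^2.
#' @return TEER in ohm cm^2 (negative values returned with a warning).
#' @export
teer <- function(measured_ohm, blank_ohm, area_cm2 = 1.12) {
  stopifnot(area_cm2 > 0)
  out <- (measured_ohm - blank_ohm) * area_cm2
  if (any(out < 0))
    warning("negative corrected TEER: measured below blank resistance")
  out
}

#' Nominal concentration after dilution
#'
#' @param concentration starting concentration (any amount/volume unit).
#' @param dilution_factor fold dilution, > 0.
#' @return `concentration / dilution_factor`.
#' @examples
#' dilution_nominal(10, 8)  # 1.25
#' @export
dilution_nominal <- function(concentration, dilution_factor) {
  stopifnot(is_scalar_num(dilution_factor), dilution_factor > 0)
  concentration / dilution_factor
}
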