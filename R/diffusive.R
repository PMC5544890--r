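#' Henry's-law equilibrium concentration of CH4 in water
#'
#' The dissolved concentration that would be in equilibrium with the
#' atmospheric partial pressure at a given water temperature:
#' `C_eq = K_H(T) * p_CH4`, with the solubility `K_H` given by a van 't
#' Hoff temperature dependence
#' `K_H(T) = K_H0 * exp(d * (1/T - 1/298.15))` (default `K_H0 = 1.4e-3`
#' mol L-1 atm-1, `d = 1750` K — a standard parameterisation for methane).
#' Both constants are injectable so an alternative solubility model can be
#' swapped in.
#'
#' @param air_ppm CH4 mixing ratio in air (ppm).
#' @param temp_k Water temperature (kelvin); must lie within `t_valid_k`.
#' @param pressure_atm Total air pressure (atm).
#' @param kh0 Solubility at 298.15 K (mol L-1 atm-1).
#' @param kh_tdep van 't Hoff temperature coefficient (K).
#' @param t_valid_k Validity range of the parameterisation (kelvin).
#' @return Equilibrium concentration in mmol m-3.
#' @examples
#' equilibrium_concentration(1.9, 298.15)  # ~2.66e-3 mmol m-3
#' @export
equilibrium_concentration <- function(air_ppm, temp_k, pressure_atm = 1,
                                      kh0 = 1.4e-3, kh_tdep = 1750,
                                      t_valid_k = c(273, 308)) {
  if (any(!is.finite(temp_k)) || any(temp_k < t_valid_k[1]) ||
      any(temp_k > t_valid_k[2])) {
    stop("domain error: temperature outside solubility validity range [",
         t_valid_k[1], ", ", t_valid_k[2], "] K", call. = FALSE)
  }
  if (any(air_ppm < 0)) {
    stop("domain error: air mixing ratio must be non-negative", call. = FALSE)
  }
  kh <- kh0 * exp(kh_tdep * (1 / temp_k - 1 / 298.15))  # mol L-1 atm-1
  p_ch4 <- air_ppm * 1e-6 * pressure_atm                # atm
  kh * p_ch4 * 1e6                                      # mol/L -> mmol/m3
}

#' Diffusive air-water CH4 flux
#'
#' Boundary-layer flux across the water surface,
#' `F = k * (C_w - C_eq)`, where `k` is the gas transfer (piston) velocity,
#' `C_w` the measured dissolved CH4 concentration, and `C_eq` the Henry's-law
#' equilibrium concentration ([equilibrium_concentration()]).  `k` is an
#' input here — it is derived from independent open-water measurements, and
#' is, if anything, an overestimate inside wind-sheltered macrophyte stands.
#' When water temperature is unmeasured, air temperature is the usual
#' stand-in (pass it as `temp_k` and note the approximation).
#'
#' @param k_m_d Gas transfer velocity (m d-1), non-negative.
#' @param cw_mmol_m3 Dissolved CH4 concentration (mmol m-3), non-negative.
#' @param temp_k Water temperature (kelvin), used for `C_eq`.
#' @param air_ppm CH4 mixing ratio in air (ppm).
#' @param pressure_atm Air pressure (atm).
#' @param ceq_mmol_m3 Optional explicit equilibrium concentration overriding
#'   the Henry's-law computation.
#' @param ... Passed to [equilibrium_concentration()].
#' @return Flux in mmol m-2 d-1 (negative = uptake by the water).
#' @export
diffusive_flux <- function(k_m_d, cw_mmol_m3, temp_k = 293.15, air_ppm = 1.9,
                           pressure_atm = 1, ceq_mmol_m3 = NULL, ...) {
  if (any(k_m_d < 0)) {
    stop("domain error: gas transfer velocity must be non-negative",
         call. = FALSE)
  }
  if (any(cw_mmol_m3 < 0)) {
    stop("domain error: dissolved concentration must be non-negative",
         call. = FALSE)
  }
  if (is.null(ceq_mmol_m3)) {
    ceq_mmol_m3 <- equilibrium_concentration(air_ppm, temp_k, pressure_atm,
                                             ...)
  }
  k_m_d * (cw_mmol_m3 - ceq_mmol_m3)
}

#' Share of the total emission carried by surface diffusion
#'
#' Convenience ratio `diffusive / (diffusive + plant)` used to judge whether
#' the open-water diffusive pathway is minor next to the plant-mediated one.
#'
#' @param diffusive_mmol_m2_d,plant_mmol_m2_d Component fluxes.
#' @return Fraction in `[0, 1]` (for non-negative inputs).
#' @export
diffusive_fraction <- function(diffusive_mmol_m2_d, plant_mmol_m2_d) {
  diffusive_mmol_m2_d / (diffusive_mmol_m2_d + plant_mmol_m2_d)
}
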