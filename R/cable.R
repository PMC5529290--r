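#' Membrane resistivity from whole-cell measurements
#'
#' R_m = R_input x membrane area, with the area obtained as total cell
#' capacitance over specific membrane capacitance. Units are reconciled
#' explicitly: MOhm x (pF / (uF/cm^2)) -> kOhm cm^2.
#'
#' @param R_input_MOhm cell input resistance (MOhm).
#' @param C_cell_pF cell capacitance (pF).
#' @param C_specific_uFcm2 specific membrane capacitance (uF/cm^2).
#' @return membrane resistivity in kOhm cm^2.
#' @examples
#' membraneResistivity(45, 150, 1)  # 6.75, "~7" kOhm cm^2
#' @export
membraneResistivity <- function(R_input_MOhm, C_cell_pF, C_specific_uFcm2 = 1) {
  if (R_input_MOhm <= 0 || C_cell_pF <= 0 || C_specific_uFcm2 <= 0)
    stop("all inputs must be positive")
  area_cm2 <- (C_cell_pF * 1e-6) / C_specific_uFcm2   # pF -> uF, / (uF/cm^2)
  R_input_MOhm * 1e6 * area_cm2 / 1e3                 # Ohm cm^2 -> kOhm cm^2
}

#' Steady-state (dc) t-tubule space constant
#'
#' lambda = sqrt(D R_m / (4 R_L)) for a sealed cable of diameter D; inputs
#' are converted to cm internally, the result returned in um.
#'
#' @param D_um tubule diameter (um).
#' @param R_m_kOhmcm2 membrane resistivity (kOhm cm^2).
#' @param R_L_Ohmcm luminal electrolyte resistivity (Ohm cm).
#' @return lambda in um.
#' @examples
#' lambdaDC(0.356, 7, 50)  # ~353 um
#' @export
lambdaDC <- function(D_um, R_m_kOhmcm2, R_L_Ohmcm = 50) {
  if (D_um <= 0 || R_m_kOhmcm2 <= 0 || R_L_Ohmcm <= 0)
    stop("all inputs must be positive")
  D_cm <- D_um * 1e-4
  lam_cm <- sqrt(D_cm * R_m_kOhmcm2 * 1e3 / (4 * R_L_Ohmcm))
  lam_cm * 1e4
}

#' Frequency-dependent space constant
#'
#' Under sinusoidal drive at frequency f the effective space constant
#' shrinks: lambda_f = lambda_dc / Re{sqrt(1 + i 2 pi f tau_m)} (default),
#' where tau_m is the membrane time constant. The alternative modulus
#' reading lambda_dc / |sqrt(1 + i 2 pi f tau_m)| is selectable; the Re
#' form is the default because it reproduces the ~50% reduction at
#' physiological frequencies (150 Hz, tau_m = 7 ms) expected for cardiac
#' tubules.
#'
#' @param lambda_dc_um dc space constant (um).
#' @param f_Hz frequency (Hz), >= 0.
#' @param tau_m_ms membrane time constant (ms).
#' @param form "re" or "mod".
#' @return lambda_f in um.
#' @examples
#' lambdaAC(353, 150, 7)  # ~180 um, ~50% of dc
#' @export
lambdaAC <- function(lambda_dc_um, f_Hz, tau_m_ms, form = c("re", "mod")) {
  form <- match.arg(form)
  if (any(f_Hz < 0)) stop("frequency must be non-negative")
  x <- 2 * pi * f_Hz * tau_m_ms / 1000
  s <- sqrt(complex(real = 1, imaginary = x))
  den <- if (form == "re") Re(s) else Mod(s)
  lambda_dc_um / den
}

#' Detubulation capacitance extrapolation
#'
#' Given total capacitance, capacitance after partial detubulation, and the
#' fraction of tubules disconnected, extrapolates the fully detubulated
#' capacitance and the TT share of total capacitance: TT capacitance =
#' (C_total - C_after) / fraction_removed.
#'
#' @param C_total_pF capacitance before detubulation (pF).
#' @param C_after_pF capacitance after partial detubulation (pF).
#' @param fraction_removed fraction of tubules disconnected, in (0, 1].
#' @return list(C_tt_pF, C_full_detub_pF, tt_fraction_pct). When the
#'   extrapolated TT capacitance exceeds C_total the fraction is capped at
#'   100% with a warning.
#' @examples
#' detubulationExtrapolation(260, 179, 0.84)  # ~164 pF, ~37%
#' @export
detubulationExtrapolation <- function(C_total_pF, C_after_pF, fraction_removed) {
  if (fraction_removed <= 0 || fraction_removed > 1)
    stop("fraction_removed must be in (0, 1]")
  if (C_after_pF >= C_total_pF)
    stop("C_after must be smaller than C_total")
  ctt <- (C_total_pF - C_after_pF) / fraction_removed
  frac <- ctt / C_total_pF * 100
  if (ctt >= C_total_pF) {
    warning("extrapolated TT capacitance reaches the total cell capacitance; ",
            "fraction capped at 100%")
    frac <- 100
  }
  list(C_tt_pF = ctt, C_full_detub_pF = max(C_total_pF - ctt, 0),
       tt_fraction_pct = frac)
}

#' Cable-property report for a species
#'
#' Convenience wrapper chaining [membraneResistivity()], [lambdaDC()] and
#' [lambdaAC()]; tau_m defaults to R_m x C_specific (ms).
#'
#' @param D_um tubule diameter (um).
#' @param R_input_MOhm,C_cell_pF,C_specific_uFcm2 whole-cell parameters.
#' @param R_L_Ohmcm luminal resistivity (Ohm cm).
#' @param f_Hz frequency for the AC space constant (Hz).
#' @param tau_m_ms membrane time constant; R_m x C_specific when NULL.
#' @return list(R_m_kOhmcm2, tau_m_ms, lambda_dc_um, lambda_ac_um,
#'   reduction_pct).
#' @export
cableReport <- function(D_um, R_input_MOhm = 45, C_cell_pF = 150,
                        C_specific_uFcm2 = 1, R_L_Ohmcm = 50, f_Hz = 150,
                        tau_m_ms = NULL) {
  Rm <- membraneResistivity(R_input_MOhm, C_cell_pF, C_specific_uFcm2)
  if (is.null(tau_m_ms)) tau_m_ms <- Rm * C_specific_uFcm2
  ldc <- lambdaDC(D_um, Rm, R_L_Ohmcm)
  lac <- lambdaAC(ldc, f_Hz, tau_m_ms)
  list(R_m_kOhmcm2 = Rm, tau_m_ms = tau_m_ms, lambda_dc_um = ldc,
       lambda_ac_um = lac, reduction_pct = (1 - lac / ldc) * 100)
}
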