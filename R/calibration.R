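#' Sensor calibration for a dual chloride/pH ratiometric biosensor
#'
#' Bundles every constant needed to map (pH, \[Cl-\]i) to wavelength-resolved
#' green/red intensities and back for a ClopHensor-type sensor read out at
#' multiple two-photon excitation wavelengths. The green fluorophore is a
#' two-state (protonated/deprotonated) pH indicator whose emission is
#' statically quenched by chloride (Stern-Volmer, pH-dependent Kd); the red
#' fluorophore is a chloride- and pH-insensitive reference.
#'
#' The pH readout is the green/green excitation ratio at `ph_pair`
#' (numerator/denominator); the chloride readout is the green/red ratio at the
#' pH-isosbestic excitation `iso_wavelength`, where both protonation states
#' are excited equally so the green signal depends on chloride only.
#'
#' The default calibration sets the acid and base excitation efficiencies
#' equal at the denominator wavelength of `ph_pair`, so the two-point
#' titration formula `pH = pKa + gamma*log10((R - R_A)/(R_B - R))` is exact
#' with `pKa` the midpoint of the ratio titration. `R_A`, `R_B` and `R0_Cl`
#' are derived from the spectra, never stored inconsistently.
#'
#' @param wavelengths_nm Excitation wavelengths (nm), unique.
#' @param red_spectrum,green_acid_spectrum,green_base_spectrum Per-wavelength
#'   excitation efficiencies (arbitrary units, all > 0) of the red reference
#'   and of the protonated (acid) / deprotonated (base) green states.
#' @param pKa Titration midpoint of the pH excitation ratio (dimensionless).
#' @param gamma Ratio-titration slope (pH units per decade).
#' @param ph_pair Length-2 wavelength pair (numerator, denominator) for the
#'   pH ratio.
#' @param iso_wavelength pH-isosbestic excitation used for the chloride ratio;
#'   must satisfy `green_acid == green_base` there.
#' @param Kd_ref Chloride dissociation constant (mM) at `pH_ref`.
#' @param pH_ref Reference pH at which `Kd_ref` applies.
#' @param kd_ph_slope log10-units of Kd per pH unit:
#'   `Kd(pH) = Kd_ref * 10^(kd_ph_slope * (pH_ref - pH))`.
#' @param ph_range Reporting range to which estimated pH is clipped near the
#'   titration asymptotes.
#'
#' @return An object of class `clop_calibration` (a list).
#' @examples
#' calib <- sensor_calibration()
#' calib$R0_Cl  # chloride-free green(iso)/red ratio
#' @export
sensor_calibration <- function(wavelengths_nm = c(800, 830, 860, 910, 960),
                               red_spectrum = c(0.30, 0.40, 0.8 / 1.8, 0.55, 0.50),
                               green_acid_spectrum = c(0.85, 1.00, 0.80, 0.30, 0.08),
                               green_base_spectrum = c(0.25, 1.00, 0.80, 2.40, 1.70),
                               pKa = 7.0,
                               gamma = 1.0,
                               ph_pair = c(910, 830),
                               iso_wavelength = 860,
                               Kd_ref = 30,
                               pH_ref = 7.0,
                               kd_ph_slope = 0.5,
                               ph_range = c(4, 10)) {
  if (anyDuplicated(wavelengths_nm)) abort("wavelengths must be unique")
  n <- length(wavelengths_nm)
  stopifnot(length(red_spectrum) == n, length(green_acid_spectrum) == n,
            length(green_base_spectrum) == n)
  if (any(red_spectrum <= 0) || any(green_acid_spectrum <= 0) ||
      any(green_base_spectrum <= 0)) {
    abort("all spectra must be > 0 at the calibrated wavelengths")
  }
  if (Kd_ref <= 0) abort("Kd_ref must be > 0")
  if (!all(ph_pair %in% wavelengths_nm) || !iso_wavelength %in% wavelengths_nm) {
    abort("ph_pair and iso_wavelength must be among wavelengths_nm")
  }
  wl <- as.character(wavelengths_nm)
  red <- setNames(red_spectrum, wl)
  gA <- setNames(green_acid_spectrum, wl)
  gB <- setNames(green_base_spectrum, wl)
  iso <- as.character(iso_wavelength)
  if (abs(gA[[iso]] - gB[[iso]]) > 1e-9 * gA[[iso]]) {
    abort("iso_wavelength must satisfy green_acid == green_base (isosbestic)")
  }
  l1 <- as.character(ph_pair[1]); l2 <- as.character(ph_pair[2])
  if (abs(gA[[l2]] - gB[[l2]]) > 1e-9 * gA[[l2]]) {
    warn(paste("acid and base excitation differ at the pH-ratio denominator",
               "wavelength; pKa is then the apparent midpoint of the ratio",
               "titration, not the chromophore pKa"))
  }
  R_A <- gA[[l1]] / gA[[l2]]
  R_B <- gB[[l1]] / gB[[l2]]
  if (abs(R_A - R_B) < 1e-9) abort("degenerate calibration: R_A == R_B")
  structure(
    list(wavelengths_nm = wavelengths_nm, red = red,
         green_acid = gA, green_base = gB,
         pKa = pKa, gamma = gamma,
         ph_pair = ph_pair, iso_wavelength = iso_wavelength,
         Kd_ref = Kd_ref, pH_ref = pH_ref, kd_ph_slope = kd_ph_slope,
         R_A = R_A, R_B = R_B,
         R0_Cl = gA[[iso]] / red[[iso]],
         ph_range = ph_range),
    class = "clop_calibration")
}

#' @export
print.clop_calibration <- function(x, ...) {
  cat("<clop_calibration>\n")
  cat("  wavelengths:", paste(x$wavelengths_nm, collapse = "/"), "nm\n")
  cat(sprintf("  pH ratio %d/%d nm: pKa %.2f, gamma %.2f, R_A %.3f, R_B %.3f\n",
              x$ph_pair[1], x$ph_pair[2], x$pKa, x$gamma, x$R_A, x$R_B))
  cat(sprintf("  Cl ratio at %d nm (isosbestic): R0 %.3f, Kd %.1f mM at pH %.1f, slope %.2f/pH\n",
              x$iso_wavelength, x$R0_Cl, x$Kd_ref, x$pH_ref, x$kd_ph_slope))
  invisible(x)
}

#' pH-dependent chloride dissociation constant
#'
#' `Kd(pH) = Kd_ref * 10^(kd_ph_slope * (pH_ref - pH))` (mM).
#'
#' @param ph pH value(s).
#' @param calib A [sensor_calibration()] object.
#' @return Kd in mM.
#' @export
chloride_kd <- function(ph, calib = sensor_calibration()) {
  calib$Kd_ref * 10^(calib$kd_ph_slope * (calib$pH_ref - ph))
}

#' Forward sensor model: intensities from (pH, chloride, brightness)
#'
#' Computes the noise-free green and red intensities at every calibrated
#' excitation wavelength for a cell at the given pH and \[Cl-\]i.
#' Red is `brightness * red_spectrum(lambda)`. Green is
#' `brightness * (greenA*theta + greenB*(1-theta)) * q` with protonated
#' fraction `theta = 1/(1 + 10^((pH - pKa)/gamma))` and Stern-Volmer quench
#' `q = 1/(1 + Cl/Kd(pH))`.
#'
#' @param ph Intracellular pH (dimensionless).
#' @param cl Intracellular chloride (mM, >= 0).
#' @param brightness Overall expression/illumination factor (a.u., > 0).
#' @inheritParams chloride_kd
#' @return A tibble with columns `wavelength_nm`, `green`, `red`.
#' @examples
#' forward_intensities(7.1, 8.9, 100)
#' @export
forward_intensities <- function(ph, cl, brightness = 1,
                                calib = sensor_calibration()) {
  stopifnot(length(ph) == 1, length(cl) == 1, length(brightness) == 1)
  if (cl < 0) abort("cl must be >= 0")
  if (brightness <= 0) abort("brightness must be > 0")
  theta <- 1 / (1 + 10^((ph - calib$pKa) / calib$gamma))
  q <- 1 / (1 + cl / chloride_kd(ph, calib))
  tibble(
    wavelength_nm = calib$wavelengths_nm,
    green = brightness * unname(calib$green_acid * theta +
                                  calib$green_base * (1 - theta)) * q,
    red = brightness * unname(calib$red))
}

.intensity_at <- function(w, wavelength, channel) {
  i <- match(wavelength, w$wavelength_nm)
  if (is.na(i)) abort(sprintf("wavelength %s nm absent from intensity table", wavelength))
  w[[channel]][i]
}

#' Estimate pH from a wavelength-intensity table
#'
#' Inverts the green/green excitation ratio at the calibrated `ph_pair`:
#' `pH = pKa + gamma * log10((R - R_A)/(R_B - R))`. The chloride quench and
#' the brightness cancel in the green/green ratio, so the estimate is
#' independent of both. Ratios outside the open interval between the acid and
#' base asymptotes are flagged `"ph_out_of_range"` and return `NA` (the cell
#' is unquantifiable, not an error); estimates beyond `calib$ph_range` are
#' clipped to that range.
#'
#' @param w A tibble as returned by [forward_intensities()] (columns
#'   `wavelength_nm`, `green`, `red`), one cell.
#' @inheritParams chloride_kd
#' @return A one-row tibble with columns `ph` and `flag` (`NA_character_`
#'   when clean).
#' @export
estimate_ph <- function(w, calib = sensor_calibration()) {
  R <- .intensity_at(w, calib$ph_pair[1], "green") /
    .intensity_at(w, calib$ph_pair[2], "green")
  lo <- min(calib$R_A, calib$R_B); hi <- max(calib$R_A, calib$R_B)
  if (!is.finite(R) || R <= lo || R >= hi) {
    return(tibble(ph = NA_real_, flag = "ph_out_of_range"))
  }
  ph <- calib$pKa + calib$gamma * log10((R - calib$R_A) / (calib$R_B - R))
  ph <- min(max(ph, calib$ph_range[1]), calib$ph_range[2])
  tibble(ph = ph, flag = NA_character_)
}

#' Estimate intracellular chloride from intensities and pH
#'
#' Inverts the Stern-Volmer quench of the isosbestic green/red ratio:
#' `Cl = Kd(pH) * (R0_Cl - R_Cl)/R_Cl`, floored at 0. `R_Cl >= R0_Cl`
#' (no detectable quench) returns 0 mM with flag `"below_detection"`;
#' a non-positive ratio is flagged `"invalid_ratio"`.
#'
#' @inheritParams estimate_ph
#' @param ph The cell's pH, typically from [estimate_ph()].
#' @return A one-row tibble with columns `cl_mM` and `flag`.
#' @export
estimate_chloride <- function(w, ph, calib = sensor_calibration()) {
  iso <- calib$iso_wavelength
  R_Cl <- .intensity_at(w, iso, "green") / .intensity_at(w, iso, "red")
  if (!is.finite(R_Cl) || R_Cl <= 0) {
    return(tibble(cl_mM = NA_real_, flag = "invalid_ratio"))
  }
  if (is.na(ph)) return(tibble(cl_mM = NA_real_, flag = "ph_unavailable"))
  if (R_Cl >= calib$R0_Cl) {
    return(tibble(cl_mM = 0, flag = "below_detection"))
  }
  cl <- chloride_kd(ph, calib) * (calib$R0_Cl - R_Cl) / R_Cl
  tibble(cl_mM = max(cl, 0), flag = NA_character_)
}

#' Nernst equilibrium potential for chloride
#'
#' `E_Cl = (R*T/F) * ln(Cl_i/Cl_o)` in mV for a monovalent anion
#' (RT/F ~ 25.85 mV at 300 K). With the conventional assumption of
#' 125 mM extracellular chloride, typical day/night intracellular medians of
#' 8.9 and 18.4 mM give -68.3 and -49.5 mV respectively, an 18.8 mV positive
#' shift of the GABA-A reversal potential at night.
#'
#' @param cl_i Intracellular chloride (mM, > 0); vectorized.
#' @param cl_o Extracellular chloride (mM, > 0). Default 125 mM.
#' @param temperature Absolute temperature in kelvin. Default 300 K.
#' @return E_Cl in mV.
#' @examples
#' nernst_potential(c(8.9, 18.4))
#' @export
nernst_potential <- function(cl_i, cl_o = 125, temperature = 300) {
  if (any(cl_i <= 0) || any(cl_o <= 0)) abort("concentrations must be > 0")
  R_gas <- 8.314462618   # J / (mol K)
  F_far <- 96485.33212   # C / mol
  1000 * R_gas * temperature / F_far * log(cl_i / cl_o)
}
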