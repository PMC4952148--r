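#' Optical extinction coefficients for dual-wavelength oximetry
#'
#' Bundles the four absorption coefficients that Beer-Lambert pulse oximetry
#' needs: deoxyhemoglobin (Hb) and oxyhemoglobin (HbO2) at the red (660 nm)
#' and infrared (940 nm) wavelengths. Units are reciprocal
#' (concentration x path); any consistent unit system works because only the
#' products coefficient x path enter results.
#'
#' Two physical orderings are enforced because they make the ratio-of-ratios
#' map R(s) strictly monotone (decreasing) in saturation, which is what
#' guarantees invertibility: Hb absorbs more red light than HbO2
#' (`eps_hb_red > eps_hbo2_red`) while HbO2 absorbs more infrared
#' (`eps_hbo2_ir > eps_hb_ir`).
#'
#' @param eps_hb_red,eps_hbo2_red Absorption coefficients at 660 nm for Hb
#'   and HbO2.
#' @param eps_hb_ir,eps_hbo2_ir Absorption coefficients at 940 nm for Hb
#'   and HbO2.
#' @return An object of class `optical_coefficients`.
#' @seealso [default_coefficients()], [saturation_from_r()]
#' @export
optical_coefficients <- function(eps_hb_red, eps_hbo2_red,
                                 eps_hb_ir, eps_hbo2_ir) {
  vals <- c(eps_hb_red = eps_hb_red, eps_hbo2_red = eps_hbo2_red,
            eps_hb_ir = eps_hb_ir, eps_hbo2_ir = eps_hbo2_ir)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop_invalid_input("all four extinction coefficients must be finite and strictly positive")
  }
  if (!(eps_hb_red > eps_hbo2_red)) {
    stop_invalid_input("eps_hb_red must exceed eps_hbo2_red (Hb absorbs more red light)")
  }
  if (!(eps_hbo2_ir > eps_hb_ir)) {
    stop_invalid_input("eps_hbo2_ir must exceed eps_hb_ir (HbO2 absorbs more infrared light)")
  }
  structure(as.list(vals), class = "optical_coefficients")
}

#' Default Hb/HbO2 extinction coefficient set
#'
#' Standard tabulated molar extinction coefficients of hemoglobin at 660 and
#' 940 nm, rescaled by 1e-3 so that optical paths expressed in centimetres
#' at physiological total-hemoglobin concentration yield absorbances of
#' order 0.1-1.
#'
#' @return An `optical_coefficients` object.
#' @export
default_coefficients <- function() {
  optical_coefficients(eps_hb_red  = 3.22656, eps_hbo2_red = 0.31960,
                       eps_hb_ir   = 0.69344, eps_hbo2_ir  = 1.21400)
}

#' Build a coefficient set from a configuration block
#'
#' Accepts the list form produced by reading a YAML/JSON block with one
#' entry per wavelength, each holding `wavelength` (660/940 or "red"/"ir"),
#' `eps_hb` and `eps_hbo2`.
#'
#' @param config A list of two wavelength entries.
#' @return An `optical_coefficients` object.
#' @export
coefficients_from_config <- function(config) {
  if (!is.list(config) || length(config) != 2L) {
    stop_config("coefficient config must list exactly two wavelength entries")
  }
  slot <- function(entry) {
    w <- tolower(as.character(entry$wavelength))
    if (w %in% c("660", "red")) "red"
    else if (w %in% c("940", "ir", "infrared")) "ir"
    else stop_config(sprintf("unknown wavelength '%s' in coefficient config", w))
  }
  out <- list()
  for (entry in config) out[[slot(entry)]] <- entry
  if (is.null(out$red) || is.null(out$ir)) {
    stop_config("coefficient config must cover both 660 nm and 940 nm")
  }
  optical_coefficients(eps_hb_red  = out$red$eps_hb,
                       eps_hbo2_red = out$red$eps_hbo2,
                       eps_hb_ir   = out$ir$eps_hb,
                       eps_hbo2_ir = out$ir$eps_hbo2)
}

#' @export
print.optical_coefficients <- function(x, ...) {
  cat("Optical extinction coefficients (per concentration x path)\n")
  cat(sprintf("  660 nm: Hb %.5f  HbO2 %.5f\n", x$eps_hb_red, x$eps_hbo2_red))
  cat(sprintf("  940 nm: Hb %.5f  HbO2 %.5f\n", x$eps_hb_ir, x$eps_hbo2_ir))
  invisible(x)
}

# Effective absorption coefficient of blood at saturation s:
# mu(s, lambda) = s * eps_HbO2(lambda) + (1 - s) * eps_Hb(lambda).
# Linear in s, which is what makes mixed compartments behave as a single
# compartment at the amplitude-weighted saturation.
effective_mu <- function(saturation, coefs, wavelength = c("red", "ir")) {
  wavelength <- match.arg(wavelength)
  if (wavelength == "red") {
    saturation * coefs$eps_hbo2_red + (1 - saturation) * coefs$eps_hb_red
  } else {
    saturation * coefs$eps_hbo2_ir + (1 - saturation) * coefs$eps_hb_ir
  }
}

#' Absorbance of a single absorbing solution
#'
#' Beer-Lambert absorbance `A = ln(Ii/It) = a * C * L` for one species.
#'
#' @param coefficient Absorption coefficient `a` (>= 0).
#' @param concentration Concentration `C` (>= 0).
#' @param path Optical path length `L` (>= 0).
#' @return The absorbance (natural-log scale), vectorised over its inputs.
#' @export
absorbance_single <- function(coefficient, concentration, path) {
  if (any(!is.finite(coefficient)) || any(!is.finite(concentration)) ||
      any(!is.finite(path)) ||
      any(coefficient < 0) || any(concentration < 0) || any(path < 0)) {
    stop_invalid_input("absorbance_single requires finite non-negative arguments")
  }
  coefficient * concentration * path
}

#' Absorbance of a mixture of absorbing species
#'
#' Superposition of Beer-Lambert absorbances: `A = sum_k a_k * C_k * L`.
#' An empty species list gives zero absorbance.
#'
#' @param species A list, each element a list (or `absorbing_species`) with
#'   fields `coefficient` and `concentration`.
#' @param path Shared optical path length `L` (>= 0).
#' @return Total absorbance.
#' @export
absorbance_mixture <- function(species, path) {
  if (!is.finite(path) || path < 0) {
    stop_invalid_input("path must be finite and non-negative")
  }
  if (length(species) == 0L) return(0)
  total <- 0
  for (sp in species) {
    total <- total + absorbance_single(sp$coefficient, sp$concentration, path)
  }
  total
}

#' One absorbing species
#'
#' @param coefficient Absorption coefficient (>= 0).
#' @param concentration Concentration (>= 0).
#' @return An `absorbing_species` list.
#' @export
absorbing_species <- function(coefficient, concentration) {
  if (!is.finite(coefficient) || !is.finite(concentration) ||
      coefficient < 0 || concentration < 0) {
    stop_invalid_input("coefficient and concentration must be finite and non-negative")
  }
  structure(list(coefficient = coefficient, concentration = concentration),
            class = "absorbing_species")
}

#' Transmitted intensity through a blood layer
#'
#' Dynamic Beer-Lambert transmission for blood of saturation `s`:
#' `I = I0 * exp(-(s * eps_HbO2 + (1 - s) * eps_Hb) * L)`. At zero path the
#' incident intensity is returned unchanged; the result is strictly
#' decreasing in path.
#'
#' @param incident Incident intensity `I0` (> 0).
#' @param saturation Oxygen saturation in `[0, 1]` (scalar or vector).
#' @param coefs An [optical_coefficients()] set.
#' @param wavelength `"red"` (660 nm) or `"ir"` (940 nm).
#' @param path Optical path length (>= 0, scalar or vector).
#' @return Transmitted intensity.
#' @export
transmitted_intensity <- function(incident, saturation, coefs,
                                  wavelength = c("red", "ir"), path) {
  wavelength <- match.arg(wavelength)
  if (any(!is.finite(incident)) || any(incident <= 0)) {
    stop_invalid_input("incident intensity must be finite and strictly positive")
  }
  if (any(!is.finite(path)) || any(path < 0)) {
    stop_invalid_input("path must be finite and non-negative")
  }
  if (any(saturation < 0) || any(saturation > 1)) {
    stop_invalid_input("saturation must lie in [0, 1]")
  }
  incident * exp(-effective_mu(saturation, coefs, wavelength) * path)
}

#' Ratio of ratios from two-time-point intensities
#'
#' The oximetry invariant
#' `R = ln(I_red(t1)/I_red(t2)) / ln(I_ir(t1)/I_ir(t2))`. In the
#' small-modulation limit this equals the familiar AC/DC form
#' `(dI/I)_red / (dI/I)_ir` (see [ac_dc_ratio()]), since
#' `ln(I + dI) - ln(I) ~ dI / I`.
#'
#' @param i_red_t1,i_red_t2 Red-channel intensities at the two time points.
#' @param i_ir_t1,i_ir_t2 Infrared-channel intensities at the two time
#'   points; they must differ, otherwise the ratio is degenerate.
#' @return The dimensionless ratio R (vectorised).
#' @export
ratio_of_ratios <- function(i_red_t1, i_red_t2, i_ir_t1, i_ir_t2) {
  all_i <- c(i_red_t1, i_red_t2, i_ir_t1, i_ir_t2)
  if (any(!is.finite(all_i)) || any(all_i <= 0)) {
    stop_invalid_input("all intensities must be finite and strictly positive")
  }
  denom <- log(i_ir_t1 / i_ir_t2)
  if (any(denom == 0)) {
    stop_venoxim("no infrared intensity change between the two time points",
                 "venoxim_degenerate_signal")
  }
  log(i_red_t1 / i_red_t2) / denom
}

#' Ratio of ratios in AC/DC (small-signal) form
#'
#' `R = (AC_red / DC_red) / (AC_ir / DC_ir)` -- the per-cycle estimator a
#' pulse oximeter uses, equivalent to [ratio_of_ratios()] when the
#' modulation depth is small.
#'
#' @param ac_red,dc_red Red-channel AC (peak-to-trough) and DC (baseline)
#'   values.
#' @param ac_ir,dc_ir Infrared-channel AC and DC values.
#' @return The dimensionless ratio R (vectorised).
#' @export
ac_dc_ratio <- function(ac_red, dc_red, ac_ir, dc_ir) {
  if (any(dc_red <= 0) || any(dc_ir <= 0)) {
    stop_invalid_input("DC values must be strictly positive")
  }
  if (any(ac_ir == 0)) {
    stop_venoxim("no infrared modulation: AC/DC ratio is degenerate",
                 "venoxim_degenerate_signal")
  }
  (ac_red / dc_red) / (ac_ir / dc_ir)
}

#' Forward map from saturation to the ratio of ratios
#'
#' `R(s) = mu_red(s) / mu_ir(s)` with
#' `mu(s) = s * eps_HbO2 + (1 - s) * eps_Hb`; strictly decreasing in `s`
#' under the coefficient-ordering invariants.
#'
#' @param saturation Saturation in `[0, 1]` (vectorised).
#' @param coefs An [optical_coefficients()] set.
#' @return The ratio R.
#' @export
r_from_saturation <- function(saturation, coefs) {
  if (any(saturation < 0) || any(saturation > 1)) {
    stop_invalid_input("saturation must lie in [0, 1]")
  }
  effective_mu(saturation, coefs, "red") / effective_mu(saturation, coefs, "ir")
}

#' Invert the ratio of ratios to an oxygen saturation
#'
#' Algebraic inversion of `R(s) = mu_red(s)/mu_ir(s)`:
#' \deqn{s = \frac{\epsilon_{Hb}(660) - R\,\epsilon_{Hb}(940)}
#'               {R\,(\epsilon_{HbO2}(940) - \epsilon_{Hb}(940)) -
#'                (\epsilon_{HbO2}(660) - \epsilon_{Hb}(660))}}
#' Values outside `[0, 1]` by at most `slack` are clipped into range;
#' values further out are returned unclipped and flagged in the
#' `out_of_range` attribute rather than silently altered.
#'
#' @param r Ratio-of-ratios value(s); must be finite.
#' @param coefs An [optical_coefficients()] set.
#' @param slack Tolerated overshoot outside `[0, 1]` that is clipped
#'   (default 0.02).
#' @return Saturation value(s) in fraction units, with a logical attribute
#'   `out_of_range` marking entries beyond the slack band.
#' @export
saturation_from_r <- function(r, coefs, slack = 0.02) {
  if (any(!is.finite(r))) stop_invalid_input("r must be finite")
  delta_red <- coefs$eps_hbo2_red - coefs$eps_hb_red
  delta_ir  <- coefs$eps_hbo2_ir - coefs$eps_hb_ir
  denom <- r * delta_ir - delta_red
  if (any(denom == 0)) {
    stop_venoxim("saturation inversion is singular at this R for these coefficients",
                 "venoxim_non_invertible")
  }
  s <- (coefs$eps_hb_red - r * coefs$eps_hb_ir) / denom
  out_of_range <- s < -slack | s > 1 + slack
  s <- ifelse(out_of_range, s, pmin(1, pmax(0, s)))
  attr(s, "out_of_range") <- out_of_range
  s
}
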