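# Electrophysiology of microperfused tubules: cable analysis, Ohm's law,
# GHK dilution potentials. All voltages are transepithelial, lumen minus bath.

#' Physical constants used throughout
#'
#' Faraday constant (C/mol) and molar gas constant (J/(mol*K)).
#' @keywords internal
#' @noRd
.FARADAY <- 96485.33212
.GAS <- 8.314462618

.check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be finite and > 0", name), call. = FALSE)
  }
  invisible(x)
}

.check_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop(sprintf("`%s` must be finite", name), call. = FALSE)
  }
  invisible(x)
}

#' Forward sealed-end cable model for a perfused tubule
#'
#' Predicts the voltage deflections at the perfusion end (`dV0`) and the
#' collection end (`dVL`) of a tubule of length `L` held in a double-barreled
#' perfusion system when a constant current `I0` is injected at the perfusion
#' end and the far end is electrically sealed. The luminal fluid acts as a
#' core conductor of resistivity `rho`; the epithelium is a distributed
#' membrane of specific resistance `Rte`.
#'
#' The model is the standard finite sealed-end cable: with core resistance per
#' length \eqn{r_c = 4\rho/(\pi d^2)} and membrane resistance per length
#' \eqn{r_m = R_{te}/(\pi d)}, the length constant is
#' \eqn{\lambda = \sqrt{r_m/r_c}} and
#' \deqn{\Delta V_0 = I_0 r_c \lambda \coth(L/\lambda), \quad
#'       \Delta V_L = \Delta V_0 / \cosh(L/\lambda).}
#'
#' @param L tubule length (micrometres).
#' @param diameter luminal diameter (micrometres).
#' @param Rte specific transepithelial resistance (Ohm cm^2).
#' @param rho luminal fluid resistivity (Ohm cm); 60 Ohm cm is physiological
#'   saline at 37 C.
#' @param I0 injected current amplitude (nA).
#' @return A data.frame with columns `dV0` and `dVL` (mV). Vectorised over
#'   all arguments.
#' @seealso [invert_cable()] for the inverse operation.
#' @examples
#' forward_cable(L = 500, diameter = 20, Rte = 300, rho = 60, I0 = 13)
#' @export
forward_cable <- function(L, diameter, Rte, rho = 60, I0 = 13) {
  .check_positive(L, "L")
  .check_positive(diameter, "diameter")
  .check_positive(Rte, "Rte")
  .check_positive(rho, "rho")
  .check_positive(I0, "I0")
  L_cm <- L * 1e-4
  d_cm <- diameter * 1e-4
  r_c <- 4 * rho / (pi * d_cm^2)      # Ohm / cm
  r_m <- Rte / (pi * d_cm)            # Ohm * cm
  lam <- sqrt(r_m / r_c)              # cm
  x <- L_cm / lam
  dV0 <- I0 * 1e-9 * r_c * lam / tanh(x)   # volts
  dVL <- dV0 / cosh(x)
  data.frame(dV0 = dV0 * 1e3, dVL = dVL * 1e3)
}

#' Invert the sealed-end cable model from two voltage deflections
#'
#' Recovers the cable length constant, luminal diameter, and specific
#' transepithelial resistance of a perfused tubule from the deflections
#' measured at both ends during constant-current injection. Inversion uses
#' the closed form \eqn{\lambda = L / \mathrm{acosh}(\Delta V_0/\Delta V_L)},
#' then the input resistance \eqn{R_{in} = |\Delta V_0|/I_0} gives the core
#' resistance per length \eqn{r_c = R_{in}/(\lambda\coth(L/\lambda))}, the
#' diameter \eqn{d = \sqrt{4\rho/(\pi r_c)}}, and
#' \eqn{R_{te} = r_m \pi d} with \eqn{r_m = \lambda^2 r_c}.
#'
#' @param L tubule length (micrometres).
#' @param I0 injected current (nA).
#' @param dV0,dVL voltage deflections at the perfusion and collection end
#'   (mV); must share sign and satisfy `|dV0| > |dVL| > 0`.
#' @param rho luminal fluid resistivity (Ohm cm).
#' @return A data.frame with columns `lam` (micrometres), `core_resistance`
#'   (Ohm/cm), `diameter` (micrometres), and `Rte` (Ohm cm^2).
#' @examples
#' fwd <- forward_cable(L = 500, diameter = 20, Rte = 300)
#' invert_cable(L = 500, I0 = 13, dV0 = fwd$dV0, dVL = fwd$dVL)
#' @export
invert_cable <- function(L, I0, dV0, dVL, rho = 60) {
  .check_positive(L, "L")
  .check_positive(I0, "I0")
  .check_positive(rho, "rho")
  .check_finite(dV0, "dV0")
  .check_finite(dVL, "dVL")
  if (any(dV0 == 0) || any(dVL == 0)) {
    stop("deflections must be nonzero", call. = FALSE)
  }
  if (any(sign(dV0) != sign(dVL))) {
    stop("dV0 and dVL must share sign", call. = FALSE)
  }
  ratio <- abs(dV0) / abs(dVL)
  if (any(ratio <= 1)) {
    stop("cable not invertible: |dV0/dVL| must exceed 1", call. = FALSE)
  }
  L_cm <- L * 1e-4
  lam <- L_cm / acosh(ratio)                     # cm
  x <- L_cm / lam
  R_in <- abs(dV0) * 1e-3 / (I0 * 1e-9)          # Ohm
  r_c <- R_in * tanh(x) / lam                    # Ohm / cm
  d_cm <- sqrt(4 * rho / (pi * r_c))
  r_m <- lam^2 * r_c
  Rte <- r_m * pi * d_cm
  data.frame(
    lam = lam * 1e4,
    core_resistance = r_c,
    diameter = d_cm * 1e4,
    Rte = Rte
  )
}

#' Equivalent short-circuit current by Ohm's law
#'
#' \eqn{I'_{sc} = V_{te} / R_{te}}, with units arranged so that mV over
#' Ohm cm^2 yields microamperes per cm^2. The sign of `Vte` is preserved:
#' a lumen-negative voltage gives a negative current.
#'
#' @param Vte transepithelial voltage (mV, lumen minus bath).
#' @param Rte specific transepithelial resistance (Ohm cm^2).
#' @return Equivalent short-circuit current (uA/cm^2).
#' @examples
#' short_circuit_current(Vte = -20, Rte = 100) # -200 uA/cm^2
#' @export
short_circuit_current <- function(Vte, Rte) {
  .check_finite(Vte, "Vte")
  .check_positive(Rte, "Rte")
  Vte * 1e3 / Rte
}

#' Amiloride-sensitive transepithelial voltage
#'
#' The component of the basal transepithelial voltage abolished by luminal
#' amiloride (plus hydrochlorothiazide), reflecting electrogenic Na+
#' transport through ENaC: `Vte_basal - Vte_amil`, reported signed
#' (lumen-negative basal voltage gives a negative value).
#'
#' @param Vte_basal basal transepithelial voltage (mV).
#' @param Vte_amil transepithelial voltage under luminal amiloride (mV).
#' @return Amiloride-sensitive voltage (mV), signed.
#' @examples
#' amiloride_delta(-25, 0)
#' @export
amiloride_delta <- function(Vte_basal, Vte_amil) {
  .check_finite(Vte_basal, "Vte_basal")
  .check_finite(Vte_amil, "Vte_amil")
  Vte_basal - Vte_amil
}

#' GHK bi-ionic dilution potential from a Na/Cl permeability ratio
#'
#' Evaluates the Goldman-Hodgkin-Katz voltage for a NaCl dilution experiment
#' in which the lumen stays at `conc_control` and the bath is switched to
#' `conc_low` (lumen minus bath, junction-corrected):
#' \deqn{V_{dp} = \frac{RT}{F}\ln\frac{\beta\,[Na]_{bath} + [Cl]_{lumen}}
#'   {\beta\,[Na]_{lumen} + [Cl]_{bath}}, \qquad \beta = P_{Na}/P_{Cl}.}
#' A purely Cl-selective paracellular pathway (`pna_pcl = 0`) gives a
#' positive potential under bath dilution; `pna_pcl = 1` gives exactly zero.
#' Concentrations are used directly (activity coefficients ignored).
#'
#' @param pna_pcl permeability ratio \eqn{P_{Na}/P_{Cl}} (>= 0; `Inf`
#'   allowed and returns the pure-Na bound).
#' @param conc_control,conc_low NaCl concentration of control (lumen) and
#'   dilute (bath) solution (mM).
#' @param temperature absolute temperature (K).
#' @return Dilution potential (mV, lumen minus bath).
#' @examples
#' ghk_dp(0, 145, 30)   # about +42.1 mV at 310.15 K
#' ghk_dp(1, 145, 30)   # exactly 0
#' @export
ghk_dp <- function(pna_pcl, conc_control = 145, conc_low = 30,
                   temperature = 310.15) {
  if (!is.numeric(pna_pcl) || any(is.na(pna_pcl)) || any(pna_pcl < 0)) {
    stop("`pna_pcl` must be numeric and >= 0", call. = FALSE)
  }
  .check_positive(conc_control, "conc_control")
  .check_positive(conc_low, "conc_low")
  .check_positive(temperature, "temperature")
  if (any(conc_control <= conc_low)) {
    stop("`conc_control` must exceed `conc_low`", call. = FALSE)
  }
  rtf_mv <- 1e3 * .GAS * temperature / .FARADAY
  num <- pna_pcl * conc_low + conc_control
  den <- pna_pcl * conc_control + conc_low
  out <- rtf_mv * log(num / den)
  # beta -> Inf limit: ln(conc_low / conc_control)
  inf <- is.infinite(pna_pcl)
  if (any(inf)) out[inf] <- rtf_mv * log(conc_low / conc_control)
  out
}

#' Paracellular Na/Cl permeability ratio from a NaCl dilution potential
#'
#' Closed-form inversion of the GHK dilution-potential expression (see
#' [ghk_dp()]): with \eqn{a = \exp(V_{dp} F/(RT))},
#' \deqn{\beta = \frac{[Cl]_{lumen} - a\,[Cl]_{bath}}
#'   {a\,[Na]_{lumen} - [Na]_{bath}}.}
#' The attainable potential interval for a given solution pair is
#' \eqn{\pm (RT/F)\ln(c_{control}/c_{low})}; a measured potential at the
#' exact bounds returns the boundary solutions 0 or `Inf` with a
#' `"boundary"` attribute, and a potential outside the interval is an error.
#'
#' @param Vdp measured dilution potential (mV, lumen minus bath,
#'   junction-corrected).
#' @param conc_control,conc_low NaCl concentrations (mM), lumen held at
#'   `conc_control`, bath switched to `conc_low`.
#' @param temperature absolute temperature (K).
#' @return Permeability ratio \eqn{P_{Na}/P_{Cl}} (dimensionless). Scalar
#'   boundary cases carry attribute `boundary = TRUE`.
#' @examples
#' pnapcl_from_dp(0, 145, 30)      # 1: symmetric permeation
#' pnapcl_from_dp(ghk_dp(0.8), 145, 30)
#' @export
pnapcl_from_dp <- function(Vdp, conc_control = 145, conc_low = 30,
                           temperature = 310.15) {
  .check_finite(Vdp, "Vdp")
  .check_positive(conc_control, "conc_control")
  .check_positive(conc_low, "conc_low")
  .check_positive(temperature, "temperature")
  if (any(conc_control <= conc_low)) {
    stop("`conc_control` must exceed `conc_low`", call. = FALSE)
  }
  rtf_mv <- 1e3 * .GAS * temperature / .FARADAY
  bound <- rtf_mv * log(conc_control / conc_low)
  if (any(abs(Vdp) > bound)) {
    stop(sprintf(
      "permeability not representable: |Vdp| exceeds the pure-ion bound %.3f mV",
      bound
    ), call. = FALSE)
  }
  a <- exp(Vdp / rtf_mv)
  beta <- (conc_control - a * conc_low) / (a * conc_control - conc_low)
  at_upper <- Vdp == bound
  at_lower <- Vdp == -bound
  beta[at_upper] <- 0
  beta[at_lower] <- Inf
  if (any(at_upper | at_lower)) attr(beta, "boundary") <- TRUE
  beta
}

#' Derive tubule phenotypes from a table of perfusion recordings
#'
#' Applies the full electrophysiology stage to a recording table (one row per
#' tubule): cable inversion for length constant, diameter and `Rte`;
#' equivalent short-circuit current; amiloride-sensitive voltage; and the
#' paracellular Na/Cl permeability ratio from the dilution potential.
#'
#' @param recordings data.frame with columns `tubule_id`, `L`, `I0`, `dV0`,
#'   `dVL`, `Vte_basal`, `Vte_amil`, `Vdp`, `rho`, `temperature`,
#'   `conc_control`, `conc_low` (see [read_recordings()]). Missing `rho`,
#'   `temperature`, `conc_control`, `conc_low` columns fall back to the
#'   defaults 60 Ohm cm, 310.15 K, 145 mM, 30 mM.
#' @return data.frame with columns `tubule_id`, `lam`, `diameter`, `Rte`,
#'   `Isc`, `dVte_amil`, `pna_pcl`, `length`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_tubules = 4, seed = 1))
#' derive_phenotypes(cohort$recordings)
#' @export
derive_phenotypes <- function(recordings) {
  stopifnot(is.data.frame(recordings))
  need <- c("tubule_id", "L", "I0", "dV0", "dVL", "Vte_basal", "Vte_amil", "Vdp")
  miss <- setdiff(need, names(recordings))
  if (length(miss) > 0) {
    stop("recordings lack columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  rho <- if ("rho" %in% names(recordings)) recordings$rho else 60
  temp <- if ("temperature" %in% names(recordings)) recordings$temperature else 310.15
  cc <- if ("conc_control" %in% names(recordings)) recordings$conc_control else 145
  cl <- if ("conc_low" %in% names(recordings)) recordings$conc_low else 30
  cab <- invert_cable(recordings$L, recordings$I0, recordings$dV0,
                      recordings$dVL, rho = rho)
  # vectorised GHK inversion needs per-row solutions; defaults are scalars
  beta <- pnapcl_from_dp(recordings$Vdp, conc_control = cc, conc_low = cl,
                         temperature = temp)
  data.frame(
    tubule_id = recordings$tubule_id,
    lam = cab$lam,
    diameter = cab$diameter,
    Rte = cab$Rte,
    Isc = short_circuit_current(recordings$Vte_basal, cab$Rte),
    dVte_amil = amiloride_delta(recordings$Vte_basal, recordings$Vte_amil),
    pna_pcl = as.numeric(beta),
    length = recordings$L
  )
}
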