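#' Carbonate-system equilibrium constants
#'
#' Temperature-dependent constants for open-system carbonate speciation:
#' Henry's constant for CO2 (`KH`, mol kg^-1 atm^-1), the first and second
#' carbonic-acid dissociation constants (`K1`, `K2`), the calcite solubility
#' product (`Ksp`) — all from the Plummer & Busenberg (1982) temperature
#' expressions — the water ion product (`Kw`, Harned & Owen form) and the
#' Debye-Huckel/Davies coefficient `A` (linear-in-T approximation). The set
#' is injectable everywhere so an alternative compilation (e.g. one exported
#' from a geochemical code) can be swapped in.
#'
#' @param temperature_C Temperature in degrees Celsius (default 20, the
#'   air-conditioned room temperature of the flow-cell experiments).
#' @return An object of class `thermo_constants`.
#' @examples
#' tc <- thermo_constants(25)
#' round(log10(tc$K1), 3)  # -6.352
#' @export
thermo_constants <- function(temperature_C = 20) {
  TK <- temperature_C + 273.15
  lgK1 <- -356.3094 - 0.06091964 * TK + 21834.37 / TK +
    126.8339 * log10(TK) - 1684915 / TK^2
  lgK2 <- -107.8871 - 0.03252849 * TK + 5151.79 / TK +
    38.92561 * log10(TK) - 563713.9 / TK^2
  lgKH <- 108.3865 + 0.01985076 * TK - 6919.53 / TK -
    40.45154 * log10(TK) + 669365 / TK^2
  lgKsp <- -171.9065 - 0.077993 * TK + 2839.319 / TK + 71.595 * log10(TK)
  lgKw <- -4470.99 / TK + 6.0875 - 0.01706 * TK
  structure(list(KH = 10^lgKH, K1 = 10^lgK1, K2 = 10^lgK2,
                 Ksp = 10^lgKsp, Kw = 10^lgKw,
                 A_davies = 0.4883 + 8.074e-4 * temperature_C,
                 temperature_C = temperature_C,
                 provenance = paste("Plummer & Busenberg (1982) carbonate",
                                    "constants; Harned & Owen Kw;",
                                    "Davies A linear in T")),
            class = "thermo_constants")
}

#' @export
print.thermo_constants <- function(x, ...) {
  cat(sprintf("thermo_constants @ %g C: pK1 %.3f, pK2 %.3f, pKH %.3f, pKsp %.3f\n",
              x$temperature_C, -log10(x$K1), -log10(x$K2), -log10(x$KH),
              -log10(x$Ksp)))
  cat(" ", x$provenance, "\n")
  invisible(x)
}

#' Aqueous solution state for open-system carbonate speciation
#'
#' Describes the flow-cell medium: a NaCl/NaHCO3 background electrolyte
#' with optional CaCl2 and additional dissolution-derived Ca, at fixed
#' gas-phase pCO2 (open system). Concentrations are entered in mmol/kg (the
#' experimental convention) and stored molal.
#'
#' @param NaCl_mM,NaHCO3_mM,CaCl2_mM Salt concentrations (mmol/kg).
#'   Defaults: the experimental medium, 99.25 mM NaCl + 1.02 mM NaHCO3.
#' @param Ca_total_mM Total dissolved Ca (mmol/kg) including
#'   dissolution-derived Ca; default = `CaCl2_mM`.
#' @param pCO2_atm CO2 partial pressure (atm); default 550e-6 (550 ppm).
#' @param temperature_C Temperature (C); default 20.
#' @param pH Optional solution pH (needed by [saturation_index()] unless
#'   passed there).
#' @return An object of class `solution_state` with molal concentrations
#'   and the stoichiometric ionic strength `I_molal`.
#' @export
solution_state <- function(NaCl_mM = 99.25, NaHCO3_mM = 1.02, CaCl2_mM = 0,
                           Ca_total_mM = NULL, pCO2_atm = 550e-6,
                           temperature_C = 20, pH = NA_real_) {
  if (is.null(Ca_total_mM)) Ca_total_mM <- CaCl2_mM
  if (any(c(NaCl_mM, NaHCO3_mM, CaCl2_mM, Ca_total_mM) < 0))
    stop("concentrations must be >= 0")
  if (pCO2_atm <= 0) stop("pCO2 must be positive")
  s <- list(NaCl = NaCl_mM / 1000, NaHCO3 = NaHCO3_mM / 1000,
            CaCl2 = CaCl2_mM / 1000, Ca_total = Ca_total_mM / 1000,
            pCO2_atm = pCO2_atm, temperature_C = temperature_C, pH = pH)
  # stoichiometric ionic strength of the salts (1:1 salts contribute c,
  # CaCl2-type 2:1 salts contribute 3c); dissolution-derived Ca counted as
  # a 2:1 contribution too
  s$I_molal <- s$NaCl + s$NaHCO3 + 3 * s$Ca_total
  class(s) <- "solution_state"
  s
}

#' @export
print.solution_state <- function(x, ...) {
  cat(sprintf(
    "solution_state: NaCl %.4g mM, NaHCO3 %.4g mM, Ca %.4g mM, pCO2 %g atm, %g C\n",
    x$NaCl * 1000, x$NaHCO3 * 1000, x$Ca_total * 1000, x$pCO2_atm,
    x$temperature_C))
  cat(sprintf("  I = %.4g molal, pH = %s\n", x$I_molal,
              if (is.na(x$pH)) "unset" else format(x$pH)))
  invisible(x)
}

#' Davies activity coefficient (log10)
#'
#' `log10(gamma) = -A z^2 (sqrt(I)/(1 + sqrt(I)) - 0.3 I)`. Valid to about
#' I = 0.5 molal; a warning is raised beyond.
#'
#' @param z Ion charge.
#' @param I Ionic strength (molal).
#' @param A Davies coefficient (default: 25 C value).
#' @return log10 of the activity coefficient.
#' @export
davies_log_gamma <- function(z, I, A = 0.5085) {
  if (any(I > 0.5))
    warning("ionic strength ", max(I), " molal exceeds the Davies validity range")
  -A * z^2 * (sqrt(I) / (1 + sqrt(I)) - 0.3 * I)
}

# Ionic strength refined once with open-system carbonate speciation at a
# given pH: add HCO3-, CO32-, OH-, H+ (charge-balancing cation assumed
# monovalent, contributing the same as the anions it balances).
refine_ionic_strength <- function(state, tc, pH) {
  I0 <- state$I_molal
  g1 <- 10^davies_log_gamma(1, I0, tc$A_davies)
  h <- 10^(-pH)
  hco3 <- tc$K1 * tc$KH * state$pCO2_atm / (h * g1)
  g2 <- 10^davies_log_gamma(2, I0, tc$A_davies)
  co3 <- tc$K2 * g1 * hco3 / (h * g2)
  oh <- tc$Kw / h / g1
  # extra monovalent anions over the stoichiometric NaHCO3, balanced by a
  # monovalent cation, add c each; CO3^2- with its two balancing monovalent
  # cations adds 3c
  I0 + pmax(hco3 + oh - state$NaHCO3, 0) + 3 * co3
}

#' Calcite saturation index of an open-system solution
#'
#' `Omega = a(Ca2+) a(CO3 2-) / Ksp`, with the carbonate-ion activity fixed
#' by the open-system condition, `a(CO3 2-) = K1 K2 KH pCO2 / {H+}^2`, and
#' the calcium activity from the Davies equation at the solution ionic
#' strength. `Omega < 1` drives dissolution, `Omega > 1` precipitation.
#'
#' @param state A [solution_state()].
#' @param constants A [thermo_constants()]; default: at the state's
#'   temperature. A warning is raised if the two temperatures differ by
#'   more than 5 C.
#' @param pH Solution pH (default: taken from `state`).
#' @param iterate_I Refine the ionic strength once with the carbonate
#'   species at this pH (default `TRUE`).
#' @return Saturation index (dimensionless, >= 0).
#' @export
saturation_index <- function(state, constants = NULL, pH = state$pH,
                             iterate_I = TRUE) {
  stopifnot(inherits(state, "solution_state"))
  tc <- constants %||% thermo_constants(state$temperature_C)
  check_constant_temperature(tc, state)
  if (is.na(pH)) stop("pH must be set to compute the saturation index")
  if (state$Ca_total == 0) return(0)
  I <- state$I_molal
  if (iterate_I) I <- refine_ionic_strength(state, tc, pH)
  gCa <- 10^davies_log_gamma(2, I, tc$A_davies)
  aCO3 <- tc$K1 * tc$K2 * tc$KH * state$pCO2_atm / (10^(-pH))^2
  gCa * state$Ca_total * aCO3 / tc$Ksp
}

#' Solve for the pH at which a solution reaches a target saturation index
#'
#' Inverts the open-system saturation relation in closed form,
#' `{H+} = sqrt(a(Ca) K1 K2 KH pCO2 / (Omega Ksp))`, with one refinement of
#' the ionic strength. The returned pH satisfies
#' `saturation_index(state, pH = pH) == omega_target` to within 1e-6.
#'
#' @param state A [solution_state()] with `Ca_total > 0`.
#' @param omega_target Target saturation index, > 0.
#' @param constants Optional [thermo_constants()].
#' @return pH (numeric scalar).
#' @examples
#' st <- solution_state(Ca_total_mM = 0.0125)  # 500 ppb Ca
#' solve_ph_for_omega(st, 0.1)
#' @export
solve_ph_for_omega <- function(state, omega_target, constants = NULL) {
  stopifnot(inherits(state, "solution_state"))
  if (omega_target <= 0)
    stop("no finite pH reaches Omega = 0; omega_target must be > 0")
  if (state$Ca_total <= 0) stop("Ca_total must be > 0")
  tc <- constants %||% thermo_constants(state$temperature_C)
  check_constant_temperature(tc, state)
  ph_from_I <- function(I) {
    gCa <- 10^davies_log_gamma(2, I, tc$A_davies)
    h <- sqrt(gCa * state$Ca_total * tc$K1 * tc$K2 * tc$KH * state$pCO2_atm /
                (omega_target * tc$Ksp))
    -log10(h)
  }
  pH <- ph_from_I(state$I_molal)
  # refine the ionic strength to self-consistency (converges in a few steps;
  # the carbonate contribution to I is small)
  for (i in seq_len(30)) {
    pH_new <- ph_from_I(refine_ionic_strength(state, tc, pH))
    if (abs(pH_new - pH) < 1e-12) break
    pH <- pH_new
  }
  pH
}

check_constant_temperature <- function(tc, state) {
  if (abs(tc$temperature_C - state$temperature_C) > 5)
    warning("constant-set temperature (", tc$temperature_C,
            " C) differs from the solution temperature (",
            state$temperature_C, " C) by more than 5 C")
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Steady-state outlet Ca concentration of a flow-through cell
#'
#' Mass balance for a flow-through dissolution cell:
#' `[Ca] (ppm) = r * M_Ca * SA / (1e-6 * flow)`, with the dissolution rate
#' `r` in mol m^-2 s^-1, the reactive surface area `SA` in m^2, the molar
#' mass in g/mol and the flow rate in mL/s.
#'
#' @param r_mol_m2_s Dissolution rate (mol m^-2 s^-1), >= 0.
#' @param SA_m2 Reactive surface area (m^2), > 0.
#' @param flow_mL_s Flow rate (mL/s), > 0.
#' @param M_Ca_g_mol Molar mass of Ca (g/mol), default 40.
#' @return Outlet concentration in ppm (multiply by 1000 for ppb).
#' @examples
#' outlet_ca_ppm(5e-7, 1e-4, 0.004) * 1000  # 500 ppb
#' @export
outlet_ca_ppm <- function(r_mol_m2_s, SA_m2, flow_mL_s, M_Ca_g_mol = 40) {
  if (any(r_mol_m2_s < 0)) stop("rate must be >= 0")
  if (SA_m2 <= 0 || M_Ca_g_mol <= 0) stop("SA and M_Ca must be positive")
  if (flow_mL_s <= 0) stop("flow rate must be positive")
  r_mol_m2_s * M_Ca_g_mol * SA_m2 / (1e-6 * flow_mL_s)
}

#' Power-law calcite dissolution rate law R(Omega) = k (1 - Omega)^n
#'
#' A pluggable stand-in family for empirical rate-versus-saturation
#' relations. The default exponent `n = log(0.8)/log(0.9) ~ 2.12` is
#' calibrated so that a 20 percent rate reduction corresponds to a
#' saturation index of 0.1 (the documented mapping used when inverting
#' under-cell rate reductions). `R(Omega >= 1) = 0`.
#'
#' @param k Far-from-equilibrium rate R(0) (mol m^-2 s^-1).
#' @param n Exponent (> 0).
#' @return A function of Omega, with attributes `k` and `n`.
#' @export
rate_law_power <- function(k = 9e-7, n = log(0.8) / log(0.9)) {
  stopifnot(k > 0, n > 0)
  f <- function(omega) ifelse(omega >= 1, 0, k * (1 - omega)^n)
  attr(f, "k") <- k; attr(f, "n") <- n
  f
}

#' Rate law from an interpolation table
#'
#' Builds a monotone rate law R(Omega) by linear interpolation of a user
#' table, for swapping in an empirical relation.
#'
#' @param omega,rate Numeric vectors (same length, omega increasing, rate
#'   non-increasing).
#' @return A function of Omega.
#' @export
rate_law_table <- function(omega, rate) {
  stopifnot(length(omega) == length(rate), !is.unsorted(omega))
  if (is.unsorted(rev(rate))) stop("rate must be non-increasing in omega")
  stats::approxfun(omega, rate, rule = 2)
}

#' Invert a rate reduction into a local saturation index
#'
#' Solves `R(Omega) = (1 - fraction) * R(0)` for Omega on \[0, 1\] by
#' bisection (tolerance 1e-6): the saturation index at which the rate law
#' predicts the observed fractional rate reduction, e.g. beneath an
#' attached cell.
#'
#' @param fraction Observed fractional rate reduction in \[0, 1).
#' @param law A rate law function (default [rate_law_power()]).
#' @return Saturation index Omega.
#' @examples
#' omega_from_rate_reduction(0.2)  # ~0.1 with the calibrated default law
#' @export
omega_from_rate_reduction <- function(fraction, law = rate_law_power()) {
  if (fraction < 0 || fraction >= 1) stop("fraction must lie in [0, 1)")
  if (fraction == 0) return(0)
  r0 <- law(0)
  probe <- law(seq(0, 1, by = 0.05))
  if (is.unsorted(rev(probe)))
    stop("rate law is not non-increasing on [0, 1]; cannot invert")
  target <- function(om) law(om) - (1 - fraction) * r0
  stats::uniroot(target, c(0, 1), tol = 1e-9)$root
}

#' Full speciation report of a solution at a given pH
#'
#' @param state A [solution_state()].
#' @param constants Optional [thermo_constants()].
#' @param pH pH at which to speciate (default: from `state`).
#' @return Data frame of species activities plus pH, ionic strength and
#'   Omega.
#' @export
speciate <- function(state, constants = NULL, pH = state$pH) {
  tc <- constants %||% thermo_constants(state$temperature_C)
  if (is.na(pH)) stop("pH must be set")
  I <- refine_ionic_strength(state, tc, pH)
  g1 <- 10^davies_log_gamma(1, I, tc$A_davies)
  g2 <- 10^davies_log_gamma(2, I, tc$A_davies)
  h <- 10^(-pH)
  aCO2 <- tc$KH * state$pCO2_atm
  aHCO3 <- tc$K1 * aCO2 / h
  aCO3 <- tc$K2 * aHCO3 / h
  om <- saturation_index(state, tc, pH = pH)
  data.frame(
    quantity = c("pH", "I_molal", "a_H", "a_OH", "a_CO2aq", "a_HCO3",
                 "a_CO3", "a_Ca", "omega_calcite"),
    value = c(pH, I, h, tc$Kw / h, aCO2, aHCO3, aCO3,
              g2 * state$Ca_total, om))
}

#' What-if: interfacial saturation state under an assumed pH shift
#'
#' Applies a pH shift (e.g. the interfacial-minus-bulk pH difference
#' inferred under far-from-equilibrium conditions) to a solution and
#' returns the resulting calcite saturation index. This is an exploratory
#' helper: the inferred value depends entirely on the assumed transferable
#' pH shift.
#'
#' @param state A [solution_state()] with `pH` set (the bulk pH).
#' @param delta_pH pH increase at the interface relative to bulk.
#' @param constants Optional [thermo_constants()].
#' @return Saturation index at `pH + delta_pH`.
#' @export
interface_omega_whatif <- function(state, delta_pH, constants = NULL) {
  if (is.na(state$pH)) stop("state$pH (bulk pH) must be set")
  saturation_index(state, constants, pH = state$pH + delta_pH)
}
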