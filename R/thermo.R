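#' Fusion properties of the solute
#'
#' Solid-state thermodynamic constants used to compute ideal solubility:
#' fusion temperature, fusion enthalpy, and the molar heat-capacity
#' difference between the hypothetical supercooled liquid and the solid.
#'
#' @param T_fus fusion (melting) temperature, K.
#' @param dH_fus fusion enthalpy, J/mol.
#' @param dC_p heat-capacity difference solid to liquid, J/(mol K).
#' @return An object of class `"fusion_properties"`.
#' @export
fusion_properties <- function(T_fus, dH_fus, dC_p) {
  vals <- c(T_fus = T_fus, dH_fus = dH_fus, dC_p = dC_p)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("fusion properties must all be positive and finite", call. = FALSE)
  structure(as.list(vals), class = "fusion_properties")
}

#' @export
print.fusion_properties <- function(x, ...) {
  cat(sprintf(
    "Fusion properties: T_fus = %.2f K, dH_fus = %.0f J/mol, dC_p = %.2f J/(mol K)\n",
    x$T_fus, x$dH_fus, x$dC_p))
  invisible(x)
}

#' Ideal mole-fraction solubility from fusion thermodynamics
#'
#' Solubility of the solute in a hypothetical ideal solution (activity
#' coefficient 1), from the fusion constants alone:
#' \deqn{\ln x^{idl} = -\frac{\Delta H_{fus}(T_{fus}-T)}{R\,T_{fus}\,T}
#'   + \frac{\Delta C_p}{R}\left[\frac{T_{fus}-T}{T}
#'   + \ln\frac{T}{T_{fus}}\right]}
#' Both terms vanish at `T = T_fus`, where the ideal solubility is 1.
#'
#' @param T temperature(s), K; must satisfy `0 < T <= T_fus`.
#' @param fp a [fusion_properties()] object.
#' @return Ideal mole-fraction solubility, same length as `T`.
#' @examples
#' ideal_solubility(298.2, ppn_fusion_properties())  # 5.13e-2
#' @export
ideal_solubility <- function(T, fp) {
  stopifnot(inherits(fp, "fusion_properties"))
  if (any(!is.finite(T)) || any(T <= 0))
    stop("temperatures must be positive", call. = FALSE)
  if (any(T > fp$T_fus))
    stop("T exceeds the fusion temperature; the solute is molten there",
         call. = FALSE)
  dT <- fp$T_fus - T
  lnx <- -fp$dH_fus * dT / (R_GAS * fp$T_fus * T) +
    (fp$dC_p / R_GAS) * (dT / T + log(T / fp$T_fus))
  exp(lnx)
}

#' Activity coefficient of the solute
#'
#' Ratio of ideal to experimental solubility, `x_idl / x_e`.  Values above 1
#' flag solute-solvent interactions weaker than in the ideal solution.
#'
#' @param x_idl ideal mole-fraction solubility, in (0, 1\].
#' @param x_e experimental mole-fraction solubility, in (0, 1\].
#' @return The activity coefficient(s).
#' @export
activity_coefficient <- function(x_idl, x_e) {
  if (any(!is.finite(x_idl)) || any(x_idl <= 0) || any(x_idl > 1) ||
      any(!is.finite(x_e)) || any(x_e <= 0) || any(x_e > 1))
    stop("solubilities must lie in (0, 1]", call. = FALSE)
  x_idl / x_e
}

## x log x with the 0 log 0 := 0 limit convention
xlogx <- function(x) ifelse(x > 0, x * log(x), 0)

#' Ideal mixing thermodynamics of a ternary composition
#'
#' For mole fractions `x1`, `x2`, `x3` (solute, cosolvent, water):
#' \deqn{\Delta_{mix}G^{id} = RT\sum x_i\ln x_i,\quad
#'   \Delta_{mix}S^{id} = -R\sum x_i\ln x_i,\quad \Delta_{mix}H^{id} = 0.}
#' Zero mole fractions contribute zero (the `x ln x` limit).
#'
#' @param x1,x2,x3 mole fractions, each in \[0, 1\], summing to 1.
#' @param T temperature(s), K.
#' @return A data frame with columns `G_mix_id` (J/mol), `S_mix_id`
#'   (J/(mol K)), `H_mix_id` (exactly 0).
#' @export
ideal_mixing <- function(x1, x2, x3, T) {
  s <- x1 + x2 + x3
  if (any(abs(s - 1) > 1e-9) || any(c(x1, x2, x3) < 0))
    stop("mole fractions must be non-negative and sum to 1", call. = FALSE)
  sum_xlx <- xlogx(x1) + xlogx(x2) + xlogx(x3)
  data.frame(G_mix_id = R_GAS * T * sum_xlx,
             S_mix_id = -R_GAS * sum_xlx,
             H_mix_id = 0)
}

#' Excess Gibbs energy of the saturated solution
#'
#' Only the solute's non-ideality is observable from solubility data, so the
#' solvent species are treated as ideal and
#' \deqn{G^E = RT\, x_1 \ln\gamma_i.}
#'
#' @param x1 solute mole fraction.
#' @param gamma_i solute activity coefficient, positive.
#' @param T temperature(s), K.
#' @return Excess Gibbs energy, J/mol.
#' @export
excess_gibbs <- function(x1, gamma_i, T) {
  if (any(!is.finite(gamma_i)) || any(gamma_i <= 0))
    stop("gamma_i must be positive", call. = FALSE)
  R_GAS * T * x1 * log(gamma_i)
}

#' Excess enthalpy via Gibbs-Helmholtz
#'
#' From a series of excess Gibbs energies over temperature,
#' \eqn{H^E = -T^2\,\partial(G^E/T)/\partial T}.  `G^E/T` is regressed
#' linearly on `1/T`; under that fitted form the Gibbs-Helmholtz derivative
#' is analytic and `H^E` equals the slope, constant across the series.  A
#' pointwise finite-difference estimate is available as a cross-check via
#' [gibbs_helmholtz_fd()].
#'
#' @param T temperatures, K; at least 2 distinct values.
#' @param GE excess Gibbs energies, J/mol, same length as `T`.
#' @return Numeric vector of `H^E` (J/mol), one per input temperature (all
#'   equal under the linear model), with the fitted intercept and slope in
#'   attribute `"coefficients"`.
#' @export
excess_enthalpy <- function(T, GE) {
  if (length(T) != length(GE))
    stop("T and GE must have equal length", call. = FALSE)
  if (length(unique(T)) < 2L)
    stop("need at least two distinct temperatures", call. = FALSE)
  fit <- stats::lm(I(GE / T) ~ I(1 / T))
  slope <- unname(stats::coef(fit)[2L])
  structure(rep(slope, length(T)), coefficients = unname(stats::coef(fit)))
}

#' Finite-difference Gibbs-Helmholtz cross-check
#'
#' Numerically evaluates \eqn{H^E = -T^2\, d(G^E/T)/dT} by central
#' differences of a supplied smooth function `ge_fun(T)`.
#'
#' @param ge_fun function of temperature returning `G^E` in J/mol.
#' @param T temperatures, K.
#' @param h step size in K for the central difference.
#' @return `H^E` at each `T`, J/mol.
#' @export
gibbs_helmholtz_fd <- function(ge_fun, T, h = 1e-3) {
  g_over_T <- function(t) ge_fun(t) / t
  -T^2 * (g_over_T(T + h) - g_over_T(T - h)) / (2 * h)
}

#' Full mixing-thermodynamics table of a solubility dataset
#'
#' For every `(m, T)` record, computes the ideal solubility, the solute's
#' activity coefficient, ideal mixing functions of the saturated ternary
#' composition, excess Gibbs energy, excess enthalpy (per `m` level via
#' Gibbs-Helmholtz over its temperature series), and the net mixing
#' functions
#' \deqn{\Delta_{mix}G = \Delta_{mix}G^{id} + G^E,\qquad
#'   \Delta_{mix}H = \Delta_{mix}H^{id} + H^E,}
#' with the mixing entropy closed by the exact identity
#' \eqn{\Delta_{mix}S = (\Delta_{mix}H - \Delta_{mix}G)/T}.
#'
#' @param dataset a [solubility_dataset()] with at least 2 temperatures per
#'   `m` level.
#' @param fp a [fusion_properties()] object for the solute.
#' @return A data frame with one row per record and columns `m`, `T_K`,
#'   `x_e`, `x_idl`, `gamma_i`, `G_mix_id`, `S_mix_id`, `H_mix_id`,
#'   `G_excess`, `H_excess`, `G_mix`, `H_mix`, `S_mix` (energies J/mol,
#'   entropies J/(mol K)).
#' @export
mixing_thermo <- function(dataset, fp) {
  stopifnot(inherits(dataset, "solubility_dataset"))
  d <- dataset$data
  n_per_m <- table(d$m)
  if (any(n_per_m < 2L))
    stop("each m level needs at least 2 temperatures for Gibbs-Helmholtz",
         call. = FALSE)
  x_idl <- ideal_solubility(d$T_K, fp)
  gamma <- activity_coefficient(x_idl, d$x_e)
  comp <- saturated_composition(d$x_e, d$m, dataset$masses)
  idm <- ideal_mixing(comp$x1, comp$x2, comp$x3, d$T_K)
  GE <- excess_gibbs(comp$x1, gamma, d$T_K)
  HE <- numeric(nrow(d))
  for (mi in unique(d$m)) {
    sel <- d$m == mi
    HE[sel] <- excess_enthalpy(d$T_K[sel], GE[sel])
  }
  G_mix <- idm$G_mix_id + GE
  H_mix <- idm$H_mix_id + HE
  S_mix <- (H_mix - G_mix) / d$T_K
  data.frame(m = d$m, T_K = d$T_K, x_e = d$x_e, x_idl = x_idl,
             gamma_i = gamma,
             G_mix_id = idm$G_mix_id, S_mix_id = idm$S_mix_id,
             H_mix_id = idm$H_mix_id,
             G_excess = GE, H_excess = HE,
             G_mix = G_mix, H_mix = H_mix, S_mix = S_mix)
}
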