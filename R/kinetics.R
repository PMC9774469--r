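# Gas-liquid film-theory kinetics for methanol-vapor microbubbles reacting
# with free fatty acids in oil: solubility correlations, liquid-film
# mass-transfer coefficient, Hatta number, enhancement factors, regime
# classification, rate laws, and Arrhenius activation-energy estimation.
#
# The printed forms of several source equations are typographically damaged;
# each function documents the adopted canonical reading.

GAS_CONSTANT <- 8.314  # J/(mol K)

check_positive <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    if (!is.numeric(args[[nm]]) || any(!is.finite(args[[nm]])) ||
        any(args[[nm]] <= 0)) {
      stop("argument '", nm, "' must be strictly positive and finite",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Published film-theory constants for the microbubble esterification study
#'
#' The gas-side coefficient, liquid-film coefficient, solubility (Henry-type)
#' constant and lumped rate constant reported for the semi-pilot reactor:
#' `kg_sigma = 5.32e-3`, `k_bl = 1.24e-4` m/s, `Hb = 43.05`,
#' `kr = 1.32e-5`.
#'
#' @return A named list of the four constants plus `g = 9.81` m/s^2 and
#'   `R = 8.314` J/(mol K).
#' @export
film_defaults <- function() {
  list(kg_sigma = 5.32e-3, k_bl = 1.24e-4, Hb = 43.05, kr = 1.32e-5,
       g = 9.81, R = GAS_CONSTANT)
}

#' Gas-in-liquid solubility at 25 degrees C
#'
#' Correlation `M_25 = 6.02e-5 * Vl^0.36 * mu_l^0.61 * Vg^0.64` (product
#' reading of the printed correlation), in the units of the source
#' correlation: `Vl`/`Vg` molar volumes of the liquid and gas species,
#' `mu_l` liquid viscosity.
#'
#' @param Vl,mu_l,Vg Strictly positive correlation inputs.
#' @return Solubility parameter at 25 C.
#' @export
solubility_25 <- function(Vl, mu_l, Vg) {
  check_positive(Vl = Vl, mu_l = mu_l, Vg = Vg)
  6.02e-5 * Vl^0.36 * mu_l^0.61 * Vg^0.64
}

#' Temperature correction of the gas-in-liquid solubility
#'
#' `M_T = 4.996e3 * M_25 * exp(-2539 / T)`. The correlation is
#' self-consistent at 25 C: at `T = 298.15` K it returns `1.0005 * M_25`.
#'
#' @param M25 Solubility at 25 C (from [solubility_25()]).
#' @param T_K Temperature, kelvin.
#' @return Solubility at `T_K`.
#' @export
solubility_T <- function(M25, T_K) {
  check_positive(M25 = M25, T_K = T_K)
  4.996e3 * M25 * exp(-2539 / T_K)
}

#' Liquid-film mass-transfer coefficient for sub-2-mm bubbles
#'
#' `k_bl = 0.31 * (D_gl^2 * rho_l * g / mu_l)^(1/3)` — the buoyancy-driven
#' small-bubble correlation.
#'
#' @param D_gl Gas-in-liquid diffusivity, m^2/s.
#' @param rho_l Liquid density, kg/m^3.
#' @param mu_l Liquid viscosity, Pa s.
#' @param g Gravitational acceleration, m/s^2.
#' @return Liquid-film coefficient, m/s.
#' @export
film_coefficient <- function(D_gl, rho_l, mu_l, g = 9.81) {
  check_positive(D_gl = D_gl, rho_l = rho_l, mu_l = mu_l, g = g)
  0.31 * (D_gl^2 * rho_l * g / mu_l)^(1 / 3)
}

#' Hatta number (pseudo-first-order form)
#'
#' `Ha = sqrt(M_glT * k * Cb) / k_bl`, the canonical pseudo-first-order
#' Hatta number with the solubility-scaled diffusivity in the numerator.
#' `Ha > 1` indicates reaction at the bubble surface rather than in the
#' liquid bulk.
#'
#' @param M_glT Solubility-scaled diffusivity term (or `D*` equivalent).
#' @param k Intrinsic rate constant.
#' @param Cb Bulk liquid reactant concentration, kmol/m^3.
#' @param k_bl Liquid-film coefficient, m/s.
#' @return Dimensionless Hatta number (>= 0).
#' @export
hatta <- function(M_glT, k, Cb, k_bl) {
  check_positive(M_glT = M_glT, Cb = Cb, k_bl = k_bl)
  stopifnot(k >= 0)
  sqrt(M_glT * k * Cb) / k_bl
}

#' Instantaneous enhancement factor
#'
#' `Ei = 1 + M_glT * Cb / (Hb * Pg)` — the additive instantaneous-reaction
#' ceiling on absorption enhancement.
#'
#' @param M_glT Solubility term at reaction temperature.
#' @param Cb Bulk reactant concentration, kmol/m^3.
#' @param Hb Solubility/Henry-type constant (published value 43.05).
#' @param Pg Gas partial pressure, Pa.
#' @return `Ei >= 1`.
#' @export
enhancement_instantaneous <- function(M_glT, Cb, Hb, Pg) {
  check_positive(M_glT = M_glT, Cb = Cb, Hb = Hb, Pg = Pg)
  1 + M_glT * Cb / (Hb * Pg)
}

#' Finite-rate enhancement factor
#'
#' Danckwerts-style correction `E = Ha * (1 - (Ha - 1) / (2 * Ei))`. In the
#' fast-pseudo-first-order limit (`Ei -> Inf`) `E -> Ha`; at `Ha = 1` the
#' correction vanishes and `E = 1`. Values below 1 fall outside the
#' approximation's validity and raise a warning.
#'
#' @param Ha Hatta number (>= 0).
#' @param Ei Instantaneous enhancement factor (>= 1).
#' @return Enhancement factor `E`.
#' @export
enhancement <- function(Ha, Ei) {
  stopifnot(Ha >= 0, Ei >= 1)
  E <- Ha * (1 - (Ha - 1) / (2 * Ei))
  if (any(E < 1)) {
    warning("enhancement factor below 1: outside the approximation's validity range")
  }
  E
}

#' Classify reaction regime and apparent order
#'
#' The reaction occurs at the bubble surface when `Ha > 1`, in the liquid
#' bulk otherwise; the kinetics are assessed as pseudo-first-order when the
#' enhancement factor tracks the Hatta number, `|E - Ha| / Ha <= tol`
#' (published narrative: the two are "almost equal").
#'
#' @param Ha Hatta number.
#' @param E Enhancement factor.
#' @param tol Relative agreement tolerance (default 0.1).
#' @return A list: `regime` (`"surface"` or `"bulk"`), `order_assessment`
#'   (`"pseudo-first-order"` or `"other"`).
#' @export
classify_regime <- function(Ha, E, tol = 0.1) {
  stopifnot(Ha >= 0)
  list(
    regime = if (Ha > 1) "surface" else "bulk",
    order_assessment = if (Ha > 0 && abs(E - Ha) / Ha <= tol)
      "pseudo-first-order" else "other"
  )
}

#' Lumped esterification rate law
#'
#' `-rA = kr * (PA * 101325) * Cb` with the methanol partial pressure given
#' in atmospheres (explicit conversion to Pa) and the published lumped
#' constant `kr = 1.32e-5`.
#'
#' @param PA Gas partial pressure, atm (>= 0).
#' @param Cb Bulk reactant concentration, kmol/m^3 (>= 0).
#' @param kr Lumped rate constant.
#' @return Reaction rate, kmol/(m^3 s).
#' @export
lumped_rate <- function(PA, Cb, kr = 1.32e-5) {
  stopifnot(PA >= 0, Cb >= 0, kr > 0)
  kr * (PA * 101325) * Cb
}

#' Two-film series-resistance absorption rate
#'
#' `rate = Pg / (1/kg_sigma + Ha / sqrt(D_glT * k * Cb))` — gas-side and
#' liquid-side resistances in series. The grouping of the source expression
#' is interpretation-dependent; this two-resistance reading is the adopted
#' canonical form.
#'
#' @param kg_sigma Gas-side coefficient (published 5.32e-3).
#' @param Ha Hatta number.
#' @param D_glT Solubility-scaled diffusivity term at reaction temperature.
#' @param k Intrinsic rate constant.
#' @param Cb Bulk reactant concentration.
#' @param Pg Gas partial pressure, Pa.
#' @return Absorption/reaction rate.
#' @export
series_resistance_rate <- function(kg_sigma, Ha, D_glT, k, Cb, Pg) {
  check_positive(kg_sigma = kg_sigma, D_glT = D_glT, k = k, Cb = Cb, Pg = Pg)
  stopifnot(Ha >= 0)
  Pg / (1 / kg_sigma + Ha / sqrt(D_glT * k * Cb))
}

#' Full film-theory kinetics evaluation
#'
#' Chains the correlations: solubility at 25 C and at the reaction
#' temperature, liquid-film coefficient, Hatta number, instantaneous and
#' finite-rate enhancement factors, regime classification, and the two rate
#' laws.
#'
#' @param props Named list of physical properties: `T_K`, `Vl`, `Vg`,
#'   `mu_l`, `rho_l`, `D_gl`, `Cb`, `Pg` (Pa), `PA` (atm), `k` (intrinsic
#'   rate constant); missing film constants default to [film_defaults()].
#' @param use_published_kbl If `TRUE` (default) use the published
#'   `k_bl = 1.24e-4` m/s; otherwise compute it from the correlation.
#' @return A list of class `film_kinetics_state` with the intermediate
#'   quantities, `Ha`, `Ei`, `E`, `regime`, `order_assessment`,
#'   `rate_series` and `rate_lumped`.
#' @export
film_kinetics <- function(props, use_published_kbl = TRUE) {
  d <- film_defaults()
  for (nm in names(d)) if (is.null(props[[nm]])) props[[nm]] <- d[[nm]]
  M25 <- solubility_25(props$Vl, props$mu_l, props$Vg)
  MT <- solubility_T(M25, props$T_K)
  k_bl <- if (use_published_kbl) props$k_bl else
    film_coefficient(props$D_gl, props$rho_l, props$mu_l, props$g)
  Ha <- hatta(MT, props$k, props$Cb, k_bl)
  Ei <- enhancement_instantaneous(MT, props$Cb, props$Hb, props$Pg)
  E <- enhancement(Ha, Ei)
  cls <- classify_regime(Ha, E)
  structure(list(
    M25 = M25, M_T = MT, k_bl = k_bl, Ha = Ha, Ei = Ei, E = E,
    regime = cls$regime, order_assessment = cls$order_assessment,
    rate_series = series_resistance_rate(props$kg_sigma, Ha, MT, props$k,
                                         props$Cb, props$Pg),
    rate_lumped = lumped_rate(props$PA, props$Cb, props$kr),
    props = props
  ), class = "film_kinetics_state")
}

#' @export
print.film_kinetics_state <- function(x, ...) {
  cat("<film_kinetics_state>\n")
  cat(sprintf("  Ha = %.4g, Ei = %.6g, E = %.4g -> %s regime, %s kinetics\n",
              x$Ha, x$Ei, x$E, x$regime, x$order_assessment))
  cat(sprintf("  rate (series resistance) = %.4g, rate (lumped) = %.4g\n",
              x$rate_series, x$rate_lumped))
  invisible(x)
}

#' Arrhenius activation-energy fit
#'
#' Ordinary least squares of `ln k` on `1/T` (`ln k = ln A0 - EA/(R T)`);
#' the activation energy is `-slope * R`, reported in kJ/mol with its
#' standard error from the slope standard error. Exact on exactly-Arrhenius
#' data.
#'
#' @param T_K Temperatures, kelvin (>= 2 distinct values).
#' @param k Rate constants (> 0), same length.
#' @return A list of class `arrhenius_fit`: `EA_kJmol`, `EA_stderr_kJmol`
#'   (`NA` with only 2 points), `lnA0`, `r2`, `n`, and the underlying `lm`.
#' @examples
#' T_K <- c(343.15, 353.15, 363.15)
#' k <- exp(-10010 / (8.314 * T_K))
#' fit_arrhenius(T_K, k)$EA_kJmol  # 10.01
#' @export
fit_arrhenius <- function(T_K, k) {
  stopifnot(length(T_K) == length(k))
  if (length(unique(T_K)) < 2L) {
    stop("underdetermined: need at least 2 distinct temperatures", call. = FALSE)
  }
  if (any(!is.finite(k)) || any(k <= 0)) {
    stop("rate constants must be strictly positive", call. = FALSE)
  }
  check_positive(T_K = T_K)
  invT <- 1 / T_K
  fit <- stats::lm(log(k) ~ invT)
  cf <- stats::coef(fit)
  slope <- unname(cf["invT"])
  se <- tryCatch(
    suppressWarnings(summary(fit)$coefficients["invT", "Std. Error"]),
    error = function(e) NA_real_)
  if (length(k) <= 2L) se <- NA_real_
  pred <- stats::fitted(fit)
  sst <- sum((log(k) - mean(log(k)))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  structure(list(EA_kJmol = -slope * GAS_CONSTANT / 1000,
                 EA_stderr_kJmol = se * GAS_CONSTANT / 1000,
                 lnA0 = unname(cf["(Intercept)"]),
                 r2 = r2, n = length(k), lm = fit),
            class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("<arrhenius_fit> EA = %.4g +/- %.2g kJ/mol, ln A0 = %.4g, R2 = %.4f (n = %d)\n",
              x$EA_kJmol, x$EA_stderr_kJmol, x$lnA0, x$r2, x$n))
  invisible(x)
}
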