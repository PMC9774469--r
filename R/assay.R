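# Titration-based acid value, FFA percentage, conversion accounting, and
# pseudo-first-order conversion-time modeling.

#' Acid value from a titration record
#'
#' `AV = (FA - FB) * N * 56.11 / W` — mg KOH per g of sample, from the
#' sample and blank titrant volumes, titrant normality and sample mass
#' (56.11 is the molar mass of KOH).
#'
#' @param FA Titrant volume for the sample, mL.
#' @param FB Blank titrant volume, mL.
#' @param N Titrant normality, mol/L.
#' @param W Sample mass, g.
#' @return Acid value, mg KOH / g. Vectorized.
#' @examples
#' acid_value(FA = 2.317, FB = 0, N = 0.5, W = 1)  # 65.0 -> FFA 32.5%
#' @export
acid_value <- function(FA, FB, N, W) {
  stopifnot(N > 0, W > 0, FB >= 0)
  if (any(FA < FB)) stop("negative titration: FA < FB", call. = FALSE)
  (FA - FB) * N * 56.11 / W
}

#' Free fatty acid percentage from acid value
#'
#' `FFA% = AV / 2`, the standard oleic-acid-basis conversion (the oleic
#' factor 28.2/56.11 is within 0.5% of one half).
#'
#' @param av Acid value, mg KOH / g (>= 0).
#' @return FFA content, % by mass. Vectorized.
#' @export
ffa_percent <- function(av) {
  stopifnot(all(av >= 0))
  av / 2
}

#' FFA conversion from initial and current FFA content
#'
#' `X = 100 * (ffa0 - ffa_t) / ffa0`.
#'
#' @param ffa0 Initial FFA content, % (> 0).
#' @param ffa_t FFA content at time t, %, in `[0, ffa0]`.
#' @return Conversion, %. Vectorized over `ffa_t`.
#' @export
conversion <- function(ffa0, ffa_t) {
  stopifnot(ffa0 > 0, all(ffa_t >= 0))
  if (any(ffa_t > ffa0 + 1e-12)) {
    stop("negative conversion: ffa_t exceeds ffa0", call. = FALSE)
  }
  100 * (ffa0 - ffa_t) / ffa0
}

#' Fit a pseudo-first-order conversion model
#'
#' Origin-constrained least squares of `-ln(1 - X/100)` on `t`: the model
#' `X(t) = 100 * (1 - exp(-k_obs t))` with `X(0) = 0` enforced. With a
#' single informative point the fit reduces to the closed form
#' `k_obs = -ln(1 - X/100) / t`.
#'
#' @param t Times, minutes.
#' @param X Conversions, %, each `< 100`.
#' @return `k_obs`, per minute.
#' @examples
#' fit_first_order(40, 97)  # -log(0.03)/40 = 0.08766 min^-1
#' @export
fit_first_order <- function(t, X) {
  stopifnot(length(t) == length(X), all(t >= 0), all(X >= 0))
  if (any(X >= 100)) {
    stop("saturation: conversion at 100% has no finite first-order rate",
         call. = FALSE)
  }
  keep <- t > 0
  if (!any(keep)) stop("need at least one point with t > 0", call. = FALSE)
  z <- -log(1 - X[keep] / 100)
  tt <- t[keep]
  sum(tt * z) / sum(tt^2)  # through-origin OLS slope
}

#' Predict conversion from a first-order rate constant
#'
#' `X(t) = 100 * (1 - exp(-k_obs t))`.
#'
#' @param k_obs Observed rate constant, per minute (>= 0).
#' @param t Times, minutes (>= 0). Vectorized.
#' @return Conversion, %.
#' @examples
#' k <- fit_first_order(40, 97)
#' predict_conversion(k, 60)  # 99.48, within the reported 99.45 +/- 1.3
#' @export
predict_conversion <- function(k_obs, t) {
  stopifnot(k_obs >= 0, all(t >= 0))
  100 * (1 - exp(-k_obs * t))
}

#' Reduce a titration series to a conversion-time series
#'
#' Applies [acid_value()], [ffa_percent()] and [conversion()] to each record;
#' the initial FFA content is taken from the `t = 0` record unless supplied.
#'
#' @param records `data.frame` with columns `t_min`, `FA_mL`, `FB_mL`, `N`,
#'   `W_g`.
#' @param ffa0 Initial FFA %, default the FFA of the earliest record.
#' @return A `data.frame`: `t_min`, `ffa_pct`, `conversion_pct`.
#' @export
reduce_titrations <- function(records, ffa0 = NULL) {
  need <- c("t_min", "FA_mL", "FB_mL", "N", "W_g")
  if (!all(need %in% names(records))) {
    stop("titration records need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  records <- records[order(records$t_min), , drop = FALSE]
  ffa <- ffa_percent(acid_value(records$FA_mL, records$FB_mL, records$N,
                                records$W_g))
  if (is.null(ffa0)) ffa0 <- ffa[1]
  data.frame(t_min = records$t_min, ffa_pct = ffa,
             conversion_pct = conversion(ffa0, ffa))
}
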