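# Seeded synthetic-data generators emulating the study's unpublished inputs:
# the 17-run design/response table, rate-constant-vs-temperature series,
# conversion-time curves, and raw titration records.
#
# Stream splitting: each generator draws from a private RNG stream seeded
# with `seed + <generator offset>` (response 101, rates 202, time course
# 303, titrations 404), so adding one generator call never perturbs the
# output of another.

#' Configuration for the synthetic-data generators
#'
#' Defaults are the published study conditions: the reported quadratic
#' conversion model as the generating surface with Gaussian response noise
#' at the reported full-data RMSE (3.0832%); an Arrhenius law with
#' EA = 10.01 kJ/mol over 70/80/90 C (`lnA0` chosen so k(343.15 K) = 1 in
#' arbitrary units — only EA matters to the fit); a pseudo-first-order time
#' course calibrated to 97% conversion at 40 min, sampled every 10 min over
#' 0--60 min; titrations consistent with a 32.5% FFA feed (0.5 N titrant,
#' 1 g samples).
#'
#' @param seed Integer master seed.
#' @param noise_sd_response Response noise standard deviation, % (>= 0).
#' @param model Generating [quadratic_model()].
#' @param n_center Center replicates in the generated design.
#' @param arrhenius List: `EA_kJmol`, `lnA0`, `T_K`, `lognoise_sd`.
#' @param timecourse List: `k_obs` (per min), `t_grid` (min), `noise_sd` (%).
#' @param assay List: `ffa0` (%), `N` (mol/L), `W_g` (g), `FB_mL` (mL).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1,
                         noise_sd_response = 3.0832,
                         model = mo_conversion_model(),
                         n_center = 5,
                         arrhenius = list(EA_kJmol = 10.01,
                                          lnA0 = 10010 / (8.314 * 343.15),
                                          T_K = c(343.15, 353.15, 363.15),
                                          lognoise_sd = 0),
                         timecourse = list(k_obs = -log(1 - 0.97) / 40,
                                           t_grid = seq(0, 60, by = 10),
                                           noise_sd = 0),
                         assay = list(ffa0 = 32.5, N = 0.5, W_g = 1,
                                      FB_mL = 0)) {
  stopifnot(noise_sd_response >= 0, inherits(model, "quadratic_model"),
            arrhenius$lognoise_sd >= 0, timecourse$noise_sd >= 0,
            length(unique(arrhenius$T_K)) == length(arrhenius$T_K))
  structure(list(seed = as.integer(seed),
                 noise_sd_response = noise_sd_response, model = model,
                 n_center = n_center, arrhenius = arrhenius,
                 timecourse = timecourse, assay = assay),
            class = "synth_config")
}

#' Generate a synthetic design/response table
#'
#' Builds the Box-Behnken design and draws responses from the generating
#' quadratic plus seeded Gaussian noise — an emulation of the study's
#' unpublished 17-run table.
#'
#' @param cfg A [synth_config()].
#' @param clip If `TRUE`, clamp responses to `[0, 100]`.
#' @return A `design_table` with responses.
#' @export
gen_response_table <- function(cfg = synth_config(), clip = FALSE) {
  stopifnot(inherits(cfg, "synth_config"))
  tab <- build_bbd(cfg$model$factors, n_center = cfg$n_center)
  mu <- predict(cfg$model, coded_matrix(tab))
  y <- if (cfg$noise_sd_response > 0) {
    with_seed(cfg$seed + 101L,
              mu + stats::rnorm(length(mu), 0, cfg$noise_sd_response))
  } else mu
  if (clip) y <- pmin(pmax(y, 0), 100)
  set_response(tab, y)
}

#' Generate a synthetic rate-constant-vs-temperature series
#'
#' `k(T) = exp(lnA0 - EA*1000 / (R*T))`, optionally multiplied by seeded
#' lognormal noise — an emulation of the unmeasured rate constants behind
#' the Arrhenius analysis over 70--90 C.
#'
#' @param cfg A [synth_config()].
#' @return A `data.frame`: `T_K`, `k`.
#' @export
gen_rate_constants <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  a <- cfg$arrhenius
  k <- exp(a$lnA0 - a$EA_kJmol * 1000 / (GAS_CONSTANT * a$T_K))
  if (a$lognoise_sd > 0) {
    k <- with_seed(cfg$seed + 202L,
                   k * exp(stats::rnorm(length(k), 0, a$lognoise_sd)))
  }
  data.frame(T_K = a$T_K, k = k)
}

#' Generate a synthetic conversion-time series
#'
#' `X(t) = 100 * (1 - exp(-k_obs t))` on the configured time grid, with
#' optional seeded Gaussian noise (the `t = 0` point stays exactly 0).
#'
#' @param cfg A [synth_config()].
#' @return A `data.frame`: `t_min`, `conversion_pct`.
#' @export
gen_timecourse <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  tc <- cfg$timecourse
  X <- predict_conversion(tc$k_obs, tc$t_grid)
  if (tc$noise_sd > 0) {
    X <- with_seed(cfg$seed + 303L, {
      Xn <- X + stats::rnorm(length(X), 0, tc$noise_sd)
      Xn[tc$t_grid == 0] <- 0
      pmin(pmax(Xn, 0), 100 - 1e-9)
    })
  }
  data.frame(t_min = tc$t_grid, conversion_pct = X)
}

#' Generate synthetic titration records along a conversion series
#'
#' Inverts the acid-value/FFA/conversion chain: for each time point the
#' titrant volume is chosen so that reducing the record reproduces the
#' conversion exactly — `FA = FB + 2 * ffa_t * W / (56.11 * N)` with
#' `ffa_t = ffa0 * (1 - X/100)`.
#'
#' @param cfg A [synth_config()].
#' @param series A conversion series (`t_min`, `conversion_pct`), default
#'   [gen_timecourse()].
#' @return A `data.frame`: `t_min`, `FA_mL`, `FB_mL`, `N`, `W_g`.
#' @export
gen_titrations <- function(cfg = synth_config(), series = gen_timecourse(cfg)) {
  stopifnot(inherits(cfg, "synth_config"))
  a <- cfg$assay
  ffa_t <- a$ffa0 * (1 - series$conversion_pct / 100)
  av <- 2 * ffa_t
  FA <- a$FB_mL + av * a$W_g / (56.11 * a$N)
  data.frame(t_min = series$t_min, FA_mL = FA, FB_mL = a$FB_mL,
             N = a$N, W_g = a$W_g)
}
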