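test_that("solubility correlations match their closed forms", {
  expect_equal(solubility_25(1, 1, 1), 6.02e-5)
  expect_equal(solubility_25(2, 3, 4) / solubility_25(2, 3, 2), 2^0.64,
               tolerance = 1e-12)
  # strictly increasing in each argument
  base <- solubility_25(10, 0.05, 30)
  expect_gt(solubility_25(11, 0.05, 30), base)
  expect_gt(solubility_25(10, 0.06, 30), base)
  expect_gt(solubility_25(10, 0.05, 31), base)
  expect_error(solubility_25(-1, 1, 1), "positive")
  # temperature correction: self-consistent at 25 C
  expect_equal(solubility_T(1, 298.15), 4.996e3 * exp(-2539 / 298.15))
  expect_equal(solubility_T(1, 298.15), 1.0005, tolerance = 1e-3)
  expect_equal(solubility_T(2, 343.15) / solubility_T(2, 298.15),
               exp(2539 * (1 / 298.15 - 1 / 343.15)), tolerance = 1e-12)
  expect_gt(solubility_T(1, 350), solubility_T(1, 340))
})

test_that("the film coefficient follows the small-bubble correlation", {
  expect_equal(film_coefficient(1, 1 / 9.81, 1), 0.31)
  expect_equal(film_coefficient(8e-9, 900, 0.03) /
                 film_coefficient(1e-9, 900, 0.03), 4, tolerance = 1e-12)
  expect_gt(film_coefficient(2e-9, 900, 0.03),
            film_coefficient(1e-9, 900, 0.03))
})

test_that("Hatta number follows the pseudo-first-order form", {
  expect_equal(hatta(1e-9, 1e-2, 1e3, 1.24e-4), sqrt(1e-8) / 1.24e-4)
  expect_equal(hatta(1e-9, 1e-2, 1e3, 1.24e-4), 0.806, tolerance = 1e-3)
  expect_equal(hatta(1e-9, 4e-2, 1e3, 1.24e-4),
               2 * hatta(1e-9, 1e-2, 1e3, 1.24e-4), tolerance = 1e-12)
  expect_equal(hatta(1e-9, 0, 1e3, 1.24e-4), 0)
})

test_that("enhancement factors behave at their limits", {
  expect_equal(enhancement_instantaneous(2e-9, 1e3, 43.05, 101325),
               1 + 2e-9 * 1e3 / (43.05 * 101325))
  expect_equal(enhancement_instantaneous(2e-9, 1e3, 43.05, 101325), 1,
               tolerance = 1e-6)
  expect_gt(enhancement_instantaneous(1, 1, 1, 1),
            enhancement_instantaneous(1, 1, 1, 2))
  expect_equal(enhancement(1, 5), 1)
  expect_equal(enhancement(5, 10), 4)
  expect_equal(enhancement(3, 1e12), 3, tolerance = 1e-9)
  expect_warning(enhancement(10, 1.1), "validity")
})

test_that("regime classification fires the published rules", {
  c1 <- classify_regime(1.5, 1.45)
  expect_equal(c1$regime, "surface")
  expect_equal(c1$order_assessment, "pseudo-first-order")
  expect_equal(classify_regime(0.5, 0.5)$regime, "bulk")
  c3 <- classify_regime(3, 1.2)
  expect_equal(c3$regime, "surface")
  expect_equal(c3$order_assessment, "other")
  # monotone: increasing Ha never flips surface back to bulk
  regimes <- vapply(seq(0.1, 5, by = 0.1),
                    function(ha) classify_regime(ha, ha)$regime, "")
  expect_false(any(regimes[-1] == "bulk" & regimes[-length(regimes)] == "surface"))
})

test_that("rate laws are linear and compose resistances correctly", {
  expect_equal(lumped_rate(1, 100), 1.32e-5 * 101325 * 100)
  expect_equal(lumped_rate(1, 100), 133.7, tolerance = 1e-3)
  expect_equal(lumped_rate(0, 50), 0)
  expect_equal(lumped_rate(2, 100), 2 * lumped_rate(1, 100))
  expect_equal(lumped_rate(1, 200), 2 * lumped_rate(1, 100))
  # series resistance: gas-side limit as the liquid resistance vanishes
  kg <- 5.32e-3
  expect_equal(series_resistance_rate(kg, 1e-9, 1, 1, 1, 101325),
               kg * 101325, tolerance = 1e-6)
  # equal resistances halve the single-resistance rate
  # liquid resistance Ha/sqrt(D k Cb) = 1/kg when Ha = sqrt(D k Cb)/kg
  ha_eq <- sqrt(1e-8 * 1 * 1) / kg
  expect_equal(series_resistance_rate(kg, ha_eq, 1e-8, 1, 1, 101325),
               kg * 101325 / 2, tolerance = 1e-10)
  expect_gt(series_resistance_rate(kg, 1, 1e-8, 1, 1, 2e5),
            series_resistance_rate(kg, 1, 1e-8, 1, 1, 1e5))
  expect_gt(series_resistance_rate(kg, 1, 1e-8, 1, 1, 1e5),
            series_resistance_rate(kg, 2, 1e-8, 1, 1, 1e5))
})

test_that("every correlation matches a straight-line oracle on random inputs", {
  set.seed(31)
  for (i in 1:10) {
    v <- runif(8, 0.1, 10)
    expect_equal(solubility_25(v[1], v[2], v[3]),
                 6.02e-5 * v[1]^0.36 * v[2]^0.61 * v[3]^0.64,
                 tolerance = 1e-12)
    expect_equal(solubility_T(v[1], 300 + 50 * v[2] / 10),
                 4.996e3 * v[1] * exp(-2539 / (300 + 50 * v[2] / 10)),
                 tolerance = 1e-12)
    expect_equal(film_coefficient(v[1], v[2], v[3]),
                 0.31 * (v[1]^2 * v[2] * 9.81 / v[3])^(1 / 3),
                 tolerance = 1e-12)
    expect_equal(hatta(v[1], v[2], v[3], v[4]),
                 sqrt(v[1] * v[2] * v[3]) / v[4], tolerance = 1e-12)
    expect_equal(enhancement_instantaneous(v[1], v[2], v[3], v[4]),
                 1 + v[1] * v[2] / (v[3] * v[4]), tolerance = 1e-12)
  }
})

test_that("the film-theory chain composes into a coherent state", {
  props <- list(T_K = 343.15, Vl = 300, Vg = 40, mu_l = 0.03, rho_l = 900,
                D_gl = 1e-9, Cb = 1.1, Pg = 101325, PA = 1, k = 6e3)
  # methanol at these conditions gives Ei ~ 1, so the Danckwerts correction
  # falls outside its validity range and warns
  st <- suppressWarnings(film_kinetics(props))
  expect_equal(st$M_T, solubility_T(st$M25, 343.15))
  expect_equal(st$Ha, hatta(st$M_T, props$k, props$Cb, film_defaults()$k_bl))
  expect_gte(st$Ei, 1)
  expect_true(st$regime %in% c("surface", "bulk"))
  expect_gt(st$rate_lumped, 0)
  expect_gt(st$rate_series, 0)
  st2 <- suppressWarnings(film_kinetics(props, use_published_kbl = FALSE))
  expect_equal(st2$k_bl,
               film_coefficient(props$D_gl, props$rho_l, props$mu_l))
})

test_that("Arrhenius fitting is exact on exactly-Arrhenius data", {
  T_K <- c(343.15, 353.15, 363.15)
  k <- exp(-10010 / (8.314 * T_K))
  fit <- fit_arrhenius(T_K, k)
  expect_equal(fit$EA_kJmol, 10.01, tolerance = 1e-6)
  expect_equal(fit$lnA0, 0, tolerance = 1e-8)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  # equal rate constants at two temperatures: zero activation energy
  expect_equal(fit_arrhenius(c(340, 360), c(2e-3, 2e-3))$EA_kJmol, 0)
  expect_error(fit_arrhenius(c(350, 350), c(1, 2)), "distinct")
  expect_error(fit_arrhenius(T_K, c(1, -1, 1)), "positive")
})

test_that("Arrhenius estimates are unbiased under ln-scale noise", {
  T_K <- c(343.15, 353.15, 363.15)
  k0 <- exp(-10010 / (8.314 * T_K))
  set.seed(41)
  ea <- replicate(200, fit_arrhenius(T_K, k0 * exp(rnorm(3, 0, 0.02)))$EA_kJmol)
  se_mean <- sd(ea) / sqrt(200)
  expect_lt(abs(mean(ea) - 10.01), 3 * se_mean + 1e-9)
})
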