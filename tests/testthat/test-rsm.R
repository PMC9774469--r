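test_that("OLS recovers the generating coefficients from noiseless data", {
  fit <- fit_quadratic(noiseless_table())
  expect_equal(unname(fit$model$coefficients), unname(ref_coefficients()),
               tolerance = 1e-8)
  expect_lt(max(abs(fit$model$coefficients - ref_coefficients())), 1e-8)
  expect_equal(fit$diagnostics$rmse, 0, tolerance = 1e-10)
})

test_that("degenerate responses give the expected degenerate fits", {
  tab <- noiseless_table()
  # constant response: intercept only
  cfit <- fit_quadratic(set_response(tab, rep(42, 17)))
  expect_equal(unname(cfit$model$coefficients["b0"]), 42)
  expect_equal(max(abs(cfit$model$coefficients[-1])), 0, tolerance = 1e-10)
  # pure linear response y = 2A
  lfit <- fit_quadratic(set_response(tab, 2 * coded_matrix(tab)[, 1]))
  expect_equal(unname(lfit$model$coefficients["bA"]), 2, tolerance = 1e-10)
  expect_equal(max(abs(lfit$model$coefficients[-2])), 0, tolerance = 1e-10)
  expect_equal(lfit$diagnostics$r2, 1, tolerance = 1e-12)
})

test_that("prediction matches a term-by-term evaluation oracle", {
  m <- mo_conversion_model()
  b <- ref_coefficients()
  set.seed(11)
  for (i in 1:25) {
    x <- runif(3, -1, 1)
    expect_equal(predict(m, x), eval_quadratic_oracle(b, x),
                 tolerance = 1e-12)
  }
  expect_equal(predict(m, c(0, 0, 0)), 88.68)
  expect_equal(predict(m, c(0.873, 0.32, 0.24475)), 99.10, tolerance = 0.05)
  expect_equal(predict(m, c(1, 1, 1)), 99.45, tolerance = 1e-10)
  expect_warning(predict(m, c(2, 0, 0)), "extrapolation")
  expect_lte(suppressWarnings(predict(m, c(2, 1, 1), clip = TRUE)), 100)
})

test_that("ANOVA sums of squares are additive and replicate-aware", {
  m <- mo_conversion_model()
  tab <- noiseless_table()
  y <- predict(m, coded_matrix(tab)) +
    with(list(), {set.seed(3); rnorm(17, 0, 3.0832)})
  fit <- fit_quadratic(set_response(tab, y))
  an <- anova_rsm(fit)
  get <- function(s, col) an[an$source == s, col]
  terms9 <- an[an$source %in% c("bA","bB","bC","bAB","bAC","bBC","bAA","bBB","bCC"), ]
  # orthogonal design: partial term SS sum to the model SS, + residual = total
  expect_equal(sum(terms9$ss), get("model", "ss"), tolerance = 1e-8)
  expect_equal(get("model", "ss") + get("residual", "ss"), get("total", "ss"),
               tolerance = 1e-8)
  expect_equal(get("lack_of_fit", "ss") + get("pure_error", "ss"),
               get("residual", "ss"), tolerance = 1e-8)
  expect_equal(get("pure_error", "df"), 4)  # 5 center replicates
  expect_equal(get("lack_of_fit", "df") + get("pure_error", "df"),
               get("residual", "df"))
  # catalyst linear term dominates all other term SS
  expect_equal(terms9$source[which.max(terms9$ss)], "bB")
})

test_that("noiseless data give zero residual SS and no lack of fit signal", {
  an <- anova_rsm(fit_quadratic(noiseless_table()))
  expect_equal(an[an$source == "residual", "ss"], 0, tolerance = 1e-16)
  expect_equal(an[an$source == "model", "ss"], an[an$source == "total", "ss"],
               tolerance = 1e-8)
})

test_that("lack-of-fit rows are omitted with a warning without replicates", {
  tab <- noiseless_table(n_center = 1)
  tab <- set_response(tab, tab$conversion_pct + c(rnorm(12, 0, 1e-6), 0))
  fit <- fit_quadratic(tab)
  expect_warning(an <- anova_rsm(fit), "replicat")
  expect_false(any(an$source %in% c("lack_of_fit", "pure_error")))
})

test_that("model hierarchy ranks the correct class first", {
  tab <- noiseless_table()
  y <- tab$conversion_pct + with(list(), {set.seed(5); rnorm(17, 0, 1)})
  h <- model_hierarchy(set_response(tab, y))
  expect_equal(nrow(h), 3)
  expect_equal(h$class[1], "quadratic")
  # pure linear truth: linear class wins on adjusted R2
  h2 <- model_hierarchy(set_response(tab, coded_matrix(tab)[, 1] +
                                       with(list(), {set.seed(6); rnorm(17, 0, 0.05)})))
  expect_equal(h2$class[1], "linear")
})

test_that("box-constrained optimization finds the exact maximizer", {
  # concave bowl: interior optimum at the origin
  bowl <- quadratic_model(c(b0 = 0, bA = 0, bB = 0, bC = 0, bAB = 0,
                            bAC = 0, bBC = 0, bAA = -1, bBB = -1, bCC = -1))
  opt <- optimize_response(bowl)
  expect_equal(opt$coded, c(0, 0, 0))
  expect_equal(opt$predicted, 0)
  expect_equal(opt$location, "interior stationary")
  # published surface: stationary point outside the cube -> boundary optimum
  m <- mo_conversion_model()
  qp <- mbester:::quad_parts(m)
  stationary <- solve(2 * qp$H, -qp$g)
  expect_gt(max(abs(stationary)), 1)  # C* ~ 2.08
  opt2 <- optimize_response(m)
  expect_equal(opt2$location, "boundary")
  expect_gt(opt2$predicted, 99.45)
  # the optimum beats a dense grid search (independent brute-force oracle)
  g <- seq(-1, 1, length.out = 21)
  grid <- as.matrix(expand.grid(g, g, g))
  expect_gte(opt2$predicted, max(predict(m, grid)) - 1e-9)
})

test_that("evaluation-point mode reproduces the reported optimum prediction", {
  rep <- optimize_response(mo_conversion_model(),
                           at = c(0.873, 0.32, 0.24475))
  expect_equal(rep$predicted, 99.10, tolerance = 0.05)
  expect_equal(rep$natural[["molar_ratio"]], 23.73)
  expect_equal(rep$location, "evaluation point")  # not the stationary point
})

test_that("perturbation traces are one-factor slices through the center", {
  m <- mo_conversion_model()
  tr <- perturbation_profiles(m, grid = c(-1, 0, 1))
  b <- ref_coefficients()
  bt <- tr[tr$factor == "catalyst_wt_pct", ]
  expect_equal(bt$response[bt$coded == 1], 88.68 + 26.13 - 29.76)
  expect_equal(bt$response[bt$coded == -1], 88.68 - 26.13 - 29.76)
  # every trace passes through predict(model, center)
  for (fac in unique(tr$factor)) {
    expect_equal(tr$response[tr$factor == fac & tr$coded == 0],
                 predict(m, c(0, 0, 0)))
  }
  # symmetric model gives a symmetric trace
  sym <- quadratic_model(c(b0 = 0, bA = 0, bB = 0, bC = 0, bAB = 0, bAC = 0,
                           bBC = 0, bAA = 0, bBB = -1, bCC = 0))
  ts <- perturbation_profiles(sym, grid = seq(-1, 1, 0.25))
  bs <- ts[ts$factor == "catalyst_wt_pct", ]
  expect_equal(bs$response, rev(bs$response))
})

test_that("linear and interaction estimates ignore the quadratic block on a BBD", {
  tab <- noiseless_table()
  y <- tab$conversion_pct + with(list(), {set.seed(9); rnorm(17, 0, 2)})
  tab <- set_response(tab, y)
  B <- mbester:::quad_basis(coded_matrix(tab))
  full <- fit_quadratic(tab)$model$coefficients
  sub <- stats::lsfit(B[, 1:7], y, intercept = FALSE)$coefficients
  expect_equal(unname(full[2:7]), unname(sub[2:7]), tolerance = 1e-8)
})

test_that("quadratic models survive a JSON round trip", {
  m <- mo_conversion_model()
  file <- tempfile(fileext = ".json")
  write_model_json(m, file)
  back <- read_model_json(file)
  expect_equal(back$coefficients, m$coefficients)
  set.seed(2)
  x <- runif(3, -1, 1)
  expect_equal(predict(back, x), predict(m, x))
})
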