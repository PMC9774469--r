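# Quadratic response-surface fitting, ANOVA with lack-of-fit, prediction,
# and exact box-constrained optimization over the coded cube.

COEF_NAMES <- c("b0", "bA", "bB", "bC", "bAB", "bAC", "bBC", "bAA", "bBB", "bCC")

#' Construct a full quadratic response-surface model
#'
#' The model, in coded units, is
#' \deqn{y = b_0 + b_A A + b_B B + b_C C + b_{AB} AB + b_{AC} AC + b_{BC} BC
#'       + b_{AA} A^2 + b_{BB} B^2 + b_{CC} C^2}
#'
#' @param coefficients Named numeric vector of the 10 coefficients, names
#'   `b0, bA, bB, bC, bAB, bAC, bBC, bAA, bBB, bCC`.
#' @param factors List of 3 [factor_spec()] objects (used by natural-unit
#'   prediction and reporting).
#' @return An object of class `quadratic_model`.
#' @export
quadratic_model <- function(coefficients, factors = esterification_factors()) {
  stopifnot(is.numeric(coefficients), length(coefficients) == 10L)
  if (is.null(names(coefficients))) names(coefficients) <- COEF_NAMES
  stopifnot(identical(names(coefficients), COEF_NAMES))
  structure(list(coefficients = coefficients, factors = factors),
            class = "quadratic_model")
}

#' Published conversion model for microbubble esterification of microalgae oil
#'
#' The quadratic response surface reported for FFA conversion (%) in the
#' semi-pilot microbubble reactor, in coded units of the three factors
#' (methanol:oil molar ratio 5--25, catalyst 0--5 wt%, time 10--90 min):
#' intercept 88.68; linear 3.27 A, 26.13 B, 7.97 C; interactions 3.24 AB,
#' 3.49 AC, 3.98 BC; quadratics -1.74 A^2, -29.76 B^2, -5.81 C^2.
#'
#' @return A [quadratic_model()].
#' @examples
#' predict(mo_conversion_model(), c(0, 0, 0))  # 88.68
#' @export
mo_conversion_model <- function() {
  quadratic_model(c(b0 = 88.68, bA = 3.27, bB = 26.13, bC = 7.97,
                    bAB = 3.24, bAC = 3.49, bBC = 3.98,
                    bAA = -1.74, bBB = -29.76, bCC = -5.81))
}

# 10-column quadratic basis from an n x 3 coded matrix
quad_basis <- function(X) {
  X <- rbind(X)  # promotes a length-3 vector to 1 x 3
  stopifnot(ncol(X) == 3L)
  B <- cbind(1, X[, 1], X[, 2], X[, 3],
             X[, 1] * X[, 2], X[, 1] * X[, 3], X[, 2] * X[, 3],
             X[, 1]^2, X[, 2]^2, X[, 3]^2)
  colnames(B) <- COEF_NAMES
  B
}

#' Predict conversion from a quadratic model
#'
#' @param object A [quadratic_model()].
#' @param coded A length-3 coded point or an n x 3 matrix of coded points.
#' @param clip If `TRUE`, clamp predictions to `[0, 100]` (the fitted
#'   polynomial can exceed 100% in parts of the cube); default `FALSE`.
#' @param ... Unused.
#' @return Predicted conversion(s), %. Points outside the coded cube are
#'   extrapolations and raise a warning.
#' @export
predict.quadratic_model <- function(object, coded, clip = FALSE, ...) {
  X <- rbind(coded)
  if (any(abs(X) > 1 + 1e-12)) {
    warning("prediction outside the coded cube [-1,1]^3 (extrapolation)")
  }
  y <- as.vector(quad_basis(X) %*% object$coefficients)
  if (clip) y <- pmin(pmax(y, 0), 100)
  y
}

#' @export
print.quadratic_model <- function(x, ...) {
  b <- x$coefficients
  cat("<quadratic_model> conversion (%) in coded units\n")
  cat(sprintf("  y = %.4g %+.4g A %+.4g B %+.4g C %+.4g AB %+.4g AC %+.4g BC %+.4g A^2 %+.4g B^2 %+.4g C^2\n",
              b[1], b[2], b[3], b[4], b[5], b[6], b[7], b[8], b[9], b[10]))
  invisible(x)
}

#' Fit the full quadratic response surface by ordinary least squares
#'
#' Fits the 10-term basis `1, A, B, C, AB, AC, BC, A^2, B^2, C^2` in coded
#' units to the `conversion_pct` column of a design table.
#'
#' @param table A `design_table` with responses (>= 10 runs).
#' @return A list of class `rsm_fit` with elements `model`
#'   (a [quadratic_model()]), `diagnostics` (list: `r2`, `adj_r2`,
#'   `residuals`, `rmse` with the `sqrt(SSE/n)` convention, `n`), and the
#'   underlying `lm` object.
#' @export
fit_quadratic <- function(table) {
  y <- table$conversion_pct
  if (any(is.na(y))) stop("design table has missing responses", call. = FALSE)
  X <- coded_matrix(table)
  if (nrow(X) < 10L) stop("need at least 10 runs to fit the 10-term quadratic", call. = FALSE)
  B <- quad_basis(X)
  df <- as.data.frame(B[, -1])
  df$y <- y
  fit <- stats::lm(y ~ ., data = df)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("singular fit: collinear columns ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  names(cf) <- COEF_NAMES
  n <- length(y)
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  diagnostics <- list(
    r2 = 1 - sse / sst,
    adj_r2 = 1 - (sse / (n - 10)) / (sst / (n - 1)),
    residuals = stats::residuals(fit),
    rmse = sqrt(sse / n),
    n = n
  )
  structure(list(model = quadratic_model(cf, attr(table, "factors")),
                 diagnostics = diagnostics, lm = fit, table = table),
            class = "rsm_fit")
}

#' @export
print.rsm_fit <- function(x, ...) {
  print(x$model)
  d <- x$diagnostics
  cat(sprintf("  n = %d, R2 = %.4f, adj R2 = %.4f, RMSE = %.4f (sqrt(SSE/n))\n",
              d$n, d$r2, d$adj_r2, d$rmse))
  invisible(x)
}

#' ANOVA for a fitted response surface, with lack-of-fit
#'
#' Sequential (Type-I) sums of squares per model term in the canonical order
#' `A, B, C, AB, AC, BC, A^2, B^2, C^2`, F-tested against the residual mean
#' square; the residual is split into lack-of-fit and pure error using
#' replicated design points (identical coded rows). Sequential SS are used
#' so that term SS, residual SS and total SS are exactly additive; on the
#' orthogonal coded Box-Behnken design they coincide with partial (Type-III)
#' SS for the linear and interaction terms, differing only within the
#' mutually correlated pure-quadratic block.
#'
#' @param fit An `rsm_fit` from [fit_quadratic()].
#' @return A `data.frame` with columns `source`, `ss`, `df`, `ms`, `f`, `p`.
#'   Rows: the 9 model terms, `model` (their joint SS), `residual`,
#'   `lack_of_fit` and `pure_error` (when replicates exist), `total`.
#' @export
anova_rsm <- function(fit) {
  stopifnot(inherits(fit, "rsm_fit"))
  table <- fit$table
  y <- table$conversion_pct
  X <- coded_matrix(table)
  B <- quad_basis(X)
  n <- length(y)
  sse_full <- sum(stats::residuals(fit$lm)^2)
  sst <- sum((y - mean(y))^2)
  terms <- COEF_NAMES[-1]
  sse_seq <- vapply(seq_along(COEF_NAMES), function(j) {
    r <- stats::lsfit(B[, 1:j, drop = FALSE], y, intercept = FALSE)$residuals
    sum(r^2)
  }, 0)
  ss <- -diff(sse_seq)
  names(ss) <- terms
  df_res <- n - 10L
  ms_res <- sse_full / df_res
  rows <- data.frame(source = terms, ss = ss, df = 1L, ms = ss,
                     f = ss / ms_res,
                     p = stats::pf(ss / ms_res, 1, df_res, lower.tail = FALSE))
  model_ss <- sst - sse_full
  rows <- rbind(
    data.frame(source = "model", ss = model_ss, df = 9L, ms = model_ss / 9,
               f = (model_ss / 9) / ms_res,
               p = stats::pf((model_ss / 9) / ms_res, 9, df_res, lower.tail = FALSE)),
    rows,
    data.frame(source = "residual", ss = sse_full, df = df_res, ms = ms_res,
               f = NA_real_, p = NA_real_)
  )
  # pure error from replicated coded points
  key <- apply(X, 1, paste, collapse = "/")
  reps <- split(y, key)
  reps <- reps[vapply(reps, length, 0L) > 1L]
  if (length(reps) > 0L) {
    ss_pe <- sum(vapply(reps, function(g) sum((g - mean(g))^2), 0))
    df_pe <- sum(vapply(reps, function(g) length(g) - 1L, 0L))
    ss_lof <- sse_full - ss_pe
    df_lof <- df_res - df_pe
    f_lof <- if (df_lof > 0 && ss_pe > 0) (ss_lof / df_lof) / (ss_pe / df_pe) else NA_real_
    rows <- rbind(rows,
      data.frame(source = "lack_of_fit", ss = ss_lof, df = df_lof,
                 ms = if (df_lof > 0) ss_lof / df_lof else NA_real_,
                 f = f_lof,
                 p = if (is.na(f_lof)) NA_real_ else
                   stats::pf(f_lof, df_lof, df_pe, lower.tail = FALSE)),
      data.frame(source = "pure_error", ss = ss_pe, df = df_pe,
                 ms = ss_pe / df_pe, f = NA_real_, p = NA_real_))
  } else {
    warning("no replicated design points: lack-of-fit rows omitted")
  }
  rows <- rbind(rows, data.frame(source = "total", ss = sst, df = n - 1L,
                                 ms = NA_real_, f = NA_real_, p = NA_real_))
  rownames(rows) <- NULL
  rows
}

#' Compare nested response-surface model classes
#'
#' Fits the linear (A, B, C), two-factor-interaction (adds AB, AC, BC) and
#' full quadratic bases and ranks them by adjusted R-squared.
#'
#' @param table A `design_table` with responses.
#' @return A `data.frame` (`class`, `n_terms`, `r2`, `adj_r2`) sorted by
#'   decreasing adjusted R-squared.
#' @export
model_hierarchy <- function(table) {
  y <- table$conversion_pct
  B <- quad_basis(coded_matrix(table))
  n <- length(y)
  sst <- sum((y - mean(y))^2)
  classes <- list(linear = 1:4, interactions = 1:7, quadratic = 1:10)
  out <- do.call(rbind, lapply(names(classes), function(cl) {
    cols <- classes[[cl]]
    r <- stats::lsfit(B[, cols, drop = FALSE], y, intercept = FALSE)$residuals
    sse <- sum(r^2)
    p <- length(cols)
    data.frame(class = cl, n_terms = p, r2 = 1 - sse / sst,
               adj_r2 = 1 - (sse / (n - p)) / (sst / (n - 1)))
  }))
  out[order(-out$adj_r2), , drop = FALSE]
}

# quadratic in matrix form: f(x) = b0 + g.x + x'Hx
quad_parts <- function(model) {
  b <- model$coefficients
  g <- b[c("bA", "bB", "bC")]
  H <- matrix(c(b["bAA"], b["bAB"] / 2, b["bAC"] / 2,
                b["bAB"] / 2, b["bBB"], b["bBC"] / 2,
                b["bAC"] / 2, b["bBC"] / 2, b["bCC"]), 3, 3)
  list(b0 = unname(b["b0"]), g = unname(g), H = unname(H))
}

#' Maximize a quadratic model over the coded cube
#'
#' Exact box-constrained maximization of the fitted quadratic over
#' `[-1, 1]^3` by active-set enumeration: for each of the 27 combinations of
#' coordinates {free, fixed at -1, fixed at +1} the stationary point of the
#' reduced quadratic is solved in closed form, feasible candidates are
#' evaluated, and the best is returned (ties broken by largest predicted
#' response, then lexicographic coded order).
#'
#' Alternatively, supply `at` to evaluate the model at an explicit coded
#' point instead of optimizing — e.g. to reproduce a reported operating
#' optimum that is not the mathematical maximizer of the fitted surface.
#'
#' @param model A [quadratic_model()].
#' @param at Optional explicit coded point (length 3); if given, no search is
#'   performed and the report describes this point.
#' @return A list of class `optimum_report`: `coded`, `natural`, `predicted`
#'   (%), `location` (`"interior stationary"`, `"boundary"`, or
#'   `"evaluation point"` in `at` mode), and `hessian_eigenvalues` (positive
#'   entries flag non-concave directions).
#' @export
optimize_response <- function(model, at = NULL) {
  qp <- quad_parts(model)
  eigH <- eigen(qp$H, symmetric = TRUE, only.values = TRUE)$values
  evalf <- function(x) qp$b0 + sum(qp$g * x) + as.numeric(t(x) %*% qp$H %*% x)
  if (!is.null(at)) {
    stopifnot(length(at) == 3L)
    return(make_optimum_report(model, at, evalf(at), eigH,
                               kind = "evaluation point"))
  }
  cand <- list()
  states <- expand.grid(s1 = c(0, -1, 1), s2 = c(0, -1, 1), s3 = c(0, -1, 1))
  for (i in seq_len(nrow(states))) {
    s <- as.numeric(states[i, ])
    free <- which(s == 0)
    x <- s
    if (length(free) > 0L) {
      Hff <- 2 * qp$H[free, free, drop = FALSE]
      rhs <- -(qp$g[free] + 2 * qp$H[free, -free, drop = FALSE] %*% s[-free])
      if (length(free) == 3L) rhs <- -qp$g
      xf <- tryCatch(solve(Hff, rhs), error = function(e) NULL)
      if (is.null(xf) || any(abs(xf) > 1)) next
      x[free] <- xf
    }
    cand[[length(cand) + 1L]] <- x
  }
  vals <- vapply(cand, evalf, 0)
  # tie-break: value first, then lexicographic coded order
  ord <- order(-vals, vapply(cand, `[`, 0, 1), vapply(cand, `[`, 0, 2),
               vapply(cand, `[`, 0, 3))
  best <- cand[[ord[1]]]
  make_optimum_report(model, best, vals[ord[1]], eigH)
}

make_optimum_report <- function(model, coded, value, eigH, kind = NULL) {
  if (is.null(kind)) {
    kind <- if (all(abs(coded) < 1 - 1e-9)) "interior stationary" else "boundary"
  }
  natural <- vapply(1:3, function(j) to_natural(coded[j], model$factors[[j]]),
                    0)
  names(natural) <- vapply(model$factors, `[[`, "", "name")
  structure(list(coded = unname(coded), natural = natural, predicted = value,
                 location = kind, hessian_eigenvalues = eigH),
            class = "optimum_report")
}

#' @export
print.optimum_report <- function(x, ...) {
  cat("<optimum_report>\n")
  cat("  coded   :", sprintf("%.4f", x$coded), "\n")
  cat("  natural :", sprintf("%s=%.4g", names(x$natural), x$natural), "\n")
  cat(sprintf("  predicted conversion: %.2f%% (%s)\n", x$predicted, x$location))
  if (any(x$hessian_eigenvalues > 0))
    cat("  note: surface not concave (positive Hessian eigenvalues present)\n")
  invisible(x)
}

#' One-factor-at-a-time perturbation traces
#'
#' For each factor, the predicted response as that factor's coded value
#' sweeps a grid while the others are held at `center` — the data behind a
#' perturbation plot.
#'
#' @param model A [quadratic_model()].
#' @param center Coded reference point (default origin).
#' @param grid Coded values to sweep (default 41 points on `[-1, 1]`).
#' @return A long `data.frame`: `factor`, `coded`, `response`.
#' @export
perturbation_profiles <- function(model, center = c(0, 0, 0),
                                  grid = seq(-1, 1, length.out = 41)) {
  stopifnot(length(center) == 3L)
  fac_names <- vapply(model$factors, `[[`, "", "name")
  out <- lapply(1:3, function(j) {
    pts <- matrix(rep(center, each = length(grid)), ncol = 3)
    pts[, j] <- grid
    data.frame(factor = unname(fac_names[j]), coded = grid,
               response = predict(model, pts))
  })
  do.call(rbind, out)
}

#' Serialize / restore a quadratic model as JSON
#'
#' Stores the 10 coefficients with the factor specifications embedded.
#'
#' @param model A [quadratic_model()].
#' @param file Path to a JSON file.
#' @return `write_model_json()` returns `file` invisibly;
#'   `read_model_json()` returns the restored [quadratic_model()].
#' @export
write_model_json <- function(model, file) {
  obj <- list(
    coefficients = as.list(model$coefficients),
    factors = lapply(model$factors, function(f)
      list(name = f$name, low = f$low, high = f$high, units = f$units))
  )
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = FALSE)
  factors <- lapply(obj$factors, function(f)
    factor_spec(f$name, f$low, f$high, f$units))
  quadratic_model(unlist(obj$coefficients), factors)
}
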