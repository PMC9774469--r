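# Box-Behnken design construction and natural <-> coded factor conversion.

#' Define an experimental factor
#'
#' A factor is described by its natural-unit range; the coded scale maps
#' `low` to -1, the midpoint to 0 and `high` to +1.
#'
#' @param name Factor name (e.g. `"molar_ratio"`).
#' @param low,high Natural-unit bounds of the design range; `low < high`.
#' @param units Human-readable units string.
#' @return An object of class `factor_spec`.
#' @examples
#' factor_spec("catalyst", 0, 5, "wt% of oil")
#' @export
factor_spec <- function(name, low, high, units = "") {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(low), is.numeric(high),
            length(low) == 1L, length(high) == 1L)
  if (!is.finite(low) || !is.finite(high) || low >= high) {
    stop("invalid factor '", name, "': require finite low < high", call. = FALSE)
  }
  structure(list(name = name, low = low, high = high, units = units),
            class = "factor_spec")
}

#' @export
print.factor_spec <- function(x, ...) {
  cat(sprintf("<factor_spec> %s: [%g, %g] %s\n", x$name, x$low, x$high, x$units))
  invisible(x)
}

#' Default factors of the esterification study
#'
#' The three factors varied in the semi-pilot microbubble esterification
#' experiments: methanol-to-oil molar ratio (the numeric multiplier N of the
#' "1:N" notation), catalyst dosage as weight percent of oil, and reaction
#' time in minutes.
#'
#' @return A list of three [factor_spec()] objects named `A`, `B`, `C`.
#' @export
esterification_factors <- function() {
  list(
    A = factor_spec("molar_ratio", 5, 25, "mol MeOH / mol oil"),
    B = factor_spec("catalyst_wt_pct", 0, 5, "wt% of oil"),
    C = factor_spec("time_min", 10, 90, "min")
  )
}

#' Convert a natural value to coded units
#'
#' Linear coding: `(value - (low + high)/2) / ((high - low)/2)`. Values
#' outside `[low, high]` are permitted (extrapolation) and produce coded
#' values outside `[-1, 1]`.
#'
#' @param value Numeric vector in natural units.
#' @param factor A [factor_spec()].
#' @return Coded value(s); the inverse of [to_natural()].
#' @examples
#' to_coded(15, factor_spec("ratio", 5, 25))  # 0
#' @export
to_coded <- function(value, factor) {
  stopifnot(inherits(factor, "factor_spec"))
  mid <- (factor$low + factor$high) / 2
  half <- (factor$high - factor$low) / 2
  (value - mid) / half
}

#' Convert a coded value to natural units
#'
#' @param coded Numeric vector on the coded scale (-1 = low, +1 = high).
#' @param factor A [factor_spec()].
#' @return Natural-unit value(s); the inverse of [to_coded()].
#' @export
to_natural <- function(coded, factor) {
  stopifnot(inherits(factor, "factor_spec"))
  mid <- (factor$low + factor$high) / 2
  half <- (factor$high - factor$low) / 2
  mid + coded * half
}

# canonical 12-run edge-point block of the 3-factor BBD, in lexicographic
# factor-pair order (A,B), (A,C), (B,C); within a pair (-,-), (+,-), (-,+), (+,+)
bbd_edge_points <- function() {
  pm <- cbind(c(-1, 1, -1, 1), c(-1, -1, 1, 1))
  rbind(
    cbind(pm[, 1], pm[, 2], 0),
    cbind(pm[, 1], 0, pm[, 2]),
    cbind(0, pm[, 1], pm[, 2])
  )
}

#' Generate a three-factor Box-Behnken design
#'
#' Produces the 12 edge-midpoint points of the factor cube,
#' `(+-1, +-1, 0), (+-1, 0, +-1), (0, +-1, +-1)`, followed by `n_center`
#' replicates of the center point `(0, 0, 0)`. Edge points are emitted in
#' lexicographic factor-pair order and centers last; set `shuffle_seed` to
#' randomize the run order reproducibly.
#'
#' @param factors A list of exactly 3 [factor_spec()] objects.
#' @param n_center Number of center-point replicates (>= 1); 5 gives the
#'   classical 17-run design.
#' @param shuffle_seed Optional integer; if supplied, rows are permuted with
#'   this seed (run_ids follow the new order).
#' @return A `design_table`: a `data.frame` with columns `run_id`, one coded
#'   column per factor (`<name>_coded`), one natural column per factor, and
#'   `conversion_pct` (all `NA` until responses are attached), plus the
#'   factor specs in attribute `"factors"`.
#' @examples
#' bbd <- build_bbd(esterification_factors(), n_center = 5)
#' nrow(bbd)  # 17
#' @export
build_bbd <- function(factors, n_center = 5, shuffle_seed = NULL) {
  if (length(factors) != 3L) {
    stop("unsupported design: build_bbd requires exactly 3 factors", call. = FALSE)
  }
  factors <- lapply(factors, function(f) {
    if (!inherits(f, "factor_spec")) stop("factors must be factor_spec objects", call. = FALSE)
    f
  })
  stopifnot(is.numeric(n_center), length(n_center) == 1L, n_center >= 1,
            n_center == round(n_center))
  coded <- rbind(bbd_edge_points(),
                 matrix(0, nrow = n_center, ncol = 3))
  if (!is.null(shuffle_seed)) {
    ord <- local({
      set.seed(as.integer(shuffle_seed))
      sample.int(nrow(coded))
    })
    coded <- coded[ord, , drop = FALSE]
  }
  nat <- vapply(1:3, function(j) to_natural(coded[, j], factors[[j]]),
                numeric(nrow(coded)))
  names_c <- paste0(vapply(factors, `[[`, "", "name"), "_coded")
  out <- data.frame(run_id = seq_len(nrow(coded)), coded, nat,
                    conversion_pct = NA_real_)
  names(out) <- c("run_id", names_c, vapply(factors, `[[`, "", "name"),
                  "conversion_pct")
  attr(out, "factors") <- factors
  class(out) <- c("design_table", "data.frame")
  out
}

#' Extract the coded design matrix
#'
#' @param table A `design_table` (or any data.frame with `*_coded` columns).
#' @return A numeric matrix with one column per factor, coded units.
#' @export
coded_matrix <- function(table) {
  cols <- grep("_coded$", names(table), value = TRUE)
  if (length(cols) == 0L) stop("no *_coded columns found", call. = FALSE)
  as.matrix(table[, cols, drop = FALSE])
}

#' Attach (or replace) the response column of a design table
#'
#' @param table A `design_table`.
#' @param response Numeric vector of conversions (%), one per run.
#' @return The table with `conversion_pct` filled in.
#' @export
set_response <- function(table, response) {
  stopifnot(length(response) == nrow(table))
  table$conversion_pct <- as.numeric(response)
  table
}

#' Read / write the design-table CSV dialect
#'
#' Columns: `run_id`, the three `*_coded` columns, the three natural-unit
#' columns, and optionally `conversion_pct`. Header mandatory; decimal point,
#' comma separator.
#'
#' @param file Path.
#' @param factors Factor specs to attach on read (default
#'   [esterification_factors()]).
#' @return `read_design_csv()` returns a `design_table`;
#'   `write_design_csv()` returns `file` invisibly.
#' @export
read_design_csv <- function(file, factors = esterification_factors()) {
  df <- utils::read.csv(file, check.names = FALSE)
  if (!"run_id" %in% names(df)) stop("design CSV must have a run_id column", call. = FALSE)
  if (!"conversion_pct" %in% names(df)) df$conversion_pct <- NA_real_
  attr(df, "factors") <- factors
  class(df) <- c("design_table", "data.frame")
  df
}

#' @rdname read_design_csv
#' @param table A `design_table` to write.
#' @export
write_design_csv <- function(table, file) {
  utils::write.csv(as.data.frame(table), file, row.names = FALSE)
  invisible(file)
}
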