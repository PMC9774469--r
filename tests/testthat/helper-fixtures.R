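# shared fixtures: the published quadratic coefficients and a noiseless
# design/response table generated from them

ref_coefficients <- function() {
  c(b0 = 88.68, bA = 3.27, bB = 26.13, bC = 7.97,
    bAB = 3.24, bAC = 3.49, bBC = 3.98,
    bAA = -1.74, bBB = -29.76, bCC = -5.81)
}

noiseless_table <- function(n_center = 5) {
  m <- mo_conversion_model()
  tab <- build_bbd(m$factors, n_center = n_center)
  set_response(tab, predict(m, coded_matrix(tab)))
}

# uniform(-1, 1) draws from a throwaway seeded stream
with_seed_vec <- function(seed, n) {
  set.seed(seed)
  runif(n, -1, 1)
}

# brute-force term-by-term polynomial evaluation, independent of quad_basis
eval_quadratic_oracle <- function(b, x) {
  b <- unname(b)
  b[1] + b[2] * x[1] + b[3] * x[2] + b[4] * x[3] +
    b[5] * x[1] * x[2] + b[6] * x[1] * x[3] + b[7] * x[2] * x[3] +
    b[8] * x[1]^2 + b[9] * x[2]^2 + b[10] * x[3]^2
}
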