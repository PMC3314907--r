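# Shared fixture builders. All randomness is seeded at the call site.

random_symmetric <- function(scale = 1) {
  m <- matrix(rnorm(9, sd = scale), 3, 3)
  (m + t(m)) / 2
}

random_spd_tensor <- function(scale = 1e-3) {
  m <- matrix(rnorm(9), 3, 3)
  scale * (crossprod(m) / 3 + diag(3) * 0.1)
}

random_unit_vector <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# contraction A : B for symmetric 3x3 matrices
contract <- function(a, b) sum(a * b)

# small simulation settings used by fast unit tests (not the study scale)
small_config <- function(...) {
  args <- list(grid_dim = 20, n_directions = 30)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# a deterministic scheme for tensor-fit tests
test_scheme <- function(n_dir = 12, b = 1000, n_b0 = 1) {
  g <- lpfdti:::fibonacci_directions(n_dir)
  gradient_scheme(c(rep(0, n_b0), rep(b, n_dir)),
                  cbind(matrix(0, 3, n_b0), g))
}
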