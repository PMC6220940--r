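# Shared toy systems and lazily cached sampled series for the test suite.

CTX <- thermo_ctx()

# 2-axis Gaussian family: bilinear stiffness, positive on the unit square
quad2d_k <- function(l, k) {
  100 * (1 - l) * (1 - k) + 400 * l * (1 - k) +
    200 * (1 - l) * k + 800 * l * k
}
QUAD2D <- quad_system(quad2d_k, id = "quad2d")
QUAD_G <- function(l, k = 0) analytic_free_energy(QUAD2D, coupling_state(l, k), CTX)

# two harmonic wells (different stiffness and centre) for EDS tests;
# also realised as a single lambda-coupled system for path estimators
WELL_A <- quad_system(function(l, k) 100, id = "wellA")
WELL_B <- quad_system(function(l, k) 400, linear = function(l, k) 60,
                      id = "wellB")
WELLS_LAM <- quad_system(function(l, k) (1 - l) * 100 + l * 400,
                         linear = function(l, k) l * 60, id = "wellsAB")
WELLS_DG <- analytic_free_energy(WELL_B, coupling_state(0), CTX) -
  analytic_free_energy(WELL_A, coupling_state(0), CTX)

CLASH <- four_state_system()

# confined variant: a fixed neighbor particle models the crowding of a
# binding site; the full-strength clash pair for EDS failure behavior
CLASH_WALLED <- four_state_system(
  wall = perturbed_atom(C12_A = 7.5e-5, C12_B = 7.5e-5,
                        C6_A = 0.075, C6_B = 0.075,
                        coupling_axis = "none"))

.cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# 11-window series on the lambda edge (kap = 0) of the quadratic family,
# cross-evaluated at both neighbors and carrying 101 probe records
quad_edge_series <- function() cached("quad_edge", {
  lam <- seq(0, 1, length.out = 11)
  lapply(seq_along(lam), function(i) {
    nb <- lapply(unique(c(max(i - 1, 1), i, min(i + 1, 11))), function(j) {
      coupling_state(lam[j], 0)
    })
    metropolis_sample(QUAD2D, coupling_state(lam[i], 0),
                      sampler_config(3e4, seed = 400 + i, record_stride = 3),
                      neighbors = nb,
                      probe_lam = seq(0, 1, length.out = 101), ctx = CTX)
  })
})

WELL_ENDS <- list(pin(WELL_A, coupling_state(0)),
                  pin(WELL_B, coupling_state(0)))

# (E, s) tuned by a short automated search, then a production run
wells_eds_params <- function() cached("wells_eds_params", {
  current_params(run_search(WELL_ENDS, init = eds_params(0.002, 0),
                            n_rounds = 120L, steps_per_round = 1200L,
                            seed = 61, ctx = CTX))
})

wells_eds_series <- function() cached("wells_eds", {
  sample_eds_reference(WELL_ENDS, wells_eds_params(),
                       sampler_config(2e5, seed = 71, record_stride = 4),
                       ctx = CTX)
})

expect_within_sigma <- function(value, reference, sigma, n_sigma = 3) {
  expect_lt(abs(value - reference), n_sigma * sigma)
}
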