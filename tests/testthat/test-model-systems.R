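# Toy Hamiltonians: parameter interpolation, soft-core pairs, restraints,
# and the analytic / quadrature free-energy oracles.

test_that("parameter interpolation is linear in the square roots with exact endpoints", {
  a <- perturbed_atom(q_A = -0.1, q_B = 0.4, C12_A = 1, C12_B = 4,
                      C6_A = 0.3, C6_B = 1.2, coupling_axis = "lam")
  p0 <- interpolate_parameters(a, 0)
  expect_identical(c(p0$q, p0$C12, p0$C6), c(-0.1, 1, 0.3))
  p1 <- interpolate_parameters(a, 1)
  expect_identical(c(p1$q, p1$C12, p1$C6), c(0.4, 4, 1.2))

  b <- perturbed_atom(q_A = 0, q_B = 0.4, C12_A = 1, C12_B = 4)
  ph <- interpolate_parameters(b, 0.5)
  expect_equal(ph$q, 0.2)
  expect_equal(ph$C12, (0.5 * 1 + 0.5 * 2)^2) # 2.25

  expect_error(interpolate_parameters(a, 1.2), "\\[0, 1\\]")
  expect_error(perturbed_atom(C12_A = -1), ">= 0")
})

test_that("harmonic restraint energies match the closed form", {
  expect_equal(restraint_energy(0.1, restraint_params(500, 0, 0)), 2.5)
  expect_equal(restraint_energy(0.2, restraint_params(150, 0, 0)), 3.0)
  expect_equal(restraint_energy(0.35, restraint_params(500, 0, 0.35)), 0)
  # vectorised over configurations, 2D anchor
  e <- restraint_energy(rbind(c(0.3, 0.4), c(0, 0)),
                        restraint_params(100, c(0, 0), 0))
  expect_equal(e, c(0.5 * 100 * 0.25, 0))
})

test_that("unperturbed pairs are plain LJ + Coulomb with zero coupling derivatives", {
  fixed <- perturbed_atom(q_A = 0.3, q_B = 0.3, C12_A = 2e-5, C12_B = 2e-5,
                          C6_A = 0.02, C6_B = 0.02, coupling_axis = "none")
  other <- perturbed_atom(q_A = -0.2, q_B = -0.2, C12_A = 1e-5, C12_B = 1e-5,
                          C6_A = 0.01, C6_B = 0.01, coupling_axis = "none")
  r <- c(0.25, 0.4, 0.8)
  out <- softcore_pair_energy(r, fixed, other, coupling_state(0.37, 0.81))
  C12 <- sqrt(2e-5 * 1e-5); C6 <- sqrt(0.02 * 0.01)
  plain <- C12 / r^12 - C6 / r^6 + 138.935458 * 0.3 * (-0.2) / r
  expect_equal(out$energy, plain, tolerance = 1e-12)
  expect_identical(out$dlam, rep(0, 3))
  expect_identical(out$dkap, rep(0, 3))
})

test_that("soft-core pair energy decays to zero at large separation", {
  g <- perturbed_atom(C12_B = 7.5e-5, C6_B = 0.075, coupling_axis = "lam")
  w <- perturbed_atom(C12_B = 7.5e-5, C6_B = 0.075, coupling_axis = "kap")
  r <- seq(1, 6.5, by = 0.5)
  e <- softcore_pair_energy(r, g, w, coupling_state(0.8, 0.9))$energy
  expect_true(all(diff(abs(e)) < 0)) # |energy| monotone down
  expect_lt(abs(e[length(e)]), 1e-6)
  expect_error(softcore_pair_energy(0, g, w, coupling_state(0.5, 0.5)),
               "r must be > 0")
})

test_that("soft-core keeps the energy finite at contact for interior states", {
  g <- perturbed_atom(C12_B = 7.5e-5, C6_B = 0.075, coupling_axis = "lam")
  w <- perturbed_atom(C12_B = 7.5e-5, C6_B = 0.075, coupling_axis = "kap")
  e <- softcore_pair_energy(1e-10, g, w, coupling_state(0.5, 0.5),
                            softcore_params(0.5, 0.5))
  expect_true(is.finite(e$energy))
  # the r -> 0 limit equals C12/a^2 - C6/a with a the softened denominator
  a <- 0.5 * (0.5^2 + 0.5^2) * 1e-3
  C12 <- 0.25 * 7.5e-5; C6 <- 0.25 * 0.075
  expect_equal(e$energy, C12 / a^2 - C6 / a, tolerance = 1e-6)
  # at a physical end state the contact energy grows without the soft core
  e11 <- softcore_pair_energy(1e-3, g, w, coupling_state(1, 1))
  expect_gt(e11$energy, 1e20)
})

test_that("coupling derivatives of the soft-core pair match central finite differences", {
  set.seed(42)
  g <- perturbed_atom(q_A = 0, q_B = 0.25, C12_B = 7.5e-5, C6_B = 0.075,
                      coupling_axis = "lam")
  w <- perturbed_atom(q_A = 0, q_B = -0.25, C12_B = 5e-5, C6_B = 0.05,
                      coupling_axis = "kap")
  h <- 1e-6
  for (i in 1:20) {
    r <- runif(1, 0.2, 0.9)
    l <- runif(1, 0.05, 0.95); k <- runif(1, 0.05, 0.95)
    e <- softcore_pair_energy(r, g, w, coupling_state(l, k))
    fd_l <- (softcore_pair_energy(r, g, w, coupling_state(l + h, k))$energy -
             softcore_pair_energy(r, g, w, coupling_state(l - h, k))$energy) /
      (2 * h)
    fd_k <- (softcore_pair_energy(r, g, w, coupling_state(l, k + h))$energy -
             softcore_pair_energy(r, g, w, coupling_state(l, k - h))$energy) /
      (2 * h)
    expect_equal(e$dlam, fd_l, tolerance = 1e-5)
    expect_equal(e$dkap, fd_k, tolerance = 1e-5)
  }
  # fully decoupled partner: zero energy, and the endpoint derivative is
  # the interior limit (matches a one-sided difference)
  e0 <- softcore_pair_energy(0.4, g, w, coupling_state(0, 0.5))
  expect_equal(e0$energy, 0)
  fd <- (softcore_pair_energy(0.4, g, w, coupling_state(h, 0.5))$energy -
           softcore_pair_energy(0.4, g, w, coupling_state(0, 0.5))$energy) / h
  expect_equal(e0$dlam, fd, tolerance = 1e-4)
  # an atom that is a dummy in both end states: zero energy and exact
  # agreement with the central difference at interior couplings
  ghost <- perturbed_atom(coupling_axis = "lam")
  eg <- softcore_pair_energy(0.4, ghost, w, coupling_state(0.5, 0.5))
  fdg <- (softcore_pair_energy(0.4, ghost, w, coupling_state(0.5 + h, 0.5))$energy -
            softcore_pair_energy(0.4, ghost, w, coupling_state(0.5 - h, 0.5))$energy) /
    (2 * h)
  expect_equal(eg$energy, 0)
  expect_equal(eg$dlam, fdg, tolerance = 1e-6)
})

test_that("single perturbed partner reverts to the one-axis soft-core expression", {
  pert <- perturbed_atom(C12_A = 0, C12_B = 7.5e-5, C6_A = 0, C6_B = 0.075,
                         coupling_axis = "lam")
  fixed <- perturbed_atom(C12_A = 2e-5, C12_B = 2e-5, C6_A = 0.02,
                          C6_B = 0.02, coupling_axis = "none")
  sc <- softcore_params(0.5, 0.5)
  for (l in c(0.2, 0.5, 0.9)) {
    for (r in c(0.1, 0.3, 0.6)) {
      got <- softcore_pair_energy(r, pert, fixed, coupling_state(l, 0), sc)
      # independent single-axis construction: interpolated pair parameters,
      # softening alpha * delta^2 * C12/C6 with delta the decoupling extent
      C12 <- (l * sqrt(7.5e-5)) * sqrt(2e-5)
      C6 <- (l * sqrt(0.075)) * sqrt(0.02)
      delta <- 1 - l # state A of the perturbed atom is the dummy
      u <- r^6 + 0.5 * delta^2 * C12 / C6
      expect_equal(got$energy, C12 / u^2 - C6 / u, tolerance = 1e-12)
    }
  }
})

test_that("system energies and derivatives are consistent (FD oracle, 50 draws)", {
  set.seed(7)
  h <- 1e-6
  for (i in 1:50) {
    sys <- if (i %% 2) QUAD2D else CLASH
    x <- if (i %% 2) runif(1, -0.4, 0.4) else runif(1, -0.8, 0.9)
    l <- runif(1, h, 1 - h); k <- runif(1, h, 1 - h)
    e <- system_energy(sys, x, coupling_state(l, k))
    fd_l <- (system_energy(sys, x, coupling_state(l + h, k), corners = FALSE)$H -
             system_energy(sys, x, coupling_state(l - h, k), corners = FALSE)$H) /
      (2 * h)
    fd_k <- (system_energy(sys, x, coupling_state(l, k + h), corners = FALSE)$H -
             system_energy(sys, x, coupling_state(l, k - h), corners = FALSE)$H) /
      (2 * h)
    expect_equal(e$dHdlam, fd_l, tolerance = 1e-5 * max(1, abs(fd_l)))
    expect_equal(e$dHdkap, fd_k, tolerance = 1e-5 * max(1, abs(fd_k)))
  }
})

test_that("state-independent quadratic systems have vanishing coupling derivatives", {
  sys <- quad_system(function(l, k) 250)
  e <- system_energy(sys, c(-0.3, 0.1, 0.6), coupling_state(0.4, 0.7))
  expect_identical(e$dHdlam, rep(0, 3))
  expect_identical(e$dHdkap, rep(0, 3))
})

test_that("the decoupled corner of the four-state toy is restraint + background only", {
  x <- c(-0.5, 0.05, 0.4)
  e <- system_energy(CLASH, x, coupling_state(0, 0), corners = FALSE)
  expect_equal(e$H, restraint_energy(x, CLASH$restraint) +
                 0.5 * CLASH$background_k * x^2)
  expect_error(system_energy(CLASH, cbind(x, x), coupling_state(0, 0)),
               "dimensionality")
})

test_that("analytic Gaussian free energies match closed forms and quadrature", {
  flat <- quad_system(function(l, k) 150)
  expect_equal(analytic_free_energy(flat, coupling_state(1, 1), CTX),
               analytic_free_energy(flat, coupling_state(0, 0), CTX))
  k14 <- quad_system(function(l, k) (1 - l) * 100 + l * 400)
  dG <- analytic_free_energy(k14, coupling_state(1), CTX) -
    analytic_free_energy(k14, coupling_state(0), CTX)
  expect_equal(dG, 0.5 * CTX$kBT * log(4), tolerance = 1e-12)

  # coupled 2D family against deterministic quadrature
  for (states in list(c(1, 0), c(0, 1), c(1, 1))) {
    st <- coupling_state(states[1], states[2])
    dq <- quadrature_free_energy(QUAD2D, st, c(-1.5, 1.5), CTX) -
      quadrature_free_energy(QUAD2D, coupling_state(0, 0), c(-1.5, 1.5), CTX)
    da <- QUAD_G(states[1], states[2]) - QUAD_G(0, 0)
    expect_equal(dq, da, tolerance = 1e-6)
  }
  expect_error(quad_system(function(l, k) -5), "positive definite")
})

test_that("quadrature oracle: decoupled corners, confinement, clash signature", {
  # grower with zero B-state parameters: lambda axis does nothing
  nog <- four_state_system(grower = perturbed_atom(coupling_axis = "lam"))
  g00 <- quadrature_free_energy(nog, coupling_state(0, 0), ctx = CTX)
  g10 <- quadrature_free_energy(nog, coupling_state(1, 0), ctx = CTX)
  expect_equal(g10 - g00, 0, tolerance = 1e-9)

  # corner free energies are a state function: diagonal equals either path
  G <- vapply(corner_states(), function(s) {
    quadrature_free_energy(CLASH, s, c(-1.5, 1.5), CTX)
  }, 0)
  expect_equal((G[["11"]] - G[["00"]]),
               (G[["10"]] - G[["00"]]) + (G[["11"]] - G[["10"]]),
               tolerance = 1e-6)

  # doubling the integration box leaves differences untouched (confinement)
  d1 <- quadrature_free_energy(CLASH, coupling_state(1, 1), c(-1.5, 1.5), CTX) -
    quadrature_free_energy(CLASH, coupling_state(0, 0), c(-1.5, 1.5), CTX)
  d2 <- quadrature_free_energy(CLASH, coupling_state(1, 1), c(-3, 3), CTX) -
    quadrature_free_energy(CLASH, coupling_state(0, 0), c(-3, 3), CTX)
  expect_lt(abs(d2 - d1), 1e-8)

  # steric clash at full coupling: the water is pushed off its target ...
  efun <- energy_fun(CLASH, coupling_state(1, 1))
  xg <- seq(-1.5, 1.5, length.out = 4001)
  E <- vapply(xg, efun, 0)
  xmin <- xg[which.min(E)]
  expect_gt(abs(xmin), CLASH$restraint$target_distance + 0.2)
  # ... and essentially never penetrates the LJ contact distance
  sigma <- (7.5e-5 / 0.075)^(1 / 6)
  w <- exp(-(E - min(E)) / CTX$kBT); w[!is.finite(E)] <- 0
  expect_lt(sum(w[abs(xg) < sigma]) / sum(w), 0.05)

  expect_error(quadrature_free_energy(quad_system(function(l, k) diag(4),
                                                  d = 4),
                                      coupling_state(0)),
               "dimensionality <= 3")
})
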