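# Free-energy estimators against closed forms, each other, and the
# analytic Gaussian oracle.

test_that("the Fermi weight obeys its closed forms and symmetry", {
  expect_equal(fermi_weight(0, CTX), 0.5)
  expect_equal(fermi_weight(CTX$kBT * log(3), CTX), 0.25)
  x <- c(-500, -3.2, 0.1, 7, 900)
  expect_equal(fermi_weight(x, CTX) + fermi_weight(-x, CTX), rep(1, 5))
  expect_true(all(is.finite(fermi_weight(c(-1e4, 1e4), CTX))))
})

test_that("BAR on two identical ensembles gives exactly zero", {
  flat <- quad_system(function(l, k) 200)
  mk <- function(seed) {
    metropolis_sample(flat, coupling_state(0),
                      sampler_config(4000, seed = seed),
                      neighbors = list(coupling_state(0), coupling_state(1)),
                      ctx = CTX)
  }
  lo <- mk(1); hi <- mk(2)
  hi$state <- coupling_state(1) # same Hamiltonian, relabelled state
  colnames(hi$neighbors$H) <- colnames(hi$neighbors$H)
  sol <- bar_pair(lo, hi, CTX)
  expect_equal(sol$delta_G, 0, tolerance = 1e-9)
  expect_equal(sol$C, 0, tolerance = 1e-9)
  expect_lt(abs(sol$residual), 1e-9)
})

test_that("the BAR residual is strictly monotone in the shift constant", {
  ser <- quad_edge_series()
  lo <- ser[[5]]; hi <- ser[[6]]
  w_f <- alchemr:::neighbor_H(lo, hi$state) - lo$frames$H
  w_r <- alchemr:::neighbor_H(hi, lo$state) - hi$frames$H
  Cs <- seq(-3, 3, length.out = 200)
  res <- vapply(Cs, function(C) {
    log(sum(fermi_weight(w_r + C, CTX))) -
      log(sum(fermi_weight(w_f - C, CTX)))
  }, 0)
  expect_true(all(diff(res) < 0))
})

test_that("BAR recovers the analytic Gaussian free energy and is antisymmetric", {
  ser <- quad_edge_series()
  est <- bar_path(ser, CTX)
  dG <- QUAD_G(1) - QUAD_G(0)
  expect_within_sigma(est$value, dG, est$error)
  # single interval reduces to bar_pair
  sol <- bar_pair(ser[[1]], ser[[2]], CTX)
  est1 <- bar_path(ser[1:2], CTX)
  expect_identical(est1$value, sol$delta_G)
  # reversing the path order flips the sign exactly
  rev_est <- bar_path(rev(ser), CTX)
  expect_equal(rev_est$value, -est$value, tolerance = 1e-12)
})

test_that("BAR refuses ensembles without energy overlap", {
  far <- quad_system(function(l, k) 1 + l * 1e6)
  mk <- function(lam, seed) {
    metropolis_sample(far, coupling_state(lam),
                      sampler_config(3000, seed = seed),
                      neighbors = list(coupling_state(0), coupling_state(1)),
                      ctx = CTX)
  }
  expect_error(bar_pair(mk(0, 1), mk(1, 2), CTX), "overlap")
})

test_that("TI integration: constants, linear exactness, trapezoid error law", {
  lam <- seq(0, 1, length.out = 7)
  expect_equal(ti_integrate(ti_profile(lam, rep(2.5, 7)))$value, 2.5)
  # linear integrand: trapezoid exact, result = mean of endpoint values
  expect_equal(ti_integrate(ti_profile(lam, 1 + 3 * lam))$value, 2.5,
               tolerance = 1e-12)
  # quadratic integrand d = 3 lam^2 (dG = 1): composite trapezoid error
  # is exactly (h^2 / 12) * (d'(1) - d'(0)) for constant curvature
  for (n in c(10L, 101L)) {
    g <- seq(0, 1, length.out = n)
    est <- ti_integrate(ti_profile(g, 3 * g^2))
    h <- 1 / (n - 1)
    expect_equal(est$value - 1, h^2 / 12 * 6, tolerance = 1e-10)
  }
  expect_error(ti_integrate(ti_profile(c(0, 0.4, 0.9), rep(1, 3))),
               "span the full interval")
  expect_error(ti_profile(c(0, 0.5, 0.5, 1), rep(1, 4)), "ascending")
  # interval weights: half-distances, summing to the grid span
  w <- ti_profile(c(0, 0.1, 0.4, 1), rep(0, 4))$weight
  expect_equal(w, c(0.05, 0.2, 0.45, 0.3))
  expect_equal(sum(w), 1)
})

test_that("X-TI reproduces direct TI bit-for-bit at simulated points", {
  ser <- quad_edge_series()
  xp <- xti_profile(ser[c(1, 3, 6, 9, 11)], CTX, seed = 5)
  for (k in c(1, 3, 6, 9, 11)) {
    p <- which(abs(xp$lam - ser[[k]]$state$lam) < 1e-12)
    expect_identical(xp$mean[p], mean(ser[[k]]$frames$dHdlam))
  }
})

test_that("X-TI from 5 windows matches the 11-window profile and the analytic value", {
  ser <- quad_edge_series()
  xp <- xti_profile(ser[c(1, 3, 6, 9, 11)], CTX, seed = 5)
  direct <- ti_profile_from_series(ser)
  for (i in seq_len(nrow(direct))) {
    p <- which(abs(xp$lam - direct$lam[i]) < 1e-12)
    se <- sqrt(xp$error[p]^2 + direct$error[i]^2)
    expect_within_sigma(xp$mean[p], direct$mean[i], se)
  }
  est <- ti_integrate(xp, "XTI")
  expect_within_sigma(est$value, QUAD_G(1) - QUAD_G(0), est$error)
})

test_that("the EDS reference energy obeys its algebraic limits", {
  expect_equal(eds_reference_energy(5.5, eds_params(0.7, 2), CTX), 3.5)
  expect_equal(eds_reference_energy(c(4, 4), eds_params(1, 0), CTX),
               4 - CTX$kBT * log(2))
  set.seed(31)
  for (i in 1:20) {
    h <- runif(2, -20, 20)
    h[2] <- h[1] + 10 * CTX$kBT # states separated by 10 kBT
    big <- eds_reference_energy(h, eds_params(1000, 0), CTX)
    expect_equal(big, min(h), tolerance = 1e-2)
  }
})

test_that("EDS recovers the two-well free-energy difference and agrees with BAR", {
  ser <- wells_eds_series()
  est <- eds_free_energy(ser, CTX)
  expect_length(est$warnings, 0)
  expect_within_sigma(est$value, WELLS_DG, est$error)
  # identical end states: exactly zero
  same <- ser
  same$ends$H[, 2] <- same$ends$H[, 1]
  same$frames$H_B <- same$frames$H_A
  same$frames$dV_BA <- 0 * same$frames$dV_BA
  expect_equal(eds_free_energy(same, CTX)$value, 0)
  # cross-estimator agreement with a BAR path over 11 windows
  lam <- seq(0, 1, length.out = 11)
  bser <- lapply(seq_along(lam), function(i) {
    nb <- lapply(lam[unique(c(max(i - 1, 1), min(i + 1, 11)))],
                 coupling_state)
    metropolis_sample(WELLS_LAM, coupling_state(lam[i]),
                      sampler_config(2e4, seed = 500 + i), neighbors = nb,
                      ctx = CTX)
  })
  bar <- bar_path(bser, CTX)
  expect_within_sigma(est$value, bar$value,
                      sqrt(est$error^2 + bar$error^2))
  # antisymmetry under swapping the enveloped end states
  swapped <- ser
  swapped$ends$H <- ser$ends$H[, 2:1]
  swapped$frames$H_A <- ser$frames$H_B
  swapped$frames$H_B <- ser$frames$H_A
  swapped$frames$dV_BA <- -ser$frames$dV_BA
  expect_equal(eds_free_energy(swapped, CTX)$value, -est$value,
               tolerance = 1e-12)
})

test_that("EDS attaches an overlap warning when one end state is unsupported", {
  clash_ends <- list(pin(CLASH, coupling_state(0, 0)),
                     pin(CLASH, coupling_state(1, 1)))
  # a sharp envelope started in the decoupled well never reaches the
  # clashed well: the reweight to that end state collapses onto a handful
  # of frames
  ser <- sample_eds_reference(clash_ends, eds_params(1, -15),
                              sampler_config(1e4, seed = 9), ctx = CTX)
  est <- eds_free_energy(ser, CTX)
  expect_gt(length(est$warnings), 0)
})

test_that("EDS-TI: degenerate envelopes reduce to plain TI and legs sum correctly", {
  # identical end states: reweighting weights are constant
  sysA <- quad_system(function(l, k) (1 - l) * 100 + l * 400)
  eser <- lapply(seq(0, 1, 0.25), function(l) {
    sample_eds_reference(list(pin(sysA, coupling_state(l)),
                              pin(sysA, coupling_state(l))),
                         eds_params(1, 0), sampler_config(5000, seed = 800),
                         state = coupling_state(l), ctx = CTX)
  })
  pA <- edsti_end_state_profile(eser, "A", CTX)
  ref <- ti_profile_from_series(eser)
  expect_equal(pA$mean, ref$mean, tolerance = 1e-12)
  # sign convention of the three-leg sum
  est <- edsti_cycle_sum(fe_estimate(2, 0.1, "EDS"),
                         fe_estimate(5, 0.2, "TI"),
                         fe_estimate(3, 0.2, "EDS"))
  expect_equal(est$value, 6)
  expect_equal(est$error, sqrt(0.01 + 0.04 + 0.04))
  expect_error(edsti_cycle_sum(NULL, fe_estimate(1, 0, "TI"),
                               fe_estimate(1, 0, "EDS")), "three legs")
})

test_that("EDS-TI recovers the analytic diagonal of the coupled Gaussian family", {
  lam <- seq(0, 1, length.out = 9)
  eser <- lapply(lam, function(l) {
    sample_eds_reference(list(pin(QUAD2D, coupling_state(l, 0)),
                              pin(QUAD2D, coupling_state(l, 1))),
                         eds_params(1, 0),
                         sampler_config(3e4, seed = 900 + round(100 * l),
                                        record_stride = 3),
                         state = coupling_state(l, 0), ctx = CTX)
  })
  # end-state profiles bracket their analytic TI integrals
  tiA <- ti_integrate(edsti_end_state_profile(eser, "A", CTX), "EDSTI")
  expect_within_sigma(tiA$value, QUAD_G(1, 0) - QUAD_G(0, 0), tiA$error)
  tiB <- ti_integrate(edsti_end_state_profile(eser, "B", CTX), "EDSTI")
  expect_within_sigma(tiB$value, QUAD_G(1, 1) - QUAD_G(0, 1), tiB$error)
  # full three-leg diagonal
  ref <- ti_integrate(ti_profile_from_series(eser), "TI")
  diag <- edsti_cycle_sum(eds_leg(eser[[1]], "A", CTX), ref,
                          eds_leg(eser[[9]], "B", CTX))
  expect_within_sigma(diag$value, QUAD_G(1, 1) - QUAD_G(0, 0), diag$error)
})

test_that("2D-TI landscapes: exact fills, corner cycle closure, oracle agreement", {
  # all derivatives zero: flat landscape
  g <- expand.grid(lam = seq(0, 1, 0.25), kap = seq(0, 1, 0.25))
  g$dHdlam <- 0; g$dHdkap <- 0
  ls0 <- landscape_2d(g, CTX)
  expect_true(all(ls0$G == 0))
  # separable derivatives linear in their own variable: trapezoid-exact
  g$dHdlam <- 1 + 2 * g$lam
  g$dHdkap <- -0.5 + g$kap
  ls1 <- landscape_2d(g, CTX)
  cd <- ls1$corner_differences
  expect_equal(cd$dG[cd$from == "00" & cd$to == "10"], 2, tolerance = 1e-9)
  expect_equal(cd$dG[cd$from == "00" & cd$to == "01"], 0, tolerance = 1e-9)
  expect_equal(cd$dG[cd$from == "00" & cd$to == "11"], 2, tolerance = 1e-9)
  # the 4-corner cycle closes identically by construction
  closure <- cd$dG[cd$from == "00" & cd$to == "10"] +
    cd$dG[cd$from == "10" & cd$to == "11"] -
    cd$dG[cd$from == "01" & cd$to == "11"] -
    cd$dG[cd$from == "00" & cd$to == "01"]
  expect_equal(closure, 0, tolerance = 1e-12)
  expect_error(landscape_2d(g[-3, ], CTX), "incomplete")
})

test_that("2D-TI reproduces the analytic corner differences of the coupled family", {
  grid <- seq(0, 1, length.out = 7)
  i <- 0
  gser <- vector("list", 49)
  for (kk in grid) for (ll in grid) {
    i <- i + 1
    gser[[i]] <- metropolis_sample(QUAD2D, coupling_state(ll, kk),
                                   sampler_config(1.2e4, seed = 2000 + i,
                                                  record_stride = 3),
                                   ctx = CTX)
  }
  ls2 <- landscape_2d(landscape_grid_from_series(gser), CTX)
  cd <- ls2$corner_differences
  ana <- c(QUAD_G(1, 0) - QUAD_G(0, 0), QUAD_G(0, 1) - QUAD_G(0, 0),
           QUAD_G(1, 1) - QUAD_G(0, 0), QUAD_G(0, 1) - QUAD_G(1, 0),
           QUAD_G(1, 1) - QUAD_G(1, 0), QUAD_G(1, 1) - QUAD_G(0, 1))
  for (r in seq_len(6)) {
    expect_within_sigma(cd$dG[r], ana[r], cd$error[r])
  }
  # path independence: corner dG matches 1D TI along the kap = 0 edge
  edge <- ti_integrate(ti_profile_from_series(gser[seq_along(grid)]))
  expect_within_sigma(cd$dG[1], edge$value,
                      sqrt(cd$error[1]^2 + edge$error^2))
})
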