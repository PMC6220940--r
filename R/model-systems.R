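# Toy model systems: lambda/kappa-coupled Hamiltonians with exact oracles.
#
# Units: energies kJ mol-1, lengths nm, charges e, temperatures K.
# All Hamiltonians are configurational only: the estimators implemented in
# this package consume ensemble averages in which kinetic terms cancel.

COULOMB_CONST <- 138.935458 # kJ mol-1 nm e-2

#' Perturbed-atom interaction parameters
#'
#' Nonbonded parameters of one atom in its two alchemical end states.
#' Pair parameters are formed by geometric combination of the square
#' roots, and the coupling variable interpolates the square roots of the
#' Lennard-Jones coefficients (and the charge linearly), so that the pair
#' interaction changes smoothly between the end states.
#'
#' @param q_A,q_B Partial charge (e) in end state A / B.
#' @param C12_A,C12_B Repulsive LJ coefficient (kJ mol-1 nm^12).
#' @param C6_A,C6_B Dispersive LJ coefficient (kJ mol-1 nm^6).
#' @param coupling_axis Which coupling variable drives this atom:
#'   `"lam"`, `"kap"`, or `"none"` for an unperturbed atom.
#' @return An object of class `perturbed_atom`.
#' @export
perturbed_atom <- function(q_A = 0, q_B = 0, C12_A = 0, C12_B = 0,
                           C6_A = 0, C6_B = 0,
                           coupling_axis = c("none", "lam", "kap")) {
  coupling_axis <- match.arg(coupling_axis)
  vals <- c(C12_A, C12_B, C6_A, C6_B)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("C12 and C6 must be finite and >= 0 in both end states")
  }
  structure(list(q_A = q_A, q_B = q_B, C12_A = C12_A, C12_B = C12_B,
                 C6_A = C6_A, C6_B = C6_B, coupling_axis = coupling_axis),
            class = "perturbed_atom")
}

#' Soft-core parameters
#'
#' @param alpha_lj Dimensionless soft-core strength for the Lennard-Jones
#'   term (default 0.5).
#' @param alpha_crf Soft-core strength for the electrostatic term, in nm^2
#'   (default 0.5).
#' @return An object of class `softcore_params`.
#' @export
softcore_params <- function(alpha_lj = 0.5, alpha_crf = 0.5) {
  if (alpha_lj < 0 || alpha_crf < 0) stop("soft-core parameters must be >= 0")
  structure(list(alpha_lj = alpha_lj, alpha_crf = alpha_crf),
            class = "softcore_params")
}

#' Harmonic distance-restraint parameters
#'
#' @param force_constant Force constant in kJ mol-1 nm-2.
#' @param anchor Anchor position (nm), a numeric vector of the particle's
#'   dimensionality.
#' @param target_distance Rest length of the restraint in nm; 0 pulls the
#'   particle directly onto the anchor.
#' @return An object of class `restraint_params`.
#' @export
restraint_params <- function(force_constant = 500, anchor = 0,
                             target_distance = 0) {
  if (force_constant < 0) stop("force_constant must be >= 0")
  structure(list(force_constant = force_constant, anchor = anchor,
                 target_distance = target_distance),
            class = "restraint_params")
}

#' Interpolate atomic interaction parameters along a coupling variable
#'
#' The charge is interpolated linearly; for the Lennard-Jones coefficients
#' the *square roots* are interpolated linearly and the returned values are
#' the squares of the interpolated roots, which under geometric combination
#' rules makes every pair coefficient change smoothly with the coupling.
#'
#' @param atom A [perturbed_atom()].
#' @param c Coupling value in `[0, 1]`.
#' @return A list with elements `q`, `C12`, `C6`.
#' @examples
#' a <- perturbed_atom(q_A = 0, q_B = 0.4, C12_A = 1, C12_B = 4)
#' interpolate_parameters(a, 0.5) # q = 0.2, C12 = 2.25
#' @export
interpolate_parameters <- function(atom, c) {
  if (!is.numeric(c) || length(c) != 1L || is.na(c) || c < 0 || c > 1) {
    stop("coupling value c must lie in [0, 1]")
  }
  if (c == 0) {
    return(list(q = atom$q_A, C12 = atom$C12_A, C6 = atom$C6_A))
  }
  if (c == 1) {
    return(list(q = atom$q_B, C12 = atom$C12_B, C6 = atom$C6_B))
  }
  s12 <- (1 - c) * sqrt(atom$C12_A) + c * sqrt(atom$C12_B)
  s6 <- (1 - c) * sqrt(atom$C6_A) + c * sqrt(atom$C6_B)
  list(q = (1 - c) * atom$q_A + c * atom$q_B, C12 = s12^2, C6 = s6^2)
}

# Full interpolation record including square roots, derivatives with
# respect to the atom's own coupling variable, and the decoupling extent
# delta used for the soft-core magnitude.  The decoupling extent tracks
# how "dummy-like" the atom currently is: it interpolates an indicator
# that is 1 at a fully noninteracting end state and 0 at an interacting
# one, so the softening vanishes exactly at physical end states.
atom_coupling <- function(atom, state) {
  c <- switch(atom$coupling_axis,
              lam = state$lam, kap = state$kap, none = 0)
  s12A <- sqrt(atom$C12_A); s12B <- sqrt(atom$C12_B)
  s6A <- sqrt(atom$C6_A); s6B <- sqrt(atom$C6_B)
  dumA <- as.numeric(atom$q_A == 0 && atom$C12_A == 0 && atom$C6_A == 0)
  dumB <- as.numeric(atom$q_B == 0 && atom$C12_B == 0 && atom$C6_B == 0)
  s12 <- (1 - c) * s12A + c * s12B
  s6 <- (1 - c) * s6A + c * s6B
  ds12 <- s12B - s12A
  ds6 <- s6B - s6A
  # per-atom sigma ratio entering C126 = C12/C6 of the pair; at a dummy
  # end the 0/0 is resolved by its interior limit so that the soft-core
  # denominator (and the TI endpoint derivative) stay continuous
  if (s6 > 0) {
    rho <- s12 / s6
    drho <- (ds12 * s6 - s12 * ds6) / s6^2
  } else if (ds6 != 0) {
    rho <- ds12 / ds6
    drho <- 0
  } else {
    rho <- 0
    drho <- 0
  }
  list(axis = atom$coupling_axis,
       q = (1 - c) * atom$q_A + c * atom$q_B,
       dq = atom$q_B - atom$q_A,
       s12 = s12, ds12 = ds12, s6 = s6, ds6 = ds6, rho = rho, drho = drho,
       delta = (1 - c) * dumA + c * dumB, ddelta = dumB - dumA)
}

#' Soft-core pair interaction between two (possibly perturbed) atoms
#'
#' Beutler-style soft-core Lennard-Jones plus Coulomb interaction for a
#' pair of atoms whose parameters are interpolated along their own
#' coupling axes (see [interpolate_parameters()]).  The Lennard-Jones
#' denominator is `r^6 + alpha_lj * Lambda^2 * C126` with
#' `C126 = C12/C6` of the interpolated pair (0 when `C6 = 0`), and the
#' electrostatic denominator is `sqrt(r^2 + alpha_crf * Lambda^2)`.
#' `Lambda` is the product of each perturbed partner's decoupling extent
#' on its own axis, so the softening vanishes at every physical end state
#' and reverts to the familiar single-axis soft-core expression when only
#' one partner is perturbed.  Unperturbed pairs are plain LJ + Coulomb.
#'
#' @param r Interatomic distance(s) in nm, all > 0.
#' @param i,j [perturbed_atom()] objects.
#' @param state A [coupling_state()].
#' @param sc [softcore_params()].
#' @param ctx A [thermo_ctx()] (kept for interface symmetry; the pair
#'   energy itself is temperature independent).
#' @return A list with vectors `energy`, `dlam`, `dkap` (kJ mol-1; the
#'   derivatives are with respect to the coupling variables).
#' @export
softcore_pair_energy <- function(r, i, j, state, sc = softcore_params(),
                                 ctx = thermo_ctx()) {
  if (any(r <= 0)) stop("pair distance r must be > 0")
  sc_pair_core(r, i, j, state, sc)
}

# Internal work-horse; tolerates r == 0 by returning +Inf energy so that
# Boltzmann factors vanish cleanly inside quadrature and sampling.
sc_pair_core <- function(r, i, j, state, sc) {
  ai <- atom_coupling(i, state)
  aj <- atom_coupling(j, state)
  pert_i <- ai$axis != "none"
  pert_j <- aj$axis != "none"

  C12 <- ai$s12 * aj$s12
  C6 <- ai$s6 * aj$s6
  qq <- ai$q * aj$q
  C126 <- ai$rho * aj$rho

  # softening magnitude: sum of the squared decoupling extents of the
  # perturbed partners, so a pair is softened whenever either partner is
  # partially decoupled and reverts to plain LJ at physical end states
  Lam2 <- (if (pert_i) ai$delta^2 else 0) + (if (pert_j) aj$delta^2 else 0)
  a_lj <- sc$alpha_lj * Lam2 * C126
  a_c <- sc$alpha_crf * Lam2

  r2 <- r * r
  r6 <- r2 * r2 * r2
  u <- r6 + a_lj
  inv_u <- ifelse(u > 0, 1 / u, Inf)
  e_lj <- C12 * inv_u^2 - C6 * inv_u
  e_lj[u <= 0 & (C12 > 0 | C6 > 0)] <- Inf
  if (C12 == 0 && C6 == 0) e_lj <- numeric(length(r))
  d_c <- sqrt(r2 + a_c)
  e_c <- if (qq != 0) COULOMB_CONST * qq / d_c else numeric(length(r)) * 0
  energy <- e_lj + e_c

  dlam <- numeric(length(r))
  dkap <- numeric(length(r))
  for (axis in c("lam", "kap")) {
    dtot <- numeric(length(r))
    any_axis <- FALSE
    for (who in c("i", "j")) {
      ap <- if (who == "i") ai else aj
      ao <- if (who == "i") aj else ai
      if (ap$axis != axis) next
      any_axis <- TRUE
      dC12 <- ap$ds12 * ao$s12
      dC6 <- ap$ds6 * ao$s6
      dqq <- ap$dq * ao$q
      dC126 <- ap$drho * ao$rho
      dLam2 <- 2 * ap$delta * ap$ddelta
      da_lj <- sc$alpha_lj * (dLam2 * C126 + Lam2 * dC126)
      da_c <- sc$alpha_crf * dLam2
      d_lj <- dC12 * inv_u^2 - dC6 * inv_u +
        (-2 * C12 * inv_u^3 + C6 * inv_u^2) * da_lj
      d_el <- if (qq != 0 || dqq != 0) {
        COULOMB_CONST * (dqq / d_c - qq * da_c / (2 * d_c^3))
      } else 0
      dtot <- dtot + d_lj + d_el
    }
    if (any_axis) {
      if (axis == "lam") dlam <- dtot else dkap <- dtot
    }
  }
  # Clean up non-finite derivative entries where the energy itself is +Inf
  bad <- !is.finite(energy)
  if (any(bad)) {
    dlam[bad] <- 0
    dkap[bad] <- 0
  }
  list(energy = energy, dlam = dlam, dkap = dkap)
}

#' Harmonic distance-restraint energy
#'
#' `0.5 * k * (|pos - anchor| - target)^2`, the simplified stand-in for
#' the spatial confinement of a binding site.
#'
#' @param pos_w Particle position (numeric vector, nm) or a matrix with
#'   one configuration per row.
#' @param params [restraint_params()].
#' @return Energy (kJ mol-1), one value per configuration.
#' @examples
#' restraint_energy(0.1, restraint_params(500, 0, 0)) # 2.5
#' @export
restraint_energy <- function(pos_w, params) {
  X <- if (is.matrix(pos_w)) pos_w else matrix(pos_w, ncol = length(params$anchor))
  dd <- sweep(X, 2, params$anchor)
  r <- sqrt(rowSums(dd * dd))
  0.5 * params$force_constant * (r - params$target_distance)^2
}

## ---------------------------------------------------------------------
## Quadratic (Gaussian) family: analytic free energies
## ---------------------------------------------------------------------

#' Quadratic (Gaussian) coupled system
#'
#' `H(x; lam, kap) = 0.5 * x' A(lam, kap) x - b(lam, kap) . x` with a
#' stiffness matrix that is positive definite on the whole unit square.
#' This family admits a closed-form free energy and serves as the exact
#' oracle for every estimator in the package.
#'
#' @param stiffness Function `(lam, kap) -> d x d` symmetric positive
#'   definite matrix (kJ mol-1 nm-2); may return a scalar for `d = 1`.
#' @param linear Optional function `(lam, kap) -> numeric(d)` for the
#'   linear term; defaults to zero.
#' @param d Dimensionality (inferred from `stiffness(0, 0)` if missing).
#' @param id Optional system identifier carried into series metadata.
#' @return An object of class `quad_system`.
#' @examples
#' sys <- quad_system(function(l, k) (1 - l) * 100 + l * 400)
#' @export
quad_system <- function(stiffness, linear = NULL, d = NULL, id = "quad") {
  A0 <- stiffness(0, 0)
  if (is.null(d)) d <- if (is.matrix(A0)) nrow(A0) else 1L
  if (is.null(linear)) linear <- function(lam, kap) numeric(d)
  sys <- structure(list(stiffness = stiffness, linear = linear,
                        d = as.integer(d), id = id),
                   class = c("quad_system", "fe_system"))
  quad_matrix(sys, coupling_state(0, 0)) # validates positive definiteness
  sys
}

quad_matrix <- function(sys, state) {
  A <- sys$stiffness(state$lam, state$kap)
  if (!is.matrix(A)) A <- matrix(A, sys$d, sys$d)
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    stop(sprintf("stiffness matrix not positive definite at state %s",
                 format(state)))
  }
  A
}

quad_terms <- function(sys, state) {
  list(A = quad_matrix(sys, state),
       b = as.numeric(sys$linear(state$lam, state$kap)))
}

# Entry-wise central difference of the stiffness/linear functions; exact
# to machine precision for the (bi)linear couplings used throughout.
quad_dterms <- function(sys, state, axis, h = 1e-6) {
  up <- function(v) min(v + h, 1); dn <- function(v) max(v - h, 0)
  if (axis == "lam") {
    l1 <- dn(state$lam); l2 <- up(state$lam); k1 <- k2 <- state$kap
  } else {
    k1 <- dn(state$kap); k2 <- up(state$kap); l1 <- l2 <- state$lam
  }
  span <- if (axis == "lam") l2 - l1 else k2 - k1
  Ad <- (as.matrix(sys$stiffness(l2, k2)) - as.matrix(sys$stiffness(l1, k1))) / span
  bd <- (as.numeric(sys$linear(l2, k2)) - as.numeric(sys$linear(l1, k1))) / span
  list(A = Ad, b = bd)
}

#' @export
system_dim <- function(system) UseMethod("system_dim")

#' @export
system_dim.quad_system <- function(system) system$d

#' Evaluate a model system's Hamiltonian and coupling derivatives
#'
#' Returns, for each configuration, the total energy `H`, the analytic
#' derivatives with respect to both coupling variables, and the energies
#' at the four corner states of the coupling square (needed by the
#' acceptance-ratio and enveloping-distribution estimators).
#'
#' @param system A model system (`quad_system` or `fourstate_system`).
#' @param coords Numeric vector (one configuration) or matrix with one
#'   configuration per row.
#' @param state A [coupling_state()].
#' @param corners Whether to also evaluate the four corner-state energies.
#' @return A list with `H`, `dHdlam`, `dHdkap`, and (if requested)
#'   `H_corners`, a matrix with columns `"00" "10" "01" "11"` (lam, kap).
#' @export
system_energy <- function(system, coords, state, corners = TRUE) {
  UseMethod("system_energy")
}

coords_matrix <- function(coords, d) {
  X <- if (is.matrix(coords)) coords else matrix(coords, ncol = d, byrow = FALSE)
  if (ncol(X) != d) {
    stop(sprintf("configuration dimensionality %d does not match system (%d)",
                 ncol(X), d))
  }
  if (any(!is.finite(X))) stop("configurations must be finite")
  X
}

quad_H <- function(sys, X, state) {
  tr <- quad_terms(sys, state)
  if (sys$d == 1L) {
    x <- X[, 1L]
    0.5 * tr$A[1L, 1L] * x * x - tr$b[1L] * x
  } else {
    0.5 * rowSums((X %*% tr$A) * X) - as.numeric(X %*% tr$b)
  }
}

#' @export
system_energy.quad_system <- function(system, coords, state, corners = TRUE) {
  X <- coords_matrix(coords, system$d)
  H <- quad_H(system, X, state)
  deriv <- lapply(c(lam = "lam", kap = "kap"), function(axis) {
    dtr <- quad_dterms(system, state, axis)
    if (system$d == 1L) {
      x <- X[, 1L]
      0.5 * dtr$A[1L, 1L] * x * x - dtr$b[1L] * x
    } else {
      0.5 * rowSums((X %*% dtr$A) * X) - as.numeric(X %*% dtr$b)
    }
  })
  out <- list(H = H, dHdlam = deriv$lam, dHdkap = deriv$kap)
  if (corners) {
    out$H_corners <- corner_energy_matrix(function(s) quad_H(system, X, s),
                                          nrow(X))
  }
  out
}

corner_states <- function() {
  list("00" = coupling_state(0, 0), "10" = coupling_state(1, 0),
       "01" = coupling_state(0, 1), "11" = coupling_state(1, 1))
}

corner_energy_matrix <- function(f, n) {
  cs <- corner_states()
  m <- vapply(cs, f, numeric(n))
  if (!is.matrix(m)) m <- matrix(m, nrow = 1L, dimnames = list(NULL, names(cs)))
  m
}

#' Fast scalar energy closure for Metropolis sampling
#'
#' @param system A model system.
#' @param state A [coupling_state()].
#' @return A function mapping a configuration vector to its energy.
#' @export
energy_fun <- function(system, state) UseMethod("energy_fun")

#' @export
energy_fun.quad_system <- function(system, state) {
  tr <- quad_terms(system, state)
  if (system$d == 1L) {
    a <- tr$A[1L, 1L]; b <- tr$b[1L]
    function(x) 0.5 * a * x * x - b * x
  } else {
    A <- tr$A; b <- tr$b
    function(x) 0.5 * sum(x * (A %*% x)) - sum(b * x)
  }
}

#' Closed-form free energy of a quadratic system
#'
#' `G(lam, kap) = (kBT/2) log det A - 0.5 * b' A^-1 b`, up to an additive
#' constant that is independent of the coupling state; differences between
#' two states of the same system are exact.
#'
#' @param system A [quad_system()].
#' @param state A [coupling_state()].
#' @param ctx A [thermo_ctx()].
#' @return Free energy in kJ mol-1 (state-dependent part).
#' @export
analytic_free_energy <- function(system, state, ctx = thermo_ctx()) {
  if (!inherits(system, "quad_system")) {
    stop("analytic_free_energy is defined for quad_system objects")
  }
  tr <- quad_terms(system, state)
  ld <- determinant(tr$A, logarithm = TRUE)
  0.5 * ctx$kBT * as.numeric(ld$modulus) -
    0.5 * sum(tr$b * solve(tr$A, tr$b))
}

## ---------------------------------------------------------------------
## Four-state restrained-water toy with a steric clash
## ---------------------------------------------------------------------

#' Four-state restrained-water toy system
#'
#' A one- or two-dimensional mobile "water" particle restrained to a
#' binding site at which a "grower" particle appears (coupled on lambda),
#' while the water's own interactions are coupled on kappa.  An optional
#' fixed, unperturbed "wall" particle gives the water a nontrivial
#' environment in every state.  At full coupling the grower's excluded
#' volume clashes with the restraint, reproducing the strained four-state
#' structure of a confined active-site water under a residue mutation.
#'
#' @param grower [perturbed_atom()] on axis `lam`; end state A must be the
#'   noninteracting dummy.
#' @param water [perturbed_atom()] on axis `kap`.
#' @param wall Optional unperturbed [perturbed_atom()] placed at
#'   `wall_position` (default `NULL`: no wall).  A wall breaks the
#'   spatial symmetry of the toy but introduces long-lived metastable
#'   basins; the default system keeps every state ergodically sampleable
#'   at modest chain lengths.
#' @param restraint [restraint_params()] pulling the water to the site.
#' @param softcore [softcore_params()].
#' @param site_position Position (nm) of the site / grower.
#' @param wall_position Position (nm) of the wall particle.
#' @param background_k Force constant of a fixed confining harmonic
#'   potential centred on the site (kJ mol-1 nm-2); 0 disables it.
#' @param d Dimensionality of the water coordinate (1 or 2).
#' @param id System identifier.
#' @return An object of class `fourstate_system`.
#' @export
four_state_system <- function(grower = perturbed_atom(C12_B = 7.5e-5,
                                                      C6_B = 0.075,
                                                      coupling_axis = "lam"),
                              water = perturbed_atom(C12_B = 7.5e-5,
                                                     C6_B = 0.075,
                                                     coupling_axis = "kap"),
                              wall = NULL,
                              restraint = restraint_params(500, NULL, 0),
                              softcore = softcore_params(0.5, 0.5),
                              site_position = 0,
                              wall_position = 0.45,
                              background_k = 25,
                              d = 1L, id = "fourstate") {
  d <- as.integer(d)
  if (!d %in% c(1L, 2L)) stop("water dimensionality d must be 1 or 2")
  site <- rep_len(site_position, d)
  wallp <- rep_len(wall_position, d)
  if (is.null(restraint$anchor)) restraint$anchor <- site
  if (grower$coupling_axis != "lam") stop("grower must couple on axis lam")
  if (water$coupling_axis != "kap") stop("water must couple on axis kap")
  structure(list(grower = grower, water = water, wall = wall,
                 restraint = restraint, softcore = softcore,
                 site = site, wallp = wallp, background_k = background_k,
                 d = d, id = id),
            class = c("fourstate_system", "fe_system"))
}

#' @export
system_dim.fourstate_system <- function(system) system$d

fourstate_r <- function(system, X, center) {
  dd <- sweep(X, 2, center)
  pmax(sqrt(rowSums(dd * dd)), 1e-12)
}

fourstate_terms <- function(system, X, state) {
  rg <- fourstate_r(system, X, system$site)
  gw <- sc_pair_core(rg, system$grower, system$water, state, system$softcore)
  H <- gw$energy
  dl <- gw$dlam
  dk <- gw$dkap
  if (!is.null(system$wall)) {
    rw <- fourstate_r(system, X, system$wallp)
    ww <- sc_pair_core(rw, system$water, system$wall, state, system$softcore)
    rgw <- sqrt(sum((system$site - system$wallp)^2))
    gwall <- sc_pair_core(rgw, system$grower, system$wall, state, system$softcore)
    H <- H + ww$energy + gwall$energy
    dl <- dl + ww$dlam + gwall$dlam
    dk <- dk + ww$dkap + gwall$dkap
  }
  H <- H + restraint_energy(X, system$restraint)
  if (system$background_k > 0) {
    dd <- sweep(X, 2, system$site)
    H <- H + 0.5 * system$background_k * rowSums(dd * dd)
  }
  list(H = H, dHdlam = dl, dHdkap = dk)
}

#' @export
system_energy.fourstate_system <- function(system, coords, state,
                                           corners = TRUE) {
  X <- coords_matrix(coords, system$d)
  out <- fourstate_terms(system, X, state)
  if (corners) {
    out$H_corners <- corner_energy_matrix(
      function(s) fourstate_terms(system, X, s)$H, nrow(X))
  }
  out
}

# Interpolated pair constants at a fixed state (for fast closures).
pair_consts <- function(i, j, state, sc) {
  ai <- atom_coupling(i, state)
  aj <- atom_coupling(j, state)
  pert_i <- ai$axis != "none"; pert_j <- aj$axis != "none"
  C12 <- ai$s12 * aj$s12
  C6 <- ai$s6 * aj$s6
  qq <- ai$q * aj$q
  C126 <- ai$rho * aj$rho
  Lam2 <- (if (pert_i) ai$delta^2 else 0) + (if (pert_j) aj$delta^2 else 0)
  list(C12 = C12, C6 = C6, qq = qq,
       a_lj = sc$alpha_lj * Lam2 * C126,
       a_c = sc$alpha_crf * Lam2)
}

#' @export
energy_fun.fourstate_system <- function(system, state) {
  gw <- pair_consts(system$grower, system$water, state, system$softcore)
  site <- system$site
  kres <- system$restraint$force_constant
  anc <- system$restraint$anchor
  tgt <- system$restraint$target_distance
  kbg <- system$background_k
  has_wall <- !is.null(system$wall)
  if (has_wall) {
    ww <- pair_consts(system$water, system$wall, state, system$softcore)
    wallp <- system$wallp
    rgw <- sqrt(sum((site - wallp)^2))
    const <- sc_pair_core(rgw, system$grower, system$wall, state,
                          system$softcore)$energy
  } else {
    const <- 0
  }
  kc <- COULOMB_CONST
  function(x) {
    dxs <- x - site
    r2s <- sum(dxs * dxs)
    r6 <- r2s * r2s * r2s
    u <- r6 + gw$a_lj
    e <- if (u > 0) gw$C12 / (u * u) - gw$C6 / u + const else {
      if (gw$C12 > 0 || gw$C6 > 0) return(Inf) else const
    }
    if (gw$qq != 0) e <- e + kc * gw$qq / sqrt(r2s + gw$a_c)
    if (has_wall) {
      dxw <- x - wallp
      r2w <- sum(dxw * dxw)
      r6w <- r2w * r2w * r2w
      uw <- r6w + ww$a_lj
      if (uw > 0) {
        e <- e + ww$C12 / (uw * uw) - ww$C6 / uw
      } else if (ww$C12 > 0 || ww$C6 > 0) {
        return(Inf)
      }
      if (ww$qq != 0) e <- e + kc * ww$qq / sqrt(r2w + ww$a_c)
    }
    da <- x - anc
    e + 0.5 * kres * (sqrt(sum(da * da)) - tgt)^2 + 0.5 * kbg * r2s
  }
}

#' Deterministic quadrature free energy of a low-dimensional toy system
#'
#' `-kBT log integral exp(-H/kBT)` over a box, computed by (nested)
#' adaptive quadrature.  For confined systems this is the gold reference
#' against which every statistical estimator is checked.  Supported for
#' total dimensionality up to 3.
#'
#' @param system Any model system with a vectorised energy.
#' @param state A [coupling_state()].
#' @param box Numeric `c(lo, hi)` applied to every coordinate, or a
#'   2-column matrix with one row per dimension.
#' @param ctx A [thermo_ctx()].
#' @param rel_tol Relative tolerance of each 1D quadrature.
#' @return Free energy in kJ mol-1 (additive constant shared between
#'   states of the same system).
#' @export
quadrature_free_energy <- function(system, state, box = c(-1.5, 1.5),
                                   ctx = thermo_ctx(), rel_tol = 1e-10) {
  d <- system_dim(system)
  if (d > 3L) stop("quadrature oracle supports dimensionality <= 3 only")
  if (!is.matrix(box)) box <- matrix(rep(box, each = d), nrow = d)
  evec <- function(X) system_energy(system, X, state, corners = FALSE)$H
  # Energy offset from a coarse scan keeps the Boltzmann integrand in range.
  grid <- lapply(seq_len(d), function(k) seq(box[k, 1], box[k, 2], length.out = 41))
  G <- as.matrix(expand.grid(grid))
  E0 <- min(evec(G))
  if (!is.finite(E0)) stop("energy not finite anywhere on the scan grid")
  beta <- 1 / ctx$kBT
  f1 <- function(x, fixed) {
    X <- cbind(x, matrix(rep(fixed, each = length(x)), nrow = length(x)))
    e <- evec(X[, seq_len(d), drop = FALSE])
    out <- exp(-beta * (e - E0))
    out[!is.finite(e)] <- 0
    out
  }
  int1 <- function(fixed) {
    stats::integrate(f1, box[1, 1], box[1, 2], fixed = fixed,
                     rel.tol = rel_tol, abs.tol = 0,
                     subdivisions = 400L)$value
  }
  Z <- if (d == 1L) {
    int1(numeric(0))
  } else if (d == 2L) {
    stats::integrate(function(y) vapply(y, function(yy) int1(yy), 0),
                     box[2, 1], box[2, 2], rel.tol = rel_tol * 10,
                     subdivisions = 200L)$value
  } else {
    stats::integrate(function(z) {
      vapply(z, function(zz) {
        stats::integrate(function(y) vapply(y, function(yy) int1(c(yy, zz)), 0),
                         box[2, 1], box[2, 2], rel.tol = rel_tol * 10,
                         subdivisions = 200L)$value
      }, 0)
    }, box[3, 1], box[3, 2], rel.tol = rel_tol * 100, subdivisions = 100L)$value
  }
  if (!is.finite(Z) || Z <= 0) stop("quadrature failed: divergent or zero integrand")
  E0 - ctx$kBT * log(Z)
}
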