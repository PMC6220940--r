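# Metropolis Monte Carlo sampling of model-system Hamiltonians.
#
# The sampler stands in for the molecular-dynamics production runs a
# practitioner would use: the estimators only consume configurational
# ensemble averages, and Metropolis MC delivers exact target distributions
# without thermostat artifacts.  Every recorded frame carries all
# observables needed downstream (end-state energies, coupling
# derivatives, neighbor-state energies, dense-grid probe derivatives),
# computed on the fly from the stored configurations.

#' Sampler configuration
#'
#' @param n_steps Total number of Monte Carlo steps.
#' @param step_size Initial displacement scale (nm); tuned during burn-in
#'   toward an acceptance rate of 0.3-0.5 and then frozen.
#' @param seed Integer seed; identical `(seed, config, system)` give
#'   bit-identical series.
#' @param record_stride Record every this-many moves (default 10).
#' @param burn_in Number of discarded equilibration steps (default 10% of
#'   `n_steps`).
#' @return An object of class `sampler_config`.
#' @export
sampler_config <- function(n_steps, step_size = 0.1, seed = 1L,
                           record_stride = 10L, burn_in = NULL) {
  if (is.null(burn_in)) burn_in <- floor(n_steps / 10)
  stopifnot(n_steps > burn_in, burn_in >= 0, step_size > 0,
            record_stride >= 1)
  structure(list(n_steps = as.integer(n_steps), step_size = step_size,
                 seed = as.integer(seed),
                 record_stride = as.integer(record_stride),
                 burn_in = as.integer(burn_in)),
            class = "sampler_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(code)
}

# Core random-walk Metropolis loop.  Proposals and uniforms are
# pregenerated; the step size adapts on 50-step windows during burn-in
# only, so detailed balance holds exactly throughout production.
mc_core <- function(efun, d, cfg, beta, x0) {
  n <- cfg$n_steps
  z <- matrix(stats::rnorm(n * d), n, d)
  lu <- log(stats::runif(n))
  step <- cfg$step_size
  x <- x0
  e <- efun(x)
  m <- (n - cfg$burn_in) %/% cfg$record_stride
  X <- matrix(NA_real_, m, d)
  rec <- 0L
  acc_win <- 0L
  acc_tot <- 0L
  acc_burn <- 0L
  for (i in seq_len(n)) {
    xn <- x + step * z[i, ]
    en <- efun(xn)
    if (is.finite(en) && (en <= e || lu[i] < -beta * (en - e))) {
      x <- xn
      e <- en
      acc_win <- acc_win + 1L
      acc_tot <- acc_tot + 1L
      if (i <= cfg$burn_in) acc_burn <- acc_burn + 1L
    }
    if (i <= cfg$burn_in) {
      if (i %% 50L == 0L) {
        r <- acc_win / 50
        if (r < 0.3) step <- step * 0.8 else if (r > 0.5) step <- step * 1.25
        acc_win <- 0L
      }
      if (i == cfg$burn_in && acc_burn == 0L && cfg$burn_in >= 50L) {
        stop("no accepted moves during burn-in; adjust step_size ",
             "(current ", signif(step, 3), " nm) or check the energy scale")
      }
    } else if ((i - cfg$burn_in) %% cfg$record_stride == 0L) {
      rec <- rec + 1L
      X[rec, ] <- x
    }
  }
  list(X = X[seq_len(rec), , drop = FALSE], step = step,
       acceptance = acc_tot / n)
}

default_start <- function(system) {
  if (inherits(system, "fourstate_system")) system$site + 0.1 else {
    numeric(system_dim(system))
  }
}

new_obs_series <- function(state, frames, neighbors = NULL, probes = NULL,
                           ends = NULL, metadata = list()) {
  stopifnot(nrow(frames) >= 1L)
  if (any(!is.finite(as.matrix(frames)))) {
    stop("recorded observables contain non-finite values")
  }
  if (all(c("H_A", "H_B", "dV_BA") %in% names(frames)) &&
      max(abs(frames$dV_BA - (frames$H_B - frames$H_A))) > 1e-9) {
    stop("dV_BA inconsistent with H_B - H_A")
  }
  structure(list(state = state, frames = frames, neighbors = neighbors,
                 probes = probes, ends = ends, metadata = metadata),
            class = "obs_series")
}

#' @export
print.obs_series <- function(x, ...) {
  cat(sprintf("<obs_series> %d frames at state %s, T = %g K\n",
              nrow(x$frames), format(x$state),
              x$metadata$temperature %||% NA))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of frames in an observable series
#' @param series An `obs_series`.
#' @export
n_frames <- function(series) nrow(series$frames)

venergy <- function(system, X, state) {
  system_energy(system, X, state, corners = FALSE)$H
}

#' Metropolis sampling of a model system at a fixed coupling state
#'
#' Runs a random-walk Metropolis chain on the system's Hamiltonian at the
#' requested coupling state and temperature, and assembles a complete
#' per-frame observable record: total energy, analytic coupling
#' derivatives, end-state energies, energies re-evaluated at arbitrary
#' neighbor states (for acceptance-ratio estimation), and derivative /
#' energy probes on a dense lambda grid (for extended TI).
#'
#' @param system A model system.
#' @param state A [coupling_state()].
#' @param cfg A [sampler_config()].
#' @param neighbors List of [coupling_state()]s at which every frame's
#'   energy is re-evaluated.
#' @param probe_lam Numeric vector of probe lambda values at which
#'   `dH/dlam` and `H` are recorded each frame (kappa held at the
#'   sampled state's value).
#' @param endstates List of two [coupling_state()]s defining the A and B
#'   end states for `H_A`, `H_B`, `dV_BA`; defaults to the lambda-axis
#'   corners at the sampled kappa.
#' @param ctx A [thermo_ctx()].
#' @return An `obs_series` object.
#' @export
metropolis_sample <- function(system, state, cfg, neighbors = list(),
                              probe_lam = NULL, endstates = NULL,
                              ctx = thermo_ctx()) {
  state <- as_coupling_state(state)
  efun <- energy_fun(system, state)
  d <- system_dim(system)
  run <- with_seed(cfg$seed,
                   mc_core(efun, d, cfg, 1 / ctx$kBT, default_start(system)))
  X <- run$X
  obs <- system_energy(system, X, state, corners = TRUE)
  if (is.null(endstates)) {
    endstates <- list(coupling_state(0, state$kap),
                      coupling_state(1, state$kap))
  }
  H_A <- venergy(system, X, endstates[[1L]])
  H_B <- venergy(system, X, endstates[[2L]])
  frames <- data.frame(H = obs$H, dHdlam = obs$dHdlam, dHdkap = obs$dHdkap,
                       H_A = H_A, H_B = H_B, dV_BA = H_B - H_A)
  nb <- NULL
  if (length(neighbors)) {
    neighbors <- lapply(neighbors, as_coupling_state)
    Hn <- vapply(neighbors, function(s) venergy(system, X, s),
                 numeric(nrow(X)))
    colnames(Hn) <- vapply(neighbors, state_key, "")
    nb <- list(states = neighbors, H = Hn)
  }
  pr <- NULL
  if (length(probe_lam)) {
    pe <- lapply(probe_lam, function(lp) {
      system_energy(system, X, coupling_state(lp, state$kap), corners = FALSE)
    })
    pr <- list(lam = probe_lam,
               dHdlam = vapply(pe, `[[`, numeric(nrow(X)), "dHdlam"),
               H = vapply(pe, `[[`, numeric(nrow(X)), "H"))
  }
  new_obs_series(state, frames, neighbors = nb, probes = pr,
                 metadata = list(temperature = ctx$temperature,
                                 system_id = system$id %||% "system",
                                 seed = cfg$seed, n_steps = cfg$n_steps,
                                 step_size = run$step,
                                 acceptance = run$acceptance,
                                 kind = "plain"))
}

#' Pin a model system to a fixed coupling state
#'
#' Used to declare the end-state Hamiltonians entering an enveloping
#' reference state, e.g. the four-state toy with the water axis fixed at
#' its two ends.
#'
#' @param system A model system.
#' @param state A [coupling_state()].
#' @return An object of class `pinned_ham`.
#' @export
pin <- function(system, state) {
  structure(list(system = system, state = as_coupling_state(state)),
            class = "pinned_ham")
}

as_pinned <- function(x, default_state) {
  if (inherits(x, "pinned_ham")) return(x)
  pin(x, default_state)
}

#' Enveloping-distribution (EDS) reference-state parameters
#'
#' @param s Smoothness parameter (> 0); lower values flatten the barrier
#'   between the enveloped end states.
#' @param E Energy offsets (kJ mol-1).  A single value is interpreted as
#'   the offset of the second (higher) state, with the first fixed at 0 --
#'   the usual two-state convention.
#' @return An object of class `eds_params`.
#' @export
eds_params <- function(s, E = 0) {
  if (!is.numeric(s) || length(s) != 1L || is.na(s) || s <= 0) {
    stop("smoothness parameter s must be > 0")
  }
  structure(list(s = s, E = E), class = "eds_params")
}

eds_offsets <- function(params, n_states) {
  E <- params$E
  if (length(E) == 1L && n_states == 2L) E <- c(0, E)
  if (length(E) != n_states) stop("EDS offsets do not match number of states")
  E
}

#' Sample the EDS reference Hamiltonian of two (or more) end states
#'
#' Propagates Metropolis MC on the enveloping reference Hamiltonian
#' (a smoothed Boltzmann envelope of the end-state Hamiltonians, see
#' [eds_reference_energy()]) and records per frame the energy of every
#' end state, the reference energy, the end-state energy gap `dV_BA`,
#' and the coupling derivatives of both the reference and each end state
#' (the latter enable end-state TI-profile reweighting).
#'
#' @param systems List of end-state Hamiltonians: [pin()]ned systems, or
#'   plain systems evaluated at `state`.
#' @param params [eds_params()].
#' @param cfg [sampler_config()].
#' @param state Default [coupling_state()] for unpinned systems, and the
#'   nominal state stored on the series (e.g. the lambda of an EDS-TI
#'   window).
#' @param ctx A [thermo_ctx()].
#' @return An `obs_series` whose `ends` field holds matrices `H`
#'   (frames x states), `dHdlam`, `dHdkap`.
#' @export
sample_eds_reference <- function(systems, params, cfg,
                                 state = coupling_state(0, 0),
                                 ctx = thermo_ctx()) {
  if (length(systems) < 2L) stop("EDS needs at least two end states")
  state <- as_coupling_state(state)
  ends <- lapply(systems, as_pinned, default_state = state)
  dims <- vapply(ends, function(p) system_dim(p$system), 1L)
  if (length(unique(dims)) != 1L) {
    stop("all end-state Hamiltonians must share one configuration space")
  }
  d <- dims[[1L]]
  E <- eds_offsets(params, length(ends))
  efuns <- lapply(ends, function(p) energy_fun(p$system, p$state))
  beta <- 1 / ctx$kBT
  sb <- params$s * beta
  eref <- function(x) {
    h <- vapply(efuns, function(f) f(x), 0) - E
    m <- min(h)
    if (!is.finite(m)) return(Inf)
    m - log(sum(exp(-sb * (h - m)))) / sb
  }
  run <- with_seed(cfg$seed,
                   mc_core(eref, d, cfg, beta,
                           default_start(ends[[1L]]$system)))
  X <- run$X
  eo <- lapply(ends, function(p) {
    system_energy(p$system, X, p$state, corners = FALSE)
  })
  Hm <- vapply(eo, `[[`, numeric(nrow(X)), "H")
  DLm <- vapply(eo, `[[`, numeric(nrow(X)), "dHdlam")
  DKm <- vapply(eo, `[[`, numeric(nrow(X)), "dHdkap")
  Hoff <- sweep(Hm, 2, E)
  mrow <- apply(Hoff, 1, min)
  Heds <- mrow - log(rowSums(exp(-sb * (Hoff - mrow)))) / sb
  # Envelope weights give the reference-state coupling derivative.
  W <- exp(-sb * (Hoff - mrow))
  W <- W / rowSums(W)
  frames <- data.frame(H = Heds, dHdlam = rowSums(W * DLm),
                       dHdkap = rowSums(W * DKm),
                       H_A = Hm[, 1L], H_B = Hm[, 2L],
                       dV_BA = Hm[, 2L] - Hm[, 1L])
  new_obs_series(state, frames,
                 ends = list(H = Hm, dHdlam = DLm, dHdkap = DKm,
                             offsets = E, s = params$s),
                 metadata = list(temperature = ctx$temperature,
                                 system_id = "eds_reference",
                                 seed = cfg$seed, n_steps = cfg$n_steps,
                                 step_size = run$step,
                                 acceptance = run$acceptance,
                                 kind = "eds"))
}
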