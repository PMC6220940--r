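# Automated iterative search for the EDS parameters (E, s).
#
# The offset E levels the two end states so both are visited; the
# smoothness s lowers the barrier of the enveloping reference state.
# The two are coupled, so the search alternates phases: first balance
# the sampling ratio with E, then tune s on the transition count, then
# refine both in small steps.  The exact percentages and thresholds are
# this package's own (config-exposed) choices, targeting the observable
# behaviors: a plateauing s on overlap-friendly end-state pairs, and a
# collapsing s with a persistently one-sided ratio under a steric clash.

#' Control constants of the EDS parameter search
#'
#' @param e_gain Offset step per round, in kBT per unit of the scaled
#'   imbalance `2 * (ratio_A - 0.5)`.
#' @param s_down Multiplicative factor applied to `s` when transitions
#'   are scarce (default 0.9).
#' @param s_up Factor applied when transitions are abundant and the
#'   ratio is balanced (default 1.05).
#' @param transition_threshold Minimum transitions per round considered
#'   adequate (default 10).
#' @param balance_tol Ratio window half-width counted as balanced during
#'   phase advancement (default 0.1).
#' @param refine_frac Relative step of the refine phase (default 0.02).
#' @param stable_rounds Consecutive in-criterion rounds required to
#'   advance a phase (default 10).
#' @param max_phase_rounds Rounds after which the offset phase yields to
#'   the smoothness phase even without a balanced ratio (default 50); a
#'   persistent imbalance then shows up as a collapsing `s` instead of a
#'   runaway `E`.
#' @param s_min Smoothness underflow bound; reaching it flags the search
#'   as failed (default 1e-4).
#' @param s_max Upper cap on s (default 2).
#' @return A list of class `eds_search_control`.
#' @export
eds_search_control <- function(e_gain = 0.4, s_down = 0.9, s_up = 1.1,
                               transition_threshold = 10,
                               balance_tol = 0.1, refine_frac = 0.02,
                               stable_rounds = 10L, max_phase_rounds = 20L,
                               s_min = 1e-4, s_max = 2) {
  structure(as.list(environment()), class = "eds_search_control")
}

#' Initial EDS offset estimate from an unbiased end-state-A run
#'
#' The mean end-state energy gap over a short simulation on state A's
#' plain Hamiltonian brings both states to the same approximate level;
#' a positive value means B lies higher and receives the offset.
#'
#' @param series An `obs_series` sampled on end state A, with `dV_BA`.
#' @return Offset E in kJ mol-1.
#' @export
initial_offset_estimate <- function(series) {
  dv <- series$frames$dV_BA
  if (!length(dv)) stop("empty series")
  mean(dv)
}

new_search_state <- function(params) {
  structure(list(round_index = 0L, phase = "offset_phase",
                 params_history = list(params),
                 ratio_history = numeric(0),
                 transitions_history = integer(0),
                 stable_count = 0L, rounds_in_phase = 0L,
                 refine_toggle = FALSE,
                 failed = FALSE, failure = NULL),
            class = "eds_search_state")
}

#' @export
print.eds_search_state <- function(x, ...) {
  p <- current_params(x)
  cat(sprintf("<eds_search_state> round %d, phase %s, E = %.3f, s = %.4g%s\n",
              x$round_index, x$phase, p$E[length(p$E)], p$s,
              if (x$failed) " [FAILED]" else ""))
  invisible(x)
}

#' Current parameters of a search state
#' @param state An `eds_search_state`.
#' @export
current_params <- function(state) {
  state$params_history[[length(state$params_history)]]
}

#' One round of the EDS parameter update scheme
#'
#' Applies the phase-dependent adjustment: in the offset phase `E` moves
#' toward the undersampled state proportionally to the imbalance; in the
#' smoothness phase `s` is lowered when transitions are scarce and gently
#' raised when sampling is balanced and transitions abundant (with a
#' reduced `E` correction kept active); the refine phase applies small
#' alternating corrections to both.  A phase advances after its criterion
#' has held for `stable_rounds` consecutive rounds.
#'
#' @param state An `eds_search_state`.
#' @param last_round List with `ratio` (fraction of frames in state A)
#'   and `transitions` (A/B switches in the round).
#' @param control [eds_search_control()].
#' @param ctx A [thermo_ctx()].
#' @return List with `params` (the new [eds_params()]) and `state` (the
#'   advanced `eds_search_state`).
#' @export
update_parameters <- function(state, last_round,
                              control = eds_search_control(),
                              ctx = thermo_ctx()) {
  p <- current_params(state)
  E <- if (length(p$E) == 1L) p$E else p$E[2L]
  s <- p$s
  imb <- 2 * (last_round$ratio - 0.5) # >0: A oversampled, push E up
  balanced <- abs(last_round$ratio - 0.5) <= control$balance_tol
  enough_tr <- last_round$transitions >= control$transition_threshold
  if (state$phase == "offset_phase") {
    E <- E + control$e_gain * ctx$kBT * imb
    ok <- balanced
  } else if (state$phase == "smoothness_phase") {
    if (!enough_tr) {
      s <- s * control$s_down
    } else {
      s <- min(s * control$s_up, control$s_max)
    }
    E <- E + 0.5 * control$e_gain * ctx$kBT * imb
    ok <- balanced && enough_tr
  } else { # refine_phase: small alternating corrections around the plateau
    if (state$refine_toggle) {
      E <- E + control$refine_frac * ctx$kBT * sign(imb)
    } else if (!enough_tr) {
      s <- s * (1 - control$refine_frac)
    } else if (!balanced) {
      s <- min(s * (1 + control$refine_frac), control$s_max)
    }
    state$refine_toggle <- !state$refine_toggle
    ok <- TRUE
  }
  state$stable_count <- if (ok) state$stable_count + 1L else 0L
  state$rounds_in_phase <- state$rounds_in_phase + 1L
  advance <- state$stable_count >= control$stable_rounds ||
    (state$phase == "offset_phase" &&
       state$rounds_in_phase >= control$max_phase_rounds)
  if (advance) {
    state$phase <- switch(state$phase,
                          offset_phase = "smoothness_phase",
                          smoothness_phase = "refine_phase",
                          refine_phase = "refine_phase")
    state$stable_count <- 0L
    state$rounds_in_phase <- 0L
  }
  if (s <= control$s_min) {
    s <- control$s_min
    state$failed <- TRUE
    state$failure <- paste0(
      "smoothness parameter collapsed to the underflow bound (",
      control$s_min, "): the reference state no longer samples the ",
      "relevant configurations of both end states")
  }
  params <- eds_params(s, E)
  state$round_index <- state$round_index + 1L
  state$params_history <- c(state$params_history, list(params))
  state$ratio_history <- c(state$ratio_history, last_round$ratio)
  state$transitions_history <- c(state$transitions_history,
                                 as.integer(last_round$transitions))
  list(params = params, state = state)
}

#' Run the automated EDS parameter search
#'
#' Alternates short reference-state sampling rounds with parameter
#' updates (see [update_parameters()]), recording the full E/s/ratio/
#' transition histories for convergence plots.
#'
#' @param systems End-state Hamiltonians as in [sample_eds_reference()].
#' @param init Initial [eds_params()]; the traditional starting point is
#'   a deliberately low `s` (0.002) with `E` from
#'   [initial_offset_estimate()].
#' @param n_rounds Number of update rounds (at least 200 recommended).
#' @param steps_per_round MC steps per sampling round.
#' @param seed Base seed; round `k` uses `seed + k`.
#' @param state Default [coupling_state()] for unpinned end states.
#' @param control [eds_search_control()].
#' @param ctx A [thermo_ctx()].
#' @return The final `eds_search_state` (histories of length
#'   `n_rounds`, or shorter if the search failed and stopped early).
#' @export
run_search <- function(systems, init = eds_params(0.002, 0),
                       n_rounds = 200L, steps_per_round = 2000L,
                       seed = 1L, state = coupling_state(0, 0),
                       control = eds_search_control(),
                       ctx = thermo_ctx()) {
  st <- new_search_state(init)
  params <- init
  for (k in seq_len(n_rounds)) {
    cfg <- sampler_config(steps_per_round, seed = seed + k,
                          record_stride = 2L)
    series <- sample_eds_reference(systems, params, cfg, state = state,
                                   ctx = ctx)
    diag <- sampling_ratio_and_transitions(series)
    up <- update_parameters(st, list(ratio = diag$ratio_A,
                                     transitions = diag$transitions),
                            control, ctx)
    st <- up$state
    params <- up$params
    if (st$failed) break
  }
  st
}

#' Convergence assessment of a finished search
#'
#' Convergence is judged mainly on the smoothness parameter: its
#' relative drift over a trailing window must be small, with a balanced
#' trailing sampling ratio and a nonzero transition count (a search with
#' zero recent transitions is never reported as converged).
#'
#' @param state An `eds_search_state`.
#' @param window Trailing window in rounds (default 50).
#' @param drift_tol Maximum relative s drift over the window.
#' @param ratio_band Acceptable band of the mean trailing ratio.
#' @return List with `converged`, `s_drift`, `ratio_mean`,
#'   `transitions_total`, `failed`.
#' @export
assess_search_convergence <- function(state, window = 50L,
                                      drift_tol = 0.05,
                                      ratio_band = c(0.35, 0.65)) {
  n <- state$round_index
  w <- min(window, n)
  if (w < 1L) {
    return(list(converged = FALSE, s_drift = NA_real_,
                ratio_mean = NA_real_, transitions_total = 0L,
                failed = state$failed))
  }
  svals <- vapply(state$params_history[seq(n - w + 2L, n + 1L)],
                  `[[`, 0, "s")
  drift <- (max(svals) - min(svals)) / stats::median(svals)
  rmean <- mean(utils::tail(state$ratio_history, w))
  ttot <- sum(utils::tail(state$transitions_history, w))
  list(converged = !state$failed && drift < drift_tol &&
         rmean > ratio_band[1] && rmean < ratio_band[2] && ttot > 0L,
       s_drift = drift, ratio_mean = rmean,
       transitions_total = ttot, failed = state$failed)
}

#' Search history as a data frame
#'
#' One row per completed round: `round`, `E`, `s`, `ratio`,
#' `transitions` -- the layout used by the `search-eds` command for
#' parameter-evolution plots.
#'
#' @param state An `eds_search_state`.
#' @export
search_history <- function(state) {
  n <- state$round_index
  ph <- state$params_history[seq_len(n) + 1L]
  data.frame(round = seq_len(n),
             E = vapply(ph, function(p) {
               if (length(p$E) == 1L) p$E else p$E[2L]
             }, 0),
             s = vapply(ph, `[[`, 0, "s"),
             ratio = state$ratio_history,
             transitions = state$transitions_history)
}
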