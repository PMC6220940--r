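# Error estimation, cycle-closure metrics, EDS sampling diagnostics,
# and the convergence / prolongation algorithms.

#' Block-averaging error of a correlated scalar series
#'
#' Flyvbjerg-Petersen blocking: the series is repeatedly pairwise
#' averaged and the standard error of the mean recomputed at each level;
#' the estimate is the maximum over all levels that retain at least 8
#' blocks (a deterministic, conservative plateau proxy).
#'
#' @param x Numeric series with at least 16 values.
#' @return 1-sigma error of the mean of `x`.
#' @export
block_average_error <- function(x) {
  n <- length(x)
  if (n < 16L) stop("block averaging needs at least 16 frames")
  best <- 0
  while (length(x) >= 8L) {
    best <- max(best, stats::sd(x) / sqrt(length(x)))
    if (length(x) %% 2L == 1L) x <- x[-length(x)]
    x <- (x[seq(1, length(x), by = 2)] + x[seq(2, length(x), by = 2)]) / 2
  }
  best
}

#' Bootstrap error of an arbitrary statistic
#'
#' @param x Numeric series (>= 2 values).
#' @param statistic Function of a numeric vector (default `mean`).
#' @param n_boot Number of resamples with replacement (default 100).
#' @param seed Seed; identical seeds give identical output.
#' @return Standard deviation of the statistic over the resamples.
#' @export
bootstrap_error <- function(x, statistic = mean, n_boot = 100L, seed = 1L) {
  if (length(x) < 2L) stop("bootstrap needs at least 2 values")
  with_seed(seed, {
    vals <- vapply(seq_len(n_boot), function(b) {
      statistic(x[sample.int(length(x), replace = TRUE)])
    }, 0)
    stats::sd(vals)
  })
}

## ---------------------------------------------------------------------
## Thermodynamic-cycle closure
## ---------------------------------------------------------------------

#' Perturbation network with audit cycles
#'
#' @param edges Data frame with columns `from`, `to`, `dG` and optionally
#'   `err` (kJ mol-1), one directed free-energy estimate per row.
#' @param cycles Named list of character vectors; each vector lists the
#'   node sequence of one closed cycle (the closing edge back to the
#'   first node is implicit).  Edges may be traversed against their
#'   stored direction (sign-flipped).
#' @return An object of class `cycle_network`.
#' @export
cycle_network <- function(edges, cycles) {
  stopifnot(all(c("from", "to", "dG") %in% names(edges)))
  if (is.null(edges$err)) edges$err <- 0
  if (is.null(names(cycles))) {
    names(cycles) <- vapply(cycles, paste, "", collapse = "-")
  }
  net <- structure(list(edges = edges, cycles = cycles),
                   class = "cycle_network")
  for (nm in names(cycles)) cycle_edges(net, cycles[[nm]]) # validates
  net
}

cycle_edges <- function(net, nodes) {
  e <- net$edges
  path <- c(nodes, nodes[1L])
  lapply(seq_len(length(nodes)), function(k) {
    a <- path[k]; b <- path[k + 1L]
    fwd <- which(e$from == a & e$to == b)
    if (length(fwd)) {
      return(list(dG = e$dG[fwd[1L]], err = e$err[fwd[1L]]))
    }
    rev <- which(e$from == b & e$to == a)
    if (length(rev)) {
      return(list(dG = -e$dG[rev[1L]], err = e$err[rev[1L]]))
    }
    stop(sprintf("network has no edge between '%s' and '%s'", a, b))
  })
}

#' Cycle-closure report with the Sigma and Omega metrics
#'
#' Traverses each audit cycle in its listed node order (edges used
#' against their stored direction contribute `-dG`) and reports the
#' signed closure with quadrature-propagated error.  Aggregates
#' `Sigma = sum over cycles of |closure|` and the average deviation per
#' perturbation `Omega = (1/N_cycles) sum |closure| / N_legs`.
#'
#' @param net A [cycle_network()].
#' @return An object of class `cycle_report`: data frame `cycles`
#'   (name, n_legs, closure, error) plus fields `Sigma`, `Sigma_error`,
#'   `Omega`, `Omega_error`.
#' @export
cycle_closure_report <- function(net) {
  rows <- lapply(names(net$cycles), function(nm) {
    legs <- cycle_edges(net, net$cycles[[nm]])
    data.frame(cycle = nm, n_legs = length(legs),
               closure = sum(vapply(legs, `[[`, 0, "dG")),
               error = sqrt(sum(vapply(legs, `[[`, 0, "err")^2)))
  })
  cyc <- do.call(rbind, rows)
  structure(list(
    cycles = cyc,
    Sigma = sum(abs(cyc$closure)),
    Sigma_error = sqrt(sum(cyc$error^2)),
    Omega = mean(abs(cyc$closure) / cyc$n_legs),
    Omega_error = sqrt(sum((cyc$error / cyc$n_legs)^2)) / nrow(cyc)),
    class = "cycle_report")
}

#' @export
print.cycle_report <- function(x, ...) {
  print(x$cycles, row.names = FALSE)
  cat(sprintf("Sigma = %.3f +/- %.3f, Omega = %.3f +/- %.3f kJ/mol\n",
              x$Sigma, x$Sigma_error, x$Omega, x$Omega_error))
  invisible(x)
}

#' Hysteresis of a forward/backward perturbation pair
#'
#' The signed closure of the minimal two-leg cycle, `forward + backward`
#' (a backward run computed on the reversed perturbation would be the
#' exact negative of the forward one in the limit of perfect sampling).
#'
#' @param forward,backward [fe_estimate()]s of the perturbation run in
#'   the two directions.
#' @return List with `closure`, `abs_closure`, `error`.
#' @export
hysteresis <- function(forward, backward) {
  cl <- forward$value + backward$value
  list(closure = cl, abs_closure = abs(cl),
       error = sqrt(forward$error^2 + backward$error^2))
}

## ---------------------------------------------------------------------
## EDS sampling diagnostics
## ---------------------------------------------------------------------

#' State-sampling ratio and transition count of an EDS trajectory
#'
#' Frames are attributed to end state A when the instantaneous gap
#' `dV_BA = H_B - H_A` is positive (the currently favorable state is A)
#' and to B when negative; exact ties keep the previous assignment.
#'
#' @param series An `obs_series` with a `dV_BA` column.
#' @return List with `ratio_A` (fraction of frames in A) and
#'   `transitions` (number of A/B switches along the trajectory).
#' @export
sampling_ratio_and_transitions <- function(series) {
  dv <- series$frames$dV_BA
  if (!length(dv)) stop("empty series")
  s <- sign(dv)
  if (s[1L] == 0) s[1L] <- 1
  for (i in seq_along(s)[-1L]) if (s[i] == 0) s[i] <- s[i - 1L]
  list(ratio_A = mean(s > 0), transitions = sum(diff(s) != 0))
}

#' Reference and reweighted end-state energy distributions
#'
#' Histograms of the reference-state energy together with the end-state
#' energy distributions recovered by exponential reweighting
#' (`w_i = exp(-(H_i - H_EDS)/kBT)`, normalised); the effective sample
#' size of each end state's weights is attached.  A sharply reduced
#' effective sample size for one end state is the signature of an
#' enveloping reference that no longer covers that state.
#'
#' @param series An `obs_series` from [sample_eds_reference()].
#' @param bin_width Histogram bin width (kJ mol-1).
#' @param ctx A [thermo_ctx()].
#' @return List of data frames `reference`, `A`, `B` (columns `mid`,
#'   `density`) and `ess = c(A = , B = )`.
#' @export
end_state_distributions <- function(series, bin_width = 1,
                                    ctx = thermo_ctx()) {
  if (is.null(series$ends)) stop("series lacks per-end-state energies")
  beta <- 1 / ctx$kBT
  href <- series$frames$H
  hall <- c(href, series$ends$H[, 1L], series$ends$H[, 2L])
  hall <- hall[is.finite(hall)]
  breaks <- seq(floor(min(hall) / bin_width) * bin_width,
                ceiling(max(hall) / bin_width) * bin_width + bin_width,
                by = bin_width)
  whist <- function(h, w) {
    w <- w / sum(w)
    bin <- findInterval(h, breaks, rightmost.closed = TRUE)
    dens <- vapply(seq_len(length(breaks) - 1L),
                   function(b) sum(w[bin == b]), 0) / bin_width
    data.frame(mid = (breaks[-1L] + breaks[-length(breaks)]) / 2,
               density = dens)
  }
  out <- list(reference = whist(href, rep(1, length(href))))
  ess <- c(A = NA_real_, B = NA_real_)
  for (j in 1:2) {
    lw <- -beta * (series$ends$H[, j] - href)
    w <- exp(lw - max(lw))
    ess[j] <- effective_sample_size(w)
    out[[c("A", "B")[j]]] <- whist(series$ends$H[, j], w)
  }
  out$ess <- ess
  out
}

## ---------------------------------------------------------------------
## Convergence / prolongation algorithms
## ---------------------------------------------------------------------

new_prolongation_plan <- function(actions, converged, total_increments,
                                  allocation = NULL) {
  structure(list(actions = actions, converged = converged,
                 total_increments = total_increments,
                 allocation = allocation),
            class = "prolongation_plan")
}

#' @export
print.prolongation_plan <- function(x, ...) {
  cat(sprintf("<prolongation_plan> %d actions, %s, total %d increments\n",
              nrow(x$actions), if (x$converged) "converged" else "NOT converged",
              x$total_increments))
  invisible(x)
}

empty_actions <- function() {
  data.frame(contribution = integer(0), lam = numeric(0),
             reason = character(0), violation = numeric(0))
}

#' Retrospective convergence analysis with prolongation
#'
#' Replays the minimal-simulation-time question: starting every
#' contribution at its first time increment, which points must be
#' prolonged until (1) each effective contribution is within the allowed
#' deviation of its final reference value (accuracy) and then (2) each
#' effective error is below the allowed error (precision)?  The overall
#' budget of half a thermal energy is split evenly over the `N`
#' contributions (lambda points for TI/X-TI, intervals for BAR), and at
#' each step only the largest violator is prolonged (ties resolved by
#' lowest lambda; for BAR both flanking lambda points are reported).
#'
#' @param values Matrix (time increments x contributions) of cumulative
#'   contribution estimates: `<dH/dlam>` for TI/X-TI, interval free
#'   energies for BAR.
#' @param errors Matrix of matching cumulative error estimates.
#' @param reference Final reference value per contribution (defaults to
#'   the last row of `values`).
#' @param weights Effective-contribution weights: interval weights
#'   `dlam_i` for TI/X-TI, 1 for BAR.
#' @param lam Lambda value per contribution (interval midpoints for BAR);
#'   used for reporting and tie-breaking.
#' @param mode `"TI"` or `"BAR"` (BAR actions name both flanking points).
#' @param ctx A [thermo_ctx()].
#' @return A `prolongation_plan`; `total_increments` sums the per-point
#'   time increments consumed.
#' @export
prolongation_retrospective <- function(values, errors, reference = NULL,
                                       weights = NULL, lam = NULL,
                                       mode = c("TI", "BAR"),
                                       ctx = thermo_ctx()) {
  mode <- match.arg(mode)
  values <- as.matrix(values); errors <- as.matrix(errors)
  if (!identical(dim(values), dim(errors))) {
    stop("values and errors grids are inconsistent")
  }
  Tn <- nrow(values); N <- ncol(values)
  if (is.null(reference)) reference <- values[Tn, ]
  if (is.null(weights)) weights <- rep(1, N)
  if (is.null(lam)) lam <- seq_len(N)
  allowed <- 0.5 * ctx$kBT / N
  t_i <- rep(1L, N)
  actions <- empty_actions()
  exhausted_unresolved <- FALSE
  for (crit in c("accuracy", "precision")) {
    repeat {
      viol <- vapply(seq_len(N), function(i) {
        if (crit == "accuracy") {
          abs(values[t_i[i], i] - reference[i]) * weights[i] - allowed
        } else {
          errors[t_i[i], i] * weights[i] - allowed
        }
      }, 0)
      open <- which(viol > 0 & t_i < Tn)
      if (!length(open)) {
        if (any(viol > 0)) exhausted_unresolved <- TRUE
        break
      }
      pick <- open[order(-viol[open], lam[open])][1L]
      t_i[pick] <- t_i[pick] + 1L
      actions <- rbind(actions, data.frame(
        contribution = pick, lam = lam[pick], reason = crit,
        violation = viol[pick] + allowed))
    }
  }
  if (mode == "BAR" && nrow(actions)) {
    # an interval prolongation touches both flanking lambda points
    actions$flanking <- paste0("lam[", actions$contribution, "],lam[",
                               actions$contribution + 1L, "]")
  }
  new_prolongation_plan(actions, !exhausted_unresolved, sum(t_i))
}

#' Predictive greedy allocation of a fixed sampling budget
#'
#' Implements on-the-fly prolongation by the largest effective error:
#' repeatedly assign one time increment to the contribution (pair of
#' simulations for BAR) with the current largest `sigma_i * weight_i`,
#' where the error is assumed to shrink as `1/sqrt(n_i)` with the
#' increments already assigned.
#'
#' @param errors Current 1-sigma error per contribution (at one increment
#'   each).
#' @param weights Effective-contribution weights (`dlam_i` for TI/X-TI,
#'   1 for BAR).
#' @param budget Number of additional increments to distribute (>= 0).
#' @param lam Lambda per contribution, for reporting/tie-breaks.
#' @param mode `"TI"` or `"BAR"`.
#' @return A `prolongation_plan` with the per-contribution `allocation`.
#' @export
prolongation_predictive <- function(errors, weights = rep(1, length(errors)),
                                    budget, lam = seq_along(errors),
                                    mode = c("TI", "BAR")) {
  mode <- match.arg(mode)
  if (budget < 0) stop("budget must be >= 0")
  N <- length(errors)
  n_i <- rep(1L, N)
  actions <- empty_actions()
  for (step in seq_len(budget)) {
    eff <- errors * weights / sqrt(n_i)
    pick <- order(-eff, lam)[1L]
    n_i[pick] <- n_i[pick] + 1L
    actions <- rbind(actions, data.frame(
      contribution = pick, lam = lam[pick],
      reason = "largest_effective_error", violation = eff[pick]))
  }
  if (mode == "BAR" && nrow(actions)) {
    actions$flanking <- paste0("lam[", actions$contribution, "],lam[",
                               actions$contribution + 1L, "]")
  }
  new_prolongation_plan(actions, TRUE, sum(n_i), allocation = n_i)
}
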