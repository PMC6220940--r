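# Free-energy estimators: BAR, TI, X-TI, EDS, EDS-TI, 2D-TI.

#' Free-energy estimate record
#'
#' @param value Estimate in kJ mol-1.
#' @param error 1-sigma statistical error in kJ mol-1.
#' @param method One of `"BAR" "TI" "XTI" "EDS" "EDSTI" "TI2D"`.
#' @param n_frames_used Number of frames entering the estimate.
#' @param warnings Character vector of quality warnings (e.g. poor
#'   reweighting overlap).
#' @return An object of class `fe_estimate`.
#' @export
fe_estimate <- function(value, error, method, n_frames_used = NA_integer_,
                        warnings = character()) {
  stopifnot(error >= 0)
  structure(list(value = value, error = error, method = method,
                 n_frames_used = n_frames_used, warnings = warnings),
            class = "fe_estimate")
}

#' @export
print.fe_estimate <- function(x, ...) {
  cat(sprintf("dG(%s) = %.4f +/- %.4f kJ/mol  [%s frames]\n",
              x$method, x$value, x$error,
              format(x$n_frames_used, big.mark = ",")))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Fermi weighting function
#'
#' `f(x) = 1 / (1 + exp(x / kBT))`, the weight entering the acceptance
#' ratio estimator; satisfies `f(x) + f(-x) = 1` and is numerically
#' stable for arguments far into both tails.
#'
#' @param x Energy argument(s), kJ mol-1.
#' @param ctx A [thermo_ctx()].
#' @return Dimensionless weight(s) in (0, 1).
#' @export
fermi_weight <- function(x, ctx = thermo_ctx()) {
  stats::plogis(-x / ctx$kBT)
}

# log(mean(exp(x))) with max subtraction.
log_mean_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}

# Kish effective sample size of (unnormalised, nonnegative) weights.
effective_sample_size <- function(w) {
  s <- sum(w)
  if (s <= 0) return(0)
  s^2 / sum(w^2)
}

# Indices of nb near-equal contiguous blocks.
block_bounds <- function(n, nb) {
  nb <- max(2L, min(nb, n))
  edges <- floor(seq(0, n, length.out = nb + 1L))
  lapply(seq_len(nb), function(k) seq(edges[k] + 1L, edges[k + 1L]))
}

# Standard error of an estimator from contiguous-block re-estimates.
block_reestimate_error <- function(n, nb, fn) {
  idx <- block_bounds(n, nb)
  vals <- vapply(idx, fn, 0)
  stats::sd(vals) / sqrt(length(vals))
}

neighbor_H <- function(series, state) {
  if (is.null(series$neighbors)) {
    stop("series carries no neighbor-state energies")
  }
  key <- state_key(as_coupling_state(state))
  hit <- match(key, colnames(series$neighbors$H))
  if (is.na(hit)) {
    stop(sprintf("series at %s carries no energies for neighbor state %s",
                 format(series$state), format(as_coupling_state(state))))
  }
  series$neighbors$H[, hit]
}

## ---------------------------------------------------------------------
## BAR
## ---------------------------------------------------------------------

#' Bennett acceptance ratio between two neighboring ensembles
#'
#' Solves the self-consistency condition
#' `sum f(H_lo - H_hi + C) over the hi ensemble =
#'  sum f(H_hi - H_lo - C) over the lo ensemble`
#' for the shift `C` by bracketing root search on the strictly monotone
#' residual; the free-energy difference follows as
#' `C - kBT log(n_hi / n_lo)` (the sample-size term vanishes for
#' equal-length runs).  Both series must carry cross-evaluated energies
#' at the other's state.
#'
#' @param series_lo,series_hi `obs_series` at the two states, each with
#'   the other's state among its `neighbors`.
#' @param ctx A [thermo_ctx()].
#' @param n_blocks Number of contiguous blocks for the error estimate
#'   (block-wise re-solving).
#' @param tol Residual tolerance of the root search.
#' @return An object of class `bar_solution` with fields `delta_G`, `C`,
#'   `error`, `iterations`, `residual`, `n_frames_used`.
#' @export
bar_pair <- function(series_lo, series_hi, ctx = thermo_ctx(),
                     n_blocks = 10L, tol = 1e-10) {
  w_f <- neighbor_H(series_lo, series_hi$state) - series_lo$frames$H
  w_r <- neighbor_H(series_hi, series_lo$state) - series_hi$frames$H
  sol <- bar_solve(w_f, w_r, ctx, tol)
  err <- block_reestimate_error(min(length(w_f), length(w_r)), n_blocks,
                                function(ix) {
    bw_f <- w_f[ix[ix <= length(w_f)]]
    bw_r <- w_r[ix[ix <= length(w_r)]]
    bar_solve(bw_f, bw_r, ctx, tol)$delta_G
  })
  structure(c(sol, list(error = err,
                        n_frames_used = length(w_f) + length(w_r))),
            class = "bar_solution")
}

#' @export
print.bar_solution <- function(x, ...) {
  cat(sprintf("BAR: dG = %.4f +/- %.4f kJ/mol (C = %.4f, residual %.2e, %d iter)\n",
              x$delta_G, x$error, x$C, x$residual, x$iterations))
  invisible(x)
}

# w_f: H_hi - H_lo in the lo ensemble; w_r: H_lo - H_hi in the hi ensemble.
bar_solve <- function(w_f, w_r, ctx, tol = 1e-10) {
  kBT <- ctx$kBT
  resid <- function(C) {
    log(sum(fermi_weight(w_r + C, ctx))) -
      log(sum(fermi_weight(w_f - C, ctx)))
  }
  C0 <- 0.5 * (-kBT * log_mean_exp(-w_f / kBT) + kBT * log_mean_exp(-w_r / kBT))
  if (!is.finite(C0)) C0 <- 0
  half <- kBT
  r_lo <- resid(C0 - half); r_hi <- resid(C0 + half)
  it <- 0L
  while (is.finite(r_lo) && is.finite(r_hi) && r_lo * r_hi > 0 && it < 200L) {
    half <- half * 2
    r_lo <- resid(C0 - half); r_hi <- resid(C0 + half)
    it <- it + 1L
  }
  if (!is.finite(r_lo) || !is.finite(r_hi) || r_lo * r_hi > 0) {
    stop("BAR failed: no energy overlap between the two ensembles ",
         "(one Fermi-weighted average underflows); use closer states ",
         "or longer sampling")
  }
  root <- stats::uniroot(resid, c(C0 - half, C0 + half), tol = 1e-14)
  C <- root$root
  list(delta_G = C - kBT * log(length(w_r) / length(w_f)), C = C,
       iterations = root$iter + it, residual = resid(C))
}

#' Sum BAR estimates along a lambda path
#'
#' Applies [bar_pair()] to every consecutive pair of series (in the given
#' lambda order) and sums the interval free-energy differences; interval
#' errors combine in quadrature.
#'
#' @param series_list List of `obs_series` ordered along the path; each
#'   consecutive pair must be mutually cross-evaluated.
#' @param ctx A [thermo_ctx()].
#' @param n_blocks Blocks for per-interval errors.
#' @return An [fe_estimate()] with method `"BAR"`.
#' @export
bar_path <- function(series_list, ctx = thermo_ctx(), n_blocks = 10L) {
  if (length(series_list) < 2L) stop("need at least two series")
  sols <- lapply(seq_len(length(series_list) - 1L), function(k) {
    bar_pair(series_list[[k]], series_list[[k + 1L]], ctx, n_blocks)
  })
  fe_estimate(sum(vapply(sols, `[[`, 0, "delta_G")),
              sqrt(sum(vapply(sols, `[[`, 0, "error")^2)),
              "BAR",
              sum(vapply(series_list, n_frames, 0L)))
}

## ---------------------------------------------------------------------
## TI
## ---------------------------------------------------------------------

#' TI profile: mean coupling derivative on a lambda grid
#'
#' Interval weights are half the distance to the flanking points (half
#' intervals at the ends), so that the weighted sum of means equals the
#' trapezoidal integral and weighted errors carry the effective
#' contribution of each point.
#'
#' @param lam Strictly ascending lambda values.
#' @param mean Mean derivative `<dH/dlam>` per point (kJ mol-1).
#' @param error 1-sigma error per point.
#' @return An object of class `ti_profile` (a data frame with columns
#'   `lam`, `mean`, `error`, `weight`).
#' @export
ti_profile <- function(lam, mean, error = rep(0, length(lam))) {
  stopifnot(length(lam) == length(mean), length(lam) == length(error),
            length(lam) >= 2L)
  if (any(diff(lam) <= 0)) stop("lambda grid must be strictly ascending")
  n <- length(lam)
  w <- numeric(n)
  w[1] <- (lam[2] - lam[1]) / 2
  w[n] <- (lam[n] - lam[n - 1]) / 2
  if (n > 2L) w[2:(n - 1)] <- (lam[3:n] - lam[1:(n - 2)]) / 2
  structure(data.frame(lam = lam, mean = mean, error = error, weight = w),
            class = c("ti_profile", "data.frame"))
}

#' Build a TI profile from sampled series
#'
#' @param series_list List of `obs_series`.
#' @param axis Which coupling derivative to average (`"lam"` or `"kap"`).
#' @param n_blocks Blocks for the per-point block-averaging error.
#' @return A [ti_profile()] sorted by lambda.
#' @export
ti_profile_from_series <- function(series_list, axis = c("lam", "kap"),
                                   n_blocks = NULL) {
  axis <- match.arg(axis)
  col <- if (axis == "lam") "dHdlam" else "dHdkap"
  lam <- vapply(series_list, function(s) {
    if (axis == "lam") s$state$lam else s$state$kap
  }, 0)
  o <- order(lam)
  m <- vapply(series_list[o], function(s) mean(s$frames[[col]]), 0)
  e <- vapply(series_list[o], function(s) {
    block_average_error(s$frames[[col]])
  }, 0)
  ti_profile(lam[o], m, e)
}

#' Integrate a TI profile
#'
#' Trapezoidal integration of the mean derivative over `[0, 1]` (the
#' weighted-sum formulation); the error is the quadrature sum of the
#' weighted per-point errors.  Refuses profiles that do not span the
#' full coupling interval rather than extrapolating silently.
#'
#' @param profile A [ti_profile()].
#' @param method Label stored on the estimate (default `"TI"`).
#' @param n_frames_used Optional frame count to record.
#' @return An [fe_estimate()].
#' @export
ti_integrate <- function(profile, method = "TI",
                         n_frames_used = NA_integer_) {
  lam <- profile$lam
  if (abs(lam[1]) > 1e-9 || abs(lam[length(lam)] - 1) > 1e-9) {
    stop("TI profile must span the full interval [0, 1]: integration ",
         "would require extrapolation (grid runs ",
         sprintf("%g..%g)", lam[1], lam[length(lam)]))
  }
  bp <- attr(profile, "bootstrap_profiles")
  err <- if (!is.null(bp)) {
    stats::sd(as.numeric(crossprod(bp, profile$weight)))
  } else {
    sqrt(sum((profile$error * profile$weight)^2))
  }
  fe_estimate(sum(profile$mean * profile$weight), err, method,
              n_frames_used)
}

## ---------------------------------------------------------------------
## X-TI
## ---------------------------------------------------------------------

#' Extended-TI profile on a dense probe grid
#'
#' Each simulated series predicts the whole TI profile by reweighting its
#' on-the-fly probe records: at probe `lam_P`,
#' `<dH/dlam>_P = < d(lam_P) w > / < w >` with
#' `w = exp(-(H(lam_P) - H(lam_S)) / kBT)` over the frames of the series
#' simulated at `lam_S`.  Probes covered by several simulated points are
#' combined by inverse-variance weighting; per-probe errors come from a
#' seeded bootstrap over frames.  At a probe equal to a simulated point
#' the weights are exactly constant and the direct TI average is
#' recovered bit-for-bit.
#'
#' @param series_list Series carrying probe records (see
#'   [metropolis_sample()]'s `probe_lam`).
#' @param ctx A [thermo_ctx()].
#' @param n_boot Bootstrap resamples per probe (default 100).
#' @param seed Seed of the bootstrap.
#' @param min_ess Probes whose reweighting effective sample size falls
#'   below this are dropped from the combination when another simulated
#'   point covers them (and flagged otherwise).
#' @param min_ess_frac Minimum effective sample size as a fraction of a
#'   source's frames for that source to enter the combination at a
#'   probe.  Reweighting far outside a source's overlap region gives
#'   estimates whose bootstrap variance stays deceptively small while
#'   the estimate itself is dominated by a biased tail, so only sources
#'   with substantial genuine overlap are combined.
#' @return A [ti_profile()] on the union probe grid, with attributes
#'   `ess` (probes x series matrix) and `flagged` (probe indices kept
#'   despite low coverage).
#' @export
xti_profile <- function(series_list, ctx = thermo_ctx(), n_boot = 100L,
                        seed = 1L, min_ess = 10, min_ess_frac = 0.05) {
  has_probes <- vapply(series_list, function(s) !is.null(s$probes), TRUE)
  if (!all(has_probes)) stop("every series needs probe records for X-TI")
  grid <- series_list[[1L]]$probes$lam
  for (s in series_list[-1L]) {
    if (!isTRUE(all.equal(s$probes$lam, grid))) {
      stop("all series must share one probe grid")
    }
  }
  P <- length(grid)
  S <- length(series_list)
  est <- err <- ess <- matrix(NA_real_, P, S)
  boot <- vector("list", S)
  beta <- 1 / ctx$kBT
  lam_S <- vapply(series_list, function(s) s$state$lam, 0)
  for (k in seq_len(S)) {
    s <- series_list[[k]]
    m <- n_frames(s)
    LW <- -beta * (s$probes$H - s$frames$H) # frames x P
    W <- exp(sweep(LW, 2, apply(LW, 2, max)))
    D <- s$probes$dHdlam
    sw <- .colSums(W, m, P)
    est[, k] <- .colSums(W * D, m, P) / sw
    ess[, k] <- sw^2 / .colSums(W * W, m, P)
    # exact reduction at the series' own lambda: unit weights, plain mean
    own <- which(abs(grid - lam_S[k]) < 1e-12)
    if (length(own)) est[own, k] <- mean(D[, own[1L]])
    # seeded bootstrap via frame-count matrix (one GEMM per quantity)
    C <- with_seed(seed + k, {
      vapply(seq_len(n_boot), function(b) {
        tabulate(sample.int(m, m, replace = TRUE), m)
      }, numeric(m))
    })
    bnum <- crossprod(W * D, C) # P x n_boot
    bden <- crossprod(W, C)
    boot[[k]] <- bnum / bden
    err[, k] <- apply(boot[[k]], 1, stats::sd)
  }
  flagged <- integer(0)
  mean_c <- err_c <- numeric(P)
  boot_c <- matrix(NA_real_, P, n_boot)
  for (p in seq_len(P)) {
    own <- which(abs(lam_S - grid[p]) < 1e-12)
    if (length(own)) {
      # a simulated point covers this probe exactly: its direct average
      # is used unchanged (zero reweighting noise)
      mean_c[p] <- est[p, own[1L]]
      err_c[p] <- err[p, own[1L]]
      boot_c[p, ] <- boot[[own[1L]]][p, ]
      next
    }
    ms <- vapply(series_list, n_frames, 0L)
    ok <- which(ess[p, ] >= pmax(min_ess, min_ess_frac * ms))
    if (!length(ok)) {
      ok <- which.max(ess[p, ] / ms)
      if (ess[p, ok] < min_ess) flagged <- c(flagged, p)
    }
    iv <- 1 / pmax(err[p, ok], 1e-12)^2
    mean_c[p] <- sum(est[p, ok] * iv) / sum(iv)
    err_c[p] <- sqrt(1 / sum(iv))
    bc <- 0
    for (k in ok) bc <- bc + boot[[k]][p, ] * iv[match(k, ok)]
    boot_c[p, ] <- bc / sum(iv)
  }
  out <- ti_profile(grid, mean_c, err_c)
  attr(out, "ess") <- ess
  attr(out, "flagged") <- flagged
  # per-bootstrap combined profiles: integration uses these so that the
  # strong correlation of neighboring probes is respected
  attr(out, "bootstrap_profiles") <- boot_c
  out
}

## ---------------------------------------------------------------------
## EDS
## ---------------------------------------------------------------------

#' EDS reference-state energy
#'
#' The smoothed Boltzmann envelope of the end-state Hamiltonians:
#' `H_EDS = -(kBT/s) log sum_i exp(-s (H_i - E_i) / kBT)`, computed with
#' max-subtraction for numerical stability.
#'
#' @param H_i Numeric vector of end-state energies (one frame), or a
#'   matrix with one frame per row.
#' @param params [eds_params()].
#' @param ctx A [thermo_ctx()].
#' @return Reference energy (one value per frame).
#' @export
eds_reference_energy <- function(H_i, params, ctx = thermo_ctx()) {
  Hm <- if (is.matrix(H_i)) H_i else matrix(H_i, nrow = 1L)
  E <- eds_offsets(params, ncol(Hm))
  sb <- params$s / ctx$kBT
  Hoff <- sweep(Hm, 2, E)
  m <- apply(Hoff, 1, min)
  out <- m - log(rowSums(exp(-sb * (Hoff - m)))) / sb
  if (!is.matrix(H_i)) out <- out[[1L]]
  out
}

#' Free-energy difference from an EDS reference simulation
#'
#' `dG = -kBT log[ <exp(-(H_B - H_EDS)/kBT)> / <exp(-(H_A - H_EDS)/kBT)> ]`
#' over the reference-state ensemble; the error comes from contiguous
#' block re-estimates of the log-ratio.  Attaches an overlap warning when
#' either exponential average is carried by fewer than `min_ess`
#' effective frames.
#'
#' @param series An `obs_series` from [sample_eds_reference()].
#' @param ctx A [thermo_ctx()].
#' @param n_blocks Blocks for the error estimate.
#' @param min_ess Effective-frame threshold for the overlap warning.
#' @return An [fe_estimate()] with method `"EDS"`.
#' @export
eds_free_energy <- function(series, ctx = thermo_ctx(), n_blocks = 10L,
                            min_ess = 10) {
  if (series$metadata$kind %||% "" != "eds") {
    stop("eds_free_energy expects a series sampled on an EDS reference")
  }
  beta <- 1 / ctx$kBT
  la <- -beta * (series$frames$H_A - series$frames$H)
  lb <- -beta * (series$frames$H_B - series$frames$H)
  dg <- function(ix) {
    -ctx$kBT * (log_mean_exp(lb[ix]) - log_mean_exp(la[ix]))
  }
  n <- length(la)
  warn <- character()
  for (side in list(c("A", "la"), c("B", "lb"))) {
    w <- exp(get(side[2]) - max(get(side[2])))
    ess <- effective_sample_size(w)
    if (ess < min_ess) {
      warn <- c(warn, sprintf(
        "end state %s reweighting carried by %.1f effective frames (< %g): insufficient overlap",
        side[1], ess, min_ess))
    }
  }
  fe_estimate(dg(seq_len(n)),
              block_reestimate_error(n, n_blocks, dg),
              "EDS", n, warnings = warn)
}

#' Free energy from the EDS reference state to one end state
#'
#' `dG(R -> i) = -kBT log < exp(-(H_i - H_EDS)/kBT) >` over the
#' reference ensemble; these are the two outer legs of an EDS-TI cycle.
#'
#' @param series An `obs_series` from [sample_eds_reference()].
#' @param end End-state index or `"A"`/`"B"`.
#' @param ctx A [thermo_ctx()].
#' @param n_blocks Blocks for the error estimate.
#' @param min_ess Effective-frame warning threshold.
#' @return An [fe_estimate()] with method `"EDS"`.
#' @export
eds_leg <- function(series, end = "A", ctx = thermo_ctx(), n_blocks = 10L,
                    min_ess = 10) {
  if (is.null(series$ends)) stop("series lacks per-end-state energies")
  j <- if (is.character(end)) match(end, c("A", "B")) else as.integer(end)
  beta <- 1 / ctx$kBT
  lw <- -beta * (series$ends$H[, j] - series$frames$H)
  dg <- function(ix) -ctx$kBT * log_mean_exp(lw[ix])
  w <- exp(lw - max(lw))
  ess <- effective_sample_size(w)
  warn <- if (ess < min_ess) {
    sprintf("end-state leg carried by %.1f effective frames (< %g)",
            ess, min_ess)
  } else character()
  fe_estimate(dg(seq_along(lw)),
              block_reestimate_error(length(lw), n_blocks, dg),
              "EDS", length(lw), warnings = warn)
}

## ---------------------------------------------------------------------
## EDS-TI
## ---------------------------------------------------------------------

#' End-state TI profile from EDS reference simulations along lambda
#'
#' For EDS-TI the reference state (enveloping, say, water present and
#' absent) is propagated along lambda; the end-state derivative at each
#' window is recovered by exponential reweighting,
#' `<dH/dlam>_end = <dH/dlam_end w> / <w>` with
#' `w = exp(-(H_end - H_EDS)/kBT)`.
#'
#' @param series_list Series from [sample_eds_reference()] at the lambda
#'   windows (E and s typically interpolated linearly between the ends).
#' @param end Which enveloped end state to reweight to: index or
#'   `"A"`/`"B"`.
#' @param ctx A [thermo_ctx()].
#' @param n_blocks Blocks for per-point errors.
#' @param min_ess Effective-sample-size warning threshold.
#' @return A [ti_profile()]; attribute `ess` holds per-window effective
#'   sample sizes, attribute `warnings` any overlap warnings.
#' @export
edsti_end_state_profile <- function(series_list, end = "A",
                                    ctx = thermo_ctx(), n_blocks = 10L,
                                    min_ess = 10) {
  j <- if (is.character(end)) match(end, c("A", "B")) else as.integer(end)
  beta <- 1 / ctx$kBT
  lam <- vapply(series_list, function(s) s$state$lam, 0)
  o <- order(lam)
  warn <- character()
  ess <- numeric(length(o))
  est <- err <- numeric(length(o))
  for (i in seq_along(o)) {
    s <- series_list[[o[i]]]
    if (is.null(s$ends)) stop("series lacks per-end-state records")
    lw <- -beta * (s$ends$H[, j] - s$frames$H)
    w <- exp(lw - max(lw))
    d <- s$ends$dHdlam[, j]
    wmean <- function(ix) sum(w[ix] * d[ix]) / sum(w[ix])
    est[i] <- wmean(seq_along(w))
    err[i] <- block_reestimate_error(length(w), n_blocks, wmean)
    ess[i] <- effective_sample_size(w)
    if (ess[i] < min_ess) {
      warn <- c(warn, sprintf(
        "window lambda = %g: end-state reweighting has %.1f effective frames",
        lam[o[i]], ess[i]))
    }
  }
  out <- ti_profile(lam[o], est, err)
  attr(out, "ess") <- ess
  attr(out, "warnings") <- warn
  out
}

#' Combine the three legs of an EDS-TI diagonal
#'
#' The diagonal free-energy difference is assembled as
#' `dG = -dG_EDS(start leg) + dG_TI(reference along lambda) +
#' dG_EDS(end leg)`, with errors propagated in quadrature.
#'
#' @param leg_start [fe_estimate()]: reference-to-end-state EDS leg at
#'   lambda = 0.
#' @param leg_ti [fe_estimate()]: TI leg of the reference along lambda.
#' @param leg_end [fe_estimate()]: reference-to-end-state EDS leg at
#'   lambda = 1.
#' @return An [fe_estimate()] with method `"EDSTI"`.
#' @export
edsti_cycle_sum <- function(leg_start, leg_ti, leg_end) {
  legs <- list(leg_start, leg_ti, leg_end)
  if (any(vapply(legs, is.null, TRUE))) stop("all three legs are required")
  fe_estimate(-leg_start$value + leg_ti$value + leg_end$value,
              sqrt(leg_start$error^2 + leg_ti$error^2 + leg_end$error^2),
              "EDSTI",
              sum(vapply(legs, function(l) {
                if (is.na(l$n_frames_used)) 0L else l$n_frames_used
              }, 0L)),
              warnings = unlist(lapply(legs, `[[`, "warnings")))
}

## ---------------------------------------------------------------------
## 2D-TI
## ---------------------------------------------------------------------

#' Two-dimensional TI free-energy landscape
#'
#' Fills `G(lam, kap)` over a rectangular coupling grid starting from
#' `G(0, 0) = 0`.  Each new node receives up to three estimates -- a
#' diagonal step using both derivatives, a lambda step from the same-row
#' predecessor, and a kappa step from the same-column predecessor (each
#' step integrates the mean derivatives trapezoidally between the two
#' nodes) -- which are combined by exponential (Boltzmann) averaging over
#' the `m` available estimates.
#'
#' @param grid A data frame with columns `lam`, `kap`, `dHdlam`,
#'   `dHdkap` (mean derivatives) and optionally `err_dHdlam`,
#'   `err_dHdkap`, covering a complete rectangular grid.
#' @param ctx A [thermo_ctx()].
#' @return An object of class `landscape_2d`: list with `lam`, `kap`,
#'   `G` (matrix lam x kap), and `corner_differences` (data frame of the
#'   6 pairwise corner free-energy differences, with edge-path errors
#'   when error columns are supplied).
#' @export
landscape_2d <- function(grid, ctx = thermo_ctx()) {
  need <- c("lam", "kap", "dHdlam", "dHdkap")
  if (!all(need %in% names(grid))) {
    stop("grid needs columns ", paste(need, collapse = ", "))
  }
  lam <- sort(unique(grid$lam))
  kap <- sort(unique(grid$kap))
  key <- paste(grid$lam, grid$kap)
  full <- as.matrix(expand.grid(lam = lam, kap = kap))
  miss <- setdiff(paste(full[, 1], full[, 2]), key)
  if (length(miss) || nrow(grid) != length(lam) * length(kap)) {
    stop("incomplete coupling grid; missing nodes: ",
         paste(utils::head(miss, 3), collapse = "; "))
  }
  at <- function(col) {
    m <- matrix(NA_real_, length(lam), length(kap))
    m[cbind(match(grid$lam, lam), match(grid$kap, kap))] <- grid[[col]]
    m
  }
  DL <- at("dHdlam"); DK <- at("dHdkap")
  nl <- length(lam); nk <- length(kap)
  G <- matrix(NA_real_, nl, nk)
  G[1, 1] <- 0
  kBT <- ctx$kBT
  for (j in seq_len(nk)) {
    for (i in seq_len(nl)) {
      if (i == 1L && j == 1L) next
      ests <- numeric(0)
      if (i > 1L) {
        dl <- lam[i] - lam[i - 1]
        ests <- c(ests, G[i - 1, j] + dl * (DL[i - 1, j] + DL[i, j]) / 2)
      }
      if (j > 1L) {
        dk <- kap[j] - kap[j - 1]
        ests <- c(ests, G[i, j - 1] + dk * (DK[i, j - 1] + DK[i, j]) / 2)
      }
      if (i > 1L && j > 1L) {
        dl <- lam[i] - lam[i - 1]; dk <- kap[j] - kap[j - 1]
        ests <- c(ests,
                  G[i - 1, j - 1] +
                    dl * (DL[i - 1, j - 1] + DL[i, j - 1]) / 2 +
                    dk * (DK[i, j - 1] + DK[i, j]) / 2)
      }
      G[i, j] <- -kBT * log(mean(exp(-(ests - min(ests)) / kBT))) + min(ests)
    }
  }
  corners <- data.frame(
    from = c("00", "00", "00", "10", "10", "01"),
    to = c("10", "01", "11", "01", "11", "11"))
  cg <- function(lbl) {
    G[if (substr(lbl, 1, 1) == "0") 1L else nl,
      if (substr(lbl, 2, 2) == "0") 1L else nk]
  }
  corners$dG <- vapply(seq_len(6), function(r) {
    cg(corners$to[r]) - cg(corners$from[r])
  }, 0)
  if (all(c("err_dHdlam", "err_dHdkap") %in% names(grid))) {
    EL <- at("err_dHdlam"); EK <- at("err_dHdkap")
    wl <- ti_profile(lam, rep(0, nl))$weight
    wk <- ti_profile(kap, rep(0, nk))$weight
    edge_var_l <- function(j) sum((EL[, j] * wl)^2)
    edge_var_k <- function(i) sum((EK[i, ] * wk)^2)
    corners$error <- sqrt(c(edge_var_l(1), edge_var_k(1),
                            edge_var_l(1) + edge_var_k(nl),
                            edge_var_k(1) + edge_var_l(1),
                            edge_var_k(nl), edge_var_l(nk)))
  }
  structure(list(lam = lam, kap = kap, G = G,
                 corner_differences = corners),
            class = "landscape_2d")
}

#' Build a 2D-TI grid data frame from sampled series
#'
#' @param series_list Series covering a rectangular (lam, kap) grid.
#' @return A data frame suitable for [landscape_2d()].
#' @export
landscape_grid_from_series <- function(series_list) {
  data.frame(
    lam = vapply(series_list, function(s) s$state$lam, 0),
    kap = vapply(series_list, function(s) s$state$kap, 0),
    dHdlam = vapply(series_list, function(s) mean(s$frames$dHdlam), 0),
    dHdkap = vapply(series_list, function(s) mean(s$frames$dHdkap), 0),
    err_dHdlam = vapply(series_list, function(s) {
      block_average_error(s$frames$dHdlam)
    }, 0),
    err_dHdkap = vapply(series_list, function(s) {
      block_average_error(s$frames$dHdkap)
    }, 0))
}
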