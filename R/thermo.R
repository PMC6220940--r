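#' Thermodynamic context
#'
#' Bundles the absolute temperature with Boltzmann's constant in the unit
#' system used throughout the package (kJ mol-1, nm, K).  `kBT` is
#' precomputed because almost every estimator works in units of it.
#'
#' @param temperature Absolute temperature in Kelvin (default 298 K).
#' @return An object of class `thermo_ctx` with fields `temperature`,
#'   `kB` (0.00831446 kJ mol-1 K-1) and `kBT`.
#' @examples
#' ctx <- thermo_ctx()
#' ctx$kBT # about 2.478 kJ/mol at 298 K
#' @export
thermo_ctx <- function(temperature = 298) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    stop("temperature must be a single finite value > 0 (Kelvin)")
  }
  kB <- 0.00831446
  structure(list(temperature = temperature, kB = kB, kBT = kB * temperature),
            class = "thermo_ctx")
}

#' @export
print.thermo_ctx <- function(x, ...) {
  cat(sprintf("<thermo_ctx> T = %g K, kBT = %.6g kJ/mol\n",
              x$temperature, x$kBT))
  invisible(x)
}

#' Coupling state on the (lambda, kappa) unit square
#'
#' A point on the alchemical coupling square.  `lam` drives the first
#' perturbed species, `kap` the second; one-dimensional perturbations
#' leave `kap` at 0.
#'
#' @param lam Coupling value in `[0, 1]` for the first axis.
#' @param kap Coupling value in `[0, 1]` for the second axis (default 0).
#' @return An object of class `coupling_state`.
#' @export
coupling_state <- function(lam, kap = 0) {
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) ||
      lam < 0 || lam > 1) {
    stop("lam must be a single value in [0, 1]")
  }
  if (!is.numeric(kap) || length(kap) != 1L || is.na(kap) ||
      kap < 0 || kap > 1) {
    stop("kap must be a single value in [0, 1]")
  }
  structure(list(lam = as.numeric(lam), kap = as.numeric(kap)),
            class = "coupling_state")
}

#' @export
print.coupling_state <- function(x, ...) {
  cat(sprintf("<coupling_state> lambda = %g, kappa = %g\n", x$lam, x$kap))
  invisible(x)
}

#' @export
format.coupling_state <- function(x, ...) {
  sprintf("(%g, %g)", x$lam, x$kap)
}

as_coupling_state <- function(x) {
  if (inherits(x, "coupling_state")) return(x)
  if (is.numeric(x) && length(x) %in% c(1L, 2L)) {
    return(coupling_state(x[[1L]], if (length(x) == 2L) x[[2L]] else 0))
  }
  stop("cannot interpret object as a coupling state")
}

same_state <- function(a, b, tol = 0) {
  abs(a$lam - b$lam) <= tol && abs(a$kap - b$kap) <= tol
}

state_key <- function(s) sprintf("%.10g_%.10g", s$lam, s$kap)
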