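# Bundled reference perturbation network.
#
# A benchmark comparison of six free-energy methods on a four-state
# side-chain x restrained-water network (states: G/A side chain crossed
# with water present H / dummy D).  The per-edge estimates and per-cycle
# closures below are reported at maximum simulation length and at a
# 20 ns budget; they drive the cycle-closure arithmetic tests and the
# acceptance checks of the Sigma / Omega metrics.

#' Canonical audit cycles of the four-state network
#'
#' One four-membered cycle and four three-membered cycles, in the
#' traversal order under which the bundled per-edge table reproduces the
#' bundled per-cycle closures.
#'
#' @return Named list of node sequences.
#' @export
four_state_cycles <- function() {
  list("4-circle" = c("GH", "AH", "AD", "GD"),
       "GH-GD-AH" = c("GH", "GD", "AH"),
       "GH-GD-AD" = c("GH", "GD", "AD"),
       "AH-AD-GD" = c("AH", "AD", "GD"),
       "AH-AD-GH" = c("AH", "AD", "GH"))
}

#' Bundled reference free-energy network tables
#'
#' @return A list with data frames:
#' \describe{
#'   \item{edges}{per-edge estimates `dG(from -> to)` with 1-sigma
#'     errors, per method, at maximum simulation length.}
#'   \item{closures_full}{per-cycle closures (and printed Sigma/Omega)
#'     at maximum simulation length.}
#'   \item{closures_20ns}{per-cycle closures at a 20 ns budget.}
#' }
#' @export
reference_network_tables <- function() {
  edge_names <- c("GH-AH", "GD-AD", "GH-GD", "AH-AD", "GH-AD", "GD-AH")
  ev <- function(method, dG, err) {
    parts <- strsplit(edge_names, "-", fixed = TRUE)
    data.frame(method = method,
               from = vapply(parts, `[[`, "", 1L),
               to = vapply(parts, `[[`, "", 2L),
               dG = dG, err = err)
  }
  edges <- rbind(
    ev("BAR", c(17.0, 3.6, 16.9, 3.3, 20.8, 0.0),
       c(0.4, 0.2, 0.04, 0.2, 0.1, 0.2)),
    ev("TI", c(16.9, 3.6, 16.5, 2.3, 20.3, 1.2),
       c(0.4, 0.3, 0.3, 0.3, 0.4, 0.4)),
    ev("XTI", c(17.0, 3.5, 16.9, 3.4, 20.8, -0.1),
       c(0.03, 0.02, 0.04, 0.05, 0.05, 0.1)),
    ev("EDS", c(16.9, 3.9, 16.6, 1.3, 21.9, 2.7),
       c(0.2, 0.2, 0.1, 0.6, 0.4, 0.7)),
    ev("EDSTI", c(18.1, 4.3, 16.7, 1.0, 19.8, 2.1),
       c(0.04, 0.1, 0.1, 0.5, 0.3, 0.5)),
    ev("TI2D", c(16.8, 3.2, 17.0, 3.0, 19.8, -0.2),
       c(0.8, 0.6, 0.7, 1.0, 1.0, 1.8)))
  cyc_names <- names(four_state_cycles())
  n_legs <- c(4L, 3L, 3L, 3L, 3L)
  cv <- function(method, closure, err, Sigma, Sigma_err, Omega, Omega_err) {
    data.frame(method = method, cycle = cyc_names, n_legs = n_legs,
               closure = closure, err = err, Sigma = Sigma,
               Sigma_err = Sigma_err, Omega = Omega, Omega_err = Omega_err)
  }
  closures_full <- rbind(
    cv("BAR", c(-0.2, -0.1, -0.3, -0.3, -0.5),
       c(0.5, 0.5, 0.2, 0.3, 0.5), 1.4, 0.9, 0.1, 0.2),
    cv("TI", c(-0.8, 0.7, -0.2, -0.1, -1.1),
       c(0.6, 0.6, 0.6, 0.6, 0.6), 3.0, 1.3, 0.2, 0.3),
    cv("XTI", c(-0.1, -0.2, -0.4, -0.3, -0.5),
       c(0.1, 0.1, 0.1, 0.1, 0.1), 1.5, 0.2, 0.1, 0.05),
    cv("EDS", c(-2.3, 2.4, -1.4, 0.1, -3.7),
       c(0.7, 0.7, 0.4, 0.9, 0.8), 10.0, 1.6, 0.6, 0.4),
    cv("EDSTI", c(-1.9, 0.7, 1.2, -1.2, -0.7),
       c(0.5, 0.5, 0.3, 0.7, 0.6), 5.8, 1.2, 0.4, 0.3),
    cv("TI2D", c(-0.4, 0.0, 0.4, -0.4, 0.0),
       c(1.4, 2.1, 1.4, 2.0, 1.5), 1.2, 3.8, 0.1, 1.0))
  closures_20ns <- rbind(
    cv("BAR", c(-1.1, -0.4, 0.3, -1.5, -0.8),
       c(0.4, 0.3, 0.4, 0.3, 0.4), 4.1, 0.8, 0.3, 0.2),
    cv("TI", c(-2.8, 0.5, 0.4, -2.3, -2.4),
       c(1.4, 1.3, 1.1, 1.4, 1.3), 8.3, 2.9, 0.5, 0.7),
    cv("XTI", c(-0.7, -0.2, 0.6, -0.9, -0.1),
       c(0.3, 0.3, 0.2, 0.4, 0.3), 2.6, 0.7, 0.2, 0.2),
    cv("EDS", c(-2.2, 3.6, -2.2, 1.4, -4.4),
       c(1.9, 1.2, 1.0, 2.0, 2.0), 13.8, 3.8, 0.9, 0.9))
  list(edges = edges, closures_full = closures_full,
       closures_20ns = closures_20ns)
}

#' Cycle network of one method from the bundled edge table
#'
#' @param method One of `"BAR" "TI" "XTI" "EDS" "EDSTI" "TI2D"`.
#' @return A [cycle_network()] over the canonical four-state cycles.
#' @export
reference_network <- function(method = "BAR") {
  e <- reference_network_tables()$edges
  e <- e[e$method == method, c("from", "to", "dG", "err")]
  if (!nrow(e)) stop("unknown method: ", method)
  cycle_network(e, four_state_cycles())
}

#' Cycle-closure report from a per-cycle closure table
#'
#' Expands each printed per-cycle closure into a chain of pseudo-edges
#' (one edge carrying the closure, the remaining legs zero) so that the
#' Sigma / Omega metrics can be recomputed from per-cycle closures alone
#' through [cycle_closure_report()].
#'
#' @param closures Data frame with columns `cycle`, `closure`, `err`,
#'   `n_legs` (one method's rows of the bundled closure tables).
#' @return A `cycle_report`.
#' @export
closure_report_from_table <- function(closures) {
  edges <- NULL
  cycles <- list()
  for (k in seq_len(nrow(closures))) {
    nodes <- paste0("c", k, "n", seq_len(closures$n_legs[k]))
    path <- c(nodes, nodes[1L])
    edges <- rbind(edges, data.frame(
      from = path[-length(path)], to = path[-1L],
      dG = c(closures$closure[k], rep(0, closures$n_legs[k] - 1L)),
      err = c(closures$err[k], rep(0, closures$n_legs[k] - 1L))))
    cycles[[closures$cycle[k]]] <- nodes
  }
  cycle_closure_report(cycle_network(edges, cycles))
}
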