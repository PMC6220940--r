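# Plain-text series files (xvg-compatible dialect), declarative run
# configurations, and the programmatic fixture generator.
#
# Series files carry `# key = value` metadata headers, a
# `# columns: ...` declaration, and whitespace-delimited numeric rows,
# one frame per row, at full double precision.  `@`-prefixed lines are
# tolerated (and their legends used) for compatibility with xvg/dhdl
# output of MD packages.

fmt_num <- function(x) sprintf("%.17g", x)

series_column_block <- function(series) {
  fr <- series$frames
  cols <- as.list(fr)
  names(cols) <- names(fr)
  if (!is.null(series$neighbors)) {
    for (k in seq_along(series$neighbors$states)) {
      s <- series$neighbors$states[[k]]
      cols[[sprintf("nbH:%g:%g", s$lam, s$kap)]] <- series$neighbors$H[, k]
    }
  }
  if (!is.null(series$probes)) {
    for (k in seq_along(series$probes$lam)) {
      lp <- series$probes$lam[k]
      cols[[sprintf("prD:%.10g", lp)]] <- series$probes$dHdlam[, k]
      cols[[sprintf("prH:%.10g", lp)]] <- series$probes$H[, k]
    }
  }
  if (!is.null(series$ends)) {
    for (k in seq_len(ncol(series$ends$H))) {
      cols[[sprintf("endH:%d", k)]] <- series$ends$H[, k]
      cols[[sprintf("endDl:%d", k)]] <- series$ends$dHdlam[, k]
      cols[[sprintf("endDk:%d", k)]] <- series$ends$dHdkap[, k]
    }
  }
  cols
}

#' Write an observable series to a plain-text file
#'
#' @param series An `obs_series`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  md <- series$metadata
  hdr <- c("# alchemr_series v1",
           sprintf("# lam = %.17g", series$state$lam),
           sprintf("# kap = %.17g", series$state$kap))
  for (key in c("temperature", "system_id", "seed", "n_steps",
                "step_size", "acceptance", "kind")) {
    if (!is.null(md[[key]])) {
      val <- md[[key]]
      hdr <- c(hdr, sprintf("# %s = %s", key,
                            if (is.numeric(val)) fmt_num(val) else val))
    }
  }
  if (!is.null(series$ends)) {
    hdr <- c(hdr,
             sprintf("# eds_s = %s", fmt_num(series$ends$s)),
             sprintf("# eds_offsets = %s",
                     paste(fmt_num(series$ends$offsets), collapse = " ")))
  }
  cols <- series_column_block(series)
  hdr <- c(hdr, paste("# columns:", paste(names(cols), collapse = " ")))
  M <- do.call(cbind, cols)
  rows <- apply(M, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

parse_xvg_legends <- function(at_lines) {
  lg <- regmatches(at_lines,
                   regexec("@\\s*s(\\d+)\\s+legend\\s+\"([^\"]*)\"", at_lines))
  lg <- Filter(length, lg)
  if (!length(lg)) return(NULL)
  idx <- as.integer(vapply(lg, `[[`, "", 2L)) + 1L
  lab <- vapply(lg, `[[`, "", 3L)
  names(lab) <- idx
  lab
}

#' Read an observable series file
#'
#' Understands the native dialect written by [write_series()] as well as
#' xvg-style files from MD packages: `#` comment/metadata lines, `@`
#' metadata lines (whose `legend` entries name the data columns), and
#' whitespace-delimited numeric rows.  Unknown columns are preserved in
#' the frame table.
#'
#' @param path Input file path.
#' @return An `obs_series`.
#' @export
read_series <- function(path) {
  lines <- readLines(path, warn = FALSE)
  at <- lines[startsWith(lines, "@")]
  hash <- lines[startsWith(lines, "#")]
  data_ln <- which(!startsWith(lines, "@") & !startsWith(lines, "#") &
                     nzchar(trimws(lines)))
  if (!length(data_ln)) stop("no frames in series file: ", path)
  meta <- list()
  cols <- NULL
  for (h in hash) {
    if (grepl("^#\\s*columns:", h)) {
      cols <- strsplit(trimws(sub("^#\\s*columns:", "", h)), "\\s+")[[1L]]
    } else if (grepl("=", h, fixed = TRUE)) {
      kv <- strsplit(sub("^#\\s*", "", h), "\\s*=\\s*")[[1L]]
      if (length(kv) == 2L) meta[[kv[1L]]] <- kv[2L]
    }
  }
  first <- strsplit(trimws(lines[data_ln[1L]]), "\\s+")[[1L]]
  arity <- length(first)
  M <- matrix(NA_real_, length(data_ln), arity)
  for (i in seq_along(data_ln)) {
    f <- suppressWarnings(
      as.numeric(strsplit(trimws(lines[data_ln[i]]), "\\s+")[[1L]]))
    if (length(f) != arity || any(is.na(f))) {
      stop(sprintf("parse error at line %d of %s: expected %d numeric fields",
                   data_ln[i], path, arity))
    }
    M[i, ] <- f
  }
  if (is.null(cols)) {
    legends <- parse_xvg_legends(at)
    cols <- rep(NA_character_, arity)
    cols[1L] <- "time"
    if (!is.null(legends)) {
      for (k in seq_along(legends)) {
        j <- as.integer(names(legends)[k]) + 1L # data sets follow the abscissa
        if (j <= arity) {
          lab <- legends[[k]]
          cols[j] <- if (grepl("dH/d", lab)) "dHdlam"
          else if (grepl("(?i)total energy|potential", lab, perl = TRUE)) "H"
          else make.names(lab)
        }
      }
    }
    cols[is.na(cols)] <- paste0("V", which(is.na(cols)))
  }
  colnames(M) <- cols
  is_nb <- startsWith(cols, "nbH:")
  is_pr <- startsWith(cols, "prD:") | startsWith(cols, "prH:")
  is_end <- startsWith(cols, "endH:") | startsWith(cols, "endDl:") |
    startsWith(cols, "endDk:")
  frames <- as.data.frame(M[, !(is_nb | is_pr | is_end), drop = FALSE])
  nb <- NULL
  if (any(is_nb)) {
    keys <- sub("^nbH:", "", cols[is_nb])
    states <- lapply(strsplit(keys, ":"), function(p) {
      coupling_state(as.numeric(p[1L]), as.numeric(p[2L]))
    })
    H <- M[, is_nb, drop = FALSE]
    colnames(H) <- vapply(states, state_key, "")
    nb <- list(states = states, H = H)
  }
  pr <- NULL
  if (any(is_pr)) {
    dcols <- grep("^prD:", cols)
    lam <- as.numeric(sub("^prD:", "", cols[dcols]))
    pr <- list(lam = lam,
               dHdlam = M[, dcols, drop = FALSE],
               H = M[, match(sprintf("prH:%.10g", lam), cols), drop = FALSE])
  }
  ends <- NULL
  ecols <- grep("^endH:", cols)
  if (length(ecols)) {
    ns <- length(ecols)
    ends <- list(H = M[, sprintf("endH:%d", 1:ns), drop = FALSE],
                 dHdlam = M[, sprintf("endDl:%d", 1:ns), drop = FALSE],
                 dHdkap = M[, sprintf("endDk:%d", 1:ns), drop = FALSE],
                 s = as.numeric(meta$eds_s %||% NA),
                 offsets = as.numeric(strsplit(meta$eds_offsets %||% "0 0",
                                               "\\s+")[[1L]]))
  }
  state <- coupling_state(as.numeric(meta$lam %||% 0),
                          as.numeric(meta$kap %||% 0))
  for (key in c("temperature", "seed", "n_steps", "step_size", "acceptance")) {
    if (!is.null(meta[[key]])) meta[[key]] <- as.numeric(meta[[key]])
  }
  new_obs_series(state, frames, neighbors = nb, probes = pr, ends = ends,
                 metadata = meta)
}

## ---------------------------------------------------------------------
## Declarative run configuration
## ---------------------------------------------------------------------

#' Read a declarative run configuration
#'
#' YAML key-value configuration describing a system, a coupling grid,
#' sampler settings and estimator selection.  Units are explicit in key
#' names (e.g. `force_constant_kJ_per_mol_nm2`).
#'
#' @param path Configuration file.
#' @return A validated list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$lam_grid)) {
    lg <- as.numeric(cfg$lam_grid)
    if (any(lg < 0 | lg > 1) || any(diff(lg) <= 0)) {
      stop("lam_grid must be strictly ascending within [0, 1]")
    }
    cfg$lam_grid <- lg
  }
  if (!is.null(cfg$kap_grid)) {
    kg <- as.numeric(cfg$kap_grid)
    if (any(kg < 0 | kg > 1) || any(diff(kg) <= 0)) {
      stop("kap_grid must be strictly ascending within [0, 1]")
    }
    cfg$kap_grid <- kg
  }
  for (key in c("series_files")) {
    for (f in cfg[[key]]) {
      if (!file.exists(f)) stop("referenced file does not exist: ", f)
    }
  }
  structure(cfg, class = c("run_config", "list"))
}

#' Construct a model system from a configuration list
#'
#' @param cfg A `run_config` or plain list with a `system` block.
#' @return A model system object.
#' @export
system_from_config <- function(cfg) {
  sysc <- cfg$system %||% cfg
  kind <- sysc$kind %||% "quadratic"
  if (kind == "quadratic") {
    kA <- sysc$stiffness_A_kJ_per_mol_nm2 %||% 100
    kB <- sysc$stiffness_B_kJ_per_mol_nm2 %||% 400
    kC <- sysc$stiffness_kap_B_kJ_per_mol_nm2
    if (is.null(kC)) {
      quad_system(function(l, k) (1 - l) * kA + l * kB,
                  id = sysc$id %||% "quad")
    } else {
      quad_system(function(l, k) {
        (1 - l) * kA + l * kB + k * (kC - kA) * (1 - l)
      }, id = sysc$id %||% "quad2d")
    }
  } else if (kind == "fourstate") {
    atom <- function(block, axis) {
      b <- sysc[[block]] %||% list()
      perturbed_atom(q_A = b$q_A_e %||% 0, q_B = b$q_B_e %||% 0,
                     C12_A = b$C12_A_kJ_per_mol_nm12 %||% 0,
                     C12_B = b$C12_B_kJ_per_mol_nm12 %||% 7.5e-5,
                     C6_A = b$C6_A_kJ_per_mol_nm6 %||% 0,
                     C6_B = b$C6_B_kJ_per_mol_nm6 %||% 0.075,
                     coupling_axis = axis)
    }
    four_state_system(
      grower = atom("grower", "lam"),
      water = atom("water", "kap"),
      restraint = restraint_params(
        sysc$force_constant_kJ_per_mol_nm2 %||% 500, NULL,
        sysc$target_distance_nm %||% 0),
      softcore = softcore_params(sysc$alpha_lj %||% 0.5,
                                 sysc$alpha_crf_nm2 %||% 0.5),
      wall_position = sysc$wall_position_nm %||% 0.45,
      background_k = sysc$background_k_kJ_per_mol_nm2 %||% 25,
      d = sysc$dimensions %||% 1L,
      id = sysc$id %||% "fourstate")
  } else {
    stop("unknown system kind: ", kind)
  }
}

## ---------------------------------------------------------------------
## Fixture generator
## ---------------------------------------------------------------------

#' Generate the on-disk test fixture bundle
#'
#' Writes, deterministically for a given seed: (a) a quadratic-family
#' system configuration with an analytic free-energy sidecar, (b) the
#' four-state clash-toy configuration, (c) a pair of small cross-
#' evaluated sampled series for estimator tests, and (d) the bundled
#' reference-network tables as edge-list / closure TSV files.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return `dir`, invisibly.
#' @export
generate_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ctx <- thermo_ctx()
  quad_cfg <- list(system = list(kind = "quadratic", id = "harm_100_400",
                                 stiffness_A_kJ_per_mol_nm2 = 100,
                                 stiffness_B_kJ_per_mol_nm2 = 400),
                   lam_grid = c(0, 0.25, 0.5, 0.75, 1))
  yaml::write_yaml(quad_cfg, file.path(dir, "quad_system.yaml"))
  sysq <- system_from_config(quad_cfg)
  dg <- analytic_free_energy(sysq, coupling_state(1), ctx) -
    analytic_free_energy(sysq, coupling_state(0), ctx)
  writeLines(c("# analytic dG(lam 0 -> 1), kJ/mol", fmt_num(dg)),
             file.path(dir, "quad_system_analytic_dG.txt"))
  yaml::write_yaml(list(system = list(kind = "fourstate", id = "clash_toy")),
                   file.path(dir, "fourstate_system.yaml"))
  for (st in list(c(0, 0), c(0.5, 0))) {
    s <- metropolis_sample(
      sysq, coupling_state(st[1], st[2]),
      sampler_config(4000L, seed = seed, record_stride = 10L),
      neighbors = list(coupling_state(0, 0), coupling_state(0.5, 0)),
      ctx = ctx)
    write_series(s, file.path(dir, sprintf("series_lam%g.txt", st[1])))
  }
  tabs <- reference_network_tables()
  wtsv <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wtsv(tabs$edges, "reference_edges.tsv")
  wtsv(tabs$closures_full, "reference_closures_full.tsv")
  wtsv(tabs$closures_20ns, "reference_closures_20ns.tsv")
  invisible(dir)
}
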