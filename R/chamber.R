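# Simulated chamber backend: executes validated protocols without hardware.

#' Run configuration for the simulated instrument
#'
#' @param p_washoff Probability that an attached hydrogel architecture
#'   detaches (and is lost to waste) during each WASH while the sacrificial
#'   layer is present. Default 0.25, calibrated to the observed loss of
#'   multi-round architectures before lift-off (12 of 25 lost over 3 rounds).
#' @param p_collect Probability that a free (lifted-off) architecture is
#'   recovered by COLLECT. Default `2/13`, calibrated to the reported
#'   collection of 2 of the 13 surviving three-domain hydrogels.
#' @param size_bias_um Additive polymerized-size bias as a function of nominal
#'   mask size, micrometers. Default `0` (ideal optics). Set
#'   `size_bias_um = paper_size_bias` for the calibration profile echoing the
#'   printed means (+1.5 at 50 um, +7.1 at 20 um, +3.7 at 10 um) - this is a
#'   descriptive calibration, not physics.
#' @param swelling A list from [swelling_defaults()].
#' @param k_hyb Hybridization rate constant for quenching, per nM per hour.
#' @param seed Default RNG seed.
#' @return A `run_config` list.
#' @export
run_config <- function(p_washoff = 0.25, p_collect = 2 / 13,
                       size_bias_um = 0, swelling = swelling_defaults(),
                       k_hyb = 0.006, seed = 0L) {
  stopifnot(p_washoff >= 0, p_washoff <= 1, p_collect >= 0, p_collect <= 1)
  structure(list(p_washoff = p_washoff, p_collect = p_collect,
                 size_bias_um = size_bias_um, swelling = swelling,
                 k_hyb = k_hyb, seed = as.integer(seed)),
            class = "run_config")
}

#' Calibrated polymerized-size bias (descriptive, from printed mean sizes)
#'
#' Piecewise-constant additive bias: +3.7 um below 15 um nominal, +7.1 um in
#' 15-35 um, +1.5 um above. Echoes measured mean sizes (13.69, 27.1, 51.5 um
#' for 10, 20, 50 um masks); it is a calibration table, not a physical model.
#'
#' @param nominal_um Nominal mask size, micrometers.
#' @return Additive bias, micrometers.
#' @export
paper_size_bias <- function(nominal_um) {
  ifelse(nominal_um < 15, 3.7, ifelse(nominal_um < 35, 7.1, 1.5))
}

#' Swelling model parameters
#'
#' The hybridization-chain-reaction swelling kinetics are represented by a
#' saturating-exponential stand-in (no kinetic law is published for this
#' system): `L(t)/L0 = 1 + A_sys * (1 - exp(-t / tau))` per free edge, with
#' constrained edges scaled by `c_edge`.
#'
#' @param profile `"single_domain"` (A_S1 = 0.51, the single-domain endpoint
#'   at 60 h) or `"multi_domain"` (A_S1 = 0.4 red, A_S2 = 0.6 blue, the
#'   free-edge endpoints of the constrained three-domain architecture).
#' @param A Named amplitudes per crosslink system; overrides the profile.
#' @param tau_h Time constant, hours (default 8; order-of-magnitude anchor:
#'   most single-system swelling occurs within the first ~10 h).
#' @param c_edge Constrained-edge factor in `[0, 1]` (default 0.5: the edge
#'   nearest a non-swelling neighbor swells about half as much).
#' @return A list with `A`, `tau_h`, `c_edge`.
#' @export
swelling_defaults <- function(profile = c("single_domain", "multi_domain"),
                              A = NULL, tau_h = 8, c_edge = 0.5) {
  profile <- match.arg(profile)
  if (is.null(A)) {
    A <- if (profile == "single_domain") c(S1 = 0.51, S2 = 0.6)
         else c(S1 = 0.4, S2 = 0.6)
  }
  stopifnot(c_edge >= 0, c_edge <= 1, tau_h > 0)
  list(A = A, tau_h = tau_h, c_edge = c_edge)
}

#' Strand registry: complements and swelling systems
#'
#' Maps solution strands to their effect: quencher strands list the anchored
#' complement whose emission they suppress; hairpin strands list the crosslink
#' system they actuate.
#'
#' @return A data.frame with columns `name`, `complement_of`, `system`.
#' @export
default_strand_registry <- function() {
  data.frame(
    name = c("5Q_R1p", "S1_H1", "S1_H2", "S2_H1", "S2_H2"),
    complement_of = c("5Acry_3Cy3_R1", NA, NA, NA, NA),
    system = c(NA, "S1", "S1", "S2", "S2"),
    stringsAsFactors = FALSE
  )
}

new_domain <- function(id, cx, cy, w0, h0, strands, exposure_s = 1) {
  systems <- unique(stats::na.omit(strands$crosslink_system))
  structure(list(
    id = id, cx = cx, cy = cy, w0 = w0, h0 = h0,
    composition = strands,
    quenched = stats::setNames(rep(0, nrow(strands)), strands$name),
    crosslink_system = if (length(systems)) systems[1L] else NA_character_,
    constrained_edges = character(),
    signal_time_h = NA_real_, swell_A = NA_real_,
    status = "attached", architecture_id = id,
    exposure_s = exposure_s
  ), class = "hydrogel_domain")
}

#' @export
print.hydrogel_domain <- function(x, ...) {
  cat(sprintf("<hydrogel_domain> #%d at (%g, %g) um, %g x %g um, %s, system %s\n",
              x$id, x$cx, x$cy, x$w0, x$h0, x$status, x$crosslink_system))
  invisible(x)
}

#' Initialize a simulated chamber
#'
#' @param p A `mapdh_protocol` (supplies the vial inventory), or `NULL`.
#' @param sacrificial Whether a dissolvable sacrificial layer is present
#'   (lift-off/collection workflow).
#' @param registry Strand registry, default [default_strand_registry()].
#' @param config A [run_config()].
#' @return A `chamber_state`.
#' @export
new_chamber <- function(p = NULL, sacrificial = FALSE,
                        registry = default_strand_registry(),
                        config = run_config()) {
  vials <- if (is.null(p)) numeric() else {
    stats::setNames(vapply(p$vials, function(v) v$volume_ul, 0),
                    vapply(p$vials, function(v) as.character(v$vial_id), ""))
  }
  structure(list(
    vials = vials,
    chamber_content = list(kind = "none"),
    domains = list(),
    sacrificial_intact = sacrificial,
    time_h = 0,
    stage = c(x = 0, y = 0),
    registry = registry,
    config = config,
    next_domain_id = 1L
  ), class = "chamber_state")
}

#' @export
print.chamber_state <- function(x, ...) {
  st <- table(factor(vapply(x$domains, function(d) d$status, ""),
                     levels = c("attached", "free", "collected", "washed_away", "lost")))
  cat(sprintf("<chamber_state> t = %g h, content = %s, %d domains (%s)\n",
              x$time_h, x$chamber_content$kind, length(x$domains),
              paste(names(st), st, sep = ":", collapse = ", ")))
  invisible(x)
}

#' Domains filtered by status
#' @param state A `chamber_state`.
#' @param status Character vector of statuses to keep.
#' @export
domains_with_status <- function(state, status = "attached") {
  Filter(function(d) d$status %in% status, state$domains)
}

# union-find over architecture ids: overlapping footprints are mechanically
# contiguous and detach together
link_architectures <- function(state, new_idx) {
  d <- state$domains[[new_idx]]
  for (i in seq_along(state$domains)) {
    if (i == new_idx) next
    o <- state$domains[[i]]
    if (!o$status %in% c("attached")) next
    xo <- min(d$cx + d$w0 / 2, o$cx + o$w0 / 2) - max(d$cx - d$w0 / 2, o$cx - o$w0 / 2)
    yo <- min(d$cy + d$h0 / 2, o$cy + o$h0 / 2) - max(d$cy - d$h0 / 2, o$cy - o$h0 / 2)
    if (xo > 0 && yo > 0) {
      old_arch <- state$domains[[new_idx]]$architecture_id
      keep <- o$architecture_id
      for (j in seq_along(state$domains)) {
        if (state$domains[[j]]$architecture_id == old_arch) {
          state$domains[[j]]$architecture_id <- keep
        }
      }
    }
  }
  state
}

#' Execute a protocol on the simulated chamber
#'
#' Semantics per command: `FLOW` decrements the vial by `rate * duration` and
#' sets the chamber content (erroring on an empty/insufficient vial);
#' `PATTERN` requires the chamber to hold the current round's ink and creates
#' a hydrogel domain at the current stage position with the mask's footprint
#' (plus any configured size bias) and the ink's strand composition; `WASH`
#' replaces the content with wash buffer and, while a sacrificial layer is
#' present, detaches each attached architecture with probability `p_washoff`
#' (such gels are lost to waste); `ADD_SOLUTION` applies quenching and/or
#' swelling signals via the strand registry; `DISSOLVE_SACRIFICIAL` releases
#' all remaining attached gels; `COLLECT` recovers each free architecture with
#' probability `p_collect`.
#'
#' @param p A `mapdh_protocol` (should pass [validate_protocol()]).
#' @param init A `chamber_state`, or `NULL` to build one from `p`.
#' @param seed Integer RNG seed; the run is reproducible per seed.
#' @param config A [run_config()] (used when `init` is `NULL`).
#' @param sacrificial Sacrificial layer present (when `init` is `NULL`).
#' @return A list with `state` (final `chamber_state`) and `events`
#'   (data.frame log: step, op, detail).
#' @export
execute <- function(p, init = NULL, seed = 0L, config = run_config(),
                    sacrificial = FALSE) {
  state <- if (is.null(init)) new_chamber(p, sacrificial = sacrificial,
                                          config = config) else init
  events <- list()
  log_ev <- function(step, op, detail) {
    events[[length(events) + 1L]] <<- data.frame(step = step, op = op,
                                                 detail = detail)
  }
  withr::with_seed(seed, {
    for (i in seq_along(p$commands)) {
      cm <- p$commands[[i]]
      if (cm$op == "FLOW") {
        vol <- p$hardware$flow_rate_ul_s * cm$duration_s
        key <- as.character(cm$vial_id)
        if (cm$vial_id == p$wash_vial_id) {
          state$chamber_content <- list(kind = "wash")
        } else {
          if (!key %in% names(state$vials)) {
            stop("execution error: FLOW from unknown vial ", key, call. = FALSE)
          }
          if (state$vials[key] < vol) {
            stop("execution error: vial ", key, " empty (needs ", vol, " uL, has ",
                 state$vials[key], ")", call. = FALSE)
          }
          state$vials[key] <- state$vials[key] - vol
          state$chamber_content <- list(kind = "ink", vial_id = cm$vial_id)
        }
        log_ev(i, "FLOW", sprintf("vial %d, %g s", cm$vial_id, cm$duration_s))
      } else if (cm$op == "MOVE") {
        state$stage <- c(x = cm$x, y = cm$y)
        log_ev(i, "MOVE", sprintf("(%g, %g)", cm$x, cm$y))
      } else if (cm$op == "PATTERN") {
        if (state$chamber_content$kind != "ink") {
          stop("execution error: PATTERN with chamber content '",
               state$chamber_content$kind, "'", call. = FALSE)
        }
        vial <- state$chamber_content$vial_id
        ink <- p$vials[[which(vapply(p$vials, function(v) v$vial_id, 0L) == vial)]]
        m <- p$masks[[cm$mask_ref]]
        w_nom <- ncol(m$bitmap) * m$pixel_size_um
        h_nom <- nrow(m$bitmap) * m$pixel_size_um
        bias <- state$config$size_bias_um
        bw <- if (is.function(bias)) bias(w_nom) else bias
        bh <- if (is.function(bias)) bias(h_nom) else bias
        d <- new_domain(state$next_domain_id, state$stage[["x"]], state$stage[["y"]],
                        max(w_nom + bw, 0), max(h_nom + bh, 0),
                        ink$strands, cm$exposure_s)
        state$next_domain_id <- state$next_domain_id + 1L
        state$domains[[length(state$domains) + 1L]] <- d
        state <- link_architectures(state, length(state$domains))
        log_ev(i, "PATTERN", sprintf("domain %d (%s) at (%g, %g)", d$id,
                                     cm$mask_ref, d$cx, d$cy))
      } else if (cm$op == "WASH") {
        state$chamber_content <- list(kind = "wash")
        if (state$sacrificial_intact && state$config$p_washoff > 0) {
          archs <- unique(vapply(domains_with_status(state, "attached"),
                                 function(d) d$architecture_id, 0L))
          for (a in archs) {
            if (stats::runif(1) < state$config$p_washoff) {
              for (j in seq_along(state$domains)) {
                if (state$domains[[j]]$architecture_id == a &&
                    state$domains[[j]]$status == "attached") {
                  state$domains[[j]]$status <- "washed_away"
                }
              }
              log_ev(i, "WASHOFF", sprintf("architecture %d detached in wash", a))
            }
          }
        }
        log_ev(i, "WASH", sprintf("%g s", cm$duration_s))
      } else if (cm$op == "ADD_SOLUTION") {
        state$chamber_content <- list(kind = "solution", strands = cm$strands)
        for (s in seq_along(cm$strands)) {
          state <- apply_solution_strand(state, cm$strands[s], cm$final_conc_nM[s])
        }
        log_ev(i, "ADD_SOLUTION", paste(cm$strands, collapse = ", "))
      } else if (cm$op == "DISSOLVE_SACRIFICIAL") {
        state$sacrificial_intact <- FALSE
        for (j in seq_along(state$domains)) {
          if (state$domains[[j]]$status == "attached") {
            state$domains[[j]]$status <- "free"
          }
        }
        state$time_h <- state$time_h + cm$duration_s / 3600
        log_ev(i, "DISSOLVE_SACRIFICIAL", "all attached domains released")
      } else if (cm$op == "COLLECT") {
        archs <- unique(vapply(domains_with_status(state, "free"),
                               function(d) d$architecture_id, 0L))
        for (a in archs) {
          got <- stats::runif(1) < state$config$p_collect
          for (j in seq_along(state$domains)) {
            if (state$domains[[j]]$architecture_id == a &&
                state$domains[[j]]$status == "free") {
              state$domains[[j]]$status <- if (got) "collected" else "lost"
            }
          }
          log_ev(i, "COLLECT", sprintf("architecture %d %s", a,
                                       if (got) "collected" else "not recovered"))
        }
      }
    }
  })
  ev <- if (length(events)) do.call(rbind, events) else {
    data.frame(step = integer(), op = character(), detail = character())
  }
  list(state = state, events = ev)
}

# Resolve one solution strand via the registry: quencher strands hybridize to
# their anchored complement; hairpin strands actuate their crosslink system.
apply_solution_strand <- function(state, strand, conc_nM) {
  reg <- state$registry
  row <- reg[reg$name == strand, , drop = FALSE]
  if (nrow(row) == 0L) {
    stop("unknown strand (not in registry): ", strand, call. = FALSE)
  }
  if (!is.na(row$complement_of)) {
    state <- hybridize(state, strand, conc_nM, duration_h = 1)
  }
  if (!is.na(row$system)) {
    state <- add_swelling_signal(state, row$system, final_conc_uM = conc_nM / 1000)
  }
  state
}

#' Write an event log as JSON lines
#' @param events Event data.frame from [execute()].
#' @param path Output path (`.jsonl`).
#' @export
write_events <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(events))) {
    writeLines(jsonlite::toJSON(as.list(events[i, ]), auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Write a chamber-state snapshot as JSON
#' @param state A `chamber_state`.
#' @param path Output path.
#' @export
write_state <- function(state, path) {
  doms <- lapply(state$domains, function(d) {
    list(id = d$id, cx = d$cx, cy = d$cy, w0 = d$w0, h0 = d$h0,
         status = d$status, architecture_id = d$architecture_id,
         crosslink_system = d$crosslink_system,
         composition = d$composition, quenched = as.list(d$quenched),
         signal_time_h = d$signal_time_h, swell_A = d$swell_A)
  })
  jsonlite::write_json(list(time_h = state$time_h, vials = as.list(state$vials),
                            chamber_content = state$chamber_content,
                            sacrificial_intact = state$sacrificial_intact,
                            domains = doms),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
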