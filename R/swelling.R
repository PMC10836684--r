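# Hybridization (quenching) and DNA-driven swelling on the simulated chamber.

#' Hybridize a solution strand to its anchored complement
#'
#' For every domain whose composition contains the registered complement of
#' `strand`, the complement's quenched fraction rises toward 1 with a
#' saturating first-order law:
#' `q <- 1 - (1 - q) * exp(-k_hyb * conc * duration)`. All other strands and
#' domains are untouched (composition locality).
#'
#' @param state A `chamber_state`.
#' @param strand Solution strand name; must exist in the state's registry.
#' @param conc_nM Solution concentration, nM.
#' @param duration_h Incubation time, hours.
#' @return The updated `chamber_state`.
#' @export
hybridize <- function(state, strand, conc_nM, duration_h = 1) {
  reg <- state$registry
  row <- reg[reg$name == strand, , drop = FALSE]
  if (nrow(row) == 0L) stop("unknown strand: ", strand, call. = FALSE)
  target <- row$complement_of
  if (is.na(target)) return(state)  # no complement declared; nothing to quench
  rate <- state$config$k_hyb * conc_nM * duration_h
  for (j in seq_along(state$domains)) {
    d <- state$domains[[j]]
    if (target %in% d$composition$name) {
      q <- d$quenched[[target]]
      state$domains[[j]]$quenched[[target]] <- 1 - (1 - q) * exp(-rate)
    }
  }
  state
}

#' Add a swelling signal (hairpin pair) for one crosslink system
#'
#' Marks every domain whose crosslink system matches as actuated from the
#' current chamber time; domains without that system (or with none) never
#' swell. The equilibrium amplitude is taken from the run config's swelling
#' parameters at the moment the signal is added.
#'
#' @param state A `chamber_state`.
#' @param system `"S1"` or `"S2"`.
#' @param final_conc_uM Hairpin final concentration, micromolar (default 20).
#'   Recorded; the stand-in kinetics saturate regardless of concentration.
#' @return The updated `chamber_state`.
#' @export
add_swelling_signal <- function(state, system, final_conc_uM = 20) {
  sw <- state$config$swelling
  if (!system %in% names(sw$A)) {
    stop("unknown crosslink system: ", system, call. = FALSE)
  }
  for (j in seq_along(state$domains)) {
    d <- state$domains[[j]]
    if (!is.na(d$crosslink_system) && d$crosslink_system == system &&
        is.na(d$signal_time_h)) {
      state$domains[[j]]$signal_time_h <- state$time_h
      state$domains[[j]]$swell_A <- unname(sw$A[[system]])
    }
  }
  state
}

#' Advance chamber time
#'
#' @param state A `chamber_state`.
#' @param dt_h Time increment in hours (`>= 0`).
#' @return The updated `chamber_state`.
#' @export
advance_time <- function(state, dt_h) {
  if (dt_h < 0) stop("invalid-parameter: negative time increment", call. = FALSE)
  state$time_h <- state$time_h + dt_h
  state
}

#' Constrain edges of a domain
#'
#' Marks edges (`"N"`, `"S"`, `"E"`, `"W"`; image convention, y down) as
#' mechanically constrained, e.g. the edge shared with a non-swelling
#' neighbor. Constrained edges swell by the factor `c_edge` of the free-edge
#' amplitude.
#'
#' @param state A `chamber_state`.
#' @param domain_id Domain id.
#' @param edges Character vector of edge labels.
#' @return The updated `chamber_state`.
#' @export
constrain_edges <- function(state, domain_id, edges) {
  stopifnot(all(edges %in% c("N", "S", "E", "W")))
  for (j in seq_along(state$domains)) {
    if (state$domains[[j]]$id == domain_id) {
      state$domains[[j]]$constrained_edges <-
        union(state$domains[[j]]$constrained_edges, edges)
      return(state)
    }
  }
  stop("unknown domain id: ", domain_id, call. = FALSE)
}

# saturating-exponential swelling progress in [0, 1)
swell_progress <- function(d, time_h, tau_h) {
  if (is.na(d$signal_time_h) || time_h <= d$signal_time_h) return(0)
  1 - exp(-(time_h - d$signal_time_h) / tau_h)
}

edge_factor <- function(d, edge, c_edge) {
  if (edge %in% d$constrained_edges) c_edge else 1
}

#' Current geometry of a domain
#'
#' Evaluates the swelling law at the chamber time. The returned geometry is an
#' axis-aligned trapezoid: the x-extent grows with the mean of the N/S edge
#' factors, and the height varies linearly from the W side to the E side with
#' each side's edge factor, so a domain constrained on one vertical edge is
#' taller at its free side.
#'
#' @param state A `chamber_state`.
#' @param domain_id Domain id.
#' @return A list with `cx`, `cy`, `x0`, `x1` (x-extent), `h_west`, `h_east`
#'   (heights at the two vertical sides), `dL_over_L0_free` (relative length
#'   change at a free edge), and `progress`.
#' @export
domain_geometry <- function(state, domain_id) {
  d <- NULL
  for (dd in state$domains) if (dd$id == domain_id) d <- dd
  if (is.null(d)) stop("unknown domain id: ", domain_id, call. = FALSE)
  sw <- state$config$swelling
  g <- swell_progress(d, state$time_h, sw$tau_h)
  A <- if (is.na(d$swell_A)) 0 else d$swell_A
  fW <- edge_factor(d, "W", sw$c_edge); fE <- edge_factor(d, "E", sw$c_edge)
  fN <- edge_factor(d, "N", sw$c_edge); fS <- edge_factor(d, "S", sw$c_edge)
  w <- d$w0 * (1 + A * g * (fN + fS) / 2)
  h_west <- d$h0 * (1 + A * g * fW)
  h_east <- d$h0 * (1 + A * g * fE)
  list(cx = d$cx, cy = d$cy, x0 = d$cx - w / 2, x1 = d$cx + w / 2,
       h_west = h_west, h_east = h_east,
       dL_over_L0_free = A * g, progress = g)
}

#' Analytic edge length of a domain
#'
#' Side length measured at a given edge at the current chamber time; the
#' measurement edge of the swelling experiments is the edge opposite the
#' non-swelling neighbor.
#'
#' @param state A `chamber_state`.
#' @param domain_id Domain id.
#' @param edge `"W"` or `"E"` return the height at that vertical side; `"N"`
#'   or `"S"` return the x-extent.
#' @return Length in micrometers.
#' @export
domain_edge_length <- function(state, domain_id, edge = "W") {
  geom <- domain_geometry(state, domain_id)
  switch(edge,
         W = geom$h_west, E = geom$h_east,
         N = , S = geom$x1 - geom$x0,
         stop("unknown edge: ", edge, call. = FALSE))
}
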