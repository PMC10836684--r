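#' Ink specification
#'
#' An ink is a pre-gel solution: monomer (PEGDA), photoinitiator (LAP), and
#' acrydite-modified DNA strands, housed in a pressurized vial.
#'
#' @param vial_id Integer vial identifier (unique within a protocol).
#' @param strands A data.frame as built by [strand_table()], or `NULL`.
#' @param monomer_label Monomer name, default `"PEGDA-575"` (use
#'   `"PEGDA-10K"` for DNA-crosslinked swelling inks).
#' @param monomer_vv_percent Monomer volume fraction, percent (default 10).
#' @param photoinitiator_label Photoinitiator name, default `"LAP"`.
#' @param photoinitiator_wv_percent Photoinitiator w/v percent (default 1).
#' @param volume_ul Ink volume in the vial, microliters (default 150).
#' @return An object of class `ink_spec`.
#' @export
ink_spec <- function(vial_id, strands = NULL, monomer_label = "PEGDA-575",
                     monomer_vv_percent = 10, photoinitiator_label = "LAP",
                     photoinitiator_wv_percent = 1, volume_ul = 150) {
  if (is.null(strands)) strands <- strand_table()
  if (any(strands$concentration_nM < 0)) {
    stop("invalid-parameter: strand concentrations must be >= 0", call. = FALSE)
  }
  if (volume_ul < 0) stop("invalid-parameter: volume must be >= 0", call. = FALSE)
  structure(list(vial_id = as.integer(vial_id), strands = strands,
                 monomer_label = monomer_label,
                 monomer_vv_percent = monomer_vv_percent,
                 photoinitiator_label = photoinitiator_label,
                 photoinitiator_wv_percent = photoinitiator_wv_percent,
                 volume_ul = volume_ul),
            class = "ink_spec")
}

#' @rdname ink_spec
#' @param name Strand names (e.g. `"5Acry_3Cy3_polyT10"`).
#' @param concentration_nM Concentrations in nM.
#' @param fluorophore Imaging channel label per strand (`"Cy3"`, `"ATTO488"`,
#'   `"TYE665"`) or `NA` for unlabeled strands.
#' @param acrydite Whether the strand copolymerizes into the network.
#' @param crosslink_system Crosslink system label (`"S1"`, `"S2"`) or `NA`.
#' @export
strand_table <- function(name = character(), concentration_nM = numeric(),
                         fluorophore = NA_character_, acrydite = TRUE,
                         crosslink_system = NA_character_) {
  data.frame(name = as.character(name),
             concentration_nM = as.numeric(concentration_nM),
             fluorophore = rep_len(as.character(fluorophore), length(name)),
             acrydite = rep_len(as.logical(acrydite), length(name)),
             crosslink_system = rep_len(as.character(crosslink_system), length(name)),
             stringsAsFactors = FALSE)
}

#' Hardware profile of the patterning instrument
#'
#' @param n_ink_ports Number of ink inlet ports (default 4; a 5th port carries
#'   wash buffer).
#' @param dead_volume_ul Tubing dead volume, microliters.
#' @param pixel_size_um Micrometers per DMD pixel at the sample plane.
#' @param flow_rate_ul_s Nominal flow rate, microliters per second (default
#'   0.1: chamber volumes are on the microliter scale, so second-scale flows
#'   move fractions of a microliter, which is what lets a whole multi-round
#'   experiment run from a 100-150 uL vial).
#' @param min_volume_ul Minimum working vial volume for reliable patterning,
#'   microliters. Default 100; patterning has been demonstrated down to 50.
#' @param dmd_dim DMD mirror array dimensions (rows, cols).
#' @return An object of class `hardware_profile`.
#' @export
hardware_profile <- function(n_ink_ports = 4L, dead_volume_ul = 10,
                             pixel_size_um = 1, flow_rate_ul_s = 0.1,
                             min_volume_ul = 100, dmd_dim = c(684L, 608L)) {
  structure(list(n_ink_ports = as.integer(n_ink_ports),
                 dead_volume_ul = dead_volume_ul, pixel_size_um = pixel_size_um,
                 flow_rate_ul_s = flow_rate_ul_s, min_volume_ul = min_volume_ul,
                 dmd_dim = as.integer(dmd_dim)),
            class = "hardware_profile")
}

#' Rectangular DMD mask
#'
#' Rasterizes a `width_um x height_um` rectangle into DMD pixel space: the
#' on-region is `round(width / pixel_size) x round(height / pixel_size)`
#' mirrors, centered in the array.
#'
#' @param width_um,height_um Mask dimensions, micrometers.
#' @param pixel_size_um Micrometers per DMD pixel.
#' @param name Mask name (used as `mask_ref` in commands).
#' @return An object of class `dmd_mask` with fields `name`, `bitmap` (0/1
#'   matrix of the on-region), `pixel_size_um`, `nominal_width_um`,
#'   `nominal_height_um`.
#' @export
make_rect_mask <- function(width_um, height_um = width_um, pixel_size_um = 1,
                           name = sprintf("rect_%gx%g", width_um, height_um)) {
  if (width_um <= 0 || height_um <= 0 || pixel_size_um <= 0) {
    stop("invalid-parameter: mask dimensions must be > 0", call. = FALSE)
  }
  w <- round(width_um / pixel_size_um)
  h <- round(height_um / pixel_size_um)
  if (w < 1 || h < 1) {
    stop("invalid-parameter: mask rounds to zero pixels at this pixel size",
         call. = FALSE)
  }
  structure(list(name = name, bitmap = matrix(1L, nrow = h, ncol = w),
                 pixel_size_um = pixel_size_um,
                 nominal_width_um = width_um, nominal_height_um = height_um),
            class = "dmd_mask")
}

# --- command constructors -------------------------------------------------

cmd <- function(op, ...) {
  x <- c(list(op = op), list(...))
  structure(x, class = "pattern_command")
}

#' Protocol commands
#'
#' Constructors for the seven command types of the instrument command stream.
#' Durations are seconds, positions micrometers.
#'
#' @param vial_id Vial to flow from.
#' @param duration_s Duration in seconds (must be > 0).
#' @name commands
#' @export
cmd_flow <- function(vial_id, duration_s) {
  if (duration_s <= 0) stop("invalid-parameter: duration must be > 0", call. = FALSE)
  cmd("FLOW", vial_id = as.integer(vial_id), duration_s = as.numeric(duration_s))
}

#' @rdname commands
#' @param x,y Stage position, micrometers.
#' @export
cmd_move <- function(x, y) cmd("MOVE", x = as.numeric(x), y = as.numeric(y))

#' @rdname commands
#' @param mask_ref Name of a mask registered in the protocol.
#' @param exposure_s UV exposure, seconds (default 1, the reduced exposure used
#'   for DNA-crosslinked inks).
#' @param intensity_label Free-text intensity setting.
#' @export
cmd_pattern <- function(mask_ref, exposure_s = 1, intensity_label = "UV") {
  if (exposure_s <= 0) stop("invalid-parameter: exposure must be > 0", call. = FALSE)
  cmd("PATTERN", mask_ref = mask_ref, exposure_s = as.numeric(exposure_s),
      intensity_label = intensity_label)
}

#' @rdname commands
#' @export
cmd_wash <- function(duration_s = 30) {
  if (duration_s <= 0) stop("invalid-parameter: duration must be > 0", call. = FALSE)
  cmd("WASH", duration_s = as.numeric(duration_s))
}

#' @rdname commands
#' @param strands Character vector of strand names to add to the surrounding
#'   solution (quencher strands or swelling-signal hairpins).
#' @param final_conc_nM Final concentrations, nM (recycled).
#' @export
cmd_add_solution <- function(strands, final_conc_nM) {
  cmd("ADD_SOLUTION", strands = as.character(strands),
      final_conc_nM = as.numeric(rep_len(final_conc_nM, length(strands))))
}

#' @rdname commands
#' @export
cmd_dissolve_sacrificial <- function(duration_s = 3600) {
  if (duration_s <= 0) stop("invalid-parameter: duration must be > 0", call. = FALSE)
  cmd("DISSOLVE_SACRIFICIAL", duration_s = as.numeric(duration_s))
}

#' @rdname commands
#' @export
cmd_collect <- function() cmd("COLLECT")

#' @export
print.pattern_command <- function(x, ...) {
  args <- x[setdiff(names(x), "op")]
  cat(sprintf("%s(%s)\n", x$op,
              paste(names(args), vapply(args, function(a) paste(a, collapse = ","), ""),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

# --- protocol -------------------------------------------------------------

#' Construct a patterning protocol
#'
#' A protocol is an ordered command stream plus the vial inventory, the wash
#' vial, the hardware profile, and the mask registry. The core round grammar:
#' between consecutive WASH commands, all FLOW commands reference exactly one
#' ink vial (a "patterning round" = ink flow, printing, washing).
#'
#' @param commands List of commands built with the `cmd_*()` constructors.
#' @param vials List of [ink_spec()] objects.
#' @param wash_vial_id Vial carrying wash buffer (default 5).
#' @param hardware A [hardware_profile()].
#' @param masks Named list of [make_rect_mask()] masks; every `PATTERN`
#'   `mask_ref` must resolve here.
#' @return An object of class `mapdh_protocol`.
#' @export
protocol <- function(commands = list(), vials = list(), wash_vial_id = 5L,
                     hardware = hardware_profile(), masks = list()) {
  vial_ids <- vapply(vials, function(v) v$vial_id, integer(1))
  if (anyDuplicated(vial_ids)) stop("invalid-input: duplicate vial ids", call. = FALSE)
  mask_names <- vapply(masks, function(m) m$name, character(1))
  names(masks) <- mask_names
  for (cm in commands) {
    if (cm$op == "PATTERN" && !(cm$mask_ref %in% mask_names)) {
      stop("invalid-input: unresolved mask_ref: ", cm$mask_ref, call. = FALSE)
    }
    if (cm$op == "FLOW" && !(cm$vial_id %in% c(vial_ids, wash_vial_id))) {
      stop("invalid-input: FLOW references unknown vial ", cm$vial_id, call. = FALSE)
    }
  }
  structure(list(schema_version = "1", commands = commands, vials = vials,
                 wash_vial_id = as.integer(wash_vial_id), hardware = hardware,
                 masks = masks),
            class = "mapdh_protocol")
}

#' @export
print.mapdh_protocol <- function(x, ...) {
  ops <- vapply(x$commands, function(cm) cm$op, character(1))
  cat(sprintf("<mapdh_protocol> %d commands (%d rounds), %d vials, %d masks\n",
              length(ops), sum(ops == "WASH"), length(x$vials), length(x$masks)))
  invisible(x)
}

#' Number of patterning rounds (WASH-terminated segments)
#' @param p A `mapdh_protocol`.
#' @export
n_rounds <- function(p) sum(vapply(p$commands, function(cm) cm$op, "") == "WASH")

#' Compile a layout and ink assignment into a protocol
#'
#' Expands the round grammar: for each round (by default one round per domain,
#' in the order domains appear in the layout), emit `FLOW(vial)`, then for each
#' site of that domain `MOVE`, `FLOW(vial, reflow_s)` (a short re-flow of the
#' round's ink just before exposure, which keeps patterned sizes uniform), and
#' `PATTERN`; the round ends with a `WASH`. A wash is emitted after the final
#' round as well.
#'
#' @param layout A [domain_layout()].
#' @param inks Named integer vector mapping `domain_id` to `vial_id`
#'   (names are domain ids).
#' @param masks Named list mapping `domain_id` to a [make_rect_mask()] mask.
#'   If `NULL`, a rectangular mask matching each domain's site size is built.
#' @param vials List of [ink_spec()]; if `NULL`, default 150-uL inks are
#'   synthesized for every referenced vial.
#' @param params List of durations: `flow_s` (primary ink flow, default 10),
#'   `reflow_s` (pre-exposure re-flow, default 3), `exposure_s` (default 1),
#'   `wash_s` (default 30).
#' @param hardware A [hardware_profile()].
#' @param wash_vial_id Wash vial (default 5).
#' @return A `mapdh_protocol`.
#' @export
compile_protocol <- function(layout, inks, masks = NULL, vials = NULL,
                             params = list(), hardware = hardware_profile(),
                             wash_vial_id = 5L) {
  par <- utils::modifyList(list(flow_s = 10, reflow_s = 3, exposure_s = 1,
                                wash_s = 30), params)
  sites <- layout$sites
  domain_ids <- unique(sites$domain_id)
  for (d in domain_ids) {
    if (!(as.character(d) %in% names(inks))) {
      stop("compilation error: no ink mapped for domain ", d, call. = FALSE)
    }
  }
  if (length(unique(inks[as.character(domain_ids)])) > hardware$n_ink_ports) {
    stop("validation error: more distinct ink vials than ink ports (",
         hardware$n_ink_ports, ")", call. = FALSE)
  }
  if (is.null(masks)) {
    masks <- lapply(domain_ids, function(d) {
      s <- sites[sites$domain_id == d, ][1L, ]
      make_rect_mask(s$width, s$height, hardware$pixel_size_um,
                     name = sprintf("mask_d%d", d))
    })
    names(masks) <- as.character(domain_ids)
  }
  for (d in domain_ids) {
    if (!(as.character(d) %in% names(masks))) {
      stop("compilation error: no mask mapped for domain ", d, call. = FALSE)
    }
  }
  if (is.null(vials)) {
    vials <- lapply(sort(unique(as.integer(inks[as.character(domain_ids)]))),
                    ink_spec)
  }
  cmds <- list()
  for (d in domain_ids) {
    v <- as.integer(inks[[as.character(d)]])
    cmds[[length(cmds) + 1L]] <- cmd_flow(v, par$flow_s)
    ds <- sites[sites$domain_id == d, , drop = FALSE]
    for (r in seq_len(nrow(ds))) {
      cmds[[length(cmds) + 1L]] <- cmd_move(ds$center_x[r], ds$center_y[r])
      cmds[[length(cmds) + 1L]] <- cmd_flow(v, par$reflow_s)
      cmds[[length(cmds) + 1L]] <- cmd_pattern(masks[[as.character(d)]]$name,
                                               par$exposure_s)
    }
    cmds[[length(cmds) + 1L]] <- cmd_wash(par$wash_s)
  }
  protocol(cmds, vials = vials, wash_vial_id = wash_vial_id,
           hardware = hardware, masks = unname(masks))
}

#' Validate a protocol against instrument constraints
#'
#' Checks, without executing: (a) the number of distinct ink vials does not
#' exceed the hardware's ink ports (default 4); (b) every referenced vial holds
#' at least the minimum working volume (default 100 uL); (c) every PATTERN is
#' preceded, within its round, by a FLOW of an ink vial ("pattern without
#' ink"); (d) a terminal WASH follows the last patterning round.
#'
#' @param p A `mapdh_protocol`.
#' @return A `protocol_validation`: list with `pass` (logical) and `violations`
#'   (data.frame with columns `rule`, `message`).
#' @export
validate_protocol <- function(p) {
  viol <- data.frame(rule = character(), message = character())
  add <- function(rule, message) {
    viol <<- rbind(viol, data.frame(rule = rule, message = message))
  }
  ops <- vapply(p$commands, function(cm) cm$op, character(1))
  flow_vials <- vapply(p$commands[ops == "FLOW"], function(cm) cm$vial_id, integer(1))
  ink_vials <- unique(setdiff(flow_vials, p$wash_vial_id))
  if (length(ink_vials) > p$hardware$n_ink_ports) {
    add("ink ports exceeded",
        sprintf("%d distinct ink vials but only %d ink ports",
                length(ink_vials), p$hardware$n_ink_ports))
  }
  for (v in p$vials) {
    if (v$vial_id %in% ink_vials && v$volume_ul < p$hardware$min_volume_ul) {
      add("insufficient ink volume",
          sprintf("vial %d holds %g uL, below the %g uL minimum working volume",
                  v$vial_id, v$volume_ul, p$hardware$min_volume_ul))
    }
  }
  current_ink <- NA_integer_
  for (i in seq_along(p$commands)) {
    cm <- p$commands[[i]]
    if (cm$op == "FLOW" && cm$vial_id != p$wash_vial_id) current_ink <- cm$vial_id
    if (cm$op == "WASH") current_ink <- NA_integer_
    if (cm$op == "PATTERN" && is.na(current_ink)) {
      add("pattern without ink",
          sprintf("command %d: PATTERN with no preceding FLOW in its round", i))
    }
  }
  if (any(ops == "PATTERN")) {
    last_pat <- max(which(ops == "PATTERN"))
    if (!any(ops[seq_along(ops) > last_pat] == "WASH")) {
      add("missing terminal wash", "no WASH after the final patterning round")
    }
  }
  structure(list(pass = nrow(viol) == 0L, violations = viol),
            class = "protocol_validation")
}

#' @export
print.protocol_validation <- function(x, ...) {
  cat(sprintf("<protocol_validation> %s\n", if (x$pass) "PASS" else "FAIL"))
  if (nrow(x$violations)) {
    for (i in seq_len(nrow(x$violations))) {
      cat(sprintf("  - [%s] %s\n", x$violations$rule[i], x$violations$message[i]))
    }
  }
  invisible(x)
}

#' Estimate per-vial ink usage
#'
#' `usage(v) = flow_rate * sum of FLOW(v) durations`.
#'
#' @param p A `mapdh_protocol`.
#' @param flow_rate Flow rate in uL/s (> 0); defaults to the hardware profile.
#' @return Named numeric vector of microliters, one entry per protocol vial.
#' @export
estimate_ink_usage <- function(p, flow_rate = p$hardware$flow_rate_ul_s) {
  if (flow_rate <= 0) stop("invalid-parameter: flow_rate must be > 0", call. = FALSE)
  vial_ids <- vapply(p$vials, function(v) v$vial_id, integer(1))
  usage <- stats::setNames(numeric(length(vial_ids)), vial_ids)
  for (cm in p$commands) {
    if (cm$op == "FLOW" && cm$vial_id != p$wash_vial_id) {
      key <- as.character(cm$vial_id)
      if (!key %in% names(usage)) stop("unknown vial in FLOW: ", key, call. = FALSE)
      usage[key] <- usage[key] + flow_rate * cm$duration_s
    }
  }
  usage
}
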