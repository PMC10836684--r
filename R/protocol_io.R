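# Protocol serialization. JSON is canonical; YAML is accepted on read.
# Schema is versioned and strict: unknown fields are rejected on parse.

CMD_FIELDS <- list(
  FLOW = c("vial_id", "duration_s"),
  MOVE = c("x", "y"),
  PATTERN = c("mask_ref", "exposure_s", "intensity_label"),
  WASH = c("duration_s"),
  ADD_SOLUTION = c("strands", "final_conc_nM"),
  DISSOLVE_SACRIFICIAL = c("duration_s"),
  COLLECT = character()
)

INK_FIELDS <- c("vial_id", "strands", "monomer_label", "monomer_vv_percent",
                "photoinitiator_label", "photoinitiator_wv_percent", "volume_ul")
TOP_FIELDS <- c("schema_version", "commands", "vials", "wash_vial_id",
                "hardware", "masks")
HW_FIELDS <- c("n_ink_ports", "dead_volume_ul", "pixel_size_um",
               "flow_rate_ul_s", "min_volume_ul", "dmd_dim")
MASK_FIELDS <- c("name", "bitmap", "pixel_size_um", "nominal_width_um",
                 "nominal_height_um")

#' Serialize a protocol to a JSON file
#'
#' The file is schema-versioned; [parse_protocol()] of the output reproduces
#' the protocol exactly (round-trip identity).
#'
#' @param p A `mapdh_protocol`.
#' @param path Output path (`.json`).
#' @return Invisibly, `path`.
#' @export
serialize_protocol <- function(p, path) {
  stopifnot(inherits(p, "mapdh_protocol"))
  obj <- list(
    schema_version = p$schema_version,
    commands = lapply(p$commands, function(cm) {
      x <- cm[c("op", CMD_FIELDS[[cm$op]])]
      x$op <- cm$op
      x
    }),
    vials = lapply(p$vials, function(v) {
      list(vial_id = v$vial_id, strands = v$strands,
           monomer_label = v$monomer_label,
           monomer_vv_percent = v$monomer_vv_percent,
           photoinitiator_label = v$photoinitiator_label,
           photoinitiator_wv_percent = v$photoinitiator_wv_percent,
           volume_ul = v$volume_ul)
    }),
    wash_vial_id = p$wash_vial_id,
    hardware = unclass(p$hardware),
    masks = lapply(unname(p$masks), function(m) {
      list(name = m$name,
           bitmap = unname(apply(m$bitmap, 1L, as.integer, simplify = FALSE)),
           pixel_size_um = m$pixel_size_um,
           nominal_width_um = m$nominal_width_um,
           nominal_height_um = m$nominal_height_um)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

parse_fail <- function(field, msg) {
  stop(sprintf("parse error at `%s`: %s", field, msg), call. = FALSE)
}

check_fields <- function(x, allowed, required, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) parse_fail(where, paste("unknown field(s):",
                                               paste(unknown, collapse = ", ")))
  missing <- setdiff(required, names(x))
  if (length(missing)) parse_fail(where, paste("missing field(s):",
                                               paste(missing, collapse = ", ")))
}

#' Parse a protocol file
#'
#' Reads JSON (canonical) or YAML (by extension `.yml`/`.yaml`). The schema is
#' strict: unknown fields, missing sections, and unknown command ops raise a
#' parse error naming the offending field.
#'
#' @param path Protocol file path.
#' @return A `mapdh_protocol`.
#' @export
parse_protocol <- function(path) {
  if (!file.exists(path)) parse_fail(path, "no such file")
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) {
    y <- yaml::read_yaml(path)
    # YAML 1.1 reads the bare key `y` as boolean TRUE; restore it on MOVEs
    y$commands <- lapply(y$commands, function(cm) {
      names(cm)[names(cm) == "TRUE"] <- "y"
      cm
    })
    y
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  check_fields(raw, TOP_FIELDS,
               c("schema_version", "commands", "vials", "wash_vial_id"),
               "protocol")
  if (!identical(as.character(raw$schema_version), "1")) {
    parse_fail("schema_version", paste("unsupported version:", raw$schema_version))
  }
  cmds <- lapply(seq_along(raw$commands), function(i) {
    cm <- raw$commands[[i]]
    where <- sprintf("commands[%d]", i)
    if (is.null(cm$op) || !(cm$op %in% names(CMD_FIELDS))) {
      parse_fail(where, paste("unknown op:", cm$op))
    }
    check_fields(cm, c("op", CMD_FIELDS[[cm$op]]), c("op", CMD_FIELDS[[cm$op]]), where)
    switch(cm$op,
      FLOW = cmd_flow(cm$vial_id, cm$duration_s),
      MOVE = cmd_move(cm$x, cm$y),
      PATTERN = cmd_pattern(cm$mask_ref, cm$exposure_s, cm$intensity_label),
      WASH = cmd_wash(cm$duration_s),
      ADD_SOLUTION = cmd_add_solution(unlist(cm$strands), unlist(cm$final_conc_nM)),
      DISSOLVE_SACRIFICIAL = cmd_dissolve_sacrificial(cm$duration_s),
      COLLECT = cmd_collect())
  })
  vials <- lapply(seq_along(raw$vials), function(i) {
    v <- raw$vials[[i]]
    where <- sprintf("vials[%d]", i)
    check_fields(v, INK_FIELDS, INK_FIELDS, where)
    s <- v$strands
    st <- if (length(s) == 0L) strand_table() else strand_table(
      name = vapply(s, function(r) r$name, ""),
      concentration_nM = vapply(s, function(r) as.numeric(r$concentration_nM), 0),
      fluorophore = vapply(s, function(r) {
        if (is.null(r$fluorophore)) NA_character_ else as.character(r$fluorophore)
      }, ""),
      acrydite = vapply(s, function(r) isTRUE(r$acrydite), TRUE),
      crosslink_system = vapply(s, function(r) {
        if (is.null(r$crosslink_system)) NA_character_ else as.character(r$crosslink_system)
      }, ""))
    ink_spec(v$vial_id, strands = st, monomer_label = v$monomer_label,
             monomer_vv_percent = v$monomer_vv_percent,
             photoinitiator_label = v$photoinitiator_label,
             photoinitiator_wv_percent = v$photoinitiator_wv_percent,
             volume_ul = v$volume_ul)
  })
  hw <- if (is.null(raw$hardware)) hardware_profile() else {
    check_fields(raw$hardware, HW_FIELDS, HW_FIELDS, "hardware")
    hardware_profile(raw$hardware$n_ink_ports, raw$hardware$dead_volume_ul,
                     raw$hardware$pixel_size_um, raw$hardware$flow_rate_ul_s,
                     raw$hardware$min_volume_ul, unlist(raw$hardware$dmd_dim))
  }
  masks <- lapply(seq_along(raw$masks), function(i) {
    m <- raw$masks[[i]]
    where <- sprintf("masks[%d]", i)
    check_fields(m, MASK_FIELDS, MASK_FIELDS, where)
    bitmap <- do.call(rbind, lapply(m$bitmap, function(r) as.integer(unlist(r))))
    structure(list(name = m$name, bitmap = bitmap,
                   pixel_size_um = as.numeric(m$pixel_size_um),
                   nominal_width_um = as.numeric(m$nominal_width_um),
                   nominal_height_um = as.numeric(m$nominal_height_um)),
              class = "dmd_mask")
  })
  protocol(cmds, vials = vials, wash_vial_id = raw$wash_vial_id,
           hardware = hw, masks = masks)
}
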