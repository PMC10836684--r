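test_that("compile_protocol expands the round grammar", {
  # 1 domain, 1 site: exactly FLOW, MOVE, FLOW(reflow), PATTERN, WASH
  lay <- domain_layout(data.frame(domain_id = 1L, center_x = 5, center_y = 7,
                                  width = 50, height = 50))
  p <- compile_protocol(lay, inks = c("1" = 1L))
  expect_equal(vapply(p$commands, function(cm) cm$op, ""),
               c("FLOW", "MOVE", "FLOW", "PATTERN", "WASH"))
  expect_equal(p$commands[[2]]$x, 5)
  expect_equal(p$commands[[3]]$duration_s, 3)  # default reflow of a few seconds

  # 12-round characterization run: 12 rounds, 60 exposures, wash per round
  p12 <- compile_protocol(grid_column_layout(), inks = cyclic_vial_map(),
                          vials = fluor_ink_set())
  ops <- vapply(p12$commands, function(cm) cm$op, "")
  expect_equal(n_rounds(p12), 12L)
  expect_equal(sum(ops == "WASH"), 12L)
  expect_equal(sum(ops == "PATTERN"), 60L)

  # empty layout: no PATTERN, no WASH
  p0 <- compile_protocol(domain_layout(data.frame(domain_id = integer(),
                                                  center_x = numeric(),
                                                  center_y = numeric(),
                                                  width = numeric(),
                                                  height = numeric())),
                         inks = integer())
  expect_length(p0$commands, 0L)

  expect_error(compile_protocol(lay, inks = c("9" = 1L)), "no ink mapped")
})

test_that("each compiled round references exactly one ink vial", {
  p <- compile_protocol(grid_column_layout(6, 3), inks = cyclic_vial_map(6, 4),
                        vials = fluor_ink_set())
  vial_now <- integer()
  per_round <- list()
  for (cm in p$commands) {
    if (cm$op == "FLOW") vial_now <- union(vial_now, cm$vial_id)
    if (cm$op == "WASH") {
      per_round[[length(per_round) + 1L]] <- vial_now
      vial_now <- integer()
    }
  }
  expect_length(per_round, 6L)
  expect_true(all(lengths(per_round) == 1L))
  # rounds with the same ink are not merged
  expect_equal(unlist(per_round), c(1L, 2L, 3L, 4L, 1L, 2L))
})

test_that("compilation is deterministic and passes validation", {
  build <- function() compile_protocol(grid_column_layout(4, 2),
                                       inks = cyclic_vial_map(4, 4),
                                       vials = fluor_ink_set())
  expect_identical(build(), build())
  expect_true(validate_protocol(build())$pass)
})

test_that("validate_protocol enforces port count, volume, and grammar", {
  # 5 distinct ink vials under the default 4-port profile
  vials5 <- c(fluor_ink_set(), list(ink_spec(6L, strand_table("x", 1, "Cy3"))))
  lay5 <- grid_column_layout(5, 1)
  expect_error(compile_protocol(lay5, inks = cyclic_vial_map(5, 5) + 0L,
                                vials = vials5),
               "validation error")
  # build the same stream by hand to exercise the report path
  cmds <- unlist(lapply(c(1L, 2L, 3L, 4L, 6L), function(v) {
    list(cmd_flow(v, 10), cmd_move(0, 0), cmd_pattern("m", 1), cmd_wash(30))
  }), recursive = FALSE)
  p5 <- protocol(cmds, vials = vials5,
                 masks = list(make_rect_mask(50, name = "m")))
  rep5 <- validate_protocol(p5)
  expect_false(rep5$pass)
  expect_true("ink ports exceeded" %in% rep5$violations$rule)

  # volume rule: exactly 100 uL passes, 99 uL fails
  lay <- domain_layout(data.frame(domain_id = 1L, center_x = 0, center_y = 0,
                                  width = 50, height = 50))
  p_ok <- compile_protocol(lay, inks = c("1" = 1L),
                           vials = list(ink_spec(1L, volume_ul = 100)))
  expect_true(validate_protocol(p_ok)$pass)
  p_low <- compile_protocol(lay, inks = c("1" = 1L),
                            vials = list(ink_spec(1L, volume_ul = 99)))
  rep_low <- validate_protocol(p_low)
  expect_false(rep_low$pass)
  expect_true("insufficient ink volume" %in% rep_low$violations$rule)
  # documented override down to 50 uL
  hw50 <- hardware_profile(min_volume_ul = 50)
  p50 <- compile_protocol(lay, inks = c("1" = 1L),
                          vials = list(ink_spec(1L, volume_ul = 50)),
                          hardware = hw50)
  expect_true(validate_protocol(p50)$pass)

  # PATTERN immediately after WASH with no FLOW
  pbad <- protocol(list(cmd_flow(1L, 5), cmd_pattern("m", 1), cmd_wash(10),
                        cmd_pattern("m", 1), cmd_wash(10)),
                   vials = list(ink_spec(1L)),
                   masks = list(make_rect_mask(50, name = "m")))
  repb <- validate_protocol(pbad)
  expect_false(repb$pass)
  expect_true("pattern without ink" %in% repb$violations$rule)

  # missing terminal wash
  pnw <- protocol(list(cmd_flow(1L, 5), cmd_pattern("m", 1)),
                  vials = list(ink_spec(1L)),
                  masks = list(make_rect_mask(50, name = "m")))
  expect_true("missing terminal wash" %in% validate_protocol(pnw)$violations$rule)
})

test_that("estimate_ink_usage sums flow durations and is monotone", {
  p0 <- protocol(list(), vials = list(ink_spec(1L), ink_spec(2L)))
  expect_equal(unname(estimate_ink_usage(p0, 1)), c(0, 0))

  p <- protocol(list(cmd_flow(1L, 5), cmd_flow(1L, 5)),
                vials = list(ink_spec(1L)))
  expect_equal(unname(estimate_ink_usage(p, 1)), 10)
  expect_equal(unname(estimate_ink_usage(p, 2.5)), 25)

  p_more <- protocol(list(cmd_flow(1L, 5), cmd_flow(1L, 5), cmd_flow(1L, 2)),
                     vials = list(ink_spec(1L)))
  expect_gte(unname(estimate_ink_usage(p_more, 1)),
             unname(estimate_ink_usage(p, 1)))
  expect_error(estimate_ink_usage(p, 0), "invalid-parameter")
})

test_that("make_rect_mask rasterizes to the rounded pixel count", {
  m50 <- make_rect_mask(50, 50, 1)
  expect_equal(dim(m50$bitmap), c(50L, 50L))
  m10 <- make_rect_mask(10, 10, 1)
  expect_equal(dim(m10$bitmap), c(10L, 10L))
  m <- make_rect_mask(20, 10, 2)
  expect_equal(dim(m$bitmap), c(5L, 10L))
  expect_error(make_rect_mask(10, 10, 25), "zero pixels")
  expect_error(make_rect_mask(-1, 10, 1), "invalid-parameter")
})

test_that("protocol serialization round-trips and rejects malformed files", {
  p <- compile_protocol(grid_column_layout(12, 5), inks = cyclic_vial_map(),
                        vials = fluor_ink_set())
  f <- withr::local_tempfile(fileext = ".json")
  serialize_protocol(p, f)
  expect_equal(parse_protocol(f), p)

  # solution/lift-off command coverage in the same round trip
  p2 <- protocol(list(cmd_flow(1L, 5), cmd_pattern("m", 1), cmd_wash(10),
                      cmd_add_solution(c("5Q_R1p"), 500),
                      cmd_dissolve_sacrificial(3600), cmd_collect()),
                 vials = list(ink_spec(1L)),
                 masks = list(make_rect_mask(20, 20, 1, name = "m")))
  f2 <- withr::local_tempfile(fileext = ".json")
  serialize_protocol(p2, f2)
  expect_equal(parse_protocol(f2), p2)

  # missing vials section
  raw <- jsonlite::read_json(f, simplifyVector = FALSE)
  raw$vials <- NULL
  f3 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(raw, f3, auto_unbox = TRUE, digits = NA)
  expect_error(parse_protocol(f3), "missing field.*vials")

  # unknown field rejected
  raw2 <- jsonlite::read_json(f, simplifyVector = FALSE)
  raw2$extra_knob <- 1
  f4 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(raw2, f4, auto_unbox = TRUE, digits = NA)
  expect_error(parse_protocol(f4), "unknown field.*extra_knob")

  # unknown command op rejected with location context
  raw3 <- jsonlite::read_json(f, simplifyVector = FALSE)
  raw3$commands[[1]]$op <- "TELEPORT"
  f5 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(raw3, f5, auto_unbox = TRUE, digits = NA)
  expect_error(parse_protocol(f5), "commands\\[1\\].*unknown op")
})

test_that("hand-written minimal YAML protocol parses to one round", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "schema_version: '1'",
    "wash_vial_id: 5",
    "commands:",
    "  - {op: FLOW, vial_id: 1, duration_s: 10}",
    "  - {op: MOVE, x: 0, y: 0}",
    "  - {op: FLOW, vial_id: 1, duration_s: 3}",
    "  - {op: PATTERN, mask_ref: sq, exposure_s: 1, intensity_label: UV}",
    "  - {op: WASH, duration_s: 30}",
    "vials:",
    "  - vial_id: 1",
    "    strands: []",
    "    monomer_label: PEGDA-575",
    "    monomer_vv_percent: 10",
    "    photoinitiator_label: LAP",
    "    photoinitiator_wv_percent: 1",
    "    volume_ul: 150",
    "masks:",
    "  - name: sq",
    "    bitmap: [[1, 1], [1, 1]]",
    "    pixel_size_um: 25",
    "    nominal_width_um: 50",
    "    nominal_height_um: 50"), f)
  p <- parse_protocol(f)
  expect_s3_class(p, "mapdh_protocol")
  expect_equal(n_rounds(p), 1L)
  expect_true(validate_protocol(p)$pass)
})
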