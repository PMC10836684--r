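test_that("executing the 12-round run yields 60 attached domains, 4 compositions", {
  p <- compile_protocol(grid_column_layout(), inks = cyclic_vial_map(),
                        vials = fluor_ink_set())
  res <- execute(p, seed = 1, config = run_config(p_washoff = 0))
  att <- domains_with_status(res$state, "attached")
  expect_length(att, 60L)
  comps <- unique(vapply(att, function(d) paste(sort(d$composition$name),
                                                collapse = "+"), ""))
  expect_length(comps, 4L)
  # mass ledger: vial decrease equals rate x total FLOW duration per vial
  usage <- estimate_ink_usage(p)
  for (v in p$vials) {
    expect_equal(v$volume_ul - res$state$vials[[as.character(v$vial_id)]],
                 unname(usage[as.character(v$vial_id)]))
  }
})

test_that("execution errors on wrong chamber content and empty vials", {
  masks <- list(make_rect_mask(50, name = "m"))
  p_dry <- protocol(list(cmd_move(0, 0), cmd_pattern("m", 1), cmd_wash(10)),
                    vials = list(ink_spec(1L)), masks = masks)
  expect_error(execute(p_dry, seed = 1), "execution error: PATTERN")

  p_wash_first <- protocol(list(cmd_flow(5L, 10), cmd_pattern("m", 1),
                                cmd_wash(10)),
                           vials = list(ink_spec(1L)), masks = masks)
  expect_error(execute(p_wash_first, seed = 1), "execution error: PATTERN")

  p_thirsty <- protocol(list(cmd_flow(1L, 10), cmd_pattern("m", 1), cmd_wash(5)),
                        vials = list(ink_spec(1L, volume_ul = 0.5)), masks = masks)
  expect_error(execute(p_thirsty, seed = 1), "execution error: vial 1 empty")
})

test_that("execution is reproducible per seed", {
  p <- compile_protocol(strip_grid_layout(5), inks = c("1" = 1L, "2" = 2L, "3" = 3L),
                        vials = crosslinked_vial_set())
  r1 <- execute(p, seed = 42, config = run_config(), sacrificial = TRUE)
  r2 <- execute(p, seed = 42, config = run_config(), sacrificial = TRUE)
  expect_identical(r1$state, r2$state)
  expect_identical(r1$events, r2$events)
})

test_that("wash-off losses match the Bernoulli detachment model", {
  # 25 three-domain sites, 3 rounds, p_washoff = 0.25 per wash:
  # P(site intact) = 0.75^3, expected lost = 25 * (1 - 0.75^3) = 14.45.
  # The bench observation (12 of 25 lost) lies within binomial sampling error
  # of that expectation (sd = 2.47).
  p <- compile_protocol(strip_grid_layout(25), inks = c("1" = 1L, "2" = 2L, "3" = 3L),
                        vials = crosslinked_vial_set())
  lost <- vapply(1:12, function(s) {
    st <- execute(p, seed = s, config = run_config(p_washoff = 0.25),
                  sacrificial = TRUE)$state
    att <- domains_with_status(st, "attached")
    intact <- sum(table(vapply(att, function(d) d$architecture_id, 0L)) == 3L)
    25 - intact
  }, numeric(1))
  p_lost <- 1 - 0.75^3
  se_mean <- sqrt(25 * p_lost * (1 - p_lost)) / sqrt(length(lost))
  expect_lt(abs(mean(lost) - 25 * p_lost), 3 * se_mean)
  # the bench count (12 lost) is a plausible draw from the model
  expect_lte(abs(12 - 25 * p_lost), 2 * sqrt(25 * p_lost * (1 - p_lost)))
})

test_that("dissolution releases everything; collection with p = 1 recovers all", {
  p <- compile_protocol(strip_grid_layout(4), inks = c("1" = 1L, "2" = 2L, "3" = 3L),
                        vials = crosslinked_vial_set(),
                        wash_vial_id = 5L)
  cfg <- run_config(p_washoff = 0, p_collect = 1)
  st <- execute(p, seed = 1, config = cfg, sacrificial = TRUE)$state
  post <- protocol(list(cmd_dissolve_sacrificial(3600), cmd_collect()),
                   vials = crosslinked_vial_set())
  st2 <- execute(post, init = st, seed = 1)$state
  expect_length(domains_with_status(st2, "attached"), 0L)
  expect_length(domains_with_status(st2, "collected"), 12L)
  expect_false(st2$sacrificial_intact)
})

test_that("overlapping domains merge into one architecture; separated ones do not", {
  p <- compile_protocol(make_strip_layout(3, 200, 10),
                        inks = c("1" = 1L, "2" = 2L, "3" = 3L),
                        vials = crosslinked_vial_set())
  st <- execute(p, seed = 1, config = run_config(p_washoff = 0),
                sacrificial = TRUE)$state
  archs <- vapply(st$domains, function(d) d$architecture_id, 0L)
  expect_length(unique(archs), 1L)

  p2 <- compile_protocol(make_strip_layout(2, 200, 0) , # abutting, no overlap
                         inks = c("1" = 1L, "2" = 2L),
                         vials = crosslinked_vial_set()[1:2])
  st2 <- execute(p2, seed = 1)$state
  expect_length(unique(vapply(st2$domains, function(d) d$architecture_id, 0L)), 2L)
})

test_that("hybridization quenches only complementary-strand domains", {
  qa <- quenching_architecture(seed = 1)
  st <- hybridize(qa$state, "5Q_R1p", 500, duration_h = 10)
  q <- lapply(st$domains, function(d) d$quenched)
  # circle (Cy3 reporter) and square (all three) rise; triangle and plus don't
  expect_gt(q[[qa$domain_roles["circle"]]][["5Acry_3Cy3_R1"]], 0.99)
  expect_gt(q[[qa$domain_roles["square"]]][["5Acry_3Cy3_R1"]], 0.99)
  expect_equal(q[[qa$domain_roles["square"]]][["5Acry_3ATTO488_polyT10"]], 0)
  expect_equal(q[[qa$domain_roles["triangle"]]][["5Acry_3ATTO488_polyT10"]], 0)
  expect_equal(q[[qa$domain_roles["plus"]]][["5Acry_3TYE665_polyT10"]], 0)

  # partial quenching at short exposure, saturating toward 1
  st_short <- hybridize(qa$state, "5Q_R1p", 500, duration_h = 0.1)
  qf <- st_short$domains[[qa$domain_roles["circle"]]]$quenched[["5Acry_3Cy3_R1"]]
  expect_gt(qf, 0)
  expect_lt(qf, 1)
  st_long <- hybridize(qa$state, "5Q_R1p", 500, duration_h = 1e6)
  expect_equal(st_long$domains[[1]]$quenched[["5Acry_3Cy3_R1"]], 1)

  # a registered strand with no complement present changes nothing
  reg <- rbind(default_strand_registry(),
               data.frame(name = "5Q_orphan", complement_of = "absent_strand",
                          system = NA))
  st0 <- qa$state
  st0$registry <- reg
  expect_identical(hybridize(st0, "5Q_orphan", 500)$domains, st0$domains)
  expect_error(hybridize(qa$state, "not_a_strand", 500), "unknown strand")
})

test_that("rendered quenching contract: square loses one channel only", {
  qa <- quenching_architecture(seed = 1)
  opt <- optics_profile(2, c(-100, -100, 400, 400))
  before <- render(qa$state, opt, seed = 1)
  after <- render(hybridize(qa$state, "5Q_R1p", 500, duration_h = 10),
                  opt, seed = 1)
  # square domain: center (300, 300) um, side 100 um, field origin -100, 2 um/px
  sq <- c(176, 225, 176, 225)
  bg <- 100
  expect_equal(roi_mean_fluorescence(after, sq, "Cy3"), bg, tolerance = 0.05)
  expect_gt(roi_mean_fluorescence(before, sq, "Cy3"), bg + 400)
  for (ch in c("ATTO488", "TYE665")) {
    expect_equal(roi_mean_fluorescence(after, sq, ch),
                 roi_mean_fluorescence(before, sq, ch), tolerance = 0.02)
  }
})

test_that("swelling kinetics: zero at t0, monotone, bounded, selective", {
  lay <- domain_layout(data.frame(domain_id = 1L, center_x = 0, center_y = 0,
                                  width = 200, height = 200))
  p <- compile_protocol(lay, inks = c("1" = 1L),
                        vials = list(crosslinked_ink("S1", 1L)))
  st <- execute(p, seed = 1)$state
  id <- st$domains[[1]]$id

  # no signal: never swells
  st_no <- advance_time(st, 60)
  expect_equal(domain_geometry(st_no, id)$dL_over_L0_free, 0)

  st <- add_swelling_signal(st, "S1", 20)
  expect_equal(domain_geometry(st, id)$dL_over_L0_free, 0)  # exactly 0 at t0
  prev <- 0
  for (t in c(1, 4, 8, 16, 32, 60)) {
    cur <- domain_geometry(advance_time(st, t), id)$dL_over_L0_free
    expect_gte(cur, prev)
    expect_lte(cur, 0.51)
    prev <- cur
  }
  expect_equal(domain_geometry(advance_time(st, 60), id)$dL_over_L0_free,
               0.51, tolerance = 1e-3)
  expect_equal(domain_geometry(advance_time(st, 1e5), id)$dL_over_L0_free, 0.51)
  expect_error(advance_time(st, -1), "invalid-parameter")

  # a domain with no crosslink system is a fixed point of every signal
  lay2 <- domain_layout(data.frame(domain_id = 1L, center_x = 0, center_y = 0,
                                   width = 200, height = 200))
  p2 <- compile_protocol(lay2, inks = c("1" = 1L),
                         vials = list(crosslinked_ink(NA, 1L)))
  st2 <- execute(p2, seed = 1)$state
  st2 <- add_swelling_signal(add_swelling_signal(st2, "S1"), "S2")
  expect_equal(domain_geometry(advance_time(st2, 60),
                               st2$domains[[1]]$id)$dL_over_L0_free, 0)
})

test_that("sequential signals actuate red then blue, never green", {
  vials <- crosslinked_vial_set()
  p <- compile_protocol(make_strip_layout(3, 200, 10),
                        inks = c("1" = 1L, "2" = 2L, "3" = 3L), vials = vials)
  cfg <- run_config(p_washoff = 0, p_collect = 1,
                    swelling = swelling_defaults("multi_domain"))
  st <- execute(p, seed = 1, config = cfg, sacrificial = TRUE)$state
  st <- add_swelling_signal(st, "S1", 20)
  st <- advance_time(st, 24)
  ids <- vapply(st$domains, function(d) d$id, 0L)
  dl <- function(s, i) domain_geometry(s, ids[i])$dL_over_L0_free
  expect_gt(dl(st, 1), 0.3)     # red moving toward 0.4
  expect_equal(dl(st, 2), 0)    # green never
  expect_equal(dl(st, 3), 0)    # blue not yet
  st <- add_swelling_signal(st, "S2", 20)
  st <- advance_time(st, 36)
  expect_equal(dl(st, 1), 0.4, tolerance = 1e-2)
  expect_equal(dl(st, 2), 0)
  expect_gt(dl(st, 3), 0.55)
})

test_that("render: linearity, channel separation, background, reproducibility", {
  mk_state <- function(conc) {
    st <- new_chamber()
    st$domains <- list(mapdh:::new_domain(1L, 0, 0, 60, 60,
                                          strand_table("s1", conc, "Cy3")))
    st
  }
  opt <- optics_profile(1, c(-50, -50, 50, 50))
  quiet <- noise_model(10, 0)
  img1 <- render(mk_state(100), opt, channels = "Cy3", noise = quiet,
                 seed = 1)$channels$Cy3
  img2 <- render(mk_state(200), opt, channels = "Cy3", noise = quiet,
                 seed = 1)$channels$Cy3
  fg <- function(img) mean(img[img > 10]) - 10
  expect_equal(fg(img2), 2 * fg(img1))

  # a strand contributes only to its fluorophore's channel
  stk <- render(mk_state(100), opt, noise = quiet, seed = 1)
  expect_true(all(stk$channels$ATTO488 == 10))
  expect_true(all(stk$channels$TYE665 == 10))
  expect_gt(max(stk$channels$Cy3), 10)

  # empty chamber renders pure background
  stk0 <- render(new_chamber(), opt, noise = noise_model(100, 0), seed = 1)
  expect_true(all(vapply(stk0$channels, function(m) all(m == 100), TRUE)))

  # multi-fluorophore ink is bright in all three channels
  st3 <- new_chamber()
  st3$domains <- list(mapdh:::new_domain(1L, 0, 0, 60, 60, strand_table(
    c("a", "b", "c"), 100, c("Cy3", "ATTO488", "TYE665"))))
  stk3 <- render(st3, opt, noise = quiet, seed = 1)
  for (ch in names(stk3$channels)) expect_gt(max(stk3$channels[[ch]]), 100)

  # pixel-identical micrographs for identical seeds
  sA <- render(mk_state(100), opt, seed = 7)
  sB <- render(mk_state(100), opt, seed = 7)
  expect_identical(sA$channels, sB$channels)
  sC <- render(mk_state(100), opt, seed = 8)
  expect_false(identical(sA$channels$Cy3, sC$channels$Cy3))
})

test_that("render -> measure round-trips nominal size within one pixel", {
  for (size in c(20, 50, 120)) {
    lay <- domain_layout(data.frame(domain_id = 1L, center_x = 0, center_y = 0,
                                    width = size, height = size))
    p <- compile_protocol(lay, inks = c("1" = 1L),
                          vials = list(fluor_ink_set(500)[[1]]))
    st <- execute(p, seed = 1)$state
    stk <- render(st, optics_profile(1, c(-100, -100, 100, 100)),
                  channels = "Cy3", noise = noise_model(0, 0), seed = 1)
    m <- measure_length(stk$channels$Cy3, 1)
    expect_lte(abs(m$length_um - size), 1)
    expect_lte(abs(m$width_um - size), 1)
  }
})

test_that("size-bias calibration shifts polymerized sizes as configured", {
  lay <- domain_layout(data.frame(domain_id = 1L, center_x = 0, center_y = 0,
                                  width = 20, height = 20))
  p <- compile_protocol(lay, inks = c("1" = 1L),
                        vials = list(fluor_ink_set(500)[[1]]))
  st <- execute(p, seed = 1,
                config = run_config(size_bias_um = paper_size_bias))$state
  expect_equal(st$domains[[1]]$w0, 27.1)
  st10 <- execute(compile_protocol(
    domain_layout(data.frame(domain_id = 1L, center_x = 0, center_y = 0,
                             width = 10, height = 10)),
    inks = c("1" = 1L), vials = list(fluor_ink_set(500)[[1]])),
    seed = 1, config = run_config(size_bias_um = paper_size_bias))$state
  expect_equal(st10$domains[[1]]$w0, 13.7)
})

test_that("micrograph stacks round-trip through the directory format", {
  st <- new_chamber()
  st$domains <- list(mapdh:::new_domain(1L, 0, 0, 40, 40,
                                        strand_table("s", 100, "Cy3")))
  stk <- render(st, optics_profile(1, c(-30, -30, 30, 30)), seed = 3)
  d <- withr::local_tempdir()
  write_micrographs(stk, d)
  stk2 <- read_micrographs(d)
  expect_equal(stk2$channels, stk$channels, tolerance = 1e-12)
  expect_equal(stk2$pixel_size_um, stk$pixel_size_um)
  expect_equal(stk2$time_h, stk$time_h)
})

test_that("state snapshots and event logs are written as JSON", {
  p <- compile_protocol(grid_column_layout(2, 1), inks = cyclic_vial_map(2, 2),
                        vials = fluor_ink_set())
  res <- execute(p, seed = 1)
  d <- withr::local_tempdir()
  write_state(res$state, file.path(d, "state.json"))
  write_events(res$events, file.path(d, "events.jsonl"))
  snap <- jsonlite::read_json(file.path(d, "state.json"), simplifyVector = TRUE)
  expect_equal(length(snap$domains$id), 2L)
  lines <- readLines(file.path(d, "events.jsonl"))
  expect_equal(length(lines), nrow(res$events))
  expect_silent(jsonlite::fromJSON(lines[1]))
})
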