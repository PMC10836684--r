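# Synthetic inputs with known ground truth, and end-to-end experiment
# drivers built from them. These are first-class package code: tests and the
# acceptance analyses generate everything here at run time.

WATERMELON_COLORS <- list(
  rind_dark = c(0, 100, 0),      # dark green rind
  rind_light = c(144, 238, 144), # light green inner rind
  flesh = c(220, 20, 60),        # red flesh
  seed_pink = c(255, 105, 180)   # pink (all-three-fluorophores ink)
)

#' Four-color pixel-art test design (15 x 15)
#'
#' A watermelon-slice-style design with exactly four colors, used to exercise
#' the image -> location-map decomposition. Returned as a 15 x 15 integer
#' matrix of color indices (1..4) plus the palette.
#'
#' @return A list with `design` (15 x 15 integer matrix) and `palette`
#'   (4 x 3 RGB matrix).
#' @export
watermelon_design <- function() {
  n <- 15L
  design <- matrix(1L, n, n)  # start as dark-green rind
  cx <- 8; cy <- 3
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < cy) next
      r <- sqrt((i - cy)^2 + (j - cx)^2)
      if (r <= 4.5) design[i, j] <- 3L           # flesh
      else if (r <= 6.0) design[i, j] <- 2L      # light rind
    }
  }
  # pink "seeds" inside the flesh
  design[4, 8] <- 4L; design[6, 6] <- 4L; design[6, 10] <- 4L; design[7, 8] <- 4L
  palette <- do.call(rbind, WATERMELON_COLORS)
  list(design = design, palette = palette)
}

#' Synthetic 355 x 355 four-color test image
#'
#' Upscales the 15 x 15 [watermelon_design()] so that every binning block of
#' [bin_image()] with `n = 15` (fourteen 23-px blocks plus one 33-px remainder
#' block per side) is a single pure color. Binning followed by `k = 4`
#' clustering therefore recovers the constructed partition exactly.
#'
#' @param side Image side in pixels (default 355).
#' @param n Design grid side (default 15).
#' @return A list with `image` (a [raster_image()]), `design`, `palette`.
#' @export
watermelon_image <- function(side = 355L, n = 15L) {
  wd <- watermelon_design()
  br <- bin_breaks(side, n)
  img <- array(0, dim = c(side, side, 3L))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      col <- wd$palette[wd$design[i, j], ]
      for (ch in 1:3) {
        img[br[i, 1L]:br[i, 2L], br[j, 1L]:br[j, 2L], ch] <- col[ch]
      }
    }
  }
  list(image = raster_image(img), design = wd$design, palette = wd$palette)
}

#' Column-grid characterization layout
#'
#' The round-to-round reproducibility experiment: `n_cols` patterning rounds,
#' each patterning a column of `sites_per_col` rectangular posts before moving
#' to the next column. Each column is its own layout domain, so
#' [compile_protocol()] with the cyclic vial map emits one round per column.
#'
#' @param n_cols Number of columns/rounds (default 12).
#' @param sites_per_col Posts per column (default 5).
#' @param size Post side length, micrometers (default 50).
#' @param pitch Center-to-center spacing, micrometers (default 100).
#' @return A [domain_layout()] with `n_cols * sites_per_col` sites.
#' @export
grid_column_layout <- function(n_cols = 12L, sites_per_col = 5L,
                               size = 50, pitch = 100) {
  sites <- do.call(rbind, lapply(seq_len(n_cols), function(cc) {
    data.frame(domain_id = cc,
               center_x = (cc - 1L) * pitch,
               center_y = (seq_len(sites_per_col) - 1L) * pitch,
               width = size, height = size)
  }))
  domain_layout(sites, pitch = pitch, overlap = 0)
}

#' Cyclic vial map for the characterization experiment
#'
#' Maps round/domain `r` to vial `((r - 1) mod n_vials) + 1`; the 12-round
#' experiment uses vials 1,2,3,4 repeated three times.
#'
#' @param n_rounds Number of rounds (default 12).
#' @param n_vials Number of vials cycled through (default 4).
#' @return Named integer vector (names are domain ids).
#' @export
cyclic_vial_map <- function(n_rounds = 12L, n_vials = 4L) {
  stats::setNames(as.integer((seq_len(n_rounds) - 1L) %% n_vials + 1L),
                  as.character(seq_len(n_rounds)))
}

#' Inks for the three-channel fluorescence experiments
#'
#' Vials 1-3 each carry one acrydite- and fluorophore-modified strand at
#' `conc_nM`; vial 4 carries all three (the "white"/"pink" ink, visible in all
#' imaging channels).
#'
#' @param conc_nM Per-strand concentration, nM (default 100, as in the
#'   characterization experiment; the pixel-art inks used 500).
#' @param volume_ul Vial volume, microliters.
#' @return List of four [ink_spec()] objects.
#' @export
fluor_ink_set <- function(conc_nM = 100, volume_ul = 150) {
  s1 <- strand_table("5Acry_3Cy3_polyT10", conc_nM, "Cy3")
  s2 <- strand_table("5Acry_3ATTO488_polyT10", conc_nM, "ATTO488")
  s3 <- strand_table("5Acry_3TYE665_polyT10", conc_nM, "TYE665")
  list(ink_spec(1L, s1, volume_ul = volume_ul),
       ink_spec(2L, s2, volume_ul = volume_ul),
       ink_spec(3L, s3, volume_ul = volume_ul),
       ink_spec(4L, rbind(s1, s2, s3), volume_ul = volume_ul))
}

#' Ink for DNA-crosslinked (swellable) hydrogels
#'
#' PEGDA-10K ink whose crosslink strands belong to one swelling system, plus a
#' Cy3-labeled reporter strand for imaging.
#'
#' @param system `"S1"` or `"S2"`, or `NA` for a non-swelling control ink.
#' @param vial_id Vial id.
#' @param fluorophore Imaging channel of the reporter strand.
#' @param volume_ul Vial volume, microliters.
#' @return An [ink_spec()].
#' @export
crosslinked_ink <- function(system = "S1", vial_id = 1L, fluorophore = "Cy3",
                            volume_ul = 150) {
  st <- strand_table(sprintf("5Acry_3%s_polyT10", fluorophore), 500, fluorophore)
  if (!is.na(system)) {
    st <- rbind(st, strand_table(paste0(system, "_crosslink"), 1000,
                                 NA_character_, TRUE, system))
  }
  ink_spec(vial_id, st, monomer_label = "PEGDA-10K", volume_ul = volume_ul)
}

#' The addressable-quenching four-domain architecture
#'
#' Builds and executes a protocol patterning four domains - circle-like (Cy3
#' reporter only), triangle-like (ATTO488), plus-like (TYE665), and a square
#' carrying all three strands - then returns the chamber ready for the
#' quencher-addition step. (All footprints are rasterized as rectangles; the
#' shapes' roles, not their outlines, carry the science here.)
#'
#' @param conc_nM Strand concentration (default 500).
#' @param size Domain size, micrometers.
#' @param seed RNG seed for execution.
#' @return A list with `state`, `protocol`, and `domain_roles` (named ids).
#' @export
quenching_architecture <- function(conc_nM = 500, size = 100, seed = 0L) {
  sC <- strand_table("5Acry_3Cy3_R1", conc_nM, "Cy3")
  sA <- strand_table("5Acry_3ATTO488_polyT10", conc_nM, "ATTO488")
  sT <- strand_table("5Acry_3TYE665_polyT10", conc_nM, "TYE665")
  vials <- list(ink_spec(1L, sC), ink_spec(2L, sA), ink_spec(3L, sT),
                ink_spec(4L, rbind(sC, sA, sT)))
  sites <- data.frame(domain_id = 1:4,
                      center_x = c(0, 300, 0, 300),
                      center_y = c(0, 0, 300, 300),
                      width = size, height = size)
  layout <- domain_layout(sites, pitch = 300)
  p <- compile_protocol(layout, inks = stats::setNames(1:4, 1:4), vials = vials)
  res <- execute(p, seed = seed)
  list(state = res$state, protocol = p,
       domain_roles = c(circle = 1L, triangle = 2L, plus = 3L, square = 4L))
}

#' Single-domain swelling experiment, end to end
#'
#' Patterns one DNA-crosslinked square domain in the virtual chamber, lifts it
#' off, adds the system-1 hairpin signal, and measures its side length through
#' the render -> Otsu -> largest-component pipeline at each checkpoint. The
#' analytic (render-free) lengths are returned alongside for comparison.
#'
#' @param seed RNG seed (render noise).
#' @param times_h Measurement checkpoints, hours (first must be 0, the
#'   pre-signal reference).
#' @param L0 Nominal domain size, micrometers (default 200).
#' @param pixel_size_um Camera pixel size (default 1).
#' @param noise A [noise_model()]; default rendering noise.
#' @param config A [run_config()]; defaults to single-domain swelling
#'   parameters and zero size bias.
#' @return A list with `curve` (a [swelling_curve()] from the measured
#'   pipeline), `analytic` (analytic dL/L0 at `times_h`), `measured_lengths`.
#' @export
single_domain_swelling <- function(seed = 0L, times_h = c(0, 60), L0 = 200,
                                   pixel_size_um = 1,
                                   noise = noise_model(),
                                   config = run_config(p_washoff = 0,
                                                       p_collect = 1)) {
  vial <- crosslinked_ink("S1", 1L)
  layout <- domain_layout(data.frame(domain_id = 1L, center_x = 0, center_y = 0,
                                     width = L0, height = L0))
  p <- compile_protocol(layout, inks = c("1" = 1L), vials = list(vial))
  res <- execute(p, seed = seed, config = config, sacrificial = TRUE)
  state <- res$state
  state <- execute(protocol(list(cmd_dissolve_sacrificial(3600), cmd_collect()),
                            vials = list(vial), masks = list()),
                   init = state, seed = seed)$state
  state$time_h <- 0  # re-zero the clock at the pre-signal reference
  half <- ceiling(L0 * (1 + 1) / 2) + 20  # field with headroom for swelling
  optics <- optics_profile(pixel_size_um, c(-half, -half, half, half))
  measure_at <- function(state, k) {
    stk <- render(state, optics, channels = "Cy3", noise = noise,
                  seed = seed * 1000L + k)
    measure_length(stk$channels$Cy3, pixel_size_um)$length_um
  }
  lengths <- numeric(length(times_h))
  analytic <- numeric(length(times_h))
  lengths[1L] <- measure_at(state, 1L)
  analytic[1L] <- 0
  state <- add_swelling_signal(state, "S1", final_conc_uM = 20)
  for (k in seq_along(times_h)[-1L]) {
    state <- advance_time(state, times_h[k] - times_h[k - 1L])
    lengths[k] <- measure_at(state, k)
    analytic[k] <- domain_geometry(state, state$domains[[1L]]$id)$dL_over_L0_free
  }
  list(curve = swelling_curve(times_h, lengths, edge = "W"),
       analytic = analytic, measured_lengths = lengths)
}

#' Three-domain constrained swelling experiment, end to end
#'
#' The red/green/blue strip: three adjacent 200 x 200 um domains overlapped by
#' 10 um, with a non-swelling (green) center domain. The outer red (system 1)
#' and blue (system 2) domains are constrained on the edge they share with
#' green. Signals are added sequentially (S1 at t = 0, S2 at `t_blue_h`);
#' lengths are measured per channel through the render -> Otsu pipeline at the
#' free edge (the bounding-box height equals the free-edge side length of the
#' trapezoidal footprint).
#'
#' @param seed RNG seed.
#' @param times_h Checkpoints, hours.
#' @param t_blue_h Time the system-2 signal is added (default 24).
#' @param size,overlap Strip geometry, micrometers.
#' @param pixel_size_um Camera pixel size.
#' @param noise A [noise_model()].
#' @param config A [run_config()]; defaults to the multi-domain swelling
#'   parameter profile.
#' @return A list of [swelling_curve()]s (`red`, `green`, `blue`) plus the
#'   final `state`.
#' @export
multi_domain_swelling <- function(seed = 0L, times_h = c(0, 24, 60),
                                  t_blue_h = 24, size = 200, overlap = 10,
                                  pixel_size_um = 1, noise = noise_model(),
                                  config = run_config(
                                    p_washoff = 0, p_collect = 1,
                                    swelling = swelling_defaults("multi_domain"))) {
  vials <- list(crosslinked_ink("S1", 1L, "Cy3"),
                crosslinked_ink(NA, 2L, "ATTO488"),
                crosslinked_ink("S2", 3L, "TYE665"))
  layout <- make_strip_layout(3L, size, overlap)
  p <- compile_protocol(layout, inks = c("1" = 1L, "2" = 2L, "3" = 3L),
                        vials = vials)
  state <- execute(p, seed = seed, config = config, sacrificial = TRUE)$state
  state <- execute(protocol(list(cmd_dissolve_sacrificial(3600), cmd_collect()),
                            vials = vials, masks = list()),
                   init = state, seed = seed)$state
  state$time_h <- 0
  # red (domain 1) is west of green (domain 2): its constrained edge is E;
  # blue (domain 3) is east of green: constrained on W
  state <- constrain_edges(state, 1L, "E")
  state <- constrain_edges(state, 3L, "W")
  chans <- c(red = "Cy3", green = "ATTO488", blue = "TYE665")
  half_y <- ceiling(size * 2 / 2) + 20
  optics <- optics_profile(pixel_size_um,
                           c(-size, -half_y, 2 * (size - overlap) + size, half_y))
  measure_all <- function(state, k) {
    stk <- render(state, optics, channels = unname(chans), noise = noise,
                  seed = seed * 1000L + k)
    vapply(chans, function(ch) {
      measure_length(stk$channels[[ch]], pixel_size_um)$length_um
    }, numeric(1))
  }
  L <- matrix(NA_real_, nrow = length(times_h), ncol = 3,
              dimnames = list(NULL, names(chans)))
  L[1L, ] <- measure_all(state, 1L)
  state <- add_swelling_signal(state, "S1", 20)
  blue_added <- FALSE
  for (k in seq_along(times_h)[-1L]) {
    target <- times_h[k]
    now <- times_h[k - 1L]
    if (!blue_added && target >= t_blue_h) {
      state <- advance_time(state, t_blue_h - now)
      state <- add_swelling_signal(state, "S2", 20)
      now <- t_blue_h
      blue_added <- TRUE
    }
    state <- advance_time(state, target - now)
    L[k, ] <- measure_all(state, k)
  }
  out <- lapply(names(chans), function(nm) {
    swelling_curve(times_h, L[, nm], edge = if (nm == "blue") "E" else "W")
  })
  names(out) <- names(chans)
  out$state <- state
  out
}

#' Repeat the single-domain swelling pipeline over many seeds
#'
#' Runs [single_domain_swelling()] (or the multi-domain variant) across
#' `n_seeds` seeds and summarizes the measured endpoint dL/L0.
#'
#' @param n_seeds Number of independent seeds (default 50).
#' @param seed Base seed; per-repeat seeds are `seed + 1:n_seeds`.
#' @param t_end_h Endpoint, hours (default 60).
#' @param multi Run the three-domain constrained experiment instead.
#' @param ... Passed to the underlying experiment function.
#' @return For `multi = FALSE`: list with `mean`, `sd`, `values`. For
#'   `multi = TRUE`: the same per domain (`red`, `green`, `blue`).
#' @export
swelling_recovery_experiment <- function(n_seeds = 50L, seed = 0L,
                                         t_end_h = 60, multi = FALSE, ...) {
  seeds <- seed + seq_len(n_seeds)
  if (!multi) {
    vals <- vapply(seeds, function(s) {
      exp1 <- single_domain_swelling(seed = s, times_h = c(0, t_end_h), ...)
      exp1$curve$dL_over_L0[2L]
    }, numeric(1))
    return(list(mean = mean(vals), sd = stats::sd(vals), values = vals))
  }
  vals <- t(vapply(seeds, function(s) {
    ex <- multi_domain_swelling(seed = s, times_h = c(0, t_end_h), ...)
    c(red = ex$red$dL_over_L0[2L], green = ex$green$dL_over_L0[2L],
      blue = ex$blue$dL_over_L0[2L])
  }, numeric(3)))
  lapply(c(red = "red", green = "green", blue = "blue"), function(nm) {
    list(mean = mean(vals[, nm]), sd = stats::sd(vals[, nm]), values = vals[, nm])
  })
}
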