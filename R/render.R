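# Synthetic multi-channel fluorescence micrograph rendering.

#' Optics profile for rendering
#'
#' @param pixel_size_um Micrometers per camera pixel (default 1).
#' @param field `c(x0, y0, x1, y1)`: imaged region in stage micrometers.
#' @return An `optics_profile` list.
#' @export
optics_profile <- function(pixel_size_um = 1, field = c(-200, -200, 200, 200)) {
  stopifnot(pixel_size_um > 0, length(field) == 4L,
            field[3L] > field[1L], field[4L] > field[2L])
  structure(list(pixel_size_um = pixel_size_um, field = field),
            class = "optics_profile")
}

#' Noise model for rendering
#'
#' @param background Mean background level, counts (default 100).
#' @param sd Gaussian read-noise standard deviation, counts (default 10).
#' @export
noise_model <- function(background = 100, sd = 10) {
  stopifnot(background >= 0, sd >= 0)
  list(background = background, sd = sd)
}

#' Render a synthetic multi-channel micrograph of the chamber
#'
#' Per channel, pixel intensity = background + sum over covering domains of
#' `gain * concentration of the channel's fluorophore strands * (1 - quenched
#' fraction)`, plus Gaussian noise, clamped at 0. Rendering is deterministic
#' per seed. Domains are drawn with their current (possibly swollen,
#' trapezoidal) footprint from [domain_geometry()].
#'
#' @param state A `chamber_state`.
#' @param optics An [optics_profile()].
#' @param channels Channel labels to render (default the three imaging
#'   channels `"Cy3"`, `"ATTO488"`, `"TYE665"`).
#' @param noise A [noise_model()]; use `noise_model(0, 0)` for noise-free.
#' @param seed RNG seed for the noise.
#' @param gain Counts per nM of fluorophore strand (default 1).
#' @param statuses Domain statuses to draw (default attached, free, collected).
#' @return A `micrograph_stack`: list with `channels` (named list of
#'   matrices), `pixel_size_um`, `time_h`, `noise`.
#' @export
render <- function(state, optics = optics_profile(),
                   channels = c("Cy3", "ATTO488", "TYE665"),
                   noise = noise_model(), seed = 0L, gain = 1,
                   statuses = c("attached", "free", "collected")) {
  px <- optics$pixel_size_um
  f <- optics$field
  nc <- max(1L, round((f[3L] - f[1L]) / px))
  nr <- max(1L, round((f[4L] - f[2L]) / px))
  xc <- f[1L] + (seq_len(nc) - 0.5) * px  # pixel-center stage coords
  yc <- f[2L] + (seq_len(nr) - 0.5) * px
  imgs <- stats::setNames(lapply(channels, function(ch) matrix(0, nr, nc)), channels)
  for (d in domains_with_status(state, statuses)) {
    geom <- domain_geometry(state, d$id)
    cols <- which(xc >= geom$x0 & xc <= geom$x1)
    if (!length(cols)) next
    # height varies linearly from the west to the east side
    tfrac <- if (geom$x1 > geom$x0) (xc[cols] - geom$x0) / (geom$x1 - geom$x0) else 0.5
    hh <- geom$h_west + tfrac * (geom$h_east - geom$h_west)
    cover <- abs(yc - geom$cy) <= matrix(hh / 2, nrow = nr, ncol = length(cols),
                                         byrow = TRUE)
    for (ch in channels) {
      comp <- d$composition
      sel <- !is.na(comp$fluorophore) & comp$fluorophore == ch
      if (!any(sel)) next
      inten <- gain * sum(comp$concentration_nM[sel] *
                            (1 - d$quenched[comp$name[sel]]))
      if (inten <= 0) next
      imgs[[ch]][, cols] <- imgs[[ch]][, cols] + inten * cover
    }
  }
  withr::with_seed(seed, {
    for (ch in channels) {
      img <- imgs[[ch]] + noise$background
      if (noise$sd > 0) img <- img + matrix(stats::rnorm(nr * nc, 0, noise$sd), nr, nc)
      imgs[[ch]] <- pmax(img, 0)
    }
  })
  structure(list(channels = imgs, pixel_size_um = px, time_h = state$time_h,
                 noise = noise),
            class = "micrograph_stack")
}

#' @export
print.micrograph_stack <- function(x, ...) {
  d <- dim(x$channels[[1L]])
  cat(sprintf("<micrograph_stack> %d channel(s) [%s], %d x %d px @ %g um/px, t = %g h\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              d[1L], d[2L], x$pixel_size_um, x$time_h))
  invisible(x)
}

#' Write / read a micrograph stack
#'
#' The stack is stored as a directory: `meta.json` (pixel size, time, noise,
#' channel list) plus one whitespace-delimited plain-text matrix per channel.
#' (A multi-page TIFF writer is not available in this toolchain; the text
#' format is lossless and diff-friendly.)
#'
#' @param stack A `micrograph_stack`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_micrographs <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(pixel_size_um = stack$pixel_size_um,
                            time_h = stack$time_h, noise = stack$noise,
                            channels = names(stack$channels)),
                       file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  for (ch in names(stack$channels)) {
    utils::write.table(stack$channels[[ch]], file.path(dir, paste0(ch, ".txt")),
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_micrographs
#' @export
read_micrographs <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  chans <- stats::setNames(lapply(meta$channels, function(ch) {
    as.matrix(utils::read.table(file.path(dir, paste0(ch, ".txt"))))
  }), meta$channels)
  chans <- lapply(chans, function(m) {
    dimnames(m) <- NULL
    m
  })
  structure(list(channels = chans, pixel_size_um = meta$pixel_size_um,
                 time_h = meta$time_h,
                 noise = noise_model(meta$noise$background, meta$noise$sd)),
            class = "micrograph_stack")
}
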