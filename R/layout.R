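#' Domain layouts: stage-coordinate placement of hydrogel domains
#'
#' A `domain_layout` is a table of patterning sites in micrometers with one row
#' per site: `domain_id`, `center_x`, `center_y`, `width`, `height`. The
#' coordinate convention is the image convention: origin at the top-left of the
#' field, x rightward, y downward.
#'
#' @param sites A data.frame with columns `domain_id`, `center_x`, `center_y`,
#'   `width`, `height` (all micrometers).
#' @param pitch Site pitch in micrometers (informational).
#' @param overlap Designed overlap between adjacent footprints, micrometers.
#' @return An object of class `domain_layout`.
#' @export
domain_layout <- function(sites, pitch = NA_real_, overlap = 0) {
  need <- c("domain_id", "center_x", "center_y", "width", "height")
  if (!is.data.frame(sites) || !all(need %in% names(sites))) {
    stop("invalid-input: sites must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(sites) > 0) {
    if (!all(is.finite(as.matrix(sites[need[-1L]])))) {
      stop("invalid-parameter: non-finite coordinates", call. = FALSE)
    }
    if (any(sites$width <= 0) || any(sites$height <= 0)) {
      stop("invalid-parameter: width and height must be > 0", call. = FALSE)
    }
  }
  structure(list(sites = sites, pitch = pitch, overlap = overlap, units = "um"),
            class = "domain_layout")
}

#' @export
print.domain_layout <- function(x, ...) {
  cat(sprintf("<domain_layout> %d sites, %d domains (units: %s)\n",
              nrow(x$sites), length(unique(x$sites$domain_id)), x$units))
  invisible(x)
}

#' Convert location maps to a stage-coordinate layout
#'
#' Every 1-cell of every location map becomes one patterning site. Cell
#' `(i, j)` (0-based row/column) maps to stage position
#' `origin + (j * pitch, i * pitch)`. Sites are grouped by `domain_id`, then
#' row-major within each domain, which is also the patterning order used by
#' [compile_protocol()].
#'
#' @param maps List of `location_grid` objects ([build_location_maps()]).
#' @param post_size Side length of each patterned post, micrometers.
#' @param pitch Center-to-center spacing, micrometers; must be `>= post_size`
#'   so pixel-art posts do not unintentionally overlap.
#' @param origin Stage position of cell (0, 0), micrometers; default `c(0, 0)`.
#' @return A [domain_layout()].
#' @export
grids_to_layout <- function(maps, post_size, pitch, origin = c(0, 0)) {
  if (!is.numeric(post_size) || post_size <= 0 || !is.numeric(pitch) || pitch <= 0) {
    stop("invalid-parameter: post_size and pitch must be positive", call. = FALSE)
  }
  if (pitch < post_size) {
    stop("invalid-parameter: pitch must be >= post_size (unintended overlap)",
         call. = FALSE)
  }
  rows <- lapply(maps, function(m) {
    idx <- which(t(m$mask) == 1L)  # row-major order
    if (length(idx) == 0L) return(NULL)
    nc <- ncol(m$mask)
    j <- (idx - 1L) %% nc          # 0-based column
    i <- (idx - 1L) %/% nc         # 0-based row
    data.frame(domain_id = m$domain_id,
               center_x = origin[1L] + j * pitch,
               center_y = origin[2L] + i * pitch,
               width = post_size, height = post_size)
  })
  sites <- do.call(rbind, rows)
  if (is.null(sites)) {
    sites <- data.frame(domain_id = integer(), center_x = numeric(),
                        center_y = numeric(), width = numeric(), height = numeric())
  }
  domain_layout(sites, pitch = pitch, overlap = 0)
}

#' Strip layout of adjacent, overlapping domains
#'
#' Places `n_domains` square domains in a horizontal strip with domain `i`
#' centered at `x = (i - 1) * (size - overlap)`, so consecutive footprints
#' intersect in a strip of width exactly `overlap` (10 um in the three-domain
#' lift-off architecture).
#'
#' @param n_domains Number of domains, `>= 1`.
#' @param size Domain side length, micrometers (e.g. 200).
#' @param overlap Overlap between adjacent footprints, micrometers;
#'   `0 <= overlap < size`.
#' @return A [domain_layout()] with one site per domain.
#' @export
make_strip_layout <- function(n_domains, size, overlap) {
  n_domains <- as.integer(n_domains)
  if (is.na(n_domains) || n_domains < 1L) {
    stop("invalid-parameter: n_domains must be >= 1", call. = FALSE)
  }
  if (!is.numeric(size) || size <= 0) stop("invalid-parameter: size must be > 0", call. = FALSE)
  if (overlap < 0 || overlap >= size) {
    stop("invalid-parameter: overlap must satisfy 0 <= overlap < size", call. = FALSE)
  }
  i <- seq_len(n_domains) - 1L
  sites <- data.frame(domain_id = seq_len(n_domains),
                      center_x = i * (size - overlap),
                      center_y = 0,
                      width = size, height = size)
  domain_layout(sites, pitch = size - overlap, overlap = overlap)
}

#' Overlap width between two layout sites
#'
#' Width (x-extent) of the intersection of the axis-aligned footprints of two
#' sites; 0 when they do not intersect.
#'
#' @param layout A [domain_layout()].
#' @param i,j Row indices into `layout$sites`.
#' @return Intersection width in micrometers.
#' @export
site_overlap_width <- function(layout, i, j) {
  s <- layout$sites
  x0 <- c(s$center_x[i] - s$width[i] / 2, s$center_x[j] - s$width[j] / 2)
  x1 <- c(s$center_x[i] + s$width[i] / 2, s$center_x[j] + s$width[j] / 2)
  max(0, min(x1) - max(x0))
}

#' Serialize a layout to JSON (micrometer units declared in the header)
#'
#' @param layout A [domain_layout()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_layout <- function(layout, path) {
  jsonlite::write_json(list(units = layout$units, pitch = layout$pitch,
                            overlap = layout$overlap, sites = layout$sites),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sites <- as.data.frame(x$sites)
  if (nrow(sites) == 0) {
    sites <- data.frame(domain_id = integer(), center_x = numeric(),
                        center_y = numeric(), width = numeric(), height = numeric())
  }
  domain_layout(sites, pitch = x$pitch, overlap = x$overlap)
}
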