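# Micrograph quantification: Otsu binarization, connected-component sizing,
# ROI fluorescence, swelling curves, per-round statistics.

#' Otsu threshold of an intensity image
#'
#' Builds a 256-bin histogram over the image's intensity range and returns the
#' bin edge that maximizes the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2`. Pixels strictly above the returned threshold are
#' foreground.
#'
#' @param img Numeric matrix of intensities (needs at least 2 distinct values).
#' @param n_bins Number of histogram bins (default 256).
#' @return The threshold value (a bin edge on the image's intensity scale).
#' @export
otsu_threshold <- function(img, n_bins = 256L) {
  v <- as.numeric(img)
  mn <- min(v); mx <- max(v)
  if (mx <= mn) stop("degenerate-image: constant image has no threshold", call. = FALSE)
  w <- (mx - mn) / n_bins
  idx <- pmin(floor((v - mn) / w) + 1L, n_bins)  # bin index per pixel
  counts <- tabulate(idx, nbins = n_bins)
  sums <- numeric(n_bins)
  rs <- rowsum(v, idx)
  sums[as.integer(rownames(rs))] <- rs
  n <- length(v)
  cum_n <- cumsum(counts)
  cum_s <- cumsum(sums)
  total <- cum_s[n_bins]
  best_k <- 0L
  best_var <- -Inf
  for (k in seq_len(n_bins - 1L)) {       # cut after bin k
    n0 <- cum_n[k]
    n1 <- n - n0
    if (n0 == 0L || n1 == 0L) next
    mu0 <- cum_s[k] / n0
    mu1 <- (total - cum_s[k]) / n1
    bc <- (n0 / n) * (n1 / n) * (mu0 - mu1)^2
    if (bc > best_var) {
      best_var <- bc
      best_k <- k
    }
  }
  mn + best_k * w
}

# Run-length connected-component labeling with 8-connectivity and union-find.
# Returns an integer matrix of labels (0 = background).
label_components <- function(binmask) {
  nr <- nrow(binmask); nc <- ncol(binmask)
  runs <- list()   # per run: row, col start, col end
  row_runs <- vector("list", nr)
  for (i in seq_len(nr)) {
    r <- rle(binmask[i, ] != 0)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    on <- which(r$values)
    ids <- integer(length(on))
    for (k in seq_along(on)) {
      runs[[length(runs) + 1L]] <- c(i, starts[on[k]], ends[on[k]])
      ids[k] <- length(runs)
    }
    row_runs[[i]] <- ids
  }
  n_runs <- length(runs)
  if (n_runs == 0L) return(matrix(0L, nr, nc))
  parent <- seq_len(n_runs)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  for (i in seq_len(nr)[-1L]) {
    for (a in row_runs[[i]]) {
      for (b in row_runs[[i - 1L]]) {
        # 8-connectivity: diagonal touch counts, hence the +/- 1 margin
        if (runs[[a]][2L] <= runs[[b]][3L] + 1L && runs[[a]][3L] >= runs[[b]][2L] - 1L) {
          ra <- find(a); rb <- find(b)
          if (ra != rb) parent[ra] <- rb
        }
      }
    }
  }
  roots <- vapply(seq_len(n_runs), find, integer(1))
  labels_map <- stats::setNames(seq_along(unique(roots)), unique(roots))
  out <- matrix(0L, nr, nc)
  for (k in seq_len(n_runs)) {
    r <- runs[[k]]
    out[r[1L], r[2L]:r[3L]] <- labels_map[[as.character(roots[k])]]
  }
  out
}

#' Measure hydrogel geometry in a micrograph
#'
#' In `"otsu"` mode the image is binarized at the Otsu threshold, the largest
#' 8-connected foreground component is selected, and its axis-aligned bounding
#' box is reported: `length_um` = box height x pixel size, `width_um` = box
#' width x pixel size (mirroring the manual rectangle procedure). In
#' `"manual_rect"` mode the caller supplies the rectangle.
#'
#' @param img Numeric intensity matrix (one channel).
#' @param pixel_size_um Micrometers per pixel.
#' @param method `"otsu"` or `"manual_rect"`.
#' @param rect For `"manual_rect"`: `c(row0, row1, col0, col1)` (1-based,
#'   inclusive).
#' @return A one-row data.frame: `object_id`, `length_um`, `width_um`,
#'   `centroid_row`, `centroid_col`, `n_pixels`, `threshold`.
#' @export
measure_length <- function(img, pixel_size_um = 1,
                           method = c("otsu", "manual_rect"), rect = NULL) {
  method <- match.arg(method)
  if (method == "manual_rect") {
    if (is.null(rect) || length(rect) != 4L) {
      stop("invalid-parameter: manual_rect needs rect = c(row0, row1, col0, col1)",
           call. = FALSE)
    }
    return(data.frame(object_id = 1L,
                      length_um = (rect[2L] - rect[1L] + 1L) * pixel_size_um,
                      width_um = (rect[4L] - rect[3L] + 1L) * pixel_size_um,
                      centroid_row = mean(rect[1:2]), centroid_col = mean(rect[3:4]),
                      n_pixels = (rect[2L] - rect[1L] + 1L) * (rect[4L] - rect[3L] + 1L),
                      threshold = NA_real_))
  }
  thr <- otsu_threshold(img)
  lab <- label_components(img > thr)
  if (max(lab) == 0L) stop("no-object: no foreground after binarization", call. = FALSE)
  sizes <- tabulate(lab[lab > 0L])
  big <- which.max(sizes)
  idx <- which(lab == big, arr.ind = TRUE)
  data.frame(object_id = 1L,
             length_um = (max(idx[, 1L]) - min(idx[, 1L]) + 1L) * pixel_size_um,
             width_um = (max(idx[, 2L]) - min(idx[, 2L]) + 1L) * pixel_size_um,
             centroid_row = mean(idx[, 1L]), centroid_col = mean(idx[, 2L]),
             n_pixels = sizes[big], threshold = thr)
}

#' Measure all objects in a micrograph
#'
#' Like [measure_length()] but returns one row per connected component (above
#' a minimum pixel count), ordered by decreasing size.
#'
#' @inheritParams measure_length
#' @param min_pixels Discard components smaller than this (default 9).
#' @return A data.frame with one row per object.
#' @export
measure_objects <- function(img, pixel_size_um = 1, min_pixels = 9L) {
  thr <- otsu_threshold(img)
  lab <- label_components(img > thr)
  if (max(lab) == 0L) stop("no-object: no foreground after binarization", call. = FALSE)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_pixels)
  keep <- keep[order(sizes[keep], decreasing = TRUE)]
  rows <- lapply(seq_along(keep), function(r) {
    idx <- which(lab == keep[r], arr.ind = TRUE)
    data.frame(object_id = r,
               length_um = (max(idx[, 1L]) - min(idx[, 1L]) + 1L) * pixel_size_um,
               width_um = (max(idx[, 2L]) - min(idx[, 2L]) + 1L) * pixel_size_um,
               centroid_row = mean(idx[, 1L]), centroid_col = mean(idx[, 2L]),
               n_pixels = sizes[keep[r]], threshold = thr)
  })
  do.call(rbind, rows)
}

#' Mean fluorescence in a rectangular ROI
#'
#' @param stack A `micrograph_stack` (or a bare matrix).
#' @param rect `c(row0, row1, col0, col1)`, 1-based inclusive, within bounds.
#' @param channel Channel label (ignored for a bare matrix).
#' @return Mean intensity (counts).
#' @export
roi_mean_fluorescence <- function(stack, rect, channel = NULL) {
  img <- if (is.matrix(stack)) stack else {
    if (is.null(channel) || !channel %in% names(stack$channels)) {
      stop("unknown channel: ", channel, call. = FALSE)
    }
    stack$channels[[channel]]
  }
  if (length(rect) != 4L || rect[1L] > rect[2L] || rect[3L] > rect[4L]) {
    stop("invalid-parameter: empty or malformed rect", call. = FALSE)
  }
  if (rect[1L] < 1L || rect[3L] < 1L || rect[2L] > nrow(img) || rect[4L] > ncol(img)) {
    stop("invalid-parameter: rect outside image bounds", call. = FALSE)
  }
  mean(img[rect[1L]:rect[2L], rect[3L]:rect[4L]])
}

#' Relative length change over time for one object
#'
#' `dL/L0(t) = (L(t) - L0) / L0` with `L0` the first (pre-signal)
#' measurement; the curve therefore starts at exactly 0.
#'
#' @param times Time points, hours (first is pre-signal).
#' @param lengths_um Lengths at those time points, micrometers.
#' @param edge Label of the measured edge (e.g. `"W"`, the edge opposite the
#'   non-swelling neighbor).
#' @return A `swelling_curve`: list with `times`, `dL_over_L0`, `L0`, `edge`.
#' @export
swelling_curve <- function(times, lengths_um, edge = "W") {
  if (length(times) < 2L || length(times) != length(lengths_um)) {
    stop("invalid-parameter: need >= 2 matched timepoints", call. = FALSE)
  }
  L0 <- lengths_um[1L]
  if (!is.finite(L0) || L0 <= 0) stop("invalid-parameter: nonpositive L0", call. = FALSE)
  structure(list(times = times, dL_over_L0 = (lengths_um - L0) / L0,
                 L0 = L0, edge = edge),
            class = "swelling_curve")
}

#' @export
print.swelling_curve <- function(x, ...) {
  cat(sprintf("<swelling_curve> L0 = %g um, edge %s, final dL/L0 = %.3f at %g h\n",
              x$L0, x$edge, x$dL_over_L0[length(x$dL_over_L0)],
              x$times[length(x$times)]))
  invisible(x)
}

#' Per-round summary statistics and homogeneity test
#'
#' Per-round mean and standard deviation of a measured quantity plus a
#' one-way ANOVA across rounds (the paper-style check that hydrogels patterned
#' in different rounds do not differ). With a single round, or zero total
#' variance, no F test is computed (`F = 0`, `p = 1` for the all-identical
#' case).
#'
#' @param values Numeric measurements (e.g. lengths or mean fluorescence).
#' @param rounds Round identifier per measurement.
#' @return A `round_stats` list: `per_round` (data.frame `round`, `n`, `mean`,
#'   `sd`), `F`, `p_value`.
#' @export
round_stats <- function(values, rounds) {
  stopifnot(length(values) == length(rounds))
  rounds <- factor(rounds)
  per <- do.call(rbind, lapply(levels(rounds), function(r) {
    v <- values[rounds == r]
    data.frame(round = r, n = length(v), mean = mean(v), sd = stats::sd(v))
  }))
  if (nlevels(rounds) < 2L) {
    return(structure(list(per_round = per, F = NA_real_, p_value = NA_real_),
                     class = "round_stats"))
  }
  if (stats::var(values) == 0) {
    return(structure(list(per_round = per, F = 0, p_value = 1),
                     class = "round_stats"))
  }
  fit <- stats::anova(stats::lm(values ~ rounds))
  structure(list(per_round = per, F = fit$`F value`[1L],
                 p_value = fit$`Pr(>F)`[1L]),
            class = "round_stats")
}

#' @export
print.round_stats <- function(x, ...) {
  cat(sprintf("<round_stats> %d rounds; F = %s, p = %s\n", nrow(x$per_round),
              format(x$F, digits = 4), format(x$p_value, digits = 4)))
  invisible(x)
}

#' Normalize a fluorescence series to a baseline
#'
#' @param series Numeric series of mean fluorescence values.
#' @param baseline_index Index of the baseline value (default 1); the baseline
#'   maps to exactly 1.
#' @return The normalized series.
#' @export
normalize_fluorescence <- function(series, baseline_index = 1L) {
  b <- series[baseline_index]
  if (!is.finite(b) || b <= 0) {
    stop("invalid-parameter: baseline must be > 0", call. = FALSE)
  }
  series / b
}

#' Match objects across timepoints by nearest centroid
#'
#' @param ref Measurement data.frame (from [measure_objects()]) at the
#'   reference timepoint.
#' @param cur Measurement data.frame at a later timepoint.
#' @return `cur` with `object_id` replaced by the id of the nearest reference
#'   centroid.
#' @export
track_objects <- function(ref, cur) {
  for (i in seq_len(nrow(cur))) {
    d2 <- (ref$centroid_row - cur$centroid_row[i])^2 +
      (ref$centroid_col - cur$centroid_col[i])^2
    cur$object_id[i] <- ref$object_id[which.min(d2)]
  }
  cur
}
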