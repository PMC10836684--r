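# Independent oracles and small fixture builders used across the suite.

# Exhaustive k-means oracle: global minimum SSE over ALL assignments of the
# points to at most k clusters (each cluster scored against its own centroid).
brute_kmeans_sse <- function(x, k) {
  m <- nrow(x)
  best <- Inf
  assign_vec <- rep(1L, m)
  total <- k^m
  for (code in 0:(total - 1L)) {
    c0 <- code
    for (i in seq_len(m)) {
      assign_vec[i] <- c0 %% k + 1L
      c0 <- c0 %/% k
    }
    sse <- 0
    for (cl in unique(assign_vec)) {
      pts <- x[assign_vec == cl, , drop = FALSE]
      ctr <- colMeans(pts)
      sse <- sse + sum(sweep(pts, 2L, ctr)^2)
    }
    if (sse < best) best <- sse
  }
  best
}

# Exhaustive Otsu oracle: for every one of the 255 interior bin edges of a
# 256-bin histogram over the image range, compute the between-class variance
# directly from the raw pixel values and return the argmax edge.
brute_otsu <- function(img, n_bins = 256L) {
  v <- as.numeric(img)
  mn <- min(v); mx <- max(v)
  w <- (mx - mn) / n_bins
  idx <- pmin(floor((v - mn) / w) + 1L, n_bins)
  n <- length(v)
  best_k <- 0L
  best_var <- -Inf
  for (k in seq_len(n_bins - 1L)) {
    lo <- v[idx <= k]
    hi <- v[idx > k]
    if (!length(lo) || !length(hi)) next
    bc <- (length(lo) / n) * (length(hi) / n) * (mean(lo) - mean(hi))^2
    if (bc > best_var) {
      best_var <- bc
      best_k <- k
    }
  }
  list(threshold = mn + best_k * w, between_var = best_var)
}

# A raster image with each pixel's channels drawn uniformly from a palette.
random_palette_image <- function(h, w, palette, seed) {
  withr::with_seed(seed, {
    pick <- sample(nrow(palette), h * w, replace = TRUE)
    img <- array(0, dim = c(h, w, 3L))
    for (ch in 1:3) img[, , ch] <- matrix(palette[pick, ch], h, w)
    raster_image(img)
  })
}

# Layout of n_sites three-domain strips stacked vertically (the lift-off
# architecture grid).
strip_grid_layout <- function(n_sites = 25L, size = 200, overlap = 10,
                              row_pitch = 500) {
  rows <- lapply(seq_len(n_sites), function(s) {
    l <- make_strip_layout(3L, size, overlap)$sites
    l$center_y <- l$center_y + (s - 1L) * row_pitch
    l
  })
  domain_layout(do.call(rbind, rows), pitch = size - overlap, overlap = overlap)
}

crosslinked_vial_set <- function() {
  list(crosslinked_ink("S1", 1L, "Cy3"),
       crosslinked_ink(NA, 2L, "ATTO488"),
       crosslinked_ink("S2", 3L, "TYE665"))
}
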