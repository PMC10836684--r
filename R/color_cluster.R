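#' Cluster the colors of a binned grid with k-means
#'
#' Clusters cell colors in RGB space with Lloyd's algorithm under k-means++
#' initialization, followed by a Hartigan-style single-point refinement pass
#' (Lloyd fixed points are not always SSE-optimal on small discrete palettes).
#' The best of up to `restarts` restarts (lowest within-cluster sum of
#' squares) is returned; the whole procedure is deterministic for a fixed
#' `seed`. When `k` exceeds the number of distinct cell colors the
#' degenerate clusters are collapsed with a warning, so every returned cluster
#' is referenced by at least one cell.
#'
#' @param grid A `binned_grid` from [bin_image()].
#' @param k Number of color clusters (one per ink domain).
#' @param seed Integer seed controlling initialization; default 0.
#' @param restarts Maximum number of k-means++ restarts (default 50).
#' @return A `color_clustering`: list with `k`, `centroids` (k x 3 matrix),
#'   `assignment` (n x n integer matrix of cluster indices in `1..k`), and
#'   `sse` (within-cluster sum of squared distances).
#' @export
cluster_colors <- function(grid, k, seed = 0L, restarts = 50L) {
  if (!inherits(grid, "binned_grid")) stop("invalid-input: expected a binned_grid", call. = FALSE)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("invalid-parameter: k must be >= 1", call. = FALSE)
  x <- grid_cells(grid)
  n_cells <- nrow(x)
  if (k > n_cells) stop("invalid-parameter: k exceeds number of cells", call. = FALSE)
  n_distinct <- nrow(unique(x))
  if (k > n_distinct) {
    warning(sprintf("k = %d exceeds %d distinct colors; collapsing to %d clusters",
                    k, n_distinct, n_distinct))
    k <- n_distinct
  }
  fit <- withr::with_seed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      # alternate init families: k-means++ seeds every basin whose centers
      # are near data points; random-partition seeds mixed-centroid basins
      # that no data-point init can reach
      init <- if (r %% 2L == 1L) kmeanspp_init(x, k) else random_partition_init(x, k)
      f <- lloyd_kmeans(x, init)
      if (is.null(best) || f$sse < best$sse - 1e-9) best <- f
      if (best$sse < 1e-12) break  # exact fit, no restart can improve
    }
    best
  })
  n <- dim(grid)[1L]
  structure(list(
    k = k,
    centroids = fit$centers,
    assignment = matrix(fit$cluster, nrow = n, ncol = dim(grid)[2L], byrow = TRUE),
    sse = fit$sse
  ), class = "color_clustering")
}

#' @export
print.color_clustering <- function(x, ...) {
  cat(sprintf("<color_clustering> k = %d, SSE = %.3f\n", x$k, x$sse))
  invisible(x)
}

# k-means++ seeding: first center uniform, subsequent centers sampled with
# probability proportional to squared distance to the nearest chosen center.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, nrow = k, ncol = ncol(x))
  centers[1L, ] <- x[sample.int(n, 1L), ]
  if (k > 1L) {
    d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
    for (i in 2:k) {
      if (sum(d2) <= 0) {
        # all remaining points coincide with a center; pick any distinct row
        centers[i, ] <- x[sample.int(n, 1L), ]
      } else {
        centers[i, ] <- x[sample.int(n, 1L, prob = d2), ]
      }
      d2 <- pmin(d2, rowSums((x - matrix(centers[i, ], n, ncol(x), byrow = TRUE))^2))
    }
  }
  centers
}

# Centroids of a uniformly random partition of the points into k groups
# (each group guaranteed one point via an initial permutation).
random_partition_init <- function(x, k) {
  n <- nrow(x)
  cl <- c(seq_len(k), sample.int(k, n - k, replace = TRUE))[sample.int(n)]
  do.call(rbind, lapply(seq_len(k), function(c) {
    colMeans(x[cl == c, , drop = FALSE])
  }))
}

# Single-point improvement pass (Hartigan-style): move one point to another
# cluster whenever that strictly lowers the total SSE, using the exact delta
#   gain = nb/(nb+1) * ||x_i - c_b||^2  -  na/(na-1) * ||x_i - c_a||^2 .
# Lloyd alone can converge to fixed points that are not SSE-optimal even with
# many restarts; this pass escapes them.
hartigan_refine <- function(x, cl, centers, max_pass = 100L) {
  k <- nrow(centers)
  n <- nrow(x)
  sizes <- tabulate(cl, nbins = k)
  for (pass in seq_len(max_pass)) {
    improved <- FALSE
    for (i in seq_len(n)) {
      a <- cl[i]
      if (sizes[a] <= 1L) next
      da <- sum((x[i, ] - centers[a, ])^2)
      cost_a <- sizes[a] / (sizes[a] - 1L) * da
      for (b in seq_len(k)) {
        if (b == a) next
        db <- sum((x[i, ] - centers[b, ])^2)
        gain <- sizes[b] / (sizes[b] + 1L) * db - cost_a
        if (gain < -1e-9) {
          centers[a, ] <- (centers[a, ] * sizes[a] - x[i, ]) / (sizes[a] - 1L)
          centers[b, ] <- (centers[b, ] * sizes[b] + x[i, ]) / (sizes[b] + 1L)
          sizes[a] <- sizes[a] - 1L
          sizes[b] <- sizes[b] + 1L
          cl[i] <- b
          improved <- TRUE
          break
        }
      }
    }
    if (!improved) break
  }
  list(cluster = cl, centers = centers)
}

# Plain Lloyd iterations; converges when assignments are stable. Empty
# clusters are reseeded at the point farthest from its center.
lloyd_kmeans <- function(x, centers, max_iter = 100L) {
  n <- nrow(x); k <- nrow(centers)
  assign_prev <- rep(0L, n)
  for (it in seq_len(max_iter)) {
    d2 <- sapply(seq_len(k), function(c) {
      rowSums((x - matrix(centers[c, ], n, ncol(x), byrow = TRUE))^2)
    })
    if (n == 1L) d2 <- matrix(d2, nrow = 1L)
    cl <- max.col(-d2, ties.method = "first")
    for (c in seq_len(k)) {
      if (!any(cl == c)) {
        far <- which.max(d2[cbind(seq_len(n), cl)])
        cl[far] <- c
      }
    }
    for (c in seq_len(k)) centers[c, ] <- colMeans(x[cl == c, , drop = FALSE])
    if (identical(cl, assign_prev)) break
    assign_prev <- cl
  }
  ref <- hartigan_refine(x, assign_prev, centers)
  d2 <- sapply(seq_len(k), function(c) {
    rowSums((x - matrix(ref$centers[c, ], n, ncol(x), byrow = TRUE))^2)
  })
  if (n == 1L) d2 <- matrix(d2, nrow = 1L)
  sse <- sum(d2[cbind(seq_len(n), ref$cluster)])
  list(cluster = ref$cluster, centers = ref$centers, sse = sse)
}

#' Build per-domain binary location maps from a color clustering
#'
#' One binary matrix ("location map") is produced per color cluster: cell
#' `(i, j)` of map `c` is 1 iff the cell was assigned to cluster `c`. Together
#' the maps partition the grid (they sum elementwise to 1). Maps are ordered by
#' descending cell count, so the largest domain becomes domain 1 (ink 1) unless
#' the caller reorders them.
#'
#' @param clustering A `color_clustering` from [cluster_colors()].
#' @return A list of `location_grid` objects, each with `mask` (binary matrix),
#'   `domain_id`, `label_color` (rounded RGB centroid), and `n_cells`.
#' @export
build_location_maps <- function(clustering) {
  if (!inherits(clustering, "color_clustering")) {
    stop("invalid-input: expected a color_clustering", call. = FALSE)
  }
  counts <- tabulate(clustering$assignment, nbins = clustering$k)
  ord <- order(counts, decreasing = TRUE)
  maps <- vector("list", clustering$k)
  for (d in seq_len(clustering$k)) {
    c_src <- ord[d]
    maps[[d]] <- structure(list(
      mask = (clustering$assignment == c_src) * 1L,
      domain_id = d,
      label_color = as.numeric(round(clustering$centroids[c_src, ])),
      n_cells = counts[c_src]
    ), class = "location_grid")
  }
  maps
}

#' @export
print.location_grid <- function(x, ...) {
  cat(sprintf("<location_grid> domain %d: %d cells, color (%s)\n",
              x$domain_id, x$n_cells, paste(x$label_color, collapse = ", ")))
  invisible(x)
}

#' Write location maps to disk
#'
#' Each map is written both as a 1-bit-style PNG (white = pattern here) and
#' collectively as a JSON file of integer matrices.
#'
#' @param maps List of `location_grid` objects.
#' @param dir Output directory (created if needed).
#' @param stem Filename stem, default `"location_map"`.
#' @return Invisibly, the JSON path.
#' @export
write_location_maps <- function(maps, dir, stem = "location_map") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in maps) {
    png::writePNG(m$mask + 0, file.path(dir, sprintf("%s_d%d.png", stem, m$domain_id)))
  }
  js <- lapply(maps, function(m) {
    list(domain_id = m$domain_id, label_color = m$label_color,
         mask = unname(apply(m$mask, 1L, as.integer, simplify = FALSE)))
  })
  path <- file.path(dir, paste0(stem, "s.json"))
  jsonlite::write_json(js, path, auto_unbox = TRUE)
  invisible(path)
}
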