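# Skeleton-based morphometry: binarisation, topology-preserving thinning,
# endpoint/junction/slab classification, cell counting, reporter-channel
# subtraction and convex-hull process area.

shift_mat <- function(m, dr, dc) {
  out <- matrix(0, nrow(m), ncol(m))
  rs <- max(1, 1 + dr):min(nrow(m), nrow(m) + dr)
  cs <- max(1, 1 + dc):min(ncol(m), ncol(m) + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Binarise a fluorescence channel
#'
#' Brightness gain, 3x3 median de-speckling (removes isolated single-pixel
#' foreground and background), then a threshold: a fixed absolute value by
#' default (the synthetic generator emits calibrated intensities), or Otsu
#' for externally acquired images.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param pixel_size um per pixel, carried on the mask.
#' @param brightness_gain multiplicative gain (clipped at 1).
#' @param despeckle apply the 3x3 median filter.
#' @param threshold `"fixed"` or `"otsu"`.
#' @param threshold_value threshold for the fixed method.
#' @return object of class `binary_mask`: logical matrix with a
#'   `pixel_size` attribute.
#' @export
preprocess <- function(img, pixel_size = 0.5, brightness_gain = 1,
                       despeckle = TRUE, threshold = c("fixed", "otsu"),
                       threshold_value = 0.5) {
  threshold <- match.arg(threshold)
  img <- pmin(img * brightness_gain, 1)
  if (despeckle) img <- EBImage::medianFilter(img, size = 1)
  thr <- if (threshold == "otsu") EBImage::otsu(EBImage::Image(img))
         else threshold_value
  mask <- img >= thr
  structure(mask, pixel_size = pixel_size, class = c("binary_mask", "matrix"))
}

as_binary_mask <- function(m, pixel_size = 0.5) {
  if (inherits(m, "binary_mask")) return(m)
  structure(m > 0, pixel_size = pixel_size, class = c("binary_mask", "matrix"))
}

#' Topology-preserving skeletonisation (Zhang-Suen thinning)
#'
#' Iteratively peels boundary pixels under the Zhang-Suen conditions until
#' stable, leaving a 1-pixel-wide skeleton that is a subset of the mask and
#' preserves the number of connected components.
#'
#' @param mask a `binary_mask` (or logical matrix).
#' @return a `binary_mask` skeleton.
#' @export
skeletonize <- function(mask) {
  ps <- attr(mask, "pixel_size") %||% 0.5
  m <- unclass(mask) * 1
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      # neighbours P2..P9 clockwise from north
      P <- list(
        shift_mat(m, -1, 0), shift_mat(m, -1, 1), shift_mat(m, 0, 1),
        shift_mat(m, 1, 1), shift_mat(m, 1, 0), shift_mat(m, 1, -1),
        shift_mat(m, 0, -1), shift_mat(m, -1, -1))
      B <- Reduce(`+`, P)
      A <- matrix(0, nrow(m), ncol(m))
      for (i in 1:8) {
        j <- i %% 8 + 1
        A <- A + (P[[i]] == 0 & P[[j]] == 1)
      }
      if (phase == 1) {
        c1 <- P[[1]] * P[[3]] * P[[5]] == 0   # P2*P4*P6
        c2 <- P[[3]] * P[[5]] * P[[7]] == 0   # P4*P6*P8
      } else {
        c1 <- P[[1]] * P[[3]] * P[[7]] == 0   # P2*P4*P8
        c2 <- P[[1]] * P[[5]] * P[[7]] == 0   # P2*P6*P8
      }
      del <- m == 1 & B >= 2 & B <= 6 & A == 1 & c1 & c2
      if (any(del)) {
        m[del] <- 0
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  structure(m == 1, pixel_size = ps, class = c("binary_mask", "matrix"))
}

#' Prune short terminal spurs from a skeleton
#'
#' Thinning a soma blob with attached processes can leave short terminal
#' artefacts ("spurs"). Every terminal branch of at most `max_px` pixels
#' that ends at a junction is removed; genuine processes (longer than
#' `max_px`) are untouched.
#'
#' @param skeleton a `binary_mask` skeleton.
#' @param max_px maximum spur length in pixels.
#' @return the pruned `binary_mask`.
#' @export
prune_spurs <- function(skeleton, max_px = 4L) {
  ps <- attr(skeleton, "pixel_size") %||% 0.5
  m <- unclass(skeleton) > 0
  nr <- nrow(m)
  nbrs <- function(rc) {
    out <- cbind(rc[1] + DIRS8[, "dr"], rc[2] + DIRS8[, "dc"])
    out[out[, 1] >= 1 & out[, 1] <= nr & out[, 2] >= 1 & out[, 2] <= ncol(m), ,
        drop = FALSE]
  }
  deg <- function(rc) {
    nb <- nbrs(rc)
    sum(m[nb])
  }
  repeat {
    ends <- which(m, arr.ind = TRUE)
    ends <- ends[apply(ends, 1, deg) == 1, , drop = FALSE]
    removed_any <- FALSE
    for (i in seq_len(nrow(ends))) {
      path <- list()
      cur <- ends[i, ]
      prev <- NULL
      is_spur <- FALSE
      for (step in seq_len(max_px)) {
        path[[step]] <- cur
        nb <- nbrs(cur)
        nb <- nb[m[nb], , drop = FALSE]
        if (!is.null(prev))
          nb <- nb[!(nb[, 1] == prev[1] & nb[, 2] == prev[2]), , drop = FALSE]
        if (nrow(nb) == 0) break            # isolated short fragment: not a spur
        if (nrow(nb) > 1 || deg(nb[1, ]) >= 3) { is_spur <- TRUE; break }
        prev <- cur
        cur <- nb[1, ]
      }
      if (is_spur) {
        for (p in path) m[p[1], p[2]] <- FALSE
        removed_any <- TRUE
      }
    }
    if (!removed_any) break
  }
  structure(m, pixel_size = ps, class = c("binary_mask", "matrix"))
}

#' Skeleton metrics container
#'
#' @param n_endpoints,n_junctions,total_length,n_cells totals for a frame.
#' @return object of class `skeleton_metrics` including per-cell values
#'   (`NA` when `n_cells` is 0).
#' @export
skeleton_metrics <- function(n_endpoints, n_junctions, total_length,
                             n_cells = 0L) {
  structure(list(
    n_endpoints = n_endpoints, n_junctions = n_junctions,
    total_length = total_length, n_cells = n_cells,
    endpoints_per_cell = if (n_cells > 0) n_endpoints / n_cells else NA_real_,
    length_per_cell = if (n_cells > 0) total_length / n_cells else NA_real_
  ), class = "skeleton_metrics")
}

#' @export
print.skeleton_metrics <- function(x, ...) {
  cat(sprintf("skeleton_metrics: %d endpoints, %d junctions, length %.1f um, %d cells\n",
              x$n_endpoints, x$n_junctions, x$total_length, x$n_cells))
  if (x$n_cells > 0)
    cat(sprintf("  per cell: %.2f endpoints, %.1f um\n",
                x$endpoints_per_cell, x$length_per_cell))
  invisible(x)
}

#' Analyse a skeleton: endpoint/junction counts and total length
#'
#' Pixels are classified by their 8-neighbour count (endpoint = 1,
#' slab = 2, junction pixel >= 3); adjacent junction pixels are merged, so
#' `n_junctions` counts distinct junctions (a plus sign has one junction,
#' not five junction pixels). Total length sums adjacent skeleton-pixel
#' steps, 1 per orthogonal and sqrt(2) per diagonal step, times the pixel
#' size; each undirected step is counted once.
#'
#' @param skeleton a `binary_mask` skeleton.
#' @param n_cells optional cell count for per-cell normalisation.
#' @return a [skeleton_metrics()] object.
#' @export
analyze_skeleton <- function(skeleton, n_cells = 0L) {
  ps <- attr(skeleton, "pixel_size") %||% 0.5
  m <- unclass(skeleton) * 1
  P <- lapply(seq_len(8), function(i)
    shift_mat(m, DIRS8[i, "dr"], DIRS8[i, "dc"]))
  B <- Reduce(`+`, P)
  on <- m == 1
  n_end <- sum(on & B == 1)
  n_junc <- n_components_8(which(on & B >= 3, arr.ind = TRUE))
  orth <- sum(m * shift_mat(m, 0, 1)) + sum(m * shift_mat(m, 1, 0))
  diag_ <- sum(m * shift_mat(m, 1, 1)) + sum(m * shift_mat(m, 1, -1))
  total_length <- (orth + sqrt(2) * diag_) * ps
  skeleton_metrics(n_end, n_junc, total_length, n_cells)
}

# Number of 8-connected components of a (row, col) coordinate set.
n_components_8 <- function(coords) {
  n <- nrow(coords)
  if (n == 0) return(0L)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  key <- split(seq_len(n), coords[, 1])   # group by row for locality
  for (i in seq_len(n)) {
    for (dr in -1:1) {
      cand <- key[[as.character(coords[i, 1] + dr)]]
      if (is.null(cand)) next
      for (j in cand) {
        if (j <= i) next
        if (abs(coords[j, 2] - coords[i, 2]) <= 1) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

#' Count cells in a binary mask
#'
#' Morphological opening (disc brush) removes thin processes; remaining
#' connected components with area at least `min_soma_area` are counted as
#' somata.
#'
#' @param mask a `binary_mask`.
#' @param min_soma_area minimum component area (pixels).
#' @param brush_size opening brush diameter (odd integer).
#' @return integer cell count.
#' @export
count_cells <- function(mask, min_soma_area = 10L, brush_size = 5L) {
  m <- unclass(as_binary_mask(mask)) * 1
  op <- EBImage::opening(m, EBImage::makeBrush(brush_size, "disc"))
  lab <- EBImage::bwlabel(op)
  if (max(lab) == 0) return(0L)
  sum(tabulate(lab[lab > 0]) >= min_soma_area)
}

#' Subtract reporter-channel metrics from the Iba-1 channel metrics
#'
#' Summary-level subtraction (totals and cell counts, floored at zero) as
#' used to obtain metrics for reporter-negative cells; per-cell values are
#' recomputed from the subtracted totals.
#'
#' @param metrics_iba1,metrics_reporter [skeleton_metrics()] of the two
#'   channels of one frame.
#' @return a `skeleton_metrics` for the reporter-negative complement.
#' @export
subtract_channel_metrics <- function(metrics_iba1, metrics_reporter) {
  stopifnot(inherits(metrics_iba1, "skeleton_metrics"),
            inherits(metrics_reporter, "skeleton_metrics"))
  skeleton_metrics(
    max(0L, metrics_iba1$n_endpoints - metrics_reporter$n_endpoints),
    max(0L, metrics_iba1$n_junctions - metrics_reporter$n_junctions),
    max(0, metrics_iba1$total_length - metrics_reporter$total_length),
    max(0L, metrics_iba1$n_cells - metrics_reporter$n_cells)
  )
}

#' Convex hull area of process endpoints
#'
#' Shoelace area over the convex hull of the endpoint coordinates.
#'
#' @param pts n x 2 matrix of (x, y) coordinates in um.
#' @return area in um^2; 0 with attribute `degenerate = TRUE` for fewer
#'   than 3 non-collinear points.
#' @export
convex_hull_area <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 3) return(structure(0, degenerate = TRUE))
  h <- grDevices::chull(pts)
  a <- polygon_area(pts[h, , drop = FALSE])
  if (a == 0) structure(0, degenerate = TRUE) else a
}

#' Full morphometry of a two-channel frame
#'
#' Runs preprocess -> skeletonize -> analyze on both channels, counts cells
#' per channel, and returns the reporter-subtracted metrics. A pixel-level
#' mode subtracts the reporter mask from the Iba-1 mask before
#' skeletonisation instead (sensitivity analysis).
#'
#' @param frame a `microglia_frame` (or list with `iba1`, `reporter`,
#'   `pixel_size`).
#' @param pixel_level use mask-difference subtraction.
#' @param prune_px spur-pruning threshold passed to [prune_spurs()]
#'   (0 disables).
#' @param ... passed to [preprocess()].
#' @return list with `iba1`, `reporter`, `subtracted` skeleton metrics.
#' @export
frame_morphometry <- function(frame, pixel_level = FALSE, prune_px = 4L, ...) {
  skel <- function(mask) {
    s <- skeletonize(mask)
    if (prune_px > 0) s <- prune_spurs(s, prune_px)
    s
  }
  chan <- function(img) {
    mask <- preprocess(img, pixel_size = frame$pixel_size, ...)
    list(mask = mask,
         metrics = analyze_skeleton(skel(mask), n_cells = count_cells(mask)))
  }
  a <- chan(frame$iba1)
  b <- chan(frame$reporter)
  sub <- if (pixel_level) {
    diff_mask <- as_binary_mask(unclass(a$mask) & !unclass(b$mask),
                                frame$pixel_size)
    analyze_skeleton(skel(diff_mask), n_cells = count_cells(diff_mask))
  } else {
    subtract_channel_metrics(a$metrics, b$metrics)
  }
  list(iba1 = a$metrics, reporter = b$metrics, subtracted = sub)
}
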