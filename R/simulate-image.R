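# Two-channel synthetic micrographs of ramified cells: every cell appears
# in the Iba-1 analog channel; a chosen subset lacks the reporter channel.
# Per-cell ground truth (skeleton length, endpoint count, hull area) is
# retained for validating the morphometry pipeline.

DIRS8 <- cbind(dr = c(0, -1, -1, -1, 0, 1, 1, 1),
               dc = c(1, 1, 0, -1, -1, -1, 0, 1))

#' Render a two-channel synthetic microglia image
#'
#' Each cell is a soma disk plus straight processes leaving the soma centre
#' at distinct multiples of 45 degrees (so the rasterised centre-line chain
#' length is exact: 1 per orthogonal step, sqrt(2) per diagonal step), with
#' optional single mid-process branches. Processes are rendered ~3 pixels
#' wide -- like real stained processes, wide enough to survive the 3x3
#' median de-speckle -- and the recorded ground-truth skeleton length is
#' that of the 1-pixel centre line the thinning step recovers. Cells sit on a jittered grid; a
#' jitter draw that would push a cell out of its grid box is retried, and
#' the renderer errors after `max_retries` failures.
#'
#' @param n_cells number of cells.
#' @param n_reporter_negative number of cells missing from the reporter
#'   channel (`<= n_cells`).
#' @param n_processes_range inclusive range of processes per cell (1--8).
#' @param proc_len_range process length range in pixels.
#' @param soma_radius soma disk radius in pixels (0 = no soma).
#' @param branch_prob probability that a process carries one branch.
#' @param jitter max absolute cell-centre jitter (pixels).
#' @param pixel_size um per pixel.
#' @param max_retries placement retries before giving up.
#' @param seed integer seed.
#' @return object of class `microglia_frame`: `iba1` and `reporter`
#'   (numeric 0/1 matrices), `pixel_size`, and `truth` (data.frame cell,
#'   x, y, reporter_negative, n_tips, skeleton_length_um, hull_area_um2).
#' @export
render_microglia_image <- function(n_cells = 10L, n_reporter_negative = 2L,
                                   n_processes_range = c(2L, 4L),
                                   proc_len_range = c(20L, 40L),
                                   soma_radius = 3L, branch_prob = 0.3,
                                   jitter = 4L, pixel_size = 0.5,
                                   max_retries = 50L, seed = 1L) {
  if (n_reporter_negative > n_cells)
    stop("n_reporter_negative must be <= n_cells")
  stopifnot(n_processes_range[1] >= 1, n_processes_range[2] <= 8,
            proc_len_range[1] >= 2)
  box <- 2L * (max(proc_len_range) + soma_radius + 3L) + 16L
  k <- ceiling(sqrt(n_cells))
  dim_px <- k * box
  with_seed(seed, {
    iba1 <- matrix(0, dim_px, dim_px)
    reporter <- matrix(0, dim_px, dim_px)
    neg_cells <- if (n_reporter_negative > 0)
      sample.int(n_cells, n_reporter_negative) else integer(0)
    truth <- vector("list", n_cells)
    for (ci in seq_len(n_cells)) {
      gx <- ((ci - 1L) %% k) * box + box %/% 2L
      gy <- ((ci - 1L) %/% k) * box + box %/% 2L
      placed <- FALSE
      reach <- max(proc_len_range) + soma_radius + 1L
      margin <- box %/% 2L - reach - 1L   # slack before leaving the grid box
      for (try in seq_len(max_retries)) {
        cx <- gx + if (jitter > 0) sample(-jitter:jitter, 1) else 0L
        cy <- gy + if (jitter > 0) sample(-jitter:jitter, 1) else 0L
        # the cell (with its full reach) must stay inside its own grid box,
        # which both keeps it on canvas and prevents overlap with neighbours
        if (abs(cx - gx) <= margin && abs(cy - gy) <= margin) {
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("cell placement failed after max_retries")
      cell <- draw_cell(cx, cy, n_processes_range, proc_len_range,
                        soma_radius, branch_prob)
      iba1[cell$pixels] <- 1
      if (!ci %in% neg_cells) reporter[cell$pixels] <- 1
      truth[[ci]] <- data.frame(
        cell = ci, x = cx, y = cy,
        reporter_negative = ci %in% neg_cells,
        n_tips = cell$n_tips,
        skeleton_length_um = cell$chain_length * pixel_size,
        hull_area_um2 = cell$hull_area_px * pixel_size^2)
    }
    structure(list(iba1 = iba1, reporter = reporter,
                   pixel_size = pixel_size,
                   truth = do.call(rbind, truth)),
              class = "microglia_frame")
  })
}

# Uniform draw from an inclusive integer range (safe for a == b).
sample_range <- function(r) {
  if (r[1] == r[2]) return(as.integer(r[1]))
  sample(r[1]:r[2], 1)
}

# Dilate a set of (row, col) points with a plus-shaped (radius-1) stamp.
thicken <- function(pts) {
  rbind(pts,
        cbind(pts[, 1] + 1L, pts[, 2]), cbind(pts[, 1] - 1L, pts[, 2]),
        cbind(pts[, 1], pts[, 2] + 1L), cbind(pts[, 1], pts[, 2] - 1L))
}

# Draw one cell; returns pixel coordinates, tip count, exact centre-line
# chain length (px) and tip convex-hull area (px^2).
draw_cell <- function(cx, cy, n_processes_range, proc_len_range,
                      soma_radius, branch_prob) {
  n_proc <- sample_range(n_processes_range)
  dirs <- DIRS8[sample.int(8, n_proc), , drop = FALSE]
  px <- matrix(integer(0), ncol = 2)
  if (soma_radius > 0) {
    rng <- -soma_radius:soma_radius
    disk <- expand.grid(dr = rng, dc = rng)
    disk <- disk[disk$dr^2 + disk$dc^2 <= soma_radius^2, ]
    px <- rbind(px, cbind(cy + disk$dr, cx + disk$dc))
  }
  chain_length <- 0
  tips <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(dirs))) {
    len <- sample_range(proc_len_range)
    step_len <- sqrt(sum(dirs[i, ]^2))   # 1 or sqrt(2)
    pts <- cbind(cy + dirs[i, "dr"] * seq_len(len),
                 cx + dirs[i, "dc"] * seq_len(len))
    px <- rbind(px, thicken(pts))
    chain_length <- chain_length + len * step_len
    tips <- rbind(tips, pts[len, , drop = FALSE])
    if (stats::runif(1) < branch_prob) {
      rot <- sample(c(-1L, 1L), 1)
      di <- which(DIRS8[, 1] == dirs[i, 1] & DIRS8[, 2] == dirs[i, 2])
      bd <- DIRS8[(di - 1L + rot) %% 8L + 1L, ]
      blen <- max(2L, len %/% 2L)
      mid <- pts[len %/% 2L, ]
      bpts <- cbind(mid[1] + bd["dr"] * seq_len(blen),
                    mid[2] + bd["dc"] * seq_len(blen))
      bthick <- thicken(bpts)
      # a branch that would touch unrelated structure (e.g. another
      # process's branch) is skipped so per-cell ground truth stays exact
      near_origin <- abs(bthick[, 1] - mid[1]) <= 2 &
        abs(bthick[, 2] - mid[2]) <= 2
      clash <- any(paste(bthick[!near_origin, 1], bthick[!near_origin, 2]) %in%
                     paste(thicken(px)[, 1], thicken(px)[, 2]))
      if (!clash) {
        px <- rbind(px, bthick)
        chain_length <- chain_length + blen * sqrt(sum(bd^2))
        tips <- rbind(tips, bpts[blen, , drop = FALSE])
      }
    }
  }
  hull <- if (nrow(tips) >= 3) polygon_area(tips[grDevices::chull(tips), ,
                                                 drop = FALSE]) else 0
  n_tips <- nrow(tips)
  if (soma_radius == 0 && n_proc == 1) n_tips <- n_tips + 1L  # free root end
  list(pixels = px, n_tips = n_tips, chain_length = chain_length,
       hull_area_px = hull)
}

# Shoelace area of an ordered polygon (n x 2 matrix).
polygon_area <- function(v) {
  n <- nrow(v)
  if (n < 3) return(0)
  i2 <- c(2:n, 1)
  abs(sum(v[, 1] * v[i2, 2] - v[i2, 1] * v[, 2])) / 2
}

#' @export
print.microglia_frame <- function(x, ...) {
  cat(sprintf("microglia_frame: %dx%d px (%g um/px), %d cells (%d reporter-negative)\n",
              nrow(x$iba1), ncol(x$iba1), x$pixel_size, nrow(x$truth),
              sum(x$truth$reporter_negative)))
  invisible(x)
}

#' Write a frame's channels as image files
#' @param frame a `microglia_frame`.
#' @param prefix output prefix; writes `<prefix>_iba1.png` and
#'   `<prefix>_reporter.png`.
#' @return invisibly, the paths.
#' @export
write_frame_images <- function(frame, prefix) {
  paths <- paste0(prefix, c("_iba1.png", "_reporter.png"))
  EBImage::writeImage(EBImage::Image(frame$iba1), paths[1])
  EBImage::writeImage(EBImage::Image(frame$reporter), paths[2])
  invisible(paths)
}
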