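test_that("preprocess removes isolated pixels and keeps solid shapes", {
  img <- matrix(0, 40, 40)
  expect_false(any(preprocess(img)))
  img[20, 20] <- 1                       # single lit pixel: despeckled away
  expect_false(any(preprocess(img)))
  img2 <- matrix(0, 40, 40)
  img2[10:20, 15:25] <- 1                # solid rectangle: preserved
  mask <- preprocess(img2)
  expect_true(all(mask[11:19, 16:24]))
  expect_false(any(mask[, 1:10]))
})

test_that("otsu thresholding is available for external images", {
  img <- matrix(0.1, 30, 30)
  img[10:20, 10:20] <- 0.9
  mask <- preprocess(img, despeckle = FALSE, threshold = "otsu")
  expect_true(all(mask[10:20, 10:20]))
  expect_false(any(mask[1:5, 1:5]))
})

test_that("skeletonization thins, preserves components, and is idempotent on lines", {
  # 1-pixel line is unchanged
  line <- mask_from_coords(cbind(10, 5:45), 20, 50)
  expect_identical(unclass(skeletonize(line)), unclass(line))
  # empty mask stays empty
  empty <- mask_from_coords(matrix(numeric(0), ncol = 2), 10, 10)
  expect_false(any(skeletonize(empty)))
  # filled 21x3 rectangle thins to a 1-px horizontal line
  rect <- mask_from_coords(as.matrix(expand.grid(10:12, 5:25)), 22, 30)
  sk <- skeletonize(rect)
  on <- which(unclass(sk), arr.ind = TRUE)
  expect_true(all(on[, 1] == 11))                 # middle row only
  expect_gte(nrow(on), 17)
  # skeleton is a subset of the mask and components are preserved
  expect_true(all(unclass(rect)[unclass(sk)]))
  expect_equal(max(EBImage::bwlabel(unclass(sk) * 1)), 1)
})

test_that("skeleton analysis matches neighbour-count oracles on fixtures", {
  # plus sign: four 10-px arms from a centre
  centre <- c(25, 25)
  arms <- rbind(cbind(25, 26:35), cbind(25, 24:15),
                cbind(26:35, 25), cbind(24:15, 25))
  plus <- mask_from_coords(rbind(t(centre), arms), 50, 50)
  m <- analyze_skeleton(plus)
  expect_identical(m$n_endpoints, 4L)
  expect_identical(m$n_junctions, 1L)     # five junction pixels, one junction
  # 40 orthogonal steps plus the 4 diagonal adjacencies around the centre
  expect_equal(m$total_length, 40 + 4 * sqrt(2))
  # straight 50-px line: 2 endpoints, 49 steps
  line <- mask_from_coords(cbind(10, 1:50), 20, 60)
  ml <- analyze_skeleton(line)
  expect_identical(ml$n_endpoints, 2L)
  expect_identical(ml$n_junctions, 0L)
  expect_equal(ml$total_length, 49)
  # diagonal line: sqrt(2) steps
  diag_m <- mask_from_coords(cbind(1:20, 1:20), 25, 25)
  expect_equal(analyze_skeleton(diag_m)$total_length, 19 * sqrt(2))
  # empty skeleton: all zero
  empty <- analyze_skeleton(mask_from_coords(matrix(numeric(0), ncol = 2),
                                             10, 10))
  expect_identical(empty$n_endpoints, 0L)
  expect_equal(empty$total_length, 0)
})

test_that("skeleton metrics are invariant under rotation and reflection", {
  fr <- render_microglia_image(n_cells = 4, n_reporter_negative = 0, seed = 6)
  sk <- skeletonize(preprocess(fr$iba1, pixel_size = 1))
  base <- analyze_skeleton(sk)
  variants <- list(t(unclass(sk)),                       # transpose
                   unclass(sk)[nrow(sk):1, ],            # vertical flip
                   t(unclass(sk))[ncol(sk):1, ])         # 90-degree rotation
  for (v in variants) {
    vm <- analyze_skeleton(structure(v, pixel_size = 1,
                                     class = c("binary_mask", "matrix")))
    expect_identical(vm$n_endpoints, base$n_endpoints)
    expect_identical(vm$n_junctions, base$n_junctions)
    expect_equal(vm$total_length, base$total_length)
  }
})

test_that("cell counting recovers disjoint somata and ignores thin processes", {
  img <- matrix(0, 60, 60)
  disk <- function(cy, cx, r) {
    for (dy in -r:r) for (dx in -r:r)
      if (dy^2 + dx^2 <= r^2) img[cy + dy, cx + dx] <<- 1
  }
  disk(15, 15, 4); disk(45, 45, 4)
  img[30, 5:55] <- 1                      # a 1-px line must not count
  expect_identical(count_cells(img), 2L)
  expect_identical(count_cells(matrix(0, 30, 30)), 0L)
})

test_that("channel subtraction obeys its algebra", {
  a <- skeleton_metrics(10L, 4L, 120, 5L)
  expect_identical(subtract_channel_metrics(a, a)$n_endpoints, 0L)
  expect_equal(subtract_channel_metrics(a, a)$total_length, 0)
  zero <- skeleton_metrics(0L, 0L, 0, 0L)
  s <- subtract_channel_metrics(a, zero)
  expect_identical(s$n_endpoints, a$n_endpoints)
  expect_equal(s$total_length, a$total_length)
  expect_equal(s$length_per_cell, 24)
  # floored at zero
  b <- skeleton_metrics(20L, 8L, 300, 9L)
  s2 <- subtract_channel_metrics(a, b)
  expect_identical(s2$n_endpoints, 0L)
  expect_equal(s2$total_length, 0)
})

test_that("generator frames are recovered: endpoints exact, lengths within 10%", {
  for (seed in c(3, 17)) {
    fr <- render_microglia_image(n_cells = 9, n_reporter_negative = 2,
                                 seed = seed)
    res <- frame_morphometry(fr)
    expect_identical(res$iba1$n_cells, 9L)
    expect_identical(res$reporter$n_cells, 7L)
    expect_identical(res$iba1$n_endpoints, as.integer(sum(fr$truth$n_tips)))
    expect_lt(abs(res$iba1$total_length / sum(fr$truth$skeleton_length_um) - 1),
              0.1)
    tneg <- fr$truth[fr$truth$reporter_negative, ]
    expect_identical(res$subtracted$n_cells, 2L)
    expect_identical(res$subtracted$n_endpoints, as.integer(sum(tneg$n_tips)))
    expect_lt(abs(res$subtracted$total_length /
                    sum(tneg$skeleton_length_um) - 1), 0.1)
  }
})

test_that("identical channels subtract to zero; single process has 2 endpoints", {
  fr <- render_microglia_image(n_cells = 4, n_reporter_negative = 0, seed = 8)
  expect_identical(fr$iba1, fr$reporter)
  res <- frame_morphometry(fr)
  expect_identical(res$subtracted$n_endpoints, 0L)
  expect_equal(res$subtracted$total_length, 0)
  # degenerate single straight process, no soma
  fr2 <- render_microglia_image(n_cells = 1, n_reporter_negative = 0,
                                n_processes_range = c(1, 1),
                                proc_len_range = c(50, 50), soma_radius = 0,
                                branch_prob = 0, jitter = 0, seed = 5)
  expect_identical(fr2$truth$n_tips, 2L)
  sk <- skeletonize(preprocess(fr2$iba1, pixel_size = fr2$pixel_size))
  expect_identical(analyze_skeleton(sk)$n_endpoints, 2L)
})

test_that("overlap rejection errors out when a cell cannot be placed", {
  expect_error(
    render_microglia_image(n_cells = 4, n_reporter_negative = 0,
                           jitter = 500L, max_retries = 3L, seed = 1),
    "max_retries")
})

test_that("convex hull area: square, collinear, and brute-force oracle", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(as.numeric(convex_hull_area(sq)), 1)
  col <- rbind(c(0, 0), c(1, 1), c(2, 2), c(3, 3))
  a <- convex_hull_area(col)
  expect_equal(as.numeric(a), 0)
  expect_true(attr(a, "degenerate"))
  expect_true(attr(convex_hull_area(rbind(c(0, 0), c(1, 1))), "degenerate"))
  # exhaustive oracle: hull area = max over triangle subsets is a lower
  # bound; the exact oracle sums fan triangles from a hull vertex after a
  # full enumeration of extreme points
  brute_hull_area <- function(pts) {
    n <- nrow(pts)
    extreme <- rep(FALSE, n)
    for (i in 1:n) {
      inside <- FALSE
      for (a in 1:n) for (b in 1:n) for (c in 1:n) {
        if (length(unique(c(a, b, c, i))) < 4) next
        d1 <- sign((pts[a, 1] - pts[i, 1]) * (pts[b, 2] - pts[i, 2]) -
                     (pts[b, 1] - pts[i, 1]) * (pts[a, 2] - pts[i, 2]))
        d2 <- sign((pts[b, 1] - pts[i, 1]) * (pts[c, 2] - pts[i, 2]) -
                     (pts[c, 1] - pts[i, 1]) * (pts[b, 2] - pts[i, 2]))
        d3 <- sign((pts[c, 1] - pts[i, 1]) * (pts[a, 2] - pts[i, 2]) -
                     (pts[a, 1] - pts[i, 1]) * (pts[c, 2] - pts[i, 2]))
        if (d1 != 0 && d1 == d2 && d2 == d3) { inside <- TRUE; break }
      }
      extreme[i] <- !inside
    }
    hp <- pts[extreme, , drop = FALSE]
    ctr <- colMeans(hp)
    ord <- order(atan2(hp[, 2] - ctr[2], hp[, 1] - ctr[1]))
    hp <- hp[ord, , drop = FALSE]
    n2 <- nrow(hp); i2 <- c(2:n2, 1)
    abs(sum(hp[, 1] * hp[i2, 2] - hp[i2, 1] * hp[, 2])) / 2
  }
  set.seed(15)
  for (rep in 1:5) {
    pts <- matrix(runif(16), ncol = 2)
    expect_equal(as.numeric(convex_hull_area(pts)), brute_hull_area(pts))
  }
})
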