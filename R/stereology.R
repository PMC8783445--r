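# Section simulation, optical-fractionator counting with the unbiased
# counting-frame rule, the Schmitz-Hof second coefficient of error, and
# percent-of-control quantification.

#' Simulate a systematically sampled section series
#'
#' Cell positions within each section are a homogeneous Poisson process:
#' per-section counts are Poisson with mean
#' `density * width * height * thickness`, positions uniform in the section
#' plane. Ground-truth totals are retained.
#'
#' @param density true cell density (cells / um^3).
#' @param width,height section plane dimensions (um).
#' @param thickness section thickness (um), 25 by default.
#' @param n_sections number of sections in the series.
#' @param seed integer seed.
#' @return object of class `section_series`: `cells` (data.frame section,
#'   x, y), dimensions, and `true_total`.
#' @export
simulate_sections <- function(density, width = 2000, height = 2000,
                              thickness = 25, n_sections = 8L, seed = 1L) {
  if (density < 0) stop("density must be >= 0")
  with_seed(seed, {
    lambda <- density * width * height * thickness
    counts <- stats::rpois(n_sections, lambda)
    cells <- data.frame(
      section = rep(seq_len(n_sections), counts),
      x = stats::runif(sum(counts), 0, width),
      y = stats::runif(sum(counts), 0, height)
    )
    structure(list(cells = cells, width = width, height = height,
                   thickness = thickness, n_sections = n_sections,
                   true_total = sum(counts), density = density),
              class = "section_series")
  })
}

#' @export
print.section_series <- function(x, ...) {
  cat(sprintf("section_series: %d sections (%g x %g x %g um), %d cells\n",
              x$n_sections, x$width, x$height, x$thickness, x$true_total))
  invisible(x)
}

#' Fractionator sampling design
#'
#' @param frame_w,frame_h unbiased counting frame dimensions (um).
#' @param grid_x,grid_y sampling grid step (um); the area sampling fraction
#'   is `asf = frame_w * frame_h / (grid_x * grid_y)`.
#' @param section_interval every `section_interval`-th section is sampled
#'   (`ssf = 1 / section_interval`).
#' @param section_thickness um; counted over the full thickness (`tsf = 1`).
#' @param mode `"fractionator"` or `"exhaustive"` (all fractions 1).
#' @return object of class `fractionator_design`.
#' @export
fractionator_design <- function(frame_w = 150, frame_h = 150,
                                grid_x = 300, grid_y = 300,
                                section_interval = 36L,
                                section_thickness = 25,
                                mode = c("fractionator", "exhaustive")) {
  mode <- match.arg(mode)
  if (frame_w > grid_x || frame_h > grid_y)
    stop("counting frame must not exceed the sampling grid")
  structure(list(frame_w = frame_w, frame_h = frame_h, grid_x = grid_x,
                 grid_y = grid_y, section_interval = as.integer(section_interval),
                 section_thickness = section_thickness, mode = mode),
            class = "fractionator_design")
}

design_fractions <- function(design) {
  if (design$mode == "exhaustive")
    return(c(asf = 1, ssf = 1, tsf = 1))
  c(asf = (design$frame_w * design$frame_h) / (design$grid_x * design$grid_y),
    ssf = 1 / design$section_interval, tsf = 1)
}

#' Apply systematic-random counting frames to a section series
#'
#' Frames are placed on a systematic grid with a uniform random offset per
#' section. The unbiased counting-frame rule counts a cell strictly inside
#' the frame or on the inclusion edges (top, right) and never on the
#' exclusion edges (bottom, left): with frame x-interval `(fx, fx + w]` and
#' y-interval `(fy, fy + h]`, a cell exactly on the left or bottom edge is
#' excluded. In exhaustive mode every cell is counted.
#'
#' @param sections a [simulate_sections()] series (or compatible list with
#'   a `cells` data.frame).
#' @param design a [fractionator_design()].
#' @param seed offset seed.
#' @param offset optional fixed `c(ox, oy)` grid offset (um) overriding the
#'   random offsets, mainly for testing the edge rule.
#' @return integer vector of per-section counts `q_i`.
#' @export
apply_counting_frames <- function(sections, design, seed = 1L, offset = NULL) {
  cells <- sections$cells
  n_sec <- sections$n_sections
  if (design$mode == "exhaustive")
    return(tabulate(cells$section, nbins = n_sec))
  with_seed(seed, {
    q <- integer(n_sec)
    for (s in seq_len(n_sec)) {
      cs <- cells[cells$section == s, , drop = FALSE]
      if (nrow(cs) == 0) next
      ox <- if (is.null(offset)) stats::runif(1, 0, design$grid_x) else offset[1]
      oy <- if (is.null(offset)) stats::runif(1, 0, design$grid_y) else offset[2]
      # in-frame iff position falls in (fx, fx+w] modulo the grid step
      rx <- (cs$x - ox) %% design$grid_x
      ry <- (cs$y - oy) %% design$grid_y
      q[s] <- sum(rx > 0 & rx <= design$frame_w &
                    ry > 0 & ry <= design$frame_h)
    }
    q
  })
}

#' Schmitz-Hof second coefficient-of-error estimate
#'
#' `CE = sqrt( m/(m-1) * ( sum(q^2) / sum(q)^2 - 1/m ) )`, equal to the
#' sample coefficient of variation of the section counts divided by
#' `sqrt(m)`.
#'
#' @param q per-section counts.
#' @return scalar CE; `NA` when `sum(q) == 0` or fewer than 2 sections.
#' @export
schmitz_hof_ce <- function(q) {
  m <- length(q)
  if (m < 2 || sum(q) == 0) return(NA_real_)
  sqrt(m / (m - 1) * (sum(q^2) / sum(q)^2 - 1 / m))
}

#' Fractionator estimate of the total cell number
#'
#' `N_hat = sum(q) / (asf * ssf * tsf)` with the Schmitz-Hof second CE.
#' A zero total count yields estimate 0 with an undefined-CE flag.
#'
#' @param q per-section counts from [apply_counting_frames()].
#' @param design a [fractionator_design()].
#' @return object of class `fractionator_estimate`: `n_hat`, `ce`,
#'   `sum_q`, the sampling fractions and `q`.
#' @export
fractionator_estimate <- function(q, design) {
  fr <- design_fractions(design)
  sum_q <- sum(q)
  structure(list(n_hat = sum_q / prod(fr), ce = schmitz_hof_ce(q),
                 ce_undefined = sum_q == 0, sum_q = sum_q,
                 asf = fr[["asf"]], ssf = fr[["ssf"]], tsf = fr[["tsf"]],
                 q = q),
            class = "fractionator_estimate")
}

#' @export
print.fractionator_estimate <- function(x, ...) {
  cat(sprintf("fractionator estimate: N_hat = %.0f (sum q = %d over %d sections, asf %.3g, ssf %.3g, tsf %.3g), CE = %s\n",
              x$n_hat, x$sum_q, length(x$q), x$asf, x$ssf, x$tsf,
              if (x$ce_undefined) "undefined" else sprintf("%.4f", x$ce)))
  invisible(x)
}

#' Percent-of-control relative cell numbers
#'
#' @param estimates numeric vector of per-animal estimates (or a list of
#'   `fractionator_estimate`s).
#' @param control_estimates estimates for the control group.
#' @return numeric vector: each animal's estimate as a percentage of the
#'   control-group mean.
#' @export
relative_number <- function(estimates, control_estimates) {
  as_num <- function(x) {
    if (is.list(x)) vapply(x, function(e) e$n_hat, numeric(1)) else as.numeric(x)
  }
  est <- as_num(estimates); ctrl <- as_num(control_estimates)
  if (mean(ctrl) <= 0) stop("control mean must be > 0")
  100 * est / mean(ctrl)
}
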