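# Stochastic branching model of the microglial pool: mitotic loss of
# heterozygosity during development, logistic proliferation, a genotype-
# restricted depletion event, and post-depletion peripheral influx.

#' Population model parameters
#'
#' @param mu_loh probability, per heterozygous division, of a reciprocal
#'   LOH division yielding one WT_WT and one KI_KI daughter (mitotic G2
#'   recombination). Default 1e-3 gives a sub-1-percent label-free pool
#'   after development.
#' @param n_divisions synchronous developmental divisions before census.
#' @param n_founders founder pool size.
#' @param founder_genotype genotype of the founders (`"KI_WT"` for the
#'   heterozygous strain, `"KI_KI"` for the homozygous control cross).
#' @param growth_rate named per-day division probabilities at an empty niche,
#'   one per genotype; wild-type homozygotes divide fastest (receptor dosage
#'   advantage), cassette homozygotes slowest.
#' @param n_days days of post-census dynamics to simulate.
#' @param depletion_day day of the depletion event (`NA` = none).
#' @param depletion_efficiency fraction of cassette-carrying resident cells
#'   killed at the depletion event (applies only to KI_WT / KI_KI residents).
#' @param influx_rate expected peripheral cells entering per day after the
#'   depletion event (scaled by remaining niche space).
#' @param carrying_capacity niche size for the logistic division term.
#' @param seed integer seed.
#' @return object of class `population_params`.
#' @export
population_params <- function(mu_loh = 1e-3, n_divisions = 15L,
                              n_founders = 200L,
                              founder_genotype = c("KI_WT", "KI_KI", "WT_WT"),
                              growth_rate = c(WT_WT = 0.35, KI_WT = 0.25,
                                              KI_KI = 0.18,
                                              peripheral = 0.25),
                              n_days = 0L, depletion_day = NA_integer_,
                              depletion_efficiency = 0.9,
                              influx_rate = 0, carrying_capacity = 1e6,
                              seed = 1L) {
  founder_genotype <- match.arg(founder_genotype)
  stopifnot(mu_loh >= 0, mu_loh <= 1,
            depletion_efficiency >= 0, depletion_efficiency <= 1,
            all(growth_rate >= 0), n_divisions >= 0, n_founders >= 1)
  structure(list(mu_loh = mu_loh, n_divisions = as.integer(n_divisions),
                 n_founders = as.integer(n_founders),
                 founder_genotype = founder_genotype,
                 growth_rate = growth_rate, n_days = as.integer(n_days),
                 depletion_day = depletion_day,
                 depletion_efficiency = depletion_efficiency,
                 influx_rate = influx_rate,
                 carrying_capacity = carrying_capacity,
                 seed = as.integer(seed)),
            class = "population_params")
}

#' Simulate the branching population dynamics
#'
#' Development: `n_divisions` synchronous divisions from the founder pool;
#' each heterozygous division is, with probability `mu_loh`, a reciprocal
#' LOH division producing one WT_WT and one KI_KI daughter instead of two
#' heterozygotes. Census at division `n_divisions` is day 0.
#'
#' Daily dynamics: every cell divides with probability
#' `min(1, g_genotype * (1 - N / K))`; heterozygous divisions again undergo
#' LOH with probability `mu_loh`. On `depletion_day` each cassette-carrying
#' resident (KI_WT, KI_KI) is killed independently with probability
#' `depletion_efficiency`. After depletion, peripheral cells immigrate at
#' `influx_rate * (1 - N / K)` expected cells/day.
#'
#' All compartments are tracked by exact count updates (binomial/Poisson
#' draws), which is distribution-identical to per-cell simulation.
#'
#' @param params a [population_params()].
#' @return object of class `population_trajectory`: data.frame with columns
#'   `day`, `wt_wt`, `ki_wt`, `ki_ki`, `peripheral`, the corresponding
#'   `frac_*` columns (fractions of the day's total) and `total`.
#' @export
simulate_population_dynamics <- function(params) {
  stopifnot(inherits(params, "population_params"))
  with_seed(params$seed, {
    n <- c(WT_WT = 0, KI_WT = 0, KI_KI = 0, peripheral = 0)
    n[params$founder_genotype] <- params$n_founders

    for (d in seq_len(params$n_divisions)) {
      loh <- stats::rbinom(1, n[["KI_WT"]], params$mu_loh)
      n[["WT_WT"]] <- 2 * n[["WT_WT"]] + loh
      n[["KI_KI"]] <- 2 * n[["KI_KI"]] + loh
      n[["KI_WT"]] <- 2 * (n[["KI_WT"]] - loh)
      n[["peripheral"]] <- 2 * n[["peripheral"]]
    }

    days <- 0:params$n_days
    traj <- matrix(0, nrow = length(days), ncol = 4,
                   dimnames = list(NULL, names(n)))
    traj[1, ] <- n
    g <- params$growth_rate
    for (d in seq_len(params$n_days)) {
      N <- sum(n)
      p_div <- pmin(1, pmax(0, g[names(n)] * (1 - N / params$carrying_capacity)))
      div <- stats::rbinom(4, n, p_div)
      names(div) <- names(n)
      loh <- stats::rbinom(1, div[["KI_WT"]], params$mu_loh)
      n <- n + div
      n[["WT_WT"]] <- n[["WT_WT"]] + loh
      n[["KI_KI"]] <- n[["KI_KI"]] + loh
      n[["KI_WT"]] <- n[["KI_WT"]] - 2 * loh
      if (!is.na(params$depletion_day) && d == params$depletion_day) {
        n[["KI_WT"]] <- n[["KI_WT"]] -
          stats::rbinom(1, n[["KI_WT"]], params$depletion_efficiency)
        n[["KI_KI"]] <- n[["KI_KI"]] -
          stats::rbinom(1, n[["KI_KI"]], params$depletion_efficiency)
      }
      if (!is.na(params$depletion_day) && d >= params$depletion_day &&
          params$influx_rate > 0) {
        room <- max(0, 1 - sum(n) / params$carrying_capacity)
        n[["peripheral"]] <- n[["peripheral"]] +
          stats::rpois(1, params$influx_rate * room)
      }
      traj[d + 1L, ] <- n
    }
    out <- data.frame(day = days, traj)
    names(out)[2:5] <- c("wt_wt", "ki_wt", "ki_ki", "peripheral")
    out$total <- rowSums(traj)
    tot <- ifelse(out$total > 0, out$total, 1)
    out$frac_wt_wt <- out$wt_wt / tot
    out$frac_ki_wt <- out$ki_wt / tot
    out$frac_ki_ki <- out$ki_ki / tot
    out$frac_peripheral <- out$peripheral / tot
    class(out) <- c("population_trajectory", "data.frame")
    out
  })
}

#' @export
print.population_trajectory <- function(x, ...) {
  cat(sprintf("population_trajectory: %d days, final fractions wt/wt %.3f, ki/wt %.3f, ki/ki %.3f, peripheral %.3f\n",
              max(x$day), x$frac_wt_wt[nrow(x)], x$frac_ki_wt[nrow(x)],
              x$frac_ki_ki[nrow(x)], x$frac_peripheral[nrow(x)]))
  invisible(x)
}

#' Homeostatic label-free fraction at census over replicate simulations
#'
#' Runs the developmental branching phase for `n_replicates` independent
#' pools and returns the WT_WT (label-free) fraction at census for each.
#' The closed-form expectation is `mu_loh * n_divisions / 2`.
#'
#' @param params a [population_params()]; `n_days` is ignored (census only).
#' @param n_replicates number of replicate pools.
#' @param seed integer seed (per-replicate seeds derived from it).
#' @return numeric vector of census WT_WT fractions.
#' @export
census_wt_fraction <- function(params, n_replicates = 200L, seed = 1L) {
  p <- params
  p$n_days <- 0L
  vapply(seq_len(n_replicates), function(i) {
    p$seed <- (seed %% 1000000L) * 1000L + i
    tr <- simulate_population_dynamics(p)
    tr$frac_wt_wt[1]
  }, numeric(1))
}
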