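# Synthetic flow-cytometry event tables with per-population log-normal
# channel models and ground-truth labels.

#' Log-normal channel model for one population
#'
#' @param meanlog,sdlog per-channel log-normal parameters; `meanlog` is a
#'   named vector over channels, `sdlog` a scalar or named vector.
#' @return list used by [simulate_flow_events()].
#' @export
channel_model <- function(meanlog, sdlog = 0.35) {
  if (length(sdlog) == 1) sdlog <- stats::setNames(rep(sdlog, length(meanlog)),
                                                   names(meanlog))
  stopifnot(identical(sort(names(meanlog)), sort(names(sdlog))))
  list(meanlog = meanlog, sdlog = sdlog[names(meanlog)])
}

#' Simulate a flow-cytometry event table
#'
#' Each event is assigned a ground-truth population according to
#' `fractions`; channel intensities are independent log-normal draws from
#' that population's model, on a linear (compensated) scale.
#'
#' @param fractions named numeric vector of population fractions (sums to 1).
#' @param channel_models named list of [channel_model()]s, one per population,
#'   all over the same channel set.
#' @param n_events number of events (>= 0).
#' @param seed integer seed.
#' @return data.frame of class `event_table`: one row per event, one column
#'   per channel, plus a `label` ground-truth column.
#' @export
simulate_flow_events <- function(fractions, channel_models, n_events,
                                 seed = 1L) {
  if (n_events < 0) stop("n_events must be >= 0")
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  stopifnot(all(names(fractions) %in% names(channel_models)))
  channels <- names(channel_models[[1]]$meanlog)
  with_seed(seed, {
    lab <- sample(names(fractions), n_events, replace = TRUE, prob = fractions)
    out <- matrix(0, nrow = n_events, ncol = length(channels),
                  dimnames = list(NULL, channels))
    for (p in unique(lab)) {
      idx <- which(lab == p)
      cm <- channel_models[[p]]
      for (ch in channels)
        out[idx, ch] <- stats::rlnorm(length(idx), cm$meanlog[[ch]],
                                      cm$sdlog[[ch]])
    }
    df <- data.frame(out, check.names = FALSE)
    df$label <- lab
    class(df) <- c("event_table", "data.frame")
    df
  })
}

#' Default microglial population models
#'
#' Two resident microglial populations differing in reporter expression --
#' the reporter-positive heterozygote and the rare reporter-negative
#' wild-type homozygote, whose CX3CR1 location parameter is twice that of
#' the heterozygote (allele dosage) -- plus optional F4/80-high
#' peripheral-derived cells and a non-myeloid "debris" population excluded
#' by the upstream gates.
#'
#' Locations are separated by >= 4 log-sd between the high and low state of
#' every gating channel, so gate recovery is essentially exact.
#'
#' @param include_peripheral include the F4/80-high peripheral population.
#' @param include_debris include a CD11b-/CD45- debris population.
#' @param sdlog channel log-sd.
#' @return named list of [channel_model()]s.
#' @export
default_flow_populations <- function(include_peripheral = FALSE,
                                     include_debris = FALSE, sdlog = 0.35) {
  base <- c(viability = log(50), CD11b = log(1000), CD45 = log(800),
            Ly6C = log(20), Ly6G = log(20), EYFP = log(1500),
            CX3CR1 = log(1000), F4_80 = log(60))
  pos <- channel_model(base, sdlog)
  neg <- pos
  neg$meanlog[["EYFP"]] <- log(25)                 # reporter lost
  neg$meanlog[["CX3CR1"]] <- log(1000) + log(2)    # two wt receptor alleles
  out <- list(eyfp_pos = pos, eyfp_neg = neg)
  if (include_peripheral) {
    per <- pos
    per$meanlog[["F4_80"]] <- log(1500)
    per$meanlog[["CX3CR1"]] <- log(400)
    out$peripheral <- per
  }
  if (include_debris) {
    deb <- channel_model(stats::setNames(rep(log(15), length(base)),
                                         names(base)), sdlog)
    out$debris <- deb
  }
  out
}
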