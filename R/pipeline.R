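# End-to-end orchestration: each stage simulates its inputs, runs the
# corresponding analysis and emits a machine-readable summary; `all` chains
# every stage on a shared global seed.

PIPELINE_STAGES <- c("wgs-call", "pcr", "morpho", "stereo", "flow",
                     "rnaseq", "popdyn")

# Stable per-stage sub-seed derived from the global seed and stage name, so
# re-running one stage reproduces its slice of a full run.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 1009 + h) %% 2147480000)
}

#' Run one pipeline stage (or all of them)
#'
#' Every stage generates its own synthetic inputs at the configured scale,
#' runs the corresponding analysis modules and returns a summary list with
#' the stage name, parameters, sub-seed and key metrics. With an output
#' directory, each summary is also written as JSON.
#'
#' @param stage one of `"wgs-call"`, `"pcr"`, `"morpho"`, `"stereo"`,
#'   `"flow"`, `"rnaseq"`, `"popdyn"`, or `"all"`.
#' @param seed global seed; per-stage sub-seeds are derived from it.
#' @param outdir optional output directory for JSON summaries.
#' @param config named list of per-stage parameter overrides (see the
#'   stage functions' defaults).
#' @return for a single stage, its summary list; for `"all"`, a named list
#'   of summaries.
#' @export
run_pipeline <- function(stage = "all", seed = 1L, outdir = NULL,
                         config = list()) {
  if (!stage %in% c(PIPELINE_STAGES, "all"))
    stop("unknown stage: ", stage, " (known: ",
         paste(c(PIPELINE_STAGES, "all"), collapse = ", "), ")")
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  stages <- if (stage == "all") PIPELINE_STAGES else stage
  out <- lapply(stages, function(s) {
    sm <- run_stage(s, stage_seed(seed, s), config[[s]] %||% list())
    sm$stage <- s
    sm$global_seed <- seed
    if (!is.null(outdir))
      jsonlite::write_json(sm, file.path(outdir, paste0(s, ".json")),
                           auto_unbox = TRUE, digits = NA)
    sm
  })
  names(out) <- stages
  if (stage == "all") out else out[[1]]
}

run_stage <- function(stage, seed, cfg) {
  switch(stage,
    "wgs-call" = {
      depth <- cfg$depth %||% 30
      model <- make_locus_model(seed = seed)
      calls <- lapply(GENOTYPES, function(g)
        wgs_zygosity_pipeline(model, g, depth = depth,
                              seed = stage_seed(seed, g)))
      names(calls) <- GENOTYPES
      list(params = list(depth = depth, seed = seed),
           calls = lapply(calls, function(x)
             list(genotype = x$call$genotype, llr = x$call$llr,
                  wt_dosage = x$dosage$wt_dosage,
                  ki_dosage = x$dosage$ki_dosage)),
           correct = all(vapply(GENOTYPES, function(g)
             calls[[g]]$call$genotype == g, logical(1))))
    },
    "pcr" = {
      model <- make_locus_model(seed = seed)
      primers <- default_primer_set(model)
      bands <- lapply(GENOTYPES, function(g)
        genotype_from_bands(model, primers, g))
      names(bands) <- GENOTYPES
      list(params = list(seed = seed), bands = bands)
    },
    "morpho" = {
      frame <- render_microglia_image(
        n_cells = cfg$n_cells %||% 9L,
        n_reporter_negative = cfg$n_reporter_negative %||% 2L, seed = seed)
      m <- frame_morphometry(frame)
      list(params = list(n_cells = cfg$n_cells %||% 9L, seed = seed),
           iba1 = unclass(m$iba1), reporter = unclass(m$reporter),
           subtracted = unclass(m$subtracted))
    },
    "stereo" = {
      density <- cfg$density %||% 6.5e-5
      s <- simulate_sections(density, n_sections = cfg$n_sections %||% 8L,
                             seed = seed)
      q <- apply_counting_frames(s, fractionator_design(section_interval = 36L),
                                 seed = seed + 1L)
      est <- fractionator_estimate(q, fractionator_design(section_interval = 36L))
      list(params = list(density = density, seed = seed),
           sum_q = est$sum_q, n_hat = est$n_hat, ce = est$ce,
           true_total = s$true_total)
    },
    "flow" = {
      f_neg <- cfg$gfp_neg_frac %||% 0.0059
      ev <- simulate_flow_events(c(eyfp_pos = 1 - f_neg, eyfp_neg = f_neg),
                                 default_flow_populations(),
                                 cfg$n_events %||% 50000L, seed = seed)
      mem <- apply_gate_tree(ev, default_microglia_gates())
      list(params = list(gfp_neg_frac = f_neg, seed = seed),
           reporter_neg_fraction =
             population_fraction(mem, "reporter_neg", "microglia"),
           mfi_ratio = mfi(ev[ev$label == "eyfp_neg", ], "CX3CR1") /
             mfi(ev[ev$label == "eyfp_pos", ], "CX3CR1"))
    },
    "rnaseq" = {
      em <- simulate_expression(n_planted_deg = cfg$n_planted_deg %||% 32L,
                                seed = seed)
      de <- differential_expression(em)
      r <- rpkm(em)
      neg <- em$groups == "EYFP_neg"
      list(params = list(n_planted_deg = cfg$n_planted_deg %||% 32L,
                         seed = seed),
           n_significant = sum(de$table$significant),
           cx3cr1_rpkm_ratio = mean(r["Cx3cr1", neg]) / mean(r["Cx3cr1", !neg]),
           cre_rpkm_neg = mean(r["Cre", neg]),
           eyfp_rpkm_neg = mean(r["Eyfp", neg]))
    },
    "popdyn" = {
      fr <- census_wt_fraction(population_params(), n_replicates = 50L,
                               seed = seed)
      list(params = list(mu_loh = 1e-3, n_divisions = 15L, seed = seed),
           median_wt_fraction = stats::median(fr))
    })
}

#' Aggregate stage summaries into one report
#'
#' @param summaries list of stage summaries from [run_pipeline()].
#' @param path optional JSON output path.
#' @return the aggregated list (stage name -> summary), invisibly written
#'   to `path` when given. Aggregation is idempotent.
#' @export
aggregate_reports <- function(summaries, path = NULL) {
  if (length(summaries) == 0) {
    out <- list()
  } else {
    nm <- vapply(summaries, function(s) s$stage %||% "unnamed", character(1))
    out <- stats::setNames(summaries, nm)
  }
  if (!is.null(path))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  out
}
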