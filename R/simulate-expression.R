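# Negative-binomial count matrices for paired two-group pool RNA-seq with
# planted differentially expressed genes and the knock-in allele-dosage
# rules for Cx3cr1, Cre and Eyfp.

#' Simulate a paired two-group expression count matrix
#'
#' Counts are negative binomial around gene base means scaled by a
#' per-sample library factor. With `allele_rule = TRUE`, gene 1 is
#' "Cx3cr1" (mean in the reporter-negative group is twice the
#' reporter-positive group: two wild-type alleles vs one), genes 2 and 3
#' are "Cre" and "Eyfp" (mean exactly 0 in the reporter-negative group) --
#' these three count toward `n_planted_deg`, mirroring a DEG list in which
#' the transgene products and Cx3cr1 itself appear. The remaining
#' `n_planted_deg - 3` genes get symmetric `+/- effect_log2fc` shifts.
#'
#' @param n_genes total genes.
#' @param n_planted_deg number of true DEGs (including the three
#'   allele-dosage genes when `allele_rule`); `<= n_genes`.
#' @param effect_log2fc absolute log2 fold change of planted DEGs.
#' @param n_pairs sample pairs (one reporter-negative and one
#'   reporter-positive sample per pair).
#' @param dispersion NB dispersion (1/size); 0.02 reflects the low
#'   biological noise of 100-cell sorted pools.
#' @param allele_rule apply the Cx3cr1/Cre/Eyfp dosage rules.
#' @param base_meanlog,base_sdlog log-normal distribution of gene base
#'   means.
#' @param seed integer seed.
#' @return object of class `expression_matrix`: `counts` (genes x samples),
#'   `gene_lengths` (bp), `groups` (factor EYFP_neg / EYFP_pos), `pairs`,
#'   `truth` (data.frame gene, is_deg, log2fc).
#' @export
simulate_expression <- function(n_genes = 2000L, n_planted_deg = 32L,
                                effect_log2fc = 3, n_pairs = 5L,
                                dispersion = 0.02, allele_rule = TRUE,
                                base_meanlog = log(100), base_sdlog = 1,
                                seed = 1L) {
  if (n_planted_deg > n_genes) stop("n_planted_deg must be <= n_genes")
  if (allele_rule && n_genes < 3) stop("allele_rule needs at least 3 genes")
  if (allele_rule && n_planted_deg < 3)
    stop("with allele_rule the three dosage genes are themselves DEGs; n_planted_deg must be >= 3")
  with_seed(seed, {
    genes <- sprintf("gene%04d", seq_len(n_genes))
    n_marker <- 0L
    if (allele_rule) {
      genes[1:3] <- c("Cx3cr1", "Cre", "Eyfp")
      n_marker <- 3L
    }
    base <- stats::rlnorm(n_genes, base_meanlog, base_sdlog)
    if (allele_rule) base[1] <- 3000    # Cx3cr1: highly expressed marker

    log2fc <- numeric(n_genes)          # EYFP_neg relative to EYFP_pos
    n_extra <- n_planted_deg - n_marker
    pool <- setdiff(seq_len(n_genes), seq_len(n_marker))
    planted <- if (n_extra > 0) sample(pool, n_extra) else integer(0)
    signs <- rep(c(1, -1), length.out = length(planted))
    log2fc[planted] <- signs * effect_log2fc

    groups <- factor(rep(c("EYFP_neg", "EYFP_pos"), each = n_pairs),
                     levels = c("EYFP_neg", "EYFP_pos"))
    pairs <- rep(seq_len(n_pairs), times = 2)
    lib_factor <- stats::rlnorm(2 * n_pairs, 0, 0.15)

    mu <- matrix(base, n_genes, 2 * n_pairs)
    neg <- groups == "EYFP_neg"
    mu[, neg] <- mu[, neg] * 2^log2fc
    if (allele_rule) {
      mu[1, neg] <- 2 * base[1]      # two wt Cx3cr1 alleles
      mu[2:3, neg] <- 0              # no Cre / Eyfp transcript
    }
    mu <- sweep(mu, 2, lib_factor, "*")
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / dispersion),
                     n_genes, 2 * n_pairs)
    dimnames(counts) <- list(genes, paste0(groups, "_", pairs))
    gene_lengths <- stats::setNames(
      round(stats::runif(n_genes, 500, 5000)), genes)

    is_deg <- log2fc != 0
    if (allele_rule) is_deg[1:3] <- TRUE
    structure(list(counts = counts, gene_lengths = gene_lengths,
                   groups = groups, pairs = pairs,
                   truth = data.frame(gene = genes, is_deg = is_deg,
                                      log2fc = log2fc,
                                      stringsAsFactors = FALSE)),
              class = "expression_matrix")
  })
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%d true DEGs)\n",
              nrow(x$counts), ncol(x$counts), sum(x$truth$is_deg)))
  invisible(x)
}
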