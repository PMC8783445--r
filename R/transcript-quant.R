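# Expression summarisation and differential-expression statistics: RPKM,
# heteroscedastic / paired t tests, one-way F test, Benjamini-Hochberg
# correction, PCA sample scores and row z-scoring.

#' RPKM normalisation
#'
#' `RPKM = counts * 1e9 / (gene_length * library_size)`, with library size
#' the per-sample total mapped counts unless supplied.
#'
#' @param counts genes x samples count matrix, or an `expression_matrix`.
#' @param gene_lengths gene lengths in bp (ignored for an
#'   `expression_matrix`).
#' @param lib_sizes per-sample library sizes; defaults to `colSums(counts)`.
#' @return matrix of RPKM values with the same dimnames.
#' @export
rpkm <- function(counts, gene_lengths = NULL, lib_sizes = NULL) {
  if (inherits(counts, "expression_matrix")) {
    gene_lengths <- counts$gene_lengths
    counts <- counts$counts
  }
  if (is.null(gene_lengths)) stop("gene_lengths required")
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  if (any(gene_lengths <= 0)) stop("gene lengths must be > 0")
  if (any(lib_sizes <= 0)) stop("library sizes must be > 0")
  sweep(counts / gene_lengths, 2, lib_sizes, "/") * 1e9
}

# Row-wise two-sided p-values; x: genes x samples matrix.
row_test_p <- function(x, sel_a, sel_b, paired = FALSE) {
  apply(x, 1, function(v) {
    a <- v[sel_a]; b <- v[sel_b]
    if (paired && length(a) != length(b))
      stop("paired test requires complete pairs")
    if (stats::sd(c(a, b)) == 0) return(NA_real_)  # degenerate, flagged upstream
    tryCatch(stats::t.test(a, b, paired = paired, var.equal = FALSE)$p.value,
             error = function(e) NA_real_)
  })
}

#' Welch (heteroscedastic) two-sided t test per gene
#'
#' @param x genes x samples matrix of expression values.
#' @param groups two-level factor over the columns.
#' @return numeric vector of p-values (NA for degenerate genes).
#' @export
welch_t <- function(x, groups) {
  groups <- as.factor(groups)
  lv <- levels(droplevels(groups))
  if (length(lv) != 2) stop("welch_t needs exactly 2 groups")
  if (min(table(groups)) < 2) stop("need >= 2 samples per group")
  row_test_p(x, groups == lv[1], groups == lv[2], paired = FALSE)
}

#' Paired two-sided t test per gene
#'
#' Columns are matched by `pairs` within the two levels of `groups`.
#'
#' @param x genes x samples matrix.
#' @param groups two-level factor.
#' @param pairs pair identifiers over the columns.
#' @return numeric vector of p-values.
#' @export
paired_t <- function(x, groups, pairs) {
  groups <- as.factor(groups)
  lv <- levels(droplevels(groups))
  if (length(lv) != 2) stop("paired_t needs exactly 2 groups")
  ia <- which(groups == lv[1]); ib <- which(groups == lv[2])
  ib <- ib[match(pairs[ia], pairs[ib])]
  if (anyNA(ib)) stop("incomplete pairs")
  row_test_p(x, ia, ib, paired = TRUE)
}

#' One-way F test per gene (3 or more groups)
#'
#' Classical equal-variance one-way ANOVA F test via [stats::oneway.test()].
#'
#' @param x genes x samples matrix.
#' @param groups factor with >= 3 levels.
#' @return numeric vector of p-values.
#' @export
oneway_f <- function(x, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 3) stop("oneway_f needs >= 3 groups")
  apply(x, 1, function(v) {
    if (stats::sd(v) == 0) return(NA_real_)
    tryCatch(stats::oneway.test(v ~ groups, var.equal = TRUE)$p.value,
             error = function(e) NA_real_)
  })
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up adjustment `q_(i) = min_(j >= i) ( p_(j) * m / j )` capped at 1,
#' returned in the original order. NAs are propagated and excluded from
#' `m`.
#'
#' @param p p-values.
#' @return q-values of the same length.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Differential expression between two groups
#'
#' Tests are run on `log2(RPKM + pseudocount)`; fold changes are
#' `log2((mean RPKM + pseudocount) / (mean RPKM + pseudocount))` between
#' groups (first level relative to second). Genes with zero counts in all
#' samples, or identical values in every sample, are excluded from testing
#' (and from the BH `m`) and flagged.
#'
#' @param em an `expression_matrix` (or a list with `counts`,
#'   `gene_lengths`, `groups`, optionally `pairs`).
#' @param method `"welch"` or `"paired"`.
#' @param fdr significance cutoff on BH-adjusted q-values.
#' @param pseudocount RPKM pseudocount for fold changes and log transforms.
#' @return object of class `deg_result`: data.frame `table` (gene, mean
#'   RPKM per group, log2fc, p, q, significant, excluded) plus the call
#'   parameters. Volcano coordinates are `(log2fc, -log10(q))`.
#' @export
differential_expression <- function(em, method = c("welch", "paired"),
                                    fdr = 0.05, pseudocount = 1) {
  method <- match.arg(method)
  r <- rpkm(em)
  groups <- as.factor(em$groups)
  lv <- levels(droplevels(groups))
  x <- log2(r + pseudocount)
  excluded <- apply(em$counts, 1, function(v) all(v == 0)) |
    apply(x, 1, stats::sd) == 0
  p <- rep(NA_real_, nrow(r))
  xt <- x[!excluded, , drop = FALSE]
  p[!excluded] <- if (method == "welch") welch_t(xt, groups)
                  else paired_t(xt, groups, em$pairs)
  q <- rep(NA_real_, length(p))
  q[!excluded] <- bh_adjust(p[!excluded])
  m_a <- rowMeans(r[, groups == lv[1], drop = FALSE])
  m_b <- rowMeans(r[, groups == lv[2], drop = FALSE])
  tab <- data.frame(
    gene = rownames(r) %||% seq_len(nrow(r)),
    mean_rpkm_a = m_a, mean_rpkm_b = m_b,
    log2fc = log2((m_a + pseudocount) / (m_b + pseudocount)),
    p = p, q = q,
    significant = !is.na(q) & q < fdr,
    excluded = excluded,
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  structure(list(table = tab, method = method, fdr = fdr,
                 groups = lv, pseudocount = pseudocount),
            class = "deg_result")
}

#' @export
print.deg_result <- function(x, ...) {
  cat(sprintf("deg_result (%s test, FDR < %g): %d significant of %d tested (%d excluded)\n",
              x$method, x$fdr, sum(x$table$significant),
              sum(!x$table$excluded), sum(x$table$excluded)))
  up <- x$table[x$table$significant & x$table$log2fc > 0, ]
  if (nrow(up)) {
    up <- up[order(up$q), ]
    cat("  top up:", paste(utils::head(up$gene, 5), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Row z-scoring (mean-centred, sigma-normalised)
#'
#' Constant rows cannot be scaled; they are dropped and reported in the
#' `dropped` attribute.
#'
#' @param x genes x samples matrix.
#' @return matrix with each remaining row at mean 0, sd 1.
#' @export
zscore_rows <- function(x) {
  sds <- apply(x, 1, stats::sd)
  keep <- sds > 0
  out <- (x[keep, , drop = FALSE] - rowMeans(x[keep, , drop = FALSE])) /
    sds[keep]
  attr(out, "dropped") <- rownames(x)[!keep] %||% which(!keep)
  out
}

#' PCA sample scores on a p-value-prefiltered gene set
#'
#' Rows are mean-centred (optionally z-scored); scores come from the
#' singular value decomposition of the centred matrix. Sign convention:
#' each component's largest-magnitude gene loading is positive.
#'
#' @param x genes x samples expression matrix.
#' @param gene_p per-gene p-values for the prefilter (e.g. from
#'   [oneway_f()]); `NULL` disables filtering.
#' @param p_cutoff prefilter cutoff (genes with `p < p_cutoff` kept).
#' @param scale_rows z-score rows before the decomposition.
#' @param n_components number of components returned.
#' @return list with `scores` (samples x components), `loadings`,
#'   `var_explained`, `n_genes_used`.
#' @export
pca_scores <- function(x, gene_p = NULL, p_cutoff = 0.05,
                       scale_rows = FALSE, n_components = 2L) {
  if (!is.null(gene_p)) {
    keep <- !is.na(gene_p) & gene_p < p_cutoff
    x <- x[keep, , drop = FALSE]
  }
  if (scale_rows) x <- zscore_rows(x) else {
    x <- x[apply(x, 1, stats::sd) > 0, , drop = FALSE]
    x <- x - rowMeans(x)
  }
  if (nrow(x) < 1) stop("no genes left after prefilter")
  sv <- svd(x)
  k <- min(n_components, length(sv$d))
  loadings <- sv$u[, seq_len(k), drop = FALSE]
  scores <- sv$v[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  for (j in seq_len(k)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- colnames(x)
  colnames(scores) <- paste0("PC", seq_len(k))
  list(scores = scores, loadings = loadings,
       var_explained = sv$d^2 / sum(sv$d^2), n_genes_used = nrow(x))
}
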