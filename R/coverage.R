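# Physical (fragment-span) coverage and the allele-dosage / junction-read
# zygosity inference: the statistic by which reporter-negative microglia were
# shown to be homozygous wild type at the knock-in locus.

#' Physical coverage track for one contig
#'
#' Physical coverage counts, for every base, the number of retained
#' fragments whose outer mapping span (paired-read outer distance) covers
#' that base -- fragment-span coverage, not read-base coverage. Computed by
#' difference-array accumulation over the proper-pair fragment spans.
#'
#' @param aln a filtered `alignment_set` (proper, non-duplicate,
#'   MAPQ-passing pairs).
#' @param contig contig name.
#' @return object of class `coverage_track`: integer vector `counts`
#'   (length = contig length), `contig`, and `n_fragments` (total retained
#'   fragments across all contigs, the per-million normalisation basis).
#' @export
physical_coverage <- function(aln, contig) {
  stopifnot(inherits(aln, "alignment_set"))
  if (!contig %in% names(aln$contig_len))
    stop("unknown contig: ", contig)
  len <- aln$contig_len[[contig]]
  r <- aln$records
  sel <- r$proper & !is.na(r$contig) & r$contig == contig
  d <- numeric(len + 1L)
  if (any(sel)) {
    s <- r$fragment_start[sel]; e <- pmin(r$fragment_end[sel], len)
    add_s <- tabulate(s + 1L, nbins = len + 1L)
    add_e <- tabulate(e + 1L, nbins = len + 1L)
    d <- add_s - add_e
  }
  counts <- as.integer(cumsum(d)[seq_len(len)])
  structure(list(counts = counts, contig = contig,
                 n_fragments = sum(r$proper)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track on %s: %d bp, mean %.2f, %d retained fragments\n",
              x$contig, length(x$counts), mean(x$counts), x$n_fragments))
  invisible(x)
}

#' Mean (optionally per-million-fragment normalised) coverage over a region
#'
#' @param track a `coverage_track`.
#' @param region 0-based half-open interval `c(start, end)` on the track's
#'   contig, or a `list(contig, interval)` from [region_lookup()].
#' @param normalize divide by (retained fragments / 1e6).
#' @return scalar mean coverage.
#' @export
region_mean_coverage <- function(track, region, normalize = FALSE) {
  stopifnot(inherits(track, "coverage_track"))
  if (is.list(region)) {
    if (!is.null(region$contig) && region$contig != track$contig)
      stop("region is on contig ", region$contig, ", track on ", track$contig)
    region <- region$interval
  }
  s <- region[1]; e <- region[2]
  if (e <= s) stop("zero-length region")
  if (s < 0 || e > length(track$counts)) stop("region outside contig bounds")
  m <- mean(track$counts[(s + 1L):e])
  if (normalize) m <- m / (track$n_fragments / 1e6)
  m
}

#' Allele dosage estimate from region coverages
#'
#' The flank coverage anchors the per-copy (single-allele) rate: a locus
#' present on both alleles has twice the per-copy coverage. Expected
#' (wt_dosage, ki_dosage) are (2,0), (1,1), (0,2) for WT_WT, KI_WT, KI_KI.
#'
#' @param cov_exon2 mean coverage over the wild-type exon (wt allele only).
#' @param cov_cassette mean coverage over the cassette contig (ki allele only).
#' @param cov_flank mean coverage over the normalisation flanks (both alleles).
#' @return object of class `dosage_estimate` with `wt_dosage`, `ki_dosage`
#'   and the input coverages.
#' @export
estimate_dosage <- function(cov_exon2, cov_cassette, cov_flank) {
  if (!is.finite(cov_flank) || cov_flank <= 0)
    stop("insufficient data: flank coverage must be > 0")
  structure(list(
    wt_dosage = 2 * cov_exon2 / cov_flank,
    ki_dosage = 2 * cov_cassette / cov_flank,
    cov_exon2 = cov_exon2, cov_cassette = cov_cassette, cov_flank = cov_flank
  ), class = "dosage_estimate")
}

#' @export
print.dosage_estimate <- function(x, ...) {
  cat(sprintf("dosage: wt %.2f, ki %.2f (exon %.2f / cassette %.2f / flank %.2f)\n",
              x$wt_dosage, x$ki_dosage, x$cov_exon2, x$cov_cassette, x$cov_flank))
  invisible(x)
}

#' Junction-read evidence for the knock-in allele
#'
#' A fragment is wild-type-spanning when its genome-contig outer span
#' strictly contains an insertion junction (at least 1 bp on each side);
#' knock-in-supporting when its mates map split between the genome and the
#' cassette contig. Pass an alignment set filtered with
#' `require_proper = FALSE` so cross-contig pairs are still present.
#'
#' @param aln an `alignment_set`.
#' @param ref a `reference_set` (provides the junction coordinates).
#' @return object of class `junction_evidence` with `n_wt_spanning` and
#'   `n_ki_supporting`.
#' @export
count_junction_pairs <- function(aln, ref) {
  stopifnot(inherits(aln, "alignment_set"), inherits(ref, "reference_set"))
  r <- aln$records
  jl <- ref$coord_map$junction_left; jr <- ref$coord_map$junction_right
  g <- r$proper & !is.na(r$contig) & r$contig == "genome"
  spans <- function(j) sum(g & r$fragment_start < j & r$fragment_end > j)
  n_wt <- spans(jl) + spans(jr)
  split_pair <- !is.na(r$r1_contig) & !is.na(r$r2_contig) &
    r$r1_contig != r$r2_contig &
    (r$r1_contig == "cassette_nongenomic" | r$r2_contig == "cassette_nongenomic")
  n_ki <- sum(split_pair & !r$duplicate)
  structure(list(n_wt_spanning = as.integer(n_wt),
                 n_ki_supporting = as.integer(n_ki)),
            class = "junction_evidence")
}

#' @export
print.junction_evidence <- function(x, ...) {
  cat(sprintf("junction evidence: %d wt-spanning, %d ki-supporting fragments\n",
              x$n_wt_spanning, x$n_ki_supporting))
  invisible(x)
}

#' Expected-count depth model for genotype likelihoods
#'
#' Per-copy Poisson rates are anchored on the flank fragment density
#' (fragments per bp per allele copy): `rho = n_flank / (2 * flank_len)`.
#' Region rates scale with region length; junction rates with the fragment
#' geometry (a fragment spans a junction point over ~`fragment_mean` start
#' positions; a split pair requires the junction to fall between the mates,
#' ~`fragment_mean - 2 * read_len` positions).
#'
#' @param n_flank fragments with midpoint in the flanks.
#' @param flank_len total flank length (bp).
#' @param exon_len,cassette_len region lengths (bp).
#' @param fragment_mean,read_len fragment geometry.
#' @return list of per-copy rates used by [call_genotype()].
#' @export
depth_model <- function(n_flank, flank_len, exon_len, cassette_len,
                        fragment_mean = 350, read_len = 75) {
  if (n_flank <= 0) stop("no-call: flank fragment rate is zero")
  rho <- n_flank / (2 * flank_len)
  list(rho = rho,
       exon_per_copy = rho * exon_len,
       cassette_per_copy = rho * cassette_len,
       junction_wt_per_copy = rho * 2 * max(fragment_mean - 2, 1),
       junction_ki_per_copy = rho * 2 * max(fragment_mean - 2 * read_len, 1))
}

# Count fragments whose midpoint falls in a genome region / on a contig.
fragment_midpoint_count <- function(aln, contig, interval = NULL) {
  r <- aln$records
  sel <- r$proper & !is.na(r$contig) & r$contig == contig
  if (is.null(interval)) return(sum(sel))
  mid <- (r$fragment_start[sel] + r$fragment_end[sel]) / 2
  sum(mid >= interval[1] & mid < interval[2])
}

#' Call the knock-in genotype from dosage and junction evidence
#'
#' Observed fragment counts over the wild-type exon, the cassette contig and
#' the two junctions are modelled as independent Poisson draws with expected
#' values (allele copies) x (per-copy rate from the flank anchor), plus a
#' small background rate (1% of the per-copy rate + 0.05) absorbing stray
#' mismapped fragments. The call is the maximum-likelihood genotype; the
#' reported confidence is the log-likelihood ratio between the best and
#' second-best genotype.
#'
#' @param dosage a `dosage_estimate` (reported alongside, not used in the
#'   likelihood).
#' @param junctions a `junction_evidence`.
#' @param counts list with observed `n_exon`, `n_cassette` (fragment
#'   midpoint counts).
#' @param model a [depth_model()].
#' @return object of class `genotype_call`: `genotype`, `loglik` (per
#'   genotype), `llr`, plus the supporting evidence.
#' @export
call_genotype <- function(dosage, junctions, counts, model) {
  stopifnot(inherits(junctions, "junction_evidence"))
  bg <- function(rate) 0.01 * rate + 0.05
  ll <- vapply(GENOTYPES, function(g) {
    ac <- allele_counts(g)
    stats::dpois(counts$n_exon, ac["wt"] * model$exon_per_copy +
                   bg(model$exon_per_copy), log = TRUE) +
      stats::dpois(counts$n_cassette, ac["ki"] * model$cassette_per_copy +
                     bg(model$cassette_per_copy), log = TRUE) +
      stats::dpois(junctions$n_wt_spanning, ac["wt"] * model$junction_wt_per_copy +
                     bg(model$junction_wt_per_copy), log = TRUE) +
      stats::dpois(junctions$n_ki_supporting, ac["ki"] * model$junction_ki_per_copy +
                     bg(model$junction_ki_per_copy), log = TRUE)
  }, numeric(1))
  ord <- order(ll, decreasing = TRUE)
  structure(list(genotype = GENOTYPES[ord[1]],
                 loglik = ll,
                 llr = ll[ord[1]] - ll[ord[2]],
                 dosage = dosage, junctions = junctions, counts = counts),
            class = "genotype_call")
}

#' @export
print.genotype_call <- function(x, ...) {
  cat(sprintf("genotype call: %s (LLR %.1f)\n", x$genotype, x$llr))
  if (!is.null(x$dosage))
    cat(sprintf("  dosage wt %.2f / ki %.2f; junctions wt %d / ki %d\n",
                x$dosage$wt_dosage, x$dosage$ki_dosage,
                x$junctions$n_wt_spanning, x$junctions$n_ki_supporting))
  invisible(x)
}

#' End-to-end zygosity call on a simulated sample
#'
#' Convenience pipeline: simulate read pairs for a genotype, map them to the
#' hybrid reference, mark duplicates, apply the duplicate + MAPQ filters,
#' compute physical coverage, dosage, junction evidence and the genotype
#' call.
#'
#' @param model a `locus_model`.
#' @param genotype true genotype to simulate.
#' @param depth target physical-coverage depth (fragments are
#'   `depth * genome_length / fragment_mean`).
#' @param seed integer seed.
#' @param dup_rate duplicate fraction passed to the simulator.
#' @param error_rate sequencing error rate.
#' @return list with `call` (a `genotype_call`), `dosage`, `tracks`,
#'   `norm_exon2_head` (per-million normalised coverage of the 290 bp exon
#'   head), and the filtered alignment set sizes.
#' @export
wgs_zygosity_pipeline <- function(model, genotype, depth = 30, seed = 1L,
                                  dup_rate = 0.02, error_rate = 1e-3) {
  ref <- build_hybrid_reference(model)
  n_frag <- round(depth * nchar(model$genome_seq) / 350)
  reads <- simulate_wgs_readpairs(model, genotype, n_fragments = n_frag,
                                  dup_rate = dup_rate,
                                  error_rate = error_rate, seed = seed)
  aln <- mark_duplicates(map_readpairs(reads, ref))
  kept_all <- filter_alignments(aln, require_proper = FALSE)
  kept <- filter_alignments(aln, require_proper = TRUE)

  track_g <- physical_coverage(kept, "genome")
  track_c <- physical_coverage(kept, "cassette_nongenomic")
  flanks <- rbind(region_lookup(ref, "flank_left")$interval,
                  region_lookup(ref, "flank_right")$interval)
  cov_flank <- mean(c(
    region_mean_coverage(track_g, region_lookup(ref, "flank_left")),
    region_mean_coverage(track_g, region_lookup(ref, "flank_right"))))
  cov_exon <- region_mean_coverage(track_g, region_lookup(ref, "exon2"))
  cov_cass <- region_mean_coverage(track_c, region_lookup(ref, "cassette_inserted"))
  dosage <- estimate_dosage(cov_exon, cov_cass, cov_flank)

  exon_iv <- region_lookup(ref, "exon2")$interval
  cass_iv <- region_lookup(ref, "cassette_inserted")$interval
  n_flank <- fragment_midpoint_count(kept, "genome", flanks[1, ]) +
    fragment_midpoint_count(kept, "genome", flanks[2, ])
  counts <- list(
    n_exon = fragment_midpoint_count(kept, "genome", exon_iv),
    n_cassette = fragment_midpoint_count(kept, "cassette_nongenomic", cass_iv))
  dm <- depth_model(n_flank,
                    flank_len = sum(flanks[, 2] - flanks[, 1]),
                    exon_len = iv_len(exon_iv),
                    cassette_len = iv_len(cass_iv),
                    fragment_mean = reads$fragment_mean,
                    read_len = reads$read_len)
  junc <- count_junction_pairs(kept_all, ref)
  call <- call_genotype(dosage, junc, counts, dm)
  list(call = call, dosage = dosage,
       norm_exon2 = region_mean_coverage(track_g, region_lookup(ref, "exon2"),
                                         normalize = TRUE),
       norm_exon2_head = region_mean_coverage(
         track_g, region_lookup(ref, "exon2_head"), normalize = TRUE),
       tracks = list(genome = track_g, cassette = track_c),
       n_retained = sum(kept$records$proper))
}

#' Export a coverage track as bedGraph
#' @param track a `coverage_track`.
#' @param path output path.
#' @param normalize write per-million-fragment normalised values.
#' @return invisibly, `path`.
#' @export
write_bedgraph <- function(track, path, normalize = FALSE) {
  stopifnot(inherits(track, "coverage_track"))
  v <- track$counts
  if (normalize) v <- v / (track$n_fragments / 1e6)
  rle_v <- rle(v)
  ends <- cumsum(rle_v$lengths)
  starts <- c(0L, ends[-length(ends)])
  writeLines(sprintf("%s\t%d\t%d\t%g", track$contig, starts, ends,
                     rle_v$values), path)
  invisible(path)
}
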