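# Toy diploid locus: a genome contig whose protein-coding exon is replaced,
# on the knock-in allele, by a CreERT2-Eyfp-like cassette segment.

#' Construct the toy knock-in locus model
#'
#' Builds a random diploid locus emulating the Cx3cr1 CreER-Eyfp knock-in: a
#' genome contig carrying the wild-type protein-coding exon (`exon2`), and a
#' cassette sequence of which only the interval `cassette_inserted` is
#' integrated into the genome on the knock-in allele, replacing `exon2`.
#' All intervals are 0-based half-open.
#'
#' Default sizes (50 kb contig, 1.5 kb exon, 5 kb inserted cassette) keep the
#' flank/exon windows well separated while allowing seconds-scale read
#' simulation and alignment.
#'
#' @param genome_length length of the genome contig (bp), 20--200 kb.
#' @param exon2_start 0-based start of the protein-coding exon.
#' @param exon2_length exon length in bp, must be >= 290.
#' @param cassette_length total cassette sequence length (4--6 kb).
#' @param cassette_inserted 0-based half-open interval of the cassette that is
#'   integrated into the genome (the non-genomic vector part analog).
#' @param flank_length length of each normalisation flank placed immediately
#'   left and right of the analysis window margins.
#' @param window_pad padding of the analysis window on each side of the exon.
#' @param seed integer seed; the model is deterministic given the seed.
#' @return an object of class `locus_model` with elements `genome_seq`,
#'   `cassette_seq`, and intervals `exon2`, `exon2_head`, `analysis_window`,
#'   `flank_left`, `flank_right`, `cassette_inserted`.
#' @export
make_locus_model <- function(genome_length = 50000L,
                             exon2_start = 24000L,
                             exon2_length = 1500L,
                             cassette_length = 6000L,
                             cassette_inserted = c(1000L, 6000L),
                             flank_length = 8000L,
                             window_pad = 10000L,
                             seed = 1L) {
  if (genome_length < 20000L || genome_length > 200000L)
    stop("genome_length must be in [20000, 200000]")
  if (exon2_length < 290L)
    stop("exon2_length must be >= 290 (the head window is its first 290 bases)")
  if (cassette_length < 4000L || cassette_length > 6000L)
    stop("cassette_length must be in [4000, 6000]")
  if (cassette_inserted[1] < 0L || cassette_inserted[2] > cassette_length ||
      cassette_inserted[2] <= cassette_inserted[1])
    stop("cassette_inserted must be a non-empty interval within the cassette")
  exon2 <- iv(exon2_start, exon2_start + exon2_length)
  if (exon2["end"] + flank_length + window_pad > genome_length ||
      exon2["start"] - flank_length - window_pad < 0L)
    stop("exon and flanks do not fit inside the genome contig")

  analysis_window <- iv(exon2["start"] - window_pad, exon2["end"] + window_pad)
  flank_left <- iv(exon2["start"] - flank_length, exon2["start"])
  flank_right <- iv(exon2["end"], exon2["end"] + flank_length)

  seqs <- with_seed(seed, {
    list(genome = random_dna(genome_length),
         cassette = random_dna(cassette_length))
  })

  model <- structure(list(
    genome_seq = seqs$genome,
    cassette_seq = seqs$cassette,
    exon2 = exon2,
    exon2_head = iv(exon2["start"], exon2["start"] + 290L),
    analysis_window = analysis_window,
    flank_left = flank_left,
    flank_right = flank_right,
    cassette_inserted = iv(cassette_inserted[1], cassette_inserted[2]),
    seed = as.integer(seed)
  ), class = "locus_model")

  stopifnot(
    iv_contains(model$analysis_window, model$exon2),
    iv_disjoint(model$flank_left, model$exon2),
    iv_disjoint(model$flank_right, model$exon2)
  )
  model
}

#' @export
print.locus_model <- function(x, ...) {
  cat("Toy knock-in locus model\n")
  cat(sprintf("  genome contig: %d bp; cassette: %d bp (inserted [%d,%d))\n",
              nchar(x$genome_seq), nchar(x$cassette_seq),
              x$cassette_inserted["start"], x$cassette_inserted["end"]))
  cat(sprintf("  exon2 [%d,%d), analysis window [%d,%d)\n",
              x$exon2["start"], x$exon2["end"],
              x$analysis_window["start"], x$analysis_window["end"]))
  invisible(x)
}

#' Haplotype sequences implied by the locus model
#'
#' The wild-type haplotype is the genome contig as-is; the knock-in haplotype
#' has `exon2` replaced by the inserted cassette segment.
#'
#' @param model a [make_locus_model()] object.
#' @return named character vector `c(wt = , ki = )`.
#' @export
haplotype_seqs <- function(model) {
  stopifnot(inherits(model, "locus_model"))
  ins <- seq_slice(model$cassette_seq, model$cassette_inserted)
  ki <- paste0(
    substr(model$genome_seq, 1L, model$exon2["start"]),
    ins,
    substr(model$genome_seq, model$exon2["end"] + 1L, nchar(model$genome_seq))
  )
  c(wt = model$genome_seq, ki = ki)
}
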