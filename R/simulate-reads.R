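# Toy-scale paired-end whole-genome read simulation from the diploid locus.

#' Simulate paired-end WGS fragments from a diploid toy locus
#'
#' Fragments are drawn uniformly from the two haplotypes implied by the
#' genotype (50:50 in expectation for a heterozygote), with truncated-normal
#' fragment lengths, FR mate orientation, per-base substitution errors and
#' optional PCR duplicates (re-emissions of already-chosen fragments; errors
#' are re-applied independently, as for real PCR copies).
#'
#' @param model a [make_locus_model()] object.
#' @param genotype `"WT_WT"`, `"KI_WT"` or `"KI_KI"`.
#' @param n_fragments number of distinct fragments (>= 1).
#' @param fragment_mean,fragment_sd fragment length distribution (bp).
#' @param read_len read length (bp), must be < `fragment_mean`.
#' @param error_rate per-base substitution probability.
#' @param dup_rate fraction of extra duplicate fragments emitted, relative to
#'   `n_fragments`.
#' @param seed integer seed.
#' @return an object of class `wgs_readpairs`: list with `reads` (data.frame
#'   of template_id, haplotype, start, fragment_length, r1, r2, is_duplicate)
#'   and the simulation parameters. Ground truth columns are retained for
#'   testing; they are not consumed by the analysis stages.
#' @export
simulate_wgs_readpairs <- function(model, genotype, n_fragments,
                                   fragment_mean = 350, fragment_sd = 50,
                                   read_len = 75, error_rate = 1e-3,
                                   dup_rate = 0, seed = 1L) {
  stopifnot(inherits(model, "locus_model"))
  genotype <- match.arg(genotype, GENOTYPES)
  if (n_fragments < 1) stop("n_fragments must be >= 1")
  if (read_len >= fragment_mean) stop("read_len must be < fragment_mean")
  haps <- haplotype_seqs(model)
  counts <- allele_counts(genotype)
  hap_pool <- rep(c("wt", "ki"), counts)
  if (any(nchar(haps[unique(hap_pool)]) == 0)) stop("empty haplotype sequence")

  with_seed(seed, {
    hap <- sample(hap_pool, n_fragments, replace = TRUE)
    flen <- round(stats::rnorm(n_fragments, fragment_mean, fragment_sd))
    flen <- pmax(flen, read_len)            # truncate below at read length
    flen <- pmin(flen, nchar(haps[hap]))
    start <- floor(stats::runif(n_fragments) * (nchar(haps[hap]) - flen + 1))

    n_dup <- floor(dup_rate * n_fragments)
    if (n_dup > 0) {
      src <- sample.int(n_fragments, n_dup, replace = TRUE)
      hap <- c(hap, hap[src]); flen <- c(flen, flen[src])
      start <- c(start, start[src])
      is_dup <- c(rep(FALSE, n_fragments), rep(TRUE, n_dup))
    } else {
      is_dup <- rep(FALSE, n_fragments)
    }
    n <- length(start)

    r1 <- substring(haps[hap], start + 1, start + read_len)
    r2 <- revcomp(substring(haps[hap], start + flen - read_len + 1, start + flen))
    if (error_rate > 0) {
      r1 <- add_seq_errors(r1, error_rate)
      r2 <- add_seq_errors(r2, error_rate)
    }
    reads <- data.frame(
      template_id = sprintf("frag%06d", seq_len(n)),
      haplotype = hap, start = as.integer(start),
      fragment_length = as.integer(flen),
      r1 = r1, r2 = r2, is_duplicate = is_dup,
      stringsAsFactors = FALSE
    )
    structure(list(reads = reads, read_len = as.integer(read_len),
                   fragment_mean = fragment_mean, genotype = genotype,
                   seed = as.integer(seed)),
              class = "wgs_readpairs")
  })
}

# Apply iid per-base substitution errors to a character vector of sequences.
add_seq_errors <- function(seqs, rate) {
  L <- nchar(seqs[1])
  n_err <- stats::rbinom(length(seqs), L, rate)
  idx <- which(n_err > 0)
  for (i in idx) {
    pos <- sample.int(L, n_err[i])
    s <- strsplit(seqs[i], "")[[1]]
    for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

#' @export
print.wgs_readpairs <- function(x, ...) {
  cat(sprintf("wgs_readpairs: %d pairs (%d duplicates), genotype %s, %d bp reads\n",
              nrow(x$reads), sum(x$reads$is_duplicate), x$genotype, x$read_len))
  invisible(x)
}

#' Write simulated read pairs as a pair of FASTQ files
#'
#' @param x a [simulate_wgs_readpairs()] object.
#' @param prefix output path prefix; `<prefix>_R1.fastq` / `<prefix>_R2.fastq`.
#' @return invisibly, the two file paths.
#' @export
write_fastq_pair <- function(x, prefix) {
  stopifnot(inherits(x, "wgs_readpairs"))
  qual <- strrep("F", x$read_len)
  files <- paste0(prefix, c("_R1.fastq", "_R2.fastq"))
  for (m in 1:2) {
    seqs <- if (m == 1) x$reads$r1 else x$reads$r2
    lines <- as.vector(rbind(paste0("@", x$reads$template_id, "/", m),
                             seqs, "+", qual))
    writeLines(lines, files[m])
  }
  invisible(files)
}

#' Read a FASTQ pair back into a `wgs_readpairs`-like read set
#'
#' Truth columns are absent; only names and sequences are recovered.
#' @param prefix path prefix used by [write_fastq_pair()].
#' @param read_len read length (bp) recorded on the object.
#' @param fragment_mean nominal fragment length, used by the aligner's
#'   proper-pair rule.
#' @return a `wgs_readpairs` object without ground-truth columns.
#' @export
read_fastq_pair <- function(prefix, read_len = 75, fragment_mean = 350) {
  parse1 <- function(path) {
    ln <- readLines(path)
    if (length(ln) %% 4 != 0) stop("malformed FASTQ: ", path)
    list(id = sub("^@", "", sub("/[12]$", "", ln[seq(1, length(ln), 4)])),
         seq = toupper(ln[seq(2, length(ln), 4)]))
  }
  a <- parse1(paste0(prefix, "_R1.fastq"))
  b <- parse1(paste0(prefix, "_R2.fastq"))
  stopifnot(identical(a$id, b$id))
  reads <- data.frame(template_id = a$id, haplotype = NA_character_,
                      start = NA_integer_, fragment_length = NA_integer_,
                      r1 = a$seq, r2 = b$seq, is_duplicate = NA,
                      stringsAsFactors = FALSE)
  structure(list(reads = reads, read_len = as.integer(read_len),
                 fragment_mean = fragment_mean, genotype = NA, seed = NA),
            class = "wgs_readpairs")
}
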