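# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so simulators are deterministic for a
#' given `seed` without clobbering the caller's RNG stream. `seed = NULL`
#' leaves the current stream untouched.
#'
#' @param seed integer seed or `NULL`.
#' @param code code to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# 0-based half-open interval [start, end)
iv <- function(start, end) {
  stopifnot(length(start) == 1L, length(end) == 1L, end >= start)
  c(start = as.integer(start), end = as.integer(end))
}

iv_len <- function(x) unname(x["end"] - x["start"])

iv_contains <- function(outer, inner) {
  inner["start"] >= outer["start"] && inner["end"] <= outer["end"]
}

iv_disjoint <- function(a, b) {
  a["end"] <= b["start"] || b["end"] <= a["start"]
}

# Extract [start, end) (0-based half-open) from a character sequence.
seq_slice <- function(seq, interval) {
  substr(seq, interval["start"] + 1L, interval["end"])
}

# Vectorised reverse complement of character DNA sequences.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

GENOTYPES <- c("WT_WT", "KI_WT", "KI_KI")

#' Allele copy numbers of a knock-in genotype
#'
#' @param genotype one of `"WT_WT"`, `"KI_WT"`, `"KI_KI"`.
#' @return named integer vector `c(wt = , ki = )`.
#' @export
allele_counts <- function(genotype) {
  genotype <- match.arg(genotype, GENOTYPES)
  switch(genotype,
    WT_WT = c(wt = 2L, ki = 0L),
    KI_WT = c(wt = 1L, ki = 1L),
    KI_KI = c(wt = 0L, ki = 2L)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
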