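# In-silico PCR genotyping: primer-site search, amplicon prediction and the
# wt/mutant/long band logic that distinguishes WT_WT, KI_WT and KI_KI.

#' Construct a primer
#'
#' @param name primer name.
#' @param sequence 5'->3' nucleotide sequence (ACGT).
#' @param role one of `"common"`, `"wt_reverse"`, `"mutant_reverse"`,
#'   `"long_target"`.
#' @return object of class `primer`.
#' @export
primer <- function(name, sequence, role = c("common", "wt_reverse",
                                            "mutant_reverse", "long_target")) {
  role <- match.arg(role)
  sequence <- toupper(gsub("[ ′-]", "", sequence))
  if (!nzchar(sequence) || grepl("[^ACGT]", sequence))
    stop("primer sequence must be non-empty ACGT")
  structure(list(name = name, sequence = sequence, role = role),
            class = "primer")
}

#' Find primer binding sites on a template
#'
#' Forward sites are plus-strand matches of the primer; reverse sites are
#' plus-strand matches of its reverse complement (the primer then primes the
#' minus strand). Up to `max_mismatch` substitutions, no indels.
#'
#' @param template template sequence (character).
#' @param prm a [primer()].
#' @param max_mismatch allowed substitutions.
#' @return data.frame with `position` (0-based start of the site on the plus
#'   strand) and `strand` (`"+"` forward / `"-"` reverse).
#' @export
find_primer_sites <- function(template, prm, max_mismatch = 0L) {
  stopifnot(inherits(prm, "primer"))
  subj <- Biostrings::DNAString(template)
  fwd <- Biostrings::matchPattern(prm$sequence, subj,
                                  max.mismatch = max_mismatch)
  rev <- Biostrings::matchPattern(revcomp(prm$sequence), subj,
                                  max.mismatch = max_mismatch)
  data.frame(
    position = c(BiocGenerics::start(fwd), BiocGenerics::start(rev)) - 1L,
    strand = rep(c("+", "-"), c(length(fwd), length(rev))),
    stringsAsFactors = FALSE
  )
}

#' Predict PCR amplicons for a primer pair on one template
#'
#' Every (forward-oriented site of `forward`, downstream reverse-oriented
#' site of `reverse`) combination with outer-edge span at most `max_len`
#' yields a product. Product length is outer edge to outer edge, i.e.
#' includes both primers, matching gel sizing. Either primer may provide the
#' forward-strand site.
#'
#' @param template template sequence.
#' @param forward,reverse [primer()] objects.
#' @param max_len maximum product length (bp).
#' @param max_mismatch allowed substitutions per site.
#' @param template_id label recorded on the predictions.
#' @return data.frame of class `amplicon_prediction`: template, pair, start,
#'   end (0-based half-open product interval), length.
#' @export
predict_amplicons <- function(template, forward, reverse, max_len = 10000L,
                              max_mismatch = 0L, template_id = "template") {
  s_f <- find_primer_sites(template, forward, max_mismatch)
  s_r <- find_primer_sites(template, reverse, max_mismatch)
  lens <- c(forward = nchar(forward$sequence), reverse = nchar(reverse$sequence))
  out <- list()
  combos <- list(list(plus = s_f[s_f$strand == "+", ], plus_len = lens["forward"],
                      minus = s_r[s_r$strand == "-", ], minus_len = lens["reverse"]),
                 list(plus = s_r[s_r$strand == "+", ], plus_len = lens["reverse"],
                      minus = s_f[s_f$strand == "-", ], minus_len = lens["forward"]))
  for (cb in combos) {
    if (nrow(cb$plus) == 0 || nrow(cb$minus) == 0) next
    for (i in seq_len(nrow(cb$plus))) {
      p <- cb$plus$position[i]
      ends <- cb$minus$position + cb$minus_len      # outer (3'->5') edge
      ok <- cb$minus$position >= p + cb$plus_len & (ends - p) <= max_len
      for (e in ends[ok]) {
        out[[length(out) + 1L]] <- data.frame(
          template = template_id,
          pair = paste(forward$name, reverse$name, sep = "/"),
          start = p, end = as.integer(e), length = as.integer(e - p),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(template = character(0), pair = character(0),
               start = integer(0), end = integer(0), length = integer(0),
               stringsAsFactors = FALSE)
  class(res) <- c("amplicon_prediction", class(res))
  res
}

#' Default synthetic primer set for a toy locus
#'
#' Mirrors the layout of the real genotyping design: a common forward primer
#' upstream of the exon (present on both haplotypes), a wild-type reverse
#' primer inside the exon (wt allele only), a mutant reverse primer inside
#' the inserted cassette (ki allele only), and a long-range reverse primer
#' downstream of the exon spanning the whole insertion. Primer sequences are
#' taken verbatim from the generated locus so they bind uniquely.
#'
#' @param model a `locus_model`.
#' @param primer_len primer length in bp.
#' @return named list of [primer()]s: `common`, `wt_reverse`,
#'   `mutant_reverse`, `long_target`.
#' @export
default_primer_set <- function(model, primer_len = 20L) {
  stopifnot(inherits(model, "locus_model"))
  e1 <- unname(model$exon2["start"]); e2 <- unname(model$exon2["end"])
  ins <- seq_slice(model$cassette_seq, model$cassette_inserted)
  g <- model$genome_seq
  site <- function(seq, at) substr(seq, at + 1L, at + primer_len)
  list(
    common = primer("common", site(g, e1 - 200L), "common"),
    wt_reverse = primer("wt_reverse", revcomp(site(g, e1 + 400L)), "wt_reverse"),
    mutant_reverse = primer("mutant_reverse", revcomp(site(ins, 2000L)),
                            "mutant_reverse"),
    long_target = primer("long_target", revcomp(site(g, e2 + 200L)),
                         "long_target")
  )
}

#' Band pattern of a genotype for a primer set
#'
#' Runs [predict_amplicons()] on each haplotype implied by the genotype with
#' (common, wt_reverse), (common, mutant_reverse) and (common, long_target)
#' pairings. A band is present iff any haplotype yields a product; the long
#' pair reports the per-haplotype product sizes (the insertion shifts them).
#'
#' @param model a `locus_model`.
#' @param primers a primer set as from [default_primer_set()].
#' @param genotype `"WT_WT"`, `"KI_WT"` or `"KI_KI"`.
#' @param max_len maximum amplifiable product (bp).
#' @return list with logical `wt_band`, `mutant_band`, `long_band` and
#'   `long_sizes` (integer vector of distinct long-pair product lengths).
#' @export
genotype_from_bands <- function(model, primers, genotype, max_len = 10000L) {
  genotype <- match.arg(genotype, GENOTYPES)
  haps <- haplotype_seqs(model)
  present <- unique(names(allele_counts(genotype))[allele_counts(genotype) > 0])
  amp <- function(rev_primer) {
    do.call(rbind, lapply(present, function(h)
      predict_amplicons(haps[[h]], primers$common, rev_primer,
                        max_len = max_len, template_id = h)))
  }
  wt <- amp(primers$wt_reverse)
  mut <- amp(primers$mutant_reverse)
  lng <- amp(primers$long_target)
  list(wt_band = nrow(wt) > 0, mutant_band = nrow(mut) > 0,
       long_band = nrow(lng) > 0,
       long_sizes = sort(unique(lng$length)))
}

#' Printed genotyping primers shipped as a fixture
#'
#' The published primer sequences for the CreER-Eyfp and DTA assays, stored
#' as CSV. They bind the real mouse locus (not shipped); unit tests exercise
#' the site matcher against short synthetic neighbourhood stubs.
#'
#' @return data.frame with assay, name, role, sequence.
#' @export
printed_primers <- function() {
  path <- system.file("extdata", "genotyping_primers.csv",
                      package = "microgliaLOH", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Render a text "virtual gel" for band patterns
#' @param patterns named list of [genotype_from_bands()] results.
#' @return character vector of gel lines (also printed).
#' @export
virtual_gel <- function(patterns) {
  lines <- c(sprintf("%-8s %-8s %-8s %-8s", "lane", "wt", "mutant", "long"))
  for (nm in names(patterns)) {
    p <- patterns[[nm]]
    band <- function(b) if (isTRUE(b)) "====" else "    "
    lines <- c(lines, sprintf("%-8s %-8s %-8s %-8s", nm,
                              band(p$wt_band), band(p$mutant_band),
                              band(p$long_band)))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
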