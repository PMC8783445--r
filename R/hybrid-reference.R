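# Hybrid mapping reference: genome contig plus the inserted (non-genomic)
# cassette segment as a separate contig, with named analysis regions and a
# coordinate map between knock-in haplotype and hybrid coordinates.

#' Build the hybrid reference and coordinate map
#'
#' The mapping reference consists of the unmodified genome contig (which
#' retains the wild-type exon) and a `cassette_nongenomic` contig holding
#' exactly the cassette segment that is integrated into the genome. Named
#' regions used downstream (exon2, its first 290 bp head, the analysis
#' window, both flanks, and the cassette) are attached, together with a
#' coordinate map relating knock-in haplotype positions to hybrid contig
#' positions.
#'
#' @param model a [make_locus_model()] object.
#' @return an object of class `reference_set`: `contigs` (named character
#'   sequences), `regions` (named list of `list(contig, interval)`), and
#'   `coord_map` (junction positions plus segment table).
#' @export
build_hybrid_reference <- function(model) {
  stopifnot(inherits(model, "locus_model"))
  ins <- seq_slice(model$cassette_seq, model$cassette_inserted)
  ins_len <- nchar(ins)
  e1 <- unname(model$exon2["start"]); e2 <- unname(model$exon2["end"])
  glen <- nchar(model$genome_seq)

  regions <- list(
    exon2 = list(contig = "genome", interval = model$exon2),
    exon2_head = list(contig = "genome", interval = model$exon2_head),
    insertion_window = list(contig = "genome", interval = model$analysis_window),
    flank_left = list(contig = "genome", interval = model$flank_left),
    flank_right = list(contig = "genome", interval = model$flank_right),
    cassette_inserted = list(contig = "cassette_nongenomic",
                             interval = iv(0L, ins_len))
  )
  # knock-in haplotype segments: [0,e1) -> genome[0,e1); [e1, e1+ins_len) ->
  # cassette[0, ins_len); [e1+ins_len, ...) -> genome[e2, glen)
  segs <- data.frame(
    ki_start = c(0L, e1, e1 + ins_len),
    ki_end = c(e1, e1 + ins_len, e1 + ins_len + (glen - e2)),
    contig = c("genome", "cassette_nongenomic", "genome"),
    contig_start = c(0L, 0L, e2),
    stringsAsFactors = FALSE
  )
  coord_map <- list(junction_left = e1, junction_right = e2, segments = segs)
  structure(list(
    contigs = c(genome = model$genome_seq, cassette_nongenomic = ins),
    regions = regions, coord_map = coord_map
  ), class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat("Hybrid reference set\n")
  for (nm in names(x$contigs))
    cat(sprintf("  contig %s: %d bp\n", nm, nchar(x$contigs[[nm]])))
  cat("  regions:", paste(names(x$regions), collapse = ", "), "\n")
  invisible(x)
}

#' Look up a named analysis region
#'
#' @param ref a [build_hybrid_reference()] object.
#' @param name region name.
#' @return `list(contig, interval)`; the interval is 0-based half-open.
#' @export
region_lookup <- function(ref, name) {
  stopifnot(inherits(ref, "reference_set"))
  if (!name %in% names(ref$regions))
    stop("unknown region: ", name, " (known: ",
         paste(names(ref$regions), collapse = ", "), ")")
  ref$regions[[name]]
}

#' Map a knock-in haplotype position to hybrid reference coordinates
#' @param ref a `reference_set`.
#' @param pos 0-based position(s) on the knock-in haplotype.
#' @return data.frame with `contig` and `pos` (0-based).
#' @export
ki_to_hybrid <- function(ref, pos) {
  segs <- ref$coord_map$segments
  idx <- findInterval(pos, segs$ki_start)
  if (any(idx < 1 | pos >= segs$ki_end[idx]))
    stop("position outside knock-in haplotype bounds")
  data.frame(contig = segs$contig[idx],
             pos = as.integer(segs$contig_start[idx] + (pos - segs$ki_start[idx])),
             stringsAsFactors = FALSE)
}

#' Map hybrid reference coordinates back to the knock-in haplotype
#' @param ref a `reference_set`.
#' @param contig,pos contig name(s) and 0-based position(s).
#' @return integer positions on the knock-in haplotype (`NA` where the
#'   position has no knock-in image, e.g. inside the replaced exon).
#' @export
hybrid_to_ki <- function(ref, contig, pos) {
  segs <- ref$coord_map$segments
  out <- rep(NA_integer_, length(pos))
  for (i in seq_len(nrow(segs))) {
    len <- segs$ki_end[i] - segs$ki_start[i]
    hit <- contig == segs$contig[i] & pos >= segs$contig_start[i] &
      pos < segs$contig_start[i] + len
    out[hit] <- as.integer(segs$ki_start[i] + (pos[hit] - segs$contig_start[i]))
  }
  out
}

#' Write a reference set as wrapped FASTA
#'
#' @param ref a `reference_set` (or any named character vector of sequences
#'   via `contigs`).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(ref, path) {
  contigs <- if (inherits(ref, "reference_set")) ref$contigs else ref
  dss <- Biostrings::DNAStringSet(unlist(contigs))
  names(dss) <- names(contigs)
  Biostrings::writeXStringSet(dss, path, width = 60L)
  invisible(path)
}

#' Read a FASTA file into a plain contig set
#'
#' Sequences are upper-cased on read. Regions/coordinate map are not part of
#' the FASTA representation; use [build_hybrid_reference()] to regenerate
#' them from a locus model.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  dss <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e)))
  out <- toupper(as.character(dss))
  names(out) <- names(dss)
  out
}

#' Export the named regions as a BED file (0-based half-open)
#' @param ref a `reference_set`.
#' @param path output BED path.
#' @return invisibly, `path`.
#' @export
write_regions_bed <- function(ref, path) {
  stopifnot(inherits(ref, "reference_set"))
  rows <- vapply(names(ref$regions), function(nm) {
    r <- ref$regions[[nm]]
    sprintf("%s\t%d\t%d\t%s", r$contig, r$interval["start"], r$interval["end"], nm)
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}

#' Read a regions BED file written by [write_regions_bed()]
#' @param path BED path.
#' @return named list of `list(contig, interval)`.
#' @export
read_regions_bed <- function(path) {
  tb <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("contig", "start", "end", "name"))
  out <- lapply(seq_len(nrow(tb)), function(i)
    list(contig = tb$contig[i], interval = iv(tb$start[i], tb$end[i])))
  names(out) <- tb$name
  out
}
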