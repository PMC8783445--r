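# Toy seed-and-extend alignment of simulated read pairs to the hybrid
# reference, with a binary MAPQ model (60 unique best placement / 0
# ambiguous), duplicate marking by fragment key, and the MAPQ < 20 /
# duplicate filters applied before coverage analysis.

# Build an exact k-mer index over all contigs.
# Returns list(kmer_env, contigs_raw, contig_names, contig_len).
build_kmer_index <- function(contigs, k) {
  contig_names <- names(contigs)
  kmers <- character(0); where <- integer(0); which_contig <- integer(0)
  for (ci in seq_along(contigs)) {
    s <- contigs[[ci]]
    n <- nchar(s) - k + 1L
    if (n < 1L) next
    km <- substring(s, seq_len(n), seq_len(n) + k - 1L)
    kmers <- c(kmers, km)
    where <- c(where, seq_len(n) - 1L)      # 0-based
    which_contig <- c(which_contig, rep.int(ci, n))
  }
  code <- (which_contig - 1L) * 2^28 + where   # pack (contig, pos)
  env <- new.env(hash = TRUE, size = length(kmers))
  grp <- split(code, kmers)
  list2env(grp, envir = env)
  list(env = env, contigs_raw = lapply(contigs, charToRaw),
       contig_names = contig_names,
       contig_len = vapply(contigs, nchar, integer(1)))
}

# Align one vector of reads (all same length). Returns data.frame
# (contig, pos, strand, mm, mapq); NA contig = unmapped.
align_reads <- function(reads, index, k, max_mismatch) {
  n <- length(reads); L <- nchar(reads[1])
  offsets <- unique(pmin(c(0L, (L - k) %/% 2L, L - k), L - k))
  offsets <- offsets[offsets >= 0L]
  rc <- revcomp(reads)
  out <- data.frame(contig = rep(NA_character_, n), pos = NA_integer_,
                    strand = NA_character_, mm = NA_integer_,
                    mapq = NA_integer_, stringsAsFactors = FALSE)
  # candidate codes per read x strand, gathered via vectorised env lookup
  cand <- vector("list", n)
  strands <- c("+", "-")
  for (si in 1:2) {
    sreads <- if (si == 1) reads else rc
    for (off in offsets) {
      keys <- substring(sreads, off + 1L, off + k)
      hits <- mget(keys, envir = index$env, ifnotfound = list(NULL))
      for (i in which(!vapply(hits, is.null, logical(1)))) {
        cand[[i]] <- c(cand[[i]], (hits[[i]] - off) + (si - 1) * 2^40)
      }
    }
  }
  raw_reads <- lapply(reads, charToRaw)
  raw_rc <- lapply(rc, charToRaw)
  for (i in seq_len(n)) {
    cc <- unique(cand[[i]])
    if (length(cc) == 0) next
    si <- ifelse(cc >= 2^40, 2L, 1L)
    code <- cc - (si - 1) * 2^40
    ci <- code %/% 2^28 + 1L
    pos <- code %% 2^28
    ok <- ci >= 1 & ci <= length(index$contig_len)
    ok[ok] <- pos[ok] >= 0 & pos[ok] + L <= index$contig_len[ci[ok]]
    if (!any(ok)) next
    si <- si[ok]; ci <- ci[ok]; pos <- pos[ok]
    mm <- integer(length(pos))
    for (j in seq_along(pos)) {
      rr <- if (si[j] == 1) raw_reads[[i]] else raw_rc[[i]]
      mm[j] <- sum(index$contigs_raw[[ci[j]]][(pos[j] + 1):(pos[j] + L)] != rr)
    }
    best <- min(mm)
    if (best > max_mismatch) next
    hit <- which(mm == best)
    b <- hit[1]
    out$contig[i] <- index$contig_names[ci[b]]
    out$pos[i] <- as.integer(pos[b])
    out$strand[i] <- strands[si[b]]
    out$mm[i] <- best
    out$mapq[i] <- if (length(hit) == 1L) 60L else 0L
  }
  out
}

#' Map simulated read pairs to the hybrid reference
#'
#' Exact-seed (k-mer) candidate lookup with full-length mismatch extension;
#' unique best placement gets MAPQ 60, ties MAPQ 0, no placement within
#' `max_mismatch` substitutions leaves the mate unmapped. A pair is flagged
#' proper when both mates map to one contig in FR orientation with an outer
#' span below `10 * fragment_mean`.
#'
#' @param reads a `wgs_readpairs` object.
#' @param ref a `reference_set`.
#' @param k exact seed length.
#' @param max_mismatch maximum substitutions for a valid placement.
#' @return an object of class `alignment_set`.
#' @export
map_readpairs <- function(reads, ref, k = 31L, max_mismatch = 6L) {
  stopifnot(inherits(reads, "wgs_readpairs"), inherits(ref, "reference_set"))
  if (length(ref$contigs) == 0 || all(nchar(ref$contigs) == 0))
    stop("empty reference")
  if (nrow(reads$reads) == 0) stop("no reads to map")
  index <- build_kmer_index(as.list(ref$contigs), k)
  a1 <- align_reads(reads$reads$r1, index, k, max_mismatch)
  a2 <- align_reads(reads$reads$r2, index, k, max_mismatch)
  L <- reads$read_len
  rec <- data.frame(
    template_id = reads$reads$template_id,
    r1_contig = a1$contig, r1_pos = a1$pos, r1_strand = a1$strand,
    r1_mm = a1$mm, r1_mapq = a1$mapq,
    r2_contig = a2$contig, r2_pos = a2$pos, r2_strand = a2$strand,
    r2_mm = a2$mm, r2_mapq = a2$mapq,
    stringsAsFactors = FALSE
  )
  both <- !is.na(rec$r1_contig) & !is.na(rec$r2_contig)
  same <- both & rec$r1_contig == rec$r2_contig
  fr <- same & rec$r1_strand != rec$r2_strand
  fs <- ifelse(fr, pmin(rec$r1_pos, rec$r2_pos), NA_integer_)
  fe <- ifelse(fr, pmax(rec$r1_pos, rec$r2_pos) + L, NA_integer_)
  # FR: leftmost mate on +, rightmost on -
  left_plus <- fr & ifelse(rec$r1_pos <= rec$r2_pos,
                           rec$r1_strand == "+", rec$r2_strand == "+")
  proper <- fr & left_plus & (fe - fs) <= 10 * reads$fragment_mean
  rec$contig <- ifelse(same, rec$r1_contig, NA_character_)
  rec$fragment_start <- ifelse(proper, fs, NA_integer_)
  rec$fragment_end <- ifelse(proper, fe, NA_integer_)
  rec$proper <- proper
  rec$mapq <- pmin(rec$r1_mapq, rec$r2_mapq)
  rec$duplicate <- FALSE
  rec$bqsum <- 2L * L * 37L   # constant 'F' base qualities from the simulator
  structure(list(records = rec,
                 contig_len = vapply(ref$contigs, nchar, integer(1)),
                 read_len = L, fragment_mean = reads$fragment_mean,
                 provenance = character(0)),
            class = "alignment_set")
}

#' @export
print.alignment_set <- function(x, ...) {
  r <- x$records
  cat(sprintf("alignment_set: %d templates, %d proper pairs, %d flagged duplicate\n",
              nrow(r), sum(r$proper), sum(r$duplicate)))
  if (length(x$provenance)) cat(paste0("  ", x$provenance, collapse = "\n"), "\n")
  invisible(x)
}

#' Mark PCR duplicates by fragment key
#'
#' Duplicate key is (contig, fragment start, fragment end, strand
#' orientation) over proper pairs; within each key the record with the
#' highest base-quality sum is kept (lexicographically smallest template id
#' on ties) and the rest are flagged. Flags are recomputed from scratch, so
#' the operation is idempotent and never removes records.
#'
#' @param aln an `alignment_set`.
#' @return the `alignment_set` with `duplicate` flags set.
#' @export
mark_duplicates <- function(aln) {
  stopifnot(inherits(aln, "alignment_set"))
  r <- aln$records
  r$duplicate <- FALSE
  p <- which(r$proper)
  if (length(p)) {
    orient <- ifelse(r$r1_pos[p] <= r$r2_pos[p],
                     paste0(r$r1_strand[p], r$r2_strand[p]),
                     paste0(r$r2_strand[p], r$r1_strand[p]))
    key <- paste(r$contig[p], r$fragment_start[p], r$fragment_end[p], orient)
    ord <- p[order(key, -r$bqsum[p], r$template_id[p])]
    keysort <- sort(key)
    dupflag <- duplicated(keysort)
    r$duplicate[ord] <- dupflag
  }
  aln$records <- r
  aln
}

#' Filter alignments by duplicate flag, MAPQ and pairing
#'
#' Duplicate-flagged pairs are dropped first, then pairs with MAPQ below
#' `mapq_min` (the "MAPQ < 20" rule). By default only proper pairs are
#' retained; set `require_proper = FALSE` to keep cross-contig pairs, which
#' carry the knock-in junction evidence. Removal counts per reason are
#' appended to the provenance log.
#'
#' @param aln an `alignment_set`.
#' @param mapq_min minimum MAPQ kept (strict `< mapq_min` removal).
#' @param drop_duplicates drop duplicate-flagged pairs.
#' @param require_proper keep only proper pairs.
#' @return the filtered `alignment_set`.
#' @export
filter_alignments <- function(aln, mapq_min = 20L, drop_duplicates = TRUE,
                              require_proper = TRUE) {
  stopifnot(inherits(aln, "alignment_set"))
  r <- aln$records
  n_in <- nrow(r)
  keep <- rep(TRUE, n_in)
  n_dup <- 0L
  if (drop_duplicates) {
    n_dup <- sum(keep & r$duplicate)
    keep <- keep & !r$duplicate
  }
  mq <- ifelse(is.na(r$mapq), -1L, r$mapq)
  n_mapq <- sum(keep & mq < mapq_min)
  keep <- keep & mq >= mapq_min
  n_improper <- 0L
  if (require_proper) {
    n_improper <- sum(keep & !r$proper)
    keep <- keep & r$proper
  }
  aln$records <- r[keep, , drop = FALSE]
  aln$provenance <- c(aln$provenance, sprintf(
    "filter: input=%d removed_duplicate=%d removed_mapq_lt_%d=%d removed_improper=%d output=%d (order: dedup then MAPQ)",
    n_in, n_dup, mapq_min, n_mapq, n_improper, sum(keep)))
  aln
}

#' Write an alignment set as SAM
#'
#' Two lines per template (one per mate) with standard flag bits, 1-based
#' POS, NM mismatch tags and a `dt:i` duplicate-from-simulation free tag
#' omitted; SEQ/QUAL are `*` (sequences are not retained in the set).
#'
#' @param aln an `alignment_set`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_sam <- function(aln, path) {
  stopifnot(inherits(aln, "alignment_set"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (nm in names(aln$contig_len))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm, aln$contig_len[[nm]]), con)
  writeLines(sprintf("@CO\tread_len:%d\tfragment_mean:%g",
                     aln$read_len, aln$fragment_mean), con)
  r <- aln$records
  for (i in seq_len(nrow(r))) {
    for (m in 1:2) {
      ctg <- r[[paste0("r", m, "_contig")]][i]
      pos <- r[[paste0("r", m, "_pos")]][i]
      strand <- r[[paste0("r", m, "_strand")]][i]
      mm <- r[[paste0("r", m, "_mm")]][i]
      mq <- r[[paste0("r", m, "_mapq")]][i]
      octg <- r[[paste0("r", 3 - m, "_contig")]][i]
      opos <- r[[paste0("r", 3 - m, "_pos")]][i]
      ostrand <- r[[paste0("r", 3 - m, "_strand")]][i]
      flag <- 1L + if (m == 1) 64L else 128L
      if (r$proper[i]) flag <- flag + 2L
      if (is.na(ctg)) flag <- flag + 4L
      if (is.na(octg)) flag <- flag + 8L
      if (!is.na(strand) && strand == "-") flag <- flag + 16L
      if (!is.na(ostrand) && ostrand == "-") flag <- flag + 32L
      if (r$duplicate[i]) flag <- flag + 1024L
      tlen <- 0L
      if (r$proper[i]) {
        span <- r$fragment_end[i] - r$fragment_start[i]
        tlen <- if (!is.na(pos) && pos == r$fragment_start[i]) span else -span
      }
      fields <- c(r$template_id[i], flag,
                  if (is.na(ctg)) "*" else ctg,
                  if (is.na(pos)) 0L else pos + 1L,
                  if (is.na(mq)) 0L else mq,
                  if (is.na(ctg)) "*" else sprintf("%dM", aln$read_len),
                  if (is.na(octg)) "*" else if (!is.na(ctg) && octg == ctg) "=" else octg,
                  if (is.na(opos)) 0L else opos + 1L,
                  tlen, "*", "*",
                  if (is.na(mm)) character(0) else sprintf("NM:i:%d", mm))
      writeLines(paste(fields, collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Read a SAM file written by [write_sam()] (or an external aligner)
#'
#' Converts 1-based POS back to internal 0-based coordinates and
#' reconstructs pair-level records (fragment spans from TLEN, MAPQ, proper
#' and duplicate flags).
#'
#' @param path SAM path.
#' @return an `alignment_set`.
#' @export
read_sam <- function(path) {
  ln <- readLines(path)
  hdr <- ln[startsWith(ln, "@")]
  body <- ln[!startsWith(ln, "@")]
  sq <- hdr[startsWith(hdr, "@SQ")]
  if (length(sq) == 0) stop("SAM parse error: missing @SQ header lines")
  contig_len <- sapply(sq, function(s) {
    f <- strsplit(s, "\t")[[1]]
    as.integer(sub("LN:", "", f[startsWith(f, "LN:")]))
  })
  names(contig_len) <- sapply(sq, function(s) {
    f <- strsplit(s, "\t")[[1]]; sub("SN:", "", f[startsWith(f, "SN:")])
  })
  read_len <- 0L; fragment_mean <- 350
  co <- hdr[startsWith(hdr, "@CO")]
  if (length(co)) {
    rl <- regmatches(co[1], regexec("read_len:(\\d+)", co[1]))[[1]]
    if (length(rl) == 2) read_len <- as.integer(rl[2])
    fm <- regmatches(co[1], regexec("fragment_mean:([0-9.]+)", co[1]))[[1]]
    if (length(fm) == 2) fragment_mean <- as.numeric(fm[2])
  }
  if (length(body) == 0) {
    return(structure(list(records = empty_alignment_records(),
                          contig_len = contig_len, read_len = read_len,
                          fragment_mean = fragment_mean,
                          provenance = "read from SAM"),
                     class = "alignment_set"))
  }
  f <- strsplit(body, "\t")
  qname <- vapply(f, `[`, "", 1)
  flag <- as.integer(vapply(f, `[`, "", 2))
  rname <- vapply(f, `[`, "", 3)
  pos1 <- as.integer(vapply(f, `[`, "", 4))
  if (any(pos1 > 2^28, na.rm = TRUE)) stop("SAM parse error: coordinate overflow")
  mapq <- as.integer(vapply(f, `[`, "", 5))
  tlen <- as.integer(vapply(f, `[`, "", 9))
  nm <- vapply(f, function(x) {
    t <- x[startsWith(x, "NM:i:")]
    if (length(t)) as.integer(sub("NM:i:", "", t[1])) else NA_integer_
  }, integer(1))
  first <- bitwAnd(flag, 64L) > 0
  ids <- unique(qname)
  take <- function(sel, what) {
    m <- match(ids, qname[sel])
    what[sel][m]
  }
  mate_df <- function(sel) {
    unmapped <- bitwAnd(flag, 4L) > 0
    data.frame(
      contig = ifelse(take(sel, unmapped), NA_character_, take(sel, rname)),
      pos = ifelse(take(sel, unmapped), NA_integer_, take(sel, pos1) - 1L),
      strand = ifelse(take(sel, unmapped), NA_character_,
                      ifelse(take(sel, bitwAnd(flag, 16L) > 0), "-", "+")),
      mm = take(sel, nm),
      mapq = ifelse(take(sel, unmapped), NA_integer_, take(sel, mapq)),
      stringsAsFactors = FALSE)
  }
  m1 <- mate_df(first); m2 <- mate_df(!first)
  proper <- take(first, bitwAnd(flag, 2L) > 0)
  dup <- take(first, bitwAnd(flag, 1024L) > 0)
  span <- abs(take(first, tlen))
  fs <- ifelse(proper, pmin(m1$pos, m2$pos), NA_integer_)
  rec <- data.frame(
    template_id = ids,
    r1_contig = m1$contig, r1_pos = m1$pos, r1_strand = m1$strand,
    r1_mm = m1$mm, r1_mapq = m1$mapq,
    r2_contig = m2$contig, r2_pos = m2$pos, r2_strand = m2$strand,
    r2_mm = m2$mm, r2_mapq = m2$mapq,
    contig = ifelse(!is.na(m1$contig) & !is.na(m2$contig) &
                      m1$contig == m2$contig, m1$contig, NA_character_),
    fragment_start = fs,
    fragment_end = ifelse(proper, fs + span, NA_integer_),
    proper = proper,
    mapq = pmin(m1$mapq, m2$mapq),
    duplicate = dup,
    bqsum = 2L * read_len * 37L,
    stringsAsFactors = FALSE
  )
  structure(list(records = rec, contig_len = contig_len, read_len = read_len,
                 fragment_mean = fragment_mean, provenance = "read from SAM"),
            class = "alignment_set")
}

empty_alignment_records <- function() {
  data.frame(template_id = character(0), r1_contig = character(0),
             r1_pos = integer(0), r1_strand = character(0),
             r1_mm = integer(0), r1_mapq = integer(0),
             r2_contig = character(0), r2_pos = integer(0),
             r2_strand = character(0), r2_mm = integer(0),
             r2_mapq = integer(0), contig = character(0),
             fragment_start = integer(0), fragment_end = integer(0),
             proper = logical(0), mapq = integer(0), duplicate = logical(0),
             bqsum = integer(0), stringsAsFactors = FALSE)
}
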