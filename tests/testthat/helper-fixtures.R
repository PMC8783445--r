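# Shared fixtures, built once per test run.

fixture_model <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- make_locus_model(seed = 1L)
    m
  }
})

fixture_reference <- local({
  r <- NULL
  function() {
    if (is.null(r)) r <<- build_hybrid_reference(fixture_model())
    r
  }
})

# Small mapped alignment set reused across alignment/coverage tests.
fixture_alignments <- local({
  a <- NULL
  function() {
    if (is.null(a)) {
      reads <- simulate_wgs_readpairs(fixture_model(), "KI_WT",
                                      n_fragments = 800, dup_rate = 0.05,
                                      seed = 7L)
      a <<- mark_duplicates(map_readpairs(reads, fixture_reference()))
    }
    a
  }
})

# Hand-built reference with a segment duplicated on both contigs, for
# ambiguity-rule tests.
make_duplicated_reference <- function(seed = 3L) {
  set.seed(seed)
  rand <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                            collapse = "")
  shared <- rand(400)
  structure(list(
    contigs = c(genome = paste0(rand(800), shared, rand(800)),
                cassette_nongenomic = paste0(rand(200), shared, rand(200))),
    regions = list(),
    coord_map = list(junction_left = 800L, junction_right = 1200L,
                     segments = data.frame())
  ), class = "reference_set")
}

# Minimal read-pair object wrapping explicit R1/R2 sequences.
manual_readpairs <- function(r1, r2, read_len = nchar(r1[1]),
                             fragment_mean = 350) {
  structure(list(
    reads = data.frame(template_id = sprintf("t%03d", seq_along(r1)),
                       haplotype = NA, start = NA_integer_,
                       fragment_length = NA_integer_, r1 = r1, r2 = r2,
                       is_duplicate = FALSE, stringsAsFactors = FALSE),
    read_len = as.integer(read_len), fragment_mean = fragment_mean,
    genotype = NA, seed = NA), class = "wgs_readpairs")
}

# Logical-matrix skeleton from (row, col) coordinates.
mask_from_coords <- function(coords, nr, nc, pixel_size = 1) {
  m <- matrix(FALSE, nr, nc)
  m[coords] <- TRUE
  structure(m, pixel_size = pixel_size,
            class = c("binary_mask", "matrix"))
}
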